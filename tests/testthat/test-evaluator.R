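# helpers building tiny in-memory fixtures ---------------------------------

tiny_reference <- function(seq, name = "c1") {
  structure(stats::setNames(seq, name), class = "reference_genome")
}

write_tiny_sam <- function(sam, contig_lengths) {
  path <- tempfile(fileext = ".sam")
  write_sam(sam, contig_lengths, path)
  path
}

sam_row <- function(qname, pos, seq, qual = strrep("5", nchar(seq)),
                    flag = 0L, cigar = paste0(nchar(seq), "M"),
                    rname = "c1", mapq = 60L) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = "*", pnext = 0L, tlen = 0L,
             seq = seq, qual = qual, stringsAsFactors = FALSE)
}

test_that("read collection keeps overlapping reads and converts qualities", {
  refseq <- strrep("ACGT", 30)
  sam <- rbind(
    sam_row("left",  1L, substr(refseq, 1, 10)),    # ends at 10 < span
    sam_row("over",  18L, substr(refseq, 18, 27)),  # overlaps
    sam_row("right", 40L, substr(refseq, 40, 49)))  # starts after span
  aln <- load_alignments(write_tiny_sam(sam, c(c1 = 120L)))
  reads <- collect_reads(aln, "c1", 19L, 21L)       # 0-based span [19, 21)
  expect_length(reads, 1)
  expect_equal(reads[[1]]$read_id, "over/0")
  # Phred "5" is Q20: e = 0.01
  expect_equal(reads[[1]]$error_probs, rep(0.01, 10))
  expect_equal(reads[[1]]$pos, 17L)                 # 0-based
})

test_that("soft-clipped bases are trimmed before scoring", {
  refseq <- strrep("ACGT", 30)
  sam <- sam_row("sc", 21L, paste0("TTT", substr(refseq, 21, 30)),
                 cigar = "3S10M")
  aln <- load_alignments(write_tiny_sam(sam, c(c1 = 120L)))
  reads <- collect_reads(aln, "c1", 22L, 25L)
  expect_equal(reads[[1]]$called_seq, substr(refseq, 21, 30))
  expect_length(reads[[1]]$error_probs, 10)
})

test_that("duplicate-flagged reads are excluded unless kept", {
  refseq <- strrep("ACGT", 30)
  sam <- rbind(sam_row("a", 18L, substr(refseq, 18, 27)),
               sam_row("b", 18L, substr(refseq, 18, 27), flag = 1024L))
  aln <- load_alignments(write_tiny_sam(sam, c(c1 = 120L)))
  expect_length(collect_reads(aln, "c1", 19L, 21L), 1)
  expect_length(collect_reads(aln, "c1", 19L, 21L, keep_duplicates = TRUE), 2)
})

test_that("secondary alignments feed multiplicity and paralog locations", {
  refseq <- strrep("ACGT", 50)
  sam <- rbind(sam_row("m", 18L, substr(refseq, 18, 27)),
               sam_row("m", 118L, substr(refseq, 18, 27), flag = 256L))
  aln <- load_alignments(write_tiny_sam(sam, c(c1 = 400L)))
  reads <- collect_reads(aln, "c1", 19L, 21L)
  expect_length(reads, 1)
  expect_equal(reads[[1]]$multiplicity, 2L)
  expect_equal(reads[[1]]$other_locations$pos, 117L)
})

test_that("simulated coverage yields the expected read yield over a window", {
  sim <- simulate_dataset(sim_config(contig_length = 20000, n_snps = 2,
                                     n_insertions = 0, n_deletions = 0,
                                     n_decoys = 0, seed = 3),
                          outdir = tempfile())
  aln <- load_alignments(sim$paths[["alignments"]])
  reads <- collect_reads(aln, "sim1", 8000L, 9000L)
  # reads overlapping a 1 kb window at 30x, l = 100: about 30*(1000+99)/100
  expected <- 30 * (1000 + 99) / 100
  expect_gt(length(reads), 0.8 * expected)
  expect_lt(length(reads), 1.2 * expected)
})

test_that("cluster scoring recovers the generating hypothesis", {
  set.seed(17)
  hits <- c(ref = 0L, hom = 0L)
  for (trial in 1:8) {
    refseq <- random_window(600)
    v <- data.frame(contig = "c1", pos = 300L,
                    ref = substr(refseq, 300, 300), alt = "", source_id = 1L,
                    stringsAsFactors = FALSE)
    v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
    cl <- cluster_variants(v)[[1]]
    hyps <- enumerate_hypotheses(cl)
    wins <- lapply(hyps, function(h)
      build_haplotype_window(refseq, cl, h$subset, 40L))
    altseq <- paste0(substr(refseq, 1, 299), v$alt, substr(refseq, 301, 600))
    mk_reads <- function(src) lapply(1:20, function(i) {
      st <- sample(260:300, 1)
      chars <- strsplit(substr(src, st, st + 39), "")[[1]]
      err <- which(stats::runif(40) < 0.01)
      if (length(err)) chars[err] <- vapply(chars[err], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      read_obs(sprintf("r%02d", i), paste(chars, collapse = ""),
               rep(0.01, 40), contig = "c1", pos = st - 1L)
    })
    ref_genome <- tiny_reference(refseq)
    tab_ref <- score_cluster(mk_reads(refseq), hyps, wins, ref_genome)
    tab_hom <- score_cluster(mk_reads(altseq), hyps, wins, ref_genome)
    zyg <- vapply(hyps, `[[`, character(1), "zygosity")
    if (zyg[which.max(tab_ref$log_lik)] == "reference") hits["ref"] <- hits["ref"] + 1L
    if (zyg[which.max(tab_hom$log_lik)] == "homozygous") hits["hom"] <- hits["hom"] + 1L
  }
  expect_equal(unname(hits), c(8L, 8L))
})

test_that("one read, one hypothesis reduces to the kernel value", {
  refseq <- random_window(200)
  v <- data.frame(contig = "c1", pos = 100L, ref = substr(refseq, 100, 100),
                  alt = setdiff(c("A", "C", "G", "T"),
                                substr(refseq, 100, 100))[1],
                  source_id = 1L, stringsAsFactors = FALSE)
  cl <- cluster_variants(v)[[1]]
  hyps <- enumerate_hypotheses(cl)
  wins <- lapply(hyps, function(h)
    build_haplotype_window(refseq, cl, h$subset, 20L))
  rd <- read_obs("r", substr(refseq, 90, 109), rep(0.01, 20),
                 contig = "c1", pos = 89L)
  tab <- score_cluster(list(rd), hyps, wins, tiny_reference(refseq),
                       params = paralog_params(0))
  is_ref <- vapply(hyps, function(h) h$zygosity == "reference", logical(1))
  expect_equal(tab$log_lik[is_ref],
               read_given_segments_log_sum(
                 rd, segment_set(wins[[which(is_ref)]]$ref_window, 20L)))
})

test_that("marginal odds follow the prior-weighted likelihood ratio", {
  # hand-built table: single-variant cluster, per-read likelihoods a / b
  a <- 0.01; b <- 0.99
  tab <- structure(list(
    log_lik = log(c(a, (a + b) / 2, b)),
    prior = c(0.5, 0.25, 0.25),
    subset = list(integer(0), 1L, 1L),
    zygosity = c("reference", "heterozygous", "homozygous"),
    n_reads = 1L), class = "hypothesis_table")
  m <- marginalize_variant(tab, 1L)
  expect_equal(exp(m$log_odds), 74.5, tolerance = 1e-12)
  expect_equal(m$posterior, 74.5 / 75.5, tolerance = 1e-12)
  expect_equal(m$best_hypothesis, "homozygous:{1}")
  # uninformative likelihoods: odds reduce to the prior odds
  tab0 <- tab; tab0$log_lik <- c(0, 0, 0)
  expect_equal(marginalize_variant(tab0, 1L)$log_odds, 0)
  # variant absent from all hypotheses
  m2 <- marginalize_variant(tab, 2L)
  expect_false(m2$evaluated)
})

test_that("two-variant clusters split hypotheses 4 versus 3 per variant", {
  cl <- cluster_variants(
    data.frame(contig = "c1", pos = c(100L, 104L), ref = "A", alt = "C",
               source_id = 1:2, stringsAsFactors = FALSE))[[1]]
  hyps <- enumerate_hypotheses(cl)
  for (v in 1:2) {
    in_v <- vapply(hyps, function(h) v %in% h$subset, logical(1))
    expect_equal(sum(in_v), 4)      # {v} and {v, w}, het and hom
    expect_equal(sum(!in_v), 3)     # reference plus {w} het and hom
  }
})

test_that("marginal odds agree with an arithmetic-space oracle", {
  set.seed(41)
  for (trial in 1:20) {
    refseq <- random_window(60)
    p <- sample(25:35, 1)
    v <- data.frame(contig = "c1", pos = p, ref = substr(refseq, p, p),
                    alt = "", source_id = 1L, stringsAsFactors = FALSE)
    v$alt <- sample(setdiff(c("A", "C", "G", "T"), v$ref), 1)
    cl <- cluster_variants(v)[[1]]
    hyps <- enumerate_hypotheses(cl)
    l <- sample(5:8, 1)
    wins <- lapply(hyps, function(h)
      build_haplotype_window(refseq, cl, h$subset, l))
    reads <- lapply(1:3, function(i) random_read(l))
    tab <- score_cluster(lapply(reads, `[[`, "obs"), hyps, wins,
                         tiny_reference(refseq), params = paralog_params(0))
    got <- exp(marginalize_variant(tab, 1L)$log_odds)
    oracle_hyps <- lapply(seq_along(hyps), function(i) {
      w <- wins[[i]]
      windows <- switch(hyps[[i]]$zygosity,
                        reference = w$ref_window,
                        homozygous = w$var_window,
                        heterozygous = c(w$ref_window, w$var_window))
      list(windows = windows, prior = hyps[[i]]$prior,
           has_v = length(hyps[[i]]$subset) > 0)
    })
    want <- arith_marginal_odds(lapply(reads, function(r)
      list(chars = r$chars, e = r$e)), oracle_hyps)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("scoring is deterministic and monotone in supporting reads", {
  sim <- simulate_dataset(sim_config(contig_length = 15000, n_snps = 4,
                                     n_insertions = 1, n_deletions = 1,
                                     n_decoys = 4, seed = 9),
                          outdir = tempfile())
  ref <- load_reference(sim$paths[["reference"]])
  cand <- load_candidates(sim$paths[["candidates"]], ref)
  aln <- load_alignments(sim$paths[["alignments"]])
  v1 <- score_variants(ref, cand, aln)
  v2 <- score_variants(ref, cand, aln)
  expect_identical(as.data.frame(v1), as.data.frame(v2))

  # duplicate a variant-supporting read: log-odds must not decrease
  truth1 <- sim$genome$truth[sim$genome$truth$type == "snp", ][1, ]
  sup <- aln[aln$pos < truth1$pos & aln$end >= truth1$pos &
               substr(aln$seq, truth1$pos - aln$pos, truth1$pos - aln$pos) ==
               truth1$alt, ][1, ]
  sup$qname <- "dupread"
  sup$rid <- "dupread/1"
  aln2 <- rbind(aln, sup)
  attr(aln2, "multi_rows") <- attr(aln, "multi_rows")
  class(aln2) <- class(aln)
  v3 <- score_variants(ref, cand, aln2)
  i1 <- which(v1$pos == truth1$pos)
  expect_gte(v3$log_odds[which(v3$pos == truth1$pos)], v1$log_odds[i1])
})

test_that("clusters without reads are flagged as no-data", {
  refseq <- random_window(3000)
  d <- tempfile(fileext = ".sam")
  write_sam(sam_row("far", 2000L, substr(refseq, 2000, 2039)),
            c(c1 = 3000L), d)
  aln <- load_alignments(d)
  cand <- data.frame(contig = "c1", pos = 500L,
                     ref = substr(refseq, 500, 500), alt = "",
                     source_id = 1L, stringsAsFactors = FALSE)
  cand$alt <- setdiff(c("A", "C", "G", "T"), cand$ref)[1]
  vs <- score_variants(tiny_reference(refseq), cand, aln)
  expect_equal(vs$log_odds, 0)
  expect_equal(vs$posterior, 0.5)
  expect_match(vs$flags, "no_data")
})
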