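# Orchestration: gather reads per cluster, score hypotheses, marginalize
# per-variant posterior odds.

#' Collect reads overlapping a cluster span
#'
#' Reads not mappable to the neighborhood of the candidate variants cannot
#' affect the likelihood ratio between hypotheses and are ignored. A read is
#' identified by (qname, mate) — paired-end mates are scored as independent
#' reads. For each collected read, soft-clipped bases are trimmed, Phred
#' qualities are converted to clamped error probabilities, and the read's
#' other mapped locations (from secondary alignment records anywhere in the
#' file) and multiplicity m_r (NH tag when present, else the record count)
#' are recorded.
#'
#' @param alignments a [load_alignments()] table
#' @param contig contig name
#' @param span_start,span_end 0-based half-open cluster span
#' @param min_mapq minimum mapping quality (default 0: the outside-paralog
#'   term, not a hard filter, is the mechanism for doubtful mappings)
#' @param max_reads cap on reads per cluster (default 10000)
#' @param keep_duplicates keep duplicate/QC-fail flagged reads (default FALSE)
#' @return list of [read_obs()] objects, with attributes `n_overlapping`
#'   (before capping) and `capped` (logical)
#' @export
collect_reads <- function(alignments, contig, span_start, span_end,
                          min_mapq = 0L, max_reads = 10000L,
                          keep_duplicates = FALSE) {
  stopifnot(inherits(alignments, "read_alignments"))
  a <- alignments
  multi <- attr(alignments, "multi_rows")
  ov <- a$contig == contig & a$pos < span_end & a$end > span_start
  if (!keep_duplicates) ov <- ov & !a$duplicate & !a$qcfail
  ov <- ov & a$mapq >= min_mapq
  rows_by_id <- split(which(ov), a$rid[ov])
  hit_ids <- unique(a$rid[ov])
  capped <- length(hit_ids) > max_reads
  if (capped) hit_ids <- hit_ids[seq_len(max_reads)]
  reads <- vector("list", length(hit_ids))
  for (i in seq_along(hit_ids)) {
    rows_ov <- rows_by_id[[hit_ids[i]]]
    rows <- multi[[hit_ids[i]]]
    if (is.null(rows)) rows <- rows_ov
    # score from the primary record if it overlaps, else the first overlap
    prim <- rows_ov[!a$secondary[rows_ov]]
    rec <- if (length(prim)) prim[1L] else rows_ov[1L]
    seq_ <- a$seq[rec]; qual <- a$qual[rec]
    sc <- .soft_clips(a$cigar[rec])
    if (sum(sc) > 0L) {
      seq_ <- substr(seq_, sc[1L] + 1L, nchar(seq_) - sc[2L])
      qual <- if (!is.na(qual) && qual != "*")
        substr(qual, sc[1L] + 1L, nchar(qual) - sc[2L]) else qual
    }
    if (nchar(seq_) == 0L) next
    e <- phred_to_error(qual, nchar(seq_))
    others <- setdiff(rows, rec)
    m_r <- if (!is.na(a$nh[rec])) max(1L, a$nh[rec]) else length(rows)
    reads[[i]] <- read_obs(
      read_id = hit_ids[i], called_seq = seq_, error_probs = e,
      contig = a$contig[rec], pos = a$pos[rec],
      strand = if (bitwAnd(a$flag[rec], 16L) > 0L) "-" else "+",
      other_locations = if (length(others))
        data.frame(contig = a$contig[others], pos = a$pos[others]) else NULL,
      multiplicity = m_r)
  }
  reads <- reads[!vapply(reads, is.null, logical(1))]
  # fixed order by read id for deterministic summation
  reads <- reads[order(vapply(reads, `[[`, character(1), "read_id"))]
  attr(reads, "n_overlapping") <- length(hit_ids)
  attr(reads, "capped") <- capped
  reads
}

# Inside-paralog segment sets for one read: a reference window of width
# l + 2*pad around each of its other mapped locations.
.inside_paralog_sets <- function(read, reference, pad) {
  locs <- read$other_locations
  if (is.null(locs) || nrow(locs) == 0L) return(list())
  l <- length(read$codes)
  out <- list()
  for (j in seq_len(nrow(locs))) {
    ctg <- locs$contig[j]
    if (!ctg %in% names(reference)) next
    clen <- nchar(reference[[ctg]])
    w0 <- max(0L, locs$pos[j] - pad)
    w1 <- min(clen, locs$pos[j] + l + pad)
    if (w1 - w0 < l) next
    out[[length(out) + 1L]] <-
      segment_set(substr(reference[[ctg]], w0 + 1L, w1), l)
  }
  out
}

#' Score all hypotheses of one cluster against its reads
#'
#' For each hypothesis G, log P\[R|G\] is the sum over reads of
#' [read_given_hypothesis_log_prob()], using only genome segments from the
#' cluster's haplotype windows and from reference windows around each read's
#' other mapped locations (the segments considered may differ per read).
#' Reads are summed in fixed (read id) order, hypotheses in enumeration
#' order, so identical inputs give bit-identical results.
#'
#' @param reads list of [read_obs()] (as from [collect_reads()])
#' @param hypotheses list of `genome_hypothesis` objects with priors
#' @param windows list parallel to `hypotheses` of window descriptors from
#'   [build_haplotype_window()]; reference/homozygous hypotheses use one
#'   window, heterozygous the ref+variant pair
#' @param reference a [load_reference()] genome (for inside-paralog windows)
#' @param params a [paralog_params()]
#' @param pad window padding (default 2)
#' @return a `hypothesis_table`: list with per-hypothesis `log_lik`,
#'   `prior`, `subset`, `zygosity`, plus `n_reads`
#' @export
score_cluster <- function(reads, hypotheses, windows, reference,
                          params = paralog_params(), pad = 2L) {
  n_h <- length(hypotheses)
  stopifnot(n_h == length(windows), n_h >= 1L)
  # distinct haplotype windows: the reference window is shared by every
  # hypothesis, each variant subset's window by its het and hom hypotheses
  wstrs <- unique(unlist(lapply(windows, function(w)
    c(w$ref_window, w$var_window))))
  wcodes <- lapply(wstrs, encode_bases)
  hyp_idx <- lapply(seq_len(n_h), function(hi) {
    ri <- match(windows[[hi]]$ref_window, wstrs)
    vi <- match(windows[[hi]]$var_window, wstrs)
    switch(hypotheses[[hi]]$zygosity,
           reference = ri, homozygous = vi, heterozygous = c(ri, vi))
  })
  log_lik <- numeric(n_h)
  n_used <- 0L
  for (read in reads) {
    l <- length(read$codes)
    m <- .read_logprob_matrix(read$codes, read$error_probs)
    wsum <- vapply(wcodes, .window_log_sum, numeric(1), l = l, m = m)
    inside <- .inside_paralog_sets(read, reference, pad)
    shared <- c(vapply(inside,
                       function(s) logsumexp(.segment_log_probs(
                         s$window_codes, s$segment_starts, NULL, NULL, m = m)),
                       numeric(1)),
                outside_paralog_log_term(read, params))
    contrib <- vapply(seq_len(n_h), function(hi) {
      hv <- wsum[hyp_idx[[hi]]]
      logsumexp(c(hv - log(length(hv)), shared))
    }, numeric(1))
    if (any(!is.finite(contrib)) || anyNA(contrib)) {
      warning("read ", read$read_id,
              " skipped (window shorter than read or degenerate likelihood)",
              call. = FALSE)
      next
    }
    log_lik <- log_lik + contrib
    n_used <- n_used + 1L
  }
  structure(list(
    log_lik = log_lik,
    prior = vapply(hypotheses, `[[`, numeric(1), "prior"),
    subset = lapply(hypotheses, `[[`, "subset"),
    zygosity = vapply(hypotheses, `[[`, character(1), "zygosity"),
    n_reads = n_used), class = "hypothesis_table")
}

#' Marginal posterior odds for one variant of a cluster
#'
#' The marginal odds ratio P\[R|v\]/P\[R|not v\]: a prior-weighted
#' log-sum-exp over the hypotheses containing v divided by the same over
#' the hypotheses not containing v (reference included, and possibly other
#' nearby variants without v).
#'
#' @param table a `hypothesis_table` from [score_cluster()]
#' @param variant_index index of the variant within the cluster's variants
#' @return list with `log_odds`, `posterior` (= odds/(1+odds)),
#'   `best_hypothesis` (descriptor of the maximum-posterior hypothesis;
#'   ties broken toward fewer variants), `evaluated` (FALSE when the
#'   variant appears in no scored hypothesis)
#' @export
marginalize_variant <- function(table, variant_index) {
  stopifnot(inherits(table, "hypothesis_table"))
  in_v <- vapply(table$subset, function(s) variant_index %in% s, logical(1))
  if (!any(in_v)) {
    return(list(log_odds = NA_real_, posterior = NA_real_,
                best_hypothesis = NA_character_, evaluated = FALSE))
  }
  w <- log(table$prior) + table$log_lik
  log_odds <- logsumexp(w[in_v]) - logsumexp(w[!in_v])
  post_h <- w - logsumexp(w)
  nv <- lengths(table$subset)
  best <- order(-post_h, nv)[1L]    # parsimony tie-break
  desc <- if (table$zygosity[best] == "reference") "reference" else
    paste0(table$zygosity[best], ":{",
           paste(table$subset[[best]], collapse = ","), "}")
  list(log_odds = log_odds,
       posterior = stats::plogis(log_odds),
       best_hypothesis = desc,
       evaluated = TRUE)
}

#' Score candidate variants against read data
#'
#' The main entry point. Candidates are chained into clusters, each cluster
#' is expanded into explicit diploid genome hypotheses (reference /
#' heterozygous / homozygous over variant subsets) with priors, every read
#' overlapping the cluster is scored under every hypothesis, and each
#' variant receives its marginal posterior log-odds.
#'
#' @param reference FASTA path or a [load_reference()] genome
#' @param variants VCF path or a candidates data.frame
#'   (contig, pos, ref, alt, source_id)
#' @param alignments SAM/BAM path or a [load_alignments()] table
#' @param max_dist cluster chaining distance in bp (default 10)
#' @param max_combos cap on variant-inclusion combinations per cluster,
#'   empty set included (default 1024)
#' @param h outside-paralog constant (default 1e-4; 0 disables)
#' @param pad haplotype-window padding beyond the read length (default 2)
#' @param min_mapq,max_reads,keep_duplicates read-collection controls, see
#'   [collect_reads()]
#' @param dump_hypotheses keep every cluster's raw hypothesis table in the
#'   result (attribute `"hypothesis_tables"`)
#' @return object of class `variant_scores`: a data.frame with columns
#'   contig, pos, ref, alt, log_odds (natural log), posterior, n_reads,
#'   n_hypotheses, cluster_id, best_hypothesis, flags; parameters in
#'   attribute `"params"`
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config(contig_length = 20000, n_snps = 5,
#'                                    n_decoys = 5, seed = 7),
#'                         outdir = tempfile())
#' vs <- score_variants(sim$paths["reference"], sim$paths["candidates"],
#'                      sim$paths["alignments"])
#' summary(vs)
#' }
#' @export
score_variants <- function(reference, variants, alignments,
                           max_dist = 10L, max_combos = 1024L, h = 1e-4,
                           pad = 2L, min_mapq = 0L, max_reads = 10000L,
                           keep_duplicates = FALSE, dump_hypotheses = FALSE) {
  if (is.character(reference) && !inherits(reference, "reference_genome")) {
    reference <- load_reference(reference)
  }
  if (is.character(variants)) variants <- load_candidates(variants, reference)
  if (is.character(alignments)) alignments <- load_alignments(alignments)
  params <- paralog_params(h)
  clusters <- cluster_variants(variants, max_dist = max_dist)
  rows <- list()
  tables <- if (dump_hypotheses) vector("list", length(clusters)) else NULL
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    contig_seq <- reference[[cl$contig]]
    if (is.null(contig_seq)) {
      stop("contig ", cl$contig, " absent from reference", call. = FALSE)
    }
    reads <- collect_reads(alignments, cl$contig, cl$span[1L], cl$span[2L],
                           min_mapq = min_mapq, max_reads = max_reads,
                           keep_duplicates = keep_duplicates)
    flags <- character(0)
    if (isTRUE(attr(reads, "capped"))) flags <- c(flags, "high_depth")
    k <- nrow(cl$variants)
    if (length(reads) == 0L) {
      for (vi in seq_len(k)) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cl$contig, pos = cl$variants$pos[vi],
          ref = cl$variants$ref[vi], alt = cl$variants$alt[vi],
          log_odds = 0, posterior = 0.5, n_reads = 0L,
          n_hypotheses = NA_integer_, cluster_id = ci,
          best_hypothesis = NA_character_,
          flags = paste(c(flags, "no_data"), collapse = ","))
      }
      next
    }
    read_len <- max(vapply(reads, function(r) length(r$codes), integer(1)))
    hyps <- enumerate_hypotheses(cl, max_combos = max_combos)
    windows <- lapply(hyps, function(h_)
      build_haplotype_window(contig_seq, cl, h_$subset, read_len, pad = pad))
    tab <- score_cluster(reads, hyps, windows, reference,
                         params = params, pad = pad)
    if (dump_hypotheses) tables[[ci]] <- tab
    for (vi in seq_len(k)) {
      m <- marginalize_variant(tab, vi)
      vflags <- flags
      if (!m$evaluated) vflags <- c(vflags, "not_evaluated")
      rows[[length(rows) + 1L]] <- data.frame(
        contig = cl$contig, pos = cl$variants$pos[vi],
        ref = cl$variants$ref[vi], alt = cl$variants$alt[vi],
        log_odds = if (m$evaluated) m$log_odds else NA_real_,
        posterior = if (m$evaluated) m$posterior else NA_real_,
        n_reads = tab$n_reads, n_hypotheses = length(hyps),
        cluster_id = ci, best_hypothesis = m$best_hypothesis,
        flags = paste(vflags, collapse = ","))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0), log_odds = numeric(0),
               posterior = numeric(0), n_reads = integer(0),
               n_hypotheses = integer(0), cluster_id = integer(0),
               best_hypothesis = character(0), flags = character(0))
  df <- df[order(df$contig, df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            params = list(max_dist = max_dist, max_combos = max_combos,
                          h = h, pad = pad, min_mapq = min_mapq,
                          max_reads = max_reads),
            hypothesis_tables = tables,
            class = c("variant_scores", "data.frame"))
}
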