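# Synthetic diploid genomes, error-bearing reads, and decoy candidates —
# the bundled fixture generator that makes the whole scorer testable
# end-to-end without external data or an external mapper.

#' Simulation configuration
#'
#' Defaults mirror a typical short-read whole-genome experiment: paired-end
#' 100 bp reads, insert size 500 +/- 30 bp, ~30x coverage, uniform Q20 base
#' quality (1% error).
#'
#' @param contig_length reference contig length in bp
#' @param seed RNG seed; a fixed seed gives byte-identical outputs
#' @param n_snps,n_insertions,n_deletions planted variant counts
#' @param het_fraction fraction of planted variants heterozygous (rest
#'   homozygous)
#' @param coverage mean sequencing depth (default 30)
#' @param read_length read length l in bp (default 100, minimum 20)
#' @param base_quality uniform Phred base quality (default 20, i.e. e=0.01)
#' @param paired simulate read pairs (default TRUE)
#' @param insert_mean,insert_sd fragment length distribution (500 +/- 30)
#' @param n_decoys false candidates planted in the VCF but absent from the
#'   sample genome
#' @param indel_p,indel_max indel length distribution: 1 + geometric(p),
#'   capped at `indel_max` bp
#' @param contig_name name of the simulated contig
#' @return a `sim_config` list
#' @export
sim_config <- function(contig_length = 100000L, seed = 1L,
                       n_snps = 30L, n_insertions = 10L, n_deletions = 10L,
                       het_fraction = 0.5, coverage = 30, read_length = 100L,
                       base_quality = 20L, paired = TRUE,
                       insert_mean = 500, insert_sd = 30,
                       n_decoys = 50L, indel_p = 0.5, indel_max = 10L,
                       contig_name = "sim1") {
  stopifnot(coverage > 0, read_length >= 20L, contig_length > 4L * read_length)
  structure(as.list(environment()), class = "sim_config")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
         character(1), USE.NAMES = FALSE)
}

#' Build a diploid sample genome with planted variants
#'
#' Generates a random reference contig, plants SNPs, insertions and
#' deletions (VCF anchored-allele convention) at mutually non-overlapping
#' positions away from the contig ends, assigns each a zygosity, and
#' applies them to two haplotype sequences. Alongside each haplotype a
#' per-base map back to reference coordinates is kept, so simulated reads
#' can be emitted at their true reference positions.
#'
#' @param config a [sim_config()]
#' @return list: `reference` (string), `haplotypes` (list of two strings),
#'   `hap_maps` (per-base 0-based reference coordinate of each haplotype
#'   base; inserted bases map to their anchor), `truth` (data.frame contig,
#'   pos, ref, alt, zygosity, type), `contig_name`
#' @export
build_diploid_genome <- function(config) {
  set.seed(config$seed)
  L <- config$contig_length
  reference <- .random_dna(L)
  n_var <- config$n_snps + config$n_insertions + config$n_deletions
  margin <- 2L * config$read_length
  # candidate anchor positions, spaced so alleles never overlap
  spacing <- config$indel_max + 2L
  avail <- seq(margin, L - margin, by = spacing)
  if (n_var > length(avail)) {
    stop("more variants requested than available positions", call. = FALSE)
  }
  pos <- sort(sample(avail, n_var))
  type <- sample(rep(c("snp", "ins", "del"),
                     c(config$n_snps, config$n_insertions, config$n_deletions)))
  ref_al <- character(n_var); alt_al <- character(n_var)
  for (i in seq_len(n_var)) {
    anchor <- substr(reference, pos[i], pos[i])
    if (type[i] == "snp") {
      ref_al[i] <- anchor
      alt_al[i] <- .other_base(anchor)
    } else {
      len <- min(1L + stats::rgeom(1L, config$indel_p), config$indel_max)
      if (type[i] == "ins") {
        ref_al[i] <- anchor
        alt_al[i] <- paste0(anchor, .random_dna(len))
      } else {
        ref_al[i] <- substr(reference, pos[i], pos[i] + len)
        alt_al[i] <- anchor
      }
    }
  }
  zyg <- ifelse(stats::runif(n_var) < config$het_fraction,
                "heterozygous", "homozygous")
  het_hap <- sample(1:2, n_var, replace = TRUE)  # carrier copy for hets
  truth <- data.frame(contig = rep(config$contig_name, n_var), pos = pos,
                      ref = ref_al, alt = alt_al, zygosity = zyg,
                      type = type, stringsAsFactors = FALSE)
  haps <- list(); maps <- list()
  for (hap in 1:2) {
    use <- zyg == "homozygous" | (zyg == "heterozygous" & het_hap == hap)
    pieces <- character(0); mpieces <- list()
    cur <- 1L
    for (i in which(use)) {
      pieces <- c(pieces, substr(reference, cur, pos[i] - 1L), alt_al[i])
      mpieces <- c(mpieces, list(seq(cur - 1L, pos[i] - 2L)),
                   list(rep(pos[i] - 1L, nchar(alt_al[i]))))
      cur <- pos[i] + nchar(ref_al[i])
    }
    pieces <- c(pieces, substr(reference, cur, L))
    mpieces <- c(mpieces, list(seq(cur - 1L, L - 1L)))
    haps[[hap]] <- paste(pieces, collapse = "")
    maps[[hap]] <- unlist(mpieces, use.names = FALSE)
  }
  stopifnot(nchar(haps[[1L]]) == length(maps[[1L]]),
            nchar(haps[[2L]]) == length(maps[[2L]]))
  list(reference = reference, haplotypes = haps, hap_maps = maps,
       truth = truth, contig_name = config$contig_name)
}

# mutate a character vector of bases at given 1-based indices, each to a
# uniformly random different base (N flips to a random base)
.ALT_BASES <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G",
                       "A","C","G"),
                     nrow = 5L, byrow = TRUE,
                     dimnames = list(c("A","C","G","T","N"), NULL))
.flip_bases <- function(chars, idx) {
  if (!length(idx)) return(chars)
  code <- match(chars[idx], rownames(.ALT_BASES))
  chars[idx] <- .ALT_BASES[cbind(code, sample.int(3L, length(idx),
                                                  replace = TRUE))]
  chars
}

# apply a uniform per-base error rate to equal-length read sequences
.inject_errors <- function(seqs, l, e) {
  if (!length(seqs)) return(seqs)
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
  err <- which(stats::runif(length(chars)) < e)
  chars <- .flip_bases(chars, err)
  m <- matrix(chars, nrow = l)
  do.call(paste0, lapply(seq_len(l), function(i) m[i, ]))
}

#' Simulate error-bearing reads from a diploid genome
#'
#' Fragments are drawn uniformly from either haplotype; each base is flipped
#' to a uniformly random different base with the error probability implied
#' by the (uniform) quality; reads are emitted as SAM records at their TRUE
#' source positions, projected from haplotype to reference coordinates
#' through the variant map. Mapping is out of scope, so alignments carry
#' simple all-M CIGARs; the scorer deliberately ignores aligner gap
#' placement. Reverse-strand mates are stored in reference orientation as
#' SAM requires.
#'
#' @param genome a [build_diploid_genome()] result
#' @param config a [sim_config()]
#' @return data.frame of SAM fields (qname, flag, rname, pos 1-based, mapq,
#'   cigar, rnext, pnext, tlen, seq, qual)
#' @export
simulate_reads <- function(genome, config) {
  l <- config$read_length
  L <- config$contig_length
  e <- 10^(-config$base_quality / 10)
  qual <- strrep(intToUtf8(config$base_quality + 33L), l)
  n_reads <- round(config$coverage * L / l)
  hlen <- nchar(c(genome$haplotypes[[1L]], genome$haplotypes[[2L]]))
  project <- function(hap, p1) {           # 1-based hap coord -> 1-based ref
    out <- integer(length(p1))
    for (h in 1:2) {
      i <- hap == h
      out[i] <- genome$hap_maps[[h]][p1[i]] + 1L
    }
    out
  }
  hapseq <- c(genome$haplotypes[[1L]], genome$haplotypes[[2L]])
  if (config$paired) {
    n_frag <- as.integer(ceiling(n_reads / 2))
    hap <- sample(1:2, n_frag, replace = TRUE)
    ins <- pmax(2L * l, as.integer(round(stats::rnorm(n_frag,
                                                      config$insert_mean,
                                                      config$insert_sd))))
    ins <- pmin(ins, hlen[hap])
    p1 <- 1L + as.integer(floor(stats::runif(n_frag) * (hlen[hap] - ins + 1L)))
    p2 <- p1 + ins - l
    seq1 <- .inject_errors(substring(hapseq[hap], p1, p1 + l - 1L), l, e)
    seq2 <- .inject_errors(substring(hapseq[hap], p2, p2 + l - 1L), l, e)
    rpos1 <- project(hap, p1)
    rpos2 <- project(hap, p2)
    qn <- sprintf("frag%06d", seq_len(n_frag))
    data.frame(qname = rep(qn, 2L),
               flag = rep(c(99L, 147L), each = n_frag),
               rname = genome$contig_name,
               pos = c(rpos1, rpos2), mapq = 60L, cigar = paste0(l, "M"),
               rnext = "=", pnext = c(rpos2, rpos1),
               tlen = c(ins, -ins), seq = c(seq1, seq2), qual = qual,
               stringsAsFactors = FALSE)
  } else {
    hap <- sample(1:2, n_reads, replace = TRUE)
    p1 <- 1L + as.integer(floor(stats::runif(n_reads) * (hlen[hap] - l + 1L)))
    seqs <- .inject_errors(substring(hapseq[hap], p1, p1 + l - 1L), l, e)
    data.frame(qname = sprintf("read%06d", seq_len(n_reads)), flag = 0L,
               rname = genome$contig_name, pos = project(hap, p1),
               mapq = 60L, cigar = paste0(l, "M"), rnext = "*", pnext = 0L,
               tlen = 0L, seq = seqs, qual = qual, stringsAsFactors = FALSE)
  }
}

#' Plant decoy candidates alongside the truth set
#'
#' Decoys are false candidate variants (the stand-in for an upstream
#' caller's false positives): SNPs and short indels at positions at least
#' `2 * read_length` away from every truth variant and from each other,
#' absent from the sample genome. Truth labels are returned as a sidecar
#' table for precision-recall evaluation.
#'
#' @param reference contig sequence string
#' @param truth truth data.frame from [build_diploid_genome()]
#' @param n_decoys number of decoys
#' @param config a [sim_config()]
#' @return list: `candidates` (data.frame contig,pos,ref,alt,source_id
#'   sorted by position), `labels` (same keys plus `label` in
#'   \{"truth","decoy"\})
#' @export
make_decoy_candidates <- function(reference, truth, n_decoys, config) {
  L <- nchar(reference)
  l <- config$read_length
  margin <- 2L * l
  forbidden <- truth$pos
  pool <- setdiff(seq(margin, L - margin),
                  unlist(lapply(forbidden, function(p) (p - margin):(p + margin))))
  dec <- list()
  if (n_decoys > 0L) {
    pos <- sort(sample(pool, n_decoys * 3L))        # thin to enforce spacing
    keep <- c(TRUE, diff(pos) > margin)
    pos <- pos[keep][seq_len(min(n_decoys, sum(keep)))]
    if (length(pos) < n_decoys) {
      stop("could not place ", n_decoys, " decoys with required spacing",
           call. = FALSE)
    }
    type <- sample(c("snp", "ins", "del"), length(pos), replace = TRUE,
                   prob = c(0.6, 0.2, 0.2))
    for (i in seq_along(pos)) {
      anchor <- substr(reference, pos[i], pos[i])
      if (type[i] == "snp") {
        dec[[i]] <- data.frame(pos = pos[i], ref = anchor,
                               alt = .other_base(anchor))
      } else if (type[i] == "ins") {
        len <- min(1L + stats::rgeom(1L, config$indel_p), config$indel_max)
        dec[[i]] <- data.frame(pos = pos[i], ref = anchor,
                               alt = paste0(anchor, .random_dna(len)))
      } else {
        len <- min(1L + stats::rgeom(1L, config$indel_p), config$indel_max)
        dec[[i]] <- data.frame(pos = pos[i],
                               ref = substr(reference, pos[i], pos[i] + len),
                               alt = anchor)
      }
    }
  }
  dec <- if (length(dec)) do.call(rbind, dec) else
    data.frame(pos = integer(0), ref = character(0), alt = character(0))
  cand <- rbind(
    data.frame(contig = truth$contig, pos = truth$pos, ref = truth$ref,
               alt = truth$alt, label = "truth", stringsAsFactors = FALSE),
    if (nrow(dec)) data.frame(contig = config$contig_name, pos = dec$pos,
                              ref = dec$ref, alt = dec$alt, label = "decoy",
                              stringsAsFactors = FALSE))
  cand <- cand[order(cand$contig, cand$pos), , drop = FALSE]
  cand$source_id <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  list(candidates = cand[, c("contig", "pos", "ref", "alt", "source_id")],
       labels = cand[, c("contig", "pos", "ref", "alt", "label")])
}

#' Simulate reads from a diverged off-reference paralog
#'
#' Emulates a repeat copy present in the sample but absent from the
#' reference: a region of the reference is copied, mutated at the given
#' divergence, and reads simulated from the mutated copy are emitted at the
#' ORIGINAL region's coordinates (where a mapper would place them). The
#' divergent sites, expressed as SNP candidates at the original region,
#' are returned as decoy candidates: reads from the copy spuriously support
#' them.
#'
#' @param reference contig sequence string
#' @param region_start,region_end 1-based inclusive region to copy
#' @param divergence per-base substitution rate of the copy (default 0.03)
#' @param coverage read depth over the copy
#' @param config a [sim_config()] (read length / quality reused)
#' @return list: `sam` (data.frame of SAM fields), `decoys` (data.frame
#'   contig,pos,ref,alt of the divergent sites)
#' @export
simulate_paralog_reads <- function(reference, region_start, region_end,
                                   divergence = 0.03, coverage = 30,
                                   config = sim_config()) {
  l <- config$read_length
  rl <- region_end - region_start + 1L
  stopifnot(rl >= 2L * l)
  chars <- strsplit(substr(reference, region_start, region_end), "")[[1L]]
  n_div <- max(1L, stats::rbinom(1L, rl, divergence))
  div_idx <- sort(sample(rl, n_div))
  orig <- chars[div_idx]
  chars <- .flip_bases(chars, div_idx)
  copy_seq <- paste(chars, collapse = "")
  decoys <- data.frame(contig = config$contig_name,
                       pos = region_start + div_idx - 1L,
                       ref = orig, alt = chars[div_idx],
                       stringsAsFactors = FALSE)
  e <- 10^(-config$base_quality / 10)
  n_reads <- round(coverage * rl / l)
  p1 <- sample.int(rl - l + 1L, n_reads, replace = TRUE)
  seqs <- .inject_errors(substring(copy_seq, p1, p1 + l - 1L), l, e)
  sam <- data.frame(
    qname = sprintf("paralog%06d", seq_len(n_reads)), flag = 0L,
    rname = config$contig_name, pos = region_start + p1 - 1L, mapq = 20L,
    cigar = paste0(l, "M"), rnext = "*", pnext = 0L, tlen = 0L,
    seq = seqs, qual = strrep(intToUtf8(config$base_quality + 33L), l),
    stringsAsFactors = FALSE)
  list(sam = sam, decoys = decoys)
}

#' Write SAM records to a file
#'
#' Minimal valid SAM: an @HD header, one @SQ line per contig, records sorted
#' by coordinate.
#'
#' @param sam data.frame of SAM fields as produced by [simulate_reads()]
#' @param contig_lengths named integer vector
#' @param path output path
#' @return the path, invisibly
#' @export
write_sam <- function(sam, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  sam <- sam[order(match(sam$rname, names(contig_lengths)), sam$pos,
                   sam$qname, sam$flag), , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq,
                  sam$cigar, sam$rnext, sam$pnext, sam$tlen, sam$seq,
                  sam$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write variants as a minimal VCF
#'
#' @param variants data.frame with contig, pos, ref, alt (and optionally
#'   zygosity, written into the INFO column)
#' @param contig_lengths named integer vector
#' @param path output path
#' @return the path, invisibly
#' @export
write_vcf <- function(variants, contig_lengths, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                   as.integer(contig_lengths)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  v <- variants[order(variants$contig, variants$pos), , drop = FALSE]
  info <- if ("zygosity" %in% names(v)) paste0("ZYG=", v$zygosity)
          else rep(".", nrow(v))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  v$contig, v$pos, v$ref, v$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Run the full simulation and write all fixture files
#'
#' Builds the diploid genome, simulates reads, plants decoy candidates, and
#' writes reference FASTA, truth VCF, candidate VCF, truth-label TSV and
#' read SAM under one output directory. Deterministic in the config seed.
#'
#' @param config a [sim_config()]
#' @param outdir output directory (created if needed)
#' @return list: `paths` (named: reference, truth, candidates, labels,
#'   alignments), `genome`, `sam`, `candidates`, `labels`
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- build_diploid_genome(config)     # seeds the RNG
  sam <- simulate_reads(genome, config)
  dc <- make_decoy_candidates(genome$reference, genome$truth,
                              config$n_decoys, config)
  clen <- stats::setNames(config$contig_length, config$contig_name)
  paths <- c(reference = file.path(outdir, "reference.fa"),
             truth = file.path(outdir, "truth.vcf"),
             candidates = file.path(outdir, "candidates.vcf"),
             labels = file.path(outdir, "labels.tsv"),
             alignments = file.path(outdir, "reads.sam"))
  writeLines(c(paste0(">", config$contig_name),
               substring(genome$reference,
                         seq(1L, config$contig_length, 70L),
                         pmin(seq(1L, config$contig_length, 70L) + 69L,
                              config$contig_length))),
             paths["reference"])
  write_vcf(genome$truth, clen, paths["truth"])
  write_vcf(dc$candidates, clen, paths["candidates"])
  utils::write.table(dc$labels, paths["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_sam(sam, clen, paths["alignments"])
  list(paths = paths, genome = genome, sam = sam,
       candidates = dc$candidates, labels = dc$labels)
}
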