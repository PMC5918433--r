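# Boundary readers/writers: FASTA reference, VCF candidates, SAM/BAM
# alignments, TSV score output.

#' Load a reference genome from FASTA
#'
#' Sequences are folded to uppercase and any symbol outside A,C,G,T (IUPAC
#' ambiguity codes and the like) to N.
#'
#' @param path FASTA file
#' @return named character vector of contig sequences, class
#'   `reference_genome`
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate contig names in ", path, call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- nm
  structure(seqs, class = "reference_genome")
}

#' Load candidate variants from VCF
#'
#' Multi-allelic records are split into one record per ALT allele; symbolic
#' alleles (`<DEL>`, breakends) are skipped with a warning. Every record's
#' REF allele is validated against the reference genome. A left-alignment
#' warning is emitted for indels whose REF/ALT share a common suffix longer
#' than warranted (input is assumed already normalized).
#'
#' @param path VCF file (plain text or gzipped)
#' @param reference a [load_reference()] genome, or NULL to skip validation
#' @return data.frame with columns `contig`, `pos` (1-based), `ref`, `alt`,
#'   `source_id` (input line index), sorted by (contig, pos)
#' @export
load_candidates <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  if (nrow(fx) == 0L) {
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      source_id = integer(0)))
  }
  out <- vector("list", nrow(fx))
  n_symbolic <- 0L
  for (i in seq_len(nrow(fx))) {
    alts <- strsplit(fx[i, "ALT"], ",", fixed = TRUE)[[1L]]
    symb <- grepl("[^ACGTNacgtn]", alts) | alts == "" | is.na(alts)
    n_symbolic <- n_symbolic + sum(symb)
    alts <- alts[!symb]
    if (!length(alts)) next
    out[[i]] <- data.frame(contig = unname(fx[i, "CHROM"]),
                           pos = as.integer(fx[i, "POS"]),
                           ref = toupper(unname(fx[i, "REF"])),
                           alt = toupper(alts),
                           source_id = i)
  }
  if (n_symbolic > 0L) {
    warning(n_symbolic, " symbolic allele(s) skipped", call. = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      source_id = integer(0)))
  }
  bad <- !grepl("^[ACGTN]+$", out$ref) | !grepl("^[ACGTN]+$", out$alt)
  if (any(bad)) {
    stop("malformed alleles in VCF record(s) at line(s) ",
         paste(unique(out$source_id[bad]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(reference)) {
    obs <- vapply(seq_len(nrow(out)), function(i) {
      ctg <- out$contig[i]
      if (!ctg %in% names(reference)) return(NA_character_)
      substr(reference[[ctg]], out$pos[i], out$pos[i] + nchar(out$ref[i]) - 1L)
    }, character(1))
    mism <- is.na(obs) | obs != out$ref
    if (any(mism)) {
      stop("REF allele mismatch against reference for: ",
           paste(sprintf("%s:%d %s", out$contig[mism], out$pos[mism],
                         out$ref[mism]), collapse = "; "),
           call. = FALSE)
    }
    # crude left-alignment sniff: anchored indel whose trailing bases agree
    ind <- nchar(out$ref) != nchar(out$alt)
    shared_suffix <- ind & nchar(out$ref) > 1L & nchar(out$alt) > 1L &
      substr(out$ref, nchar(out$ref), nchar(out$ref)) ==
      substr(out$alt, nchar(out$alt), nchar(out$alt))
    if (any(shared_suffix)) {
      warning(sum(shared_suffix),
              " indel(s) share a REF/ALT suffix; input may not be left-aligned",
              call. = FALSE)
    }
  }
  out <- out[order(out$contig, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Soft-clip lengths from a CIGAR string: c(leading, trailing).
.soft_clips <- function(cigar) {
  lead <- regmatches(cigar, regexpr("^[0-9]+S", cigar))
  trail <- regmatches(cigar, regexpr("[0-9]+S$", cigar))
  c(if (length(lead)) as.integer(sub("S", "", lead)) else 0L,
    if (length(trail)) as.integer(sub("S", "", trail)) else 0L)
}

#' Load read alignments from BAM or SAM
#'
#' The whole file is scanned once into an alignment table: secondary
#' alignments of a read — needed for its mapping multiplicity and
#' inside-paralog windows — may lie far from any cluster, outside any
#' regional query. SAM input is converted, sorted and indexed into a
#' temporary BAM via Rsamtools; BAM input must be accompanied by an index.
#'
#' @param path SAM (`.sam`) or coordinate-sorted indexed BAM file
#' @return data.frame of class `read_alignments`: one row per alignment
#'   record with qname, mate (1/2, 0 if unpaired), flag, contig, pos
#'   (0-based), end (0-based exclusive), mapq, cigar, seq, qual, nh,
#'   secondary/duplicate/qcfail logicals
#' @export
load_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    tmp <- tempfile()
    bam <- Rsamtools::asBam(path, tmp, overwrite = TRUE)
  } else {
    bam <- path
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam))) {
      stop("BAM index (.bai) not found for ", bam, call. = FALSE)
    }
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "NH")
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(res$pos)                       # drop unmapped records
  flag <- res$flag[keep]
  cigar <- res$cigar[keep]
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  nh <- res$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(res$qname))
  df <- data.frame(
    qname = res$qname[keep],
    mate = ifelse(bitwAnd(flag, 1L) == 0L, 0L,
                  ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L)),
    flag = flag,
    contig = as.character(res$rname[keep]),
    pos = res$pos[keep] - 1L,
    end = res$pos[keep] - 1L + refw,
    mapq = res$mapq[keep],
    cigar = cigar,
    seq = as.character(res$seq[keep]),
    qual = as.character(res$qual[keep]),
    nh = nh[keep],
    secondary = bitwAnd(flag, 256L) > 0L,
    duplicate = bitwAnd(flag, 1024L) > 0L,
    qcfail = bitwAnd(flag, 512L) > 0L,
    stringsAsFactors = FALSE)
  # read identity: (qname, mate) — paired mates are independent reads
  df$rid <- paste(df$qname, df$mate, sep = "/")
  # row index per read id, for ids with several alignment records only
  # (multiplicity and inside-paralog lookups)
  dup <- df$rid %in% df$rid[duplicated(df$rid)]
  attr(df, "multi_rows") <- split(which(dup), df$rid[dup])
  class(df) <- c("read_alignments", "data.frame")
  df
}

#' Convert a Phred quality string to error probabilities
#'
#' `e = 10^(-Q/10)` with Phred+33 encoding, clamped via
#' [clamp_error_probs()]. A missing quality string (`*`) yields the Q20
#' default e = 0.01 for every base, with a warning.
#'
#' @param qual quality string
#' @param len read length (used when `qual` is `"*"`)
#' @return numeric vector of clamped error probabilities
#' @export
phred_to_error <- function(qual, len = nchar(qual)) {
  if (is.na(qual) || qual == "*") {
    warning("read without base qualities; assuming Q20 (e = 0.01)",
            call. = FALSE)
    return(rep(0.01, len))
  }
  q <- utf8ToInt(qual) - 33L
  clamp_error_probs(10^(-q / 10))
}

#' Write scored variants to TSV (and optionally annotated VCF)
#'
#' The TSV carries columns contig, pos, ref, alt, log_odds (natural log),
#' posterior, n_reads, n_hypotheses, cluster_id, flags, in stable
#' (contig, pos) order, with numeric fields printed to full precision so a
#' write-then-read round trip is faithful.
#'
#' @param scored a `variant_scores` object or its data.frame
#' @param tsv_path output TSV path
#' @param vcf_path optional annotated-VCF output path
#' @param input_vcf input VCF whose records are annotated (required when
#'   `vcf_path` is given); log-odds and posterior are added as `VLO` and
#'   `VPP` INFO fields
#' @return invisibly, the paths written
#' @export
write_scores <- function(scored, tsv_path, vcf_path = NULL, input_vcf = NULL) {
  df <- as.data.frame(scored)
  cols <- c("contig", "pos", "ref", "alt", "log_odds", "posterior",
            "n_reads", "n_hypotheses", "cluster_id", "flags")
  stopifnot(all(cols %in% names(df)))
  df <- df[order(df$contig, df$pos, df$ref, df$alt), cols, drop = FALSE]
  fmt <- df
  fmt$log_odds <- sprintf("%.15g", df$log_odds)
  fmt$posterior <- sprintf("%.15g", df$posterior)
  utils::write.table(fmt, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(vcf_path)) {
    if (is.null(input_vcf)) stop("input_vcf required for VCF annotation",
                                 call. = FALSE)
    lines <- readLines(input_vcf)
    hdr <- grepl("^#", lines)
    info_hdr <- c(
      '##INFO=<ID=VLO,Number=1,Type=Float,Description="Marginal posterior log-odds (natural log)">',
      '##INFO=<ID=VPP,Number=1,Type=Float,Description="Marginal posterior probability">')
    body <- lines[!hdr]
    key <- function(ctg, pos, ref, alt) paste(ctg, pos, ref, alt, sep = "\r")
    score_map <- stats::setNames(seq_len(nrow(df)),
                                 key(df$contig, df$pos, df$ref, df$alt))
    out_body <- vapply(body, function(ln) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      alts <- strsplit(f[5L], ",", fixed = TRUE)[[1L]]
      hits <- score_map[key(f[1L], f[2L], toupper(f[4L]), toupper(alts))]
      hits <- hits[!is.na(hits)]
      if (length(hits)) {
        ann <- sprintf("VLO=%s;VPP=%s",
                       paste(sprintf("%.6g", df$log_odds[hits]), collapse = ","),
                       paste(sprintf("%.6g", df$posterior[hits]), collapse = ","))
        f[8L] <- if (is.na(f[8L]) || f[8L] == "." || f[8L] == "") ann
                 else paste(f[8L], ann, sep = ";")
      }
      paste(f, collapse = "\t")
    }, character(1), USE.NAMES = FALSE)
    last_hdr <- max(which(hdr))
    writeLines(c(lines[hdr][-sum(hdr)], info_hdr, lines[hdr][sum(hdr)],
                 out_body), vcf_path)
  }
  invisible(c(tsv = tsv_path, vcf = vcf_path))
}

#' Read a score TSV written by [write_scores()]
#'
#' @param path TSV path
#' @return data.frame
#' @export
read_scores <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(contig = "character", ref = "character",
                                   alt = "character", flags = "character"),
                    stringsAsFactors = FALSE)
}
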