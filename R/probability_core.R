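# Log-space probability kernel for the generative read model.
#
# Every quantity is kept in natural-log space; products over 100-base reads
# underflow double precision long before they become scientifically small.
# Arithmetic-space computation appears only in the test oracles.

.BASES <- c("A", "C", "G", "T", "N")
.N_CODE <- 5L

#' Encode a nucleotide string as integer codes
#'
#' Internal helper: A,C,G,T,N -> 1..5. Lowercase is folded to uppercase and
#' any other symbol to N.
#' @param x single nucleotide string
#' @return integer vector of codes
#' @keywords internal
encode_bases <- function(x) {
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  code <- match(v, .BASES)
  code[is.na(code)] <- .N_CODE
  code
}

.check_error_probs <- function(e) {
  if (!is.numeric(e) || any(!is.finite(e)) || any(e <= 0) || any(e >= 1)) {
    stop("error probabilities must be finite and strictly inside (0, 1)",
         call. = FALSE)
  }
  invisible(e)
}

#' Clamp per-base error probabilities
#'
#' Phred-converted error probabilities are clamped away from the degenerate
#' endpoints: 0 and 1 break both branches of the base-match model, and 0.75
#' is the uniform-base limit beyond which a "mismatch" would be evidence of
#' a match.
#'
#' @param e numeric vector of error probabilities
#' @param lo,hi clamping bounds (defaults 1e-6 and 0.75)
#' @return clamped numeric vector
#' @export
clamp_error_probs <- function(e, lo = 1e-6, hi = 0.75) {
  pmin(pmax(e, lo), hi)
}

#' Per-base match log-probability
#'
#' The single-base term of the read model: the probability that the genome
#' base is `g` given the called read base `r` with error probability `e` —
#' `1 - e` on a match, `e/3` split evenly over the three mismatching bases.
#' An N on either side scores 1/4 regardless of `e` (maximum entropy; the
#' model is silent on ambiguous calls).
#'
#' Vectorised over its arguments.
#'
#' @param g genome (segment) base(s), characters in A,C,G,T,N
#' @param r called read base(s)
#' @param e per-base error probability(ies), each strictly in (0,1)
#' @return log-probability vector
#' @examples
#' base_match_log_prob("A", "A", 0.01)  # log(0.99)
#' base_match_log_prob("A", "C", 0.03)  # log(0.01)
#' @export
base_match_log_prob <- function(g, r, e) {
  .check_error_probs(e)
  g <- toupper(g)
  r <- toupper(r)
  if (!all(c(g, r) %in% .BASES)) {
    stop("bases must be one of A, C, G, T, N", call. = FALSE)
  }
  n <- max(length(g), length(r), length(e))
  g <- rep_len(g, n); r <- rep_len(r, n); e <- rep_len(e, n)
  out <- ifelse(g == r, log1p(-e), log(e / 3))
  out[g == "N" | r == "N"] <- log(0.25)
  out
}

# Per-position log-probability lookup for one read: a 5 x l matrix M with
# M[b, i] = log P[segment base b at i | read]. Rows follow .BASES order.
.read_logprob_matrix <- function(read_codes, e) {
  l <- length(read_codes)
  m <- matrix(0, nrow = 5L, ncol = l)
  le_mis <- log(e / 3)
  m[1L, ] <- le_mis; m[2L, ] <- le_mis; m[3L, ] <- le_mis; m[4L, ] <- le_mis
  idx_acgt <- read_codes <= 4L
  m[cbind(read_codes[idx_acgt], seq_len(l)[idx_acgt])] <- log1p(-e[idx_acgt])
  m[5L, ] <- log(0.25)           # segment N
  m[, !idx_acgt] <- log(0.25)    # read N
  m
}

# Vectorised scoring of many same-length segments of one window against one
# read: returns log P[r|g] for the segment starting at each 0-based offset.
# `m` may be supplied to reuse one read's matrix across windows.
.segment_log_probs <- function(window_codes, starts0, read_codes, e,
                               m = .read_logprob_matrix(read_codes, e)) {
  l <- ncol(m)
  n <- length(starts0)
  cols <- rep(seq_len(l), each = n)
  pos <- rep.int(starts0, l) + cols            # 1-based window index
  vals <- m[(cols - 1L) * 5L + window_codes[pos]]
  dim(vals) <- c(n, l)
  rowSums(vals)
}

# log-sum over all full-length segments of a pre-encoded window, given a
# read's log-prob matrix; -Inf when no segment fits.
.window_log_sum <- function(window_codes, l, m) {
  n_last <- length(window_codes) - l
  if (n_last < 0L) return(NA_real_)
  logsumexp(.segment_log_probs(window_codes, 0:n_last, NULL, NULL, m = m))
}

#' Construct a segment set
#'
#' A haplotype window together with the 0-based offsets of the read-length
#' segments to sum over. By default every offset at which a full-length
#' segment fits is used.
#'
#' @param window_seq nucleotide string (the haplotype window)
#' @param segment_length read length `l`
#' @param segment_starts integer vector of 0-based offsets; default all
#' @return object of class `segment_set`
#' @export
segment_set <- function(window_seq, segment_length,
                        segment_starts = NULL) {
  stopifnot(is.character(window_seq), length(window_seq) == 1L,
            segment_length >= 1L)
  wlen <- nchar(window_seq)
  if (is.null(segment_starts)) {
    segment_starts <-
      if (wlen >= segment_length) 0:(wlen - segment_length) else integer(0)
  }
  if (length(segment_starts) &&
      (min(segment_starts) < 0 ||
       max(segment_starts) > wlen - segment_length)) {
    stop("segment start out of range for window", call. = FALSE)
  }
  structure(list(window_seq = window_seq,
                 window_codes = encode_bases(window_seq),
                 segment_length = as.integer(segment_length),
                 segment_starts = as.integer(segment_starts)),
            class = "segment_set")
}

#' Construct a read observation
#'
#' One sequenced read as consumed by the kernel: the called sequence, its
#' per-base error probabilities, the mapped location(s), and the mapping
#' multiplicity m_r.
#'
#' @param read_id identifier
#' @param called_seq nucleotide string over A,C,G,T,N
#' @param error_probs numeric vector, same length, each in (0,1)
#' @param contig,pos mapped contig and 0-based leftmost reference position
#' @param strand `"+"` or `"-"` (reads are consumed in reference orientation;
#'   strand is bookkeeping only)
#' @param other_locations data.frame with columns `contig`, `pos` (0-based)
#'   for the read's additional mapped locations, or NULL
#' @param multiplicity m_r, the number of places the read maps; defaults to
#'   1 + number of other locations
#' @return object of class `read_obs`
#' @export
read_obs <- function(read_id, called_seq, error_probs,
                     contig = NA_character_, pos = NA_integer_, strand = "+",
                     other_locations = NULL, multiplicity = NULL) {
  if (nchar(called_seq) == 0L) stop("empty read", call. = FALSE)
  if (nchar(called_seq) != length(error_probs)) {
    stop("called_seq and error_probs lengths differ", call. = FALSE)
  }
  .check_error_probs(error_probs)
  if (is.null(other_locations)) {
    other_locations <- data.frame(contig = character(0), pos = integer(0))
  }
  if (is.null(multiplicity)) multiplicity <- 1L + nrow(other_locations)
  if (multiplicity < 1L) stop("multiplicity must be >= 1", call. = FALSE)
  structure(list(read_id = read_id,
                 called_seq = toupper(called_seq),
                 codes = encode_bases(called_seq),
                 error_probs = as.numeric(error_probs),
                 contig = contig, pos = pos, strand = strand,
                 other_locations = other_locations,
                 multiplicity = as.integer(multiplicity)),
            class = "read_obs")
}

#' Outside-paralog parameters
#'
#' @param h probability-scale constant for the outside-paralog term
#'   (default 1e-4); `h = 0` disables the outside source
#' @return object of class `paralog_params`
#' @export
paralog_params <- function(h = 1e-4) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h < 0) {
    stop("h must be a single finite number >= 0", call. = FALSE)
  }
  structure(list(h = h, include_outside = h > 0), class = "paralog_params")
}

#' Log-probability of a read given one genome segment
#'
#' Ungapped product over positions of the per-base term: the model assumes
#' no indel sequencing errors, so read and segment must have equal length.
#'
#' @param read a [read_obs()]
#' @param segment nucleotide string of the read's length
#' @return log-probability
#' @export
read_segment_log_prob <- function(read, segment) {
  stopifnot(inherits(read, "read_obs"))
  seg_codes <- encode_bases(segment)
  if (length(seg_codes) != length(read$codes)) {
    stop("segment length (", length(seg_codes), ") != read length (",
         length(read$codes), ")", call. = FALSE)
  }
  m <- .read_logprob_matrix(read$codes, read$error_probs)
  sum(m[cbind(seg_codes, seq_along(seg_codes))])
}

#' Log-sum of read probability over a segment set
#'
#' The unnormalised sum over segments g of P\[r|g\] (uniform segment prior
#' dropped, as a proportionality), returned in log space via log-sum-exp.
#'
#' @param read a [read_obs()]
#' @param segments a [segment_set()] with at least one segment
#' @return log of the probability sum
#' @export
read_given_segments_log_sum <- function(read, segments) {
  stopifnot(inherits(read, "read_obs"), inherits(segments, "segment_set"))
  if (length(segments$segment_starts) == 0L) {
    stop("empty segment set", call. = FALSE)
  }
  if (segments$segment_length != length(read$codes)) {
    stop("segment length != read length", call. = FALSE)
  }
  lp <- .segment_log_probs(segments$window_codes, segments$segment_starts,
                           read$codes, read$error_probs)
  logsumexp(lp)
}

#' Hamming-neighborhood probability sum (closed form)
#'
#' Sum over all sequences f within Hamming distance 1 of the called read
#' of the product of per-base terms. With p_i the match probability at
#' position i and s_i the total substitution probability, the closed form is
#' `prod(p_i) * (1 + sum(s_i / p_i))`: the exact-match term plus all 3*l
#' single-substitution terms. For an N read base p_i = 1/4 and s_i = 3/4.
#'
#' @param read a [read_obs()]
#' @return log of the neighborhood probability sum (always <= 0; equals 0
#'   exactly when l = 1, where HD <= 1 covers all four sequences)
#' @export
hamming_neighborhood_log_sum <- function(read) {
  stopifnot(inherits(read, "read_obs"))
  e <- read$error_probs
  p_match <- ifelse(read$codes == .N_CODE, 0.25, 1 - e)
  s_sub   <- ifelse(read$codes == .N_CODE, 0.75, e)
  sum(log(p_match)) + log1p(sum(s_sub / p_match))
}

#' Outside-paralog log term
#'
#' The contribution of an outside (reference-external) paralog source to a
#' read's probability: `m_r * h * sum_{f : HD(f, r*) <= 1} prod P[f_i|r_i]`.
#' The multiplicity factor m_r reflects that segments with many paralogs
#' inside the reference are more likely to have extra copies outside it.
#'
#' @param read a [read_obs()]
#' @param params a [paralog_params()]
#' @return log-probability; `-Inf` when `h = 0` (outside source disabled)
#' @export
outside_paralog_log_term <- function(read, params = paralog_params()) {
  stopifnot(inherits(read, "read_obs"), inherits(params, "paralog_params"))
  if (params$h == 0) return(-Inf)
  log(read$multiplicity) + log(params$h) + hamming_neighborhood_log_sum(read)
}

#' Log-probability of a read under a full genome hypothesis
#'
#' Combines, in log space: the mean over the hypothesis haplotype windows of
#' the per-window segment sums (a diploid hypothesis contributes the average
#' of its two chromosome copies; for homozygous or reference hypotheses the
#' copies coincide and the mean is the single-window sum), plus the
#' inside-paralog segment sums from the read's other mapped locations, plus
#' the outside-paralog term. The paralog terms are shared across hypotheses
#' and damp per-read likelihood ratios toward 1.
#'
#' @param read a [read_obs()]
#' @param hypothesis_segments list of one or two [segment_set()]s (the
#'   haplotype windows of the hypothesis)
#' @param inside_paralog_segments list (possibly empty) of [segment_set()]s,
#'   reference windows around the read's other mapped locations
#' @param params a [paralog_params()]
#' @return log-probability
#' @export
read_given_hypothesis_log_prob <- function(read, hypothesis_segments,
                                           inside_paralog_segments = list(),
                                           params = paralog_params()) {
  if (length(hypothesis_segments) == 0L) {
    stop("at least one hypothesis segment set required", call. = FALSE)
  }
  hap <- vapply(hypothesis_segments,
                function(s) read_given_segments_log_sum(read, s), numeric(1))
  terms <- hap - log(length(hap))
  if (length(inside_paralog_segments)) {
    terms <- c(terms, vapply(inside_paralog_segments,
                             function(s) read_given_segments_log_sum(read, s),
                             numeric(1)))
  }
  terms <- c(terms, outside_paralog_log_term(read, params))
  logsumexp(terms)
}

#' Numerically stable log(sum(exp(x)))
#'
#' @param x numeric vector of log-space values; `-Inf` entries are allowed
#' @return log of the sum of the exponentials
#' @export
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf (or an Inf/NaN propagates)
  m + log(sum(exp(x - m)))
}
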