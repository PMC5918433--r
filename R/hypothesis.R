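# Explicit genome hypotheses: clustering of nearby candidates, combinatorial
# subset enumeration with zygosity, haplotype-window construction, priors.

# Reference interval affected by a variant, 1-based inclusive [pos, pos+nchar(ref)-1].
.affected_start <- function(variants) variants$pos
.affected_end   <- function(variants) variants$pos + nchar(variants$ref) - 1L

#' Chain nearby candidate variants into clusters
#'
#' Transitive single-linkage chaining: two variants join one cluster iff the
#' gap between their reference-affected intervals is at most `max_dist` bp
#' (measured end-of-one to start-of-next, so indel REF alleles spanning
#' several bases chain by their full footprint, not their POS fields).
#' Variants a single read can span must be evaluated jointly, since a read
#' carrying one allele is evidence about its neighbours too.
#'
#' @param variants data.frame with columns `contig`, `pos` (1-based),
#'   `ref`, `alt`, `source_id`, sorted by (contig, pos)
#' @param max_dist chaining distance in bp (default 10)
#' @return list of `variant_cluster` objects, each a list with `variants`
#'   (data.frame rows) and `span` (0-based half-open interval on the contig)
#' @export
cluster_variants <- function(variants, max_dist = 10L) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) == 0L) return(list())
  ord <- order(variants$contig, variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    stop("variants must be sorted by (contig, pos)", call. = FALSE)
  }
  st <- .affected_start(variants)
  en <- .affected_end(variants)
  new_cluster <- c(TRUE, variants$contig[-1L] != variants$contig[-nrow(variants)] |
                     st[-1L] - cummax_by_contig(en, variants$contig)[-nrow(variants)] > max_dist)
  cid <- cumsum(new_cluster)
  lapply(split(seq_len(nrow(variants)), cid), function(idx) {
    v <- variants[idx, , drop = FALSE]
    rownames(v) <- NULL
    structure(list(variants = v,
                   contig = v$contig[1L],
                   span = c(min(.affected_start(v)) - 1L, max(.affected_end(v)))),
              class = "variant_cluster")
  })
}

# running max of interval ends within each contig (chaining must compare the
# next start against the furthest end seen so far, not just the previous row)
cummax_by_contig <- function(x, contig) {
  unlist(lapply(split(x, factor(contig, levels = unique(contig))), cummax),
         use.names = FALSE)
}

# Ordered subset selection under the combination cap: all subsets when
# 2^k <= max_combos; otherwise the empty set, all singletons, the full set,
# then subsets by increasing size until max_combos subsets (counting the
# empty set) are chosen.
.select_subsets <- function(k, max_combos) {
  if (k <= 30 && 2^k <= max_combos) {
    subsets <- list(integer(0))
    for (i in seq_len(k)) {
      subsets <- c(subsets, lapply(subsets, function(s) c(s, i)))
    }
    return(subsets)
  }
  subsets <- c(list(integer(0)), lapply(seq_len(k), function(i) i),
               list(seq_len(k)))
  size <- 2L
  while (length(subsets) < max_combos && size < k) {
    cmb <- utils::combn(k, size, simplify = FALSE)
    take <- min(length(cmb), max_combos - length(subsets))
    subsets <- c(subsets, cmb[seq_len(take)])
    size <- size + 1L
  }
  subsets[seq_len(min(length(subsets), max_combos))]
}

.subset_overlaps <- function(cluster, subset) {
  if (length(subset) < 2L) return(FALSE)
  v <- cluster$variants[subset, , drop = FALSE]
  st <- .affected_start(v); en <- .affected_end(v)
  o <- order(st)
  any(st[o][-1L] <= en[o][-length(o)])
}

#' Enumerate genome hypotheses for one cluster
#'
#' One reference hypothesis, plus a heterozygous and a homozygous hypothesis
#' for every non-empty subset of the cluster's variants (mixed zygosity is
#' not considered). The number of variant-inclusion combinations (subsets,
#' including the empty set) is capped at `max_combos`; for k variants with
#' 2^k <= max_combos the alternative-hypothesis count is 2*(2^k - 1).
#' Subsets whose variants overlap on the reference (e.g. two ALT alleles of
#' one multi-allelic site) are skipped; singletons are always evaluated.
#'
#' @param cluster a `variant_cluster`
#' @param max_combos cap on subsets tried, empty set included (default 1024)
#' @return list of `genome_hypothesis` objects: `subset` (integer indices
#'   into the cluster's variants; empty = reference), `zygosity` one of
#'   `"reference"`, `"heterozygous"`, `"homozygous"`, `prior` (assigned)
#' @export
enumerate_hypotheses <- function(cluster, max_combos = 1024L) {
  stopifnot(inherits(cluster, "variant_cluster"))
  k <- nrow(cluster$variants)
  if (k == 0L) stop("empty cluster", call. = FALSE)
  subsets <- .select_subsets(k, max_combos)
  keep <- !vapply(subsets, function(s) .subset_overlaps(cluster, s), logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " subset(s) with overlapping variants skipped",
            call. = FALSE)
    subsets <- subsets[keep]
  }
  hyps <- list(structure(list(subset = integer(0), zygosity = "reference",
                              prior = NA_real_), class = "genome_hypothesis"))
  for (s in subsets) {
    if (length(s) == 0L) next
    for (z in c("heterozygous", "homozygous")) {
      hyps[[length(hyps) + 1L]] <-
        structure(list(subset = s, zygosity = z, prior = NA_real_),
                  class = "genome_hypothesis")
    }
  }
  assign_priors(hyps)
}

#' Assign hypothesis priors within a cluster
#'
#' The reference hypothesis always receives prior 0.5; the remaining 0.5 is
#' divided evenly among the alternative hypotheses — an adjustment playing
#' the role of a multiple-hypothesis correction when many combinations are
#' tried. This prior expresses belief *after* knowing an upstream caller
#' proposed the variants, so it is unrelated to population polymorphism
#' rates.
#'
#' @param hypotheses list of `genome_hypothesis` objects containing exactly
#'   one reference hypothesis
#' @return the list with `prior` fields filled; priors sum to 1
#' @export
assign_priors <- function(hypotheses) {
  is_ref <- vapply(hypotheses, function(h) h$zygosity == "reference", logical(1))
  if (sum(is_ref) != 1L) {
    stop("exactly one reference hypothesis required", call. = FALSE)
  }
  n_alt <- length(hypotheses) - 1L
  if (n_alt == 0L) {
    stop("degenerate cluster: no alternative hypotheses", call. = FALSE)
  }
  for (i in seq_along(hypotheses)) {
    hypotheses[[i]]$prior <- if (is_ref[i]) 0.5 else 0.5 / n_alt
  }
  hypotheses
}

#' Build the haplotype window pair for a variant subset
#'
#' The reference window is the slice `[span_start - l - pad, span_end + l +
#' pad)` of the contig (0-based half-open, clipped to the contig); the
#' variant window is that slice with the subset's substitutions, insertions
#' and deletions applied right-to-left under the VCF anchored-allele
#' convention. The window width guarantees that every read overlapping the
#' cluster finds all of its shifted segments inside the window.
#'
#' @param reference contig sequence (single nucleotide string)
#' @param cluster a `variant_cluster`
#' @param subset integer indices into the cluster's variants (empty =
#'   reference window only)
#' @param read_length l, the read length the windows must accommodate
#' @param pad extra bases beyond l on each side (default 2)
#' @return list with `ref_window`, `var_window`, `window_start` (0-based
#'   contig offset of the windows), and `variant_seg_starts` (0-based
#'   offsets, within the variant window, of length-l segments overlapping at
#'   least one applied variant)
#' @export
build_haplotype_window <- function(reference, cluster, subset,
                                   read_length, pad = 2L) {
  stopifnot(inherits(cluster, "variant_cluster"))
  if (.subset_overlaps(cluster, subset)) {
    warning("overlapping variants in subset; skipped", call. = FALSE)
    return(NULL)
  }
  contig_len <- nchar(reference)
  w0 <- max(0L, cluster$span[1L] - read_length - pad)
  w1 <- min(contig_len, cluster$span[2L] + read_length + pad)
  ref_window <- substr(reference, w0 + 1L, w1)
  var_window <- ref_window
  v <- cluster$variants[subset, , drop = FALSE]
  if (nrow(v)) {
    v <- v[order(v$pos, decreasing = TRUE), , drop = FALSE]
    var_starts <- integer(0)   # 0-based offsets in the *variant* window
    for (i in seq_len(nrow(v))) {
      off <- v$pos[i] - 1L - w0                   # 0-based offset in window
      rlen <- nchar(v$ref[i])
      obs <- substr(var_window, off + 1L, off + rlen)
      if (obs != v$ref[i]) {
        stop("REF allele mismatch for variant at ", v$contig[i], ":",
             v$pos[i], " (expected ", v$ref[i], ", window has ", obs, ")",
             call. = FALSE)
      }
      var_window <- paste0(substr(var_window, 1L, off),
                           v$alt[i],
                           substr(var_window, off + rlen + 1L,
                                  nchar(var_window)))
    }
    # offsets of applied alleles in the final variant window: re-walk
    # left-to-right accumulating length deltas
    v_asc <- v[order(v$pos), , drop = FALSE]
    delta <- 0L
    ivs <- matrix(0L, nrow = nrow(v_asc), ncol = 2L)
    for (i in seq_len(nrow(v_asc))) {
      off <- v_asc$pos[i] - 1L - w0 + delta
      ivs[i, ] <- c(off, off + nchar(v_asc$alt[i]) - 1L)
      delta <- delta + nchar(v_asc$alt[i]) - nchar(v_asc$ref[i])
    }
    n_starts <- nchar(var_window) - read_length
    if (n_starts >= 0L) {
      starts <- 0:n_starts
      hit <- rep(FALSE, length(starts))
      for (i in seq_len(nrow(ivs))) {
        hit <- hit | (starts <= ivs[i, 2L] & starts + read_length - 1L >= ivs[i, 1L])
      }
      var_starts <- starts[hit]
    }
  } else {
    var_starts <- integer(0)
  }
  list(ref_window = ref_window, var_window = var_window,
       window_start = w0, variant_seg_starts = var_starts)
}
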