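# Ranking by marginal log-odds and precision-recall evaluation against a
# truth-labelled candidate set.

#' Rank scored variants
#'
#' Descending by marginal log-odds (equivalently by posterior, which is
#' monotone in the odds); ties broken by (contig, pos, ref, alt) so the
#' ordering is deterministic regardless of input order. Unevaluated
#' variants (NA log-odds) sink to the bottom.
#'
#' @param scored a `variant_scores` object or compatible data.frame
#' @return the data.frame in rank order
#' @export
rank_variants <- function(scored) {
  df <- as.data.frame(scored)
  stopifnot("log_odds" %in% names(df))
  df <- df[order(-df$log_odds, df$contig, df$pos, df$ref, df$alt,
                 na.last = TRUE), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Precision vs recall over ranked variants
#'
#' At each rank cutoff c (in increments of `step` calls, plus a final
#' partial increment at the callset size), precision is the fraction of the
#' top c candidates that exactly match a truth variant in sequence and
#' position — zygosity is not compared.
#'
#' @param ranked a rank-ordered data.frame (from [rank_variants()])
#' @param labels data.frame with contig, pos, ref, alt, label
#'   (`"truth"`/`"decoy"`), covering every ranked variant
#' @param step cutoff increment in calls (default 50)
#' @return object of class `pr_curve`: data.frame with `cutoff`, `n_true`
#'   (truth calls among the top cutoff), `precision`
#' @export
precision_recall <- function(ranked, labels, step = 50L) {
  key <- function(d) paste(d$contig, d$pos, d$ref, d$alt, sep = "\r")
  lab <- stats::setNames(labels$label, key(labels))
  rl <- lab[key(ranked)]
  if (anyNA(rl)) stop("every ranked variant needs a truth label", call. = FALSE)
  is_true <- rl == "truth"
  n <- length(is_true)
  cutoffs <- unique(c(seq(step, n, by = step), n))
  cum_true <- cumsum(is_true)
  out <- data.frame(cutoff = cutoffs,
                    n_true = unname(cum_true[cutoffs]),
                    precision = unname(cum_true[cutoffs] / cutoffs))
  structure(out, class = c("pr_curve", "data.frame"))
}

#' @export
plot.pr_curve <- function(x, ...) {
  graphics::plot(x$cutoff, x$precision, type = "b", pch = 16,
                 ylim = c(0, 1), xlab = "rank cutoff (calls)",
                 ylab = "precision", ...)
  invisible(x)
}

#' @export
print.variant_scores <- function(x, n = 10L, ...) {
  p <- attr(x, "params")
  cat(sprintf("Variant scores: %d candidate(s) in %d cluster(s)\n",
              nrow(x), length(unique(x$cluster_id))))
  cat(sprintf("  chaining <= %d bp, <= %d combinations, h = %g\n",
              p$max_dist, p$max_combos, p$h))
  print.data.frame(utils::head(as.data.frame(x), n), ...)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more row(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.variant_scores <- function(object, ...) {
  df <- as.data.frame(object)
  fin <- df$log_odds[is.finite(df$log_odds)]
  out <- list(n = nrow(df),
              n_clusters = length(unique(df$cluster_id)),
              n_supported = sum(fin > 0),
              n_no_data = sum(grepl("no_data", df$flags)),
              log_odds_quartiles = stats::quantile(fin, c(0.25, 0.5, 0.75),
                                                   na.rm = TRUE))
  class(out) <- "summary.variant_scores"
  out
}

#' @export
print.summary.variant_scores <- function(x, ...) {
  cat(sprintf("%d candidate(s), %d cluster(s); %d with positive log-odds, %d without data\n",
              x$n, x$n_clusters, x$n_supported, x$n_no_data))
  cat("log-odds quartiles:\n")
  print(signif(x$log_odds_quartiles, 4))
  invisible(x)
}

#' @export
plot.variant_scores <- function(x, ...) {
  lo <- x$log_odds[is.finite(x$log_odds)]
  graphics::hist(lo, breaks = 30, col = "grey80",
                 main = "Marginal posterior log-odds",
                 xlab = "log-odds (natural log)", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' @export
as.data.frame.variant_scores <- function(x, ...) {
  attr(x, "params") <- NULL
  attr(x, "hypothesis_tables") <- NULL
  class(x) <- "data.frame"
  x
}
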