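# Arithmetic-space brute-force oracles. These deliberately avoid the
# package's log-space code paths: plain products and sums over explicitly
# enumerated segments and sequences, usable only at toy sizes.

BASES4 <- c("A", "C", "G", "T")

# P[g_i | r_i] for one base pair, arithmetic space
arith_base_prob <- function(g, r, e) {
  if (g == "N" || r == "N") return(0.25)
  if (g == r) 1 - e else e / 3
}

# prod_i P[g_i | r_i]
arith_read_seg_prob <- function(read_chars, e, seg_chars) {
  stopifnot(length(read_chars) == length(seg_chars))
  p <- 1
  for (i in seq_along(read_chars)) {
    p <- p * arith_base_prob(seg_chars[i], read_chars[i], e[i])
  }
  p
}

# sum over every length-l substring of the window
arith_segments_sum <- function(window, read_chars, e) {
  l <- length(read_chars)
  wc <- strsplit(window, "")[[1]]
  n <- length(wc) - l + 1
  stopifnot(n >= 1)
  s <- 0
  for (st in seq_len(n)) {
    s <- s + arith_read_seg_prob(read_chars, e, wc[st:(st + l - 1)])
  }
  s
}

# sum over all sequences f with HD(f, r*) <= 1 of prod P[f_i | r_i],
# by explicit enumeration of the 3l + 1 neighbors
arith_hamming_sum <- function(read_chars, e) {
  total <- arith_read_seg_prob(read_chars, e, read_chars)
  for (i in seq_along(read_chars)) {
    for (b in BASES4) {
      if (b == read_chars[i]) next
      f <- read_chars
      f[i] <- b
      total <- total + arith_read_seg_prob(read_chars, e, f)
    }
  }
  total
}

# Arithmetic per-read likelihood under one hypothesis: mean over haplotype
# windows of the window segment sums, plus inside-paralog window sums, plus
# the outside term m_r * h * hamming_sum.
arith_read_hyp_prob <- function(read_chars, e, hyp_windows,
                                inside_windows = character(0),
                                m_r = 1, h = 0) {
  hap <- mean(vapply(hyp_windows, arith_segments_sum, numeric(1),
                     read_chars = read_chars, e = e))
  ins <- if (length(inside_windows))
    sum(vapply(inside_windows, arith_segments_sum, numeric(1),
               read_chars = read_chars, e = e)) else 0
  out <- if (h > 0) m_r * h * arith_hamming_sum(read_chars, e) else 0
  hap + ins + out
}

# Arithmetic marginal odds for variant v over a list of hypotheses, each
# list(windows = character vector, prior = p, has_v = logical); reads is a
# list of list(chars, e).
arith_marginal_odds <- function(reads, hyp_list, h = 0) {
  lik <- vapply(hyp_list, function(hp) {
    prod(vapply(reads, function(r)
      arith_read_hyp_prob(r$chars, r$e, as.list(hp$windows), h = h),
      numeric(1)))
  }, numeric(1))
  w <- vapply(hyp_list, `[[`, numeric(1), "prior") * lik
  has_v <- vapply(hyp_list, `[[`, logical(1), "has_v")
  sum(w[has_v]) / sum(w[!has_v])
}

random_read <- function(l, e_range = c(0.005, 0.3)) {
  chars <- sample(BASES4, l, replace = TRUE)
  e <- stats::runif(l, e_range[1], e_range[2])
  list(chars = chars, e = e,
       obs = read_obs("r", paste(chars, collapse = ""), e))
}

random_window <- function(n) paste(sample(BASES4, n, replace = TRUE),
                                   collapse = "")
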