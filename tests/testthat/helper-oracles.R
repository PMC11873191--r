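# Independent oracles used by the unit and acceptance suites.  These are
# deliberately brute-force / closed-form so they share no code path with the
# implementation they check.

# exhaustive Otsu: for every candidate threshold t (class 0 = intensity <= t)
# compute the between-class variance from the class means directly
brute_otsu <- function(counts) {
  n <- sum(counts)
  lv <- 0:255
  best <- -1
  best_t <- NA_integer_
  for (t in 0:254) {
    c0 <- counts[1:(t + 1)]
    c1 <- counts[(t + 2):256]
    n0 <- sum(c0); n1 <- sum(c1)
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(c0 * lv[1:(t + 1)]) / n0
    m1 <- sum(c1 * lv[(t + 2):256]) / n1
    v <- (n0 / n) * (n1 / n) * (m0 - m1)^2
    if (v > best + 1e-12) {   # strict improvement => smallest maximiser
      best <- v
      best_t <- t
    }
  }
  best_t
}

# geometric triangle oracle: signed point-to-line distance from the textbook
# formula (ax0 + by0 + c) / sqrt(a^2 + b^2), oriented so that points BELOW
# the peak-to-tail chord are positive (checked via the chord midpoint at
# height 0).  Integer numerators, so ties are detected exactly; the
# documented tie rule picks the maximiser nearest the tail end.
brute_triangle <- function(counts) {
  nz <- which(counts > 0) - 1L
  first <- min(nz); last <- max(nz)
  peak <- which.max(counts) - 1L
  tail_end <- if ((peak - first) >= (last - peak)) first else last
  if (peak == tail_end) return(peak)
  x1 <- peak; y1 <- counts[peak + 1L]
  x2 <- tail_end; y2 <- 0
  a <- y2 - y1; b <- x1 - x2; cc <- x2 * y1 - x1 * y2
  mid <- (x1 + x2) / 2
  sgn <- sign(a * mid + cc)          # side of the chord below it (y = 0)
  xs <- min(x1, x2):max(x1, x2)
  num <- sgn * (a * xs + b * counts[xs + 1L] + cc)
  cand <- xs[num == max(num)]
  cand[which.min(abs(cand - tail_end))]
}

# random bimodal histogram as a quantised Gaussian mixture image histogram
random_bimodal_hist <- function(n = 4000, mean_lo = 60, mean_hi = 200,
                                sd_lo = 15, sd_hi = 20, w_hi = 0.5) {
  n_hi <- round(n * w_hi)
  v <- c(round(rnorm(n - n_hi, mean_lo, sd_lo)),
         round(rnorm(n_hi, mean_hi, sd_hi)))
  tabulate(pmin(pmax(v, 0), 255) + 1L, nbins = 256L)
}

# strongly skewed unimodal histogram (background-dominated scan)
random_skewed_hist <- function(n = 6000) {
  v <- round(c(rnorm(n, 30, 8), rexp(round(n / 10), 1 / 40) + 60))
  tabulate(pmin(pmax(v, 0), 255) + 1L, nbins = 256L)
}

# random single-pixel chain, one pixel per column (monotone in x), so the
# only skeleton adjacencies are between consecutive chain pixels and the
# total length equals the polyline length through the pixel centres
random_chain <- function(n_steps = 40, nr = NULL) {
  nr <- nr %||% (n_steps + 10L)
  r <- numeric(n_steps + 1L)
  r[1] <- sample(5:(nr - 5), 1L)
  for (k in seq_len(n_steps)) {
    r[k + 1] <- min(max(r[k] + sample(-1:1, 1L), 2L), nr - 1L)
  }
  cbind(row = r, col = seq_len(n_steps + 1L) + 1L)
}

chain_to_matrix <- function(chain, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  m[chain] <- TRUE
  m
}

# Euclidean length of the polyline through the chain pixel centres
polyline_length <- function(chain) {
  d <- diff(chain)
  sum(sqrt(rowSums(d^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# logical matrix helpers
count_2x2_blocks <- function(s) {
  s <- unclass(s); attributes(s) <- list(dim = dim(s))
  sum(s[-nrow(s), -ncol(s)] & s[-1, -ncol(s)] &
      s[-nrow(s), -1] & s[-1, -1])
}

raw_logical <- function(m) {
  out <- unclass(m)
  attributes(out) <- list(dim = dim(m))
  out
}

rotate90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
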