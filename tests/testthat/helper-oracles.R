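# independent oracles used across test files; these deliberately use
# different mechanics from the package implementations they check

# activity_series-shaped object from a raw displacement vector
make_series <- function(d_mm, t0 = 0L, valid = rep(TRUE, length(d_mm)),
                        body_length_mm = 2.5) {
  out <- data.frame(t_s = t0 + seq_along(d_mm), d_mm = d_mm, valid = valid)
  out$d_mm[!valid] <- NA_real_
  attr(out, "body_length_mm") <- body_length_mm
  class(out) <- c("activity_series", "data.frame")
  out
}

# maximal sub-threshold runs found by boundary detection on the padded
# indicator (vs the rle-based scorer in the package)
oracle_sleep_runs <- function(quiescent, min_bout = 300L, t0 = 0L) {
  q <- as.logical(quiescent)
  n <- length(q)
  starts <- which(q & !c(FALSE, q[-n]))
  ends <- which(q & !c(q[-1], FALSE))
  len <- ends - starts + 1L
  keep <- len >= min_bout
  data.frame(start_s = t0 + starts[keep] - 1L, end_s = t0 + ends[keep],
             duration_s = len[keep])
}

# literal O(n^2) enumeration: every (i, j) window checked for being a
# maximal all-quiescent run of sufficient length
oracle_sleep_quadratic <- function(quiescent, min_bout = 300L, t0 = 0L) {
  q <- as.logical(quiescent)
  n <- length(q)
  rows <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!all(q[i:j])) break
      maximal <- (i == 1L || !q[i - 1L]) && (j == n || !q[j + 1L])
      if (maximal && j - i + 1L >= min_bout)
        rows[[length(rows) + 1L]] <-
          data.frame(start_s = t0 + i - 1L, end_s = t0 + j,
                     duration_s = j - i + 1L)
    }
  }
  if (!length(rows))
    return(data.frame(start_s = integer(), end_s = integer(),
                      duration_s = integer()))
  do.call(rbind, rows)
}

# random activity with realistic run structure: alternating quiescent /
# active blocks with geometric lengths
random_activity_day <- function(n = 86400L, mean_block = 400) {
  d <- numeric(0)
  state <- runif(1) < 0.5
  while (length(d) < n) {
    len <- 1L + stats::rgeom(1, 1 / mean_block)
    d <- c(d, if (state) runif(len, 0, 2.4) else runif(len, 2.6, 12))
    state <- !state
  }
  d[seq_len(n)]
}

expect_bouts_equal <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a)) {
    expect_equal(as.integer(a$start_s), as.integer(b$start_s))
    expect_equal(as.integer(a$end_s), as.integer(b$end_s))
  }
}
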