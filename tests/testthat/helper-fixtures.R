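# Shared fixtures, computed once per test run and memoised.  The clock
# pipeline (entrainment + 24 h analysis at 0.01 h grid) is the expensive
# part; everything downstream reuses it.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

clock_fixture <- function() {
  memo("clock_result", run_pipeline("clock"))
}

toy_linear_fixture <- function() {
  memo("toy_linear_result", run_pipeline("toy-linear"))
}

# reference always-inactive list for the packaged clock model (24 processes)
CLOCK_ALWAYS_INACTIVE <- c(
  "f_1,3", "f_2,3", "f_3,3", "f_4,6", "f_5,3", "f_5,6", "f_6,4", "f_7,4",
  "f_8,2", "f_8,7", "f_9,6", "f_9,7", "f_10,4", "f_11,4", "f_12,3",
  "f_12,6", "f_13,2", "f_13,4", "f_14,2", "f_14,6", "f_14,7", "f_15,4",
  "f_16,1", "f_16,4")

# brute-force 1-D clustering oracle: enumerate contiguous partitions
exhaustive_1d_kmeans <- function(x, z) {
  x <- sort(x); n <- length(x)
  cuts <- utils::combn(n - 1, z - 1, simplify = FALSE)
  if (z == 1) cuts <- list(integer(0))
  best <- NULL; best_ss <- Inf
  for (ct in cuts) {
    bnd <- c(0, ct, n)
    ss <- 0; means <- numeric(z)
    for (k in seq_len(z)) {
      seg <- x[(bnd[k] + 1):bnd[k + 1]]
      means[k] <- mean(seg)
      ss <- ss + sum((seg - means[k])^2)
    }
    if (ss < best_ss - 1e-12) { best_ss <- ss; best <- means }
  }
  list(means = best, inertia = best_ss)
}
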