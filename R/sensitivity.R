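#' Two-level resolution-V fractional factorial design
#'
#' Constructs a regular \eqn{2^{k-p}} fraction in which main effects and all
#' two-way interactions are mutually unaliased (resolution V or better).
#' Factor columns are chosen by a greedy search over the non-zero words of
#' \eqn{GF(2)^m} such that no product of up to four chosen words collapses to
#' the identity -- the defining relation then contains no word of length
#' \eqn{\le 4}.  For few factors the construction reduces to the classical
#' designs (full factorials; the 16-run, 5-factor half fraction with
#' generator E = ABCD).  The run count is the smallest power of two for
#' which the search succeeds within `max_runs`.
#'
#' @param n_factors number of two-level factors.
#' @param max_runs largest admissible run count (power of two).
#' @param factor_names optional column names.
#' @return A `ppa_design`: coded matrix `matrix` (runs x factors, entries
#'   -1/+1), the generating `words`, `n_basic` (the design is a
#'   \eqn{2^{k-p}} with \eqn{k-p =} `n_basic`), and `resolution = 5`
#'   (verified lower bound).
#' @export
build_two_level_design <- function(n_factors, max_runs = 4096,
                                   factor_names = NULL) {
  stopifnot(n_factors >= 1)
  need_df <- 1 + n_factors + n_factors * (n_factors - 1) / 2
  m <- max(ceiling(log2(need_df)), ceiling(log2(n_factors + 1)), 2)
  words <- NULL
  while (2^m <= max_runs) {
    words <- resV_words(n_factors, m)
    if (!is.null(words)) break
    m <- m + 1
  }
  if (is.null(words)) {
    m_ok <- m
    while (is.null(resV_words(n_factors, m_ok))) m_ok <- m_ok + 1
    stop(sprintf(
      "no clear resolution-V design for %d factors within %d runs (need %d)",
      n_factors, max_runs, 2^m_ok))
  }
  runs <- 2^m
  ## level of factor f in run u: parity of bits of (u AND word_f)
  u <- 0:(runs - 1)
  X <- vapply(words, function(w)
    1 - 2 * (bit_parity(bitwAnd(u, w))), numeric(runs))
  if (is.null(factor_names)) factor_names <- paste0("F", seq_len(n_factors))
  colnames(X) <- factor_names
  structure(list(matrix = X, words = words, n_basic = m,
                 n_factors = n_factors, resolution = 5L),
            class = "ppa_design")
}

## greedy 4-wise-independent word selection in GF(2)^m; NULL if impossible
resV_words <- function(n_factors, m) {
  forb <- logical(2^m); forb[1] <- TRUE
  chosen <- integer(0); S1 <- integer(0); S2 <- integer(0)
  w <- 1L
  while (length(chosen) < n_factors && w < 2^m) {
    if (!forb[w + 1L]) {
      n2 <- bitwXor(w, S1)   # new pairwise XORs
      n3 <- bitwXor(w, S2)   # new triple XORs
      chosen <- c(chosen, w)
      forb[c(w, n2, n3) + 1L] <- TRUE
      S2 <- c(S2, n2); S1 <- c(S1, w)
    }
    w <- w + 1L
  }
  if (length(chosen) < n_factors) NULL else chosen
}

bit_parity <- function(x) {
  p <- integer(length(x))
  while (any(x > 0)) { p <- bitwXor(p, bitwAnd(x, 1L)); x <- bitwShiftR(x, 1L) }
  p
}

#' @export
print.ppa_design <- function(x, ...) {
  cat(sprintf("<ppa_design> %d factors, %d runs (2^%d), resolution >= V\n",
              x$n_factors, nrow(x$matrix), x$n_basic))
  invisible(x)
}

#' Verify the alias structure of a design
#'
#' Exhaustively checks that no product of up to four factor words equals the
#' identity, i.e. that mains and two-way interactions are mutually clear.
#'
#' @param design a `ppa_design`.
#' @return `TRUE` (or stops with the offending word set).
#' @export
verify_resolution_v <- function(design) {
  w <- design$words
  n <- length(w)
  if (anyDuplicated(w) || any(w == 0)) stop("aliased main effects")
  if (n >= 2) {
    pair <- combn(n, 2)
    px <- bitwXor(w[pair[1, ]], w[pair[2, ]])
    if (any(px == 0)) stop("two mains aliased")
    if (any(px %in% w)) stop("a main is aliased with a two-way interaction")
    if (anyDuplicated(px)) stop("two two-way interactions aliased")
  }
  TRUE
}

#' Reduction-error experiment over a factorial design
#'
#' For every run of the design, every factor parameter is set to its coded
#' level (`0.8 x` or `1.2 x` nominal) and the original model and the
#' window's sub-model are re-simulated over the window with those
#' parameters; the window's global relative errors are recorded.  Both
#' systems start from the *nominal* original model's state at the window
#' opening: every sub-model is treated as valid for its own window
#' independently of the others, so parameter influence is measured within
#' the window, not through drift accumulated before it.  The schedule --
#' windows, masks and starting states -- stays frozen at its
#' nominal-parameter form.
#'
#' @param model a [process_model()].
#' @param schedule a `ppa_schedule` from the nominal analysis.
#' @param design a `ppa_design` whose column names are parameter names.
#' @param window window index `v`.
#' @param targets `"variables"` (16 per-variable errors) or `"outputs"`.
#' @param rel_levels low/high multipliers applied to the nominal values.
#' @param grid_step quadrature step in hours (coarser than the weight grid;
#'   the error integrals are smooth).
#' @param progress print a dot every 256 runs.
#' @return A `ppa_experiment`: `errors` (runs x targets), the design, the
#'   window, and the count of failed (excluded) runs.
#' @export
run_error_experiment <- function(model, schedule, design, window,
                                 targets = c("variables", "outputs"),
                                 rel_levels = c(0.8, 1.2),
                                 grid_step = 0.05, progress = FALSE) {
  targets <- match.arg(targets)
  fac <- colnames(design$matrix)
  miss <- setdiff(fac, names(model$parameters))
  if (length(miss))
    stop("design factors not in model parameters: ", paste(miss, collapse = ", "))
  bnd <- schedule$boundaries
  stopifnot(window >= 1, window <= length(bnd) - 1)
  a <- bnd[window]; b <- bnd[window + 1]
  win_grid <- sort(unique(c(seq(a, b, by = grid_step), b)))
  ## frozen nominal starting state at the window opening
  start <- schedule$x0
  if (a > bnd[1]) {
    pre <- simulate_model(model, seq(bnd[1], a, by = grid_step),
                          x0 = schedule$x0)
    start <- stats::setNames(pre$state[nrow(pre$state), ], model$variables)
  }

  n_t <- if (targets == "variables") length(model$variables)
         else length(model$outputs)
  E <- matrix(NA_real_, nrow(design$matrix), n_t)
  colnames(E) <- if (targets == "variables") model$variables
                 else names(model$outputs)
  failed <- 0L
  for (r in seq_len(nrow(design$matrix))) {
    p <- model$parameters
    lev <- ifelse(design$matrix[r, ] > 0, rel_levels[2], rel_levels[1])
    p[fac] <- p[fac] * lev
    ok <- tryCatch({
      orig <- simulate_model(model, win_grid, params = p, x0 = start)
      sub <- simulate_model(model, win_grid, params = p, x0 = start,
                            mask = schedule$masks[[window]])
      E[r, ] <- if (targets == "variables")
        global_relative_error(orig$state, sub$state, win_grid)
      else
        global_relative_error(evaluate_outputs(orig), evaluate_outputs(sub),
                              win_grid)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) failed <- failed + 1L
    if (progress && r %% 256 == 0) cat(".")
  }
  if (progress) cat("\n")
  if (failed)
    warning(sprintf("%d run(s) failed to integrate and were excluded", failed))
  keep <- stats::complete.cases(E)
  structure(list(errors = E[keep, , drop = FALSE],
                 design_matrix = design$matrix[keep, , drop = FALSE],
                 window = window, targets = targets, n_failed = failed),
            class = "ppa_experiment")
}

#' ANOVA decomposition for a two-level orthogonal design
#'
#' Least-squares estimation of the second-order linear model (grand mean,
#' main effects, two-way interactions).  For balanced orthogonal designs the
#' estimates are contrast means and the sums of squares split exactly:
#' \eqn{SS_T = SS_M + SS_r} with per-factor and per-pair components.  The
#' test suite checks the decomposition against a direct `lm()` fit.
#'
#' @param response numeric vector, one value per design run.
#' @param design_matrix coded -1/+1 matrix (runs x factors).
#' @return A `ppa_anova`: `mu`, `main` (named effect coefficients), `inter`
#'   (named pair coefficients), `SS_f`, `SS_fk`, `SS_T`, `SS_M`, `SS_r`.
#' @export
anova_decompose <- function(response, design_matrix) {
  X <- design_matrix
  if (inherits(X, "ppa_design")) X <- X$matrix
  n <- nrow(X)
  stopifnot(length(response) == n)
  if (!all(is.finite(response))) stop("response contains non-finite values")
  y <- response
  mu <- mean(y)
  yc <- y - mu
  b_main <- as.vector(crossprod(X, yc)) / n
  names(b_main) <- colnames(X)
  nf <- ncol(X)
  if (nf >= 2) {
    pr <- utils::combn(nf, 2)
    XI <- X[, pr[1, ], drop = FALSE] * X[, pr[2, ], drop = FALSE]
    b_int <- as.vector(crossprod(XI, yc)) / n
    names(b_int) <- paste(colnames(X)[pr[1, ]], colnames(X)[pr[2, ]],
                          sep = ":")
  } else {
    pr <- NULL; b_int <- numeric(0)
  }
  SS_f <- n * b_main^2
  SS_fk <- n * b_int^2
  SS_T <- sum(yc^2)
  SS_M <- sum(SS_f) + sum(SS_fk)
  structure(list(mu = mu, main = b_main, inter = b_int,
                 pairs = pr, SS_f = SS_f, SS_fk = SS_fk,
                 SS_T = SS_T, SS_M = SS_M, SS_r = SS_T - SS_M,
                 n_runs = n),
            class = "ppa_anova")
}

#' Total sensitivity indices from an ANOVA decomposition
#'
#' \eqn{tSI_f = (SS_f + \sum_{k \ne f} SS_{fk}) / SS_T}: the share of the
#' response variance attributable to a factor's main effect plus all its
#' two-way interactions.  The non-normalised variant multiplies by the
#' response variance \eqn{\sigma^2 = SS_T/(N-1)} so indices remain
#' comparable across responses.  A zero-variance response yields all-zero
#' indices.
#'
#' @param decomp a `ppa_anova`.
#' @return A `ppa_tsi`: `tSI`, `tSI_prime`, `sigma2`.
#' @export
total_sensitivity_indices <- function(decomp) {
  nf <- length(decomp$main)
  tSI <- stats::setNames(numeric(nf), names(decomp$main))
  if (decomp$SS_T > 0) {
    inter_sum <- stats::setNames(numeric(nf), names(decomp$main))
    if (!is.null(decomp$pairs)) {
      for (q in seq_len(ncol(decomp$pairs))) {
        inter_sum[decomp$pairs[1, q]] <-
          inter_sum[decomp$pairs[1, q]] + decomp$SS_fk[q]
        inter_sum[decomp$pairs[2, q]] <-
          inter_sum[decomp$pairs[2, q]] + decomp$SS_fk[q]
      }
    }
    tSI <- (decomp$SS_f + inter_sum) / decomp$SS_T
  }
  sigma2 <- decomp$SS_T / max(decomp$n_runs - 1, 1)
  structure(list(tSI = tSI, tSI_prime = sigma2 * tSI, sigma2 = sigma2),
            class = "ppa_tsi")
}

#' PCA-generalised sensitivity indices for multivariate errors
#'
#' Decomposes the runs x targets error matrix by unscaled (covariance) PCA,
#' retains the smallest number of components whose cumulated inertia reaches
#' `inertia`, performs the factorial ANOVA on each component's scores, and
#' aggregates: \eqn{tGSI_f = \sum_c \omega_c\, tSI^c_f} with \eqn{\omega_c}
#' the component's inertia share.
#'
#' @param errors numeric matrix (runs x targets), e.g.
#'   `ppa_experiment$errors`.
#' @param design_matrix coded design matrix matching the rows.
#' @param inertia cumulated-inertia cut-off (default 0.95).
#' @return A `ppa_gsi`: `tGSI` (named), `omega` (all inertia shares),
#'   `n_components`, and the per-component `tSI` matrix.
#' @export
pca_generalised_indices <- function(errors, design_matrix, inertia = 0.95) {
  X <- design_matrix
  if (inherits(X, "ppa_design")) X <- X$matrix
  errors <- cbind(errors)
  stopifnot(nrow(errors) == nrow(X), nrow(errors) >= 2)
  pc <- stats::prcomp(errors, center = TRUE, scale. = FALSE)
  lam <- pc$sdev^2
  if (sum(lam) == 0) {
    z <- stats::setNames(numeric(ncol(X)), colnames(X))
    return(structure(list(tGSI = z, omega = lam, n_components = 0L,
                          component_tSI = NULL),
                     class = "ppa_gsi"))
  }
  omega <- lam / sum(lam)
  nc <- which(cumsum(omega) >= inertia - 1e-12)[1]
  comp_tsi <- sapply(seq_len(nc), function(c) {
    dec <- anova_decompose(pc$x[, c], X)
    total_sensitivity_indices(dec)$tSI
  })
  comp_tsi <- cbind(comp_tsi)
  rownames(comp_tsi) <- colnames(X)
  tGSI <- as.vector(comp_tsi %*% omega[seq_len(nc)])
  names(tGSI) <- colnames(X)
  structure(list(tGSI = tGSI, omega = omega, n_components = nc,
                 component_tSI = comp_tsi),
            class = "ppa_gsi")
}

#' @export
print.ppa_gsi <- function(x, ...) {
  cat(sprintf("<ppa_gsi> %d components (%.1f%% inertia), top factors: %s\n",
              x$n_components,
              100 * sum(x$omega[seq_len(max(x$n_components, 1))]),
              paste(names(sort(x$tGSI, decreasing = TRUE))[1:min(5, length(x$tGSI))],
                    collapse = ", ")))
  invisible(x)
}

#' Parameters occurring in a set of processes
#'
#' @param model a [process_model()].
#' @param labels process labels (`"f_i,j"`).
#' @return Character vector of parameter names referenced by those terms.
#' @export
parameters_in_processes <- function(model, labels) {
  idx <- match(labels, model$labels)
  if (anyNA(idx)) stop("unknown process label")
  flat <- unlist(model$terms, recursive = FALSE)
  syms <- unique(unlist(lapply(flat[idx], function(trm) all.vars(trm$expr))))
  intersect(syms, names(model$parameters))
}

#' Share of top-k generalised sensitivity carried by neglected-process parameters
#'
#' Restricts to the `k` factors with the largest tGSI and reports the
#' percentage of their summed tGSI belonging to factors classified as
#' "inactive-process parameters" -- parameters appearing in at least one
#' process dropped in the window, even if they also appear in kept processes
#' (worst-case classification).
#'
#' @param gsi a `ppa_gsi`.
#' @param inactive_params character vector of inactive-classified parameter
#'   names.
#' @param k number of top factors to use (default 10).
#' @return Percentage in `[0, 100]`.
#' @export
inactive_parameter_ratio <- function(gsi, inactive_params, k = 10) {
  stopifnot(k >= 1, k <= length(gsi$tGSI))
  top <- names(sort(gsi$tGSI, decreasing = TRUE))[seq_len(k)]
  tot <- sum(gsi$tGSI[top])
  if (tot == 0) return(0)
  100 * sum(gsi$tGSI[intersect(top, inactive_params)]) / tot
}

#' Design export as CSV (coded -1/+1 levels)
#' @param design a `ppa_design`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design$matrix), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
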