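#' Drop always-inactive processes
#'
#' Builds the first reduced model: every process whose weight stays below the
#' activity threshold over the whole horizon is set to zero, all other terms
#' are kept verbatim.
#'
#' @param model a [process_model()].
#' @param activity a `ppa_activity` computed on the model's own trajectory.
#' @return A `ppa_reduced` object: the base model, a named logical `mask`
#'   (`TRUE` = keep), and a `provenance` string per dropped term.
#' @export
eliminate_always_inactive <- function(model, activity) {
  mask <- stats::setNames(!(model$labels %in% activity$always_inactive),
                          model$labels)
  structure(list(base = model, mask = mask,
                 provenance = stats::setNames(
                   rep("always inactive", sum(!mask)),
                   model$labels[!mask])),
            class = "ppa_reduced")
}

#' @export
print.ppa_reduced <- function(x, ...) {
  cat(sprintf("<ppa_reduced> %s: %d/%d processes kept\n",
              x$base$name, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Number of switching-time clusters
#'
#' The trade-off rule: half the difference between the maximum and minimum
#' number of simultaneously active processes, rounded half away from zero.
#'
#' @param activity a `ppa_activity` object.
#' @return Integer cluster count `z` (0 when the count never varies).
#' @export
choose_cluster_count <- function(activity) {
  ex <- activity_extrema(activity)
  z <- (ex[2] - ex[1]) / 2
  as.integer(floor(z + 0.5))  # half rounds up (values are non-negative)
}

#' Optimal 1-D clustering of switching times
#'
#' Partitions the sorted times into `z` contiguous clusters minimising the
#' within-cluster sum of squares.  In one dimension the optimum is contiguous,
#' so it is found exactly by dynamic programming; the result is deterministic
#' and `seed` is accepted only for interface symmetry with stochastic
#' clustering routines.
#'
#' @param times numeric vector of switching times (any order).
#' @param z number of clusters, `1 <= z <= length(times)`.
#' @param seed ignored (the algorithm is exact).
#' @return A `ppa_clusters` object: sorted cluster `means`, cluster `sizes`,
#'   an `assignment` (cluster id per sorted time), the sorted `times`, and
#'   the achieved `inertia`.
#' @export
cluster_switching_times <- function(times, z, seed = NULL) {
  x <- sort(as.numeric(times))
  n <- length(x)
  if (z < 1 || z > n) stop("z must satisfy 1 <= z <= length(times)")
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssq <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    max(s2 - s^2 / (j - i + 1), 0)
  }
  D <- matrix(Inf, z, n); B <- matrix(0L, z, n)
  for (j in 1:n) { D[1, j] <- ssq(1, j); B[1, j] <- 1L }
  if (z > 1) for (k in 2:z) for (j in k:n) for (i in k:j) {
    v <- D[k - 1, i - 1] + ssq(i, j)
    if (v < D[k, j]) { D[k, j] <- v; B[k, j] <- i }
  }
  starts <- integer(z); e <- n
  for (k in z:1) { starts[k] <- B[k, e]; e <- starts[k] - 1L }
  assignment <- rep(seq_len(z), times = diff(c(starts, n + 1L)))
  means <- vapply(seq_len(z), function(k) mean(x[assignment == k]), 0)
  structure(list(z = z, means = means, sizes = tabulate(assignment, z),
                 assignment = assignment, times = x, inertia = D[z, n]),
            class = "ppa_clusters")
}

#' @export
print.ppa_clusters <- function(x, ...) {
  cat(sprintf("<ppa_clusters> z = %d, means = %s, sizes = %s\n", x$z,
              paste(signif(x$means, 4), collapse = ", "),
              paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Build the sub-model schedule
#'
#' Processes whose switching times fall in one cluster are assumed to switch
#' together at the cluster mean (the *reduced switching time*).  Each
#' process's activity timeline is therefore snapped: every crossing moves to
#' its cluster's mean, and a pair of crossings landing in the same cluster
#' annihilates (the process keeps its pre-crossing state).  A process is
#' dropped in a window exactly when its snapped timeline is inactive
#' throughout that window.  The first window keeps everything except the
#' always-inactive set: the first reduced model is by construction the
#' global simplification, processes that only become active at the first
#' reduced switching time included.
#'
#' @param model a [process_model()].
#' @param activity `ppa_activity` from [classify_activity()].
#' @param switching switching data frame from [classify_activity()].
#' @param clusters `ppa_clusters` from [cluster_switching_times()]; `NULL`
#'   for a single-window schedule (no switching).
#' @param x0 analysis initial state (stored for downstream error runs).
#' @return A `ppa_schedule`: window `boundaries`, per-window named keep
#'   `masks`, per-window `dropped` and `extra_dropped` label sets, the
#'   always-inactive set, and the analysis state.
#' @export
build_schedule <- function(model, activity, switching, clusters,
                           x0 = model$initial_state) {
  t0 <- activity$times[1]
  tT <- activity$times[length(activity$times)]
  ai <- activity$always_inactive
  base_mask <- stats::setNames(!(model$labels %in% ai), model$labels)

  if (is.null(clusters) || nrow(switching) == 0 ||
      (!is.null(clusters) && clusters$z == 0)) {
    return(structure(list(
      boundaries = c(t0, tT), masks = list(base_mask),
      dropped = list(ai), extra_dropped = list(character(0)),
      always_inactive = ai, x0 = x0[model$variables], model = model$name),
      class = "ppa_schedule"))
  }

  means <- clusters$means
  bnd <- c(t0, means, tT)
  nw <- length(means) + 1

  ## nearest-mean cluster assignment for each crossing of each process
  edges <- (means[-length(means)] + means[-1]) / 2
  cluster_of <- function(tc) findInterval(tc, edges) + 1L

  act0 <- activity$active[1, ]
  masks <- vector("list", nw)
  masks[[1]] <- base_mask
  for (v in 2:nw) {
    keep <- base_mask
    for (lab in model$labels[base_mask]) {
      s <- act0[lab]
      tc <- switching$time[switching$process == lab]
      if (length(tc)) {
        cl <- cluster_of(tc)
        for (k in sort(unique(cl)))
          if (sum(cl == k) %% 2 == 1 && means[k] <= bnd[v] + 1e-9)
            s <- !s   # odd number of crossings in the cluster: net toggle
      }
      keep[lab] <- s
    }
    masks[[v]] <- keep
  }
  dropped <- lapply(masks, function(mk) names(mk)[!mk])
  structure(list(
    boundaries = bnd, masks = masks, dropped = dropped,
    extra_dropped = lapply(dropped, setdiff, y = ai),
    always_inactive = ai, x0 = x0[model$variables], model = model$name),
    class = "ppa_schedule")
}

#' @export
print.ppa_schedule <- function(x, ...) {
  cat(sprintf("<ppa_schedule> %s: %d windows\n", x$model,
              length(x$masks)))
  for (v in seq_along(x$masks))
    cat(sprintf("  SM%d [%5.2f, %5.2f) h: %d dropped (%d beyond always-inactive)\n",
                v, x$boundaries[v], x$boundaries[v + 1],
                length(x$dropped[[v]]), length(x$extra_dropped[[v]])))
  invisible(x)
}

#' Global relative error between two output series
#'
#' \deqn{e_h = \int_a^b |y_h - y_h^r|\,dt \Big/ \int_a^b |y_h|\,dt,}
#' evaluated by trapezoidal quadrature on the common grid.
#'
#' @param reference numeric matrix (or vector), reference series by column.
#' @param approx matching matrix of approximating series.
#' @param times shared time grid.
#' @return Named numeric vector of errors, one per column.
#' @export
global_relative_error <- function(reference, approx, times) {
  reference <- cbind(reference); approx <- cbind(approx)
  stopifnot(nrow(reference) == length(times),
            all(dim(reference) == dim(approx)))
  trap <- function(y) sum(diff(times) * (y[-length(y)] + y[-1]) / 2)
  vapply(seq_len(ncol(reference)), function(h) {
    den <- trap(abs(reference[, h]))
    if (den == 0) stop("reference series is identically zero: error undefined")
    trap(abs(reference[, h] - approx[, h])) / den
  }, 0) |> stats::setNames(colnames(reference))
}

#' Per-window reduction errors of a sub-model schedule
#'
#' Integrates each sub-model over its window and compares it with the
#' original model.  Without propagation every sub-model starts from the
#' original model's state at the window opening; with propagation it starts
#' from the previous sub-model's final state.
#'
#' @param model a [process_model()].
#' @param schedule a `ppa_schedule`.
#' @param propagate propagate sub-model end states into the next window?
#' @param grid_step quadrature/reporting step within windows (hours).
#' @param params parameters for both systems.
#' @return A `ppa_errors` object: matrices `outputs` and `variables`
#'   (window x series) of global relative errors, the window boundaries and
#'   the propagation flag.
#' @export
windowed_errors <- function(model, schedule, propagate = FALSE,
                            grid_step = 0.01, params = model$parameters) {
  bnd <- schedule$boundaries
  nw <- length(bnd) - 1
  full_grid <- seq(bnd[1], bnd[nw + 1], by = grid_step)
  full_grid <- sort(unique(c(full_grid, bnd)))
  orig <- simulate_model(model, full_grid, params = params, x0 = schedule$x0)

  out_err <- matrix(NA_real_, nw, length(model$outputs),
                    dimnames = list(paste0("SM", seq_len(nw)),
                                    names(model$outputs)))
  var_err <- matrix(NA_real_, nw, length(model$variables),
                    dimnames = list(paste0("SM", seq_len(nw)),
                                    model$variables))
  carry <- NULL
  for (v in seq_len(nw)) {
    w <- full_grid[full_grid >= bnd[v] & full_grid <= bnd[v + 1]]
    io <- which(abs(full_grid - bnd[v]) < 1e-9)[1]
    start <- if (propagate && v > 1) carry
             else stats::setNames(orig$state[io, ], model$variables)
    sub <- simulate_model(model, w, params = params, x0 = start,
                          mask = schedule$masks[[v]])
    carry <- stats::setNames(sub$state[nrow(sub$state), ], model$variables)
    sel <- full_grid >= bnd[v] & full_grid <= bnd[v + 1]
    ref_state <- orig$state[sel, , drop = FALSE]
    out_err[v, ] <- global_relative_error(
      evaluate_outputs(orig_window(orig, sel)),
      evaluate_outputs(sub), w)
    var_err[v, ] <- global_relative_error(ref_state, sub$state, w)
  }
  structure(list(outputs = out_err, variables = var_err,
                 boundaries = bnd, propagate = propagate,
                 model = model$name),
            class = "ppa_errors")
}

orig_window <- function(traj, sel) {
  structure(list(times = traj$times[sel],
                 state = traj$state[sel, , drop = FALSE],
                 params = traj$params, outputs = traj$outputs,
                 model = traj$model),
            class = "ppa_trajectory")
}

#' @export
print.ppa_errors <- function(x, ...) {
  cat(sprintf("<ppa_errors> %s (%s propagation)\n", x$model,
              if (x$propagate) "with" else "without"))
  print(round(x$outputs, 4))
  invisible(x)
}

#' Average per-variable error in one window
#'
#' Arithmetic mean of the state-variable errors of window `v`.
#'
#' @param errors a `ppa_errors` object.
#' @param v window index.
#' @return Scalar mean error.
#' @export
average_variable_error <- function(errors, v) {
  stopifnot(v >= 1, v <= nrow(errors$variables))
  mean(errors$variables[v, ])
}

#' Conservative a priori bound on the reduction error
#'
#' A Gronwall-type estimate for the deviation between the full model and a
#' model with sub-threshold processes removed: if on a box `domain` every
#' per-equation process sum is bounded by \eqn{B_i} and the vector field has
#' Lipschitz constant \eqn{L}, then
#' \deqn{\|x(t) - y(t)\| \le \delta \frac{\|B\|}{L}\left(e^{L (t - t_0)} - 1\right).}
#' \eqn{L} is estimated numerically as the maximum induced infinity-norm of
#' the Jacobian over sampled box points (central finite differences), and
#' \eqn{B_i} as the sampled maximum of \eqn{\sum_j |f_{ij}|}.  The bound is
#' deliberately conservative; its only guaranteed property is to dominate
#' the realised deviation while the trajectory stays inside the box.
#'
#' @param model a [process_model()].
#' @param domain 2 x n matrix (rows: lower, upper bounds per variable).
#' @param delta activity threshold used in the reduction.
#' @param window numeric length-2 time window.
#' @param params parameter vector.
#' @param n_samples number of quasi-random box samples.
#' @param t_eval times (within the window) at which to tabulate the bound.
#' @return A `ppa_bound`: `L`, per-variable `B`, `delta` and a function-like
#'   table `bound` on `t_eval`.
#' @export
theoretical_error_bound <- function(model, domain, delta,
                                    window = model$horizon,
                                    params = model$parameters,
                                    n_samples = 128,
                                    t_eval = seq(window[1], window[2],
                                                 length.out = 49)) {
  domain <- rbind(domain)
  if (ncol(domain) != length(model$variables) || nrow(domain) != 2)
    stop("domain must be a 2 x n_variables matrix of box bounds")
  if (any(domain[2, ] < domain[1, ])) stop("empty domain box")
  nv <- length(model$variables)
  ## deterministic low-discrepancy sampling (Kronecker sequence)
  golden <- (sqrt(5) - 1) / 2
  u <- sapply(seq_len(nv), function(j) (seq_len(n_samples) * j * golden) %% 1)
  pts <- t(domain[1, ] + t(u) * (domain[2, ] - domain[1, ]))
  pts <- rbind(pts, domain[1, ], domain[2, ], colMeans(domain))

  var_of <- rep(seq_len(nv), lengths(model$terms))
  rhs_at <- function(x, t) {
    vals <- as.vector(eval_terms_grid(model, t, matrix(x, 1), params))
    as.vector(tapply(vals, var_of, sum))
  }
  tmid <- mean(window)
  L <- 0; B <- rep(0, nv)
  h <- pmax(1e-6, 1e-6 * (domain[2, ] - domain[1, ]))
  for (r in seq_len(nrow(pts))) {
    x <- pts[r, ]
    vals <- as.vector(eval_terms_grid(model, tmid, matrix(x, 1), params))
    B <- pmax(B, as.vector(tapply(abs(vals), var_of, sum)))
    J <- matrix(0, nv, nv)
    for (j in seq_len(nv)) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h[j]; xm[j] <- xm[j] - h[j]
      J[, j] <- (rhs_at(xp, tmid) - rhs_at(xm, tmid)) / (2 * h[j])
    }
    L <- max(L, max(rowSums(abs(J))))
  }
  if (L <= 0) stop("estimated Lipschitz constant is not positive")
  bnd <- delta * (sqrt(sum(B^2)) / L) * (exp(L * (t_eval - window[1])) - 1)
  structure(list(L = L, B = B, delta = delta, window = window,
                 t = t_eval, bound = bnd),
            class = "ppa_bound")
}

#' @export
print.ppa_bound <- function(x, ...) {
  cat(sprintf("<ppa_bound> L = %.4g, ||B|| = %.4g, delta = %g on [%g, %g] h\n",
              x$L, sqrt(sum(x$B^2)), x$delta, x$window[1], x$window[2]))
  invisible(x)
}

#' Export a schedule as JSON
#'
#' Boundaries and per-window dropped-process labels, machine readable.
#'
#' @param schedule a `ppa_schedule`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(
    list(boundaries = schedule$boundaries,
         always_inactive = schedule$always_inactive,
         windows = lapply(seq_along(schedule$masks), function(v)
           list(window = v,
                from = schedule$boundaries[v],
                to = schedule$boundaries[v + 1],
                dropped = schedule$dropped[[v]]))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
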