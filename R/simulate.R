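#' Simulate a process model
#'
#' Numerically integrates the ODE system on a fixed output grid with the
#' stiff-capable `lsoda` solver (deSolve).  Forced models are integrated in
#' segments split at the forcing discontinuities so the step-size controller
#' never integrates across a jump.  Individual process terms can be switched
#' off through `mask`, which is how reduced models and sub-models are
#' simulated; dropped terms contribute exactly zero while all kept terms are
#' evaluated verbatim.
#'
#' The packaged clock model is dispatched to a compiled right-hand side;
#' every other model (and the clock with `use_compiled = FALSE`) is
#' integrated through an R-level evaluator of the symbolic terms.  The two
#' paths agree to solver precision and the equivalence is covered by the test
#' suite.
#'
#' @param model a [process_model()].
#' @param times strictly increasing output grid (hours).
#' @param params parameter vector; defaults to the model's.
#' @param x0 named initial state; defaults to the model's.
#' @param mask optional logical vector over `process_labels(model)` (`TRUE` =
#'   keep).  `NULL` keeps every term.
#' @param rtol,atol solver tolerances (defaults 1e-8, 1e-10: switching times
#'   are reported to sub-0.1 h precision downstream, which needs tight
#'   integration).
#' @param use_compiled use the compiled fast path when available.
#' @return A `ppa_trajectory`: list with `times`, `state` (matrix), `params`,
#'   `mask`, `outputs` and the model name.
#' @export
simulate_model <- function(model, times, params = model$parameters,
                           x0 = model$initial_state, mask = NULL,
                           rtol = 1e-8, atol = 1e-10, use_compiled = TRUE) {
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  if (is.null(mask)) mask <- rep(TRUE, length(model$labels))
  if (length(mask) != length(model$labels))
    stop("mask must have one entry per process term")
  x0 <- x0[model$variables]
  if (anyNA(x0)) stop("x0 must contain every model variable")

  segs <- forcing_segments(model, times)
  compiled <- use_compiled && identical(model$name, "clock")
  rhs <- if (compiled) NULL else make_r_rhs(model, params, mask)
  parms <- if (compiled) clock_parms_vector(params, mask, model$forcing)

  state <- matrix(NA_real_, length(times), length(x0),
                  dimnames = list(NULL, model$variables))
  y <- unname(x0)
  for (sg in segs) {
    tt <- sg$times
    sol <- if (compiled)
      deSolve::ode(y, tt, func = "clock_derivs", parms = parms,
                   dllname = "ppa", initfunc = "clock_init",
                   method = "lsoda", rtol = rtol, atol = atol)
    else
      deSolve::ode(y, tt, rhs, NULL, method = "lsoda",
                   rtol = rtol, atol = atol)
    sol <- unclass(sol)
    if (nrow(sol) < length(tt) || !all(is.finite(sol[, -1]))) {
      bad <- if (nrow(sol)) tt[min(nrow(sol), which(!stats::complete.cases(
        is.finite(sol[, -1, drop = FALSE]) * 1))[1])] else tt[1]
      stop(sprintf("integration failed near t = %.4g h (non-finite state)",
                   bad))
    }
    y <- sol[nrow(sol), -1]
    keep <- match(round(sg$report, 10), round(tt, 10))
    state[match(round(sg$report, 10), round(times, 10)), ] <-
      sol[keep, -1, drop = FALSE]
  }

  structure(list(times = times, state = state, params = params,
                 mask = mask, outputs = model$outputs, model = model$name),
            class = "ppa_trajectory")
}

#' @export
print.ppa_trajectory <- function(x, ...) {
  cat(sprintf("<ppa_trajectory> %s: %d points on [%g, %g] h, %d variables\n",
              x$model, length(x$times), min(x$times), max(x$times),
              ncol(x$state)))
  invisible(x)
}

## split the output grid at forcing discontinuities; each segment reports the
## original grid points it contains (boundaries are added for integration only)
forcing_segments <- function(model, times) {
  t0 <- times[1]; t1 <- times[length(times)]
  brk <- numeric(0)
  if (!is.null(model$forcing)) {
    f <- model$forcing
    k0 <- floor(t0 / f$period); k1 <- ceiling(t1 / f$period)
    cand <- sort(unique(c(outer(seq(k0, k1) * f$period, c(0, f$on), `+`))))
    brk <- cand[cand > t0 & cand < t1]
  }
  edges <- c(t0, brk, t1)
  lapply(seq_len(length(edges) - 1), function(s) {
    lo <- edges[s]; hi <- edges[s + 1]
    rep_pts <- times[times >= lo & times <= hi]
    tt <- sort(unique(c(lo, rep_pts, hi)))
    list(times = tt, report = rep_pts)
  })
}

## build an R closure dy/dt from the symbolic terms (masked terms folded out)
make_r_rhs <- function(model, params, mask) {
  keep <- split(mask, rep(seq_along(model$terms), lengths(model$terms)))
  sums <- lapply(seq_along(model$terms), function(i) {
    kept <- model$terms[[i]][keep[[i]]]
    if (!length(kept)) return(quote(0))
    Reduce(function(a, b) call("+", a, b), lapply(kept, `[[`, "expr"))
  })
  pl <- as.list(params)
  vars <- model$variables
  forcing <- model$forcing
  function(t, y, dots) {
    env <- list2env(pl)
    if (!is.null(forcing)) {
      tau <- t %% forcing$period
      if (tau == 0 && t > 0) tau <- forcing$period  # left-continuous
      if (tau < forcing$on)
        env[[forcing$param]] <- pl[[forcing$param]] * forcing$multiplier
    }
    for (j in seq_along(vars)) assign(vars[j], y[j], envir = env)
    assign("t", t, envir = env)
    list(vapply(sums, eval, numeric(1), envir = env))
  }
}

#' Entrain a forced model to its limit cycle
#'
#' Integrates the model for a number of forcing periods and returns the state
#' at the end of the burn-in, i.e. at a phase equal to the start of the
#' forcing cycle (lights-on for the clock model).  For autonomous models the
#' model's own initial state is returned unchanged when `periods = 0`.
#'
#' @param model a [process_model()].
#' @param periods number of burn-in periods (default 2).
#' @param params,x0 as in [simulate_model()].
#' @param grid_step burn-in output step in hours (coarse; only the final
#'   state is used).
#' @return Named numeric state vector.
#' @export
entrained_state <- function(model, periods = 2, params = model$parameters,
                            x0 = model$initial_state, grid_step = 0.05) {
  if (periods <= 0) return(x0[model$variables])
  period <- if (!is.null(model$forcing)) model$forcing$period
            else diff(model$horizon)
  tt <- seq(0, periods * period, by = grid_step)
  traj <- simulate_model(model, tt, params = params, x0 = x0)
  stats::setNames(traj$state[nrow(traj$state), ], model$variables)
}
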