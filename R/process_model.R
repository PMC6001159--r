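#' Process-decomposed ODE models
#'
#' A process model is an ODE system in which the right-hand side of every
#' equation is written as an explicit sum of signed biological processes,
#' \deqn{\dot x_i = \sum_j f_{ij}(x, p),}
#' each term corresponding to a mechanism such as transcription, complex
#' formation or degradation.  Keeping the decomposition explicit is what makes
#' the rest of the analysis possible: the relative weight of each process can
#' be followed along a trajectory, and terms can be switched off individually
#' to build reduced models.
#'
#' @param variables character vector of state-variable names, in equation
#'   order.
#' @param terms list with one element per variable; each element is itself a
#'   list of process terms created by [process_term()].
#' @param parameters named numeric vector of kinetic parameters.
#' @param initial_state named numeric vector of initial concentrations (nM),
#'   names matching `variables`.
#' @param horizon numeric length-2, analysis time span in hours.
#' @param forcing optional periodic forcing of one parameter: a list with
#'   entries `param` (parameter name), `multiplier` (factor applied during the
#'   on-phase), `period` and `on` (hours).  `NULL` for autonomous models.
#' @param links list of character vectors; each vector collects the labels
#'   (`"f_i,j"`) of terms that represent one and the same biochemical process
#'   appearing in several equations.
#' @param outputs named list of named numeric vectors; each vector gives the
#'   coefficients of a linear combination of state variables.
#' @param descriptions optional character vector of human-readable variable
#'   descriptions.
#' @param meta optional named list of auxiliary quantities (aggregate
#'   parameters, cooperativity coefficients held fixed, ...) kept for
#'   documentation but never varied.
#' @param name model name used in printing and to select compiled fast paths.
#'
#' @return An object of class `ppa_model`.
#' @seealso [clock_model()], [toy_linear_model()], [simulate_model()]
#' @export
process_model <- function(variables, terms, parameters, initial_state,
                          horizon = c(0, 24), forcing = NULL,
                          links = list(), outputs = list(),
                          descriptions = NULL, meta = list(),
                          name = "model") {
  stopifnot(is.character(variables), length(variables) >= 1,
            is.list(terms), length(terms) == length(variables),
            is.numeric(parameters), !is.null(names(parameters)),
            is.numeric(initial_state), length(horizon) == 2)
  if (any(lengths(terms) < 1))
    stop("every equation must contain at least one process term")
  initial_state <- initial_state[variables]
  if (anyNA(initial_state))
    stop("initial_state must contain every variable")

  labels <- unlist(lapply(seq_along(terms), function(i)
    sprintf("f_%d,%d", i, seq_along(terms[[i]]))))
  m <- structure(
    list(variables = variables, terms = terms, parameters = parameters,
         initial_state = initial_state, horizon = as.numeric(horizon),
         forcing = forcing, links = links, outputs = outputs,
         descriptions = descriptions, meta = meta, name = name,
         labels = labels),
    class = "ppa_model")
  validate_model(m)
  m
}

#' Create a single process term
#'
#' @param expr an R expression (typically from `quote()`) for the signed term;
#'   it may reference state variables, parameters and `t`.
#' @param sign +1 or -1, the direction in which the process changes the
#'   variable; the expression itself already carries the sign.
#' @param label biological name of the process (e.g. `"nuclear import"`).
#' @return A list of class `ppa_term`.
#' @export
process_term <- function(expr, sign, label = "") {
  stopifnot(sign %in% c(-1, 1))
  structure(list(expr = expr, sign = as.integer(sign), label = label),
            class = "ppa_term")
}

validate_model <- function(m) {
  known <- c(m$variables, names(m$parameters), "t")
  for (i in seq_along(m$terms)) for (trm in m$terms[[i]]) {
    bad <- setdiff(all.vars(trm$expr), known)
    if (length(bad))
      stop(sprintf("equation %d references undeclared symbol(s): %s",
                   i, paste(bad, collapse = ", ")))
  }
  all_members <- unlist(m$links)
  if (anyDuplicated(all_members))
    stop("process links must be disjoint")
  if (length(all_members) && !all(all_members %in% m$labels))
    stop("process link refers to unknown term label")
  for (o in m$outputs)
    if (!all(names(o) %in% m$variables))
      stop("output refers to unknown variable")
  invisible(m)
}

#' @export
print.ppa_model <- function(x, ...) {
  cat(sprintf("<ppa_model> %s: %d variables, %d processes\n",
              x$name, length(x$variables), length(x$labels)))
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  cat(sprintf("  horizon: [%g, %g] h;  %d parameters; %d outputs; %d links\n",
              x$horizon[1], x$horizon[2], length(x$parameters),
              length(x$outputs), length(x$links)))
  if (!is.null(x$forcing))
    cat(sprintf("  forcing: %s x%g for first %g h of each %g h period\n",
                x$forcing$param, x$forcing$multiplier, x$forcing$on,
                x$forcing$period))
  invisible(x)
}

#' Number of process terms per equation
#' @param model a `ppa_model`.
#' @return Integer vector, one entry per state variable.
#' @export
n_processes <- function(model) lengths(model$terms)

#' Process labels of a model
#' @param model a `ppa_model`.
#' @return Character vector `"f_i,j"` in equation order.
#' @export
process_labels <- function(model) model$labels

#' Render every process term as text
#'
#' Used by the structural tests: a reduced model must keep its terms
#' *verbatim*, so term identity is checked on the deparsed expressions.
#'
#' @param model a `ppa_model`.
#' @return Named character vector (names are the `"f_i,j"` labels).
#' @export
render_terms <- function(model) {
  out <- unlist(lapply(model$terms, function(tl)
    vapply(tl, function(trm) paste(deparse(trm$expr), collapse = " "), "")))
  names(out) <- model$labels
  out
}

## effective parameter values at (possibly vector) time t, applying forcing
effective_parameters <- function(model, t, params = model$parameters) {
  if (is.null(model$forcing)) return(lapply(as.list(params), rep, length(t)))
  f <- model$forcing
  pl <- lapply(as.list(params), rep, length(t))
  tau <- t %% f$period
  tau[tau == 0 & t > 0] <- f$period   # left-continuous at period multiples
  pl[[f$param]] <- params[[f$param]] * ifelse(tau < f$on, f$multiplier, 1)
  pl
}

## evaluate all process terms on a grid of states; returns T x n_proc matrix
eval_terms_grid <- function(model, times, states, params = model$parameters) {
  states <- rbind(states)
  env <- list2env(effective_parameters(model, times, params))
  for (j in seq_len(ncol(states)))
    assign(model$variables[j], states[, j], envir = env)
  assign("t", times, envir = env)
  nt <- length(times)
  vals <- matrix(NA_real_, nt, length(model$labels),
                 dimnames = list(NULL, model$labels))
  k <- 0
  for (tl in model$terms) for (trm in tl) {
    k <- k + 1
    vals[, k] <- rep_len(eval(trm$expr, env), nt)
  }
  vals
}

#' Evaluate every process term at one state
#'
#' Returns the signed value \eqn{f_{ij}(x, p)} of each declared process; the
#' row sums over each equation's terms equal the time derivative of the state.
#'
#' @param model a `ppa_model`.
#' @param state named numeric state vector (non-negative concentrations).
#' @param t time in hours (relevant for forced models).
#' @param params parameter vector; defaults to the model's.
#' @return Named numeric vector of process values, with attributes
#'   `variable` (equation index) and `position` (term index within the
#'   equation).
#' @export
evaluate_processes <- function(model, state, t = model$horizon[1],
                               params = model$parameters) {
  state <- state[model$variables]
  if (anyNA(state)) stop("state must contain every model variable")
  vals <- drop(eval_terms_grid(model, t, matrix(state, 1), params))
  idx <- rep(seq_along(model$terms), lengths(model$terms))
  structure(vals, variable = idx,
            position = unlist(lapply(lengths(model$terms), seq_len)))
}

#' Evaluate model outputs along a trajectory
#'
#' @param traj a `ppa_trajectory` from [simulate_model()].
#' @param outputs named list of coefficient vectors; defaults to the model
#'   outputs stored in the trajectory.
#' @return Numeric matrix, one column per output, rows on the trajectory grid.
#' @export
evaluate_outputs <- function(traj, outputs = traj$outputs) {
  if (!length(outputs)) stop("no outputs defined")
  st <- traj$state
  out <- sapply(outputs, function(co) {
    miss <- setdiff(names(co), colnames(st))
    if (length(miss))
      stop("output refers to missing variable(s): ", paste(miss, collapse = ", "))
    as.vector(st[, names(co), drop = FALSE] %*% co)
  })
  out <- rbind(out)  # keep matrix for single-row trajectories
  rownames(out) <- NULL
  out
}

#' Write a trajectory to CSV
#'
#' Plain `time,<var1>,...` layout, hours and nM.
#'
#' @param traj a `ppa_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$state, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
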