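#' Relative process weights along a trajectory
#'
#' For every equation and every grid time, the weight of a process is its
#' absolute value normalised by the sum of absolute values of all processes
#' in the same equation,
#' \deqn{W_{ij}(t) = \frac{|f_{ij}(x(t),p)|}{\sum_j |f_{ij}(x(t),p)|},}
#' so that \eqn{0 \le W_{ij} \le 1} and the weights of one equation sum to 1
#' wherever the denominator is positive.  If every process of an equation
#' vanishes at some time, all weights of that equation are set to 0 there
#' (no process contributes and the ratio is undefined).
#'
#' @param model a [process_model()].
#' @param traj a `ppa_trajectory` covering the analysis horizon.
#' @param params parameter vector used for the evaluation; defaults to the
#'   trajectory's.
#' @return A `ppa_weights` object: `times`, `W` (matrix grid x process,
#'   columns named `"f_i,j"`), `denominators` (grid x variable), and the
#'   process-to-variable index.
#' @export
compute_weights <- function(model, traj, params = traj$params) {
  vals <- eval_terms_grid(model, traj$times, traj$state, params)
  var_of <- rep(seq_along(model$terms), lengths(model$terms))
  av <- abs(vals)
  den <- t(rowsum(t(av), var_of))            # grid x variable sums
  colnames(den) <- model$variables
  W <- av / den[, var_of, drop = FALSE]
  W[den[, var_of, drop = FALSE] == 0] <- 0
  structure(list(times = traj$times, W = W, denominators = den,
                 var_of = var_of, labels = model$labels,
                 variables = model$variables, model = model$name),
            class = "ppa_weights")
}

#' @export
print.ppa_weights <- function(x, ...) {
  cat(sprintf("<ppa_weights> %s: %d processes on %d grid points\n",
              x$model, ncol(x$W), nrow(x$W)))
  invisible(x)
}

#' Classify process activity and locate switching times
#'
#' A process is *active* at time t when its weight is at or above the
#' threshold `delta`, *inactive* otherwise, and *always inactive* when its
#' weight stays below `delta` on the whole grid.  Switching times are the
#' interior times at which a weight crosses the threshold; they are located
#' by linear interpolation of \eqn{W - \delta} between adjacent grid points.
#' Crossings at the exact grid boundaries are not counted (the horizon ends
#' are window bounds, not switches).
#'
#' @param weights a `ppa_weights` object.
#' @param delta activity threshold in `[0, 1]` (default 0.1).
#' @return A list with components
#' \describe{
#'   \item{activity}{`ppa_activity`: logical matrix `active`, the
#'     `always_inactive` label set, and the per-time count `n_act`.}
#'   \item{switching}{`ppa_switching`: data frame `variable`, `process`,
#'     `time`, `direction` (`"up"`/`"down"`), sorted by time.}
#' }
#' @export
classify_activity <- function(weights, delta = 0.1) {
  stopifnot(delta >= 0, delta <= 1)
  W <- weights$W
  tt <- weights$times
  active <- W >= delta
  always_inactive <- colnames(W)[colSums(active) == 0]

  rows <- vector("list", ncol(W))
  for (j in seq_len(ncol(W))) {
    w <- W[, j] - delta
    s <- sign(w)
    # treat exact zeros as belonging to the active side (W >= delta)
    s[s == 0] <- 1
    idx <- which(s[-1] * s[-length(s)] < 0)
    if (!length(idx)) next
    tc <- tt[idx] + (tt[idx + 1] - tt[idx]) * (-w[idx]) / (w[idx + 1] - w[idx])
    interior <- tc > tt[1] & tc < tt[length(tt)]
    if (!any(interior)) next
    rows[[j]] <- data.frame(
      variable = weights$variables[weights$var_of[j]],
      process = colnames(W)[j],
      time = tc[interior],
      direction = ifelse(w[idx + 1][interior] > 0, "up", "down"),
      stringsAsFactors = FALSE)
  }
  switching <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(switching))
    switching <- data.frame(variable = character(), process = character(),
                            time = numeric(), direction = character())
  switching <- switching[order(switching$time), , drop = FALSE]
  rownames(switching) <- NULL

  list(
    activity = structure(
      list(times = tt, active = active, always_inactive = always_inactive,
           n_act = rowSums(active), delta = delta,
           var_of = weights$var_of, variables = weights$variables,
           model = weights$model),
      class = "ppa_activity"),
    switching = structure(switching, class = c("ppa_switching", "data.frame")))
}

#' @export
print.ppa_activity <- function(x, ...) {
  cat(sprintf(paste0("<ppa_activity> %s: delta = %g, %d/%d always inactive, ",
                     "%d-%d simultaneously active\n"),
              x$model, x$delta, length(x$always_inactive), ncol(x$active),
              min(x$n_act), max(x$n_act)))
  invisible(x)
}

#' Switching-time set of one variable
#'
#' @param switching the switching data frame from [classify_activity()].
#' @param variable variable name.
#' @return Numeric vector of crossing times, sorted.
#' @export
switching_set <- function(switching, variable) {
  sort(switching$time[switching$variable == variable])
}

#' Extremes of the number of simultaneously active processes
#'
#' @param activity a `ppa_activity` object.
#' @return Numeric length-2: `c(min, max)` of `n_act` over the grid.
#' @export
activity_extrema <- function(activity) {
  if (!length(activity$n_act)) stop("empty activity profile")
  c(min(activity$n_act), max(activity$n_act))
}

#' Export weights and activity as long-format CSV
#'
#' Columns `time,variable,process,weight,active`.
#'
#' @param weights a `ppa_weights`.
#' @param activity the matching `ppa_activity`.
#' @param path output file.
#' @param thin write every `thin`-th grid point (the full 0.01 h grid is
#'   usually more than a spreadsheet wants).
#' @return `path`, invisibly.
#' @export
write_weights_csv <- function(weights, activity, path, thin = 10L) {
  sel <- seq(1, nrow(weights$W), by = thin)
  df <- data.frame(
    time = rep(weights$times[sel], times = ncol(weights$W)),
    variable = rep(weights$variables[weights$var_of], each = length(sel)),
    process = rep(colnames(weights$W), each = length(sel)),
    weight = as.vector(weights$W[sel, ]),
    active = as.vector(activity$active[sel, ]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export switching times as CSV
#' @param switching switching data frame from [classify_activity()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_switching_csv <- function(switching, path) {
  utils::write.csv(switching, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
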