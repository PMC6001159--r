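#' Toy one-variable decay model
#'
#' \eqn{dx/dt = -k x + c}: a first-order decay opposed by a small constant
#' production.  Its two processes have closed-form weights along the explicit
#' solution \eqn{x(t) = (x_0 - c/k) e^{-kt} + c/k}, which makes the model the
#' package's analytic test bed: the production term's weight
#' \eqn{W_2 = c / (c + k x)} crosses a threshold \eqn{\delta} exactly when
#' \eqn{x = c (1 - \delta) / (k \delta)}.
#'
#' @param k decay rate constant (1/h).
#' @param c production rate (nM/h).
#' @param x0 initial concentration (nM).
#' @param horizon analysis span in hours.
#' @return A [process_model()] named `"toy-linear"`.
#' @export
toy_linear_model <- function(k = 1, c = 0.05, x0 = 1, horizon = c(0, 10)) {
  process_model(
    variables = "x",
    terms = list(list(
      process_term(quote(-k * x), -1, "first-order decay"),
      process_term(quote(c + 0 * x), +1, "constant production"))),
    parameters = c(k = k, c = c),
    initial_state = c(x = x0),
    horizon = horizon,
    outputs = list(x = c(x = 1)),
    name = "toy-linear")
}

#' Toy two-variable negative-feedback loop
#'
#' A repressor--target pair: `x1` is produced under repression by `x2` and
#' degraded linearly; `x2` is produced from `x1` and degraded linearly.  With
#' the default parameters the loop relaxes through damped oscillations, so
#' process weights cross an activity threshold at non-trivial times.
#'
#' @param a maximal production rate of `x1` (nM/h).
#' @param b production rate constant of `x2` (1/h).
#' @param d1,d2 degradation rate constants (1/h).
#' @param h Hill coefficient of the repression.
#' @param x0 named initial state.
#' @param horizon analysis span in hours.
#' @return A [process_model()] named `"toy-feedback"`.
#' @export
toy_feedback_model <- function(a = 4, b = 1.5, d1 = 0.6, d2 = 0.4, h = 4,
                               x0 = c(x1 = 0.2, x2 = 3),
                               horizon = c(0, 24)) {
  process_model(
    variables = c("x1", "x2"),
    terms = list(
      list(process_term(quote(a / (1 + x2^h)), +1, "repressed production"),
           process_term(quote(-d1 * x1), -1, "degradation")),
      list(process_term(quote(b * x1), +1, "activation by x1"),
           process_term(quote(-d2 * x2), -1, "degradation"))),
    parameters = c(a = a, b = b, d1 = d1, d2 = d2, h = h),
    initial_state = x0,
    horizon = horizon,
    outputs = list(x1 = c(x1 = 1), x2 = c(x2 = 1)),
    name = "toy-feedback")
}

#' Fetch a packaged model by name
#'
#' @param name one of `"clock"`, `"toy-linear"`, `"toy-feedback"`.
#' @return The corresponding [process_model()].
#' @export
builtin_model <- function(name = c("clock", "toy-linear", "toy-feedback")) {
  switch(match.arg(name),
         "clock" = clock_model(),
         "toy-linear" = toy_linear_model(),
         "toy-feedback" = toy_feedback_model())
}
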