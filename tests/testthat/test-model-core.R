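test_that("clock model has the documented process structure", {
  m <- clock_model()
  expect_length(m$variables, 16)
  expect_equal(n_processes(m),
               c(3, 3, 3, 6, 6, 4, 4, 7, 7, 4, 4, 6, 4, 7, 4, 4))
  expect_length(process_labels(m), 76)
  expect_equal(unname(m$initial_state["M_P"]), 2.188)
  expect_equal(unname(m$initial_state["I_N"]), 0.051)
  expect_equal(unname(m$parameters["k7"]), 0.5)
  expect_equal(unname(m$parameters["v_sP"]), 1.5)
  # BMAL1 nuclear export is the 4th process of equation 14
  rt <- render_terms(m)
  expect_equal(rt[["f_14,4"]], "-k6 * B_N")
  expect_equal(rt[["f_14,1"]], "-V_3B * B_N/(K_p + B_N)")
  # links are disjoint and refer to existing terms (validated on build)
  expect_true(all(unlist(m$links) %in% m$labels))
})

test_that("process evaluation matches independent scalar arithmetic", {
  m <- clock_model()
  v <- evaluate_processes(m, m$initial_state, t = 0)
  # equation 14 recomputed by hand from the printed kinetics
  p <- as.list(m$parameters); s <- as.list(m$initial_state)
  expected <- c(
    -p$V_3B * s$B_N / (p$K_p + s$B_N),
    p$V_4B * s$B_NP / (p$K_dp + s$B_NP),
    p$k5 * s$B_C,
    -p$k6 * s$B_N,
    -p$k7 * s$B_N * s$PC_N,
    p$k8 * s$I_N,
    -p$k_dn * s$B_N)
  i14 <- which(attr(v, "variable") == 14)
  expect_equal(unname(v[i14]), expected, tolerance = 1e-12)

  # an all-zero state annihilates every mass-action and saturable term
  z <- evaluate_processes(m, setNames(rep(0, 16), m$variables), t = 0)
  expect_true(all(abs(z[-c(1, 4, 7)]) == 0))  # transcription terms excepted
  # Bmal1 transcription at zero B_N equals its unrepressed maximum
  expect_equal(unname(z["f_3,1"]), unname(m$parameters["v_sB"]))

  # doubling a mass-action rate constant doubles that term only
  p2 <- m$parameters; p2["k5"] <- 2 * p2["k5"]
  v2 <- evaluate_processes(m, m$initial_state, t = 0, params = p2)
  expect_equal(unname(v2["f_14,3"]), 2 * unname(v["f_14,3"]))
  expect_equal(unname(v2["f_14,1"]), unname(v["f_14,1"]))
})

test_that("undeclared symbols in terms are rejected", {
  expect_error(
    process_model(
      variables = "x",
      terms = list(list(process_term(quote(-k_missing * x), -1))),
      parameters = c(k = 1), initial_state = c(x = 1)),
    "undeclared")
})

test_that("simulation solves trivial systems exactly", {
  # all-zero vector field: constant trajectory
  null_model <- process_model(
    variables = "x",
    terms = list(list(process_term(quote(0 * x), -1, "null"))),
    parameters = c(dummy = 1), initial_state = c(x = 2.5))
  tr <- simulate_model(null_model, seq(0, 5, by = 0.5))
  expect_true(all(tr$state[, "x"] == 2.5))

  # pure exponential decay against the closed form
  dec <- process_model(
    variables = "x",
    terms = list(list(process_term(quote(-k * x), -1, "decay"))),
    parameters = c(k = 1), initial_state = c(x = 1))
  tr <- simulate_model(dec, seq(0, 1, by = 0.01))
  expect_equal(unname(tr$state[nrow(tr$state), "x"]), exp(-1),
               tolerance = 1e-8)
})

test_that("compiled and symbolic clock paths agree", {
  m <- clock_model()
  tt <- seq(0, 6, by = 0.05)
  a <- simulate_model(m, tt)
  b <- simulate_model(m, tt, use_compiled = FALSE)
  expect_equal(a$state, b$state, tolerance = 1e-9)
  # masks flow through both paths identically
  mask <- rep(TRUE, 76); mask[c(3, 40, 76)] <- FALSE
  am <- simulate_model(m, tt, mask = mask)
  bm <- simulate_model(m, tt, mask = mask, use_compiled = FALSE)
  expect_equal(am$state, bm$state, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(a$state, am$state)))
})

test_that("simulation is reproducible and consistent with the vector field", {
  m <- clock_model()
  tt <- seq(0, 24, by = 0.01)
  a <- simulate_model(m, tt)
  b <- simulate_model(m, tt)
  expect_identical(a$state, b$state)

  # sum of process terms equals the numerically differentiated state
  vals <- ppa:::eval_terms_grid(m, a$times, a$state)
  var_of <- rep(seq_along(m$terms), lengths(m$terms))
  rhs <- t(rowsum(t(vals), var_of))
  mid_rhs <- (rhs[-1, ] + rhs[-nrow(rhs), ]) / 2
  num_deriv <- diff(a$state) / diff(tt)
  # the vector field jumps at the light transition; skip that interval
  smooth <- abs(tt[-length(tt)] - 12) > 0.02
  expect_lt(max(abs(mid_rhs[smooth, ] - num_deriv[smooth, ])), 5e-3)
})

test_that("clock outputs oscillate within one light-dark cycle", {
  res <- clock_fixture()
  Y <- evaluate_outputs(res$trajectory)
  for (h in colnames(Y)) {
    i_max <- which.max(Y[, h]); i_min <- which.min(Y[, h])
    # neither extreme sits at the window edges: the series rises and falls
    expect_gt(min(i_max, i_min), 1)
    expect_lt(max(i_max, i_min), nrow(Y))
  }
})

test_that("output evaluation is a plain linear combination", {
  res <- clock_fixture()
  tr <- res$trajectory
  Y <- evaluate_outputs(tr)
  expect_equal(unname(Y[1, "B_Tot"]),
               sum(tr$state[1, c("B_C", "B_CP", "B_N", "B_NP", "I_N")]))
  expect_equal(Y[, "M_P"], tr$state[, "M_P"])
  zero <- evaluate_outputs(tr, outputs = list(z = c(M_P = 0)))
  expect_true(all(zero == 0))
  expect_error(evaluate_outputs(tr, outputs = list(bad = c(nope = 1))),
               "missing variable")
})

test_that("entrained clock state settles on the 24 h cycle", {
  m <- clock_model()
  s2 <- entrained_state(m, periods = 2)
  s3 <- entrained_state(m, periods = 3)
  # one extra period moves the lights-on state only slightly
  expect_lt(max(abs(s3 - s2) / pmax(abs(s2), 0.1)), 0.05)
})
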