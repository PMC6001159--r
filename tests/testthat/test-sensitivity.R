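test_that("small factorial designs reduce to the classical constructions", {
  d2 <- build_two_level_design(2)
  expect_equal(nrow(d2$matrix), 4)            # full 2^2
  expect_equal(sort(unique(as.vector(d2$matrix))), c(-1, 1))
  d5 <- build_two_level_design(5, max_runs = 16)
  expect_equal(nrow(d5$matrix), 16)           # 2^(5-1), E = ABCD
  expect_equal(d5$words[1:4], c(1L, 2L, 4L, 8L))
  expect_equal(d5$words[5], 15L)              # the ABCD word
  expect_true(verify_resolution_v(d5))
})

test_that("generated designs are balanced, orthogonal and resolution V", {
  for (nf in c(3, 7, 12, 20)) {
    d <- build_two_level_design(nf)
    X <- d$matrix
    expect_true(all(colSums(X) == 0))                       # balance
    G <- crossprod(X)
    expect_true(all(G[upper.tri(G)] == 0))                  # orthogonality
    expect_true(verify_resolution_v(d))
    # interaction columns clear of mains and of each other
    pr <- combn(nf, 2)
    XI <- X[, pr[1, ]] * X[, pr[2, ]]
    expect_true(all(abs(crossprod(XI, X)) == 0))
    GI <- crossprod(XI)
    expect_true(all(GI[upper.tri(GI)] == 0))
  }
  # the clock's 50-factor design fits in 4096 runs
  d50 <- build_two_level_design(50, max_runs = 4096)
  expect_equal(nrow(d50$matrix), 4096)
  expect_true(verify_resolution_v(d50))
  # infeasible request names the minimal run count
  expect_error(build_two_level_design(50, max_runs = 64), "4096")
})

test_that("ANOVA decomposition matches a direct least-squares fit", {
  d <- build_two_level_design(3)
  X <- d$matrix
  set.seed(7)
  y <- 1 + 2 * X[, 1] + 0.5 * X[, 2] * X[, 3] + rnorm(nrow(X), sd = 0.1)
  dec <- anova_decompose(y, X)
  # oracle: lm() on the full second-order model matrix
  df <- data.frame(y = y, A = X[, 1], B = X[, 2], C = X[, 3])
  fit <- lm(y ~ (A + B + C)^2, data = df)
  co <- coef(fit)
  expect_equal(unname(dec$mu), unname(co["(Intercept)"]), tolerance = 1e-10)
  expect_equal(unname(dec$main), unname(co[c("A", "B", "C")]),
               tolerance = 1e-10)
  expect_equal(unname(dec$inter),
               unname(co[c("A:B", "A:C", "B:C")]), tolerance = 1e-10)
  expect_equal(dec$SS_r, sum(residuals(fit)^2), tolerance = 1e-10)
  expect_equal(dec$SS_T, dec$SS_M + dec$SS_r, tolerance = 1e-8)

  # degenerate cases
  cst <- anova_decompose(rep(3, 8), X)
  expect_equal(cst$SS_T, 0)
  expect_true(all(cst$main == 0))
  pure <- anova_decompose(X[, 1], X)
  expect_equal(unname(pure$SS_f["F1"]), pure$SS_T)
  expect_error(anova_decompose(c(1, NA, rep(1, 6)), X), "non-finite")
})

test_that("total sensitivity indices attribute variance correctly", {
  d <- build_two_level_design(3)
  X <- d$matrix
  # single-factor response: full attribution
  t1 <- total_sensitivity_indices(anova_decompose(X[, 1], X))
  expect_equal(unname(t1$tSI["F1"]), 1)
  expect_equal(unname(t1$tSI["F2"]), 0)
  # A + 2 A:B, checked against brute-force sums of squares
  y <- X[, 1] + 2 * X[, 1] * X[, 2]
  dec <- anova_decompose(y, X)
  tt <- total_sensitivity_indices(dec)
  SS_A <- dec$SS_f["F1"]; SS_AB <- dec$SS_fk["F1:F2"]
  expect_equal(unname(tt$tSI["F1"]), unname((SS_A + SS_AB) / dec$SS_T))
  expect_equal(unname(tt$tSI["F2"]), unname(SS_AB / dec$SS_T))
  expect_equal(tt$tSI_prime, tt$sigma2 * tt$tSI)
  # all-zero response: indices defined zero
  t0 <- total_sensitivity_indices(anova_decompose(rep(0, 8), X))
  expect_true(all(t0$tSI == 0))
})

test_that("PCA-generalised indices aggregate per-component analyses", {
  d <- build_two_level_design(4)
  X <- d$matrix
  # a single error column: tGSI equals that column's tSI
  y <- 2 * X[, 1] + X[, 2]
  g1 <- pca_generalised_indices(cbind(y), X)
  t1 <- total_sensitivity_indices(anova_decompose(y, X))
  expect_equal(g1$n_components, 1)
  expect_equal(g1$tGSI, t1$tSI, tolerance = 1e-10)
  # two identical columns: one component carries all inertia
  g2 <- pca_generalised_indices(cbind(y, y), X)
  expect_equal(unname(g2$omega[1]), 1, tolerance = 1e-12)
  expect_equal(g2$tGSI, t1$tSI, tolerance = 1e-10)
  # disjoint factors driving independent responses: tGSI splits by variance
  y1 <- 4 * X[, 1]          # variance 16
  y2 <- 2 * X[, 3]          # variance 4
  g3 <- pca_generalised_indices(cbind(y1, y2), X)
  expect_equal(unname(g3$tGSI["F1"] / g3$tGSI["F3"]), 4, tolerance = 1e-6)
  expect_equal(unname(g3$tGSI["F2"]), 0, tolerance = 1e-10)
  # rank-0 matrix: all indices zero
  g0 <- pca_generalised_indices(matrix(1, 16, 2), X)
  expect_true(all(g0$tGSI == 0))
})

test_that("inactive-parameter ratio is a share of the top-k indices", {
  gsi <- structure(list(tGSI = c(a = 5, b = 3, c = 1, d = 1)),
                   class = "ppa_gsi")
  expect_equal(inactive_parameter_ratio(gsi, character(0), k = 3), 0)
  expect_equal(inactive_parameter_ratio(gsi, c("a", "b", "c"), k = 3), 100)
  expect_equal(inactive_parameter_ratio(gsi, "a", k = 3), 100 * 5 / 9)
  expect_error(inactive_parameter_ratio(gsi, "a", k = 9))
})

test_that("the error experiment is consistent and label-invariant", {
  res <- toy_linear_fixture()
  model <- res$model
  # two-window schedule from the toy's single switching time
  cl <- cluster_switching_times(res$switching$time, 1)
  sch <- build_schedule(model, res$activity, res$switching, cl)
  d <- build_two_level_design(2, factor_names = c("k", "c"))
  ex <- run_error_experiment(model, sch, d, window = 2,
                             targets = "variables", grid_step = 0.02)
  expect_equal(nrow(ex$errors), 4)
  expect_equal(ex$n_failed, 0)
  # a degenerate design with both levels nominal gives identical errors
  ex0 <- run_error_experiment(model, sch, d, window = 2,
                              rel_levels = c(1, 1), grid_step = 0.02)
  expect_equal(max(apply(ex0$errors, 2, stats::sd)), 0, tolerance = 1e-12)
  # permuting design columns permutes nothing but labels
  d2 <- d; d2$matrix <- d$matrix[, c(2, 1)]
  colnames(d2$matrix) <- c("c", "k")
  ex2 <- run_error_experiment(model, sch, d2, window = 2, grid_step = 0.02)
  expect_equal(sort(ex$errors[, 1]), sort(ex2$errors[, 1]), tolerance = 1e-12)
  # the all-nominal row reproduces the windowed-error computation
  e_win <- windowed_errors(model, sch, grid_step = 0.02)
  expect_equal(unname(ex0$errors[1, ]), unname(e_win$variables[2, ]),
               tolerance = 1e-6)
})

test_that("parameter classification finds symbols in dropped terms", {
  m <- clock_model()
  got <- parameters_in_processes(m, c("f_1,1", "f_14,4"))
  expect_setequal(got, c("v_sP", "n", "K_AP", "k6"))
  expect_error(parameters_in_processes(m, "f_99,1"), "unknown")
})
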