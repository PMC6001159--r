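test_that("always-inactive elimination keeps kept terms verbatim", {
  res <- clock_fixture()
  red <- res$reduced
  expect_setequal(names(red$mask)[!red$mask],
                  res$activity$always_inactive)
  # kept terms render identically to the base model's
  expect_identical(render_terms(red$base)[red$mask],
                   render_terms(clock_model())[red$mask])
  # delta = 0 drops nothing
  cls0 <- classify_activity(res$weights, delta = 0)
  red0 <- eliminate_always_inactive(res$model, cls0$activity)
  expect_true(all(red0$mask))
})

test_that("the reduced nuclear-BMAL1 equation keeps exactly four terms", {
  res <- clock_fixture()
  kept14 <- names(res$reduced$mask)[res$reduced$mask &
                                    grepl("^f_14,", names(res$reduced$mask))]
  expect_setequal(kept14, c("f_14,1", "f_14,3", "f_14,4", "f_14,5"))
})

test_that("cluster-count rule rounds half away from zero", {
  mk <- function(nact) structure(list(n_act = nact, times = seq_along(nact)),
                                 class = "ppa_activity")
  expect_equal(choose_cluster_count(mk(c(38, 45))), 4)   # 3.5 -> 4
  expect_equal(choose_cluster_count(mk(c(7, 7, 7))), 0)  # constant
  expect_equal(choose_cluster_count(mk(c(4, 9))), 3)     # 2.5 -> 3
  expect_equal(choose_cluster_count(mk(c(4, 8))), 2)     # exact
})

test_that("1-D clustering is exact against the enumeration oracle", {
  # deterministic hand case
  cl <- cluster_switching_times(c(1, 2, 10, 11), 2)
  expect_equal(cl$means, c(1.5, 10.5))
  expect_equal(cl$sizes, c(2, 2))
  # singleton clusters reproduce the data
  xs <- c(3.2, 1.1, 7.7)
  cls <- cluster_switching_times(xs, 3)
  expect_equal(cls$means, sort(xs))
  # random cases vs exhaustive contiguous-partition enumeration
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    z <- sample(2:min(4, n - 1), 1)
    x <- round(sort(runif(n, 0, 24)), 2)
    got <- cluster_switching_times(x, z)
    oracle <- exhaustive_1d_kmeans(x, z)
    expect_equal(got$inertia, oracle$inertia, tolerance = 1e-9)
    expect_equal(got$means, oracle$means, tolerance = 1e-9)
  }
  expect_error(cluster_switching_times(c(1, 2), 3), "z must satisfy")
})

test_that("schedule snapping follows the cluster assignment", {
  res <- clock_fixture()
  sch <- res$schedule
  # five windows tiling the horizon
  expect_length(sch$masks, 5)
  expect_equal(sch$boundaries[c(1, 6)], c(0, 24))
  expect_equal(sch$boundaries[2:5], res$clusters$means)
  # window 1 is the always-inactive reduction only
  expect_setequal(sch$dropped[[1]], sch$always_inactive)
  # every window's dropped set contains the always-inactive set
  for (v in seq_along(sch$masks))
    expect_true(all(sch$always_inactive %in% sch$dropped[[v]]))
  # kept terms stay verbatim in every sub-model
  rt <- render_terms(res$model)
  for (v in seq_along(sch$masks))
    expect_identical(rt[sch$masks[[v]]],
                     render_terms(clock_model())[sch$masks[[v]]])
})

test_that("a model without switching times yields a single window", {
  bal <- toy_linear_model(k = 1, c = 1, x0 = 1)
  tr <- simulate_model(bal, seq(0, 5, by = 0.05))
  cls <- classify_activity(compute_weights(bal, tr))
  sch <- build_schedule(bal, cls$activity, cls$switching, NULL)
  expect_length(sch$masks, 1)
  expect_true(all(sch$masks[[1]]))
})

test_that("global relative error has the defining properties", {
  tt <- seq(0, 4, by = 0.1)
  a <- cbind(y = rep(2, length(tt)))
  b <- cbind(y = rep(1, length(tt)))
  expect_equal(unname(global_relative_error(a, b, tt)), 0.5)
  expect_equal(unname(global_relative_error(a, a, tt)), 0)
  # scale invariance
  expect_equal(global_relative_error(3 * a, 3 * b, tt),
               global_relative_error(a, b, tt))
  expect_error(global_relative_error(0 * a, b, tt), "identically zero")
})

test_that("windowed errors agree across propagation modes in window one", {
  res <- clock_fixture()
  e_no <- res$window_errors
  e_yes <- windowed_errors(res$model, res$schedule, propagate = TRUE,
                           grid_step = 0.05)
  e_no5 <- windowed_errors(res$model, res$schedule, propagate = FALSE,
                           grid_step = 0.05)
  expect_equal(e_yes$outputs[1, ], e_no5$outputs[1, ], tolerance = 1e-8)
  # propagation accumulates: by the last window it cannot be smaller on
  # average than the re-initialised run
  expect_gt(mean(e_yes$outputs[5, ]), mean(e_no5$outputs[5, ]) * 0.99)
  # average variable error behaves like a mean
  expect_equal(average_variable_error(e_no, 2),
               mean(e_no$variables[2, ]))
  # late windows (where transcription shuts down) err more than window 1
  expect_gt(average_variable_error(e_no, 3), average_variable_error(e_no, 1))
  expect_gt(average_variable_error(e_no, 4), average_variable_error(e_no, 1))
})

test_that("the a priori bound dominates the realised deviation", {
  # toy: drop the small production term, compare with the exact deviation
  model <- toy_linear_model(k = 1, c = 0.02, x0 = 1, horizon = c(0, 3))
  tt <- seq(0, 3, by = 0.01)
  full <- simulate_model(model, tt)
  red <- simulate_model(model, tt, mask = c(TRUE, FALSE))
  dev <- abs(full$state[, 1] - red$state[, 1])
  # delta chosen so the dropped process is genuinely sub-threshold on [0,3]
  w <- compute_weights(model, full)
  delta <- max(w$W[, "f_1,2"]) * 1.01
  bound <- theoretical_error_bound(
    model, domain = rbind(0, 1.2), delta = delta, window = c(0, 3),
    t_eval = tt)
  expect_true(all(bound$bound >= dev - 1e-12))
  expect_equal(bound$bound[1], 0)
  expect_true(all(diff(bound$bound) >= 0))
  # zero threshold: zero bound
  b0 <- theoretical_error_bound(model, domain = rbind(0, 1.2), delta = 0,
                                window = c(0, 3))
  expect_true(all(b0$bound == 0))
  expect_error(theoretical_error_bound(model, rbind(2, 1), 0.1), "empty")
})

test_that("schedule export round-trips through JSON", {
  res <- clock_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_schedule_json(res$schedule, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$boundaries, res$schedule$boundaries)
  expect_setequal(back$windows$dropped[[3]], res$schedule$dropped[[3]])
})
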