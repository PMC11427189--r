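test_that("parabolic correction solves the three-point vertex", {
  obs <- structure(list(M0 = 1, Mplus = 0.8, Mminus = 0.6, b = 0.2,
                        mode_order = 4L), class = "bias_observations")
  corr <- parabolic_correct(obs)
  expect_equal(as.numeric(corr), 0.04 / 1.2, tolerance = 1e-12)
  # the raw aberration estimate has the opposite sign
  expect_equal(as.numeric(attr(corr, "estimate")), -0.04 / 1.2,
               tolerance = 1e-12)

  # symmetric observations give no correction
  obs$Mplus <- obs$Mminus
  expect_equal(as.numeric(parabolic_correct(obs)), 0)
})

test_that("degenerate observation triples are flagged and clamped", {
  flat <- structure(list(M0 = 0.5, Mplus = 0.5, Mminus = 0.5, b = 0.2,
                         mode_order = 4L), class = "bias_observations")
  corr <- parabolic_correct(flat)
  expect_equal(as.numeric(corr), 0)
  expect_true(attr(corr, "flagged"))

  convex <- structure(list(M0 = 0.4, Mplus = 0.6, Mminus = 0.5, b = 0.2,
                           mode_order = 4L), class = "bias_observations")
  expect_true(attr(parabolic_correct(convex), "flagged"))

  # near-flat concave triple: enormous vertex is clamped to the limit
  steep <- structure(list(M0 = 0.75, Mplus = 0.99, Mminus = 0.5, b = 0.2,
                          mode_order = 4L), class = "bias_observations")
  expect_false(attr(parabolic_correct(steep, limit = 0.2), "flagged"))
  expect_equal(abs(as.numeric(parabolic_correct(steep, limit = 0.2))), 0.2)
})

test_that("parabolic maximization is exact on a quadratic metric", {
  for (b in c(0.1, 0.2)) {
    env <- quadratic_env(kappa = 0.4, bias = b)
    env_set_aberration(env, c(`4` = 0.05))
    corr <- parabolic_method(env, bias = b)
    expect_equal(as.numeric(corr["4"]), -0.05, tolerance = 1e-9)
    expect_equal(as.numeric(corr[-1]), numeric(11), tolerance = 1e-9)
  }
  # multi-mode, still exact because the metric is separable quadratic
  env <- quadratic_env(kappa = 0.4)
  set.seed(1)
  tgt <- stats::setNames(runif(12, -0.1, 0.1), 4:15)
  env_set_aberration(env, tgt)
  expect_equal(as.numeric(parabolic_method(env, bias = 0.2)),
               as.numeric(-tgt), tolerance = 1e-9)
  # 2N+1 images per correction
  env_image_count(env, reset = TRUE)
  parabolic_method(env, bias = 0.2)
  expect_equal(env_image_count(env), 25)
})

test_that("ZMHC spends exactly 132 images per round and 396 in total", {
  env <- quadratic_env(kappa = 0.4)
  env_set_aberration(env, stats::setNames(numeric(12), 4:15))
  env_image_count(env, reset = TRUE)
  one_round <- zmhc_correct(env, zmhc_plan(limits = 0.2))
  expect_equal(one_round$image_count, 132)

  res <- zmhc_correct(env, zmhc_plan())
  expect_equal(res$image_count, 396)
  # final-round scan step is the printed 0.01 um resolution
  offsets <- seq(-zmhc_plan()$limits[3], zmhc_plan()$limits[3],
                 length.out = zmhc_plan()$n_values)
  expect_equal(unique(round(diff(offsets), 12)), 0.01)
})

test_that("ZMHC recovers grid-aligned aberrations to its resolution", {
  env <- quadratic_env(kappa = 0.4)
  set.seed(2)
  for (rep in 1:3) {
    tgt <- stats::setNames(sample(seq(-0.15, 0.15, by = 0.01), 12), 4:15)
    env_set_aberration(env, tgt)
    res <- zmhc_correct(env)
    expect_true(all(abs(tgt + res$coeffs) <= 0.01 + 1e-9))
  }
})

test_that("ZMHC never ends below the unbiased starting metric", {
  env <- sao_env(tiny_system(64),
                 aberration_config("B", target_indices = 4:7,
                                   noise_indices = 16:18), bias = 0.5)
  set.seed(3)
  ab <- sample_aberration(env$config)
  env_set_aberration(env, ab$target, ab$noise)
  start <- mossddpg:::.env_acquire(env, stats::setNames(numeric(4), 4:7))
  res <- zmhc_correct(env, zmhc_plan(limits = c(0.1, 0.05), n_values = 5))
  expect_gte(res$best_metric, start)
  expect_equal(res$image_count, 2 * 4 * 5)
  expect_lt(rms_wfe(ab$target, res$coeffs), rms_wfe(ab$target, numeric(4)))
})

test_that("plans validate their structure", {
  expect_error(zmhc_plan(limits = c(0.1, 0.2)))
  expect_error(zmhc_plan(n_values = 10))
})
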