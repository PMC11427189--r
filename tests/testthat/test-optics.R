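sys64 <- tiny_system(64)
zb64 <- make_zernike_basis(4:15, 64, 31)

test_that("unaberrated PSF peaks at the grid centre and phase conserves energy", {
  flat <- compose_wavefront(c(`4` = 0), zb64)
  h0 <- compute_psf(flat, sys64)
  expect_true(all(h0$intensity >= 0))
  centre <- sys64$fft_size %/% 2 + 1
  expect_equal(as.vector(which(h0$intensity == max(h0$intensity),
                               arr.ind = TRUE)[1, ]), c(centre, centre))

  # Parseval: pupil phase cannot change total PSF energy
  set.seed(3)
  for (i in 1:5) {
    cf <- stats::setNames(rnorm(12, 0, 0.2), 4:15)
    h <- compute_psf(compose_wavefront(cf, zb64), sys64)
    expect_equal(sum(h$intensity), sum(h0$intensity), tolerance = 1e-9)
  }
})

test_that("a tip ramp translates the PSF without changing its energy", {
  # OPD linear in x with slope chosen to shift the PSF by exactly 2 px
  P <- sys64$fft_size
  shift_px <- 2
  centre <- 64 %/% 2 + 1
  xpix <- matrix(seq_len(64) - centre, 64, 64)
  opd <- xpix * shift_px * sys64$wavelength / (P * sys64$dm_gain)
  h0 <- compute_psf(matrix(0, 64, 64), sys64)$intensity
  h1 <- compute_psf(opd, sys64)$intensity
  expect_equal(sum(h1), sum(h0), tolerance = 1e-9)
  shifted_up <- rbind(h0[-seq_len(shift_px), ], h0[seq_len(shift_px), ])
  shifted_dn <- rbind(h0[P - shift_px + seq_len(shift_px), ],
                      h0[seq_len(P - shift_px), ])
  err <- min(max(abs(h1 - shifted_up)), max(abs(h1 - shifted_dn)))
  expect_lt(err / max(h0), 1e-8)
})

test_that("point-detector limit and delta-fiber limit reduce to the PSF product", {
  wf <- compose_wavefront(c(`4` = 0.05, `7` = -0.03), zb64)
  h <- compute_psf(wf, sys64)

  sys_pt <- tiny_system(64, fiber_diameter = 0)
  hs_pt <- effective_psf(h, h, sys_pt)
  expect_equal(hs_pt$intensity, h$intensity^2, tolerance = 1e-12)

  # fiber disk of a single pixel acts as a delta kernel
  sys_px <- tiny_system(64, fiber_diameter = 1.9 / sys64$airy_diameter_px)
  hs_px <- effective_psf(h, h, sys_px)
  expect_equal(hs_px$intensity, h$intensity^2, tolerance = 1e-9)

  expect_error(effective_psf(h$intensity, h$intensity[1:10, 1:10], sys64))
})

test_that("normalized metric curvature at focus flattens as the fiber grows", {
  curv <- sapply(c(0, 1, 2, 3), function(fd) {
    s <- tiny_system(64, fiber_diameter = fd)
    e <- sao_env(s, aberration_config("B"))
    env_set_aberration(e, c(`4` = 0))
    m <- sapply(c(-0.04, 0, 0.04), function(cc)
      mossddpg:::.env_acquire(e, c(`4` = cc)))
    (m[1] + m[3] - 2 * m[2]) / m[2]
  })
  expect_true(all(diff(curv) > 0))   # less negative = flatter response
  expect_true(all(curv < 0))
})

test_that("image formation obeys delta-kernel identities and conserves mass", {
  P <- sys64$fft_size
  centre <- P %/% 2 + 1
  delta <- matrix(0, P, P)
  delta[centre, centre] <- 1
  img <- render_image(delta, system = sys64)
  expect_equal(img, sys64$sample_image, tolerance = 1e-10)

  wf <- compose_wavefront(c(`4` = 0.08), zb64)
  hs <- effective_psf(compute_psf(wf, sys64), compute_psf(wf, sys64), sys64)
  img <- render_image(hs, system = sys64)
  expect_true(all(img >= 0))
  hw <- (sys64$kernel_size - 1) %/% 2
  wP <- mossddpg:::.wrap_window(P, hw)
  kern_mass <- sum(mossddpg:::ifftshift(hs$intensity)[wP, wP])
  expect_equal(sum(img), kern_mass * sum(sys64$sample_image),
               tolerance = 1e-9)

  # delta sample reproduces the (cropped, recentred) kernel values
  delta_s <- matrix(0, 64, 64); delta_s[1, 1] <- 1
  img_d <- render_image(hs, delta_s, sys64)
  mu <- mossddpg:::ifftshift(hs$intensity)
  wS <- mossddpg:::.wrap_window(64L, hw)
  expected <- matrix(0, 64, 64); expected[wS, wS] <- mu[wP, wP]
  expect_equal(img_d, expected, tolerance = 1e-10)
})

test_that("sharpness metric is the homogeneous sum of squared intensities", {
  expect_equal(sharpness_metric(matrix(0, 4, 4)), 0)
  img <- matrix(runif(16), 4, 4)
  expect_equal(sharpness_metric(3 * img), 9 * sharpness_metric(img))
  expect_equal(sharpness_metric(matrix(c(1, 2), 1, 2)), 5)
  expect_error(sharpness_metric(matrix(-1, 2, 2)))
})

test_that("fast metric path matches the full render pipeline bit-for-bit scale", {
  for (bg in c(0, 0.5)) {
    s <- tiny_system(64, background = bg)
    e <- sao_env(s, aberration_config("B"))
    set.seed(4)
    ab <- sample_aberration(aberration_config("B"))
    env_set_aberration(e, ab$target, ab$noise)
    m_fast <- mossddpg:::.env_acquire(e, stats::setNames(numeric(12), 4:15))
    basis <- e$basis
    wf <- compose_wavefront(c(ab$target, ab$noise), basis)
    h <- compute_psf(wf, s)
    hs <- effective_psf(h, h, s)
    img <- render_image(hs, system = s) + detector_background(s)
    expect_equal(m_fast, sharpness_metric(img), tolerance = 1e-9)
  }
})

test_that("metric at zero aberration beats any single-mode offset", {
  e <- sao_env(sys64, aberration_config("B"))
  env_set_aberration(e, c(`4` = 0))
  m0 <- mossddpg:::.env_acquire(e, c(`4` = 0))
  for (md in as.character(4:15)) {
    for (off in c(-0.05, 0.05)) {
      probe <- stats::setNames(off, md)
      expect_lt(mossddpg:::.env_acquire(e, probe), m0)
    }
  }
})

test_that("identical configuration gives bit-identical metrics", {
  e1 <- sao_env(tiny_system(64), aberration_config("B"))
  e2 <- sao_env(tiny_system(64), aberration_config("B"))
  ab <- list(target = c(`5` = 0.07, `11` = -0.04), noise = c(`16` = 0.01))
  env_set_aberration(e1, ab$target, ab$noise)
  env_set_aberration(e2, ab$target, ab$noise)
  expect_identical(mossddpg:::.env_acquire(e1, c(`4` = 0.02)),
                   mossddpg:::.env_acquire(e2, c(`4` = 0.02)))
})
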