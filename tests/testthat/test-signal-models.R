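test_that("signal at TE -> 0 approaches the amplitude sum and matches printed demo models", {
  # extrapolating the kernel to t = 0 gives sum(c_i) exactly
  m <- mc_model(c(0.2, 0.8), T2 = c(20, 150))
  expect_equal(sum(m$amplitude), 1.0)
  d <- lanczos_demo(c(0, 10, 100))
  expect_equal(d$S1[1], 1.0)
  expect_equal(d$S2[1], 0.98)

  # direct evaluation on a tiny grid matches the naive pointwise formula
  g <- acq_grid(TE = c(10, 50, 300))
  s <- eval_signal(m, g)
  expect_equal(s$values,
               naive_signal_flat(m$amplitude, m$T2, NULL, NULL, g))
})

test_that("inversion-recovery factor has its null at TI = T1 log(2) and vanishes at long TI", {
  m <- mc_model(c(0.4, 0.6), T2 = c(40, 80), T1 = c(700, 1400))
  te <- seq(10, 200, by = 10)
  g_null <- acq_grid(TE = te, TI = 700 * log(2))
  s_null <- eval_signal(m, g_null)
  # component 1 contributes nothing: remaining signal is pure component 2
  m2only <- mc_model(0.6, T2 = 80, T1 = 1400)
  expect_equal(as.vector(s_null$values),
               as.vector(eval_signal(m2only, g_null)$values),
               tolerance = 1e-12)

  # TI >> all T1: signal approaches the T2-only model within exp(-TI/T1)
  TI_big <- 30000
  s_big <- eval_signal(m, acq_grid(TE = te, TI = TI_big))
  s_1d <- eval_signal(mc_model(c(0.4, 0.6), T2 = c(40, 80)), acq_grid(TE = te))
  expect_lt(max(abs(as.vector(s_big$values) - s_1d$values)),
            2 * exp(-TI_big / 1400) * 1.01)
})

test_that("3D signal at b = 0 equals the 2D evaluation and separability matches a triple-loop oracle", {
  m <- mc_model(c(0.3, 0.7), T2 = c(45, 60), T1 = c(1000, 500),
                ADC = c(1.5, 0.8))
  g3 <- acq_grid(TE = c(10, 60, 150), TI = c(100, 800, 2500), b = c(0, 1, 2))
  s3 <- eval_signal(m, g3)
  m2 <- mc_model(c(0.3, 0.7), T2 = c(45, 60), T1 = c(1000, 500))
  g2 <- acq_grid(TE = g3$TE, TI = g3$TI)
  expect_equal(s3$values[, , 1], eval_signal(m2, g2)$values, tolerance = 1e-15)

  expect_equal(vectorize(s3),
               naive_signal_flat(m$amplitude, m$T2, m$T1, m$ADC, g3),
               tolerance = 1e-13)
})

test_that("signal is linear in amplitudes and strictly decreasing in TE for 1D models", {
  set.seed(101)
  for (k in 1:20) {
    m <- rand_model("T2")
    g <- rand_grid("T2")
    s1 <- eval_signal(m, g)$values
    m2 <- mc_model(2 * m$amplitude, T2 = m$T2)
    expect_equal(eval_signal(m2, g)$values, 2 * s1, tolerance = 1e-15)
    expect_true(all(diff(s1) < 0))
  }
})

test_that("coalesced components collapse to a single component with summed amplitude", {
  g <- acq_grid(TE = seq(8, 512, by = 8))
  m <- mc_model(c(0.3, 0.7), T2 = c(80, 80))
  mono <- mc_model(1.0, T2 = 80)
  expect_equal(eval_signal(m, g)$values, eval_signal(mono, g)$values,
               tolerance = 1e-15)
  m2 <- mc_model(c(0.2, 0.3, 0.5), T2 = rep(60, 3), T1 = rep(900, 3))
  g2 <- acq_grid(TE = c(20, 100), TI = c(100, 1200))
  mono2 <- mc_model(1.0, T2 = 60, T1 = 900)
  expect_equal(eval_signal(m2, g2)$values, eval_signal(mono2, g2)$values,
               tolerance = 1e-15)
})

test_that("analytic Jacobian matches central finite differences over randomized draws", {
  set.seed(202)
  worst <- 0
  for (k in 1:100) {
    dimensionality <- sample(c("T2", "T1T2", "T1T2ADC"), 1)
    m <- rand_model(dimensionality)
    g <- rand_grid(dimensionality)
    B <- eval_jacobian(m, g)
    Bfd <- fd_jacobian(m, g)
    # with this step size central differences carry ~2e-10 absolute
    # round-off, so entries below ~1e-4 of the matrix scale cannot be
    # resolved at 1e-5 relative accuracy; floor the denominator there
    rel <- abs(B - Bfd) / pmax(abs(Bfd), 1e-4 * max(abs(Bfd)))
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 1e-5)
})

test_that("amplitude Jacobian columns are the pure kernels and coalescence makes B rank-deficient", {
  m <- mc_model(c(0.3, 0.7), T2 = c(45, 120))
  g <- acq_grid(TE = seq(10, 400, by = 10))
  B <- eval_jacobian(m, g)
  expect_equal(unname(B[, "c1"]), exp(-g$TE / 45), tolerance = 1e-15)
  expect_equal(unname(B[, "c2"]), exp(-g$TE / 120), tolerance = 1e-15)

  mcoal <- mc_model(c(0.3, 0.7), T2 = c(60, 60))
  Bc <- eval_jacobian(mcoal, default_grid("T2"))
  expect_equal(unname(Bc[, "c1"]), unname(Bc[, "c2"]))
  expect_identical(condition_number(Bc), Inf)
})

test_that("vectorize uses TE-fastest order and devectorize restores the tensor exactly", {
  g <- acq_grid(TE = c(10, 20, 30), TI = c(100, 500))
  m <- mc_model(c(0.5, 0.5), T2 = c(30, 90), T1 = c(400, 1200))
  s <- eval_signal(m, g)
  v <- vectorize(s)
  expect_length(v, 6)
  # element (TI index 2, TE index 1) sits right after the first TE block
  expect_equal(v[4], s$values[1, 2])
  expect_equal(devectorize(v, g)$values, s$values)

  g1 <- acq_grid(TE = c(5, 10, 20))
  s1 <- eval_signal(mc_model(1, T2 = 50), g1)
  expect_identical(vectorize(s1), s1$values)

  rm <- grid_row_map <- attr(eval_jacobian(m, g), "row_map")
  expect_equal(rm$TE, rep(g$TE, times = 2))
  expect_equal(rm$TI, rep(g$TI, each = 3))
})

test_that("model/grid dimensionality mismatches raise errors naming the missing attribute", {
  m1 <- mc_model(c(0.3, 0.7), T2 = c(45, 60))
  g2 <- acq_grid(TE = c(10, 20), TI = c(100, 200))
  expect_error(eval_signal(m1, g2), "no T1")
  m2 <- mc_model(c(0.3, 0.7), T2 = c(45, 60), T1 = c(500, 1000))
  expect_error(eval_signal(m2, acq_grid(TE = c(10, 20))), "no TI")
  m3 <- mc_model(c(0.5, 0.5), T2 = c(40, 90), T1 = c(400, 900),
                 ADC = c(1, 2))
  expect_error(eval_signal(m3, g2), "no b")
})

test_that("parameter vector layout round-trips and relabeling sorts by fitted T2", {
  m <- mc_model(c(0.3, 0.7), T2 = c(45, 60), T1 = c(1000, 500))
  p <- model_params(m)
  expect_named(p, c("c1", "c2", "T1_1", "T1_2", "T2_1", "T2_2"))
  back <- model_from_params(p, 2, "T1T2")
  expect_equal(back$amplitude, m$amplitude)
  expect_equal(back$T1, m$T1)
  expect_equal(back$T2, m$T2)

  # descending fitted T2s get swapped coherently, carrying c and T1 along
  messy <- c(0.7, 0.3, 500, 1000, 60, 45)
  fixed <- relabel_params(messy, 2, "T1T2")
  expect_equal(unname(fixed), c(0.3, 0.7, 1000, 500, 45, 60))
})

test_that("model/grid JSON serialization round-trips", {
  m <- mc_model(c(0.47, 0.53), T2 = c(36.3, 45.9), T1 = c(157, 405))
  g <- acq_grid(TE = c(0.4, 0.8, 1.2), TI = c(15, 100, 2000))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, g, path)
  got <- read_model_json(path)
  expect_equal(got$model$amplitude, m$amplitude)
  expect_equal(got$model$T1, m$T1)
  expect_equal(got$grid$TE, g$TE)
  expect_equal(got$grid$TI, g$TI)
})

test_that("constructor rejects invalid components and grids", {
  expect_error(mc_model(c(-0.1, 0.5), T2 = c(10, 20)), "positive")
  expect_error(mc_model(c(0.5, 0.5), T2 = c(10, -20)), "positive")
  expect_error(mc_model(c(0.5, 0.5), T2 = c(10, 20), ADC = c(1, 2)),
               "requires 'T1'")
  expect_error(acq_grid(TE = c(10, 10, 20)), "strictly increasing")
  expect_error(acq_grid(TE = c(0, 10)), "out of range")
  expect_error(acq_grid(TE = c(10, 20), TI = c(50, 40)), "strictly increasing")
})
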