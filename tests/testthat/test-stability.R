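test_that("orthonormal designs give identity covariance and condition number one", {
  Q <- qr.Q(qr(matrix(rnorm(80), 20, 4)))
  rep <- linear_covariance(Q, sigma = 1)
  expect_equal(unname(rep$covariance), diag(4), tolerance = 1e-12)
  expect_equal(rep$condition_number, 1, tolerance = 1e-10)
  expect_false(rep$singular)
})

test_that("covariance scales as sigma squared and sd as sigma", {
  set.seed(7)
  G <- matrix(rnorm(60), 20, 3)
  a <- linear_covariance(G, sigma = 0.5)
  b <- linear_covariance(G, sigma = 1.5)
  expect_equal(b$covariance, a$covariance * 9, tolerance = 1e-12)
  expect_equal(b$sd, a$sd * 3, tolerance = 1e-12)
  expect_equal(a$condition_number, b$condition_number)
})

test_that("covariance diagonal matches an explicit normal-equations inverse oracle", {
  set.seed(12)
  G <- matrix(rnorm(80), 20, 4)
  sigma <- 0.37
  rep <- linear_covariance(G, sigma)
  oracle <- solve(t(G) %*% G) * sigma^2   # explicit small-matrix inverse
  expect_lt(max(abs(diag(rep$covariance) - diag(oracle)) / diag(oracle)),
            1e-8)
  expect_equal(rep$sd, sqrt(diag(rep$covariance)))
})

test_that("condition number agrees with an independent eigenvalue oracle and is scale invariant", {
  set.seed(30)
  B <- matrix(rnorm(180), 30, 6)
  kappa <- condition_number(B)
  ev <- eigen(t(B) %*% B, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(kappa, sqrt(max(ev) / min(ev)), tolerance = 1e-6)
  expect_equal(condition_number(3.7 * B), kappa, tolerance = 1e-12)
  expect_equal(condition_number(-0.2 * B), kappa, tolerance = 1e-12)
})

test_that("rank-deficient designs are flagged with infinite condition number and undefined covariance", {
  G <- cbind(1:10, 2 * (1:10), rnorm(10))
  rep <- linear_covariance(G, 1)
  expect_true(rep$singular)
  expect_identical(rep$condition_number, Inf)
  expect_true(all(is.na(rep$covariance)))
  expect_true(all(is.na(rep$sd)))

  m <- mc_model(c(0.3, 0.7), T2 = c(60, 60))
  r2 <- nonlinear_covariance(m, default_grid("T2"), noise_spec(snr = 800))
  expect_true(r2$singular)
  expect_identical(r2$condition_number, Inf)
})

test_that("sigma resolves from SNR against the maximum absolute signal", {
  s <- signal_array <- structure(list(values = c(-0.8, 0.2, 1.0, 0.4),
                                      grid = acq_grid(TE = 1:4)),
                                 class = "signal_array")
  expect_equal(resolve_sigma(noise_spec(snr = 400), s), 0.0025)
  expect_equal(resolve_sigma(noise_spec(sigma = 0.01), s), 0.01)
  # signed IR signal: the absolute value matters
  s$values <- c(-2, 0.5, 1)
  expect_equal(resolve_sigma(noise_spec(snr = 100), s), 0.02)
  expect_error(noise_spec(snr = -3), "positive")
  expect_error(noise_spec(sigma = -1), "nonnegative")
  expect_error(noise_spec(snr = 10, sigma = 1), "exactly one")
})

test_that("1D coalescence sweep shows strictly decreasing sd and condition number", {
  g <- default_grid("T2")
  noise <- noise_spec(snr = 800)
  T22 <- c(61, 65, 70, 80, 100, 150)
  out <- t(vapply(T22, function(x) {
    rep <- nonlinear_covariance(mc_model(c(0.3, 0.7), T2 = c(60, x)), g, noise)
    c(rep$sd["T2_2"], kappa = rep$condition_number)
  }, numeric(2)))
  expect_true(all(diff(out[, 1]) < 0))
  expect_true(all(diff(out[, 2]) < 0))
})

test_that("2D instability peaks at T1 equality for the 1D-shared parameters and stays finite", {
  g2 <- default_grid("T1T2")
  T12 <- seq(800, 1200, by = 50)
  sds <- t(vapply(T12, function(x) {
    nonlinear_covariance(mc_model(c(0.3, 0.7), T2 = c(60, 45),
                                  T1 = c(1000, x)),
                         g2, noise_spec(snr = 800))$sd
  }, numeric(6)))
  mid <- which(T12 == 1000)
  for (p in c("c1", "c2", "T2_1", "T2_2")) {
    expect_equal(which.max(sds[, p]), mid)
    # decreasing on both sides of the peak
    expect_true(all(diff(sds[1:mid, p]) > 0))
    expect_true(all(diff(sds[mid:length(T12), p]) < 0))
  }
  # equal T1s with distinct T2s: finite condition number
  r_eq <- nonlinear_covariance(mc_model(c(0.3, 0.7), T2 = c(60, 45),
                                        T1 = c(1000, 1000)),
                               g2, noise_spec(snr = 800))
  expect_false(r_eq$singular)
  expect_true(is.finite(r_eq$condition_number))
})

test_that("conditioning improves from 1D to 2D to 3D on matched settings", {
  sw <- sweep_condition_numbers(c(500, 1000, 2000),
                                amplitude = c(0.3, 0.7), T2 = c(60, 45))
  r <- sw$rows
  expect_equal(r$cond_2d[r$T1_2 == 1000] / r$cond_1d[1], 1, tolerance = 0.05)
  expect_lt(r$cond_2d[r$T1_2 == 500], r$cond_1d[1])
  expect_lt(r$cond_2d[r$T1_2 == 2000], r$cond_1d[1])
  # 1D condition number has no T1 dependence
  expect_equal(length(unique(r$cond_1d)), 1L)
})

test_that("linearized sd agrees with a high-SNR Monte-Carlo oracle", {
  m <- mc_model(c(0.3, 0.7), T2 = c(60, 150))
  g <- default_grid("T2")
  lin <- nonlinear_covariance(m, g, noise_spec(snr = 1e6))
  mc <- run_mc(m, g, noise_spec(snr = 1e6), n_realizations = 400, seed = 99)
  expect_equal(mc$failure_count, 0)
  expect_lt(max(abs(mc$sd / lin$sd - 1)), 0.10)
})

test_that("stability reports serialize to JSON and flat sweep rows", {
  rep <- nonlinear_covariance(mc_model(c(0.3, 0.7), T2 = c(45, 90)),
                              default_grid("T2"), noise_spec(snr = 800))
  txt <- report_to_json(rep)
  doc <- jsonlite::fromJSON(txt)
  expect_equal(doc$param_layout, rep$param_layout)
  expect_equal(unlist(doc$sd), rep$sd)
  row <- report_row(rep)
  expect_equal(row$sd_T2_2, unname(rep$sd["T2_2"]))
  expect_equal(row$condition_number, rep$condition_number)
})
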