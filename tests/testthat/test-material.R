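test_that("noiseless cubic data are recovered exactly with R^2 = 1", {
  eps <- seq(0.02, 0.4, length.out = 20)
  cv <- tensile_curve(eps, 1.0 * eps + 2.0 * eps^3)
  fit <- fit_polynomial_average(list(cv))
  expect_equal(unname(coef(fit)), c(1, 0, 2), tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("fit equals a direct normal-equations solve on random data", {
  set.seed(2024)
  for (k in 1:50) {
    ncv <- sample(1:4, 1)
    curves <- lapply(seq_len(ncv), function(i) {
      eps <- sort(runif(sample(6:25, 1), 0.01, 0.5))
      eps <- eps + seq_along(eps) * 1e-9  # ensure strictly increasing
      tensile_curve(eps, runif(1, 0.5, 3) * eps + runif(1, 0, 200) * eps^3 +
                      rnorm(length(eps), 0, 0.05))
    })
    fit <- fit_polynomial_average(curves)
    eps <- unlist(lapply(curves, `[[`, "strain"))
    sig <- unlist(lapply(curves, `[[`, "stress"))
    X <- outer(eps, 1:3, `^`)
    beta_ne <- drop(solve(crossprod(X), crossprod(X, sig)))
    expect_equal(unname(coef(fit)), beta_ne, tolerance = 1e-8)
  }
})

test_that("pooled fit recovers generator truth within 3 SE on the fixture", {
  curves <- synth_tensile_curves(10, seed = 42, noise_sd = 0.05)
  fit <- fit_polynomial_average(curves)
  truth <- attr(curves, "truth_coeffs")
  eps <- unlist(lapply(curves, `[[`, "strain"))
  sig <- unlist(lapply(curves, `[[`, "stress"))
  X <- outer(eps, 1:3, `^`)
  resid <- sig - drop(X %*% coef(fit))
  s2 <- sum(resid^2) / (length(sig) - 3)
  se <- sqrt(diag(solve(crossprod(X)) * s2))
  expect_true(all(abs(coef(fit) - truth) <= 3 * se))
  expect_gt(fit$r2, 0.8)
  expect_lt(fit$r2, 1)
})

test_that("pooled fitting is the contract, not coefficient averaging", {
  # Heteroscedastic two-curve counterexample: one dense, one sparse curve.
  e1 <- seq(0.01, 0.4, length.out = 40)
  e2 <- seq(0.05, 0.2, length.out = 5)
  cv1 <- tensile_curve(e1, 2.0 * e1 + 100 * e1^3)
  cv2 <- tensile_curve(e2, 0.5 * e2 + 300 * e2^3)
  pooled <- coef(fit_polynomial_average(list(cv1, cv2)))
  avg <- (coef(fit_polynomial_average(list(cv1))) +
            coef(fit_polynomial_average(list(cv2)))) / 2
  expect_gt(max(abs(pooled - avg)), 1e-3)
})

test_that("R^2 does not increase with stress noise", {
  r2 <- vapply(c(0.02, 0.1, 0.3), function(ns) {
    mean(vapply(1:20, function(r) {
      fit_polynomial_average(synth_tensile_curves(
        10, seed = 1000 + r, noise_sd = ns, stiffness_sdlog = 0))$r2
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(r2) < 0))
})

test_that("stress evaluation: origin, direct value, odd extension, tangent", {
  fit <- material_fit(c(1, 0, 2), strain_max = 0.6)
  expect_equal(stress_at_strain(fit, 0), 0)
  expect_equal(stress_at_strain(fit, 0.5), 0.75)
  expect_equal(stress_at_strain(fit, -0.5), -0.75)
  # beyond the fitted range: tangent-line extrapolation (hand oracle)
  s_end <- 1 * 0.6 + 2 * 0.6^3
  t_end <- 1 + 3 * 2 * 0.6^2
  expect_equal(stress_at_strain(fit, 0.8), s_end + t_end * 0.2)
  expect_equal(tangent_modulus(fit, 0), 1)
  expect_equal(tangent_modulus(fit, c(0.2, 1)), c(1 + 6 * 0.04, t_end))
  expect_error(stress_at_strain(fit, NA_real_), "finite")
})

test_that("tensile-curve validation rejects malformed inputs", {
  expect_error(tensile_curve(c(0.1, 0.1, 0.2), c(1, 2, 3)), "increasing")
  expect_error(tensile_curve(c(0.2, 0.1), c(1, 2)), "increasing")
  expect_error(tensile_curve(c(-0.1, 0.1), c(1, 2)), "non-negative")
  expect_error(tensile_curve(c(0.1, 0.2), c(1)), "equal length")
  expect_error(fit_polynomial_average(
    list(tensile_curve(c(0.1, 0.2), c(1, 2)))), "points")
})

test_that("synthetic tensile curves are deterministic and unbiased at zero noise", {
  a <- synth_tensile_curves(5, seed = 7)
  b <- synth_tensile_curves(5, seed = 7)
  expect_identical(a, b)
  exact <- synth_tensile_curves(3, seed = 3, noise_sd = 0,
                                stiffness_sdlog = 0,
                                truth_coeffs = c(1, 0, 2))
  for (cv in exact) {
    expect_equal(cv$stress, cv$strain + 2 * cv$strain^3, tolerance = 1e-12)
  }
})

test_that("tensile CSV and material-fit files round-trip", {
  curves <- synth_tensile_curves(3, seed = 11)
  f <- tempfile(fileext = ".csv")
  write_tensile_csv(curves, f)
  back <- read_tensile_csv(f)
  expect_equal(length(back), 3L)
  expect_equal(back[[1]]$strain, curves[[1]]$strain)
  expect_equal(back[[1]]$stress, curves[[1]]$stress)

  fit <- fit_polynomial_average(curves)
  for (ext in c(".json", ".yaml")) {
    ff <- tempfile(fileext = ext)
    write_material_fit(fit, ff)
    fit2 <- read_material_fit(ff)
    expect_equal(coef(fit2), coef(fit), tolerance = 1e-9)
    expect_equal(fit2$r2, fit$r2, tolerance = 1e-9)
    expect_equal(fit2$strain_max, fit$strain_max, tolerance = 1e-9)
  }
})
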