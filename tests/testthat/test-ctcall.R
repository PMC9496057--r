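test_that("5PL value and analytic derivatives are correct", {
  p <- list(fb = 0.05, fmax = 0.9, x0 = 25, k = 1, s = 1)
  # symmetric logistic midpoint
  expect_equal(fivepl(p, 25), 0.05 + (0.9 - 0.05) / 2)
  # second derivative vanishes at the asymptotes
  expect_equal(fivepl_d2(p, c(-200, 200)), c(0, 0), tolerance = 1e-12)

  # finite-difference oracle on random parameter draws
  set.seed(4)
  h <- 1e-5
  for (i in 1:25) {
    q <- list(fb = runif(1, 0, 0.2), fmax = runif(1, 0.5, 2),
              x0 = runif(1, 10, 35), k = runif(1, 0.5, 3),
              s = runif(1, 0.4, 2.5))
    x <- runif(3, 5, 38)
    d1_fd <- (fivepl(q, x + h) - fivepl(q, x - h)) / (2 * h)
    d2_fd <- (fivepl_d1(q, x + h) - fivepl_d1(q, x - h)) / (2 * h)
    expect_equal(fivepl_d1(q, x), d1_fd, tolerance = 1e-6)
    expect_equal(fivepl_d2(q, x), d2_fd, tolerance = 1e-6)
  }
})

test_that("init_guess lands near the truth and rejects flat traces", {
  set.seed(9)
  for (i in 1:10) {
    truth <- list(fb = runif(1, 0.02, 0.1), fmax = runif(1, 0.6, 1),
                  x0 = runif(1, 15, 32), k = runif(1, 0.8, 1.8),
                  s = runif(1, 0.7, 1.4))
    g <- init_guess(fivepl(truth, 1:40))
    expect_lt(abs(g$x0 - truth$x0), 2)
  }
  expect_error(init_guess(rep(0.05, 40)), "not-amplifying")
  # a monotone ramp yields a guess (fit quality judged later)
  ramp <- noiseless_curve("class_F")
  expect_silent(init_guess(ramp))
})

test_that("Gauss-Newton recovers noiseless 5PL parameters to 1e-4 relative", {
  set.seed(12)
  for (i in 1:10) {
    truth <- list(fb = runif(1, 0.02, 0.1), fmax = runif(1, 0.6, 1),
                  x0 = runif(1, 18, 30), k = runif(1, 0.8, 1.8),
                  s = runif(1, 0.7, 1.4))
    y <- fivepl(truth, 1:40)
    fit <- gauss_newton_fit(y, init_guess(y))
    expect_true(fit$converged)
    rel <- abs(unlist(fit$params) - unlist(truth)) / abs(unlist(truth))
    expect_lt(max(rel), 1e-4)
    expect_lt(fit$residual_norm, 1e-12 * sum(y^2))
  }
})

test_that("a fit started at the optimum converges immediately", {
  truth <- list(fb = 0.05, fmax = 0.9, x0 = 25, k = 1.2, s = 0.9)
  y <- fivepl(truth, 1:40)
  fit <- gauss_newton_fit(y, truth)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2)
  expect_lt(fit$residual_norm, 1e-20)
})

test_that("x0 recovery under noise: median error < 0.1 cycles", {
  truth <- list(fb = 0.05, fmax = 1.05, x0 = 25, k = 1, s = 1)
  errs <- vapply(1:60, function(i) {
    set.seed(1000 + i)
    yn <- fivepl(truth, 1:40) + rnorm(40, 0, 0.005)
    f <- gauss_newton_fit(yn, init_guess(yn))
    abs(f$params$x0 - truth$x0)
  }, 0)
  expect_lt(median(errs), 0.1)
})

test_that("SDM Ct matches the closed form and the dense-grid oracle", {
  # symmetric logistic: ct = x0 - k*log(2 + sqrt(3))
  p <- list(fb = 0.05, fmax = 0.9, x0 = 25, k = 1, s = 1)
  ct <- ct_from_fit(as_fit(p))
  expect_equal(ct$ct, 25 - log(2 + sqrt(3)), tolerance = 1e-6)
  expect_equal(ct$method, "SDM")

  set.seed(21)
  for (i in 1:8) {
    q <- list(fb = 0.05, fmax = runif(1, 0.6, 1.2), x0 = runif(1, 15, 32),
              k = runif(1, 0.8, 2), s = runif(1, 0.5, 1.5))
    ct_pkg <- ct_from_fit(as_fit(q))$ct
    expect_equal(ct_pkg, sdm_grid_oracle(q), tolerance = 1e-3)
    # inflection of the rising sigmoid precedes the midpoint for s <= 1
    if (q$s <= 1) expect_lt(ct_pkg, q$x0)
  }
})

test_that("Ct shifts exactly with the curve and survives affine rescaling", {
  base <- list(fb = 0.05, fmax = 0.9, x0 = 22, k = 1.1, s = 0.8)
  ct0 <- ct_from_fit(as_fit(base))$ct
  for (delta in c(-3, 2, 5.5)) {
    shifted <- base; shifted$x0 <- base$x0 + delta
    expect_equal(ct_from_fit(as_fit(shifted))$ct, ct0 + delta,
                 tolerance = 1e-6)
  }
  # affine rescaling of the fluorescence axis is absorbed by fb/fmax
  y <- fivepl(base, 1:40)
  f1 <- gauss_newton_fit(y, init_guess(y))
  y2 <- 7.3 * y + 41
  f2 <- gauss_newton_fit(y2, init_guess(y2, min_range = 0.5))
  expect_true(f1$converged && f2$converged)
  expect_equal(ct_from_fit(as_fit(f2$params))$ct,
               ct_from_fit(as_fit(f1$params))$ct, tolerance = 1e-6)
})

test_that("degenerate fits are refused with ct-undefined errors", {
  p <- list(fb = 0.05, fmax = 0.9, x0 = 2, k = 1, s = 1)
  expect_error(ct_from_fit(as_fit(p)), "boundary")
  bad <- as_fit(list(fb = 0.9, fmax = 0.05, x0 = 25, k = 1, s = 1))
  expect_error(ct_from_fit(bad), "plateau")
  nc <- as_fit(p); nc$converged <- FALSE
  expect_error(ct_from_fit(nc), "did not converge")
})

test_that("call_ct chains the stages and degrades to a status, not an error", {
  truth <- list(fb = 0.05, fmax = 0.9, x0 = 25, k = 1, s = 1)
  cc <- call_ct(fivepl(truth, 1:40))
  expect_equal(cc$status, "ok")
  expect_equal(round_ct(cc$ct), 23.68)
  flat <- call_ct(rep(0.07, 40))
  expect_equal(flat$status, "positive-but-uncallable")
  expect_true(is.na(flat$ct))
  expect_match(flat$message, "not-amplifying")
})

test_that("reported Ct rounding is two-decimal half-up", {
  # 0.125 is exactly representable: half-up gives 0.13 where
  # round-half-even would give 0.12
  expect_equal(round_ct(0.125), 0.13)
  expect_equal(round_ct(23.6849), 23.68)
  expect_equal(round_ct(23.6851), 23.69)
})
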