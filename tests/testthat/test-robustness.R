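m <- normal_model()

test_that("contaminated sampling: moments, reproducibility, validation", {
  spec0 <- contamination_spec(0, 6)
  x0 <- sample_contaminated(spec0, 20000, seed = 1)
  expect_lt(abs(mean(x0)), 3 / sqrt(20000))
  spec <- contamination_spec(0.2, 6)
  x <- sample_contaminated(spec, 1e6, seed = 2)
  # mixture mean eps * nu = 1.2, sd of the mixture ~ sqrt(1 + eps(1-eps)nu^2)
  mix_sd <- sqrt(1 + 0.2 * 0.8 * 36)
  expect_lt(abs(mean(x) - 1.2), 3 * mix_sd / sqrt(1e6))
  expect_identical(x[1:50], sample_contaminated(spec, 1e6, seed = 2)[1:50])
  expect_error(contamination_spec(1, 6), "\\[0, 1\\)")
  expect_error(contamination_spec(-0.1, 6), "\\[0, 1\\)")
  # the mixture density integrates to one
  expect_equal(quad(function(z) dcontam(spec, z)), 1, tolerance = 1e-8)
})

test_that("tail condition: closed-form Gaussian oracles and tail decay", {
  expect_equal(nu_condition(std_normal, std_normal, 1), 1 / (2 * sqrt(pi)),
               tolerance = 1e-9)
  # delta = N(6,1), f = N(0,1), gamma0 = 2: Gaussian product with
  # exponent -(3/2)(x-2)^2 - 12
  oracle <- sqrt((2 * pi)^(-1) * 3^(-1 / 2) * exp(-12))
  expect_equal(nu_condition(function(x) dnorm(x, 6, 1), std_normal, 2),
               oracle, tolerance = 1e-8)
  vals <- sapply(c(4, 6, 8, 10), function(nu)
    nu_condition(function(x) dnorm(x, nu, 1), std_normal, 1.5))
  expect_true(all(diff(vals) < 0))
})

test_that("clean sandwich matrices: information identity and Monte-Carlo oracle", {
  # KL loss: I = J = H = Fisher = diag(1, 2) at (0, 1)
  s <- sandwich_matrices(m, kl_loss(), c(0, 1))
  expect_equal(unname(s$I), diag(c(1, 2)), tolerance = 1e-8)
  expect_equal(unname(s$J), diag(c(1, 2)), tolerance = 1e-8)
  expect_equal(s$J, s$H)
  # gamma loss: J = H under clean data; quadrature matches a Monte-Carlo
  # average of the loss Hessian over 2e5 draws within 3 standard errors
  sg <- sandwich_matrices(m, gamma_loss(0.5), c(0, 1))
  expect_equal(sg$J, sg$H)
  set.seed(77)
  xs <- rnorm(2e5)
  d2 <- gposterior:::.q_derivs(m, xs, c(0, 1), gamma_loss(0.5), 2L)$d2
  for (i in 1:2) for (j in 1:2) {
    mc <- -mean(d2[, i, j])
    se <- sd(d2[, i, j]) / sqrt(2e5)
    expect_lt(abs(sg$J[i, j] - mc), 3 * se + 1e-12)
  }
})

test_that("contaminated J obeys the first-order mixture decomposition", {
  # J_contaminated ~ (1-eps) H + eps * (delta part); the delta part is
  # bounded, so the distance from (1-eps) H is small at nu = 6
  spec <- contamination_spec(0.2, 6)
  sg <- sandwich_matrices(m, gamma_loss(0.5), c(0, 1), spec)
  expect_lt(norm(sg$J - 0.8 * sg$H, "F"), 0.05)
  expect_gt(norm(sg$J - 0.8 * sg$H, "F"), 0)
})

test_that("asymptotic covariance: Fisher inverse, small-gamma limit, closed form", {
  V0 <- asymptotic_covariance(m, kl_loss(), c(0, 1))
  expect_equal(unname(V0), diag(c(1, 0.5)), tolerance = 1e-8)
  Vsmall <- asymptotic_covariance(m, gamma_loss(1e-4), c(0, 1))
  expect_equal(unname(Vsmall), diag(c(1, 0.5)), tolerance = 1e-3)
  # independently derived closed form of the gamma-loss sandwich covariance:
  # V_mumu = (1+g)^3/(1+2g)^{3/2},
  # V_ss   = (1+g)^3 (2+4g+3g^2) / {4 (1+2g)^{5/2}}
  for (g in c(0.3, 0.5)) {
    V <- asymptotic_covariance(m, gamma_loss(g), c(0, 1))
    expect_equal(V[1, 1], (1 + g)^3 / (1 + 2 * g)^1.5, tolerance = 1e-8)
    expect_equal(V[2, 2],
                 (1 + g)^3 * (2 + 4 * g + 3 * g^2) / (4 * (1 + 2 * g)^2.5),
                 tolerance = 1e-8)
    expect_equal(V[1, 2], 0, tolerance = 1e-8)
  }
})

test_that("efficiency curve: limits, monotonicity, and the two routes", {
  expect_identical(are_normal(0)$are, 1)
  grid <- seq(0.02, 1, by = 0.07)
  vals <- sapply(grid, function(g) are_normal(g)$are)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals < 1))
  expect_equal(are_normal(1e-9)$are, 1, tolerance = 1e-7)
  # the sandwich (first-principles) route matches its own closed form,
  # which differs from the tabulated curve for gamma > 0
  g <- 0.3
  sw <- are_normal(g, method = "sandwich")
  expect_equal(sw$are, sqrt(2 * (1 + 2 * g)^4 /
                              ((1 + g)^6 * (2 + 4 * g + 3 * g^2))),
               tolerance = 1e-7)
  expect_gt(sw$are, are_normal(g)$are)
})

test_that("tuning selection inverts the efficiency curve", {
  for (t in c(0.3, 0.6, 0.9)) {
    g <- choose_gamma_for_are(t)
    expect_equal(are_normal(g)$are, t, tolerance = 1e-10)
  }
  expect_equal(choose_gamma_for_are(0.9999), 0, tolerance = 1e-3)
  expect_error(choose_gamma_for_are(1.2), "between 0 and 1")
  expect_error(choose_gamma_for_are(0), "between 0 and 1")
})
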