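m <- normal_model()

test_that("per-observation gamma loss: value, KL limit, location invariance", {
  pn <- quad(function(x) dnorm(x)^1.5)
  expect_equal(q_gamma(m, 0, c(0, 1), 0.5),
               2 * dnorm(0)^0.5 * pn^(-1 / 3), tolerance = 1e-9)
  # q_gamma - 1/gamma -> log f as gamma -> 0
  g <- 1e-6
  expect_equal(q_gamma(m, 0, c(0, 1), g) - 1 / g, dnorm(0, log = TRUE),
               tolerance = 1e-4)
  # joint location shift of x and mu leaves the loss unchanged
  expect_equal(q_gamma(m, 0.4 + 3, c(0.1 + 3, 1.2), 0.5),
               q_gamma(m, 0.4, c(0.1, 1.2), 0.5), tolerance = 1e-12)
  expect_error(q_gamma(m, 0, c(0, 1), 0), "invalid tuning")
})

test_that("per-observation density-power loss: value, KL limit, monotone in the density", {
  pn <- quad(function(x) dnorm(x)^1.5)
  expect_equal(q_alpha(m, 0, c(0, 1), 0.5),
               2 * dnorm(0)^0.5 - (2 / 3) * pn, tolerance = 1e-9)
  a <- 1e-6
  expect_equal(q_alpha(m, 0, c(0, 1), a) - 1 / a + 1 / (1 + a),
               dnorm(0, log = TRUE), tolerance = 1e-4)
  # increasing in f(x): ordering across x follows the density ordering
  xs <- c(0, 0.5, 1, 2)
  qs <- q_alpha(m, xs, c(0, 1), 0.5)
  expect_true(all(diff(qs) < 0))
})

test_that("empirical cross-entropy: limits, point-mass identity, duplication invariance", {
  # gamma ~ 0 recovers the mean negative log-likelihood
  expect_equal(empirical_cross_entropy(0, m, c(0, 1), gamma_loss(1e-6)),
               0.918939, tolerance = 1e-4)
  # for a single observation, the monotone transform identity
  # d~ = (1/g)(1 - exp(-g * d_gamma)) with d_gamma computed from its
  # definition under the point mass at 0
  g <- 0.5
  dg <- -log(dnorm(0)^g) / g + log(quad(function(x) dnorm(x)^(1 + g))) / (1 + g)
  expect_equal(empirical_cross_entropy(0, m, c(0, 1), gamma_loss(g)),
               (1 - exp(-g * dg)) / g, tolerance = 1e-10)
  # mean of per-point terms: duplicating every observation changes nothing
  x <- c(-0.3, 0.8, 2.1)
  for (loss in list(kl_loss(), gamma_loss(0.4), dp_loss(0.4)))
    expect_equal(empirical_cross_entropy(c(x, x), m, c(0.1, 1.1), loss),
                 empirical_cross_entropy(x, m, c(0.1, 1.1), loss),
                 tolerance = 1e-12)
  expect_error(empirical_cross_entropy(numeric(0), m, c(0, 1), kl_loss()),
               "nonempty")
  expect_error(empirical_cross_entropy(0, m, c(0, -1), kl_loss()), "domain")
})

test_that("sum of gamma losses and the cross-entropy differ by the constant n/gamma", {
  set.seed(5)
  x <- rnorm(25)
  g <- 0.5
  for (th in list(c(0, 1), c(0.4, 0.7), c(-1, 2.5))) {
    lhs <- -length(x) * empirical_cross_entropy(x, m, th, gamma_loss(g))
    rhs <- sum(q_gamma(m, x, th, g)) - length(x) / g
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("gamma divergence: self-divergence zero, quadrature oracle, nonnegativity, KL limit", {
  expect_equal(gamma_divergence(std_normal, m, c(0, 1), 0.5), 0,
               tolerance = 1e-9)
  # independent three-integral oracle for g = N(1,1) vs N(0,1)
  g <- 0.5
  gd <- function(x) dnorm(x, 1, 1)
  oracle <- log(quad(function(x) gd(x)^(1 + g))) / (g * (1 + g)) -
    log(quad(function(x) gd(x) * dnorm(x)^g)) / g +
    log(quad(function(x) dnorm(x)^(1 + g))) / (1 + g)
  v <- gamma_divergence(gd, m, c(0, 1), g)
  expect_gt(v, 0)
  expect_equal(v, oracle, tolerance = 1e-9)
  # nonnegative on a grid of (g, theta) pairs
  for (mu_g in c(-1, 0.5)) for (th in list(c(0, 1), c(0.5, 1.5)))
    expect_gte(gamma_divergence(function(x) dnorm(x, mu_g, 1), m, th, 0.3),
               -1e-10)
  # KL(N(0.5,1), N(0,1)) = 0.125 as gamma -> 0
  expect_equal(gamma_divergence(function(x) dnorm(x, 0.5, 1), m, c(0, 1), 1e-5),
               0.125, tolerance = 1e-4)
})

test_that("gamma and density-power cross-entropies converge to the KL one as tuning -> 0", {
  set.seed(6)
  x <- rnorm(30)
  th <- c(0.2, 1.4)
  kl <- empirical_cross_entropy(x, m, th, kl_loss())
  # the transformed gamma cross-entropy already carries its +1/gamma constant
  g <- 1e-6
  expect_equal(empirical_cross_entropy(x, m, th, gamma_loss(g)), kl,
               tolerance = 1e-4)
  # the density-power cross-entropy diverges like -1/alpha
  a <- 1e-6
  expect_equal(empirical_cross_entropy(x, m, th, dp_loss(a)) + 1 / a, kl,
               tolerance = 1e-4)
})

test_that("tuning 0 collapses a loss_spec to KL and invalid specs error", {
  expect_identical(gamma_loss(0)$kind, "KL")
  expect_identical(dp_loss(0)$kind, "KL")
  expect_error(loss_spec("gamma", -0.1), "nonnegative")
  expect_error(loss_spec("KL", 0.5), "no tuning")
  expect_identical(gamma_loss(0.5)$omega, 1)
})
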