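#' Quasi-posterior objects
#'
#' Bundles data, model, loss and prior into the unnormalized quasi-posterior
#' \deqn{\pi^{(d)}(\theta \mid X^n) \propto \exp\{-n\, d(\bar g, f_\theta)\}\,
#' \pi(\theta) = \exp\{\textstyle\sum_i q^{(d)}(X_i; \theta)\}\, \pi(\theta).}
#' The learning rate is fixed at 1 (asserted, not tunable). Theta-free
#' constants in the exponent are dropped in [log_quasi_posterior()]; the
#' two displayed forms then coincide.
#'
#' @param data numeric sample.
#' @param model a [parametric_model()].
#' @param loss a [loss_spec()].
#' @param prior a [prior_spec()].
#' @param omega learning rate; must equal 1.
#' @return An object of class `quasi_posterior`.
#' @export
quasi_posterior <- function(data, model, loss, prior = uniform_prior(),
                            omega = 1) {
  stopifnot(length(data) >= 1, inherits(loss, "loss_spec"),
            inherits(prior, "prior_spec"))
  if (!identical(omega, 1) && !(is.numeric(omega) && omega == 1))
    stop("the learning rate omega is fixed at 1")
  structure(list(data = as.numeric(data), model = model, loss = loss,
                 prior = prior, n = length(data), omega = 1),
            class = "quasi_posterior")
}

#' @export
print.quasi_posterior <- function(x, ...) {
  cat(sprintf("<quasi_posterior> %s loss, %s prior, n = %d (%s model)\n",
              .loss_label(x$loss), x$prior$kind, x$n, x$model$name))
  invisible(x)
}

#' Unnormalized log quasi-posterior density
#'
#' \eqn{\sum_i q^{(d)}(X_i;\theta) + \log\pi(\theta)} up to a theta-free
#' constant. Parameters outside the domain (e.g. \eqn{\sigma \le 0}) give
#' `-Inf` rather than an error, so rejected proposal draws are handled
#' gracefully.
#'
#' @param qp a [quasi_posterior()].
#' @param theta parameter vector.
#' @return Scalar log density (possibly `-Inf`).
#' @export
log_quasi_posterior <- function(qp, theta) {
  if (!qp$model$in_domain(theta)) return(-Inf)
  sum(q_loss(qp$model, qp$data, theta, qp$loss)) + qp$prior$log_prior(theta)
}

# vectorized unnormalized log quasi-posterior for the normal model over
# paired draws (mu_k, sigma_k); the workhorse of the importance sampler
# and the grid oracle
.log_qpost_normal <- function(data, loss, prior, mu, sigma) {
  n <- length(data)
  K <- length(mu)
  ls <- rep(log(sigma), each = n)
  z <- (outer(data, mu, "-")) / rep(sigma, each = n)
  lp <- -0.9189385332046727 - ls - 0.5 * z * z        # n x K log densities
  dim(lp) <- c(n, K)
  core <- switch(loss$kind,
    KL = colSums(lp),
    gamma = {
      g <- loss$tuning
      logpn <- -(g / 2) * log(2 * pi * sigma^2) - 0.5 * log(1 + g)
      colSums(exp(g * lp)) * exp(-(g / (1 + g)) * logpn) / g
    },
    density_power = {
      a <- loss$tuning
      pn <- (2 * pi * sigma^2)^(-a / 2) / sqrt(1 + a)
      colSums(exp(a * lp)) / a - n * pn / (1 + a)
    })
  lprior <- if (!is.null(prior$sigma_exponent))
    prior$sigma_exponent * log(sigma)
  else
    vapply(seq_len(K), function(k) prior$log_prior(c(mu[k], sigma[k])),
           numeric(1))
  out <- core + lprior
  out[sigma <= 0] <- -Inf
  out
}

#' Importance sampler configuration
#'
#' Settings for the self-normalized importance-sampling estimate of the
#' posterior mean. The proposal draws \eqn{\mu \sim N(\bar x, s^2)} and
#' \eqn{\sigma \sim IG(6, 5s)} independently, where \eqn{\bar x} and
#' \eqn{s^2} are the sample mean and (n-1)-divisor variance. The inverse
#' gamma IG(a, b) has density \eqn{\propto \sigma^{-a-1} e^{-b/\sigma}}, so
#' IG(6, 5s) has mean \eqn{b/(a-1) = s}: the proposal for the scale is
#' centered at the sample scale.
#'
#' @param n_draws number of draws (at least 100; default 10,000).
#' @param seed integer seed.
#' @param ig_shape,ig_scale_factor proposal parameters a and b/s.
#' @param ess_warn_threshold warn when ESS falls below this fraction of
#'   `n_draws`.
#' @return An object of class `is_config`.
#' @export
is_config <- function(n_draws = 10000L, seed = 1L, ig_shape = 6,
                      ig_scale_factor = 5, ess_warn_threshold = 0.02) {
  stopifnot(n_draws >= 100, ig_shape > 0, ig_scale_factor > 0)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 ig_shape = ig_shape, ig_scale_factor = ig_scale_factor,
                 ess_warn_threshold = ess_warn_threshold),
            class = "is_config")
}

#' Importance-sampling posterior mean
#'
#' Self-normalized importance-sampling estimate of the quasi-posterior mean
#' of \eqn{(\mu, \sigma)}. Log weights are stabilized by subtracting their
#' maximum before exponentiation; the effective sample size
#' \eqn{(\sum w)^2 / \sum w^2} is reported and a warning is emitted when it
#' degenerates below the configured fraction of the draw count.
#'
#' @param qp a [quasi_posterior()] for a two-parameter location-scale model.
#' @param cfg an [is_config()].
#' @return An object of class `posterior_summary` with fields
#'   `posterior_mean` (named vector), `ess`, `n_draws`, `seed`.
#' @examples
#' x <- rnorm(50)
#' qp <- quasi_posterior(x, normal_model(), gamma_loss(0.5),
#'                       normal_closed_form_prior("reference", gamma_loss(0.5)))
#' importance_sampling_mean(qp, is_config(n_draws = 2000, seed = 7))
#' @export
importance_sampling_mean <- function(qp, cfg = is_config()) {
  if (qp$n < 2L) stop("need at least 2 observations")
  if (qp$model$p != 2L) stop("the importance sampler targets (mu, sigma) models")
  data <- qp$data
  xbar <- mean(data)
  s <- stats::sd(data)
  if (!is.finite(s) || s <= 0) stop("sample scale must be positive")
  a <- cfg$ig_shape
  b <- cfg$ig_scale_factor * s
  K <- cfg$n_draws
  set.seed(cfg$seed)
  mu_k <- stats::rnorm(K, xbar, s)
  sigma_k <- 1 / stats::rgamma(K, shape = a, rate = b)
  if (qp$model$name == "normal") {
    # evaluate in chunks to bound the n x K working matrix
    chunk <- max(1L, as.integer(ceiling(4e6 / qp$n)))
    lpost <- numeric(K)
    for (st in seq(1L, K, by = chunk)) {
      en <- min(st + chunk - 1L, K)
      lpost[st:en] <- .log_qpost_normal(data, qp$loss, qp$prior,
                                        mu_k[st:en], sigma_k[st:en])
    }
  } else {
    lpost <- vapply(seq_len(K), function(k)
      log_quasi_posterior(qp, c(mu_k[k], sigma_k[k])), numeric(1))
  }
  lprop <- stats::dnorm(mu_k, xbar, s, log = TRUE) +
    a * log(b) - lgamma(a) - (a + 1) * log(sigma_k) - b / sigma_k
  lw <- lpost - lprop
  ok <- is.finite(lw)
  if (!any(ok)) stop("all importance weights are zero or non-finite")
  w <- numeric(K)
  w[ok] <- exp(lw[ok] - max(lw[ok]))
  sw <- sum(w)
  ess <- sw^2 / sum(w^2)
  if (ess < cfg$ess_warn_threshold * K)
    warning(sprintf("effective sample size %.1f of %d draws", ess, K))
  pm <- c(mu = sum(w * mu_k) / sw, sigma = sum(w * sigma_k) / sw)
  structure(list(posterior_mean = pm, ess = ess, n_draws = K,
                 seed = cfg$seed),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary>\n")
  print(signif(x$posterior_mean, 6))
  cat(sprintf("  ESS %.1f / %d draws (seed %d)\n", x$ess, x$n_draws, x$seed))
  invisible(x)
}

#' Deterministic grid-quadrature posterior mean
#'
#' Trapezoid-rule posterior mean of \eqn{(\mu, \sigma)} on a rectangular
#' grid; a slow, sampler-free oracle for validating the importance sampler.
#' The grid must cover essentially all posterior mass.
#'
#' @param qp a [quasi_posterior()] on the normal model.
#' @param mu_range,sigma_range grid ranges.
#' @param n_mu,n_sigma grid sizes.
#' @return Named vector `c(mu, sigma)` of posterior means.
#' @export
grid_posterior_mean <- function(qp, mu_range, sigma_range,
                                n_mu = 400L, n_sigma = 400L) {
  stopifnot(qp$model$name == "normal")
  mu <- seq(mu_range[1], mu_range[2], length.out = n_mu)
  sg <- seq(sigma_range[1], sigma_range[2], length.out = n_sigma)
  L <- matrix(0, n_sigma, n_mu)
  for (j in seq_len(n_sigma))
    L[j, ] <- .log_qpost_normal(qp$data, qp$loss, qp$prior, mu,
                                rep(sg[j], n_mu))
  W <- exp(L - max(L))
  # composite trapezoid weights
  tw <- function(k) { w <- rep(1, k); w[c(1, k)] <- 0.5; w }
  Wt <- outer(tw(n_sigma), tw(n_mu)) * W
  tot <- sum(Wt)
  c(mu = sum(Wt * matrix(mu, n_sigma, n_mu, byrow = TRUE)) / tot,
    sigma = sum(Wt * matrix(sg, n_sigma, n_mu)) / tot)
}
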