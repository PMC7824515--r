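#' Parametric model objects
#'
#' A `parametric_model` bundles a univariate density family \eqn{f_\theta}
#' with the quantities the quasi-posterior machinery needs: the log-density,
#' its parameter derivatives up to third order, and the power norm
#' \eqn{\int_\Omega f_\theta(x)^{1+c}\,dx}. Analytic components may be
#' supplied; anything missing falls back to finite differences (derivatives)
#' or adaptive quadrature (power norms).
#'
#' @param name short identifier, used to select fast paths (e.g. `"normal"`).
#' @param param_names character vector naming \eqn{\theta = (\theta_1, \ldots, \theta_p)}.
#' @param support numeric length-2 vector, the support \eqn{\Omega} of the density.
#' @param logpdf function `(x, theta)` returning the log density, vectorized in `x`.
#' @param in_domain function `(theta)` returning `TRUE` when `theta` lies in
#'   the (open) parameter domain.
#' @param logpdf_derivs optional function `(x, theta, order)` returning a list
#'   with elements `l1` (n x p), `l2` (n x p x p) and, for `order = 3`,
#'   `l3` (n x p x p x p) of partial derivatives of the log density.
#' @param power_norm optional function `(theta, c)` returning
#'   \eqn{\int f_\theta^{1+c}}.
#' @param log_power_norm_derivs optional function `(theta, c, order)` giving
#'   parameter derivatives of \eqn{\log \int f_\theta^{1+c}} (list `c1`, `c2`, `c3`).
#' @param rdist optional sampler `(n, theta)`.
#' @param moment_init optional function `(data, robust)` returning a starting
#'   value for optimization.
#' @param transform,inv_transform optional reparameterization to and from an
#'   unconstrained scale used by the optimizer.
#' @param default_theta a reference parameter value inside the domain; also
#'   used to anchor antiderivatives of moment-matching priors.
#'
#' @return An object of class `parametric_model`.
#' @seealso [normal_model()], [exponential_model()]
#' @export
parametric_model <- function(name, param_names, support, logpdf, in_domain,
                             logpdf_derivs = NULL, power_norm = NULL,
                             log_power_norm_derivs = NULL, rdist = NULL,
                             moment_init = NULL, transform = NULL,
                             inv_transform = NULL, default_theta = NULL) {
  stopifnot(is.character(param_names), length(support) == 2L,
            is.function(logpdf), is.function(in_domain))
  m <- list(name = name, param_names = param_names, p = length(param_names),
            support = support, logpdf = logpdf, in_domain = in_domain,
            logpdf_derivs = logpdf_derivs, power_norm = power_norm,
            log_power_norm_derivs = log_power_norm_derivs, rdist = rdist,
            moment_init = moment_init, transform = transform,
            inv_transform = inv_transform, default_theta = default_theta)
  class(m) <- "parametric_model"
  m
}

#' @export
print.parametric_model <- function(x, ...) {
  cat("<parametric_model>", x$name, "\n  parameters:",
      paste(x$param_names, collapse = ", "),
      sprintf("\n  support: (%g, %g)\n", x$support[1], x$support[2]))
  invisible(x)
}

.check_theta <- function(model, theta) {
  if (length(theta) != model$p)
    stop("theta must have length ", model$p)
  if (!model$in_domain(theta))
    stop("theta = (", paste(signif(theta, 6), collapse = ", "),
         ") is outside the parameter domain of model '", model$name, "'")
  invisible(TRUE)
}

#' Power norm of the normal density
#'
#' Closed form of \eqn{\int N(x; \mu, \sigma^2)^{1+c}\,dx =
#' (2\pi\sigma^2)^{-c/2} (1+c)^{-1/2}}; independent of \eqn{\mu}.
#'
#' @param mu location.
#' @param sigma scale, positive.
#' @param c power offset, positive.
#' @return The value of the integral.
#' @export
normal_power_norm <- function(mu, sigma, c) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.finite(c) || c <= 0) stop("c must be positive")
  (2 * pi * sigma^2)^(-c / 2) / sqrt(1 + c)
}

# log power norm of the normal and its (mu, sigma) derivatives, closed form
.normal_lpn_derivs <- function(theta, c, order = 3L) {
  s <- theta[2]
  out <- list(c1 = c(0, -c / s))
  if (order >= 2L) out$c2 <- matrix(c(0, 0, 0, c / s^2), 2, 2)
  if (order >= 3L) {
    c3 <- array(0, c(2, 2, 2)); c3[2, 2, 2] <- -2 * c / s^3
    out$c3 <- c3
  }
  out
}

#' Normal location-scale model
#'
#' The family \eqn{N(\mu, \sigma^2)} parameterized by \eqn{(\mu, \sigma)}
#' (the scale, not the variance), with closed-form log-density derivatives
#' and power norms.
#'
#' @return A [parametric_model()].
#' @examples
#' m <- normal_model()
#' m$power_norm(c(0, 1), 0.5)   # (2*pi)^(-1/4) / sqrt(1.5)
#' @export
normal_model <- function() {
  derivs <- function(x, theta, order = 3L) {
    mu <- theta[1]; s <- theta[2]
    z <- (x - mu) / s
    n <- length(x)
    l1 <- cbind(z / s, (z^2 - 1) / s)
    out <- list(l1 = l1)
    if (order >= 2L) {
      l2 <- array(0, c(n, 2, 2))
      l2[, 1, 1] <- -1 / s^2
      l2[, 1, 2] <- l2[, 2, 1] <- -2 * z / s^2
      l2[, 2, 2] <- (1 - 3 * z^2) / s^2
      out$l2 <- l2
    }
    if (order >= 3L) {
      l3 <- array(0, c(n, 2, 2, 2))
      l3[, 1, 1, 2] <- l3[, 1, 2, 1] <- l3[, 2, 1, 1] <- 2 / s^3
      l3[, 1, 2, 2] <- l3[, 2, 1, 2] <- l3[, 2, 2, 1] <- 6 * z / s^3
      l3[, 2, 2, 2] <- (12 * z^2 - 2) / s^3
      out$l3 <- l3
    }
    out
  }
  parametric_model(
    name = "normal",
    param_names = c("mu", "sigma"),
    support = c(-Inf, Inf),
    logpdf = function(x, theta) stats::dnorm(x, theta[1], theta[2], log = TRUE),
    in_domain = function(theta) all(is.finite(theta)) && theta[2] > 0,
    logpdf_derivs = derivs,
    power_norm = function(theta, c) normal_power_norm(theta[1], theta[2], c),
    log_power_norm_derivs = .normal_lpn_derivs,
    rdist = function(n, theta) stats::rnorm(n, theta[1], theta[2]),
    moment_init = function(data, robust = TRUE) {
      if (robust) c(stats::median(data), stats::mad(data))
      else c(mean(data), stats::sd(data) * sqrt((length(data) - 1) / length(data)))
    },
    transform = function(theta) c(theta[1], log(theta[2])),
    inv_transform = function(eta) c(eta[1], exp(eta[2])),
    default_theta = c(0, 1)
  )
}

#' Exponential model (rate parameterization)
#'
#' One-parameter family \eqn{f_\lambda(x) = \lambda e^{-\lambda x}} on
#' \eqn{(0, \infty)}; used mainly to exercise the one-dimensional
#' moment-matching prior machinery.
#'
#' @return A [parametric_model()].
#' @export
exponential_model <- function() {
  derivs <- function(x, theta, order = 3L) {
    lam <- theta[1]; n <- length(x)
    out <- list(l1 = cbind(1 / lam - x))
    if (order >= 2L) out$l2 <- array(-1 / lam^2, c(n, 1, 1))
    if (order >= 3L) out$l3 <- array(2 / lam^3, c(n, 1, 1, 1))
    out
  }
  parametric_model(
    name = "exponential",
    param_names = "rate",
    support = c(0, Inf),
    logpdf = function(x, theta) stats::dexp(x, theta[1], log = TRUE),
    in_domain = function(theta) is.finite(theta[1]) && theta[1] > 0,
    logpdf_derivs = derivs,
    power_norm = function(theta, c) theta[1]^c / (1 + c),
    rdist = function(n, theta) stats::rexp(n, theta[1]),
    moment_init = function(data, robust = TRUE) {
      if (robust) log(2) / stats::median(data) else 1 / mean(data)
    },
    transform = function(theta) log(theta),
    inv_transform = function(eta) exp(eta),
    default_theta = 1
  )
}

#' Normal model with a single free parameter
#'
#' One-dimensional restrictions of the normal family: location with known
#' scale, or scale with known location. Used by the one-dimensional
#' moment-matching prior.
#'
#' @param sigma known scale for the location model.
#' @param mu known location for the scale model.
#' @return A [parametric_model()] with `p = 1`.
#' @export
normal_location_model <- function(sigma = 1) {
  stopifnot(sigma > 0)
  derivs <- function(x, theta, order = 3L) {
    z <- (x - theta[1]) / sigma; n <- length(x)
    out <- list(l1 = cbind(z / sigma))
    if (order >= 2L) out$l2 <- array(-1 / sigma^2, c(n, 1, 1))
    if (order >= 3L) out$l3 <- array(0, c(n, 1, 1, 1))
    out
  }
  parametric_model(
    name = "normal_location", param_names = "mu", support = c(-Inf, Inf),
    logpdf = function(x, theta) stats::dnorm(x, theta[1], sigma, log = TRUE),
    in_domain = function(theta) is.finite(theta[1]),
    logpdf_derivs = derivs,
    power_norm = function(theta, c) normal_power_norm(theta[1], sigma, c),
    log_power_norm_derivs = function(theta, c, order = 3L)
      list(c1 = 0, c2 = matrix(0, 1, 1), c3 = array(0, c(1, 1, 1))),
    rdist = function(n, theta) stats::rnorm(n, theta[1], sigma),
    moment_init = function(data, robust = TRUE)
      if (robust) stats::median(data) else mean(data),
    transform = identity, inv_transform = identity,
    default_theta = 0
  )
}

#' @rdname normal_location_model
#' @export
normal_scale_model <- function(mu = 0) {
  derivs <- function(x, theta, order = 3L) {
    s <- theta[1]; z <- (x - mu) / s; n <- length(x)
    out <- list(l1 = cbind((z^2 - 1) / s))
    if (order >= 2L) out$l2 <- array((1 - 3 * z^2) / s^2, c(n, 1, 1))
    if (order >= 3L) out$l3 <- array((12 * z^2 - 2) / s^3, c(n, 1, 1, 1))
    out
  }
  parametric_model(
    name = "normal_scale", param_names = "sigma", support = c(-Inf, Inf),
    logpdf = function(x, theta) stats::dnorm(x, mu, theta[1], log = TRUE),
    in_domain = function(theta) is.finite(theta[1]) && theta[1] > 0,
    logpdf_derivs = derivs,
    power_norm = function(theta, c) normal_power_norm(mu, theta[1], c),
    log_power_norm_derivs = function(theta, c, order = 3L) {
      s <- theta[1]
      list(c1 = -c / s, c2 = matrix(c / s^2, 1, 1),
           c3 = array(-2 * c / s^3, c(1, 1, 1)))
    },
    rdist = function(n, theta) stats::rnorm(n, mu, theta[1]),
    moment_init = function(data, robust = TRUE)
      if (robust) stats::mad(data - mu, center = 0) else
        sqrt(mean((data - mu)^2)),
    transform = log, inv_transform = exp,
    default_theta = 1
  )
}

# ---- generic fallbacks ------------------------------------------------------

# central finite differences; step scaled per coordinate
.fd_steps <- function(theta, pow = 1 / 3) .Machine$double.eps^pow * pmax(1, abs(theta))

.num_logpdf_derivs <- function(model, x, theta, order = 3L) {
  p <- model$p
  n <- length(x)
  h <- .fd_steps(theta)
  lp <- function(th) model$logpdf(x, th)
  l1 <- matrix(0, n, p)
  for (i in seq_len(p)) {
    e <- replace(numeric(p), i, h[i])
    l1[, i] <- (lp(theta + e) - lp(theta - e)) / (2 * h[i])
  }
  out <- list(l1 = l1)
  if (order >= 2L) {
    h2 <- .fd_steps(theta, 1 / 4)
    l2 <- array(0, c(n, p, p))
    for (i in seq_len(p)) for (j in i:p) {
      ei <- replace(numeric(p), i, h2[i]); ej <- replace(numeric(p), j, h2[j])
      v <- (lp(theta + ei + ej) - lp(theta + ei - ej) -
              lp(theta - ei + ej) + lp(theta - ei - ej)) / (4 * h2[i] * h2[j])
      l2[, i, j] <- l2[, j, i] <- v
    }
    out$l2 <- l2
  }
  if (order >= 3L) {
    # third derivatives: central difference of the numeric Hessian
    h3 <- .fd_steps(theta, 1 / 5)
    l3 <- array(0, c(n, p, p, p))
    for (k in seq_len(p)) {
      e <- replace(numeric(p), k, h3[k])
      Hp <- .num_logpdf_derivs(model, x, theta + e, order = 2L)$l2
      Hm <- .num_logpdf_derivs(model, x, theta - e, order = 2L)$l2
      l3[, , , k] <- (Hp - Hm) / (2 * h3[k])
    }
    # symmetrize over index permutations
    for (i in seq_len(p)) for (j in seq_len(p)) for (k in seq_len(p)) {
      v <- (l3[, i, j, k] + l3[, i, k, j] + l3[, j, i, k] +
              l3[, j, k, i] + l3[, k, i, j] + l3[, k, j, i]) / 6
      l3[, i, j, k] <- v
    }
    out$l3 <- l3
  }
  out
}

# model-facing accessors used across the package
.model_logpdf_derivs <- function(model, x, theta, order = 3L) {
  if (!is.null(model$logpdf_derivs)) model$logpdf_derivs(x, theta, order)
  else .num_logpdf_derivs(model, x, theta, order)
}

#' Integrate a function against the model density by adaptive quadrature
#' @noRd
.model_power_norm <- function(model, theta, c) {
  if (!is.null(model$power_norm)) return(model$power_norm(theta, c))
  stats::integrate(function(x) exp((1 + c) * model$logpdf(x, theta)),
                   model$support[1], model$support[2],
                   rel.tol = 1e-12, abs.tol = 1e-10)$value
}

.model_lpn_derivs <- function(model, theta, c, order = 3L) {
  if (!is.null(model$log_power_norm_derivs))
    return(model$log_power_norm_derivs(theta, c, order))
  p <- model$p
  f <- function(th) log(.model_power_norm(model, th, c))
  h <- .fd_steps(theta)
  c1 <- numeric(p)
  for (i in seq_len(p)) {
    e <- replace(numeric(p), i, h[i])
    c1[i] <- (f(theta + e) - f(theta - e)) / (2 * h[i])
  }
  out <- list(c1 = c1)
  if (order >= 2L) {
    h2 <- .fd_steps(theta, 1 / 4)
    c2 <- matrix(0, p, p)
    for (i in seq_len(p)) for (j in i:p) {
      ei <- replace(numeric(p), i, h2[i]); ej <- replace(numeric(p), j, h2[j])
      c2[i, j] <- c2[j, i] <- (f(theta + ei + ej) - f(theta + ei - ej) -
                                 f(theta - ei + ej) + f(theta - ei - ej)) /
        (4 * h2[i] * h2[j])
    }
    out$c2 <- c2
  }
  if (order >= 3L) {
    h3 <- .fd_steps(theta, 1 / 5)
    c3 <- array(0, c(p, p, p))
    for (k in seq_len(p)) {
      e <- replace(numeric(p), k, h3[k])
      c3[, , k] <- (.model_lpn_derivs(model, theta + e, c, 2L)$c2 -
                      .model_lpn_derivs(model, theta - e, c, 2L)$c2) / (2 * h3[k])
    }
    out$c3 <- c3
  }
  out
}

#' Log-density derivatives of a parametric model
#'
#' Partial derivatives of \eqn{\log f_\theta(x)} with respect to the
#' parameters, up to third order, for a single observation.
#'
#' @param model a [parametric_model()].
#' @param x a scalar observation inside the support.
#' @param theta parameter vector inside the domain.
#' @param order 1, 2 or 3.
#' @return A list with `l1` (length p), `l2` (p x p) and, if requested,
#'   `l3` (p x p x p); symmetric in exchangeable indices.
#' @export
log_density_derivatives <- function(model, x, theta, order = 3L) {
  stopifnot(length(x) == 1L, order %in% 1:3)
  .check_theta(model, theta)
  if (x < model$support[1] || x > model$support[2])
    stop("x is outside the support of the model")
  d <- .model_logpdf_derivs(model, x, theta, order)
  out <- list(l1 = drop(d$l1))
  if (order >= 2L) out$l2 <- array(d$l2, dim(d$l2)[-1])
  if (order >= 3L) out$l3 <- array(d$l3, dim(d$l3)[-1])
  out
}
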