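#' Epsilon-contamination specification
#'
#' Describes the data-generating mixture
#' \eqn{g(x) = (1-\varepsilon) f_{\theta}(x) + \varepsilon\,\delta(x)} with
#' contamination ratio \eqn{\varepsilon} and contaminant density
#' \eqn{\delta}. The default contaminant is \eqn{N(\nu, 1)}.
#'
#' @param epsilon contamination ratio in `[0, 1)`.
#' @param nu location of the default normal contaminant.
#' @param core_model a [parametric_model()] for the clean component.
#' @param core_theta parameter of the clean component.
#' @param delta optional contaminant density function (vectorized); defaults
#'   to `dnorm(x, nu, 1)`.
#' @param rdelta optional contaminant sampler `(n)`; defaults to
#'   `rnorm(n, nu, 1)`.
#' @param delta_support interval carrying essentially all contaminant mass,
#'   used to bound quadrature; defaults to `nu + c(-12, 12)` for the normal
#'   contaminant.
#' @return An object of class `contamination_spec`.
#' @examples
#' spec <- contamination_spec(epsilon = 0.2, nu = 6)
#' x <- sample_contaminated(spec, 100, seed = 1)
#' @export
contamination_spec <- function(epsilon, nu = 6,
                               core_model = normal_model(),
                               core_theta = c(0, 1),
                               delta = NULL, rdelta = NULL,
                               delta_support = NULL) {
  if (!is.numeric(epsilon) || epsilon < 0 || epsilon >= 1)
    stop("epsilon must lie in [0, 1)")
  .check_theta(core_model, core_theta)
  if (is.null(delta)) {
    force(nu)
    delta <- function(x) stats::dnorm(x, nu, 1)
    rdelta <- function(n) stats::rnorm(n, nu, 1)
    if (is.null(delta_support)) delta_support <- nu + c(-12, 12)
  }
  if (is.null(delta_support)) delta_support <- c(-Inf, Inf)
  structure(list(epsilon = epsilon, nu = nu, core_model = core_model,
                 core_theta = core_theta, delta = delta, rdelta = rdelta,
                 delta_support = delta_support),
            class = "contamination_spec")
}

#' @export
print.contamination_spec <- function(x, ...) {
  cat(sprintf("<contamination_spec> (1 - %.3g) * %s(%s) + %.3g * delta (nu = %g)\n",
              x$epsilon, x$core_model$name,
              paste(signif(x$core_theta, 4), collapse = ", "),
              x$epsilon, x$nu))
  invisible(x)
}

#' Mixture density of a contamination specification
#' @param spec a [contamination_spec()].
#' @param x evaluation points.
#' @return Density values of the mixture.
#' @export
dcontam <- function(spec, x) {
  (1 - spec$epsilon) * exp(spec$core_model$logpdf(x, spec$core_theta)) +
    spec$epsilon * spec$delta(x)
}

#' Sample from an epsilon-contaminated mixture
#'
#' Draws `n` iid observations; each observation independently comes from the
#' contaminant with probability `epsilon` (a Bernoulli mixture, not fixed
#' counts).
#'
#' @param spec a [contamination_spec()].
#' @param n sample size.
#' @param seed optional integer seed for reproducibility.
#' @return Numeric vector of length `n`.
#' @export
sample_contaminated <- function(spec, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- spec$core_model$rdist(n, spec$core_theta)
  if (spec$epsilon > 0) {
    idx <- stats::runif(n) < spec$epsilon
    if (any(idx)) out[idx] <- spec$rdelta(sum(idx))
  }
  out
}

#' Tail condition on the contaminant
#'
#' The quantity \eqn{\nu_f = \{\int \delta(x) f(x)^{\gamma_0} dx\}^{1/\gamma_0}},
#' which is close to zero exactly when the contaminant mass lies in the tail
#' of `f`. It underpins the approximate contamination-invariance of the
#' gamma-loss sandwich matrices and of the robust objective priors.
#'
#' @param delta contaminant density function (vectorized).
#' @param f reference density function (vectorized).
#' @param gamma0 positive exponent.
#' @param lower,upper quadrature bounds (defaults cover the real line).
#' @return Scalar value of the tail condition.
#' @examples
#' nu_condition(function(x) dnorm(x), function(x) dnorm(x), 1)  # 1/(2*sqrt(pi))
#' @export
nu_condition <- function(delta, f, gamma0, lower = -Inf, upper = Inf) {
  stopifnot(gamma0 > 0)
  r <- tryCatch(
    stats::integrate(function(x) delta(x) * f(x)^gamma0, lower, upper,
                     rel.tol = 1e-11, abs.tol = 0),
    error = function(e) stop("quadrature for the tail condition failed: ",
                             conditionMessage(e), call. = FALSE))
  r$value^(1 / gamma0)
}

# expectation of a vectorized scalar function under a weight density by
# adaptive quadrature on a (possibly infinite) interval
.quad_expect <- function(h, dens, lower, upper) {
  stats::integrate(function(x) h(x) * dens(x), lower, upper,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Sandwich matrices of a per-observation loss
#'
#' Computes, by deterministic quadrature, the matrices
#' \eqn{I(\theta) = E_g[\partial q\, \partial^\top q]},
#' \eqn{J(\theta) = -E_g[\partial\partial^\top q]}, the clean-data version
#' \eqn{H(\theta) = -E_{f_\theta}[\partial\partial^\top q]}, and the
#' third-derivative tensors \eqn{g_{ijk} = E_g[\partial_i\partial_j\partial_k q]}
#' and its clean counterpart. Expectations under a contaminated `g` are
#' evaluated as \eqn{(1-\varepsilon) E_{f_{core}} + \varepsilon E_\delta} with
#' separate quadrature per mixture component, so far-out contaminant
#' locations cannot be missed.
#'
#' @param model a [parametric_model()].
#' @param loss a [loss_spec()].
#' @param theta parameter at which the loss derivatives are evaluated.
#' @param g either `"clean"` (expectations under \eqn{f_\theta}) or a
#'   [contamination_spec()].
#' @return An object of class `sandwich_matrices` with fields `I`, `J`, `H`,
#'   `g_ijk`, `g_tilde_ijk`, `theta`.
#' @export
sandwich_matrices <- function(model, loss, theta, g = "clean") {
  .check_theta(model, theta)
  p <- model$p
  lo <- model$support[1]; hi <- model$support[2]
  clean_dens <- function(x) exp(model$logpdf(x, theta))

  comp <- function(extract, dens, lwr = lo, upr = hi) {
    .quad_expect(function(x) extract(.q_derivs(model, x, theta, loss, 3L)),
                 dens, lwr, upr)
  }
  expect_all <- function(dens, lwr = lo, upr = hi) {
    I <- matrix(0, p, p); J <- matrix(0, p, p); G <- array(0, c(p, p, p))
    for (i in seq_len(p)) for (j in i:p) {
      I[i, j] <- I[j, i] <- comp(function(d) d$d1[, i] * d$d1[, j], dens, lwr, upr)
      J[i, j] <- J[j, i] <- -comp(function(d) d$d2[, i, j], dens, lwr, upr)
    }
    for (i in seq_len(p)) for (j in i:p) for (k in j:p) {
      v <- comp(function(d) d$d3[, i, j, k], dens, lwr, upr)
      for (pr in list(c(i,j,k), c(i,k,j), c(j,i,k), c(j,k,i), c(k,i,j), c(k,j,i)))
        G[pr[1], pr[2], pr[3]] <- v
    }
    list(I = I, J = J, G = G)
  }

  cl <- expect_all(clean_dens)
  H <- cl$J
  g_tilde <- cl$G
  if (identical(g, "clean")) {
    I <- cl$I; J <- cl$J; G <- cl$G
  } else {
    if (!inherits(g, "contamination_spec"))
      stop("g must be \"clean\" or a contamination_spec")
    eps <- g$epsilon
    core_dens <- function(x) exp(g$core_model$logpdf(x, g$core_theta))
    core <- expect_all(core_dens)
    del <- expect_all(g$delta, g$delta_support[1], g$delta_support[2])
    I <- (1 - eps) * core$I + eps * del$I
    J <- (1 - eps) * core$J + eps * del$J
    G <- (1 - eps) * core$G + eps * del$G
  }
  dimnames(I) <- dimnames(J) <- dimnames(H) <-
    list(model$param_names, model$param_names)
  ev <- eigen(J, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    warning("J is not positive definite at theta = (",
            paste(signif(theta, 6), collapse = ", "), ")")
  structure(list(I = I, J = J, H = H, g_ijk = G, g_tilde_ijk = g_tilde,
                 theta = theta, loss = loss),
            class = "sandwich_matrices")
}

#' Asymptotic covariance of a minimum cross-entropy estimator
#'
#' The sandwich covariance \eqn{V(\theta) = J^{-1} I J^{-1}} under the clean
#' model \eqn{g = f_\theta}. For the KL loss this is the inverse Fisher
#' information.
#'
#' @inheritParams sandwich_matrices
#' @return A p x p covariance matrix.
#' @export
asymptotic_covariance <- function(model, loss, theta) {
  s <- sandwich_matrices(model, loss, theta, g = "clean")
  Jinv <- tryCatch(solve(s$J),
                   error = function(e) stop("J is singular at theta", call. = FALSE))
  V <- Jinv %*% s$I %*% Jinv
  dimnames(V) <- list(model$param_names, model$param_names)
  V
}

#' Asymptotic relative efficiency for joint normal location-scale estimation
#'
#' Efficiency of the gamma-posterior mean relative to the standard posterior
#' mean for joint \eqn{(\mu, \sigma)} estimation, as a function of the
#' robustness tuning \eqn{\gamma}. Two routes are provided:
#'
#' * `"closed_form"` (default) evaluates the curve
#'   \deqn{h(\gamma) = \left\{\frac{2}{(1+\gamma)^6 (1+2\gamma)
#'   (2+4\gamma+3\gamma^2)}\right\}^{1/2},}
#'   the tabulated tuning-selection curve for this family in the
#'   robust-divergence literature. It satisfies \eqn{h(\gamma)\to 1} as
#'   \eqn{\gamma\to 0} and decreases strictly in \eqn{\gamma}.
#' * `"sandwich"` recomputes the determinant-ratio efficiency
#'   \eqn{\{\det V / \det V^{(\gamma)}\}^{1/p}} (p = 2) from first
#'   principles, with \eqn{V = J^{-1} I J^{-1}} obtained by quadrature for
#'   the KL and gamma losses at \eqn{(\mu,\sigma)=(0,1)}.
#'
#' The two routes do not coincide for \eqn{\gamma > 0}: the closed-form curve
#' decays much faster than the first-principles determinant ratio (whose
#' efficiency loss is second order at \eqn{\gamma = 0}). See the methods
#' vignette for the derivation and a discussion of the discrepancy.
#'
#' @param gamma nonnegative tuning value.
#' @param method `"closed_form"` or `"sandwich"`.
#' @return An object of class `are_result` with fields `gamma`, `are`, `p`,
#'   `method`, and (for the sandwich route) `V` and `V_gamma`.
#' @examples
#' are_normal(0.3)$are
#' @export
are_normal <- function(gamma, method = c("closed_form", "sandwich")) {
  method <- match.arg(method)
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0)
  V <- V_gamma <- NULL
  if (gamma == 0) {
    are <- 1
  } else if (method == "closed_form") {
    are <- sqrt(2 / ((1 + gamma)^6 * (1 + 2 * gamma) *
                       (2 + 4 * gamma + 3 * gamma^2)))
  } else {
    m <- normal_model()
    V <- asymptotic_covariance(m, kl_loss(), c(0, 1))
    V_gamma <- asymptotic_covariance(m, gamma_loss(gamma), c(0, 1))
    are <- sqrt(det(V) / det(V_gamma))
  }
  structure(list(gamma = gamma, are = are, p = 2L, method = method,
                 V = V, V_gamma = V_gamma),
            class = "are_result")
}

#' @export
print.are_result <- function(x, ...) {
  cat(sprintf("<are_result> gamma = %g: ARE = %.6f (%s, p = %d)\n",
              x$gamma, x$are, x$method, x$p))
  invisible(x)
}

#' Choose the gamma tuning for a target efficiency
#'
#' Solves \eqn{h(\gamma) = } `target_are` by bracketed root finding on the
#' strictly decreasing efficiency curve.
#'
#' @param target_are target efficiency in (0, 1).
#' @param method passed to [are_normal()].
#' @return The tuning value \eqn{\gamma} with `are_normal(gamma)$are`
#'   equal to the target (residual below 1e-10).
#' @export
choose_gamma_for_are <- function(target_are, method = c("closed_form", "sandwich")) {
  method <- match.arg(method)
  if (!is.numeric(target_are) || target_are <= 0 || target_are >= 1)
    stop("target_are must lie strictly between 0 and 1")
  f <- function(g) are_normal(g, method = method)$are - target_are
  upper <- 1
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, c(1e-12, upper), tol = 1e-13)$root
}
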