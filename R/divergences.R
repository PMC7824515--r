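#' Loss specifications for quasi-posteriors
#'
#' A `loss_spec` selects the cross-entropy that defines the quasi-posterior:
#' the ordinary negative log-likelihood (`"KL"`), the density-power
#' cross-entropy with tuning \eqn{\alpha} (`"density_power"`), or the
#' (monotonically transformed) gamma cross-entropy with tuning \eqn{\gamma}
#' (`"gamma"`). Tuning 0 is the Kullback-Leibler limit. The learning rate
#' of the quasi-posterior is fixed at 1.
#'
#' @param kind one of `"KL"`, `"gamma"`, `"density_power"`.
#' @param tuning nonnegative tuning parameter (\eqn{\gamma} or \eqn{\alpha});
#'   must be 0 for `"KL"`.
#' @return An object of class `loss_spec` with fields `kind`, `tuning`,
#'   `omega` (always 1).
#' @examples
#' gamma_loss(0.5)
#' dp_loss(0.3)
#' kl_loss()
#' @export
loss_spec <- function(kind = c("KL", "gamma", "density_power"), tuning = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(tuning) || length(tuning) != 1L || !is.finite(tuning) || tuning < 0)
    stop("tuning must be a finite nonnegative number")
  if (kind == "KL" && tuning != 0)
    stop("the KL loss has no tuning parameter")
  if (tuning == 0) kind <- "KL"  # tuning -> 0 limit is the log-likelihood
  structure(list(kind = kind, tuning = tuning, omega = 1), class = "loss_spec")
}

#' @rdname loss_spec
#' @export
kl_loss <- function() loss_spec("KL", 0)

#' @rdname loss_spec
#' @param gamma positive robustness tuning for the gamma loss.
#' @export
gamma_loss <- function(gamma) loss_spec("gamma", gamma)

#' @rdname loss_spec
#' @param alpha positive robustness tuning for the density-power loss.
#' @export
dp_loss <- function(alpha) loss_spec("density_power", alpha)

#' @export
print.loss_spec <- function(x, ...) {
  cat("<loss_spec>", x$kind,
      if (x$kind != "KL") sprintf("(tuning = %g)", x$tuning), "\n")
  invisible(x)
}

.loss_label <- function(loss) {
  switch(loss$kind,
         KL = "KL",
         gamma = sprintf("gamma(%g)", loss$tuning),
         density_power = sprintf("dp(%g)", loss$tuning))
}

#' Per-observation gamma loss
#'
#' \eqn{q^{(\gamma)}(x; \theta) = \gamma^{-1} f_\theta(x)^\gamma
#' \left(\int f_\theta^{1+\gamma}\right)^{-\gamma/(1+\gamma)}}, the summand of
#' the gamma quasi-posterior exponent. Strictly positive; as
#' \eqn{\gamma \to 0}, \eqn{q^{(\gamma)} - 1/\gamma \to \log f_\theta(x)}.
#'
#' @param model a [parametric_model()].
#' @param x observations (vectorized).
#' @param theta parameter vector.
#' @param gamma positive tuning parameter.
#' @return Numeric vector of per-observation loss values.
#' @export
q_gamma <- function(model, x, theta, gamma) {
  if (!is.numeric(gamma) || gamma <= 0)
    stop("invalid tuning: gamma must be positive (use the KL loss for gamma = 0)")
  .check_theta(model, theta)
  pn <- .model_power_norm(model, theta, gamma)
  exp(gamma * model$logpdf(x, theta)) * pn^(-gamma / (1 + gamma)) / gamma
}

#' Per-observation density-power loss
#'
#' \eqn{q^{(\alpha)}(x; \theta) = \alpha^{-1} f_\theta(x)^\alpha -
#' (1+\alpha)^{-1} \int f_\theta^{1+\alpha}}. As \eqn{\alpha \to 0},
#' \eqn{q^{(\alpha)} - 1/\alpha + 1/(1+\alpha) \to \log f_\theta(x)}.
#'
#' @inheritParams q_gamma
#' @param alpha positive tuning parameter.
#' @return Numeric vector of per-observation loss values.
#' @export
q_alpha <- function(model, x, theta, alpha) {
  if (!is.numeric(alpha) || alpha <= 0)
    stop("invalid tuning: alpha must be positive (use the KL loss for alpha = 0)")
  .check_theta(model, theta)
  pn <- .model_power_norm(model, theta, alpha)
  exp(alpha * model$logpdf(x, theta)) / alpha - pn / (1 + alpha)
}

#' Per-observation loss under any loss specification
#'
#' Dispatches to the log-likelihood, [q_gamma()] or [q_alpha()]. The
#' quasi-posterior is proportional to \eqn{\exp\{\sum_i q(X_i;\theta)\}\pi(\theta)}.
#'
#' @inheritParams q_gamma
#' @param loss a [loss_spec()].
#' @return Numeric vector of per-observation loss values.
#' @export
q_loss <- function(model, x, theta, loss) {
  switch(loss$kind,
         KL = { .check_theta(model, theta); model$logpdf(x, theta) },
         gamma = q_gamma(model, x, theta, loss$tuning),
         density_power = q_alpha(model, x, theta, loss$tuning))
}

#' Empirically estimated cross-entropy
#'
#' The plug-in cross-entropy \eqn{d(\bar g, f_\theta)} between the empirical
#' distribution of `data` and the model:
#' \itemize{
#'   \item KL: \eqn{-n^{-1}\sum_i \log f_\theta(X_i)};
#'   \item gamma: \eqn{\tilde d_\gamma(\bar g, f_\theta) =
#'     -\gamma^{-1}\{n^{-1}\sum_i f_\theta(X_i)^\gamma\}
#'     (\int f_\theta^{1+\gamma})^{-\gamma/(1+\gamma)} + \gamma^{-1}}, the
#'     monotone transform of the gamma cross-entropy;
#'   \item density power: \eqn{-\alpha^{-1} n^{-1}\sum_i f_\theta(X_i)^\alpha +
#'     (1+\alpha)^{-1}\log\int f_\theta^{1+\alpha}}.
#' }
#' All theta-free constants are kept, so the identity
#' \eqn{-n\,\tilde d_\gamma(\bar g,f_\theta) = \sum_i q^{(\gamma)}(X_i;\theta) - n/\gamma}
#' holds exactly.
#'
#' @param data nonempty numeric sample.
#' @param model a [parametric_model()].
#' @param theta parameter vector in the domain.
#' @param loss a [loss_spec()].
#' @return Scalar cross-entropy value.
#' @export
empirical_cross_entropy <- function(data, model, theta, loss) {
  if (length(data) == 0L) stop("data must be nonempty")
  .check_theta(model, theta)
  lp <- model$logpdf(data, theta)
  switch(loss$kind,
         KL = -mean(lp),
         gamma = {
           g <- loss$tuning
           pn <- .model_power_norm(model, theta, g)
           -mean(exp(g * lp)) * pn^(-g / (1 + g)) / g + 1 / g
         },
         density_power = {
           a <- loss$tuning
           pn <- .model_power_norm(model, theta, a)
           -mean(exp(a * lp)) / a + log(pn) / (1 + a)
         })
}

#' Gamma divergence between a density and a model member
#'
#' \eqn{D_\gamma(g, f_\theta) = \frac{1}{\gamma(\gamma+1)}\log\int g^{1+\gamma}
#' - \frac{1}{\gamma}\log\int g f_\theta^\gamma
#' + \frac{1}{1+\gamma}\log\int f_\theta^{1+\gamma}},
#' computed by adaptive quadrature. Nonnegative, and zero iff \eqn{g = f_\theta}
#' almost everywhere.
#'
#' @param g a vectorized density function on the model support.
#' @param model a [parametric_model()].
#' @param theta parameter vector.
#' @param gamma positive tuning parameter.
#' @return Scalar divergence value.
#' @export
gamma_divergence <- function(g, model, theta, gamma) {
  stopifnot(is.function(g), gamma > 0)
  .check_theta(model, theta)
  lo <- model$support[1]; hi <- model$support[2]
  quad <- function(f) {
    r <- tryCatch(stats::integrate(f, lo, hi, rel.tol = 1e-11, abs.tol = 1e-12),
                  error = function(e) stop("quadrature failed: ",
                                           conditionMessage(e), call. = FALSE))
    r$value
  }
  t1 <- quad(function(x) g(x)^(1 + gamma))
  t2 <- quad(function(x) g(x) * exp(gamma * model$logpdf(x, theta)))
  t3 <- .model_power_norm(model, theta, gamma)
  log(t1) / (gamma * (gamma + 1)) - log(t2) / gamma + log(t3) / (1 + gamma)
}
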