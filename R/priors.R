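#' Prior specifications
#'
#' A `prior_spec` wraps a possibly unnormalized log-prior density. Improper
#' priors are allowed throughout; the posterior machinery never needs the
#' prior's normalizing constant.
#'
#' @param kind one of `"uniform"`, `"reference"`, `"moment_matching"`,
#'   `"custom"`.
#' @param log_prior function `(theta)` returning the unnormalized log prior;
#'   ignored for `"uniform"`.
#' @param sigma_exponent optional exponent `e` when the prior has the
#'   power-law form \eqn{\pi(\mu, \sigma) \propto \sigma^e} (flat in the
#'   location); enables fast vectorized evaluation.
#' @param closed_form logical, whether the prior is an exact closed form.
#' @param cm the density-power moment-matching exponent constant, if relevant.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(kind = c("uniform", "reference", "moment_matching", "custom"),
                       log_prior = NULL, sigma_exponent = NULL,
                       closed_form = FALSE, cm = NULL) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    log_prior <- function(theta) 0
    sigma_exponent <- 0
    closed_form <- TRUE
  }
  if (is.null(log_prior) && !is.null(sigma_exponent)) {
    e <- sigma_exponent
    log_prior <- function(theta) e * log(theta[2])
  }
  if (is.null(log_prior)) stop("log_prior must be supplied")
  structure(list(kind = kind, log_prior = log_prior,
                 sigma_exponent = sigma_exponent, closed_form = closed_form,
                 cm = cm),
            class = "prior_spec")
}

#' @rdname prior_spec
#' @export
uniform_prior <- function() prior_spec("uniform")

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec>", x$kind)
  if (!is.null(x$sigma_exponent))
    cat(sprintf(": pi(mu, sigma) ~ sigma^%.6g", x$sigma_exponent))
  cat("\n")
  invisible(x)
}

#' Reference log-prior for a quasi-posterior
#'
#' The (unnormalized) reference prior for a loss-based quasi-posterior is
#' \eqn{\pi_R(\theta) \propto \det\{J^{(d)}(\theta)\}^{1/2}}. Under
#' contamination the population \eqn{J^{(d)}} depends on the unknown mixture;
#' for the gamma loss, however, \eqn{J^{(\gamma)} = (1-\varepsilon)
#' H^{(\gamma)} + O(\varepsilon\nu^\gamma)} with
#' \eqn{H^{(\gamma)}(\theta) = -E_{f_\theta}[\partial\partial^\top q^{(\gamma)}]},
#' so the clean-data evaluation is the robust choice and is what this
#' function returns: \eqn{\frac{1}{2}\log\det H(\theta)} (the constant
#' \eqn{(1-\varepsilon)^{p/2}} is absorbed by normalization).
#'
#' @param model a [parametric_model()].
#' @param loss a [loss_spec()].
#' @param theta parameter vector.
#' @return Scalar unnormalized log prior value.
#' @export
reference_log_prior <- function(model, loss, theta) {
  s <- sandwich_matrices(model, loss, theta, g = "clean")
  ch <- tryCatch(chol(s$H), error = function(e)
    stop("H is not positive definite at theta = (",
         paste(signif(theta, 6), collapse = ", "), ")", call. = FALSE))
  sum(log(diag(ch)))
}

# u_l(theta) = sum_ij g~_ijl(theta) h^{ij}(theta): the moment-matching
# drift whose antiderivative defines log pi_M (all clean-model quantities)
.mm_drift <- function(model, loss, theta) {
  s <- sandwich_matrices(model, loss, theta, g = "clean")
  Hinv <- solve(s$H)
  vapply(seq_len(model$p), function(l)
    sum(s$g_tilde_ijk[, , l] * Hinv), numeric(1))
}

#' Moment-matching log-prior on a grid (one-parameter models)
#'
#' For a one-dimensional parameter the moment-matching prior is
#' \eqn{\pi_M(\theta) \propto \exp\{-\int^\theta g_3(t) / (2 J(t))\, dt\}},
#' where \eqn{g_3} and \eqn{J} are the clean-model third-derivative moment
#' and negative-Hessian moment of the per-observation loss. The
#' antiderivative is evaluated by adaptive quadrature anchored at the grid
#' midpoint (the additive constant is irrelevant).
#'
#' @param model a one-parameter [parametric_model()].
#' @param loss a [loss_spec()].
#' @param theta_grid increasing grid of parameter values in the domain.
#' @return Numeric vector of log-prior values on the grid.
#' @export
moment_matching_log_prior_1d <- function(model, loss, theta_grid) {
  if (model$p != 1L) stop("moment_matching_log_prior_1d requires p = 1")
  r <- function(t) {
    s <- sandwich_matrices(model, loss, t, g = "clean")
    if (s$H[1, 1] <= 0) stop("J is nonpositive at theta = ", signif(t, 6))
    s$g_tilde_ijk[1, 1, 1] / (2 * s$H[1, 1])
  }
  rv <- Vectorize(r)
  anchor <- theta_grid[ceiling(length(theta_grid) / 2)]
  vapply(theta_grid, function(t) {
    if (t == anchor) return(0)
    -stats::integrate(rv, anchor, t, rel.tol = 1e-9)$value
  }, numeric(1))
}

#' Moment-matching log-prior for separable two-parameter models
#'
#' When \eqn{u_\ell(\theta) = \sum_{ij} \tilde g_{ij\ell}(\theta)
#' h^{ij}(\theta)} depends only on \eqn{\theta_\ell} for each \eqn{\ell}, the
#' moment-matching equation decouples and
#' \eqn{\pi_M(\theta_1,\theta_2) \propto \prod_\ell \exp\{-\frac{1}{2}
#' \int^{\theta_\ell} u_\ell\}}. Separability is verified numerically on a
#' probe grid before integrating; when it fails, the function stops and a
#' custom prior must be supplied.
#'
#' @param model a two-parameter [parametric_model()].
#' @param loss a [loss_spec()].
#' @param theta parameter vector at which to evaluate the log prior.
#' @param check_separability verify the decoupling on a probe grid.
#' @return Scalar unnormalized log prior value (anchored at the model's
#'   default parameter).
#' @export
moment_matching_log_prior_separable <- function(model, loss, theta,
                                                check_separability = TRUE) {
  if (model$p != 2L) stop("requires a two-parameter model")
  .check_theta(model, theta)
  anchor <- model$default_theta
  if (check_separability) .check_mm_separable(model, loss, theta, anchor)
  u_of <- function(l) function(t) {
    th <- anchor; th[l] <- t
    .mm_drift(model, loss, th)[l]
  }
  val <- 0
  for (l in 1:2) {
    if (theta[l] != anchor[l]) {
      ul <- Vectorize(u_of(l))
      val <- val - 0.5 * stats::integrate(ul, anchor[l], theta[l],
                                          rel.tol = 1e-9)$value
    }
  }
  val
}

.check_mm_separable <- function(model, loss, theta, anchor, tol = 1e-6) {
  # probe: u_l must not move when the *other* coordinate changes
  probes <- list(theta,
                 replace(theta, 1, anchor[1] + 0.7 * (theta[1] - anchor[1]) + 0.3),
                 replace(theta, 2, anchor[2] * 1.5 + 0.1))
  u <- lapply(probes, function(th) .mm_drift(model, loss, th))
  scale1 <- max(abs(u[[1]][1]), 1)
  scale2 <- max(abs(u[[1]][2]), 1)
  ok <- abs(u[[1]][1] - u[[3]][1]) / scale1 < tol &&
    abs(u[[1]][2] - u[[2]][2]) / scale2 < tol
  if (!ok)
    stop("the moment-matching equation does not separate for this model/loss; ",
         "supply a custom prior", call. = FALSE)
  invisible(TRUE)
}

# cache for the numerically solved density-power moment-matching constant
.cm_cache <- new.env(parent = emptyenv())

#' Density-power moment-matching exponent constant
#'
#' For the normal model under the density-power loss, the (formal,
#' contamination-free) moment-matching prior is a power law
#' \eqn{\pi_M(\mu,\sigma) \propto \sigma^{C_M/2}}. The constant is obtained
#' by solving the moment-matching equation numerically at the given
#' \eqn{\alpha} — the defining equation, not a transcribed expression — and
#' cached. As \eqn{\alpha \to 0}, \eqn{C_M \to -7} (the KL-limit exponent
#' \eqn{-7/2} doubled).
#'
#' @param alpha positive density-power tuning.
#' @return The scalar constant \eqn{C_M}.
#' @export
dp_mm_constant <- function(alpha) {
  stopifnot(alpha > 0)
  key <- sprintf("%.12g", alpha)
  if (!is.null(.cm_cache[[key]])) return(.cm_cache[[key]])
  m <- normal_model()
  # pi ~ sigma^(CM/2) solves d(log pi)/d(sigma) = -u_sigma/2, so
  # CM = -sigma * u_sigma(sigma); u_sigma ~ 1/sigma makes this sigma-free
  u1 <- .mm_drift(m, dp_loss(alpha), c(0, 1))[2]
  u2 <- .mm_drift(m, dp_loss(alpha), c(0.3, 2))[2]
  if (abs(1 * u1 - 2 * u2) > 1e-6 * max(1, abs(u1)))
    stop("moment-matching drift is not a power law in sigma")
  cm <- -u1
  .cm_cache[[key]] <- cm
  cm
}

#' Closed-form objective priors for the normal model
#'
#' Reference and moment-matching priors for the normal \eqn{(\mu, \sigma)}
#' model are power laws in \eqn{\sigma} (flat in \eqn{\mu}):
#' \deqn{\pi_R^{(\gamma)} \propto \sigma^{-3 + 1/(1+\gamma)}, \qquad
#'       \pi_M^{(\gamma)} \propto \sigma^{-(\gamma+7)/\{2(1+\gamma)\}}}
#' for the gamma loss — these are the contamination-robust forms — and,
#' formally (setting the contamination ratio to zero),
#' \deqn{\pi_R^{(\alpha)} \propto \sigma^{-2-\alpha}, \qquad
#'       \pi_M^{(\alpha)} \propto \sigma^{C_M/2}}
#' for the density-power loss, with \eqn{C_M} from [dp_mm_constant()]. The
#' KL loss takes the \eqn{\gamma \to 0} limits \eqn{\sigma^{-2}} (Jeffreys
#' form) and \eqn{\sigma^{-7/2}}.
#'
#' @param kind `"uniform"`, `"reference"` or `"moment_matching"`.
#' @param loss a [loss_spec()].
#' @return A [prior_spec()] with the appropriate `sigma_exponent`.
#' @examples
#' normal_closed_form_prior("reference", gamma_loss(0.5))  # sigma^(-7/3)
#' @export
normal_closed_form_prior <- function(kind = c("uniform", "reference",
                                              "moment_matching"),
                                     loss = kl_loss()) {
  kind <- match.arg(kind)
  if (kind == "uniform") return(uniform_prior())
  cm <- NULL
  e <- switch(loss$kind,
    KL = if (kind == "reference") -2 else -3.5,
    gamma = {
      g <- loss$tuning
      if (kind == "reference") -3 + 1 / (1 + g) else -(g + 7) / (2 * (1 + g))
    },
    density_power = {
      a <- loss$tuning
      if (kind == "reference") -2 - a else {
        cm <- dp_mm_constant(a)
        cm / 2
      }
    },
    stop("unsupported loss kind"))
  prior_spec(kind, sigma_exponent = e, closed_form = TRUE, cm = cm)
}
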