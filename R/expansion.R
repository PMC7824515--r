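#' First-order posterior-expansion terms
#'
#' Components of the first-order Edgeworth-type correction to the
#' quasi-posterior of the normalized coordinate
#' \eqn{t_n = \sqrt n(\theta - \hat\theta_n^{(d)})}:
#' \deqn{A_1(t) = \sum_i \frac{\partial_i \pi(\hat\theta)}{\pi(\hat\theta)} t_i
#'  + \frac{1}{6}\sum_{i,j,k} \bar D_{ijk}(\hat\theta)\, t_i t_j t_k,}
#' where \eqn{\bar D_{ijk}} is the empirical mean of
#' \eqn{\partial_i\partial_j\partial_k q^{(d)}(X_i; \cdot)} at
#' \eqn{\hat\theta} and \eqn{\tilde J} the empirical negative-Hessian moment.
#' \eqn{A_1} is an odd polynomial in `t` with \eqn{A_1(0) = 0}.
#'
#' @param data numeric sample.
#' @param model a [parametric_model()].
#' @param loss a [loss_spec()].
#' @param prior a [prior_spec()].
#' @return An object of class `expansion_terms` with fields `theta_hat`,
#'   `Dbar_ijk`, `J_tilde`, `J_tilde_inv`, `prior_grad` and the function
#'   `A1(t)`.
#' @export
expansion_terms <- function(data, model, loss, prior = uniform_prior()) {
  est <- minimize_cross_entropy(data, model, loss)
  if (!est$converged)
    warning("minimum cross-entropy estimate did not fully converge")
  th <- est$theta_hat
  p <- model$p
  qd <- .q_derivs(model, data, th, loss, 3L)
  Dbar <- apply(qd$d3, c(2, 3, 4), mean)
  J_tilde <- -apply(qd$d2, c(2, 3), mean)
  J_inv <- solve(J_tilde)
  pg <- .num_gradient(prior$log_prior, th)
  A1 <- function(t) {
    t <- as.numeric(t)
    cub <- 0
    for (i in seq_len(p)) for (j in seq_len(p)) for (k in seq_len(p))
      cub <- cub + Dbar[i, j, k] * t[i] * t[j] * t[k]
    sum(pg * t) + cub / 6
  }
  structure(list(theta_hat = th, Dbar_ijk = Dbar, J_tilde = J_tilde,
                 J_tilde_inv = J_inv, prior_grad = pg, A1 = A1,
                 estimator = est),
            class = "expansion_terms")
}

#' First-order difference between posterior mean and point estimate
#'
#' The limit of \eqn{n(\tilde\theta_n^{(d)} - \hat\theta_n^{(d)})}: with
#' \eqn{J^{-1} = (J^{ij})} and \eqn{g_{ijk} = E[\partial_i\partial_j\partial_k
#' q^{(d)}]},
#' \deqn{b_\ell = \sum_i \frac{\partial_i\pi}{\pi} J^{i\ell} + \frac{1}{6}
#' \sum_{i,j,k} g_{ijk}\,(J^{ij}J^{k\ell} + J^{ik}J^{j\ell} + J^{i\ell}J^{jk}),}
#' evaluated at the minimum cross-entropy estimate with the clean-model
#' matrices (\eqn{J = H}, \eqn{g = \tilde g}). A prior solving the
#' moment-matching equation makes this vector vanish, so the quasi-posterior
#' mean and the frequentist minimum-divergence estimator then agree to
#' \eqn{o(n^{-1})}.
#'
#' For the KL loss on the normal model with a flat prior the vector is
#' \eqn{(0, 7\hat\sigma/4)}, a useful analytic anchor.
#'
#' @inheritParams expansion_terms
#' @param theta_hat optional known estimate; computed when missing.
#' @return Numeric p-vector.
#' @export
first_order_mean_shift <- function(data, model, loss, prior = uniform_prior(),
                                   theta_hat = NULL) {
  if (is.null(theta_hat))
    theta_hat <- minimize_cross_entropy(data, model, loss)$theta_hat
  s <- sandwich_matrices(model, loss, theta_hat, g = "clean")
  Jinv <- tryCatch(solve(s$H),
                   error = function(e) stop("J is singular at theta_hat",
                                            call. = FALSE))
  p <- model$p
  pg <- .num_gradient(prior$log_prior, theta_hat)
  G <- s$g_tilde_ijk
  b <- numeric(p)
  for (l in seq_len(p)) {
    cub <- 0
    for (i in seq_len(p)) for (j in seq_len(p)) for (k in seq_len(p))
      cub <- cub + G[i, j, k] * (Jinv[i, j] * Jinv[k, l] +
                                   Jinv[i, k] * Jinv[j, l] +
                                   Jinv[i, l] * Jinv[j, k])
    b[l] <- sum(pg * Jinv[, l]) + cub / 6
  }
  names(b) <- model$param_names
  b
}
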