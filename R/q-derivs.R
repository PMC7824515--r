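# Parameter derivatives of the per-observation loss q^(d)(x; theta), up to
# third order, vectorized over x. These feed the sandwich matrices, the
# objective priors and the posterior-expansion terms.
#
# gamma loss:  q = (1/g) exp(g*l + c),  c(theta) = -(g/(1+g)) log PN(theta, g)
#   with a_i = g*l_i + c_i:
#   d_i q      = q * a_i
#   d_ij q     = q * (a_i a_j + g*l_ij + c_ij)
#   d_ijk q    = q * (a_i a_j a_k + a_i b_jk + a_j b_ik + a_k b_ij
#                     + g*l_ijk + c_ijk),   b_ij = g*l_ij + c_ij
# density-power loss:  q = (1/a) exp(a*l) - PN/(1+a)
#   d_i q      = exp(a*l) l_i - PN_i/(1+a),  etc.
# KL loss: q = l, so the derivatives are the log-density derivatives.
.q_derivs <- function(model, x, theta, loss, order = 3L) {
  n <- length(x)
  p <- model$p
  ld <- .model_logpdf_derivs(model, x, theta, order)
  lp <- model$logpdf(x, theta)
  if (loss$kind == "KL") {
    out <- list(q = lp, d1 = ld$l1)
    if (order >= 2L) out$d2 <- ld$l2
    if (order >= 3L) out$d3 <- ld$l3
    return(out)
  }
  tu <- loss$tuning
  lpn <- log(.model_power_norm(model, theta, tu))
  lpd <- .model_lpn_derivs(model, theta, tu, order)

  if (loss$kind == "gamma") {
    kap <- -tu / (1 + tu)
    cc <- kap * lpn
    c1 <- kap * lpd$c1
    q <- exp(tu * lp + cc) / tu
    a1 <- tu * ld$l1 + matrix(c1, n, p, byrow = TRUE)       # n x p
    d1 <- q * a1
    out <- list(q = q, d1 = d1)
    if (order >= 2L) {
      c2 <- kap * lpd$c2
      b2 <- tu * ld$l2 + aperm(array(c2, c(p, p, n)), c(3, 1, 2))
      d2 <- array(0, c(n, p, p))
      for (i in seq_len(p)) for (j in seq_len(p))
        d2[, i, j] <- q * (a1[, i] * a1[, j] + b2[, i, j])
      out$d2 <- d2
      if (order >= 3L) {
        c3 <- kap * lpd$c3
        d3 <- array(0, c(n, p, p, p))
        for (i in seq_len(p)) for (j in seq_len(p)) for (k in seq_len(p))
          d3[, i, j, k] <- q * (a1[, i] * a1[, j] * a1[, k] +
                                  a1[, i] * b2[, j, k] +
                                  a1[, j] * b2[, i, k] +
                                  a1[, k] * b2[, i, j] +
                                  tu * ld$l3[, i, j, k] + c3[i, j, k])
        out$d3 <- d3
      }
    }
    return(out)
  }

  # density-power loss
  a <- tu
  pn <- exp(lpn)
  fa <- exp(a * lp)
  pn1 <- pn * lpd$c1                                         # PN_i
  q <- fa / a - pn / (1 + a)
  d1 <- fa * ld$l1 - matrix(pn1 / (1 + a), n, p, byrow = TRUE)
  out <- list(q = q, d1 = d1)
  if (order >= 2L) {
    pn2 <- pn * (outer(lpd$c1, lpd$c1) + lpd$c2)             # PN_ij
    d2 <- array(0, c(n, p, p))
    for (i in seq_len(p)) for (j in seq_len(p))
      d2[, i, j] <- fa * (a * ld$l1[, i] * ld$l1[, j] + ld$l2[, i, j]) -
        pn2[i, j] / (1 + a)
    out$d2 <- d2
    if (order >= 3L) {
      pn3 <- array(0, c(p, p, p))
      for (i in seq_len(p)) for (j in seq_len(p)) for (k in seq_len(p))
        pn3[i, j, k] <- pn * (lpd$c1[i] * lpd$c1[j] * lpd$c1[k] +
                                lpd$c1[i] * lpd$c2[j, k] +
                                lpd$c1[j] * lpd$c2[i, k] +
                                lpd$c1[k] * lpd$c2[i, j] +
                                lpd$c3[i, j, k])
      d3 <- array(0, c(n, p, p, p))
      for (i in seq_len(p)) for (j in seq_len(p)) for (k in seq_len(p))
        d3[, i, j, k] <- fa * (a^2 * ld$l1[, i] * ld$l1[, j] * ld$l1[, k] +
                                 a * (ld$l2[, i, j] * ld$l1[, k] +
                                        ld$l2[, i, k] * ld$l1[, j] +
                                        ld$l2[, j, k] * ld$l1[, i]) +
                                 ld$l3[, i, j, k]) - pn3[i, j, k] / (1 + a)
      out$d3 <- d3
    }
  }
  out
}
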