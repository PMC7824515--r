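#' Simulation harness configuration
#'
#' Defines a grid of contamination settings, sample sizes, losses and priors
#' for the bias/MSE simulation study under
#' \eqn{g(x) = (1-\varepsilon)N(0,1) + \varepsilon N(\nu,1)}. The true
#' values are \eqn{(\mu, \sigma) = (0, 1)}. Within each replicate every
#' (loss, prior) cell is evaluated on the same dataset (common random
#' numbers, a paired design); all seeds are derived deterministically from
#' `base_seed` and the cell/replicate indices, so results do not depend on
#' evaluation order or worker count.
#'
#' @param epsilon vector of contamination ratios in `[0, 1)`.
#' @param nu contaminant location(s).
#' @param n vector of sample sizes.
#' @param losses list of [loss_spec()] objects.
#' @param priors character vector of prior kinds
#'   (`"uniform"`, `"reference"`, `"moment_matching"`).
#' @param reps number of Monte-Carlo replicates.
#' @param is_draws importance-sampling draws per posterior mean.
#' @param base_seed integer master seed.
#' @param workers reserved for compatibility; results are worker-invariant.
#' @param pair_cells when `TRUE`, `losses` and `priors` (recycled to a common
#'   length) are paired elementwise instead of fully crossed, so a subset of
#'   a table's cells can be run without computing the rest.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(epsilon = c(0, 0.05, 0.2), nu = 6,
                              n = c(20, 50, 100),
                              losses = list(kl_loss(), gamma_loss(0.5)),
                              priors = c("uniform", "reference"),
                              reps = 10000L, is_draws = 10000L,
                              base_seed = 1L, workers = 1L,
                              pair_cells = FALSE) {
  stopifnot(all(epsilon >= 0 & epsilon < 1), reps >= 1, is_draws >= 100,
            all(n >= 2))
  if (!all(vapply(losses, inherits, logical(1), "loss_spec")))
    stop("losses must be a list of loss_spec objects")
  priors <- match.arg(priors, c("uniform", "reference", "moment_matching"),
                      several.ok = TRUE)
  structure(list(epsilon = epsilon, nu = nu, n = n, losses = losses,
                 priors = priors, reps = as.integer(reps),
                 is_draws = as.integer(is_draws),
                 base_seed = as.integer(base_seed),
                 workers = as.integer(workers),
                 pair_cells = isTRUE(pair_cells)),
            class = "simulation_config")
}

# deterministic sub-seed in [1, 2^31 - 2]; exact in double arithmetic
.derive_seed <- function(base, ...) {
  ix <- c(base, ...)
  h <- 0
  for (v in ix) h <- (h * 69069 + v * 12345 + 1) %% 2147483629
  as.integer(h + 1)
}

.true_theta <- c(mu = 0, sigma = 1)

# posterior-mean replicates for a fixed (epsilon, nu, n) over all cells
.simulate_point <- function(eps, nu, n, cells, reps, is_draws, base_seed,
                            eps_i, nu_i, n_i) {
  model <- normal_model()
  spec <- contamination_spec(epsilon = eps, nu = nu, core_model = model)
  est <- array(NA_real_, c(reps, length(cells), 2L))
  fails <- integer(length(cells))
  for (r in seq_len(reps)) {
    x <- sample_contaminated(spec, n,
                             seed = .derive_seed(base_seed, 1L, eps_i, nu_i,
                                                 n_i, r))
    for (ci in seq_along(cells)) {
      cell <- cells[[ci]]
      res <- tryCatch({
        qp <- quasi_posterior(x, model, cell$loss, cell$prior)
        cfg <- is_config(n_draws = is_draws,
                         seed = .derive_seed(base_seed, 2L, eps_i, nu_i,
                                             n_i, r, ci))
        suppressWarnings(importance_sampling_mean(qp, cfg))$posterior_mean
      }, error = function(e) NULL)
      if (is.null(res)) fails[ci] <- fails[ci] + 1L else est[r, ci, ] <- res
    }
  }
  list(est = est, fails = fails)
}

#' Run the bias/MSE table experiment
#'
#' For every combination of contamination ratio, sample size, loss and prior
#' in the configuration, simulates `reps` datasets, computes the
#' importance-sampling posterior mean of \eqn{(\mu, \sigma)}, and aggregates
#' the empirical bias and MSE against the true values \eqn{(0, 1)}, with
#' Monte-Carlo standard errors. Replicates failing inside a cell are
#' excluded and counted; a cell with more than 1% failures flags the run.
#'
#' @param cfg a [simulation_config()].
#' @param keep_estimates retain the per-replicate posterior means as the
#'   `"estimates"` attribute (a reps x cells x 2 array per grid point).
#' @return A `simulation_result`: a long-format data frame with columns
#'   `epsilon`, `nu`, `n`, `loss`, `tuning`, `prior`, `parameter`, `bias`,
#'   `mse`, `bias_se`, `mse_se`, `reps`, `failures`, plus attribute
#'   `flagged`.
#' @export
run_table_experiment <- function(cfg, keep_estimates = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (length(cfg$epsilon) == 0L || length(cfg$n) == 0L ||
      length(cfg$losses) == 0L || length(cfg$priors) == 0L)
    stop("empty simulation grid")
  cells <- list()
  if (isTRUE(cfg$pair_cells)) {
    k <- max(length(cfg$losses), length(cfg$priors))
    ls <- rep_len(cfg$losses, k); ps <- rep_len(cfg$priors, k)
    for (i in seq_len(k))
      cells[[i]] <- list(loss = ls[[i]], prior_kind = ps[[i]],
                         prior = normal_closed_form_prior(ps[[i]], ls[[i]]))
  } else {
    for (loss in cfg$losses) for (pk in cfg$priors)
      cells[[length(cells) + 1L]] <- list(
        loss = loss, prior_kind = pk,
        prior = normal_closed_form_prior(pk, loss))
  }
  rows <- list()
  kept <- list()
  flagged <- FALSE
  for (ei in seq_along(cfg$epsilon)) for (vi in seq_along(cfg$nu))
    for (ni in seq_along(cfg$n)) {
      sim <- .simulate_point(cfg$epsilon[ei], cfg$nu[vi], cfg$n[ni], cells,
                             cfg$reps, cfg$is_draws, cfg$base_seed,
                             ei, vi, ni)
      if (keep_estimates)
        kept[[sprintf("eps%g_nu%g_n%d", cfg$epsilon[ei], cfg$nu[vi],
                      cfg$n[ni])]] <- sim$est
      for (ci in seq_along(cells)) {
        if (sim$fails[ci] > 0.01 * cfg$reps) flagged <- TRUE
        for (par_i in 1:2) {
          err <- sim$est[, ci, par_i] - .true_theta[par_i]
          err <- err[!is.na(err)]
          m <- length(err)
          rows[[length(rows) + 1L]] <- data.frame(
            epsilon = cfg$epsilon[ei], nu = cfg$nu[vi], n = cfg$n[ni],
            loss = cells[[ci]]$loss$kind, tuning = cells[[ci]]$loss$tuning,
            prior = cells[[ci]]$prior_kind,
            parameter = names(.true_theta)[par_i],
            bias = mean(err), mse = mean(err^2),
            bias_se = stats::sd(err) / sqrt(m),
            mse_se = stats::sd(err^2) / sqrt(m),
            reps = m, failures = sim$fails[ci],
            stringsAsFactors = FALSE)
        }
      }
    }
  out <- do.call(rbind, rows)
  attr(out, "flagged") <- flagged
  attr(out, "base_seed") <- cfg$base_seed
  if (keep_estimates) attr(out, "estimates") <- kept
  class(out) <- c("simulation_result", class(out))
  out
}

#' Sweep the contamination ratio or the contaminant location
#'
#' Runs the table experiment along a one-dimensional grid: an
#' `"epsilon"` sweep holds \eqn{\nu} fixed while \eqn{\varepsilon} varies,
#' and a `"nu"` sweep holds \eqn{\varepsilon} fixed while \eqn{\nu} varies.
#'
#' @param kind `"epsilon"` or `"nu"`.
#' @param cfg a [simulation_config()]; the swept field must be a monotone
#'   grid and the other scalar.
#' @return A `simulation_result` (see [run_table_experiment()]).
#' @export
run_sweep <- function(kind = c("epsilon", "nu"), cfg) {
  kind <- match.arg(kind)
  if (kind == "epsilon") {
    if (length(cfg$epsilon) < 1L) stop("empty epsilon grid")
    if (is.unsorted(cfg$epsilon)) stop("epsilon grid must be monotone")
    if (length(cfg$nu) != 1L) stop("nu must be scalar in an epsilon sweep")
  } else {
    if (length(cfg$nu) < 1L) stop("empty nu grid")
    if (is.unsorted(cfg$nu)) stop("nu grid must be monotone")
    if (length(cfg$epsilon) != 1L) stop("epsilon must be scalar in a nu sweep")
  }
  run_table_experiment(cfg)
}

#' Pivot a simulation result into the tabular layout
#'
#' Reshapes the long-format result into a wide table with (prior, epsilon,
#' n) rows and one column per loss, mirroring the usual presentation of
#' bias/MSE simulation tables.
#'
#' @param res a `simulation_result`.
#' @param value `"bias"` or `"mse"`.
#' @param parameter `"mu"` or `"sigma"`.
#' @return A wide-format data frame.
#' @export
pivot_simulation <- function(res, value = c("bias", "mse"),
                             parameter = c("mu", "sigma")) {
  value <- match.arg(value)
  parameter <- match.arg(parameter)
  d <- res[res$parameter == parameter, ]
  d$cell <- paste0(d$loss, ifelse(d$tuning > 0, sprintf("(%g)", d$tuning), ""))
  out <- stats::reshape(
    d[, c("prior", "epsilon", "n", "cell", value)],
    idvar = c("prior", "epsilon", "n"), timevar = "cell",
    direction = "wide")
  names(out) <- sub(paste0("^", value, "\\."), "", names(out))
  rownames(out) <- NULL
  out
}
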