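#' Simulate one posterior predictive replicate
#'
#' Draws a replicate n x 4 log-trait matrix from the multivariate normal
#' observation model at a single posterior draw: mean
#' \eqn{\mu_{i,Y} = \alpha_{Y,t(i)} + b_{Y,t(i)} \log\rho_i} evaluated at
#' that draw's latent diameters, covariance that draw's `Sigma`.
#'
#' @param state A list with `tree_alpha`, `tree_b` (n_trees x 4), `Sigma`
#'   (4x4) and `log_rho` (length n), e.g. one element of the internal draw
#'   reconstruction or an [allom_state()].
#' @param data An `allom_obs` table (supplies the tree index of each
#'   observation).
#' @return n x 4 matrix of replicated log traits.
#' @export
simulate_replicate <- function(state, data) {
  tree_idx <- as.integer(data$tree)
  mu <- state$tree_alpha[tree_idx, , drop = FALSE] +
    state$tree_b[tree_idx, , drop = FALSE] * state$log_rho
  rep <- mu + rmvn_chol(nrow(mu), state$Sigma)
  colnames(rep) <- TRAITS
  rep
}

#' Posterior predictive checks
#'
#' Computes, per trait, the Bayesian p-values of two discrepancy
#' statistics and the squared correlation between observed log traits and
#' posterior-mean predictions. The first statistic is the trait mean
#' (ability to capture the central tendency); the second is the sum of
#' squared deviations from the model mean surface (ability to capture the
#' variability). For each posterior draw used, one replicate dataset is
#' simulated and \eqn{P_B} is the fraction of draws whose replicate
#' statistic is at least as large as the observed one (ties count as
#' extreme). Values near 0 or 1 indicate lack of fit; values near 0.5
#' indicate none.
#'
#' @param fit An `allom_hb` fit (latents must have been stored, the
#'   default).
#' @param n_replicates Number of posterior draws used, subsampled evenly
#'   from the pooled chains (default 1000; at least 100).
#' @param seed Integer seed for the replicate simulation.
#' @return An object of class `allom_ppc`: a `data.frame` with columns
#'   trait, r2, p_b_mean, p_b_fit, plus attributes `n_replicates` and
#'   `seed`. A zero-variance observed trait yields `NA` r2 with a warning.
#' @export
allom_ppc <- function(fit, n_replicates = 1000, seed = 1L) {
  stopifnot(inherits(fit, "allom_hb"))
  if (n_replicates < 100) {
    stop("`n_replicates` must be at least 100", call. = FALSE)
  }
  set.seed(as.integer(seed))
  y <- obs_matrix(fit$data)
  idx <- draw_subsample(fit, n_replicates)
  states <- draw_states(fit, idx)
  n_used <- length(states)

  t_mean_obs <- colMeans(y)
  ge_mean <- matrix(0L, n_used, N_TRAITS)
  ge_fit <- matrix(0L, n_used, N_TRAITS)
  mu_sum <- matrix(0, nrow(y), N_TRAITS)
  tree_idx <- as.integer(fit$data$tree)
  for (j in seq_len(n_used)) {
    st <- states[[j]]
    mu <- st$tree_alpha[tree_idx, , drop = FALSE] +
      st$tree_b[tree_idx, , drop = FALSE] * st$log_rho
    y_rep <- mu + rmvn_chol(nrow(y), st$Sigma)
    mu_sum <- mu_sum + mu
    ge_mean[j, ] <- colMeans(y_rep) >= t_mean_obs
    ge_fit[j, ] <- colSums((y_rep - mu)^2) >= colSums((y - mu)^2)
  }
  mu_bar <- mu_sum / n_used

  r2 <- vapply(seq_len(N_TRAITS), function(k) {
    if (sd(y[, k]) < 1e-12) {
      warning("observed trait '", TRAITS[k],
              "' has zero variance; r2 undefined", call. = FALSE)
      return(NA_real_)
    }
    cor(y[, k], mu_bar[, k])^2
  }, numeric(1))

  out <- data.frame(
    trait = TRAITS,
    r2 = r2,
    p_b_mean = colMeans(ge_mean),
    p_b_fit = colMeans(ge_fit),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("allom_ppc", "data.frame"),
            n_replicates = n_used, seed = as.integer(seed))
}

#' @export
print.allom_ppc <- function(x, ...) {
  cat("Posterior predictive checks (", attr(x, "n_replicates"),
      " replicates)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 3)
  cat("P_B near 0 or 1 indicates lack of fit; near 0.5, none.\n")
  invisible(x)
}
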