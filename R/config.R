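#' Model configuration
#'
#' Fixed (non-sampled) quantities of the hierarchical model: the diameter
#' measurement-error standard deviation, uniform hyperprior bounds, the
#' Wishart prior on the residual precision matrix and the support of the
#' latent log-diameters.
#'
#' @param sigma_rho Log-scale standard deviation of the lognormal diameter
#'   measurement error (default 0.05, i.e. roughly 5% relative error).
#' @param alpha_bounds Length-2 numeric, uniform prior support for the
#'   global log normalization constants \eqn{A_Y}.
#' @param b_bounds Uniform prior support for the global exponents
#'   \eqn{B_Y}.
#' @param sd_bounds Uniform prior support shared by all hierarchical
#'   standard deviations (tree-level and species-level, intercepts and
#'   exponents).
#' @param log_rho_bounds Support of the uniform prior on the latent log
#'   diameters, on the log-cm scale (default `log(c(0.5, 500))`).
#' @param wishart_df Degrees of freedom of the Wishart prior on the
#'   residual precision matrix; must be at least 5 (trait dimension + 1).
#' @param wishart_scale 4x4 symmetric positive-definite scale matrix of the
#'   Wishart prior (default identity).
#'
#' @return An object of class `allom_model_config` (a validated list).
#' @export
allom_model_config <- function(sigma_rho = 0.05,
                               alpha_bounds = c(-20, 20),
                               b_bounds = c(-5, 5),
                               sd_bounds = c(0, 10),
                               log_rho_bounds = log(c(0.5, 500)),
                               wishart_df = 5,
                               wishart_scale = diag(N_TRAITS)) {
  stopifnot(
    is.numeric(sigma_rho), length(sigma_rho) == 1L, sigma_rho >= 0,
    length(alpha_bounds) == 2L, alpha_bounds[1] < alpha_bounds[2],
    length(b_bounds) == 2L, b_bounds[1] < b_bounds[2],
    length(sd_bounds) == 2L, sd_bounds[1] >= 0, sd_bounds[1] < sd_bounds[2],
    length(log_rho_bounds) == 2L, log_rho_bounds[1] < log_rho_bounds[2],
    all(is.finite(c(alpha_bounds, b_bounds, sd_bounds, log_rho_bounds))),
    wishart_df >= N_TRAITS + 1
  )
  wishart_scale <- as.matrix(wishart_scale)
  if (!is_spd(wishart_scale)) {
    stop("`wishart_scale` must be symmetric positive-definite", call. = FALSE)
  }
  structure(
    list(
      sigma_rho = sigma_rho,
      alpha_bounds = as.numeric(alpha_bounds),
      b_bounds = as.numeric(b_bounds),
      sd_bounds = as.numeric(sd_bounds),
      log_rho_bounds = as.numeric(log_rho_bounds),
      wishart_df = wishart_df,
      wishart_scale = wishart_scale
    ),
    class = "allom_model_config"
  )
}

#' Sampler control settings
#'
#' MCMC protocol settings. The study-scale protocol is 3 chains of
#' 1,000,000 iterations each, thinned by 10 after a 200,000-iteration
#' burn-in; the package default is a desk-scale protocol (3 chains of
#' 6,000, burn-in 2,000, thin 2) suitable for the bundled fixture.
#'
#' @param n_chains Number of independent chains (default 3).
#' @param n_iterations Total iterations per chain, including burn-in.
#' @param burn_in Iterations discarded from the front of each chain;
#'   random-walk scale adaptation happens only during burn-in and is frozen
#'   at its end.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param adapt_every Iterations between adaptation updates during burn-in.
#' @param keep_latents Store the latent log-diameter draws (default TRUE).
#'
#' @return An object of class `allom_sampler_control`.
#' @export
#' @examples
#' # the study-scale protocol:
#' ctrl <- allom_sampler_control(n_chains = 3, n_iterations = 1e6,
#'                               burn_in = 2e5, thin = 10)
allom_sampler_control <- function(n_chains = 3,
                                  n_iterations = 6000,
                                  burn_in = 2000,
                                  thin = 2,
                                  adapt_every = 50,
                                  keep_latents = TRUE) {
  stopifnot(
    n_chains >= 1, n_iterations >= 2, burn_in >= 0,
    burn_in < n_iterations, thin >= 1, adapt_every >= 1
  )
  structure(
    list(
      n_chains = as.integer(n_chains),
      n_iterations = as.integer(n_iterations),
      burn_in = as.integer(burn_in),
      thin = as.integer(thin),
      adapt_every = as.integer(adapt_every),
      keep_latents = isTRUE(keep_latents)
    ),
    class = "allom_sampler_control"
  )
}

#' The study protocol as published
#'
#' @return An `allom_sampler_control` with 3 chains, 1,000,000 iterations,
#'   burn-in 200,000 and thinning 10.
#' @export
study_sampler_control <- function() {
  allom_sampler_control(n_chains = 3, n_iterations = 1e6,
                        burn_in = 2e5, thin = 10)
}

# symmetric positive definite check via Cholesky
is_spd <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) < tol * (1 + max(abs(m))) &&
    !inherits(try(chol(m), silent = TRUE), "try-error")
}
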