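#' Construct a parameter state
#'
#' Bundles one full point in parameter space: latent log diameters, tree-
#' and species-level intercepts (\eqn{\alpha = \log a}) and exponents (b),
#' the global means, all hierarchical standard deviations, and the residual
#' covariance. Dimensions are validated against each other.
#'
#' @param log_rho Per-observation latent log diameters.
#' @param tree_alpha,tree_b n_trees x 4 matrices.
#' @param species_alpha,species_b n_species x 4 matrices.
#' @param global_alpha,global_b Per-trait numeric vectors (length 4).
#' @param sd_tree_alpha,sd_tree_b Per-trait tree-level sds (shared across
#'   species).
#' @param sd_species_alpha,sd_species_b Per-trait among-species sds.
#' @param Sigma 4x4 residual covariance of the log traits.
#' @return A list of class `allom_state`.
#' @export
allom_state <- function(log_rho, tree_alpha, tree_b,
                        species_alpha, species_b,
                        global_alpha, global_b,
                        sd_tree_alpha, sd_tree_b,
                        sd_species_alpha, sd_species_b,
                        Sigma) {
  tree_alpha <- as.matrix(tree_alpha); tree_b <- as.matrix(tree_b)
  species_alpha <- as.matrix(species_alpha)
  species_b <- as.matrix(species_b)
  stopifnot(
    ncol(tree_alpha) == N_TRAITS, ncol(tree_b) == N_TRAITS,
    ncol(species_alpha) == N_TRAITS, ncol(species_b) == N_TRAITS,
    nrow(tree_alpha) == nrow(tree_b),
    nrow(species_alpha) == nrow(species_b),
    length(global_alpha) == N_TRAITS, length(global_b) == N_TRAITS,
    length(sd_tree_alpha) == N_TRAITS, length(sd_tree_b) == N_TRAITS,
    length(sd_species_alpha) == N_TRAITS,
    length(sd_species_b) == N_TRAITS,
    all(c(sd_tree_alpha, sd_tree_b, sd_species_alpha, sd_species_b) >= 0),
    is.matrix(Sigma), all(dim(Sigma) == N_TRAITS)
  )
  structure(
    list(
      log_rho = as.numeric(log_rho),
      tree_alpha = tree_alpha, tree_b = tree_b,
      species_alpha = species_alpha, species_b = species_b,
      global_alpha = as.numeric(global_alpha),
      global_b = as.numeric(global_b),
      sd_tree_alpha = as.numeric(sd_tree_alpha),
      sd_tree_b = as.numeric(sd_tree_b),
      sd_species_alpha = as.numeric(sd_species_alpha),
      sd_species_b = as.numeric(sd_species_b),
      Sigma = Sigma
    ),
    class = "allom_state"
  )
}

# data indices used by all density components
data_indices <- function(data) {
  list(
    tree = as.integer(data$tree),
    species_of_tree = attr(data, "tree_species"),
    n = nrow(data)
  )
}

#' Multivariate normal log-likelihood of the log traits
#'
#' \eqn{\sum_i \log \mathrm{MVN}(y_i \mid \mu_i, \Sigma)} with
#' \eqn{\mu_{i,Y} = \alpha_{Y,t(i)} + b_{Y,t(i)} \log\rho_i} and \eqn{y_i}
#' the four log traits of observation i. Returns `-Inf` when `Sigma` is
#' not positive-definite (out of support).
#'
#' @param state An [allom_state()].
#' @param data An `allom_obs` table.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(state, data) {
  idx <- data_indices(data)
  if (nrow(state$tree_alpha) < max(idx$tree)) {
    stop("state has fewer trees than the data", call. = FALSE)
  }
  ch <- try(chol(state$Sigma), silent = TRUE)
  if (inherits(ch, "try-error")) {
    return(structure(-Inf, flag = "Sigma not positive-definite"))
  }
  y <- obs_matrix(data)
  mu <- state$tree_alpha[idx$tree, , drop = FALSE] +
    state$tree_b[idx$tree, , drop = FALSE] * state$log_rho
  r <- y - mu
  # solve against the Cholesky factor: q_i = r_i' Sigma^{-1} r_i
  z <- backsolve(ch, t(r), transpose = TRUE)
  q <- colSums(z^2)
  logdet <- 2 * sum(log(diag(ch)))
  -0.5 * idx$n * (N_TRAITS * log(2 * pi) + logdet) - 0.5 * sum(q)
}

#' Berkson measurement-error log-density
#'
#' Lognormal density of the observed diameters around the latent true
#' diameters, \eqn{\sum_i \log \mathrm{LogNormal}(D_i \mid \log\rho_i,
#' \sigma_\rho^2)}, plus the uniform prior on each latent log diameter over
#' its support; `-Inf` if any latent falls outside the support.
#'
#' @inheritParams log_likelihood
#' @param config An [allom_model_config()].
#' @return Scalar log-density.
#' @export
log_measurement <- function(state, data, config) {
  lr <- state$log_rho
  b <- config$log_rho_bounds
  if (any(lr < b[1] | lr > b[2])) return(-Inf)
  prior <- -length(lr) * log(b[2] - b[1])
  if (config$sigma_rho == 0) {
    # degenerate limit: latent pinned at the observed diameter
    if (any(abs(lr - log(data$diameter_cm)) > 1e-12)) return(-Inf)
    return(prior)
  }
  sum(dlnorm(data$diameter_cm, meanlog = lr, sdlog = config$sigma_rho,
             log = TRUE)) + prior
}

#' Hierarchical (partial-pooling) log-density
#'
#' Normal log-densities of the tree-level intercepts and exponents around
#' their species-level means (tree-level sds, shared across species per
#' trait) plus those of the species-level values around the global means
#' (among-species sds), summed over traits. A zero sd contributes `-Inf`
#' unless the corresponding values match exactly (degenerate hierarchy).
#'
#' @inheritParams log_likelihood
#' @return Scalar log-density.
#' @export
log_hierarchy <- function(state) {
  sp_of_tree <- attr(state, "species_of_tree")
  if (is.null(sp_of_tree)) {
    # infer a 1:1 mapping when trees and species counts match
    if (nrow(state$tree_alpha) == nrow(state$species_alpha)) {
      sp_of_tree <- seq_len(nrow(state$tree_alpha))
    } else {
      stop("state needs a `species_of_tree` attribute mapping trees ",
           "to species", call. = FALSE)
    }
  }
  total <- 0
  for (k in seq_len(N_TRAITS)) {
    total <- total +
      sum_dnorm0(state$tree_alpha[, k],
                 state$species_alpha[sp_of_tree, k], state$sd_tree_alpha[k]) +
      sum_dnorm0(state$tree_b[, k],
                 state$species_b[sp_of_tree, k], state$sd_tree_b[k]) +
      sum_dnorm0(state$species_alpha[, k],
                 state$global_alpha[k], state$sd_species_alpha[k]) +
      sum_dnorm0(state$species_b[, k],
                 state$global_b[k], state$sd_species_b[k])
  }
  total
}

# normal log-density sum with the sd = 0 convention: 0 when all values
# equal the mean (Dirac), -Inf otherwise
sum_dnorm0 <- function(x, mean, sd) {
  if (sd == 0) {
    if (all(x == mean)) 0 else -Inf
  } else {
    sum(dnorm(x, mean, sd, log = TRUE))
  }
}

#' Joint log-posterior kernel
#'
#' Sum of [log_likelihood()], [log_measurement()] and [log_hierarchy()]
#' plus the uniform hyperprior indicators on the global means and all
#' hierarchical sds, and the Wishart log-density of the residual precision
#' matrix \eqn{\Sigma^{-1}}. Returns `-Inf` outside any support.
#'
#' @inheritParams log_measurement
#' @return Scalar log-posterior (up to additive constants independent of
#'   the state).
#' @export
log_posterior <- function(state, data, config) {
  ab <- config$alpha_bounds; bb <- config$b_bounds; sb <- config$sd_bounds
  sds <- c(state$sd_tree_alpha, state$sd_tree_b,
           state$sd_species_alpha, state$sd_species_b)
  if (any(state$global_alpha < ab[1]) || any(state$global_alpha > ab[2]) ||
      any(state$global_b < bb[1]) || any(state$global_b > bb[2]) ||
      any(sds < sb[1]) || any(sds > sb[2])) {
    return(-Inf)
  }
  ch <- try(chol(state$Sigma), silent = TRUE)
  if (inherits(ch, "try-error")) return(-Inf)
  # attach the data's tree->species map for the hierarchy term
  attr(state, "species_of_tree") <- attr(data, "tree_species")
  prec <- chol2inv(ch)
  lw <- dwishart_log(prec, config$wishart_df, config$wishart_scale)
  lm_ <- log_measurement(state, data, config)
  if (!is.finite(lm_)) return(-Inf)
  ll <- log_likelihood(state, data)
  lh <- log_hierarchy(state)
  ll + lm_ + lh + lw
}

#' Wishart log-density
#'
#' Density of a symmetric positive-definite matrix `W` under a Wishart
#' distribution with `df` degrees of freedom and scale matrix `S`
#' (expectation `df * S`).
#'
#' @param W Symmetric positive-definite matrix.
#' @param df Degrees of freedom (> p - 1).
#' @param S Scale matrix.
#' @return Scalar log-density.
#' @export
dwishart_log <- function(W, df, S) {
  p <- nrow(W)
  chW <- chol(W)
  chS <- chol(S)
  ldW <- 2 * sum(log(diag(chW)))
  ldS <- 2 * sum(log(diag(chS)))
  tr <- sum(diag(chol2inv(chS) %*% W))
  0.5 * (df - p - 1) * ldW - 0.5 * tr -
    0.5 * df * p * log(2) - 0.5 * df * ldS - lmvgamma(p, df / 2)
}

# log multivariate gamma function
lmvgamma <- function(p, a) {
  0.25 * p * (p - 1) * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}
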