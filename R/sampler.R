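#' Run the Metropolis-within-Gibbs sampler
#'
#' Draws from the joint posterior of the hierarchical error-in-variables
#' allometry model. Conjugate blocks are used where available — a joint
#' normal update of each tree's (intercept, exponent) pair across the four
#' traits given the residual precision and latent diameters, normal updates
#' of the species and global means, and a Wishart update of the residual
#' precision matrix — while the hierarchical standard deviations and each
#' latent log diameter get adaptive random-walk Metropolis updates whose
#' scales are tuned only during burn-in (frozen thereafter, preserving
#' ergodicity). Fully reproducible from `seed`.
#'
#' @param data An `allom_obs` table (see [allom_observations()]).
#' @param model_config An [allom_model_config()].
#' @param control An [allom_sampler_control()].
#' @param seed Integer seed.
#' @param init Optional initial `allom_state`; by default initial values
#'   come from per-tree ordinary least squares on the log data (species
#'   pools for trees too small to regress), the pooled OLS residual
#'   covariance, and latents at the observed log diameters.
#' @return An object of class `allom_samples`: kept draws per chain
#'   (matrices, iterations x named parameters), a parameter registry
#'   mapping every column to hierarchy level, trait and kind, acceptance
#'   rates, and the configurations used.
#' @export
run_mcmc <- function(data, model_config = allom_model_config(),
                     control = allom_sampler_control(),
                     seed = 1L, init = NULL) {
  stopifnot(inherits(data, "allom_obs"), nrow(data) > 0)
  prep <- sampler_prep(data, model_config)
  if (is.null(init)) init <- init_state(data, model_config)
  lp0 <- log_posterior(init, data, model_config)
  if (!is.finite(lp0)) {
    stop("log-posterior is not finite at the initial state ",
         "(components: likelihood = ", log_likelihood(init, data),
         ", measurement = ", log_measurement(init, data, model_config),
         ")", call. = FALSE)
  }
  reg <- build_registry(prep, control$keep_latents)
  t0 <- proc.time()[["elapsed"]]
  chains <- vector("list", control$n_chains)
  acceptance <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    chain_seed <- (as.integer(seed) %% 1000000L) * 1000L + ch
    set.seed(chain_seed)
    res <- run_chain(prep, model_config, control, init, reg$names)
    chains[[ch]] <- res$draws
    acceptance[[ch]] <- res$acceptance
  }
  structure(
    list(
      chains = chains,
      registry = reg$registry,
      control = control,
      model_config = model_config,
      seed = as.integer(seed),
      acceptance = acceptance,
      species_ids = prep$species_ids,
      tree_ids = prep$tree_ids,
      tree_species = prep$sp_of_tree,
      runtime_s = proc.time()[["elapsed"]] - t0
    ),
    class = "allom_samples"
  )
}

# static data quantities shared by all chains
sampler_prep <- function(data, config) {
  y <- obs_matrix(data)
  tree_idx <- as.integer(data$tree)
  list(
    y = y,
    logD = log(data$diameter_cm),
    tree_idx = tree_idx,
    n = nrow(y),
    n_tree = attr(data, "n_trees"),
    n_species = attr(data, "n_species"),
    sp_of_tree = attr(data, "tree_species"),
    n_per_tree = tabulate(tree_idx, attr(data, "n_trees")),
    species_ids = levels(data$species),
    tree_ids = levels(data$tree)
  )
}

# OLS-based initial state
init_state <- function(data, config) {
  y <- obs_matrix(data)
  logD <- log(data$diameter_cm)
  tree_idx <- as.integer(data$tree)
  sp_of_tree <- attr(data, "tree_species")
  sp_idx <- sp_of_tree[tree_idx]
  Tn <- attr(data, "n_trees")
  Sn <- attr(data, "n_species")

  ols <- function(x, ym) {
    vx <- var(x)
    if (length(x) < 3 || !is.finite(vx) || vx < 1e-10) return(NULL)
    b <- apply(ym, 2, function(col) cov(x, col) / vx)
    a <- colMeans(ym) - b * mean(x)
    list(a = a, b = b)
  }
  sp_fit <- lapply(seq_len(Sn), function(s) {
    ols(logD[sp_idx == s], y[sp_idx == s, , drop = FALSE])
  })
  pooled <- ols(logD, y)
  for (s in seq_len(Sn)) if (is.null(sp_fit[[s]])) sp_fit[[s]] <- pooled
  sa <- t(vapply(sp_fit, `[[`, numeric(N_TRAITS), "a"))
  sb <- t(vapply(sp_fit, `[[`, numeric(N_TRAITS), "b"))
  ta <- matrix(NA_real_, Tn, N_TRAITS)
  tb <- matrix(NA_real_, Tn, N_TRAITS)
  for (t in seq_len(Tn)) {
    f <- ols(logD[tree_idx == t], y[tree_idx == t, , drop = FALSE])
    if (is.null(f)) f <- sp_fit[[sp_of_tree[t]]]
    ta[t, ] <- f$a; tb[t, ] <- f$b
  }
  mu <- ta[tree_idx, , drop = FALSE] + tb[tree_idx, , drop = FALSE] * logD
  Sigma <- var(y - mu) + diag(1e-3, N_TRAITS)

  clamp <- function(x, b) pmin(pmax(x, b[1] + 1e-6), b[2] - 1e-6)
  sd_floor <- function(x) {
    x[!is.finite(x)] <- 0.1  # single tree/species: no empirical spread
    pmin(pmax(x, 0.05), config$sd_bounds[2] - 1e-3)
  }
  allom_state(
    log_rho = clamp(logD, config$log_rho_bounds),
    tree_alpha = ta, tree_b = tb,
    species_alpha = sa, species_b = sb,
    global_alpha = clamp(colMeans(sa), config$alpha_bounds),
    global_b = clamp(colMeans(sb), config$b_bounds),
    sd_tree_alpha = sd_floor(apply(ta - sa[sp_of_tree, ], 2, sd)),
    sd_tree_b = sd_floor(apply(tb - sb[sp_of_tree, ], 2, sd)),
    sd_species_alpha = sd_floor(apply(sa, 2, sd)),
    sd_species_b = sd_floor(apply(sb, 2, sd)),
    Sigma = Sigma
  )
}

# parameter naming and registry
build_registry <- function(prep, keep_latents) {
  sp <- prep$species_ids
  tr <- prep$tree_ids
  ut <- which(upper.tri(diag(N_TRAITS), diag = TRUE), arr.ind = TRUE)
  piece <- function(names, level, kind, trait = NA, species = NA, tree = NA) {
    data.frame(name = names, level = level, kind = kind, trait = trait,
               species = species, tree = tree, stringsAsFactors = FALSE)
  }
  cross <- function(fmt, ids) as.vector(outer(ids, TRAITS, function(i, k) {
    sprintf(fmt, i, k)
  }))
  regs <- list(
    piece(sprintf("A[%s]", TRAITS), "global", "alpha", TRAITS),
    piece(sprintf("B[%s]", TRAITS), "global", "b", TRAITS),
    piece(sprintf("tau_A[%s]", TRAITS), "species", "sd_alpha", TRAITS),
    piece(sprintf("tau_B[%s]", TRAITS), "species", "sd_b", TRAITS),
    piece(sprintf("sigma_a[%s]", TRAITS), "tree", "sd_alpha", TRAITS),
    piece(sprintf("sigma_b[%s]", TRAITS), "tree", "sd_b", TRAITS),
    piece(cross("alpha_sp[%s,%s]", sp), "species", "alpha",
          rep(TRAITS, each = length(sp)), species = rep(sp, N_TRAITS)),
    piece(cross("b_sp[%s,%s]", sp), "species", "b",
          rep(TRAITS, each = length(sp)), species = rep(sp, N_TRAITS)),
    piece(cross("alpha_tree[%s,%s]", tr), "tree", "alpha",
          rep(TRAITS, each = length(tr)), tree = rep(tr, N_TRAITS)),
    piece(cross("b_tree[%s,%s]", tr), "tree", "b",
          rep(TRAITS, each = length(tr)), tree = rep(tr, N_TRAITS)),
    piece(sprintf("Sigma[%d,%d]", ut[, 1], ut[, 2]), "residual", "Sigma")
  )
  if (keep_latents) {
    regs <- c(regs, list(
      piece(sprintf("log_rho[%d]", seq_len(prep$n)), "latent", "log_rho")
    ))
  }
  registry <- do.call(rbind, regs)
  list(registry = registry, names = registry$name)
}

# one chain of the Metropolis-within-Gibbs sampler
run_chain <- function(prep, config, control, init, par_names) {
  n <- prep$n; Tn <- prep$n_tree; Sn <- prep$n_species
  y <- prep$y; logD <- prep$logD; tree_idx <- prep$tree_idx
  sp_of_tree <- prep$sp_of_tree
  n_per_tree <- prep$n_per_tree
  n_per_species <- tabulate(sp_of_tree, Sn)
  srho <- config$sigma_rho
  lr_b <- config$log_rho_bounds
  sd_b <- config$sd_bounds
  V0inv <- chol2inv(chol(config$wishart_scale))
  df_post <- config$wishart_df + n
  ut <- upper.tri(diag(N_TRAITS), diag = TRUE)

  # mutable state
  lr <- init$log_rho
  ta <- init$tree_alpha; tb <- init$tree_b
  sa <- init$species_alpha; sb <- init$species_b
  ga <- init$global_alpha; gb <- init$global_b
  sd_ta <- init$sd_tree_alpha; sd_tb <- init$sd_tree_b
  sd_sa <- init$sd_species_alpha; sd_sb <- init$sd_species_b
  Sigma <- init$Sigma
  Sigma_inv <- chol2inv(chol(Sigma))
  U <- chol(Sigma_inv)  # Sigma_inv = t(U) %*% U
  tU <- t(U)

  # adaptive RW log-scales and acceptance bookkeeping
  ls_rho <- rep(log(0.2), n)
  ls_sd <- rep(log(0.5), 4L * N_TRAITS)  # sd_ta, sd_tb, sd_sa, sd_sb
  acc_rho <- numeric(n); acc_sd <- numeric(16L)
  tot_rho <- 0L; tot_sd <- 0L
  acc_rho_all <- 0; acc_sd_all <- 0; n_post <- 0L
  target_rate <- 0.35
  batch <- 0L

  n_keep <- (control$n_iterations - control$burn_in) %/% control$thin
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  keep_row <- 0L

  quad <- function(r) {
    z <- r %*% tU
    rowSums(z * z)
  }
  # full-conditional log-kernels of the four hierarchical sd families;
  # defined once, they read the live state through the chain environment
  sd_groups <- list(
    function(k, s) sum(dnorm(ta[, k], sa[sp_of_tree, k], s, log = TRUE)),
    function(k, s) sum(dnorm(tb[, k], sb[sp_of_tree, k], s, log = TRUE)),
    function(k, s) sum(dnorm(sa[, k], ga[k], s, log = TRUE)),
    function(k, s) sum(dnorm(sb[, k], gb[k], s, log = TRUE))
  )
  for (iter in seq_len(control$n_iterations)) {
    mu <- ta[tree_idx, , drop = FALSE] + tb[tree_idx, , drop = FALSE] * lr

    ## 1. latent log diameters: vectorized random-walk Metropolis
    if (srho > 0) {
      lr2 <- lr + exp(ls_rho) * rnorm(n)
      mu2 <- ta[tree_idx, , drop = FALSE] + tb[tree_idx, , drop = FALSE] * lr2
      lt_cur <- dnorm(logD, lr, srho, log = TRUE) - 0.5 * quad(y - mu)
      lt_new <- dnorm(logD, lr2, srho, log = TRUE) - 0.5 * quad(y - mu2)
      lt_new[lr2 < lr_b[1] | lr2 > lr_b[2]] <- -Inf
      acc <- log(runif(n)) < (lt_new - lt_cur)
      lr[acc] <- lr2[acc]
      mu[acc, ] <- mu2[acc, , drop = FALSE]
      acc_rho <- acc_rho + acc
      tot_rho <- tot_rho + 1L
      if (iter > control$burn_in) acc_rho_all <- acc_rho_all + mean(acc)
    }

    ## 2. per-tree joint conjugate update of (alpha, b) across traits
    sums <- rowsum(cbind(lr, lr^2, y, y * lr), tree_idx)
    prior_prec <- c(1 / sd_ta^2, 1 / sd_tb^2)
    for (t in seq_len(Tn)) {
      sp <- sp_of_tree[t]
      mom <- tree_block_moments(
        n_per_tree[t], sums[t, 1L], sums[t, 2L],
        sums[t, 3:6], sums[t, 7:10], Sigma_inv,
        prior_mean = c(sa[sp, ], sb[sp, ]), prior_prec = prior_prec
      )
      Up <- chol(mom$P)
      m <- backsolve(Up, backsolve(Up, mom$h, transpose = TRUE))
      theta <- m + backsolve(Up, rnorm(2L * N_TRAITS))
      ta[t, ] <- theta[1:4]
      tb[t, ] <- theta[5:8]
    }

    ## 3. species means: scalar conjugate normal updates (vectorized)
    mta <- rowsum(ta, sp_of_tree) / n_per_species
    mtb <- rowsum(tb, sp_of_tree) / n_per_species
    for (k in seq_len(N_TRAITS)) {
      prec <- n_per_species / sd_ta[k]^2 + 1 / sd_sa[k]^2
      mpost <- (n_per_species * mta[, k] / sd_ta[k]^2 +
                  ga[k] / sd_sa[k]^2) / prec
      sa[, k] <- rnorm(Sn, mpost, 1 / sqrt(prec))
      prec <- n_per_species / sd_tb[k]^2 + 1 / sd_sb[k]^2
      mpost <- (n_per_species * mtb[, k] / sd_tb[k]^2 +
                  gb[k] / sd_sb[k]^2) / prec
      sb[, k] <- rnorm(Sn, mpost, 1 / sqrt(prec))
    }

    ## 4. global means: conjugate normal truncated to the uniform bounds
    ga <- rtnorm(colMeans(sa), sd_sa / sqrt(Sn), config$alpha_bounds)
    gb <- rtnorm(colMeans(sb), sd_sb / sqrt(Sn), config$b_bounds)

    ## 5. hierarchical sds: random-walk Metropolis on the log scale
    sd_cur <- c(sd_ta, sd_tb, sd_sa, sd_sb)
    for (j in seq_len(16L)) {
      g <- (j - 1L) %/% N_TRAITS + 1L
      k <- (j - 1L) %% N_TRAITS + 1L
      s_old <- sd_cur[j]
      s_new <- exp(log(s_old) + exp(ls_sd[j]) * rnorm(1L))
      if (s_new > sd_b[1] && s_new <= sd_b[2]) {
        lacc <- sd_groups[[g]](k, s_new) - sd_groups[[g]](k, s_old) +
          log(s_new) - log(s_old)
        if (log(runif(1L)) < lacc) {
          sd_cur[j] <- s_new
          acc_sd[j] <- acc_sd[j] + 1
          if (iter > control$burn_in) acc_sd_all <- acc_sd_all + 1 / 16
        }
      }
      # keep the live vectors in sync for subsequent targets
      if (g == 1L) sd_ta[k] <- sd_cur[j]
      else if (g == 2L) sd_tb[k] <- sd_cur[j]
      else if (g == 3L) sd_sa[k] <- sd_cur[j]
      else sd_sb[k] <- sd_cur[j]
    }
    tot_sd <- tot_sd + 1L

    ## 6. residual precision: conjugate Wishart
    mu <- ta[tree_idx, , drop = FALSE] + tb[tree_idx, , drop = FALSE] * lr
    A <- crossprod(y - mu)
    scale_post <- chol2inv(chol(V0inv + A))
    W <- rWishart(1L, df_post, scale_post)[, , 1L]
    Sigma_inv <- (W + t(W)) / 2
    U <- chol(Sigma_inv)
    tU <- t(U)
    Sigma <- chol2inv(U)

    ## adaptation (burn-in only), Robbins-Monro toward the target rate
    if (iter <= control$burn_in && iter %% control$adapt_every == 0L) {
      batch <- batch + 1L
      gam <- 1 / sqrt(batch)
      if (srho > 0) {
        ls_rho <- ls_rho + gam * (acc_rho / tot_rho - 0.44)
        acc_rho[] <- 0; tot_rho <- 0L
      }
      ls_sd <- ls_sd + gam * (acc_sd / tot_sd - target_rate)
      acc_sd[] <- 0; tot_sd <- 0L
    }

    ## store
    if (iter > control$burn_in &&
        (iter - control$burn_in) %% control$thin == 0L) {
      keep_row <- keep_row + 1L
      n_post <- n_post + 1L
      row <- c(ga, gb, sd_sa, sd_sb, sd_ta, sd_tb,
               as.vector(sa), as.vector(sb),
               as.vector(ta), as.vector(tb),
               Sigma[ut])
      if (control$keep_latents) row <- c(row, lr)
      draws[keep_row, ] <- row
    }
  }

  post_iters <- control$n_iterations - control$burn_in
  list(
    draws = draws,
    acceptance = list(
      latents = if (srho > 0) acc_rho_all / post_iters else NA_real_,
      sds = acc_sd_all / post_iters
    )
  )
}

# Gaussian full-conditional of one tree's stacked (alpha, b) vector across
# the four traits: precision P = [[n, S1],[S1, S2]] (x) Sigma^{-1} + prior
# precision, linear term h = [Sigma^{-1} sum(y), Sigma^{-1} sum(r y)] +
# prior precision * prior mean; the conditional is MVN(P^{-1} h, P^{-1})
tree_block_moments <- function(n_t, s1, s2, Sy, Sry, Sigma_inv,
                               prior_mean, prior_prec) {
  i1 <- seq_len(N_TRAITS)
  i2 <- N_TRAITS + i1
  P <- matrix(0, 2L * N_TRAITS, 2L * N_TRAITS)
  P[i1, i1] <- n_t * Sigma_inv
  P[i1, i2] <- s1 * Sigma_inv
  P[i2, i1] <- s1 * Sigma_inv
  P[i2, i2] <- s2 * Sigma_inv
  diag(P) <- diag(P) + prior_prec
  h <- c(Sigma_inv %*% Sy, Sigma_inv %*% Sry) + prior_prec * prior_mean
  list(P = P, h = h)
}

# truncated normal draws via inverse CDF (vectorized over means/sds)
rtnorm <- function(mean, sd, bounds) {
  plo <- pnorm((bounds[1] - mean) / sd)
  phi <- pnorm((bounds[2] - mean) / sd)
  u <- runif(length(mean), pmin(plo, phi - 1e-12), phi)
  u <- pmin(pmax(u, 1e-16), 1 - 1e-16)
  mean + sd * qnorm(u)
}

#' Conjugate Wishart update of the residual precision matrix
#'
#' Draws the residual precision \eqn{\Sigma^{-1}} from its full
#' conditional: Wishart with degrees of freedom `prior_df + n` and scale
#' \eqn{(S_0^{-1} + R'R)^{-1}}, where R is the n x 4 residual matrix. With
#' zero rows the draw comes from the prior.
#'
#' @param residuals n x 4 matrix of residuals (may have zero rows).
#' @param prior_df Prior degrees of freedom.
#' @param prior_scale Prior scale matrix \eqn{S_0}.
#' @return A 4x4 symmetric positive-definite precision draw.
#' @export
conjugate_update_precision <- function(residuals, prior_df, prior_scale) {
  residuals <- as.matrix(residuals)
  if (!all(is.finite(residuals))) {
    stop("`residuals` must be finite", call. = FALSE)
  }
  p <- ncol(prior_scale)
  ch0 <- try(chol(prior_scale), silent = TRUE)
  if (inherits(ch0, "try-error")) {
    stop("`prior_scale` must be positive-definite", call. = FALSE)
  }
  A <- if (nrow(residuals)) crossprod(residuals) else matrix(0, p, p)
  scale_post <- chol2inv(chol(chol2inv(ch0) + A))
  W <- rWishart(1L, prior_df + nrow(residuals), scale_post)[, , 1L]
  (W + t(W)) / 2
}

#' Potential scale reduction factor (R-hat)
#'
#' Gelman–Rubin between/within-chain variance ratio,
#' \eqn{\sqrt{((n-1)/n\,W + B/n)/W}}.
#'
#' @param x A draws-by-chains matrix, or a list of equal-length numeric
#'   chains (at least 2 chains of at least 10 draws).
#' @return Scalar R-hat.
#' @export
rhat <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  m <- ncol(x); n <- nrow(x)
  if (m < 2L) stop("R-hat needs at least 2 chains", call. = FALSE)
  if (n < 10L) stop("R-hat needs at least 10 draws per chain", call. = FALSE)
  W <- mean(apply(x, 2, var))
  B_over_n <- var(colMeans(x))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Heidelberger–Welch convergence diagnostic
#'
#' Cramér–von-Mises stationarity test with iterative front-truncation and
#' a halfwidth test comparing the spectral-density-based confidence
#' halfwidth of the chain mean against a fraction of the mean. Computed
#' with [coda::heidel.diag()], the implementation the original analysis
#' protocol relied on.
#'
#' @param chain Numeric vector of at least 100 draws.
#' @param pvalue Stationarity test level (default 0.05).
#' @param eps Halfwidth tolerance as a fraction of the mean (default 0.1).
#' @return A list with `stationarity` (logical pass), `halfwidth` (logical
#'   pass; `TRUE` also when the chain mean is numerically degenerate),
#'   and `kept_fraction` (fraction of the chain retained after
#'   front-truncation).
#' @export
heidelberger_welch <- function(chain, pvalue = 0.05, eps = 0.1) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 100L) stop("need at least 100 draws", call. = FALSE)
  if (sd(chain) < 1e-12) {
    # constant chain: trivially stationary, zero halfwidth
    return(list(stationarity = TRUE, halfwidth = TRUE, kept_fraction = 1))
  }
  h <- coda::heidel.diag(coda::mcmc(chain), eps = eps, pvalue = pvalue)
  stat <- isTRUE(h[1, "stest"] == 1)
  start <- h[1, "start"]
  kept <- if (stat && is.finite(start)) (n - start + 1) / n else 0
  half <- isTRUE(h[1, "htest"] == 1)
  list(stationarity = stat, halfwidth = half, kept_fraction = kept)
}

#' Summarize posterior draws at a hierarchy level
#'
#' Posterior mean, median and equal-tailed 95% interval (interpolated
#' quantiles of the pooled post-burn-in draws across chains) for every
#' parameter of the requested kind at the requested level and trait.
#'
#' @param samples An `allom_samples` object (or an `allom_hb` fit).
#' @param level `"tree"`, `"species"` or `"global"`.
#' @param trait One of [allom_traits()].
#' @param kind `"b"` (exponents, default), `"alpha"`, `"sd_alpha"` or
#'   `"sd_b"`.
#' @return A `data.frame` with columns parameter, level, trait, unit
#'   (tree/species id or `"global"`), mean, median, lower, upper.
#' @export
summarize_level <- function(samples, level = c("global", "species", "tree"),
                            trait = TRAITS, kind = "b") {
  samples <- as_allom_samples(samples)
  level <- match.arg(level)
  trait <- match.arg(trait)
  reg <- samples$registry
  sel <- reg$level == level & !is.na(reg$trait) & reg$trait == trait &
    reg$kind == kind
  if (!any(sel)) {
    stop("no parameters for level '", level, "', trait '", trait,
         "', kind '", kind, "'", call. = FALSE)
  }
  m <- pooled_draws(samples, reg$name[sel])
  qs <- apply(m, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  unit <- if (level == "global") "global"
          else if (level == "species") reg$species[sel]
          else reg$tree[sel]
  data.frame(
    parameter = colnames(m),
    level = level,
    trait = trait,
    unit = unit,
    mean = colMeans(m),
    median = qs[2, ],
    lower = qs[1, ],
    upper = qs[3, ],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# pooled draws (all chains stacked) for a set of parameter names
pooled_draws <- function(samples, names) {
  m <- do.call(rbind, lapply(samples$chains, function(ch) {
    ch[, names, drop = FALSE]
  }))
  m
}

as_allom_samples <- function(x) {
  if (inherits(x, "allom_hb")) x$samples
  else if (inherits(x, "allom_samples")) x
  else stop("expected an `allom_samples` or `allom_hb` object",
            call. = FALSE)
}
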