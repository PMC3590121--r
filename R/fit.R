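#' Fit the hierarchical Bayesian allometry model
#'
#' Estimates the four power-law scaling relationships (length, aboveground
#' mass, stem mass and leaf mass against diameter) simultaneously by MCMC,
#' with lognormal Berkson measurement error on diameter and partial pooling
#' of intercepts and exponents across trees within species and species
#' within a global population.
#'
#' @param data An `allom_obs` observation table ([allom_observations()]) or
#'   a branch-record `data.frame` together with `ratios` (it is then
#'   preprocessed first).
#' @param ratios Named dry:wet ratio vector, required only when `data` is a
#'   raw record table.
#' @param model An [allom_model_config()].
#' @param control An [allom_sampler_control()].
#' @param seed Integer seed.
#' @param ... Passed to [run_mcmc()].
#' @return An object of class `allom_hb` with components `samples` (an
#'   `allom_samples`), `data` (the observation table), `model`, `control`
#'   and `seed`. Supports `print`, `summary`, `coef`, `plot`, `predict`,
#'   `residuals` and `simulate` methods.
#' @export
#' @examples
#' \donttest{
#' fx <- study_fixture(seed = 42)
#' fit <- allom_hb(fx$observations, seed = 42,
#'                 control = allom_sampler_control(n_chains = 2,
#'                                                 n_iterations = 1500,
#'                                                 burn_in = 500))
#' coef(fit)$global_b
#' }
allom_hb <- function(data, ratios = NULL,
                     model = allom_model_config(),
                     control = allom_sampler_control(),
                     seed = 1L, ...) {
  if (!inherits(data, "allom_obs")) {
    if (is.null(ratios)) {
      stop("`ratios` are required when `data` is a raw record table",
           call. = FALSE)
    }
    data <- allom_observations(data, ratios)
  }
  samples <- run_mcmc(data, model_config = model, control = control,
                      seed = seed, ...)
  structure(
    list(samples = samples, data = data, model = model,
         control = control, seed = as.integer(seed)),
    class = "allom_hb"
  )
}

#' @export
print.allom_hb <- function(x, ...) {
  s <- x$samples
  cat("Hierarchical Bayesian allometric scaling fit\n")
  cat("  observations:", attr(x$data, "n_obs"),
      " trees:", attr(x$data, "n_trees"),
      " species:", attr(x$data, "n_species"), "\n")
  cat("  chains:", s$control$n_chains,
      " iterations:", s$control$n_iterations,
      " burn-in:", s$control$burn_in,
      " thin:", s$control$thin, "\n")
  g <- do.call(rbind, lapply(TRAITS, function(k) {
    summarize_level(x, "global", k, "b")
  }))
  cat("\nGlobal scaling exponents (posterior mean [95% CI]):\n")
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-10s %6.3f [%6.3f, %6.3f]\n",
                g$trait[i], g$mean[i], g$lower[i], g$upper[i]))
  }
  invisible(x)
}

#' Summarize an allometric scaling fit
#'
#' @param object An `allom_hb` fit.
#' @param levels Hierarchy levels to summarize.
#' @param ... Unused.
#' @return A list with per-level exponent and intercept summary tables,
#'   variance components, and R-hat values on the global parameters.
#' @export
summary.allom_hb <- function(object,
                             levels = c("global", "species", "tree"),
                             ...) {
  exps <- exponent_summaries(object, levels = levels)
  ints <- do.call(rbind, unlist(lapply(levels, function(lv) {
    lapply(TRAITS, function(k) summarize_level(object, lv, k, "alpha"))
  }), recursive = FALSE))
  out <- list(
    exponents = exps,
    intercepts = ints,
    variance_components = variance_components(object),
    rhat = global_rhat(object),
    runtime_s = object$samples$runtime_s
  )
  class(out) <- "summary.allom_hb"
  out
}

#' @export
print.summary.allom_hb <- function(x, ...) {
  cat("Global scaling exponents:\n")
  print(x$exponents[x$exponents$level == "global",
                    c("trait", "mean", "median", "lower", "upper")],
        row.names = FALSE, digits = 3)
  cat("\nSpecies-level exponents:\n")
  print(x$exponents[x$exponents$level == "species",
                    c("trait", "unit", "mean", "lower", "upper")],
        row.names = FALSE, digits = 3)
  cat("\nVariance components (exponents):\n")
  print(x$variance_components, row.names = FALSE, digits = 3)
  cat("\nmax R-hat over global parameters:",
      format(max(x$rhat), digits = 4), "\n")
  invisible(x)
}

# exponent CI rows for all requested levels, all traits
exponent_summaries <- function(fit, levels = c("global", "species", "tree")) {
  do.call(rbind, unlist(lapply(levels, function(lv) {
    lapply(TRAITS, function(k) summarize_level(fit, lv, k, "b"))
  }), recursive = FALSE))
}

#' Variance components of the fitted hierarchy
#'
#' Posterior means and 95% CIs of the tree-level and species-level
#' variances of the scaling exponents (the squares of the hierarchical
#' sds), one row per trait.
#'
#' @param fit An `allom_hb` fit (or `allom_samples`).
#' @return A `data.frame` with columns trait, tree_var, tree_lower,
#'   tree_upper, species_var, species_lower, species_upper.
#' @export
variance_components <- function(fit) {
  samples <- as_allom_samples(fit)
  one <- function(name) {
    v <- pooled_draws(samples, name)^2
    c(mean(v), quantile(v, c(0.025, 0.975), names = FALSE))
  }
  rows <- lapply(TRAITS, function(k) {
    tr <- one(sprintf("sigma_b[%s]", k))
    sp <- one(sprintf("tau_B[%s]", k))
    data.frame(trait = k,
               tree_var = tr[1], tree_lower = tr[2], tree_upper = tr[3],
               species_var = sp[1], species_lower = sp[2],
               species_upper = sp[3], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# R-hat for every global-level parameter (needs >= 2 chains)
global_rhat <- function(fit) {
  samples <- as_allom_samples(fit)
  if (length(samples$chains) < 2L) return(NA_real_)
  names <- samples$registry$name[samples$registry$level == "global"]
  vapply(names, function(nm) {
    rhat(lapply(samples$chains, function(ch) ch[, nm]))
  }, numeric(1))
}

#' @export
coef.allom_hb <- function(object, ...) {
  samples <- object$samples
  pm <- function(names) colMeans(pooled_draws(samples, names))
  sp <- samples$species_ids
  tr <- samples$tree_ids
  shape <- function(v, ids) matrix(v, length(ids), N_TRAITS,
                                   dimnames = list(ids, TRAITS))
  list(
    global_alpha = setNames(pm(sprintf("A[%s]", TRAITS)), TRAITS),
    global_b = setNames(pm(sprintf("B[%s]", TRAITS)), TRAITS),
    species_alpha = shape(pm(samples$registry$name[
      samples$registry$kind == "alpha" &
        samples$registry$level == "species"]), sp),
    species_b = shape(pm(samples$registry$name[
      samples$registry$kind == "b" &
        samples$registry$level == "species"]), sp),
    tree_alpha = shape(pm(samples$registry$name[
      samples$registry$kind == "alpha" &
        samples$registry$level == "tree"]), tr),
    tree_b = shape(pm(samples$registry$name[
      samples$registry$kind == "b" &
        samples$registry$level == "tree"]), tr)
  )
}

#' Posterior-mean trait predictions
#'
#' Posterior mean (and 95% interval) of the log-scale trait values at new
#' diameters, using global, species- or tree-level parameters.
#'
#' @param object An `allom_hb` fit.
#' @param newdata Numeric vector of diameters (cm).
#' @param level `"global"`, `"species"` or `"tree"`.
#' @param unit Species or tree id when `level != "global"`.
#' @param ... Unused.
#' @return A `data.frame` with diameter, trait, mean, lower, upper (log
#'   scale).
#' @export
predict.allom_hb <- function(object, newdata, level = "global",
                             unit = NULL, ...) {
  samples <- object$samples
  stopifnot(is.numeric(newdata), all(newdata > 0))
  nm <- switch(level,
    global = list(a = sprintf("A[%s]", TRAITS),
                  b = sprintf("B[%s]", TRAITS)),
    species = {
      if (is.null(unit) || !unit %in% samples$species_ids) {
        stop("`unit` must name a species", call. = FALSE)
      }
      list(a = sprintf("alpha_sp[%s,%s]", unit, TRAITS),
           b = sprintf("b_sp[%s,%s]", unit, TRAITS))
    },
    tree = {
      if (is.null(unit) || !unit %in% samples$tree_ids) {
        stop("`unit` must name a tree", call. = FALSE)
      }
      list(a = sprintf("alpha_tree[%s,%s]", unit, TRAITS),
           b = sprintf("b_tree[%s,%s]", unit, TRAITS))
    },
    stop("unknown level", call. = FALSE)
  )
  a <- pooled_draws(samples, nm$a)
  b <- pooled_draws(samples, nm$b)
  out <- lapply(seq_len(N_TRAITS), function(k) {
    m <- outer(a[, k], rep(1, length(newdata))) +
      outer(b[, k], log(newdata))
    qs <- apply(m, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    data.frame(diameter_cm = newdata, trait = TRAITS[k],
               mean = colMeans(m), lower = qs[1, ], upper = qs[2, ],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
residuals.allom_hb <- function(object, ...) {
  y <- obs_matrix(object$data)
  y - posterior_mean_mu(object)
}

# posterior mean of the observation-level mean surface mu_i
posterior_mean_mu <- function(fit, draw_idx = NULL) {
  samples <- fit$samples
  tree_idx <- as.integer(fit$data$tree)
  reg <- samples$registry
  ta <- pooled_draws(samples, reg$name[reg$kind == "alpha" &
                                         reg$level == "tree"])
  tb <- pooled_draws(samples, reg$name[reg$kind == "b" &
                                         reg$level == "tree"])
  lr <- latent_draws(fit)
  if (!is.null(draw_idx)) {
    ta <- ta[draw_idx, , drop = FALSE]
    tb <- tb[draw_idx, , drop = FALSE]
    lr <- lr[draw_idx, , drop = FALSE]
  }
  Tn <- length(samples$tree_ids)
  mu <- matrix(0, nrow(fit$data), N_TRAITS, dimnames = list(NULL, TRAITS))
  for (k in seq_len(N_TRAITS)) {
    cols <- (k - 1L) * Tn + seq_len(Tn)
    a_mean <- colMeans(ta[, cols, drop = FALSE])
    # E[alpha + b * rho] across draws, per observation
    ab <- colMeans(tb[, cols, drop = FALSE][, tree_idx, drop = FALSE] * lr)
    mu[, k] <- a_mean[tree_idx] + ab
  }
  mu
}

# pooled latent log-diameter draws (falls back to observed log D when the
# latents were not stored)
latent_draws <- function(fit) {
  samples <- fit$samples
  reg <- samples$registry
  nm <- reg$name[reg$kind == "log_rho"]
  if (length(nm)) {
    pooled_draws(samples, nm)
  } else {
    n_draws <- sum(vapply(samples$chains, nrow, integer(1)))
    matrix(log(fit$data$diameter_cm), n_draws, nrow(fit$data), byrow = TRUE)
  }
}

#' Simulate posterior predictive datasets
#'
#' Draws replicate log-trait matrices from the posterior predictive
#' distribution: for each retained posterior draw used, replicates come
#' from the multivariate normal at that draw's tree-level parameters,
#' latent diameters and residual covariance (see [simulate_replicate()]).
#'
#' @param object An `allom_hb` fit.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` matrices (n x 4, log scale).
#' @export
simulate.allom_hb <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- draw_subsample(object, nsim)
  states <- draw_states(object, idx)
  lapply(states, simulate_replicate, data = object$data)
}

# evenly spaced subsample of pooled draw indices
draw_subsample <- function(fit, n) {
  total <- sum(vapply(fit$samples$chains, nrow, integer(1)))
  if (n >= total) seq_len(total)
  else unique(round(seq(1, total, length.out = n)))
}

# reconstruct minimal states (tree params, Sigma, latents) from pooled draw
# rows; pools the draw matrix once for efficiency
draw_states <- function(fit, idx) {
  samples <- fit$samples
  reg <- samples$registry
  pool <- pooled_draws(samples, reg$name)
  Tn <- length(samples$tree_ids)
  ut <- which(upper.tri(diag(N_TRAITS), diag = TRUE))
  lr_names <- reg$name[reg$kind == "log_rho"]
  lapply(idx, function(i) {
    row <- pool[i, ]
    get <- function(kind, level, n_units) {
      matrix(row[reg$name[reg$kind == kind & reg$level == level]],
             n_units, N_TRAITS)
    }
    Sigma <- matrix(0, N_TRAITS, N_TRAITS)
    Sigma[ut] <- row[reg$name[reg$kind == "Sigma"]]
    Sigma <- Sigma + t(Sigma) - diag(diag(Sigma))
    lr <- if (length(lr_names)) row[lr_names]
          else log(fit$data$diameter_cm)
    list(
      tree_alpha = get("alpha", "tree", Tn),
      tree_b = get("b", "tree", Tn),
      Sigma = Sigma,
      log_rho = as.numeric(lr)
    )
  })
}

# single-draw convenience wrapper
draw_state <- function(fit, i) draw_states(fit, i)[[1L]]

#' Plot exponent credible intervals by hierarchy level
#'
#' One panel per trait: posterior means and 95% CIs of the scaling
#' exponents for every tree, species and the global level, with horizontal
#' lines at the theoretical predictions of MST, GEOM and STRESS.
#'
#' @param x An `allom_hb` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.allom_hb <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  preds <- scaling_model_predictions()
  for (k in TRAITS) {
    s <- do.call(rbind, lapply(c("tree", "species", "global"),
                               function(lv) summarize_level(x, lv, k, "b")))
    xi <- seq_len(nrow(s))
    graphics::plot(xi, s$mean, ylim = range(s$lower, s$upper, preds[, k],
                                            na.rm = TRUE),
                   xlab = "unit (trees, species, global)",
                   ylab = "exponent b", main = k,
                   pch = c(tree = 1, species = 16,
                           global = 18)[s$level], ...)
    graphics::segments(xi, s$lower, xi, s$upper)
    for (m in rownames(preds)) {
      if (!is.na(preds[m, k])) {
        graphics::abline(h = preds[m, k], lty = match(m, rownames(preds)),
                         col = "grey40")
      }
    }
  }
  invisible(x)
}
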