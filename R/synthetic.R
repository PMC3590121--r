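#' Generator configuration for forward simulation
#'
#' Describes a synthetic branch-harvest study: the sampling design (species,
#' trees, branches), the true global power laws, the hierarchical spread of
#' intercepts and exponents across species and trees, the residual
#' covariance of the four log traits, and the lognormal diameter
#' measurement error. Intercepts are on the natural-log scale
#' (\eqn{\alpha = \log a}); traits follow the canonical order of
#' [allom_traits()].
#'
#' @param n_species Number of species.
#' @param trees_per_species Integer vector, one count per species.
#' @param branches_per_tree Either a single count, or a list (one integer
#'   vector per species) of non-stem branch counts per tree. Each tree
#'   additionally gets one main-stem record.
#' @param global_alpha,global_b Per-trait global intercepts (log scale) and
#'   exponents.
#' @param sd_species_alpha,sd_species_b Per-trait among-species standard
#'   deviations of intercepts/exponents.
#' @param sd_tree_alpha,sd_tree_b Per-trait within-species (tree-to-tree)
#'   standard deviations.
#' @param Sigma 4x4 symmetric positive-definite residual covariance of the
#'   log traits.
#' @param sigma_rho Log-scale sd of the lognormal measurement error on
#'   diameter.
#' @param diameter_range Length-2 positive numeric, range of true diameters
#'   (cm); latent log-diameters are drawn uniformly over the log range.
#' @param dry_wet_ratios Per-species dry:wet mass ratios in (0, 1].
#' @param min_observed_diameter If not `NA`, observed diameters are
#'   truncated (by resampling the measurement error) to stay at or above
#'   this value, emulating a field protocol that only records branches
#'   above a minimum calliper size.
#'
#' @return An object of class `allom_sim_config`.
#' @export
allom_sim_config <- function(n_species,
                             trees_per_species,
                             branches_per_tree,
                             global_alpha,
                             global_b,
                             sd_species_alpha = rep(0.1, N_TRAITS),
                             sd_species_b = rep(0.05, N_TRAITS),
                             sd_tree_alpha = rep(0.05, N_TRAITS),
                             sd_tree_b = rep(0.03, N_TRAITS),
                             Sigma = default_sigma(),
                             sigma_rho = 0.05,
                             diameter_range = c(2.5, 40),
                             dry_wet_ratios = rep(0.6, n_species),
                             min_observed_diameter = NA_real_) {
  n_species <- as.integer(n_species)
  trees_per_species <- as.integer(trees_per_species)
  if (length(trees_per_species) != n_species) {
    stop("`trees_per_species` must have one entry per species", call. = FALSE)
  }
  if (is.numeric(branches_per_tree) && length(branches_per_tree) == 1L) {
    branches_per_tree <- lapply(trees_per_species, function(nt) {
      rep(as.integer(branches_per_tree), nt)
    })
  }
  stopifnot(
    is.list(branches_per_tree),
    length(branches_per_tree) == n_species,
    all(lengths(branches_per_tree) == trees_per_species),
    all(unlist(branches_per_tree) >= 0)
  )
  sds <- c(sd_species_alpha, sd_species_b, sd_tree_alpha, sd_tree_b)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("hierarchical standard deviations must be finite and >= 0",
         call. = FALSE)
  }
  stopifnot(
    length(global_alpha) == N_TRAITS, length(global_b) == N_TRAITS,
    length(sd_species_alpha) == N_TRAITS, length(sd_species_b) == N_TRAITS,
    length(sd_tree_alpha) == N_TRAITS, length(sd_tree_b) == N_TRAITS,
    sigma_rho >= 0,
    length(diameter_range) == 2L, diameter_range[1] > 0,
    diameter_range[1] < diameter_range[2],
    length(dry_wet_ratios) == n_species,
    all(dry_wet_ratios > 0), all(dry_wet_ratios <= 1)
  )
  Sigma <- as.matrix(Sigma)
  if (!is_spd(Sigma)) {
    stop("`Sigma` must be symmetric positive-definite", call. = FALSE)
  }
  structure(
    list(
      n_species = n_species,
      trees_per_species = trees_per_species,
      branches_per_tree = lapply(branches_per_tree, as.integer),
      global_alpha = setNames(as.numeric(global_alpha), TRAITS),
      global_b = setNames(as.numeric(global_b), TRAITS),
      sd_species_alpha = setNames(as.numeric(sd_species_alpha), TRAITS),
      sd_species_b = setNames(as.numeric(sd_species_b), TRAITS),
      sd_tree_alpha = setNames(as.numeric(sd_tree_alpha), TRAITS),
      sd_tree_b = setNames(as.numeric(sd_tree_b), TRAITS),
      Sigma = Sigma,
      sigma_rho = sigma_rho,
      diameter_range = as.numeric(diameter_range),
      dry_wet_ratios = as.numeric(dry_wet_ratios),
      min_observed_diameter = min_observed_diameter
    ),
    class = "allom_sim_config"
  )
}

# residual covariance used by the bundled fixture: log-scale sds chosen to
# give trait r^2 in the 0.85-0.95 range over the fixture diameter span,
# with positive correlations among the mass traits
default_sigma <- function() {
  sds <- c(0.25, 0.20, 0.20, 0.60)
  cors <- diag(N_TRAITS)
  cors[1, 2:4] <- cors[2:4, 1] <- 0.30
  cors[2, 3] <- cors[3, 2] <- 0.70
  cors[2, 4] <- cors[4, 2] <- 0.40
  cors[3, 4] <- cors[4, 3] <- 0.20
  m <- diag(sds) %*% cors %*% diag(sds)
  dimnames(m) <- list(TRAITS, TRAITS)
  m
}

#' Draw true hierarchical parameters
#'
#' Runs the hierarchy forward: species intercepts/exponents are drawn
#' normally around the global values with the among-species sds, and tree
#' intercepts/exponents normally around their species values with the
#' within-species sds, independently per trait and per parameter.
#'
#' @param config An [allom_sim_config()].
#' @return A list with `species_alpha`, `species_b` (n_species x 4),
#'   `tree_alpha`, `tree_b` (n_trees x 4), `tree_species` (species index of
#'   each tree), and the id vectors `species_ids`, `tree_ids`.
#' @export
sample_true_parameters <- function(config) {
  stopifnot(inherits(config, "allom_sim_config"))
  S <- config$n_species
  Tn <- sum(config$trees_per_species)
  species_ids <- sprintf("sp%d", seq_len(S))
  tree_species <- rep(seq_len(S), config$trees_per_species)
  tree_ids <- unlist(lapply(seq_len(S), function(s) {
    sprintf("%s_t%02d", species_ids[s], seq_len(config$trees_per_species[s]))
  }))

  draw <- function(center, sds, n, groups = NULL) {
    # center: vector over groups (or global scalar per trait); sds per trait
    m <- matrix(NA_real_, n, N_TRAITS, dimnames = list(NULL, TRAITS))
    for (k in seq_len(N_TRAITS)) {
      mu <- if (is.null(groups)) rep(center[k], n) else center[groups, k]
      m[, k] <- rnorm(n, mu, sds[k])
    }
    m
  }
  species_alpha <- draw(config$global_alpha, config$sd_species_alpha, S)
  species_b <- draw(config$global_b, config$sd_species_b, S)
  tree_alpha <- draw(species_alpha, config$sd_tree_alpha, Tn, tree_species)
  tree_b <- draw(species_b, config$sd_tree_b, Tn, tree_species)
  rownames(species_alpha) <- rownames(species_b) <- species_ids
  rownames(tree_alpha) <- rownames(tree_b) <- tree_ids

  list(
    species_alpha = species_alpha, species_b = species_b,
    tree_alpha = tree_alpha, tree_b = tree_b,
    tree_species = tree_species,
    species_ids = species_ids, tree_ids = tree_ids
  )
}

#' Generate a random rooted branching topology
#'
#' Node 1 is the main stem; every other node attaches to a uniformly chosen
#' earlier node. When nodes are ordered by strictly decreasing diameter
#' (the convention used by [generate_dataset()]), every daughter branch is
#' thinner than its parent.
#'
#' @param n_branches Number of nodes including the main stem (>= 1).
#' @return Integer vector of parent indices; the root has parent `NA`.
#' @export
generate_topology <- function(n_branches) {
  n_branches <- as.integer(n_branches)
  if (is.na(n_branches) || n_branches < 1L) {
    stop("`n_branches` must be >= 1", call. = FALSE)
  }
  parent <- rep(NA_integer_, n_branches)
  if (n_branches > 1L) {
    for (k in 2:n_branches) {
      parent[k] <- sample.int(k - 1L, 1L)
    }
  }
  parent
}

#' Generate a synthetic branch-harvest dataset
#'
#' Forward-simulates data with exactly the statistical structure the
#' hierarchical model assumes. Per observation a latent log diameter is
#' drawn uniformly over the log diameter range, the observed diameter is
#' lognormal around the latent value with sd `sigma_rho`, and the four log
#' traits are drawn from a multivariate normal with mean
#' \eqn{\alpha_{Y,t} + b_{Y,t}\log\rho} and covariance `Sigma`. Trait
#' masses are subtree *aggregates* (all biomass downstream of the branching
#' node, the quantity the model regresses on diameter).
#'
#' In `"model-exact"` mode the emitted records carry the aggregated masses
#' directly (converted to wet weight) and no parent links. In
#' `"raw-field"` mode each tree additionally gets a branching topology and
#' the aggregates are disaggregated into per-segment wet masses (a
#' segment's mass is its own aggregate minus its daughters' aggregates), so
#' that preprocessing with [allom_observations()] must reproduce the
#' aggregated values.
#'
#' @param config An [allom_sim_config()].
#' @param mode `"model-exact"` or `"raw-field"`.
#' @return A list with:
#'   \describe{
#'     \item{records}{`data.frame` with the branch-record CSV schema
#'       (species_id, tree_id, branch_id, parent_id, diameter_cm, length_m,
#'       wood_wet_kg, leaf_wet_kg).}
#'     \item{observations}{an `allom_obs` table built from the exact
#'       generated log traits and observed diameters (the model's data
#'       contract, bypassing CSV serialization).}
#'     \item{truth}{true parameters ([sample_true_parameters()] output plus
#'       per-observation latent log diameters `log_rho`, the exact log-trait
#'       matrix `Y`, aggregated dry masses, and the config).}
#'   }
#' @export
generate_dataset <- function(config, mode = c("model-exact", "raw-field")) {
  stopifnot(inherits(config, "allom_sim_config"))
  mode <- match.arg(mode)
  truth <- sample_true_parameters(config)
  S <- config$n_species
  n_tree <- sum(config$trees_per_species)
  obs_per_tree <- unlist(config$branches_per_tree) + 1L  # + main stem
  n <- sum(obs_per_tree)
  tree_idx <- rep(seq_len(n_tree), obs_per_tree)

  lo <- log(config$diameter_range[1])
  hi <- log(config$diameter_range[2])
  log_rho <- runif(n, lo, hi)
  # per tree: sort descending so node 1 (main stem) is the thickest
  ord <- order(tree_idx, -log_rho)
  log_rho <- log_rho[ord]

  D <- draw_observed_diameter(log_rho, config)

  mu <- truth$tree_alpha[tree_idx, , drop = FALSE] +
    truth$tree_b[tree_idx, , drop = FALSE] * log_rho
  Y <- mu + rmvn_chol(n, config$Sigma)
  colnames(Y) <- TRAITS

  sp_idx <- truth$tree_species[tree_idx]
  ratios <- config$dry_wet_ratios[sp_idx]
  node_in_tree <- sequence(obs_per_tree)
  branch_id <- sprintf("b%03d", node_in_tree)

  agg_stem <- exp(Y[, "stem_mass"])
  agg_leaf <- exp(Y[, "leaf_mass"])

  resampled <- 0L
  if (mode == "model-exact") {
    parent_id <- rep(NA_character_, n)
    wood_wet <- agg_stem / ratios
    leaf_wet <- agg_leaf / ratios
  } else {
    parent_id <- rep(NA_character_, n)
    wood_wet <- numeric(n)
    leaf_wet <- numeric(n)
    for (t in seq_len(n_tree)) {
      idx <- which(tree_idx == t)
      fit <- attach_with_slack(
        agg_stem[idx], agg_leaf[idx],
        regen = function(k) {
          # redraw the trait vector of node k (same latent diameter)
          y <- mu[idx[k], ] + drop(rmvn_chol(1L, config$Sigma))
          Y[idx[k], ] <<- y
          c(exp(y[3L]), exp(y[4L]))
        }
      )
      resampled <- resampled + fit$n_resampled
      agg_stem[idx] <- fit$agg_stem
      agg_leaf[idx] <- fit$agg_leaf
      parent_id[idx] <- ifelse(is.na(fit$parent), NA_character_,
                               branch_id[idx][fit$parent])
      wood_wet[idx] <- fit$seg_stem / ratios[idx]
      leaf_wet[idx] <- fit$seg_leaf / ratios[idx]
    }
    if (resampled > 0L) {
      message("raw-field disaggregation: resampled ", resampled,
              " trait draw(s) to keep segment masses nonnegative")
    }
  }

  records <- data.frame(
    species_id = truth$species_ids[sp_idx],
    tree_id = truth$tree_ids[tree_idx],
    branch_id = branch_id,
    parent_id = parent_id,
    diameter_cm = D,
    length_m = exp(Y[, "length"]),
    wood_wet_kg = wood_wet,
    leaf_wet_kg = leaf_wet,
    stringsAsFactors = FALSE
  )

  truth$log_rho <- log_rho
  truth$Y <- Y
  truth$agg_stem_kg <- agg_stem
  truth$agg_leaf_kg <- agg_leaf
  truth$config <- config
  truth$n_resampled <- resampled

  observations <- new_allom_obs(
    species = factor(truth$species_ids[sp_idx], levels = truth$species_ids),
    tree = factor(truth$tree_ids[tree_idx], levels = truth$tree_ids),
    diameter_cm = D,
    Y = Y
  )

  list(records = records, observations = observations, truth = truth)
}

# observed diameter: lognormal around the latent value; optionally
# truncated from below by resampling the multiplicative error
draw_observed_diameter <- function(log_rho, config) {
  n <- length(log_rho)
  if (config$sigma_rho == 0) {
    return(exp(log_rho))
  }
  D <- exp(rnorm(n, log_rho, config$sigma_rho))
  dmin <- config$min_observed_diameter
  if (!is.na(dmin)) {
    for (rep in 1:100) {
      bad <- which(D < dmin)
      if (!length(bad)) break
      D[bad] <- exp(rnorm(length(bad), log_rho[bad], config$sigma_rho))
    }
    D <- pmax(D, dmin)  # guard against pathological ranges
  }
  D
}

# Attach nodes (ordered by decreasing diameter; node 1 = root) to earlier
# nodes subject to mass feasibility: a parent's aggregate must exceed the
# sum of its direct daughters' aggregates for both stem and leaf mass.
# When no earlier node has enough slack the node's trait draw is
# regenerated (counted in n_resampled). A chain attachment is always
# feasible once aggregates are monotone, so this terminates in practice;
# a hard cap guards against degenerate configurations.
attach_with_slack <- function(agg_stem, agg_leaf, regen,
                              max_resample = 1000L) {
  m <- length(agg_stem)
  parent <- rep(NA_integer_, m)
  slack_s <- agg_stem
  slack_l <- agg_leaf
  n_resampled <- 0L
  if (m > 1L) {
    for (k in 2:m) {
      repeat {
        ok <- which(slack_s[seq_len(k - 1L)] > agg_stem[k] &
                      slack_l[seq_len(k - 1L)] > agg_leaf[k])
        if (length(ok)) {
          p <- if (length(ok) == 1L) ok else sample(ok, 1L)
          parent[k] <- p
          slack_s[p] <- slack_s[p] - agg_stem[k]
          slack_l[p] <- slack_l[p] - agg_leaf[k]
          break
        }
        n_resampled <- n_resampled + 1L
        if (n_resampled > max_resample) {
          stop("could not construct a mass-feasible topology; ",
               "residual variance too large relative to the mass range",
               call. = FALSE)
        }
        new <- regen(k)
        agg_stem[k] <- new[1L]
        agg_leaf[k] <- new[2L]
        slack_s[k] <- new[1L]
        slack_l[k] <- new[2L]
      }
    }
  }
  list(parent = parent,
       agg_stem = agg_stem, agg_leaf = agg_leaf,
       seg_stem = slack_s, seg_leaf = slack_l,
       n_resampled = n_resampled)
}

# n draws from MVN(0, Sigma) via Cholesky
rmvn_chol <- function(n, Sigma) {
  p <- ncol(Sigma)
  z <- matrix(rnorm(n * p), n, p)
  z %*% chol(Sigma)
}

#' Study-design fixture
#'
#' Generates a synthetic dataset replicating the harvest study's sampling
#' design: three species with 10, 5 and 10 trees carrying 103, 30 and 128
#' non-stem branches respectively, plus one main-stem record per tree (286
#' observations in total), all observed diameters at or above 2 cm. True
#' global exponents default to (0.75, 2.65, 2.70, 2.0) for length,
#' aboveground mass, stem mass and leaf mass — inside the credible ranges
#' typically reported for savanna trees — and are configurable through
#' `...`.
#'
#' @param seed Integer seed; the fixture is fully reproducible from it.
#' @param mode Passed to [generate_dataset()].
#' @param ... Overrides for [allom_sim_config()] fields.
#' @return As [generate_dataset()].
#' @export
#' @examples
#' fx <- study_fixture(seed = 1)
#' nrow(fx$records)          # 286
#' nlevels(fx$observations$tree)  # 25
study_fixture <- function(seed = 1L, mode = "model-exact", ...) {
  cfg_args <- list(
    n_species = 3L,
    trees_per_species = c(10L, 5L, 10L),
    branches_per_tree = list(
      split_branches(103L, 10L),
      split_branches(30L, 5L),
      split_branches(128L, 10L)
    ),
    global_alpha = c(-0.34, -2.70, -2.96, -3.50),
    global_b = c(0.75, 2.65, 2.70, 2.00),
    dry_wet_ratios = c(0.58, 0.55, 0.60),
    diameter_range = c(2.5, 40),
    min_observed_diameter = 2.0
  )
  dots <- list(...)
  cfg_args[names(dots)] <- dots
  config <- do.call(allom_sim_config, cfg_args)
  set.seed(as.integer(seed))
  out <- generate_dataset(config, mode = mode)
  out$seed <- as.integer(seed)
  out
}

# deterministic near-even split of n_branches across n_trees
split_branches <- function(n_branches, n_trees) {
  base <- n_branches %/% n_trees
  extra <- n_branches %% n_trees
  as.integer(base + (seq_len(n_trees) <= extra))
}
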