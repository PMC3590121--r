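# shared fixtures and independent oracles for the test suite

quick_control <- function() {
  allom_sampler_control(n_chains = 2, n_iterations = 800, burn_in = 300,
                        thin = 1)
}

# small generator config: 2 species, 3 trees each, 8 branches per tree
tiny_sim_config <- function(...) {
  args <- list(
    n_species = 2L,
    trees_per_species = c(3L, 3L),
    branches_per_tree = 8L,
    global_alpha = c(-0.3, -2.7, -3.0, -3.5),
    global_b = c(0.7, 2.6, 2.7, 2.0),
    dry_wet_ratios = c(0.6, 0.55)
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(allom_sim_config, args)
}

# fits are expensive; memoise the ones shared across test files
.fit_cache <- new.env(parent = emptyenv())

cached_quick_fit <- function() {
  if (is.null(.fit_cache$quick)) {
    fx <- study_fixture(seed = 7)
    .fit_cache$quick <- list(
      fx = fx,
      fit = allom_hb(fx$observations, seed = 7, control = quick_control())
    )
  }
  .fit_cache$quick
}

# desk-scale fit of the study-design fixture (default sampler control);
# shared by the acceptance checks
cached_desk_fit <- function() {
  if (is.null(.fit_cache$desk)) {
    fx <- study_fixture(seed = 101)
    .fit_cache$desk <- list(
      fx = fx,
      fit = allom_hb(fx$observations, seed = 101)
    )
  }
  .fit_cache$desk
}

# brute-force MVN log-density via explicit inverse and determinant
oracle_dmvnorm <- function(x, mean, Sigma) {
  p <- length(mean)
  r <- x - mean
  -0.5 * (p * log(2 * pi) + log(det(Sigma)) +
            drop(t(r) %*% solve(Sigma) %*% r))
}

# brute-force Wishart log-density written out from the textbook formula
oracle_dwishart <- function(W, df, S) {
  p <- nrow(W)
  lmvg <- 0.25 * p * (p - 1) * log(pi) +
    sum(lgamma((df + 1 - seq_len(p)) / 2))
  0.5 * (df - p - 1) * log(det(W)) -
    0.5 * sum(diag(solve(S) %*% W)) -
    0.5 * df * p * log(2) - 0.5 * df * log(det(S)) - lmvg
}

# brute-force downstream aggregation: sum each node's full descendant set
oracle_aggregate <- function(parent_id, branch_id, masses) {
  n <- length(branch_id)
  pidx <- match(parent_id, branch_id)
  descendants_of <- function(i) {
    out <- integer(0)
    frontier <- i
    repeat {
      kids <- which(pidx %in% frontier)
      if (!length(kids)) break
      out <- c(out, kids)
      frontier <- kids
    }
    out
  }
  vapply(seq_len(n), function(i) {
    masses[i] + sum(masses[descendants_of(i)])
  }, numeric(1))
}

# random parameter state consistent with a dataset, for density oracles
random_state <- function(obs, seed = 1) {
  set.seed(seed)
  Tn <- attr(obs, "n_trees")
  Sn <- attr(obs, "n_species")
  n <- nrow(obs)
  A <- crossprod(matrix(rnorm(36), 9, 4)) / 9 + diag(0.1, 4)
  allom_state(
    log_rho = log(obs$diameter_cm) + rnorm(n, 0, 0.02),
    tree_alpha = matrix(rnorm(Tn * 4, -2, 0.5), Tn, 4),
    tree_b = matrix(rnorm(Tn * 4, 2, 0.3), Tn, 4),
    species_alpha = matrix(rnorm(Sn * 4, -2, 0.5), Sn, 4),
    species_b = matrix(rnorm(Sn * 4, 2, 0.3), Sn, 4),
    global_alpha = rnorm(4, -2, 0.5),
    global_b = rnorm(4, 2, 0.3),
    sd_tree_alpha = runif(4, 0.05, 0.5),
    sd_tree_b = runif(4, 0.05, 0.5),
    sd_species_alpha = runif(4, 0.05, 0.5),
    sd_species_b = runif(4, 0.05, 0.5),
    Sigma = A
  )
}

# a minimal hand-built allom_samples object holding given draws for one
# parameter name per registry row
manual_samples <- function(chains, registry, species_ids = character(0),
                           tree_ids = character(0)) {
  structure(
    list(chains = chains, registry = registry,
         control = quick_control(), model_config = allom_model_config(),
         seed = 1L, acceptance = list(),
         species_ids = species_ids, tree_ids = tree_ids,
         tree_species = seq_along(tree_ids), runtime_s = 0),
    class = "allom_samples"
  )
}
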