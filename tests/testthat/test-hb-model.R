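small_obs <- function(seed = 2) {
  set.seed(seed)
  out <- generate_dataset(tiny_sim_config())
  out$observations
}

test_that("the likelihood matches the textbook MVN density", {
  obs <- small_obs()
  st <- random_state(obs, seed = 5)
  tree_idx <- as.integer(obs$tree)
  y <- as.matrix(obs[, 4:7])
  want <- sum(vapply(seq_len(nrow(y)), function(i) {
    mu <- st$tree_alpha[tree_idx[i], ] + st$tree_b[tree_idx[i], ] *
      st$log_rho[i]
    oracle_dmvnorm(y[i, ], mu, st$Sigma)
  }, numeric(1)))
  got <- log_likelihood(st, obs)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("likelihood equals its closed form at zero residual and scales with Sigma", {
  # single observation, identity covariance, y = mu
  rec <- data.frame(
    species_id = "sp1", tree_id = "t1", branch_id = "b1",
    parent_id = NA_character_, diameter_cm = 10,
    length_m = 1, wood_wet_kg = 1, leaf_wet_kg = 1
  )
  obs <- allom_observations(rec, c(sp1 = 1))
  # log traits: length 0, ag mass log(2) (stem 1 + leaf 1), stem 0, leaf 0;
  # choose intercepts equal to them so the residual is exactly zero
  st <- allom_state(
    log_rho = log(10),
    tree_alpha = matrix(c(0, log(2), 0, 0), 1, 4), tree_b = matrix(0, 1, 4),
    species_alpha = matrix(0, 1, 4), species_b = matrix(0, 1, 4),
    global_alpha = rep(0, 4), global_b = rep(0, 4),
    sd_tree_alpha = rep(1, 4), sd_tree_b = rep(1, 4),
    sd_species_alpha = rep(1, 4), sd_species_b = rep(1, 4),
    Sigma = diag(4)
  )
  expect_equal(log_likelihood(st, obs), -2 * log(2 * pi))
  st2 <- st
  st2$Sigma <- 2 * diag(4)
  expect_equal(log_likelihood(st2, obs),
               -2 * log(2 * pi) - 2 * log(2))
  st3 <- st
  st3$Sigma <- matrix(1, 4, 4)  # singular
  expect_identical(as.numeric(log_likelihood(st3, obs)), -Inf)
})

test_that("measurement term matches independent lognormal evaluation", {
  obs <- small_obs()
  cfg <- allom_model_config()
  st <- random_state(obs, seed = 6)
  width <- diff(cfg$log_rho_bounds)
  want <- sum(dlnorm(obs$diameter_cm, st$log_rho, cfg$sigma_rho,
                     log = TRUE)) - nrow(obs) * log(width)
  expect_equal(log_measurement(st, obs, cfg), want, tolerance = 1e-12)

  # the per-observation density is maximised at log rho = log D
  st_at <- st
  st_at$log_rho <- log(obs$diameter_cm)
  st_off <- st
  st_off$log_rho <- log(obs$diameter_cm) + 0.1
  expect_gt(log_measurement(st_at, obs, cfg),
            log_measurement(st_off, obs, cfg))

  # outside the latent support the density vanishes
  st_out <- st
  st_out$log_rho[1] <- cfg$log_rho_bounds[2] + 1
  expect_identical(log_measurement(st_out, obs, cfg), -Inf)
})

test_that("hierarchy term matches scalar normal log-densities", {
  obs <- small_obs()
  st <- random_state(obs, seed = 7)
  sp_of_tree <- attr(obs, "tree_species")
  attr(st, "species_of_tree") <- sp_of_tree
  want <- 0
  for (k in 1:4) {
    want <- want +
      sum(dnorm(st$tree_alpha[, k], st$species_alpha[sp_of_tree, k],
                st$sd_tree_alpha[k], log = TRUE)) +
      sum(dnorm(st$tree_b[, k], st$species_b[sp_of_tree, k],
                st$sd_tree_b[k], log = TRUE)) +
      sum(dnorm(st$species_alpha[, k], st$global_alpha[k],
                st$sd_species_alpha[k], log = TRUE)) +
      sum(dnorm(st$species_b[, k], st$global_b[k],
                st$sd_species_b[k], log = TRUE))
  }
  expect_equal(log_hierarchy(st), want, tolerance = 1e-9)
})

test_that("hierarchy has the Gaussian kernel shape around the mean", {
  centered <- allom_state(
    log_rho = numeric(0),
    tree_alpha = matrix(2, 1, 4), tree_b = matrix(1, 1, 4),
    species_alpha = matrix(2, 1, 4), species_b = matrix(1, 1, 4),
    global_alpha = rep(2, 4), global_b = rep(1, 4),
    sd_tree_alpha = rep(1, 4), sd_tree_b = rep(1, 4),
    sd_species_alpha = rep(1, 4), sd_species_b = rep(1, 4),
    Sigma = diag(4)
  )
  attr(centered, "species_of_tree") <- 1L
  # 16 centred standard-normal terms
  expect_equal(log_hierarchy(centered), -16 * 0.5 * log(2 * pi))
  shifted <- centered
  shifted$tree_b[1, 1] <- 2  # one sd away
  expect_equal(log_hierarchy(centered) - log_hierarchy(shifted), 0.5)
  # zero sd with mismatched values is out of support
  degen <- centered
  degen$sd_tree_b <- rep(0, 4)
  degen$tree_b[1, 1] <- 1.5
  expect_identical(log_hierarchy(degen), -Inf)
})

test_that("log-posterior is the sum of its components plus priors", {
  obs <- small_obs()
  cfg <- allom_model_config()
  st <- random_state(obs, seed = 8)
  attr(st, "species_of_tree") <- attr(obs, "tree_species")
  want <- log_likelihood(st, obs) +
    log_measurement(st, obs, cfg) +
    log_hierarchy(st) +
    dwishart_log(solve(st$Sigma), cfg$wishart_df, cfg$wishart_scale)
  expect_equal(log_posterior(st, obs, cfg), want, tolerance = 1e-9)

  # any hyperparameter outside its uniform bounds kills the posterior
  st_bad <- st
  st_bad$global_b[1] <- cfg$b_bounds[2] + 1
  expect_identical(log_posterior(st_bad, obs, cfg), -Inf)
  st_bad2 <- st
  st_bad2$sd_species_b[2] <- cfg$sd_bounds[2] + 1
  expect_identical(log_posterior(st_bad2, obs, cfg), -Inf)
})

test_that("Wishart log-density matches the textbook formula and gamma special case", {
  set.seed(9)
  X <- matrix(rnorm(40), 10, 4)
  W <- crossprod(X) / 10 + diag(0.5, 4)
  expect_equal(dwishart_log(W, 5, diag(4)), oracle_dwishart(W, 5, diag(4)),
               tolerance = 1e-9)
  S <- crossprod(matrix(rnorm(36), 9, 4)) / 9 + diag(0.3, 4)
  expect_equal(dwishart_log(W, 8, S), oracle_dwishart(W, 8, S),
               tolerance = 1e-9)
  # p = 1: Wishart(df, s) is Gamma(df/2, rate = 1/(2s))
  w <- matrix(2.3, 1, 1)
  expect_equal(dwishart_log(w, 7, matrix(1.5, 1, 1)),
               dgamma(2.3, shape = 7 / 2, rate = 1 / 3, log = TRUE),
               tolerance = 1e-12)
})

test_that("posterior kernel is invariant to data row order", {
  obs <- small_obs()
  cfg <- allom_model_config()
  st <- random_state(obs, seed = 10)
  set.seed(30)
  perm <- sample(nrow(obs))
  obs_p <- obs[perm, ]
  for (a in c("n_obs", "n_trees", "n_species", "tree_species", "report")) {
    attr(obs_p, a) <- attr(obs, a)
  }
  class(obs_p) <- class(obs)
  st_p <- st
  st_p$log_rho <- st$log_rho[perm]
  expect_equal(log_posterior(st, obs, cfg), log_posterior(st_p, obs_p, cfg),
               tolerance = 1e-9)
})

test_that("shifting latents and compensating intercepts leaves the likelihood unchanged", {
  obs <- small_obs()
  st <- random_state(obs, seed = 11)
  delta <- 0.3
  st2 <- st
  st2$log_rho <- st$log_rho + delta
  st2$tree_alpha <- st$tree_alpha - st$tree_b * delta
  # valid reparameterization only when all observations of a tree shift
  # together; this tiny config has one latent pattern per tree, so apply
  # per-tree: regenerate with a common shift
  expect_equal(log_likelihood(st2, obs), log_likelihood(st, obs),
               tolerance = 1e-9)
})

test_that("with sigma_rho -> 0 the model reduces to hierarchical regression", {
  obs <- small_obs()
  cfg0 <- allom_model_config(sigma_rho = 0)
  st1 <- random_state(obs, seed = 12)
  st1$log_rho <- log(obs$diameter_cm)
  st2 <- st1
  st2$tree_b <- st1$tree_b + 0.05
  # posterior differences equal reduced-model (fixed covariate) differences
  d_full <- log_posterior(st2, obs, cfg0) - log_posterior(st1, obs, cfg0)
  reduced <- function(st) {
    attr(st, "species_of_tree") <- attr(obs, "tree_species")
    log_likelihood(st, obs) + log_hierarchy(st)
  }
  expect_equal(d_full, reduced(st2) - reduced(st1), tolerance = 1e-9)
})
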