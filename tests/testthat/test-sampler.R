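test_that("same seed and data give bit-identical draws", {
  set.seed(1)
  out <- generate_dataset(tiny_sim_config())
  ctrl <- allom_sampler_control(n_chains = 2, n_iterations = 150,
                                burn_in = 50, thin = 1)
  s1 <- run_mcmc(out$observations, control = ctrl, seed = 33)
  s2 <- run_mcmc(out$observations, control = ctrl, seed = 33)
  expect_identical(s1$chains, s2$chains)
  s3 <- run_mcmc(out$observations, control = ctrl, seed = 34)
  expect_false(identical(s1$chains[[1]], s3$chains[[1]]))
})

test_that("default sampler control matches the study protocol at study scale", {
  ctrl <- study_sampler_control()
  expect_identical(ctrl$n_chains, 3L)
  expect_identical(ctrl$n_iterations, 1000000L)
  expect_identical(ctrl$burn_in, 200000L)
  expect_identical(ctrl$thin, 10L)
})

test_that("tree-block conditional matches the curvature of the log-posterior", {
  # the Gaussian full conditional of one tree's (alpha, b) must satisfy
  # log p(theta_m + v) - log p(theta_m) = h'(...)- quadratic identity
  set.seed(2)
  out <- generate_dataset(tiny_sim_config())
  obs <- out$observations
  cfg <- allom_model_config()
  st <- random_state(obs, seed = 20)
  tree_idx <- as.integer(obs$tree)
  t <- 2L
  idx <- tree_idx == t
  lr <- st$log_rho[idx]
  y <- as.matrix(obs[idx, 4:7])
  Sigma_inv <- solve(st$Sigma)
  sp <- attr(obs, "tree_species")[t]
  mom <- allomhb:::tree_block_moments(
    sum(idx), sum(lr), sum(lr^2), colSums(y), colSums(y * lr), Sigma_inv,
    prior_mean = c(st$species_alpha[sp, ], st$species_b[sp, ]),
    prior_prec = c(1 / st$sd_tree_alpha^2, 1 / st$sd_tree_b^2)
  )
  m <- solve(mom$P, mom$h)

  lp_at <- function(theta) {
    s <- st
    s$tree_alpha[t, ] <- theta[1:4]
    s$tree_b[t, ] <- theta[5:8]
    log_posterior(s, obs, cfg)
  }
  # conditional mode: gradient vanishes, so small perturbations only lose
  # the quadratic form 0.5 v' P v
  set.seed(3)
  for (r in 1:5) {
    v <- rnorm(8, 0, 0.1)
    got <- lp_at(m + v) - lp_at(m)
    want <- -0.5 * drop(t(v) %*% mom$P %*% v)
    expect_equal(got, want, tolerance = 1e-7)
  }
})

test_that("posterior concentrates on the truth in a conjugate toy setting", {
  # near-degenerate hierarchy and tiny measurement error make the tree-level
  # exponent posterior match ordinary Bayesian regression: mean close to OLS
  cfg <- allom_sim_config(
    n_species = 1L, trees_per_species = 1L, branches_per_tree = 199L,
    global_alpha = c(-0.3, -2.7, -3.0, -3.5),
    global_b = c(0.7, 2.6, 2.7, 2.0),
    sd_species_alpha = rep(0, 4), sd_species_b = rep(0, 4),
    sd_tree_alpha = rep(0, 4), sd_tree_b = rep(0, 4),
    Sigma = diag(0.04, 4), sigma_rho = 0, dry_wet_ratios = 1
  )
  set.seed(4)
  out <- generate_dataset(cfg)
  obs <- out$observations
  ctrl <- allom_sampler_control(n_chains = 2, n_iterations = 1500,
                                burn_in = 500, thin = 1)
  fit <- run_mcmc(obs, model_config = allom_model_config(sigma_rho = 0),
                  control = ctrl, seed = 5)
  x <- log(obs$diameter_cm)
  for (k in seq_len(4)) {
    draws <- do.call(c, lapply(fit$chains, function(ch) {
      ch[, sprintf("b_tree[sp1_t01,%s]", allom_traits()[k])]
    }))
    ols <- cov(x, as.matrix(obs[, 4:7])[, k]) / var(x)
    se <- sqrt(0.04 / (length(x) * var(x)))
    mcse <- sd(draws) / sqrt(coda::effectiveSize(coda::mcmc(draws)))
    expect_lt(abs(mean(draws) - ols), 3 * (se + mcse))
  }
})

test_that("the Wishart conjugate block has the right no-data and large-n limits", {
  # n = 0: moments of the prior (mean = df * scale)
  set.seed(6)
  draws <- replicate(3000, conjugate_update_precision(
    matrix(numeric(0), 0, 4), 5, diag(4) / 5
  ))
  expect_equal(apply(draws, 1:2, mean), diag(4), tolerance = 0.05)
  # always symmetric positive definite
  w <- conjugate_update_precision(matrix(rnorm(40), 10, 4), 5, diag(4))
  expect_true(isSymmetric(w))
  expect_true(all(eigen(w, only.values = TRUE)$values > 0))
  # singular prior scale is rejected
  expect_error(conjugate_update_precision(matrix(0, 0, 4), 5,
                                          matrix(1, 4, 4)),
               "positive-definite")
})

test_that("Wishart conjugate block concentrates on the true precision", {
  sds <- c(0.25, 0.2, 0.2, 0.6)
  C <- matrix(0.3, 4, 4); diag(C) <- 1
  Sig <- diag(sds) %*% C %*% diag(sds)
  P_true <- solve(Sig)
  set.seed(7)
  ch <- chol(Sig)
  draws <- replicate(200, {
    R <- matrix(rnorm(10000 * 4), 10000, 4) %*% ch
    conjugate_update_precision(R, 5, diag(4))
  })
  post_mean <- apply(draws, 1:2, mean)
  expect_true(all(abs(post_mean / P_true - 1) < 0.05))
})

test_that("R-hat separates mixed from unmixed chains", {
  expect_error(rhat(matrix(rnorm(100), 100, 1)), "2 chains")
  expect_error(rhat(matrix(rnorm(10), 5, 2)), "10 draws")
  x <- rnorm(500)
  expect_lte(rhat(cbind(x, x)), 1.001)   # identical copies
  set.seed(8)
  displaced <- cbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(rhat(displaced), 1.1)
  iid <- matrix(rnorm(3000), 1000, 3)
  expect_lt(abs(rhat(iid) - 1), 0.05)
  # cross-check against the coda implementation
  cl <- coda::mcmc.list(coda::mcmc(iid[, 1]), coda::mcmc(iid[, 2]),
                        coda::mcmc(iid[, 3]))
  expect_equal(rhat(iid),
               unname(coda::gelman.diag(cl, autoburnin = FALSE,
                                        transform = FALSE)$psrf[1, 1]),
               tolerance = 0.01)
})

test_that("Heidelberger-Welch passes stationary chains and fails trended ones", {
  expect_error(heidelberger_welch(rnorm(50)), "100")
  set.seed(9)
  iid <- rnorm(2000, 5, 1)
  h <- heidelberger_welch(iid)
  expect_true(h$stationarity)
  expect_gt(h$kept_fraction, 0.4)
  # moderate drift relative to the noise; extreme trends inflate the
  # spectral variance estimate and defeat the test by design
  trended <- rnorm(2000) + seq(0, 3, length.out = 2000)
  expect_false(heidelberger_welch(trended)$stationarity)
  # near-constant chain passes the halfwidth test trivially
  const <- rep(3.2, 500)
  expect_true(heidelberger_welch(const)$halfwidth)
})

test_that("level summaries report interpolated quantiles of pooled draws", {
  reg <- data.frame(name = "B[length]", level = "global", kind = "b",
                    trait = "length", species = NA, tree = NA,
                    stringsAsFactors = FALSE)
  # constant draws: all summary fields collapse to the constant
  s0 <- manual_samples(list(matrix(2.5, 100, 1,
                                   dimnames = list(NULL, "B[length]"))), reg)
  got <- summarize_level(s0, "global", "length")
  expect_equal(unlist(got[, c("mean", "median", "lower", "upper")]),
               c(mean = 2.5, median = 2.5, lower = 2.5, upper = 2.5))
  # large standard-normal sample: CI close to +/- 1.96, mean ~ median
  set.seed(10)
  z <- matrix(rnorm(100000), ncol = 1, dimnames = list(NULL, "B[length]"))
  s1 <- manual_samples(list(z), reg)
  got <- summarize_level(s1, "global", "length")
  expect_lt(abs(got$lower + 1.96), 0.03)
  expect_lt(abs(got$upper - 1.96), 0.03)
  expect_lt(abs(got$mean - got$median), 0.02)
  expect_error(summarize_level(s1, "species", "length"), "no parameters")
})

test_that("relabelling species permutes summaries and preserves global ones", {
  cq <- cached_quick_fit()
  fit <- cq$fit
  obs <- cq$fx$observations
  obs2 <- obs
  levels(obs2$species) <- c("spC", "spA", "spB")  # rename, keep positions
  fit2 <- allom_hb(obs2, seed = 7, control = quick_control())
  g1 <- summarize_level(fit, "global", "length")
  g2 <- summarize_level(fit2, "global", "length")
  expect_equal(g1$mean, g2$mean, tolerance = 1e-12)
  s1 <- summarize_level(fit, "species", "length")
  s2 <- summarize_level(fit2, "species", "length")
  expect_equal(s1$mean, s2$mean, tolerance = 1e-12)
  expect_identical(s2$unit, c("spC", "spA", "spB"))
})

test_that("a non-finite initial state is rejected with a diagnostic", {
  set.seed(11)
  out <- generate_dataset(tiny_sim_config())
  bad_init <- allomhb:::init_state(out$observations, allom_model_config())
  bad_init$global_b[1] <- 99  # outside the uniform prior support
  expect_error(
    run_mcmc(out$observations, control = quick_control(), init = bad_init),
    "not finite"
  )
})

test_that("acceptance rates of the adaptive blocks are in a healthy range", {
  fit <- cached_quick_fit()$fit
  for (acc in fit$samples$acceptance) {
    expect_gt(acc$latents, 0.15)
    expect_lt(acc$latents, 0.75)
    expect_gt(acc$sds, 0.10)
    expect_lt(acc$sds, 0.80)
  }
})
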