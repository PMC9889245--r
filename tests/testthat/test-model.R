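test_that("log_mean assembles the linear predictor", {
  expect_equal(log_mean(0, numeric(0), numeric(0)), 0)
  expect_equal(exp(log_mean(log(10), numeric(0), numeric(0))), 10)
  # intercept at exp(alpha) = 11.22 and one covariate one unit above its
  # mean with coefficient 0.69 compose multiplicatively
  expect_equal(exp(log_mean(log(11.22), 0.69, 1)), 11.22 * exp(0.69))
  expect_equal(log_mean(1, c(2, 3), c(1, -1), phi_i = 0.5, xi_t = -0.25,
                        delta_it = 0.1),
               1 + 2 - 3 + 0.5 - 0.25 + 0.1)
  expect_error(log_mean(Inf, 0, 0), "non-finite")
})

test_that("CAR full conditional is the neighbour mean with variance var/n", {
  g <- graph_from_nb(list(c(2L, 3L, 4L), 1L, 1L, 1L))  # star, hub first
  p <- car_full_conditional_params(1, c(0, 1, 2, 3), g, var_phi = 1)
  expect_equal(p$mean, 2)
  expect_equal(p$variance, 1 / 3)
  p0 <- car_full_conditional_params(1, c(9, 0, 0, 0), g, var_phi = 2)
  expect_equal(p0$mean, 0)
  # two-node graph: single neighbour, variance = var_phi
  g2 <- two_area_graph()
  p2 <- car_full_conditional_params(1, c(0, 5), g2, var_phi = 2)
  expect_equal(p2$mean, 5)
  expect_equal(p2$variance, 2)
  # isolated area falls back to the exchangeable prior
  gi <- graph_from_nb(list(2L, 1L, integer(0)))
  piso <- car_full_conditional_params(3, c(1, 2, 3), gi, var_phi = 4)
  expect_equal(piso$mean, 0)
  expect_equal(piso$variance, 4)
})

test_that("variance full conditionals match hand-computed Gamma parameters", {
  cfg <- model_config()
  # phi identically 0 on a connected 4-node graph: rank 3, quadratic form 0
  g4 <- graph_from_nb(list(2L, c(1L, 3L), c(2L, 4L), 3L))
  fc <- variance_full_conditionals(list(phi = rep(0, 4)), g4, cfg)
  expect_equal(unname(fc$phi), c(0.5 + 1.5, 0.005))
  # mean precision of that conditional is shape/rate = 400
  expect_equal(fc$phi[["shape"]] / fc$phi[["rate"]], 400)
  # constant xi: rate stays at the prior rate
  fc2 <- variance_full_conditionals(list(xi = rep(2, 5)), config = cfg)
  expect_equal(unname(fc2$xi), c(0.5 + 2, 0.005))
  # one-step walk (-1, 1): rate = 0.005 + (1 - (-1))^2 / 2
  fc3 <- variance_full_conditionals(list(xi = c(-1, 1)), config = cfg)
  expect_equal(unname(fc3$xi), c(1, 2.005))
  # interaction: increments of each row
  d <- rbind(c(0, 1, 3), c(2, 2, 2))
  fc4 <- variance_full_conditionals(list(delta = d), config = cfg)
  expect_equal(unname(fc4$delta), c(0.5 + 2 * 2 / 2, 0.005 + (1 + 4) / 2))
  # isolated areas contribute phi_i^2 and one rank unit each
  gi <- graph_from_nb(list(2L, 1L, integer(0)))
  fci <- variance_full_conditionals(list(phi = c(1, -1, 3)), gi, cfg)
  expect_equal(unname(fci$phi), c(0.5 + (3 - 2 + 1) / 2, 0.005 + (4 + 9) / 2))
})

test_that("update_variances draws from the stated full conditionals", {
  set.seed(60)
  g4 <- graph_from_nb(list(2L, c(1L, 3L), c(2L, 4L), 3L))
  draws <- replicate(4000, update_variances(
    list(phi = rep(0, 4)), g4, model_config())["var_phi"])
  # precision ~ Gamma(2, 0.005); compare mean of sampled precisions
  expect_equal(mean(1 / draws), 400, tolerance = 0.1)
  expect_true(all(draws > 0))
})

test_that("single-block sweeps preserve constraints and touch only their block", {
  set.seed(3)
  g <- make_lattice_graph(3, 3)
  sim <- simulate_panel(g, T = 4, beta = c(0.2, -0.1), seed = 14)
  st <- list(alpha = log(10), beta = c(0, 0), phi = simulate_icar(g, 0.2),
             xi = simulate_rw1(4, 0.05),
             delta = simulate_interaction(9, 4, 0.01),
             var_phi = 0.2, var_xi = 0.05, var_delta = 0.01)
  upd <- update_latent_block("phi", st, sim$panel, g)
  expect_lt(abs(sum(upd$phi)), 1e-8)
  expect_equal(upd$xi, st$xi)
  expect_equal(upd$beta, st$beta)
  upd2 <- update_latent_block("delta", st, sim$panel, g)
  expect_lt(max(abs(rowSums(upd2$delta))), 1e-8)
  expect_equal(upd2$phi, st$phi)
  upd3 <- update_latent_block("variances", st, sim$panel, g)
  expect_true(all(c(upd3$var_phi, upd3$var_xi, upd3$var_delta) > 0))
  expect_false(upd3$var_phi == st$var_phi)
  acc <- attr(update_latent_block("alpha_beta", st, sim$panel, g),
              "acceptance")
  expect_true(acc[["alpha_beta"]] %in% c(0, 1))
})

test_that("prior-only chains reproduce the prior moments of beta and the precisions", {
  g <- make_lattice_graph(2, 2)
  set.seed(50)
  panel <- area_panel(g$area_ids, 1:3, matrix(0L, 4, 3),
                      covariates = array(rnorm(12), c(4, 3, 1)),
                      centered = TRUE)
  cfg <- model_config(n_chains = 1, n_burnin = 1000, n_samples = 8000,
                      seed = 6, prior_only = TRUE)
  fit <- run_mcmc(panel, g, cfg)
  b <- fit_draws(fit, "beta")[, 1]
  expect_equal(var(b), 1000, tolerance = 0.25)
  expect_equal(mean(b) / sqrt(1000), 0, tolerance = 0.15)
  # prior precision Gamma(0.5, 0.005): mean 100
  tau_xi <- 1 / fit_draws(fit, "var_xi")
  expect_equal(mean(tau_xi), 100, tolerance = 0.35)
})

test_that("data generated without spatial structure yield phi near zero", {
  g <- make_lattice_graph(5, 5)
  sim <- simulate_panel(g, T = 6, alpha = log(20), beta = numeric(0),
                        var_phi = 0, var_xi = 0.02, var_delta = 0,
                        seed = 30)
  cfg <- model_config(n_chains = 1, n_burnin = 800, n_samples = 1000,
                      seed = 2, include_interaction = FALSE)
  fit <- run_mcmc(sim$panel, g, cfg)
  phim <- colMeans(fit_draws(fit, "phi"))
  expect_lt(max(abs(phim)), 0.15)
  expect_lt(mean(fit_draws(fit, "var_phi")), 0.05)
})

test_that("without random effects the posterior matches the ML Poisson fit", {
  g <- make_lattice_graph(4, 4)
  sim <- simulate_panel(g, T = 6, beta = c(0.3, -0.2),
                        var_phi = 0, var_xi = 0, var_delta = 0, seed = 44)
  cfg <- model_config(n_chains = 2, n_burnin = 1000, n_samples = 4000,
                      seed = 9, include_spatial = FALSE,
                      include_temporal = FALSE,
                      include_interaction = FALSE)
  fit <- run_mcmc(sim$panel, NULL, cfg)
  y <- as.vector(sim$panel$counts)
  X <- cbind(as.vector(sim$panel$covariates[, , 1]),
             as.vector(sim$panel$covariates[, , 2]))
  ml <- glm(y ~ X, family = poisson())
  bpost <- colMeans(fit_draws(fit, "beta"))
  se <- summary(ml)$coefficients[2:3, "Std. Error"]
  expect_lt(abs(bpost[1] - coef(ml)[2]), se[1])
  expect_lt(abs(bpost[2] - coef(ml)[3]), se[2])
  expect_lt(abs(mean(fit_draws(fit, "alpha")) - coef(ml)[1]),
            summary(ml)$coefficients[1, "Std. Error"])
})

test_that("the interaction variance posterior tracks a well-identified truth", {
  g <- make_lattice_graph(10, 10)
  sim <- simulate_panel(g, T = 10, var_delta = 0.05, seed = 8)
  cfg <- model_config(n_chains = 1, n_burnin = 1500, n_samples = 1500,
                      seed = 12)
  fit <- run_mcmc(sim$panel, g, cfg)
  vd <- mean(fit_draws(fit, "var_delta"))
  expect_gt(vd, 0.05 / 2)
  expect_lt(vd, 0.05 * 2)
})

test_that("chains are bit-reproducible under a fixed seed and config", {
  g <- make_lattice_graph(3, 3)
  sim <- simulate_panel(g, T = 4, seed = 2)
  cfg <- model_config(n_chains = 2, n_burnin = 100, n_samples = 200,
                      seed = 5)
  f1 <- run_mcmc(sim$panel, g, cfg)
  f2 <- run_mcmc(sim$panel, g, cfg)
  expect_identical(fit_draws(f1, "alpha"), fit_draws(f2, "alpha"))
  expect_identical(fit_draws(f1, "delta"), fit_draws(f2, "delta"))
})

test_that("every retained draw satisfies the active constraints", {
  g <- make_lattice_graph(3, 4)
  sim <- simulate_panel(g, T = 5, seed = 19)
  cfg <- model_config(n_chains = 1, n_burnin = 200, n_samples = 400,
                      seed = 8)
  fit <- run_mcmc(sim$panel, g, cfg)
  phi <- fit_draws(fit, "phi")
  expect_lt(max(abs(rowSums(phi))), 1e-8)
  xi <- fit_draws(fit, "xi")
  expect_lt(max(abs(rowSums(xi))), 1e-8)
  d <- array(fit_draws(fit, "delta"), c(400, 12, 5))
  expect_lt(max(abs(apply(d, c(1, 2), sum))), 1e-8)
  expect_true(all(fit_draws(fit, "var_phi") > 0))
  expect_true(all(fit_draws(fit, "var_delta") > 0))
})

test_that("competing model family enumerates the named structural variants", {
  g <- make_lattice_graph(2, 2)
  sim <- simulate_panel(g, T = 3, beta = 0.1, seed = 3)
  cfg <- model_config(n_chains = 1, n_burnin = 50, n_samples = 50, seed = 1)
  fits <- competing_model_family(sim$panel, g, cfg,
                                 variants = c("full", "no_interaction",
                                              "iid_spatial", "no_spatial"))
  expect_named(fits, c("full", "no_interaction", "iid_spatial",
                       "no_spatial"))
  expect_false(fits$no_interaction$config$include_interaction)
  expect_identical(fits$iid_spatial$config$spatial_structure, "iid")
  expect_false(fits$no_spatial$config$include_spatial)
  expect_true(fits$full$config$include_interaction)
})
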