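test_that("log-likelihood matches a naive per-observation oracle", {
  td <- tiny_model_data()
  for (seed in 1:3) {
    params <- full_params(td$ds, td$d, seed = seed)
    # perturb the location parameters so the check is not at a special point
    set.seed(seed + 100)
    loc <- !grepl("(_sigma$|_site_sd$)", names(params)) & names(params) != "herb_phi"
    params[loc] <- params[loc] + rnorm(sum(loc), 0, 0.05)
    expect_equal(log_likelihood(params, td$d), ll_brute(params, td$d),
                 tolerance = 1e-10)
  }
})

test_that("special-case tiers contribute their closed-form log-densities", {
  td <- tiny_model_data()
  params <- full_params(td$ds, td$d)
  # a Beta(1,1) herbivory tier is uniform: zero log-density at any damage
  params[grepl("^herb_", names(params))] <- 0
  params["herb_phi"] <- 2
  expect_equal(log_likelihood(params, td$d, tiers = "herbivory"), 0)

  # zero-residual Gaussian tier with sd 1 contributes -log(2*pi)/2 per point
  ds0 <- generate_dataset(landscape_config(seed = 42), local({
    tr <- default_true_parameters()
    tr$soil$sigma[] <- 0
    tr
  }))
  d0 <- prepare_model_data(ds0$sites, ds0$soil, ds0$trees, ds0$leaves)
  p0 <- full_params(ds0, d0)
  p0[grepl("^soil_.*_sigma$", names(p0))] <- 1
  n_obs <- length(ds0$truth$elements) * nrow(ds0$sites)
  expect_equal(log_likelihood(p0, d0, tiers = "soil"), -0.5 * log(2 * pi) * n_obs,
               tolerance = 1e-10)
})

test_that("log-posterior is prior plus likelihood and -Inf off the support", {
  td <- tiny_model_data()
  for (seed in 4:6) {
    params <- full_params(td$ds, td$d, seed = seed)
    expect_equal(log_posterior(params, td$d),
                 log_prior(params, td$d) + log_likelihood(params, td$d),
                 tolerance = 1e-12)
  }
  bad <- full_params(td$ds, td$d)
  bad["herb_phi"] <- -1
  expect_identical(log_posterior(bad, td$d), -Inf)
  bad2 <- full_params(td$ds, td$d)
  bad2["soil_N_sigma"] <- 0
  expect_identical(log_posterior(bad2, td$d), -Inf)
})

test_that("the prior is zero-centred, unimodal and proper per coefficient", {
  td <- tiny_model_data()
  params <- full_params(td$ds, td$d)
  for (nm in c("soil_N_MAP", "herb_Flindersia_soil_CN", "fol_totalN_Alphitonia_MAT")) {
    p1 <- params; p1[nm] <- 0.7
    p2 <- params; p2[nm] <- 1.4
    expect_gte(log_prior(p1, td$d), log_prior(p2, td$d))
  }
  # the marginal prior over one coefficient integrates to 1
  base <- params
  base["soil_N_MAP"] <- 0
  c0 <- log_prior(base, td$d) - dnorm(0, 0, td$d$spec$priors$coef_sd, log = TRUE)
  dens <- Vectorize(function(b) {
    p <- base
    p["soil_N_MAP"] <- b
    exp(log_prior(p, td$d) - c0)
  })
  expect_equal(integrate(dens, -Inf, Inf)$value, 1, tolerance = 1e-6)
})

test_that("better-fitting parameters raise the log-posterior at matched prior cost", {
  td <- tiny_model_data()
  params <- full_params(td$ds, td$d)
  worse <- params
  worse["soil_N_intercept"] <- params["soil_N_intercept"] + 3  # degrade the fit
  better_lp <- log_posterior(params, td$d)
  worse_lp <- log_posterior(worse, td$d)
  expect_gt(better_lp, worse_lp)
})

test_that("likelihood factorizes over tiers and ignores row order", {
  td <- tiny_model_data()
  params <- full_params(td$ds, td$d, seed = 9)
  total <- log_likelihood(params, td$d)
  parts <- sapply(c("soil", "foliage", "herbivory"),
                  function(t) log_likelihood(params, td$d, tiers = t))
  expect_equal(total, sum(parts), tolerance = 1e-12)

  perm <- sample(nrow(td$ds$trees))
  d2 <- prepare_model_data(td$ds$sites, td$ds$soil, td$ds$trees[perm, ],
                           td$ds$leaves, td$d$spec)
  expect_equal(log_likelihood(params, d2), total, tolerance = 1e-10)
})

test_that("replicates degenerate to fitted means and are seed-reproducible", {
  td <- tiny_model_data()
  params <- full_params(td$ds, td$d)
  degenerate <- params
  degenerate[grepl("_sigma$", names(degenerate))] <- 1e-12
  degenerate["herb_phi"] <- 1e12
  set.seed(1)
  rep0 <- simulate_replicate(degenerate, td$d)
  expect_equal(rep0$soil, rep0$fitted$soil, tolerance = 1e-9)
  expect_equal(rep0$damage, rep0$fitted$herb_mu, tolerance = 1e-4)

  set.seed(7); r1 <- simulate_replicate(params, td$d)
  set.seed(7); r2 <- simulate_replicate(params, td$d)
  expect_identical(r1, r2)

  # replicate averages converge to the fitted means
  set.seed(8)
  acc <- 0
  n_rep <- 2000
  for (k in seq_len(n_rep)) acc <- acc + simulate_replicate(params, td$d)$soil[1, "N"]
  mu <- fitted_means(params, td$d)$soil[1, "N"]
  se <- params[["soil_N_sigma"]] / sqrt(n_rep)
  expect_lt(abs(acc / n_rep - mu), 3 * se)
})
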