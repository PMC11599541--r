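test_that("site generation respects geology coverage, ranges and the seed", {
  # with as many sites as classes, every class appears exactly once
  cfg3 <- landscape_config(n_sites = 3, seed = 1,
                           species_plan = default_species_plan())
  s3 <- generate_sites(cfg3)
  expect_setequal(s3$geology, c("basalt", "granite", "rhyolite"))

  cfg <- landscape_config(seed = 7)
  expect_identical(generate_sites(cfg), generate_sites(cfg))

  big <- generate_sites(landscape_config(n_sites = 200, seed = 3))
  expect_true(all(big$MAT >= 14 & big$MAT <= 26))
  expect_true(all(big$MAP >= 1200 & big$MAP <= 4000))
  expect_gte(diff(range(big$MAT)), 0.9 * 12)   # covers >= 90% of the span
  expect_gte(diff(range(big$MAP)), 0.9 * 2800)
  expect_true(all(table(big$geology) >= 1))
})

test_that("config validation rejects degenerate landscapes", {
  expect_error(landscape_config(n_sites = 2), "geology classes")
  expect_error(landscape_config(mat_range = c(20, 20)), "non-degenerate")
  plan <- default_species_plan()
  plan$n_trees[1] <- 0L
  expect_error(landscape_config(species_plan = plan), "n_trees")
})

test_that("soil values equal the linear predictor in the noiseless limit and are monotone in MAP", {
  truth <- default_true_parameters()
  truth$soil$sigma[] <- 0
  sites <- generate_sites(landscape_config(n_sites = 12, seed = 5))
  soil <- generate_soil(sites, truth, seed = 9)
  for (e in truth$elements) {
    expect_equal(soil[[e]], attr(soil, paste0("mu_", e)), tolerance = 1e-12)
  }
  # same geology, effectively constant MAT, increasing MAP, no noise:
  # positive MAP slope means soil N strictly increases along the sites
  flat <- data.frame(site = sprintf("F%02d", 1:8), geology = "basalt",
                     MAT = 20 + 1e-9 * (1:8), MAP = seq(1500, 3600, length.out = 8))
  truth2 <- truth
  truth2$soil$coef[, c("MAT", "MAT2", "MAP2")] <- 0
  soil2 <- generate_soil(flat, truth2, seed = 2)
  expect_true(all(diff(soil2$N) > 0))
})

test_that("soil residual noise has the configured spread", {
  truth <- default_true_parameters()
  truth$soil$sigma[] <- 1
  sites <- generate_sites(landscape_config(n_sites = 500, seed = 11))
  soil <- generate_soil(sites, truth, seed = 13)
  resid <- soil$N - attr(soil, "mu_N")
  expect_gt(sd(resid), 0.9)
  expect_lt(sd(resid), 1.1)
})

test_that("tree generation honours the sampling plan and the degenerate model", {
  cfg <- landscape_config(seed = 21)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$trees), 115 + 22 + 42)
  expect_equal(as.numeric(table(ds$trees$species)[default_species_plan()$species]),
               c(115, 22, 42))
  # late-successional species occupy a strict subset of sites
  expect_lt(length(unique(ds$trees$site[ds$trees$species == "Flindersia_brayleyana"])),
            length(unique(ds$trees$site[ds$trees$species == "Alphitonia_petriei"])))

  plan1 <- data.frame(species = "Solo_species", genus = "Solo", n_trees = 30L,
                      site_coverage = 1, stringsAsFactors = FALSE)
  truth1 <- default_true_parameters(species_plan = plan1)
  truth1$foliage$totalN$slopes[] <- 0
  truth1$foliage$totalN$sigma <- 0
  truth1$foliage$totalN$site_sd <- 0
  sites <- generate_sites(landscape_config(n_sites = 5, seed = 3,
                                           species_plan = plan1))
  soil <- generate_soil(sites, truth1, seed = 4)
  trees <- generate_trees(sites, soil, truth1, plan1, seed = 5)
  expect_equal(trees$totalN, rep(unname(truth1$foliage$totalN$intercept), 30))
})

test_that("site random effects produce the configured between-site spread", {
  plan <- data.frame(species = "Solo_species", genus = "Solo", n_trees = 5000L,
                     site_coverage = 1, stringsAsFactors = FALSE)
  truth <- default_true_parameters(species_plan = plan)
  truth$foliage$totalN$slopes[] <- 0
  truth$foliage$totalN$sigma <- 0
  truth$foliage$totalN$site_sd <- 2
  sites <- generate_sites(landscape_config(n_sites = 100, seed = 6, species_plan = plan))
  soil <- generate_soil(sites, truth, seed = 7)
  trees <- generate_trees(sites, soil, truth, plan, seed = 8)
  site_means <- tapply(trees$totalN, trees$site, mean)
  expect_gt(sd(site_means), 2 * 0.8)
  expect_lt(sd(site_means), 2 * 1.2)
})

test_that("herbivory damage follows the mean-precision beta model", {
  ds <- tiny_model_data()$ds
  # flat model: logit mean 0 everywhere -> expected damage exactly 1/2
  truth0 <- ds$truth
  truth0$herbivory$intercept[] <- 0
  truth0$herbivory$slopes[] <- 0
  truth0$herbivory$site_sd <- 0
  flat <- generate_herbivory(ds$trees, ds$soil, ds$sites, truth0,
                             leaves_per_tree = 5, seed = 1)
  expect_equal(unname(attr(flat, "mu")), rep(0.5, nrow(ds$trees)))

  # enormous precision collapses within-tree variation
  truth0$herbivory$phi <- 1e6
  tight <- generate_herbivory(ds$trees, ds$soil, ds$sites, truth0,
                              leaves_per_tree = 20, seed = 2)
  expect_lt(max(tapply(tight$damage, tight$tree, sd)), 1e-2)

  # mu = 0.04, phi = 50: the sample mean over 1e5 leaves sits within 0.002
  truth4 <- truth0
  truth4$herbivory$intercept[] <- qlogis(0.04)
  truth4$herbivory$phi <- 50
  many <- generate_herbivory(ds$trees[1:10, ], ds$soil, ds$sites, truth4,
                             leaves_per_tree = 10000, seed = 3)
  expect_lt(abs(mean(many$damage) - 0.04), 0.002)
  expect_true(all(many$damage > 0 & many$damage < 1))
})

test_that("composed datasets validate, repeat under a seed, and have the right shape", {
  cfg <- landscape_config(seed = 31)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_true(validate_dataset(ds1))
  expect_identical(ds1$sites, ds2$sites)
  expect_identical(ds1$leaves, ds2$leaves)
  expect_equal(nrow(ds1$leaves), (115 + 22 + 42) * 20)

  dir <- withr::local_tempdir()
  write_dataset_csv(ds1, dir)
  rt <- read_dataset_csv(dir)
  expect_equal(rt$soil$N, ds1$soil$N, tolerance = 1e-12)
  expect_equal(rt$leaves$damage, ds1$leaves$damage, tolerance = 1e-12)
  expect_identical(rt$trees$species, ds1$trees$species)
})
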