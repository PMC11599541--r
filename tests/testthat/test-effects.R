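# parameter names with the full naming structure, without running a sampler
effect_par_names <- function() tiny_model_data()$d$par_names

test_that("effect summaries report means and equal-tailed intervals", {
  nm <- effect_par_names()
  const <- make_draws(nm, values = list(soil_N_MAP = 0.7))
  s <- summarize_effect(const, "soil_N_MAP")
  expect_equal(s$mean, 0.7)
  expect_equal(c(s$lower, s$upper), c(0.7, 0.7))
  expect_true(s$excludes_zero)
  s0 <- summarize_effect(const, "soil_P_MAP")  # all-zero draws
  expect_false(s0$excludes_zero)

  grid <- make_draws(nm, n = 500)
  grid$draws[, , "soil_K_MAT"] <- matrix(1:1000, 500, 2)
  g <- summarize_effect(grid, "soil_K_MAT")
  expect_equal(c(g$lower, g$upper), quantile_brute(1:1000, c(0.055, 0.945)))
  expect_equal(g$mean, mean(1:1000))

  sym <- make_draws(nm, n = 500)
  sym$draws[, , "soil_Na_MAT"] <- matrix(c(-(1:500), 1:500), 500, 2)
  expect_false(summarize_effect(sym, "soil_Na_MAT")$excludes_zero)

  expect_error(summarize_effect(const, "not_a_parameter"), "unknown parameter")
})

test_that("indirect effects are draw-wise products along valid chains", {
  nm <- effect_par_names()
  dr <- make_draws(nm, values = list(soil_CN_MAP = 2,
                                     herb_Flindersia_soil_CN = 3))
  pe <- indirect_effect(dr, c("MAP", "soil_CN", "herb:Flindersia"))
  expect_equal(pe$coefficients, c("soil_CN_MAP", "herb_Flindersia_soil_CN"))
  expect_equal(unique(pe$draws), 6)
  expect_equal(pe$summary$mean, 6)

  # a zero coefficient annihilates the whole path
  pe0 <- indirect_effect(dr, c("MAT", "soil_CN", "herb:Flindersia"))
  expect_true(all(pe0$draws == 0))
  expect_false(pe0$summary$excludes_zero)

  # genus mismatch along foliage -> herbivory is a broken chain
  expect_error(
    indirect_effect(dr, c("MAT", "fol_totalN:Alphitonia", "herb:Flindersia")),
    "broken chain")
  expect_error(indirect_effect(dr, c("soil_CN", "MAP")), "unknown node|no edge")

  # Monte Carlo: independent normal coefficients multiply to ab on average
  set.seed(5)
  mc <- make_draws(nm, n = 3000)
  mc$draws[, , "soil_CN_MAP"] <- rnorm(6000, 2, 0.1)
  mc$draws[, , "herb_Flindersia_soil_CN"] <- rnorm(6000, 3, 0.1)
  pm <- indirect_effect(mc, c("MAP", "soil_CN", "herb:Flindersia"))
  se <- sd(pm$draws) / sqrt(length(pm$draws))
  expect_lt(abs(pm$summary$mean - 6), 3 * se)

  # single-edge path is identical to the plain summary
  one <- indirect_effect(mc, c("MAP", "soil_CN"))
  expect_equal(one$summary[, c("mean", "lower", "upper")],
               summarize_effect(mc, "soil_CN_MAP")[, c("mean", "lower", "upper")])
})

test_that("path products always equal the brute-force elementwise product", {
  nm <- effect_par_names()
  set.seed(6)
  for (k in 1:5) {
    dr <- make_draws(nm, n = 50)
    edges <- c("fol_Ndig_Flindersia_soil_P", "herb_Flindersia_fol_Ndig")
    for (e in edges) dr$draws[, , e] <- rnorm(100)
    pe <- indirect_effect(dr, c("soil_P", "fol_Ndig:Flindersia", "herb:Flindersia"))
    brute <- as.numeric(dr$draws[, , edges[1]]) * as.numeric(dr$draws[, , edges[2]])
    expect_equal(pe$draws, brute)
  }
})

test_that("genus contrasts difference the two genus slopes draw by draw", {
  nm <- effect_par_names()
  dr <- make_draws(nm, values = list(fol_Ndig_Alphitonia_soil_Na = 0.2,
                                     fol_Ndig_Flindersia_soil_Na = 0.5))
  gc <- genus_contrast(dr, "soil_Na", "Ndig")
  expect_equal(gc$mean, 0.3)
  expect_true(gc$excludes_zero)
  same <- make_draws(nm, values = list(herb_Alphitonia_MAT = 0.4,
                                       herb_Flindersia_MAT = 0.4))
  gc0 <- genus_contrast(same, "MAT", "herb")
  expect_equal(gc0$mean, 0)
  expect_false(gc0$excludes_zero)
})

test_that("the path graph retains planted chains and stays acyclic", {
  nm <- effect_par_names()
  set.seed(7)
  dr <- make_draws(nm, n = 500)
  # weak noise on every coefficient, a strong planted two-edge chain
  for (p in nm) dr$draws[, , p] <- rnorm(1000, 0, 0.02)
  dr$draws[, , "soil_CN_MAP"] <- rnorm(1000, -0.7, 0.05)
  dr$draws[, , "herb_Flindersia_soil_CN"] <- rnorm(1000, -0.6, 0.05)
  g <- build_path_graph(dr)
  expect_true("soil_CN_MAP" %in% g$edges$coefficient)
  planted <- vapply(g$paths, function(p) {
    identical(p$nodes, c("MAP", "soil_CN", "herb:Flindersia"))
  }, logical(1))
  expect_true(any(planted))
  expect_true(g$paths[[which(planted)[1]]]$summary$excludes_zero)

  # edges only ever point down the tier ordering
  rank_of <- function(x) {
    ifelse(grepl("^soil_", x), 2, ifelse(grepl("^fol_", x), 3,
      ifelse(grepl("^herb", x), 4, 1)))
  }
  expect_true(all(rank_of(g$all_edges$from) < rank_of(g$all_edges$to)))
})

test_that("89% intervals are calibrated over repeated simulate-fit rounds", {
  hits <- 0
  total <- 0
  for (i in 1:20) {
    af <- acceptance_fit(i)
    tv <- true_parameter_vector(af$ds$truth, af$d)
    coefs <- names(tv)[attr(tv, "kind") == "coef"]
    s <- summarize_effects(af$fit, coefs)
    truth <- tv[s$parameter]
    hits <- hits + sum(truth >= s$lower & truth <= s$upper)
    total <- total + nrow(s)
  }
  coverage <- hits / total
  expect_gte(coverage, 0.75)
  expect_lte(coverage, 0.97)
})

test_that("a zero-effect landscape keeps near-nominal edge retention", {
  truth0 <- default_true_parameters()
  truth0$soil$coef[, -1] <- 0
  for (r in truth0$responses) truth0$foliage[[r]]$slopes[] <- 0
  truth0$herbivory$slopes[] <- 0
  ds <- generate_dataset(landscape_config(seed = 77), truth0)
  d <- prepare_model_data(ds$sites, ds$soil, ds$trees, ds$leaves)
  fit <- run_mcmc(d, desk_schedule(seed = 707))
  g <- build_path_graph(fit)
  # about 11% of null edges may exclude zero at the 89% level; allow
  # binomial noise on top of that expectation
  expect_lt(nrow(g$edges) / nrow(g$all_edges), 0.2)
})
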