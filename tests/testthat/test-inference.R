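test_that("retained-draw bookkeeping follows the schedule exactly", {
  expect_equal(retained_draw_count(chain_schedule(3, 400000, 0.5, 100)), 6000)
  expect_equal(retained_draw_count(chain_schedule(1, 200, 0.5, 1)), 100)
  expect_equal(retained_draw_count(chain_schedule(2, 1000, 0.5, 10)), 100)

  # property: sampled draws match the floor formula for arbitrary schedules
  set.seed(10)
  target <- function(x) dnorm(x, log = TRUE)
  for (k in 1:8) {
    sc <- chain_schedule(n_chains = sample(1:3, 1),
                         n_iterations = sample(50:300, 1),
                         burn_in = runif(1, 0, 0.9),
                         thinning = sample(1:7, 1),
                         seeds = NULL)
    fit <- run_mcmc(target, sc, init = 0)
    expect_equal(dim(fit$draws)[1] * dim(fit$draws)[2],
                 retained_draw_count(sc))
  }
})

test_that("schedule validation enforces its invariants", {
  expect_error(chain_schedule(burn_in = 1), "burn_in")
  expect_error(chain_schedule(thinning = 0), "thinning")
  expect_error(chain_schedule(seeds = 1:2), "one seed per chain")
})

test_that("Gelman-Rubin matches its closed form and detects divergence", {
  two_chains <- function(a, b) {
    arr <- array(c(a, b), dim = c(length(a), 2, 1),
                 dimnames = list(NULL, c("chain1", "chain2"), "x"))
    structure(list(draws = arr,
                   schedule = chain_schedule(2, length(a), 0, 1, seeds = 1:2),
                   par_info = data.frame(name = "x", tier = "t", kind = "coef")),
              class = "hbm_draws")
  }
  same <- two_chains(c(1:3, rep(c(1, 2, 3), 3)), c(1:3, rep(c(1, 2, 3), 3)))
  expect_equal(gelman_rubin(same, "x"), sqrt((12 - 1) / 12), tolerance = 1e-12)
  # the canonical 3-draw case evaluates the same closed form sqrt((n-1)/n)
  tiny <- two_chains(1:3, 1:3)
  expect_error(gelman_rubin(tiny, "x"), "at least 10")
  set.seed(1)
  apart <- two_chains(rnorm(50, 0), rnorm(50, 100))
  expect_gt(gelman_rubin(apart, "x"), 10)
  expect_error(gelman_rubin(structure(list(draws = array(1, c(20, 1, 1),
                                                         dimnames = list(NULL, "chain1", "x"))),
                                      class = "hbm_draws"), "x"),
               "2 chains")

  # long chains from one normal target converge by the R-hat - 1 < 0.1 rule
  fit <- run_mcmc(function(x) dnorm(x, log = TRUE),
                  chain_schedule(3, 4000, 0.5, 1, seeds = 11:13), init = 0)
  expect_lt(gelman_rubin(fit, "par1") - 1, 0.1)
})

test_that("the adaptive kernel samples simple targets to Monte Carlo accuracy", {
  set.seed(2)
  draws <- adaptive_mh(function(x) dnorm(x, log = TRUE), init = 0,
                       n_iterations = 20000, burn_in = 0.5)
  x <- draws[, 1]
  expect_lt(abs(mean(x)), 3 * mcse_mean(x))
  expect_error(adaptive_mh(function(x) -Inf, init = 0), "finite")
})

test_that("the reference sampler reproduces conjugate posteriors", {
  # Normal mean with known variance
  set.seed(3)
  y <- rnorm(20, 1.7, 2)
  m0 <- 1; s0 <- 3; sig <- 2
  s1 <- sqrt(1 / (1 / s0^2 + length(y) / sig^2))
  m1 <- s1^2 * (m0 / s0^2 + sum(y) / sig^2)
  target <- function(th) sum(dnorm(y, th, sig, log = TRUE)) + dnorm(th, m0, s0, log = TRUE)
  fit <- run_mcmc(target, chain_schedule(2, 20000, 0.5, 1, seeds = 21:22), init = 0)
  x <- as.numeric(as_draws_matrix(fit))
  expect_lt(abs(mean(x) - m1), 3 * mcse_mean(x))
  expect_lt(abs(sd(x) - s1), 3 * sd(x) / sqrt(length(x) / 20))

  # beta-binomial proportion
  n <- 25; succ <- 7; a <- 2; b <- 2
  post_mean <- (a + succ) / (a + b + n)
  post_sd <- sqrt((a + succ) * (b + n - succ) /
                    ((a + b + n)^2 * (a + b + n + 1)))
  targ <- function(p) {
    if (p <= 0 || p >= 1) return(-Inf)
    dbinom(succ, n, p, log = TRUE) + dbeta(p, a, b, log = TRUE)
  }
  fitp <- run_mcmc(targ, chain_schedule(2, 20000, 0.5, 1, seeds = 31:32),
                   init = 0.3, step = 0.2)
  p <- as.numeric(as_draws_matrix(fitp))
  expect_lt(abs(mean(p) - post_mean), 3 * mcse_mean(p))
  expect_lt(abs(sd(p) - post_sd), 3 * sd(p) / sqrt(length(p) / 20))
})

test_that("chains are reproducible from their seeds", {
  sc <- chain_schedule(2, 500, 0.5, 2, seeds = c(41, 42))
  f1 <- run_mcmc(function(x) dnorm(x, log = TRUE), sc, init = 0)
  f2 <- run_mcmc(function(x) dnorm(x, log = TRUE), sc, init = 0)
  expect_identical(f1$draws, f2$draws)

  td <- tiny_model_data()
  sc2 <- chain_schedule(2, 400, 0.5, 4, seeds = c(51, 52))
  g1 <- run_mcmc(td$d, sc2)
  g2 <- run_mcmc(td$d, sc2)
  expect_identical(g1$draws, g2$draws)
  expect_equal(dim(g1$draws)[1] * dim(g1$draws)[2], retained_draw_count(sc2))
  # positivity of scale draws
  m <- as_draws_matrix(g1)
  sds <- grepl("(_sigma$|_site_sd$)", colnames(m)) | colnames(m) == "herb_phi"
  expect_true(all(m[, sds] > 0))

  # draws survive a CSV round trip with schedule provenance
  f <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(g1, f)
  back <- read_draws_csv(f)
  expect_equal(unname(back$draws), unname(g1$draws), tolerance = 1e-12)
  expect_equal(back$schedule$seeds, g1$schedule$seeds)
  expect_equal(dimnames(back$draws)[[3]], dimnames(g1$draws)[[3]])
})

test_that("tied discrepancies give a Bayesian p-value of one", {
  expect_equal(bayesian_p(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(bayesian_p(c(1, 2), c(0, 3)), 0.5)
})
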