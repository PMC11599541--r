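# Independent oracles used across the suite. These deliberately re-derive
# quantities with naive per-observation loops or closed forms, never through
# the code paths they check.

# naive per-observation log-likelihood of the three-tier model
ll_brute <- function(params, data) {
  spec <- data$spec
  total <- 0
  for (e in spec$elements) {
    beta <- params[paste0("soil_", e, "_", colnames(data$X_site))]
    sig <- params[[paste0("soil_", e, "_sigma")]]
    for (i in seq_len(nrow(data$X_site))) {
      mu <- sum(data$X_site[i, ] * beta)
      total <- total + dnorm(data$Y_soil[i, e], mu, sig, log = TRUE)
    }
  }
  for (r in spec$responses) {
    beta <- params[paste0("fol_", r, "_", colnames(data$X_fol))]
    sig <- params[[paste0("fol_", r, "_sigma")]]
    u <- params[paste0("fol_", r, "_u_", data$sites$site)]
    for (i in seq_len(nrow(data$X_fol))) {
      mu <- sum(data$X_fol[i, ] * beta) + u[[data$site_index[i]]]
      total <- total + dnorm(data$Y_fol[i, r], mu, sig, log = TRUE)
    }
  }
  beta <- params[paste0("herb_", colnames(data$X_herb))]
  u <- params[paste0("herb_u_", data$sites$site)]
  phi <- params[["herb_phi"]]
  for (i in seq_len(nrow(data$X_herb))) {
    mu <- plogis(sum(data$X_herb[i, ] * beta) + u[[data$site_index[i]]])
    total <- total + dbeta(data$y_damage[i], mu * phi, (1 - mu) * phi, log = TRUE)
  }
  unname(total)
}

# type-7 sample quantile computed by hand from the sorted values
quantile_brute <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  sapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    if (lo >= n) return(xs[n])
    xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
  })
}

# Monte Carlo standard error of a chain mean via batch means
mcse_mean <- function(x, n_batches = 30) {
  b <- floor(length(x) / n_batches)
  bm <- sapply(seq_len(n_batches), function(k) mean(x[((k - 1) * b + 1):(k * b)]))
  sd(bm) / sqrt(n_batches)
}

# a small dataset + prepared model data, cached per session
tiny_model_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      plan <- default_species_plan()
      plan$n_trees <- c(12L, 5L, 8L)
      cfg <- landscape_config(n_sites = 6, species_plan = plan,
                              leaves_per_tree = 12, seed = 42)
      ds <- generate_dataset(cfg)
      cache <<- list(ds = ds,
                     d = prepare_model_data(ds$sites, ds$soil, ds$trees, ds$leaves))
    }
    cache
  }
})

# a full parameter vector (coefficients + sds + site effects) for a dataset
full_params <- function(ds, d, seed = 1) {
  set.seed(seed)
  tv <- true_parameter_vector(ds$truth, d)
  u <- c()
  for (r in d$spec$responses) {
    u <- c(u, setNames(rnorm(nrow(d$sites), 0, 0.1),
                       paste0("fol_", r, "_u_", d$sites$site)))
  }
  u <- c(u, setNames(rnorm(nrow(d$sites), 0, 0.1),
                     paste0("herb_u_", d$sites$site)))
  c(tv, u)
}

# hand-built draws object with the naming structure of a real fit
make_draws <- function(par_names, values = list(), n = 200, n_chains = 2,
                       fill = 0) {
  arr <- array(fill, dim = c(n, n_chains, length(par_names)),
               dimnames = list(NULL, paste0("chain", seq_len(n_chains)), par_names))
  for (nm in names(values)) {
    v <- values[[nm]]
    arr[, , nm] <- matrix(rep_len(v, n * n_chains), n, n_chains)
  }
  structure(list(draws = arr,
                 schedule = chain_schedule(n_chains, n, 0, 1,
                                           seeds = seq_len(n_chains)),
                 par_info = data.frame(name = par_names, tier = "any",
                                       kind = "coef", stringsAsFactors = FALSE)),
            class = "hbm_draws")
}
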