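#' Chain schedule for posterior sampling
#'
#' @param n_chains number of parallel chains (at least 2 for convergence
#'   diagnostics; default 3).
#' @param n_iterations iterations per chain (default 400000, the full
#'   production schedule; see [desk_schedule()] for a lighter one).
#' @param burn_in fraction of iterations discarded as burn-in, in `[0, 1)`
#'   (default 0.5).
#' @param thinning keep every `thinning`-th post-burn-in iteration (default
#'   100).
#' @param seeds integer seed per chain; defaults to `100 + 1:n_chains`.
#' @return object of class `chain_schedule`.
#' @export
chain_schedule <- function(n_chains = 3, n_iterations = 400000, burn_in = 0.5,
                           thinning = 100, seeds = NULL) {
  if (n_chains < 1) stop("need at least one chain")
  if (burn_in < 0 || burn_in >= 1) stop("burn_in must lie in [0, 1)")
  if (thinning < 1) stop("thinning must be >= 1")
  if (is.null(seeds)) seeds <- 100L + seq_len(n_chains)
  if (length(seeds) != n_chains) stop("need one seed per chain")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = burn_in, thinning = as.integer(thinning),
                 seeds = as.integer(seeds)),
            class = "chain_schedule")
}

#' Desk-scale chain schedule
#'
#' A light schedule (3 chains of 20000 iterations, half burn-in, thinning
#' 10) suitable for simulation studies and tests; the production default in
#' [chain_schedule()] is 3 chains of 400000 thinned by 100.
#'
#' @param seed base seed; per-chain seeds are `seed + 1:n_chains`.
#' @param n_chains,n_iterations,burn_in,thinning as in [chain_schedule()].
#' @return a `chain_schedule`.
#' @export
desk_schedule <- function(seed = 1, n_chains = 3, n_iterations = 20000,
                          burn_in = 0.5, thinning = 10) {
  chain_schedule(n_chains, n_iterations, burn_in, thinning,
                 seeds = as.integer(seed) + seq_len(n_chains))
}

#' Total retained draws implied by a chain schedule
#'
#' `n_chains * floor(n_iterations * (1 - burn_in) / thinning)`.
#'
#' @param schedule a [chain_schedule()].
#' @return integer draw count.
#' @examples
#' retained_draw_count(chain_schedule(3, 400000, 0.5, 100)) # 6000
#' @export
retained_draw_count <- function(schedule) {
  stopifnot(inherits(schedule, "chain_schedule"))
  schedule$n_chains *
    floor(schedule$n_iterations * (1 - schedule$burn_in) / schedule$thinning)
}

.keep_per_chain <- function(schedule) {
  floor(schedule$n_iterations * (1 - schedule$burn_in) / schedule$thinning)
}

#' Component-wise adaptive random-walk Metropolis sampler
#'
#' The scalar kernel used throughout the package's Metropolis-within-Gibbs
#' sweep, exposed for arbitrary log-targets: each coordinate is updated in
#' turn with a Gaussian random-walk proposal whose step size adapts towards a
#' 0.44 acceptance rate in batches of 50 iterations during burn-in only, so
#' retained draws come from a fixed kernel.
#'
#' @param log_target function taking a numeric vector, returning a scalar
#'   log-density (`-Inf` allowed outside the support).
#' @param init numeric starting vector with finite log-target.
#' @param n_iterations,burn_in,thinning schedule for this single chain.
#' @param step initial proposal sd (scalar or per-coordinate).
#' @return matrix of retained draws (rows) by coordinates (columns).
#' @export
adaptive_mh <- function(log_target, init, n_iterations = 10000, burn_in = 0.5,
                        thinning = 1, step = 0.5) {
  d <- length(init)
  x <- as.numeric(init)
  lp <- log_target(x)
  if (!is.finite(lp)) stop("log target not finite at the initial value")
  ls <- rep_len(log(step), d)
  acc <- integer(d)
  n_burn <- n_iterations - floor(n_iterations * (1 - burn_in) / thinning) * thinning
  keep <- (n_iterations - n_burn) %/% thinning
  out <- matrix(NA_real_, keep, d)
  colnames(out) <- names(init)
  kept <- 0L
  batch <- 0L
  for (it in seq_len(n_iterations)) {
    for (j in seq_len(d)) {
      prop <- x
      prop[j] <- x[j] + exp(ls[j]) * stats::rnorm(1)
      lpp <- log_target(prop)
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
        x <- prop
        lp <- lpp
        acc[j] <- acc[j] + 1L
      }
    }
    if (it <= n_burn && it %% 50 == 0) {
      batch <- batch + 1L
      delta <- min(0.1, 1 / sqrt(batch))
      ls <- ls + ifelse(acc / 50 > 0.44, delta, -delta)
      acc[] <- 0L
    }
    if (it > n_burn && (it - n_burn) %% thinning == 0) {
      kept <- kept + 1L
      out[kept, ] <- x
    }
  }
  out
}

#' Sample the joint posterior
#'
#' `run_mcmc()` is generic: applied to an [prepare_model_data()] object it
#' runs the package's compiled Metropolis-within-Gibbs sampler on the full
#' three-tier model; applied to a function it treats the function as a
#' log-target and runs the reference [adaptive_mh()] kernel (useful for toy
#' targets and oracle checks). Each chain is seeded separately and
#' initialized with chain-specific overdispersion, and is fully reproducible
#' from its seed.
#'
#' @param model an `hbm_data` object or a log-target function.
#' @param schedule a [chain_schedule()].
#' @param ... passed on to methods (`init` for the function method).
#' @return object of class `hbm_draws`: a list with `draws` (array of
#'   retained iterations x chains x parameters), `schedule` and `par_info`.
#' @export
run_mcmc <- function(model, schedule, ...) UseMethod("run_mcmc")

#' @rdname run_mcmc
#' @param init starting vector for the function method.
#' @param step initial proposal sd for the function method.
#' @export
run_mcmc.function <- function(model, schedule, init, step = 0.5, ...) {
  stopifnot(inherits(schedule, "chain_schedule"))
  chains <- vector("list", schedule$n_chains)
  for (c in seq_len(schedule$n_chains)) {
    set.seed(schedule$seeds[c])
    start <- init + 0.5 * stats::rnorm(length(init))
    if (!is.finite(model(start))) start <- init
    chains[[c]] <- adaptive_mh(model, start, schedule$n_iterations,
                               schedule$burn_in, schedule$thinning, step)
  }
  nm <- colnames(chains[[1]])
  if (is.null(nm)) nm <- paste0("par", seq_len(ncol(chains[[1]])))
  .new_draws(chains, nm, schedule,
             par_info = data.frame(name = nm, tier = "target", kind = "coef",
                                   stringsAsFactors = FALSE))
}

#' @rdname run_mcmc
#' @export
run_mcmc.hbm_data <- function(model, schedule, ...) {
  data <- model
  stopifnot(inherits(schedule, "chain_schedule"))
  keep <- .keep_per_chain(schedule)
  n_burn <- schedule$n_iterations - keep * schedule$thinning
  chains <- vector("list", schedule$n_chains)
  for (c in seq_len(schedule$n_chains)) {
    set.seed(schedule$seeds[c])
    init <- .init_chain(data)
    v <- .init_to_vector(init, data)
    lp <- log_posterior(v, data)
    if (!is.finite(lp)) {
      stop("non-finite log-posterior at initialization of chain ", c,
           " (seed ", schedule$seeds[c], "); check the data for damage values",
           " on the unit-interval boundary or degenerate predictors")
    }
    chains[[c]] <- hbm_sample_chain(
      data$X_site, data$Y_soil, data$X_fol, data$Y_fol, data$X_herb,
      data$y_damage, data$site_index - 1L, nrow(data$sites),
      schedule$n_iterations, n_burn, schedule$thinning,
      data$spec$priors$coef_sd, data$spec$priors$sd_scale,
      data$spec$priors$phi_shape, data$spec$priors$phi_rate, init)
  }
  .new_draws(chains, data$par_names, schedule, data$par_info)
}

.new_draws <- function(chains, par_names, schedule, par_info) {
  keep <- nrow(chains[[1]])
  arr <- array(NA_real_, dim = c(keep, length(chains), length(par_names)),
               dimnames = list(NULL, paste0("chain", seq_along(chains)), par_names))
  for (c in seq_along(chains)) arr[, c, ] <- chains[[c]]
  structure(list(draws = arr, schedule = schedule, par_info = par_info),
            class = "hbm_draws")
}

# Overdispersed chain-specific starting values built from rough least-squares
# fits; consumes the chain's RNG stream so chains differ deterministically.
.init_chain <- function(data) {
  ols <- function(X, y) {
    b <- stats::lm.fit(X, y)$coefficients
    b[is.na(b)] <- 0
    b
  }
  ne <- length(data$spec$elements)
  nr <- length(data$spec$responses)
  ns <- nrow(data$sites)
  soil_beta <- matrix(0, ncol(data$X_site), ne)
  soil_sigma <- numeric(ne)
  for (e in seq_len(ne)) {
    b <- ols(data$X_site, data$Y_soil[, e])
    soil_beta[, e] <- b + 0.5 * stats::rnorm(length(b))
    soil_sigma[e] <- max(stats::sd(data$Y_soil[, e] - data$X_site %*% b), 0.05) *
      exp(stats::rnorm(1, 0, 0.3))
  }
  fol_beta <- matrix(0, ncol(data$X_fol), nr)
  fol_sigma <- numeric(nr)
  for (r in seq_len(nr)) {
    b <- ols(data$X_fol, data$Y_fol[, r])
    fol_beta[, r] <- b + 0.3 * stats::rnorm(length(b))
    fol_sigma[r] <- max(stats::sd(data$Y_fol[, r] - data$X_fol %*% b), 0.02) *
      exp(stats::rnorm(1, 0, 0.3))
  }
  y <- data$y_damage
  herb_beta <- 0.2 * stats::rnorm(ncol(data$X_herb))
  nsp <- length(data$spec$species)
  for (k in seq_len(nsp)) {
    sel <- data$X_herb[, k] == 1
    herb_beta[k] <- stats::qlogis(mean(y[sel])) + stats::rnorm(1, 0, 0.3)
  }
  mu0 <- mean(y)
  phi0 <- max(mu0 * (1 - mu0) / stats::var(y) - 1, 2)
  list(soil_beta = soil_beta, soil_sigma = soil_sigma,
       fol_beta = fol_beta, fol_sigma = fol_sigma,
       fol_site_sd = rep(0.2, nr) * exp(stats::rnorm(nr, 0, 0.3)),
       fol_u = matrix(0, ns, nr),
       herb_beta = herb_beta, herb_u = rep(0, ns),
       herb_site_sd = 0.2 * exp(stats::rnorm(1, 0, 0.3)),
       herb_phi = min(phi0 * exp(stats::rnorm(1, 0, 0.3)), 1e4))
}

.init_to_vector <- function(init, data) {
  spec <- data$spec
  out <- numeric(0)
  for (e in seq_along(spec$elements)) {
    out <- c(out, init$soil_beta[, e], init$soil_sigma[e])
  }
  for (r in seq_along(spec$responses)) {
    out <- c(out, init$fol_beta[, r], init$fol_sigma[r], init$fol_site_sd[r],
             init$fol_u[, r])
  }
  out <- c(out, init$herb_beta, init$herb_site_sd, init$herb_u, init$herb_phi)
  stats::setNames(out, data$par_names)
}

#' Write posterior draws to a CSV file (with schedule provenance)
#'
#' One row per retained iteration per chain, columns `chain`, `iteration`
#' and one per parameter; the chain schedule and seeds are stored in a
#' comment header so [read_draws_csv()] can restore them.
#'
#' @param draws an `hbm_draws`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(draws, path) {
  stopifnot(inherits(draws, "hbm_draws"))
  sc <- draws$schedule
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# schedule chains=%d iterations=%d burn_in=%g thinning=%d seeds=%s",
                     sc$n_chains, sc$n_iterations, sc$burn_in, sc$thinning,
                     paste(sc$seeds, collapse = ";")), con)
  a <- draws$draws
  tab <- data.frame(chain = rep(seq_len(dim(a)[2]), each = dim(a)[1]),
                    iteration = rep(seq_len(dim(a)[1]), times = dim(a)[2]))
  tab <- cbind(tab, as.data.frame(as_draws_matrix(draws)))
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_draws_csv()]
#'
#' @param path CSV file.
#' @return an `hbm_draws` (parameter kinds re-derived from the names).
#' @export
read_draws_csv <- function(path) {
  header <- readLines(path, n = 1)
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  par_names <- setdiff(names(tab), c("chain", "iteration"))
  chains <- lapply(sort(unique(tab$chain)), function(c) {
    as.matrix(tab[tab$chain == c, par_names, drop = FALSE])
  })
  fields <- regmatches(header, gregexpr("[a-z_]+=[0-9.;]+", header))[[1]]
  kv <- strsplit(fields, "=")
  vals <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, 1, FUN.VALUE = ""))
  sc <- chain_schedule(as.integer(vals$chains), as.integer(vals$iterations),
                       as.numeric(vals$burn_in), as.integer(vals$thinning),
                       seeds = as.integer(strsplit(vals$seeds, ";")[[1]]))
  kind <- ifelse(grepl("_sigma$", par_names), "sigma",
          ifelse(grepl("_site_sd$", par_names), "site_sd",
          ifelse(grepl("_u_", par_names), "u",
          ifelse(par_names == "herb_phi", "phi", "coef"))))
  tier <- ifelse(grepl("^soil_", par_names), "soil",
          ifelse(grepl("^fol_", par_names), "foliage", "herbivory"))
  .new_draws(chains, par_names, sc,
             data.frame(name = par_names, tier = tier, kind = kind,
                        stringsAsFactors = FALSE))
}

#' Flatten posterior draws into a matrix
#'
#' @param draws an `hbm_draws`.
#' @return matrix with one row per retained draw (chains stacked) and one
#'   column per parameter.
#' @export
as_draws_matrix <- function(draws) {
  stopifnot(inherits(draws, "hbm_draws"))
  a <- draws$draws
  m <- do.call(rbind, lapply(seq_len(dim(a)[2]),
                             function(c) matrix(a[, c, ], nrow = dim(a)[1])))
  colnames(m) <- dimnames(a)[[3]]
  m
}

#' Extract the pooled draws of one parameter
#'
#' @param draws an `hbm_draws`.
#' @param parameter parameter name.
#' @return numeric vector of draws (all chains).
#' @export
draws_of <- function(draws, parameter) {
  a <- draws$draws
  if (!parameter %in% dimnames(a)[[3]]) {
    stop("unknown parameter `", parameter, "`")
  }
  as.numeric(a[, , parameter])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic (non-split, non-rank-normalized) diagnostic: with `m` chains
#' of length `n`, within-chain variance `W` and between-chain variance `B`,
#' \eqn{\hat R = \sqrt{((n-1)/n \, W + B/n) / W}}. Values with
#' \eqn{\hat R - 1 < 0.1} are taken as converged. `split = TRUE` halves each
#' chain first.
#'
#' @param draws an `hbm_draws` (at least 2 chains, 10 retained draws each).
#' @param parameter parameter name.
#' @param split split each chain in half before computing (default FALSE).
#' @return scalar R-hat.
#' @export
gelman_rubin <- function(draws, parameter, split = FALSE) {
  stopifnot(inherits(draws, "hbm_draws"))
  a <- draws$draws
  if (dim(a)[2] < 2) stop("convergence diagnostics need at least 2 chains")
  if (dim(a)[1] < 10) stop("need at least 10 retained draws per chain")
  x <- a[, , parameter, drop = TRUE]
  if (split) {
    n <- nrow(x)
    h <- n %/% 2
    x <- cbind(x[seq_len(h), , drop = FALSE],
               x[(n - h + 1):n, , drop = FALSE])
  }
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B_over_n <- stats::var(colMeans(x))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' R-hat for many parameters at once
#'
#' @inheritParams gelman_rubin
#' @param parameters parameter names (default all).
#' @return named numeric vector of R-hat values.
#' @export
rhat <- function(draws, parameters = NULL, split = FALSE) {
  if (is.null(parameters)) parameters <- dimnames(draws$draws)[[3]]
  vapply(parameters, function(p) gelman_rubin(draws, p, split), numeric(1))
}

#' Bayesian p-value from paired discrepancies
#'
#' Fraction of draws whose replicated discrepancy is at least the observed
#' one; ties count as exceedance, so identical pairs give 1.
#'
#' @param rss_obs,rss_rep numeric vectors of observed and replicated
#'   discrepancies, one per retained draw.
#' @return scalar in `[0, 1]`.
#' @export
bayesian_p <- function(rss_obs, rss_rep) {
  stopifnot(length(rss_obs) == length(rss_rep), length(rss_obs) > 0)
  mean(rss_rep >= rss_obs)
}

#' Posterior-predictive check via residual sums of squares
#'
#' For each retained draw, computes the residual sum of squares of the
#' observed responses around the draw's fitted means, and the same quantity
#' for one dataset replicated from the likelihood at that draw. Raw RSS is
#' reported per tier; the pooled headline discrepancy standardizes every
#' residual by its model scale (the tier's residual sd, or
#' `sqrt(mu (1 - mu) / (1 + phi))` for the beta tier) so tiers with large
#' units do not dominate. A model that fits well puts the observed/replicated
#' pairs on the 1:1 line and the Bayesian p-value near 0.5.
#'
#' @param draws an `hbm_draws` from the full model.
#' @param data the `hbm_data` the draws were fitted to (or a modified copy,
#'   to probe sensitivity to a mis-specification).
#' @param max_draws cap on the number of draws scored (evenly spaced subset;
#'   default 400).
#' @param seed optional seed for the replicate simulation.
#' @return object of class `hbm_ppc`: list with `discrepancies` (data.frame
#'   of draw, tier, rss_obs, rss_rep) and `bayesian_p` (named vector, one
#'   entry per tier plus `"pooled"` for the standardized pooled RSS).
#' @export
posterior_predictive_check <- function(draws, data, max_draws = 400,
                                       seed = NULL) {
  stopifnot(inherits(draws, "hbm_draws"), inherits(data, "hbm_data"))
  m <- as_draws_matrix(draws)
  if (nrow(m) == 0) stop("no retained draws")
  idx <- if (nrow(m) > max_draws) {
    unique(round(seq(1, nrow(m), length.out = max_draws)))
  } else {
    seq_len(nrow(m))
  }
  if (!is.null(seed)) set.seed(seed)
  tiers <- c("soil", "foliage", "herbivory", "pooled")
  res <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    params <- m[idx[k], ]
    p <- .tier_pieces(params, data)
    rep <- simulate_replicate(params, data)
    fit <- rep$fitted
    soil_obs <- sum((data$Y_soil - fit$soil)^2)
    soil_rep <- sum((rep$soil - fit$soil)^2)
    fol_obs <- sum((data$Y_fol - fit$foliage)^2)
    fol_rep <- sum((rep$foliage - fit$foliage)^2)
    herb_obs <- sum((data$y_damage - fit$herb_mu)^2)
    herb_rep <- sum((rep$damage - fit$herb_mu)^2)
    soil_sd <- vapply(p$soil, `[[`, numeric(1), "sigma")
    fol_sd <- vapply(p$fol, `[[`, numeric(1), "sigma")
    herb_scale <- sqrt(fit$herb_mu * (1 - fit$herb_mu) / (1 + p$herb$phi))
    pool_obs <- sum(sweep(data$Y_soil - fit$soil, 2, soil_sd, "/")^2) +
      sum(sweep(data$Y_fol - fit$foliage, 2, fol_sd, "/")^2) +
      sum(((data$y_damage - fit$herb_mu) / herb_scale)^2)
    pool_rep <- sum(sweep(rep$soil - fit$soil, 2, soil_sd, "/")^2) +
      sum(sweep(rep$foliage - fit$foliage, 2, fol_sd, "/")^2) +
      sum(((rep$damage - fit$herb_mu) / herb_scale)^2)
    res[[k]] <- data.frame(draw = idx[k], tier = tiers,
                           rss_obs = c(soil_obs, fol_obs, herb_obs, pool_obs),
                           rss_rep = c(soil_rep, fol_rep, herb_rep, pool_rep),
                           stringsAsFactors = FALSE)
  }
  disc <- do.call(rbind, res)
  p_by_tier <- vapply(tiers, function(t) {
    sel <- disc$tier == t
    bayesian_p(disc$rss_obs[sel], disc$rss_rep[sel])
  }, numeric(1))
  structure(list(discrepancies = disc, bayesian_p = p_by_tier),
            class = "hbm_ppc")
}
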