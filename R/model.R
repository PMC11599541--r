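#' Specification of the three-tier hierarchical model
#'
#' The joint model has a fixed acyclic tier ordering: climate and geology
#' drive site-level soil chemistry (Gaussian), soil chemistry and climate
#' drive tree-level foliar chemistry (Gaussian, species intercepts, genus
#' slopes, site random effect), and everything upstream drives tree-level
#' herbivory damage (beta likelihood on (0,1) with a logit-linear mean,
#' species intercepts, genus slopes, site random effect).
#'
#' Priors: Normal(0, `coef_sd`) on every intercept, geology offset and slope;
#' half-Normal(`sd_scale`) on residual and site-effect standard deviations;
#' Gamma(`phi_shape`, `phi_rate`) on the beta precision. These are weakly
#' informative on standardized predictors.
#'
#' @param elements soil elements modelled (default N, P, K, Na, C:N).
#' @param responses foliar responses modelled (default total N and N
#'   digestibility; dry-matter digestibility is carried in the data but not
#'   modelled).
#' @param geology_levels geology classes; the first is the reference class
#'   absorbed by the intercepts.
#' @param species_plan data.frame with `species` and `genus` columns covering
#'   every species in the data.
#' @param priors named list with `coef_sd`, `sd_scale`, `phi_shape`,
#'   `phi_rate`.
#' @return object of class `hbm_spec`.
#' @export
model_spec <- function(elements = c("N", "P", "K", "Na", "CN"),
                       responses = c("totalN", "Ndig"),
                       geology_levels = c("basalt", "granite", "rhyolite"),
                       species_plan = default_species_plan(),
                       priors = list(coef_sd = 10, sd_scale = 5,
                                     phi_shape = 0.01, phi_rate = 0.01)) {
  stopifnot(length(elements) >= 1, length(responses) >= 1,
            length(geology_levels) >= 1,
            all(c("species", "genus") %in% names(species_plan)),
            all(c("coef_sd", "sd_scale", "phi_shape", "phi_rate") %in% names(priors)))
  if (anyDuplicated(species_plan$species)) stop("duplicate species in plan")
  structure(list(elements = elements, responses = responses,
                 geology_levels = geology_levels,
                 species = species_plan$species,
                 genus_map = stats::setNames(species_plan$genus, species_plan$species),
                 genus_levels = unique(species_plan$genus),
                 priors = priors),
            class = "hbm_spec")
}

#' Assemble model-ready data from the four raw tables
#'
#' Aggregates leaf damage to a tree-level response with [tree_damage()],
#' standardizes all predictors (site-level covariates over sites, foliar
#' covariates over trees, quadratic climate terms as squares of the
#' standardized linear terms) and builds the three design matrices together
#' with the canonical parameter-name vector used by the sampler and all
#' posterior summaries.
#'
#' @param sites,soil,trees,leaves the four tables (see [generate_dataset()]
#'   for the column contract).
#' @param spec an [model_spec()]; defaults to one inferred from the data's
#'   species and geology labels.
#' @return object of class `hbm_data`.
#' @export
prepare_model_data <- function(sites, soil, trees, leaves, spec = NULL) {
  if (is.null(spec)) {
    plan <- unique(trees[, c("species", "genus")])
    spec <- model_spec(species_plan = plan,
                       geology_levels = unique(c("basalt", sites$geology)))
  }
  if (!all(trees$species %in% spec$species)) {
    stop("species->genus map does not cover every species in the data")
  }
  if (!all(sites$geology %in% spec$geology_levels)) {
    stop("geology class in data missing from the model spec")
  }

  damage <- vapply(split(leaves$damage, leaves$tree), tree_damage, numeric(1))
  trees$damage <- unname(damage[trees$tree])
  if (anyNA(trees$damage)) stop("some trees have no leaves")

  cov <- .site_covariates(sites, spec$geology_levels, soil, spec$elements)
  X_site <- .soil_design(cov, spec$geology_levels)
  Y_soil <- as.matrix(soil[match(sites$site, soil$site), spec$elements, drop = FALSE])
  rownames(Y_soil) <- sites$site

  folz <- .fol_tree_covariates(trees, spec$responses)
  tree_cov <- cbind(folz[, -1, drop = FALSE],
                    cov[match(trees$site, cov$site), -1, drop = FALSE])

  fol_preds <- .fol_predictors(spec$elements, spec$geology_levels)
  herb_preds <- .herb_predictors(spec$responses, spec$elements, spec$geology_levels)
  X_fol <- .genus_design(tree_cov, trees$species, trees$genus,
                         spec$species, spec$genus_levels, fol_preds)
  X_herb <- .genus_design(tree_cov, trees$species, trees$genus,
                          spec$species, spec$genus_levels, herb_preds)
  Y_fol <- as.matrix(trees[, spec$responses, drop = FALSE])
  site_index <- match(trees$site, sites$site)

  soil_cols <- colnames(X_site)
  par_info <- list()
  for (e in spec$elements) {
    par_info[[length(par_info) + 1]] <- data.frame(
      name = c(paste0("soil_", e, "_", soil_cols), paste0("soil_", e, "_sigma")),
      tier = "soil", kind = c(rep("coef", length(soil_cols)), "sigma"),
      stringsAsFactors = FALSE)
  }
  for (r in spec$responses) {
    par_info[[length(par_info) + 1]] <- data.frame(
      name = c(paste0("fol_", r, "_", colnames(X_fol)),
               paste0("fol_", r, "_sigma"), paste0("fol_", r, "_site_sd"),
               paste0("fol_", r, "_u_", sites$site)),
      tier = "foliage",
      kind = c(rep("coef", ncol(X_fol)), "sigma", "site_sd",
               rep("u", nrow(sites))),
      stringsAsFactors = FALSE)
  }
  par_info[[length(par_info) + 1]] <- data.frame(
    name = c(paste0("herb_", colnames(X_herb)), "herb_site_sd",
             paste0("herb_u_", sites$site), "herb_phi"),
    tier = "herbivory",
    kind = c(rep("coef", ncol(X_herb)), "site_sd", rep("u", nrow(sites)), "phi"),
    stringsAsFactors = FALSE)
  par_info <- do.call(rbind, par_info)

  analysis_table <- cbind(
    trees[, c("tree", "site", "species", "genus", "damage")],
    trees[, spec$responses, drop = FALSE], tree_cov)

  structure(list(spec = spec, sites = sites, trees = trees,
                 analysis_table = analysis_table,
                 X_site = X_site, Y_soil = Y_soil,
                 X_fol = X_fol, Y_fol = Y_fol,
                 X_herb = X_herb, y_damage = trees$damage,
                 site_index = site_index, par_info = par_info,
                 par_names = par_info$name),
            class = "hbm_data")
}

.get_pars <- function(params, names) {
  out <- params[names]
  if (anyNA(out)) {
    stop("parameter vector is missing: ",
         paste(names[is.na(out)][seq_len(min(3, sum(is.na(out))))], collapse = ", "))
  }
  unname(out)
}

.tier_pieces <- function(params, data) {
  spec <- data$spec
  sites <- data$sites$site
  soil_cols <- colnames(data$X_site)
  soil <- lapply(spec$elements, function(e) {
    list(beta = .get_pars(params, paste0("soil_", e, "_", soil_cols)),
         sigma = .get_pars(params, paste0("soil_", e, "_sigma")))
  })
  names(soil) <- spec$elements
  fol <- lapply(spec$responses, function(r) {
    list(beta = .get_pars(params, paste0("fol_", r, "_", colnames(data$X_fol))),
         sigma = .get_pars(params, paste0("fol_", r, "_sigma")),
         site_sd = .get_pars(params, paste0("fol_", r, "_site_sd")),
         u = .get_pars(params, paste0("fol_", r, "_u_", sites)))
  })
  names(fol) <- spec$responses
  herb <- list(beta = .get_pars(params, paste0("herb_", colnames(data$X_herb))),
               site_sd = .get_pars(params, "herb_site_sd"),
               u = .get_pars(params, paste0("herb_u_", sites)),
               phi = .get_pars(params, "herb_phi"))
  list(soil = soil, fol = fol, herb = herb)
}

#' Joint log-likelihood of the three-tier model
#'
#' Sums Gaussian log-densities for each soil element at site level and each
#' foliar response at tree level (conditional on the site effects carried in
#' the parameter vector), and a beta log-density for tree damage with mean
#' `plogis(eta)` and shapes `(mu * phi, (1 - mu) * phi)`.
#'
#' @param params full named parameter vector (coefficients, sds, site
#'   effects, phi).
#' @param data an `hbm_data`.
#' @param tiers subset of `c("soil", "foliage", "herbivory")` to include.
#' @return scalar log-density.
#' @export
log_likelihood <- function(params, data,
                           tiers = c("soil", "foliage", "herbivory")) {
  stopifnot(inherits(data, "hbm_data"))
  if (any(data$y_damage <= 0 | data$y_damage >= 1)) {
    stop("tree damage outside the open unit interval")
  }
  p <- .tier_pieces(params, data)
  ll <- 0
  if ("soil" %in% tiers) {
    for (e in data$spec$elements) {
      if (p$soil[[e]]$sigma <= 0) stop("non-positive residual sd for soil ", e)
      mu <- as.numeric(data$X_site %*% p$soil[[e]]$beta)
      ll <- ll + sum(stats::dnorm(data$Y_soil[, e], mu, p$soil[[e]]$sigma, log = TRUE))
    }
  }
  if ("foliage" %in% tiers) {
    for (r in data$spec$responses) {
      f <- p$fol[[r]]
      if (f$sigma <= 0) stop("non-positive residual sd for foliage ", r)
      mu <- as.numeric(data$X_fol %*% f$beta) + f$u[data$site_index]
      ll <- ll + sum(stats::dnorm(data$Y_fol[, r], mu, f$sigma, log = TRUE))
    }
  }
  if ("herbivory" %in% tiers) {
    h <- p$herb
    if (h$phi <= 0) stop("non-positive beta precision phi")
    mu <- stats::plogis(as.numeric(data$X_herb %*% h$beta) + h$u[data$site_index])
    ll <- ll + sum(stats::dbeta(data$y_damage, mu * h$phi, (1 - mu) * h$phi, log = TRUE))
  }
  ll
}

#' Joint log-prior
#'
#' Independent vague priors on all top-level parameters (see [model_spec()]),
#' plus the hierarchical Normal(0, site sd) contribution of the site effects.
#' Returns `-Inf` outside the support (non-positive sds or phi).
#'
#' @inheritParams log_likelihood
#' @return scalar log-density (`-Inf` outside the support).
#' @export
log_prior <- function(params, data) {
  stopifnot(inherits(data, "hbm_data"))
  pr <- data$spec$priors
  p <- .tier_pieces(params, data)
  sds <- c(vapply(p$soil, `[[`, numeric(1), "sigma"),
           vapply(p$fol, `[[`, numeric(1), "sigma"),
           vapply(p$fol, `[[`, numeric(1), "site_sd"),
           p$herb$site_sd)
  if (any(sds <= 0) || p$herb$phi <= 0) return(-Inf)
  coefs <- c(unlist(lapply(p$soil, `[[`, "beta")),
             unlist(lapply(p$fol, `[[`, "beta")),
             p$herb$beta)
  lp <- sum(stats::dnorm(coefs, 0, pr$coef_sd, log = TRUE))
  lp <- lp + sum(stats::dnorm(sds, 0, pr$sd_scale, log = TRUE) + log(2))
  lp <- lp + stats::dgamma(p$herb$phi, shape = pr$phi_shape, rate = pr$phi_rate, log = TRUE)
  for (r in data$spec$responses) {
    lp <- lp + sum(stats::dnorm(p$fol[[r]]$u, 0, p$fol[[r]]$site_sd, log = TRUE))
  }
  lp <- lp + sum(stats::dnorm(p$herb$u, 0, p$herb$site_sd, log = TRUE))
  lp
}

#' Joint log-posterior (up to the normalizing constant)
#'
#' @inheritParams log_likelihood
#' @return `log_prior + log_likelihood`, or `-Inf` outside the support.
#' @export
log_posterior <- function(params, data) {
  lp <- log_prior(params, data)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(params, data)
}

#' Fitted (conditional) means of every response at a parameter vector
#'
#' @inheritParams log_likelihood
#' @return list with `soil` (sites x elements), `foliage` (trees x
#'   responses) and `herb_mu` (per-tree expected damage).
#' @export
fitted_means <- function(params, data) {
  p <- .tier_pieces(params, data)
  soil <- vapply(data$spec$elements,
                 function(e) as.numeric(data$X_site %*% p$soil[[e]]$beta),
                 numeric(nrow(data$X_site)))
  fol <- vapply(data$spec$responses, function(r) {
    as.numeric(data$X_fol %*% p$fol[[r]]$beta) + p$fol[[r]]$u[data$site_index]
  }, numeric(nrow(data$X_fol)))
  herb_mu <- stats::plogis(as.numeric(data$X_herb %*% p$herb$beta) +
                             p$herb$u[data$site_index])
  list(soil = soil, foliage = fol, herb_mu = herb_mu)
}

#' Simulate one replicated dataset from the likelihood at fixed parameters
#'
#' Holds all covariates fixed and draws each response from its likelihood:
#' Gaussian for the soil and foliage tiers, mean-precision beta for tree
#' damage. Used by the posterior-predictive check.
#'
#' @inheritParams log_likelihood
#' @return list with `soil`, `foliage`, `damage` replicate draws and the
#'   `fitted` means they were drawn around.
#' @export
simulate_replicate <- function(params, data) {
  p <- .tier_pieces(params, data)
  fit <- fitted_means(params, data)
  soil_rep <- fit$soil
  for (e in data$spec$elements) {
    soil_rep[, e] <- soil_rep[, e] +
      stats::rnorm(nrow(soil_rep), 0, p$soil[[e]]$sigma)
  }
  fol_rep <- fit$foliage
  for (r in data$spec$responses) {
    fol_rep[, r] <- fol_rep[, r] + stats::rnorm(nrow(fol_rep), 0, p$fol[[r]]$sigma)
  }
  phi <- p$herb$phi
  damage_rep <- stats::rbeta(length(fit$herb_mu), fit$herb_mu * phi,
                             (1 - fit$herb_mu) * phi)
  list(soil = soil_rep, foliage = fol_rep, damage = damage_rep, fitted = fit)
}

#' Express ground-truth generator parameters as a named parameter vector
#'
#' Maps a `true_parameters` object onto the fitted model's parameter names so
#' recovery can be checked coefficient by coefficient. Site effects are
#' realization-specific and are not included; the returned `phi` is the
#' leaf-level precision, whereas the model fits a tree-level precision (the
#' response is a leaf mean), so variance-type entries are labelled by the
#' `kind` attribute for optional exclusion.
#'
#' @param truth a `true_parameters` object.
#' @param data an `hbm_data` prepared from a dataset generated under `truth`.
#' @return named numeric vector with attribute `kind`.
#' @export
true_parameter_vector <- function(truth, data) {
  spec <- data$spec
  out <- c()
  kind <- c()
  soil_cols <- colnames(data$X_site)
  for (e in spec$elements) {
    b <- truth$soil$coef[e, soil_cols]
    v <- c(stats::setNames(b, paste0("soil_", e, "_", soil_cols)),
           stats::setNames(truth$soil$sigma[e], paste0("soil_", e, "_sigma")))
    out <- c(out, v)
    kind <- c(kind, rep("coef", length(soil_cols)), "sigma")
  }
  for (r in spec$responses) {
    f <- truth$foliage[[r]]
    ints <- stats::setNames(f$intercept[spec$species],
                            paste0("fol_", r, "_int_", gsub(" ", "_", spec$species)))
    sl <- c()
    for (g in spec$genus_levels) {
      preds <- .fol_predictors(spec$elements, spec$geology_levels)
      sl <- c(sl, stats::setNames(f$slopes[g, preds],
                                  paste0("fol_", r, "_", g, "_", preds)))
    }
    out <- c(out, ints, sl,
             stats::setNames(f$sigma, paste0("fol_", r, "_sigma")),
             stats::setNames(f$site_sd, paste0("fol_", r, "_site_sd")))
    kind <- c(kind, rep("coef", length(ints) + length(sl)), "sigma", "site_sd")
  }
  h <- truth$herbivory
  ints <- stats::setNames(h$intercept[spec$species],
                          paste0("herb_int_", gsub(" ", "_", spec$species)))
  preds <- .herb_predictors(spec$responses, spec$elements, spec$geology_levels)
  sl <- c()
  for (g in spec$genus_levels) {
    sl <- c(sl, stats::setNames(h$slopes[g, preds], paste0("herb_", g, "_", preds)))
  }
  out <- c(out, ints, sl,
           stats::setNames(h$site_sd, "herb_site_sd"),
           stats::setNames(h$phi, "herb_phi"))
  kind <- c(kind, rep("coef", length(ints) + length(sl)), "site_sd", "phi")
  attr(out, "kind") <- kind
  out
}
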