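#' Configuration for a synthetic montane-rainforest landscape
#'
#' Defines the study conditions the generator emulates: a network of sites
#' spanning crossed temperature and precipitation gradients over three soil
#' parent materials, and an unbalanced sample of canopy trees from a pioneer
#' genus and a late-successional genus, each tree contributing a fixed number
#' of leaves scored for herbivory damage.
#'
#' @param n_sites number of study sites (default 25).
#' @param geology_classes ordered character vector of parent materials; the
#'   first is the reference class (default basalt, granite, rhyolite).
#' @param mat_range mean annual temperature interval, degrees C (default 14-26).
#' @param map_range mean annual precipitation interval, mm/yr (default
#'   1200-4000).
#' @param species_plan data.frame with columns `species`, `genus`, `n_trees`,
#'   `site_coverage` (the probability that a site is within the species'
#'   range). Defaults to one widespread pioneer (Alphitonia petriei, n = 115,
#'   full coverage) and two range-restricted late-successional congeners
#'   (Flindersia brayleyana n = 22 at 48% coverage, F. pimenteliana n = 42 at
#'   60% coverage).
#' @param leaves_per_tree leaves scored per tree (default 20).
#' @param climate_jitter sd of the noise partially decorrelating climate from
#'   its latent geographic axis, on the unit gradient scale (default 0.05).
#' @param seed integer RNG seed.
#' @return object of class `landscape_config`.
#' @export
landscape_config <- function(n_sites = 25,
                             geology_classes = c("basalt", "granite", "rhyolite"),
                             mat_range = c(14, 26),
                             map_range = c(1200, 4000),
                             species_plan = default_species_plan(),
                             leaves_per_tree = 20,
                             climate_jitter = 0.05,
                             seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites), geology_classes = geology_classes,
              mat_range = mat_range, map_range = map_range,
              species_plan = species_plan,
              leaves_per_tree = as.integer(leaves_per_tree),
              climate_jitter = climate_jitter, seed = as.integer(seed))
  class(cfg) <- "landscape_config"
  validate_landscape_config(cfg)
  cfg
}

#' Default species sampling plan
#'
#' @return data.frame with one row per species: label, genus, number of trees
#'   and site coverage.
#' @export
default_species_plan <- function() {
  data.frame(
    species = c("Alphitonia_petriei", "Flindersia_brayleyana", "Flindersia_pimenteliana"),
    genus = c("Alphitonia", "Flindersia", "Flindersia"),
    n_trees = c(115L, 22L, 42L),
    site_coverage = c(1.00, 0.48, 0.60),
    stringsAsFactors = FALSE
  )
}

validate_landscape_config <- function(cfg) {
  if (cfg$n_sites < length(cfg$geology_classes)) {
    stop("n_sites must be at least the number of geology classes")
  }
  if (length(cfg$geology_classes) < 1 || anyDuplicated(cfg$geology_classes)) {
    stop("geology classes must be distinct labels")
  }
  for (rng in list(cfg$mat_range, cfg$map_range)) {
    if (length(rng) != 2 || !all(is.finite(rng)) || rng[2] <= rng[1]) {
      stop("climate ranges must be non-degenerate intervals")
    }
  }
  sp <- cfg$species_plan
  if (!all(c("species", "genus", "n_trees", "site_coverage") %in% names(sp))) {
    stop("species_plan must have columns species, genus, n_trees, site_coverage")
  }
  if (any(sp$n_trees < 1)) stop("every species needs n_trees >= 1")
  if (anyDuplicated(sp$species)) stop("species must map to exactly one genus each")
  if (any(sp$site_coverage <= 0 | sp$site_coverage > 1)) {
    stop("site_coverage must lie in (0, 1]")
  }
  if (cfg$leaves_per_tree < 1) stop("leaves_per_tree must be positive")
  invisible(TRUE)
}

#' Default ground-truth parameters for the synthetic landscape
#'
#' Coefficients are on the fitted model's scale: predictors standardized
#' (site-level covariates over sites, foliar covariates over trees; quadratic
#' climate terms are squares of the standardized linear term), responses in
#' their native units. The sign pattern encodes the qualitative structure the
#' package is designed to recover: basalt-derived soils are nutrient-rich,
#' precipitation raises soil N and P while depleting K and C:N, temperature
#' raises K and lowers Na and C:N; foliar chemistry responds to geology and
#' (for the late-successional genus) to climate and soil P/Na; herbivory rises
#' with temperature for both genera, with foliar N for the pioneer genus, and
#' falls with soil C:N for the late-successional genus. Standardized effect
#' magnitudes sit around 0.3-0.8; herbivory intercepts put mean damage near
#' 2-7% of leaf area, and the beta precision `phi` applies at the leaf level.
#'
#' @param geology_levels geology classes, reference first.
#' @param species_plan species plan (see [default_species_plan()]).
#' @param elements soil elements modelled.
#' @param responses foliar responses modelled.
#' @return object of class `true_parameters`.
#' @export
default_true_parameters <- function(geology_levels = c("basalt", "granite", "rhyolite"),
                                    species_plan = default_species_plan(),
                                    elements = c("N", "P", "K", "Na", "CN"),
                                    responses = c("totalN", "Ndig")) {
  soil_cols <- c("intercept", geology_levels[-1], "MAT", "MAT2", "MAP", "MAP2")
  soil_coef <- matrix(0, length(elements), length(soil_cols),
                      dimnames = list(elements, soil_cols))
  soil_coef["N", c("granite", "rhyolite", "MAP")] <- c(-0.6, -0.6, 0.5)
  soil_coef["P", c("granite", "rhyolite", "MAP")] <- c(-0.6, -0.7, 0.5)
  soil_coef["K", c("granite", "rhyolite", "MAT", "MAP")] <- c(-0.5, -0.5, 0.4, -0.5)
  soil_coef["Na", c("granite", "rhyolite", "MAT")] <- c(-0.3, -0.3, -0.5)
  soil_coef["CN", c("granite", "rhyolite", "MAT", "MAP")] <- c(0.4, 0.5, -0.5, -0.7)
  soil_sigma <- stats::setNames(rep(0.6, length(elements)), elements)

  genus_levels <- unique(species_plan$genus)
  fol_preds <- .fol_predictors(elements, geology_levels)
  zero_slopes <- function(preds) {
    matrix(0, length(genus_levels), length(preds),
           dimnames = list(genus_levels, preds))
  }

  totalN_slopes <- zero_slopes(fol_preds)
  Ndig_slopes <- zero_slopes(fol_preds)
  fill <- function(m, genus, vals) {
    if (genus %in% rownames(m)) {
      ok <- names(vals) %in% colnames(m)
      m[genus, names(vals)[ok]] <- vals[ok]
    }
    m
  }
  totalN_slopes <- fill(totalN_slopes, "Alphitonia", c(granite = -0.15, rhyolite = -0.15))
  totalN_slopes <- fill(totalN_slopes, "Flindersia",
                        c(granite = -0.15, rhyolite = -0.15, MAT = 0.12, MAP = -0.12))
  Ndig_slopes <- fill(Ndig_slopes, "Alphitonia", c(granite = 0.04, rhyolite = 0.04))
  Ndig_slopes <- fill(Ndig_slopes, "Flindersia",
                      c(soil_P = -0.04, soil_Na = 0.04, MAT = 0.03))

  nsp <- nrow(species_plan)
  foliage <- list(
    totalN = list(
      intercept = stats::setNames(rep_len(c(2.2, 1.5, 1.7), nsp), species_plan$species),
      slopes = totalN_slopes, sigma = 0.25, site_sd = 0.10),
    Ndig = list(
      intercept = stats::setNames(rep_len(c(0.45, 0.55, 0.62), nsp), species_plan$species),
      slopes = Ndig_slopes, sigma = 0.07, site_sd = 0.03)
  )

  herb_preds <- .herb_predictors(responses, elements, geology_levels)
  herb_slopes <- matrix(0, length(genus_levels), length(herb_preds),
                        dimnames = list(genus_levels, herb_preds))
  herb_slopes <- fill(herb_slopes, "Alphitonia",
                      c(granite = -0.4, rhyolite = -0.4, MAT = 0.5, fol_totalN = 0.5))
  herb_slopes <- fill(herb_slopes, "Flindersia", c(soil_CN = -0.6, MAT = 0.4))
  herbivory <- list(
    intercept = stats::setNames(rep_len(c(-3.55, -2.70, -3.70), nsp), species_plan$species),
    slopes = herb_slopes, site_sd = 0.30, phi = 40
  )

  structure(list(soil = list(coef = soil_coef, sigma = soil_sigma),
                 foliage = foliage, herbivory = herbivory,
                 geology_levels = geology_levels,
                 species_plan = species_plan,
                 elements = elements, responses = responses),
            class = "true_parameters")
}

validate_true_parameters <- function(truth) {
  stopifnot(inherits(truth, "true_parameters"))
  if (any(truth$soil$sigma < 0)) stop("soil residual sds must be non-negative")
  for (r in truth$responses) {
    f <- truth$foliage[[r]]
    if (is.null(f)) stop("missing foliage coefficients for response ", r)
    if (f$sigma < 0 || f$site_sd < 0) stop("foliage sds must be non-negative")
  }
  if (truth$herbivory$phi <= 0) stop("beta precision phi must be strictly positive")
  if (truth$herbivory$site_sd < 0) stop("herbivory site sd must be non-negative")
  invisible(TRUE)
}

#' Generate the site table of a synthetic landscape
#'
#' Sites sit on two latent geographic axes: an elevation axis that cools mean
#' annual temperature and a longitude axis (distance from the coast) that
#' dries mean annual precipitation. Both climate variables are jittered and
#' then clamped so they span exactly their configured ranges; geology classes
#' are assigned so that every class is represented.
#'
#' @param config a [landscape_config()].
#' @return data.frame with columns `site`, `elevation` (m), `longitude`
#'   (km inland), `geology`, `MAT` (deg C), `MAP` (mm/yr).
#' @export
generate_sites <- function(config) {
  validate_landscape_config(config)
  set.seed(config$seed)
  n <- config$n_sites
  elev_axis <- stats::runif(n)
  long_axis <- stats::runif(n)
  uT <- pmin(pmax(1 - elev_axis + config$climate_jitter * stats::rnorm(n), 0), 1)
  uP <- pmin(pmax(1 - long_axis + config$climate_jitter * stats::rnorm(n), 0), 1)
  classes <- config$geology_classes
  k <- length(classes)
  geology <- sample(c(sample(classes), if (n > k) sample(classes, n - k, replace = TRUE)))
  data.frame(
    site = sprintf("S%03d", seq_len(n)),
    elevation = 400 + 900 * elev_axis,
    longitude = 70 * long_axis,
    geology = geology,
    MAT = config$mat_range[1] + diff(config$mat_range) * uT,
    MAP = config$map_range[1] + diff(config$map_range) * uP,
    stringsAsFactors = FALSE
  )
}

#' Generate depth-averaged soil chemistry for a site table
#'
#' Each element is a Gaussian response to geology (reference-cell coding) and
#' to standardized linear and quadratic climate terms. Values are on a
#' standardized concentration scale (ground-truth intercepts of 0).
#'
#' @param sites site table from [generate_sites()].
#' @param truth a `true_parameters` object.
#' @param seed integer seed.
#' @return data.frame with `site` plus one column per element.
#' @export
generate_soil <- function(sites, truth, seed) {
  validate_true_parameters(truth)
  if (nrow(sites) == 0) stop("empty site table")
  set.seed(seed)
  cov <- .site_covariates(sites, truth$geology_levels)
  X <- .soil_design(cov, truth$geology_levels)
  need <- colnames(truth$soil$coef)
  if (!all(need %in% colnames(X))) stop("soil coefficient set incomplete for this design")
  out <- data.frame(site = sites$site, stringsAsFactors = FALSE)
  for (e in truth$elements) {
    mu <- as.numeric(X[, need] %*% truth$soil$coef[e, ])
    out[[e]] <- mu + stats::rnorm(nrow(sites), 0, truth$soil$sigma[e])
    attr(out, paste0("mu_", e)) <- mu
  }
  out
}

#' Generate the tree table: species placement and foliar chemistry
#'
#' Trees are allocated to sites within each species' realized range (each
#' site enters a species' range with probability `site_coverage`, so
#' late-successional species occupy a subset of sites). Foliar total N and N
#' digestibility follow genus-slope / species-intercept Gaussian models with
#' a site random effect; digestibility indices are clipped to `[0, 1]`.
#'
#' @param sites,soil tables from the upstream generators.
#' @param truth a `true_parameters` object.
#' @param species_plan species plan (defaults to the one in `truth`).
#' @param seed integer seed.
#' @return data.frame with columns `tree`, `site`, `species`, `genus`,
#'   `totalN` (% dry matter), `Ndig`, `DMdig` (fractions). The realized site
#'   effects are attached as attribute `site_effects`.
#' @export
generate_trees <- function(sites, soil, truth, species_plan = truth$species_plan,
                           seed = 1L) {
  validate_true_parameters(truth)
  if (!all(sites$site %in% soil$site)) stop("soil table must cover all sites")
  if (anyNA(species_plan$genus)) stop("species with no genus mapping")
  set.seed(seed)
  cov <- .site_covariates(sites, truth$geology_levels, soil, truth$elements)
  preds <- .fol_predictors(truth$elements, truth$geology_levels)

  rows <- list()
  for (i in seq_len(nrow(species_plan))) {
    in_range <- stats::runif(nrow(sites)) <= species_plan$site_coverage[i]
    if (!any(in_range)) in_range[sample.int(nrow(sites), 1)] <- TRUE
    elig <- sites$site[in_range]
    rows[[i]] <- data.frame(
      site = if (length(elig) == 1) rep(elig, species_plan$n_trees[i])
             else sample(elig, species_plan$n_trees[i], replace = TRUE),
      species = species_plan$species[i],
      genus = species_plan$genus[i],
      stringsAsFactors = FALSE
    )
  }
  trees <- do.call(rbind, rows)
  trees <- data.frame(tree = sprintf("T%04d", seq_len(nrow(trees))), trees,
                      stringsAsFactors = FALSE)

  Xrow <- cov[match(trees$site, cov$site), preds, drop = FALSE]
  site_effects <- list()
  for (r in truth$responses) {
    f <- truth$foliage[[r]]
    u <- stats::setNames(stats::rnorm(nrow(sites), 0, f$site_sd), sites$site)
    site_effects[[r]] <- u
    eta <- f$intercept[trees$species] +
      rowSums(as.matrix(Xrow) * f$slopes[trees$genus, preds, drop = FALSE]) +
      u[trees$site]
    val <- eta + stats::rnorm(nrow(trees), 0, f$sigma)
    if (r %in% c("Ndig", "DMdig")) val <- pmin(pmax(val, 0), 1)
    trees[[r]] <- as.numeric(val)
  }
  # dry-matter digestibility is carried in the data model but not modelled:
  # generate it as a noisy correlate of N digestibility, clipped to [0, 1]
  if (!"DMdig" %in% names(trees)) {
    trees$DMdig <- pmin(pmax(0.35 + 0.5 * trees$Ndig + stats::rnorm(nrow(trees), 0, 0.05), 0), 1)
  }
  attr(trees, "site_effects") <- site_effects
  trees
}

#' Generate leaf-level herbivory damage
#'
#' Each tree gets an expected damage fraction `mu` through an inverse-logit
#' linear predictor (species intercepts, genus slopes over foliar chemistry,
#' soil, climate and geology, plus a site random effect); its leaves are then
#' drawn from a mean-precision beta distribution `Beta(mu * phi,
#' (1 - mu) * phi)` and clamped into the open unit interval.
#'
#' @param trees,soil,sites upstream tables.
#' @param truth a `true_parameters` object.
#' @param leaves_per_tree leaves per tree (default 20).
#' @param seed integer seed.
#' @param eps clamp width keeping damage strictly inside (0, 1).
#' @return data.frame with columns `tree`, `leaf`, `damage`; the per-tree
#'   expected damages are attached as attribute `mu`.
#' @export
generate_herbivory <- function(trees, soil, sites, truth, leaves_per_tree = 20,
                               seed = 1L, eps = 1e-6) {
  validate_true_parameters(truth)
  if (truth$herbivory$phi <= 0) stop("phi must be positive")
  set.seed(seed)
  cov <- .site_covariates(sites, truth$geology_levels, soil, truth$elements)
  folz <- .fol_tree_covariates(trees, truth$responses)
  preds <- .herb_predictors(truth$responses, truth$elements, truth$geology_levels)
  tree_cov <- cbind(folz[, -1, drop = FALSE],
                    cov[match(trees$site, cov$site), -1, drop = FALSE])
  h <- truth$herbivory
  u <- stats::setNames(stats::rnorm(nrow(sites), 0, h$site_sd), sites$site)
  eta <- h$intercept[trees$species] +
    rowSums(as.matrix(tree_cov[, preds, drop = FALSE]) * h$slopes[trees$genus, preds, drop = FALSE]) +
    u[trees$site]
  mu <- stats::plogis(as.numeric(eta))
  L <- leaves_per_tree
  damage <- stats::rbeta(nrow(trees) * L, shape1 = rep(mu, each = L) * h$phi,
                         shape2 = rep(1 - mu, each = L) * h$phi)
  damage <- pmin(pmax(damage, eps), 1 - eps)
  leaves <- data.frame(tree = rep(trees$tree, each = L),
                       leaf = rep(seq_len(L), times = nrow(trees)),
                       damage = damage, stringsAsFactors = FALSE)
  attr(leaves, "mu") <- stats::setNames(mu, trees$tree)
  attr(leaves, "site_effects") <- u
  leaves
}

#' Generate a complete synthetic dataset with known ground truth
#'
#' Composes the site, soil, tree and leaf generators under a single seed and
#' returns the four tables together with the true parameters that produced
#' them.
#'
#' @param config a [landscape_config()].
#' @param truth ground-truth parameters; defaults to
#'   [default_true_parameters()] matched to the config's geology classes and
#'   species plan.
#' @return object of class `herb_dataset`: list with `sites`, `soil`,
#'   `trees`, `leaves`, `truth`, `config`, `seed`.
#' @export
generate_dataset <- function(config = landscape_config(),
                             truth = default_true_parameters(
                               geology_levels = config$geology_classes,
                               species_plan = config$species_plan)) {
  validate_landscape_config(config)
  validate_true_parameters(truth)
  if (!identical(truth$species_plan$species, config$species_plan$species)) {
    stop("truth and config disagree on the species plan")
  }
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4)
  cfg_sites <- config
  cfg_sites$seed <- seeds[1]
  sites <- generate_sites(cfg_sites)
  soil <- generate_soil(sites, truth, seed = seeds[2])
  trees <- generate_trees(sites, soil, truth, config$species_plan, seed = seeds[3])
  leaves <- generate_herbivory(trees, soil, sites, truth,
                               leaves_per_tree = config$leaves_per_tree,
                               seed = seeds[4])
  structure(list(sites = sites, soil = soil, trees = trees, leaves = leaves,
                 truth = truth, config = config, seed = config$seed),
            class = "herb_dataset")
}

#' Check the structural invariants of a synthetic dataset
#'
#' Every tree must reference an existing site, every leaf an existing tree,
#' leaf damage must lie strictly inside (0, 1) and digestibility indices in
#' `[0, 1]`.
#'
#' @param dataset a `herb_dataset`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "herb_dataset"))
  if (!all(dataset$trees$site %in% dataset$sites$site)) {
    stop("tree references a non-existent site")
  }
  if (!all(dataset$leaves$tree %in% dataset$trees$tree)) {
    stop("leaf references a non-existent tree")
  }
  d <- dataset$leaves$damage
  if (any(d <= 0 | d >= 1)) stop("leaf damage proportions must lie strictly in (0, 1)")
  for (col in c("Ndig", "DMdig")) {
    v <- dataset$trees[[col]]
    if (any(v < 0 | v > 1)) stop(col, " must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Write the four dataset tables as CSV fixtures
#'
#' @param dataset a `herb_dataset`.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  utils::write.csv(dataset$soil, file.path(dir, "soil.csv"), row.names = FALSE)
  utils::write.csv(dataset$trees, file.path(dir, "trees.csv"), row.names = FALSE)
  utils::write.csv(dataset$leaves, file.path(dir, "leaves.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read the four dataset tables written by [write_dataset_csv()]
#'
#' @param dir directory holding `sites.csv`, `soil.csv`, `trees.csv`,
#'   `leaves.csv`.
#' @return list with elements `sites`, `soil`, `trees`, `leaves`.
#' @export
read_dataset_csv <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  list(sites = rd("sites.csv"), soil = rd("soil.csv"),
       trees = rd("trees.csv"), leaves = rd("leaves.csv"))
}
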