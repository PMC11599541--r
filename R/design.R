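# Shared construction of model covariates. The synthetic generator and the
# model-preparation step both go through these helpers, so a dataset's true
# coefficients are expressed on exactly the scale the fitted model uses.

.soil_elements_default <- c("N", "P", "K", "Na", "CN")
.fol_responses_default <- c("totalN", "Ndig")

.fol_predictors <- function(elements, geology_levels) {
  c(paste0("soil_", elements), "MAT", "MAT2", "MAP", "MAP2", geology_levels[-1])
}

.herb_predictors <- function(responses, elements, geology_levels) {
  c(paste0("fol_", responses), .fol_predictors(elements, geology_levels))
}

# Site-level covariate frame: geology dummies (reference = first level),
# standardized climate with squared terms, optionally standardized soil.
# Standardization is over sites; squares are of the standardized column.
.site_covariates <- function(sites, geology_levels, soil = NULL,
                             elements = .soil_elements_default) {
  stopifnot(all(sites$geology %in% geology_levels))
  sz <- standardize_columns(sites[, c("MAT", "MAP")], c("MAT", "MAP"),
                            quadratic = c("MAT", "MAP"))
  out <- data.frame(site = sites$site, stringsAsFactors = FALSE)
  for (g in geology_levels[-1]) out[[g]] <- as.numeric(sites$geology == g)
  out$MAT <- sz$table$MAT
  out$MAT2 <- sz$table$MAT_sq
  out$MAP <- sz$table$MAP
  out$MAP2 <- sz$table$MAP_sq
  if (!is.null(soil)) {
    ord <- match(sites$site, soil$site)
    if (anyNA(ord)) stop("soil table does not cover all sites")
    soilz <- standardize_columns(soil[ord, elements, drop = FALSE], elements)
    for (e in elements) out[[paste0("soil_", e)]] <- soilz$table[[e]]
  }
  out
}

# Design matrix for the site-level (soil) tier.
.soil_design <- function(site_cov, geology_levels) {
  X <- cbind(intercept = 1,
             as.matrix(site_cov[, c(geology_levels[-1], "MAT", "MAT2", "MAP", "MAP2")]))
  rownames(X) <- site_cov$site
  X
}

# Tree-level design with species-specific intercept columns and genus-masked
# slope columns (a predictor column times the indicator of the tree's genus).
.genus_design <- function(cov, species, genus, species_levels, genus_levels,
                          predictors) {
  n <- length(species)
  Xint <- vapply(species_levels, function(sp) as.numeric(species == sp),
                 numeric(n))
  colnames(Xint) <- paste0("int_", gsub(" ", "_", species_levels))
  Xsl <- matrix(0, n, length(genus_levels) * length(predictors))
  nms <- character(ncol(Xsl))
  k <- 0
  for (g in genus_levels) {
    mask <- as.numeric(genus == g)
    for (p in predictors) {
      k <- k + 1
      Xsl[, k] <- cov[[p]] * mask
      nms[k] <- paste0(g, "_", p)
    }
  }
  colnames(Xsl) <- nms
  cbind(Xint, Xsl)
}

# Standardized tree-level foliar predictor columns (over trees).
.fol_tree_covariates <- function(trees, responses = .fol_responses_default) {
  z <- standardize_columns(trees[, responses, drop = FALSE], responses)
  out <- data.frame(tree = trees$tree, stringsAsFactors = FALSE)
  for (r in responses) out[[paste0("fol_", r)]] <- z$table[[r]]
  out
}
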