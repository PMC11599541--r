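#' Posterior summary of one parameter
#'
#' Posterior mean plus an equal-tailed credible interval at the given level
#' (default 89%), with a flag for whether the interval excludes zero — the
#' operational version of "does not greatly overlap zero" used to retain
#' effects. A highest-density interval is available as an option.
#'
#' @param draws an `hbm_draws`.
#' @param parameter parameter name.
#' @param level interval mass (default 0.89).
#' @param method `"eti"` (equal-tailed, default) or `"hdi"`.
#' @return one-row data.frame: `parameter`, `mean`, `lower`, `upper`,
#'   `excludes_zero`, `level`.
#' @export
summarize_effect <- function(draws, parameter, level = 0.89,
                             method = c("eti", "hdi")) {
  method <- match.arg(method)
  x <- draws_of(draws, parameter)
  .summ_vec(x, parameter, level, method)
}

.summ_vec <- function(x, parameter, level, method = "eti") {
  if (method == "eti") {
    q <- stats::quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE, type = 7)
  } else {
    xs <- sort(x)
    n <- length(xs)
    k <- max(1, floor(level * n))
    widths <- xs[(n - k + 1):n] - xs[seq_len(k)]
    i <- which.min(widths)
    q <- c(xs[i], xs[i + n - k])
  }
  data.frame(parameter = parameter, mean = mean(x), lower = q[1], upper = q[2],
             excludes_zero = q[1] > 0 || q[2] < 0, level = level,
             stringsAsFactors = FALSE)
}

#' Posterior summaries for many parameters
#'
#' @inheritParams summarize_effect
#' @param parameters parameter names (default: all coefficients).
#' @return data.frame with one row per parameter.
#' @export
summarize_effects <- function(draws, parameters = NULL, level = 0.89) {
  if (is.null(parameters)) {
    parameters <- draws$par_info$name[draws$par_info$kind == "coef"]
  }
  out <- do.call(rbind, lapply(parameters, summarize_effect,
                               draws = draws, level = level))
  rownames(out) <- NULL
  out
}

# Node vocabulary: abiotic nodes "MAT", "MAP" and the non-reference geology
# classes; soil nodes "soil_<element>"; foliage nodes "fol_<response>:<genus>";
# the herbivory node "herb:<genus>". Only linear coefficients form edges.
.edge_coefficient <- function(from, to, spec) {
  abiotic <- c("MAT", "MAP", spec$geology_levels[-1])
  soil_nodes <- paste0("soil_", spec$elements)
  if (grepl("^soil_", to)) {
    if (!to %in% soil_nodes) stop("unknown soil node `", to, "`")
    if (!from %in% abiotic) stop("no edge from `", from, "` to `", to, "`")
    return(paste0(to, "_", from))
  }
  if (grepl("^fol_", to)) {
    parts <- strsplit(to, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[2] %in% spec$genus_levels) {
      stop("foliage node must be written `fol_<response>:<genus>`")
    }
    if (!from %in% c(abiotic, soil_nodes)) {
      stop("no edge from `", from, "` to `", to, "`")
    }
    return(paste0(parts[1], "_", parts[2], "_", from))
  }
  if (grepl("^herb", to)) {
    genus <- sub("^herb:", "", to)
    if (!genus %in% spec$genus_levels) stop("herbivory node must be `herb:<genus>`")
    if (grepl("^fol_", from)) {
      fparts <- strsplit(from, ":", fixed = TRUE)[[1]]
      if (length(fparts) == 2 && fparts[2] != genus) {
        stop("broken chain: foliage genus `", fparts[2],
             "` does not match herbivory genus `", genus, "`")
      }
      return(paste0("herb_", genus, "_", fparts[1]))
    }
    if (!from %in% c(abiotic, soil_nodes)) {
      stop("no edge from `", from, "` to `", to, "`")
    }
    return(paste0("herb_", genus, "_", from))
  }
  stop("unknown node `", to, "`")
}

#' Indirect effect along a path through the tier cascade
#'
#' Multiplies the standardized linear coefficients along an ordered chain of
#' model edges, draw by draw (never from summarized means), and summarizes
#' the product with its equal-tailed credible interval. Nodes are written as
#' `"MAT"`, `"MAP"`, a geology class, `"soil_<element>"`,
#' `"fol_<response>:<genus>"` or `"herb:<genus>"`; quadratic terms do not
#' form path edges.
#'
#' @param draws an `hbm_draws` from the full model fit.
#' @param nodes character vector of nodes, head to tail (at least 2).
#' @param level credible-interval mass (default 0.89).
#' @return object of class `path_effect`: list with `nodes`, `coefficients`
#'   (the edge parameter names), `draws` (the per-draw product) and
#'   `summary` (as in [summarize_effect()]).
#' @export
indirect_effect <- function(draws, nodes, level = 0.89) {
  if (length(nodes) < 2) stop("a path needs at least two nodes")
  spec <- attr(draws$par_info, "spec")
  if (is.null(spec)) spec <- .spec_from_parnames(draws)
  coefs <- character(length(nodes) - 1)
  for (k in seq_len(length(nodes) - 1)) {
    coefs[k] <- .edge_coefficient(nodes[k], nodes[k + 1], spec)
  }
  prod_draws <- Reduce(`*`, lapply(coefs, draws_of, draws = draws))
  summ <- .summ_vec(prod_draws, paste(nodes, collapse = " -> "), level)
  structure(list(nodes = nodes, coefficients = coefs, draws = prod_draws,
                 summary = summ),
            class = "path_effect")
}

# Reconstruct the minimal spec information needed for edge naming from the
# parameter names themselves (used when draws come without an attached spec).
.spec_from_parnames <- function(draws) {
  nm <- draws$par_info$name
  elements <- unique(sub("^soil_([^_]+)_.*$", "\\1", nm[grepl("^soil_", nm)]))
  fol <- nm[grepl("^fol_.*_sigma$", nm)]
  responses <- sub("^fol_(.*)_sigma$", "\\1", fol)
  herb_int <- nm[grepl("^herb_int_", nm)]
  species <- sub("^herb_int_", "", herb_int)
  slope_nm <- nm[grepl("^herb_", nm) & !grepl("^herb_(int_|u_|site_sd|phi)", nm)]
  genus <- unique(sub("^herb_([^_]+)_.*$", "\\1", slope_nm))
  soil_cols <- nm[grepl(paste0("^soil_", elements[1], "_"), nm)]
  soil_cols <- sub(paste0("^soil_", elements[1], "_"), "", soil_cols)
  geology <- setdiff(soil_cols, c("intercept", "MAT", "MAT2", "MAP", "MAP2", "sigma"))
  list(elements = elements, responses = responses, species = species,
       genus_levels = genus, geology_levels = c("reference", geology))
}

#' Directed graph of retained effects and abiotic-to-herbivory paths
#'
#' Builds the path diagram the fitted cascade implies: every linear
#' coefficient whose credible interval excludes zero becomes a signed edge
#' (sign of the posterior mean), and all 1- and 2-edge directed paths from an
#' abiotic node (climate or geology) to a herbivory node through retained
#' edges are enumerated, each with its draw-wise product effect. The graph is
#' acyclic by construction because edges only point down the tier ordering.
#'
#' @param draws an `hbm_draws` from the full model fit.
#' @param level credible-interval mass used for retention (default 0.89).
#' @return object of class `hbm_path_graph`: list with `edges` (data.frame
#'   `from`, `to`, `coefficient`, `mean`, `lower`, `upper`, `sign`),
#'   `paths` (list of [indirect_effect()] results over retained edges) and
#'   `level`.
#' @export
build_path_graph <- function(draws, level = 0.89) {
  spec <- .spec_from_parnames(draws)
  abiotic <- c("MAT", "MAP", spec$geology_levels[-1])
  soil_nodes <- paste0("soil_", spec$elements)
  fol_nodes <- as.vector(outer(paste0("fol_", spec$responses),
                               spec$genus_levels, paste, sep = ":"))
  herb_nodes <- paste0("herb:", spec$genus_levels)

  cand <- list()
  add <- function(from, to) {
    coef <- .edge_coefficient(from, to, spec)
    cand[[length(cand) + 1]] <<- data.frame(from = from, to = to,
                                            coefficient = coef,
                                            stringsAsFactors = FALSE)
  }
  for (s in soil_nodes) for (a in abiotic) add(a, s)
  for (f in fol_nodes) for (x in c(abiotic, soil_nodes)) add(x, f)
  for (h in herb_nodes) {
    g <- sub("^herb:", "", h)
    my_fol <- fol_nodes[endsWith(fol_nodes, paste0(":", g))]
    for (x in c(abiotic, soil_nodes, my_fol)) add(x, h)
  }
  cand <- do.call(rbind, cand)

  summ <- summarize_effects(draws, cand$coefficient, level = level)
  edges <- cbind(cand, summ[, c("mean", "lower", "upper", "excludes_zero")])
  edges$sign <- ifelse(edges$mean >= 0, "+", "-")
  retained <- edges[edges$excludes_zero, , drop = FALSE]
  rownames(retained) <- NULL

  paths <- list()
  direct <- retained[retained$from %in% abiotic & retained$to %in% herb_nodes, ]
  for (k in seq_len(nrow(direct))) {
    paths[[length(paths) + 1]] <-
      indirect_effect(draws, c(direct$from[k], direct$to[k]), level)
  }
  mid <- retained[retained$from %in% abiotic &
                    retained$to %in% c(soil_nodes, fol_nodes), ]
  for (k in seq_len(nrow(mid))) {
    onward <- retained[retained$from == mid$to[k] & retained$to %in% herb_nodes, ]
    for (j in seq_len(nrow(onward))) {
      paths[[length(paths) + 1]] <-
        indirect_effect(draws, c(mid$from[k], mid$to[k], onward$to[j]), level)
    }
  }
  structure(list(edges = retained, all_edges = edges, paths = paths,
                 level = level),
            class = "hbm_path_graph")
}

#' Contrast of genus-specific slopes
#'
#' Draw-wise difference (second genus minus first, by default the
#' late-successional minus the pioneer genus) of the two genus slopes for one
#' predictor-response pair, summarized like any effect.
#'
#' @param draws an `hbm_draws`.
#' @param predictor predictor name as used in coefficient names (e.g.
#'   `"soil_Na"`, `"MAT"`, `"fol_totalN"`).
#' @param response a foliar response name (e.g. `"totalN"`, `"Ndig"`) or
#'   `"herb"` for the herbivory tier.
#' @param level credible-interval mass (default 0.89).
#' @return one-row data.frame as in [summarize_effect()].
#' @export
genus_contrast <- function(draws, predictor, response, level = 0.89) {
  spec <- .spec_from_parnames(draws)
  if (length(spec$genus_levels) != 2) {
    stop("genus contrast needs exactly two genus levels")
  }
  prefix <- if (identical(response, "herb")) "herb" else paste0("fol_", response)
  nms <- paste0(prefix, "_", spec$genus_levels, "_", predictor)
  diff_draws <- draws_of(draws, nms[2]) - draws_of(draws, nms[1])
  .summ_vec(diff_draws, paste0(nms[2], " - ", nms[1]), level)
}
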