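#' Sympatric and allopatric infection/susceptibility rates
#'
#' For each entity (phage or strain) the rate is the fraction of successful
#' interactions over a set of partners on the other side of the network:
#' from the phage perspective, the proportion of strains a phage infects;
#' from the strain perspective, the proportion of phages that infect the
#' strain.  Partners from the entity's own site are sympatric, all others
#' allopatric (phages isolated via the standard laboratory collection carry
#' the site of the soil filtrate used for their enrichment, so they
#' participate like locally-isolated phages).
#'
#' @param mat binary infection matrix (rows = strains, columns = phages).
#' @param metadata metadata with columns `id`, `site` (and optionally
#'   `region`, `collection`) covering every matrix identifier.
#' @param perspective `"phage"` (infection rates) or `"strain"`
#'   (susceptibility rates).
#' @param partner_sites optional character vector restricting partners to
#'   these sites (e.g. the sites of one region, for within-region contrasts).
#' @param entity_sites optional character vector restricting the focal
#'   entities to these sites (paired with `partner_sites` for region-level
#'   contrasts).
#' @param collection optional `"LC"`/`"SC"` filter on the focal entities
#'   (requires a `collection` metadata column).
#' @return data frame of class `"rate_table"` with one row per entity:
#'   `id`, `site`, `region`, `collection`, `rate` (all partners),
#'   `sympatric_rate`, `allopatric_rate`, `sympatric_n`, `allopatric_n`.
#' @export
entity_rates <- function(mat, metadata, perspective = c("phage", "strain"),
                         partner_sites = NULL, entity_sites = NULL,
                         collection = NULL) {
  perspective <- match.arg(perspective)
  m <- as_binary_matrix(mat)
  check_metadata_cover(m, metadata)
  md <- metadata[match(c(rownames(m), colnames(m)), metadata$id), ]
  strain_md <- md[seq_len(nrow(m)), ]
  phage_md <- md[nrow(m) + seq_len(ncol(m)), ]

  if (perspective == "phage") {
    outcomes <- t(m) # entity x partner
    entity_md <- phage_md; partner_md <- strain_md
  } else {
    outcomes <- m
    entity_md <- strain_md; partner_md <- phage_md
  }
  if (!is.null(partner_sites)) {
    keep <- partner_md$site %in% partner_sites
    if (!any(keep)) stop("no partners left after site filter")
    outcomes <- outcomes[, keep, drop = FALSE]
    partner_md <- partner_md[keep, , drop = FALSE]
  }
  if (!is.null(entity_sites)) {
    keep <- entity_md$site %in% entity_sites
    if (!any(keep)) stop("no entities left after site filter")
    outcomes <- outcomes[keep, , drop = FALSE]
    entity_md <- entity_md[keep, , drop = FALSE]
  }
  if (!is.null(collection)) {
    if (is.null(entity_md$collection)) stop("metadata has no collection column")
    keep <- entity_md$collection %in% collection
    if (!any(keep)) stop("no entities left after collection filter")
    outcomes <- outcomes[keep, , drop = FALSE]
    entity_md <- entity_md[keep, , drop = FALSE]
  }
  symp <- outer(entity_md$site, partner_md$site, "==")
  n_symp <- rowSums(symp)
  n_allo <- ncol(outcomes) - n_symp
  if (any(n_symp == 0))
    stop("entity with an empty sympatric partner set: ",
         paste(utils::head(entity_md$id[n_symp == 0], 3), collapse = ", "))
  if (any(n_allo == 0))
    stop("entity with an empty allopatric partner set: ",
         paste(utils::head(entity_md$id[n_allo == 0], 3), collapse = ", "))
  res <- data.frame(
    id = entity_md$id,
    site = entity_md$site,
    region = if (!is.null(entity_md$region)) entity_md$region else NA,
    collection = if (!is.null(entity_md$collection)) entity_md$collection else NA,
    rate = rowMeans(outcomes),
    sympatric_rate = rowSums(outcomes * symp) / n_symp,
    allopatric_rate = rowSums(outcomes * !symp) / n_allo,
    sympatric_n = n_symp,
    allopatric_n = n_allo,
    stringsAsFactors = FALSE)
  attr(res, "perspective") <- perspective
  class(res) <- c("rate_table", class(res))
  res
}

#' Local-adaptation index from a rate table
#'
#' The index is the difference between the mean sympatric rate (S) and the
#' mean allopatric rate (A) over the entities in scope.  From the phage
#' perspective a positive index indicates phage local adaptation; from the
#' strain perspective, higher sympatric than allopatric susceptibility
#' indicates host maladaptation to the local phages.
#'
#' @param rates a `"rate_table"` from [entity_rates()].
#' @param scope `"overall"`, `"region"` or `"site"`: grouping at which the
#'   means are taken.
#' @return data frame of class `"local_adaptation"`: one row per group with
#'   `n`, `mean_S`, `mean_A`, `la_index`, standard errors, coefficients of
#'   variation and variances of each rate set.
#' @export
local_adaptation <- function(rates, scope = c("overall", "region", "site")) {
  scope <- match.arg(scope)
  if (nrow(rates) == 0L) stop("empty rate table")
  groups <- switch(scope,
    overall = rep("overall", nrow(rates)),
    region = as.character(rates$region),
    site = as.character(rates$site))
  if (scope != "overall" && anyNA(groups))
    stop("rate table lacks the metadata column needed for scope ", scope)
  out <- do.call(rbind, lapply(split(rates, groups), function(g) {
    s <- g$sympatric_rate; a <- g$allopatric_rate
    data.frame(
      scope = scope, group = g[[if (scope == "site") "site" else
        if (scope == "region") "region" else "id"]][1],
      n = nrow(g),
      mean_S = mean(s), mean_A = mean(a),
      la_index = mean(s) - mean(a),
      se_S = stats::sd(s) / sqrt(length(s)),
      se_A = stats::sd(a) / sqrt(length(a)),
      cv_S = stats::sd(s) / mean(s), cv_A = stats::sd(a) / mean(a),
      var_S = stats::var(s), var_A = stats::var(a),
      stringsAsFactors = FALSE)
  }))
  if (scope == "overall") out$group <- "overall"
  rownames(out) <- NULL
  class(out) <- c("local_adaptation", class(out))
  out
}

#' Quasi-binomial GLM F-test for sympatric vs allopatric rates
#'
#' Each entity contributes two proportion observations, its sympatric and
#' its allopatric rate, with a binary sympatry predictor.  A logit-link
#' binomial GLM is fitted with quasi-likelihood dispersion (Pearson
#' chi-squared over residual df), and the sympatry effect is tested with the
#' dispersion-scaled F-test: F = (deviance_null - deviance_full) /
#' (delta_df * phi).  With n entities the residual df is 2n - 2 (e.g.
#' F with df 1 and 390 for 196 phages).  Unweighted proportions are the
#' default; `weight = TRUE` weights each observation by its partner count.
#'
#' @param rates a `"rate_table"`.
#' @param weight logical; weight observations by partner counts.
#' @return list of class `"glm_f_result"`: `f_statistic`, `df1`, `df2`,
#'   `p_value`, `dispersion`, `coefficients` (logit scale), `fit`.
#' @export
quasibinomial_f_test <- function(rates, weight = FALSE) {
  s <- rates$sympatric_rate; a <- rates$allopatric_rate
  if (any(c(s, a) < 0 | c(s, a) > 1)) stop("rates must lie in [0, 1]")
  df <- data.frame(
    rate = c(s, a),
    sympatric = factor(rep(c("sympatric", "allopatric"), each = nrow(rates)),
                       levels = c("allopatric", "sympatric")),
    w = if (weight) c(rates$sympatric_n, rates$allopatric_n) else
      rep(1, 2 * nrow(rates)))
  fit <- stats::glm(rate ~ sympatric, family = stats::quasibinomial(),
                    data = df, weights = df$w)
  if (!fit$converged) stop("quasi-binomial GLM did not converge")
  an <- stats::anova(fit, test = "F")
  phi <- sum(stats::residuals(fit, "pearson")^2) / fit$df.residual
  structure(list(
    f_statistic = an[["F"]][2], df1 = an[["Df"]][2],
    df2 = fit$df.residual, p_value = an[["Pr(>F)"]][2],
    dispersion = phi,
    coefficients = stats::coef(fit), fit = fit), class = "glm_f_result")
}

#' @export
print.glm_f_result <- function(x, ...) {
  cat(sprintf("Quasi-binomial GLM: F(%d, %d) = %.2f, p = %.3g (dispersion %.3f)\n",
              x$df1, x$df2, x$f_statistic, x$p_value, x$dispersion))
  invisible(x)
}

#' Mean rates for every entity-site by partner-site pair
#'
#' The diagonal holds sympatric rates; off-diagonal cells give cross-site
#' infection (or susceptibility) structure, mirroring among-population
#' rate matrices.
#'
#' @inheritParams entity_rates
#' @return numeric matrix, entity sites x partner sites.
#' @export
site_by_site_rates <- function(mat, metadata, perspective = c("phage", "strain")) {
  perspective <- match.arg(perspective)
  m <- as_binary_matrix(mat)
  check_metadata_cover(m, metadata)
  md <- metadata[match(c(rownames(m), colnames(m)), metadata$id), ]
  strain_md <- md[seq_len(nrow(m)), ]
  phage_md <- md[nrow(m) + seq_len(ncol(m)), ]
  if (perspective == "phage") {
    outcomes <- t(m); entity_md <- phage_md; partner_md <- strain_md
  } else {
    outcomes <- m; entity_md <- strain_md; partner_md <- phage_md
  }
  e_sites <- sort(unique(entity_md$site))
  p_sites <- sort(unique(partner_md$site))
  res <- matrix(NA_real_, length(e_sites), length(p_sites),
                dimnames = list(entity_site = e_sites, partner_site = p_sites))
  for (es in e_sites) {
    rows <- entity_md$site == es
    if (!any(rows)) stop("site with zero entities: ", es)
    for (ps in p_sites) {
      cols <- partner_md$site == ps
      # mean over entities of each entity's per-partner-site rate
      res[es, ps] <- mean(rowMeans(outcomes[rows, cols, drop = FALSE]))
    }
  }
  res
}
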