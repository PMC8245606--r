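#' Distance-based community composition statistics
#'
#' Thin, seeded wrappers around the standard vegan machinery (vegdist,
#' adonis2, mantel, pcnm, envfit) plus a principal-coordinates analysis,
#' operating on per-sample count tables of genotype or phenotype types.
#'
#' @name community-stats
#' @keywords internal
NULL

#' Distance matrix between community samples
#'
#' Jaccard distances are computed on presence/absence; Bray-Curtis distances
#' on relative abundances (rows normalized to sum 1).
#'
#' @param counts samples x types count matrix (row names = sample ids).
#' @param metric `"jaccard_binary"` or `"bray_curtis"`.
#' @return a `dist` object.
#' @export
community_distances <- function(counts, metric = c("jaccard_binary", "bray_curtis")) {
  metric <- match.arg(metric)
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop("need at least two samples")
  if (any(counts < 0)) stop("negative counts")
  if (any(rowSums(counts) == 0)) stop("zero-sum sample")
  if (metric == "jaccard_binary")
    vegan::vegdist(counts, method = "jaccard", binary = TRUE)
  else
    vegan::vegdist(counts / rowSums(counts), method = "bray")
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the double-centred Gower matrix.  Coordinates are
#' returned for the positive eigenvalues only; negative eigenvalues (from
#' non-Euclidean distances) are reported but carry no axes.
#'
#' @param d a `dist` object or symmetric distance matrix (n >= 3).
#' @return list of class `"pcoa_result"`: `points` (samples x positive
#'   axes), `eig` (all eigenvalues, decreasing), `prop_explained`
#'   (per positive axis, relative to the sum of positive eigenvalues).
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 3L) stop("PCoA needs at least 3 samples")
  if (!isTRUE(all.equal(dm, t(dm))) || any(diag(dm) != 0))
    stop("not a valid distance matrix")
  g <- -0.5 * dm^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))
  g <- g + mean(-0.5 * dm^2)
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                 sum(pos), sum(pos))
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("Axis.", seq_len(ncol(pts)))
  structure(list(points = pts, eig = e$values,
                 prop_explained = e$values[pos] / sum(e$values[pos])),
            class = "pcoa_result")
}

#' Permutational multivariate analysis of variance
#'
#' McArdle-Anderson partitioning of a distance matrix over a one- or
#' two-factor design with sequential (Type I) sums of squares and raw-data
#' permutation of sample identities, via `vegan::adonis2(by = "terms")`.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param design data frame of factors, rows aligned with `d`.
#' @param terms character vector of 1 or 2 design columns, in the order the
#'   sequential sums of squares should be assigned.
#' @param interaction include the two-factor interaction term.
#' @param permutations number of permutations (default 999).
#' @param seed integer seed; fixed seed gives bit-reproducible p-values.
#' @return list of class `"permutation_test"`: `table` (per-term df, SS, R2,
#'   F, p), `statistic` and `p_value` for the first term, `permutations`,
#'   `seed`.
#' @export
permanova <- function(d, design, terms, interaction = FALSE,
                      permutations = 999, seed = NULL) {
  if (!length(terms) %in% 1:2) stop("one or two terms are supported")
  if (!all(terms %in% names(design))) stop("terms must name design columns")
  design <- as.data.frame(design)
  for (tm in terms) {
    design[[tm]] <- factor(design[[tm]])
    if (nlevels(design[[tm]]) < 2) stop("factor with fewer than 2 levels: ", tm)
  }
  dm <- stats::as.dist(d)
  n <- attr(dm, "Size")
  if (nrow(design) != n) stop("design rows must match distance matrix size")
  rhs <- paste(terms, collapse = if (interaction) " * " else " + ")
  form <- stats::as.formula(paste("dm ~", rhs))
  run <- function() vegan::adonis2(form, data = design, by = "terms",
                                   permutations = permutations)
  a <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tab <- as.data.frame(a)
  if (tab["Residual", "SumOfSqs"] <= max(1e-12, sum(tab$SumOfSqs) * 1e-12))
    stop("zero residual variation: pseudo-F is undefined")
  structure(list(table = tab, statistic = tab[["F"]][1],
                 p_value = tab[["Pr(>F)"]][1],
                 permutations = permutations, seed = seed),
            class = "permutation_test")
}

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation of the corresponding off-diagonal entries, with
#' significance from simultaneous row/column permutation of one matrix
#' (add-one rule), via `vegan::mantel`.
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same samples
#'   in the same order.
#' @param permutations number of permutations (default 999).
#' @param seed integer seed.
#' @return list of class `"permutation_test"` with `statistic` (r) and
#'   `p_value`.
#' @export
mantel_test <- function(d1, d2, permutations = 999, seed = NULL) {
  d1 <- stats::as.dist(d1); d2 <- stats::as.dist(d2)
  if (attr(d1, "Size") != attr(d2, "Size"))
    stop("distance matrices must have the same size")
  if (stats::sd(as.vector(d1)) == 0 || stats::sd(as.vector(d2)) == 0)
    stop("constant distance vector: Mantel r is undefined")
  run <- function() vegan::mantel(d1, d2, permutations = permutations)
  m <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(statistic = unname(m$statistic), p_value = m$signif,
                 permutations = permutations, seed = seed,
                 table = NULL), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  if (!is.null(x$table)) {
    cat("Permutation test (", x$permutations, " permutations):\n", sep = "")
    print(x$table)
  } else {
    cat(sprintf("statistic = %.4f, p = %.4g (%d permutations)\n",
                x$statistic, x$p_value, x$permutations))
  }
  invisible(x)
}

#' Principal coordinates of neighbour matrices (spatial eigenvectors)
#'
#' Orthogonal spatial variables from a truncated geographic distance matrix
#' (distances beyond the threshold, by default the longest edge of the
#' minimum spanning tree, are set to 4x the threshold), via `vegan::pcnm`.
#' The first eigenvector (PCNM1) captures the broadest spatial contrast,
#' e.g. the separation between two regions.
#'
#' @param coords matrix of coordinates (rows = locations) or a `dist`.
#' @param threshold optional truncation distance.
#' @return list of class `"pcnm_result"`: `vectors` (locations x PCNM axes),
#'   `values` (eigenvalues), `threshold`.
#' @export
pcnm_vectors <- function(coords, threshold = NULL) {
  d <- if (inherits(coords, "dist")) coords else stats::dist(as.matrix(coords))
  if (attr(d, "Size") < 3L) stop("need at least 3 locations")
  if (all(as.vector(d) == 0)) stop("all locations identical")
  p <- if (is.null(threshold)) vegan::pcnm(d) else vegan::pcnm(d, threshold = threshold)
  structure(list(vectors = as.matrix(p$vectors), values = p$values,
                 threshold = p$threshold), class = "pcnm_result")
}

#' Fit a variable onto an ordination
#'
#' Squared multiple correlation (r2) of the regression of a per-sample
#' variable on the ordination axes, with significance by permuting the
#' variable, via `vegan::envfit`.
#'
#' @param ordination a `"pcoa_result"` (or any matrix of sample scores).
#' @param variable numeric vector, one value per sample.
#' @param permutations number of permutations (default 9999).
#' @param seed integer seed.
#' @param choices which axes to use (default all positive axes).
#' @return list of class `"permutation_test"` with `statistic` (r2) and
#'   `p_value`.
#' @export
envfit_vector <- function(ordination, variable, permutations = 9999,
                          seed = NULL, choices = NULL) {
  pts <- if (inherits(ordination, "pcoa_result")) ordination$points
         else as.matrix(ordination)
  if (length(variable) != nrow(pts))
    stop("variable length must equal the number of samples")
  if (stats::sd(variable) == 0) stop("constant variable")
  if (!is.null(choices)) pts <- pts[, choices, drop = FALSE]
  run <- function() vegan::envfit(pts, data.frame(v = variable),
                                  permutations = permutations,
                                  choices = seq_len(ncol(pts)))
  ef <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(statistic = unname(ef$vectors$r), p_value = ef$vectors$pvals,
                 permutations = permutations, seed = seed, table = NULL),
            class = "permutation_test")
}
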