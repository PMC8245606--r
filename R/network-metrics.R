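#' Connectance of a bipartite binary network
#'
#' The fraction of realized interactions: number of 1-cells divided by the
#' number of tested phage-strain pairs.
#'
#' @param mat binary matrix (rows = strains, columns = phages).
#' @return fraction in \[0, 1\].
#' @export
connectance <- function(mat) {
  m <- as_binary_matrix(mat)
  if (length(m) == 0L) stop("empty matrix")
  sum(m) / length(m)
}

#' Nestedness metric based on overlap and decreasing fill (NODF)
#'
#' For every pair of rows with strictly different fills (both non-zero for
#' the smaller), the paired term is the number of shared 1-columns divided by
#' the smaller fill; pairs with equal fills contribute 0.  The same is
#' computed over column pairs, and NODF is the mean over all row and column
#' pairs.  Because the decreasing-fill condition is evaluated on fills, not
#' positions, the metric is invariant under row/column permutation.
#'
#' @param mat binary matrix with at least 2 rows and 2 columns.
#' @return NODF on the \[0, 1\] scale (multiply by 100 for the conventional
#'   percentage scale).
#' @export
nodf <- function(mat) {
  m <- as_binary_matrix(mat)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("NODF needs at least 2 rows and 2 columns")
  axis_sum <- function(m) {
    f <- rowSums(m)
    s <- tcrossprod(m) # shared 1-columns for each row pair
    fmin <- outer(f, f, pmin)
    ok <- outer(f, f, "!=") & fmin > 0
    ut <- upper.tri(s)
    sum((s / pmax(fmin, 1L))[ok & ut])
  }
  n_pairs <- choose(nrow(m), 2) + choose(ncol(m), 2)
  (axis_sum(m) + axis_sum(t(m))) / n_pairs
}

#' Nestedness temperature of a packed matrix
#'
#' Implements the matrix-temperature idea behind the Nestedness Temperature
#' Calculator: the matrix is packed by decreasing row and column totals (ties
#' broken by original index), an isocline of perfect nestedness is fitted for
#' the observed fill, and each unexpected cell (a presence beyond the
#' isocline or an absence inside it) contributes its squared normalized
#' distance from the isocline, measured along the diagonal through the cell.
#' The sum is scaled by the conventional constant so that temperature lies in
#' \[0, 100\]; 0 is perfectly nested, 100 maximally disordered.
#'
#' The isocline family used is `y = (1 - (1 - x)^phi)^(1/phi)` on the unit
#' square, with `phi` solved numerically so the area of the presence region
#' above the curve equals the matrix fill.
#'
#' All-zero rows and columns carry no packing information and are dropped
#' with a warning before the computation.
#'
#' @param mat binary matrix, at least 3x3 after dropping empty lines.
#' @return a list of class `"ntc_result"`: `temperature` (T in \[0, 100\]),
#'   `nestedness` ((100 - T)/100), `phi`, and the packing permutations
#'   `row_order`, `col_order`.
#' @export
nestedness_temperature <- function(mat) {
  m <- as_binary_matrix(mat)
  zr <- rowSums(m) == 0
  zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warning(sprintf("dropping %d all-zero row(s) and %d all-zero column(s) before packing",
                    sum(zr), sum(zc)))
    m <- m[!zr, !zc, drop = FALSE]
  }
  if (nrow(m) < 3L || ncol(m) < 3L)
    stop("matrix too small for isocline fit (need at least 3x3 non-empty)")
  rs <- rowSums(m); cs <- colSums(m)
  # pack by decreasing marginal totals; ties broken lexicographically on the
  # line's pattern over the other axis's packed order (iterated to a fixed
  # point), so the packing is invariant under input permutation
  row_order <- order(-rs, -as.vector(m %*% cs))
  col_order <- order(-cs, -as.vector(crossprod(m, rs)))
  for (it in 1:10) {
    rkeys <- apply(m[, col_order, drop = FALSE], 1, paste0, collapse = "")
    new_row <- order(-rs, -rank(rkeys, ties.method = "min"))
    ckeys <- apply(m[new_row, , drop = FALSE], 2, paste0, collapse = "")
    new_col <- order(-cs, -rank(ckeys, ties.method = "min"))
    if (identical(new_row, row_order) && identical(new_col, col_order)) break
    row_order <- new_row; col_order <- new_col
  }
  p <- m[row_order, col_order, drop = FALSE]
  nr <- nrow(p); nc <- ncol(p)
  fill <- sum(p) / length(p)

  iso <- function(x, phi) (1 - (1 - x)^phi)^(1 / phi)
  area_under <- function(phi) stats::integrate(iso, 0, 1, phi = phi,
                                               rel.tol = 1e-9)$value
  # presence region is above the curve; its area must equal the fill
  target <- 1 - fill
  f_of <- function(lphi) area_under(exp(lphi)) - target
  phi <- exp(stats::uniroot(f_of, c(-12, 12), tol = 1e-10)$root)

  # cell centres in the unit square; y runs upward so row 1 (most filled) is on top
  x <- (col(p) - 0.5) / nc
  y <- 1 - (row(p) - 0.5) / nr
  above <- y > iso(x, phi)
  unexpected <- (p == 1 & !above) | (p == 0 & above)
  u2 <- 0
  if (any(unexpected)) {
    xu <- x[unexpected]; yu <- y[unexpected]
    # distance to the isocline along the (1, -1) diagonal through each cell,
    # normalized by the diagonal's length inside the unit square
    tlo <- pmax(-xu, yu - 1)
    thi <- pmin(1 - xu, yu)
    g <- function(t) yu - t - iso(xu + t, phi) # decreasing in t
    lo <- tlo; hi <- thi
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      pos <- g(mid) > 0
      lo[pos] <- mid[pos]
      hi[!pos] <- mid[!pos]
    }
    tstar <- (lo + hi) / 2
    u2 <- sum((abs(tstar) / (thi - tlo))^2)
  }
  temp <- min(100, (100 / 0.04145) * u2 / length(p))
  structure(list(temperature = temp, nestedness = (100 - temp) / 100,
                 phi = phi, fill = fill,
                 row_order = if (any(zr)) which(!zr)[row_order] else row_order,
                 col_order = if (any(zc)) which(!zc)[col_order] else col_order),
            class = "ntc_result")
}

#' @export
print.ntc_result <- function(x, ...) {
  cat(sprintf("Nestedness temperature T = %.2f (nestedness %.3f, fill %.3f)\n",
              x$temperature, x$nestedness, x$fill))
  invisible(x)
}
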