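#' Binary infection matrices and spot-assay consensus calling
#'
#' The central data structure of the package is a complete binary
#' phage-by-strain infection matrix: rows are bacterial strains, columns are
#' phages, and a cell is 1 when the phage lyses the strain (full or partial
#' lysis in the spot assay) and 0 when the strain resists.  This orientation
#' (rows = strains, columns = phages) is fixed throughout the package.
#'
#' @name infection-data
#' @keywords internal
NULL

.spot_levels <- c("full_lysis", "partial_lysis", "resistant")
.lytic_levels <- c("full_lysis", "partial_lysis")

#' Construct and validate a binary infection matrix
#'
#' Checks that `cells` is a complete binary matrix (no missing values: the
#' assay design tests every phage against every strain, so an absent cell is
#' an error, not a zero) with unique strain (row) and phage (column)
#' identifiers.
#'
#' @param cells matrix of 0/1 values; rows are strains, columns are phages.
#' @param strain_ids,phage_ids character identifiers; default taken from
#'   `dimnames(cells)`.
#' @return an integer matrix with class `"infection_matrix"`, rows named by
#'   strain, columns by phage.
#' @export
infection_matrix <- function(cells, strain_ids = rownames(cells),
                             phage_ids = colnames(cells)) {
  cells <- as.matrix(cells)
  if (length(cells) == 0L) stop("infection matrix is empty")
  if (is.null(strain_ids) || is.null(phage_ids))
    stop("strain and phage identifiers are required")
  strain_ids <- as.character(strain_ids)
  phage_ids <- as.character(phage_ids)
  if (length(strain_ids) != nrow(cells) || length(phage_ids) != ncol(cells))
    stop("identifier lists do not match matrix dimensions")
  if (anyDuplicated(strain_ids)) stop("duplicate strain identifiers")
  if (anyDuplicated(phage_ids)) stop("duplicate phage identifiers")
  if (anyNA(cells))
    stop("missing cells: every phage-strain pair must have a consensus call")
  if (!all(cells %in% c(0, 1))) stop("cells must all be 0 or 1")
  storage.mode(cells) <- "integer"
  dimnames(cells) <- list(strain = strain_ids, phage = phage_ids)
  class(cells) <- c("infection_matrix", class(cells))
  cells
}

#' @export
print.infection_matrix <- function(x, ...) {
  cat(sprintf("Infection matrix: %d strains x %d phages, fill = %.3f\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

# strip class for arithmetic-heavy internals
as_binary_matrix <- function(m) {
  if (inherits(m, "infection_matrix")) {
    cls <- class(m)
    class(m) <- setdiff(cls, "infection_matrix")
  }
  m <- as.matrix(m)
  if (anyNA(m) || !all(m %in% c(0, 1))) stop("matrix must be binary (0/1)")
  storage.mode(m) <- "integer"
  m
}

#' Consensus call for replicated spot assays
#'
#' Collapses replicate spot-assay outcomes for one phage-strain pair to a
#' binary interaction.  Full and partial lysis both count as lytic; an
#' interaction is positive when the lytic outcome is seen in the majority of
#' replicates (at least 2 of 3 in the standard design) and negative when the
#' resistant outcome is.  A tie (e.g. one lytic and one resistant replicate)
#' is indeterminate: the pair must be re-assayed, so the call errors rather
#' than imputing.
#'
#' @param outcomes character vector of at least two replicate outcomes, each
#'   one of `"full_lysis"`, `"partial_lysis"` or `"resistant"`.
#' @return integer 0 or 1.
#' @examples
#' consensus_call(c("full_lysis", "full_lysis", "resistant")) # 1
#' consensus_call(c("partial_lysis", "full_lysis", "resistant")) # 1
#' @export
consensus_call <- function(outcomes) {
  outcomes <- as.character(outcomes)
  if (length(outcomes) < 2L)
    stop("at least two replicates are required for a consensus call")
  bad <- setdiff(outcomes, .spot_levels)
  if (length(bad))
    stop("unknown spot outcome(s): ", paste(unique(bad), collapse = ", "))
  n_lytic <- sum(outcomes %in% .lytic_levels)
  n_resistant <- length(outcomes) - n_lytic
  if (n_lytic == n_resistant)
    stop(sprintf(
      "indeterminate consensus (%d lytic vs %d resistant): pair must be re-assayed",
      n_lytic, n_resistant))
  as.integer(n_lytic > n_resistant)
}

#' Read an infection matrix and its metadata from CSV
#'
#' Two matrix dialects are supported.  The wide format has strain identifiers
#' in the first column, phage identifiers in the header row, and 0/1 cells.
#' The long format has columns `phage_id`, `strain_id` and two or more
#' replicate columns (`rep1`, `rep2`, ...) holding raw categorical spot
#' outcomes; these are collapsed with [consensus_call()] and the matrix must
#' cover every phage-strain pair exactly once.
#'
#' The metadata file has columns `id`, `entity_class` (`phage`/`strain`),
#' `site`, `region`, `taxon`, `genotype`, `collection`.  Every matrix
#' identifier must have exactly one metadata record.
#'
#' @param matrix_path path to the wide or long interaction CSV.
#' @param metadata_path path to the metadata CSV (optional; `NULL` to skip).
#' @param format `"wide"` or `"long"`.
#' @return a list with elements `matrix` (an [infection_matrix()]) and
#'   `metadata` (a data frame or `NULL`).
#' @export
read_interaction_data <- function(matrix_path, metadata_path = NULL,
                                  format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    raw <- utils::read.csv(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    strain_ids <- as.character(raw[[1]])
    cells <- as.matrix(raw[, -1, drop = FALSE])
    mat <- infection_matrix(cells, strain_ids, colnames(raw)[-1])
  } else {
    raw <- utils::read.csv(matrix_path, stringsAsFactors = FALSE)
    need <- c("phage_id", "strain_id")
    if (!all(need %in% names(raw)))
      stop("long format requires columns phage_id and strain_id")
    rep_cols <- grep("^rep[0-9]+$", names(raw), value = TRUE)
    if (length(rep_cols) < 2L)
      stop("long format requires at least two replicate columns (rep1, rep2, ...)")
    key <- paste(raw$strain_id, raw$phage_id, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate phage-strain pair in long table")
    calls <- vapply(seq_len(nrow(raw)), function(i) {
      out <- as.character(unlist(raw[i, rep_cols]))
      out <- out[!is.na(out) & nzchar(out)]
      tryCatch(consensus_call(out), error = function(e)
        stop(sprintf("pair (%s, %s): %s", raw$phage_id[i], raw$strain_id[i],
                     conditionMessage(e)), call. = FALSE))
    }, integer(1))
    strains <- unique(raw$strain_id)
    phages <- unique(raw$phage_id)
    if (nrow(raw) != length(strains) * length(phages))
      stop("long table does not cover every phage-strain pair")
    cells <- matrix(NA_integer_, length(strains), length(phages),
                    dimnames = list(strains, phages))
    cells[cbind(match(raw$strain_id, strains), match(raw$phage_id, phages))] <- calls
    mat <- infection_matrix(cells)
  }
  metadata <- NULL
  if (!is.null(metadata_path)) {
    metadata <- read_metadata(metadata_path)
    check_metadata_cover(mat, metadata)
  }
  list(matrix = mat, metadata = metadata)
}

#' @rdname read_interaction_data
#' @param path metadata CSV path.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "entity_class", "site", "region")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(md$id)) stop("duplicate identifiers in metadata")
  bad_class <- setdiff(unique(md$entity_class), c("phage", "strain"))
  if (length(bad_class))
    stop("entity_class must be 'phage' or 'strain'")
  # site determines region
  sr <- unique(md[, c("site", "region")])
  if (anyDuplicated(sr$site))
    stop("inconsistent site-to-region mapping in metadata")
  md
}

check_metadata_cover <- function(mat, metadata) {
  ids <- c(rownames(mat), colnames(mat))
  miss <- setdiff(ids, metadata$id)
  if (length(miss))
    stop("metadata missing for ", length(miss), " identifier(s), e.g. ",
         paste(utils::head(miss, 3), collapse = ", "))
  invisible(TRUE)
}

#' Write an infection matrix (wide CSV)
#'
#' Row 1 holds phage identifiers, column 1 strain identifiers, cells 0/1.
#' `read_interaction_data()` on the written file round-trips bit-exactly.
#'
#' @param mat an [infection_matrix()].
#' @param path output CSV path.
#' @export
write_interaction_matrix <- function(mat, path) {
  mat <- as_binary_matrix(mat)
  df <- data.frame(strain_id = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate an infection matrix against its metadata
#'
#' Collects errors (dataset unusable) and warnings (dataset usable but
#' noteworthy, e.g. all-zero rows or columns, which are retained in all
#' computations) plus summary counts.
#'
#' @param mat matrix to validate (anything coercible; need not pass
#'   [infection_matrix()] checks first).
#' @param metadata optional metadata data frame as read by [read_metadata()].
#' @return a list of class `"validation_report"` with elements `errors`,
#'   `warnings` and `summary`.
#' @export
validate_interaction_data <- function(mat, metadata = NULL) {
  errors <- character()
  warnings <- character()
  m <- try(as.matrix(mat), silent = TRUE)
  if (inherits(m, "try-error") || length(m) == 0L) {
    errors <- c(errors, "matrix is empty or not coercible to a matrix")
    m <- matrix(integer(), 0, 0)
  } else {
    if (anyNA(m)) errors <- c(errors, "matrix contains missing cells")
    else if (!all(m %in% c(0, 1))) errors <- c(errors, "matrix contains non-binary cells")
    if (anyDuplicated(rownames(m))) errors <- c(errors, "duplicate strain identifiers")
    if (anyDuplicated(colnames(m))) errors <- c(errors, "duplicate phage identifiers")
  }
  n_pos <- if (length(m) && !anyNA(m)) sum(m == 1) else NA_integer_
  if (length(m) && !anyNA(m) && all(m %in% c(0, 1))) {
    zr <- sum(rowSums(m) == 0)
    zc <- sum(colSums(m) == 0)
    if (zr) warnings <- c(warnings, sprintf("%d all-zero strain row(s)", zr))
    if (zc) warnings <- c(warnings, sprintf("%d all-zero phage column(s)", zc))
  }
  per_site <- NULL
  if (!is.null(metadata)) {
    ids <- c(rownames(m), colnames(m))
    miss <- setdiff(ids, metadata$id)
    if (length(miss))
      errors <- c(errors, sprintf("metadata missing for %d identifier(s)", length(miss)))
    sr <- unique(metadata[, c("site", "region")])
    if (anyDuplicated(sr$site))
      errors <- c(errors, "site-to-region mapping is not functional")
    per_site <- table(metadata$site, metadata$entity_class)
  }
  structure(list(
    errors = errors, warnings = warnings,
    summary = list(n_strains = nrow(m), n_phages = ncol(m),
                   n_cells = length(m), n_positive = n_pos,
                   fill = if (length(m)) n_pos / length(m) else NA_real_,
                   per_site = per_site)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Validation: %d strains x %d phages, %s positive of %d cells (fill %.3f)\n",
              s$n_strains, s$n_phages, format(s$n_positive), s$n_cells, s$fill))
  if (length(x$errors)) cat("Errors:\n", paste(" -", x$errors, collapse = "\n"), "\n")
  if (length(x$warnings)) cat("Warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  if (!length(x$errors)) cat("Dataset usable.\n")
  invisible(x)
}
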