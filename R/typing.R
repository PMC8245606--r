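#' Genotype and phenotype grouping rules
#'
#' Strains are grouped into sequence types (STs) by exact identity of
#' concatenated marker-gene sequences; phage genomes into genomic types
#' (PGTs) by single-linkage clustering of pairwise ANI/coverage; and both
#' sides of the infection matrix into phenotype groups (RPGs for strains,
#' PPGs for phages) by hierarchical clustering of Bray-Curtis dissimilarity
#' between interaction profiles.
#'
#' @name typing
#' @keywords internal
NULL

# shared constructor: labels by decreasing group size, ties by first member
type_assignment <- function(ids, groups, prefix, kind) {
  groups <- as.character(groups)
  first_seen <- !duplicated(groups)
  order_key <- stats::setNames(seq_along(groups)[first_seen], groups[first_seen])
  sizes <- table(groups)
  ord <- order(-as.vector(sizes[names(order_key)]), order_key)
  remap <- stats::setNames(seq_along(ord), names(order_key)[ord])
  lab_num <- unname(remap[groups])
  labels <- paste0(prefix, "-", lab_num)
  assignment <- data.frame(id = as.character(ids), type = labels,
                           stringsAsFactors = FALSE)
  structure(list(assignment = assignment, type_kind = kind,
                 n_types = length(remap),
                 n_singletons = sum(sizes == 1)),
            class = "type_assignment")
}

#' @export
print.type_assignment <- function(x, ...) {
  cat(sprintf("%s assignment: %d ids in %d types (%d singletons)\n",
              x$type_kind, nrow(x$assignment), x$n_types, x$n_singletons))
  invisible(x)
}

#' Sequence types from marker-gene identity
#'
#' Identical concatenated marker sequences (case-insensitive exact string
#' equality) share a sequence type.  Labels are `ST-1`, `ST-2`, ... by
#' decreasing abundance, ties by first occurrence.
#'
#' @param sequences named character vector: id -> concatenated marker string.
#' @return a `"type_assignment"`.
#' @export
assign_sts <- function(sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by strain id")
  seqs <- toupper(as.character(sequences))
  if (any(!nzchar(seqs)) || anyNA(seqs)) stop("empty sequence")
  type_assignment(names(sequences), seqs, "ST", "ST")
}

#' Phage genomic types from pairwise ANI and coverage
#'
#' Builds a graph with an edge between two genomes when ANI >= `ani_min`
#' percent AND alignment coverage of the smaller genome >= `cov_min` percent,
#' and takes connected components (single linkage) as genomic types.
#' Genomes with no qualifying edge become singleton types.
#'
#' @param table data frame with columns `id_a`, `id_b`, `ani`, `coverage`
#'   (percent scales); symmetric duplicates and record order do not matter.
#' @param ids optional character vector of all genome ids (to declare
#'   genomes absent from `table` as nodes).
#' @param ani_min,cov_min inclusive thresholds in percent (defaults 80, 60).
#' @return a `"type_assignment"` with labels `PGT-1`, ...
#' @export
cluster_pgts <- function(table, ids = NULL, ani_min = 80, cov_min = 60) {
  need <- c("id_a", "id_b", "ani", "coverage")
  if (!all(need %in% names(table)))
    stop("table requires columns id_a, id_b, ani, coverage")
  if (any(table$ani < 0 | table$ani > 100, na.rm = TRUE) ||
      any(table$coverage < 0 | table$coverage > 100, na.rm = TRUE))
    stop("ani and coverage must lie in [0, 100]")
  all_ids <- unique(c(as.character(table$id_a), as.character(table$id_b),
                      as.character(ids)))
  keep <- table$ani >= ani_min & table$coverage >= cov_min
  edges <- table[keep & table$id_a != table$id_b, c("id_a", "id_b")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = all_ids))
  comp <- igraph::components(g)$membership
  type_assignment(all_ids, comp[all_ids], "PGT", "PGT")
}

#' Bray-Curtis dissimilarity between two binary profiles
#'
#' For presence/absence vectors this is `1 - 2 * |shared 1s| / (|x| + |y|)`,
#' the quantity whose complement (">80% similarity") defines the phenotype
#' groups.
#'
#' @param x,y equal-length binary vectors, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis_binary <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (!all(c(x, y) %in% c(0, 1))) stop("vectors must be binary")
  sx <- sum(x); sy <- sum(y)
  if (sx + sy == 0) stop("Bray-Curtis is undefined for two all-zero profiles")
  1 - 2 * sum(x == 1 & y == 1) / (sx + sy)
}

#' Phenotype groups from interaction-profile similarity
#'
#' Clusters strains by their susceptibility profiles (matrix rows) or phages
#' by their host-range profiles (columns) with agglomerative hierarchical
#' clustering on Bray-Curtis dissimilarity, cutting the tree at
#' `cut` (default 0.2, i.e. >80% similarity within a group).  All-zero
#' profiles (entities with no interactions) are excluded with a warning,
#' since their dissimilarity to everything is undefined.
#'
#' @param mat binary infection matrix (rows = strains, columns = phages).
#' @param axis `"strains"` (RPGs) or `"phages"` (PPGs).
#' @param cut dissimilarity threshold at which the dendrogram is cut.
#' @param linkage `"average"` (UPGMA, default) or `"complete"`.
#' @return a `"type_assignment"` with labels `RPG-1`, ... or `PPG-1`, ...
#' @export
phenotype_groups <- function(mat, axis = c("strains", "phages"), cut = 0.2,
                             linkage = c("average", "complete")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  m <- as_binary_matrix(mat)
  profiles <- if (axis == "strains") m else t(m)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0(if (axis == "strains") "strain" else "phage",
                                 "_", seq_len(nrow(profiles)))
  empty <- rowSums(profiles) == 0
  if (any(empty)) {
    warning(sprintf("excluding %d all-zero profile(s) from %s clustering",
                    sum(empty), axis))
    profiles <- profiles[!empty, , drop = FALSE]
  }
  if (nrow(profiles) < 2L) stop("need at least two non-empty profiles")
  d <- vegan::vegdist(profiles, method = "bray")
  prefix <- if (axis == "strains") "RPG" else "PPG"
  if (cut <= 0) {
    # degenerate cut: only identical profiles group together
    key <- apply(profiles, 1, paste, collapse = "")
    return(type_assignment(rownames(profiles), key, prefix, prefix))
  }
  hc <- stats::hclust(d, method = linkage)
  groups <- stats::cutree(hc, h = cut)
  type_assignment(rownames(profiles), groups, prefix, prefix)
}

#' Per-site composition table of assigned types
#'
#' Cross-tabulates type labels against a grouping column of the metadata
#' (site by default), yielding the community table consumed by the
#' distance-based composition statistics.
#'
#' @param assignment a `"type_assignment"`.
#' @param metadata metadata data frame with `id` and the grouping column.
#' @param group metadata column to aggregate by (default `"site"`).
#' @return integer matrix, groups x types.
#' @export
type_composition <- function(assignment, metadata, group = "site") {
  a <- assignment$assignment
  idx <- match(a$id, metadata$id)
  if (anyNA(idx)) stop("metadata missing for some assigned ids")
  tab <- table(metadata[[group]][idx], a$type)
  mat <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  mat
}
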