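#' Run the full cross-infection analysis pipeline
#'
#' Executes the stages in the order of the study design: network structure
#' (connectance, NODF, temperature nestedness, Barber modularity with
#' equiprobable null tests), phenotype grouping on both axes, genotype
#' clustering when an ANI table is supplied, sympatric/allopatric rates with
#' the local-adaptation index and quasi-binomial GLM, and community
#' composition statistics when a community table is supplied.  All results
#' are written as CSV/JSON to `out_dir` together with a JSON run manifest
#' (inputs, seeds, versions, per-stage runtimes) and a plain-text summary.
#' Any stage failure aborts with a stage-tagged error.
#'
#' All randomness flows from the single `seed`, split deterministically per
#' stage, so a rerun with the same inputs and seed reproduces the bundle
#' bit-identically.
#'
#' @param mat an [infection_matrix()] (or path to a wide CSV).
#' @param metadata metadata data frame (or path to a metadata CSV).
#' @param out_dir output directory (created if absent); `NULL` skips writing.
#' @param seed integer master seed.
#' @param null_replicates replicates for the equiprobable null tests
#'   (default 100, a smoke setting; 1000 for full runs).
#' @param community optional list with `counts` and `sample_meta` (as from
#'   [simulate_communities()]) for the composition statistics.
#' @param ani_table optional pairwise ANI/coverage data frame for
#'   [cluster_pgts()].
#' @param cut,linkage phenotype-group clustering parameters.
#' @param brim_restarts restarts for the observed modularity search.
#' @return list of class `"run_bundle"` with elements `validation`,
#'   `network`, `phenotypes`, `genotypes`, `rates`, `community`, `manifest`.
#' @export
run_all <- function(mat, metadata, out_dir = NULL, seed = 1L,
                    null_replicates = 100, community = NULL, ani_table = NULL,
                    cut = 0.2, linkage = "average", brim_restarts = 20) {
  t0 <- proc.time()[["elapsed"]]
  stage_times <- list()
  input_info <- list()
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    stage_times[[name]] <<- round(proc.time()[["elapsed"]] - ts, 3)
    res
  }

  if (is.character(mat)) {
    input_info$matrix_path <- mat
    input_info$matrix_md5 <- unname(tools::md5sum(mat))
    mat <- stage("read", read_interaction_data(mat)$matrix)
  }
  if (is.character(metadata)) {
    input_info$metadata_path <- metadata
    input_info$metadata_md5 <- unname(tools::md5sum(metadata))
    metadata <- stage("read", read_metadata(metadata))
  }

  validation <- stage("validate", {
    v <- validate_interaction_data(mat, metadata)
    if (length(v$errors))
      stop("dataset not usable: ", paste(v$errors, collapse = "; "))
    v
  })

  network <- stage("network", network_structure(
    mat, null_replicates = null_replicates, seed = seed,
    brim_restarts = brim_restarts))

  phenotypes <- stage("phenotypes", list(
    rpg = suppressWarnings(phenotype_groups(mat, "strains", cut, linkage)),
    ppg = suppressWarnings(phenotype_groups(mat, "phages", cut, linkage))))

  genotypes <- if (!is.null(ani_table))
    stage("genotypes", cluster_pgts(ani_table)) else NULL

  rates <- stage("rates", {
    phage_rates <- entity_rates(mat, metadata, "phage")
    strain_rates <- entity_rates(mat, metadata, "strain")
    list(phage = phage_rates, strain = strain_rates,
         la_phage = local_adaptation(phage_rates),
         la_strain = local_adaptation(strain_rates),
         glm_phage = quasibinomial_f_test(phage_rates),
         glm_strain = quasibinomial_f_test(strain_rates),
         site_by_site_phage = site_by_site_rates(mat, metadata, "phage"))
  })

  community_res <- if (!is.null(community)) stage("community", {
    dj <- community_distances(community$counts, "jaccard_binary")
    db <- community_distances(community$counts, "bray_curtis")
    list(jaccard = dj, bray = db, pcoa = pcoa(db),
         permanova_jaccard = permanova(dj, community$sample_meta, "site",
                                       permutations = 999, seed = seed + 10L),
         permanova_bray = permanova(db, community$sample_meta, "site",
                                    permutations = 999, seed = seed + 11L))
  }) else NULL

  manifest <- list(
    package = "phagehostnet",
    version = as.character(utils::packageVersion("phagehostnet")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    inputs = c(input_info, list(
      n_strains = nrow(mat), n_phages = ncol(mat), fill = mean(mat))),
    seed = seed,
    parameters = list(null_replicates = null_replicates, cut = cut,
                      linkage = linkage, brim_restarts = brim_restarts),
    stage_runtimes_s = stage_times,
    total_runtime_s = round(proc.time()[["elapsed"]] - t0, 3))

  bundle <- structure(list(validation = validation, network = network,
                           phenotypes = phenotypes, genotypes = genotypes,
                           rates = rates, community = community_res,
                           manifest = manifest), class = "run_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, mat, out_dir)
  bundle
}

write_bundle <- function(bundle, mat, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(out_dir, ...)
  nw <- bundle$network
  full <- function(x) sprintf("%.17g", x) # doubles survive the CSV round trip
  metrics <- data.frame(
    metric = c("connectance", "nodf", "ntc_temperature", "ntc_nestedness",
               "qb", "n_modules"),
    value = full(c(nw$connectance, nw$nodf, nw$ntc$temperature,
                   nw$ntc$nestedness, nw$qb, nw$partition$n_modules)))
  if (!is.null(nw$null)) {
    nulls <- do.call(rbind, lapply(nw$null, function(x)
      data.frame(metric = x$metric, observed = full(x$observed),
                 null_mean = full(mean(x$null_values)), z = full(x$z_score),
                 p = full(x$p_value), replicates = x$replicates)))
    utils::write.csv(nulls, out("null_tests.csv"), row.names = FALSE)
  }
  utils::write.csv(metrics, out("network_metrics.csv"), row.names = FALSE)
  so <- sorting_orders(mat, nw$partition)
  m <- as_binary_matrix(mat)
  write_interaction_matrix(
    infection_matrix(m[so$nested$row_order, so$nested$col_order]),
    out("matrix_nested_sorted.csv"))
  write_interaction_matrix(
    infection_matrix(m[so$modular$row_order, so$modular$col_order]),
    out("matrix_modular_sorted.csv"))
  utils::write.csv(bundle$phenotypes$rpg$assignment, out("rpg_assignment.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$phenotypes$ppg$assignment, out("ppg_assignment.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$genotypes))
    utils::write.csv(bundle$genotypes$assignment, out("pgt_assignment.csv"),
                     row.names = FALSE)
  utils::write.csv(bundle$rates$phage, out("phage_rates.csv"), row.names = FALSE)
  utils::write.csv(bundle$rates$strain, out("strain_rates.csv"), row.names = FALSE)
  la <- rbind(cbind(perspective = "phage", bundle$rates$la_phage),
              cbind(perspective = "strain", bundle$rates$la_strain))
  utils::write.csv(la, out("local_adaptation.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(phage = unclass(bundle$rates$glm_phage[c("f_statistic", "df1", "df2",
                                                  "p_value", "dispersion")]),
         strain = unclass(bundle$rates$glm_strain[c("f_statistic", "df1", "df2",
                                                    "p_value", "dispersion")])),
    out("glm_tests.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$community)) {
    utils::write.csv(bundle$community$permanova_jaccard$table,
                     out("permanova_jaccard.csv"))
    utils::write.csv(bundle$community$permanova_bray$table,
                     out("permanova_bray.csv"))
    utils::write.csv(data.frame(sample_id = rownames(bundle$community$pcoa$points),
                                bundle$community$pcoa$points),
                     out("community_pcoa.csv"), row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  summary_lines <- c(
    "Cross-infection analysis summary",
    sprintf("Matrix: %d strains x %d phages", nrow(m), ncol(m)),
    sprintf("Connectance %.4f | NODF %.4f | NTC nestedness %.4f | Qb %.4f (%d modules)",
            nw$connectance, nw$nodf, nw$ntc$nestedness, nw$qb,
            nw$partition$n_modules),
    sprintf("RPGs: %d (%d singletons) | PPGs: %d (%d singletons)",
            bundle$phenotypes$rpg$n_types, bundle$phenotypes$rpg$n_singletons,
            bundle$phenotypes$ppg$n_types, bundle$phenotypes$ppg$n_singletons),
    sprintf("Phage LA index %.4f (S %.4f, A %.4f); GLM F(%d,%d) = %.2f, p = %.3g",
            bundle$rates$la_phage$la_index, bundle$rates$la_phage$mean_S,
            bundle$rates$la_phage$mean_A, bundle$rates$glm_phage$df1,
            bundle$rates$glm_phage$df2, bundle$rates$glm_phage$f_statistic,
            bundle$rates$glm_phage$p_value),
    sprintf("Strain susceptibility: S %.4f, A %.4f; GLM F(%d,%d) = %.2f, p = %.3g",
            bundle$rates$la_strain$mean_S, bundle$rates$la_strain$mean_A,
            bundle$rates$glm_strain$df1, bundle$rates$glm_strain$df2,
            bundle$rates$glm_strain$f_statistic, bundle$rates$glm_strain$p_value))
  writeLines(summary_lines, out("summary.txt"))
  invisible(out_dir)
}

#' @export
print.run_bundle <- function(x, ...) {
  print(x$network)
  cat(sprintf("RPGs %d | PPGs %d\n", x$phenotypes$rpg$n_types,
              x$phenotypes$ppg$n_types))
  print(x$rates$glm_phage)
  invisible(x)
}
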