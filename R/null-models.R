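#' Equiprobable null-model test for a network metric
#'
#' Generates same-shape replicate matrices with every cell an independent
#' Bernoulli draw at the observed connectance (the "equiprobable" null),
#' recomputes the chosen metric on each, and reports the add-one permutation
#' p-value `(count(null >= observed) + 1) / (replicates + 1)` together with
#' the z-score against the null distribution.
#'
#' @param mat binary matrix.
#' @param metric one of `"nodf"`, `"ntc"` (temperature-based nestedness,
#'   `(100 - T)/100`), `"qb"` (Barber modularity maximized by
#'   [adaptive_brim()]) or `"connectance"`.
#' @param replicates number of null matrices (default 1000).
#' @param seed integer seed.
#' @param brim_restarts restarts used for `"qb"` (observed and null); fewer
#'   than the [adaptive_brim()] default to keep the null loop tractable.
#' @return list of class `"null_test"`: `observed`, `null_values`, `p_value`,
#'   `z_score`, `model`, `replicates`, `seed`, `metric`.
#' @export
null_test <- function(mat, metric = c("nodf", "ntc", "qb", "connectance"),
                      replicates = 1000, seed = NULL, brim_restarts = 5) {
  metric <- match.arg(metric)
  m <- as_binary_matrix(mat)
  if (replicates < 1) stop("replicates must be >= 1")
  fill <- sum(m) / length(m)
  metric_fun <- switch(metric,
    nodf = nodf,
    ntc = function(x) suppressWarnings(nestedness_temperature(x)$nestedness),
    qb = function(x) adaptive_brim(x, restarts = brim_restarts)$qb,
    connectance = connectance)
  run <- function() {
    observed <- metric_fun(m)
    null_values <- vapply(seq_len(replicates), function(i) {
      repeat {
        r <- matrix(stats::rbinom(length(m), 1L, fill), nrow(m), ncol(m))
        if (sum(r) > 0) break # metrics are undefined on an empty network
      }
      metric_fun(r)
    }, numeric(1))
    list(observed = observed, null_values = null_values)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  nv <- res$null_values
  structure(list(
    observed = res$observed, null_values = nv,
    p_value = (sum(nv >= res$observed) + 1) / (replicates + 1),
    z_score = (res$observed - mean(nv)) / stats::sd(nv),
    model = "equiprobable", replicates = replicates, seed = seed,
    metric = metric), class = "null_test")
}

#' @export
print.null_test <- function(x, ...) {
  cat(sprintf("%s = %.4f vs equiprobable null (%d reps): mean %.4f, z = %.2f, p = %.4g\n",
              x$metric, x$observed, x$replicates, mean(x$null_values),
              x$z_score, x$p_value))
  invisible(x)
}

#' Full network-structure summary
#'
#' Computes connectance, NODF, temperature-based nestedness and Barber
#' modularity for one matrix, with optional equiprobable null tests per
#' metric.
#'
#' @param mat binary matrix.
#' @param null_replicates replicates for the null tests; 0 skips them.
#' @param seed integer seed (split internally per metric).
#' @param brim_restarts restarts for the observed [adaptive_brim()] run.
#' @return list of class `"network_result"` with `connectance`, `nodf`,
#'   `ntc` (the `"ntc_result"`), `partition` (`"brim_result"`), `qb`, and a
#'   `null` sublist of `"null_test"` objects when requested.
#' @export
network_structure <- function(mat, null_replicates = 1000, seed = 1L,
                              brim_restarts = 20) {
  m <- as_binary_matrix(mat)
  ntc <- suppressWarnings(nestedness_temperature(m))
  part <- adaptive_brim(m, restarts = brim_restarts, seed = seed)
  out <- list(connectance = connectance(m), nodf = nodf(m), ntc = ntc,
              partition = part, qb = part$qb, null = NULL)
  if (null_replicates > 0) {
    out$null <- list(
      nodf = null_test(m, "nodf", null_replicates, seed = seed + 1L),
      ntc = null_test(m, "ntc", null_replicates, seed = seed + 2L),
      qb = null_test(m, "qb", null_replicates, seed = seed + 3L))
  }
  structure(out, class = "network_result")
}

#' @export
print.network_result <- function(x, ...) {
  cat(sprintf("Connectance %.3f | NODF %.3f | NTC nestedness %.3f | Qb %.3f (%d modules)\n",
              x$connectance, x$nodf, x$ntc$nestedness, x$qb, x$partition$n_modules))
  if (!is.null(x$null)) for (nt in x$null) print(nt)
  invisible(x)
}
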