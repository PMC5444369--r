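# Readers, the end-to-end pipeline, and the run manifest.

#' Read the three input tables
#'
#' CSV orientation: sites as rows; the environmental and abundance tables
#' have a header row and the site id in the first column (or a column named
#' `site`); the partition file has columns `site,subset`. The decimal mark is
#' always ".".
#'
#' @param path File path.
#' @param delim Field delimiter (default ",").
#' @return A tibble.
#' @export
read_env_csv <- function(path, delim = ",") read_table_csv(path, delim, "env")

#' @rdname read_env_csv
#' @export
read_abundance_csv <- function(path, delim = ",") read_table_csv(path, delim, "abund")

#' @rdname read_env_csv
#' @export
read_partition_csv <- function(path, delim = ",") {
  df <- read_table_csv(path, delim, "partition")
  if (ncol(df) < 2L) abort("Partition file needs columns site,subset.")
  df
}

read_table_csv <- function(path, delim, what) {
  if (!file.exists(path)) abort(sprintf("Input file not found: %s", path))
  out <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE),
    error = function(e) abort(sprintf("Malformed %s CSV '%s': %s",
                                      what, path, conditionMessage(e)))
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0L) {
    abort(sprintf("Malformed %s CSV '%s' at line %d: %s",
                  what, path, probs$row[1], probs$expected[1]))
  }
  out
}

#' Run the full niche-decomposition pipeline
#'
#' Standardizes the environment, fits the OMI ordination, decomposes the
#' realized niches into subniches, runs all permutation tests, builds the
#' envelope geometry, and writes tidy CSV tables plus GeoJSON polygons and a
#' machine-readable JSON manifest (seed, config echo, table dimensions,
#' package version) to `out_dir`. Reruns with the same inputs and seed
#' reproduce the outputs exactly.
#'
#' @param env,abund,partition Data frames, or paths to CSV files.
#' @param out_dir Output directory (created if missing). `NULL` skips
#'   writing and just returns the results.
#' @param n_axes Retained factorial axes (default 2).
#' @param n_perm Permutations per test (default 1000).
#' @param seed Master seed for all randomness (recorded in the manifest).
#' @param tolerance Tolerance convention, see [fit_omi()].
#' @param min_freq Occupancy threshold for envelope membership.
#' @param adjust_p Add BH-adjusted p-values to the test table.
#' @param delim CSV delimiter for file inputs.
#' @param stages Which stages to run: any of `"omi"`, `"subniche"`,
#'   `"test"`, `"constraint"` (later stages imply earlier ones).
#' @return Invisibly, a list with `fit`, `sub`, `tests`, `envelopes`,
#'   `manifest`.
#' @export
run_pipeline <- function(env, abund, partition, out_dir = NULL,
                         n_axes = 2L, n_perm = 1000L, seed = 1L,
                         tolerance = c("direction", "axes"), min_freq = 0,
                         adjust_p = FALSE, delim = ",",
                         stages = c("omi", "subniche", "test", "constraint")) {
  tolerance <- match.arg(tolerance)
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- check_seed(seed)
  if (is.character(env)) env <- read_env_csv(env, delim)
  if (is.character(abund)) abund <- read_abundance_csv(abund, delim)
  if (is.character(partition)) partition <- read_partition_csv(partition, delim)

  fit <- fit_omi(env, abund, n_axes = n_axes, tolerance = tolerance)
  otest <- omi_test(fit, n_perm = n_perm, seed = seed)

  sub <- tests <- envelopes <- NULL
  need_sub <- any(stages %in% c("subniche", "test", "constraint"))
  if (need_sub) sub <- fit_subniche(fit, partition)
  if ("test" %in% stages) {
    tests <- run_tests(sub, n_perm = n_perm, seed = seed, adjust_p = adjust_p)
  }
  if ("constraint" %in% stages) {
    envelopes <- build_envelopes(sub, min_freq = min_freq)
  }

  manifest <- list(
    package = "witomi",
    version = as.character(utils::packageVersion("witomi")),
    seed = seed, n_perm = as.integer(n_perm), n_axes = as.integer(n_axes),
    tolerance = tolerance, min_freq = min_freq, adjust_p = adjust_p,
    stages = stages,
    n_sites = nrow(fit$z0), n_vars = ncol(fit$z0),
    n_species = length(fit$species),
    subsets = if (!is.null(sub)) sub$subsets else NULL
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(x, f) readr::write_csv(x, file.path(out_dir, f))
    wcsv(eigen_table(fit), "eigen.csv")
    wcsv(dplyr::left_join(tidy(fit),
                          dplyr::select(otest, "species", "p_value"),
                          by = "species"),
         "omi_params.csv")
    wcsv(project_sites(fit), "site_scores.csv")
    spc <- matrix_to_df(fit$species_scores[, seq_len(fit$n_axes), drop = FALSE],
                        "species")
    wcsv(spc, "species_scores.csv")
    if (!is.null(sub)) {
      sp_tab <- subniche_params(sub)
      if (!is.null(tests)) {
        pj <- tests |>
          dplyr::filter(.data$level == "pair") |>
          dplyr::select("species", "subset", "statistic", "p_value") |>
          tidyr::pivot_wider(names_from = "statistic", values_from = "p_value",
                             names_prefix = "p_")
        sp_tab <- dplyr::left_join(sp_tab, pj, by = c("species", "subset"))
      }
      sp_tab$p_omi <- otest$p_value[match(sp_tab$species, otest$species)]
      wcsv(sp_tab, "subniche_params.csv")
    }
    if (!is.null(tests)) wcsv(tests, "tests.csv")
    if (!is.null(envelopes)) {
      wcsv(constraint_table(envelopes), "constraint.csv")
      write_envelopes_geojson(envelopes, file.path(out_dir, "envelopes.geojson"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(fit = fit, omi_test = otest, sub = sub, tests = tests,
                 envelopes = envelopes, manifest = manifest))
}

#' Write a simulated community to CSV files
#'
#' @param sim A `niche_sim` from [simulate_community()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  stopifnot(inherits(sim, "niche_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$env, file.path(out_dir, "env.csv"))
  readr::write_csv(sim$abund, file.path(out_dir, "abund.csv"))
  readr::write_csv(sim$partition, file.path(out_dir, "partition.csv"))
  truth <- sim$truth$species |>
    dplyr::mutate(dplyr::across(c("optimum", "breadth", "optimum_std",
                                  "breadth_std"),
                                ~ purrr::map_chr(.x, paste, collapse = ";")))
  readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  invisible(out_dir)
}
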