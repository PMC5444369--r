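#' Standardize an environmental table
#'
#' Centers and scales each environmental variable under uniform site weights
#' (1/n) and the population (divide-by-n) variance, so the standardized table
#' Z0 has weighted column means 0 and weighted variances 1. The origin of the
#' standardized space is then G, the mean habitat condition of the whole
#' sampling domain.
#'
#' @param env A data frame with one row per site: a site-id column (named
#'   `site`, or the first column otherwise) and numeric environmental
#'   variables. At least 3 sites; no missing values; every variable must vary.
#' @param site_col Name of the site-id column (default: `"site"` if present,
#'   else the first column).
#'
#' @return A tibble with the site-id column and the standardized variables.
#'   Each returned column has mean 0 and population variance 1.
#' @examples
#' env <- tibble::tibble(site = paste0("s", 1:4), depth = c(1, 2, 3, 4))
#' standardize_env(env)
#' @export
standardize_env <- function(env, site_col = NULL) {
  site_col <- site_col %||% id_col_name(env)
  x <- df_to_matrix(env, site_col, what = "env")
  if (nrow(x) < 3L) abort("Need at least 3 sites to standardize.")
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    abort(sprintf("Missing value in env at row %d (site '%s'), column '%s'.",
                  idx[1], rownames(x)[idx[1]], colnames(x)[idx[2]]))
  }
  mu <- colMeans(x)
  v <- colMeans(sweep(x, 2L, mu)^2)  # population variance, uniform weights
  if (any(v <= 0)) {
    abort(sprintf("Zero-variance environmental variable(s): %s",
                  paste(colnames(x)[v <= 0], collapse = ", ")))
  }
  z <- sweep(sweep(x, 2L, mu), 2L, sqrt(v), `/`)
  matrix_to_df(z, site_col)
}

#' Species frequency profiles over all sites
#'
#' Converts abundances (or occurrences) to per-species relative frequency
#' profiles Fr: each species column is divided by its total, so columns sum
#' to 1 and give the species' distribution of use over the sampling units.
#'
#' @param abund A data frame with one row per site: a site-id column and one
#'   non-negative numeric column per species. Every species must have a
#'   positive total.
#' @param site_col Name of the site-id column.
#'
#' @return A tibble of the same shape with columns summing to 1.
#' @examples
#' ab <- tibble::tibble(site = paste0("s", 1:4), sp1 = c(0, 0, 2, 2))
#' species_profiles(ab)
#' @export
species_profiles <- function(abund, site_col = NULL) {
  site_col <- site_col %||% id_col_name(abund)
  x <- df_to_matrix(abund, site_col, what = "abund")
  if (anyNA(x) || any(x < 0)) abort("Abundances must be non-negative and complete.")
  tot <- colSums(x)
  if (any(tot <= 0)) {
    abort(sprintf("Species with zero total abundance: %s",
                  paste(colnames(x)[tot <= 0], collapse = ", ")))
  }
  matrix_to_df(sweep(x, 2L, tot, `/`), site_col)
}

# Validate a partition data frame against site ids; returns a factor-ish list.
as_partition <- function(partition, site_ids) {
  if (is.data.frame(partition)) {
    nm <- names(partition)
    scol <- if ("site" %in% nm) "site" else nm[[1L]]
    kcol <- if ("subset" %in% nm) "subset" else nm[[2L]]
    lab <- setNames(as.character(partition[[kcol]]), as.character(partition[[scol]]))
  } else {
    lab <- setNames(as.character(partition), names(partition) %||% site_ids)
  }
  missing <- setdiff(site_ids, names(lab))
  if (length(missing)) {
    abort(sprintf("Partition is missing site(s): %s", paste(missing, collapse = ", ")))
  }
  lab <- lab[site_ids]
  subsets <- unique(unname(lab))  # declared order = order of first appearance
  sizes <- table(factor(lab, levels = subsets))
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    abort(sprintf("Subset(s) with fewer than 2 sites: %s", paste(small, collapse = ", ")))
  }
  list(labels = lab, subsets = subsets)
}

#' Per-subset species frequency profiles (Fr*)
#'
#' Renormalizes each species' frequencies within each subset K of the
#' sampling domain: for a species present in K, its abundance over the sites
#' of K is rescaled to sum to 1 (the subset profile Fr_K). Species with no
#' individuals in a subset are flagged absent rather than given NaN profiles.
#'
#' @param abund Site-by-species abundance data frame (as in
#'   [species_profiles()]).
#' @param partition A data frame with columns `site` and `subset` (or any
#'   two columns in that order) assigning every site to a subset, each subset
#'   holding at least 2 sites.
#' @param site_col Name of the site-id column of `abund`.
#'
#' @return A long tibble with columns `subset`, `species`, `site`, `freq`
#'   and `present` — one row per (subset, species, site-in-subset). For a
#'   present pair the `freq` values over the subset sum to 1; absent pairs
#'   have all-zero `freq` and `present = FALSE`.
#' @export
subset_profiles <- function(abund, partition, site_col = NULL) {
  site_col <- site_col %||% id_col_name(abund)
  x <- df_to_matrix(abund, site_col, what = "abund")
  if (anyNA(x) || any(x < 0)) abort("Abundances must be non-negative and complete.")
  part <- as_partition(partition, rownames(x))
  purrr::map_dfr(part$subsets, function(K) {
    rows <- which(part$labels == K)
    xk <- x[rows, , drop = FALSE]
    tot <- colSums(xk)
    frk <- sweep(xk, 2L, ifelse(tot > 0, tot, 1), `/`)
    tibble(
      subset = K,
      species = rep(colnames(x), each = length(rows)),
      site = rep(rownames(x)[rows], times = ncol(x)),
      freq = as.vector(frk),
      present = rep(tot > 0, each = length(rows))
    )
  })
}

#' Center the standardized table within each subset
#'
#' Computes the subset centroids G_K (uniform within-subset means of Z0) and
#' the within-subset-centered table Z*: row i becomes `z0[i,] - G_K(i)`.
#' G_K is the origin from which subset-relative marginalities (WitOMI G_K)
#' are measured.
#'
#' @param z0 Standardized environmental tibble from [standardize_env()].
#' @param partition Site-to-subset assignment (see [subset_profiles()]).
#' @param site_col Name of the site-id column.
#'
#' @return A list of class `subset_env` with elements `z_star` (tibble:
#'   site, subset, centered variables), `gk` (tibble: subset, variable
#'   means), and `subsets` (subset order).
#' @export
subset_center <- function(z0, partition, site_col = NULL) {
  site_col <- site_col %||% id_col_name(z0)
  z <- df_to_matrix(z0, site_col, what = "z0")
  part <- as_partition(partition, rownames(z))
  gk <- do.call(rbind, lapply(part$subsets, function(K) {
    colMeans(z[part$labels == K, , drop = FALSE])
  }))
  rownames(gk) <- part$subsets
  zs <- z - gk[part$labels, , drop = FALSE]
  z_star <- matrix_to_df(zs, site_col)
  z_star <- tibble::add_column(z_star, subset = unname(part$labels), .after = 1)
  structure(
    list(
      z_star = z_star,
      gk = tibble::add_column(as_tibble(gk), subset = part$subsets, .before = 1),
      subsets = part$subsets
    ),
    class = "subset_env"
  )
}
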