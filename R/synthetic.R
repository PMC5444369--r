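#' Describe a synthetic community scenario
#'
#' Defines the study conditions for [simulate_community()]: sites lie along
#' correlated multivariate-normal environmental gradients whose mean can be
#' displaced per subset (e.g. deeper conditions in one season); species have
#' unimodal Gaussian responses with a per-variable optimum and breadth; counts
#' get Poisson or negative-binomial noise; optional exclusion rules zero a
#' species in a stated region after sampling, imposing a biotic-style
#' constraint with a known ground truth.
#'
#' The defaults describe a community of 12 specialists whose optima tile the
#' first two gradients, observed at 2 subsets of 150 sites each with the
#' second subset's first gradient displaced by +1 raw unit.
#'
#' @param n_sites Integer vector: sites per subset (names become subset ids;
#'   default `c(K1 = 150, K2 = 150)`); each at least 3.
#' @param p_vars Number of environmental variables (default 3).
#' @param gradient_cov p x p covariance of the gradients (default AR(1) with
#'   correlation 0.5, unit variances). Must be positive definite.
#' @param subset_shift Matrix (subsets x p) of mean displacements of available
#'   conditions, in raw units (default: subset 2 shifted +1 on variable 1).
#' @param species Tibble with columns `species`, `optimum` (list of p-vectors,
#'   raw units), `breadth` (list of positive p-vectors), `max_abundance`.
#'   Default: 12 specialists on a 6 x 2 grid over variables 1-2, breadth 1,
#'   peak abundance 30.
#' @param n_species Convenience: take the first `n_species` default species.
#' @param noise `"poisson"` (default) or `"nbinom"`.
#' @param dispersion Negative-binomial size parameter (only for
#'   `noise = "nbinom"`); must be positive.
#' @param exclusions Optional tibble with columns `species`, `var`, `lower`,
#'   `upper` and optionally `subset`: counts of that species are zeroed at
#'   sites whose raw variable value lies in `[lower, upper]` (within the
#'   subset, if given).
#' @return A `niche_scenario` object.
#' @export
scenario <- function(n_sites = c(K1 = 150L, K2 = 150L),
                     p_vars = 3L,
                     gradient_cov = NULL,
                     subset_shift = NULL,
                     species = NULL,
                     n_species = NULL,
                     noise = c("poisson", "nbinom"),
                     dispersion = 1,
                     exclusions = NULL) {
  noise <- match.arg(noise)
  if (any(n_sites < 3L)) abort("Each subset needs at least 3 sites.")
  if (is.null(names(n_sites))) names(n_sites) <- paste0("K", seq_along(n_sites))
  p_vars <- as.integer(p_vars)
  if (is.null(gradient_cov)) {
    gradient_cov <- 0.5^abs(outer(seq_len(p_vars), seq_len(p_vars), `-`))
  }
  ev <- eigen(gradient_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 1e-10)) abort("`gradient_cov` must be positive definite.")
  if (is.null(subset_shift)) {
    subset_shift <- matrix(0, length(n_sites), p_vars)
    if (length(n_sites) >= 2L) subset_shift[2L, 1L] <- 1
  }
  if (is.null(species)) species <- default_species(p_vars)
  if (!is.null(n_species)) species <- head(species, n_species)
  if (any(unlist(species$breadth) <= 0)) abort("Breadths must be positive.")
  if (noise == "nbinom" && dispersion <= 0) abort("`dispersion` must be positive.")
  structure(
    list(n_sites = n_sites, p_vars = p_vars, gradient_cov = gradient_cov,
         subset_shift = subset_shift, species = species, noise = noise,
         dispersion = dispersion, exclusions = exclusions),
    class = "niche_scenario"
  )
}

# 12 specialists: optima on a 6 x 2 grid over the first two gradients.
default_species <- function(p_vars) {
  g1 <- rep(seq(-2, 2, length.out = 6), times = 2)
  g2 <- rep(c(-1, 1), each = 6)
  opt <- lapply(seq_len(12), function(j) {
    v <- numeric(p_vars)
    v[1] <- g1[j]
    if (p_vars >= 2) v[2] <- g2[j]
    v
  })
  tibble(
    species = sprintf("sp%02d", 1:12),
    optimum = opt,
    # breadth well below the unit gradient sd: genuine specialists whose
    # realized optima stay close to their fundamental optima
    breadth = rep(list(rep(0.6, p_vars)), 12),
    max_abundance = 30
  )
}

#' Simulate a community with known niche structure
#'
#' Draws sites from the scenario's gradients (multivariate normal with
#' subset-specific mean shifts), computes each species' expected abundance
#' `max_abundance * exp(-0.5 * sum(((x - opt) / breadth)^2))` at each site,
#' adds count noise, and applies any exclusion rules. The returned truth
#' records the generating optima and breadths both in raw units and mapped
#' into the standardized space of the realized sample (via the sample's
#' divide-by-n moments), plus the realized subset centroids.
#'
#' @param scn A `niche_scenario` from [scenario()].
#' @param seed Integer seed; fixed seed gives bit-identical tables.
#' @return A list of class `niche_sim`: `env`, `abund`, `partition` tibbles
#'   ready for [fit_omi()], and `truth` (list with `species` tibble,
#'   `subset_centroids`, `excluded` mask tibble).
#' @examples
#' sim <- simulate_community(scenario(n_sites = c(30, 30), n_species = 4), seed = 7)
#' dplyr::glimpse(sim$env)
#' @export
simulate_community <- function(scn, seed = NULL) {
  stopifnot(inherits(scn, "niche_scenario"))
  seed <- check_seed(seed)
  n <- sum(scn$n_sites)
  p <- scn$p_vars
  subsets <- names(scn$n_sites)
  labels <- rep(subsets, times = scn$n_sites)
  site_ids <- sprintf("s%03d", seq_len(n))

  withr_seed(seed, {
    x <- matrix(0, n, p)
    offset <- 0L
    for (K in seq_along(subsets)) {
      nk <- scn$n_sites[[K]]
      x[offset + seq_len(nk), ] <- MASS::mvrnorm(nk, mu = scn$subset_shift[K, ],
                                                 Sigma = scn$gradient_cov)
      offset <- offset + nk
    }
    colnames(x) <- paste0("env", seq_len(p))
    rownames(x) <- site_ids

    S <- nrow(scn$species)
    lambda <- matrix(0, n, S)
    for (j in seq_len(S)) {
      opt <- scn$species$optimum[[j]]
      br <- scn$species$breadth[[j]]
      dev2 <- sweep(x, 2L, opt)^2
      lambda[, j] <- scn$species$max_abundance[[j]] *
        exp(-0.5 * as.vector(dev2 %*% (1 / br^2)))
    }
    counts <- if (scn$noise == "poisson") {
      matrix(rpois(n * S, lambda), n, S)
    } else {
      matrix(rnbinom(n * S, mu = lambda, size = scn$dispersion), n, S)
    }
    colnames(counts) <- scn$species$species
    rownames(counts) <- site_ids

    excluded <- matrix(FALSE, n, S, dimnames = dimnames(counts))
    if (!is.null(scn$exclusions)) {
      for (i in seq_len(nrow(scn$exclusions))) {
        ex <- scn$exclusions[i, ]
        hit <- x[, ex$var] >= ex$lower & x[, ex$var] <= ex$upper
        if ("subset" %in% names(ex) && !is.na(ex$subset)) {
          hit <- hit & labels == ex$subset
        }
        counts[hit, ex$species] <- 0L
        excluded[hit, ex$species] <- TRUE
      }
    }

    # standardized images of the truth under the realized sample moments
    mu <- colMeans(x)
    sd_pop <- sqrt(colMeans(sweep(x, 2L, mu)^2))
    truth_species <- scn$species |>
      dplyr::mutate(
        optimum_std = purrr::map(.data$optimum, ~ (.x - mu) / sd_pop),
        breadth_std = purrr::map(.data$breadth, ~ .x / sd_pop),
        true_omi = purrr::map_dbl(.data$optimum_std, ~ sum(.x^2))
      )
    z <- sweep(sweep(x, 2L, mu), 2L, sd_pop, `/`)
    cent <- do.call(rbind, lapply(subsets, function(K) {
      colMeans(z[labels == K, , drop = FALSE])
    }))
    dimnames(cent) <- list(subsets, colnames(x))

    list(
      env = matrix_to_df(x, "site"),
      abund = matrix_to_df(counts, "site"),
      partition = tibble(site = site_ids, subset = labels),
      truth = list(
        species = truth_species,
        subset_centroids = tibble::add_column(as_tibble(cent),
                                              subset = subsets, .before = 1),
        excluded = matrix_to_df(excluded * 1, "site"),
        seed = seed
      )
    ) |> structure(class = "niche_sim")
  })
}

#' Compare fitted niche indexes with the generating truth
#'
#' Reports how well the ordination recovered the generator's niche structure:
#' * `spearman_omi` — rank correlation, across species, between the true
#'   squared displacement of each optimum from the available-conditions
#'   centroid (in standardized units) and the fitted OMI;
#' * `spearman_witomi_gk` — per-(species, subset) analogue against the true
#'   squared displacement of the optimum from the subset centroid.
#'
#' Species never observed in the data are dropped with a warning.
#'
#' @param sim A `niche_sim` (provides the truth).
#' @param fit The `omi` fit on the simulated tables.
#' @param sub Optional `subniche` object for the per-subset comparison.
#' @return A one-row tibble: spearman_omi, spearman_witomi_gk (NA when `sub`
#'   is missing), n_species, n_pairs.
#' @export
recovery_report <- function(sim, fit, sub = NULL) {
  stopifnot(inherits(sim, "niche_sim"), inherits(fit, "omi"))
  truth <- sim$truth$species
  dropped <- setdiff(truth$species, fit$species)
  if (length(dropped)) {
    warn(sprintf("Species never observed, dropped from recovery: %s",
                 paste(dropped, collapse = ", ")))
    truth <- dplyr::filter(truth, .data$species %in% fit$species)
  }
  fitted <- tidy(fit)
  joined <- dplyr::inner_join(truth, fitted, by = "species")
  sp_omi <- cor(joined$true_omi, joined$omi, method = "spearman")

  sp_gk <- NA_real_
  n_pairs <- NA_integer_
  if (!is.null(sub)) {
    cent <- df_to_matrix(sim$truth$subset_centroids, "subset", what = "centroids")
    pairs <- dplyr::filter(sub$table, .data$present,
                           .data$species %in% truth$species)
    true_gk <- purrr::map2_dbl(pairs$species, pairs$subset, function(sp, K) {
      opt <- truth$optimum_std[[match(sp, truth$species)]]
      sum((opt - cent[K, ])^2)
    })
    sp_gk <- cor(true_gk, pairs$witomi_gk, method = "spearman")
    n_pairs <- nrow(pairs)
  }
  tibble(spearman_omi = sp_omi, spearman_witomi_gk = sp_gk,
         n_species = nrow(joined), n_pairs = n_pairs)
}
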