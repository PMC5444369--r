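#' Decompose realized niches into subset-specific realized subniches
#'
#' Splits the sampling domain into the subsets of `partition` and, for every
#' (species, subset) pair with at least one individual in the subset,
#' computes the realized subniche: the within-subset frequency profile Fr_K,
#' the subniche centroid `m_jK = sum_{i in K} fr_K[i, j] * z0[i, ]`, and two
#' marginality indexes on the common OMI axes —
#' * `witomi_g = ||m_jK||^2`, the subniche marginality measured from the
#'   overall habitat centroid G, and
#' * `witomi_gk = ||m_jK - G_K||^2`, measured from the subset centroid G_K
#'   (equivalently the weighted mean of the within-subset-centered table Z*).
#'
#' The subniche inertia decomposes as
#' `inertia_k = witomi_g + tol_k + rtol_k` (Huygens), with `tol_k` the
#' within-subset tolerance under the fit's tolerance convention. The species'
#' whole-niche marginality is the abundance-weighted barycenter of its
#' subniche centroids: `m_j = sum_K occ_share_jK * m_jK`.
#'
#' @param fit An `omi` fit.
#' @param partition Site-to-subset assignment (see [subset_profiles()]);
#'   every subset needs at least 2 sites.
#' @return An object of class `subniche` wrapping the fit, the subset
#'   geometry ([subset_center()] output) and the per-pair table; use
#'   [subniche_params()] / [tidy()] to extract it.
#' @examples
#' sim <- simulate_community(scenario(n_sites = c(30, 30), n_species = 6), seed = 1)
#' fit <- fit_omi(sim$env, sim$abund)
#' sub <- fit_subniche(fit, sim$partition)
#' subniche_params(sub)
#' @export
fit_subniche <- function(fit, partition) {
  stopifnot(inherits(fit, "omi"))
  part <- as_partition(partition, rownames(fit$z0))
  gk <- do.call(rbind, lapply(part$subsets, function(K) {
    colMeans(fit$z0[part$labels == K, , drop = FALSE])
  }))
  rownames(gk) <- part$subsets

  r <- fit$n_axes
  ur <- fit$eigenvectors[, seq_len(r), drop = FALSE]
  sp_tot <- colSums(fit$counts)

  rows <- purrr::map_dfr(part$subsets, function(K) {
    idx <- which(part$labels == K)
    z0K <- fit$z0[idx, , drop = FALSE]
    zsK <- sweep(z0K, 2L, gk[K, ])
    cK <- fit$counts[idx, , drop = FALSE]
    totK <- colSums(cK)
    present <- totK > 0
    frK <- sweep(cK, 2L, ifelse(present, totK, 1), `/`)

    mK <- t(frK) %*% z0K                       # S x p subniche centroids
    dec <- decompose_inertia(z0K, frK, mK, tolerance = fit$tolerance,
                             u = fit$eigenvectors, n_axes = r)
    mK_gk <- sweep(mK, 2L, gk[K, ])
    coords_g <- mK %*% ur
    coords_gk <- mK_gk %*% ur

    out <- tibble(
      species = fit$species,
      subset = K,
      present = unname(present),
      witomi_g = unname(rowSums(mK^2)),
      witomi_gk = unname(rowSums(mK_gk^2)),
      tol_k = dec$tol,
      rtol_k = dec$rtol,
      inertia_k = dec$inertia,
      occ_share = unname(totK / sp_tot)
    )
    for (a in seq_len(r)) {
      out[[paste0("axis", a, "_g")]] <- unname(coords_g[, a])
      out[[paste0("axis", a, "_gk")]] <- unname(coords_gk[, a])
    }
    # absent pairs carry no numeric subniche values
    num <- setdiff(names(out), c("species", "subset", "present", "occ_share"))
    for (cl in num) out[[cl]][!present] <- NA_real_
    out$marg <- unname(split(mK, row(mK)))
    out
  })
  rows <- dplyr::arrange(rows, factor(.data$species, levels = fit$species),
                         factor(.data$subset, levels = part$subsets))

  structure(
    list(
      fit = fit,
      labels = part$labels,
      subsets = part$subsets,
      gk = gk,
      table = rows
    ),
    class = "subniche"
  )
}

#' Subniche parameter table
#'
#' @param sub A `subniche` object from [fit_subniche()].
#' @return A tibble with one row per (species, subset): presence flag,
#'   `witomi_g`, `witomi_gk`, `tol_k`, `rtol_k`, `inertia_k`, the species'
#'   share of abundance mass in the subset (`occ_share`), and the subniche
#'   coordinates on the retained OMI axes in both frames (`axis*_g` from G,
#'   `axis*_gk` from G_K). Absent pairs carry `NA` indexes.
#' @export
subniche_params <- function(sub) {
  stopifnot(inherits(sub, "subniche"))
  dplyr::select(sub$table, -"marg")
}

#' Subniche coordinates on the OMI factorial axes
#'
#' Projects each present subniche centroid onto the retained OMI axes, in the
#' G frame (`m_jK %*% u`) and the G_K frame (`(m_jK - G_K) %*% u`). With all
#' p axes retained the squared coordinates sum back to `witomi_g` /
#' `witomi_gk`.
#'
#' @param sub A `subniche` object.
#' @param n_axes Number of axes (default: the fit's retained axes).
#' @return A long tibble: species, subset, axis, coord_g, coord_gk.
#' @export
project_subniches <- function(sub, n_axes = NULL) {
  stopifnot(inherits(sub, "subniche"))
  r <- n_axes %||% sub$fit$n_axes
  p <- ncol(sub$fit$eigenvectors)
  if (r > p) abort(sprintf("Cannot retain %d axes from %d variables.", r, p))
  ur <- sub$fit$eigenvectors[, seq_len(r), drop = FALSE]
  tab <- dplyr::filter(sub$table, .data$present)
  purrr::pmap_dfr(
    list(tab$species, tab$subset, tab$marg),
    function(sp, K, m) {
      cg <- as.vector(m %*% ur)
      cgk <- as.vector((m - sub$gk[K, ]) %*% ur)
      tibble(species = sp, subset = K, axis = paste0("Axis", seq_len(r)),
             coord_g = cg, coord_gk = cgk)
    }
  )
}

#' @export
print.subniche <- function(x, ...) {
  cat("Subniche decomposition on OMI axes\n")
  cat(sprintf("  %d species x %d subsets (%s); %d present pairs\n",
              length(x$fit$species), length(x$subsets),
              paste(x$subsets, collapse = ", "), sum(x$table$present)))
  invisible(x)
}
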