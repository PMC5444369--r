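#' Tidy an OMI fit
#'
#' @param x An `omi` fit.
#' @param ... Unused.
#' @return One row per species: inertia, omi, tol, rtol, species weight, and
#'   the species scores on the retained axes.
#' @method tidy omi
#' @export
tidy.omi <- function(x, ...) {
  out <- x$params
  out$weight <- unname(x$species_weights)
  for (a in seq_len(x$n_axes)) {
    out[[paste0("axis", a)]] <- unname(x$species_scores[, a])
  }
  out
}

#' One-line summary of an OMI fit
#'
#' @param x An `omi` fit.
#' @param ... Unused.
#' @return A one-row tibble: n_sites, n_vars, n_species, n_axes,
#'   total_marginality (sum of eigenvalues = community-average OMI) and
#'   var_explained (share of the first `n_axes` eigenvalues).
#' @method glance omi
#' @export
glance.omi <- function(x, ...) {
  tibble(
    n_sites = nrow(x$z0), n_vars = ncol(x$z0),
    n_species = length(x$species), n_axes = x$n_axes,
    total_marginality = sum(x$eigenvalues),
    var_explained = sum(x$eigenvalues[seq_len(x$n_axes)]) / sum(x$eigenvalues)
  )
}

#' Eigenvalue table of an OMI fit
#'
#' @param fit An `omi` fit.
#' @return A tibble: axis, eigenvalue, proportion, cumulative.
#' @export
eigen_table <- function(fit) {
  stopifnot(inherits(fit, "omi"))
  prop <- fit$eigenvalues / sum(fit$eigenvalues)
  tibble(axis = names(fit$eigenvalues), eigenvalue = unname(fit$eigenvalues),
         proportion = unname(prop), cumulative = cumsum(unname(prop)))
}

#' @rdname subniche_params
#' @param x A `subniche` object.
#' @param ... Unused.
#' @method tidy subniche
#' @export
tidy.subniche <- function(x, ...) subniche_params(x)

#' @method glance subniche
#' @export
glance.subniche <- function(x, ...) {
  tibble(n_subsets = length(x$subsets),
         n_species = length(x$fit$species),
         n_pairs_present = sum(x$table$present))
}

#' Plot an OMI ordination
#'
#' Shows the sites on the first factorial plane (with the minimum convex
#' polygon of all available sampling units, the realized environmental space
#' E) and the species niche positions; the origin is G, the overall mean
#' habitat condition.
#'
#' @param object An `omi` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot omi
#' @export
autoplot.omi <- function(object, ...) {
  sc <- as.data.frame(object$site_scores[, 1:2, drop = FALSE])
  names(sc) <- c("Axis1", "Axis2")
  hull <- convex_hull(sc)
  spc <- as.data.frame(object$species_scores[, 1:2, drop = FALSE])
  names(spc) <- c("Axis1", "Axis2")
  spc$species <- object$species
  pct <- 100 * object$eigenvalues / sum(object$eigenvalues)
  ggplot2::ggplot(sc, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::geom_polygon(data = as.data.frame(hull),
                          ggplot2::aes(.data$x, .data$y),
                          fill = "lightblue", alpha = 0.3, colour = "grey40") +
    ggplot2::geom_point(colour = "grey50", size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point(data = spc, colour = "firebrick") +
    ggplot2::geom_text(data = spc, ggplot2::aes(label = .data$species),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = sprintf("OMI1 (%.1f%%)", pct[1]),
                  y = sprintf("OMI2 (%.1f%%)", pct[2]),
                  title = "OMI ordination: sites and species niche positions")
}

#' Plot the subniche envelopes of one species
#'
#' Draws, per subset, the available conditions K, the species' realized niche
#' N_R, the existing fundamental subniche S_P = K intersect N_R, and the
#' realized subniche S_R, with the subset centroid G_K marked. The empty part
#' of S_P is the biological constraint S_B.
#'
#' @param envelopes Output of [build_envelopes()].
#' @param species Species to plot (must be present in `envelopes`).
#' @return A ggplot object faceted by subset.
#' @export
plot_subniche <- function(envelopes, species) {
  rows <- dplyr::filter(envelopes, .data$species == !!species, .data$present)
  if (nrow(rows) == 0L) abort(sprintf("No present subniche for '%s'.", species))
  layer_df <- function(col, lab) {
    purrr::map_dfr(seq_len(nrow(rows)), function(i) {
      poly <- rows[[col]][[i]]
      if (is.null(poly) || nrow(poly) == 0L) return(NULL)
      tibble(subset = rows$subset[i], x = poly$x, y = poly$y, layer = lab)
    })
  }
  polys <- dplyr::bind_rows(
    layer_df("k_hull", "K"), layer_df("nr_hull", "N_R"),
    layer_df("sp_poly", "S_P"), layer_df("sr_hull", "S_R")
  )
  polys$layer <- factor(polys$layer, levels = c("K", "N_R", "S_P", "S_R"))
  ggplot2::ggplot(polys, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_polygon(ggplot2::aes(fill = .data$layer,
                                       colour = .data$layer),
                          alpha = 0.25) +
    ggplot2::facet_wrap(~subset) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::scale_fill_manual(values = c(K = "navy", N_R = "orange",
                                          S_P = "gold", S_R = "forestgreen")) +
    ggplot2::scale_colour_manual(values = c(K = "navy", N_R = "orange",
                                            S_P = "gold", S_R = "forestgreen")) +
    ggplot2::labs(x = "OMI1", y = "OMI2",
                  title = sprintf("Realized subniches of %s", species))
}
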