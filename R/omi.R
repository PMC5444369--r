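#' Fit the outlying mean index (OMI) ordination
#'
#' Finds the combinations of environmental variables that maximize the
#' average marginality of the species in the community. Each species j has a
#' marginality vector `m_j = sum_i fr[i, j] * z0[i, ]` — its frequency-
#' weighted mean position in the standardized environmental space whose
#' origin G is the mean habitat condition of the sampling domain. The
#' analysis eigen-decomposes `C = t(M) %*% diag(w) %*% M`, with species
#' weights `w_j` proportional to total abundance, so that the eigenvalues sum
#' to the community-average OMI (squared marginality).
#'
#' Axis sign and order are made reproducible: eigenvalues are sorted in
#' decreasing order and each eigenvector is flipped so its first non-zero
#' loading (variables in input order) is positive.
#'
#' @param env Site-by-variable environmental data frame (raw units); see
#'   [standardize_env()].
#' @param abund Site-by-species abundance (or occurrence) data frame with the
#'   same sites.
#' @param n_axes Number of factorial axes retained for displays and subniche
#'   projection (default 2).
#' @param tolerance Convention for the tolerance (niche breadth) component:
#'   `"direction"` (default) measures variance along each species' own
#'   marginality direction; `"axes"` sums the weighted variances of the
#'   species' scores over the `n_axes` retained axes.
#' @param site_col Name of the site-id column in both tables.
#'
#' @return An object of class `omi`: a list with the standardized table,
#'   frequency profiles, species weights, marginality vectors, eigenvalues,
#'   eigenvectors, site and species scores, and the per-species niche
#'   parameter table (see [niche_params()]). Use [tidy()] for per-species
#'   parameters, [glance()] for the eigenvalue summary.
#' @examples
#' sim <- simulate_community(scenario(n_sites = c(30, 30), n_species = 6), seed = 1)
#' fit <- fit_omi(sim$env, sim$abund)
#' tidy(fit)
#' glance(fit)
#' @export
fit_omi <- function(env, abund, n_axes = NULL, tolerance = c("direction", "axes"),
                    site_col = NULL) {
  tolerance <- match.arg(tolerance)
  site_col <- site_col %||% id_col_name(env)
  z0_df <- standardize_env(env, site_col)
  z0 <- df_to_matrix(z0_df, site_col, what = "z0")

  counts <- df_to_matrix(abund, id_col_name(abund), what = "abund")
  mismatch <- c(setdiff(rownames(z0), rownames(counts)),
                setdiff(rownames(counts), rownames(z0)))
  if (length(mismatch)) {
    abort(sprintf("Site ids disagree between env and abund: %s",
                  paste(unique(mismatch), collapse = ", ")))
  }
  counts <- counts[rownames(z0), , drop = FALSE]
  fr_df <- species_profiles(matrix_to_df(counts, "site"), "site")
  fr <- df_to_matrix(fr_df, "site", what = "fr")

  if (ncol(fr) < 1L) abort("Need at least one species.")
  p <- ncol(z0)
  n_axes <- as.integer(n_axes %||% min(2L, p))
  if (n_axes < 1L || n_axes > p) {
    abort(sprintf("`n_axes` must be between 1 and %d.", p))
  }

  w <- colSums(counts) / sum(counts)
  M <- t(fr) %*% z0                      # S x p marginality vectors
  C <- t(M) %*% (w * M)                  # p x p weighted cross-product
  eig <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  u <- eig$vectors
  u <- fix_axis_signs(u)
  dimnames(u) <- list(colnames(z0), paste0("Axis", seq_len(p)))
  names(lambda) <- colnames(u)

  site_scores <- z0 %*% u
  species_scores <- M %*% u

  fit <- structure(
    list(
      z0 = z0, fr = fr, counts = counts, site_col = site_col,
      species = colnames(fr), var_names = colnames(z0),
      species_weights = w, marginality = M,
      eigenvalues = lambda, eigenvectors = u,
      n_axes = n_axes, tolerance = tolerance,
      site_scores = site_scores, species_scores = species_scores
    ),
    class = "omi"
  )
  fit$params <- niche_params(fit)
  fit
}

# Deterministic sign convention: first non-zero loading positive.
fix_axis_signs <- function(u, tol = 1e-12) {
  for (a in seq_len(ncol(u))) {
    nz <- which(abs(u[, a]) > tol)
    if (length(nz) && u[nz[1L], a] < 0) u[, a] <- -u[, a]
  }
  u
}

#' Per-species niche parameters
#'
#' Decomposes each species' niche inertia (frequency-weighted mean squared
#' distance of its used sites from G) into OMI + Tol + Rtol:
#' * `omi` — squared norm of the marginality vector, the squared distance
#'   between the species' mean used conditions and G;
#' * `tol` — tolerance (niche breadth): with the `"direction"` convention the
#'   weighted variance of used conditions along the species' own marginality
#'   direction, with `"axes"` the summed score variance over retained axes;
#' * `rtol` — residual tolerance, the remaining spread.
#'
#' A species with zero marginality has no defined marginality direction; its
#' `tol` is 0 and `rtol` carries all spread.
#'
#' @param fit An `omi` fit.
#' @return A tibble: species, inertia, omi, tol, rtol.
#' @export
niche_params <- function(fit) {
  stopifnot(inherits(fit, "omi"))
  decompose_inertia(fit$z0, fit$fr, fit$marginality,
                    tolerance = fit$tolerance,
                    u = fit$eigenvectors, n_axes = fit$n_axes) |>
    tibble::add_column(species = fit$species, .before = 1)
}

# Shared Huygens decomposition: rows of M are weighted means of `ref` rows
# under the columns of `fr` (n x S). Returns tibble inertia/omi/tol/rtol.
decompose_inertia <- function(ref, fr, M, tolerance = "direction",
                              u = NULL, n_axes = NULL) {
  sq <- rowSums(ref^2)
  inertia <- as.vector(t(fr) %*% sq)
  omi <- unname(rowSums(M^2))
  S <- ncol(fr)
  tol <- numeric(S)
  if (tolerance == "direction") {
    for (j in seq_len(S)) {
      nm <- sqrt(omi[j])
      if (nm > 0) {
        t_i <- as.vector(ref %*% (M[j, ] / nm))
        tol[j] <- sum(fr[, j] * (t_i - nm)^2)
      }
    }
  } else {
    scores <- ref %*% u[, seq_len(n_axes), drop = FALSE]
    cent <- M %*% u[, seq_len(n_axes), drop = FALSE]
    for (j in seq_len(S)) {
      dev <- sweep(scores, 2L, cent[j, ])
      tol[j] <- sum(fr[, j] * rowSums(dev^2))
    }
  }
  rtol <- inertia - omi - tol
  tibble(inertia = inertia, omi = omi, tol = tol, rtol = pmax(rtol, 0))
}

#' Project sites onto the OMI factorial axes
#'
#' Computes `Z0 %*% u` restricted to the first `n_axes` axes: the coordinates
#' of all available sampling units on the OMI plane. When all axes are kept
#' the projection is an isometry (per-site norms are preserved).
#'
#' @param x An `omi` fit, or a standardized environmental tibble (in which
#'   case `eigenvectors` must be supplied).
#' @param n_axes Number of axes (default: the fit's retained axes; at most p).
#' @param eigenvectors p-by-p orthonormal matrix when `x` is a tibble.
#' @param site_col Site-id column name when `x` is a tibble.
#' @return A tibble: site id plus `Axis1..Axisr` coordinates.
#' @export
project_sites <- function(x, n_axes = NULL, eigenvectors = NULL, site_col = NULL) {
  if (inherits(x, "omi")) {
    z <- x$z0
    u <- x$eigenvectors
    n_axes <- n_axes %||% x$n_axes
    site_col <- x$site_col
  } else {
    site_col <- site_col %||% id_col_name(x)
    z <- df_to_matrix(x, site_col, what = "z0")
    u <- eigenvectors
    if (is.null(u)) abort("Supply `eigenvectors` when projecting a raw table.")
    n_axes <- n_axes %||% ncol(u)
  }
  if (n_axes > ncol(u)) {
    abort(sprintf("Cannot retain %d axes from a %d-variable analysis.",
                  n_axes, ncol(u)))
  }
  sc <- z %*% u[, seq_len(n_axes), drop = FALSE]
  if (is.null(colnames(sc))) colnames(sc) <- paste0("Axis", seq_len(n_axes))
  matrix_to_df(sc, site_col)
}

#' Permutation test of species marginality (whole domain)
#'
#' Monte-Carlo test of each species' OMI against the null hypothesis that the
#' species is uninfluenced by the environment (ubiquitous). Each permutation
#' shuffles whole rows of the standardized table Z0 (preserving inter-variable
#' correlation) and recomputes every species' squared marginality. P-values
#' use the `(b + 1) / (n_perm + 1)` rule, so the attainable minimum is
#' `1 / (n_perm + 1)`.
#'
#' @param fit An `omi` fit.
#' @param n_perm Number of permutations (default 1000, minimum 99).
#' @param seed Integer master seed; permutations are drawn from a dedicated
#'   substream so results are reproducible.
#' @return A tibble: species, omi (observed), p_value, n_perm, seed.
#' @export
omi_test <- function(fit, n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(fit, "omi"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 99L) abort("`n_perm` must be at least 99.")
  seed <- check_seed(seed)
  n <- nrow(fit$z0)
  observed <- rowSums(fit$marginality^2)
  tfr <- t(fit$fr)
  ge <- integer(length(observed))
  withr_seed(seed_stream(seed, "omi_test"), {
    for (b in seq_len(n_perm)) {
      Mb <- tfr %*% fit$z0[sample.int(n), , drop = FALSE]
      ge <- ge + (rowSums(Mb^2) >= observed - 1e-14)
    }
  })
  tibble(
    species = fit$species,
    omi = unname(observed),
    p_value = unname(ge + 1) / (n_perm + 1),
    n_perm = n_perm,
    seed = seed
  )
}

# Evaluate `code` under a local RNG state seeded with `seed`.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' @export
print.omi <- function(x, ...) {
  cat("OMI ordination\n")
  cat(sprintf("  %d sites, %d variables, %d species; %d axes retained\n",
              nrow(x$z0), ncol(x$z0), length(x$species), x$n_axes))
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("  eigenvalues: %s\n",
              paste(sprintf("%.4f (%.1f%%)", x$eigenvalues, pct), collapse = ", ")))
  cat(sprintf("  community-average OMI (sum of eigenvalues): %.4f\n",
              sum(x$eigenvalues)))
  invisible(x)
}
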