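# Convex-polygon niche envelopes on the 2-D OMI display plane.
#
# Polygons are stored counter-clockwise; areas come from the shoelace
# formula; intersection is Sutherland-Hodgman clipping (both inputs convex,
# so the result is convex). Degenerate hulls (points, segments, collinear
# sets) are legal and carry area 0.

new_polygon <- function(xy, label = NA_character_) {
  xy <- as.matrix(xy)
  if (nrow(xy) > 1L) {
    keep <- c(TRUE, rowSums(abs(diff(xy))) > 0)
    xy <- xy[keep, , drop = FALSE]
    if (nrow(xy) > 1L && all(abs(xy[1L, ] - xy[nrow(xy), ]) < 1e-300)) {
      xy <- xy[-nrow(xy), , drop = FALSE]
    }
  }
  structure(
    tibble(x = xy[, 1], y = xy[, 2]),
    label = label,
    area = shoelace(xy),
    class = c("niche_polygon", class(tibble()))
  )
}

shoelace <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

#' Area of a niche polygon
#' @param poly A `niche_polygon`.
#' @return The enclosed area (0 for degenerate polygons).
#' @export
polygon_area <- function(poly) attr(poly, "area") %||% 0

#' Minimum convex polygon of a 2-D point set
#'
#' The minimum convex polygon (convex hull) is the niche envelope used to
#' outline available and used sampling units on the ordination plane.
#'
#' @param points A data frame or matrix whose first two numeric columns are
#'   the plane coordinates (id columns are ignored); at least one point.
#' @param label Optional envelope label (e.g. `"E"`, `"K"`, `"N_R"`,
#'   `"S_R"`).
#' @return A `niche_polygon`: a tibble of counter-clockwise vertices `x`, `y`
#'   with attributes `area` and `label`. One point or collinear points give a
#'   degenerate polygon of area 0.
#' @examples
#' convex_hull(cbind(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5)))
#' @export
convex_hull <- function(points, label = NA_character_) {
  xy <- points_xy(points)
  if (nrow(xy) == 0L) abort("Cannot build a hull from an empty point set.")
  xy <- unique(xy)
  if (nrow(xy) <= 2L) return(new_polygon(xy, label))
  h <- grDevices::chull(xy[, 1], xy[, 2])
  hull <- xy[rev(h), , drop = FALSE]  # chull is clockwise
  if (shoelace(hull) == 0 && nrow(hull) > 2L) {
    # collinear set: keep the two extreme points of the segment
    dir <- hull[which.max(rowSums(sweep(hull, 2L, hull[1L, ])^2)), ] - hull[1L, ]
    t <- as.vector(sweep(hull, 2L, hull[1L, ]) %*% dir)
    hull <- hull[c(which.min(t), which.max(t)), , drop = FALSE]
  }
  new_polygon(hull, label)
}

points_xy <- function(points) {
  if (is.matrix(points)) {
    m <- points[, 1:2, drop = FALSE]
  } else {
    df <- as.data.frame(points)
    num <- df[vapply(df, is.numeric, logical(1))]
    if (ncol(num) < 2L) abort("Need two numeric coordinate columns.")
    m <- as.matrix(num[, 1:2])
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Intersection of two convex polygons
#'
#' Clips `p` against each edge of `q` (Sutherland-Hodgman); since both are
#' convex the result is the convex intersection, possibly empty (area 0).
#' Degenerate inputs (area 0) intersect to an empty polygon.
#'
#' @param p,q `niche_polygon` objects (or vertex matrices).
#' @param label Label for the result (default `"S_P"` convention is up to the
#'   caller).
#' @return A `niche_polygon`.
#' @export
intersect_convex <- function(p, q, label = NA_character_) {
  pv <- points_xy(p); qv <- points_xy(q)
  if (nrow(pv) < 3L || nrow(qv) < 3L ||
      shoelace(ccw(pv)) == 0 || shoelace(ccw(qv)) == 0) {
    return(new_polygon(matrix(numeric(0), 0, 2), label))
  }
  subject <- ccw(pv)
  clip <- ccw(qv)
  nq <- nrow(clip)
  for (e in seq_len(nq)) {
    a <- clip[e, ]; b <- clip[if (e == nq) 1L else e + 1L, ]
    subject <- clip_halfplane(subject, a, b)
    if (nrow(subject) == 0L) break
  }
  new_polygon(subject, label)
}

# Ensure counter-clockwise orientation (signed shoelace > 0).
ccw <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(xy)
  j <- c(2:n, 1L)
  s <- sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
  if (s < 0) xy[n:1, , drop = FALSE] else xy
}

# Keep the part of `poly` on the left of directed edge a -> b.
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- (b[1] - a[1]) * (poly[, 2] - a[2]) - (b[2] - a[2]) * (poly[, 1] - a[1])
  inside <- d >= -1e-12
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) out <- rbind(out, poly[i, ])
    if (xor(inside[i], inside[j])) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Biological constraint S_B of a realized subniche
#'
#' Quantifies the part of the existing fundamental subniche S_P (the
#' intersection of the subset's available conditions K with the realized
#' niche N_R) left unoccupied by the realized subniche S_R:
#' `area_sb = area(S_P) - area(S_R clipped to S_P)`, also expressed as a
#' percentage of the S_P area. S_R is clipped to S_P first because convex
#' envelopes can spill outside the intersection.
#'
#' @param sp The S_P polygon (from [intersect_convex()] of the K and N_R
#'   hulls).
#' @param sr The S_R polygon (hull of the species' used sites in the
#'   subset).
#' @return A one-row tibble: area_sp, area_sr, area_sb, sb_percent,
#'   degenerate (TRUE when S_P has zero area, in which case sb_percent is
#'   defined as 0).
#' @export
biological_constraint <- function(sp, sr) {
  area_sp <- polygon_area(sp)
  area_sr <- polygon_area(sr)
  if (area_sp <= 0) {
    return(tibble(area_sp = area_sp, area_sr = area_sr, area_sb = 0,
                  sb_percent = 0, degenerate = TRUE))
  }
  clipped <- polygon_area(intersect_convex(sr, sp))
  if (clipped <= 0 && area_sr > 0) {
    warn("Realized subniche S_R lies entirely outside S_P; S_B is 100% of S_P.")
  }
  area_sb <- max(area_sp - clipped, 0)
  tibble(area_sp = area_sp, area_sr = area_sr, area_sb = area_sb,
         sb_percent = 100 * area_sb / area_sp, degenerate = FALSE)
}

#' Niche envelopes and constraint estimates for every subniche
#'
#' Builds, on the first two OMI axes, the minimum convex polygons of the
#' whole domain (E), each subset's available conditions (K), each species'
#' realized niche (N_R: sites with positive frequency), and each realized
#' subniche (S_R: subset sites with positive within-subset frequency); then
#' S_P = K intersect N_R and the biological constraint via
#' [biological_constraint()].
#'
#' @param sub A `subniche` object fitted with at least 2 retained axes.
#' @param species Species to include (default all).
#' @param min_freq Minimum frequency for a site to count as used (default 0,
#'   i.e. any presence).
#' @return A tibble, one row per present (species, subset): list-columns
#'   `e_hull`, `k_hull`, `nr_hull`, `sr_hull`, `sp_poly` plus the constraint
#'   columns of [biological_constraint()]. Absent pairs are flagged with
#'   `present = FALSE` and NA areas.
#' @export
build_envelopes <- function(sub, species = NULL, min_freq = 0) {
  stopifnot(inherits(sub, "subniche"))
  fit <- sub$fit
  if (fit$n_axes < 2L) abort("Envelopes need at least 2 retained axes.")
  species <- species %||% fit$species
  unknown <- setdiff(species, fit$species)
  if (length(unknown)) {
    abort(sprintf("Unknown species: %s", paste(unknown, collapse = ", ")))
  }
  sc <- fit$site_scores[, 1:2, drop = FALSE]
  e_hull <- convex_hull(sc, label = "E")
  k_hulls <- lapply(setNames(sub$subsets, sub$subsets), function(K) {
    convex_hull(sc[sub$labels == K, , drop = FALSE], label = "K")
  })

  purrr::map_dfr(species, function(sp) {
    used <- fit$fr[, sp] > min_freq
    nr_hull <- convex_hull(sc[used, , drop = FALSE], label = "N_R")
    purrr::map_dfr(sub$subsets, function(K) {
      in_k <- sub$labels == K
      used_k <- used & in_k
      if (!any(used_k)) {
        return(tibble(species = sp, subset = K, present = FALSE,
                      e_hull = list(e_hull), k_hull = list(k_hulls[[K]]),
                      nr_hull = list(nr_hull), sr_hull = list(NULL),
                      sp_poly = list(NULL),
                      area_sp = NA_real_, area_sr = NA_real_,
                      area_sb = NA_real_, sb_percent = NA_real_,
                      degenerate = NA))
      }
      sr_hull <- convex_hull(sc[used_k, , drop = FALSE], label = "S_R")
      sp_poly <- intersect_convex(k_hulls[[K]], nr_hull, label = "S_P")
      bc <- biological_constraint(sp_poly, sr_hull)
      tibble(species = sp, subset = K, present = TRUE,
             e_hull = list(e_hull), k_hull = list(k_hulls[[K]]),
             nr_hull = list(nr_hull), sr_hull = list(sr_hull),
             sp_poly = list(sp_poly)) |>
        dplyr::bind_cols(bc)
    })
  })
}

#' Flat constraint table
#'
#' @param envelopes Output of [build_envelopes()].
#' @return The numeric columns only: species, subset, present, area_sp,
#'   area_sr, area_sb, sb_percent.
#' @export
constraint_table <- function(envelopes) {
  dplyr::select(envelopes, "species", "subset", "present", "area_sp",
                "area_sr", "area_sb", "sb_percent")
}

#' Write niche envelopes as GeoJSON
#'
#' One FeatureCollection per (species, subset) pair would be unwieldy in a
#' single file, so all polygons are emitted as features of one collection
#' with `species`, `subset`, `label` and `area` properties. Coordinates are
#' OMI-plane scores, not geographic coordinates.
#'
#' @param envelopes Output of [build_envelopes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_envelopes_geojson <- function(envelopes, path) {
  feats <- list()
  for (i in seq_len(nrow(envelopes))) {
    row <- envelopes[i, ]
    for (col in c("e_hull", "k_hull", "nr_hull", "sr_hull", "sp_poly")) {
      poly <- row[[col]][[1]]
      if (is.null(poly) || nrow(poly) < 3L) next
      ring <- cbind(poly$x, poly$y)
      ring <- rbind(ring, ring[1L, ])
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(species = row$species, subset = row$subset,
                          label = attr(poly, "label"),
                          area = polygon_area(poly)),
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(ring)),
                                                  function(r) ring[r, ])))
      )
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
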