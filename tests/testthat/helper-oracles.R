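# Independent, loop-based oracles and fixture builders. These deliberately
# avoid the package's matrix code paths: everything is written as explicit
# per-site / per-species summations.

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_standardize <- function(x) {
  out <- x
  for (c in seq_len(ncol(x))) {
    m <- sum(x[, c]) / nrow(x)
    v <- sum((x[, c] - m)^2) / nrow(x)
    out[, c] <- (x[, c] - m) / sqrt(v)
  }
  out
}

# Per-species niche parameters by direct summation over sites.
oracle_niche <- function(z, counts) {
  n <- nrow(z); p <- ncol(z); S <- ncol(counts)
  res <- list()
  grand <- sum(counts)
  sum_lambda <- 0
  for (j in seq_len(S)) {
    fr <- counts[, j] / sum(counts[, j])
    m <- numeric(p)
    for (i in seq_len(n)) m <- m + fr[i] * z[i, ]
    omi <- sum(m^2)
    inertia <- 0
    for (i in seq_len(n)) inertia <- inertia + fr[i] * sum(z[i, ]^2)
    tol <- 0
    if (omi > 0) {
      d <- m / sqrt(omi)
      for (i in seq_len(n)) tol <- tol + fr[i] * (sum(z[i, ] * d) - sqrt(omi))^2
    }
    res[[j]] <- c(inertia = inertia, omi = omi, tol = tol,
                  rtol = inertia - omi - tol)
    sum_lambda <- sum_lambda + (sum(counts[, j]) / grand) * omi
  }
  list(params = do.call(rbind, res), sum_lambda = sum_lambda)
}

# Per-(species, subset) subniche parameters by direct summation.
oracle_subniche <- function(z, counts, labels) {
  n <- nrow(z); p <- ncol(z)
  rows <- list()
  for (K in unique(labels)) {
    idx <- which(labels == K)
    gk <- numeric(p)
    for (i in idx) gk <- gk + z[i, ] / length(idx)
    for (j in seq_len(ncol(counts))) {
      totK <- sum(counts[idx, j])
      if (totK == 0) next
      frk <- counts[idx, j] / totK
      m <- numeric(p)
      for (a in seq_along(idx)) m <- m + frk[a] * z[idx[a], ]
      witg <- sum(m^2)
      witgk <- sum((m - gk)^2)
      inertia <- 0
      for (a in seq_along(idx)) inertia <- inertia + frk[a] * sum(z[idx[a], ]^2)
      tol <- 0
      if (witg > 0) {
        d <- m / sqrt(witg)
        for (a in seq_along(idx)) {
          tol <- tol + frk[a] * (sum(z[idx[a], ] * d) - sqrt(witg))^2
        }
      }
      rows[[paste(K, j)]] <- tibble::tibble(
        subset = K, species = colnames(counts)[j],
        witomi_g = witg, witomi_gk = witgk, tol_k = tol,
        rtol_k = inertia - witg - tol, inertia_k = inertia,
        occ_share = totK / sum(counts[, j]),
        m = list(m), gk = list(gk)
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Random small instance with valid invariants (counts > 0 per species,
# subsets >= 2 sites). Returns tibbles ready for the package functions.
random_instance <- function(seed, n = NULL, p = NULL, S = NULL, N = NULL) {
  set.seed(seed)
  n <- n %||% sample(10:40, 1)
  p <- p %||% sample(1:5, 1)
  S <- S %||% sample(1:8, 1)
  N <- N %||% sample(1:3, 1)
  x <- matrix(rnorm(n * p, sd = runif(p, 0.5, 3)), n, p, byrow = TRUE)
  colnames(x) <- paste0("v", seq_len(p))
  counts <- matrix(rpois(n * S, 1.2), n, S)
  for (j in seq_len(S)) {
    if (sum(counts[, j]) == 0) counts[sample.int(n, 1), j] <- 1L
  }
  colnames(counts) <- paste0("sp", seq_len(S))
  # partition with every subset >= 2 sites
  repeat {
    labels <- sample(paste0("K", seq_len(N)), n, replace = TRUE)
    if (all(table(labels) >= 2) && length(unique(labels)) == N) break
  }
  sites <- sprintf("s%02d", seq_len(n))
  list(
    env = tibble::tibble(site = sites, tibble::as_tibble(x)),
    abund = tibble::tibble(site = sites, tibble::as_tibble(counts)),
    partition = tibble::tibble(site = sites, subset = labels),
    x = x, counts = counts, labels = labels
  )
}

# O(n^3) brute-force convex hull: (i, j) is a hull edge iff every other
# point lies on its left (or on the line). Vertices ordered by angle.
brute_hull <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n <= 2) return(xy)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- xy[i, ]; b <- xy[j, ]
      cr <- (b[1] - a[1]) * (xy[, 2] - a[2]) - (b[2] - a[2]) * (xy[, 1] - a[1])
      if (all(cr >= -1e-12)) { on_hull[i] <- TRUE; on_hull[j] <- TRUE }
    }
  }
  v <- xy[on_hull, , drop = FALSE]
  ctr <- colMeans(v)
  v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
}

# Point-in-convex-polygon (vectorized over points).
points_in_poly <- function(pts, poly, eps = 1e-9) {
  v <- cbind(poly$x, poly$y)
  n <- nrow(v)
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & cr >= -eps
  }
  inside
}

square_poly <- function(x0, y0, x1, y1, label = NA_character_) {
  convex_hull(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)), label = label)
}

micro_tables <- function() {
  list(
    env = tibble::tibble(site = paste0("s", 1:4), v = c(1, 2, 3, 4)),
    abund = tibble::tibble(site = paste0("s", 1:4), sp1 = c(1, 0, 0, 0)),
    partition = tibble::tibble(site = paste0("s", 1:4),
                               subset = c("K1", "K1", "K2", "K2"))
  )
}
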