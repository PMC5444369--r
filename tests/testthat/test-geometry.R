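# Convex envelopes, intersection, and the biological constraint S_B.

shoelace_test <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}
sort_rows <- function(m) m[order(round(m[, 1], 9), round(m[, 2], 9)), , drop = FALSE]

test_that("hull of a square with interior points is the square", {
  pts <- rbind(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
               cbind(runif(20, 0.1, 0.9), runif(20, 0.1, 0.9)))
  h <- convex_hull(pts, label = "E")
  expect_equal(polygon_area(h), 1, tolerance = 1e-12)
  expect_equal(nrow(h), 4)
  expect_identical(attr(h, "label"), "E")
})

test_that("degenerate point sets give degenerate polygons of area 0", {
  expect_equal(polygon_area(convex_hull(cbind(1, 2))), 0)
  seg <- convex_hull(cbind(c(0, 1, 2), c(0, 1, 2)))  # collinear
  expect_equal(nrow(seg), 2)
  expect_equal(polygon_area(seg), 0)
  expect_error(convex_hull(matrix(numeric(0), 0, 2)), "empty")
})

test_that("hull matches the brute-force oracle and is idempotent", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    pts <- cbind(rnorm(n), rnorm(n))
    h <- convex_hull(pts)
    bh <- brute_hull(pts)
    expect_equal(polygon_area(h), shoelace_test(bh), tolerance = 1e-9)
    expect_true(all(points_in_poly(pts, h)))
    expect_equal(sort_rows(cbind(h$x, h$y)), sort_rows(bh), tolerance = 1e-9)
    h2 <- convex_hull(cbind(h$x, h$y))
    expect_equal(sort_rows(cbind(h2$x, h2$y)), sort_rows(cbind(h$x, h$y)),
                 tolerance = 1e-12)
  }
})

test_that("convex intersection handles exact and degenerate cases", {
  sq <- square_poly(0, 0, 1, 1)
  expect_equal(polygon_area(intersect_convex(sq, sq)), 1, tolerance = 1e-12)
  shifted <- square_poly(0.5, 0, 1.5, 1)
  expect_equal(polygon_area(intersect_convex(sq, shifted)), 0.5,
               tolerance = 1e-12)
  far <- square_poly(5, 5, 6, 6)
  expect_equal(polygon_area(intersect_convex(sq, far)), 0)
  seg <- convex_hull(cbind(c(0, 1), c(0, 1)))
  expect_equal(polygon_area(intersect_convex(sq, seg)), 0)
})

test_that("intersection area agrees with a Monte-Carlo membership oracle", {
  set.seed(99)
  for (rep in 1:8) {
    p <- convex_hull(cbind(rnorm(12), rnorm(12)))
    q <- convex_hull(cbind(rnorm(12, 0.5), rnorm(12, 0.5)))
    inter <- intersect_convex(p, q)
    a <- polygon_area(inter)
    expect_lte(a, min(polygon_area(p), polygon_area(q)) + 1e-12)
    # MC estimate over the bounding box of p
    lo <- c(min(p$x), min(p$y)); hi <- c(max(p$x), max(p$y))
    m <- 1e4
    pts <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]))
    hit <- points_in_poly(pts, p) & points_in_poly(pts, q)
    box <- prod(hi - lo)
    est <- mean(hit) * box
    se <- box * sqrt(mean(hit) * (1 - mean(hit)) / m)
    expect_lt(abs(a - est), max(3 * se, 1e-6))
  }
})

test_that("biological constraint: exact 0, 50 and 100 percent cases", {
  sp <- square_poly(0, 0, 1, 1, label = "S_P")
  full <- biological_constraint(sp, sp)
  expect_equal(full$area_sb, 0)
  expect_equal(full$sb_percent, 0)

  half <- biological_constraint(sp, square_poly(0, 0, 0.5, 1))
  expect_equal(half$area_sb, 0.5, tolerance = 1e-12)
  expect_equal(half$sb_percent, 50, tolerance = 1e-10)

  expect_warning(
    none <- biological_constraint(sp, square_poly(3, 3, 4, 4)),
    "outside"
  )
  expect_equal(none$sb_percent, 100, tolerance = 1e-10)
  expect_equal(none$area_sb, 1, tolerance = 1e-12)

  # degenerate S_P: percentage defined as 0 and flagged
  degen <- biological_constraint(convex_hull(cbind(0, 0)), sp)
  expect_true(degen$degenerate)
  expect_equal(degen$sb_percent, 0)
})

test_that("S_R spilling outside S_P is clipped before differencing", {
  sp <- square_poly(0, 0, 1, 1)
  sr <- square_poly(0.5, -1, 2, 2)  # only a 0.5 x 1 sliver lies inside S_P
  bc <- biological_constraint(sp, sr)
  expect_equal(bc$area_sb, 0.5, tolerance = 1e-12)
  expect_equal(bc$sb_percent, 50, tolerance = 1e-10)
})

test_that("rotating all scores leaves every area unchanged", {
  set.seed(101)
  pts <- cbind(rnorm(30), rnorm(30))
  th <- 0.93
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  h1 <- convex_hull(pts)
  h2 <- convex_hull(pts %*% R)
  expect_equal(polygon_area(h1), polygon_area(h2), tolerance = 1e-9)
  q1 <- convex_hull(pts[1:15, ]); q2 <- convex_hull(pts[1:15, ] %*% R)
  expect_equal(polygon_area(intersect_convex(h1, q1)),
               polygon_area(intersect_convex(h2, q2)), tolerance = 1e-9)
})

test_that("envelopes nest correctly and flag absent pairs", {
  inst <- random_instance(311, n = 40, p = 3, S = 5, N = 2)
  fit <- fit_omi(inst$env, inst$abund)
  sub <- fit_subniche(fit, inst$partition)
  env <- build_envelopes(sub)
  pres <- dplyr::filter(env, present)
  expect_gt(nrow(pres), 0)
  for (i in seq_len(nrow(pres))) {
    sr <- pres$sr_hull[[i]]
    k <- pres$k_hull[[i]]; nr <- pres$nr_hull[[i]]; spp <- pres$sp_poly[[i]]
    v <- cbind(sr$x, sr$y)
    expect_true(all(points_in_poly(v, k, eps = 1e-8)))
    expect_true(all(points_in_poly(v, nr, eps = 1e-8)))
    expect_lte(polygon_area(spp),
               min(polygon_area(k), polygon_area(nr)) + 1e-10)
    expect_gte(pres$sb_percent[i], 0)
    expect_lte(pres$sb_percent[i], 100)
    expect_lte(pres$area_sb[i], pres$area_sp[i] + 1e-12)
  }
  # a species absent from one subset is flagged, not errored
  ab <- inst$abund
  ab$onlyk1 <- ifelse(inst$labels == "K1", 1L, 0L)
  # 'rare' occupies several K2 sites but a single K1 site: its K1 realized
  # subniche is a point while its whole niche N_R is a real polygon
  ab$rare <- ifelse(inst$labels == "K2", 2L, 0L)
  ab$rare[which(inst$labels == "K1")[1]] <- 2L
  fit2 <- fit_omi(inst$env, ab)
  sub2 <- fit_subniche(fit2, inst$partition)
  env2 <- build_envelopes(sub2, species = c("onlyk1", "rare"))
  expect_false(dplyr::filter(env2, species == "onlyk1", subset == "K2")$present)
  k1row <- dplyr::filter(env2, species == "rare", subset == "K1")
  expect_equal(k1row$area_sr, 0)
  expect_gt(k1row$area_sp, 0)
  expect_equal(k1row$sb_percent, 100, tolerance = 1e-10)
})

test_that("whole-domain subset makes S_P coincide with the realized niche hull", {
  inst <- random_instance(313, n = 30, p = 3, S = 3, N = 1)
  fit <- fit_omi(inst$env, inst$abund)
  env <- build_envelopes(fit_subniche(fit, inst$partition))
  for (i in seq_len(nrow(env))) {
    if (!env$present[i]) next
    expect_equal(env$area_sp[i], polygon_area(env$nr_hull[[i]]),
                 tolerance = 1e-9)
  }
})
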