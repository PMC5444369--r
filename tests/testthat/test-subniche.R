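# Subniche decomposition: WitOMI in both frames, tolerances, projections.

# local helper: matrix with site rownames -> tibble (site first)
matrix_to_df_test <- function(m) {
  tibble::tibble(site = rownames(m), tibble::as_tibble(m))
}

test_that("the four-site micro example gives the closed-form indexes", {
  mt <- micro_tables()
  fit <- fit_omi(mt$env, mt$abund, n_axes = 1)
  expect_equal(tidy(fit)$omi, 1.8, tolerance = 1e-12)
  sub <- fit_subniche(fit, mt$partition)
  k1 <- dplyr::filter(subniche_params(sub), subset == "K1")
  expect_equal(k1$witomi_g, 1.8, tolerance = 1e-12)
  expect_equal(k1$witomi_gk, 0.2, tolerance = 1e-12)
  # species only at one site of the subset: no spread
  expect_equal(k1$tol_k + k1$rtol_k, 0, tolerance = 1e-12)
  # absent in K2: flagged, no numbers
  k2 <- dplyr::filter(subniche_params(sub), subset == "K2")
  expect_false(k2$present)
  expect_true(is.na(k2$witomi_g))
})

test_that("a whole-domain subset reproduces the whole-niche parameters", {
  inst <- random_instance(83, N = 1, S = 5)
  fit <- fit_omi(inst$env, inst$abund)
  sub <- fit_subniche(fit, inst$partition)
  pars <- tidy(fit)
  spars <- subniche_params(sub)
  expect_equal(spars$witomi_g, pars$omi, tolerance = 1e-10)
  expect_equal(spars$witomi_gk, pars$omi, tolerance = 1e-10)
  expect_equal(spars$tol_k, pars$tol, tolerance = 1e-10)
  expect_equal(spars$rtol_k, pars$rtol, tolerance = 1e-10)
  expect_equal(spars$inertia_k, pars$inertia, tolerance = 1e-10)
})

test_that("subniche indexes match the direct-summation oracle", {
  for (seed in c(89, 97, 103)) {
    inst <- random_instance(seed, N = 3)
    fit <- fit_omi(inst$env, inst$abund)
    sub <- fit_subniche(fit, inst$partition)
    z0 <- oracle_standardize(inst$x)
    orc <- oracle_subniche(z0, inst$counts, inst$labels)
    got <- dplyr::filter(subniche_params(sub), present) |>
      dplyr::inner_join(orc, by = c("species", "subset"),
                        suffix = c("", "_orc"))
    expect_equal(nrow(got), nrow(orc))
    expect_lt(max(abs(got$witomi_g - got$witomi_g_orc)), 1e-10)
    expect_lt(max(abs(got$witomi_gk - got$witomi_gk_orc)), 1e-10)
    expect_lt(max(abs(got$tol_k - got$tol_k_orc)), 1e-10)
    expect_lt(max(abs(got$inertia_k - got$inertia_k_orc)), 1e-10)
    expect_lt(max(abs(got$occ_share - got$occ_share_orc)), 1e-12)
  }
})

test_that("conservation identities hold: Huygens, barycenter, frame shift", {
  for (seed in 131:140) {
    inst <- random_instance(seed)
    fit <- fit_omi(inst$env, inst$abund)
    sub <- fit_subniche(fit, inst$partition)
    tab <- dplyr::filter(sub$table, present)
    # inertia_K = WitOMI_G + Tol_K + Rtol_K
    expect_lt(max(abs(tab$inertia_k - tab$witomi_g - tab$tol_k - tab$rtol_k)),
              1e-10)
    # norm expansion linking both frames
    gknorm <- rowSums(sub$gk^2)[tab$subset]
    cross <- purrr::map2_dbl(tab$marg, tab$subset,
                             ~ sum(sub$gk[.y, ] * (.x - sub$gk[.y, ])))
    expect_lt(max(abs(tab$witomi_g -
                        (tab$witomi_gk + gknorm + 2 * cross))), 1e-10)
    # abundance-share barycenter recovers the whole-niche marginality vector
    for (sp in fit$species) {
      rows <- dplyr::filter(sub$table, species == sp)
      m_rebuilt <- Reduce(`+`, purrr::map2(rows$occ_share, rows$marg, function(w, m) {
        if (is.null(m) || any(is.na(m))) rep(0, ncol(fit$z0)) else w * m
      }))
      expect_lt(max(abs(m_rebuilt - fit$marginality[sp, ])), 1e-10)
    }
    # occupancy shares partition each species' abundance mass
    shares <- dplyr::summarise(sub$table, s = sum(occ_share), .by = species)
    expect_lt(max(abs(shares$s - 1)), 1e-12)
    # frame identity m_jK = G_K + within-subset weighted mean of z*
    sc <- subset_center(matrix_to_df_test(fit$z0), inst$partition)
    zs <- as.matrix(sc$z_star[, -(1:2)])
    for (i in seq_len(nrow(tab))) {
      K <- tab$subset[i]; sp <- tab$species[i]
      idx <- which(inst$labels == K)
      cK <- inst$counts[idx, sp]
      mstar <- colSums((cK / sum(cK)) * zs[idx, , drop = FALSE])
      expect_lt(max(abs(tab$marg[[i]] - (sub$gk[K, ] + mstar))), 1e-12)
    }
  }
})

test_that("translating one subset moves G_K but not the centered frame", {
  inst <- random_instance(149, N = 2, p = 3)
  z0 <- standardize_env(inst$env)
  sc <- subset_center(z0, inst$partition)
  v <- c(0.7, -1.2, 0.4)
  z0_shift <- z0
  shift_rows <- inst$partition$subset == "K2"
  z0_shift[shift_rows, -1] <- sweep(as.matrix(z0[shift_rows, -1]), 2L, -v)
  sc2 <- subset_center(z0_shift, inst$partition)
  expect_equal(as.numeric(sc2$gk[2, -1]), as.numeric(sc$gk[2, -1]) + v,
               tolerance = 1e-12)
  # the within-subset frame (hence every WitOMI G_K) is unchanged
  expect_equal(sc2$z_star[, -(1:2)], sc$z_star[, -(1:2)], tolerance = 1e-12)
})

test_that("subniche projections are isometric at full rank", {
  inst <- random_instance(151, p = 4, N = 2, S = 4)
  fit <- fit_omi(inst$env, inst$abund, n_axes = 4)
  sub <- fit_subniche(fit, inst$partition)
  pr <- project_subniches(sub, n_axes = 4)
  sums <- pr |>
    dplyr::summarise(g = sum(coord_g^2), gk = sum(coord_gk^2),
                     .by = c(species, subset))
  tab <- dplyr::filter(subniche_params(sub), present)
  joined <- dplyr::inner_join(tab, sums, by = c("species", "subset"))
  expect_lt(max(abs(joined$witomi_g - joined$g)), 1e-10)
  expect_lt(max(abs(joined$witomi_gk - joined$gk)), 1e-10)
  # projected barycenter: niche coords = sum_K share * subniche coords
  fullc <- fit$marginality %*% fit$eigenvectors
  shares <- dplyr::filter(sub$table, present)
  for (sp in unique(shares$species)) {
    rows <- dplyr::inner_join(dplyr::filter(shares, species == sp),
                              dplyr::filter(pr, species == sp),
                              by = c("species", "subset"))
    rb <- rows |>
      dplyr::summarise(v = sum(occ_share * coord_g), .by = axis)
    expect_equal(rb$v, unname(fullc[sp, ]), tolerance = 1e-10)
  }
  expect_error(project_subniches(sub, n_axes = 9), "axes")
})
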