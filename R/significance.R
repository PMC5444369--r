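# Monte-Carlo permutation tests. All tests share the (b + 1) / (N + 1)
# p-value rule and derive per-(statistic, ids) RNG substreams from one master
# seed, so adding a species or subset never changes another one's p-value.

perm_pvalue <- function(observed, null_values) {
  (sum(null_values >= observed - 1e-14) + 1) / (length(null_values) + 1)
}

#' Permutation test of subset habitat conditions
#'
#' Tests, for each subset K, whether its centroid G_K differs from the
#' overall mean habitat condition G (the origin). The statistic is
#' `||G_K||^2`. Under the null of equiprobable row permutations of the
#' standardized table Z0, whole rows are shuffled (keeping inter-variable
#' correlation) and the statistic recomputed.
#'
#' @param sub A `subniche` object (or an `omi` fit plus `partition`).
#' @param partition Required when `sub` is an `omi` fit.
#' @param n_perm Number of permutations (>= 99; default 1000).
#' @param seed Integer master seed.
#' @param keep_null Keep the null distributions as a list-column (default
#'   TRUE; needed by [test_subniche_means()]).
#' @return A tibble: subset, statistic, observed, p_value, n_perm, seed, and
#'   (optionally) `null` list-column.
#' @export
test_subset_conditions <- function(sub, partition = NULL, n_perm = 1000L,
                                   seed = NULL, keep_null = TRUE) {
  if (inherits(sub, "omi")) sub <- fit_subniche(sub, partition)
  stopifnot(inherits(sub, "subniche"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 99L) abort("`n_perm` must be at least 99.")
  seed <- check_seed(seed)
  z0 <- sub$fit$z0
  n <- nrow(z0)
  out <- purrr::map_dfr(sub$subsets, function(K) {
    idx <- which(sub$labels == K)
    k <- length(idx)
    observed <- sum(sub$gk[K, ]^2)
    null_values <- withr_seed(seed_stream(seed, "subset_conditions", K), {
      vapply(seq_len(n_perm), function(b) {
        rows <- sample.int(n)[idx]
        sum(colMeans(z0[rows, , drop = FALSE])^2)
      }, numeric(1))
    })
    tibble(subset = K, statistic = "GK_dist2", observed = observed,
           p_value = perm_pvalue(observed, null_values),
           n_perm = n_perm, seed = seed,
           null = if (keep_null) list(null_values) else list(NULL))
  })
  if (!keep_null) out$null <- NULL
  out
}

# Null WitOMI statistics for one (species, subset) pair: permute the species'
# within-subset frequency vector over the k sites of K. `ref` is z0 (G frame)
# or z* (G_K frame) restricted to K. Exhaustive enumeration replaces Monte
# Carlo when k! <= n_perm.
witomi_null <- function(v, ref, n_perm, stream_seed) {
  k <- length(v)
  if (factorial(k) <= n_perm) {
    P <- all_permutations(k)
    stats <- rowSums((matrix(v[P], nrow(P), k) %*% ref)^2)
    list(null = stats, n_perm = nrow(P), exhaustive = TRUE)
  } else {
    stats <- withr_seed(stream_seed, {
      vapply(seq_len(n_perm), function(b) {
        sum((as.vector(v[sample.int(k)] %*% ref))^2)
      }, numeric(1))
    })
    list(null = stats, n_perm = n_perm, exhaustive = FALSE)
  }
}

#' Permutation tests of subniche marginality (WitOMI)
#'
#' For each present (species, subset) pair, tests the subniche marginality by
#' permuting the species' within-subset frequency profile Fr_K across the k
#' sites of the subset:
#' * statistic `"witomi_g"` — null: the species within the subset is
#'   uninfluenced by the overall average habitat conditions (ubiquitous);
#' * statistic `"witomi_gk"` — null: uninfluenced by the subset habitat
#'   conditions.
#'
#' When `k! <= n_perm` the permutation group is enumerated exhaustively and
#' the effective `n_perm` becomes `k!`; otherwise permutations are sampled.
#'
#' @param sub A `subniche` object.
#' @param which `"both"` (default), `"G"` or `"GK"`.
#' @param n_perm Number of permutations (>= 99; default 1000).
#' @param seed Integer master seed.
#' @param keep_null Keep null distributions as a list-column.
#' @return A tibble: species, subset, statistic, observed, p_value, n_perm,
#'   exhaustive, seed (+ `null` list-column). Absent pairs are omitted.
#' @export
test_subniche <- function(sub, which = c("both", "G", "GK"), n_perm = 1000L,
                          seed = NULL, keep_null = TRUE) {
  stopifnot(inherits(sub, "subniche"))
  which <- match.arg(which)
  stats <- switch(which, both = c("witomi_g", "witomi_gk"),
                  G = "witomi_g", GK = "witomi_gk")
  n_perm <- as.integer(n_perm)
  if (n_perm < 99L) abort("`n_perm` must be at least 99.")
  seed <- check_seed(seed)

  fit <- sub$fit
  tab <- dplyr::filter(sub$table, .data$present)
  out <- purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    sp <- tab$species[i]; K <- tab$subset[i]
    idx <- which(sub$labels == K)
    cK <- fit$counts[idx, sp]
    v <- cK / sum(cK)
    purrr::map_dfr(stats, function(st) {
      ref <- if (st == "witomi_g") {
        fit$z0[idx, , drop = FALSE]
      } else {
        sweep(fit$z0[idx, , drop = FALSE], 2L, sub$gk[K, ])
      }
      observed <- sum((as.vector(v %*% ref))^2)
      nl <- witomi_null(v, ref, n_perm, seed_stream(seed, st, sp, K))
      tibble(species = sp, subset = K, statistic = st, observed = observed,
             p_value = perm_pvalue(observed, nl$null),
             n_perm = nl$n_perm, exhaustive = nl$exhaustive, seed = seed,
             null = if (keep_null) list(nl$null) else list(NULL))
    })
  })
  if (!keep_null) out$null <- NULL
  out
}

#' Species-level test: mean marginality over subsets
#'
#' Combines per-subset WitOMI permutation results into one test per species
#' and statistic: the observed value is the mean of the per-subset observed
#' marginalities, and the null distribution is the per-iteration mean of the
#' per-subset null values, paired by permutation index (independent streams
#' per subset). When subsets differ in effective permutation count (e.g. one
#' was enumerated exhaustively), shorter null streams are recycled
#' cyclically.
#'
#' @param pair_results Output of [test_subniche()] with `keep_null = TRUE`.
#' @return A tibble: species, statistic, observed (mean over subsets),
#'   p_value, n_perm (pairing length), n_subsets, seed.
#' @export
test_subniche_means <- function(pair_results) {
  if (!"null" %in% names(pair_results)) {
    abort("`pair_results` must keep null distributions (keep_null = TRUE).")
  }
  pair_results |>
    dplyr::group_by(.data$species, .data$statistic) |>
    dplyr::group_modify(function(d, key) {
      observed <- mean(d$observed)
      N <- max(d$n_perm)
      null_mean <- rowMeans(vapply(d$null, function(nv) {
        nv[((seq_len(N) - 1L) %% length(nv)) + 1L]
      }, numeric(N)))
      tibble(observed = observed,
             p_value = perm_pvalue(observed, null_mean),
             n_perm = N, n_subsets = nrow(d), seed = d$seed[1])
    }) |>
    dplyr::ungroup()
}

#' Gather all permutation tests into one tidy table
#'
#' Runs the subset-conditions test, both WitOMI pair tests and the
#' species-mean combination, and stacks them in a single long table, the
#' shape written out by [run_pipeline()].
#'
#' @param sub A `subniche` object.
#' @param n_perm,seed Passed to the individual tests.
#' @param adjust_p Add a Benjamini-Hochberg adjusted `p_adj` column
#'   (within each level x statistic group). Raw p-values are always kept.
#' @return A tibble: level (`subset` | `pair` | `species_mean`), subset,
#'   species, statistic, observed, p_value, (p_adj), n_perm, seed.
#' @export
run_tests <- function(sub, n_perm = 1000L, seed = NULL, adjust_p = FALSE) {
  seed <- check_seed(seed)
  ts <- test_subset_conditions(sub, n_perm = n_perm, seed = seed, keep_null = FALSE)
  tp <- test_subniche(sub, n_perm = n_perm, seed = seed, keep_null = TRUE)
  tm <- test_subniche_means(tp)
  out <- dplyr::bind_rows(
    dplyr::mutate(ts, level = "subset", species = NA_character_),
    tp |> dplyr::select(-"null", -"exhaustive") |> dplyr::mutate(level = "pair"),
    dplyr::mutate(tm, level = "species_mean", subset = NA_character_)
  ) |>
    dplyr::select("level", "subset", "species", "statistic", "observed",
                  "p_value", "n_perm", "seed", dplyr::any_of("n_subsets"))
  if (adjust_p) {
    out <- out |>
      dplyr::group_by(.data$level, .data$statistic) |>
      dplyr::mutate(p_adj = p.adjust(.data$p_value, method = "BH")) |>
      dplyr::ungroup()
  }
  out
}
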