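# Internal helpers shared across modules.

# First column of a user table is taken as the id column unless named `site`
# (or `species` for wide species tables). Returns the id column name.
id_col_name <- function(df, default = "site") {
  nm <- names(df)
  if (default %in% nm) default else nm[[1L]]
}

# Wide tibble (id column + numeric columns) -> numeric matrix with rownames.
df_to_matrix <- function(df, id_col = NULL, what = "table") {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame (got %s).", what, class(df)[1]))
  }
  id_col <- id_col %||% id_col_name(df)
  if (!id_col %in% names(df)) {
    abort(sprintf("Column '%s' not found in %s.", id_col, what))
  }
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicated ids in %s: %s", what,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  num <- df[setdiff(names(df), id_col)]
  bad <- names(num)[!vapply(num, is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("Non-numeric columns in %s: %s", what,
                  paste(bad, collapse = ", ")))
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  m
}

matrix_to_df <- function(m, id_col = "site") {
  out <- as_tibble(m)
  out <- tibble::add_column(out, !!id_col := rownames(m), .before = 1)
  out
}

# Stable 32-bit string hash so permutation substreams depend only on ids,
# never on the order species/subsets are processed in.
hash_id <- function(...) {
  s <- paste(c(...), collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Derive a per-(statistic, ids) seed from the master seed.
seed_stream <- function(seed, ...) {
  as.integer((as.numeric(seed) + hash_id(...)) %% 2147483629)
}

check_seed <- function(seed) {
  if (is.null(seed)) return(sample.int(2147483629L, 1L))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != as.integer(seed)) {
    abort("`seed` must be a single integer.")
  }
  as.integer(seed)
}

# All permutations of 1..k (k small; used only when k! <= n_perm).
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow = factorial(k), ncol = k)
  r <- 0L
  for (pos in seq_len(k)) {
    for (i in seq_len(nrow(sub))) {
      out[r + i, ] <- append(sub[i, ], k, after = pos - 1L)
    }
    r <- r + nrow(sub)
  }
  out
}
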