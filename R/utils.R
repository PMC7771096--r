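# Internal validation helpers and seeded-RNG plumbing shared across modules.

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}

assert_count <- function(x, name, min = 1L) {
  assert_that(
    is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min,
    sprintf("`%s` must be a single integer >= %d", name, min)
  )
  as.integer(x)
}

assert_fraction <- function(x, name) {
  assert_that(
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1,
    sprintf("`%s` must be a fraction in [0, 1]", name)
  )
  as.numeric(x)
}

# Evaluate `expr` under a deterministic RNG stream without disturbing the
# caller's RNG state. `offset` derives independent sub-streams from one seed.
with_seed <- function(seed, expr, offset = 0L) {
  seed <- as.integer(seed)
  sub <- (abs(seed) + 104729L * as.integer(offset)) %% .Machine$integer.max
  withr::with_seed(sub, expr)
}

# Canonical 1-based index of unordered pair (i, j), i < j, among all C(n, 2)
# pairs in lexicographic order. Used for fast edge-set overlap arithmetic.
pair_index <- function(i, j, n) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  (lo - 1) * n - lo * (lo - 1) / 2 + (hi - lo)
}

# Unordered edge key for character gene ids.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
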