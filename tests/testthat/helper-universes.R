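# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

tiny_spec <- function(...) {
  synthetic_spec(n_targets = 2, n_activating = 15, n_binding = 10,
                 n_inactive = 120, ...)
}

# A small, well-separated two-target universe (cached; treat as read-only).
tiny_universe <- function(seed = 3) {
  key <- paste0("u", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_universe(tiny_spec(), seed = seed)
  }
  .fixture_cache[[key]]
}

# Random short bit vectors for similarity tests.
rand_fp <- function(n, n_bits = 64, density = 0.3, seed = 1, prefix = "x") {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n * n_bits, 1, density), n, n_bits)
    dimnames(m) <- list(paste0(prefix, seq_len(n)), paste0("b", seq_len(n_bits)))
    storage.mode(m) <- "integer"
    m
  })
}

# Build a universe directly from explicit per-role fingerprint matrices.
manual_universe <- function(sets, protein_class = "GPCR", target_id = "T01") {
  memb <- list(); fps <- list()
  for (role in names(sets)) {
    m <- sets[[role]]
    memb[[role]] <- tibble::tibble(target_id = target_id,
                                   compound_id = rownames(m), role = role)
    fps[[role]] <- m
  }
  moa_universe(
    tibble::tibble(target_id = target_id, protein_class = protein_class),
    dplyr::bind_rows(memb), do.call(rbind, fps)
  )
}

# Stratified 80/20 split of a universe's membership, preserving roles.
split_universe <- function(universe, seed = 1, test_frac = 0.2) {
  memb <- universe$membership
  fold <- stratified_kfold_split(paste(memb$target_id, memb$role),
                                 k = round(1 / test_frac), seed = seed)
  train <- moa_universe(universe$targets, memb[fold != 1, , drop = FALSE],
                        universe$fp, truth = universe$truth)
  list(train = train, test = memb[fold == 1, , drop = FALSE])
}
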