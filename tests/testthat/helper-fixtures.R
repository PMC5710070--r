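# shared helpers: small pedigrees, toy record tables and design systems

# random valid pedigree: founders then offspring with random earlier parents
random_pedigree <- function(n, n_founders = 10L, seed = 1L) {
  set.seed(seed)
  sire <- dam <- integer(n)
  for (i in (n_founders + 1L):n) {
    sire[i] <- sample.int(i - 1L, 1L)
    dam[i] <- sample.int(i - 1L, 1L)
    if (dam[i] == sire[i]) dam[i] <- 0L
  }
  pedigree_table(seq_len(n), sire, dam)
}

# independent tabular-method oracle (plain double loop, no shared code path
# with relationship_matrix's vectorized recursion)
tabular_oracle <- function(animal, sire, dam) {
  n <- length(animal)
  si <- match(sire, animal); di <- match(dam, animal)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      v <- 0
      if (!is.na(si[i])) v <- v + 0.5 * A[si[i], j]
      if (!is.na(di[i])) v <- v + 0.5 * A[di[i], j]
      A[i, j] <- A[j, i] <- v
    }
    A[i, i] <- 1 + if (!is.na(si[i]) && !is.na(di[i]))
      0.5 * A[si[i], di[i]] else 0
  }
  A
}

# weekly records from independent animals with zero covariates
toy_records <- function(n_animals, n_rec = 1L, y, pens = 4L) {
  data.frame(animal = rep(seq_len(n_animals), each = n_rec),
             pen = rep_len(seq_len(pens), n_animals * n_rec),
             fi = y, mw = 0, wg = 0, fg = 0)
}

# small weekly dataset + model-8 design system used across inference tests
small_model8_system <- function(seed = 42L, n_sires = 6L) {
  cfg <- fixture_config(n_batches = 1L, n_sires = n_sires, dams_per_sire = 3L,
                        offspring_per_litter = 4L, seed = seed)
  ds <- simulate_weekly_dataset(cfg)
  list(ds = ds,
       system = build_design_system(ds$records, model_spec(8),
                                    pedigree = ds$pedigree))
}
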