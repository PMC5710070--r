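# Observational-study-style fixtures with known truth: a litter-structured
# pedigree, weekly latent covariates with the pen/genetic/permanent/residual
# covariance structure of the real standardized traits, feed intake from the
# full animal-specific allocation model with week-varying fixed regressions,
# and (optionally) disaggregated daily intake plus weight/backfat measurement
# events that the preparation pipeline can turn back into weekly records.

# week-level raw-scale means and sds used to de-standardize the latent
# covariates into plausible raw units (metabolic weight kg^0.75, gains kg/d
# and mm/d, feed intake g/d), patterned on the descriptive statistics of the
# real data at 15-25 weeks of age
default_cov_scale <- function(weeks) {
  i <- weeks - 14L
  list(
    fi_mean = c(2220, 2390, 2510, 2690, 2850, 2910, 2980, 3030, 3100,
                3040, 3070)[i],
    mw = list(mean = c(19.85, 21.47, 23.06, 24.62, 26.17, 27.71, 29.21,
                       30.80, 32.35, 33.87, 35.55)[i],
              sd = c(1.97, 2.05, 2.12, 2.20, 2.26, 2.32, 2.38, 2.42, 2.53,
                     2.59, 2.46)[i]),
    wg = list(mean = c(0.85, 0.84, 0.85, 0.87, 0.87, 0.88, 0.89, 0.90, 0.89,
                       0.89, 0.91)[i],
              sd = c(0.12, 0.12, 0.12, 0.13, 0.13, 0.14, 0.14, 0.15, 0.15,
                     0.15, 0.15)[i]),
    fg = list(mean = c(0.13, 0.13, 0.13, 0.14, 0.14, 0.15, 0.16, 0.16, 0.17,
                       0.17, 0.18)[i],
              sd = c(0.07, 0.07, 0.07, 0.07, 0.07, 0.07, 0.08, 0.08, 0.08,
                     0.09, 0.09)[i])
  )
}

# week-varying fixed regressions (g/d per sd unit), posterior means of the
# real-data analysis at 15-25 weeks
default_beta_week <- function(weeks) {
  tab <- cbind(mw = c(295, 286, 284, 266, 272, 220, 210, 205, 192, 193, 157),
               wg = c(13, 2, 8, 13, 49, 57, 96, 101, 102, 120, 146),
               fg = c(16, 36, 24, 37, 24, 37, 38, 24, 56, 23, 49))
  tab[weeks - 14L, , drop = FALSE]
}

#' Fixture configuration for the synthetic-data generator
#'
#' The default scale (2 batches of 8 sires x 4 dams x 5 offspring = 320
#' phenotyped animals, weeks 15-25) keeps a full preparation + fitting run
#' fast while retaining the family structure the variance components need.
#'
#' @param n_batches number of batches (independent founder sets).
#' @param n_sires,dams_per_sire,offspring_per_litter family structure per
#'   batch.
#' @param pen_size animals per pen.
#' @param weeks age-week range (within 15-25).
#' @param missing_frac fraction of daily intake records knocked out.
#' @param events measurement events per animal: `"boundaries"` places an
#'   event on the first and last day of every week (weekly covariates are
#'   then recovered exactly by the preparation pipeline), or an integer 4-11
#'   of randomly placed events (recovery is then approximate, as with real
#'   sparse weighings).
#' @param components true feed-intake variance components (defaults to
#'   [reconstruct_model8_components()]).
#' @param covariate_params a [covariate_trait_params()] list.
#' @param beta_week weeks x 3 matrix of fixed regressions (g/d per sd).
#' @param batch_sd sd of batch-level feed-intake shifts, g/d.
#' @param daily_noise_sd sd of the within-week daily intake noise, g/d.
#' @param phenotype_founders logical; give the founder parents weekly records
#'   too (parent-offspring information then helps separate additive from
#'   permanent variance in recovery studies).
#' @param seed integer seed.
#' @return list of class `"fixture_config"`.
#' @export
fixture_config <- function(n_batches = 2L, n_sires = 8L, dams_per_sire = 4L,
                           offspring_per_litter = 5L, pen_size = 10L,
                           weeks = 15:25, missing_frac = 0.05,
                           events = "boundaries",
                           components = reconstruct_model8_components(),
                           covariate_params = covariate_trait_params(),
                           beta_week = NULL, batch_sd = 100,
                           daily_noise_sd = 50, phenotype_founders = FALSE,
                           seed = 1L) {
  stopifnot(all(weeks >= 15L & weeks <= 25L), missing_frac >= 0,
            missing_frac < 1)
  if (is.null(beta_week)) beta_week <- default_beta_week(weeks)
  structure(as.list(environment()), class = "fixture_config")
}

#' Simulate a weekly-record dataset with known truth
#'
#' Generates the pedigree, pen/batch layout, weekly standardized covariates
#' (pen + additive + permanent + weekly residual, per the covariate-trait
#' covariances) and feed intake from the full animal-specific allocation
#' model (batch-week means, week-varying fixed regressions, batch-week random
#' regressions, pen, correlated animal intercepts and slopes, residual).
#'
#' @param config a [fixture_config()].
#' @return list of class `"weekly_dataset"`: `records` (weekly record table
#'   with standardized covariates `mw`,`wg`,`fg` and raw-scale `*_raw`
#'   columns), `pedigree` (a [pedigree_table()]), `truth` (all latent effects
#'   and the generating parameters).
#' @export
simulate_weekly_dataset <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  vc <- config$components
  cp <- config$covariate_params
  weeks <- config$weeks
  nw <- length(weeks)
  scale <- default_cov_scale(weeks)

  ped <- list(); eff <- list()
  id <- 0L
  rows <- list()
  gamma <- list()
  for (b in seq_len(config$n_batches)) {
    sires <- id + seq_len(config$n_sires); id <- id + config$n_sires
    dams <- id + seq_len(config$n_sires * config$dams_per_sire)
    id <- id + length(dams)
    ped[[length(ped) + 1L]] <- data.frame(
      animal = c(sires, dams), sire = 0L, dam = 0L, batch = b,
      phenotyped = isTRUE(config$phenotype_founders))
    n_off <- length(dams) * config$offspring_per_litter
    off <- id + seq_len(n_off); id <- id + n_off
    ped[[length(ped) + 1L]] <- data.frame(
      animal = off,
      sire = rep(rep(sires, each = config$dams_per_sire),
                 each = config$offspring_per_litter),
      dam = rep(dams, each = config$offspring_per_litter),
      batch = b, phenotyped = TRUE)
  }
  ped <- do.call(rbind, ped)
  n <- nrow(ped)
  founder <- ped$sire == 0L
  a_fi <- matrix(0, n, 4); a_cov <- matrix(0, n, 3)
  a_fi[founder, ] <- rmvn(sum(founder), vc$G0)
  a_cov[founder, ] <- rmvn(sum(founder), cp$G_t)
  si <- match(ped$sire, ped$animal); di <- match(ped$dam, ped$animal)
  for (i in which(!founder)) {
    a_fi[i, ] <- 0.5 * (a_fi[si[i], ] + a_fi[di[i], ]) +
      rmvn(1L, 0.5 * vc$G0)
    a_cov[i, ] <- 0.5 * (a_cov[si[i], ] + a_cov[di[i], ]) +
      rmvn(1L, 0.5 * cp$G_t)
  }
  phen <- which(ped$phenotyped)
  p_fi <- matrix(0, n, 4); p_cov <- matrix(0, n, 3)
  p_fi[phen, ] <- rmvn(length(phen), vc$P0)
  p_cov[phen, ] <- rmvn(length(phen), cp$P_t)

  # pens within batch
  pen_of <- integer(n); pen_id <- 0L
  for (b in seq_len(config$n_batches)) {
    ib <- phen[ped$batch[phen] == b]
    n_pens <- ceiling(length(ib) / config$pen_size)
    pen_of[ib] <- pen_id + sample(rep(seq_len(n_pens), length.out = length(ib)))
    pen_id <- pen_id + n_pens
  }
  pen_fi <- stats::rnorm(pen_id, 0, sqrt(vc$var_pen))
  pen_cov <- rmvn(pen_id, cp$B_t)

  batch_shift <- stats::rnorm(config$n_batches, 0, config$batch_sd)
  # batch-week random regressions, one level per batch x week x covariate
  gamma <- array(0, c(config$n_batches, nw, 3))
  for (c3 in 1:3)
    gamma[, , c3] <- stats::rnorm(config$n_batches * nw, 0,
                                  sqrt(vc$var_gamma[c(1, 2, 3)[c3]]))

  n_ph <- length(phen)
  covs <- matrix(0, n_ph * nw, 3)
  for (jj in seq_len(n_ph)) {
    i <- phen[jj]
    covs[(jj - 1L) * nw + seq_len(nw), ] <- generate_covariate_traits(
      a_cov[i, ], p_cov[i, ], pen_cov[pen_of[i], ], nw, cp)
  }
  wk <- rep(seq_len(nw), n_ph)
  bt <- rep(ped$batch[phen], each = nw)
  gam_val <- cbind(gamma[cbind(bt, wk, 1L)], gamma[cbind(bt, wk, 2L)],
                   gamma[cbind(bt, wk, 3L)])
  idx <- rep(seq_len(n_ph), each = nw)
  fi <- scale$fi_mean[wk] + batch_shift[bt] +
    rowSums(covs * config$beta_week[wk, , drop = FALSE]) +
    rowSums(covs * gam_val) +
    pen_fi[pen_of[phen]][idx] +
    a_fi[phen, 1L][idx] + rowSums(covs * a_fi[phen, 2:4, drop = FALSE][idx, ]) +
    p_fi[phen, 1L][idx] + rowSums(covs * p_fi[phen, 2:4, drop = FALSE][idx, ]) +
    stats::rnorm(n_ph * nw, 0, sqrt(vc$var_e))
  records <- data.frame(
    animal = ped$animal[phen][idx], batch = bt, pen = pen_of[phen][idx],
    week = weeks[wk], fi = fi,
    mw = covs[, 1L], wg = covs[, 2L], fg = covs[, 3L],
    mw_raw = scale$mw$mean[wk] + scale$mw$sd[wk] * covs[, 1L],
    wg_raw = scale$wg$mean[wk] + scale$wg$sd[wk] * covs[, 2L],
    fg_raw = scale$fg$mean[wk] + scale$fg$sd[wk] * covs[, 3L],
    stringsAsFactors = FALSE)
  pedtab <- pedigree_table(ped$animal, ped$sire, ped$dam)
  structure(list(
    records = records, pedigree = pedtab,
    truth = list(components = vc, covariate_params = cp,
                 beta_week = config$beta_week, batch_shift = batch_shift,
                 gamma = gamma, a_fi = a_fi, p_fi = p_fi, a_cov = a_cov,
                 p_cov = p_cov, pen_fi = pen_fi, pen_cov = pen_cov,
                 phenotyped = ped$animal[phen], scale = scale,
                 seed = config$seed),
    config = config), class = "weekly_dataset")
}

#' Disaggregate a weekly dataset into raw observational input files
#'
#' Produces the raw tables the preparation pipeline consumes: daily feed
#' intake (weekly mean plus zero-sum daily noise, with a fraction of days
#' knocked out as missing), weight/backfat measurement events on a per-week
#' linear schedule consistent with the weekly raw covariates (weight
#' midpoints pinned to `mw_raw^(4/3)`, endpoint differences pinned to
#' `7 * wg_raw` and `7 * fg_raw`), and the batch/pen assignment table.
#'
#' @param config a [fixture_config()].
#' @return list of class `"observational_dataset"`: `daily`, `events`,
#'   `assignments`, `weekly` (the underlying [simulate_weekly_dataset()]
#'   result), `truth`.
#' @export
generate_observational_dataset <- function(config) {
  ds <- simulate_weekly_dataset(config)
  rec <- ds$records
  nw <- nrow(rec)
  # daily intake: 7 days per animal-week, noise summing to zero within week
  age0 <- 7L * rec$week
  noise <- matrix(stats::rnorm(nw * 7L, 0, config$daily_noise_sd), nw)
  noise <- noise - rowMeans(noise)
  daily <- data.frame(
    animal = rep(rec$animal, each = 7L),
    age = as.integer(t(outer(age0, 0:6, "+"))),
    intake = as.numeric(t(rec$fi + noise)))
  if (config$missing_frac > 0) {
    miss <- stats::runif(nrow(daily)) < config$missing_frac
    daily$intake[miss] <- NA_real_
  }
  # measurement events at weekly boundary days
  w_mid <- rec$mw_raw^(4 / 3)
  bf_gain <- 7 * rec$fg_raw
  ev <- list()
  for (an in unique(rec$animal)) {
    ra <- rec[rec$animal == an, , drop = FALSE]
    ra <- ra[order(ra$week), , drop = FALSE]
    mid <- ra$mw_raw^(4 / 3)
    bf_mid <- 10 + cumsum(7 * ra$fg_raw) - 3.5 * ra$fg_raw
    e <- data.frame(
      animal = an,
      age = as.integer(c(7L * ra$week, 7L * ra$week + 6L)),
      weight = c(mid - 3.5 * ra$wg_raw, mid + 3.5 * ra$wg_raw),
      backfat = c(bf_mid - 3.5 * ra$fg_raw, bf_mid + 3.5 * ra$fg_raw))
    e <- e[order(e$age), , drop = FALSE]
    if (is.numeric(config$events)) {
      ne <- max(3L, min(nrow(e), as.integer(config$events)))
      keep <- sort(c(1L, nrow(e),
                     sample(2:(nrow(e) - 1L), ne - 2L)))
      e <- e[keep, , drop = FALSE]
    }
    ev[[length(ev) + 1L]] <- e
  }
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  assignments <- unique(rec[c("animal", "batch", "pen")])
  structure(list(daily = daily, events = events, assignments = assignments,
                 weekly = ds, truth = ds$truth, config = config),
            class = "observational_dataset")
}

#' Write fixture files to a directory
#'
#' Writes the delimited input tables (`pedigree.tsv`, `daily_intake.tsv`,
#' `measurements.tsv`, `assignments.tsv`), the underlying weekly records
#' (`weekly_records.tsv`) and a long parameter/value truth table
#' (`truth.tsv`). Output bytes are deterministic given the dataset.
#'
#' @param dataset an [generate_observational_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths.
#' @export
write_fixture_files <- function(dataset, dir) {
  stopifnot(inherits(dataset, "observational_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    df_fmt <- df
    for (j in seq_along(df_fmt))
      if (is.numeric(df_fmt[[j]]) && !is.integer(df_fmt[[j]]))
        df_fmt[[j]] <- formatC(df_fmt[[j]], format = "g", digits = 12)
    utils::write.table(df_fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  ped <- dataset$weekly$pedigree
  truth <- dataset$truth
  vc <- truth$components
  terms <- vc$terms
  truth_tab <- data.frame(
    parameter = c(paste0("G0_", outer(terms, terms, paste, sep = "_")),
                  paste0("P0_", outer(terms, terms, paste, sep = "_")),
                  paste0("var_gamma_", names(vc$var_gamma)),
                  "var_pen", "var_e", "seed"),
    value = c(as.vector(vc$G0), as.vector(vc$P0), as.numeric(vc$var_gamma),
              vc$var_pen, vc$var_e, truth$seed))
  paths <- c(
    wr(data.frame(animal = ped$animal, sire = ped$sire, dam = ped$dam),
       "pedigree.tsv"),
    wr(dataset$daily, "daily_intake.tsv"),
    wr(dataset$events, "measurements.tsv"),
    wr(dataset$assignments, "assignments.tsv"),
    wr(dataset$weekly$records, "weekly_records.tsv"),
    wr(truth_tab, "truth.tsv"))
  invisible(paths)
}
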