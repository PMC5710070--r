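test_that("animal trajectories reproduce polynomials exactly", {
  # constant series: only the order-0 coefficient is nonzero
  tr <- fit_animal_trajectory(c(100, 110, 120, 130), rep(7, 4))
  expect_equal(unname(tr$coef), c(7, 0, 0), tolerance = 1e-10)

  # quadratic data are in the span of the 3-coefficient basis
  age <- c(105, 115, 125, 140, 160)
  quad <- function(t) 2 + 0.3 * t - 0.001 * t^2
  tr2 <- fit_animal_trajectory(age, quad(age))
  expect_equal(predict_trajectory(tr2, age), quad(age), tolerance = 1e-8)
  # held-out age inside the range evaluates to the quadratic's value
  expect_equal(predict_trajectory(tr2, 133), quad(133), tolerance = 1e-8)

  expect_error(fit_animal_trajectory(c(1, 1, 2), c(5, 5, 6), animal = "A7"),
               "A7")
})

test_that("daily intake imputation fills only missing days, within range", {
  age <- 105:125
  quad <- function(t) 2000 + 30 * (t - 105) - 0.9 * (t - 105)^2
  daily <- data.frame(animal = 1L, age = age, intake = quad(age))
  expect_identical(impute_daily_intake(daily), daily)

  holey <- daily
  holey$intake[c(5, 12)] <- NA
  out <- impute_daily_intake(holey)
  expect_equal(out$intake[c(5, 12)], quad(age[c(5, 12)]), tolerance = 1e-6)
  expect_identical(out$intake[-c(5, 12)], daily$intake[-c(5, 12)])

  # boundary day: imputed from the trajectory at that age, no extrapolation
  edge <- daily
  edge$intake[1L] <- NA
  out2 <- impute_daily_intake(edge)
  tr <- fit_animal_trajectory(age[-1L], quad(age)[-1L])
  expect_equal(out2$intake[1L], predict_trajectory(tr, age[1L]))

  all_na <- data.frame(animal = 2L, age = age, intake = NA_real_)
  expect_warning(res <- impute_daily_intake(rbind(daily, all_na)),
                 "no observed")
  expect_false(2L %in% res$animal)
})

test_that("weight/backfat interpolation hits weekly endpoints", {
  age <- seq(100, 180, by = 8)
  lin_w <- 30 + 0.8 * age
  quad_b <- 5 + 0.05 * age + 4e-4 * age^2
  ev <- data.frame(animal = 1L, age = age, weight = lin_w, backfat = quad_b)
  out <- interpolate_weight_backfat(ev, weeks = 15:25)
  expect_equal(out$weight_start, 30 + 0.8 * (7 * out$week), tolerance = 1e-6)
  expect_equal(out$backfat_end,
               5 + 0.05 * (7 * out$week + 6) + 4e-4 * (7 * out$week + 6)^2,
               tolerance = 1e-6)
  # weeks outside the measured range are not emitted
  expect_true(all(7 * out$week >= 100 & 7 * out$week + 6 <= 180))
  expect_false(25 %in% out$week)  # day 181 is beyond the last event at 180
})

test_that("weekly covariates follow their definitions", {
  daily <- data.frame(animal = 1L, age = 105:111, intake = rep(2500, 7))
  endpoints <- data.frame(animal = 1L, week = 15L,
                          weight_start = 81 - 1.75, weight_end = 81 + 1.75,
                          backfat_start = 10, backfat_end = 10.7)
  asg <- data.frame(animal = 1L, batch = 1L, pen = 1L)
  rec <- derive_weekly_covariates(daily, endpoints, asg)
  expect_equal(rec$mw_raw, 81^0.75)  # mean weight 81 kg -> 27 kg^0.75
  expect_equal(rec$mw_raw, 27)
  expect_equal(rec$wg_raw, 0.5)     # 3.5 kg over the week
  expect_equal(rec$fg_raw, 0.1)
  expect_equal(rec$fi, 2500)
})

test_that("within-cell standardization is exact and invertible", {
  rec <- data.frame(animal = 1:6, batch = rep(1:2, each = 3),
                    pen = 1, week = 15L, fi = 2500,
                    mw_raw = c(1, 2, 3, 4, 6, 8),
                    wg_raw = c(0.5, 0.7, 0.9, 1, 1, 1.3),
                    fg_raw = c(0.1, 0.2, 0.3, 0.15, 0.25, 0.35))
  out <- standardize_within_cell(rec)
  expect_equal(out$mw[1:3], c(-1, 0, 1))
  for (v in c("mw", "wg", "fg")) {
    m <- as.numeric(tapply(out[[v]], out$batch, mean))
    s <- as.numeric(tapply(out[[v]], out$batch, sd))
    expect_equal(m, c(0, 0), tolerance = 1e-10)
    expect_equal(s, c(1, 1), tolerance = 1e-10)
  }
  # round trip via the stored cell statistics
  cs <- attr(out, "cell_stats")$mw
  cell <- paste(out$week, out$batch, sep = ".")
  back <- out$mw * cs$sd[match(cell, cs$cell)] +
    cs$mean[match(cell, cs$cell)]
  expect_equal(back, rec$mw_raw, tolerance = 1e-10)

  const <- rec; const$wg_raw <- 1
  expect_error(standardize_within_cell(const), "zero within-cell sd")
  expect_error(standardize_within_cell(rec[c(1, 4), ]), "fewer than 2")
})

test_that("filters drop out-of-window weeks and small pens", {
  rec <- expand.grid(animal = 1:20, week = 14:26)
  rec$pen <- ifelse(rec$animal <= 8, "small7", "big12")
  rec$pen[rec$animal > 8 & rec$animal <= 12] <- "small4"
  rec$pen[rec$animal > 12] <- "big8"
  rec$fi <- 2500
  out <- apply_filters(rec, min_group = 8L)
  expect_true(all(out$week >= 15 & out$week <= 25))
  # pen of 8 kept ("seven or more pen mates"), pens of 7 and 4 dropped
  expect_setequal(unique(out$pen), c("small7", "big8"))
  expect_false(any(out$pen == "small4"))
  log <- attr(out, "filter_log")
  expect_equal(unname(log["removed_week"]), 20 * 2)

  # identity on clean input
  clean <- rec[rec$week %in% 15:25 & rec$pen %in% c("small7", "big8"), ]
  out2 <- apply_filters(clean, min_group = 8L)
  expect_equal(nrow(out2), nrow(clean))
  expect_warning(apply_filters(clean[clean$week == 30, ]), "all records")
})

test_that("preparation pipeline recovers the generator's weekly records", {
  cfg <- fixture_config(n_batches = 1L, n_sires = 4L, dams_per_sire = 3L,
                        offspring_per_litter = 4L, pen_size = 8L,
                        missing_frac = 0, seed = 31L)
  obs <- generate_observational_dataset(cfg)
  weekly <- prep_weekly(obs$daily, obs$events, obs$assignments)
  truth <- obs$weekly$records
  key <- paste(weekly$animal, weekly$week)
  tkey <- paste(truth$animal, truth$week)
  expect_setequal(key, tkey)
  m <- match(key, tkey)
  # zero missing days: weekly feed intake is recovered exactly
  expect_equal(weekly$fi, truth$fi[m], tolerance = 1e-9)
  # events on week boundaries: raw covariates are recovered exactly, and the
  # standardized ones match re-standardizing the generator's latents
  expect_equal(weekly$mw_raw, truth$mw_raw[m], tolerance = 1e-9)
  cell <- paste(truth$week, truth$batch)[m]
  z <- truth$wg[m]
  zstd <- unlist(lapply(split(z, cell), scale))
  expect_equal(unlist(lapply(split(weekly$wg, cell), identity)),
               unname(zstd), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("preparation is idempotent on its weekly output", {
  cfg <- fixture_config(n_batches = 1L, n_sires = 4L, dams_per_sire = 3L,
                        offspring_per_litter = 4L, pen_size = 8L,
                        missing_frac = 0.1, seed = 8L)
  obs <- generate_observational_dataset(cfg)
  weekly <- prep_weekly(obs$daily, obs$events, obs$assignments)
  again <- standardize_within_cell(apply_filters(weekly))
  expect_equal(again$mw, weekly$mw, tolerance = 1e-10)
  expect_equal(nrow(again), nrow(weekly))
})
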