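#' Legendre polynomial basis on a rescaled age axis
#'
#' Ages are rescaled to the interval from -1 to 1 over `age_range` (by default each animal's own
#' observed range, since trajectory fits are animal-nested) and the Legendre
#' polynomials of order 0..(n_coef-1) are evaluated.
#'
#' @param age numeric ages (days).
#' @param n_coef number of coefficients (order n_coef - 1), default 3.
#' @param age_range numeric length-2; defaults to `range(age)`.
#' @return matrix with `n_coef` columns.
#' @export
legendre_basis <- function(age, n_coef = 3L, age_range = range(age)) {
  if (diff(age_range) <= 0) {
    x <- rep(0, length(age))
  } else {
    x <- 2 * (age - age_range[1L]) / diff(age_range) - 1
  }
  B <- matrix(0, length(age), n_coef)
  B[, 1L] <- 1
  if (n_coef >= 2L) B[, 2L] <- x
  if (n_coef >= 3L) B[, 3L] <- 0.5 * (3 * x^2 - 1)
  if (n_coef >= 4L) {
    for (r in 4:n_coef) {  # Bonnet recursion for higher orders
      nn <- r - 2L
      B[, r] <- ((2 * nn + 1) * x * B[, r - 1L] - nn * B[, r - 2L]) / (nn + 1)
    }
  }
  B
}

#' Fit an animal-nested growth trajectory
#'
#' Least-squares fit of a three-coefficient (order 0..2) Legendre polynomial
#' to one animal's (age, value) series, on the animal's own observed age range.
#'
#' @param age,value numeric vectors of observed ages and trait values.
#' @param n_coef number of Legendre coefficients (default 3).
#' @param animal id used in error messages.
#' @return object of class `"growth_trajectory"`: list with `coef`,
#'   `age_range`, `n_coef`. Evaluate with [predict_trajectory()].
#' @export
fit_animal_trajectory <- function(age, value, n_coef = 3L, animal = NULL) {
  ok <- !is.na(value) & !is.na(age)
  age <- age[ok]; value <- value[ok]
  if (length(unique(age)) < n_coef)
    stop("animal ", if (is.null(animal)) "" else animal,
         " has fewer than ", n_coef, " distinct measurement ages")
  rng <- range(age)
  B <- legendre_basis(age, n_coef, rng)
  coef <- stats::lm.fit(B, value)$coefficients
  coef[is.na(coef)] <- 0
  structure(list(coef = coef, age_range = rng, n_coef = n_coef),
            class = "growth_trajectory")
}

#' Evaluate a fitted growth trajectory
#'
#' @param object a [fit_animal_trajectory()] result.
#' @param age ages at which to evaluate; must lie within the fitted range
#'   (values outside return `NA`, no extrapolation).
#' @return numeric vector.
#' @export
predict_trajectory <- function(object, age) {
  stopifnot(inherits(object, "growth_trajectory"))
  out <- as.numeric(legendre_basis(age, object$n_coef, object$age_range) %*%
                      object$coef)
  out[age < object$age_range[1L] | age > object$age_range[2L]] <- NA_real_
  out
}

#' Impute missing daily feed intake from animal-nested trajectories
#'
#' Missing daily records are predicted by each animal's three-coefficient
#' Legendre trajectory fitted to its observed days; observed values are never
#' altered, and days outside the animal's observed age range are left missing
#' (no extrapolation).
#'
#' @param daily data.frame with columns `animal`, `age`, `intake` (`NA` =
#'   missing/invalid day).
#' @param n_coef Legendre coefficients for the trajectory fit.
#' @return `daily` with missing `intake` filled where imputable.
#' @export
impute_daily_intake <- function(daily, n_coef = 3L) {
  stopifnot(all(c("animal", "age", "intake") %in% names(daily)))
  out <- daily
  drop <- character(0)
  for (an in unique(daily$animal)) {
    idx <- which(daily$animal == an)
    obs <- !is.na(daily$intake[idx])
    if (!any(obs)) { drop <- c(drop, as.character(an)); next }
    if (all(obs)) next
    if (sum(obs) < n_coef) next  # too sparse to fit; leave missing
    tr <- fit_animal_trajectory(daily$age[idx][obs], daily$intake[idx][obs],
                                n_coef, animal = an)
    mi <- idx[!obs]
    out$intake[mi] <- predict_trajectory(tr, daily$age[mi])
  }
  if (length(drop))
    warning("excluded animals with no observed intake: ",
            paste(drop, collapse = ", "))
  out[!(as.character(out$animal) %in% drop), , drop = FALSE]
}

#' Interpolate body weight and backfat to weekly first/last days
#'
#' Fits animal-nested three-coefficient Legendre trajectories to the
#' measurement events and evaluates them at the first (`7w`) and last
#' (`7w + 6`) day of each age-week within the animal's measured range. When an
#' event falls exactly on a required day the measured value is used directly.
#'
#' @param events data.frame with columns `animal`, `age`, `weight`, `backfat`.
#' @param weeks integer vector of age-weeks to cover (default 15:25).
#' @return data.frame with columns `animal`, `week`, `weight_start`,
#'   `weight_end`, `backfat_start`, `backfat_end`; weeks not fully inside the
#'   measured range are omitted.
#' @export
interpolate_weight_backfat <- function(events, weeks = 15:25) {
  stopifnot(all(c("animal", "age", "weight", "backfat") %in% names(events)))
  res <- list()
  for (an in unique(events$animal)) {
    ev <- events[events$animal == an, , drop = FALSE]
    trW <- fit_animal_trajectory(ev$age, ev$weight, animal = an)
    trB <- fit_animal_trajectory(ev$age, ev$backfat, animal = an)
    for (w in weeks) {
      d0 <- 7L * w; d1 <- 7L * w + 6L
      if (d0 < trW$age_range[1L] || d1 > trW$age_range[2L]) next
      val <- function(tr, col, day) {
        hit <- which(ev$age == day)
        if (length(hit)) ev[[col]][hit[1L]] else predict_trajectory(tr, day)
      }
      res[[length(res) + 1L]] <- data.frame(
        animal = an, week = w,
        weight_start = val(trW, "weight", d0),
        weight_end = val(trW, "weight", d1),
        backfat_start = val(trB, "backfat", d0),
        backfat_end = val(trB, "backfat", d1),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res))
    return(data.frame(animal = character(0), week = integer(0),
                      weight_start = numeric(0), weight_end = numeric(0),
                      backfat_start = numeric(0), backfat_end = numeric(0)))
  do.call(rbind, res)
}

#' Derive weekly feed-intake records and raw covariates
#'
#' For each animal-week: `fi` is the mean of the week's daily intake (g/d),
#' `wg_raw = (weight_end - weight_start)/7` (kg/d), `fg_raw =
#' (backfat_end - backfat_start)/7` (mm/d), and `mw_raw` is the mean of the
#' weekly endpoint weights raised to the power 0.75 (kg^0.75, metabolic
#' weight as a maintenance proxy).
#'
#' @param daily completed daily intake (see [impute_daily_intake()]).
#' @param endpoints weekly endpoints from [interpolate_weight_backfat()].
#' @param assignments data.frame with columns `animal`, `batch`, `pen`.
#' @return data.frame of weekly records (one row per animal-week) with columns
#'   `animal`, `batch`, `pen`, `week`, `fi`, `mw_raw`, `wg_raw`, `fg_raw`.
#' @export
derive_weekly_covariates <- function(daily, endpoints, assignments) {
  stopifnot(all(c("animal", "batch", "pen") %in% names(assignments)))
  daily$week <- daily$age %/% 7L
  agg <- stats::aggregate(intake ~ animal + week, data = daily,
                          FUN = mean, na.rm = TRUE, na.action = NULL)
  names(agg)[names(agg) == "intake"] <- "fi"
  rec <- merge(endpoints, agg, by = c("animal", "week"))
  rec <- rec[!is.na(rec$fi) & !is.na(rec$weight_start) & !is.na(rec$weight_end) &
               !is.na(rec$backfat_start) & !is.na(rec$backfat_end), ]
  rec$mw_raw <- ((rec$weight_start + rec$weight_end) / 2)^0.75
  rec$wg_raw <- (rec$weight_end - rec$weight_start) / 7
  rec$fg_raw <- (rec$backfat_end - rec$backfat_start) / 7
  rec <- merge(rec, assignments[c("animal", "batch", "pen")], by = "animal")
  rec <- rec[order(rec$animal, rec$week),
             c("animal", "batch", "pen", "week", "fi",
               "mw_raw", "wg_raw", "fg_raw")]
  rownames(rec) <- NULL
  rec
}

#' Standardize covariates within week-by-batch cells
#'
#' Each of `mw_raw`, `wg_raw`, `fg_raw` is centred and scaled (sample sd,
#' divisor n-1) within its week x batch cell, producing the standardized
#' regression covariates `mw`, `wg`, `fg`. Cell means/sds are attached as the
#' `"cell_stats"` attribute so raw values can be recovered.
#'
#' @param records weekly records from [derive_weekly_covariates()].
#' @return `records` with columns `mw`, `wg`, `fg` added.
#' @export
standardize_within_cell <- function(records) {
  cell <- interaction(records$week, records$batch, drop = TRUE)
  stats_list <- list()
  for (v in c("mw", "wg", "fg")) {
    raw <- records[[paste0(v, "_raw")]]
    m <- tapply(raw, cell, mean)
    s <- tapply(raw, cell, stats::sd)
    nc <- tapply(raw, cell, length)
    if (any(nc < 2L))
      stop("cannot standardize: week x batch cell with fewer than 2 records (",
           names(nc)[which(nc < 2L)[1L]], ")")
    if (any(s == 0))
      stop("cannot standardize: zero within-cell sd for ", v, " in cell ",
           names(s)[which(s == 0)[1L]])
    records[[v]] <- as.numeric((raw - m[as.character(cell)]) /
                                 s[as.character(cell)])
    stats_list[[v]] <- data.frame(cell = names(m), mean = as.numeric(m),
                                  sd = as.numeric(s))
  }
  attr(records, "cell_stats") <- stats_list
  records
}

#' Filter weekly records by age window and pen group size
#'
#' Keeps records with `week` inside `weeks` (default 15-25) from animals housed
#' in pens whose group size is at least `min_group` animals ("seven or more
#' pen mates" read as the animal plus at least seven others, i.e. groups of 8+).
#'
#' @param records weekly records.
#' @param weeks integer window, default `15:25`.
#' @param min_group minimum pen group size (animals), default 8.
#' @return filtered records; counts removed per rule are attached as the
#'   `"filter_log"` attribute. An empty result triggers a warning, not an error.
#' @export
apply_filters <- function(records, weeks = 15:25, min_group = 8L) {
  n0 <- nrow(records)
  keep_week <- records$week %in% weeks
  rec <- records[keep_week, , drop = FALSE]
  grp <- tapply(rec$animal, rec$pen, function(a) length(unique(a)))
  ok_pen <- names(grp)[grp >= min_group]
  keep_pen <- as.character(rec$pen) %in% ok_pen
  out <- rec[keep_pen, , drop = FALSE]
  attr(out, "filter_log") <- c(removed_week = n0 - nrow(rec),
                               removed_pen = nrow(rec) - nrow(out))
  if (!nrow(out)) warning("all records removed by filters")
  rownames(out) <- NULL
  out
}

#' Full weekly phenotype preparation pipeline
#'
#' Runs imputation of daily intake, weight/backfat interpolation, weekly
#' covariate derivation, filtering and within-cell standardization, in the
#' order in which the source data were processed: daily -> weekly -> filters ->
#' standardization (so cells are standardized over the records actually kept).
#'
#' @inheritParams derive_weekly_covariates
#' @inheritParams apply_filters
#' @param events measurement events (`animal`, `age`, `weight`, `backfat`).
#' @return standardized, filtered weekly record table.
#' @export
prep_weekly <- function(daily, events, assignments, weeks = 15:25,
                        min_group = 8L) {
  daily <- impute_daily_intake(daily)
  endpoints <- interpolate_weight_backfat(events, weeks)
  rec <- derive_weekly_covariates(daily, endpoints, assignments)
  rec <- apply_filters(rec, weeks, min_group)
  standardize_within_cell(rec)
}
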