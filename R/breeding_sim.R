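# Stochastic simulation of a small pig selection nucleus: discrete
# generations of 120 sows x 30 boars, litters of N(9, 6), juvenile losses of
# 0.2, Weibull sow culling across parities, truncation selection of females
# and within-sire-family selection of males on one of six feed-efficiency
# indexes, with genetic evaluation by BLUP/EM-REML on the generating model.

#' Breeding-program simulation configuration
#'
#' Defaults are the nucleus structure of the study: 120 sows, 30 boars,
#' litter size N(9, 6), 20% juvenile mortality/culling, candidates from the
#' first two parities, up to six parities with Weibull stochastic culling,
#' three generations and 50 replicates.
#'
#' @param n_sows,n_boars nucleus size.
#' @param max_parities hard cap on sow parities.
#' @param weibull_shape,weibull_scale sow-culling survival parameters
#'   (`S(t) = exp(-(t/scale)^shape)` in parity units, applied as conditional
#'   survival at each parity transition); the default scale makes ~80% of
#'   sows survive a parity, i.e. `S(2)/S(1) = 0.8` at shape 2.
#' @param litter_mean,litter_variance litter size at birth distribution.
#' @param juvenile_loss joint mortality/culling rate to end of growing.
#' @param n_generations,n_replicates selection rounds and replicates.
#' @param scenario selection criterion: `"FI"`, `"tRFI"`, `"RFI"`,
#'   `"FI/MW"`, `"FI/WG"`, `"FI/FG"`, or `"random"` (a null control that
#'   ranks candidates at random).
#' @param evaluation_mode `"true_components"` (BLUP at the generating
#'   components), `"gibbs_reestimate"` (components re-estimated each
#'   generation and replicate by a short Gibbs run, then BLUP at the
#'   posterior means; emulates per-generation re-estimation at nucleus
#'   scale), or `"reml_reestimate"` (EM-REML per generation; dense
#'   inversion, desk-scale configurations only).
#' @param pen_size animals per pen during growing.
#' @param mate_max_rel mating between pairs with additive relationship at or
#'   above this value is avoided (default 0.25: parent-offspring, full sibs).
#' @param n_weeks weekly feed-intake records per animal.
#' @param seed base seed; replicate r uses `seed + r - 1`.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_sows = 120L, n_boars = 30L, max_parities = 6L,
                       weibull_shape = 2, weibull_scale = 3.667,
                       litter_mean = 9, litter_variance = 6,
                       juvenile_loss = 0.2, n_generations = 3L,
                       n_replicates = 50L,
                       scenario = c("RFI", "FI", "tRFI", "FI/MW", "FI/WG",
                                    "FI/FG", "random"),
                       evaluation_mode = c("true_components",
                                           "gibbs_reestimate",
                                           "reml_reestimate"),
                       pen_size = 10L, mate_max_rel = 0.25, n_weeks = 11L,
                       seed = 1L) {
  scenario <- match.arg(scenario)
  evaluation_mode <- match.arg(evaluation_mode)
  stopifnot(n_sows > 0, n_boars > 0, juvenile_loss >= 0, juvenile_loss <= 1,
            n_generations >= 1, n_replicates >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Covariate-trait generating parameters
#'
#' The 3 x 3 covariance matrices of the weekly standardized covariates
#' (MW, WG, FG): pen (`B_t`), additive-genetic (`G_t`), permanent-
#' environmental (`P_t`) and weekly residual (`R_t`) components, as estimated
#' by EM-REML from the real standardized records. At the published precision
#' `B_t` is marginally indefinite (determinant about -2e-5); any such matrix
#' is repaired to the nearest positive-definite matrix by eigenvalue clipping
#' and its name recorded in the `"repaired"` attribute.
#'
#' @return list of class `"covariate_trait_params"`.
#' @export
covariate_trait_params <- function() {
  nm <- c("mw", "wg", "fg")
  m <- function(...) {
    M <- matrix(c(...), 3, 3, dimnames = list(nm, nm))
    (M + t(M)) / 2
  }
  out <- list(
    B_t = m(0.25, 0.05, 0.02, 0.05, 0.02, 0.02, 0.02, 0.02, 0.02),
    G_t = m(0.44, 0.21, 0.14, 0.21, 0.22, 0.15, 0.14, 0.15, 0.20),
    P_t = m(0.31, 0.19, 0.08, 0.19, 0.21, 0.07, 0.08, 0.07, 0.09),
    R_t = m(0.04, 0.03, 0.02, 0.03, 0.53, 0.17, 0.02, 0.17, 0.67))
  repaired <- character(0)
  for (nm2 in names(out)) {
    if (any(eigen(out[[nm2]], symmetric = TRUE,
                  only.values = TRUE)$values <= 0)) {
      out[[nm2]] <- nearest_pd(out[[nm2]], eps = 1e-6)
      repaired <- c(repaired, nm2)
    }
  }
  structure(out, class = "covariate_trait_params", repaired = repaired)
}

#' True generating parameters of the selection simulation
#'
#' @param components feed-intake variance components (defaults to
#'   [reconstruct_model8_components()]).
#' @param mu overall feed-intake mean, g/d.
#' @param beta overall fixed regressions on standardized MW/WG/FG, g/d per sd.
#' @param covariate_params a [covariate_trait_params()] list.
#' @return list of class `"true_params"`.
#' @export
true_params <- function(components = reconstruct_model8_components(),
                        mu = 3000, beta = c(mw = 235, wg = 64, fg = 33),
                        covariate_params = covariate_trait_params()) {
  stopifnot(inherits(components, "variance_components"), components$k == 4L)
  structure(list(components = components, mu = mu, beta = beta,
                 covariate_params = covariate_params),
            class = "true_params")
}

# internal: multivariate normal draws (rows) via Cholesky
rmvn <- function(n, Sigma) {
  L <- chol(Sigma)
  matrix(stats::rnorm(n * ncol(Sigma)), n) %*% L
}

# internal: empty population container
new_population <- function() {
  list(ped = data.frame(id = integer(0), sire = integer(0), dam = integer(0),
                        sex = character(0), generation = integer(0),
                        parity = integer(0), stringsAsFactors = FALSE),
       a_fi = matrix(0, 0, 4), p_fi = matrix(0, 0, 4),
       a_cov = matrix(0, 0, 3), p_cov = matrix(0, 0, 3),
       records = NULL, sows = integer(0), boars = integer(0),
       next_id = 1L, next_pen = 1L)
}

#' Initialize the base nucleus population
#'
#' Unrelated founder sows and boars with breeding values and permanent
#' effects drawn from the generating multivariate normals (feed-intake
#' components from `params$components`, covariate traits from `G_t`/`P_t`).
#'
#' @param config a [sim_config()].
#' @param params a [true_params()].
#' @return a population list (internal structure).
#' @export
init_base_population <- function(config, params) {
  pop <- new_population()
  n <- config$n_boars + config$n_sows
  ids <- seq_len(n)
  pop$ped <- data.frame(
    id = ids, sire = 0L, dam = 0L,
    sex = c(rep("M", config$n_boars), rep("F", config$n_sows)),
    generation = 0L, parity = 0L, stringsAsFactors = FALSE)
  pop$a_fi <- rmvn(n, params$components$G0)
  pop$p_fi <- rmvn(n, params$components$P0)
  pop$a_cov <- rmvn(n, params$covariate_params$G_t)
  pop$p_cov <- rmvn(n, params$covariate_params$P_t)
  pop$boars <- ids[seq_len(config$n_boars)]
  pop$sows <- ids[config$n_boars + seq_len(config$n_sows)]
  pop$next_id <- n + 1L
  pop
}

#' Weekly standardized covariate traits for one animal
#'
#' Each week: pen effect + additive + permanent (constant across weeks)
#' plus an independent weekly residual from `R_t`.
#'
#' @param a_cov,p_cov length-3 additive and permanent effect vectors.
#' @param pen_effect length-3 pen effect vector.
#' @param n_weeks number of weekly records.
#' @param covariate_params a [covariate_trait_params()] list.
#' @return `n_weeks` x 3 matrix (columns mw, wg, fg).
#' @export
generate_covariate_traits <- function(a_cov, p_cov, pen_effect, n_weeks,
                                      covariate_params = covariate_trait_params()) {
  base <- matrix(rep(a_cov + p_cov + pen_effect, each = n_weeks), n_weeks)
  out <- base + rmvn(n_weeks, covariate_params$R_t)
  colnames(out) <- c("mw", "wg", "fg")
  out
}

#' Weekly feed-intake records for one animal
#'
#' `fi = mu + pen + MW b1 + WG b2 + FG b3 + a1 + MW a2 + WG a3 + FG a4
#'  + p1 + MW p2 + WG p3 + FG p4 + e`, one record per week.
#'
#' @param covariates `n_weeks` x 3 matrix of standardized covariates.
#' @param a,p length-4 effect vectors (intercept + slopes).
#' @param pen_fi scalar pen effect on feed intake.
#' @param params a [true_params()].
#' @return numeric vector of weekly feed intake, g/d.
#' @export
generate_feed_intake <- function(covariates, a, p, pen_fi, params) {
  n_weeks <- nrow(covariates)
  params$mu + pen_fi +
    as.numeric(covariates %*% params$beta) +
    a[1L] + as.numeric(covariates %*% a[2:4]) +
    p[1L] + as.numeric(covariates %*% p[2:4]) +
    stats::rnorm(n_weeks, 0, sqrt(params$components$var_e))
}

# internal: conditional probability a sow survives culling to parity p,
# given she reached parity p - 1
parity_survival <- function(p, shape, scale) {
  exp(-((p / scale)^shape - ((p - 1) / scale)^shape))
}

#' Advance the nucleus by one generation
#'
#' Mates sows to boars avoiding close relatives, draws litters across
#' parities with Weibull sow culling (capped at `max_parities`), applies
#' juvenile losses, assigns survivors to pens, samples their true effects by
#' the Mendelian rule, and generates their covariate and feed-intake records.
#' Offspring of parities 1-2 are the selection candidates of this generation;
#' later-parity offspring carry records that enter the evaluation data of the
#' next generation.
#'
#' @param pop a population from [init_base_population()] (or a previous call).
#' @param config a [sim_config()].
#' @param params a [true_params()].
#' @param generation integer label for the new cohort.
#' @return updated population; components `candidates` (ids) and
#'   `litter_sizes` (born counts) describe the new cohort.
#' @export
advance_generation <- function(pop, config, params, generation) {
  if (!length(pop$sows) || !length(pop$boars))
    stop("parent pool exhausted")
  # mate avoiding close relatives
  parents <- c(pop$boars, pop$sows)
  pedtab <- pedigree_table(pop$ped$id, pop$ped$sire, pop$ped$dam)
  A <- pairwise_relationship(pedtab, parents)
  mate <- integer(length(pop$sows))
  for (i in seq_along(pop$sows)) {
    sow <- pop$sows[i]
    ok <- pop$boars[A[as.character(pop$boars), as.character(sow)] <
                      config$mate_max_rel]
    if (!length(ok)) stop("no acceptable mate for sow ", sow)
    mate[i] <- if (length(ok) == 1L) ok else sample(ok, 1L)
  }
  G0h <- 0.5 * params$components$G0
  Gth <- 0.5 * params$covariate_params$G_t
  litter_sizes <- integer(0)
  off <- list()
  alive_sows <- rep(TRUE, length(pop$sows))
  for (par in seq_len(config$max_parities)) {
    if (par > 1L) {
      surv_p <- parity_survival(par, config$weibull_shape,
                                config$weibull_scale)
      alive_sows <- alive_sows & (stats::runif(length(alive_sows)) < surv_p)
    }
    for (i in which(alive_sows)) {
      born <- max(0L, round(stats::rnorm(1, config$litter_mean,
                                         sqrt(config$litter_variance))))
      litter_sizes <- c(litter_sizes, born)
      if (!born) next
      surv <- stats::rbinom(1L, born, 1 - config$juvenile_loss)
      if (!surv) next
      off[[length(off) + 1L]] <- data.frame(
        sire = mate[i], dam = pop$sows[i], parity = par,
        n = surv, stringsAsFactors = FALSE)
    }
  }
  if (!length(off)) stop("no offspring produced")
  off <- do.call(rbind, off)
  n_off <- sum(off$n)
  ids <- pop$next_id - 1L + seq_len(n_off)
  sire <- rep(off$sire, off$n); dam <- rep(off$dam, off$n)
  parity <- rep(off$parity, off$n)
  sex <- ifelse(stats::runif(n_off) < 0.5, "F", "M")
  si <- match(sire, pop$ped$id); di <- match(dam, pop$ped$id)
  a_fi <- 0.5 * (pop$a_fi[si, , drop = FALSE] + pop$a_fi[di, , drop = FALSE]) +
    rmvn(n_off, G0h)
  a_cov <- 0.5 * (pop$a_cov[si, , drop = FALSE] +
                    pop$a_cov[di, , drop = FALSE]) + rmvn(n_off, Gth)
  p_fi <- rmvn(n_off, params$components$P0)
  p_cov <- rmvn(n_off, params$covariate_params$P_t)

  pop$ped <- rbind(pop$ped, data.frame(
    id = ids, sire = sire, dam = dam, sex = sex, generation = generation,
    parity = parity, stringsAsFactors = FALSE))
  pop$a_fi <- rbind(pop$a_fi, a_fi)
  pop$p_fi <- rbind(pop$p_fi, p_fi)
  pop$a_cov <- rbind(pop$a_cov, a_cov)
  pop$p_cov <- rbind(pop$p_cov, p_cov)
  pop$next_id <- pop$next_id + n_off

  # pens filled sequentially in litter order (litter mates are penned
  # together at weaning), so pens typically hold one or two litters
  n_pens <- ceiling(n_off / config$pen_size)
  pen_of <- pop$next_pen - 1L + rep(seq_len(n_pens),
                                    each = config$pen_size)[seq_len(n_off)]
  pop$next_pen <- pop$next_pen + n_pens
  pen_fi <- stats::rnorm(n_pens, 0, sqrt(params$components$var_pen))
  pen_cov <- rmvn(n_pens, params$covariate_params$B_t)
  nw <- config$n_weeks
  pidx <- pen_of - (pop$next_pen - 1L - n_pens)
  covs <- matrix(0, n_off * nw, 3)
  for (i in seq_len(n_off)) {
    covs[(i - 1L) * nw + seq_len(nw), ] <- generate_covariate_traits(
      a_cov[i, ], p_cov[i, ], pen_cov[pidx[i], ], nw, params$covariate_params)
  }
  fi <- params$mu + rep(pen_fi[pidx], each = nw) +
    as.numeric(covs %*% params$beta) +
    rep(a_fi[, 1L], each = nw) + rowSums(covs * a_fi[rep(seq_len(n_off),
                                                         each = nw), 2:4]) +
    rep(p_fi[, 1L], each = nw) + rowSums(covs * p_fi[rep(seq_len(n_off),
                                                         each = nw), 2:4]) +
    stats::rnorm(n_off * nw, 0, sqrt(params$components$var_e))
  rec <- data.frame(
    animal = rep(ids, each = nw), week = rep(seq_len(nw), n_off),
    fi = fi, mw = covs[, 1L], wg = covs[, 2L], fg = covs[, 3L],
    pen = rep(pen_of, each = nw),
    avail_gen = rep(ifelse(parity <= 2L, generation, generation + 1L),
                    each = nw),
    stringsAsFactors = FALSE)
  pop$records <- if (is.null(pop$records)) rec else rbind(pop$records, rec)
  pop$candidates <- ids[parity <= 2L]
  pop$litter_sizes <- litter_sizes
  pop
}

# internal: map scenario to model spec, fixed-regression flag and index term
scenario_rules <- function(scenario) {
  switch(scenario,
         "FI" = list(spec = model_spec(1L), fixed_reg = FALSE, term = "icpt"),
         "tRFI" = list(spec = model_spec(1L), fixed_reg = TRUE, term = "icpt"),
         "RFI" = list(spec = model_spec(8L), fixed_reg = TRUE, term = "icpt"),
         "FI/MW" = list(spec = model_spec(8L), fixed_reg = TRUE, term = "mw"),
         "FI/WG" = list(spec = model_spec(8L), fixed_reg = TRUE, term = "wg"),
         "FI/FG" = list(spec = model_spec(8L), fixed_reg = TRUE, term = "fg"),
         "random" = list(spec = model_spec(8L), fixed_reg = TRUE,
                         term = "icpt"),
         stop("unknown scenario ", scenario))
}

#' Genetic evaluation of the current selection candidates
#'
#' Builds the evaluation model for the configured scenario (animal model on
#' raw feed intake for `"FI"`, the classic residual-feed-intake model for
#' `"tRFI"`, the full animal-specific model for the others), predicts
#' breeding values by BLUP at the generating components or by EM-REML, and
#' returns the selection index (negative predicted breeding value of the
#' scenario's term) for every candidate.
#'
#' @param pop population after [advance_generation()].
#' @param generation current generation number.
#' @param config a [sim_config()].
#' @param params a [true_params()].
#' @return data.frame: `id`, `sex`, `sire`, `index` (predicted, to maximize),
#'   `true_index` (same sign convention, from the true effects).
#' @export
evaluate_candidates <- function(pop, generation, config, params) {
  rules <- scenario_rules(config$scenario)
  # per-generation evaluation dataset: this generation's candidates plus the
  # later-parity offspring of the previous generation (whose records become
  # available now); the pedigree links them to all earlier animals
  rec <- pop$records[pop$records$avail_gen == generation, , drop = FALSE]
  pedtab <- pedigree_table(pop$ped$id, pop$ped$sire, pop$ped$dam)
  system <- build_design_system(rec, rules$spec, pedigree = pedtab,
                                week_structure = FALSE,
                                fixed_regressions = rules$fixed_reg)
  if (config$evaluation_mode == "reml_reestimate") {
    sol <- em_reml(system, start = reduce_components(params$components,
                                                     rules$spec),
                   tol = 1e-4, max_iter = 50L)
    ebv <- sol$ebv
  } else if (config$evaluation_mode == "gibbs_reestimate") {
    gseed <- sample.int(.Machine$integer.max %/% 2L, 1L)
    gfit <- gibbs_sample(system, chain_config(
      n_iter = 4000L, burn_in = 1000L, thin = 5L, n_chains = 1L,
      seed = gseed))
    vc <- posterior_mean_components(gfit)
    ebv <- predict_breeding_values(system, vc)$ebv
  } else {
    vc <- reduce_components(params$components, rules$spec)
    ebv <- predict_breeding_values(system, vc)$ebv
  }
  cand <- pop$candidates
  ci <- match(cand, pop$ped$id)
  tcol <- match(rules$term, params$components$terms)
  idx <- if (config$scenario == "random") {
    stats::runif(length(cand))
  } else {
    -ebv[as.character(cand), rules$term]
  }
  data.frame(
    id = cand, sex = pop$ped$sex[ci], sire = pop$ped$sire[ci],
    index = as.numeric(idx),
    true_index = -pop$a_fi[ci, tcol],
    stringsAsFactors = FALSE)
}

#' Truncation selection of the next generation's parents
#'
#' The best `n_sows` females over all female candidates; for males, the
#' single best-ranked candidate within each sire family. Ties are broken by
#' id, so selection is deterministic given the index.
#'
#' @param candidates data.frame from [evaluate_candidates()].
#' @param n_sows number of females to select.
#' @return list with `sows` and `boars` (id vectors).
#' @export
select_parents <- function(candidates, n_sows) {
  fem <- candidates[candidates$sex == "F", , drop = FALSE]
  if (nrow(fem) < n_sows)
    stop("too few female candidates (", nrow(fem), " < ", n_sows, ")")
  fem <- fem[order(-fem$index, fem$id), , drop = FALSE]
  males <- candidates[candidates$sex == "M", , drop = FALSE]
  boars <- if (nrow(males)) {
    males <- males[order(-males$index, males$id), , drop = FALSE]
    as.integer(sort(vapply(split(males, males$sire),
                           function(d) d$id[1L], numeric(1))))
  } else integer(0)
  list(sows = fem$id[seq_len(n_sows)], boars = boars)
}

#' Selection intensity, selected proportions and evaluation accuracy
#'
#' Intensity is realized on the predicted-breeding-value scale (negative
#' when selecting to decrease the trait) and is reported for each sex;
#' proportions are selected/candidates by sex; accuracy is the correlation
#' between predicted and true index over all candidates.
#'
#' @param candidates data.frame from [evaluate_candidates()].
#' @param selected list from [select_parents()].
#' @return list: `intensity_f`, `intensity_m`, `proportion_f`,
#'   `proportion_m`, `accuracy`.
#' @export
selection_metrics <- function(candidates, selected) {
  out <- list(intensity_f = NA_real_, intensity_m = NA_real_,
              proportion_f = NA_real_, proportion_m = NA_real_)
  for (sx in c("F", "M")) {
    cc <- candidates[candidates$sex == sx, , drop = FALSE]
    if (!nrow(cc)) next
    sel <- cc$id %in% unlist(selected)
    sdx <- stats::sd(cc$index)
    if (is.na(sdx) || sdx == 0) stop("zero candidate index sd")
    # EBV scale = -index; selecting high index = selecting low EBV
    intensity <- (mean(-cc$index[sel]) - mean(-cc$index)) / sdx
    if (sx == "F") {
      out$intensity_f <- intensity; out$proportion_f <- mean(sel)
    } else {
      out$intensity_m <- intensity; out$proportion_m <- mean(sel)
    }
  }
  out$accuracy <- stats::cor(candidates$index, candidates$true_index)
  out
}

#' Run a selection scenario across replicates
#'
#' Repeats the full cycle (base population, then `n_generations` rounds of
#' offspring generation, evaluation, and truncation selection) and averages
#' the responses of all feed-efficiency components across replicates.
#' Responses are per-generation changes in cohort mean true breeding values
#' between the first and last selected cohort. Selection metrics (intensity,
#' proportions, accuracy) are averaged over generations after the first:
#' the first round is evaluated on the unselected founder base with no
#' ancestral records, so its accuracy is a start-up transient rather than
#' the scheme's operating value.
#'
#' @param config a [sim_config()].
#' @param params a [true_params()].
#' @param max_abort_frac abort the run if more than this fraction of
#'   replicates fails (default 0.2).
#' @return object of class `"scenario_result"`: `response` /`response_sd`
#'   (named per-generation genetic-mean changes), `metrics` /`metrics_sd`
#'   (intensity, proportions, accuracy averaged over replicates and
#'   generations), `trajectories` (per-replicate cohort means), `n_replicates`
#'   completed.
#' @export
run_scenario <- function(config, params = true_params(),
                         max_abort_frac = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  resp_names <- c("mw", "wg", "fg", "rfi", "fi_mw", "fi_wg", "fi_fg", "fi")
  reps <- list(); metr <- list(); aborted <- 0L
  for (r in seq_len(config$n_replicates)) {
    set.seed(config$seed + r - 1L)
    res <- tryCatch({
      pop <- init_base_population(config, params)
      gen_means <- matrix(NA_real_, config$n_generations, length(resp_names),
                          dimnames = list(NULL, resp_names))
      mets <- matrix(NA_real_, config$n_generations, 5L,
                     dimnames = list(NULL, c("intensity_f", "intensity_m",
                                             "proportion_f", "proportion_m",
                                             "accuracy")))
      for (g in seq_len(config$n_generations)) {
        pop <- advance_generation(pop, config, params, g)
        cand <- evaluate_candidates(pop, g, config, params)
        sel <- select_parents(cand, config$n_sows)
        m <- selection_metrics(cand, sel)
        mets[g, ] <- unlist(m)[colnames(mets)]
        ci <- match(pop$candidates, pop$ped$id)
        gen_means[g, ] <- c(
          colMeans(pop$a_cov[ci, , drop = FALSE]),
          mean(pop$a_fi[ci, 1L]),
          colMeans(pop$a_fi[ci, 2:4, drop = FALSE]),
          mean(pop$a_fi[ci, 1L] +
                 pop$a_cov[ci, , drop = FALSE] %*% params$beta))
        pop$sows <- sel$sows
        pop$boars <- sel$boars
      }
      list(gen_means = gen_means, mets = mets)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      aborted <- aborted + 1L
      warning("replicate ", r, " aborted: ", conditionMessage(res))
      next
    }
    reps[[length(reps) + 1L]] <- res$gen_means
    metr[[length(metr) + 1L]] <- res$mets
  }
  if (aborted > max_abort_frac * config$n_replicates)
    stop("more than ", 100 * max_abort_frac, "% of replicates aborted")
  G <- config$n_generations
  resp <- t(vapply(reps, function(m) {
    if (G > 1L) (m[G, ] - m[1L, ]) / (G - 1L) else m[1L, ]
  }, numeric(length(resp_names))))
  met_gens <- if (G > 1L) 2:G else 1L  # drop the base-round transient
  met_mean <- t(vapply(metr, function(m)
    colMeans(m[met_gens, , drop = FALSE]), numeric(5L)))
  structure(list(
    scenario = config$scenario,
    response = colMeans(resp), response_sd = apply(resp, 2L, stats::sd),
    metrics = colMeans(met_mean), metrics_sd = apply(met_mean, 2L, stats::sd),
    trajectories = reps, n_replicates = length(reps)),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("scenario", x$scenario, "-", x$n_replicates, "replicates\n")
  cat("per-generation responses (mean (sd)):\n")
  for (nm in names(x$response))
    cat(sprintf("  %-6s %8.3f (%.3f)\n", nm, x$response[nm],
                x$response_sd[nm]))
  cat("selection metrics:\n")
  for (nm in names(x$metrics))
    cat(sprintf("  %-13s %6.3f (%.3f)\n", nm, x$metrics[nm],
                x$metrics_sd[nm]))
  invisible(x)
}
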