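#' Intercept (residual feed intake) heritability
#'
#' Ratio of the intercept additive-genetic variance to the sum of the
#' intercept additive, intercept permanent, pen and residual variances.
#' Slope variances are excluded because the ratio is evaluated at the means
#' of the standardized covariates, which are zero.
#'
#' @param vc a [variance_components()] object.
#' @return heritability in (0, 1).
#' @export
heritability_intercept <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  den <- vc$G0[1, 1] + vc$P0[1, 1] + vc$var_pen + vc$var_e
  if (den <= 0) stop("zero phenotypic denominator")
  vc$G0[1, 1] / den
}

#' Slope additive-to-total variance ratio
#'
#' For the animal-specific regression on one covariate: additive slope
#' variance divided by the sum of its additive and permanent slope variances.
#'
#' @param vc a [variance_components()] object.
#' @param covariate one of the slope terms in `vc$terms` (e.g. `"fg"`).
#' @return ratio between 0 and 1.
#' @export
slope_variance_ratio <- function(vc, covariate) {
  stopifnot(inherits(vc, "variance_components"))
  j <- match(covariate, vc$terms)
  if (is.na(j) || j == 1L)
    stop("covariate ", covariate, " is not a slope term of this model")
  vc$G0[j, j] / (vc$G0[j, j] + vc$P0[j, j])
}

#' Genetic correlation matrix
#'
#' @param vc a [variance_components()] object (PD `G0`).
#' @return correlation matrix of the intercept and slope genetic effects.
#' @export
genetic_correlations <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (any(eigen(vc$G0, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("G0 is not positive definite")
  stats::cov2cor(vc$G0)
}

#' Heritability and variances at a covariate value
#'
#' Conditional decomposition along one standardized covariate, the other
#' covariates held at their mean (zero): genetic variance
#' `G0[1,1] + 2x G0[1,j] + x^2 G0[j,j]`, permanent analogue from `P0`,
#' phenotypic = genetic + permanent + pen + residual (batch-week regression
#' variances are environmental context and excluded, matching the intercept
#' heritability's denominator).
#'
#' @param vc a [variance_components()] object.
#' @param covariate slope term name.
#' @param x covariate value in sd units (finite).
#' @return list with `h2`, `var_genetic`, `var_phenotypic`.
#' @export
h2_at_covariate <- function(vc, covariate, x) {
  stopifnot(inherits(vc, "variance_components"))
  if (!is.finite(x)) stop("x must be finite")
  j <- match(covariate, vc$terms)
  if (is.na(j) || j == 1L)
    stop("covariate ", covariate, " is not a slope term of this model")
  va <- vc$G0[1, 1] + 2 * x * vc$G0[1, j] + x^2 * vc$G0[j, j]
  vp <- vc$P0[1, 1] + 2 * x * vc$P0[1, j] + x^2 * vc$P0[j, j]
  phen <- va + vp + vc$var_pen + vc$var_e
  list(h2 = va / phen, var_genetic = va, var_phenotypic = phen)
}

#' Percentage of individual variance absorbed between two models
#'
#' `100 (1 - sum_b / sum_a)`: the share of the individual (additive +
#' permanent intercept) variance of the simpler model that is absorbed by the
#' animal-specific allocation terms of the richer model.
#'
#' @param sum_model_a,sum_model_b intercept additive + permanent sums
#'   ((g/d)^2) under the simpler and richer model; both positive.
#' @return percentage.
#' @export
variance_partition_percent <- function(sum_model_a, sum_model_b) {
  if (sum_model_a <= 0 || sum_model_b <= 0) stop("sums must be positive")
  100 * (1 - sum_model_b / sum_model_a)
}

#' Draw-wise posterior summary of a derived genetic parameter
#'
#' Applies a function of [variance_components()] to every retained draw and
#' summarizes the resulting posterior (chains merged; differences such as
#' h2(-0.75) - h2(+0.75) should be computed inside `fun`, draw-wise).
#'
#' @param fit an [gibbs_sample()] result.
#' @param fun function taking a [variance_components()] object and returning
#'   a single numeric value.
#' @return a `posterior_summary` (see [summarize_posterior()]).
#' @export
posterior_genetic_summary <- function(fit, fun) {
  stopifnot(inherits(fit, "rfi_gibbs_fit"))
  per_chain <- lapply(fit$chains, function(m) {
    apply(m, 1L, function(row) fun(vc_from_row(as.list(row), fit$system)))
  })
  draws <- unlist(per_chain)
  structure(list(
    mean = mean(draws), median = stats::median(draws), sd = stats::sd(draws),
    hpd_low = hpd_interval(draws)[1L], hpd_high = hpd_interval(draws)[2L],
    prob_gt_zero = mean(draws > 0),
    ess = sum(vapply(per_chain, effective_sample_size, numeric(1)))
  ), class = "posterior_summary")
}

#' Genetic-parameter table for a fitted model
#'
#' Posterior summaries (mean, median, sd, 95% HPD, Pr(>0), ESS) of the
#' intercept heritability, the slope variance ratios and the genetic
#' correlations, computed draw-wise from the retained samples.
#'
#' @param fit an [gibbs_sample()] result.
#' @return data.frame, one row per parameter.
#' @export
genetic_parameter_table <- function(fit) {
  specs <- list(h2_rfi = heritability_intercept)
  terms <- fit$system$spec$terms
  for (v in terms[-1L]) {
    local({
      vv <- v
      specs[[paste0("ratio_", vv)]] <<- function(vc) slope_variance_ratio(vc, vv)
    })
  }
  if (length(terms) > 1L) {
    for (a in seq_along(terms)) for (b in seq_along(terms)) {
      if (b <= a) next
      local({
        aa <- a; bb <- b
        specs[[paste0("r_g_", terms[aa], "_", terms[bb])]] <<-
          function(vc) genetic_correlations(vc)[aa, bb]
      })
    }
  }
  rows <- lapply(names(specs), function(nm) {
    s <- posterior_genetic_summary(fit, specs[[nm]])
    data.frame(parameter = nm, mean = s$mean, median = s$median, sd = s$sd,
               hpd_low = s$hpd_low, hpd_high = s$hpd_high,
               prob_gt_zero = s$prob_gt_zero, ess = s$ess)
  })
  do.call(rbind, rows)
}
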