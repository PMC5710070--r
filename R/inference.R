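#' Gibbs sampling configuration
#'
#' Defaults are a desk-scale protocol (50,000 iterations, 10,000 burn-in,
#' thinning 10, 2 chains); the full-scale analysis protocol (10^6 iterations,
#' 10^5 burn-in, thinning 100, 5 chains) is available by argument.
#'
#' @param n_iter iterations per chain.
#' @param burn_in discarded initial iterations (must be < `n_iter`).
#' @param thin retain one draw per `thin` iterations (>= 1).
#' @param n_chains number of independent chains (different seeds, same
#'   starting values).
#' @param seed base seed; chain `c` uses `seed + c - 1`.
#' @param init optional [variance_components()] starting values.
#' @param update_resid draw the residual variance (set `FALSE` to hold it
#'   fixed at its starting value).
#' @param var_max upper prior bound for every variance (bounded uniform
#'   prior); default very wide.
#' @return list of class `"chain_config"`.
#' @export
chain_config <- function(n_iter = 50000L, burn_in = 10000L, thin = 10L,
                         n_chains = 2L, seed = 1L, init = NULL,
                         update_resid = TRUE, var_max = 1e12) {
  stopifnot(burn_in < n_iter, thin >= 1L, n_chains >= 1L)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), init = init,
                 update_resid = update_resid, var_max = var_max),
            class = "chain_config")
}

# internal: parameter names of the sampled variance components
vc_param_names <- function(system) {
  terms <- system$spec$terms
  k <- system$k
  tri <- function(prefix) {
    out <- character(0)
    for (r in seq_len(k)) for (s in r:k)
      out <- c(out, paste0(prefix, ".", terms[r], ".", terms[s]))
    out
  }
  iid_names <- vapply(Filter(function(b) b$type == "iid", system$blocks),
                      function(b) b$vc, character(1))
  types <- vapply(system$blocks, function(b) b$type, character(1))
  c(if ("genetic" %in% types) tri("G0"),
    if ("permanent" %in% types) tri("P0"),
    iid_names, "var_e", "deviance")
}

# internal: default starting components
default_init <- function(system) {
  vy <- stats::var(system$y)
  k <- system$k
  G0 <- diag(vy / 10, k); P0 <- diag(vy / 10, k)
  dimnames(G0) <- dimnames(P0) <- list(system$spec$terms, system$spec$terms)
  iid <- Filter(function(b) b$type == "iid", system$blocks)
  vg <- stats::setNames(rep(vy / 10, length(iid)),
                        vapply(iid, function(b) b$vc, character(1)))
  gam <- vg[grep("^var_gamma_", names(vg))]
  names(gam) <- sub("^var_gamma_", "", names(gam))
  variance_components(G0, P0, gam,
                      var_pen = if ("var_pen" %in% names(vg)) vg[["var_pen"]]
                                else vy / 10,
                      var_e = vy / 2)
}

# internal: iid-block variance by name from a variance_components object
iid_variance <- function(vc, name) {
  if (name == "var_pen") return(vc$var_pen)
  if (grepl("^var_gamma_", name)) {
    v <- sub("^var_gamma_", "", name)
    if (v %in% names(vc$var_gamma)) return(vc$var_gamma[[v]])
    stop("components lack ", name)
  }
  stop("unknown iid variance ", name)
}

#' Gibbs sampler for a random-regression design system
#'
#' Samples all location effects from their univariate normal full
#' conditionals (single-site updates with residual bookkeeping), scalar
#' variances from scaled inverse chi-square full conditionals, and the
#' genetic and permanent covariance matrices from the inverse-Wishart full
#' conditionals implied by flat (bounded uniform) priors; draws above the
#' prior bound are rejected. Chains are reproducible given the seed.
#'
#' @param system a [build_design_system()] result.
#' @param config a [chain_config()].
#' @return object of class `"rfi_gibbs_fit"`: per-chain matrices of retained
#'   draws of every variance component (and the conditional deviance), the
#'   posterior-mean location effects, and the system.
#' @export
gibbs_sample <- function(system, config = chain_config()) {
  stopifnot(inherits(system, "design_system"), inherits(config, "chain_config"))
  init <- if (is.null(config$init)) default_init(system) else config$init
  if (!identical(init$terms, system$spec$terms))
    init <- reduce_components(init, system$spec)
  blocks <- system$blocks
  p <- ncol(system$W)
  col_type <- integer(p); col_iid <- rep(-1L, p)
  col_level <- rep(-1L, p); col_trait <- rep(-1L, p)
  iid_idx <- 0L; iid_names <- character(0); iid_init <- numeric(0)
  g_off <- -1L; p_off <- -1L; n_anim <- 0L; n_perm <- 0L
  for (b in blocks) {
    if (b$type == "fixed") {
      col_type[b$cols] <- 0L
    } else if (b$type == "iid") {
      if (length(b$cols) < 3L)
        stop("iid block ", b$name, " has fewer than 3 levels; ",
             "its variance full conditional is improper under a flat prior")
      col_type[b$cols] <- 1L
      col_iid[b$cols] <- iid_idx
      iid_idx <- iid_idx + 1L
      iid_names <- c(iid_names, b$vc)
      iid_init <- c(iid_init, iid_variance(init, b$vc))
    } else if (b$type %in% c("genetic", "permanent")) {
      code <- if (b$type == "genetic") 2L else 3L
      col_type[b$cols] <- code
      lev <- rep(seq_len(b$n_levels) - 1L, each = b$k)
      tr <- rep(seq_len(b$k) - 1L, b$n_levels)
      col_level[b$cols] <- lev
      col_trait[b$cols] <- tr
      if (b$type == "genetic") { g_off <- b$cols[1L] - 1L; n_anim <- b$n_levels }
      else { p_off <- b$cols[1L] - 1L; n_perm <- b$n_levels }
    }
  }
  W <- methods::as(system$W, "CsparseMatrix")
  Ainv <- methods::as(methods::as(system$Ainv, "generalMatrix"),
                      "CsparseMatrix")
  pnames <- vc_param_names(system)
  chains <- vector("list", config$n_chains)
  theta_means <- matrix(0, p, config$n_chains)
  ve_means <- numeric(config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    res <- .gibbs_chain_cpp(
      system$y, W@p, W@i, W@x, col_type, col_iid, col_level, col_trait,
      iid_idx, Ainv@p, Ainv@i, Ainv@x, system$k, n_anim, n_perm,
      g_off, p_off, config$n_iter, config$burn_in, config$thin,
      init$G0, init$P0, init$var_e, iid_init,
      config$update_resid, config$var_max)
    sm <- res$samples
    colnames(sm) <- pnames
    chains[[ch]] <- sm
    theta_means[, ch] <- res$theta_mean
    ve_means[ch] <- res$ve_mean
  }
  structure(list(chains = chains, theta_means = theta_means,
                 theta_mean = rowMeans(theta_means), ve_means = ve_means,
                 param_names = pnames, system = system, config = config),
            class = "rfi_gibbs_fit")
}

#' @export
print.rfi_gibbs_fit <- function(x, ...) {
  cat("rfi_gibbs_fit: model", x$system$spec$code, "-",
      length(x$chains), "chain(s) x", nrow(x$chains[[1L]]), "retained draws\n")
  pm <- colMeans(do.call(rbind, x$chains))
  print(round(pm[setdiff(names(pm), "deviance")], 3))
  invisible(x)
}

#' Merge retained draws across chains
#'
#' @param fit an [gibbs_sample()] result.
#' @return matrix of draws (all chains stacked) with parameter columns.
#' @export
merged_draws <- function(fit) {
  stopifnot(inherits(fit, "rfi_gibbs_fit"))
  do.call(rbind, fit$chains)
}

#' Variance components from a single retained draw
#'
#' @param fit an [gibbs_sample()] result.
#' @param draw row index into [merged_draws()].
#' @return a [variance_components()] object.
#' @export
vc_from_draw <- function(fit, draw) {
  d <- merged_draws(fit)[draw, ]
  vc_from_row(d, fit$system)
}

# internal: build variance_components from one named draw row
vc_from_row <- function(d, system) {
  k <- system$k; terms <- system$spec$terms
  G0 <- matrix(0, k, k); P0 <- matrix(0, k, k)
  for (r in seq_len(k)) for (s in r:k) {
    G0[r, s] <- G0[s, r] <- d[[paste0("G0.", terms[r], ".", terms[s])]]
    P0[r, s] <- P0[s, r] <- d[[paste0("P0.", terms[r], ".", terms[s])]]
  }
  dimnames(G0) <- dimnames(P0) <- list(terms, terms)
  gam <- d[grep("^var_gamma_", names(d))]
  names(gam) <- sub("^var_gamma_", "", names(gam))
  variance_components(G0, P0, gam,
                      var_pen = if ("var_pen" %in% names(d)) d[["var_pen"]]
                                else 1e-12,
                      var_e = d[["var_e"]])
}

#' Posterior means of the variance components
#'
#' @param fit an [gibbs_sample()] result.
#' @return a [variance_components()] object of posterior means.
#' @export
posterior_mean_components <- function(fit) {
  vc_from_row(colMeans(merged_draws(fit)), fit$system)
}

# ---------------------------------------------------------------------------
# DIC

#' Deviance information criterion of a fitted model
#'
#' Uses the conditional deviance `-2 log p(y | effects, var_e)` (normal
#' likelihood given all location effects), so the effective number of
#' parameters `p_D` counts the effective location dimension. DIC = mean
#' posterior deviance + p_D, with p_D = mean deviance - deviance at the
#' posterior means.
#'
#' @param fit an [gibbs_sample()] result.
#' @param chain chain index, or `NULL` (default) to merge chains.
#' @return list of class `"model_fit_summary"`: `dic`, `mean_deviance`,
#'   `deviance_at_mean`, `p_d`.
#' @export
dic <- function(fit, chain = NULL) {
  stopifnot(inherits(fit, "rfi_gibbs_fit"))
  if (is.null(chain)) {
    dev <- unlist(lapply(fit$chains, function(m) m[, "deviance"]))
    theta <- fit$theta_mean
    ve <- mean(fit$ve_means)
  } else {
    dev <- fit$chains[[chain]][, "deviance"]
    theta <- fit$theta_means[, chain]
    ve <- fit$ve_means[chain]
  }
  if (length(dev) < 50L) stop("too few retained draws (< 50) for DIC")
  n <- fit$system$n
  e <- fit$system$y - as.numeric(fit$system$W %*% theta)
  d_at_mean <- n * log(2 * pi * ve) + sum(e^2) / ve
  mean_dev <- mean(dev)
  p_d <- mean_dev - d_at_mean
  structure(list(dic = mean_dev + p_d, mean_deviance = mean_dev,
                 deviance_at_mean = d_at_mean, p_d = p_d),
            class = "model_fit_summary")
}

#' @export
print.model_fit_summary <- function(x, ...) {
  cat(sprintf("DIC %.1f  (mean deviance %.1f, p_D %.1f)\n",
              x$dic, x$mean_deviance, x$p_d))
  invisible(x)
}

# ---------------------------------------------------------------------------
# posterior summaries

#' Shortest (highest posterior density) interval
#'
#' @param draws numeric vector of posterior draws.
#' @param prob interval mass (default 0.95).
#' @return numeric length-2 (lower, upper).
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[(m + 1L):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Effective sample size by the initial positive sequence method
#'
#' Sums sample autocovariances in adjacent pairs (Geyer's initial positive
#' sequence) until a pair sum turns negative, giving an estimate of the
#' autocorrelation time that is assumption-light for reversible chains.
#'
#' @param draws numeric vector (a single chain's draws of one parameter).
#' @return estimated effective sample size (capped at `length(draws)`).
#' @export
effective_sample_size <- function(draws) {
  n <- length(draws)
  if (n < 4L || stats::sd(draws) == 0) return(n)
  max_lag <- min(n - 2L, 2000L)
  ac <- stats::acf(draws, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # ac[1] = lag 0
  tau <- 1
  m <- 1L
  while (2L * m + 1L <= length(ac)) {
    pair <- ac[2L * m] + ac[2L * m + 1L]
    if (pair <= 0) break
    tau <- tau + 2 * pair
    m <- m + 1L
  }
  min(n, n / tau)
}

#' Summarize the marginal posterior of one parameter
#'
#' Chains are merged before summarizing; the effective sample size is the sum
#' of per-chain estimates.
#'
#' @param fit an [gibbs_sample()] result, or a numeric vector of draws (then
#'   treated as one chain).
#' @param parameter parameter name (see `fit$param_names`); ignored when `fit`
#'   is a numeric vector.
#' @param transform optional function applied draw-wise before summarizing
#'   (e.g. a heritability computed from each draw).
#' @return list of class `"posterior_summary"`: `mean`, `median`, `sd`,
#'   `hpd_low`, `hpd_high` (95%), `prob_gt_zero`, `ess`.
#' @export
summarize_posterior <- function(fit, parameter = NULL, transform = NULL) {
  if (is.numeric(fit)) {
    per_chain <- list(fit)
  } else {
    stopifnot(inherits(fit, "rfi_gibbs_fit"))
    if (is.null(parameter)) stop("parameter must be given")
    if (!parameter %in% fit$param_names) stop("unknown parameter ", parameter)
    per_chain <- lapply(fit$chains, function(m) m[, parameter])
  }
  if (!is.null(transform)) per_chain <- lapply(per_chain, transform)
  draws <- unlist(per_chain)
  if (length(draws) < 50L) stop("too few draws (< 50) to summarize")
  structure(list(
    mean = mean(draws), median = stats::median(draws), sd = stats::sd(draws),
    hpd_low = hpd_interval(draws)[1L], hpd_high = hpd_interval(draws)[2L],
    prob_gt_zero = mean(draws > 0),
    ess = sum(vapply(per_chain, effective_sample_size, numeric(1)))
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "mean %.4g  median %.4g  sd %.4g  HPD95 [%.4g, %.4g]  Pr(>0) %.2f  ESS %.0f\n",
    x$mean, x$median, x$sd, x$hpd_low, x$hpd_high, x$prob_gt_zero, x$ess))
  invisible(x)
}

# ---------------------------------------------------------------------------
# mixed-model equations, BLUP and EM-REML

# internal: prior precision Q = blockdiag(0_fixed, Sigma_u^{-1}); relies on
# design columns being contiguous in block order
prior_precision <- function(system, vc) {
  G0inv <- solve(vc$G0); P0inv <- solve(vc$P0)
  parts <- lapply(system$blocks, function(b) {
    switch(b$type,
      fixed = Matrix::Diagonal(length(b$cols), 0),
      iid = Matrix::Diagonal(length(b$cols), 1 / iid_variance(vc, b$vc)),
      genetic = Matrix::kronecker(system$Ainv, G0inv),
      permanent = Matrix::kronecker(Matrix::Diagonal(b$n_levels), P0inv))
  })
  Matrix::bdiag(parts)
}

#' Best linear unbiased prediction of all effects at fixed components
#'
#' Solves the mixed-model equations `(W'W + var_e Q) theta = W'y` (Q the
#' block prior precision, genetic block `A^-1 (x) G0^-1`) by sparse Cholesky.
#' Ancestors without records receive breeding values through the relationship
#' matrix.
#'
#' @param system a [build_design_system()] result.
#' @param vc a [variance_components()] object with terms matching the spec.
#' @return list with `theta` (all effects), `ebv` (animals x k matrix of
#'   genetic effects, rownames = animal ids), `perm` (animals-with-records x k
#'   permanent effects).
#' @export
predict_breeding_values <- function(system, vc) {
  stopifnot(inherits(system, "design_system"))
  if (!identical(vc$terms, system$spec$terms))
    vc <- reduce_components(vc, system$spec)
  Q <- prior_precision(system, vc)
  M <- Matrix::forceSymmetric(Matrix::crossprod(system$W) + vc$var_e * Q)
  rhs <- Matrix::crossprod(system$W, system$y)
  theta <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Cholesky(M, LDL = FALSE, perm = TRUE),
                             rhs)),
    error = function(e) stop("singular coefficient matrix: ",
                             conditionMessage(e)))
  names(theta) <- system$labels
  gbl <- Filter(function(b) b$type == "genetic", system$blocks)
  if (!length(gbl)) stop("system has no animal effects")
  gb <- gbl[[1L]]
  pb <- Filter(function(b) b$type == "permanent", system$blocks)[[1L]]
  ebv <- matrix(theta[gb$cols], ncol = system$k, byrow = TRUE,
                dimnames = list(system$animal_ids, system$spec$terms))
  perm <- matrix(theta[pb$cols], ncol = system$k, byrow = TRUE,
                 dimnames = list(system$perm_ids, system$spec$terms))
  list(theta = theta, ebv = ebv, perm = perm)
}

#' EM-REML estimation of variance components
#'
#' Expectation-maximization restricted maximum likelihood on the mixed-model
#' equations: each iteration solves the equations at the current components,
#' then updates every variance from the effect solutions plus the matching
#' blocks of the inverse coefficient matrix. Intended for desk-scale systems
#' (the coefficient matrix is inverted densely).
#'
#' @param system a [build_design_system()] result.
#' @param start optional starting [variance_components()].
#' @param tol convergence tolerance on the maximum relative component change.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with `converged = FALSE`.
#' @return list of class `"reml_fit"`: `vc`, `theta` (BLUP at convergence),
#'   `ebv`, `converged`, `iterations`, `loglik` (REML log-likelihood trace).
#' @export
em_reml <- function(system, start = NULL, tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(system, "design_system"))
  vc <- if (is.null(start)) default_init(system) else start
  if (!identical(vc$terms, system$spec$terms))
    vc <- reduce_components(vc, system$spec)
  p <- ncol(system$W)
  if (p > 4000L)
    warning("EM-REML inverts a ", p, "x", p,
            " coefficient matrix densely; this may be slow")
  W <- system$W
  WtW <- Matrix::crossprod(W)
  Wty <- as.numeric(Matrix::crossprod(W, system$y))
  yty <- sum(system$y^2)
  n <- system$n
  k <- system$k
  gbl <- Filter(function(b) b$type == "genetic", system$blocks)
  if (!length(gbl)) stop("system has no animal effects")
  gb <- gbl[[1L]]
  pb <- Filter(function(b) b$type == "permanent", system$blocks)[[1L]]
  n_fixed <- sum(vapply(system$blocks,
                        function(b) if (b$type == "fixed") length(b$cols)
                                    else 0L, integer(1)))
  Ainv <- methods::as(system$Ainv, "generalMatrix")
  Asum <- Matrix::summary(Ainv)  # triplets for trace computations
  logdet_Ainv <- as.numeric(Matrix::determinant(system$Ainv,
                                                logarithm = TRUE)$modulus)
  loglik <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Q <- prior_precision(system, vc)
    M <- as.matrix(WtW + vc$var_e * Q)
    Minv <- tryCatch(solve(M), error = function(e)
      stop("coefficient matrix singular during EM-REML"))
    theta <- as.numeric(Minv %*% Wty)
    # REML log-likelihood (up to a constant): -0.5 (log|G| + log|R| + log|C| + y'Py)
    ypy <- (yty - sum(theta * Wty)) / vc$var_e
    logdetG <- gb$n_levels * as.numeric(determinant(vc$G0)$modulus) +
      k * (-logdet_Ainv) +
      pb$n_levels * as.numeric(determinant(vc$P0)$modulus) +
      sum(vapply(system$blocks, function(b) {
        if (b$type == "iid") length(b$cols) * log(iid_variance(vc, b$vc))
        else 0
      }, numeric(1)))
    logdetC <- as.numeric(determinant(M)$modulus) - p * log(vc$var_e)
    loglik <- c(loglik, -0.5 * (logdetG + n * log(vc$var_e) + logdetC + ypy))

    new_iid <- vc$var_gamma; new_pen <- vc$var_pen
    for (b in system$blocks) {
      if (b$type != "iid") next
      q <- length(b$cols)
      val <- (sum(theta[b$cols]^2) +
                vc$var_e * sum(diag(Minv)[b$cols])) / q
      if (b$vc == "var_pen") new_pen <- val
      else new_iid[[sub("^var_gamma_", "", b$vc)]] <- val
    }
    amat <- matrix(theta[gb$cols], ncol = k, byrow = TRUE)
    G0new <- matrix(0, k, k)
    for (r in seq_len(k)) for (s in r:k) {
      quad <- as.numeric(amat[, r] %*% (Ainv %*% amat[, s]))
      rows <- gb$cols[(seq_len(gb$n_levels) - 1L) * k + r]
      cols <- gb$cols[(seq_len(gb$n_levels) - 1L) * k + s]
      tr <- sum(Asum$x * Minv[cbind(cols[Asum$i], rows[Asum$j])])
      G0new[r, s] <- G0new[s, r] <- (quad + vc$var_e * tr) / gb$n_levels
    }
    pmat <- matrix(theta[pb$cols], ncol = k, byrow = TRUE)
    P0new <- matrix(0, k, k)
    for (r in seq_len(k)) for (s in r:k) {
      rows <- pb$cols[(seq_len(pb$n_levels) - 1L) * k + r]
      cols <- pb$cols[(seq_len(pb$n_levels) - 1L) * k + s]
      tr <- sum(Minv[cbind(rows, cols)])
      P0new[r, s] <- P0new[s, r] <-
        (sum(pmat[, r] * pmat[, s]) + vc$var_e * tr) / pb$n_levels
    }
    ve_new <- (yty - sum(theta * Wty)) / (n - n_fixed)
    dimnames(G0new) <- dimnames(P0new) <- dimnames(vc$G0)
    old <- c(diag(vc$G0), diag(vc$P0), vc$var_gamma, vc$var_pen, vc$var_e)
    new <- c(diag(G0new), diag(P0new), new_iid, new_pen, ve_new)
    rel <- max(abs(new - old) / pmax(abs(old), 1e-10))
    # guard against exact singularity at the boundary
    G0new <- G0new + diag(1e-10 * max(ve_new, 1), k)
    P0new <- P0new + diag(1e-10 * max(ve_new, 1), k)
    vc <- variance_components(G0new, P0new, new_iid, max(new_pen, 1e-10),
                              ve_new)
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM-REML did not converge in ", max_iter, " iterations")
  sol <- predict_breeding_values(system, vc)
  structure(list(vc = vc, theta = sol$theta, ebv = sol$ebv,
                 converged = converged, iterations = length(loglik),
                 loglik = loglik),
            class = "reml_fit")
}
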