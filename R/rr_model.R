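#' Random-regression model specification by code
#'
#' The eight nested models differ only in which animal-specific random
#' regressions (on standardized MW, WG, FG) accompany the animal intercepts:
#' 1 none (classic residual-feed-intake model), 2 MW, 3 WG, 4 FG, 5 MW+WG,
#' 6 MW+FG, 7 WG+FG, 8 MW+WG+FG.
#'
#' @param code integer 1-8.
#' @return object of class `"rfi_model_spec"`: list with `code`,
#'   `animal_terms` (subset of `c("mw","wg","fg")`), `terms`
#'   (`"icpt"` + animal_terms) and `k = 1 + length(animal_terms)`.
#' @export
model_spec <- function(code) {
  if (length(code) != 1L || is.na(code) || !(code %in% 1:8))
    stop("model code must be a single integer in 1..8")
  map <- list(character(0), "mw", "wg", "fg", c("mw", "wg"),
              c("mw", "fg"), c("wg", "fg"), c("mw", "wg", "fg"))
  at <- map[[code]]
  structure(list(code = as.integer(code), animal_terms = at,
                 terms = c("icpt", at), k = 1L + length(at)),
            class = "rfi_model_spec")
}

#' Build the mixed-model design system for a model specification
#'
#' Assembles the response, the sparse design matrix and the random-effect
#' block structure for weekly feed-intake records: batch-by-week fixed classes,
#' within-week fixed regressions on standardized MW/WG/FG, random pen effects,
#' random batch-by-week regressions on each covariate, and `k` correlated
#' animal effects (intercept + slopes in `spec`) in both an additive-genetic
#' block (covariance `G0 (x) A`, all pedigree animals) and a permanent-
#' environmental block (`P0 (x) I`, animals with records).
#'
#' With `week_structure = FALSE` (the structure used by the selection
#' simulator, where batch and age patterns are ignored) the fixed part is a
#' single intercept plus one overall regression per covariate, and the
#' batch-week regression blocks are omitted.
#'
#' @param records weekly records with standardized covariates (`mw`,`wg`,`fg`).
#' @param spec an [model_spec()] object.
#' @param pedigree optional sorted [pedigree_table()]; defaults to treating the
#'   recorded animals as unrelated.
#' @param week_structure logical; include batch-week classes, week-nested fixed
#'   regressions and batch-week random regressions (default `TRUE`).
#' @param fixed_regressions logical; include the fixed regressions on the
#'   covariates (set `FALSE` for the raw feed-intake evaluation model).
#' @param pen_effect logical; include the random pen block (default `TRUE`).
#' @param animal_effects logical; include the genetic and permanent animal
#'   blocks (default `TRUE`; `FALSE` gives a fixed/iid-only system for
#'   reduced designs).
#' @return object of class `"design_system"`.
#' @export
build_design_system <- function(records, spec, pedigree = NULL,
                                week_structure = TRUE,
                                fixed_regressions = TRUE,
                                pen_effect = TRUE, animal_effects = TRUE) {
  stopifnot(inherits(spec, "rfi_model_spec"))
  if (!nrow(records)) stop("empty record list")
  need <- c("animal", "fi", "mw", "wg", "fg")
  if (pen_effect) need <- c(need, "pen")
  if (week_structure) need <- c(need, "batch", "week")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  n <- nrow(records)
  y <- records$fi
  covs <- c("mw", "wg", "fg")

  if (!is.null(pedigree)) {
    stopifnot(inherits(pedigree, "pedigree_table"))
    animal_ids <- as.character(pedigree$animal)
    if (!all(as.character(records$animal) %in% animal_ids))
      stop("record references animal absent from the pedigree: ",
           setdiff(as.character(records$animal), animal_ids)[1L])
    Ainv <- relationship_inverse(pedigree)$a_inverse
  } else {
    animal_ids <- as.character(sort(unique(records$animal)))
    Ainv <- Matrix::Diagonal(length(animal_ids))
    dimnames(Ainv) <- list(animal_ids, animal_ids)
  }
  rec_animal <- match(as.character(records$animal), animal_ids)
  perm_ids <- animal_ids[sort(unique(rec_animal))]
  rec_perm <- match(as.character(records$animal), perm_ids)

  Ti <- list(); Tj <- list(); Tx <- list()   # design triplets
  blocks <- list()
  labels <- character(0)
  col0 <- 0L
  push <- function(i, j, x) {
    Ti[[length(Ti) + 1L]] <<- i
    Tj[[length(Tj) + 1L]] <<- j
    Tx[[length(Tx) + 1L]] <<- x
  }

  if (week_structure) {
    ba <- interaction(records$batch, records$week, drop = TRUE, sep = ":")
    ba_lev <- levels(ba)
    push(seq_len(n), col0 + as.integer(ba), rep(1, n))
    blocks[[length(blocks) + 1L]] <- list(
      name = "ba", type = "fixed", cols = col0 + seq_along(ba_lev))
    labels <- c(labels, paste0("ba.", ba_lev))
    col0 <- col0 + length(ba_lev)
    if (fixed_regressions) {
      wk <- factor(records$week)
      for (v in covs) {
        push(seq_len(n), col0 + as.integer(wk), records[[v]])
        blocks[[length(blocks) + 1L]] <- list(
          name = paste0("beta_", v), type = "fixed",
          cols = col0 + seq_along(levels(wk)))
        labels <- c(labels, paste0("beta_", v, ".wk", levels(wk)))
        col0 <- col0 + length(levels(wk))
      }
    }
  } else {
    push(seq_len(n), rep(col0 + 1L, n), rep(1, n))
    blocks[[length(blocks) + 1L]] <- list(name = "mu", type = "fixed",
                                          cols = col0 + 1L)
    labels <- c(labels, "mu")
    col0 <- col0 + 1L
    if (fixed_regressions) {
      for (v in covs) {
        push(seq_len(n), rep(col0 + 1L, n), records[[v]])
        blocks[[length(blocks) + 1L]] <- list(name = paste0("beta_", v),
                                              type = "fixed", cols = col0 + 1L)
        labels <- c(labels, paste0("beta_", v))
        col0 <- col0 + 1L
      }
    }
  }

  if (pen_effect) {
    pen <- factor(records$pen)
    push(seq_len(n), col0 + as.integer(pen), rep(1, n))
    blocks[[length(blocks) + 1L]] <- list(
      name = "pen", type = "iid", vc = "var_pen",
      cols = col0 + seq_along(levels(pen)))
    labels <- c(labels, paste0("pen.", levels(pen)))
    col0 <- col0 + length(levels(pen))
  }

  if (week_structure && fixed_regressions) {
    # batch-week random regressions accompany the fixed ones; the raw
    # feed-intake model drops both
    ba <- interaction(records$batch, records$week, drop = TRUE, sep = ":")
    for (v in covs) {
      push(seq_len(n), col0 + as.integer(ba), records[[v]])
      blocks[[length(blocks) + 1L]] <- list(
        name = paste0("gamma_", v), type = "iid", vc = paste0("var_gamma_", v),
        cols = col0 + seq_along(levels(ba)))
      labels <- c(labels, paste0("gamma_", v, ".", levels(ba)))
      col0 <- col0 + length(levels(ba))
    }
  }

  k <- spec$k
  n_anim <- length(animal_ids)
  if (animal_effects) {
  # genetic block: animal-major, trait-within-animal ordering
  for (t in seq_len(k)) {
    xv <- if (t == 1L) rep(1, n) else records[[spec$animal_terms[t - 1L]]]
    push(seq_len(n), col0 + (rec_animal - 1L) * k + t, xv)
  }
  blocks[[length(blocks) + 1L]] <- list(
    name = "genetic", type = "genetic", cols = col0 + seq_len(n_anim * k),
    k = k, n_levels = n_anim)
  labels <- c(labels, paste0("a.", rep(animal_ids, each = k), ".",
                             rep(spec$terms, n_anim)))
  col0 <- col0 + n_anim * k

  n_perm <- length(perm_ids)
  for (t in seq_len(k)) {
    xv <- if (t == 1L) rep(1, n) else records[[spec$animal_terms[t - 1L]]]
    push(seq_len(n), col0 + (rec_perm - 1L) * k + t, xv)
  }
  blocks[[length(blocks) + 1L]] <- list(
    name = "permanent", type = "permanent", cols = col0 + seq_len(n_perm * k),
    k = k, n_levels = n_perm)
  labels <- c(labels, paste0("p.", rep(perm_ids, each = k), ".",
                             rep(spec$terms, n_perm)))
  col0 <- col0 + n_perm * k
  }

  W <- Matrix::sparseMatrix(i = unlist(Ti), j = unlist(Tj), x = unlist(Tx),
                            dims = c(n, col0))
  colnames(W) <- labels
  structure(list(
    y = y, W = W, blocks = blocks, k = k, spec = spec,
    animal_ids = animal_ids, perm_ids = perm_ids, Ainv = Ainv,
    rec_animal = rec_animal, n = n, labels = labels,
    week_structure = week_structure
  ), class = "design_system")
}

#' @export
print.design_system <- function(x, ...) {
  cat("design_system: model", x$spec$code, "(k =", x$k, ")\n")
  cat(" ", x$n, "records,", length(x$animal_ids), "pedigree animals,",
      length(x$perm_ids), "with records,", ncol(x$W), "effects\n")
  for (b in x$blocks)
    cat("  block", b$name, "[", b$type, "]:", length(b$cols), "columns\n")
  invisible(x)
}

#' Expected feed intake of one record given all effect values
#'
#' Sums the record's contributions: its batch-week class, the week-nested
#' fixed regressions times its covariates, its pen, the batch-week random
#' regressions, and the animal genetic and permanent intercepts and slopes
#' present in the model specification.
#'
#' @param system a [build_design_system()] result.
#' @param record integer record index.
#' @param effects full effect vector (one value per design column, in
#'   `system$labels` order).
#' @return the expected `fi` for that record.
#' @export
assemble_record_mean <- function(system, record, effects) {
  stopifnot(inherits(system, "design_system"))
  if (length(effects) != ncol(system$W))
    stop("effects must supply one value per design column (",
         ncol(system$W), ")")
  if (anyNA(effects)) stop("missing effect value")
  as.numeric(system$W[record, , drop = FALSE] %*% effects)
}

#' Fitted means for all records
#'
#' @inheritParams assemble_record_mean
#' @return numeric vector of expected `fi`, one per record.
#' @export
fitted_means <- function(system, effects) {
  as.numeric(system$W %*% effects)
}
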