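#' Validate and topologically sort a pedigree
#'
#' Builds a pedigree table from animal/sire/dam triples, checking id uniqueness
#' and the absence of ancestral cycles, and reordering rows so that every known
#' parent appears before its offspring. Unknown parents are coded `0` (or `NA`,
#' which is converted to `0`).
#'
#' @param animal integer or character ids, one per animal.
#' @param sire,dam parent ids; `0`/`NA` for unknown.
#' @return A `data.frame` of class `"pedigree_table"` with columns `animal`,
#'   `sire`, `dam` (ids as given) and `birth_order` (the validated topological
#'   position). Parents always precede offspring.
#' @examples
#' ped <- pedigree_table(c(3, 1, 2), c(1, 0, 0), c(2, 0, 0))
#' ped$animal  # 1, 2, 3
#' @export
pedigree_table <- function(animal, sire, dam) {
  if (length(animal) != length(sire) || length(animal) != length(dam))
    stop("animal, sire and dam must have equal length")
  sire[is.na(sire)] <- 0L
  dam[is.na(dam)] <- 0L
  if (any(animal == 0)) stop("animal id 0 is reserved for unknown parents")
  if (anyDuplicated(animal))
    stop("duplicate animal id: ", animal[duplicated(animal)][1L])
  n <- length(animal)
  id <- as.character(animal)
  # NA = unknown parent; parents referenced but not listed as animals are
  # treated as unknown founders (no genetic-group structure)
  si <- match(as.character(sire), id)
  di <- match(as.character(dam), id)
  # Kahn's algorithm on edges parent -> offspring
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  indeg_work <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg_work[ch] <- indeg_work[ch] - 1L
      if (indeg_work[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    bad <- setdiff(seq_len(n), order)
    stop("pedigree cycle detected involving animal id: ", id[bad[1L]])
  }
  out <- data.frame(
    animal = animal[order],
    sire = sire[order],
    dam = dam[order],
    birth_order = seq_len(n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pedigree_table", "data.frame")
  out
}

#' Read a pedigree from a delimited file
#'
#' Three columns (animal, sire, dam), whitespace- or tab-delimited, optional
#' header; `0` codes an unknown parent.
#'
#' @param path file path.
#' @return a sorted [pedigree_table()].
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[0-9]", first)
  tab <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("pedigree file must have 3 columns (animal, sire, dam)")
  pedigree_table(tab[[1L]], tab[[2L]], tab[[3L]])
}

# internal: parent row indices (0 = unknown) for a sorted pedigree
ped_parent_index <- function(ped) {
  id <- as.character(ped$animal)
  si <- match(as.character(ped$sire), id)
  di <- match(as.character(ped$dam), id)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L
  if (any(si >= seq_along(si) & si > 0L) || any(di >= seq_along(di) & di > 0L))
    stop("pedigree is not sorted: a parent appears at or after its offspring")
  list(sire = si, dam = di)
}

#' Numerator relationship matrix by the tabular method
#'
#' Computes the additive (numerator) relationship matrix `A` by the tabular
#' recursion `a(i,j) = (a(j,s_i) + a(j,d_i))/2` for `j < i` and
#' `a(i,i) = 1 + a(s_i,d_i)/2`; unknown parents contribute 0. Inbreeding
#' coefficients are `diag(A) - 1`.
#'
#' @param ped a sorted [pedigree_table()].
#' @return list of class `"relationship_structure"` with elements `a_matrix`
#'   (dense symmetric matrix, dimnames = animal ids), `inbreeding` (named
#'   numeric) and `animal` (ids in pedigree order).
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  pi <- ped_parent_index(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- pi$sire[i]; d <- pi$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[s, j]
      if (d > 0L) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  ids <- as.character(ped$animal)
  dimnames(A) <- list(ids, ids)
  structure(
    list(a_matrix = A, inbreeding = stats::setNames(diag(A) - 1, ids),
         animal = ped$animal),
    class = "relationship_structure"
  )
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes per-animal inbreeding coefficients F without forming the dense
#' relationship matrix, tracing each animal's ancestor list and accumulating
#' `L^2 * D` contributions (D = Mendelian sampling variance of the ancestor).
#'
#' @param ped a sorted [pedigree_table()].
#' @return named numeric vector of F in pedigree order.
#' @export
inbreeding_coefficients <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  pi <- ped_parent_index(ped)
  n <- nrow(ped)
  F <- numeric(n)
  Dv <- numeric(n)  # Mendelian sampling variance of each animal
  for (i in seq_len(n)) {
    s <- pi$sire[i]; d <- pi$dam[i]
    Dv[i] <-
      if (s > 0L && d > 0L) 0.5 - 0.25 * (F[s] + F[d])
      else if (s > 0L) 0.75 - 0.25 * F[s]
      else if (d > 0L) 0.75 - 0.25 * F[d]
      else 1
    if (s == 0L || d == 0L) { F[i] <- 0; next }
    # a(s,d)/2: accumulate over the joint ancestor expansion of i
    L <- numeric(n)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      sj <- pi$sire[j]; dj <- pi$dam[j]
      if (sj > 0L) L[sj] <- L[sj] + 0.5 * L[j]
      if (dj > 0L) L[dj] <- L[dj] + 0.5 * L[j]
      aii <- aii + L[j]^2 * Dv[j]
    }
    F[i] <- aii - 1
  }
  stats::setNames(F, as.character(ped$animal))
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Direct construction of `A^-1` by Henderson's rules with inbreeding from the
#' Meuwissen-Luo recursion: each animal contributes `1/d_i` to the inverse,
#' where `d_i = 1 - 0.25(1+F_s) - 0.25(1+F_d)` (terms present for known
#' parents) is its Mendelian sampling variance.
#'
#' @param ped a sorted [pedigree_table()].
#' @return list of class `"relationship_structure"` with `a_inverse` (sparse
#'   `dsCMatrix`), `inbreeding`, and `animal`.
#' @export
relationship_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  pi <- ped_parent_index(ped)
  n <- nrow(ped)
  F <- inbreeding_coefficients(ped)
  # accumulate triplets per animal, assemble once
  ti <- vector("list", n); tj <- vector("list", n); tx <- vector("list", n)
  for (i in seq_len(n)) {
    s <- pi$sire[i]; d <- pi$dam[i]
    di <- 1 -
      (if (s > 0L) 0.25 * (1 + F[s]) else 0) -
      (if (d > 0L) 0.25 * (1 + F[d]) else 0)
    b <- 1 / di
    I <- i; J <- i; X <- b
    for (p in c(s, d)) {
      if (p > 0L) {
        I <- c(I, i, p); J <- c(J, p, i); X <- c(X, -b / 2, -b / 2)
      }
    }
    if (s > 0L) { I <- c(I, s); J <- c(J, s); X <- c(X, b / 4) }
    if (d > 0L) { I <- c(I, d); J <- c(J, d); X <- c(X, b / 4) }
    if (s > 0L && d > 0L) {
      I <- c(I, s, d); J <- c(J, d, s); X <- c(X, b / 4, b / 4)
    }
    ti[[i]] <- I; tj[[i]] <- J; tx[[i]] <- X
  }
  Ainv <- Matrix::sparseMatrix(
    i = unlist(ti), j = unlist(tj), x = unlist(tx), dims = c(n, n),
    dimnames = list(as.character(ped$animal), as.character(ped$animal))
  )
  Ainv <- Matrix::forceSymmetric(Ainv)
  structure(
    list(a_inverse = Ainv, inbreeding = F, animal = ped$animal),
    class = "relationship_structure"
  )
}

# internal: pairwise additive relationships among `ids`, computed on the
# ancestor closure only (used by the breeding simulator for mate restrictions)
pairwise_relationship <- function(ped, ids) {
  id_all <- as.character(ped$animal)
  keep <- logical(nrow(ped))
  keep[match(as.character(ids), id_all)] <- TRUE
  pi <- ped_parent_index(ped)
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (pi$sire[i] > 0L) keep[pi$sire[i]] <- TRUE
      if (pi$dam[i] > 0L) keep[pi$dam[i]] <- TRUE
    }
  }
  sub <- ped[keep, , drop = FALSE]
  sub$sire[!(as.character(sub$sire) %in% as.character(sub$animal))] <- 0
  sub$dam[!(as.character(sub$dam) %in% as.character(sub$animal))] <- 0
  class(sub) <- c("pedigree_table", "data.frame")
  A <- relationship_matrix(sub)$a_matrix
  A[as.character(ids), as.character(ids), drop = FALSE]
}
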