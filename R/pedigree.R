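#' Read a pedigree file
#'
#' Reads a whitespace-delimited pedigree file with three columns
#' `animal sire dam` (the blupf90 dialect). `0` (or `NA`) marks an unknown
#' parent. Identifiers may be arbitrary strings; [renumber_pedigree()] maps
#' them to consecutive integer codes with parents preceding offspring.
#'
#' @param path path to the pedigree file.
#' @return A tibble with character columns `animal`, `sire`, `dam`.
#' @seealso [renumber_pedigree()]
#' @export
read_pedigree <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = FALSE, colClasses = "character",
                          col.names = c("animal", "sire", "dam"))
  tibble::as_tibble(df)
}

#' Renumber a pedigree topologically
#'
#' Assigns consecutive integer codes `1..n` such that every parent's code is
#' strictly smaller than its offspring's code, validates that all non-zero
#' parents appear as animals, and rejects cycles and duplicate animals.
#'
#' @param ped tibble/data frame with columns `animal`, `sire`, `dam`
#'   (characters or integers; `0`/`NA` = unknown parent).
#' @return A tibble of class `mcg_pedigree` with integer columns
#'   `animal`, `sire`, `dam` (codes; 0 = unknown) and an `id_map` attribute,
#'   a tibble mapping original `id` to `code`.
#' @examples
#' renumber_pedigree(tibble::tibble(animal = c("c", "a", "b"),
#'                                  sire = c("a", "0", "0"),
#'                                  dam = c("b", "0", "0")))
#' @export
renumber_pedigree <- function(ped) {
  ped <- tibble::as_tibble(ped)
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  id <- as.character(ped$animal)
  sire <- as.character(ped$sire)
  dam <- as.character(ped$dam)
  sire[is.na(sire)] <- "0"
  dam[is.na(dam)] <- "0"
  if (anyDuplicated(id)) {
    abort(sprintf("duplicated animal id(s): %s",
                  paste(unique(id[duplicated(id)])[1:3], collapse = ", ")))
  }
  known <- c("0", id)
  missing_par <- setdiff(c(sire, dam), known)
  if (length(missing_par)) {
    abort(sprintf("parent id(s) not present as animals: %s",
                  paste(utils::head(missing_par, 5), collapse = ", ")))
  }
  n <- length(id)
  pos <- stats::setNames(seq_len(n), id)
  s_idx <- ifelse(sire == "0", 0L, pos[sire])
  d_idx <- ifelse(dam == "0", 0L, pos[dam])
  # Kahn topological sort (parents before offspring)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(s_idx[i], d_idx[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != n) abort("pedigree contains a cycle")
  code <- integer(n)
  code[order] <- seq_len(n)
  recode <- function(v) {
    out <- integer(n)
    nz <- v > 0L
    out[nz] <- code[v[nz]]
    out
  }
  out <- tibble::tibble(
    animal = seq_len(n),
    sire = recode(s_idx[order]),
    dam  = recode(d_idx[order])
  )
  attr(out, "id_map") <- tibble::tibble(id = id[order], code = seq_len(n))
  class(out) <- c("mcg_pedigree", class(out))
  out
}

# Accept either an already-renumbered mcg_pedigree or raw ids.
as_pedigree <- function(ped) {
  if (inherits(ped, "mcg_pedigree")) return(ped)
  renumber_pedigree(ped)
}

#' Inbreeding coefficients and Mendelian sampling variances
#'
#' Computes inbreeding coefficients `F` by the Meuwissen–Luo recursion
#' (tracing each animal's ancestor contributions through the Cholesky
#' decomposition A = TDT') and the Mendelian sampling variance fraction
#' `phi`: `0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_p` with one parent known, and 1 with none.
#'
#' @param ped a renumbered pedigree ([renumber_pedigree()]).
#' @return A tibble with columns `animal`, `f` (inbreeding) and `phi`.
#' @export
compute_inbreeding_phi <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  s <- ped$sire; d <- ped$dam
  f <- numeric(n)
  phi <- numeric(n)
  # phi of animal j, given F of its parents (codes < j)
  phi_of <- function(sj, dj) {
    if (sj > 0L && dj > 0L) 0.5 - 0.25 * (f[sj] + f[dj])
    else if (sj > 0L) 0.75 - 0.25 * f[sj]
    else if (dj > 0L) 0.75 - 0.25 * f[dj]
    else 1.0
  }
  L <- numeric(n)
  for (i in seq_len(n)) {
    if (s[i] == 0L && d[i] == 0L) {
      f[i] <- 0
      phi[i] <- 1
      next
    }
    # a_ii = 1 + F_i = sum_j L_j^2 phi_j over ancestors j (L_i = 1)
    L[seq_len(i)] <- 0
    L[i] <- 1
    acc <- 0
    for (j in i:1) {
      lj <- L[j]
      if (lj == 0) next
      acc <- acc + lj * lj * phi_of(s[j], d[j])
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * lj
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * lj
    }
    f[i] <- acc - 1
    phi[i] <- phi_of(s[i], d[i])
  }
  tibble::tibble(animal = ped$animal, f = f, phi = phi)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding: for animal i with Mendelian
#' sampling variance `d_i = phi_i`, add `1/d_i` at (i,i), `-0.5/d_i` at
#' (i, parent) and `0.25/d_i` at (parent, parent) pairs.
#'
#' @param ped a renumbered pedigree.
#' @param fphi optional result of [compute_inbreeding_phi()] (computed if
#'   missing).
#' @return A sparse symmetric `dgCMatrix` A-inverse.
#' @export
build_a_inverse <- function(ped, fphi = NULL) {
  ped <- as_pedigree(ped)
  if (is.null(fphi)) fphi <- compute_inbreeding_phi(ped)
  n <- nrow(ped)
  phi <- fphi$phi
  if (any(phi <= 0)) abort("non-positive Mendelian sampling variance: corrupt inbreeding input")
  s <- ped$sire; d <- ped$dam
  ii <- jj <- xx <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- c(i, if (s[i] > 0L) s[i], if (d[i] > 0L) d[i])
    w <- c(1, if (s[i] > 0L) -0.5, if (d[i] > 0L) -0.5)
    k <- length(idx)
    ii[[i]] <- rep(idx, each = k)
    jj[[i]] <- rep(idx, times = k)
    xx[[i]] <- as.vector(outer(w, w)) / phi[i]
  }
  A_inv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                                dims = c(n, n))
  Matrix::drop0(Matrix::forceSymmetric(A_inv, uplo = "U"))
}

#' Dense numerator relationship matrix by the tabular method
#'
#' Brute-force recursive (tabular) construction of A; quadratic in the number
#' of animals, intended for desk-scale work and as the independent oracle for
#' the Henderson-rule A-inverse.
#'
#' @param ped a renumbered pedigree.
#' @return Dense symmetric matrix A.
#' @export
pedigree_A <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  s <- ped$sire; d <- ped$dam
  for (i in seq_len(n)) {
    ai_sd <- if (s[i] > 0L && d[i] > 0L) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * ai_sd
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s[i] > 0L) row <- row + 0.5 * A[prev, s[i]]
      if (d[i] > 0L) row <- row + 0.5 * A[prev, d[i]]
      A[i, prev] <- row
      A[prev, i] <- row
    }
  }
  A
}

#' Pedigree relationships among the genotyped subset
#'
#' Dense `A22`, the block of the numerator relationship matrix for the
#' genotyped animals (tabular method; desk scale).
#'
#' @param ped renumbered pedigree.
#' @param geno_codes codes of the genotyped animals.
#' @return dense symmetric matrix.
#' @export
pedigree_A22 <- function(ped, geno_codes) {
  A <- pedigree_A(ped)
  A[geno_codes, geno_codes, drop = FALSE]
}
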