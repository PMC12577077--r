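#' Implicit H-inverse operator
#'
#' The single-step relationship matrix H combines pedigree and genomic
#' information; its inverse is `A^{-1}` plus a correction `G^{-1} - A22^{-1}`
#' on the genotyped block. This constructor pre-factorises everything needed
#' to apply `H^{-1}` (and the auxiliary products `A22^{-1} x`,
#' `A12 A22^{-1} x`) without ever forming H:
#' \itemize{
#'   \item the sparse Henderson `A^{-1}` and its diagonal blocks,
#'   \item a dense Cholesky of `A22` (direct backend),
#'   \item a sparse Cholesky of the non-genotyped block of `A^{-1}` for the
#'     identity `A22^{-1}x = A^{22}x - A^{21}(A^{11})^{-1}A^{12}x`
#'     (superscripts = blocks of `A^{-1}`, 1 = non-genotyped, 2 = genotyped),
#'   \item either a dense inverse of the blended G or its APY sparse inverse.
#' }
#' With no genotyped animals the operator reduces to `A^{-1}`.
#'
#' @param ped renumbered pedigree.
#' @param genomic optional `mcg_genomic` ([build_genomic()]).
#' @param apy optional `mcg_apy` ([apy_decompose()]); if supplied, the APY
#'   sparse inverse replaces the dense G inverse.
#' @param fphi optional output of [compute_inbreeding_phi()].
#' @return A list of class `mcg_hop`.
#' @export
h_operator <- function(ped, genomic = NULL, apy = NULL, fphi = NULL) {
  ped <- as_pedigree(ped)
  if (is.null(fphi)) fphi <- compute_inbreeding_phi(ped)
  a_inv <- build_a_inverse(ped, fphi)
  n <- nrow(ped)
  op <- list(ped = ped, fphi = fphi, a_inv = a_inv, n = n,
             geno_idx = integer(0), genomic = genomic, apy = apy)
  if (!is.null(genomic)) {
    gi <- genomic$ids
    stopifnot(all(gi >= 1L & gi <= n))
    op$geno_idx <- gi
    op$A22 <- genomic$A22
    op$A22_chol <- chol(op$A22)
    nong <- setdiff(seq_len(n), gi)
    op$nong_idx <- nong
    P <- a_inv
    op$P12 <- P[nong, gi, drop = FALSE]
    op$P22 <- P[gi, gi, drop = FALSE]
    if (length(nong)) {
      op$P11_chol <- Matrix::Cholesky(Matrix::forceSymmetric(P[nong, nong, drop = FALSE]),
                                      LDL = FALSE, perm = TRUE)
    }
    if (!is.null(apy)) {
      stopifnot(identical(apy$ids, gi))
      op$g_inv <- apy$g_inv
    } else {
      op$g_inv <- chol2inv(chol(genomic$g_blend))
    }
  }
  class(op) <- "mcg_hop"
  op
}

#' Apply the inverse of A22
#'
#' Computes `A22^{-1} x2` (`mode = "solve"`) or the quadratic form
#' `x2' A22^{-1} x2` (`mode = "quad"`) over the genotyped animals. Backend
#' `"factor"` uses the dense Cholesky of A22; backend `"ainv"` uses the sparse
#' identity through the blocks of `A^{-1}`. Both are kept so they can
#' cross-check each other.
#'
#' @param op an `mcg_hop` operator.
#' @param x2 numeric vector or matrix over the genotyped animals.
#' @param mode `"solve"` or `"quad"`.
#' @param backend `"factor"` or `"ainv"`.
#' @return vector/matrix (`solve`) or scalar/matrix of quadratic forms
#'   (`quad`, computed as `crossprod(x2, A22^{-1} x2)`).
#' @export
a22_apply <- function(op, x2, mode = c("solve", "quad"), backend = c("factor", "ainv")) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  stopifnot(inherits(op, "mcg_hop"), length(op$geno_idx) > 0)
  x2 <- as.matrix(x2)
  stopifnot(nrow(x2) == length(op$geno_idx))
  if (backend == "factor") {
    y <- backsolve(op$A22_chol, forwardsolve(op$A22_chol, x2, upper.tri = TRUE, transpose = TRUE))
  } else {
    y <- as.matrix(op$P22 %*% x2)
    if (length(op$nong_idx)) {
      w <- as.matrix(Matrix::solve(op$P11_chol, op$P12 %*% x2, system = "A"))
      y <- y - as.matrix(Matrix::t(op$P12) %*% w)
    }
  }
  if (mode == "solve") drop(y) else drop(crossprod(x2, y))
}

# A12 %*% A22^{-1} %*% x2 mapped to the non-genotyped animals.
# Default backend uses the sparse identity A12 A22^{-1} = -(A^11)^{-1} A^12;
# "dense" solves A22 w = x2 and multiplies by dense A12 (cross-check path).
a12_a22inv_apply <- function(op, x2, backend = c("ainv", "dense")) {
  backend <- match.arg(backend)
  x2 <- as.matrix(x2)
  if (!length(op$nong_idx)) return(matrix(0, 0, ncol(x2)))
  if (backend == "ainv") {
    -as.matrix(Matrix::solve(op$P11_chol, op$P12 %*% x2, system = "A"))
  } else {
    A <- pedigree_A(op$ped)
    A12 <- A[op$nong_idx, op$geno_idx, drop = FALSE]
    w <- a22_apply(op, x2, mode = "solve", backend = "factor")
    A12 %*% as.matrix(w)
  }
}

#' Apply the H-inverse operator
#'
#' Evaluates `H^{-1} x` (`mode = "matvec"`) or the bilinear form
#' `x' H^{-1} y` (`mode = "bilinear"`) through the decomposition
#' `x'H^{-1}y = x'A^{-1}y + x2'G^{-1}y2 - x2'A22^{-1}y2`, never forming H.
#'
#' @param op an `mcg_hop` operator.
#' @param x numeric vector or matrix over all pedigree animals.
#' @param y optional second argument for the bilinear form (defaults to `x`).
#' @param mode `"matvec"` or `"bilinear"`.
#' @return `H^{-1} x` or the (matrix of) bilinear form values.
#' @export
h_inverse_apply <- function(op, x, y = NULL, mode = c("matvec", "bilinear")) {
  mode <- match.arg(mode)
  stopifnot(inherits(op, "mcg_hop"))
  x <- as.matrix(x)
  stopifnot(nrow(x) == op$n)
  gi <- op$geno_idx
  if (mode == "matvec") {
    out <- as.matrix(op$a_inv %*% x)
    if (length(gi)) {
      x2 <- x[gi, , drop = FALSE]
      corr <- as.matrix(op$g_inv %*% x2) - as.matrix(a22_apply(op, x2, "solve"))
      out[gi, ] <- out[gi, ] + corr
    }
    drop(out)
  } else {
    if (is.null(y)) y <- x
    y <- as.matrix(y)
    stopifnot(nrow(y) == op$n)
    val <- as.matrix(crossprod(x, op$a_inv %*% y))
    if (length(gi)) {
      x2 <- x[gi, , drop = FALSE]
      y2 <- y[gi, , drop = FALSE]
      val <- val + as.matrix(crossprod(x2, op$g_inv %*% y2)) -
        as.matrix(crossprod(x2, as.matrix(a22_apply(op, y2, "solve"))))
    }
    drop(val)
  }
}

# Materialised sparse H^{-1} (desk scale): A^{-1} plus the genotyped-block
# correction. Used to assemble the MME coefficient matrix.
h_inv_matrix <- function(op) {
  H <- op$a_inv
  gi <- op$geno_idx
  if (length(gi)) {
    A22inv <- chol2inv(op$A22_chol)
    corr <- as.matrix(op$g_inv) - A22inv
    n <- op$n
    S <- Matrix::sparseMatrix(i = rep(gi, times = length(gi)),
                              j = rep(gi, each = length(gi)),
                              x = as.vector(corr), dims = c(n, n))
    H <- H + S
  }
  Matrix::forceSymmetric(Matrix::drop0(H, tol = 0))
}

# Dense H from its block formula (independent oracle route):
# H22 = G, H12 = A12 A22^{-1} G, H11 = A11 + A12 A22^{-1} (G - A22) A22^{-1} A21.
h_dense <- function(ped, g_blend, geno_idx) {
  ped <- as_pedigree(ped)
  A <- pedigree_A(ped)
  n <- nrow(A)
  gi <- geno_idx
  ni <- setdiff(seq_len(n), gi)
  H <- A
  A22 <- A[gi, gi, drop = FALSE]
  G <- as.matrix(g_blend)
  if (length(ni)) {
    B <- A[ni, gi, drop = FALSE] %*% solve(A22)  # A12 A22^{-1}
    H[ni, gi] <- B %*% G
    H[gi, ni] <- t(H[ni, gi])
    H[ni, ni] <- A[ni, ni] + B %*% (G - A22) %*% t(B)
  }
  H[gi, gi] <- G
  H
}

# log|H| = log|A| - log|A22| + log|G| (identity groups contribute 0).
h_logdet <- function(op) {
  logA <- sum(log(op$fphi$phi))
  if (!length(op$geno_idx)) return(logA)
  logA22 <- 2 * sum(log(diag(op$A22_chol)))
  logG <- if (!is.null(op$apy)) {
    # |G_apy| = |G_cc| * prod(Psi)
    -determinant(as.matrix(op$apy$g_cc_inv), logarithm = TRUE)$modulus +
      sum(log(op$apy$psi))
  } else {
    as.numeric(determinant(op$genomic$g_blend, logarithm = TRUE)$modulus)
  }
  logA - logA22 + as.numeric(logG)
}
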