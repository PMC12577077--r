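#' Assemble the mixed-model-equations operator
#'
#' Builds the coefficient matrix `C = Q'R^{-1}Q + sum_k theta_k^{-1} (x) K_k^{-1}`
#' of Henderson's mixed model equations as one sparse symmetric matrix (the
#' H-group blocks use the scatter structure `A^{-1} + (G^{-1} - A22^{-1})`),
#' together with a block-diagonal preconditioner over (level x group-column)
#' blocks in which zero pivots — equations untouched by data and prior, e.g.
#' redundant fixed levels — are pseudo-inverted.
#'
#' @param design an `mcg_design`.
#' @param theta an `mcg_theta` variance state.
#' @param hop an `mcg_hop` H-inverse operator (required if any group has
#'   `kind = "h"`).
#' @return A list of class `mcg_mme` with the sparse matrix `C`, the sparse
#'   preconditioner `Pinv`, the right-hand-side helper pieces (`Rinv`, `rhs`)
#'   and references to `design`, `theta`, `hop`.
#' @export
assemble_operator <- function(design, theta, hop = NULL) {
  Rinv <- rinv_matrix(design, theta$R0)
  QtRi <- Matrix::t(design$Q) %*% Rinv
  C <- QtRi %*% design$Q
  Kinv_h <- NULL
  for (g in design$groups) {
    th <- theta$groups[[g$name]]
    th_inv <- tryCatch(solve(th), error = function(e)
      abort(sprintf("singular covariance matrix for group '%s'", g$name)))
    if (g$kind == "h") {
      if (is.null(hop)) abort("an H operator is required for pedigree/H groups")
      if (is.null(Kinv_h)) Kinv_h <- h_inv_matrix(hop)
      Kin <- Kinv_h
    } else {
      Kin <- Matrix::Diagonal(g$q)
    }
    blk <- kronecker(as(th_inv, "CsparseMatrix"), Kin)
    idx <- g$eq_offset + seq_len(g$t * g$q)
    C[idx, idx] <- C[idx, idx] + blk
  }
  C <- Matrix::forceSymmetric(Matrix::drop0(C, tol = 0))
  rhs <- as.numeric(QtRi %*% design$y)
  op <- list(C = C, design = design, theta = theta, hop = hop,
             Rinv = Rinv, rhs = rhs, n_eq = design$n_eq,
             factor = NULL)
  op$Pinv <- build_preconditioner(op)
  class(op) <- "mcg_mme"
  op
}

# Block-diagonal preconditioner: fixed equations are 1x1 blocks; for group k
# the block of level i collects its t_k coupled equations. Zero pivots are
# pseudo-inverted (dropped from the block before inversion).
build_preconditioner <- function(op) {
  design <- op$design
  Cd <- op$C
  dC <- Matrix::diag(Cd)
  ii <- jj <- xx <- list()
  if (design$n_fixed > 0) {
    d <- dC[seq_len(design$n_fixed)]
    pinv <- ifelse(d > 0, 1 / d, 0)
    ii[[1]] <- seq_len(design$n_fixed); jj[[1]] <- ii[[1]]; xx[[1]] <- pinv
  }
  for (g in design$groups) {
    tk <- g$t; q <- g$q
    base <- g$eq_offset
    if (tk == 1L) {
      idx <- base + seq_len(q)
      d <- dC[idx]
      ii[[length(ii) + 1L]] <- idx; jj[[length(jj) + 1L]] <- idx
      xx[[length(xx) + 1L]] <- ifelse(d > 0, 1 / d, 0)
    } else {
      idx_mat <- sapply(seq_len(tk), function(c) base + (c - 1L) * q + seq_len(q))
      # gather the tk x tk diagonal blocks: entries C[idx_mat[i,a], idx_mat[i,b]]
      sub <- as.matrix(Cd[as.vector(idx_mat), as.vector(idx_mat)])
      for (i in seq_len(q)) {
        rows <- seq(i, by = q, length.out = tk)
        blk <- sub[rows, rows, drop = FALSE]
        binv <- pseudo_inv_sym(blk)
        ii[[length(ii) + 1L]] <- rep(idx_mat[i, ], each = tk)
        jj[[length(jj) + 1L]] <- rep(idx_mat[i, ], times = tk)
        xx[[length(xx) + 1L]] <- as.vector(binv)
      }
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(op$n_eq, op$n_eq), symmetric = FALSE)
}

# symmetric pseudo-inverse of a small block (zero rows/cols dropped)
pseudo_inv_sym <- function(blk) {
  k <- nrow(blk)
  act <- which(diag(blk) > 0)
  out <- matrix(0, k, k)
  if (length(act)) {
    sub <- blk[act, act, drop = FALSE]
    inv <- tryCatch(chol2inv(chol(sub)), error = function(e) {
      e <- eigen(sub, symmetric = TRUE)
      pos <- e$values > max(e$values) * 1e-12
      e$vectors[, pos, drop = FALSE] %*% ((1 / e$values[pos]) * t(e$vectors[, pos, drop = FALSE]))
    })
    out[act, act] <- inv
  }
  out
}

#' Solve the mixed model equations by preconditioned conjugate gradients
#'
#' Standard PCG on the assembled sparse coefficient matrix with the
#' block-diagonal preconditioner. `rhs` may be a matrix, in which case all
#' columns are iterated jointly until every column satisfies the relative
#' residual tolerance (used for the blocked Monte Carlo sample solves).
#'
#' @param op an `mcg_mme` operator.
#' @param rhs right-hand side vector or matrix (defaults to the data
#'   right-hand side `Q'R^{-1}y`).
#' @param tol relative residual tolerance `||C x - rhs|| / ||rhs||`.
#' @param max_iter iteration cap; reaching it flags the solution and warns.
#' @param warm_start optional starting value.
#' @return A list of class `mcg_solution`: `sol` (same shape as `rhs`),
#'   `iterations`, `converged`, `rel_resid`.
#' @export
pcg_solve <- function(op, rhs = op$rhs, tol = 1e-10, max_iter = 5000L,
                      warm_start = NULL) {
  C <- op$C
  Pinv <- op$Pinv
  b <- as.matrix(rhs)
  nc <- ncol(b)
  x <- if (is.null(warm_start)) matrix(0, nrow(b), nc) else as.matrix(warm_start)
  bnorm <- sqrt(colSums(b^2))
  bnorm[bnorm == 0] <- 1
  r <- b - as.matrix(C %*% x)
  z <- as.matrix(Pinv %*% r)
  p <- z
  rz <- colSums(r * z)
  it <- 0L
  repeat {
    rel <- sqrt(colSums(r^2)) / bnorm
    if (all(rel <= tol) || it >= max_iter) break
    Cp <- as.matrix(C %*% p)
    alpha <- rz / colSums(p * Cp)
    alpha[!is.finite(alpha)] <- 0
    x <- x + sweep(p, 2L, alpha, "*")
    r <- r - sweep(Cp, 2L, alpha, "*")
    if (anyNA(r) || any(!is.finite(r))) abort("PCG diverged (non-finite iterates)")
    z <- as.matrix(Pinv %*% r)
    rz_new <- colSums(r * z)
    beta <- rz_new / rz
    beta[!is.finite(beta)] <- 0
    p <- z + sweep(p, 2L, beta, "*")
    rz <- rz_new
    it <- it + 1L
  }
  converged <- all(rel <= tol)
  if (!converged) {
    warn(sprintf("PCG stopped at max_iter = %d (max relative residual %.2e)",
                 max_iter, max(rel)))
  }
  structure(list(sol = if (nc == 1L && !is.matrix(rhs)) drop(x) else x,
                 iterations = it, converged = converged,
                 rel_resid = max(rel)),
            class = "mcg_solution")
}

# Direct sparse-Cholesky solve (cached factor); used for the data solve and
# the AI right-hand sides on full-rank systems at desk scale.
direct_solve <- function(op, rhs) {
  if (is.null(op$factor)) {
    op$factor <- Matrix::Cholesky(op$C, LDL = FALSE, perm = TRUE)
  }
  list(op = op, sol = as.matrix(Matrix::solve(op$factor, rhs, system = "A")))
}

#' Solve the data MME and derive solution-side quantities
#'
#' Convenience wrapper: solves `C sol = Q'R^{-1}y`, splits the solutions by
#' effect, and computes observation-level fitted values and residuals.
#'
#' @param op an `mcg_mme` operator.
#' @param tol,max_iter,warm_start passed to [pcg_solve()].
#' @param method `"pcg"` or `"direct"` (sparse Cholesky; requires a full-rank
#'   system).
#' @return list of class `mcg_fit_solution` with `sol`, `e_hat`
#'   (observation-level residuals), `yhat`, `iterations`, `converged`.
#' @export
solve_mme <- function(op, tol = 1e-10, max_iter = 5000L, warm_start = NULL,
                      method = c("pcg", "direct")) {
  method <- match.arg(method)
  if (method == "direct") {
    ds <- direct_solve(op, op$rhs)
    sol <- drop(ds$sol)
    iterations <- NA_integer_
    converged <- TRUE
  } else {
    ps <- pcg_solve(op, op$rhs, tol = tol, max_iter = max_iter,
                    warm_start = warm_start)
    sol <- ps$sol
    iterations <- ps$iterations
    converged <- ps$converged
  }
  yhat <- as.numeric(op$design$Q %*% sol)
  structure(list(sol = sol, yhat = yhat, e_hat = op$design$y - yhat,
                 iterations = iterations, converged = converged),
            class = "mcg_fit_solution")
}

#' Solution-side quadratic forms
#'
#' Computes, for each random group, the matrix `S_k` of bilinear forms
#' `u_i' K^{-1} u_j` over the group's columns (through the H-inverse operator
#' for pedigree/H groups, plain dot products for identity groups), and the
#' residual products `e_i'e_j` over records where both traits are observed.
#'
#' @param solution an `mcg_fit_solution` (or any list with `sol`, `e_hat`).
#' @param op the `mcg_mme` operator used for the solve.
#' @return list of class `mcg_quadforms`: `S` (named list of matrices),
#'   `resid_raw` (matrix of `e_i'e_j`), `e_star` (R^{-1} e per observation),
#'   `n_ij`.
#' @export
compute_quadforms <- function(solution, op) {
  design <- op$design
  S <- list()
  for (g in design$groups) {
    U <- sapply(seq_len(g$t), function(c) solution$sol[group_col_idx(design, g$name, c)])
    U <- matrix(U, ncol = g$t)
    if (g$kind == "h") {
      S[[g$name]] <- as.matrix(h_inverse_apply(op$hop, U, mode = "bilinear"))
    } else {
      S[[g$name]] <- crossprod(U)
    }
  }
  Emat <- obs_to_matrix(design, solution$e_hat)
  resid_raw <- crossprod(Emat)  # zeros at missing entries make this the both-observed sum
  e_star <- as.numeric(op$Rinv %*% solution$e_hat)
  structure(list(S = S, resid_raw = resid_raw, e_star = e_star,
                 n_ij = design$n_ij),
            class = "mcg_quadforms")
}
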