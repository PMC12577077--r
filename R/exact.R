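# Exact (dense) reference computations on small instances: the test bed
# standing in for the exact ss-GREML benchmark.

MCG_DENSE_GUARD <- 5000L

#' Exact PEV traces from the dense inverse of C
#'
#' Computes every trace the REML derivatives need by explicit blocks of
#' `C^{-1}`: per group `T_k[i,j] = tr(K^{-1} C^{k_i k_j})` and, per
#' missingness pattern, the matrices `Wsum_pi[c,d] = sum_{rec in pi}
#' (Q C^{-1} Q')_{cd}`. Returned as an `mcg_traceset`, so it is a drop-in
#' replacement for [run_mc_round()].
#'
#' @param op an `mcg_mme` operator (at most 5000 equations).
#' @return An `mcg_traceset` with attribute `"Cinv"` (reused by the AI
#'   matrix).
#' @export
exact_traces <- function(op) {
  design <- op$design
  if (design$n_eq > MCG_DENSE_GUARD) {
    abort(sprintf("dense oracle limited to %d equations (model has %d)",
                  MCG_DENSE_GUARD, design$n_eq))
  }
  Cd <- as.matrix(op$C)
  Cinv <- tryCatch(solve(Cd), error = function(e)
    abort("dense C is singular; exact traces need a full-rank system"))
  Tmats <- list()
  Kinv_h <- NULL
  for (g in design$groups) {
    if (g$kind == "h" && is.null(Kinv_h)) Kinv_h <- as.matrix(h_inv_matrix(op$hop))
    tk <- g$t
    Tm <- matrix(0, tk, tk)
    for (i in seq_len(tk)) for (j in i:tk) {
      B <- Cinv[group_col_idx(design, g$name, i),
                group_col_idx(design, g$name, j), drop = FALSE]
      Tm[i, j] <- Tm[j, i] <- if (g$kind == "h") sum(Kinv_h * t(B)) else sum(diag(B))
    }
    Tmats[[g$name]] <- Tm
  }
  # per-pattern Wsum from row products of Q C^{-1} and Q
  t <- length(design$traits)
  V1 <- as.matrix(design$Q %*% Cinv)
  Qd <- as.matrix(design$Q)
  pos <- matrix(0L, design$n_rec, t)
  pos[cbind(design$obs_rec, design$obs_trait)] <- seq_len(design$n_obs)
  resid_wsum <- list()
  for (p in seq_along(design$patterns)) {
    recs <- which(design$pattern_of == p)
    msk <- design$patterns[[p]]
    tr <- which(msk)
    Wp <- matrix(0, t, t)
    for (a in seq_along(tr)) for (b in seq_along(tr)) {
      o1 <- pos[recs, tr[a]]
      o2 <- pos[recs, tr[b]]
      Wp[tr[a], tr[b]] <- sum(V1[o1, , drop = FALSE] * Qd[o2, , drop = FALSE])
    }
    resid_wsum[[p]] <- (Wp + t(Wp)) / 2
  }
  out <- new_traceset(Tmats, resid_wsum, s = Inf, variant = "exact")
  attr(out, "Cinv") <- Cinv
  out
}

#' Exact ss-GREML reference fit
#'
#' Runs the same EM/AI loop as [run_reml()] with the traces computed exactly
#' from the dense inverse of C: the benchmark that Monte Carlo runs are
#' validated against.
#'
#' @inheritParams run_reml
#' @return An `mcg_reml` object.
#' @export
exact_reml_reference <- function(ped, pheno, spec, geno = NULL,
                                 method = c("ai", "em"), theta0 = NULL,
                                 verbose = FALSE) {
  run_reml(ped, pheno, spec, geno = geno, method = match.arg(method),
           traces = "exact", theta0 = theta0, verbose = verbose)
}

#' Central finite differences of the exact restricted -2 logL
#'
#' Independent check of the analytic gradient: each free parameter is
#' perturbed symmetrically (both (i,j) and (j,i)) by `step` and the exact
#' [restricted_loglik()] differenced.
#'
#' @param design,theta,hop model pieces; `index` free-parameter index;
#'   `step` perturbation size.
#' @return numeric vector over the free parameters.
#' @export
finite_difference_gradient <- function(design, theta, hop,
                                       index = theta_index(theta),
                                       step = 1e-5) {
  if (step < .Machine$double.eps^0.75) warn("finite-difference step underflow")
  v0 <- theta_to_vech(theta, index)
  vapply(seq_len(nrow(index)), function(r) {
    vp <- v0; vp[r] <- vp[r] + step
    vm <- v0; vm[r] <- vm[r] - step
    lp <- restricted_loglik(design, vech_to_theta(theta, vp, index), hop)
    lm <- restricted_loglik(design, vech_to_theta(theta, vm, index), hop)
    (lp - lm) / (2 * step)
  }, numeric(1))
}

#' Dense-V evaluation of the restricted -2 logL
#'
#' Builds `V = sum_k Z_k (theta_k (x) K_k) Z_k' + R` explicitly (H from its
#' dense block formula) and evaluates
#' `log|V| + log|X'V^{-1}X| + y'Py` directly. Tiny instances only; this is the
#' independent oracle for [restricted_loglik()].
#'
#' @param design,theta,hop model pieces.
#' @return scalar `-2 logL` (same constant convention as
#'   [restricted_loglik()]).
#' @export
loglik_dense_V <- function(design, theta, hop) {
  n_obs <- design$n_obs
  if (n_obs > 2000L) abort("dense V oracle limited to 2000 observations")
  K_h <- NULL
  V <- matrix(0, n_obs, n_obs)
  for (g in design$groups) {
    if (g$kind == "h") {
      if (is.null(K_h)) {
        K_h <- if (length(hop$geno_idx)) {
          h_dense(hop$ped, hop$genomic$g_blend, hop$geno_idx)
        } else {
          pedigree_A(hop$ped)
        }
      }
      K <- K_h
    } else {
      K <- diag(g$q)
    }
    Sig <- kronecker(theta$groups[[g$name]], K)
    Z <- as.matrix(design$Z[[g$name]])
    V <- V + Z %*% Sig %*% t(Z)
  }
  # residual: R0 entries at same-record observation pairs
  for (r in seq_len(design$n_rec)) {
    oo <- which(design$obs_rec == r)
    V[oo, oo] <- V[oo, oo] + theta$R0[design$obs_trait[oo], design$obs_trait[oo]]
  }
  X <- as.matrix(design$X)
  Vinv <- solve(V)
  XtViX <- crossprod(X, Vinv %*% X)
  P <- Vinv - Vinv %*% X %*% solve(XtViX, crossprod(X, Vinv))
  as.numeric(determinant(V, logarithm = TRUE)$modulus) +
    as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
    as.numeric(crossprod(design$y, P %*% design$y))
}
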