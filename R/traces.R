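# Hutchinson-type Monte Carlo approximation of the PEV traces.
#
# A TraceSet carries, per random group, the estimate of
#   T_k[i,j] = tr(K^{-1} C^{k_i k_j})
# and, for the residual, per-missingness-pattern matrices
#   Wsum_pi[c,d] = sum_{rec in pi} (Q C^{-1} Q')_{cd, rec}
# from which both the aggregate estimator
#   tr-hat = n_ij R0[i,j] - s^{-1} sum_l e~hat_i' e~hat_j
# and the full residual gradient term tr(R^{-1} R_ij R^{-1} Q C^{-1} Q') are
# recovered. The primary estimators subtract the sample average of solution
# quadratic forms from the prior quantities; the centered variants average
# quadratic forms of (truth - estimate).

new_traceset <- function(T, resid_wsum, s, variant, per_sample = NULL) {
  structure(list(T = T, resid_wsum = resid_wsum, s = s, variant = variant,
                 per_sample = per_sample),
            class = "mcg_traceset")
}

# sum over patterns of the Wsum matrices = the aggregate n_ij-style matrix
resid_wsum_total <- function(traces) Reduce(`+`, traces$resid_wsum)

#' Monte Carlo estimate of a group's PEV trace matrix
#'
#' Given solved Monte Carlo samples, estimates
#' `T_k[i,j] = tr(K^{-1} C^{k_i k_j})`. The primary variant is
#' `q_k theta_k[i,j] - s^{-1} sum_l uhat~_i' K^{-1} uhat~_j`; the centered
#' variant averages `(u~ - uhat~)_i' K^{-1} (u~ - uhat~)_j`.
#'
#' @param samples list of solved samples; each element needs `sol` (MME
#'   solution of the simulated system) and, for the centered variant,
#'   `u_list`.
#' @param op the `mcg_mme` operator the samples were solved with.
#' @param gname group name.
#' @param variant `"primary"` or `"centered"`.
#' @return symmetric `t_k x t_k` matrix.
#' @export
estimate_trace_Tk <- function(samples, op, gname, variant = c("primary", "centered")) {
  variant <- match.arg(variant)
  s <- length(samples)
  if (s == 0L) abort("no Monte Carlo samples")
  design <- op$design
  g <- design$groups[[gname]]
  theta_k <- op$theta$groups[[gname]]
  acc <- matrix(0, g$t, g$t)
  for (sm in samples) {
    U <- sapply(seq_len(g$t), function(c) sm$sol[group_col_idx(design, gname, c)])
    U <- matrix(U, ncol = g$t)
    if (variant == "centered") U <- matrix(sm$u_list[[gname]], ncol = g$t) - U
    acc <- acc + if (g$kind == "h") {
      as.matrix(h_inverse_apply(op$hop, U, mode = "bilinear"))
    } else {
      crossprod(U)
    }
  }
  if (variant == "primary") g$q * theta_k - acc / s else acc / s
}

#' Monte Carlo estimate of the residual trace term
#'
#' Estimates, per missingness pattern, the matrices
#' `Wsum_pi[c,d] = sum_{rec in pi} (Q C^{-1} Q')_{cd}`; summed over patterns
#' and read at `(i,j)` this is the trace term
#' `n_ij R0[i,j] - s^{-1} sum e~hat_i' e~hat_j` of the residual derivative.
#' Residual vectors are combined with identity weighting (residuals are
#' independent across records given R0).
#'
#' @param samples list of solved samples with `sol`, `y` (simulated records)
#'   and `e` (simulated residuals, needed for the centered variant).
#' @param op the `mcg_mme` operator.
#' @param variant `"primary"` or `"centered"`.
#' @return list of `t x t` matrices, one per missingness pattern (primary:
#'   estimates of `Wsum_pi`; centered: pattern sums of centered products).
#' @export
estimate_trace_residual <- function(samples, op, variant = c("primary", "centered")) {
  variant <- match.arg(variant)
  s <- length(samples)
  if (s == 0L) abort("no Monte Carlo samples")
  design <- op$design
  t <- length(design$traits)
  np <- length(design$patterns)
  acc <- replicate(np, matrix(0, t, t), simplify = FALSE)
  for (sm in samples) {
    ehat <- sm$y - as.numeric(design$Q %*% sm$sol)
    if (variant == "centered") ehat <- sm$e - ehat
    Em <- obs_to_matrix(design, ehat)
    for (p in seq_len(np)) {
      recs <- design$pattern_of == p
      acc[[p]] <- acc[[p]] + crossprod(Em[recs, , drop = FALSE])
    }
  }
  if (variant == "primary") {
    lapply(seq_len(np), function(p) {
      n_p <- sum(design$pattern_of == p)
      msk <- design$patterns[[p]]
      Rp <- op$theta$R0
      Rp[!msk, ] <- 0; Rp[, !msk] <- 0
      n_p * Rp - acc[[p]] / s
    })
  } else {
    lapply(acc, function(a) a / s)
  }
}

#' Run one Monte Carlo trace round
#'
#' Draws `s` complete samples (breeding values, other random effects,
#' residuals, phenotypes) under the current variance state, solves the mixed
#' model equations for all samples as one blocked PCG system, and accumulates
#' the trace estimators. Deterministic given `(base_seed, round,
#' reuse_sequence)`: with sequence reuse on, the standard normal deviates do
#' not depend on the round.
#'
#' @param op the round's `mcg_mme` operator (same operator as the data solve).
#' @param s number of Monte Carlo samples.
#' @param base_seed stream base seed.
#' @param round round index (only keyed into the stream when
#'   `reuse_sequence = FALSE`).
#' @param reuse_sequence reuse the deviate sequence across rounds.
#' @param apy optional `mcg_apy`.
#' @param variant trace estimator variant.
#' @param tol,max_iter PCG settings for the sample solves.
#' @return An `mcg_traceset`: `T` (named list of group trace matrices),
#'   `resid_wsum` (per-pattern matrices), `s`, and `per_sample` diagnostics
#'   (per-sample group quadratic forms, for Monte Carlo error estimation).
#' @export
run_mc_round <- function(op, s, base_seed, round = 1L, reuse_sequence = TRUE,
                         apy = NULL, variant = c("primary", "centered"),
                         tol = 1e-6, max_iter = 5000L) {
  variant <- match.arg(variant)
  stopifnot(s >= 1)
  design <- op$design
  theta <- op$theta
  seed_eff <- if (reuse_sequence) base_seed else site_seed(base_seed, sprintf("round%d", round))
  draws <- mc_draws(design, theta, op$hop, samples = seq_len(s),
                    base_seed = seed_eff, apy = apy)
  u_all <- draws$u_list
  e_all <- draws$e
  y_all <- draws$y
  rhs <- as.matrix(Matrix::t(design$Q) %*% (op$Rinv %*% y_all))
  sol <- pcg_solve(op, rhs, tol = tol, max_iter = max_iter)$sol
  sol <- as.matrix(sol)

  t <- length(design$traits)
  Tmats <- list()
  per_sample <- list()
  for (g in design$groups) {
    tk <- g$t
    # bilinear forms u_i' K^{-1} u_j for all samples at once
    idx <- lapply(seq_len(tk), function(c) group_col_idx(design, g$name, c))
    Ucols <- lapply(idx, function(ii) sol[ii, , drop = FALSE])   # q x s each
    if (variant == "centered") {
      Ucols <- lapply(seq_len(tk), function(c)
        u_all[[g$name]][(c - 1L) * g$q + seq_len(g$q), , drop = FALSE] - Ucols[[c]])
    }
    if (g$kind == "h") {
      KU <- lapply(Ucols, function(U) h_inverse_apply(op$hop, U, mode = "matvec"))
      KU <- lapply(KU, as.matrix)
    } else {
      KU <- Ucols
    }
    qf <- array(0, dim = c(tk, tk, s))
    for (i in seq_len(tk)) for (j in i:tk) {
      v <- colSums(Ucols[[i]] * KU[[j]])
      qf[i, j, ] <- v
      qf[j, i, ] <- v
    }
    per_sample[[g$name]] <- qf
    mean_qf <- apply(qf, c(1, 2), mean)
    Tmats[[g$name]] <- if (variant == "primary") {
      g$q * theta$groups[[g$name]] - mean_qf
    } else {
      mean_qf
    }
  }
  # residual accumulations per pattern
  ehat <- y_all - as.matrix(design$Q %*% sol)
  if (variant == "centered") ehat <- e_all - ehat
  np <- length(design$patterns)
  resid_wsum <- vector("list", np)
  resid_per_sample <- array(0, dim = c(t, t, s, np))
  pos <- matrix(0L, design$n_rec, t)
  pos[cbind(design$obs_rec, design$obs_trait)] <- seq_len(design$n_obs)
  for (p in seq_len(np)) {
    recs <- which(design$pattern_of == p)
    msk <- design$patterns[[p]]
    tr <- which(msk)
    acc <- matrix(0, t, t)
    for (l in seq_len(s)) {
      Em <- matrix(0, length(recs), length(tr))
      for (k in seq_along(tr)) Em[, k] <- ehat[pos[recs, tr[k]], l]
      cp <- crossprod(Em)
      acc[tr, tr] <- acc[tr, tr] + cp
      resid_per_sample[tr, tr, l, p] <- cp
    }
    if (variant == "primary") {
      Rp <- theta$R0
      Rp[!msk, ] <- 0; Rp[, !msk] <- 0
      resid_wsum[[p]] <- length(recs) * Rp - acc / s
    } else {
      resid_wsum[[p]] <- acc / s
    }
  }
  new_traceset(Tmats, resid_wsum, s, variant,
               per_sample = list(groups = per_sample, resid = resid_per_sample))
}
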