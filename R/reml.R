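# EM and Average-Information REML over masked (co)variance structures.
#
# Conventions shared by the gradient, the AI matrix, finite differences and
# the standard errors: free parameters are the unmasked upper-triangle
# entries (theta_index()); derivatives are taken with respect to symmetric
# perturbations (E_ij + E_ji for i != j), which doubles off-diagonal entries
# relative to the matrix calculus form.

vech_weight <- function(index) ifelse(index$i == index$j, 1, 2)

#' EM-REML update
#'
#' `theta_k <- (T_k + S_k) / q_k` on the unmasked entries (masked entries are
#' forced to 0) and
#' `R0[i,j] <- (e_i'e_j + trace term) / n_ij`, where the trace term is the
#' per-pattern `Wsum` total of the trace set. An updated unmasked block that
#' leaves the parameter space is projected to the nearest positive definite
#' matrix with a warning.
#'
#' @param traces an `mcg_traceset` (Monte Carlo or exact).
#' @param quads an `mcg_quadforms`.
#' @param theta current `mcg_theta`.
#' @param design the `mcg_design`.
#' @return updated `mcg_theta`.
#' @export
em_update <- function(traces, quads, theta, design) {
  for (nm in names(theta$groups)) {
    g <- design$groups[[nm]]
    new <- (traces$T[[nm]] + quads$S[[nm]]) / g$q
    new <- (new + t(new)) / 2
    new[!theta$masks[[nm]]] <- 0
    if (!spd_ok(new)) {
      warn(sprintf("EM update for group '%s' left the parameter space; projected to nearest SPD", nm))
      new <- project_spd(new, theta$masks[[nm]])
    }
    theta$groups[[nm]] <- new
  }
  Wtot <- resid_wsum_total(traces)
  n_ij <- design$n_ij
  Rnew <- theta$R0
  t <- nrow(Rnew)
  for (i in seq_len(t)) for (j in i:t) {
    if (!theta$R_mask[i, j]) { Rnew[i, j] <- Rnew[j, i] <- 0; next }
    if (n_ij[i, j] == 0) abort(sprintf("no joint records for residual pair (%d,%d) with a free parameter", i, j))
    val <- (quads$resid_raw[i, j] + Wtot[i, j]) / n_ij[i, j]
    Rnew[i, j] <- Rnew[j, i] <- val
  }
  if (!spd_ok_patterns(Rnew, design)) {
    warn("EM residual update left the parameter space; projected to nearest SPD")
    Rnew <- project_spd(Rnew, theta$R_mask)
  }
  theta$R0 <- Rnew
  theta
}

spd_ok <- function(m) {
  if (any(diag(m) <= 0)) return(FALSE)
  !inherits(tryCatch(chol(m), error = function(e) e), "error")
}

spd_ok_patterns <- function(R0, design) {
  for (p in design$patterns) {
    if (!spd_ok(R0[p, p, drop = FALSE])) return(FALSE)
  }
  TRUE
}

#' Gradient of -2 times the restricted log-likelihood
#'
#' Group parameters: `q_k theta_k^{-1} - theta_k^{-1} (T_k + S_k) theta_k^{-1}`
#' read at the free positions (off-diagonals doubled for the symmetric
#' perturbation). Residual parameters:
#' `tr(R_ij R^{-1}) - tr(R^{-1} R_ij R^{-1} Q C^{-1} Q') - e'R^{-1}R_ij R^{-1}e`,
#' assembled from the per-pattern restricted inverses and `Wsum` matrices.
#'
#' @inheritParams em_update
#' @param index free-parameter index ([theta_index()]).
#' @return numeric vector over the free parameters.
#' @export
reml_gradient <- function(traces, quads, theta, design, index = theta_index(theta)) {
  t <- nrow(theta$R0)
  blocks <- pattern_blocks(design, theta$R0)
  cnt <- tabulate(design$pattern_of, nbins = length(design$patterns))
  term1 <- term2 <- matrix(0, t, t)
  for (p in seq_along(blocks)) {
    term1 <- term1 + cnt[p] * blocks[[p]]$inv_full
    term2 <- term2 + blocks[[p]]$inv_full %*% traces$resid_wsum[[p]] %*% blocks[[p]]$inv_full
  }
  Estar <- obs_to_matrix(design, quads$e_star)
  term3 <- crossprod(Estar)
  Rgrad <- term1 - term2 - term3
  Mgrad <- list()
  for (nm in names(theta$groups)) {
    g <- design$groups[[nm]]
    th_inv <- solve(theta$groups[[nm]])
    Mgrad[[nm]] <- g$q * th_inv - th_inv %*% (traces$T[[nm]] + quads$S[[nm]]) %*% th_inv
  }
  w <- vech_weight(index)
  vapply(seq_len(nrow(index)), function(r) {
    b <- index$block[r]
    m <- if (b == "residual") Rgrad else Mgrad[[b]]
    w[r] * m[index$i[r], index$j[r]]
  }, numeric(1))
}

# Wishart-style expected information of the prior/residual terms; used to
# safeguard AI steps (blended with the AI matrix) — SPD by construction.
em_information <- function(theta, design, index = theta_index(theta)) {
  np <- nrow(index)
  B <- matrix(0, np, np)
  w <- vech_weight(index)
  blocks <- pattern_blocks(design, theta$R0)
  cnt <- tabulate(design$pattern_of, nbins = length(design$patterns))
  inv <- list()
  for (nm in names(theta$groups)) inv[[nm]] <- solve(theta$groups[[nm]])
  for (r in seq_len(np)) for (c in r:np) {
    if (index$block[r] != index$block[c]) next
    i <- index$i[r]; j <- index$j[r]; k <- index$i[c]; l <- index$j[c]
    b <- index$block[r]
    if (b == "residual") {
      val <- 0
      for (p in seq_along(blocks)) {
        Ri <- blocks[[p]]$inv_full
        val <- val + cnt[p] * (Ri[i, k] * Ri[j, l] + Ri[i, l] * Ri[j, k]) / 2
      }
    } else {
      Ti <- inv[[b]]
      q <- design$groups[[b]]$q
      val <- q * (Ti[i, k] * Ti[j, l] + Ti[i, l] * Ti[j, k]) / 2
    }
    B[r, c] <- B[c, r] <- w[r] * w[c] * val
  }
  B
}

#' Average-information matrix
#'
#' `AI[p,q] = f_p' P f_q` with `f_p = (dV/dtheta_p) P y`; `Py` is the scaled
#' residual `R^{-1} e` mapped to observations, the group-parameter `f` vectors
#' are incidence-mapped combinations of the BLUPs weighted by `theta_k^{-1}`,
#' and `f' P f` is evaluated through one MME solve per parameter:
#' `f_p' R^{-1} f_q - (Q'R^{-1}f_p)' C^{-1} (Q'R^{-1}f_q)`.
#'
#' @param solution data-solve result ([solve_mme()]).
#' @param op the `mcg_mme` operator.
#' @param index free-parameter index.
#' @param Cinv optional dense inverse of C (reused when the exact-trace path
#'   has already computed it).
#' @param tol PCG tolerance for the per-parameter solves when `Cinv` is not
#'   given.
#' @return symmetric matrix over the free parameters.
#' @export
ai_matrix <- function(solution, op, index = theta_index(op$theta), Cinv = NULL,
                      tol = 1e-8) {
  design <- op$design
  theta <- op$theta
  e_star <- as.numeric(op$Rinv %*% solution$e_hat)   # Py at observation level
  Estar <- obs_to_matrix(design, e_star)
  np <- nrow(index)
  F <- matrix(0, design$n_obs, np)
  for (r in seq_len(np)) {
    b <- index$block[r]; i <- index$i[r]; j <- index$j[r]
    if (b == "residual") {
      f <- numeric(design$n_obs)
      sel_i <- design$obs_trait == i
      f[sel_i] <- f[sel_i] + Estar[design$obs_rec[sel_i], j]
      if (i != j) {
        sel_j <- design$obs_trait == j
        f[sel_j] <- f[sel_j] + Estar[design$obs_rec[sel_j], i]
      }
      F[, r] <- f
    } else {
      g <- design$groups[[b]]
      U <- sapply(seq_len(g$t), function(c) solution$sol[group_col_idx(design, b, c)])
      U <- matrix(U, ncol = g$t)
      KW <- U %*% solve(theta$groups[[b]])    # column j = K Z_j' P y
      stack <- function(col, vec) {
        v <- numeric(g$t * g$q)
        v[(col - 1L) * g$q + seq_len(g$q)] <- vec
        v
      }
      fv <- stack(i, KW[, j])
      if (i != j) fv <- fv + stack(j, KW[, i])
      F[, r] <- as.numeric(design$Z[[b]] %*% fv)
    }
  }
  RF <- as.matrix(op$Rinv %*% F)
  B <- as.matrix(Matrix::t(design$Q) %*% RF)
  S <- if (!is.null(Cinv)) {
    Cinv %*% B
  } else {
    as.matrix(pcg_solve(op, B, tol = tol, max_iter = 10000L)$sol)
  }
  AI <- crossprod(F, RF) - crossprod(B, S)
  (AI + t(AI)) / 2
}

#' Safeguarded AI-REML step
#'
#' Newton-type update `vech(theta)+ = vech(theta) - AI^{-1} grad`. If the
#' updated state leaves the parameter space (any unmasked block or observed
#' residual pattern loses positive definiteness), the AI matrix is blended
#' with the EM expected information with escalating weights
#' `w in {0.1, 0.3, 0.5, 0.9, 1}` and the step retried; the final fallback is
#' the plain EM update.
#'
#' @param theta current state; `grad` gradient of -2logL; `AI` the AI matrix;
#'   `traces`, `quads`, `design` as in [em_update()] (needed for the
#'   fallback); `index` free-parameter index.
#' @return list with the updated `theta`, the blending weight used
#'   (`0` = pure AI, `1` includes the pure-EM fallback) and `fallback_em`
#'   flag.
#' @export
ai_step <- function(theta, grad, AI, traces, quads, design,
                    index = theta_index(theta)) {
  try_step <- function(B) {
    delta <- tryCatch(solve(B, grad), error = function(e) NULL)
    if (is.null(delta) || anyNA(delta)) return(NULL)
    cand <- vech_to_theta(theta, theta_to_vech(theta, index) - delta, index)
    if (theta_in_space(cand, design)) cand else NULL
  }
  cand <- try_step(AI)
  if (!is.null(cand)) return(list(theta = cand, weight = 0, fallback_em = FALSE))
  Bem <- em_information(theta, design, index)
  for (w in c(0.1, 0.3, 0.5, 0.9, 1.0)) {
    cand <- try_step((1 - w) * AI + w * Bem)
    if (!is.null(cand)) return(list(theta = cand, weight = w, fallback_em = FALSE))
  }
  cand <- em_update(traces, quads, theta, design)
  if (!theta_in_space(cand, design)) {
    abort("AI step and EM fallback both left the parameter space")
  }
  list(theta = cand, weight = 1, fallback_em = TRUE)
}

#' Exact restricted log-likelihood
#'
#' `-2 logL = log|C| + log|R| + sum_k (q_k log|theta_k| + t_k log|K_k|) + y'Py`
#' with `y'Py = y'R^{-1}y - rhs'sol`, all determinants from sparse/dense
#' factorizations (`log|H| = log|A| - log|A22| + log|G|`). Deterministic;
#' requires a full-rank fixed-effects block.
#'
#' @param design an `mcg_design`; `theta` the variance state; `hop` the H
#'   operator.
#' @param op optional pre-assembled operator at `theta` (assembled if
#'   missing).
#' @return scalar `-2 logL` (up to the usual additive constant
#'   `n log(2 pi)`, which is omitted consistently everywhere).
#' @export
restricted_loglik <- function(design, theta, hop, op = NULL) {
  if (is.null(op)) op <- assemble_operator(design, theta, hop)
  ldC <- tryCatch(
    as.numeric(Matrix::determinant(op$C, logarithm = TRUE)$modulus),
    error = function(e) abort("factorization of C failed (rank-deficient fixed effects?)"))
  fac <- Matrix::Cholesky(op$C, LDL = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(fac, op$rhs, system = "A"))
  yPy <- as.numeric(crossprod(design$y, op$Rinv %*% design$y)) - sum(op$rhs * sol)
  blocks <- pattern_blocks(design, theta$R0)
  cnt <- tabulate(design$pattern_of, nbins = length(design$patterns))
  ldR <- sum(cnt * vapply(blocks, `[[`, numeric(1), "logdet"))
  ldPrior <- 0
  for (g in design$groups) {
    th <- theta$groups[[g$name]]
    ldTh <- as.numeric(determinant(th, logarithm = TRUE)$modulus)
    ldK <- if (g$kind == "h") h_logdet(hop) else 0
    ldPrior <- ldPrior + g$q * ldTh + g$t * ldK
  }
  ldC + ldR + ldPrior + yPy
}

#' Convergence check for (MC-)REML
#'
#' Converged when the maximum relative round-to-round parameter change
#' `max |theta+ - theta| / (|theta| + 1e-10)` drops below `t1`, or when the
#' coefficient of variation of the restricted log-likelihood over the five
#' most recent rounds drops below `t2` (only evaluated once five values
#' exist).
#'
#' @param vech_old,vech_new free-parameter vectors of consecutive rounds.
#' @param logl_history numeric vector of `-2 logL` values so far.
#' @param t1,t2 thresholds (defaults `1e-12`, `1e-4`).
#' @return list `(converged, reason, delta_theta, cv_logl)`.
#' @export
check_convergence <- function(vech_old, vech_new, logl_history,
                              t1 = 1e-12, t2 = 1e-4) {
  delta <- max(abs(vech_new - vech_old) / (abs(vech_old) + 1e-10))
  cv <- NA_real_
  if (length(logl_history) >= 5) {
    lastv <- utils::tail(logl_history, 5)
    cv <- stats::sd(lastv) / abs(mean(lastv))
  }
  if (delta < t1) {
    list(converged = TRUE, reason = "delta_theta", delta_theta = delta, cv_logl = cv)
  } else if (!is.na(cv) && cv < t2) {
    list(converged = TRUE, reason = "cv_logl", delta_theta = delta, cv_logl = cv)
  } else {
    list(converged = FALSE, reason = NA_character_, delta_theta = delta, cv_logl = cv)
  }
}

#' Standard errors from the inverse AI matrix
#'
#' `SE_p = sqrt(diag(2 AI^{-1}))`: the AI matrix tracks the curvature of
#' `-2 logL`, whose expectation is twice the Fisher information of `logL`,
#' hence the factor 2. Masked parameters carry no standard error.
#'
#' @param AI the AI matrix at the optimum.
#' @param index free-parameter index.
#' @return tibble `param`, `se`.
#' @export
standard_errors <- function(AI, index) {
  se <- rep(NA_real_, nrow(index))
  inv <- tryCatch(solve(AI), error = function(e) NULL)
  if (is.null(inv)) {
    warn("AI matrix is singular; standard errors reported as missing")
  } else {
    d <- 2 * diag(inv)
    se <- ifelse(d > 0, sqrt(d), NA_real_)
  }
  tibble::tibble(param = index$param, se = se)
}

#' Fit variance components by (Monte Carlo) ss-GREML
#'
#' The full estimation loop: per round, solve the data MME, compute the
#' solution-side quadratic forms, obtain the PEV traces (Monte Carlo
#' simulation or exact dense inversion), update theta by EM or a safeguarded
#' AI step, evaluate the exact restricted log-likelihood, and test the dual
#' convergence criterion.
#'
#' @param ped renumbered pedigree (or raw pedigree tibble).
#' @param pheno phenotype tibble (see [build_design()]).
#' @param spec an [model_spec()].
#' @param geno optional `mcg_genotypes` ([genotype_set()]); enables the
#'   single-step H structure.
#' @param method `"ai"` (default) or `"em"`.
#' @param traces `"mc"` (default) or `"exact"`.
#' @param theta0 optional starting `mcg_theta` (defaults to
#'   [variance_state()] starting values).
#' @param verbose print a per-round log line.
#' @return An object of class `mcg_reml`: final `theta`, `index`,
#'   `estimates` tibble (parameter, estimate, SE), `history` (per-round
#'   tibble with `-2 logL`, `delta_theta`, `cv_logl`, blending weight),
#'   `converged`, `reason`, `rounds`, plus the `design`, `hop` and settings
#'   used.
#' @export
run_reml <- function(ped, pheno, spec, geno = NULL,
                     method = c("ai", "em"), traces = c("mc", "exact"),
                     theta0 = NULL, verbose = FALSE) {
  method <- match.arg(method)
  traces <- match.arg(traces)
  ped <- as_pedigree(ped)
  fphi <- compute_inbreeding_phi(ped)
  genomic <- NULL
  apy <- NULL
  if (!is.null(geno)) {
    A22 <- pedigree_A22(ped, geno$ids)
    genomic <- build_genomic(geno, A22, alpha = spec$alpha, blend = spec$blend)
    if (isTRUE(spec$apy$enabled)) {
      core <- select_core(genomic$ids, spec$apy$n_core, spec$apy$seed)
      apy <- apy_decompose(genomic, core)
    }
  }
  hop <- h_operator(ped, genomic = genomic, apy = apy, fphi = fphi)
  design <- build_design(ped, pheno, spec)
  theta <- theta0 %||% variance_state(spec)
  index <- theta_index(theta)
  conv <- spec$convergence
  hist_rows <- list()
  logl_hist <- numeric(0)
  warm <- NULL
  converged <- FALSE
  reason <- "max_rounds"
  AI <- NULL
  for (round in seq_len(conv$max_rounds)) {
    op <- assemble_operator(design, theta, hop)
    sol <- solve_mme(op, tol = spec$solver$tol_data,
                     max_iter = spec$solver$max_iter, warm_start = warm)
    warm <- sol$sol
    quads <- compute_quadforms(sol, op)
    Cinv <- NULL
    if (traces == "exact") {
      tr_set <- exact_traces(op)
      Cinv <- attr(tr_set, "Cinv")
    } else {
      tr_set <- run_mc_round(op, s = spec$mc$samples, base_seed = spec$mc$seed,
                             round = round,
                             reuse_sequence = isTRUE(spec$mc$reuse_sequence),
                             apy = apy, tol = spec$solver$tol_mc,
                             max_iter = spec$solver$max_iter)
    }
    m2ll <- restricted_loglik(design, theta, hop, op = op)
    logl_hist <- c(logl_hist, m2ll)
    vech_old <- theta_to_vech(theta, index)
    grad <- reml_gradient(tr_set, quads, theta, design, index)
    weight <- NA_real_
    if (method == "em") {
      theta_new <- em_update(tr_set, quads, theta, design)
    } else {
      AI <- ai_matrix(sol, op, index, Cinv = Cinv)
      stp <- ai_step(theta, grad, AI, tr_set, quads, design, index)
      theta_new <- stp$theta
      weight <- stp$weight
    }
    vech_new <- theta_to_vech(theta_new, index)
    cc <- check_convergence(vech_old, vech_new, logl_hist,
                            t1 = conv$t1, t2 = conv$t2)
    hist_rows[[round]] <- tibble::tibble(
      round = round, minus2_logl = m2ll, delta_theta = cc$delta_theta,
      cv_logl = cc$cv_logl, ai_blend_weight = weight,
      grad_norm = max(abs(grad)))
    if (verbose) {
      inform(sprintf("round %3d  -2logL %.6f  max|grad| %.3e  dTheta %.3e  CV %.3e",
                     round, m2ll, max(abs(grad)), cc$delta_theta,
                     ifelse(is.na(cc$cv_logl), NaN, cc$cv_logl)))
    }
    theta <- theta_new
    if (cc$converged) {
      converged <- TRUE
      reason <- cc$reason
      break
    }
  }
  # AI matrix at the final state, for standard errors
  op <- assemble_operator(design, theta, hop)
  sol <- solve_mme(op, tol = spec$solver$tol_data,
                   max_iter = spec$solver$max_iter, warm_start = warm)
  Cinv_f <- if (traces == "exact" && design$n_eq <= 5000)
    solve(as.matrix(op$C)) else NULL
  AI <- ai_matrix(sol, op, index, Cinv = Cinv_f)
  se <- standard_errors(AI, index)
  estimates <- dplyr::mutate(index, estimate = theta_to_vech(theta, index))
  estimates <- dplyr::left_join(estimates, se, by = "param")
  structure(list(
    theta = theta, index = index, estimates = estimates, ai = AI,
    history = dplyr::bind_rows(hist_rows), converged = converged,
    reason = reason, rounds = length(hist_rows),
    method = method, traces = traces, spec = spec,
    design = design, hop = hop, apy = apy, solution = sol
  ), class = "mcg_reml")
}

# seeded uniform core selection for APY
select_core <- function(geno_ids, n_core, seed) {
  stopifnot(n_core >= 1, n_core <= length(geno_ids))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sort(sample(geno_ids, n_core))
}

#' @export
print.mcg_reml <- function(x, ...) {
  cat(sprintf("%s-REML (%s traces): %d round(s), %s\n",
              toupper(x$method), x$traces, x$rounds,
              if (x$converged) sprintf("converged (%s)", x$reason) else "NOT converged"))
  print(x$estimates, n = Inf)
  invisible(x)
}
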