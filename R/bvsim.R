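# Breeding-value and phenotype simulation under the exact model covariances.
#
# All samplers operate on "stacked" matrices: a group with t correlated
# columns over q levels is a (t*q) x ndraw matrix with the level index running
# fastest (column c of the group occupies rows (c-1)*q + 1..q), matching the
# equation layout of the MME. Standard normal deviates are drawn per sample
# through keyed_normals() (so each sample's stream is reproducible and
# reusable across rounds) but the linear algebra runs once, blocked over all
# sample columns.

# rows of level i across the t columns of a stacked (t*q) x nd matrix
stack_rows <- function(i, q, t) (seq_len(t) - 1L) * q + i

# lower Cholesky factor tolerating the all-zero degenerate matrix
chol_lower <- function(m) {
  if (all(m == 0)) return(matrix(0, nrow(m), ncol(m)))
  t(chol(m))
}

# n x length(sites) matrix: column l holds the deviates of site sites[l]
draw_block <- function(base_seed, sites, n) {
  X <- matrix(0, n, length(sites))
  for (l in seq_along(sites)) X[, l] <- keyed_normals(base_seed, sites[l], n, 1L)
  X
}

#' Gene dropping: pedigree-structured breeding-value samples
#'
#' Simulates breeding values with covariance `theta (x) A` down the pedigree:
#' `a_i = 0.5 (a_s + a_d) + sqrt(phi_i) L x_i` with `L L' = theta` and `phi_i`
#' the Mendelian sampling variance fraction; unknown parents contribute 0.
#'
#' @param ped renumbered pedigree.
#' @param phi Mendelian sampling variances ([compute_inbreeding_phi()]).
#' @param L lower Cholesky factor of the t x t genetic covariance.
#' @param base_seed,site RNG key ([keyed_normals()]).
#' @param ndraw number of independent samples.
#' @return A `(t * n_animals) x ndraw` matrix (level index fastest).
#' @export
gene_drop <- function(ped, phi, L, base_seed, site = "gd", ndraw = 1L) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  t <- nrow(L)
  X <- keyed_normals(base_seed, site, n * t, ndraw)
  gene_drop_core(ped, phi, L, X)
}

gene_drop_core <- function(ped, phi, L, X) {
  n <- nrow(ped)
  t <- nrow(L)
  a <- matrix(0, n * t, ncol(X))
  s <- ped$sire; d <- ped$dam
  for (i in seq_len(n)) {
    ri <- stack_rows(i, n, t)
    val <- sqrt(phi[i]) * (L %*% X[ri, , drop = FALSE])
    if (s[i] > 0L) val <- val + 0.5 * a[stack_rows(s[i], n, t), , drop = FALSE]
    if (d[i] > 0L) val <- val + 0.5 * a[stack_rows(d[i], n, t), , drop = FALSE]
    a[ri, ] <- val
  }
  a
}

#' Sample marker effects and the J-factor mean
#'
#' Marker effects are drawn with covariance `theta (x) (2*sum(p*q))^{-1} I`
#' and the J-factor mean with covariance `theta * v`, `v = mean(A22 - G_raw)`
#' (truncated at 0 if numerically negative).
#'
#' @param genomic an `mcg_genomic`.
#' @param L lower Cholesky factor of the genetic covariance.
#' @param base_seed,site_g,site_mu RNG keys.
#' @param ndraw number of samples.
#' @return list with `g` (`(t*m) x ndraw`, locus fastest) and `mu`
#'   (`t x ndraw`).
#' @export
sample_genomic_terms <- function(genomic, L, base_seed, site_g = "g",
                                 site_mu = "mu", ndraw = 1L) {
  t <- nrow(L)
  m <- ncol(genomic$M)
  Xg <- keyed_normals(base_seed, site_g, m * t, ndraw)
  Xmu <- keyed_normals(base_seed, site_mu, t, ndraw)
  genomic_terms_core(genomic, L, Xg, Xmu)
}

genomic_terms_core <- function(genomic, L, Xg, Xmu) {
  t <- nrow(L)
  m <- ncol(genomic$M)
  v <- genomic$j_var
  if (v < -1e-8 * mean(diag(genomic$A22))) {
    abort("negative J-factor variance: relationship matrices are inconsistent")
  }
  v <- max(v, 0)
  g <- stacked_transform(Xg, L, m) / sqrt(genomic$center_scale)
  mu <- (L %*% Xmu) * sqrt(v)
  list(g = g, mu = mu)
}

# apply the t x t factor L to each level of a stacked (t*q) x nd matrix
stacked_transform <- function(X, L, q) {
  t <- nrow(L)
  if (t == 1L) return(X * L[1, 1])
  nd <- ncol(X)
  out <- array(X, dim = c(q, t, nd))
  for (dcol in seq_len(nd)) out[, , dcol] <- out[, , dcol] %*% t(L)
  matrix(out, nrow = q * t, ncol = nd)
}

# (I_t (x) M) g plus the J-factor mean broadcast over animals
genomic_values <- function(genomic, g, mu, rows = NULL) {
  t <- nrow(mu)
  m <- ncol(genomic$M)
  M <- if (is.null(rows)) genomic$M else genomic$M[rows, , drop = FALSE]
  ng <- nrow(M)
  nd <- ncol(g)
  out <- matrix(0, t * ng, nd)
  for (c in seq_len(t)) {
    gc <- g[(c - 1L) * m + seq_len(m), , drop = FALSE]
    out[(c - 1L) * ng + seq_len(ng), ] <-
      M %*% gc + matrix(mu[c, ], ng, nd, byrow = TRUE)
  }
  out
}

# rows of the genotyped animals in a stacked all-animal matrix
geno_stack_idx <- function(hop, t) {
  n <- hop$n
  as.vector(vapply(seq_len(t), function(c) (c - 1L) * n + hop$geno_idx,
                   integer(length(hop$geno_idx))))
}

#' Combine pedigree and genomic samples into ssGBLUP breeding values
#'
#' Implements the sampling identity that realises `u ~ N(0, theta (x) H)`
#' without forming H: for the genotyped animals
#' `u2 = sqrt(1-alpha) (1 mu' + M g) + sqrt(alpha) a2` and
#' `delta = sqrt(1-alpha) (1 mu' + M g) + (sqrt(alpha) - 1) a2`; for the
#' non-genotyped animals `u1 = A12 A22^{-1} delta + a1`, computed through the
#' sparse blocks of `A^{-1}` (default) or a dense A22 solve.
#'
#' @param a stacked pedigree samples from [gene_drop()].
#' @param g,mu stacked genomic terms from [sample_genomic_terms()].
#' @param alpha residual polygenic fraction.
#' @param hop an `mcg_hop` with genomic information.
#' @param backend backend for `A12 A22^{-1}`: `"ainv"` or `"dense"`.
#' @return list with `u` (stacked over all animals) and `delta` (stacked over
#'   genotyped animals).
#' @export
combine_ssgblup <- function(a, g, mu, alpha, hop, backend = c("ainv", "dense")) {
  backend <- match.arg(backend)
  n <- hop$n
  gi <- hop$geno_idx
  t <- nrow(mu)
  if (!length(gi) || alpha >= 1) {
    return(list(u = a, delta = matrix(0, t * length(gi), ncol(a))))
  }
  gv <- genomic_values(hop$genomic, g, mu)      # (t*ng) x nd
  ng <- length(gi)
  a2 <- a[geno_stack_idx(hop, t), , drop = FALSE]
  u2 <- sqrt(1 - alpha) * gv + sqrt(alpha) * a2
  delta <- sqrt(1 - alpha) * gv + (sqrt(alpha) - 1) * a2
  finish_combine(a, u2, delta, hop, t, backend)
}

# scatter u2 into the full stack and add A12 A22^{-1} delta to non-genotyped
finish_combine <- function(a, u2, delta, hop, t, backend) {
  n <- hop$n
  gi <- hop$geno_idx
  ni <- hop$nong_idx
  ng <- length(gi)
  u <- a
  for (c in seq_len(t)) {
    rows_g <- (c - 1L) * ng + seq_len(ng)
    u[(c - 1L) * n + gi, ] <- u2[rows_g, , drop = FALSE]
    if (length(ni)) {
      u[(c - 1L) * n + ni, ] <- u[(c - 1L) * n + ni, , drop = FALSE] +
        a12_a22inv_apply(hop, delta[rows_g, , drop = FALSE], backend = backend)
    }
  }
  list(u = u, delta = delta)
}

#' Combine samples under the APY covariance structure
#'
#' APY variant of [combine_ssgblup()]: core animals are combined exactly as in
#' the full scheme; non-core values are the core regression `P_nc u_c` plus an
#' independent error with the diagonal conditional variances Psi,
#' `psi_i = sqrt(Psi_ii) L x`. With every genotyped animal in the core (given
#' the same RNG stream) the output is identical to [combine_ssgblup()].
#'
#' @inheritParams combine_ssgblup
#' @param apy an `mcg_apy` decomposition.
#' @param L lower Cholesky factor of the genetic covariance (for the psi
#'   draws).
#' @param base_seed,site_psi RNG key for the non-core error draws.
#' @return list with `u` and `delta` as in [combine_ssgblup()].
#' @export
combine_apy <- function(a, g, mu, alpha, hop, apy, L, base_seed,
                        site_psi = "psi", backend = c("ainv", "dense")) {
  backend <- match.arg(backend)
  n <- hop$n
  gi <- hop$geno_idx
  t <- nrow(mu)
  nd <- ncol(a)
  ng <- length(gi)
  ci <- apy$core_idx; nci <- apy$noncore_idx
  gv_c <- genomic_values(hop$genomic, g, mu, rows = ci)  # core genomic values
  a2 <- a[geno_stack_idx(hop, t), , drop = FALSE]
  nc <- length(ci)
  u2 <- matrix(0, t * ng, nd)
  for (c in seq_len(t)) {
    ac <- a2[(c - 1L) * ng + ci, , drop = FALSE]
    u2[(c - 1L) * ng + ci, ] <- sqrt(1 - alpha) *
      gv_c[(c - 1L) * nc + seq_len(nc), , drop = FALSE] + sqrt(alpha) * ac
  }
  if (length(nci)) {
    nn <- length(nci)
    Xp <- keyed_normals(base_seed, site_psi, nn * t, nd)
    psi_err <- stacked_transform(Xp, L, nn) *
      rep(sqrt(apy$psi), times = t)
    for (c in seq_len(t)) {
      uc <- u2[(c - 1L) * ng + ci, , drop = FALSE]
      u2[(c - 1L) * ng + nci, ] <- apy$P_nc %*% uc +
        psi_err[(c - 1L) * nn + seq_len(nn), , drop = FALSE]
    }
  }
  delta <- u2 - a2
  finish_combine(a, u2, delta, hop, t, backend)
}

#' Draw genetic samples for an H-structured group
#'
#' Dispatches on the model: pure pedigree (`alpha = 1` or no genotypes) uses
#' gene dropping only; otherwise the ssGBLUP (or APY) combination is applied.
#' The genetic covariance Cholesky is recomputed per call (theta changes
#' between rounds) but the underlying standard normal deviates depend only on
#' `(base_seed, site prefix)`.
#'
#' @param hop H operator.
#' @param theta_g group covariance matrix.
#' @param alpha residual polygenic fraction.
#' @param base_seed RNG base seed.
#' @param prefix site prefix, e.g. `"s3:"`.
#' @param ndraw number of samples.
#' @param apy optional `mcg_apy`.
#' @return stacked `(t * n) x ndraw` matrix of genetic samples.
#' @export
draw_u_tilde <- function(hop, theta_g, alpha, base_seed, prefix = "",
                         ndraw = 1L, apy = NULL) {
  L <- chol_lower(theta_g)
  a <- gene_drop(hop$ped, hop$fphi$phi, L, base_seed,
                 site = paste0(prefix, "gd"), ndraw = ndraw)
  if (!length(hop$geno_idx) || alpha >= 1) return(a)
  gm <- sample_genomic_terms(hop$genomic, L, base_seed,
                             site_g = paste0(prefix, "g"),
                             site_mu = paste0(prefix, "mu"), ndraw = ndraw)
  if (is.null(apy)) {
    combine_ssgblup(a, gm$g, gm$mu, alpha, hop)$u
  } else {
    combine_apy(a, gm$g, gm$mu, alpha, hop, apy, L, base_seed,
                site_psi = paste0(prefix, "psi"))$u
  }
}

#' Simulate residuals and phenotypes for the current model
#'
#' Residuals are drawn per record from the missingness-pattern-restricted
#' `N(0, R0[pattern, pattern])`; simulated phenotypes are the sum of all
#' random-effect contributions plus the residual (fixed effects contribute 0
#' but remain in the fitted model). The number of deviates consumed per record
#' does not depend on R0, so streams replay across rounds.
#'
#' @param design an `mcg_design`.
#' @param u_list named list of stacked samples, one per random group.
#' @param R0 residual covariance.
#' @param base_seed,site RNG key.
#' @param ndraw number of samples.
#' @return list with `e` and `y` (both `n_obs x ndraw`).
#' @export
simulate_phenotypes <- function(design, u_list, R0, base_seed, site = "e",
                                ndraw = 1L) {
  t <- length(design$traits)
  Zx <- keyed_normals(base_seed, site, design$n_rec * t, ndraw)
  e <- resid_core(design, R0, Zx)
  ysim <- e
  for (nm in names(design$Z)) {
    ysim <- ysim + as.matrix(design$Z[[nm]] %*% u_list[[nm]])
  }
  list(e = e, y = ysim)
}

resid_core <- function(design, R0, Zx) {
  t <- length(design$traits)
  blocks <- pattern_blocks(design, R0)
  ndraw <- ncol(Zx)
  e <- matrix(0, design$n_obs, ndraw)
  pos <- matrix(0L, design$n_rec, t)
  pos[cbind(design$obs_rec, design$obs_trait)] <- seq_len(design$n_obs)
  for (p in seq_along(blocks)) {
    recs <- which(design$pattern_of == p)
    if (!length(recs)) next
    msk <- blocks[[p]]$mask
    k <- sum(msk)
    Lp <- blocks[[p]]$chol_lower
    idx <- as.vector(outer(recs, (seq_len(k) - 1L) * design$n_rec, "+"))
    Zarr <- array(Zx[idx, , drop = FALSE], dim = c(length(recs), k, ndraw))
    for (dcol in seq_len(ndraw)) {
      Zarr[, , dcol] <- Zarr[, , dcol] %*% t(Lp)
    }
    oi <- pos[recs, which(msk), drop = FALSE]
    for (ktr in seq_len(k)) {
      e[oi[, ktr], ] <- Zarr[, ktr, ]
    }
  }
  e
}

#' Draw complete Monte Carlo samples
#'
#' Draws every random effect of the model with its exact covariance structure,
#' the residuals, and the simulated phenotypes, for the sample indices
#' `samples`. Deviates are keyed per sample index so the per-sample and
#' blocked paths consume identical numbers.
#'
#' @param design an `mcg_design`.
#' @param theta current variance state.
#' @param hop the H operator.
#' @param samples integer vector of sample indices.
#' @param base_seed stream base seed.
#' @param apy optional APY decomposition.
#' @return list with `u_list` (stacked matrices, one column per sample), `e`,
#'   `y`.
#' @export
mc_draws <- function(design, theta, hop, samples, base_seed, apy = NULL) {
  spec <- design$spec
  u_list <- list()
  for (g in design$groups) {
    th <- theta$groups[[g$name]]
    L <- chol_lower(th)
    if (g$kind == "h") {
      X <- draw_block(base_seed, sprintf("s%d:%s:gd", samples, g$name), hop$n * g$t)
      a <- gene_drop_core(hop$ped, hop$fphi$phi, L, X)
      if (!length(hop$geno_idx) || spec$alpha >= 1) {
        u_list[[g$name]] <- a
      } else {
        Xg <- draw_block(base_seed, sprintf("s%d:%s:g", samples, g$name),
                         ncol(hop$genomic$M) * g$t)
        Xmu <- draw_block(base_seed, sprintf("s%d:%s:mu", samples, g$name), g$t)
        gm <- genomic_terms_core(hop$genomic, L, Xg, Xmu)
        if (is.null(apy)) {
          u_list[[g$name]] <- combine_ssgblup(a, gm$g, gm$mu, spec$alpha, hop)$u
        } else {
          nn <- length(apy$noncore_idx)
          if (nn > 0) {
            # per-sample psi keying: assemble the blocked draw, then combine
            Xp <- draw_block(base_seed, sprintf("s%d:%s:psi", samples, g$name),
                             nn * g$t)
            u_list[[g$name]] <- combine_apy_given(a, gm$g, gm$mu, spec$alpha,
                                                  hop, apy, L, Xp)$u
          } else {
            u_list[[g$name]] <- combine_ssgblup(a, gm$g, gm$mu, spec$alpha, hop)$u
          }
        }
      }
    } else {
      X <- draw_block(base_seed, sprintf("s%d:%s:iid", samples, g$name),
                      g$q * g$t)
      u_list[[g$name]] <- stacked_transform(X, L, g$q)
    }
  }
  Zx <- draw_block(base_seed, sprintf("s%d:e", samples),
                   design$n_rec * length(design$traits))
  e <- resid_core(design, theta$R0, Zx)
  ysim <- e
  for (nm in names(design$Z)) {
    ysim <- ysim + as.matrix(design$Z[[nm]] %*% u_list[[nm]])
  }
  list(u_list = u_list, e = e, y = ysim)
}

# combine_apy with externally supplied psi deviates (blocked path)
combine_apy_given <- function(a, g, mu, alpha, hop, apy, L, Xp,
                              backend = c("ainv", "dense")) {
  backend <- match.arg(backend)
  n <- hop$n
  gi <- hop$geno_idx
  t <- nrow(mu)
  nd <- ncol(a)
  ng <- length(gi)
  ci <- apy$core_idx; nci <- apy$noncore_idx
  gv_c <- genomic_values(hop$genomic, g, mu, rows = ci)
  a2 <- a[geno_stack_idx(hop, t), , drop = FALSE]
  nc <- length(ci)
  u2 <- matrix(0, t * ng, nd)
  for (c in seq_len(t)) {
    ac <- a2[(c - 1L) * ng + ci, , drop = FALSE]
    u2[(c - 1L) * ng + ci, ] <- sqrt(1 - alpha) *
      gv_c[(c - 1L) * nc + seq_len(nc), , drop = FALSE] + sqrt(alpha) * ac
  }
  nn <- length(nci)
  psi_err <- stacked_transform(Xp, L, nn) * rep(sqrt(apy$psi), times = t)
  for (c in seq_len(t)) {
    uc <- u2[(c - 1L) * ng + ci, , drop = FALSE]
    u2[(c - 1L) * ng + nci, ] <- apy$P_nc %*% uc +
      psi_err[(c - 1L) * nn + seq_len(nn), , drop = FALSE]
  }
  delta <- u2 - a2
  finish_combine(a, u2, delta, hop, t, backend)
}

#' Draw one complete Monte Carlo sample
#'
#' Single-sample convenience wrapper around [mc_draws()].
#'
#' @inheritParams mc_draws
#' @param l sample index within the stream.
#' @return list with `u_list`, `e`, `y` (single-column matrices).
#' @export
mc_sample <- function(design, theta, hop, l, base_seed, apy = NULL) {
  mc_draws(design, theta, hop, samples = l, base_seed = base_seed, apy = apy)
}
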