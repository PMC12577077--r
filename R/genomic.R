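#' Read a SNP dosage file
#'
#' Parses the compact genotype dialect `"ID<whitespace>digits"` where each
#' digit in `{0,1,2}` is an allele dosage for one locus.
#'
#' @param path path to the genotype file.
#' @return A tibble with columns `id` (character) and `dosage` (list of
#'   integer vectors).
#' @export
read_genotypes <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  ids <- vapply(parts, `[[`, character(1), 1L)
  strs <- vapply(parts, `[[`, character(1), 2L)
  m <- unique(nchar(strs))
  if (length(m) != 1L) abort("genotype strings have unequal lengths")
  dos <- lapply(strs, function(s) {
    v <- as.integer(strsplit(s, "")[[1]])
    if (anyNA(v) || any(v < 0L | v > 2L)) abort("genotype characters must be 0/1/2")
    v
  })
  tibble::tibble(id = ids, dosage = dos)
}

#' Build a genotype set
#'
#' Assembles the dosage matrix over genotyped animals, computes observed
#' allele frequencies, drops monomorphic loci, and centres dosages by twice
#' the allele frequency.
#'
#' @param ids genotyped animal codes (integer, pedigree codes) or original ids
#'   to be matched through the pedigree `id_map`.
#' @param dosages `n x m` matrix of allele counts in `{0,1,2}` (rows = `ids`).
#' @param ped optional renumbered pedigree used to map original ids to codes.
#' @return A list of class `mcg_genotypes` with elements `ids` (codes),
#'   `M_raw` (dosages after locus filtering), `M` (centred), `p` (allele
#'   frequencies), `center_scale` (`2 * sum(p*q)`), `n_dropped` (monomorphic
#'   loci removed).
#' @export
genotype_set <- function(ids, dosages, ped = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (!is.null(ped)) {
    ped <- as_pedigree(ped)
    map <- attr(ped, "id_map")
    codes <- map$code[match(as.character(ids), map$id)]
    if (anyNA(codes)) {
      abort(sprintf("genotyped id(s) absent from the pedigree: %s",
                    paste(utils::head(as.character(ids)[is.na(codes)], 5), collapse = ", ")))
    }
    ids <- codes
  }
  ids <- as.integer(ids)
  stopifnot(length(ids) == nrow(dosages))
  p <- colMeans(dosages) / 2
  keep <- p > 0 & p < 1
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d monomorphic locus/loci", n_dropped))
  }
  M_raw <- dosages[, keep, drop = FALSE]
  p <- p[keep]
  if (!length(p)) abort("no polymorphic loci left after filtering")
  center_scale <- 2 * sum(p * (1 - p))
  M <- sweep(M_raw, 2L, 2 * p, "-")
  structure(list(ids = ids, M_raw = M_raw, M = M, p = p,
                 center_scale = center_scale, n_dropped = n_dropped),
            class = "mcg_genotypes")
}

#' Genomic relationship matrix with polygenic blending and J-factor
#'
#' Builds the marker-based relationship matrix `G_raw = MM'/(2*sum(p*q))`
#' (VanRaden's first method with observed allele frequencies), the J-factor
#' variance `v = mean(A22 - G_raw)` aligning the genomic and pedigree base
#' populations, and the blended matrix used in the H matrix. Two blending
#' conventions are available:
#' \describe{
#'   \item{`"variance"`}{`(1-alpha) (G_raw + v 11') + alpha A22` — consistent
#'     with the variance of the ssGBLUP breeding-value decomposition used by
#'     the sampler (the default).}
#'   \item{`"sqrt"`}{`sqrt(1-alpha) (G_raw + v 11') + sqrt(alpha) A22`.}
#' }
#'
#' @param geno an `mcg_genotypes` object.
#' @param A22 dense pedigree relationships among the genotyped animals
#'   (matching the row order of `geno$ids`), or a renumbered pedigree from
#'   which it is computed.
#' @param alpha residual polygenic fraction in `[0, 1]`.
#' @param blend `"variance"` (default) or `"sqrt"`.
#' @return A list of class `mcg_genomic` with `g_raw`, `j_var`, `g_blend`,
#'   `alpha`, `ids`, plus the centred marker matrix and scale carried over
#'   from `geno`.
#' @export
build_genomic <- function(geno, A22, alpha = 0.05, blend = c("variance", "sqrt")) {
  blend <- match.arg(blend)
  stopifnot(inherits(geno, "mcg_genotypes"), alpha >= 0, alpha <= 1)
  if (inherits(A22, "mcg_pedigree") || (is.data.frame(A22) && all(c("animal", "sire", "dam") %in% names(A22)))) {
    A22 <- pedigree_A22(as_pedigree(A22), geno$ids)
  }
  A22 <- as.matrix(A22)
  n <- length(geno$ids)
  stopifnot(nrow(A22) == n, ncol(A22) == n)
  g_raw <- tcrossprod(geno$M) / geno$center_scale
  j_var <- mean(A22 - g_raw)
  if (j_var < 0) {
    warn(sprintf("J-factor variance is negative (%.3g); truncated to 0 for sampling", j_var))
  }
  w <- if (blend == "variance") c(1 - alpha, alpha) else c(sqrt(1 - alpha), sqrt(alpha))
  g_blend <- w[1] * (g_raw + j_var) + w[2] * A22
  ev_min <- min(eigen(g_blend, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-10) {
    abort(sprintf("blended G is not positive definite (min eigenvalue %.3g); increase alpha", ev_min))
  }
  structure(list(ids = geno$ids, g_raw = g_raw, j_var = j_var,
                 g_blend = g_blend, alpha = alpha, blend = blend,
                 M = geno$M, center_scale = geno$center_scale, A22 = A22),
            class = "mcg_genomic")
}

#' APY decomposition of the genomic relationship matrix
#'
#' Splits the genotyped animals into core and non-core sets and computes the
#' pieces of the APY sparse inverse: `P_nc = G_nc G_cc^{-1}`, the diagonal
#' conditional variances `Psi = diag(G_nn - G_nc G_cc^{-1} G_cn)`, and the
#' assembled sparse APY G-inverse in the original genotyped order.
#'
#' @param genomic an `mcg_genomic` object.
#' @param core_ids pedigree codes of the core animals (subset of
#'   `genomic$ids`).
#' @return A list of class `mcg_apy` with `core_idx`, `noncore_idx` (positions
#'   within the genotyped set), `P_nc`, `psi`, `g_cc_inv` and `g_inv`
#'   (sparse APY inverse over all genotyped animals).
#' @export
apy_decompose <- function(genomic, core_ids) {
  stopifnot(inherits(genomic, "mcg_genomic"), length(core_ids) >= 1)
  ids <- genomic$ids
  core_idx <- match(core_ids, ids)
  if (anyNA(core_idx)) abort("core_ids must be genotyped animals")
  core_idx <- sort(unique(core_idx))
  noncore_idx <- setdiff(seq_along(ids), core_idx)
  G <- genomic$g_blend
  Gcc <- G[core_idx, core_idx, drop = FALSE]
  ch <- tryCatch(chol(Gcc), error = function(e) abort("singular core block G_cc"))
  g_cc_inv <- chol2inv(ch)
  if (length(noncore_idx)) {
    Gnc <- G[noncore_idx, core_idx, drop = FALSE]
    P_nc <- Gnc %*% g_cc_inv
    psi <- diag(G)[noncore_idx] - rowSums(P_nc * Gnc)
    if (any(psi <= 0)) abort("non-positive APY conditional variance Psi")
    # Sparse APY inverse in (core, non-core) blocks, scattered to genotyped order
    n <- length(ids)
    Psi_inv <- 1 / psi
    M11 <- g_cc_inv + crossprod(P_nc * sqrt(Psi_inv))
    G_inv <- matrix(0, n, n)
    G_inv[core_idx, core_idx] <- M11
    G_inv[core_idx, noncore_idx] <- -t(P_nc * Psi_inv)
    G_inv[noncore_idx, core_idx] <- -(P_nc * Psi_inv)
    G_inv[noncore_idx, noncore_idx] <- diag(Psi_inv, nrow = length(noncore_idx))
  } else {
    P_nc <- matrix(0, 0, length(core_idx))
    psi <- numeric(0)
    G_inv <- g_cc_inv
  }
  structure(list(ids = ids, core_idx = core_idx, noncore_idx = noncore_idx,
                 P_nc = P_nc, psi = psi, g_cc_inv = g_cc_inv,
                 g_inv = as(G_inv, "CsparseMatrix")),
            class = "mcg_apy")
}

# APY-implied genomic relationship matrix (dense reconstruction oracle):
# core block exact, non-core conditioned on core with diagonal Psi.
apy_implied_G <- function(genomic, apy) {
  G <- genomic$g_blend
  n <- nrow(G)
  ci <- apy$core_idx; ni <- apy$noncore_idx
  H <- matrix(0, n, n)
  H[ci, ci] <- G[ci, ci]
  if (length(ni)) {
    H[ni, ci] <- apy$P_nc %*% G[ci, ci]
    H[ci, ni] <- t(H[ni, ci])
    Hnn <- apy$P_nc %*% G[ci, ci] %*% t(apy$P_nc)
    diag(Hnn) <- diag(Hnn) + apy$psi
    H[ni, ni] <- Hnn
  }
  H
}
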