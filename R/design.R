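#' Build the model design
#'
#' Turns a renumbered pedigree, a phenotype table and a model specification
#' into the equation layout and sparse incidence structures of the mixed model
#' equations: observations are the observed (record, trait) pairs, fixed class
#' effects expand to one equation per (level, trait), H-structured groups span
#' all pedigree animals, identity groups span the observed mapping levels, and
#' each record carries a missingness-pattern id used for per-pattern residual
#' inversion. Records that need a dam mapping (maternal columns) but have an
#' unknown dam are dropped (default policy) or raise an error.
#'
#' @param ped renumbered pedigree.
#' @param pheno phenotype tibble: `animal` (codes or original ids), fixed
#'   effect columns, one numeric column per trait with `NA` for missing.
#' @param spec an [model_spec()].
#' @return A list of class `mcg_design`; key elements: `y` (observation
#'   vector), `X`, `Z` (list per group), `Q`, `groups` (layout metadata),
#'   `patterns`, `pattern_of`, `n_ij`, `layout` tibble, `n_eq`.
#' @export
build_design <- function(ped, pheno, spec) {
  ped <- as_pedigree(ped)
  pheno <- tibble::as_tibble(pheno)
  traits <- spec$traits
  t <- length(traits)
  stopifnot(all(traits %in% names(pheno)))

  # map animal ids to codes
  if (is.character(pheno$animal) || is.factor(pheno$animal)) {
    map <- attr(ped, "id_map")
    code <- map$code[match(as.character(pheno$animal), map$id)]
  } else {
    code <- as.integer(pheno$animal)
    code[code < 1L | code > nrow(ped)] <- NA_integer_
  }
  if (anyNA(code)) {
    abort(sprintf("%d phenotype record(s) reference animals absent from the pedigree",
                  sum(is.na(code))))
  }
  dam <- ped$dam[code]

  vals <- as.matrix(pheno[, traits, drop = FALSE])
  obs_mask <- !is.na(vals)
  keep <- rowSums(obs_mask) > 0

  # unknown-dam policy for maternal (dam-mapped) columns
  dam_traits <- unique(unlist(lapply(spec$random, function(g)
    g$columns$trait[g$columns$role == "dam"])))
  if (length(dam_traits)) {
    needs_dam <- rowSums(obs_mask[, match(dam_traits, traits), drop = FALSE]) > 0
    bad <- needs_dam & dam == 0L
    if (any(bad)) {
      if (spec$unknown_dam == "error") {
        abort(sprintf("%d record(s) with unknown dam under a maternal model", sum(bad)))
      }
      inform(sprintf("dropping %d record(s) with unknown dam (maternal model)", sum(bad)))
      keep <- keep & !bad
    }
  }

  code <- code[keep]; dam <- dam[keep]
  vals <- vals[keep, , drop = FALSE]
  obs_mask <- obs_mask[keep, , drop = FALSE]
  pheno <- pheno[keep, , drop = FALSE]
  n_rec <- nrow(vals)
  if (n_rec == 0L) abort("no usable records")

  # observations, record-major
  obs_rec <- rep(seq_len(n_rec), each = t)[as.vector(t(obs_mask))]
  obs_trait <- rep(seq_len(t), times = n_rec)[as.vector(t(obs_mask))]
  n_obs <- length(obs_rec)
  y <- vals[cbind(obs_rec, obs_trait)]

  # missingness patterns
  pat_key <- apply(obs_mask, 1L, function(r) paste(as.integer(r), collapse = ""))
  pat_levels <- unique(pat_key)
  pattern_of <- match(pat_key, pat_levels)
  patterns <- lapply(pat_levels, function(k) as.integer(strsplit(k, "")[[1]]) == 1L)

  n_ij <- crossprod(obs_mask)
  dimnames(n_ij) <- list(traits, traits)

  layout <- list()
  eq <- 0L

  # fixed effects
  Xi <- Xj <- list()
  for (f in spec$fixed) {
    fac <- factor(pheno[[f$column]])
    for (tr in f$traits) {
      k <- match(tr, traits)
      sel <- which(obs_trait == k)
      lv <- droplevels(fac[obs_rec[sel]])
      levs <- levels(lv)
      if (!length(levs)) next
      Xi[[length(Xi) + 1L]] <- sel
      Xj[[length(Xj) + 1L]] <- eq + as.integer(lv)
      layout[[length(layout) + 1L]] <- tibble::tibble(
        effect = f$name, type = "fixed", trait = tr, role = NA_character_,
        level = levs, eq = eq + seq_along(levs))
      eq <- eq + length(levs)
    }
  }
  n_fixed <- eq
  X <- Matrix::sparseMatrix(i = unlist(Xi) %||% integer(0),
                            j = unlist(Xj) %||% integer(0),
                            x = 1, dims = c(n_obs, n_fixed))

  # random groups
  groups <- list()
  Z <- list()
  for (g in spec$random) {
    cols <- g$columns
    tk <- nrow(cols)
    mapv <- function(role) if (role == "dam") dam else code
    if (g$kind == "h") {
      q <- nrow(ped)
      level_codes <- seq_len(q)
      lvl_of <- function(codes) codes
    } else {
      used <- sort(unique(unlist(lapply(seq_len(tk), function(c) {
        k <- match(cols$trait[c], traits)
        mv <- mapv(cols$role[c])
        mv[obs_rec[obs_trait == k]]
      }))))
      used <- used[used > 0L]
      q <- length(used)
      level_codes <- used
      lvl_of <- function(codes) match(codes, used)
    }
    zi <- zj <- list()
    for (c in seq_len(tk)) {
      k <- match(cols$trait[c], traits)
      sel <- which(obs_trait == k)
      mv <- mapv(cols$role[c])[obs_rec[sel]]
      ok <- mv > 0L
      lv <- lvl_of(mv[ok])
      zi[[c]] <- sel[ok]
      zj[[c]] <- (c - 1L) * q + lv
    }
    Zg <- Matrix::sparseMatrix(i = unlist(zi), j = unlist(zj), x = 1,
                               dims = c(n_obs, tk * q))
    Z[[g$name]] <- Zg
    for (c in seq_len(tk)) {
      layout[[length(layout) + 1L]] <- tibble::tibble(
        effect = g$name, type = "random", trait = cols$trait[c],
        role = cols$role[c], level = as.character(level_codes),
        eq = eq + (c - 1L) * q + seq_len(q))
    }
    groups[[g$name]] <- list(name = g$name, kind = g$kind, q = q, t = tk,
                             columns = cols, mask = g$mask,
                             level_codes = level_codes, eq_offset = eq)
    eq <- eq + tk * q
  }

  Q <- do.call(cbind, c(list(X), Z))
  structure(list(
    ped = ped, spec = spec, traits = traits, n_rec = n_rec, n_obs = n_obs,
    record_animal = code, record_dam = dam,
    obs_rec = obs_rec, obs_trait = obs_trait, y = y,
    X = X, Z = Z, Q = Q, n_fixed = n_fixed, n_eq = eq,
    groups = groups, patterns = patterns, pattern_of = pattern_of,
    n_ij = n_ij, layout = dplyr::bind_rows(layout),
    n_dropped_records = sum(!keep)
  ), class = "mcg_design")
}

# Per-pattern restricted residual matrices under R0: inverses (embedded in
# t x t with zeros at missing traits) and lower Cholesky factors for sampling.
pattern_blocks <- function(design, R0) {
  t <- length(design$traits)
  lapply(design$patterns, function(msk) {
    sub <- R0[msk, msk, drop = FALSE]
    ch <- tryCatch(chol(sub), error = function(e)
      abort("residual covariance not positive definite on an observed pattern"))
    inv <- chol2inv(ch)
    inv_full <- matrix(0, t, t)
    inv_full[msk, msk] <- inv
    list(mask = msk, inv = inv, inv_full = inv_full,
         chol_lower = t(ch), logdet = 2 * sum(log(diag(ch))))
  })
}

# Sparse R^{-1} over observations (block diagonal per record).
rinv_matrix <- function(design, R0) {
  blocks <- pattern_blocks(design, R0)
  t <- length(design$traits)
  # observation index lookup: (rec, trait) -> obs position
  pos <- matrix(0L, design$n_rec, t)
  pos[cbind(design$obs_rec, design$obs_trait)] <- seq_len(design$n_obs)
  ii <- jj <- xx <- list()
  for (p in seq_along(blocks)) {
    recs <- which(design$pattern_of == p)
    if (!length(recs)) next
    msk <- blocks[[p]]$mask
    tr <- which(msk)
    inv <- blocks[[p]]$inv
    k <- length(tr)
    oi <- pos[recs, tr, drop = FALSE]  # n_recs x k obs indices
    ii[[p]] <- as.vector(oi[, rep(seq_len(k), each = k), drop = FALSE])
    jj[[p]] <- as.vector(oi[, rep(seq_len(k), times = k), drop = FALSE])
    xx[[p]] <- rep(as.vector(t(inv)), each = length(recs))
  }
  Matrix::forceSymmetric(Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(design$n_obs, design$n_obs)))
}

# Map an observation-level vector to a record x trait matrix (0 where missing).
obs_to_matrix <- function(design, v) {
  out <- matrix(0, design$n_rec, length(design$traits))
  out[cbind(design$obs_rec, design$obs_trait)] <- v
  out
}

# Equation indices of column c of group g.
group_col_idx <- function(design, gname, c) {
  g <- design$groups[[gname]]
  g$eq_offset + (c - 1L) * g$q + seq_len(g$q)
}
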