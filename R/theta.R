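#' Initial variance state for a model
#'
#' The parameter set θ holds one symmetric covariance matrix per random-effect
#' group plus the residual covariance R0, together with structural-zero masks.
#' Starting values are 1 for variances and 0.1 for covariances unless the
#' specification overrides them; masked entries are exactly 0.
#'
#' @param spec an [model_spec()].
#' @return A list of class `mcg_theta` with elements `groups` (named list of
#'   matrices), `masks`, `R0`, `R_mask`.
#' @export
variance_state <- function(spec) {
  t <- length(spec$traits)
  v0 <- spec$start$variance
  c0 <- spec$start$covariance
  mk <- function(k, mask) {
    m <- matrix(c0, k, k)
    diag(m) <- v0
    m[!mask] <- 0
    m
  }
  groups <- list()
  masks <- list()
  for (g in spec$random) {
    k <- nrow(g$columns)
    groups[[g$name]] <- mk(k, g$mask)
    masks[[g$name]] <- g$mask
  }
  R0 <- mk(t, spec$residual_mask)
  structure(list(groups = groups, masks = masks, R0 = R0,
                 R_mask = spec$residual_mask),
            class = "mcg_theta")
}

#' Free-parameter index of a variance state
#'
#' Enumerates the free (unmasked, upper-triangle) parameters across all group
#' covariance matrices and R0, in group order then residual; this ordering is
#' shared by the gradient, the AI matrix and the update steps.
#'
#' @param theta an `mcg_theta`.
#' @return tibble with columns `param`, `block` (group name or `"residual"`),
#'   `i`, `j`, `type` (`"variance"`/`"covariance"`).
#' @export
theta_index <- function(theta) {
  rows <- list()
  for (nm in names(theta$groups)) {
    m <- theta$masks[[nm]]
    k <- nrow(m)
    for (i in seq_len(k)) for (j in i:k) {
      if (m[i, j]) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          block = nm, i = i, j = j,
          type = if (i == j) "variance" else "covariance")
      }
    }
  }
  t <- nrow(theta$R0)
  for (i in seq_len(t)) for (j in i:t) {
    if (theta$R_mask[i, j]) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        block = "residual", i = i, j = j,
        type = if (i == j) "variance" else "covariance")
    }
  }
  out <- dplyr::bind_rows(rows)
  out$param <- paste0(out$block, "[", out$i, ",", out$j, "]")
  out[, c("param", "block", "i", "j", "type")]
}

# vech extraction / insertion over the free parameters
theta_to_vech <- function(theta, index = theta_index(theta)) {
  vapply(seq_len(nrow(index)), function(r) {
    b <- index$block[r]
    m <- if (b == "residual") theta$R0 else theta$groups[[b]]
    m[index$i[r], index$j[r]]
  }, numeric(1))
}

vech_to_theta <- function(theta, v, index = theta_index(theta)) {
  for (r in seq_len(nrow(index))) {
    b <- index$block[r]
    if (b == "residual") {
      theta$R0[index$i[r], index$j[r]] <- v[r]
      theta$R0[index$j[r], index$i[r]] <- v[r]
    } else {
      theta$groups[[b]][index$i[r], index$j[r]] <- v[r]
      theta$groups[[b]][index$j[r], index$i[r]] <- v[r]
    }
  }
  theta
}

# Positive-definiteness of every unmasked principal structure: each group's
# covariance restricted to columns with any free entry, and R0 restricted to
# every observed pattern, must admit a Cholesky factor.
theta_in_space <- function(theta, design = NULL) {
  ok_mat <- function(m) {
    d <- diag(m)
    if (any(d <= 0)) return(FALSE)
    !inherits(tryCatch(chol(m), error = function(e) e), "error")
  }
  for (nm in names(theta$groups)) {
    if (!ok_mat(theta$groups[[nm]])) return(FALSE)
  }
  if (!is.null(design)) {
    for (p in design$patterns) {
      if (!ok_mat(theta$R0[p, p, drop = FALSE])) return(FALSE)
    }
    TRUE
  } else {
    ok_mat(theta$R0)
  }
}

# Nearest-SPD projection (eigenvalue clipping), preserving the mask.
project_spd <- function(m, mask, floor_frac = 1e-6) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  floor_val <- max(abs(e$values)) * floor_frac
  vals <- pmax(e$values, floor_val)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  out[!mask] <- 0
  out
}
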