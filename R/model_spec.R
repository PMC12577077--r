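#' Specify a multi-trait mixed model
#'
#' Declares the traits, fixed class effects, correlated random-effect groups,
#' residual structure and the estimation settings of a (single-step) animal
#' model. A random-effect group is a set of columns (trait, role) sharing one
#' covariance structure `K`:
#' \itemize{
#'   \item `kind = "h"` — pedigree (or H when genotypes are present) structure
#'     over all pedigree animals; `role = "animal"` maps a record to its
#'     animal (direct genetic effect), `role = "dam"` to its dam (maternal
#'     genetic effect).
#'   \item `kind = "identity"` — i.i.d. levels; `role = "animal"` gives a
#'     permanent environmental effect, `role = "dam"` a maternal permanent
#'     environmental effect.
#' }
#' Structural zeros in a group's covariance matrix or in the residual
#' covariance are declared with symmetric logical masks (`TRUE` = free).
#'
#' @param traits character vector of trait names.
#' @param fixed fixed class effects: a character vector of phenotype-table
#'   column names (each applied to every trait), or a list of
#'   `list(name=, column=, traits=)`.
#' @param random list of groups `list(name=, kind=, columns=, mask=)`, where
#'   `columns` is a data frame with columns `trait` and `role`.
#' @param residual_mask optional symmetric logical matrix (`TRUE` = free);
#'   defaults to all free.
#' @param alpha residual polygenic fraction used when blending G (default
#'   0.05).
#' @param blend G blending convention, `"variance"` or `"sqrt"`.
#' @param apy list `(enabled, n_core, core_rule, seed)`; `core_rule` is
#'   `"random"` (seeded uniform sampling without replacement).
#' @param mc list `(samples, seed, reuse_sequence)`; defaults to 30 samples.
#' @param solver list `(tol_data, tol_mc, max_iter)`.
#' @param convergence list `(t1, t2, max_rounds)`; defaults `1e-12`, `1e-4`,
#'   100.
#' @param start list `(variance, covariance)` starting values (defaults 1 and
#'   0.1).
#' @param missing_code sentinel for missing trait values in phenotype files.
#' @param zero_is_missing logical (scalar or per trait): treat the sentinel as
#'   missing (blupf90 convention).
#' @param unknown_dam policy for records needing a dam mapping with unknown
#'   dam: `"drop"` (default, logged) or `"error"`.
#' @return A list of class `mcg_model_spec`.
#' @export
model_spec <- function(traits, fixed = character(), random = list(),
                       residual_mask = NULL, alpha = 0.05,
                       blend = c("variance", "sqrt"),
                       apy = list(enabled = FALSE, n_core = 0L,
                                  core_rule = "random", seed = 1L),
                       mc = list(samples = 30L, seed = 1L, reuse_sequence = TRUE),
                       solver = list(tol_data = 1e-10, tol_mc = 1e-6, max_iter = 5000L),
                       convergence = list(t1 = 1e-12, t2 = 1e-4, max_rounds = 100L),
                       start = list(variance = 1.0, covariance = 0.1),
                       missing_code = 0, zero_is_missing = TRUE,
                       unknown_dam = c("drop", "error")) {
  blend <- match.arg(blend)
  unknown_dam <- match.arg(unknown_dam)
  traits <- as.character(traits)
  t <- length(traits)
  stopifnot(t >= 1)
  if (is.character(fixed)) {
    fixed <- lapply(fixed, function(cn) list(name = cn, column = cn, traits = traits))
  } else {
    fixed <- lapply(fixed, function(f) {
      list(name = f$name %||% f$column, column = f$column %||% f$name,
           traits = f$traits %||% traits)
    })
  }
  random <- lapply(random, function(g) {
    cols <- tibble::as_tibble(g$columns)
    stopifnot(all(c("trait", "role") %in% names(cols)),
              all(cols$trait %in% traits),
              all(cols$role %in% c("animal", "dam")))
    tk <- nrow(cols)
    mask <- g$mask %||% matrix(TRUE, tk, tk)
    mask <- as.matrix(mask)
    stopifnot(nrow(mask) == tk, ncol(mask) == tk,
              isTRUE(all(mask == t(mask))), all(diag(mask)))
    kind <- match.arg(g$kind, c("h", "identity"))
    list(name = g$name, kind = kind, columns = cols, mask = mask)
  })
  if (is.null(residual_mask)) residual_mask <- matrix(TRUE, t, t)
  residual_mask <- as.matrix(residual_mask)
  stopifnot(nrow(residual_mask) == t, isTRUE(all(residual_mask == t(residual_mask))),
            all(diag(residual_mask)))
  stopifnot(alpha >= 0, alpha <= 1, (mc$samples %||% 30L) >= 1)
  defaults <- function(x, d) utils::modifyList(d, as.list(x))
  spec <- list(
    traits = traits,
    fixed = fixed,
    random = random,
    residual_mask = residual_mask,
    alpha = alpha,
    blend = blend,
    apy = defaults(apy, list(enabled = FALSE, n_core = 0L, core_rule = "random", seed = 1L)),
    mc = defaults(mc, list(samples = 30L, seed = 1L, reuse_sequence = TRUE)),
    solver = defaults(solver, list(tol_data = 1e-10, tol_mc = 1e-6, max_iter = 5000L)),
    convergence = defaults(convergence, list(t1 = 1e-12, t2 = 1e-4, max_rounds = 100L)),
    start = defaults(start, list(variance = 1.0, covariance = 0.1)),
    missing_code = missing_code,
    zero_is_missing = zero_is_missing,
    unknown_dam = unknown_dam
  )
  class(spec) <- "mcg_model_spec"
  spec
}

#' Read a model configuration file
#'
#' Reads a YAML configuration with sections `files`, `model`, `solver`, `mc`,
#' `apy`, `convergence` and builds an [model_spec()]. The `model` section
#' declares trait names, the 1-based column positions of the animal id, fixed
#' effects and traits in the phenotype file, the random-effect groups, masks
#' (as 0/1 matrices, row lists), `alpha` and the missing-value convention.
#'
#' @param path path to the YAML configuration.
#' @return An `mcg_model_spec`; the `files` section (if present) is attached
#'   as attribute `"files"`, the phenotype column map as attribute `"columns"`.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  m <- cfg$model
  if (is.null(m)) abort("config must contain a 'model' section")
  traits <- as.character(m$traits)
  as_mask <- function(x, d) {
    if (is.null(x)) return(NULL)
    mm <- do.call(rbind, lapply(x, as.numeric))
    matrix(mm != 0, nrow(mm), ncol(mm))
  }
  random <- lapply(m$random %||% list(), function(g) {
    cols <- do.call(rbind, lapply(g$columns, function(cc)
      data.frame(trait = cc$trait, role = cc$role %||% "animal")))
    list(name = g$name, kind = g$kind %||% "h", columns = cols,
         mask = as_mask(g$mask))
  })
  fixed <- lapply(m$fixed %||% list(), function(f) {
    list(name = f$name, column = f$name, traits = f$traits %||% traits)
  })
  spec <- model_spec(
    traits = traits, fixed = fixed, random = random,
    residual_mask = as_mask(m$residual_mask),
    alpha = m$alpha %||% 0.05,
    blend = m$blend %||% "variance",
    apy = cfg$apy %||% list(),
    mc = cfg$mc %||% list(),
    solver = cfg$solver %||% list(),
    convergence = cfg$convergence %||% list(),
    start = cfg$start %||% list(),
    missing_code = m$missing_code %||% 0,
    zero_is_missing = m$zero_is_missing %||% TRUE,
    unknown_dam = m$unknown_dam %||% "drop"
  )
  attr(spec, "files") <- cfg$files
  attr(spec, "columns") <- m$columns
  spec
}

#' Read a phenotype file
#'
#' Whitespace-delimited phenotype table without header; column roles come from
#' the configuration (`columns` attribute of [read_config()]) or from the
#' `columns` argument.
#'
#' @param path path to the phenotype file.
#' @param spec an `mcg_model_spec`.
#' @param columns list with 1-based positions: `animal`, named list `fixed`,
#'   named list `traits`. Defaults to the spec's `"columns"` attribute.
#' @return tibble with columns `animal` (character), one column per fixed
#'   effect and one numeric column per trait (`NA` = missing after applying
#'   the sentinel convention).
#' @export
read_phenotypes <- function(path, spec, columns = NULL) {
  stopifnot(file.exists(path))
  columns <- columns %||% attr(spec, "columns")
  if (is.null(columns)) abort("phenotype column map missing (config 'model: columns')")
  raw <- utils::read.table(path, header = FALSE, colClasses = "character")
  out <- tibble::tibble(animal = raw[[columns$animal]])
  for (nm in names(columns$fixed %||% list())) {
    out[[nm]] <- raw[[columns$fixed[[nm]]]]
  }
  zim <- spec$zero_is_missing
  if (length(zim) == 1L) zim <- rep(zim, length(spec$traits))
  for (k in seq_along(spec$traits)) {
    tr <- spec$traits[k]
    v <- as.numeric(raw[[columns$traits[[tr]]]])
    if (zim[k]) v[v == spec$missing_code] <- NA_real_
    out[[tr]] <- v
  }
  out
}

#' Load a full dataset from a configuration file
#'
#' Reads the configuration, then the pedigree, genotype (optional) and
#' phenotype files it points to; renumbers the pedigree, maps genotyped and
#' recorded ids to codes, and drops monomorphic loci.
#'
#' @param config path to the YAML configuration, or an `mcg_model_spec` with
#'   `files`/`columns` attributes.
#' @param dir base directory for relative file paths (defaults to the
#'   configuration file's directory).
#' @return list with elements `ped`, `geno` (or `NULL`), `pheno`, `spec`.
#' @export
load_dataset <- function(config, dir = NULL) {
  if (is.character(config)) {
    dir <- dir %||% dirname(config)
    spec <- read_config(config)
  } else {
    spec <- config
    dir <- dir %||% "."
  }
  files <- attr(spec, "files")
  if (is.null(files)) abort("configuration has no 'files' section")
  pth <- function(p) if (file.exists(p)) p else file.path(dir, p)
  ped <- renumber_pedigree(read_pedigree(pth(files$pedigree)))
  geno <- NULL
  if (!is.null(files$genotypes)) {
    gt <- read_genotypes(pth(files$genotypes))
    geno <- genotype_set(gt$id, do.call(rbind, gt$dosage), ped = ped)
  }
  pheno <- read_phenotypes(pth(files$phenotypes), spec)
  list(ped = ped, geno = geno, pheno = pheno, spec = spec)
}
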