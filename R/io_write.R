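# Writers for the file dialects the package reads (round-trip safe), plus
# debugging writers for relationship matrices and MME solutions.

#' Write a pedigree file
#'
#' `animal sire dam` whitespace-delimited, using the original ids of the
#' renumbered pedigree's `id_map` (codes if no map is attached).
#'
#' @param ped renumbered pedigree.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  ped <- as_pedigree(ped)
  map <- attr(ped, "id_map")
  id_of <- function(code) ifelse(code == 0L, "0", map$id[match(code, map$code)])
  df <- data.frame(a = id_of(ped$animal), s = id_of(ped$sire), d = id_of(ped$dam))
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a SNP dosage file
#'
#' `"ID<space>digits"` with one `{0,1,2}` character per locus.
#'
#' @param geno an `mcg_genotypes` (raw dosages are written).
#' @param path output path.
#' @param ids optional ids to write (defaults to the stored codes).
#' @return the path, invisibly.
#' @export
write_genotypes <- function(geno, path, ids = NULL) {
  ids <- ids %||% geno$ids
  strs <- apply(geno$M_raw, 1L, function(r) paste(as.integer(r), collapse = ""))
  writeLines(paste(ids, strs), path)
  invisible(path)
}

#' Write a phenotype file
#'
#' Whitespace-delimited, no header: animal id, fixed-effect columns, trait
#' values with missing entries written as the spec's missing code.
#'
#' @param pheno phenotype tibble (`animal`, fixed columns, trait columns).
#' @param spec the `mcg_model_spec`.
#' @param path output path.
#' @return the column map (`animal`, `fixed`, `traits` positions), invisibly.
#' @export
write_phenotypes <- function(pheno, spec, path) {
  fixed_cols <- unique(vapply(spec$fixed, `[[`, character(1), "column"))
  df <- data.frame(animal = as.character(pheno$animal))
  for (fc in fixed_cols) df[[fc]] <- as.character(pheno[[fc]])
  for (tr in spec$traits) {
    v <- pheno[[tr]]
    v[is.na(v)] <- spec$missing_code
    df[[tr]] <- format(v, digits = 10, trim = TRUE, scientific = FALSE)
  }
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  columns <- list(animal = 1L,
                  fixed = stats::setNames(as.list(seq_along(fixed_cols) + 1L), fixed_cols),
                  traits = stats::setNames(as.list(seq_along(spec$traits) + 1L + length(fixed_cols)),
                                           spec$traits))
  invisible(columns)
}

#' Write a model configuration file
#'
#' Serialises an `mcg_model_spec` (plus file paths and phenotype column map)
#' to the YAML dialect [read_config()] reads.
#'
#' @param spec the model spec.
#' @param files named list of data file paths (`pedigree`, `genotypes`,
#'   `phenotypes`).
#' @param columns phenotype column map (as returned by
#'   [write_phenotypes()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(spec, files, columns, path) {
  mask_out <- function(m) if (is.null(m) || all(m)) NULL else
    lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
  cfg <- list(
    files = files,
    model = list(
      traits = as.list(spec$traits),
      columns = columns,
      missing_code = spec$missing_code,
      zero_is_missing = spec$zero_is_missing,
      unknown_dam = spec$unknown_dam,
      alpha = spec$alpha,
      blend = spec$blend,
      fixed = lapply(spec$fixed, function(f) list(name = f$name, traits = as.list(f$traits))),
      random = lapply(spec$random, function(g) {
        list(name = g$name, kind = g$kind,
             columns = lapply(seq_len(nrow(g$columns)), function(r)
               list(trait = g$columns$trait[r], role = g$columns$role[r])),
             mask = mask_out(g$mask))
      }),
      residual_mask = mask_out(spec$residual_mask)
    ),
    apy = spec$apy, mc = spec$mc, solver = spec$solver,
    convergence = spec$convergence, start = spec$start
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# write pedigree + genotypes + phenotypes + config + truth for a simulated study
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- list(pedigree = file.path(dir, "pedigree.txt"),
            phenotypes = file.path(dir, "phenotypes.txt"),
            config = file.path(dir, "config.yaml"),
            truth = file.path(dir, "truth.yaml"))
  write_pedigree(study$ped, f$pedigree)
  if (!is.null(study$geno)) {
    f$genotypes <- file.path(dir, "genotypes.txt")
    map <- attr(study$ped, "id_map")
    write_genotypes(study$geno, f$genotypes,
                    ids = map$id[match(study$geno$ids, map$code)])
  }
  # phenotypes must carry original ids for the round trip
  map <- attr(study$ped, "id_map")
  ph <- study$pheno
  ph$animal <- map$id[match(ph$animal, map$code)]
  columns <- write_phenotypes(ph, study$spec, f$phenotypes)
  write_config(study$spec,
               files = list(pedigree = basename(f$pedigree),
                            genotypes = if (!is.null(study$geno)) basename(f$genotypes),
                            phenotypes = basename(f$phenotypes)),
               columns = columns, path = f$config)
  yaml::write_yaml(lapply(as.list(study$truth), identity), f$truth)
  f
}

#' Write MME solutions
#'
#' Plain-text `effect trait level solution` table.
#'
#' @param solution an `mcg_fit_solution` (or `mcg_reml`, whose data solution
#'   is used).
#' @param design the matching `mcg_design`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_solutions <- function(solution, design, path) {
  if (inherits(solution, "mcg_reml")) {
    design <- solution$design
    solution <- solution$solution
  }
  df <- design$layout
  df$solution <- solution$sol[df$eq]
  utils::write.table(df[, c("effect", "trait", "level", "solution")], path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a (sparse) matrix in Matrix Market format
#'
#' Debug writer for relationship matrices (`A^{-1}`, G, ...).
#'
#' @param m a base or Matrix matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_matrix_market <- function(m, path) {
  Matrix::writeMM(as(as(m, "CsparseMatrix"), "generalMatrix"), path)
  invisible(path)
}
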