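# Synthetic study generator: multi-generation pedigree with a genotyped
# subset, multi-trait records with trait-specific missingness, contemporary
# group fixed effects, and direct + maternal + permanent-environment random
# effects with known true (co)variances.

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration of a synthetic study
#'
#' Bundles the population structure, marker panel, recording scheme and true
#' parameter values from which [simulate_study()] generates a dataset.
#'
#' @param spec the [model_spec()] that will also be used for estimation.
#' @param theta_true an `mcg_theta` with the true (co)variances (masks must
#'   match the spec).
#' @param n_founders founder animals (generation 1).
#' @param n_generations total number of discrete generations (including
#'   founders).
#' @param n_matings random matings per generation.
#' @param n_offspring offspring per mating.
#' @param m_loci marker count.
#' @param freq_range range of founder allele frequencies (uniform).
#' @param genotyped_fraction fraction of animals genotyped.
#' @param genotyped_rule `"youngest"` (default) or `"random"`.
#' @param record_prob per-trait probability that a recorded animal has an
#'   observation for the trait (recycled).
#' @param cg_per_gen contemporary groups per generation (sizes kept >= 5 by
#'   construction when matings are not tiny).
#' @param cg_sd standard deviation of the contemporary-group effects.
#' @param h_truth if `TRUE`, true breeding values are drawn from the
#'   ssGBLUP (H) covariance through the sampler instead of the pedigree
#'   covariance.
#' @param base_seed seed controlling every random choice of the generator.
#' @return list of class `mcg_sim_config`.
#' @export
sim_config <- function(spec, theta_true,
                       n_founders = 40L, n_generations = 4L,
                       n_matings = 30L, n_offspring = 2L,
                       m_loci = 200L, freq_range = c(0.1, 0.9),
                       genotyped_fraction = 0.3,
                       genotyped_rule = c("youngest", "random"),
                       record_prob = 0.9, cg_per_gen = 2L, cg_sd = 1,
                       h_truth = FALSE, base_seed = 1L) {
  genotyped_rule <- match.arg(genotyped_rule)
  stopifnot(inherits(spec, "mcg_model_spec"), inherits(theta_true, "mcg_theta"),
            n_founders >= 2)
  record_prob <- rep(record_prob, length.out = length(spec$traits))
  structure(list(spec = spec, theta_true = theta_true,
                 n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 n_matings = as.integer(n_matings),
                 n_offspring = as.integer(n_offspring),
                 m_loci = as.integer(m_loci), freq_range = freq_range,
                 genotyped_fraction = genotyped_fraction,
                 genotyped_rule = genotyped_rule,
                 record_prob = record_prob,
                 cg_per_gen = as.integer(cg_per_gen), cg_sd = cg_sd,
                 h_truth = isTRUE(h_truth), base_seed = as.integer(base_seed)),
            class = "mcg_sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations with random mating among the previous generation
#' (sires among males, dams among females, sex assigned at birth); parents
#' always precede offspring, so the returned pedigree is already in
#' topological order.
#'
#' @param cfg an `mcg_sim_config`.
#' @return renumbered `mcg_pedigree` with a `generation` attribute (integer
#'   per animal).
#' @export
simulate_pedigree <- function(cfg) {
  with_seed(site_seed(cfg$base_seed, "pedigree"), {
    animal <- seq_len(cfg$n_founders)
    sire <- dam <- rep(0L, cfg$n_founders)
    sex <- rep_len(c(1L, 2L), cfg$n_founders)  # deterministic alternation keeps both sexes
    gen <- rep(1L, cfg$n_founders)
    if (cfg$n_generations > 1L) {
      for (g in 2L:cfg$n_generations) {
        prev <- which(gen == g - 1L)
        males <- prev[sex[prev] == 1L]
        females <- prev[sex[prev] == 2L]
        if (!length(males) || !length(females)) abort("a generation lost one sex")
        for (m in seq_len(cfg$n_matings)) {
          s <- males[sample.int(length(males), 1L)]
          d <- females[sample.int(length(females), 1L)]
          for (o in seq_len(cfg$n_offspring)) {
            animal <- c(animal, length(animal) + 1L)
            sire <- c(sire, s); dam <- c(dam, d)
            sex <- c(sex, sample(c(1L, 2L), 1L))
            gen <- c(gen, g)
          }
        }
      }
    }
    ped <- renumber_pedigree(tibble::tibble(animal = as.character(animal),
                                            sire = as.character(sire),
                                            dam = as.character(dam)))
    attr(ped, "generation") <- gen
    ped
  })
}

#' Simulate genotypes by allele gene dropping
#'
#' Founder haplotypes are drawn per locus from the configured allele-frequency
#' distribution; descendants inherit one random allele per parent per locus
#' (unlinked loci). Dosage is the allele sum; the genotyped subset is the
#' youngest (or a random) fraction.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param cfg an `mcg_sim_config`.
#' @return `mcg_genotypes` over the genotyped subset, with attributes
#'   `haplo1`/`haplo2` (all-animal allele matrices) and `freq_true`.
#' @export
simulate_genotypes <- function(ped, cfg) {
  with_seed(site_seed(cfg$base_seed, "genotypes"), {
    n <- nrow(ped)
    m <- cfg$m_loci
    p <- runif(m, cfg$freq_range[1], cfg$freq_range[2])
    h1 <- h2 <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      s <- ped$sire[i]; d <- ped$dam[i]
      h1[i, ] <- if (s > 0L) {
        ifelse(runif(m) < 0.5, h1[s, ], h2[s, ])
      } else rbinom(m, 1L, p)
      h2[i, ] <- if (d > 0L) {
        ifelse(runif(m) < 0.5, h1[d, ], h2[d, ])
      } else rbinom(m, 1L, p)
    }
    dosage <- h1 + h2
    n_geno <- max(1L, round(cfg$genotyped_fraction * n))
    gids <- if (cfg$genotyped_rule == "youngest") {
      seq.int(n - n_geno + 1L, n)
    } else {
      sort(sample.int(n, n_geno))
    }
    gs <- genotype_set(gids, dosage[gids, , drop = FALSE])
    attr(gs, "haplo1") <- h1
    attr(gs, "haplo2") <- h2
    attr(gs, "freq_true") <- p
    gs
  })
}

#' Simulate a complete study at known truth
#'
#' Generates pedigree and genotypes, draws the true random effects with the
#' exact model covariances (pedigree gene dropping by default, the ssGBLUP
#' sampler when `h_truth` is set), builds records
#' `y = Xb + sum_k Z_k u_k + e` with contemporary-group fixed effects and
#' per-trait missingness, and optionally writes the files in the dialects
#' [load_dataset()] reads.
#'
#' @param cfg an `mcg_sim_config`.
#' @param dir optional output directory; when given, `pedigree.txt`,
#'   `genotypes.txt`, `phenotypes.txt`, `config.yaml` and `truth.yaml` are
#'   written there.
#' @return list with `ped`, `geno`, `pheno`, `spec`, `theta_true`, `truth`
#'   (named true parameter vector), `u_true` (list of stacked true effects)
#'   and `files` (paths, when written).
#' @export
simulate_study <- function(cfg, dir = NULL) {
  spec <- cfg$spec
  theta <- cfg$theta_true
  ped <- simulate_pedigree(cfg)
  gen <- attr(ped, "generation")
  geno <- if (length(spec$random) && any(vapply(spec$random, function(g) g$kind == "h", logical(1))) &&
              cfg$m_loci > 0) simulate_genotypes(ped, cfg) else NULL
  fphi <- compute_inbreeding_phi(ped)
  genomic <- NULL
  if (!is.null(geno) && cfg$h_truth) {
    genomic <- build_genomic(geno, pedigree_A22(ped, geno$ids),
                             alpha = spec$alpha, blend = spec$blend)
  }
  hop <- h_operator(ped, genomic = genomic, fphi = fphi)
  n <- nrow(ped)
  t <- length(spec$traits)
  seed_u <- site_seed(cfg$base_seed, "true-effects")

  # records: all animals with known parents (so maternal models are clean)
  rec_animals <- which(ped$sire > 0L & ped$dam > 0L)
  if (!length(rec_animals)) rec_animals <- seq_len(n)
  n_rec <- length(rec_animals)

  # true random effects (stacked, one column)
  u_true <- list()
  u_levels <- list()
  for (g in spec$random) {
    tk <- nrow(g$columns)
    th <- theta$groups[[g$name]]
    if (g$kind == "h") {
      alpha_true <- if (cfg$h_truth) spec$alpha else 1
      u <- draw_u_tilde(hop, th, alpha_true, seed_u,
                        prefix = paste0("truth:", g$name, ":"), ndraw = 1L)
      lev <- seq_len(n)
    } else {
      mapv <- function(role) if (role == "dam") ped$dam[rec_animals] else rec_animals
      lev <- sort(unique(unlist(lapply(seq_len(tk), function(c) mapv(g$columns$role[c])))))
      lev <- lev[lev > 0L]
      L <- chol_lower(th)
      X <- keyed_normals(seed_u, paste0("truth:", g$name, ":iid"),
                         length(lev) * tk, 1L)
      u <- stacked_transform(X, L, length(lev))
    }
    u_true[[g$name]] <- u
    u_levels[[g$name]] <- lev
  }

  out <- with_seed(site_seed(cfg$base_seed, "records"), {
    cg <- paste0("g", gen[rec_animals], "b",
                 sample.int(cfg$cg_per_gen, n_rec, replace = TRUE))
    b <- stats::setNames(lapply(seq_len(t), function(k) {
      lv <- sort(unique(cg))
      stats::setNames(rnorm(length(lv), 0, cfg$cg_sd), lv)
    }), spec$traits)
    Lr <- chol_lower(theta$R0)
    E <- matrix(rnorm(n_rec * t), n_rec, t) %*% t(Lr)
    obs <- matrix(runif(n_rec * t), n_rec, t) <
      matrix(cfg$record_prob, n_rec, t, byrow = TRUE)
    vals <- matrix(NA_real_, n_rec, t)
    for (r in seq_len(n_rec)) {
      an <- rec_animals[r]
      for (k in seq_len(t)) {
        if (!obs[r, k]) next
        y <- b[[k]][cg[r]] + E[r, k]
        for (g in spec$random) {
          cols <- g$columns
          lev <- u_levels[[g$name]]
          q <- length(lev)
          for (c in seq_len(nrow(cols))) {
            if (cols$trait[c] != spec$traits[k]) next
            code <- if (cols$role[c] == "dam") ped$dam[an] else an
            li <- match(code, lev)
            if (!is.na(li)) y <- y + u_true[[g$name]][(c - 1L) * q + li, 1L]
          }
        }
        vals[r, k] <- y
      }
    }
    list(cg = cg, vals = vals)
  })

  pheno <- tibble::tibble(animal = rec_animals, cg = out$cg)
  for (k in seq_len(t)) pheno[[spec$traits[k]]] <- out$vals[, k]

  index <- theta_index(theta)
  truth <- stats::setNames(theta_to_vech(theta, index), index$param)
  res <- list(ped = ped, geno = geno, pheno = pheno, spec = spec,
              theta_true = theta, truth = truth, u_true = u_true,
              generation = gen)
  if (!is.null(dir)) {
    res$files <- write_study(res, dir)
  }
  res
}
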