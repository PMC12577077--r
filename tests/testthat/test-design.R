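test_that("equation counts follow levels x traits for generated model specs", {
  ped <- random_ped(40, 2)
  set.seed(6)
  pheno <- tibble::tibble(animal = 11:40,
                          cg = sample(c("a", "b", "c"), 30, replace = TRUE),
                          herd = sample(c("h1", "h2"), 30, replace = TRUE),
                          t1 = rnorm(30), t2 = rnorm(30))
  pheno$t2[sample(30, 8)] <- NA
  for (groups in list(
    list(list(name = "g", kind = "h",
              columns = data.frame(trait = c("t1", "t2"), role = "animal"))),
    list(list(name = "g", kind = "h",
              columns = data.frame(trait = "t1", role = "animal")),
         list(name = "pe", kind = "identity",
              columns = data.frame(trait = c("t1", "t2"), role = "animal")))
  )) {
    spec <- model_spec(traits = c("t1", "t2"), fixed = c("cg", "herd"),
                       random = groups)
    design <- build_design(ped, pheno, spec)
    expected <- design$n_fixed +
      sum(vapply(design$groups, function(g) g$t * g$q, numeric(1)))
    expect_equal(design$n_eq, expected)
    expect_equal(ncol(design$Q), design$n_eq)
    expect_equal(length(design$y), design$n_obs)
    # H-structured groups span the whole pedigree
    for (g in design$groups) {
      if (g$kind == "h") expect_equal(g$q, nrow(ped))
    }
  }
})

test_that("single trait, mean-only fixed effect gives 1 + q equations", {
  ped <- renumber_pedigree(tibble::tibble(animal = as.character(1:6),
                                          sire = "0", dam = "0"))
  pheno <- tibble::tibble(animal = 1:6, mu = "1", y = rnorm(6))
  spec <- model_spec(traits = "y", fixed = "mu",
                     random = list(list(name = "u", kind = "h",
                                        columns = data.frame(trait = "y",
                                                             role = "animal"))))
  design <- build_design(ped, pheno, spec)
  expect_equal(design$n_eq, 1L + 6L)
})

test_that("maternal columns map records to the dam; unknown dams are dropped", {
  # animals 3..6 have dams; animal 7 has unknown dam
  ped <- renumber_pedigree(tibble::tibble(
    animal = as.character(1:7),
    sire = c("0", "0", "1", "1", "1", "1", "1"),
    dam = c("0", "0", "2", "2", "2", "2", "0")))
  pheno <- tibble::tibble(animal = 3:7, cg = "1", y = rnorm(5))
  spec <- model_spec(traits = "y", fixed = "cg",
                     random = list(list(name = "mat", kind = "h",
                                        columns = data.frame(trait = "y",
                                                             role = "dam"))))
  expect_message(design <- build_design(ped, pheno, spec), "unknown dam")
  expect_equal(design$n_rec, 4L)
  # incidence points at the dam's equation
  Z <- design$Z$mat
  expect_equal(which(Z[1, ] != 0), 2L)  # dam of animal 3 is code 2
  spec_err <- spec; spec_err$unknown_dam <- "error"
  expect_error(build_design(ped, pheno, spec_err), "unknown dam")
})

test_that("per-pattern residual handling matches a dense GLS fit with absent rows", {
  # fixed-effects-only two-trait model with missing trait-2 records
  ped <- renumber_pedigree(tibble::tibble(animal = as.character(1:8),
                                          sire = "0", dam = "0"))
  set.seed(12)
  pheno <- tibble::tibble(animal = 1:8,
                          cg = rep(c("a", "b"), 4),
                          t1 = rnorm(8), t2 = rnorm(8))
  pheno$t2[c(2, 5, 7)] <- NA
  spec <- model_spec(traits = c("t1", "t2"), fixed = "cg")
  design <- build_design(ped, pheno, spec)
  R0 <- matrix(c(1.0, 0.3, 0.3, 0.8), 2)
  theta <- variance_state(spec); theta$R0 <- R0
  op <- assemble_operator(design, theta)
  sol <- solve_mme(op, tol = 1e-12)
  # dense GLS treating missing observations as absent rows
  X <- as.matrix(design$X)
  R <- matrix(0, design$n_obs, design$n_obs)
  for (r in seq_len(design$n_rec)) {
    oo <- which(design$obs_rec == r)
    R[oo, oo] <- R0[design$obs_trait[oo], design$obs_trait[oo]]
  }
  b_gls <- solve(t(X) %*% solve(R, X), t(X) %*% solve(R, design$y))
  expect_equal(sol$sol, drop(b_gls), tolerance = 1e-8)
  # pattern bookkeeping
  expect_equal(sort(unique(design$pattern_of)), seq_along(design$patterns))
  expect_equal(design$n_ij["t1", "t1"], 8)
  expect_equal(design$n_ij["t1", "t2"], 5)
})

test_that("config and file round trips reproduce the internal structures", {
  fx <- small_ss_fixture()
  dir <- withr::local_tempdir()
  st <- fx$st
  files <- mcgreml:::write_study(st, dir)
  ds <- load_dataset(files$config)
  expect_equal(nrow(ds$ped), nrow(st$ped))
  expect_equal(ds$ped$sire, st$ped$sire)
  expect_equal(ds$geno$M, st$geno$M, tolerance = 1e-12)
  expect_equal(ds$geno$ids, st$geno$ids)
  expect_equal(ds$spec$alpha, st$spec$alpha)
  expect_equal(ds$spec$residual_mask, st$spec$residual_mask)
  # phenotypes: identical observed values and missing pattern
  for (tr in st$spec$traits) {
    expect_equal(is.na(ds$pheno[[tr]]), is.na(st$pheno[[tr]]))
    expect_equal(ds$pheno[[tr]], st$pheno[[tr]], tolerance = 1e-8)
  }
  # identical design after the round trip
  d1 <- build_design(st$ped, st$pheno, st$spec)
  d2 <- build_design(ds$ped, ds$pheno, ds$spec)
  expect_equal(d1$n_eq, d2$n_eq)
  expect_equal(as.matrix(d1$Q), as.matrix(d2$Q))
})
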