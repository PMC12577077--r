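test_that("gene dropping reproduces the pedigree covariance", {
  ped <- fullsib_ped()
  fp <- compute_inbreeding_phi(ped)
  theta <- matrix(1)
  nd <- 50000
  a <- gene_drop(ped, fp$phi, mcgreml:::chol_lower(theta), 42, ndraw = nd)
  A <- pedigree_A(ped)
  emp <- tcrossprod(a) / nd
  expect_cov_match(emp, A, nd, label = "gene drop vs tabular A")
  # founders only, theta = I, two columns: unit variances, zero correlation
  pedf <- renumber_pedigree(tibble::tibble(animal = as.character(1:3),
                                           sire = "0", dam = "0"))
  fpf <- compute_inbreeding_phi(pedf)
  a2 <- gene_drop(pedf, fpf$phi, diag(2), 7, ndraw = nd)
  expect_cov_match(tcrossprod(a2) / nd, diag(6), nd, label = "founder draws")
  # degenerate zero covariance
  a0 <- gene_drop(ped, fp$phi, mcgreml:::chol_lower(matrix(0, 1, 1)), 1, ndraw = 3)
  expect_equal(max(abs(a0)), 0)
})

test_that("marker-effect samples realise G_raw and the J-factor variance", {
  fx <- small_ss_fixture()
  gen <- fx$gen
  nd <- 40000
  L <- diag(1)
  gm <- sample_genomic_terms(gen, L, 99, ndraw = nd)
  vals <- gen$M %*% gm$g
  emp <- tcrossprod(vals) / nd
  expect_cov_match(emp, gen$g_raw, nd, label = "M g covariance")
  expect_equal(var(as.numeric(gm$mu)), gen$j_var, tolerance = 0.05 * gen$j_var + 1e-3)
  # independent columns under theta = I2
  gm2 <- sample_genomic_terms(gen, diag(2), 100, ndraw = nd)
  m <- ncol(gen$M)
  c1 <- gm2$g[1:m, 1]; c2 <- gm2$g[m + (1:m), 1]
  expect_lt(abs(cor(gm2$g[1, ], gm2$g[m + 1, ])), 3 / sqrt(nd))
})

test_that("ssGBLUP combination realises theta (x) H; alpha = 1 is the pure pedigree sample", {
  fx <- small_ss_fixture()
  hop <- fx$hop
  th <- matrix(c(1.0, 0.4, 0.4, 0.7), 2)
  # alpha = 1: u = a exactly
  L <- mcgreml:::chol_lower(th)
  a <- gene_drop(hop$ped, hop$fphi$phi, L, 5, site = "x:gd", ndraw = 4)
  gm <- sample_genomic_terms(fx$gen, L, 5, site_g = "x:g", site_mu = "x:mu", ndraw = 4)
  expect_equal(combine_ssgblup(a, gm$g, gm$mu, alpha = 1, hop)$u, a)
  # the two A12 A22^{-1} backends agree
  c1 <- combine_ssgblup(a, gm$g, gm$mu, 0.05, hop, backend = "ainv")
  c2 <- combine_ssgblup(a, gm$g, gm$mu, 0.05, hop, backend = "dense")
  expect_lt(max(abs(c1$u - c2$u)), 1e-8)
})

test_that("APY all-core equals the full combination bit for bit; psi = 0 is deterministic", {
  fx <- small_ss_fixture()
  hop <- fx$hop
  gen <- fx$gen
  th <- matrix(c(1.0, 0.4, 0.4, 0.7), 2)
  L <- mcgreml:::chol_lower(th)
  a <- gene_drop(hop$ped, hop$fphi$phi, L, 5, site = "y:gd", ndraw = 3)
  gm <- sample_genomic_terms(gen, L, 5, site_g = "y:g", site_mu = "y:mu", ndraw = 3)
  apy_all <- apy_decompose(gen, gen$ids)
  u_full <- combine_ssgblup(a, gm$g, gm$mu, 0.05, hop)$u
  u_apy <- combine_apy(a, gm$g, gm$mu, 0.05, hop, apy_all, L, 5, site_psi = "y:psi")$u
  expect_lt(max(abs(u_full - u_apy)), 1e-10)

  # strict core: non-core values are P_nc u_c plus psi error; with psi forced
  # to zero the non-core values are deterministic given the core
  core <- gen$ids[1:8]
  apy2 <- apy_decompose(gen, core)
  apy0 <- apy2; apy0$psi[] <- 0
  u1 <- combine_apy(a, gm$g, gm$mu, 0.05, hop, apy0, L, 5, site_psi = "z1")$u
  u2 <- combine_apy(a, gm$g, gm$mu, 0.05, hop, apy0, L, 5, site_psi = "z2")$u
  expect_equal(u1, u2, tolerance = 1e-12)
})

test_that("simulated phenotypes respect the missing pattern and residual covariance", {
  fx <- small_ss_fixture()
  design <- fx$design
  th <- fx$theta
  sm <- mc_sample(design, th, fx$hop, l = 1, base_seed = 77)
  expect_equal(dim(sm$y), c(design$n_obs, 1))
  # same missing pattern as the data by construction (observation layout)
  expect_equal(length(sm$e), design$n_obs)
  # empirical residual covariance on complete records
  R0 <- matrix(c(1, 0.5, 0.5, 2), 2)
  ped <- renumber_pedigree(tibble::tibble(animal = as.character(1:2),
                                          sire = "0", dam = "0"))
  nrec <- 40000
  pheno <- tibble::tibble(animal = rep(1:2, nrec / 2), cg = "1",
                          t1 = rnorm(nrec), t2 = rnorm(nrec))
  spec2 <- model_spec(traits = c("t1", "t2"), fixed = "cg")
  d2 <- build_design(ped, pheno, spec2)
  th2 <- variance_state(spec2); th2$R0 <- R0
  e <- simulate_phenotypes(d2, list(), R0, 13, ndraw = 1)$e
  Em <- mcgreml:::obs_to_matrix(d2, e[, 1])
  expect_cov_match(crossprod(Em) / nrec, R0, nrec, label = "residual cov")
})

test_that("streams replay bit for bit and differ across samples", {
  fx <- small_ss_fixture()
  s1 <- mc_sample(fx$design, fx$theta, fx$hop, l = 2, base_seed = 5)
  s2 <- mc_sample(fx$design, fx$theta, fx$hop, l = 2, base_seed = 5)
  expect_identical(s1, s2)
  s3 <- mc_sample(fx$design, fx$theta, fx$hop, l = 3, base_seed = 5)
  expect_false(isTRUE(all.equal(s1$y, s3$y)))
  # blocked draws equal the per-sample draws
  dd <- mc_draws(fx$design, fx$theta, fx$hop, samples = 1:4, base_seed = 5)
  expect_equal(dd$u_list$genetic[, 2], s1$u_list$genetic[, 1], tolerance = 1e-14)
  expect_equal(dd$y[, 3], s3$y[, 1], tolerance = 1e-14)
})
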