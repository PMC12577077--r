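# Shared fixtures, built in code and cached per test run.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# hand-built pedigrees -------------------------------------------------------

trio_ped <- function() {
  renumber_pedigree(tibble::tibble(animal = c("1", "2", "3"),
                                   sire = c("0", "0", "1"),
                                   dam = c("0", "0", "2")))
}

fullsib_ped <- function() {
  # 1 x 2 -> 3, 4 (full sibs); 3 x 4 -> 5
  renumber_pedigree(tibble::tibble(animal = as.character(1:5),
                                   sire = c("0", "0", "1", "1", "3"),
                                   dam = c("0", "0", "2", "2", "4")))
}

random_ped <- function(n, seed, founder = max(4L, n %/% 6L)) {
  set.seed(seed)
  s <- d <- integer(n)
  for (i in (founder + 1L):n) {
    s[i] <- sample.int(i - 1L, 1L)
    d[i] <- sample.int(i - 1L, 1L)
    if (d[i] == s[i]) d[i] <- 0L
  }
  renumber_pedigree(tibble::tibble(animal = as.character(1:n),
                                   sire = as.character(s),
                                   dam = as.character(d)))
}

# standard two-trait single-step spec ----------------------------------------

two_trait_spec <- function(mc_samples = 30L, mc_seed = 5L) {
  model_spec(
    traits = c("t1", "t2"), fixed = "cg",
    random = list(list(name = "genetic", kind = "h",
                       columns = data.frame(trait = c("t1", "t2"),
                                            role = "animal"))),
    alpha = 0.05,
    mc = list(samples = mc_samples, seed = mc_seed, reuse_sequence = TRUE))
}

two_trait_theta <- function(spec) {
  th <- variance_state(spec)
  th$groups$genetic <- matrix(c(1.2, 0.3, 0.3, 0.8), 2)
  th$R0 <- matrix(c(1.5, 0.4, 0.4, 2.0), 2)
  th
}

# small complete single-step study + everything assembled at a given theta
small_ss_fixture <- function() {
  cached("small_ss", {
    spec <- two_trait_spec()
    th <- two_trait_theta(spec)
    cfg <- sim_config(spec, th, n_founders = 14, n_generations = 3,
                      n_matings = 12, n_offspring = 2, m_loci = 60,
                      genotyped_fraction = 0.3, record_prob = c(0.95, 0.7),
                      base_seed = 3)
    st <- simulate_study(cfg)
    gen <- build_genomic(st$geno, pedigree_A22(st$ped, st$geno$ids),
                         alpha = spec$alpha)
    hop <- h_operator(st$ped, genomic = gen)
    design <- build_design(st$ped, st$pheno, spec)
    op <- assemble_operator(design, th, hop)
    list(spec = spec, theta = th, st = st, gen = gen, hop = hop,
         design = design, op = op)
  })
}

# balanced one-way random-effects design ------------------------------------

oneway_fixture <- function(a = 25L, nper = 8L, su2 = 2, se2 = 3, seed = 2) {
  key <- sprintf("oneway_%d_%d_%d", a, nper, seed)
  cached(key, {
    spec <- model_spec(
      traits = "y", fixed = "mu",
      random = list(list(name = "grp", kind = "identity",
                         columns = data.frame(trait = "y", role = "animal"))))
    ped <- renumber_pedigree(tibble::tibble(animal = as.character(seq_len(a)),
                                            sire = "0", dam = "0"))
    set.seed(seed)
    u <- rnorm(a, 0, sqrt(su2))
    pheno <- tibble::tibble(animal = rep(seq_len(a), each = nper), mu = "1")
    pheno$y <- 10 + u[pheno$animal] + rnorm(a * nper, 0, sqrt(se2))
    list(spec = spec, ped = ped, pheno = pheno, a = a, nper = nper)
  })
}

# closed-form balanced one-way ANOVA-REML (independent oracle)
oneway_closed_form <- function(fx) {
  ybar_i <- tapply(fx$pheno$y, fx$pheno$animal, mean)
  ybar <- mean(fx$pheno$y)
  MSB <- fx$nper * sum((ybar_i - ybar)^2) / (fx$a - 1)
  MSW <- sum((fx$pheno$y - ybar_i[fx$pheno$animal])^2) / (fx$a * (fx$nper - 1))
  c(sigma_u = (MSB - MSW) / fx$nper, sigma_e = MSW)
}

# covariance-agreement check: nominal 3-SE coverage over unique elements plus
# an extreme-value bound on the maximum standardized deviation
expect_cov_match <- function(emp, Sig, ndraw, label = "cov") {
  se <- sqrt((outer(diag(Sig), diag(Sig)) + Sig^2) / ndraw)
  ut <- upper.tri(Sig, diag = TRUE)
  z <- abs(emp - Sig)[ut] / se[ut]
  m <- length(z)
  zmax_bound <- qnorm(1 - 0.0005 / m) + 1.0
  # correlated elements (shared draws) inflate the variance of the empirical
  # coverage, so the nominal 99.7% is asserted at 97%
  expect_gt(mean(z <= 3), 0.97, label = paste(label, "3-SE coverage"))
  expect_lt(max(z), zmax_bound, label = paste(label, "max |z|"))
}
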