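test_that("EM update: stationarity, masks, and the ANOVA fixed point", {
  fx <- small_ss_fixture()
  op <- fx$op
  th <- fx$theta
  design <- fx$design
  sol <- solve_mme(op, tol = 1e-12)
  quads <- compute_quadforms(sol, op)
  # stationary point: T_k + S_k = q_k theta_k leaves theta unchanged;
  # residual stationarity constructed on the aggregate form
  Wstat <- design$n_ij * th$R0 - quads$resid_raw
  tr0 <- mcgreml:::new_traceset(
    list(genetic = design$groups$genetic$q * th$groups$genetic - quads$S$genetic),
    list(Wstat), s = Inf, variant = "exact")
  up <- em_update(tr0, quads, th, design)
  expect_equal(up$groups$genetic, th$groups$genetic, tolerance = 1e-12)
  expect_equal(up$R0, th$R0, tolerance = 1e-12)
})

test_that("masked parameters stay exactly zero through EM and AI rounds", {
  spec <- model_spec(
    traits = c("t1", "t2"), fixed = "cg",
    random = list(list(name = "genetic", kind = "h",
                       columns = data.frame(trait = c("t1", "t2"), role = "animal"),
                       mask = matrix(c(TRUE, FALSE, FALSE, TRUE), 2))),
    residual_mask = matrix(c(TRUE, FALSE, FALSE, TRUE), 2))
  th <- variance_state(spec)
  expect_equal(th$groups$genetic[1, 2], 0)
  cfg <- sim_config(spec, th, n_founders = 12, n_generations = 3, n_matings = 10,
                    n_offspring = 2, m_loci = 40, genotyped_fraction = 0.3,
                    base_seed = 8)
  st <- simulate_study(cfg)
  for (method in c("em", "ai")) {
    fit <- run_reml(st$ped, st$pheno, spec, geno = st$geno, method = method,
                    traces = "exact")
    expect_identical(fit$theta$groups$genetic[1, 2], 0)
    expect_identical(fit$theta$R0[1, 2], 0)
    expect_false(any(fit$index$param == "genetic[1,2]"))
  }
})

test_that("analytic gradient matches finite differences of the exact -2 logL", {
  fx <- small_ss_fixture()
  th <- fx$theta
  sol <- solve_mme(fx$op, tol = 1e-12)
  quads <- compute_quadforms(sol, fx$op)
  tr <- exact_traces(fx$op)
  idx <- theta_index(th)
  g <- reml_gradient(tr, quads, th, fx$design, idx)
  fd <- finite_difference_gradient(fx$design, th, fx$hop, idx, step = 1e-5)
  expect_lt(max(abs(g - fd) / (abs(fd) + 1e-6)), 1e-4)
  # far-from-optimum residual variance flips the gradient sign
  th_hi <- th; th_hi$R0 <- th$R0 * 50
  op_hi <- assemble_operator(fx$design, th_hi, fx$hop)
  sol_hi <- solve_mme(op_hi, tol = 1e-12)
  g_hi <- reml_gradient(exact_traces(op_hi), compute_quadforms(sol_hi, op_hi),
                        th_hi, fx$design, idx)
  r_ix <- which(idx$block == "residual" & idx$i == 1 & idx$j == 1)
  th_lo <- th; th_lo$R0 <- th$R0 / 50
  op_lo <- assemble_operator(fx$design, th_lo, fx$hop)
  sol_lo <- solve_mme(op_lo, tol = 1e-12)
  g_lo <- reml_gradient(exact_traces(op_lo), compute_quadforms(sol_lo, op_lo),
                        th_lo, fx$design, idx)
  expect_true(g_hi[r_ix] > 0 && g_lo[r_ix] < 0)
})

test_that("AI matrix matches the dense-P oracle and uses symmetric conventions", {
  fx <- oneway_fixture()
  design <- build_design(fx$ped, fx$pheno, fx$spec)
  th <- variance_state(fx$spec)
  th$groups$grp <- matrix(2.5); th$R0 <- matrix(3.5)
  op <- assemble_operator(design, th, h_operator(fx$ped))
  sol <- solve_mme(op, tol = 1e-12)
  idx <- theta_index(th)
  AI <- ai_matrix(sol, op, idx, Cinv = solve(as.matrix(op$C)))
  # dense V / P oracle
  Z <- as.matrix(design$Z$grp)
  X <- as.matrix(design$X)
  V <- th$groups$grp[1, 1] * tcrossprod(Z) + th$R0[1, 1] * diag(design$n_obs)
  Vinv <- solve(V)
  P <- Vinv - Vinv %*% X %*% solve(crossprod(X, Vinv %*% X), crossprod(X, Vinv))
  Py <- P %*% design$y
  dV <- list(tcrossprod(Z), diag(design$n_obs))
  AI_dense <- matrix(0, 2, 2)
  for (p in 1:2) for (q in 1:2) {
    AI_dense[p, q] <- drop(t(Py) %*% dV[[p]] %*% P %*% dV[[q]] %*% Py)
  }
  expect_equal(AI, AI_dense, tolerance = 1e-6)
  expect_equal(AI, t(AI), tolerance = 1e-8)
})

test_that("AI step blends towards EM when the raw step leaves the parameter space", {
  # engineered: near-zero group variance, gradient pushing the variance negative
  fx <- oneway_fixture()
  th <- variance_state(fx$spec)
  th$groups$grp <- matrix(0.01); th$R0 <- matrix(5)
  grad <- c(10, 0.1)        # strong push on the tiny variance
  AI <- diag(c(1e-4, 1))    # raw Newton step: 0.01 - 10/1e-4 << 0
  design <- build_design(fx$ped, fx$pheno, fx$spec)
  op <- assemble_operator(design, th, h_operator(fx$ped))
  sol <- solve_mme(op, tol = 1e-10)
  quads <- compute_quadforms(sol, op)
  tr <- exact_traces(op)
  stp <- ai_step(th, grad, AI, tr, quads, design)
  expect_true(mcgreml:::theta_in_space(stp$theta, design))
  expect_gt(stp$weight, 0)
  # gradient = 0 leaves theta unchanged
  stp0 <- ai_step(th, c(0, 0), diag(2), tr, quads, design)
  expect_equal(theta_to_vech(stp0$theta), theta_to_vech(th), tolerance = 1e-14)
  # exact quadratic surrogate: one Newton step hits the optimum
  target <- c(2, 3)
  cur <- c(1, 1)
  H <- matrix(c(2, 0.5, 0.5, 1), 2)
  g_quad <- H %*% (cur - target)
  th2 <- th; th2$groups$grp <- matrix(cur[1]); th2$R0 <- matrix(cur[2])
  stp2 <- ai_step(th2, drop(g_quad), H, tr, quads, design)
  expect_equal(theta_to_vech(stp2$theta), target, tolerance = 1e-10)
})

test_that("exact logL matches the dense-V oracle and is invariant to reordering", {
  fx <- small_ss_fixture()
  m2a <- restricted_loglik(fx$design, fx$theta, fx$hop)
  m2b <- loglik_dense_V(fx$design, fx$theta, fx$hop)
  expect_equal(m2a, m2b, tolerance = 1e-6)
  # reordering the records leaves the likelihood unchanged
  set.seed(33)
  perm <- sample(nrow(fx$st$pheno))
  design_p <- build_design(fx$st$ped, fx$st$pheno[perm, ], fx$spec)
  expect_equal(restricted_loglik(design_p, fx$theta, fx$hop), m2a,
               tolerance = 1e-8)
  # no random effects, R = I: -2logL = log|X'X| + RSS
  ped <- renumber_pedigree(tibble::tibble(animal = as.character(1:6),
                                          sire = "0", dam = "0"))
  set.seed(2)
  pheno <- tibble::tibble(animal = 1:6, cg = rep(c("a", "b"), 3), y = rnorm(6))
  spec0 <- model_spec(traits = "y", fixed = "cg")
  d0 <- build_design(ped, pheno, spec0)
  th0 <- variance_state(spec0)  # R0 = 1
  X <- as.matrix(d0$X)
  rss <- sum(residuals(lm(d0$y ~ X - 1))^2)
  expect_equal(restricted_loglik(d0, th0, NULL),
               as.numeric(determinant(crossprod(X), TRUE)$modulus) + rss,
               tolerance = 1e-8)
})

test_that("convergence criterion implements the dual thresholds", {
  v <- c(1, 2, 3)
  expect_true(check_convergence(v, v, numeric(0))$converged)
  expect_equal(check_convergence(v, v, numeric(0))$reason, "delta_theta")
  # flat logL over five rounds converges on CV even when theta still moves
  cc <- check_convergence(v, v * 1.5, rep(-123.4, 5))
  expect_true(cc$converged)
  expect_equal(cc$reason, "cv_logl")
  # fewer than five values: no CV decision
  cc2 <- check_convergence(v, v * 1.5, rep(-123.4, 4))
  expect_false(cc2$converged)
  expect_true(is.na(cc2$cv_logl))
  # spec defaults
  spec <- model_spec(traits = "y")
  expect_equal(spec$convergence$t1, 1e-12)
  expect_equal(spec$convergence$t2, 1e-4)
  expect_equal(spec$start$variance, 1.0)
  expect_equal(spec$start$covariance, 0.1)
  expect_equal(spec$mc$samples, 30L)
})

test_that("standard errors: positive at an SPD optimum, closed form on one-way design", {
  fx <- oneway_fixture(a = 40, nper = 10, seed = 5)
  fit <- run_reml(fx$ped, fx$pheno, fx$spec, method = "ai", traces = "exact")
  est <- tidy(fit)
  expect_true(all(est$se > 0))
  # asymptotic covariance of balanced one-way REML estimates:
  # var(sigma_e) = 2 se^4 / (N - a); group-mean variance lambda = se2 + n su2,
  # var(lambda-hat) = 2 lambda^2 / (a - 1); su2 = (lambda - se2)/n
  se2 <- est$estimate[est$block == "residual"]
  su2 <- est$estimate[est$block == "grp"]
  a <- fx$a; nper <- fx$nper; N <- a * nper
  lam <- se2 + nper * su2
  var_se2 <- 2 * se2^2 / (N - a)
  var_su2 <- (2 * lam^2 / (a - 1) + var_se2) / nper^2
  expect_equal(est$se[est$block == "grp"], sqrt(var_su2), tolerance = 0.1)
  expect_equal(est$se[est$block == "residual"], sqrt(var_se2), tolerance = 0.1)
})

test_that("tidy/glance/autoplot provide the fit surface", {
  fx <- oneway_fixture()
  fit <- run_reml(fx$ped, fx$pheno, fx$spec, method = "ai", traces = "exact")
  td <- tidy(fit)
  expect_true(all(c("param", "estimate", "se") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$rounds, fit$rounds)
  expect_true(gl$converged)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  p2 <- plot_estimates(fit, truth = c("grp[1,1]" = 2, "residual[1,1]" = 3))
  expect_s3_class(p2, "ggplot")
})
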