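test_that("assembled operator reproduces the dense coefficient matrix column by column", {
  fx <- small_ss_fixture()
  op <- fx$op
  design <- fx$design
  # dense assembly oracle: Q'R^{-1}Q + prior blocks built independently
  Rinv <- as.matrix(mcgreml:::rinv_matrix(design, fx$theta$R0))
  Qd <- as.matrix(design$Q)
  Cd <- t(Qd) %*% Rinv %*% Qd
  Hinv <- solve(mcgreml:::h_dense(fx$st$ped, fx$gen$g_blend, fx$gen$ids))
  g <- design$groups$genetic
  idx <- g$eq_offset + seq_len(g$t * g$q)
  Cd[idx, idx] <- Cd[idx, idx] + kronecker(solve(fx$theta$groups$genetic), Hinv)
  Cop <- as.matrix(op$C)
  expect_lt(max(abs(Cop - Cd)), 1e-8)
  # operator applied to unit vectors gives the dense columns
  for (j in sample(design$n_eq, 5)) {
    ej <- numeric(design$n_eq); ej[j] <- 1
    expect_lt(max(abs(as.numeric(op$C %*% ej) - Cd[, j])), 1e-10)
  }
})

test_that("no random effects gives C = X'R^{-1}X on a toy", {
  ped <- renumber_pedigree(tibble::tibble(animal = as.character(1:5),
                                          sire = "0", dam = "0"))
  pheno <- tibble::tibble(animal = 1:5, cg = c("a", "a", "b", "b", "b"),
                          y = rnorm(5))
  spec <- model_spec(traits = "y", fixed = "cg")
  design <- build_design(ped, pheno, spec)
  theta <- variance_state(spec)
  op <- assemble_operator(design, theta)
  X <- as.matrix(design$X)
  expect_equal(as.matrix(op$C), crossprod(X) / theta$R0[1, 1], tolerance = 1e-12)
})

test_that("single-trait animal model with unit variances gives Z'Z + A^{-1}", {
  ped <- trio_ped()
  pheno <- tibble::tibble(animal = 1:3, mu = "1", y = c(1.0, 2.0, 1.5))
  spec <- model_spec(traits = "y", fixed = "mu",
                     random = list(list(name = "u", kind = "h",
                                        columns = data.frame(trait = "y",
                                                             role = "animal"))))
  design <- build_design(ped, pheno, spec)
  theta <- variance_state(spec)  # variances 1
  op <- assemble_operator(design, theta, h_operator(ped))
  Cd <- as.matrix(op$C)
  Z <- as.matrix(design$Z$u)
  expect_equal(Cd[2:4, 2:4], crossprod(Z) + as.matrix(build_a_inverse(ped)),
               tolerance = 1e-10)
})

test_that("PCG matches a dense solve, handles zero rhs, and is deterministic", {
  fx <- small_ss_fixture()
  op <- fx$op
  xd <- solve(as.matrix(op$C), op$rhs)
  p1 <- pcg_solve(op, tol = 1e-12)
  expect_lt(max(abs(p1$sol - xd)), 1e-8)
  expect_true(p1$converged)
  p2 <- pcg_solve(op, tol = 1e-12)
  expect_identical(p1$sol, p2$sol)
  expect_equal(pcg_solve(op, rhs = numeric(op$n_eq))$sol, numeric(op$n_eq))
  # warm start from the solution converges immediately
  p3 <- pcg_solve(op, tol = 1e-10, warm_start = p1$sol)
  expect_lte(p3$iterations, 1L)
})

test_that("rank-deficient fixed effects are solved in a least-squares sense", {
  ped <- renumber_pedigree(tibble::tibble(animal = as.character(1:6),
                                          sire = "0", dam = "0"))
  set.seed(3)
  # two confounded class effects (mu and cg): C is singular
  pheno <- tibble::tibble(animal = 1:6, mu = "1",
                          cg = rep(c("a", "b"), each = 3), y = rnorm(6))
  spec <- model_spec(traits = "y", fixed = c("mu", "cg"),
                     random = list(list(name = "u", kind = "h",
                                        columns = data.frame(trait = "y",
                                                             role = "animal"))))
  design <- build_design(ped, pheno, spec)
  theta <- variance_state(spec)
  op <- assemble_operator(design, theta, h_operator(ped))
  sol <- solve_mme(op, tol = 1e-10)
  # normal equations are satisfied even though the solution is not unique
  expect_lt(max(abs(as.numeric(op$C %*% sol$sol) - op$rhs)),
            1e-8 * max(abs(op$rhs)))
  # fitted values match the full-rank parameterization (drop mu)
  spec2 <- model_spec(traits = "y", fixed = "cg",
                      random = list(list(name = "u", kind = "h",
                                         columns = data.frame(trait = "y",
                                                              role = "animal"))))
  design2 <- build_design(ped, pheno, spec2)
  sol2 <- solve_mme(assemble_operator(design2, theta, h_operator(ped)),
                    tol = 1e-10)
  expect_equal(sol$yhat, sol2$yhat, tolerance = 1e-6)
})

test_that("quadratic forms match the dense oracle", {
  fx <- small_ss_fixture()
  sol <- solve_mme(fx$op, tol = 1e-12)
  quads <- compute_quadforms(sol, fx$op)
  g <- fx$design$groups$genetic
  U <- sapply(1:2, function(c) sol$sol[mcgreml:::group_col_idx(fx$design, "genetic", c)])
  Hinv <- solve(mcgreml:::h_dense(fx$st$ped, fx$gen$g_blend, fx$gen$ids))
  expect_equal(quads$S$genetic, t(U) %*% Hinv %*% U, tolerance = 1e-8)
  # residual products restricted to jointly observed records
  Em <- mcgreml:::obs_to_matrix(fx$design, sol$e_hat)
  expect_equal(quads$resid_raw, crossprod(Em), tolerance = 1e-12)
  # u = 0 gives S = 0
  zero_sol <- sol; zero_sol$sol <- numeric(fx$design$n_eq)
  zero_sol$e_hat <- fx$design$y
  expect_equal(compute_quadforms(zero_sol, fx$op)$S$genetic, matrix(0, 2, 2))
})
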