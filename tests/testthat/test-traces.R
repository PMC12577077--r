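test_that("trace estimators recover their analytic limits", {
  fx <- small_ss_fixture()
  op <- fx$op
  design <- fx$design
  th <- fx$theta
  # build two solved samples, then force degenerate limits
  draws <- mc_draws(design, th, fx$hop, samples = 1:2, base_seed = 3)
  rhs <- as.matrix(Matrix::t(design$Q) %*% (op$Rinv %*% draws$y))
  sol <- pcg_solve(op, rhs, tol = 1e-8)$sol
  samples <- lapply(1:2, function(l) {
    list(sol = sol[, l], y = draws$y[, l], e = draws$e[, l],
         u_list = list(genetic = draws$u_list$genetic[, l, drop = FALSE]))
  })
  # zero solutions: primary estimator returns q_k theta_k
  zero_samples <- lapply(samples, function(s) { s$sol <- 0 * s$sol; s })
  Tz <- estimate_trace_Tk(zero_samples, op, "genetic")
  expect_equal(Tz, design$groups$genetic$q * th$groups$genetic, tolerance = 1e-12)
  # perfect-information limit: centered estimator returns 0
  perfect <- lapply(samples, function(s) {
    s$sol[mcgreml:::group_col_idx(design, "genetic", 1)] <-
      s$u_list$genetic[seq_len(design$groups$genetic$q), 1]
    s$sol[mcgreml:::group_col_idx(design, "genetic", 2)] <-
      s$u_list$genetic[design$groups$genetic$q + seq_len(design$groups$genetic$q), 1]
    s
  })
  Tc <- estimate_trace_Tk(perfect, op, "genetic", variant = "centered")
  expect_equal(Tc, matrix(0, 2, 2), tolerance = 1e-20)
  # residual: zero simulated estimates -> primary returns the n_ij R term
  zs <- lapply(samples, function(s) { s$sol <- 0 * s$sol; s$y <- 0 * s$y; s })
  Wz <- Reduce(`+`, estimate_trace_residual(zs, op))
  Rexp <- matrix(0, 2, 2)
  for (p in seq_along(design$patterns)) {
    msk <- design$patterns[[p]]
    Rp <- th$R0; Rp[!msk, ] <- 0; Rp[, !msk] <- 0
    Rexp <- Rexp + sum(design$pattern_of == p) * Rp
  }
  expect_equal(Wz, Rexp, tolerance = 1e-12)
  # e~ = e-hat~: centered residual variant returns 0
  ec <- lapply(samples, function(s) { s$e <- s$y - as.numeric(design$Q %*% s$sol); s })
  expect_equal(Reduce(`+`, estimate_trace_residual(ec, op, variant = "centered")),
               matrix(0, 2, 2), tolerance = 1e-20)
})

test_that("Monte Carlo traces are unbiased for the exact traces (both variants)", {
  fx <- small_ss_fixture()
  op <- fx$op
  ex <- exact_traces(op)
  reps <- lapply(1:6, function(k) run_mc_round(op, s = 150, base_seed = 100 + k))
  for (variant in c("primary", "centered")) {
    if (variant == "centered") {
      reps <- lapply(1:6, function(k)
        run_mc_round(op, s = 150, base_seed = 100 + k, variant = "centered"))
    }
    Ts <- sapply(reps, function(r) r$T$genetic[cbind(c(1, 1, 2), c(1, 2, 2))])
    mu <- rowMeans(Ts)
    se <- apply(Ts, 1, sd) / sqrt(ncol(Ts))
    ref <- ex$T$genetic[cbind(c(1, 1, 2), c(1, 2, 2))]
    expect_true(all(abs(mu - ref) <= 3.5 * se),
                label = sprintf("%s trace unbiasedness", variant))
  }
})

test_that("relaxing the sample-solve tolerance changes traces by less than the MC noise", {
  fx <- small_ss_fixture()
  op <- fx$op
  ex <- exact_traces(op)
  tight <- run_mc_round(op, s = 120, base_seed = 8, tol = 1e-10)
  loose <- run_mc_round(op, s = 120, base_seed = 8, tol = 1e-6)
  mc_noise <- max(abs(tight$T$genetic - ex$T$genetic))
  expect_lt(max(abs(tight$T$genetic - loose$T$genetic)), mc_noise)
})

test_that("rounds at identical theta reuse the sequence and reproduce the trace set", {
  fx <- small_ss_fixture()
  op <- fx$op
  a <- run_mc_round(op, s = 40, base_seed = 5, round = 1)
  b <- run_mc_round(op, s = 40, base_seed = 5, round = 9)
  expect_identical(a$T, b$T)
  expect_identical(a$resid_wsum, b$resid_wsum)
  # without reuse the rounds differ
  c <- run_mc_round(op, s = 40, base_seed = 5, round = 9, reuse_sequence = FALSE)
  expect_false(isTRUE(all.equal(a$T, c$T)))
})

test_that("blocked round equals the per-sample estimator path", {
  fx <- small_ss_fixture()
  op <- fx$op
  s <- 8
  mc <- run_mc_round(op, s = s, base_seed = 21, tol = 1e-10)
  draws <- mc_draws(fx$design, fx$theta, fx$hop, samples = 1:s, base_seed = 21)
  rhs <- as.matrix(Matrix::t(fx$design$Q) %*% (op$Rinv %*% draws$y))
  sol <- pcg_solve(op, rhs, tol = 1e-10)$sol
  samples <- lapply(seq_len(s), function(l)
    list(sol = sol[, l], y = draws$y[, l], e = draws$e[, l],
         u_list = lapply(draws$u_list, function(u) u[, l, drop = FALSE])))
  expect_equal(estimate_trace_Tk(samples, op, "genetic"), mc$T$genetic,
               tolerance = 1e-9)
  W1 <- estimate_trace_residual(samples, op)
  expect_equal(W1, mc$resid_wsum, tolerance = 1e-9)
})
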