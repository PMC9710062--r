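p_def <- hgt_params()

test_that("a fixed seed reproduces the trajectory exactly", {
  st <- metapop(10, 10, 500)
  prm <- hgt_params(beta = 0.08)
  tr1 <- run_stochastic(st, prm, mappings = 100, seed = 11)
  tr2 <- run_stochastic(st, prm, mappings = 100, seed = 11)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_identical(final_state(tr1), final_state(tr2))
})

test_that("no death, no birth, no mutation leaves integer counts unchanged", {
  frozen <- hgt_params(delta = 0, beta = 0, p_plus = 0, p_minus = 0)
  st <- metapop(c(2, 7), c(1, 9), c(40, 60))
  set.seed(1)
  expect_equal(step_stochastic(st, frozen), st)
})

test_that("single-class step moments match the Binomial/Poisson closed forms", {
  prm <- hgt_params(beta = 0.08)
  n <- 1000
  reps <- 2000
  # survivors stay at (5, 10), newborns land at (0, 10), so the two counts
  # are identifiable and should be Binomial and Poisson respectively
  set.seed(4)
  sv <- numeric(reps); bn_ <- numeric(reps)
  p_surv5 <- 1 - 0.01 * exp(-1)
  lam5 <- n * 0.08 * (1 - n / 1e4) * exp(-2)
  for (r in seq_len(reps)) {
    out <- step_stochastic(metapop(5, 10, n), prm, mutation = FALSE)
    sv[r] <- sum(out$count[out$y == 5])
    bn_[r] <- sum(out$count[out$y == 0])
  }
  expect_lt(abs(mean(sv) - n * p_surv5),
            4 * sqrt(n * p_surv5 * (1 - p_surv5) / reps))
  expect_lt(abs(var(sv) - n * p_surv5 * (1 - p_surv5)),
            4 * n * p_surv5 * (1 - p_surv5) * sqrt(2 / (reps - 1)))
  expect_lt(abs(mean(bn_) - lam5), 4 * sqrt(lam5 / reps))
  expect_lt(abs(var(bn_) - lam5), 4 * lam5 * sqrt(2 / (reps - 1)))
})

test_that("replicate-mean one-step outcome converges to the expected step", {
  prm <- hgt_params(beta = 0.08)
  st <- metapop(c(2, 6), c(3, 8), c(300, 200))
  exp_out <- step_expected(st, prm)
  reps <- 2000
  set.seed(5)
  totals <- replicate(reps, metapop_n(step_stochastic(st, prm)))
  se <- sd(totals) / sqrt(reps)
  expect_lt(abs(mean(totals) - metapop_n(exp_out)), 4 * se)
})

test_that("extinction is absorbing and ends the run", {
  doomed <- hgt_params(delta = 1, beta = 0, p_plus = 0, p_minus = 0)
  tr <- run_stochastic(metapop(0, 0, 50), doomed, mappings = 100, seed = 9)
  s <- run_summary(tr)
  expect_true(s$extinct)
  expect_equal(s$extinction_mapping, 1L)
  expect_equal(s$final_n, 0)
  expect_equal(nrow(tr), 2L)  # initial state + the extinction mapping
  expect_true(all(tr$n_total >= 0))
})

test_that("mutation moves survivors by at most one lattice step per mapping", {
  hot <- hgt_params(p_plus = 0.3, p_minus = 0.2, delta = 0, beta = 0)
  st <- metapop(4, 4, 1000)
  set.seed(6)
  out <- step_stochastic(st, hot)
  expect_true(all(abs(out$y - 4) <= 1))
  expect_true(all(abs(out$z - 4) <= 1))
  expect_equal(metapop_n(out), 1000)  # no death, no birth: count conserved
  # boundary: populations at 0 never go negative
  st0 <- metapop(0, 0, 1000)
  out0 <- step_stochastic(st0, hot)
  expect_true(all(out0$y >= 0) && all(out0$z >= 0))
})

test_that("beta sweeps are reproducible and shaped as expected", {
  st <- metapop(10, 10, 100)
  sw1 <- sweep_beta(c(0.06, 0.08), 1, st, p_def, mappings = 20, base_seed = 2)
  expect_equal(nrow(sw1), 2L)  # one row per beta at one replicate
  sw2 <- sweep_beta(c(0.06, 0.08), 3, st, p_def, mappings = 20, base_seed = 2)
  expect_identical(as.data.frame(sw2),
                   as.data.frame(sweep_beta(c(0.06, 0.08), 3, st, p_def,
                                            mappings = 20, base_seed = 2)))
  expect_equal(nrow(sw2), 6L)
  expect_false(any(duplicated(sw2$seed)))
  sm <- sweep_means(sw2)
  expect_equal(sm$beta, c(0.06, 0.08))
  expect_equal(sm$n_replicates, c(3L, 3L))
})
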