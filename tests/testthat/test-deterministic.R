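p06 <- hgt_params(beta = 0.06)
p08 <- hgt_params(beta = 0.08)

test_that("expected lifetime is the geometric mean count of persistences", {
  expect_equal(expected_lifetime(0, p06), 99)
  p <- 0.01 * exp(-2)
  expect_equal(expected_lifetime(10, p06), (1 - p) / p)
  expect_equal(expected_lifetime(10, p06), 737.9, tolerance = 1e-4)
  expect_equal(expected_lifetime(0, hgt_params(delta = 1)), 0)
  expect_identical(expected_lifetime(3, hgt_params(delta = 0)), Inf)
})

test_that("elimination time matches the closed-form geometric decay", {
  expect_equal(expected_elimination_time(1000, 10, p06), 5101L)
  expect_equal(expected_elimination_time(1000, 0, p06),
               as.integer(ceiling(log(1000) / -log(0.99))))  # 688
  expect_equal(expected_elimination_time(1, 5, p06), 1L)
  expect_identical(expected_elimination_time(1000, 3, hgt_params(delta = 0)),
                   Inf)
})

test_that("elimination time agrees with direct iteration of the recursion", {
  set.seed(42)
  for (i in 1:100) {
    n0 <- runif(1, 2, 5000)
    y <- sample(0:15, 1)
    prm <- hgt_params(delta = runif(1, 0.005, 0.2), beta = 0)
    t_closed <- expected_elimination_time(n0, y, prm)
    n <- n0
    t_iter <- 0L
    rate <- 1 - prm$delta * p_death(y, prm)
    while (n >= 1) {
      n <- n * rate
      t_iter <- t_iter + 1L
    }
    expect_lte(abs(t_closed - t_iter), 1L)
  }
})

test_that("one expected mapping splits mass into survivors and newborns", {
  out <- step_expected(metapop(10, 10, 1000), p06, mutation = FALSE)
  surv <- 1000 * (1 - 0.01 * exp(-2))
  births <- 1000 * 0.06 * (1 - 1000 / 1e4) * exp(-2)
  expect_equal(out$count[out$y == 10 & out$z == 10], surv)
  expect_equal(out$count[out$y == 0 & out$z == 10], births)
  expect_equal(metapop_n(out), surv + births)
})

test_that("no death, no birth, no mutation conserves the state exactly", {
  frozen <- hgt_params(delta = 0, beta = 0)
  st <- metapop(c(3, 8), c(2, 11), c(120, 7))
  expect_equal(step_expected(st, frozen, mutation = FALSE), st)
  # mutation flag with zero rates is also the identity
  null_mut <- hgt_params(delta = 0, beta = 0, p_plus = 0, p_minus = 0)
  expect_equal(step_expected(st, null_mut, mutation = TRUE), st)
})

test_that("total descendant mass satisfies the class-mean linearity identity", {
  set.seed(7)
  for (i in 1:20) {
    st <- random_state()
    prm <- random_params()
    out <- step_expected(st, prm)
    n <- metapop_n(st)
    q <- st$count / n
    pd_bar <- sum(q * p_death(st$y, prm))
    pb_bar <- sum(q * p_birth(st$z, prm))
    expect_equal(metapop_n(out),
                 n * (1 - prm$delta * pd_bar) + n * beta_n(n, prm) * pb_bar,
                 tolerance = 1e-10)
  }
})

test_that("without births each class decays at its own geometric rate", {
  prm <- hgt_params(beta = 0)
  st <- metapop(c(0, 10), c(5, 5), c(500, 500))
  tr <- run_expected(st, prm, mappings = 200, mutation = FALSE,
                     stop_at_extinction = FALSE)
  fin <- final_state(tr)
  expect_equal(fin$count[fin$y == 0], 500 * (1 - 0.01)^200, tolerance = 1e-9)
  expect_equal(fin$count[fin$y == 10],
               500 * (1 - 0.01 * exp(-2))^200, tolerance = 1e-9)
  # selection by survival: the longer-lived high-y class gains in proportion,
  # so mean y rises monotonically even though both classes dwindle
  expect_true(all(diff(tr$mean_y) > 0))
  expect_true(all(diff(tr$n_total) < 0))
})

test_that("full deterministic run reproduces extinction and persistence fates", {
  tr06 <- run_expected(metapop(10, 10, 1000), p06, mappings = 1e4,
                       mutation = FALSE)
  s06 <- run_summary(tr06)
  expect_true(s06$extinct)
  expect_equal(s06$extinction_mapping, 7120, tolerance = 0.01)
  expect_equal(nrow(tr06), s06$extinction_mapping + 1L)  # truncated there

  tr08 <- run_expected(metapop(10, 10, 1000), p08, mappings = 2000,
                       mutation = FALSE)
  expect_false(run_summary(tr08)$extinct)

  empty <- run_expected(metapop(), p06, mappings = 10)
  expect_true(all(empty$n_total == 0))
})

test_that("analytic equilibrium matches its defining balance equation", {
  ne <- equilibrium_size(0, 10, p08)
  expect_equal(ne, 1e4 * (1 - 0.01 / (0.08 * exp(-2))))
  # balance: death rate equals birth rate at N*
  expect_equal(0.01 * p_death(0, p08),
               0.08 * (1 - ne / 1e4) * p_birth(10, p08), tolerance = 1e-12)
  expect_true(is.na(equilibrium_size(0, 10, p06)))  # decay regime: no fixed point
  expect_equal(equilibrium_size(5, 5, hgt_params(delta = 0)), 1e4)
})
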