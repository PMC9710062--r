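p08 <- hgt_params(beta = 0.08)

test_that("homogeneous state without transmission bias has zero total change", {
  st <- metapop(4, 7, 100)
  pd <- price_delta_z(st, p08, mutation = FALSE)
  # selection -(w_bar - w_m) z / w_bar cancels transmission w_p z / w_bar
  # exactly, since w_bar = w_p + w_m for a single class
  expect_equal(pd$total, 0, tolerance = 1e-14)
  expect_equal(pd$selection_term + pd$transmission_term, pd$total)
  expect_lt(pd$selection_term, 0)
})

test_that("connectivity selection favors the lower-z class", {
  st <- metapop(c(10, 10), c(10, 9), c(500, 500))
  pd <- price_delta_z(st, p08, mutation = FALSE)
  expect_lt(pd$selection_term, 0)
  oracle <- one_step_mean_change_oracle(st, p08, "z", mutation = FALSE)
  expect_equal(pd$total, oracle, tolerance = 1e-10)
  # and against the lattice engine directly
  out <- step_expected(st, p08, mutation = FALSE)
  expect_equal(pd$total,
               unname(metapop_means(out)["mean_z"] -
                        metapop_means(st)["mean_z"]),
               tolerance = 1e-10)
})

test_that("decomposition remains exact without colonization", {
  st <- metapop(c(2, 5), c(1, 8), c(50, 150))
  prm <- hgt_params(beta = 0)
  pd <- price_delta_z(st, prm)
  expect_equal(pd$total, one_step_mean_change_oracle(st, prm, "z"),
               tolerance = 1e-10)
})

test_that("indispensability analog: HGT offspring dilute y", {
  # homogeneous, no mutation, no death: only births at y = 0 change the mean
  prm <- hgt_params(beta = 0.08, delta = 0)
  st <- metapop(6, 3, 400)
  pd <- price_delta_y(st, prm, mutation = FALSE)
  fc <- fitness_components(6, 3, 400, prm)
  expect_equal(pd$total, 6 * fc$w_p / fc$w - 6, tolerance = 1e-12)
  expect_lt(pd$total, 0)

  # no colonization, no mutation: a homogeneous mean cannot move
  still <- price_delta_y(metapop(6, 3, 400), hgt_params(beta = 0),
                         mutation = FALSE)
  expect_equal(still$total, 0, tolerance = 1e-14)

  # selection by survival: with two classes differing only in y and no
  # births, the more indispensable class gains in proportion
  two <- metapop(c(3, 9), c(4, 4), c(200, 200))
  pd2 <- price_delta_y(two, hgt_params(beta = 0), mutation = FALSE)
  expect_gt(pd2$total, 0)
  expect_equal(pd2$total,
               one_step_mean_change_oracle(two, hgt_params(beta = 0), "y",
                                           mutation = FALSE),
               tolerance = 1e-10)
})

test_that("Price identity holds against the brute-force oracle on random states", {
  set.seed(123)
  for (i in 1:200) {
    st <- random_state()
    prm <- random_params()
    for (coord in c("z", "y")) {
      pd <- price_decomposition(st, prm, coordinate = coord)
      expect_equal(pd$selection_term + pd$transmission_term, pd$total)
      expect_equal(pd$total, one_step_mean_change_oracle(st, prm, coord),
                   tolerance = 1e-10)
    }
  }
})

test_that("lattice redistribution and mean-shift bookkeeping agree on means", {
  # step_expected moves survivor mass on the (y, z) lattice; the Price
  # machinery uses per-class mean shifts E(dx). Both must give the same
  # descendant mean.
  set.seed(321)
  for (i in 1:50) {
    st <- random_state()
    prm <- random_params()
    out <- step_expected(st, prm, mutation = TRUE)
    mo <- metapop_means(out)
    ms <- metapop_means(st)
    expect_equal(price_delta_z(st, prm)$total,
                 unname(mo["mean_z"] - ms["mean_z"]), tolerance = 1e-10)
    expect_equal(price_delta_y(st, prm)$total,
                 unname(mo["mean_y"] - ms["mean_y"]), tolerance = 1e-10)
  }
})

test_that("selection on connectivity is never positive without mutation", {
  set.seed(99)
  for (i in 1:50) {
    st <- random_state()
    prm <- random_params()
    pd <- price_delta_z(st, prm, mutation = FALSE)
    expect_lte(pd$selection_term, 1e-12)
  }
})

test_that("empty metapopulations are rejected", {
  expect_error(price_delta_z(metapop(), p08), "empty")
  expect_error(one_step_mean_change_oracle(metapop(), p08), "empty")
})
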