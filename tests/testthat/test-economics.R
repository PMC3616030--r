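test_that("catch is the harvest fraction of post-movement biomass", {
  expect_equal(catch_biomass(rep(0, 4), rep(100, 4)), rep(0, 4))
  expect_equal(catch_biomass(0.2, 100), 20)
  u <- runif(10); B <- runif(10, 0, 1e6)
  expect_lte(sum(catch_biomass(u, B)), sum(B))
  expect_error(catch_biomass(c(0.1, 0.2), 100), "length")
})

test_that("fishery profit is revenue minus effort cost and scales linearly in price", {
  ec <- econ_params(cost = 10)
  expect_equal(fishery_profit(0, 0, price = 1, ec), 0)
  expect_equal(fishery_profit(100, 0.5, price = 1, ec), 95)
  p1 <- fishery_profit(c(100, 50), c(0.5, 0.1), price = 1, ec)
  p2 <- fishery_profit(c(100, 50), c(0.5, 0.1), price = 2, ec)
  expect_equal(p2 - p1, sum(c(100, 50)))  # doubling price adds the revenue
})

test_that("the demand line has the stated intercept, slope and biomass shift", {
  t <- tourism_params(alpha = 10, beta = -0.001, gamma = 2e-6)
  expect_equal(marginal_dive_value(0, 0, t), 10)
  q <- seq(0, 1000, by = 100)
  expect_true(all(diff(marginal_dive_value(q, 0, t)) < 0))
  dB <- 5e5
  expect_equal(marginal_dive_value(q, dB, t) - marginal_dive_value(q, 0, t),
               rep(t$gamma * dB, length(q)))
})

test_that("dives demanded invert the demand line and truncate at the choke price", {
  t <- tourism_params(alpha = 10, beta = -0.001, gamma = 0)
  expect_equal(dives_demanded(5, 0, t), 5000)
  expect_equal(dives_demanded(10, 0, t), 0)
  expect_equal(dives_demanded(25, 0, t), 0)
  tg <- tourism_params(alpha = 10, beta = -0.001, gamma = 1e-6)
  expect_equal(dives_demanded(tg$alpha + tg$gamma * 2e6, 2e6, tg), 0)
})

test_that("optimal dives and fee sit at the revenue vertex", {
  t <- tourism_params(alpha = 10, beta = -0.001, gamma = 0)
  expect_equal(optimal_dives(0, t), 5000)
  expect_equal(optimal_fee(0, t), 5)
  # grid-search oracle over dives
  q_grid <- seq(0, 10000, length.out = 10001)
  tr <- marginal_dive_value(q_grid, 0, t) * q_grid
  expect_equal(optimal_dives(0, t), q_grid[which.max(tr)], tolerance = 1e-3)
  # degenerate: nothing worth paying for
  t0 <- tourism_params(alpha = 0, beta = -0.001, gamma = 0)
  expect_equal(optimal_dives(0, t0), 0)
  # q* increases with biomass when gamma > 0
  tg <- tourism_params(alpha = 10, beta = -0.001, gamma = 1e-6)
  expect_true(optimal_dives(2e6, tg) > optimal_dives(1e6, tg))
})

test_that("the optimal fee is half the choke price and beats a fee grid", {
  set.seed(11)
  for (i in 1:100) {
    t <- random_tourism()
    B <- runif(1, 0, 1e8)
    choke <- t$alpha + t$gamma * B
    P <- optimal_fee(B, t)
    expect_equal(P, choke / 2)
    expect_equal(dives_demanded(P, B, t), optimal_dives(B, t))
    fees <- seq(0, choke, length.out = 10000)
    tr_grid <- tourism_revenue(fees, dives_demanded(fees, B, t))
    expect_gte(tourism_revenue(P, dives_demanded(P, B, t)),
               max(tr_grid) * (1 - 1e-12))
  }
})

test_that("consumer surplus matches the area oracle and the welfare identity", {
  t <- tourism_params(alpha = 10, beta = -0.001, gamma = 0)
  expect_equal(consumer_surplus(5, 5000, 0, t), 12500)  # triangle
  choke <- t$alpha
  expect_equal(consumer_surplus(choke, 0, 0, t), 0)
  set.seed(12)
  for (i in 1:20) {
    tt <- random_tourism()
    B <- runif(1, 0, 1e8)
    fee <- runif(1, 0, tt$alpha + tt$gamma * B)
    q <- dives_demanded(fee, B, tt)
    cs <- consumer_surplus(fee, q, B, tt)
    quad <- stats::integrate(function(x)
      marginal_dive_value(x, B, tt) - fee, 0, q, rel.tol = 1e-10)
    expect_equal(cs, quad$value, tolerance = 1e-8)
    expect_gte(cs, 0)
    # CS + TR = total area under the demand line up to q
    area <- stats::integrate(function(x) marginal_dive_value(x, B, tt),
                             0, q, rel.tol = 1e-10)
    expect_equal(cs + tourism_revenue(fee, q), area$value,
                 tolerance = 1e-9 * max(1, area$value))
  }
  expect_error(consumer_surplus(1, 1e9, 0, t), "exceeds")
})

test_that("tourism value at a fixed fee is non-decreasing in biomass", {
  t <- tourism_params(alpha = 5, beta = -1e-4, gamma = 1e-7, fixed_fee = 3.5)
  B <- seq(0, 1e8, length.out = 50)
  tv <- vapply(B, function(b) {
    q <- dives_demanded(3.5, b, t)
    tourism_revenue(3.5, q) + consumer_surplus(3.5, q, b, t)
  }, 0)
  expect_true(all(diff(tv) >= 0))
})

test_that("demand calibration reproduces its operating point", {
  set.seed(13)
  for (i in 1:25) {
    target <- runif(1, 1e3, 1e5)
    fee <- runif(1, 0.5, 10)
    B_ref <- runif(1, 1e6, 1e9)
    t <- calibrate_demand(target, fee, B_ref,
                          choke_multiple = runif(1, 1.2, 5),
                          biomass_share = runif(1, 0, 0.95))
    expect_equal(dives_demanded(fee, B_ref, t), target, tolerance = 1e-9)
    expect_lt(t$beta, 0)
    expect_gte(t$gamma, 0)
  }
  # degenerate split: all of the choke price in the intercept
  t0 <- calibrate_demand(1000, fee = 2, B_ref = 1, choke_multiple = 2,
                         biomass_share = 0)
  expect_equal(t0$alpha, 4)
  expect_equal(t0$gamma, 0)
  expect_error(calibrate_demand(1000, 2, B_ref = 0, biomass_share = 0.5),
               "B_ref")
  expect_error(calibrate_demand(1000, 2, B_ref = 1, choke_multiple = 1),
               "choke_multiple")
})
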