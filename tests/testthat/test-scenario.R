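test_that("zoning fractions map to centred patch blocks", {
  co <- build_zones(100, c(0.01, 0.12, 0.87))
  expect_equal(sum(co$zone == "no_take"), 1)
  expect_equal(sum(co$zone == "partial"), 12)
  expect_equal(sum(co$zone == "open"), 87)
  expect_equal(which(co$zone == "no_take"), 50)
  expect_equal(which(co$zone == "partial"), c(44:49, 51:56))

  expect_equal(build_zones(100, c(0, 0, 1))$zone, rep("open", 100))
  expect_error(build_zones(100, c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("largest-remainder counts always sum to the patch total", {
  set.seed(3)
  for (i in 1:50) {
    f <- runif(3); f <- f / sum(f)
    n <- sample(5:200, 1)
    co <- build_zones(n, f)
    expect_equal(length(co$zone), n)
    counts <- table(factor(co$zone, c("no_take", "partial", "open")))
    expect_equal(sum(counts), n)
    expect_true(all(abs(counts - n * f) < 1))
  }
})

test_that("reserve implementation rezones the harvest rates", {
  co <- build_zones(10, c(0.1, 0.2, 0.7))
  u <- apply_reserve(0.4, co, partial_reduction = 0.5)
  expect_equal(unique(u[co$zone == "no_take"]), 0)
  expect_equal(unique(u[co$zone == "partial"]), 0.2)
  expect_equal(unique(u[co$zone == "open"]), 0.4)
  expect_equal(apply_reserve(0, co), rep(0, 10))
  u_full <- apply_reserve(0.4, co, partial_reduction = 1)
  expect_equal(unique(u_full[co$zone == "partial"]), 0)
})

test_that("an unfished, unvisited coastline generates no value and stays put", {
  sp <- species_params("calm", s_nat = 0.7, w_k = 100, rho = 0.6,
                       R0 = 1e4, sigma_L = 0.01, sigma_A = 0.01, h = 0.75,
                       price = 0.01, role = "fished")
  tsp <- species_params("seen", s_nat = 0.8, w_k = 200, rho = 0.7,
                        R0 = 1e3, sigma_L = 0.01, sigma_A = 0.01, h = 0.75,
                        role = "tourism")
  cfg <- scenario_config(
    coast = build_zones(20, c(0.1, 0.2, 0.7)),
    species = list(sp, tsp), u_pre = c(0, 0),
    econ = econ_params(0),
    tourism = tourism_params(alpha = 0, beta = -0.001, gamma = 0,
                             fixed_fee = 1),
    burn_in_years = 10, post_years = 10)
  sim <- run_scenario(cfg)
  expect_equal(sim$annual$FV, rep(0, 20))
  expect_equal(sim$annual$TR, rep(0, 20))
  expect_equal(sim$annual$TV, rep(0, 20))
  b <- tidy(sim, "patches")
  first <- b$biomass[b$year == min(b$year) & b$species == "calm"]
  last <- b$biomass[b$year == max(b$year) & b$species == "calm"]
  expect_lt(max(abs(last - first) / first), 1e-6)
})

test_that("protection rebuilds no-take biomass above its fished level within 20 years", {
  sim <- run_scenario(small_medes(post_years = 25))
  b <- tidy(sim, "patches")
  for (sp in c("red_mullet", "european_seabass")) {
    pre <- b$biomass[b$year == -1 & b$zone == "no_take" & b$species == sp]
    post <- b$biomass[b$year == 19 & b$zone == "no_take" & b$species == sp]
    expect_gt(sum(post), sum(pre))
  }
})

test_that("annual records are complete and internally consistent", {
  sim <- run_scenario(small_medes())
  ann <- tidy(sim)
  expect_equal(nrow(ann), 40 + 30)
  expect_equal(ann$year, seq(-40, 29))
  expect_equal(ann$TV, ann$FV + ann$TR + ann$CS)
  expect_true(all(ann$dives >= 0) && all(ann$fee >= 0))
  b <- tidy(sim, "patches")
  expect_true(all(b$biomass >= 0) && all(b$catch >= 0))
  expect_equal(nrow(b), 70 * 2 * 100)
})

test_that("tourism value is non-decreasing after reserve creation at a fixed fee", {
  sim <- run_scenario(small_medes())
  ann <- tidy(sim)
  tourism <- (ann$TR + ann$CS)[ann$year >= 0]
  expect_true(all(diff(tourism) >= -1e-9 * tourism[1]))
})

test_that("the dive-cap event freezes the fee and caps dives at the event-year demand", {
  sim <- run_scenario(small_medes(cap_dives = TRUE, cap_year = 8))
  ann <- tidy(sim)
  ev <- sim$events_log[[1]]
  expect_equal(ev$year, 8)
  post_cap <- ann[ann$year >= 8, ]
  expect_true(all(post_cap$policy == "capped"))
  expect_true(all(post_cap$dives <= ev$cap + 1e-9))
  expect_equal(post_cap$dives[1], ev$cap)
  # demand keeps growing with biomass, so the cap binds and revenue freezes
  expect_equal(post_cap$TR, rep(3.5 * ev$cap, nrow(post_cap)))
  # before the event the two runs are identical
  base <- tidy(run_scenario(small_medes()))
  expect_equal(ann[ann$year < 8, ], base[base$year < 8, ])
})

test_that("a cap above demand never binds", {
  # tourism species unharvested: reserve biomass is already at equilibrium,
  # so demand never grows past its event-year level
  sim <- run_scenario(small_medes(u_bycatch = 0, cap_dives = TRUE,
                                  cap_year = 5))
  base <- run_scenario(small_medes(u_bycatch = 0))
  a <- tidy(sim); b <- tidy(base)
  expect_equal(a$dives, b$dives, tolerance = 1e-6)
  expect_equal(a$TR, b$TR, tolerance = 1e-6)
})

test_that("runs are deterministic and independent of species ordering", {
  cfg <- small_medes()
  s1 <- run_scenario(cfg)
  s2 <- run_scenario(cfg)
  expect_identical(s1$annual, s2$annual)
  expect_identical(s1$patches, s2$patches)

  cfg_rev <- cfg
  cfg_rev$species <- rev(cfg$species)
  cfg_rev$u_pre <- rev(cfg$u_pre)
  s3 <- run_scenario(cfg_rev)
  expect_equal(s3$annual, s1$annual)
})

test_that("spillover raises long-run fishery profit over the no-reserve counterfactual", {
  cfg <- medes_scenario(burn_in_years = 60, post_years = 100,
                        msy_multiple = 2, target_dives = 1)
  cfg$tourism <- tourism_params(alpha = 0, beta = -0.001, gamma = 0)
  sim <- run_scenario(cfg)

  cfg0 <- cfg
  cfg0$coast <- build_zones(100, c(0, 0, 1))  # counterfactual: no reserve
  sim0 <- run_scenario(cfg0)
  fv_reserve <- tidy(sim)$FV[tidy(sim)$year == 99]
  fv_none <- tidy(sim0)$FV[tidy(sim0)$year == 99]
  expect_gt(fv_reserve, fv_none)
})

test_that("the logged update terms reconstruct next year's biomass", {
  sim <- run_scenario(small_medes(cap_dives = TRUE))
  au <- tidy(sim, "audit")
  recon <- au$growth + au$lag + au$recruit_weight + au$recruitment +
    au$clamped
  expect_lt(max(abs(recon - au$biomass_next) /
                  pmax(au$biomass_next, 1)), 1e-6)
  expect_true(all(au$catch >= 0))
})

test_that("payback year is the first post-reserve year at or above the burn-in baseline", {
  fake <- function(tv_pre, tv_post) {
    structure(list(annual = tibble::tibble(
      year = c(seq(-length(tv_pre), -1), seq(0, length(tv_post) - 1)),
      TV = c(tv_pre, tv_post))), class = "reserve_sim")
  }
  # monotone recovery crossing once
  expect_equal(payback_year(fake(rep(100, 12), c(60, 80, 99, 101, 120))), 3)
  # never dropped
  expect_equal(payback_year(fake(rep(100, 12), c(100, 110))), 0)
  # never recovers
  expect_equal(payback_year(fake(rep(100, 12), rep(50, 5))), NA_integer_)
})
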