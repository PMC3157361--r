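test_that("vaccination schedules land on 8-hour step multiples", {
  expect_equal(build_schedule(), c(0, 84, 168, 252, 336, 420))
  expect_equal(build_schedule(n_boosts = 0), 0)
  expect_equal(build_schedule(n_boosts = 3, interval_days = 1), c(0, 3, 6, 9))
  expect_error(build_schedule(interval_days = 0), "positive")
})

test_that("initialisation places the tumor and scales leukocytes with volume", {
  cfg <- variant_cfg(duration = 10L, schedule = 0L)
  st <- withr::with_seed(1, sim_initialize(cfg))
  expect_equal(sum(st$cancer), 100)
  expect_equal(st$L, 20)
  # solid tumor: occupied sites form one compact central cluster
  occ <- which(st$cancer > 0)
  expect_lte(length(occ), 100)
  n5 <- sum(st$alive)

  cfg10 <- variant_cfg(duration = 10L, schedule = 0L, volume_ul = 10)
  st10 <- withr::with_seed(1, sim_initialize(cfg10))
  n10 <- sum(st10$alive)
  expect_lte(abs(n10 - 2 * n5), 5)  # densities double within rounding
})

test_that("runs are reproducible and zero-length runs record the initial state", {
  cfg <- variant_cfg(duration = 60L, schedule = c(0L, 30L), seed = 11L)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$series, b$series)
  expect_equal(nrow(a$series), 61)

  cfg0 <- variant_cfg(duration = 0L, schedule = integer(0))
  s0 <- run_simulation(cfg0)
  expect_equal(nrow(s0$series), 1)
  expect_equal(s0$series$cancer, 100)
})

test_that("molecules and counts never go negative and ledgers balance", {
  cfg <- variant_cfg(duration = 150L, schedule = c(0L, 84L), seed = 21L)
  sim <- run_simulation(cfg)
  d <- sim$series
  expect_true(all(as.matrix(d) >= 0))
  expect_equal(d$immune_total[-1],
               head(d$immune_total, -1) + d$births[-1] - d$deaths[-1])
  expect_equal(d$cancer[-1],
               head(d$cancer, -1) + d$cancer_born[-1] - d$cancer_killed[-1])
})

test_that("outcome classification uses a strict final-vs-initial comparison", {
  expect_equal(classify_outcome(fake_sim(99)), "success")
  expect_equal(classify_outcome(fake_sim(100)), "failure")
  expect_equal(classify_outcome(fake_sim(0)), "success")
})

test_that("reactiveness is the percent reduction against unlimited growth", {
  expect_equal(reactiveness(fake_sim(0), fake_sim(200)), 100)
  expect_equal(reactiveness(fake_sim(200), fake_sim(200)), 0)
  expect_equal(reactiveness(fake_sim(50), fake_sim(200)), 75)
  expect_equal(reactiveness(fake_sim(300), fake_sim(200)), 0)  # floored
  expect_error(reactiveness(fake_sim(50), fake_sim(0)), "undefined")
})

test_that("failure profiles group by success rate and bound propensities", {
  wins <- lapply(1:4, function(i) fake_sim(0))
  for (i in seq_along(wins)) {
    wins[[i]]$series <- tibble::tibble(step = 0:1, cancer = c(100, 0),
                                       TC_active = c(0, 5), TH_active = c(0, 3),
                                       DC_presenting_I = c(0, 2),
                                       DC_presenting_II = c(0, 2),
                                       MA_presenting_II = c(0, 1))
  }
  fp <- failure_profile(wins)
  expect_equal(fp$group, "rare_failures")
  expect_equal(nrow(fp$propensity), 0)

  fails <- lapply(1:4, function(i) {
    s <- fake_sim(150)
    s$series <- tibble::tibble(step = 0:1, cancer = c(100, 150),
                               TC_active = c(0, 0), TH_active = c(0, 0),
                               DC_presenting_I = c(0, i %% 2),
                               DC_presenting_II = c(0, 1),
                               MA_presenting_II = c(0, 0))
    s
  })
  fp2 <- failure_profile(fails)
  expect_equal(fp2$group, "frequent_failures")
  pr <- fp2$propensity
  expect_true(all(pr$propensity >= 0 & pr$propensity <= 1))
  expect_equal(pr$propensity[pr$population == "TC_active"], 0)
  expect_equal(pr$propensity[pr$population == "DC_presenting_II"], 1)
})

test_that("tidy and glance expose the time series and run summary", {
  cfg <- variant_cfg(duration = 30L, schedule = 0L, seed = 31L)
  sim <- run_simulation(cfg)
  long <- tidy(sim)
  expect_true(all(c("step", "population", "count") %in% names(long)))
  expect_true("cancer" %in% long$population)
  g <- glance(sim)
  expect_equal(g$initial_cancer, 100)
  expect_true(g$outcome %in% c("success", "failure"))
  p <- autoplot(sim)
  expect_s3_class(p, "ggplot")
})
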