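test_that("the generator is reproducible from its seed", {
  a <- simulate_responses(simulation_config(n_persons = 50, n_items = 5,
                                            seed = 200))
  b <- simulate_responses(simulation_config(n_persons = 50, n_items = 5,
                                            seed = 200))
  expect_identical(a$responses$values, b$responses$values)
  expect_identical(a$factors, b$factors)
  c <- simulate_responses(simulation_config(n_persons = 50, n_items = 5,
                                            seed = 201))
  expect_false(identical(a$responses$values, c$responses$values))
})

test_that("flat parameters give uniform category usage", {
  cfg <- simulation_config(n_persons = 4000, n_items = 5, theta_mean = 0,
                           theta_sd = 0, delta = rep(0, 5),
                           tau = rep(0, 4), seed = 210)
  sim <- simulate_responses(cfg)
  mf <- as.matrix(marginal_frequencies(sim$responses)[-1])
  expect_true(all(abs(mf / 4000 - 0.2) < 0.03))
})

test_that("generated frequencies track the analytic category probabilities", {
  # chi-square goodness-of-fit per item on model-true data with a
  # point-mass ability distribution (known cell probabilities)
  rejections <- 0L; trials <- 0L
  for (s in 1:10) {
    cfg <- simulation_config(n_persons = 1500, n_items = 4, theta_mean = 0.4,
                             theta_sd = 0, delta = c(-0.6, -0.2, 0.2, 0.6),
                             seed = 220 + s)
    sim <- simulate_responses(cfg)
    mf <- as.matrix(marginal_frequencies(sim$responses)[-1])
    for (i in 1:4) {
      p <- rsm_category_probs(0.4, cfg$delta[i], cfg$tau)
      pv <- suppressWarnings(stats::chisq.test(mf[i, ], p = p)$p.value)
      trials <- trials + 1L
      if (pv < 0.01) rejections <- rejections + 1L
    }
  }
  expect_lte(rejections / trials, 0.05)
})

test_that("the default cohort emulates a ceiling-prone agreement survey", {
  sim <- simulate_responses(simulation_config(seed = 230))
  mf <- as.matrix(marginal_frequencies(sim$responses)[-1])
  # right-skewed marginals: modal categories 4-5 for every item
  expect_true(all(apply(mf, 1, which.max) >= 4))
  # a small all-maximum ceiling group exists
  ceiling_rate <- mean(apply(sim$responses$values, 1, function(r) all(r == 5)))
  expect_gt(ceiling_rate, 0.01)
  expect_lt(ceiling_rate, 0.15)
  # factor table covers the design margins
  expect_equal(nrow(sim$factors), 761L)
  expect_setequal(levels(sim$factors$age_group), c("<45", "45-55", ">55"))
  expect_true(all(sim$factors$enps_class[!is.na(sim$factors$enps_raw)] ==
                    classify_enps(sim$factors$enps_raw[!is.na(sim$factors$enps_raw)])))
})

test_that("careless respondents are overwritten and recorded", {
  cfg <- simulation_config(n_persons = 200, n_items = 8,
                           careless_fraction = 0.1, seed = 240)
  sim <- simulate_responses(cfg)
  expect_equal(length(sim$truth$careless), 20L)
  expect_true(all(sim$truth$careless %in% sim$responses$persons))
})

test_that("marginal fixtures reproduce printed counts bit-exactly", {
  tab <- hse_marginals()
  expect_equal(unname(rowSums(as.matrix(tab[-1]))), rep(761, 11))
  m <- fixture_from_marginals(tab, seed = 250)
  expect_equal(dim(m), c(761L, 11L))
  got <- marginal_frequencies(m)
  expect_equal(as.matrix(got[-1]), as.matrix(tab[-1]), ignore_attr = TRUE)
  expect_equal(got$item, tab$item)
  # the printed first and fifth rows, as published
  expect_equal(unlist(tab[tab$item == "HSE1", -1], use.names = FALSE),
               c(5, 33, 116, 294, 313))
  expect_equal(unlist(tab[tab$item == "HSE5", -1], use.names = FALSE),
               c(1, 4, 15, 256, 485))
})

test_that("degenerate and malformed marginal tables are handled", {
  m <- fixture_from_marginals(rbind(c(6, 0, 0, 0, 0), c(0, 0, 0, 0, 6)),
                              seed = 1)
  expect_true(all(m$values[, 1] == 1L))
  expect_true(all(m$values[, 2] == 5L))
  expect_error(fixture_from_marginals(rbind(c(3, 1), c(2, 1))), "same total")
  expect_error(fixture_from_marginals(rbind(c(-1, 5), c(2, 2))),
               "non-negative")
})

test_that("invalid configurations are rejected up front", {
  expect_error(simulation_config(theta_sd = -1), "non-negative")
  expect_error(simulation_config(careless_fraction = 1), "careless_fraction")
  expect_error(simulation_config(tau = c(1, 1, 1, 1)), "sum to zero")
  expect_error(simulation_config(dif_spec = list(list(item = 1))), "shift")
})
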