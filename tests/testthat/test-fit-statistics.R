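test_that("standardized residuals match hand-computed cells", {
  # theta = delta, flat thresholds, K = 4: E = 2, W = 2, so a top-category
  # response has e = 2 and z = sqrt(2)
  mom <- rsm_expected_moments(0.7, 0.7, c(0, 0, 0, 0))
  expect_equal(mom[["E"]], 2)
  expect_equal(mom[["W"]], 2)
  z <- (4 - mom[["E"]]) / sqrt(mom[["W"]])
  expect_equal(z, sqrt(2))

  fit <- hse_null()$fit
  res <- standardized_residuals(fit)
  expect_equal(res$residual, res$observed - res$expected)
  expect_equal(res$std_residual, res$residual / sqrt(res$variance))
})

test_that("per-item residual sums vanish at the JMLE solution", {
  sim <- simulate_responses(simulation_config(n_persons = 300, n_items = 6,
                                              seed = 55))
  fit <- fit_rsm(sim$responses, estimation_settings(convergence_tol = 1e-8))
  res <- standardized_residuals(fit)
  core <- res[!res$person %in% names(which(fit$extreme_persons)), ]
  sums <- tapply(core$residual, core$item, sum)
  expect_true(all(abs(sums) < 1e-3))
})

test_that("infit equals the weighted ratio on a hand-checked matrix", {
  toy <- toy_6x2()
  fit <- fit_rsm(toy, estimation_settings(convergence_tol = 1e-7))
  # spreadsheet-style oracle: per-cell E and W from the closed-form
  # probabilities, then infit = sum(e^2)/sum(W), outfit = mean(z^2)
  x <- toy$values - 1L
  for (i in 1:2) {
    e2 <- w <- z2 <- numeric(nrow(x))
    for (n in seq_len(nrow(x))) {
      mom <- rsm_expected_moments(fit$theta[n], fit$delta[i], fit$tau)
      e2[n] <- (x[n, i] - mom[["E"]])^2
      w[n] <- mom[["W"]]
      z2[n] <- e2[n] / mom[["W"]]
    }
    ft <- item_fit(fit)
    expect_equal(ft$infit_mnsq[i], sum(e2) / sum(w), tolerance = 1e-10)
    expect_equal(ft$outfit_mnsq[i], mean(z2), tolerance = 1e-10)
  }
})

test_that("item mean squares concentrate near 1 on model-true data", {
  ft <- item_fit(null_1000()$fit)
  expect_equal(mean(ft$infit_mnsq), 1, tolerance = 0.05)
  expect_equal(mean(ft$outfit_mnsq), 1, tolerance = 0.05)
  expect_true(all(ft$infit_mnsq > 0.85 & ft$infit_mnsq < 1.15))
})

test_that("a noise item is caught by outfit across seeds", {
  hits <- 0L
  for (s in 1:10) {
    sim <- simulate_responses(simulation_config(n_persons = 400, n_items = 8,
                                                theta_mean = 0, seed = 400 + s))
    vals <- sim$responses$values
    set.seed(s)
    vals[, 3] <- sample.int(5, nrow(vals), TRUE)  # uniform random item
    fit <- fit_rsm(response_matrix(vals, n_categories = 5))
    if (item_fit(fit)$outfit_mnsq[3] > 1.3) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("item fit classification uses a closed interval", {
  tab <- tibble::tibble(item = c("a", "b", "c", "d"),
                        infit_mnsq = c(1.42, 1.29, 0.7, 1.3))
  out <- classify_item_fit(tab)
  expect_equal(out$verdict, c("misfit", "fit", "fit", "fit"))
})

test_that("person flagging needs both mean square and z to exceed", {
  cfg <- analysis_config()
  tab <- tibble::tibble(person = c("p1", "p2", "p3"),
                        infit_mnsq = c(1.5, 1.5, 1.39),
                        infit_z = c(2.5, 1.0, 3.0))
  fr <- flag_rate(tab, cfg)
  expect_equal(fr$flags$flagged, c(TRUE, FALSE, FALSE))
  expect_equal(fr$flag_rate, 1 / 3)
  expect_false(fr$pass)
})

test_that("infit is information-weighted: a far-off wild response moves outfit more", {
  sim <- simulate_responses(simulation_config(n_persons = 300, n_items = 8,
                                              theta_mean = 0, seed = 66))
  vals <- sim$responses$values
  fit0 <- fit_rsm(vals)
  # most able non-extreme person answers the easiest item at the bottom
  ok <- !fit0$extreme_persons
  p <- which(ok)[which.max(fit0$theta[ok])]
  i <- which.min(fit0$delta)
  vals[p, i] <- 1L
  fit1 <- fit_rsm(vals)
  ft0 <- item_fit(fit0); ft1 <- item_fit(fit1)
  d_out <- ft1$outfit_mnsq[i] - ft0$outfit_mnsq[i]
  d_in <- ft1$infit_mnsq[i] - ft0$infit_mnsq[i]
  expect_gt(d_out, d_in)
  expect_gt(d_out, 0)
})

test_that("fit tables are invariant to person ordering", {
  sim <- simulate_responses(simulation_config(n_persons = 150, n_items = 6,
                                              seed = 91))
  m <- sim$responses
  set.seed(2)
  pp <- sample(nrow(m$values))
  mp <- response_matrix(m$values[pp, ], persons = m$persons[pp],
                        items = m$items, n_categories = 5)
  f1 <- item_fit(fit_rsm(m))
  f2 <- item_fit(fit_rsm(mp))
  expect_equal(f2$infit_mnsq, f1$infit_mnsq, tolerance = 1e-5)
  expect_equal(f2$outfit_mnsq, f1$outfit_mnsq, tolerance = 1e-5)
})
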