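test_that("JMLE matches a grid-search likelihood oracle on a toy matrix", {
  toy <- toy_6x2()
  fit <- fit_rsm(toy, estimation_settings(convergence_tol = 1e-7))

  # oracle: profile persons out on a fine measure grid, search the
  # identified (delta1, tau1) plane coarse-to-fine down to 0.01 logits
  x <- toy$values - 1L
  th_grid <- seq(-5, 5, 0.01)
  profile_ll <- function(d1, t1) {
    tau <- c(t1, -t1)
    psi <- c(0, cumsum(tau))
    logz <- function(eta) {
      a0 <- -psi[1]; a1 <- eta - psi[2]; a2 <- 2 * eta - psi[3]
      m <- pmax(a0, a1, a2)
      m + log(exp(a0 - m) + exp(a1 - m) + exp(a2 - m))
    }
    a <- th_grid - d1; b <- th_grid + d1
    lza <- logz(a); lzb <- logz(b)
    tot <- 0
    for (n in seq_len(nrow(x))) {
      lln <- x[n, 1] * a - psi[x[n, 1] + 1] +
        x[n, 2] * b - psi[x[n, 2] + 1] - lza - lzb
      tot <- tot + max(lln)
    }
    tot
  }
  search <- function(d1s, t1s) {
    best <- c(NA, NA, -Inf)
    for (d1 in d1s) for (t1 in t1s) {
      ll <- profile_ll(d1, t1)
      if (ll > best[3]) best <- c(d1, t1, ll)
    }
    best
  }
  coarse <- search(seq(-1.5, 1.5, 0.05), seq(-2, 2, 0.05))
  fine <- search(seq(coarse[1] - 0.06, coarse[1] + 0.06, 0.01),
                 seq(coarse[2] - 0.06, coarse[2] + 0.06, 0.01))
  expect_equal(fit$delta[[1]], fine[1], tolerance = 0.02)
  expect_equal(fit$tau[[1]], fine[2], tolerance = 0.02)
})

test_that("identification constraints hold at convergence", {
  for (f in list(hse_null()$fit, null_1000()$fit)) {
    expect_equal(mean(f$delta[!f$extreme_items]), 0, tolerance = 1e-6)
    expect_equal(sum(f$tau), 0, tolerance = 1e-6)
    expect_true(all(f$se_theta[!f$extreme_persons] > 0))
    expect_true(all(f$se_delta[!f$extreme_items] > 0))
  }
})

test_that("the log-likelihood never decreases across accepted cycles", {
  traj <- hse_null()$fit$trajectory
  expect_true(all(diff(traj) >= -1e-8))
})

test_that("estimates are equivariant under person and item relabeling", {
  sim <- simulate_responses(simulation_config(n_persons = 120, n_items = 6,
                                              seed = 31))
  m <- sim$responses
  fit <- fit_rsm(m)
  set.seed(77)
  pp <- sample(nrow(m$values)); ii <- sample(ncol(m$values))
  mp <- response_matrix(m$values[pp, ii], persons = m$persons[pp],
                        items = m$items[ii], n_categories = m$n_categories)
  fitp <- fit_rsm(mp)
  expect_equal(fitp$delta[m$items], fit$delta, tolerance = 1e-4)
  expect_equal(fitp$theta[m$persons], fit$theta, tolerance = 1e-4)
  expect_equal(fitp$tau, fit$tau, tolerance = 1e-4)
})

test_that("extreme persons are flagged and placed beyond the core range", {
  sim <- simulate_responses(simulation_config(n_persons = 60, n_items = 5,
                                              theta_mean = 0, seed = 8))
  vals <- sim$responses$values
  vals[1, ] <- 5L  # perfect ceiling pattern
  vals[2, ] <- 1L  # floor pattern
  m <- response_matrix(vals, n_categories = 5)
  fit <- fit_rsm(m)
  expect_true(fit$extreme_persons[1])
  expect_true(fit$extreme_persons[2])
  expect_gt(fit$theta[1], max(fit$theta[!fit$extreme_persons]))
  expect_lt(fit$theta[2], min(fit$theta[!fit$extreme_persons]))
  expect_true(all(is.finite(fit$se_theta[1:2])))
})

test_that("an unobserved category stops estimation with advice", {
  vals <- matrix(sample(c(1L, 2L, 4L, 5L), 80, TRUE), 20)
  vals[1, 1] <- 1L; vals[2, 1] <- 5L
  m <- response_matrix(vals, n_categories = 5)
  expect_error(fit_rsm(m), "never observed.*collapse")
})

test_that("difficulty recovery sharpens as the sample grows", {
  # matched seeds, N = 200 vs N = 2000
  rmse <- function(n, seed) {
    cfg <- simulation_config(n_persons = n, n_items = 8, theta_mean = 0,
                             delta = seq(-1.2, 1.2, length.out = 8),
                             seed = seed)
    sim <- simulate_responses(cfg)
    fit <- fit_rsm(sim$responses)
    sqrt(mean((fit$delta - sim$truth$delta)^2))
  }
  seeds <- 300 + seq_len(20)
  small <- vapply(seeds, function(s) rmse(200, s), 0)
  large <- vapply(seeds, function(s) rmse(2000, s), 0)
  expect_lt(mean(large), mean(small))
})

test_that("fitted parameters serialize to JSON and back", {
  fit <- hse_null()$fit
  path <- withr::local_tempfile(fileext = ".json")
  rsm_to_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$thresholds, fit$tau)
  expect_equal(back$items$difficulty, unname(fit$delta))
  expect_true(back$converged)
})
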