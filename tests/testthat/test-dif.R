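test_that("identical group distributions give a zero Mantel statistic", {
  scores <- rep(c(1, 2, 3, 4, 5), times = 4)
  group <- rep(c("a", "b"), each = 10)
  strata <- rep(rep(c("s1", "s2"), each = 5), 2)
  res <- mantel_polytomous(scores, group, strata)
  expect_equal(res$chi_square, 0)
  expect_equal(res$p_value, 1)
  expect_true(is.na(res$direction))
})

test_that("the statistic matches an enumeration oracle on a toy table", {
  # 2 strata x 2 groups x 3 categories; exact conditional moments of
  # the focal score sum by enumerating all focal subsets per stratum
  scores <- c(1, 1, 2, 3, 3, 2,   2, 2, 3, 1, 3, 3, 2)
  group <- c("f", "f", "f", "r", "r", "r",  "f", "f", "r", "r", "r", "f", "r")
  strata <- c(rep("s1", 6), rep("s2", 7))
  res <- mantel_polytomous(scores, group, strata)

  enum_moments <- function(y, n_f) {
    subsets <- utils::combn(length(y), n_f)
    sums <- apply(subsets, 2, function(ix) sum(y[ix]))
    c(mean = mean(sums), var = mean(sums^2) - mean(sums)^2)
  }
  oe <- 0; vv <- 0
  for (s in unique(strata)) {
    y <- scores[strata == s]
    g <- group[strata == s]
    mom <- enum_moments(y, sum(g == "f"))
    oe <- oe + sum(y[g == "f"]) - mom["mean"]
    vv <- vv + mom["var"]
  }
  expect_equal(res$chi_square, unname(oe^2 / vv), tolerance = 1e-12)
  expect_equal(res$sum_o_minus_e, unname(oe), tolerance = 1e-12)
})

test_that("the statistic is invariant to relabeling, direction flips", {
  set.seed(180)
  scores <- sample.int(5, 120, TRUE)
  group <- sample(c("x", "y"), 120, TRUE)
  strata <- sample(letters[1:4], 120, TRUE)
  a <- mantel_polytomous(scores, group, strata)
  # relabel strata
  b <- mantel_polytomous(scores, group, paste0("band_", strata))
  expect_equal(b$chi_square, a$chi_square)
  # swap group labels: magnitude unchanged, direction flips
  swapped <- ifelse(group == "x", "y", "x")
  cc <- mantel_polytomous(scores, swapped, strata)
  expect_equal(cc$chi_square, a$chi_square, tolerance = 1e-12)
  if (!is.na(a$direction)) expect_false(identical(cc$direction, a$direction))
  expect_equal(cc$sum_o_minus_e, -a$sum_o_minus_e, tolerance = 1e-12)
})

test_that("merging two strata with identical tables changes nothing", {
  y <- c(1, 2, 3, 4, 2, 3)
  g <- c("f", "f", "r", "r", "f", "r")
  scores <- c(y, y)
  group <- c(g, g)
  two <- mantel_polytomous(scores, group, rep(c("s1", "s2"), each = 6))
  one <- mantel_polytomous(scores, group, rep("s", 12))
  # identical group-by-category composition: both are exchangeable
  expect_equal(two$sum_o_minus_e, one$sum_o_minus_e, tolerance = 1e-12)
})

test_that("single-group strata are dropped, all-dropped is undefined", {
  res <- suppressWarnings(
    mantel_polytomous(c(1, 2, 3, 4), c("f", "f", "f", "f"),
                      c("s1", "s1", "s2", "s2")))
  expect_true(is.na(res$chi_square))
  expect_equal(res$n_strata_used, 0L)
})

test_that("a three-level factor yields three pairwise scans per item", {
  hn <- hse_null()
  dif <- suppressWarnings(dif_scan(hn$fit, hn$sim$factors))
  age <- dif[dif$factor == "age_group", ]
  expect_equal(length(unique(paste(age$group_a, age$group_b))), 3L)
  expect_equal(nrow(age), 3L * 11L)
  # Bonferroni family: adjusted p = min(1, raw * (items x pairs))
  expect_equal(age$p_adj, pmin(1, age$p_raw * nrow(age)))
})

test_that("null factors produce no flags on model-true data", {
  hn <- hse_null()
  dif <- suppressWarnings(dif_scan(hn$fit, hn$sim$factors))
  expect_false(any(dif$flagged, na.rm = TRUE))
  expect_true(all(dif$chi_square >= 0, na.rm = TRUE))
})

test_that("an injected DIF shift is detected and oriented correctly", {
  cfg <- simulation_config(
    n_persons = 1000, n_items = 11, seed = 190,
    dif_spec = list(list(item = "HSE7", factor = "age_group",
                         level = "45-55", shift = 0.8)))
  sim <- simulate_responses(cfg)
  fit <- fit_rsm(sim$responses)
  dif <- suppressWarnings(dif_scan(fit, sim$factors))
  hits <- dif[dif$item == "HSE7" & dif$factor == "age_group" &
                (dif$group_a == "45-55" | dif$group_b == "45-55"), ]
  expect_true(any(hits$flagged))
  # the focal level is the one finding the item harder to endorse
  expect_true(all(hits$direction[hits$flagged] == "45-55"))
})
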