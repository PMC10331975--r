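# Shared fixtures, built lazily once per test run. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# model-true cohort at the default survey-emulation settings, fitted
hse_null <- function() fixture("hse_null", function() {
  sim <- simulate_responses(simulation_config(seed = 101))
  list(sim = sim, fit = fit_rsm(sim$responses))
})

# on-target model-true cohort at N = 1000, L = 10, used for the
# concentration and recovery checks
null_1000 <- function() fixture("null_1000", function() {
  cfg <- simulation_config(n_persons = 1000, n_items = 10,
                           theta_mean = 0, theta_sd = 1.5,
                           delta = seq(-1.5, 1.5, length.out = 10),
                           seed = 202)
  sim <- simulate_responses(cfg)
  list(sim = sim, fit = fit_rsm(sim$responses))
})

# an item drawn from a shifted, noise-contaminated process: harder by
# `shift` logits and with a `noise` fraction of uniform random answers
contaminated_item <- function(theta, shift = 1, noise = 0.35, seed = 1) {
  set.seed(seed)
  tau <- c(-1.9, -0.9, 0.3, 2.5)
  x <- vapply(theta, function(th) {
    sample.int(5, 1, prob = rsm_category_probs(th, shift, tau))
  }, 0L)
  wild <- runif(length(x)) < noise
  x[wild] <- sample.int(5, sum(wild), TRUE)
  x
}

# a two-group cohort for DIF power studies: the focal half answers one
# item `shift` logits harder, everything else shared
dif_power_draw <- function(n_each, shift, item = 3, seed = 1) {
  base <- simulation_config(n_persons = n_each, n_items = 11,
                            theta_mean = 0, seed = seed)
  ref <- simulate_responses(base)
  delta_f <- base$delta
  delta_f[item] <- delta_f[item] + shift
  foc <- simulate_responses(
    simulation_config(n_persons = n_each, n_items = 11, theta_mean = 0,
                      delta = delta_f, seed = seed + 50000))
  list(scores = c(ref$responses$values[, item], foc$responses$values[, item]),
       raw = c(rowSums(ref$responses$values),
               rowSums(foc$responses$values)),
       group = rep(c("reference", "focal"), each = n_each))
}

# matched-score strata from raw-total deciles
decile_bands <- function(raw) {
  br <- unique(stats::quantile(raw, seq(0, 1, 0.1)))
  as.integer(cut(raw, breaks = br, include.lowest = TRUE))
}

# small complete toy matrix with all categories in use, no extremes
toy_6x2 <- function() {
  response_matrix(matrix(c(2, 1, 2, 3, 2, 3,
                           1, 2, 2, 2, 3, 1), ncol = 2),
                  n_categories = 3)
}
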