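#' Configuration of the synthetic response-generating process
#'
#' Describes a unidimensional rating-scale Rasch process with optional,
#' controlled violations: uniform DIF shifts for a focal group, an
#' additive secondary trait loading on an item subset, and a fraction
#' of careless respondents who answer uniformly at random.
#'
#' The defaults emulate the safety-climate survey cohort the pipeline
#' was designed around: 761 respondents, 11 items on a five-category
#' agreement scale, item difficulties spread over about one logit, a
#' ceiling-prone ability distribution centred 1.6 logits above the
#' average item with a 2-logit spread (calibrated so about 5% of
#' respondents score the all-maximum ceiling while every rating-scale
#' category keeps acceptable outfit), and thresholds that leave the
#' second category
#' sparsely used -- producing right-skewed marginals with modal
#' categories 4-5 and a small all-maximum ceiling group.
#'
#' @param n_persons,n_items,n_categories cohort shape.
#' @param theta_mean,theta_sd normal ability distribution (logits).
#' @param delta explicit item-difficulty vector, or `NULL` for a
#'   uniform grid over `delta_range` (centered).
#' @param delta_range numeric length-2, used when `delta` is `NULL`.
#' @param tau shared step thresholds (length `n_categories - 1`,
#'   must sum to zero).
#' @param dif_spec list of uniform-DIF injections, each a list with
#'   `item` (identifier or index), `factor` (column of the generated
#'   factor table), `level` (focal level) and `shift` (logits added to
#'   the item difficulty for focal-group members; positive = harder to
#'   endorse).
#' @param second_dimension `NULL`, or a list with `items` (identifiers
#'   or indices), `loading` and `sd`: a person-specific nuisance trait
#'   `u ~ N(0, sd)` enters the linear predictor of the loaded items as
#'   `loading * u`.
#' @param careless_fraction proportion of persons whose rows are
#'   overwritten with uniform random categories.
#' @param seed integer seed; the whole draw is reproducible from it.
#' @return A list with class `simulation_config`.
#' @export
simulation_config <- function(n_persons = 761L, n_items = 11L,
                              n_categories = 5L,
                              theta_mean = 1.6, theta_sd = 2.0,
                              delta = NULL, delta_range = c(-0.5, 0.5),
                              tau = NULL,
                              dif_spec = list(),
                              second_dimension = NULL,
                              careless_fraction = 0,
                              seed = NULL) {
  k <- as.integer(n_categories) - 1L
  if (is.null(tau)) {
    tau <- default_tau(k)
  }
  if (length(tau) != k) abort(sprintf("`tau` must have length %d", k))
  if (abs(sum(tau)) > 1e-8) abort("`tau` must sum to zero")
  if (theta_sd < 0) abort("`theta_sd` must be non-negative")
  if (careless_fraction < 0 || careless_fraction >= 1) {
    abort("`careless_fraction` must lie in [0, 1)")
  }
  if (is.null(delta)) {
    delta <- if (n_items == 1L) 0 else
      seq(delta_range[1L], delta_range[2L], length.out = n_items)
    delta <- delta - mean(delta)
  }
  if (length(delta) != n_items) abort("`delta` must have length `n_items`")
  if (!all(vapply(dif_spec, function(d)
    all(c("item", "factor", "level", "shift") %in% names(d)) &&
      is.finite(d$shift), TRUE))) {
    abort("each `dif_spec` entry needs finite `shift` plus `item`, `factor`, `level`")
  }
  structure(list(n_persons = as.integer(n_persons),
                 n_items = as.integer(n_items),
                 n_categories = as.integer(n_categories),
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 delta = delta, tau = tau,
                 dif_spec = dif_spec,
                 second_dimension = second_dimension,
                 careless_fraction = careless_fraction,
                 seed = seed),
            class = "simulation_config")
}

# default thresholds: second category squeezed between its neighbours,
# top step well above centre, mimicking agreement-scale usage where the
# mild-disagreement option is rarely chosen
default_tau <- function(k) {
  if (k == 4L) return(c(-1.9, -0.9, 0.3, 2.5))
  tau <- seq(-1, 1, length.out = k)
  tau - mean(tau)
}

#' Simulate a response matrix from a rating-scale Rasch process
#'
#' Draws person abilities, builds the respondent background-factor
#' table, applies any configured DIF shifts and secondary-dimension
#' contributions to the linear predictor, samples categories from the
#' rating-scale model, and finally overwrites careless respondents with
#' uniform random categories. Background factors are drawn
#' independently of the responses, so factors not named in `dif_spec`
#' are exact nulls for DIF testing.
#'
#' @param cfg a [simulation_config()].
#' @return A list: `responses` (a [response_matrix()]), `factors`
#'   (background-factor tibble with gender, age group, employee type,
#'   tenure band and eNPS), and `truth` (the generating parameters:
#'   `theta`, `delta`, `tau`, per-person secondary trait, careless
#'   person ids, and the effective per-cell difficulty shifts).
#' @export
simulate_responses <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_persons; l <- cfg$n_items; kk <- cfg$n_categories - 1L
  persons <- sprintf("P%04d", seq_len(n))
  items <- paste0("HSE", seq_len(l))

  theta <- rnorm(n, cfg$theta_mean, cfg$theta_sd)
  factors <- simulate_factors(persons)

  # per-cell linear-predictor shifts from DIF injections
  shift <- matrix(0, n, l, dimnames = list(persons, items))
  for (d in cfg$dif_spec) {
    i <- if (is.character(d$item)) match(d$item, items) else as.integer(d$item)
    if (is.na(i) || i < 1L || i > l) abort("dif_spec item not in the design")
    if (!d$factor %in% names(factors)) {
      abort(sprintf("dif_spec factor '%s' is not a generated factor", d$factor))
    }
    focal <- as.character(factors[[d$factor]]) == as.character(d$level)
    focal[is.na(focal)] <- FALSE
    shift[focal, i] <- shift[focal, i] + d$shift
  }

  u <- rep(0, n)
  if (!is.null(cfg$second_dimension)) {
    sdm <- cfg$second_dimension
    u <- rnorm(n, 0, sdm$sd %||% 1)
    idx <- if (is.character(sdm$items)) match(sdm$items, items) else
      as.integer(sdm$items)
    if (anyNA(idx)) abort("second_dimension items not in the design")
    shift[, idx] <- shift[, idx] - (sdm$loading %||% 1) * u
  }

  eta <- outer(theta, cfg$delta, "-") - shift
  vals <- sample_rsm(eta, cfg$tau)

  careless <- integer(0)
  if (cfg$careless_fraction > 0) {
    n_car <- round(cfg$careless_fraction * n)
    careless <- sample.int(n, n_car)
    vals[careless, ] <- sample.int(kk + 1L, n_car * l, replace = TRUE) - 1L
  }

  responses <- response_matrix(vals + 1L, persons = persons, items = items,
                               n_categories = cfg$n_categories)
  list(responses = responses,
       factors = factors,
       truth = list(theta = setNames(theta, persons),
                    delta = setNames(cfg$delta, items),
                    tau = cfg$tau,
                    second_trait = setNames(u, persons),
                    careless = persons[sort(careless)],
                    shift = shift,
                    config = cfg))
}

# inverse-CDF sampling of rating-scale categories for an eta matrix
sample_rsm <- function(eta, tau) {
  kk <- length(tau)
  fld <- rsm_field(eta, tau, want = "P")
  uu <- matrix(runif(length(eta)), nrow(eta), ncol(eta))
  out <- matrix(0L, nrow(eta), ncol(eta))
  acc <- fld$P[[1L]]
  for (k in 1:kk) {
    out <- out + (uu >= acc)
    acc <- acc + fld$P[[k + 1L]]
  }
  out
}

# background factors with marginal composition matching the study
# cohort (returned proportions, not fixed counts); independent of the
# latent trait unless dif_spec routes them into the difficulty
simulate_factors <- function(persons) {
  n <- length(persons)
  enps_present <- runif(n) < 303 / 761
  enps_class <- sample(c("detractor", "passive", "promoter"), n, TRUE,
                       prob = c(109, 118, 76) / 303)
  enps_raw <- ifelse(enps_class == "detractor", sample(0:6, n, TRUE),
              ifelse(enps_class == "passive", sample(7:8, n, TRUE),
                     sample(9:10, n, TRUE)))
  enps_raw[!enps_present] <- NA_integer_
  tibble(
    person = persons,
    gender = factor(sample(c("female", "male"), n, TRUE,
                           prob = c(673, 88) / 761)),
    age_group = factor(sample(c("<45", "45-55", ">55"), n, TRUE,
                              prob = c(233, 225, 303) / 761),
                       levels = c("<45", "45-55", ">55")),
    employee_type = factor(sample(c("manager", "co-worker"), n, TRUE,
                                  prob = c(137, 624) / 761)),
    tenure_band = factor(sample(c("<3", "3-10", ">10"), n, TRUE,
                                prob = c(210, 399, 152) / 761),
                         levels = c("<3", "3-10", ">10")),
    enps_raw = as.integer(enps_raw),
    enps_class = factor(ifelse(enps_present, enps_class, NA_character_),
                        levels = c("detractor", "passive", "promoter")))
}

#' Build a fixture matrix with exact per-item category frequencies
#'
#' Constructs an N x L response matrix whose per-item marginal counts
#' equal the given table bit-exactly, by independently shuffling each
#' item's multiset of codes. The joint structure across items is
#' random, so such a fixture validates input/output and marginal
#' bookkeeping -- not fitted statistics.
#'
#' @param counts an L x K count matrix, or a tibble as returned by
#'   [marginal_frequencies()] (an `item` column plus one column per
#'   category). All rows must sum to the same N.
#' @param seed integer seed for the per-item shuffles.
#' @return A [response_matrix()] with N persons.
#' @export
fixture_from_marginals <- function(counts, seed = NULL) {
  if (is.data.frame(counts)) {
    items <- if ("item" %in% names(counts)) as.character(counts$item) else NULL
    counts <- as.matrix(counts[setdiff(names(counts), "item")])
    rownames(counts) <- items
  }
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers")
  }
  n <- unique(rowSums(counts))
  if (length(n) != 1L) abort("all item rows must sum to the same total N")
  if (!is.null(seed)) set.seed(seed)
  vals <- apply(counts, 1L, function(row) {
    sample(rep.int(seq_along(row), row))
  })
  response_matrix(vals,
                  items = rownames(counts),
                  n_categories = ncol(counts))
}

#' Published per-item category frequencies of the HSE instrument
#'
#' The per-item response-category counts of the 11-item HSE
#' safety-climate questionnaire in the 761-respondent validation
#' cohort. Useful with [fixture_from_marginals()] to build a
#' marginally exact fixture.
#'
#' @return A tibble: `item`, `cat_1`..`cat_5`; every row sums to 761.
#' @export
hse_marginals <- function() {
  counts <- matrix(c(
      5,  33, 116, 294, 313,
     11,  17,  97, 372, 264,
      4,  22,  99, 359, 277,
     13,  40, 140, 339, 229,
      1,   4,  15, 256, 485,
      2,   1,  28, 282, 448,
      5,  11,  67, 278, 400,
     10,  32, 197, 376, 146,
     12,  32, 148, 342, 227,
     15,  25,  92, 269, 360,
     34,  62, 284, 252, 129), ncol = 5L, byrow = TRUE)
  out <- as_tibble(as.data.frame(counts))
  names(out) <- paste0("cat_", 1:5)
  dplyr::bind_cols(tibble(item = paste0("HSE", 1:11)), out)
}
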