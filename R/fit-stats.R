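# Residual field of a fitted model: matrices E, W, C, e, z over the
# full person x item grid (NA where missing), plus masks identifying
# the non-extreme core used by fit statistics.
residual_field <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  m <- fit$data
  x <- m$values - 1L
  eta <- outer(fit$theta, fit$delta, "-")
  fld <- rsm_field(eta, fit$tau, want = c("E", "W", "C"))
  e <- x - fld$E
  z <- e / sqrt(fld$W)
  core <- outer(!fit$extreme_persons, !fit$extreme_items, "&") &
    !m$missing_mask
  list(x = x, E = fld$E, W = fld$W, C = fld$C, e = e, z = z,
       obs = !m$missing_mask, core = core)
}

#' Standardized response residuals
#'
#' Per-cell raw residuals `e = x - E` and standardized residuals
#' `z = e / sqrt(W)` under the fitted rating-scale model, the raw
#' material of the local-independence screen, the residual PCA, and
#' the item/person fit statistics. Missing cells propagate as `NA`.
#'
#' @param fit an [fit_rsm()] result.
#' @return A tibble with one row per observed person-item encounter:
#'   `person`, `item`, `observed` (external 1-based code), `expected`,
#'   `variance`, `residual`, `std_residual`.
#' @export
standardized_residuals <- function(fit) {
  rf <- residual_field(fit)
  m <- fit$data
  tibble(person = rep(m$persons, times = ncol(rf$e)),
         item = rep(m$items, each = nrow(rf$e)),
         observed = as.vector(m$values),
         expected = as.vector(rf$E) + 1,
         variance = as.vector(rf$W),
         residual = as.vector(rf$e),
         std_residual = as.vector(rf$z)) |>
    dplyr::filter(!is.na(.data$observed))
}

#' @rdname standardized_residuals
#' @param x an `rsm_fit`.
#' @param ... unused.
#' @export
augment.rsm_fit <- function(x, ...) standardized_residuals(x)

# mean-square fit statistics along one margin of the residual field.
# margin 1 = persons (sum over items), margin 2 = items.
msq_margin <- function(rf, margin) {
  use <- rf$core
  z2 <- rf$z^2; z2[!use] <- NA
  e2 <- rf$e^2; e2[!use] <- 0
  ww <- rf$W; ww[!use] <- 0
  cc <- rf$C; cc[!use] <- 0
  n_obs <- apply(use, margin, sum)
  outfit <- apply(z2, margin, mean, na.rm = TRUE)
  sum_e2 <- apply(e2, margin, sum)
  sum_w <- apply(ww, margin, sum)
  infit <- sum_e2 / sum_w
  # variance of the mean squares under the model, for standardization
  rat <- rf$C / rf$W^2; rat[!use] <- 0
  q2_out <- apply(rat, margin, sum) / n_obs^2 - 1 / n_obs
  q2_in <- apply(cc - ww^2, margin, sum) / sum_w^2
  list(n_obs = unname(n_obs),
       outfit = unname(ifelse(n_obs > 0, outfit, NA_real_)),
       infit = unname(ifelse(n_obs > 0, infit, NA_real_)),
       outfit_z = unname(wilson_hilferty(outfit, q2_out)),
       infit_z = unname(wilson_hilferty(infit, q2_in)))
}

# cube-root normalizing transform of a mean square with variance q2
wilson_hilferty <- function(msq, q2) {
  q <- sqrt(pmax(q2, 1e-12))
  (msq^(1 / 3) - 1) * (3 / q) + q / 3
}

#' Item goodness-of-fit statistics
#'
#' Unweighted (outfit) and information-weighted (infit) mean-square
#' residual statistics per item, with standardized values from the
#' cube-root (Wilson-Hilferty) transform. Outfit is the mean squared
#' standardized residual; infit weights each squared score residual by
#' its model variance, so off-target responses influence it less.
#' Extreme persons carry no information and are excluded; an item with
#' no usable observations gets `NA` statistics.
#'
#' @param fit an [fit_rsm()] result.
#' @return A tibble: `item`, `difficulty`, `se`, `n_obs`,
#'   `infit_mnsq`, `infit_z`, `outfit_mnsq`, `outfit_z`.
#' @export
item_fit <- function(fit) {
  rf <- residual_field(fit)
  ms <- msq_margin(rf, 2L)
  tibble(item = fit$data$items,
         difficulty = unname(fit$delta),
         se = unname(fit$se_delta),
         n_obs = ms$n_obs,
         infit_mnsq = ms$infit, infit_z = ms$infit_z,
         outfit_mnsq = ms$outfit, outfit_z = ms$outfit_z)
}

#' Person goodness-of-fit statistics
#'
#' @inheritParams item_fit
#' @return A tibble: `person`, `measure`, `se`, `n_obs`,
#'   `infit_mnsq`, `infit_z`, `outfit_mnsq`, `outfit_z`. Persons with
#'   extreme raw scores have `n_obs = 0` and `NA` statistics.
#' @export
person_fit <- function(fit) {
  rf <- residual_field(fit)
  ms <- msq_margin(rf, 1L)
  tibble(person = fit$data$persons,
         measure = unname(fit$theta),
         se = unname(fit$se_theta),
         n_obs = ms$n_obs,
         infit_mnsq = ms$infit, infit_z = ms$infit_z,
         outfit_mnsq = ms$outfit, outfit_z = ms$outfit_z)
}

#' Classify items against the infit criterion
#'
#' An item misfits when its infit mean square falls outside the closed
#' interval `[item_infit_lo, item_infit_hi]`; values on the boundary
#' count as fitting.
#'
#' @param fit_table output of [item_fit()].
#' @param cfg an [analysis_config()].
#' @return The table with an added `verdict` column (`"fit"`/
#'   `"misfit"`; `NA` statistics give `NA` verdicts).
#' @export
classify_item_fit <- function(fit_table, cfg = analysis_config()) {
  dplyr::mutate(fit_table, verdict = dplyr::case_when(
    is.na(.data$infit_mnsq) ~ NA_character_,
    .data$infit_mnsq < cfg$item_infit_lo ~ "misfit",
    .data$infit_mnsq > cfg$item_infit_hi ~ "misfit",
    TRUE ~ "fit"))
}

#' Flag misfitting persons and compute the flag rate
#'
#' A person is flagged only when both conditions hold: infit mean
#' square at least `person_infit_max` (default 1.4) and infit z at
#' least `person_z_max` (default 2). The protocol accepts the scale
#' when at most `person_misfit_budget` (default 5%) of the assessable
#' sample is flagged, the fraction expected to fail by chance alone.
#'
#' @param fit_table output of [person_fit()].
#' @param cfg an [analysis_config()].
#' @return A list: `flags` (the table with a logical `flagged`
#'   column), `n_flagged`, `n_assessable`, `flag_rate`, `pass`.
#' @export
flag_rate <- function(fit_table, cfg = analysis_config()) {
  flags <- dplyr::mutate(fit_table,
    flagged = !is.na(.data$infit_mnsq) &
      .data$infit_mnsq >= cfg$person_infit_max &
      .data$infit_z >= cfg$person_z_max)
  n_ok <- sum(!is.na(fit_table$infit_mnsq))
  n_fl <- sum(flags$flagged)
  rate <- if (n_ok > 0) n_fl / n_ok else NA_real_
  list(flags = flags, n_flagged = n_fl, n_assessable = n_ok,
       flag_rate = rate,
       pass = !is.na(rate) && rate <= cfg$person_misfit_budget)
}
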