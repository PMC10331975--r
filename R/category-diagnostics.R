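#' Rating-scale category functioning diagnostics
#'
#' Step 1 of the validation protocol: do all categories of the shared
#' rating scale work as intended? For each category this reports its
#' observation count, the average measure of the persons who used it,
#' and its outfit mean square. The scale passes when average measures
#' advance monotonically with category order and every category outfit
#' stays below `category_outfit_max` (default 2.0).
#'
#' Average measures are pooled across items by default (the
#' rating-scale model shares one category structure); set
#' `by_item = TRUE` for the per-item breakdown.
#'
#' @param fit an [fit_rsm()] result.
#' @param cfg an [analysis_config()].
#' @param by_item also compute the per-item category table.
#' @return An object of class `category_diagnostics`: a list with
#'   `categories` (per-category tibble), `thresholds` (Andrich step
#'   calibrations), `monotonic`, `outfit_ok`, `pass`, and optionally
#'   `by_item`.
#' @export
category_diagnostics <- function(fit, cfg = analysis_config(),
                                 by_item = FALSE) {
  rf <- residual_field(fit)
  kk <- length(fit$tau)
  theta_mat <- matrix(fit$theta, nrow(rf$x), ncol(rf$x))
  cat_stats <- function(mask) {
    purrr::map_dfr(0:kk, function(k) {
      sel <- mask & !is.na(rf$x) & rf$x == k
      n <- sum(sel)
      tibble(category = k + 1L,
             n_obs = n,
             avg_measure = if (n > 0) mean(theta_mat[sel]) else NA_real_,
             outfit_mnsq = if (n > 0) mean(rf$z[sel]^2) else NA_real_)
    })
  }
  categories <- cat_stats(rf$core)
  if (any(categories$n_obs == 0L)) {
    warn(sprintf("category %s is unobserved; its diagnostics are undefined",
                 paste(categories$category[categories$n_obs == 0L],
                       collapse = ", ")))
  }
  am <- categories$avg_measure[categories$n_obs > 0L]
  monotonic <- !is.unsorted(am, strictly = FALSE)
  outfits <- categories$outfit_mnsq[categories$n_obs > 0L]
  outfit_ok <- all(outfits < cfg$category_outfit_max)
  out <- list(
    categories = categories,
    thresholds = tibble(step = seq_len(kk), tau = fit$tau),
    monotonic = monotonic,
    outfit_ok = outfit_ok,
    pass = monotonic && outfit_ok)
  if (by_item) {
    out$by_item <- purrr::map_dfr(seq_along(fit$data$items), function(i) {
      mask <- rf$core
      mask[, -i] <- FALSE
      dplyr::mutate(cat_stats(mask), item = fit$data$items[i],
                    .before = 1L)
    })
  }
  structure(out, class = "category_diagnostics")
}

#' @export
print.category_diagnostics <- function(x, ...) {
  cat("<category_diagnostics>\n")
  print(x$categories)
  cat(sprintf("monotonic advance: %s | category outfits ok: %s | pass: %s\n",
              x$monotonic, x$outfit_ok, x$pass))
  invisible(x)
}

#' Category probability curves
#'
#' Model-implied probability of each response category along the
#' latent continuum, the standard visual check of rating-scale
#' functioning. Adjacent-category curves cross exactly at the Andrich
#' thresholds; with disordered thresholds some category is never the
#' most probable response anywhere on the continuum.
#'
#' @param fit an [fit_rsm()] result (only its thresholds are used).
#' @param grid numeric vector of `theta - delta` values (logits).
#' @return A tibble: `eta` (relative measure), `category` (external
#'   1-based code, as an ordered factor), `prob`.
#' @export
category_curves <- function(fit, grid = seq(-6, 6, by = 0.05)) {
  tau <- if (inherits(fit, "rsm_fit")) fit$tau else fit
  kk <- length(tau)
  fld <- rsm_field(matrix(grid, ncol = 1L), tau, want = "P")
  purrr::map_dfr(0:kk, function(k) {
    tibble(eta = grid, category = k + 1L, prob = fld$P[[k + 1L]][, 1L])
  }) |>
    dplyr::mutate(category = factor(.data$category, levels = 1:(kk + 1L),
                                    ordered = TRUE))
}

#' @rdname category_curves
#' @param object a `category_diagnostics` result.
#' @param ... unused.
#' @export
autoplot.category_diagnostics <- function(object, ...) {
  curves <- category_curves(object$thresholds$tau)
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$eta, .data$prob,
                               colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$thresholds$tau,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "measure relative to item difficulty (logits)",
                  y = "category probability", colour = "category") +
    ggplot2::theme_minimal()
}

#' Collapse rating-scale categories
#'
#' Applies a merge map to the external category codes, e.g.
#' `c(1, 2, 2, 3, 4)` folds the middle category of a five-point scale
#' into its lower neighbour. Not applied anywhere by default: the
#' protocol analyses the scale as administered and only reports when a
#' category adds little information.
#'
#' @param m a [response_matrix()] or coercible object.
#' @param map integer vector of length `n_categories` giving the new
#'   code for each old external code; new codes must cover
#'   `1..max(map)` without gaps and be non-decreasing (order-preserving
#'   merges only).
#' @return A [response_matrix()] with `max(map)` categories.
#' @export
collapse_categories <- function(m, map) {
  m <- as_response_matrix(m)
  map <- as.integer(map)
  if (length(map) != m$n_categories) {
    abort(sprintf("`map` must have length %d", m$n_categories))
  }
  if (is.unsorted(map) || map[1L] != 1L || any(diff(map) > 1L)) {
    abort("`map` must be a non-decreasing sequence starting at 1 without gaps")
  }
  vals <- matrix(map[m$values], nrow(m$values), ncol(m$values))
  vals[m$missing_mask] <- NA_integer_
  response_matrix(vals, persons = m$persons, items = m$items,
                  n_categories = max(map))
}
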