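#' Mean-value benchmarking index
#'
#' Per-person raw mean of the index items on the original category
#' scale, plus the 0-100 rescaling `(mean - 1) / (K - 1) * 100` used
#' for benchmarking displays. Persons with missing responses on any
#' index item are excluded with a warning.
#'
#' @param m a [response_matrix()] or coercible object.
#' @param items character vector of index items (a subset of the
#'   matrix's items).
#' @return A tibble: `person`, `raw_mean`, `index` (0-100).
#' @export
mean_value_index <- function(m, items = NULL) {
  m <- as_response_matrix(m)
  items <- items %||% m$items
  miss <- setdiff(items, m$items)
  if (length(miss)) abort(sprintf("unknown index item '%s'", miss[1L]))
  v <- m$values[, items, drop = FALSE]
  complete <- rowSums(is.na(v)) == 0L
  if (any(!complete)) {
    warn(sprintf("%d person(s) with missing index-item responses excluded",
                 sum(!complete)))
  }
  raw_mean <- unname(rowMeans(v[complete, , drop = FALSE]))
  tibble(person = m$persons[complete],
         raw_mean = raw_mean,
         index = (raw_mean - 1) / (m$n_categories - 1) * 100)
}

#' Correlation between the mean-value index and the Rasch measure
#'
#' Pearson correlation of the 0-100 index with the Rasch person
#' measure. All-minimum (floor) response patterns are excluded by
#' default -- their measures are extrapolated, not estimated -- and
#' all-maximum (ceiling) patterns can optionally be excluded too.
#'
#' @param idx a tibble with columns `index`, `measure` and `raw_mean`
#'   (as built by [run_protocol()], or [mean_value_index()] joined
#'   with measures).
#' @param exclude_floor,exclude_ceiling drop all-minimum /
#'   all-maximum patterns before correlating.
#' @param n_categories number of categories (defines the ceiling mean).
#' @return A list: `r`, `p_value`, `n_used`, `n_excluded`.
#' @export
index_measure_correlation <- function(idx, exclude_floor = TRUE,
                                      exclude_ceiling = FALSE,
                                      n_categories = 5L) {
  keep <- rep(TRUE, nrow(idx))
  if (exclude_floor) keep <- keep & idx$raw_mean > 1
  if (exclude_ceiling) keep <- keep & idx$raw_mean < n_categories
  d <- idx[keep & !is.na(idx$measure), ]
  if (nrow(d) < 3L) abort("fewer than 3 persons after exclusions")
  if (var(d$index) < 1e-12 || var(d$measure) < 1e-12) {
    return(list(r = NA_real_, p_value = NA_real_, n_used = nrow(d),
                n_excluded = nrow(idx) - nrow(d),
                note = "zero variance after exclusion"))
  }
  ct <- stats::cor.test(d$index, d$measure)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_used = nrow(d), n_excluded = nrow(idx) - nrow(d))
}

#' Run the five-step Rasch validation protocol
#'
#' End-to-end orchestration: fit the rating-scale model, check
#' category functioning (step 1) and local independence (step 2a),
#' iteratively remove the single worst-misfitting item and refit until
#' every remaining item shows acceptable infit (step 2b), then screen
#' unidimensionality (step 2c), person fit (step 3), separation and
#' reliability (step 4) and DIF across background factors (step 5),
#' and finally correlate the mean-value benchmarking index with the
#' Rasch measure of the retained item set. The report is a pure
#' function of the data and configuration: re-running with identical
#' inputs reproduces it exactly.
#'
#' @param data responses: a [response_matrix()], wide data frame or
#'   matrix.
#' @param factors optional background-factor table for the DIF step.
#' @param cfg an [analysis_config()].
#' @param settings an [estimation_settings()].
#' @return An object of class `protocol_report`; see [tidy()] for the
#'   per-step verdict table and `print()` for the three-column
#'   summary.
#' @export
run_protocol <- function(data, factors = NULL, cfg = analysis_config(),
                         settings = estimation_settings()) {
  m <- as_response_matrix(data)
  fit0 <- fit_rsm(m, settings = settings)

  step1 <- category_diagnostics(fit0, cfg)
  step2a <- local_independence(fit0, cfg)

  # step 2b: drop the single worst infit item per pass and refit
  removed <- tibble(order = integer(), item = character(),
                    infit_mnsq = numeric())
  fit <- fit0
  current <- m$items
  repeat {
    ft <- classify_item_fit(item_fit(fit), cfg)
    bad <- dplyr::filter(ft, .data$verdict == "misfit")
    if (nrow(bad) == 0L) break
    worst <- bad[which.max(abs(bad$infit_mnsq - 1)), ]
    current <- setdiff(current, worst$item)
    if (length(current) < 2L) {
      abort(sprintf(paste0("fewer than 2 items would remain after removing ",
                           "'%s'; the scale cannot be salvaged under the ",
                           "current fit criteria"), worst$item))
    }
    removed <- dplyr::bind_rows(removed,
      tibble(order = nrow(removed) + 1L, item = worst$item,
             infit_mnsq = worst$infit_mnsq))
    fit <- fit_rsm(m, settings = settings, items = current)
  }
  step2b <- list(initial_fit_table = classify_item_fit(item_fit(fit0), cfg),
                 final_fit_table = classify_item_fit(item_fit(fit), cfg),
                 removed = removed,
                 pass = TRUE)

  step2c <- pca_of_residuals(fit, cfg)
  pf <- person_fit(fit)
  step3 <- flag_rate(pf, cfg)
  step4 <- reliability(fit, cfg)
  step5 <- if (!is.null(factors)) dif_scan(fit, factors, cfg) else NULL
  step5_pass <- if (is.null(step5)) NA else !any(step5$flagged, na.rm = TRUE)

  index_items <- cfg$index_items %||%
    head(current, min(cfg$index_n_items, length(current)))
  idx <- mean_value_index(m, index_items)
  # internal 0-based raw scores on the retained item set
  raw <- rowSums(m$values[, current, drop = FALSE]) - length(current)
  lookup <- score_to_measure(sort(unique(raw)), fit, items = current)
  idx$measure <- lookup$measure[match(raw[match(idx$person, m$persons)],
                                      lookup$raw_score)]
  corr <- index_measure_correlation(idx, n_categories = m$n_categories)

  structure(list(
    steps = list(step1 = step1, step2a = step2a, step2b = step2b,
                 step2c = step2c, step3 = step3, step4 = step4,
                 step5 = step5),
    step5_pass = step5_pass,
    removed_items = removed,
    final_items = current,
    index_items = index_items,
    index = idx,
    index_measure_r = corr,
    initial_fit = fit0,
    final_fit = fit,
    config = cfg,
    seed = cfg$random_seed),
    class = "protocol_report")
}

#' @rdname run_protocol
#' @param x a `protocol_report`.
#' @param ... unused.
#' @export
tidy.protocol_report <- function(x, ...) {
  s <- x$steps
  tibble(
    step = c("1", "2a", "2b", "2c", "3", "4", "5", "index"),
    property = c("rating scale functioning", "local independence",
                 "item goodness-of-fit", "unidimensionality",
                 "person goodness-of-fit", "separation & reliability",
                 "differential item functioning",
                 "index-measure correlation"),
    criterion = c(
      sprintf("monotonic average measures; category outfit < %.1f",
              x$config$category_outfit_max),
      sprintf("max residual |r| < %.2f", x$config$residual_corr_max),
      sprintf("item infit in [%.1f, %.1f] after removals",
              x$config$item_infit_lo, x$config$item_infit_hi),
      sprintf("variance explained >= %.0f%%; first contrast < %.1f",
              x$config$variance_explained_min,
              x$config$first_contrast_eigen_max),
      sprintf("flagged persons <= %.0f%%",
              100 * x$config$person_misfit_budget),
      sprintf("separation >= %.1f; reliability >= %.1f",
              x$config$separation_min, x$config$reliability_min),
      sprintf("no Bonferroni-adjusted Mantel p < %.2f", x$config$dif_alpha),
      "reported"),
    observed = c(
      sprintf("monotonic: %s; max category outfit %.2f", s$step1$monotonic,
              max(s$step1$categories$outfit_mnsq, na.rm = TRUE)),
      sprintf("max |r| = %.2f (%s ~ %s)", s$step2a$max_abs_corr,
              s$step2a$max_pair$item_a, s$step2a$max_pair$item_b),
      if (nrow(x$removed_items)) {
        sprintf("removed %s; %d items retained",
                paste(x$removed_items$item, collapse = ", "),
                length(x$final_items))
      } else "no removals",
      sprintf("%.1f%% explained; first contrast %.2f",
              s$step2c$variance_explained_pct,
              s$step2c$first_contrast_eigenvalue),
      sprintf("%d/%d flagged (%.1f%%)", s$step3$n_flagged,
              s$step3$n_assessable, 100 * s$step3$flag_rate),
      sprintf("G = %.2f, R = %.2f; floor %.1f%%, ceiling %.1f%%",
              s$step4$separation, s$step4$reliability,
              s$step4$floor_pct, s$step4$ceiling_pct),
      if (is.null(s$step5)) "no factor table supplied" else
        sprintf("%d/%d comparisons flagged", sum(s$step5$flagged),
                nrow(s$step5)),
      sprintf("r = %.3f (n = %d)", x$index_measure_r$r,
              x$index_measure_r$n_used)),
    pass = c(s$step1$pass, s$step2a$pass, s$step2b$pass, s$step2c$pass,
             s$step3$pass, s$step4$pass, x$step5_pass, NA))
}

#' @export
print.protocol_report <- function(x, ...) {
  cat(sprintf("<protocol_report> %d -> %d items; index on %d items\n",
              length(x$initial_fit$delta), length(x$final_items),
              length(x$index_items)))
  df <- as.data.frame(tidy(x))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("step %-3s %-28s\n  criterion: %s\n  observed:  %s\n  pass: %s\n",
                df$step[i], df$property[i], df$criterion[i], df$observed[i],
                df$pass[i]))
  }
  invisible(x)
}

#' @rdname run_protocol
#' @export
glance.protocol_report <- function(x, ...) {
  s <- x$steps
  tibble(n_items_initial = length(x$initial_fit$delta),
         n_items_final = length(x$final_items),
         n_removed = nrow(x$removed_items),
         variance_explained_pct = s$step2c$variance_explained_pct,
         first_contrast_eigenvalue = s$step2c$first_contrast_eigenvalue,
         max_residual_corr = s$step2a$max_abs_corr,
         person_flag_rate = s$step3$flag_rate,
         separation = s$step4$separation,
         reliability = s$step4$reliability,
         cronbach_alpha = s$step4$cronbach_alpha,
         floor_pct = s$step4$floor_pct,
         ceiling_pct = s$step4$ceiling_pct,
         index_measure_r = x$index_measure_r$r,
         all_pass = all(c(s$step1$pass, s$step2a$pass, s$step2c$pass,
                          s$step3$pass, s$step4$pass,
                          if (!is.na(x$step5_pass)) x$step5_pass)))
}

#' @rdname run_protocol
#' @param object a `protocol_report`.
#' @export
autoplot.protocol_report <- function(object, ...) {
  ggplot2::ggplot(object$index,
                  ggplot2::aes(.data$measure, .data$index)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(
      x = sprintf("Rasch measure, %d-item scale (logits)",
                  length(object$final_items)),
      y = "mean-value index (0-100)",
      title = sprintf("index vs measure, r = %.3f",
                      object$index_measure_r$r)) +
    ggplot2::theme_minimal()
}

#' Serialize a protocol report to JSON
#'
#' @param report a [run_protocol()] result.
#' @param path output path; `NULL` returns the JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "protocol_report"))
  payload <- list(
    verdicts = tidy(report),
    summary = glance(report),
    removed_items = report$removed_items,
    final_items = report$final_items,
    index_items = report$index_items,
    index_measure = report$index_measure_r,
    dif = report$steps$step5,
    config = unclass(report$config)[!vapply(unclass(report$config),
                                            is.null, TRUE)],
    seed = report$seed)
  if (is.null(path)) {
    jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                     digits = NA, na = "null")
  } else {
    jsonlite::write_json(payload, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
  }
}
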