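#' Person separation, reliability, and floor/ceiling effects
#'
#' Step 4 of the protocol. Person reliability is the Rasch analogue of
#' internal-consistency coefficients:
#' `R = (observed measure variance - mean squared SE) / observed
#' variance`, clipped at zero. The separation index is
#' `G = sqrt(R / (1 - R))` and the number of statistically distinct
#' strata `H = (4G + 1) / 3`; `G >= 2` corresponds to at least three
#' distinguishable levels of the trait. Both are computed over
#' non-extreme persons (extreme measures are extrapolations), while
#' floor and ceiling counts scan all raw response patterns. A raw-score
#' Cronbach alpha is reported alongside for reference.
#'
#' @param fit an [fit_rsm()] result.
#' @param cfg an [analysis_config()].
#' @return A list of class `reliability_result`: `observed_variance`,
#'   `mean_se2`, `reliability`, `separation`, `strata`,
#'   `cronbach_alpha`, `floor_count`, `ceiling_count`, `floor_pct`,
#'   `ceiling_pct`, `targeting_offset`, `pass_separation`,
#'   `pass_reliability`, `pass`.
#' @export
reliability <- function(fit, cfg = analysis_config()) {
  ok <- !fit$extreme_persons
  if (sum(ok) < 2L) abort("need at least 2 non-extreme persons")
  th <- fit$theta[ok]
  obs_var <- var(th)
  mean_se2 <- mean(fit$se_theta[ok]^2)
  if (obs_var < 1e-12) {
    rel <- NA_real_; sep <- NA_real_; strata <- NA_real_
  } else {
    rel <- max(0, (obs_var - mean_se2) / obs_var)
    sep <- sqrt(rel / (1 - rel))
    strata <- (4 * sep + 1) / 3
  }
  m <- fit$data
  n <- nrow(m$values)
  row_obs <- !m$missing_mask
  floor_n <- sum(rowSums(row_obs) > 0 &
                   rowSums((m$values == 1L) | !row_obs) == ncol(m$values))
  ceil_n <- sum(rowSums(row_obs) > 0 &
                  rowSums((m$values == m$n_categories) | !row_obs) ==
                    ncol(m$values))
  offset <- mean(th) - mean(fit$delta[!fit$extreme_items])
  structure(list(
    observed_variance = obs_var, mean_se2 = mean_se2,
    reliability = rel, separation = sep, strata = strata,
    cronbach_alpha = cronbach_alpha(m),
    floor_count = floor_n, ceiling_count = ceil_n,
    floor_pct = 100 * floor_n / n, ceiling_pct = 100 * ceil_n / n,
    targeting_offset = offset,
    n_persons = n, n_used = sum(ok),
    pass_separation = !is.na(sep) && sep >= cfg$separation_min,
    pass_reliability = !is.na(rel) && rel >= cfg$reliability_min,
    pass = !is.na(sep) && sep >= cfg$separation_min &&
      rel >= cfg$reliability_min,
    note = if (is.na(rel)) "zero observed person-measure variance" else NULL),
    class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(paste0("<reliability_result> R = %.3f, G = %.2f, ",
                     "strata = %.2f, alpha = %.3f\n",
                     "  floor %d (%.1f%%), ceiling %d (%.1f%%), ",
                     "targeting offset %+.2f logits, pass: %s\n"),
              x$reliability, x$separation, x$strata, x$cronbach_alpha,
              x$floor_count, x$floor_pct, x$ceiling_count, x$ceiling_pct,
              x$targeting_offset, x$pass))
  invisible(x)
}

# classical raw-score internal consistency over complete rows
cronbach_alpha <- function(m) {
  m <- as_response_matrix(m)
  rows <- rowSums(m$missing_mask) == 0L
  v <- m$values[rows, , drop = FALSE]
  if (nrow(v) < 3L) return(NA_real_)
  l <- ncol(v)
  tot_var <- var(rowSums(v))
  if (tot_var < 1e-12) return(NA_real_)
  (l / (l - 1)) * (1 - sum(apply(v, 2L, var)) / tot_var)
}

#' Wright map: joint person-item targeting summary
#'
#' Bins person measures and item difficulties on a common logit axis.
#' The targeting offset (mean person measure minus mean item
#' difficulty) summarizes how well the items are aimed at the sample;
#' large positive offsets indicate an easy, ceiling-prone instrument.
#'
#' @param fit an [fit_rsm()] result.
#' @param bin_width bin width in logits.
#' @return A list of class `wright_map`: `bins` (tibble with `bin_mid`,
#'   `n_persons`, `items` label), `targeting_offset`, plus the raw
#'   measures. Print renders the classic monospaced two-column map.
#' @export
wright_map <- function(fit, bin_width = 0.5) {
  th <- fit$theta
  de <- fit$delta
  rng <- range(c(th, de), finite = TRUE)
  breaks <- seq(floor(rng[1L] / bin_width) * bin_width,
                ceiling(rng[2L] / bin_width) * bin_width + bin_width,
                by = bin_width)
  pb <- findInterval(th, breaks, rightmost.closed = TRUE)
  ib <- findInterval(de, breaks, rightmost.closed = TRUE)
  bins <- tibble(
    bin_lo = breaks[-length(breaks)],
    bin_mid = breaks[-length(breaks)] + bin_width / 2,
    n_persons = vapply(seq_len(length(breaks) - 1L),
                       function(b) sum(pb == b, na.rm = TRUE), 0L),
    items = vapply(seq_len(length(breaks) - 1L), function(b) {
      paste(names(de)[which(ib == b)], collapse = " ")
    }, ""))
  structure(list(bins = bins,
                 targeting_offset = mean(th[!fit$extreme_persons]) -
                   mean(de[!fit$extreme_items]),
                 person_measures = th, item_difficulties = de),
            class = "wright_map")
}

#' @export
print.wright_map <- function(x, max_hash = 40L, ...) {
  b <- x$bins[rev(seq_len(nrow(x$bins))), ]
  scale <- max(1, ceiling(max(b$n_persons) / max_hash))
  cat(sprintf("persons (one '#' = %d) | logits | items\n", scale))
  for (i in seq_len(nrow(b))) {
    cat(sprintf("%40s |%+6.2f | %s\n",
                paste(rep("#", ceiling(b$n_persons[i] / scale)),
                      collapse = ""),
                b$bin_mid[i], b$items[i]))
  }
  cat(sprintf("targeting offset (persons - items): %+.2f logits\n",
              x$targeting_offset))
  invisible(x)
}

#' @rdname wright_map
#' @param object a `wright_map`.
#' @param ... unused.
#' @export
autoplot.wright_map <- function(object, ...) {
  pd <- tibble(measure = object$person_measures)
  id <- tibble(difficulty = object$item_difficulties,
               item = names(object$item_difficulties))
  ggplot2::ggplot(pd, ggplot2::aes(.data$measure)) +
    ggplot2::geom_histogram(binwidth = 0.25, fill = "grey70") +
    ggplot2::geom_vline(data = id,
                        ggplot2::aes(xintercept = .data$difficulty),
                        colour = "firebrick") +
    ggplot2::geom_text(data = id, y = Inf, vjust = 1.2, angle = 90,
                       ggplot2::aes(x = .data$difficulty,
                                    label = .data$item),
                       colour = "firebrick", size = 3) +
    ggplot2::labs(x = "logits (persons as bars, items as lines)",
                  y = "persons") +
    ggplot2::theme_minimal()
}
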