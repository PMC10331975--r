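#' Mantel chi-square test for polytomous DIF (two groups)
#'
#' Stratified location test for ordinal item scores: within each
#' stratum (normally a raw-score band, so that respondents are matched
#' on the latent trait) the focal group's observed score sum `O_s` is
#' compared with its conditional hypergeometric expectation `E_s` and
#' variance `V_s`; the statistic `(sum O - sum E)^2 / sum V` is
#' referred to a chi-square distribution with 1 df. Category codes
#' enter as integer scores.
#'
#' @param scores integer vector of item responses.
#' @param group factor (or vector) with exactly two levels; the first
#'   level is treated as the focal group.
#' @param strata stratum labels (any vector).
#' @return A list: `chi_square`, `p_value`, `direction` (the group
#'   label that finds the item harder to endorse, `NA` when the
#'   statistic is 0), `sum_o_minus_e`, `n_strata_used`.
#' @export
mantel_polytomous <- function(scores, group, strata) {
  keep <- !is.na(scores) & !is.na(group) & !is.na(strata)
  scores <- as.numeric(scores[keep])
  group <- droplevels(as.factor(group[keep]))
  strata <- as.factor(as.character(strata[keep]))
  if (nlevels(group) > 2L) abort("`group` must have exactly two levels")
  if (nlevels(group) < 2L) {
    warn("only one group present; Mantel statistic undefined")
    return(list(chi_square = NA_real_, p_value = NA_real_,
                direction = NA_character_, sum_o_minus_e = NA_real_,
                n_strata_used = 0L))
  }
  focal <- levels(group)[1L]
  used <- 0L
  sum_oe <- 0; sum_v <- 0
  for (s in levels(strata)) {
    in_s <- strata == s
    y <- scores[in_s]
    g <- group[in_s]
    n_s <- length(y)
    n_f <- sum(g == focal)
    if (n_f == 0L || n_f == n_s || n_s < 2L) next  # one group only
    used <- used + 1L
    o_s <- sum(y[g == focal])
    e_s <- n_f * mean(y)
    v_s <- n_f * (n_s - n_f) / (n_s^2 * (n_s - 1)) *
      (n_s * sum(y^2) - sum(y)^2)
    sum_oe <- sum_oe + (o_s - e_s)
    sum_v <- sum_v + v_s
  }
  if (used == 0L) {
    warn("all strata contained a single group; Mantel statistic undefined")
    return(list(chi_square = NA_real_, p_value = NA_real_,
                direction = NA_character_, sum_o_minus_e = NA_real_,
                n_strata_used = 0L))
  }
  chi2 <- if (sum_v > 0) sum_oe^2 / sum_v else 0
  direction <- if (abs(sum_oe) < .Machine$double.eps^0.5) NA_character_
    else if (sum_oe < 0) focal else setdiff(levels(group), focal)
  list(chi_square = chi2,
       p_value = pchisq(chi2, df = 1L, lower.tail = FALSE),
       direction = direction,
       sum_o_minus_e = sum_oe,
       n_strata_used = used)
}

# greedy merge of adjacent raw-score values into bands of >= band_min
score_bands <- function(raw, band_min = 10L) {
  tab <- table(raw)
  vals <- as.numeric(names(tab))
  band <- integer(length(vals))
  b <- 1L; acc <- 0L
  for (i in seq_along(vals)) {
    band[i] <- b
    acc <- acc + tab[i]
    if (acc >= band_min && i < length(vals)) { b <- b + 1L; acc <- 0L }
  }
  if (acc < band_min && b > 1L) band[band == b] <- b - 1L
  band[match(raw, vals)]
}

#' Scan all items and background factors for DIF
#'
#' Runs [mantel_polytomous()] for every item x factor x group-pair
#' combination, stratifying respondents by bands of the total raw
#' score on the analysed item set (adjacent scores merged until every
#' band holds at least `band_min` respondents). Within each factor the
#' Bonferroni family is items x group-pairs; an adjusted p-value below
#' `dif_alpha` flags the item.
#'
#' @param fit an [fit_rsm()] result (defines the item set and data).
#' @param factors background-factor table (see [factor_table()]);
#'   persons missing from it, or with `NA` on a factor, are excluded
#'   from that factor's scan only.
#' @param cfg an [analysis_config()].
#' @param factor_cols which columns of `factors` to scan (default: all
#'   categorical columns except the person identifier; the raw eNPS
#'   score enters through its class).
#' @param band_min minimum respondents per raw-score band.
#' @param min_group_size factor levels with fewer respondents are
#'   dropped from the scan with a warning.
#' @return A tibble of class `dif_result`: `item`, `factor`,
#'   `group_a`, `group_b` (focal), `n_strata`, `chi_square`, `p_raw`,
#'   `p_adj`, `direction`, `flagged`.
#' @export
dif_scan <- function(fit, factors, cfg = analysis_config(),
                     factor_cols = NULL, band_min = 10L,
                     min_group_size = 10L) {
  m <- fit$data
  factors <- factor_table(factors, m)
  factor_cols <- factor_cols %||%
    setdiff(names(factors)[vapply(factors, function(c)
      is.factor(c) || is.character(c), TRUE)], "person")
  idx <- match(factors$person, m$persons)
  raw <- rowSums(m$values, na.rm = TRUE)[idx]

  out <- purrr::map_dfr(factor_cols, function(fc) {
    lev_all <- as.factor(factors[[fc]])
    tab <- table(lev_all)
    small <- names(tab)[tab < min_group_size]
    if (length(small)) {
      warn(sprintf("factor '%s': dropping level(s) %s with < %d respondents",
                   fc, paste(small, collapse = ", "), min_group_size))
    }
    levs <- names(tab)[tab >= min_group_size]
    if (length(levs) < 2L) return(tibble())
    pairs <- utils::combn(levs, 2L, simplify = FALSE)
    fam <- purrr::map_dfr(pairs, function(pr) {
      in_pair <- !is.na(lev_all) & lev_all %in% pr
      strata <- score_bands(raw[in_pair], band_min = band_min)
      purrr::map_dfr(m$items, function(it) {
        sc <- m$values[idx[in_pair], it]
        res <- mantel_polytomous(sc, factor(lev_all[in_pair], levels = pr),
                                 strata)
        tibble(item = it, factor = fc,
               group_a = pr[1L], group_b = pr[2L],
               n_strata = res$n_strata_used,
               chi_square = res$chi_square, p_raw = res$p_value,
               direction = res$direction)
      })
    })
    n_comp <- nrow(fam)
    dplyr::mutate(fam, p_adj = pmin(1, .data$p_raw * n_comp))
  })
  out <- dplyr::mutate(out,
                       flagged = !is.na(.data$p_adj) &
                         .data$p_adj < cfg$dif_alpha)
  class(out) <- c("dif_result", class(out))
  out
}
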