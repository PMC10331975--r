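#' Local independence screen via residual correlations
#'
#' Step 2a: after conditioning on the Rasch measure, item responses
#' should be uncorrelated. This computes pairwise Pearson correlations
#' between the items' standardized-residual columns (pairwise-complete
#' over non-extreme persons) and passes when the largest absolute
#' off-diagonal coefficient stays below `residual_corr_max` (default
#' 0.7, i.e. shared residual variance below 50%).
#'
#' @param fit an [fit_rsm()] result.
#' @param cfg an [analysis_config()].
#' @return A list of class `local_independence`: `correlations`
#'   (L x L matrix), `pairs` (tibble of item pairs sorted by |r|),
#'   `max_pair`, `max_abs_corr`, `pass`.
#' @export
local_independence <- function(fit, cfg = analysis_config()) {
  z <- residual_z_core(fit)
  if (nrow(z) < 3L) abort("need at least 3 non-extreme persons")
  const <- apply(z, 2L, function(col) {
    v <- var(col, na.rm = TRUE)
    !is.na(v) && v < 1e-12
  })
  if (any(const)) {
    warn(sprintf("constant residual column for item %s; correlations undefined",
                 paste(colnames(z)[const], collapse = ", ")))
  }
  rr <- suppressWarnings(cor(z, use = "pairwise.complete.obs"))
  diag(rr) <- 1
  ut <- which(upper.tri(rr), arr.ind = TRUE)
  pairs <- tibble(item_a = colnames(z)[ut[, 1L]],
                  item_b = colnames(z)[ut[, 2L]],
                  r = rr[ut]) |>
    dplyr::arrange(dplyr::desc(abs(.data$r)))
  max_abs <- suppressWarnings(max(abs(pairs$r), na.rm = TRUE))
  structure(list(correlations = rr,
                 pairs = pairs,
                 max_pair = pairs[1L, ],
                 max_abs_corr = max_abs,
                 pass = is.finite(max_abs) && max_abs < cfg$residual_corr_max),
            class = "local_independence")
}

#' @export
print.local_independence <- function(x, ...) {
  cat(sprintf("<local_independence> max |r| = %.3f (%s ~ %s), pass: %s\n",
              x$max_abs_corr, x$max_pair$item_a, x$max_pair$item_b, x$pass))
  invisible(x)
}

# standardized residual matrix over the non-extreme core; NA elsewhere
residual_z_core <- function(fit) {
  rf <- residual_field(fit)
  z <- rf$z
  z[!rf$core] <- NA
  z <- z[!fit$extreme_persons, !fit$extreme_items, drop = FALSE]
  colnames(z) <- fit$data$items[!fit$extreme_items]
  z
}

#' Unidimensionality check: PCA of standardized residuals
#'
#' Step 2c. Two quantities are monitored. The percentage of
#' observation variance explained by the Rasch measures decomposes the
#' variance of the observations into variance of the model
#' expectations plus residual variance:
#' `100 * sum_i Var_n(E_ni) / (sum_i Var_n(E_ni) + sum_i Var_n(e_ni))`.
#' The first-contrast eigenvalue is the largest eigenvalue of the
#' L x L correlation matrix of standardized residuals; because the
#' eigenvalues of a correlation matrix sum to L, a value of 2.0 means
#' "two items' worth" of residual covariation and signals a secondary
#' dimension. The check passes when the explained variance reaches
#' `variance_explained_min` and the first contrast stays below
#' `first_contrast_eigen_max`.
#'
#' @param fit an [fit_rsm()] result.
#' @param cfg an [analysis_config()].
#' @return A list of class `structure_result`: `variance_explained_pct`,
#'   `first_contrast_eigenvalue`, `eigenvalues`, `contrast_loadings`
#'   (first eigenvector, named by item), `residual_correlations`,
#'   `pass_variance`, `pass_contrast`, `pass`.
#' @export
pca_of_residuals <- function(fit, cfg = analysis_config()) {
  rf <- residual_field(fit)
  ee <- rf$E; ee[!rf$core] <- NA
  res <- rf$e; res[!rf$core] <- NA
  ee <- ee[!fit$extreme_persons, !fit$extreme_items, drop = FALSE]
  res <- res[!fit$extreme_persons, !fit$extreme_items, drop = FALSE]
  var_model <- sum(apply(ee, 2L, var, na.rm = TRUE))
  var_resid <- sum(apply(res, 2L, var, na.rm = TRUE))
  ve <- 100 * var_model / (var_model + var_resid)

  z <- residual_z_core(fit)
  rr <- suppressWarnings(cor(z, use = "pairwise.complete.obs"))
  diag(rr) <- 1
  bad <- apply(rr, 1L, function(row) any(!is.finite(row)))
  if (any(bad)) {
    warn(sprintf("dropping item %s from the residual PCA (undefined correlations)",
                 paste(colnames(rr)[bad], collapse = ", ")))
    rr <- rr[!bad, !bad, drop = FALSE]
  }
  dec <- eigen(rr, symmetric = TRUE)
  first <- dec$values[1L]
  loadings <- setNames(dec$vectors[, 1L], colnames(rr))
  structure(list(variance_explained_pct = ve,
                 first_contrast_eigenvalue = first,
                 eigenvalues = dec$values,
                 contrast_loadings = loadings,
                 residual_correlations = rr,
                 pass_variance = ve >= cfg$variance_explained_min,
                 pass_contrast = first < cfg$first_contrast_eigen_max,
                 pass = ve >= cfg$variance_explained_min &&
                   first < cfg$first_contrast_eigen_max),
            class = "structure_result")
}

#' @export
print.structure_result <- function(x, ...) {
  cat(sprintf(paste0("<structure_result> variance explained %.1f%% ",
                     "(pass: %s), first contrast eigenvalue %.2f ",
                     "(pass: %s)\n"),
              x$variance_explained_pct, x$pass_variance,
              x$first_contrast_eigenvalue, x$pass_contrast))
  invisible(x)
}
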