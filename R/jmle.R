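#' Estimation settings for the JMLE engine
#'
#' @param max_iterations maximum number of alternating update cycles.
#' @param convergence_tol convergence is declared when the largest
#'   absolute parameter change in a cycle falls below this (logits).
#' @param extreme_adjust fractional-score correction applied to minimum
#'   and maximum raw scores when assigning measures to extreme persons
#'   or items (score points; must lie in (0, 0.5)).
#' @param step_cap largest Newton step accepted per cycle (logits).
#' @return A list with class `estimation_settings`.
#' @export
estimation_settings <- function(max_iterations = 200L,
                                convergence_tol = 1e-4,
                                extreme_adjust = 0.3,
                                step_cap = 1.0) {
  if (convergence_tol <= 0) abort("`convergence_tol` must be positive")
  if (extreme_adjust <= 0 || extreme_adjust >= 0.5) {
    abort("`extreme_adjust` must lie strictly between 0 and 0.5")
  }
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 extreme_adjust = extreme_adjust,
                 step_cap = step_cap),
            class = "estimation_settings")
}

# N x L matrix of per-cell log-likelihood contributions (NA -> 0).
ll_cells <- function(x, eta, tau) {
  kk <- length(tau)
  psi <- c(0, cumsum(tau))
  logn <- lapply(0:kk, function(k) k * eta - psi[k + 1L])
  mx <- Reduce(pmax, logn)
  logz <- mx + log(Reduce(`+`, lapply(logn, function(l) exp(l - mx))))
  ll <- x * eta - matrix(psi[x + 1L], nrow(eta), ncol(eta)) - logz
  ll[is.na(ll)] <- 0
  ll
}

#' Fit the rating-scale Rasch model by joint maximum likelihood
#'
#' Alternating Newton-Raphson updates of person measures, item
#' difficulties and the shared category thresholds, in the tradition of
#' the Winsteps-family estimators. Each block update is damped so the
#' joint log-likelihood never decreases; cycles stop when the largest
#' absolute parameter change drops below `convergence_tol`.
#'
#' Identification uses the conventional double constraint: item
#' difficulties average zero over non-extreme items and the thresholds
#' sum to zero. Persons and items with minimum or maximum raw scores
#' carry no information about their own location; they are excluded
#' from estimation and assigned measures afterwards at raw score
#' plus/minus `extreme_adjust` score points.
#'
#' @param data a [response_matrix()], wide data frame, or matrix.
#' @param settings an [estimation_settings()] list.
#' @param items optional character vector restricting the fit to a
#'   subset of items (used by the iterative removal loop).
#' @param bias_correction if `TRUE`, apply the (L-1)/L shrinkage to the
#'   centered item difficulties to offset the well-known JMLE bias at
#'   small item counts. Off by default.
#' @return An object of class `rsm_fit` with person measures `theta`,
#'   item difficulties `delta`, thresholds `tau`, standard errors,
#'   extreme flags, the joint log-likelihood trajectory and convergence
#'   metadata. Explore with [tidy()], [glance()] and [autoplot()].
#' @examples
#' sim <- simulate_responses(simulation_config(n_persons = 80, n_items = 6,
#'                                             seed = 1))
#' fit <- fit_rsm(sim$responses)
#' glance(fit)
#' @export
fit_rsm <- function(data, settings = estimation_settings(), items = NULL,
                    bias_correction = FALSE) {
  m <- as_response_matrix(data)
  if (!is.null(items)) {
    miss <- setdiff(items, m$items)
    if (length(miss)) abort(sprintf("unknown item '%s'", miss[1L]))
    keep <- match(items, m$items)
    m <- response_matrix(m$values[, keep, drop = FALSE], persons = m$persons,
                         items = m$items[keep], n_categories = m$n_categories)
  }
  kk <- m$n_categories - 1L
  x <- m$values - 1L  # internal 0-based categories
  obs <- !m$missing_mask
  n <- nrow(x); l <- ncol(x)

  # iterate extreme-flagging to a fixed point
  x0 <- x; x0[!obs] <- 0L
  ext_p <- rep(FALSE, n); ext_i <- rep(FALSE, l)
  repeat {
    core_i <- !ext_i
    r <- (x0 %*% core_i)[, 1L]
    r_max <- kk * (obs %*% core_i)[, 1L]
    new_p <- r_max == 0 | r == 0 | r == r_max
    core_p <- !new_p
    s <- (core_p %*% x0)[1L, ]
    s_max <- kk * (core_p %*% obs)[1L, ]
    new_i <- s_max == 0 | s == 0 | s == s_max
    if (identical(new_p, ext_p) && identical(new_i, ext_i)) break
    ext_p <- new_p; ext_i <- new_i
  }
  if (sum(!ext_p) < 2L || sum(!ext_i) < 2L) {
    abort("need at least 2 non-extreme persons and 2 non-extreme items")
  }

  cp <- which(!ext_p); ci <- which(!ext_i)
  core_obs <- obs[cp, ci, drop = FALSE]
  missing_cats <- setdiff(0:kk, unique(x[cp, ci, drop = FALSE][core_obs]))
  if (length(missing_cats)) {
    abort(sprintf(paste0(
      "category with external code %s is never observed among non-extreme ",
      "responses; the shared thresholds are not estimable -- collapse ",
      "adjacent categories (see `collapse_categories()`) or recode the data"),
      missing_cats[1L] + 1L))
  }
  xc <- x[cp, ci, drop = FALSE]
  oc <- obs[cp, ci, drop = FALSE]
  xc[!oc] <- NA_integer_
  nc <- length(cp); lc <- length(ci)

  # PROX-style start values from logit-transformed raw score fractions
  rc <- rowSums(xc, na.rm = TRUE)
  rmaxc <- kk * rowSums(oc)
  theta <- log((rc + 0.5) / (rmaxc - rc + 0.5))
  sc <- colSums(xc, na.rm = TRUE)
  smaxc <- kk * colSums(oc)
  delta <- -log((sc + 0.5) / (smaxc - sc + 0.5))
  delta <- delta - mean(delta)
  tau <- rep(0, kk)
  cap <- settings$step_cap

  xge <- lapply(1:kk, function(j) {
    g <- (xc >= j); g[!oc] <- FALSE; g
  })
  g_obs <- vapply(xge, sum, 0)  # observed counts of X >= j

  eta <- outer(theta, delta, "-")
  ll_old <- sum(ll_cells(xc, eta, tau))
  trajectory <- ll_old
  converged <- FALSE
  iter <- 0L

  damped <- function(cur, cand, ll_ref, eval_ll) {
    # halve the proposed block step until the joint loglik does not drop
    for (h in 1:12) {
      llv <- eval_ll(cand)
      if (is.finite(llv) && llv >= ll_ref - 1e-10) return(list(par = cand, ll = llv))
      cand <- cur + (cand - cur) / 2
    }
    list(par = cur, ll = ll_ref)
  }

  while (iter < settings$max_iterations) {
    iter <- iter + 1L
    th0 <- theta; de0 <- delta; ta0 <- tau

    # --- persons ---
    eta <- outer(theta, delta, "-")
    fld <- rsm_field(eta, tau)
    ew <- fld$E; ew[!oc] <- 0
    ww <- fld$W; ww[!oc] <- 0
    step <- (rc - rowSums(ew)) / pmax(rowSums(ww), 1e-10)
    step <- pmin(pmax(step, -cap), cap)
    res <- damped(theta, theta + step, ll_old, function(th)
      sum(ll_cells(xc, outer(th, delta, "-"), tau)))
    theta <- res$par; ll_old <- res$ll

    # --- items ---
    eta <- outer(theta, delta, "-")
    fld <- rsm_field(eta, tau)
    ew <- fld$E; ew[!oc] <- 0
    ww <- fld$W; ww[!oc] <- 0
    step <- (colSums(ew) - sc) / pmax(colSums(ww), 1e-10)
    step <- pmin(pmax(step, -cap), cap)
    res <- damped(delta, delta + step, ll_old, function(de)
      sum(ll_cells(xc, outer(theta, de, "-"), tau)))
    delta <- res$par; ll_old <- res$ll
    cshift <- mean(delta)           # equivalence shift: likelihood preserved
    delta <- delta - cshift
    theta <- theta - cshift

    # --- thresholds: full Newton on the K-vector ---
    eta <- outer(theta, delta, "-")
    fld <- rsm_field(eta, tau, want = c("E", "W", "Pge"))
    pge <- lapply(fld$Pge, function(p) { p[!oc] <- 0; p })
    grad <- vapply(1:kk, function(j) sum(pge[[j]]) - g_obs[j], 0)
    hess <- matrix(0, kk, kk)
    for (j in 1:kk) for (h in j:kk) {
      v <- sum(pge[[j]] * pge[[h]]) - sum(pge[[max(j, h)]])
      hess[j, h] <- v; hess[h, j] <- v
    }
    step <- tryCatch(solve(hess, -grad), error = function(e) grad * 0)
    step <- pmin(pmax(step, -cap), cap)
    res <- damped(tau, tau + step, ll_old, function(ta)
      sum(ll_cells(xc, outer(theta, delta, "-"), ta)))
    tau <- res$par; ll_old <- res$ll
    tshift <- mean(tau)             # equivalence shift via theta
    tau <- tau - tshift
    theta <- theta - tshift

    trajectory <- c(trajectory, ll_old)
    delta_max <- max(abs(theta - th0), abs(delta - de0), abs(tau - ta0))
    if (delta_max < settings$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(sprintf(paste0("JMLE did not converge in %d cycles; final max ",
                         "change %.2e, loglik trajectory tail: %s"),
                  settings$max_iterations, delta_max,
                  paste(sprintf("%.4f", tail(trajectory, 4L)), collapse = " ")))
  }
  if (bias_correction) delta <- delta * (lc - 1) / lc

  eta <- outer(theta, delta, "-")
  fld <- rsm_field(eta, tau)
  ww <- fld$W; ww[!oc] <- 0
  se_theta_c <- 1 / sqrt(rowSums(ww))
  se_delta_c <- 1 / sqrt(colSums(ww))

  # assemble full-length vectors; extremes assigned via adjusted scores
  theta_all <- rep(NA_real_, n); se_theta_all <- rep(NA_real_, n)
  delta_all <- rep(NA_real_, l); se_delta_all <- rep(NA_real_, l)
  theta_all[cp] <- theta; se_theta_all[cp] <- se_theta_c
  delta_all[ci] <- delta; se_delta_all[ci] <- se_delta_c

  params <- list(theta = theta_all, delta = delta_all, tau = tau,
                 n_categories = m$n_categories)
  adj <- settings$extreme_adjust
  for (p in which(ext_p)) {
    it_obs <- m$items[obs[p, ] & !ext_i]
    if (!length(it_obs)) next
    rmax <- kk * length(it_obs)
    rp <- sum(x[p, obs[p, ] & !ext_i])
    radj <- if (rp <= 0) adj else if (rp >= rmax) rmax - adj else rp
    sm <- solve_measure(radj, delta_all[match(it_obs, m$items)], tau)
    theta_all[p] <- sm$measure; se_theta_all[p] <- sm$se
  }
  for (i in which(ext_i)) {
    # mirror adjustment for a degenerate item: pick delta matching the
    # adjusted mean observed score against the fitted person measures
    pn <- which(obs[, i] & !ext_p)
    if (length(pn) < 1L) next
    smax <- kk * length(pn)
    si <- sum(x[pn, i])
    sadj <- if (si <= 0) adj else if (si >= smax) smax - adj else si
    f <- function(d) sum(rsm_field(matrix(theta_all[pn] - d, ncol = 1), tau)$E) - sadj
    rt <- uniroot(f, c(-25, 25), extendInt = "yes", tol = 1e-8)
    delta_all[i] <- rt$root
    wsum <- sum(rsm_field(matrix(theta_all[pn] - rt$root, ncol = 1), tau)$W)
    se_delta_all[i] <- 1 / sqrt(wsum)
  }

  structure(
    list(theta = setNames(theta_all, m$persons),
         delta = setNames(delta_all, m$items),
         tau = tau,
         se_theta = setNames(se_theta_all, m$persons),
         se_delta = setNames(se_delta_all, m$items),
         extreme_persons = setNames(ext_p, m$persons),
         extreme_items = setNames(ext_i, m$items),
         loglik = ll_old,
         trajectory = trajectory,
         iterations = iter,
         converged = converged,
         settings = settings,
         data = m),
    class = "rsm_fit")
}

# root of sum_i E_i(theta) = target over given item difficulties
solve_measure <- function(target, delta, tau) {
  f <- function(th) sum(rsm_field(matrix(th - delta, nrow = 1), tau)$E) - target
  rt <- uniroot(f, c(-25, 25), extendInt = "yes", tol = 1e-9)
  wsum <- sum(rsm_field(matrix(rt$root - delta, nrow = 1), tau)$W)
  list(measure = rt$root, se = 1 / sqrt(wsum))
}

#' Convert a raw score to a Rasch measure
#'
#' With complete data the raw sum score is sufficient for the person
#' measure: this solves `sum_i E_i(theta) = raw_score` over the chosen
#' item subset by monotone root-finding. Extreme raw scores (0 or the
#' maximum) are moved inward by the `extreme_adjust` of the fit's
#' settings before solving.
#'
#' @param raw_score integer raw sum score (vectorized).
#' @param fit an [fit_rsm()] result.
#' @param items optional item-identifier subset (default: all items).
#' @return A tibble with `raw_score`, `measure` and `se` (logits).
#' @export
score_to_measure <- function(raw_score, fit, items = NULL) {
  stopifnot(inherits(fit, "rsm_fit"))
  items <- items %||% names(fit$delta)
  miss <- setdiff(items, names(fit$delta))
  if (length(miss)) abort(sprintf("unknown item '%s'", miss[1L]))
  delta <- fit$delta[items]
  kk <- length(fit$tau)
  rmax <- kk * length(delta)
  if (any(raw_score < 0 | raw_score > rmax)) {
    abort(sprintf("raw score outside 0..%d for this %d-item subset",
                  rmax, length(delta)))
  }
  adj <- fit$settings$extreme_adjust
  purrr::map_dfr(raw_score, function(r) {
    radj <- if (r <= 0) adj else if (r >= rmax) rmax - adj else r
    sm <- solve_measure(radj, delta, fit$tau)
    tibble(raw_score = r, measure = sm$measure, se = sm$se)
  })
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf(paste0("<rsm_fit> %d persons x %d items, %d categories\n",
                     "  loglik %.2f after %d cycles (converged: %s)\n",
                     "  extreme persons: %d, extreme items: %d\n"),
              length(x$theta), length(x$delta), x$data$n_categories,
              x$loglik, x$iterations, x$converged,
              sum(x$extreme_persons), sum(x$extreme_items)))
  cat("  thresholds:", sprintf("%.3f", x$tau), "\n")
  invisible(x)
}

#' @rdname fit_rsm
#' @param x an `rsm_fit`.
#' @param type which parameter table to return: `"items"`, `"persons"`
#'   or `"thresholds"`.
#' @param ... unused.
#' @export
tidy.rsm_fit <- function(x, type = c("items", "persons", "thresholds"), ...) {
  type <- match.arg(type)
  switch(type,
    items = tibble(item = names(x$delta), difficulty = unname(x$delta),
                   se = unname(x$se_delta),
                   extreme = unname(x$extreme_items)),
    persons = tibble(person = names(x$theta), measure = unname(x$theta),
                     se = unname(x$se_theta),
                     extreme = unname(x$extreme_persons)),
    thresholds = tibble(step = seq_along(x$tau), tau = x$tau))
}

#' @rdname fit_rsm
#' @export
glance.rsm_fit <- function(x, ...) {
  tibble(n_persons = length(x$theta), n_items = length(x$delta),
         n_categories = x$data$n_categories,
         n_extreme_persons = sum(x$extreme_persons),
         n_extreme_items = sum(x$extreme_items),
         loglik = x$loglik, iterations = x$iterations,
         converged = x$converged)
}

#' Serialize fitted parameters to JSON
#'
#' @param fit an [fit_rsm()] result.
#' @param path output path; if `NULL`, the JSON string is returned.
#' @export
rsm_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "rsm_fit"))
  payload <- list(
    persons = tidy(fit, "persons"), items = tidy(fit, "items"),
    thresholds = fit$tau, n_categories = fit$data$n_categories,
    loglik = fit$loglik, iterations = fit$iterations,
    converged = fit$converged)
  if (is.null(path)) {
    jsonlite::toJSON(payload, dataframe = "columns", auto_unbox = TRUE,
                     digits = NA)
  } else {
    jsonlite::write_json(payload, path, dataframe = "columns",
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
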