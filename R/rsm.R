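#' Rating-scale model category probabilities
#'
#' For the Andrich rating-scale model with person measure `theta`, item
#' difficulty `delta`, and shared step thresholds `tau` (length K), the
#' probability of responding in category k (internal coding 0..K) is
#' proportional to `exp(sum_{j<=k} (theta - delta - tau_j))`, with an
#' empty sum for k = 0. Adjacent-category curves cross exactly at
#' `theta - delta = tau_j` (the Andrich thresholds).
#'
#' @param theta person measure (logits).
#' @param delta item difficulty (logits).
#' @param tau numeric vector of K step thresholds (logits).
#' @return Probability vector over categories `0..K`, summing to 1.
#' @examples
#' rsm_category_probs(0, 0, c(0, 0, 0, 0))  # uniform over 5 categories
#' rsm_category_probs(log(2), 0, c(0, 0))   # (1, 2, 4)/7
#' @export
rsm_category_probs <- function(theta, delta, tau) {
  if (!all(is.finite(c(theta, delta, tau)))) {
    abort("`theta`, `delta` and `tau` must all be finite")
  }
  k <- length(tau)
  eta <- theta - delta
  lognum <- (0:k) * eta - c(0, cumsum(tau))
  p <- exp(lognum - max(lognum))
  p / sum(p)
}

#' Expected score, variance and fourth moment under the model
#'
#' Conditional moments of the category score for one person-item
#' encounter: the expected score E in `[0, K]`, the score variance W,
#' and the fourth central moment C used by the standardized fit
#' statistics.
#'
#' @inheritParams rsm_category_probs
#' @return Named numeric vector `c(E, W, C)`.
#' @examples
#' rsm_expected_moments(0, 0, c(0, 0, 0, 0))["E"]  # 2: symmetric scale
#' @export
rsm_expected_moments <- function(theta, delta, tau) {
  p <- rsm_category_probs(theta, delta, tau)
  k <- seq_along(p) - 1
  e <- sum(k * p)
  w <- sum((k - e)^2 * p)
  cc <- sum((k - e)^4 * p)
  c(E = e, W = w, C = cc)
}

# Vectorized model evaluation over an N x L grid of person-item
# encounters. eta is the N x L matrix theta - delta; tau has length K.
# Returns list of N x L matrices: E, W, and optionally C and the
# category probabilities (list of K+1 matrices) and P(X >= j) matrices.
# Workhorse for estimation and fit statistics; log-sum-exp guarded.
rsm_field <- function(eta, tau, want = c("E", "W")) {
  kk <- length(tau)
  psi <- c(0, cumsum(tau))
  logn <- vector("list", kk + 1L)
  mx <- NULL
  for (k in 0:kk) {
    logn[[k + 1L]] <- k * eta - psi[k + 1L]
    mx <- if (is.null(mx)) logn[[k + 1L]] else pmax(mx, logn[[k + 1L]])
  }
  denom <- 0
  p <- vector("list", kk + 1L)
  for (k in 0:kk) {
    p[[k + 1L]] <- exp(logn[[k + 1L]] - mx)
    denom <- denom + p[[k + 1L]]
  }
  e <- 0
  for (k in 0:kk) {
    p[[k + 1L]] <- p[[k + 1L]] / denom
    if (k > 0) e <- e + k * p[[k + 1L]]
  }
  m2 <- 0
  for (k in 0:kk) m2 <- m2 + (k - e)^2 * p[[k + 1L]]
  out <- list(E = e, W = m2)
  if ("C" %in% want) {
    m4 <- 0
    for (k in 0:kk) m4 <- m4 + (k - e)^4 * p[[k + 1L]]
    out$C <- m4
  }
  if ("P" %in% want) out$P <- p
  if ("Pge" %in% want) {
    pge <- vector("list", kk)  # P(X >= j), j = 1..K
    acc <- p[[kk + 1L]]
    for (j in kk:1) {
      pge[[j]] <- acc
      if (j > 1L) acc <- acc + p[[j]]
    }
    out$Pge <- pge
  }
  out
}

# Joint log-likelihood of responses x (0-based, NA allowed) under
# theta/delta/tau; obs is the non-missing mask.
rsm_loglik <- function(x, theta, delta, tau, obs = !is.na(x)) {
  eta <- outer(theta, delta, "-")
  kk <- length(tau)
  psi <- c(0, cumsum(tau))
  logn <- lapply(0:kk, function(k) k * eta - psi[k + 1L])
  mx <- Reduce(pmax, logn)
  logz <- mx + log(Reduce(`+`, lapply(logn, function(l) exp(l - mx))))
  ll <- x * eta - matrix(psi[x + 1L], nrow(eta), ncol(eta)) - logz
  sum(ll[obs])
}
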