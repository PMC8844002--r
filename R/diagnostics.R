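# MCMC convergence diagnostics: rank-normalised split R-hat and bulk
# effective sample size, following the now-standard definitions of
# Vehtari, Gelman, Simpson, Carpenter & Buerkner (2021).

# Split each chain into halves, giving a draws/2 x (2 * chains) matrix.
split_chains <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 draws per chain to split")
  h <- n %/% 2
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

# Map draws to normal scores via pooled average ranks.
rank_normalise <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  matrix(z, nrow = nrow(x), ncol = ncol(x))
}

# Classic potential scale reduction factor on an already-prepared matrix.
rhat_basic <- function(x) {
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B_over_n <- stats::var(colMeans(x))
  if (W < .Machine$double.eps) return(NA_real_)
  sqrt((n - 1) / n + B_over_n / W)
}

#' Rank-normalised split R-hat
#'
#' Maximum of the rank-normalised split potential-scale-reduction factor
#' computed on the draws and on their folded (median-absolute) transform, so
#' both location and scale disagreements between chains are detected. Values
#' near 1 indicate convergence; values above about 1.01 are suspect.
#' Constant draws return `NA` (no variation to compare).
#'
#' @param x A draws-by-chains numeric matrix (at least 2 chains, 4 draws).
#' @return A scalar R-hat estimate.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("R-hat needs at least 2 chains")
  if (diff(range(x)) < .Machine$double.eps) return(NA_real_)
  s <- split_chains(x)
  bulk <- rhat_basic(rank_normalise(s))
  folded <- rhat_basic(rank_normalise(abs(s - stats::median(s))))
  max(bulk, folded, na.rm = TRUE)
}

# Per-chain autocovariance (biased, lag 0..n-1) via FFT.
autocovariance <- function(v) {
  n <- length(v)
  a <- v - mean(v)
  L <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(a, numeric(L - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / L
  ac[seq_len(n)] / n
}

# Effective sample size of the mean on a prepared (split, possibly
# rank-normalised) draws matrix, via Geyer's initial monotone sequence.
ess_mean <- function(x) {
  n <- nrow(x); C <- ncol(x)
  acov <- apply(x, 2, autocovariance)
  chain_var <- acov[1, ] * n / (n - 1)
  W <- mean(chain_var)
  var_plus <- W * (n - 1) / n + (if (C > 1) stats::var(colMeans(x)) else 0)
  if (var_plus < .Machine$double.eps) return(NA_real_)

  mean_acov <- rowMeans(acov)
  rho <- numeric(n)
  rho[1] <- 1
  rho_even <- 1
  rho_odd <- 1 - (W - mean_acov[2]) / var_plus
  rho[2] <- rho_odd
  t <- 1
  while (t < n - 4 && (rho_even + rho_odd) > 0) {
    rho_even <- 1 - (W - mean_acov[t + 2]) / var_plus
    rho_odd <- 1 - (W - mean_acov[t + 3]) / var_plus
    if ((rho_even + rho_odd) >= 0) {
      rho[t + 2] <- rho_even
      rho[t + 3] <- rho_odd
    }
    t <- t + 2
  }
  max_t <- t
  # enforce monotone non-increasing pair sums (Geyer initial monotone seq.)
  t <- 3
  while (t <= max_t - 2) {
    if (rho[t + 1] + rho[t + 2] > rho[t - 1] + rho[t]) {
      rho[t + 1] <- (rho[t - 1] + rho[t]) / 2
      rho[t + 2] <- rho[t + 1]
    }
    t <- t + 2
  }
  tau <- -1 + 2 * sum(rho[seq_len(max_t)])
  # floor for antithetic chains, whose negative autocorrelation would
  # otherwise drive tau to zero or below; caps ESS at S * log10(S)
  tau <- max(tau, 1 / log10(C * n))
  C * n / tau
}

#' Bulk effective sample size
#'
#' Effective sample size of the rank-normalised split chains: the number of
#' independent draws that would estimate a central posterior quantity with
#' the same precision as these autocorrelated draws.
#'
#' @inheritParams split_rhat
#' @return A scalar effective sample size (`NA` for constant draws).
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  if (diff(range(x)) < .Machine$double.eps) return(NA_real_)
  ess_mean(rank_normalise(split_chains(x)))
}

#' Convergence diagnostics for every model parameter
#'
#' @param fit A [sample_posterior()] fit with at least 2 chains.
#' @return A data frame with columns `parameter`, `rhat` and `ess_bulk`.
#' @export
mcmc_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "shadepath_fit"))
  if (dim(fit$draws)[2] < 2)
    stop("R-hat is undefined for a single chain; run at least 2")
  out <- data.frame(parameter = fit$params,
                    rhat = NA_real_, ess_bulk = NA_real_)
  for (i in seq_along(fit$params)) {
    m <- fit$draws[, , i, drop = TRUE]
    out$rhat[i] <- split_rhat(m)
    out$ess_bulk[i] <- ess_bulk(m)
  }
  out
}
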