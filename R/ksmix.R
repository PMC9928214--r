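# Gaussian mixture modelling of Ks distributions by EM, with BIC model
# selection, to flag candidate genome duplication components.

## one EM run; returns list(weights, means, sigmas, loglik, trace) or NULL
## if the run degenerated
.emRun <- function(x, w, mu, sigma, tol, max_iter, sigma_floor) {
  n <- length(x)
  k <- length(w)
  ll_old <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      w[j] * stats::dnorm(x, mu[j], sigma[j])
    }, numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) / (abs(ll_old) + 1e-12) < tol) break
    ll_old <- ll
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * (outer(x, mu, `-`))^2) / nk)
    sigma <- pmax(sigma, sigma_floor)
  }
  list(weights = w, means = mu, sigmas = sigma,
       loglik = trace[length(trace)], trace = trace)
}

#' Fit a Gaussian mixture to a Ks distribution
#'
#' Filters the Ks values to the window `[ks_min, ks_max]` (excluding allelic
#' noise near 0 and the saturated tail), then fits univariate normal
#' mixtures with k = 1..`k_max` components by EM. Each k is fitted from
#' `n_starts` seeded starts with quantile-spread initialization (component
#' means at data quantiles, spread jittered across starts); a run converges
#' when the relative log-likelihood change drops below `tol` or after
#' `max_iter` iterations. The component count minimizing BIC is reported,
#' with components re-ordered by increasing mean, and components carrying at
#' least `weight_threshold` of the mixture weight flagged significant --
#' candidate large-scale duplication events.
#'
#' @param ks numeric vector of Ks values.
#' @param k_max maximum component count tried (default 4).
#' @param n_starts EM starts per k (default 5).
#' @param seed integer seed controlling the start jitter.
#' @param ks_min,ks_max inclusion window (defaults 0.02 and 4.0).
#' @param weight_threshold significance weight cutoff (default 0.05).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter EM iteration cap (default 1000).
#' @return a [KsMixture-class].
#' @export
fitKsMixture <- function(ks, k_max = 4L, n_starts = 5L, seed = 1L,
                         ks_min = 0.02, ks_max = 4.0,
                         weight_threshold = 0.05, tol = 1e-6,
                         max_iter = 1000L) {
  x <- ks[!is.na(ks) & ks >= ks_min & ks <= ks_max]
  if (length(x) < 20L) {
    .okitStop(sprintf(
      "need at least 20 Ks values in [%g, %g], have %d", ks_min, ks_max,
      length(x)))
  }
  if (stats::sd(x) == 0) {
    .okitStop("all Ks values identical: mixture variance degenerate")
  }
  n <- length(x)
  sigma_floor <- max(1e-4, stats::sd(x) * 1e-3)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  fits <- vector("list", k_max)
  bics <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    best <- NULL
    for (s in seq_len(n_starts)) {
      probs <- if (s == 1L) {
        (seq_len(k) - 0.5) / k
      } else {
        sort(stats::runif(k, 0.02, 0.98))
      }
      mu0 <- unname(stats::quantile(x, probs))
      sigma0 <- rep(max(stats::sd(x) / k, sigma_floor), k)
      fit <- .emRun(x, rep(1 / k, k), mu0, sigma0, tol, max_iter, sigma_floor)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
    if (is.null(best)) next
    fits[[k]] <- best
    bics[k] <- -2 * best$loglik + (3 * k - 1) * log(n)
  }
  if (all(is.na(bics))) .okitStop("mixture fitting failed for every k")
  k_sel <- which.min(bics)
  fit <- fits[[k_sel]]
  ord <- order(fit$means)
  new("KsMixture",
      k = as.integer(k_sel),
      weights = fit$weights[ord],
      means = fit$means[ord],
      sigmas = fit$sigmas[ord],
      loglik = fit$loglik,
      bic = bics[k_sel],
      bicByK = stats::setNames(bics, paste0("k", seq_len(k_max))),
      significant = fit$weights[ord] >= weight_threshold,
      n = as.integer(n),
      ksRange = c(ks_min, ks_max),
      loglikTrace = fit$trace)
}

setMethod("show", "KsMixture", function(object) {
  cat(sprintf("KsMixture: %d component(s), n = %d, logLik = %.2f, BIC = %.2f\n",
              object@k, object@n, object@loglik, object@bic))
  for (j in seq_len(object@k)) {
    cat(sprintf("  [%d] weight %.3f, mean %.4f, sigma %.4f%s\n", j,
                object@weights[j], object@means[j], object@sigmas[j],
                if (object@significant[j]) " *" else ""))
  }
})

#' Histogram and component-density overlay data for a Ks distribution
#'
#' Bins the (window-filtered) Ks values into `bins` equal-width bins and
#' evaluates each mixture component's weighted density at the bin midpoints,
#' scaled to count space (times n times bin width), so the component curves
#' sum exactly to the total mixture curve and the total curve integrates to
#' approximately n over the window.
#'
#' @param m a fitted [KsMixture-class].
#' @param ks the Ks values (the fit window of `m` is applied).
#' @param bins number of histogram bins (default 50).
#' @return data.frame with `bin_mid`, `count`, one `comp_<j>_density`
#'   column per component, and `total_density`.
#' @export
ksPlotData <- function(m, ks, bins = 50L) {
  if (bins < 1L) .okitStop("bins must be >= 1")
  x <- ks[!is.na(ks) & ks >= m@ksRange[1L] & ks <= m@ksRange[2L]]
  if (!length(x)) .okitStop("no Ks values inside the fitted window")
  breaks <- seq(min(x), max(x), length.out = bins + 1L)
  if (breaks[1L] == breaks[length(breaks)]) {
    breaks <- breaks[1L] + c(-0.5, 0.5)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  width <- diff(h$breaks)[1L]
  out <- data.frame(bin_mid = h$mids, count = h$counts)
  total <- rep(0, length(h$mids))
  for (j in seq_len(m@k)) {
    dj <- m@weights[j] * stats::dnorm(h$mids, m@means[j], m@sigmas[j]) *
      length(x) * width
    out[[sprintf("comp_%d_density", j)]] <- dj
    total <- total + dj
  }
  out$total_density <- total
  out
}
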