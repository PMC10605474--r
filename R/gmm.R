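# Univariate Gaussian mixture fitting by EM, with the BIC + minimum-weight
# model-selection rule used to decide between one and two alleles.

#' Tuning parameters of the sizing pipeline
#'
#' All unstated knobs of the algorithm are pinned here so that a run is a
#' pure function of (data, config).
#'
#' @param min_samples DBSCAN minPts, shared with the k of the k-distance
#'   curve (default 5).
#' @param knee_sensitivity Kneedle sensitivity S (default 1).
#' @param weight_threshold Minimum mixture weight each component of the
#'   two-component model must exceed (strictly) to be accepted; default
#'   0.25, must lie in (0, 0.5).
#' @param n_restarts EM restarts per fit (default 10): restart 1 is a
#'   deterministic equal-count split of the sorted data, the rest start
#'   from random responsibilities.
#' @param em_tol Relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param variance_floor_frac Component variances are floored at this
#'   fraction of the total sample variance (default 1e-6).
#' @param min_molecules Minimum molecules required to size a sample
#'   (default 10); a value below `2 * min_samples` triggers a warning.
#' @param seed Integer seed for the random restarts (default 1).
#' @param expanded_threshold_repeats,normal_threshold_repeats Classification
#'   cut-offs in repeat units: alleles with mean below
#'   `normal_threshold_repeats` (default 100) are "normal", at or above
#'   `expanded_threshold_repeats` (default 250) "expanded", in between
#'   "intermediate".  Pathogenic expansions at this class of locus run from
#'   roughly 250 to over 4000 repeats while benign alleles stay under 100,
#'   hence the defaults; the labels are informational only.
#' @return A list of class `sizing_config`.
#' @export
sizing_config <- function(min_samples = 5L,
                          knee_sensitivity = 1.0,
                          weight_threshold = 0.25,
                          n_restarts = 10L,
                          em_tol = 1e-6,
                          max_iter = 500L,
                          variance_floor_frac = 1e-6,
                          min_molecules = 10L,
                          seed = 1L,
                          expanded_threshold_repeats = 250,
                          normal_threshold_repeats = 100) {
  if (!(weight_threshold > 0 && weight_threshold < 0.5)) {
    stop_ogmstr("validation", "weight_threshold must lie in (0, 0.5)")
  }
  stopifnot(is_count(min_samples), is_count(n_restarts), is_count(max_iter),
            is_count(min_molecules), em_tol > 0, variance_floor_frac > 0,
            knee_sensitivity > 0)
  if (min_molecules < 2L * min_samples) {
    warn_ogmstr("config",
                "min_molecules (%d) < 2 * min_samples (%d): sizing may be unstable",
                min_molecules, 2L * min_samples)
  }
  structure(
    list(min_samples = as.integer(min_samples),
         knee_sensitivity = knee_sensitivity,
         weight_threshold = weight_threshold,
         n_restarts = as.integer(n_restarts),
         em_tol = em_tol,
         max_iter = as.integer(max_iter),
         variance_floor_frac = variance_floor_frac,
         min_molecules = as.integer(min_molecules),
         seed = as.integer(seed),
         expanded_threshold_repeats = expanded_threshold_repeats,
         normal_threshold_repeats = normal_threshold_repeats),
    class = "sizing_config"
  )
}

#' Fit a univariate Gaussian mixture by maximum likelihood
#'
#' EM with multiple restarts.  Restart 1 initialises from an equal-count
#' split of the sorted data (block means and variances); remaining restarts
#' draw random responsibilities seeded from `config$seed`, so the fit is
#' deterministic given (data, config).  Component variances are floored at
#' `variance_floor_frac` times the total (maximum-likelihood) sample
#' variance.  BIC is computed as `p * log(n) - 2 * loglik` with
#' `p = 3k - 1` free parameters (k means, k variances, k - 1 weights);
#' lower is better.
#'
#' @param distances Numeric vector of observations (bp).
#' @param k Number of components, 1 or 2.
#' @param config A [sizing_config()].
#' @return An object of class `mixture_fit`: list with `k`, `components`
#'   (data.frame `mean_bp`, `sd_bp`, `weight`, sorted by mean), `loglik`,
#'   `bic`, `n`, `converged`.
#' @export
fit_gmm <- function(distances, k, config = sizing_config()) {
  d <- as.numeric(distances)
  n <- length(d)
  if (!(length(k) == 1L && k %in% c(1, 2))) {
    stop_ogmstr("unsupported_k", "k must be 1 or 2 (got %s)", format(k))
  }
  if (n < 2L * k) {
    stop_ogmstr("insufficient_data",
                "need at least %d observations for k = %d, got %d", 2L * k, k, n)
  }
  mu_all <- mean(d)
  var_total <- mean((d - mu_all)^2)
  if (var_total == 0) {
    stop_ogmstr("degenerate_data",
                "zero-variance input: all %d observations identical", n)
  }
  floor_var <- config$variance_floor_frac * var_total

  if (k == 1L) {
    # EM with one component is closed form: responsibilities are all 1
    fit <- list(w = 1, mu = mu_all, var = max(var_total, floor_var),
                loglik = sum(stats::dnorm(d, mu_all,
                                          sqrt(max(var_total, floor_var)),
                                          log = TRUE)),
                converged = TRUE)
  } else {
    fit <- with_seed(config$seed, {
      best <- NULL
      for (r in seq_len(config$n_restarts)) {
        init <- if (r == 1L) {
          block_init(d, k, floor_var)
        } else {
          resp <- matrix(stats::runif(n * k), n, k)
          m_step(d, resp / rowSums(resp), floor_var)
        }
        cand <- run_em(d, init, floor_var, config$em_tol, config$max_iter)
        if (is.null(best) || cand$loglik > best$loglik) best <- cand
      }
      best
    })
  }

  ord <- order(fit$mu)
  comp <- data.frame(mean_bp = fit$mu[ord],
                     sd_bp = sqrt(fit$var[ord]),
                     weight = fit$w[ord])
  structure(
    list(k = as.integer(k),
         components = comp,
         loglik = fit$loglik,
         bic = (3 * k - 1) * log(n) - 2 * fit$loglik,
         n = n,
         converged = fit$converged),
    class = "mixture_fit"
  )
}

block_init <- function(d, k, floor_var) {
  s <- sort(d)
  n <- length(s)
  blocks <- split(s, cut(seq_len(n), k, labels = FALSE))
  list(w = lengths(blocks) / n,
       mu = vapply(blocks, mean, 0),
       var = pmax(vapply(blocks, function(b) mean((b - mean(b))^2), 0),
                  floor_var))
}

log_densities <- function(d, th) {
  vapply(seq_along(th$w), function(j) {
    stats::dnorm(d, th$mu[j], sqrt(th$var[j]), log = TRUE) + log(th$w[j])
  }, numeric(length(d)))
}

m_step <- function(d, resp, floor_var) {
  nk <- pmax(colSums(resp), 1e-12)
  mu <- colSums(resp * d) / nk
  v <- vapply(seq_along(nk),
              function(j) sum(resp[, j] * (d - mu[j])^2) / nk[j], 0)
  list(w = nk / length(d), mu = mu, var = pmax(v, floor_var))
}

run_em <- function(d, th, floor_var, tol, max_iter) {
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ld <- log_densities(d, th)
    mx <- apply(ld, 1, max)
    ll_i <- mx + log(rowSums(exp(ld - mx)))
    ll <- sum(ll_i)
    resp <- exp(ld - ll_i)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll) + .Machine$double.eps)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    th <- m_step(d, resp, floor_var)
  }
  c(th, list(loglik = ll_old, converged = converged))
}

#' Choose between the one- and two-component mixture
#'
#' The two-component model is preferred only when (a) its BIC is strictly
#' lower (BIC improves) and (b) both component weights strictly exceed
#' `weight_threshold`.  Equal BICs fall back to the one-component model
#' (parsimony).  The rule is affine-invariant: rescaling the data shifts
#' both BICs by the same additive constant.
#'
#' @param fit1 `mixture_fit` with `k == 1`.
#' @param fit2 `mixture_fit` with `k == 2`.
#' @param weight_threshold Minimum component weight (default 0.25).
#' @return The selected `mixture_fit`.
#' @export
select_model <- function(fit1, fit2, weight_threshold = 0.25) {
  stopifnot(inherits(fit1, "mixture_fit"), inherits(fit2, "mixture_fit"),
            fit1$k == 1L, fit2$k == 2L)
  if (fit2$bic < fit1$bic && min(fit2$components$weight) > weight_threshold) {
    fit2
  } else {
    fit1
  }
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d, n = %d, loglik = %.3f, BIC = %.3f%s\n",
              x$k, x$n, x$loglik, x$bic,
              if (x$converged) "" else " (not converged)"))
  print(format(x$components, digits = 6))
  invisible(x)
}
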