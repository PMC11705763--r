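#' Fixed-TPM-threshold expression states
#'
#' The classical baseline: a gene is not expressed when its abundance falls
#' strictly below the cutoff (the "TPM < 1" / "TPM < 2" convention), and
#' expressed otherwise. The posterior column is the degenerate 0/1 state.
#'
#' @param tpm Named numeric vector of TPM abundances for one sample.
#' @param cutoff Positive TPM cutoff.
#' @param sample_id Sample identifier.
#' @return A `state_call_set` (see [call_states()]).
#' @export
fixed_threshold_states <- function(tpm, cutoff = 1, sample_id = "sample") {
  check_expression_vector(tpm)
  ts_assert(is.numeric(cutoff) && length(cutoff) == 1 && cutoff > 0,
            "cutoff must be a positive TPM value", "ts_parameter_error")
  state <- as.integer(!(tpm < cutoff))
  new_state_call_set(gene_id = names(tpm), tpm = unname(tpm),
                     posterior = as.numeric(state), state = state,
                     sample_id = sample_id,
                     method = sprintf("fixed_tpm_%g", cutoff))
}

#' zFPKM-style expression states
#'
#' Standardizes log2 abundances against the active-expression peak: the peak
#' location is the mode of a Gaussian kernel density over the positive log2
#' abundances (Sheather-Jones plug-in bandwidth), and the scale is the
#' root-mean-square deviation of the values above the mode, treating the
#' active peak as symmetric. A gene is expressed when its z-score is at least
#' `threshold`; zero abundances map to `z = -Inf` and are never expressed.
#'
#' @param tpm Named numeric vector of TPM abundances for one sample.
#' @param threshold z-score activity threshold (default -3, the published
#'   operating point where the active:repressed promoter ratio drops below 1).
#' @param sample_id Sample identifier.
#' @param min_positive Minimum number of positive abundances required.
#' @param bw_adjust Multiplier on the plug-in bandwidth. The default
#'   oversmooths threefold: under the method's symmetric-peak assumption this
#'   leaves the mode location unbiased while substantially reducing its
#'   sampling noise, and the expression peaks are far enough apart that they
#'   are not merged.
#' @return A `state_call_set` with an extra `z` column; the fitted peak is
#'   attached as attribute `fit` (list with `mu`, `sigma` on the log2 scale).
#' @export
zfpkm_states <- function(tpm, threshold = -3, sample_id = "sample",
                         min_positive = 500L, bw_adjust = 3) {
  check_expression_vector(tpm)
  pos <- tpm[tpm > 0]
  ts_assert(length(pos) >= min_positive,
            sprintf("only %d positive abundances (need >= %d)",
                    length(pos), min_positive),
            "ts_degenerate_input")
  y <- log2(pos)
  ts_assert(sd(y) > 0, "flat abundance distribution; no density mode",
            "ts_degenerate_input")
  d <- tryCatch(density(y, bw = "SJ", adjust = bw_adjust),
                error = function(e) density(y, bw = "nrd0",
                                            adjust = bw_adjust))
  mu <- d$x[which.max(d$y)]
  upper <- y[y > mu]
  ts_assert(length(upper) > 0,
            "no abundances above the density mode; degenerate peak",
            "ts_degenerate_input")
  sigma <- sqrt(mean((upper - mu)^2))
  z <- rep(-Inf, length(tpm))
  z[tpm > 0] <- (log2(tpm[tpm > 0]) - mu) / sigma
  state <- as.integer(z >= threshold)
  new_state_call_set(gene_id = names(tpm), tpm = unname(tpm),
                     posterior = as.numeric(state), state = state,
                     sample_id = sample_id, method = "zfpkm",
                     fit = list(mu = mu, sigma = sigma, threshold = threshold),
                     extra = data.frame(z = z))
}

# weighted negative-binomial size MLE given fixed mean, on the log scale
nb_size_mle <- function(k, w, mu) {
  obj <- function(ls) -sum(w * dnbinom(k, size = exp(ls), mu = mu, log = TRUE))
  exp(optimize(obj, interval = c(-7, 9))$minimum)
}

# continuous surrogate of the NB log density (gamma-interpolated), used for
# threshold root-finding on the TPM axis
nb_log_density_cont <- function(x, size, mu) {
  lgamma(x + size) - lgamma(size) - lgamma(x + 1) +
    size * log(size / (size + mu)) + x * log(mu / (size + mu))
}

enb_posterior_active <- function(x, fit) {
  l1 <- log(1 - fit$pi_active) + dexp(x, rate = fit$rate, log = TRUE)
  l2 <- log(fit$pi_active) + nb_log_density_cont(x, fit$size, fit$mu)
  1 / (1 + exp(l1 - l2))
}

# solve posterior_active(x) = 1 - prob_cutoff on the abundance axis
enb_threshold <- function(fit, prob_cutoff) {
  target <- 1 - prob_cutoff
  f <- function(x) enb_posterior_active(x, fit) - target
  xs <- exp(seq(log(1e-4), log(max(fit$mu * 20, 100)), length.out = 400))
  vals <- vapply(xs, f, numeric(1))
  idx <- which(vals[-1] >= 0 & vals[-length(vals)] < 0)[1]
  ts_assert(!is.na(idx),
            "active-component posterior never crosses the probability cutoff",
            "ts_nonconvergence", data = fit)
  uniroot(f, lower = xs[idx], upper = xs[idx + 1], tol = 1e-10)$root
}

#' Exponential + negative-binomial (EnB) mixture expression states
#'
#' Models positive abundances as a mixture of an exponential component
#' (transcripts of inactive genes) and a negative-binomial component (active
#' genes), fitted by expectation-maximization. The negative-binomial mass is
#' evaluated at abundances rounded to the nearest integer, an approximation
#' made explicit because TPM values are continuous, while the exponential
#' component uses the raw values. The expressed/not-expressed boundary is the
#' abundance at which the active-component posterior crosses
#' `1 - prob_cutoff`; genes at or above the boundary are expressed, zeros are
#' always not expressed.
#'
#' @param tpm Named numeric vector of TPM abundances for one sample.
#' @param prob_cutoff Probability cutoff for the threshold (default 0.01).
#' @param sample_id Sample identifier.
#' @param min_positive Minimum number of positive abundances.
#' @param tol,max_iter,restarts EM settings, as in
#'   [fit_expression_mixture()].
#' @return A `state_call_set`; the fitted mixture and the derived TPM
#'   threshold are attached as attribute `fit` (list with `pi_active`,
#'   `rate`, `mu`, `size`, `threshold`).
#' @export
enb_states <- function(tpm, prob_cutoff = 0.01, sample_id = "sample",
                       min_positive = 500L, tol = 1e-8, max_iter = 500L,
                       restarts = 3L) {
  check_expression_vector(tpm)
  ts_assert(prob_cutoff > 0 && prob_cutoff < 1,
            "prob_cutoff must lie in (0, 1)", "ts_parameter_error")
  x <- tpm[tpm > 0]
  ts_assert(length(x) >= min_positive,
            sprintf("only %d positive abundances (need >= %d)",
                    length(x), min_positive),
            "ts_degenerate_input")
  k <- round(x)
  med <- median(x)
  low <- x[x <= med]; high <- x[x > med]
  init <- list(pi_active = 0.5,
               rate = 1 / max(mean(low), 1e-3),
               mu = max(mean(high), 1),
               size = {
                 v <- var(high); m <- mean(high)
                 if (is.finite(v) && v > m) m^2 / (v - m) else 10
               })
  run_em <- function(init) {
    pi_a <- init$pi_active; rate <- init$rate
    mu <- init$mu; size <- init$size
    ll_old <- -Inf; converged <- FALSE; n_iter <- 0L
    for (it in seq_len(max_iter)) {
      l1 <- log(1 - pi_a) + dexp(x, rate = rate, log = TRUE)
      l2 <- log(pi_a) + dnbinom(k, size = size, mu = mu, log = TRUE)
      mx <- pmax(l1, l2)
      ll <- sum(mx + log(exp(l1 - mx) + exp(l2 - mx)))
      n_iter <- it
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      g2 <- 1 / (1 + exp(l1 - l2))
      pi_new <- mean(g2)
      if (pi_new < 1e-3 || pi_new > 1 - 1e-3) {
        return(list(collapsed = TRUE, reason = "component weight collapsed"))
      }
      rate <- sum(1 - g2) / sum((1 - g2) * x)
      mu <- sum(g2 * k) / sum(g2)
      if (!is.finite(mu) || mu <= 0) {
        return(list(collapsed = TRUE, reason = "active mean degenerate"))
      }
      size <- nb_size_mle(k, g2, mu)
      pi_a <- pi_new
    }
    list(collapsed = FALSE, pi_active = pi_a, rate = rate, mu = mu,
         size = size, n_iter = n_iter, converged = converged,
         log_likelihood = ll)
  }
  fit <- NULL
  reasons <- character(0)
  for (try in seq_len(restarts + 1L)) {
    res <- run_em(init)
    if (!res$collapsed) { fit <- res; break }
    reasons <- c(reasons, res$reason)
    init$pi_active <- min(max(init$pi_active + rnorm(1, 0, 0.1), 0.05), 0.95)
    init$rate <- init$rate * exp(rnorm(1, 0, 0.2))
    init$mu <- init$mu * exp(rnorm(1, 0, 0.2))
  }
  if (is.null(fit)) {
    ts_abort(paste0("EnB EM failed to converge: ",
                    paste(reasons, collapse = "; ")),
             "ts_nonconvergence", data = reasons)
  }
  thr <- enb_threshold(fit, prob_cutoff)
  fit$threshold <- thr
  state <- as.integer(tpm >= thr)
  new_state_call_set(gene_id = names(tpm), tpm = unname(tpm),
                     posterior = as.numeric(state), state = state,
                     sample_id = sample_id, method = "enb", fit = fit)
}
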