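#' Construct a two-component lognormal mixture fit
#'
#' Container for the per-sample mixture that separates not-expressed from
#' expressed genes. Locations and scales are on the log2(TPM) scale; the
#' component with the higher location is the expressed component by
#' convention.
#'
#' @param pi_e Mixing proportion of the expressed component, in (0, 1).
#' @param mu_ne,sigma_ne Location and scale of the not-expressed component
#'   (log2 scale); `sigma_ne` must be positive.
#' @param mu_e,sigma_e Location and scale of the expressed component
#'   (log2 scale); must satisfy `mu_e > mu_ne`, `sigma_e > 0`.
#' @param n_iter,converged,log_likelihood,n_fitted EM diagnostics (optional).
#' @param loglik_trace Numeric vector of observed-data log likelihoods, one
#'   per EM iteration (optional).
#' @return An object of class `mixture_fit`.
#' @export
mixture_fit <- function(pi_e, mu_ne, sigma_ne, mu_e, sigma_e,
                        n_iter = NA_integer_, converged = NA,
                        log_likelihood = NA_real_, n_fitted = NA_integer_,
                        loglik_trace = NULL) {
  pars <- c(pi_e = pi_e, mu_ne = mu_ne, sigma_ne = sigma_ne,
            mu_e = mu_e, sigma_e = sigma_e)
  ts_assert(all(is.finite(pars)), "mixture parameters must be finite",
            "ts_invalid_fit", data = as.list(pars))
  ts_assert(pi_e > 0 && pi_e < 1,
            "pi_e must lie strictly in (0, 1)", "ts_invalid_fit")
  ts_assert(sigma_ne > 0 && sigma_e > 0,
            "component scales must be positive", "ts_invalid_fit")
  ts_assert(mu_e > mu_ne,
            "expressed component must have the higher location (mu_e > mu_ne)",
            "ts_invalid_fit")
  structure(
    list(pi_ne = 1 - pi_e, pi_e = pi_e,
         mu_ne = mu_ne, sigma_ne = sigma_ne,
         mu_e = mu_e, sigma_e = sigma_e,
         n_iter = as.integer(n_iter), converged = converged,
         log_likelihood = log_likelihood, n_fitted = as.integer(n_fitted),
         loglik_trace = loglik_trace),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-component lognormal mixture (log2 scale)\n")
  cat(sprintf("  not expressed: pi = %.4f, mu = %.3f, sigma = %.3f\n",
              x$pi_ne, x$mu_ne, x$sigma_ne))
  cat(sprintf("  expressed:     pi = %.4f, mu = %.3f, sigma = %.3f\n",
              x$pi_e, x$mu_e, x$sigma_e))
  cat(sprintf("  EM: %s iterations, converged = %s, logLik = %.3f, n = %s\n",
              x$n_iter, x$converged, x$log_likelihood, x$n_fitted))
  invisible(x)
}

# validate a named, non-negative TPM vector
check_expression_vector <- function(tpm) {
  ts_assert(is.numeric(tpm) && length(tpm) > 0,
            "expression input must be a non-empty numeric vector",
            "ts_domain_error")
  ts_assert(!is.null(names(tpm)) && !anyNA(names(tpm)) && all(nzchar(names(tpm))),
            "expression vector must carry gene identifiers as names",
            "ts_domain_error")
  dup <- names(tpm)[duplicated(names(tpm))]
  ts_assert(length(dup) == 0,
            paste0("duplicated gene identifiers: ",
                   paste(head(unique(dup), 5), collapse = ", ")),
            "ts_duplicate_id", data = unique(dup))
  ts_assert(!anyNA(tpm) && all(is.finite(tpm)),
            "expression values must be finite and non-missing",
            "ts_domain_error")
  ts_assert(all(tpm >= 0), "TPM abundances must be non-negative",
            "ts_domain_error")
  invisible(tpm)
}

# one EM run on log2 abundances; returns either a parameter list or a
# collapse marker with diagnostics
em_two_normals <- function(y, init, tol, max_iter) {
  pi_e <- init$pi_e
  mu_ne <- init$mu_ne; s_ne <- init$sigma_ne
  mu_e <- init$mu_e;  s_e <- init$sigma_e
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    l_ne <- log(1 - pi_e) + dnorm(y, mu_ne, s_ne, log = TRUE)
    l_e <- log(pi_e) + dnorm(y, mu_e, s_e, log = TRUE)
    m <- pmax(l_ne, l_e)
    ll <- sum(m + log(exp(l_ne - m) + exp(l_e - m)))
    ll_trace <- c(ll_trace, ll)
    n_iter <- it
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    g <- 1 / (1 + exp(l_ne - l_e)) # responsibility of the expressed component
    se <- sum(g); sn <- sum(1 - g)
    pi_e_new <- se / length(y)
    if (pi_e_new < 1e-3 || pi_e_new > 1 - 1e-3) {
      return(list(collapsed = TRUE,
                  reason = sprintf("component weight collapsed (pi_e = %.2g)",
                                   pi_e_new),
                  pi_e = pi_e_new, n_iter = it))
    }
    mu_e_new <- sum(g * y) / se
    mu_ne_new <- sum((1 - g) * y) / sn
    s_e_new <- sqrt(sum(g * (y - mu_e_new)^2) / se)
    s_ne_new <- sqrt(sum((1 - g) * (y - mu_ne_new)^2) / sn)
    if (!is.finite(s_e_new) || !is.finite(s_ne_new) ||
        s_e_new < 1e-6 || s_ne_new < 1e-6 ||
        abs(mu_e_new - mu_ne_new) < 1e-4) {
      return(list(collapsed = TRUE,
                  reason = sprintf(
                    "degenerate components (|mu_e - mu_ne| = %.2g, scales %.2g/%.2g)",
                    abs(mu_e_new - mu_ne_new), s_ne_new, s_e_new),
                  n_iter = it))
    }
    pi_e <- pi_e_new
    mu_e <- mu_e_new; mu_ne <- mu_ne_new
    s_e <- s_e_new; s_ne <- s_ne_new
  }
  list(collapsed = FALSE, pi_e = pi_e, mu_ne = mu_ne, sigma_ne = s_ne,
       mu_e = mu_e, sigma_e = s_e, n_iter = n_iter, converged = converged,
       log_likelihood = ll_trace[length(ll_trace)], loglik_trace = ll_trace)
}

#' Fit the per-sample two-component lognormal mixture
#'
#' Fits, by expectation-maximization on log2-transformed strictly positive
#' abundances, the mixture `f(x) = pi_ne * f_ne(x) + pi_e * f_e(x)` of a
#' not-expressed and an expressed lognormal component. Housekeeping genes —
#' constitutively expressed in essentially every sample — anchor the initial
#' values of the expressed component; the not-expressed component is
#' initialized from the lower quartile of the remaining positive genes.
#' Exact zeros are excluded from the fit (they receive posterior 0 at call
#' time).
#'
#' @param tpm Named numeric vector of TPM abundances for one sample (gene
#'   identifiers as names, all values >= 0).
#' @param housekeeping Character vector of housekeeping gene identifiers.
#' @param tol EM stopping tolerance on the relative change of the
#'   observed-data log likelihood.
#' @param max_iter Maximum EM iterations per run.
#' @param restarts Number of jittered restarts attempted after an EM collapse
#'   before a non-convergence error is raised.
#' @param min_positive Minimum number of genes with positive abundance
#'   required for an identifiable fit.
#' @param min_housekeeping Minimum number of housekeeping genes that must be
#'   detected (positive abundance) in the sample.
#' @return A [mixture_fit()] object.
#' @export
fit_expression_mixture <- function(tpm, housekeeping,
                                   tol = 1e-8, max_iter = 1000L,
                                   restarts = 3L,
                                   min_positive = 500L,
                                   min_housekeeping = 10L) {
  check_expression_vector(tpm)
  ts_assert(is.character(housekeeping) && length(housekeeping) > 0,
            "a housekeeping gene list is required for EM initialization",
            "ts_init_error")
  pos <- tpm[tpm > 0]
  ts_assert(length(pos) >= min_positive,
            sprintf("only %d genes with positive abundance (need >= %d)",
                    length(pos), min_positive),
            "ts_degenerate_input")
  y <- log2(pos)
  ts_assert(sd(y) > 0,
            "all positive abundances are identical; mixture is unidentifiable",
            "ts_degenerate_input")
  hk <- intersect(housekeeping, names(pos))
  ts_assert(length(hk) >= min_housekeeping,
            sprintf(paste0("only %d of %d housekeeping genes detected with ",
                           "positive abundance (need >= %d); check that the ",
                           "housekeeping list matches the matrix gene IDs"),
                    length(hk), length(housekeeping), min_housekeeping),
            "ts_init_error",
            data = list(missing = setdiff(housekeeping, names(pos))))

  # housekeeping-informed initialization
  y_hk <- y[hk]
  mu_e0 <- mean(y_hk)
  s_e0 <- max(sd(y_hk), 0.05)
  y_rest <- y[setdiff(names(y), hk)]
  y_low <- y_rest[y_rest <= quantile(y_rest, 0.25)]
  mu_ne0 <- mean(y_low)
  s_ne0 <- max(sd(y_low), 0.05)
  if (!is.finite(s_ne0)) s_ne0 <- 0.5
  if (mu_ne0 >= mu_e0) mu_ne0 <- mu_e0 - 1 # pathological lists; keep ordered
  mid <- (mu_ne0 + mu_e0) / 2
  pi_e0 <- min(max(mean(y > mid), 0.05), 0.95)
  init <- list(pi_e = pi_e0, mu_ne = mu_ne0, sigma_ne = s_ne0,
               mu_e = mu_e0, sigma_e = s_e0)

  attempts <- list()
  for (try in seq_len(restarts + 1L)) {
    res <- em_two_normals(y, init, tol = tol, max_iter = max_iter)
    if (!res$collapsed) {
      # enforce the label convention: higher location is "expressed"
      if (res$mu_e < res$mu_ne) {
        res <- within(res, {
          tmp <- mu_e; mu_e <- mu_ne; mu_ne <- tmp
          tmp <- sigma_e; sigma_e <- sigma_ne; sigma_ne <- tmp
          pi_e <- 1 - pi_e
          rm(tmp)
        })
      }
      return(mixture_fit(pi_e = res$pi_e,
                         mu_ne = res$mu_ne, sigma_ne = res$sigma_ne,
                         mu_e = res$mu_e, sigma_e = res$sigma_e,
                         n_iter = res$n_iter, converged = res$converged,
                         log_likelihood = res$log_likelihood,
                         n_fitted = length(y),
                         loglik_trace = res$loglik_trace))
    }
    attempts[[try]] <- res$reason
    ts_log("debug", sprintf("EM collapse on attempt %d: %s", try, res$reason))
    init <- list(pi_e = min(max(pi_e0 + rnorm(1, 0, 0.05), 0.05), 0.95),
                 mu_ne = mu_ne0 + rnorm(1, 0, 0.25),
                 sigma_ne = s_ne0 * exp(rnorm(1, 0, 0.1)),
                 mu_e = mu_e0 + rnorm(1, 0, 0.25),
                 sigma_e = s_e0 * exp(rnorm(1, 0, 0.1)))
  }
  ts_abort(paste0("EM failed to converge after ", restarts,
                  " jittered restarts: ",
                  paste(unlist(attempts), collapse = "; ")),
           "ts_nonconvergence", data = attempts)
}

#' Posterior probability that a gene is expressed
#'
#' Applies Bayes' rule to a fitted two-component mixture:
#' `P(expressed | x) = pi_e f_e(x) / (pi_ne f_ne(x) + pi_e f_e(x))` for
#' `x > 0`, and exactly 0 at `x = 0` (a zero read count carries no evidence
#' of expression under the piecewise definition). The lognormal Jacobian is
#' common to both components and cancels, so the ratio is evaluated from the
#' two normal densities on the log2 scale.
#'
#' @param x Numeric vector of TPM abundances (>= 0).
#' @param fit A [mixture_fit()].
#' @return Numeric vector of posterior probabilities in `[0, 1]`.
#' @export
posterior_expressed <- function(x, fit) {
  ts_assert(inherits(fit, "mixture_fit"), "fit must be a mixture_fit",
            "ts_invalid_fit")
  pars <- unlist(fit[c("pi_ne", "pi_e", "mu_ne", "sigma_ne", "mu_e", "sigma_e")])
  ts_assert(all(is.finite(pars)), "non-finite mixture parameters",
            "ts_invalid_fit")
  ts_assert(is.numeric(x) && !anyNA(x), "abundances must be numeric, no NA",
            "ts_domain_error")
  ts_assert(all(x >= 0), "abundances must be non-negative", "ts_domain_error")
  out <- numeric(length(x))
  pos <- x > 0
  if (any(pos)) {
    lx <- log2(x[pos])
    l_ne <- log(fit$pi_ne) + dnorm(lx, fit$mu_ne, fit$sigma_ne, log = TRUE)
    l_e <- log(fit$pi_e) + dnorm(lx, fit$mu_e, fit$sigma_e, log = TRUE)
    out[pos] <- 1 / (1 + exp(l_ne - l_e))
  }
  out
}

# internal constructor shared by all calling methods
new_state_call_set <- function(gene_id, tpm, posterior, state, sample_id,
                               method, fit = NULL, extra = NULL) {
  df <- data.frame(gene_id = gene_id, tpm = tpm, posterior = posterior,
                   state = as.integer(state), stringsAsFactors = FALSE,
                   row.names = NULL)
  if (!is.null(extra)) df <- cbind(df, extra)
  structure(df, class = c("state_call_set", "data.frame"),
            sample_id = sample_id, method = method, fit = fit)
}

#' Call binary expression states for one sample
#'
#' Converts abundances to posterior expression probabilities under `fit` and
#' applies the 0.5 probability cutoff: a gene is called expressed (state 1)
#' if and only if its posterior is at least 0.5; genes with zero abundance
#' are always not expressed (state 0).
#'
#' @param tpm Named numeric vector of TPM abundances for one sample.
#' @param fit A [mixture_fit()] for this sample.
#' @param sample_id Sample identifier stored on the result.
#' @param posterior Optional precomputed posterior vector (same length and
#'   order as `tpm`); supplied mainly by pipeline code.
#' @return A `state_call_set`: a data frame with columns `gene_id`, `tpm`,
#'   `posterior`, `state` (one row per gene, input order preserved), with the
#'   fit attached as attribute `fit`.
#' @export
call_states <- function(tpm, fit, sample_id = "sample", posterior = NULL) {
  check_expression_vector(tpm)
  if (is.null(posterior)) {
    posterior <- posterior_expressed(unname(tpm), fit)
  } else {
    ts_assert(length(posterior) == length(tpm),
              sprintf("posterior length (%d) does not match gene count (%d)",
                      length(posterior), length(tpm)),
              "ts_shape_error")
  }
  new_state_call_set(gene_id = names(tpm), tpm = unname(tpm),
                     posterior = posterior,
                     state = posterior >= 0.5,
                     sample_id = sample_id, method = "variable", fit = fit)
}

#' Fit the mixture and call states in one step
#'
#' @inheritParams fit_expression_mixture
#' @inheritParams call_states
#' @param ... Passed to [fit_expression_mixture()].
#' @return A `state_call_set` (see [call_states()]).
#' @export
infer_sample_states <- function(tpm, housekeeping, sample_id = "sample", ...) {
  fit <- fit_expression_mixture(tpm, housekeeping, ...)
  call_states(tpm, fit, sample_id = sample_id)
}

#' @export
print.state_call_set <- function(x, ...) {
  cat(sprintf("state_call_set: sample %s, method %s, %d genes, %d expressed (%.1f%%)\n",
              attr(x, "sample_id"), attr(x, "method"), nrow(x),
              sum(x$state), 100 * mean(x$state)))
  invisible(x)
}
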