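# Shared fixture builders. Everything is generated in code; no stored data.

options(taascreen.log_level = "warn")

# a deterministic, well-formed fit for posterior tests
toy_fit <- function(pi_e = 0.5, mu_ne = 0, sigma_ne = 1,
                    mu_e = 5, sigma_e = 1) {
  mixture_fit(pi_e = pi_e, mu_ne = mu_ne, sigma_ne = sigma_ne,
              mu_e = mu_e, sigma_e = sigma_e)
}

# independent oracle for the expressed posterior: full lognormal densities on
# the natural scale, Jacobians included (the implementation works on the log2
# scale without Jacobians; the two routes must agree)
oracle_posterior <- function(x, pi_e, mu_ne, sigma_ne, mu_e, sigma_e) {
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    dens <- function(mu, sigma) {
      dnorm(log2(xi), mu, sigma) / (xi * log(2))
    }
    num <- pi_e * dens(mu_e, sigma_e)
    den <- (1 - pi_e) * dens(mu_ne, sigma_ne) + num
    num / den
  }, numeric(1))
}

# named TPM vector from explicit log2 values (positive genes only)
tpm_from_log2 <- function(y) {
  setNames(2^y, sprintf("G%05d", seq_along(y)))
}

# a cohort_states object from a plain 0/1 matrix definition
make_cohort <- function(states, tissue_of) {
  if (is.null(rownames(states)))
    rownames(states) <- sprintf("G%03d", seq_len(nrow(states)))
  if (is.null(colnames(states)))
    colnames(states) <- sprintf("S%03d", seq_len(ncol(states)))
  if (is.null(names(tissue_of))) names(tissue_of) <- colnames(states)
  cohort_states(states, tissue_of)
}

# a well-separated single sample with zero inflation and known latent truth
separable_sample <- function(n = 2000, seed = 1, mu_ne = -1, mu_e = 6,
                             sigma = 0.8, pi_e = 0.55, zero_inflation = 0.7) {
  set.seed(seed)
  simulate_mixture_sample(n, pi_e = pi_e, mu_ne = mu_ne, sigma_ne = sigma,
                          mu_e = mu_e, sigma_e = sigma,
                          zero_inflation = zero_inflation)
}

# small well-separated atlas + tumor config used by end-to-end tests
separable_config <- function(seed, n_genes = 1500L) {
  simulation_config(
    n_genes = n_genes, seed = seed,
    mu_ne = -1, sigma_ne = 0.8, mu_e = 6, sigma_e = 0.8,
    tissues = data.frame(name = c("brain", "liver", "lung", "ovary", "testis"),
                         n_samples = c(8L, 8L, 8L, 8L, 6L)),
    tumor_cohorts = data.frame(name = "tumor_a", n_samples = 40L,
                               n_taa = 10L, taa_prevalence = 0.10))
}

# reference standard data frame from explicit labels
make_ref <- function(gene_id, label) {
  data.frame(gene_id = gene_id,
             label = factor(label, levels = c("active", "inactive",
                                              "ambiguous")),
             stringsAsFactors = FALSE)
}

# state_call_set straight from explicit states (for evaluation tests)
calls_from_states <- function(states, sample_id = "s1") {
  taascreen:::new_state_call_set(
    gene_id = names(states), tpm = as.numeric(states),
    posterior = as.numeric(states), state = as.integer(states),
    sample_id = sample_id, method = "manual")
}
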