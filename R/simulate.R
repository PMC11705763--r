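#' Configuration for the cohort simulator
#'
#' Defines the generative model behind the synthetic atlases: per-gene latent
#' expression states with tissue-restricted dormancy patterns and a
#' testis-like tissue, abundances drawn from a zero-inflated two-component
#' lognormal mixture on the log2 scale, and tumor cohorts in which a chosen
#' set of dormant genes is reactivated at a configured prevalence.
#'
#' Latent-state layout: housekeeping genes are expressed in every sample;
#' dormant genes are silent in every non-testis normal tissue, with a
#' `testis_exclusive_fraction` of them expressed in testis samples at
#' `testis_prevalence`; every remaining ("regular") gene is expressed in a
#' guaranteed home tissue plus an independent random subset of the others,
#' calibrated so the per-sample expressed fraction matches `pi_e`. Tumor
#' cohorts inherit the latent states of an origin tissue for regular genes;
#' planted TAA genes are reactivated in `max(1, round(prevalence * m))`
#' samples so the configured prevalence is realized exactly.
#'
#' @param n_genes Total number of genes.
#' @param n_housekeeping Number of housekeeping genes (always expressed).
#' @param tissues Data frame with columns `name`, `n_samples` describing the
#'   normal atlas (include a testis-like tissue to exercise testis-exclusive
#'   dormancy).
#' @param testis_label Which tissue name is the testis-like tissue.
#' @param tumor_cohorts Data frame with columns `name`, `n_samples`, `n_taa`,
#'   `taa_prevalence` and optional `origin` (tissue whose latent states the
#'   cohort inherits; defaults to the first non-testis tissue).
#' @param pi_e Target per-sample expressed fraction.
#' @param mu_ne,sigma_ne,mu_e,sigma_e Mixture locations/scales on the log2
#'   scale (`mu_e > mu_ne`).
#' @param zero_inflation Probability that a not-expressed gene reads exactly
#'   zero.
#' @param dormant_fraction Fraction of genes planted as dormant.
#' @param testis_exclusive_fraction Fraction of dormant genes that are
#'   testis-exclusive (the remainder are silent everywhere).
#' @param testis_prevalence Expressed prevalence of testis-exclusive genes in
#'   testis samples.
#' @param tissue_shift_sd SD (log2 units) of the per-tissue location shift
#'   applied to both components; 0 disables tissue effects.
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000L, n_housekeeping = 50L,
                              tissues = data.frame(
                                name = c("brain", "liver", "lung", "ovary",
                                         "pancreas", "testis"),
                                n_samples = c(10L, 10L, 10L, 10L, 10L, 8L)),
                              testis_label = "testis",
                              tumor_cohorts = data.frame(
                                name = "tumor_a", n_samples = 40L,
                                n_taa = 10L, taa_prevalence = 0.10),
                              pi_e = 0.55,
                              mu_ne = -1.0, sigma_ne = 0.8,
                              mu_e = 4.5, sigma_e = 1.6,
                              zero_inflation = 0.7,
                              dormant_fraction = 0.05,
                              testis_exclusive_fraction = 0.32,
                              testis_prevalence = 0.8,
                              tissue_shift_sd = 0.2,
                              seed) {
  ts_assert(!missing(seed) && is.numeric(seed) && length(seed) == 1 &&
              is.finite(seed),
            "a seed is mandatory", "ts_config_error")
  frac <- c(pi_e = pi_e, zero_inflation = zero_inflation,
            dormant_fraction = dormant_fraction,
            testis_exclusive_fraction = testis_exclusive_fraction,
            testis_prevalence = testis_prevalence)
  ts_assert(all(frac >= 0 & frac <= 1),
            "all fractions must lie in [0, 1]", "ts_config_error")
  ts_assert(mu_e > mu_ne, "mu_e must exceed mu_ne", "ts_config_error")
  ts_assert(sigma_ne > 0 && sigma_e > 0 && tissue_shift_sd >= 0,
            "scales must be positive (tissue_shift_sd >= 0)",
            "ts_config_error")
  ts_assert(is.data.frame(tissues) &&
              all(c("name", "n_samples") %in% names(tissues)) &&
              nrow(tissues) >= 1 && all(tissues$n_samples >= 1),
            "tissues must be a data frame with name and n_samples >= 1",
            "ts_config_error")
  if (!is.null(tumor_cohorts)) {
    ts_assert(is.data.frame(tumor_cohorts) &&
                all(c("name", "n_samples", "n_taa", "taa_prevalence") %in%
                      names(tumor_cohorts)),
              "tumor_cohorts needs name, n_samples, n_taa, taa_prevalence",
              "ts_config_error")
    ts_assert(all(tumor_cohorts$taa_prevalence >= 0 &
                    tumor_cohorts$taa_prevalence <= 1),
              "taa_prevalence must lie in [0, 1]", "ts_config_error")
  }
  n_dormant <- round(dormant_fraction * n_genes)
  if (!is.null(tumor_cohorts) && nrow(tumor_cohorts) > 0) {
    ts_assert(all(tumor_cohorts$n_taa <= n_dormant),
              sprintf("requested TAA genes exceed the %d planted dormant genes",
                      n_dormant),
              "ts_config_error")
  }
  ts_assert(n_housekeeping + n_dormant < n_genes,
            "housekeeping + dormant genes must leave room for regular genes",
            "ts_config_error")
  structure(list(n_genes = as.integer(n_genes),
                 n_housekeeping = as.integer(n_housekeeping),
                 tissues = tissues, testis_label = testis_label,
                 tumor_cohorts = tumor_cohorts,
                 pi_e = pi_e, mu_ne = mu_ne, sigma_ne = sigma_ne,
                 mu_e = mu_e, sigma_e = sigma_e,
                 zero_inflation = zero_inflation,
                 dormant_fraction = dormant_fraction,
                 testis_exclusive_fraction = testis_exclusive_fraction,
                 testis_prevalence = testis_prevalence,
                 tissue_shift_sd = tissue_shift_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# draw abundances for one sample given latent 0/1 states
draw_abundances <- function(latent, cfg, shift) {
  n <- length(latent)
  x <- numeric(n)
  on <- latent == 1L
  x[on] <- 2^rnorm(sum(on), cfg$mu_e + shift, cfg$sigma_e)
  off <- which(!on)
  zero <- runif(length(off)) < cfg$zero_inflation
  x[off[zero]] <- 0
  x[off[!zero]] <- 2^rnorm(sum(!zero), cfg$mu_ne + shift, cfg$sigma_ne)
  x
}

# pick exactly max(1, round(p * m)) of m slots
planted_slots <- function(m, p) {
  k <- max(1L, round(p * m))
  sort(sample.int(m, min(k, m)))
}

#' Simulate a multi-tissue normal atlas and tumor cohorts with known truth
#'
#' @param config A [simulation_config()].
#' @return A `taa_simulation`: list with `normal` (gene x sample TPM matrix
#'   over all normal tissues), `tumors` (named list of gene x sample
#'   matrices), `sample_map` (sample_id, tissue; covers normal and tumor
#'   samples, tumor samples labelled by cohort name), `housekeeping` (gene
#'   identifiers), `truth` (latent state matrices, the planted dormant table,
#'   the planted TAA table with realized expressed counts, and the generating
#'   config), and `config`.
#' @export
simulate_cohorts <- function(config) {
  ts_assert(inherits(config, "simulation_config"),
            "config must come from simulation_config()", "ts_config_error")
  cfg <- config
  set.seed(cfg$seed)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  hk <- genes[seq_len(cfg$n_housekeeping)]
  n_dormant <- round(cfg$dormant_fraction * cfg$n_genes)
  pool <- setdiff(genes, hk)
  dormant <- if (n_dormant > 0) sort(sample(pool, n_dormant)) else character(0)
  n_te <- round(cfg$testis_exclusive_fraction * n_dormant)
  testis_excl <- if (n_te > 0) sort(sample(dormant, n_te)) else character(0)
  regular <- setdiff(pool, dormant)

  tissues <- cfg$tissues
  T <- nrow(tissues)
  # every regular gene gets a guaranteed non-testis home tissue (so chance
  # alone can never make a regular gene dormant) plus independent membership
  # in the other tissues, calibrated so a sample's expressed count is close
  # to pi_e * n_genes: hk always on, dormant off, regular on with
  # probability 1/T_nt (home) + (1 - 1/T_nt) q in a non-testis tissue
  nt_idx <- which(tissues$name != cfg$testis_label)
  ts_assert(length(nt_idx) > 0, "at least one non-testis tissue is required",
            "ts_config_error")
  T_nt <- length(nt_idx)
  target <- (cfg$pi_e * cfg$n_genes - cfg$n_housekeeping) / length(regular)
  q <- if (T_nt > 1) (target - 1 / T_nt) / (1 - 1 / T_nt) else target
  q <- min(max(q, 0), 1)
  home <- nt_idx[sample.int(T_nt, length(regular), replace = TRUE)]
  member <- matrix(runif(length(regular) * T) < q, length(regular), T)
  member[cbind(seq_along(regular), home)] <- TRUE
  latent_tissue <- matrix(0L, cfg$n_genes, T,
                          dimnames = list(genes, tissues$name))
  latent_tissue[hk, ] <- 1L
  latent_tissue[regular, ] <- member * 1L

  shifts <- if (cfg$tissue_shift_sd > 0) {
    rnorm(T, 0, cfg$tissue_shift_sd)
  } else rep(0, T)
  names(shifts) <- tissues$name

  # normal samples; testis-exclusive genes get per-sample reactivation slots
  sample_ids <- character(0)
  sample_tissue <- character(0)
  latent_normal <- NULL
  testis_truth <- NULL
  normal_cols <- list()
  for (ti in seq_len(T)) {
    tname <- tissues$name[ti]
    m <- tissues$n_samples[ti]
    ids <- sprintf("%s_s%02d", tname, seq_len(m))
    lat <- matrix(latent_tissue[, ti], cfg$n_genes, m,
                  dimnames = list(genes, ids))
    if (tname == cfg$testis_label && length(testis_excl) > 0) {
      slots <- lapply(testis_excl, function(g) planted_slots(m, cfg$testis_prevalence))
      for (i in seq_along(testis_excl)) lat[testis_excl[i], slots[[i]]] <- 1L
      testis_truth <- data.frame(gene_id = testis_excl,
                                 n_expressed = vapply(slots, length, integer(1)),
                                 m = m, stringsAsFactors = FALSE)
    }
    x <- vapply(seq_len(m),
                function(j) draw_abundances(lat[, j], cfg, shifts[ti]),
                numeric(cfg$n_genes))
    dimnames(x) <- list(genes, ids)
    normal_cols[[tname]] <- x
    latent_normal <- cbind(latent_normal, lat)
    sample_ids <- c(sample_ids, ids)
    sample_tissue <- c(sample_tissue, rep(tname, m))
  }
  normal <- do.call(cbind, normal_cols)

  # tumor cohorts
  tumors <- list()
  latent_tumor <- list()
  taa_truth <- NULL
  tc <- cfg$tumor_cohorts
  if (!is.null(tc) && nrow(tc) > 0) {
    non_testis <- setdiff(tissues$name, cfg$testis_label)
    for (ci in seq_len(nrow(tc))) {
      cname <- tc$name[ci]
      m <- tc$n_samples[ci]
      origin <- if ("origin" %in% names(tc) && !is.na(tc$origin[ci])) {
        tc$origin[ci]
      } else non_testis[1]
      ts_assert(origin %in% tissues$name,
                sprintf("tumor cohort %s: unknown origin tissue %s",
                        cname, origin),
                "ts_config_error")
      ids <- sprintf("%s_t%03d", cname, seq_len(m))
      lat <- matrix(latent_tissue[, origin], cfg$n_genes, m,
                    dimnames = list(genes, ids))
      planted <- if (tc$n_taa[ci] > 0) sort(sample(dormant, tc$n_taa[ci]))
                 else character(0)
      slots <- lapply(planted,
                      function(g) planted_slots(m, tc$taa_prevalence[ci]))
      for (i in seq_along(planted)) lat[planted[i], slots[[i]]] <- 1L
      shift <- if (cfg$tissue_shift_sd > 0) rnorm(1, 0, cfg$tissue_shift_sd)
               else 0
      x <- vapply(seq_len(m),
                  function(j) draw_abundances(lat[, j], cfg, shift),
                  numeric(cfg$n_genes))
      dimnames(x) <- list(genes, ids)
      tumors[[cname]] <- x
      latent_tumor[[cname]] <- lat
      if (length(planted) > 0) {
        taa_truth <- rbind(taa_truth, data.frame(
          cohort = cname, gene_id = planted,
          n_expressed = vapply(slots, length, integer(1)), m = m,
          prevalence = tc$taa_prevalence[ci], stringsAsFactors = FALSE))
      }
      sample_ids <- c(sample_ids, ids)
      sample_tissue <- c(sample_tissue, rep(cname, m))
    }
  }

  dormant_truth <- data.frame(
    gene_id = dormant,
    category = ifelse(dormant %in% testis_excl, "testis_exclusive",
                      "silent_everywhere"),
    stringsAsFactors = FALSE)
  structure(list(
    normal = normal,
    tumors = tumors,
    sample_map = data.frame(sample_id = sample_ids, tissue = sample_tissue,
                            stringsAsFactors = FALSE),
    housekeeping = hk,
    truth = list(latent_normal = latent_normal,
                 latent_tumor = latent_tumor,
                 latent_tissue = latent_tissue,
                 dormant = dormant_truth,
                 testis = testis_truth,
                 taa = taa_truth,
                 tissue_shifts = shifts),
    config = cfg), class = "taa_simulation")
}

#' Simulate a single sample from the two-component lognormal model
#'
#' Draws one sample's abundances directly from the assumed generative model
#' (no tissue structure): a gene is expressed with probability `pi_e`;
#' expressed abundances are lognormal(`mu_e`, `sigma_e`) and not-expressed
#' ones lognormal(`mu_ne`, `sigma_ne`) on the log2 scale, with optional exact
#' zeros. The first `n_housekeeping` expressed genes are designated
#' housekeeping. Used for parameter-recovery checks where the fitted model
#' matches the generator exactly.
#'
#' @param n_genes Number of genes.
#' @param pi_e,mu_ne,sigma_ne,mu_e,sigma_e Generating parameters (log2 scale).
#' @param zero_inflation Probability an unexpressed gene reads exactly zero.
#' @param n_housekeeping Number of housekeeping identifiers to designate.
#' @return List with `tpm` (named vector), `housekeeping`, `latent` (0/1),
#'   and the generating parameters.
#' @export
simulate_mixture_sample <- function(n_genes = 20000L, pi_e = 0.55,
                                    mu_ne = -1.0, sigma_ne = 0.8,
                                    mu_e = 4.5, sigma_e = 1.6,
                                    zero_inflation = 0,
                                    n_housekeeping = 50L) {
  latent <- as.integer(runif(n_genes) < pi_e)
  x <- numeric(n_genes)
  on <- latent == 1L
  x[on] <- 2^rnorm(sum(on), mu_e, sigma_e)
  off <- which(!on)
  zero <- runif(length(off)) < zero_inflation
  x[off[zero]] <- 0
  x[off[!zero]] <- 2^rnorm(sum(!zero), mu_ne, sigma_ne)
  names(x) <- sprintf("G%05d", seq_len(n_genes))
  hk <- head(names(x)[on], n_housekeeping)
  list(tpm = x, housekeeping = hk, latent = setNames(latent, names(x)),
       params = list(pi_e = pi_e, mu_ne = mu_ne, sigma_ne = sigma_ne,
                     mu_e = mu_e, sigma_e = sigma_e,
                     zero_inflation = zero_inflation))
}

#' Simulate a toy chromatin annotation consistent with simulation truth
#'
#' Builds interval fixtures on a toy chromosome such that, at
#' `noise_rate = 0`, [build_reference_standard()] reproduces each gene's
#' tissue-level latent state in the chosen tissue: expressed genes receive a
#' state-1 segment over their first exon and a state-4 segment over the gene
#' body; silent genes receive a single state-13 segment. A `noise_rate`
#' fraction of genes is flipped to an ambiguous-inducing combination (state-1
#' exon mark plus state-10 body mark).
#'
#' @param sim A `taa_simulation` (see [simulate_cohorts()]).
#' @param tissue Tissue whose latent truth the annotation should encode.
#' @param noise_rate Fraction of genes flipped to ambiguous, in `[0, 1]`.
#' @param seed Seed for the flip draw (defaults to the simulation seed + 1).
#' @return List of class `chromatin_sim` with `exons` (GRangesList),
#'   `segmentation` (GRanges with `state`), `expected` (gene_id, label
#'   at noise 0 adjusted for flips), and `flipped` (gene identifiers).
#' @export
simulate_chromatin_reference <- function(sim, tissue, noise_rate = 0,
                                         seed = NULL) {
  ts_assert(inherits(sim, "taa_simulation"), "need a taa_simulation",
            "ts_config_error")
  ts_assert(is.numeric(noise_rate) && noise_rate >= 0 && noise_rate <= 1,
            "noise_rate must lie in [0, 1]", "ts_parameter_error")
  ts_assert(tissue %in% colnames(sim$truth$latent_tissue),
            paste0("unknown tissue: ", tissue), "ts_parameter_error")
  cols <- sim$sample_map$sample_id[sim$sample_map$tissue == tissue]
  lat <- sim$truth$latent_normal[, cols, drop = FALSE]
  expressed <- rowMeans(lat) > 0.5
  genes <- rownames(lat)
  n <- length(genes)
  if (is.null(seed)) seed <- sim$config$seed + 1L
  set.seed(seed)
  n_flip <- round(noise_rate * n)
  flipped <- if (n_flip > 0) sort(sample(genes, n_flip)) else character(0)

  starts <- (seq_len(n) - 1L) * 10000L + 1L
  exons <- GenomicRanges::GRangesList(setNames(lapply(seq_len(n), function(i) {
    GenomicRanges::GRanges("chrS", IRanges::IRanges(
      start = c(starts[i], starts[i] + 1500L),
      end = c(starts[i] + 199L, starts[i] + 1999L)))
  }), genes))
  seg <- do.call(c, lapply(seq_len(n), function(i) {
    s <- starts[i]
    if (genes[i] %in% flipped) {
      GenomicRanges::GRanges("chrS",
        IRanges::IRanges(start = c(s, s + 500L), end = c(s + 199L, s + 1999L)),
        state = c(1L, 10L))
    } else if (expressed[i]) {
      GenomicRanges::GRanges("chrS",
        IRanges::IRanges(start = c(s, s + 500L), end = c(s + 199L, s + 1999L)),
        state = c(1L, 4L))
    } else {
      GenomicRanges::GRanges("chrS",
        IRanges::IRanges(start = s, end = s + 1999L), state = 13L)
    }
  }))
  label <- ifelse(genes %in% flipped, "ambiguous",
                  ifelse(expressed, "active", "inactive"))
  structure(list(exons = exons, segmentation = seg,
                 expected = data.frame(
                   gene_id = genes,
                   label = factor(label,
                                  levels = c("active", "inactive", "ambiguous")),
                   stringsAsFactors = FALSE),
                 flipped = flipped, tissue = tissue),
            class = "chromatin_sim")
}
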