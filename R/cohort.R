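#' Assemble a cohort state matrix
#'
#' Bundles per-sample binary expression states with a sample-to-tissue (or
#' sample-to-cancer-type) mapping.
#'
#' @param states Integer matrix of 0/1 states, genes in rows (rownames = gene
#'   identifiers), samples in columns (colnames = sample identifiers).
#' @param tissue_of Either a named character vector mapping sample identifier
#'   to tissue/cohort label, or a two-column data frame with columns
#'   `sample_id` and `tissue`.
#' @return An object of class `cohort_states`.
#' @export
cohort_states <- function(states, tissue_of) {
  ts_assert(is.matrix(states) && !is.null(rownames(states)) &&
              !is.null(colnames(states)),
            "states must be a matrix with gene rownames and sample colnames",
            "ts_shape_error")
  ts_assert(all(states %in% c(0L, 1L)),
            "states must be strictly 0/1", "ts_shape_error")
  if (is.data.frame(tissue_of)) {
    ts_assert(all(c("sample_id", "tissue") %in% names(tissue_of)),
              "sample map needs columns sample_id and tissue",
              "ts_mapping_error")
    tissue_of <- setNames(as.character(tissue_of$tissue),
                          as.character(tissue_of$sample_id))
  }
  missing <- setdiff(colnames(states), names(tissue_of))
  ts_assert(length(missing) == 0,
            paste0("samples without a tissue label: ",
                   paste(head(missing, 10), collapse = ", ")),
            "ts_mapping_error", data = missing)
  dup <- names(tissue_of)[duplicated(names(tissue_of))]
  ts_assert(length(dup) == 0,
            paste0("samples mapped to more than one tissue: ",
                   paste(head(unique(dup), 10), collapse = ", ")),
            "ts_mapping_error", data = unique(dup))
  structure(
    list(states = states,
         tissue_of = tissue_of[colnames(states)]),
    class = "cohort_states"
  )
}

#' @export
print.cohort_states <- function(x, ...) {
  cat(sprintf("cohort_states: %d genes x %d samples, %d tissue(s): %s\n",
              nrow(x$states), ncol(x$states),
              length(unique(x$tissue_of)),
              paste(unique(x$tissue_of), collapse = ", ")))
  invisible(x)
}

#' Infer states for every sample of a cohort
#'
#' Runs the chosen single-sample method column by column over a TPM matrix
#' and assembles the binary calls into a [cohort_states()] object.
#'
#' @param tpm_matrix Numeric gene x sample TPM matrix with dimnames.
#' @param tissue_of Sample-to-tissue mapping (see [cohort_states()]).
#' @param housekeeping Housekeeping gene identifiers (required for
#'   `method = "variable"`).
#' @param method One of `"variable"` (the mixture posterior), `"zfpkm"`,
#'   `"enb"`, or `"fixed"`.
#' @param fixed_cutoff TPM cutoff when `method = "fixed"`.
#' @param zfpkm_threshold z-score threshold when `method = "zfpkm"`.
#' @param enb_prob Probability cutoff when `method = "enb"`.
#' @param ... Further arguments passed to the per-sample method.
#' @return A [cohort_states()] object; per-sample fits are attached as
#'   attribute `fits` (a named list) for the variable method.
#' @export
infer_cohort_states <- function(tpm_matrix, tissue_of, housekeeping = NULL,
                                method = c("variable", "zfpkm", "enb", "fixed"),
                                fixed_cutoff = 1, zfpkm_threshold = -3,
                                enb_prob = 0.01, ...) {
  method <- match.arg(method)
  ts_assert(is.matrix(tpm_matrix) && !is.null(rownames(tpm_matrix)) &&
              !is.null(colnames(tpm_matrix)),
            "tpm_matrix must have gene rownames and sample colnames",
            "ts_shape_error")
  states <- matrix(0L, nrow(tpm_matrix), ncol(tpm_matrix),
                   dimnames = dimnames(tpm_matrix))
  fits <- vector("list", ncol(tpm_matrix))
  names(fits) <- colnames(tpm_matrix)
  for (s in colnames(tpm_matrix)) {
    v <- setNames(tpm_matrix[, s], rownames(tpm_matrix))
    calls <- switch(method,
      variable = infer_sample_states(v, housekeeping, sample_id = s, ...),
      zfpkm = zfpkm_states(v, threshold = zfpkm_threshold, sample_id = s, ...),
      enb = enb_states(v, prob_cutoff = enb_prob, sample_id = s, ...),
      fixed = fixed_threshold_states(v, cutoff = fixed_cutoff, sample_id = s))
    states[, s] <- calls$state
    fits[[s]] <- attr(calls, "fit")
    if (method == "variable") {
      f <- fits[[s]]
      ts_log("info", sprintf(
        "sample %s: pi_e = %.3f, %d EM iterations, converged = %s",
        s, f$pi_e, f$n_iter, f$converged))
    }
  }
  out <- cohort_states(states, tissue_of)
  attr(out, "fits") <- fits
  attr(out, "method") <- method
  out
}

#' Tissue-level non-expressed and expressed ratios
#'
#' For every gene and tissue with `m` samples, the non-expressed ratio is
#' `sum_n (1 - state_n) / m` — the fraction of that tissue's samples in which
#' the gene is called not expressed.
#'
#' @param cohort A [cohort_states()] object.
#' @param min_m Tissues with fewer samples than this trigger a logged warning
#'   (ratios are still computed as-is).
#' @return Data frame with columns `gene_id`, `tissue`, `m`,
#'   `non_expressed_ratio`, `expressed_ratio`; one row per gene x tissue.
#' @export
tissue_ratios <- function(cohort, min_m = 10L) {
  ts_assert(inherits(cohort, "cohort_states"), "need a cohort_states object",
            "ts_shape_error")
  tissues <- unique(unname(cohort$tissue_of))
  out <- lapply(tissues, function(tt) {
    cols <- names(cohort$tissue_of)[cohort$tissue_of == tt]
    m <- length(cols)
    if (m < min_m) {
      ts_log("warn", sprintf("tissue %s has only %d samples (< %d)",
                             tt, m, min_m))
    }
    ne <- rowSums(1L - cohort$states[, cols, drop = FALSE]) / m
    data.frame(gene_id = rownames(cohort$states), tissue = tt, m = m,
               non_expressed_ratio = ne, expressed_ratio = 1 - ne,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Identify dormant genes across a normal-tissue atlas
#'
#' A gene is dormant when its non-expressed ratio is at least `ratio_cutoff`
#' in every normal tissue except testis. Dormant genes with a testicular
#' expressed ratio strictly above `testis_exclusive_cutoff` are classified
#' `testis_exclusive`; the rest are `silent_everywhere`.
#'
#' @param summaries Output of [tissue_ratios()] over the normal atlas.
#' @param testis_label Tissue label of the testis-like tissue; may be absent
#'   from the summaries, in which case every tissue must pass the cutoff and
#'   all dormant genes are `silent_everywhere`.
#' @param ratio_cutoff Dormancy cutoff on the non-expressed ratio
#'   (default 0.9, inclusive).
#' @param testis_exclusive_cutoff Testis expressed-ratio cutoff (default
#'   0.10, strict).
#' @return Data frame with columns `gene_id`,
#'   `min_non_expressed_ratio`, `testis_expressed_ratio` (NA when the atlas
#'   has no testis tissue), `category`.
#' @export
identify_dormant_genes <- function(summaries, testis_label = "testis",
                                   ratio_cutoff = 0.9,
                                   testis_exclusive_cutoff = 0.10) {
  ts_assert(all(c("gene_id", "tissue", "non_expressed_ratio",
                  "expressed_ratio") %in% names(summaries)),
            "summaries must come from tissue_ratios()", "ts_shape_error")
  ts_assert(ratio_cutoff > 0 && ratio_cutoff <= 1,
            "ratio_cutoff must be in (0, 1]", "ts_parameter_error")
  non_testis <- summaries[summaries$tissue != testis_label, , drop = FALSE]
  ts_assert(nrow(non_testis) > 0, "no non-testis tissues in the summaries",
            "ts_incomplete_atlas")
  genes <- unique(summaries$gene_id)
  tissues <- unique(non_testis$tissue)
  # completeness: every gene needs a summary in every non-testis tissue
  tab <- table(non_testis$gene_id)[genes]
  tab[is.na(tab)] <- 0L
  if (any(tab != length(tissues))) {
    bad_gene <- genes[which(tab != length(tissues))[1]]
    bad_tissue <- setdiff(tissues,
                          non_testis$tissue[non_testis$gene_id == bad_gene])
    ts_abort(sprintf("incomplete atlas: gene %s has no summary for tissue %s",
                     bad_gene,
                     paste(head(bad_tissue, 3), collapse = ", ")),
             "ts_incomplete_atlas",
             data = list(gene = bad_gene, tissue = bad_tissue))
  }
  min_ratio <- tapply(non_testis$non_expressed_ratio, non_testis$gene_id, min)
  min_ratio <- min_ratio[genes]
  testis <- summaries[summaries$tissue == testis_label, , drop = FALSE]
  testis_ratio <- setNames(rep(NA_real_, length(genes)), genes)
  if (nrow(testis) > 0) {
    testis_ratio[testis$gene_id] <- testis$expressed_ratio
  }
  keep <- min_ratio >= ratio_cutoff
  gid <- genes[keep]
  tr <- unname(testis_ratio[gid])
  category <- ifelse(!is.na(tr) & tr > testis_exclusive_cutoff,
                     "testis_exclusive", "silent_everywhere")
  data.frame(gene_id = gid,
             min_non_expressed_ratio = unname(min_ratio[gid]),
             testis_expressed_ratio = tr,
             category = category,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Predict candidate tumor-associated antigens
#'
#' Dormant genes with an expressed state in at least `expressed_cutoff` of a
#' tumor cohort's samples are designated candidate TAAs. When the cohort
#' matrix carries several cancer-type labels, prediction runs per label;
#' results are concatenated, never pooled.
#'
#' @param tumor_cohort A [cohort_states()] object over tumor samples (labels
#'   are cancer types).
#' @param dormant Output of [identify_dormant_genes()].
#' @param expressed_cutoff Minimum tumor expressed ratio (default 0.05,
#'   inclusive).
#' @return Data frame with columns `gene_id`, `cancer_type`,
#'   `tumor_expressed_ratio`, `n_expressed`, `m`, and the list column
#'   `expressed_sample_ids`; annotation flags `membrane`, `known_cta`,
#'   `testis_specific` are initialized to `FALSE` (see
#'   [annotate_candidates()]).
#' @export
predict_taas <- function(tumor_cohort, dormant, expressed_cutoff = 0.05) {
  ts_assert(inherits(tumor_cohort, "cohort_states"),
            "need a cohort_states object", "ts_shape_error")
  ts_assert(is.data.frame(dormant) && nrow(dormant) > 0 &&
              "gene_id" %in% names(dormant),
            "dormant gene list must be a non-empty data frame",
            "ts_parameter_error")
  ts_assert(is.numeric(expressed_cutoff) && length(expressed_cutoff) == 1 &&
              expressed_cutoff > 0 && expressed_cutoff <= 1,
            "expressed_cutoff must lie in (0, 1]", "ts_parameter_error")
  present <- intersect(dormant$gene_id, rownames(tumor_cohort$states))
  absent <- setdiff(dormant$gene_id, present)
  if (length(absent) > 0) {
    ts_log("warn", sprintf(
      "%d dormant gene(s) absent from the tumor matrix, excluded: %s",
      length(absent), paste(head(absent, 5), collapse = ", ")))
  }
  cohorts <- unique(unname(tumor_cohort$tissue_of))
  res <- lapply(cohorts, function(ct) {
    cols <- names(tumor_cohort$tissue_of)[tumor_cohort$tissue_of == ct]
    sub <- tumor_cohort$states[present, cols, drop = FALSE]
    ratio <- rowMeans(sub)
    keep <- ratio >= expressed_cutoff
    gid <- present[keep]
    if (length(gid) == 0) {
      return(data.frame(gene_id = character(0), cancer_type = character(0),
                        tumor_expressed_ratio = numeric(0),
                        n_expressed = integer(0), m = integer(0),
                        expressed_sample_ids = I(list()),
                        membrane = logical(0), known_cta = logical(0),
                        testis_specific = logical(0)))
    }
    expressed_ids <- lapply(gid, function(g) cols[sub[g, ] == 1L])
    data.frame(gene_id = gid, cancer_type = ct,
               tumor_expressed_ratio = unname(ratio[keep]),
               n_expressed = vapply(expressed_ids, length, integer(1)),
               m = length(cols),
               expressed_sample_ids = I(expressed_ids),
               membrane = FALSE, known_cta = FALSE, testis_specific = FALSE,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Annotate candidate TAAs with gene-set memberships
#'
#' Flags each candidate by membership in the membrane-protein (surfaceome),
#' known cancer/testis antigen, and testis-specific protein lists. Missing or
#' empty lists leave the corresponding flag `FALSE` for every candidate (with
#' a logged warning).
#'
#' @param candidates Output of [predict_taas()].
#' @param membrane,cta,testis_specific Character vectors of gene identifiers
#'   (may be empty or `NULL`).
#' @return `candidates` with the `membrane`, `known_cta`, `testis_specific`
#'   columns filled in.
#' @export
annotate_candidates <- function(candidates, membrane = character(),
                                cta = character(),
                                testis_specific = character()) {
  sets <- list(membrane = membrane, known_cta = cta,
               testis_specific = testis_specific)
  for (nm in names(sets)) {
    s <- sets[[nm]]
    if (is.null(s) || length(s) == 0) {
      ts_log("warn", sprintf("annotation list '%s' is empty; flags all FALSE", nm))
      candidates[[nm]] <- FALSE
    } else {
      candidates[[nm]] <- candidates$gene_id %in% s
      ts_log("info", sprintf("%d candidate(s) flagged %s",
                             sum(candidates[[nm]]), nm))
    }
  }
  candidates
}

#' Candidate counts across a sweep of expressed-ratio cutoffs
#'
#' @param tumor_cohort A [cohort_states()] object over tumor samples.
#' @param dormant Output of [identify_dormant_genes()].
#' @param cutoffs Strictly increasing vector of cutoffs, each in (0, 1].
#' @return Data frame with columns `cutoff`, `cancer_type`,
#'   `candidate_count`; counts are non-increasing in the cutoff within each
#'   cancer type.
#' @export
cutoff_sweep <- function(tumor_cohort, dormant, cutoffs) {
  ts_assert(is.numeric(cutoffs) && length(cutoffs) > 0 &&
              all(cutoffs > 0 & cutoffs <= 1),
            "cutoffs must lie in (0, 1]", "ts_parameter_error")
  ts_assert(!is.unsorted(cutoffs, strictly = TRUE),
            "cutoffs must be sorted in strictly ascending order",
            "ts_parameter_error")
  rows <- lapply(cutoffs, function(ct) {
    cand <- predict_taas(tumor_cohort, dormant, expressed_cutoff = ct)
    agg <- table(factor(cand$cancer_type,
                        levels = unique(unname(tumor_cohort$tissue_of))))
    data.frame(cutoff = ct, cancer_type = names(agg),
               candidate_count = as.integer(agg),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
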