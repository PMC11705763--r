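#' Assemble and validate a pipeline run configuration
#'
#' All thresholds default to the published operating points (posterior 0.5,
#' dormancy non-expressed ratio 0.9, tumor expressed ratio 0.05,
#' testis-exclusive 0.10, zFPKM -3, EnB 0.01) but are tunable, anticipating
#' use cases where some normal-tissue expression is acceptable.
#'
#' @param normal_expression Path to the normal-atlas matrix (GCT or TSV).
#' @param tumor_expression Named character vector of tumor matrix paths; the
#'   names are the cancer-type labels.
#' @param sample_map Path to the sample-to-tissue TSV for normal samples.
#' @param housekeeping Path to the housekeeping gene list.
#' @param out_dir Output directory.
#' @param method State-calling method (`"variable"`, `"zfpkm"`, `"enb"`,
#'   `"fixed"`).
#' @param fixed_cutoff TPM cutoff when `method = "fixed"`.
#' @param dormancy_cutoff,taa_cutoff,testis_exclusive_cutoff,zfpkm_threshold,enb_prob
#'   Workflow thresholds (see the defaults above).
#' @param testis_label Tissue label treated as testis.
#' @param em List of EM settings (`tol`, `max_iter`, `restarts`).
#' @param membrane,cta,testis_specific Optional paths to annotation gene
#'   lists.
#' @param seed Integer seed (covers EM restart jitter).
#' @param log_level `"debug"`, `"info"`, or `"warn"`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(normal_expression, tumor_expression, sample_map,
                       housekeeping, out_dir,
                       method = c("variable", "zfpkm", "enb", "fixed"),
                       fixed_cutoff = 1,
                       dormancy_cutoff = 0.9, taa_cutoff = 0.05,
                       testis_exclusive_cutoff = 0.10,
                       zfpkm_threshold = -3, enb_prob = 0.01,
                       testis_label = "testis",
                       em = list(tol = 1e-8, max_iter = 1000L, restarts = 3L),
                       membrane = NULL, cta = NULL, testis_specific = NULL,
                       seed = 1L, log_level = "info") {
  method <- match.arg(method)
  ts_assert(dormancy_cutoff > 0 && dormancy_cutoff <= 1 &&
              taa_cutoff > 0 && taa_cutoff <= 1 &&
              testis_exclusive_cutoff >= 0 && testis_exclusive_cutoff < 1,
            "cutoffs out of their documented domains", "ts_parameter_error")
  ts_assert(enb_prob > 0 && enb_prob < 1, "enb_prob must lie in (0, 1)",
            "ts_parameter_error")
  ts_assert(length(tumor_expression) >= 1 &&
              !is.null(names(tumor_expression)) &&
              all(nzchar(names(tumor_expression))),
            "tumor_expression must be a named vector of paths (names = cancer types)",
            "ts_parameter_error")
  structure(list(normal_expression = normal_expression,
                 tumor_expression = tumor_expression,
                 sample_map = sample_map, housekeeping = housekeeping,
                 out_dir = out_dir, method = method,
                 fixed_cutoff = fixed_cutoff,
                 dormancy_cutoff = dormancy_cutoff, taa_cutoff = taa_cutoff,
                 testis_exclusive_cutoff = testis_exclusive_cutoff,
                 zfpkm_threshold = zfpkm_threshold, enb_prob = enb_prob,
                 testis_label = testis_label, em = em,
                 membrane = membrane, cta = cta,
                 testis_specific = testis_specific,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys mirror the [run_config()]
#'   arguments (`tumor_expression` given as a name -> path mapping).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  ts_assert(file.exists(path), paste0("no such file: ", path), "ts_io_error")
  y <- yaml::read_yaml(path)
  if (!is.null(y$tumor_expression)) {
    y$tumor_expression <- unlist(y$tumor_expression)
  }
  do.call(run_config, y)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

flatten_candidates <- function(cand) {
  if (is.null(cand) || nrow(cand) == 0) {
    return(data.frame(gene_id = character(0), cancer_type = character(0),
                      tumor_expressed_ratio = numeric(0),
                      n_expressed = integer(0), m = integer(0),
                      annotations = character(0),
                      expressed_sample_ids = character(0)))
  }
  flags <- c("membrane", "known_cta", "testis_specific")
  ann <- apply(cand[flags], 1, function(r) {
    paste(flags[as.logical(r)], collapse = ";")
  })
  data.frame(gene_id = cand$gene_id, cancer_type = cand$cancer_type,
             tumor_expressed_ratio = cand$tumor_expressed_ratio,
             n_expressed = cand$n_expressed, m = cand$m,
             annotations = ann,
             expressed_sample_ids = vapply(cand$expressed_sample_ids,
                                           paste, character(1),
                                           collapse = ","),
             stringsAsFactors = FALSE)
}

#' Run the full TAA-prediction workflow
#'
#' Stage 1 infers per-sample states over the normal atlas; stage 2 does the
#' same over each tumor cohort; stage 3 aggregates tissue ratios, identifies
#' dormant genes, and intersects them with tumor-expressed genes to produce
#' candidate TAAs; stage 4 writes annotation flags and the cross-tissue
#' expressed-ratio table for the candidate genes. Every artifact lands in
#' `config$out_dir`, together with a JSON manifest recording the
#' configuration, seed, and package version. On a stage failure the manifest
#' is written with a `FAILED` marker for that stage (earlier outputs are
#' retained) and a classed error naming the stage is signalled.
#'
#' @param config A [run_config()], or a path to a YAML file for
#'   [read_run_config()].
#' @return (Invisibly) a list with the dormant table, the candidate table,
#'   the tissue ratios, and the manifest.
#' @export
run_taa_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  ts_assert(inherits(config, "run_config"), "config must be a run_config",
            "ts_parameter_error")
  old <- options(taascreen.log_level = config$log_level)
  on.exit(options(old), add = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(
    package = "taascreen",
    version = as.character(packageVersion("taascreen")),
    seed = config$seed,
    config = unclass(config),
    stages = list()
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "FAILED",
                                      error = conditionMessage(e))
    write_manifest()
    ts_abort(sprintf("pipeline stage %s failed: %s", stage,
                     conditionMessage(e)),
             c("ts_stage_error", paste0("ts_stage_", stage)))
  }
  hk <- NULL # assigned in stage 1, reused by stage 2
  infer <- function(mat, map) {
    infer_cohort_states(mat, map, housekeeping = hk, method = config$method,
                        fixed_cutoff = config$fixed_cutoff,
                        zfpkm_threshold = config$zfpkm_threshold,
                        enb_prob = config$enb_prob)
  }
  dump_states <- function(cohort, stem) {
    df <- data.frame(gene_id = rownames(cohort$states), cohort$states,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, file.path(config$out_dir, paste0(stem, "_states.tsv")))
    fits <- attr(cohort, "fits")
    if (!is.null(fits) && any(!vapply(fits, is.null, logical(1)))) {
      write_fit_summary(fits,
                        file.path(config$out_dir,
                                  paste0(stem, "_fit_summary.tsv")))
    }
  }

  # stage 1: normal atlas
  normal_cohort <- tryCatch({
    normal <- read_expression(config$normal_expression)
    map <- read_sample_map(config$sample_map)
    hk <- read_gene_list(config$housekeeping)
    cohort <- infer(normal, map)
    dump_states(cohort, "normal")
    manifest$stages$normal_inference <- list(status = "OK",
                                             n_genes = nrow(normal),
                                             n_samples = ncol(normal))
    cohort
  }, error = function(e) fail("normal_inference", e))

  # stage 2: tumor cohorts
  tumor_cohort <- tryCatch({
    mats <- lapply(names(config$tumor_expression), function(ct) {
      read_expression(config$tumor_expression[[ct]])
    })
    names(mats) <- names(config$tumor_expression)
    states <- NULL
    tissue_of <- character(0)
    for (ct in names(mats)) {
      map <- setNames(rep(ct, ncol(mats[[ct]])), colnames(mats[[ct]]))
      cohort <- infer(mats[[ct]], map)
      dump_states(cohort, paste0("tumor_", ct))
      states <- cbind(states, cohort$states)
      tissue_of <- c(tissue_of, map)
    }
    cohort <- cohort_states(states, tissue_of)
    manifest$stages$tumor_inference <- list(status = "OK",
                                            cohorts = names(mats))
    cohort
  }, error = function(e) fail("tumor_inference", e))

  # stage 3: dormant genes and candidate TAAs
  res <- tryCatch({
    ratios <- tissue_ratios(normal_cohort)
    write_tsv(ratios, file.path(config$out_dir, "tissue_ratios.tsv"))
    dormant <- identify_dormant_genes(
      ratios, testis_label = config$testis_label,
      ratio_cutoff = config$dormancy_cutoff,
      testis_exclusive_cutoff = config$testis_exclusive_cutoff)
    write_tsv(dormant, file.path(config$out_dir, "dormant_genes.tsv"))
    candidates <- if (nrow(dormant) > 0) {
      predict_taas(tumor_cohort, dormant,
                   expressed_cutoff = config$taa_cutoff)
    } else NULL
    manifest$stages$taa_prediction <- list(
      status = "OK", n_dormant = nrow(dormant),
      n_candidates = if (is.null(candidates)) 0L else nrow(candidates))
    list(ratios = ratios, dormant = dormant, candidates = candidates)
  }, error = function(e) fail("taa_prediction", e))

  # stage 4: annotation flags and cross-tissue ratio table
  res$candidates <- tryCatch({
    cand <- res$candidates
    if (!is.null(cand) && nrow(cand) > 0) {
      load_list <- function(p) if (is.null(p)) character(0) else read_gene_list(p)
      cand <- annotate_candidates(cand,
                                  membrane = load_list(config$membrane),
                                  cta = load_list(config$cta),
                                  testis_specific = load_list(config$testis_specific))
      cross <- res$ratios[res$ratios$gene_id %in% cand$gene_id,
                          c("gene_id", "tissue", "expressed_ratio")]
      write_tsv(cross, file.path(config$out_dir, "cross_tissue_ratios.tsv"))
    }
    write_tsv(flatten_candidates(cand),
              file.path(config$out_dir, "taa_candidates.tsv"))
    manifest$stages$annotation <- list(status = "OK")
    cand
  }, error = function(e) fail("annotation", e))

  write_manifest()
  ts_log("info", sprintf("pipeline complete: %d dormant gene(s), %d candidate TAA(s)",
                         nrow(res$dormant),
                         if (is.null(res$candidates)) 0L else nrow(res$candidates)))
  invisible(list(dormant = res$dormant, candidates = res$candidates,
                 ratios = res$ratios, manifest = manifest,
                 out_dir = config$out_dir))
}
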