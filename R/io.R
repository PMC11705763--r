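#' Read an expression matrix in GCT 1.2 format
#'
#' Expects the `#1.2` version line, a dimensions line (`n_genes<TAB>n_samples`),
#' and a body whose first two columns are `Name` and `Description`.
#'
#' @param path Path to the GCT file.
#' @return Numeric gene x sample matrix (gene identifiers as rownames).
#' @export
read_gct <- function(path) {
  ts_assert(file.exists(path), paste0("no such file: ", path), "ts_io_error")
  header <- readLines(path, n = 2)
  ts_assert(length(header) >= 2 && trimws(header[1]) == "#1.2",
            sprintf("malformed GCT header: expected '#1.2', got '%s'",
                    header[1]),
            "ts_gct_version")
  dims <- suppressWarnings(as.integer(strsplit(header[2], "\t")[[1]]))
  ts_assert(length(dims) >= 2 && !anyNA(dims[1:2]),
            "malformed GCT dimensions line", "ts_gct_version")
  body <- read.delim(path, skip = 2, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
  ts_assert(ncol(body) >= 3, "GCT body needs Name, Description and samples",
            "ts_io_error")
  ts_assert(nrow(body) == dims[1] && ncol(body) - 2L == dims[2],
            sprintf(paste0("GCT dimension mismatch: header says %d genes x ",
                           "%d samples, body has %d x %d"),
                    dims[1], dims[2], nrow(body), ncol(body) - 2L),
            "ts_dimension_mismatch")
  gene_ids <- as.character(body[[1]])
  values_to_matrix(body[, -(1:2), drop = FALSE], gene_ids, path)
}

# shared validation for matrix bodies
values_to_matrix <- function(df, gene_ids, path) {
  dup <- gene_ids[duplicated(gene_ids)]
  ts_assert(length(dup) == 0,
            paste0("duplicated gene identifier(s) in ", path, ": ",
                   paste(head(unique(dup), 5), collapse = ", ")),
            "ts_duplicate_id", data = unique(dup))
  mat <- as.matrix(df)
  mode(mat) <- "numeric"
  ts_assert(!anyNA(mat), paste0("non-numeric or missing values in ", path),
            "ts_io_error")
  ts_assert(all(mat >= 0), paste0("negative abundances in ", path),
            "ts_io_error")
  rownames(mat) <- gene_ids
  mat
}

#' Write an expression matrix in GCT 1.2 format
#'
#' @param mat Numeric gene x sample matrix with dimnames.
#' @param path Output path.
#' @param description Optional per-gene description column (defaults to the
#'   gene identifier).
#' @export
write_gct <- function(mat, path, description = NULL) {
  ts_assert(is.matrix(mat) && !is.null(rownames(mat)) &&
              !is.null(colnames(mat)),
            "matrix must carry gene rownames and sample colnames",
            "ts_shape_error")
  if (is.null(description)) description <- rownames(mat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
  df <- data.frame(Name = rownames(mat), Description = description,
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from plain TSV
#'
#' First column holds gene identifiers; remaining columns are samples.
#'
#' @param path Path to the TSV file.
#' @return Numeric gene x sample matrix.
#' @export
read_expression_tsv <- function(path) {
  ts_assert(file.exists(path), paste0("no such file: ", path), "ts_io_error")
  body <- read.delim(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
  ts_assert(ncol(body) >= 2, "TSV needs a gene column plus >= 1 sample",
            "ts_io_error")
  values_to_matrix(body[, -1, drop = FALSE], as.character(body[[1]]), path)
}

#' Read an expression matrix, dispatching on format
#'
#' @param path Path to the file.
#' @param format `"auto"` (GCT when the file starts with `#1.2` or has a
#'   `.gct` extension), `"gct"`, or `"tsv"`.
#' @return Numeric gene x sample matrix.
#' @export
read_expression <- function(path, format = c("auto", "gct", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ts_assert(file.exists(path), paste0("no such file: ", path), "ts_io_error")
    first <- readLines(path, n = 1)
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE) ||
                  identical(trimws(first), "#1.2")) "gct" else "tsv"
  }
  switch(format, gct = read_gct(path), tsv = read_expression_tsv(path))
}

#' Read a plain-text gene list
#'
#' One identifier per line; `#` comments and blank lines are ignored.
#'
#' @param path Path to the list.
#' @return Character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  ts_assert(file.exists(path), paste0("no such file: ", path), "ts_io_error")
  lines <- trimws(readLines(path))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Read a sample-to-tissue mapping table
#'
#' Two-column TSV with header `sample_id`, `tissue` (any two columns are
#' accepted positionally).
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `sample_id`, `tissue`.
#' @export
read_sample_map <- function(path) {
  ts_assert(file.exists(path), paste0("no such file: ", path), "ts_io_error")
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  ts_assert(ncol(df) >= 2, "sample map needs two columns", "ts_mapping_error")
  out <- data.frame(sample_id = as.character(df[[1]]),
                    tissue = as.character(df[[2]]),
                    stringsAsFactors = FALSE)
  dup <- out$sample_id[duplicated(out$sample_id)]
  ts_assert(length(dup) == 0,
            paste0("duplicated sample identifier(s): ",
                   paste(head(unique(dup), 5), collapse = ", ")),
            "ts_mapping_error")
  out
}

#' Write per-sample state calls as TSV
#'
#' @param calls A `state_call_set` or a list of them.
#' @param path Output path.
#' @export
write_state_table <- function(calls, path) {
  if (inherits(calls, "state_call_set")) calls <- list(calls)
  df <- do.call(rbind, lapply(calls, function(cs) {
    data.frame(gene_id = cs$gene_id,
               sample_id = attr(cs, "sample_id"),
               tpm = cs$tpm, posterior = cs$posterior, state = cs$state,
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-sample mixture-fit summaries as TSV
#'
#' @param fits Named list of [mixture_fit()] objects (names = sample ids).
#' @param path Output path.
#' @export
write_fit_summary <- function(fits, path) {
  df <- do.call(rbind, lapply(names(fits), function(s) {
    f <- fits[[s]]
    if (is.null(f) || !inherits(f, "mixture_fit")) return(NULL)
    data.frame(sample_id = s, pi_e = f$pi_e,
               mu_ne = f$mu_ne, sigma_ne = f$sigma_ne,
               mu_e = f$mu_e, sigma_e = f$sigma_e,
               n_iter = f$n_iter, converged = f$converged,
               log_likelihood = f$log_likelihood,
               n_fitted = f$n_fitted, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulated cohorts to disk in the formats the pipeline reads
#'
#' Emits the normal-atlas matrix, one matrix per tumor cohort, the sample
#' map, the housekeeping list, and the truth tables.
#'
#' @param sim A `taa_simulation` (see [simulate_cohorts()]).
#' @param dir Output directory (created if missing).
#' @param format `"gct"` or `"tsv"` for the matrices.
#' @return Named list of written paths.
#' @export
write_simulation <- function(sim, dir, format = c("gct", "tsv")) {
  format <- match.arg(format)
  ts_assert(inherits(sim, "taa_simulation"), "need a taa_simulation",
            "ts_config_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix <- function(mat, stem) {
    p <- file.path(dir, paste0(stem, ".", format))
    if (format == "gct") write_gct(mat, p) else {
      df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                       stringsAsFactors = FALSE)
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    p
  }
  paths <- list(normal = write_matrix(sim$normal, "normal_tpm"))
  for (nm in names(sim$tumors)) {
    paths[[paste0("tumor_", nm)]] <-
      write_matrix(sim$tumors[[nm]], paste0("tumor_", nm, "_tpm"))
  }
  paths$sample_map <- file.path(dir, "sample_map.tsv")
  write.table(sim$sample_map, paths$sample_map, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$housekeeping <- file.path(dir, "housekeeping.txt")
  writeLines(sim$housekeeping, paths$housekeeping)
  paths$truth_dormant <- file.path(dir, "truth_dormant.tsv")
  write.table(sim$truth$dormant, paths$truth_dormant, sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth$taa)) {
    paths$truth_taa <- file.path(dir, "truth_taa.tsv")
    write.table(sim$truth$taa, paths$truth_taa, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  paths
}

#' Write a simulated chromatin fixture as BED files
#'
#' @param chrom A `chromatin_sim` (see [simulate_chromatin_reference()]).
#' @param dir Output directory.
#' @return List with `segmentation` (BED4, state as `E<k>` labels) and
#'   `gene_models` (BED12) paths.
#' @export
write_chromatin_fixture <- function(chrom, dir) {
  ts_assert(inherits(chrom, "chromatin_sim"), "need a chromatin_sim",
            "ts_config_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg <- chrom$segmentation
  S4Vectors::mcols(seg)$name <-
    paste0("E", S4Vectors::mcols(seg)$state)
  S4Vectors::mcols(seg)$state <- NULL
  seg_path <- file.path(dir, "segmentation.bed")
  rtracklayer::export(seg, seg_path, format = "BED")
  gm_path <- file.path(dir, "gene_models.bed")
  rtracklayer::export(rtracklayer::asBED(chrom$exons), gm_path,
                      format = "BED")
  list(segmentation = seg_path, gene_models = gm_path)
}
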