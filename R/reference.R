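#' Read a chromHMM-style chromatin-state segmentation
#'
#' Expects BED4 with the 15-state label in the name column, either as
#' `"E1"`..`"E15"` or bare `"1"`..`"15"`.
#'
#' @param path Path to the BED file.
#' @return A `GRanges` with an integer metadata column `state`.
#' @export
read_chromatin_segmentation <- function(path) {
  ts_assert(file.exists(path), paste0("no such file: ", path), "ts_io_error")
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  ts_assert(!is.null(nm), "segmentation BED needs a state label in column 4",
            "ts_io_error")
  state <- suppressWarnings(as.integer(sub("^E", "", nm)))
  bad <- is.na(state) | state < 1L | state > 15L
  ts_assert(!any(bad),
            paste0("invalid chromatin-state labels: ",
                   paste(head(unique(nm[bad]), 5), collapse = ", ")),
            "ts_io_error")
  S4Vectors::mcols(gr)$state <- state
  gr
}

#' Read gene models as per-gene exon intervals
#'
#' Accepts BED12 (exon blocks, gene identifier in the name column) or GTF
#' (exon features aggregated by `gene_id`).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"bed12"`, or `"gtf"`.
#' @return A named `GRangesList` of exon intervals, one element per gene.
#' @export
read_gene_models <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  ts_assert(file.exists(path), paste0("no such file: ", path), "ts_io_error")
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "GTF")
    gr <- gr[!is.na(S4Vectors::mcols(gr)$type) &
               S4Vectors::mcols(gr)$type == "exon"]
    ts_assert(length(gr) > 0, "no exon features in the GTF", "ts_io_error")
    gid <- S4Vectors::mcols(gr)$gene_id
    ts_assert(!is.null(gid) && !anyNA(gid),
              "GTF exon records must carry gene_id", "ts_io_error")
    exons <- GenomicRanges::split(gr, gid)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    ts_assert(!is.null(S4Vectors::mcols(gr)$blocks),
              "BED12 exon blocks (columns 10-12) are required", "ts_io_error")
    exons <- rtracklayer::blocks(gr)
    names(exons) <- S4Vectors::mcols(gr)$name
  }
  dup <- names(exons)[duplicated(names(exons))]
  ts_assert(length(dup) == 0,
            paste0("duplicated gene identifiers in gene models: ",
                   paste(head(unique(dup), 5), collapse = ", ")),
            "ts_duplicate_id")
  exons
}

#' Overlap gene models with a chromatin-state segmentation
#'
#' Records, per gene, the set of chromatin states whose segments overlap
#' (i) its exons and (ii) its gene body (the range spanned by its exons).
#'
#' @param exons Named `GRangesList` of per-gene exon intervals
#'   (see [read_gene_models()]).
#' @param segmentation `GRanges` with integer `state` column
#'   (see [read_chromatin_segmentation()]).
#' @return A `chromatin_annotation`: data frame with `gene_id` and list
#'   columns `exon_states`, `body_states`.
#' @export
annotate_chromatin <- function(exons, segmentation) {
  ts_assert(methods::is(exons, "GRangesList") && length(exons) > 0 &&
              !is.null(names(exons)),
            "exons must be a named GRangesList", "ts_annotation_error")
  n_exons <- S4Vectors::elementNROWS(exons)
  ts_assert(all(n_exons > 0),
            paste0("gene(s) without exon intervals: ",
                   paste(head(names(exons)[n_exons == 0], 5), collapse = ", ")),
            "ts_annotation_error")
  st <- S4Vectors::mcols(segmentation)$state
  ts_assert(!is.null(st) && all(st %in% 1:15),
            "segmentation must carry integer states 1..15",
            "ts_annotation_error")
  collect_states <- function(query) {
    hits <- GenomicRanges::findOverlaps(query, segmentation)
    split(st[S4Vectors::subjectHits(hits)],
          factor(S4Vectors::queryHits(hits), levels = seq_along(query)))
  }
  exon_states <- lapply(collect_states(exons), unique)
  body <- unlist(range(exons))
  body_states <- lapply(collect_states(body), unique)
  structure(
    data.frame(gene_id = names(exons),
               exon_states = I(unname(exon_states)),
               body_states = I(unname(body_states)),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("chromatin_annotation", "data.frame")
  )
}

#' Build the chromatin-state reference standard
#'
#' Labels each gene `active`, `inactive`, or `ambiguous` from its overlapping
#' chromatin states. A gene is active when all three hold: (1) at least one
#' active promoter or promoter-flanking mark (states 1-2) overlaps its exons;
#' (2) at least one active transcription mark (states 3-5) overlaps its
#' transcription span; (3) no repressed mark (states 9-15) overlaps it. A
#' gene is inactive when it lacks every active promoter or transcription mark
#' (states 1-5) and carries at least one repressed mark (states 9-15). Genes
#' satisfying neither conjunction are ambiguous and are excluded from all
#' benchmark metrics.
#'
#' @param annotation A `chromatin_annotation` (see [annotate_chromatin()]).
#' @param transcription_span Region the transcription marks (states 3-5) must
#'   overlap: the whole gene `"body"` (default) or the `"exons"` only.
#' @return Data frame with columns `gene_id` and `label` (factor with levels
#'   `active`, `inactive`, `ambiguous`).
#' @export
build_reference_standard <- function(annotation,
                                     transcription_span = c("body", "exons")) {
  transcription_span <- match.arg(transcription_span)
  ts_assert(inherits(annotation, "chromatin_annotation"),
            "need a chromatin_annotation (see annotate_chromatin())",
            "ts_annotation_error")
  label <- vapply(seq_len(nrow(annotation)), function(i) {
    e <- annotation$exon_states[[i]]
    b <- annotation$body_states[[i]]
    tr <- if (transcription_span == "body") b else e
    promoter <- any(e %in% 1:2)
    transcription <- any(tr %in% 3:5)
    repressed <- any(b %in% 9:15)
    if (promoter && transcription && !repressed) return("active")
    if (!any(b %in% 1:5) && repressed) return("inactive")
    "ambiguous"
  }, character(1))
  data.frame(gene_id = annotation$gene_id,
             label = factor(label, levels = c("active", "inactive",
                                              "ambiguous")),
             stringsAsFactors = FALSE, row.names = NULL)
}
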