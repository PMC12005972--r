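#' Estimate the false-positive detection rate from non-targeting barcodes
#'
#' Non-targeting barcode combinations have no matching primary probe, so any
#' spots decoded for them are false positives. The conservative rate is the
#' largest embryo-wide total over control barcodes divided by the number of
#' cells: e.g. a worst control with 200 spots over 11,029 cells gives ~0.018
#' spots per cell.
#'
#' @param sce Count matrix with `is_control` flags in `rowData`.
#' @return List: `fp_rate_per_cell`, `per_control` (named totals), `n_cells`.
#' @export
estimate_false_positive_rate <- function(sce) {
  ctrl <- SummarizedExperiment::rowData(sce)$is_control
  if (!any(ctrl)) stop("no control genes flagged in rowData", call. = FALSE)
  totals <- Matrix::rowSums(SummarizedExperiment::assay(sce, "counts"))[ctrl]
  list(fp_rate_per_cell = max(totals) / ncol(sce),
       per_control = totals,
       n_cells = ncol(sce))
}

#' Identify actively transcribed genes
#'
#' A gene is active iff its embryo-wide total spot count exceeds `min_total`
#' and it is not a control. By default the threshold is data-driven: the
#' maximum total observed over the non-targeting controls (the conservative
#' "control ceiling"); 200 is the documented fallback when no controls are
#' present.
#'
#' @param sce Count matrix.
#' @param min_total Threshold; `NULL` (default) uses the max control total.
#' @return Character vector of active gene names; the threshold used is in
#'   attribute `min_total`.
#' @export
filter_active_genes <- function(sce, min_total = NULL) {
  totals <- Matrix::rowSums(SummarizedExperiment::assay(sce, "counts"))
  ctrl <- SummarizedExperiment::rowData(sce)$is_control
  if (is.null(min_total)) {
    min_total <- if (any(ctrl)) max(totals[ctrl]) else 200
  }
  if (min_total < 0) stop("'min_total' must be >= 0", call. = FALSE)
  active <- names(totals)[totals > min_total & !ctrl]
  attr(active, "min_total") <- min_total
  active
}

#' Flag low-count cells for exclusion
#'
#' A cell is excluded iff its total count over the active genes falls below
#' `min_cell_total`; a cell exactly at the threshold is retained. Excluded
#' cells are flagged, never dropped, so spot conservation holds downstream.
#'
#' @param sce Count matrix.
#' @param active Active gene set from [filter_active_genes()]; `NULL` uses
#'   all non-control genes.
#' @param min_cell_total Minimum per-cell total (default 10).
#' @return Integer vector of excluded cell ids; the updated `qc_excluded`
#'   flag vector is in attribute `flags`.
#' @export
filter_cells <- function(sce, active = NULL, min_cell_total = 10) {
  if (is.null(active)) {
    active <- rownames(sce)[!SummarizedExperiment::rowData(sce)$is_control]
  }
  totals <- Matrix::colSums(
    SummarizedExperiment::assay(sce, "counts")[active, , drop = FALSE])
  excl <- unname(totals < min_cell_total)
  out <- SummarizedExperiment::colData(sce)$cell[excl]
  attr(out, "flags") <- excl
  out
}

#' Detection rate by imaging cycle
#'
#' Mean total spot count per active gene, by the imaging cycle each gene was
#' read out in (from the codebook), with the linear trend of rate on cycle.
#' Detection is flagged stable when the 95% confidence interval of the trend
#' slope covers zero.
#'
#' @param sce Count matrix.
#' @param codebook Codebook mapping genes to cycles.
#' @param active Active gene set; `NULL` uses all non-control genes.
#' @return List: `per_cycle` (data.frame cycle, n_genes, mean_count),
#'   `slope`, `slope_ci`, `stable` (or `trend_undefined = TRUE` with a
#'   single cycle).
#' @export
detection_rate_by_cycle <- function(sce, codebook, active = NULL) {
  if (is.null(active)) {
    active <- rownames(sce)[!SummarizedExperiment::rowData(sce)$is_control]
  }
  totals <- Matrix::rowSums(
    SummarizedExperiment::assay(sce, "counts")[active, , drop = FALSE])
  cyc <- codebook$cycle[match(active, codebook$target)]
  if (anyNA(cyc)) stop("active genes missing from the codebook", call. = FALSE)
  per <- stats::aggregate(list(mean_count = totals), by = list(cycle = cyc),
                          FUN = mean)
  per$n_genes <- as.integer(table(cyc)[as.character(per$cycle)])
  if (nrow(per) < 2L) {
    return(list(per_cycle = per, slope = NA_real_,
                slope_ci = c(NA_real_, NA_real_),
                stable = NA, trend_undefined = TRUE))
  }
  fit <- stats::lm(mean_count ~ cycle, data = per)
  # a perfectly flat profile triggers the "essentially perfect fit" warning
  ci <- suppressWarnings(stats::confint(fit)["cycle", ])
  list(per_cycle = per,
       slope = unname(stats::coef(fit)["cycle"]),
       slope_ci = unname(ci),
       stable = ci[1] <= 0 && ci[2] >= 0,
       trend_undefined = FALSE)
}

#' Nuclear volume stability across imaging cycles
#'
#' Median per-nucleus volume for each cycle's segmentation and the maximum
#' relative drift from the first cycle — a check that the specimen did not
#' deform over multicycle imaging.
#'
#' @param volumes List of [label_volume()] objects, one per cycle, or a list
#'   of numeric per-nucleus volume vectors.
#' @return List: `median_volume_um3` per cycle, `max_relative_drift`.
#' @export
nuclear_volume_stability <- function(volumes) {
  if (length(volumes) == 0L) stop("'volumes' must be non-empty", call. = FALSE)
  med <- vapply(volumes, function(v) {
    if (inherits(v, "label_volume")) v <- label_volumes_um3(v)
    stats::median(as.numeric(v))
  }, 0)
  drift <- if (length(med) > 1L) max(abs(med - med[1]) / med[1]) else 0
  list(median_volume_um3 = med, max_relative_drift = drift)
}

#' Assemble a QC report
#'
#' Combines the false-positive estimate, active-gene and cell filters, and
#' the per-cycle detection-rate trend into one structure, serializable with
#' [write_qc_report()].
#'
#' @param sce Count matrix.
#' @param codebook Codebook.
#' @param min_total,min_cell_total Thresholds as in the individual filters.
#' @return A `qc_report` list.
#' @export
qc_report <- function(sce, codebook, min_total = NULL, min_cell_total = 10) {
  fp <- estimate_false_positive_rate(sce)
  active <- filter_active_genes(sce, min_total)
  excluded <- filter_cells(sce, active, min_cell_total)
  rate <- detection_rate_by_cycle(sce, codebook, active)
  structure(list(
    fp_rate_per_cell = fp$fp_rate_per_cell,
    per_control = fp$per_control,
    n_cells = fp$n_cells,
    active_genes = as.character(active),
    active_min_total = attr(active, "min_total"),
    excluded_cells = as.integer(excluded),
    min_cell_total = min_cell_total,
    detection_by_cycle = rate
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: fp rate %.4f spots/cell (worst of %d controls), %d active genes (threshold > %g), %d cells excluded (< %g counts)\n",
              x$fp_rate_per_cell, length(x$per_control),
              length(x$active_genes), x$active_min_total,
              length(x$excluded_cells), x$min_cell_total))
  if (!isTRUE(x$detection_by_cycle$trend_undefined)) {
    cat(sprintf("  detection trend: slope %.4g [%.4g, %.4g] per cycle — %s\n",
                x$detection_by_cycle$slope, x$detection_by_cycle$slope_ci[1],
                x$detection_by_cycle$slope_ci[2],
                if (isTRUE(x$detection_by_cycle$stable)) "stable" else "drifting"))
  }
  invisible(x)
}

#' @rdname qc_report
#' @param report A `qc_report`.
#' @param path Output JSON path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
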