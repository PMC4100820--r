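#' Relative abundance of each miRNA
#'
#' Each probe's processed value divided by the sample's total processed
#' counts, so per-sample fractions sum to one; cell-type averages are the
#' arithmetic means of the member samples' fractions, and probes are ranked
#' within each cell type by average abundance (descending, ties broken by
#' probe id).
#'
#' @param proc a [mir_processed()].
#' @return object of class `relative_abundance`: list with `per_sample`
#'   (probe x sample fraction matrix), `cell_type_avg` (probe x cell-type
#'   matrix), `ranks` (probe x cell-type integer matrix) and `samples`.
#' @export
relative_abundance <- function(proc) {
  stopifnot(inherits(proc, "mir_processed"))
  totals <- colSums(proc$values)
  if (any(totals <= 0)) {
    stop("validation error: all-zero sample(s): ",
         paste(colnames(proc$values)[totals <= 0], collapse = ", "))
  }
  per_sample <- sweep(proc$values, 2, totals, `/`)
  cts <- unique(proc$samples$cell_type)
  avg <- vapply(cts, function(ct) {
    rowMeans(per_sample[, proc$samples$cell_type == ct, drop = FALSE])
  }, numeric(nrow(per_sample)))
  # rank 1 = most abundant; ties broken by probe id
  ids <- rownames(avg)
  ranks <- vapply(colnames(avg), function(ct) {
    r <- integer(length(ids))
    r[order(-avg[, ct], ids)] <- seq_along(ids)
    r
  }, integer(length(ids)))
  rownames(ranks) <- ids
  structure(list(per_sample = per_sample, cell_type_avg = avg,
                 ranks = ranks, samples = proc$samples),
            class = "relative_abundance")
}

#' Union of each cell type's top-n most abundant miRNAs
#'
#' The probe panel used for cross-lineage clustering: every cell type
#' contributes its `n` most abundant probes (by cell-type average relative
#' abundance); the union is returned in deterministic order — first
#' appearance by cell type (column order), then by within-type rank.
#'
#' @param abund a [relative_abundance()].
#' @param n probes per cell type.
#' @return character vector of probe ids.
#' @export
top_n_union <- function(abund, n = 20L) {
  stopifnot(inherits(abund, "relative_abundance"))
  if (nrow(abund$cell_type_avg) < n) {
    stop("validation error: fewer probes than n")
  }
  out <- character(0)
  for (ct in colnames(abund$cell_type_avg)) {
    top <- rownames(abund$ranks)[order(abund$ranks[, ct])][seq_len(n)]
    out <- c(out, setdiff(top, out))
  }
  out
}

#' Detection and expression-level summary
#'
#' A probe is "detected" in a cell type when its cell-type mean processed
#' value is positive (`rule = "mean"`, default) or when any member sample is
#' positive (`rule = "any-sample"`). Expression classes are assigned on the
#' cell-type mean processed value: `not detected` (0), `low` (< `low`
#' counts), `high` (> `high` counts), `mid` otherwise.
#'
#' @param proc a [mir_processed()] (background-corrected).
#' @param low,high class boundaries on the processed count scale.
#' @param rule detection rule, `"mean"` or `"any-sample"`.
#' @return object of class `detection_summary`: list with
#'   `detected` (probe x cell-type logical), `class` (probe x cell-type
#'   character), `detected_in_n` (per probe, number of cell types),
#'   `n_detected_any`, `n_detected_all`, `n_not_detected`,
#'   `expressed_per_type` (mean over member samples of the number of probes
#'   above background), `low_per_type`, `high_per_type`.
#' @export
detection_summary <- function(proc, low = 10, high = 5000,
                              rule = c("mean", "any-sample")) {
  stopifnot(inherits(proc, "mir_processed"))
  rule <- match.arg(rule)
  if (low >= high) stop("configuration error: low must be < high")
  cts <- unique(proc$samples$cell_type)
  means <- vapply(cts, function(ct) {
    rowMeans(proc$values[, proc$samples$cell_type == ct, drop = FALSE])
  }, numeric(nrow(proc$values)))
  detected <- if (rule == "mean") {
    means > 0
  } else {
    vapply(cts, function(ct) {
      apply(proc$values[, proc$samples$cell_type == ct, drop = FALSE] > 0, 1, any)
    }, logical(nrow(proc$values)))
  }
  cls <- matrix("mid", nrow = nrow(means), ncol = ncol(means),
                dimnames = dimnames(means))
  cls[means == 0] <- "not detected"
  cls[means > 0 & means < low] <- "low"
  cls[means > high] <- "high"

  expressed_per_type <- vapply(cts, function(ct) {
    mean(colSums(proc$values[, proc$samples$cell_type == ct, drop = FALSE] > 0))
  }, numeric(1))
  detected_in_n <- rowSums(detected)
  structure(list(
    detected = detected, class = cls, detected_in_n = detected_in_n,
    n_detected_any = sum(detected_in_n > 0),
    n_detected_all = sum(detected_in_n == length(cts)),
    n_not_detected = sum(detected_in_n == 0),
    expressed_per_type = expressed_per_type,
    low_per_type = colSums(cls == "low"),
    high_per_type = colSums(cls == "high"),
    thresholds = c(low = low, high = high), rule = rule
  ), class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat(sprintf("detection_summary (%s rule): %d probes detected in >=1 cell type, %d in all, %d in none\n",
              x$rule, x$n_detected_any, x$n_detected_all, x$n_not_detected))
  invisible(x)
}
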