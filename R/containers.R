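#' Probe-level count experiment
#'
#' Container for a probe x sample count matrix from a hybridization-count
#' miRNA assay, together with probe classes and sample annotations. Probe
#' classes follow the platform convention: `Endogenous` probes target miRNAs,
#' `Negative` probes carry no target and estimate background, `Positive`
#' probes are spike-in controls.
#'
#' @param counts numeric matrix, probes x samples; non-negative; rownames are
#'   probe ids (unique), colnames are sample ids.
#' @param probe_class character vector, one of `"Endogenous"`, `"Negative"`,
#'   `"Positive"` per row of `counts`.
#' @param samples data.frame with columns `sample`, `donor`, `cell_type`
#'   annotating every column of `counts`.
#' @param codeset_version character scalar, assay codeset label.
#'
#' @return An object of class `mir_experiment`: a list with elements
#'   `counts`, `probe_class`, `samples`, `codeset_version`.
#' @export
mir_experiment <- function(counts, probe_class, samples, codeset_version = "v2") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) stop("validation error: counts must have probe-id rownames")
  if (is.null(colnames(counts))) stop("validation error: counts must have sample-id colnames")
  if (anyDuplicated(rownames(counts))) {
    stop("validation error: duplicate probe ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("validation error: negative count for probe '%s' in sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  probe_class <- as.character(probe_class)
  if (length(probe_class) != nrow(counts)) {
    stop("validation error: probe_class length must match number of probes")
  }
  if (!all(probe_class %in% c("Endogenous", "Negative", "Positive"))) {
    stop("format error: probe classes must be Endogenous, Negative or Positive")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample", "donor", "cell_type")
  if (!all(need %in% names(samples))) {
    stop("format error: sample sheet must have columns sample, donor, cell_type")
  }
  missing_ann <- setdiff(colnames(counts), samples$sample)
  if (length(missing_ann)) {
    stop("validation error: unannotated samples: ", paste(missing_ann, collapse = ", "))
  }
  samples <- samples[match(colnames(counts), samples$sample), need, drop = FALSE]
  rownames(samples) <- NULL
  structure(
    list(counts = counts, probe_class = probe_class, samples = samples,
         codeset_version = codeset_version),
    class = "mir_experiment"
  )
}

#' @export
print.mir_experiment <- function(x, ...) {
  tab <- table(x$probe_class)
  cat(sprintf("mir_experiment: %d probes x %d samples (codeset %s)\n",
              nrow(x$counts), ncol(x$counts), x$codeset_version))
  cat("  probes:  ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  cell types:", paste(unique(x$samples$cell_type), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mir_experiment <- function(x) dim(x$counts)

# Subset helper used by io and normalization: rows by class.
class_rows <- function(x, cls) which(x$probe_class == cls)

#' Processed (normalized, background-corrected) expression matrix
#'
#' Built by [top100_geomean_normalize()] and [apply_background()]; holds the
#' endogenous expression values along with the per-sample normalization
#' factors, background thresholds and override flags so every processing
#' decision stays auditable.
#'
#' @param values numeric matrix of endogenous probe values (probes x samples).
#' @param neg_values numeric matrix of negative-control values on the same
#'   normalized scale.
#' @param samples sample annotation data.frame (`sample`, `donor`, `cell_type`).
#' @param factors per-sample normalization factors (named).
#' @param thresholds per-sample background thresholds (named); `NULL` before
#'   background filtering.
#' @param threshold_overridden logical per sample; `TRUE` where the
#'   cell-type override replaced the sample's own threshold.
#' @param background_mode `"none"`, `"subtract"` or `"censor"`.
#'
#' @return An object of class `mir_processed`.
#' @export
mir_processed <- function(values, neg_values, samples, factors,
                          thresholds = NULL, threshold_overridden = NULL,
                          background_mode = "none") {
  stopifnot(is.matrix(values), all(values >= 0), all(factors > 0))
  if (!is.null(thresholds) && any(thresholds < 0)) {
    stop("validation error: background thresholds must be >= 0")
  }
  structure(
    list(values = values, neg_values = neg_values, samples = samples,
         factors = factors, thresholds = thresholds,
         threshold_overridden = threshold_overridden %||%
           setNames(rep(FALSE, ncol(values)), colnames(values)),
         background_mode = background_mode),
    class = "mir_processed"
  )
}

#' @export
print.mir_processed <- function(x, ...) {
  cat(sprintf("mir_processed: %d probes x %d samples (background: %s)\n",
              nrow(x$values), ncol(x$values), x$background_mode))
  if (!is.null(x$thresholds)) {
    cat(sprintf("  thresholds: %.3g-%.3g (%d overridden)\n",
                min(x$thresholds), max(x$thresholds), sum(x$threshold_overridden)))
  }
  invisible(x)
}

#' @export
dim.mir_processed <- function(x) dim(x$values)
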