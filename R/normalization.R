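#' Top-N geometric-mean count normalization
#'
#' Lane normalization in the platform's standard convention: for each sample
#' the geometric mean of its `top_n` highest endogenous counts is computed;
#' the sample's factor is the across-sample arithmetic mean of those
#' geometric means (or a fixed `target`, if given) divided by the sample's
#' own geometric mean; every value in the sample — endogenous and
#' negative-control rows alike — is multiplied by that factor, so the
#' background threshold is later computed on the same normalized scale the
#' expression values live on.
#'
#' Ties at rank `top_n` are broken by probe-id lexicographic order, making
#' the selected top set deterministic.
#'
#' @param raw a [mir_experiment()].
#' @param top_n number of highest-expressed endogenous probes per sample.
#' @param pseudocount added to counts before the geometric mean (0 keeps the
#'   plain convention; any sample whose top-`top_n` geometric mean is zero is
#'   an error).
#' @param target optional fixed normalization target. The default (`NULL`,
#'   mean of the per-sample geometric means) is the vendor convention; a
#'   fixed target makes normalized values of one sample independent of the
#'   other samples.
#' @return a [mir_processed()] with `background_mode = "none"`.
#' @export
top100_geomean_normalize <- function(raw, top_n = 100L, pseudocount = 0,
                                     target = NULL) {
  stopifnot(inherits(raw, "mir_experiment"))
  endo <- raw$counts[class_rows(raw, "Endogenous"), , drop = FALSE]
  neg <- raw$counts[class_rows(raw, "Negative"), , drop = FALSE]
  if (nrow(endo) < top_n) {
    stop(sprintf("normalization error: %d endogenous probes < top_n = %d",
                 nrow(endo), top_n))
  }
  ord_ids <- order(rownames(endo))  # lexicographic tie-break
  gm <- vapply(seq_len(ncol(endo)), function(j) {
    v <- endo[ord_ids, j]
    top <- v[order(-v)][seq_len(top_n)]
    geo_mean(top + pseudocount)
  }, numeric(1))
  names(gm) <- colnames(endo)
  if (any(gm == 0)) {
    stop("normalization error: zero top-", top_n, " geometric mean in sample ",
         names(gm)[which(gm == 0)[1]])
  }
  factors <- (target %||% mean(gm)) / gm
  mir_processed(
    values = sweep(endo, 2, factors, `*`),
    neg_values = sweep(neg, 2, factors, `*`),
    samples = raw$samples, factors = factors
  )
}

#' Negative-control background threshold for one sample
#'
#' `mean + k * SD` of the sample's normalized negative-control probe values,
#' with the sample (n-1 denominator) standard deviation.
#'
#' @param neg_values numeric vector of negative-control values (>= 2).
#' @param k number of standard deviations above the mean (default 2).
#' @return threshold (scalar, >= 0 whenever the values are).
#' @export
background_threshold <- function(neg_values, k = 2) {
  if (length(neg_values) < 2) {
    stop("validation error: need >= 2 negative-control values")
  }
  mean(neg_values) + k * stats::sd(neg_values)
}

#' Subtract (or censor at) the per-sample background threshold
#'
#' Thresholds default to [background_threshold()] of each sample's normalized
#' negative controls. For cell types named in `override` (by default the
#' erythrocyte lineage, whose negative controls run anomalously low and would
#' otherwise admit an excess of biologically irrelevant low-expressed
#' probes), the sample's own threshold is replaced by the mean of the
#' own-sample thresholds of all samples of the *other* cell types, and the
#' sample's `threshold_overridden` flag is set.
#'
#' With `mode = "subtract"` (default) values become
#' `max(value - threshold, 0)`; with `mode = "censor"` values at or below the
#' threshold are zeroed and values above it pass unchanged. Either way, a
#' probe is "expressed above background" in a sample iff its result is > 0.
#'
#' @param pre a [mir_processed()] from [top100_geomean_normalize()].
#' @param k standard-deviation multiplier for [background_threshold()].
#' @param override character vector of cell types whose thresholds are
#'   replaced by the mean of the other cell types' thresholds; use
#'   `character(0)` for none.
#' @param mode `"subtract"` or `"censor"`.
#' @param thresholds optional named per-sample thresholds, bypassing the
#'   negative-control computation (must cover every sample).
#' @return a [mir_processed()] with thresholds, flags and `background_mode` set.
#' @export
apply_background <- function(pre, k = 2, override = "erythrocyte",
                             mode = c("subtract", "censor"), thresholds = NULL) {
  stopifnot(inherits(pre, "mir_processed"))
  mode <- match.arg(mode)
  cts <- pre$samples$cell_type
  override <- intersect_override(override, cts)
  if (is.null(thresholds)) {
    thresholds <- vapply(seq_len(ncol(pre$values)),
                         function(j) background_threshold(pre$neg_values[, j], k),
                         numeric(1))
    names(thresholds) <- colnames(pre$values)
  } else {
    missing <- setdiff(colnames(pre$values), names(thresholds))
    if (length(missing)) {
      stop("validation error: thresholds missing for samples: ",
           paste(missing, collapse = ", "))
    }
    thresholds <- thresholds[colnames(pre$values)]
  }
  overridden <- setNames(cts %in% override, colnames(pre$values))
  if (any(overridden)) {
    donor_pool <- thresholds[!cts %in% override]
    if (!length(donor_pool)) {
      stop("configuration error: override would leave no samples to average")
    }
    thresholds[overridden] <- mean(donor_pool)
  }
  thresholds <- pmax(thresholds, 0)
  vals <- if (mode == "subtract") {
    pmax(sweep(pre$values, 2, thresholds, `-`), 0)
  } else {
    pre$values * sweep(pre$values, 2, thresholds, `>`)
  }
  mir_processed(vals, pre$neg_values, pre$samples, pre$factors,
                thresholds = thresholds, threshold_overridden = overridden,
                background_mode = mode)
}

intersect_override <- function(override, cell_types) {
  if (!length(override)) return(character(0))
  # silently drop the default override when that lineage is absent, but
  # error on explicitly named unknown cell types
  unknown <- setdiff(override, cell_types)
  if (length(unknown) && !identical(override, "erythrocyte")) {
    stop("configuration error: override names unknown cell type(s): ",
         paste(unknown, collapse = ", "))
  }
  intersect(override, cell_types)
}

#' One-call normalization and background filtering
#'
#' Convenience wrapper: [top100_geomean_normalize()] followed by
#' [apply_background()].
#'
#' @inheritParams top100_geomean_normalize
#' @inheritParams apply_background
#' @return a [mir_processed()].
#' @export
process_counts <- function(raw, top_n = 100L, k = 2, override = "erythrocyte",
                           mode = "subtract", target = NULL) {
  apply_background(top100_geomean_normalize(raw, top_n = top_n, target = target),
                   k = k, override = override, mode = mode)
}
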