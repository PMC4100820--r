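#' Model-based reference-gene stability (Andersen-style)
#'
#' Scores candidate normalizer miRNAs by a variance-decomposition model on
#' log2-scale values. Values are first sample-centered (the per-sample mean
#' across probes is subtracted, removing sample-level loading differences).
#' For each probe and group the model estimates:
#'
#' * an inter-group deviation `d_gi` (group mean of centered values minus the
#'   probe's overall mean), shrunk toward zero by the empirical-Bayes factor
#'   `gamma^2 / (gamma^2 + s2_gi / n_g)`, where `gamma^2` is the
#'   across-probe variance of the raw deviations net of their sampling
#'   variance (floored at 0);
#' * an intra-group variance `s2_gi`, bias-corrected for the share of the
#'   sample-centering term contributed by the other probes
#'   (`(s2_raw - mean_raw / (k - 1) * k / (k - 1)) ...` solved exactly from
#'   the centering algebra, see below) and floored at 0.
#'
#' The stability value is the mean over groups of
#' `|shrunk d_gi| + sqrt(s2_gi / n_g)`; lower is more stable. A probe that is
#' constant across all samples after centering scores exactly 0.
#'
#' The bias correction: centering inflates/deflates each probe's observed
#' within-group variance; with `k` probes, `E[s2_obs,i] =
#' s2_i (1 - 2/k) + S/k^2` with `S` the sum of all probes' variances, which
#' is inverted exactly before flooring at zero.
#'
#' @param values probe x sample numeric matrix on the log2 scale.
#' @param groups character/factor vector of group (cell-type) labels per
#'   sample.
#' @return data.frame of class `stability_ranking`: `probe`, `stability`,
#'   `intra_var` (mean corrected within-group variance),
#'   `inter_dev` (mean absolute shrunk group deviation), `rank`.
#' @export
normfinder_stability <- function(values, groups) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    stop("validation error: one group label per sample required")
  }
  tab <- table(groups)
  if (length(tab) < 2) stop("validation error: need >= 2 groups")
  if (any(tab < 2)) {
    stop("validation error: every group needs >= 2 samples, offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  k <- nrow(values)
  if (k < 3) stop("validation error: need >= 3 probes")

  z <- sweep(values, 2, colMeans(values))           # sample centering
  gs <- names(tab)
  ng <- as.integer(tab)
  overall <- rowMeans(z)

  d <- matrix(0, k, length(gs), dimnames = list(rownames(values), gs))
  s2 <- matrix(0, k, length(gs), dimnames = dimnames(d))
  for (gi in seq_along(gs)) {
    zin <- z[, groups == gs[gi], drop = FALSE]
    d[, gi] <- rowMeans(zin) - overall
    raw <- apply(zin, 1, stats::var)
    # invert E[s2_obs] = s2 (1 - 2/k) + S/k^2, S_hat = k/(k-1) * sum(s2_obs)
    s_hat <- k / (k - 1) * sum(raw)
    s2[, gi] <- pmax((raw - s_hat / k^2) / (1 - 2 / k), 0)
  }
  samp_var <- sweep(s2, 2, ng, `/`)                 # s2_gi / n_g
  df_d <- (k - 1) * (length(gs) - 1)
  gamma2 <- max(sum(d^2) / df_d - mean(samp_var), 0)
  shrink <- if (gamma2 == 0) 0 * samp_var else gamma2 / (gamma2 + samp_var)
  d_shrunk <- d * shrink

  stability <- rowMeans(abs(d_shrunk) + sqrt(samp_var))
  out <- data.frame(probe = rownames(values), stability = stability,
                    intra_var = rowMeans(s2), inter_dev = rowMeans(abs(d_shrunk)),
                    row.names = NULL)
  out$rank <- rank(out$stability, ties.method = "first")
  class(out) <- c("stability_ranking", "data.frame")
  out
}

#' Coefficient of variation per probe
#'
#' Sample SD divided by mean across all samples, on linear normalized values.
#' Probes with zero mean get `NA` and are excluded from ranking.
#'
#' @param values probe x sample numeric matrix (linear scale).
#' @return data.frame with `probe`, `cv`, `rank` (NA-last).
#' @export
cv_stability <- function(values) {
  values <- as.matrix(values)
  m <- rowMeans(values)
  s <- apply(values, 1, stats::sd)
  cv <- ifelse(m > 0, s / m, NA_real_)
  out <- data.frame(probe = rownames(values), cv = cv, row.names = NULL)
  out$rank <- rank(out$cv, ties.method = "first", na.last = "keep")
  out
}

#' Combined normalizer-stability ranking for a processed experiment
#'
#' Runs the model-based criterion on `log2(x + 1)` values and the CV
#' criterion on linear values, excluding probes absent (all samples zero) in
#' any cell type — a usable normalizer must be expressed everywhere.
#'
#' @param proc a [mir_processed()].
#' @param top_k how many top candidates to report per method.
#' @return list with `normfinder`, `cv` (full ranked data.frames) and
#'   `top` (data.frame with the two top-k candidate lists side by side).
#' @export
stability_ranking <- function(proc, top_k = 10L) {
  stopifnot(inherits(proc, "mir_processed"))
  cts <- unique(proc$samples$cell_type)
  present <- rowSums(vapply(cts, function(ct) {
    apply(proc$values[, proc$samples$cell_type == ct, drop = FALSE] == 0, 1, all)
  }, logical(nrow(proc$values)))) == 0
  vals <- proc$values[present, , drop = FALSE]
  nf <- normfinder_stability(log2(vals + 1), proc$samples$cell_type)
  cv <- cv_stability(vals)
  top_k <- min(top_k, nrow(nf))
  list(
    normfinder = nf[order(nf$rank), ],
    cv = cv[order(cv$rank), ],
    top = data.frame(
      rank = seq_len(top_k),
      normfinder = nf$probe[order(nf$rank)][seq_len(top_k)],
      cv = cv$probe[order(cv$rank)][seq_len(top_k)]
    )
  )
}

#' qRT-PCR relative expression by the 2^-dCt method
#'
#' Expression of a target relative to a reference gene from their Ct values:
#' `2^-(ct_target - ct_reference)`. Equal Cts give 1; each extra cycle of the
#' target halves the value.
#'
#' @param ct_target,ct_reference finite Ct values (vectors recycle).
#' @return relative expression.
#' @export
delta_ct_normalize <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("validation error: Ct values must be finite")
  }
  2^-(ct_target - ct_reference)
}
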