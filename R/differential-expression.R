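#' Welch's unequal-variance one-way ANOVA
#'
#' Welch (1951) statistic with the Welch-Satterthwaite denominator degrees of
#' freedom; the p-value is the upper tail of the F distribution. With two
#' groups the statistic equals the squared Welch t statistic.
#'
#' Degenerate inputs are resolved deterministically: if every group is
#' constant and all means are equal the test returns `F = 0, p = 1`; if some
#' groups are constant, their variance is floored at a negligible fraction
#' (1e-12) of the largest within-group variance, so a constant group whose
#' mean differs drives the statistic to (numerically) infinity.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("validation error: need >= 2 groups")
  ns <- lengths(groups)
  if (any(ns < 2)) {
    stop("validation error: every group needs >= 2 values")
  }
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, stats::var, numeric(1))
  if (all(vars == 0)) {
    if (diff(range(means)) == 0) {
      return(list(F = 0, df1 = k - 1, df2 = Inf, p = 1))
    }
    return(list(F = Inf, df1 = k - 1, df2 = Inf, p = 0))
  }
  vars <- pmax(vars, 1e-12 * max(vars))
  w <- ns / vars
  sw <- sum(w)
  grand <- sum(w * means) / sw
  a <- sum(w * (means - grand)^2) / (k - 1)
  lambda <- sum((1 - w / sw)^2 / (ns - 1))
  f <- a / (1 + 2 * (k - 2) / (k^2 - 1) * lambda)
  df2 <- (k^2 - 1) / (3 * lambda)
  list(F = f, df1 = k - 1, df2 = df2,
       p = stats::pf(f, k - 1, df2, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (q-values), preserving the
#' input order. Backed by [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed, passed
#'   through).
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("validation error: p-values must be in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

# Pooled within-group variance and residual df (classical equal-variance
# pooling, as the studentized-range post-hoc tests assume).
pooled_variance <- function(groups) {
  ns <- lengths(groups)
  vars <- vapply(groups, stats::var, numeric(1))
  df <- sum(ns - 1)
  list(s2 = sum((ns - 1) * vars) / df, df = df)
}

#' Studentized-range post-hoc comparisons (Tukey HSD or Student-Newman-Keuls)
#'
#' Both procedures use the pooled within-group variance and the studentized
#' range distribution at family alpha.
#'
#' `mode = "tukey"`: every pair is tested against the full k-group critical
#' range (Tukey-Kramer standard error for unequal group sizes).
#'
#' `mode = "snk"`: group means are ordered and each pair is tested against
#' the critical value for the number of ordered means it spans, working from
#' the widest span inward; once a span tests non-significant, every pair
#' nested inside it is declared non-significant without testing (the
#' classical stepwise protection rule).
#'
#' Homogeneous subsets are the maximal runs of ordered means containing no
#' significant pair; a group may belong to several subsets.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @param mode `"tukey"` or `"snk"`.
#' @param alpha family-wise significance level.
#' @return list with `significant` (symmetric logical matrix),
#'   `p` (Tukey: studentized-range p-values; SNK: `NA`, decisions are
#'   stepwise), `means`, `subsets` (list of group-name vectors), `mode`.
#' @export
posthoc <- function(groups, mode = c("tukey", "snk"), alpha = 0.05) {
  mode <- match.arg(mode)
  k <- length(groups)
  if (k < 2) stop("validation error: need >= 2 groups")
  if (any(lengths(groups) < 2)) stop("validation error: every group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  ns <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  pool <- pooled_variance(groups)
  if (pool$s2 == 0) {
    # no within-group variability: any mean difference separates exactly
    sig <- outer(means, means, `!=`)
    diag(sig) <- FALSE
    pmat <- ifelse(sig, 0, 1)
    diag(pmat) <- NA_real_
    return(list(significant = sig, p = pmat, means = means,
                subsets = homogeneous_subsets(means, sig), mode = mode))
  }
  se <- function(i, j) sqrt(pool$s2 / 2 * (1 / ns[i] + 1 / ns[j]))
  qobs <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    qobs[i, j] <- qobs[j, i] <- abs(means[i] - means[j]) / se(i, j)
  }

  sig <- matrix(FALSE, k, k, dimnames = dimnames(qobs))
  pmat <- matrix(NA_real_, k, k, dimnames = dimnames(qobs))
  if (mode == "tukey") {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      pv <- stats::ptukey(qobs[i, j], nmeans = k, df = pool$df, lower.tail = FALSE)
      pmat[i, j] <- pmat[j, i] <- pv
      sig[i, j] <- sig[j, i] <- pv < alpha
    }
  } else {
    ord <- order(means)
    blocked <- matrix(FALSE, k, k)  # inside a retained non-significant span
    for (span in seq(k, 2)) {
      for (a in seq_len(k - span + 1)) {
        b <- a + span - 1
        i <- ord[a]; j <- ord[b]
        if (blocked[i, j]) next
        crit <- stats::qtukey(1 - alpha, nmeans = span, df = pool$df)
        if (qobs[i, j] > crit) {
          sig[i, j] <- sig[j, i] <- TRUE
        } else {
          for (aa in seq(a, b - 1)) for (bb in seq(aa + 1, b)) {
            ii <- ord[aa]; jj <- ord[bb]
            blocked[ii, jj] <- blocked[jj, ii] <- TRUE
          }
        }
      }
    }
  }
  list(significant = sig, p = pmat, means = means,
       subsets = homogeneous_subsets(means, sig), mode = mode)
}

# Maximal runs of ordered means with no significant pair inside.
homogeneous_subsets <- function(means, sig) {
  ord <- order(means)
  k <- length(means)
  runs <- list()
  for (a in seq_len(k)) {
    b <- a
    while (b < k && !any(sig[ord[a:(b + 1)], ord[a:(b + 1)]])) b <- b + 1
    runs[[a]] <- ord[a:b]
  }
  keep <- !vapply(seq_along(runs), function(i) {
    any(vapply(seq_along(runs), function(j) {
      i != j && all(runs[[i]] %in% runs[[j]])
    }, logical(1)))
  }, logical(1))
  lapply(runs[keep], function(idx) names(means)[idx])
}

#' Lineage-wise differential expression across blood cell types
#'
#' Runs [welch_anova()] per probe across the cell-type groups on
#' `log2(x + 1)`-transformed (default) or linear processed values, adjusts
#' p-values with [bh_adjust()], and follows up globally significant probes
#' (`q < alpha_q`) with a studentized-range post-hoc test: Tukey when the
#' probe is present in all cell types, Student-Newman-Keuls when it is
#' absent (all samples zero after background correction) in one or more cell
#' types. A probe lands on a lineage's DE list when it is globally
#' significant and the post-hoc test separates that lineage from all other
#' cell types; direction is the sign of the lineage mean minus the mean of
#' the remaining cell types.
#'
#' "Selectively reduced" probes are highly expressed (cell-type mean above
#' `high`) in at least two lineages yet below the `low` threshold in at
#' least one: abundant miRNAs that one lineage has largely shed.
#'
#' Probes with zero variance everywhere are reported with `F = 0, p = 1`
#' rather than an error.
#'
#' @param proc a [mir_processed()] (background-corrected).
#' @param alpha_q BH q-value cutoff for global differential expression.
#' @param scale `"log2p1"` (default) or `"linear"` test scale.
#' @param posthoc_alpha family-wise alpha for the post-hoc tests.
#' @param low,high expression-class boundaries on the linear processed scale.
#' @return object of class `de_result`: list with `table` (per-probe F, df1,
#'   df2, p, q, posthoc mode, per-lineage separation flags and directions),
#'   `by_lineage` (named list of per-lineage DE probe data.frames),
#'   `selectively_reduced` (data.frame), `alpha_q`, `scale`.
#' @export
de_by_cell_type <- function(proc, alpha_q = 0.05, scale = c("log2p1", "linear"),
                            posthoc_alpha = 0.05, low = 10, high = 5000) {
  stopifnot(inherits(proc, "mir_processed"))
  scale <- match.arg(scale)
  cts <- unique(proc$samples$cell_type)
  if (any(table(proc$samples$cell_type) < 2)) {
    stop("validation error: need >= 2 samples per cell type")
  }
  vals <- if (scale == "log2p1") log2(proc$values + 1) else proc$values
  split_groups <- lapply(cts, function(ct) {
    which(proc$samples$cell_type == ct)
  })
  names(split_groups) <- cts

  n_probe <- nrow(vals)
  res <- data.frame(probe = rownames(vals), F = NA_real_, df1 = NA_real_,
                    df2 = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  absent <- matrix(FALSE, n_probe, length(cts),
                   dimnames = list(rownames(vals), cts))
  for (i in seq_len(n_probe)) {
    groups <- lapply(split_groups, function(idx) vals[i, idx])
    absent[i, ] <- vapply(split_groups, function(idx) {
      all(proc$values[i, idx] == 0)
    }, logical(1))
    if (diff(range(vals[i, ])) == 0) {
      res$F[i] <- 0; res$df1[i] <- length(cts) - 1
      res$df2[i] <- Inf; res$p[i] <- 1
    } else {
      w <- welch_anova(groups)
      res$F[i] <- w$F; res$df1[i] <- w$df1; res$df2[i] <- w$df2; res$p[i] <- w$p
    }
  }
  res$q <- bh_adjust(res$p)
  res$de <- res$q < alpha_q
  res$posthoc_mode <- ifelse(rowSums(absent) > 0, "snk", "tukey")

  sep <- matrix(FALSE, n_probe, length(cts), dimnames = list(rownames(vals), cts))
  dir <- matrix(NA_character_, n_probe, length(cts), dimnames = list(rownames(vals), cts))
  for (i in which(res$de)) {
    groups <- lapply(split_groups, function(idx) vals[i, idx])
    ph <- posthoc(groups, mode = res$posthoc_mode[i], alpha = posthoc_alpha)
    for (ct in cts) {
      others <- setdiff(cts, ct)
      sep[i, ct] <- all(ph$significant[ct, others])
      if (sep[i, ct]) {
        dir[i, ct] <- if (ph$means[ct] > mean(ph$means[others])) "up" else "down"
      }
    }
  }

  ct_means <- vapply(cts, function(ct) {
    rowMeans(proc$values[, split_groups[[ct]], drop = FALSE])
  }, numeric(n_probe))
  sel_red <- rowSums(ct_means > high) >= 2 & rowSums(ct_means < low) >= 1

  by_lineage <- lapply(cts, function(ct) {
    idx <- which(sep[, ct])
    data.frame(probe = rownames(vals)[idx], q = res$q[idx],
               direction = dir[idx, ct], stringsAsFactors = FALSE)
  })
  names(by_lineage) <- cts

  structure(list(
    table = cbind(res, separated = I(sep)),
    separated = sep, direction = dir, absent = absent,
    by_lineage = by_lineage,
    selectively_reduced = if (any(sel_red)) data.frame(
      probe = rownames(vals)[sel_red],
      high_in = apply(ct_means[sel_red, , drop = FALSE] > high, 1,
                      function(z) paste(cts[z], collapse = ";")),
      low_in = apply(ct_means[sel_red, , drop = FALSE] < low, 1,
                     function(z) paste(cts[z], collapse = ";")),
      stringsAsFactors = FALSE, row.names = NULL
    ) else data.frame(probe = character(0), high_in = character(0),
                      low_in = character(0)),
    alpha_q = alpha_q, scale = scale
  ), class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d/%d probes DE at q < %g (%s scale)\n",
              sum(x$table$de), nrow(x$table), x$alpha_q, x$scale))
  for (ct in names(x$by_lineage)) {
    cat(sprintf("  %-12s %d lineage-specific probes\n", ct, nrow(x$by_lineage[[ct]])))
  }
  invisible(x)
}
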