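validate_trace <- function(trace) {
  if (!is.data.frame(trace) || !all(c("size_nt", "intensity") %in% names(trace))) {
    stop("validation error: trace needs columns size_nt, intensity")
  }
  if (nrow(trace) < 2) stop("validation error: trace needs >= 2 points")
  if (any(!is.finite(trace$size_nt)) || any(!is.finite(trace$intensity))) {
    stop("validation error: trace contains non-finite values")
  }
  if (any(diff(trace$size_nt) <= 0)) {
    stop("validation error: trace size coordinate must be strictly increasing")
  }
  if (any(trace$intensity < 0)) {
    stop("validation error: trace intensity must be >= 0")
  }
  invisible(trace)
}

# Trapezoidal integral of intensity over size on [a, b] within the trace's
# support, with linear interpolation at the endpoints.
trapz_between <- function(size, intensity, a, b) {
  a <- max(a, size[1])
  b <- min(b, size[length(size)])
  if (b <= a) return(0)
  interp <- function(x) stats::approx(size, intensity, xout = x)$y
  inside <- size > a & size < b
  xs <- c(a, size[inside], b)
  ys <- c(interp(a), intensity[inside], interp(b))
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Area-under-curve fraction of an electropherogram below a size cutoff
#'
#' Trapezoidal integral of fluorescence intensity over fragment size from the
#' trace start to `cutoff_nt` (linear interpolation at the cutoff), divided
#' by the integral over the full trace. This is how size-resolved
#' electrophoresis quantifies the mass fraction of RNA in a size class
#' (small RNA < 150 nt of a total-RNA assay; miRNA < 40 nt of a small-RNA
#' assay).
#'
#' @param trace data.frame with strictly increasing `size_nt` and
#'   non-negative `intensity`.
#' @param cutoff_nt size cutoff in nucleotides.
#' @return fraction in `[0, 1]`.
#' @export
auc_fraction <- function(trace, cutoff_nt) {
  validate_trace(trace)
  total <- trapz_between(trace$size_nt, trace$intensity,
                         trace$size_nt[1], trace$size_nt[nrow(trace)])
  if (total <= 0) stop("validation error: trace has zero total area")
  min(max(trapz_between(trace$size_nt, trace$intensity,
                        trace$size_nt[1], cutoff_nt) / total, 0), 1)
}

#' Total RNA yield per cell
#'
#' Converts an extraction yield (ng) and the number of cells extracted into
#' femtograms of total RNA per cell: `ng * 1e6 / cells`.
#'
#' @param total_rna_ng total RNA recovered, nanograms.
#' @param cells number of cells extracted (> 0).
#' @return femtograms per cell.
#' @export
total_rna_per_cell <- function(total_rna_ng, cells) {
  if (any(cells <= 0)) stop("validation error: cells must be > 0")
  if (any(total_rna_ng < 0)) stop("validation error: total_rna_ng must be >= 0")
  total_rna_ng * 1e6 / cells
}

#' Ratio of two per-cell masses
#'
#' Fold difference between two lineages' per-cell RNA masses (e.g. T-cell vs
#' B-cell total RNA).
#'
#' @param a,b per-cell masses (same units).
#' @return `a / b`.
#' @export
fold_ratio <- function(a, b) {
  if (any(b == 0)) stop("validation error: denominator mass is zero")
  a / b
}

#' miRNA fraction of total RNA from a pair of electropherograms
#'
#' The small-RNA fraction of the total-RNA assay (area below `small_cutoff`)
#' times the miRNA fraction of the small-RNA assay (area below
#' `mirna_cutoff`): the chained size-fractionation that turns two traces into
#' one miRNA:total-RNA mass ratio.
#'
#' @param total_trace,small_trace electropherogram data.frames.
#' @param small_cutoff small-RNA size cutoff on the total-RNA trace, nt.
#' @param mirna_cutoff miRNA size cutoff on the small-RNA trace, nt.
#' @return fraction in `[0, 1]`.
#' @export
mirna_fraction_of_total <- function(total_trace, small_trace,
                                    small_cutoff = 150, mirna_cutoff = 40) {
  auc_fraction(total_trace, small_cutoff) * auc_fraction(small_trace, mirna_cutoff)
}

#' Per-blood-volume miRNA contribution of each lineage
#'
#' `fg/cell x cells/ul x 1e-3 = pg/ul` of blood, with the lineages ranked by
#' contribution (rank 1 = largest).
#'
#' @param mirna_fg_per_cell per-cell miRNA mass, femtograms.
#' @param cells_per_ul circulating concentration, cells per microlitre.
#' @return data.frame with `mirna_pg_per_ul_blood` and `rank`.
#' @export
per_volume_contribution <- function(mirna_fg_per_cell, cells_per_ul) {
  if (any(mirna_fg_per_cell < 0) || any(cells_per_ul < 0)) {
    stop("validation error: inputs must be >= 0")
  }
  pg <- mirna_fg_per_cell * cells_per_ul * 1e-3
  data.frame(mirna_pg_per_ul_blood = pg,
             rank = rank(-pg, ties.method = "min"))
}

#' Assemble the per-lineage mass budget
#'
#' Combines cell-prep records with per-lineage electropherogram size
#' fractions into the full budget: total RNA fg/cell, miRNA fraction of
#' total, miRNA fg/cell, cells/ul and miRNA pg/ul blood.
#'
#' @param records a `cell_prep_table` (see [generate_cell_records()]).
#' @param fractions either a data.frame with columns `cell_type`,
#'   `small_fraction`, `mirna_fraction_of_small` (already-reduced AUC
#'   fractions), or a named list of per-cell-type trace pairs
#'   `list(total =, small =)` from which fractions are computed with
#'   [auc_fraction()].
#' @param small_cutoff,mirna_cutoff size cutoffs in nt.
#' @return data.frame of class `mass_budget`.
#' @export
build_mass_budget <- function(records, fractions = default_mass_fractions(),
                              small_cutoff = 150, mirna_cutoff = 40) {
  stopifnot(all(c("cell_type", "cells_extracted", "total_rna_ng",
                  "cells_per_ul_blood") %in% names(records)))
  if (is.data.frame(fractions)) {
    frac <- fractions$small_fraction * fractions$mirna_fraction_of_small
    names(frac) <- fractions$cell_type
  } else {
    frac <- vapply(fractions, function(tr) {
      mirna_fraction_of_total(tr$total, tr$small, small_cutoff, mirna_cutoff)
    }, numeric(1))
  }
  missing <- setdiff(records$cell_type, names(frac))
  if (length(missing)) {
    stop("validation error: no size fractions for cell type(s): ",
         paste(missing, collapse = ", "))
  }
  total_fg <- total_rna_per_cell(records$total_rna_ng, records$cells_extracted)
  mirna_fg <- total_fg * frac[records$cell_type]
  contrib <- per_volume_contribution(mirna_fg, records$cells_per_ul_blood)
  out <- data.frame(
    cell_type = records$cell_type,
    total_rna_fg_per_cell = total_fg,
    mirna_fraction_of_total = unname(frac[records$cell_type]),
    mirna_fg_per_cell = unname(mirna_fg),
    cells_per_ul = records$cells_per_ul_blood,
    mirna_pg_per_ul_blood = contrib$mirna_pg_per_ul_blood,
    rank = contrib$rank,
    row.names = NULL
  )
  class(out) <- c("mass_budget", "data.frame")
  out
}

#' Apportion each miRNA's blood content across lineages
#'
#' For each probe, the mass contributed by cell type `c` per microlitre of
#' blood is `relative abundance_c x miRNA fg/cell_c x cells/ul_c`; shares are
#' those masses as percentages of the probe's row total. Probes with zero
#' total mass get `NA` shares and are flagged. Each non-flagged row sums to
#' exactly 100% before any display rounding.
#'
#' @param abund a [relative_abundance()] (its cell-type averages are used) or
#'   a probe x cell-type abundance matrix.
#' @param budget a `mass_budget` data.frame covering the same cell types.
#' @return data.frame of class `blood_share_table`: `probe`, one share column
#'   per cell type (percent), `total_pg_per_ul`, `zero_mass` flag.
#' @export
apportion_blood_shares <- function(abund, budget) {
  avg <- if (inherits(abund, "relative_abundance")) abund$cell_type_avg else as.matrix(abund)
  cts_a <- colnames(avg)
  cts_b <- budget$cell_type
  if (!setequal(cts_a, cts_b)) {
    stop("validation error: cell-type mismatch between abundance and budget: ",
         paste(c(setdiff(cts_a, cts_b), setdiff(cts_b, cts_a)), collapse = ", "))
  }
  w <- setNames(budget$mirna_fg_per_cell * budget$cells_per_ul, cts_b)[cts_a]
  mass <- sweep(avg, 2, w, `*`)          # fg per ul blood
  total <- rowSums(mass)
  shares <- 100 * mass / total           # NaN where total == 0
  zero <- total == 0
  shares[zero, ] <- NA_real_
  out <- data.frame(probe = rownames(avg), shares,
                    total_pg_per_ul = total * 1e-3, zero_mass = zero,
                    check.names = FALSE, row.names = NULL)
  class(out) <- c("blood_share_table", "data.frame")
  out
}

#' Serialize a blood-share table with display rounding
#'
#' Shares are rounded to whole percent at write time only (rounded rows may
#' total 99-101%); the in-memory table keeps full precision.
#'
#' @param shares a `blood_share_table`.
#' @param path CSV path.
#' @param digits decimal places for the share columns.
#' @return invisibly, `path`.
#' @export
write_blood_shares <- function(shares, path, digits = 0) {
  df <- as.data.frame(shares)
  ct_cols <- setdiff(names(df), c("probe", "total_pg_per_ul", "zero_mass"))
  df[ct_cols] <- lapply(df[ct_cols], round, digits = digits)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
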