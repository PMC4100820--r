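#' Canonical peripheral-blood lineages
#'
#' The five purified hematopoietic cell populations the pipeline models.
#' @return character vector of lineage labels.
#' @export
blood_cell_types <- function() {
  c("platelet", "T-cell", "B-cell", "granulocyte", "erythrocyte")
}

#' Default differential-expression plan for the simulator
#'
#' Plants two lineage-specific miRNAs per cell type at the given fold change,
#' mirroring the strong lineage-preferential expression seen in real blood
#' cells (e.g. erythroid miR-451a, granulocytic miR-223-3p).
#'
#' @param cell_types lineage labels.
#' @param per_type planted probes per lineage.
#' @param fold linear fold change of the planted probes in their lineage.
#' @return list of entries `list(probe =, lineages =, fold =)`.
#' @export
default_de_plan <- function(cell_types = blood_cell_types(), per_type = 2L, fold = 8) {
  plan <- list()
  k <- 0L
  for (ct in cell_types) {
    for (i in seq_len(per_type)) {
      k <- k + 1L
      plan[[k]] <- list(probe = sprintf("syn-miR-de-%03d", k), lineages = ct, fold = fold)
    }
  }
  plan
}

#' Default stable-normalizer plan for the simulator
#'
#' Probes with zero inter-lineage effect and reduced dispersion: the ground
#' truth against which reference-normalizer selection is scored.
#' @param n number of stable probes.
#' @return character vector of probe ids.
#' @export
default_stable_plan <- function(n = 3L) sprintf("syn-miR-stable-%02d", seq_len(n))

#' Simulation configuration
#'
#' Describes a synthetic blood-cell miRNA profiling study. Defaults emulate
#' the design the pipeline targets: 5 donors x 5 purified cell types, 623
#' endogenous probes plus 6 negative controls, log2-scale lognormal counts
#' around per-probe lineage profiles, and planted differential / stable
#' probes with known truth.
#'
#' @param n_donors number of donors (>= 2); each donor contributes one sample
#'   of every cell type (paired design).
#' @param cell_types lineage labels (>= 2).
#' @param n_endogenous number of endogenous probes.
#' @param n_negative number of negative-control probes.
#' @param baseline_log_mean mean of per-probe baseline expression, log2 counts.
#' @param baseline_log_sd sd of per-probe baselines (log2); the default 2.5
#'   spreads probes over roughly five orders of magnitude of counts, matching
#'   the dynamic range of real blood-cell miRNA profiles.
#' @param donor_sd sd of the per-probe donor effect (log2), shared across the
#'   donor's cell types to emulate paired sampling of the same individuals.
#' @param residual_sd residual log2-scale noise sd.
#' @param lineage_frac fraction of endogenous probes carrying lineage-profile
#'   variation (independent per-cell-type log2 offsets), emulating the broad
#'   cell-type-preferential expression of real blood miRNAs; planted DE,
#'   stable and share-plan probes are never drawn from this pool.
#' @param lineage_sd sd of those per-cell-type profile offsets (log2).
#' @param neg_mean,neg_sd count-scale mean and sd of negative-control probes
#'   (truncated normal at 0). The platform's raw background level is a free
#'   parameter here.
#' @param neg_mean_by_type optional named numeric: per-cell-type override of
#'   `neg_mean`. The default gives erythrocytes an anomalously low background
#'   (0.8), reproducing the situation that motivates the erythrocyte
#'   threshold override in [apply_background()].
#' @param de_plan list of `list(probe, lineages, fold)` entries: probe is
#'   elevated `fold`-fold in the named lineages.
#' @param stable_plan probe ids with zero inter-lineage effect, a fixed
#'   moderately-high baseline (`baseline_log_mean + 3`) and donor/residual
#'   noise damped by `stable_dispersion`: ground-truth reference normalizers.
#' @param stable_dispersion noise multiplier for stable probes.
#' @param share_plan optional list of `list(probe, shares)` entries where
#'   `shares` is a named percentage vector over `cell_types`; the probe's
#'   lineage means are set so that blood-volume apportionment under the
#'   default mass budget recovers those shares (see
#'   [apportion_blood_shares()]).
#' @param absent_plan optional list of `list(probe, lineages)`: the probe's
#'   expected count is exactly zero in the named lineages.
#' @param seed RNG seed.
#'
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_donors = 5L,
                       cell_types = blood_cell_types(),
                       n_endogenous = 623L,
                       n_negative = 6L,
                       baseline_log_mean = 5,
                       baseline_log_sd = 2.5,
                       donor_sd = 0.25,
                       residual_sd = 0.25,
                       lineage_frac = 0.15,
                       lineage_sd = 1.5,
                       neg_mean = 4,
                       neg_sd = 2,
                       neg_mean_by_type = c(erythrocyte = 0.8),
                       de_plan = default_de_plan(cell_types),
                       stable_plan = default_stable_plan(),
                       stable_dispersion = 0.2,
                       share_plan = NULL,
                       absent_plan = NULL,
                       seed = 1L) {
  if (!is.numeric(n_donors) || n_donors < 2) stop_config("n_donors", "must be >= 2")
  if (length(cell_types) < 2) stop_config("cell_types", "need at least 2 cell types")
  if (anyDuplicated(cell_types)) stop_config("cell_types", "labels must be unique")
  if (n_endogenous < 1) stop_config("n_endogenous", "must be >= 1")
  if (n_negative < 2) stop_config("n_negative", "must be >= 2")
  for (nm in c("baseline_log_sd", "donor_sd", "residual_sd", "neg_sd", "lineage_sd")) {
    if (get(nm) < 0) stop_config(nm, "must be >= 0")
  }
  if (lineage_frac < 0 || lineage_frac > 1) stop_config("lineage_frac", "must be in [0, 1]")
  if (neg_mean < 0) stop_config("neg_mean", "must be >= 0")
  for (e in de_plan) {
    if (is.null(e$probe) || is.null(e$lineages) || is.null(e$fold)) {
      stop_config("de_plan", "entries need fields probe, lineages, fold")
    }
    if (e$fold <= 0) stop_config("de_plan", "fold changes must be > 0")
    if (!all(e$lineages %in% cell_types)) {
      stop_config("de_plan", paste("unknown lineage:",
                                   setdiff(e$lineages, cell_types)[1]))
    }
  }
  if (length(intersect(vapply(de_plan, `[[`, "", "probe"), stable_plan))) {
    stop_config("stable_plan", "planted DE and stable sets must be disjoint")
  }
  structure(
    list(n_donors = as.integer(n_donors), cell_types = cell_types,
         n_endogenous = as.integer(n_endogenous),
         n_negative = as.integer(n_negative),
         baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
         donor_sd = donor_sd, residual_sd = residual_sd,
         lineage_frac = lineage_frac, lineage_sd = lineage_sd,
         neg_mean = neg_mean, neg_sd = neg_sd,
         neg_mean_by_type = neg_mean_by_type,
         de_plan = de_plan, stable_plan = stable_plan,
         stable_dispersion = stable_dispersion,
         share_plan = share_plan, absent_plan = absent_plan,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Build the probe x cell-type log2 lineage-profile matrix (entries may be
# -Inf for structurally absent probes) plus per-probe dispersion multipliers.
build_lineage_profile <- function(config) {
  ct <- config$cell_types
  ids <- sprintf("syn-miR-%04d", seq_len(config$n_endogenous))
  # planted probes replace the tail of the id list so n_endogenous is exact
  planted <- unique(c(vapply(config$de_plan, `[[`, "", "probe"),
                      config$stable_plan,
                      vapply(config$share_plan %||% list(), `[[`, "", "probe"),
                      vapply(config$absent_plan %||% list(), `[[`, "", "probe")))
  planted <- setdiff(planted, ids)
  if (length(planted) > config$n_endogenous) {
    stop_config("n_endogenous", "fewer probes than planted plan entries")
  }
  if (length(planted)) {
    ids[seq(config$n_endogenous - length(planted) + 1L, config$n_endogenous)] <- planted
  }

  baseline <- stats::rnorm(length(ids), config$baseline_log_mean, config$baseline_log_sd)
  names(baseline) <- ids
  # planted normalizers: moderately expressed (clear of background) with a
  # fixed baseline so their only variation is the damped noise below
  baseline[config$stable_plan[config$stable_plan %in% ids]] <-
    config$baseline_log_mean + 3

  profile <- matrix(baseline, nrow = length(ids), ncol = length(ct),
                    dimnames = list(ids, ct))

  # broad lineage-profile variation on a random subset of unplanted probes
  planned <- unique(c(planted, config$stable_plan,
                      vapply(config$de_plan, `[[`, "", "probe")))
  pool <- setdiff(ids, planned)
  n_var <- round(config$lineage_frac * length(pool))
  lineage_var_probes <- character(0)
  if (n_var > 0 && config$lineage_sd > 0) {
    lineage_var_probes <- sample(pool, n_var)
    profile[lineage_var_probes, ] <- profile[lineage_var_probes, ] +
      matrix(stats::rnorm(n_var * length(ct), 0, config$lineage_sd),
             nrow = n_var)
  }

  for (e in config$de_plan) {
    profile[e$probe, ] <- config$baseline_log_mean
    profile[e$probe, e$lineages] <- config$baseline_log_mean + log2(e$fold)
  }
  for (e in config$share_plan %||% list()) {
    profile[e$probe, ] <- share_plan_profile(e$shares, ct)
  }
  for (e in config$absent_plan %||% list()) {
    profile[e$probe, e$lineages] <- -Inf
  }

  disp <- setNames(rep(1, length(ids)), ids)
  disp[config$stable_plan[config$stable_plan %in% ids]] <- config$stable_dispersion
  list(ids = ids, profile = profile, dispersion = disp,
       lineage_var_probes = lineage_var_probes)
}

# Translate a target blood-share percentage vector into per-lineage log2 mean
# counts, inverting the apportionment arithmetic under the default budget:
# share_c proportional to count_c x (miRNA fg/cell)_c x (cells/ul)_c.
share_plan_profile <- function(shares, cell_types, peak_log2 = 14.3) {
  if (is.null(names(shares))) names(shares) <- cell_types
  shares <- shares[cell_types]
  if (any(is.na(shares)) || any(shares < 0)) {
    stop_config("share_plan", "shares must be named, non-negative, covering all cell types")
  }
  budget <- default_mass_budget()
  mass_per_ul <- setNames(budget$mirna_fg_per_cell * budget$cells_per_ul, budget$cell_type)
  rel <- shares / mass_per_ul[cell_types]
  mu <- rel / max(rel) * 2^peak_log2
  ifelse(mu > 0, log2(mu), -Inf)
}

#' Generate a synthetic count dataset with known ground truth
#'
#' Endogenous counts are `round(2^(baseline + lineage effect + donor effect +
#' residual))`; negative controls are truncated-normal(neg_mean, neg_sd) at
#' zero. The same seed always yields byte-identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `experiment` (a [mir_experiment()]) and `truth`
#'   (lineage-profile log2 means, planted DE/stable/absent sets, config).
#' @export
generate_count_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(config$seed, function() {
    lp <- build_lineage_profile(config)
    ct <- config$cell_types
    donors <- sprintf("D%d", seq_len(config$n_donors))
    samples <- expand.grid(donor = donors, cell_type = ct,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    samples$sample <- paste(samples$donor, samples$cell_type, sep = "_")
    samples <- samples[, c("sample", "donor", "cell_type")]

    n_probe <- length(lp$ids)
    # donor effect: per probe x donor, shared across the donor's cell types
    donor_eff <- matrix(stats::rnorm(n_probe * config$n_donors, 0, config$donor_sd),
                        nrow = n_probe, dimnames = list(lp$ids, donors))
    donor_eff <- donor_eff * lp$dispersion  # stable probes damp all biological noise
    counts <- matrix(0, nrow = n_probe, ncol = nrow(samples),
                     dimnames = list(lp$ids, samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu <- lp$profile[, samples$cell_type[j]] + donor_eff[, samples$donor[j]]
      eps <- stats::rnorm(n_probe, 0, config$residual_sd) * lp$dispersion
      counts[, j] <- round(2^(mu + eps))
    }

    neg_ids <- sprintf("NEG_%s", LETTERS[seq_len(config$n_negative)])
    neg <- matrix(0, nrow = config$n_negative, ncol = nrow(samples),
                  dimnames = list(neg_ids, samples$sample))
    for (j in seq_len(nrow(samples))) {
      m <- config$neg_mean
      ov <- config$neg_mean_by_type
      if (!is.null(ov) && samples$cell_type[j] %in% names(ov)) {
        m <- ov[[samples$cell_type[j]]]
      }
      neg[, j] <- rtruncnorm0(config$n_negative, m, config$neg_sd)
    }

    exper <- mir_experiment(
      counts = rbind(counts, neg),
      probe_class = c(rep("Endogenous", n_probe), rep("Negative", config$n_negative)),
      samples = samples, codeset_version = "synthetic"
    )
    truth <- list(
      profile_log2 = lp$profile,
      lineage_var_probes = lp$lineage_var_probes,
      de_probes = vapply(config$de_plan, `[[`, "", "probe"),
      de_plan = config$de_plan,
      stable_probes = config$stable_plan,
      share_plan = config$share_plan,
      absent_plan = config$absent_plan,
      config = config
    )
    list(experiment = exper, truth = truth)
  })
}

#' Generate a matched pair of synthetic electropherogram traces
#'
#' Emulates capillary-electrophoresis size profiles of a total-RNA assay and
#' a small-RNA assay for one cell preparation. The total-RNA trace carries
#' `small_fraction` of its area below 150 nt (small-RNA region vs ribosomal
#' peaks); the small-RNA trace carries `mirna_fraction_of_small` of its area
#' below 40 nt (the miRNA window). Peaks are Gaussian with means/widths far
#' enough from the cutoffs that the realized area fractions match the targets
#' to well within 1% despite multiplicative intensity noise.
#'
#' @param total_mass_ng total RNA mass; scales the total-trace area.
#' @param small_fraction target area fraction of the total trace below 150 nt.
#' @param mirna_fraction_of_small target area fraction of the small-RNA trace
#'   below 40 nt.
#' @param seed RNG seed.
#' @param noise_cv multiplicative intensity noise coefficient of variation.
#' @return list with `total` and `small` trace data.frames
#'   (`size_nt`, `intensity`) and `truth` (the generating fractions).
#' @export
generate_electropherogram <- function(total_mass_ng, small_fraction,
                                      mirna_fraction_of_small, seed = 1L,
                                      noise_cv = 0.02) {
  if (small_fraction < 0 || small_fraction > 1) {
    stop("domain error: small_fraction must be in [0, 1]")
  }
  if (mirna_fraction_of_small < 0 || mirna_fraction_of_small > 1) {
    stop("domain error: mirna_fraction_of_small must be in [0, 1]")
  }
  if (total_mass_ng < 0) stop("domain error: total_mass_ng must be >= 0")
  with_seed(seed, function() {
    gauss <- function(x, m, s) stats::dnorm(x, mean = m, sd = s)
    noisy <- function(y) pmax(y * (1 + stats::rnorm(length(y), 0, noise_cv)), 0)

    size_tot <- seq(20, 5000, length.out = 1200)
    y_tot <- small_fraction * gauss(size_tot, 100, 15) +
      (1 - small_fraction) * (0.45 * gauss(size_tot, 1900, 120) +
                              0.55 * gauss(size_tot, 4700, 60))
    y_tot <- noisy(y_tot * total_mass_ng)

    size_sm <- seq(4, 150, length.out = 800)
    y_sm <- mirna_fraction_of_small * gauss(size_sm, 25, 4) +
      (1 - mirna_fraction_of_small) * gauss(size_sm, 90, 12)
    y_sm <- noisy(y_sm)

    list(
      total = data.frame(size_nt = size_tot, intensity = y_tot),
      small = data.frame(size_nt = size_sm, intensity = y_sm),
      truth = list(total_mass_ng = total_mass_ng,
                   small_fraction = small_fraction,
                   mirna_fraction_of_small = mirna_fraction_of_small)
    )
  })
}

#' Default per-lineage electropherogram size fractions
#'
#' Area fractions (total-RNA trace below 150 nt; small-RNA trace below 40 nt)
#' whose product reproduces the per-lineage miRNA:total-RNA mass ratios of the
#' reference per-cell mass table (see [generate_cell_records()]). Non-nucleated
#' cells (platelets, erythrocytes) carry the largest small-RNA fractions,
#' lymphocytes the smallest, as observed in real blood preparations.
#'
#' @return data.frame with columns `cell_type`, `small_fraction`,
#'   `mirna_fraction_of_small`.
#' @export
default_mass_fractions <- function() {
  b <- default_mass_budget()
  ratio <- b$mirna_fg_per_cell / b$total_rna_fg_per_cell
  small <- c(platelet = 0.25, `T-cell` = 0.05, `B-cell` = 0.05,
             granulocyte = 0.15, erythrocyte = 0.35)[b$cell_type]
  data.frame(cell_type = b$cell_type,
             small_fraction = unname(small),
             mirna_fraction_of_small = unname(ratio / small),
             row.names = NULL)
}

# Reference per-cell mass and concentration table for the five lineages.
# fg/cell masses are assay-derived constants for healthy adult blood;
# cells/ul are derived from those masses and the per-volume miRNA
# contributions (pg/ul / fg/cell x 1000) and sit at physiological values
# (approx. 338e3 platelets, 1082 T-cells, 203 B-cells, 4911 granulocytes,
# 4.6e6 erythrocytes per ul).
default_mass_budget <- function() {
  data.frame(
    cell_type = blood_cell_types(),
    total_rna_fg_per_cell = c(2.20, 2187.97, 1360.34, 646.30, 0.57),
    mirna_fg_per_cell = c(0.05, 3.28, 3.16, 10.23, 0.04),
    cells_per_ul = c(338000, 3.55 / 3.28 * 1000, 0.64 / 3.16 * 1000,
                     50.24 / 10.23 * 1000, 4.6e6),
    row.names = NULL
  )
}

#' Generate per-cell-type RNA extraction and cell-count records
#'
#' One record per cell type: number of cells RNA was extracted from, total
#' RNA yield (ng), and circulating cell concentration (cells per microlitre
#' of blood, CBC-style). With `cv = 0` the records reproduce the reference
#' per-cell masses exactly; a positive `cv` adds lognormal preparation noise.
#'
#' @param seed RNG seed (used only when `cv > 0`).
#' @param cv lognormal coefficient of variation of the yields.
#' @return data.frame of class `cell_prep_table` with columns `cell_type`,
#'   `cells_extracted`, `total_rna_ng`, `cells_per_ul_blood`.
#' @export
generate_cell_records <- function(seed = 1L, cv = 0) {
  b <- default_mass_budget()
  cells <- c(1e9, 1e7, 1e7, 1e7, 1e9)  # typical preparation scales
  ng <- b$total_rna_fg_per_cell * cells / 1e6
  rec <- data.frame(cell_type = b$cell_type,
                    cells_extracted = cells,
                    total_rna_ng = ng,
                    cells_per_ul_blood = b$cells_per_ul,
                    row.names = NULL)
  if (cv > 0) {
    rec <- with_seed(seed, function() {
      sdlog <- sqrt(log(1 + cv^2))
      rec$total_rna_ng <- rec$total_rna_ng *
        stats::rlnorm(nrow(rec), -sdlog^2 / 2, sdlog)
      rec$cells_per_ul_blood <- rec$cells_per_ul_blood *
        stats::rlnorm(nrow(rec), -sdlog^2 / 2, sdlog)
      rec
    })
  }
  if (any(rec$cells_extracted <= 0) || any(rec$cells_per_ul_blood <= 0)) {
    stop("validation error: cell records must be strictly positive")
  }
  class(rec) <- c("cell_prep_table", "data.frame")
  rec
}
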