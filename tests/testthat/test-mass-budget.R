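test_that("AUC fractions match closed-form rectangle and triangle areas", {
  rect <- data.frame(size_nt = seq(0, 300, by = 10), intensity = 2)
  expect_equal(auc_fraction(rect, 150), 0.5, tolerance = 1e-12)
  expect_equal(auc_fraction(rect, 1000), 1)
  expect_equal(auc_fraction(rect, -5), 0)

  tri <- data.frame(size_nt = seq(0, 100, by = 1), intensity = seq(0, 100, by = 1))
  expect_equal(auc_fraction(tri, 50), 0.25, tolerance = 1e-12)

  # cutoff between grid points: linear interpolation, rectangle stays exact
  expect_equal(auc_fraction(rect, 155), 155 / 300, tolerance = 1e-12)

  flat <- data.frame(size_nt = c(1, 2), intensity = c(0, 0))
  expect_error(auc_fraction(flat, 1.5), "zero total area")
})

test_that("AUC fraction agrees with an independent trapezoid oracle", {
  set.seed(42)
  tr <- data.frame(size_nt = sort(runif(200, 10, 500)),
                   intensity = rexp(200))
  for (cut in c(50, 120, 333)) {
    idx <- tr$size_nt <= cut
    oracle_num <- pracma::trapz(tr$size_nt[idx], tr$intensity[idx])
    # add the partial trapezoid up to the cutoff
    i <- max(which(idx))
    if (i < nrow(tr)) {
      y_cut <- approx(tr$size_nt, tr$intensity, xout = cut)$y
      oracle_num <- oracle_num +
        (cut - tr$size_nt[i]) * (tr$intensity[i] + y_cut) / 2
    }
    oracle <- oracle_num / pracma::trapz(tr$size_nt, tr$intensity)
    expect_equal(auc_fraction(tr, cut), oracle, tolerance = 1e-10)
  }
})

test_that("AUC fraction is monotone non-decreasing in the cutoff", {
  tr <- generate_electropherogram(8, 0.4, 0.5, seed = 5)$total
  fr <- sapply(seq(20, 5000, length.out = 40), function(cut) auc_fraction(tr, cut))
  expect_true(all(diff(fr) >= -1e-12))
})

test_that("per-cell RNA mass and lineage fold ratios match the reference table", {
  expect_equal(total_rna_per_cell(2.20, 1e6), 2.20)
  expect_equal(total_rna_per_cell(0, 1e6), 0)
  expect_error(total_rna_per_cell(2, 0), "cells")

  rec <- generate_cell_records()
  fg <- setNames(total_rna_per_cell(rec$total_rna_ng, rec$cells_extracted),
                 rec$cell_type)
  expect_equal(round(fold_ratio(fg[["T-cell"]], fg[["B-cell"]]), 2), 1.61)
  expect_equal(round(fold_ratio(fg[["B-cell"]], fg[["granulocyte"]]), 2), 2.10)
  expect_equal(round(fold_ratio(fg[["platelet"]], fg[["erythrocyte"]]), 2), 3.86)
})

test_that("miRNA fraction of total is the product of the two AUC fractions", {
  tr <- generate_electropherogram(10, 0.5, 0.5, seed = 1)
  expect_equal(mirna_fraction_of_total(tr$total, tr$small),
               auc_fraction(tr$total, 150) * auc_fraction(tr$small, 40))

  # platelet-like inputs: fraction 0.05/2.20 makes miRNA mass 0.05 fg/cell
  frac <- default_mass_fractions()
  plat <- frac[frac$cell_type == "platelet", ]
  f <- plat$small_fraction * plat$mirna_fraction_of_small
  expect_equal(f, 0.05 / 2.20, tolerance = 1e-12)
  expect_equal(2.20 * f, 0.05, tolerance = 1e-12)

  # only the far Gaussian tail of the >40 nt peak remains below the cutoff
  none <- generate_electropherogram(10, 0.5, 0, seed = 1)
  expect_lt(mirna_fraction_of_total(none$total, none$small), 1e-4)
})

test_that("per-volume contributions convert units and rank lineages correctly", {
  expect_equal(per_volume_contribution(0.04, 4.6e6)$mirna_pg_per_ul_blood, 184.0)
  expect_equal(per_volume_contribution(0.5, 0)$mirna_pg_per_ul_blood, 0)

  bud <- build_mass_budget(generate_cell_records())
  pg <- setNames(bud$mirna_pg_per_ul_blood, bud$cell_type)
  expect_equal(round(unname(pg[blood_cell_types()]), 2),
               c(16.90, 3.55, 0.64, 50.24, 184.0))
  expect_identical(bud$cell_type[order(bud$rank)],
                   c("erythrocyte", "granulocyte", "platelet", "T-cell", "B-cell"))
})

test_that("budgets built from generated traces agree with the fraction route", {
  rec <- generate_cell_records()
  frac <- default_mass_fractions()
  traces <- lapply(seq_len(nrow(frac)), function(i) {
    generate_electropherogram(rec$total_rna_ng[i], frac$small_fraction[i],
                              frac$mirna_fraction_of_small[i], seed = 100 + i)
  })
  names(traces) <- frac$cell_type
  via_traces <- build_mass_budget(rec, traces)
  via_fracs <- build_mass_budget(rec, frac)
  expect_equal(via_traces$mirna_fg_per_cell, via_fracs$mirna_fg_per_cell,
               tolerance = 0.03)
  expect_equal(via_traces$total_rna_fg_per_cell, via_fracs$total_rna_fg_per_cell)
})

test_that("apportionment handles exclusive, symmetric and planted patterns", {
  bud <- build_mass_budget(generate_cell_records())

  # probe present in one cell type only -> 100% from that cell type
  avg <- matrix(0, 1, 5, dimnames = list("only", blood_cell_types()))
  avg[1, "granulocyte"] <- 0.4
  sh <- apportion_blood_shares(avg, bud)
  expect_equal(sh$granulocyte, 100)
  expect_equal(sh$platelet, 0)

  # equal fractions and equal budgets -> 20% each
  eq_bud <- bud
  eq_bud$mirna_fg_per_cell <- rep(1, 5)
  eq_bud$cells_per_ul <- rep(1000, 5)
  avg2 <- matrix(0.1, 2, 5, dimnames = list(c("a", "b"), blood_cell_types()))
  sh2 <- apportion_blood_shares(avg2, eq_bud)
  expect_equal(unlist(sh2[1, blood_cell_types()], use.names = FALSE), rep(20, 5))

  # planted shares recovered exactly when abundances invert the mass weights
  target <- c(platelet = 0, "T-cell" = 84, "B-cell" = 10,
              granulocyte = 5, erythrocyte = 1)
  w <- setNames(bud$mirna_fg_per_cell * bud$cells_per_ul, bud$cell_type)
  avg3 <- matrix(target[blood_cell_types()] / w[blood_cell_types()], 1,
                 dimnames = list("planted", blood_cell_types()))
  sh3 <- apportion_blood_shares(avg3 / sum(avg3), bud)
  expect_equal(unlist(sh3[1, blood_cell_types()], use.names = FALSE),
               unname(target), tolerance = 1e-9)

  # zero-mass probes are flagged with NA shares
  avg4 <- rbind(avg, zero = 0)
  sh4 <- apportion_blood_shares(avg4, bud)
  expect_true(sh4$zero_mass[2])
  expect_true(all(is.na(sh4[2, blood_cell_types()])))

  expect_error(apportion_blood_shares(avg[, 1:4, drop = FALSE], bud),
               "cell-type mismatch")
})

test_that("shares are conserved and invariant to a common cell-count rescale", {
  set.seed(7)
  bud <- build_mass_budget(generate_cell_records())
  avg <- matrix(rexp(40 * 5), 40, 5,
                dimnames = list(sprintf("p%02d", 1:40), blood_cell_types()))
  avg <- sweep(avg, 2, colSums(avg), `/`)
  sh <- apportion_blood_shares(avg, bud)
  expect_true(all(abs(rowSums(sh[, blood_cell_types()]) - 100) < 1e-6))

  bud2 <- bud
  bud2$cells_per_ul <- bud2$cells_per_ul * 3.7
  sh2 <- apportion_blood_shares(avg, bud2)
  expect_equal(sh[, blood_cell_types()], sh2[, blood_cell_types()],
               tolerance = 1e-12)
})

test_that("display rounding happens only at serialization", {
  bud <- build_mass_budget(generate_cell_records())
  avg <- matrix(c(0.333, 0.333, 0.334, 0.2, 0.1), 1,
                dimnames = list("p1", blood_cell_types()))
  sh <- apportion_blood_shares(avg, bud)
  path <- withr::local_tempfile(fileext = ".csv")
  write_blood_shares(sh, path)
  disk <- read.csv(path, check.names = FALSE)
  expect_true(all(disk[blood_cell_types()] == round(disk[blood_cell_types()])))
  expect_equal(sum(sh[1, blood_cell_types()]), 100, tolerance = 1e-9)
})
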