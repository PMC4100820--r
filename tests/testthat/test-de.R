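test_that("Welch ANOVA handles degenerate and two-group cases", {
  same <- replicate(5, c(3, 3, 3), simplify = FALSE)
  res <- welch_anova(same)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  expect_error(welch_anova(list(c(1, 2), 3)), ">= 2 values")
  expect_error(welch_anova(list(c(1, 2))), ">= 2 groups")

  # two groups: F is the squared Welch t statistic with the same p
  set.seed(17)
  for (i in 1:25) {
    g1 <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 2))
    g2 <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    w <- welch_anova(list(g1, g2))
    tt <- t.test(g1, g2)
    expect_equal(w$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(w$p, tt$p.value, tolerance = 1e-10)
    expect_equal(w$df2, unname(tt$parameter), tolerance = 1e-10)
  }
})

test_that("Welch ANOVA agrees with the base oneway.test oracle", {
  set.seed(18)
  for (i in 1:25) {
    k <- sample(3:6, 1)
    groups <- lapply(seq_len(k), function(g) rnorm(sample(3:9, 1), mean = g / 3))
    w <- welch_anova(groups)
    vals <- unlist(groups)
    fac <- factor(rep(seq_len(k), lengths(groups)))
    ow <- oneway.test(vals ~ fac, var.equal = FALSE)
    expect_equal(w$F, unname(ow$statistic), tolerance = 1e-10)
    expect_equal(w$p, ow$p.value, tolerance = 1e-10)
  }
})

test_that("clearly separated hand data is significant", {
  w <- welch_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_lt(w$p, 0.05)
  # closed-form Welch t on this data: t = 3 / sqrt(2/3)
  expect_equal(w$F, (3 / sqrt(2 / 3))^2, tolerance = 1e-12)
})

test_that("Welch F is invariant to location and scale changes", {
  set.seed(19)
  groups <- lapply(1:4, function(g) rnorm(5, mean = g))
  base <- welch_anova(groups)
  shifted <- welch_anova(lapply(groups, function(g) g + 100))
  scaled <- welch_anova(lapply(groups, function(g) g * 0.01))
  expect_equal(base$F, shifted$F, tolerance = 1e-8)
  expect_equal(base$F, scaled$F, tolerance = 1e-8)
})

test_that("BH adjustment matches hand arithmetic and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.73), 0.73)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(20)
  for (i in 1:50) {
    p <- runif(sample(2:200, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("BH preserves p-value ordering and bounds q in [p, 1]", {
  set.seed(23)
  p <- runif(500)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15 & q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("Tukey post-hoc flags exactly the separated group", {
  jitter5 <- c(-0.02, -0.01, 0, 0.01, 0.02)
  groups <- c(lapply(1:4, function(i) jitter5), list(10 + jitter5))
  names(groups) <- paste0("g", 1:5)
  ph <- posthoc(groups, mode = "tukey")
  expect_equal(sum(ph$significant) / 2, 4)  # symmetric matrix
  expect_true(all(ph$significant["g5", paste0("g", 1:4)]))
  expect_length(ph$subsets, 2)

  flat <- posthoc(lapply(1:5, function(i) jitter5), mode = "tukey")
  expect_false(any(flat$significant))
  expect_length(flat$subsets, 1)

  expect_error(posthoc(groups, mode = "lsd"), "arg")
})

test_that("Tukey p-values agree with TukeyHSD on balanced data", {
  set.seed(24)
  vals <- rnorm(20, rep(c(0, 0.5, 1.5, 3), each = 5))
  fac <- factor(rep(paste0("g", 1:4), each = 5))
  ph <- posthoc(split(vals, fac), mode = "tukey")
  hsd <- TukeyHSD(aov(vals ~ fac))$fac
  for (row in rownames(hsd)) {
    pair <- strsplit(row, "-")[[1]]
    expect_equal(ph$p[pair[1], pair[2]], hsd[row, "p adj"], tolerance = 1e-8)
  }
})

test_that("SNK lets a middle group join both homogeneous subsets", {
  pattern <- c(-1, -0.5, 0, 0.5, 1) * 1.7
  groups <- list(g1 = 0 + pattern, g2 = 1.4 + pattern, g3 = 2.8 + pattern)
  # hand check: se_unit = sqrt(s2/5) = 0.601; q13 = 4.66 > qtukey(.95,3,12) = 3.77;
  # q12 = q23 = 2.33 < qtukey(.95,2,12) = 3.08
  ph <- posthoc(groups, mode = "snk")
  expect_true(ph$significant["g1", "g3"])
  expect_false(ph$significant["g1", "g2"])
  expect_false(ph$significant["g2", "g3"])
  expect_equal(length(ph$subsets), 2)
  expect_true(all(c("g1", "g2") %in% ph$subsets[[1]]))
  expect_true(all(c("g2", "g3") %in% ph$subsets[[2]]))
})

test_that("SNK stepwise protection blocks nested comparisons", {
  # overall range non-significant -> every nested pair non-significant too
  pattern <- c(-1, -0.5, 0, 0.5, 1) * 3
  groups <- list(g1 = 0 + pattern, g2 = 0.5 + pattern, g3 = 1 + pattern)
  ph <- posthoc(groups, mode = "snk")
  expect_false(any(ph$significant))
  expect_length(ph$subsets, 1)
})

test_that("null data keeps the raw false-positive rate near alpha", {
  ds <- generate_count_dataset(null_config(n_endogenous = 1000, seed = 22))
  proc <- process_counts(ds$experiment)
  de <- de_by_cell_type(proc)
  fp <- mean(de$table$p < 0.05)
  se3 <- 3 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(fp, 0.05 - se3)
  expect_lt(fp, 0.05 + se3)
  expect_lte(sum(de$table$de), 10)  # BH under the global null
})

test_that("planted lineage-specific probes land on the right DE lists", {
  cfg <- sim_config(seed = 25, lineage_frac = 0, stable_plan = character(0))
  ds <- generate_count_dataset(cfg)
  de <- de_by_cell_type(process_counts(ds$experiment))
  truth_by_ct <- split(vapply(cfg$de_plan, `[[`, "", "probe"),
                       vapply(cfg$de_plan, function(e) e$lineages[1], ""))
  found <- 0; planted_total <- 0; assigned_total <- 0
  for (ct in names(truth_by_ct)) {
    hits <- de$by_lineage[[ct]]$probe
    found <- found + sum(truth_by_ct[[ct]] %in% hits)
    planted_total <- planted_total + length(truth_by_ct[[ct]])
    assigned_total <- assigned_total + length(hits)
  }
  expect_gte(found / planted_total, 0.9)              # sensitivity
  all_planted <- unlist(truth_by_ct)
  false_assigned <- sum(!unlist(lapply(de$by_lineage, `[[`, "probe")) %in% all_planted)
  expect_lte(false_assigned / max(assigned_total, 1), 0.1)
  # planted probes are elevated in their lineage
  for (ct in names(truth_by_ct)) {
    dirs <- de$by_lineage[[ct]]
    expect_true(all(dirs$direction[dirs$probe %in% truth_by_ct[[ct]]] == "up"))
  }
})

test_that("probes absent in a lineage are routed to the SNK post-hoc", {
  cfg <- sim_config(seed = 26, n_endogenous = 150, lineage_frac = 0,
                    baseline_log_mean = 8,
                    de_plan = list(list(probe = "syn-miR-de", lineages = "T-cell",
                                        fold = 16)),
                    stable_plan = character(0),
                    absent_plan = list(list(probe = "syn-miR-gone",
                                            lineages = "platelet")))
  ds <- generate_count_dataset(cfg)
  de <- de_by_cell_type(process_counts(ds$experiment))
  tab <- de$table
  expect_equal(tab$posthoc_mode[tab$probe == "syn-miR-gone"], "snk")
  expect_equal(tab$posthoc_mode[tab$probe == "syn-miR-de"], "tukey")
})

test_that("selectively reduced probes are high in two lineages, lost in one", {
  vals <- rbind(
    reduced = c(9000, 9000, 8000, 8000, 2, 2),
    high_everywhere = rep(8000, 6),
    low_everywhere = rep(5, 6)
  )
  colnames(vals) <- paste0("s", 1:6)
  samples <- data.frame(sample = colnames(vals),
                        donor = rep(c("D1", "D2"), 3),
                        cell_type = rep(c("platelet", "T-cell", "B-cell"), each = 2))
  proc <- mir_processed(vals, vals[0, , drop = FALSE], samples,
                        factors = setNames(rep(1, 6), colnames(vals)))
  de <- de_by_cell_type(proc)
  expect_identical(de$selectively_reduced$probe, "reduced")
  expect_match(de$selectively_reduced$low_in, "B-cell")
})
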