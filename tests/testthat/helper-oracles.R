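# Independent oracles and small fixtures shared across tests.

# Brute-force Benjamini-Hochberg step-up, written directly from the
# definition: q_(i) = min over j >= i of p_(j) * m / j.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# O(n^3) complete-linkage agglomeration on a distance matrix; returns the
# merge heights in order.
brute_complete_linkage_heights <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best_h <- Inf
    best <- c(1L, 2L)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Generator configuration with no planted structure of any kind: every probe
# is exchangeable across cell types (global null).
null_config <- function(n_endogenous = 200, n_donors = 5, seed = 1,
                        baseline_log_mean = 8, baseline_log_sd = 1,
                        residual_sd = 0.4, donor_sd = 0) {
  sim_config(
    n_donors = n_donors, n_endogenous = n_endogenous,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    donor_sd = donor_sd, residual_sd = residual_sd,
    lineage_frac = 0, de_plan = list(), stable_plan = character(0),
    seed = seed
  )
}

# miR-150-like target apportionment pattern used in recovery tests.
planted_shares <- c(platelet = 0, "T-cell" = 84, "B-cell" = 10,
                    granulocyte = 5, erythrocyte = 1)

share_config <- function(seed = 1, ...) {
  sim_config(
    share_plan = list(list(probe = "syn-miR-planted", shares = planted_shares)),
    seed = seed, ...
  )
}

# Minimal GEO series-matrix text fixture written from a mir_experiment.
write_series_matrix_fixture <- function(exper, path, exponent = FALSE) {
  titles <- exper$samples$sample
  gsm <- sprintf("GSM%04d", seq_along(titles))
  fmt <- function(x) {
    if (exponent) sprintf("%.6e", x) else format(x, scientific = FALSE, trim = TRUE)
  }
  lines <- c(
    "!Series_title\t\"synthetic blood-cell miRNA profiles\"",
    paste0("!Sample_title\t", paste(sprintf('"%s"', titles), collapse = "\t")),
    paste0("!Sample_geo_accession\t", paste(sprintf('"%s"', gsm), collapse = "\t")),
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"", sprintf('"%s"', gsm)), collapse = "\t")
  )
  for (i in seq_len(nrow(exper$counts))) {
    lines <- c(lines, paste(c(sprintf('"%s"', rownames(exper$counts)[i]),
                              fmt(exper$counts[i, ])), collapse = "\t"))
  }
  lines <- c(lines, "!series_matrix_table_end")
  writeLines(lines, path)
  data.frame(title = titles, donor = exper$samples$donor,
             cell_type = exper$samples$cell_type, stringsAsFactors = FALSE)
}
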