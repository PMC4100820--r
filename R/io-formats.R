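#' Write / read a probe count matrix as CSV
#'
#' Layout: first column `probe_id`, second column `probe_class`
#' (Endogenous / Negative / Positive), remaining columns one per sample.
#' A sample sheet (columns `sample`, `donor`, `cell_type`) travels in a
#' separate CSV.
#'
#' @param x a [mir_experiment()].
#' @param counts_path,samples_path output CSV paths.
#' @return invisibly, the paths written.
#' @export
write_count_matrix <- function(x, counts_path, samples_path) {
  stopifnot(inherits(x, "mir_experiment"))
  df <- data.frame(probe_id = rownames(x$counts), probe_class = x$probe_class,
                   x$counts, check.names = FALSE)
  utils::write.csv(df, counts_path, row.names = FALSE)
  utils::write.csv(x$samples, samples_path, row.names = FALSE)
  invisible(c(counts_path, samples_path))
}

#' @rdname write_count_matrix
#' @param codeset_version codeset label attached to the returned object.
#' @export
read_count_matrix <- function(counts_path, samples_path, codeset_version = "v2") {
  if (!file.exists(counts_path)) stop("format error: no such file: ", counts_path)
  df <- utils::read.csv(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df)[1:2], c("probe_id", "probe_class"))) {
    stop("format error: count matrix must start with columns probe_id, probe_class")
  }
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$probe_id
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  mir_experiment(counts, df$probe_class, samples, codeset_version)
}

#' Write / read electropherogram traces and cell-prep records
#'
#' Traces are two-column CSVs (`size_nt`, `intensity`); cell records use the
#' [generate_cell_records()] column layout.
#'
#' @param trace data.frame with columns `size_nt`, `intensity`.
#' @param path CSV path.
#' @return the object read, or invisibly the path written.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace[, c("size_nt", "intensity")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("size_nt", "intensity") %in% names(df))) {
    stop("format error: trace CSV needs columns size_nt, intensity")
  }
  validate_trace(df)
  df
}

#' @rdname write_trace
#' @param records a `cell_prep_table` data.frame.
#' @export
write_cell_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_cell_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_type", "cells_extracted", "total_rna_ng", "cells_per_ul_blood")
  if (!all(need %in% names(rec))) {
    stop("format error: cell records CSV needs columns ", paste(need, collapse = ", "))
  }
  if (any(rec$cells_extracted <= 0) || any(rec$cells_per_ul_blood <= 0) ||
      any(rec$total_rna_ng < 0)) {
    stop("validation error: cell records must be positive")
  }
  class(rec) <- c("cell_prep_table", "data.frame")
  rec
}

#' Read a GEO series-matrix file into a count experiment
#'
#' Parses the plain-text series-matrix format (tab-delimited table between
#' `!series_matrix_table_begin` / `!series_matrix_table_end`, `!`-prefixed
#' metadata headers). Sample titles are mapped to donor and cell type through
#' a user-supplied mapping table; expression values pass through unmodified.
#' Probe classes are inferred from the probe id prefix (`NEG*` negative,
#' `POS*` positive, everything else endogenous).
#'
#' @param path local series-matrix text file (no network retrieval).
#' @param sample_map data.frame with columns `title`, `donor`, `cell_type`.
#' @return a [mir_experiment()].
#' @export
read_geo_series_matrix <- function(path, sample_map) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  if (!all(c("title", "donor", "cell_type") %in% names(sample_map))) {
    stop("format error: sample_map needs columns title, donor, cell_type")
  }
  lines <- readLines(path, warn = FALSE)
  unq <- function(x) gsub('^"|"$', "", x)

  grab <- function(key) {
    i <- grep(paste0("^!", key, "\\b"), lines)
    if (!length(i)) return(NULL)
    unq(strsplit(lines[i[1]], "\t")[[1]][-1])
  }
  titles <- grab("Sample_title")
  accessions <- grab("Sample_geo_accession")
  if (is.null(titles)) stop("format error: no !Sample_title line")

  beg <- grep("^!series_matrix_table_begin", lines)
  fin <- grep("^!series_matrix_table_end", lines)
  if (!length(beg) || !length(fin)) {
    stop("format error: series-matrix table markers not found")
  }
  tab <- lines[(beg + 1):(fin - 1)]
  header <- unq(strsplit(tab[1], "\t")[[1]])
  body <- strsplit(tab[-1], "\t")
  ids <- vapply(body, function(r) unq(r[1]), "")
  vals <- t(vapply(body, function(r) as.numeric(unq(r[-1])), numeric(length(header) - 1)))
  if (length(ids) == 1L) vals <- matrix(vals, nrow = 1)
  dimnames(vals) <- list(ids, header[-1])

  # columns are named by GSM accession; map accession -> title -> annotation
  col_titles <- if (!is.null(accessions) &&
                    all(colnames(vals) %in% accessions)) {
    titles[match(colnames(vals), accessions)]
  } else {
    titles[seq_len(ncol(vals))]
  }
  unmapped <- setdiff(col_titles, sample_map$title)
  if (length(unmapped)) {
    stop("validation error: unmapped sample titles: ",
         paste(unmapped, collapse = ", "))
  }
  m <- sample_map[match(col_titles, sample_map$title), ]
  samples <- data.frame(sample = colnames(vals), donor = m$donor,
                        cell_type = m$cell_type, stringsAsFactors = FALSE)
  probe_class <- ifelse(grepl("^NEG", ids), "Negative",
                        ifelse(grepl("^POS", ids), "Positive", "Endogenous"))
  mir_experiment(vals, probe_class, samples, codeset_version = "geo")
}

# Probe identity across codeset versions: the probe-name string with any
# assay-version suffix ("-v1", "_v2", "|v1", ".v2", ...) stripped. Compound
# multi-target names ("miR-106a-5p/17-5p") are kept whole.
canonical_probe_id <- function(ids) {
  sub("[._|-][vV][0-9]+$", "", ids)
}

#' Restrict two count experiments to their shared probe set
#'
#' Probes are matched by canonical id (assay-version suffixes stripped), the
#' way codeset v1/v2 panels are merged by miRNA identity. Both outputs carry
#' the shared probes in the same order (order of first appearance in `a`).
#'
#' @param a,b [mir_experiment()] objects.
#' @return list with elements `a` and `b`, both restricted to the shared
#'   probes; a message reports how many probes were dropped from each input.
#' @export
intersect_probe_sets <- function(a, b) {
  stopifnot(inherits(a, "mir_experiment"), inherits(b, "mir_experiment"))
  ca <- canonical_probe_id(rownames(a$counts))
  cb <- canonical_probe_id(rownames(b$counts))
  shared <- unique(ca[ca %in% cb])
  if (!length(shared)) stop("validation error: probe sets have empty intersection")
  ia <- match(shared, ca)
  ib <- match(shared, cb)
  message(sprintf("intersect_probe_sets: kept %d probes (dropped %d from a, %d from b)",
                  length(shared), nrow(a$counts) - length(shared),
                  nrow(b$counts) - length(shared)))
  take <- function(x, idx, ids) {
    cnt <- x$counts[idx, , drop = FALSE]
    rownames(cnt) <- ids
    mir_experiment(cnt, x$probe_class[idx], x$samples, x$codeset_version)
  }
  list(a = take(a, ia, shared), b = take(b, ib, shared))
}
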