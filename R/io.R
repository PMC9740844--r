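#' Read a tab-separated table
#'
#' Plain TSV with a header row; lines starting with `#` (the config-hash
#' stamp written by this package) are skipped.
#'
#' @param path File path.
#' @param ... Passed to [utils::read.delim()].
#' @return Data frame.
#' @export
read_tsv <- function(path, ...) {
  if (!file.exists(path))
    stop_ctx("file not found: ", path, class = "input_error")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Write a tab-separated table
#'
#' @param x Data frame.
#' @param path Output path.
#' @param config_hash Optional hash string stamped as a leading `#` comment
#'   so every table declares the configuration that produced it.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

id_columns <- c("accession", "description", "gene", "group",
                "n_peptides", "min_peptide_score", "spectral_count")

#' Read a protein identification table
#'
#' Expects the documented TSV layout: `accession`, `description`, `gene`,
#' `group`, `n_peptides`, `min_peptide_score`, `spectral_count` — one row
#' per protein per group, holding that protein's identification evidence
#' and pooled spectral count within the group.
#'
#' @param path TSV path.
#' @return Data frame with the columns above.
#' @export
read_identifications <- function(path) {
  df <- read_tsv(path)
  missing <- setdiff(id_columns, names(df))
  if (length(missing))
    stop_ctx("identification table lacks columns: ",
             paste(missing, collapse = ", "), class = "input_error")
  df
}

#' Write a protein identification table
#' @param x Identification data frame.
#' @param path Output TSV path.
#' @param config_hash Optional provenance stamp; see [write_tsv()].
#' @return `path`, invisibly.
#' @export
write_identifications <- function(x, path, config_hash = NULL) {
  missing <- setdiff(id_columns, names(x))
  if (length(missing))
    stop_ctx("identification table lacks columns: ",
             paste(missing, collapse = ", "), class = "input_error")
  write_tsv(x[id_columns], path, config_hash = config_hash)
}

#' Construct a metabolite panel
#'
#' The container for targeted metabolomics data: a metabolite-by-sample
#' matrix of strictly positive concentrations (units: amount per total
#' protein content of the extract) with exactly one group label per sample
#' and exactly two groups present.
#'
#' @param concentrations Numeric matrix, metabolites in rows (rownames =
#'   metabolite identifiers), samples in columns.
#' @param groups Group label per sample (character or factor, length
#'   `ncol(concentrations)`); the first factor level is the contrast's
#'   numerator group A.
#' @return A `metabolite_panel` object.
#' @export
metabolite_panel <- function(concentrations, groups) {
  if (!is.matrix(concentrations) || !is.numeric(concentrations))
    stop_ctx("concentrations must be a numeric matrix", class = "input_error")
  if (is.null(rownames(concentrations)))
    rownames(concentrations) <- sprintf("M%03d", seq_len(nrow(concentrations)))
  if (is.null(colnames(concentrations)))
    colnames(concentrations) <- sprintf("S%03d", seq_len(ncol(concentrations)))
  if (length(groups) != ncol(concentrations))
    stop_ctx("need exactly one group label per sample", class = "input_error")
  groups <- if (is.factor(groups)) droplevels(groups) else
    factor(groups, levels = unique(groups))
  if (nlevels(groups) != 2)
    stop_ctx("a metabolite panel must contain exactly two groups, got ",
             nlevels(groups), class = "input_error")
  bad <- which(!is.finite(concentrations) | concentrations <= 0,
               arr.ind = TRUE)
  if (nrow(bad))
    stop_ctx("non-positive concentration for metabolite '",
             rownames(concentrations)[bad[1, 1]], "', sample '",
             colnames(concentrations)[bad[1, 2]], "'",
             class = "validation_error")
  structure(list(concentrations = concentrations, groups = groups,
                 metabolite_ids = rownames(concentrations),
                 sample_ids = colnames(concentrations)),
            class = "metabolite_panel")
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat(sprintf("metabolite_panel: %d metabolites x %d samples (%s)\n",
              nrow(x$concentrations), ncol(x$concentrations),
              paste(sprintf("%s: n=%d", levels(x$groups),
                            tabulate(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Read a metabolite panel from TSV files
#'
#' @param panel_path TSV with metabolite identifiers in the first column and
#'   one column per sample.
#' @param groups_path Two-column TSV mapping `sample` to `group`.
#' @return A [metabolite_panel()].
#' @export
read_panel <- function(panel_path, groups_path) {
  tab <- read_tsv(panel_path, check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  map <- read_tsv(groups_path)
  if (!all(c("sample", "group") %in% names(map)))
    stop_ctx("group map needs columns 'sample' and 'group'",
             class = "input_error")
  i <- match(colnames(mat), map$sample)
  if (anyNA(i))
    stop_ctx("samples missing from group map: ",
             paste(colnames(mat)[is.na(i)], collapse = ", "),
             class = "input_error")
  metabolite_panel(mat, map$group[i])
}

#' Write a metabolite panel to TSV files
#' @param panel A [metabolite_panel()].
#' @param panel_path,groups_path Output TSV paths (concentration matrix and
#'   sample-to-group map).
#' @param config_hash Optional provenance stamp; see [write_tsv()].
#' @return `panel_path`, invisibly.
#' @export
write_panel <- function(panel, panel_path, groups_path,
                        config_hash = NULL) {
  stopifnot(inherits(panel, "metabolite_panel"))
  df <- data.frame(metabolite_id = panel$metabolite_ids,
                   panel$concentrations, check.names = FALSE)
  write_tsv(df, panel_path, config_hash = config_hash)
  write_tsv(data.frame(sample = panel$sample_ids,
                       group = as.character(panel$groups)),
            groups_path, config_hash = config_hash)
  invisible(panel_path)
}
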