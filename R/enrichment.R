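#' Read annotation sets from a GMT file
#'
#' Standard gene-matrix-transposed format: one term per line, tab-separated
#' as term id, description, then members. The description column is kept
#' (it carries the human-readable term name).
#'
#' @param path GMT file path.
#' @param case Case normalisation applied to member identifiers: `"upper"`
#'   (default, the gene-symbol convention), `"lower"`, or `"asis"`.
#' @return An `annotation_sets` object: named list of terms, each a list
#'   with `term_id`, `term_name`, `members`.
#' @export
read_gmt <- function(path, case = c("upper", "lower", "asis")) {
  case <- match.arg(case)
  if (!file.exists(path))
    stop_ctx("file not found: ", path, class = "input_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop_ctx("malformed GMT line (need id, description, >= 1 member): ",
               substr(ln, 1, 60), class = "input_error")
    members <- unique(parts[-(1:2)])
    members <- switch(case, upper = toupper(members),
                      lower = tolower(members), asis = members)
    list(term_id = parts[1], term_name = parts[2], members = members)
  })
  names(sets) <- vapply(sets, `[[`, "", "term_id")
  structure(sets, class = "annotation_sets")
}

#' Write annotation sets to a GMT file
#' @param sets An `annotation_sets` object (or compatible named list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$term_id, s$term_name %||% s$term_id, s$members),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis by one-sided Fisher's exact test
#'
#' For each annotation term, tests whether the query protein set contains
#' more term members than expected under hypergeometric sampling from the
#' background, i.e. the one-sided ("greater") Fisher exact p-value of the
#' 2x2 table (k, n-k; K-k, N-K-n+k) with k = |query & term|,
#' K = |background & term|, n = |query|, N = |background|. Terms with fewer
#' than `min_set_size` background members are skipped (degenerate
#' single-member terms carry no enrichment signal).
#'
#' @param query Character vector of query identifiers; must be a subset of
#'   `background`.
#' @param background Character vector: the identifier universe (for
#'   spectral-count proteomics, the filtered identification universe, not
#'   the whole genome).
#' @param sets An `annotation_sets` object ([read_gmt()],
#'   [simulate_annotation_sets()]).
#' @param min_set_size Minimum background members per tested term
#'   (default 2).
#' @param ease If `TRUE`, apply the EASE-score modification (the Fisher
#'   p-value computed on k - 1, a conservative variant used by some
#'   annotation servers). Default plain Fisher.
#' @param case Case normalisation applied to query/background; see
#'   [read_gmt()].
#' @return Data frame sorted by p ascending with columns term_id,
#'   term_name, k, K, n, N, p_value, fdr (Benjamini-Hochberg across the
#'   tested terms).
#' @export
#' @examples
#' sets <- simulate_annotation_sets(10, sprintf("G%02d", 1:40),
#'                                  planted_subset = sprintf("G%02d", 1:8),
#'                                  seed = 2)
#' head(fisher_enrichment(sprintf("G%02d", 1:8), sprintf("G%02d", 1:40), sets))
fisher_enrichment <- function(query, background, sets, min_set_size = 2,
                              ease = FALSE,
                              case = c("upper", "lower", "asis")) {
  case <- match.arg(case)
  norm <- switch(case, upper = toupper, lower = tolower, asis = identity)
  query <- unique(norm(query))
  background <- unique(norm(background))
  if (length(background) == 0)
    stop_ctx("background must be non-empty", class = "input_error")
  offenders <- setdiff(query, background)
  if (length(offenders))
    stop_ctx("query identifiers absent from background: ",
             paste(utils::head(offenders, 10), collapse = ", "),
             if (length(offenders) > 10) ", ..." else "",
             class = "identifier_mismatch_error")
  N <- length(background)
  n <- length(query)
  rows <- lapply(sets, function(s) {
    members <- intersect(norm(s$members), background)
    K <- length(members)
    if (K < min_set_size) return(NULL)
    k <- length(intersect(members, query))
    keff <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(keff - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = s$term_id, term_name = s$term_name %||% s$term_id,
               k = k, K = K, n = n, N = N, p_value = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric())
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1; input order is preserved.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order and length.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop_ctx("p-values must be numbers in [0, 1]",
             class = "validation_error")
  stats::p.adjust(p_values, method = "BH")
}

#' Threshold enrichment results on p or FDR
#'
#' Inclusive thresholds, mirroring the two published usages: raw Fisher
#' p <= 0.05 (annotation-server mode) or Benjamini-Hochberg FDR <= 0.05
#' (network-server mode).
#'
#' @param results Data frame from [fisher_enrichment()].
#' @param alpha_p,alpha_fdr Significance levels for the two modes.
#' @param mode `"p"` gates on the raw p-value, `"fdr"` on the adjusted one.
#' @return The retained rows.
#' @export
filter_significant <- function(results, alpha_p = 0.05, alpha_fdr = 0.05,
                               mode = c("p", "fdr")) {
  mode <- match.arg(mode)
  if (nrow(results) == 0) return(results)
  keep <- if (mode == "p") results$p_value <= alpha_p
          else results$fdr <= alpha_fdr
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
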