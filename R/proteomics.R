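#' Filter a protein identification table by peptide evidence
#'
#' Retains proteins identified by at least `min_peptides` assigned peptides
#' whose weakest counted peptide scores strictly above `min_score` (the
#' classical search-engine acceptance rule for confident identifications:
#' at least two peptides, each with score > 19). Inclusive on the peptide
#' count, strict on the score.
#'
#' @param records Data frame with columns `n_peptides` and
#'   `min_peptide_score` (plus any others, e.g. the standard identification
#'   layout of [read_identifications()]).
#' @param min_peptides Minimum number of assigned peptides (inclusive).
#' @param min_score Score that every counted peptide must exceed (strict).
#' @param quiet Suppress the before/after log line.
#' @return The retained rows, input order preserved.
#' @export
#' @examples
#' ids <- data.frame(accession = c("P1", "P2"), n_peptides = c(3, 1),
#'                   min_peptide_score = c(25, 100))
#' filter_identifications(ids)  # P2 dropped: single-peptide identification
filter_identifications <- function(records, min_peptides = 2,
                                   min_score = 19, quiet = FALSE) {
  need <- c("n_peptides", "min_peptide_score")
  if (!all(need %in% names(records)))
    stop_ctx("identification table lacks columns: ",
             paste(setdiff(need, names(records)), collapse = ", "),
             class = "input_error")
  keep <- records$n_peptides >= min_peptides &
    records$min_peptide_score > min_score
  out <- records[keep, , drop = FALSE]
  if (!quiet)
    message(sprintf(
      "identification filter (>= %d peptides, score > %g): %d -> %d records",
      min_peptides, min_score, nrow(records), nrow(out)))
  rownames(out) <- NULL
  out
}

#' Aggregate identification records into pooled spectral-count entries
#'
#' Builds one entry per accession seen in either group of the contrast, with
#' spectral count 0 where a protein was not observed, and lane totals
#' `t1`/`t2` equal to the column sums of the retained proteins (totals are
#' computed after identification filtering, over exactly the quantified
#' universe).
#'
#' @param records Filtered identification data frame with columns
#'   `accession`, `group`, `spectral_count`.
#' @param sample1,sample2 Group labels mapped to the `n1` and `n2` slots of
#'   the Rsc formula respectively (positive Rsc means higher in `sample2`;
#'   see [compute_rsc()]).
#' @return Data frame (accession, n1, n2, t1, t2), accessions in first-seen
#'   order.
#' @export
aggregate_counts <- function(records, sample1, sample2) {
  need <- c("accession", "group", "spectral_count")
  if (!all(need %in% names(records)))
    stop_ctx("identification table lacks columns: ",
             paste(setdiff(need, names(records)), collapse = ", "),
             class = "input_error")
  if (identical(sample1, sample2))
    stop_ctx("sample1 and sample2 must differ", class = "input_error")
  records <- records[records$group %in% c(sample1, sample2), , drop = FALSE]
  dup <- duplicated(records[c("accession", "group")])
  if (any(dup))
    stop_ctx("duplicate (accession, group) records for: ",
             paste(unique(records$accession[dup]), collapse = ", "),
             class = "duplicate_record_error")
  acc <- unique(records$accession)
  pick <- function(grp) {
    i <- match(acc, records$accession[records$group == grp])
    cnt <- records$spectral_count[records$group == grp][i]
    ifelse(is.na(cnt), 0L, cnt)
  }
  n1 <- pick(sample1)
  n2 <- pick(sample2)
  data.frame(accession = acc, n1 = n1, n2 = n2,
             t1 = sum(n1), t2 = sum(n2))
}

#' Spectral-count log-ratio statistic (Rsc)
#'
#' `Rsc = log2((n2 + f)/(n1 + f)) + log2((t1 - n1 + f)/(t2 - n2 + f))`,
#' where `n1`, `n2` are a protein's spectral counts in the two pooled
#' samples, `t1`, `t2` the total spectra over all quantified proteins in
#' each sample, and `f` an additive correction (default 0.5) that removes
#' the discontinuity at zero counts. Positive values mean higher abundance
#' in the sample contributing `n2` (the contrast's numerator group); the
#' second term is the complementary-count correction that makes the
#' statistic an exact log odds ratio of lane composition.
#'
#' @param n1 Either a data frame with columns `n1`, `n2`, `t1`, `t2`
#'   (e.g. from [aggregate_counts()]), or the numeric vector of counts `n1`.
#' @param n2,t1,t2 Numeric vectors, recycled, when `n1` is a vector.
#' @param f Positive zero-count correction factor.
#' @return Numeric vector of Rsc values (log2 units), finite for all valid
#'   inputs.
#' @export
#' @examples
#' compute_rsc(n1 = 0, n2 = 20, t1 = 10000, t2 = 10000)  # ~ 5.36
#' compute_rsc(data.frame(n1 = 10, n2 = 10, t1 = 1000, t2 = 1000))  # 0
compute_rsc <- function(n1, n2 = NULL, t1 = NULL, t2 = NULL, f = 0.5) {
  if (is.data.frame(n1)) {
    entry <- n1
    n1 <- entry$n1; n2 <- entry$n2; t1 <- entry$t1; t2 <- entry$t2
  }
  if (!is.numeric(f) || length(f) != 1L || f <= 0)
    stop_ctx("f must be a positive scalar", class = "input_error")
  if (any(n1 < 0) || any(n2 < 0) || any(t1 < n1) || any(t2 < n2))
    stop_ctx("invalid spectral-count entry: need 0 <= n1 <= t1 and ",
             "0 <= n2 <= t2", class = "invariant_error")
  log2((n2 + f) / (n1 + f)) + log2((t1 - n1 + f) / (t2 - n2 + f))
}

#' Classify proteins as differentially represented by their Rsc
#'
#' Thresholds the Rsc statistic at `+/- threshold` with inclusive
#' boundaries: `over` when `rsc >= threshold`, `under` when
#' `rsc <= -threshold`, otherwise `unchanged`.
#'
#' @param results Data frame with columns `rsc` and (typically) `accession`;
#'   all other columns are carried through.
#' @param threshold Positive classification threshold in log2 units
#'   (default 1.40).
#' @return The input data frame with a `diff_class` factor column appended,
#'   classed `"rsc_classification"`; `summary()` returns the counts
#'   `n_over`, `n_under`, `n_unchanged`, `n_total_differential`.
#' @export
#' @examples
#' cls <- classify_differential(data.frame(accession = c("a", "b", "c"),
#'                                         rsc = c(1.40, -0.2, -1.41)))
#' summary(cls)
classify_differential <- function(results, threshold = 1.40) {
  if (!is.data.frame(results) || !"rsc" %in% names(results))
    stop_ctx("results must be a data frame with an 'rsc' column",
             class = "input_error")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop_ctx("threshold must be a positive scalar", class = "input_error")
  cls <- ifelse(results$rsc >= threshold, "over",
                ifelse(results$rsc <= -threshold, "under", "unchanged"))
  out <- results
  out$diff_class <- factor(cls, levels = c("over", "under", "unchanged"))
  attr(out, "threshold") <- threshold
  class(out) <- c("rsc_classification", class(out))
  out
}

#' @export
summary.rsc_classification <- function(object, ...) {
  tab <- table(object$diff_class)
  list(n_over = unname(tab[["over"]]),
       n_under = unname(tab[["under"]]),
       n_unchanged = unname(tab[["unchanged"]]),
       n_total_differential = unname(tab[["over"]] + tab[["under"]]))
}

#' @export
print.rsc_classification <- function(x, ...) {
  s <- summary(x)
  cat(sprintf(
    "Rsc classification (|Rsc| >= %.2f): %d over, %d under, %d unchanged\n",
    attr(x, "threshold"), s$n_over, s$n_under, s$n_unchanged))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Run the spectral-count differential proteomics chain
#'
#' Chains identification filtering, pooled-count aggregation, the Rsc
#' statistic and differential classification for a two-group contrast.
#' `group_a` is the contrast's numerator (first-named) group: positive Rsc
#' and class `over` mean higher abundance in `group_a`.
#'
#' @param identifications Identification table: a data frame or a TSV path
#'   in the layout of [read_identifications()].
#' @param group_a,group_b Labels of the two contrast groups as used in the
#'   table's `group` column.
#' @param f Zero-count correction factor (default 0.5).
#' @param rsc_threshold Differential threshold on |Rsc| (default 1.40).
#' @param min_peptides,min_score Identification acceptance rule; see
#'   [filter_identifications()].
#' @param out_dir Optional directory: writes `proteomics_results.tsv` and
#'   `proteomics_summary.json` there.
#' @param quiet Suppress stage log lines.
#' @return List with `results` (an [classify_differential()] data frame with
#'   columns accession, gene, n1, n2, t1, t2, rsc, diff_class) and `summary`
#'   (counts plus the thresholds used).
#' @export
run_proteomics <- function(identifications, group_a, group_b, f = 0.5,
                           rsc_threshold = 1.40, min_peptides = 2,
                           min_score = 19, out_dir = NULL, quiet = FALSE) {
  if (is.character(identifications))
    identifications <- read_identifications(identifications)
  stage <- function(name, expr)
    tryCatch(expr, muscleomics_error = function(e)
      stop_ctx("[", name, "] ", conditionMessage(e), class = "stage_error"))

  kept <- stage("filter", filter_identifications(
    identifications, min_peptides = min_peptides, min_score = min_score,
    quiet = quiet))
  if (nrow(kept) == 0) {
    empty <- classify_differential(
      data.frame(accession = character(), gene = character(),
                 n1 = integer(), n2 = integer(), t1 = integer(),
                 t2 = integer(), rsc = numeric()),
      threshold = rsc_threshold)
    return(list(results = empty,
                summary = c(summary(empty),
                            list(f = f, rsc_threshold = rsc_threshold,
                                 min_peptides = min_peptides,
                                 min_score = min_score))))
  }
  ## group_a feeds the formula's n2 slot so positive Rsc = higher in group_a
  entries <- stage("aggregate",
                   aggregate_counts(kept, sample1 = group_b,
                                    sample2 = group_a))
  entries$rsc <- stage("rsc", compute_rsc(entries, f = f))
  gene <- kept$gene[match(entries$accession, kept$accession)] %||% NA
  entries <- cbind(entries[, "accession", drop = FALSE], gene = gene,
                   entries[, c("n1", "n2", "t1", "t2", "rsc")])
  results <- stage("classify",
                   classify_differential(entries, threshold = rsc_threshold))
  smry <- c(summary(results),
            list(f = f, rsc_threshold = rsc_threshold,
                 min_peptides = min_peptides, min_score = min_score,
                 group_a = group_a, group_b = group_b))
  if (!quiet)
    message(sprintf("Rsc classification: %d over, %d under, %d unchanged",
                    smry$n_over, smry$n_under, smry$n_unchanged))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(as.data.frame(results),
              file.path(out_dir, "proteomics_results.tsv"))
    jsonlite::write_json(smry, file.path(out_dir, "proteomics_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(results = results, summary = smry)
}

#' Load the transcription of the published differential-protein tables
#'
#' The packaged fixture lists accession, gene symbol and printed Rsc value
#' for the 188 proteins reported as differentially represented between
#' lifelong-trained and untrained muscle (92 over-, 96 underexpressed at
#' |Rsc| >= 1.40).
#'
#' @return Data frame with columns accession, gene, rsc.
#' @export
#' @examples
#' summary(classify_differential(published_rsc_table()))
published_rsc_table <- function() {
  path <- system.file("extdata", "table2_table3_rsc.tsv",
                      package = "muscleomics", mustWork = TRUE)
  read_tsv(path, colClasses = c("character", "character", "numeric"))
}
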