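default_pipeline_config <- function() {
  list(
    proteomics = list(
      enabled = TRUE, f = 0.5, rsc_threshold = 1.40,
      min_peptides = 2, min_score = 19,
      group_a = "VPG", group_b = "CG"),
    enrichment = list(
      enabled = FALSE, mode = "p", alpha_p = 0.05, alpha_fdr = 0.05,
      min_set_size = 2, ease = FALSE),
    metabolomics = list(
      enabled = FALSE, n_components = 2, vip_cutoff = 1.5,
      alpha = 0.05, alpha_normality = 0.05, linkage = "ward.D2",
      volcano_fc_threshold = 0, volcano_p_threshold = 0.05, top_k = 40),
    io = list(
      identifications = NULL, rsc_table = NULL, gmt = NULL,
      panel = NULL, groups = NULL, out_dir = NULL),
    seed = 1)
}

validate_pipeline_config <- function(cfg) {
  for (key in c("f", "rsc_threshold", "min_score"))
    assert_positive(cfg$proteomics[[key]], paste0("proteomics.", key))
  assert_count(cfg$proteomics$min_peptides, "proteomics.min_peptides")
  for (key in c("alpha_p", "alpha_fdr"))
    assert_fraction(cfg$enrichment[[key]], paste0("enrichment.", key))
  if (!cfg$enrichment$mode %in% c("p", "fdr"))
    stop_ctx("enrichment.mode must be 'p' or 'fdr'", class = "config_error")
  assert_count(cfg$metabolomics$n_components, "metabolomics.n_components")
  assert_positive(cfg$metabolomics$vip_cutoff, "metabolomics.vip_cutoff")
  for (key in c("alpha", "alpha_normality", "volcano_p_threshold"))
    assert_fraction(cfg$metabolomics[[key]], paste0("metabolomics.", key))
  if (cfg$metabolomics$volcano_fc_threshold < 0)
    stop_ctx("metabolomics.volcano_fc_threshold must be >= 0",
             class = "config_error")
  if (!cfg$metabolomics$linkage %in%
      c("ward.D2", "single", "complete", "average"))
    stop_ctx("metabolomics.linkage must be one of ward.D2/single/",
             "complete/average", class = "config_error")
  assert_count(cfg$metabolomics$top_k, "metabolomics.top_k")
  assert_count(cfg$seed, "seed", positive = FALSE)
  cfg
}

merge_config <- function(defaults, user, prefix = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_ctx("unknown configuration key(s): ",
             paste0(prefix, unknown, collapse = ", "),
             class = "config_error")
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && nm != "io")
      merge_config(defaults[[nm]], user[[nm]], paste0(prefix, nm, "."))
    else user[[nm]]
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, injects defaults for absent keys (an empty
#' file yields the all-defaults configuration: f = 0.5, Rsc threshold 1.40,
#' VIP cutoff 1.5, ...), rejects unknown keys by name, and validates every
#' threshold. Blocks: `proteomics`, `enrichment`, `metabolomics`, `io`,
#' plus the top-level `seed`.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A validated `pipeline_config` list.
#' @export
#' @examples
#' cfg <- load_config(NULL)
#' cfg$proteomics$rsc_threshold
load_config <- function(path = NULL) {
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  cfg <- merge_config(default_pipeline_config(), user)
  cfg <- validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## hash of the analytic configuration; io paths are excluded so the same
## analysis written to different directories reports the same provenance
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$io <- NULL
  fnv1a_hash(yaml::as.yaml(cfg))
}

#' Run the full multi-omics analysis chain
#'
#' Chains the configured stages: spectral-count differential proteomics
#' (from an identification table, or directly from a precomputed Rsc table
#' such as the packaged published transcription), over-representation
#' analysis run separately on the over- and underexpressed protein sets
#' against the filtered identification universe, and the metabolite-panel
#' statistics suite (PLS-DA + VIP, normality-gated univariate tests,
#' volcano, clustering). Writes result TSVs stamped with the configuration
#' hash and a machine-readable `summary.json` when `io$out_dir` is set.
#'
#' @param config A `pipeline_config` from [load_config()], or a YAML path.
#' @return List with per-stage results and `summary` (the content of
#'   summary.json), invisibly when an output directory is written.
#' @export
#' @examples
#' cfg <- load_config(NULL)
#' cfg$io$rsc_table <- system.file("extdata", "table2_table3_rsc.tsv",
#'                                 package = "muscleomics")
#' run_all(cfg)$summary$proteomics[c("n_over", "n_under")]
run_all <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  io <- config$io
  out_dir <- io$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    if (!is.null(out_dir))
      write_tsv(df, file.path(out_dir, name), config_hash = hash)
  }
  results <- list()
  summary <- list(config_hash = hash, seed = config$seed,
                  thresholds = list(
                    f = config$proteomics$f,
                    rsc_threshold = config$proteomics$rsc_threshold,
                    min_peptides = config$proteomics$min_peptides,
                    min_score = config$proteomics$min_score,
                    vip_cutoff = config$metabolomics$vip_cutoff,
                    alpha = config$metabolomics$alpha))
  universe <- NULL

  if (isTRUE(config$proteomics$enabled)) {
    pr <- config$proteomics
    if (!is.null(io$rsc_table)) {
      ## precomputed Rsc values: classification only
      tab <- if (is.character(io$rsc_table)) read_tsv(io$rsc_table)
             else io$rsc_table
      res <- classify_differential(tab, threshold = pr$rsc_threshold)
      results$proteomics <- list(results = res, summary = summary(res))
    } else if (!is.null(io$identifications)) {
      results$proteomics <- run_proteomics(
        io$identifications, group_a = pr$group_a, group_b = pr$group_b,
        f = pr$f, rsc_threshold = pr$rsc_threshold,
        min_peptides = pr$min_peptides, min_score = pr$min_score,
        quiet = TRUE)
      universe <- results$proteomics$results$gene
    } else {
      stop_ctx("[proteomics] needs io.identifications or io.rsc_table",
               class = "config_error")
    }
    emit(as.data.frame(results$proteomics$results),
         "proteomics_results.tsv")
    summary$proteomics <- results$proteomics$summary
  }

  if (isTRUE(config$enrichment$enabled)) {
    en <- config$enrichment
    if (is.null(io$gmt))
      stop_ctx("[enrichment] needs io.gmt", class = "config_error")
    if (is.null(results$proteomics))
      stop_ctx("[enrichment] needs the proteomics stage",
               class = "config_error")
    sets <- if (is.character(io$gmt)) read_gmt(io$gmt) else io$gmt
    res <- results$proteomics$results
    key <- if (!is.null(res$gene) && !anyNA(res$gene)) "gene" else "accession"
    universe <- unique(toupper(res[[key]]))
    ## the over- and underexpressed subsets are analysed separately
    enr <- lapply(c(over = "over", under = "under"), function(side) {
      qry <- unique(toupper(res[[key]][res$diff_class == side]))
      hits <- fisher_enrichment(qry, universe, sets,
                                min_set_size = en$min_set_size,
                                ease = en$ease)
      filter_significant(hits, alpha_p = en$alpha_p,
                         alpha_fdr = en$alpha_fdr, mode = en$mode)
    })
    results$enrichment <- enr
    emit(enr$over, "enrichment_over.tsv")
    emit(enr$under, "enrichment_under.tsv")
    summary$enrichment <- list(mode = en$mode,
                               n_significant_over = nrow(enr$over),
                               n_significant_under = nrow(enr$under),
                               top_term_over = enr$over$term_id[1] %||% NA,
                               top_term_under = enr$under$term_id[1] %||% NA)
  }

  if (isTRUE(config$metabolomics$enabled)) {
    me <- config$metabolomics
    if (is.null(io$panel) || is.null(io$groups))
      stop_ctx("[metabolomics] needs io.panel and io.groups",
               class = "config_error")
    panel <- if (inherits(io$panel, "metabolite_panel")) io$panel
             else read_panel(io$panel, io$groups)
    pre <- preprocess(panel)
    fit <- fit_plsda(pre, n_components = me$n_components)
    vip_tab <- data.frame(metabolite_id = names(fit$vip),
                          vip = unname(fit$vip))
    univ <- univariate_panel(panel, alpha_normality = me$alpha_normality,
                             alpha = me$alpha)
    volc <- volcano(univ, fc_threshold_log2 = me$volcano_fc_threshold,
                    p_threshold = me$volcano_p_threshold)
    clust <- cluster_heatmap(panel, top_k = min(me$top_k, nrow(univ)),
                             linkage = me$linkage)
    disc <- discriminant_features(fit, cutoff = me$vip_cutoff)
    results$metabolomics <- list(fit = fit, vip = vip_tab,
                                 univariate = univ, volcano = volc,
                                 clustering = clust,
                                 discriminant = disc)
    emit(univ, "metabolomics_univariate.tsv")
    emit(vip_tab[order(-vip_tab$vip), ], "metabolomics_vip.tsv")
    emit(as.data.frame(volc), "metabolomics_volcano.tsv")
    if (!is.null(out_dir))
      jsonlite::write_json(
        list(linkage = clust$linkage, rows = clust$rows,
             cols = clust$cols),
        file.path(out_dir, "metabolomics_clustering.json"),
        auto_unbox = TRUE, digits = NA)
    summary$metabolomics <- list(
      n_components = fit$n_components,
      explained_y_variance_pct =
        round(100 * fit$explained_y_variance, 1),
      discriminant_metabolites = disc$metabolite_id,
      n_volcano_increased = sum(volc$class == "increased"),
      n_volcano_decreased = sum(volc$class == "decreased"),
      n_univariate_significant =
        sum(univ$p_value <= me$alpha))
  }

  if (!is.null(out_dir))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$summary <- summary
  if (is.null(out_dir)) results else invisible(results)
}
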