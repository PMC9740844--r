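#' Default 50-metabolite amino-acid / acylcarnitine panel
#'
#' The metabolite identifiers emulated by [simulate_metabolite_panel()]:
#' 16 free amino acids and 34 acylcarnitines as quantified by targeted
#' flow-injection MS/MS of butylated muscle extracts (Cn = acylcarnitine
#' with an n-carbon acyl chain; `:m` unsaturations; `OH` hydroxylated;
#' `DC` dicarboxylic).
#'
#' @return Character vector of 50 metabolite identifiers.
#' @export
#' @examples
#' default_metabolite_names()
default_metabolite_names <- function() {
  c("Ala", "Arg", "Asn", "Asp", "Cit", "Glu", "Gln", "Gly", "His", "Leu",
    "Met", "Orn", "Phe", "Pro", "Tyr", "Val",
    "C0", "C2", "C3", "C4", "C4OH", "C5", "C5:1", "C5OH", "C5DC", "C6",
    "C6DC", "C8", "C8:1", "C8DC", "C10", "C10:1", "C10:2", "C12", "C12:1",
    "C12OH", "C14", "C14:1", "C14:2", "C14OH", "C16", "C16:1", "C16OH",
    "C16:1OH", "C18", "C18:1", "C18:2", "C18OH", "C18:1OH", "C18:2OH")
}

#' Configuration for the synthetic pooled spectral-count proteome
#'
#' Describes a two-group pooled label-free design: one SDS-PAGE lane per
#' group, each lane yielding a fixed total number of MS/MS spectra that is
#' divided among proteins in proportion to their relative abundance.
#' A fraction of proteins carries a planted differential effect of
#' `planted_log2fc` log2 units between the groups; the fold change is split
#' symmetrically across the two lanes (up: multiplied by `2^(fc/2)` in group
#' A and by `2^(-fc/2)` in group B) so that planting does not shift the
#' lane-wide composition against the null proteins.
#'
#' @param n_proteins Number of simulated proteins.
#' @param frac_up,frac_down Fractions of proteins planted up-/down-regulated
#'   in group A relative to group B; `frac_up + frac_down <= 1`.
#' @param planted_log2fc Planted effect size in log2 units (> 0).
#' @param total_spectra_per_group Total spectra per lane (the Rsc `t1`, `t2`).
#' @param baseline_dispersion Log-normal sdlog of per-protein baseline
#'   relative abundance; larger values give more low-count proteins.
#' @param seed Integer seed; all draws derive from it.
#' @return A `proteome_sim_config` list.
#' @export
proteome_sim_config <- function(n_proteins = 500L, frac_up = 0.1,
                                frac_down = 0.1, planted_log2fc = 3,
                                total_spectra_per_group = 20000L,
                                baseline_dispersion = 1.0, seed = 1L) {
  cfg <- list(
    n_proteins = assert_count(n_proteins, "n_proteins"),
    frac_up = assert_fraction(frac_up, "frac_up"),
    frac_down = assert_fraction(frac_down, "frac_down"),
    planted_log2fc = assert_positive(planted_log2fc, "planted_log2fc"),
    total_spectra_per_group = assert_count(total_spectra_per_group,
                                           "total_spectra_per_group"),
    baseline_dispersion = assert_positive(baseline_dispersion,
                                          "baseline_dispersion"),
    seed = assert_count(seed, "seed", positive = FALSE))
  if (cfg$frac_up + cfg$frac_down > 1)
    stop_ctx("frac_up + frac_down must not exceed 1", class = "config_error")
  structure(cfg, class = "proteome_sim_config")
}

#' Configuration for the synthetic metabolite panel
#'
#' Emulates a targeted amino-acid/acylcarnitine panel measured on two groups
#' of muscle biopsies, concentrations normalised to total protein content.
#' Per-metabolite baselines are drawn log-normally (median 10, sdlog 1.5,
#' spanning micromolar amino-acid pools down to trace hydroxylated
#' acylcarnitines); measurements add log-normal noise with coefficient of
#' variation `cv_noise`, and `planted_effects` multiply group-A means by
#' `2^fc`.
#'
#' @param metabolite_names Metabolite identifiers
#'   (default [default_metabolite_names()]).
#' @param n_per_group Samples per group (>= 3; default 9 subjects per group).
#' @param planted_effects Named numeric vector of log2 fold changes
#'   (group A over group B); names must be metabolites in the panel.
#' @param cv_noise Log-normal coefficient of variation of the measurement
#'   noise (> 0).
#' @param seed Integer seed.
#' @return A `metabo_sim_config` list.
#' @export
metabo_sim_config <- function(metabolite_names = default_metabolite_names(),
                              n_per_group = 9L, planted_effects = numeric(),
                              cv_noise = 0.2, seed = 1L) {
  if (!is.character(metabolite_names) || length(metabolite_names) == 0 ||
      anyDuplicated(metabolite_names))
    stop_ctx("metabolite_names must be unique identifiers",
             class = "config_error")
  n_per_group <- assert_count(n_per_group, "n_per_group")
  if (n_per_group < 3)
    stop_ctx("n_per_group must be at least 3", class = "config_error")
  planted_effects <- unlist(planted_effects) %||% numeric()
  if (length(planted_effects) &&
      (is.null(names(planted_effects)) ||
       !all(names(planted_effects) %in% metabolite_names)))
    stop_ctx("every planted_effects name must appear in metabolite_names",
             class = "config_error")
  structure(list(
    metabolite_names = metabolite_names,
    n_per_group = n_per_group,
    planted_effects = planted_effects,
    cv_noise = assert_positive(cv_noise, "cv_noise"),
    seed = assert_count(seed, "seed", positive = FALSE)),
    class = "metabo_sim_config")
}

#' Simulate a pooled two-group spectral-count experiment
#'
#' Draws per-protein baseline relative abundances log-normally, applies the
#' planted fold changes, and distributes each lane's fixed spectral total
#' multinomially across proteins, so realized lane totals equal
#' `total_spectra_per_group` exactly (the counts are conditioned on the lane
#' total, as in a one-lane-per-group pooled design). RNG stream order under
#' the config seed: (1) baseline abundances, (2) group-A counts, (3) group-B
#' counts.
#'
#' @param cfg A [proteome_sim_config()].
#' @return A list with `counts`: data frame (accession, n1, n2, t1, t2) where
#'   `n2` is the group-A count and `n1` the group-B count (the orientation
#'   fed to [compute_rsc()] so positive Rsc means higher in group A), and
#'   `truth`: data frame (accession, class) with class in up/down/null.
#' @export
#' @examples
#' sim <- simulate_spectral_counts(proteome_sim_config(n_proteins = 50,
#'   total_spectra_per_group = 2000, seed = 7))
#' table(sim$truth$class)
#' sum(sim$counts$n2)  # exactly 2000
simulate_spectral_counts <- function(cfg) {
  stopifnot(inherits(cfg, "proteome_sim_config"))
  n <- cfg$n_proteins
  n_up <- round(cfg$frac_up * n)
  n_down <- round(cfg$frac_down * n)
  cls <- rep("null", n)
  if (n_up > 0) cls[seq_len(n_up)] <- "up"
  if (n_down > 0) cls[n_up + seq_len(n_down)] <- "down"

  with_preserved_seed(cfg$seed, {
    base <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$baseline_dispersion)
    half <- 2^(cfg$planted_log2fc / 2)
    mult_a <- ifelse(cls == "up", half, ifelse(cls == "down", 1 / half, 1))
    abund_a <- base * mult_a
    abund_b <- base / mult_a
    tot <- cfg$total_spectra_per_group
    exp_a <- tot * abund_a / sum(abund_a)
    exp_b <- tot * abund_b / sum(abund_b)
    if (max(exp_a) < 1 && max(exp_b) < 1)
      stop_ctx("degenerate configuration: every protein's expected spectral ",
               "count is below 1; increase total_spectra_per_group or reduce ",
               "n_proteins", class = "degenerate_config_error")
    n_a <- as.integer(stats::rmultinom(1, tot, abund_a))
    n_b <- as.integer(stats::rmultinom(1, tot, abund_b))
    acc <- sprintf("SIMP%04d", seq_len(n))
    list(
      counts = data.frame(accession = acc, n1 = n_b, n2 = n_a,
                          t1 = tot, t2 = tot),
      truth = data.frame(accession = acc, class = cls))
  })
}

#' Simulate a synthetic identification table
#'
#' Wraps [simulate_spectral_counts()] into the long identification-table
#' format consumed by [run_proteomics()]: one row per protein per group with
#' peptide evidence. A configurable fraction of rows is given failing
#' identification evidence (single peptide or weak best score) to exercise
#' the acceptance filter.
#'
#' @param cfg A [proteome_sim_config()].
#' @param group_a,group_b Group labels used in the `group` column; group A
#'   receives the planted up-regulation.
#' @param frac_low_evidence Fraction of proteins given sub-threshold
#'   identification evidence in both groups.
#' @return A list with `identifications` (data frame in the standard
#'   identification-table layout) and `truth` as in
#'   [simulate_spectral_counts()].
#' @export
simulate_identifications <- function(cfg, group_a = "VPG", group_b = "CG",
                                     frac_low_evidence = 0) {
  frac_low_evidence <- assert_fraction(frac_low_evidence, "frac_low_evidence")
  sim <- simulate_spectral_counts(cfg)
  n <- nrow(sim$counts)
  n_low <- round(frac_low_evidence * n)
  low <- rep(FALSE, n)
  if (n_low > 0) low[with_preserved_seed(cfg$seed + 1L,
                                         sample.int(n, n_low))] <- TRUE
  one_group <- function(grp, spc) data.frame(
    accession = sim$counts$accession,
    description = paste("synthetic protein", seq_len(n)),
    gene = sprintf("SGENE%04d", seq_len(n)),
    group = grp,
    n_peptides = ifelse(low, 1L, pmax(2L, pmin(spc, 25L))),
    min_peptide_score = ifelse(low, 15, 25),
    spectral_count = spc)
  list(identifications = rbind(one_group(group_a, sim$counts$n2),
                               one_group(group_b, sim$counts$n1)),
       truth = sim$truth)
}

#' Simulate a two-group metabolite concentration panel
#'
#' Concentrations are drawn log-normally around per-metabolite baselines;
#' `planted_effects` multiply the group-A mean by `2^fc`. All concentrations
#' are strictly positive, so the downstream log10 transform is always
#' defined. RNG stream order under the config seed: (1) per-metabolite
#' baselines, (2) the noise matrix (metabolite-major).
#'
#' @param cfg A [metabo_sim_config()].
#' @return A list with `panel` (a [metabolite_panel()] with groups "A"/"B")
#'   and `truth`: data frame (metabolite_id, planted_log2fc) for planted
#'   metabolites.
#' @export
#' @examples
#' sim <- simulate_metabolite_panel(metabo_sim_config(
#'   planted_effects = c(Orn = 1, Cit = -1), seed = 3))
#' sim$truth
simulate_metabolite_panel <- function(cfg) {
  stopifnot(inherits(cfg, "metabo_sim_config"))
  p <- length(cfg$metabolite_names)
  m <- cfg$n_per_group
  sdlog <- sqrt(log(1 + cfg$cv_noise^2))   # log-normal sd from CV
  with_preserved_seed(cfg$seed, {
    baseline <- stats::rlnorm(p, meanlog = log(10), sdlog = 1.5)
    mean_a <- baseline
    idx <- match(names(cfg$planted_effects), cfg$metabolite_names)
    if (length(idx)) mean_a[idx] <- mean_a[idx] * 2^cfg$planted_effects
    noise <- matrix(stats::rlnorm(p * 2 * m, meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog),
                    nrow = p, byrow = TRUE)   # metabolite-major stream
    conc <- cbind(mean_a * noise[, seq_len(m), drop = FALSE],
                  baseline * noise[, m + seq_len(m), drop = FALSE])
    dimnames(conc) <- list(cfg$metabolite_names,
                           c(sprintf("A%02d", seq_len(m)),
                             sprintf("B%02d", seq_len(m))))
    panel <- metabolite_panel(conc, rep(c("A", "B"), each = m))
    truth <- data.frame(metabolite_id = names(cfg$planted_effects),
                        planted_log2fc = unname(cfg$planted_effects))
    list(panel = panel, truth = truth)
  })
}

#' Simulate annotation sets with one planted enriched term
#'
#' Generates random term memberships over a protein universe, plus (when
#' `planted_subset` is given) one term whose members are drawn
#' preferentially from that subset, for testing over-representation
#' analysis. The result serialises to standard GMT via [write_gmt()].
#'
#' @param n_terms Number of random background terms (>= 0).
#' @param proteins Character vector: the protein/gene universe.
#' @param planted_subset Optional character vector (subset of `proteins`)
#'   from which the planted term draws `planted_frac` of its members.
#' @param planted_size Number of members of the planted term.
#' @param planted_frac Fraction of planted-term members drawn from
#'   `planted_subset` (the rest are background draws).
#' @param seed Integer seed.
#' @return An `annotation_sets` object: named list of terms, each a list
#'   with `term_id`, `term_name`, `members`. The planted term (if any) is
#'   named `PLANTED`.
#' @export
simulate_annotation_sets <- function(n_terms, proteins,
                                     planted_subset = NULL,
                                     planted_size = 20L,
                                     planted_frac = 0.8, seed = 1L) {
  n_terms <- assert_count(n_terms, "n_terms", positive = FALSE)
  if (length(proteins) == 0)
    stop_ctx("protein universe must be non-empty", class = "config_error")
  if (!is.null(planted_subset) && length(planted_subset) == 0)
    stop_ctx("planted_subset must be non-empty when given",
             class = "config_error")
  with_preserved_seed(seed, {
    sets <- list()
    if (n_terms > 0) {
      hi <- min(25L, length(proteins))
      lo <- min(5L, hi)
      sizes <- lo + floor(stats::runif(n_terms) * (hi - lo + 1))
      for (i in seq_len(n_terms)) {
        id <- sprintf("TERM%03d", i)
        sets[[id]] <- list(term_id = id,
                           term_name = paste("random term", i),
                           members = sample(proteins, sizes[i]))
      }
    }
    if (!is.null(planted_subset)) {
      planted_size <- min(planted_size, length(proteins))
      k_in <- min(round(planted_frac * planted_size), length(planted_subset))
      members <- c(sample(planted_subset, k_in),
                   sample(setdiff(proteins, planted_subset),
                          min(planted_size - k_in,
                              length(proteins) - length(planted_subset))))
      sets[["PLANTED"]] <- list(term_id = "PLANTED",
                                term_name = "planted enriched term",
                                members = unique(members))
    }
    structure(sets, class = "annotation_sets")
  })
}
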