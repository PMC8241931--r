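# End-to-end orchestration: simulate the full SIP study design, run the
# fraction -> enrichment -> ecology -> colonization stages, and persist
# machine-readable outputs.

#' Simulate the complete SIP experiment
#'
#' Emulates the study design: 3 replicate planted pots per isotope
#' (\eqn{^{12}}CO\eqn{_2} / \eqn{^{13}}CO\eqn{_2}) with one rhizosphere
#' gradient each (1.5 ug DNA loaded), endosphere DNA pooled across the three
#' replicates into a single gradient per isotope (3 x 0.2 ug = 0.6 ug; pooled
#' samples have no replicate error), three unplanted \eqn{^{13}}CO\eqn{_2}
#' control gradients (1 ug each), unfractionated 16S profiles of the soil,
#' rhizosphere and root compartments (3 replicates each), and a CFU
#' colonization assay.
#'
#' @param design community design, see [default_community_design()].
#' @param gmodel gradient physics, see [gradient_model()].
#' @param smodel sequencing/qPCR noise, see [sequencing_model()].
#' @param seed root seed; every random stream is derived from it.
#' @param n_replicates replicate pots per treatment (default 3).
#' @param cfu_design CFU assay design ([cfu_design_default()]) or `NULL` to
#'   skip the colonization arm.
#' @return list of class `sip_experiment`: `taxa`, `runs` (gradient runs),
#'   `unfractionated` (counts matrix + meta), `cfu`, `truth`, models and seed.
#' @export
simulate_sip_experiment <- function(design = default_community_design(),
                                    gmodel = gradient_model(),
                                    smodel = sequencing_model(),
                                    seed = 1, n_replicates = 3L,
                                    cfu_design = cfu_design_default()) {
  taxa <- build_taxa(design, seed)
  reps <- seq_len(n_replicates)
  runs <- list()
  add_run <- function(run) {
    key <- paste(run$isotope, run$compartment, run$replicate, sep = "_")
    runs[[key]] <<- run
  }

  for (iso in c("12C", "13C")) {
    prof <- simulate_compartment_profiles(taxa, design, "rhizosphere", reps,
                                          seed, stream = paste0("pots_", iso))
    for (p in prof)
      add_run(simulate_gradient_run(p, iso, taxa, dna_mass_loaded = 1.5,
                                    gmodel, smodel, seed))
    endo <- simulate_compartment_profiles(taxa, design, "endosphere", reps,
                                          seed, stream = paste0("pots_", iso))
    pooled <- pool_replicate_dna(endo, mass_each = 0.2)
    add_run(simulate_gradient_run(pooled, iso, taxa,
                                  dna_mass_loaded = attr(pooled, "total_mass"),
                                  gmodel, smodel, seed))
  }
  ctrl <- simulate_compartment_profiles(taxa, design, "unplanted_control",
                                        reps, seed, stream = "pots_13C")
  for (p in ctrl)
    add_run(simulate_gradient_run(p, "13C", taxa, dna_mass_loaded = 1.0,
                                  gmodel, smodel, seed))

  # unfractionated 16S profiles for the community summary (Shannon, phylum
  # shares): one multinomial library per compartment replicate
  unfrac_comps <- c("bulk_soil", "rhizosphere", "endosphere")
  uprof <- simulate_compartment_profiles(taxa, design, unfrac_comps, reps,
                                         seed, stream = "profiling")
  ucounts <- vapply(uprof, function(p) {
    with_seed_(derive_seed(seed, "profiling_reads", p$compartment, p$replicate),
               function() rmultinom(1, smodel$library_size, p$proportions)[, 1])
  }, numeric(nrow(taxa)))
  rownames(ucounts) <- taxa$genus
  umeta <- data.frame(
    sample_key = names(uprof),
    compartment = vapply(uprof, `[[`, "", "compartment"),
    replicate = vapply(uprof, function(p) as.character(p$replicate), ""),
    row.names = NULL, stringsAsFactors = FALSE)

  cfu <- if (!is.null(cfu_design)) simulate_cfu_dataset(cfu_design, seed)
  truth <- taxa[, c("taxon_id", "genus", "role", "active_rhizosphere",
                    "active_endosphere")]
  truth$a_13C_rhizosphere <- atom_excess(taxa, "13C", "rhizosphere")
  truth$a_13C_endosphere <- atom_excess(taxa, "13C", "endosphere")
  truth$a_13C_unplanted <- atom_excess(taxa, "13C", "unplanted_control")

  structure(list(taxa = taxa, design = design, gmodel = gmodel,
                 smodel = smodel, seed = seed, n_replicates = n_replicates,
                 runs = runs,
                 unfractionated = list(counts = ucounts, meta = umeta),
                 cfu = cfu, truth = truth),
            class = "sip_experiment")
}

run_genus_counts <- function(run, taxa) {
  counts <- run$counts
  rownames(counts) <- taxa$genus[match(rownames(counts), taxa$taxon_id)]
  counts
}

#' Pool all gradient runs of an experiment into an H/L abundance table
#'
#' Heavy/light windows are selected on each \eqn{^{13}}C gradient with
#' [select_heavy_light()] and the same fraction windows are applied to the
#' paired \eqn{^{12}}C gradient of the same compartment/replicate (an
#' unlabeled profile is unimodal and has no detached heavy peak of its own);
#' unplanted control gradients use their own windows. Pooled window counts
#' are assembled into one genus x sample matrix and normalized with
#' [to_relative_abundance()] so all compartments share one genus universe.
#'
#' @param experiment a `sip_experiment` (or a compatible list of runs +
#'   taxa, as reconstructed from files in real mode).
#' @param delta_density,background_fraction window parameters, see
#'   [select_heavy_light()].
#' @param drop_singletons,drop_plastid filters, see [to_relative_abundance()].
#' @return list: `table` (a `sip_abundance`), `partitions` (per 13C run).
#' @export
pool_experiment <- function(experiment, delta_density = 0.015,
                            background_fraction = 0.05,
                            drop_singletons = TRUE, drop_plastid = TRUE) {
  runs <- experiment$runs
  taxa <- experiment$taxa
  iso_of <- vapply(runs, `[[`, "", "isotope")
  comp_of <- vapply(runs, `[[`, "", "compartment")
  rep_of <- vapply(runs, function(r) as.character(r$replicate), "")

  cols <- list(); meta <- list(); partitions <- list()
  for (key in names(runs)[iso_of == "13C"]) {
    run13 <- runs[[key]]
    part <- select_heavy_light(run13, delta_density, background_fraction)
    partitions[[key]] <- part
    mates <- which(iso_of == "12C" & comp_of == run13$compartment &
                     rep_of == as.character(run13$replicate))
    for (run in c(list(run13), runs[mates])) {
      pooled <- pool_fractions(list(counts = run_genus_counts(run, taxa),
                                    fractions = run$fractions), part)
      for (fc in c("H", "L")) {
        sk <- paste(run$isotope, run$compartment, run$replicate, fc, sep = "_")
        cols[[sk]] <- if (fc == "H") pooled$counts_H else pooled$counts_L
        meta[[sk]] <- data.frame(sample_key = sk, isotope = run$isotope,
                                 compartment = run$compartment,
                                 fraction_class = fc,
                                 replicate = as.character(run$replicate),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(cols)
  list(table = to_relative_abundance(mat, do.call(rbind, meta),
                                     drop_singletons, drop_plastid),
       partitions = partitions)
}

#' Analyze a SIP experiment end to end
#'
#' Runs the full analysis on a (simulated or reconstructed) experiment:
#' window selection and pooling ([pool_experiment()]), autotroph detection
#' from the unplanted controls, dual two-fold enrichment classification per
#' planted compartment, compartment overlap, fraction-class ordination and
#' PERMANOVA on the rhizosphere samples, compartment diversity summaries,
#' colonization statistics (if a CFU table is present), and — when the truth
#' is known (synthetic mode) — a confusion matrix of the labeled calls
#' against the simulated roles.
#'
#' @param experiment a `sip_experiment`.
#' @param threshold fold-enrichment threshold (default 2).
#' @param pseudo denominator floor for fold ratios.
#' @param delta_density,background_fraction window parameters.
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param seed seed for the permutation stream (defaults to the experiment
#'   seed).
#' @return list of class `sip_analysis`.
#' @export
analyze_sip_experiment <- function(experiment, threshold = 2.0, pseudo = 1e-6,
                                   delta_density = 0.015,
                                   background_fraction = 0.05,
                                   n_permutations = 999L, seed = NULL) {
  if (is.null(seed)) seed <- experiment$seed
  pooled <- pool_experiment(experiment, delta_density, background_fraction)
  tab <- pooled$table

  autotrophs <- detect_autotrophs(tab, threshold, pseudo)
  reports <- list()
  for (comp in c("rhizosphere", "endosphere")) {
    comp_tab <- subset_samples(tab, compartment = comp)
    reports[[comp]] <- classify_labeled_genera(comp_tab, autotrophs,
                                               threshold, pseudo)
  }
  overlap <- compare_compartments(reports$rhizosphere, reports$endosphere)

  rhizo_tab <- subset_samples(tab, compartment = "rhizosphere")
  d <- bray_curtis(rhizo_tab)
  groups <- paste0(sub("C$", "", rhizo_tab$meta$isotope),
                   rhizo_tab$meta$fraction_class)  # 12H, 12L, 13H, 13L
  ecology <- list(dissimilarity = d, ordination = pcoa(d),
                  permanova = permanova(d, groups, n_permutations, seed))

  diversity <- NULL
  if (!is.null(experiment$unfractionated)) {
    uf <- experiment$unfractionated
    proteo <- experiment$taxa$phylum[match(rownames(uf$counts),
                                           experiment$taxa$genus)] ==
      "Proteobacteria"
    diversity <- data.frame(
      sample_key = uf$meta$sample_key, compartment = uf$meta$compartment,
      shannon = apply(uf$counts, 2, shannon),
      proteobacteria_share = colSums(uf$counts[which(proteo), , drop = FALSE]) /
        colSums(uf$counts),
      row.names = NULL, stringsAsFactors = FALSE)
  }

  colonization <- NULL
  if (!is.null(experiment$cfu)) {
    per_plant <- cfu_table_to_per_gram(experiment$cfu)
    anova_tab <- two_way_anova(per_plant$log10_cfu_g, per_plant$genotype,
                               per_plant$strain)
    tukey <- tukey_hsd(per_plant$log10_cfu_g, per_plant$genotype,
                       error_ms = attr(anova_tab, "residual_ms"),
                       error_df = attr(anova_tab, "residual_df"))
    colonization <- list(per_plant = per_plant, anova = anova_tab,
                         tukey = tukey)
  }

  confusion <- if (!is.null(experiment$truth))
    truth_confusion(experiment$truth, reports)

  structure(list(table = tab, partitions = pooled$partitions,
                 autotrophs = autotrophs, reports = reports,
                 overlap = overlap, ecology = ecology,
                 diversity = diversity, colonization = colonization,
                 confusion = confusion,
                 params = list(threshold = threshold, pseudo = pseudo,
                               delta_density = delta_density,
                               background_fraction = background_fraction,
                               n_permutations = n_permutations, seed = seed)),
            class = "sip_analysis")
}

truth_confusion <- function(truth, reports) {
  out <- list()
  for (comp in names(reports)) {
    rep_tab <- reports[[comp]]
    active <- if (comp == "rhizosphere") truth$active_rhizosphere
              else truth$active_endosphere
    should <- truth$genus[truth$role == "exudate_metabolizer" & active]
    bystanders <- truth$genus[truth$role == "bystander"]
    autos <- truth$genus[truth$role == "autotroph"]
    labeled <- rep_tab$genus[rep_tab$labeled]
    universe <- intersect(truth$genus, rep_tab$genus)
    tp <- length(intersect(labeled, should))
    fn <- length(setdiff(intersect(should, universe), labeled))
    out[[comp]] <- list(
      true_positives = tp, false_negatives = fn,
      false_positives = length(setdiff(labeled, should)),
      bystander_false_positives = length(intersect(labeled, bystanders)),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      autotrophs_excluded = !any(autos %in% labeled),
      labeled = sort(labeled), expected = sort(intersect(should, universe)))
  }
  out
}
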