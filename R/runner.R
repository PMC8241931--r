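# Single-config pipeline runner. The config is an R list or a JSON document;
# every result directory gets a manifest echoing the full parameter set and
# seed so outputs are self-describing.

default_run_config <- function() {
  list(mode = "synthetic", seed = 1L, out_dir = NULL,
       threshold = 2.0, pseudo = 1e-6, delta_density = 0.015,
       background_fraction = 0.05, n_permutations = 999L,
       a_label = 0.5, library_size = 50000L, qpcr_noise_cv = 0.1,
       n_replicates = 3L, simulate_cfu = TRUE,
       counts = NULL, meta = NULL, qpcr = NULL, standards = NULL, cfu = NULL)
}

load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file does not exist: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  cfg <- utils::modifyList(default_run_config(), config)
  if (!cfg$mode %in% c("synthetic", "real"))
    stop("config error: mode must be 'synthetic' or 'real'")
  if (cfg$mode == "synthetic" && is.null(cfg$seed))
    stop("config error: synthetic mode requires a seed")
  if (cfg$mode == "real") {
    for (p in c("counts", "meta")) {
      if (is.null(cfg[[p]]))
        stop("config error: real mode requires a '", p, "' path")
      if (!file.exists(cfg[[p]]))
        stop("config error: ", p, " path does not exist: ", cfg[[p]])
    }
  }
  cfg
}

stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the whole pipeline from a single configuration
#'
#' Synthetic mode simulates the full study design
#' ([simulate_sip_experiment()]) and analyzes it; real mode reconstructs
#' gradient runs from count/metadata (and optionally qPCR) tables and runs
#' the same analysis stages: fraction window selection and pooling,
#' autotroph exclusion, enrichment classification per compartment,
#' compartment overlap, ordination/PERMANOVA, and colonization statistics if
#' a CFU table is supplied. Any stage error aborts with the stage name. When
#' `out_dir` is set, all tables plus `summary.json` and `manifest.json` are
#' written there.
#'
#' @param config an R list or path to a JSON config. Recognized fields:
#'   `mode` ("synthetic"/"real"), `seed`, `out_dir`, analysis parameters
#'   (`threshold`, `pseudo`, `delta_density`, `background_fraction`,
#'   `n_permutations`), simulator parameters (`a_label`, `library_size`,
#'   `qpcr_noise_cv`, `n_replicates`, `simulate_cfu`), and real-mode paths
#'   (`counts`, `meta`, `qpcr`, `standards`, `cfu`).
#' @return the `sip_analysis`, invisibly, with the experiment attached as
#'   attribute `experiment` and the effective config as attribute `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_run_config(config)
  if (cfg$mode == "synthetic") {
    experiment <- stage("simulate", simulate_sip_experiment(
      design = default_community_design(a_label = cfg$a_label),
      smodel = sequencing_model(library_size = cfg$library_size,
                                qpcr_noise_cv = cfg$qpcr_noise_cv),
      seed = cfg$seed, n_replicates = cfg$n_replicates,
      cfu_design = if (isTRUE(cfg$simulate_cfu)) cfu_design_default()))
  } else {
    tabs <- stage("read", read_experiment_tables(cfg$counts, cfg$meta,
                                                 cfg$qpcr, cfg$standards))
    experiment <- list(taxa = tabs$taxa, runs = tabs$runs, seed = cfg$seed,
                       truth = NULL, unfractionated = NULL,
                       cfu = if (!is.null(cfg$cfu))
                         stage("read", read_cfu_table(cfg$cfu)))
    class(experiment) <- "sip_experiment"
    if (!any(vapply(tabs$runs, `[[`, "", "compartment") == "unplanted_control"))
      stop("stage 'enrich' failed: no unplanted_control gradients in input; ",
           "the autotroph filter cannot be applied", call. = FALSE)
  }
  analysis <- stage("analyze", analyze_sip_experiment(
    experiment, threshold = cfg$threshold, pseudo = cfg$pseudo,
    delta_density = cfg$delta_density,
    background_fraction = cfg$background_fraction,
    n_permutations = cfg$n_permutations, seed = cfg$seed))
  if (!is.null(cfg$out_dir))
    stage("write", write_analysis(analysis, experiment, cfg))
  attr(analysis, "experiment") <- experiment
  attr(analysis, "config") <- cfg
  invisible(analysis)
}

analysis_summary <- function(analysis) {
  perm <- analysis$ecology$permanova
  s <- list(
    labeled = list(
      rhizosphere = analysis$overlap$labeled_rhizosphere,
      endosphere = analysis$overlap$labeled_endosphere,
      both = analysis$overlap$both,
      rhizosphere_only = analysis$overlap$rhizosphere_only,
      endosphere_only = analysis$overlap$endosphere_only),
    autotrophs = autotroph_set(analysis$autotrophs),
    permanova = list(f = perm$f, r_squared = perm$r_squared,
                     p_value = perm$p_value, p_label = perm$p_label,
                     n_permutations = perm$n_permutations),
    variance_explained = as.numeric(
      head(analysis$ecology$ordination$variance_explained, 2)),
    params = analysis$params)
  if (!is.null(analysis$confusion)) s$confusion <- analysis$confusion
  if (!is.null(analysis$colonization)) {
    at <- analysis$colonization$anova
    s$colonization_anova <- lapply(seq_len(nrow(at)), function(i)
      list(term = at$term[i], df = at$df[i], f = at$f[i], p = at$p[i]))
  }
  if (!is.null(analysis$diversity)) {
    s$diversity <- lapply(split(analysis$diversity,
                                analysis$diversity$compartment),
                          function(d) list(mean_shannon = mean(d$shannon),
                                           mean_proteobacteria =
                                             mean(d$proteobacteria_share)))
  }
  s
}

write_analysis <- function(analysis, experiment, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- cfg$out_dir
  paths <- character()
  if (inherits(experiment, "sip_experiment") &&
      inherits(experiment$runs[[1]]$fractions, "data.frame") &&
      !is.null(experiment$truth))
    paths <- write_experiment_tables(experiment, out)
  for (comp in names(analysis$reports)) {
    p <- file.path(out, paste0("enrichment_", comp, ".tsv"))
    write_tsv(as.data.frame(analysis$reports[[comp]]), p)
    paths[paste0("enrichment_", comp)] <- p
  }
  write_tsv(as.data.frame(analysis$autotrophs),
            paths["autotrophs"] <- file.path(out, "autotrophs.tsv"))
  write_tsv(analysis$ecology$ordination$coordinates,
            paths["ordination"] <- file.path(out, "ordination.tsv"),
            rownames_as = "sample_key")
  if (!is.null(analysis$colonization)) {
    write_tsv(as.data.frame(analysis$colonization$anova),
              paths["anova"] <- file.path(out, "cfu_anova.tsv"))
    write_tsv(as.data.frame(analysis$colonization$tukey),
              paths["tukey"] <- file.path(out, "cfu_tukey.tsv"))
  }
  jsonlite::write_json(analysis_summary(analysis),
                       paths["summary"] <- file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(config = cfg[!vapply(cfg, is.null, TRUE)],
                   seed = cfg$seed, files = as.list(paths))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
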