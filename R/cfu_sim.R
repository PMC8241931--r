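#' Default design for the simulated root colonization assay
#'
#' Mirrors the colonization experiment: four plant genotypes (wild-type Col-0,
#' the salicylate-overproducing cpr5 mutant, and the salicylate-deficient pad4
#' and sid2-2 lines) crossed with two marked Streptomyces strains (M145, M3),
#' six plants per cell, colony counts on three replicate selective plates per
#' plant. The cpr5 effect raises the generating log10 cfu/g mean by
#' `cpr5_effect` in both strains.
#'
#' @param base_log10_cfu baseline log10 cfu per gram of root (wild-type).
#' @param cpr5_effect additive shift (log10 units) for the cpr5 genotype.
#' @param strain_effect half-difference between strains (M145 = +, M3 = -).
#' @param sdlog10 residual sd of log10 cfu/g across plants.
#' @param n_per_cell plants per genotype x strain cell (>= 2).
#' @param n_plates replicate plates per plant.
#' @return list describing the design, consumed by [simulate_cfu_dataset()].
#' @export
cfu_design_default <- function(base_log10_cfu = 5.0, cpr5_effect = 0.8,
                               strain_effect = 0.1, sdlog10 = 0.4,
                               n_per_cell = 6L, n_plates = 3L) {
  genotypes <- c("Col-0", "cpr5", "pad4", "sid2-2")
  strains <- c("M145", "M3")
  cells <- expand.grid(genotype = genotypes, strain = strains,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$log10_mean <- base_log10_cfu +
    ifelse(cells$genotype == "cpr5", cpr5_effect, 0) +
    ifelse(cells$strain == "M145", strain_effect, -strain_effect)
  list(cells = cells, sdlog10 = sdlog10, n_per_cell = as.integer(n_per_cell),
       n_plates = as.integer(n_plates), plated_volume_ul = 100,
       homogenate_volume_ul = 1000, dilution_factor = 10,
       root_mass_mean_g = 0.05, root_mass_cv = 0.3)
}

#' Simulate a CFU colonization dataset
#'
#' Per plant, a true cfu/g value is drawn log-normally (normal on the log10
#' scale around the cell mean), the root mass log-normally around
#' `root_mass_mean_g`, and observed colony counts per plate are Poisson around
#' the expected count implied by the plating scheme (plated volume, homogenate
#' volume, dilution factor). One row per plant x plate.
#'
#' @param design a design list, see [cfu_design_default()].
#' @param seed integer seed (stream `"cfu"`); identical seeds give identical
#'   tables.
#' @return data.frame of class `sip_cfu_table` with columns plant_id,
#'   genotype, strain, plate, colonies, plated_volume_ul, homogenate_volume_ul,
#'   dilution_factor, root_mass_g, and attribute `truth` (per-plant generating
#'   log10 cfu/g).
#' @export
simulate_cfu_dataset <- function(design = cfu_design_default(), seed = 1) {
  if (design$n_per_cell < 2L)
    stop("n_per_cell must be >= 2 (ANOVA needs residual degrees of freedom)")
  stopifnot(nrow(design$cells) >= 1L, design$sdlog10 >= 0)
  with_seed_(derive_seed(seed, "cfu"), function() {
    rows <- list()
    truth <- list()
    plant <- 0L
    mass_sdlog <- sqrt(log(1 + design$root_mass_cv^2))
    for (ci in seq_len(nrow(design$cells))) {
      cell <- design$cells[ci, ]
      for (r in seq_len(design$n_per_cell)) {
        plant <- plant + 1L
        log10_cfu <- rnorm(1, cell$log10_mean, design$sdlog10)
        root_mass <- design$root_mass_mean_g *
          exp(rnorm(1, -mass_sdlog^2 / 2, mass_sdlog))
        expected_colonies <- 10^log10_cfu * root_mass /
          ((design$homogenate_volume_ul / design$plated_volume_ul) *
             design$dilution_factor)
        colonies <- rpois(design$n_plates, expected_colonies)
        rows[[plant]] <- data.frame(
          plant_id = sprintf("P%03d", plant), genotype = cell$genotype,
          strain = cell$strain, plate = seq_len(design$n_plates),
          colonies = colonies, plated_volume_ul = design$plated_volume_ul,
          homogenate_volume_ul = design$homogenate_volume_ul,
          dilution_factor = design$dilution_factor, root_mass_g = root_mass,
          stringsAsFactors = FALSE)
        truth[[plant]] <- data.frame(
          plant_id = sprintf("P%03d", plant), genotype = cell$genotype,
          strain = cell$strain, log10_cfu_true = log10_cfu,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("sip_cfu_table", "data.frame")
    attr(out, "truth") <- do.call(rbind, truth)
    out
  })
}
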