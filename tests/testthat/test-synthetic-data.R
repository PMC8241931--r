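# Synthetic data generator: taxa, community profiles, gradient physics,
# replicate pooling, CFU simulation.

test_that("build_taxa keeps role bookkeeping and the Streptomyces bystander", {
  taxa <- build_taxa(default_community_design(), seed = 1)
  expect_setequal(unique(taxa$role),
                  c("exudate_metabolizer", "autotroph", "bystander"))
  # autotrophs (and only they) are labeled in unplanted 13C controls
  a_ctrl <- atom_excess(taxa, "13C", "unplanted_control")
  expect_true(all(a_ctrl[taxa$role == "autotroph"] > 0))
  expect_true(all(a_ctrl[taxa$role != "autotroph"] == 0))
  # Streptomyces is an unlabeled bystander everywhere
  strep <- which(taxa$genus == "Streptomyces")
  for (iso in c("12C", "13C"))
    for (comp in c("bulk_soil", "rhizosphere", "endosphere", "unplanted_control"))
      expect_equal(atom_excess(taxa, iso, comp)[strep], 0)
  # nothing is labeled under 12C
  expect_true(all(atom_excess(taxa, "12C", "rhizosphere") == 0))
  # determinism: same seed, same table
  expect_identical(taxa, build_taxa(default_community_design(), seed = 1))
})

test_that("build_taxa validates its configuration", {
  d <- default_community_design()
  d$taxa <- d$taxa[0, ]
  expect_error(build_taxa(d), "empty clade list")
  d2 <- default_community_design()
  d2$taxa <- d2$taxa[d2$taxa$role != "autotroph", ]
  expect_error(build_taxa(d2), "autotroph")
  d3 <- default_community_design()
  d3$taxa <- d3$taxa[d3$taxa$genus != "Streptomyces", ]
  expect_error(build_taxa(d3), "Streptomyces")
})

test_that("community profiles are simplexes with the endosphere boost", {
  design <- default_community_design()
  taxa <- build_taxa(design, seed = 1)
  prof <- simulate_compartment_profiles(taxa, design, seed = 3)
  for (p in prof) {
    expect_equal(sum(p$proportions), 1, tolerance = 1e-12)
    expect_true(all(p$proportions >= 0))
  }
  # single taxon: proportion exactly 1 in every compartment
  d1 <- design; d1$taxa <- d1$taxa[1, ]
  t1 <- d1$taxa; t1$taxon_id <- "t1"; rownames(t1) <- "t1"
  attr(t1, "a_label") <- 0.5
  p1 <- simulate_compartment_profiles(t1, d1, "bulk_soil", 1, seed = 1)
  expect_equal(unname(p1[[1]]$proportions), 1)
  # Monte-Carlo check of the configured Proteobacteria boost
  proteo <- taxa$phylum == "Proteobacteria"
  share <- function(comp) mean(vapply(
    simulate_compartment_profiles(taxa, design, comp, 1:1000, seed = 11),
    function(p) sum(p$proportions[proteo]), 0))
  expect_gt(share("endosphere"), share("bulk_soil"))
  expect_gt(share("endosphere"), 0.85)
  # different seeds give different profiles; same seed reproduces
  prof_b <- simulate_compartment_profiles(taxa, design, seed = 4)
  expect_false(identical(prof[[1]]$proportions, prof_b[[1]]$proportions))
  expect_identical(prof, simulate_compartment_profiles(taxa, design, seed = 3))
  bad <- design; bad$replicate_sdlog <- 0
  expect_error(simulate_compartment_profiles(taxa, bad, seed = 1), "positive")
})

test_that("buoyant density follows the linear GC/label model", {
  m <- gradient_model()
  expect_equal(buoyant_density(0.5, 0, m), 1.709)
  expect_equal(buoyant_density(0.5, 1, m), 1.745)
  # shift between A=0 and A=1 is exactly delta_rho_full_label for any gc
  gc <- seq(0, 1, by = 0.1)
  expect_equal(buoyant_density(gc, 1, m) - buoyant_density(gc, 0, m),
               rep(m$delta_rho_full_label, length(gc)))
  # strictly increasing in both arguments
  expect_true(all(diff(buoyant_density(gc, 0.3, m)) > 0))
  expect_true(all(diff(buoyant_density(0.4, gc, m)) > 0))
  expect_error(buoyant_density(-0.1, 0, m), "gc")
  expect_error(buoyant_density(0.5, 1.5, m), "atom excess")
})

one_taxon <- function(gc, role = "bystander", a_label = 0.5) {
  tx <- data.frame(taxon_id = "t1", genus = "Solo", phylum = "Proteobacteria",
                   role = role, gc = gc, base_weight = 1,
                   active_rhizosphere = TRUE, active_endosphere = TRUE,
                   stringsAsFactors = FALSE)
  rownames(tx) <- "t1"
  attr(tx, "a_label") <- a_label
  tx
}

solo_profile <- function() {
  structure(list(compartment = "rhizosphere", replicate = 1,
                 proportions = c(t1 = 1)), class = "sip_community_profile")
}

test_that("gradient runs conserve mass and shift with labeling", {
  gm <- gradient_model()
  sm0 <- sequencing_model(qpcr_noise_cv = 0)  # noise off
  run0 <- simulate_gradient_run(solo_profile(), "12C", one_taxon(0.5), 1.5,
                                gm, sm0, seed = 1)
  # per-taxon fraction masses equal the Gaussian bin integrals x loaded mass
  edges <- seq(gm$density_min, gm$density_max, length.out = gm$n_fractions + 1)
  expected <- 1.5 * diff(pnorm(edges, buoyant_density(0.5, 0, gm), gm$band_sd))
  expect_equal(sort(unname(run0$mass[1, ]), decreasing = FALSE),
               sort(expected), tolerance = 1e-12)
  expect_lte(sum(run0$mass), 1.5)
  expect_equal(sum(run0$mass),
               1.5 * diff(pnorm(c(gm$density_min, gm$density_max),
                                buoyant_density(0.5, 0, gm), gm$band_sd)),
               tolerance = 1e-9)
  # full label shifts the copy-weighted mean density by delta_rho +- one bin
  run1 <- simulate_gradient_run(
    solo_profile(), "13C", one_taxon(0.5, "exudate_metabolizer", a_label = 1),
    1.5, gm, sm0, seed = 1)
  bin_width <- (gm$density_max - gm$density_min) / gm$n_fractions
  expect_lt(abs((mean_density(run1) - mean_density(run0)) -
                  gm$delta_rho_full_label), bin_width)
})

# a_label must be in (0,1]; an effectively unlabeled taxon uses a tiny A
a_eff <- function(a) if (a == 0) 1e-9 else a

test_that("monotone labeling: atom excess never lightens a taxon (noise off)", {
  gm <- gradient_model()
  sm0 <- sequencing_model(qpcr_noise_cv = 0)
  md <- vapply(seq(0, 1, by = 0.2), function(a) {
    mean_density(simulate_gradient_run(
      solo_profile(), "13C", one_taxon(0.45, "exudate_metabolizer", a_label = a_eff(a)),
      1, gm, sm0, seed = 1))
  }, 0)
  expect_true(all(diff(md) >= -1e-12))
})

test_that("heavy-tail fractions of a 12C run hold the high-GC taxa only", {
  design <- small_design()
  taxa <- build_taxa(design, seed = 1)
  prof <- simulate_compartment_profiles(taxa, design, "rhizosphere", 1, seed = 5)[[1]]
  run <- simulate_gradient_run(prof, "12C", taxa, 1.5,
                               smodel = sequencing_model(qpcr_noise_cv = 0),
                               seed = 1)
  # brute-force per-bin expectation: composition of the densest two informative
  # fractions must be dominated by the highest-GC taxa (Streptomyces gc=0.72)
  informative <- which(colSums(run$mass) > 1e-6)
  densest <- informative[1:2]  # fractions are ordered densest-first
  comp <- rowSums(run$mass[, densest, drop = FALSE])
  comp <- comp / sum(comp)
  expect_equal(names(which.max(comp)),
               taxa$taxon_id[which.max(taxa$gc)])
  low_gc <- taxa$gc < 0.55
  expect_lt(sum(comp[low_gc]), 0.01)
})

test_that("gradient run errors when a taxon bands outside the window", {
  gm <- gradient_model(density_min = 1.70, density_max = 1.72)
  expect_error(
    simulate_gradient_run(solo_profile(), "12C", one_taxon(0.98), 1, gm,
                          sequencing_model(qpcr_noise_cv = 0), seed = 1),
    "t1 bands entirely outside")
})

test_that("pool_replicate_dna is the arithmetic mean of compositions", {
  mk <- function(p, rep) structure(
    list(compartment = "endosphere", replicate = rep,
         proportions = p / sum(p)), class = "sip_community_profile")
  # identical replicates: idempotent
  p <- c(a = 0.3, b = 0.7)
  pooled <- pool_replicate_dna(list(mk(p, 1), mk(p, 2)), mass_each = 0.2)
  expect_equal(pooled$proportions, p)
  expect_identical(pooled$replicate, "pooled")
  expect_equal(attr(pooled, "total_mass"), 0.4)
  # {1,0} and {0,1} pool to {0.5, 0.5}
  pooled2 <- pool_replicate_dna(list(mk(c(a = 1, b = 0), 1),
                                     mk(c(a = 0, b = 1), 2)))
  expect_equal(unname(pooled2$proportions), c(0.5, 0.5))
  # three unequal replicates: arithmetic mean, sums to 1
  ps <- list(mk(c(a = 1, b = 3), 1), mk(c(a = 2, b = 2), 2),
             mk(c(a = 5, b = 1), 3))
  pooled3 <- pool_replicate_dna(ps)
  expect_equal(sum(pooled3$proportions), 1)
  expect_equal(unname(pooled3$proportions[1]),
               mean(c(0.25, 0.5, 5 / 6)))
  # mixed compartments refuse to pool
  bad <- mk(p, 1); bad$compartment <- "rhizosphere"
  expect_error(pool_replicate_dna(list(mk(p, 1), bad)), "compartments")
})

test_that("CFU simulation is deterministic and encodes the cpr5 effect", {
  tab1 <- simulate_cfu_dataset(seed = 7)
  tab2 <- simulate_cfu_dataset(seed = 7)
  expect_identical(tab1, tab2)
  expect_false(identical(tab1, simulate_cfu_dataset(seed = 8)))
  truth <- attr(tab1, "truth")
  expect_equal(nrow(truth), 4 * 2 * 6)  # genotypes x strains x plants
  design <- cfu_design_default()
  expect_true(all(design$cells$log10_mean[design$cells$genotype == "cpr5"] >
                    design$cells$log10_mean[design$cells$genotype == "Col-0"]))
  expect_error(simulate_cfu_dataset(cfu_design_default(n_per_cell = 1)),
               "n_per_cell")
})

test_that("identical seeds reproduce whole experiments byte-identically", {
  e1 <- simulate_sip_experiment(design = small_design(), seed = 42,
                                cfu_design = NULL)
  e2 <- simulate_sip_experiment(design = small_design(), seed = 42,
                                cfu_design = NULL)
  expect_identical(e1, e2)
  e3 <- simulate_sip_experiment(design = small_design(), seed = 43,
                                cfu_design = NULL)
  expect_false(identical(e1$runs[[1]]$counts, e3$runs[[1]]$counts))
})
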