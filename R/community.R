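# Community profiles: per-(compartment, replicate) relative abundance vectors
# with log-normal replicate noise and compartment-specific weight multipliers.

compartment_weights <- function(taxa, design, compartment) {
  w <- taxa$base_weight
  if (compartment == "rhizosphere") {
    boost <- taxa$role == "exudate_metabolizer" & taxa$active_rhizosphere
    w[boost] <- w[boost] * design$rhizosphere_metabolizer_boost
  } else if (compartment == "endosphere") {
    proteo <- taxa$phylum == "Proteobacteria"
    w[proteo] <- w[proteo] * design$endosphere_proteo_boost
  }
  w
}

new_profile <- function(compartment, replicate, proportions) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9, all(proportions >= 0))
  structure(list(compartment = compartment, replicate = replicate,
                 proportions = proportions),
            class = "sip_community_profile")
}

#' Simulate per-pot community profiles
#'
#' One relative-abundance profile per (compartment, replicate): taxon weights
#' are the design's base weights times the compartment multiplier (rhizosphere
#' effect for active metabolizers; Proteobacteria boost in the endosphere),
#' perturbed by multiplicative log-normal replicate noise and renormalized to
#' sum to one. Each (compartment, replicate) pair has its own derived random
#' stream, so subsets of the design are reproducible independently.
#'
#' @param taxa taxon table from [build_taxa()].
#' @param design the `sip_community_design` used to build `taxa`.
#' @param compartments character vector of compartments to simulate.
#' @param replicates integer vector of replicate ids (default `1:3`).
#' @param seed integer root seed.
#' @param stream extra label mixed into the derived seeds, so e.g. the 12C and
#'   13C pots of the same compartment/replicate are distinct plants.
#' @return list of `sip_community_profile` objects (compartment, replicate,
#'   named proportions vector over taxon ids).
#' @export
simulate_compartment_profiles <- function(taxa, design = default_community_design(),
                                          compartments = sip_compartments,
                                          replicates = 1:3, seed = 1,
                                          stream = "community") {
  if (design$replicate_sdlog <= 0)
    stop("replicate_sdlog (dispersion) must be positive")
  compartments <- match.arg(compartments, sip_compartments, several.ok = TRUE)
  out <- list()
  for (comp in compartments) {
    w0 <- compartment_weights(taxa, design, comp)
    for (rep_i in replicates) {
      child <- derive_seed(seed, stream, comp, rep_i)
      prop <- with_seed_(child, function() {
        w <- w0 * exp(rnorm(length(w0), 0, design$replicate_sdlog))
        w / sum(w)
      })
      names(prop) <- taxa$taxon_id
      out[[paste(comp, rep_i, sep = ".")]] <- new_profile(comp, rep_i, prop)
    }
  }
  out
}

#' Pool equal DNA masses from replicate community profiles
#'
#' Models the wet-lab step of combining equal DNA quantities from each
#' replicate before ultracentrifugation (used for the low-yield root samples):
#' an equal-mass mixture has pooled proportions equal to the arithmetic mean
#' of the replicate proportions.
#'
#' @param profiles list of `sip_community_profile` objects, all from the same
#'   compartment.
#' @param mass_each DNA mass (ug) contributed by each replicate; recorded as
#'   attribute `total_mass` on the result.
#' @return a `sip_community_profile` with `replicate = "pooled"`.
#' @export
pool_replicate_dna <- function(profiles, mass_each = 0.2) {
  stopifnot(length(profiles) >= 1L)
  comps <- vapply(profiles, `[[`, "", "compartment")
  if (length(unique(comps)) != 1L)
    stop("cannot pool DNA across compartments: ",
         paste(unique(comps), collapse = ", "))
  mat <- vapply(profiles, `[[`, profiles[[1]]$proportions, "proportions")
  pooled <- new_profile(comps[1], "pooled", rowMeans(mat))
  attr(pooled, "total_mass") <- mass_each * length(profiles)
  pooled
}
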