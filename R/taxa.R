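#' Default community design for the synthetic SIP experiment
#'
#' The stated world the simulator emulates: a compost community of 20 genera
#' with three ecological roles. Exudate metabolizers acquire \eqn{^{13}}C label
#' (atom fraction excess `a_label`) only in planted compartments where they are
#' active; autotrophs fix CO\eqn{_2} directly and are labeled in planted and
#' unplanted compartments alike; bystanders never acquire label. GC contents
#' are literature-style values per genus (Streptomyces is high-GC, ~72%, which
#' is what makes it the canonical false-positive risk in density gradients).
#' Base weights are set so that Proteobacteria make up roughly 30% of the bulk
#' soil community and, after the endosphere boost, ~91% of the root-associated
#' community, with labeled taxa a minority (~19%) of the 13C rhizosphere
#' community.
#'
#' @param a_label atom fraction excess of \eqn{^{13}}C in the DNA of labeled
#'   taxa (0-1); default 0.5.
#' @param gc_interval interval from which GC contents are drawn for taxa whose
#'   `gc` is `NA`; default `c(0.35, 0.75)`.
#' @param rhizosphere_metabolizer_boost multiplicative weight boost for active
#'   exudate metabolizers in the rhizosphere (the rhizosphere effect).
#' @param endosphere_proteo_boost multiplicative weight boost for all
#'   Proteobacteria in the endosphere (drives the observed ~91% dominance).
#' @param replicate_sdlog standard deviation of the log-normal replicate noise
#'   applied to taxon weights (per pot); must be > 0.
#' @return a list of class `sip_community_design` with elements `taxa`
#'   (data.frame: genus, phylum, role, gc, base_weight, active_rhizosphere,
#'   active_endosphere), `a_label`, `gc_interval` and the boost parameters.
#' @export
default_community_design <- function(a_label = 0.5,
                                     gc_interval = c(0.35, 0.75),
                                     rhizosphere_metabolizer_boost = 1.8,
                                     endosphere_proteo_boost = 25,
                                     replicate_sdlog = 0.4) {
  taxa <- data.frame(
    genus = c("Pseudomonas", "Shinella", "Rhizobium", "Duganella",
              "Dechloromonas", "Herbaspirillum",
              "Nitrosomonas", "Paracoccus", "Nitrospira",
              "Sphingomonas", "Acinetobacter", "Janthinobacterium",
              "Streptomyces", "Arthrobacter", "Bacillus", "Paenibacillus",
              "Flavobacterium", "Chitinophaga", "Opitutus", "Gemmata"),
    phylum = c(rep("Proteobacteria", 8), "Nitrospirae",
               rep("Proteobacteria", 3),
               "Actinobacteria", "Actinobacteria", "Firmicutes", "Firmicutes",
               "Bacteroidetes", "Bacteroidetes", "Verrucomicrobia",
               "Planctomycetes"),
    role = c(rep("exudate_metabolizer", 6), rep("autotroph", 3),
             rep("bystander", 11)),
    gc = c(0.61, 0.60, 0.59, 0.55, 0.59, 0.61,
           0.51, 0.66, 0.57,
           0.65, 0.40, 0.61,
           0.72, 0.63, 0.44, 0.45, 0.36, 0.48, 0.58, 0.64),
    base_weight = c(2.0, 1.2, 1.6, 1.2, 1.0, 1.5,
                    1.5, 1.0, 1.5,
                    6, 6, 5,
                    6, 6, 9, 6, 11, 9, 9, 8),
    active_rhizosphere = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                           rep(FALSE, 14)),
    active_endosphere = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
                          rep(FALSE, 14)),
    stringsAsFactors = FALSE
  )
  structure(
    list(taxa = taxa, a_label = a_label, gc_interval = gc_interval,
         rhizosphere_metabolizer_boost = rhizosphere_metabolizer_boost,
         endosphere_proteo_boost = endosphere_proteo_boost,
         replicate_sdlog = replicate_sdlog),
    class = "sip_community_design"
  )
}

sip_roles <- c("exudate_metabolizer", "autotroph", "bystander")
sip_compartments <- c("bulk_soil", "rhizosphere", "endosphere",
                      "unplanted_control")
planted_compartments <- c("rhizosphere", "endosphere")

#' Build the simulated taxon set from a community design
#'
#' Validates the design, fills in any missing GC contents by uniform draws
#' from `design$gc_interval`, and assigns opaque taxon ids. The returned table
#' satisfies the role/labeling invariants used throughout the simulator:
#' bystanders have zero atom excess everywhere, autotrophs are labeled under
#' \eqn{^{13}}CO\eqn{_2} in every compartment, exudate metabolizers only in
#' planted compartments where they are active, and nothing is labeled under
#' \eqn{^{12}}CO\eqn{_2} (see [atom_excess()]).
#'
#' @param design a `sip_community_design`, see [default_community_design()].
#' @param seed integer seed for the GC draws (only consumed if any `gc` is
#'   `NA`); identical seeds give identical taxon tables.
#' @return data.frame with columns taxon_id, genus, phylum, role, gc,
#'   base_weight, active_rhizosphere, active_endosphere and attribute
#'   `a_label`.
#' @export
build_taxa <- function(design = default_community_design(), seed = NULL) {
  taxa <- design$taxa
  if (is.null(taxa) || nrow(taxa) == 0L)
    stop("community design contains no taxa (empty clade list)")
  missing_roles <- setdiff(sip_roles, taxa$role)
  if (length(missing_roles))
    stop("community design must name at least one taxon per role; missing: ",
         paste(missing_roles, collapse = ", "))
  if (!any(taxa$genus == "Streptomyces" & taxa$role == "bystander"))
    stop("design must include a bystander 'Streptomyces' taxon")
  if (!all(taxa$role %in% sip_roles))
    stop("unknown role(s): ", paste(setdiff(taxa$role, sip_roles), collapse = ", "))
  if (design$a_label <= 0 || design$a_label > 1)
    stop("a_label must be in (0, 1]")
  if (anyNA(taxa$gc)) {
    iv <- design$gc_interval
    stopifnot(length(iv) == 2L, iv[1] < iv[2], iv[1] >= 0, iv[2] <= 1)
    with_seed_(if (is.null(seed)) NULL else derive_seed(seed, "gc"), function() {
      na <- which(is.na(taxa$gc))
      taxa$gc[na] <<- runif(length(na), iv[1], iv[2])
    })
  }
  if (any(taxa$gc < 0 | taxa$gc > 1)) stop("gc values must lie in [0, 1]")
  if (any(taxa$base_weight <= 0)) stop("base weights must be positive")
  taxa$taxon_id <- sprintf("t%02d_%s", seq_len(nrow(taxa)), taxa$genus)
  rownames(taxa) <- taxa$taxon_id
  taxa <- taxa[, c("taxon_id", "genus", "phylum", "role", "gc", "base_weight",
                   "active_rhizosphere", "active_endosphere")]
  attr(taxa, "a_label") <- design$a_label
  taxa
}

#' Atom fraction excess of a taxon under a given treatment
#'
#' Encodes the labeling rules of the simulation: under \eqn{^{12}}CO\eqn{_2}
#' nothing is labeled; under \eqn{^{13}}CO\eqn{_2} autotrophs are labeled in
#' every compartment, exudate metabolizers only in planted compartments where
#' they are active, bystanders never.
#'
#' @param taxa taxon table from [build_taxa()] (or any subset of its rows).
#' @param isotope `"12C"` or `"13C"`.
#' @param compartment one of bulk_soil, rhizosphere, endosphere,
#'   unplanted_control.
#' @return numeric vector of atom fraction excess values, one per taxon row.
#' @export
atom_excess <- function(taxa, isotope, compartment) {
  isotope <- match.arg(isotope, c("12C", "13C"))
  compartment <- match.arg(compartment, sip_compartments)
  a_label <- attr(taxa, "a_label")
  if (is.null(a_label)) stop("taxa table lacks an a_label attribute; use build_taxa()")
  a <- numeric(nrow(taxa))
  if (isotope == "12C") return(a)
  a[taxa$role == "autotroph"] <- a_label
  if (compartment == "rhizosphere")
    a[taxa$role == "exudate_metabolizer" & taxa$active_rhizosphere] <- a_label
  if (compartment == "endosphere")
    a[taxa$role == "exudate_metabolizer" & taxa$active_endosphere] <- a_label
  a
}
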