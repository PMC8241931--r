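#' Isopycnic gradient model
#'
#' Parameterizes the CsCl buoyant-density physics used by the simulator: a
#' Schildkraut-type linear GC relation (rho = 1.660 + 0.098 GC g/mL), a full
#' \eqn{^{13}}C label shift of 0.036 g/mL, Gaussian band broadening, and a set
#' of equal-width density bins representing the collected fractions.
#'
#' @param rho0_intercept buoyant density (g/mL) of hypothetical 0% GC,
#'   unlabeled DNA.
#' @param rho0_slope_per_gc density increase per unit GC fraction (g/mL).
#' @param delta_rho_full_label density shift at atom fraction excess A = 1.
#' @param band_sd Gaussian band width (g/mL) of a single taxon's DNA.
#' @param n_fractions number of equal-width fractions collected (>= 4).
#' @param density_min,density_max outer bin edges (g/mL).
#' @return list of class `gradient_model`.
#' @export
gradient_model <- function(rho0_intercept = 1.660, rho0_slope_per_gc = 0.098,
                           delta_rho_full_label = 0.036, band_sd = 0.006,
                           n_fractions = 12L, density_min = 1.690,
                           density_max = 1.760) {
  stopifnot(density_min < density_max, n_fractions >= 4, band_sd > 0,
            rho0_slope_per_gc > 0, delta_rho_full_label > 0)
  structure(list(rho0_intercept = rho0_intercept,
                 rho0_slope_per_gc = rho0_slope_per_gc,
                 delta_rho_full_label = delta_rho_full_label,
                 band_sd = band_sd, n_fractions = as.integer(n_fractions),
                 density_min = density_min, density_max = density_max),
            class = "gradient_model")
}

#' Sequencing and qPCR noise model
#'
#' @param library_size total reads drawn per gradient fraction (and per
#'   unfractionated sample) by multinomial sampling.
#' @param qpcr_noise_cv coefficient of variation of the multiplicative
#'   log-normal noise on per-fraction 16S copy numbers (0 disables noise).
#' @param copies_per_ug 16S rRNA gene copies per microgram of community DNA,
#'   the scale factor linking simulated DNA mass to qPCR copy numbers.
#' @return list of class `sequencing_model`.
#' @export
sequencing_model <- function(library_size = 50000L, qpcr_noise_cv = 0.1,
                             copies_per_ug = 2e8) {
  stopifnot(library_size > 0, qpcr_noise_cv >= 0, copies_per_ug > 0)
  structure(list(library_size = as.integer(library_size),
                 qpcr_noise_cv = qpcr_noise_cv, copies_per_ug = copies_per_ug),
            class = "sequencing_model")
}

#' Equilibrium buoyant density of DNA in a CsCl gradient
#'
#' `rho = rho0_intercept + rho0_slope_per_gc * gc + A * delta_rho_full_label`,
#' strictly increasing in both GC content and atom fraction excess.
#'
#' @param gc G+C fraction of the genome (0-1); vectorized.
#' @param a atom fraction excess of \eqn{^{13}}C (0-1); vectorized.
#' @param model a [gradient_model()].
#' @return buoyant density in g/mL.
#' @examples
#' buoyant_density(0.5, 0)  # 1.709
#' buoyant_density(0.5, 1)  # 1.745
#' @export
buoyant_density <- function(gc, a, model = gradient_model()) {
  if (any(gc < 0 | gc > 1)) stop("gc must lie in [0, 1]")
  if (any(a < 0 | a > 1)) stop("atom excess must lie in [0, 1]")
  model$rho0_intercept + model$rho0_slope_per_gc * gc +
    a * model$delta_rho_full_label
}

fraction_edges <- function(model) {
  seq(model$density_min, model$density_max, length.out = model$n_fractions + 1L)
}

#' Simulate one density-gradient ultracentrifugation run
#'
#' Each taxon's DNA mass (loaded mass times community proportion) is spread
#' over the fraction density bins as a Gaussian band centered at its buoyant
#' density ([buoyant_density()] of its GC and treatment-dependent atom
#' excess) with sd `band_sd`. Per fraction, 16S copies are total in-bin mass
#' scaled by `copies_per_ug` under multiplicative log-normal noise, and read
#' counts are a multinomial draw over taxa proportional to in-bin mass with
#' total `library_size`. Fractions are indexed 1-based from the densest
#' fraction; densities are carried explicitly so the convention never affects
#' results.
#'
#' @param profile a `sip_community_profile`.
#' @param isotope `"12C"` or `"13C"`; determines which atom excess applies.
#' @param taxa taxon table from [build_taxa()] (order must match
#'   `profile$proportions`).
#' @param dna_mass_loaded DNA mass loaded into the gradient (ug); the study
#'   used 1.5 ug per rhizosphere replicate, 1 ug per unplanted control and
#'   0.6 ug for the pooled root samples.
#' @param gmodel a [gradient_model()].
#' @param smodel a [sequencing_model()].
#' @param seed root seed; the run uses the derived stream
#'   (`"gradient"`, compartment, replicate, isotope). `NULL` leaves the RNG
#'   state alone.
#' @return list of class `sip_gradient_run`: sample metadata, `fractions`
#'   data.frame (fraction_index, density, copies), `counts` and `mass`
#'   matrices (taxa x fractions, densest first).
#' @export
simulate_gradient_run <- function(profile, isotope, taxa, dna_mass_loaded,
                                  gmodel = gradient_model(),
                                  smodel = sequencing_model(), seed = NULL) {
  stopifnot(inherits(profile, "sip_community_profile"),
            dna_mass_loaded > 0,
            identical(names(profile$proportions), taxa$taxon_id))
  isotope <- match.arg(isotope, c("12C", "13C"))
  edges <- fraction_edges(gmodel)
  a <- atom_excess(taxa, isotope, profile$compartment)
  mu <- buoyant_density(taxa$gc, a, gmodel)

  mass <- matrix(0, nrow(taxa), gmodel$n_fractions,
                 dimnames = list(taxa$taxon_id, NULL))
  for (i in seq_len(nrow(taxa))) {
    p_bin <- diff(pnorm(edges, mean = mu[i], sd = gmodel$band_sd))
    if (profile$proportions[i] > 0 && sum(p_bin) < 1e-6)
      stop("taxon ", taxa$taxon_id[i], " bands entirely outside the collected ",
           "density range [", gmodel$density_min, ", ", gmodel$density_max, "]")
    mass[i, ] <- dna_mass_loaded * profile$proportions[i] * p_bin
  }
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  ord <- order(centers, decreasing = TRUE)  # index 1 = densest fraction
  mass <- mass[, ord, drop = FALSE]
  centers <- centers[ord]
  colnames(mass) <- sprintf("F%02d", seq_along(centers))

  child <- if (is.null(seed)) NULL else
    derive_seed(seed, "gradient", profile$compartment, profile$replicate, isotope)
  run <- with_seed_(child, function() {
    fraction_mass <- colSums(mass)
    noise <- if (smodel$qpcr_noise_cv > 0) {
      sdlog <- sqrt(log(1 + smodel$qpcr_noise_cv^2))
      exp(rnorm(length(fraction_mass), -sdlog^2 / 2, sdlog))
    } else rep(1, length(fraction_mass))
    copies <- fraction_mass * smodel$copies_per_ug * noise
    counts <- matrix(0L, nrow(mass), ncol(mass), dimnames = dimnames(mass))
    for (f in seq_len(ncol(mass))) {
      if (fraction_mass[f] > 0)
        counts[, f] <- rmultinom(1, smodel$library_size, mass[, f])[, 1]
    }
    list(copies = copies, counts = counts)
  })

  structure(list(
    isotope = isotope, compartment = profile$compartment,
    replicate = profile$replicate, dna_mass_loaded = dna_mass_loaded,
    fractions = data.frame(fraction_index = seq_along(centers),
                           density = centers, copies = run$copies),
    counts = run$counts, mass = mass,
    gmodel = gmodel, smodel = smodel
  ), class = "sip_gradient_run")
}

#' Copy-weighted mean buoyant density of a gradient run
#'
#' @param run a `sip_gradient_run` (or data.frame with density and copies).
#' @return mean density (g/mL) weighted by 16S copies per fraction.
#' @export
mean_density <- function(run) {
  fr <- if (inherits(run, "sip_gradient_run")) run$fractions else run
  sum(fr$density * fr$copies) / sum(fr$copies)
}
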