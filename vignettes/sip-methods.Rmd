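---
title: "Methods: stable-isotope-probing analysis of root-exudate feeders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stable-isotope-probing analysis of root-exudate feeders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizoSIP)
```

## The experiment this package models

In a ^13^CO~2~ DNA stable-isotope-probing (SIP) experiment, plants fix the
heavy carbon isotope and exude part of it into the soil around the roots.
Bacteria that grow on those exudates (or on plant metabolites inside the
root) incorporate ^13^C into newly synthesized DNA, which raises the DNA's
equilibrium buoyant density in a CsCl gradient. After ultracentrifugation,
gradient fractions are quantified by 16S rRNA gene qPCR, fractions spanning
the heavy and light copy-number peaks are pooled, and the pooled fractions
are amplicon sequenced. A genus whose relative abundance is much higher in
the ^13^C heavy fraction (^13^CH) than in both the ^13^C light (^13^CL) and
the ^12^C heavy (^12^CH) fractions is called *labeled* — an active consumer
of plant-derived carbon. Genera that are also enriched in the heavy fractions
of *unplanted* ^13^CO~2~ control pots fix CO~2~ directly (e.g. nitrifiers)
and are excluded.

The package implements this analysis as composable stages plus a synthetic
generator that emulates the full study design so everything can be tested at
desk scale.

## The enrichment rule and its conventions

A genus is labeled in a compartment when

$$\frac{\bar x_{13CH}}{\bar x_{13CL}} \ge t
  \quad\text{and}\quad
  \frac{\bar x_{13CH}}{\bar x_{12CH}} \ge t
  \quad\text{and}\quad
  \text{genus} \notin \text{autotrophs},$$

with $t = 2$ by default and $\bar x$ the arithmetic mean relative abundance
over replicate samples of a class.

Conventions, all of which were genuinely open choices:

* **Ratio of means, not mean of ratios.** Means are computed first and one
  ratio is formed. The alternative (per-replicate ratios, then averaged) is
  undefined for the pooled endosphere gradients, which have $n = 1$ per
  class, so ratio-of-means is the only convention that treats both
  compartments identically.
* **Threshold is inclusive** (`>= 2`): "two-fold or more".
* **Printed folds truncate.** Reported integer folds are `floor(ratio)`;
  this is the only rounding convention consistent with fold values printed
  from the same abundances in the source domain (38 from 38.85, 23 from
  23.17, 26 from 26.51, 23 from 23.32).
* **Zero denominators** are floored at a pseudo-abundance of $10^{-6}$
  (one read in a million), and every record where the floor fired carries a
  `pseudo_used` flag. Without a floor, a single zero column would produce
  infinite folds and unstable orderings.
* **The autotroph filter reuses the same threshold** $t$ on the unplanted
  control H/L ratio; no separate value is defensible from the design, and
  the filter is mandatory — the classifier refuses to run without control
  samples rather than silently skipping it.

## Gradient windows: "fractions spanning the peaks"

`select_heavy_light()` formalizes the judgment call of picking heavy and
light windows from a qPCR copy-number profile:

* the **light window** is the contiguous block of fractions around the main
  copy peak with copies above a background floor
  (`background_fraction` × peak, default 5%);
* the **heavy window** is the contiguous block at density at least
  `delta_density` (default 0.015 g/mL) above the peak density with copies
  above the same floor; if several blocks qualify, the one with the most
  copies wins.

Both parameters are exposed on the CLI and a manual override
(`heavy_ids`/`light_ids`) exists because no automatic rule survives every
pathological profile. Two further design points:

* **Anchoring.** The global copy peak is the light anchor by default, which
  is correct whenever unlabeled DNA dominates the gradient (true for all the
  simulated designs here, where labeled taxa are a minority). For heavily
  labeled communities the global peak *is* the heavy band; for that case an
  explicit `light_anchor` (the expected unlabeled density, e.g. from a
  paired ^12^C gradient) places the windows correctly.
* **Window sharing.** In the pipeline, windows are selected on each ^13^C
  gradient and the same fraction indices are applied to the paired ^12^C
  gradient. An unlabeled profile is unimodal — it has no detached heavy peak
  of its own to find — but the ^12^CH class must still be measured at the
  same densities as ^13^CH for the second ratio to be meaningful.

**Equal-quantity pooling.** Combining "equal quantities" of DNA from each
window fraction means each fraction contributes equal mass, so the pooled
composition is the arithmetic mean of the per-fraction compositions,
rescaled to the window's total read count. Pooling by raw read sums would
instead weight fractions by sequencing depth, which is an artifact of
library construction, not of the gradient.

## The synthetic world

`simulate_sip_experiment()` generates the full design: 3 replicate planted
pots per isotope with one rhizosphere gradient each (1.5 µg DNA loaded),
endosphere DNA pooled across replicates into one gradient per isotope
(3 × 0.2 µg), three unplanted ^13^C control gradients (1 µg), unfractionated
community profiles, and a CFU colonization assay. Because the endosphere is
pooled before ultracentrifugation, endosphere enrichment has no replicate
error — exactly as in the modeled study design.

Physics: buoyant density follows the Schildkraut-type linear relation
$\rho = 1.660 + 0.098\,\mathrm{GC}$ g/mL with a full-label shift of
0.036 g/mL scaled by the atom fraction excess $A$; bands are Gaussian with
sd 0.006 g/mL; fractions are 12 equal-width bins over 1.690–1.760 g/mL. The
source study performed but did not parameterize its gradients, so these are
standard SIP physics constants, all config-exposed; the fraction count and
bin edges are our choice (stated, not inferred). 16S copies per fraction are
in-bin DNA mass × 2 × 10^8 copies/µg under multiplicative log-normal noise
(CV 0.1); reads are multinomial over in-bin taxon mass with 50 000 reads per
fraction.

The default community has 20 genera with literature-style GC contents and
fixed roles: six exudate metabolizers (A = 0.5 under ^13^CO~2~ in the
planted compartments where each is active, with rhizosphere-only,
endosphere-only and shared subsets), three autotrophs (labeled under
^13^CO~2~ everywhere, including unplanted controls; the nitrifiers among
them mirror genera reported enriched in such controls), and eleven
bystanders including high-GC (72%) *Streptomyces*. Base weights were set
once so that Proteobacteria are ~30% of the bulk-soil community and ~91% of
the endosphere after the configured boost, and labeled taxa are ~19% of the
^13^C rhizosphere community — minorities, as in real gradients. Replicate
pots perturb weights log-normally (sdlog 0.4).

**What a green test does and does not establish.** The generator reproduces
the *statistical structure* the analysis assumes: GC-driven density
banding, label-driven shifts, compositional read sampling, qPCR noise,
pooled endosphere gradients. It does not emulate thousands of rare OTUs,
chimeras or OTU clustering artifacts (counts are emitted post-taxonomy),
primer or extraction bias, gradient curvature, or diffusion between
fractions. End-to-end recovery therefore validates the pipeline's logic and
conventions, not the field performance of SIP on any real soil.

**The GC confound is deliberately present.** High-GC unlabeled DNA bands at
the same density as moderately labeled moderate-GC DNA. In the default
world, *Streptomyces* (and occasionally other high-GC bystanders) is
enriched in the heavy fractions of the unplanted controls purely through
its GC content and is flagged "autotroph". That is a false mechanism but
the correct conservative outcome — the flag removes it from the labeled
set, which is what the control comparison is for. The confusion matrix in
synthetic summaries counts bystander false *positives* in the labeled set,
which remain zero.

## Supporting statistics

* **Shannon diversity** uses the natural log (matching the ~6.2 magnitude
  of published values for soil communities); the base is an argument.
* **Bray–Curtis / PCoA.** Classical scaling of the double-centered Gower
  matrix. Bray–Curtis matrices are non-Euclidean, so negative eigenvalues
  occur; they are dropped from the `variance_explained` denominator and the
  alternative (absolute-value) convention is reported in the diagnostics.
  No Lingoes/Cailliez correction is applied because none was specified for
  the analysis being reproduced.
* **PERMANOVA** uses the standard pseudo-F on among/within sums of squared
  dissimilarities, with $p = (1 + \#\{F^* \ge F\})/(1 + N)$ under seeded
  random relabeling. When the observed F exceeds every permutation the
  result is additionally reported as the string `"< 1/(N+1)"`, mirroring
  the usual "p < 0.01" reporting style. The pipeline's default factor is
  the fraction type (12H/12L/13H/13L) of the rhizosphere samples.
* **Colonization.** Colony counts on replicate plates are averaged per
  plant, converted to cfu/g and transformed as `log10(cfu/g + 1)` — the +1
  guards zero counts, which the source protocol leaves unspecified. The
  two-way ANOVA uses sequential (Type-I) sums of squares; the modeled
  design is balanced, where all SS types coincide, and unbalanced input
  triggers an explicit warning. Tukey HSD uses the Tukey–Kramer standard
  error and the studentized range distribution, with the residual mean
  square taken from the two-way fit.

## Numerical choices and degenerate inputs

* Simplex sums are checked to 10^-9^; gradient mass conservation holds to
  10^-9^ with noise off by construction.
* A taxon whose band captures less than 10^-6^ of its mass inside the
  collected density range aborts the gradient simulation, naming the taxon.
* Flat copy-number profiles (no peak) and windows with zero reads are
  errors, not silent empties; a missing heavy window instructs the user to
  supply windows manually.
* qPCR curves require ≥ 3 distinct dilutions, a negative slope and an
  efficiency in (0, 1.2]; efficiencies outside 0.8–1.1 warn. Copy
  extrapolation beyond the fitted dilution range is allowed but flagged.
* Every random stream derives from one root seed via a label hash
  (`derive_seed()`), so any subset of the design regenerates identically
  and independently; identical seeds give byte-identical outputs.

## Known limitations

* The fold rule is a deterministic screen, not a statistical test: no
  uncertainty is attached to the labeled/unlabeled verdict (the source
  analysis has none either). Differential-abundance modeling is explicitly
  out of scope.
* Real-mode inputs must already be genus-aggregated count tables; read
  processing, taxonomy and OTU clustering live upstream.
* The simulator's 20-genus world makes singleton filtering almost a no-op;
  the filter is exercised by dedicated unit fixtures instead.
* With pooled endosphere gradients the endosphere fold ratios rest on
  single samples; this is faithful to the modeled design, and it is why
  ratio-of-means is the only available convention there.
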