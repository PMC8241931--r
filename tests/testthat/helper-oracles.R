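# Shared fixtures and independent oracles, built in code at test time.

# a bare fraction profile table for window-selection tests
make_profile <- function(densities, copies) {
  data.frame(fraction_index = seq_along(densities), density = densities,
             copies = copies)
}

# random abundance table over one compartment with 3 replicates per class,
# for property tests of the enrichment rule
random_class_table <- function(n_genera, seed, compartment = "rhizosphere",
                               n_rep = 3L, sparsity = 0.3) {
  set.seed(seed)
  genera <- paste0("g", seq_len(n_genera))
  classes <- list(c("13C", "H"), c("13C", "L"), c("12C", "H"), c("12C", "L"))
  cols <- list(); meta <- list()
  for (cl in classes) for (r in seq_len(n_rep)) {
    v <- rexp(n_genera) * rbinom(n_genera, 1, 1 - sparsity)
    if (sum(v) == 0) v[sample.int(n_genera, 1)] <- 1
    sk <- paste(cl[1], compartment, r, cl[2], sep = "_")
    cols[[sk]] <- v / sum(v)
    meta[[sk]] <- data.frame(sample_key = sk, isotope = cl[1],
                             compartment = compartment, fraction_class = cl[2],
                             replicate = as.character(r),
                             stringsAsFactors = FALSE)
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- genera
  sip_abundance(vals, do.call(rbind, meta))
}

# literal, independent evaluation of the dual two-fold rule, genus by genus
brute_force_labeled <- function(tab, autotrophs, threshold = 2, pseudo = 1e-6) {
  m <- tab$values
  meta <- tab$meta
  col_of <- function(iso, fc) which(meta$isotope == iso & meta$fraction_class == fc)
  out <- logical(nrow(m))
  names(out) <- rownames(m)
  for (g in rownames(m)) {
    m13h <- mean(m[g, col_of("13C", "H")])
    m13l <- mean(m[g, col_of("13C", "L")])
    m12h <- mean(m[g, col_of("12C", "H")])
    r1 <- m13h / max(m13l, pseudo)
    r2 <- m13h / max(m12h, pseudo)
    out[g] <- (r1 >= threshold) && (r2 >= threshold) && !(g %in% autotrophs)
  }
  out
}

# small community design (8 taxa) for cheaper simulator tests
small_design <- function(...) {
  d <- default_community_design(...)
  keep <- c("Pseudomonas", "Shinella", "Duganella", "Herbaspirillum",
            "Nitrosomonas", "Streptomyces", "Bacillus", "Flavobacterium")
  d$taxa <- d$taxa[d$taxa$genus %in% keep, ]
  d
}
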