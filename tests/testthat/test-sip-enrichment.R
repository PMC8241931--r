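# Relative-abundance conversion, class means, fold ratios, autotroph
# detection and the dual two-fold classifier.

simple_meta <- function(keys) data.frame(
  sample_key = keys, isotope = NA, compartment = NA, fraction_class = NA,
  replicate = NA, stringsAsFactors = FALSE)

test_that("to_relative_abundance filters singletons and plastids, then renormalizes", {
  counts <- rbind(A = c(3, 2), B = c(1, 0), Chloroplast = c(50, 80))
  colnames(counts) <- c("s1", "s2")
  tab <- to_relative_abundance(counts, simple_meta(colnames(counts)))
  expect_identical(rownames(tab$values), "A")
  expect_equal(unname(tab$values["A", ]), c(1, 1))
  expect_setequal(attr(tab, "dropped"), c("B", "Chloroplast"))
  # plain normalization
  counts2 <- rbind(A = c(25), B = c(75)); colnames(counts2) <- "s1"
  tab2 <- to_relative_abundance(counts2, simple_meta("s1"),
                                drop_singletons = FALSE, drop_plastid = FALSE)
  expect_equal(unname(tab2$values[, 1]), c(0.25, 0.75))
  # filters off: identical genus set in and out
  tab3 <- to_relative_abundance(counts, simple_meta(colnames(counts)),
                                drop_singletons = FALSE, drop_plastid = FALSE)
  expect_identical(rownames(tab3$values), rownames(counts))
  # a sample emptied by filtering is an error naming the sample
  counts4 <- rbind(A = c(5, 0), B = c(0, 1)); colnames(counts4) <- c("s1", "s2")
  expect_error(to_relative_abundance(counts4, simple_meta(colnames(counts4))),
               "s2")
})

class_tab <- function(vals_by_class, genera = paste0("g", seq_len(nrow(vals_by_class[[1]]))),
                      compartment = "rhizosphere") {
  cols <- list(); meta <- list()
  for (cl in names(vals_by_class)) {
    iso <- substr(cl, 1, 3); fc <- substr(cl, 4, 4)
    m <- vals_by_class[[cl]]
    for (r in seq_len(ncol(m))) {
      sk <- paste(iso, compartment, r, fc, sep = "_")
      cols[[sk]] <- m[, r] / sum(m[, r])
      meta[[sk]] <- data.frame(sample_key = sk, isotope = iso,
                               compartment = compartment, fraction_class = fc,
                               replicate = as.character(r),
                               stringsAsFactors = FALSE)
    }
  }
  v <- do.call(cbind, cols); rownames(v) <- genera
  sip_abundance(v, do.call(rbind, meta))
}

test_that("mean_class_abundance averages replicates and reports SE correctly", {
  m <- cbind(c(0.06, 0.94), c(0.09, 0.91), c(0.1089, 0.8911))
  tab <- class_tab(list(`13CH` = m))
  r <- mean_class_abundance(tab, "g1", "13C", "H")
  expect_equal(r$mean, 0.0863)           # replicates averaging to 8.63%
  expect_equal(r$se, sd(m[1, ]) / sqrt(3))
  # single pooled sample: mean passes through, SE absent
  tab1 <- class_tab(list(`13CH` = cbind(c(0.2642, 0.7358))),
                    compartment = "endosphere")
  r1 <- mean_class_abundance(tab1, "g1", "13C", "H")
  expect_equal(r1$mean, 0.2642)
  expect_true(is.na(r1$se))
  # equal replicates: SE exactly 0
  tab2 <- class_tab(list(`13CH` = cbind(c(0.3, 0.7), c(0.3, 0.7))))
  expect_equal(mean_class_abundance(tab2, "g1", "13C", "H")$se, 0)
  expect_error(mean_class_abundance(tab, "nope", "13C", "H"), "unknown genus")
  expect_error(mean_class_abundance(tab, "g1", "12C", "H"), "match")
})

test_that("fold_enrichment reproduces the printed integer folds", {
  # Shinella, endosphere: 13CH 26.42% vs 13CL 0.68% and 12CH 1.14%
  expect_equal(fold_enrichment(26.42, 0.68)$printed_fold, 38)
  expect_equal(fold_enrichment(26.42, 0.68)$ratio, 26.42 / 0.68)
  expect_equal(fold_enrichment(26.42, 1.14)$printed_fold, 23)
  # Pseudomonas: endosphere 13CH 15.64% vs 13CL 0.59%; rhizosphere 13CH
  # 8.63% vs 12CH 0.37%
  expect_equal(fold_enrichment(15.64, 0.59)$printed_fold, 26)
  expect_equal(fold_enrichment(8.63, 0.37)$printed_fold, 23)
  # zero denominator falls back to the pseudo floor and is flagged
  z <- fold_enrichment(0.5, 0, pseudo = 1e-6)
  expect_equal(z$ratio, 0.5e6)
  expect_true(z$pseudo_used)
  expect_false(fold_enrichment(1, 0.5)$pseudo_used)
})

test_that("detect_autotrophs flags control-enriched genera only", {
  h <- cbind(c(0.30, 0.35, 0.35), c(0.32, 0.34, 0.34))
  l <- cbind(c(0.10, 0.45, 0.45), c(0.12, 0.44, 0.44))
  tab <- class_tab(list(`13CH` = h, `13CL` = l),
                   genera = c("Nitro", "By1", "By2"),
                   compartment = "unplanted_control")
  res <- detect_autotrophs(tab)
  expect_identical(autotroph_set(res), "Nitro")  # ratio ~2.8 vs ~0.77
  # bystander with equal H/L abundance: ratio ~ 1, not flagged
  expect_false(res$autotroph[res$genus == "By1"])
  # infinite threshold: empty set
  expect_length(autotroph_set(detect_autotrophs(tab, threshold = Inf)), 0)
  # missing controls must error, never silently skip
  planted <- class_tab(list(`13CH` = h, `13CL` = l))
  expect_error(detect_autotrophs(planted), "control")
  h_only <- class_tab(list(`13CH` = h), compartment = "unplanted_control")
  expect_error(detect_autotrophs(h_only), "H and L")
})

test_that("simulated autotrophs are detected from unplanted controls", {
  e <- simulate_sip_experiment(design = default_community_design(a_label = 0.7),
                               seed = 5, cfu_design = NULL)
  a <- analyze_sip_experiment(e, n_permutations = 0)
  autos <- autotroph_set(a$autotrophs)
  true_autos <- e$truth$genus[e$truth$role == "autotroph"]
  expect_true(all(true_autos %in% autos))
})

test_that("classifier applies the dual two-fold rule and autotroph veto", {
  tab <- class_tab(list(
    `13CH` = cbind(c(0.08, 0.03, 0.89), c(0.08, 0.03, 0.89)),
    `13CL` = cbind(c(0.01, 0.01, 0.98), c(0.01, 0.01, 0.98)),
    `12CH` = cbind(c(0.01, 0.02, 0.97), c(0.01, 0.02, 0.97))),
    genera = c("gA", "gB", "gC"))
  rep1 <- classify_labeled_genera(tab)
  expect_true(rep1$labeled[rep1$genus == "gA"])      # 8x and 8x
  expect_false(rep1$labeled[rep1$genus == "gB"])     # 3x but only 1.5x vs 12CH
  expect_false(rep1$labeled[rep1$genus == "gC"])
  # every genus gets a record, sorted by 13CH/12CH fold descending
  expect_setequal(rep1$genus, c("gA", "gB", "gC"))
  expect_true(all(diff(rep1$fold_13CH_vs_12CH) <= 0))
  # same abundances but autotroph-flagged: vetoed, flag reported
  rep2 <- classify_labeled_genera(tab, autotrophs = "gA")
  expect_false(rep2$labeled[rep2$genus == "gA"])
  expect_true(rep2$autotroph[rep2$genus == "gA"])
  # missing class errors
  tab_noctl <- class_tab(list(
    `13CH` = cbind(c(0.5, 0.5)), `13CL` = cbind(c(0.5, 0.5))),
    genera = c("gA", "gB"))
  expect_error(classify_labeled_genera(tab_noctl), "12CH")
})

test_that("classification is monotone in threshold and always vetoes autotrophs", {
  for (s in 1:20) {
    tab <- random_class_table(n_genera = 8, seed = s)
    autos <- rownames(tab$values)[1:2]
    prev <- NULL
    for (thr in c(1, 1.5, 2, 4, 8, 1e6)) {
      rep_t <- classify_labeled_genera(tab, autos, threshold = thr)
      labeled <- sort(rep_t$genus[rep_t$labeled])
      expect_length(intersect(labeled, autos), 0)
      if (!is.null(prev)) expect_true(all(labeled %in% prev))
      prev <- labeled
    }
  }
})

test_that("classifier matches the brute-force rule oracle", {
  for (s in 1:50) {
    n <- sample(2:10, 1)
    tab <- random_class_table(n_genera = n, seed = 1000 + s)
    autos <- sample(rownames(tab$values), sample(0:n, 1))
    rep_t <- classify_labeled_genera(tab, autos)
    oracle <- brute_force_labeled(tab, autos)
    expect_identical(setNames(rep_t$labeled, rep_t$genus)[names(oracle)],
                     oracle)
  }
})

test_that("compare_compartments is exact set algebra", {
  ov <- compare_compartments(c("A", "B", "C"), c("B", "C", "D"))
  expect_identical(ov$both, c("B", "C"))
  expect_identical(ov$rhizosphere_only, "A")
  expect_identical(ov$endosphere_only, "D")
  expect_equal(length(ov$both) + length(ov$rhizosphere_only),
               length(ov$labeled_rhizosphere))
  expect_length(compare_compartments(c("A"), c("B"))$both, 0)
  ident <- compare_compartments(c("X", "Y"), c("X", "Y"))
  expect_length(ident$rhizosphere_only, 0)
  expect_length(ident$endosphere_only, 0)
})
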