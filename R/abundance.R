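# AbundanceTable: genus x sample relative abundances keyed by
# (isotope, compartment, fraction class, replicate).

#' Construct an abundance table
#'
#' @param values genus x sample matrix of relative abundances; every column
#'   must sum to 1 (tolerance 1e-9) with no negative entries.
#' @param meta data.frame with one row per column of `values`: sample_key,
#'   isotope (`12C`/`13C` or `NA`), compartment, fraction_class (`H`/`L` or
#'   `NA`), replicate (integer or `"pooled"`).
#' @return object of class `sip_abundance`.
#' @export
sip_abundance <- function(values, meta) {
  stopifnot(is.matrix(values), nrow(meta) == ncol(values),
            all(c("sample_key", "isotope", "compartment", "fraction_class",
                  "replicate") %in% names(meta)))
  if (any(values < 0)) stop("relative abundances must be non-negative")
  bad <- abs(colSums(values) - 1) > 1e-9
  if (any(bad))
    stop("sample column(s) do not sum to 1: ",
         paste(meta$sample_key[bad], collapse = ", "))
  colnames(values) <- meta$sample_key
  structure(list(values = values, meta = meta), class = "sip_abundance")
}

#' @export
print.sip_abundance <- function(x, ...) {
  cat("sip_abundance:", nrow(x$values), "genera x", ncol(x$values),
      "samples\n")
  cat("classes:", paste(sort(unique(paste0(x$meta$isotope,
                                           x$meta$fraction_class))),
                        collapse = " "), "\n")
  invisible(x)
}

default_plastid_patterns <- c("chloroplast", "plastid", "mitochond")

#' Convert read counts to relative abundances with standard filters
#'
#' Removes singleton genera (total reads across all samples <= 1) and
#' plastid-like genera (name matching `plastid_patterns`, case-insensitive)
#' before renormalizing each sample column to sum to 1 — the order used in
#' amplicon pipelines, so filtering happens on counts, not proportions.
#' Counts may be non-integer (equal-quantity pooled windows rescale to the
#' window read total).
#'
#' @param counts genus x sample matrix of non-negative counts.
#' @param meta sample metadata, see [sip_abundance()]. If omitted, a skeleton
#'   is built from the column names.
#' @param drop_singletons,drop_plastid logical filter switches.
#' @param plastid_patterns regexes marking plastid-like genera.
#' @return a `sip_abundance`; attribute `dropped` lists removed genera.
#' @export
to_relative_abundance <- function(counts, meta = NULL, drop_singletons = TRUE,
                                  drop_plastid = TRUE,
                                  plastid_patterns = default_plastid_patterns) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(meta))
    meta <- data.frame(sample_key = colnames(counts), isotope = NA,
                       compartment = NA, fraction_class = NA, replicate = NA,
                       stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(counts))
  if (drop_singletons) keep <- keep & rowSums(counts) > 1
  if (drop_plastid) {
    plastid <- Reduce(`|`, lapply(plastid_patterns, grepl,
                                  x = rownames(counts), ignore.case = TRUE))
    keep <- keep & !plastid
  }
  dropped <- rownames(counts)[!keep]
  counts <- counts[keep, , drop = FALSE]
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero reads after filtering: ",
         paste(meta$sample_key[totals == 0], collapse = ", "))
  tab <- sip_abundance(sweep(counts, 2, totals, "/"), meta)
  attr(tab, "dropped") <- dropped
  tab
}

match_class <- function(tab, isotope = NULL, fraction_class = NULL,
                        compartment = NULL) {
  m <- tab$meta
  sel <- rep(TRUE, nrow(m))
  if (!is.null(isotope)) sel <- sel & m$isotope %in% isotope
  if (!is.null(fraction_class)) sel <- sel & m$fraction_class %in% fraction_class
  if (!is.null(compartment)) sel <- sel & m$compartment %in% compartment
  which(sel)
}

#' Subset an abundance table by sample class
#'
#' @param tab a `sip_abundance`.
#' @param isotope,fraction_class,compartment optional class filters; `NULL`
#'   matches everything.
#' @return a `sip_abundance` over the matching samples.
#' @export
subset_samples <- function(tab, isotope = NULL, fraction_class = NULL,
                           compartment = NULL) {
  cols <- match_class(tab, isotope, fraction_class, compartment)
  if (!length(cols)) stop("no samples match the requested class")
  sip_abundance(tab$values[, cols, drop = FALSE], tab$meta[cols, , drop = FALSE])
}

#' Mean (and standard error) relative abundance of a genus in a sample class
#'
#' Arithmetic mean over the replicate samples matching the class; the
#' standard error is sd/sqrt(n) and is reported as `NA` for single (pooled)
#' samples, where replication does not exist.
#'
#' @param tab a `sip_abundance`.
#' @param genus genus (row) name.
#' @param isotope,fraction_class,compartment class selectors.
#' @return list with `mean`, `se`, `n`.
#' @export
mean_class_abundance <- function(tab, genus, isotope, fraction_class,
                                 compartment = NULL) {
  if (!genus %in% rownames(tab$values)) stop("unknown genus: ", genus)
  cols <- match_class(tab, isotope, fraction_class, compartment)
  if (!length(cols))
    stop("no samples match class ", isotope, fraction_class,
         if (!is.null(compartment)) paste0(" in ", compartment))
  x <- tab$values[genus, cols]
  list(mean = mean(x),
       se = if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_,
       n = length(x))
}
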