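# Tab-delimited readers/writers for the pipeline's external interfaces.
# Gradient fraction samples are keyed `<isotope>_<compartment>_<rep>_F<index>`
# (compartment names may themselves contain underscores, so keys are parsed
# from both ends).

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- cbind(setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                        rownames_as),
               as.data.frame(x, stringsAsFactors = FALSE))
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-fraction gradient tables for an experiment
#'
#' Emits the external-format tables: a genus x fraction-sample count table
#' (`counts.tsv`), fraction metadata (`meta.tsv`: sample_key,
#' density_g_per_ml, copies_per_ul), and — in synthetic mode — the taxon
#' truth table (`truth.tsv`) used by test oracles.
#'
#' @param experiment a `sip_experiment`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_experiment_tables <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list(); meta <- list()
  for (run in experiment$runs) {
    gcounts <- run_genus_counts(run, experiment$taxa)
    for (f in seq_len(ncol(gcounts))) {
      sk <- paste(run$isotope, run$compartment, run$replicate,
                  sprintf("F%02d", run$fractions$fraction_index[f]), sep = "_")
      counts[[sk]] <- gcounts[, f]
      meta[[sk]] <- data.frame(sample_key = sk,
                               density_g_per_ml = run$fractions$density[f],
                               copies_per_ul = run$fractions$copies[f],
                               stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(cbind, counts)
  colnames(mat) <- names(counts)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             meta = file.path(dir, "meta.tsv"))
  write_tsv(mat, paths["counts"], rownames_as = "genus")
  write_tsv(do.call(rbind, meta), paths["meta"])
  if (!is.null(experiment$truth)) {
    paths["truth"] <- file.path(dir, "truth.tsv")
    write_tsv(experiment$truth, paths["truth"])
  }
  if (!is.null(experiment$cfu)) {
    paths["cfu"] <- file.path(dir, "cfu.tsv")
    write_tsv(as.data.frame(experiment$cfu), paths["cfu"])
  }
  invisible(paths)
}

parse_sample_key <- function(keys) {
  parts <- strsplit(keys, "_", fixed = TRUE)
  bad <- lengths(parts) < 4L
  if (any(bad)) stop("malformed sample key(s): ",
                     paste(keys[bad], collapse = ", "))
  do.call(rbind, lapply(parts, function(p) {
    n <- length(p)
    data.frame(isotope = p[1],
               compartment = paste(p[2:(n - 2)], collapse = "_"),
               replicate = p[n - 1], fraction = p[n],
               stringsAsFactors = FALSE)
  }))
}

#' Read per-fraction count and metadata tables back into gradient runs
#'
#' Inverse of [write_experiment_tables()]: reconstructs one run per
#' (isotope, compartment, replicate), with fraction densities and copies from
#' the metadata table. When a qPCR CT table and a dilution-series table are
#' supplied, copies are recomputed from CT values via [fit_standard_curve()]
#' and [ct_to_copies()] (replicate CT values are averaged per sample key)
#' instead of being taken from the metadata.
#'
#' @param counts_path genus x fraction-sample TSV (first column `genus`).
#' @param meta_path fraction metadata TSV (sample_key, density_g_per_ml,
#'   copies_per_ul).
#' @param qpcr_path optional qPCR TSV (sample_key, ct, replicate).
#' @param standards_path optional dilution-series TSV (log10_copies, ct);
#'   required if `qpcr_path` is given.
#' @return list with `runs` (compatible with [pool_experiment()]), `taxa`
#'   (genus-level skeleton), and `curve` (the standard curve, if fitted).
#' @export
read_experiment_tables <- function(counts_path, meta_path, qpcr_path = NULL,
                                   standards_path = NULL) {
  counts_df <- read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(mat) <- counts_df[[1]]
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  need <- c("sample_key", "density_g_per_ml", "copies_per_ul")
  if (!all(need %in% names(meta)))
    stop("fraction metadata must have columns: ", paste(need, collapse = ", "))
  if (!all(colnames(mat) %in% meta$sample_key))
    stop("count columns missing from fraction metadata: ",
         paste(setdiff(colnames(mat), meta$sample_key), collapse = ", "))
  meta <- meta[match(colnames(mat), meta$sample_key), ]

  curve <- NULL
  if (!is.null(qpcr_path)) {
    if (is.null(standards_path))
      stop("qPCR table given without a standards dilution series")
    std <- read.delim(standards_path, stringsAsFactors = FALSE)
    curve <- fit_standard_curve(std)
    qpcr <- read.delim(qpcr_path, stringsAsFactors = FALSE)
    mean_ct <- tapply(qpcr$ct, qpcr$sample_key, mean)
    missing <- setdiff(meta$sample_key, names(mean_ct))
    if (length(missing))
      stop("qPCR table lacks sample key(s): ", paste(missing, collapse = ", "))
    meta$copies_per_ul <- as.numeric(ct_to_copies(curve,
                                                  mean_ct[meta$sample_key]))
  }

  key_info <- parse_sample_key(meta$sample_key)
  grp <- paste(key_info$isotope, key_info$compartment, key_info$replicate,
               sep = "_")
  runs <- list()
  for (g in unique(grp)) {
    ix <- which(grp == g)
    ord <- ix[order(meta$density_g_per_ml[ix], decreasing = TRUE)]
    info <- key_info[ord[1], ]
    runs[[g]] <- structure(list(
      isotope = info$isotope, compartment = info$compartment,
      replicate = info$replicate,
      fractions = data.frame(fraction_index = seq_along(ord),
                             density = meta$density_g_per_ml[ord],
                             copies = meta$copies_per_ul[ord]),
      counts = {
        cm <- mat[, ord, drop = FALSE]
        colnames(cm) <- sprintf("F%02d", seq_along(ord))
        cm
      }), class = "sip_gradient_run")
  }
  taxa <- data.frame(taxon_id = rownames(mat), genus = rownames(mat),
                     stringsAsFactors = FALSE)
  list(runs = runs, taxa = taxa, curve = curve)
}

#' Read a CFU table from a comma- or tab-delimited file
#'
#' @param path file path; the delimiter is sniffed from the header line.
#' @return data.frame in the layout expected by [cfu_table_to_per_gram()].
#' @export
read_cfu_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE)
}
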