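# The paper-style SIP enrichment rule: a genus is called a root-exudate
# metabolizer ("labeled") when its mean relative abundance in the 13C heavy
# fraction is at least `threshold`-fold that of BOTH the 13C light fraction
# and the 12C heavy fraction, and it is not flagged as an autotroph from the
# unplanted 13CO2 controls.

#' Fold enrichment between two mean relative abundances
#'
#' Ratio-of-means convention (means are computed first, then one ratio),
#' which is the only convention compatible with single pooled samples. The
#' denominator is floored at `pseudo` to guard zeros; `printed_fold` is the
#' truncated (floor) integer fold, the convention that reproduces the
#' published integer fold changes.
#'
#' @param mean_num,mean_den mean relative abundances (>= 0); any common scale
#'   (fractions or percent) as long as both sides share it.
#' @param pseudo denominator floor; default 1e-6.
#' @return list: `ratio`, `printed_fold`, `pseudo_used`.
#' @examples
#' fold_enrichment(26.42, 0.68)$printed_fold  # 38
#' @export
fold_enrichment <- function(mean_num, mean_den, pseudo = 1e-6) {
  stopifnot(mean_num >= 0, mean_den >= 0, pseudo > 0)
  pseudo_used <- mean_den < pseudo
  ratio <- mean_num / max(mean_den, pseudo)
  list(ratio = ratio, printed_fold = floor(ratio), pseudo_used = pseudo_used)
}

#' Detect putative autotrophs from unplanted \eqn{^{13}}CO\eqn{_2} controls
#'
#' A genus enriched in the heavy versus light fractions of the unplanted
#' control gradients can fix CO\eqn{_2} directly and must not be credited
#' with exudate metabolism. The control table must contain both H and L
#' classes — this filter is mandatory, never silently skipped.
#'
#' @param control_tab a `sip_abundance`; only samples with compartment
#'   `unplanted_control` and isotope `13C` are used (an error if absent).
#' @param threshold H/L ratio at or above which a genus is flagged; default
#'   reuses the main two-fold threshold.
#' @param pseudo denominator floor, see [fold_enrichment()].
#' @return data.frame of class `sip_autotrophs` (genus, mean_H, mean_L,
#'   ratio, autotroph) for audit; use [autotroph_set()] for the genus set.
#' @export
detect_autotrophs <- function(control_tab, threshold = 2.0, pseudo = 1e-6) {
  stopifnot(inherits(control_tab, "sip_abundance"))
  ctrl_cols <- match_class(control_tab, isotope = "13C",
                           compartment = "unplanted_control")
  if (!length(ctrl_cols))
    stop("no unplanted 13C control samples present; the autotroph filter ",
         "cannot be skipped")
  ctrl <- sip_abundance(control_tab$values[, ctrl_cols, drop = FALSE],
                        control_tab$meta[ctrl_cols, , drop = FALSE])
  h <- match_class(ctrl, fraction_class = "H")
  l <- match_class(ctrl, fraction_class = "L")
  if (!length(h) || !length(l))
    stop("unplanted control must contain both H and L fraction classes")
  mean_h <- rowMeans(ctrl$values[, h, drop = FALSE])
  mean_l <- rowMeans(ctrl$values[, l, drop = FALSE])
  ratio <- mean_h / pmax(mean_l, pseudo)
  out <- data.frame(genus = rownames(ctrl$values), mean_H = mean_h,
                    mean_L = mean_l, ratio = ratio,
                    autotroph = ratio >= threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("sip_autotrophs", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Extract the autotroph genus set
#'
#' @param autotrophs a [detect_autotrophs()] result, or a character vector
#'   (returned as-is).
#' @return character vector of flagged genera.
#' @export
autotroph_set <- function(autotrophs) {
  if (is.character(autotrophs)) return(autotrophs)
  stopifnot(inherits(autotrophs, "sip_autotrophs"))
  autotrophs$genus[autotrophs$autotroph]
}

#' Classify labeled (root-exudate-metabolizing) genera in one compartment
#'
#' Every genus in the table receives a record: mean relative abundances
#' (with standard errors where replicated) in the 13CH, 13CL and 12CH
#' classes, both fold ratios with printed (floored) folds, the autotroph
#' flag, and the labeled verdict
#' `fold(13CH/13CL) >= threshold & fold(13CH/12CH) >= threshold & !autotroph`.
#' Records are sorted by the 13CH/12CH ratio, descending — the ordering used
#' for "greatest overall enrichment" summaries.
#'
#' @param tab a `sip_abundance` restricted to one planted compartment, with
#'   13CH, 13CL and 12CH classes present.
#' @param autotrophs autotroph genus set (character) or a
#'   [detect_autotrophs()] result.
#' @param threshold fold threshold; `>= threshold` qualifies ("two-fold or
#'   more"); default 2.
#' @param pseudo denominator floor, see [fold_enrichment()].
#' @return data.frame of class `sip_enrichment_report` with one row per
#'   genus; attributes `compartment`, `threshold`.
#' @export
classify_labeled_genera <- function(tab, autotrophs = character(),
                                    threshold = 2.0, pseudo = 1e-6) {
  stopifnot(inherits(tab, "sip_abundance"))
  comp <- unique(tab$meta$compartment)
  if (length(comp) != 1L)
    stop("table must be restricted to a single compartment; got: ",
         paste(comp, collapse = ", "))
  for (cls in list(c("13C", "H"), c("13C", "L"), c("12C", "H"))) {
    if (!length(match_class(tab, isotope = cls[1], fraction_class = cls[2])))
      stop("missing sample class ", cls[1], cls[2], " in compartment ", comp)
  }
  auto <- autotroph_set(autotrophs)
  genera <- rownames(tab$values)
  cls_stat <- function(g, iso, fc) mean_class_abundance(tab, g, iso, fc)
  rec <- lapply(genera, function(g) {
    s13h <- cls_stat(g, "13C", "H"); s13l <- cls_stat(g, "13C", "L")
    s12h <- cls_stat(g, "12C", "H")
    f1 <- fold_enrichment(s13h$mean, s13l$mean, pseudo)
    f2 <- fold_enrichment(s13h$mean, s12h$mean, pseudo)
    is_auto <- g %in% auto
    data.frame(genus = g,
               mean_13CH = s13h$mean, se_13CH = s13h$se,
               mean_13CL = s13l$mean, se_13CL = s13l$se,
               mean_12CH = s12h$mean, se_12CH = s12h$se,
               fold_13CH_vs_13CL = f1$ratio, printed_fold_13CH_vs_13CL = f1$printed_fold,
               fold_13CH_vs_12CH = f2$ratio, printed_fold_13CH_vs_12CH = f2$printed_fold,
               pseudo_used = f1$pseudo_used || f2$pseudo_used,
               autotroph = is_auto,
               labeled = f1$ratio >= threshold && f2$ratio >= threshold && !is_auto,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  out <- out[order(-out$fold_13CH_vs_12CH), ]
  rownames(out) <- NULL
  class(out) <- c("sip_enrichment_report", "data.frame")
  attr(out, "compartment") <- comp
  attr(out, "threshold") <- threshold
  out
}

#' Compare labeled genus sets between two compartments
#'
#' Exact set algebra over the labeled genera of two enrichment reports
#' (typically rhizosphere and endosphere): the shared set and the
#' compartment-exclusive sets.
#'
#' @param rhizo,endo `sip_enrichment_report`s (or plain character vectors of
#'   labeled genera) over the same genus universe.
#' @return list of class `sip_overlap`: labeled_rhizosphere,
#'   labeled_endosphere, both, rhizosphere_only, endosphere_only.
#' @export
compare_compartments <- function(rhizo, endo) {
  lab <- function(x) if (is.character(x)) x else {
    stopifnot(inherits(x, "sip_enrichment_report")); x$genus[x$labeled]
  }
  uni <- function(x) if (is.character(x)) x else x$genus
  if (!is.character(rhizo) && !is.character(endo) &&
      !setequal(uni(rhizo), uni(endo)))
    warning("reports cover different genus universes; overlap computed on ",
            "the labeled sets as given")
  r <- lab(rhizo); e <- lab(endo)
  structure(list(labeled_rhizosphere = sort(r), labeled_endosphere = sort(e),
                 both = sort(intersect(r, e)),
                 rhizosphere_only = sort(setdiff(r, e)),
                 endosphere_only = sort(setdiff(e, r))),
            class = "sip_overlap")
}

#' @export
print.sip_overlap <- function(x, ...) {
  cat("labeled in rhizosphere:", length(x$labeled_rhizosphere),
      "| endosphere:", length(x$labeled_endosphere),
      "| both:", length(x$both), "\n")
  invisible(x)
}
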