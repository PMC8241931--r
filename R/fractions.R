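# Heavy/light fraction window selection and equal-quantity pooling.

as_fraction_table <- function(run) {
  fr <- if (is.data.frame(run)) run else run$fractions
  stopifnot(is.data.frame(fr),
            all(c("fraction_index", "density", "copies") %in% names(fr)))
  if (anyDuplicated(fr$fraction_index))
    stop("fraction_index must be unique within a run")
  if (any(fr$copies < 0)) stop("copies must be non-negative")
  fr
}

#' Select heavy and light fraction windows from a copy-number profile
#'
#' Formalizes the "fractions spanning the peaks" judgment. The light window
#' is the contiguous block of fractions around the main (unlabeled) peak of
#' the 16S copy-number profile whose copies exceed `background_fraction`
#' times the peak; the heavy window is the contiguous block at density at
#' least `delta_density` above the peak density whose copies exceed the same
#' background floor (the block with the most copies, if several qualify).
#'
#' By default the light window is anchored at the global copy-number maximum,
#' which is correct whenever unlabeled DNA dominates the gradient. When it
#' does not (e.g. a heavily labeled community), supply `light_anchor`, the
#' expected unlabeled buoyant density — from a paired \eqn{^{12}}C gradient
#' peak or from known GC content — and the windows are placed relative to it.
#' `heavy_ids`/`light_ids` override the rule entirely (manual windows).
#'
#' @param run a `sip_gradient_run` or a data.frame with columns
#'   fraction_index, density, copies (>= 4 fractions).
#' @param delta_density minimum density offset (g/mL) separating the heavy
#'   window from the light peak; default 0.015.
#' @param background_fraction copies floor as a fraction of the peak copies;
#'   default 0.05.
#' @param light_anchor optional reference density (g/mL) of unlabeled DNA.
#' @param heavy_ids,light_ids optional manual windows (fraction_index values).
#' @return list of class `sip_fraction_partition`: `heavy_ids`, `light_ids`
#'   and `diagnostics` (peak density, threshold, rule used). Every heavy
#'   fraction is denser than every light fraction.
#' @export
select_heavy_light <- function(run, delta_density = 0.015,
                               background_fraction = 0.05,
                               light_anchor = NULL,
                               heavy_ids = NULL, light_ids = NULL) {
  fr <- as_fraction_table(run)
  make_partition <- function(heavy, light, diag) {
    heavy <- sort(heavy); light <- sort(light)
    if (!length(heavy) || !length(light))
      stop("both heavy and light windows must be non-empty")
    if (length(intersect(heavy, light)))
      stop("heavy and light windows overlap")
    dh <- fr$density[match(heavy, fr$fraction_index)]
    dl <- fr$density[match(light, fr$fraction_index)]
    if (min(dh) <= max(dl))
      stop("every heavy fraction must be denser than every light fraction")
    structure(list(heavy_ids = heavy, light_ids = light, diagnostics = diag),
              class = "sip_fraction_partition")
  }
  if (!is.null(heavy_ids) || !is.null(light_ids)) {
    if (is.null(heavy_ids) || is.null(light_ids))
      stop("manual override requires both heavy_ids and light_ids")
    return(make_partition(heavy_ids, light_ids, list(rule = "manual")))
  }
  if (nrow(fr) < 4L) stop("need >= 4 fractions to select windows")
  fr <- fr[order(fr$density), ]
  if (diff(range(fr$copies)) == 0)
    stop("copy-number profile is flat: no peak to anchor windows; ",
         "supply heavy_ids/light_ids manually")
  peak_copies <- max(fr$copies)
  floor_copies <- background_fraction * peak_copies
  anchor_i <- if (is.null(light_anchor)) which.max(fr$copies)
              else which.min(abs(fr$density - light_anchor))
  thr <- fr$density[anchor_i] + delta_density

  # light: contiguous block containing the anchor, below the density
  # threshold and above the background floor (the anchor bin is always kept)
  light_ok <- fr$density < thr & (fr$copies >= floor_copies |
                                    seq_len(nrow(fr)) == anchor_i)
  light_sel <- contiguous_block(light_ok, anchor_i)

  heavy_ok <- fr$density >= thr & fr$copies >= floor_copies
  if (!any(heavy_ok))
    stop("no fraction qualifies as heavy (density >= ", round(thr, 4),
         " g/mL with copies above the background floor); supply ",
         "heavy_ids/light_ids manually")
  runs <- split(which(heavy_ok), cumsum(c(1, diff(which(heavy_ok)) != 1)))
  totals <- vapply(runs, function(ix) sum(fr$copies[ix]), 0)
  heavy_sel <- runs[[which.max(totals)]]

  make_partition(fr$fraction_index[heavy_sel], fr$fraction_index[light_sel],
                 list(rule = "peak_offset",
                      peak_density = fr$density[anchor_i],
                      density_threshold = thr,
                      background_floor = floor_copies,
                      anchored = !is.null(light_anchor)))
}

contiguous_block <- function(ok, center) {
  lo <- center
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- center
  while (hi < length(ok) && ok[hi + 1L]) hi <- hi + 1L
  lo:hi
}

#' Pool gradient fractions into heavy and light counts by equal quantity
#'
#' "Equal quantities" of DNA combined per window means each fraction
#' contributes the same DNA mass, so the pooled composition is the arithmetic
#' mean of the within-fraction relative abundances; the pooled composition is
#' then rescaled to the window's total read count. Fractions with zero reads
#' carry no compositional information and are skipped (an all-zero window is
#' an error).
#'
#' @param run a `sip_gradient_run`, or a list with elements `counts`
#'   (genus x fraction matrix, columns ordered as `fractions$fraction_index`)
#'   and `fractions`.
#' @param partition a [select_heavy_light()] result valid for `run`.
#' @return list with `counts_H` and `counts_L`, named numeric vectors over
#'   genera (non-integer in general).
#' @export
pool_fractions <- function(run, partition) {
  stopifnot(inherits(partition, "sip_fraction_partition"))
  fr <- as_fraction_table(run)
  counts <- run$counts
  if (is.null(counts)) stop("run carries no per-fraction counts")
  pool_one <- function(ids, label) {
    cols <- match(ids, fr$fraction_index)
    if (anyNA(cols)) stop("partition refers to unknown fractions: ",
                          paste(ids[is.na(cols)], collapse = ", "))
    sub <- counts[, cols, drop = FALSE]
    totals <- colSums(sub)
    if (sum(totals) == 0)
      stop(label, " window has zero total reads")
    comp <- sweep(sub[, totals > 0, drop = FALSE], 2, totals[totals > 0], "/")
    rowMeans(comp) * sum(totals)
  }
  list(counts_H = pool_one(partition$heavy_ids, "heavy"),
       counts_L = pool_one(partition$light_ids, "light"))
}
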