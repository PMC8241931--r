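#' Fit a qPCR standard curve
#'
#' Ordinary least squares of threshold cycle on log10 template copies over a
#' dilution series: `CT = slope * log10(copies) + intercept`. Amplification
#' efficiency is `10^(-1/slope) - 1` (1.0 means perfect doubling per cycle,
#' slope -3.3219); a warning is issued outside the conventional 0.8-1.1
#' quality band.
#'
#' @param log10_copies numeric vector of log10 template copy numbers, or a
#'   data.frame with columns `log10_copies` and `ct`.
#' @param ct threshold cycles matching `log10_copies`.
#' @return list of class `sip_standard_curve`: slope, intercept, efficiency,
#'   r_squared and the fitted `range` of log10 copies.
#' @examples
#' fit_standard_curve(5:1, 10 + 3.3219 * (5 - (5:1)))
#' @export
fit_standard_curve <- function(log10_copies, ct = NULL) {
  if (is.data.frame(log10_copies)) {
    ct <- log10_copies$ct
    log10_copies <- log10_copies$log10_copies
  }
  stopifnot(length(log10_copies) == length(ct))
  keep <- is.finite(log10_copies) & is.finite(ct)
  x <- log10_copies[keep]; y <- ct[keep]
  if (length(unique(x)) < 3L)
    stop("standard curve needs >= 3 distinct dilution points")
  if (var(x) == 0) stop("zero variance in log10 copies")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope >= 0)
    stop("standard curve slope must be negative (CT decreasing with copies); ",
         "got ", format(slope))
  efficiency <- 10^(-1 / slope) - 1
  if (efficiency <= 0 || efficiency > 1.2)
    stop("implied amplification efficiency ", round(efficiency, 3),
         " outside (0, 1.2]")
  if (efficiency < 0.8 || efficiency > 1.1)
    warning("amplification efficiency ", round(efficiency, 3),
            " outside the usual 0.8-1.1 band")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = slope, intercept = intercept,
                 efficiency = efficiency, r_squared = r2,
                 range = range(x)),
            class = "sip_standard_curve")
}

#' Convert threshold cycles to template copy numbers
#'
#' `copies = 10^((ct - intercept) / slope)`; strictly decreasing in CT.
#' Values outside the fitted dilution range are extrapolated and flagged in
#' the `extrapolated` attribute.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param ct numeric vector of threshold cycles.
#' @return copy numbers, with logical attribute `extrapolated`.
#' @export
ct_to_copies <- function(curve, ct) {
  stopifnot(inherits(curve, "sip_standard_curve"))
  lg <- (ct - curve$intercept) / curve$slope
  structure(10^lg, extrapolated = lg < curve$range[1] | lg > curve$range[2])
}

#' Inverse of [ct_to_copies()]: expected CT for a copy number
#'
#' Used by the simulator to emit qPCR CT tables from known copy numbers.
#'
#' @param curve a `sip_standard_curve`.
#' @param copies template copy numbers (> 0).
#' @return threshold cycles.
#' @export
copies_to_ct <- function(curve, copies) {
  stopifnot(inherits(curve, "sip_standard_curve"), all(copies > 0))
  curve$slope * log10(copies) + curve$intercept
}
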