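# CFU-based root colonization statistics: cfu/g conversion, two-way ANOVA
# (genotype x strain), Tukey HSD post-hoc comparisons.

#' Colony counts to colony-forming units per gram of root
#'
#' `cfu/g = mean(colonies) * (homogenate_volume / plated_volume) *
#' dilution_factor / root_mass`; replicate plate counts are averaged first.
#'
#' @param colonies colony count(s); a vector is treated as replicate plates.
#' @param plated_volume_ul volume plated per plate (uL).
#' @param homogenate_volume_ul total homogenate volume (uL).
#' @param dilution_factor dilution applied before plating (>= 1).
#' @param root_mass_g root fresh mass (g, > 0).
#' @return cfu per gram of root tissue.
#' @examples
#' cfu_per_gram(50, 100, 1000, 1, 0.1)  # 5000
#' @export
cfu_per_gram <- function(colonies, plated_volume_ul, homogenate_volume_ul,
                         dilution_factor, root_mass_g) {
  stopifnot(all(colonies >= 0), plated_volume_ul > 0,
            homogenate_volume_ul > 0, dilution_factor >= 1)
  if (root_mass_g <= 0) stop("root mass must be positive")
  mean(colonies) * (homogenate_volume_ul / plated_volume_ul) *
    dilution_factor / root_mass_g
}

#' Aggregate a CFU table to one log-transformed value per plant
#'
#' Averages replicate plates per plant, converts to cfu/g and applies
#' `log10(cfu/g + 1)` (the +1 guards plants with zero colonies).
#'
#' @param cfu_table data.frame as produced by [simulate_cfu_dataset()] or
#'   read from file: plant_id, genotype, strain, colonies, plated_volume_ul,
#'   homogenate_volume_ul, dilution_factor, root_mass_g.
#' @return data.frame with one row per plant: plant_id, genotype, strain,
#'   cfu_g, log10_cfu_g.
#' @export
cfu_table_to_per_gram <- function(cfu_table) {
  need <- c("plant_id", "genotype", "strain", "colonies", "plated_volume_ul",
            "homogenate_volume_ul", "dilution_factor", "root_mass_g")
  missing <- setdiff(need, names(cfu_table))
  if (length(missing)) stop("CFU table lacks column(s): ",
                            paste(missing, collapse = ", "))
  by_plant <- split(cfu_table, cfu_table$plant_id)
  out <- do.call(rbind, lapply(by_plant, function(p) {
    cfu <- cfu_per_gram(p$colonies, p$plated_volume_ul[1],
                        p$homogenate_volume_ul[1], p$dilution_factor[1],
                        p$root_mass_g[1])
    data.frame(plant_id = p$plant_id[1], genotype = p$genotype[1],
               strain = p$strain[1], cfu_g = cfu,
               log10_cfu_g = log10(cfu + 1), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-way ANOVA with interaction
#'
#' Sequential (Type-I) sums of squares via [stats::aov()]: main effects of
#' both factors, their interaction, and the residual. With a balanced design
#' (the default study layout) Type-I, II and III coincide; unbalanced data
#' triggers a warning that the sequential decomposition depends on term
#' order. A degenerate response (zero total variance) yields F = 0, p = 1.
#'
#' @param values numeric response (e.g. log10 cfu/g), one per experimental
#'   unit.
#' @param factor_a,factor_b factors (>= 2 levels each, >= 2 replicates per
#'   cell, no empty cells).
#' @return data.frame of class `sip_anova`: term, df, sum_sq, mean_sq, f, p;
#'   attributes `residual_ms`, `residual_df`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("both factors need >= 2 levels")
  cells <- table(a, b)
  if (any(cells == 0L)) stop("empty factor cell(s): design must be complete")
  if (any(cells < 2L)) stop("need >= 2 replicates per cell")
  if (length(unique(as.vector(cells))) > 1L)
    warning("unbalanced design: sequential (Type-I) sums of squares depend ",
            "on term order")
  fit <- aov(values ~ a * b)
  tab <- summary(fit)[[1]]
  term_names <- c("factor_a", "factor_b", "factor_a:factor_b", "Residuals")
  out <- data.frame(term = term_names, df = tab[["Df"]],
                    sum_sq = tab[["Sum Sq"]], mean_sq = tab[["Mean Sq"]],
                    f = tab[["F value"]], p = tab[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  if (sum(out$sum_sq) < 1e-12) {  # all responses identical
    out$f[-nrow(out)] <- 0
    out$p[-nrow(out)] <- 1
  }
  class(out) <- c("sip_anova", "data.frame")
  attr(out, "residual_ms") <- out$mean_sq[nrow(out)]
  attr(out, "residual_df") <- out$df[nrow(out)]
  out
}

#' Tukey's honest significant difference comparisons
#'
#' For each pair of groups, `q = |mean difference| / sqrt(MS_resid/2 *
#' (1/n_i + 1/n_j))` (the Tukey-Kramer standard error, equal to
#' `sqrt(MS_resid / n_h)` with `n_h` the pairwise harmonic mean), with the
#' adjusted p-value from the studentized range distribution with `k` groups
#' and the residual degrees of freedom. The residual mean square defaults to
#' the one-way fit on `group` but can be supplied from a larger model (e.g.
#' the two-way ANOVA residual, as when comparing genotypes with strains in
#' the model).
#'
#' @param values numeric response.
#' @param group grouping factor (>= 2 groups).
#' @param error_ms,error_df residual mean square and degrees of freedom; both
#'   `NULL` (default) uses the one-way decomposition on `group`.
#' @return data.frame of class `sip_tukey`: group_1, group_2, diff, se, q,
#'   p_adj, p_unadjusted (plain pairwise t, for reference).
#' @export
tukey_hsd <- function(values, group, error_ms = NULL, error_df = NULL) {
  g <- factor(group)
  if (nlevels(g) < 2L) stop("Tukey HSD needs >= 2 groups")
  stopifnot(length(values) == length(g))
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  if (is.null(error_ms) != is.null(error_df))
    stop("supply both error_ms and error_df, or neither")
  if (is.null(error_ms)) {
    error_df <- length(values) - nlevels(g)
    if (error_df < 1L) stop("no residual degrees of freedom")
    error_ms <- sum((values - means[g])^2) / error_df
  }
  k <- nlevels(g)
  pairs <- utils::combn(levels(g), 2L)
  out <- do.call(rbind, apply(pairs, 2L, function(pr) {
    d <- means[pr[2]] - means[pr[1]]
    se <- sqrt(error_ms / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    q <- if (se > 0) abs(d) / se else 0
    t_se <- sqrt(error_ms * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    t_stat <- if (t_se > 0) abs(d) / t_se else 0
    data.frame(group_1 = pr[1], group_2 = pr[2], diff = unname(d),
               se = unname(se), q = unname(q),
               p_adj = if (se > 0) ptukey(q, k, error_df, lower.tail = FALSE) else 1,
               p_unadjusted = if (t_se > 0) 2 * pt(-t_stat, error_df) else 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("sip_tukey", "data.frame")
  attr(out, "error_ms") <- error_ms
  attr(out, "error_df") <- error_df
  out
}
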