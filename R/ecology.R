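# Supporting community statistics: Shannon diversity, Bray-Curtis
# dissimilarity, principal coordinates analysis, PERMANOVA.

#' Shannon diversity of a count or abundance vector
#'
#' `H = -sum p_i log(p_i)` over non-zero proportions, natural log by default
#' (the base is exposed because published values differ in convention).
#'
#' @param x non-negative counts or proportions with positive total.
#' @param base logarithm base; default `exp(1)`.
#' @return Shannon index H.
#' @export
shannon <- function(x, base = exp(1)) {
  if (any(x < 0)) stop("negative counts")
  tot <- sum(x)
  if (tot <= 0) stop("total count must be positive")
  p <- x[x > 0] / tot
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity matrix between samples
#'
#' `d(j,k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)` over the genus
#' profiles of each pair of samples.
#'
#' @param x a `sip_abundance`, or a genus x sample matrix (columns are
#'   samples) of non-negative values.
#' @return list of class `sip_dissimilarity` with `sample_keys` and the
#'   symmetric `values` matrix (zero diagonal, entries in `[0, 1]`).
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "sip_abundance")) x$values else x
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  if (any(m < 0)) stop("negative abundances")
  if (any(colSums(m) == 0))
    stop("sample(s) with zero total: ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (j in seq_len(n - 1L)) for (k in (j + 1L):n) {
    d[j, k] <- d[k, j] <- sum(abs(m[, j] - m[, k])) / sum(m[, j] + m[, k])
  }
  structure(list(sample_keys = colnames(m), values = d),
            class = "sip_dissimilarity")
}

as_dissimilarity_matrix <- function(d) {
  m <- if (inherits(d, "sip_dissimilarity")) d$values
       else if (inherits(d, "dist")) as.matrix(d)
       else d
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-12) stop("dissimilarity matrix is not symmetric")
  m
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Eigendecomposition of the double-centered Gower matrix
#' `B = -(I - 11'/n) (D^2/2) (I - 11'/n)`. Axes are ordered by eigenvalue;
#' `variance_explained` divides each positive eigenvalue by the sum of the
#' positive eigenvalues (negative eigenvalues, which arise for non-Euclidean
#' dissimilarities such as Bray-Curtis, are dropped from the denominator; the
#' alternative convention using the sum of absolute values is reported in
#' `diagnostics`). For Euclidean-embeddable matrices, pairwise distances in
#' the full coordinate space reproduce the input.
#'
#' @param d a `sip_dissimilarity`, `dist`, or symmetric matrix.
#' @return list of class `sip_ordination`: `coordinates` (sample x axis),
#'   `variance_explained`, `eigenvalues`, `diagnostics`.
#' @export
pcoa <- function(d) {
  m <- as_dissimilarity_matrix(d)
  n <- nrow(m)
  a <- -m^2 / 2
  b <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  eig <- eigen(b, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-12 & eig$values > 0
  if (!any(pos)) stop("no positive eigenvalues: degenerate configuration")
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(
    coordinates = coords,
    variance_explained = eig$values[pos] / sum(eig$values[pos]),
    eigenvalues = eig$values,
    diagnostics = list(
      n_negative_eigenvalues = sum(eig$values < -max(eig$values) * 1e-12),
      variance_explained_abs = eig$values[pos] / sum(abs(eig$values)),
      note = paste("negative eigenvalues dropped from the",
                   "variance_explained denominator"))
  ), class = "sip_ordination")
}

permanova_stats <- function(d2, groups) {
  n <- nrow(d2)
  lev <- unique(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in lev) {
    ix <- which(groups == g)
    if (length(ix) > 1L)
      ss_within <- ss_within + sum(d2[ix, ix][upper.tri(d2[ix, ix])]) / length(ix)
  }
  ss_among <- ss_total - ss_within
  a <- length(lev)
  f <- (ss_among / (a - 1)) / (ss_within / (n - a))
  list(f = f, r_squared = ss_among / ss_total)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Pseudo-F from among/within sums of squared dissimilarities; the p-value is
#' `(1 + #permuted F >= observed F) / (1 + n_permutations)` under random
#' relabeling. When the observed F exceeds every permutation the label
#' `p_label` reports the resolution bound (e.g. `"< 0.01"` at 99
#' permutations), mirroring the usual reporting convention.
#'
#' @param d a `sip_dissimilarity`, `dist`, or symmetric matrix.
#' @param groups factor/character of group labels, one per sample (>= 2
#'   groups, each non-empty).
#' @param n_permutations number of random permutations; default 999.
#' @param seed integer seed for the permutation stream (`NULL` = current RNG).
#' @return list of class `sip_permanova`: `f`, `r_squared`, `p_value`,
#'   `p_label`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = NULL) {
  m <- as_dissimilarity_matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  if (length(unique(groups)) < 2L)
    stop("PERMANOVA needs >= 2 groups")
  d2 <- m^2
  obs <- permanova_stats(d2, groups)
  exceed <- with_seed_(if (is.null(seed)) NULL else derive_seed(seed, "permanova"),
    function() {
      count <- 0L
      for (i in seq_len(n_permutations)) {
        fp <- permanova_stats(d2, sample(groups))$f
        if (fp >= obs$f - 1e-12) count <- count + 1L
      }
      count
    })
  p <- (1 + exceed) / (1 + n_permutations)
  structure(list(
    f = obs$f, r_squared = obs$r_squared, p_value = p,
    p_label = if (exceed == 0L) sprintf("< %.3g", 1 / (1 + n_permutations))
              else format(p),
    n_permutations = as.integer(n_permutations), seed = seed
  ), class = "sip_permanova")
}

#' @export
print.sip_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: F = %.3f, R2 = %.3f, p %s (%d permutations)\n",
              x$f, x$r_squared,
              if (startsWith(x$p_label, "<")) x$p_label
              else paste("=", x$p_label),
              x$n_permutations))
  invisible(x)
}
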