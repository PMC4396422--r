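#' Euclidean community distance (ECD)
#'
#' Percent deviation of the final community biomass vector from the
#' unperturbed one:
#' `100 * sqrt((E-Eu)^2 + (S-Su)^2) / sqrt(Eu^2 + Su^2)`.
#' ECD is 0 exactly when the perturbed community reaches the unperturbed
#' biomasses, and is invariant to a common rescaling of all biomasses.
#'
#' @param E,S final biomasses of the two species in the perturbed
#'   community, gDW.
#' @param Eu,Su final biomasses in the unperturbed community.
#' @return ECD in percent.
#' @export
ecd <- function(E, S, Eu, Su) {
  if (Eu == 0 && Su == 0)
    stop("ECD undefined: unperturbed community has zero biomass")
  if (any(c(E, S) < 0)) stop("biomasses must be >= 0")
  100 * sqrt((E - Eu)^2 + (S - Su)^2) / sqrt(Eu^2 + Su^2)
}

#' Normalized community composition (%E)
#'
#' Fraction of the focal first species in the perturbed community divided
#' by the unperturbed fraction: `(E/(E+S)) / (Eu/(Eu+Su))`. Equals 1 for
#' the unperturbed community.
#'
#' @inheritParams ecd
#' @return dimensionless normalized composition.
#' @export
normalized_percent_e <- function(E, S, Eu, Su) {
  if (Eu + Su <= 0 || Eu <= 0)
    stop("unperturbed composition undefined")
  if (E + S == 0)
    stop("extinct community: composition undefined")
  (E / (E + S)) / (Eu / (Eu + Su))
}

#' Normalized community biomass (BM)
#'
#' Total perturbed biomass over total unperturbed biomass:
#' `(E+S)/(Eu+Su)`.
#'
#' @inheritParams ecd
#' @return dimensionless normalized biomass.
#' @export
normalized_bm <- function(E, S, Eu, Su) {
  if (Eu + Su <= 0) stop("unperturbed biomass must be positive")
  (E + S) / (Eu + Su)
}

#' Mean-centered Levene test for equality of variances
#'
#' One-way ANOVA on absolute deviations from the group means
#' `Z_ij = |x_ij - mean_i|`:
#' `W = ((N-k)/(k-1)) * sum n_i (Zbar_i - Zbar)^2 / sum sum (Z_ij - Zbar_i)^2`
#' with the p-value from the upper tail of `F(k-1, N-k)`. Unlike an F
#' test on raw variances this does not assume normality; the mean-centered
#' variant (rather than Brown-Forsythe's median centering) is used.
#'
#' @param groups list of two or more numeric vectors, each of length >= 2.
#' @return an object of class `htest` with `statistic` (W), `parameter`
#'   (df1, df2) and `p.value`.
#' @export
levene_mean_centered <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  n_i <- lengths(groups)
  if (any(n_i < 2L)) stop("each group needs at least two values")
  k <- length(groups)
  N <- sum(n_i)
  Z <- lapply(groups, function(g) abs(g - mean(g)))
  zbar_i <- vapply(Z, mean, 0)
  zbar <- sum(n_i * zbar_i) / N
  ss_between <- sum(n_i * (zbar_i - zbar)^2)
  ss_within <- sum(vapply(seq_len(k),
                          function(i) sum((Z[[i]] - zbar_i[i])^2), 0))
  if (ss_within <= 0) {
    ## identical nonzero deviations in every group compare as equal
    ## variances (W = 0); constant groups carry no variance at all
    if (ss_between > 0 || all(unlist(Z) == 0))
      stop("degenerate variance: zero within-group deviation of ",
           "|x - mean|")
    W <- 0
  } else {
    W <- (N - k) / (k - 1) * ss_between / ss_within
  }
  structure(list(statistic = c(W = W),
                 parameter = c(df1 = k - 1, df2 = N - k),
                 p.value = stats::pf(W, k - 1, N - k,
                                     lower.tail = FALSE),
                 method = "mean-centered Levene test",
                 data.name = paste(k, "groups, N =", N)),
            class = "htest")
}

#' Count substantive effects
#'
#' Number of normalized metric values whose deviation from 1 is at least
#' `threshold` (inclusive); with the default 0.01, a knockout is
#' substantive when it changes composition or biomass by >= 1% of the
#' unperturbed value.
#'
#' @param values numeric vector of normalized metrics (1 = unperturbed).
#' @param threshold inclusive fraction, > 0.
#' @return integer count.
#' @export
count_substantive <- function(values, threshold = 0.01) {
  if (threshold <= 0) stop("threshold must be > 0")
  values <- values[!is.na(values)]
  sum(abs(values - 1) >= threshold)
}

#' Cross-condition effect correlation
#'
#' Squared Pearson correlation between the per-mutant values of one
#' metric in two growth conditions.
#'
#' @param x,y equal-length numeric vectors (>= 3 mutants), e.g. a
#'   normalized metric under cooperation and under competition.
#' @return R squared.
#' @export
effect_r2 <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least three paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)^2
}
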