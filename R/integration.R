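#' Eigenvalue variance of a correlation matrix (overall integration)
#'
#' The variance of the eigenvalues of a correlation matrix measures overall
#' phenotypic integration: 0 when all traits are uncorrelated (all
#' eigenvalues equal 1) and n - 1 when all pairwise correlations are +/-1.
#' The population (divide-by-n) variance is used so that the relative index
#' V_eigen/(n - 1) spans \[0, 1\].
#'
#' @param corr correlation matrix.
#' @return list with `v_eigen` and `v_eigen_rel` (= v_eigen/(n - 1)).
#' @export
v_eigen <- function(corr) {
  check_correlation(corr)
  lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  v <- mean((lambda - mean(lambda))^2)
  list(v_eigen = v, v_eigen_rel = v / (ncol(corr) - 1))
}

#' Covariance-ratio (CR) modularity statistic
#'
#' Contrasts between-module covariances with within-module off-diagonal
#' covariances. For a pair of modules with covariance blocks M11, M22
#' (within) and M12 = t(M21) (between), and M11*, M22* the within blocks
#' with zeroed diagonals:
#' * `as_printed`: CR = sqrt( trace(M12 M21) /
#'   sqrt( trace(M11* M11*) + trace(M22* M22*) ) )
#' * `product_denominator`: CR = sqrt( trace(M12 M21) /
#'   sqrt( trace(M11* M11*) * trace(M22* M22*) ) ), the form used in the
#'   covariance-ratio literature, which is invariant to rescaling the whole
#'   covariance matrix (the `as_printed` form scales as c^(1/4) under
#'   covariance scaling by c; results should always name the variant).
#' With more than two modules the unweighted mean over all module pairs is
#' returned. Lower CR indicates stronger modularity.
#'
#' @param cov covariance matrix with trait dimnames.
#' @param partition named vector/list mapping every analyzed trait ID to a
#'   module label; at least 2 modules with at least 2 traits each.
#' @param variant `"as_printed"` (default) or `"product_denominator"`.
#' @return scalar CR, with attribute `pairwise` (per-module-pair values).
#' @export
cr_statistic <- function(cov, partition,
                         variant = c("as_printed", "product_denominator")) {
  variant <- match.arg(variant)
  check_covariance(cov)
  partition <- unlist(partition)
  traits <- colnames(cov)
  if (is.null(traits)) stop("'cov' needs trait IDs as dimnames")
  missing <- setdiff(traits, names(partition))
  if (length(missing))
    stop("traits without a module: ", paste(missing, collapse = ", "))
  partition <- partition[traits]
  mods <- split(traits, partition)
  if (length(mods) < 2L) stop("need at least 2 modules")
  small <- names(mods)[lengths(mods) < 2L]
  if (length(small))
    stop("module(s) with fewer than 2 traits: ",
         paste(small, collapse = ", "))
  pair_cr <- function(a, b) {
    m12 <- cov[a, b, drop = FALSE]
    m11 <- cov[a, a, drop = FALSE]; diag(m11) <- 0
    m22 <- cov[b, b, drop = FALSE]; diag(m22) <- 0
    num <- sum(m12 * m12)                     # trace(M12 %*% t(M12))
    t11 <- sum(m11 * m11)
    t22 <- sum(m22 * m22)
    den <- if (variant == "as_printed") sqrt(t11 + t22) else sqrt(t11 * t22)
    if (den <= 0)
      stop("zero within-module off-diagonal covariance makes the ",
           variant, " denominator 0")
    sqrt(num / den)
  }
  combos <- combn(names(mods), 2L)
  vals <- apply(combos, 2L, function(ab) pair_cr(mods[[ab[1L]]],
                                                 mods[[ab[2L]]]))
  names(vals) <- apply(combos, 2L, paste, collapse = ":")
  out <- mean(vals)
  attr(out, "pairwise") <- vals
  attr(out, "variant") <- variant
  out
}

#' Rank-matched subsampling null for integration/modularity statistics
#'
#' A correlation matrix estimated from few units has few positive
#' eigenvalues and an inflated V_eigen, so an evolutionary matrix of rank
#' n_tips - 1 cannot be compared directly with a mutational matrix built
#' from thousands of lines. This null re-estimates the statistic from
#' `n_subsets` random subsets of `k` mutant lines, with `k` chosen so that
#' the subset matrices match the rank (positive-eigenvalue count) of the
#' evolutionary matrix.
#'
#' @param mutant_table trait table of mutant lines.
#' @param k lines per subset (2 <= k <= lines available).
#' @param n_subsets number of subsets (default 5000).
#' @param statistic `"v_eigen"` (computed from the subset correlation
#'   matrix) or `"cr"` (from the subset covariance matrix).
#' @param partition module assignment, required for `statistic = "cr"`.
#' @param variant CR variant, passed to [cr_statistic()].
#' @param seed optional seed.
#' @return numeric vector of `n_subsets` null statistics.
#' @export
rank_matched_null <- function(mutant_table, k, n_subsets = 5000,
                              statistic = c("v_eigen", "cr"),
                              partition = NULL,
                              variant = "as_printed", seed = NULL) {
  statistic <- match.arg(statistic)
  m <- unclass(mutant_table)
  if (k < 2) stop("k must be at least 2")
  if (k > nrow(m)) stop("k exceeds the number of mutant lines")
  if (statistic == "cr" && is.null(partition))
    stop("'partition' is required for the CR statistic")
  with_seed(seed, {
    vapply(seq_len(n_subsets), function(i) {
      sub <- m[sample(nrow(m), k), , drop = FALSE]
      if (statistic == "v_eigen")
        v_eigen(stats::cor(sub))$v_eigen
      else
        as.numeric(cr_statistic(stats::cov(sub), partition,
                                variant = variant))
    }, numeric(1))
  })
}

#' Empirical two-tailed P-value from a null distribution
#'
#' With q the fraction of null values strictly below the observed
#' statistic, p = 2 * min(q, 1 - q): significance means the observed value
#' falls in either the left or right 2.5% tail of the null. When the
#' observed value lies beyond every null value the resolution of the sample
#' is exhausted and the p-value is reported as the band "< 2/n_null".
#'
#' @param observed scalar statistic.
#' @param null numeric vector of null statistics.
#' @return list with `p`, `q_below` (fraction of null strictly below), and
#'   `report` (printable p, possibly a "<" band).
#' @export
empirical_two_tailed_p <- function(observed, null) {
  if (!length(null)) stop("null distribution is empty")
  q <- mean(null < observed)
  p <- 2 * min(q, 1 - q)
  report <- if (all(null < observed) || all(null > observed))
    paste0("< ", format(2 / length(null))) else format(p)
  list(p = p, q_below = q, report = report)
}
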