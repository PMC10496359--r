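#' Fisher r-to-Z transformation
#'
#' Z = (1/2) * \[ln(1 + r) - ln(1 - r)\] = arctanh(r). Odd and strictly
#' increasing; variance approximately 1/(n - 3) for a Pearson correlation
#' estimated from n observations.
#'
#' @param r correlation(s), strictly inside (-1, 1).
#' @return z-score(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z requires |r| < 1")
  atanh(r)
}

#' Test the difference between an evolutionary and a mutational correlation
#'
#' Z = (Z_E - Z_M) / sqrt(1/(n_E - 3) + 1/(n_M - 3)), where Z_E and Z_M are
#' the Fisher z-scores of COR_E and COR_M, n_E the number of independent
#' contrasts and n_M the number of mutant lines. Under the null of equal
#' population correlations Z is approximately standard normal; the returned
#' p-value is the two-sided normal tail probability.
#'
#' @param cor_e,cor_m correlations, |r| < 1.
#' @param n_e,n_m sample sizes, both > 3.
#' @return list with `z` and `p`.
#' @export
compare_correlations <- function(cor_e, cor_m, n_e, n_m) {
  if (n_e <= 3 || n_m <= 3) stop("both sample sizes must exceed 3")
  z <- (fisher_z(cor_e) - fisher_z(cor_m)) /
    sqrt(1 / (n_e - 3) + 1 / (n_m - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, in the order
#' of the input vector.
#'
#' @param p_values raw p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

# Two-sided p for H0: rho = 0 from the Fisher z statistic arctanh(r)*sqrt(n-3).
cor_nonzero_p <- function(r, n) {
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)) * sqrt(n - 3)
  2 * pnorm(-abs(z))
}

#' Classify a significant COR_E vs COR_M difference
#'
#' A pair whose adjusted p-value passes the FDR cut is classified as:
#' * `strengthened` - same sign and |COR_E| > |COR_M|, or different signs
#'   but only COR_E significantly different from 0 at `nominal_alpha`;
#' * `weakened` - same sign and |COR_E| < |COR_M|, or different signs but
#'   only COR_M significantly different from 0;
#' * `reversed` - different signs, both significantly different from 0;
#' * `unclassified` - significant but matching none of the above (possible
#'   on synthetic data, e.g. different signs with neither correlation
#'   distinguishable from 0).
#' Pairs failing the FDR cut are `not_significant`.
#'
#' @param cor_m,cor_e the two correlations.
#' @param p_adj FDR-adjusted p-value of the COR_E vs COR_M test.
#' @param p_m_nonzero,p_e_nonzero two-sided p-values for each correlation
#'   being nonzero (Fisher z against standard normal).
#' @param fdr FDR threshold (default 0.05).
#' @param nominal_alpha nominal level for the per-correlation nonzero tests
#'   (default 0.05).
#' @return one of `"strengthened"`, `"weakened"`, `"reversed"`,
#'   `"unclassified"`, `"not_significant"`.
#' @export
classify_pair <- function(cor_m, cor_e, p_adj, p_m_nonzero, p_e_nonzero,
                          fdr = 0.05, nominal_alpha = 0.05) {
  if (p_adj >= fdr) return("not_significant")
  same_sign <- cor_e * cor_m > 0
  m_nonzero <- p_m_nonzero < nominal_alpha
  e_nonzero <- p_e_nonzero < nominal_alpha
  if (same_sign) {
    if (abs(cor_e) > abs(cor_m)) return("strengthened")
    if (abs(cor_e) < abs(cor_m)) return("weakened")
    return("unclassified")
  }
  if (m_nonzero && e_nonzero) return("reversed")
  if (e_nonzero && !m_nonzero) return("strengthened")
  if (m_nonzero && !e_nonzero) return("weakened")
  "unclassified"
}

#' Scan all trait pairs for selection on their coevolution
#'
#' For every unordered trait pair, tests whether the evolutionary
#' correlation differs from the mutational correlation
#' ([compare_correlations()]), adjusts across pairs by Benjamini-Hochberg,
#' and classifies significant pairs ([classify_pair()]).
#'
#' @param mcorr mutational correlation matrix (traits x traits).
#' @param ecorr evolutionary correlation matrix over the same traits.
#' @param n_e number of independent contrasts behind `ecorr`.
#' @param n_m number of mutant lines behind `mcorr`.
#' @param fdr FDR threshold (default 0.05).
#' @param nominal_alpha level for per-correlation nonzero tests.
#' @return list with `results` (data.frame: trait_i, trait_j, cor_m, cor_e,
#'   z_m, z_e, z_stat, p_raw, p_adj, cor_m_nonzero_p, cor_e_nonzero_p,
#'   category), `counts` (named category counts incl. `total_significant`),
#'   and the scan parameters.
#' @export
run_pairwise_scan <- function(mcorr, ecorr, n_e, n_m, fdr = 0.05,
                              nominal_alpha = 0.05) {
  if (!identical(colnames(mcorr), colnames(ecorr))) {
    d <- c(setdiff(colnames(mcorr), colnames(ecorr)),
           setdiff(colnames(ecorr), colnames(mcorr)))
    stop("trait sets differ between matrices: ", paste(d, collapse = ", "))
  }
  if (n_e <= 3 || n_m <= 3) stop("both sample sizes must exceed 3")
  traits <- colnames(mcorr)
  idx <- which(upper.tri(mcorr), arr.ind = TRUE)
  cm <- mcorr[idx]
  ce <- ecorr[idx]
  clamp <- function(r) {
    out <- abs(r) >= 1
    if (any(out)) {
      warning(sum(out), " correlation(s) at |r| >= 1 clamped for the z-test")
      r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    }
    r
  }
  cm_c <- clamp(cm)
  ce_c <- clamp(ce)
  z_m <- atanh(cm_c)
  z_e <- atanh(ce_c)
  z_stat <- (z_e - z_m) / sqrt(1 / (n_e - 3) + 1 / (n_m - 3))
  p_raw <- 2 * pnorm(-abs(z_stat))
  p_adj <- bh_adjust(p_raw)
  p_m0 <- cor_nonzero_p(cm_c, n_m)
  p_e0 <- cor_nonzero_p(ce_c, n_e)
  category <- vapply(seq_along(cm), function(k) {
    classify_pair(cm[k], ce[k], p_adj[k], p_m0[k], p_e0[k],
                  fdr = fdr, nominal_alpha = nominal_alpha)
  }, character(1))
  results <- data.frame(
    trait_i = traits[idx[, 1L]], trait_j = traits[idx[, 2L]],
    cor_m = cm, cor_e = ce, z_m = z_m, z_e = z_e, z_stat = z_stat,
    p_raw = p_raw, p_adj = p_adj,
    cor_m_nonzero_p = p_m0, cor_e_nonzero_p = p_e0,
    category = category, stringsAsFactors = FALSE
  )
  lv <- c("strengthened", "weakened", "reversed", "unclassified",
          "not_significant")
  counts <- table(factor(category, levels = lv))
  counts <- c(as.vector(counts), sum(category != "not_significant"),
              nrow(results))
  names(counts) <- c(lv, "total_significant", "total_pairs")
  list(results = results, counts = counts,
       n_e = n_e, n_m = n_m, fdr = fdr, nominal_alpha = nominal_alpha)
}

#' Random non-overlapping pairing control
#'
#' Repeatedly arranges the traits into random non-overlapping pairs (a
#' uniform perfect matching), re-tests only those pairs (BH adjustment
#' within each repeat), and records the fraction found significant. Because
#' every trait enters exactly one pair per repeat, this checks whether
#' re-using each trait in many pairs biased the all-pairs significant
#' fraction.
#'
#' @inheritParams run_pairwise_scan
#' @param n_repeats number of random pairings.
#' @param seed optional seed.
#' @return list with `fractions` (length `n_repeats`), their `median`, and
#'   the central 95% interval `ci95`.
#' @export
disjoint_pairing_control <- function(mcorr, ecorr, n_e, n_m, n_repeats = 1000,
                                     fdr = 0.05, nominal_alpha = 0.05,
                                     seed = NULL) {
  if (n_repeats < 1) stop("n_repeats must be at least 1")
  traits <- colnames(mcorr)
  with_seed(seed, {
    fractions <- vapply(seq_len(n_repeats), function(rep) {
      perm <- sample(traits)
      if (length(perm) %% 2L == 1L) {
        perm <- perm[-1L]  # odd trait count: one trait sat out at random
      }
      i <- perm[seq(1L, length(perm), by = 2L)]
      j <- perm[seq(2L, length(perm), by = 2L)]
      cm <- mcorr[cbind(i, j)]
      ce <- ecorr[cbind(i, j)]
      cm <- pmin(pmax(cm, -1 + 1e-15), 1 - 1e-15)
      ce <- pmin(pmax(ce, -1 + 1e-15), 1 - 1e-15)
      z <- (atanh(ce) - atanh(cm)) / sqrt(1 / (n_e - 3) + 1 / (n_m - 3))
      p_adj <- p.adjust(2 * pnorm(-abs(z)), method = "BH")
      mean(p_adj < fdr)
    }, numeric(1))
    list(fractions = fractions, median = median(fractions),
         ci95 = quantile(fractions, c(0.025, 0.975), names = FALSE))
  })
}

#' Null expectation for the overlap of two significant-pair sets
#'
#' Draws `|set_b|` pairs uniformly without replacement from the universe of
#' tested pairs `n_draws` times, counting the overlap with `set_a` in each
#' draw. The empirical P-value is the fraction of draws whose overlap is at
#' least the observed overlap of `set_a` and `set_b`.
#'
#' @param set_a,set_b character vectors of pair identifiers (e.g.
#'   `"t1|t7"`), subsets of `universe`.
#' @param universe character vector of all tested pair identifiers.
#' @param n_draws random draws (default 1000).
#' @param seed optional seed.
#' @return list with `observed`, `null` (vector of draw overlaps), their
#'   `median`, and the empirical `p`.
#' @export
overlap_expectation <- function(set_a, set_b, universe, n_draws = 1000,
                                seed = NULL) {
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("both sets must be subsets of the universe")
  if (length(set_b) > length(universe))
    stop("set_b larger than the universe")
  observed <- length(intersect(set_a, set_b))
  with_seed(seed, {
    null <- vapply(seq_len(n_draws), function(i) {
      length(intersect(set_a, sample(universe, length(set_b))))
    }, numeric(1))
    list(observed = observed, null = null, median = median(null),
         p = mean(null >= observed))
  })
}
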