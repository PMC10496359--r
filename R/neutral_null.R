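#' Simulate neutral Brownian-motion evolution along a tree
#'
#' Each branch receives one multivariate-normal deviate with covariance `M`
#' (the mutational covariance matrix); a tip's phenotype is the sum of the
#' increments on the branches between it and the root, the root itself
#' starting at 0 for every trait. Two branch scalings are provided:
#' * `standard` (default) - increment = deviate * sqrt(l), canonical
#'   Brownian motion with tip variance proportional to path length; this is
#'   the model under which independent contrasts are i.i.d., so the
#'   downstream z-test is calibrated;
#' * `as_printed` - increment = deviate * l (per-branch variance grows
#'   with l^2), a literal per-branch reading of "amount of evolution is
#'   M_i * l".
#' Both scalings multiply all traits of a branch by the same factor, so
#' the population correlation of any trait pair across tips is identical
#' under the two choices; the sampling dispersion of the contrasts-based
#' COR_E estimator, however, is inflated under `as_printed` on trees with
#' unequal branch lengths (contrasts are standardized by sqrt(l) while the
#' increments scale with l), which is why `standard` is the default.
#'
#' @param tree rooted `phylo` with non-negative branch lengths.
#' @param M trait covariance matrix (positive semidefinite); its dimnames
#'   name the traits.
#' @param seed optional seed.
#' @param scaling `"as_printed"` (default) or `"standard"`.
#' @return a `trait_table` of simulated tip phenotypes (tips x traits).
#' @export
simulate_bm <- function(tree, M, seed = NULL,
                        scaling = c("standard", "as_printed")) {
  scaling <- match.arg(scaling)
  check_covariance(M)
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")
  p <- ncol(M)
  traits <- colnames(M)
  if (is.null(traits)) traits <- paste0("trait", seq_len(p))
  with_seed(seed, {
    n_edge <- nrow(tree$edge)
    dev <- MASS::mvrnorm(n_edge, mu = rep(0, p), Sigma = M)
    if (n_edge == 1L) dev <- matrix(dev, nrow = 1L)
    fac <- if (scaling == "as_printed") tree$edge.length
           else sqrt(tree$edge.length)
    inc <- dev * fac
    # accumulate node values root-down
    ord <- reorder(tree, "postorder")
    val <- matrix(0, ape::Ntip(tree) + tree$Nnode, p)
    for (k in rev(seq_len(n_edge))) {
      e <- ord$edge[k, ]
      val[e[2L], ] <- val[e[1L], ] +
        inc[match(e[2L], tree$edge[, 2L]), ]
    }
    tips <- val[seq_len(ape::Ntip(tree)), , drop = FALSE]
    dimnames(tips) <- list(tree$tip.label, traits)
    trait_table(tips)
  })
}

#' Neutral null distribution of significant-pair counts
#'
#' Simulates `n_datasets` neutral Brownian-motion datasets along the tree
#' with mutational input `M` (the full matrix, sampled jointly, so the
#' simulated evolutionary correlation matrices inherit realistic cross-pair
#' dependence), recomputes the evolutionary correlation matrix of each via
#' independent contrasts, and scans it against the fixed mutational
#' correlation matrix. The per-category counts across datasets form the
#' null; if an observed total is supplied, the empirical P is the fraction
#' of datasets whose total significant count reaches it.
#'
#' @param tree rooted `phylo`.
#' @param M mutational covariance matrix driving the simulation.
#' @param mcorr fixed mutational correlation matrix scanned against
#'   (default: the correlation implied by `M`).
#' @param n_m mutant-line count entering the z-test.
#' @param n_datasets simulated datasets (default 1000).
#' @param fdr FDR threshold.
#' @param seed optional seed.
#' @param scaling passed to [simulate_bm()].
#' @param observed_total optional observed significant-pair total.
#' @return list with `counts` (datasets x categories matrix), `medians`,
#'   and `p_observed` (or `NA` when no observed total given).
#' @export
neutral_count_null <- function(tree, M, mcorr = stats::cov2cor(M), n_m,
                               n_datasets = 1000, fdr = 0.05, seed = NULL,
                               scaling = "standard",
                               observed_total = NULL) {
  if (n_datasets < 1) stop("n_datasets must be at least 1")
  check_covariance(M)
  if (is.null(colnames(mcorr)))
    dimnames(mcorr) <- list(colnames(M), colnames(M))
  with_seed(seed, {
    counts <- t(vapply(seq_len(n_datasets), function(i) {
      tips <- simulate_bm(tree, M, scaling = scaling)
      pic <- independent_contrasts(tree, tips)
      ec <- evolutionary_covariance(pic)
      dimnames(ec$correlation) <- dimnames(mcorr)
      suppressWarnings(
        run_pairwise_scan(mcorr, ec$correlation, n_e = pic$n, n_m = n_m,
                          fdr = fdr)$counts
      )
    }, numeric(7)))
    medians <- apply(counts, 2L, median)
    p_obs <- if (is.null(observed_total)) NA_real_
             else mean(counts[, "total_significant"] >= observed_total)
    list(counts = counts, medians = medians, p_observed = p_obs)
  })
}
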