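#' Standardize raw trait values against a reference phenotype
#'
#' Converts each raw measurement to the natural log of its ratio to the
#' reference value of the same trait, X~ = ln(X / X_ref). On typical
#' morphological data this brings trait distributions close to normal, which
#' the downstream Fisher r-to-Z machinery assumes. The reference is either a
#' per-trait vector of positive values (e.g. the wild-type phenotype) or the
#' ID of a row of `raw` (e.g. the progenitor of a mutation-accumulation
#' panel); a reference row is removed from the output since its standardized
#' values are identically zero.
#'
#' @param raw units x traits matrix of strictly positive raw values, with
#'   unit IDs as row names and trait IDs as column names.
#' @param reference either a named numeric vector covering every trait of
#'   `raw`, or a single string naming a row of `raw`.
#' @return a `trait_table` of dimensionless log-ratios.
#' @export
standardize_traits <- function(raw, reference) {
  if (is.null(rownames(raw)) || is.null(colnames(raw)))
    stop("'raw' needs unit IDs as row names and trait IDs as column names")
  if (is.character(reference) && length(reference) == 1L) {
    if (!reference %in% rownames(raw))
      stop("reference row '", reference, "' not found in 'raw'")
    ref <- raw[reference, ]
    raw <- raw[rownames(raw) != reference, , drop = FALSE]
  } else {
    ref <- reference
    if (is.null(names(ref))) {
      if (length(ref) != ncol(raw))
        stop("unnamed reference must have one value per trait")
      names(ref) <- colnames(raw)
    }
    missing <- setdiff(colnames(raw), names(ref))
    if (length(missing))
      stop("reference lacks traits: ", paste(missing, collapse = ", "))
    ref <- ref[colnames(raw)]
  }
  if (any(!is.finite(ref)) || any(ref <= 0))
    stop("non-positive reference value for trait '",
         names(ref)[which(!is.finite(ref) | ref <= 0)[1L]], "'")
  bad <- which(!is.finite(raw) | raw <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive raw value at unit '%s', trait '%s'",
                 rownames(raw)[bad[1L, 1L]], colnames(raw)[bad[1L, 2L]]))
  out <- log(sweep(raw, 2L, ref, "/"))
  trait_table(out)
}

#' Mutational correlation and covariance matrices from a mutant panel
#'
#' Pearson correlations of every trait pair across the mutant lines of a
#' panel, estimating the correlation of mutational effects (COR_M), with the
#' companion sample covariance matrix (the M matrix, n-1 denominator). Rows
#' containing any missing value are dropped (listwise) so that all pairwise
#' estimates share one sample size, and that size is reported as `n`.
#'
#' @param table trait table (lines x traits); missing cells allowed but the
#'   rows carrying them are dropped with a message.
#' @return list with `correlation`, `covariance`, and `n` (lines used).
#' @export
mutational_correlation <- function(table) {
  m <- unclass(table)
  keep <- rowSums(!is.finite(m)) == 0L
  if (any(!keep)) {
    message(sum(!keep), " line(s) dropped for missing values")
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) < 4L) stop("need at least 4 complete mutant lines")
  v <- apply(m, 2L, var)
  if (any(v == 0))
    stop("zero-variance trait(s): ",
         paste(colnames(m)[v == 0], collapse = ", "))
  list(correlation = stats::cor(m), covariance = stats::cov(m), n = nrow(m))
}

#' Mutational bias coefficient B for one trait
#'
#' Splits the standardized effects of one trait by sign, takes the mean of
#' the positive values and the mean of the negative values, forms the ratio
#' of their absolute values with the larger magnitude as numerator, and
#' returns its square root. B >= 1 by construction; B = 1 means the positive
#' and negative mutational effects are balanced in mean magnitude.
#'
#' @param values numeric vector of one trait's values across mutant lines;
#'   must contain at least one strictly positive and one strictly negative
#'   value (zeros are ignored).
#' @return scalar B >= 1.
#' @export
estimate_bias_coefficient <- function(values) {
  values <- values[is.finite(values)]
  pos <- values[values > 0]
  neg <- values[values < 0]
  if (!length(pos) || !length(neg))
    stop("bias coefficient undefined: values must include both signs")
  p <- abs(mean(pos))
  n <- abs(mean(neg))
  sqrt(max(p, n) / min(p, n))
}

#' Sampling-error diagnostic for an estimated covariance matrix
#'
#' Repeatedly resamples `n_samples` phenotype vectors from the multivariate
#' normal distribution with covariance `M`, re-estimates the covariance
#' matrix, and correlates the sorted eigenvalues of the estimate with those
#' of `M`. Correlations near 1 across repetitions indicate that sampling
#' error at this panel size barely perturbs the eigenstructure of M.
#'
#' @param M covariance matrix (positive semidefinite).
#' @param n_samples rows drawn per repetition; should exceed the trait count
#'   for full-rank estimates.
#' @param n_reps repetitions.
#' @param seed optional integer seed (caller's RNG stream is restored).
#' @return numeric vector of `n_reps` eigenvalue correlations; `NaN` with a
#'   warning where the reference eigenvalues are all equal.
#' @export
matrix_sampling_error_check <- function(M, n_samples, n_reps = 1000,
                                        seed = NULL) {
  check_covariance(M)
  ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (stats::sd(ev) == 0)
    warning("all eigenvalues of M are equal; correlations are undefined")
  with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      x <- MASS::mvrnorm(n_samples, mu = rep(0, ncol(M)), Sigma = M)
      ev_hat <- sort(eigen(stats::cov(x), symmetric = TRUE,
                           only.values = TRUE)$values, decreasing = TRUE)
      if (stats::sd(ev) == 0 || stats::sd(ev_hat) == 0) return(NaN)
      stats::cor(ev, ev_hat)
    }, numeric(1))
  })
}

#' Principal-component envelope check for a query phenotype
#'
#' Projects a query phenotype onto the principal components of a cloud of
#' replicate phenotypes and reports, for each of the first `n_pcs`
#' components, whether the projection falls inside the central envelope
#' (default 95%) of the replicate projections. Used to check whether a
#' phenotype measured under a different condition is compatible with the
#' replicate distribution, i.e. whether a condition shift distorts the
#' correlational structure.
#'
#' @param replicates trait table of replicate phenotypes (rows).
#' @param query numeric vector, one value per trait of `replicates`.
#' @param n_pcs number of leading components to check; must not exceed the
#'   rank of the centered replicate matrix.
#' @param level central coverage level (default 0.95).
#' @return list with `per_pc` (data.frame: pc, projection, lower, upper,
#'   inside) and `variance_explained` (fraction captured by the `n_pcs`
#'   components together).
#' @export
pc_envelope_check <- function(replicates, query, n_pcs = 3, level = 0.95) {
  m <- unclass(replicates)
  if (!is.null(names(query))) query <- query[colnames(m)]
  if (length(query) != ncol(m) || any(!is.finite(query)))
    stop("query must supply one finite value per trait")
  if (nrow(m) <= n_pcs)
    stop("need more replicate rows than components checked")
  pca <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(pca$sdev > max(pca$sdev) * 1e-12)
  if (n_pcs > rank)
    stop("n_pcs (", n_pcs, ") exceeds the rank (", rank,
         ") of the replicate matrix")
  proj <- drop((query - pca$center) %*% pca$rotation[, seq_len(n_pcs),
                                                     drop = FALSE])
  alpha <- (1 - level) / 2
  lims <- apply(pca$x[, seq_len(n_pcs), drop = FALSE], 2L, quantile,
                probs = c(alpha, 1 - alpha), names = FALSE)
  per_pc <- data.frame(
    pc = seq_len(n_pcs),
    projection = proj,
    lower = lims[1L, ],
    upper = lims[2L, ],
    inside = proj >= lims[1L, ] & proj <= lims[2L, ]
  )
  ve <- sum(pca$sdev[seq_len(n_pcs)]^2) / sum(pca$sdev^2)
  list(per_pc = per_pc, variance_explained = ve)
}
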