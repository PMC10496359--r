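# Small fixtures shared across test files; everything is built in code.

toy_table <- function(values, units = rownames(values),
                      traits = colnames(values)) {
  if (is.null(units)) units <- paste0("u", seq_len(nrow(values)))
  if (is.null(traits)) traits <- paste0("t", seq_len(ncol(values)))
  dimnames(values) <- list(units, traits)
  trait_table(values)
}

# Random positive-definite correlation matrix with named traits.
random_corr <- function(p, seed) {
  set.seed(seed)
  a <- matrix(rnorm(p * (p + 2)), p + 2, p)
  r <- stats::cov2cor(crossprod(a))
  dimnames(r) <- list(paste0("t", seq_len(p)), paste0("t", seq_len(p)))
  r
}

# Equicorrelation matrix (PSD for rho in (-1/(p-1), 1)).
equicorr <- function(p, rho) {
  r <- matrix(rho, p, p)
  diag(r) <- 1
  dimnames(r) <- list(paste0("t", seq_len(p)), paste0("t", seq_len(p)))
  r
}
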