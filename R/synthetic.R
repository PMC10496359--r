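#' Generate a synthetic mutant panel
#'
#' Draws `n_lines` independent phenotype rows from a multivariate normal
#' with the given target covariance, emulating a mutant panel (gene
#' deletion or mutation accumulation lines) whose estimated correlations
#' converge to the targets as the panel grows.
#'
#' @param n_lines rows to draw.
#' @param sigma positive-definite target covariance matrix.
#' @param seed optional seed.
#' @param line_prefix prefix for unit IDs (default `"line"`).
#' @return a `trait_table` (`n_lines` x traits).
#' @export
gen_mutant_panel <- function(n_lines, sigma, seed = NULL,
                             line_prefix = "line") {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8 * max(ev))
    stop("target covariance is not positive definite (min eigenvalue ",
         format(min(ev)), ")")
  traits <- colnames(sigma)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(sigma)))
  with_seed(seed, {
    x <- MASS::mvrnorm(n_lines, mu = rep(0, ncol(sigma)), Sigma = sigma)
    dimnames(x) <- list(paste0(line_prefix, seq_len(n_lines)), traits)
    trait_table(x)
  })
}

#' Generate a pure-birth (Yule) tree
#'
#' Ultrametric tree with exponential waiting times between speciation
#' events, emulating the phylogeny of a set of natural strains or species.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (default 1).
#' @param seed optional seed.
#' @param tip_prefix prefix for tip labels (default `"s"`).
#' @return a rooted `phylo` object with unique tip labels.
#' @export
gen_tree <- function(n_tips, birth_rate = 1, seed = NULL, tip_prefix = "s") {
  if (n_tips < 2) stop("need at least 2 tips")
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    tree$tip.label <- paste0(tip_prefix, seq_len(n_tips))
    tree
  })
}

# Linear map from tip values to scaled independent contrasts for a fixed
# tree: column i is the contrast vector of the indicator phenotype of tip i.
contrast_transform <- function(tree) {
  n <- ape::Ntip(tree)
  basis <- diag(n)
  dimnames(basis) <- list(tree$tip.label, tree$tip.label)
  suppressMessages(
    independent_contrasts(tree, trait_table(basis))$contrasts
  )
}

#' Generate divergence data along a tree with optional selection injections
#'
#' Baseline tip phenotypes follow neutral Brownian motion with mutational
#' covariance `M` ([simulate_bm()]). For each injected trait pair the two
#' traits are re-drawn in contrast space: their independent contrasts are
#' sampled directly from a bivariate normal whose correlation equals the
#' injection target (variances taken from `M`), then mapped back to tip
#' space through the pseudo-inverse of the tree's contrast transform. The
#' estimator downstream therefore sees contrasts whose population
#' correlation is exactly the target - sharp ground truth for power
#' studies - while non-injected traits retain pure Brownian behavior.
#'
#' @param tree rooted `phylo`.
#' @param M mutational covariance matrix (traits named by its dimnames).
#' @param injections list of `list(pair = c(id_i, id_j), target = r)` with
#'   `|r| < 1`; pairs must not share traits (jointly unsatisfiable targets
#'   are rejected).
#' @param seed optional seed.
#' @param scaling passed to [simulate_bm()] for the baseline.
#' @return a `trait_table` of tip phenotypes.
#' @export
gen_divergence_data <- function(tree, M, injections = NULL, seed = NULL,
                                scaling = "standard") {
  traits <- colnames(M)
  if (!is.null(injections)) {
    used <- unlist(lapply(injections, `[[`, "pair"))
    if (anyDuplicated(used))
      stop("injections share trait(s): ",
           paste(unique(used[duplicated(used)]), collapse = ", "))
    if (!all(used %in% traits))
      stop("injection trait(s) not in M: ",
           paste(setdiff(used, traits), collapse = ", "))
    targets <- vapply(injections, `[[`, numeric(1), "target")
    if (any(abs(targets) >= 1)) stop("injection targets must satisfy |r| < 1")
  }
  with_seed(seed, {
    tips <- unclass(simulate_bm(tree, M, scaling = scaling))
    if (length(injections)) {
      A <- contrast_transform(tree)
      A_pinv <- MASS::ginv(A)
      for (inj in injections) {
        pair <- inj$pair
        v <- diag(M)[pair]
        sig <- matrix(c(v[1L], inj$target * sqrt(v[1L] * v[2L]),
                        inj$target * sqrt(v[1L] * v[2L]), v[2L]), 2L, 2L)
        cc <- MASS::mvrnorm(nrow(A), mu = c(0, 0), Sigma = sig)
        if (nrow(A) == 1L) cc <- matrix(cc, 1L)
        tips[, pair] <- A_pinv %*% cc
      }
    }
    trait_table(tips)
  })
}

#' Exact block-modular covariance matrix with its partition
#'
#' Builds a covariance matrix with constant correlation `r_within` inside
#' each module and `r_between` across modules (emulating e.g. the
#' actin / nucleus / cell-wall trait categories), plus the matching module
#' partition. The matrix is exact (not sampled), so closed-form checks of
#' CR and V_eigen apply downstream.
#'
#' @param module_sizes integer vector of traits per module (each >= 2).
#' @param r_within within-module correlation.
#' @param r_between between-module correlation.
#' @param variances per-trait variances, length 1 or sum(module_sizes).
#' @return list with `cov`, `partition` (named vector trait -> module
#'   label), and `trait_ids`.
#' @export
gen_modular_cov <- function(module_sizes, r_within, r_between,
                            variances = 1) {
  if (length(module_sizes) < 2L || any(module_sizes < 2L))
    stop("need at least 2 modules of at least 2 traits each")
  p <- sum(module_sizes)
  labels <- rep(paste0("M", seq_along(module_sizes)), module_sizes)
  traits <- paste0("t", seq_len(p))
  R <- matrix(r_between, p, p)
  for (mod in unique(labels)) {
    i <- which(labels == mod)
    R[i, i] <- r_within
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8)
    stop("block structure is not positive definite (min eigenvalue ",
         format(min(ev)), ")")
  sds <- sqrt(rep_len(variances, p))
  cov <- R * tcrossprod(sds)
  dimnames(cov) <- list(traits, traits)
  partition <- stats::setNames(labels, traits)
  list(cov = cov, partition = partition, trait_ids = traits)
}
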