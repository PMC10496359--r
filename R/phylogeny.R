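#' Parse a rooted Newick tree with branch lengths
#'
#' Thin validating wrapper around [ape::read.tree()]: the tree must be
#' rooted, carry a branch length on every edge, have unique tip labels, and
#' have non-negative branch lengths. Multifurcations are allowed here and
#' resolved later by [independent_contrasts()].
#'
#' @param text Newick string, or `NULL` when `file` is given.
#' @param file path to a Newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text)
          else ape::read.tree(file = file)
  if (is.null(tree)) stop("malformed Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("every branch must carry a length")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (!ape::is.rooted(tree))
    stop("tree must be rooted (basal polytomies of unrooted trees rejected)")
  tree
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree)
  else ape::write.tree(tree, file = file)
}

#' Phylogenetically independent contrasts for a trait table
#'
#' Computes Felsenstein's independent contrasts for every trait: at each
#' internal node with child values x1, x2 on (rank-adjusted) branches v1,
#' v2, the contrast is (x1 - x2)/sqrt(v1 + v2), the ancestral value is the
#' precision-weighted mean, and the parent branch is extended by
#' v1*v2/(v1 + v2). An n-tip binary tree yields n - 1 contrasts per trait;
#' under Brownian motion they are independent draws from the mutational
#' process, which is what makes the evolutionary covariance estimable.
#'
#' Multifurcations are resolved into zero-length binary splits (this leaves
#' the induced tip covariance unchanged); zero-length branches are then
#' floored at `branch_floor` times the tree height so the pruning weights
#' stay finite. Both adjustments emit a message.
#'
#' @param tree rooted `phylo` with branch lengths; tip labels must all be
#'   present among the unit IDs of `table`.
#' @param table trait table whose rows cover the tips.
#' @param branch_floor relative floor for zero-length branches (default
#'   1e-8; set to 0 to disable, in which case zero-length cherries are an
#'   error).
#' @return list with `contrasts` ((n_tips - 1) x traits matrix), `n`
#'   (contrast count), and the resolved `tree`.
#' @export
independent_contrasts <- function(tree, table, branch_floor = 1e-8) {
  m <- unclass(table)
  missing <- setdiff(tree$tip.label, rownames(m))
  if (length(missing))
    stop("tips absent from trait table: ", paste(missing, collapse = ", "))
  m <- m[tree$tip.label, , drop = FALSE]
  if (any(!is.finite(m))) stop("trait values at tips must be finite")
  if (!ape::is.binary(tree)) {
    message("multifurcation(s) resolved into zero-length binary splits")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (branch_floor > 0) {
    height <- max(ape::node.depth.edgelength(tree))
    eps <- branch_floor * max(height, .Machine$double.eps)
    nzero <- sum(tree$edge.length < eps)
    if (nzero > 0) {
      message(nzero, " near-zero branch length(s) floored at ", format(eps))
      tree$edge.length[tree$edge.length < eps] <- eps
    }
  } else {
    zero_cherry <- vapply(seq_len(tree$Nnode) + ape::Ntip(tree), function(nd) {
      kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
      all(tree$edge.length[match(kids, tree$edge[, 2L])] == 0)
    }, logical(1))
    if (any(zero_cherry))
      stop("zero-length cherry at internal node ",
           (which(zero_cherry) + ape::Ntip(tree))[1L])
  }
  contrasts <- apply(m, 2L, function(x) ape::pic(x, tree, scaled = TRUE))
  if (is.null(dim(contrasts)))
    contrasts <- matrix(contrasts, nrow = 1L,
                        dimnames = list(NULL, colnames(m)))
  list(contrasts = contrasts, n = nrow(contrasts), tree = tree)
}

#' Evolutionary covariance and correlation from independent contrasts
#'
#' The evolutionary covariance of traits i and j is the mean cross-product
#' of their contrasts through the origin (contrasts have expectation zero
#' under Brownian motion, so no mean is subtracted by default); the
#' evolutionary correlation COR_E normalizes by the through-origin standard
#' deviations. A centered (ordinary sample-moment) variant is available via
#' `center = TRUE`.
#'
#' @param contrasts output of [independent_contrasts()], or a plain
#'   contrasts matrix.
#' @param center logical; subtract contrast means before averaging
#'   cross-products (default `FALSE`).
#' @return list with `covariance`, `correlation`, and `n` (contrast count).
#'   Traits whose contrasts are all zero yield `NaN` correlations with a
#'   warning.
#' @export
evolutionary_covariance <- function(contrasts, center = FALSE) {
  cc <- if (is.list(contrasts)) contrasts$contrasts else contrasts
  if (nrow(cc) < 1L) stop("need at least 1 contrast")
  if (center) cc <- sweep(cc, 2L, colMeans(cc))
  cov_e <- crossprod(cc) / nrow(cc)
  sds <- sqrt(diag(cov_e))
  if (any(sds == 0))
    warning("all-zero contrasts for trait(s): ",
            paste(colnames(cc)[sds == 0], collapse = ", "),
            "; correlations are NaN")
  cor_e <- cov_e / tcrossprod(sds)
  diag(cor_e)[sds > 0] <- 1
  list(covariance = cov_e, correlation = cor_e, n = nrow(cc))
}
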