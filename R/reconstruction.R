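# Ancestral reconstruction: per-component Gaussian posteriors of the mixing
# coefficients at internal nodes via phylogenetic GP regression, combined
# across (independent) components into a functional posterior with pointwise
# bands; plus the phylogenetically aware autocovariance estimate of the trait.

#' Posterior distribution of the function-valued trait at one node
#'
#' Runs the phylogenetic GP posterior of each coefficient row at the target
#' node (zero prior mean, tip noise on the observed diagonal only, noise-free
#' latent target) and combines components through the basis: posterior mean
#' curve `mean_curve + sum_i mu_i phi_i(s)` and pointwise phylogenetic
#' variance `sum_i v_i phi_i(s)^2` (components evolve independently). For tip
#' targets the non-phylogenetic band `sqrt(sum_i sigma_n_i^2 phi_i(s)^2)` is
#' also returned; for ancestral targets it is zero, since ancestors carry only
#' the phylogenetic part of variation.
#'
#' @param sep A `pgp_separation` (estimated or assembled via [as_separation()]).
#' @param gammas List of `pgp_hyperparams`, one per component of `sep`.
#' @param tree A `phylo` object whose tips match the columns of `sep$coeffs`.
#' @param node_id A node id of `tree` (internal `"node<k>"`, or a tip label).
#' @return An object of class `pgp_fposterior`: `node_id`, `grid`,
#'   `mean_curve`, `phylo_sd_curve`, `nonphylo_sd_curve`, and
#'   `coeff_posteriors` (per-component means/variances).
#' @export
reconstruct_node <- function(sep, gammas, tree, node_id) {
  res <- reconstruct_nodes(sep, gammas, tree, node_id)
  res[[1]]
}

# Shared machinery: posterior at an arbitrary set of target node ids.
reconstruct_nodes <- function(sep, gammas, tree, target_ids) {
  validate_tree(tree)
  if (!inherits(sep, "pgp_separation")) stopf("sep must be a pgp_separation")
  k <- nrow(sep$coeffs)
  if (length(gammas) != k) stopf("need one gamma per component (k = %d)", k)
  ids <- node_ids(tree)
  unknown <- setdiff(target_ids, ids)
  if (length(unknown)) stopf("unknown node id(s): %s", paste(unknown, collapse = ", "))
  tips <- tree$tip.label
  if (!setequal(colnames(sep$coeffs), tips))
    stopf("coefficient columns must match the tree's tips")

  D_all <- patristic(tree, include_internal = TRUE)
  nt <- length(target_ids)
  mu <- matrix(0, k, nt)
  v <- matrix(0, k, nt)
  for (i in seq_len(k)) {
    post <- gp_posterior(sep$coeffs[i, tips], gammas[[i]], D_all,
                         target_ids = target_ids, extant_ids = tips,
                         latent = TRUE)
    mu[i, ] <- post$mean
    v[i, ] <- pmax(diag(post$covariance), 0)
  }

  B <- sep$basis$curves                    # k x m
  B2 <- B^2
  sn2 <- vapply(gammas, function(g) g$sigma_n^2, numeric(1))
  out <- vector("list", nt)
  names(out) <- target_ids
  for (j in seq_len(nt)) {
    is_tip <- target_ids[j] %in% tips
    nonphylo <- if (is_tip) sqrt(colSums(sn2 * B2)) else numeric(ncol(B))
    out[[j]] <- structure(list(
      node_id = target_ids[j],
      grid = sep$basis$grid,
      mean_curve = as.numeric(sep$mean_curve + colSums(mu[, j] * B)),
      phylo_sd_curve = sqrt(as.numeric(colSums(v[, j] * B2))),
      nonphylo_sd_curve = as.numeric(nonphylo),
      coeff_posteriors = data.frame(component = seq_len(k),
                                    mean = mu[, j], var = v[, j])
    ), class = "pgp_fposterior")
  }
  out
}

#' @export
print.pgp_fposterior <- function(x, ...) {
  cat(sprintf("functional posterior at %s: m = %d, mean phylo sd = %.4g\n",
              x$node_id, length(x$grid), mean(x$phylo_sd_curve)))
  invisible(x)
}

#' Reconstruct all ancestral nodes
#'
#' Maps [reconstruct_node()] over every internal node of the tree (marginal
#' posteriors; no joint cross-node covariance is emitted), optionally also
#' over the tips.
#'
#' @inheritParams reconstruct_node
#' @param include_tips Also reconstruct the latent phylogenetic component at
#'   each tip?
#' @return Named list of `pgp_fposterior`, one per reconstructed node.
#' @export
reconstruct_all <- function(sep, gammas, tree, include_tips = FALSE) {
  validate_tree(tree)
  internal <- setdiff(node_ids(tree), tree$tip.label)
  targets <- if (include_tips) c(internal, tree$tip.label) else internal
  reconstruct_nodes(sep, gammas, tree, targets)
}

#' Phylogenetically aware autocovariance of the function-valued trait
#'
#' Under the independent-component mixing model the trait autocovariance is
#' `C(s, t) = sum_i (sigma_f_i^2 + sigma_n_i^2) phi_i(s) phi_i(t)`: a rank-k
#' Gram construction, hence symmetric positive semidefinite for any input.
#'
#' @param sep A `pgp_separation` (or a `pgp_basis` given directly).
#' @param gammas List of `pgp_hyperparams`, one per component.
#' @return An object of class `pgp_autocov`: `grid`, `values` (`m x m`
#'   matrix) and `weights` (the per-component variance contributions).
#' @export
autocovariance <- function(sep, gammas) {
  basis <- if (inherits(sep, "pgp_basis")) sep else sep$basis
  B <- basis$curves
  if (length(gammas) != nrow(B)) stopf("need one gamma per basis curve")
  w <- vapply(gammas, function(g) g$sigma_f^2 + g$sigma_n^2, numeric(1))
  C <- symmetrize(crossprod(w * B, B))
  structure(list(grid = basis$grid, values = C, weights = w),
            class = "pgp_autocov")
}

#' @export
print.pgp_autocov <- function(x, ...) {
  cat(sprintf("autocovariance estimate on a %d-point grid; component weights: %s\n",
              length(x$grid), paste(format(x$weights, digits = 3), collapse = ", ")))
  invisible(x)
}

#' Coverage of true curves by posterior bands
#'
#' Evaluation helper: fraction of (node, grid point) pairs at which reference
#' curves lie within `width` posterior phylogenetic standard deviations of the
#' posterior mean.
#'
#' @param posteriors List of `pgp_fposterior` (named by node id).
#' @param reference A `pgp_fdata` of reference (e.g. simulated true) curves.
#' @param width Band half-width in posterior sds (default 2).
#' @return Scalar coverage fraction.
#' @export
band_coverage <- function(posteriors, reference, width = 2) {
  ids <- intersect(names(posteriors), reference$ids)
  if (!length(ids)) stopf("no overlapping node ids between posteriors and reference")
  hits <- 0L
  total <- 0L
  for (id in ids) {
    p <- posteriors[[id]]
    truth <- reference$curves[id, ]
    ok <- abs(truth - p$mean_curve) <= width * p$phylo_sd_curve
    hits <- hits + sum(ok)
    total <- total + length(ok)
  }
  hits / total
}
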