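# Generative model: basis functions, phylogenetic OU mixing coefficients
# simulated recursively over the whole tree, i.i.d. Gaussian tip noise, and
# the resulting function-valued traits d = X phi at tips and W phi at
# ancestors. The recursive branch-wise simulator is deliberately independent
# of the kernel module; their agreement is a keystone test of both.

#' Construct a basis set
#'
#' @param grid Strictly increasing sample points (length m >= 2).
#' @param curves k x m matrix, one basis function per row.
#' @return An object of class `pgp_basis`.
#' @export
basis_set <- function(grid, curves) {
  curves <- as.matrix(curves)
  if (length(grid) != ncol(curves)) stopf("grid length must equal ncol(curves)")
  if (length(grid) < 2 || any(diff(grid) <= 0)) stopf("grid must be strictly increasing, m >= 2")
  if (!all(is.finite(curves))) stopf("basis curves must be finite")
  structure(list(grid = as.numeric(grid), curves = curves), class = "pgp_basis")
}

#' @export
print.pgp_basis <- function(x, ...) {
  cat(sprintf("basis set: %d curve(s) on a %d-point grid [%g, %g]\n",
              nrow(x$curves), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Default simulated basis: three non-orthogonal unimodal bumps
#'
#' Three fixed beta-density bumps on a uniform grid over `[0, 1]`:
#' `dbeta(., 3, 7)`, `dbeta(., 5, 5)` and `dbeta(., 7, 3)`, each rescaled to
#' unit Euclidean norm on its grid -- the same normalization convention the
#' separation stage uses for estimated basis functions, so that simulated and
#' recovered mixing coefficients (and hence hyperparameters) live on directly
#' comparable scales. Supports overlap, so every pairwise inner product is
#' nonzero (the Gram matrix is not diagonal) and each curve has a single
#' interior maximum. Deterministic.
#'
#' @param m Grid size (>= 16), default 1024.
#' @return A `pgp_basis` with 3 rows.
#' @export
default_basis <- function(m = 1024) {
  if (!is_scalar_number(m) || m < 16) stopf("m must be >= 16")
  grid <- seq(0, 1, length.out = m)
  shapes <- list(c(3, 7), c(5, 5), c(7, 3))
  curves <- t(vapply(shapes, function(sh) {
    f <- stats::dbeta(grid, sh[1], sh[2])
    f / sqrt(sum(f^2))
  }, numeric(m)))
  rownames(curves) <- paste0("phi", 1:3)
  basis_set(grid, curves)
}

#' Simulate a phylogenetic OU process over a whole tree
#'
#' Recursive branch-wise simulation of the stationary OU process with
#' covariance `sigma_f^2 exp(-d/(2 ell))`: the root value is
#' `Normal(0, sigma_f^2)` and each child, down a branch of length `b`, is
#' `parent * exp(-b/(2 ell)) + Normal(0, sigma_f^2 (1 - exp(-b/ell)))`.
#' Returns values at every node (tips and internal). `gamma$sigma_n` is
#' ignored here; tip noise is added separately by [add_tip_noise()]. When
#' `sigma_f = 0` all values are exactly zero.
#'
#' @param tree A `phylo` object.
#' @param gamma A `pgp_hyperparams` object.
#' @param seed Optional integer seed.
#' @param n_rep Number of independent replicate processes.
#' @return `n_rep x n_nodes` matrix, columns named by [node_ids()].
#' @export
simulate_ou_on_tree <- function(tree, gamma, seed = NULL, n_rep = 1) {
  validate_tree(tree)
  ids <- node_ids(tree)
  n_nodes <- length(ids)
  vals <- matrix(0, n_rep, n_nodes, dimnames = list(NULL, ids))
  if (gamma$sigma_f == 0) return(vals)

  set_seed_if(seed)
  sf <- gamma$sigma_f
  ell <- gamma$ell
  root <- length(tree$tip.label) + 1L
  vals[, root] <- stats::rnorm(n_rep, 0, sf)
  # cladewise edge order visits every parent before its children
  tr <- ape::reorder.phylo(tree, "cladewise")
  edges <- tr$edge
  blen <- tr$edge.length
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]; b <- blen[e]
    w <- exp(-b / (2 * ell))
    s <- sf * sqrt(max(0, 1 - exp(-b / ell)))
    vals[, ch] <- w * vals[, p] + stats::rnorm(n_rep, 0, s)
  }
  vals
}

#' Add non-phylogenetic noise at tips
#'
#' Adds i.i.d. `Normal(0, sigma_n^2)` to each value: `X = Y + eps`.
#'
#' @param coeffs Numeric vector or matrix of tip coefficients.
#' @param sigma_n Non-phylogenetic standard deviation, >= 0.
#' @param seed Optional integer seed.
#' @return Object of the same shape with noise added.
#' @export
add_tip_noise <- function(coeffs, sigma_n, seed = NULL) {
  if (!is_scalar_number(sigma_n) || sigma_n < 0) stopf("sigma_n must be >= 0")
  if (sigma_n == 0) return(coeffs)
  set_seed_if(seed)
  coeffs + stats::rnorm(length(coeffs), 0, sigma_n)
}

#' Functional dataset container
#'
#' @param grid Common sample grid.
#' @param ids Taxon / node identifiers (one per curve).
#' @param curves `n x m` matrix of curves, rows named by `ids`.
#' @param mean_curve Length-`m` mean curve (zero by default).
#' @return An object of class `pgp_fdata`.
#' @export
functional_dataset <- function(grid, ids, curves, mean_curve = NULL) {
  curves <- as.matrix(curves)
  if (nrow(curves) != length(ids)) stopf("curves must have one row per id")
  if (ncol(curves) != length(grid)) stopf("curves must have one column per grid point")
  if (is.null(mean_curve)) mean_curve <- numeric(length(grid))
  rownames(curves) <- ids
  structure(list(grid = as.numeric(grid), ids = as.character(ids),
                 curves = curves, mean_curve = as.numeric(mean_curve)),
            class = "pgp_fdata")
}

#' @export
print.pgp_fdata <- function(x, ...) {
  cat(sprintf("functional dataset: %d curve(s) on a %d-point grid\n",
              length(x$ids), length(x$grid)))
  invisible(x)
}

#' Default simulation hyperparameters
#'
#' Three components with length-scales expressed as fractions of the tree's
#' maximum tip-to-tip distance: `(2.5, 0.75 l_max, 0.5)`, `(0, n.a., 1.0)`
#' (no phylogenetic signal) and `(1.5, 0.25 l_max, 0.5)`.
#'
#' @param l_max Maximum patristic distance of the target tree, default 8.22.
#' @return List of three `pgp_hyperparams`.
#' @export
default_gammas <- function(l_max = 8.22) {
  list(hyperparams(2.5, 0.75 * l_max, 0.5),
       hyperparams(0, NA, 1.0),
       hyperparams(1.5, 0.25 * l_max, 0.5))
}

#' Simulate function-valued traits on a phylogeny
#'
#' For each component i, simulates a phylogenetic OU process over the whole
#' tree with `gammas[[i]]` and adds i.i.d. tip noise `sigma_n^i`, then mixes:
#' tip curves are `t(X) %*% phi` (with noise), ancestral curves `t(W) %*% phi`
#' (noise-free). Per-component seeds are derived from `seed` by a fixed
#' splitting rule, so adding components leaves earlier ones unchanged.
#'
#' @param tree A `phylo` object.
#' @param basis A `pgp_basis` with k rows.
#' @param gammas List of k `pgp_hyperparams`.
#' @param seed Optional integer master seed.
#' @return List of class `pgp_sim` with elements `tips` and `ancestors`
#'   (both `pgp_fdata`) and `truth` (list with `X` noisy tip coefficients,
#'   `Y` noise-free tip coefficients, `W` ancestral coefficients -- all
#'   `k x n` matrices -- plus `gammas` and `basis`).
#' @export
synthesize_dataset <- function(tree, basis = default_basis(),
                               gammas = default_gammas(tree_l_max(tree)),
                               seed = NULL) {
  validate_tree(tree)
  if (!inherits(basis, "pgp_basis")) stopf("basis must be a pgp_basis")
  k <- nrow(basis$curves)
  if (length(gammas) != k)
    stopf("need one hyperparameter set per basis curve: k = %d, got %d", k, length(gammas))

  tips <- tree$tip.label
  internal <- setdiff(node_ids(tree), tips)
  Y <- matrix(0, k, length(tips), dimnames = list(NULL, tips))
  W <- matrix(0, k, length(internal), dimnames = list(NULL, internal))
  X <- Y
  for (i in seq_len(k)) {
    g <- gammas[[i]]
    vals <- simulate_ou_on_tree(tree, g, seed = split_seed(seed, i, 0L))[1, ]
    Y[i, ] <- vals[tips]
    W[i, ] <- vals[internal]
    X[i, ] <- add_tip_noise(Y[i, ], g$sigma_n, seed = split_seed(seed, i, 1L))
  }
  tip_curves <- t(X) %*% basis$curves
  anc_curves <- t(W) %*% basis$curves
  structure(list(
    tips = functional_dataset(basis$grid, tips, tip_curves),
    ancestors = functional_dataset(basis$grid, internal, anc_curves),
    truth = list(X = X, Y = Y, W = W, gammas = gammas, basis = basis)
  ), class = "pgp_sim")
}

#' @export
print.pgp_sim <- function(x, ...) {
  cat(sprintf("simulated functional dataset: %d tips, %d ancestors, %d components, m = %d\n",
              length(x$tips$ids), length(x$ancestors$ids),
              nrow(x$truth$X), length(x$tips$grid)))
  invisible(x)
}
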