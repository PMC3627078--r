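# Phylogenetic OU covariance, Gaussian process posterior and marginal
# likelihood. The marginal covariance between two nodes at patristic distance
# d is sigma_f^2 * exp(-d / (2*ell)), the stationary Ornstein-Uhlenbeck
# covariance with selection strength alpha = 1/(2*ell); i.i.d. non-phylogenetic
# variance sigma_n^2 is added only for extant (tip) taxa.

#' Hyperparameters of a phylogenetic OU component
#'
#' A triple gamma = (sigma_f, ell, sigma_n): the stationary phylogenetic
#' standard deviation (trait units), the characteristic length-scale of
#' correlation decay (tree-distance units), and the non-phylogenetic standard
#' deviation at extant taxa (trait units). `ell` may be `NA` only when
#' `sigma_f = 0`, in which case the length-scale plays no role.
#'
#' @param sigma_f Phylogenetic standard deviation, >= 0.
#' @param ell Characteristic length-scale, > 0 (or `NA` if `sigma_f = 0`).
#' @param sigma_n Non-phylogenetic standard deviation, >= 0.
#' @return An object of class `pgp_hyperparams`.
#' @export
hyperparams <- function(sigma_f, ell, sigma_n) {
  if (!is_scalar_number(sigma_f) || sigma_f < 0) stopf("sigma_f must be >= 0")
  if (!is_scalar_number(sigma_n) || sigma_n < 0) stopf("sigma_n must be >= 0")
  if (is.na(ell)) {
    if (sigma_f > 0) stopf("ell may be NA only when sigma_f = 0")
  } else if (!is_scalar_number(ell) || ell <= 0) {
    stopf("ell must be > 0")
  }
  structure(list(sigma_f = sigma_f, ell = ell, sigma_n = sigma_n),
            class = "pgp_hyperparams")
}

#' @export
print.pgp_hyperparams <- function(x, ...) {
  cat(sprintf("phylogenetic OU hyperparameters: sigma_f = %.4g, ell = %s, sigma_n = %.4g\n",
              x$sigma_f, ifelse(is.na(x$ell), "n.a.", format(x$ell, digits = 4)),
              x$sigma_n))
  cat(sprintf("  (alpha = %s, phylogenetic fraction = %.3f)\n",
              ifelse(is.na(x$ell), "n.a.", format(1 / (2 * x$ell), digits = 4)),
              phylo_fraction(x)))
  invisible(x)
}

#' Strength of selection alpha = 1 / (2 * ell)
#' @param gamma A `pgp_hyperparams` object.
#' @return alpha, or `NA` when the length-scale is undefined.
#' @export
ou_alpha <- function(gamma) if (is.na(gamma$ell)) NA_real_ else 1 / (2 * gamma$ell)

#' Proportion of variation attributable to the phylogeny
#'
#' sigma_f^2 / (sigma_f^2 + sigma_n^2), in `[0, 1]`; closely related to
#' Pagel's lambda.
#' @param gamma A `pgp_hyperparams` object.
#' @return The phylogenetic fraction of total variance at a tip.
#' @export
phylo_fraction <- function(gamma) {
  tot <- gamma$sigma_f^2 + gamma$sigma_n^2
  if (tot == 0) return(0)
  gamma$sigma_f^2 / tot
}

# Phylogenetic (noise-free) part of the covariance at distances D.
phylo_cov_part <- function(gamma, D) {
  D <- as.matrix(D)
  if (gamma$sigma_f == 0)
    return(matrix(0, nrow(D), ncol(D), dimnames = dimnames(D)))
  gamma$sigma_f^2 * exp(-D / (2 * gamma$ell))
}

#' Marginal OU covariance between two nodes
#'
#' `sigma_f^2 * exp(-d/(2*ell))`, plus `sigma_n^2` only when both indices refer
#' to the same extant taxon (`d = 0` and `same_extant_taxon = TRUE`).
#'
#' @param gamma A `pgp_hyperparams` object.
#' @param d Patristic distance(s), >= 0; vectorized.
#' @param same_extant_taxon Do both indices refer to one and the same tip?
#' @return Covariance value(s).
#' @export
ou_cov <- function(gamma, d, same_extant_taxon = FALSE) {
  if (any(d < 0)) stopf("patristic distance must be non-negative")
  base <- if (gamma$sigma_f == 0) 0 * d else gamma$sigma_f^2 * exp(-d / (2 * gamma$ell))
  if (same_extant_taxon) base + gamma$sigma_n^2 else base
}

#' Covariance matrix over a set of nodes
#'
#' Applies the marginal OU covariance elementwise to a patristic distance
#' matrix; `sigma_n^2` is added on the diagonal entries of extant taxa only.
#'
#' @param gamma A `pgp_hyperparams` object.
#' @param dist Patristic distance matrix (named).
#' @param extant Character vector of ids that are extant tips, or `TRUE` for
#'   all rows (the default, appropriate for tip-only matrices).
#' @return Symmetric positive semidefinite covariance matrix.
#' @export
cov_matrix <- function(gamma, dist, extant = TRUE) {
  D <- as.matrix(dist)
  if (any(D < 0)) stopf("patristic distances must be non-negative")
  K <- phylo_cov_part(gamma, D)
  ids <- rownames(D)
  ex <- if (isTRUE(extant)) rep(TRUE, nrow(D)) else ids %in% extant
  diag(K) <- diag(K) + ifelse(ex, gamma$sigma_n^2, 0)
  dimnames(K) <- dimnames(D)
  K
}

#' Gaussian log marginal likelihood of tip coefficients
#'
#' Log density of `y` under the zero-mean Gaussian with covariance
#' `K = sigma_f^2 exp(-D/(2 ell)) + sigma_n^2 I` over the tips:
#' `-1/2 y' K^-1 y - 1/2 log|K| - (n/2) log(2 pi)`, computed via Cholesky
#' with jitter fallback.
#'
#' @param y Coefficient vector at tips (named or in `dist` row order).
#' @param gamma A `pgp_hyperparams` object.
#' @param dist Tip patristic distance matrix.
#' @return The log marginal likelihood (scalar).
#' @export
log_marginal_likelihood <- function(y, gamma, dist) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (length(y) != n) stopf("length(y) = %d but dist has %d tips", length(y), n)
  if (!is.null(names(y)) && !is.null(rownames(D))) {
    if (!setequal(names(y), rownames(D))) stopf("names of y do not match dist")
    y <- y[rownames(D)]
  }
  K <- cov_matrix(gamma, D, extant = TRUE)
  L <- chol_safe(K)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(-0.5 * sum(y * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi))
}

#' Gaussian process posterior for unobserved nodes
#'
#' Conditions the phylogenetic OU process on coefficients observed at extant
#' tips and returns the joint Gaussian posterior at the target nodes:
#' mean `K(x*,x) K(x,x)^-1 y`, covariance
#' `K(x*,x*) - K(x*,x) K(x,x)^-1 K(x,x*)`. The prior mean is zero (centre the
#' data upstream). `K(x,x)` always carries `sigma_n^2` on its diagonal. With
#' `latent = FALSE` (default) a target that coincides with an observed tip
#' shares that tip's noise (its cross and self entries gain `sigma_n^2`), so
#' the posterior interpolates the observation; with `latent = TRUE` targets are
#' noise-free everywhere, giving the posterior of the phylogenetic component
#' only -- this is the mode used for ancestral reconstruction.
#'
#' @param y Named coefficient vector at observed tips.
#' @param gamma A `pgp_hyperparams` object.
#' @param dist_all Patristic distance matrix over observed tips and targets
#'   (named; typically `patristic(tree, include_internal = TRUE)`).
#' @param target_ids Ids of target nodes (rows of `dist_all`).
#' @param extant_ids Ids that are extant taxa; defaults to `names(y)`.
#' @param latent Reconstruct the noise-free phylogenetic component?
#' @return List with `mean`, `covariance`, `node_ids` (class `pgp_posterior`).
#' @export
gp_posterior <- function(y, gamma, dist_all, target_ids,
                         extant_ids = names(y), latent = FALSE) {
  D <- as.matrix(dist_all)
  ids <- rownames(D)
  if (is.null(ids)) stopf("dist_all must have row/column names")
  if (is.null(names(y))) stopf("y must be named by tip ids")
  miss <- setdiff(c(names(y), target_ids), ids)
  if (length(miss)) stopf("unknown node id(s): %s", paste(miss, collapse = ", "))

  obs <- names(y)
  sn2 <- gamma$sigma_n^2

  Kxx <- phylo_cov_part(gamma, D[obs, obs, drop = FALSE])
  diag(Kxx) <- diag(Kxx) + sn2
  Ksx <- phylo_cov_part(gamma, D[target_ids, obs, drop = FALSE])
  Kss <- phylo_cov_part(gamma, D[target_ids, target_ids, drop = FALSE])

  if (!latent && sn2 > 0) {
    # targets that are themselves extant taxa share the tip noise
    for (j in seq_along(target_ids)) {
      t_id <- target_ids[j]
      if (t_id %in% extant_ids) {
        if (t_id %in% obs) Ksx[j, match(t_id, obs)] <- Ksx[j, match(t_id, obs)] + sn2
        Kss[j, j] <- Kss[j, j] + sn2
      }
    }
  }

  L <- chol_safe(Kxx)
  solve_K <- function(B) backsolve(L, forwardsolve(t(L), B))
  mean_post <- as.numeric(Ksx %*% solve_K(y))
  cov_post <- symmetrize(Kss - Ksx %*% solve_K(t(Ksx)))
  names(mean_post) <- target_ids
  dimnames(cov_post) <- list(target_ids, target_ids)
  structure(list(mean = mean_post, covariance = cov_post, node_ids = target_ids),
            class = "pgp_posterior")
}

#' @export
print.pgp_posterior <- function(x, ...) {
  cat(sprintf("Gaussian posterior over %d node(s)\n", length(x$node_ids)))
  print(utils::head(data.frame(node = x$node_ids, mean = x$mean,
                               sd = sqrt(pmax(diag(x$covariance), 0)),
                               row.names = NULL), 10))
  if (length(x$node_ids) > 10) cat("  ...\n")
  invisible(x)
}
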