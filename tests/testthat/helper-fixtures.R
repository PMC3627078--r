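# Shared fixtures and independent oracles used across the suite.

tiny_tree <- function() read_newick("((A:1,B:2):0.5,C:3):0;")

cherry_tree <- function() read_newick("(A:1,B:1):0;")

rand_gamma <- function(sigma_n_max = 0.8) {
  hyperparams(stats::runif(1, 0.5, 2), stats::runif(1, 0.3, 2),
              stats::runif(1, 0, sigma_n_max))
}

# Brute-force conditional multivariate normal: partition a joint covariance
# over (observed, targets) and condition with dense solves. Independent of the
# package's Cholesky path.
brute_conditional <- function(K_joint, obs_idx, tar_idx, y) {
  Koo <- K_joint[obs_idx, obs_idx, drop = FALSE]
  Kto <- K_joint[tar_idx, obs_idx, drop = FALSE]
  Ktt <- K_joint[tar_idx, tar_idx, drop = FALSE]
  Koo_inv <- solve(Koo)
  list(mean = as.numeric(Kto %*% Koo_inv %*% y),
       cov = Ktt - Kto %*% Koo_inv %*% t(Kto))
}

# Dense-inverse Gaussian log-density oracle (no Cholesky).
dense_mvn_logdens <- function(y, K) {
  as.numeric(-0.5 * t(y) %*% solve(K) %*% y -
               0.5 * determinant(K, logarithm = TRUE)$modulus -
               0.5 * length(y) * log(2 * pi))
}

# Joint covariance over all nodes of a tree (tips noisy, internals noise-free).
joint_cov_all_nodes <- function(tree, gamma) {
  D <- patristic(tree, include_internal = TRUE)
  cov_matrix(gamma, D, extant = tree$tip.label)
}

# One simulated coefficient vector at the tips (OU + tip noise).
sim_tip_coeffs <- function(tree, gamma, seed) {
  y <- simulate_ou_on_tree(tree, gamma, seed = seed)[1, tree$tip.label]
  add_tip_noise(y, gamma$sigma_n, seed = seed + 500000L)
}
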