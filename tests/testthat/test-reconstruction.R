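oracle_sep <- function(sim) {
  as_separation(sim$truth$basis, sim$truth$X)
}

test_that("a noiseless single-component tip reconstruction interpolates", {
  tr <- rescale_tree(random_tree(12, seed = 401), 8.22)
  b1 <- basis_set(default_basis(64)$grid, default_basis(64)$curves[1, , drop = FALSE])
  g <- list(hyperparams(2, 3, 0))
  sim <- synthesize_dataset(tr, b1, g, seed = 31)
  sep <- oracle_sep(sim)
  post <- reconstruct_node(sep, g, tr, "t3")
  expect_equal(post$mean_curve, unname(sim$tips$curves["t3", ]),
               tolerance = 1e-6)
  expect_lt(max(post$phylo_sd_curve), 1e-5)
  expect_true(all(post$nonphylo_sd_curve == 0))
})

test_that("pointwise variance adds across independent components", {
  tr <- rescale_tree(random_tree(10, seed = 411), 8.22)
  sim <- synthesize_dataset(tr, default_basis(64), default_gammas(8.22), seed = 37)
  sep <- oracle_sep(sim)
  gam <- default_gammas(8.22)
  post <- reconstruct_node(sep, gam, tr, "node11")
  v <- post$coeff_posteriors$var
  B2 <- sim$truth$basis$curves^2
  expect_equal(post$phylo_sd_curve^2, as.numeric(colSums(v * B2)),
               tolerance = 1e-10)
  mu <- post$coeff_posteriors$mean
  expect_equal(post$mean_curve,
               as.numeric(colSums(mu * sim$truth$basis$curves)),
               tolerance = 1e-10)
  # tip target additionally reports the non-phylogenetic band
  tip_post <- reconstruct_node(sep, gam, tr, "t1")
  sn2 <- vapply(gam, function(g) g$sigma_n^2, numeric(1))
  expect_equal(tip_post$nonphylo_sd_curve, sqrt(as.numeric(colSums(sn2 * B2))),
               tolerance = 1e-12)
})

test_that("reconstruct_all covers exactly the internal nodes", {
  tr <- cherry_tree()
  sim <- synthesize_dataset(tr, default_basis(32),
                            list(hyperparams(1, 1, 0.2), hyperparams(0, NA, 1),
                                 hyperparams(1, 0.5, 0.2)), seed = 41)
  sep <- oracle_sep(sim)
  posts <- reconstruct_all(sep, default_gammas(2), tr)
  expect_equal(names(posts), "node3")

  tr2 <- random_tree(9, seed = 421)
  sim2 <- synthesize_dataset(tr2, default_basis(32), default_gammas(tree_l_max(tr2)),
                             seed = 43)
  posts2 <- reconstruct_all(oracle_sep(sim2), default_gammas(tree_l_max(tr2)), tr2)
  expect_equal(length(posts2), tr2$Nnode)
  posts3 <- reconstruct_all(oracle_sep(sim2), default_gammas(tree_l_max(tr2)), tr2,
                            include_tips = TRUE)
  expect_equal(length(posts3), tr2$Nnode + 9)
  expect_error(reconstruct_node(oracle_sep(sim2), default_gammas(tree_l_max(tr2)),
                                tr2, "nodeXYZ"), "unknown node")
})

test_that("posterior mean curves are linear in the observations", {
  tr <- random_tree(8, seed = 431)
  gam <- default_gammas(tree_l_max(tr))
  sim <- synthesize_dataset(tr, default_basis(48), gam, seed = 47)
  sep1 <- oracle_sep(sim)
  sep2 <- as_separation(sim$truth$basis, 2 * sim$truth$X)
  p1 <- reconstruct_node(sep1, gam, tr, "node9")
  p2 <- reconstruct_node(sep2, gam, tr, "node9")
  expect_equal(p2$mean_curve, 2 * p1$mean_curve, tolerance = 1e-9)
  expect_equal(p2$phylo_sd_curve, p1$phylo_sd_curve, tolerance = 1e-12)
})

test_that("standardized ancestral residuals are calibrated in oracle mode", {
  g <- hyperparams(1.8, 3.0, 0.4)
  z <- c()
  for (r in 1:6) {
    tr <- rescale_tree(random_tree(20, seed = 440 + r), 8.22)
    vals <- simulate_ou_on_tree(tr, g, seed = 900 + r)[1, ]
    y <- add_tip_noise(vals[tr$tip.label], g$sigma_n, seed = 950 + r)
    internal <- setdiff(node_ids(tr), tr$tip.label)
    post <- gp_posterior(y, g, patristic(tr, TRUE), target_ids = internal,
                         latent = TRUE)
    sds <- sqrt(pmax(diag(post$covariance), 0))
    z <- c(z, (vals[internal] - post$mean) / sds)
  }
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("true ancestral curves fall inside the 2-sd band about 95% of the time", {
  gs <- default_gammas(8.22)
  cov_frac <- vapply(1:5, function(r) {
    tr <- rescale_tree(random_tree(24, seed = 460 + r), 8.22)
    sim <- synthesize_dataset(tr, default_basis(64), gs, seed = 470 + r)
    posts <- reconstruct_all(as_separation(sim$truth$basis, sim$truth$X), gs, tr)
    band_coverage(posts, sim$ancestors, width = 2)
  }, numeric(1))
  expect_gt(mean(cov_frac), 0.9)
})

test_that("the autocovariance estimate is a weighted Gram matrix, PSD", {
  flat <- basis_set(seq(0, 1, length.out = 16), matrix(1, 1, 16))
  ac <- autocovariance(flat, list(hyperparams(1, 1, 0)))
  expect_true(all(ac$values == 1))

  set.seed(451)
  for (i in 1:20) {
    k <- sample(1:4, 1)
    B <- matrix(stats::rnorm(k * 24), k, 24)
    gammas <- replicate(k, rand_gamma(), simplify = FALSE)
    ac <- autocovariance(basis_set(seq(0, 1, length.out = 24), B), gammas)
    expect_equal(ac$values, t(ac$values))
    ev <- eigen(ac$values, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * sum(diag(ac$values)) / 24)
    expect_equal(ac$weights,
                 vapply(gammas, function(g) g$sigma_f^2 + g$sigma_n^2,
                        numeric(1)))
  }
})
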