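test_that("pure-noise data recovers the total variance, flagged as non-phylogenetic", {
  # In the ell -> 0 limit the sigma_f / sigma_n split is not identifiable:
  # any phylogenetic variance the MLE reports comes with a length-scale far
  # below the observed tip distances, which is the absence-of-signal reading.
  # The recoverable quantities are the total standard deviation and that
  # diagnostic.
  for (r in 1:3) {
    tr <- random_tree(400, seed = 300 + r)
    D <- patristic(tr)
    set.seed(400 + r)
    y <- stats::rnorm(400)            # iid tips, sd 1
    names(y) <- tr$tip.label
    fit <- mle_gamma(y, D, seed = r)
    total_sd <- sqrt(fit$sigma_f^2 + fit$sigma_n^2)
    expect_lt(abs(total_sd - 1), 0.1)
    q01 <- stats::quantile(D[upper.tri(D)], 0.01)
    expect_true(fit$sigma_f < 0.5 || fit$ell < q01)
  }
})

test_that("degenerate zero data returns flagged boundary estimates", {
  tr <- random_tree(10, seed = 311)
  y <- numeric(10)
  names(y) <- tr$tip.label
  fit <- mle_gamma(y, patristic(tr))
  fl <- attr(fit, "flags")
  expect_true(fl$degenerate_data)
  expect_true(fl$sigma_f_at_bound && fl$sigma_n_at_bound)
})

test_that("the MLE dominates the true parameters on its own sample", {
  tr <- rescale_tree(random_tree(64, seed = 321), 8.22)
  g <- hyperparams(2.5, 6.17, 0.5)
  y <- sim_tip_coeffs(tr, g, seed = 17)
  D <- patristic(tr)
  fit <- mle_gamma(y, D, seed = 1)
  expect_gte(log_marginal_likelihood(y, fit, D) + 1e-6,
             log_marginal_likelihood(y, g, D))
})

test_that("known-ratio limits collapse to the noise-free and pure-noise models", {
  tr <- rescale_tree(random_tree(32, seed = 331), 8.22)
  g <- hyperparams(1.5, 2.06, 0.5)
  y <- sim_tip_coeffs(tr, g, seed = 23)
  D <- patristic(tr)

  inf_fit <- mle_gamma_known_ratio(y, D, ratio = Inf, seed = 2)
  expect_equal(inf_fit$sigma_n, 0)
  expect_gt(inf_fit$sigma_f, 0)

  zero_fit <- mle_gamma_known_ratio(y, D, ratio = 0, seed = 2)
  expect_equal(zero_fit$sigma_f, 0)
  expect_equal(zero_fit$sigma_n, sqrt(mean(y^2)))
  expect_true(attr(zero_fit, "flags")$ell_unidentifiable)
})

test_that("knowing the variance ratio stabilizes the phylogenetic sd", {
  n_rep <- 10
  free <- constrained <- numeric(n_rep)
  g <- hyperparams(2.5, 6.17, 0.5)
  for (r in 1:n_rep) {
    tr <- rescale_tree(random_tree(48, seed = 340 + r), 8.22)
    y <- sim_tip_coeffs(tr, g, seed = 600 + r)
    D <- patristic(tr)
    free[r] <- mle_gamma(y, D, n_restarts = 6, seed = r)$sigma_f
    constrained[r] <- mle_gamma_known_ratio(y, D, ratio = (2.5 / 0.5)^2,
                                            n_restarts = 6, seed = r)$sigma_f
  }
  expect_lte(stats::var(constrained), stats::var(free))
})

test_that("bagging aggregates by the mean and degenerates correctly", {
  tr <- rescale_tree(random_tree(24, seed = 351), 8.22)
  g <- hyperparams(1.5, 2.06, 0.5)
  y <- sim_tip_coeffs(tr, g, seed = 29)

  bag <- bagged_mle(y, tr, n_bags = 8, bag_size = 18, seed = 5, n_restarts = 5)
  expect_equal(bag$gamma_hat$sigma_f, mean(bag$per_bag$sigma_f))
  expect_equal(bag$gamma_hat$ell, mean(bag$per_bag$ell))
  expect_equal(bag$gamma_hat$sigma_n, mean(bag$per_bag$sigma_n))
  expect_equal(nrow(bag$per_bag), 8)

  # full-size bags are identical, so the spread collapses to zero
  full <- bagged_mle(y, tr, n_bags = 3, bag_size = 24, seed = 5, n_restarts = 5)
  expect_equal(unname(full$gamma_sd), c(0, 0, 0))
})

test_that("bagging reduces the across-replicate variance of sigma_f", {
  n_rep <- 8
  single <- bagged <- numeric(n_rep)
  g <- hyperparams(2.5, 6.17, 0.5)
  for (r in 1:n_rep) {
    tr <- rescale_tree(random_tree(64, seed = 360 + r), 8.22)
    y <- sim_tip_coeffs(tr, g, seed = 700 + r)
    single[r] <- mle_gamma(y, patristic(tr), n_restarts = 6, seed = r)$sigma_f
    bagged[r] <- bagged_mle(y, tr, n_bags = 20, bag_size = 50, seed = r,
                            n_restarts = 6)$gamma_hat$sigma_f
  }
  expect_lte(stats::var(bagged), stats::var(single))
})

test_that("estimation error of sigma_f shrinks with the number of taxa", {
  g <- hyperparams(2.5, 6.17, 0.5)
  mean_abs_err <- vapply(c(32, 128), function(n) {
    errs <- vapply(1:8, function(r) {
      tr <- rescale_tree(random_tree(n, seed = 370 + 10 * n + r), 8.22)
      y <- sim_tip_coeffs(tr, g, seed = 800 + 10 * n + r)
      abs(mle_gamma(y, patristic(tr), n_restarts = 6, seed = r)$sigma_f -
            g$sigma_f)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(mean_abs_err[2], mean_abs_err[1])
})

test_that("the robustness study returns the requested table", {
  empty <- robustness_study(0)
  expect_equal(nrow(empty), 0)
  expect_true(all(is.na(attr(empty, "medians"))))

  small <- robustness_study(3, n_tips = 24, n_restarts = 4, seed = 9)
  expect_equal(nrow(small), 3)
  expect_true(all(is.finite(small$rel_err_sigma_n)))
  expect_true(all(small$rel_err_sigma_f > -1))
})
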