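test_that("the marginal OU covariance takes its closed-form values", {
  g <- hyperparams(2.5, 6.17, 0.5)
  expect_equal(ou_cov(g, 0, same_extant_taxon = TRUE), 2.5^2 + 0.5^2) # 6.5
  expect_equal(ou_cov(hyperparams(1, 1, 0), 2), exp(-1))
  expect_lt(ou_cov(g, 1e6), 1e-12)
  expect_error(ou_cov(g, -0.1), "non-negative")
  expect_equal(ou_alpha(hyperparams(1, 2, 0)), 0.25)
  expect_equal(phylo_fraction(g), 6.25 / 6.5)
})

test_that("covariance matrices follow the kernel and stay PSD", {
  g0 <- hyperparams(1.3, 0.7, 0)
  tr <- cherry_tree()
  K <- cov_matrix(hyperparams(1, 1, 0), patristic(tr))
  expect_equal(unname(K[1, 2]), exp(-1))
  expect_equal(unname(diag(cov_matrix(g0, patristic(tiny_tree())))),
               rep(1.3^2, 3))

  set.seed(31)
  for (i in 1:100) {
    trr <- random_tree(sample(3:20, 1), seed = 4000 + i)
    K <- cov_matrix(rand_gamma(), patristic(trr))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * mean(diag(K)))
  }
})

test_that("log marginal likelihood matches an independent dense-inverse oracle", {
  v <- 2^2 + 0.3^2
  y0 <- 0.7
  expect_equal(log_marginal_likelihood(y0, hyperparams(2, 1, 0.3),
                                       matrix(0, 1, 1)),
               -0.5 * y0^2 / v - 0.5 * log(v) - 0.5 * log(2 * pi))

  set.seed(32)
  for (i in 1:30) {
    tr <- random_tree(sample(3:8, 1), seed = 5000 + i)
    g <- rand_gamma()
    D <- patristic(tr)
    y <- stats::rnorm(nrow(D))
    names(y) <- rownames(D)
    expect_equal(log_marginal_likelihood(y, g, D),
                 dense_mvn_logdens(y, cov_matrix(g, D)),
                 tolerance = 1e-8)
  }
})

test_that("likelihood scaling and taxon-reordering identities hold", {
  tr <- random_tree(12, seed = 51)
  D <- patristic(tr)
  g <- hyperparams(1.2, 0.9, 0.4)
  set.seed(52)
  y <- stats::rnorm(12)
  names(y) <- rownames(D)

  cc <- 3.7
  gc <- hyperparams(cc * g$sigma_f, g$ell, cc * g$sigma_n)
  expect_equal(log_marginal_likelihood(cc * y, gc, D),
               log_marginal_likelihood(y, g, D) - 12 * log(cc),
               tolerance = 1e-9)

  perm <- sample(rownames(D))
  expect_equal(log_marginal_likelihood(y[perm], g, D[perm, perm]),
               log_marginal_likelihood(y, g, D), tolerance = 1e-10)
})

test_that("in the independence limit the likelihood factorizes", {
  tr <- random_tree(10, seed = 61)
  D <- patristic(tr)
  g <- hyperparams(1.5, min(D[D > 0]) * 1e-5, 0.6)
  set.seed(62)
  y <- stats::rnorm(10)
  names(y) <- rownames(D)
  expect_equal(log_marginal_likelihood(y, g, D),
               sum(stats::dnorm(y, 0, sqrt(g$sigma_f^2 + g$sigma_n^2),
                                log = TRUE)),
               tolerance = 1e-6)
})

test_that("the GP posterior interpolates noiseless observations", {
  tr <- tiny_tree()
  Dall <- patristic(tr, include_internal = TRUE)
  g <- hyperparams(1.4, 1.1, 0)
  y <- c(A = 0.3, B = -1.2, C = 0.8)
  post <- gp_posterior(y, g, Dall, target_ids = "B")
  expect_equal(unname(post$mean), -1.2, tolerance = 1e-7)
  expect_lt(post$covariance[1, 1], 1e-7)
})

test_that("a far-away target reverts to the prior", {
  tr <- read_newick("(A:1,(B:1,C:1):200):0;")
  Dall <- patristic(tr, include_internal = TRUE)
  g <- hyperparams(1.3, 0.8, 0.2)
  post <- gp_posterior(c(B = 1.1, C = -0.4), g, Dall, target_ids = "A")
  expect_equal(unname(post$mean), 0, tolerance = 1e-8)
  expect_equal(unname(post$covariance[1, 1]), g$sigma_f^2, tolerance = 1e-8)
})

test_that("GP posterior agrees with brute-force conditioning, both modes", {
  set.seed(71)
  for (i in 1:40) {
    tr <- random_tree(sample(3:6, 1), seed = 6000 + i)
    g <- rand_gamma()
    ids <- node_ids(tr)
    tips <- tr$tip.label
    internal <- setdiff(ids, tips)
    y <- stats::rnorm(length(tips))
    names(y) <- tips
    tar <- sample(internal, min(2, length(internal)))
    latent <- i %% 2 == 0

    post <- gp_posterior(y, g, patristic(tr, TRUE), target_ids = tar,
                         latent = latent)
    Kj <- joint_cov_all_nodes(tr, g)  # internal targets carry no noise
    ref <- brute_conditional(Kj, match(tips, ids), match(tar, ids), y)
    expect_equal(post$mean, ref$mean, tolerance = 1e-7,
                 ignore_attr = TRUE)
    expect_equal(unname(post$covariance), unname(ref$cov), tolerance = 1e-7)
    # posterior variance never exceeds prior variance
    expect_true(all(diag(post$covariance) <= g$sigma_f^2 + 1e-9))
  }
})

test_that("non-latent tip targets share the observation noise", {
  tr <- tiny_tree()
  g <- hyperparams(1.2, 0.9, 0.5)
  y <- c(A = 0.4, B = -0.7, C = 1.1)
  ids <- node_ids(tr)
  Kj <- cov_matrix(g, patristic(tr, TRUE), extant = tr$tip.label)
  post <- gp_posterior(y, g, patristic(tr, TRUE), target_ids = "A",
                       latent = FALSE)
  ref <- brute_conditional(Kj, match(names(y), ids), match("A", ids), y)
  expect_equal(unname(post$mean), unname(y["A"]), tolerance = 1e-9)
  expect_equal(unname(post$mean), ref$mean, tolerance = 1e-9)
  expect_lt(post$covariance[1, 1], 1e-9)

  # latent mode instead shrinks towards the prior mean and keeps variance
  lat <- gp_posterior(y, g, patristic(tr, TRUE), target_ids = "A",
                      latent = TRUE)
  expect_lt(abs(lat$mean["A"]), abs(y["A"]))
  expect_gt(lat$covariance[1, 1], 0)
})
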