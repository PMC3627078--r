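# Hyperparameter estimation: per-component maximum likelihood for
# gamma = (sigma_f, ell, sigma_n) from tip coefficients via the Gaussian
# marginal likelihood, with multi-start box-constrained optimization in
# log-parameter space, an optional known-variance-ratio constrained variant,
# bootstrap aggregation (bagging) over random subtrees, and a
# tree-and-parameter randomized robustness study.

# Negative log-likelihood and its analytic gradient in
# theta = (log sigma_f, log ell, log sigma_n). With a fixed variance ratio
# r = sigma_f^2/sigma_n^2, theta = (log sigma_f, log ell) and
# sigma_n = sigma_f / sqrt(r).
make_nll <- function(y, D, ratio = NULL) {
  n <- length(y)
  I_n <- diag(n)
  const <- 0.5 * n * log(2 * pi)
  big <- 1e10

  unpack <- function(theta) {
    if (is.null(ratio)) {
      list(sf = exp(theta[1]), ell = exp(theta[2]), sn = exp(theta[3]))
    } else {
      sf <- exp(theta[1])
      list(sf = sf, ell = exp(theta[2]), sn = sf / sqrt(ratio))
    }
  }
  kernel_parts <- function(p) {
    E <- exp(-D / (2 * p$ell))
    K <- p$sf^2 * E + p$sn^2 * I_n
    list(E = E, K = K)
  }

  fn <- function(theta) {
    p <- unpack(theta)
    kp <- kernel_parts(p)
    L <- tryCatch(chol_safe(kp$K), error = function(e) NULL)
    if (is.null(L)) return(big)
    a <- backsolve(L, forwardsolve(t(L), y))
    val <- 0.5 * sum(y * a) + sum(log(diag(L))) + const
    if (!is.finite(val)) big else val
  }

  gr <- function(theta) {
    p <- unpack(theta)
    kp <- kernel_parts(p)
    L <- tryCatch(chol_safe(kp$K), error = function(e) NULL)
    if (is.null(L)) return(numeric(length(theta)))
    Kinv <- chol2inv(L)
    a <- Kinv %*% y
    # d(-ll)/d theta_j = -(1/2) a' dK a + (1/2) tr(Kinv dK)
    dneg <- function(dK) as.numeric(-0.5 * crossprod(a, dK %*% a) + 0.5 * sum(Kinv * dK))
    dK_lsf <- 2 * p$sf^2 * kp$E
    if (!is.null(ratio)) dK_lsf <- dK_lsf + 2 * p$sn^2 * I_n
    dK_lell <- p$sf^2 * kp$E * (D / (2 * p$ell))
    if (is.null(ratio)) {
      c(dneg(dK_lsf), dneg(dK_lell), dneg(2 * p$sn^2 * I_n))
    } else {
      c(dneg(dK_lsf), dneg(dK_lell))
    }
  }

  list(fn = fn, gr = gr)
}

boundary_gamma <- function(lb_sigma, lb_ell, loglik = -Inf) {
  g <- hyperparams(lb_sigma, lb_ell, lb_sigma)
  attr(g, "loglik") <- loglik
  attr(g, "flags") <- list(sigma_f_at_bound = TRUE, sigma_n_at_bound = TRUE,
                           ell_unidentifiable = TRUE, degenerate_data = TRUE)
  g
}

#' Maximum likelihood estimation of OU hyperparameters
#'
#' Maximizes the Gaussian marginal likelihood of tip coefficients over
#' `(log sigma_f, log ell, log sigma_n)` with box constraints and multi-start
#' L-BFGS-B (analytic gradients; starts from a seeded Latin hypercube plus one
#' deterministic centre start). Bounds default to `[1e-3, 1e3]` times the data
#' scale: `sd(y)` for the standard deviations, the maximum patristic distance
#' for the length-scale.
#'
#' When the optimum has `ell` near zero the phylogenetic and non-phylogenetic
#' variances are not separately identifiable (the kernel degenerates to
#' `(sigma_f^2 + sigma_n^2) I`): among restarts whose log-likelihoods tie
#' within `1e-4`, the candidate with the smallest `sigma_f` is returned, and
#' if `sigma_f` lies at its lower bound `ell` is reported at its lower bound
#' and flagged as unidentifiable.
#'
#' @param y Numeric coefficient vector at tips (length >= 3), named or in the
#'   row order of `dist`.
#' @param dist Tip patristic distance matrix.
#' @param bounds Optional list with elements `sigma` and `ell`, each a
#'   length-2 range overriding the default box.
#' @param n_restarts Number of Latin-hypercube restarts (default 10).
#' @param seed Optional integer seed (restart placement).
#' @param ratio Optional known variance ratio `sigma_f^2 / sigma_n^2`; see
#'   [mle_gamma_known_ratio()].
#' @return A `pgp_hyperparams` with attributes `loglik`, `flags` (boundary and
#'   identifiability flags) and `restarts` (per-restart summary table).
#' @export
mle_gamma <- function(y, dist, bounds = NULL, n_restarts = 10, seed = NULL,
                      ratio = NULL) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (length(y) != n) stopf("length(y) = %d but dist has %d tips", length(y), n)
  if (n < 3) stopf("need at least 3 tips")
  if (!is.null(names(y)) && !is.null(rownames(D))) {
    if (!setequal(names(y), rownames(D))) stopf("names of y do not match dist")
    y <- y[rownames(D)]
  }
  y <- as.numeric(y)
  if (!all(is.finite(y))) stopf("y must be finite")
  if (!is.null(ratio) && (!is.numeric(ratio) || ratio < 0)) stopf("ratio must be >= 0")

  s_y <- stats::sd(y)
  l_max <- max(D)
  lb_sigma <- 1e-3 * max(s_y, .Machine$double.eps)
  ub_sigma <- 1e3 * max(s_y, .Machine$double.eps)
  lb_ell <- 1e-3 * l_max
  ub_ell <- 1e3 * l_max
  if (!is.null(bounds$sigma)) { lb_sigma <- bounds$sigma[1]; ub_sigma <- bounds$sigma[2] }
  if (!is.null(bounds$ell)) { lb_ell <- bounds$ell[1]; ub_ell <- bounds$ell[2] }

  if (s_y < 1e-12) return(boundary_gamma(lb_sigma, lb_ell))

  # r = 0 is the pure-noise model: closed-form sigma_n, no phylogenetic part
  if (!is.null(ratio) && ratio == 0) {
    sn_hat <- sqrt(mean(y^2))
    g <- hyperparams(0, NA, sn_hat)
    attr(g, "loglik") <- sum(stats::dnorm(y, 0, sn_hat, log = TRUE))
    attr(g, "flags") <- list(sigma_f_at_bound = TRUE, sigma_n_at_bound = FALSE,
                             ell_unidentifiable = TRUE, degenerate_data = FALSE)
    return(g)
  }
  nllf <- make_nll(y, D, ratio = ratio)
  np <- if (is.null(ratio)) 3L else 2L
  lower <- log(c(lb_sigma, lb_ell, lb_sigma))[seq_len(np)]
  upper <- log(c(ub_sigma, ub_ell, ub_sigma))[seq_len(np)]

  # restart box (log-uniform): sigma in sd(y)*[0.05, 2], ell in l_max*[0.01, 1.5]
  set_seed_if(seed)
  H <- lhs::randomLHS(max(1, n_restarts), np)
  lo_start <- log(c(max(0.05 * s_y, lb_sigma), max(0.01 * l_max, lb_ell),
                    max(0.05 * s_y, lb_sigma)))[seq_len(np)]
  hi_start <- log(c(min(2 * s_y, ub_sigma), min(1.5 * l_max, ub_ell),
                    min(2 * s_y, ub_sigma)))[seq_len(np)]
  starts <- t(t(H) * (hi_start - lo_start) + lo_start)
  centre <- log(c(s_y / sqrt(2), 0.25 * l_max, s_y / sqrt(2)))[seq_len(np)]
  starts <- rbind(centre, starts)

  res <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    res[[i]] <- tryCatch(
      stats::optim(pmin(pmax(starts[i, ], lower), upper), nllf$fn, nllf$gr,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
  }
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) stopf("all %d restarts failed", length(res))
  res <- res[ok]

  vals <- vapply(res, function(r) r$value, numeric(1))
  best <- min(vals)
  # tie-break along the small-ell ridge: smallest sigma_f among near-ties
  cand <- which(vals <= best + 1e-4)
  pick <- cand[which.min(vapply(res[cand], function(r) r$par[1], numeric(1)))]
  par <- res[[pick]]$par

  sf <- exp(par[1])
  ell <- exp(par[2])
  sn <- if (is.null(ratio)) exp(par[3]) else sf / sqrt(ratio)

  flags <- list(sigma_f_at_bound = sf <= 2 * lb_sigma,
                sigma_n_at_bound = sn <= 2 * lb_sigma,
                ell_unidentifiable = FALSE,
                degenerate_data = FALSE)
  if (flags$sigma_f_at_bound) {
    # no phylogenetic variance: the length-scale is meaningless; report it at
    # its lower bound so absence of signal is visible downstream
    ell <- lb_ell
    flags$ell_unidentifiable <- TRUE
  }
  g <- hyperparams(sf, ell, sn)
  attr(g, "loglik") <- -res[[pick]]$value
  attr(g, "flags") <- flags
  attr(g, "restarts") <- data.frame(
    loglik = -vals,
    sigma_f = vapply(res, function(r) exp(r$par[1]), numeric(1)),
    ell = vapply(res, function(r) exp(r$par[2]), numeric(1)),
    convergence = vapply(res, function(r) r$convergence, numeric(1)))
  g
}

#' Constrained MLE with known variance ratio
#'
#' Two-parameter variant of [mle_gamma()] with
#' `sigma_n^2 = sigma_f^2 / ratio` substituted into the likelihood. The ratio
#' `sigma_f^2/sigma_n^2` is closely related to Pagel's lambda; when known a
#' priori it removes one dimension from a weakly identified problem.
#' `ratio = Inf` collapses to the noise-free model; `ratio = 0` to the
#' pure-noise model (with `sigma_n` in closed form and `ell` undefined).
#'
#' @inheritParams mle_gamma
#' @param ratio Known `sigma_f^2 / sigma_n^2`, in `[0, Inf]`.
#' @return A `pgp_hyperparams`, as in [mle_gamma()].
#' @export
mle_gamma_known_ratio <- function(y, dist, ratio, bounds = NULL,
                                  n_restarts = 10, seed = NULL) {
  if (is.infinite(ratio)) {
    # noise-free model: use the unconstrained machinery with an effectively
    # infinite ratio so sigma_n = sigma_f/sqrt(r) underflows to ~0
    g <- mle_gamma(y, dist, bounds = bounds, n_restarts = n_restarts,
                   seed = seed, ratio = 1e16)
    g$sigma_n <- 0
    return(g)
  }
  mle_gamma(y, dist, bounds = bounds, n_restarts = n_restarts, seed = seed,
            ratio = ratio)
}

#' Bagged maximum likelihood estimation
#'
#' Bootstrap-aggregated MLE of the hyperparameters: `n_bags` random subtrees
#' of `bag_size` tips are drawn by sampling tips without replacement (the
#' induced subtree preserves patristic distances exactly), the MLE is computed
#' on each, and the per-parameter estimates are averaged on the natural scale.
#' Per-bag spread is reported as the standard deviation across bags.
#'
#' Absence of phylogenetic signal is diagnosed from the aggregated
#' length-scale: `signal_absent_small_ell` when the bagged `ell` falls below
#' the 1st percentile of tip patristic distances (taxon-specific variation
#' masquerading as phylogenetic), `signal_absent_large_ell` when it exceeds
#' the 99th percentile (non-decaying variation indifferent to the tree).
#'
#' @param y Named coefficient vector over all tips of `tree`.
#' @param tree A `phylo` object.
#' @param n_bags Number of bags (default 100).
#' @param bag_size Tips per bag; default `round(100/128 * n_tips)`.
#' @param seed Optional integer seed.
#' @param ratio Optional known variance ratio, passed to the per-bag MLE.
#' @param n_restarts Restarts per bag (default 10).
#' @return An object of class `pgp_bag`: `gamma_hat`, `gamma_sd`, `per_bag`
#'   (data frame), `n_bags`, `bag_size`, `diagnostics`, `n_failed`.
#' @export
bagged_mle <- function(y, tree, n_bags = 100, bag_size = NULL, seed = NULL,
                       ratio = NULL, n_restarts = 10) {
  validate_tree(tree)
  tips <- tree$tip.label
  n <- length(tips)
  if (is.null(names(y))) {
    if (length(y) != n) stopf("y must cover all %d tips", n)
    names(y) <- tips
  }
  if (!setequal(names(y), tips)) stopf("names of y must match the tree's tips")
  y <- y[tips]
  if (is.null(bag_size)) bag_size <- round(100 / 128 * n)
  if (bag_size < 3 || bag_size > n) stopf("bag_size must be in [3, n_tips]")

  D <- patristic(tree)
  per_bag <- data.frame(bag = seq_len(n_bags), sigma_f = NA_real_,
                        ell = NA_real_, sigma_n = NA_real_, loglik = NA_real_)
  for (b in seq_len(n_bags)) {
    set_seed_if(split_seed(seed, b, 0L))
    idx <- if (bag_size == n) tips else sample(tips, bag_size)
    # seed the per-bag optimizer from the bag content so identical bags give
    # identical estimates (and the full-tree "bag" is deterministic)
    pos <- sort(match(idx, tips))
    bag_hash <- sum(pos * seq_along(pos)) %% 1000003
    fit <- tryCatch(
      mle_gamma(y[idx], D[idx, idx, drop = FALSE],
                seed = split_seed(seed, bag_hash, 1L),
                n_restarts = n_restarts, ratio = ratio),
      error = function(e) NULL)
    if (!is.null(fit)) {
      per_bag$sigma_f[b] <- fit$sigma_f
      per_bag$ell[b] <- fit$ell
      per_bag$sigma_n[b] <- fit$sigma_n
      per_bag$loglik[b] <- attr(fit, "loglik")
    }
  }
  failed <- is.na(per_bag$sigma_f)
  if (any(failed)) warning(sprintf("%d of %d bags failed and were dropped",
                                   sum(failed), n_bags))
  if (mean(failed) > 0.2) stopf("more than 20%% of bags failed (%d of %d)",
                                sum(failed), n_bags)
  pb <- per_bag[!failed, , drop = FALSE]

  gamma_hat <- hyperparams(mean(pb$sigma_f), mean(pb$ell), mean(pb$sigma_n))
  gamma_sd <- c(sigma_f = stats::sd(pb$sigma_f), ell = stats::sd(pb$ell),
                sigma_n = stats::sd(pb$sigma_n))

  dvec <- D[upper.tri(D)]
  q <- stats::quantile(dvec, c(0.01, 0.99), names = FALSE)
  diagnostics <- list(signal_absent_small_ell = gamma_hat$ell < q[1],
                      signal_absent_large_ell = gamma_hat$ell > q[2],
                      ell_percentiles = q)

  structure(list(gamma_hat = gamma_hat, gamma_sd = gamma_sd, per_bag = pb,
                 n_bags = n_bags, bag_size = bag_size,
                 diagnostics = diagnostics, n_failed = sum(failed)),
            class = "pgp_bag")
}

#' @export
print.pgp_bag <- function(x, ...) {
  g <- x$gamma_hat
  cat(sprintf("bagged MLE over %d bags of %d tips (%d failed):\n",
              x$n_bags, x$bag_size, x$n_failed))
  cat(sprintf("  sigma_f = %.3f (%.3f)  ell = %.3f (%.3f)  sigma_n = %.3f (%.3f)\n",
              g$sigma_f, x$gamma_sd["sigma_f"], g$ell, x$gamma_sd["ell"],
              g$sigma_n, x$gamma_sd["sigma_n"]))
  if (x$diagnostics$signal_absent_small_ell)
    cat("  diagnostic: length-scale unrealistically small -- phylogenetic signal absent\n")
  if (x$diagnostics$signal_absent_large_ell)
    cat("  diagnostic: length-scale unrealistically large -- phylogenetic signal absent\n")
  invisible(x)
}

#' Randomized robustness study of the estimation procedure
#'
#' Repeatedly regenerates a random tree and a random hyperparameter vector,
#' simulates tip coefficients (phylogenetic OU plus tip noise), re-estimates
#' gamma by (unbagged) maximum likelihood, and records the per-parameter
#' relative errors `(hat - true)/true`.
#'
#' The default sampling prior draws `sigma_f` and `sigma_n` log-uniformly on
#' `[0.25, 4]` and `ell` log-uniformly on `[0.1, 1] * l_max` of each tree.
#'
#' @param n_runs Number of runs.
#' @param n_tips Tips per regenerated tree (default 64).
#' @param branch_dist Branch-length specification for the random trees.
#' @param sigma_range Range of the log-uniform prior for both sigmas.
#' @param ell_frac_range Range of the log-uniform prior for `ell / l_max`.
#' @param n_restarts Restarts per MLE (default 6).
#' @param seed Optional integer seed.
#' @return Data frame with one row per run (true values, estimates, relative
#'   errors, failure flag); medians of the relative errors in attribute
#'   `medians`.
#' @export
robustness_study <- function(n_runs, n_tips = 64,
                             branch_dist = default_branch_dist(),
                             sigma_range = c(0.25, 4),
                             ell_frac_range = c(0.1, 1.0),
                             n_restarts = 6, seed = NULL) {
  cols <- c("run", "sigma_f", "ell", "sigma_n",
            "sigma_f_hat", "ell_hat", "sigma_n_hat",
            "rel_err_sigma_f", "rel_err_ell", "rel_err_sigma_n", "failed")
  out <- as.data.frame(matrix(NA_real_, nrow = n_runs, ncol = length(cols),
                              dimnames = list(NULL, cols)))
  if (n_runs == 0) {
    attr(out, "medians") <- c(sigma_f = NA_real_, ell = NA_real_, sigma_n = NA_real_)
    return(out)
  }
  runif_log <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  for (r in seq_len(n_runs)) {
    tree <- random_tree(n_tips, branch_dist, seed = split_seed(seed, r, 0L))
    lmax <- tree_l_max(tree)
    set_seed_if(split_seed(seed, r, 1L))
    g <- hyperparams(runif_log(sigma_range[1], sigma_range[2]),
                     runif_log(ell_frac_range[1], ell_frac_range[2]) * lmax,
                     runif_log(sigma_range[1], sigma_range[2]))
    yv <- simulate_ou_on_tree(tree, g, seed = split_seed(seed, r, 2L))[1, tree$tip.label]
    yv <- add_tip_noise(yv, g$sigma_n, seed = split_seed(seed, r, 3L))
    fit <- tryCatch(
      mle_gamma(yv, patristic(tree), n_restarts = n_restarts,
                seed = split_seed(seed, r, 4L)),
      error = function(e) NULL)
    out$run[r] <- r
    out$sigma_f[r] <- g$sigma_f; out$ell[r] <- g$ell; out$sigma_n[r] <- g$sigma_n
    out$failed[r] <- is.null(fit)
    if (!is.null(fit)) {
      out$sigma_f_hat[r] <- fit$sigma_f
      out$ell_hat[r] <- fit$ell
      out$sigma_n_hat[r] <- fit$sigma_n
      out$rel_err_sigma_f[r] <- (fit$sigma_f - g$sigma_f) / g$sigma_f
      out$rel_err_ell[r] <- (fit$ell - g$ell) / g$ell
      out$rel_err_sigma_n[r] <- (fit$sigma_n - g$sigma_n) / g$sigma_n
    }
  }
  attr(out, "medians") <- c(
    sigma_f = stats::median(out$rel_err_sigma_f, na.rm = TRUE),
    ell = stats::median(out$rel_err_ell, na.rm = TRUE),
    sigma_n = stats::median(out$rel_err_sigma_n, na.rm = TRUE))
  out
}
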