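test_that("decline factor matches its closed form and limits", {
  expect_equal(decline_factor(0, 0), 1)
  expect_equal(decline_factor(7.3, 0), 1) # k = 0 is 1 for any d
  expect_equal(decline_factor(0, 1), 0.75)
  expect_equal(decline_factor(0, 2), 2 / 3)
  expect_equal(decline_factor(50, 2), 1, tolerance = 1e-12)
  expect_equal(decline_factor(-50, 2), 1 / 3, tolerance = 1e-12)
})

test_that("truncated Poisson pmf is the renormalized Poisson head", {
  expect_equal(truncated_poisson_pmf(0.2, 2), c(1, 0.2, 0.02) / 1.22,
               tolerance = 1e-12)
  expect_equal(truncated_poisson_pmf(1e-12, 2), c(1, 0, 0), tolerance = 1e-9)
  for (theta in c(0.05, 0.5, 2, 10)) {
    p <- truncated_poisson_pmf(theta, 3)
    expect_equal(sum(p), 1)
    expect_true(all(p > 0))
  }
  expect_error(truncated_poisson_pmf(0, 2))
})

test_that("conditional densities reduce correctly at k = 0", {
  gp <- gamma_params(m = 2)
  x <- c(95, 130)
  expect_equal(conditional_logdensity(gp, 0, x),
               dgamma(x, shape = gp$alpha, rate = gp$beta, log = TRUE))
  np <- gaussian_params(m = 2)
  expect_equal(conditional_logdensity(np, 0, x),
               dnorm(x, np$mu, sqrt(np$var), log = TRUE))
  expect_error(conditional_logdensity(gp, 3, x), "k outside")
  expect_error(conditional_logdensity(gp, 0, c(1, 2, 3)), "length")
})

test_that("without decline a doublet's conditional mean is twice the singlet mean", {
  gp <- gamma_params(m = 1, d = 50) # f -> 1
  cond_dens <- function(params, k) {
    function(x) vapply(x, function(v) exp(conditional_logdensity(params, k, v)),
                       numeric(1))
  }
  mean_k1 <- integrate(function(x) x * cond_dens(gp, 1)(x), 0, 2000,
                       rel.tol = 1e-10)$value
  expect_equal(mean_k1, 2 * gp$alpha / gp$beta, tolerance = 1e-6)
})

test_that("conditional densities integrate to one", {
  cond_dens <- function(params, k) {
    function(x) vapply(x, function(v) exp(conditional_logdensity(params, k, v)),
                       numeric(1))
  }
  gp <- gamma_params(m = 1, d = 0.5)
  for (k in 0:2) {
    total <- integrate(cond_dens(gp, k), 0, 2000, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  np <- gaussian_params(m = 1)
  for (k in 0:2) {
    total <- integrate(cond_dens(np, k), -500, 1000, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  mp <- cp_params("gaussian-mvg", theta = 0.2, d = 0.5, mu = 100,
                  cov = matrix(50), modality = "ADT")
  total <- integrate(function(x) {
    vapply(x, function(v) exp(conditional_logdensity(mp, 1, v)), numeric(1))
  }, -500, 1000, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("conditional means respect the between-1-and-k+1 bounds", {
  set.seed(10)
  for (rep in 1:50) {
    d <- runif(1, -8, 8)
    k <- sample(1:3, 1)
    f <- decline_factor(d, k)
    ratio <- (k + 1) * f # E[X|K=k] / E[X|K=0]
    expect_gt(ratio, 1)
    expect_lt(ratio, k + 1)
  }
})

test_that("joint likelihood collapses to the singlet model as theta -> 0", {
  gp <- gamma_params(m = 3, theta = 1e-9)
  set.seed(11)
  X <- matrix(rgamma(30, 100, 1), 10, 3)
  plain <- -sum(dgamma(X, shape = rep(gp$alpha, each = 10),
                       rate = rep(gp$beta, each = 10), log = TRUE))
  expect_equal(joint_negloglik(gp, X), plain, tolerance = 1e-6)
})

test_that("joint likelihood equals a hand-computed scalar mixture", {
  gp <- gamma_params(m = 1, theta = 0.3, d = 0.2)
  x <- matrix(150, 1, 1)
  pi_ <- truncated_poisson_pmf(0.3, 2)
  mix <- sum(vapply(0:2, function(k) {
    pi_[k + 1] * exp(conditional_logdensity(gp, k, 150))
  }, numeric(1)))
  expect_equal(joint_negloglik(gp, x), -log(mix), tolerance = 1e-12)
})

test_that("joint likelihood is additive over droplets", {
  gp <- gamma_params(m = 2)
  set.seed(12)
  X <- matrix(rgamma(20, 100, 1), 10, 2)
  expect_equal(joint_negloglik(gp, rbind(X, X)), 2 * joint_negloglik(gp, X),
               tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  set.seed(13)
  X <- matrix(rgamma(200 * 4, 90, 1), 200, 4)
  obj_g <- multipletr:::.make_gamma_objective(pmax(X, 0.5), 2)
  par_g <- c(log(0.15), 0.4, log(runif(4, 60, 130)), log(runif(4, 0.8, 1.2)))
  expect_equal(obj_g$gr(par_g), central_diff_grad(obj_g$fn, par_g),
               tolerance = 1e-5)
  Xn <- matrix(rnorm(200 * 4, 100, 8), 200, 4)
  obj_n <- multipletr:::.make_gaussian_objective(Xn, 2)
  par_n <- c(log(0.15), 0.4, colMeans(Xn) * 0.97, log(apply(Xn, 2, var)))
  expect_equal(obj_n$gr(par_n), central_diff_grad(obj_n$fn, par_n),
               tolerance = 1e-5)
})

test_that("posterior matches the brute-force Bayes oracle on small instances", {
  for (seed in 1:8) {
    params <- random_small_params(seed)
    set.seed(seed + 100)
    n <- sample(5:20, 1)
    m <- length(params$feature_names)
    X <- if (params$family == "gamma") {
      matrix(rgamma(n * m, 80, 1), n, m)
    } else {
      matrix(rnorm(n * m, 100, 12), n, m)
    }
    post <- cp_posterior(params, X)
    oracle <- brute_force_posterior(params, X)
    expect_lt(max(abs(post$probs - oracle)), 1e-10)
    expect_true(all(abs(rowSums(post$probs) - 1) < 1e-9))
  }
})

test_that("extreme observations pin the posterior to the right class", {
  gp <- gamma_params(m = 1, theta = 0.2, d = 10, alpha = 100, beta = 1)
  post <- cp_posterior(gp, matrix(c(200, 100), 2, 1))
  expect_gt(post$probs[1, "k1"], 0.99) # x = 200 is a clear doublet
  expect_gt(post$probs[2, "k0"], 0.99) # x at the singlet mean
})

test_that("posterior never yields NaN even deep in the tails", {
  gp <- gamma_params(m = 3, alpha = rep(100, 3), beta = rep(1, 3))
  X <- matrix(c(1e4, 1e4, 1e4, 0.5, 0.5, 0.5), 2, 3, byrow = TRUE)
  post <- cp_posterior(gp, X)
  expect_false(anyNA(post$probs))
  expect_true(all(abs(rowSums(post$probs) - 1) < 1e-9))
})

test_that("posterior mass moves to larger k as a droplet is scaled up", {
  gp <- gamma_params(m = 1, theta = 0.2, d = 0.5, alpha = 100, beta = 1)
  xs <- matrix(seq(80, 400, by = 20), ncol = 1)
  post <- cp_posterior(gp, xs)
  expect_true(all(diff(post$probs[, "k0"]) <= 1e-12))
})

test_that("classification follows the 0.5-boundary and smallest-k tie rules", {
  probs <- rbind(c(0.5, 0.5, 0), c(0.1, 0.7, 0.2), c(0.2, 0.3, 0.5))
  colnames(probs) <- c("k0", "k1", "k2")
  pt <- structure(list(probs = probs, k_max = 2L, source = "RNA"),
                  class = "posterior_table")
  calls <- classify_droplets(pt)
  expect_identical(calls$call, c("singlet", "multiplet", "multiplet"))
  expect_identical(calls$predicted_k, c(0L, 1L, 2L)) # tie at 0.5 -> k = 0
})

test_that("pure singlet data drives the fitted rate to (almost) zero", {
  set.seed(14)
  X <- matrix(rgamma(2000 * 8, rep(seq(60, 130, 10), each = 2000), 1), 2000, 8)
  fit <- fit_cp(X, "gamma", seed = 14)
  expect_lte(fit$params$theta, 0.02)
})

test_that("refitting identical data reproduces the likelihood exactly", {
  set.seed(15)
  gp <- gamma_params(m = 5, theta = 0.2)
  sim <- simulate_droplets(list(RNA = gp), n = 600, seed = 15)
  X <- sim$matrices$RNA$values
  f1 <- fit_cp(X, "gamma", seed = 3)
  f2 <- fit_cp(X, "gamma", seed = 3)
  expect_lt(abs(f1$diagnostics$negloglik - f2$diagnostics$negloglik), 1e-8)
  expect_equal(f1$params$theta, f2$params$theta)
})

test_that("parameter recovery sharpens with sample size", {
  gp <- gamma_params(m = 6, theta = 0.2, d = 0.5,
                     alpha = seq(60, 140, length.out = 6))
  rmse <- function(n, seeds) {
    errs <- vapply(seeds, function(s) {
      sim <- simulate_droplets(list(RNA = gp), n = n, seed = s)
      fit <- fit_cp(sim$matrices$RNA$values, "gamma", seed = s)
      fit$params$theta - 0.2
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  expect_lte(rmse(4000, 1:6), rmse(300, 1:6))
})

test_that("fitted parameters survive a JSON round trip", {
  gp <- gamma_params(m = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_cp_params(gp, path)
  back <- read_cp_params(path)
  expect_equal(back$alpha, gp$alpha)
  expect_equal(back$theta, gp$theta)
  X <- matrix(c(90, 100, 110), 1, 3)
  expect_equal(joint_negloglik(back, X), joint_negloglik(gp, X))
  mp <- cp_params("gaussian-mvg", theta = 0.2, d = 0, mu = c(1, 2),
                  cov = matrix(c(2, 0.5, 0.5, 3), 2), modality = "ADT")
  write_cp_params(mp, path)
  back2 <- read_cp_params(path)
  expect_equal(back2$cov, mp$cov)
})
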