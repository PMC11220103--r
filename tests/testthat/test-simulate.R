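test_that("droplet values are the summed per-cell contributions", {
  # with a huge decline parameter, f = 1 and a doublet is the sum of two
  # i.i.d. singlet draws: mean and variance must both double
  gp <- gamma_params(m = 1, theta = 5, d = 50, alpha = 100, beta = 1)
  sim <- simulate_droplets(list(RNA = gp), n = 30000, seed = 40)
  X <- sim$matrices$RNA$values[, 1]
  k <- sim$labels$k
  expect_equal(mean(X[k == 1]), 200, tolerance = 0.02)
  expect_equal(var(X[k == 1]), 200, tolerance = 0.1)
})

test_that("a vanishing rate yields only singlets", {
  gp <- gamma_params(m = 2, theta = 1e-9)
  sim <- simulate_droplets(list(RNA = gp), n = 500, seed = 41)
  expect_true(all(sim$labels$k == 0))
  expect_true(all(sim$labels$call == "singlet"))
})

test_that("label frequencies follow the truncated Poisson prior", {
  gp <- gamma_params(m = 1, theta = 0.3)
  sim <- simulate_droplets(list(RNA = gp), n = 100000, seed = 42)
  pmf <- truncated_poisson_pmf(0.3, 2)
  obs <- tabulate(sim$labels$k + 1, 3) / 100000
  se <- sqrt(pmf * (1 - pmf) / 100000)
  expect_true(all(abs(obs - pmf) < 3 * se))
})

test_that("the same seed reproduces matrices exactly; modalities share labels", {
  gp <- gamma_params(m = 3, theta = 0.2)
  np <- gaussian_params(m = 2, theta = 0.2)
  s1 <- simulate_droplets(list(RNA = gp, ADT = np), n = 300, seed = 43)
  s2 <- simulate_droplets(list(RNA = gp, ADT = np), n = 300, seed = 43)
  expect_identical(s1$matrices$RNA$values, s2$matrices$RNA$values)
  expect_identical(s1$matrices$ADT$values, s2$matrices$ADT$values)
  expect_identical(s1$labels, s2$labels)
  # dropping the second modality must not change the first modality's draws
  s3 <- simulate_droplets(list(RNA = gp), n = 300, seed = 43)
  expect_identical(s1$matrices$RNA$values, s3$matrices$RNA$values)
})

test_that("singlet moments recover the gamma parameters at scale", {
  gp <- gamma_params(m = 4, theta = 0.2, alpha = c(60, 90, 120, 150))
  sim <- simulate_droplets(list(RNA = gp), n = 10000, seed = 44)
  X <- sim$matrices$RNA$values[sim$labels$k == 0, ]
  alpha_mom <- colMeans(X)^2 / apply(X, 2, var)
  expect_equal(unname(alpha_mom), c(60, 90, 120, 150), tolerance = 0.06)
})

test_that("rounded gamma output mimics integer count matrices", {
  gp <- gamma_params(m = 2)
  sim <- simulate_droplets(list(RNA = gp), n = 50, seed = 45,
                           round_counts = TRUE)
  expect_true(all(sim$matrices$RNA$values == round(sim$matrices$RNA$values)))
})

test_that("artificial multiplet counts follow the rounding contract", {
  set.seed(46)
  singlets <- tiny_counts(matrix(rgamma(1000 * 3, 100, 1), 1000, 3),
                          barcodes = sprintf("S%04d", 1:1000))
  out <- simulate_artificial_multiplets(singlets, doublet_rate = 0.10,
                                        triplet_rate = 0, seed = 46)
  expect_equal(sum(out$labels$k == 1), 100L)
  expect_equal(sum(out$labels$k == 0), 900L)
  expect_equal(nrow(out$labels), 1000L)
})

test_that("each artificial multiplet is the exact sum of its constituents", {
  set.seed(47)
  singlets <- tiny_counts(matrix(rgamma(200 * 4, 80, 1), 200, 4),
                          barcodes = sprintf("S%03d", 1:200))
  out <- simulate_artificial_multiplets(singlets, doublet_rate = 0.2,
                                        triplet_rate = 0.05, seed = 47)
  for (j in which(out$labels$k > 0)) {
    src <- strsplit(out$labels$constituents[j], ";")[[1]]
    expect_equal(length(src), out$labels$k[j] + 1)
    expect_false(anyDuplicated(src) > 0) # distinct within a multiplet
    expect_equal(unname(out$matrices$values[j, ]),
                 unname(colSums(singlets$values[src, , drop = FALSE])))
  }
  # multiplets dominate their constituents element-wise
  j <- which(out$labels$k == 1)[1]
  src <- strsplit(out$labels$constituents[j], ";")[[1]]
  expect_true(all(out$matrices$values[j, ] >= singlets$values[src[1], ]))
})

test_that("homotypic mode never mixes cell-type labels", {
  set.seed(48)
  singlets <- tiny_counts(matrix(rgamma(400 * 2, 90, 1), 400, 2),
                          barcodes = sprintf("S%03d", 1:400))
  type <- rep(c("T", "B"), each = 200)
  out <- simulate_artificial_multiplets(singlets, doublet_rate = 0.15,
                                        triplet_rate = 0.05,
                                        cell_labels = type,
                                        homotypic_label = "T", seed = 48)
  t_barcodes <- singlets$barcodes[type == "T"]
  for (j in which(out$labels$k > 0)) {
    src <- strsplit(out$labels$constituents[j], ";")[[1]]
    expect_true(all(src %in% t_barcodes))
  }
  expect_error(
    simulate_artificial_multiplets(singlets, 0.1, cell_labels = type,
                                   homotypic_label = "NK", seed = 1),
    "absent")
})

test_that("multi-modality artificial multiplets share constituents", {
  set.seed(49)
  rna <- tiny_counts(matrix(rgamma(100 * 3, 100, 1), 100, 3),
                     barcodes = sprintf("S%03d", 1:100))
  adt <- tiny_counts(matrix(rnorm(100 * 2, 100, 10)^2, 100, 2),
                     barcodes = sprintf("S%03d", 1:100), modality = "ADT")
  out <- simulate_artificial_multiplets(list(RNA = rna, ADT = adt),
                                        doublet_rate = 0.2, seed = 49)
  j <- which(out$labels$k == 1)[1]
  src <- strsplit(out$labels$constituents[j], ";")[[1]]
  expect_equal(unname(out$matrices$RNA$values[j, ]),
               unname(colSums(rna$values[src, , drop = FALSE])))
  expect_equal(unname(out$matrices$ADT$values[j, ]),
               unname(colSums(adt$values[src, , drop = FALSE])))
})

test_that("infeasible rates are rejected", {
  singlets <- tiny_counts(matrix(1, 4, 1))
  expect_error(simulate_artificial_multiplets(singlets, 0.6, 0.5, seed = 1))
})
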