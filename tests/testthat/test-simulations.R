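test_that("Gaussian entropy follows the determinant formula", {
  expect_equal(gaussian_entropy(diag(2)), 1 + log(2 * pi), tolerance = 1e-12)
  # determinant 1 -> same entropy as the identity
  expect_equal(gaussian_entropy(diag(c(2, 0.5))), gaussian_entropy(diag(2)),
               tolerance = 1e-12)

  # seeded SPD matrix vs an eigenvalue-product log-determinant oracle
  set.seed(15)
  A <- matrix(rnorm(25), 5, 5)
  S <- crossprod(A) + diag(5)
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(gaussian_entropy(S),
               5 / 2 + (5 / 2) * log(2 * pi) + sum(log(lam)),
               tolerance = 1e-8)

  expect_error(gaussian_entropy(matrix(c(1, 0, 1, 1), 2)),
               class = "clearf_not_spd")
  expect_error(gaussian_entropy(diag(c(1, -1))), class = "clearf_not_spd")
})

test_that("entropy simulation reports the squared Pearson correlation of its vectors", {
  sim <- simulate_entropy_correlation(60, 10, k = 1, reps = 50, seed = 9)
  expect_length(sim$entropies, 50)
  expect_length(sim$recon_errors, 50)
  expect_true(all(sim$recon_errors >= 0))
  expect_equal(sim$r_squared, cor(sim$entropies, sim$recon_errors)^2,
               tolerance = 1e-12)
  expect_gte(sim$r_squared, 0)
  expect_lte(sim$r_squared, 1)

  # affine rescaling of either vector leaves R^2 unchanged (Pearson property)
  expect_equal(cor(3 * sim$entropies - 7, sim$recon_errors)^2, sim$r_squared,
               tolerance = 1e-12)
})

test_that("entropy and reconstruction error are positively correlated", {
  for (seed in c(2, 31)) {
    sim <- simulate_entropy_correlation(150, 30, k = 1, reps = 40, seed = seed)
    expect_gt(cor(sim$entropies, sim$recon_errors), 0)
  }
})

test_that("a constant generator is flagged as degenerate", {
  const <- local({
    M <- matrix(rnorm(60 * 10), 60, 10)
    function(n, p) M
  })
  expect_error(
    simulate_entropy_correlation(60, 10, k = 1, reps = 5, seed = 1,
                                 generator = const),
    class = "clearf_degenerate_correlation")
  expect_error(simulate_entropy_correlation(60, 10, reps = 2, seed = 1),
               class = "clearf_invalid_spec")
  expect_error(simulate_entropy_correlation(10, 60, reps = 5, seed = 1),
               class = "clearf_invalid_spec")
})

test_that("generators are bit-identical under a fixed seed", {
  expect_identical(simulate_entropy_correlation(60, 10, reps = 5, seed = 3),
                   simulate_entropy_correlation(60, 10, reps = 5, seed = 3))
  expect_identical(generate_two_class_2d("separated", 100, seed = 4),
                   generate_two_class_2d("separated", 100, seed = 4))
  expect_identical(generate_informative(60, 3, 5, shift = 2, seed = 6),
                   generate_informative(60, 3, 5, shift = 2, seed = 6))
})

test_that("two-class 2D scenarios have the intended centroid geometry", {
  d_sep <- generate_two_class_2d("separated", 500, seed = 1)
  d_ovl <- generate_two_class_2d("overlapping", 500, seed = 1)
  for (d in list(d_sep, d_ovl)) {
    expect_identical(unname(d$class_counts), c(250L, 250L))
    expect_identical(d$feature_names, c("X1", "X2"))
  }
  centroid_gap <- function(d) {
    m1 <- colMeans(d$X[d$y == "c1", ]); m2 <- colMeans(d$X[d$y == "c2", ])
    pooled_sd <- mean(c(apply(d$X[d$y == "c1", ], 2, sd),
                        apply(d$X[d$y == "c2", ], 2, sd)))
    sqrt(sum((m1 - m2)^2)) / pooled_sd
  }
  expect_gte(centroid_gap(d_sep), 4)
  expect_lte(centroid_gap(d_ovl), 0.3)

  # opposing within-class trends in the separated scenario
  expect_gt(cor(d_sep$X[d_sep$y == "c1", 1], d_sep$X[d_sep$y == "c1", 2]), 0.5)
  expect_lt(cor(d_sep$X[d_sep$y == "c2", 1], d_sep$X[d_sep$y == "c2", 2]), -0.5)

  expect_error(generate_two_class_2d("separated", 2, seed = 1),
               class = "clearf_too_few_samples")
  expect_error(generate_two_class_2d("separated", 11, seed = 1),
               class = "clearf_invalid_spec")
})

test_that("informative generator balances classes and shifts only the informative block", {
  d <- generate_informative(300, 4, 6, shift = 3, n_classes = 3, seed = 2)
  expect_identical(unname(d$class_counts), rep(100L, 3))
  expect_identical(d$feature_names,
                   c(paste0("inf_", 1:4), paste0("noise_", 1:6)))
  m_by_class <- sapply(d$classes, function(cl) colMeans(d$X[d$y == cl, ]))
  # adjacent class means of informative features differ by about `shift`
  expect_equal(unname(m_by_class[1, "c2"] - m_by_class[1, "c1"]), 3,
               tolerance = 0.5)
  # noise features show no class shift beyond sampling noise
  expect_lt(max(abs(m_by_class[5:10, ])), 0.5)

  expect_error(generate_informative(20, 0, 0, shift = 1, seed = 1),
               class = "clearf_empty_feature_set")
  expect_error(generate_informative(20, 2, 2, shift = 1, n_classes = 1,
                                    seed = 1),
               class = "clearf_invalid_spec")
})

test_that("a null dataset yields no systematic top-group", {
  # with no informative block, the best score should not stand out from the
  # score distribution seed after seed
  hits <- vapply(1:10, function(s) {
    d <- generate_informative(80, 0, 40, shift = 0, seed = 400 + s)
    tab <- clearf_scores(d, score_config(embedding_spec("pca", 1)))
    top10 <- tab$feature[order(tab$rank)][1:10]
    mean(top10 %in% paste0("noise_", 1:10))
  }, numeric(1))
  # the first ten features are exchangeable with the rest: recall near the
  # chance level 10/40, far from the enrichment seen with a real shift
  expect_lt(mean(hits), 0.5)
})
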