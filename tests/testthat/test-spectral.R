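test_that("channel vectors normalize signals and flag degenerate input", {
  v <- channel_vector(matrix(c(10, 10, 10, 10,
                               0, 0, 0, 7,
                               0, 0, 0, 0), 3, byrow = TRUE))
  expect_equal(unlist(v[1, 1:4], use.names = FALSE), rep(0.25, 4))
  expect_equal(unlist(v[2, 1:4], use.names = FALSE), c(0, 0, 0, 1))
  expect_true(v$rejected[3])
  expect_false(any(v$rejected[1:2]))
})

test_that("the first moment places vectors on the channel axis", {
  m <- first_moment(matrix(c(1, 0, 0, 0,
                             0, 0, 0, 1,
                             0.25, 0.25, 0.25, 0.25), 3, byrow = TRUE))
  expect_equal(m, c(0, 3, 1.5))
  # invariant to overall signal scaling
  s <- matrix(c(5, 3, 1, 1), 1)
  expect_equal(first_moment(channel_vector(s)),
               first_moment(channel_vector(10 * s)))
})

test_that("k-means separates point-mass clusters and is seed-deterministic", {
  X <- rbind(matrix(rep(c(1, 0, 0, 0), 50), ncol = 4, byrow = TRUE),
             matrix(rep(c(0, 0, 0, 1), 50), ncol = 4, byrow = TRUE))
  model <- train_clusters(X, k = 2, seed = 7)
  res <- classify(model, X, rejection_fraction = 0)
  expect_equal(length(unique(res$label[1:50])), 1)
  expect_equal(length(unique(res$label[51:100])), 1)
  expect_false(res$label[1] == res$label[51])
  expect_false(any(res$rejected))

  model2 <- train_clusters(X, k = 2, seed = 7)
  expect_identical(model$means, model2$means)
})

test_that("fractional rejection discards exactly the requested count", {
  set.seed(151)
  X <- matrix(abs(rnorm(40)), 10, 4)
  X <- X / rowSums(X)
  model <- train_clusters(X, k = 2, seed = 3)
  res <- classify(model, X, rejection_fraction = 0.20)
  expect_equal(sum(res$rejected), 2)
  expect_equal(sum(is.na(res$label)), 2)
  res0 <- classify(model, X, rejection_fraction = 0)
  expect_equal(sum(res0$rejected), 0)
})

test_that("classification agrees with a brute-force nearest-mean oracle", {
  sigs <- list(dye_signature(c(0.55, 0.25, 0.15, 0.05)),
               dye_signature(c(0.25, 0.45, 0.20, 0.10)),
               dye_signature(c(0.10, 0.25, 0.45, 0.20)),
               dye_signature(c(0.05, 0.10, 0.30, 0.55)))
  sim <- simulate_spectral_localizations(sigs, n_per_dye = 400,
                                         mean_photons = 3000, seed = 157)
  vecs <- channel_vector(sim)
  model <- train_clusters(vecs, k = 4, seed = 11)
  res <- classify(model, vecs, rejection_fraction = 0)
  # oracle: explicit distance minimization against the trained means
  X <- as.matrix(vecs[, c("v1", "v2", "v3", "v4")])
  oracle <- apply(X, 1, function(r) {
    which.min(colSums((t(model$means) - r)^2))
  })
  expect_equal(res$label, as.integer(oracle))
})

test_that("cross-talk matrices count misassignments row-normalized", {
  perfect <- crosstalk_matrix(rep(1:3, each = 10), rep(1:3, each = 10), 3)
  expect_equal(perfect$matrix, diag(3))
  expect_equal(perfect$max_offdiag, 0)

  set.seed(163)
  tl <- sample(1:3, 300, replace = TRUE)
  al <- ifelse(runif(300) < 0.9, tl, sample(1:3, 300, replace = TRUE))
  ct <- crosstalk_matrix(tl, al, 3)
  expect_equal(rowSums(ct$matrix), rep(1, 3))
  # oracle: direct counting
  for (i in 1:3) for (j in 1:3) {
    expect_equal(ct$matrix[i, j], sum(tl == i & al == j) / sum(tl == i))
  }
  expect_warning(crosstalk_matrix(c(1, 1), c(1, 1), 2), "empty")
})

test_that("raising the rejection fraction does not raise cross-talk", {
  sigs <- list(dye_signature(c(0.45, 0.30, 0.15, 0.10)),
               dye_signature(c(0.15, 0.30, 0.35, 0.20)))
  sim <- simulate_spectral_localizations(sigs, n_per_dye = 1500,
                                         mean_photons = 500, seed = 167)
  vecs <- channel_vector(sim)
  model <- train_clusters(vecs, k = 2, seed = 13)
  xt <- sapply(c(0, 0.1, 0.2, 0.3), function(q) {
    res <- classify(model, vecs, rejection_fraction = q)
    # align cluster labels to true dyes by majority vote
    map <- sapply(1:2, function(cl) {
      tab <- table(sim$dye[!res$rejected][res$label[!res$rejected] == cl])
      as.integer(names(tab)[which.max(tab)])
    })
    lab <- map[res$label]
    crosstalk_matrix(sim$dye[!res$rejected], lab[!res$rejected],
                     2)$max_offdiag
  })
  expect_true(all(diff(xt) <= 1e-9))
})

test_that("first-moment thresholds classify well-separated dyes", {
  sigs <- list(dye_signature(c(0.7, 0.2, 0.07, 0.03)),
               dye_signature(c(0.05, 0.15, 0.25, 0.55)))
  sim <- simulate_spectral_localizations(sigs, n_per_dye = 500,
                                         mean_photons = 3000, seed = 173)
  vecs <- channel_vector(sim)
  m <- first_moment(vecs)
  lab <- classify_first_moment(m, m, sim$dye)
  expect_gt(mean(lab == sim$dye), 0.99)
})
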