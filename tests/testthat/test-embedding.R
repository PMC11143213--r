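test_that("loss components match their closed forms", {
  cfg <- embedder_config()
  d_a <- 400; d_t <- 136; d_z <- 32
  # at the standard-normal prior the KL term vanishes exactly
  flat_a <- rep(1 / d_a, d_a); flat_t <- rep(1 / d_t, d_t)
  at_prior <- loss_components(flat_a, flat_t, flat_a, flat_t,
                              mu = rep(0, d_z), sigma = rep(1, d_z), cfg)
  expect_equal(at_prior$l_kl, 0)
  # derived weights come from the dimensions, evaluated at alpha = 0.1
  expect_equal(at_prior$w_a, 0.1 / log(400), tolerance = 1e-12)
  expect_equal(at_prior$w_a, 0.016690, tolerance = 1e-4)
  expect_equal(at_prior$w_t, 0.9 / log(136))
  expect_equal(at_prior$w_kl, 0.015 / 32)
  # perfect one-hot reconstruction has (near-)zero cross-entropy
  onehot <- c(1, rep(0, d_a - 1))
  perfect <- loss_components(onehot, flat_t, onehot, flat_t,
                             rep(0, d_z), rep(1, d_z), cfg)
  expect_equal(perfect$l_a, -log(1 + 1e-9))
  expect_lt(abs(perfect$l_a), 1e-8)
  # weighted-sum identity
  expect_equal(
    at_prior$total,
    at_prior$w_a * at_prior$l_a + at_prior$w_t * at_prior$l_t +
      at_prior$w_kl * at_prior$l_kl,
    tolerance = 1e-12
  )
})

test_that("the as-printed audit formula flips the reconstruction sign", {
  d_a <- 4; d_t <- 4
  xa <- c(0.7, 0.1, 0.1, 0.1); xt <- rep(0.25, 4)
  std <- loss_components(xa, xt, xt, xt, rep(0, 2), rep(1, 2),
                         embedder_config(latent_dim = 2))
  lit <- loss_components(xa, xt, xt, xt, rep(0, 2), rep(1, 2),
                         embedder_config(latent_dim = 2, as_printed = TRUE))
  expect_equal(lit$l_a, -std$l_a)
  expect_gt(std$l_a, 0)
})

test_that("loss_components validates inputs", {
  expect_error(
    loss_components(rep(0.5, 2), rep(0.5, 2), rep(0.5, 3), rep(0.5, 2),
                    0, 1),
    "dimension mismatch"
  )
  expect_error(
    loss_components(rep(0.5, 2), rep(0.5, 2), rep(0.5, 2), rep(0.5, 2),
                    0, -1),
    "positive"
  )
})

test_that("weighted sampler draws proportionally, deterministically", {
  s <- make_weighted_sampler(c(1, 3), seed = 42)
  draws <- s(1e5)
  expect_lt(abs(mean(draws == 2) - 0.75), 0.02)
  # single record -> always that record
  s1 <- make_weighted_sampler(5, seed = 1)
  expect_true(all(s1(100) == 1))
  # fixed seed -> identical draw sequence, and the stream continues across calls
  a <- make_weighted_sampler(c(2, 1, 1), seed = 7)
  b <- make_weighted_sampler(c(2, 1, 1), seed = 7)
  expect_identical(c(a(10), a(10)), c(b(10), b(10)))
  # zero weights error unless the uniform fallback is requested
  expect_error(make_weighted_sampler(c(0, 0)), "uniform_fallback")
  u <- make_weighted_sampler(c(0, 0), seed = 1, uniform_fallback = TRUE)
  expect_setequal(unique(u(100)), c(1, 2))
})

small_training_fixture <- function() {
  memo("small_training", function() {
    com <- study_community(800, seed = 2)
    cfg <- embedder_config(hidden_sizes = c(32, 32), batch_size = 64,
                           max_epochs = 8, patience = 8, min_delta = 0,
                           seed = 3)
    list(com = com, cfg = cfg, fit = train_embedder(com$features, cfg))
  })
}

test_that("training reduces the loss and logs the weighted-sum identity", {
  fx <- small_training_fixture()
  log <- tidy(fx$fit)
  expect_lte(log$total[5], log$total[1])
  w <- fx$fit$weights
  expect_true(all(abs(
    log$total - (w$w_a * log$l_a + w$w_t * log$l_t + w$w_kl * log$l_kl)
  ) < 1e-6))
  expect_true(all(is.finite(log$val_total)))
})

test_that("training is reproducible under a fixed seed", {
  fx <- small_training_fixture()
  refit <- train_embedder(fx$com$features, fx$cfg)
  expect_identical(refit$val_loss, fx$fit$val_loss)
  expect_identical(refit$log, fx$fit$log)
  expect_identical(
    embed_barcodes(refit, fx$com$features),
    embed_barcodes(fx$fit, fx$com$features)
  )
})

test_that("embedding is a deterministic n x 32 map excluding flagged records", {
  fx <- small_training_fixture()
  mu <- embed_barcodes(fx$fit, fx$com$features)
  usable <- sum(!fx$com$features$flagged)
  expect_equal(dim(mu), c(usable, 32))
  expect_equal(rownames(mu),
               fx$com$features$barcode[!fx$com$features$flagged])
  # duplicating a record yields identical rows
  fm <- feature_matrix(fx$com$features)
  twice <- fm
  twice$x <- fm$x[c(1, 1), , drop = FALSE]
  twice$barcode <- fm$barcode[c(1, 1)]
  mu2 <- embed_barcodes(fx$fit, twice)
  expect_identical(mu2[1, ], mu2[2, ])
  # flagged records are excluded and reported
  flagged <- fx$com$features
  flagged$flagged[1] <- TRUE
  expect_message(mu3 <- embed_barcodes(fx$fit, flagged), "excluded")
  expect_equal(nrow(mu3), usable - 1)
})

test_that("glance summarises the fit", {
  fx <- small_training_fixture()
  g <- glance(fx$fit)
  expect_equal(g$latent_dim, 32L)
  expect_equal(g$n_train + g$n_val, sum(!fx$com$features$flagged))
})

test_that("latent space separates genomes (inter > intra distance)", {
  emb <- study_embedding(3000, seed = 1)
  com <- study_community(3000, seed = 1)
  mu <- emb$mu
  lab <- com$truth$genome[match(rownames(mu), com$truth$barcode)]
  d <- as.matrix(dist(mu))
  same <- outer(lab, lab, "==")
  ut <- upper.tri(d)
  expect_gt(mean(d[!same & ut]), mean(d[same & ut]))
})

test_that("weighted sampling raises the low-abundance share of training batches", {
  com <- study_community(3000, seed = 1)
  f <- dplyr::filter(com$features, !flagged)
  lab <- com$truth$genome[match(f$barcode, com$truth$barcode)]
  low <- lab == "genome3"
  weighted <- make_weighted_sampler(f$weight, seed = 11)(2e4)
  unweighted <- make_weighted_sampler(rep(1, nrow(f)), seed = 11)(2e4)
  expect_gt(mean(low[weighted]), mean(low[unweighted]))
})
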