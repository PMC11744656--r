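emb2 <- function(vals) embedding_table(matrix(vals, ncol = 1),
                                       gene_names = paste0("G", seq_along(vals)))
lat0 <- function(n) structure(list(gene_names = paste0("G", seq_len(n)),
                                   features = matrix(0, n, 1)),
                              class = "latent_features")

test_that("fusion attention weights are a softmax over genes", {
  # zero scoring layer -> uniform weights
  p <- fusion_params(2, 4)
  p$att_score$W[] <- 0; p$att_score$b[] <- 0
  fu <- fuse(emb2(rnorm(6)), lat0(6), params = p)
  expect_equal(unname(fu$alpha), rep(1 / 6, 6))
  expect_equal(ncol(fu$h0), 2L)

  # scores (ln 3, 0) -> weights (0.75, 0.25)
  p2 <- fusion_params(2, 4)
  p2$att_score$W[] <- c(1, 0); p2$att_score$b[] <- 0
  fu2 <- fuse(emb2(c(log(3), 0)), lat0(2), params = p2)
  expect_equal(unname(fu2$alpha), c(0.75, 0.25))
  expect_equal(fu2$h0_att, fu2$alpha * fu2$h0, ignore_attr = TRUE)

  # normalization holds for arbitrary parameters
  for (s in 1:5) {
    fu3 <- fuse(emb2(rnorm(10)), lat0(10), seed = s)
    expect_equal(sum(fu3$alpha), 1, tolerance = 1e-9)
    expect_true(all(fu3$alpha >= 0))
  }

  expect_error(fuse(emb2(1:3), lat0(4)), class = "grnlink_usage_error")
})

test_that("gene encoder is deterministic in eval mode and permutation-equivariant", {
  cfg <- predictor_config(hidden_dim = 8, n_heads = 2, ff_dim = 12)
  h1 <- matrix(rnorm(6 * 8), 6, 8)
  p <- with_seed_local(5, encoder_params(8, 12))
  a <- encode_genes(h1, p, cfg)
  b <- encode_genes(h1, p, cfg)
  expect_identical(a$h5, b$h5)

  # no positional encoding: permuting token rows permutes outputs identically
  perm <- c(4, 1, 6, 2, 5, 3)
  c_ <- encode_genes(h1[perm, ], p, cfg)
  expect_equal(c_$h5, a$h5[perm, ], tolerance = 1e-12)

  # each row is LayerNorm output: zero mean, unit (population) variance
  expect_equal(rowMeans(a$h5), rep(0, 6), tolerance = 1e-8)
  expect_equal(apply(a$h5, 1, function(r) mean(r^2)), rep(1, 6),
               tolerance = 1e-4)

  expect_error(encode_genes(matrix(0, 3, 9), cfg = cfg),
               class = "grnlink_config_error")
})

test_that("edge scores are sigmoid-affine in the ordered pair features", {
  h5 <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(paste0("G", 1:5), NULL))
  pairs <- data.frame(regulator = c("G1", "G2"), target = c("G2", "G1"))

  pz <- decoder_params(4); pz$dec$W[] <- 0; pz$dec$b[] <- 0
  expect_equal(score_edges(h5, pairs, pz)$score, c(0.5, 0.5))

  pb <- decoder_params(4); pb$dec$W[] <- 0; pb$dec$b[] <- log(3)
  expect_equal(score_edges(h5, pairs, pb)$score, c(0.75, 0.75))

  pg <- with_seed_local(3, decoder_params(4))
  sc <- score_edges(h5, pairs, pg)$score
  expect_false(isTRUE(all.equal(sc[1], sc[2])))  # direction sensitivity
  expect_true(all(sc >= 0 & sc <= 1))

  expect_error(score_edges(h5, data.frame(regulator = "G1", target = "GX")),
               class = "grnlink_usage_error")
})

test_that("clipped binary cross-entropy matches direct evaluation and stays finite", {
  expect_equal(bce_loss(1, 1), 0, tolerance = 1e-6)
  expect_equal(bce_loss(0.5, 1), log(2))
  set.seed(11)
  s <- runif(7); y <- rbinom(7, 1, 0.5)
  brute <- 0
  for (i in 1:7) brute <- brute - (y[i] * log(s[i]) + (1 - y[i]) * log(1 - s[i]))
  expect_equal(bce_loss(s, y), brute / 7)
  expect_true(is.finite(bce_loss(c(0, 1), c(1, 0))))
  expect_error(bce_loss(numeric(0), numeric(0)), class = "grnlink_usage_error")
})

test_that("negative sampling honours counts, disjointness, determinism and exhaustion", {
  pos <- edge_set(data.frame(regulator = rep("G1", 5), target = paste0("G", 2:6)))
  uni <- paste0("G", 1:30)
  n1 <- sample_negatives(pos, uni, ratio = 2, seed = 42)
  expect_equal(nrow(n1$edges), 10L)
  expect_true(all(n1$edges$label == 0L))
  expect_true(all(n1$edges$regulator == "G1"))
  expect_length(intersect(grnlink:::edge_keys(n1), grnlink:::edge_keys(pos)), 0)

  n2 <- sample_negatives(pos, uni, ratio = 2, seed = 42)
  expect_identical(n1$edges, n2$edges)

  # exclusion set respected
  n3 <- sample_negatives(pos, uni, ratio = 1, seed = 7, exclude = n1)
  expect_length(intersect(grnlink:::edge_keys(n3), grnlink:::edge_keys(n1)), 0)

  # exhausted candidate pool: 1 regulator, universe of 3, both non-self
  # targets already positive -> no candidates remain
  tiny <- edge_set(data.frame(regulator = c("A", "A"), target = c("B", "C")))
  expect_error(sample_negatives(tiny, c("A", "B", "C"), ratio = 1, seed = 1),
               class = "grnlink_structural_error")
})

test_that("predictor training descends, is reproducible, and separates separable toys", {
  bench <- small_benchmark(3)
  ds <- bench$dataset
  ae <- fit_autoencoder(ds$trajectory, quick_tcn(seed = 3))
  temporal <- encode_trajectory(ds$trajectory, ae)
  neg <- sample_negatives(ds$edges, ds$gene_names, 1, seed = 5)
  train <- grnlink:::combine_edges(ds$edges, neg)

  m1 <- train_predictor(ds$embeddings, temporal, train, quick_predictor(7))
  m2 <- train_predictor(ds$embeddings, temporal, train, quick_predictor(7))
  expect_identical(m1$loss, m2$loss)
  expect_lt(m1$loss[length(m1$loss)], m1$loss[1])

  expect_error(train_predictor(ds$embeddings, temporal, ds$edges,
                               quick_predictor()),
               class = "grnlink_structural_error")

  # linearly separable toy: positive targets carry +3 in the first embedding
  # coordinate, negative targets -3
  genes <- paste0("G", 1:12)
  E <- matrix(rnorm(12 * 2, sd = 0.1), 12, 2)
  E[7:9, 1] <- 3; E[10:12, 1] <- -3
  emb <- embedding_table(E, gene_names = genes)
  lat <- structure(list(gene_names = genes, features = matrix(0, 12, 2)),
                   class = "latent_features")
  edges <- edge_set(data.frame(
    regulator = rep(paste0("G", 1:3), 2),
    target = paste0("G", 7:12),
    label = rep(c(1L, 0L), each = 3)))
  m <- train_predictor(emb, lat, edges,
                       predictor_config(hidden_dim = 16, n_heads = 2,
                                        ff_dim = 16, seed = 2))
  sc <- predict(m, edges$edges[, 1:2], sort = FALSE)
  expect_equal(auroc(sc$score, edges$edges$label), 1)
})

test_that("prediction is deterministic, covers all-pairs and unseen regulators", {
  bench <- small_benchmark(4)
  ds <- bench$dataset
  ae <- fit_autoencoder(ds$trajectory, quick_tcn(seed = 4))
  temporal <- encode_trajectory(ds$trajectory, ae)
  neg <- sample_negatives(ds$edges, ds$gene_names, 1, seed = 6)
  m <- train_predictor(ds$embeddings, temporal,
                       grnlink:::combine_edges(ds$edges, neg),
                       quick_predictor(1))

  p1 <- predict(m, ds$edges$edges[, 1:2], sort = FALSE)
  p2 <- predict(m, ds$edges$edges[, 1:2], sort = FALSE)
  expect_identical(p1, p2)
  expect_true(all(p1$score >= 0 & p1$score <= 1))

  # training positives outrank the sampled negatives on average
  pn <- predict(m, neg$edges[, 1:2], sort = FALSE)
  expect_gt(mean(p1$score), mean(pn$score))

  # all-pairs combinatorics: 3 regulators x (20 - 1) targets
  ap <- predict(m, all_pairs = TRUE, regulators = ds$gene_names[1:3])
  expect_equal(nrow(ap), 3 * 19)
  expect_true(!is.unsorted(rev(ap$score)))

  # a gene never seen as a training-edge source is scored, not rejected
  sc <- predict(m, data.frame(regulator = ds$gene_names[15],
                              target = ds$gene_names[1]), sort = FALSE)
  expect_equal(nrow(sc), 1L)

  expect_error(predict(m, data.frame(regulator = "nope", target = "G001")),
               class = "grnlink_usage_error")
})

test_that("consistent gene relabeling leaves edge scores unchanged", {
  bench <- small_benchmark(6)
  ds <- bench$dataset
  ae <- fit_autoencoder(ds$trajectory, quick_tcn(seed = 6))
  temporal <- encode_trajectory(ds$trajectory, ae)
  neg <- sample_negatives(ds$edges, ds$gene_names, 1, seed = 2)
  train <- grnlink:::combine_edges(ds$edges, neg)
  m <- train_predictor(ds$embeddings, temporal, train, quick_predictor(9))
  base <- predict(m, train$edges[, 1:2], sort = FALSE)

  # relabel the gene universe consistently: features travel with genes and
  # no positional encoding exists, so scores must not move
  perm <- with_seed_local(8, sample(length(m$gene_names)))
  m_p <- m
  m_p$gene_names <- m$gene_names[perm]
  m_p$h0 <- m$h0[perm, ]
  got <- predict(m_p, train$edges[, 1:2], sort = FALSE)
  expect_equal(got$score, base$score, tolerance = 1e-10)
})

test_that("zeroed temporal features never improve training loss on temporal-signal data", {
  # planted signal is partly temporal; ablating the temporal branch at
  # inference must not reduce the training-set loss (checked over 5 seeds)
  deltas <- vapply(1:5, function(s) {
    bench <- small_benchmark(s)
    ds <- bench$dataset
    ae <- fit_autoencoder(ds$trajectory, quick_tcn(seed = s, epochs = 10))
    temporal <- encode_trajectory(ds$trajectory, ae)
    neg <- sample_negatives(ds$edges, ds$gene_names, 1, seed = s)
    train <- grnlink:::combine_edges(ds$edges, neg)
    m <- train_predictor(ds$embeddings, temporal, train, quick_predictor(s))
    ed <- train$edges
    src <- match(ed$regulator, m$gene_names)
    dst <- match(ed$target, m$gene_names)
    full <- grnlink:::predictor_fwd(m$h0, src, dst, m$params, m$cfg, FALSE)
    l_full <- bce_loss(full$scores, ed$label)
    F_emb <- ds$embeddings$dim
    h0z <- cbind(ds$embeddings$vectors,
                 matrix(0, nrow(m$h0), ncol(m$h0) - F_emb))
    if (!is.null(m$scaling))
      h0z <- sweep(sweep(h0z, 2, m$scaling$center, "-"), 2, m$scaling$scale, "/")
    abl <- grnlink:::predictor_fwd(h0z, src, dst, m$params, m$cfg, FALSE)
    bce_loss(abl$scores, ed$label) - l_full
  }, numeric(1))
  expect_gte(mean(deltas), 0)
})
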