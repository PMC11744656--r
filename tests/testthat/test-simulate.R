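test_that("planted networks are reproducible with the expected edge counts", {
  cfg <- sim_config(n_genes = 30, n_tfs = 4, edge_prob = 0.2, seed = 17)
  g1 <- generate_grn(cfg)
  g2 <- generate_grn(cfg)
  expect_identical(g1$edges, g2$edges)
  expect_true(all(g1$edges$tf %in% g1$tfs))
  expect_false(any(g1$edges$tf == g1$edges$target))
  expect_false(anyDuplicated(paste(g1$edges$tf, g1$edges$target)) > 0)
  expect_true(all(abs(g1$edges$weight) >= 0.5 & abs(g1$edges$weight) <= 1.5))
  expect_true(all(g1$edges$sign %in% c(-1, 1)))

  # saturated network: every non-self (TF, target) pair
  full <- generate_grn(sim_config(n_genes = 5, n_tfs = 2, edge_prob = 1))
  expect_equal(nrow(full$edges), 2 * 4)

  expect_error(generate_grn(sim_config(n_genes = 10, n_tfs = 1,
                                       edge_prob = 0, seed = 1)),
               class = "grnlink_structural_error")
})

test_that("edge counts follow the binomial the generator claims", {
  cfg0 <- sim_config(n_tfs = 5, n_genes = 50, edge_prob = 0.1)
  counts <- vapply(1:100, function(s) {
    cfg <- cfg0; cfg$seed <- s + 300L
    nrow(generate_grn(cfg)$edges)
  }, numeric(1))
  n_cand <- 5 * 49
  mu <- n_cand * 0.1
  sigma <- sqrt(n_cand * 0.1 * 0.9)
  expect_lt(abs(mean(counts) - mu), 3 * sigma / sqrt(100))
})

test_that("trajectories follow the planted dynamics", {
  # no edges, no noise, no dropout: pure exponential-style decay toward 0
  grn0 <- toy_grn(); grn0$edges <- grn0$edges[0, ]
  cfg <- sim_config(n_genes = 5, n_tfs = 2, n_cells = 50, noise_sd = 0,
                    dropout_rate = 0, decay = 0.2, step_size = 0.3, seed = 5)
  tr <- simulate_trajectory(grn0, cfg)
  diffs <- t(apply(tr$values, 1, diff))
  expect_true(all(diffs <= 1e-12))
  expect_true(all(tr$values >= 0))
  expect_lt(max(tr$values[, 50]), max(tr$values[, 1]))

  # a single strong activating edge: target rises while the regulator is high
  grn1 <- toy_grn()
  grn1$edges <- data.frame(tf = "T1", target = "A", sign = 1, weight = 1.5,
                           stringsAsFactors = FALSE)
  tr1 <- simulate_trajectory(grn1, cfg)
  # early (regulator still high) the target rises faster than late
  expect_gt(mean(diff(tr1$values["A", 1:10])),
            mean(diff(tr1$values["A", 40:50])))

  # determinism
  expect_identical(simulate_trajectory(grn1, cfg)$values, tr1$values)
})

test_that("dropout zeroes the advertised fraction of observed entries", {
  grn <- generate_grn(sim_config(n_genes = 30, n_tfs = 4, edge_prob = 0.2,
                                 seed = 2))
  base_cfg <- sim_config(n_genes = 30, n_tfs = 4, n_cells = 100,
                         dropout_rate = 0, seed = 2)
  drop_cfg <- base_cfg; drop_cfg$dropout_rate <- 0.5
  pre <- simulate_trajectory(grn, base_cfg)$values
  post <- simulate_trajectory(grn, drop_cfg)$values
  nz <- pre > 0
  frac <- mean(post[nz] == 0)
  n <- sum(nz)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
  expect_true(all(post >= 0))
})

test_that("embedding fixtures expose shared regulatory context", {
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

  # identical regulatory context, no noise, full signal -> identical vectors
  emb <- generate_embeddings(toy_grn(),
                             embedding_fixture_config(dim = 16, noise_sd = 0,
                                                      signal_fraction = 1,
                                                      seed = 3))
  expect_equal(cos(emb$vectors["A", ], emb$vectors["B", ]), 1)

  # pure noise: similarity unrelated to co-regulation on average
  grn <- generate_grn(sim_config(n_genes = 50, n_tfs = 5, edge_prob = 0.15,
                                 seed = 4))
  A <- grnlink:::grn_adjacency(grn)
  shared <- crossprod(A != 0)  # shared-regulator counts between targets
  co_pairs <- which(shared > 0 & upper.tri(shared), arr.ind = TRUE)
  set.seed(1)
  rand_pairs <- cbind(sample(50, 200, TRUE), sample(50, 200, TRUE))
  rand_pairs <- rand_pairs[rand_pairs[, 1] != rand_pairs[, 2], ]
  # genes with empty regulatory context embed at the origin under full
  # signal; their undefined cosines are excluded from both means
  mean_cos <- function(E, pairs) {
    v <- apply(pairs, 1, function(p) cos(E[p[1], ], E[p[2], ]))
    mean(v[is.finite(v)])
  }

  strong <- generate_embeddings(grn, embedding_fixture_config(
    signal_fraction = 1, noise_sd = 0, seed = 6))
  expect_gt(mean_cos(strong$vectors, co_pairs),
            mean_cos(strong$vectors, rand_pairs))

  # determinism
  strong2 <- generate_embeddings(grn, embedding_fixture_config(
    signal_fraction = 1, noise_sd = 0, seed = 6))
  expect_identical(strong$vectors, strong2$vectors)
})

test_that("embedding-only separability of planted edges grows with the signal fraction", {
  # probe: split-half nearest-centroid scoring with a product kernel over
  # (regulator, target) embedding pairs -- an embedding-only scorer that,
  # unlike an additive linear model, can see pair-specific structure
  sep <- function(sf) {
    mean(vapply(1:5, function(s) {
      grn <- generate_grn(sim_config(seed = s))
      emb <- generate_embeddings(grn, embedding_fixture_config(
        signal_fraction = sf, seed = s))
      pos <- edge_set(data.frame(regulator = grn$edges$tf,
                                 target = grn$edges$target, label = 1),
                      regulator_universe = grn$tfs)
      neg <- sample_negatives(pos, grn$genes, 1, seed = s + 50)
      all <- rbind(pos$edges, neg$edges)
      En <- emb$vectors / sqrt(pmax(rowSums(emb$vectors^2), 1e-12))
      f <- seq_len(nrow(all)) %% 2 == 1
      tr <- all[f, ]; te <- all[!f, ]
      K <- (En[te$regulator, , drop = FALSE] %*%
              t(En[tr$regulator, , drop = FALSE])) *
        (En[te$target, , drop = FALSE] %*% t(En[tr$target, , drop = FALSE]))
      sc <- rowMeans(K[, tr$label == 1, drop = FALSE]) -
        rowMeans(K[, tr$label == 0, drop = FALSE])
      auroc(sc, te$label)
    }, numeric(1)))
  }
  s0 <- sep(0); s5 <- sep(0.5); s1 <- sep(1)
  expect_gt(s5, s0)
  expect_gt(s1, s5)
})

test_that("make_benchmark bundles aligned inputs with the planted truth", {
  bench <- small_benchmark(9)
  ds <- bench$dataset
  expect_s3_class(ds, "aligned_dataset")
  expect_identical(ds$gene_names, bench$grn$genes)
  expect_identical(ds$embeddings$gene_names, ds$trajectory$gene_names)
  got <- ds$edges$edges[, c("regulator", "target")]
  want <- bench$grn$edges[, c("tf", "target")]
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$regulator, got$target),
                  paste(want$tf, want$target))
  expect_true(all(ds$edges$edges$label == 1L))
})
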