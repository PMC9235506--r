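make_pairs <- function(phage, host) {
  data.frame(phage_id = phage, host_id = host, stringsAsFactors = FALSE)
}

test_that("split is leakage-free and moves shared clusters to validation", {
  set.seed(20)
  # engineered table: 100 pairs, some phages share clusters, some hosts
  # shared across many phages
  pairs <- make_pairs(sprintf("p%03d", 1:100),
                      sprintf("h%02d", rep(1:25, each = 4)))
  cluster_of <- stats::setNames(sprintf("c%03d", c(1:90, 1:10)),
                                sprintf("p%03d", 1:100))
  sp <- split_pairs(pairs, cluster_of)
  tr_cl <- unique(cluster_of[sp$train$phage_id])
  va_cl <- unique(cluster_of[sp$validation$phage_id])
  expect_length(intersect(tr_cl, va_cl), 0L)
  expect_length(intersect(unique(sp$train$host_id),
                          unique(sp$validation$host_id)), 0L)
  # every retained pair lands in exactly one set
  expect_identical(nrow(sp$train) + nrow(sp$validation),
                   length(unique(paste(sp$train$phage_id, sp$train$host_id))) +
                     length(unique(paste(sp$validation$phage_id,
                                         sp$validation$host_id))))
})

test_that("pairs sharing a phage cluster end up in validation together", {
  pairs <- make_pairs(c("pA", "pB", "pC", "pD"), c("h1", "h2", "h3", "h4"))
  cluster_of <- c(pA = "c1", pB = "c9", pC = "c2", pD = "c3")
  # cluster c9 collapses pB away only if pA/pB share it; here all four
  # are representatives. Force pA into validation by making the split
  # deterministic over many seeds and checking the invariant instead.
  for (seed in 1:10) {
    set.seed(seed)
    sp <- split_pairs(pairs, cluster_of, train_fraction = 0.5)
    expect_length(intersect(unique(cluster_of[sp$train$phage_id]),
                            unique(cluster_of[sp$validation$phage_id])), 0L)
  }
  # degenerate: all pairs in one cluster -> single representative kept
  pairs2 <- make_pairs(c("p1", "p2", "p3"), c("h1", "h1", "h1"))
  one_cl <- c(p1 = "c1", p2 = "c1", p3 = "c1")
  set.seed(1)
  sp2 <- suppressWarnings(split_pairs(pairs2, one_cl, train_fraction = 0.5))
  expect_identical(nrow(sp2$train) + nrow(sp2$validation), 1L)
  # missing mappings are reported by name
  expect_error(split_pairs(pairs, cluster_of[-1]), "pA")
})

test_that("split is reproducible under a fixed seed", {
  pairs <- make_pairs(sprintf("p%d", 1:100), sprintf("h%d", rep(1:50, 2)))
  cl <- stats::setNames(sprintf("c%d", 1:100), sprintf("p%d", 1:100))
  set.seed(33); a <- split_pairs(pairs, cl)
  set.seed(33); b <- split_pairs(pairs, cl)
  expect_identical(a, b)
})

test_that("contig sampling respects bounds, short genomes and seeding", {
  set.seed(40)
  g <- random_dna(10000)
  for (i in 1:20) {
    s <- sample_contig(g, 200L)
    expect_identical(nchar(s), 200L)
    expect_true(grepl(s, g, fixed = TRUE))
  }
  short <- random_dna(150)
  expect_identical(sample_contig(short, 200L), short)
  expect_error(sample_contig("", 100L), "empty")
  set.seed(41); s1 <- sample_contig(g, 500L)
  set.seed(41); s2 <- sample_contig(g, 500L)
  expect_identical(s1, s2)
})

test_that("negative hosts are uniform over non-positive hosts", {
  hosts <- sprintf("h%02d", 1:10)
  idx <- list(pX = "h01")
  set.seed(42)
  draws <- replicate(10000, make_negative("pX", hosts, idx)$host_id)
  expect_false("h01" %in% draws)
  tab <- table(factor(draws, levels = hosts[-1]))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  # exhausted host pool is an error
  expect_error(make_negative("pX", "h01", idx), "every host")
})

test_that("each epoch pairs every positive with exactly one fresh negative", {
  corpus <- micro_corpus()
  pos <- corpus$pairs
  idx <- phanet:::.positives_index(pos)
  set.seed(43)
  ep <- phanet:::.epoch_pairs(pos, unique(pos$host_id), idx, 1L)
  expect_identical(sum(ep$label == 1L), nrow(pos))
  expect_identical(sum(ep$label == 0L), nrow(pos))
  negs <- ep[ep$label == 0L, ]
  expect_false(any(paste(negs$phage_id, negs$host_id) %in%
                     paste(pos$phage_id, pos$host_id)))
  # consecutive epochs draw different contig instances
  store <- corpus_store(corpus)
  i1 <- phanet:::.sample_instances(ep, store, 200L, 200L)
  i2 <- phanet:::.sample_instances(ep, store, 200L, 200L)
  expect_false(identical(i1$phage_seq, i2$phage_seq))
})

test_that("a zero learning rate leaves parameters unchanged", {
  corpus <- micro_corpus()
  store <- corpus_store(corpus)
  cfg <- tiny_config(seed = 50)
  before <- phanet_init(cfg)
  fit <- phanet(corpus$pairs, store, config = cfg,
                control = phanet_control(learning_rate = 0, max_epochs = 1L,
                                         phage_lengths = 200L,
                                         host_lengths = 200L, seed = 51),
                model = before)
  expect_identical(phanet:::.flatten_params(fit$model$params),
                   phanet:::.flatten_params(before$params))
})

test_that("training is deterministic given a seed and reduces loss on planted signal", {
  corpus <- micro_corpus(signal = 1)
  store <- corpus_store(corpus)
  set.seed(52)
  sp <- holdout_split(corpus, 0.25)
  run <- function() {
    phanet(sp$train, store, config = tiny_config(seed = 53),
           control = phanet_control(learning_rate = 0.01, max_epochs = 6L,
                                    phage_lengths = c(200L, 400L),
                                    host_lengths = c(200L, 400L),
                                    seed = 54, val_reps = 2L),
           validation = sp$validation)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_lt(mean(utils::tail(f1$history$train_loss, 2)),
            f1$history$train_loss[1])
})

test_that("early stopping fires on a plateau within patience + 1 epochs", {
  corpus <- micro_corpus()
  store <- corpus_store(corpus)
  set.seed(55)
  sp <- holdout_split(corpus, 0.25)
  fit <- phanet(sp$train, store, config = tiny_config(seed = 56),
                control = phanet_control(learning_rate = 0,  # frozen model
                                         max_epochs = 50L,
                                         early_stop_patience = 3L,
                                         phage_lengths = 200L,
                                         host_lengths = 200L, seed = 57),
                validation = sp$validation)
  expect_lte(nrow(fit$history), 4L)
})

test_that("grid search partitions pairs into folds and picks the better cell", {
  corpus <- micro_corpus(signal = 1)
  store <- corpus_store(corpus)
  gs <- phanet_grid_search(
    corpus$pairs, store, lr_grid = 0.01, batch_grid = 8L, folds = 2L,
    config = tiny_config(seed = 60),
    control = phanet_control(max_epochs = 1L, phage_lengths = 200L,
                             host_lengths = 200L, seed = 61))
  expect_identical(gs$best$learning_rate, 0.01)
  expect_identical(gs$best$batch_size, 8L)
  expect_identical(length(gs$fold_of), nrow(corpus$pairs))
  expect_identical(sort(unique(gs$fold_of)), 1:2)
  gs2 <- phanet_grid_search(
    corpus$pairs, store, lr_grid = c(0.01, 1e-5), batch_grid = 8L,
    folds = 2L, config = tiny_config(seed = 62),
    control = phanet_control(max_epochs = 3L, phage_lengths = c(200L, 400L),
                             host_lengths = c(200L, 400L), seed = 63))
  expect_identical(nrow(gs2$results), 2L)
  expect_identical(gs2$best$learning_rate, 0.01)
})

test_that("the fitted object supports the standard S3 surface", {
  corpus <- micro_corpus()
  store <- corpus_store(corpus)
  set.seed(64)
  sp <- holdout_split(corpus, 0.25)
  fit <- phanet(sp$train, store, config = tiny_config(seed = 65),
                control = phanet_control(learning_rate = 0.005,
                                         max_epochs = 2L,
                                         phage_lengths = 200L,
                                         host_lengths = 200L, seed = 66),
                validation = sp$validation)
  expect_s3_class(fit, "phanet")
  expect_output(print(fit), "association network")
  expect_output(print(summary(fit)), "Training history")
  expect_true(is.list(coef(fit)))
  p <- predict(fit, corpus$phages[1], corpus$hosts[1])
  expect_gt(p, 0); expect_lt(p, 1)
  ft <- predict(fit, corpus$phages[1:2], corpus$hosts[1:2], type = "features")
  expect_identical(dim(ft), c(2L, 32L))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
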