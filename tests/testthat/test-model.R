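test_that("configuration is validated and sharing shapes the parameter set", {
  expect_error(phanet_config(paths = character(0)))
  expect_error(phanet_config(conv_channels = c(8L, 16L),
                             base_kernels = 7L), "equal length")
  shared <- phanet_init(tiny_config(seed = 1))
  expect_identical(names(shared$params$paths), c("base", "codon"))
  indep <- phanet_init(tiny_config(share_weights = FALSE, seed = 1))
  expect_setequal(names(indep$params$paths),
                  c("phage_base", "phage_codon", "host_base", "host_codon"))
  # single-path ablations halve the head input
  codon_only <- phanet_init(phanet_config(paths = "codon", seed = 1))
  expect_identical(nrow(codon_only$params$head[[1]]$W), 512L)
  both <- phanet_init(phanet_config(seed = 1))
  expect_identical(nrow(both$params$head[[1]]$W), 1024L)
})

test_that("feature dimension is invariant to contig length", {
  mod <- phanet_init(tiny_config(seed = 3))
  set.seed(4)
  f1 <- extract_features(mod, random_dna(60))
  f2 <- extract_features(mod, random_dna(5000))
  expect_length(f1, 16L)  # 8 per path x 2 paths
  expect_length(f2, 16L)
  expect_error(extract_features(mod, random_dna(20)), "at least 30")
})

test_that("shared weights make the extractor role-agnostic; independent weights do not", {
  set.seed(5)
  s <- random_dna(300)
  shared <- phanet_init(tiny_config(seed = 6))
  expect_identical(extract_features(shared, s, role = "phage"),
                   extract_features(shared, s, role = "host"))
  indep <- phanet_init(tiny_config(share_weights = FALSE, seed = 6))
  expect_false(isTRUE(all.equal(extract_features(indep, s, role = "phage"),
                                extract_features(indep, s, role = "host"))))
})

test_that("max-pooled base features cannot decrease when the contig is duplicated", {
  # exact superset argument requires aligned pooling blocks: use the
  # base path alone with |s| divisible by the pool width
  mod <- phanet_init(phanet_config(paths = "base", conv_channels = c(4L, 8L),
                                   base_kernels = c(5L, 3L),
                                   codon_kernels = c(3L, 3L),
                                   fc_hidden = 8L, min_length = 30L,
                                   pool_width = 4L, pooling = "max",
                                   seed = 8))
  set.seed(9)
  s <- random_dna(200)
  f1 <- extract_features(mod, s)
  f2 <- extract_features(mod, paste0(s, s))
  expect_true(all(f2 >= f1 - 1e-12))
})

test_that("association scores are probabilities with the fixed head convention", {
  mod <- phanet_init(tiny_config(seed = 10))
  set.seed(11)
  p <- random_dna(200); h <- random_dna(400)
  s <- predict_association(mod, p, h)
  expect_gt(s, 0); expect_lt(s, 1)
  # zeroed head -> sigmoid(0) = 0.5 exactly
  zeroed <- mod
  for (i in seq_along(zeroed$params$head)) {
    zeroed$params$head[[i]]$W[] <- 0
    zeroed$params$head[[i]]$b[] <- 0
  }
  expect_identical(predict_association(zeroed, p, h), 0.5)
  # batch scoring equals single-pair scoring
  ps <- replicate(5, random_dna(150)); hs <- replicate(5, random_dna(250))
  batch <- predict_association(mod, ps, hs)
  single <- vapply(1:5, function(i) predict_association(mod, ps[i], hs[i]),
                   numeric(1))
  expect_equal(batch, single, tolerance = 1e-6)
})

test_that("analytic gradients match numerical differentiation", {
  for (share in c(TRUE, FALSE)) {
    cfg <- phanet_config(conv_channels = c(3L, 4L), base_kernels = c(5L, 3L),
                         codon_kernels = c(3L, 3L), fc_hidden = 6L,
                         min_length = 10L, pool_width = 2L,
                         share_weights = share, seed = 12)
    mod <- phanet_init(cfg)
    set.seed(13)
    # jitter all parameters: zero-bias init leaves exact ties in the
    # max-pooling layers, where the loss is kinked and finite
    # differences disagree with the (valid) subgradient
    flat <- phanet:::.flatten_params(mod$params)
    flat <- lapply(flat, function(x) x + stats::runif(length(x), -1e-3, 1e-3))
    mod$params <- phanet:::.unflatten_params(flat, mod$params)
    p <- random_dna(60, alphabet = c("A", "C", "G", "T", "N"))
    h <- random_dna(80)
    g <- phanet:::.pair_grad(mod, p, h, 1)
    eps <- 1e-6
    for (nm in names(flat)) {
      ii <- sample(length(flat[[nm]]), min(3L, length(flat[[nm]])))
      for (i in ii) {
        fp2 <- flat; fp2[[nm]][i] <- fp2[[nm]][i] + eps
        fm2 <- flat; fm2[[nm]][i] <- fm2[[nm]][i] - eps
        mp <- mod; mp$params <- phanet:::.unflatten_params(fp2, mod$params)
        mm <- mod; mm$params <- phanet:::.unflatten_params(fm2, mod$params)
        num <- (phanet:::.pair_grad(mp, p, h, 1)$loss -
                  phanet:::.pair_grad(mm, p, h, 1)$loss) / (2 * eps)
        expect_lt(abs(g$grads[[nm]][i] - num), 1e-5)
      }
    }
  }
})

test_that("max global pooling is supported as an alternative", {
  cfg <- tiny_config(pooling = "max", seed = 14)
  mod <- phanet_init(cfg)
  set.seed(15)
  s <- random_dna(120)
  expect_length(extract_features(mod, s), 16L)
  g <- phanet:::.pair_grad(mod, s, random_dna(90), 0)
  expect_true(is.finite(g$loss))
})

test_that("checkpoints round-trip scores bit-for-bit", {
  mod <- phanet_init(tiny_config(seed = 16))
  set.seed(17)
  p <- random_dna(100); h <- random_dna(100)
  f <- withr::local_tempfile(fileext = ".rds")
  write_phanet(mod, f)
  back <- read_phanet(f)
  expect_identical(predict_association(mod, p, h),
                   predict_association(back, p, h))
  # non-checkpoint files are rejected
  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), junk)
  expect_error(read_phanet(junk), "not a phanet checkpoint")
})
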