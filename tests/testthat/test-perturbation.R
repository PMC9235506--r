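test_that("error profile validates rates and zero rates are the identity", {
  expect_error(error_profile(-0.1, 0))
  expect_error(error_profile(0.6, 0.5))
  set.seed(70)
  s <- random_dna(2000)
  out <- introduce_errors(s, error_profile(0, 0))
  expect_identical(as.vector(out), s)
  expect_identical(unlist(attr(out, "counts")), c(substitutions = 0L,
                                                  insertions = 0L,
                                                  deletions = 0L))
})

test_that("realized error counts follow the binomial model", {
  set.seed(71)
  n <- 1000000L
  s <- random_dna(n)
  out <- introduce_errors(s, error_profile(mu = 0.06, delta = 0.04))
  cts <- attr(out, "counts")
  # marginal rates: substitution mu; insertion delta/2; deletion delta/2
  for (spec in list(c("substitutions", 0.06), c("insertions", 0.02),
                    c("deletions", 0.02))) {
    p <- as.numeric(spec[2])
    expect_lt(abs(cts[[spec[1]]] - n * p), 4 * sqrt(n * p * (1 - p)))
  }
  # length bookkeeping: insertions lengthen, deletions shorten
  expect_identical(nchar(out) - n,
                   as.integer(cts[["insertions"]] - cts[["deletions"]]))
  # length change stays within 4 sigma of its zero-mean model
  expect_lt(abs(nchar(out) - n), 4 * sqrt(2 * n * 0.02 * 0.98))
})

test_that("conditional event split is 1/2, 1/4, 1/4 when mu equals delta", {
  set.seed(72)
  out <- introduce_errors(random_dna(4e5), error_profile(0.05, 0.05))
  cts <- attr(out, "counts")
  tot <- sum(unlist(cts))
  expect_equal(cts[["substitutions"]] / tot, 0.5, tolerance = 0.03)
  expect_equal(cts[["insertions"]] / tot, 0.25, tolerance = 0.06)
  expect_equal(cts[["deletions"]] / tot, 0.25, tolerance = 0.06)
})

test_that("substitutions always change the base", {
  set.seed(73)
  s <- strrep("A", 5000)
  out <- introduce_errors(s, error_profile(mu = 0.5, delta = 0))
  expect_identical(nchar(out), 5000L)
  mismatches <- sum(strsplit(out, "")[[1]] != "A")
  expect_identical(mismatches, as.integer(attr(out, "counts")[["substitutions"]]))
  expect_gt(mismatches, 0L)
})

test_that("chimera exchange conserves lengths and the combined base multiset", {
  set.seed(74)
  a <- random_dna(5000); b <- random_dna(5000)
  sw <- make_chimera(a, b, 0.2)
  expect_identical(nchar(sw$a), 5000L)
  expect_identical(nchar(sw$b), 5000L)
  count <- function(x) table(factor(strsplit(x, "")[[1]],
                                    levels = c("A", "C", "G", "T")))
  expect_identical(count(paste0(sw$a, sw$b)), count(paste0(a, b)))
  # exactly round(0.2 * 5000) = 1000 positions form the exchanged window
  diff_a <- which(strsplit(sw$a, "")[[1]] != strsplit(a, "")[[1]])
  expect_lte(max(diff_a) - min(diff_a) + 1L, 1000L)
  # fraction 0 is the identity; oversized segments are rejected
  expect_identical(make_chimera(a, b, 0), list(a = a, b = b))
  expect_error(make_chimera(random_dna(2000), random_dna(100), 0.9),
               "exceeds")
})

test_that("seeded perturbations are reproducible", {
  s <- random_dna(3000); p <- random_dna(3000)
  set.seed(75); e1 <- introduce_errors(s, error_profile(0.05, 0.05))
  set.seed(75); e2 <- introduce_errors(s, error_profile(0.05, 0.05))
  expect_identical(e1, e2)
  set.seed(76); c1 <- make_chimera(s, p, 0.1)
  set.seed(76); c2 <- make_chimera(s, p, 0.1)
  expect_identical(c1, c2)
})

test_that("corrupt_eval_set targets only the designated side", {
  corpus <- micro_corpus()
  store <- corpus_store(corpus)
  lens <- c(400L, 400L)
  set.seed(77)
  clean <- corrupt_eval_set(corpus$pairs, store, lengths = lens, reps = 2L)
  set.seed(77)
  clean2 <- corrupt_eval_set(corpus$pairs, store,
                             profile = error_profile(0, 0),
                             chimera_fraction = 0, lengths = lens, reps = 2L)
  expect_identical(clean, clean2)
  set.seed(77)
  ph_only <- corrupt_eval_set(corpus$pairs, store, chimera_fraction = 0.2,
                              target = "phage_only", lengths = lens,
                              reps = 2L)
  expect_identical(ph_only$host_seq, clean$host_seq)
  expect_false(identical(ph_only$phage_seq, clean$phage_seq))
  # 1:1 labels at the requested lengths
  expect_identical(sum(clean$label == 1L), sum(clean$label == 0L))
  expect_true(all(nchar(clean$phage_seq) == 400L))
})

test_that("the published error grid enumerates 18 cells", {
  corpus <- micro_corpus()
  store <- corpus_store(corpus)
  mod <- phanet_init(tiny_config(seed = 78))
  set.seed(79)
  grid <- evaluate_error_grid(mod, corpus$pairs[1:4, ], store,
                              lengths = c(300L, 300L), reps = 1L)
  expect_identical(nrow(grid), 18L)
  expect_identical(sort(unique(grid$mu)), seq(0, 0.1, by = 0.02))
  expect_identical(sort(unique(grid$delta)), c(0, 0.05, 0.1))
  expect_true(all(grid$auroc >= 0 & grid$auroc <= 1))
})
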