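# Shared fixtures, all generated in code.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small architecture for fast unit tests
tiny_config <- function(...) {
  phanet_config(conv_channels = c(4L, 8L), base_kernels = c(5L, 3L),
                codon_kernels = c(3L, 3L), fc_hidden = 8L,
                min_length = 30L, pool_width = 2L, ...)
}

# small synthetic corpus for pipeline tests
micro_corpus <- function(seed = 7, signal = 0.9, hosts_per_clade = 2L,
                         phages_per_host = 4L) {
  generate_corpus(synthetic_config(
    n_host_clades = 2L, hosts_per_clade = hosts_per_clade,
    phages_per_host = phages_per_host,
    host_genome_length = 4000L, phage_genome_length = 2000L,
    signal_strength = signal, seed = seed))
}

# Study-condition corpus (generator defaults) and the desk-scale
# training setup used for the end-to-end checks. Fitted models are
# cached so several tests can share one training run.
.e2e_cache <- new.env(parent = emptyenv())

e2e_corpus <- function(signal) {
  key <- sprintf("corpus_%g", signal)
  if (is.null(.e2e_cache[[key]]))
    .e2e_cache[[key]] <- generate_corpus(synthetic_config(
      signal_strength = signal, seed = if (signal > 0) 101L else 102L))
  .e2e_cache[[key]]
}

e2e_fit <- function(signal) {
  key <- sprintf("fit_%g", signal)
  if (is.null(.e2e_cache[[key]])) {
    corpus <- e2e_corpus(signal)
    set.seed(11L)
    sp <- holdout_split(corpus, 0.2)
    menus <- c(200L, 500L, 1000L, 5000L)
    fit <- phanet(
      sp$train, corpus_store(corpus),
      config = phanet_config(conv_channels = c(16L, 64L), fc_hidden = 32L,
                             seed = 1L),
      control = phanet_control(learning_rate = 0.003, batch_size = 4L,
                               max_epochs = 30L,
                               phage_lengths = menus, host_lengths = menus,
                               seed = 1L),
      validation = sp$validation)
    .e2e_cache[[key]] <- list(fit = fit, split = sp, corpus = corpus)
  }
  .e2e_cache[[key]]
}

# pooled AUROC of a fitted model on held-out pairs at one length cell
holdout_auroc <- function(fitted, L_p = 1000L, L_h = 1000L, reps = 10L) {
  g <- evaluate_length_grid(fitted$fit, fitted$split$validation,
                            corpus_store(fitted$corpus),
                            phage_lengths = L_p, host_lengths = L_h,
                            reps = reps)
  unname(g$auroc[1, 1])
}

# brute-force AUROC oracle: count positive/negative score pairs,
# ties half
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
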