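# AUROC and the contig-length-grid evaluation protocol.

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly
#' chosen positive outscores a randomly chosen negative, with ties
#' counted half (midranks). Invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores Numeric score vector (higher = more likely associated).
#' @param labels 0/1 vector of the same length.
#' @return AUROC in \[0, 1\].
#' @examples
#' compute_auroc(c(0.9, 0.1), c(1, 0))  # 1
#' compute_auroc(c(0.5, 0.5), c(1, 0))  # 0.5 by the tie convention
#' @export
compute_auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("AUROC needs at least one positive and one negative label")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Naive k-mer composition baseline
#'
#' Manhattan (L1) distance between the normalized k-mer frequency
#' vectors of the two contigs; lower means more similar. Serves as a
#' simple alignment-free comparator in the role the d2*/WIsH family of
#' tools plays in benchmark comparisons: negate it to use it as an
#' association score.
#'
#' @param phage,host DNA strings or [contig_record()]s.
#' @param k Word size (default 4).
#' @return Non-negative dissimilarity (0 for identical composition,
#'   at most 2).
#' @export
kmer_baseline_score <- function(phage, host, k = 4L) {
  f <- function(x) {
    s <- .seq_chr(x)
    if (nchar(s) < k) stop("contig shorter than k = ", k)
    v <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s), k)
    v / sum(v)
  }
  sum(abs(f(phage) - f(host)))
}

# scorer interface used by the grid: a function(model, phage_seqs,
# host_seqs) -> numeric scores, higher = more associated
.model_scorer <- function(model, phage_seq, host_seq) {
  predict_association(model, phage_seq, host_seq)
}

.baseline_scorer <- function(k) {
  force(k)
  function(model, phage_seq, host_seq) {
    -vapply(seq_along(phage_seq),
            function(i) kmer_baseline_score(phage_seq[i], host_seq[i], k),
            numeric(1))
  }
}

#' AUROC over a grid of contig lengths
#'
#' For every (phage length, host length) cell, repeats `reps` times:
#' draws one negative per positive pair (training rule), samples a
#' contig of the requested length from each genome, and scores the
#' pair. The cell AUROC pools all sampled scores by default
#' (`pool = TRUE`); `pool = FALSE` instead averages one AUROC per
#' repetition. The published protocol uses 10 repetitions, a 6-length
#' phage menu and a 7-length host menu (a 6 x 7 matrix).
#'
#' @param model A `phanet_model` or fitted `phanet` object, or `NULL`
#'   when `scorer` is supplied.
#' @param pairs Positive pairs data frame.
#' @param store A [genome_store()].
#' @param phage_lengths,host_lengths Length menus (bases).
#' @param reps Repetitions per cell (default 10).
#' @param pool Pool scores across repetitions (default) or average
#'   per-repetition AUROCs.
#' @param scorer Optional scoring function `(model, phage_seqs,
#'   host_seqs) -> scores`; defaults to the model, or to the negated
#'   [kmer_baseline_score()] when `model` is `NULL`.
#' @param scores_out Optional path of a TSV to receive all per-pair
#'   scores (phage_id, host_id, L_p, L_h, repetition, score, label).
#' @return A `phanet_grid` object: list with `phage_lengths`,
#'   `host_lengths`, the AUROC `matrix`, `reps` and the per-pair score
#'   table.
#' @export
evaluate_length_grid <- function(model, pairs, store,
                                 phage_lengths = c(200L, 500L, 1000L, 5000L, 10000L, 50000L),
                                 host_lengths = c(200L, 500L, 1000L, 5000L, 10000L, 50000L, 100000L),
                                 reps = 10L, pool = TRUE, scorer = NULL,
                                 scores_out = NULL) {
  pairs <- .with_labels(pairs, 1L)
  if (!any(pairs$label == 1L)) stop("need positive pairs")
  if (is.null(scorer))
    scorer <- if (is.null(model)) .baseline_scorer(4L) else .model_scorer
  if (!is.null(model)) model <- .as_model(model)
  pos <- pairs[pairs$label == 1L, , drop = FALSE]
  pos_index <- .positives_index(pos)
  host_pool <- names(store$hosts)
  auroc <- matrix(NA_real_, length(phage_lengths), length(host_lengths),
                  dimnames = list(phage_lengths, host_lengths))
  all_scores <- NULL
  for (i in seq_along(phage_lengths)) {
    for (j in seq_along(host_lengths)) {
      per_rep <- numeric(reps)
      cell <- NULL
      for (r in seq_len(reps)) {
        ep <- .epoch_pairs(pos, host_pool, pos_index, 1L)
        inst <- .sample_instances(ep, store, phage_lengths[i], host_lengths[j])
        sc <- scorer(model, inst$phage_seq, inst$host_seq)
        per_rep[r] <- compute_auroc(sc, inst$label)
        cell <- rbind(cell, data.frame(
          phage_id = inst$phage_id, host_id = inst$host_id,
          L_p = phage_lengths[i], L_h = host_lengths[j], repetition = r,
          score = sc, label = inst$label, stringsAsFactors = FALSE))
      }
      auroc[i, j] <- if (pool) compute_auroc(cell$score, cell$label)
                     else mean(per_rep)
      if (!is.null(scores_out)) all_scores <- rbind(all_scores, cell)
    }
  }
  if (!is.null(scores_out))
    utils::write.table(all_scores, scores_out, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  structure(list(phage_lengths = phage_lengths, host_lengths = host_lengths,
                 auroc = auroc, reps = reps, pooled = pool),
            class = "phanet_grid")
}

#' @export
print.phanet_grid <- function(x, ...) {
  cat(sprintf("AUROC over contig lengths (%d repetitions, %s)\n",
              x$reps, if (x$pooled) "pooled scores" else "averaged AUROCs"))
  cat("rows: phage length (bp); columns: host length (bp)\n")
  print(round(x$auroc, 3))
  invisible(x)
}

#' Heatmap of a length-grid result
#'
#' @param x A `phanet_grid` from [evaluate_length_grid()].
#' @param ... Passed to [graphics::image()].
#' @method plot phanet_grid
#' @export
plot.phanet_grid <- function(x, ...) {
  m <- x$auroc
  graphics::image(seq_along(x$host_lengths), seq_along(x$phage_lengths),
                  t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  axes = FALSE, xlab = "host contig length (bp)",
                  ylab = "phage contig length (bp)", ...)
  graphics::axis(1, seq_along(x$host_lengths), labels = x$host_lengths)
  graphics::axis(2, seq_along(x$phage_lengths), labels = rev(x$phage_lengths))
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      graphics::text(j, nrow(m) - i + 1, sprintf("%.2f", m[i, j]), cex = 0.8)
  invisible(x)
}

#' Write the AUROC matrix of a grid result as TSV
#'
#' @param x A `phanet_grid`.
#' @param path Output file.
#' @export
write_grid_tsv <- function(x, path) {
  stopifnot(inherits(x, "phanet_grid"))
  df <- data.frame(phage_length = rep(x$phage_lengths,
                                      times = length(x$host_lengths)),
                   host_length = rep(x$host_lengths,
                                     each = length(x$phage_lengths)),
                   auroc = as.vector(x$auroc))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
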