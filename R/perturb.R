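# Robustness machinery: a contig-level sequencing-error model
# (substitutions at rate mu, insertions/deletions at rate delta) and a
# chimeric-contig simulator that exchanges contiguous segments between
# contigs of the same role, as in the published robustness experiments.

#' Sequencing-error profile
#'
#' The model acts per input base: an error occurs with probability
#' `mu + delta`; given an error, it is a substitution with probability
#' `mu / (mu + delta)` (the base is replaced by one of the other three
#' nucleotides with equal probability), a deletion with probability
#' `delta / (2 (mu + delta))`, or an insertion with the same probability
#' (one of A, C, G, T, equal probability, placed after the base). At
#' most one event occurs per original base.
#'
#' @param mu Substitution rate per base.
#' @param delta Insertion/deletion rate per base.
#' @return An `error_profile` list.
#' @export
error_profile <- function(mu = 0, delta = 0) {
  if (!is.numeric(mu) || !is.numeric(delta) || mu < 0 || delta < 0 ||
      mu + delta > 1)
    stop("need mu >= 0, delta >= 0 and mu + delta <= 1")
  structure(list(mu = mu, delta = delta), class = "error_profile")
}

#' Introduce sequencing errors into a sequence
#'
#' Applies the per-base error model of [error_profile()] in a single
#' pass. Substitutions always change the base; insertions lengthen and
#' deletions shorten the output, so the result length is
#' `L - #deletions + #insertions`.
#'
#' @param sequence A DNA string.
#' @param profile An [error_profile()] (or `mu`/`delta` given directly).
#' @param mu,delta Convenience scalars used when `profile` is missing.
#' @return The perturbed DNA string, with a `counts` attribute recording
#'   the realized numbers of substitutions, insertions and deletions.
#' @export
introduce_errors <- function(sequence, profile = error_profile(mu, delta),
                             mu = 0, delta = 0) {
  stopifnot(inherits(profile, "error_profile"))
  s <- .seq_chr(sequence)
  .counted <- function(x, ns, ni, nd) {
    attr(x, "counts") <- list(substitutions = ns, insertions = ni,
                              deletions = nd)
    x
  }
  rate <- profile$mu + profile$delta
  if (rate == 0) return(.counted(s, 0L, 0L, 0L))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  err <- which(stats::runif(n) < rate)
  if (length(err) == 0L) return(.counted(s, 0L, 0L, 0L))
  # conditional event type: sub mu/(mu+delta), del delta/2(mu+delta),
  # ins delta/2(mu+delta)
  u <- stats::runif(length(err))
  p_sub <- profile$mu / rate
  p_del <- p_sub + profile$delta / (2 * rate)
  subs <- err[u < p_sub]
  dels <- err[u >= p_sub & u < p_del]
  inss <- err[u >= p_del]
  if (length(subs)) {
    # replace by one of the other three bases, uniformly
    others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))
    ri <- match(toupper(chars[subs]), rownames(others))
    known <- !is.na(ri)
    pick <- sample.int(3L, length(subs), replace = TRUE)
    new <- chars[subs]
    new[known] <- others[cbind(ri[known], pick[known])]
    new[!known] <- sample(BASES, sum(!known), replace = TRUE)
    chars[subs] <- new
  }
  if (length(inss))
    chars[inss] <- paste0(chars[inss],
                          sample(BASES, length(inss), replace = TRUE))
  if (length(dels)) chars[dels] <- ""
  .counted(paste(chars, collapse = ""),
           length(subs), length(inss), length(dels))
}

#' Exchange a contiguous segment between two contigs
#'
#' Simulates a chimeric assembly join: a contiguous segment of length
#' `round(fraction * nchar(a))` at a uniformly random position of `a` is
#' swapped with an equal-length segment at a uniformly random position
#' of `b`. Both output lengths are unchanged and the combined base
#' multiset is conserved. Swaps should only pair contigs of the same
#' role (phage with phage, host with host); [corrupt_eval_set()]
#' enforces that convention.
#'
#' @param a,b DNA strings.
#' @param fraction Fraction of `a` to exchange (the published
#'   experiments cover 0 to 0.2).
#' @return List with perturbed elements `a` and `b`.
#' @export
make_chimera <- function(a, b, fraction) {
  a <- .seq_chr(a); b <- .seq_chr(b)
  stopifnot(is.numeric(fraction), fraction >= 0, fraction <= 1)
  seg <- round(fraction * nchar(a))
  if (seg == 0L) return(list(a = a, b = b))
  if (seg > nchar(a) || seg > nchar(b))
    stop(sprintf("segment of %d bases exceeds a contig length (%d / %d)",
                 seg, nchar(a), nchar(b)))
  sa <- sample.int(nchar(a) - seg + 1L, 1L)
  sb <- sample.int(nchar(b) - seg + 1L, 1L)
  pa <- substr(a, sa, sa + seg - 1L)
  pb <- substr(b, sb, sb + seg - 1L)
  list(a = paste0(substr(a, 1L, sa - 1L), pb,
                  substr(a, sa + seg, nchar(a))),
       b = paste0(substr(b, 1L, sb - 1L), pa,
                  substr(b, sb + seg, nchar(b))))
}

#' Build a perturbed evaluation set
#'
#' Samples contig pairs from the association pairs at fixed lengths
#' (5000/5000 bases by default, the setting of the published robustness
#' experiments), then applies either the sequencing-error model or the
#' chimera model to the designated side(s). Contigs are sampled before
#' any perturbation, so with the same seed the unperturbed columns are
#' identical across perturbation settings. Chimera partners are drawn
#' among contigs of the same role within the set.
#'
#' @param pairs Data frame of positive pairs (`phage_id`, `host_id`);
#'   negatives are constructed per the training rule.
#' @param store A [genome_store()].
#' @param profile Optional [error_profile()] applied to both sides.
#' @param chimera_fraction Optional fraction for [make_chimera()].
#' @param target Which side chimeras hit: `"both"`, `"phage_only"` or
#'   `"host_only"`.
#' @param lengths Two integers: phage and host contig lengths.
#' @param reps Contig draws per association pair (default 10, matching
#'   the averaging over 10 repeated experiments).
#' @return Data frame of labelled, possibly perturbed contig instances
#'   (`phage_id`, `host_id`, `label`, `phage_seq`, `host_seq`).
#' @export
corrupt_eval_set <- function(pairs, store, profile = NULL,
                             chimera_fraction = NULL,
                             target = c("both", "phage_only", "host_only"),
                             lengths = c(5000L, 5000L), reps = 10L) {
  target <- match.arg(target)
  pairs <- .with_labels(pairs, 1L)
  pos_index <- .positives_index(pairs[pairs$label == 1L, ])
  host_pool <- names(store$hosts)
  inst <- do.call(rbind, lapply(seq_len(reps), function(r) {
    ep <- .epoch_pairs(pairs[pairs$label == 1L, ], host_pool, pos_index, 1L)
    .sample_instances(ep, store, lengths[1], lengths[2])
  }))
  if (!is.null(profile) && (profile$mu + profile$delta) > 0) {
    if (target != "host_only")
      inst$phage_seq <- vapply(inst$phage_seq, introduce_errors,
                               character(1), profile = profile)
    if (target != "phage_only")
      inst$host_seq <- vapply(inst$host_seq, introduce_errors,
                              character(1), profile = profile)
  }
  if (!is.null(chimera_fraction) && chimera_fraction > 0) {
    if (target != "host_only")
      inst$phage_seq <- .chimerize_pool(inst$phage_seq, chimera_fraction)
    if (target != "phage_only")
      inst$host_seq <- .chimerize_pool(inst$host_seq, chimera_fraction)
  }
  inst
}

# swap a segment of each contig with a randomly drawn partner of the
# same role (a fresh copy, so each contig is perturbed independently)
.chimerize_pool <- function(seqs, fraction) {
  originals <- seqs
  n <- length(seqs)
  if (n < 2L) stop("need at least two contigs of a role to form chimeras")
  for (i in seq_len(n)) {
    j <- sample.int(n - 1L, 1L)
    if (j >= i) j <- j + 1L
    seqs[i] <- make_chimera(seqs[i], originals[j], fraction)$a
  }
  seqs
}

#' Evaluate robustness to sequencing errors over a parameter grid
#'
#' For every (mu, delta) cell, builds a perturbed evaluation set with
#' [corrupt_eval_set()], scores it with the model and records the
#' AUROC. The published grid is mu in 0 to 0.1 by 0.02 and delta in
#' {0, 0.05, 0.1} (18 cells) at 5000/5000-base contigs.
#'
#' @param model A `phanet_model` or fitted `phanet` object.
#' @param pairs Positive association pairs.
#' @param store A [genome_store()].
#' @param mus,deltas Grid values.
#' @param lengths,reps Passed to [corrupt_eval_set()].
#' @return Data frame (mu, delta, auroc, n_pairs).
#' @export
evaluate_error_grid <- function(model, pairs, store,
                                mus = seq(0, 0.1, by = 0.02),
                                deltas = c(0, 0.05, 0.1),
                                lengths = c(5000L, 5000L), reps = 10L) {
  grid <- expand.grid(mu = mus, delta = deltas)
  grid$auroc <- NA_real_
  grid$n_pairs <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    set_ <- corrupt_eval_set(pairs, store,
                             profile = error_profile(grid$mu[i], grid$delta[i]),
                             lengths = lengths, reps = reps)
    ev <- .eval_instances(.as_model(model), set_)
    grid$auroc[i] <- ev$auroc
    grid$n_pairs[i] <- nrow(set_)
  }
  grid
}

#' Evaluate robustness to chimeric contigs
#'
#' AUROC as a function of the exchanged-sequence fraction, for chimeras
#' applied to phage contigs only, host contigs only, or both.
#'
#' @param model A `phanet_model` or fitted `phanet` object.
#' @param pairs Positive association pairs.
#' @param store A [genome_store()].
#' @param fractions Exchanged fractions (published range 0 to 0.2).
#' @param targets Subset of `c("phage_only", "host_only", "both")`.
#' @param lengths,reps Passed to [corrupt_eval_set()].
#' @return Data frame (fraction, target, auroc, n_pairs).
#' @export
evaluate_chimera_curve <- function(model, pairs, store,
                                   fractions = seq(0, 0.2, by = 0.05),
                                   targets = c("phage_only", "host_only", "both"),
                                   lengths = c(5000L, 5000L), reps = 10L) {
  grid <- expand.grid(fraction = fractions, target = targets,
                      stringsAsFactors = FALSE)
  grid$auroc <- NA_real_
  grid$n_pairs <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    set_ <- corrupt_eval_set(pairs, store,
                             chimera_fraction = grid$fraction[i],
                             target = grid$target[i],
                             lengths = lengths, reps = reps)
    ev <- .eval_instances(.as_model(model), set_)
    grid$auroc[i] <- ev$auroc
    grid$n_pairs[i] <- nrow(set_)
  }
  grid
}
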