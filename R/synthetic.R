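# Synthetic phage/host corpus with a planted compositional signal.
# Host genomes follow clade-specific order-m Markov models over
# A/C/G/T; each phage genome is a per-base mixture of its host clade's
# model (probability = signal_strength) and a uniform background. This
# emulates the statistical structure the association network exploits
# (host-specific nucleotide/codon bias shared by resident phages)
# without attempting genuine phage biology.

#' Synthetic corpus configuration
#'
#' Defaults give 5 host clades x 4 hosts x 10 phages per host = 20
#' hosts, 200 phages and 200 positive pairs, with 200 kb host and 40 kb
#' phage genomes and an order-2 Markov compositional signal of strength
#' 0.8.
#'
#' @param n_host_clades Number of compositional clades.
#' @param hosts_per_clade Hosts drawn per clade.
#' @param phages_per_host Phages generated per host (each positive for
#'   exactly that host).
#' @param host_genome_length,phage_genome_length Genome lengths in
#'   bases.
#' @param signal_strength Probability, per phage base, of following the
#'   host clade's transition model rather than the background; 0 plants
#'   no phage-host coupling.
#' @param markov_order Order of the clade Markov models.
#' @param concentration Dirichlet concentration for transition rows.
#' @param min_tv Minimum pairwise total-variation distance between clade
#'   stationary base compositions (clades are resampled until met).
#' @param seed Optional integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_host_clades = 5L, hosts_per_clade = 4L,
                             phages_per_host = 10L,
                             host_genome_length = 200000L,
                             phage_genome_length = 40000L,
                             signal_strength = 0.8,
                             markov_order = 2L,
                             concentration = 0.5,
                             min_tv = 0.1,
                             seed = NULL) {
  stopifnot(n_host_clades >= 1, hosts_per_clade >= 1, phages_per_host >= 1,
            host_genome_length >= 1, phage_genome_length >= 1,
            signal_strength >= 0, signal_strength <= 1, markov_order >= 0)
  structure(as.list(environment()), class = "synthetic_config")
}

# stationary distribution over single bases of an order-m chain
.stationary_composition <- function(tab, order) {
  if (order == 0L) return(as.numeric(tab))
  S <- nrow(tab)
  # context chain: state' = (4*state + x) mod S, most recent base in the
  # least significant base-4 digit
  P <- matrix(0, S, S)
  for (s in seq_len(S))
    for (x in 1:4) {
      sp <- ((s - 1L) * 4L + (x - 1L)) %% S + 1L
      P[s, sp] <- P[s, sp] + tab[s, x]
    }
  pi <- rep(1 / S, S)
  for (it in 1:500) {
    p2 <- as.vector(pi %*% P)
    if (max(abs(p2 - pi)) < 1e-13) { pi <- p2; break }
    pi <- p2
  }
  last <- (seq_len(S) - 1L) %% 4L + 1L
  as.vector(tapply(pi, last, sum))
}

#' Draw a clade composition model
#'
#' Samples an order-m Markov transition table over A/C/G/T with
#' Dirichlet rows. [generate_corpus()] draws one per clade and resamples
#' until all pairwise total-variation distances between the clades'
#' stationary base compositions reach the configured minimum, so
#' distinct clades are compositionally separable.
#'
#' @param markov_order Chain order (0 gives a single base distribution).
#' @param concentration Dirichlet concentration parameter.
#' @return Row-normalized matrix with `4^markov_order` rows and 4
#'   columns (a 1 x 4 matrix for order 0).
#' @export
sample_clade_composition <- function(markov_order = 2L, concentration = 0.5) {
  S <- 4L^max(0L, markov_order)
  g <- matrix(stats::rgamma(S * 4L, shape = concentration), S, 4L)
  tab <- g / rowSums(g)
  colnames(tab) <- BASES
  tab
}

.sample_clade_tables <- function(n, order, concentration, min_tv) {
  tabs <- list()
  comps <- list()
  for (i in seq_len(n)) {
    for (try in 1:10000) {
      tab <- sample_clade_composition(order, concentration)
      comp <- .stationary_composition(tab, order)
      ok <- all(vapply(comps, function(c2) sum(abs(comp - c2)) / 2 >= min_tv,
                       logical(1)))
      if (ok) break
    }
    if (!ok) stop("could not separate clade compositions; lower 'min_tv'")
    tabs[[i]] <- tab
    comps[[i]] <- comp
  }
  list(tables = tabs, compositions = comps)
}

.markov_string <- function(n, tab, order, signal) {
  cum <- t(apply(tab, 1L, cumsum))
  if (nrow(tab) == 1L) cum <- matrix(cum, 1L)
  x <- markov_sequence(as.integer(n), cum, cumsum(rep(0.25, 4)),
                       as.integer(order), signal)
  paste(BASES[x], collapse = "")
}

#' Generate a synthetic phage/host corpus
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_corpus` object: list with `hosts` and `phages`
#'   (named character vectors of genome sequences), `pairs` (positive
#'   [data.frame] phage_id/host_id/label), `clade_of` (host id ->
#'   clade), and `truth` (the generator parameters and clade models,
#'   for audit).
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ct <- .sample_clade_tables(config$n_host_clades, config$markov_order,
                             config$concentration, config$min_tv)
  hosts <- character(0); clade_of <- integer(0)
  phages <- character(0)
  pairs <- NULL
  h <- 0L; p <- 0L
  for (cl in seq_len(config$n_host_clades)) {
    for (hi in seq_len(config$hosts_per_clade)) {
      h <- h + 1L
      host_id <- sprintf("host_%03d", h)
      hosts[host_id] <- .markov_string(config$host_genome_length,
                                       ct$tables[[cl]], config$markov_order, 1)
      clade_of[host_id] <- cl
      for (pi in seq_len(config$phages_per_host)) {
        p <- p + 1L
        phage_id <- sprintf("phage_%04d", p)
        phages[phage_id] <- .markov_string(config$phage_genome_length,
                                           ct$tables[[cl]],
                                           config$markov_order,
                                           config$signal_strength)
        pairs <- rbind(pairs, data.frame(phage_id = phage_id,
                                         host_id = host_id, label = 1L,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(hosts = hosts, phages = phages, pairs = pairs,
                 clade_of = clade_of,
                 truth = list(config = config, clade_tables = ct$tables,
                              clade_compositions = ct$compositions)),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(paste0("<synthetic_corpus> %d hosts (%d clades), %d phages, ",
                     "%d positive pairs\n"),
              length(x$hosts), cfg$n_host_clades, length(x$phages),
              nrow(x$pairs)))
  cat(sprintf("  signal strength %.2f, Markov order %d\n",
              cfg$signal_strength, cfg$markov_order))
  invisible(x)
}

#' Hold out phages of a synthetic corpus for evaluation
#'
#' Default mode holds out a fraction of phages (unseen phages of seen
#' clades, the within-distribution task): their positive pairs form the
#' validation set and all remaining pairs the training set. `by =
#' "clade"` instead holds out every phage and host of one or more whole
#' clades (the harder generalization task to unseen compositional
#' neighbourhoods). Phage-level leakage control is trivially satisfied
#' here because every synthetic phage is its own cluster; hosts are
#' deliberately shared between the sets in the default mode, mirroring
#' how a host species seen in training is queried with novel phages.
#'
#' @param corpus A `synthetic_corpus`.
#' @param fraction Fraction of phages (or clades) held out.
#' @param by `"phage"` (default) or `"clade"`.
#' @return List with data frames `train` and `validation`.
#' @export
holdout_split <- function(corpus, fraction = 0.2, by = c("phage", "clade")) {
  stopifnot(inherits(corpus, "synthetic_corpus"),
            fraction > 0, fraction < 1)
  by <- match.arg(by)
  pairs <- corpus$pairs
  if (by == "phage") {
    ids <- unique(pairs$phage_id)
    val_ids <- sample(ids, max(1L, round(fraction * length(ids))))
    val <- pairs$phage_id %in% val_ids
  } else {
    clades <- sort(unique(corpus$clade_of))
    val_cl <- sample(clades, max(1L, round(fraction * length(clades))))
    val <- corpus$clade_of[pairs$host_id] %in% val_cl
  }
  list(train = pairs[!val, , drop = FALSE],
       validation = pairs[val, , drop = FALSE])
}

#' Genome store of a synthetic corpus
#'
#' @param corpus A `synthetic_corpus`.
#' @return A [genome_store()] usable by [phanet()] and the evaluators.
#' @export
corpus_store <- function(corpus) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  genome_store(corpus$phages, as.list(corpus$hosts))
}

#' Write / read a corpus directory
#'
#' `write_corpus` emits `hosts.fasta`, `phages.fasta`, `pairs.tsv`, a
#' one-cluster-per-phage `clusters.tsv` and a `manifest.json` recording
#' the generator parameters - exactly the formats the training pipeline
#' consumes. `read_corpus` round-trips them losslessly (the `truth`
#' slot keeps only what the manifest records).
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Directory (created if needed).
#' @return `write_corpus` returns `dir` invisibly; `read_corpus` returns
#'   a `synthetic_corpus`.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(corpus$hosts, file.path(dir, "hosts.fasta"))
  write_fasta(corpus$phages, file.path(dir, "phages.fasta"))
  write_pairs(corpus$pairs, file.path(dir, "pairs.tsv"))
  clusters <- data.frame(contig_id = names(corpus$phages),
                         cluster_id = paste0("cl_", names(corpus$phages)),
                         stringsAsFactors = FALSE)
  utils::write.table(clusters, file.path(dir, "clusters.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- corpus$truth$config
  manifest <- list(format = "phanet-synthetic-corpus", version = 1L,
                   clade_of = as.list(corpus$clade_of),
                   config = Filter(Negate(is.null), unclass(cfg)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  hosts_rec <- read_fasta(file.path(dir, "hosts.fasta"))
  phages_rec <- read_fasta(file.path(dir, "phages.fasta"))
  to_vec <- function(recs) {
    v <- vapply(recs, function(r) r$sequence, character(1))
    names(v) <- vapply(recs, function(r) r$id, character(1))
    v
  }
  cfgl <- man$config
  cfg <- do.call(synthetic_config,
                 cfgl[intersect(names(cfgl), names(formals(synthetic_config)))])
  structure(list(hosts = to_vec(hosts_rec), phages = to_vec(phages_rec),
                 pairs = read_pairs(file.path(dir, "pairs.tsv")),
                 clade_of = unlist(man$clade_of),
                 truth = list(config = cfg, clade_tables = NULL,
                              clade_compositions = NULL)),
            class = "synthetic_corpus")
}
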