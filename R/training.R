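# Training: leakage-aware splitting, per-epoch contig resampling from
# length menus, 1:1 negative-pair construction, Adam on binary
# cross-entropy, early stopping on validation loss.

#' Training control parameters
#'
#' Defaults follow the published protocol: learning rate 0.001, batch
#' size 32, up to 5000 epochs with early stopping when the monitored
#' validation loss fails to improve by 1e-5 for 50 consecutive epochs,
#' and contig lengths drawn per batch from the menus 200/500/1000/5000/
#' 10000/50000 bases for phages and the same plus 100000 for hosts.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Pairs per gradient step.
#' @param max_epochs Upper bound on epochs.
#' @param early_stop_delta Minimum improvement in validation loss that
#'   counts as progress.
#' @param early_stop_patience Epochs without such improvement before
#'   stopping.
#' @param phage_lengths,host_lengths Contig-length menus (bases); one
#'   phage length and one host length are drawn per batch, and contig
#'   sequences are re-sampled from the genomes at the start of every
#'   epoch.
#' @param negatives_per_positive Negative pairs drawn per positive pair
#'   each epoch (1 gives the 1:1 class balance used throughout).
#' @param val_reps Contig draws per validation pair when the fixed
#'   validation instance set is materialized at the start of training.
#' @param seed Optional integer seed for the whole run.
#' @return A `phanet_control` list.
#' @export
phanet_control <- function(learning_rate = 0.001, batch_size = 32L,
                           max_epochs = 5000L,
                           early_stop_delta = 1e-5,
                           early_stop_patience = 50L,
                           phage_lengths = c(200L, 500L, 1000L, 5000L, 10000L, 50000L),
                           host_lengths = c(200L, 500L, 1000L, 5000L, 10000L, 50000L, 100000L),
                           negatives_per_positive = 1L,
                           val_reps = 2L,
                           seed = NULL) {
  stopifnot(learning_rate >= 0, batch_size >= 1, max_epochs >= 1,
            length(phage_lengths) >= 1, length(host_lengths) >= 1,
            negatives_per_positive >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_delta = early_stop_delta,
                 early_stop_patience = as.integer(early_stop_patience),
                 phage_lengths = as.integer(phage_lengths),
                 host_lengths = as.integer(host_lengths),
                 negatives_per_positive = as.integer(negatives_per_positive),
                 val_reps = as.integer(val_reps),
                 seed = seed),
            class = "phanet_control")
}

#' A genome store
#'
#' Bundles phage genomes (one sequence per phage id) and host genomes
#' (one or more assemblies per host id) for the samplers.
#'
#' @param phages Named character vector or named list of single DNA
#'   strings, names = phage ids.
#' @param hosts Named list; each element a character vector of assembly
#'   sequences for that host id (a named character vector is promoted to
#'   one assembly each).
#' @return A `genome_store` list.
#' @export
genome_store <- function(phages, hosts) {
  if (is.list(phages)) phages <- unlist(phages)
  if (is.null(names(phages)) || anyNA(names(phages)))
    stop("'phages' must be named by phage id")
  if (!is.list(hosts)) hosts <- as.list(hosts)
  if (is.null(names(hosts))) stop("'hosts' must be named by host id")
  structure(list(phages = phages, hosts = hosts), class = "genome_store")
}

.check_pairs <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("phage_id", "host_id") %in% names(pairs)))
    stop("'pairs' must be a data frame with columns phage_id and host_id")
  pairs$phage_id <- as.character(pairs$phage_id)
  pairs$host_id <- as.character(pairs$host_id)
  pairs
}

#' Leakage-aware train/validation split
#'
#' Collapses each phage sequence cluster (from an external clustering
#' run at, e.g., 95% identity / 50% coverage) to one randomly chosen
#' representative phage, splits the remaining pairs at random into
#' training and validation fractions, then removes leakage: any training
#' pair whose phage cluster or host taxon also occurs in the validation
#' set is moved to the validation set, iterated to a fixed point, so no
#' phage cluster and no host taxon spans both sets.
#'
#' @param pairs Data frame with columns `phage_id`, `host_id` (positive
#'   pairs).
#' @param cluster_of Named character vector mapping every phage id to
#'   its cluster id.
#' @param host_taxon_of Optional named vector mapping host ids to a
#'   taxon at the rank used for leakage control; defaults to the host id
#'   itself.
#' @param train_fraction Fraction of pairs initially assigned to
#'   training (default 0.8).
#' @return List with data frames `train` and `validation`.
#' @export
split_pairs <- function(pairs, cluster_of, host_taxon_of = NULL,
                        train_fraction = 0.8) {
  pairs <- .check_pairs(pairs)
  stopifnot(train_fraction > 0, train_fraction < 1)
  missing_cl <- setdiff(unique(pairs$phage_id), names(cluster_of))
  if (length(missing_cl))
    stop("no cluster assignment for phage(s): ",
         paste(missing_cl, collapse = ", "))
  if (is.null(host_taxon_of)) {
    host_taxon_of <- unique(pairs$host_id)
    names(host_taxon_of) <- host_taxon_of
  }
  missing_tx <- setdiff(unique(pairs$host_id), names(host_taxon_of))
  if (length(missing_tx))
    stop("no taxon assignment for host(s): ",
         paste(missing_tx, collapse = ", "))

  # one representative phage per cluster
  phages <- unique(pairs$phage_id)
  reps <- vapply(split(phages, cluster_of[phages]),
                 function(x) if (length(x) == 1L) x else sample(x, 1L),
                 character(1))
  keep <- pairs$phage_id %in% reps
  pairs <- unique(pairs[keep, c("phage_id", "host_id")])

  n <- nrow(pairs)
  idx <- sample(n)
  n_train <- floor(train_fraction * n)
  in_train <- logical(n)
  in_train[idx[seq_len(n_train)]] <- TRUE

  cl <- unname(cluster_of[pairs$phage_id])
  tx <- unname(host_taxon_of[pairs$host_id])
  repeat {
    leak <- in_train & (cl %in% cl[!in_train] | tx %in% tx[!in_train])
    if (!any(leak)) break
    in_train[leak] <- FALSE
  }
  if (!any(in_train))
    warning("training set is empty after leakage removal")
  list(train = pairs[in_train, , drop = FALSE],
       validation = pairs[!in_train, , drop = FALSE])
}

#' Sample a contig from a genome
#'
#' Draws a substring of the requested length at a uniformly random start
#' position. A genome shorter than the requested length is returned
#' whole (rejecting such genomes would bias which species contribute
#' training contigs).
#'
#' @param genome A DNA string.
#' @param length Target contig length in bases.
#' @return A DNA string of `length` bases (or the whole genome if
#'   shorter).
#' @export
sample_contig <- function(genome, length) {
  genome <- .seq_chr(genome)
  L <- nchar(genome)
  if (L < 1L) stop("cannot sample from an empty genome")
  if (L <= length) return(genome)
  start <- sample.int(L - length + 1L, 1L)
  substr(genome, start, start + length - 1L)
}

# draw one element from a menu (safe for length-1 menus)
.pick <- function(v) v[sample.int(length(v), 1L)]

# phage id -> character vector of its positive host ids
.positives_index <- function(pairs) {
  pairs <- .check_pairs(pairs)
  split(pairs$host_id, pairs$phage_id)
}

#' Construct a negative pair for a phage
#'
#' Draws a host uniformly among hosts with no recorded positive
#' association with the phage, giving a label-0 pair. Used once per
#' positive pair per epoch to maintain the 1:1 positive/negative ratio.
#'
#' @param phage_id Phage identifier.
#' @param host_pool Character vector of candidate host ids.
#' @param positives_index Named list mapping phage id to its positive
#'   host ids (include all known positives, not just the training
#'   split, so sampled negatives are never mislabelled positives).
#' @return Data frame row (phage_id, host_id, label = 0).
#' @export
make_negative <- function(phage_id, host_pool, positives_index) {
  excl <- positives_index[[phage_id]]
  cand <- setdiff(host_pool, excl)
  if (length(cand) == 0L)
    stop("phage ", phage_id, " has a recorded positive pair with every host")
  data.frame(phage_id = phage_id,
             host_id = cand[sample.int(length(cand), 1L)],
             label = 0L, stringsAsFactors = FALSE)
}

.draw_host_assembly <- function(store, host_id) {
  g <- store$hosts[[host_id]]
  if (is.null(g)) stop("no genome for host ", host_id)
  if (length(g) == 1L) g else g[[sample.int(length(g), 1L)]]
}

.draw_phage_genome <- function(store, phage_id) {
  g <- store$phages[[phage_id]]
  if (is.null(g) || is.na(g)) stop("no genome for phage ", phage_id)
  g
}

# materialize labelled contig-pair instances from association pairs
.sample_instances <- function(pairs, store, L_p, L_h) {
  data.frame(
    phage_id = pairs$phage_id, host_id = pairs$host_id,
    label = pairs$label,
    phage_seq = vapply(pairs$phage_id, function(id)
      sample_contig(.draw_phage_genome(store, id), L_p), character(1)),
    host_seq = vapply(pairs$host_id, function(id)
      sample_contig(.draw_host_assembly(store, id), L_h), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

.with_labels <- function(pairs, label = 1L) {
  pairs <- .check_pairs(pairs)
  if (is.null(pairs$label)) pairs$label <- label
  pairs[, c("phage_id", "host_id", "label")]
}

# one epoch's worth of labelled pairs: all positives plus fresh negatives
.epoch_pairs <- function(positives, host_pool, pos_index, npn) {
  negs <- do.call(rbind, lapply(rep(positives$phage_id, npn), make_negative,
                                host_pool = host_pool,
                                positives_index = pos_index))
  rbind(.with_labels(positives, 1L), negs)
}

.adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

.adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

.eval_instances <- function(model, inst) {
  p <- predict_association(model, inst$phage_seq, inst$host_seq)
  eps <- 1e-12
  loss <- mean(-(inst$label * log(p + eps) + (1 - inst$label) * log(1 - p + eps)))
  auroc <- if (length(unique(inst$label)) == 2L)
    compute_auroc(p, inst$label) else NA_real_
  list(loss = loss, auroc = auroc, prob = p)
}

#' Fit a phage-host association network
#'
#' Trains the convolutional association model on positive pairs plus
#' per-epoch resampled negatives by minimizing binary cross-entropy with
#' Adam. At the start of every epoch, fresh negative pairs are drawn
#' (one per positive by default) and every pair is re-instantiated as a
#' newly sampled contig pair: one phage length and one host length are
#' drawn per batch from the menus in `control`, and contig start
#' positions are re-drawn from the genomes, so the network never sees
#' the same batch twice. Validation pairs are materialized once as a
#' fixed contig instance set and the validation loss is monitored for
#' early stopping; the returned model is the one from the best
#' validation epoch.
#'
#' @param pairs Data frame of positive training pairs (`phage_id`,
#'   `host_id`).
#' @param store A [genome_store()].
#' @param config Model architecture, a [phanet_config()].
#' @param control Optimization settings, a [phanet_control()].
#' @param validation Optional data frame of positive validation pairs;
#'   without it, early stopping monitors the training epoch loss.
#' @param model Optional pre-initialized `phanet_model` to continue
#'   training (its config overrides `config`).
#' @param verbose Print one line per epoch.
#' @return An object of class `phanet`: list with the trained `model`,
#'   per-epoch `history` (train loss, validation loss, validation
#'   AUROC), the `control`, and the fixed validation instance set.
#' @seealso [predict.phanet()], [evaluate_length_grid()]
#' @export
phanet <- function(pairs, store, config = phanet_config(),
                   control = phanet_control(), validation = NULL,
                   model = NULL, verbose = FALSE) {
  cl <- match.call()
  pairs <- .with_labels(pairs, 1L)
  if (nrow(pairs) == 0L) stop("no training pairs")
  stopifnot(inherits(store, "genome_store"))
  if (!is.null(control$seed)) set.seed(control$seed)
  if (is.null(model)) model <- phanet_init(config)
  cfg <- model$config

  host_pool <- names(store$hosts)
  all_pos <- rbind(pairs[, c("phage_id", "host_id")],
                   if (!is.null(validation))
                     .with_labels(validation)[, c("phage_id", "host_id")])
  pos_index <- .positives_index(all_pos)

  # fixed validation instance set (contigs drawn once, reused per epoch)
  val_inst <- NULL
  if (!is.null(validation) && nrow(validation) > 0L) {
    val_inst <- do.call(rbind, lapply(seq_len(control$val_reps), function(r) {
      vp <- .epoch_pairs(.with_labels(validation), host_pool, pos_index,
                         control$negatives_per_positive)
      .sample_instances(vp, store, .pick(control$phage_lengths),
                        .pick(control$host_lengths))
    }))
  }

  flat <- .flatten_params(model$params)
  opt <- .adam_init(flat)
  best <- list(loss = Inf, flat = flat, epoch = 0L)
  history <- NULL
  stall <- 0L

  for (epoch in seq_len(control$max_epochs)) {
    ep <- .epoch_pairs(pairs, host_pool, pos_index,
                       control$negatives_per_positive)
    ep <- ep[sample(nrow(ep)), , drop = FALSE]
    n_batch <- ceiling(nrow(ep) / control$batch_size)
    epoch_loss <- 0
    for (b in seq_len(n_batch)) {
      rows <- ((b - 1L) * control$batch_size + 1L):min(b * control$batch_size, nrow(ep))
      L_p <- .pick(control$phage_lengths)
      L_h <- .pick(control$host_lengths)
      inst <- .sample_instances(ep[rows, , drop = FALSE], store, L_p, L_h)
      model$params <- .unflatten_params(flat, model$params)
      acc <- NULL
      batch_loss <- 0
      for (i in seq_len(nrow(inst))) {
        g <- .pair_grad(model, inst$phage_seq[i], inst$host_seq[i],
                        inst$label[i])
        batch_loss <- batch_loss + g$loss
        if (is.null(acc)) acc <- g$grads
        else for (nm in names(g$grads)) acc[[nm]] <- acc[[nm]] + g$grads[[nm]]
      }
      if (!is.finite(batch_loss))
        stop(sprintf(paste0("non-finite loss in epoch %d, batch %d ",
                            "(L_p=%d, L_h=%d); try a lower learning rate"),
                     epoch, b, L_p, L_h))
      nb <- nrow(inst)
      acc <- lapply(acc, function(x) x / nb)
      if (control$learning_rate > 0) {
        st <- .adam_step(flat, acc, opt, control$learning_rate)
        flat <- st$flat
        opt <- st$state
      }
      epoch_loss <- epoch_loss + batch_loss
    }
    epoch_loss <- epoch_loss / nrow(ep)
    model$params <- .unflatten_params(flat, model$params)

    if (!is.null(val_inst)) {
      ev <- .eval_instances(model, val_inst)
      mon_loss <- ev$loss
      val_auroc <- ev$auroc
    } else {
      mon_loss <- epoch_loss
      val_auroc <- NA_real_
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = epoch_loss,
                                val_loss = if (!is.null(val_inst)) mon_loss else NA_real_,
                                val_auroc = val_auroc))
    if (verbose)
      message(sprintf("epoch %4d  train %.4f  val %.4f  auroc %s",
                      epoch, epoch_loss,
                      if (!is.null(val_inst)) mon_loss else NA,
                      ifelse(is.na(val_auroc), "-", sprintf("%.3f", val_auroc))))

    if (mon_loss < best$loss - control$early_stop_delta) {
      best <- list(loss = mon_loss, flat = flat, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= control$early_stop_patience) break
    }
  }

  model$params <- .unflatten_params(best$flat, model$params)
  structure(list(model = model, history = history, control = control,
                 best_epoch = best$epoch, validation = val_inst,
                 call = cl),
            class = "phanet")
}

#' Grid search over learning rate and batch size
#'
#' Evaluates each (learning rate, batch size) cell by k-fold
#' cross-validated validation loss at a reduced epoch budget and returns
#' the cell with the lowest mean fold loss. The published protocol used
#' a 4 x 4 grid with ten-fold cross-validation at the full epoch budget;
#' the default budget here is deliberately small so the search runs at
#' desk scale, and is exposed for larger runs.
#'
#' @param pairs Positive pairs data frame.
#' @param store A [genome_store()].
#' @param lr_grid,batch_grid Candidate values.
#' @param folds Number of cross-validation folds.
#' @param config Model architecture.
#' @param control Template [phanet_control()]; its learning rate and
#'   batch size are overridden per cell, `max_epochs` caps the per-fold
#'   budget.
#' @return List: `best` (learning_rate, batch_size), and `results` data
#'   frame of mean fold losses per cell.
#' @export
phanet_grid_search <- function(pairs, store, lr_grid = c(0.001, 0.0001),
                               batch_grid = c(32L), folds = 10L,
                               config = phanet_config(),
                               control = phanet_control(max_epochs = 3L)) {
  pairs <- .with_labels(pairs, 1L)
  stopifnot(length(lr_grid) >= 1, length(batch_grid) >= 1,
            folds >= 2 || nrow(pairs) == 0)
  if (!is.null(control$seed)) set.seed(control$seed)
  fold_of <- sample(rep_len(seq_len(folds), nrow(pairs)))
  cells <- expand.grid(learning_rate = lr_grid, batch_size = batch_grid)
  cells$mean_loss <- NA_real_
  for (ci in seq_len(nrow(cells))) {
    losses <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- pairs[fold_of != f, , drop = FALSE]
      va <- pairs[fold_of == f, , drop = FALSE]
      ctl <- control
      ctl$learning_rate <- cells$learning_rate[ci]
      ctl$batch_size <- as.integer(cells$batch_size[ci])
      ctl$seed <- NULL
      fit <- phanet(tr, store, config = config, control = ctl,
                    validation = va)
      losses[f] <- min(fit$history$val_loss, na.rm = TRUE)
    }
    cells$mean_loss[ci] <- mean(losses)
  }
  best <- cells[which.min(cells$mean_loss), , drop = FALSE]
  list(best = list(learning_rate = best$learning_rate,
                   batch_size = as.integer(best$batch_size)),
       results = cells, fold_of = fold_of)
}

## ---- methods for the fitted object ----

#' @export
print.phanet <- function(x, ...) {
  cat("Phage-host association network\n")
  cat(sprintf("  epochs run: %d (best validation epoch: %d)\n",
              nrow(x$history), x$best_epoch))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final train loss: %.4f\n", last$train_loss))
  if (!is.na(last$val_loss))
    cat(sprintf("  best validation loss: %.4f; validation AUROC at best: %.3f\n",
                min(x$history$val_loss, na.rm = TRUE),
                x$history$val_auroc[x$best_epoch]))
  print(x$model)
  invisible(x)
}

#' @method summary phanet
#' @export
summary.phanet <- function(object, ...) {
  structure(list(history = object$history, best_epoch = object$best_epoch,
                 config = object$model$config,
                 n_params = n_params(object)),
            class = "summary.phanet")
}

#' @export
print.summary.phanet <- function(x, ...) {
  cat("Training history (", nrow(x$history), " epochs):\n", sep = "")
  print(utils::tail(x$history, 5), row.names = FALSE)
  cat(sprintf("Best validation epoch: %d\nTrainable parameters: %s\n",
              x$best_epoch, format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Predict association probabilities from a fitted model
#'
#' @param object A fitted `phanet` object.
#' @param phage,host DNA strings or [contig_record()]s (equal-length
#'   vectors for batch scoring).
#' @param type `"response"` for probabilities, `"features"` for the
#'   concatenated phage/host feature vectors (one row per pair).
#' @param ... Unused.
#' @return Numeric vector of probabilities, or a feature matrix.
#' @export
predict.phanet <- function(object, phage, host, type = c("response", "features"),
                           ...) {
  type <- match.arg(type)
  if (type == "response") return(predict_association(object, phage, host))
  t(vapply(seq_along(phage),
           function(i) c(extract_features(object, phage[i], "phage"),
                         extract_features(object, host[i], "host")),
           numeric(2L * object$model$config$features_per_path *
                     length(object$model$config$paths))))
}

#' @method coef phanet
#' @export
coef.phanet <- function(object, ...) .flatten_params(object$model$params)

#' Plot the training history of a fitted model
#'
#' Loss curves (training and, when present, validation) on the left
#' axis; validation AUROC on the right axis when available.
#'
#' @param x A fitted `phanet` object.
#' @param ... Passed to [plot()].
#' @method plot phanet
#' @export
plot.phanet <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       ylim = range(c(h$train_loss, h$val_loss), na.rm = TRUE), ...)
  if (any(!is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", legend = c("train", "validation"),
                     lty = c(1, 2), bty = "n")
  }
  graphics::abline(v = x$best_epoch, col = "grey", lty = 3)
  invisible(x)
}
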