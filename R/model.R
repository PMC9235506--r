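# The four-path convolutional association network. Each enabled path
# (base, codon) is a stack of valid 1-D convolutions with ReLU and local
# max pooling, closed by a global pooling layer so contigs of any length
# map to a fixed-length feature vector. Phage and host sides share path
# weights by default; the codon-transformer front end is fixed, never
# trained. Forward and backward passes are written against the compiled
# kernels in src/.

#' Model configuration
#'
#' @param paths Character subset of `c("base", "codon")`; which encoding
#'   paths the network uses (both by default; single-path configurations
#'   support ablation experiments).
#' @param share_weights Logical; if `TRUE` (default) the phage and host
#'   sides of each path use the same parameters, making the feature
#'   extractor role-agnostic.
#' @param conv_channels Integer vector of output channels per
#'   convolution block. The last entry is the per-path feature count
#'   (256 by default, so a two-path model extracts 512 features per
#'   contig).
#' @param base_kernels,codon_kernels Kernel sizes per block for the base
#'   and codon paths; lengths must match `conv_channels`.
#' @param pool_width Width (= stride) of the local max pooling after
#'   each convolution block.
#' @param fc_hidden Integer vector of hidden widths of the fully
#'   connected head (the head input is the concatenated phage + host
#'   features; the output is a single sigmoid unit).
#' @param pooling Global pooling type: `"mean"` (default; matches the
#'   reading of convolution outputs as k-mer-frequency-like statistics,
#'   whose natural length-free summary is an average) or `"max"`.
#' @param min_length Minimum accepted contig length in bases; shorter
#'   inputs are rejected rather than padded.
#' @param seed Optional integer seed consumed by [phanet_init()].
#' @return A `phanet_config` list.
#' @export
phanet_config <- function(paths = c("base", "codon"),
                          share_weights = TRUE,
                          conv_channels = c(64L, 256L),
                          base_kernels = c(7L, 5L),
                          codon_kernels = c(3L, 3L),
                          pool_width = 4L,
                          fc_hidden = 256L,
                          pooling = c("mean", "max"),
                          min_length = 200L,
                          seed = NULL) {
  paths <- match.arg(paths, c("base", "codon"), several.ok = TRUE)
  if (length(paths) < 1L) stop("at least one of the 'base'/'codon' paths is required")
  pooling <- match.arg(pooling)
  nb <- length(conv_channels)
  if (length(base_kernels) != nb || length(codon_kernels) != nb)
    stop("'conv_channels', 'base_kernels' and 'codon_kernels' must have equal length")
  if (any(conv_channels < 1L) || any(base_kernels < 1L) || any(codon_kernels < 1L))
    stop("channel counts and kernel sizes must be positive")
  structure(list(
    paths = paths, share_weights = isTRUE(share_weights),
    conv_channels = as.integer(conv_channels),
    base_kernels = as.integer(base_kernels),
    codon_kernels = as.integer(codon_kernels),
    pool_width = as.integer(pool_width),
    features_per_path = as.integer(conv_channels[nb]),
    fc_hidden = as.integer(fc_hidden),
    pooling = pooling,
    min_length = as.integer(min_length),
    seed = seed
  ), class = "phanet_config")
}

.path_keys <- function(config) {
  if (config$share_weights) config$paths
  else as.vector(outer(c("phage", "host"), config$paths, paste, sep = "_"))
}

.path_key <- function(config, role, path) {
  if (config$share_weights) path else paste(role, path, sep = "_")
}

.init_mat <- function(nr, nc) {
  s <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

.init_path <- function(config, path) {
  ks <- if (path == "base") config$base_kernels else config$codon_kernels
  cin <- if (path == "base") 4L else 64L
  conv <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    cout <- config$conv_channels[i]
    conv[[i]] <- list(W = .init_mat(ks[i] * cin, cout),
                      b = rep(0, cout))
    cin <- cout
  }
  list(conv = conv)
}

#' Initialize an association network
#'
#' Draws seeded uniform fan-in initial weights (biases start at zero,
#' which keeps sparse one-hot-driven ReLU units alive) for the enabled
#' paths and the fully connected head. With shared weights the phage and host
#' sides of a path are literally the same parameter set; with
#' independent weights each role gets its own seeded draw. The
#' codon-transformer filter bank is analytic and carries no trainable
#' parameters.
#'
#' @param config A [phanet_config()].
#' @return An object of class `phanet_model`.
#' @export
phanet_init <- function(config = phanet_config()) {
  stopifnot(inherits(config, "phanet_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  params <- list(paths = list(), head = list())
  for (key in .path_keys(config)) {
    path <- sub("^(phage|host)_", "", key)
    params$paths[[key]] <- .init_path(config, path)
  }
  d <- 2L * config$features_per_path * length(config$paths)
  dims <- c(d, config$fc_hidden, 1L)
  layers <- vector("list", length(dims) - 1L)
  for (i in seq_along(layers)) {
    layers[[i]] <- list(W = .init_mat(dims[i], dims[i + 1L]),
                        b = rep(0, dims[i + 1L]))
  }
  # Siamese comparator initialization: with shared extractors the head
  # receives [phage features, host features]; start each first-layer
  # unit antisymmetric, u on the phage block and -u on the host block,
  # so it reads a signed feature difference from step one. The
  # association signal lives in the relation between the two blocks,
  # and a generic init leaves gradient descent to discover that
  # structure from scratch.
  half <- d %/% 2L
  U <- .init_mat(half, dims[2])
  layers[[1]]$W <- rbind(U, -U)
  params$head <- layers
  structure(list(config = config, params = params), class = "phanet_model")
}

#' @export
print.phanet_model <- function(x, ...) {
  cfg <- x$config
  cat("<phanet_model>\n")
  cat(sprintf("  paths: %s (%s weights)\n", paste(cfg$paths, collapse = " + "),
              if (cfg$share_weights) "shared phage/host" else "independent"))
  cat(sprintf("  features per contig: %d; global pooling: %s\n",
              cfg$features_per_path * length(cfg$paths), cfg$pooling))
  cat(sprintf("  parameters: %s\n",
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `phanet_model` or fitted `phanet` object.
#' @return Integer count.
#' @export
n_params <- function(model) {
  model <- .as_model(model)
  sum(vapply(.flatten_params(model$params), length, integer(1)))
}

.as_model <- function(x) {
  if (inherits(x, "phanet")) x$model
  else if (inherits(x, "phanet_model")) x
  else stop("expected a 'phanet_model' or a fitted 'phanet' object")
}

## ---- flat parameter registry (used by the optimizer) ----

.flatten_params <- function(params) {
  out <- list()
  for (key in names(params$paths)) {
    conv <- params$paths[[key]]$conv
    for (i in seq_along(conv)) {
      out[[paste("paths", key, i, "W", sep = ".")]] <- conv[[i]]$W
      out[[paste("paths", key, i, "b", sep = ".")]] <- conv[[i]]$b
    }
  }
  for (i in seq_along(params$head)) {
    out[[paste("head", i, "W", sep = ".")]] <- params$head[[i]]$W
    out[[paste("head", i, "b", sep = ".")]] <- params$head[[i]]$b
  }
  out
}

.unflatten_params <- function(flat, skeleton) {
  for (key in names(skeleton$paths)) {
    for (i in seq_along(skeleton$paths[[key]]$conv)) {
      skeleton$paths[[key]]$conv[[i]]$W <- flat[[paste("paths", key, i, "W", sep = ".")]]
      skeleton$paths[[key]]$conv[[i]]$b <- flat[[paste("paths", key, i, "b", sep = ".")]]
    }
  }
  for (i in seq_along(skeleton$head)) {
    skeleton$head[[i]]$W <- flat[[paste("head", i, "W", sep = ".")]]
    skeleton$head[[i]]$b <- flat[[paste("head", i, "b", sep = ".")]]
  }
  skeleton
}

## ---- forward / backward ----

.path_input <- function(path, base_mat, codon_mat) {
  X <- if (path == "base") base_mat else codon_mat
  storage.mode(X) <- "double"
  attr(X, "frame_rows") <- NULL
  dimnames(X) <- NULL
  X
}

.forward_path <- function(X, p, ks, pool_width, pooling) {
  nb <- length(p$conv)
  blocks <- vector("list", nb)
  for (i in seq_len(nb)) {
    if (nrow(X) < ks[i])
      stop(sprintf("contig too short for the network: %d rows reach a size-%d kernel",
                   nrow(X), ks[i]))
    Z <- nn_conv1d_fwd(X, p$conv[[i]]$W, p$conv[[i]]$b, ks[i])
    mask <- Z > 0
    A <- Z * mask
    w <- min(pool_width, nrow(A))
    mp <- nn_maxpool_fwd(A, w)
    blocks[[i]] <- list(X = X, mask = mask, pool_idx = mp$idx,
                        conv_rows = nrow(A), pool_width = w)
    X <- mp$Y
  }
  if (pooling == "max") {
    g <- nn_gmax_fwd(X)
    f <- as.numeric(g$y)
    gcache <- list(idx = as.integer(g$idx), n = nrow(X))
  } else {
    f <- colMeans(X)
    gcache <- list(idx = NULL, n = nrow(X))
  }
  list(f = f, cache = list(blocks = blocks, global = gcache, pooling = pooling))
}

.backward_path <- function(df, cache, p, ks) {
  g <- cache$global
  C <- length(df)
  if (cache$pooling == "max") {
    dX <- matrix(0, g$n, C)
    dX[cbind(g$idx, seq_len(C))] <- df
  } else {
    dX <- matrix(rep(df / g$n, each = g$n), g$n, C)
  }
  nb <- length(p$conv)
  grads <- vector("list", nb)
  for (i in rev(seq_len(nb))) {
    blk <- cache$blocks[[i]]
    dA <- nn_maxpool_bwd(blk$pool_idx, dX, blk$conv_rows)
    dZ <- dA * blk$mask
    bw <- nn_conv1d_bwd(blk$X, p$conv[[i]]$W, dZ, ks[i])
    grads[[i]] <- list(W = bw$dW, b = as.numeric(bw$db))
    dX <- bw$dX
  }
  grads
}

# Hidden head layers use a leaky rectifier (slope 0.01): the head's
# inputs are globally pooled post-ReLU features and hence non-negative,
# so with a hard rectifier a hidden unit whose weights turn negative
# would be dead for every input, permanently. The small negative slope
# keeps a recovery gradient.
.head_leak <- 0.01

.head_forward <- function(v, layers) {
  a <- v
  acts <- vector("list", length(layers))
  nl <- length(layers)
  for (i in seq_len(nl)) {
    acts[[i]] <- a
    z <- drop(a %*% layers[[i]]$W) + layers[[i]]$b
    a <- if (i < nl) ifelse(z > 0, z, .head_leak * z) else z
  }
  list(logit = a, acts = acts)
}

.head_backward <- function(dlogit, fwd, layers) {
  nl <- length(layers)
  grads <- vector("list", nl)
  da <- dlogit
  for (i in rev(seq_len(nl))) {
    a_in <- fwd$acts[[i]]
    if (i < nl) {
      z <- drop(a_in %*% layers[[i]]$W) + layers[[i]]$b
      da <- da * ifelse(z > 0, 1, .head_leak)
    }
    grads[[i]] <- list(W = outer(a_in, da), b = da)
    da <- drop(layers[[i]]$W %*% da)
  }
  list(grads = grads, dv = da)
}

.role_features <- function(model, seq, role, want_cache = FALSE) {
  cfg <- model$config
  base_mat <- encode_bases(seq)
  codon_mat <- if ("codon" %in% cfg$paths) apply_codon_transformer(base_mat) else NULL
  fs <- list(); caches <- list()
  for (path in cfg$paths) {
    key <- .path_key(cfg, role, path)
    ks <- if (path == "base") cfg$base_kernels else cfg$codon_kernels
    X <- .path_input(path, base_mat, codon_mat)
    r <- .forward_path(X, model$params$paths[[key]], ks, cfg$pool_width, cfg$pooling)
    fs[[path]] <- r$f
    caches[[path]] <- r$cache
  }
  out <- list(f = unlist(fs, use.names = FALSE))
  if (want_cache) out$caches <- caches
  out
}

.check_min_length <- function(model, seq, what) {
  L <- nchar(.seq_chr(seq))
  if (L < model$config$min_length)
    stop(sprintf("%s contig has %d bases; the model requires at least %d",
                 what, L, model$config$min_length))
}

#' Extract fixed-length features from a contig
#'
#' Runs the enabled convolutional paths and the global pooling layer,
#' producing a feature vector whose length (`features_per_path` per
#' path; 512 under the default two-path configuration) does not depend
#' on the contig length. With shared weights the `role` argument has no
#' effect on the result.
#'
#' @param model A `phanet_model` or fitted `phanet` object.
#' @param x A DNA string or [contig_record()].
#' @param role `"phage"` or `"host"`; selects the parameter set when
#'   weights are not shared. Defaults to the record's role, or
#'   `"phage"` for plain strings.
#' @return Numeric feature vector.
#' @export
extract_features <- function(model, x, role = NULL) {
  model <- .as_model(model)
  if (is.null(role))
    role <- if (inherits(x, "contig_record")) x$role else "phage"
  role <- match.arg(role, c("phage", "host"))
  .check_min_length(model, x, role)
  .role_features(model, .seq_chr(x), role)$f
}

#' Score a phage-host contig pair
#'
#' Concatenates the phage-side and host-side feature vectors (phage
#' features first) and passes them through the fully connected head with
#' a terminal sigmoid, yielding the probability that the two contigs are
#' associated. Vectorized over equal-length sequence vectors.
#'
#' @param model A `phanet_model` or fitted `phanet` object.
#' @param phage,host DNA strings (or [contig_record()]s); recycled
#'   pairwise if vectors of equal length.
#' @return Numeric vector of probabilities, strictly in (0, 1).
#' @export
predict_association <- function(model, phage, host) {
  model <- .as_model(model)
  if (inherits(phage, "contig_record")) phage <- phage$sequence
  if (inherits(host, "contig_record")) host <- host$sequence
  if (length(phage) != length(host))
    stop("'phage' and 'host' must have the same length")
  vapply(seq_along(phage), function(i) {
    .check_min_length(model, phage[i], "phage")
    .check_min_length(model, host[i], "host")
    fp <- .role_features(model, phage[i], "phage")$f
    fh <- .role_features(model, host[i], "host")$f
    .score_pair_features(model, fp, fh)
  }, numeric(1))
}

.score_pair_features <- function(model, fp, fh) {
  stats::plogis(.head_forward(c(fp, fh), model$params$head)$logit)
}

# Full forward + backward for one labelled pair; returns the BCE loss
# and a flat named gradient list (shared path keys accumulate both
# roles' contributions).
.pair_grad <- function(model, phage_seq, host_seq, label) {
  cfg <- model$config
  rp <- .role_features(model, phage_seq, "phage", want_cache = TRUE)
  rh <- .role_features(model, host_seq, "host", want_cache = TRUE)
  v <- c(rp$f, rh$f)
  hf <- .head_forward(v, model$params$head)
  p <- stats::plogis(hf$logit)
  eps <- 1e-12
  loss <- -(label * log(p + eps) + (1 - label) * log(1 - p + eps))
  hb <- .head_backward(p - label, hf, model$params$head)
  flat <- list()
  for (i in seq_along(hb$grads)) {
    flat[[paste("head", i, "W", sep = ".")]] <- hb$grads[[i]]$W
    flat[[paste("head", i, "b", sep = ".")]] <- hb$grads[[i]]$b
  }
  F1 <- cfg$features_per_path
  off <- 0L
  for (side in list(list(role = "phage", r = rp), list(role = "host", r = rh))) {
    for (path in cfg$paths) {
      df <- hb$dv[(off + 1L):(off + F1)]
      off <- off + F1
      key <- .path_key(cfg, side$role, path)
      ks <- if (path == "base") cfg$base_kernels else cfg$codon_kernels
      pg <- .backward_path(df, side$r$caches[[path]],
                           model$params$paths[[key]], ks)
      for (i in seq_along(pg)) {
        nw <- paste("paths", key, i, "W", sep = ".")
        nb_ <- paste("paths", key, i, "b", sep = ".")
        if (is.null(flat[[nw]])) {
          flat[[nw]] <- pg[[i]]$W
          flat[[nb_]] <- pg[[i]]$b
        } else {
          flat[[nw]] <- flat[[nw]] + pg[[i]]$W
          flat[[nb_]] <- flat[[nb_]] + pg[[i]]$b
        }
      }
    }
  }
  list(loss = loss, prob = p, grads = flat)
}

## ---- checkpoint I/O ----

#' Save / load a model checkpoint
#'
#' Checkpoints embed the configuration and a format version alongside
#' the parameters; loading a file that is not a phanet checkpoint, or a
#' newer format than this package understands, is an error. Round trips
#' are exact: a reloaded model scores fixed inputs bit-for-bit
#' identically.
#'
#' @param model A `phanet_model` or fitted `phanet` object.
#' @param path File path.
#' @return `read_phanet` returns the `phanet_model`; `write_phanet`
#'   returns `path` invisibly.
#' @export
write_phanet <- function(model, path) {
  model <- .as_model(model)
  saveRDS(list(format = "phanet-checkpoint", version = 1L,
               config = model$config, params = model$params),
          path)
  invisible(path)
}

#' @rdname write_phanet
#' @export
read_phanet <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "phanet-checkpoint"))
    stop("'", path, "' is not a phanet checkpoint")
  if (x$version > 1L)
    stop("checkpoint format version ", x$version, " is newer than this package")
  structure(list(config = x$config, params = x$params), class = "phanet_model")
}
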