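# Dual-granularity one-hot encodings of DNA contigs: a base-level L x 4
# matrix and a codon-level (3-frame) R x 64 matrix, plus the fixed
# codon-transformer convolution that maps the former to the latter.

BASES <- c("A", "C", "G", "T")

#' The 64 codons in lexicographic order
#'
#' Codon channel order is lexicographic over the alphabet (A, C, G, T),
#' i.e. AAA, AAC, AAG, AAT, ACA, ... This ordering is fixed: it defines
#' both the columns of [encode_codons()] and the kernel order of
#' [codon_filter()].
#'
#' @return Character vector of length 64.
#' @export
codon_alphabet <- function() .codons

.codons <- local({
  g <- expand.grid(c3 = BASES, c2 = BASES, c1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$c1, g$c2, g$c3)
})

# byte -> base code (1..4) lookup; everything else (N, ambiguity codes,
# gaps) maps to NA and hence to an all-zero one-hot row
.base_code <- local({
  m <- rep(NA_integer_, 256)
  m[utf8ToInt("A")] <- 1L; m[utf8ToInt("a")] <- 1L
  m[utf8ToInt("C")] <- 2L; m[utf8ToInt("c")] <- 2L
  m[utf8ToInt("G")] <- 3L; m[utf8ToInt("g")] <- 3L
  m[utf8ToInt("T")] <- 4L; m[utf8ToInt("t")] <- 4L
  m
})

.seq_chr <- function(x) {
  if (inherits(x, "contig_record")) x <- x$sequence
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("expected a single DNA sequence string")
  x
}

.base_codes <- function(x) .base_code[utf8ToInt(.seq_chr(x))]

#' A contig record
#'
#' Light-weight container for an identified DNA sequence with its role in
#' a phage-host pair and the genome it derives from.
#'
#' @param id Record identifier.
#' @param sequence DNA string over A/C/G/T plus ambiguity characters;
#'   case-insensitive.
#' @param role Either `"phage"` or `"host"`.
#' @param source_id Identifier of the genome/assembly of origin (defaults
#'   to `id`).
#' @return An object of class `contig_record`.
#' @export
contig_record <- function(id, sequence, role = c("phage", "host"),
                          source_id = id) {
  role <- match.arg(role)
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop("'sequence' must be a non-empty DNA string")
  structure(list(id = as.character(id), sequence = sequence, role = role,
                 source_id = as.character(source_id)),
            class = "contig_record")
}

#' @export
print.contig_record <- function(x, ...) {
  cat(sprintf("<contig_record> %s [%s] %d bp (source: %s)\n",
              x$id, x$role, nchar(x$sequence), x$source_id))
  invisible(x)
}

#' Base-level one-hot encoding
#'
#' Encodes a contig as an L x 4 binary matrix with column order
#' (A, C, G, T): A is (1,0,0,0), C is (0,1,0,0), G is (0,0,1,0) and T is
#' (0,0,0,1). Any other character (N, IUPAC ambiguity codes, gaps) yields
#' an all-zero row. Lower-case input encodes identically to upper-case.
#'
#' @param x A DNA string or a [contig_record()].
#' @return Integer matrix with `nchar(x)` rows, 4 columns named A,C,G,T.
#' @examples
#' encode_bases("ACGT")
#' encode_bases("N")  # all-zero row
#' @export
encode_bases <- function(x) {
  code <- .base_codes(x)
  n <- length(code)
  if (n == 0L) stop("cannot encode an empty sequence")
  m <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
  ok <- !is.na(code)
  m[cbind(seq_len(n)[ok], code[ok])] <- 1L
  m
}

#' Enumerate the three forward reading frames
#'
#' Reads the sequence left to right in each of the three codon phases on
#' the forward strand; trailing bases that do not complete a codon are
#' dropped. Frame f (0, 1, 2) therefore contains `floor((L - f) / 3)`
#' codons.
#'
#' @param x A DNA string or [contig_record()].
#' @return List of three character vectors, one per frame.
#' @examples
#' enumerate_frames("ATGCGTCAT")
#' @export
enumerate_frames <- function(x) {
  s <- toupper(.seq_chr(x))
  L <- nchar(s)
  lapply(0:2, function(f) {
    n <- max(0L, (L - f) %/% 3L)
    if (n == 0L) return(character(0))
    starts <- f + 1L + 3L * (seq_len(n) - 1L)
    substring(s, starts, starts + 2L)
  })
}

.codon_rows <- function(code, L) {
  # codon index rows (1..64 or NA) for one frame given base codes
  lapply(0:2, function(f) {
    n <- max(0L, (L - f) %/% 3L)
    if (n == 0L) return(integer(0))
    st <- f + 1L + 3L * (seq_len(n) - 1L)
    16L * (code[st] - 1L) + 4L * (code[st + 1L] - 1L) + code[st + 2L]
  })
}

#' Codon-level one-hot encoding (3-frame, direct enumeration)
#'
#' Encodes the three forward reading frames of a contig as a single
#' R x 64 binary matrix, R = sum over frames of `floor((L - f) / 3)`,
#' with the frame blocks stacked in frame order 0, 1, 2 along the rows.
#' Codon channels follow [codon_alphabet()]. A codon containing any
#' character outside A/C/G/T yields an all-zero row.
#'
#' @param x A DNA string or [contig_record()].
#' @return Integer matrix (R x 64) with a `frame_rows` attribute: a list
#'   of the three row-index ranges, one per frame.
#' @export
encode_codons <- function(x) {
  code <- .base_codes(x)
  rows <- .codon_rows(code, length(code))
  n <- lengths(rows)
  idx <- unlist(rows, use.names = FALSE)
  m <- matrix(0L, sum(n), 64L, dimnames = list(NULL, .codons))
  ok <- !is.na(idx)
  if (any(ok)) m[cbind(which(ok), idx[ok])] <- 1L
  ends <- cumsum(n)
  attr(m, "frame_rows") <- lapply(1:3, function(i) {
    if (n[i] == 0L) integer(0) else (ends[i] - n[i] + 1L):ends[i]
  })
  m
}

#' The fixed codon-transformer filter bank
#'
#' 64 convolution kernels of size 3 x 4, one per codon, each the
#' base-level one-hot matrix of that codon. Applied to a base one-hot
#' matrix together with a -2 bias and rectification, these kernels
#' compute the exact codon one-hot encoding (see
#' [apply_codon_transformer()]). The kernel order matches
#' [codon_alphabet()] and is stable across runs.
#'
#' @return List with elements `kernels` (named list of 64 3x4 integer
#'   matrices), `codons` (the index-to-codon mapping) and `W` (the same
#'   bank flattened to the 12 x 64 layout used by the convolution
#'   kernels, rows grouped by window offset).
#' @export
codon_filter <- function() {
  kernels <- lapply(.codons, encode_bases)
  names(kernels) <- .codons
  W <- matrix(0, 12L, 64L, dimnames = list(NULL, .codons))
  for (j in seq_len(64L)) {
    k <- kernels[[j]]
    for (o in 0:2) W[o * 4L + which(k[o + 1L, ] == 1L), j] <- 1
  }
  list(kernels = kernels, codons = .codons, W = W)
}

.codon_W <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- codon_filter()$W
    cache
  }
})

#' Codon encoding via the analytic codon-transformer convolution
#'
#' Computes f(M) = ReLU(F * M - 2) over every 3-row window of a base
#' one-hot matrix, where F is the fixed 64-kernel codon filter bank of
#' [codon_filter()]. A window matching codon c has inner product 3 with
#' kernel c and at most 2 with every other kernel, so after subtracting
#' 2 and rectifying, the output row is exactly the codon one-hot; any
#' window touching a non-A/C/G/T position has all inner products at most
#' 2 and yields an all-zero row. Window outputs are regrouped into the
#' three frame blocks, so the result is bit-identical to
#' [encode_codons()] on the same contig.
#'
#' @param base An L x 4 base one-hot matrix from [encode_bases()].
#' @return Integer matrix (R x 64) matching [encode_codons()], with the
#'   same `frame_rows` attribute.
#' @export
apply_codon_transformer <- function(base) {
  stopifnot(is.matrix(base), ncol(base) == 4L)
  L <- nrow(base)
  if (L < 3L) {
    m <- matrix(0L, 0L, 64L, dimnames = list(NULL, .codons))
    attr(m, "frame_rows") <- list(integer(0), integer(0), integer(0))
    return(m)
  }
  Y <- nn_conv1d_fwd(base, .codon_W(), rep(-2, 64L), 3L)
  Y[Y < 0] <- 0
  Lo <- L - 2L
  ord <- unlist(lapply(0:2, function(f) {
    if (f + 1L > Lo) integer(0) else seq.int(f + 1L, Lo, by = 3L)
  }), use.names = FALSE)
  out <- Y[ord, , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- list(NULL, .codons)
  n <- vapply(0:2, function(f) (L - f) %/% 3L, integer(1))
  ends <- cumsum(n)
  attr(out, "frame_rows") <- lapply(1:3, function(i) {
    if (n[i] == 0L) integer(0) else (ends[i] - n[i] + 1L):ends[i]
  })
  out
}
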