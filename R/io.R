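# Standard-format readers/writers shared across the package: FASTA
# (gzip-transparent, via Biostrings), pair tables, cluster maps.

#' Read a FASTA file into contig records
#'
#' Handles multi-line records, CRLF line endings and gzip compression
#' transparently; record order is preserved and the id is the first
#' whitespace-delimited token of the header.
#'
#' @param path FASTA file (optionally gzipped).
#' @param role Role to assign to the records, `"phage"` or `"host"`.
#' @return List of [contig_record()]s.
#' @export
read_fasta <- function(path, role = c("phage", "host")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  w <- Biostrings::width(set)
  if (any(w == 0L))
    stop("record(s) with empty sequence in ", path, ": ",
         paste(ids[w == 0L], collapse = ", "))
  if (anyDuplicated(ids))
    warning("duplicated record ids in ", path)
  seqs <- as.character(set)
  lapply(seq_along(set), function(i)
    contig_record(ids[i], unname(seqs[i]), role = role))
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of DNA strings, or a list of
#'   [contig_record()]s.
#' @param path Output path (a `.gz` suffix writes gzip).
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (is.list(seqs) && length(seqs) && inherits(seqs[[1]], "contig_record")) {
    v <- vapply(seqs, function(r) r$sequence, character(1))
    names(v) <- vapply(seqs, function(r) r$id, character(1))
    seqs <- v
  }
  if (is.null(names(seqs))) stop("'seqs' must be named")
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read / write a pair table
#'
#' TSV with header columns `phage_id`, `host_id` and optionally
#' `label` (assumed 1, i.e. positive, when absent).
#'
#' @param path TSV file.
#' @param pairs Data frame to write.
#' @return `read_pairs` returns the data frame with a `label` column.
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("phage_id", "host_id") %in% names(df)))
    stop(path, " must have columns phage_id and host_id")
  df$label <- if (is.null(df$label)) 1L else as.integer(df$label)
  df
}

#' @rdname read_pairs
#' @export
write_pairs <- function(pairs, path) {
  pairs <- .with_labels(pairs)
  utils::write.table(pairs, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a cluster map
#'
#' TSV with header columns `contig_id` and `cluster_id` (e.g. exported
#' from a CD-HIT or MMseqs2 run).
#'
#' @param path TSV file.
#' @return Named character vector: contig id -> cluster id.
#' @export
read_cluster_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("contig_id", "cluster_id") %in% names(df)))
    stop(path, " must have columns contig_id and cluster_id")
  stats::setNames(df$cluster_id, df$contig_id)
}
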