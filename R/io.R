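#' Read sequences from FASTA or FASTQ
#'
#' Thin wrappers around Biostrings' parsers that return plain [seq_record()]
#' lists. Sequences are uppercased; characters outside A/C/G/T/N are
#' collapsed to N with a warning; duplicate ids are suffixed with an ordinal
#' and logged rather than rejected. FASTQ qualities are decoded from
#' Phred+33.
#'
#' @param path file path.
#' @param circular logical, recycled over records (FASTA carries no topology,
#'   so circularity is declared by the caller; default linear).
#' @return A named list of [seq_record()]s, in file order.
#' @export
read_fasta <- function(path, circular = FALSE) {
  xs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(xs) == 0L) {
    warning(sprintf("no records in '%s'", path))
    return(structure(list(), names = character(0)))
  }
  circular <- rep_len(circular, length(xs))
  ids <- sub("\\s.*$", "", names(xs))
  recs <- lapply(seq_along(xs), function(k)
    seq_record(ids[k], as.character(xs[[k]]), circular = circular[k]))
  name_records(recs)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  xs <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  if (length(xs) == 0L) {
    warning(sprintf("no records in '%s'", path))
    return(structure(list(), names = character(0)))
  }
  quals <- S4Vectors::mcols(xs)$qualities
  ids <- sub("\\s.*$", "", names(xs))
  recs <- lapply(seq_along(xs), function(k)
    seq_record(ids[k], as.character(xs[[k]]),
               qualities = utf8ToInt(as.character(quals[[k]])) - 33L))
  name_records(recs)
}

#' Write sequence records to FASTA or FASTQ
#'
#' @param records a list of [seq_record()]s.
#' @param path output file path.
#' @param width line-wrap width for FASTA sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    n <- nchar(r$sequence)
    starts <- seq.int(1L, max(n, 1L), by = width)
    writeLines(substring(r$sequence, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    if (is.null(r$qualities))
      stop(sprintf("record '%s' has no qualities; cannot write FASTQ", r$id))
    writeLines(c(paste0("@", r$id), r$sequence, "+",
                 intToUtf8(r$qualities + 33L)), con)
  }
  invisible(path)
}

#' Filter reads by mean quality and length
#'
#' Mean read quality is the Phred transform of the arithmetic mean per-base
#' error probability (`-10 log10(mean(10^(-Q/10)))`), the convention of the
#' usual nanopore filtering tools - not the mean of the Q values, which would
#' be systematically optimistic. The standard passing-read threshold is Q >= 7.
#'
#' @param reads list of [seq_record()]s with qualities.
#' @param params a [filter_params()] object.
#' @return `list(kept = <records>, rejected = <count>)`.
#' @export
filter_reads <- function(reads, params = filter_params()) {
  if (length(reads) == 0L) return(list(kept = reads, rejected = 0L))
  has_q <- vapply(reads, function(r) !is.null(r$qualities), TRUE)
  if (!all(has_q)) stop("reads without qualities cannot be quality-filtered")
  keep <- vapply(reads, function(r) {
    len <- nchar(r$sequence)
    mean_read_quality(r$qualities) >= params$min_mean_q &&
      len >= params$min_len && len <= params$max_len
  }, TRUE)
  list(kept = reads[keep], rejected = sum(!keep))
}

#' @rdname filter_reads
#' @param min_mean_q Phred threshold on the mean read quality (default 7).
#' @param min_len,max_len read-length bounds in bases.
#' @export
filter_params <- function(min_mean_q = 7, min_len = 0L, max_len = Inf) {
  stopifnot(min_mean_q >= 0, min_len <= max_len)
  structure(list(min_mean_q = min_mean_q, min_len = min_len,
                 max_len = max_len), class = "filter_params")
}

#' @rdname filter_reads
#' @param qualities integer vector of per-base Phred scores.
#' @export
mean_read_quality <- function(qualities) {
  -10 * log10(mean(10^(-qualities / 10)))
}
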