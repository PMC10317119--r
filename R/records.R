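#' Sequence records
#'
#' A `seq_record` is the package's light-weight container for a named,
#' possibly circular DNA sequence with optional per-base Phred qualities.
#' Collections of records are plain named lists (names = record ids).
#'
#' @param id record identifier (non-empty string, no whitespace).
#' @param sequence DNA string over A/C/G/T/N (uppercased on input; any other
#'   character is collapsed to N with a warning).
#' @param qualities optional integer vector of per-base Phred scores, same
#'   length as the sequence.
#' @param circular logical topology flag (plasmids are circular; rotated
#'   references and reads are linear).
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, sequence, qualities = NULL, circular = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("id must be a non-empty string")
  sequence <- toupper(as.character(sequence))
  n_bad <- nchar(gsub("[ACGTN]", "", sequence))
  if (n_bad > 0) {
    warning(sprintf("record '%s': %d non-ACGTN character(s) collapsed to N",
                    id, n_bad))
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  if (!is.null(qualities)) {
    qualities <- as.integer(qualities)
    if (length(qualities) != nchar(sequence))
      stop(sprintf("record '%s': qualities length != sequence length", id))
  }
  structure(list(id = id, sequence = sequence, qualities = qualities,
                 circular = isTRUE(circular)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$sequence)
  head <- if (n > 40) paste0(substr(x$sequence, 1, 37), "...") else x$sequence
  cat(sprintf("seq_record %s: %d bp, %s%s\n", x$id, n,
              if (x$circular) "circular" else "linear",
              if (!is.null(x$qualities)) ", with qualities" else ""))
  cat(" ", head, "\n")
  invisible(x)
}

# name a list of records by their ids, de-duplicating ids with an ordinal
# suffix (real FASTQ dumps sometimes contain duplicates; not fatal)
name_records <- function(records) {
  ids <- vapply(records, `[[`, "", "id")
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sprintf("%d duplicate record id(s) suffixed with an ordinal",
                    sum(dup)))
    ids <- make.unique(ids, sep = "_dup")
    for (k in which(dup)) records[[k]]$id <- ids[k]
  }
  names(records) <- ids
  records
}

#' Extract the sequences of a record collection
#'
#' @param records a list of [seq_record()]s.
#' @return A character vector of sequences, named by element.
#' @export
seq_of <- function(records) vapply(records, `[[`, "", "sequence")
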