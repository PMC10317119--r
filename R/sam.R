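# SAM text output for read-to-reference alignments, so pileups can be viewed
# in IGV or processed with samtools. Reads mapped across a circular origin are
# split into a primary + supplementary record (FLAG 2048) so that POS + CIGAR
# never run past the reference length.

# merge M/X into CIGAR M and prepend/append soft clips
cigar_string <- function(ops, clip_left = 0L, clip_right = 0L) {
  op <- ifelse(ops$op %in% c("M", "X"), "M", ops$op)
  keep <- ops$len > 0L
  op <- op[keep]; len <- ops$len[keep]
  if (length(op) > 1L) {
    grp <- cumsum(c(TRUE, op[-1] != op[-length(op)]))
    len <- as.integer(tapply(len, grp, sum))
    op <- op[!duplicated(grp)]
  }
  parts <- paste0(len, op)
  if (clip_left > 0L) parts <- c(paste0(clip_left, "S"), parts)
  if (clip_right > 0L) parts <- c(parts, paste0(clip_right, "S"))
  paste(parts, collapse = "")
}

# split run-length ops after `tcols` consumed target columns
split_ops_at_target <- function(ops, tcols) {
  consumed <- 0L; q_used <- 0L
  out1 <- list(); out2 <- list()
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    uses_t <- op %in% c("M", "X", "D")
    uses_q <- op %in% c("M", "X", "I")
    if (!uses_t) {
      if (consumed < tcols) { out1[[length(out1) + 1L]] <- c(op, len); if (uses_q) q_used <- q_used + len }
      else out2[[length(out2) + 1L]] <- c(op, len)
      next
    }
    if (consumed + len <= tcols) {
      out1[[length(out1) + 1L]] <- c(op, len)
      if (uses_q) q_used <- q_used + len
      consumed <- consumed + len
    } else if (consumed >= tcols) {
      out2[[length(out2) + 1L]] <- c(op, len)
    } else {
      left <- tcols - consumed
      out1[[length(out1) + 1L]] <- c(op, left)
      out2[[length(out2) + 1L]] <- c(op, len - left)
      if (uses_q) q_used <- q_used + left
      consumed <- tcols
    }
  }
  to_df <- function(x) {
    if (length(x) == 0L) return(data.frame(op = character(0), len = integer(0)))
    data.frame(op = vapply(x, `[`, "", 1L),
               len = as.integer(vapply(x, `[`, "", 2L)),
               stringsAsFactors = FALSE)
  }
  list(first = to_df(out1), second = to_df(out2), query_in_first = q_used)
}

#' Write alignments as SAM
#'
#' Emits an unsorted text SAM (`@HD`/`@SQ` headers) for the alignments kept by
#' [map_reads()]. Reverse-orientation reads are flagged 16 and stored
#' reverse-complemented (the orientation the aligner used). Alignments that
#' wrap a circular reference origin are split into primary + supplementary
#' records so coordinates stay within the reference length.
#'
#' @param alignments list of read alignments from [map_reads()].
#' @param refs named list of reference [seq_record()]s (for `@SQ` lines).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (r in refs)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", r$id, nchar(r$sequence)), con)
  writeLines("@PG\tID:plasmidpool\tPN:plasmidpool", con)
  for (a in alignments) {
    L <- a$ref_len
    if (a$target_start < 0 || a$target_start >= L || a$target_end > 2 * L)
      stop(sprintf("read '%s': alignment coordinates outside reference", a$read_id))
    flag0 <- if (a$orientation == "reverse") 16L else 0L
    qual <- if (is.null(a$qual)) "*" else intToUtf8(a$qual + 33L)
    if (a$target_end <= L) {
      cig <- cigar_string(a$ops, a$clip_left, a$clip_right)
      writeLines(paste(a$read_id, flag0, a$ref_id, a$target_start + 1L, 60L,
                       cig, "*", 0L, 0L, a$seq, qual, sep = "\t"), con)
    } else {
      sp <- split_ops_at_target(a$ops, L - a$target_start)
      aligned_q <- sum(a$ops$len[a$ops$op %in% c("M", "X", "I")])
      q1 <- sp$query_in_first
      cig1 <- cigar_string(sp$first, a$clip_left,
                           a$clip_right + aligned_q - q1)
      cig2 <- cigar_string(sp$second, a$clip_left + q1, a$clip_right)
      writeLines(paste(a$read_id, flag0, a$ref_id, a$target_start + 1L, 60L,
                       cig1, "*", 0L, 0L, a$seq, qual, sep = "\t"), con)
      writeLines(paste(a$read_id, flag0 + 2048L, a$ref_id, 1L, 60L,
                       cig2, "*", 0L, 0L, a$seq, qual, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Parse a CIGAR string
#'
#' Splits a SAM CIGAR string into its operation/length runs, e.g. for
#' counting read populations by their deletion signature.
#'
#' @param cigar a CIGAR string (`"100M22D78M"`), or `"*"`.
#' @return A data frame with columns `op` and `len` (empty for `"*"`).
#' @export
parse_cigar <- function(cigar) {
  if (cigar == "*") return(data.frame(op = character(0), len = integer(0)))
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  tok <- regmatches(cigar, list(m))[[1]]
  data.frame(op = sub("^\\d+", "", tok),
             len = as.integer(sub("[MIDNSHP=X]$", "", tok)),
             stringsAsFactors = FALSE)
}
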