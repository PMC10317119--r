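# Consensus-versus-reference validation: a global alignment under the
# needle-default scheme, tallies of substitutions and gap events/bases, and a
# per-plasmid 0-100 quality score defined as the per-column error fraction:
# 100 * (1 - (substitutions + inserted bases + deleted bases) / columns).

#' Compare a consensus sequence against its reference
#'
#' Globally aligns consensus (query) against reference (target) and tallies
#' per-column differences. Each maximal gap run counts as one event; its
#' length counts in bases. An insertion is consensus sequence absent from the
#' reference, a deletion is reference sequence missing from the consensus.
#'
#' @param consensus consensus sequence (character scalar or
#'   `consensus_result`).
#' @param ref reference [seq_record()] (or character scalar).
#' @param scheme the comparison [scoring_scheme()]; defaults to
#'   [report_scheme()] (match 5, mismatch -4, gap open -10, extend -0.5).
#' @return A `gap_report`: `ref_id`, `substitutions`, `insertion_events`,
#'   `insertion_bases`, `deletion_events`, `deletion_bases`,
#'   `alignment_columns`, `identity_pct`, `quality_score`, plus the
#'   underlying `alignment`.
#' @export
compare_consensus <- function(consensus, ref, scheme = report_scheme()) {
  cseq <- if (inherits(consensus, "consensus_result")) consensus$sequence else consensus
  rseq <- if (inherits(ref, "seq_record")) ref$sequence else ref
  rid <- if (inherits(ref, "seq_record")) ref$id else "reference"
  if (!nzchar(cseq) || !nzchar(rseq)) stop("empty sequence in comparison")
  aln <- global_align(cseq, rseq, scheme)
  ops <- aln$ops
  subs <- sum(ops$len[ops$op == "X"])
  ins_e <- sum(ops$op == "I"); ins_b <- sum(ops$len[ops$op == "I"])
  del_e <- sum(ops$op == "D"); del_b <- sum(ops$len[ops$op == "D"])
  ncols <- aln$n_cols
  structure(list(
    ref_id = rid,
    substitutions = subs,
    insertion_events = ins_e, insertion_bases = ins_b,
    deletion_events = del_e, deletion_bases = del_b,
    alignment_columns = ncols,
    identity_pct = 100 * aln$n_match / ncols,
    quality_score = max(0, 100 * (1 - (subs + ins_b + del_b) / ncols)),
    alignment = aln
  ), class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("gap report vs %s: %d substitutions, %d insertion(s) (%d bp), %d deletion(s) (%d bp)\n",
              x$ref_id, x$substitutions, x$insertion_events, x$insertion_bases,
              x$deletion_events, x$deletion_bases))
  cat(sprintf("  identity %.2f%% over %d columns; quality score %.2f\n",
              x$identity_pct, x$alignment_columns, x$quality_score))
  invisible(x)
}

#' Largest single indel event in a gap report
#'
#' @param report a `gap_report` from [compare_consensus()].
#' @return Length in bases of the largest single insertion or deletion run.
#' @export
max_indel_bases <- function(report) {
  ops <- report$alignment$ops
  idx <- ops$op %in% c("I", "D")
  if (!any(idx)) 0L else max(ops$len[idx])
}

#' Net indel at a reference position
#'
#' Net inserted-minus-deleted bases among the gap runs of a
#' consensus-versus-reference alignment near a reference position. A global
#' aligner may render one long insertion of foreign sequence as several gap
#' runs broken by chance matches, so the net gap count in a window - the way
#' one reads a needle report - is the robust measure of "an indel of size N
#' at this locus".
#'
#' @param report a `gap_report` from [compare_consensus()].
#' @param position 0-based reference position of interest.
#' @param window half-width of the reference window (bases).
#' @return Net inserted bases minus deleted bases within the window
#'   (positive = insertion, negative = deletion).
#' @export
indel_at <- function(report, position, window = 50L) {
  ops <- report$alignment$ops
  tlen <- ifelse(ops$op %in% c("M", "X", "D"), ops$len, 0L)
  t_end <- cumsum(tlen)
  t_start <- t_end - tlen
  near <- t_end >= position - window & t_start <= position + window
  sum(ops$len[near & ops$op == "I"]) - sum(ops$len[near & ops$op == "D"])
}

#' Summarize a validation run per plasmid
#'
#' Emits a per-plasmid TSV (reads assigned, mean depth, gap tallies, quality
#' score, pass/flag status) and a needle-style alignment file per plasmid.
#' A plasmid is flagged when its quality score falls below `flag_quality` or
#' when any single indel of at least `flag_indel` bases is present; flagging
#' is advisory, nothing is removed.
#'
#' @param assignments assignment data frame (from [bin_reads()] or
#'   [assign_clonal_reads()]), or `NULL`.
#' @param consensuses named list (ref id -> `consensus_result` or `NULL`).
#' @param gap_reports named list (ref id -> `gap_report` or `NULL`).
#' @param refs named list of reference [seq_record()]s.
#' @param dir output directory (created if needed).
#' @param flag_quality quality-score threshold (default 99.5).
#' @param flag_indel single-indel size that triggers a flag (default 10 bp).
#' @return The summary data frame, invisibly; written to
#'   `<dir>/summary.tsv` together with one `<ref>_vs_consensus.txt` per
#'   plasmid with a consensus.
#' @export
run_report <- function(assignments, consensuses, gap_reports, refs, dir,
                       flag_quality = 99.5, flag_indel = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (id in names(refs)) {
    n_reads <- if (!is.null(assignments))
      sum(assignments$assigned_ref == id, na.rm = TRUE) else NA_integer_
    cons <- consensuses[[id]]
    rep <- gap_reports[[id]]
    if (is.null(cons) || is.null(rep)) {
      rows[[id]] <- data.frame(
        ref_id = id, reads = n_reads, mean_depth = 0,
        substitutions = NA_integer_, insertion_bases = NA_integer_,
        deletion_bases = NA_integer_, gaps = NA_integer_,
        quality_score = NA_real_, max_indel = NA_integer_,
        status = "no-consensus", stringsAsFactors = FALSE)
      next
    }
    mi <- max_indel_bases(rep)
    flagged <- rep$quality_score < flag_quality || mi >= flag_indel
    rows[[id]] <- data.frame(
      ref_id = id, reads = n_reads,
      mean_depth = round(cons$mean_depth, 1),
      substitutions = rep$substitutions,
      insertion_bases = rep$insertion_bases,
      deletion_bases = rep$deletion_bases,
      gaps = rep$substitutions + rep$insertion_bases + rep$deletion_bases,
      quality_score = round(rep$quality_score, 3),
      max_indel = mi,
      status = if (flagged) "flagged" else "pass",
      stringsAsFactors = FALSE)
    write_pairwise_report(
      rep$alignment, paste0(id, "_consensus"), id,
      cons$sequence, refs[[id]]$sequence,
      file.path(dir, paste0(id, "_vs_consensus.txt")))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  utils::write.table(summary, file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(summary)
}
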