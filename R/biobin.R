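# Two-stage barcode-free read binning. Stage 1 ("context score") local-aligns
# the read against each unique region extended by 20-bp flanks; stage 2
# ("fine score") re-aligns the context-stage hit against the bare marker.
# A read is assigned iff exactly one reference passes both thresholds.

#' Binning parameters
#'
#' @param scheme alignment [scoring_scheme()]; default the binning scheme
#'   (match 3, mismatch -6, gap open -10, extend -5).
#' @param context_threshold minimum normalized context score (percent of the
#'   perfect-match score of the flanked region). The default of 55 lets a
#'   full-context hit tolerate roughly 10 percent read error.
#' @param fine_threshold normalized fine-score gate; a read is assigned only
#'   when its context hit scores strictly above this against the bare marker
#'   (default 80).
#' @param flank context flank width (bases).
#' @return A `binning_params` object.
#' @export
binning_params <- function(scheme = binning_scheme(), context_threshold = 55,
                           fine_threshold = 80, flank = 20L) {
  stopifnot(context_threshold >= 0, context_threshold <= 100,
            fine_threshold >= 0, fine_threshold <= 100)
  structure(list(scheme = scheme, context_threshold = context_threshold,
                 fine_threshold = fine_threshold, flank = flank),
            class = "binning_params")
}

# seed-and-extend local alignment of a long read against a short target:
# shared k-mers nominate diagonals; a windowed Smith-Waterman around the best
# diagonal clusters gives the local alignment without touching the rest of
# the read. Falls back to a full local DP when no seed is found and the read
# is short enough for that to be cheap.
seeded_local <- function(read_seq, read_codes, target, target_codes, scheme,
                         k = 11L, max_clusters = 2L) {
  tlen <- nchar(target)
  hits <- which(read_codes %in% target_codes)
  windows <- list()
  if (length(hits)) {
    tpos <- match(read_codes[hits], target_codes)
    diag <- hits - tpos
    ord <- order(diag)
    d <- diag[ord]
    grp <- cumsum(c(1L, as.integer(diff(d) > 50L)))
    sizes <- tapply(d, grp, length)
    centers <- tapply(d, grp, stats::median)
    top <- order(-sizes)[seq_len(min(max_clusters, length(sizes)))]
    pad <- 30L + ceiling(0.15 * tlen)
    for (g in top) {
      c0 <- as.integer(centers[g])
      windows[[length(windows) + 1L]] <-
        c(max(0L, c0 - pad), min(nchar(read_seq), c0 + tlen + pad))
    }
  } else if (nchar(read_seq) <= 2000L) {
    windows[[1L]] <- c(0L, nchar(read_seq))
  } else {
    return(NULL)
  }
  best <- NULL
  for (w in windows) {
    if (w[2] - w[1] < 1L) next
    seg <- substr(read_seq, w[1] + 1L, w[2])
    aln <- local_align(seg, target, scheme)
    if (is.null(best) || aln$score > best$score) {
      best <- aln
      best$query_interval <- best$query_interval + w[1]
    }
  }
  best
}

#' Context score of a read against a unique region
#'
#' Local-aligns the read (both orientations) against the marker's flanked
#' context and normalizes by the perfect-match score of the context. Returns
#' the better orientation and the read span covering the hit, which feeds the
#' fine-score stage.
#'
#' @param read a [seq_record()].
#' @param region a `unique_region` from [find_unique_regions()].
#' @param params [binning_params()].
#' @return `list(score, orientation, read_span)` with `read_span` a 0-based
#'   half-open interval on the read in the reported orientation; score 0 and
#'   `NULL` span when nothing aligns.
#' @export
context_score <- function(read, region, params = binning_params()) {
  k <- min(11L, nchar(region$context))
  ctx_codes <- kmer_codes_cpp(region$context, k)
  res <- context_score_prepared(
    list(fwd = read$sequence, rev = revcomp(read$sequence)),
    list(fwd = kmer_codes_cpp(read$sequence, k),
         rev = kmer_codes_cpp(revcomp(read$sequence), k)),
    region$context, ctx_codes, params)
  res
}

context_score_prepared <- function(seqs, codes, context, ctx_codes, params) {
  best <- list(score = 0, orientation = "forward", read_span = NULL)
  for (ori in c("forward", "reverse")) {
    key <- if (ori == "forward") "fwd" else "rev"
    aln <- seeded_local(seqs[[key]], codes[[key]], context, ctx_codes,
                        params$scheme)
    if (is.null(aln)) next
    sc <- normalized_score(aln, nchar(context), params$scheme)
    if (sc > best$score) {
      best <- list(score = sc, orientation = ori,
                   read_span = aln$query_interval)
    }
  }
  best
}

#' Fine score of a context hit against the bare marker
#'
#' @param read_span_seq the read subsequence covering the context-stage hit
#'   (in the orientation the context stage chose).
#' @param region the `unique_region`.
#' @param params [binning_params()].
#' @return Normalized percent score against the bare marker.
#' @export
fine_score <- function(read_span_seq, region, params = binning_params()) {
  if (!nzchar(read_span_seq)) return(0)
  aln <- local_align(read_span_seq, region$marker, params$scheme)
  normalized_score(aln, nchar(region$marker), params$scheme)
}

#' Assign pooled reads to references by two-stage unique-region binning
#'
#' For each read the best region per reference is scored (context stage, then
#' fine stage on the context hit). A read is assigned iff exactly one
#' reference passes both thresholds; reads passing for two or more references
#' are ambiguous; the rest are below-threshold. Every input read lands in
#' exactly one of those states.
#'
#' @param reads list of read [seq_record()]s.
#' @param refs named list of reference [seq_record()]s.
#' @param regions result of [find_unique_regions()] on the same references.
#' @param params [binning_params()].
#' @return `list(bins = <ref_id -> list of reads>, assignments = <data frame
#'   with read_id, assigned_ref, context, fine, orientation, status>)`.
#'   `context` and `fine` are the scores for the assigned reference, or the
#'   best-scoring reference otherwise.
#' @export
bin_reads <- function(reads, refs, regions, params = binning_params()) {
  ids <- names(regions)
  n_regions <- lengths(regions)
  if (any(n_regions == 0L))
    warning(sprintf("reference(s) without unique regions excluded from binning: %s",
                    paste(ids[n_regions == 0L], collapse = ", ")))
  cand <- ids[n_regions > 0L]
  ctx_codes <- lapply(regions, function(rl)
    lapply(rl, function(r) kmer_codes_cpp(r$context, min(11L, nchar(r$context)))))

  bins <- stats::setNames(lapply(ids, function(i) list()), ids)
  rows <- vector("list", length(reads))
  short_logged <- FALSE

  for (ri in seq_along(reads)) {
    read <- reads[[ri]]
    fwd <- read$sequence
    rev <- revcomp(fwd)
    seqs <- list(fwd = fwd, rev = rev)
    codes <- list(fwd = kmer_codes_cpp(fwd, 11L),
                  rev = kmer_codes_cpp(rev, 11L))
    best_ctx <- best_fine <- stats::setNames(numeric(length(cand)), cand)
    best_ori <- stats::setNames(rep("forward", length(cand)), cand)
    ref_pass <- stats::setNames(logical(length(cand)), cand)
    for (id in cand) {
      rl <- regions[[id]]
      for (gi in seq_along(rl)) {
        region <- rl[[gi]]
        if (!short_logged && nchar(fwd) < nchar(region$context)) {
          message("note: some reads are shorter than a marker context; ",
                  "they are still scored by local alignment")
          short_logged <- TRUE
        }
        cs <- context_score_prepared(seqs, codes, region$context,
                                     ctx_codes[[id]][[gi]], params)
        fine <- 0
        if (cs$score >= params$context_threshold && !is.null(cs$read_span)) {
          span_seq <- substr(seqs[[if (cs$orientation == "forward") "fwd" else "rev"]],
                             cs$read_span[1] + 1L, cs$read_span[2])
          fine <- fine_score(span_seq, region, params)
          if (fine > params$fine_threshold) ref_pass[id] <- TRUE
        }
        if (cs$score > best_ctx[id]) {
          best_ctx[id] <- cs$score
          best_ori[id] <- cs$orientation
        }
        best_fine[id] <- max(best_fine[id], fine)
      }
    }
    passing <- cand[ref_pass]
    if (length(passing) == 1L) {
      status <- "assigned"; ref <- passing
      bins[[ref]][[length(bins[[ref]]) + 1L]] <- read
    } else if (length(passing) >= 2L) {
      status <- "ambiguous"
      ref <- NA_character_
    } else {
      status <- if (any(best_ctx >= params$context_threshold))
        "below_fine" else "below_context"
      ref <- NA_character_
    }
    top <- if (!is.na(ref)) ref else cand[which.max(best_ctx)]
    rows[[ri]] <- data.frame(
      read_id = read$id, assigned_ref = ref,
      context = round(unname(best_ctx[top]), 2),
      fine = round(unname(best_fine[top]), 2),
      orientation = unname(best_ori[top]), status = status,
      stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, rows)
  list(bins = bins, assignments = assignments)
}

#' Write a bin assignment table as TSV
#'
#' @param assignments the `assignments` data frame from [bin_reads()] or
#'   [assign_clonal_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignments_tsv <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
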