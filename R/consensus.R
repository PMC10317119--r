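# Reference-guided consensus. Reads are seeded to a diagonal by shared
# k-mers, banded-semiglobal aligned, piled up per reference column and called
# by per-column plurality vote. Uncovered positions are never filled from the
# reference: consensus ends are trimmed to the covered interval and
# low-depth interior columns are called N.

default_band <- function(read_len) as.integer(100 + 0.05 * read_len)

# cluster seed diagonals; returns data.frame(center, size) sorted by size
cluster_diagonals <- function(d, gap = 50L, L = NULL) {
  if (!length(d)) return(data.frame(center = integer(0), size = integer(0)))
  if (!is.null(L)) d <- d %% L
  d <- sort(d)
  grp <- cumsum(c(1L, as.integer(diff(d) > gap)))
  cl <- data.frame(center = as.integer(tapply(d, grp, stats::median)),
                   size = as.integer(tapply(d, grp, length)))
  if (!is.null(L) && nrow(cl) > 1L) {
    # collapse clusters that wrap the modulus boundary
    first <- cl[1, ]; last <- cl[nrow(cl), ]
    if (L - last$center + first$center <= gap) {
      cl$center[1] <- last$center
      cl$size[1] <- first$size + last$size
      cl <- cl[-nrow(cl), , drop = FALSE]
    }
  }
  cl[order(-cl$size), , drop = FALSE]
}

# align one read against one reference (both orientations, seeded + banded).
# Returns NULL when no seed cluster is found, when the seed locus is not
# unique enough, or when the band admits no path; the reason is in attr.
map_read_to_ref <- function(read, ref, scan_codes, scheme, band = NULL,
                            k = 13L, require_unique_seed = FALSE) {
  L <- nchar(ref$sequence)
  scan_seq <- if (ref$circular) paste0(ref$sequence, ref$sequence) else ref$sequence
  rlen <- nchar(read$sequence)
  if (is.null(band)) band <- default_band(rlen)
  modL <- if (ref$circular) L else NULL

  cand <- list()
  for (ori in c("forward", "reverse")) {
    seq <- if (ori == "forward") read$sequence else revcomp(read$sequence)
    codes <- kmer_codes_cpp(seq, k)
    hits <- which(codes %in% scan_codes)
    if (!length(hits)) next
    tpos <- match(codes[hits], scan_codes)
    cl <- cluster_diagonals(tpos - hits, gap = max(50L, band %/% 2L), L = modL)
    if (nrow(cl))
      cand[[ori]] <- list(seq = seq, clusters = cl)
  }
  if (!length(cand)) return(structure(list(), failed = "no_seed"))

  sizes <- vapply(cand, function(x) x$clusters$size[1], 0L)
  oris <- names(cand)[order(-sizes)]
  # evaluate the dominant orientation; also the other if it seeds comparably
  if (length(oris) == 2L && sizes[oris[2]] < 0.25 * sizes[oris[1]])
    oris <- oris[1]

  best <- NULL
  for (ori in oris) {
    cl <- cand[[ori]]$clusters
    if (require_unique_seed && nrow(cl) > 1L && cl$size[2] >= 0.5 * cl$size[1])
      return(structure(list(), failed = "ambiguous_seed"))
    aln <- semiglobal_align(cand[[ori]]$seq, scan_seq, scheme,
                            band = band, diag = cl$center[1])
    if (is.null(aln) && as.double(rlen) * nchar(scan_seq) <= 8e6)
      aln <- semiglobal_align(cand[[ori]]$seq, scan_seq, scheme)
    if (!is.null(aln) && (is.null(best) || aln$score > best$aln$score))
      best <- list(aln = aln, ori = ori, seq = cand[[ori]]$seq)
  }
  if (is.null(best)) return(structure(list(), failed = "band_failure"))

  aln <- best$aln
  t0 <- aln$target_interval[1]; t1 <- aln$target_interval[2]
  if (ref$circular && t0 >= L) { t0 <- t0 - L; t1 <- t1 - L }
  qual <- read$qualities
  if (!is.null(qual) && best$ori == "reverse") qual <- rev(qual)
  list(read_id = read$id, ref_id = ref$id, orientation = best$ori,
       seq = best$seq, qual = qual,
       clip_left = aln$query_interval[1],
       clip_right = rlen - aln$query_interval[2],
       target_start = t0, target_end = t1,
       ops = aln$ops, score = aln$score, identity_pct = aln$identity_pct,
       ref_len = L)
}

#' Map reads to a reference for consensus building
#'
#' Seeds each read by shared k-mers to a diagonal, aligns banded-semiglobal
#' in the better-seeded orientation(s), and keeps the alignment iff its
#' identity is at least `min_identity` percent and the best seed locus is
#' unambiguous. Circular references are handled on their doubled sequence;
#' reads spanning the origin get a single alignment with wrapped coordinates.
#'
#' @param reads list of read [seq_record()]s.
#' @param ref the reference [seq_record()] (linear, or circular - doubled
#'   internally).
#' @param scheme [scoring_scheme()]; the needle-style default keeps long
#'   indels as single gap runs, which downstream insertion calling relies
#'   on (a heavy gap-extend penalty would shred them into fragments).
#' @param min_identity identity filter in percent (default 70); stands in for
#'   a mapping-quality filter.
#' @param k seed k-mer length.
#' @param band band half-width; `NULL` for `100 + 0.05 * read length`.
#' @return `list(alignments = <kept alignment records>, dropped = <data frame
#'   read_id, reason>)`.
#' @export
map_reads <- function(reads, ref, scheme = report_scheme(),
                      min_identity = 70, k = 13L, band = NULL) {
  scan_seq <- if (ref$circular) paste0(ref$sequence, ref$sequence) else ref$sequence
  scan_codes <- kmer_codes_cpp(scan_seq, k)
  kept <- list(); dropped <- list()
  for (read in reads) {
    m <- map_read_to_ref(read, ref, scan_codes, scheme, band = band, k = k,
                         require_unique_seed = TRUE)
    why <- attr(m, "failed")
    if (!is.null(why)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        read_id = read$id, reason = why, stringsAsFactors = FALSE)
    } else if (m$identity_pct < min_identity) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        read_id = read$id, reason = "low_identity", stringsAsFactors = FALSE)
    } else {
      kept[[length(kept) + 1L]] <- m
    }
  }
  list(alignments = kept,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(read_id = character(0), reason = character(0)))
}

#' Build a per-column pileup from read alignments
#'
#' Match/mismatch operations increment base counts at their reference
#' column, deletions increment the deletion row, and insertions are recorded
#' as observations at the junction (reference position) where they occur.
#' Coordinates wrap modulo the reference length for circular references.
#'
#' @param alignments kept alignments from [map_reads()], all against `ref`.
#' @param ref the reference [seq_record()].
#' @return A `pileup` object: `counts` (5 x L matrix, rows A/C/G/T/-),
#'   `insertions` (list: junction -> character vector of inserted sequences),
#'   `junction_span` (reads spanning each junction), `ref_id`, `ref_base`.
#' @export
build_pileup <- function(alignments, ref) {
  L <- nchar(ref$sequence)
  sym_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 6L, `-` = 5L) # N discarded
  col_acc <- list(); sym_acc <- list()
  ins <- new.env(parent = emptyenv())
  span_diff <- numeric(L + 1L)

  for (a in alignments) {
    runs <- a$ops
    if (!nrow(runs)) next
    qlen_runs <- ifelse(runs$op %in% c("M", "X", "I"), runs$len, 0L)
    tlen_runs <- ifelse(runs$op %in% c("M", "X", "D"), runs$len, 0L)
    q_off <- cumsum(qlen_runs) - qlen_runs # query offset before each run
    t_off <- cumsum(tlen_runs) - tlen_runs
    chars <- strsplit(substr(a$seq, a$clip_left + 1L,
                             a$clip_left + sum(qlen_runs)), "")[[1]]
    cols <- integer(0); syms <- integer(0)
    ievt <- list() # per-read insertion events: junction, query span
    for (r in seq_len(nrow(runs))) {
      op <- runs$op[r]; len <- runs$len[r]
      tcols <- (a$target_start + t_off[r] + seq_len(len) - 1L) %% L
      if (op %in% c("M", "X")) {
        cols <- c(cols, tcols)
        syms <- c(syms, sym_idx[chars[q_off[r] + seq_len(len)]])
      } else if (op == "D") {
        cols <- c(cols, tcols)
        syms <- c(syms, rep(5L, len))
      } else {
        ievt[[length(ievt) + 1L]] <-
          c(j = a$target_start + t_off[r], q0 = q_off[r], q1 = q_off[r] + len)
      }
    }
    # a long insertion can be split by the aligner around a short chance
    # match-island; re-join insertion events whose junctions are close, as
    # the contiguous read substring from the first to the last
    if (length(ievt)) {
      ievt <- do.call(rbind, ievt)
      # re-join split fragments of one long insertion (both runs substantial,
      # close junctions) or immediate traceback jitter; never absorb
      # isolated single-base error insertions into a distant event
      n_ev <- nrow(ievt)
      lens <- ievt[, "q1"] - ievt[, "q0"]
      joined <- logical(n_ev)
      if (n_ev > 1L) {
        gaps <- diff(ievt[, "j"])
        joined[-1L] <- gaps <= 2L |
          (gaps <= 25L & lens[-n_ev] >= 3L & lens[-1L] >= 3L)
      }
      grp <- cumsum(!joined)
      for (g in unique(grp)) {
        rows_g <- which(grp == g)
        j <- ievt[rows_g[1], "j"] %% L
        # extend by a little read context on both sides: the aligner can
        # absorb an insertion edge base into a junction match, so the bare
        # inserted strings are biased; the caller re-anchors the extended
        # segment against the local reference window
        q0 <- max(0L, ievt[rows_g[1], "q0"] - 12L)
        q1 <- min(length(chars), ievt[rows_g[length(rows_g)], "q1"] + 12L)
        key <- as.character(j)
        seq_ins <- paste(chars[(q0 + 1L):q1], collapse = "")
        ins[[key]] <- c(if (!is.null(ins[[key]])) ins[[key]], seq_ins)
      }
    }
    keep <- syms <= 5L # drop N read bases
    col_acc[[length(col_acc) + 1L]] <- cols[keep]
    sym_acc[[length(sym_acc) + 1L]] <- syms[keep]
    # junctions strictly inside the aligned target interval are spanned
    c0 <- a$target_start; c1 <- a$target_end
    if (c1 - c0 >= 2L) {
      if (c1 <= L) { # spanned junctions c0+1 .. c1-1 (index j+1)
        span_diff[c0 + 2L] <- span_diff[c0 + 2L] + 1
        span_diff[c1 + 1L] <- span_diff[c1 + 1L] - 1
      } else { # wrapped: junctions c0+1 .. L-1 and 0 .. c1-L-1
        span_diff[c0 + 2L] <- span_diff[c0 + 2L] + 1
        span_diff[1L] <- span_diff[1L] + 1
        span_diff[c1 - L + 1L] <- span_diff[c1 - L + 1L] - 1
      }
    }
  }
  counts <- matrix(0L, nrow = 5L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  if (length(col_acc)) {
    cols <- unlist(col_acc, use.names = FALSE)
    syms <- unlist(sym_acc, use.names = FALSE)
    tab <- tabulate(cols * 5L + syms, nbins = 5L * L)
    counts[] <- tab
  }
  junction_span <- cumsum(span_diff)[seq_len(L)] # span at junction j = before col j
  ins_list <- as.list(ins)
  structure(list(ref_id = ref$id, counts = counts, insertions = ins_list,
                 junction_span = junction_span,
                 ref_base = strsplit(ref$sequence, "")[[1]],
                 alignments = alignments),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cov <- colSums(x$counts)
  cat(sprintf("pileup on %s: %d columns, mean depth %.1f, %d insertion junction(s)\n",
              x$ref_id, ncol(x$counts), mean(cov), length(x$insertions)))
  invisible(x)
}

# query substring of one alignment covering target columns [c0, c1), or
# NULL when the alignment does not span that window
query_span_at <- function(a, c0, c1) {
  if (a$target_start > c0 || a$target_end < c1) return(NULL)
  runs <- a$ops
  qoff <- cumsum(ifelse(runs$op %in% c("M", "X", "I"), runs$len, 0L))
  toff <- cumsum(ifelse(runs$op %in% c("M", "X", "D"), runs$len, 0L))
  tpos_start <- a$target_start + c(0L, utils::head(toff, -1))
  tpos_end <- a$target_start + toff
  q_at <- function(tc) {
    r <- which(tpos_end >= tc & runs$op %in% c("M", "X", "D"))[1]
    if (is.na(r)) return(NA_integer_)
    qbefore <- if (r > 1L) qoff[r - 1L] else 0L
    if (runs$op[r] == "D") qbefore
    else qbefore + (tc - tpos_start[r])
  }
  q0 <- q_at(c0); q1 <- q_at(c1)
  if (is.na(q0) || is.na(q1) || q1 <= q0) return(NULL)
  substr(a$seq, a$clip_left + q0 + 1L, a$clip_left + q1)
}

# consensus of a set of similar short sequences (the inserted sequences
# observed at one junction): draft = most frequent modal-length sequence,
# then per-column plurality votes of all members globally aligned to the
# draft - including majority insertions relative to it - iterated to a
# fixed point. A plain plurality of the raw strings cannot work here: at
# 10% read error the probability that any single read carries a 100-bp
# insertion verbatim is negligible.
consensus_of_sequences <- function(seqs, scheme = report_scheme(),
                                   max_rounds = 6L) {
  if (length(seqs) == 1L) return(seqs[[1]])
  lens <- nchar(seqs)
  # short stragglers (isolated error insertions, split fragments) only blur
  # the vote; drop them when enough full-length observations remain
  keep <- lens >= 0.35 * max(lens)
  if (sum(keep) >= 3L) { seqs <- seqs[keep]; lens <- lens[keep] }
  # draft: most common sequence among those closest to the median length -
  # the median is stable where the modal length is not
  d <- abs(lens - stats::median(lens))
  pool <- sort(seqs[d == min(d)])
  draft <- names(sort(table(pool), decreasing = TRUE))[1]
  if (length(seqs) < 3L || nchar(draft) == 1L) return(draft)
  for (round in seq_len(max_rounds)) {
    polished <- polish_against_draft(seqs, draft, scheme)
    if (identical(polished, draft) || !nzchar(polished)) break
    draft <- polished
  }
  draft
}

polish_against_draft <- function(seqs, draft, scheme) {
  Ld <- nchar(draft)
  counts <- matrix(0L, nrow = 5L, ncol = Ld,
                   dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  ins_at <- vector("list", Ld + 1L) # junction j = before draft column j+1
  for (s in seqs) {
    aln <- global_align(s, draft, scheme)
    sv <- strsplit(s, "")[[1]]
    qp <- 0L; tp <- 0L
    for (r in seq_len(nrow(aln$ops))) {
      op <- aln$ops$op[r]; len <- aln$ops$len[r]
      if (op %in% c("M", "X")) {
        b <- sv[qp + seq_len(len)]
        cols <- tp + seq_len(len)
        ok <- b %in% rownames(counts)
        if (any(ok)) counts[cbind(match(b[ok], rownames(counts)), cols[ok])] <-
            counts[cbind(match(b[ok], rownames(counts)), cols[ok])] + 1L
        qp <- qp + len; tp <- tp + len
      } else if (op == "I") {
        j <- tp + 1L
        ins_at[[j]] <- c(ins_at[[j]], paste(sv[qp + seq_len(len)], collapse = ""))
        qp <- qp + len
      } else {
        counts[cbind(5L, tp + seq_len(len))] <-
          counts[cbind(5L, tp + seq_len(len))] + 1L
        tp <- tp + len
      }
    }
  }
  dv <- strsplit(draft, "")[[1]]
  drow <- match(dv, rownames(counts))
  drow[is.na(drow)] <- 0L
  score <- counts + 0.4 * (row(counts) == drow[col(counts)]) -
    1e-6 * row(counts)
  win <- rownames(counts)[max.col(t(score), ties.method = "first")]
  chars <- ifelse(win == "-", "", win)
  n <- length(seqs)
  # insertion placement jitters by a column (e.g. at homopolymer edges), so
  # pool votes over adjacent junctions and call each neighbourhood once
  counts_j <- vapply(ins_at, length, 0L)
  used <- logical(Ld + 1L)
  for (j in order(-counts_j)) {
    if (counts_j[j] == 0L) break
    lo <- max(1L, j - 1L); hi <- min(Ld + 1L, j + 1L)
    if (any(used[lo:hi])) next
    obs <- unlist(ins_at[lo:hi], use.names = FALSE)
    if (length(obs) > n / 2) {
      used[lo:hi] <- TRUE
      add <- names(sort(table(obs), decreasing = TRUE))[1]
      if (j == 1L) chars[1] <- paste0(add, chars[1])
      else chars[j - 1L] <- paste0(chars[j - 1L], add)
    }
  }
  paste(chars, collapse = "")
}

#' Call a consensus sequence from a pileup
#'
#' Per column, the plurality symbol among A/C/G/T/deletion is emitted
#' (deletion emits nothing); ties resolve toward the reference base, then
#' lexicographically. Junctions where more than `ins_frac` of spanning reads
#' carry an insertion (observations pooled within +/-2 columns, since
#' traceback placement jitters by a few bases) emit a consensus of the
#' inserted sequences. Columns with coverage below `min_depth` inside the
#' covered interval are called N; zero-coverage runs at the extremities are
#' trimmed - never filled from the reference.
#'
#' @param pileup a [build_pileup()] result.
#' @param min_depth minimum coverage for a base call (default 5).
#' @param ins_frac fraction of spanning reads that must carry an insertion
#'   for it to be called (default 0.5).
#' @return A `consensus_result`: `sequence`, `called_interval` (0-based
#'   half-open on the reference), `low_depth_positions` (0-based columns
#'   called N), `mean_depth`.
#' @export
call_consensus <- function(pileup, min_depth = 5L, ins_frac = 0.5) {
  counts <- pileup$counts
  L <- ncol(counts)
  cov <- colSums(counts)
  nz <- which(cov > 0L)
  if (!length(nz))
    return(structure(list(sequence = "", called_interval = c(0L, 0L),
                          low_depth_positions = integer(0), mean_depth = 0),
                     class = "consensus_result"))
  from <- min(nz); to <- max(nz) # 1-based column range
  idx <- from:to
  ref_row <- match(pileup$ref_base, rownames(counts))
  ref_row[is.na(ref_row)] <- 0L
  score <- counts + 0.4 * (row(counts) == ref_row[col(counts)]) -
    1e-6 * row(counts)
  win <- rownames(counts)[max.col(t(score[, idx, drop = FALSE]),
                                  ties.method = "first")]
  low <- cov[idx] < min_depth
  chars <- ifelse(low, "N", ifelse(win == "-", "", win))

  # insertion calls, pooled over +/-2 junction jitter
  ins_j <- as.integer(names(pileup$insertions))
  ins_calls <- list()
  if (length(ins_j)) {
    ins_n <- vapply(pileup$insertions, length, 0L)
    for (jc in ins_j[order(-ins_n[as.character(ins_j)])]) {
      wnd <- ins_j[abs(ins_j - jc) <= 5L]
      # one call per neighbourhood: observations of one long insertion can
      # scatter over a stretch comparable to the insertion's own length
      if (any(vapply(ins_calls, function(x)
        abs(x$j - jc) <= max(15L, nchar(x$seq)), TRUE))) next
      n_obs <- sum(ins_n[as.character(wnd)])
      span <- pileup$junction_span[jc + 1L]
      if (jc <= from - 1L || jc >= to) next # outside called interval
      if (span >= 1L && n_obs > ins_frac * span) {
        # local reassembly: consensus of every spanning read's segment over
        # the junction window, re-anchored against the reference window.
        # This is independent of how individual read alignments fragmented
        # the inserted sequence.
        w0 <- jc - 25L; w1 <- jc + 25L
        frames <- if (w0 < 0L) c(L) else if (w1 > L) c(0L, L) else c(0L)
        segs <- list()
        for (a in pileup$alignments) {
          for (off in frames) {
            s <- query_span_at(a, w0 + off, w1 + off)
            if (!is.null(s)) { segs[[length(segs) + 1L]] <- s; break }
          }
        }
        if (length(segs) < 3L) next
        seg_cons <- consensus_of_sequences(unlist(segs))
        wcols <- (w0:(w1 - 1L)) %% L
        window <- paste(pileup$ref_base[wcols + 1L], collapse = "")
        # global, so the insertion cannot be clipped away at window edges;
        # stiff gap opening keeps the foreign block one run instead of
        # letting chance matches inside it split the gap
        anch <- global_align(seg_cons, window, scoring_scheme(5, -4, -40, -0.5))
        if (!is.null(anch) && any(anch$ops$op == "I")) {
          runs <- anch$ops
          big <- which(runs$op == "I")
          big <- big[which.max(runs$len[big])]
          qoff <- cumsum(ifelse(runs$op %in% c("M", "X", "I"), runs$len, 0L))
          toff <- cumsum(ifelse(runs$op %in% c("M", "X", "D"), runs$len, 0L))
          q0r <- qoff[big] - runs$len[big]
          jstar <- (w0 + (if (big > 1L) toff[big - 1L] else 0L)) %% L
          ins_seq <- substr(seg_cons, q0r + 1L, q0r + runs$len[big])
          ins_calls[[length(ins_calls) + 1L]] <-
            list(j = as.integer(jstar), seq = ins_seq)
        }
      }
    }
  }
  if (length(ins_calls)) {
    for (ic in ins_calls) {
      pos <- ic$j - from + 1L # insert before column ic$j -> after chars[pos]
      if (pos >= 1L && pos <= length(chars) && nzchar(ic$seq))
        chars[pos] <- paste0(chars[pos], ic$seq)
    }
  }
  structure(list(
    sequence = paste(chars, collapse = ""),
    called_interval = c(from - 1L, to),
    low_depth_positions = idx[low] - 1L,
    mean_depth = mean(cov)
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus: %d bp called over [%d,%d), mean depth %.1f, %d low-depth column(s)\n",
              nchar(x$sequence), x$called_interval[1], x$called_interval[2],
              x$mean_depth, length(x$low_depth_positions)))
  invisible(x)
}
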