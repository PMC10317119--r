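# Unique-region scanning: the indexing step of two-stage binning. A unique
# region (marker) is a subsequence that occurs - in either orientation - in
# exactly one reference of the pool, so that a read containing it can be
# attributed without a barcode.
#
# Strategy: for every start position, find the shortest window absent from
# all other references (checked on a geometric length grid, exact at grid
# points), keep positions that are locally minimal from the right, merge
# overlapping windows, cap the merged region length and the number of regions
# per reference. Circular references are scanned across the origin on their
# doubled sequence; coordinates are reported mod length.

unique_region <- function(ref_id, start, end, marker, context, context_left) {
  structure(list(ref_id = ref_id, start = start, end = end, marker = marker,
                 context = context, context_left = context_left),
            class = "unique_region")
}

#' @export
print.unique_region <- function(x, ...) {
  cat(sprintf("unique_region %s:[%d,%d) %d bp marker, %d bp context\n",
              x$ref_id, x$start, x$end, nchar(x$marker), nchar(x$context)))
  invisible(x)
}

#' Find reference subsequences unique to one plasmid
#'
#' Scans a pool of plasmid references for maximal-ish marker intervals whose
#' sequence is absent (forward and reverse-complement) from every other
#' reference. Repeats within the owning reference do not disqualify a marker:
#' uniqueness is across references, which is what read attribution needs.
#'
#' @param refs named list of at least two reference [seq_record()]s.
#' @param min_len minimum marker length (default 4, i.e. markers longer than
#'   3 bp).
#' @param max_marker_len merged regions are truncated to this length; a
#'   truncated region always still contains a complete unique substring.
#' @param max_regions per-reference cap on the number of regions reported
#'   (longest first), keeping downstream binning cost bounded.
#' @param flank context flank width in bases (default 20).
#' @return A named list (one element per reference) of lists of
#'   `unique_region` objects, each with fields `ref_id`, `start`, `end`
#'   (0-based half-open; `end` may exceed the reference length when the
#'   region wraps a circular origin), `marker`, `context` and `context_left`
#'   (left-flank bases included in the context). References with no unique
#'   region get an empty list and a warning naming them.
#' @export
find_unique_regions <- function(refs, min_len = 4L, max_marker_len = 64L,
                                max_regions = 8L, flank = 20L) {
  if (length(refs) < 2L) stop("need at least 2 references")
  ids <- unname(vapply(refs, `[[`, "", "id"))
  if (anyDuplicated(ids)) stop("reference ids must be unique")
  nrefs <- length(refs)
  lens <- vapply(refs, function(r) nchar(r$sequence), 0L)
  scan_seq <- unname(vapply(refs, function(r)
    if (r$circular) paste0(r$sequence, r$sequence) else r$sequence, ""))
  rc_scan <- revcomp(scan_seq)
  scan_len <- nchar(scan_seq)

  ks <- unique(pmin(as.integer(max_marker_len),
                    as.integer(ceiling(min_len * 1.5^(0:15)))))
  ks <- ks[ks <= max(scan_len)]

  # minimal absent window length per start position (NA = none found <= cap)
  minL <- lapply(scan_len - min_len + 1L, function(n) rep(NA_integer_, max(n, 0L)))

  for (k in ks) {
    unresolved <- vapply(seq_len(nrefs), function(i) {
      n <- scan_len[i] - k + 1L
      n > 0L && anyNA(minL[[i]][seq_len(min(n, length(minL[[i]])))])
    }, TRUE)
    if (!any(unresolved)) break
    win <- lapply(seq_len(nrefs), function(i) {
      n <- scan_len[i] - k + 1L
      if (n < 1L) character(0) else substring(scan_seq[i], 1:n, k:(k + n - 1L))
    })
    rcw <- lapply(seq_len(nrefs), function(i) {
      n <- scan_len[i] - k + 1L
      if (n < 1L) character(0) else substring(rc_scan[i], 1:n, k:(k + n - 1L))
    })
    for (i in which(unresolved)) {
      pool <- c(unlist(win[-i], use.names = FALSE),
                unlist(rcw[-i], use.names = FALSE))
      absent <- !(win[[i]] %in% pool)
      idx <- which(absent & is.na(minL[[i]][seq_along(absent)]))
      if (length(idx)) minL[[i]][idx] <- k
    }
  }

  out <- stats::setNames(vector("list", nrefs), ids)
  for (i in seq_len(nrefs)) {
    L <- lens[i]
    Lp <- minL[[i]]
    nstart <- min(L, length(Lp))
    keep <- integer(0)
    for (p in seq_len(nstart)) {
      if (is.na(Lp[p])) next
      nxt <- if (p + 1L <= length(Lp)) Lp[p + 1L] else NA_integer_
      if (is.na(nxt) || nxt >= Lp[p]) keep <- c(keep, p)
    }
    if (!length(keep)) {
      warning(sprintf("reference '%s' has no unique region >= %d bp",
                      ids[i], min_len))
      out[[i]] <- list()
      next
    }
    iv <- data.frame(start = keep - 1L, end = keep - 1L + Lp[keep],
                     L = Lp[keep])
    iv <- iv[order(iv$start), , drop = FALSE]
    # cluster overlapping windows, then keep each cluster's minimal-length
    # plateau: windows within one grid step of the cluster minimum. This pins
    # the region to the actual difference zone instead of letting long
    # just-unique windows drag it into sequence shared with other references.
    cl <- cumsum(c(1L, as.integer(iv$start[-1] >= cummax(iv$end)[-nrow(iv)])))
    merged <- lapply(split(iv, cl), function(d) {
      sel <- d$L <= 1.5 * min(d$L) + 1e-9
      c(min(d$start[sel]), max(d$end[sel]))
    })
    # circular: a region wrapping the origin may physically overlap regions
    # at the start of the sequence
    if (refs[[i]]$circular && length(merged) > 1L) {
      last <- merged[[length(merged)]]
      if (last[2] > L) {
        over <- vapply(merged, function(x) x[1] < last[2] - L, TRUE)
        over[length(merged)] <- FALSE
        if (any(over)) {
          last[2] <- max(last[2], L + max(vapply(merged[over], `[`, 0, 2)))
          merged <- c(merged[!over & seq_along(merged) != length(merged)], list(last))
        }
      }
    }
    merged <- lapply(merged, function(x) {
      if (x[2] - x[1] > max_marker_len) x[2] <- x[1] + max_marker_len
      x
    })
    rl <- vapply(merged, function(x) x[2] - x[1], 0)
    ord <- order(-rl, vapply(merged, `[`, 0, 1))
    merged <- merged[ord[seq_len(min(max_regions, length(merged)))]]
    merged <- merged[order(vapply(merged, `[`, 0, 1))]
    regs <- lapply(merged, function(x) {
      marker <- substr(scan_seq[i], x[1] + 1L, x[2])
      region_with_context(ids[i], x[1], x[2], marker, refs[[i]], flank)
    })
    out[[i]] <- regs
  }
  out
}

# build a unique_region with its flanked context
region_with_context <- function(ref_id, start, end, marker, ref, flank) {
  ctx <- extract_context_seq(ref, start, end, flank)
  unique_region(ref_id, start, end, marker, ctx$context, ctx$left)
}

extract_context_seq <- function(ref, start, end, flank) {
  L <- nchar(ref$sequence)
  if (ref$circular) {
    mlen <- end - start
    avail <- max(0L, L - mlen) # flanks may not wrap onto the marker itself
    left <- min(flank, avail)
    right <- min(flank, avail - left)
    big <- paste0(ref$sequence, ref$sequence, ref$sequence)
    s0 <- start - left + L
    list(context = substr(big, s0 + 1L, start + L + mlen + right), left = left)
  } else {
    s0 <- max(0L, start - flank)
    e0 <- min(L, end + flank)
    list(context = substr(ref$sequence, s0 + 1L, e0), left = start - s0)
  }
}

#' Extract the flanked context of a unique region
#'
#' The marker extended by up to `flank` bases of reference sequence on each
#' side - truncated at the ends of a linear reference, wrapped across the
#' origin of a circular one.
#'
#' @param region a `unique_region` from [find_unique_regions()].
#' @param ref the owning reference [seq_record()].
#' @param flank flank width in bases.
#' @return The context sequence (character scalar).
#' @export
extract_context <- function(region, ref, flank = 20L) {
  if (!identical(region$ref_id, ref$id)) stop("region does not belong to ref")
  extract_context_seq(ref, region$start, region$end, flank)$context
}

#' Write unique regions as TSV
#'
#' @param regions result of [find_unique_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  rows <- do.call(rbind, lapply(unlist(regions, recursive = FALSE), function(r)
    data.frame(ref_id = r$ref_id, start = r$start, end = r$end,
               marker = r$marker, context = r$context,
               stringsAsFactors = FALSE)))
  if (is.null(rows))
    rows <- data.frame(ref_id = character(0), start = integer(0),
                       end = integer(0), marker = character(0),
                       context = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
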