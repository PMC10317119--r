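# Rotated-reference demultiplexing for clonal pools. Each clone of a plasmid
# is linearized at a different restriction site before pooling; providing one
# copy of the reference per clone with its linear origin set at that clone's
# cut site ("rotated" reference) makes full-length reads map well only to
# their matched rotation - a mismatched rotation forces the origin-offset
# stretch of the read into gaps or clipping.

#' Cut-site specification
#'
#' @param ref_id id of the circular reference the cut applies to.
#' @param cut_position 0-based position on the circular sequence where the
#'   linear origin is set.
#' @param enzyme_label free-text label for reports (e.g. the enzyme name).
#' @return A `cut_spec` object.
#' @export
cut_spec <- function(ref_id, cut_position, enzyme_label = "") {
  stopifnot(cut_position >= 0)
  structure(list(ref_id = ref_id, cut_position = as.integer(cut_position),
                 enzyme_label = enzyme_label), class = "cut_spec")
}

#' Rotate a circular reference to a cut site
#'
#' Returns the same sequence written linearly starting at the cut position;
#' the id is suffixed with the cut label (or position) so each clone's
#' rotation is distinguishable.
#'
#' @param ref a circular reference [seq_record()].
#' @param cut a [cut_spec()].
#' @return A linear [seq_record()] of the same length.
#' @export
rotate_reference <- function(ref, cut) {
  if (!ref$circular) stop("rotate_reference needs a circular reference")
  L <- nchar(ref$sequence)
  if (cut$cut_position < 0 || cut$cut_position >= L)
    stop("cut_position out of range")
  p <- cut$cut_position
  seq <- if (p == 0L) ref$sequence else
    paste0(substr(ref$sequence, p + 1L, L), substr(ref$sequence, 1L, p))
  label <- if (nzchar(cut$enzyme_label)) cut$enzyme_label else paste0("cut", p)
  seq_record(paste0(ref$id, "_", label), seq, circular = FALSE)
}

#' Assign clonal-pool reads to rotated references
#'
#' Every read is aligned (seeded, banded, both orientations) to every rotated
#' reference; it is assigned to the top-scoring rotation iff the margin
#' between the top and second scores is at least `margin_pct` percent of the
#' read's maximum possible score (`match * read length`). Ties - in
#' particular the all-tie outcome against non-rotated duplicate references -
#' leave reads unassigned.
#'
#' @param reads list of read [seq_record()]s.
#' @param rotated_refs named list of linear rotated references (comparable
#'   lengths).
#' @param scheme [scoring_scheme()].
#' @param margin_pct assignment margin, percent of the read's maximum score.
#' @param band alignment band half-width; `NULL` for the default
#'   `100 + 0.05 * read length`.
#' @return `list(assignments = <data frame read_id, assigned_ref, score,
#'   second_score, margin, orientation, status>, counts = <per-reference
#'   unique-read counts>)`.
#' @export
assign_clonal_reads <- function(reads, rotated_refs, scheme = binning_scheme(),
                                margin_pct = 5, band = NULL) {
  if (length(rotated_refs) < 2L)
    warning("single rotated reference: demultiplexing is vacuous")
  ids <- vapply(rotated_refs, `[[`, "", "id")
  names(rotated_refs) <- ids
  ref_codes <- lapply(rotated_refs, function(r) kmer_codes_cpp(r$sequence, 13L))
  rows <- vector("list", length(reads))
  for (ri in seq_along(reads)) {
    read <- reads[[ri]]
    scores <- stats::setNames(rep(-Inf, length(ids)), ids)
    oris <- stats::setNames(rep("forward", length(ids)), ids)
    for (id in ids) {
      m <- map_read_to_ref(read, rotated_refs[[id]], ref_codes[[id]],
                           scheme, band = band)
      if (!is.null(m)) {
        scores[id] <- m$score
        oris[id] <- m$orientation
      }
    }
    ord <- order(-scores)
    top <- scores[ord[1]]; second <- if (length(scores) > 1L) scores[ord[2]] else -Inf
    max_possible <- scheme$match * nchar(read$sequence)
    margin <- 100 * (top - second) / max_possible
    ok <- is.finite(top) && (length(scores) == 1L || margin >= margin_pct)
    rows[[ri]] <- data.frame(
      read_id = read$id,
      assigned_ref = if (ok) ids[ord[1]] else NA_character_,
      score = if (is.finite(top)) round(top, 1) else NA_real_,
      second_score = if (is.finite(second)) round(second, 1) else NA_real_,
      margin = if (is.finite(margin)) round(margin, 2) else NA_real_,
      orientation = oris[ord[1]],
      status = if (ok) "assigned" else "unassigned",
      stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, rows)
  counts <- table(factor(assignments$assigned_ref, levels = ids))
  list(assignments = assignments, counts = as.integer(counts) |>
         stats::setNames(ids))
}

#' Read a cut-site manifest
#'
#' Tab-separated columns `ref_id`, `cut_position`, `enzyme_label` (header
#' required; label optional).
#'
#' @param path TSV path.
#' @return A list of [cut_spec()]s.
#' @export
read_cut_manifest <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(c("ref_id", "cut_position") %in% names(d)))
    stop("cut manifest needs columns ref_id, cut_position")
  if (is.null(d$enzyme_label)) d$enzyme_label <- ""
  specs <- lapply(seq_len(nrow(d)), function(k)
    cut_spec(d$ref_id[k], d$cut_position[k], d$enzyme_label[k]))
  by_ref <- split(vapply(specs, `[[`, 0L, "cut_position"),
                  vapply(specs, `[[`, "", "ref_id"))
  for (r in names(by_ref))
    if (anyDuplicated(by_ref[[r]]))
      stop(sprintf("duplicate cut positions for reference '%s'", r))
  specs
}
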