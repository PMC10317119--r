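# End-to-end pipeline: filter -> assign (biobin / rotated / map-all) ->
# per-plasmid consensus -> validation report, with every output written to
# an output directory and a reproducibility manifest of all parameters.

#' Pipeline run configuration
#'
#' @param mode `"biobin"` (two-stage unique-region binning), `"rotated"`
#'   (clonal pools linearized at distinct cut sites; requires `cuts`) or
#'   `"map-all"` (each read goes to its single best reference; closest to
#'   running a consensus tool on the pooled reads directly, and not
#'   recommended for highly similar pools).
#' @param refs named list of reference [seq_record()]s.
#' @param reads list of read [seq_record()]s (with qualities).
#' @param cuts list of [cut_spec()]s, `"rotated"` mode only.
#' @param filter a [filter_params()] object.
#' @param binning a [binning_params()] object.
#' @param margin_pct assignment margin for `"rotated"` mode.
#' @param min_identity,min_depth,ins_frac consensus-stage tunables (see
#'   [map_reads()] and [call_consensus()]).
#' @param flag_quality,flag_indel report-stage flag thresholds (see
#'   [run_report()]).
#' @param out_dir output directory.
#' @return A `run_config` object.
#' @export
run_config <- function(mode = c("biobin", "rotated", "map-all"),
                       refs, reads, cuts = NULL,
                       filter = filter_params(),
                       binning = binning_params(),
                       margin_pct = 5,
                       min_identity = 70, min_depth = 5L, ins_frac = 0.5,
                       flag_quality = 99.5, flag_indel = 10L,
                       out_dir = "plasmidpool_out") {
  mode <- match.arg(mode)
  if (mode == "rotated" && is.null(cuts))
    stop("rotated mode requires a cut-site table (cuts)")
  structure(list(mode = mode, refs = refs, reads = reads, cuts = cuts,
                 filter = filter, binning = binning, margin_pct = margin_pct,
                 min_identity = min_identity, min_depth = min_depth,
                 ins_frac = ins_frac, flag_quality = flag_quality,
                 flag_indel = flag_indel, out_dir = out_dir),
            class = "run_config")
}

#' Run the validation pipeline
#'
#' Executes read filtering, read-to-plasmid assignment in the configured
#' mode, per-plasmid reference-guided consensus, and the
#' consensus-versus-reference report. Writes per-plasmid consensus FASTA,
#' SAM, needle-style alignment text, the assignment table, a summary TSV and
#' a manifest of all parameters to `out_dir`.
#'
#' @param config a [run_config()].
#' @return `list(status, summary, assignments, consensuses, reports)`,
#'   invisibly; `status` is 0 when no plasmid is flagged, 1 otherwise.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  refs <- config$refs

  flt <- filter_reads(config$reads, config$filter)
  if (length(flt$kept) == 0L) stop("no reads pass the quality filter")

  # --- assignment stage ---------------------------------------------------
  if (config$mode == "biobin") {
    regions <- find_unique_regions(refs, flank = config$binning$flank)
    write_regions_tsv(regions, file.path(config$out_dir, "unique_regions.tsv"))
    bb <- bin_reads(flt$kept, refs, regions, config$binning)
    assignments <- bb$assignments
    bins <- bb$bins
    for (id in names(bins))
      if (length(bins[[id]]))
        write_fastq(bins[[id]], file.path(config$out_dir,
                                          paste0(id, "_bin.fastq")))
    frames <- refs
  } else if (config$mode == "rotated") {
    rotated <- lapply(config$cuts, function(ct) {
      if (is.null(refs[[ct$ref_id]])) stop("cut for unknown reference ", ct$ref_id)
      rotate_reference(refs[[ct$ref_id]], ct)
    })
    names(rotated) <- vapply(rotated, `[[`, "", "id")
    rr <- assign_clonal_reads(flt$kept, rotated,
                              scheme = config$binning$scheme,
                              margin_pct = config$margin_pct)
    assignments <- rr$assignments
    bins <- stats::setNames(lapply(names(rotated), function(id) {
      flt$kept[assignments$read_id[!is.na(assignments$assigned_ref) &
                                     assignments$assigned_ref == id]]
    }), names(rotated))
    frames <- rotated # consensus in each clone's rotated coordinate frame
  } else { # map-all: best-scoring reference wins, no uniqueness guarantee
    scan_codes <- lapply(refs, function(r) {
      scan <- if (r$circular) paste0(r$sequence, r$sequence) else r$sequence
      kmer_codes_cpp(scan, 13L)
    })
    rows <- vector("list", length(flt$kept))
    bins <- stats::setNames(lapply(refs, function(r) list()), names(refs))
    for (ri in seq_along(flt$kept)) {
      read <- flt$kept[[ri]]
      best <- NULL; best_id <- NA_character_
      for (id in names(refs)) {
        m <- map_read_to_ref(read, refs[[id]], scan_codes[[id]],
                             report_scheme())
        if (is.null(attr(m, "failed")) &&
            (is.null(best) || m$score > best$score)) {
          best <- m; best_id <- id
        }
      }
      ok <- !is.null(best) && best$identity_pct >= config$min_identity
      if (ok) bins[[best_id]][[length(bins[[best_id]]) + 1L]] <- read
      rows[[ri]] <- data.frame(
        read_id = read$id,
        assigned_ref = if (ok) best_id else NA_character_,
        score = if (!is.null(best)) best$score else NA_real_,
        orientation = if (!is.null(best)) best$orientation else NA_character_,
        status = if (ok) "assigned" else "unassigned",
        stringsAsFactors = FALSE)
    }
    assignments <- do.call(rbind, rows)
    frames <- refs
  }
  write_assignments_tsv(assignments, file.path(config$out_dir, "assignments.tsv"))

  # --- consensus stage ----------------------------------------------------
  consensuses <- stats::setNames(vector("list", length(frames)), names(frames))
  reports <- stats::setNames(vector("list", length(frames)), names(frames))
  depth_rows <- list()
  for (id in names(frames)) {
    bin <- bins[[id]]
    if (length(bin) == 0L) next
    mp <- map_reads(bin, frames[[id]], min_identity = config$min_identity)
    if (length(mp$alignments) == 0L) next
    write_sam(mp$alignments, frames[id],
              file.path(config$out_dir, paste0(id, ".sam")))
    pl <- build_pileup(mp$alignments, frames[[id]])
    cons <- call_consensus(pl, min_depth = config$min_depth,
                           ins_frac = config$ins_frac)
    if (!nzchar(cons$sequence)) next
    consensuses[[id]] <- cons
    reports[[id]] <- compare_consensus(cons, frames[[id]])
    depth_rows[[id]] <- data.frame(ref_id = id,
                                   reads_mapped = length(mp$alignments),
                                   mean_depth = round(cons$mean_depth, 2),
                                   stringsAsFactors = FALSE)
    write_fasta(list(seq_record(paste0(id, "_consensus"), cons$sequence)),
                file.path(config$out_dir, paste0(id, "_consensus.fasta")))
  }
  if (length(depth_rows))
    utils::write.table(do.call(rbind, depth_rows),
                       file.path(config$out_dir, "depth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # --- report stage -------------------------------------------------------
  summary <- run_report(assignments, consensuses, reports, frames,
                        config$out_dir, flag_quality = config$flag_quality,
                        flag_indel = config$flag_indel)
  manifest <- c(
    sprintf("plasmidpool %s", as.character(utils::packageVersion("plasmidpool"))),
    sprintf("mode\t%s", config$mode),
    sprintf("n_refs\t%d", length(refs)),
    sprintf("n_reads_in\t%d", length(config$reads)),
    sprintf("n_reads_filtered_out\t%d", flt$rejected),
    sprintf("min_mean_q\t%g", config$filter$min_mean_q),
    sprintf("context_threshold\t%g", config$binning$context_threshold),
    sprintf("fine_threshold\t%g", config$binning$fine_threshold),
    sprintf("margin_pct\t%g", config$margin_pct),
    sprintf("min_identity\t%g", config$min_identity),
    sprintf("min_depth\t%d", config$min_depth),
    sprintf("ins_frac\t%g", config$ins_frac),
    sprintf("flag_quality\t%g", config$flag_quality),
    sprintf("flag_indel\t%d", config$flag_indel))
  writeLines(manifest, file.path(config$out_dir, "manifest.tsv"))

  status <- if (any(summary$status != "pass")) 1L else 0L
  invisible(list(status = status, summary = summary,
                 assignments = assignments, consensuses = consensuses,
                 reports = reports))
}
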