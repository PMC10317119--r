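# Synthetic plasmid pools and nanopore-style reads. The error model is
# parametric - independent per-base substitution/insertion/deletion draws
# with an elevated deletion rate inside homopolymer runs - with defaults
# anchored to the ~10% aggregate error of nanopore base calls and a
# lognormal read-length model targeting an N50 around 6 kb (truncated at the
# template length, so most reads span a whole plasmid). Read starts are
# uniform on the circle (transposase preparation) or fixed at a cut site
# with exponential end trims (restriction preparation).

BASES <- c("A", "C", "G", "T")

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities of substitution,
#'   single-base insertion, and deletion (defaults 0.04/0.03/0.03, about 10
#'   percent aggregate).
#' @param homopolymer_del_factor multiplier on `del_rate` inside homopolymer
#'   runs of length 4 or more (deletions in homopolymers are the dominant
#'   nanopore error mode).
#' @param start_mode `"random"` (transposase preparation: uniform starts on
#'   the circle) or `"cut_site"` (restriction preparation: reads start at the
#'   declared cut position, minus exponential end trims).
#' @param length_meanlog,length_sdlog lognormal read-length parameters
#'   (defaults target an N50 near 6 kb); lengths are truncated at the
#'   template length.
#' @param end_trim_mean mean of the exponential end trims in `cut_site` mode
#'   (bases).
#' @param seed RNG seed; a fixed seed makes output byte-identical.
#' @return A `sim_config` object.
#' @export
sim_config <- function(sub_rate = 0.04, ins_rate = 0.03, del_rate = 0.03,
                       homopolymer_del_factor = 2.0,
                       start_mode = c("random", "cut_site"),
                       length_meanlog = log(6000), length_sdlog = 0.55,
                       end_trim_mean = 20, seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  stopifnot(all(rates >= 0), all(rates < 1), sum(rates) < 1,
            homopolymer_del_factor >= 0, end_trim_mean >= 0)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate,
                 homopolymer_del_factor = homopolymer_del_factor,
                 start_mode = match.arg(start_mode),
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 end_trim_mean = end_trim_mean,
                 seed = as.integer(seed)), class = "sim_config")
}

#' Generate a synthetic plasmid pool
#'
#' Either `n_plasmids` fully random (dissimilar) circular sequences, or - with
#' `marker_len > 0` - copies of one random backbone that differ only by a
#' distinct random marker substituted at a fixed locus, the hard case for
#' barcode-free binning. GC content is 0.5 in expectation.
#'
#' @param n_plasmids number of references.
#' @param base_len approximate plasmid length (dissimilar pools get a +/-10
#'   percent length jitter; marker pools share one backbone of exactly this
#'   length).
#' @param marker_len marker length in bases; 0 for dissimilar plasmids.
#' @param seed RNG seed.
#' @return A named list of circular [seq_record()]s (`p01`, `p02`, ...).
#' @export
make_pool <- function(n_plasmids, base_len = 4500L, marker_len = 24L,
                      seed = 1L) {
  stopifnot(n_plasmids >= 1, base_len >= 100, marker_len >= 0)
  with_seed(seed, {
    ids <- sprintf("p%02d", seq_len(n_plasmids))
    if (marker_len == 0L) {
      lens <- round(base_len * stats::runif(n_plasmids, 0.9, 1.1))
      recs <- lapply(seq_len(n_plasmids), function(i)
        seq_record(ids[i],
                   paste(sample(BASES, lens[i], TRUE), collapse = ""),
                   circular = TRUE))
    } else {
      backbone <- paste(sample(BASES, base_len, TRUE), collapse = "")
      locus <- base_len %/% 2L
      markers <- character(0)
      for (tries in seq_len(100L)) {
        markers <- unique(replicate(n_plasmids,
          paste(sample(BASES, marker_len, TRUE), collapse = "")))
        if (length(markers) == n_plasmids) break
      }
      if (length(markers) < n_plasmids)
        stop("could not draw distinct markers; increase marker_len")
      recs <- lapply(seq_len(n_plasmids), function(i) {
        s <- backbone
        substr(s, locus + 1L, locus + marker_len) <- markers[i]
        seq_record(ids[i], s, circular = TRUE)
      })
    }
    stats::setNames(recs, ids)
  })
}

#' Variant specification
#'
#' @param ref_id reference the variant applies to.
#' @param kind `"insertion"`, `"deletion"` or `"substitution"`.
#' @param position 0-based position (insertions are placed before it).
#' @param length variant length in bases (ignored when `sequence` given for
#'   insertions).
#' @param sequence optional explicit inserted sequence.
#' @param subclonal_fraction fraction of that plasmid's reads drawn from the
#'   variant haplotype (default 1 = clonal).
#' @return A `variant_spec` object.
#' @export
variant_spec <- function(ref_id, kind = c("insertion", "deletion", "substitution"),
                         position, length = NULL, sequence = NULL,
                         subclonal_fraction = 1.0) {
  kind <- match.arg(kind)
  if (is.null(length)) {
    if (is.null(sequence)) stop("need length or sequence")
    length <- nchar(sequence)
  }
  stopifnot(position >= 0, length >= 1,
            subclonal_fraction > 0, subclonal_fraction <= 1)
  structure(list(ref_id = ref_id, kind = kind,
                 position = as.integer(position), length = as.integer(length),
                 sequence = sequence,
                 subclonal_fraction = subclonal_fraction),
            class = "variant_spec")
}

#' Apply a variant to a reference
#'
#' @param ref a [seq_record()].
#' @param spec a [variant_spec()].
#' @param seed RNG seed for random inserted/substituted bases.
#' @return `list(record = <variant seq_record>, truth = <list kind, position,
#'   length>)`.
#' @export
apply_variant <- function(ref, spec, seed = 1L) {
  s <- ref$sequence
  L <- nchar(s)
  p <- spec$position; len <- spec$length
  with_seed(seed, {
    if (spec$kind == "deletion") {
      if (p + len > L) stop("deletion out of bounds")
      s2 <- paste0(substr(s, 1L, p), substr(s, p + len + 1L, L))
    } else if (spec$kind == "insertion") {
      if (p > L) stop("insertion position out of bounds")
      insseq <- if (!is.null(spec$sequence)) toupper(spec$sequence) else
        paste(sample(BASES, len, TRUE), collapse = "")
      s2 <- paste0(substr(s, 1L, p), insseq, substr(s, p + 1L, L))
    } else {
      if (p + len > L) stop("substitution out of bounds")
      old <- strsplit(substr(s, p + 1L, p + len), "")[[1]]
      idx <- match(old, BASES)
      idx[is.na(idx)] <- sample(4L, sum(is.na(idx)), TRUE)
      shift <- sample(3L, len, TRUE)
      new <- BASES[((idx - 1L + shift) %% 4L) + 1L]
      s2 <- s
      substr(s2, p + 1L, p + len) <- paste(new, collapse = "")
    }
    list(record = seq_record(ref$id, s2, circular = ref$circular),
         truth = list(ref_id = ref$id, kind = spec$kind, position = p,
                      length = len))
  })
}

# apply the parametric error model to one template string
mutate_read <- function(template, cfg) {
  b <- strsplit(template, "")[[1]]
  n <- length(b)
  if (n == 0L) return("")
  r <- rle(b)
  runlen <- rep(r$lengths, r$lengths)
  delp <- ifelse(runlen >= 4L,
                 pmin(0.95, cfg$del_rate * cfg$homopolymer_del_factor),
                 cfg$del_rate)
  b <- b[stats::runif(n) >= delp]
  m <- length(b)
  if (m == 0L) return("")
  sub <- stats::runif(m) < cfg$sub_rate
  if (any(sub)) {
    idx <- match(b[sub], BASES)
    idx[is.na(idx)] <- sample(4L, sum(is.na(idx)), TRUE)
    b[sub] <- BASES[((idx - 1L + sample(3L, sum(sub), TRUE)) %% 4L) + 1L]
  }
  ins <- stats::runif(m) < cfg$ins_rate
  if (any(ins))
    b[ins] <- paste0(b[ins], sample(BASES, sum(ins), TRUE))
  paste(b, collapse = "")
}

#' Simulate a pooled nanopore read library
#'
#' Draws reads from each reference (optionally from a variant haplotype with
#' the declared subclonal fraction), with random or cut-site starts, a
#' truncated lognormal length model, the parametric error model of
#' [sim_config()], random orientation, and constant per-base qualities
#' consistent with the configured error rate. Identical inputs and seed give
#' byte-identical output.
#'
#' @param refs named list of circular reference [seq_record()]s.
#' @param reads_per_plasmid reads to draw per reference.
#' @param config a [sim_config()].
#' @param cuts list of [cut_spec()]s (required in `cut_site` mode, one per
#'   reference).
#' @param variants list of [variant_spec()]s (at most one per reference).
#' @return `list(reads = <list of seq_record with qualities>, truth = <data
#'   frame read_id, ref_id, haplotype, start, strand, length>)`.
#' @export
simulate_pool <- function(refs, reads_per_plasmid, config = sim_config(),
                          cuts = NULL, variants = NULL) {
  stopifnot(reads_per_plasmid > 0)
  if (config$start_mode == "cut_site") {
    if (is.null(cuts)) stop("cut_site mode requires a cut-site table")
    cut_by_ref <- stats::setNames(cuts, vapply(cuts, `[[`, "", "ref_id"))
    missing <- setdiff(names(refs), names(cut_by_ref))
    if (length(missing))
      stop("no cut site for reference(s): ", paste(missing, collapse = ", "))
  }
  var_by_ref <- list()
  if (!is.null(variants))
    var_by_ref <- stats::setNames(variants,
                                  vapply(variants, `[[`, "", "ref_id"))
  total_rate <- config$sub_rate + config$ins_rate + config$del_rate
  q_const <- if (total_rate <= 0) 40L else
    max(2L, as.integer(round(-10 * log10(total_rate))))

  with_seed(config$seed, {
    reads <- list(); truth <- list(); counter <- 0L
    for (id in names(refs)) {
      ref <- refs[[id]]
      vs <- var_by_ref[[id]]
      hap_rec <- NULL
      if (!is.null(vs))
        hap_rec <- apply_variant(ref, vs,
                                 seed = sample.int(.Machine$integer.max, 1L))$record
      for (i in seq_len(reads_per_plasmid)) {
        counter <- counter + 1L
        use_var <- !is.null(vs) && stats::runif(1) < vs$subclonal_fraction
        src <- if (use_var) hap_rec else ref
        L <- nchar(src$sequence)
        if (config$start_mode == "random") {
          start <- sample.int(L, 1L) - 1L
          len <- min(L, max(50L, round(stats::rlnorm(1, config$length_meanlog,
                                                     config$length_sdlog))))
          template <- substr(paste0(src$sequence, src$sequence),
                             start + 1L, start + len)
        } else {
          cut <- cut_by_ref[[id]]$cut_position
          rot <- rotate_reference(src, cut_by_ref[[id]])
          trims <- if (config$end_trim_mean > 0)
            round(stats::rexp(2, 1 / config$end_trim_mean)) else c(0, 0)
          if (sum(trims) >= L - 50) trims <- c(0, 0)
          len <- L - sum(trims)
          template <- substr(rot$sequence, trims[1] + 1L, L - trims[2])
          start <- (cut + trims[1]) %% L
        }
        seq <- mutate_read(template, config)
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        if (strand == "-") seq <- revcomp(seq)
        rid <- sprintf("read%05d_%s", counter, id)
        reads[[counter]] <- seq_record(rid, seq,
                                       qualities = rep(q_const, nchar(seq)))
        truth[[counter]] <- data.frame(
          read_id = rid, ref_id = id,
          haplotype = if (use_var) "variant" else "ref",
          start = start, strand = strand, length = nchar(template),
          stringsAsFactors = FALSE)
      }
    }
    list(reads = stats::setNames(reads, vapply(reads, `[[`, "", "id")),
         truth = do.call(rbind, truth))
  })
}

#' Write a simulation's truth table as TSV
#'
#' @param truth the `truth` data frame from [simulate_pool()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
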