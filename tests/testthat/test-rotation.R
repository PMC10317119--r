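test_that("rotate_reference is index arithmetic with an identity and inverse", {
  ref <- seq_record("pl", "ACGTAC", circular = TRUE)
  expect_equal(rotate_reference(ref, cut_spec("pl", 2))$sequence, "GTACAC")
  expect_equal(rotate_reference(ref, cut_spec("pl", 0))$sequence, "ACGTAC")
  once <- rotate_reference(ref, cut_spec("pl", 2))
  once$circular <- TRUE
  back <- rotate_reference(once, cut_spec("pl", 6 - 2))
  expect_equal(back$sequence, ref$sequence)

  set.seed(71)
  big <- seq_record("b", random_dna(500), circular = TRUE)
  rot <- rotate_reference(big, cut_spec("b", 123, "EcoRI"))
  expect_equal(nchar(rot$sequence), 500)
  expect_equal(sort(strsplit(rot$sequence, "")[[1]]),
               sort(strsplit(big$sequence, "")[[1]]))
  expect_false(rot$circular)
  expect_match(rot$id, "EcoRI")
  expect_error(rotate_reference(big, cut_spec("b", 500)), "out of range")
  expect_error(rotate_reference(rot, cut_spec("b", 1)), "circular")
})

clonal_fixture <- function(L, cut_positions, reads_per_clone, cfg_seed,
                           err = FALSE, pool_seed = 72) {
  plasmid <- make_pool(1, base_len = L, marker_len = 0, seed = pool_seed)[[1]]
  cuts <- lapply(seq_along(cut_positions), function(i)
    cut_spec("p01", cut_positions[i], sprintf("enz%d", i)))
  rotated <- lapply(cuts, function(ct) rotate_reference(plasmid, ct))
  names(rotated) <- vapply(rotated, `[[`, "", "id")
  cfg <- if (err) sim_config(start_mode = "cut_site", seed = cfg_seed)
  else sim_config(sub_rate = 0, ins_rate = 0, del_rate = 0,
                  start_mode = "cut_site", end_trim_mean = 0, seed = cfg_seed)
  # simulate each clone as its own pool so each uses its own cut site
  reads <- list(); truth_ref <- character(0)
  for (i in seq_along(cuts)) {
    sim <- simulate_pool(stats::setNames(list(plasmid), "p01"),
                         reads_per_clone,
                         cfg, cuts = cuts[i])
    names(sim$reads) <- paste0(names(sim$reads), "_clone", i)
    reads <- c(reads, sim$reads)
    truth_ref <- c(truth_ref, rep(names(rotated)[i], reads_per_clone))
  }
  list(rotated = rotated, reads = reads, truth_ref = truth_ref)
}

test_that("error-free clonal reads assign uniquely to their matched rotation", {
  fx <- clonal_fixture(2000, c(0, 600, 1300), reads_per_clone = 6,
                       cfg_seed = 73)
  res <- assign_clonal_reads(fx$reads, fx$rotated)
  expect_true(all(res$assignments$status == "assigned"))
  expect_equal(res$assignments$assigned_ref, fx$truth_ref)
  expect_equal(sum(res$counts), length(fx$reads))
})

test_that("identical non-rotated duplicate references give all ties", {
  fx <- clonal_fixture(2000, c(0, 600, 1300), reads_per_clone = 4,
                       cfg_seed = 74)
  dup <- fx$rotated[c(1, 1, 1)]
  for (i in 1:3) dup[[i]]$id <- paste0("copy", i)
  names(dup) <- vapply(dup, `[[`, "", "id")
  res <- assign_clonal_reads(fx$reads, dup)
  expect_true(all(res$assignments$status == "unassigned"))
  expect_equal(sum(res$counts), 0L)
})

test_that("cut separations above the margin-equivalent distance separate clones", {
  for (gap in c(100, 579)) {
    margin <- if (gap == 100) 1 else 5 # percent of max score
    fx <- clonal_fixture(3000, c(0, gap), reads_per_clone = 4,
                         cfg_seed = 75 + gap)
    res <- assign_clonal_reads(fx$reads, fx$rotated, margin_pct = margin)
    expect_true(all(res$assignments$status == "assigned"),
                info = sprintf("gap %d", gap))
    expect_equal(res$assignments$assigned_ref, fx$truth_ref)
  }
})

test_that("short fragments that span no cut junction stay unassigned", {
  plasmid <- make_pool(1, base_len = 2000, marker_len = 0, seed = 76)[[1]]
  cuts <- list(cut_spec("p01", 0), cut_spec("p01", 600))
  rotated <- lapply(cuts, function(ct) rotate_reference(plasmid, ct))
  names(rotated) <- vapply(rotated, `[[`, "", "id")
  # a fragment from 800..1400 on the circle lies inside both rotations
  frag <- seq_record("frag", substr(plasmid$sequence, 801, 1400))
  res <- assign_clonal_reads(list(frag = frag), rotated)
  expect_equal(res$assignments$status, "unassigned")
  expect_lt(res$assignments$margin, 5)
})

test_that("noisy full-length reads still demultiplex almost completely", {
  fx <- clonal_fixture(2000, c(0, 600, 1300), reads_per_clone = 10,
                       cfg_seed = 77, err = TRUE)
  res <- assign_clonal_reads(fx$reads, fx$rotated)
  correct <- res$assignments$status == "assigned" &
    res$assignments$assigned_ref == fx$truth_ref
  expect_gte(mean(correct), 0.95)
  wrong <- res$assignments$status == "assigned" &
    res$assignments$assigned_ref != fx$truth_ref
  expect_equal(sum(wrong), 0)
})

test_that("a single rotated reference warns that demultiplexing is vacuous", {
  plasmid <- make_pool(1, base_len = 800, marker_len = 0, seed = 78)[[1]]
  rot <- rotate_reference(plasmid, cut_spec("p01", 0))
  read <- seq_record("r", substr(plasmid$sequence, 1, 700))
  expect_warning(res <- assign_clonal_reads(list(r = read),
                                            stats::setNames(list(rot), rot$id)),
                 "vacuous")
  expect_equal(res$assignments$status, "assigned")
})

test_that("cut manifests round-trip and reject duplicate positions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ref_id\tcut_position\tenzyme_label",
               "p01\t0\tEcoRI", "p01\t579\tBamHI"), path)
  specs <- read_cut_manifest(path)
  expect_length(specs, 2)
  expect_equal(specs[[2]]$cut_position, 579L)
  writeLines(c("ref_id\tcut_position", "p01\t5", "p01\t5"), path)
  expect_error(read_cut_manifest(path), "duplicate")
})
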