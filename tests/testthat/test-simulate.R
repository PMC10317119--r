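test_that("make_pool is deterministic and markers are distinct and recoverable", {
  p1 <- make_pool(16, base_len = 1500, marker_len = 24, seed = 9)
  p2 <- make_pool(16, base_len = 1500, marker_len = 24, seed = 9)
  expect_identical(seq_of(p1), seq_of(p2))
  expect_true(all(vapply(p1, `[[`, TRUE, "circular")))
  # all pairs differ only at the marker locus; markers pairwise distinct
  locus <- 750
  markers <- vapply(p1, function(r) substr(r$sequence, locus + 1, locus + 24), "")
  expect_equal(anyDuplicated(markers), 0L)
  regs <- find_unique_regions(p1)
  expect_true(all(lengths(regs) >= 1))
  covered <- vapply(seq_along(p1), function(i)
    any(vapply(regs[[i]], function(r) r$start <= locus && r$end >= locus + 24,
               TRUE)), TRUE)
  expect_true(all(covered))
})

test_that("dissimilar pools share no long exact subsequence", {
  pool <- make_pool(2, base_len = 3000, marker_len = 0, seed = 21)
  k1 <- kmer_codes_cpp(pool[[1]]$sequence, 12L)
  k2 <- c(kmer_codes_cpp(pool[[2]]$sequence, 12L),
          kmer_codes_cpp(revcomp(pool[[2]]$sequence), 12L))
  shared12 <- intersect(k1, k2)
  # a few chance 12-mers are expected; a 24-mer in common is not
  expect_lt(length(shared12), 30)
  w1 <- substring(pool[[1]]$sequence, 1:(3000 - 23), 24:3000)
  s2 <- pool[[2]]$sequence
  expect_false(any(vapply(w1[seq(1, length(w1), by = 7)],
                          function(w) grepl(w, s2, fixed = TRUE), TRUE)))
})

test_that("apply_variant changes length and content as declared", {
  ref <- make_pool(1, base_len = 800, marker_len = 0, seed = 2)[[1]]
  L <- nchar(ref$sequence)
  del <- apply_variant(ref, variant_spec("p01", "deletion", 300, 22))
  expect_equal(nchar(del$record$sequence), L - 22)
  ins <- apply_variant(ref, variant_spec("p01", "insertion", 300, 1))
  expect_equal(nchar(ins$record$sequence), L + 1)
  sub <- apply_variant(ref, variant_spec("p01", "substitution", 300, 5))
  expect_equal(nchar(sub$record$sequence), L)
  a <- strsplit(ref$sequence, "")[[1]]
  b <- strsplit(sub$record$sequence, "")[[1]]
  expect_equal(sum(a != b), 5)
  expect_true(all(which(a != b) %in% 301:305))
  expect_error(apply_variant(ref, variant_spec("p01", "deletion", L - 5, 22)),
               "out of bounds")
})

test_that("error-free cut-site reads equal the rotated reference exactly", {
  pool <- make_pool(2, base_len = 900, marker_len = 0, seed = 5)
  cuts <- list(cut_spec("p01", 100), cut_spec("p02", 400))
  cfg <- sim_config(sub_rate = 0, ins_rate = 0, del_rate = 0,
                    start_mode = "cut_site", end_trim_mean = 0, seed = 8)
  sim <- simulate_pool(pool, 5, cfg, cuts = cuts)
  rot1 <- rotate_reference(pool$p01, cuts[[1]])
  for (r in sim$reads[sim$truth$ref_id == "p01" & sim$truth$strand == "+"])
    expect_equal(r$sequence, rot1$sequence)
  for (r in sim$reads[sim$truth$ref_id == "p01" & sim$truth$strand == "-"])
    expect_equal(r$sequence, revcomp(rot1$sequence))
})

test_that("simulation output is byte-identical under a fixed seed", {
  pool <- make_pool(3, base_len = 700, marker_len = 0, seed = 5)
  s1 <- simulate_pool(pool, 10, sim_config(seed = 42))
  s2 <- simulate_pool(pool, 10, sim_config(seed = 42))
  expect_identical(seq_of(s1$reads), seq_of(s2$reads))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_pool(pool, 10, sim_config(seed = 43))
  expect_false(identical(seq_of(s1$reads), seq_of(s3$reads)))
})

test_that("realized per-base error is near the configured 10%", {
  pool <- make_pool(1, base_len = 2000, marker_len = 0, seed = 7)
  sim <- simulate_pool(pool, 60, sim_config(seed = 13))
  mp <- map_reads(sim$reads, pool[[1]], scheme = report_scheme())
  errs <- cols <- 0
  for (a in mp$alignments) {
    errs <- errs + sum(a$ops$len[a$ops$op %in% c("X", "I", "D")])
    cols <- cols + sum(a$ops$len[a$ops$op %in% c("M", "X", "D")])
  }
  rate <- errs / cols
  expect_gt(rate, 0.08)
  expect_lt(rate, 0.12)
})

test_that("deletions are enriched in homopolymer runs", {
  # template with long homopolymers interleaved with mixed sequence
  set.seed(31)
  mixed <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  seqs <- character(40)
  for (i in seq_along(seqs))
    seqs[i] <- paste0(mixed(40), paste(rep("A", 8), collapse = ""))
  template <- paste(seqs, collapse = "")
  ref <- seq_record("hp", template, circular = FALSE)
  cfg <- sim_config(sub_rate = 0, ins_rate = 0, del_rate = 0.03,
                    homopolymer_del_factor = 2, seed = 99)
  n_del_hp <- 0; n_hp <- 0; n_del_bg <- 0; n_bg <- 0
  with_seed <- plasmidpool:::with_seed
  with_seed(99, {
    for (rep in 1:40) {
      read <- plasmidpool:::mutate_read(template, cfg)
      aln <- global_align(read, template, report_scheme())
      opv <- plasmidpool:::expand_ops(aln$ops)
      tstep <- opv %in% c("M", "X", "D")
      tpos <- cumsum(tstep)
      rl <- rle(strsplit(template, "")[[1]])
      in_hp <- rep(rl$lengths >= 4, rl$lengths)
      del_here <- opv == "D" & tstep
      hp_cols <- in_hp[tpos[tstep]]
      n_hp <- n_hp + sum(hp_cols); n_bg <- n_bg + sum(!hp_cols)
      n_del_hp <- n_del_hp + sum(del_here[tstep][hp_cols])
      n_del_bg <- n_del_bg + sum(del_here[tstep][!hp_cols])
    }
  })
  rate_hp <- n_del_hp / n_hp
  rate_bg <- n_del_bg / n_bg
  expect_gt(rate_hp, rate_bg * 1.3) # boosted ~2x, allow sampling noise
})

test_that("random-start read starts are uniform on the circle", {
  pool <- make_pool(1, base_len = 1000, marker_len = 0, seed = 17)
  sim <- simulate_pool(pool, 2000, sim_config(seed = 55))
  L <- nchar(pool[[1]]$sequence)
  bins <- cut(sim$truth$start, breaks = seq(0, L, length.out = 11),
              include.lowest = TRUE)
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("subclonal mixtures draw reads from both haplotypes", {
  pool <- make_pool(1, base_len = 1200, marker_len = 0, seed = 3)
  vs <- variant_spec("p01", "deletion", 600, 40, subclonal_fraction = 0.7)
  sim <- simulate_pool(pool, 200, sim_config(seed = 12), variants = list(vs))
  frac <- mean(sim$truth$haplotype == "variant")
  expect_gt(frac, 0.55)
  expect_lt(frac, 0.85)
})
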