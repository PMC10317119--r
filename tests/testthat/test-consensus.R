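test_that("map_reads recovers exact substrings at their true coordinates", {
  set.seed(81)
  ref <- seq_record("ref", random_dna(2000))
  reads <- list(seq_record("a", substr(ref$sequence, 501, 900)),
                seq_record("b", revcomp(substr(ref$sequence, 1201, 1500))))
  mp <- map_reads(reads, ref)
  expect_length(mp$alignments, 2)
  a <- mp$alignments[[1]]
  expect_equal(a$identity_pct, 100)
  expect_equal(c(a$target_start, a$target_end), c(500, 900))
  b <- mp$alignments[[2]]
  expect_equal(b$orientation, "reverse")
  expect_equal(c(b$target_start, b$target_end), c(1200, 1500))
})

test_that("cross-plasmid reads are dropped, not forced onto the reference", {
  pool <- make_pool(2, base_len = 1500, marker_len = 0, seed = 82)
  sim <- simulate_pool(pool["p02"], 8, sim_config(seed = 83))
  mp <- map_reads(sim$reads, pool$p01)
  expect_length(mp$alignments, 0)
  expect_equal(nrow(mp$dropped), 8)
  expect_true(all(mp$dropped$reason %in%
                    c("no_seed", "low_identity", "ambiguous_seed")))
})

test_that("reads spanning the circular origin map once with wrapped coordinates", {
  set.seed(84)
  ref <- seq_record("circ", random_dna(1000), circular = TRUE)
  read <- seq_record("w", paste0(substr(ref$sequence, 901, 1000),
                                 substr(ref$sequence, 1, 150)))
  mp <- map_reads(list(read), ref)
  expect_length(mp$alignments, 1)
  a <- mp$alignments[[1]]
  expect_equal(a$identity_pct, 100)
  expect_equal(a$target_start, 900)
  expect_equal(a$target_end, 1150) # wraps: end > L encodes mod-L coordinates
})

test_that("pileup counts match coverage and capture a subclonal deletion", {
  set.seed(85)
  ref <- seq_record("r", random_dna(400))
  reads <- lapply(1:10, function(i) seq_record(paste0("e", i), ref$sequence))
  mp <- map_reads(reads, ref)
  pl <- build_pileup(mp$alignments, ref)
  expect_true(all(colSums(pl$counts) == 10))
  expect_true(all(apply(pl$counts, 2, max) == 10)) # one symbol per column

  # 7 reads with a 40-bp deletion + 3 without
  del_seq <- paste0(substr(ref$sequence, 1, 180), substr(ref$sequence, 221, 400))
  reads2 <- c(lapply(1:7, function(i) seq_record(paste0("d", i), del_seq)),
              lapply(1:3, function(i) seq_record(paste0("n", i), ref$sequence)))
  mp2 <- map_reads(reads2, ref, scheme = report_scheme())
  pl2 <- build_pileup(mp2$alignments, ref)
  expect_true(all(pl2$counts["-", 181:220] == 7))
  expect_true(all(colSums(pl2$counts)[181:220] == 10))

  # empty alignment set -> all-zero pileup
  pl0 <- build_pileup(list(), ref)
  expect_true(all(pl0$counts == 0))
  expect_error(suppressWarnings(call_consensus(pl0)), NA) # empty, not an error
  expect_equal(call_consensus(pl0)$sequence, "")
})

test_that("plurality calling reproduces the reference and respects depth rules", {
  set.seed(86)
  ref <- seq_record("r", random_dna(600))
  reads <- lapply(1:12, function(i) seq_record(paste0("e", i), ref$sequence))
  mp <- map_reads(reads, ref)
  cons <- call_consensus(build_pileup(mp$alignments, ref))
  expect_identical(cons$sequence, ref$sequence)
  expect_equal(cons$called_interval, c(0, 600))
  expect_equal(cons$mean_depth, 12)

  # uncovered extremities are trimmed, never filled from the reference
  clipped <- lapply(1:12, function(i)
    seq_record(paste0("c", i), substr(ref$sequence, 3, 600)))
  mpc <- map_reads(clipped, ref)
  consc <- call_consensus(build_pileup(mpc$alignments, ref))
  expect_identical(consc$sequence, substr(ref$sequence, 3, 600))
  expect_equal(consc$called_interval, c(2, 600))

  # an interior low-depth stretch is called N, not filled in
  left <- lapply(1:8, function(i)
    seq_record(paste0("l", i), substr(ref$sequence, 1, 300)))
  right <- lapply(1:8, function(i)
    seq_record(paste0("r", i), substr(ref$sequence, 341, 600)))
  thin <- list(seq_record("t", substr(ref$sequence, 250, 400)))
  mpl <- map_reads(c(left, right, thin), ref)
  consl <- call_consensus(build_pileup(mpl$alignments, ref), min_depth = 5)
  # columns 300..339 are covered by the single thin read only -> N
  expect_false(grepl("N", substr(consl$sequence, 1, 300)))
  expect_equal(consl$low_depth_positions, 300:339)
  expect_equal(substr(consl$sequence, 301, 340),
               paste(rep("N", 40), collapse = ""))
  expect_equal(substr(consl$sequence, 341, 600), substr(ref$sequence, 341, 600))
})

test_that("plurality calling is invariant to read input order", {
  pool <- make_pool(1, base_len = 800, marker_len = 0, seed = 87)
  sim <- simulate_pool(pool, 30, sim_config(seed = 88))
  mp <- map_reads(sim$reads, pool[[1]], scheme = report_scheme())
  c1 <- call_consensus(build_pileup(mp$alignments, pool[[1]]))
  set.seed(89)
  c2 <- call_consensus(build_pileup(sample(mp$alignments), pool[[1]]))
  expect_identical(c1$sequence, c2$sequence)
})

test_that("majority insertions are called once, at the right junction", {
  set.seed(90)
  ref <- seq_record("r", random_dna(500))
  insseq <- random_dna(10)
  with_ins <- paste0(substr(ref$sequence, 1, 250), insseq,
                     substr(ref$sequence, 251, 500))
  reads <- lapply(1:9, function(i) seq_record(paste0("i", i), with_ins))
  mp <- map_reads(reads, ref, scheme = report_scheme())
  cons <- call_consensus(build_pileup(mp$alignments, ref))
  expect_identical(cons$sequence, with_ins)

  # minority insertions (3 of 9) stay out of the consensus
  reads2 <- c(lapply(1:3, function(i) seq_record(paste0("i", i), with_ins)),
              lapply(1:6, function(i) seq_record(paste0("p", i), ref$sequence)))
  mp2 <- map_reads(reads2, ref, scheme = report_scheme())
  cons2 <- call_consensus(build_pileup(mp2$alignments, ref))
  expect_identical(cons2$sequence, ref$sequence)
})

test_that("round trip: error-free pools reproduce every reference exactly", {
  pool <- make_pool(6, base_len = 1000, marker_len = 0, seed = 91)
  sim <- simulate_pool(pool, 25, sim_config(sub_rate = 0, ins_rate = 0,
                                            del_rate = 0, seed = 92))
  for (id in names(pool)) {
    reads <- sim$reads[sim$truth$ref_id == id]
    mp <- map_reads(reads, pool[[id]])
    cons <- call_consensus(build_pileup(mp$alignments, pool[[id]]))
    expect_identical(cons$sequence, pool[[id]]$sequence)
  }
})
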