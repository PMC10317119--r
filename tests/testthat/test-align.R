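test_that("worked examples under the binning scheme score as expected", {
  s <- binning_scheme()
  expect_equal(global_align("ACGT", "ACGT", s)$score, 12)
  expect_equal(global_align("ACGT", "ACGT", s)$identity_pct, 100)
  expect_equal(global_align("ACGT", "AGT", s)$score, -1)
  expect_equal(global_align("AAAA", "TTTT", s)$score, -24)

  hit <- local_align("TTTACGTTTT", "ACGT", s)
  expect_equal(hit$score, 12)
  expect_equal(hit$target_interval, c(0, 4))
  expect_equal(local_align("GGGG", "CCCC", s)$score, 0)
  mer24 <- "ACGTTGCAACGTGGCATCAATGCA"
  expect_equal(local_align(mer24, mer24, s)$score, 72)
})

test_that("scores agree exactly with the brute-force DP oracle", {
  set.seed(42)
  schemes <- list(binning_scheme(), report_scheme(), scoring_scheme(1, -1, -2, -1))
  for (rep in 1:200) {
    a <- random_dna(sample(1:20, 1), c("A", "C", "G", "T", "N"))
    b <- random_dna(sample(1:20, 1), c("A", "C", "G", "T", "N"))
    s <- schemes[[1 + rep %% 3]]
    for (mode in c("global", "local", "semiglobal")) {
      got <- switch(mode,
        global = global_align(a, b, s),
        local = local_align(a, b, s),
        semiglobal = semiglobal_align(a, b, s))
      expect_equal(got$score, oracle_align_score(a, b, s, mode),
                   info = sprintf("%s: %s vs %s", mode, a, b))
    }
  }
})

test_that("alignment object is internally consistent", {
  set.seed(7)
  s <- binning_scheme()
  for (rep in 1:50) {
    a <- random_dna(sample(5:40, 1))
    b <- random_dna(sample(5:40, 1))
    aln <- global_align(a, b, s)
    qlen <- sum(aln$ops$len[aln$ops$op %in% c("M", "X", "I")])
    tlen <- sum(aln$ops$len[aln$ops$op %in% c("M", "X", "D")])
    expect_equal(qlen, diff(aln$query_interval))
    expect_equal(tlen, diff(aln$target_interval))
    expect_equal(diff(aln$query_interval), nchar(a))
    expect_equal(diff(aln$target_interval), nchar(b))
    expect_equal(aln$score, plasmidpool:::score_from_ops(aln$ops, s))
    expect_gte(aln$identity_pct, 0)
    expect_lte(aln$identity_pct, 100)
  }
})

test_that("global alignment is symmetric and self-alignment scores match*len", {
  set.seed(11)
  s <- binning_scheme()
  for (rep in 1:25) {
    a <- random_dna(sample(3:25, 1))
    b <- random_dna(sample(3:25, 1))
    expect_equal(global_align(a, b, s)$score, global_align(b, a, s)$score)
    expect_equal(global_align(a, a, s)$score, s$match * nchar(a))
    expect_gte(local_align(a, b, s)$score, 0)
  }
})

test_that("scores match Biostrings pairwiseAlignment (converted convention)", {
  skip_if_not_installed("Biostrings")
  set.seed(99)
  s <- binning_scheme()
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = s$match, mismatch = s$mismatch, baseOnly = TRUE)
  # Biostrings charges gapOpening + L*gapExtension for a length-L gap;
  # ours is open + (L-1)*extend, so shift the opening penalty.
  go <- -(s$gap_open - s$gap_extend)
  ge <- -s$gap_extend
  for (rep in 1:30) {
    a <- random_dna(sample(4:30, 1))
    b <- random_dna(sample(4:30, 1))
    for (type in c("global", "local")) {
      ref <- Biostrings::pairwiseAlignment(
        a, b, type = type, substitutionMatrix = mat,
        gapOpening = go, gapExtension = ge, scoreOnly = TRUE)
      got <- if (type == "global") global_align(a, b, s) else local_align(a, b, s)
      expect_equal(got$score, ref, info = paste(type, a, b))
    }
  }
})

test_that("semiglobal alignment maps substrings at their true coordinates", {
  set.seed(3)
  s <- binning_scheme()
  ref <- random_dna(1000)
  read <- substr(ref, 301, 400)
  aln <- semiglobal_align(read, ref, s)
  expect_equal(aln$identity_pct, 100)
  expect_equal(aln$target_interval, c(300, 400))

  # one substitution -> identity 99, score 99*match + mismatch
  sub <- read
  substr(sub, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(read, 50, 50))[1]
  aln2 <- semiglobal_align(sub, ref, s)
  expect_equal(aln2$score, 99 * s$match + s$mismatch)
  expect_equal(round(aln2$identity_pct), 99)
})

test_that("reads spanning a circular origin map on the doubled reference", {
  set.seed(5)
  s <- binning_scheme()
  ref <- random_dna(1000)
  read <- paste0(substr(ref, 951, 1000), substr(ref, 1, 50))
  aln <- semiglobal_align(read, paste0(ref, ref), s)
  expect_equal(aln$identity_pct, 100)
  expect_equal(aln$target_interval[1] %% 1000, 950)
  expect_equal(diff(aln$target_interval), 100)
})

test_that("banded semiglobal equals unbanded when the path fits the band", {
  set.seed(13)
  s <- binning_scheme()
  ref <- random_dna(3000)
  for (rep in 1:10) {
    start <- sample(1:2000, 1)
    read <- substr(ref, start, start + 799)
    # ~2% substitution noise
    rv <- strsplit(read, "")[[1]]
    idx <- sample(length(rv), 16)
    rv[idx] <- sample(c("A", "C", "G", "T"), 16, replace = TRUE)
    read <- paste(rv, collapse = "")
    free <- semiglobal_align(read, ref, s)
    banded <- semiglobal_align(read, ref, s, band = 50, diag = start - 1)
    expect_equal(banded$score, free$score)
  }
})

test_that("a band that excludes every cell signals failure", {
  s <- binning_scheme()
  ref <- random_dna(500)
  read <- substr(ref, 401, 480)
  expect_null(semiglobal_align(read, ref, s, band = 20, diag = 2000))
})

test_that("normalized_score maps raw scores onto percent of maximum", {
  s <- binning_scheme()
  mer24 <- "ACGTTGCAACGTGGCATCAATGCA"
  aln <- local_align(mer24, mer24, s)
  expect_equal(normalized_score(aln, 24, s), 100)
  expect_equal(normalized_score(list(score = 36), 24, s), 50)
  neg <- global_align("AAAA", "TTTT", s)
  expect_equal(normalized_score(neg, 4, s), 0)
})

test_that("empty sequences are rejected", {
  s <- binning_scheme()
  expect_error(global_align("", "ACGT", s))
  expect_error(local_align("ACGT", "", s))
})
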