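# Independent brute-force three-state DP oracle (scores only, dense matrices,
# plain R). Written separately from the package's aligner; shares only the
# conventions: gap of length L costs open + (L-1)*extend, N always mismatches,
# semiglobal = overlap (free starts on row 0 / column 0, free ends on last
# row / column).
oracle_align_score <- function(a, b, scheme,
                               mode = c("global", "local", "semiglobal")) {
  mode <- match.arg(mode)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  M <- X <- Y <- matrix(-Inf, m + 1, n + 1)
  M[1, 1] <- 0
  if (mode == "global") {
    Y[1, 1 + seq_len(n)] <- scheme$gap_open + (seq_len(n) - 1) * scheme$gap_extend
    X[1 + seq_len(m), 1] <- scheme$gap_open + (seq_len(m) - 1) * scheme$gap_extend
  } else {
    M[1, ] <- 0
    M[, 1] <- 0
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sub <- if (av[i] == bv[j] && av[i] != "N") scheme$match else scheme$mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub
      if (mode == "local") M[i + 1, j + 1] <- max(0, M[i + 1, j + 1])
      X[i + 1, j + 1] <- max(M[i, j + 1] + scheme$gap_open,
                             X[i, j + 1] + scheme$gap_extend,
                             Y[i, j + 1] + scheme$gap_open)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + scheme$gap_open,
                             Y[i + 1, j] + scheme$gap_extend,
                             X[i + 1, j] + scheme$gap_open)
    }
  }
  if (mode == "global") {
    max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
  } else if (mode == "local") {
    max(0, max(M))
  } else {
    max(M[m + 1, ], X[m + 1, ], Y[m + 1, ],
        M[, n + 1], X[, n + 1], Y[, n + 1])
  }
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
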