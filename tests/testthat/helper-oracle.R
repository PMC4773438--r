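# Independent alignment oracle: full-matrix dynamic program over the same
# scoring model (semi-global, affine gaps, flat-cost long deletion), written
# as plain R loops with a naive scan over all jump sources. Returns the
# optimal score only.
oracle_align_score <- function(q, r, match = 2, mismatch = -4, gap_open = 6,
                               gap_ext = 1, jump_cost = 24, min_jump = 30) {
  n <- nchar(q)
  m <- nchar(r)
  qs <- strsplit(q, "")[[1]]
  rs <- strsplit(r, "")[[1]]
  NEG <- -1e9
  M <- X <- Y <- H <- matrix(NEG, n + 1, m + 1)
  H[1, ] <- 0
  for (i in 1:n) {
    X[i + 1, 1] <- -(gap_open + i * gap_ext)
    H[i + 1, 1] <- X[i + 1, 1]
  }
  for (i in 1:n) {
    for (j in 1:m) {
      M[i + 1, j + 1] <- H[i, j] + if (qs[i] == rs[j]) match else mismatch
      X[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
      jmp <- if (j - min_jump >= 0)
        max(H[i + 1, 1:(j - min_jump + 1)]) - jump_cost else NEG
      H[i + 1, j + 1] <- max(M[i + 1, j + 1], X[i + 1, j + 1],
                             Y[i + 1, j + 1], jmp)
    }
  }
  max(H[n + 1, ])
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
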