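# Independent brute-force DP oracles for the alignment cores, written
# plainly in R with full matrices. A gap run of length k costs
# gap_open + (k - 1) * gap_extend, as in the package scheme.

NEGINF <- -1e15

# semi-global: query aligned end-to-end, target flanks free; returns the
# best score and the smallest 1-based target end among optima
oracle_semiglobal <- function(q, t, match = 1, mismatch = -1,
                              gap_open = -2, gap_extend = -2) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  m <- length(qc); n <- length(tc)
  M <- matrix(NEGINF, m + 1, n + 1)  # ends in aligned pair
  X <- matrix(NEGINF, m + 1, n + 1)  # ends in query-char-vs-gap
  Y <- matrix(NEGINF, m + 1, n + 1)  # ends in target-char-vs-gap
  S <- matrix(NEGINF, m + 1, n + 1)  # start state (free target prefix)
  S[1, ] <- 0
  for (i in 1:m) {
    for (j in 0:n) {
      ii <- i + 1; jj <- j + 1
      if (j >= 1) {
        prev <- max(S[ii - 1, jj - 1], M[ii - 1, jj - 1],
                    X[ii - 1, jj - 1], Y[ii - 1, jj - 1])
        if (prev > NEGINF / 2)
          M[ii, jj] <- prev + if (qc[i] == tc[j]) match else mismatch
      }
      up <- max(S[ii - 1, jj], M[ii - 1, jj], Y[ii - 1, jj])
      X[ii, jj] <- max(if (up > NEGINF / 2) up + gap_open else NEGINF,
                       if (X[ii - 1, jj] > NEGINF / 2)
                         X[ii - 1, jj] + gap_extend else NEGINF)
      if (j >= 1) {
        left <- max(M[ii, jj - 1], X[ii, jj - 1])
        Y[ii, jj] <- max(if (left > NEGINF / 2) left + gap_open else NEGINF,
                         if (Y[ii, jj - 1] > NEGINF / 2)
                           Y[ii, jj - 1] + gap_extend else NEGINF)
      }
    }
  }
  fin <- pmax(M[m + 1, ], X[m + 1, ])
  best <- max(fin)
  list(score = best, target_end = which(fin >= best - 1e-9)[1] - 1L)
}

# local alignment maximising (score, identity columns) lexicographically;
# integer scores assumed so the pair packs into score * 1000 + matches
oracle_local <- function(q, t, match = 1, mismatch = -1,
                         gap_open = -2, gap_extend = -2) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  m <- length(qc); n <- length(tc)
  pack <- function(s, mm) s * 1000 + mm
  M <- matrix(NEGINF, m + 1, n + 1)
  X <- matrix(NEGINF, m + 1, n + 1)
  Y <- matrix(NEGINF, m + 1, n + 1)
  best <- pack(0, 0)
  for (i in 1:m) {
    for (j in 1:n) {
      ii <- i + 1; jj <- j + 1
      diag <- max(M[ii - 1, jj - 1], X[ii - 1, jj - 1],
                  Y[ii - 1, jj - 1], pack(0, 0))
      is_match <- qc[i] == tc[j]
      M[ii, jj] <- diag + pack(if (is_match) match else mismatch,
                               if (is_match) 1 else 0)
      up <- max(M[ii - 1, jj], Y[ii - 1, jj])
      X[ii, jj] <- max(if (up > NEGINF / 2) up + pack(gap_open, 0) else NEGINF,
                       if (X[ii - 1, jj] > NEGINF / 2)
                         X[ii - 1, jj] + pack(gap_extend, 0) else NEGINF)
      left <- max(M[ii, jj - 1], X[ii, jj - 1])
      Y[ii, jj] <- max(if (left > NEGINF / 2) left + pack(gap_open, 0) else NEGINF,
                       if (Y[ii, jj - 1] > NEGINF / 2)
                         Y[ii, jj - 1] + pack(gap_extend, 0) else NEGINF)
      if (M[ii, jj] > best) best <- M[ii, jj]
    }
  }
  list(score = floor(best / 1000), matches = best %% 1000)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
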