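# Independent oracles, implemented with no code shared with the package.

# Literal simulation of the upstream A-counter: walk the proximal-first
# bases one by one, +1 for A, -1 otherwise, stop when the counter hits
# -1 or the window ends; report the running maximum (floored at 0) and
# the halting index.
oracle_a_count <- function(chars) {
  counter <- 0L
  best <- 0L
  halt <- length(chars)
  for (i in seq_along(chars)) {
    counter <- counter + if (chars[i] == "A") 1L else -1L
    if (counter > best) best <- counter
    if (counter == -1L) {
      halt <- i
      break
    }
  }
  list(a_count = best, halt = halt)
}

# Full-matrix Smith-Waterman score against a homopolymer-A target with
# linear gap cost. Row-wise recurrence: for each query base i,
#   A[j] = max(0, H[i-1][j-1] + s(q_i), H[i-1][j] + gap)
#   H[i][j] = max(A[j], H[i][j-1] + gap)
# the second line resolved in closed form via a running decayed
# maximum, so every DP cell is computed.
oracle_sw_score <- function(query, target_len = 180L, match = 2,
                            mismatch = -3, gap = -3) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  m <- length(q)
  if (m == 0L) return(0)
  n <- target_len
  j <- seq_len(n)
  prev <- numeric(n)
  best <- 0
  for (i in seq_len(m)) {
    s <- if (q[i] == "A") match else mismatch
    diag <- c(0, prev[-n]) + s
    up <- prev + gap
    a <- pmax(0, diag, up)
    row <- cummax(a - gap * j) + gap * j
    best <- max(best, row)
    prev <- row
  }
  best
}

# Brute-force window-maximum reference: repeatedly take the candidate
# with the highest support (ties toward the transcript 3'-most
# position) and drop everything within `half` nt of it.
oracle_window_max <- function(pos, support, strand, half = 10L) {
  keep <- integer(0)
  alive <- rep(TRUE, length(pos))
  while (any(alive)) {
    idx <- which(alive)
    tie <- if (strand == "+") -pos[idx] else pos[idx]
    i <- idx[order(-support[idx], tie)[1]]
    keep <- c(keep, i)
    alive[abs(pos - pos[i]) <= half] <- FALSE
  }
  sort(keep)
}
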