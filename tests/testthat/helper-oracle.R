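# Independent brute-force oracles. These deliberately share no code with
# the package pipeline: residues are tallied by explicit iteration over
# records and the entropy is evaluated term by term.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
SP8 <- c("P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p")

# S_i by direct tally at one subpocket: counts -> divide by abundance ->
# renormalize -> -sum p ln p / ln 20.
oracle_subpocket_entropy <- function(records, pos, bg) {
  counts <- setNames(numeric(20), AA20)
  for (r in seq_len(nrow(records))) {
    aa <- records[[pos]][r]
    if (aa %in% AA20) counts[aa] <- counts[aa] + 1
  }
  w <- numeric(20)
  for (k in 1:20) w[k] <- counts[k] / bg[[AA20[k]]]
  p <- w / sum(w)
  s <- 0
  for (k in 1:20) if (p[k] > 0) s <- s - p[k] * log(p[k])
  s / log(20)
}

# S_ij by direct pair tally over 400 cells.
oracle_pairwise_entropy <- function(records, i, j, bg) {
  counts <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  for (r in seq_len(nrow(records))) {
    a <- records[[i]][r]; b <- records[[j]][r]
    if (a %in% AA20 && b %in% AA20) counts[a, b] <- counts[a, b] + 1
  }
  w <- matrix(0, 20, 20)
  for (ka in 1:20) for (kb in 1:20)
    w[ka, kb] <- counts[ka, kb] / (bg[[AA20[ka]]] * bg[[AA20[kb]]])
  q <- w / sum(w)
  s <- 0
  for (ka in 1:20) for (kb in 1:20)
    if (q[ka, kb] > 0) s <- s - q[ka, kb] * log(q[ka, kb])
  s / log(400)
}

# Random small record set over all 8 positions (canonical residues plus
# optional gaps/unknowns), as a plain data.frame.
random_records <- function(n, p_gap = 0, p_unknown = 0, id = "rnd") {
  symbols <- c(AA20, "-", "X")
  probs <- c(rep((1 - p_gap - p_unknown) / 20, 20), p_gap, p_unknown)
  mat <- matrix(sample(symbols, n * 8, replace = TRUE, prob = probs), n, 8)
  # guarantee the "at least one canonical residue" invariant
  mat[, 4] <- sample(AA20, n, replace = TRUE)
  df <- data.frame(protease_id = id, mat, stringsAsFactors = FALSE)
  names(df) <- c("protease_id", SP8)
  df
}
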