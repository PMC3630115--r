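# Pairwise cleavage entropy S_ij between subpockets: joint 20 x 20
# residue-pair distributions, normalized against the independence product
# of background abundances, count-gated because 400 cells need far more
# observations than 20.

#' Joint residue-pair counts for one subpocket pair
#'
#' `counts[a, b]` = number of records with canonical residue `a` at
#' subpocket `i` AND canonical `b` at `j`. Records with a gap or ambiguity
#' code at either position are excluded from this pair only (pairwise
#' exclusion, consistent with the single-column handling).
#'
#' @param records a `cleavage_records` data frame (single protease).
#' @param i,j distinct subpocket names (see [subpockets()]).
#' @param alphabet an [aa_alphabet()].
#' @return 20 x 20 integer matrix, rows = residue at `i`, cols = residue
#'   at `j`; `attr(., "pair_total")` holds the effective observation count.
#' @export
build_pair_counts <- function(records, i, j, alphabet = aa_alphabet()) {
  stopifnot(is.data.frame(records))
  i <- match.arg(i, SUBPOCKETS); j <- match.arg(j, SUBPOCKETS)
  if (identical(i, j))
    cleavent_stop("subpockets i and j must differ", "cleavent_argument_error")
  a <- factor(records[[i]], levels = alphabet$residues)
  b <- factor(records[[j]], levels = alphabet$residues)
  counts <- table(a, b, useNA = "no")
  counts <- matrix(as.integer(counts), 20L, 20L,
                   dimnames = list(alphabet$residues, alphabet$residues))
  attr(counts, "pair_total") <- sum(counts)
  counts
}

#' Pairwise cleavage entropy S_ij from joint pair counts
#'
#' Joint counts are divided by the independence product of background
#' abundances and renormalized over all 400 pairs,
#' \deqn{q_{ab} = \frac{c_{ab}/(f_a f_b)}{\sum_{cd} c_{cd}/(f_c f_d)},}
#' then scored as \eqn{S_{ij} = -\sum_{ab} q_{ab} \log q_{ab} / \log 400}:
#' 0 for a single conserved residue pair, 1 for pairs distributed as
#' expected by chance from the background. A perfectly coupled pair with
#' uniform marginals (20 equiprobable pairs) scores log(20)/log(400) = 0.5
#' even though both marginal entropies are 1 -- the cooperativity signal.
#'
#' @param pair_counts 20 x 20 matrix from [build_pair_counts()].
#' @param bg background [load_abundance()] table.
#' @param base logarithm base (normalizer follows it).
#' @return S_ij in \[0, 1\].
#' @export
pairwise_entropy <- function(pair_counts, bg = load_abundance("mccaldon"),
                             base = exp(1)) {
  stopifnot(is.matrix(pair_counts), all(dim(pair_counts) == c(20L, 20L)))
  if (any(pair_counts < 0))
    cleavent_stop("pair counts must be non-negative", "cleavent_contract_error")
  if (sum(pair_counts) == 0)
    cleavent_stop("pair has zero effective observations",
                  "cleavent_unavailable")
  f <- validate_abundance(stats::setNames(as.numeric(bg), names(bg)))
  w <- pair_counts / outer(f, f)
  q <- w / sum(w)
  pos <- q > 0
  -sum(q[pos] * log(q[pos], base = base)) / log(400, base = base) + 0
}

#' Pairwise cleavage entropy matrix over all subpocket pairs
#'
#' Computes S_ij for every unordered subpocket pair whose effective pair
#' total (records canonical at both positions) reaches
#' `min_pair_substrates`; pairs below the cutoff are gated and carry no
#' numeric value. The stringent default of 10000 mirrors the 100-substrate
#' rule of the one-dimensional analysis scaled to 400 cells. Single
#' subpocket entropies S_i are computed alongside for the standard
#' grid-plus-marginals report layout.
#'
#' @param records a `cleavage_records` data frame for one protease.
#' @param bg background [load_abundance()] table.
#' @param min_pair_substrates inclusive gating cutoff on effective pair
#'   totals; default 10000.
#' @param base logarithm base.
#' @param alphabet an [aa_alphabet()].
#' @return a `pairwise_entropy_matrix`: list with `protease_id`, `S_ij`
#'   (8 x 8, upper triangle, `NA` elsewhere/gated), `gated` (logical 8 x 8),
#'   `pair_totals`, `S_i`, `min_pair_substrates`, `n_records`.
#' @export
pairwise_matrix <- function(records, bg = load_abundance("mccaldon"),
                            min_pair_substrates = 10000L, base = exp(1),
                            alphabet = aa_alphabet()) {
  stopifnot(min_pair_substrates >= 1L)
  m <- build_count_matrix(records, alphabet = alphabet)
  dimn <- list(SUBPOCKETS, SUBPOCKETS)
  S_ij <- matrix(NA_real_, 8L, 8L, dimnames = dimn)
  gated <- matrix(FALSE, 8L, 8L, dimnames = dimn)
  pair_totals <- matrix(NA_integer_, 8L, 8L, dimnames = dimn)
  for (ii in 1:7) for (jj in (ii + 1L):8L) {
    pc <- build_pair_counts(records, SUBPOCKETS[ii], SUBPOCKETS[jj],
                            alphabet = alphabet)
    tot <- attr(pc, "pair_total")
    pair_totals[ii, jj] <- tot
    if (tot < min_pair_substrates) {
      gated[ii, jj] <- TRUE
    } else {
      S_ij[ii, jj] <- pairwise_entropy(pc, bg, base = base)
    }
  }
  pm <- normalize_counts(m, bg)
  S_i <- vapply(seq_len(8L), function(i) {
    if (!pm$available[i]) NA_real_ else subpocket_entropy(pm$p[, i], base = base)
  }, numeric(1))
  names(S_i) <- SUBPOCKETS
  structure(list(protease_id = m$protease_id, S_ij = S_ij, gated = gated,
                 pair_totals = pair_totals, S_i = S_i,
                 min_pair_substrates = as.integer(min_pair_substrates),
                 n_records = m$n_records),
            class = "pairwise_entropy_matrix")
}

#' @export
print.pairwise_entropy_matrix <- function(x, ...) {
  cat(sprintf("Pairwise cleavage entropies: %s  (n = %d, pair cutoff %d)\n",
              x$protease_id, x$n_records, x$min_pair_substrates))
  n_gated <- sum(x$gated)
  grid <- round(x$S_ij, 3)
  print(grid, na.print = ".")
  cat(sprintf("%d of 28 pairs gated below the substrate cutoff\n", n_gated))
  cat("single-subpocket S_i:\n"); print(round(x$S_i, 3))
  invisible(x)
}

#' Write a pairwise entropy matrix as delimited text
#'
#' Emits the 8 x 8 grid with gated/absent cells as `NA` plus a final row of
#' single-subpocket entropies labelled `S_i`.
#'
#' @param x a [pairwise_matrix()] result.
#' @param path output file.
#' @param digits decimal places for the fixed-format output.
#' @return `path`, invisibly.
#' @export
write_pairwise_matrix <- function(x, path, digits = 6L) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf(paste0("%.", digits, "f"), v))
  grid <- x$S_ij
  grid[lower.tri(grid)] <- t(grid)[lower.tri(grid)]  # symmetric display
  rows <- c(paste(c("subpocket", SUBPOCKETS), collapse = "\t"),
            vapply(seq_len(8L), function(i) {
              paste(c(SUBPOCKETS[i], fmt(grid[i, ])), collapse = "\t")
            }, character(1)),
            paste(c("S_i", fmt(x$S_i)), collapse = "\t"))
  writeLines(rows, path)
  invisible(path)
}
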