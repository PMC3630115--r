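# Entropy core: abundance-normalized probability matrices, subpocket-wise
# cleavage entropy S_i, and total cleavage entropy S_cleavage.

#' Abundance-normalize a count matrix into per-subpocket probabilities
#'
#' Two-stage normalization: raw counts are first divided by the background
#' abundance f_a of each residue, then each subpocket column is rescaled to
#' sum to 1, giving
#' \deqn{p_{a,i} = \frac{c_{a,i}/f_a}{\sum_b c_{b,i}/f_b}.}
#' A subpocket distribution matching the background therefore normalizes to
#' the uniform column, the entropy-1 endpoint. Columns with zero effective
#' counts are flagged unavailable (`NA`), never silently zero.
#'
#' @param m a [build_count_matrix()] result.
#' @param bg an `abundance_table` from [load_abundance()].
#' @return a `probability_matrix`: list with `protease_id`, `p` (20 x 8,
#'   columns summing to 1 or all-`NA`), `available` (logical per
#'   subpocket), `column_totals`, `n_records`.
#' @export
normalize_counts <- function(m, bg = load_abundance("mccaldon")) {
  stopifnot(inherits(m, "count_matrix"))
  f <- validate_abundance(stats::setNames(as.numeric(bg), names(bg)))
  w <- m$counts / f  # recycles f down each column (rows = residues)
  tot <- colSums(w)
  available <- tot > 0
  p <- sweep(w, 2L, ifelse(available, tot, NA_real_), "/")
  structure(list(protease_id = m$protease_id, p = p, available = available,
                 column_totals = m$column_totals, n_records = m$n_records),
            class = "probability_matrix")
}

#' Subpocket-wise cleavage entropy S_i
#'
#' Normalized Shannon entropy of a 20-residue probability column:
#' \deqn{S_i = -\sum_a p_{a,i} \log p_{a,i} / \log 20,}
#' with 0 log 0 := 0 by continuity. Ranges from 0 for a perfectly conserved
#' single amino acid to 1 for an equal (after abundance normalization:
#' background-like) distribution. The log base is irrelevant as long as the
#' normalizer matches; `base` exists to demonstrate that invariance.
#'
#' @param column numeric vector of 20 probabilities, entries >= 0, summing
#'   to 1 within 1e-9.
#' @param base logarithm base; default natural log.
#' @return S_i in \[0, 1\].
#' @export
#' @examples
#' subpocket_entropy(c(1, rep(0, 19)))            # 0: conserved
#' subpocket_entropy(rep(0.05, 20))               # 1: unspecific
#' subpocket_entropy(c(0.5, 0.5, rep(0, 18)))     # log(2)/log(20)
subpocket_entropy <- function(column, base = exp(1)) {
  column <- as.numeric(column)
  if (length(column) != 20L || anyNA(column))
    cleavent_stop("probability column must be 20 finite values",
                  "cleavent_contract_error")
  if (any(column < -1e-12))
    cleavent_stop("probability column has negative entries",
                  "cleavent_contract_error")
  if (abs(sum(column) - 1) > 1e-9)
    cleavent_stop(sprintf("probability column sums to %.12g, not 1",
                          sum(column)), "cleavent_contract_error")
  pos <- column > 0
  # trailing + 0 normalizes IEEE negative zero for conserved columns
  -sum(column[pos] * log(column[pos], base = base)) / log(20, base = base) + 0
}

#' Total cleavage entropy S_cleavage
#'
#' Sum of the eight subpocket entropies P4..P4', ranging from 0 for a
#' single conserved substrate to 8 for a background-random distribution of
#' cleaved sequences; the scale on which whole proteases are ranked.
#'
#' @param S_values numeric vector of 8 subpocket entropies, each in
#'   \[0, 1\]; `NA` marks an unavailable subpocket.
#' @param partial if `FALSE` (default), any unavailable subpocket is an
#'   error; if `TRUE`, available subpockets are summed and the count of
#'   summed subpockets is attached as attribute `n_subpockets` (a partial
#'   total is not comparable to full 0-8 totals, hence always annotated).
#' @return S_cleavage.
#' @export
total_cleavage_entropy <- function(S_values, partial = FALSE) {
  if (length(S_values) != 8L)
    cleavent_stop("expected exactly 8 subpocket entropies",
                  "cleavent_contract_error")
  if (any(!is.na(S_values) & (S_values < -1e-12 | S_values > 1 + 1e-12)))
    cleavent_stop("subpocket entropies must lie in [0, 1]",
                  "cleavent_contract_error")
  if (anyNA(S_values)) {
    if (!partial)
      cleavent_stop("unavailable subpocket(s); pass partial = TRUE to sum the rest",
                    "cleavent_unavailable")
    out <- sum(S_values, na.rm = TRUE)
    attr(out, "n_subpockets") <- sum(!is.na(S_values))
    return(out)
  }
  sum(S_values)
}

#' Compute a full specificity profile for one protease
#'
#' Chains [build_count_matrix()], [normalize_counts()],
#' [subpocket_entropy()] per subpocket and [total_cleavage_entropy()].
#'
#' @inheritParams build_count_matrix
#' @param bg background [load_abundance()] table.
#' @param partial allow a partial total when some subpocket has zero
#'   effective counts (see [total_cleavage_entropy()]).
#' @param base logarithm base passed through to the entropy.
#' @return a `specificity_profile`: list with `protease_id`, `S_i` (named
#'   length-8), `S_cleavage`, `column_totals` (effective counts per
#'   subpocket), `n_records`.
#' @export
compute_profile <- function(records, protease_id = NULL,
                            bg = load_abundance("mccaldon"),
                            partial = FALSE, base = exp(1),
                            alphabet = aa_alphabet()) {
  m <- build_count_matrix(records, protease_id, alphabet = alphabet)
  pm <- normalize_counts(m, bg)
  S_i <- vapply(seq_len(8L), function(i) {
    if (!pm$available[i]) return(NA_real_)
    subpocket_entropy(pm$p[, i], base = base)
  }, numeric(1))
  names(S_i) <- SUBPOCKETS
  total <- total_cleavage_entropy(S_i, partial = partial)
  structure(list(protease_id = m$protease_id, S_i = S_i,
                 S_cleavage = as.numeric(total),
                 n_subpockets = attr(total, "n_subpockets") %||% sum(!is.na(S_i)),
                 column_totals = m$column_totals, n_records = m$n_records),
            class = "specificity_profile")
}

#' @export
print.specificity_profile <- function(x, ...) {
  cat(sprintf("Specificity profile: %s  (n = %d substrates)\n",
              x$protease_id, x$n_records))
  S <- stats::setNames(x$S_i, SUBPOCKET_LABELS)
  print(round(S, 3))
  cat(sprintf("S_cleavage = %.3f over %d subpockets\n",
              x$S_cleavage, x$n_subpockets))
  invisible(x)
}

#' Mean subpocket entropy over the P- or P'-region
#'
#' Region summaries of the sort "serine proteases bind conserved residues
#' on the non-prime side": mean of S_P4..S_P1 or of S_P1'..S_P4'.
#'
#' @param profile a [compute_profile()] result.
#' @param region `"P"` (non-prime, P4..P1) or `"Pprime"` (P1'..P4').
#' @return arithmetic mean of the four subpocket entropies.
#' @export
region_average <- function(profile, region = c("P", "Pprime")) {
  region <- match.arg(region)
  idx <- if (region == "P") 1:4 else 5:8
  S <- profile$S_i[idx]
  if (anyNA(S))
    cleavent_stop(sprintf("region '%s' has unavailable subpocket(s)", region),
                  "cleavent_unavailable")
  mean(S)
}
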