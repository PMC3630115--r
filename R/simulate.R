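# Seeded synthetic substrate generators. Two modes everywhere:
#   "sampled"          -- i.i.d. draws, realistic sampling noise;
#   "expected_counts"  -- deterministic largest-remainder allocation of the
#                         target distribution, so analytic entropy
#                         endpoints (0, 1, 0.5, ...) are hit exactly.
# All generators are deterministic given their seed, and emit the same
# cleavage_records container that read_cleavage_table() produces.

records_from_matrix <- function(mat, protease_id) {
  colnames(mat) <- SUBPOCKETS
  df <- data.frame(protease_id = protease_id,
                   as.data.frame(mat, stringsAsFactors = FALSE))
  new_cleavage_records(df)
}

# A column of n residues whose counts follow `probs`: exact allocation in
# expected mode (then shuffled so columns are not trivially co-ordered),
# i.i.d. sampling otherwise. Caller provides seeded RNG context.
column_draw <- function(n, probs, mode) {
  if (mode == "expected_counts") {
    sample(rep(names(probs), allocate_counts(n, probs)))
  } else {
    sample(names(probs), n, replace = TRUE, prob = probs)
  }
}

check_mode <- function(mode) match.arg(mode, c("sampled", "expected_counts"))

#' Generate substrates with conserved residues at chosen subpockets
#'
#' Every record carries the mapped residue at each mapped subpocket
#' (`S_i = 0` there); unmapped subpockets are filled with draws from
#' `fill`. With `position_map` covering all 8 slots this degenerates to a
#' single repeated substrate window, the S_cleavage = 0 endpoint.
#'
#' @param position_map named character vector, subpocket name -> residue,
#'   e.g. `c(P1 = "K")`.
#' @param n number of records.
#' @param fill background [load_abundance()] table for unmapped slots.
#' @param seed RNG seed; the caller's RNG state is left untouched.
#' @param protease_id identifier stamped on every record.
#' @return a `cleavage_records` data frame.
#' @export
#' @examples
#' r <- generate_conserved(c(P1 = "K"), n = 50, seed = 7)
#' compute_profile(r, bg = load_abundance("uniform"))$S_i[["P1"]]
generate_conserved <- function(position_map, n,
                               fill = load_abundance("uniform"),
                               seed = 1L, protease_id = "synthetic") {
  stopifnot(n >= 1L, length(position_map) >= 1L)
  pos <- match.arg(names(position_map), SUBPOCKETS, several.ok = TRUE)
  if (length(pos) != length(position_map) || anyDuplicated(pos))
    cleavent_stop("position_map must be named by distinct subpockets",
                  "cleavent_argument_error")
  if (!all(position_map %in% AA_RESIDUES))
    cleavent_stop("position_map residues must be canonical one-letter codes",
                  "cleavent_argument_error")
  f <- validate_abundance(stats::setNames(as.numeric(fill), names(fill)))
  with_seed(seed, {
    mat <- matrix(NA_character_, n, 8L)
    for (k in seq_len(8L)) {
      sp <- SUBPOCKETS[k]
      mat[, k] <- if (sp %in% pos) position_map[[match(sp, pos)]]
                  else sample(names(f), n, replace = TRUE, prob = f)
    }
    records_from_matrix(mat, protease_id)
  })
}

#' Generate background-distributed substrates
#'
#' Every subpocket follows the background abundance independently. In
#' `expected_counts` mode each column's residue counts are exactly
#' proportional to `bg` (largest-remainder allocation), so after abundance
#' normalization every column is uniform and every `S_i` is exactly 1 --
#' the S_cleavage = 8 endpoint.
#'
#' @param n number of records (>= 20 in expected-counts mode so the
#'   allocation error of at most 1 per residue is controlled).
#' @param bg background [load_abundance()] table.
#' @param mode `"sampled"` or `"expected_counts"`.
#' @inheritParams generate_conserved
#' @return a `cleavage_records` data frame.
#' @export
generate_background <- function(n, bg = load_abundance("uniform"),
                                mode = "sampled", seed = 1L,
                                protease_id = "synthetic") {
  mode <- check_mode(mode)
  stopifnot(n >= 1L)
  if (mode == "expected_counts" && n < 20L)
    cleavent_stop("expected_counts mode needs n >= 20", "cleavent_argument_error")
  f <- validate_abundance(stats::setNames(as.numeric(bg), names(bg)))
  with_seed(seed, {
    mat <- vapply(seq_len(8L), function(k) column_draw(n, f, mode),
                  character(n))
    records_from_matrix(matrix(mat, nrow = n), protease_id)
  })
}

#' Generate substrates with two perfectly coupled subpockets
#'
#' The residue at subpocket `i` is uniform over the 20 amino acids and the
#' residue at `j` is its image under a fixed bijection, giving uniform
#' marginals (S_i = S_j = 1 under uniform background) but only 20 occupied
#' cells of the 400-cell joint table: S_ij = log(20)/log(400) = 0.5 in
#' expected-counts mode. Remaining subpockets are uniform and independent.
#'
#' @param i,j distinct subpocket names.
#' @param bijection named character vector permuting the 20 residues
#'   (default: cyclic shift by one alphabet position).
#' @inheritParams generate_background
#' @return a `cleavage_records` data frame.
#' @export
generate_coupled_pair <- function(i, j, bijection = NULL, n = 12000L,
                                  mode = "sampled", seed = 1L,
                                  protease_id = "synthetic") {
  mode <- check_mode(mode)
  i <- match.arg(i, SUBPOCKETS); j <- match.arg(j, SUBPOCKETS)
  if (identical(i, j))
    cleavent_stop("subpockets i and j must differ", "cleavent_argument_error")
  if (is.null(bijection))
    bijection <- stats::setNames(AA_RESIDUES[c(2:20, 1)], AA_RESIDUES)
  if (!setequal(names(bijection), AA_RESIDUES) ||
      !setequal(unname(bijection), AA_RESIDUES))
    cleavent_stop("bijection must be a permutation of the 20 residues",
                  "cleavent_argument_error")
  uni <- stats::setNames(rep(1 / 20, 20), AA_RESIDUES)
  with_seed(seed, {
    a <- column_draw(n, uni, mode)
    mat <- matrix(NA_character_, n, 8L)
    for (k in seq_len(8L)) {
      sp <- SUBPOCKETS[k]
      mat[, k] <- if (sp == i) a else if (sp == j) unname(bijection[a])
                  else column_draw(n, uni, mode)
    }
    records_from_matrix(mat, protease_id)
  })
}

#' Generate substrates whose joint pair distribution is the independence
#' product of the background
#'
#' For one chosen subpocket pair, allocates the 400 joint cell counts
#' exactly proportional to `f_a * f_b` (largest-remainder over cells, ties
#' by alphabet order of the pair), the expected-by-chance joint under the
#' background: its pairwise entropy is exactly 1. Other subpockets are
#' drawn from `bg`. In `"sampled"` mode pairs are drawn i.i.d. from the
#' product instead.
#'
#' @inheritParams generate_coupled_pair
#' @param bg background [load_abundance()] table.
#' @return a `cleavage_records` data frame.
#' @export
generate_independent_pair <- function(i, j, n = 12000L,
                                      bg = load_abundance("uniform"),
                                      mode = "expected_counts", seed = 1L,
                                      protease_id = "synthetic") {
  mode <- check_mode(mode)
  i <- match.arg(i, SUBPOCKETS); j <- match.arg(j, SUBPOCKETS)
  if (identical(i, j))
    cleavent_stop("subpockets i and j must differ", "cleavent_argument_error")
  f <- validate_abundance(stats::setNames(as.numeric(bg), names(bg)))
  cells <- expand.grid(b = AA_RESIDUES, a = AA_RESIDUES,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$a, cells$b), c("a", "b")]  # alphabet tie order
  w <- f[cells$a] * f[cells$b]
  with_seed(seed, {
    if (mode == "expected_counts") {
      alloc <- allocate_counts(n, w)
      idx <- sample(rep.int(seq_len(400L), alloc))
    } else {
      idx <- sample(seq_len(400L), n, replace = TRUE, prob = w)
    }
    mat <- matrix(NA_character_, n, 8L)
    for (k in seq_len(8L)) {
      sp <- SUBPOCKETS[k]
      mat[, k] <- if (sp == i) cells$a[idx] else if (sp == j) cells$b[idx]
                  else sample(names(f), n, replace = TRUE, prob = f)
    }
    records_from_matrix(mat, protease_id)
  })
}

#' Generate a motif/background substrate mixture
#'
#' A fraction `q` of records carry a conserved motif (the synthetic
#' analogue of, say, trypsin's basic-residue preference at P1); the rest
#' are background draws. Motif-position entropy decreases monotonically in
#' `q`, from the background value at q = 0 to 0 at q = 1.
#'
#' @param motif named character vector, subpocket -> residue (as in
#'   [generate_conserved()]).
#' @param q motif fraction in \[0, 1\]; expected-counts mode allocates
#'   `round-to-largest-remainder(n * q)` motif records exactly.
#' @inheritParams generate_background
#' @return a `cleavage_records` data frame.
#' @export
generate_motif_mixture <- function(motif, q, n, bg = load_abundance("uniform"),
                                   mode = "sampled", seed = 1L,
                                   protease_id = "synthetic") {
  mode <- check_mode(mode)
  stopifnot(q >= 0, q <= 1, n >= 1L)
  f <- validate_abundance(stats::setNames(as.numeric(bg), names(bg)))
  with_seed(seed, {
    n_motif <- if (mode == "expected_counts")
      allocate_counts(n, c(motif = q, background = 1 - q))[["motif"]]
    else stats::rbinom(1L, n, q)
    parts <- list()
    if (n_motif > 0)
      parts$motif <- generate_conserved(motif, n_motif, fill = f,
                                        seed = NULL, protease_id = protease_id)
    if (n - n_motif > 0)
      parts$bg <- generate_background(n - n_motif, f, mode = mode,
                                      seed = NULL, protease_id = protease_id)
    df <- do.call(rbind, unname(parts))
    out <- df[sample(nrow(df)), , drop = FALSE]
    new_cleavage_records(out)
  })
}

#' Write cleavage records as a TSV cleavage table
#'
#' Emits the window-column dialect [read_cleavage_table()] reads, preceded
#' by `#`-prefixed provenance header lines (generator spec, seed, ...).
#' Identical provenance plus identical records give byte-identical files.
#'
#' @param records a `cleavage_records` data frame.
#' @param path output file.
#' @param provenance named list echoed into the header.
#' @return `path`, invisibly.
#' @export
write_cleavage_table <- function(records, path, provenance = list()) {
  stopifnot(is.data.frame(records), all(SUBPOCKETS %in% names(records)))
  hdr <- character(0)
  if (length(provenance))
    hdr <- sprintf("# %s: %s", names(provenance),
                   vapply(provenance, function(v) paste(format(v), collapse = ","),
                          character(1)))
  body <- c(paste(c("protease_id", SUBPOCKETS), collapse = "\t"),
            do.call(paste, c(records[c("protease_id", SUBPOCKETS)],
                             list(sep = "\t"))))
  writeLines(c(hdr, body), path)
  invisible(path)
}
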