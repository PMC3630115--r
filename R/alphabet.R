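# Amino-acid alphabet and background abundance tables.

#' Canonical amino-acid alphabet
#'
#' The fixed 20-letter alphabet over which all entropies are defined, plus
#' the gap symbol used for window positions beyond a substrate's terminus
#' and the set of ambiguity/non-standard codes treated as unresolved.
#' Gap and unknown slots are excluded per position when tallying; they are
#' never assigned a background abundance.
#'
#' @param gap_symbol single character marking an unoccupied window slot.
#' @param unknown_symbols characters treated as unresolved residues.
#' @return an object of class `aa_alphabet`: list with `residues`,
#'   `gap_symbol`, `unknown_symbols`.
#' @export
#' @examples
#' aa_alphabet()$residues
aa_alphabet <- function(gap_symbol = "-",
                        unknown_symbols = c("X", "B", "Z", "J", "U", "O")) {
  stopifnot(is.character(gap_symbol), length(gap_symbol) == 1L,
            nchar(gap_symbol) == 1L)
  unknown_symbols <- toupper(unknown_symbols)
  if (gap_symbol %in% AA_RESIDUES || any(unknown_symbols %in% AA_RESIDUES))
    cleavent_stop("gap/unknown symbols must be disjoint from the 20 canonical residues",
                  "cleavent_alphabet_error")
  if (toupper(gap_symbol) %in% unknown_symbols)
    cleavent_stop("gap symbol collides with an unknown symbol",
                  "cleavent_alphabet_error")
  structure(list(residues = AA_RESIDUES, gap_symbol = gap_symbol,
                 unknown_symbols = unknown_symbols),
            class = "aa_alphabet")
}

validate_abundance <- function(freq, where = "abundance table") {
  if (is.null(names(freq)) || any(!nzchar(names(freq))))
    cleavent_stop(sprintf("%s: all rows must be named by residue", where),
                  "cleavent_abundance_error")
  names(freq) <- toupper(names(freq))
  extra <- setdiff(names(freq), AA_RESIDUES)
  if (length(extra))
    cleavent_stop(sprintf("%s: unknown residue code(s): %s", where,
                          paste(extra, collapse = ", ")),
                  "cleavent_abundance_error")
  missing <- setdiff(AA_RESIDUES, names(freq))
  if (length(missing))
    cleavent_stop(sprintf("%s: missing residue(s): %s", where,
                          paste(missing, collapse = ", ")),
                  "cleavent_abundance_error")
  if (anyDuplicated(names(freq)))
    cleavent_stop(sprintf("%s: duplicated residue row(s): %s", where,
                          paste(unique(names(freq)[duplicated(names(freq))]),
                                collapse = ", ")),
                  "cleavent_abundance_error")
  bad <- names(freq)[!is.finite(freq) | freq <= 0]
  if (length(bad))
    cleavent_stop(sprintf("%s: non-positive frequency for residue(s): %s",
                          where, paste(bad, collapse = ", ")),
                  "cleavent_abundance_error")
  freq <- freq[AA_RESIDUES]
  freq / sum(freq)
}

#' Load a background amino-acid abundance table
#'
#' Abundance normalization is what makes a cleavage entropy of 1 mean
#' "indistinguishable from background" rather than "uniform over the
#' alphabet": observed counts are divided by these frequencies before the
#' per-subpocket renormalization.
#'
#' @param source one of:
#'   \describe{
#'     \item{`"mccaldon"`}{the packaged natural-abundance table transcribed
#'       from McCaldon & Argos (1988), Proteins 4:99-122 (the default).}
#'     \item{`"uniform"`}{1/20 per residue; turns abundance normalization
#'       into a no-op, used by the analytic test fixtures.}
#'     \item{a file path}{two-column delimited text with header
#'       `residue<TAB>frequency` (comma also accepted).}
#'   }
#' @return an `abundance_table`: named numeric vector over the 20 canonical
#'   residues in alphabet order, strictly positive, summing to 1 (input
#'   frequencies are renormalized).
#' @export
#' @examples
#' load_abundance("uniform")["K"]
load_abundance <- function(source = "mccaldon") {
  stopifnot(is.character(source), length(source) == 1L)
  if (identical(source, "uniform")) {
    freq <- stats::setNames(rep(1 / 20, 20), AA_RESIDUES)
  } else {
    path <- if (identical(source, "mccaldon")) {
      system.file("extdata", "abundance_mccaldon.tsv", package = "cleavent",
                  mustWork = TRUE)
    } else source
    if (!file.exists(path))
      cleavent_stop(sprintf("abundance table not found: %s", path),
                    "cleavent_abundance_error")
    tab <- utils::read.table(path, header = TRUE, sep = "",
                             colClasses = c("character", "numeric"),
                             comment.char = "#", strip.white = TRUE)
    if (ncol(tab) < 2L)
      cleavent_stop("abundance table must have columns residue, frequency",
                    "cleavent_abundance_error")
    freq <- stats::setNames(tab[[2L]], tab[[1L]])
  }
  freq <- validate_abundance(freq, where = paste0("abundance '", source, "'"))
  structure(freq, class = c("abundance_table", "numeric"), source = source)
}

#' Write an abundance table to delimited text
#'
#' Emits the two-column `residue`/`frequency` dialect [load_abundance()]
#' reads; the round trip is the identity up to 1e-12.
#'
#' @param abundance an `abundance_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(abundance, path) {
  freq <- validate_abundance(stats::setNames(as.numeric(abundance),
                                             names(abundance)))
  df <- data.frame(residue = names(freq),
                   frequency = format(unname(freq), digits = 17))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Background amino-acid abundance (source: %s)\n",
              attr(x, "source") %||% "user"))
  print(round(unclass(x), 4), ...)
  invisible(x)
}
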