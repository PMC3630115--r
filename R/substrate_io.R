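# Cleavage-site table parsing and per-protease count matrices.

#' Parse one 8-residue substrate window
#'
#' A window spans the eight subpockets P4..P4' with the scissile bond
#' between positions 4 and 5 (P1 | P1'). Lowercase input is accepted and
#' uppercased; the gap symbol marks positions beyond a substrate terminus
#' and ambiguity codes are kept as-is (both are excluded per position by
#' the downstream tally).
#'
#' @param text 8-character string.
#' @param alphabet an [aa_alphabet()].
#' @return named character vector of length 8 (names `subpockets()`).
#' @export
#' @examples
#' parse_window("ADGKLMNP")[["P1"]]
#' parse_window("---KLM--")
parse_window <- function(text, alphabet = aa_alphabet()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || nchar(text) != 8L)
    cleavent_stop(sprintf("window '%s' must be exactly 8 characters, got %d",
                          text, nchar(text)), "cleavent_parse_error")
  chars <- toupper(strsplit(text, "", fixed = TRUE)[[1L]])
  legal <- c(alphabet$residues, alphabet$gap_symbol, alphabet$unknown_symbols)
  bad <- which(!(chars %in% legal))
  if (length(bad))
    cleavent_stop(sprintf("window '%s': illegal character '%s' at position %d",
                          text, chars[bad[1L]], bad[1L]),
                  "cleavent_parse_error")
  if (!any(chars %in% alphabet$residues))
    cleavent_stop(sprintf("window '%s' holds no canonical residue", text),
                  "cleavent_parse_error")
  stats::setNames(chars, SUBPOCKETS)
}

# Map the column-name spellings in the wild (P1', P1′, P1prime, p1p)
# onto the canonical ASCII names.
normalize_subpocket_names <- function(nms) {
  key <- toupper(gsub("′|'", "P", trimws(nms)))
  key <- sub("PRIME$", "P", key)
  sub("^P([1-4])P$", "P\\1p", key)
}

new_cleavage_records <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("cleavage_records", "data.frame")
  df
}

#' Read a cleavage-site table
#'
#' Accepts the two dialects of delimited text (TSV or CSV, UTF-8, `#`
#' comment lines allowed): either a `protease_id` column plus one `window`
#' column of 8-character strings, or `protease_id` plus eight single-letter
#' columns named `P4,P3,P2,P1,P1',P2',P3',P4'` (primes may be spelled
#' `p`/`prime`/Unicode prime). Input row order is preserved.
#'
#' @param path input file.
#' @param mode `"strict"` (default) fails on the first set of malformed
#'   rows, reporting line numbers; `"permissive"` warns, records them in
#'   the `"skipped"` attribute and drops them.
#' @param alphabet an [aa_alphabet()].
#' @return a `cleavage_records` data frame: `protease_id` plus the eight
#'   subpocket columns.
#' @export
read_cleavage_table <- function(path, mode = c("strict", "permissive"),
                                alphabet = aa_alphabet()) {
  mode <- match.arg(mode)
  if (!file.exists(path))
    cleavent_stop(sprintf("cleavage table not found: %s", path),
                  "cleavent_format_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  content <- grep("^\\s*#", lines, invert = TRUE)
  content <- content[nzchar(trimws(lines[content]))]
  if (!length(content))
    cleavent_stop(sprintf("cleavage table is empty: %s", path),
                  "cleavent_format_error")
  sep <- if (grepl("\t", lines[content[1L]], fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(text = lines[content], header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, quote = "")
  names(tab) <- ifelse(tolower(names(tab)) %in% c("protease_id", "window"),
                       tolower(names(tab)),
                       normalize_subpocket_names(names(tab)))
  if (!"protease_id" %in% names(tab))
    cleavent_stop("cleavage table must contain a 'protease_id' column",
                  "cleavent_format_error")
  has_window <- "window" %in% names(tab)
  has_cols <- all(SUBPOCKETS %in% names(tab))
  if (!has_window && !has_cols)
    cleavent_stop("cleavage table needs a 'window' column or all eight P4..P4' columns",
                  "cleavent_format_error")
  # original file line of each data row, for error reporting
  src_line <- content[-1L][seq_len(nrow(tab))]

  windows <- if (has_window) tab$window else
    apply(as.matrix(tab[SUBPOCKETS]), 1L, paste0, collapse = "")
  parsed <- vector("list", length(windows))
  errs <- character(0)
  for (r in seq_along(windows)) {
    parsed[[r]] <- tryCatch(parse_window(windows[[r]], alphabet),
                            cleavent_parse_error = function(e) {
                              errs[[length(errs) + 1L]] <<-
                                sprintf("line %d: %s", src_line[r], conditionMessage(e))
                              NULL
                            })
  }
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad)) {
    report <- paste(errs, collapse = "\n  ")
    if (mode == "strict")
      cleavent_stop(sprintf("%d malformed row(s) in %s:\n  %s",
                            sum(bad), path, report), "cleavent_parse_error")
    warning(sprintf("skipped %d malformed row(s) in %s:\n  %s",
                    sum(bad), path, report), call. = FALSE)
  }
  keep <- !bad
  mat <- do.call(rbind, parsed[keep])
  df <- data.frame(protease_id = tab$protease_id[keep],
                   as.data.frame(mat, stringsAsFactors = FALSE))
  names(df) <- c("protease_id", SUBPOCKETS)
  out <- new_cleavage_records(df)
  attr(out, "skipped") <- errs
  out
}

#' Build the 20 x 8 occurrence-count matrix for one protease
#'
#' `counts[a, i]` is the number of records carrying canonical residue `a`
#' at subpocket `i`. Gap and ambiguity slots contribute to no residue, so
#' each subpocket has its own effective total (`column_totals[i] <=
#' n_records`); a whole record is never discarded for a single gap.
#'
#' @param records a `cleavage_records` data frame.
#' @param protease_id protease to tally; may be omitted when `records`
#'   holds a single protease.
#' @param alphabet an [aa_alphabet()].
#' @return a `count_matrix`: list with `protease_id`, `counts` (20 x 8
#'   integer), `column_totals`, `n_records`.
#' @export
build_count_matrix <- function(records, protease_id = NULL,
                               alphabet = aa_alphabet()) {
  stopifnot(is.data.frame(records), all(SUBPOCKETS %in% names(records)))
  if (is.null(protease_id)) {
    ids <- unique(records$protease_id)
    if (length(ids) != 1L)
      cleavent_stop("records hold several proteases; pass protease_id",
                    "cleavent_input_error")
    protease_id <- ids
  } else {
    records <- records[records$protease_id == protease_id, , drop = FALSE]
  }
  if (!nrow(records))
    cleavent_stop(sprintf("no records for protease '%s'", protease_id),
                  "cleavent_empty_input")
  counts <- vapply(SUBPOCKETS, function(s) {
    tabulate(factor(records[[s]], levels = alphabet$residues), nbins = 20L)
  }, integer(20))
  dimnames(counts) <- list(alphabet$residues, SUBPOCKETS)
  structure(list(protease_id = protease_id, counts = counts,
                 column_totals = colSums(counts), n_records = nrow(records)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Cleavage count matrix: %s (%d records)\n",
              x$protease_id, x$n_records))
  cat("effective per-subpocket totals:\n")
  print(x$column_totals)
  invisible(x)
}

#' Select proteases with enough substrates
#'
#' Applies the minimum-substrate-count filter (100 in the original
#' analysis) and an explicit-identifier exclusion list (the route by which
#' methionyl aminopeptidases, whose P4-P2 slots are systematically
#' unoccupied, are removed).
#'
#' @param records a `cleavage_records` data frame over any number of
#'   proteases.
#' @param min_substrates inclusive lower bound on per-protease record
#'   count; default 100.
#' @param exclude_ids protease identifiers dropped regardless of count.
#' @return list with `records` (the retained rows) and `selection`, a log
#'   data frame with one row per input protease: `protease_id`,
#'   `n_records`, `included`, `reason`.
#' @export
filter_proteases <- function(records, min_substrates = 100L,
                             exclude_ids = character(0)) {
  stopifnot(min_substrates >= 1L)
  tab <- table(records$protease_id)
  ids <- names(tab)
  n <- as.integer(tab)
  excluded <- ids %in% exclude_ids
  too_few <- n < min_substrates
  included <- !excluded & !too_few
  reason <- ifelse(excluded, "excluded_id",
                   ifelse(too_few,
                          sprintf("below_min_substrates(%d)", min_substrates),
                          ""))
  sel <- data.frame(protease_id = ids, n_records = n,
                    included = included, reason = reason)
  sel <- sel[order(sel$protease_id), , drop = FALSE]
  rownames(sel) <- NULL
  keep <- records$protease_id %in% ids[included]
  list(records = new_cleavage_records(records[keep, , drop = FALSE]),
       selection = sel)
}
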