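# Small fixture builders shared across test files.

# Records with every window identical.
constant_records <- function(window = "ADGKLMNP", n = 10, id = "const") {
  w <- strsplit(window, "")[[1]]
  df <- data.frame(protease_id = id,
                   matrix(rep(w, each = n), nrow = n),
                   stringsAsFactors = FALSE)
  names(df) <- c("protease_id", SP8)
  df
}

# Write records to a temp TSV in the window-string dialect.
tmp_table <- function(records, dialect = c("window", "columns"), sep = "\t") {
  dialect <- match.arg(dialect)
  path <- tempfile(fileext = ".tsv")
  if (dialect == "window") {
    df <- data.frame(protease_id = records$protease_id,
                     window = apply(as.matrix(records[SP8]), 1, paste0,
                                    collapse = ""))
  } else {
    df <- records[c("protease_id", SP8)]
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# A tiny abundance table file.
tmp_abundance <- function(freq) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("residue\tfrequency",
               paste(names(freq), freq, sep = "\t")), path)
  path
}

uniform_bg <- function() load_abundance("uniform")

# Fresh temp directory per test block (no withr dependency).
withr_like_tempdir <- function() {
  d <- tempfile("cleavent-test-")
  dir.create(d)
  d
}
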