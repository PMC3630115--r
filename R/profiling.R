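# Downstream profiling: classification at the standard entropy cutoffs,
# ranking by total cleavage entropy, group summaries, and the
# count-vs-entropy diagnostic correlations.

#' Classify a subpocket entropy
#'
#' Standard color-coding cutoffs: subpockets with S_i equal to or below
#' 0.85 count as specific ("yellow"), those strictly below 0.5 as highly
#' specific ("red"). Note the asymmetric boundary semantics, which follow
#' the conventional definitions literally: 0.85 is inclusive, 0.5 is not.
#'
#' @param S_i numeric vector of subpocket entropies in \[0, 1\].
#' @param yellow_cutoff inclusive upper bound for "specific"; default 0.85.
#' @param red_cutoff exclusive upper bound for "highly_specific"; default 0.5.
#' @return character vector of labels: `highly_specific`, `specific`,
#'   `unspecific`.
#' @export
#' @examples
#' classify_subpocket(c(0.455, 0.85, 0.95))
classify_subpocket <- function(S_i, yellow_cutoff = 0.85, red_cutoff = 0.5) {
  if (any(!is.na(S_i) & (S_i < -1e-12 | S_i > 1 + 1e-12)))
    cleavent_stop("subpocket entropy outside [0, 1]", "cleavent_contract_error")
  ifelse(is.na(S_i), NA_character_,
         ifelse(S_i < red_cutoff, "highly_specific",
                ifelse(S_i <= yellow_cutoff, "specific", "unspecific")))
}

#' Classify a total cleavage entropy
#'
#' Protease-level cutoffs on the 0-8 scale: S_cleavage < 6.8 (an average
#' subpocket entropy of 0.85) is specific, S_cleavage < 4.0 (average below
#' 0.5) highly specific. Both bounds are strict.
#'
#' @param S_cleavage numeric vector of total cleavage entropies in \[0, 8\].
#' @param specific_cutoff strict upper bound for "specific"; default 6.8.
#' @param highly_cutoff strict upper bound for "highly_specific"; default 4.0.
#' @return character vector of labels.
#' @export
#' @examples
#' classify_protease(c(7.528, 2.932, 6.8))
classify_protease <- function(S_cleavage, specific_cutoff = 6.8,
                              highly_cutoff = 4.0) {
  if (any(!is.na(S_cleavage) &
          (S_cleavage < -1e-12 | S_cleavage > 8 + 1e-12)))
    cleavent_stop("total cleavage entropy outside [0, 8]",
                  "cleavent_contract_error")
  ifelse(is.na(S_cleavage), NA_character_,
         ifelse(S_cleavage < highly_cutoff, "highly_specific",
                ifelse(S_cleavage < specific_cutoff, "specific",
                       "unspecific")))
}

# Collapse a list of specificity_profile objects into one table row each.
profiles_to_df <- function(profiles) {
  if (inherits(profiles, "specificity_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) > 0,
            all(vapply(profiles, inherits, logical(1), "specificity_profile")))
  S <- t(vapply(profiles, function(p) p$S_i, numeric(8)))
  colnames(S) <- paste0("S_", SUBPOCKETS)
  data.frame(protease_id = vapply(profiles, `[[`, character(1), "protease_id"),
             S,
             S_cleavage = vapply(profiles, `[[`, numeric(1), "S_cleavage"),
             n_subpockets = vapply(profiles, `[[`, numeric(1), "n_subpockets"),
             n_records = vapply(profiles, `[[`, numeric(1), "n_records"))
}

#' Rank proteases by total cleavage entropy
#'
#' Stable sort (ascending by default, most specific first); ties broken
#' lexicographically by protease identifier for reproducibility.
#'
#' @param profiles list of [compute_profile()] results.
#' @param order `"ascending"` or `"descending"`.
#' @param allow_partial permit profiles whose total covers fewer than 8
#'   subpockets; refused by default because partial totals are not
#'   comparable on the 0-8 scale.
#' @return data frame with `rank`, `protease_id`, the eight `S_*` columns,
#'   `S_cleavage`, `n_subpockets`, `n_records`.
#' @export
rank_proteases <- function(profiles, order = c("ascending", "descending"),
                           allow_partial = FALSE) {
  order <- match.arg(order)
  if (length(profiles) == 0L)
    return(data.frame(rank = integer(0), protease_id = character(0)))
  df <- profiles_to_df(profiles)
  if (!allow_partial && any(df$n_subpockets < 8))
    cleavent_stop("partial totals present; pass allow_partial = TRUE",
                  "cleavent_contract_error")
  o <- order(df$S_cleavage, df$protease_id,
             decreasing = c(order == "descending", FALSE), method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  cbind(rank = seq_len(nrow(df)), df)
}

#' Per-group summary statistics of cleavage entropies
#'
#' Summarizes S_cleavage and every subpocket entropy per user-supplied
#' group (catalytic type, structural clan, ...): mean, min, max, standard
#' deviation and member count, the statistics behind family-level
#' specificity comparisons.
#'
#' @param profiles list of [compute_profile()] results.
#' @param grouping named character vector mapping every `protease_id` to a
#'   group key.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`;
#'   a group of one member reports sd 0 (see `n` column).
#' @return data frame with one row per group x metric (`S_cleavage`,
#'   `S_P4` ... `S_P4p`): `group`, `metric`, `n`, `mean`, `min`, `max`, `sd`.
#' @export
group_summary <- function(profiles, grouping,
                          sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  df <- profiles_to_df(profiles)
  unmapped <- setdiff(df$protease_id, names(grouping))
  if (length(unmapped))
    cleavent_stop(sprintf("protease(s) missing from grouping: %s",
                          paste(unmapped, collapse = ", ")),
                  "cleavent_input_error")
  df$group <- unname(grouping[df$protease_id])
  metrics <- c("S_cleavage", paste0("S_", SUBPOCKETS))
  sd_fun <- function(v) {
    if (length(v) < 2L) return(0)
    s <- stats::sd(v)
    if (sd_type == "population") s * sqrt((length(v) - 1) / length(v)) else s
  }
  out <- do.call(rbind, lapply(sort(unique(df$group)), function(g) {
    sub <- df[df$group == g, , drop = FALSE]
    do.call(rbind, lapply(metrics, function(m) {
      v <- sub[[m]]
      data.frame(group = g, metric = m, n = length(v), mean = mean(v),
                 min = min(v), max = max(v), sd = sd_fun(v))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Correlation between total cleavage entropy and substrate count
#'
#' The diagnostic showing that cleavage entropy carries information beyond
#' sheer database coverage: Pearson r-squared and Spearman rank correlation
#' (average ranks on ties) between S_cleavage and the number of known
#' substrates per protease. Descriptive only; no p-values.
#'
#' @param profiles list of [compute_profile()] results (>= 3).
#' @param substrate_counts named numeric vector of substrate counts; names
#'   must cover every profiled protease. Defaults to each profile's own
#'   `n_records`.
#' @return list with `r_squared`, `spearman`, `n`. A constant vector on
#'   either side raises a `cleavent_undefined_correlation` condition
#'   rather than returning a number.
#' @export
count_correlation <- function(profiles, substrate_counts = NULL) {
  df <- profiles_to_df(profiles)
  if (is.null(substrate_counts))
    substrate_counts <- stats::setNames(df$n_records, df$protease_id)
  missing <- setdiff(df$protease_id, names(substrate_counts))
  if (length(missing))
    cleavent_stop(sprintf("no substrate count for: %s",
                          paste(missing, collapse = ", ")),
                  "cleavent_input_error")
  x <- df$S_cleavage
  y <- as.numeric(substrate_counts[df$protease_id])
  if (length(x) < 3L)
    cleavent_stop("need at least 3 proteases for correlations",
                  "cleavent_input_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    cleavent_stop("correlation undefined: constant values on one side",
                  "cleavent_undefined_correlation")
  list(r_squared = stats::cor(x, y)^2,
       spearman = stats::cor(x, y, method = "spearman"),
       n = length(x))
}
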