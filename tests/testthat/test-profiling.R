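# Profiles used below don't need real data: build minimal stand-in
# specificity_profile objects directly.
fake_profile <- function(id, S_i, n = 500) {
  structure(list(protease_id = id,
                 S_i = setNames(S_i, SP8),
                 S_cleavage = sum(S_i), n_subpockets = sum(!is.na(S_i)),
                 column_totals = setNames(rep(n, 8), SP8), n_records = n),
            class = "specificity_profile")
}

test_that("subpocket classification follows the caption boundary semantics", {
  expect_identical(classify_subpocket(0.455), "highly_specific")
  expect_identical(classify_subpocket(0.5), "specific")      # red bound strict
  expect_identical(classify_subpocket(0.85), "specific")     # yellow inclusive
  expect_identical(classify_subpocket(0.95), "unspecific")
  expect_identical(classify_subpocket(c(0, 1)),
                   c("highly_specific", "unspecific"))
  expect_error(classify_subpocket(1.2), class = "cleavent_contract_error")
})

test_that("protease classification uses strict total-entropy cutoffs", {
  expect_identical(classify_protease(7.528), "unspecific")
  expect_identical(classify_protease(2.932), "highly_specific")
  expect_identical(classify_protease(6.8), "unspecific")     # strict <
  expect_identical(classify_protease(4.0), "specific")       # strict <
  expect_identical(classify_protease(6.79), "specific")
  expect_error(classify_protease(8.5), class = "cleavent_contract_error")
})

test_that("classification thresholds are monotone and configurable", {
  S <- seq(0, 1, by = 0.05)
  l1 <- classify_subpocket(S, yellow_cutoff = 0.7)
  l2 <- classify_subpocket(S, yellow_cutoff = 0.9)
  # raising the yellow cutoff never turns a specific label unspecific
  expect_false(any(l1 == "specific" & l2 == "unspecific"))
  expect_identical(classify_protease(5, specific_cutoff = 4.5), "unspecific")
})

test_that("ranking sorts ascending with lexicographic tie-break", {
  ps <- list(fake_profile("B", rep(7.5 / 8, 8)),
             fake_profile("A", rep(4.5 / 8, 8)),
             fake_profile("C", rep(6.0 / 8, 8)))
  r <- rank_proteases(ps)
  expect_identical(r$protease_id, c("A", "C", "B"))
  expect_identical(r$rank, 1:3)
  # tie rule
  tie <- rank_proteases(list(fake_profile("B", rep(0.625, 8)),
                             fake_profile("A", rep(0.625, 8))))
  expect_identical(tie$protease_id, c("A", "B"))
  # permutation of input, idempotent
  expect_setequal(r$protease_id, c("A", "B", "C"))
  desc <- rank_proteases(ps, order = "descending")
  expect_identical(desc$protease_id, rev(r$protease_id))
  expect_identical(nrow(rank_proteases(list())), 0L)
  # partial totals refused without the flag
  pp <- fake_profile("D", c(rep(0.5, 7), NA))
  pp$S_cleavage <- 3.5; pp$n_subpockets <- 7
  expect_error(rank_proteases(list(pp)), class = "cleavent_contract_error")
  expect_equal(nrow(rank_proteases(list(pp), allow_partial = TRUE)), 1)
})

test_that("group summaries match direct recomputation", {
  ps <- list(fake_profile("a1", rep(0.5, 8)),
             fake_profile("a2", rep(0.75, 8)),
             fake_profile("b1", rep(0.25, 8)))
  g <- c(a1 = "ser", a2 = "ser", b1 = "met")
  gs <- group_summary(ps, g)
  ser_total <- gs[gs$group == "ser" & gs$metric == "S_cleavage", ]
  expect_equal(ser_total$mean, mean(c(4, 6)))
  expect_equal(ser_total$min, 4); expect_equal(ser_total$max, 6)
  expect_equal(ser_total$sd, sd(c(4, 6)), tolerance = 1e-12)
  expect_equal(ser_total$n, 2)
  # single-member group: sd reported as 0 with n = 1
  met_total <- gs[gs$group == "met" & gs$metric == "S_cleavage", ]
  expect_equal(met_total$sd, 0); expect_equal(met_total$n, 1)
  expect_equal(met_total$mean, met_total$min)
  # population sd option
  gp <- group_summary(ps, g, sd_type = "population")
  expect_equal(gp[gp$group == "ser" & gp$metric == "S_cleavage", "sd"],
               sd(c(4, 6)) * sqrt(1 / 2), tolerance = 1e-12)
  # regrouping by permuted keys permutes but preserves values
  g2 <- c(a1 = "met", a2 = "met", b1 = "ser")
  gs2 <- group_summary(ps, g2)
  expect_equal(gs2[gs2$group == "met", c("mean", "sd")],
               gs[gs$group == "ser", c("mean", "sd")],
               ignore_attr = TRUE)
  expect_error(group_summary(ps, g[1:2]), "b1",
               class = "cleavent_input_error")
})

test_that("count correlations reproduce hand-computed rank statistics", {
  S <- c(4.2, 5.0, 5.5, 6.1, 7.3)
  counts <- c(120, 800, 150, 4000, 90)
  ps <- lapply(seq_along(S), function(i)
    fake_profile(paste0("p", i), rep(S[i] / 8, 8), n = counts[i]))
  cc <- count_correlation(ps)
  # hand-checkable Spearman: ranks of S are 1..5, ranks of counts 2,4,3,5,1
  rs <- 1 - 6 * sum((1:5 - c(2, 4, 3, 5, 1))^2) / (5 * 24)
  expect_equal(cc$spearman, rs, tolerance = 1e-12)
  expect_equal(cc$r_squared, cor(S, counts)^2, tolerance = 1e-12)
  expect_equal(cc$n, 5)

  # perfect agreement / reversal
  ps2 <- lapply(1:4, function(i) fake_profile(paste0("q", i), rep(i / 8, 8)))
  expect_equal(count_correlation(ps2, setNames(1:4, paste0("q", 1:4))),
               list(r_squared = 1, spearman = 1, n = 4), tolerance = 1e-12)
  expect_equal(count_correlation(ps2, setNames(4:1, paste0("q", 1:4)))$spearman,
               -1, tolerance = 1e-12)

  expect_error(count_correlation(ps2[1:2]), class = "cleavent_input_error")
  expect_error(count_correlation(ps2, setNames(rep(7, 4), paste0("q", 1:4))),
               class = "cleavent_undefined_correlation")
})
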