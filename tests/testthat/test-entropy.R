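test_that("normalize_counts implements divide-then-renormalize", {
  rec <- constant_records("ADGKLMNP", 10)
  m <- build_count_matrix(rec)
  u <- uniform_bg()

  # uniform counts under uniform background -> uniform column
  m10 <- m
  m10$counts[] <- 10L
  m10$column_totals <- colSums(m10$counts)
  p <- normalize_counts(m10, u)
  expect_equal(unname(p$p[, "P1"]), rep(0.05, 20), tolerance = 1e-12)

  # counts proportional to the background cancel exactly under any bg
  mc <- load_abundance("mccaldon")
  mprop <- m
  mprop$counts[] <- matrix(rep(unclass(mc) * 1000, 8), 20)
  p2 <- normalize_counts(mprop, mc)
  expect_equal(unname(p2$p[, "P2"]), rep(0.05, 20), tolerance = 1e-12)

  # direct proportion: (30, 10, 0...) -> (0.75, 0.25, 0...)
  mdir <- m
  mdir$counts[] <- 0L
  mdir$counts["A", ] <- 30L
  mdir$counts["C", ] <- 10L
  p3 <- normalize_counts(mdir, u)
  expect_equal(unname(p3$p[c("A", "C", "D"), "P4"]), c(0.75, 0.25, 0))
  expect_true(all(abs(colSums(p3$p) - 1) < 1e-9))
})

test_that("subpocket entropy hits its analytic endpoints and closed forms", {
  expect_identical(subpocket_entropy(c(1, rep(0, 19))), 0)
  expect_equal(subpocket_entropy(rep(0.05, 20)), 1, tolerance = 1e-12)
  expect_equal(subpocket_entropy(c(0.5, 0.5, rep(0, 18))),
               log(2) / log(20), tolerance = 1e-12)
  # contract errors
  expect_error(subpocket_entropy(rep(0.1, 20)), "sums",
               class = "cleavent_contract_error")
  expect_error(subpocket_entropy(c(-0.1, 1.1, rep(0, 18))),
               class = "cleavent_contract_error")
})

test_that("total entropy sums eight subpockets, partial totals are explicit", {
  expect_identical(total_cleavage_entropy(rep(0, 8)), 0)
  expect_equal(total_cleavage_entropy(rep(1, 8)), 8)
  expect_equal(total_cleavage_entropy(c(rep(0, 4), rep(1, 4))), 4)
  expect_error(total_cleavage_entropy(rep(0.5, 7)),
               class = "cleavent_contract_error")
  S <- c(rep(0.5, 7), NA)
  expect_error(total_cleavage_entropy(S), class = "cleavent_unavailable")
  part <- total_cleavage_entropy(S, partial = TRUE)
  expect_equal(as.numeric(part), 3.5)
  expect_equal(attr(part, "n_subpockets"), 7)
})

test_that("pipeline matches the brute-force oracle on random data (incl. gaps)", {
  set.seed(42)
  for (k in 1:12) {
    rec <- random_records(sample(30:150, 1), p_gap = 0.05, p_unknown = 0.03)
    bg <- if (k %% 2) uniform_bg() else load_abundance("mccaldon")
    prof <- compute_profile(rec, bg = bg)
    for (pos in subpockets()) {
      expect_equal(prof$S_i[[pos]], oracle_subpocket_entropy(rec, pos, bg),
                   tolerance = 1e-12)
    }
    expect_equal(prof$S_cleavage, sum(prof$S_i), tolerance = 1e-12)
  }
})

test_that("entropy bounds and their attainment conditions", {
  set.seed(7)
  for (k in 1:20) {
    p <- stats::runif(20); p <- p / sum(p)
    S <- subpocket_entropy(p)
    expect_gte(S, 0); expect_lte(S, 1 + 1e-12)
  }
  # S = 0 iff a single residue carries all mass
  expect_identical(subpocket_entropy(c(rep(0, 19), 1)), 0)
  expect_gt(subpocket_entropy(c(0.999, 0.001, rep(0, 18))), 0)
  # S = 1 iff uniform
  expect_lt(subpocket_entropy(c(0.06, 0.04, rep(0.05, 18))), 1)
})

test_that("log-base invariance", {
  set.seed(13)
  p <- stats::runif(20); p <- p / sum(p)
  ref <- subpocket_entropy(p)
  expect_equal(subpocket_entropy(p, base = 2), ref, tolerance = 1e-12)
  expect_equal(subpocket_entropy(p, base = 10), ref, tolerance = 1e-12)
  rec <- random_records(80)
  bg <- load_abundance("mccaldon")
  expect_equal(compute_profile(rec, bg = bg, base = 2)$S_i,
               compute_profile(rec, bg = bg)$S_i, tolerance = 1e-12)
})

test_that("count-scale (dataset duplication) invariance", {
  set.seed(21)
  rec <- random_records(70, p_gap = 0.04)
  bg <- load_abundance("mccaldon")
  p1 <- compute_profile(rec, bg = bg)
  p2 <- compute_profile(rbind(rec, rec), "rnd", bg = bg)
  expect_equal(p2$S_i, p1$S_i, tolerance = 1e-12)
  expect_equal(p2$S_cleavage, p1$S_cleavage, tolerance = 1e-12)
})

test_that("label-permutation invariance under uniform abundance", {
  set.seed(31)
  rec <- random_records(90)
  perm <- setNames(sample(AA20), AA20)
  rec2 <- rec
  for (pos in SP8) rec2[[pos]] <- unname(perm[rec[[pos]]])
  u <- uniform_bg()
  expect_equal(compute_profile(rec2, bg = u)$S_i,
               compute_profile(rec, bg = u)$S_i, tolerance = 1e-12)
})

test_that("motif-fraction sweep drives the motif subpocket entropy down", {
  u <- uniform_bg()
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  S <- vapply(qs, function(q) {
    rec <- generate_motif_mixture(c(P2 = "R"), q, n = 2000, bg = u,
                                  mode = "expected_counts", seed = 99)
    compute_profile(rec, bg = u)$S_i[["P2"]]
  }, numeric(1))
  expect_true(all(diff(S) < 0))          # strictly decreasing on this grid
  expect_equal(S[1], 1, tolerance = 1e-12)
  expect_identical(S[5], 0)
  # closed-form check at q = 0.5: p = q e_R + (1-q)/20
  p_mix <- rep(0.5 / 20, 20); p_mix[15] <- p_mix[15] + 0.5  # R is residue 15
  expect_equal(S[3], -sum(p_mix * log(p_mix)) / log(20), tolerance = 1e-12)
})

test_that("region averages split P- and P'-sides", {
  rec <- constant_records(n = 5)
  prof <- compute_profile(rec, bg = uniform_bg())
  prof$S_i <- setNames(c(0, 0, 0, 0, 1, 1, 1, 1), SP8)
  expect_equal(region_average(prof, "P"), 0)
  expect_equal(region_average(prof, "Pprime"), 1)
  prof$S_i <- setNames(c(0.2, 0.4, 0.6, 0.8, rep(0.5, 4)), SP8)
  expect_equal(region_average(prof, "P"), 0.5)
  prof$S_i[["P4"]] <- NA
  expect_error(region_average(prof, "P"), class = "cleavent_unavailable")
})

test_that("unavailable columns are flagged, not silently zero", {
  rec <- constant_records("---KLMNP", 5)   # P4..P2 all gaps
  m <- build_count_matrix(rec)
  p <- normalize_counts(m, uniform_bg())
  expect_false(p$available[["P4"]])
  expect_true(all(is.na(p$p[, "P4"])))
  expect_error(compute_profile(rec, bg = uniform_bg()),
               class = "cleavent_unavailable")
  prof <- compute_profile(rec, bg = uniform_bg(), partial = TRUE)
  expect_equal(prof$n_subpockets, 5)
})
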