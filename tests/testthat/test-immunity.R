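test_that("the scoring rubric maps each phenotype class to its score", {
  expect_equal(score_observation(plate_observation(FALSE)), 0L)
  expect_equal(score_observation(plate_observation(FALSE, spot_titers_with_lysis = 2L)), 1L)
  expect_equal(score_observation(plate_observation(TRUE, eop = 1e-5)), 2L)
  expect_equal(score_observation(plate_observation(FALSE, spot_titers_with_lysis = 3L)), 2L)
  expect_equal(score_observation(plate_observation(TRUE, eop = 1e-2)), 3L)
  expect_equal(score_observation(plate_observation(FALSE, spot_titers_with_lysis = 5L)), 3L)
  expect_equal(score_observation(plate_observation(TRUE, eop = 1, turbidity = "increased")), 4L)
  expect_equal(score_observation(plate_observation(TRUE, eop = 1, plaque_size = "reduced")), 4L)
  expect_equal(score_observation(plate_observation(TRUE, eop = 1)), 5L)
  expect_equal(score_observation(plate_observation(TRUE, eop = 1, turbidity = "reduced")), 6L)
  expect_equal(score_observation(plate_observation(TRUE, eop = 1, plaque_size = "increased")), 6L)
  # inconsistent observation rejected at construction
  expect_error(plate_observation(TRUE), "no EOP")
  # shipped rubric transcription covers scores 0..6
  expect_equal(scoring_rubric()$score, 0:6)
})

test_that("replicate aggregation matches a brute-force group-by", {
  set.seed(41)
  recs <- empty_assay_records()
  for (i in 1:10) {
    recs <- rbind(recs, assay_record(
      sample(c("A", "B", "C"), 1), sample(c("A", "B"), 1), "lysogen",
      sample(0:6, sample(1:4, 1), replace = TRUE)))
  }
  m <- aggregate_replicates(recs)
  oracle <- oracle_aggregate(recs)
  for (kk in names(oracle)) {
    parts <- strsplit(kk, "|", fixed = TRUE)[[1]]
    expect_equal(m$n[parts[1], parts[2]], unname(oracle[[kk]]["n"]))
    expect_equal(m$mean[parts[1], parts[2]], unname(oracle[[kk]]["mean"]))
    expect_equal(m$min[parts[1], parts[2]], unname(oracle[[kk]]["min"]))
    expect_equal(m$max[parts[1], parts[2]], unname(oracle[[kk]]["max"]))
  }
  # single replicate and {0,1}
  m2 <- aggregate_replicates(rbind(
    assay_record("X", "Y", "lysogen", 4L),
    assay_record("X", "Z", "lysogen", c(0L, 1L))))
  expect_equal(m2$mean["X", "Y"], 4)
  expect_equal(m2$max["X", "Y"] - m2$min["X", "Y"], 0)
  expect_equal(m2$mean["X", "Z"], 0.5)
  # permutation invariance of replicate order
  m3a <- aggregate_replicates(assay_record("P", "Q", "lysogen", c(1L, 3L, 5L)))
  m3b <- aggregate_replicates(assay_record("P", "Q", "lysogen", c(5L, 1L, 3L)))
  expect_identical(m3a$mean, m3b$mean)
  # conflicting defender kinds are rejected
  expect_error(aggregate_replicates(rbind(
    assay_record("A", "D", "lysogen", 1L),
    assay_record("B", "D", "CRS", 1L))), "conflicting defender_kind")
})

test_that("reciprocal asymmetry pairs and deltas are correct", {
  recs <- rbind(
    assay_record("A", "B", "lysogen", 5L), assay_record("B", "A", "lysogen", 0L),
    assay_record("A", "C", "lysogen", 3L), assay_record("C", "A", "lysogen", 3L),
    assay_record("B", "C", "lysogen", 2L))  # one direction missing for {B,C}
  m <- aggregate_replicates(recs)
  ra <- reciprocal_asymmetry(m)
  expect_equal(nrow(ra), 2L)
  ab <- ra[ra$phage_a == "A" & ra$phage_b == "B", ]
  expect_equal(ab$delta, 5)
  ac <- ra[ra$phage_a == "A" & ra$phage_b == "C", ]
  expect_equal(ac$delta, 0)
  expect_true(all(ra$delta <= pmax(ra$i_ab, ra$i_ba)))
  expect_equal(attr(ra, "one_directional_excluded"), 1L)
  # fully symmetric matrix: all deltas zero
  sym <- rbind(assay_record("A", "B", "lysogen", 4L),
               assay_record("B", "A", "lysogen", 4L))
  expect_equal(reciprocal_asymmetry(aggregate_replicates(sym))$delta, 0)
})

test_that("profile correlations match the textbook formula", {
  recs <- empty_assay_records()
  scores <- list(A = c(0L, 1L, 2L, 3L), B = c(3L, 2L, 1L, 0L), C = c(0L, 1L, 2L, 3L),
                 D = c(2L, 5L, 1L, 4L))
  defs <- c("A", "B", "C", "W")
  for (ch in names(scores)) for (k in seq_along(defs))
    recs <- rbind(recs, assay_record(ch, defs[k], "lysogen", scores[[ch]][k]))
  m <- aggregate_replicates(recs)
  expect_equal(profile_correlation(m, "A", "C", "challenging")$r, 1)
  expect_equal(profile_correlation(m, "A", "B", "challenging")$r, -1)
  r <- profile_correlation(m, "A", "D", "challenging")$r
  expect_lt(abs(r - oracle_pearson(scores$A, scores$D)), 1e-12)
  # constant vector flagged as degenerate
  recs2 <- rbind(recs, do.call(rbind, lapply(seq_along(defs), function(k)
    assay_record("E", defs[k], "lysogen", 2L))))
  m2 <- aggregate_replicates(recs2)
  out <- profile_correlation(m2, "E", "A", "challenging")
  expect_true(is.na(out$r) && out$degenerate)
  # defending axis correlates columns
  rd <- profile_correlation(m, "A", "B", "defending")
  expect_lt(abs(rd$r - oracle_pearson(vapply(names(scores), function(ch) scores[[ch]][1], numeric(1)),
                                      vapply(names(scores), function(ch) scores[[ch]][2], numeric(1)))),
            1e-12)
})

test_that("phenotype-distance regression matches closed-form least squares", {
  ids <- paste0("p", 1:6)
  D <- matrix(0, 6, 6, dimnames = list(ids, ids))
  set.seed(42)
  for (i in 1:6) for (j in 1:6) if (i < j) D[i, j] <- D[j, i] <- runif(1, 0, 0.4)
  dt <- structure(list(ids = ids, matrices = list(D_Stop_motif = D)),
                  class = "distance_table")
  recs <- empty_assay_records()
  for (ch in ids) for (de in ids)
    recs <- rbind(recs, assay_record(ch, de, "lysogen",
                                     as.integer(round(min(6, max(0, 12 * D[ch, de])))),
                                     ))
  m <- aggregate_replicates(recs)
  rg <- regress_phenotype_vs_distance(m, dt, response = "I", metric = "D_Stop_motif")
  o <- oracle_ols(rg$points$x, rg$points$y)
  expect_lt(abs(rg$slope - o$slope), 1e-10)
  expect_lt(abs(rg$intercept - o$intercept), 1e-10)
  expect_lt(abs(rg$r_squared - o$r_squared), 1e-10)
  # exactly linear points give R^2 = 1 (use a noiseless linear response)
  recs2 <- empty_assay_records()
  for (ch in ids) for (de in ids) {
    recs2 <- rbind(recs2, assay_record(ch, de, "lysogen", scores = NULL, n = 1L,
                                       mean_score = 10 * D[ch, de],
                                       min_score = 10 * D[ch, de],
                                       max_score = 10 * D[ch, de]))
  }
  rg2 <- suppressWarnings(  # lm flags the intentionally perfect fit
    regress_phenotype_vs_distance(aggregate_replicates(recs2), dt, "I"))
  expect_equal(rg2$r_squared, 1)
  expect_equal(rg2$slope, 10, tolerance = 1e-9)
  # clade scope filter restricts the points
  rg3 <- regress_phenotype_vs_distance(m, dt, "I", clade = ids[1:4])
  expect_equal(rg3$n, 16L)
  expect_error(regress_phenotype_vs_distance(m, dt, "I", clade = ids[1]),
               "fewer than 3")
})

test_that("lysogen-versus-CRS deltas join cognate systems", {
  recs <- rbind(
    assay_record("L5", "L5", "lysogen", 0L),
    assay_record("L5", "L5_CRS", "CRS", 2L),
    assay_record("Trixie", "L5", "lysogen", 4L),
    assay_record("Trixie", "L5_CRS", "CRS", 4L),
    assay_record("L5", "Trixie", "lysogen", 5L))  # no Trixie CRS
  m <- aggregate_replicates(recs)
  cd <- lysogen_crs_delta(m)
  expect_equal(nrow(cd), 2L)
  homo <- cd[cd$challenger == "L5", ]
  expect_equal(homo$delta, 2)  # CRS is weaker than the lysogen against homotypic phage
  expect_equal(cd[cd$challenger == "Trixie", ]$delta, 0)
  # unpaired CRS produces a warning and is skipped
  recs2 <- rbind(recs, assay_record("L5", "Orphan_CRS", "CRS", 1L))
  expect_warning(lysogen_crs_delta(aggregate_replicates(recs2)), "no cognate lysogen")
})

test_that("assay count summaries match hand enumeration", {
  expect_equal(summarize_assay_counts(empty_assay_records())$total_assays, 0L)
  # 12 records: 2 reciprocal lysogen pairs, 1 complete lysogen-CRS pairing
  recs <- rbind(
    assay_record("A", "B", "lysogen", c(2L, 3L)),   # recip pair 1 (A,B)
    assay_record("B", "A", "lysogen", c(1L, 1L, 2L)),
    assay_record("A", "C", "lysogen", 5L),          # recip pair 2 (A,C)
    assay_record("C", "A", "lysogen", c(0L, 4L)),   # range 4 (>= 2)
    assay_record("B", "C", "lysogen", 3L),          # one-directional
    assay_record("A", "A", "lysogen", 0L),
    assay_record("A", "A_CRS", "CRS", c(2L, 2L)),   # paired with A lysogen
    assay_record("B", "B_CRS", "CRS", 4L),          # B challenger never on B lysogen
    assay_record("D", "A", "lysogen", c(5L, 5L)),
    assay_record("D", "A_CRS", "CRS", c(4L, 5L)),   # second complete A pairing
    assay_record("E", "C", "lysogen", 1L),
    assay_record("E", "C", "lysogen", 2L))          # same comparison, pooled
  s <- summarize_assay_counts(recs)
  expect_equal(s$total_assays, 19L)
  expect_equal(s$unique_comparisons, 11L)
  expect_equal(s$reciprocal_pairs, 2L)
  # challengers scored on both A lysogen and A CRS: A and D -> 2 pairs x 2
  expect_equal(s$lysogen_crs_paired_comparisons, 4L)
  # multi-replicate comparisons: AB, BA, CA, AA_CRS, DA, DA_CRS, EC = 7 of 11
  expect_equal(s$pct_multireplicate, 100 * 7 / 11)
  # of those, range < 2 for all but CA (range 4) -> 6/7
  expect_equal(s$pct_multireplicate_range_lt2, 100 * 6 / 7)
})
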