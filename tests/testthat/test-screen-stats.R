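test_that("the unscaled MAD matches sort-based evaluation", {
  expect_equal(mad_unscaled(c(1, 2, 3)), 1)
  expect_equal(mad_unscaled(c(5, 5, 5, 5)), 0)
  expect_equal(mad_unscaled(c(1, 1, 2, 2, 4, 6, 9)), 1)
  expect_equal(mad_unscaled(c(1, 1, 2, 2, 4, 6, 9)),
               brute_mad(c(1, 1, 2, 2, 4, 6, 9)))
  expect_error(mad_unscaled(numeric(0)), ">= 1")
})

test_that("SSMD* evaluates the robust formula with its degenerate conventions", {
  s <- ssmd_star(c(3, 4, 5), c(1, 2, 3))
  expect_equal(as.numeric(s), 2 / (1.4826 * sqrt(2)))
  expect_equal(as.numeric(s), 0.9539, tolerance = 1e-4)
  expect_false(attr(s, "degenerate"))

  ident <- ssmd_star(c(2, 5, 9), c(2, 5, 9))
  expect_equal(as.numeric(ident), 0)

  degen <- ssmd_star(c(2, 2, 2), c(1, 1, 1))
  expect_equal(as.numeric(degen), Inf)
  expect_true(attr(degen, "degenerate"))
  expect_equal(as.numeric(ssmd_star(c(1, 1), c(1, 1))), 0)
  expect_error(ssmd_star(numeric(0), 1), "non-empty")
})

test_that("single-replicate SSMD* uses the vehicle MAD on both sides", {
  neg <- c(0.9, 1.0, 1.1, 1.0)
  expect_equal(as.numeric(ssmd_star_single(median(neg), neg)), 0)
  x <- median(neg) + 1.4826 * sqrt(2) * mad_unscaled(neg)
  expect_equal(as.numeric(ssmd_star_single(x, neg)), 1)
  expect_equal(as.numeric(ssmd_star_single(1.4, neg)),
               0.4 / (1.4826 * sqrt(2) * 0.05))
  expect_equal(as.numeric(ssmd_star_single(1.4, neg)), 3.815,
               tolerance = 1e-3)
  d <- ssmd_star_single(c(1, 2), c(1, 1, 1))
  expect_true(attr(d, "degenerate"))
  expect_equal(as.numeric(d), c(0, Inf))
})

test_that("SSMD* is antisymmetric and scale/translation invariant", {
  set.seed(123)
  for (k in 1:25) {
    a <- rnorm(sample(3:12, 1), 5, 2)
    b <- rnorm(sample(3:12, 1), 4, 1)
    s <- as.numeric(ssmd_star(a, b))
    expect_equal(as.numeric(ssmd_star(b, a)), -s, tolerance = 1e-12)
    cc <- runif(1, 0.1, 10)
    expect_equal(as.numeric(ssmd_star(cc * a, cc * b)), s, tolerance = 1e-12)
    expect_equal(as.numeric(ssmd_star(a + 3.7, b + 3.7)), s,
                 tolerance = 1e-12)
  }
})

test_that("plate normalization uses the non-artifact vehicle median", {
  meas <- data.frame(
    well = c("B02", "C02", "D02", "E05", "F05"),
    role = c("vehicle", "vehicle", "vehicle", "compound", "compound"),
    compound_id = c(NA, NA, NA, "c1", "c2"),
    value = c(90, 100, 110, 140, 100),
    artifact_flag = FALSE)
  m <- normalize_plate(meas)
  expect_equal(m$fold_change[m$compound_id %in% "c1"], 1.4)
  expect_equal(m$fold_change[m$compound_id %in% "c2"], 1)
  expect_equal(median(m$fold_change[m$role == "vehicle"]), 1)

  # artifact-flagged vehicle well excluded from the reference median
  meas2 <- meas
  meas2$value[3] <- 1e6
  meas2$artifact_flag[3] <- TRUE
  m2 <- normalize_plate(meas2)
  expect_equal(m2$fold_change[m2$compound_id %in% "c1"], 140 / 95)

  meas3 <- meas[c(1, 4, 5), ]
  expect_error(normalize_plate(meas3), class = "plate_invalid_error")
})

test_that("plate QC thresholds SSMD* inclusively", {
  meas <- data.frame(
    well = sprintf("W%02d", 1:8),
    role = rep(c("vehicle", "positive_control"), each = 4),
    compound_id = NA_character_,
    value = c(10, 11, 12, 13, 14, 15, 16, 17),
    artifact_flag = FALSE)
  qc <- plate_qc(meas)
  expect_equal(qc$ssmd_star,
               as.numeric(ssmd_star(c(14, 15, 16, 17), c(10, 11, 12, 13))))
  # qc_pass is inclusive: a plate exactly at the cutoff passes
  qc_at <- plate_qc(meas, qc_cutoff = qc$ssmd_star)
  expect_true(qc_at$qc_pass)
  qc_above <- plate_qc(meas, qc_cutoff = qc$ssmd_star + 1e-9)
  expect_false(qc_above$qc_pass)
})

test_that("primary hit rule: fold inclusive, SSMD strict, artifacts excluded", {
  veh <- c(95, 100, 105, 100)
  meas <- data.frame(
    well = c(sprintf("V%02d", 1:4), "C01", "C02", "C03"),
    role = c(rep("vehicle", 4), rep("compound", 3)),
    compound_id = c(rep(NA, 4), "a", "b", "c"),
    value = c(veh, 139, 160, 160),
    artifact_flag = c(rep(FALSE, 6), TRUE))
  hits <- call_hits_primary(meas)
  expect_equal(hits$hit, c(FALSE, TRUE, FALSE))  # 1.39 fold; ok; artifact
  # strict SSMD cutoff: a compound exactly at the cutoff is not a hit
  h2 <- call_hits_primary(meas, ssmd_cutoff = hits$ssmd_star[2])
  expect_false(h2$hit[2])
  # inclusive fold cutoff: fold exactly at the cutoff is a hit
  h3 <- call_hits_primary(meas, fold_cutoff = hits$fold_change[2])
  expect_true(h3$hit[2])
})

test_that("validation requires replicate SSMD* above cutoff on the plate median", {
  # identical compound and vehicle distributions at cv 0 -> SSMD* 0
  reps <- do.call(rbind, lapply(c("vp1", "vp2"), function(p)
    rbind(data.frame(plate_id = p, compound_id = NA, role = "vehicle",
                     value = rep(100, 8)),
          data.frame(plate_id = p, compound_id = "c1", role = "compound",
                     value = rep(100, 6)))))
  v <- validate_hits(reps)
  expect_equal(v$ssmd_star, 0)
  expect_false(v$validated)
  expect_equal(v$fold_change, 1)

  # planted 1.5-fold enhancer at cv 0.1 validates (n = 24 x 2 plates)
  cmp <- data.frame(compound_id = "enh", true_fold = 1.5)
  reps2 <- simulate_validation_plates(cmp, seed = 9)
  v2 <- validate_hits(reps2)
  expect_true(v2$validated)
  expect_gt(v2$ssmd_star, 0.25)

  expect_error(validate_hits(reps[reps$role == "compound", ]),
               class = "plate_invalid_error")
})

test_that("viability normalizes to the vehicle median", {
  expect_equal(viability_percent(800, c(900, 1000, 1100)), 80)
  expect_equal(viability_percent(1000, c(900, 1000, 1100)), 100)
  expect_equal(viability_percent(0, c(900, 1000, 1100)), 0)
  expect_error(viability_percent(1, c(0, 0)), "> 0")
})

test_that("dose-response summaries sort doses and pool duplicates", {
  flat <- dose_response_summary(c(1, 10, 1, 10), rep(1, 4))
  expect_equal(flat$fold_change, c(1, 1))
  d <- dose_response_summary(c(10, 1, 10), c(1.4, 1.0, 1.6), "felodipine")
  expect_equal(d$dose_uM, c(1, 10))
  expect_equal(d$fold_change, c(1.0, 1.5))
  expect_equal(d$n, c(1L, 2L))
  expect_true(all(diff(d$dose_uM) > 0))
  expect_error(dose_response_summary(c(1, 1), c(1, 2)), "2 distinct")
})
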