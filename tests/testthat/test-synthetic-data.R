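test_that("simulated screens are deterministic and respect the noiseless limit", {
  cfg <- screen_sim_config(seed = 11, n_plates = 2)
  expect_identical(simulate_screen(cfg), simulate_screen(cfg))

  cfg0 <- screen_sim_config(seed = 3, well_cv = 0, positive_effect = 1.4,
                            artifact_rate = 0, enhancer_fraction = 0)
  g <- simulate_screen(cfg0)
  m <- g$plates[[1]]
  expect_true(all(m$value[m$role == "positive_control"] ==
                    1.4 * cfg0$baseline_intensity))
  expect_true(all(m$value[m$role == "vehicle"] == cfg0$baseline_intensity))
  expect_equal(sum(g$truth$compounds$enhancer), 0)
})

test_that("planted positive-control effect is recovered in the large-sample limit", {
  # medians of lognormal draws converge to the planted fold
  cfg <- screen_sim_config(seed = 21, well_cv = 0.10, positive_effect = 1.4,
                           artifact_rate = 0)
  vals <- hcscreen:::rlnorm_median
  set.seed(21)
  veh <- vals(1000, cfg$baseline_intensity, 0.10)
  pos <- vals(1000, cfg$baseline_intensity * 1.4, 0.10)
  expect_lt(abs(median(pos) / median(veh) - 1.4) / 1.4, 0.02)
})

test_that("synthetic well images carry exact ground truth", {
  cfg <- image_sim_config(shape = c(256, 256), n_objects = 1,
                          object_width_px = c(20, 20),
                          object_length_px = c(80, 80),
                          object_intensity_above_bg = c(1000, 1000),
                          noise_sd = 0)
  sw <- simulate_well_image(cfg, seed = 2)
  expect_identical(sw, simulate_well_image(cfg, seed = 2))
  ob <- sw$truth$objects
  expect_equal(nrow(ob), 1)
  expect_equal(ob$integrated_intensity, 1000 * ob$area_px)
  expect_equal(sum(sw$truth$labels == 1), ob$area_px)
  # image equals background + intensity on the truth mask, background off it
  expect_true(all(sw$image[sw$truth$labels == 1] == 1800))
  expect_true(all(sw$image[sw$truth$labels == 0] == 800))
  expect_true(ob$meets_criteria)

  empty <- simulate_well_image(image_sim_config(shape = c(64, 64),
                                                n_objects = 0, noise_sd = 0),
                               seed = 1)
  expect_true(all(empty$image == 800))

  sub <- simulate_well_image(
    image_sim_config(shape = c(256, 256), n_objects = 1,
                     object_width_px = c(5, 5),
                     object_length_px = c(150, 150),
                     object_intensity_above_bg = c(1000, 1000),
                     noise_sd = 0), seed = 3)
  expect_false(sub$truth$objects$meets_criteria)
  expect_equal(sub$truth$objects$sub_threshold_reason, "width_below_min")
})

test_that("Ct tables encode planted folds in the noiseless limit", {
  tab <- simulate_ct_table(c(SSPN = 2), "ACTB", n_replicates = 3,
                           ct_sd = 0, seed = 1)
  ct <- function(s, g) mean(tab$ct[tab$sample_id == s & tab$gene == g])
  expect_equal(ct("treated", "SSPN"), ct("vehicle", "SSPN") - 1)
  tab1 <- simulate_ct_table(c(SSPN = 1), "ACTB", ct_sd = 0, seed = 1)
  ct1 <- function(s, g) mean(tab1$ct[tab1$sample_id == s & tab1$gene == g])
  expect_equal(ct1("treated", "SSPN") - ct1("treated", "ACTB"),
               ct1("vehicle", "SSPN") - ct1("vehicle", "ACTB"))
})

test_that("Ct generator recovers a planted fold in a replicate Monte Carlo", {
  tab <- simulate_ct_table(c(G = 4), "REF", n_replicates = 1000,
                           ct_sd = 0.1, seed = 7)
  fc <- ddct_fold_change(tab, "REF", "vehicle")
  got <- fc$fold[fc$sample_id == "treated" & fc$gene == "G"]
  expect_lt(abs(got - 4) / 4, 0.02)
})

test_that("fusion image generator plants exact fused fractions", {
  for (frac in c(0, 0.3, 1)) {
    sim <- simulate_fusion_images(100, frac, seed = 5)
    inside <- sim$mhc_mask[cbind(round(sim$truth$cx), round(sim$truth$cy))]
    expect_equal(sum(inside), round(100 * frac))
    expect_equal(sum(sim$truth$fused), round(100 * frac))
  }
})
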