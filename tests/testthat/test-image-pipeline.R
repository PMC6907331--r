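se_r <- hcscreen:::se_radius(pipeline_config())

test_that("top hat matches a brute-force opening oracle", {
  # constant image -> all zeros
  expect_true(all(top_hat(matrix(123, 40, 40)) == 0))

  # single bright disk of diameter 6 on flat background: retained at
  # (intensity - background)
  img <- matrix(50, 41, 41)
  d2 <- outer((1:41 - 21)^2, (1:41 - 21)^2, "+")
  img[d2 <= 3^2] <- 50 + 400
  th <- top_hat(img, 12)
  expect_equal(th, brute_tophat(img, 12))
  expect_true(all(th[d2 <= 3^2] == 400))
  expect_true(all(th[d2 > 3^2] == 0))

  # broad plateau, wider than the structuring element in all directions:
  # interior suppressed to 0
  img2 <- matrix(50, 80, 80)
  img2[11:70, 11:70] <- 650
  th2 <- top_hat(img2, 12)
  expect_equal(th2, brute_tophat(img2, 12))
  expect_true(all(th2[30:51, 30:51] == 0))

  # random image agrees with the oracle (small radius keeps oracle fast)
  set.seed(42)
  rnd <- matrix(sample(0:1000, 900, TRUE), 30, 30)
  expect_equal(top_hat(rnd, 4, size_as = "radius"),
               brute_tophat(rnd, 4))
  expect_error(top_hat(array(1, c(2, 2, 2))), "2-D")
})

test_that("top hat is background-invariant and shrinking under iteration", {
  set.seed(7)
  for (k in 1:5) {
    img <- matrix(sample(0:2000, 625, TRUE), 25, 25)
    th <- top_hat(img, 5)
    expect_true(all(th >= 0))
    expect_true(all(th <= img))
    expect_equal(top_hat(img + 137, 5), th)        # translation invariance
    expect_true(all(top_hat(th, 5) <= th + 1e-9))  # shrinking
  }
})

test_that("adaptive threshold applies intensity and width rules", {
  # intensity 400 < 500 -> excluded
  low <- capsule_image(width = 16, length = 80, intensity = 400)
  expect_equal(sum(adaptive_threshold(top_hat(low$image))), 0)

  # width 5 at intensity 1000 -> excluded by min width
  thin <- capsule_image(width = 5, length = 100, intensity = 1000)
  expect_equal(sum(adaptive_threshold(top_hat(thin$image))), 0)

  # width 20 at intensity 1000 -> retained, area matches ground truth
  ok <- capsule_image(width = 20, length = 80, intensity = 1000)
  mask <- adaptive_threshold(top_hat(ok$image))
  expect_equal(sum(mask & ok$mask), sum(ok$mask))
  expect_lte(sum(mask & !ok$mask), 0)
})

test_that("minimum-area filter is inclusive at the boundary", {
  # 499-px component removed, 500 retained (inclusive rule)
  a <- matrix(FALSE, 40, 40); a[1:20, 1:25][1:499] <- TRUE
  expect_equal(max(filter_mask(a, 500)), 0)
  b <- matrix(FALSE, 40, 40); b[1:20, 1:25][1:500] <- TRUE
  expect_equal(max(filter_mask(b, 500)), 1)
  expect_equal(sum(filter_mask(b, 500) > 0), 500)
})

test_that("area filtering agrees with a flood-fill labeling oracle", {
  m <- matrix(FALSE, 50, 50)
  m[2:21, 2:21][1:400] <- TRUE    # 400-px component
  m[26:49, 26:50][1:600] <- TRUE  # 600-px component
  lab_oracle <- brute_label(m, 8)
  expect_equal(max(lab_oracle), 2)
  filt <- filter_mask(m, 500)
  expect_equal(max(filt), 1)
  areas <- tabulate(lab_oracle[lab_oracle > 0])
  surviving_label <- which(areas >= 500)
  expect_true(all((filt > 0) == (lab_oracle == surviving_label)))
  # connectivity: diagonal touch merges under 8, not under 4
  dg <- matrix(FALSE, 4, 4); dg[1, 1] <- TRUE; dg[2, 2] <- TRUE
  expect_equal(max(hcscreen:::label_components(dg, 8)), 1)
  expect_equal(max(hcscreen:::label_components(dg, 4)), 2)
  set.seed(3)
  rnd <- matrix(runif(400) < 0.35, 20, 20)
  for (conn in c(4, 8)) {
    got <- hcscreen:::label_components(rnd, conn)
    want <- brute_label(rnd, conn)
    # same partition (labels may differ in order; here both scan column-major)
    expect_equal(got, want)
  }
})

test_that("quantification sums source pixels under the mask", {
  img <- matrix(1000, 40, 40)
  mask <- matrix(FALSE, 40, 40); mask[1:24, 1:25] <- TRUE  # 600 px
  q <- quantify(img, mask)
  expect_equal(q$total_intensity, 600000)
  expect_equal(q$mean_intensity, 1000)
  q0 <- quantify(img, matrix(FALSE, 40, 40))
  expect_equal(q0$total_intensity, 0)
  expect_equal(q0$object_count, 0)
  expect_error(quantify(img, matrix(FALSE, 10, 10)), "shape")
})

test_that("mask monotonicity holds along the chain", {
  sw <- simulate_well_image(image_sim_config(shape = c(384, 384)), seed = 9)
  cfg <- pipeline_config()
  th <- top_hat(sw$image, cfg$tophat_size_px)
  cand <- th >= cfg$intensity_above_background
  atm <- adaptive_threshold(th, cfg$min_width_px, cfg$max_width_px,
                            cfg$intensity_above_background)
  final <- filter_mask(atm, cfg$min_area_px)
  expect_true(all(atm <= cand))
  expect_true(all((final > 0) <= atm))
})

test_that("well aggregation averages sites and honors artifact flags", {
  good <- capsule_image(width = 16, length = 80, intensity = 1000)$image
  r2 <- analyze_well(list(good, good), well = "B02")
  r1 <- analyze_well(list(good), well = "B02")
  expect_equal(r2$total_intensity, r1$total_intensity)
  expect_equal(r2$n_sites, 2)
  expect_error(analyze_well(list()), ">= 1")

  # mean rule on two constructed sites with different masses
  s1 <- capsule_image(width = 16, length = 60, intensity = 1000)$image
  s2 <- capsule_image(width = 16, length = 60, intensity = 2000)$image
  r <- analyze_well(list(s1, s2))
  expect_equal(r$total_intensity,
               mean(c(analyze_well(list(s1))$total_intensity,
                      analyze_well(list(s2))$total_intensity)))

  # a saturated-debris site is dropped from the aggregate and flags the well
  bad <- good
  bad[1:10, 1:10] <- 65535  # 100 px of 16384 = 0.6% saturated
  rb <- analyze_well(list(good, bad))
  expect_true(rb$artifact_flag)
  expect_match(rb$artifact_reason, "debris")
  expect_equal(rb$total_intensity, r1$total_intensity)
})

test_that("artifact rules flag debris, bright objects and autofluorescence", {
  clean <- capsule_image(width = 16, length = 80, intensity = 1000)
  cfg <- pipeline_config()
  th <- top_hat(clean$image)
  lab <- filter_mask(adaptive_threshold(th), cfg$min_area_px)
  obj <- hcscreen:::measure_objects(lab, clean$image, th)
  ps <- list(median_object_mean_intensity = median(obj$mean_intensity),
             median_background = 800)
  expect_false(flag_artifacts(clean$image, lab, obj, ps, cfg)$flag)

  # debris: planted saturating disks
  deb <- simulate_well_image(
    image_sim_config(shape = c(256, 256), n_objects = 0, noise_sd = 0,
                     debris = list(n = 3, size_px = 12, intensity = 70000)),
    seed = 4)
  labd <- matrix(0L, 256, 256)
  fd <- flag_artifacts(deb$image, labd, obj[0, ], ps, cfg)
  expect_true(fd$flag)
  expect_true("debris" %in% fd$reason)

  # autofluorescence: +5000 offset against a plate median background of 800
  auto <- clean$image + 5000
  fa <- flag_artifacts(auto, matrix(0L, nrow(auto), ncol(auto)), obj[0, ],
                       ps, cfg)
  expect_true("autofluorescence" %in% fa$reason)

  # bright object: mean intensity 10x the plate median object intensity
  obj_bright <- obj
  obj_bright$mean_intensity <- 10 * ps$median_object_mean_intensity
  fb <- flag_artifacts(clean$image, lab, obj_bright, ps, cfg)
  expect_true("bright_object" %in% fb$reason)
})

test_that("well images round-trip through 16-bit TIFF", {
  img <- matrix(sample(0:65535, 64 * 64, TRUE), 64, 64)
  path <- tempfile(fileext = ".tif")
  write_well_image(img, path)
  expect_equal(read_well_image(path), matrix(as.numeric(img), 64, 64))
})
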