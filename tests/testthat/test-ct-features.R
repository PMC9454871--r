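test_that("weighted center reproduces hand-computed examples", {
  # single voxel at physical (2, 3, 4) mm
  v <- vol_from(0, c(7, 7, 7), spacing = c(1, 1, 1))
  v$data[3, 4, 5] <- 10
  m <- array(FALSE, c(7, 7, 7)); m[3, 4, 5] <- TRUE
  expect_equal(unname(weighted_center(v, m)), c(2, 3, 4))

  # intensities 1 at x = 0 and 3 at x = 4: cx = (0*1 + 4*3) / 4 = 3
  v2 <- vol_from(0, c(5, 1, 1), spacing = c(1, 1, 1))
  v2$data[1, 1, 1] <- 1; v2$data[5, 1, 1] <- 3
  m2 <- array(TRUE, c(5, 1, 1))
  expect_equal(unname(weighted_center(v2, m2)["cx"] - 0), 3)

  # uniform intensities on a symmetric mask: center at the centroid
  v3 <- vol_from(5, c(3, 3, 3), spacing = c(1, 1, 1), origin = c(-1, -1, -1))
  expect_equal(unname(weighted_center(v3, full_mask(c(3, 3, 3)))), c(0, 0, 0))

  expect_error(weighted_center(vol_from(0, c(2, 2, 2)),
                               full_mask(c(2, 2, 2))), "zero")
})

test_that("dispersion and center shifts follow their printed definitions", {
  # single voxel: dispersion 0
  v <- vol_from(1, c(1, 1, 1))
  m <- full_mask(c(1, 1, 1))
  expect_equal(loc_sd(v, m, weighted_center(v, m)), 0)

  # two equal voxels 2 mm apart, center at midpoint: LocSd = 1 mm
  v2 <- vol_from(7, c(2, 1, 1), spacing = c(2, 1, 1))
  m2 <- full_mask(c(2, 1, 1))
  ctr <- weighted_center(v2, m2)
  expect_equal(loc_sd(v2, m2, ctr), 1)

  # volume-normalized: 2 voxels x 0.125 mm^3 -> V = 0.25, LocSd/V = 4
  v3 <- vol_from(7, c(5, 1, 1), spacing = c(0.5, 0.5, 0.5))
  m3 <- array(FALSE, c(5, 1, 1)); m3[1, 1, 1] <- TRUE; m3[5, 1, 1] <- TRUE
  nd <- nested_dispersion_features(v3, m3)
  expect_equal(unname(nd["volume_mm3"]), 0.25)
  expect_equal(unname(nd["locsd100"]), 1)
  expect_equal(unname(nd["locsd100v"]), 4)
  # homogeneous lesion: all nested centers coincide
  expect_equal(unname(nd[c("d50", "d20")]), c(0, 0))

  expect_equal(unname(center_shifts(c(0, 0, 0), c(3, 4, 0), c(0, 0, 0))),
               c(5, 0))
  expect_equal(unname(center_shifts(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))),
               c(0, 0))
})

test_that("first-order features match hand arithmetic", {
  fo <- first_order_features(rep(42, 10))
  expect_equal(unname(fo[c("entropy", "uniformity", "sd", "skewness")]),
               c(0, 1, 0, 0))
  expect_equal(unname(first_order_features(c(3, 4))["rms"]), sqrt(12.5))
  expect_equal(unname(first_order_features(c(1, 2, 3))["energy"]), 14)
  expect_equal(unname(first_order_features(c(1, 2, 3))["q25"]), 1.5)
  expect_error(first_order_features(numeric(0)), "empty")
})

test_that("intensity ratios use type-7 quantiles and surface zero division", {
  r <- intensity_ratios(c(400, 600), c(200, 300))
  expect_equal(unname(r), c(2, 2, 2))
  x <- c(10, 20, 30, 40)
  expect_equal(unname(intensity_ratios(2 * x, x)), c(2, 2, 2))
  expect_equal(unname(intensity_ratios(x, x)), c(1, 1, 1))
  expect_error(intensity_ratios(c(1, 2), c(0, 0)), "zero denominator")
})

test_that("the 13 texture directions are exactly the printed vectors", {
  expected <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(-1, 1, 0),
                    c(1, 0, 1), c(1, 1, 1), c(1, -1, 1), c(0, 0, 1),
                    c(0, 1, 1), c(0, -1, 1), c(-1, 0, 1), c(-1, 1, 1),
                    c(-1, -1, 1))
  expect_equal(unname(texture_directions()), expected,
               ignore_attr = "storage.mode")
  expect_equal(nrow(texture_directions()), 13L)
})

test_that("GLCM degenerates correctly on constant input", {
  v <- vol_from(150, c(3, 3, 3))
  g <- glcm_features(v, full_mask(c(3, 3, 3)))
  expect_equal(unname(g["contrast"]), 0)
  expect_equal(unname(g["max_probability"]), 1)
  expect_equal(unname(g["energy"]), 1)
})

test_that("GLCM matches brute-force pair enumeration on a hand-set plane", {
  set.seed(4)
  v <- vol_from(sample(1:4, 9, TRUE) * 100 - 50, c(3, 3, 1))
  m <- full_mask(c(3, 3, 1))
  got <- glcm_features(v, m, bin_size = 100)
  want <- oracle_glcm_features(v, m, bin_size = 100)
  expect_true(max(abs(got[names(want)] - want)) < 1e-10)
})

test_that("GLRLM strided-run convention matches the hand enumeration", {
  # constant 1 x 1 x 8 line, direction (0,0,1), stride 2:
  # two interleaved chains of length 4 -> 2 runs, RP = 2/8
  v <- vol_from(50, c(1, 1, 8))
  m <- full_mask(c(1, 1, 8))
  lev <- array(oracle_quantize(v$data, 100), dim(v$data))
  runs <- oracle_glrlm_runs(lev, m, c(0, 0, 1), 2)
  expect_equal(nrow(runs), 2L)
  expect_equal(unname(runs[, "len"]), c(4, 4))
  # package average over all 13 directions x stride 2 agrees with the oracle
  got <- glrlm_features(v, m, distances = 2)
  want <- oracle_glrlm_features(v, m, distances = 2)
  expect_true(max(abs(got[names(want)] - want)) < 1e-12)
})

test_that("all-distinct gray levels give only length-1 runs (SRE = 1)", {
  v <- vol_from((1:8) * 100 - 50, c(2, 2, 2))
  g <- glrlm_features(v, full_mask(c(2, 2, 2)))
  expect_equal(unname(g["sre"]), 1)
  expect_equal(unname(g["lre"]), 1)
})

test_that("GLRLM builds 52 matrices and GLCM uses 13 directions", {
  v <- vol_from(sample(1:3, 27, TRUE) * 100, c(3, 3, 3))
  m <- full_mask(c(3, 3, 3))
  expect_equal(attr(glrlm_features(v, m), "n_matrices"), 52L)
  expect_equal(attr(glcm_features(v, m), "n_directions"), 13L)
})

test_that("texture families equal the brute-force oracles on random masks", {
  set.seed(42)
  for (rep in 1:30) {
    cs <- random_texture_case(max_side = 4, n_levels = 4, bin_size = 100)
    got_glcm <- tryCatch(glcm_features(cs$vol, cs$mask, bin_size = 100),
                         error = function(e) NULL)
    if (!is.null(got_glcm)) {
      want <- oracle_glcm_features(cs$vol, cs$mask, bin_size = 100)
      expect_lt(max(abs(got_glcm[names(want)] - want)), 1e-10)
    }
    got_rlm <- glrlm_features(cs$vol, cs$mask, bin_size = 100)
    want_rlm <- oracle_glrlm_features(cs$vol, cs$mask, bin_size = 100)
    expect_lt(max(abs(got_rlm[names(want_rlm)] - want_rlm)), 1e-10)
  }
})

test_that("texture features are invariant to whole-voxel translation", {
  set.seed(7)
  base <- array(0, c(9, 9, 9))
  vals <- sample(1:4, 27, TRUE) * 100 - 50
  base[2:4, 2:4, 2:4] <- vals
  m1 <- array(FALSE, c(9, 9, 9)); m1[2:4, 2:4, 2:4] <- TRUE
  shifted <- array(0, c(9, 9, 9)); shifted[5:7, 4:6, 3:5] <- vals
  m2 <- array(FALSE, c(9, 9, 9)); m2[5:7, 4:6, 3:5] <- TRUE
  v1 <- vol_from(base, c(9, 9, 9)); v2 <- vol_from(shifted, c(9, 9, 9))
  expect_equal(glcm_features(v1, m1), glcm_features(v2, m2))
  expect_equal(glrlm_features(v1, m1), glrlm_features(v2, m2))
  expect_equal(first_order_features(v1$data[m1]),
               first_order_features(v2$data[m2]))
  # dispersion unchanged, centers shifted by exactly the translation (mm)
  nd1 <- nested_dispersion_features(v1, m1)
  nd2 <- nested_dispersion_features(v2, m2)
  expect_equal(nd1, nd2)
  expect_equal(weighted_center(v2, m2) - weighted_center(v1, m1),
               c(cx = 3, cy = 2, cz = 1))
})

test_that("the feature registry holds exactly 173 uniquely named features", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 173L)
  expect_equal(anyDuplicated(reg$name), 0L)
  expect_equal(sum(reg$family == "first_order"), 45L)
  expect_equal(sum(reg$family == "glcm"), 66L)
  expect_equal(sum(reg$family == "glrlm"), 33L)
  expect_equal(sum(reg$family == "nested_spatial"), 9L)
  expect_equal(sum(reg$family == "intensity_ratio"), 3L)
  expect_equal(sum(reg$family == "lung_level"), 17L)
})

test_that("lung-level features count lesions and flag attenuation classes", {
  lt <- data.frame(patient_id = "P", lesion_id = c("L1", "L2", "L3"),
                   lobe = c("rul", "rul", "lll"),
                   mean_hu = c(-100, -450, -700),
                   volume_mm3 = c(900, 200, 100))
  lf <- lung_level_features(lt)
  expect_equal(unname(lf["lobe_rul_lesion_count"]), 2)
  expect_equal(unname(lf["lobe_rul_any_solid"]), 1)       # -100 > -300
  expect_equal(unname(lf["lobe_rul_any_part_solid"]), 1)  # -450 in (-600,-300]
  expect_equal(unname(lf["lobe_lll_any_solid"]), 0)
  expect_equal(unname(lf["total_lesion_count"]), 3)
  expect_equal(unname(lf["total_lesion_volume_mm3"]), 1200)
  expect_error(lung_level_features(data.frame(lobe = "rul")), "columns")
})
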