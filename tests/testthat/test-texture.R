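# Discretization, matrix builders and feature formulas.

test_that("discretization maps the fixed 480-grey-level window to 32 bins", {
  cfg <- discretization_config()
  expect_identical(cfg$hu_max - cfg$hu_min + 1, 480)
  expect_identical(cfg$bin_width, 15)
  vol <- make_volume(array(c(-200, 279, -186, -185, 500, -999, 0, 0),
                           c(2, 2, 2)))
  msk <- make_mask(array(TRUE, c(2, 2, 2)))
  d <- discretize(vol, msk, cfg)
  expect_identical(d$bin_labels[1, 1, 1], 1L)   # -200 -> bin 1
  expect_identical(d$bin_labels[2, 1, 1], 32L)  # 279 -> bin 32
  expect_identical(d$bin_labels[1, 2, 1], 1L)   # -186 -> bin 1
  expect_identical(d$bin_labels[2, 2, 1], 2L)   # -185 -> bin 2
  expect_identical(d$bin_labels[1, 1, 2], 32L)  # 500 clamps to bin 32
  expect_identical(d$bin_labels[2, 1, 2], 1L)   # -999 clamps to bin 1
  expect_identical(d$n_clamped, 2L)
  expect_error(discretization_config(hu_min = 0, hu_max = 99, n_bins = 32),
               "divisible")
})

test_that("GLCM of a constant patch has a single entry and is symmetric", {
  vol <- make_volume(array(0, c(2, 2, 1)))
  msk <- make_mask(array(TRUE, c(2, 2, 1)), dimensionality = "2D-axial")
  g <- build_glcm(discretize(vol, msk), mode = "2D")
  k <- 14L  # 0 HU -> bin 14 under the default window
  expect_equal(sum(g$p), 1, tolerance = 1e-12)
  expect_identical(g$p[k, k], 1)
  expect_identical(g$p, t(g$p))
})

test_that("GLCM of the [1,1,2,2] row matches brute-force pair counting", {
  # one row, values in bins 1 and 2 of the default window
  vol <- make_volume(array(c(-200, -200, -185, -185), c(4, 1, 1)))
  msk <- make_mask(array(TRUE, c(4, 1, 1)), dimensionality = "2D-axial")
  d <- discretize(vol, msk)
  g <- build_glcm(d, mode = "2D")
  # only the horizontal direction produces pairs: symmetrized counts
  # {(1,1): 2, (1,2): 1, (2,1): 1, (2,2): 2}, total 6
  expect_equal(g$counts[1, 1], 2)
  expect_equal(g$counts[1, 2], 1)
  expect_equal(g$counts[2, 1], 1)
  expect_equal(g$counts[2, 2], 2)
  expect_equal(g$p[1:2, 1:2],
               matrix(c(2, 1, 1, 2) / 6, 2), tolerance = 1e-15)
  oc <- oracle_glcm_counts(d$bin_labels, texrob:::texture_directions("2D"), 32)
  expect_equal(unname(g$counts + 0), unname(oc))
})

test_that("GLRLM toy rows decompose into the expected runs", {
  # constant 1x4 row, horizontal direction: one run of length 4
  lab <- array(NA_integer_, c(4, 1, 1)); lab[, 1, 1] <- 3L
  coords <- which(!is.na(lab), arr.ind = TRUE)
  runs <- texrob:::glrlm_direction_runs(coords, lab[!is.na(lab)],
                                        c(1L, 0L, 0L), dim(lab))
  expect_identical(runs$len, 4L)
  expect_identical(runs$bin, 3L)

  # row [1,1,2,1]: runs (1,2), (2,1), (1,1)
  lab2 <- array(NA_integer_, c(4, 1, 1)); lab2[, 1, 1] <- c(1L, 1L, 2L, 1L)
  runs2 <- texrob:::glrlm_direction_runs(which(!is.na(lab2), arr.ind = TRUE),
                                         lab2[!is.na(lab2)],
                                         c(1L, 0L, 0L), dim(lab2))
  got <- sort(paste(runs2$bin, runs2$len))
  expect_identical(got, sort(c("1 2", "2 1", "1 1")))

  # a mask hole splits a constant row into two runs of length 2
  lab3 <- array(NA_integer_, c(5, 1, 1)); lab3[c(1, 2, 4, 5), 1, 1] <- 2L
  runs3 <- texrob:::glrlm_direction_runs(which(!is.na(lab3), arr.ind = TRUE),
                                         lab3[!is.na(lab3)],
                                         c(1L, 0L, 0L), dim(lab3))
  expect_identical(runs3$len, c(2L, 2L))
})

test_that("GLRLM features reproduce the single-run worked example", {
  # one run of length 4, grey level 1, 4 voxels, 1 direction
  m <- structure(list(r = matrix(c(0, 0, 0, 1), 1, 4), n_voxels = 4L,
                      n_directions = 1L, mode = "2D"),
                 class = "glrlm_matrix")
  f <- glrlm_features(m)
  expect_equal(f[["SRE"]], 1 / 16, tolerance = 1e-12)
  expect_equal(f[["LRE"]], 16, tolerance = 1e-12)
  expect_equal(f[["RunPercentage"]], 0.25, tolerance = 1e-12)
  expect_equal(f[["GLNU"]], 1, tolerance = 1e-12)
  expect_equal(f[["RLNU"]], 1, tolerance = 1e-12)
  expect_equal(f[["HGLRE"]], 1, tolerance = 1e-12)
  expect_equal(f[["LGLRE"]], 1, tolerance = 1e-12)
  expect_equal(f[["LRHGLE"]], 16, tolerance = 1e-12)
  expect_equal(f[["SRLGLE"]], 1 / 16, tolerance = 1e-12)
})

test_that("GLCM features reproduce hand-derived values on the toy matrices", {
  # constant image: single entry p(k,k) = 1
  pk <- matrix(0, 32, 32); k <- 14L; pk[k, k] <- 1
  mk <- structure(list(p = pk, counts = pk * 4, directions = NULL,
                       mode = "2D", aggregate = "sum"),
                  class = "glcm_matrix")
  f <- glcm_features(mk)
  expect_equal(f[["Energy"]], 1, tolerance = 1e-12)
  expect_equal(f[["Entropy"]], 0, tolerance = 1e-12)
  expect_equal(f[["Contrast"]], 0, tolerance = 1e-12)
  expect_equal(f[["MaxProbability"]], 1, tolerance = 1e-12)
  expect_equal(f[["Dissimilarity"]], 0, tolerance = 1e-12)
  expect_equal(f[["Homogeneity"]], 1, tolerance = 1e-12)
  expect_equal(f[["Homogeneity2"]], 1, tolerance = 1e-12)
  expect_equal(f[["InverseDifferNormal"]], 1, tolerance = 1e-12)
  expect_equal(f[["InverseDifferMomentNormal"]], 1, tolerance = 1e-12)
  expect_equal(f[["AutoCorrelation"]], k^2, tolerance = 1e-12)
  expect_equal(f[["SumAverage"]], 2 * k, tolerance = 1e-12)
  expect_equal(f[["SumEntropy"]], 0, tolerance = 1e-12)
  expect_equal(f[["SumVariance"]], 0, tolerance = 1e-12)
  expect_equal(f[["DifferenceEntropy"]], 0, tolerance = 1e-12)
  expect_equal(f[["ClusterProminence"]], 0, tolerance = 1e-12)
  expect_equal(f[["ClusterShade"]], 0, tolerance = 1e-12)
  expect_equal(f[["ClusterTendency"]], 0, tolerance = 1e-12)
  # zero-variance sentinels
  expect_true(is.nan(f[["Correlation"]]))
  expect_true(is.nan(f[["InformationMeasureCorrel1"]]))
  expect_true(is.nan(f[["InformationMeasureCorrel2"]]))
  expect_true(is.nan(f[["InverseVariance"]]))

  # the [1,1,2,2] row: p = {(1,1): 1/3, (1,2): 1/6, (2,1): 1/6, (2,2): 1/3}
  p2 <- matrix(0, 2, 2)
  p2[1, 1] <- 1 / 3; p2[2, 2] <- 1 / 3; p2[1, 2] <- 1 / 6; p2[2, 1] <- 1 / 6
  m2 <- structure(list(p = p2, counts = p2 * 6, directions = NULL,
                       mode = "2D", aggregate = "sum"),
                  class = "glcm_matrix")
  g <- glcm_features(m2)
  expect_equal(g[["Contrast"]], 1 / 3, tolerance = 1e-12)
  expect_equal(g[["Dissimilarity"]], 1 / 3, tolerance = 1e-12)
  expect_equal(g[["AutoCorrelation"]], 7 / 3, tolerance = 1e-12)
  expect_equal(g[["ClusterTendency"]], 2 / 3, tolerance = 1e-12)
  expect_equal(g[["ClusterShade"]], 0, tolerance = 1e-12)
  expect_equal(g[["ClusterProminence"]], 2 / 3, tolerance = 1e-12)
  expect_equal(g[["Energy"]], 5 / 18, tolerance = 1e-12)
  expect_equal(g[["Entropy"]],
               -(2 / 3) * log2(1 / 3) - (1 / 3) * log2(1 / 6), tolerance = 1e-12)
  expect_equal(g[["Correlation"]], 1 / 3, tolerance = 1e-12)
  expect_equal(g[["Homogeneity"]], 5 / 6, tolerance = 1e-12)
  expect_equal(g[["Homogeneity2"]], 5 / 6, tolerance = 1e-12)
  expect_equal(g[["InverseDifferNormal"]], 2 / 3 + (1 / 3) / (1 + 0.5),
               tolerance = 1e-12)
  expect_equal(g[["InverseDifferMomentNormal"]], 2 / 3 + (1 / 3) / (1 + 0.25),
               tolerance = 1e-12)
  expect_equal(g[["InverseVariance"]], 1 / 3, tolerance = 1e-12)
  expect_equal(g[["MaxProbability"]], 1 / 3, tolerance = 1e-12)
  expect_equal(g[["SumAverage"]], 3, tolerance = 1e-12)
  expect_equal(g[["SumVariance"]], 2 / 3, tolerance = 1e-12)
  expect_equal(g[["SumEntropy"]], log2(3), tolerance = 1e-12)
  expect_equal(g[["DifferenceEntropy"]],
               -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3), tolerance = 1e-12)
  # HX = HY = 1, HXY1 = HXY2 = 2
  expect_equal(g[["InformationMeasureCorrel1"]],
               (g[["Entropy"]] - 2) / 1, tolerance = 1e-12)
  expect_equal(g[["InformationMeasureCorrel2"]],
               sqrt(1 - exp(-2 * (2 - g[["Entropy"]]))), tolerance = 1e-12)
})

test_that("matrix builders match brute-force enumeration on random ROIs", {
  set.seed(42)
  cfg <- discretization_config(hu_min = 0, hu_max = 4, n_bins = 5)
  for (rep in 1:25) {
    d3 <- sample(2:6, 3, replace = TRUE)
    vals <- array(sample(0:4, prod(d3), replace = TRUE), d3)
    fg <- array(runif(prod(d3)) < 0.7, d3)
    if (sum(fg) < 3) next
    vol <- make_volume(vals)
    msk <- make_mask(fg)
    dd <- discretize(vol, msk, cfg)
    for (mode in c("3D", "2D")) {
      dirs <- texrob:::texture_directions(mode)
      g <- tryCatch(build_glcm(dd, mode), error = function(e) NULL)
      oc <- oracle_glcm_counts(dd$bin_labels, dirs, 5)
      if (is.null(g)) {
        expect_equal(sum(oc), 0)
      } else {
        expect_equal(unname(g$counts + 0), unname(oc))
        expect_equal(sum(g$p), 1, tolerance = 1e-12)
        expect_identical(g$p, t(g$p))
      }
      r <- build_glrlm(dd, mode)
      or <- oracle_glrlm_counts(dd$bin_labels, dirs, 5)
      expect_equal(unname(r$r[, seq_len(ncol(or)), drop = FALSE]), unname(or))
      # run conservation
      expect_equal(sum(sweep(r$r, 2, seq_len(ncol(r$r)), "*")),
                   length(dirs) * sum(fg), tolerance = 1e-9)
    }
  }
})

test_that("2D and 3D GLCMs coincide on a single-slice mask", {
  set.seed(5)
  vals <- array(rnorm(9 * 9 * 1, 50, 40), c(9, 9, 1))
  vol <- make_volume(vals, spacing = c(0.8, 0.8, 3))
  msk <- make_mask(array(runif(81) < 0.8, c(9, 9, 1)), spacing = c(0.8, 0.8, 3))
  d <- discretize(vol, msk)
  g2 <- build_glcm(d, "2D"); g3 <- build_glcm(d, "3D")
  expect_identical(g2$counts, g3$counts)
  expect_identical(g2$p, g3$p)
})

test_that("texture features are invariant to whole-voxel translation", {
  set.seed(12)
  pat <- array(rnorm(6 * 6 * 4, 40, 30), c(6, 6, 4))
  vals <- array(0, c(20, 20, 10))
  vals[2:7, 2:7, 2:5] <- pat
  vals[10:15, 9:14, 5:8] <- pat  # identical copy, shifted
  vol <- make_volume(vals, spacing = c(0.8, 0.8, 3))
  blob <- array(runif(6 * 6 * 4) < 0.85, c(6, 6, 4))
  m1 <- array(FALSE, c(20, 20, 10)); m1[2:7, 2:7, 2:5] <- blob
  m2 <- array(FALSE, c(20, 20, 10)); m2[10:15, 9:14, 5:8] <- blob
  f1 <- extract_features(vol, make_mask(m1, spacing = c(0.8, 0.8, 3)))
  f2 <- extract_features(vol, make_mask(m2, spacing = c(0.8, 0.8, 3)))
  tex <- texture_feature_names()
  expect_equal(unclass(f1)[tex], unclass(f2)[tex], tolerance = 1e-12)
})

test_that("morphology features are exact on constructed masks", {
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  f <- morphology_features(make_mask(one))
  expect_equal(unname(f), c(0, 1, 0.001), tolerance = 1e-12)

  cube <- array(FALSE, c(12, 12, 12)); cube[2:11, 2:11, 2:11] <- TRUE
  f2 <- morphology_features(make_mask(cube))
  expect_equal(f2[["NumberOfVoxels"]], 1000)
  expect_equal(f2[["Volume"]], 1, tolerance = 1e-12)
  expect_equal(f2[["Max3DDiameter"]], 9 * sqrt(3), tolerance = 1e-12)

  two <- array(FALSE, c(3, 3, 5)); two[2, 2, 1] <- TRUE; two[2, 2, 4] <- TRUE
  f3 <- morphology_features(make_mask(two, spacing = c(0.8, 0.8, 3)))
  expect_equal(f3[["Max3DDiameter"]], 9, tolerance = 1e-12)
})

test_that("extraction yields exactly 32 named texture features, deterministically", {
  spec <- lesion_spec(target_diameter = 14)
  gen <- generate_lesion_volume(spec, c(41, 41, 15), c(0.8, 0.8, 3), seed = 77)
  f <- extract_features(gen$volume, gen$truth)
  tex <- unclass(f)[texture_feature_names()]
  expect_length(tex, 32)
  expect_identical(sum(names(f) %in% glcm_feature_names()), 21L)
  expect_identical(sum(names(f) %in% glrlm_feature_names()), 11L)
  expect_true(f[["Energy"]] > 0 && f[["Energy"]] <= 1)
  expect_true(f[["MaxProbability"]] > 0 && f[["MaxProbability"]] <= 1)
  expect_gte(f[["Entropy"]], 0)
  expect_true(f[["RunPercentage"]] > 0 && f[["RunPercentage"]] <= 1)
  expect_true(f[["SRE"]] > 0 && f[["SRE"]] <= 1)
  g <- extract_features(gen$volume, gen$truth)
  expect_identical(unclass(f), unclass(g))
})

test_that("single-voxel ROI gives a degenerate-matrix error", {
  vol <- make_volume(array(0, c(5, 5, 5)))
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  d <- discretize(vol, make_mask(one))
  expect_error(build_glcm(d, "3D"), "degenerate")
})
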