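# Synthetic lesion phantoms and simulated readers.

test_that("noise-free limit yields exactly two intensity values", {
  spec <- lesion_spec(target_diameter = 12, noise_sd = 0,
                      boundary_blur_sigma = 0, shape_irregularity = 0)
  gen <- generate_lesion_volume(spec, c(33, 33, 33), c(1, 1, 1), seed = 5)
  vals <- sort(unique(as.vector(gen$volume$values)))
  expect_identical(vals, c(60, 110))
  expect_true(all(gen$volume$values[gen$truth$values] == 60))
  expect_true(all(gen$volume$values[!gen$truth$values] == 110))
})

test_that("generation is deterministic and clamped to the HU range", {
  spec <- lesion_spec(target_diameter = 15, noise_sd = 40)
  a <- generate_lesion_volume(spec, c(41, 41, 15), c(0.8, 0.8, 3), seed = 9)
  b <- generate_lesion_volume(spec, c(41, 41, 15), c(0.8, 0.8, 3), seed = 9)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$truth$values, b$truth$values)
  expect_true(all(a$volume$values >= -1024 & a$volume$values <= 3071))
  d <- generate_lesion_volume(spec, c(41, 41, 15), c(0.8, 0.8, 3), seed = 10)
  expect_false(identical(a$volume$values, d$volume$values))
})

test_that("truth mask diameter tracks the target diameter within 10%", {
  spec <- lesion_spec(target_diameter = 30)
  gen <- generate_lesion_volume(spec, c(79, 79, 23), c(0.8, 0.8, 3), seed = 3)
  # brute-force max pairwise distance over surface voxel centers
  bnd <- which(mask_boundary(gen$truth), arr.ind = TRUE)
  pts <- sweep(bnd - 1, 2, gen$truth$spacing, "*")
  dmax <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    d2 <- colSums((t(pts[(i + 1):nrow(pts), , drop = FALSE]) - pts[i, ])^2)
    dmax <- max(dmax, max(d2))
  }
  dmax <- sqrt(dmax)
  expect_lt(abs(dmax - 30) / 30, 0.10)
  expect_equal(max_3d_diameter_mm(gen$truth), dmax, tolerance = 1e-12)
})

test_that("lesion that does not fit the grid is a sizing error", {
  spec <- lesion_spec(target_diameter = 30)
  expect_error(generate_lesion_volume(spec, c(20, 20, 20), c(1, 1, 1), 1),
               "does not fit")
  expect_error(generate_lesion_volume(spec, c(41, 41, 41), c(-1, 1, 1), 1),
               "positive")
})

test_that("identity perturbation returns the truth unchanged", {
  spec <- lesion_spec(target_diameter = 16, noise_sd = 0,
                      boundary_blur_sigma = 0)
  gen <- generate_lesion_volume(spec, c(41, 41, 41), c(1, 1, 1), seed = 2)
  pert <- reader_perturbation(radial_bias = 0, radial_jitter_sd = 0,
                              seed = 4, reader_id = "R1")
  m <- simulate_reader(gen$truth, pert)
  expect_identical(m$values, gen$truth$values)
  expect_identical(m$reader_id, "R1")
})

test_that("pure positive bias dilates a sphere", {
  spec <- lesion_spec(target_diameter = 24, shape_irregularity = 0)
  gen <- generate_lesion_volume(spec, c(51, 51, 51), c(1, 1, 1), seed = 6)
  m <- simulate_reader(gen$truth,
                       reader_perturbation(radial_bias = 1,
                                           radial_jitter_sd = 0, seed = 1))
  expect_gt(sum(m$values), sum(gen$truth$values))
  # the dilated mask should (essentially) contain the truth
  expect_gt(sum(m$values & gen$truth$values) / sum(gen$truth$values), 0.99)
})

test_that("independent seeds give distinct readers that still overlap truth", {
  spec <- lesion_spec(target_diameter = 30)
  gen <- generate_lesion_volume(spec, c(79, 79, 23), c(0.8, 0.8, 3), seed = 11)
  dices <- vapply(1:20, function(s) {
    m <- simulate_reader(gen$truth,
                         reader_perturbation(radial_bias = 0,
                                             radial_jitter_sd = 1,
                                             partial_volume_scale = 0,
                                             seed = s))
    dice(m, gen$truth)
  }, 0)
  expect_true(all(dices > 0.5))
  m1 <- simulate_reader(gen$truth, reader_perturbation(radial_jitter_sd = 1, seed = 1))
  m2 <- simulate_reader(gen$truth, reader_perturbation(radial_jitter_sd = 1, seed = 2))
  expect_false(identical(m1$values, m2$values))
})

test_that("reader masks stay single connected components", {
  spec <- lesion_spec(target_diameter = 20)
  gen <- generate_lesion_volume(spec, c(53, 53, 19), c(0.8, 0.8, 2.5), seed = 8)
  for (s in 1:5) {
    m <- simulate_reader(gen$truth,
                         reader_perturbation(radial_jitter_sd = 1, seed = s))
    expect_identical(texrob:::count_components(m$values), 1L)
  }
})

test_that("mean Dice against truth is non-increasing in the jitter sd", {
  spec <- lesion_spec(target_diameter = 25)
  gen <- generate_lesion_volume(spec, c(67, 67, 21), c(0.8, 0.8, 2.5), seed = 13)
  sds <- c(0.4, 0.8, 1.6, 2.4)
  reps <- 20L
  means <- ses <- numeric(length(sds))
  for (k in seq_along(sds)) {
    d <- vapply(seq_len(reps), function(s)
      dice(simulate_reader(gen$truth,
                           reader_perturbation(radial_bias = 0,
                                               radial_jitter_sd = sds[k],
                                               partial_volume_scale = 0,
                                               seed = 1000 + s)),
           gen$truth), 0)
    means[k] <- mean(d); ses[k] <- sd(d) / sqrt(reps)
  }
  for (k in seq_len(length(sds) - 1))
    expect_lte(means[k + 1], means[k] + 2 * (ses[k] + ses[k + 1]))
  expect_lt(means[length(sds)], means[1])  # overall trend strictly down
})

test_that("symmetric-difference thickness matches the jitter sd within 50%", {
  spec <- lesion_spec(target_diameter = 24, shape_irregularity = 0)
  gen <- generate_lesion_volume(spec, c(51, 51, 51), c(1, 1, 1), seed = 17)
  r0 <- 12
  area <- 4 * pi * r0^2
  sd_mm <- 1
  th <- vapply(1:20, function(s) {
    m <- simulate_reader(gen$truth,
                         reader_perturbation(radial_bias = 0,
                                             radial_jitter_sd = sd_mm,
                                             partial_volume_scale = 0,
                                             seed = 300 + s))
    sum(xor(m$values, gen$truth$values)) * prod(gen$truth$spacing) / area
  }, 0)
  expect_gt(mean(th), 0.5 * sd_mm)
  expect_lt(mean(th), 1.5 * sd_mm)
})

test_that("exclusion criteria retain lesions at and above 10 mm", {
  row_mask <- function(nvox) {
    m <- array(FALSE, c(801, 3, 3))
    m[seq_len(nvox), 2, 2] <- TRUE
    roi_mask(m, c(0.1, 0.1, 3))
  }
  # voxel-center diameters: 5, 9.9, 10, 27, 80 mm
  masks <- lapply(c(51, 100, 101, 271, 801), row_mask)
  res <- apply_exclusion_criteria(masks, min_diameter = 10)
  expect_identical(sum(res$kept), 3L)
  expect_equal(res$log$axial_diameter_mm, c(5, 9.9, 10, 27, 80))
  expect_identical(res$kept, c(FALSE, FALSE, TRUE, TRUE, TRUE))

  empty <- roi_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1))
  res2 <- apply_exclusion_criteria(list(empty))
  expect_false(res2$kept[1])
  expect_identical(res2$log$reason[1], "empty")

  single <- make_mask(array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)), c(3, 3, 3)),
                      spacing = c(0.8, 0.8, 3))
  res3 <- apply_exclusion_criteria(list(single))
  expect_false(res3$kept[1])
  expect_equal(res3$log$axial_diameter_mm[1], 0)
})

test_that("cohort generation is reproducible and internally consistent", {
  rng <- list(target_diameter = c(12, 25))
  a <- generate_cohort(3, 42, population_ranges = rng)
  b <- generate_cohort(3, 42, population_ranges = rng)
  expect_identical(lapply(a$volumes, `[[`, "values"),
                   lapply(b$volumes, `[[`, "values"))
  expect_identical(lapply(a$reader1_masks, `[[`, "values"),
                   lapply(b$reader1_masks, `[[`, "values"))
  expect_length(a$volumes, 3)
  expect_length(a$reader2_masks, 3)
  for (i in 1:3) {
    expect_gt(dice(a$reader1_masks[[i]], a$truth_masks[[i]]), 0)
    expect_gt(dice(a$reader2_masks[[i]], a$truth_masks[[i]]), 0)
    expect_true(all(a$volumes[[i]]$values >= -1024 &
                      a$volumes[[i]]$values <= 3071))
  }
  single <- generate_cohort(1, 7, population_ranges = rng)
  expect_length(single$volumes, 1)
  expect_error(generate_cohort(2, 1,
                               population_ranges = list(noise_sd = c(5, 2))),
               "degenerate")
})

test_that("cohort round-trips through NIfTI files and a manifest", {
  co <- generate_cohort(2, 31, population_ranges = list(target_diameter = c(12, 18)))
  dir <- withr::local_tempdir()
  mf <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(man$lesions, 2)
  vol <- read_volume(file.path(dir, man$lesions[[1]]$volume))
  m1 <- read_labelmap(file.path(dir, man$lesions[[1]]$reader1_mask), vol)
  expect_identical(m1$values, co$reader1_masks[[1]]$values)
  expect_equal(vol$spacing, co$volumes[[1]]$spacing, tolerance = 1e-6)
})
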