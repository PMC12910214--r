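# Phantom generator: determinism, diameter and contrast control, dataset
# bookkeeping and regeneration, and the augmentation contracts.

test_that("phantom generation is bitwise reproducible and respects n_lesions", {
  cfg <- phantom_config(seed = 101L)
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$image >= 0 & p1$image <= 1))
  expect_true(all(p1$mask %in% c(0L, 1L)))
  p0 <- generate_phantom(phantom_config(n_lesions = 0L, seed = 5L))
  expect_equal(sum(p0$mask), 0)
  # over-sized lesion is rejected
  expect_error(generate_phantom(
    phantom_config(image_size = c(32L, 32L), diameter_range_mm = c(60, 80),
                   seed = 1L)), "exceeds organ size")
})

test_that("requested lesion diameter is recovered from the generated mask", {
  hits <- 0L; tries <- 0L
  for (s in 1:12) {
    cfg <- phantom_config(image_size = c(96L, 96L), spacing_mm = 0.5,
                          n_lesions = 1L, diameter_range_mm = c(10, 10),
                          necrotic_core_prob = 0, seed = 300L + s)
    ph <- generate_phantom(cfg)
    lr <- stratify_lesions(ph$mask, 0.5)
    if (nrow(lr) != 1) next
    tries <- tries + 1L
    if (lr$equiv_diameter_mm >= 9 && lr$equiv_diameter_mm <= 11)
      hits <- hits + 1L
  }
  expect_gte(tries, 10L)
  expect_equal(hits, tries)
})

test_that("lesion contrast is recovered inside the lesion interior", {
  cfg <- phantom_config(image_size = c(96L, 96L), n_lesions = 1L,
                        diameter_range_mm = c(20, 20), lesion_contrast = -0.3,
                        necrotic_core_prob = 0, noise_sd = 0.02, seed = 77L)
  ph <- generate_phantom(cfg)
  interior <- lcmamba:::erode_zeropad(ph$mask, EBImage::makeBrush(5L, "box")) == 1
  organ <- ph$image > 0.3 & ph$mask == 0   # parenchyma, away from lesion
  diffm <- mean(ph$image[interior]) - mean(ph$image[organ])
  tol <- 0.05 * abs(cfg$lesion_contrast) + 2 * cfg$noise_sd / sqrt(sum(interior))
  expect_lt(abs(diffm - cfg$lesion_contrast), tol + 0.02)
})

test_that("dataset writing follows largest-remainder splits and regenerates exactly", {
  dir <- file.path(tempdir(), "lcmamba-split-ds")
  unlink(dir, recursive = TRUE)
  cfg <- phantom_config(seed = 42L, image_size = c(32L, 32L),
                        diameter_range_mm = c(6, 10), n_lesions = 1L)
  mfp <- generate_dataset(10, c(0.7, 0.15, 0.15), cfg, dir)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  expect_equal(mf$split_sizes, c(7L, 2L, 1L))
  expect_equal(sum(mf$split_sizes), 10L)
  # per-item sub-seeds are disjoint
  expect_equal(anyDuplicated(mf$items$seed), 0L)
  # regenerating any item from its manifest seed reproduces the file hash
  h0 <- tools::md5sum(file.path(dir, mf$items$image))
  for (i in c(1L, 5L, 10L)) {
    ci <- cfg; ci$seed <- mf$items$seed[i]
    ph <- generate_phantom(ci)
    tmp <- tempfile(fileext = ".png")
    write_image_slice(ph$image, tmp, "png", ph$spacing_mm)
    expect_identical(unname(tools::md5sum(tmp)),
                     unname(h0[file.path(dir, mf$items$image[i])]))
  }
  expect_error(generate_dataset(3, c(0.9, 0.05, 0.05), cfg, dir),
               "zero-size")
})

test_that("NIfTI-format datasets round-trip through the manifest", {
  dir <- file.path(tempdir(), "lcmamba-nii-ds")
  unlink(dir, recursive = TRUE)
  cfg <- phantom_config(seed = 9L, image_size = c(32L, 32L),
                        spacing_mm = 0.8, n_lesions = 1L,
                        diameter_range_mm = c(6, 10))
  generate_dataset(8, c(0.5, 0.25, 0.25), cfg, dir, format = "nifti")
  ds <- load_manifest(dir)
  expect_length(ds$items, 8)
  expect_equal(ds$items[[1]]$spacing_mm, 0.8)
  expect_true(all(ds$items[[3]]$mask %in% c(0L, 1L)))
  expect_equal(dim(ds$items[[1]]$image), c(32L, 32L))
})

test_that("train and test draws share the same lesion-size distribution", {
  cfg <- phantom_config(seed = 202L, image_size = c(48L, 48L), n_lesions = 1L,
                        diameter_range_mm = c(8, 20))
  areas <- function(offset) {
    vapply(1:100, function(i) {
      ci <- cfg; ci$seed <- lcmamba:::item_seed(cfg$seed, offset + i)
      sum(generate_phantom(ci)$mask)
    }, numeric(1))
  }
  a_train <- areas(0); a_test <- areas(1000)
  ks <- suppressWarnings(stats::ks.test(a_train, a_test))
  expect_gt(ks$p.value, 0.01)
})

test_that("augmentation keeps masks binary, bounds the angle, and flips are involutions", {
  cfg <- phantom_config(seed = 55L)
  ph <- generate_phantom(cfg)
  for (s in 1:10) {
    au <- augment(ph$image, ph$mask, seed = s)
    expect_true(all(au$mask %in% c(0L, 1L)))
    expect_gte(au$angle, -15); expect_lte(au$angle, 15)
    expect_equal(dim(au$image), dim(ph$image))
  }
  # flipping twice restores the original
  f1 <- ph$image[, ncol(ph$image):1]
  expect_identical(f1[, ncol(f1):1], ph$image)
  # preset "none" with no resize is the identity
  id <- augment(ph$image, ph$mask, seed = 3, preset = "none")
  expect_identical(id$image, ph$image)
  expect_identical(id$mask, ph$mask)
  # resize target honoured, mask still binary
  rs <- augment(ph$image, ph$mask, seed = 4, size = c(32L, 32L))
  expect_equal(dim(rs$image), c(32L, 32L))
  expect_true(all(rs$mask %in% c(0L, 1L)))
})

test_that("augmentation preserves the lesion count", {
  for (s in 1:8) {
    cfg <- phantom_config(seed = 400L + s, n_lesions = 2L,
                          diameter_range_mm = c(8, 14))
    ph <- generate_phantom(cfg)
    n0 <- nrow(stratify_lesions(ph$mask))
    au <- augment(ph$image, ph$mask, seed = s)
    expect_equal(nrow(stratify_lesions(au$mask)), n0)
  }
})
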