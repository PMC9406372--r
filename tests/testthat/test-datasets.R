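test_that("save/load round-trips a dataset through PNG + manifest", {
  ds <- tiny_source(n = 2, resolution = 24)
  dir <- withr::local_tempdir()
  mp <- save_dataset(ds, dir)
  expect_true(file.exists(mp))
  back <- load_dataset(mp)
  expect_equal(n_images(back), n_images(ds))
  expect_identical(back$meta$label, ds$meta$label)
  expect_identical(back$meta$domain, ds$meta$domain)
  expect_identical(back$meta$split, ds$meta$split)
  # PNG is 8-bit: intensities round-trip to within one quantization step
  expect_lt(max(abs(back$images[[1]] - cytocoral:::unclass_image(ds$images[[1]]))),
            1 / 255)
})

test_that("manifest errors are typed and informative", {
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "manifest.csv")
  writeLines("path,label,domain,split\nmissing.png,XYZ,source,", mp)
  expect_error(load_dataset(mp), "unknown Bethesda label")
  writeLines("path,label,domain,split\nmissing.png,NILM,source,", mp)
  expect_error(load_dataset(mp), "missing.png")
  writeLines("path,label,domain,split", mp)
  empty <- load_dataset(mp)
  expect_equal(n_images(empty), 0)
  expect_error(load_dataset(file.path(dir, "nope.csv")), "not found")
})

test_that("augment_image implements flips and bounded rotation", {
  img <- synth_cell_image("NILM", seed = 1, resolution = 24)
  pol <- augmentation_policy()
  # 2x2 index arithmetic on a larger canvas: horizontal flip reverses cols
  m <- array(stats::runif(24 * 24 * 3), dim = c(24, 24, 3))
  fh <- augment_image(m, augment_transform(flip_horizontal = TRUE), pol)
  expect_equal(fh[1, 1, 1], m[1, 24, 1])
  expect_equal(fh[5, 3, 2], m[5, 22, 2])
  # flips are involutions
  fhh <- augment_image(fh, augment_transform(flip_horizontal = TRUE), pol)
  expect_equal(fhh, m, ignore_attr = TRUE)
  fv2 <- augment_image(
    augment_image(m, augment_transform(flip_vertical = TRUE), pol),
    augment_transform(flip_vertical = TRUE), pol)
  expect_equal(fv2, m, ignore_attr = TRUE)
  # shape, range and label preserved under rotation
  rot <- augment_image(img, augment_transform(rotation_degrees = 15), pol)
  expect_equal(dim(rot), dim(img))
  expect_true(all(rot >= 0 & rot <= 1))
  expect_identical(attr(rot, "label"), "NILM")
  # policy violations
  expect_error(augment_image(img, augment_transform(rotation_degrees = 30),
                             augmentation_policy(max_rotation = 10)),
               "outside the policy range")
  expect_error(augment_image(img, augment_transform(), pol, as_copy = TRUE),
               "identity transform is excluded")
  expect_error(augmentation_policy(max_rotation = 60), "45")
})

test_that("balance_classes equalizes to the majority with provenance", {
  ds <- synth_dataset(c(NILM = 6, LSIL = 2, HSIL = 3, SCC = 1),
                      seed = 3, resolution = 24)
  bal <- balance_classes(ds, augmentation_policy(), seed = 9)
  expect_equal(unname(class_counts(bal)), rep(6L, 4))
  expect_equal(n_images(bal), 24)
  # originals retained unmodified
  expect_identical(bal$images[seq_len(12)], ds$images)
  aug <- bal$meta[!is.na(bal$meta$source_id), ]
  expect_equal(nrow(aug), 12)
  # (source, transform) pairs unique; identity never used
  expect_false(any(duplicated(aug[, c("source_id", "transform")])))
  expect_false(any(aug$transform == "r+0_h0_v0"))
  # already balanced: unchanged
  expect_identical(balance_classes(bal, seed = 1), bal)
  # reproducible
  expect_identical(balance_classes(ds, augmentation_policy(), seed = 9)$meta,
                   bal$meta)
})

test_that("balancing capacity is counted exactly for a flips-only policy", {
  ds <- synth_dataset(c(NILM = 5, SCC = 2), seed = 4, resolution = 24)
  flips_only <- augmentation_policy(max_rotation = 0, allow_flips = TRUE)
  # 3 distinct non-identity flip transforms per source: 2 + 2*3 = 8 max
  bal <- balance_classes(ds, flips_only, seed = 1)
  cc <- class_counts(bal)
  expect_equal(cc[["NILM"]], 5L)
  expect_equal(cc[["SCC"]], 5L)
  expect_error(balance_classes(ds, flips_only, seed = 1, target = 9),
               "capacity error")
})

test_that("stratified split follows the per-class rounding rule", {
  ds <- tiny_source(n = 10, resolution = 24)
  sp <- stratified_split(ds, seed = 2)
  tab <- table(sp$meta$label, sp$meta$split)
  # per class of 10: test round(2) = 2, val round(1.5) = 2, train 6
  expect_true(all(tab[, "test"] == 2))
  expect_true(all(tab[, "val"] == 2))
  expect_true(all(tab[, "train"] == 6))
  # partitions disjoint and exhaustive
  expect_true(all(sp$meta$split %in% c("train", "val", "test")))
  expect_equal(n_images(get_split(sp, "train")) +
                 n_images(get_split(sp, "val")) +
                 n_images(get_split(sp, "test")), n_images(ds))
  # deterministic given seed
  expect_identical(stratified_split(ds, seed = 2)$meta$split, sp$meta$split)
  expect_false(identical(stratified_split(ds, seed = 3)$meta$split,
                         sp$meta$split))
  # all-train fractions
  all_tr <- stratified_split(ds, c(1, 0, 0), seed = 1)
  expect_true(all(all_tr$meta$split == "train"))
  # degenerate class warns
  tiny <- synth_dataset(c(NILM = 2), seed = 1, resolution = 24)
  expect_warning(stratified_split(tiny, seed = 1), "fewer than 3")
})

test_that("the published protocol counts fall out of balance + split", {
  # counting only (no images needed at this scale)
  paper_counts <- c(NILM = 613, LSIL = 113, HSIL = 163, SCC = 74)
  expect_equal(sum(paper_counts), 963)
  balanced <- rep(max(paper_counts), 4)
  expect_equal(sum(balanced), 2452)
  m <- 613
  n_test <- floor(0.20 * m + 0.5); n_val <- floor(0.15 * m + 0.5)
  expect_equal(n_test * 4, 492)
  expect_equal(n_val, 92)
  expect_equal(m - n_test - n_val, 398)
})
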