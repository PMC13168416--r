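make_disc <- function(nr, nc, cr, cc, r, id = 1L, labels = NULL) {
  if (is.null(labels)) labels <- matrix(0L, nr, nc)
  rowm <- matrix(0:(nr - 1), nr, nc)
  colm <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  labels[(rowm - cr)^2 + (colm - cc)^2 <= r^2] <- id
  labels
}

test_that("area and distance conversions are inverse of each other", {
  for (cal in list(calibration(),
                   calibration(0.568, "legacy_area_factor"))) {
    x <- c(1, 70, 2000, 338511.7)
    expect_equal(um2_to_px(px_to_um2(x, cal), cal), x)
    expect_equal(um_to_px(px_to_um(x, cal), cal), x)
  }
})

test_that("legacy calibration reproduces the published medium-bin conversion", {
  leg <- calibration(area_mode = "legacy_area_factor")
  expect_equal(trunc(px_to_um2(2000, leg)), 1136)
  # linear-squared mode differs: the two printed conventions are distinct
  expect_lt(px_to_um2(2000, calibration()), 1136)
})

test_that("default linear pixel size reproduces the total imaged area", {
  expect_equal(px_to_um2(1024 * 1024, calibration()), 338511.7,
               tolerance = 1e-4)
})

test_that("size classes follow the published pixel bins, with gaps unclassified", {
  bins <- size_bins_preset("methods_px")
  cal <- calibration(area_mode = "legacy_area_factor")
  grab <- function(px) assign_size_class(px, px_to_um2(px, cal), bins)
  expect_equal(grab(1000), "small")
  expect_equal(grab(3000), "medium")
  expect_equal(grab(5000), "unclassified")   # gap between 4000 and 6000
  expect_equal(grab(7000), "large")
  expect_equal(assign_size_class(1e6, 4e5, bins), "major")
  bins_um <- size_bins_preset("results_um2")
  expect_equal(assign_size_class(500, 300, bins_um), "small")
  expect_equal(assign_size_class(500, 500, bins_um), "unclassified")
})

test_that("overlapping size bins are rejected at construction", {
  expect_error(size_class_bins(list(a = c(0, 10), b = c(5, 20))), "overlap")
})

test_that("label_tumors applies the 130 um2 floor and reports both units", {
  cal <- calibration()
  # 130 um2 = ~402.7 px under the default calibration
  labels <- make_disc(128, 128, 30, 30, 13, 1L)       # ~530 px, survives
  labels <- make_disc(128, 128, 90, 90, 9, 2L, labels) # ~253 px, dropped
  expect_message(lt <- label_tumors(labels, cal), "below the 130")
  expect_equal(nrow(lt$lesions), 1L)
  expect_equal(lt$lesions$area_um2, px_to_um2(lt$lesions$area_px, cal))
  expect_gt(lt$lesions$area_um2, 130)
  expect_equal(sort(unique(as.vector(lt$labels))), c(0L, 1L))
})

test_that("label_tumors handles empty and invalid masks", {
  empty <- label_tumors(matrix(0L, 16, 16))
  expect_equal(nrow(empty$lesions), 0L)
  expect_error(label_tumors(matrix(0.5, 4, 4)), "non-negative integers")
})

test_that("components are 8-connected: diagonal pixels form one lesion", {
  m <- matrix(0L, 10, 10)
  m[3, 3] <- 1L; m[4, 4] <- 1L; m[5, 5] <- 1L
  lt <- label_tumors(m, min_area_um2 = 0)
  expect_equal(nrow(lt$lesions), 1L)
  expect_equal(lt$lesions$area_px, 3)
})

test_that("rasterized disc area is close to the analytic value", {
  m <- make_disc(100, 100, 49.5, 49.5, 30)
  expect_equal(sum(m > 0), pi * 30^2, tolerance = 0.02)
})

test_that("partition conservation holds for random lesions", {
  set.seed(101)
  for (rep in 1:10) {
    labels <- random_disc_mask(96, 96, 3)
    part <- region_partition(labels)
    for (id in unique(labels[labels > 0])) {
      a <- part$areas[part$areas$id == id, ]
      expect_equal(a$interior_px + a$inner_px, sum(labels == id))
    }
    # frame = tumor-free + lesions (to numerical precision)
    expect_equal(part$tumor_free_area_um2 + px_to_um2(sum(labels > 0)),
                 px_to_um2(96 * 96))
  }
})

test_that("band area of a r=50 disc matches the analytic annulus", {
  labels <- make_disc(128, 128, 63.5, 63.5, 50)
  d <- decompose_periphery_interior(labels, 1, band_width_px = 7)
  band <- sum(d$periphery_inner) + sum(d$periphery_outer)
  expect_equal(band, pi * (53.5^2 - 46.5^2), tolerance = 0.05)
})

test_that("a band wider than the lesion empties the interior with a warning", {
  labels <- make_disc(20, 20, 10, 10, 3)
  expect_warning(d <- decompose_periphery_interior(labels, 1, 7),
                 "swallows")
  expect_equal(sum(d$interior), 0)
  expect_true(all(which(labels == 1) %in% which(d$periphery_inner)))
})

test_that("fast decomposition equals the exhaustive oracle exactly", {
  set.seed(202)
  cal <- calibration()
  buffer_px <- um_to_px(4, cal)
  for (rep in 1:5) {
    labels <- random_disc_mask(64, 64, 2)
    part <- region_partition(labels, cal)
    oc <- oracle_partition(labels, 7, buffer_px)
    expect_identical(part$region == "periphery_inner", oc$inner)
    expect_identical(part$region == "periphery_outer", oc$outer)
    expect_identical(part$region == "interior", oc$interior)
    expect_identical(part$intertumoral_mask, oc$intertumoral)
  }
})

test_that("intertumoral region of an empty mask is the whole frame", {
  labels <- matrix(0L, 64, 64)
  it <- intertumoral_region(labels, frame_area_um2 = 338511.7)
  expect_true(all(it$intertumoral_mask))
  expect_equal(it$tumor_free_area_um2, 338511.7)
})

test_that("tumor-free area is the frame minus the lesion area", {
  labels <- make_disc(64, 64, 32, 32, 10)
  it <- intertumoral_region(labels)
  expect_equal(it$tumor_free_area_um2,
               px_to_um2(64 * 64) - px_to_um2(sum(labels > 0)))
  expect_error(intertumoral_region(labels, buffer_um = -1), ">= 0")
})

test_that("the 4-um buffer excludes points below and keeps points above it", {
  cal <- calibration(0.568)
  labels <- matrix(0L, 64, 64); labels[30, 30] <- 1L  # pixel (29,29) 0-based
  d_lo <- distance_to_nearest_lesion(labels, cbind(29, 29 + 3.9 / 0.568), cal)
  d_hi <- distance_to_nearest_lesion(labels, cbind(29, 29 + 4.1 / 0.568), cal)
  expect_lt(d_lo, 4); expect_gt(d_hi, 4)
})

test_that("band and buffer are monotone in their parameters", {
  set.seed(303)
  labels <- random_disc_mask(80, 80, 2)
  p_small <- region_partition(labels, band_width_px = 5)
  p_big <- region_partition(labels, band_width_px = 9)
  band_px <- function(p) sum(p$region %in% c("periphery_inner",
                                             "periphery_outer"))
  expect_gte(band_px(p_big), band_px(p_small))
  i_small <- intertumoral_region(labels, buffer_um = 2)
  i_big <- intertumoral_region(labels, buffer_um = 8)
  expect_true(all(i_small$intertumoral_mask[i_big$intertumoral_mask]))
})

test_that("point-to-lesion distances match spec arithmetic and the brute force", {
  cal <- calibration(0.568)
  labels <- matrix(0L, 64, 64); labels[21, 21] <- 1L  # (20,20) 0-based
  expect_equal(distance_to_nearest_lesion(labels, cbind(20, 30), cal), 5.68)
  expect_equal(distance_to_nearest_lesion(labels, cbind(20, 20), cal), 0)
  set.seed(404)
  labels2 <- random_disc_mask(64, 64, 3)
  pts <- cbind(runif(40, 0, 63), runif(40, 0, 63))
  d_fast <- distance_to_nearest_lesion(labels2, pts, cal)
  d_brute <- vapply(seq_len(nrow(pts)), function(i) {
    pr <- round(pts[i, 1]); pc <- round(pts[i, 2])
    if (labels2[pr + 1, pc + 1] > 0) 0
    else oracle_point_distance(labels2, pts[i, 1], pts[i, 2]) * 0.568
  }, numeric(1))
  expect_equal(d_fast, d_brute, tolerance = 1e-12)
  expect_error(distance_to_nearest_lesion(labels2, cbind(100, 5)),
               "outside frame")
})

test_that("masks survive a TIFF and PNG round trip", {
  labels <- make_disc(32, 32, 15, 15, 6, id = 3L)
  f1 <- tempfile(fileext = ".tiff"); f2 <- tempfile(fileext = ".png")
  write_mask(labels, f1); write_mask(labels, f2)
  expect_identical(read_mask(f1), labels)
  expect_identical(read_mask(f2), labels)
  unlink(c(f1, f2))
})
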