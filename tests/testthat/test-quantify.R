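test_that("density arithmetic: cells per 0.01 mm2", {
  cal <- calibration(1)            # 1 um/px so areas are exact integers
  mask <- matrix(FALSE, 200, 200)
  mask[1:100, 1:200] <- TRUE       # 20,000 px = 0.02 mm2
  cells <- data.frame(x_px = rep(seq(10, 120, 10), 1),
                      y_px = rep(50, 12), class = "MG")
  rec <- region_density(cells, mask, cal, "MG")
  expect_equal(rec$count, 12)
  expect_equal(rec$density_per_0p01mm2, 6.0)
  # empty cell set -> zero density; zero-area region -> error
  rec0 <- region_density(cells[0, ], mask, cal, "MG")
  expect_equal(rec0$density_per_0p01mm2, 0)
  expect_error(region_density(cells, mask & FALSE, cal, "MG"), "zero-area")
})

test_that("between-tumor density uses the tumor-free denominator", {
  cal <- calibration(1)
  labels <- matrix(0L, 100, 100)
  part0 <- region_partition(labels, cal, frame_area_um2 = 1e4)
  cells <- data.frame(x_px = runif(20, 10, 90), y_px = runif(20, 10, 90),
                      class = "MDM")
  rec <- between_tumor_density(cells, part0, "MDM")
  # no tumors: equals the plain frame density
  expect_equal(rec$density_per_0p01mm2, 20 / (1e4 / 1e4))
  expect_equal(between_tumor_density(cells[0, ], part0,
                                     "MDM")$density_per_0p01mm2, 0)
  # with a lesion, numerator counts only intertumoral cells but the
  # denominator keeps the full tumor-free area (no buffer subtracted)
  labels[40:60, 40:60] <- 1L
  part <- region_partition(labels, cal, frame_area_um2 = 1e4)
  rec2 <- between_tumor_density(cells, part, "MDM")
  expect_equal(rec2$area_um2, 1e4 - 21^2)
  inside_cnt <- sum(part$intertumoral_mask[cbind(round(cells$y_px) + 1,
                                                 round(cells$x_px) + 1)])
  expect_equal(rec2$count, inside_cnt)
})

test_that("border-compartment density records its normalizer", {
  cal <- calibration(1)
  cp <- matrix(FALSE, 100, 100); cp[1:50, 1:10] <- TRUE  # 500 px = 500 um2
  cells <- data.frame(x_px = rep(5, 5), y_px = seq(5, 45, 10),
                      class = "BAM_candidate")
  rec <- border_region_density(cells, cp, "cp_area", cal)
  expect_equal(rec$density_per_0p01mm2, 5 / (500 / 1e4))
  expect_equal(rec$normalizer, "cp_area")
  expect_error(border_region_density(cells, cp & FALSE, "tumor_area", cal),
               "no tumor region")
})

test_that("composition fractions and MG/MDM ratio behave as published", {
  cr <- composition_and_ratio(c(MG = 10, MDM = 5))
  expect_equal(unname(cr$fractions), c(2 / 3, 1 / 3))
  expect_equal(cr$ratio, 2.0)
  expect_warning(cr0 <- composition_and_ratio(c(MG = 4, MDM = 0)),
                 "undefined")
  expect_true(is.na(cr0$ratio))
  expect_warning(crz <- composition_and_ratio(c(MG = 0, MDM = 0)),
                 "all-zero")
  expect_true(all(is.na(crz$fractions)))
})

test_that("proliferation fraction is the Ki-67+ share of reporter+ cells", {
  cells <- data.frame(tdT = rep(TRUE, 30), Ki67 = rep(c(TRUE, FALSE),
                                                      c(3, 27)))
  expect_equal(proliferation_fraction(cells), 10)
  cells$Ki67 <- FALSE
  expect_equal(proliferation_fraction(cells), 0)
  expect_warning(pf <- proliferation_fraction(
    data.frame(tdT = FALSE, Ki67 = TRUE)), "undefined")
  expect_true(is.na(pf))
})

test_that("CD206 co-expression fractions partition Iba1+ cells", {
  all_pos <- data.frame(tdT = TRUE, Iba1 = TRUE, CD206 = TRUE)
  expect_equal(unname(cd206_coexpression(all_pos)), c(1, 0, 0, 0))
  four_way <- data.frame(tdT = rep(c(TRUE, TRUE, FALSE, FALSE), 10),
                         Iba1 = TRUE,
                         CD206 = rep(c(TRUE, FALSE, TRUE, FALSE), 10))
  expect_equal(unname(cd206_coexpression(four_way)), rep(0.25, 4))
  expect_equal(sum(cd206_coexpression(four_way)), 1)
  expect_warning(cd206_coexpression(
    data.frame(tdT = TRUE, Iba1 = FALSE, CD206 = TRUE)), "no Iba1")
})

test_that("per-mouse aggregation pools counts over areas", {
  rec <- function(mouse, section, count, area) {
    data.frame(mouse_id = mouse, section_id = section,
               region_kind = "periphery", size_class = "small",
               tam_class = "MG", count = count, area_um2 = area,
               density_per_0p01mm2 = count / (area / 1e4))
  }
  # one section per mouse: identity
  one <- rec("m1", "s1", 8, 2e4)
  expect_equal(per_mouse_aggregate(one)$density_per_0p01mm2, 4)
  # two equal-area sections with densities 4 and 6 -> 5
  two <- rbind(rec("m1", "s1", 4, 1e4), rec("m1", "s2", 6, 1e4))
  expect_equal(per_mouse_aggregate(two)$density_per_0p01mm2, 5)
  # unequal areas: ratio of sums differs from mean of ratios
  uneq <- rbind(rec("m1", "s1", 2, 1e4),   # density 2
                rec("m1", "s2", 12, 4e4))  # density 3
  expect_equal(per_mouse_aggregate(uneq)$density_per_0p01mm2, 2.8)
  expect_equal(per_mouse_aggregate(uneq,
                                   "mean_of_ratios")$density_per_0p01mm2,
               2.5)
  dup <- rbind(rec("m1", "s1", 1, 1e4), rec("m1", "s1", 2, 1e4))
  expect_error(per_mouse_aggregate(dup), "duplicate")
})

test_that("whole-tumor records are additive over interior and periphery", {
  ints <- rbind(MG = c(nontumor = 20, periphery = 60, interior = 30),
                MDM = c(nontumor = 5, periphery = 10, interior = 10))
  sp <- section_spec(frame_shape_px = c(256, 256),
                     frame_area_um2 = 256 * 256 * 0.5681818^2,
                     tumors = list(tumor_spec("disc", c(70, 70), 25),
                                   tumor_spec("disc", c(180, 180), 13)),
                     intensity = ints, seed = 21)
  sec <- make_section(sp)
  cls <- classify_cells(sec$cells, "cx3cr1creer", "parenchyma")
  q <- quantify_section(
    list(labels = sec$mask,
         lesions = label_tumors(sec$mask, sec$cal, 0,
                                relabel = FALSE)$lesions),
    cls, sec$cal, sp$bins, mouse_id = "m1", section_id = "s1")
  lr <- q$lesion_records
  for (id in unique(lr$lesion_id)) for (cl in unique(lr$tam_class)) {
    sub <- lr[lr$lesion_id == id & lr$tam_class == cl, ]
    expect_equal(sub$count[sub$region_kind == "whole_tumor"],
                 sub$count[sub$region_kind == "interior"] +
                   sub$count[sub$region_kind == "periphery"])
    expect_equal(sub$area_px[sub$region_kind == "whole_tumor"],
                 sub$area_px[sub$region_kind == "interior"] +
                   sub$area_px[sub$region_kind == "periphery"])
  }
  # every cell in a tumor region is attributed to exactly one lesion
  expect_equal(sum(lr$count[lr$region_kind == "whole_tumor"]),
               sum(cls$true_region %in% c("interior", "periphery")))
})
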