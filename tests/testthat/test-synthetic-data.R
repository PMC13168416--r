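small_spec <- function(seed = 1, intensity = default_intensity_microtumor(),
                       tumors = list(tumor_spec("disc", c(40, 40), 13,
                                                "small")),
                       ...) {
  section_spec(frame_shape_px = c(128, 128),
               frame_area_um2 = 128 * 128 * 0.5681818^2,
               tumors = tumors, intensity = intensity, seed = seed, ...)
}

test_that("zero intensity yields an empty cell table but intact mask", {
  ints <- default_intensity_microtumor() * 0
  sec <- make_section(small_spec(intensity = ints))
  expect_equal(nrow(sec$cells), 0L)
  expect_gt(sum(sec$mask > 0), 0)
})

test_that("a rendered disc's area is within 2% of pi r^2", {
  sp <- section_spec(frame_shape_px = c(128, 128),
                     frame_area_um2 = 128 * 128 * 0.5681818^2,
                     tumors = list(tumor_spec("disc", c(63.5, 63.5), 30)),
                     seed = 1)
  sec <- make_section(sp)
  expect_equal(sum(sec$mask == 1), pi * 30^2, tolerance = 0.02)
})

test_that("cell counts are Poisson with the programmed mean", {
  # no tumors: the whole frame is intertumoral; lambda = 50 * area / 0.01mm2
  ints <- rbind(MG = c(nontumor = 50, periphery = 0, interior = 0))
  counts <- vapply(1:200, function(s) {
    sec <- make_section(small_spec(seed = s, intensity = ints,
                                   tumors = list()))
    nrow(sec$cells)
  }, numeric(1))
  lambda <- 50 * px_to_um2(128 * 128) / 1e4
  expect_gt(lambda, 20)
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("identical spec and seed reproduce byte-identical sections", {
  a <- make_section(small_spec(seed = 7))
  b <- make_section(small_spec(seed = 7))
  expect_identical(a$mask, b$mask)
  expect_identical(a$cells, b$cells)
  c2 <- make_section(small_spec(seed = 8))
  expect_false(identical(a$cells, c2$cells))
})

test_that("marker assignment round-trips through classification for every model", {
  cases <- list(c("cx3cr1creer", "parenchyma"),
                c("cx3cr1creer", "ventricle_cp"),
                c("ms4a3", "parenchyma"),
                c("ms4a3", "leptomeninges"),
                c("sall1", "parenchyma"),
                c("lyve1", "leptomeninges"))
  for (cs in cases) {
    border <- cs[2] != "parenchyma"
    ints <- if (cs[1] == "sall1")
      rbind(MG = c(nontumor = 30, periphery = 30, interior = 30),
            MDM = c(nontumor = 20, periphery = 20, interior = 20))
    else if (border)
      rbind(BAM_candidate = c(nontumor = 30, periphery = 30, interior = 30),
            MDM = c(nontumor = 20, periphery = 20, interior = 20))
    else
      rbind(MG = c(nontumor = 30, periphery = 30, interior = 30),
            MDM = c(nontumor = 20, periphery = 20, interior = 20))
    sec <- make_section(small_spec(seed = 3, intensity = ints,
                                   mouse_model = cs[1], compartment = cs[2]))
    cls <- classify_cells(sec$cells, cs[1], cs[2])
    expect_equal(mean(cls$class == cls$true_class), 1,
                 info = paste(cs, collapse = "/"))
  }
})

test_that("overlapping tumors and super-saturating intensities are rejected", {
  sp <- small_spec(tumors = list(tumor_spec("disc", c(40, 40), 13),
                                 tumor_spec("disc", c(45, 45), 13)))
  expect_error(make_section(sp), "overlap|merge")
  dense <- default_intensity_microtumor()
  dense["MG", "nontumor"] <- 1e9
  expect_error(make_section(small_spec(intensity = dense)),
               "one cell per pixel")
})

test_that("a tumor missing its target size class is rejected", {
  sp <- small_spec(tumors = list(tumor_spec("disc", c(60, 60), 30, "small")))
  expect_error(make_section(sp), "targeted size class")
})

test_that("ground-truth columns are present and never used by classification", {
  sec <- make_section(small_spec(seed = 5))
  expect_true(all(c("true_class", "true_region") %in% names(sec$cells)))
  shuffled <- sec$cells
  shuffled$true_class <- rev(shuffled$true_class)
  cls <- classify_cells(shuffled, "cx3cr1creer", "parenchyma")
  expect_identical(cls$class,
                   classify_cells(sec$cells, "cx3cr1creer",
                                  "parenchyma")$class)
})

test_that("channel rendering is empty, peaked and linear as expected", {
  cells0 <- data.frame(x_px = numeric(), y_px = numeric(), tdT = logical(),
                       GFP = logical(), Iba1 = logical())
  expect_true(all(render_channels(c(32, 32), cells0) == 0))
  one <- data.frame(x_px = 10, y_px = 20, tdT = TRUE, GFP = FALSE,
                    Iba1 = TRUE)
  ch <- render_channels(c(32, 32), one)
  peak <- which(ch[, , "tdT"] == max(ch[, , "tdT"]), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(21, 11))  # 1-based (row, col)
  expect_true(all(ch[, , "GFP"] == 0))
  two <- rbind(one, transform(one, x_px = 11))
  ch2 <- render_channels(c(32, 32), two)
  ch_a <- render_channels(c(32, 32), one)
  ch_b <- render_channels(c(32, 32), transform(one, x_px = 11))
  expect_equal(ch2[, , "tdT"], ch_a[, , "tdT"] + ch_b[, , "tdT"])
  expect_error(render_channels(c(32, 32), transform(one, x_px = 50)),
               "outside frame")
})

test_that("flow events honor degenerate weights and zero dispersion", {
  sp <- flow_spec(n_events = 500, weights = c(Q3i = 1), seed = 2)
  ev <- make_flow_events(sp)
  expect_true(all(ev$true_pop == "Q3i"))
  sp0 <- flow_spec(n_events = 100, dispersion = 0, seed = 2)
  ev0 <- make_flow_events(sp0)
  med <- default_flow_medians()
  for (ch in colnames(med))
    expect_identical(ev0[[ch]], unname(med[ev0$true_pop, ch]))
  expect_error(flow_spec(n_events = 0), "positive")
})

test_that("flow label fractions match the weights within binomial 3 SE", {
  sp <- flow_spec(n_events = 20000, seed = 9)
  ev <- make_flow_events(sp)
  w <- default_flow_weights()
  for (pop in names(w)) {
    phat <- mean(ev$true_pop == pop)
    se <- sqrt(w[[pop]] * (1 - w[[pop]]) / 20000)
    expect_lt(abs(phat - w[[pop]]), 3 * se + 1e-12)
  }
})

test_that("FMO tables replace only the requested channel with background", {
  sp <- flow_spec(n_events = 5000, seed = 4)
  fmo <- make_flow_events(sp, fmo_channel = "CD38")
  bg <- default_fmo_background()[["CD38"]]
  expect_equal(median(fmo$CD38), bg, tolerance = 0.01)
  expect_gt(median(fmo$CD11b), 1000)   # other channels untouched
  expect_equal(unique(fmo$fmo_channel), "CD38")
})
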