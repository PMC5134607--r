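test_that("load_image_series sorts by timestamp and skips unparseable names", {
  dir <- withr::local_tempdir()
  # written out of order; loader must sort
  stamps <- c("site_2015_05_07_1600", "site_2015_05_07_0800",
              "site_2015_05_07_1200")
  for (s in stamps) {
    png::writePNG(array(0.5, c(2, 2, 3)), file.path(dir, paste0(s, ".png")))
  }
  idx <- load_image_series(dir)
  expect_equal(nrow(idx), 3)
  expect_true(!is.unsorted(idx$time))
  expect_equal(attr(idx, "n_skipped"), 0)

  png::writePNG(array(0.5, c(2, 2, 3)), file.path(dir, "site_badstamp.png"))
  expect_warning(idx2 <- load_image_series(dir), "unparseable")
  expect_equal(nrow(idx2), 3)
  expect_equal(attr(idx2, "n_skipped"), 1)

  expect_error(load_image_series(withr::local_tempdir()), "empty")
})

test_that("five frames per day over two days index to ten images", {
  dir <- withr::local_tempdir()
  spec <- scene_spec(3, 3, matrix(1L, 3, 3),
                     classes = list(flat = list(type = "flat", level = 0.33)),
                     days = 10:11, images_per_day = 5L, seed = 1)
  render_scene(spec, dir)
  idx <- load_image_series(dir)
  expect_equal(nrow(idx), 10)
  expect_equal(sort(unique(floor(idx$doy))), c(10, 11))
})

test_that("axis-aligned square mask covers exactly its pixel grid", {
  roi <- build_roi_mask(rbind(c(0, 0), c(0, 9), c(9, 9), c(9, 0)), 20, 20)
  expect_equal(sum(roi$mask), 100)
  expect_true(all(roi$mask[1:10, 1:10]))
})

test_that("polygon masks agree with a brute-force point-in-polygon oracle", {
  set.seed(42)
  for (i in 1:8) {
    h <- sample(8:14, 1); w <- sample(8:14, 1)
    # random star-shaped polygon around the image centre
    k <- sample(3:7, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    rad <- runif(k, 1.5, min(h, w) / 2 - 0.5)
    verts <- cbind(row = (h - 1) / 2 + rad * sin(ang),
                   col = (w - 1) / 2 + rad * cos(ang))
    verts <- pmin(pmax(verts, 0), cbind(rep(h - 1, k), rep(w - 1, k)))
    roi <- try(build_roi_mask(verts, h, w), silent = TRUE)
    if (inherits(roi, "try-error")) next  # degenerate random draw
    expect_identical(roi$mask, oracle_roi_mask(verts, h, w))
  }
})

test_that("degenerate polygons are rejected", {
  expect_error(build_roi_mask(rbind(c(1, 1), c(2, 2), c(3, 3)), 10, 10),
               "degenerate")
  expect_error(build_roi_mask(rbind(c(1, 1), c(2, 2)), 10, 10), "3 vertices")
})

test_that("ROI vertex files round-trip bit-exactly", {
  roi <- build_roi_mask(rbind(c(0.25, 1), c(0, 7.125), c(6, 6), c(5, 0.5)),
                        10, 10, name = "veg patch")
  path <- withr::local_tempfile(fileext = ".roi")
  write_roi(roi, path)
  back <- read_roi(path)
  expect_identical(names(back), "veg patch")
  expect_identical(unname(back[["veg patch"]]), unname(unclass(roi$vertices)))
})

test_that("chromatic coordinates follow the channel-share definition", {
  roi <- full_roi()
  cc <- extract_chromatic(make_frame(100, 150, 50), roi)
  expect_equal(cc$gcc, 0.5)
  expect_equal(cc$rcc, 1 / 3)
  expect_equal(cc$bcc, 1 / 6)
  # gray frame: all shares one third
  gray <- extract_chromatic(make_frame(80, 80, 80), roi)
  expect_equal(gray$gcc, 1 / 3)
  expect_equal(gray$gcc + gray$rcc + gray$bcc, 1, tolerance = 1e-9)
})

test_that("roi-average convention is ratio of means, with mean of ratios as option", {
  fr <- make_frame(10, 10, 10, h = 2, w = 2)
  fr$pixels[1, 1, ] <- c(30, 60, 10)
  fr$pixels[1, 2, ] <- c(90, 20, 40)
  # thin polygon covering only the first pixel row
  roi <- build_roi_mask(rbind(c(0, 0), c(0, 1), c(0.5, 1), c(0.5, 0)), 2, 2)
  expect_equal(sum(roi$mask), 2)
  rom <- extract_chromatic(fr, roi, average = "ratio-of-means")
  expect_equal(rom$gcc, (60 + 20) / (100 + 150))
  mor <- extract_chromatic(fr, roi, average = "mean-of-ratios")
  expect_equal(mor$gcc, mean(c(0.6, 2 / 15)))
  pp <- extract_chromatic(fr, roi, scope = "per-pixel")
  expect_equal(sort(pp$gcc), sort(c(0.6, 2 / 15)))
})

test_that("zero-DN pixels are excluded and an all-zero ROI yields a missing sample", {
  fr <- make_frame(30, 60, 10, h = 2, w = 2)
  fr$pixels[1, 1, ] <- 0L
  roi <- full_roi(2, 2)
  cc <- suppressMessages(extract_chromatic(fr, roi))
  expect_equal(cc$n_pixels, 3L)
  expect_equal(cc$n_zero, 1L)
  expect_equal(cc$gcc, 0.6)
  dark <- suppressMessages(extract_chromatic(make_frame(0, 0, 0), full_roi()))
  expect_true(is.na(dark$gcc))
  expect_equal(dark$n_pixels, 0L)
})

test_that("chromatic coordinates are invariant to brightness scaling", {
  roi <- full_roi()
  for (k in c(2L, 3L)) {
    a <- extract_chromatic(make_frame(20, 40, 15), roi)
    b <- extract_chromatic(make_frame(20 * k, 40 * k, 15 * k), roi)
    expect_equal(a[c("gcc", "rcc", "bcc")], b[c("gcc", "rcc", "bcc")],
                 tolerance = 1e-12)
  }
})

test_that("extract_series produces a normalized, time-ordered sub-daily series", {
  dir <- withr::local_tempdir()
  spec <- scene_spec(4, 4, matrix(1L, 4, 4),
                     classes = list(flat = list(type = "flat", level = 0.34)),
                     days = 5:7, images_per_day = 3L, noise_sigma = 0,
                     seed = 2)
  render_scene(spec, dir)
  idx <- load_image_series(dir)
  roi <- full_roi(4, 4)
  ser <- extract_series(idx, roi)
  expect_equal(nrow(ser), 9)
  expect_true(all(abs(ser$gcc + ser$rcc + ser$bcc - 1) < 1e-9))
  expect_true(!is.unsorted(ser$doy))
  expect_lt(max(abs(ser$gcc - 0.34)), 1 / 255)
})
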