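test_that("blank images yield zero nuclei without error", {
  seg <- segment_nuclei(matrix(100L, 64, 64), pixel_size = 0.325)
  expect_equal(nrow(seg$measurements), 0)
  expect_true(all(seg$labels == 0))
})

test_that("segmentation recovers 50 rendered nuclei against ground truth", {
  cells <- grid_cells(50, seed = 7)
  # noise sd = 2% of typical signal
  f <- render_field(cells, dims = grid_dims(50), noise_sd = 0.02 * 3000,
                    seed = 1)
  seg <- segment_nuclei(f$channels$GFP, f$pixel_size,
                        channels = list(GFP = f$channels$GFP))
  m <- seg$measurements
  expect_equal(nrow(m), 50)
  d2 <- outer(m$centroid_x, cells$x, "-")^2 +
    outer(m$centroid_y, cells$y, "-")^2
  nearest <- apply(d2, 1, which.min)
  expect_true(all(!duplicated(nearest)))
  expect_lt(max(sqrt(apply(d2, 1, min))), 2)
  rel <- abs(m$pixel_count - f$truth$area_px[nearest]) /
    f$truth$area_px[nearest]
  expect_lt(max(rel), 0.05)
  # measured mean GFP close to each cell's base intensity
  expect_lt(max(abs(m$mean_gfp - (cells$gfp[nearest] + 100)) /
                  cells$gfp[nearest]), 0.1)
})

test_that("measured area matches the analytic ellipse area", {
  cell <- data.frame(cell_id = 1, x = 100, y = 100, a_px = 30, b_px = 20,
                     theta = 0.3, gfp = 3000, bfp_ln = 0, mifp = 0)
  f <- render_field(cell, dims = c(200, 200), seed = 1)
  seg <- segment_nuclei(f$channels$GFP, 0.325)
  analytic <- pi * 30 * 20 * 0.325^2  # 199.1 um^2
  expect_equal(nrow(seg$measurements), 1)
  expect_lt(abs(seg$measurements$area_um2 - analytic) / analytic, 0.05)
})

test_that("area is invariant under translation and 90-degree rotation", {
  cell <- data.frame(cell_id = 1, x = 80, y = 60, a_px = 24, b_px = 15,
                     theta = 0.9, gfp = 3000, bfp_ln = 0, mifp = 0)
  f <- render_field(cell, dims = c(160, 160), noise_sd = 0, seed = 1)
  base <- segment_nuclei(f$channels$GFP, 0.325)$measurements$pixel_count
  shifted <- cell; shifted$x <- 95; shifted$y <- 85
  fs <- render_field(shifted, dims = c(160, 160), noise_sd = 0, seed = 1)
  px_s <- segment_nuclei(fs$channels$GFP, 0.325)$measurements$pixel_count
  rot <- t(f$channels$GFP)[ncol(f$channels$GFP):1, ]
  px_r <- segment_nuclei(rot, 0.325)$measurements$pixel_count
  expect_lte(abs(px_s - base), 1)
  expect_lte(abs(px_r - base), 1)
})

test_that("control size threshold uses interpolated quantiles", {
  expect_equal(size_threshold_from_controls(1:1000, 0.005), 995.005)
  expect_equal(size_threshold_from_controls(rep(7, 50), 0.005), 7)
  expect_error(size_threshold_from_controls(numeric(), 0.005), "empty")
  expect_error(size_threshold_from_controls(1:10, 0), "top_fraction")
  # calibrated baseline reproduces the 1,000 um^2 screening threshold
  ba <- baseline_area_default()
  lp <- optenrich:::.lnorm_pars(ba[["mean"]], ba[["sd"]])
  set.seed(31)
  thr <- size_threshold_from_controls(stats::rlnorm(2e5, lp$meanlog,
                                                    lp$sdlog), 0.005)
  expect_lt(abs(thr - 1000) / 1000, 0.02)
})

test_that("threshold is monotone and never grows when adding small values", {
  set.seed(12)
  for (i in 1:20) {
    areas <- stats::rlnorm(500, 5.3, 0.6)
    thr <- size_threshold_from_controls(areas, 0.02)
    # monotone non-decreasing in any element
    bumped <- areas
    j <- sample(500, 1)
    bumped[j] <- bumped[j] * 2
    expect_gte(size_threshold_from_controls(bumped, 0.02), thr)
    # appending values below the threshold cannot raise it
    low <- stats::runif(50, 0, thr * 0.9)
    expect_lte(size_threshold_from_controls(c(areas, low), 0.02), thr)
  }
})

test_that("filters partition nuclei into selected/negative/rejected", {
  cfg <- filter_config(min_area = 40, max_area = 4000,
                       bfp_ln_threshold = 7.6, size_threshold = 1000)
  m <- data.frame(
    area_um2 = c(1200, 900, 1200, 5000, 1200),
    bfp_ln = c(8.0, 8.0, 7.0, 8.0, 8.0),
    touches_border = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- apply_filters(m, cfg)
  expect_equal(as.character(out$class),
               c("selected", "negative", "rejected", "rejected", "rejected"))
  expect_match(out$reasons[3], "BFP_LOW")
  expect_match(out$reasons[4], "AREA_RANGE")
  expect_match(out$reasons[5], "BORDER")
  # partition is exhaustive and disjoint
  expect_false(anyNA(out$class))
  # mean_bfp column works as the gate input too
  m2 <- data.frame(area_um2 = 1200, mean_bfp = exp(8), touches_border = FALSE)
  expect_equal(as.character(apply_filters(m2, cfg)$class), "selected")
  expect_error(filter_config(min_area = 100, max_area = 50), "min_area")
})
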