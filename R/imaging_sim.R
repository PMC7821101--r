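# Synthetic multi-channel fields of view with ground truth.
#
# Nuclei are rendered as uniform-intensity filled ellipses (optionally with a
# 1 px Gaussian edge blur) on a camera background; the ground-truth label
# mask is always the exact raster, so segmentation can be scored against it.

#' Plan an acquisition over wells
#'
#' Fields of view are laid out on an `grid_n` x `grid_n` grid per well and
#' visited in deterministic serpentine order (odd rows left-to-right, even
#' rows right-to-left), as a stage would.
#'
#' @param wells character vector of well names.
#' @param grid_n grid side; `fields_per_well = grid_n^2` (64 for an 8x8 day
#'   run, 81 for a 9x9 night run).
#' @param exposures named numeric vector of per-channel exposure times (ms).
#' @return object of class `acquisition_plan`: list with `fields` (data.frame
#'   `well, field, row, col`), `fields_per_well`, `exposures`.
#' @export
plan_acquisition <- function(wells, grid_n,
                             exposures = c(GFP = 500, mCherry = 100,
                                           mIFP = 1000)) {
  grid_n <- .check_count(grid_n, "grid_n", min = 1L)
  rows <- rep(seq_len(grid_n), each = grid_n)
  cols <- unlist(lapply(seq_len(grid_n), function(r)
    if (r %% 2 == 1) seq_len(grid_n) else rev(seq_len(grid_n))))
  per_well <- data.frame(field = seq_len(grid_n^2), row = rows, col = cols)
  fields <- do.call(rbind, lapply(wells, function(w)
    cbind(well = w, per_well, stringsAsFactors = FALSE)))
  structure(list(fields = fields, fields_per_well = grid_n^2,
                 exposures = exposures),
            class = "acquisition_plan")
}

# raster of one ellipse within the field; returns integer pixel indices
.ellipse_pixels <- function(cx, cy, a, b, theta, h, w) {
  r <- max(a, b)
  x0 <- max(0L, floor(cx - r)); x1 <- min(w - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(h - 1L, ceiling(cy + r))
  if (x1 < x0 || y1 < y0) return(integer())
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(ys * 0, xs - cx, `+`)
  dy <- outer(ys - cy, xs * 0, `+`)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u * u + v * v <= 1
  # row-major pixel (x, y), 0-based; matrix storage is [y + 1, x + 1]
  row_idx <- outer(ys, xs * 0, `+`)[inside] + 1L
  col_idx <- outer(ys * 0, xs, `+`)[inside] + 1L
  (col_idx - 1L) * h + row_idx
}

#' Render a synthetic field of view
#'
#' Renders each cell's nucleus as a filled ellipse at its base GFP intensity;
#' BFP and mIFP channels are rendered only for cells carrying those markers
#' (`bfp_ln` > 0, `mifp` > 0). The PA-mCherry channel is flat pre-activation
#' background. The returned label mask is the exact raster (no blur, no
#' noise). Cells without `x`/`y` columns are laid out on a jittered grid.
#'
#' @param cells data.frame of cell records (see [simulate_population()]);
#'   optional columns `x`, `y` give nucleus centers in 0-based pixel units.
#' @param dims `c(height, width)` in pixels.
#' @param pixel_size um per pixel.
#' @param noise_sd Gaussian read-noise standard deviation (camera units);
#'   0 disables.
#' @param poisson if TRUE, replace each signal pixel by a Poisson draw.
#' @param edge_blur_px Gaussian edge blur sigma applied to signal channels
#'   (0 disables; the label mask is never blurred).
#' @param background camera offset added to every channel.
#' @param max_overlap overlap fraction above which a cell is flagged
#'   `overlap_warn` in the truth table (a warning, not an error).
#' @param field_id list or vector identifying the field (well, row, col).
#' @param seed RNG seed (noise and layout jitter).
#' @return object of class `image_field`: list with `channels` (named list of
#'   integer matrices: GFP, BFP, mIFP, PAmCherry), `labels` (integer matrix,
#'   background 0), `truth` (data.frame `cell_id, label, x, y, area_px,
#'   overlap_warn`), `pixel_size`, `field_id`.
#' @export
render_field <- function(cells, dims = c(512L, 512L), pixel_size = 0.325,
                         noise_sd = 0, poisson = FALSE, edge_blur_px = 1,
                         background = 100, max_overlap = 0.1,
                         field_id = "F1", seed = NULL) {
  if (any(dims <= 0)) .stopf("dims must be positive")
  if (pixel_size <= 0) .stopf("pixel_size must be > 0")
  .set_seed(seed)
  h <- as.integer(dims[1]); w <- as.integer(dims[2])
  n <- nrow(cells)

  if (n > 0 && (is.null(cells$x) || is.null(cells$y))) {
    # jittered grid layout; dense fields may overlap, which is flagged per
    # cell in the truth table rather than treated as an error
    margin <- min(max(cells$a_px, 1) + 2, min(h, w) / 4)
    gw <- max(w - 2 * margin, 1); gh <- max(h - 2 * margin, 1)
    k <- ceiling(sqrt(n))
    if (min(gw, gh) / k < 4)
      .stopf("%d cells do not fit a %dx%d field", n, h, w)
    slots <- sample.int(k * k, n)
    cells$x <- margin + (((slots - 1L) %% k) + 0.5) / k * gw +
      stats::runif(n, -0.2, 0.2) * gw / k
    cells$y <- margin + (((slots - 1L) %/% k) + 0.5) / k * gh +
      stats::runif(n, -0.2, 0.2) * gh / k
  }

  labels <- matrix(0L, h, w)
  gfp <- matrix(0, h, w); bfp <- matrix(0, h, w); mifp <- matrix(0, h, w)
  overlap_warn <- logical(n)
  area_px <- integer(n)
  for (i in seq_len(n)) {
    px <- .ellipse_pixels(cells$x[i], cells$y[i], cells$a_px[i], cells$b_px[i],
                          cells$theta[i], h, w)
    area_px[i] <- length(px)
    if (length(px) == 0) next
    taken <- labels[px] != 0L
    if (mean(taken) > max_overlap) overlap_warn[i] <- TRUE
    free <- px[!taken]
    labels[free] <- i
    gfp[free] <- cells$gfp[i]
    if (!is.null(cells$bfp_ln) && is.finite(cells$bfp_ln[i]) &&
        cells$bfp_ln[i] > 0) bfp[free] <- exp(cells$bfp_ln[i])
    if (!is.null(cells$mifp) && cells$mifp[i] > 0) mifp[free] <- cells$mifp[i]
  }

  finish <- function(signal) {
    if (edge_blur_px > 0 && n > 0)
      signal <- as.matrix(EBImage::gblur(signal, sigma = edge_blur_px))
    img <- signal + background
    if (poisson) img <- matrix(stats::rpois(h * w, pmax(img, 0)), h, w)
    if (noise_sd > 0) img <- img + stats::rnorm(h * w, 0, noise_sd)
    matrix(as.integer(pmin(pmax(round(img), 0), 65535L)), h, w)
  }
  channels <- list(GFP = finish(gfp), BFP = finish(bfp), mIFP = finish(mifp),
                   PAmCherry = finish(matrix(0, h, w)))

  truth <- data.frame(cell_id = if (n > 0) cells$cell_id else integer(),
                      label = seq_len(n),
                      x = if (n > 0) cells$x else numeric(),
                      y = if (n > 0) cells$y else numeric(),
                      area_px = area_px, overlap_warn = overlap_warn)
  structure(list(channels = channels, labels = labels, truth = truth,
                 pixel_size = pixel_size, field_id = field_id),
            class = "image_field")
}

#' Write / read an image field as per-channel 16-bit TIFFs
#'
#' One grayscale TIFF per channel named `{prefix}_{channel}.tif`, the label
#' mask as `{prefix}_labels.tif`, and the truth table as `{prefix}_truth.tsv`.
#' Pixel values round-trip bit-exactly.
#'
#' @param field an `image_field`.
#' @param dir output directory.
#' @param prefix filename prefix, e.g. `"A1_3"` for well A1 field 3.
#' @return the prefix path invisibly (writer); an `image_field` (reader).
#' @export
write_field <- function(field, dir, prefix) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, prefix)
  for (ch in names(field$channels))
    tiff::writeTIFF(field$channels[[ch]] / 65535, sprintf("%s_%s.tif", base, ch),
                    bits.per.sample = 16L)
  tiff::writeTIFF(field$labels / 65535, sprintf("%s_labels.tif", base),
                  bits.per.sample = 16L)
  write_tsv(field$truth, sprintf("%s_truth.tsv", base))
  invisible(base)
}

#' @rdname write_field
#' @param channels channel names to read back.
#' @param pixel_size um per pixel to attach.
#' @export
read_field <- function(dir, prefix, channels = c("GFP", "BFP", "mIFP",
                                                 "PAmCherry"),
                       pixel_size = 0.325) {
  base <- file.path(dir, prefix)
  rd <- function(p) {
    m <- tiff::readTIFF(p)
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  }
  chs <- lapply(sprintf("%s_%s.tif", base, channels), rd)
  names(chs) <- channels
  structure(list(channels = chs, labels = rd(sprintf("%s_labels.tif", base)),
                 truth = read_tsv(sprintf("%s_truth.tsv", base)),
                 pixel_size = pixel_size, field_id = prefix),
            class = "image_field")
}
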