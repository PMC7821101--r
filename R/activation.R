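# Patterned-illumination activation plans (the DMD frame analog) and the
# PA-mCherry photoactivation response model.
#
# Response model: saturating first-order kinetics
#   I(t) = background + (i_max - background) * (1 - exp(-t / tau)),
# with multiplicative log-normal noise of coefficient of variation
# `noise_cv`. The expected intensity is strictly increasing in exposure and
# saturates at i_max, which is all the method requires: distinct exposure
# classes map to FACS-separable intensity populations.

#' PA-mCherry activation response parameters
#'
#' @param i_max saturation intensity (camera units).
#' @param tau_ms activation time constant (ms).
#' @param background non-activated intensity (camera units).
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   intensity noise.
#' @return object of class `activation_response`.
#' @export
activation_response <- function(i_max = 1500, tau_ms = 800, background = 10,
                                noise_cv = 0.15) {
  if (!(i_max > background) || background < 0) .stopf("need i_max > background >= 0")
  if (tau_ms <= 0) .stopf("tau_ms must be > 0")
  if (noise_cv < 0) .stopf("noise_cv must be >= 0")
  structure(list(i_max = i_max, tau_ms = tau_ms, background = background,
                 noise_cv = noise_cv), class = "activation_response")
}

#' Expected activation intensity at an exposure
#' @param exposure_ms exposure duration(s), ms.
#' @param response an [activation_response()].
#' @return expected mCherry intensity (camera units).
#' @export
activation_mean <- function(exposure_ms, response) {
  if (any(exposure_ms < 0)) .stopf("exposure must be >= 0")
  response$background +
    (response$i_max - response$background) *
    (1 - exp(-exposure_ms / response$tau_ms))
}

#' Build a patterned-illumination activation plan
#'
#' Produces one binary mask per exposure class. Each selected nucleus
#' contributes its footprint eroded by `erode_px` (a conservative spill-over
#' guard), so no mask pixel ever touches an unselected nucleus and masks for
#' different exposure classes are disjoint.
#'
#' @param labels integer label mask from [segment_nuclei()] or an
#'   `image_field` ground truth.
#' @param positive_labels labels to activate at `pos_ms`.
#' @param negative_labels labels to activate at `neg_ms` (true-negative
#'   marking in dual-activation screens); may be empty.
#' @param pos_ms,neg_ms exposure durations (ms); defaults 2000/100 as in the
#'   dual-activation design.
#' @param erode_px erosion margin in px.
#' @return object of class `activation_plan`: list with `assignments`
#'   (data.frame `label, exposure_ms`) and `masks` (named list of logical
#'   matrices keyed by exposure duration).
#' @export
make_activation_plan <- function(labels, positive_labels,
                                 negative_labels = integer(),
                                 pos_ms = 2000, neg_ms = 100, erode_px = 1) {
  positive_labels <- as.integer(positive_labels)
  negative_labels <- as.integer(negative_labels)
  if (length(intersect(positive_labels, negative_labels)) > 0)
    .stopf("positive and negative label sets overlap")
  present <- sort(unique(labels[labels > 0L]))
  unknown <- setdiff(c(positive_labels, negative_labels), present)
  if (length(unknown) > 0)
    .stopf("unknown labels: %s", paste(unknown, collapse = ","))

  class_mask <- function(lab_set) {
    h <- nrow(labels); w <- ncol(labels)
    mask <- matrix(FALSE, h, w)
    if (length(lab_set) == 0) return(mask)
    if (erode_px == 0) {
      mask[labels %in% lab_set] <- TRUE
      return(mask)
    }
    brush <- EBImage::makeBrush(2L * erode_px + 1L, shape = "box")
    for (l in lab_set) {
      pos <- which(labels == l)
      if (length(pos) == 0) next
      ri <- ((pos - 1L) %% h) + 1L; ci <- ((pos - 1L) %/% h) + 1L
      r0 <- max(1L, min(ri) - erode_px); r1 <- min(h, max(ri) + erode_px)
      c0 <- max(1L, min(ci) - erode_px); c1 <- min(w, max(ci) + erode_px)
      sub <- labels[r0:r1, c0:c1, drop = FALSE] == l
      er <- as.matrix(EBImage::erode(EBImage::Image(sub * 1), brush)) > 0
      mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | er
    }
    mask
  }

  masks <- list()
  masks[[as.character(pos_ms)]] <- class_mask(positive_labels)
  if (length(negative_labels) > 0)
    masks[[as.character(neg_ms)]] <- class_mask(negative_labels)

  assignments <- data.frame(
    label = c(positive_labels, negative_labels),
    exposure_ms = c(rep(pos_ms, length(positive_labels)),
                    rep(neg_ms, length(negative_labels))))
  structure(list(assignments = assignments, masks = masks),
            class = "activation_plan")
}

#' Simulate photoactivated mCherry intensities
#'
#' Unplanned cells (exposure 0) sit at background. The expected intensity is
#' strictly increasing in exposure and deterministic given the seed.
#'
#' @param exposure_ms numeric vector of per-cell exposures (ms), 0 for cells
#'   not in any mask.
#' @param response an [activation_response()].
#' @param seed RNG seed.
#' @return numeric vector of mCherry intensities.
#' @export
photoactivate <- function(exposure_ms, response, seed = NULL) {
  stopifnot(inherits(response, "activation_response"))
  mu <- activation_mean(exposure_ms, response)
  if (response$noise_cv == 0) return(mu)
  .set_seed(seed)
  s <- sqrt(log1p(response$noise_cv^2))
  mu * stats::rlnorm(length(mu), -s^2 / 2, s)
}

#' Per-cell exposures from an activation plan
#' @param plan an `activation_plan`.
#' @param labels_of_cells integer vector of cell labels (NA or 0 for cells
#'   with no nucleus label).
#' @return numeric exposure vector, 0 for unplanned cells.
#' @export
plan_exposures <- function(plan, labels_of_cells) {
  idx <- match(labels_of_cells, plan$assignments$label)
  exp_ms <- plan$assignments$exposure_ms[idx]
  exp_ms[is.na(exp_ms)] <- 0
  exp_ms
}

#' Write / read an activation plan (TSV + per-class binary mask TIFFs)
#'
#' Masks round-trip bit-exactly; the TIFFs are the DMD frame analog.
#' @param plan an `activation_plan`.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return prefix path invisibly (writer); an `activation_plan` (reader).
#' @export
write_activation_plan <- function(plan, dir, prefix) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, prefix)
  write_tsv(plan$assignments, sprintf("%s_plan.tsv", base))
  for (cls in names(plan$masks))
    tiff::writeTIFF((plan$masks[[cls]] * 1L) / 65535,
                    sprintf("%s_mask_%s.tif", base, cls),
                    bits.per.sample = 16L)
  invisible(base)
}

#' @rdname write_activation_plan
#' @export
read_activation_plan <- function(dir, prefix) {
  base <- file.path(dir, prefix)
  assignments <- read_tsv(sprintf("%s_plan.tsv", base))
  files <- list.files(dir, pattern = sprintf("^%s_mask_.*\\.tif$", prefix),
                      full.names = TRUE)
  masks <- lapply(files, function(p) {
    m <- tiff::readTIFF(p)
    matrix(as.integer(round(m * 65535)) > 0, nrow(m), ncol(m))
  })
  names(masks) <- sub(sprintf("^%s_mask_(.*)\\.tif$", prefix), "\\1",
                      basename(files))
  structure(list(assignments = assignments, masks = masks),
            class = "activation_plan")
}
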