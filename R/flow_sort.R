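# FACS simulation: flow events from cell records, 1D gating, enrichment
# precision, recovery losses, and multinomial sequencing-count generation.

#' Build flow events from cell records
#'
#' One event per cell with channels mCherry (photoactivated intensity), mIFP,
#' GFP (total H2B-GFP, proportional to nuclear area), BFP, and FSC (forward
#' scatter, a noisy proxy for cell size assumed proportional to nuclear area
#' under the karyoplasmic-ratio assumption).
#'
#' @param cells data.frame of cell records (see [simulate_population()]).
#' @param mcherry numeric vector of photoactivated intensities (from
#'   [photoactivate()]).
#' @param fsc_cv coefficient of variation of the FSC noise.
#' @param seed RNG seed.
#' @return data.frame `cell_id, sgrna_id, mCherry, mIFP, GFP, BFP, FSC`.
#' @export
flow_events <- function(cells, mcherry, fsc_cv = 0.2, seed = NULL) {
  stopifnot(nrow(cells) == length(mcherry))
  .set_seed(seed)
  n <- nrow(cells)
  s <- sqrt(log1p(fsc_cv^2))
  data.frame(cell_id = cells$cell_id, sgrna_id = cells$sgrna_id,
             mCherry = mcherry, mIFP = cells$mifp,
             GFP = cells$gfp * cells$area_um2,
             BFP = exp(cells$bfp_ln),
             FSC = cells$area_um2 * stats::rlnorm(n, -s^2 / 2, s),
             stringsAsFactors = FALSE)
}

#' Define a set of 1D sort gates
#'
#' Each gate is a named population definition; events are assigned to the
#' first gate they satisfy, in order, and to `"unsorted"` otherwise, so used
#' sort populations are disjoint by construction.
#'
#' @param ... gate definitions created by [gate_range()] or
#'   [gate_top_fraction()].
#' @return object of class `gate_set`.
#' @export
gate_set <- function(...) {
  gates <- list(...)
  nm <- vapply(gates, `[[`, character(1), "name")
  if (anyDuplicated(nm)) .stopf("gate names must be unique")
  names(gates) <- nm
  structure(gates, class = "gate_set")
}

#' @rdname gate_set
#' @param name population name.
#' @param channel event channel the gate applies to.
#' @param min,max interval bounds; the gate keeps `min < x <= max`.
#' @param log if TRUE the bounds are on `ln(x)`.
#' @export
gate_range <- function(name, channel, min = -Inf, max = Inf, log = TRUE) {
  if (!is.finite(min) && !is.finite(max) && min == max)
    .stopf("gate bounds must define an interval")
  list(name = name, type = "range", channel = channel,
       min = min, max = max, log = log)
}

#' @rdname gate_set
#' @param fraction top fraction of events to keep (e.g. 0.10 for a top-10%
#'   sort); exactly `round(fraction * n)` events are gated.
#' @export
gate_top_fraction <- function(name, channel, fraction) {
  .check_fraction(fraction, "fraction")
  list(name = name, type = "top_fraction", channel = channel,
       fraction = fraction)
}

#' Assign events to sort populations
#'
#' @param events data.frame from [flow_events()].
#' @param gates a [gate_set()].
#' @return character vector, one population per event (`"unsorted"` when no
#'   gate matches); deterministic.
#' @export
gate_events <- function(events, gates) {
  stopifnot(inherits(gates, "gate_set"))
  n <- nrow(events)
  assigned <- rep("unsorted", n)
  free <- rep(TRUE, n)
  for (g in gates) {
    if (!g$channel %in% names(events))
      .stopf("gate '%s' references missing channel '%s'", g$name, g$channel)
    x <- events[[g$channel]]
    if (g$type == "range") {
      v <- if (g$log) log(pmax(x, 1e-12)) else x
      hit <- v > g$min & v <= g$max
    } else {
      k <- round(g$fraction * n)
      hit <- rep(FALSE, n)
      if (k > 0) hit[order(x, decreasing = TRUE)[seq_len(k)]] <- TRUE
    }
    take <- hit & free
    assigned[take] <- g$name
    free[take] <- FALSE
  }
  assigned
}

#' Derive multi-level mCherry gates from calibration populations
#'
#' Emulates predefining sorting gates using samples photoactivated for known
#' durations: simulates `n_cal` calibration intensities per exposure class
#' from the response model and places boundaries midway between consecutive
#' class medians in log space; the lowest boundary is the `q_bg` quantile of
#' the unactivated class.
#'
#' @param response an [activation_response()].
#' @param exposures sorted unique exposure durations (ms) actually used;
#'   0 (unactivated) is always included.
#' @param names population name per nonzero exposure, in increasing exposure
#'   order.
#' @param n_cal calibration events per class.
#' @param q_bg background-exclusion quantile for the lowest gate.
#' @param seed RNG seed for the calibration draw.
#' @return a [gate_set()] with one range gate per nonzero exposure.
#' @export
calibrate_mcherry_gates <- function(response, exposures, names = NULL,
                                    n_cal = 5000, q_bg = 0.999, seed = 1L) {
  exposures <- sort(unique(c(0, exposures)))
  cal <- lapply(exposures, function(t)
    log(photoactivate(rep(t, n_cal), response, seed = .subseed(seed, t + 1))))
  med <- vapply(cal, stats::median, numeric(1))
  if (is.unsorted(med)) .stopf("calibration medians are not increasing")
  k <- length(exposures)
  lower <- numeric(k - 1)
  lower[1] <- max(stats::quantile(cal[[1]], q_bg, names = FALSE),
                  (med[1] + med[2]) / 2)
  if (k > 2) for (i in 2:(k - 1)) lower[i] <- (med[i] + med[i + 1]) / 2
  upper <- c(lower[-1], Inf)
  if (is.null(names)) names <- paste0("act_", exposures[-1], "ms")
  gates <- mapply(function(nm, lo, hi)
    gate_range(nm, "mCherry", min = lo, max = hi, log = TRUE),
    names, lower, upper, SIMPLIFY = FALSE)
  do.call(gate_set, gates)
}

#' Enrichment precision of called-positive events
#'
#' Precision = TP / (TP + FP) over the events called positive (the
#' photoactivated, mCherry-positive events). Calling no event positive is an
#' explicit error, not a silent 0/0.
#'
#' @param called_positive logical vector (e.g. assignment to the positive
#'   sort population).
#' @param truth logical vector of the true phenotype per event.
#' @return precision in `[0, 1]`.
#' @examples
#' precision(rep(TRUE, 60), c(rep(TRUE, 59), FALSE))  # 0.98333
#' @export
precision <- function(called_positive, truth) {
  stopifnot(length(called_positive) == length(truth))
  if (anyNA(truth[called_positive]))
    .stopf("every called-positive event needs a truth entry")
  tp <- sum(called_positive & truth)
  fp <- sum(called_positive & !truth)
  if (tp + fp == 0) .stopf("no events called positive; precision undefined")
  tp / (tp + fp)
}

#' Simulate FACS recovery losses
#' @param n number of gated cells.
#' @param p per-cell recovery probability.
#' @param seed RNG seed.
#' @return logical vector: recovered or lost.
#' @export
recover_cells <- function(n, p = 0.8, seed = NULL) {
  .set_seed(seed)
  stats::runif(n) < .check_fraction(p, "p")
}

#' Sequencing counts from a sorted cell population
#'
#' Reads are drawn multinomially over the library's sgRNAs with probabilities
#' proportional to the sorted population's sgRNA composition; the returned
#' column sums exactly to `depth`.
#'
#' @param sorted_sgrnas character vector: the sgRNA of each sorted cell.
#' @param library a `crispr_library`.
#' @param depth total reads.
#' @param seed RNG seed.
#' @return named integer vector of counts over `library$sgrnas$sgrna_id`.
#' @export
sort_to_counts <- function(sorted_sgrnas, library, depth = 1e6, seed = NULL) {
  stopifnot(inherits(library, "crispr_library"))
  if (depth <= 0) .stopf("depth must be > 0")
  sorted_sgrnas <- sorted_sgrnas[!is.na(sorted_sgrnas)]
  if (length(sorted_sgrnas) == 0) .stopf("sorted population is empty")
  ids <- library$sgrnas$sgrna_id
  comp <- tabulate(factor(sorted_sgrnas, levels = ids), nbins = length(ids))
  if (sum(comp) == 0) .stopf("no sorted cell carries a library sgRNA")
  .set_seed(seed)
  counts <- as.integer(stats::rmultinom(1, size = as.integer(depth),
                                        prob = comp))
  names(counts) <- ids
  counts
}
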