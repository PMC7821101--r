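# End-to-end screen orchestration: the mock marker-gene screen, the
# nuclear-size screen (runs x replicates with replicate-intersection hit
# calling), and the sort-only (FSC / H2B-GFP) count-level screens.
#
# Screens run at desk scale (tens of thousands of cells per run) at the
# cell-record level: nuclear areas and channel intensities carry measurement
# noise, selection applies the same filter chain as the image-analysis
# module, and photoactivation/FACS/sequencing use the same operations as the
# image-based path. Image rendering and segmentation are exercised by their
# own module on small fields rather than by rendering hundreds of full
# fields per run.

#' Default nuclear-size screen configuration
#'
#' The defaults mirror the screen design: a 544-gene CRISPRi library
#' (10 sgRNAs/TSS, 63 genes with two TSSs, 22 nontargeting controls), four
#' runs per replicate and two replicates, dual activation (2,000 ms positives
#' / 200 ms negatives), a top-0.5% control size threshold near 1,000 um^2,
#' the ln(BFP) = 7.6 infection gate, sequencing depth 1e6 per sample, and hit
#' calling at eFDR 0.1% against 100 draws of simulated negatives with the
#' sorted-negative reference.
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param ... named overrides merged into the defaults (nested lists are
#'   merged recursively).
#' @return a nested configuration list.
#' @export
size_screen_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    library = list(n_single_tss_genes = 481L, n_double_tss_genes = 63L,
                   sgrnas_per_tss = 10L, n_nontargeting = 22L),
    effects = list(n_hit_genes = 15L, hit_genes = NULL, effect_size = 4,
                   penetrance = 0.6),
    cells_per_run = 50000L, runs = 4L, replicates = 2L,
    infected_fraction = 1, imaged_fraction = 0.7,
    n_control_cells = 10000L, measurement_cv = 0.03,
    filters = list(min_area = 40, max_area = 4000, bfp_ln_threshold = 7.6,
                   top_fraction = 0.005),
    activation = list(pos_ms = 2000, neg_ms = 200, i_max = 1500,
                      tau_ms = 800, background = 10, noise_cv = 0.15),
    recovery = 0.8, depth = 1e6,
    analysis = list(reference = "sorted_negative", pseudocount = 1,
                    efdr_target = 0.001, simneg_draws = 100L,
                    sgrna_subset = "all", runs_used = NULL))
  utils::modifyList(cfg, list(...))
}

#' Read a run configuration from JSON
#'
#' @param path JSON file; keys override the defaults of `default_fn`.
#' @param default_fn configuration builder supplying defaults.
#' @return configuration list.
#' @export
read_run_config <- function(path, default_fn = size_screen_config) {
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- default_fn()
  utils::modifyList(cfg, user)
}

.response_from_cfg <- function(act) {
  activation_response(i_max = act$i_max, tau_ms = act$tau_ms,
                      background = act$background, noise_cv = act$noise_cv)
}

# one imaging/photoactivation/FACS/sequencing run of the size screen;
# returns the per-sample count columns plus stage tallies
.size_screen_run <- function(library, effects, cfg, seed) {
  pop <- simulate_population(library, effects, cfg$cells_per_run,
                             infected_fraction = cfg$infected_fraction,
                             seed = .subseed(seed, 1))

  # control cells measured separately to set the size gate (top 0.5%)
  set.seed(.subseed(seed, 2))
  lp <- .lnorm_pars(baseline_area_default()[["mean"]],
                    baseline_area_default()[["sd"]])
  mcv <- sqrt(log1p(cfg$measurement_cv^2))
  ctrl_areas <- stats::rlnorm(cfg$n_control_cells, lp$meanlog, lp$sdlog) *
    stats::rlnorm(cfg$n_control_cells, -mcv^2 / 2, mcv)
  threshold <- size_threshold_from_controls(ctrl_areas,
                                            cfg$filters$top_fraction)

  set.seed(.subseed(seed, 3))
  n <- nrow(pop)
  imaged <- stats::runif(n) < cfg$imaged_fraction
  measured_area <- pop$area_um2 * stats::rlnorm(n, -mcv^2 / 2, mcv)

  fcfg <- filter_config(min_area = cfg$filters$min_area,
                        max_area = cfg$filters$max_area,
                        bfp_ln_threshold = cfg$filters$bfp_ln_threshold,
                        size_threshold = threshold)
  meas <- data.frame(area_um2 = measured_area, bfp_ln = pop$bfp_ln,
                     touches_border = FALSE)
  filt <- apply_filters(meas, fcfg)
  cls <- as.character(filt$class)
  cls[!imaged] <- "unimaged"

  exposure <- numeric(n)
  exposure[cls == "selected"] <- cfg$activation$pos_ms
  exposure[cls == "negative"] <- cfg$activation$neg_ms
  response <- .response_from_cfg(cfg$activation)
  mcherry <- photoactivate(exposure, response, seed = .subseed(seed, 4))
  events <- flow_events(pop, mcherry, seed = .subseed(seed, 5))

  gates <- calibrate_mcherry_gates(
    response, c(cfg$activation$neg_ms, cfg$activation$pos_ms),
    names = c("sorted_negative", "sorted_positive"), seed = .subseed(seed, 6))
  assign <- gate_events(events, gates)
  recovered <- recover_cells(n, cfg$recovery, seed = .subseed(seed, 7))

  take <- function(pop_name) events$sgrna_id[assign == pop_name & recovered]
  sorted_pos <- take("sorted_positive")
  sorted_neg <- take("sorted_negative")
  unanalyzed <- events$sgrna_id[assign == "unsorted" & recovered]

  list(counts = list(
         pos = sort_to_counts(sorted_pos, library, cfg$depth,
                              seed = .subseed(seed, 8)),
         neg = sort_to_counts(sorted_neg, library, cfg$depth,
                              seed = .subseed(seed, 9)),
         una = sort_to_counts(unanalyzed, library, cfg$depth,
                              seed = .subseed(seed, 10))),
       tallies = c(cells = n, imaged = sum(imaged),
                   selected = sum(cls == "selected" & imaged),
                   sorted_positive = length(sorted_pos),
                   sorted_negative = length(sorted_neg)),
       size_threshold = threshold)
}

# score one replicate's count table: per-run epsilon, run averaging,
# TSS-level Mann-Whitney, simulated negatives, eFDR hit calling
.score_replicate <- function(tab, library, cfg, seed) {
  an <- cfg$analysis
  if (an$sgrna_subset != "all")
    tab <- subset_by_efficacy(tab, library, an$sgrna_subset)
  nt <- nontargeting_ids(library)
  runs_used <- an$runs_used %||% cfg$runs
  ref_tag <- switch(an$reference, sorted_negative = "neg",
                    unanalyzed = "una",
                    .stopf("unknown reference '%s'", an$reference))
  run_scores <- lapply(seq_len(runs_used), function(j)
    phenotypic_scores(tab, sprintf("pos_run%d", j),
                      sprintf("%s_run%d", ref_tag, j), nt,
                      pseudocount = an$pseudocount))
  avg <- average_runs(run_scores)
  tss <- score_tss(avg, nt)
  gsize <- max(tss$n_sgrnas)
  simneg <- simulated_negatives(avg, nt, group_size = gsize,
                                n_draws = an$simneg_draws,
                                seed = .subseed(seed, 99))
  res <- call_hits(tss, simneg, target = an$efdr_target)
  list(scores = avg, tss = tss, genes = res$genes, curve = res$curve,
       hits = res$genes$gene[res$genes$hit], cutoff = res$cutoff)
}

#' Run the nuclear-size screen
#'
#' Executes `replicates` x `runs` simulated imaging/photoactivation/FACS/
#' sequencing runs, scores each replicate (per-run epsilon averaged across
#' runs, TSS-level Mann-Whitney against the 22 nontargeting controls,
#' simulated negatives, eta, eFDR-0.1% hit calling), and intersects the
#' per-replicate hit lists. Deterministic given `cfg$seed`.
#'
#' @param cfg configuration from [size_screen_config()].
#' @param outdir optional output directory; when given, count tables,
#'   per-gene volcano tables, eFDR curves and the hit list are written as
#'   headered TSVs.
#' @return list with `replicates` (per-replicate scoring results),
#'   `hits_per_replicate`, `intersection_hits`, `hit_genes_true` (planted),
#'   `tallies`, `size_thresholds`, `library`, `config_hash`.
#' @export
run_size_screen <- function(cfg = size_screen_config(), outdir = NULL) {
  hash <- fnv1a_hash(cfg)
  library <- build_library(cfg$library$n_single_tss_genes,
                           cfg$library$n_double_tss_genes,
                           cfg$library$sgrnas_per_tss,
                           cfg$library$n_nontargeting)
  set.seed(.subseed(cfg$seed, 0))
  hit_genes <- cfg$effects$hit_genes %||%
    sample(library$genes, cfg$effects$n_hit_genes)
  effects <- effect_model(library, hit_genes = hit_genes,
                          effect_size = cfg$effects$effect_size,
                          penetrance = cfg$effects$penetrance,
                          seed = .subseed(cfg$seed, 1))

  reps <- vector("list", cfg$replicates)
  tallies <- list(); thresholds <- numeric(0)
  for (r in seq_len(cfg$replicates)) {
    cols <- list()
    for (j in seq_len(cfg$runs)) {
      run <- .size_screen_run(library, effects, cfg,
                              seed = .subseed(cfg$seed, 1000 * r + j))
      cols[[sprintf("pos_run%d", j)]] <- run$counts$pos
      cols[[sprintf("neg_run%d", j)]] <- run$counts$neg
      cols[[sprintf("una_run%d", j)]] <- run$counts$una
      tallies[[sprintf("rep%d_run%d", r, j)]] <- run$tallies
      thresholds <- c(thresholds, run$size_threshold)
    }
    tab <- do.call(count_table, c(list(library), cols))
    reps[[r]] <- .score_replicate(tab, library, cfg,
                                  seed = .subseed(cfg$seed, 5000 + r))
    reps[[r]]$counts <- tab
  }

  hits_per_rep <- lapply(reps, `[[`, "hits")
  intersection <- Reduce(intersect, hits_per_rep)
  out <- list(replicates = reps, hits_per_replicate = hits_per_rep,
              intersection_hits = intersection, hit_genes_true = hit_genes,
              tallies = tallies, size_thresholds = thresholds,
              library = library, config_hash = hash)
  if (!is.null(outdir)) .write_size_screen(out, cfg, outdir, hash)
  out
}

.write_size_screen <- function(out, cfg, outdir, hash) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  for (r in seq_along(out$replicates)) {
    rep <- out$replicates[[r]]
    write_tsv(rep$counts, file.path(outdir, sprintf("counts_rep%d.tsv", r)),
              cfg$seed, hash)
    vol <- rep$genes
    vol$neg_ln_p <- -log(vol$p_value)
    write_tsv(vol, file.path(outdir, sprintf("genes_rep%d.tsv", r)),
              cfg$seed, hash)
    write_tsv(rep$curve$curve,
              file.path(outdir, sprintf("efdr_curve_rep%d.tsv", r)),
              cfg$seed, hash)
  }
  write_tsv(data.frame(gene = out$intersection_hits),
            file.path(outdir, "hits_intersection.tsv"), cfg$seed, hash)
  invisible(outdir)
}

#' Default mock (marker-gene) screen configuration
#'
#' A 9:1 mixture of marker-negative cells (6,100 control barcodes) and
#' marker-positive cells (860 barcodes), imaged with a detection model,
#' dual-activated (2,000 / 100 ms), sorted and sequenced; groups of `group_k`
#' sgRNAs emulate genes.
#'
#' @inheritParams size_screen_config
#' @export
mock_screen_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_cells = 100000L, positive_fraction = 0.1,
    n_positive_barcodes = 860L, n_control_barcodes = 6100L,
    imaged_fraction = 0.7,
    detect = list(p_detect = 0.98, p_false = 0.002),
    activation = list(pos_ms = 2000, neg_ms = 100, i_max = 1500,
                      tau_ms = 800, background = 10, noise_cv = 0.15),
    recovery = 0.8, depth = 1e6,
    analysis = list(group_k = 2L, pseudocount = 1,
                    references = c("sorted_negative", "unanalyzed")))
  utils::modifyList(cfg, list(...))
}

.barcode_library <- function(n, prefix) {
  sg <- data.frame(sgrna_id = sprintf("%s_%05d", prefix, seq_len(n)),
                   gene = prefix, tss = NA_character_,
                   efficacy_class = NA_character_, stringsAsFactors = FALSE)
  structure(list(genes = prefix, tss_map = list(), sgrnas = sg,
                 sgrnas_per_tss = 0L, n_nontargeting = 0L),
            class = "crispr_library")
}

.merge_libraries <- function(a, b) {
  structure(list(genes = c(a$genes, b$genes), tss_map = c(a$tss_map, b$tss_map),
                 sgrnas = rbind(a$sgrnas, b$sgrnas),
                 sgrnas_per_tss = 0L, n_nontargeting = 0L),
            class = "crispr_library")
}

#' Run the mock marker-gene screen
#'
#' Marker-positive and marker-negative cells carry disjoint barcode
#' libraries; the marker is the phenotype. Imaged cells are detected with the
#' configured accuracy, positives activated long and negatives short, and
#' the three samples (sorted positive, sorted negative, unanalyzed) are
#' sequenced. Group scores are computed against each configured reference
#' sample, centered on the control barcodes.
#'
#' @param cfg configuration from [mock_screen_config()].
#' @param outdir optional output directory for headered TSVs.
#' @return list with `groups` (data.frame `reference, class, group,
#'   epsilon`), `auc` (named by reference), `separation` (mean positive-group
#'   minus mean control-group epsilon, named by reference), `precision`,
#'   `tallies`, `config_hash`.
#' @export
run_mock_screen <- function(cfg = mock_screen_config(), outdir = NULL) {
  hash <- fnv1a_hash(cfg)
  lib_pos <- .barcode_library(cfg$n_positive_barcodes, "MIFP")
  lib_ctl <- .barcode_library(cfg$n_control_barcodes, "CTRL")
  lib <- .merge_libraries(lib_pos, lib_ctl)

  set.seed(.subseed(cfg$seed, 11))
  n <- cfg$n_cells
  is_pos <- stats::runif(n) < cfg$positive_fraction
  sgrna <- character(n)
  sgrna[is_pos] <- sample(lib_pos$sgrnas$sgrna_id, sum(is_pos), replace = TRUE)
  sgrna[!is_pos] <- sample(lib_ctl$sgrnas$sgrna_id, sum(!is_pos),
                           replace = TRUE)
  lp <- .lnorm_pars(baseline_area_default()[["mean"]],
                    baseline_area_default()[["sd"]])
  pop <- data.frame(cell_id = seq_len(n), sgrna_id = sgrna,
                    area_um2 = stats::rlnorm(n, lp$meanlog, lp$sdlog),
                    gfp = stats::rlnorm(n, log(3000), 0.2),
                    bfp_ln = stats::rnorm(n, 8.6, 0.5),
                    mifp = ifelse(is_pos, stats::rlnorm(n, log(2000), 0.3),
                                  stats::rlnorm(n, log(5), 0.3)),
                    stringsAsFactors = FALSE)

  imaged <- stats::runif(n) < cfg$imaged_fraction
  detected <- imaged & ifelse(is_pos, stats::runif(n) < cfg$detect$p_detect,
                              stats::runif(n) < cfg$detect$p_false)
  exposure <- numeric(n)
  exposure[detected] <- cfg$activation$pos_ms
  exposure[imaged & !detected] <- cfg$activation$neg_ms

  response <- .response_from_cfg(cfg$activation)
  mcherry <- photoactivate(exposure, response, seed = .subseed(cfg$seed, 12))
  events <- flow_events(pop, mcherry, seed = .subseed(cfg$seed, 13))
  gates <- calibrate_mcherry_gates(
    response, c(cfg$activation$neg_ms, cfg$activation$pos_ms),
    names = c("sorted_negative", "sorted_positive"),
    seed = .subseed(cfg$seed, 14))
  assign <- gate_events(events, gates)
  recovered <- recover_cells(n, cfg$recovery, seed = .subseed(cfg$seed, 15))

  # precision() raises when nothing was called positive; a screen with no
  # activated cells still yields count tables, so record NA instead
  prec <- tryCatch(precision(assign == "sorted_positive", is_pos),
                   error = function(e) NA_real_)

  counts <- list(
    sorted_positive = sort_to_counts(
      events$sgrna_id[assign == "sorted_positive" & recovered], lib,
      cfg$depth, seed = .subseed(cfg$seed, 16)),
    sorted_negative = sort_to_counts(
      events$sgrna_id[assign == "sorted_negative" & recovered], lib,
      cfg$depth, seed = .subseed(cfg$seed, 17)),
    unanalyzed = sort_to_counts(
      events$sgrna_id[assign == "unsorted" & recovered], lib,
      cfg$depth, seed = .subseed(cfg$seed, 18)))
  tab <- do.call(count_table, c(list(lib), counts))

  ctl_ids <- lib_ctl$sgrnas$sgrna_id
  groups <- list(); aucs <- numeric(0); seps <- numeric(0)
  for (ref in cfg$analysis$references) {
    sc <- phenotypic_scores(tab, "sorted_positive", ref, ctl_ids,
                            pseudocount = cfg$analysis$pseudocount)
    gp <- group_scores(sc[sc$gene == "MIFP", ], cfg$analysis$group_k,
                       "random", seed = .subseed(cfg$seed, 21))
    gc <- group_scores(sc[sc$gene == "CTRL", ], cfg$analysis$group_k,
                       "random", seed = .subseed(cfg$seed, 22))
    groups[[ref]] <- rbind(
      data.frame(reference = ref, class = "mIFP", gp,
                 stringsAsFactors = FALSE),
      data.frame(reference = ref, class = "Ctrl", gc,
                 stringsAsFactors = FALSE))
    aucs[ref] <- auc_rank(gp$epsilon, gc$epsilon)
    seps[ref] <- mean(gp$epsilon) - mean(gc$epsilon)
  }
  groups <- do.call(rbind, groups)
  rownames(groups) <- NULL

  out <- list(groups = groups, auc = aucs, separation = seps,
              precision = prec, counts = tab,
              tallies = c(cells = n, positives = sum(is_pos),
                          imaged = sum(imaged),
                          sorted_positive = sum(assign == "sorted_positive"),
                          sorted_negative = sum(assign == "sorted_negative")),
              config_hash = hash)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_tsv(tab, file.path(outdir, "counts.tsv"), cfg$seed, hash)
    write_tsv(groups, file.path(outdir, "group_scores.tsv"), cfg$seed, hash)
  }
  out
}

#' Default sort-only screen configuration
#' @inheritParams size_screen_config
#' @export
sort_screen_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    library = list(n_single_tss_genes = 481L, n_double_tss_genes = 63L,
                   sgrnas_per_tss = 10L, n_nontargeting = 22L),
    effects = list(n_hit_genes = 15L, hit_genes = NULL, effect_size = 4,
                   penetrance = 0.6),
    # sort-only screens have no imaging bottleneck; 400k cells keep the
    # top-10% aliquot at ~5 recovered cells/sgRNA so counts are not
    # dominated by the zero-count pseudocount floor
    n_cells = 400000L, infected_fraction = 1, recovery = 0.8, depth = 1e6,
    analysis = list(pseudocount = 1, efdr_target = 0.001,
                    simneg_draws = 100L))
  utils::modifyList(cfg, list(...))
}

#' Run a sort-only (FSC or H2B-GFP) screen
#'
#' No imaging: the top `top_fraction` of cells by the chosen flow channel is
#' sorted and compared against an unsorted aliquot with the same statistics
#' stack as the size screen (epsilon, TSS Mann-Whitney, simulated negatives,
#' eta, eFDR hit calling).
#'
#' @param cfg configuration from [sort_screen_config()].
#' @param channel flow channel to sort on: `"FSC"`, `"GFP"`, or `"mIFP"`.
#' @param top_fraction top fraction sorted (default 0.10).
#' @param outdir optional output directory.
#' @return list with `genes`, `hits`, `curve`, `hit_genes_true`, `scores`,
#'   `config_hash`.
#' @export
run_sort_only_screen <- function(cfg = sort_screen_config(),
                                 channel = c("FSC", "GFP", "mIFP"),
                                 top_fraction = 0.10, outdir = NULL) {
  channel <- match.arg(channel)
  hash <- fnv1a_hash(c(cfg, channel = channel, top_fraction = top_fraction))
  library <- build_library(cfg$library$n_single_tss_genes,
                           cfg$library$n_double_tss_genes,
                           cfg$library$sgrnas_per_tss,
                           cfg$library$n_nontargeting)
  set.seed(.subseed(cfg$seed, 30))
  hit_genes <- cfg$effects$hit_genes %||%
    sample(library$genes, cfg$effects$n_hit_genes)
  effects <- effect_model(library, hit_genes = hit_genes,
                          effect_size = cfg$effects$effect_size,
                          penetrance = cfg$effects$penetrance,
                          seed = .subseed(cfg$seed, 31))
  pop <- simulate_population(library, effects, cfg$n_cells,
                             infected_fraction = cfg$infected_fraction,
                             seed = .subseed(cfg$seed, 32))
  set.seed(.subseed(cfg$seed, 33))
  pop$mifp <- stats::rlnorm(nrow(pop), log(5), 0.3)  # null far-red channel
  mcherry <- photoactivate(rep(0, nrow(pop)),
                           .response_from_cfg(list(i_max = 1500, tau_ms = 800,
                                                   background = 10,
                                                   noise_cv = 0.15)),
                           seed = .subseed(cfg$seed, 34))
  events <- flow_events(pop, mcherry, seed = .subseed(cfg$seed, 35))

  if (top_fraction >= 1) {
    sorted <- rep(TRUE, nrow(events))
  } else {
    gates <- gate_set(gate_top_fraction("sorted_high", channel, top_fraction))
    sorted <- gate_events(events, gates) == "sorted_high"
  }
  recovered <- recover_cells(nrow(events), cfg$recovery,
                             seed = .subseed(cfg$seed, 36))
  counts <- list(
    sorted_high = sort_to_counts(events$sgrna_id[sorted & recovered], library,
                                 cfg$depth, seed = .subseed(cfg$seed, 37)),
    unsorted = sort_to_counts(events$sgrna_id, library, cfg$depth,
                              seed = .subseed(cfg$seed, 38)))
  tab <- do.call(count_table, c(list(library), counts))

  nt <- nontargeting_ids(library)
  sc <- phenotypic_scores(tab, "sorted_high", "unsorted", nt,
                          pseudocount = cfg$analysis$pseudocount)
  tss <- score_tss(sc, nt)
  simneg <- simulated_negatives(sc, nt, group_size = max(tss$n_sgrnas),
                                n_draws = cfg$analysis$simneg_draws,
                                seed = .subseed(cfg$seed, 39))
  res <- call_hits(tss, simneg, target = cfg$analysis$efdr_target)

  out <- list(genes = res$genes, hits = res$genes$gene[res$genes$hit],
              curve = res$curve, hit_genes_true = hit_genes, scores = sc,
              counts = tab, channel = channel, config_hash = hash)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_tsv(res$genes, file.path(outdir, sprintf("genes_%s.tsv", channel)),
              cfg$seed, hash)
  }
  out
}
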