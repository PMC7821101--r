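# Synthetic sgRNA libraries and cell populations with planted phenotypes.
#
# The library layout mirrors a CRISPRi screening library in which sgRNAs are
# clustered by transcription start site (TSS): most genes carry one TSS with
# `sgrnas_per_tss` sgRNAs, a minority carry two TSSs, and a small set of
# nontargeting control sgRNAs defines the null phenotype distribution.

#' Build a synthetic sgRNA library
#'
#' Constructs a library of `n_single_tss_genes` genes with one TSS and
#' `n_double_tss_genes` genes with two TSSs, each TSS targeted by
#' `sgrnas_per_tss` sgRNAs, plus `n_nontargeting` nontargeting controls
#' (gene = `"NONTARGETING"`). Within every TSS the first half of the sgRNAs is
#' labelled efficacy class `"top5"` and the rest `"supp5"`, mirroring
#' libraries split by predicted knockdown activity.
#'
#' The default composition (481 single-TSS genes, 63 double-TSS genes,
#' 10 sgRNAs/TSS, 22 nontargeting) yields 544 genes and 6,092 sgRNAs.
#'
#' @param n_single_tss_genes number of genes with a single TSS.
#' @param n_double_tss_genes number of genes with two TSSs.
#' @param sgrnas_per_tss sgRNAs per TSS.
#' @param n_nontargeting number of nontargeting control sgRNAs.
#' @param seed unused (the layout is deterministic); kept so every generator
#'   in the package shares one signature.
#' @return An object of class `crispr_library`: a list with elements `genes`,
#'   `tss_map` (gene -> TSS ids), `sgrnas` (data.frame with `sgrna_id`,
#'   `gene`, `tss`, `efficacy_class`), `sgrnas_per_tss`, `n_nontargeting`.
#' @examples
#' lib <- build_library(481, 63, 10, 22)
#' nrow(lib$sgrnas)  # 6092
#' @export
build_library <- function(n_single_tss_genes, n_double_tss_genes = 0L,
                          sgrnas_per_tss = 10L, n_nontargeting = 22L,
                          seed = NULL) {
  n1 <- .check_count(n_single_tss_genes, "n_single_tss_genes")
  n2 <- .check_count(n_double_tss_genes, "n_double_tss_genes")
  m  <- .check_count(sgrnas_per_tss, "sgrnas_per_tss")
  nt <- .check_count(n_nontargeting, "n_nontargeting")

  n_genes <- n1 + n2
  genes <- if (n_genes > 0) sprintf("G%04d", seq_len(n_genes)) else character()
  n_tss_per_gene <- rep(c(1L, 2L), c(n1, n2))
  tss_map <- lapply(seq_len(n_genes), function(i)
    sprintf("%s_T%d", genes[i], seq_len(n_tss_per_gene[i])))
  names(tss_map) <- genes

  tss_all <- unlist(tss_map, use.names = FALSE)
  gene_of_tss <- rep(genes, n_tss_per_gene)
  if (length(tss_all) > 0 && m > 0) {
    eff <- rep(c("top5", "supp5"), c(ceiling(m / 2), floor(m / 2)))
    targeting <- data.frame(
      sgrna_id = sprintf("%s_sg%02d", rep(tss_all, each = m),
                         rep(seq_len(m), length(tss_all))),
      gene = rep(gene_of_tss, each = m),
      tss = rep(tss_all, each = m),
      efficacy_class = rep(eff, length(tss_all)),
      stringsAsFactors = FALSE)
  } else {
    targeting <- data.frame(sgrna_id = character(), gene = character(),
                            tss = character(), efficacy_class = character(),
                            stringsAsFactors = FALSE)
  }
  nontarg <- data.frame(
    sgrna_id = if (nt > 0) sprintf("NTC_%03d", seq_len(nt)) else character(),
    gene = rep("NONTARGETING", nt),
    tss = rep(NA_character_, nt),
    efficacy_class = rep(NA_character_, nt),
    stringsAsFactors = FALSE)

  lib <- list(genes = genes, tss_map = tss_map,
              sgrnas = rbind(targeting, nontarg),
              sgrnas_per_tss = m, n_nontargeting = nt)
  class(lib) <- "crispr_library"
  stopifnot(!anyDuplicated(lib$sgrnas$sgrna_id))
  lib
}

#' @export
print.crispr_library <- function(x, ...) {
  cat(sprintf("crispr_library: %d genes, %d TSSs, %d sgRNAs (%d nontargeting)\n",
              length(x$genes), length(unlist(x$tss_map)),
              nrow(x$sgrnas), x$n_nontargeting))
  invisible(x)
}

#' Nontargeting sgRNA ids of a library
#' @param library a `crispr_library`.
#' @return character vector of nontargeting sgRNA ids.
#' @export
nontargeting_ids <- function(library) {
  library$sgrnas$sgrna_id[library$sgrnas$gene == "NONTARGETING"]
}

#' Default baseline nucleus-area distribution
#'
#' Log-normal baseline for 2D nuclear area, parameterized by its arithmetic
#' mean and standard deviation (both in square micrometers). The default is
#' calibrated so that the 99.5th percentile of control areas is 1,000 um^2,
#' i.e. the top-0.5% screening threshold computed from control cells lands at
#' 1,000 um^2; the implied median is ~202 um^2, a realistic interphase
#' RPE-1 nucleus.
#'
#' @param threshold_um2 target 99.5th percentile.
#' @param top_fraction upper-tail fraction defining the threshold.
#' @param sdlog log-scale standard deviation of the baseline.
#' @return named numeric vector `c(mean =, sd =)` in um^2.
#' @export
baseline_area_default <- function(threshold_um2 = 1000, top_fraction = 0.005,
                                  sdlog = 0.62) {
  meanlog <- log(threshold_um2) - stats::qnorm(1 - top_fraction) * sdlog
  m <- exp(meanlog + sdlog^2 / 2)
  s <- m * sqrt(exp(sdlog^2) - 1)
  c(mean = m, sd = s)
}

.lnorm_pars <- function(mean, sd) {
  sdlog <- sqrt(log1p((sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Define the planted-phenotype effect model
#'
#' Hit genes multiply the phenotype distribution (here: nuclear area) by
#' `effect_size` in cells that express the phenotype. A cell carrying a hit
#' sgRNA expresses the phenotype with probability `penetrance * efficacy`,
#' where efficacy is drawn per sgRNA from a class-dependent Beta distribution
#' ("top5"-like sgRNAs around 0.9, "supp5"-like around 0.5), emulating
#' libraries split by predicted knockdown activity.
#'
#' @param library a `crispr_library`.
#' @param hit_genes character vector of planted hit genes (subset of
#'   `library$genes`).
#' @param effect_size multiplicative shift of the phenotype distribution for
#'   phenotype-expressing cells (1 = no effect).
#' @param penetrance fraction in `[0,1]` of phenotype-expressing cells among
#'   cells whose sgRNA is fully effective.
#' @param efficacy optional named numeric vector overriding the per-sgRNA
#'   efficacy draw (values in `[0,1]`).
#' @param seed RNG seed for the efficacy draw.
#' @return object of class `effect_model`.
#' @export
effect_model <- function(library, hit_genes = character(), effect_size = 3,
                         penetrance = 0.6, efficacy = NULL, seed = NULL) {
  stopifnot(inherits(library, "crispr_library"))
  if (!all(hit_genes %in% library$genes))
    .stopf("hit_genes not in library: %s",
           paste(setdiff(hit_genes, library$genes), collapse = ","))
  .check_fraction(penetrance, "penetrance")
  if (effect_size <= 0) .stopf("effect_size must be > 0")
  sg <- library$sgrnas
  if (is.null(efficacy)) {
    .set_seed(seed)
    efficacy <- numeric(nrow(sg))
    top <- !is.na(sg$efficacy_class) & sg$efficacy_class == "top5"
    sup <- !is.na(sg$efficacy_class) & sg$efficacy_class == "supp5"
    efficacy[top] <- stats::rbeta(sum(top), 18, 2)   # mean 0.9
    efficacy[sup] <- stats::rbeta(sum(sup), 5, 5)    # mean 0.5
    names(efficacy) <- sg$sgrna_id
  } else {
    if (!all(sg$sgrna_id %in% names(efficacy)))
      .stopf("efficacy must name every sgRNA")
    if (any(efficacy < 0 | efficacy > 1)) .stopf("efficacy must be in [0,1]")
    efficacy <- efficacy[sg$sgrna_id]
  }
  structure(list(hit_genes = hit_genes, effect_size = effect_size,
                 penetrance = penetrance, sgrna_efficacy = efficacy),
            class = "effect_model")
}

#' Simulate a cell population under an infection and effect model
#'
#' Each cell is infected with probability `infected_fraction`; infected cells
#' carry exactly one sgRNA drawn uniformly from the library (low-MOI
#' single-sgRNA contract). Cells carrying a hit-gene sgRNA express the
#' phenotype with probability `penetrance * efficacy(sgRNA)` and draw their
#' nuclear area from the baseline log-normal shifted by `effect_size`; all
#' other cells draw from the baseline. Infection is tracked by the BFP
#' reporter: infected cells have `ln(mean BFP)` ~ Normal(8.6, 0.5), uninfected
#' Normal(6.6, 0.5), so a 7.6 gate separates them.
#'
#' @param library a `crispr_library`.
#' @param effects an `effect_model` (or NULL for no planted effects).
#' @param n_cells number of cells.
#' @param infected_fraction probability a cell carries an sgRNA.
#' @param baseline_area `c(mean =, sd =)` of the baseline area distribution
#'   in um^2 (see [baseline_area_default()]).
#' @param bfp named vector `c(infected_mean, uninfected_mean, sd)` of
#'   `ln(mean BFP)`.
#' @param pixel_size um per pixel, used to derive nucleus ellipse semi-axes.
#' @param seed RNG seed; fixed seed gives a bit-identical population.
#' @return data.frame with one row per cell: `cell_id`, `sgrna_id` (NA when
#'   uninfected), `gene`, `efficacy`, `is_hit_sgrna`, `true_phenotype`,
#'   `area_um2`, ellipse `a_px`, `b_px`, `theta`, `gfp`, `bfp_ln`, `mifp`.
#' @export
simulate_population <- function(library, effects = NULL, n_cells,
                                infected_fraction = 1,
                                baseline_area = baseline_area_default(),
                                bfp = c(infected_mean = 8.6,
                                        uninfected_mean = 6.6, sd = 0.5),
                                pixel_size = 0.325, seed = NULL) {
  stopifnot(inherits(library, "crispr_library"))
  n_cells <- .check_count(n_cells, "n_cells", min = 1L)
  f <- .check_fraction(infected_fraction, "infected_fraction")
  if (nrow(library$sgrnas) == 0 && f > 0)
    .stopf("cannot infect cells from an empty library")
  .set_seed(seed)

  infected <- stats::runif(n_cells) < f
  sg_idx <- rep(NA_integer_, n_cells)
  sg_idx[infected] <- sample.int(nrow(library$sgrnas), sum(infected),
                                 replace = TRUE)
  sgrna_id <- library$sgrnas$sgrna_id[sg_idx]
  gene <- library$sgrnas$gene[sg_idx]

  if (is.null(effects)) effects <- effect_model(library, seed = 1L)
  eff <- unname(effects$sgrna_efficacy[sgrna_id])
  eff[is.na(eff)] <- 0
  is_hit <- !is.na(gene) & gene %in% effects$hit_genes
  p_phen <- ifelse(is_hit, effects$penetrance * eff, 0)
  true_phenotype <- stats::runif(n_cells) < p_phen

  lp <- .lnorm_pars(baseline_area[["mean"]], baseline_area[["sd"]])
  shift <- ifelse(true_phenotype, log(effects$effect_size), 0)
  area <- stats::rlnorm(n_cells, lp$meanlog + shift, lp$sdlog)

  aspect <- stats::runif(n_cells, 1, 1.6)
  area_px <- area / pixel_size^2
  b_px <- sqrt(area_px / (pi * aspect))
  a_px <- aspect * b_px
  theta <- stats::runif(n_cells, 0, pi)

  bfp_ln <- ifelse(infected,
                   stats::rnorm(n_cells, bfp[["infected_mean"]], bfp[["sd"]]),
                   stats::rnorm(n_cells, bfp[["uninfected_mean"]], bfp[["sd"]]))
  gfp <- stats::rlnorm(n_cells, log(3000), 0.2)

  data.frame(cell_id = seq_len(n_cells), sgrna_id = sgrna_id, gene = gene,
             efficacy = eff, is_hit_sgrna = is_hit,
             true_phenotype = true_phenotype, area_um2 = area,
             a_px = a_px, b_px = b_px, theta = theta,
             gfp = gfp, bfp_ln = bfp_ln, mifp = 0,
             stringsAsFactors = FALSE)
}

#' Write / read a library as TSV
#'
#' Columns `sgrna_id, gene, tss, efficacy_class`; nontargeting rows carry
#' gene `NONTARGETING`.
#' @param library a `crispr_library`.
#' @param path file path.
#' @return `path` invisibly for the writer; a `crispr_library` for the reader.
#' @export
write_library <- function(library, path) {
  write_tsv(library$sgrnas, path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  sg <- read_tsv(path)
  sg$tss[sg$gene == "NONTARGETING"] <- NA_character_
  targ <- sg[sg$gene != "NONTARGETING", ]
  genes <- unique(targ$gene)
  tss_map <- lapply(genes, function(g) unique(targ$tss[targ$gene == g]))
  names(tss_map) <- genes
  m <- if (nrow(targ)) max(table(targ$tss)) else 0L
  lib <- list(genes = genes, tss_map = tss_map, sgrnas = sg,
              sgrnas_per_tss = as.integer(m),
              n_nontargeting = sum(sg$gene == "NONTARGETING"))
  class(lib) <- "crispr_library"
  lib
}
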