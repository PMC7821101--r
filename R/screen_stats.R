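# Counts-to-hits statistics: per-sgRNA phenotypic scores (epsilon), run
# averaging, grouping, Mann-Whitney tests of TSS groups against nontargeting
# controls, simulated negative controls by random regrouping, the combined
# score eta, and empirical-FDR hit calling.

#' Assemble a count table
#'
#' @param library a `crispr_library`.
#' @param ... named integer count vectors over `library$sgrnas$sgrna_id`
#'   (e.g. from [sort_to_counts()]); each becomes a `count_<name>` column.
#' @return data.frame `sgrna_id, gene, tss, count_<sample>...`.
#' @export
count_table <- function(library, ...) {
  cols <- list(...)
  tab <- library$sgrnas[, c("sgrna_id", "gene", "tss")]
  for (nm in names(cols)) {
    x <- cols[[nm]]
    if (!is.null(names(x))) x <- x[tab$sgrna_id]
    if (length(x) != nrow(tab)) .stopf("column '%s' has wrong length", nm)
    if (any(x < 0)) .stopf("negative counts in '%s'", nm)
    tab[[paste0("count_", nm)]] <- as.integer(x)
  }
  tab
}

.count_col <- function(table, sample) {
  col <- paste0("count_", sample)
  if (!col %in% names(table)) .stopf("sample '%s' not in count table", sample)
  table[[col]]
}

#' Per-sgRNA phenotypic scores (epsilon)
#'
#' For each sgRNA, epsilon is the log2 ratio of pseudocounted,
#' depth-normalized read frequencies between the sorted sample and the
#' reference sample, centered so that the median epsilon of the nontargeting
#' control sgRNAs is exactly 0:
#'
#'   epsilon = log2\[ ((c_s + pc)/N_s) / ((c_r + pc)/N_r) \] - median_NT(...)
#'
#' @param table count table (see [count_table()]).
#' @param sample name of the sorted sample column.
#' @param reference name of the reference sample column.
#' @param nontargeting_ids sgRNA ids defining the null for centering.
#' @param pseudocount pseudocount added to both counts.
#' @return data.frame `sgrna_id, gene, tss, epsilon`.
#' @export
phenotypic_scores <- function(table, sample, reference, nontargeting_ids,
                              pseudocount = 1) {
  if (identical(sample, reference)) .stopf("sample and reference must differ")
  if (length(nontargeting_ids) == 0) .stopf("nontargeting_ids is empty")
  cs <- .count_col(table, sample)
  cr <- .count_col(table, reference)
  ns <- sum(cs); nr <- sum(cr)
  if (ns == 0 || nr == 0) .stopf("a count column has zero total reads")
  eps <- log2(((cs + pseudocount) / ns) / ((cr + pseudocount) / nr))
  nt <- table$sgrna_id %in% nontargeting_ids
  if (!any(nt)) .stopf("no nontargeting sgRNA found in the table")
  eps <- eps - stats::median(eps[nt])
  data.frame(sgrna_id = table$sgrna_id, gene = table$gene, tss = table$tss,
             epsilon = eps, stringsAsFactors = FALSE)
}

#' Average phenotypic scores across runs
#'
#' @param runs list of score data.frames from [phenotypic_scores()], one per
#'   run, over the identical sgRNA set.
#' @return one score data.frame with `epsilon` the arithmetic mean across
#'   runs; a single run is returned unchanged.
#' @export
average_runs <- function(runs) {
  if (length(runs) == 0) .stopf("need at least one run")
  ids <- runs[[1]]$sgrna_id
  for (r in runs) if (!identical(r$sgrna_id, ids))
    .stopf("runs have mismatched sgRNA sets")
  out <- runs[[1]]
  out$epsilon <- rowMeans(vapply(runs, `[[`, numeric(length(ids)), "epsilon"))
  out
}

#' Group sgRNA scores into pseudo-genes
#'
#' Random mode partitions the sgRNAs without replacement into groups of `k`
#' (leftover sgRNAs are dropped); `by_tss` mode uses the library's TSS
#' clustering. Group score = mean member epsilon.
#'
#' @param scores score data.frame.
#' @param k group size (random mode).
#' @param mode `"random"` or `"by_tss"`.
#' @param seed RNG seed (random mode); deterministic per seed.
#' @return data.frame `group, epsilon, n_members`.
#' @export
group_scores <- function(scores, k = 2, mode = c("random", "by_tss"),
                         seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "by_tss") {
    keep <- !is.na(scores$tss)
    g <- rowsum(scores$epsilon[keep], scores$tss[keep])
    n <- rowsum(rep(1, sum(keep)), scores$tss[keep])
    return(data.frame(group = rownames(g), epsilon = as.numeric(g / n),
                      n_members = as.integer(n), stringsAsFactors = FALSE))
  }
  k <- .check_count(k, "k", min = 1L)
  n <- nrow(scores)
  if (k > n) .stopf("group size k = %d exceeds the %d available sgRNAs", k, n)
  .set_seed(seed)
  perm <- sample.int(n)
  ngrp <- n %/% k
  idx <- perm[seq_len(ngrp * k)]
  gid <- rep(seq_len(ngrp), each = k)
  eps <- rowsum(scores$epsilon[idx], gid)
  data.frame(group = sprintf("group_%04d", seq_len(ngrp)),
             epsilon = as.numeric(eps) / k, n_members = k,
             stringsAsFactors = FALSE)
}

# midrank Mann-Whitney U of x vs y (number of (x, y) pairs with y < x,
# ties counted half)
mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# cache of two-sided exact p lookup tables indexed by U (no-ties null)
.mw_cache <- new.env(parent = emptyenv())
.mw_exact_table <- function(n1, n2) {
  key <- paste(n1, n2, sep = "_")
  if (!is.null(.mw_cache[[key]])) return(.mw_cache[[key]])
  u <- 0:(n1 * n2)
  lo <- stats::pwilcox(u, n1, n2)
  hi <- 1 - stats::pwilcox(u - 1, n1, n2)
  tab <- pmin(1, 2 * pmin(lo, hi))
  .mw_cache[[key]] <- tab
  tab
}

#' Two-sided Mann-Whitney p-value of a TSS group vs nontargeting controls
#'
#' Exact p from the null U distribution when the permutation space
#' `n1 * n2 <= exact_max` and the combined sample is tie-free; otherwise a
#' tie-corrected normal approximation with continuity correction. An input in
#' which every value is identical in both lists is degenerate and returns
#' p = 1.
#'
#' @param member_eps epsilon values of the TSS group members.
#' @param nontargeting_eps epsilon values of the nontargeting sgRNAs.
#' @param exact_max largest `n1 * n2` for which the exact distribution is
#'   used.
#' @return two-sided p-value in (0, 1].
#' @examples
#' tss_pvalue(c(3, 4, 5), c(0, 1, 2))  # exact: 0.1
#' @export
tss_pvalue <- function(member_eps, nontargeting_eps, exact_max = 1e5) {
  n1 <- length(member_eps); n2 <- length(nontargeting_eps)
  if (n1 == 0 || n2 == 0) .stopf("both groups must be non-empty")
  comb <- c(member_eps, nontargeting_eps)
  ties <- anyDuplicated(comb) > 0
  u <- mw_u(member_eps, nontargeting_eps)
  if (!ties && n1 * n2 <= exact_max)
    return(.mw_exact_table(n1, n2)[round(u) + 1])
  .mw_normal_p(u, n1, n2, comb)
}

# vectorized grouped Mann-Whitney vs one shared control vector.
# values/gid: one entry per member sgRNA; gid must be consecutive integers
# 1..G with constant group size where possible. Returns data.frame(gid, n, U, p).
.grouped_mw <- function(values, gid, controls, exact_max = 1e5) {
  ys <- sort(controls)
  n2 <- length(ys)
  le <- findInterval(values, ys)
  lt <- findInterval(values, ys, left.open = TRUE)
  contrib <- lt + 0.5 * (le - lt)
  gmax <- max(gid)
  u <- rowsum(contrib, gid, reorder = TRUE)
  n1 <- tabulate(gid, gmax)
  cross_tied <- rowsum(as.numeric(le - lt), gid, reorder = TRUE) > 0
  # within-group duplicated values (vectorized adjacent comparison)
  o <- order(gid, values)
  dup <- c(FALSE, gid[o][-1] == gid[o][-length(o)] &
             values[o][-1] == values[o][-length(o)])
  within_tied <- rowsum(as.numeric(dup), gid[o], reorder = TRUE) > 0
  ctrl_tied <- anyDuplicated(ys) > 0
  tied <- as.logical(cross_tied) | as.logical(within_tied) | ctrl_tied

  p <- numeric(gmax)
  member_of <- split(seq_along(values), gid)
  for (nn1 in unique(n1)) {
    sel <- which(n1 == nn1 & !tied & nn1 * n2 <= exact_max)
    if (length(sel) > 0)
      p[sel] <- .mw_exact_table(nn1, n2)[round(u[sel]) + 1]
    rest <- setdiff(which(n1 == nn1), sel)
    for (g in rest)
      p[g] <- .mw_normal_p(u[g], nn1, n2,
                           c(values[member_of[[g]]], controls))
  }
  data.frame(gid = seq_len(gmax), n = n1, U = as.numeric(u), p = p)
}

# tie-corrected normal approximation with continuity correction, given a
# precomputed midrank U and the combined sample
.mw_normal_p <- function(u, n1, n2, comb) {
  nn <- n1 + n2
  t <- rle(sort(comb))$lengths
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(t^3 - t) / (nn * (nn - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - n1 * n2 / 2
  z <- sign(z) * max(abs(z) - 0.5, 0)
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
}

#' Combined gene score eta
#'
#' eta combines phenotype severity and significance:
#' `eta = |epsilon| * (-ln p)`. It is 0 iff epsilon = 0 or p = 1, and is
#' monotone increasing in `|epsilon|` at fixed p and in `-ln p` at fixed
#' epsilon.
#'
#' @param epsilon gene-level phenotypic score(s).
#' @param p two-sided Mann-Whitney p-value(s) in (0, 1].
#' @return eta >= 0.
#' @export
eta <- function(epsilon, p) {
  if (any(p <= 0) || any(p > 1)) .stopf("p must be in (0, 1]")
  abs(epsilon) * (-log(p))
}

#' Score every TSS of a library
#'
#' Each TSS group is scored by its mean member epsilon, a two-sided
#' Mann-Whitney test against the nontargeting sgRNAs' epsilons, and eta.
#'
#' @param scores score data.frame (per sgRNA; e.g. run-averaged).
#' @param nt_ids nontargeting sgRNA ids.
#' @return data.frame `gene, tss, n_sgrnas, epsilon, p_value, eta`.
#' @export
score_tss <- function(scores, nt_ids) {
  nt_eps <- scores$epsilon[scores$sgrna_id %in% nt_ids]
  if (length(nt_eps) == 0) .stopf("no nontargeting sgRNAs in scores")
  memb <- scores[!is.na(scores$tss), ]
  tss_f <- factor(memb$tss)
  mw <- .grouped_mw(memb$epsilon, as.integer(tss_f), nt_eps)
  eps <- as.numeric(rowsum(memb$epsilon, as.integer(tss_f),
                           reorder = TRUE)) / mw$n
  gene <- memb$gene[match(levels(tss_f), memb$tss)]
  data.frame(gene = gene, tss = levels(tss_f), n_sgrnas = mw$n,
             epsilon = eps, p_value = mw$p, eta = eta(eps, mw$p),
             stringsAsFactors = FALSE)
}

#' Simulated negative controls by random sgRNA regrouping
#'
#' Draws `n_draws` random partitions of *all* sgRNAs in the library
#' (targeting and nontargeting) into groups of `group_size`, dropping
#' leftovers, and scores each group exactly like a gene (mean epsilon,
#' Mann-Whitney vs the nontargeting epsilons, eta). With 6,092 sgRNAs and
#' groups of 10 each draw yields 609 simulated negatives.
#'
#' @param scores per-sgRNA score data.frame.
#' @param nt_ids nontargeting sgRNA ids.
#' @param group_size sgRNAs per simulated negative.
#' @param n_draws number of independent regroupings; eFDR computation scales
#'   exceedance counts by this so a single draw reproduces the raw formula.
#' @param seed RNG seed; deterministic per seed.
#' @return data.frame `draw, group, epsilon, p_value, eta` with attribute
#'   `n_draws`.
#' @export
simulated_negatives <- function(scores, nt_ids, group_size = 10,
                                n_draws = 100, seed = NULL) {
  group_size <- .check_count(group_size, "group_size", min = 1L)
  n <- nrow(scores)
  if (n < group_size) .stopf("library smaller than one group")
  nt_eps <- scores$epsilon[scores$sgrna_id %in% nt_ids]
  .set_seed(seed)
  ngrp <- n %/% group_size
  gid <- rep(seq_len(ngrp), each = group_size)
  out <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    idx <- sample.int(n)[seq_len(ngrp * group_size)]
    vals <- scores$epsilon[idx]
    mw <- .grouped_mw(vals, gid, nt_eps)
    eps <- as.numeric(rowsum(vals, gid, reorder = TRUE)) / group_size
    out[[d]] <- data.frame(draw = d, group = seq_len(ngrp), epsilon = eps,
                           p_value = mw$p, eta = eta(eps, mw$p))
  }
  res <- do.call(rbind, out)
  attr(res, "n_draws") <- n_draws
  res
}

#' Empirical FDR at given cutoffs
#'
#' `eFDR(c) = (#simneg eta > c / n_draws) / (#gene eta > c +
#' #simneg eta > c / n_draws)`, with 0/0 defined as 0. Inequalities are
#' strict: scores tied with the cutoff do not count as positives. With
#' `n_draws = 1` this is the raw count formula.
#'
#' @param cutoffs cutoff value(s) of eta.
#' @param gene_etas gene-level eta scores.
#' @param simneg_etas simulated-negative eta scores (all draws pooled).
#' @param n_draws number of simulated-negative draws pooled in
#'   `simneg_etas`.
#' @return eFDR value(s) in `[0, 1]`.
#' @export
efdr <- function(cutoffs, gene_etas, simneg_etas, n_draws = 1) {
  gs <- sort(gene_etas); ss <- sort(simneg_etas)
  g <- length(gs) - findInterval(cutoffs, gs)
  s <- (length(ss) - findInterval(cutoffs, ss)) / n_draws
  ifelse(g + s == 0, 0, s / (g + s))
}

#' eFDR curve and hit calling
#'
#' Evaluates the eFDR over the observed support (all distinct gene and
#' simulated-negative eta values), monotonizes it (running maximum from the
#' highest cutoff down, so eFDR is non-increasing in the cutoff), picks the
#' smallest observed cutoff whose monotone eFDR is at or below `target`, and
#' calls genes with eta strictly above that cutoff as hits.
#'
#' @param gene_etas gene-level eta scores.
#' @param simneg_etas pooled simulated-negative eta scores.
#' @param target target eFDR (default 0.001, i.e. 0.1%).
#' @param n_draws simulated-negative draw count (see [efdr()]).
#' @return object of class `efdr_curve`: list with `curve` (data.frame
#'   `cutoff, efdr_raw, efdr`), `cutoff` (chosen cutoff; `Inf` when no
#'   observed cutoff attains the target), `target`, and `hits` (logical per
#'   gene in input order).
#' @export
efdr_curve <- function(gene_etas, simneg_etas, target = 0.001, n_draws = 1) {
  if (length(gene_etas) == 0 || length(simneg_etas) == 0)
    .stopf("need non-empty gene and simulated-negative scores")
  cutoffs <- sort(unique(c(gene_etas, simneg_etas)))
  raw <- efdr(cutoffs, gene_etas, simneg_etas, n_draws)
  mono <- rev(cummax(rev(raw)))
  ok <- which(mono <= target)
  chosen <- if (length(ok) > 0) cutoffs[ok[1]] else Inf
  structure(list(curve = data.frame(cutoff = cutoffs, efdr_raw = raw,
                                    efdr = mono),
                 cutoff = chosen, target = target,
                 hits = gene_etas > chosen),
            class = "efdr_curve")
}

#' Collapse TSS scores to gene scores
#'
#' Multi-TSS genes take the TSS with maximal eta.
#' @param tss_scores data.frame from [score_tss()].
#' @return one row per gene.
#' @export
collapse_genes <- function(tss_scores) {
  o <- order(tss_scores$gene, -tss_scores$eta)
  s <- tss_scores[o, ]
  s[!duplicated(s$gene), , drop = FALSE]
}

#' Call hit genes at a target eFDR
#'
#' @param tss_scores data.frame from [score_tss()].
#' @param simnegs data.frame from [simulated_negatives()].
#' @param target target eFDR.
#' @return list with `genes` (gene-level data.frame incl. `hit`), `curve`
#'   (the `efdr_curve`), `cutoff`.
#' @export
call_hits <- function(tss_scores, simnegs, target = 0.001) {
  genes <- collapse_genes(tss_scores)
  nd <- attr(simnegs, "n_draws") %||% max(simnegs$draw)
  ec <- efdr_curve(genes$eta, simnegs$eta, target, n_draws = nd)
  genes$hit <- ec$hits
  rownames(genes) <- NULL
  list(genes = genes, curve = ec, cutoff = ec$cutoff)
}

#' Screen hit rate
#'
#' Hit count as a percentage of genes screened; 15 hits among 544 genes give
#' 2.76%.
#' @param n_hits number of hit genes.
#' @param n_genes number of genes screened.
#' @return percentage.
#' @export
hit_rate <- function(n_hits, n_genes) 100 * n_hits / n_genes

#' Subset a count table by sgRNA efficacy class
#'
#' Keeps nontargeting rows and targeting rows of the requested class
#' (`"top5"` or `"supp5"`), mirroring re-analysis with commercially split
#' half-libraries.
#'
#' @param table count table.
#' @param library a `crispr_library` (provides the efficacy classes).
#' @param class `"top5"` or `"supp5"`.
#' @return filtered count table.
#' @export
subset_by_efficacy <- function(table, library, class = c("top5", "supp5")) {
  class <- match.arg(class)
  cls <- library$sgrnas$efficacy_class[match(table$sgrna_id,
                                             library$sgrnas$sgrna_id)]
  table[is.na(cls) | cls == class, , drop = FALSE]
}

#' Write / read a count table as TSV
#' @param table count table.
#' @param path file path.
#' @param ... passed to [write_tsv()].
#' @return path invisibly (writer); data.frame (reader).
#' @export
write_count_table <- function(table, path, ...) write_tsv(table, path, ...)

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  tab <- read_tsv(path)
  tab$tss[tab$gene == "NONTARGETING"] <- NA_character_
  tab
}
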