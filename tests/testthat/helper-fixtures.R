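# shared fixtures, all built in code at test time

# tiny 3-sgRNA library for hand-arithmetic score checks
toy_library <- function() {
  structure(list(
    genes = "A", tss_map = list(A = "A_T1"),
    sgrnas = data.frame(
      sgrna_id = c("A1", "NT1", "NT2"),
      gene = c("A", "NONTARGETING", "NONTARGETING"),
      tss = c("A_T1", NA, NA),
      efficacy_class = c("top5", NA, NA), stringsAsFactors = FALSE),
    sgrnas_per_tss = 1L, n_nontargeting = 2L), class = "crispr_library")
}

# n well-separated elliptical nuclei on a regular grid (non-overlapping,
# >= 3 px apart), the ground-truth fixture for segmentation oracles
grid_cells <- function(n, pitch = 120, seed = 1) {
  set.seed(seed)
  k <- ceiling(sqrt(n))
  g <- expand.grid(gx = seq_len(k), gy = seq_len(k))[seq_len(n), ]
  data.frame(cell_id = seq_len(n),
             x = g$gx * pitch + stats::runif(n, -8, 8),
             y = g$gy * pitch + stats::runif(n, -8, 8),
             a_px = stats::runif(n, 18, 30), b_px = stats::runif(n, 12, 20),
             theta = stats::runif(n, 0, pi),
             gfp = stats::rlnorm(n, log(3000), 0.2),
             bfp_ln = stats::rnorm(n, 8.6, 0.5), mifp = 0)
}

grid_dims <- function(n, pitch = 120) {
  k <- ceiling(sqrt(n))
  rep((k + 1) * pitch, 2)
}

# exact two-sided Mann-Whitney p by full enumeration of label assignments
# (independent oracle; feasible for small n1, n2)
mw_enum_p <- function(x, y) {
  comb <- c(x, y)
  n1 <- length(x)
  obs <- optenrich:::mw_u(x, y)
  stat_dev <- abs(obs - n1 * length(y) / 2)
  picks <- utils::combn(length(comb), n1)
  stats <- apply(picks, 2, function(ix) optenrich:::mw_u(comb[ix], comb[-ix]))
  mean(abs(stats - n1 * length(y) / 2) >= stat_dev - 1e-9)
}
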