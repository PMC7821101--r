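#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    .stopf("`%s` must be a single integer >= %d (got %s)", name, min,
           paste(x, collapse = ","))
  as.integer(x)
}

.check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || is.na(x) || x < lo || x > hi)
    .stopf("`%s` must be in [%g, %g]", name, lo, hi)
  as.numeric(x)
}

# deterministic sub-seed derivation; stays within 32-bit integer range
.subseed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647)
}

.set_seed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

# FNV-1a hash of a string, hex encoded; used to stamp output files with the
# configuration they came from without an external digest dependency
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 84696351 %% 2147483648
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

#' Write a table as TSV with a provenance header
#'
#' All pipeline outputs carry a comment header recording the seed and a hash
#' of the configuration that produced them, so a run can be matched to its
#' inputs and re-runs can be compared byte for byte.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param seed integer seed recorded in the header (or NULL).
#' @param config_hash configuration hash string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(seed) || !is.null(config_hash)) {
    writeLines(sprintf("# optenrich seed=%s config=%s",
                       seed %||% "NA", config_hash %||% "NA"), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame (header comment lines are skipped).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# rank-sum AUC for a two-class separation (probability that a randomly chosen
# positive scores above a randomly chosen negative, ties counted half)
auc_rank <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
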