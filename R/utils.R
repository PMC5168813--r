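# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named substream seed from a master seed
#'
#' Each stochastic component of the synthetic generator draws from its own
#' substream so that, e.g., regenerating germination data does not perturb
#' the metabolite draws. The substream seed is a deterministic hash of the
#' master seed and the component name, kept below 2^31.
#'
#' @param seed master integer seed.
#' @param name component name (character scalar).
#' @return an integer seed.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) + 7919 * h) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones. Used to score recovery of the planted metabolite sets.
#'
#' @param a,b vectors of labels of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# TSV I/O conventions: tab separated, UTF-8, "NA" for missing, no quoting
# unless needed, never row names.
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# stop() with a consistent prefix so pipeline errors name their stage
stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
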