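# Shared fixtures, all generated in code.

# Reduced-size generator configuration for fast unit tests.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_lines = 10, n_metabolites = 12, set_sizes = c(7, 5),
         n_plots = 5, n_blocks = 2, rng_seed = 101),
    list(...))
  do.call(synth_config, args)
}

# A generator configuration with every systematic effect switched off:
# pure two-set correlation noise.
null_config <- function(...) {
  small_config(qtl_effect = 0, treatment_effect = 0, failure_frac = 0,
               abortion_salinity_effect = 0, n_weight_qtl_lines = 0,
               germ_beta = 0, t50_gamma = 0, ...)
}

# Hand-built peak table: `n` samples in one block, values supplied by rows.
manual_peak_table <- function(values, seed_mass = NULL, block = NULL,
                              treatment = NULL) {
  n <- nrow(values)
  mets <- sprintf("m%d", seq_len(ncol(values)))
  colnames(values) <- mets
  df <- data.frame(
    sample_id = sprintf("s%d", seq_len(n)),
    line = sprintf("L%d", seq_len(n)),
    treatment = treatment %||% rep("SDF", n),
    season = "S1", plot = seq_len(n),
    run_block = block %||% rep("B1", n),
    seed_mass_extracted = seed_mass %||% rep(1, n))
  peak_table(cbind(df, values), metabolites = mets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent per-seed reconstruction of plate traits: expand the daily
# increments into individual seed days and recompute everything directly.
brute_force_plate <- function(cumulative, seeds_sown) {
  inc <- diff(c(0, cumulative))
  days <- rep(seq_along(cumulative), inc)
  final <- length(days)
  list(
    percent = 100 * final / seeds_sown,
    t50 = if (final == 0) NA_real_ else {
      target <- final / 2
      cnt <- 0
      ans <- NA_real_
      for (d in seq_along(cumulative)) {
        cnt <- cumulative[d]
        if (cnt >= target) { ans <- d; break }
      }
      as.numeric(ans)
    },
    sd_plate = if (final < 2) NA_real_ else stats::sd(days))
}

# Random plate generator for property tests.
random_plate <- function(max_day = 10, seeds = 50) {
  inc <- stats::rmultinom(1, stats::rbinom(1, seeds, stats::runif(1)),
                          prob = stats::runif(max_day))[, 1]
  cumsum(inc)
}

# Exhaustive minimum-frustration search over all 2-colorings, written
# directly against the edge list (independent of signed_bipartition).
exhaustive_frustration <- function(edges, n, weighted = TRUE) {
  best <- Inf
  w <- if (weighted) abs(edges$w) else rep(1, nrow(edges))
  for (code in 0:(2^n - 1)) {
    side <- as.integer(intToBits(code))[seq_len(n)]
    same <- side[edges$from] == side[edges$to]
    f <- sum(w[(edges$s > 0 & !same) | (edges$s < 0 & same)])
    if (f < best) best <- f
  }
  best
}

# Random signed graph as edge list + igraph object.
random_signed_graph <- function(n, p_edge = 0.5) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0)
    return(NULL)
  w <- stats::runif(nrow(pairs), 0.2, 1)
  s <- sample(c(-1L, 1L), nrow(pairs), replace = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = sprintf("v%d", pairs[, 1]),
               to = sprintf("v%d", pairs[, 2]),
               sign = s, weight = w, r = w * s),
    directed = FALSE, vertices = sprintf("v%d", seq_len(n)))
  list(g = g, edges = data.frame(from = pairs[, 1], to = pairs[, 2],
                                 w = w, s = s), n = n)
}
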