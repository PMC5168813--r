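#' Principal component analysis of the metabolite matrix
#'
#' PCA of the (column-centered, by default unit-scaled) complete log RMC
#' matrix. Component signs are fixed by making the largest-magnitude
#' loading of every component positive, so results are deterministic.
#'
#' @param mat complete numeric matrix, plots in rows.
#' @param center,scale passed to [stats::prcomp()].
#' @return object of class `seedmet_pca`: `scores` (plots x components),
#'   `loadings` (metabolites x components), `variance_explained`
#'   (fractions, non-increasing).
#' @export
run_pca <- function(mat, center = TRUE, scale = TRUE) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2) stop("PCA needs at least two plots")
  if (anyNA(mat)) stop("PCA needs a complete (imputed) matrix")
  keep <- apply(mat, 2, stats::sd) > 0
  pc <- stats::prcomp(mat[, keep, drop = FALSE], center = center,
                      scale. = scale)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve), class = "seedmet_pca")
}

#' K-means clustering of plots by metabolic profile
#'
#' Euclidean k-means with multiple random restarts (best within-cluster sum
#' of squares kept); deterministic given `rng_seed`.
#'
#' @param mat complete numeric matrix, plots in rows.
#' @param k number of clusters.
#' @param n_restarts random initializations.
#' @param rng_seed seed for the restarts.
#' @return integer cluster assignment named by row; attributes `wcss`
#'   (total within-cluster sum of squares) and `centers`.
#' @export
kmeans_plots <- function(mat, k = 3, n_restarts = 50, rng_seed = 1) {
  stopifnot(is.matrix(mat), k >= 1)
  if (k > nrow(mat)) stop("k exceeds the number of plots")
  set.seed(substream_seed(rng_seed, "kmeans"))
  km <- stats::kmeans(mat, centers = k, nstart = n_restarts, iter.max = 100)
  structure(stats::setNames(km$cluster, rownames(mat)),
            wcss = km$tot.withinss, centers = km$centers)
}

#' Chi-square enrichment of germination groups across clusters
#'
#' Pearson chi-square test (no continuity correction) of the k x g
#' contingency table of cluster assignment against germination group,
#' plus the per-cluster composition percentages and the overall group
#' proportions they are compared against.
#'
#' @param assignment cluster ids, aligned with `groups`.
#' @param groups germination groups ([classify_germination_group()]).
#' @return list: `table`, `composition` (percent within cluster),
#'   `overall` (percent over all plots), `statistic`, `df`, `p_value`,
#'   `low_expected` flag (any expected cell below 1).
#' @export
cluster_germination_enrichment <- function(assignment, groups) {
  stopifnot(length(assignment) == length(groups))
  ok <- !is.na(assignment) & !is.na(groups)
  tab <- table(cluster = assignment[ok], group = droplevels(factor(groups[ok])))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1))
    warning("expected cell count below 1; chi-square approximation is weak")
  chi <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(table = tab,
       composition = 100 * prop.table(tab, margin = 1),
       overall = 100 * prop.table(colSums(tab)),
       statistic = unname(chi), df = df,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE),
       low_expected = any(expected < 1))
}

#' Per-metabolite contrasts between germination groups
#'
#' Welch t-test of every metabolite between the well-germinating and
#' non-germinating plots on the log scale, marked by the permissive
#' Bonferroni rule with n = number of metabolites. Fold differences are
#' reported on the linear RMC scale (ratio of back-transformed group
#' means), in both directions, with the intermediate-group mean for the
#' three-group profile.
#'
#' @param mat complete log RMC matrix, plots in rows.
#' @param groups germination groups aligned with the rows.
#' @param rule multiplicity rule.
#' @return data frame: metabolite, means (linear scale) per group, t, p,
#'   fold_non_over_well, fold_well_over_non, significant.
#' @export
germination_group_contrasts <- function(mat, groups, rule = "Bcp_05") {
  stopifnot(is.matrix(mat), length(groups) == nrow(mat))
  groups <- factor(groups, levels = c("non", "intermediate", "well"))
  n_non <- sum(groups == "non", na.rm = TRUE)
  n_well <- sum(groups == "well", na.rm = TRUE)
  if (n_non < 2 || n_well < 2)
    stop("need at least two plots in each of the non and well groups")
  lin <- exp(mat)
  mean_of <- function(g) colMeans(lin[which(groups == g), , drop = FALSE])
  m_non <- mean_of("non"); m_int <- mean_of("intermediate")
  m_well <- mean_of("well")
  w <- welch_rows(colMeans(mat[which(groups == "well"), , drop = FALSE]),
                  apply(mat[which(groups == "well"), , drop = FALSE], 2,
                        stats::var),
                  rep(n_well, ncol(mat)),
                  colMeans(mat[which(groups == "non"), , drop = FALSE]),
                  apply(mat[which(groups == "non"), , drop = FALSE], 2,
                        stats::var),
                  rep(n_non, ncol(mat)))
  cutoff <- multiplicity_cutoff(rule, ncol(mat))
  out <- data.frame(metabolite = colnames(mat),
                    mean_non = m_non, mean_intermediate = m_int,
                    mean_well = m_well,
                    t = w$t, p_value = w$p,
                    fold_non_over_well = m_non / m_well,
                    fold_well_over_non = m_well / m_non,
                    threshold_rule = rule,
                    significant = !is.na(w$p) & w$p < cutoff)
  rownames(out) <- NULL
  out
}
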