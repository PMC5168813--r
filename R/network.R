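#' Spearman correlation matrix with p-values
#'
#' Pairwise Spearman rank correlations (average ranks for ties, pairwise
#' complete observations) with two-sided p-values from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))`. Constant columns cannot be ranked
#' against anything; they are reported in the `excluded` attribute and their
#' correlations set to `NA`.
#'
#' @param mat numeric matrix, observations in rows, variables in columns.
#' @return list with `r`, `p` and `n` matrices; attribute `excluded` lists
#'   constant columns.
#' @export
spearman_matrix <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  const <- apply(mat, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) < 2 || stats::sd(x) == 0
  })
  r <- suppressWarnings(stats::cor(mat, method = "spearman",
                                   use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(mat))
  r[const, ] <- NA; r[, const] <- NA
  diag(r) <- 1
  tstat <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), pmax(n - 2, 1))
  p[n < 4] <- NA
  diag(p) <- NA
  structure(list(r = r, p = p, n = n), excluded = colnames(mat)[const])
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Classic FDR step-up: sorted p-values are multiplied by m / i and made
#' monotone from the largest down, capped at 1. `NA`s are preserved and do
#' not count towards m.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  m <- sum(ok)
  if (m == 0) return(out)
  po <- p[ok]
  o <- order(po, decreasing = TRUE)
  adj <- pmin(1, cummin(po[o] * m / seq(m, 1)))
  out[ok] <- adj[order(o)]
  out
}

#' Build a signed correlation network
#'
#' Edges are the variable pairs with FDR-adjusted p below `q` and |r| of at
#' least `r_min`; the sign of r is carried as an edge attribute and |r| as the
#' edge weight (random-walk algorithms need non-negative weights). Nodes
#' without any retained edge are dropped.
#'
#' @param sp result of [spearman_matrix()], or a list with `r` and `p`
#'   matrices.
#' @param r_min minimal absolute correlation.
#' @param q FDR threshold applied to [bh_fdr()]-adjusted p-values of the
#'   upper triangle.
#' @return an [igraph][igraph::graph_from_data_frame] graph with edge
#'   attributes `r`, `p_adj`, `sign`, `weight`.
#' @export
build_network <- function(sp, r_min = 0.4, q = 0.05) {
  r <- sp$r; p <- sp$p
  stopifnot(identical(dim(r), dim(p)))
  vars <- colnames(r)
  ut <- upper.tri(r)
  idx <- which(ut, arr.ind = TRUE)
  p_adj <- bh_fdr(p[ut])
  keep <- !is.na(p_adj) & p_adj < q & !is.na(r[ut]) & abs(r[ut]) >= r_min
  edges <- data.frame(from = vars[idx[keep, 1]], to = vars[idx[keep, 2]],
                      r = r[ut][keep], p_adj = p_adj[keep],
                      sign = ifelse(r[ut][keep] >= 0, 1L, -1L),
                      weight = abs(r[ut][keep]))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vars)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  g$r_min <- r_min
  g$q <- q
  g
}

#' Graph-theory attributes of a network
#'
#' The standard descriptors of the unsigned topology: node and signed edge
#' counts, edge/node ratio, average degree (2E/N), density (2E/(N(N-1))),
#' global transitivity, and diameter / average path length computed
#' unweighted on the largest connected component.
#'
#' @param g network from [build_network()].
#' @return one-row data frame.
#' @export
network_attributes <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0)
    return(data.frame(n_nodes = 0, n_pos_edges = NA, n_neg_edges = NA,
                      n_edges = NA, edge_node_ratio = NA, avg_degree = NA,
                      diameter = NA, density = NA, avg_path_length = NA,
                      transitivity = NA))
  e <- igraph::ecount(g)
  sgn <- igraph::E(g)$sign %||% rep(1L, e)
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  data.frame(
    n_nodes = n,
    n_pos_edges = sum(sgn > 0),
    n_neg_edges = sum(sgn < 0),
    n_edges = e,
    edge_node_ratio = e / n,
    avg_degree = 2 * e / n,
    diameter = igraph::diameter(giant, weights = NA),
    density = if (n > 1) 2 * e / (n * (n - 1)) else NA,
    avg_path_length = igraph::mean_distance(giant, weights = NA),
    transitivity = igraph::transitivity(giant, type = "global"))
}

#' Network attributes across candidate |r| thresholds
#'
#' Rebuilds the network at each candidate cutoff and tabulates the
#' attributes, supporting a graph-measure-guided choice of threshold (edge
#' counts are non-increasing in the cutoff by construction).
#'
#' @inheritParams build_network
#' @param thresholds ascending vector of candidate |r| cutoffs.
#' @return data frame, one row per threshold.
#' @export
threshold_scan <- function(sp, thresholds, q = 0.05) {
  stopifnot(!is.unsorted(thresholds))
  do.call(rbind, lapply(thresholds, function(th) {
    cbind(r_min = th, network_attributes(build_network(sp, r_min = th, q = q)))
  }))
}

#' Walktrap community detection
#'
#' Agglomerative communities from short random walks, using |r| as edge
#' weight (edge signs are not valid walk weights and are carried
#' separately); the dendrogram is cut at maximal modularity. Deterministic
#' for a fixed input graph.
#'
#' @param g network from [build_network()].
#' @param steps random-walk length.
#' @return named integer vector: community id per node; attributes record
#'   the parameters.
#' @export
walktrap_communities <- function(g, steps = 4) {
  stopifnot(igraph::vcount(g) > 0)
  wt <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                 steps = steps)
  structure(stats::setNames(igraph::membership(wt),
                            igraph::V(g)$name),
            steps = steps, weights = "abs_r")
}

# frustration of a two-coloring: positive edges across sides and negative
# edges within a side are frustrated; weighted by w
frustration_of <- function(side, ep, w, sgn) {
  same <- side[ep[, 1]] == side[ep[, 2]]
  sum(w[(sgn > 0 & !same) | (sgn < 0 & same)])
}

signed_edge_parts <- function(g, weighted) {
  ep <- igraph::as_edgelist(g, names = FALSE)
  sgn <- igraph::E(g)$sign %||% sign(igraph::E(g)$r)
  w <- if (weighted) igraph::E(g)$weight %||% rep(1, nrow(ep)) else
    rep(1, nrow(ep))
  list(ep = ep, sgn = sgn, w = w)
}

#' Minimum-frustration signed bipartition of a (sub)graph
#'
#' Splits the nodes into two subsets so that positive edges fall within a
#' subset and negative edges across, minimizing the total (|r|-weighted)
#' frustration. Exact enumeration over all 2-colorings up to `exact_limit`
#' nodes; above that, a deterministic spectral start (leading eigenvector of
#' the signed adjacency) refined by single-move local search. An
#' all-positive graph yields one subset and an empty partner.
#'
#' @param g signed (sub)graph with edge attributes `sign` and `weight`.
#' @param exact_limit maximal size for exhaustive search.
#' @param weighted use |r| weights (`TRUE`) or count edges (`FALSE`).
#' @return list with `A`, `B` (node name vectors) and `frustration`.
#' @export
signed_bipartition <- function(g, exact_limit = 15, weighted = TRUE) {
  n <- igraph::vcount(g)
  stopifnot(n >= 1)
  nodes <- igraph::V(g)$name
  if (igraph::ecount(g) == 0)
    return(list(A = nodes, B = character(0), frustration = 0))
  parts <- signed_edge_parts(g, weighted)

  if (n <= exact_limit) {
    best <- NULL; best_f <- Inf
    for (code in 0:(2^(n - 1) - 1)) {           # node 1 fixed to side A
      side <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
      f <- frustration_of(side, parts$ep, parts$w, parts$sgn)
      if (f < best_f) { best_f <- f; best <- side }
    }
    side <- best
  } else {
    # deterministic multi-start: spectral seed plus LCG-generated restarts,
    # each refined by single-move local search; best coloring kept
    S <- matrix(0, n, n)
    S[parts$ep] <- parts$w * parts$sgn
    S <- S + t(S)
    ev <- eigen(S, symmetric = TRUE)$vectors[, 1]
    starts <- list(as.integer(ev < 0), as.integer(ev > 0),
                   rep(0L, n))
    lcg <- 48271
    for (k in seq_len(25)) {
      bits <- integer(n)
      for (i in seq_len(n)) {
        lcg <- (lcg * 69621) %% 2147483647
        bits[i] <- as.integer(lcg %% 2L)
      }
      starts[[length(starts) + 1]] <- bits
    }
    side <- NULL; best_f <- Inf
    for (s0 in starts) {
      s1 <- local_search_bipartition(s0, parts)
      f <- frustration_of(s1, parts$ep, parts$w, parts$sgn)
      if (f < best_f) { best_f <- f; side <- s1 }
    }
  }
  list(A = nodes[side == 0L], B = nodes[side == 1L],
       frustration = frustration_of(side, parts$ep, parts$w, parts$sgn))
}

local_search_bipartition <- function(side, parts) {
  repeat {
    f0 <- frustration_of(side, parts$ep, parts$w, parts$sgn)
    gains <- vapply(seq_along(side), function(i) {
      s2 <- side; s2[i] <- 1L - s2[i]
      f0 - frustration_of(s2, parts$ep, parts$w, parts$sgn)
    }, numeric(1))
    if (max(gains) <= 1e-12) return(side)
    i <- which.max(gains)
    side[i] <- 1L - side[i]
  }
}

#' Assemble the global metabolite sets ms1/ms2
#'
#' Every community is first split into its two sign-consistent subsets
#' ([signed_bipartition()]); the subsets then become the nodes of a signed
#' meta-graph whose meta-edges aggregate all correlations between two
#' subsets (weight = sum of |r|, sign = sign of the signed sum). A second
#' frustration minimization 2-colors the meta-graph, producing the two
#' global, mutually antagonistic sets. Orientation rule: the side holding
#' the majority of metabolites negatively tied to germination percent (or
#' positively to T50 / SD-plate) is labelled ms1.
#'
#' @param g network from [build_network()].
#' @param membership community vector from [walktrap_communities()].
#' @param germination_nodes names of germination trait nodes (assigned to a
#'   set like any node but excluded from the orientation majority count).
#' @param exact_limit passed to [signed_bipartition()].
#' @return object of class `metabolite_sets`: data frame `sets` (node,
#'   community, subset, set), `frustration` (within-community total),
#'   `meta_frustration`, and `orientation` ("germination_anchored" or
#'   "arbitrary").
#' @export
assemble_metabolite_sets <- function(g, membership,
                                     germination_nodes = c("percent", "t50",
                                                           "sd_plate"),
                                     exact_limit = 15) {
  nodes <- igraph::V(g)$name
  stopifnot(all(nodes %in% names(membership)))
  subset_id <- character(length(nodes)); names(subset_id) <- nodes
  frustration <- 0
  for (cm in sort(unique(membership[nodes]))) {
    members <- nodes[membership[nodes] == cm]
    sub <- igraph::induced_subgraph(g, members)
    bp <- signed_bipartition(sub, exact_limit = exact_limit)
    subset_id[bp$A] <- sprintf("c%s.a", cm)
    if (length(bp$B) > 0) subset_id[bp$B] <- sprintf("c%s.b", cm)
    frustration <- frustration + bp$frustration
  }

  # signed meta-graph over community subsets
  subsets <- sort(unique(subset_id))
  ep <- igraph::as_edgelist(g)
  r <- igraph::E(g)$r
  su <- subset_id[ep[, 1]]; sv <- subset_id[ep[, 2]]
  cross <- su != sv
  meta_side <- stats::setNames(rep(0L, length(subsets)), subsets)
  meta_frustration <- 0
  if (any(cross)) {
    key <- paste(pmin(su[cross], sv[cross]), pmax(su[cross], sv[cross]),
                 sep = "|")
    ssum <- tapply(r[cross], key, sum)
    wsum <- tapply(abs(r[cross]), key, sum)
    pair <- do.call(rbind, strsplit(names(ssum), "|", fixed = TRUE))
    mg <- igraph::graph_from_data_frame(
      data.frame(from = pair[, 1], to = pair[, 2],
                 sign = ifelse(ssum >= 0, 1L, -1L),
                 weight = as.numeric(wsum), r = as.numeric(ssum)),
      directed = FALSE, vertices = subsets)
    mbp <- signed_bipartition(mg, exact_limit = exact_limit)
    meta_side[mbp$B] <- 1L
    meta_frustration <- mbp$frustration
  }
  side <- stats::setNames(unname(meta_side[subset_id]), nodes)

  # orient: germination-negative metabolites define ms1
  orientation <- "arbitrary"
  gnodes <- intersect(germination_nodes, nodes)
  if (length(gnodes) > 0) {
    votes <- c(0, 0)  # votes for side 0/1 being ms1
    for (i in seq_len(nrow(ep))) {
      a <- ep[i, 1]; b <- ep[i, 2]
      tn <- if (a %in% gnodes) a else if (b %in% gnodes) b else next
      mn <- setdiff(c(a, b), tn)
      if (mn %in% gnodes) next
      ms1_like <- (tn == "percent" && r[i] < 0) ||
        (tn %in% c("t50", "sd_plate") && r[i] > 0)
      if (ms1_like) votes[side[mn] + 1] <- votes[side[mn] + 1] + abs(r[i])
    }
    if (sum(votes) > 0) {
      orientation <- "germination_anchored"
      ms1_side <- which.max(votes) - 1L
      if (ms1_side == 1L) side <- 1L - side
    }
  }

  sets <- data.frame(node = nodes,
                     community = as.integer(membership[nodes]),
                     subset = unname(subset_id),
                     set = ifelse(side[nodes] == 0L, "ms1", "ms2"),
                     is_trait = nodes %in% germination_nodes)
  rownames(sets) <- NULL
  structure(list(sets = sets, frustration = frustration,
                 meta_frustration = meta_frustration,
                 orientation = orientation),
            class = "metabolite_sets")
}

#' Germination-edge consistency report
#'
#' Lists, per germination trait node, all incident metabolite edges with
#' their correlation, sign and set membership, and scores how well they obey
#' the canonical structure: percent-negative / T50-positive /
#' SD-plate-positive partners in ms1, the mirrored signs in ms2.
#'
#' @param g network including germination trait nodes.
#' @param sets result of [assemble_metabolite_sets()].
#' @param germination_nodes trait node names.
#' @return data frame of germination edges; attribute `consistency` holds
#'   the fraction of edges obeying the rule.
#' @export
germination_edge_report <- function(g, sets,
                                    germination_nodes = c("percent", "t50",
                                                          "sd_plate")) {
  stopifnot(inherits(sets, "metabolite_sets"))
  set_of <- stats::setNames(sets$sets$set, sets$sets$node)
  ep <- igraph::as_edgelist(g)
  r <- igraph::E(g)$r
  rows <- list()
  for (i in seq_len(nrow(ep))) {
    a <- ep[i, 1]; b <- ep[i, 2]
    tn <- if (a %in% germination_nodes) a else
      if (b %in% germination_nodes) b else next
    mn <- setdiff(c(a, b), tn)
    if (length(mn) != 1 || mn %in% germination_nodes) next
    expected_set <- if ((tn == "percent" && r[i] < 0) ||
                          (tn %in% c("t50", "sd_plate") && r[i] > 0))
      "ms1" else "ms2"
    rows[[length(rows) + 1]] <- data.frame(
      trait = tn, metabolite = mn, r = r[i],
      sign = ifelse(r[i] >= 0, "+", "-"),
      set = unname(set_of[mn]), expected_set = expected_set,
      consistent = unname(set_of[mn]) == expected_set)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(trait = character(), metabolite = character(), r = numeric(),
               sign = character(), set = character(),
               expected_set = character(), consistent = logical())
  attr(out, "consistency") <- if (nrow(out) > 0) mean(out$consistent) else
    NA_real_
  out
}
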