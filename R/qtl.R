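#' Permissive Bonferroni cutoff
#'
#' The strict Bonferroni rule (alpha / n) is severe for thousands of
#' IL-by-metabolite comparisons at five replicates; the permissive variant
#' divides alpha by the square root of the number of comparisons instead,
#' trading family-wise stringency for discovery power.
#'
#' @param alpha nominal level in (0, 1).
#' @param n number of comparisons (>= 1).
#' @return alpha / sqrt(n).
#' @export
permissive_bonferroni_cutoff <- function(alpha, n) {
  stopifnot(alpha > 0, alpha < 1)
  if (n < 1) stop("n must be >= 1")
  alpha / sqrt(n)
}

#' Resolve a multiplicity rule to a p-value cutoff
#'
#' Rules: `Bcp_05`, `Bcp_01`, `Bcp_001` (permissive Bonferroni at alpha
#' 0.05 / 0.01 / 0.001, the three asterisk tiers), `Bc_05` (strict
#' Bonferroni at 0.05), `raw_05`, `raw_01` (unadjusted).
#'
#' @param rule rule name.
#' @param n number of comparisons in the scan.
#' @return numeric cutoff.
#' @export
multiplicity_cutoff <- function(rule, n) {
  if (n < 1) stop("n must be >= 1")
  switch(rule,
         Bcp_05 = permissive_bonferroni_cutoff(0.05, n),
         Bcp_01 = permissive_bonferroni_cutoff(0.01, n),
         Bcp_001 = permissive_bonferroni_cutoff(0.001, n),
         Bc_05 = 0.05 / n,
         raw_05 = 0.05,
         raw_01 = 0.01,
         stop("unknown multiplicity rule: ", rule))
}

# Vectorized Welch machinery over aligned columns: x_* and y_* are matrices
# with one row per test. Returns t, df, p and the mean difference.
welch_rows <- function(mx, vx, nx, my, vy, ny) {
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  degenerate <- se2 == 0
  t[degenerate] <- 0
  df[degenerate] <- nx[degenerate] + ny[degenerate] - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[degenerate & (mx == my)] <- 1
  list(t = t, df = df, p = p, estimate = mx - my)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. When both groups have zero variance and equal
#' means the p-value is 1 by convention.
#'
#' @param x,y numeric vectors with at least two values each.
#' @return list with `t`, `df`, `p` and `estimate` (mean(x) - mean(y)).
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least two values")
  r <- welch_rows(mean(x), stats::var(x), length(x),
                  mean(y), stats::var(y), length(y))
  lapply(r, unname)
}

group_stats <- function(mat, rows) {
  sub <- mat[rows, , drop = FALSE]
  n <- colSums(!is.na(sub))
  m <- colMeans(sub, na.rm = TRUE)
  v <- apply(sub, 2, stats::var, na.rm = TRUE)
  list(m = m, v = v, n = n)
}

qtl_record <- function(line, trait, contrast, estimate, p_value, rule,
                       cutoff) {
  data.frame(line = line, trait = trait, contrast = contrast,
             direction = ifelse(estimate >= 0, "+", "-"),
             estimate = estimate, p_value = p_value,
             threshold_rule = rule,
             significant = !is.na(p_value) & p_value < cutoff)
}

#' Scan a trait table for putative QTLs (IL vs control)
#'
#' Each IL is compared to the control line by a Welch t-test on plot-level
#' values within one condition: log RMC for metabolites, raw values for
#' morphology and germination traits. Significance is marked by the
#' multiplicity rule with n = the number of IL-by-trait comparisons
#' actually performed in the scan.
#'
#' @param traits data frame with `line`, `treatment` and numeric trait
#'   columns (e.g. a log `rmc_table` or [germination_traits()] output).
#' @param trait_cols trait columns to scan.
#' @param control control line name.
#' @param condition treatment level to scan (`"SDF"` or `"SDS"`).
#' @param rule multiplicity rule (see [multiplicity_cutoff()]).
#' @return data frame of QTL records (one row per IL x trait).
#' @export
detect_trait_qtls <- function(traits, trait_cols, control,
                              condition = "SDF", rule = "Bcp_05") {
  df <- as.data.frame(traits)[traits$treatment == condition, , drop = FALSE]
  mat <- as.matrix(df[, trait_cols, drop = FALSE])
  if (!any(df$line == control)) stop("control line absent from condition")
  ctl <- group_stats(mat, df$line == control)
  if (any(ctl$n < 2))
    stop("control line needs >= 2 replicates for every trait")
  ils <- setdiff(unique(df$line), control)
  contrast <- paste0("IL_vs_control@", condition)
  recs <- list()
  for (ln in ils) {
    g <- group_stats(mat, df$line == ln)
    ok <- g$n >= 2
    if (!all(ok))
      warning("line ", ln, " skipped for ", sum(!ok),
              " trait(s) with < 2 replicates")
    if (!any(ok)) next
    r <- welch_rows(g$m[ok], g$v[ok], g$n[ok],
                    ctl$m[ok], ctl$v[ok], ctl$n[ok])
    recs[[ln]] <- data.frame(line = ln, trait = trait_cols[ok],
                             estimate = r$estimate, p_value = r$p)
  }
  flat <- do.call(rbind, recs)
  if (is.null(flat))
    return(qtl_record(character(), character(), character(), numeric(),
                      numeric(), character(), 1))
  n_comp <- nrow(flat)
  cutoff <- multiplicity_cutoff(rule, n_comp)
  out <- qtl_record(flat$line, flat$trait, contrast, flat$estimate,
                    flat$p_value, rule, cutoff)
  rownames(out) <- NULL
  attr(out, "n_comparisons") <- n_comp
  attr(out, "cutoff") <- cutoff
  out
}

#' Within-line salinity (SDS vs SDF) treatment-effect tests
#'
#' For every line and trait, a Welch t-test of SDS against SDF plot-level
#' values; the estimate is the SDS minus SDF mean difference.
#'
#' @inheritParams detect_trait_qtls
#' @return data frame of QTL records (contrast `SDS_vs_SDF_within_line`).
#' @export
detect_treatment_effects <- function(traits, trait_cols, rule = "raw_01") {
  df <- as.data.frame(traits)
  mat <- as.matrix(df[, trait_cols, drop = FALSE])
  recs <- list()
  for (ln in unique(df$line)) {
    sds <- group_stats(mat, df$line == ln & df$treatment == "SDS")
    sdf <- group_stats(mat, df$line == ln & df$treatment == "SDF")
    ok <- sds$n >= 2 & sdf$n >= 2
    if (!any(ok)) {
      warning("line ", ln, " skipped: a treatment has < 2 replicates")
      next
    }
    r <- welch_rows(sds$m[ok], sds$v[ok], sds$n[ok],
                    sdf$m[ok], sdf$v[ok], sdf$n[ok])
    recs[[ln]] <- data.frame(line = ln, trait = trait_cols[ok],
                             estimate = r$estimate, p_value = r$p)
  }
  flat <- do.call(rbind, recs)
  if (is.null(flat))
    return(qtl_record(character(), character(), character(), numeric(),
                      numeric(), character(), 1))
  n_comp <- nrow(flat)
  cutoff <- multiplicity_cutoff(rule, n_comp)
  out <- qtl_record(flat$line, flat$trait, "SDS_vs_SDF_within_line",
                    flat$estimate, flat$p_value, rule, cutoff)
  rownames(out) <- NULL
  attr(out, "n_comparisons") <- n_comp
  attr(out, "cutoff") <- cutoff
  out
}

#' Fold-change (salinity response) QTL scan
#'
#' Compares the salinity fold change of each metabolite in each IL to the
#' control line's fold change on the log scale, i.e. the interaction
#' contrast (IL,SDS - IL,SDF) - (control,SDS - control,SDF). The standard
#' error pools the four cell variances and the degrees of freedom follow
#' Welch-Satterthwaite over the four cells. The estimate's sign equals the
#' sign of log(FC_IL / FC_control) computed from the cell means.
#'
#' @param log_rmc log-transformed trait table (`line`, `treatment`, trait
#'   columns).
#' @inheritParams detect_trait_qtls
#' @return data frame of QTL records (contrast `FC_vs_control`).
#' @export
detect_fc_qtls <- function(log_rmc, trait_cols, control, rule = "Bc_05") {
  df <- as.data.frame(log_rmc)
  mat <- as.matrix(df[, trait_cols, drop = FALSE])
  cells <- function(ln) list(
    sdf = group_stats(mat, df$line == ln & df$treatment == "SDF"),
    sds = group_stats(mat, df$line == ln & df$treatment == "SDS"))
  ctl <- cells(control)
  if (any(ctl$sdf$n < 2) || any(ctl$sds$n < 2))
    stop("control line needs >= 2 replicates in both conditions")
  recs <- list()
  for (ln in setdiff(unique(df$line), control)) {
    il <- cells(ln)
    ok <- il$sdf$n >= 2 & il$sds$n >= 2
    if (!all(ok))
      warning("line ", ln, " skipped for ", sum(!ok),
              " trait(s): empty or singleton cell")
    if (!any(ok)) next
    est <- (il$sds$m[ok] - il$sdf$m[ok]) - (ctl$sds$m[ok] - ctl$sdf$m[ok])
    parts <- cbind(il$sds$v[ok] / il$sds$n[ok],
                   il$sdf$v[ok] / il$sdf$n[ok],
                   ctl$sds$v[ok] / ctl$sds$n[ok],
                   ctl$sdf$v[ok] / ctl$sdf$n[ok])
    dfs <- cbind(il$sds$n[ok] - 1, il$sdf$n[ok] - 1,
                 ctl$sds$n[ok] - 1, ctl$sdf$n[ok] - 1)
    se2 <- rowSums(parts)
    nu <- se2^2 / rowSums(parts^2 / dfs)
    t <- est / sqrt(se2)
    p <- 2 * stats::pt(-abs(t), nu)
    p[se2 == 0 & est == 0] <- 1
    recs[[ln]] <- data.frame(line = ln, trait = trait_cols[ok],
                             estimate = est, p_value = p)
  }
  flat <- do.call(rbind, recs)
  if (is.null(flat))
    return(qtl_record(character(), character(), character(), numeric(),
                      numeric(), character(), 1))
  n_comp <- nrow(flat)
  cutoff <- multiplicity_cutoff(rule, n_comp)
  out <- qtl_record(flat$line, flat$trait, "FC_vs_control", flat$estimate,
                    flat$p_value, rule, cutoff)
  rownames(out) <- NULL
  attr(out, "n_comparisons") <- n_comp
  attr(out, "cutoff") <- cutoff
  out
}
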