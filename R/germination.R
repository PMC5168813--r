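#' Final germination percent of a plate
#'
#' @param cumulative non-decreasing vector of cumulative germinated counts,
#'   one entry per scored day.
#' @param seeds_sown number of seeds sown (> 0).
#' @return percent of sown seeds that germinated (0-100).
#' @export
plate_percent <- function(cumulative, seeds_sown) {
  check_cumulative(cumulative, seeds_sown)
  100 * utils::tail(cumulative, 1) / seeds_sown
}

#' T50 of a plate
#'
#' The first day on which cumulative germination reaches 50% of the seeds
#' that eventually germinated in that plate (not of the seeds sown).
#' Undefined (`NA`) when nothing germinated.
#'
#' @inheritParams plate_percent
#' @return integer day, or `NA` if no seed germinated.
#' @export
plate_t50 <- function(cumulative, seeds_sown = NULL) {
  check_cumulative(cumulative, seeds_sown)
  final <- utils::tail(cumulative, 1)
  if (final == 0) return(NA_real_)
  as.numeric(which(cumulative >= final / 2)[1])
}

#' Within-plate SD of germination day (uniformity)
#'
#' Per-seed germination days are reconstructed from the daily increments;
#' the sample standard deviation (n - 1 denominator) over the germinated
#' seeds measures germination uniformity (lower = more uniform). Undefined
#' when fewer than two seeds germinated.
#'
#' @inheritParams plate_percent
#' @return SD in days, or `NA`.
#' @export
plate_sd <- function(cumulative, seeds_sown = NULL) {
  check_cumulative(cumulative, seeds_sown)
  inc <- diff(c(0, cumulative))
  days <- rep(seq_along(cumulative), inc)
  if (length(days) < 2) return(NA_real_)
  stats::sd(days)
}

check_cumulative <- function(cumulative, seeds_sown) {
  if (length(cumulative) == 0) stop("empty cumulative count vector")
  if (any(diff(cumulative) < 0)) stop("cumulative counts must be non-decreasing")
  if (!is.null(seeds_sown)) {
    if (seeds_sown <= 0) stop("seeds_sown must be > 0")
    if (utils::tail(cumulative, 1) > seeds_sown)
      stop("final count exceeds seeds sown")
  }
  invisible(TRUE)
}

#' Read germination plate records
#'
#' Two dialects are accepted: long format with columns `plate_id`, `line`,
#' `treatment`, `season`, `plot`, `seeds_sown`, `day`, `cumulative` (one row
#' per plate-day), or wide format where the per-day cumulative counts sit in
#' columns `day_1`, `day_2`, ...
#'
#' @param path TSV path.
#' @return long-format data frame (the wide dialect is pivoted).
#' @export
read_germination_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read_tsv_file(path)
  need <- c("plate_id", "line", "treatment", "season", "plot", "seeds_sown")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("germination table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if ("day" %in% names(df) && "cumulative" %in% names(df)) return(df)
  day_cols <- grep("^day_[0-9]+$", names(df), value = TRUE)
  if (length(day_cols) == 0)
    stop("germination table has neither day/cumulative nor day_* columns")
  days <- as.integer(sub("^day_", "", day_cols))
  long <- do.call(rbind, lapply(order(days), function(i) {
    data.frame(df[need], day = days[i], cumulative = df[[day_cols[i]]])
  }))
  long[order(long$plate_id, long$day), ]
}

#' Per-plate germination traits
#'
#' @param germ long-format plate records (see [read_germination_table()]).
#' @return one row per plate with `percent`, `t50`, `sd_plate`.
#' @export
plate_traits <- function(germ) {
  plates <- split(germ, germ$plate_id)
  out <- do.call(rbind, lapply(plates, function(p) {
    p <- p[order(p$day), ]
    data.frame(p[1, c("plate_id", "line", "treatment", "season", "plot",
                      "seeds_sown")],
               percent = plate_percent(p$cumulative, p$seeds_sown[1]),
               t50 = plate_t50(p$cumulative),
               sd_plate = plate_sd(p$cumulative))
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate per-plate traits to the field plot
#'
#' The field plot (pooled seeds of its plants) is the analysis unit; plate
#' values are averaged unweighted over the plates with a defined value, with
#' standard errors retained. Undefined plate values (no or single-seed
#' germination) propagate as missing, never as zero.
#'
#' @param plate_df result of [plate_traits()].
#' @return one row per plot with `percent`, `t50`, `sd_plate`, their SEs and
#'   `n_plates`.
#' @export
aggregate_plot <- function(plate_df) {
  key <- interaction(plate_df$line, plate_df$treatment, plate_df$season,
                     plate_df$plot, drop = TRUE)
  mean_se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(c(NA_real_, NA_real_))
    c(mean(x), if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_)
  }
  out <- do.call(rbind, lapply(split(plate_df, key), function(g) {
    pc <- mean_se(g$percent); t5 <- mean_se(g$t50); sd <- mean_se(g$sd_plate)
    data.frame(g[1, c("line", "treatment", "season", "plot")],
               percent = pc[1], percent_se = pc[2],
               t50 = t5[1], t50_se = t5[2],
               sd_plate = sd[1], sd_plate_se = sd[2],
               n_plates = nrow(g))
  }))
  rownames(out) <- NULL
  out
}

#' Compute plot-level germination traits from plate records
#'
#' Convenience wrapper: [plate_traits()] then [aggregate_plot()], with a
#' `sample_id` key added for joining to the RMC table.
#'
#' @inheritParams plate_traits
#' @return plot-level trait table.
#' @export
germination_traits <- function(germ) {
  out <- aggregate_plot(plate_traits(germ))
  out$sample_id <- sprintf("%s_%s_%s_p%s", out$season, out$line,
                           out$treatment, out$plot)
  out[, c("sample_id", setdiff(names(out), "sample_id"))]
}

#' Salinity response fold changes of the germination traits
#'
#' For every line with both maternal conditions, the ratio of the SDS mean
#' to the SDF mean of each germination trait (plot-level means), together
#' with a Welch t-test between conditions (when both have at least two
#' plots) and a permissive-Bonferroni significance mark across all
#' line-by-trait comparisons.
#'
#' @param traits plot-level trait table ([germination_traits()]), columns
#'   `line`, `treatment` and the trait columns.
#' @param trait_cols traits to compare.
#' @param rule multiplicity rule (see [multiplicity_cutoff()]).
#' @return data frame: line, trait, sdf_mean, sds_mean, fc, t, p_value,
#'   significant.
#' @export
salinity_fold_change <- function(traits,
                                 trait_cols = c("percent", "t50", "sd_plate"),
                                 rule = "Bcp_05") {
  res <- list()
  for (ln in unique(traits$line)) {
    sub <- traits[traits$line == ln, ]
    if (!all(c("SDF", "SDS") %in% sub$treatment)) next
    for (tr in trait_cols) {
      x_sdf <- sub[[tr]][sub$treatment == "SDF"]
      x_sds <- sub[[tr]][sub$treatment == "SDS"]
      x_sdf <- x_sdf[!is.na(x_sdf)]; x_sds <- x_sds[!is.na(x_sds)]
      if (length(x_sdf) == 0 || length(x_sds) == 0) next
      m_sdf <- mean(x_sdf); m_sds <- mean(x_sds)
      fc <- if (m_sdf == 0) NA_real_ else m_sds / m_sdf
      tt <- if (length(x_sdf) >= 2 && length(x_sds) >= 2)
        welch_t_test(x_sds, x_sdf) else list(t = NA_real_, p = NA_real_)
      res[[length(res) + 1]] <- data.frame(
        line = ln, trait = tr, sdf_mean = m_sdf, sds_mean = m_sds, fc = fc,
        t = tt$t, p_value = tt$p)
    }
  }
  out <- do.call(rbind, res)
  n_tests <- sum(!is.na(out$p_value))
  if (n_tests > 0) {
    cutoff <- multiplicity_cutoff(rule, n_tests)
    out$significant <- !is.na(out$p_value) & out$p_value < cutoff
  } else {
    out$significant <- NA
  }
  out
}

#' Classify a plot into germination vigor groups
#'
#' Non-germinating plots have exactly 0% germination; well-germinating
#' plots reach at least `well_min` (default 95%); everything in between is
#' intermediate.
#'
#' @param percent final germination percent (0-100), vectorized.
#' @param well_min lower bound of the well-germinating group.
#' @return factor with levels non / intermediate / well.
#' @export
classify_germination_group <- function(percent, well_min = 95) {
  stopifnot(all(is.na(percent) | (percent >= 0 & percent <= 100)))
  out <- ifelse(is.na(percent), NA_character_,
                ifelse(percent == 0, "non",
                       ifelse(percent >= well_min, "well", "intermediate")))
  factor(out, levels = c("non", "intermediate", "well"))
}

#' Seed maturation percent
#'
#' Mature seeds as a percentage of all (mature + aborted) seeds of a fruit.
#'
#' @param mature,aborted non-negative counts (vectorized).
#' @return percent, `NA` where the total count is zero.
#' @export
maturation_percent <- function(mature, aborted) {
  stopifnot(all(mature >= 0, na.rm = TRUE), all(aborted >= 0, na.rm = TRUE))
  total <- mature + aborted
  ifelse(total > 0, 100 * mature / total, NA_real_)
}

#' Read the seed morphology table
#'
#' @param path TSV with columns `sample_id`, `line`, `treatment`, `season`,
#'   `plot`, `avg_seed_weight`, `mature`, `aborted`.
#' @return data frame with `maturation_percent` added.
#' @export
read_morphology_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read_tsv_file(path)
  need <- c("line", "treatment", "season", "plot", "avg_seed_weight",
            "mature", "aborted")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("morphology table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  morphology_traits(df)
}

#' Derive morphology traits (adds maturation percent)
#'
#' @param morph morphology data frame with `mature` and `aborted` counts.
#' @return the same table with `maturation_percent`.
#' @export
morphology_traits <- function(morph) {
  morph$maturation_percent <- maturation_percent(morph$mature, morph$aborted)
  morph
}
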