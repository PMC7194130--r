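# Descriptive and inferential summaries across summits, aspects, and
# survey years: richness per quadrat, group means with standard errors,
# per-species cover change, fixed-effects ANOVA (aspect nested within
# summit; summit x year), Tukey post-hoc comparisons, and the
# Shapiro-Wilk / Levene assumption gates.

#' Species richness per quadrat
#'
#' @param observations Quadrat-schema observations.
#' @param summits Optional summit table; adds an `elevation` column.
#' @return data.frame with `summit_id`, `aspect`, `quadrat_index`, `year`,
#'   `richness` (and `elevation` if `summits` given).
#' @export
richness_per_quadrat <- function(observations, summits = NULL) {
  x <- as.data.frame(validate_observations(observations, "quadrat"))
  key <- data.frame(summit_id = x$summit_id, aspect = x$aspect,
                    quadrat_index = x$quadrat_index, year = x$year,
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(x$species_id, key, function(s) length(unique(s)))
  names(agg)[names(agg) == "x"] <- "richness"
  if (!is.null(summits)) {
    summits <- validate_summits(summits)
    agg$elevation <- summits$elevation[match(agg$summit_id,
                                             summits$summit_id)]
  }
  agg <- agg[order(agg$summit_id, agg$aspect, agg$quadrat_index, agg$year), ]
  rownames(agg) <- NULL
  agg
}

#' Total percent cover per quadrat
#'
#' Summed species covers per quadrat (may exceed 100 through layering).
#'
#' @inheritParams richness_per_quadrat
#' @return data.frame like [richness_per_quadrat()] with `total_cover`.
#' @export
cover_per_quadrat <- function(observations, summits = NULL) {
  x <- as.data.frame(validate_observations(observations, "quadrat"))
  key <- data.frame(summit_id = x$summit_id, aspect = x$aspect,
                    quadrat_index = x$quadrat_index, year = x$year,
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(x$cover, key, sum)
  names(agg)[names(agg) == "x"] <- "total_cover"
  if (!is.null(summits)) {
    summits <- validate_summits(summits)
    agg$elevation <- summits$elevation[match(agg$summit_id,
                                             summits$summit_id)]
  }
  agg <- agg[order(agg$summit_id, agg$aspect, agg$quadrat_index, agg$year), ]
  rownames(agg) <- NULL
  agg
}

#' Group means with standard errors
#'
#' @param data data.frame.
#' @param value Name of the numeric column to summarize.
#' @param by Character vector of grouping columns.
#' @return data.frame with the grouping columns plus `n`, `mean`, `se`.
#' @export
group_summary <- function(data, value, by) {
  .assert(value %in% names(data), "no column '", value, "'")
  .assert(all(by %in% names(data)), "missing grouping column(s)")
  grp <- split(data, data[by], drop = TRUE)
  rows <- lapply(grp, function(g) {
    cbind(g[1, by, drop = FALSE],
          data.frame(n = nrow(g), mean = mean(g[[value]]),
                     se = .se(g[[value]])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}

#' Per-species cover change between the two survey years
#'
#' For each species, the change `cover_resurvey - cover_baseline` is taken
#' per quadrat over the quadrats where the species occurs in at least one
#' year (absence in one year counts as cover 0, the only convention under
#' which "simple subtraction" is defined).  A one-sample paired test of
#' the per-quadrat changes against zero is reported per species;
#' per-species p-values are unadjusted unless `adjust` is set.
#'
#' @param observations Quadrat-schema observations covering both years.
#' @param attributes Optional species attribute table used to filter by
#'   growth form and to label rows.
#' @param growth_form Optional growth-form filter (e.g. `"shrub"`).
#' @param species Optional explicit species filter.
#' @param adjust Multiplicity adjustment for the per-species p-values
#'   (passed to [stats::p.adjust()]; default `"none"`).
#' @return data.frame with `species_id`, `growth_form` (if available),
#'   `n_quadrats`, `mean_change`, `se_change`, `p_value`.
#' @export
cover_change_table <- function(observations, attributes = NULL,
                               growth_form = NULL, species = NULL,
                               adjust = "none") {
  x <- as.data.frame(validate_observations(observations, "quadrat"))
  ys <- sort(unique(x$year))
  .assert(length(ys) == 2L, "need exactly two survey years")
  if (!is.null(attributes)) attributes <- validate_species_attributes(attributes)
  sp_keep <- unique(x$species_id)
  if (!is.null(growth_form)) {
    .assert(!is.null(attributes), "growth-form filter needs 'attributes'")
    sp_keep <- intersect(sp_keep,
      attributes$species_id[attributes$growth_form %in% growth_form])
  }
  if (!is.null(species)) sp_keep <- intersect(sp_keep, species)
  .assert(length(sp_keep) > 0, "no species left after filtering")
  quad <- paste(x$summit_id, x$aspect, x$quadrat_index, sep = ".")
  rows <- lapply(sort(sp_keep), function(sp) {
    xs <- x[x$species_id == sp, , drop = FALSE]
    qs <- paste(xs$summit_id, xs$aspect, xs$quadrat_index, sep = ".")
    quads <- unique(qs)
    c1 <- xs$cover[xs$year == ys[1]][match(quads, qs[xs$year == ys[1]])]
    c2 <- xs$cover[xs$year == ys[2]][match(quads, qs[xs$year == ys[2]])]
    d <- ifelse(is.na(c2), 0, c2) - ifelse(is.na(c1), 0, c1)
    p <- if (length(d) > 1 && stats::sd(d) > 0) {
      stats::t.test(d, mu = 0)$p.value
    } else NA_real_
    data.frame(species_id = sp, n_quadrats = length(d),
               mean_change = mean(d), se_change = .se(d), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(attributes)) {
    out$growth_form <- attributes$growth_form[match(out$species_id,
                                                    attributes$species_id)]
    out <- out[c("species_id", "growth_form", "n_quadrats", "mean_change",
                 "se_change", "p_value")]
  }
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  rownames(out) <- NULL
  out
}

#' Fixed-effects ANOVA for the summit designs
#'
#' `design = "oneway_nested"` fits summit plus aspect nested within summit
#' (both fixed); `design = "twoway_interaction"` fits summit, year, and
#' their interaction.  Sums of squares are sequential (the balanced-design
#' convention; the synthetic designs are balanced, where sequential and
#' marginal coincide).  Terms with zero sum of squares are reported with
#' F = 0 and p = 1.
#'
#' @param response Per-quadrat numeric response.
#' @param data data.frame with columns `summit_id`, `aspect`, `year`
#'   aligned with `response`.
#' @param design `"oneway_nested"` or `"twoway_interaction"`.
#' @return data.frame with one row per model term (and a residual row):
#'   `term`, `df`, `sum_sq`, `mean_sq`, `statistic`, `p_value`.
#' @export
factor_effects <- function(response, data,
                           design = c("oneway_nested",
                                      "twoway_interaction")) {
  design <- match.arg(design)
  .assert(length(response) == nrow(data),
          "'response' must match 'data' rows")
  d <- data.frame(y = response,
                  summit = factor(data$summit_id),
                  aspect = factor(data$aspect))
  d$year <- if (!is.null(data$year)) factor(data$year) else factor(1)
  if (design == "oneway_nested") {
    .assert(nlevels(d$summit) >= 2, "need >= 2 summits")
    cells <- table(d$summit, d$aspect)
    # a single aspect level degenerates to the summit-only one-way model
    form <- if (nlevels(d$aspect) >= 2) {
      y ~ summit + summit:aspect
    } else {
      y ~ summit
    }
  } else {
    .assert(nlevels(d$summit) >= 2 && nlevels(d$year) >= 2,
            "need >= 2 summits and >= 2 years")
    cells <- table(d$summit, d$year)
    form <- y ~ summit * year
  }
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    warning("unbalanced design; empty cell(s): ",
            paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
                  sep = ":", collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(form, data = d)
  .assert(stats::df.residual(fit) > 0,
          "no residual degrees of freedom (single replicate per cell)")
  an <- suppressWarnings(stats::anova(fit))  # perfect fits handled below
  out <- data.frame(term = rownames(an), df = an$Df, sum_sq = an$`Sum Sq`,
                    mean_sq = an$`Mean Sq`, statistic = an$`F value`,
                    p_value = an$`Pr(>F)`, stringsAsFactors = FALSE)
  degenerate <- out$term != "Residuals" &
    (out$sum_sq < 1e-12 * max(1, sum(an$`Sum Sq`)) | is.na(out$statistic))
  out$statistic[degenerate] <- 0
  out$p_value[degenerate] <- 1
  out$statistic[out$term == "Residuals"] <- NA_real_
  out$p_value[out$term == "Residuals"] <- NA_real_
  rownames(out) <- NULL
  attr(out, "ss_type") <- "sequential"
  out
}

#' Tukey honest significant differences for one factor
#'
#' Studentized-range based simultaneous pairwise comparisons with
#' family-wise adjusted p-values.
#'
#' @param response Numeric response.
#' @param group Factor (coerced) with at least 2 levels; every level needs
#'   more than one observation.
#' @return data.frame with `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adjusted`.
#' @export
tukey_posthoc <- function(response, group) {
  g <- factor(group)
  .assert(nlevels(g) >= 2, "need >= 2 factor levels")
  n_per <- table(g)
  .assert(all(n_per >= 2), "level(s) with a single observation: ",
          paste(names(n_per)[n_per < 2], collapse = ", "))
  fit <- stats::aov(response ~ g)
  tk <- stats::TukeyHSD(fit)$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adjusted = tk[, "p adj"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Normality and variance-homogeneity checks before ANOVA
#'
#' Shapiro-Wilk on the within-group-centered residuals, and Levene's test
#' in the robust Brown-Forsythe form (absolute deviations from group
#' medians), which is less sensitive to departures from normality.
#'
#' @param response Numeric response.
#' @param groups Factor (coerced) defining the groups.
#' @return List with `shapiro` (`statistic`, `p_value`) and `levene`
#'   (`statistic`, `df`, `p_value`).
#' @export
assumption_checks <- function(response, groups) {
  g <- factor(groups)
  .assert(stats::sd(response) > 0, "constant response: checks undefined")
  .assert(length(response) >= 3, "need at least 3 observations")
  res <- response - stats::ave(response, g)
  sw <- stats::shapiro.test(res)
  lv <- car::leveneTest(response, g, center = stats::median)
  list(shapiro = list(statistic = unname(sw$statistic),
                      p_value = sw$p.value),
       levene = list(statistic = lv$`F value`[1],
                     df = c(lv$Df[1], lv$Df[2]),
                     p_value = lv$`Pr(>F)`[1]))
}
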