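# Thermophilization: the cover-weighted thermic vegetation indicator S,
# its change D between surveys, and the signed-rank test of D against 0.
#
#   S = sum(rank_i * cover_i) / sum(cover_i)
#
# Elevational ranks are consumed as given integers; higher ranks belong to
# warm-adapted (lower-elevation) species, so a positive
# D = S_resurvey - S_baseline indicates thermophilization.

#' Thermic vegetation indicator for one quadrat composition
#'
#' @param species_id Character vector of species present.
#' @param cover Numeric percent covers (> 0), same length.
#' @param attributes Species attribute table with `species_id` and
#'   `elevational_rank` (see [read_species_attributes()]).
#' @return Scalar S, the cover-weighted mean elevational rank; lies
#'   between the minimum and maximum rank present.
#' @export
#' @examples
#' attrs <- data.frame(species_id = c("a", "b", "c"),
#'                     elevational_rank = c(1, 2, 4),
#'                     growth_form = "forb")
#' thermic_indicator(c("a", "b", "c"), c(10, 20, 10), attrs)  # 2.25
thermic_indicator <- function(species_id, cover, attributes) {
  .assert(length(species_id) >= 1, "empty composition: S is undefined")
  .assert(length(cover) == length(species_id) && all(cover > 0),
          "'cover' must be positive and match 'species_id'")
  rank <- attributes$elevational_rank[match(species_id,
                                            attributes$species_id)]
  missing_sp <- species_id[is.na(rank)]
  .assert(length(missing_sp) == 0L,
          "species without an elevational rank: ",
          paste(missing_sp, collapse = ", "))
  sum(rank * cover) / sum(cover)
}

#' Per-quadrat thermic indicators for a whole survey
#'
#' @param observations Quadrat-schema observations.
#' @param attributes Species attribute table.
#' @return data.frame with `summit_id`, `aspect`, `quadrat_index`, `year`,
#'   `S`.
#' @export
thermic_indicators <- function(observations, attributes) {
  x <- as.data.frame(validate_observations(observations, "quadrat"))
  attributes <- validate_species_attributes(attributes)
  key <- paste(x$summit_id, x$aspect, x$quadrat_index, x$year, sep = "\r")
  grp <- split(seq_len(nrow(x)), key)
  rows <- lapply(grp, function(i) {
    data.frame(summit_id = x$summit_id[i[1]], aspect = x$aspect[i[1]],
               quadrat_index = x$quadrat_index[i[1]], year = x$year[i[1]],
               S = thermic_indicator(x$species_id[i], x$cover[i],
                                     attributes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$summit_id, out$aspect, out$quadrat_index, out$year), ]
  rownames(out) <- NULL
  out
}

#' Thermophilization change per quadrat
#'
#' `D = S_resurvey - S_baseline` by simple subtraction for every quadrat
#' vegetated in both years.  Quadrats present in only one year are not
#' silently dropped: they are listed in the `unmatched` attribute.
#'
#' @param indicators Output of [thermic_indicators()] covering both survey
#'   years.
#' @param years Optional length-2 numeric (baseline, resurvey); defaults
#'   to the two years present.
#' @return data.frame with `summit_id`, `aspect`, `quadrat_index`,
#'   `S_baseline`, `S_resurvey`, `D`; attribute `unmatched` holds keys of
#'   quadrats seen in exactly one year.
#' @export
thermophilization_change <- function(indicators, years = NULL) {
  ys <- sort(unique(indicators$year))
  if (is.null(years)) {
    .assert(length(ys) == 2L, "need exactly two survey years, found: ",
            paste(ys, collapse = ", "))
    years <- ys
  }
  b <- indicators[indicators$year == years[1], , drop = FALSE]
  r <- indicators[indicators$year == years[2], , drop = FALSE]
  kb <- paste(b$summit_id, b$aspect, b$quadrat_index, sep = ".")
  kr <- paste(r$summit_id, r$aspect, r$quadrat_index, sep = ".")
  matched <- intersect(kb, kr)
  .assert(length(matched) > 0, "no quadrats matched across years")
  i <- match(matched, kb); j <- match(matched, kr)
  out <- data.frame(summit_id = b$summit_id[i], aspect = b$aspect[i],
                    quadrat_index = b$quadrat_index[i],
                    S_baseline = b$S[i], S_resurvey = r$S[j],
                    D = r$S[j] - b$S[i], stringsAsFactors = FALSE)
  out <- out[order(out$summit_id, out$aspect, out$quadrat_index), ]
  rownames(out) <- NULL
  attr(out, "unmatched") <- c(setdiff(kb, kr), setdiff(kr, kb))
  out
}

#' Wilcoxon signed-rank test of paired differences against zero
#'
#' Zero differences are dropped (standard zero-handling); ties receive
#' mid-ranks.  The exact signed-rank distribution is used for up to 25
#' non-zero differences without ties; otherwise the normal approximation
#' with tie and continuity correction.
#'
#' @param d Numeric vector of paired differences (e.g. quadrat-level D).
#' @param alternative Passed to the test (default two-sided).
#' @return List with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_nonzero`, `method` ("exact" or "normal_approximation").
#' @export
#' @examples
#' wilcoxon_signed_rank(1:6)   # exact two-sided p = 1/32
wilcoxon_signed_rank <- function(d, alternative = "two.sided") {
  .assert(is.numeric(d) && length(d) >= 1, "'d' must be a numeric vector")
  dz <- d[d != 0]
  .assert(length(dz) >= 1,
          "all differences are exactly zero; test is degenerate")
  ties <- any(duplicated(abs(dz)))
  use_exact <- length(dz) <= 25 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(dz, mu = 0, alternative = alternative,
                       exact = use_exact, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n_nonzero = length(dz),
       method = if (use_exact) "exact" else "normal_approximation")
}

#' Per-summit thermophilization summary
#'
#' Mean and standard error of D over quadrats, with a signed-rank test per
#' group, mirroring a per-summit indicator figure.
#'
#' @param changes Output of [thermophilization_change()].
#' @param by Grouping column(s), default `"summit_id"`.
#' @return data.frame with `n`, `mean_D`, `se_D`, `p_value` per group
#'   (p is NA for groups whose D are all zero).
#' @export
thermophilization_summary <- function(changes, by = "summit_id") {
  grp <- split(changes, changes[by], drop = TRUE)
  rows <- lapply(grp, function(g) {
    p <- if (any(g$D != 0)) wilcoxon_signed_rank(g$D)$p_value else NA_real_
    cbind(g[1, by, drop = FALSE],
          data.frame(n = nrow(g), mean_D = mean(g$D), se_D = .se(g$D),
                     p_value = p, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
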