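# Variation partitioning of a per-quadrat response into pure and shared
# adjusted-R2 fractions of elevation (E), aspect (A), and survey year (Y).
#
# The seven nested ordinary-least-squares models {E}, {A}, {Y}, {E,A},
# {E,Y}, {A,Y}, {E,A,Y} give adjusted R2 values from which pure fractions
# are differences against the model omitting the variable, and shared
# fractions follow by inclusion-exclusion.  Fractions may be slightly
# negative (adjusted R2 is unbiased, not truncated); the seven fractions
# always sum exactly to the full-model adjusted R2.

# adjusted R2 from a QR decomposition of the design (fast path reused by
# the permutation test)
.adj_r2_qr <- function(qr_x, y, p) {
  n <- length(y)
  res <- qr.resid(qr_x, y)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / tss
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

.design_matrix <- function(df) {
  stats::model.matrix(~., data = df)
}

#' Adjusted R-squared of an ordinary least-squares fit
#'
#' `1 - (1 - R2) (n - 1) / (n - p - 1)`, with `p` the number of fitted
#' parameters beyond the intercept.  Categorical predictors are expanded
#' to treatment contrasts.
#'
#' @param response Numeric vector.
#' @param predictors data.frame of predictors (factors and/or numeric
#'   covariates), or a single vector.
#' @return Adjusted R-squared (scalar; may be negative).
#' @export
adjusted_r2 <- function(response, predictors) {
  if (!is.data.frame(predictors)) predictors <- data.frame(x = predictors)
  .assert(is.numeric(response) && !anyNA(response),
          "'response' must be numeric without missing values")
  .assert(nrow(predictors) == length(response),
          "predictor rows must match response length")
  X <- .design_matrix(predictors)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    .stop("rank-deficient design; aliased term(s): ",
          paste(aliased, collapse = ", "))
  }
  p <- ncol(X) - 1
  .assert(length(response) > p + 1,
          "need more observations than fitted parameters")
  .adj_r2_qr(qr_x, response, p)
}

#' Three-way variation partitioning (elevation, aspect, year)
#'
#' @param response Per-quadrat numeric response (species richness or
#'   summed percent cover).
#' @param elevation Numeric elevation per observation (metres), or the
#'   summit identity if `elevation_as_factor = TRUE`.
#' @param aspect,year Factors (coerced).
#' @param elevation_as_factor Treat elevation as a categorical summit
#'   identity instead of a numeric covariate.
#' @return Object of class `varpart_fractions`: list with `pure_E`,
#'   `pure_A`, `pure_Y`, `shared_EA`, `shared_EY`, `shared_AY`,
#'   `shared_EAY`, `total` (adjusted R2 of the full model), `residual`
#'   (`1 - total`), and `n`.
#' @export
varpart3 <- function(response, elevation, aspect, year,
                     elevation_as_factor = FALSE) {
  E <- if (elevation_as_factor) factor(elevation) else as.numeric(elevation)
  A <- factor(aspect); Y <- factor(year)
  .assert(length(unique(E)) > 1 && nlevels(A) > 1 && nlevels(Y) > 1,
          "every predictor must vary (constant factor in design)")
  r2 <- function(df) adjusted_r2(response, df)
  aE   <- r2(data.frame(E = E))
  aA   <- r2(data.frame(A = A))
  aY   <- r2(data.frame(Y = Y))
  aEA  <- r2(data.frame(E = E, A = A))
  aEY  <- r2(data.frame(E = E, Y = Y))
  aAY  <- r2(data.frame(A = A, Y = Y))
  aEAY <- r2(data.frame(E = E, A = A, Y = Y))
  pure_E <- aEAY - aAY
  pure_A <- aEAY - aEY
  pure_Y <- aEAY - aEA
  shared_EA <- aEAY - aY - pure_E - pure_A
  shared_EY <- aEAY - aA - pure_E - pure_Y
  shared_AY <- aEAY - aE - pure_A - pure_Y
  shared_EAY <- aEAY - pure_E - pure_A - pure_Y -
    shared_EA - shared_EY - shared_AY
  structure(list(pure_E = pure_E, pure_A = pure_A, pure_Y = pure_Y,
                 shared_EA = shared_EA, shared_EY = shared_EY,
                 shared_AY = shared_AY, shared_EAY = shared_EAY,
                 total = aEAY, residual = 1 - aEAY,
                 n = length(response),
                 elevation_as_factor = elevation_as_factor),
            class = "varpart_fractions")
}

#' @export
print.varpart_fractions <- function(x, ...) {
  cat("Variation partitioning (adjusted R2)\n")
  f <- c("pure_E", "pure_A", "pure_Y", "shared_EA", "shared_EY",
         "shared_AY", "shared_EAY", "total", "residual")
  for (k in f) cat(sprintf("  %-10s %8.4f\n", k, x[[k]]))
  invisible(x)
}

#' Permutation test of a pure variation-partitioning fraction
#'
#' Residuals of the reduced model (the model omitting the tested variable)
#' are permuted and added back to its fitted values, and
#' `p = (1 + #(perm >= observed)) / (n_perm + 1)`.  Permutations are
#' ranked by the partial pseudo-F comparing the full against the reduced
#' model (the pivotal statistic with the same numerator as the pure
#' adjusted-R2 fraction); ranking by the raw fraction itself is measurably
#' conservative because its denominator (the permuted response's total sum
#' of squares) varies across permutations.  Shared fractions are obtained
#' by subtraction and cannot be tested.
#'
#' @inheritParams varpart3
#' @param fraction One of `"pure_E"`, `"pure_A"`, `"pure_Y"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with `observed` (the pure fraction), `p_value`, `n_perm`.
#' @export
permute_fraction <- function(response, elevation, aspect, year,
                             fraction = c("pure_E", "pure_A", "pure_Y"),
                             n_perm = 999, seed = 1,
                             elevation_as_factor = FALSE) {
  if (length(fraction) == 1L &&
      grepl("^shared", as.character(fraction)[1])) {
    .stop("shared fractions are obtained by subtraction and cannot be ",
          "tested for significance")
  }
  fraction <- match.arg(fraction)
  .assert(.is_count(n_perm), "'n_perm' must be a non-negative integer")
  E <- if (elevation_as_factor) factor(elevation) else as.numeric(elevation)
  A <- factor(aspect); Y <- factor(year)
  full_df <- data.frame(E = E, A = A, Y = Y)
  reduced_df <- switch(fraction,
                       pure_E = data.frame(A = A, Y = Y),
                       pure_A = data.frame(E = E, Y = Y),
                       pure_Y = data.frame(E = E, A = A))
  X_full <- .design_matrix(full_df)
  X_red <- .design_matrix(reduced_df)
  qr_full <- qr(X_full); qr_red <- qr(X_red)
  .assert(qr_full$rank == ncol(X_full), "rank-deficient full design")
  p_full <- ncol(X_full) - 1
  p_red <- ncol(X_red) - 1
  n <- length(response)
  df_extra <- p_full - p_red
  pseudo_f <- function(y) {
    rss_full <- sum(qr.resid(qr_full, y)^2)
    rss_red <- sum(qr.resid(qr_red, y)^2)
    ((rss_red - rss_full) / df_extra) / (rss_full / (n - p_full - 1))
  }
  observed_fraction <- .adj_r2_qr(qr_full, response, p_full) -
    .adj_r2_qr(qr_red, response, p_red)
  if (n_perm == 0) {
    return(list(observed = observed_fraction, p_value = 1, n_perm = 0L,
                fraction = fraction))
  }
  observed_f <- pseudo_f(response)
  fit_red <- qr.fitted(qr_red, response)
  res_red <- response - fit_red
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    y_star <- fit_red + res_red[sample.int(n)]
    if (pseudo_f(y_star) >= observed_f) exceed <- exceed + 1L
  }
  list(observed = observed_fraction,
       p_value = (1 + exceed) / (n_perm + 1),
       n_perm = as.integer(n_perm), fraction = fraction)
}

#' Variation-partitioning table for several responses
#'
#' One row per response with the seven fractions, residual, total, and
#' permutation p-values for the pure fractions.
#'
#' @param responses Named list of numeric response vectors.
#' @inheritParams permute_fraction
#' @return data.frame, one row per response.
#' @export
varpart_table <- function(responses, elevation, aspect, year,
                          n_perm = 999, seed = 1,
                          elevation_as_factor = FALSE) {
  .assert(is.list(responses) && !is.null(names(responses)),
          "'responses' must be a named list")
  rows <- lapply(names(responses), function(nm) {
    y <- responses[[nm]]
    vp <- varpart3(y, elevation, aspect, year,
                   elevation_as_factor = elevation_as_factor)
    ps <- vapply(c("pure_E", "pure_A", "pure_Y"), function(fr) {
      permute_fraction(y, elevation, aspect, year, fraction = fr,
                       n_perm = n_perm, seed = seed,
                       elevation_as_factor = elevation_as_factor)$p_value
    }, numeric(1))
    data.frame(response = nm,
               pure_E = vp$pure_E, p_E = ps[["pure_E"]],
               pure_A = vp$pure_A, p_A = ps[["pure_A"]],
               pure_Y = vp$pure_Y, p_Y = ps[["pure_Y"]],
               shared_EA = vp$shared_EA, shared_EY = vp$shared_EY,
               shared_AY = vp$shared_AY, shared_EAY = vp$shared_EAY,
               total = vp$total, residual = vp$residual,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
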