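# Survey records, species attributes, summit table, and community matrices.
#
# Records follow the GLORIA multi-summit layout: per summit, four aspect
# clusters (N, S, E, W) each with corner 1-m2 quadrats, surveyed in a
# baseline and a resurvey year.  Absence is encoded by the absence of a
# record; a cover of zero is invalid.

#' Default abundance-class to percent-cover map
#'
#' Summit-area sections are scored on a five-class ordinal abundance scale.
#' This map assigns each class a representative percent cover (class
#' midpoints of an approximately geometric cover scale).  The class bounds
#' behind the five-class convention are not standardized, so the map is a
#' declared convention and can be replaced by the caller wherever it is
#' consumed.
#'
#' @return Named numeric vector of length 5; names are the classes "1".."5".
#' @export
#' @examples
#' abundance_class_map()
abundance_class_map <- function() {
  c("1" = 0.5, "2" = 3, "3" = 15, "4" = 37.5, "5" = 87.5)
}

#' Convert an ordinal abundance class to a representative percent cover
#'
#' @param class Integer vector with values in 1..5.
#' @param map Named numeric vector mapping classes to percent cover; must be
#'   strictly increasing in class. Defaults to [abundance_class_map()].
#' @return Numeric vector of percent covers.
#' @export
#' @examples
#' abundance_class_to_cover(c(1, 5))
abundance_class_to_cover <- function(class, map = abundance_class_map()) {
  .assert(length(map) == 5L && !is.null(names(map)) &&
            identical(names(map), as.character(1:5)),
          "'map' must be a named numeric vector for classes 1..5")
  .assert(all(diff(map) > 0), "'map' must be strictly increasing in class")
  cl <- as.integer(class)
  .assert(!anyNA(cl) && all(cl %in% 1:5),
          "abundance class must be an integer in 1..5")
  unname(map[cl])
}

.QUADRAT_COLS <- c("summit_id", "aspect", "quadrat_index", "year",
                   "species_id", "cover")
.SECTION_COLS <- c("summit_id", "aspect", "section", "year",
                   "species_id", "abundance_class")

#' Validate a table of survey observations
#'
#' Checks the schema invariants of quadrat records (cover in (0, 100],
#' quadrat index 1..4, unique record keys, valid aspect labels) or of
#' summit-area section records (abundance class 1..5, section labels).
#'
#' @param x A data.frame of observations.
#' @param schema `"quadrat"` (1-m2 corner quadrats, percent cover) or
#'   `"section"` (summit-area sections, ordinal abundance classes).
#' @return The validated data.frame, with class `"summit_observations"` and
#'   attribute `schema`, invisibly usable wherever a plain data.frame is.
#' @export
validate_observations <- function(x, schema = c("quadrat", "section")) {
  schema <- match.arg(schema)
  .assert(is.data.frame(x), "observations must be a data.frame")
  cols <- if (schema == "quadrat") .QUADRAT_COLS else .SECTION_COLS
  missing_cols <- setdiff(cols, names(x))
  .assert(length(missing_cols) == 0L,
          "missing column(s): ", paste(missing_cols, collapse = ", "))
  x <- x[cols]
  .assert(nrow(x) >= 1L, "observations table is empty")
  .check_aspect(x$aspect)
  .assert(!anyNA(x$year) && is.numeric(x$year), "'year' must be numeric")

  if (schema == "quadrat") {
    .assert(is.numeric(x$cover) && !anyNA(x$cover),
            "'cover' must be numeric and non-missing")
    bad <- which(x$cover <= 0 | x$cover > 100)
    .assert(length(bad) == 0L,
            "cover must lie in (0, 100]; offending row(s): ",
            paste(utils::head(bad, 5L), collapse = ", "))
    qi <- x$quadrat_index
    .assert(is.numeric(qi) && all(qi == round(qi)) && all(qi >= 1 & qi <= 4),
            "'quadrat_index' must be an integer in 1..4")
    key <- do.call(paste, c(x[c("summit_id", "aspect", "quadrat_index",
                                "year", "species_id")], sep = "\r"))
  } else {
    .assert(all(x$section %in% c("upper_5m", "lower_10m")),
            "'section' must be 'upper_5m' or 'lower_10m'")
    ac <- x$abundance_class
    .assert(is.numeric(ac) && all(ac %in% 1:5),
            "'abundance_class' must be an integer in 1..5")
    key <- do.call(paste, c(x[c("summit_id", "aspect", "section",
                                "year", "species_id")], sep = "\r"))
  }
  dup <- which(duplicated(key))
  .assert(length(dup) == 0L,
          "duplicated record key(s) at row(s): ",
          paste(utils::head(dup, 5L), collapse = ", "))
  class(x) <- c("summit_observations", "data.frame")
  attr(x, "schema") <- schema
  x
}

#' Read survey observations from a delimited text file
#'
#' Expects a comma-separated UTF-8 file with a header row naming the record
#' fields (`summit_id, aspect, quadrat_index, year, species_id, cover` for
#' the quadrat schema). Rows failing type or range checks are reported by
#' file line number.
#'
#' @inheritParams validate_observations
#' @param path Path to a CSV file. Lines starting with `#` are ignored.
#' @return A validated observation data.frame (see [validate_observations()]).
#' @export
read_observations <- function(path, schema = c("quadrat", "section")) {
  schema <- match.arg(schema)
  .assert(file.exists(path), "file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  num_col <- if (schema == "quadrat") "cover" else "abundance_class"
  for (col in intersect(c(num_col, "year", "quadrat_index"), names(x))) {
    raw <- x[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    .assert(length(bad) == 0L,
            "malformed value in column '", col, "' at data row(s): ",
            paste(utils::head(bad, 5L), collapse = ", "), " of ", path)
    x[[col]] <- val
  }
  validate_observations(x, schema)
}

#' Write survey observations to a delimited text file
#'
#' @param x Observation data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the species attribute table
#'
#' One row per species: an elevational rank (a positive integer; higher
#' ranks are assigned to warm-adapted species characteristic of lower
#' elevations, so that an increase of the cover-weighted mean rank over
#' time indicates thermophilization) and a growth form.
#'
#' @param path CSV with columns `species_id, elevational_rank, growth_form`.
#' @return Validated data.frame.
#' @export
read_species_attributes <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_species_attributes(x)
}

#' Validate a species attribute table
#'
#' @param x data.frame with columns `species_id, elevational_rank,
#'   growth_form`.
#' @return The validated data.frame.
#' @export
validate_species_attributes <- function(x) {
  need <- c("species_id", "elevational_rank", "growth_form")
  missing_cols <- setdiff(need, names(x))
  .assert(length(missing_cols) == 0L,
          "missing column(s): ", paste(missing_cols, collapse = ", "))
  .assert(!any(duplicated(x$species_id)),
          "duplicated species_id in attribute table")
  r <- x$elevational_rank
  .assert(is.numeric(r) && all(r == round(r)) && all(r >= 1),
          "'elevational_rank' must be a positive integer")
  .assert(all(x$growth_form %in% c("shrub", "graminoid", "forb", "other")),
          "'growth_form' must be one of shrub, graminoid, forb, other")
  x[need]
}

#' Read the summit table
#'
#' @param path CSV with columns `summit_id, elevation` (metres a.s.l.),
#'   listed from lowest to highest; elevations must be strictly increasing.
#' @return Validated data.frame.
#' @export
read_summits <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_summits(x)
}

#' Validate a summit table
#'
#' @param x data.frame with columns `summit_id, elevation`.
#' @return The validated data.frame.
#' @export
validate_summits <- function(x) {
  need <- c("summit_id", "elevation")
  .assert(all(need %in% names(x)),
          "summit table needs columns summit_id, elevation")
  .assert(!any(duplicated(x$summit_id)), "duplicated summit_id")
  .assert(is.numeric(x$elevation) && all(diff(x$elevation) > 0),
          "elevations must be strictly increasing in table order")
  x[need]
}

#' Build a sites-by-species community matrix from quadrat observations
#'
#' Aggregates validated quadrat records to the requested site resolution.
#' Cover aggregation sums percent covers (aspect- or summit-level sums may
#' exceed 100; they are not capped); incidence aggregation is a logical OR.
#' Species absent from every retained site are dropped.  When a summit
#' table is supplied, site metadata carries elevation.
#'
#' @param observations Quadrat-schema observations (see
#'   [validate_observations()]).
#' @param grouping Site resolution: `"quadrat"`, `"aspect"`, or `"summit"`.
#' @param year Optional single survey year to retain; default keeps all
#'   years as separate sites.
#' @param mode `"cover"` (summed percent cover) or `"incidence"` (0/1).
#' @param summits Optional summit table (see [read_summits()]) supplying
#'   elevations for the site metadata.
#' @return An object of class `community_matrix`: a list with `values`
#'   (numeric sites x species matrix), `sites` (data.frame of site
#'   metadata, one row per matrix row), and `species` (character vector of
#'   column names).
#' @export
#' @examples
#' obs <- data.frame(summit_id = "GUL1", aspect = "N", quadrat_index = 1,
#'                   year = 2014, species_id = c("spA", "spB"),
#'                   cover = c(30, 20))
#' m <- build_matrix(validate_observations(obs), grouping = "quadrat")
#' m$values
build_matrix <- function(observations,
                         grouping = c("quadrat", "aspect", "summit"),
                         year = NULL,
                         mode = c("cover", "incidence"),
                         summits = NULL) {
  grouping <- match.arg(grouping)
  mode <- match.arg(mode)
  x <- as.data.frame(validate_observations(observations, "quadrat"))
  if (!is.null(year)) {
    x <- x[x$year %in% year, , drop = FALSE]
    .assert(nrow(x) > 0L, "no observations left after year filter")
  }
  meta_cols <- switch(grouping,
    quadrat = c("summit_id", "aspect", "quadrat_index", "year"),
    aspect  = c("summit_id", "aspect", "year"),
    summit  = c("summit_id", "year"))
  site_key <- do.call(paste, c(x[meta_cols], sep = "."))
  sites <- unique(data.frame(site = site_key, x[meta_cols],
                             stringsAsFactors = FALSE))
  sites <- sites[order(sites$site), , drop = FALSE]
  rownames(sites) <- NULL
  species <- sort(unique(x$species_id))
  values <- matrix(0, nrow(sites), length(species),
                   dimnames = list(sites$site, species))
  i <- match(site_key, sites$site)
  j <- match(x$species_id, species)
  for (k in seq_along(i)) {
    values[i[k], j[k]] <- values[i[k], j[k]] + x$cover[k]
  }
  if (mode == "incidence") values[] <- as.numeric(values > 0)
  if (!is.null(summits)) {
    summits <- validate_summits(summits)
    sites$elevation <- summits$elevation[match(sites$summit_id,
                                               summits$summit_id)]
  }
  structure(list(values = values, sites = sites, species = species,
                 mode = mode, grouping = grouping),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d site(s) x %d species (%s, %s level)\n",
              nrow(x$values), length(x$species), x$mode, x$grouping))
  invisible(x)
}

#' @export
as.matrix.community_matrix <- function(x, ...) x$values

#' Write a community matrix as delimited text
#'
#' Site metadata columns come first, then one column per species.
#'
#' @param x A `community_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  .assert(inherits(x, "community_matrix"), "'x' must be a community_matrix")
  out <- cbind(x$sites, as.data.frame(x$values, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Coerce a community_matrix (or plain matrix) to an incidence matrix.
.incidence <- function(m) {
  v <- if (inherits(m, "community_matrix")) m$values else as.matrix(m)
  .assert(is.numeric(v) && all(is.finite(v)), "matrix values must be finite")
  (v > 0) * 1
}
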