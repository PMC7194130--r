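# Synthetic survey and soil-logger generator.
#
# Emulates a four-summit GLORIA design: an elevation gradient from treeline
# to the nival zone, four aspect clusters per summit with corner 1-m2
# quadrats, a baseline and a resurvey year.  The generator imposes, by
# construction: richness declining with elevation, warmer/richer S and E
# aspects, species pools of higher summits nested in those of the summit
# below, species replacement between years on warm aspects, net species
# loss on cold aspects, and a controlled thermophilization shift of the
# cover-weighted elevational rank.  Every stochastic choice is driven by
# the design's seed, so identical designs give identical data.

#' Define a synthetic survey design
#'
#' The defaults describe the study conditions the package is calibrated
#' against: four summits from 3530 to 3740 m, four aspects with four corner
#' quadrats each (64 quadrats), surveys in 2014 and 2018, richness falling
#' by about 3 species per quadrat per 100 m from 15 at the lowest summit,
#' south/east aspects richer than north/west, strongly nested summit pools,
#' and moderate between-year replacement/loss rates.
#'
#' @param summits data.frame with `summit_id` and strictly increasing
#'   `elevation` (m a.s.l.).
#' @param aspects Aspect labels; fixed vocabulary N, S, E, W.
#' @param quadrats_per_aspect Corner quadrats per aspect cluster.
#' @param years Length-2 numeric: baseline and resurvey year.
#' @param pool_size Total size of the regional species pool.
#' @param richness_at_base Expected per-quadrat richness at the lowest
#'   summit (species per m2).
#' @param richness_lapse Expected per-quadrat species lost per 100 m of
#'   elevation.
#' @param aspect_richness_offsets Named additive per-aspect effects on
#'   expected quadrat richness (species); S and E positive, N and W
#'   negative by default.
#' @param nestedness_strength Probability in \[0, 1\] that a higher summit's
#'   pool member is drawn from the pool of the summit below rather than
#'   from the regional pool; 1 forces perfectly nested pools.
#' @param shift_magnitude Imposed upward displacement (rank units) of each
#'   quadrat's cover-weighted elevational rank between the two surveys.
#'   Higher ranks denote warm-adapted species, so a positive shift is a
#'   thermophilization signal.
#' @param shift_aspects Aspects on which the shift is applied (default all
#'   four; restrict to e.g. `c("N", "W")` for aspect-contrast experiments).
#' @param turnover_rate_warm_aspects Per-species probability, on S/E
#'   aspects, of being replaced (equal loss and gain) between years.
#' @param loss_rate_cold_aspects Per-species deletion probability on N/W
#'   aspects between years.
#' @param gain_rate_cold_aspects Per-resident gain probability on N/W
#'   aspects (kept below the loss rate so cold aspects lose species net).
#' @param pool_multiplier Summit pool size as a multiple of the summit's
#'   expected per-quadrat richness; controls how exhaustively 16 quadrats
#'   sample their summit's flora.
#' @param commonness_sdlog Log-normal SD of the shared species commonness
#'   weights that drive which pool members actually occur in quadrats
#'   (larger values concentrate occurrence on fewer, very common species).
#' @param cover_meanlog,cover_sdlog Log-normal parameters of species
#'   percent cover in a quadrat.
#' @param cover_noise_sdlog SD of multiplicative log-normal noise applied
#'   to resurvey covers of persisting species (0 = resurvey covers change
#'   only through the imposed processes, so an all-zero design reproduces
#'   the baseline exactly).
#' @param seed Integer seed; the design is reproducible from it.
#' @return Object of class `survey_design`.
#' @export
survey_design <- function(summits = data.frame(
                            summit_id = c("GUL1", "GUL2", "GUL3", "GUL4"),
                            elevation = c(3530, 3600, 3670, 3740),
                            stringsAsFactors = FALSE),
                          aspects = c("N", "S", "E", "W"),
                          quadrats_per_aspect = 4,
                          years = c(2014, 2018),
                          pool_size = 150,
                          richness_at_base = 15,
                          richness_lapse = 3,
                          aspect_richness_offsets = c(N = -2, S = 2,
                                                      E = 1.5, W = -1.5),
                          nestedness_strength = 0.9,
                          shift_magnitude = 0.5,
                          shift_aspects = c("N", "S", "E", "W"),
                          turnover_rate_warm_aspects = 0.15,
                          loss_rate_cold_aspects = 0.15,
                          gain_rate_cold_aspects = 0.05,
                          pool_multiplier = 6,
                          commonness_sdlog = 1,
                          cover_meanlog = log(5),
                          cover_sdlog = 0.8,
                          cover_noise_sdlog = 0,
                          seed = 1) {
  summits <- validate_summits(summits)
  .check_aspect(aspects)
  .check_aspect(shift_aspects)
  .assert(.is_count(quadrats_per_aspect) && quadrats_per_aspect >= 1,
          "'quadrats_per_aspect' must be a positive integer")
  .assert(length(years) == 2L && years[2] > years[1],
          "'years' must be (baseline, resurvey) with resurvey later")
  probs <- c(nestedness_strength, turnover_rate_warm_aspects,
             loss_rate_cold_aspects, gain_rate_cold_aspects)
  .assert(all(probs >= 0 & probs <= 1), "rates must lie in [0, 1]")
  .assert(richness_at_base > 0 && richness_lapse >= 0 && pool_size >= 1,
          "richness parameters must be positive")
  .assert(all(aspects %in% names(aspect_richness_offsets)),
          "'aspect_richness_offsets' must name every aspect")
  design <- list(summits = summits, aspects = aspects,
                 quadrats_per_aspect = quadrats_per_aspect, years = years,
                 pool_size = pool_size, richness_at_base = richness_at_base,
                 richness_lapse = richness_lapse,
                 aspect_richness_offsets = aspect_richness_offsets,
                 nestedness_strength = nestedness_strength,
                 shift_magnitude = shift_magnitude,
                 shift_aspects = shift_aspects,
                 turnover_rate_warm_aspects = turnover_rate_warm_aspects,
                 loss_rate_cold_aspects = loss_rate_cold_aspects,
                 gain_rate_cold_aspects = gain_rate_cold_aspects,
                 pool_multiplier = pool_multiplier,
                 commonness_sdlog = commonness_sdlog,
                 cover_meanlog = cover_meanlog, cover_sdlog = cover_sdlog,
                 cover_noise_sdlog = cover_noise_sdlog,
                 seed = as.integer(seed))
  # pool must be able to supply the richest quadrat and the base summit pool
  max_lambda <- richness_at_base + max(aspect_richness_offsets)
  .assert(pool_size >= 4 * max_lambda,
          "'pool_size' too small for 'richness_at_base'")
  class(design) <- "survey_design"
  design
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf(paste0("survey_design: %d summits (%.0f-%.0f m), %d aspects x ",
                     "%d quadrats, years %d/%d, pool %d, seed %d\n"),
              nrow(x$summits), min(x$summits$elevation),
              max(x$summits$elevation), length(x$aspects),
              x$quadrats_per_aspect, x$years[1], x$years[2], x$pool_size,
              x$seed))
  invisible(x)
}

# expected per-quadrat richness per summit (before aspect offsets)
.expected_richness <- function(design) {
  e <- design$summits$elevation
  design$richness_at_base - design$richness_lapse * (e - e[1]) / 100
}

# draw percent covers for n species
.draw_cover <- function(n, design) {
  pmin(100, pmax(0.1, stats::rlnorm(n, design$cover_meanlog,
                                    design$cover_sdlog)))
}

# sample n elements of x with weights, safe for length-1 x
.sample_vec <- function(x, n, prob = NULL) {
  if (length(x) == 0L || n == 0L) return(x[0])
  x[sample.int(length(x), n, prob = prob)]
}

# Tilt covers multiplicatively along the rank gradient so that the
# cover-weighted mean rank increases by exactly `shift` (capped near the
# maximum attainable rank for the quadrat's composition).
.tilt_covers <- function(cover, rank, shift) {
  if (shift == 0 || length(unique(rank)) < 2L) return(cover)
  s0 <- sum(rank * cover) / sum(cover)
  target <- min(s0 + shift, s0 + 0.95 * (max(rank) - s0))
  if (target <= s0) return(cover)
  f <- function(g) {
    w <- cover * exp(g * (rank - mean(rank)))
    sum(rank * w) / sum(w) - target
  }
  g <- stats::uniroot(f, c(0, 60), tol = 1e-10)$root
  cover * exp(g * (rank - mean(rank)))
}

#' Generate a two-year synthetic summit survey
#'
#' Builds a regional species pool with elevation optima (ranks binned by
#' summit, higher rank = lower-elevation/warm-adapted), nested summit
#' pools, baseline quadrat communities, and resurvey communities derived
#' from the baseline by aspect-specific replacement/loss processes plus a
#' controlled thermophilization tilt of covers along the rank gradient.
#'
#' @param design A [survey_design()].
#' @return A list with `observations` (quadrat records for both years),
#'   `attributes` (species attribute table), and `truth` (the generating
#'   parameters actually realized: species ranks, per-summit/aspect
#'   expected richness, summit pools, the imposed shift and the per-aspect
#'   between-year process).
#' @export
generate_survey <- function(design) {
  .assert(inherits(design, "survey_design"), "'design' must be a survey_design")
  set.seed(design$seed)
  ns <- nrow(design$summits)
  elev <- design$summits$elevation

  # --- regional pool -------------------------------------------------------
  pool_ids <- sprintf("sp%03d", seq_len(design$pool_size))
  optimum <- stats::runif(design$pool_size, min(elev) - 35, max(elev) + 35)
  band <- vapply(optimum, function(o) which.min(abs(o - elev)), integer(1))
  rank <- ns + 1L - band            # warm-adapted lowland species: high rank
  commonness <- stats::rlnorm(design$pool_size, 0, design$commonness_sdlog)
  growth_form <- sample(c("shrub", "graminoid", "forb", "other"),
                        design$pool_size, replace = TRUE,
                        prob = c(0.15, 0.3, 0.45, 0.1))

  # --- nested summit pools -------------------------------------------------
  exp_rich <- .expected_richness(design)
  .assert(all(exp_rich > 0), "richness_lapse drives expected richness <= 0")
  pool_sizes <- pmin(design$pool_size,
                     pmax(4, round(design$pool_multiplier * exp_rich)))
  pools <- vector("list", ns)
  # Flora members not inherited from the summit below are colonizers from
  # lower elevations, so their elevation affinity is centred 150 m
  # downslope of the summit.
  affinity <- function(k, downslope = 0) {
    stats::dnorm(optimum, elev[k] - downslope, 120)
  }
  pools[[1]] <- sample.int(design$pool_size, pool_sizes[1],
                           prob = commonness * affinity(1))
  for (k in seq_len(ns)[-1]) {
    size_k <- min(pool_sizes[k], length(pools[[k - 1]]))
    n_parent <- stats::rbinom(1, size_k, design$nestedness_strength)
    from_parent <- .sample_vec(pools[[k - 1]], n_parent,
                               commonness[pools[[k - 1]]])
    rest <- setdiff(seq_len(design$pool_size), from_parent)
    n_free <- size_k - n_parent
    from_free <- .sample_vec(rest, n_free,
                             (commonness * affinity(k, 150))[rest])
    pools[[k]] <- sort(c(from_parent, from_free))
  }

  # --- baseline communities ------------------------------------------------
  # The summit pool is treated as the summit's realized flora: a survey of
  # all 16 corner quadrats is a complete inventory, so every flora member
  # is allocated to at least one quadrat (coverage pass), and the
  # remaining quadrat slots are filled by commonness-weighted draws.  This
  # makes the pooled summit incidence inherit the pools' nested structure
  # while quadrat-level richness follows its Poisson targets.
  y1 <- design$years[1]; y2 <- design$years[2]
  warm <- c("S", "E")
  quads <- expand.grid(q = seq_len(design$quadrats_per_aspect),
                       aspect = design$aspects, summit = seq_len(ns),
                       stringsAsFactors = FALSE)
  comm <- vector("list", nrow(quads))   # per quadrat: list(sp, cover)
  for (k in seq_len(ns)) {
    flora <- pools[[k]]
    qidx <- which(quads$summit == k)
    lambda <- vapply(qidx, function(i) {
      max(1, exp_rich[k] + design$aspect_richness_offsets[[quads$aspect[i]]])
    }, numeric(1))
    n_q <- pmax(1L, stats::rpois(length(qidx), lambda))
    assigned <- rep(list(integer(0)), length(qidx))
    cap <- n_q
    for (sp in sample(flora)) {
      w <- pmax(cap, 0)
      if (sum(w) == 0) w <- rep(1, length(cap))
      pick <- sample.int(length(qidx), 1, prob = w)
      assigned[[pick]] <- c(assigned[[pick]], sp)
      cap[pick] <- cap[pick] - 1L
    }
    for (qq in seq_along(qidx)) {
      need <- n_q[qq] - length(assigned[[qq]])
      if (need > 0) {
        avail <- setdiff(flora, assigned[[qq]])
        need <- min(need, length(avail))
        assigned[[qq]] <- c(assigned[[qq]],
                            .sample_vec(avail, need, commonness[avail]))
      }
      sp <- sort(assigned[[qq]])
      comm[[qidx[qq]]] <- list(sp = sp,
                               cover = .draw_cover(length(sp), design))
    }
  }

  # --- resurvey communities ------------------------------------------------
  comm2 <- vector("list", nrow(quads))
  for (idx in seq_len(nrow(quads))) {
    k <- quads$summit[idx]; a <- quads$aspect[idx]
    sp <- comm[[idx]]$sp; cov <- comm[[idx]]$cover
    if (a %in% warm) {
      n_rep <- stats::rbinom(1, length(sp), design$turnover_rate_warm_aspects)
      candidates <- setdiff(pools[[k]], sp)
      n_rep <- min(n_rep, length(candidates), length(sp) - 1L)
      if (n_rep > 0) {
        out <- sample(seq_along(sp), n_rep)
        gained <- .sample_vec(candidates, n_rep, commonness[candidates])
        sp <- c(sp[-out], gained)
        cov <- c(cov[-out], .draw_cover(n_rep, design))
      }
    } else {
      n_loss <- min(stats::rbinom(1, length(sp),
                                  design$loss_rate_cold_aspects),
                    length(sp) - 1L)
      if (n_loss > 0) {
        out <- sample(seq_along(sp), n_loss)
        sp <- sp[-out]; cov <- cov[-out]
      }
      candidates <- setdiff(pools[[k]], sp)
      n_gain <- min(stats::rbinom(1, length(sp),
                                  design$gain_rate_cold_aspects),
                    length(candidates))
      if (n_gain > 0) {
        gained <- .sample_vec(candidates, n_gain, commonness[candidates])
        sp <- c(sp, gained)
        cov <- c(cov, .draw_cover(n_gain, design))
      }
    }
    if (a %in% design$shift_aspects) {
      cov <- .tilt_covers(cov, rank[sp], design$shift_magnitude)
    }
    if (design$cover_noise_sdlog > 0) {
      cov <- cov * exp(stats::rnorm(length(cov), 0, design$cover_noise_sdlog))
    }
    comm2[[idx]] <- list(sp = sp, cover = pmin(100, pmax(0.1, cov)))
  }

  # --- assemble records ----------------------------------------------------
  mk_rows <- function(cl, yr) {
    do.call(rbind, lapply(seq_len(nrow(quads)), function(idx) {
      cc <- cl[[idx]]
      data.frame(summit_id = design$summits$summit_id[quads$summit[idx]],
                 aspect = quads$aspect[idx],
                 quadrat_index = quads$q[idx],
                 year = yr,
                 species_id = pool_ids[cc$sp],
                 cover = round(cc$cover, 4),
                 stringsAsFactors = FALSE)
    }))
  }
  obs <- rbind(mk_rows(comm, y1), mk_rows(comm2, y2))
  obs <- obs[order(obs$year, obs$summit_id, obs$aspect, obs$quadrat_index,
                   obs$species_id), ]
  rownames(obs) <- NULL
  used <- sort(unique(obs$species_id))
  attributes_tab <- data.frame(species_id = pool_ids,
                               elevational_rank = rank,
                               growth_form = growth_form,
                               stringsAsFactors = FALSE)
  attributes_tab <- attributes_tab[attributes_tab$species_id %in% used, ]
  rownames(attributes_tab) <- NULL

  expected <- expand.grid(summit_id = design$summits$summit_id,
                          aspect = design$aspects,
                          stringsAsFactors = FALSE)
  expected$expected_richness <- pmax(1,
    .expected_richness(design)[match(expected$summit_id,
                                     design$summits$summit_id)] +
      unlist(design$aspect_richness_offsets[expected$aspect]))
  truth <- list(
    ranks = data.frame(species_id = pool_ids, elevational_rank = rank,
                       optimum_elevation = optimum,
                       stringsAsFactors = FALSE),
    expected_richness = expected,
    summit_pools = stats::setNames(lapply(pools, function(p) pool_ids[p]),
                                   design$summits$summit_id),
    shift_magnitude = design$shift_magnitude,
    shift_aspects = design$shift_aspects,
    aspect_process = data.frame(
      aspect = design$aspects,
      process = ifelse(design$aspects %in% warm, "replacement", "net_loss"),
      stringsAsFactors = FALSE),
    design = design)
  list(observations = validate_observations(obs, "quadrat"),
       attributes = validate_species_attributes(attributes_tab),
       truth = truth)
}

#' Generate hourly soil-temperature logger series
#'
#' One logger per (summit, aspect), recording hourly at 10 cm depth over
#' two 12-month August-July windows (one per survey period).  The signal is
#' an annual sinusoid plus a diurnal sinusoid, an elevation lapse term, an
#' aspect offset, a between-window warming increment, and Gaussian noise;
#' requested gaps are recorded as missing values.
#'
#' @param summits Summit table (`summit_id`, `elevation`).
#' @param aspect_offsets Named per-aspect temperature offsets (degC).
#' @param lapse_rate Cooling per 100 m of elevation (degC).
#' @param baseline_mean Annual mean soil temperature at the lowest summit
#'   in the first window (degC).
#' @param seasonal_amplitude,diurnal_amplitude Sinusoid amplitudes (degC).
#' @param noise_sd SD of hourly Gaussian noise (degC).
#' @param warming_increment Added to every hour of the second window
#'   (degC).
#' @param window_starts Length-2 character, the August 1st starting each
#'   12-month window.
#' @param gap_spec Optional data.frame (`logger_id`, `start` timestamp,
#'   `hours`) marking logger outages; overlapping gaps on one logger are an
#'   error.
#' @param seed Integer seed.
#' @return data.frame of class `logger_series` with columns `logger_id`,
#'   `summit_id`, `aspect`, `window` (1 or 2), `timestamp` (POSIXct, UTC),
#'   `temperature` (degC, NA inside gaps).
#' @export
generate_logger_series <- function(summits = data.frame(
                                     summit_id = c("GUL1", "GUL2",
                                                   "GUL3", "GUL4"),
                                     elevation = c(3530, 3600, 3670, 3740),
                                     stringsAsFactors = FALSE),
                                   aspect_offsets = c(N = -0.8, S = 0.8,
                                                      E = 0.5, W = -0.5),
                                   lapse_rate = 1.2,
                                   baseline_mean = 5,
                                   seasonal_amplitude = 8,
                                   diurnal_amplitude = 2,
                                   noise_sd = 1,
                                   warming_increment = 1.5,
                                   window_starts = c("2014-08-01",
                                                     "2017-08-01"),
                                   gap_spec = NULL,
                                   seed = 1) {
  summits <- validate_summits(summits)
  .check_aspect(names(aspect_offsets))
  .assert(all(is.finite(c(lapse_rate, baseline_mean, seasonal_amplitude,
                          diurnal_amplitude, noise_sd, warming_increment))),
          "logger parameters must be finite")
  .assert(noise_sd >= 0, "'noise_sd' must be non-negative")
  set.seed(as.integer(seed))

  windows <- lapply(seq_along(window_starts), function(w) {
    start <- as.POSIXct(paste(window_starts[w], "00:00:00"), tz = "UTC")
    seq(start, by = "hour", length.out = 365L * 24L)
  })
  aspects <- names(aspect_offsets)
  out <- vector("list", nrow(summits) * length(aspects) * length(windows))
  n <- 0L
  for (s in seq_len(nrow(summits))) {
    for (a in aspects) {
      for (w in seq_along(windows)) {
        ts <- windows[[w]]
        lt <- as.POSIXlt(ts, tz = "UTC")
        frac_year <- (lt$yday + lt$hour / 24) / 365
        hour <- lt$hour
        temp <- baseline_mean -
          lapse_rate * (summits$elevation[s] - summits$elevation[1]) / 100 +
          aspect_offsets[[a]] +
          seasonal_amplitude * cos(2 * pi * (frac_year - 200 / 365)) +
          diurnal_amplitude * cos(2 * pi * (hour - 14) / 24) +
          (w == 2L) * warming_increment
        if (noise_sd > 0) temp <- temp + stats::rnorm(length(ts), 0, noise_sd)
        n <- n + 1L
        out[[n]] <- data.frame(
          logger_id = paste0(summits$summit_id[s], ".", a),
          summit_id = summits$summit_id[s], aspect = a, window = w,
          timestamp = ts, temperature = temp, stringsAsFactors = FALSE)
      }
    }
  }
  series <- do.call(rbind, out)

  if (!is.null(gap_spec) && nrow(gap_spec) > 0) {
    .assert(all(c("logger_id", "start", "hours") %in% names(gap_spec)),
            "'gap_spec' needs columns logger_id, start, hours")
    gap_spec$start <- as.POSIXct(gap_spec$start, tz = "UTC")
    for (lg in unique(gap_spec$logger_id)) {
      g <- gap_spec[gap_spec$logger_id == lg, , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      ends <- g$start + (g$hours - 1) * 3600
      if (nrow(g) > 1L) {
        .assert(all(g$start[-1] > ends[-nrow(g)]),
                "overlapping gap specs on logger ", lg)
      }
      for (i in seq_len(nrow(g))) {
        hit <- series$logger_id == lg &
          series$timestamp >= g$start[i] & series$timestamp <= ends[i]
        .assert(any(hit), "gap for logger ", lg,
                " lies outside the simulated period")
        series$temperature[hit] <- NA_real_
      }
    }
  }
  class(series) <- c("logger_series", "data.frame")
  series
}

#' Write a synthetic survey and logger bundle to disk
#'
#' @param survey Result of [generate_survey()].
#' @param loggers Optional result of [generate_logger_series()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_survey <- function(survey, loggers = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(observations = file.path(dir, "observations.csv"),
             attributes = file.path(dir, "species_attributes.csv"),
             summits = file.path(dir, "summits.csv"),
             truth = file.path(dir, "truth.yaml"))
  write_observations(survey$observations, paths[["observations"]])
  utils::write.csv(survey$attributes, paths[["attributes"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(survey$truth$design$summits, paths[["summits"]],
                   row.names = FALSE, quote = FALSE)
  truth <- survey$truth
  truth$design <- unclass(truth$design)
  yaml::write_yaml(lapply(truth, function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }), paths[["truth"]])
  if (!is.null(loggers)) {
    paths[["loggers"]] <- file.path(dir, "loggers.csv")
    utils::write.csv(as.data.frame(loggers), paths[["loggers"]],
                     row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
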