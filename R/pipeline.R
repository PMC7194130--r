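# End-to-end orchestration: configuration, staged execution, logged and
# seeded runs writing a bundle of delimited-text tables.
#
# The run either simulates its inputs (a `simulation` section) or reads
# them from disk (an `inputs` section) -- exactly one of the two.  Stages
# run in a fixed order (simulate -> validate -> microclimate -> summaries
# -> beta -> varpart -> thermophilization) and communicate only through
# their output tables.

#' Build or read a pipeline run configuration
#'
#' @param config A named list, or the path to a YAML file with the same
#'   structure.  Recognized top-level sections: exactly one of `inputs`
#'   (paths `observations`, `attributes`, `summits`, optionally `loggers`)
#'   or `simulation` (arguments for [survey_design()] plus an optional
#'   `loggers` subsection for [generate_logger_series()]); optional
#'   `analysis` (`beta_grouping` "summit" or "aspect", `gdd_threshold`,
#'   `n_perm`, `seed`).
#' @return Validated configuration list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    .assert(file.exists(config), "config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  .assert(is.list(config), "'config' must be a list or a YAML path")
  has_inputs <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulation)
  .assert(xor(has_inputs, has_sim),
          "exactly one of 'inputs' or 'simulation' must be configured")
  if (has_inputs) {
    need <- c("observations", "attributes", "summits")
    missing_keys <- setdiff(need, names(config$inputs))
    .assert(length(missing_keys) == 0L,
            "inputs section missing: ", paste(missing_keys, collapse = ", "))
    for (p in unlist(config$inputs)) {
      .assert(file.exists(p), "input file not found: ", p)
    }
  }
  analysis <- config$analysis %||% list()
  analysis$beta_grouping <- match.arg(analysis$beta_grouping %||% "aspect",
                                      c("aspect", "summit"))
  analysis$gdd_threshold <- analysis$gdd_threshold %||% 5
  analysis$n_perm <- analysis$n_perm %||% 199
  analysis$seed <- as.integer(analysis$seed %||% 1)
  config$analysis <- analysis
  class(config) <- "run_config"
  config
}

.meta_header <- function(config, seed) {
  c(sprintf("# summitveg %s",
            as.character(utils::packageVersion("summitveg"))),
    sprintf("# seed: %d", seed),
    sprintf("# config: %s", .config_hash(unclass(config))))
}

.write_table <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full resurvey analysis pipeline
#'
#' Executes every stage on simulated or on-disk inputs and writes the
#' result bundle (delimited-text tables, Newick dendrograms, and a run
#' log) to `out_dir`.  Identical configuration and seed give a
#' byte-identical bundle.
#'
#' @param config A [run_config()] (or list / YAML path coercible to one).
#' @param out_dir Output directory, created if needed.
#' @param seed Optional integer overriding the configured seed.
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  config <- run_config(config)
  if (!is.null(seed)) config$analysis$seed <- as.integer(seed)
  seed <- config$analysis$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  header <- .meta_header(config, seed)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  paths <- list()
  emit <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    .write_table(df, p, header)
    paths[[name]] <<- p
  }

  # --- simulate / load -----------------------------------------------------
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    logger_cfg <- sim_cfg$loggers
    sim_cfg$loggers <- NULL
    sim_cfg$seed <- seed
    stage("simulate", {
      design <- do.call(survey_design, sim_cfg)
      survey <- generate_survey(design)
      loggers <- do.call(generate_logger_series,
                         c(list(summits = design$summits,
                                seed = seed + 1L),
                           logger_cfg %||% list()))
      obs <- survey$observations
      attrs <- survey$attributes
      summits <- design$summits
      write_survey(survey, loggers, file.path(out_dir, "inputs"))
    })
    say("simulate: %d observation rows, %d species, %d logger rows",
        nrow(obs), nrow(attrs), nrow(loggers))
  } else {
    stage("load", {
      obs <- read_observations(config$inputs$observations, "quadrat")
      attrs <- read_species_attributes(config$inputs$attributes)
      summits <- read_summits(config$inputs$summits)
      loggers <- if (!is.null(config$inputs$loggers)) {
        read_logger_series(config$inputs$loggers)
      } else NULL
    })
    say("load: %d observation rows, %d species", nrow(obs), nrow(attrs))
  }
  years <- sort(unique(obs$year))
  .assert(length(years) == 2L, "pipeline expects two survey years")

  # --- microclimate --------------------------------------------------------
  if (!is.null(loggers)) {
    stage("microclimate", {
      mc <- microclimate_summary(loggers,
                                 threshold = config$analysis$gdd_threshold)
      emit(mc, "microclimate_gdd")
      wide <- stats::reshape(mc[c("logger_id", "window", "annual_mean")],
                             idvar = "logger_id", timevar = "window",
                             direction = "wide")
      trend <- data.frame(
        logger_id = wide$logger_id,
        warming = wide$annual_mean.2 - wide$annual_mean.1)
      emit(trend, "microclimate_warming")
    })
    say("microclimate: %d logger-window summaries", nrow(mc))
  }

  # --- summaries -----------------------------------------------------------
  stage("summaries", {
    rich <- richness_per_quadrat(obs, summits)
    cov <- cover_per_quadrat(obs, summits)
    emit(rich, "richness_per_quadrat")
    emit(group_summary(rich, "richness", c("summit_id", "year")),
         "richness_summary")
    emit(cover_change_table(obs, attrs), "cover_change")
    an1 <- factor_effects(rich$richness[rich$year == years[1]],
                          rich[rich$year == years[1], ], "oneway_nested")
    an2 <- factor_effects(rich$richness, rich, "twoway_interaction")
    an1$model <- "aspect_nested_in_summit"
    an2$model <- "summit_x_year"
    emit(rbind(an1, an2), "anova")
  })
  say("summaries: %d quadrat-year richness values", nrow(rich))

  # --- beta diversity ------------------------------------------------------
  stage("beta", {
    grouping <- config$analysis$beta_grouping
    m1 <- build_matrix(obs, grouping, year = years[1], mode = "incidence",
                       summits = summits)
    m2 <- build_matrix(obs, grouping, year = years[2], mode = "incidence",
                       summits = summits)
    ms <- lapply(years, function(y) {
      bp <- multisite_partition(build_matrix(obs, grouping, year = y,
                                             mode = "incidence"))
      data.frame(year = y, grouping = grouping, bsor = bp$bsor,
                 bsim = bp$bsim, bsne = bp$bsne)
    })
    emit(do.call(rbind, ms), "beta_multisite")
    emit(temporal_partition(m1, m2), "beta_temporal")
    for (comp in c("bsim", "bsne")) {
      dmat <- component_distance_matrix(m1, comp)
      emit(cbind(data.frame(site = rownames(dmat)),
                 as.data.frame(dmat, check.names = FALSE)),
           paste0("beta_", comp, "_distance"))
      hc <- average_linkage_cluster(dmat)
      p <- file.path(out_dir, paste0("dendrogram_", comp, ".nwk"))
      write_dendrogram(hc, p)
      paths[[paste0("dendrogram_", comp)]] <- p
    }
  })
  say("beta: grouping = %s", config$analysis$beta_grouping)

  # --- variation partitioning ---------------------------------------------
  stage("varpart", {
    key <- paste(rich$summit_id, rich$aspect, rich$quadrat_index,
                 rich$year)
    ckey <- paste(cov$summit_id, cov$aspect, cov$quadrat_index, cov$year)
    vp <- varpart_table(
      list(richness = rich$richness,
           cover = cov$total_cover[match(key, ckey)]),
      elevation = rich$elevation, aspect = rich$aspect, year = rich$year,
      n_perm = config$analysis$n_perm, seed = seed)
    emit(vp, "varpart")
  })
  say("varpart: %d permutations", config$analysis$n_perm)

  # --- thermophilization ---------------------------------------------------
  stage("thermophilization", {
    ind <- thermic_indicators(obs, attrs)
    ch <- thermophilization_change(ind, years)
    emit(ch, "thermophilization")
    emit(thermophilization_summary(ch), "thermophilization_summary")
  })
  say("thermophilization: done")

  log_path <- file.path(out_dir, "run.log")
  writeLines(c(header, log_lines), log_path)
  paths$log <- log_path
  invisible(paths)
}
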