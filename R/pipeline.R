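#' Pipeline run configuration
#'
#' Collects every tunable of the staged pipeline: generator parameters,
#' processing thresholds, matching tolerances, forcing constants, the
#' ensemble grid and the master seed.  \code{read_pipeline_config} loads
#' overrides from a YAML file; unknown keys are rejected.
#'
#' @param generator \code{\link{generator_params}} overrides (list).
#' @param processing \code{\link{process_config}} overrides (list).
#' @param matching \code{\link{match_tolerances}} overrides (list).
#' @param constants \code{\link{forcing_constants}} overrides (list).
#' @param seed master seed; overrides the generator seed.
#' @param years forcing horizon.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(generator = list(), processing = list(),
                            matching = list(), constants = list(),
                            seed = 1L, years = 100L) {
  cfg <- list(
    generator = do.call(generator_params,
                        utils::modifyList(list(seed = seed), generator)),
    processing = do.call(process_config, processing),
    matching = do.call(match_tolerances, matching),
    constants = do.call(forcing_constants, constants),
    seed = as.integer(seed), years = as.integer(years))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file with any of the keys generator, processing,
#'   matching, constants, seed, years.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("generator", "processing", "matching", "constants", "seed",
             "years")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Validate a directory of FLUXNET-dialect inputs
#'
#' Checks the metadata table (required columns, IGBP vocabulary, MAT/MAP
#' completeness) and each site CSV (required columns, uniform half-hourly
#' timestamp grid, non-negative radiation).  Missing MAT/MAP yields a
#' warning (they are recoverable from the series means); structural
#' problems are fatal.
#'
#' @param dir directory containing \code{site_metadata.csv} and one
#'   \code{<site_id>.csv} per site.
#' @return data.frame report (level, site, message); empty when all checks
#'   pass.
#' @export
validate_inputs <- function(dir) {
  report <- list()
  note <- function(level, site, msg)
    report[[length(report) + 1L]] <<- data.frame(
      level = level, site = site, message = msg, stringsAsFactors = FALSE)
  meta_path <- file.path(dir, "site_metadata.csv")
  if (!file.exists(meta_path)) {
    note("fatal", NA, "site_metadata.csv not found")
    return(do.call(rbind, report))
  }
  meta <- tryCatch(read_site_metadata(meta_path), error = function(e) {
    note("fatal", NA, conditionMessage(e)); NULL
  })
  if (!is.null(meta)) {
    for (i in seq_len(nrow(meta))) {
      sid <- meta$site_id[i]
      if (is.na(meta$mat[i]))
        note("warning", sid, "missing MAT; series mean will be used")
      if (is.na(meta$map[i]))
        note("warning", sid, "missing MAP; series mean will be used")
      f <- file.path(dir, paste0(sid, ".csv"))
      if (!file.exists(f)) {
        note("fatal", sid, "series CSV not found")
        next
      }
      tryCatch(invisible(read_fluxnet_csv(f, sid)), error = function(e)
        note("fatal", sid, conditionMessage(e)))
    }
  }
  out <- if (length(report)) do.call(rbind, report)
  else data.frame(level = character(), site = character(),
                  message = character(), stringsAsFactors = FALSE)
  out
}

# Small stable hash (FNV-1a over the serialised object) for the manifest.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the staged analysis pipeline
#'
#' Stages: \code{simulate} writes a synthetic network as FLUXNET-dialect
#' CSVs; \code{process} turns the CSVs into labelled windows, annual and
#' monthly tables; \code{densities} computes the NEP-albedo density
#' analysis and rank correlation; \code{scenarios} assigns the paired-site
#' permutation scenarios; \code{forcing} integrates the 100-year forcing
#' ensemble; \code{report} writes a manifest (stages, record counts,
#' config hash, seed, package version).  Later stages read the delimited
#' tables written by earlier ones, so a subset of stages can be re-run; a
#' missing upstream artifact raises an error naming the stage to run
#' first.  Identical configuration yields byte-identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param stages subset of simulate, process, densities, scenarios,
#'   forcing, report (in pipeline order).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the stage outputs produced in this call.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "process", "densities",
                                    "scenarios", "forcing", "report"),
                         out_dir) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  input_dir <- file.path(out_dir, "input")
  res <- list()
  counts <- list()
  need <- function(path, stage) {
    if (!file.exists(path))
      stop("missing artifact ", basename(path),
           ": run stage '", stage, "' first", call. = FALSE)
    path
  }

  if ("simulate" %in% stages) {
    dir.create(input_dir, showWarnings = FALSE)
    net <- generate_network(config$generator)
    write_site_metadata(net$meta, file.path(input_dir, "site_metadata.csv"))
    truth_rows <- list()
    for (sid in names(net$series)) {
      for (yr in names(net$series[[sid]])) {
        write_fluxnet_csv(net$series[[sid]][[yr]],
                          file.path(input_dir, paste0(sid, "_", yr, ".csv")))
        tr <- net$truth[[sid]][[yr]]
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          site_id = sid, year = as.integer(yr), albedo = tr$albedo,
          nep = tr$nep, stringsAsFactors = FALSE)
      }
    }
    write_table(do.call(rbind, truth_rows),
                file.path(input_dir, "truth_log.tsv"))
    counts$sites_simulated <- nrow(net$meta)
    res$network <- net
  }

  if ("process" %in% stages) {
    meta <- read_site_metadata(need(file.path(input_dir,
                                              "site_metadata.csv"),
                                    "simulate"))
    annual_rows <- list(); monthly_rows <- list(); window_rows <- list()
    series_by_site <- list()
    for (sid in meta$site_id) {
      files <- list.files(input_dir, pattern = paste0("^", sid, "_\\d{4}\\.csv$"),
                          full.names = TRUE)
      if (!length(files))
        stop("missing artifact ", sid, "_<year>.csv: run stage 'simulate'",
             " first", call. = FALSE)
      processed <- lapply(files, function(f) {
        s <- read_fluxnet_csv(f, sid)
        attr(s, "year") <- as.integer(
          format(s$timestamp[1], "%Y", tz = "UTC"))
        process_site(s, config$processing)
      })
      imputed <- lapply(processed, `[[`, "series")
      series_by_site[[sid]] <- imputed
      ann <- withCallingHandlers(
        screen_full_years(imputed, sid),
        warning = function(w) invokeRestart("muffleWarning"))
      annual_rows[[sid]] <- ann
      complete <- imputed[ann$complete]
      if (length(complete))
        monthly_rows[[sid]] <- monthly_climatology(complete, sid)
      for (p in processed) {
        w <- p$windows
        w$site_id <- sid
        window_rows[[length(window_rows) + 1L]] <-
          w[, c("site_id", "start", "end", "albedo", "t_min", "n_records",
                "snow", "nep", "nep_month", "condition", "sw_in_sum",
                "sw_out_sum")]
      }
    }
    meta <- fill_missing_meta(meta, series_by_site)
    annual <- do.call(rbind, annual_rows)
    site_means <- stats::aggregate(cbind(nep, albedo) ~ site_id,
                                   annual[annual$complete, ], mean)
    write_table(annual, file.path(out_dir, "site_annual.tsv"))
    write_table(site_means, file.path(out_dir, "site_means.tsv"))
    write_table(do.call(rbind, monthly_rows),
                file.path(out_dir, "monthly_climatology.tsv"))
    write_table(do.call(rbind, window_rows),
                file.path(out_dir, "windows.tsv"))
    write_site_metadata(meta, file.path(out_dir, "site_metadata_filled.csv"))
    counts$sites_processed <- length(annual_rows)
    counts$years_dropped <- sum(!annual$complete)
    res$annual <- annual; res$site_means <- site_means
  }

  if ("densities" %in% stages) {
    sm <- utils::read.delim(need(file.path(out_dir, "site_means.tsv"),
                                 "process"))
    kde <- kde_tradeoff(sm$albedo, sm$nep)
    rho <- spearman_cor(sm$albedo, sm$nep)
    grid <- expand.grid(alpha = kde$alpha, nep = kde$nep)
    grid$d_joint <- as.vector(kde$d_joint)
    grid$d_prod <- as.vector(kde$d_prod)
    grid$d_diff <- as.vector(kde$d_diff)
    write_table(grid, file.path(out_dir, "density_surfaces.tsv"))
    write_table(data.frame(statistic = "spearman_rho_albedo_nep",
                           value = rho$rho, p = rho$p, n = rho$n),
                file.path(out_dir, "correlations.tsv"))
    counts$density_points <- kde$n
    res$kde <- kde; res$spearman <- rho
  }

  if ("scenarios" %in% stages) {
    sm <- utils::read.delim(need(file.path(out_dir, "site_means.tsv"),
                                 "process"))
    mc <- utils::read.delim(need(file.path(out_dir,
                                           "monthly_climatology.tsv"),
                                 "process"))
    meta <- read_site_metadata(need(
      file.path(out_dir, "site_metadata_filled.csv"), "process"))
    asn <- assign_scenarios(sm, meta, monthly = mc,
                            tol = config$matching)
    write_table(asn, file.path(out_dir, "scenario_assignments.tsv"))
    write_table(scenario_summary(asn),
                file.path(out_dir, "scenario_summary.tsv"))
    counts$sites_with_partners <- sum(asn$has_partners) / 4
    res$assignments <- asn
  }

  if ("forcing" %in% stages) {
    asn <- utils::read.delim(need(file.path(out_dir,
                                            "scenario_assignments.tsv"),
                                  "scenarios"))
    sm <- utils::read.delim(need(file.path(out_dir, "site_means.tsv"),
                                 "process"))
    mc <- utils::read.delim(need(file.path(out_dir,
                                           "monthly_climatology.tsv"),
                                 "process"))
    meta <- read_site_metadata(need(
      file.path(out_dir, "site_metadata_filled.csv"), "process"))
    traj <- build_trajectories(asn, sm, meta, mc,
                               constants = config$constants,
                               years = config$years)
    write_table(traj$trajectories, file.path(out_dir, "trajectories.tsv"))
    write_table(traj$summary, file.path(out_dir, "trajectory_summary.tsv"))
    counts$trajectories <- nrow(traj$trajectories)
    res$trajectories <- traj
  }

  if ("report" %in% stages) {
    manifest <- list(
      stages = stages,
      seed = config$seed,
      config_hash = config_hash(unclass(config)),
      package_version = as.character(utils::packageVersion("nepalbedo")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      counts = counts,
      thresholds = list(
        drift_tol = config$processing$drift_tol,
        swin_floor = config$processing$swin_floor,
        snow_albedo_min = config$processing$snow_albedo_min,
        snow_tmax = config$processing$snow_tmax,
        mat_abs = config$matching$mat_abs,
        sw_rel = config$matching$sw_rel,
        map_rel = config$matching$map_rel,
        snowdays_rel = config$matching$snowdays_rel))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    res$manifest <- manifest
  }
  invisible(res)
}
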