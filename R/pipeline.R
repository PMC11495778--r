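#' Default run configuration (demo study)
#'
#' Six locations over five observed years, three pseudo earth-system
#' models with model-specific biases and variability, a warming control
#' scenario plus two land-use scenarios perturbing the control trend,
#' two ensemble members per model, and the 1980-2099 projection horizon.
#' All values can be overridden through a YAML file ([read_config()]).
#'
#' @param out_dir output directory of the run.
#' @return a nested configuration list of class `run_config`.
#' @export
default_config <- function(out_dir = "results/pipeline") {
  structure(list(
    seed = 1L,
    out_dir = out_dir,
    write_scenario_series = FALSE,
    study = list(n_locations = 6L, years_per_location = 5L,
                 n_regions = 3L, start_year = 2000L),
    models = list(
      list(name = "ESM-A", additive_bias = 1.2, variability_scale = 1.1),
      list(name = "ESM-B", additive_bias = -0.8, variability_scale = 0.9),
      list(name = "ESM-C", additive_bias = 0.3, variability_scale = 1.0)
    ),
    scenarios = list(
      list(name = "noLULCC", trend_per_decade = 0.10),
      list(name = "sustainability", trend_per_decade = 0.08),
      list(name = "inequality", trend_per_decade = 0.13)
    ),
    n_members = 2L,
    horizon = c(1980L, 2099L),
    first_stage = list(var_percentiles = c(10, 50, 90), max_lag = 21L,
                       seasonal_df_per_year = 8),
    meta = list(predictors = c("avg_tmean"), include_zone = FALSE),
    mmt_window = c(1, 99),
    monte_carlo = list(n_samples = 1000L, project_ci = FALSE),
    calibration_window = c(1980, 2014),
    decades = c("1980-1989", "2050-2059", "2090-2099")
  ), class = "run_config")
}

#' Read a run configuration from YAML, merged over the defaults.
#'
#' @param path YAML file with any subset of the [default_config()] keys.
#' @return a `run_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  class(cfg) <- "run_config"
  cfg
}

#' @noRd
pipeline_paths <- function(cfg) {
  out <- cfg$out_dir
  list(out = out,
       series_dir = file.path(out, "data", "series"),
       scenario_dir = file.path(out, "data", "scenarios"),
       metadata = file.path(out, "data", "metadata.csv"),
       curves_fs = file.path(out, "results", "curves_first_stage.csv"),
       curves_blup = file.path(out, "results", "curves_blup.csv"),
       meta_beta = file.path(out, "results", "meta_beta.csv"),
       meta_psi = file.path(out, "results", "meta_psi.csv"),
       mmt = file.path(out, "results", "mmt.csv"),
       attribution = file.path(out, "results", "attribution.csv"),
       decade_sums = file.path(out, "results", "projection_decade_sums.csv"),
       project_ci = file.path(out, "results", "projection_ci.csv"),
       by_member = file.path(out, "results", "projection_by_member.csv"),
       by_model = file.path(out, "results", "projection_by_model.csv"),
       multimodel = file.path(out, "results", "projection_multimodel.csv"),
       regional = file.path(out, "results", "projection_regional.csv"),
       dictionary = file.path(out, "results", "data_dictionary.csv"),
       manifest = file.path(out, "manifest.json"))
}

#' @noRd
regen_study <- function(cfg) {
  make_study(n_locations = cfg$study$n_locations,
             years_per_location = cfg$study$years_per_location,
             seed = cfg$seed, n_regions = cfg$study$n_regions,
             start_year = cfg$study$start_year)
}

#' @noRd
basis_spec_from <- function(cfg) {
  cross_basis_spec(var_percentiles = cfg$first_stage$var_percentiles,
                   max_lag = cfg$first_stage$max_lag)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the stages in dependency order: `simulate` (synthetic study
#' and, optionally, persisted pseudo-ESM series), `first_stage` (one
#' DLNM per location), `meta` (pooling and BLUPs), `attribute`
#' (MMT, excess-mortality fractions, Monte-Carlo CIs), `project`
#' (calibrated scenario projections collapsed to decade sums) and
#' `aggregate` (decadal fractions, deltas, ensemble/multimodel means,
#' regional aggregates).  All artifacts are delimited text under
#' `out_dir`; a JSON manifest records the seed, the configuration and
#' its hash, and per-stage row counts, so any intermediate file can be
#' deleted and regenerated bit-identically.
#'
#' @param config a `run_config` list ([default_config()],
#'   [read_config()]) or a YAML path.
#' @param stages subset of stages to run (in dependency order); earlier
#'   artifacts must already exist on disk when a stage is rerun alone.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "first_stage", "meta",
                                    "attribute", "project", "aggregate")) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  p <- pipeline_paths(cfg)
  for (d in c(p$series_dir, file.path(p$out, "results"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  counts <- list()
  spec <- basis_spec_from(cfg)
  control <- fit_control(seasonal_df_per_year = cfg$first_stage$seasonal_df_per_year)

  if ("simulate" %in% stages) {
    study <- regen_study(cfg)
    for (id in names(study$series)) {
      write_series(study$series[[id]], file.path(p$series_dir, paste0(id, ".csv")))
    }
    write_metadata(study$metadata, p$metadata)
    counts$simulate <- sum(vapply(study$series, nrow, 0L)) + nrow(study$metadata)
    if (isTRUE(cfg$write_scenario_series)) {
      dir.create(p$scenario_dir, recursive = TRUE, showWarnings = FALSE)
      for (id in names(study$series)) {
        scen <- do.call(rbind, lapply(cfg$models, function(mod) {
          do.call(rbind, lapply(cfg$scenarios, function(sc) {
            make_scenario_series(study$series[[id]],
                                 scenario_cfg(cfg, mod, sc), cfg$seed)
          }))
        }))
        write_scenario_series(scen, file.path(p$scenario_dir, paste0(id, ".csv")))
      }
    }
  }

  if ("first_stage" %in% stages) {
    meta_tab <- read_metadata(p$metadata)
    curves <- lapply(meta_tab$location, function(id) {
      series <- read_series(file.path(p$series_dir, paste0(id, ".csv")), id)
      fit <- fit_location(series, spec, control)
      reduce_to_overall_cumulative(fit)
    })
    names(curves) <- meta_tab$location
    write_curves(curves, p$curves_fs, spec = spec)
    counts$first_stage <- length(curves)
  }

  if ("meta" %in% stages) {
    meta_tab <- read_metadata(p$metadata)
    curves <- read_curves(p$curves_fs)
    design <- build_meta_design(meta_tab,
                                predictors = cfg$meta$predictors,
                                include_zone = isTRUE(cfg$meta$include_zone))
    mf <- fit_meta(curves, design)
    blups <- compute_blups(mf, curves)
    write_curves(blups, p$curves_blup, spec = spec)
    beta_df <- as.data.frame(mf$beta)
    colnames(beta_df) <- mf$predictors
    write.csv(cbind(coef = paste0("theta", seq_len(mf$k)), beta_df),
              p$meta_beta, row.names = FALSE, quote = FALSE)
    write.csv(as.data.frame(mf$psi), p$meta_psi, row.names = FALSE, quote = FALSE)
    counts$meta <- length(blups)
  }

  if ("attribute" %in% stages) {
    meta_tab <- read_metadata(p$metadata)
    blups <- read_curves(p$curves_blup)
    rows <- list(); mmts <- list()
    for (id in meta_tab$location) {
      series <- read_series(file.path(p$series_dir, paste0(id, ".csv")), id)
      res <- attribute_location(series, blups[[id]], window = cfg$mmt_window,
                                n_samples = cfg$monte_carlo$n_samples,
                                seed = substream_seed(cfg$seed, c(id, "mc")))
      rows[[id]] <- res
      m <- attr(res, "mmt")
      mmts[[id]] <- data.frame(location = id, mmt = m$value,
                               percentile = m$percentile,
                               boundary = m$boundary)
    }
    write.csv(do.call(rbind, c(rows, make.row.names = FALSE)),
              p$attribution, row.names = FALSE, quote = FALSE)
    write.csv(do.call(rbind, c(mmts, make.row.names = FALSE)),
              p$mmt, row.names = FALSE, quote = FALSE)
    counts$attribute <- length(rows) * 3L
  }

  if ("project" %in% stages) {
    study <- regen_study(cfg)
    blups <- read_curves(p$curves_blup)
    mmt_tab <- read.csv(p$mmt, stringsAsFactors = FALSE)
    sums <- list(); cis <- list()
    for (id in names(study$series)) {
      series <- study$series[[id]]
      mmt <- mmt_tab$mmt[mmt_tab$location == id]
      base <- baseline_mortality(series, cfg$horizon[1], cfg$horizon[2])
      for (mod in cfg$models) {
        for (sc in cfg$scenarios) {
          scfg <- scenario_cfg(cfg, mod, sc)
          scen <- make_scenario_series(series, scfg, cfg$seed)
          for (mem in seq_len(scfg$n_members)) {
            run <- scen[scen$member == mem, c("date", "tmean")]
            cal <- calibrate_bias(run, series, cfg$calibration_window)
            daily <- project_em(cal, base, blups[[id]], mmt)
            daily$location <- id
            daily$model <- mod$name
            daily$scenario <- sc$name
            daily$member <- mem
            sums[[length(sums) + 1L]] <- decade_sums(daily)
            if (isTRUE(cfg$monte_carlo$project_ci)) {
              ci <- project_decade_ci(cal, base, blups[[id]], mmt,
                                      decades = cfg$decades,
                                      n_samples = cfg$monte_carlo$n_samples,
                                      seed = substream_seed(cfg$seed,
                                        c(id, mod$name, sc$name, mem, "pci")))
              ci$location <- id; ci$model <- mod$name
              ci$scenario <- sc$name; ci$member <- mem
              cis[[length(cis) + 1L]] <- ci
            }
          }
        }
      }
    }
    sums <- do.call(rbind, sums)
    write.csv(sums, p$decade_sums, row.names = FALSE, quote = FALSE)
    counts$project <- nrow(sums)
    if (length(cis)) {
      write.csv(do.call(rbind, cis), p$project_ci, row.names = FALSE, quote = FALSE)
    }
  }

  if ("aggregate" %in% stages) {
    sums <- read.csv(p$decade_sums, stringsAsFactors = FALSE)
    meta_tab <- read_metadata(p$metadata)
    agg <- aggregate_projection(sums, meta_tab[c("location", "region")],
                                decades = cfg$decades)
    bm <- agg$by_member
    bm$region <- meta_tab$region[match(bm$location, meta_tab$location)]
    if (file.exists(p$project_ci)) {
      ci <- read.csv(p$project_ci, stringsAsFactors = FALSE)
      bm <- merge(bm, ci,
                  by = c("location", "model", "scenario", "member",
                         "decade", "component"),
                  all.x = TRUE, sort = FALSE)
    }
    ord <- c("location", "region", "model", "scenario", "member", "decade",
             "component")
    bm <- bm[do.call(order, bm[ord]), c(ord, setdiff(names(bm), ord))]
    write.csv(bm, p$by_member, row.names = FALSE, quote = FALSE)
    write.csv(agg$by_model, p$by_model, row.names = FALSE, quote = FALSE)
    write.csv(agg$multimodel, p$multimodel, row.names = FALSE, quote = FALSE)
    write.csv(agg$regional, p$regional, row.names = FALSE, quote = FALSE)
    write.csv(data_dictionary(), p$dictionary, row.names = FALSE)
    counts$aggregate <- nrow(bm)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tempmort")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    stages = stages,
    row_counts = counts
  )
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' @noRd
scenario_cfg <- function(cfg, mod, sc) {
  scenario_config(scenario_name = sc$name, model_name = mod$name,
                  n_members = cfg$n_members,
                  additive_bias = mod$additive_bias,
                  trend_per_decade = sc$trend_per_decade,
                  variability_scale = mod$variability_scale,
                  horizon_start = cfg$horizon[1], horizon_end = cfg$horizon[2])
}

#' MD5 hash of the canonical JSON form of a configuration.
#'
#' @param cfg a `run_config` list.
#' @return a character hash.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' @noRd
data_dictionary <- function() {
  data.frame(
    column = c("location", "region", "model", "scenario", "member", "decade",
               "component", "an", "an_cold", "an_heat", "an_total", "deaths",
               "fraction_pct", "delta_pp", "ci_low", "ci_high"),
    description = c(
      "location identifier",
      "geographic region of the location",
      "pseudo earth-system model name",
      "scenario name (noLULCC control, sustainability, inequality)",
      "ensemble member index",
      "calendar decade, e.g. 1980-1989",
      "cold / heat / total attribution component",
      "attributable deaths (sum over the period)",
      "attributable deaths on days below the MMT",
      "attributable deaths on days above the MMT",
      "cold + heat attributable deaths",
      "baseline (or observed) deaths in the period",
      "excess-mortality fraction: 100 * AN / deaths",
      "difference of fractions in percentage points (control decade minus its 1980-1989; land-use scenario minus control, same decade)",
      "lower bound of the 95% empirical Monte-Carlo interval (fraction scale)",
      "upper bound of the 95% empirical Monte-Carlo interval (fraction scale)"),
    units = c("-", "-", "-", "-", "-", "-", "-", "deaths", "deaths", "deaths",
              "deaths", "deaths", "%", "percentage points", "%", "%")
  )
}
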