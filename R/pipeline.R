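# Pipeline orchestration: simulate -> map -> fit -> compare with a single
# config, deterministic seeding and stable CSV/JSON artifacts.

.trial_cols <- c("subject_id", "series_id", "ta_C", "pa_kPa", "wind",
                 "hr_bpm", "tre_C", "tsk_C", "sr_gph",
                 paste0("tsk_", c("head", "chest", "back", "arm", "thigh",
                                  "leg"), "_C"),
                 "aborted")

#' Write a trial table to CSV
#'
#' UTF-8 CSV with header row and '.' decimal separator; numeric fields are
#' written at full precision so a write/read round trip is lossless.
#'
#' @param trials Trial table (see \code{\link{generate_trials}}).
#' @param path Output file path.
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(.trial_cols, names(trials))
  if (length(missing_cols) > 0L)
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "))
  out <- trials[, .trial_cols]
  out$wind <- as.character(out$wind)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- vapply(out[[col]], function(x)
        if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE),
        character(1))
      out[[col]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Validates the documented schema: all columns present, numeric fields
#' numeric (an offending row index is reported otherwise), and wind levels
#' among ref/refwind/hi/hiwind (case-insensitive), normalized to the
#' factor levels ref/hi.
#'
#' @param path CSV file path.
#' @return Trial table data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  if (nrow(raw) == 0L) stop("empty trial table: ", path)
  missing_cols <- setdiff(.trial_cols, names(raw))
  if (length(missing_cols) > 0L)
    stop("trial CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(.trial_cols, c("subject_id", "series_id", "wind",
                                     "aborted"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric value in column '%s' at row %d: '%s'",
                   col, bad[1L], raw[[col]][bad[1L]]))
    raw[[col]] <- v
  }
  wind <- tolower(raw$wind)
  wind[wind == "refwind"] <- "ref"
  wind[wind == "hiwind"] <- "hi"
  unknown <- setdiff(unique(wind), c("ref", "hi"))
  if (length(unknown) > 0L)
    stop("unknown wind level token(s): ", paste(unknown, collapse = ", "))
  raw$wind <- factor(wind, levels = c("ref", "hi"))
  raw$aborted <- as.logical(toupper(raw$aborted))
  raw
}

#' Pipeline configuration
#'
#' Bundles the generator configuration, the psychrometric grid, the wind
#' pair, the GAM specification and the master seed. All stage seeds are
#' derived deterministically from the master seed.
#'
#' @param generator A \code{\link{generator_config}}.
#' @param spec A \code{\link{spline_spec}}.
#' @param v10_hi,v10_ref Wind pair for the UTCI field, m/s at 10 m.
#' @param grid_ta_range,grid_pa_range,grid_steps UTCI grid specification.
#' @param responses Responses to fit; default all four.
#' @param seed Master seed (mandatory for reproducibility).
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(generator = generator_config(),
                            spec = spline_spec(),
                            v10_hi = 3, v10_ref = 0.5,
                            grid_ta_range = c(25, 50),
                            grid_pa_range = c(0.1, 5),
                            grid_steps = c(0.5, 0.1),
                            responses = c("hr", "tre", "tsk", "sr"),
                            seed = 1L) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(spec, "spline_spec"), is.numeric(seed))
  responses <- match.arg(responses, c("hr", "tre", "tsk", "sr"),
                         several.ok = TRUE)
  structure(list(generator = generator, spec = spec, v10_hi = v10_hi,
                 v10_ref = v10_ref, grid_ta_range = grid_ta_range,
                 grid_pa_range = grid_pa_range, grid_steps = grid_steps,
                 responses = responses, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate a trial table; (2) map the UTCI wind-effect field
#' with its zero contour and percentile summary; (3) fit the strain GAM
#' and wind-effect difference surface per response; (4) compare the UTCI
#' and physiological wind effects. All tabular artifacts are CSV, scalar
#' summaries JSON. Re-running with the same config produces byte-identical
#' outputs.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Writable output directory (created if missing).
#' @return Invisibly, a manifest list: config hash, stage wall-clock
#'   seconds, and per-stage artifact paths. The manifest is also written
#'   to \code{manifest.json}.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L)
    stop("output directory is not writable: ", out_dir)
  paths <- list()
  times <- list()
  stage <- function(name, f) {
    t0 <- Sys.time()
    res <- tryCatch(f(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    times[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    res
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(.config_as_list(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  message("[heatwind ", cfg_hash, "] pipeline start, seed ", config$seed)

  trials <- stage("simulate", function() {
    tr <- generate_trials(config$generator, config$seed)
    write_trials(tr, file.path(out_dir, "trials.csv"))
    paths$trials <<- file.path(out_dir, "trials.csv")
    tr
  })

  field <- stage("map", function() {
    g <- build_grid(config$grid_ta_range, config$grid_pa_range,
                    config$grid_steps)
    fld <- delta_v_field(g, config$v10_hi, config$v10_ref)
    utils::write.csv(as.data.frame(fld),
                     file.path(out_dir, "utci_field.csv"), row.names = FALSE)
    ct <- zero_effect_contour(fld)
    utils::write.csv(as.data.frame(unclass(ct)),
                     file.path(out_dir, "utci_contour.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(percentile_summary(fld)),
                         file.path(out_dir, "utci_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    paths$field <<- file.path(out_dir, "utci_field.csv")
    paths$contour <<- file.path(out_dir, "utci_contour.csv")
    paths$field_summary <<- file.path(out_dir, "utci_summary.json")
    fld
  })

  surfaces <- stage("fit", function() {
    out <- list()
    for (r in config$responses) {
      m <- fit_strain_gam(trials, r, config$spec)
      s <- delta_surface(m, steps = config$grid_steps)
      fp <- file.path(out_dir, sprintf("delta_surface_%s.csv", r))
      utils::write.csv(as.data.frame(unclass(s))[
        , c("ta_C", "pa_kPa", "delta", "se", "p", "significant",
            "supported")], fp, row.names = FALSE)
      sj <- file.path(out_dir, sprintf("model_summary_%s.json", r))
      jsonlite::write_json(c(m$summary, list(
        n = m$n, edf = term_tests(m))), sj, auto_unbox = TRUE, digits = NA,
        dataframe = "rows")
      paths[[paste0("surface_", r)]] <<- fp
      paths[[paste0("model_", r)]] <<- sj
      out[[r]] <- s
    }
    out
  })

  comparison <- stage("compare", function() {
    cmp <- compare_effects(trials, surfaces, field)
    res <- lapply(cmp, function(x)
      c(x$spearman[c("r_s", "p", "n")], x$classification))
    jsonlite::write_json(res, file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    pr <- do.call(rbind, lapply(cmp, `[[`, "pairs"))
    utils::write.csv(pr, file.path(out_dir, "effect_pairs.csv"),
                     row.names = FALSE)
    paths$comparison <<- file.path(out_dir, "comparison.json")
    paths$pairs <<- file.path(out_dir, "effect_pairs.csv")
    cmp
  })

  manifest <- list(config_hash = cfg_hash,
                   heatwind_version =
                     as.character(utils::packageVersion("heatwind")),
                   r_version = as.character(getRversion()),
                   seed = config$seed, stage_seconds = times,
                   artifacts = paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("[heatwind ", cfg_hash, "] pipeline done (",
          length(paths), " artifacts)")
  invisible(manifest)
}

# plain-list view of a pipeline config for YAML serialization
.config_as_list <- function(config) {
  g <- unclass(config$generator)
  g <- lapply(g, function(x) if (is.numeric(x)) unname(x) else x)
  gnames <- lapply(config$generator, names)
  list(seed = config$seed,
       wind = list(v10_hi = config$v10_hi, v10_ref = config$v10_ref),
       grid = list(ta_range = config$grid_ta_range,
                   pa_range = config$grid_pa_range,
                   steps = config$grid_steps),
       responses = config$responses,
       gam = unclass(config$spec),
       generator = g,
       generator_names = Filter(Negate(is.null), gnames))
}
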