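#' Trace interchange CSV
#'
#' Traces are exchanged as plain-text CSV with a `# key=value` header block
#' (temperature_C, dilation_factor, cell_id, density_normalized, and any
#' scalar metadata) followed by `time_ms,current_pA` columns — or
#' `time_ms,current_pA_per_pF` for density-normalized traces, in which case
#' the flag is set on reading. Values are written with full double precision
#' so a write/read round trip is lossless.
#'
#' @param trace a [current_trace()].
#' @param path file path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a [current_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  if (!inherits(trace, "current_trace"))
    stop_field("trace", "must be a current_trace")
  fmt <- function(x) if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
  hdr <- c(sprintf("# temperature_C=%.17g", trace$temperature),
           sprintf("# dilation_factor=%.17g", trace$dilation_factor),
           sprintf("# cell_id=%s", trace$cell_id))
  scalars <- trace$meta[vapply(trace$meta, function(m)
    is.atomic(m) && length(m) == 1L, logical(1))]
  for (k in names(scalars))
    hdr <- c(hdr, sprintf("# %s=%s", k, fmt(scalars[[k]])))
  col <- if (trace$density_normalized) "current_pA_per_pF" else "current_pA"
  writeLines(c(hdr, paste0("time_ms,", col),
               sprintf("%.17g,%.17g", trace$times, trace$current)),
             path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  meta <- parse_hash_header(lines)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  cols <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  if (cols[1L] != "time_ms" ||
      !cols[2L] %in% c("current_pA", "current_pA_per_pF"))
    stop("expected columns time_ms and current_pA[_per_pF] in ", path,
         call. = FALSE)
  dat <- utils::read.csv(text = body)
  if (any(diff(dat$time_ms) <= 0))
    stop("non-monotone time column in ", path, call. = FALSE)
  core <- c("temperature_C", "dilation_factor", "cell_id")
  extra <- meta[setdiff(names(meta), core)]
  extra <- lapply(extra, function(v) utils::type.convert(v, as.is = TRUE))
  current_trace(dat$time_ms, dat[[cols[2L]]],
                temperature = as.numeric(meta$temperature_C),
                dilation_factor = as.numeric(meta$dilation_factor),
                cell_id = if (is.null(meta$cell_id)) "" else meta$cell_id,
                density_normalized = cols[2L] == "current_pA_per_pF",
                meta = extra)
}

# the full default run configuration; every load_config result is this
# structure with user values merged in
default_run_config <- function() {
  list(
    protocol = list(holding_potential = -80, peak_voltage = 40,
                    upstroke_duration = 2, plateau_voltage = 20,
                    apd90 = 300, repolarization_shape = "spline",
                    pre_hold = 100, post_hold = 100, sample_interval = 0.5),
    model = list(variant = "WT"),
    temperatures = c(22, 27, 32, 37),
    factors = c(0.5, 1, 1.5, 2, 3, 5),
    population = list(n_cells = 8, conductance_cv = 0.2,
                      artifacts = list(noise_sd = 0, leak_conductance = 0,
                                       leak_reversal = 0,
                                       contamination_amplitude = 0,
                                       contamination_onset_fraction = 0.7)),
    analysis = list(window = "full", blank_late_artifact = FALSE),
    stats = list(test = "wilcoxon", alpha = c(0.05, 0.01)),
    seed = 1,
    output_dir = "."
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills every omitted field with its documented
#' default (see `default_run_config` in the package sources) and validates
#' the result. Unknown keys are rejected, with the offending field path in
#' the error message. A minimal configuration may contain only `seed`.
#'
#' @param path YAML file path.
#' @return The validated configuration as a nested list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_run_config(), user, path = "")
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param config a configuration list (e.g. from [load_config()]).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_config <- function(defaults, user, path) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                        collapse = ", ")), call. = FALSE)
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(defaults[[k]], user[[k]], paste0(path, ".", k))
    else if (is.list(defaults[[k]]) && !is.list(user[[k]]))
      stop(sprintf("config key '%s' must be a mapping",
                   sub("^\\.", "", paste0(path, ".", k))), call. = FALSE)
    else user[[k]]
  }
  defaults
}

validate_config <- function(cfg) {
  if (!all(is.finite(unlist(cfg$factors))) || any(unlist(cfg$factors) <= 0))
    stop_field("factors", "must all be > 0")
  if (!all(unlist(cfg$temperatures) >= 15 & unlist(cfg$temperatures) <= 40))
    stop_field("temperatures", "must lie within [15, 40] degrees C")
  if (!cfg$model$variant %in% c("WT", "R328C", "D591H"))
    stop_field("model.variant", "must be one of WT, R328C, D591H")
  if (cfg$population$n_cells < 1)
    stop_field("population.n_cells", "must be >= 1")
  if (cfg$population$conductance_cv < 0)
    stop_field("population.conductance_cv", "must be >= 0")
  do.call(ap_shape_params, cfg$protocol)  # field-level validation
  invisible(cfg)
}

#' Analyze a set of traces into a results table
#'
#' Computes the repolarization power and time of peak for each trace,
#' returning one row per trace with its identifying metadata — the tabular
#' result written alongside figures in a typical run.
#'
#' @param traces a list of [current_trace()] objects, or a directory path
#'   containing trace CSVs (read with [read_trace_csv()]).
#' @param window_start,window_end optional integration window (default: full
#'   span of each trace).
#' @return A `data.frame` with columns `cell_id`, `temperature_C`,
#'   `dilation_factor`, `repower`, `time_of_peak`, `density_normalized`.
#' @export
analyze_traces <- function(traces, window_start = NULL, window_end = NULL) {
  if (is.character(traces) && length(traces) == 1L) {
    files <- list.files(traces, pattern = "\\.csv$", full.names = TRUE)
    files <- files[basename(files) != "manifest.csv"]
    traces <- lapply(files, read_trace_csv)
  }
  rows <- lapply(traces, function(tr) {
    rp <- repolarization_power(tr, window_start, window_end)
    data.frame(cell_id = tr$cell_id, temperature_C = tr$temperature,
               dilation_factor = tr$dilation_factor,
               repower = rp$value,
               time_of_peak = suppressWarnings(time_of_peak(tr)),
               density_normalized = tr$density_normalized)
  })
  do.call(rbind, rows)
}

#' Generate the packaged deterministic fixture set
#'
#' Simulates small trace sets spanning variants, temperatures and dilation
#' factors (defaults mirror the experimental design: WT/R328C/D591H at
#' 22/27/32/37 degrees C, factors 0.5--5, 8 cells per condition with 20%
#' conductance variability and mild recording artifacts), writes one CSV per
#' cell plus a `manifest.csv` index, and returns the manifest. Regeneration
#' with the same seed is bitwise identical.
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed integer master seed; per-condition seeds are derived from it.
#' @param variants,temperatures,factors,n_cells condition grid.
#' @param conductance_cv cell-to-cell conductance coefficient of variation.
#' @param artifacts an [artifact_params()] applied to every cell (per-cell
#'   seeds derived from the condition seed).
#' @return The manifest `data.frame` (columns `path`, `variant`,
#'   `temperature_C`, `factor`, `cell_id`, `seed`), invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L,
                          variants = c("WT", "R328C", "D591H"),
                          temperatures = c(22, 27, 32, 37),
                          factors = c(0.5, 1, 1.5, 2, 3, 5),
                          n_cells = 8, conductance_cv = 0.2,
                          artifacts = artifact_params(
                            noise_sd = 5, contamination_amplitude = 15)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base_protocol <- build_ap_waveform(ap_shape_params())
  wt <- default_wt_model()
  manifest <- list()
  for (iv in seq_along(variants)) {
    mv <- apply_variant(wt, hERG_variant(variants[iv]))
    for (it in seq_along(temperatures)) {
      mt <- scale_for_temperature(mv, temperatures[it])
      for (ifa in seq_along(factors)) {
        cond_seed <- as.integer(seed) * 10000L +
          iv * 1000L + it * 100L + ifa
        pop <- simulate_population(mt, dilate(base_protocol, factors[ifa]),
                                   n_cells = n_cells,
                                   conductance_cv = conductance_cv,
                                   artifacts = artifacts,
                                   rng_seed = cond_seed)
        for (k in seq_along(pop)) {
          fn <- sprintf("%s_T%g_f%g_cell%03d.csv",
                        variants[iv], temperatures[it], factors[ifa], k)
          write_trace_csv(pop[[k]], file.path(out_dir, fn))
          manifest[[length(manifest) + 1L]] <- data.frame(
            path = fn, variant = variants[iv],
            temperature_C = temperatures[it], factor = factors[ifa],
            cell_id = pop[[k]]$cell_id, seed = cond_seed)
        }
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
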