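# Plain-text interchange: traces as two-column CSV, a competition series
# as a directory of trace CSVs plus a JSON manifest, run configs as JSON.

#' Write/read a kinetic trace as CSV
#'
#' Columns `time_s`, `absorbance_490`. Metadata (scavenger concentration,
#' replicate, seed, control flag) travels in the series manifest, not in
#' the trace file.
#'
#' @param trace A `kinetic_trace`.
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `kinetic_trace` with metadata taken from arguments.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("time_s", "absorbance_490")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param nucleophile_conc,replicate,is_control,seed Metadata to attach to
#'   the trace read from `path`.
#' @export
read_trace <- function(path, nucleophile_conc = 0, replicate = 1L,
                       is_control = nucleophile_conc == 0, seed = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "absorbance_490") %in% names(d)))
    stop("trace CSV must have columns 'time_s' and 'absorbance_490'")
  if (any(diff(d$time_s) <= 0)) stop("trace times must be strictly increasing")
  new_kinetic_trace(d$time_s, d$absorbance_490,
                    list(nucleophile_conc = nucleophile_conc,
                         is_control = is_control,
                         replicate = as.integer(replicate), seed = seed,
                         compound = NA_character_))
}

#' Write/read a competition series as a directory of CSVs plus manifest
#'
#' The control and every inhibited trace are written as two-column CSVs;
#' `manifest.json` records conditions, optics, ground-truth rate constants,
#' the concentration grid, per-trace seeds and file names, so
#' `read_series()` can rebuild the series object exactly.
#'
#' @param series A `competition_series`.
#' @param dir Directory (created if missing).
#' @return `write_series` returns `dir` invisibly; `read_series` a
#'   `competition_series`.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trace(series$control, file.path(dir, "control.csv"))
  files <- character(length(series$inhibited))
  meta <- vector("list", length(series$inhibited))
  for (i in seq_along(series$inhibited)) {
    md <- attr(series$inhibited[[i]], "metadata")
    files[i] <- sprintf("trace_c%02d_r%02d.csv",
                        match(md$nucleophile_conc, series$nucleophile_concs),
                        md$replicate)
    write_trace(series$inhibited[[i]], file.path(dir, files[i]))
    meta[[i]] <- list(file = files[i], nucleophile_conc = md$nucleophile_conc,
                      replicate = md$replicate, seed = md$seed)
  }
  manifest <- list(
    schema = "hnokinetics/series-1",
    compound = series$compound,
    master_seed = series$seed,
    replicates = series$replicates,
    nucleophile_concs = series$nucleophile_concs,
    conditions = unclass(series$conditions),
    optics = unclass(series$optics),
    rates_true = unclass(series$rates_true),
    control = list(file = "control.csv",
                   seed = attr(series$control, "metadata")$seed),
    inhibited = meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_series
#' @export
read_series <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  conditions <- as_experiment_conditions(manifest$conditions)
  optics <- as_optics_model(manifest$optics)
  rates_true <- as_rate_constants(manifest$rates_true)
  compound <- if (is.null(manifest$compound)) NA_character_ else manifest$compound
  control <- read_trace(file.path(dir, manifest$control$file),
                        nucleophile_conc = 0, is_control = TRUE,
                        seed = manifest$control$seed)
  inh_meta <- manifest$inhibited
  inhibited <- lapply(seq_len(nrow(inh_meta)), function(i) {
    read_trace(file.path(dir, inh_meta$file[i]),
               nucleophile_conc = inh_meta$nucleophile_conc[i],
               replicate = inh_meta$replicate[i],
               is_control = FALSE, seed = inh_meta$seed[i])
  })
  structure(list(control = control, inhibited = inhibited,
                 conditions = conditions, optics = optics,
                 rates_true = rates_true,
                 nucleophile_concs = manifest$nucleophile_concs,
                 replicates = as.integer(manifest$replicates),
                 seed = manifest$master_seed, compound = compound),
            class = "competition_series")
}

#' Save/load a reproduction run configuration as JSON
#'
#' @param config A `run_config` from [run_config()].
#' @param path JSON file path.
#' @return `save_run_config` returns `path` invisibly; `load_run_config` a
#'   `run_config`.
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(conditions = as_experiment_conditions(raw$conditions),
             rates = as_rate_constants(raw$rates),
             optics = as_optics_model(raw$optics),
             conc_targets = raw$conc_targets,
             replicates = raw$replicates,
             noise_sd = raw$noise_sd,
             master_seed = raw$master_seed,
             compounds = if (!is.null(raw$compounds)) raw$compounds,
             output_dir = if (is.null(raw$output_dir) ||
                              length(raw$output_dir) == 0) NULL
             else raw$output_dir)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

# FNV-1a 32-bit hash of a character scalar, used to bind report files to
# the configuration that produced them (16-bit split keeps the modular
# multiplication exact in doubles)
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}
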