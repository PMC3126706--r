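# Recording and configuration I/O. Recordings are plain CSV (one 10 Hz
# pressure file and one 1 Hz flow file per arm) with a JSON metadata sidecar;
# configurations round-trip through YAML.

#' Write a recording to disk
#'
#' Writes `<prefix>_pressure.csv` (`time_s`, `p1_mmHg`, `p2_mmHg`),
#' `<prefix>_flow.csv` (`time_s`, `v_mps`) and `<prefix>_meta.json`.
#' Values round-trip through [read_recording()] exactly.
#'
#' @param rec an [simulate_experiment()] recording.
#' @param prefix path prefix (directories are created).
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "experiment_recording"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(rec$pressure, paste0(prefix, "_pressure.csv"))
  data.table::fwrite(rec$flow, paste0(prefix, "_flow.csv"))
  jsonlite::write_json(rec$meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

.read_csv_checked <- function(path, cols) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  d <- as.data.frame(data.table::fread(path))
  if (!identical(names(d), cols))
    stop(sprintf("malformed header in %s (expected %s)", path,
                 paste(cols, collapse = ", ")), call. = FALSE)
  bad <- which(diff(d$time_s) <= 0)
  if (length(bad))
    stop(sprintf("non-monotone time in %s at row %d", path, bad[1] + 1L),
         call. = FALSE)
  d
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix path prefix used at write time.
#' @return an `experiment_recording`.
#' @export
read_recording <- function(prefix) {
  meta_path <- paste0(prefix, "_meta.json")
  if (!file.exists(meta_path))
    stop("missing metadata sidecar: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pressure <- .read_csv_checked(paste0(prefix, "_pressure.csv"),
                                c("time_s", "p1_mmHg", "p2_mmHg"))
  flow <- .read_csv_checked(paste0(prefix, "_flow.csv"),
                            c("time_s", "v_mps"))
  n_p <- meta$duration * meta$pressure_rate_hz + 1L
  n_f <- meta$duration * meta$flow_rate_hz + 1L
  if (nrow(pressure) != n_p || nrow(flow) != n_f)
    stop("stream length inconsistent with metadata duration/rate",
         call. = FALSE)
  structure(list(pressure = pressure, flow = flow, meta = meta),
            class = "experiment_recording")
}

#' Default run configuration
#'
#' All tunables of the simulate/calibrate/analyze workflow in one
#' serialisable list: circuit, carrier, lysis kinetics per group, drug
#' schedule, sensor noise, study design and waveform pinning. Every default
#' traces to a printed study value or a documented emulation choice.
#'
#' @param seed master seed.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  circuit <- default_circuit()
  structure(list(
    circuit = unclass(circuit),
    carrier = unclass(default_carrier()),
    lysis = list(A = unclass(default_lysis_params("A")),
                 B = unclass(default_lysis_params("B"))),
    drug = unclass(drug_schedule()),
    noise = unclass(sensor_noise_model()),
    design = unclass(study_design(seed = seed)),
    waveform = list(v_diastolic = 0.29, v_systolic = 0.64, period = 0.9)
  ), class = "run_config")
}

# rebuild classed objects from a (possibly deserialised) run_config
.config_objects <- function(cfg) {
  drop_extra <- function(x, fn) do.call(fn, x[names(x) %in% names(formals(fn))])
  list(
    circuit = drop_extra(cfg$circuit, circuit_config),
    carrier = drop_extra(cfg$carrier, carrier_model),
    lysis = lapply(cfg$lysis, drop_extra, fn = lysis_params),
    schedule = drop_extra(cfg$drug, drug_schedule),
    noise = drop_extra(cfg$noise, sensor_noise_model),
    design = drop_extra(cfg$design, study_design),
    waveform = do.call(make_ica_waveform, cfg$waveform)
  )
}

#' Write / read a run configuration as YAML
#'
#' @param cfg a [default_run_config()]-style list.
#' @param path file path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(cfg, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.list(x)) lapply(x, identity) else x), path,
    precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("missing config: ", path, call. = FALSE)
  structure(yaml::read_yaml(path), class = "run_config")
}
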