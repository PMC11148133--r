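# File formats and configuration. Waveforms and simulation results travel as
# plain CSV (tiny volumes, diffable); configuration as YAML or JSON; reports
# as JSON. Every CLI run leaves a manifest sufficient to reproduce it.

#' Write a flow waveform to CSV
#'
#' Two mandatory columns, `time_s` and `flow_ml_s`, UTF-8, '.' decimal
#' separator, full double precision (17 significant digits) so that
#' `read_waveform_csv(write_waveform_csv(x))` is lossless.
#'
#' @param wf A [flow_waveform()] or a data frame / list with `times_s` and
#'   `flows_ml_s` (or `time_s` / `flow_ml_s`) elements.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wf, path) {
  if (inherits(wf, "flow_waveform")) {
    t <- wf$times_s
    q <- wf$flows_ml_s
  } else {
    t <- wf$times_s %||% wf$time_s
    q <- wf$flows_ml_s %||% wf$flow_ml_s
    if (is.null(t) || is.null(q)) stop("wf must carry times and flows")
  }
  lines <- c("time_s,flow_ml_s",
             paste(sprintf("%.17g", t), sprintf("%.17g", q), sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a flow waveform CSV
#'
#' Parses the two-column waveform format written by [write_waveform_csv()],
#' with descriptive errors (naming the offending line) for missing columns,
#' non-numeric cells and non-monotone time.
#'
#' @param path Input file path.
#' @param as_waveform Return a [flow_waveform()] (default) or, if `FALSE`, a
#'   bare list (useful for raw gated series whose grid need not start at 0).
#' @return A [flow_waveform()] or a list with `times_s`, `flows_ml_s`.
#' @export
read_waveform_csv <- function(path, as_waveform = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !nzchar(trimws(lines[1L]))) {
    stop("schema error in ", path, ": empty file or missing header")
  }
  header <- trimws(strsplit(lines[1L], ",", fixed = TRUE)[[1L]])
  need <- c("time_s", "flow_ml_s")
  if (!all(need %in% header)) {
    stop("schema error in ", path, ": header must contain columns ",
         paste(need, collapse = ", "))
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("schema error in ", path, ": no data rows")
  it <- match("time_s", header)
  iq <- match("flow_ml_s", header)
  t <- numeric(length(body))
  q <- numeric(length(body))
  for (i in seq_along(body)) {
    cells <- strsplit(body[i], ",", fixed = TRUE)[[1L]]
    if (length(cells) < length(header)) {
      stop(sprintf("parse error in %s, line %d: expected %d cells, found %d",
                   path, i + 1L, length(header), length(cells)))
    }
    ti <- suppressWarnings(as.numeric(cells[it]))
    qi <- suppressWarnings(as.numeric(cells[iq]))
    if (is.na(ti) || is.na(qi)) {
      stop(sprintf("parse error in %s, line %d: non-numeric cell", path, i + 1L))
    }
    t[i] <- ti
    q[i] <- qi
  }
  bad <- which(diff(t) <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("monotonicity error in %s, line %d: time does not increase",
                 path, bad[1L] + 2L))
  }
  if (as_waveform && abs(t[1L]) < 1e-12) {
    flow_waveform(t, q)
  } else {
    list(times_s = t, flows_ml_s = q)
  }
}

#' Full default run configuration
#'
#' A nested list with every configurable quantity of the pipeline at its
#' default. Printed physiological constants keep their published values
#' (outlet resistances and compliances, fluid properties, cough parameters,
#' obstruction presets); geometry entries are configuration values.
#'
#' @return Nested named list (sections: `geometry`, `fluid`, `outlets`,
#'   `calibration`, `cough`, `obstruction`, `simulation`, `coupling`).
#' @export
default_run_config <- function() {
  list(
    geometry = list(A_lv_m2 = 5.85e-4, V_basilar_m3 = 1e-5,
                    V_spinal_m3 = 5.575625e-6, A_canal_m2 = 1.5e-4),
    fluid = list(rho_kg_m3 = 998.2, mu_kg_ms = 0.001003),
    outlets = list(
      interstitium = list(kind = "windkessel2", R = 7500, C = 0.0988, P_ext = 0),
      spinal = list(kind = "windkessel2", R = 7500, C = 0.1977, P_ext = 0),
      lymphatic = list(kind = "resistive", R = 5000, C = 0, P_ext = 0),
      arachnoid_villi = list(kind = "resistive", R = 5000, C = 0, P_ext = 0)
    ),
    calibration = list(P_mean_mmHg = 10, dP_pp_mmHg = 4, tol_pp_mmHg = 0.01,
                       compliance_split = c(1, 2)),
    cough = list(A_kg_m3_s = 2356.30, sigma_s = 0.1, mu_p_s = 1.88,
                 mu_n_s = 2.13),
    obstruction = list(case = "control", R_open = 0.05,
                       posterior_area_fraction = 0.75),
    simulation = list(duration_s = 4, dt_s = 0.01, dt_cough_s = 0.001,
                      cough_window_s = c(1.5, 2.5), solver = "monolithic"),
    coupling = list(jacobian_iters = 4, residual_factor = 1e-3,
                    max_coupling_iters = 50)
  )
}

# merge user values over defaults, rejecting unknown keys and recording
# which leaves were user-set
.merge_config <- function(defaults, user, path = character()) {
  prov <- list()
  out <- defaults
  if (is.null(user)) return(list(value = out, provenance = prov))
  if (!is.list(user)) stop("config section '", paste(path, collapse = "."),
                           "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ",
         paste(vapply(unknown, function(u) paste(c(path, u), collapse = "."),
                      character(1)), collapse = ", "))
  }
  for (k in names(user)) {
    here <- c(path, k)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      sub <- .merge_config(defaults[[k]], user[[k]], here)
      out[[k]] <- sub$value
      prov <- c(prov, sub$provenance)
    } else {
      out[[k]] <- user[[k]]
      prov[[paste(here, collapse = ".")]] <- "user"
    }
  }
  list(value = out, provenance = prov)
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration, applies defaults for everything not
#' set, rejects unknown keys, validates ranges by constructing the typed
#' objects, and records per-field provenance (user-set vs default).
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for the full
#'   default configuration.
#' @return A list of class `run_config` with constructed objects (`geometry`,
#'   `fluid`, `outlets`, `calibration`, `cough_spec`, `obstruction`,
#'   `simulation`, `coupling`), the raw merged `values`, and `provenance`.
#' @export
load_run_config <- function(path = NULL) {
  user <- if (is.null(path)) {
    list()
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merged <- .merge_config(default_run_config(), user)
  v <- merged$value
  known_cases <- c("control", "OBS-1", "OBS-2", "OBS-3", "custom")
  if (!v$obstruction$case %in% known_cases) {
    stop("obstruction case must be one of: ", paste(known_cases, collapse = ", "))
  }
  geom <- geometry_config(v$geometry$A_lv_m2, v$geometry$V_basilar_m3,
                          v$geometry$V_spinal_m3, v$geometry$A_canal_m2)
  fluid <- fluid_properties(v$fluid$rho_kg_m3, v$fluid$mu_kg_ms)
  outlets <- lapply(names(v$outlets), function(nm) {
    o <- v$outlets[[nm]]
    outlet_spec(nm, o$kind, R = o$R, C = o$C, P_ext = o$P_ext)
  })
  names(outlets) <- names(v$outlets)
  target <- calibration_target(v$calibration$P_mean_mmHg,
                               v$calibration$dP_pp_mmHg,
                               v$calibration$tol_pp_mmHg,
                               as.numeric(v$calibration$compliance_split))
  cough <- cough_spec(v$cough$A_kg_m3_s, v$cough$sigma_s, v$cough$mu_p_s,
                      v$cough$mu_n_s, V_spinal_m3 = geom$V_spinal_m3,
                      rho_kg_m3 = fluid$rho_kg_m3)
  case <- if (v$obstruction$case == "custom") {
    obstruction_case("custom",
                     R_v_anterior_m2 = v$obstruction$R_v_anterior_m2,
                     R_v_posterior_m2 = v$obstruction$R_v_posterior_m2,
                     posterior_area_fraction = v$obstruction$posterior_area_fraction)
  } else {
    obstruction_case(v$obstruction$case,
                     posterior_area_fraction = v$obstruction$posterior_area_fraction)
  }
  if (!is.finite(v$obstruction$R_open) || v$obstruction$R_open < 0) {
    stop("obstruction R_open must be non-negative")
  }
  sim <- simulation_config(v$simulation$duration_s, v$simulation$dt_s,
                           v$simulation$dt_cough_s,
                           as.numeric(v$simulation$cough_window_s),
                           v$simulation$solver)
  coup <- coupling_config(jacobian_iters = v$coupling$jacobian_iters,
                          residual_factor = v$coupling$residual_factor,
                          max_coupling_iters = v$coupling$max_coupling_iters)
  structure(
    list(geometry = geom, fluid = fluid, outlets = outlets,
         calibration = target, cough_spec = cough, obstruction = case,
         R_open = v$obstruction$R_open, simulation = sim, coupling = coup,
         values = v, provenance = merged$provenance),
    class = "run_config"
  )
}

#' Write a reproducibility manifest
#'
#' Records what a CLI run needs to be reproduced bit-identically in
#' deterministic modes: package version, the configuration values (with a
#' canonical hash), the seed, and the output files written.
#'
#' @param path Manifest output path (JSON).
#' @param config_values The merged configuration value list (or `NULL`).
#' @param seed Seed used (or `NULL`).
#' @param outputs Character vector of files written by the run.
#' @param extra Optional named list of additional entries.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config_values = NULL, seed = NULL,
                               outputs = character(), extra = list()) {
  cfg_json <- jsonlite::toJSON(config_values, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- c(list(
    package = "csfdyn",
    version = as.character(utils::packageVersion("csfdyn")),
    seed = seed,
    config_hash = hash,
    config = config_values,
    outputs = outputs
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a simulation result to CSV
#'
#' Times plus named pressure/flow columns, full precision.
#'
#' @param sim A `csf_simulation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(sim, path) {
  df <- as.data.frame(sim)
  utils::write.csv(format(df, digits = 17, scientific = NA, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation-result CSV
#'
#' @param path Path written by [write_simulation_csv()].
#' @return A data frame with the result columns.
#' @export
read_simulation_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "P_IC_mmHg", "P_SP_mmHg", "Q_FM_ml_s")
  if (!all(need %in% names(df))) {
    stop("schema error in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  }
  df
}
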