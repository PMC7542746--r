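#' Write a cell's sweep sets to the delimited sweep format
#'
#' The pipeline's on-disk sweep dialect is human-auditable delimited text:
#' a header block (cell id, group, sampling rate, an explicit units
#' declaration), then one `protocol:` section per protocol, each sweep
#' introduced by a `sweep:` line carrying its step descriptor and followed
#' by interleaved time/voltage sample lines. Numbers are written with 17
#' significant digits so a write/read round trip is bit-exact.
#'
#' @param cell A cell record: list with `cell_id`, `group`, `protocols`
#'   (named list of [step_protocol()] objects and/or single [sweep()]s, as
#'   produced by [generate_cell_population()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(cell, path) {
  con <- file(path, "w")
  on.exit(close(con))
  all_sweeps <- unlist(lapply(cell$protocols, function(p) {
    if (inherits(p, "step_protocol")) p$sweeps else list(p)
  }), recursive = FALSE)
  rate <- all_sweeps[[1]]$sampling_rate
  writeLines(c("# okrephys sweep file v1",
               paste0("cell_id: ", cell$cell_id),
               paste0("group_label: ", cell$group),
               sprintf("sampling_rate_hz: %.17g", rate),
               "units: time=s voltage=mV current=pA"), con)
  for (pk in names(cell$protocols)) {
    p <- cell$protocols[[pk]]
    sweeps <- if (inherits(p, "step_protocol")) p$sweeps else list(p)
    writeLines(sprintf("protocol: %s", pk), con)
    for (sw in sweeps) {
      writeLines(sprintf("sweep: amplitude_pa=%.17g baseline_pa=%.17g onset_s=%.17g offset_s=%.17g n_samples=%d",
                         sw$step$amplitude, sw$step$baseline, sw$step$onset,
                         sw$step$offset, length(sw$time)), con)
      writeLines(sprintf("%.17g\t%.17g", sw$time, sw$voltage), con)
    }
  }
  invisible(path)
}

parse_kv_line <- function(line, prefix) {
  body <- sub(paste0("^", prefix, ":\\s*"), "", line)
  parts <- strsplit(trimws(body), "\\s+")[[1]]
  kv <- strsplit(parts, "=")
  vals <- vapply(kv, `[`, character(1), 2)
  names(vals) <- vapply(kv, `[`, character(1), 1)
  vals
}

#' Read a delimited sweep file into validated protocols
#'
#' Parses the dialect written by [write_sweeps()]. The units declaration is
#' mandatory and must state voltage in mV and current in pA; time may be
#' declared in s or ms (ms is converted on read). Malformed sweep sections
#' are skipped with a per-sweep diagnostic (collected in the `diagnostics`
#' attribute and raised as warnings), never silently; an undeclared units
#' line or an inconsistent sampling rate rejects the file.
#'
#' @param path File path.
#' @param format Only `"delimited"` is supported. Axon Binary Format files
#'   are not parsed by this build; convert such recordings to the delimited
#'   dialect first.
#' @return A cell record (list with `cell_id`, `group`, `protocols`) whose
#'   multi-sweep sections are [step_protocol()]s and single-sweep sections
#'   plain [sweep()]s; `diagnostics` attribute lists skipped sweeps.
#' @export
read_sweeps <- function(path, format = c("delimited", "abf")) {
  format <- match.arg(format)
  if (format == "abf") {
    stop("Axon Binary Format ingestion is not available in this build; ",
         "export the recording to the delimited sweep dialect (see write_sweeps)",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^", key, ":"), "", ln[1]))
  }
  units <- get_field("units")
  if (is.null(units)) stop("sweep file rejected: no units declaration", call. = FALSE)
  u <- parse_kv_line(paste0("units: ", units), "units")
  if (!identical(unname(u["voltage"]), "mV") || !identical(unname(u["current"]), "pA") ||
      !(u["time"] %in% c("s", "ms"))) {
    stop("sweep file rejected: units must declare time=s|ms voltage=mV current=pA",
         call. = FALSE)
  }
  t_scale <- if (u[["time"]] == "ms") 1e-3 else 1
  rate <- as.numeric(get_field("sampling_rate_hz"))
  if (!length(rate) || is.na(rate)) {
    stop("sweep file rejected: missing sampling_rate_hz", call. = FALSE)
  }
  cell_id <- get_field("cell_id")
  group <- get_field("group_label")

  proto_idx <- grep("^protocol:", lines)
  sweep_idx <- grep("^sweep:", lines)
  diagnostics <- character(0)
  protocols <- list()
  for (pi in seq_along(proto_idx)) {
    p_start <- proto_idx[pi]
    p_end <- if (pi < length(proto_idx)) proto_idx[pi + 1] - 1 else length(lines)
    pname <- trimws(sub("^protocol:", "", lines[p_start]))
    s_in <- sweep_idx[sweep_idx > p_start & sweep_idx <= p_end]
    sweeps <- list()
    for (si in seq_along(s_in)) {
      s_start <- s_in[si]
      s_end <- if (si < length(s_in)) s_in[si + 1] - 1 else p_end
      hdr <- tryCatch(parse_kv_line(lines[s_start], "sweep"),
                      error = function(e) NULL)
      block <- lines[(s_start + 1):s_end]
      block <- block[nzchar(block)]
      smp <- suppressWarnings(as.numeric(unlist(strsplit(block, "\t", fixed = TRUE))))
      ok <- !is.null(hdr) &&
        all(c("amplitude_pa", "baseline_pa", "onset_s", "offset_s", "n_samples") %in% names(hdr)) &&
        !anyNA(smp) && length(smp) == 2 * as.integer(hdr["n_samples"])
      if (!ok) {
        diagnostics <- c(diagnostics,
                         sprintf("%s: sweep %d of protocol '%s' malformed; skipped",
                                 basename(path), si, pname))
        next
      }
      m <- matrix(smp, ncol = 2, byrow = TRUE)
      sw <- tryCatch(
        sweep(time = m[, 1] * t_scale, voltage = m[, 2],
              step = list(baseline = as.numeric(hdr["baseline_pa"]),
                          amplitude = as.numeric(hdr["amplitude_pa"]),
                          onset = as.numeric(hdr["onset_s"]) * t_scale,
                          offset = as.numeric(hdr["offset_s"]) * t_scale),
              sampling_rate = rate),
        error = function(e) {
          diagnostics <<- c(diagnostics,
                            sprintf("%s: sweep %d of protocol '%s' invalid (%s); skipped",
                                    basename(path), si, pname, conditionMessage(e)))
          NULL
        })
      if (!is.null(sw)) {
        if (abs(sw$sampling_rate - 1 / diff(sw$time[1:2])) > 1e-3 * sw$sampling_rate) {
          stop("sweep file rejected: sample spacing inconsistent with declared sampling rate",
               call. = FALSE)
        }
        sweeps[[length(sweeps) + 1]] <- sw
      }
    }
    if (!length(sweeps)) next
    protocols[[pname]] <- if (length(sweeps) > 1) step_protocol(sweeps, kind = pname)
                          else sweeps[[1]]
  }
  for (d in diagnostics) warning(d, call. = FALSE)
  cell <- list(cell_id = cell_id, group = group, protocols = protocols)
  attr(cell, "diagnostics") <- diagnostics
  cell
}

#' Write / read an oculography record as delimited text
#'
#' Three tab-separated columns (time s, screen deg, eye deg) preceded by
#' commented header lines carrying the sampling rate, stimulus frequency and
#' labels.
#'
#' @param record An [eye_record()].
#' @param path File path.
#' @return `path` ([write_eye_record()]) or an [eye_record()]
#'   ([read_eye_record()]).
#' @export
write_eye_record <- function(record, path) {
  stopifnot(inherits(record, "eye_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# okrephys eye record v1",
               sprintf("# sampling_rate_hz: %.17g", record$sampling_rate),
               sprintf("# stimulus_frequency_hz: %.17g", record$stimulus_frequency),
               sprintf("# animal_id: %s", record$animal_id),
               sprintf("# session_label: %s", record$session_label),
               "# columns: time_s\tscreen_deg\teye_deg"), con)
  writeLines(sprintf("%.17g\t%.17g\t%.17g", record$time, record$screen_position,
                     record$eye_position), con)
  invisible(path)
}

#' @rdname write_eye_record
#' @export
read_eye_record <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  get_h <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  vals <- suppressWarnings(as.numeric(unlist(strsplit(body, "\t", fixed = TRUE))))
  if (anyNA(vals) || length(vals) %% 3 != 0) {
    stop("malformed eye record: expected three numeric columns", call. = FALSE)
  }
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  eye_record(time = m[, 1], screen_position = m[, 2], eye_position = m[, 3],
             sampling_rate = as.numeric(get_h("sampling_rate_hz")),
             stimulus_frequency = as.numeric(get_h("stimulus_frequency_hz")),
             animal_id = get_h("animal_id"),
             session_label = get_h("session_label"))
}

#' Pipeline run configuration
#'
#' Every tunable knob of the end-to-end pipeline with its documented
#' default; unknown keys are rejected. `features` nests a
#' [feature_config()].
#'
#' @param seed Master seed of the run.
#' @param out_dir Output directory for the report bundle.
#' @param n_control,n_learned Simulated cells per group.
#' @param learned_shift Named offsets of the learned group's mean neuron
#'   parameters.
#' @param nonregular_fraction Bursting-phenotype fraction.
#' @param noise_sd Membrane noise SD, mV.
#' @param hyper_amplitude Hyperpolarizing step, pA.
#' @param okr Run the oculography arm.
#' @param n_animals,gain_pre,gain_increase OKR cohort design.
#' @param stimulus_amplitude Screen peak amplitude, degrees.
#' @param velocity_threshold,pad Desaccading knobs (deg/s, ms).
#' @param contrasts Compute per-step mixed-model contrasts.
#' @param write_sweep_files Serialize every simulated sweep set (large).
#' @param features A [feature_config()].
#' @return A classed list of knobs.
#' @export
run_config <- function(seed = 1, out_dir = "okrephys_run",
                       n_control = 8, n_learned = 8,
                       learned_shift = c(soft_threshold = 4),
                       nonregular_fraction = 0.2, noise_sd = 0.8,
                       hyper_amplitude = -200,
                       okr = TRUE, n_animals = 6, gain_pre = 0.5,
                       gain_increase = 0.2, stimulus_amplitude = 5,
                       velocity_threshold = 50, pad = 50,
                       contrasts = TRUE, write_sweep_files = FALSE,
                       features = feature_config()) {
  cfg <- as.list(environment())
  if (!inherits(cfg$features, "feature_config")) {
    cfg$features <- do.call(feature_config, as.list(cfg$features))
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file keep their [run_config()] defaults; unknown
#' keys are rejected with an error naming them.
#'
#' @param path YAML file path.
#' @param overrides Named list applied on top of the file (e.g. CLI flags).
#' @return A [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  raw[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$features)) {
    fknown <- names(formals(feature_config))
    funk <- setdiff(names(raw$features), fknown)
    if (length(funk)) {
      stop("unknown feature configuration keys: ", paste(funk, collapse = ", "),
           call. = FALSE)
    }
    raw$features <- do.call(feature_config, raw$features)
  }
  if (!is.null(raw$learned_shift)) raw$learned_shift <- unlist(raw$learned_shift)
  do.call(run_config, raw)
}

config_fingerprint <- function(config) {
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  txt <- yaml::as.yaml(plain)
  tf <- tempfile()
  writeLines(txt, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

stats_report_lines <- function(summary, okr_cmp = NULL) {
  fmt <- function(s) {
    stat_name <- if (grepl("mixed|likelihood", tolower(s$test_label))) "chi^2" else "t"
    sprintf("%s = %.4g, df = %.4g, p = %.4g, %s", stat_name, s$statistic, s$df,
            s$p_value, s$test_label)
  }
  out <- c("okrephys group-statistics report",
           sprintf("included regular-spiking cells: %s",
                   paste(sprintf("%s = %d", names(summary$included_n),
                                 as.integer(summary$included_n)), collapse = ", ")),
           sprintf("excluded cells: %d", nrow(summary$exclusions)))
  for (nm in names(summary$tests)) {
    out <- c(out, sprintf("%-17s %s", nm, fmt(summary$tests[[nm]])))
  }
  if (!is.null(summary$fi)) {
    out <- c(out, sprintf("%-17s %s", "fi_curve", fmt(summary$fi$test)),
             sprintf("  contrast adjustment: %s", summary$fi$adjust_method))
  }
  if (!is.null(okr_cmp)) {
    out <- c(out, sprintf("%-17s %s", "okr_gain", fmt(okr_cmp$test)))
  }
  out
}

stat_table <- function(summary, okr_cmp = NULL) {
  rows <- lapply(names(summary$tests), function(nm) {
    s <- summary$tests[[nm]]
    data.frame(comparison = nm, statistic = s$statistic, df = s$df,
               p_value = s$p_value, test = s$test_label)
  })
  if (!is.null(summary$fi)) {
    s <- summary$fi$test
    rows <- c(rows, list(data.frame(comparison = "fi_curve", statistic = s$statistic,
                                    df = s$df, p_value = s$p_value, test = s$test_label)))
  }
  if (!is.null(okr_cmp)) {
    s <- okr_cmp$test
    rows <- c(rows, list(data.frame(comparison = "okr_gain", statistic = s$statistic,
                                    df = s$df, p_value = s$p_value, test = s$test_label)))
  }
  do.call(rbind, rows)
}

#' Run the end-to-end pipeline
#'
#' Executes simulate -> extract -> OKR gain -> group statistics -> report.
#' Every stage failure halts the run naming the stage. The report bundle
#' written to `config$out_dir` contains the resolved configuration, a
#' manifest (seed, configuration fingerprint, ground-truth summary), the
#' per-cell feature table, the long F-I table, the per-session gain table,
#' the exclusion table and the statistics report (delimited and
#' human-readable); a rerun with the same configuration and seed reproduces
#' it byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the population, extracted results, group
#'   summary, gain table, OKR comparison and output paths.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- config_fingerprint(config)

  pop <- stage("simulate", generate_cell_population(
    control_params = neuron_params(noise_sd = config$noise_sd),
    learned_shift = config$learned_shift,
    n_control = config$n_control, n_learned = config$n_learned,
    nonregular_fraction = config$nonregular_fraction,
    hyper_amplitude = config$hyper_amplitude,
    seed = config$seed))

  res <- stage("extract", extract_features(pop, config$features))
  ftab <- stage("extract", feature_table(res))
  fi_tab <- stage("extract", fi_long_table(res, regular_only = FALSE))

  gain_tab <- NULL
  okr_cmp <- NULL
  if (isTRUE(config$okr)) {
    cohort <- stage("okr-gain", generate_okr_cohort(
      n_animals = config$n_animals, gain_pre = config$gain_pre,
      gain_increase = config$gain_increase,
      base_params = eye_sim_params(stimulus_amplitude = config$stimulus_amplitude),
      seed = config$seed + 1L))
    gains <- stage("okr-gain", lapply(cohort, analyze_eye_record,
                                      velocity_threshold = config$velocity_threshold,
                                      pad = config$pad))
    gain_tab <- data.frame(
      animal_id = vapply(gains, `[[`, character(1), "animal_id"),
      session_label = vapply(gains, `[[`, character(1), "session_label"),
      gain = vapply(gains, `[[`, numeric(1), "gain"),
      phase_lead = vapply(gains, `[[`, numeric(1), "phase_lead"))
    okr_cmp <- stage("okr-gain", compare_learning(gain_tab))
  }

  summ <- stage("group-stats",
                summarize_groups(res, contrasts = config$contrasts))

  paths <- list(
    config = file.path(config$out_dir, "config.yaml"),
    manifest = file.path(config$out_dir, "manifest.yaml"),
    features = file.path(config$out_dir, "features.csv"),
    fi = file.path(config$out_dir, "fi_long.csv"),
    gains = file.path(config$out_dir, "gains.csv"),
    exclusions = file.path(config$out_dir, "exclusions.csv"),
    stats_csv = file.path(config$out_dir, "stats.csv"),
    stats_txt = file.path(config$out_dir, "stats_report.txt"))

  stage("report", {
    plain <- rapply(unclass(config), function(x) x, how = "replace")
    writeLines(yaml::as.yaml(plain), paths$config)
    utils::write.csv(ftab, paths$features, row.names = FALSE)
    utils::write.csv(fi_tab, paths$fi, row.names = FALSE)
    if (!is.null(gain_tab)) utils::write.csv(gain_tab, paths$gains, row.names = FALSE)
    excl <- summ$exclusions
    utils::write.csv(excl, paths$exclusions, row.names = FALSE)
    utils::write.csv(stat_table(summ, okr_cmp), paths$stats_csv, row.names = FALSE)
    writeLines(stats_report_lines(summ, okr_cmp), paths$stats_txt)
    manifest <- list(
      pipeline = "okrephys",
      seed = config$seed,
      config_md5 = fp,
      n_cells = nrow(pop$manifest),
      n_excluded = nrow(excl),
      groups = as.list(table(pop$manifest$group)),
      ground_truth = list(
        learned_shift = as.list(config$learned_shift),
        nonregular_fraction = config$nonregular_fraction),
      outputs = lapply(paths[setdiff(names(paths), "manifest")], basename))
    writeLines(yaml::as.yaml(manifest), paths$manifest)
    if (isTRUE(config$write_sweep_files)) {
      sd <- file.path(config$out_dir, "sweeps")
      dir.create(sd, showWarnings = FALSE)
      for (cell in pop$cells) {
        write_sweeps(cell, file.path(sd, paste0(cell$cell_id, ".sweeps.txt")))
      }
    }
  })
  invisible(list(population = pop, results = res, summary = summ,
                 gain_table = gain_tab, okr = okr_cmp, paths = paths,
                 config = config))
}
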