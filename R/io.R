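#' Read a tidy trace table
#'
#' Reads a delimited text table with header columns `time_s`, `value` and
#' optional `voxel_id` / `trial_id`, validates each (voxel, trial) series
#' (strictly increasing times, uniform sampling), and returns one
#' [gevi_trace()] per series.
#'
#' @param path File path (TSV or CSV; delimiter is auto-detected).
#' @param value_kind `"counts"` or `"dff"`.
#' @param frame_rate Optional frame rate override (Hz).
#' @return List of [gevi_trace()] objects.
#' @export
read_trace_table <- function(path, value_kind = c("counts", "dff"),
                             frame_rate = NULL) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  need <- c("time_s", "value")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0) {
    stop("missing header column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"voxel_id" %in% names(dt)) dt$voxel_id <- "v1"
  if (!"trial_id" %in% names(dt)) dt$trial_id <- "t1"
  if (any(!is.finite(dt$value))) {
    stop("non-finite value at row ", which(!is.finite(dt$value))[1])
  }
  groups <- split(as.data.frame(dt), list(dt$voxel_id, dt$trial_id),
                  drop = TRUE)
  traces <- lapply(groups, function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    dtt <- diff(g$time_s)
    if (any(dtt == 0)) {
      stop("duplicated timestamp in series (voxel ", g$voxel_id[1],
           ", trial ", g$trial_id[1], ") at time_s = ",
           g$time_s[which(dtt == 0)[1]])
    }
    period <- stats::median(dtt)
    if (max(abs(dtt - period)) > 0.01 * period) {
      stop("non-uniform sampling in series (voxel ", g$voxel_id[1],
           ", trial ", g$trial_id[1], "): interval jitter exceeds 1%")
    }
    gevi_trace(g$time_s, g$value, kind = value_kind,
               frame_rate = frame_rate, voxel_id = g$voxel_id[1],
               trial_id = g$trial_id[1])
  })
  unname(traces)
}

#' Write traces as a tidy table with a sidecar metadata record
#'
#' @param traces A [gevi_trace()], a list of them, or a `gevi_experiment`.
#' @param path Output path; delimiter chosen by extension (`.csv` comma,
#'   otherwise tab).
#' @param metadata Optional named list merged into the sidecar JSON
#'   (written to `paste0(path, ".json")`): the sidecar always records the
#'   value kind, frame rate, any schedule/seed attributes, and a
#'   content hash of the table.
#' @return Invisibly, the sidecar metadata list.
#' @export
write_trace_table <- function(traces, path, metadata = list()) {
  if (inherits(traces, "gevi_trace")) traces <- list(traces)
  tab <- do.call(rbind, lapply(unclass(traces), as.data.frame))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(tab, path, sep = sep)
  first <- traces[[1]]
  meta <- c(list(value_kind = first$kind, frame_rate = first$frame_rate,
                 n_traces = length(traces),
                 table_md5 = unname(tools::md5sum(path))),
            metadata)
  sched <- attr(first, "schedule")
  if (!is.null(sched)) meta$schedule <- unclass(sched)
  seed <- attr(first, "seed")
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(meta)
}

# Canonical md5 hash of a config list (via its serialized JSON).
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run an analysis pipeline from a declarative config
#'
#' Dispatches on `config$subcommand`:
#' \describe{
#'   \item{`simulate`}{Forward-simulate an experiment (indicator preset,
#'     AP waveform, geometry, schedule, optional bleach) and write a tidy
#'     trace table plus sidecar metadata.}
#'   \item{`dff`}{Read a counts table, compute dF/F per trace, write the
#'     dF/F table.}
#'   \item{`dprime`}{Read a counts table with a spike time and report
#'     per-trace d' as JSON.}
#'   \item{`roc`}{Run the ROC simulation at a given d' and report
#'     empirical and analytic rates as JSON.}
#'   \item{`roi`}{Read a dF/F table, compute stimulus-locked averages,
#'     the responding criterion and phase metrics per ROI, write JSON.}
#' }
#' Every run writes a provenance record (package version, seed, config
#' hash, timestamp) alongside its outputs. Given the same inputs, config
#' and seed, outputs are byte-identical apart from the timestamp, which can
#' be disabled with `config$timestamp = FALSE`.
#'
#' @param config Named list, or path to a JSON config file.
#' @return Invisibly, a list of result objects; side effect: files under
#'   `config$out` (a directory, created if needed).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$subcommand)) stop("config must name a subcommand")
  sub <- config$subcommand
  known <- c("simulate", "dff", "dprime", "roc", "roi")
  if (!sub %in% known) {
    stop("unknown subcommand '", sub, "' (expected one of: ",
         paste(known, collapse = ", "), ")")
  }
  out_dir <- if (is.null(config$out)) "." else config$out
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  result <- switch(sub,
    simulate = {
      kin <- indicator_preset(if (is.null(config$indicator)) "ASAP2s"
                              else config$indicator)
      wf <- make_ap_waveform(
        fwhm = config$fwhm_ms %||% 4.0,
        peak_amplitude = config$peak_amplitude_mv %||% 100,
        rest = kin$holding_potential,
        duration = config$duration_ms %||% 400)
      sch <- scan_schedule(config$n_voxels %||% 20L)
      geom <- if (!is.null(config$geometry)) {
        cell_geometry(as.data.frame(config$geometry),
                      config$conduction_velocity %||% 0.16)
      } else {
        cell_geometry(data.frame(voxel_id = "soma", distance_um = 0,
                                 rest_rate = config$rest_rate %||% 30,
                                 attenuation = 1))
      }
      bleach <- if (!is.null(config$bleach)) {
        bleach_model(config$bleach$weights, config$bleach$taus)
      }
      exper <- simulate_experiment(
        kin, wf, geom, sch, bleach = bleach,
        n_trials = config$n_trials %||% 1L, seed = seed,
        events = data.frame(kind = "spike_trigger",
                            time = (config$duration_ms %||% 400) / 2000))
      write_trace_table(exper, file.path(out_dir, "traces.tsv"),
                        metadata = list(indicator = kin$name, seed = seed,
                                        config_hash = config_hash(config)))
      exper
    },
    dff = {
      traces <- read_trace_table(config$input, value_kind = "counts")
      trig <- config$trigger_s %||% stop("dff subcommand needs trigger_s")
      dffs <- lapply(traces, compute_dff, trigger = trig)
      write_trace_table(dffs, file.path(out_dir, "dff.tsv"),
                        metadata = list(trigger_s = trig,
                                        config_hash = config_hash(config)))
      dffs
    },
    dprime = {
      traces <- read_trace_table(config$input, value_kind = "counts")
      spike <- config$spike_time_s %||% stop("dprime needs spike_time_s")
      reports <- lapply(traces, function(tr) {
        r <- dprime_single(tr, spike_time = spike)
        c(list(voxel_id = tr$voxel_id, trial_id = tr$trial_id), r)
      })
      jsonlite::write_json(reports, file.path(out_dir, "dprime.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      reports
    },
    roc = {
      dp <- config$dprime %||% stop("roc needs a dprime value")
      emp <- roc_simulate(dp, n_samples = config$n_samples %||% 1e6,
                          spike_period = config$spike_period %||% 10,
                          seed = seed)
      ana <- roc_analytic(dp, spike_fraction =
                            1 / (config$spike_period %||% 10))
      rep <- list(dprime = dp,
                  empirical = emp[c("tp_rate", "fp_rate", "threshold_f")],
                  analytic = ana[c("tp_rate", "fp_rate", "threshold_f")])
      jsonlite::write_json(rep, file.path(out_dir, "roc.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      rep
    },
    roi = {
      traces <- read_trace_table(config$input, value_kind = "dff")
      proto <- stimulus_protocol(
        flash_duration_ms = config$flash_duration_ms %||% 300,
        frame_rate = config$frame_rate %||% 38.9,
        first_transition_s = config$first_transition_s %||% 0)
      cyc <- proto$cycle_s
      recs <- lapply(traces, function(tr) {
        avg <- stimulus_locked_average(tr, proto)
        m1 <- tryCatch(quantify_phase_response(avg, c(0, cyc / 2)),
                       error = function(e) NULL)
        m2 <- tryCatch(quantify_phase_response(avg, c(cyc / 2, cyc)),
                       error = function(e) NULL)
        list(roi_id = tr$voxel_id,
             phase1 = if (is.null(m1)) NULL else unclass(m1)[1:6],
             phase2 = if (is.null(m2)) NULL else unclass(m2)[1:6])
      })
      jsonlite::write_json(recs, file.path(out_dir, "roi.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      recs
    })

  prov <- list(package = "gevitools",
               version = as.character(utils::packageVersion("gevitools")),
               subcommand = sub, seed = seed,
               config_hash = config_hash(config))
  if (!isFALSE(config$timestamp)) prov$timestamp <- format(Sys.time())
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
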