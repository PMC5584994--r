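#' Fluorescence trace container
#'
#' A uniformly sampled fluorescence time series — either raw photon counts
#' per frame or a dimensionless dF/F series — with its frame rate, identity
#' labels, and event annotations (spike triggers, stimulus onsets and
#' transitions).
#'
#' @param times Sample times in seconds, uniformly spaced (jitter under 1%
#'   of the period is tolerated).
#' @param values Photon counts per frame or dF/F values; must be finite.
#' @param kind `"counts"` or `"dff"`.
#' @param frame_rate Sampling rate in Hz; inferred from `times` if missing.
#' @param voxel_id,trial_id Identity labels.
#' @param events data.frame with columns `kind` (one of `spike_trigger`,
#'   `stimulus_onset`, `stimulus_transition`) and `time` (s), or NULL.
#' @param polarity Expected response sign: -1 for negative-going indicators
#'   such as the ASAPs (default), +1 for positive-going.
#' @return A `gevi_trace`.
#' @export
gevi_trace <- function(times, values, kind = c("counts", "dff"),
                       frame_rate = NULL, voxel_id = "v1", trial_id = "t1",
                       events = NULL, polarity = -1) {
  kind <- match.arg(kind)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  if (length(times) < 2) stop("a trace needs at least two samples")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  period <- stats::median(dt)
  if (max(abs(dt - period)) > 0.01 * period) {
    stop("sampling must be uniform (jitter exceeds 1% of the period)")
  }
  if (!all(is.finite(values))) stop("values must be finite")
  if (is.null(frame_rate)) frame_rate <- 1 / period
  if (!is.null(events)) {
    events <- as.data.frame(events)
    stopifnot(all(c("kind", "time") %in% names(events)))
    bad <- events$time < times[1] - period | events$time > times[length(times)] + period
    if (any(bad)) stop("event times must lie within the trace time span")
  }
  structure(list(times = times, values = values, kind = kind,
                 frame_rate = frame_rate, voxel_id = voxel_id,
                 trial_id = trial_id, events = events, polarity = polarity),
            class = "gevi_trace")
}

#' @export
print.gevi_trace <- function(x, ...) {
  cat(sprintf(
    "GEVI trace [%s] voxel %s trial %s: %d frames at %.4g Hz (%.4g s)\n",
    x$kind, x$voxel_id, x$trial_id, length(x$times), x$frame_rate,
    max(x$times) - min(x$times)))
  if (!is.null(x$events) && nrow(x$events) > 0) {
    cat("  events:", paste(sprintf("%s@%.4gs", x$events$kind, x$events$time),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.gevi_trace <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values, voxel_id = x$voxel_id,
             trial_id = x$trial_id, stringsAsFactors = FALSE)
}

# First event time of a given kind, or NULL.
trace_event <- function(trace, kind) {
  ev <- trace$events
  if (is.null(ev)) return(NULL)
  hit <- ev$time[ev$kind == kind]
  if (length(hit) == 0) NULL else hit[1]
}

# Resolve a trigger argument: explicit time, else first matching event.
resolve_event <- function(trace, time, kind, what) {
  if (!is.null(time)) return(time)
  t <- trace_event(trace, kind)
  if (is.null(t)) {
    stop("no ", what, " given and trace has no '", kind, "' event")
  }
  t
}

# Evaluate code with a temporarily seeded RNG, restoring (or clearing) the
# prior state afterwards so simulation calls do not perturb the caller's
# random stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
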