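# Results data model: neural trace sets on a uniform clock (CSV with a
# JSON-in-comment metadata header), worm locomotion recordings (JSON
# lines, one frame per line: timestamp, 3D midline points, 95 body-wall
# muscle activations), and a manifest tying both to a common timeline.
# Muscle channel order is anatomical: dorsal-left 24, dorsal-right 24,
# ventral-left 24, ventral-right 23 (95 total), each quadrant
# anterior-to-posterior.

N_BODY_WALL_MUSCLES <- 95L
.muscle_quadrants <- c(DL = 24L, DR = 24L, VL = 24L, VR = 23L)

#' Construct a neural trace set
#'
#' @param time_ms uniform time grid, ms.
#' @param traces numeric matrix, one row per grid point, one column per
#'   `(neuron, variable)` pair named `"neuron/variable"`.
#' @param metadata named list of provenance metadata (experiment id,
#'   network configuration id, ...).
#' @return A `wl_trace_set`.
#' @export
trace_set <- function(time_ms, traces, metadata = list()) {
  traces <- as.matrix(traces)
  stopifnot(length(time_ms) == nrow(traces), all(is.finite(traces)))
  if (length(time_ms) > 2L) {
    steps <- diff(time_ms)
    stopifnot(max(abs(steps - steps[1])) < 1e-9 * max(1, steps[1]))
  }
  structure(list(time_ms = as.numeric(time_ms), traces = traces,
                 metadata = metadata), class = "wl_trace_set")
}

#' @rdname trace_set
#' @param result a `wl_result_set` from [run_simulation()].
#' @export
as_trace_set <- function(result, metadata = list()) {
  stopifnot(inherits(result, "wl_result_set"))
  trace_set(result$time_ms, result$traces, metadata)
}

#' Write / read a trace set as CSV
#'
#' First line is a `#`-prefixed JSON object with the metadata; then a
#' regular CSV with a `time_ms` column plus one column per
#' `(neuron, variable)` trace. Values are printed with 12 significant
#' digits, so write-read round-trips are exact at the printed precision
#' and write-read-write is byte-stable.
#'
#' @param x a `wl_trace_set`.
#' @param path output file.
#' @return `write_traces_csv`: the path, invisibly. `read_traces_csv`:
#'   a `wl_trace_set`.
#' @export
write_traces_csv <- function(x, path) {
  stopifnot(inherits(x, "wl_trace_set"))
  meta <- jsonlite::toJSON(x$metadata, auto_unbox = TRUE, digits = NA)
  fmt <- function(v) formatC(v, digits = 12, format = "g")
  header <- paste(c("time_ms", colnames(x$traces)), collapse = ",")
  body <- apply(cbind(fmt(x$time_ms),
                      matrix(fmt(x$traces), nrow = nrow(x$traces))),
                1, paste, collapse = ",")
  writeLines(c(paste0("# ", meta), header, body), path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "# "))
    stop("not a trace CSV: missing metadata header line", call. = FALSE)
  metadata <- jsonlite::fromJSON(sub("^# ", "", lines[1]),
                                 simplifyVector = TRUE)
  header <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  if (header[1] != "time_ms")
    stop("first trace column must be time_ms", call. = FALSE)
  if (length(lines) > 2L) {
    cells <- do.call(rbind, strsplit(lines[-(1:2)], ",", fixed = TRUE))
    vals <- matrix(as.numeric(cells), nrow = nrow(cells))
  } else {
    vals <- matrix(numeric(), ncol = length(header))
  }
  traces <- vals[, -1, drop = FALSE]
  colnames(traces) <- header[-1]
  trace_set(vals[, 1], traces, as.list(metadata))
}

#' Construct a locomotion recording
#'
#' @param frames list of frames, each `list(timestamp = <ms>, midline =
#'   <N x 3 matrix, mm>, muscle_activations = <95 values in [0, 1]>)`.
#'   Timestamps must be strictly increasing and the midline point count
#'   constant.
#' @return A `wl_locomotion`.
#' @export
locomotion_recording <- function(frames) {
  if (length(frames) > 0L) {
    ts <- vapply(frames, `[[`, 0, "timestamp")
    stopifnot(all(diff(ts) > 0))
    n_pts <- vapply(frames, function(f) nrow(f$midline), 0L)
    stopifnot(length(unique(n_pts)) == 1L)
    for (f in frames) {
      stopifnot(ncol(f$midline) == 3L,
                length(f$muscle_activations) == N_BODY_WALL_MUSCLES,
                all(f$muscle_activations >= 0 & f$muscle_activations <= 1))
    }
  }
  structure(list(frames = frames), class = "wl_locomotion")
}

#' @export
print.wl_locomotion <- function(x, ...) {
  n <- length(x$frames)
  cat("<locomotion recording: ", n, " frame(s)",
      if (n > 0) paste0(", ", nrow(x$frames[[1]]$midline),
                        " midline points, ", N_BODY_WALL_MUSCLES,
                        " muscle channels"),
      ">\n", sep = "")
  invisible(x)
}

#' Write / read a locomotion recording as JSON lines
#'
#' One frame per line: `{"timestamp": ..., "midline": [[x,y,z], ...],
#' "muscles": [...]}`.
#'
#' @param x a `wl_locomotion`.
#' @param path file path.
#' @export
write_locomotion_jsonl <- function(x, path) {
  stopifnot(inherits(x, "wl_locomotion"))
  lines <- vapply(x$frames, function(f) {
    jsonlite::toJSON(list(
      timestamp = f$timestamp,
      midline = unname(apply(f$midline, 1, function(p)
        round(unname(p), 6), simplify = FALSE)),
      muscles = round(unname(f$muscle_activations), 6)
    ), auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_locomotion_jsonl
#' @export
read_locomotion_jsonl <- function(path) {
  lines <- readLines(path)
  frames <- lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    midline <- matrix(as.numeric(obj$midline), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
    list(timestamp = obj$timestamp, midline = midline,
         muscle_activations = obj$muscles)
  })
  locomotion_recording(frames)
}

#' Result manifest
#'
#' Ties a trace file and a locomotion file (plus optional experiment and
#' network documents) to one timeline via a common clock offset.
#'
#' @param trace_file,locomotion_file file names (relative to the
#'   manifest's directory).
#' @param experiment_file,network_file optional provenance documents.
#' @param clock_offset_ms offset added to locomotion timestamps to land
#'   on the trace clock.
#' @param duration,dt grid parameters, ms.
#' @return A `wl_manifest`.
#' @export
result_manifest <- function(trace_file, locomotion_file,
                            experiment_file = NULL, network_file = NULL,
                            clock_offset_ms = 0, duration = NULL,
                            dt = NULL) {
  structure(list(trace_file = trace_file,
                 locomotion_file = locomotion_file,
                 experiment_file = experiment_file,
                 network_file = network_file,
                 clock_offset_ms = clock_offset_ms,
                 duration = duration, dt = dt),
            class = "wl_manifest")
}

#' @rdname result_manifest
#' @param manifest a `wl_manifest`.
#' @param path file path for the manifest JSON.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "wl_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname result_manifest
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(result_manifest, obj[!vapply(obj, is.null, TRUE)])
}

#' Load the result bundle a manifest references
#'
#' Referenced files must exist and parse; the trace and locomotion
#' clocks must reconcile: after offset correction, every frame timestamp
#' must lie within dt/2 of a trace grid point.
#'
#' @param path path to a manifest JSON file.
#' @return A `wl_results` bundle: `list(traces, locomotion, manifest)`.
#' @export
load_results <- function(path) {
  manifest <- read_manifest(path)
  dir <- dirname(path)
  tf <- file.path(dir, manifest$trace_file)
  lf <- file.path(dir, manifest$locomotion_file)
  for (f in c(tf, lf)) {
    if (!file.exists(f))
      stop("manifest references missing file: ", f, call. = FALSE)
  }
  traces <- read_traces_csv(tf)
  locomotion <- read_locomotion_jsonl(lf)
  dt <- manifest$dt %||% diff(traces$time_ms[1:2])
  for (f in locomotion$frames) {
    t_corr <- f$timestamp + manifest$clock_offset_ms
    if (min(abs(traces$time_ms - t_corr)) > dt / 2 + 1e-9)
      stop("locomotion frame at ", f$timestamp,
           " ms does not reconcile with the trace clock", call. = FALSE)
  }
  structure(list(traces = traces, locomotion = locomotion,
                 manifest = manifest), class = "wl_results")
}

#' Generate synthetic simulation results
#'
#' Stands in for the external body/environment simulation so that the
#' results pipeline can be exercised offline. Deterministic per seed.
#' Neural traces are spiking-like membrane potentials (leaky baseline
#' with noise plus stereotyped spike transients at seeded random times);
#' locomotion is a traveling-wave undulation of the midline with
#' matching antiphase dorsal/ventral muscle activations (95 channels:
#' DL 24, DR 24, VL 24, VR 23). Both share one clock starting at 0.
#'
#' @param seed integer RNG seed.
#' @param duration total time, ms.
#' @param dt grid step, ms.
#' @param connectome a `wl_connectome`; one voltage trace per neuron.
#' @param n_midline_points midline resolution (default 33).
#' @param wave_frequency_hz undulation frequency (default 0.5 Hz).
#' @return A `wl_results` bundle (`traces`, `locomotion`, `manifest`;
#'   the manifest carries placeholder file names until written).
#' @export
generate_synthetic_results <- function(seed, duration, dt, connectome,
                                       n_midline_points = 33,
                                       wave_frequency_hz = 0.5) {
  stopifnot(duration > 0, dt > 0, dt <= duration)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  time_ms <- seq(0, by = dt, length.out = floor(duration / dt) + 1L)
  n <- length(time_ms)
  neurons <- connectome$neurons$name

  v_rest <- -0.065; v_spike <- 0.030  # volts
  traces <- matrix(NA_real_, nrow = n, ncol = length(neurons),
                   dimnames = list(NULL, paste0(neurons, "/v")))
  spike_shape <- v_spike - v_rest
  for (j in seq_along(neurons)) {
    noise <- stats::filter(rnorm(n, 0, 0.0015), 0.9, method = "recursive")
    v <- v_rest + as.numeric(noise)
    rate_hz <- runif(1, 1, 8)
    n_spk <- stats::rpois(1, rate_hz * duration / 1000)
    if (n_spk > 0) {
      at <- sort(sample.int(n, min(n_spk, n)))
      for (k in at) {
        idx <- k:min(n, k + 2L)
        v[idx] <- v[idx] + spike_shape * c(1, 0.4, 0.15)[seq_along(idx)]
      }
    }
    traces[, j] <- v
  }

  body_mm <- 1
  s <- seq(0, body_mm, length.out = n_midline_points)
  amp <- 0.1; wavelength <- 0.6
  omega <- 2 * pi * wave_frequency_hz
  k_wave <- 2 * pi / wavelength
  quadrant_phase <- c(DL = 0, DR = 0, VL = pi, VR = pi)
  m_pos <- unlist(lapply(names(.muscle_quadrants), function(q)
    seq(0, body_mm, length.out = .muscle_quadrants[[q]])))
  m_phase <- unlist(lapply(names(.muscle_quadrants), function(q)
    rep(quadrant_phase[[q]], .muscle_quadrants[[q]])))
  frames <- lapply(seq_len(n), function(i) {
    t_s <- time_ms[i] / 1000
    y <- amp * sin(k_wave * s - omega * t_s)
    act <- 0.5 + 0.5 * sin(k_wave * m_pos - omega * t_s + m_phase)
    list(timestamp = time_ms[i],
         midline = cbind(x = s, y = y, z = rep(0.04, n_midline_points)),
         muscle_activations = pmin(1, pmax(0, act)))
  })

  manifest <- result_manifest(
    trace_file = "traces.csv", locomotion_file = "locomotion.jsonl",
    clock_offset_ms = 0, duration = duration, dt = dt)
  structure(list(
    traces = trace_set(time_ms, traces,
                       metadata = list(generator = "synthetic",
                                       seed = seed, duration = duration,
                                       dt = dt)),
    locomotion = locomotion_recording(frames),
    manifest = manifest
  ), class = "wl_results")
}

#' Write a result bundle to a directory
#'
#' @param results a `wl_results` bundle.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "wl_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_traces_csv(results$traces,
                   file.path(dir, results$manifest$trace_file))
  write_locomotion_jsonl(results$locomotion,
                         file.path(dir, results$manifest$locomotion_file))
  write_manifest(results$manifest, file.path(dir, "manifest.json"))
  invisible(file.path(dir, "manifest.json"))
}

#' Slice a result bundle to a time window
#'
#' Keeps grid points and frames with `t0 <= t < t1` and rebases the
#' clock so the slice starts at 0; slicing is therefore a monoid action:
#' `slice(slice(x, a, b), c, d)` equals `slice(x, a + c, a + d)`, and
#' abutting slices concatenate back to the original via
#' [concat_results()].
#'
#' @param results a `wl_results` bundle.
#' @param t0,t1 window bounds, ms, `0 <= t0 < t1 <= duration`.
#' @return A `wl_results` bundle covering `[t0, t1)`.
#' @export
slice_results <- function(results, t0, t1) {
  stopifnot(inherits(results, "wl_results"))
  dur <- results$manifest$duration
  if (!(t0 >= 0 && t0 < t1 && t1 <= dur + 1e-9))
    stop("slice bounds must satisfy 0 <= t0 < t1 <= duration", call. = FALSE)
  # half-open [t0, t1), except that a window ending at the recording end
  # keeps the terminal grid point (the grid spans the closed interval
  # [0, duration], so pure half-open slicing could never recover it)
  at_end <- abs(t1 - dur) <= 1e-9
  in_window <- function(t)
    t >= t0 - 1e-9 & (t < t1 - 1e-9 | (at_end & t <= t1 + 1e-9))
  tr <- results$traces
  keep <- in_window(tr$time_ms)
  new_tr <- trace_set(tr$time_ms[keep] - t0,
                      tr$traces[keep, , drop = FALSE], tr$metadata)
  frames <- Filter(function(f) in_window(f$timestamp),
                   results$locomotion$frames)
  frames <- lapply(frames, function(f) {
    f$timestamp <- f$timestamp - t0
    f
  })
  manifest <- results$manifest
  manifest$duration <- t1 - t0
  structure(list(traces = new_tr,
                 locomotion = locomotion_recording(frames),
                 manifest = manifest), class = "wl_results")
}

#' @rdname slice_results
#' @param a,b two bundles on the same grid; `b` is appended after `a`.
#' @export
concat_results <- function(a, b) {
  stopifnot(inherits(a, "wl_results"), inherits(b, "wl_results"))
  offset <- a$manifest$duration
  tr <- trace_set(c(a$traces$time_ms, b$traces$time_ms + offset),
                  rbind(a$traces$traces, b$traces$traces),
                  a$traces$metadata)
  frames <- c(a$locomotion$frames,
              lapply(b$locomotion$frames, function(f) {
                f$timestamp <- f$timestamp + offset
                f
              }))
  manifest <- a$manifest
  manifest$duration <- a$manifest$duration + b$manifest$duration
  structure(list(traces = tr, locomotion = locomotion_recording(frames),
                 manifest = manifest), class = "wl_results")
}

#' Selection highlight sets for results exploration
#'
#' The selected neuron and its postsynaptic partners (the sets the
#' results viewer colors green and yellow); the selected neuron is not
#' in the postsynaptic set unless an autapse exists.
#'
#' @param connectome a `wl_connectome`.
#' @param neuron selected neuron name.
#' @return `list(selected =, postsynaptic =)`.
#' @export
highlight_sets <- function(connectome, neuron) {
  partners <- postsynaptic_partners(connectome, neuron)
  list(selected = neuron, postsynaptic = partners$postsynaptic)
}
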