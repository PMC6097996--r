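#' Tap take constructor
#'
#' One tapping recording: a drummer tapping along to a musical excerpt.
#'
#' @param drummer_id,take_id Identifiers.
#' @param onsets Strictly increasing tap onset times in seconds
#'   (`>= 3`).
#' @param latency_correction Equipment latency in seconds, subtracted
#'   from the onsets before any analysis.
#' @return A list of class `"tap_take"`.
#' @export
tap_take <- function(drummer_id, take_id, onsets,
                     latency_correction = 0) {
  onsets <- as.numeric(onsets)
  if (length(onsets) < 3L || any(diff(onsets) <= 0))
    stop("`onsets` must be >= 3 strictly increasing times",
         call. = FALSE)
  structure(list(drummer_id = as.character(drummer_id),
                 take_id = as.character(take_id),
                 onsets = onsets,
                 latency_correction = latency_correction),
            class = "tap_take")
}

## nearest-neighbour alignment of two onset sequences, within half a
## period; robust to a missing first/last tap
align_onsets <- function(ref, other, period) {
  idx <- vapply(ref, function(t) which.min(abs(other - t)), integer(1))
  d <- abs(other[idx] - ref)
  keep <- d <= period / 2
  if (sum(keep) < 3L || anyDuplicated(idx[keep]))
    stop("tap takes could not be aligned beat-for-beat", call. = FALSE)
  cbind(ref = ref[keep], other = other[idx[keep]])
}

phase_difference <- function(discrepancies, period) {
  2 * pi * abs(mean(discrepancies)) / period
}

#' Consensus beat annotation from tap takes
#'
#' Derives canonical beat locations for an excerpt: after latency
#' correction, each drummer's two takes with the smallest difference in
#' mean inter-tap interval are aligned beat-for-beat (nearest-neighbour
#' within half a period) and averaged; drummer averages are then aligned
#' and averaged across drummers. Consistency is screened with circular
#' phase differences, `2 * pi * |mean signed onset discrepancy| / mean
#' period`: an excerpt is flagged for rejection when any within-drummer
#' phase difference exceeds `within_threshold` (0.6 rad, i.e. 9.5% of a
#' beat) or any between-drummer pair exceeds `between_threshold`
#' (0.7 rad, 11.1% of a beat).
#'
#' @param takes List of [tap_take()] objects (or plain lists with the
#'   same fields); at least one drummer with at least two takes.
#' @param within_threshold,between_threshold Phase-difference rejection
#'   thresholds in radians.
#' @return An object of class `"beat_annotation"`: `beat_times`,
#'   `mean_period`, and a `screening` report (per-drummer and pairwise
#'   phase differences, selected takes, `flagged`).
#' @export
consensus_beats <- function(takes, within_threshold = 0.6,
                            between_threshold = 0.7) {
  onsets <- lapply(takes, function(t) t$onsets - t$latency_correction)
  drummers <- vapply(takes, `[[`, character(1), "drummer_id")
  take_ids <- vapply(takes, `[[`, character(1), "take_id")
  groups <- split(seq_along(takes), drummers)
  if (any(lengths(groups) < 2L))
    stop("every drummer needs at least two takes", call. = FALSE)
  per_drummer <- list()
  within <- numeric(0)
  selected <- character(0)
  for (d in names(groups)) {
    ix <- groups[[d]]
    iti <- vapply(onsets[ix], function(o) mean(diff(o)), numeric(1))
    ## pick the two takes with the closest mean inter-tap interval
    pairs <- utils::combn(seq_along(ix), 2L)
    gap <- abs(iti[pairs[1L, ]] - iti[pairs[2L, ]])
    best <- pairs[, which.min(gap)]
    o1 <- onsets[[ix[best[1L]]]]
    o2 <- onsets[[ix[best[2L]]]]
    period <- mean(c(iti[best[1L]], iti[best[2L]]))
    al <- align_onsets(o1, o2, period)
    per_drummer[[d]] <- rowMeans(al)
    within[d] <- phase_difference(al[, "other"] - al[, "ref"], period)
    selected <- c(selected, take_ids[ix[best]])
  }
  ## average across drummers, aligned to the first drummer
  ref <- per_drummer[[1L]]
  period0 <- mean(diff(ref))
  aligned <- matrix(ref, ncol = 1L)
  between <- numeric(0)
  if (length(per_drummer) > 1L) {
    for (d in 2:length(per_drummer)) {
      al <- align_onsets(ref, per_drummer[[d]], period0)
      full <- rep(NA_real_, length(ref))
      full[match(al[, "ref"], ref)] <- al[, "other"]
      aligned <- cbind(aligned, full)
    }
    dn <- names(per_drummer)
    for (i in seq_len(ncol(aligned) - 1L)) {
      for (j in (i + 1L):ncol(aligned)) {
        ok <- stats::complete.cases(aligned[, c(i, j)])
        between[paste(dn[i], dn[j], sep = ":")] <-
          phase_difference(aligned[ok, j] - aligned[ok, i], period0)
      }
    }
  }
  beat_times <- rowMeans(aligned, na.rm = TRUE)
  flagged <- any(within > within_threshold) ||
    (length(between) > 0 && any(between > between_threshold))
  structure(list(beat_times = beat_times,
                 mean_period = mean(diff(beat_times)),
                 screening = list(within_phase = within,
                                  between_phase = between,
                                  selected_takes = selected,
                                  flagged = flagged)),
            class = "beat_annotation")
}

#' @export
print.beat_annotation <- function(x, ...) {
  cat(sprintf("Beat annotation: %d beats, mean period %.3f s%s\n",
              length(x$beat_times), x$mean_period,
              if (isTRUE(x$screening$flagged)) " [FLAGGED]" else ""))
  invisible(x)
}

#' Beep schedule for a target or lure version
#'
#' Target beeps sit on the annotated beat times; lure beeps are
#' displaced by `offset` times the local inter-beat interval (the
#' interval following each beat; the last beat uses the preceding
#' interval) — earlier for `"ahead"`, later for `"behind"`. Onsets
#' falling outside `[0, duration]` are dropped.
#'
#' @param beats A `"beat_annotation"` (or numeric vector of beat
#'   times).
#' @param version `"target"` or `"lure"`.
#' @param offset Displacement as a fraction of a beat, `(0, 0.5]`
#'   (lures only).
#' @param direction `"ahead"` or `"behind"` (lures only).
#' @param duration Excerpt duration in seconds (default: last beat plus
#'   one mean period).
#' @return An object of class `"beep_schedule"`: `version`, `onsets`,
#'   `offset`, `direction`, `duration`.
#' @export
beep_schedule <- function(beats, version = c("target", "lure"),
                          offset = NULL, direction = NULL,
                          duration = NULL) {
  version <- match.arg(version)
  bt <- if (inherits(beats, "beat_annotation")) beats$beat_times
        else as.numeric(beats)
  period <- mean(diff(bt))
  if (is.null(duration)) duration <- max(bt) + period
  if (version == "target") {
    onsets <- bt
    offset <- 0; direction <- NA_character_
  } else {
    if (is.null(offset) || offset <= 0 || offset > 0.5)
      stop("lure `offset` must lie in (0, 0.5]", call. = FALSE)
    direction <- match.arg(direction, c("ahead", "behind"))
    ibi <- diff(bt)
    local_ibi <- c(ibi, ibi[length(ibi)])   # last beat: preceding interval
    shift <- offset * local_ibi * if (direction == "ahead") -1 else 1
    onsets <- bt + shift
  }
  onsets <- onsets[onsets >= 0 & onsets <= duration]
  structure(list(version = version, onsets = onsets, offset = offset,
                 direction = direction, duration = duration),
            class = "beep_schedule")
}

#' Render a beep schedule as audio
#'
#' Each beep is a sine tone (default 1000 Hz, 20 ms) with a linear fade
#' to zero over its final `fade_dur` (default 10 ms). Overlapping beeps
#' are summed; the output is peak-normalised to `amplitude`.
#'
#' @param schedule A `"beep_schedule"`.
#' @param sample_rate Samples per second (default 44100).
#' @param beep_freq Sine frequency in Hz.
#' @param beep_dur Beep duration in seconds.
#' @param fade_dur Fade-out duration in seconds (`<= beep_dur`).
#' @param amplitude Peak amplitude in `(0, 1]`.
#' @return An object of class `"waveform"`: `samples` (numeric vector in
#'   `[-1, 1]`) and `sample_rate`.
#' @export
render_beep_track <- function(schedule, sample_rate = 44100,
                              beep_freq = 1000, beep_dur = 0.020,
                              fade_dur = 0.010, amplitude = 1) {
  stopifnot(fade_dur <= beep_dur, amplitude > 0, amplitude <= 1)
  n <- ceiling(schedule$duration * sample_rate)
  samples <- numeric(n)
  nb <- round(beep_dur * sample_rate)
  nf <- round(fade_dur * sample_rate)
  if (nb > 0 && length(schedule$onsets)) {
    t <- (seq_len(nb) - 1L) / sample_rate
    beep <- sin(2 * pi * beep_freq * t)
    env <- rep(1, nb)
    if (nf > 0)
      env[(nb - nf + 1L):nb] <- seq(1, 0, length.out = nf)
    beep <- beep * env
    for (onset in schedule$onsets) {
      start <- round(onset * sample_rate) + 1L
      stop_ <- min(start + nb - 1L, n)
      if (start > n) next
      span <- seq.int(start, stop_)
      samples[span] <- samples[span] + beep[seq_along(span)]
    }
    peak <- max(abs(samples))
    if (peak > 0) samples <- samples * amplitude / peak
  }
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("Waveform: %.3f s at %d Hz, peak %.3f\n",
              length(x$samples) / x$sample_rate, x$sample_rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Assemble a two-version 2-AFC trial
#'
#' Concatenates version A, a silent gap (default 2 s), and version B.
#'
#' @param version_a,version_b `"waveform"` objects with equal sample
#'   rates.
#' @param gap Silence between versions, seconds.
#' @return A `"waveform"` of duration `dur(A) + gap + dur(B)`.
#' @export
assemble_trial <- function(version_a, version_b, gap = 2.0) {
  if (version_a$sample_rate != version_b$sample_rate)
    stop("sample rates differ", call. = FALSE)
  sr <- version_a$sample_rate
  silence <- numeric(round(gap * sr))
  structure(list(samples = c(version_a$samples, silence,
                             version_b$samples),
                 sample_rate = sr),
            class = "waveform")
}

#' Detect beep onsets in a rendered waveform
#'
#' Threshold-based onset recovery, for round-trip checks of the
#' renderer: a beep onset is a sample whose absolute amplitude first
#' exceeds `threshold` after at least `min_gap` seconds of
#' sub-threshold signal.
#'
#' @param waveform A `"waveform"`.
#' @param threshold Detection threshold (fraction of full scale).
#' @param min_gap Minimum silence between distinct beeps, seconds.
#' @return Numeric vector of detected onset times in seconds.
#' @export
detect_onsets <- function(waveform, threshold = 0.01, min_gap = 0.005) {
  active <- abs(waveform$samples) > threshold
  ix <- which(active)
  if (!length(ix)) return(numeric(0))
  gap <- round(min_gap * waveform$sample_rate)
  starts <- ix[c(TRUE, diff(ix) > gap)]
  (starts - 1L) / waveform$sample_rate
}

## --- WAV and JSON interchange ------------------------------------------

#' Write / read a waveform as WAV
#'
#' Minimal RIFF/WAVE support: mono, 16-bit PCM or 32-bit IEEE float.
#'
#' @param waveform A `"waveform"` object.
#' @param path File path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` returns
#'   a `"waveform"`.
#' @export
write_wav <- function(waveform, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  x <- waveform$samples
  sr <- as.integer(waveform$sample_rate)
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per <- bits %/% 8L
  data_len <- length(x) * bytes_per
  audio_fmt <- if (format == "pcm16") 1L else 3L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * bytes_per, con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(as.integer(round(pmax(pmin(x, 1), -1) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE")
    stop("not a RIFF/WAVE file", call. = FALSE)
  sr <- NULL; fmt <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L)
      stop("no data chunk found", call. = FALSE)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (id == "data") {
      n <- size %/% (bits %/% 8L)
      samples <- if (fmt == 1L && bits == 16L)
        readBin(con, "integer", n, size = 2, signed = TRUE,
                endian = "little") / 32767
      else if (fmt == 3L && bits == 32L)
        readBin(con, "numeric", n, size = 4, endian = "little")
      else stop("unsupported WAV encoding", call. = FALSE)
      return(structure(list(samples = samples, sample_rate = sr),
                       class = "waveform"))
    } else {
      readBin(con, "raw", size)
    }
  }
}

#' Write / read beat annotations and tap takes as JSON
#'
#' Onset arrays in seconds; one JSON object per file.
#'
#' @param annotation A `"beat_annotation"`.
#' @param takes A list of [tap_take()] objects.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the parsed
#'   object.
#' @export
write_annotation <- function(annotation, path) {
  jsonlite::write_json(list(beat_times = annotation$beat_times,
                            mean_period = annotation$mean_period),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  obj <- jsonlite::fromJSON(path)
  bt <- as.numeric(obj$beat_times)
  if (length(bt) < 2L || any(diff(bt) <= 0))
    stop("annotation beat times must be strictly increasing",
         call. = FALSE)
  structure(list(beat_times = bt, mean_period = mean(diff(bt)),
                 screening = NULL),
            class = "beat_annotation")
}

#' @rdname write_annotation
#' @export
write_tap_takes <- function(takes, path) {
  recs <- lapply(takes, function(t)
    list(drummer_id = t$drummer_id, take_id = t$take_id,
         onsets = t$onsets, latency_correction = t$latency_correction))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_tap_takes <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(recs, function(r)
    tap_take(r$drummer_id, r$take_id, as.numeric(r$onsets),
             r$latency_correction))
}
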