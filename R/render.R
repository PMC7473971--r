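## Standard MIDI file and RIFF/WAV serialization, written against the format
## specifications. Both writers have matching readers used for round-trip
## verification.

uint_be <- function(x, nbytes) {
  out <- raw(nbytes)
  for (i in nbytes:1) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

uint_le <- function(x, nbytes) rev(uint_be(x, nbytes))

# MIDI variable-length quantity
vlq_encode <- function(x) {
  stopifnot(x >= 0)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0) {
    bytes <- c(x %% 128L, bytes)
    x <- x %/% 128L
  }
  if (length(bytes) > 1)
    bytes[-length(bytes)] <- bytes[-length(bytes)] + 128L
  as.raw(bytes)
}

#' Write note events to a standard MIDI file
#'
#' Format-1 file: one conductor track holding the tempo, then one track per
#' hierarchical level present in `events`. At the default 960 pulses per
#' quarter note and 120 bpm one tick is ~0.52 ms, so note boundaries are
#' accurate to well under 1 ms after rounding.
#'
#' @param events A `note_events` data frame from [schedule_events()].
#' @param path Output `.mid` path.
#' @param ppq Pulses per quarter note.
#' @param tempo Microseconds per quarter note (500000 = 120 bpm).
#' @param velocity Note-on velocity, 1-127.
#' @return `path`, invisibly.
#' @export
render_midi <- function(events, path, ppq = 960L, tempo = 500000L,
                        velocity = 96L) {
  if (is.null(events) || nrow(events) == 0L) stop("no events to render")
  sec_to_tick <- function(s) as.integer(round(s * 1e6 / tempo * ppq))

  track_chunk <- function(body) {
    c(charToRaw("MTrk"), uint_be(length(body), 4L), body)
  }
  end_of_track <- c(vlq_encode(0L), as.raw(c(0xFF, 0x2F, 0x00)))

  tempo_track <- track_chunk(c(
    vlq_encode(0L), as.raw(c(0xFF, 0x51, 0x03)), uint_be(tempo, 3L),
    end_of_track))

  levels <- sort(unique(events$level))
  note_tracks <- lapply(levels, function(lv) {
    ev <- events[events$level == lv, , drop = FALSE]
    msgs <- rbind(
      data.frame(tick = sec_to_tick(ev$onset), on = 1L, pitch = ev$pitch),
      data.frame(tick = sec_to_tick(ev$onset + ev$duration), on = 0L,
                 pitch = ev$pitch))
    msgs <- msgs[order(msgs$tick, msgs$on), , drop = FALSE]  # offs first on ties
    body <- raw(0)
    last <- 0L
    for (i in seq_len(nrow(msgs))) {
      delta <- msgs$tick[i] - last
      last <- msgs$tick[i]
      status <- if (msgs$on[i] == 1L) 0x90 else 0x80
      vel <- if (msgs$on[i] == 1L) velocity else 0x40
      body <- c(body, vlq_encode(delta),
                as.raw(c(status, msgs$pitch[i], vel)))
    }
    track_chunk(c(body, end_of_track))
  })

  header <- c(charToRaw("MThd"), uint_be(6L, 4L), uint_be(1L, 2L),
              uint_be(length(levels) + 1L, 2L), uint_be(ppq, 2L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, tempo_track, unlist(note_tracks)), con)
  invisible(path)
}

#' Read a standard MIDI file back into a note table
#'
#' Minimal SMF parser covering the subset [render_midi()] emits (plus running
#' status and foreign meta/sysex events, which are skipped). Note-ons are
#' paired with note-offs per pitch in FIFO order.
#'
#' @param path `.mid` file path.
#' @return `data.frame` with columns `onset`, `duration`, `pitch`, `track`
#'   (track 1 = first note track), times in seconds.
#' @export
read_midi <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  take <- function(n) {
    out <- raw[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  be <- function(b) sum(as.integer(b) * 256^((length(b) - 1):0))
  read_vlq <- function() {
    val <- 0
    repeat {
      b <- as.integer(take(1L))
      val <- val * 128 + (b %% 128L)
      if (b < 128L) return(val)
    }
  }
  stopifnot(rawToChar(take(4L)) == "MThd")
  take(4L)                      # header length (6)
  take(2L)                      # format
  ntrk <- be(take(2L))
  ppq <- be(take(2L))
  tempo <- 500000
  notes <- list()
  note_track <- 0L
  for (trk in seq_len(ntrk)) {
    stopifnot(rawToChar(take(4L)) == "MTrk")
    len <- be(take(4L))
    end <- pos + len
    tick <- 0
    status <- NULL
    open <- list()  # pitch -> vector of (tick) FIFO
    has_notes <- FALSE
    while (pos < end) {
      tick <- tick + read_vlq()
      b <- as.integer(raw[pos])
      if (b >= 128L) {
        status <- b
        pos <- pos + 1L
      }
      if (status == 0xFF) {
        take(1L)                               # meta type
        mlen <- read_vlq()
        take(mlen)
      } else if (status %in% c(0xF0, 0xF7)) {
        mlen <- read_vlq()
        take(mlen)
      } else {
        kind <- status %/% 16L
        nd <- switch(as.character(kind),
                     "12" = 1L, "13" = 1L,       # program change, channel pressure
                     2L)
        dat <- as.integer(take(nd))
        if (kind == 9L && dat[2] > 0L) {        # note on
          has_notes <- TRUE
          key <- as.character(dat[1])
          open[[key]] <- c(open[[key]], tick)
        } else if (kind == 8L || (kind == 9L && dat[2] == 0L)) {  # note off
          key <- as.character(dat[1])
          t_on <- open[[key]][1]
          open[[key]] <- open[[key]][-1]
          notes[[length(notes) + 1L]] <- data.frame(
            on_tick = t_on, off_tick = tick, pitch = dat[1],
            track = note_track + 1L)
        }
      }
    }
    if (has_notes) note_track <- note_track + 1L
    pos <- end
  }
  # recover tempo: scan for the set-tempo meta event (FF 51 03)
  idx <- which(raw == as.raw(0xFF))
  for (i in idx) {
    if (i + 4L <= length(raw) && raw[i + 1L] == as.raw(0x51) &&
        raw[i + 2L] == as.raw(0x03)) {
      tempo <- be(raw[(i + 3L):(i + 5L)])
      break
    }
  }
  out <- do.call(rbind, notes)
  out <- out[order(out$track, out$on_tick, out$pitch), , drop = FALSE]
  tick_sec <- tempo / 1e6 / ppq
  data.frame(onset = out$on_tick * tick_sec,
             duration = (out$off_tick - out$on_tick) * tick_sec,
             pitch = out$pitch, track = out$track, row.names = NULL)
}

## --- WAV --------------------------------------------------------------------

#' Synthesis configuration for WAV rendering
#'
#' @param sample_rate Samples per second (>= 8000).
#' @param level_gain Per-level sine amplitudes; defaults sum below 1 so that
#'   a fully sustained depth-4 stack cannot clip.
#' @param ramp_dur Raised-cosine onset/offset ramp, s.
#' @param bits `"pcm16"` or `"float32"`.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(sample_rate = 44100L,
                         level_gain = c(0.25, 0.24, 0.23, 0.22),
                         ramp_dur = 0.010, bits = c("pcm16", "float32")) {
  if (sample_rate < 8000) stop("sample_rate must be at least 8 kHz")
  bits <- match.arg(bits)
  structure(list(sample_rate = as.integer(sample_rate),
                 level_gain = level_gain, ramp_dur = ramp_dur, bits = bits),
            class = "synth_config")
}

#' Pitch (MIDI note number) to frequency, 12-TET, A4 = 440 Hz
#' @param pitch MIDI note number(s).
#' @return Frequency in Hz.
#' @export
midi_to_hz <- function(pitch) 440 * 2^((pitch - 69) / 12)

#' Additive sine synthesis of note events
#'
#' Each event contributes a sine at its equal-temperament frequency, scaled
#' by its level's gain, with raised-cosine on/off ramps.
#'
#' @param events A `note_events` data frame.
#' @param cfg A [synth_config].
#' @return Numeric vector of samples, length `ceiling(total span * rate)`.
#' @export
synth_events <- function(events, cfg = synth_config()) {
  if (is.null(events) || nrow(events) == 0L) stop("no events to synthesize")
  sr <- cfg$sample_rate
  span <- max(events$onset + events$duration)
  n <- as.integer(ceiling(span * sr - 1e-6))  # guard fp noise in span
  sig <- numeric(n)
  for (i in seq_len(nrow(events))) {
    dur <- events$duration[i]
    ns <- as.integer(round(dur * sr))
    if (ns < 1L) next
    tt <- (seq_len(ns) - 1L) / sr
    tone <- sin(2 * pi * midi_to_hz(events$pitch[i]) * tt)
    nr <- min(as.integer(round(cfg$ramp_dur * sr)), ns %/% 2L)
    if (nr > 0L) {
      ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
      tone[seq_len(nr)] <- tone[seq_len(nr)] * ramp
      tone[(ns - nr + 1L):ns] <- tone[(ns - nr + 1L):ns] * rev(ramp)
    }
    gain <- cfg$level_gain[min(events$level[i], length(cfg$level_gain))]
    at <- as.integer(round(events$onset[i] * sr))
    idx <- (at + 1L):min(at + ns, n)
    sig[idx] <- sig[idx] + gain * tone[seq_along(idx)]
  }
  if (max(abs(sig)) > 1)
    stop("mixdown clips (peak > 1): lower level_gain")
  sig
}

#' Render note events to a WAV file
#'
#' @param events A `note_events` data frame.
#' @param path Output `.wav` path.
#' @param cfg A [synth_config].
#' @return `path`, invisibly.
#' @export
render_wav <- function(events, path, cfg = synth_config()) {
  sig <- synth_events(events, cfg)
  write_wav(sig, path, cfg$sample_rate, cfg$bits)
}

#' Write a mono sample vector as a WAV file
#' @param x Samples in `[-1, 1]`.
#' @param path Output path.
#' @param sample_rate Samples per second.
#' @param bits `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate, bits = c("pcm16", "float32")) {
  bits <- match.arg(bits)
  n <- length(x)
  bytes_per <- if (bits == "pcm16") 2L else 4L
  fmt_code <- if (bits == "pcm16") 1L else 3L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("RIFF"), con)
  writeBin(uint_le(36L + data_size, 4L), con)
  writeBin(charToRaw("WAVE"), con)
  writeBin(charToRaw("fmt "), con)
  writeBin(uint_le(16L, 4L), con)
  writeBin(uint_le(fmt_code, 2L), con)
  writeBin(uint_le(1L, 2L), con)                       # mono
  writeBin(uint_le(sample_rate, 4L), con)
  writeBin(uint_le(sample_rate * bytes_per, 4L), con)  # byte rate
  writeBin(uint_le(bytes_per, 2L), con)                # block align
  writeBin(uint_le(8L * bytes_per, 2L), con)
  writeBin(charToRaw("data"), con)
  writeBin(uint_le(data_size, 4L), con)
  if (bits == "pcm16") {
    writeBin(as.integer(round(pmax(pmin(x, 1), -1) * 32767)), con,
             size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file written by [write_wav()]
#' @param path `.wav` file path.
#' @return List with `samples` (numeric, normalized to `[-1, 1]` for PCM) and
#'   `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  stopifnot(rawToChar(readBin(con, "raw", 4L)) == "RIFF")
  readBin(con, "raw", 4L)
  stopifnot(rawToChar(readBin(con, "raw", 4L)) == "WAVE")
  fmt_code <- NULL
  sr <- NULL
  bits <- NULL
  repeat {
    id <- rawToChar(readBin(con, "raw", 4L))
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      readBin(con, "integer", 1L, size = 2L, endian = "little")
      sr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      readBin(con, "raw", 6L)
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (id == "data") {
      n <- size %/% (bits %/% 8L)
      samples <- if (fmt_code == 3L) {
        readBin(con, "numeric", n, size = 4L, endian = "little")
      } else {
        readBin(con, "integer", n, size = 2L, endian = "little") / 32767
      }
      return(list(samples = samples, sample_rate = sr))
    } else {
      readBin(con, "raw", size)
    }
  }
}
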