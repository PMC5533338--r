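#' Describe one synthetic syllable
#'
#' Building block for [corpus_spec()]. Four syllable classes cover the
#' acoustic variety relevant to a spectrogram-window detector: harmonic
#' stacks (a fundamental plus overtones at integer multiples, the classic
#' "stacked bands" zebra finch syllable), band-limited noise bursts (syllables
#' closer to bandpass-filtered white noise), frequency sweeps (downward or
#' upward slides), and silent gaps.
#'
#' @param kind One of `"harmonic_stack"`, `"broadband_noise"`, `"sweep"`,
#'   `"silence_gap"`.
#' @param duration_ms Duration in milliseconds (> 0).
#' @param f0 Fundamental frequency in Hz (stack and sweep start).
#' @param n_harmonics Number of harmonics (stack/sweep); harmonic `h` is
#'   weighted `1/h`.
#' @param f0_end Final fundamental for sweeps.
#' @param band Two-element numeric band in Hz for noise bursts.
#' @param amplitude Linear gain (> 0).
#' @return An object of class `"syllable_spec"`.
#' @export
syllable_spec <- function(kind = c("harmonic_stack", "broadband_noise", "sweep",
                                   "silence_gap"),
                          duration_ms, f0 = NULL, n_harmonics = 1L,
                          f0_end = NULL, band = NULL, amplitude = 1) {
  kind <- match.arg(kind)
  if (duration_ms <= 0) stop("syllable duration must be positive")
  if (amplitude <= 0) stop("syllable amplitude must be positive")
  if (n_harmonics < 1) stop("n_harmonics must be at least 1")
  if (kind %in% c("harmonic_stack", "sweep") && is.null(f0)) {
    stop(kind, " syllable needs f0")
  }
  if (kind == "sweep" && is.null(f0_end)) stop("sweep syllable needs f0_end")
  if (kind == "broadband_noise" && is.null(band)) {
    stop("broadband_noise syllable needs a band")
  }
  structure(list(kind = kind, duration_ms = duration_ms, f0 = f0,
                 n_harmonics = as.integer(n_harmonics), f0_end = f0_end,
                 band = band, amplitude = amplitude),
            class = "syllable_spec")
}

#' Specify a synthetic aligned song corpus
#'
#' Describes the conditions under which an aligned corpus is rendered: the
#' stereotyped syllable sequence (the motif), corpus sizes, per-song onset and
#' amplitude jitter, background noise level, and the canonical target times
#' `t*` at which the detector should fire.
#'
#' Each clip has the same fixed length (motif plus `pad_ms` of margin on each
#' side, motif centred), emulating the equal-length aligned clips an offline
#' alignment pipeline produces. Targets are clip-relative offsets in ms of the
#' *nominal* (unjittered) rendering; each song's realized canonical times are
#' the targets shifted by that song's onset jitter.
#'
#' @param syllables List of [syllable_spec()] objects, in motif order.
#' @param targets Numeric vector of canonical target times, ms from clip start.
#' @param n_songs,n_nonsong Number of song and non-song clips. Non-song clips
#'   cycle through silence, cage-noise, band-limited noise bursts and short
#'   call-like tones, and never contain the full motif.
#' @param onset_jitter_sd_ms SD of the per-song onset shift (ms), quantized to
#'   whole samples when rendered.
#' @param amplitude_jitter_sd SD of the per-song multiplicative gain
#'   (fraction; gain floored at 0.05).
#' @param noise_snr_db Additive white-noise level as SNR in dB relative to the
#'   motif RMS; `Inf` disables noise.
#' @param sample_rate Sample rate in Hz.
#' @param seed Integer seed; the corpus is a pure function of the spec.
#' @param pad_ms Silent margin on each side of the motif.
#' @return An object of class `"corpus_spec"`.
#' @export
corpus_spec <- function(syllables, targets, n_songs = 200, n_nonsong = n_songs,
                        onset_jitter_sd_ms = 2, amplitude_jitter_sd = 0.1,
                        noise_snr_db = 30, sample_rate = 44100, seed = 1,
                        pad_ms = 40) {
  stopifnot(is.list(syllables), length(syllables) >= 1)
  if (n_songs < 1) stop("n_songs must be at least 1")
  if (onset_jitter_sd_ms < 0) stop("onset_jitter_sd_ms must be non-negative")
  lapply(syllables, function(sy) .check_nyquist(sy, sample_rate))
  motif_ms <- sum(vapply(syllables, function(s) s$duration_ms, 0))
  clip_ms <- motif_ms + 2 * pad_ms
  if (any(targets <= 0) || any(targets >= clip_ms)) {
    stop("each target must lie inside the clip (0, ", clip_ms, ") ms")
  }
  structure(list(syllables = syllables, targets = as.numeric(targets),
                 n_songs = as.integer(n_songs),
                 n_nonsong = as.integer(n_nonsong),
                 onset_jitter_sd_ms = onset_jitter_sd_ms,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 noise_snr_db = noise_snr_db, sample_rate = sample_rate,
                 seed = as.integer(seed), pad_ms = pad_ms,
                 motif_ms = motif_ms, clip_ms = clip_ms),
            class = "corpus_spec")
}

.check_nyquist <- function(sy, rate) {
  ny <- rate / 2
  top <- switch(sy$kind,
                harmonic_stack = sy$f0 * sy$n_harmonics,
                sweep = max(sy$f0, sy$f0_end) * sy$n_harmonics,
                broadband_noise = sy$band[2],
                silence_gap = 0)
  lo <- switch(sy$kind,
               harmonic_stack = sy$f0,
               sweep = min(sy$f0, sy$f0_end),
               broadband_noise = sy$band[1],
               silence_gap = NULL)
  if (!is.null(lo) && lo <= 0) {
    stop("syllable frequencies must be positive (", sy$kind, ")")
  }
  if (top >= ny) {
    stop("syllable '", sy$kind, "' reaches ", top,
         " Hz, at or above the Nyquist frequency ", ny, " Hz")
  }
  invisible(sy)
}

#' A zebra-finch-like demonstration motif
#'
#' A five-element motif — harmonic stack, gap, broadband noise burst, gap,
#' downward sweep — spanning roughly 1–6 kHz, with one canonical target placed
#' mid-motif so that the 50 ms recognition window covers multi-syllable
#' context. Defaults follow the corpus regime used throughout the package's
#' own evaluation: 200 songs and 200 non-song clips at a 1:1 ratio, 2 ms onset
#' jitter, 10% amplitude jitter, 30 dB SNR.
#'
#' @param n_songs,n_nonsong Corpus sizes.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [corpus_spec()].
#' @return A `"corpus_spec"`.
#' @export
zebra_finch_spec <- function(n_songs = 200, n_nonsong = n_songs, seed = 1, ...) {
  syl <- list(
    syllable_spec("harmonic_stack", duration_ms = 60, f0 = 700,
                  n_harmonics = 8),
    syllable_spec("silence_gap", duration_ms = 20),
    syllable_spec("broadband_noise", duration_ms = 40, band = c(2000, 6000)),
    syllable_spec("silence_gap", duration_ms = 20),
    syllable_spec("sweep", duration_ms = 50, f0 = 6000, f0_end = 3000)
  )
  # motif 190 ms inside a 270 ms clip (40 ms pads); target at the noise burst's
  # end so the window must integrate stack + gap + burst context
  corpus_spec(syl, targets = 160, n_songs = n_songs, n_nonsong = n_nonsong,
              seed = seed, ...)
}

# run expr under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.ramp <- function(n, rate, ramp_ms = 5) {
  r <- min(round(ramp_ms / 1000 * rate), n %/% 2)
  env <- rep(1, n)
  if (r > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- up
    env[n + 1 - seq_len(r)] <- up
  }
  env
}

# Render one syllable; uses the current RNG stream for noise syllables.
.render_syllable <- function(sy, rate) {
  n <- round(sy$duration_ms / 1000 * rate)
  if (sy$kind == "silence_gap") return(numeric(n))
  t <- (seq_len(n) - 1) / rate
  x <- switch(sy$kind,
    harmonic_stack = {
      s <- numeric(n)
      for (h in seq_len(sy$n_harmonics)) {
        s <- s + sin(2 * pi * h * sy$f0 * t) / h
      }
      s
    },
    sweep = {
      dur <- n / rate
      phase <- 2 * pi * (sy$f0 * t + (sy$f0_end - sy$f0) * t^2 / (2 * dur))
      s <- numeric(n)
      for (h in seq_len(sy$n_harmonics)) s <- s + sin(h * phase) / h
      s
    },
    broadband_noise = {
      # frozen noise: a noisy syllable is a fixed motor pattern, stereotyped
      # across renditions and corpora, so its realization is a deterministic
      # function of the syllable parameters, not of the corpus seed
      syl_seed <- as.integer((sy$duration_ms * 31 + sy$band[1] * 7 +
                                sy$band[2] * 13) %% 2147483647)
      .with_seed(syl_seed, .bandlimited_noise(n, rate, sy$band))
    })
  x <- x / max(abs(x))
  x * .ramp(n, rate) * sy$amplitude
}

# white noise brick-wall filtered to [band] via FFT masking
.bandlimited_noise <- function(n, rate, band) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)  # frequency of each bin, mirrored
  X[f < band[1] | f > band[2]] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Render an aligned synthetic corpus
#'
#' The motif is rendered once from the seed (so that with zero jitter and no
#' noise all songs are bit-identical), then each song receives a sample-
#' quantized onset shift, a multiplicative gain and additive white noise.
#' Canonical times are the spec targets shifted by each song's realized onset
#' shift. Non-song clips are the same length as songs and cycle through
#' silence, cage-like white noise, band-limited noise bursts and short
#' call-like harmonic tones; none contains the motif.
#'
#' @param spec A [corpus_spec()].
#' @return An object of class `"annotated_corpus"`: list with `songs` and
#'   `nonsong` (lists of numeric sample vectors, all equal length), `rate`,
#'   `canonical_times` (`n_songs x n_targets` matrix, ms), `onset_shift_ms`,
#'   `nonsong_kinds`, `spec` and a corpus `id` used to assert train/test
#'   disjointness.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  rate <- spec$sample_rate
  .with_seed(spec$seed, {
    motif <- unlist(lapply(spec$syllables, .render_syllable, rate = rate))
    pad <- round(spec$pad_ms / 1000 * rate)
    clip_n <- length(motif) + 2L * pad
    motif_rms <- sqrt(mean(motif^2))

    songs <- vector("list", spec$n_songs)
    shifts_ms <- numeric(spec$n_songs)
    for (i in seq_len(spec$n_songs)) {
      shift <- round(stats::rnorm(1, 0, spec$onset_jitter_sd_ms) / 1000 * rate)
      shift <- max(min(shift, pad), -pad)
      gain <- max(0.05, 1 + stats::rnorm(1, 0, spec$amplitude_jitter_sd))
      clip <- numeric(clip_n)
      clip[pad + shift + seq_along(motif)] <- motif * gain
      if (is.finite(spec$noise_snr_db)) {
        noise_sd <- motif_rms * 10^(-spec$noise_snr_db / 20)
        clip <- clip + stats::rnorm(clip_n, 0, noise_sd)
      }
      songs[[i]] <- clip
      shifts_ms[i] <- shift / rate * 1000
    }
    canonical <- outer(shifts_ms, spec$targets, "+")

    kinds <- c("silence", "cage_noise", "noise_burst", "call")
    nonsong <- vector("list", spec$n_nonsong)
    nonsong_kinds <- character(spec$n_nonsong)
    for (i in seq_len(spec$n_nonsong)) {
      kind <- kinds[(i - 1L) %% length(kinds) + 1L]
      nonsong[[i]] <- .render_nonsong(kind, clip_n, rate, motif_rms, spec)
      nonsong_kinds[i] <- kind
    }

    structure(
      list(songs = songs, nonsong = nonsong, rate = rate,
           canonical_times = canonical, onset_shift_ms = shifts_ms,
           nonsong_kinds = nonsong_kinds, spec = spec,
           id = sprintf("song-%d-%d-%d-%s", spec$seed, spec$n_songs,
                        spec$n_nonsong,
                        paste(round(spec$targets, 3), collapse = "_"))),
      class = "annotated_corpus")
  })
}

.render_nonsong <- function(kind, clip_n, rate, motif_rms, spec) {
  clip <- numeric(clip_n)
  if (kind == "silence") return(clip)
  if (is.finite(spec$noise_snr_db)) {
    clip <- stats::rnorm(clip_n, 0, motif_rms * 10^(-spec$noise_snr_db / 20))
  }
  if (kind == "cage_noise") {
    clip <- clip + stats::rnorm(clip_n, 0, motif_rms * stats::runif(1, 0.2, 0.6))
  } else if (kind == "noise_burst") {
    dur <- round(stats::runif(1, 0.02, 0.06) * rate)
    lo <- stats::runif(1, 500, 3000)
    burst <- .bandlimited_noise(dur, rate, c(lo, lo + stats::runif(1, 1000, 4000)))
    burst <- burst / max(abs(burst)) * .ramp(dur, rate)
    at <- sample.int(clip_n - dur, 1)
    clip[at + seq_len(dur)] <- clip[at + seq_len(dur)] + burst
  } else if (kind == "call") {
    sy <- syllable_spec("harmonic_stack",
                        duration_ms = stats::runif(1, 40, 80),
                        f0 = stats::runif(1, 500, 1500),
                        n_harmonics = sample(3:8, 1))
    tone <- .render_syllable(sy, rate)
    at <- sample.int(clip_n - length(tone), 1)
    clip[at + seq_along(tone)] <- clip[at + seq_along(tone)] + tone
  }
  clip
}

#' Render a delta-syllable test corpus
#'
#' The delta-syllable isolates the timing inherent in the detection pipeline
#' from any acoustic variability: each "song" is a single full-scale unit
#' impulse in an otherwise silent clip, and the canonical target is placed a
#' fixed offset (default 5 ms) after the impulse. The impulse position is
#' stepped through `phase_sweep_samples` consecutive sample offsets across
#' songs so that the impulse phase relative to the spectrogram frame grid
#' uniformly covers one hop — the frame-phase aliasing a live detector sees.
#'
#' @param n_songs Number of impulse clips (an equal number of silent non-song
#'   clips is generated).
#' @param target_offset_ms Canonical target time minus impulse time, ms.
#' @param sample_rate Sample rate, Hz.
#' @param seed Integer seed (used only when `noise_floor_db` is finite).
#' @param clip_ms Clip length, ms.
#' @param impulse_ms Nominal impulse position within the clip, ms.
#' @param phase_sweep_samples Number of consecutive sample offsets to sweep;
#'   defaults to one default frame hop (`round(1.5 ms * sample_rate)`).
#' @param noise_floor_db If finite, white background noise at this level (dB
#'   re full scale) is added; default `-Inf` (digital silence) for exact
#'   reproducibility.
#' @return An `"annotated_corpus"` (see [generate_corpus()]) with one target.
#' @export
generate_delta_corpus <- function(n_songs = 200, target_offset_ms = 5,
                                  sample_rate = 44100, seed = 1,
                                  clip_ms = 130, impulse_ms = 60,
                                  phase_sweep_samples =
                                    round_half_away(1.5 * sample_rate / 1000),
                                  noise_floor_db = -Inf) {
  if (target_offset_ms <= 0) stop("target_offset_ms must be positive")
  if (n_songs < 1) stop("n_songs must be at least 1")
  clip_n <- as.integer(round(clip_ms / 1000 * sample_rate))
  base <- as.integer(round(impulse_ms / 1000 * sample_rate))
  phase_sweep_samples <- as.integer(phase_sweep_samples)
  .with_seed(seed, {
    songs <- vector("list", n_songs)
    canonical <- matrix(0, n_songs, 1)
    for (i in seq_len(n_songs)) {
      k <- base + (i - 1L) %% phase_sweep_samples  # impulse sample index
      clip <- numeric(clip_n)
      if (is.finite(noise_floor_db)) {
        clip <- stats::rnorm(clip_n, 0, 10^(noise_floor_db / 20))
      }
      clip[k] <- 1
      songs[[i]] <- clip
      canonical[i, 1] <- k / sample_rate * 1000 + target_offset_ms
    }
    nonsong <- replicate(n_songs, {
      if (is.finite(noise_floor_db)) stats::rnorm(clip_n, 0, 10^(noise_floor_db / 20))
      else numeric(clip_n)
    }, simplify = FALSE)
    structure(
      list(songs = songs, nonsong = nonsong, rate = sample_rate,
           canonical_times = canonical,
           impulse_sample = base + (seq_len(n_songs) - 1L) %% phase_sweep_samples,
           onset_shift_ms = ((seq_len(n_songs) - 1L) %% phase_sweep_samples) /
             sample_rate * 1000,
           nonsong_kinds = rep("silence", n_songs), spec = NULL,
           id = sprintf("delta-%d-%d-%g-%g", seed, n_songs, target_offset_ms,
                        clip_ms)),
      class = "annotated_corpus")
  })
}

#' @export
print.annotated_corpus <- function(x, ...) {
  cat(sprintf("Annotated corpus '%s': %d songs + %d non-song clips, %d samples each @ %g Hz\n",
              x$id, length(x$songs), length(x$nonsong),
              length(x$songs[[1]]), x$rate))
  cat(sprintf("  targets per song: %d; canonical time range %.2f-%.2f ms\n",
              ncol(x$canonical_times), min(x$canonical_times),
              max(x$canonical_times)))
  invisible(x)
}

#' Write an annotated corpus to disk
#'
#' One mono WAV per clip plus a plain-text sidecar `annotations.tsv` with one
#' row per clip: `filename`, `is_song` (1/0), and comma-separated canonical
#' times in ms at nanosecond resolution. Header comment lines record the
#' corpus id and sample rate. Round-trips losslessly through [read_corpus()]
#' with the default float64 sample format.
#'
#' @param corpus An `"annotated_corpus"`.
#' @param directory Output directory (created if absent).
#' @param format Sample format for [write_wav()].
#' @return The manifest data frame (`filename`, `is_song`, `times`), invisibly.
#' @export
write_corpus <- function(corpus, directory, format = "float64") {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  n_s <- length(corpus$songs)
  n_n <- length(corpus$nonsong)
  files <- c(sprintf("song_%04d.wav", seq_len(n_s)),
             sprintf("nonsong_%04d.wav", seq_len(n_n)))
  is_song <- rep(c(1L, 0L), c(n_s, n_n))
  times <- character(n_s + n_n)
  for (i in seq_len(n_s)) {
    write_wav(corpus$songs[[i]], corpus$rate, file.path(directory, files[i]),
              format = format)
    times[i] <- paste(sprintf("%.9f", corpus$canonical_times[i, ]),
                      collapse = ",")
  }
  for (i in seq_len(n_n)) {
    write_wav(corpus$nonsong[[i]], corpus$rate,
              file.path(directory, files[n_s + i]), format = format)
    times[n_s + i] <- ""
  }
  man <- data.frame(filename = files, is_song = is_song, times = times,
                    stringsAsFactors = FALSE)
  ann <- file.path(directory, "annotations.tsv")
  header <- c(sprintf("# syldetect corpus annotations v1"),
              sprintf("# id: %s", corpus$id),
              sprintf("# rate: %d", as.integer(corpus$rate)))
  writeLines(c(header, "filename\tis_song\ttimes_ms",
               sprintf("%s\t%d\t%s", man$filename, man$is_song, man$times)),
             ann)
  invisible(man)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param directory Directory containing the WAV clips and `annotations.tsv`.
#' @return An `"annotated_corpus"`.
#' @export
read_corpus <- function(directory) {
  ann <- file.path(directory, "annotations.tsv")
  if (!file.exists(ann)) stop("no annotations.tsv in ", directory)
  lines <- readLines(ann)
  hdr <- lines[startsWith(lines, "#")]
  id <- sub("^# id: ", "", grep("^# id: ", hdr, value = TRUE))
  rate <- as.numeric(sub("^# rate: ", "", grep("^# rate: ", hdr, value = TRUE)))
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "character"))
  songs <- list(); nonsong <- list(); can <- list()
  for (i in seq_len(nrow(tab))) {
    w <- read_wav(file.path(directory, tab$filename[i]))
    if (w$rate != rate) {
      stop("sample-rate mismatch in ", tab$filename[i], ": ", w$rate,
           " vs corpus rate ", rate)
    }
    if (tab$is_song[i] == 1L) {
      songs[[length(songs) + 1L]] <- w$samples
      can[[length(can) + 1L]] <-
        as.numeric(strsplit(tab$times[i], ",")[[1]])
    } else {
      nonsong[[length(nonsong) + 1L]] <- w$samples
    }
  }
  canonical <- do.call(rbind, can)
  structure(list(songs = songs, nonsong = nonsong, rate = rate,
                 canonical_times = canonical,
                 nonsong_kinds = rep(NA_character_, length(nonsong)),
                 spec = NULL, id = if (length(id)) id else directory),
            class = "annotated_corpus")
}
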