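#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# representative oscillator frequency (Hz) per band, kept well inside the
# band edges so band-limited filtering and band-power integration both
# capture essentially all of the oscillation
band_carrier_freqs <- c(delta = 2.5, theta = 6, alpha = 10,
                        low_beta = 14, high_beta = 20, gamma = 35)

#' Learning stage implied by a session index
#'
#' Sessions are mapped to curriculum stages by cumulative session counts;
#' with the default `c(3, 3, 5)` split, sessions 1-3 are stage 1 (basic
#' knowledge), 4-6 stage 2 (core knowledge) and 7-11 stage 3 (knowledge
#' application).
#'
#' @param session integer session index (vectorized).
#' @param sessions_per_stage integer vector of sessions in each stage.
#' @return integer stage labels.
#' @export
stage_of_session <- function(session, sessions_per_stage = c(3L, 3L, 5L)) {
  stop_if_not(all(session >= 1 & session <= sum(sessions_per_stage)),
              "session index outside the curriculum")
  findInterval(session - 1L, cumsum(sessions_per_stage)) + 1L
}

#' Default stage/task band-amplitude profiles
#'
#' Per-channel, per-band oscillation amplitudes (uV) encoding the qualitative
#' stage and task effects reported for multi-session learning EEG: posterior
#' alpha dominance with a progressive decline across virtual-lab stages,
#' high-beta enhancement in late lab and quiz stages, elevated frontal theta
#' in early lecture stages, and overall amplitude growing across lecture
#' stages while shrinking for labs and quizzes. `effect_size` scales the
#' stage/task deviations multiplicatively; 0 makes all stages identically
#' distributed.
#'
#' @param stage learning stage (1, 2 or 3).
#' @param task one of `"lecture"`, `"lab"`, `"quiz"`.
#' @param effect_size nonnegative scale for the stage/task deviations.
#' @param montage montage tibble.
#' @return 14 x 6 amplitude matrix (channels x bands, uV).
#' @export
default_band_profiles <- function(stage = 1L, task = c("lecture", "lab", "quiz"),
                                  effect_size = 1,
                                  montage = emotiv_montage()) {
  task <- match.arg(task)
  stop_if_not(stage %in% 1:3, "stage must be 1, 2 or 3")
  stop_if_not(effect_size >= 0, "effect_size must be >= 0")
  bands <- names(band_carrier_freqs)
  base <- c(delta = 6, theta = 5, alpha = 6, low_beta = 3.5,
            high_beta = 2.5, gamma = 1.5)
  amp <- matrix(rep(base, each = 14L), nrow = 14L,
                dimnames = list(montage$channel, bands))
  posterior <- c("O1", "O2", "P7", "P8")
  frontal <- c("AF3", "AF4", "F3", "F4", "F7", "F8")
  amp[posterior, "alpha"] <- amp[posterior, "alpha"] * 1.6
  amp[frontal, c("delta", "theta")] <- amp[frontal, c("delta", "theta")] * 1.3
  amp[frontal, "gamma"] <- amp[frontal, "gamma"] * 1.2

  e <- effect_size
  s <- stage - 2L                       # -1, 0, +1
  if (task == "lecture") {
    amp[frontal, "theta"] <- amp[frontal, "theta"] * (1 + e * 0.15 * (stage == 1))
    amp[, "alpha"] <- amp[, "alpha"] * (1 + e * 0.12 * (stage >= 2))
    amp <- amp * (1 + e * 0.08 * s)     # amplitude heightened across stages
  } else {
    amp[, "alpha"] <- amp[, "alpha"] * (1 - e * 0.12 * s)   # progressive decline
    if (task == "lab")
      amp[, "low_beta"] <- amp[, "low_beta"] * (1 - e * 0.10 * s)
    amp[, "high_beta"] <- amp[, "high_beta"] * (1 + e * 0.20 * (stage == 3))
    amp <- amp * (1 - e * 0.08 * s)     # activity narrows in later stages
  }
  amp
}

#' Synthetic session configuration
#'
#' @param fs sampling rate (Hz), 128 by default.
#' @param duration session length in seconds (>= 40 so at least one 10 s
#'   segment survives the 30 s setup discard).
#' @param band_profiles 14 x 6 channels x bands amplitude matrix (uV); see
#'   [default_band_profiles()].
#' @param coupling list of channel-pair couplings, each a list with elements
#'   `a`, `b` (channel names), `band`, `lag` (radians) and `strength` in
#'   \[0, 1\]; a shared oscillator is mixed into both channels with a fixed
#'   phase offset so the phase-lag index between them has an analytic target.
#' @param noise_sd standard deviation (uV) of the 1/f background noise.
#' @param amp_jitter SD of the multiplicative amplitude jitter applied
#'   independently per 10 s block, channel and band (models waxing/waning of
#'   rhythms while keeping non-overlapping 10 s segments independent).
#' @param artifact_spec artifact injection rates, see [artifact_spec()].
#' @param seed integer RNG seed; identical configs give bit-identical data.
#' @param subject,session,task session metadata; the learning stage is derived
#'   from the session index via [stage_of_session()].
#' @param sessions_per_stage stage boundaries used for that derivation.
#' @return a `synth_config` list.
#' @export
synth_config <- function(fs = 128, duration = 230,
                         band_profiles = default_band_profiles(),
                         coupling = list(),
                         noise_sd = 10, amp_jitter = 0.15,
                         artifact_spec = NULL,
                         seed = 1L,
                         subject = "S01", session = 1L,
                         task = c("lecture", "lab", "quiz"),
                         sessions_per_stage = c(3L, 3L, 5L)) {
  task <- match.arg(task)
  stop_if_not(fs > 0, "fs must be positive")
  stop_if_not(is.matrix(band_profiles) &&
              all(dim(band_profiles) == c(14L, 6L)),
              "band_profiles must be a 14 x 6 matrix")
  for (cp in coupling) {
    stop_if_not(all(c(cp$a, cp$b) %in% emotiv_montage()$channel),
                "coupling references an unknown channel")
    stop_if_not(cp$band %in% names(band_carrier_freqs), "unknown coupling band")
    stop_if_not(cp$strength >= 0 && cp$strength <= 1,
                "coupling strength must be in [0, 1]")
  }
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(fs = fs, duration = duration, band_profiles = band_profiles,
                 coupling = coupling, noise_sd = noise_sd,
                 amp_jitter = amp_jitter, artifact_spec = artifact_spec,
                 seed = as.integer(seed), subject = subject,
                 session = as.integer(session), task = task,
                 sessions_per_stage = sessions_per_stage),
            class = "synth_config")
}

#' @keywords internal
new_recording <- function(data, fs, meta, montage = emotiv_montage()) {
  stop_if_not(nrow(data) == nrow(montage),
              "data row count must equal montage size")
  rownames(data) <- montage$channel
  structure(list(data = data, fs = fs, montage = montage, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  subject %s, session %s, task %s, stage %s\n",
              x$meta$subject, x$meta$session, x$meta$task, x$meta$stage))
  invisible(x)
}

#' Generate one synthetic EEG session
#'
#' Sums per-band amplitude-jittered sinusoids with random phases and
#' 1/f-shaped Gaussian noise on each channel, applies any configured
#' channel-pair phase couplings, then injects artifacts if an
#' `artifact_spec` is present. The per-band spectral content matches the
#' configured `band_profiles` up to sampling error; identical configurations
#' (including seed) give bit-identical output.
#'
#' @param config a [synth_config()].
#' @return an `eeg_recording` (channels x samples matrix in uV, plus fs,
#'   montage and metadata). If artifacts were injected the recording carries
#'   an `artifacts` attribute with the injection ledger.
#' @export
generate_session <- function(config) {
  stop_if_not(inherits(config, "synth_config"), "config must be a synth_config")
  stop_if_not(config$duration >= 40,
              "duration must be >= 40 s for at least one QC-able segment")
  fs <- config$fs
  n <- round(config$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  bands <- names(band_carrier_freqs)
  montage <- emotiv_montage()
  nblocks <- ceiling(config$duration / 10)
  blk_w <- round(10 * fs)                  # samples per jitter block

  rec <- with_seed(config$seed, {
    jit <- array(stats::rnorm(nblocks * 14L * 6L, 1, config$amp_jitter),
                 dim = c(nblocks, 14L, 6L))
    jit <- pmax(jit, 0.1)
    phases <- matrix(stats::runif(14L * 6L, 0, 2 * pi), 14L, 6L,
                     dimnames = list(montage$channel, bands))
    # couplings replace the independent phase of the coupled band by a shared
    # oscillator phase, mixed by strength
    mix <- matrix(0, 14L, 6L, dimnames = dimnames(phases))
    shared_phase <- matrix(NA_real_, 14L, 6L, dimnames = dimnames(phases))
    for (cp in config$coupling) {
      phi <- stats::runif(1, 0, 2 * pi)
      for (ch in c(cp$a, cp$b)) {
        mix[ch, cp$band] <- cp$strength
        shared_phase[ch, cp$band] <- if (ch == cp$a) phi else phi - cp$lag
      }
    }
    x <- matrix(0, 14L, n)
    for (b in seq_along(bands)) {
      wt <- 2 * pi * band_carrier_freqs[[b]] * tt
      sb <- sin(wt)
      cb <- cos(wt)
      for (ch in seq_len(14L)) {
        a0 <- config$band_profiles[ch, b]
        if (a0 == 0) next
        # sin(wt + phi) expanded on the shared (sin, cos) basis so each
        # channel-band costs only multiply-adds
        mo <- 1 - mix[ch, b]
        cc <- mo * cos(phases[ch, b])
        ss <- mo * sin(phases[ch, b])
        if (mix[ch, b] > 0) {
          cc <- cc + mix[ch, b] * cos(shared_phase[ch, b])
          ss <- ss + mix[ch, b] * sin(shared_phase[ch, b])
        }
        gain <- rep(a0 * jit[, ch, b], each = blk_w)[seq_len(n)]
        x[ch, ] <- x[ch, ] + gain * (cc * sb + ss * cb)
      }
    }
    if (config$noise_sd > 0) {
      w <- matrix(stats::rnorm(n * 14L), n, 14L)
      f2 <- seq_len(n) - 1L
      f2 <- pmin(f2, n - f2) * fs / n
      g <- 1 / sqrt(pmax(f2, 1))
      pn <- Re(stats::mvfft(stats::mvfft(w) * g, inverse = TRUE)) / n
      # theoretical scale (Parseval): empirical rescaling would fix each
      # recording's total noise power and negatively couple its segments
      x <- x + t(pn) * (config$noise_sd / sqrt(mean(g^2)))
    }
    x
  })

  meta <- list(subject = config$subject, session = config$session,
               task = config$task,
               stage = stage_of_session(config$session,
                                        config$sessions_per_stage))
  out <- new_recording(rec, fs, meta, montage)
  if (!is.null(config$artifact_spec))
    out <- inject_artifacts(out, config$artifact_spec,
                            seed = config$seed + 1L)
  out
}

#' Artifact injection specification
#'
#' Rates are probabilities that a given 10 s analysis segment receives an
#' artifact of each type (at most one type per segment so the injection
#' ledger predicts a unique QC outcome):
#' \describe{
#'   \item{spike}{a few isolated 1-sample excursions of 160-240 uV; the
#'     outlier rule corrects them, so the segment should survive as
#'     `kept_corrected`.}
#'   \item{drift}{a slow triangular baseline bump (80 uV peak); removed by
#'     high-pass filtering and detrending, segment stays `kept`.}
#'   \item{excursion}{a 2 s, 5 Hz burst above the amplitude limit on all
#'     channels (emulating a motion/cable artifact); it dominates the segment
#'     variance so the outlier rule leaves it alone and the >150 uV check
#'     discards the segment (`discarded_amplitude`).}
#'   \item{half_lead}{dense +-amplitude spikes on more than half the samples
#'     of one lead; the half-lead rule discards the segment
#'     (`discarded_outliers`).}
#' }
#'
#' @param spike_rate,drift_rate,excursion_rate,half_lead_rate per-segment
#'   probabilities (must sum to <= 1).
#' @param amplitude artifact amplitude in uV (> 150 so the excursion and
#'   half-lead artifacts exceed the QC amplitude limit).
#' @param discard,seg_len seconds discarded at the start and segment length,
#'   mirroring the QC slicing so injections align with analysis segments.
#' @param margin seconds kept clear of segment boundaries so filter
#'   transients do not leak into neighbouring segments.
#' @return an `artifact_spec` list.
#' @export
artifact_spec <- function(spike_rate = 0, drift_rate = 0, excursion_rate = 0,
                          half_lead_rate = 0, amplitude = 220,
                          discard = 30, seg_len = 10, margin = 1.5) {
  rates <- c(spike_rate, drift_rate, excursion_rate, half_lead_rate)
  stop_if_not(all(rates >= 0), "artifact rates must be >= 0")
  stop_if_not(sum(rates) <= 1, "artifact rates must sum to <= 1")
  stop_if_not(amplitude > 150, "artifact amplitude should exceed 150 uV")
  structure(list(spike_rate = spike_rate, drift_rate = drift_rate,
                 excursion_rate = excursion_rate,
                 half_lead_rate = half_lead_rate, amplitude = amplitude,
                 discard = discard, seg_len = seg_len, margin = margin),
            class = "artifact_spec")
}

#' Inject seed-reproducible artifacts into a recording
#'
#' Returns a copy of the recording with artifacts inserted according to
#' `spec` and an `artifacts` attribute: a ledger tibble with one row per
#' injected event (type, analysis segment index, channels, absolute sample
#' range and the QC status the event is expected to produce). All rates zero
#' returns the input unchanged.
#'
#' @param rec an `eeg_recording`.
#' @param spec an [artifact_spec()].
#' @param seed integer seed for the injection RNG.
#' @return the recording with artifacts and ledger attached.
#' @export
inject_artifacts <- function(rec, spec, seed = 1L) {
  stop_if_not(inherits(spec, "artifact_spec"), "spec must be an artifact_spec")
  empty <- tibble::tibble(type = character(), segment = integer(),
                          channels = character(), start = integer(),
                          end = integer(), expected_status = character())
  if (spec$spike_rate + spec$drift_rate + spec$excursion_rate +
      spec$half_lead_rate == 0) {
    attr(rec, "artifacts") <- empty
    return(rec)
  }
  fs <- rec$fs
  n <- ncol(rec$data)
  seg_samp <- round(spec$seg_len * fs)
  first <- round(spec$discard * fs)            # 0-based sample of segment 1
  nseg <- floor((n - first) / seg_samp)
  margin <- round(spec$margin * fs)
  chans <- rownames(rec$data)
  ledger <- list()
  x <- rec$data

  with_seed(seed, {
    u <- stats::runif(nseg)
    thr <- cumsum(c(spec$half_lead_rate, spec$excursion_rate,
                    spec$spike_rate, spec$drift_rate))
    for (k in seq_len(nseg)) {
      s0 <- first + (k - 1L) * seg_samp + 1L    # 1-based first sample
      s1 <- first + k * seg_samp                # 1-based last sample
      lo <- s0 + margin
      hi <- s1 - margin
      type <- if (u[k] <= thr[1]) "half_lead"
      else if (u[k] <= thr[2]) "excursion"
      else if (u[k] <= thr[3]) "spike"
      else if (u[k] <= thr[4]) "drift"
      else next
      if (type == "half_lead") {
        ch <- sample(chans, 1L)
        idx <- s0:s1
        hit <- sort(sample(idx, ceiling(0.58 * length(idx))))
        x[ch, hit] <- x[ch, hit] +
          spec$amplitude * sample(c(-1, 1), length(hit), replace = TRUE)
        ledger[[length(ledger) + 1L]] <- tibble::tibble(
          type = type, segment = k, channels = ch,
          start = min(hit), end = max(hit),
          expected_status = "discarded_outliers")
      } else if (type == "excursion") {
        len <- round(2 * fs)
        st <- lo + floor((hi - lo - len) / 2)
        idx <- st:(st + len - 1L)
        tl <- (seq_along(idx) - 1) / fs
        env <- rep(1, length(idx))              # raised-cosine edges (0.25 s)
        ramp <- round(0.25 * fs)
        env[1:ramp] <- (1 - cos(pi * (1:ramp) / ramp)) / 2
        env[(length(idx) - ramp + 1L):length(idx)] <- rev(env[1:ramp])
        burst <- spec$amplitude * env * sin(2 * pi * 5 * tl + pi / 2)
        x[, idx] <- sweep(x[, idx, drop = FALSE], 2L, burst, `+`)
        ledger[[length(ledger) + 1L]] <- tibble::tibble(
          type = type, segment = k, channels = "all",
          start = min(idx), end = max(idx),
          expected_status = "discarded_amplitude")
      } else if (type == "spike") {
        pos <- lo + sort(sample.int(hi - lo, 3L))
        pos <- pos[c(TRUE, diff(pos) > 50)]     # keep spikes isolated
        for (p in pos) {
          ch <- sample(chans, 1L)
          x[ch, p] <- x[ch, p] +
            sample(c(-1, 1), 1L) * stats::runif(1, 160, 240)
          ledger[[length(ledger) + 1L]] <- tibble::tibble(
            type = type, segment = k, channels = ch, start = p, end = p,
            expected_status = "kept_corrected")
        }
      } else {                                  # drift
        idx <- s0:s1
        half <- ceiling(length(idx) / 2)
        tri <- c(seq(0, 80, length.out = half),
                 seq(80, 0, length.out = length(idx) - half))
        ch <- sample(chans, 1L)
        x[ch, idx] <- x[ch, idx] + tri
        ledger[[length(ledger) + 1L]] <- tibble::tibble(
          type = type, segment = k, channels = ch,
          start = min(idx), end = max(idx), expected_status = "kept")
      }
    }
  })
  rec$data <- x
  attr(rec, "artifacts") <- if (length(ledger)) do.call(rbind, ledger) else empty
  rec
}

#' Generate a stage-labelled set of synthetic sessions
#'
#' Emulates the study design: each subject contributes one recording per
#' session, sessions map to learning stages by `sessions_per_stage`, and the
#' stage/task band-power profiles are scaled by `effect_size`
#' (`effect_size = 0` draws all stages from the identical generative law).
#' Per-recording seeds are derived deterministically from `seed`.
#'
#' @param n_subjects number of subjects.
#' @param sessions_per_stage sessions per stage, default `c(3, 3, 5)`.
#' @param effect_size nonnegative stage-effect scale.
#' @param seed master seed.
#' @param task task label for the sessions.
#' @param duration session duration (s).
#' @param noise_sd,amp_jitter generator noise parameters.
#' @param artifacts optional [artifact_spec()] applied to every session.
#' @param handler optional function applied to each recording as it is
#'   generated; when supplied, the list of handler results is returned and
#'   raw recordings are discarded (keeps memory flat for large runs).
#' @return list of `eeg_recording`s, or of handler results.
#' @export
make_stage_dataset <- function(n_subjects = 1L,
                               sessions_per_stage = c(3L, 3L, 5L),
                               effect_size = 1, seed = 1L,
                               task = c("lab", "lecture", "quiz"),
                               duration = 230, noise_sd = 10,
                               amp_jitter = 0.15, artifacts = NULL,
                               handler = NULL) {
  task <- match.arg(task)
  stop_if_not(effect_size >= 0, "effect_size must be >= 0")
  n_sessions <- sum(sessions_per_stage)
  out <- vector("list", n_subjects * n_sessions)
  i <- 0L
  for (subj in seq_len(n_subjects)) {
    for (sess in seq_len(n_sessions)) {
      i <- i + 1L
      stage <- stage_of_session(sess, sessions_per_stage)
      cfg <- synth_config(
        duration = duration,
        band_profiles = default_band_profiles(stage, task, effect_size),
        noise_sd = noise_sd, amp_jitter = amp_jitter,
        artifact_spec = artifacts,
        seed = as.integer((as.numeric(seed) * 100003 + subj * 1009 + sess) %%
                            2147483647),
        subject = sprintf("S%02d", subj), session = sess, task = task,
        sessions_per_stage = sessions_per_stage)
      rec <- generate_session(cfg)
      out[[i]] <- if (is.null(handler)) rec else handler(rec)
    }
  }
  out
}

#' Write a recording as an Emotiv-style CSV with JSON sidecar
#'
#' First row holds the channel names, one sample per row (uV). Sampling
#' rate, session metadata and any artifact ledger go to `<path>.json`.
#'
#' @param rec an `eeg_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_emotiv_csv <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  utils::write.csv(df, path, row.names = FALSE)
  ledger <- attr(rec, "artifacts")
  meta <- list(fs = rec$fs, meta = rec$meta,
               artifacts = if (is.null(ledger)) NULL else as.list(ledger))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an Emotiv-style CSV (with optional JSON sidecar)
#'
#' @param path CSV path as written by [write_emotiv_csv()] or exported from
#'   acquisition software (header = channel names, one sample per row).
#' @param fs sampling rate, used only when no sidecar is present.
#' @param meta metadata list, used only when no sidecar is present.
#' @return an `eeg_recording`.
#' @export
read_emotiv_csv <- function(path, fs = 128,
                            meta = list(subject = NA, session = NA,
                                        task = NA, stage = NA)) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- paste0(path, ".json")
  ledger <- NULL
  if (file.exists(side)) {
    js <- jsonlite::read_json(side, simplifyVector = TRUE)
    fs <- js$fs
    meta <- js$meta
    if (!is.null(js$artifacts) && length(js$artifacts))
      ledger <- tibble::as_tibble(js$artifacts)
  }
  montage <- emotiv_montage()
  stop_if_not(all(montage$channel %in% names(df)),
              "CSV is missing montage channels")
  rec <- new_recording(t(as.matrix(df[, montage$channel])), fs, meta, montage)
  if (!is.null(ledger)) attr(rec, "artifacts") <- ledger
  rec
}
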