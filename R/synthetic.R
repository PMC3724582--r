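# Seeded synthetic facial-EMG generation.
#
# Signals are modelled as amplitude-modulated, band-limited Gaussian
# processes: white Gaussian noise band-pass filtered to the EMG band,
# rescaled so the trial RMS tracks amplitude x envelope, plus independent
# broadband sensor noise. Gesture identity is carried entirely by a
# 3-channel amplitude signature (left temporalis, frontalis, right
# temporalis), which is what amplitude-type time-domain features respond to.

#' Facial gesture labels
#'
#' The ten facial gestures used as class labels, with short descriptions.
#' Channel convention throughout the package: channel 1 = left temporalis,
#' channel 2 = frontalis, channel 3 = right temporalis.
#'
#' @return Named character vector; names are `G1`..`G10`.
#' @export
emg_gestures <- function() {
  c(G1  = "opening the mouth",
    G2  = "clenching the molars",
    G3  = "raising the eyebrows",
    G4  = "closing both eyes",
    G5  = "closing the left eye",
    G6  = "closing the right eye",
    G7  = "frowning",
    G8  = "smiling with both sides of the mouth",
    G9  = "smiling with the left side of the mouth",
    G10 = "smiling with the right side of the mouth")
}

#' Simulation configuration
#'
#' Acquisition geometry and noise model for the synthetic facial-EMG
#' generator. Defaults emulate a three-channel surface recording at 1000 Hz
#' with five 2-s active trials per gesture.
#'
#' @param sampling_rate Sampling frequency in Hz.
#' @param trial_duration Active-signal duration of one trial, in ms.
#' @param trials_per_gesture Number of trials recorded per gesture.
#' @param band Length-2 numeric, low/high band edges in Hz of the EMG band.
#' @param noise_floor Standard deviation of additive broadband sensor noise,
#'   in arbitrary EMG units.
#' @param class_separation Multiplier on the inter-gesture amplitude
#'   contrast around the per-channel grand mean; gestures marked confusable
#'   keep their base contrast to their partner (it is shrunk back by
#'   `1/class_separation`).
#' @param seed Integer seed; together with the subject identifier it fully
#'   determines every sample.
#' @return A list of class `emg_sim_config`.
#' @export
emg_sim_config <- function(sampling_rate = 1000, trial_duration = 2000,
                           trials_per_gesture = 5, band = c(30, 450),
                           noise_floor = 0.05, class_separation = 1,
                           seed = 1L) {
  stopifnot(length(band) == 2, is.numeric(band))
  if (!(band[1] > 0 && band[1] < band[2])) {
    stop("invalid band: need 0 < low < high")
  }
  if (sampling_rate <= 2 * band[2]) {
    stop("sampling_rate must exceed twice the upper band edge (Nyquist)")
  }
  stopifnot(trial_duration > 0, trials_per_gesture >= 1,
            noise_floor >= 0, class_separation > 0)
  structure(list(sampling_rate = sampling_rate,
                 trial_duration = trial_duration,
                 trials_per_gesture = as.integer(trials_per_gesture),
                 band = as.numeric(band),
                 noise_floor = noise_floor,
                 class_separation = class_separation,
                 seed = as.integer(seed)),
            class = "emg_sim_config")
}

#' Gesture amplitude profile
#'
#' @param gesture_id Gesture label (e.g. `"G1"`).
#' @param amplitude Non-negative per-channel RMS amplitude signature
#'   (length 3 at the default channel count), arbitrary EMG units.
#' @param envelope_shape Within-trial amplitude modulation: `"constant"`
#'   (sustained contraction) or `"trapezoid"` (10% onset/offset ramps).
#' @param confusable_with Optional gesture_id sharing a signalling source;
#'   the pair's amplitude contrast is exempted from `class_separation`
#'   scaling (see [emg_sim_config()]).
#' @return A list of class `gesture_profile`.
#' @export
gesture_profile <- function(gesture_id, amplitude,
                            envelope_shape = c("constant", "trapezoid"),
                            confusable_with = NULL) {
  envelope_shape <- match.arg(envelope_shape)
  stopifnot(is.numeric(amplitude), all(amplitude >= 0))
  if (!is.null(confusable_with) && identical(confusable_with, gesture_id)) {
    stop("a gesture cannot be confusable with itself")
  }
  structure(list(gesture_id = gesture_id,
                 amplitude = as.numeric(amplitude),
                 envelope_shape = envelope_shape,
                 confusable_with = confusable_with),
            class = "gesture_profile")
}

#' Default gesture profiles
#'
#' Ten 3-channel amplitude signatures chosen so that muscles anatomically
#' involved in each gesture dominate its signature (temporalis channels for
#' jaw/smile gestures, frontalis for brow gestures, lateralized signatures
#' for one-sided gestures). Mouth opening (G1) and bilateral smiling (G8)
#' share a signalling source and are marked confusable: their signatures
#' differ only modestly, so they remain the most easily confused pair.
#'
#' @return Named list of [gesture_profile()] objects, `G1`..`G10`.
#' @export
default_gesture_profiles <- function() {
  amps <- list(
    G1  = c(0.70, 0.55, 0.70),
    G2  = c(1.20, 0.60, 1.20),
    G3  = c(0.60, 1.20, 0.60),
    G4  = c(0.80, 1.00, 0.80),
    G5  = c(0.95, 0.80, 0.60),
    G6  = c(0.60, 0.80, 0.95),
    G7  = c(0.75, 1.15, 0.75),
    G8  = c(0.80, 0.60, 0.80),
    G9  = c(1.00, 0.55, 0.65),
    G10 = c(0.65, 0.55, 1.00))
  profs <- lapply(names(amps), function(g) {
    gesture_profile(g, amps[[g]],
                    confusable_with = if (g == "G8") "G1")
  })
  names(profs) <- names(amps)
  profs
}

# Deterministic within-trial modulation, sampled at n points.
envelope_values <- function(shape, n) {
  if (shape == "constant") return(rep(1, n))
  ramp <- max(2L, round(0.1 * n))
  env <- rep(1, n)
  env[seq_len(ramp)] <- seq(0, 1, length.out = ramp)
  env[(n - ramp + 1L):n] <- seq(1, 0, length.out = ramp)
  env
}

#' Generate one synthetic EMG trial
#'
#' Each channel is white Gaussian noise band-pass filtered to the configured
#' band, rescaled to unit RMS, multiplied by `amplitude[channel] x envelope`,
#' plus independent Gaussian sensor noise of standard deviation
#' `noise_floor`. Every sample is a deterministic function of
#' `(config$seed, subject, gesture_id, trial, channel)`.
#'
#' @param profile A [gesture_profile()].
#' @param config An [emg_sim_config()].
#' @param trial 1-based trial index.
#' @param subject Subject identifier (character).
#' @return An `emg_recording`: list with `samples` (n x channels matrix),
#'   `sampling_rate`, `gesture_id`, `trial`, `subject`.
#' @export
#' @examples
#' rec <- generate_gesture_trial(default_gesture_profiles()$G1,
#'                               emg_sim_config(seed = 7), trial = 1)
#' dim(rec$samples)
generate_gesture_trial <- function(profile, config, trial, subject = "S1") {
  stopifnot(inherits(profile, "gesture_profile"),
            inherits(config, "emg_sim_config"),
            trial >= 1, trial <= config$trials_per_gesture)
  fs <- config$sampling_rate
  n <- round(config$trial_duration * fs / 1000)
  n_ch <- length(profile$amplitude)
  env <- envelope_values(profile$envelope_shape, n)
  samples <- matrix(0, nrow = n, ncol = n_ch)
  for (ch in seq_len(n_ch)) {
    s <- derive_seed(config$seed, subject, profile$gesture_id, trial, ch)
    old <- .Random.seed_save()
    set.seed(s)
    w <- stats::rnorm(n)
    y <- bandpass_filter(w, fs, config$band[1], config$band[2])
    y <- y / sqrt(mean(y^2))
    sig <- profile$amplitude[ch] * env * y
    if (config$noise_floor > 0) {
      sig <- sig + stats::rnorm(n, sd = config$noise_floor)
    }
    .Random.seed_restore(old)
    samples[, ch] <- sig
  }
  structure(list(samples = samples, sampling_rate = fs,
                 gesture_id = profile$gesture_id, trial = as.integer(trial),
                 subject = subject),
            class = "emg_recording")
}

# Save/restore the global RNG state so the generator does not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Effective per-gesture amplitudes after class_separation adjustment:
# contrast around the per-channel grand mean is scaled by cs, then a
# confusable gesture is pulled back towards its partner by 1/cs so the pair
# retains its base contrast. Amplitudes are floored at zero.
effective_amplitudes <- function(profiles, class_separation) {
  amps <- do.call(rbind, lapply(profiles, function(p) p$amplitude))
  rownames(amps) <- vapply(profiles, function(p) p$gesture_id, "")
  cs <- class_separation
  m <- colMeans(amps)
  scaled <- sweep(sweep(amps, 2, m, "-") * cs, 2, m, "+")
  for (p in profiles) {
    if (!is.null(p$confusable_with)) {
      g <- p$gesture_id
      partner <- p$confusable_with
      if (!partner %in% rownames(scaled)) next
      scaled[g, ] <- scaled[partner, ] +
        (scaled[g, ] - scaled[partner, ]) / cs
    }
  }
  pmax(scaled, 0)
}

#' Generate a full synthetic dataset for one subject
#'
#' Produces `trials_per_gesture` recordings per gesture. Inter-gesture
#' amplitude contrast is scaled by `config$class_separation` (confusable
#' pairs exempted; see [emg_sim_config()]).
#'
#' @param profiles Named list of [gesture_profile()]s with distinct ids.
#' @param config An [emg_sim_config()].
#' @param subject Subject identifier.
#' @return List of `emg_recording` objects (gesture-major order), with
#'   attributes `subject` and `config`.
#' @export
generate_dataset <- function(profiles = default_gesture_profiles(),
                             config = emg_sim_config(), subject = "S1") {
  ids <- vapply(profiles, function(p) p$gesture_id, "")
  if (anyDuplicated(ids)) stop("duplicate gesture_id in profiles")
  amps <- effective_amplitudes(profiles, config$class_separation)
  recs <- list()
  for (p in profiles) {
    p_eff <- p
    p_eff$amplitude <- amps[p$gesture_id, ]
    for (tr in seq_len(config$trials_per_gesture)) {
      recs[[length(recs) + 1L]] <-
        generate_gesture_trial(p_eff, config, tr, subject)
    }
  }
  structure(recs, subject = subject, config = config, class = "emg_dataset")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> subject %s, gesture %s, trial %d: %d samples x %d channels @ %g Hz\n",
              x$subject, x$gesture_id, x$trial,
              nrow(x$samples), ncol(x$samples), x$sampling_rate))
  invisible(x)
}

#' @export
print.emg_dataset <- function(x, ...) {
  g <- unique(vapply(x, function(r) r$gesture_id, ""))
  cat(sprintf("<emg_dataset> subject %s: %d recordings, %d gestures\n",
              attr(x, "subject"), length(x), length(g)))
  invisible(x)
}

#' Write a dataset to delimited text
#'
#' One long-format CSV per subject with columns
#' `subject,gesture,trial,channel,sample_index,value`, plus a JSON sidecar
#' holding the simulation configuration.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the CSV path.
#' @export
write_emg_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  subject <- attr(dataset, "subject")
  rows <- lapply(dataset, function(r) {
    n <- nrow(r$samples); n_ch <- ncol(r$samples)
    data.frame(subject = r$subject, gesture = r$gesture_id, trial = r$trial,
               channel = rep(seq_len(n_ch), each = n),
               sample_index = rep(seq_len(n), times = n_ch),
               value = as.vector(r$samples))
  })
  df <- do.call(rbind, rows)
  csv <- file.path(dir, paste0(subject, ".csv"))
  utils::write.csv(df, csv, row.names = FALSE)
  cfg <- attr(dataset, "config")
  jsonlite::write_json(unclass(cfg),
                       file.path(dir, paste0(subject, "_config.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Read a dataset written by [write_emg_dataset()]
#'
#' @param csv Path to the per-subject CSV; the `_config.json` sidecar is
#'   expected alongside it.
#' @return An `emg_dataset`.
#' @export
read_emg_dataset <- function(csv) {
  df <- utils::read.csv(csv)
  cfg_path <- sub("\\.csv$", "_config.json", csv)
  cfg_list <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  config <- do.call(emg_sim_config, cfg_list[setdiff(names(cfg_list), NULL)])
  subject <- df$subject[1]
  recs <- list()
  for (g in unique(df$gesture)) {
    for (tr in sort(unique(df$trial[df$gesture == g]))) {
      sub <- df[df$gesture == g & df$trial == tr, ]
      chans <- sort(unique(sub$channel))
      mat <- sapply(chans, function(ch) {
        s <- sub[sub$channel == ch, ]
        s$value[order(s$sample_index)]
      })
      recs[[length(recs) + 1L]] <- structure(
        list(samples = mat, sampling_rate = config$sampling_rate,
             gesture_id = g, trial = as.integer(tr), subject = subject),
        class = "emg_recording")
    }
  }
  structure(recs, subject = subject, config = config, class = "emg_dataset")
}
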