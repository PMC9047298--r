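#' Specify a synthetic squeal model
#'
#' A parametric generator of squeal-like audio with the statistical
#' structure the analysis pipeline assumes: a stack of harmonics of a
#' linearly gliding fundamental, whose amplitudes are flat up to a corner
#' frequency and roll off above it, plus additive white Gaussian noise at a
#' controlled signal-to-noise ratio. Lowering `rolloff_cutoff` condenses
#' spectral energy into the low frequencies — the signature change of the
#' impaired voice — without touching any other knob.
#'
#' @param f0_start,f0_end Fundamental frequency at clip start and end in Hz
#'   (linear glide). Healthy squeals are high-pitched; the default is a
#'   flat 1300 Hz contour so that the only pre/post contrast in a default
#'   cohort is the spectral-envelope attenuation itself (an intra-squeal
#'   glide adds sweep-driven spectral flux of its own; set
#'   `f0_start != f0_end` to study it).
#' @param n_harmonics Number of harmonics requested; harmonics whose
#'   frequency would reach the Nyquist limit anywhere along the glide are
#'   dropped.
#' @param rolloff_cutoff Corner frequency of the amplitude envelope in Hz.
#'   Harmonics below it have unit amplitude.
#' @param rolloff_db_per_octave Attenuation slope above the corner
#'   (default 12 dB/octave).
#' @param noise_snr_db Ratio of harmonic to noise power over the whole
#'   clip, in dB (default 20).
#' @param duration_s Clip duration in seconds (>= 0.3 so generated squeals
#'   are screenable; default 0.5).
#' @param amplitude_envelope Overall amplitude contour: `"hann"` (default,
#'   a smooth onset-offset shape) or `"flat"`.
#' @param seed Optional integer; fixes the harmonic phases and the noise so
#'   the clip is fully reproducible.
#' @return A `squeal_model` list.
#' @export
#' @examples
#' m <- squeal_model(rolloff_cutoff = 2000, seed = 1)
#' clip <- generate_squeal(m)
squeal_model <- function(f0_start = 1300, f0_end = 1300, n_harmonics = 30L,
                         rolloff_cutoff = 8000, rolloff_db_per_octave = 12,
                         noise_snr_db = 20, duration_s = 0.5,
                         amplitude_envelope = c("hann", "flat"),
                         seed = NULL) {
  amplitude_envelope <- match.arg(amplitude_envelope)
  if (duration_s < 0.3) {
    stop("`duration_s` must be >= 0.3 s (screening-compatible squeal)",
      call. = FALSE
    )
  }
  if (f0_start <= 0 || f0_end <= 0) stop("f0 contour must be > 0", call. = FALSE)
  if (n_harmonics < 1L) stop("`n_harmonics` must be >= 1", call. = FALSE)
  if (rolloff_cutoff <= 0) stop("`rolloff_cutoff` must be > 0", call. = FALSE)
  structure(
    list(
      f0_start = f0_start, f0_end = f0_end,
      n_harmonics = as.integer(n_harmonics),
      rolloff_cutoff = rolloff_cutoff,
      rolloff_db_per_octave = rolloff_db_per_octave,
      noise_snr_db = noise_snr_db, duration_s = duration_s,
      amplitude_envelope = amplitude_envelope, seed = seed
    ),
    class = "squeal_model"
  )
}

# Run code under a temporary RNG state when seed is given; otherwise use
# (and advance) the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Per-harmonic amplitudes of the rolloff envelope, evaluated at the
# mid-glide harmonic frequencies; harmonics reaching Nyquist are dropped.
harmonic_amplitudes <- function(model, sample_rate) {
  f0_max <- max(model$f0_start, model$f0_end)
  f0_mid <- (model$f0_start + model$f0_end) / 2
  k <- seq_len(model$n_harmonics)
  k <- k[k * f0_max < sample_rate / 2]
  if (length(k) == 0L) {
    stop("invalid model: every harmonic lies above the Nyquist frequency",
      call. = FALSE
    )
  }
  f_k <- k * f0_mid
  amp <- ifelse(
    f_k <= model$rolloff_cutoff, 1,
    10^(-(model$rolloff_db_per_octave / 20) *
      log2(f_k / model$rolloff_cutoff))
  )
  list(k = k, freq = f_k, amp = amp)
}

#' Generate one synthetic squeal
#'
#' Synthesizes the model: harmonics of the gliding fundamental with
#' rolloff-shaped amplitudes and random phases, plus white Gaussian noise
#' scaled to the model's SNR, the amplitude contour applied to the sum, and
#' the result peak-normalized into a [squeal_clip()]. Fully determined by
#' the model's `seed`.
#'
#' @param model A [squeal_model()].
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param id Clip identifier.
#' @return A [squeal_clip()].
#' @export
generate_squeal <- function(model, sample_rate = 44100, id = "synthetic") {
  stopifnot(inherits(model, "squeal_model"))
  with_seed(model$seed, {
    n <- as.integer(round(model$duration_s * sample_rate))
    t_idx <- seq_len(n)
    f0 <- model$f0_start +
      (model$f0_end - model$f0_start) * (t_idx - 1) / max(n - 1, 1)
    phase0 <- 2 * pi * cumsum(f0) / sample_rate

    hs <- harmonic_amplitudes(model, sample_rate)
    phi <- stats::runif(length(hs$k), 0, 2 * pi)
    sig <- numeric(n)
    for (i in seq_along(hs$k)) {
      sig <- sig + hs$amp[i] * sin(hs$k[i] * phase0 + phi[i])
    }

    sig_power <- mean(sig^2)
    noise_sd <- sqrt(sig_power / 10^(model$noise_snr_db / 10))
    x <- sig + stats::rnorm(n, 0, noise_sd)

    if (model$amplitude_envelope == "hann") {
      env <- 0.5 - 0.5 * cos(2 * pi * (t_idx - 1) / (n - 1))
      # keep a small floor so the clip never decays to digital silence
      x <- x * (0.05 + 0.95 * env)
    }
    squeal_clip(x, sample_rate, id = id)
  })
}

#' Expected Q50 of a squeal model
#'
#' Closed-form prediction of the 50% spectral energy quantile from the
#' harmonic amplitude profile alone (noise ignored): the frequency of the
#' first harmonic at which the cumulative squared amplitude reaches half
#' the total. Accurate for measured Q50 at high SNR.
#'
#' @inheritParams generate_squeal
#' @return Frequency in Hz.
#' @export
theoretical_q50 <- function(model, sample_rate = 44100) {
  hs <- harmonic_amplitudes(model, sample_rate)
  e <- hs$amp^2
  hs$freq[which(cumsum(e) >= 0.5 * sum(e))[1L]]
}

#' Perturbation magnitudes for cohort generation
#'
#' Relative standard deviations of the per-squeal random perturbations
#' applied by [generate_cohort()] to create within-group variance:
#' multiplicative log-normal jitter on the fundamental contour and the
#' rolloff corner, log-normal jitter on duration (floored at 0.3 s), and
#' additive Gaussian jitter on the SNR in dB.
#'
#' @param f0_rel,cutoff_rel,duration_rel Relative SDs (log scale).
#' @param snr_sd_db Additive SD of the per-squeal SNR in dB.
#' @return A `cohort_jitter` list.
#' @export
cohort_jitter <- function(f0_rel = 0.05, cutoff_rel = 0.10,
                          duration_rel = 0.15, snr_sd_db = 3) {
  structure(
    list(
      f0_rel = f0_rel, cutoff_rel = cutoff_rel,
      duration_rel = duration_rel, snr_sd_db = snr_sd_db
    ),
    class = "cohort_jitter"
  )
}

perturb_model <- function(model, jitter, seed) {
  f0_fac <- exp(stats::rnorm(1, 0, jitter$f0_rel))
  cut_fac <- exp(stats::rnorm(1, 0, jitter$cutoff_rel))
  dur <- max(0.3, model$duration_s * exp(stats::rnorm(1, 0, jitter$duration_rel)))
  snr <- model$noise_snr_db + stats::rnorm(1, 0, jitter$snr_sd_db)
  squeal_model(
    f0_start = model$f0_start * f0_fac,
    f0_end = model$f0_end * f0_fac,
    n_harmonics = model$n_harmonics,
    rolloff_cutoff = model$rolloff_cutoff * cut_fac,
    rolloff_db_per_octave = model$rolloff_db_per_octave,
    noise_snr_db = snr,
    duration_s = dur,
    amplitude_envelope = model$amplitude_envelope,
    seed = seed
  )
}

#' Generate a pre/post cohort of synthetic squeals with metadata
#'
#' Simulates one animal's recording sessions: `n_pre` squeals from the
#' pre-surgery model and `n_post` from the post-surgery model, each with
#' per-squeal random perturbations of the model fields (see
#' [cohort_jitter()]) to create realistic within-group variance. Metadata
#' is prefilled: phase labels, three per-rater noise scores drawn with
#' probabilities 0.6 / 0.3 / 0.1 for ratings 0 / 1 / 2, and artifact flags
#' set to `FALSE`. Fully reproducible from `seed`.
#'
#' @param pre_model,post_model [squeal_model()] objects for the two phases.
#' @param n_pre,n_post Squeal counts per phase (>= 1).
#' @param pig_id Animal label attached to every row.
#' @param jitter A [cohort_jitter()].
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed controlling perturbations, phases, noise and
#'   ratings.
#' @return A tibble with one row per squeal: `clip_id`, `pig_id`, `phase`
#'   (`"pre"`/`"post"`), `duration`, `ratings` (list-column), `artifact`
#'   and the list-column `clip`.
#' @export
#' @examples
#' cohort <- generate_cohort(
#'   squeal_model(duration_s = 0.35),
#'   squeal_model(rolloff_cutoff = 2000, duration_s = 0.35),
#'   n_pre = 3, n_post = 3, seed = 42
#' )
#' cohort
generate_cohort <- function(pre_model, post_model, n_pre = 20L, n_post = 20L,
                            pig_id = "pig1", jitter = cohort_jitter(),
                            sample_rate = 44100, seed = NULL) {
  stopifnot(inherits(pre_model, "squeal_model"),
    inherits(post_model, "squeal_model")
  )
  if (n_pre < 1L || n_post < 1L) {
    stop("`n_pre` and `n_post` must be >= 1", call. = FALSE)
  }
  with_seed(seed, {
    phases <- c(rep("pre", n_pre), rep("post", n_post))
    models <- c(rep(list(pre_model), n_pre), rep(list(post_model), n_post))
    n_total <- n_pre + n_post
    clip_seeds <- sample.int(.Machine$integer.max, n_total)
    rows <- purrr::map(seq_len(n_total), function(i) {
      m <- perturb_model(models[[i]], jitter, seed = clip_seeds[i])
      clip_id <- sprintf("%s_%s_%03d", pig_id, phases[i], i)
      clip <- generate_squeal(m, sample_rate = sample_rate, id = clip_id)
      ratings <- sample(0:2, 3L, replace = TRUE, prob = c(0.6, 0.3, 0.1))
      tibble::tibble(
        clip_id = clip_id, pig_id = pig_id, phase = phases[i],
        duration = clip_duration(clip), ratings = list(ratings),
        artifact = FALSE, clip = list(clip)
      )
    })
    dplyr::bind_rows(rows)
  })
}
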