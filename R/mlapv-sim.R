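#' Multi-frequency pulse excitation specification
#'
#' Describes one MLAPV excitation cycle: a train of square pulses at each
#' of several frequencies, every frequency segment stepping through the
#' same ladder of pulse amplitudes, with zero-valued blank intervals
#' between segments (a cooling-off period for the electrodes). Defaults
#' follow a 60 s cycle sampled at 150 Hz with segments at 0.2, 1 and 2 Hz
#' and effective solution voltages of 1.0 down to 0.2 V, i.e. 9000 points
#' per electrode per cycle.
#'
#' Each segment is active for `length(pulse_amplitudes)` pulse periods
#' (25, 5 and 2.5 s at the default frequencies); the remaining cycle time
#' is split equally between the inter-segment blanks.
#'
#' @param segment_frequencies pulse frequencies in Hz.
#' @param pulse_amplitudes pulse amplitudes in V (applied in order within
#'   every segment).
#' @param cycle_duration cycle length in seconds.
#' @param sampling_rate samples per second.
#' @return object of class `excitation_spec`.
#' @examples
#' sp <- excitation_spec()
#' length(build_excitation(sp))  # 9000
#' @export
excitation_spec <- function(segment_frequencies = c(0.2, 1, 2),
                            pulse_amplitudes = c(1.0, 0.8, 0.6, 0.4, 0.2),
                            cycle_duration = 60,
                            sampling_rate = 150) {
  if (any(segment_frequencies <= 0)) stop("frequencies must be positive")
  if (cycle_duration <= 0 || sampling_rate <= 0)
    stop("'cycle_duration' and 'sampling_rate' must be positive")
  n_pulses <- length(pulse_amplitudes)
  active <- n_pulses / segment_frequencies
  if (sum(active) > cycle_duration)
    stop("active pulse time (", sum(active), " s) exceeds the cycle ",
         "duration (", cycle_duration, " s)")
  n_gaps <- max(length(segment_frequencies) - 1L, 0L)
  blank <- if (n_gaps > 0) (cycle_duration - sum(active)) / n_gaps else 0
  structure(list(segment_frequencies = segment_frequencies,
                 pulse_amplitudes = pulse_amplitudes,
                 cycle_duration = cycle_duration,
                 sampling_rate = sampling_rate,
                 segment_active = active,
                 blank_duration = blank),
            class = "excitation_spec")
}

# internal: waveform plus per-sample pulse-amplitude index (0 = off/blank)
excitation_parts <- function(spec) {
  stopifnot(inherits(spec, "excitation_spec"))
  n <- round(spec$cycle_duration * spec$sampling_rate)
  t <- (seq_len(n) - 1L) / spec$sampling_rate
  wave <- numeric(n)
  pulse_id <- integer(n)
  n_pulses <- length(spec$pulse_amplitudes)
  start <- 0
  for (s in seq_along(spec$segment_frequencies)) {
    f <- spec$segment_frequencies[s]
    seg_len <- spec$segment_active[s]
    local <- t - start
    in_seg <- local >= 0 & local < seg_len
    phase <- local[in_seg] * f
    k <- pmin(floor(phase) + 1L, n_pulses)   # pulse index within segment
    on <- (phase - floor(phase)) < 0.5       # 50% duty cycle
    idx <- which(in_seg)
    wave[idx[on]] <- spec$pulse_amplitudes[k[on]]
    pulse_id[idx[on]] <- k[on]
    start <- start + seg_len + spec$blank_duration
  }
  list(wave = wave, pulse_id = pulse_id, n = n, t = t)
}

#' Build an MLAPV excitation waveform
#'
#' @param spec an [excitation_spec()].
#' @return numeric vector of length
#'   `round(cycle_duration * sampling_rate)`; pulse plateaus at the given
#'   amplitudes, zeros during off half-periods and blanks.
#' @export
build_excitation <- function(spec) {
  excitation_parts(spec)$wave
}

#' Electrode-array response model
#'
#' Parameterizes the simulated response of a working-electrode array to an
#' MLAPV excitation. The current of electrode `e` is modelled as
#' \deqn{x_e(t) = g_{cm} \, s(t) +
#'   \mathrm{transient}\big(w(t)\,[b_e + c^{\alpha} G_{k,e,p(t)}];\;
#'   \tau_e \tau_{k,e}\big) + \varepsilon(t),}
#' where `s(t)` is a shared excitation-locked template (identical across
#' electrodes — the common-mode part that carries no class information),
#' `w(t)` the excitation waveform, `b_e` a class-independent background
#' sensitivity (double-layer/electrolyte charging, present regardless of
#' the analyte), `G[k, e, p]` the per-(class, electrode, pulse) analyte
#' gain fingerprint scaled by concentration `c^alpha`, and the transient a
#' first-order (RC-style) charge/discharge response to the pulse edges
#' with a time constant modulated per (class, electrode) — liquids alter
#' the interface kinetics, not just the amplitudes. `eps` is Gaussian
#' instrument noise.
#'
#' Default magnitudes span the wide dynamic ranges typical of liquid
#' sensing with a cross-sensitive mixed-metal array: per-electrode pulse
#' sensitivities of 0.35 down to 0.1 uA/V, per-(class, electrode)
#' magnitudes covering more than six orders of magnitude (strong
#' electrolytes versus weakly conducting liquids, active versus passive
#' electrode/liquid pairings), transient time constants 0.07-0.9 s, a
#' common-mode amplitude at least ten times the strongest specificity
#' amplitude, sub-linear concentration response (activity saturation in
#' concentrated stocks), and 0.0001 uA r.m.s. instrument noise.
#'
#' @param n_electrodes number of working electrodes.
#' @param pulse_sensitivity per-electrode analyte gain scale (uA per V of
#'   pulse).
#' @param baseline_gain per-electrode class-independent background
#'   sensitivity (uA/V); defaults to `pulse_sensitivity`.
#' @param decay_constants per-electrode transient time constants in s.
#' @param common_mode_gain amplitude of the shared excitation-locked
#'   template (same units as the specificity gains).
#' @param common_mode_tau time constant of the shared template in s.
#' @param noise_sd standard deviation of additive Gaussian noise (uA).
#' @param concentration_exponent exponent mapping concentration fraction
#'   to gain scaling.
#' @param class_gain_sdlog lognormal sdlog of the per-(class, electrode,
#'   pulse) fingerprint drawn around `pulse_sensitivity`. A share of this
#'   variation (`class_gain_shared`) is common to all electrodes — the
#'   liquid's redox chemistry drives every electrode with the same pulse
#'   pattern — and the rest is electrode-specific.
#' @param class_gain_shared fraction (0-1) of the squared log-variation of
#'   the gain fingerprint shared across electrodes.
#' @param class_magnitude_decades per-(class, electrode) response
#'   magnitudes, in decades: each liquid excites the array over a wide
#'   dynamic range — some electrodes strongly, others barely — with the
#'   loud/quiet pattern specific to the liquid. Each class's log10
#'   magnitudes are a random permutation of a fixed rung ladder plus
#'   jitter, so every liquid spans the range while cross-sensitivity
#'   patterns differ. A scalar gives `n_electrodes` rungs evenly spaced
#'   over `[-decades, +decades]`; a length-`n_electrodes` vector gives the
#'   rungs directly.
#' @param class_tau_sdlog lognormal sdlog of the per-(class, electrode)
#'   time-constant modulation.
#' @param replicate_sdlog lognormal sdlog of per-replicate electrode
#'   drift.
#' @param electrode_ids electrode identifiers.
#' @return object of class `electrode_model`.
#' @export
electrode_model <- function(n_electrodes = 6,
                            pulse_sensitivity = c(0.35, 0.25, 0.2,
                                                  0.16, 0.13, 0.1),
                            baseline_gain = 0,
                            decay_constants = c(0.9, 0.55, 0.35,
                                                0.2, 0.12, 0.07),
                            common_mode_gain = 2e4,
                            common_mode_tau = 0.5,
                            noise_sd = 1e-4,
                            concentration_exponent = 0.35,
                            class_gain_sdlog = 0.8,
                            class_gain_shared = 0.7,
                            class_magnitude_decades = c(-3.2, -2.0, -1.8,
                                                        -0.5, 1.2, 3.0),
                            class_tau_sdlog = 0.3,
                            replicate_sdlog = 0.01,
                            electrode_ids = c("Au", "Pt", "Pd",
                                              "Ti", "W", "Ag")) {
  n_electrodes <- as.integer(n_electrodes)
  if (n_electrodes < 2L) stop("need at least 2 electrodes")
  recycle <- function(v) rep_len(v, n_electrodes)
  pulse_sensitivity <- recycle(pulse_sensitivity)
  baseline_gain <- recycle(baseline_gain)
  decay_constants <- recycle(decay_constants)
  electrode_ids <- if (length(electrode_ids) >= n_electrodes)
    electrode_ids[seq_len(n_electrodes)]
  else paste0("E", seq_len(n_electrodes))
  if (any(decay_constants <= 0)) stop("decay constants must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!all(is.finite(pulse_sensitivity)) || !all(is.finite(baseline_gain)))
    stop("gains must be finite")
  structure(list(n_electrodes = n_electrodes,
                 pulse_sensitivity = pulse_sensitivity,
                 baseline_gain = baseline_gain,
                 decay_constants = decay_constants,
                 common_mode_gain = common_mode_gain,
                 common_mode_tau = common_mode_tau,
                 noise_sd = noise_sd,
                 concentration_exponent = concentration_exponent,
                 class_gain_sdlog = class_gain_sdlog,
                 class_gain_shared = class_gain_shared,
                 class_magnitude_decades = class_magnitude_decades,
                 class_tau_sdlog = class_tau_sdlog,
                 replicate_sdlog = replicate_sdlog,
                 electrode_ids = electrode_ids),
            class = "electrode_model")
}

# internal: first-order high-pass (RC differentiator) response to the
# excitation edges: decaying exponential spike at each rise/fall
edge_transient <- function(u, tau, fs) {
  alpha <- exp(-1 / (tau * fs))
  du <- c(u[1], diff(u))
  as.numeric(stats::filter(du, alpha, method = "recursive"))
}

# internal: draw the per-class fingerprints — gain per (class, electrode,
# pulse) and time-constant modulation per (class, electrode)
draw_class_gains <- function(model, class_names, n_pulses) {
  C <- length(class_names)
  m <- model$n_electrodes
  sh <- sqrt(model$class_gain_shared) * model$class_gain_sdlog
  ind <- sqrt(1 - model$class_gain_shared) * model$class_gain_sdlog
  g_shared <- array(rep(stats::rnorm(C * n_pulses, 0, sh), times = m),
                    dim = c(C, n_pulses, m))
  g <- aperm(g_shared, c(1, 3, 2)) +
    array(stats::rnorm(C * m * n_pulses, 0, ind), dim = c(C, m, n_pulses))
  dimnames(g) <- list(class_names, model$electrode_ids, NULL)
  base <- array(rep(model$pulse_sensitivity, each = C), dim = c(C, m, n_pulses))
  r <- model$class_magnitude_decades
  rungs <- if (length(r) == 1L) seq(-r, r, length.out = m) else rep_len(r, m)
  half_step <- if (m > 1) mean(diff(sort(rungs))) / 2 else abs(r)
  mag_log <- t(vapply(seq_len(C), function(i)
    sample(rungs) + stats::runif(m, -half_step, half_step), numeric(m)))
  magnitude <- array(10^mag_log, dim = c(C, m, n_pulses))
  tau_mod <- matrix(exp(stats::rnorm(C * m, 0, model$class_tau_sdlog)),
                    C, m, dimnames = list(class_names, model$electrode_ids))
  list(gains = magnitude * base * exp(g), tau_mod = tau_mod)
}

#' Simulate the response of one sample
#'
#' Generates the `m x d` response matrix of one measurement: every
#' electrode shares the same common-mode template; class identity and
#' concentration act only on the per-electrode transient amplitudes.
#' Randomness (noise, replicate drift) comes from the current RNG state,
#' so calls are reproducible under [set.seed()].
#'
#' @param parts output of the internal excitation decomposition, or an
#'   [excitation_spec()] (decomposed on the fly).
#' @param model an [electrode_model()].
#' @param gains `m x n_pulses` matrix of this class's gain fingerprint.
#' @param concentration fraction in (0, 1].
#' @param tau_mod length-`m` multiplier on the electrode time constants
#'   (this class's kinetic fingerprint; default 1).
#' @param label,sample_id passed to [sensor_sample()].
#' @return a [sensor_sample()].
#' @export
simulate_sample <- function(parts, model, gains, concentration = 1,
                            tau_mod = 1, label = NULL, sample_id = NULL) {
  if (inherits(parts, "excitation_spec")) {
    spec <- parts
    parts <- excitation_parts(parts)
    parts$fs <- spec$sampling_rate
  }
  fs <- parts$fs
  if (!is.numeric(concentration) || concentration <= 0 || concentration > 1)
    stop("'concentration' must be in (0, 1]")
  m <- model$n_electrodes
  n <- parts$n
  tau_mod <- rep_len(tau_mod, m)
  template <- edge_transient(parts$wave, model$common_mode_tau, fs)
  cm <- model$common_mode_gain * template
  conc_scale <- concentration^model$concentration_exponent
  drift <- exp(stats::rnorm(m, 0, model$replicate_sdlog))
  X <- matrix(0, m, n)
  gains <- as.matrix(gains)
  for (e in seq_len(m)) {
    # per-pulse amplitude: class-independent background plus the
    # concentration-scaled analyte fingerprint of this electrode
    amp <- model$baseline_gain[e] +
      conc_scale * drift[e] * gains[e, ][pmax(parts$pulse_id, 1L)]
    u <- parts$wave * amp * (parts$pulse_id > 0L)
    tr <- edge_transient(u, model$decay_constants[e] * tau_mod[e], fs)
    X[e, ] <- cm + tr
  }
  if (model$noise_sd > 0)
    X <- X + matrix(stats::rnorm(m * n, 0, model$noise_sd), m, n)
  sensor_sample(X, electrode_ids = model$electrode_ids, label = label,
                sample_id = sample_id)
}

# internal: shared driver for the dataset builders
simulate_dataset <- function(class_names, concentrations, replicates_per,
                             excitation, model, seed, design) {
  restore <- local_rng(seed)
  on.exit(restore())
  parts <- excitation_parts(excitation)
  parts$fs <- excitation$sampling_rate
  n_pulses <- length(excitation$pulse_amplitudes)
  fp <- draw_class_gains(model, class_names, n_pulses)
  samples <- list(); labels <- character(); conc <- numeric(); rep_id <- integer()
  k <- 0L
  for (ci in seq_along(class_names)) {
    cls <- class_names[ci]
    plan <- design[[ci]]  # data.frame: concentration, replicate
    for (r in seq_len(nrow(plan))) {
      k <- k + 1L
      samples[[k]] <- simulate_sample(
        parts, model, fp$gains[ci, , ], concentration = plan$concentration[r],
        tau_mod = fp$tau_mod[ci, ], label = cls,
        sample_id = sprintf("%s_c%02d_r%02d", cls,
                            round(100 * plan$concentration[r]),
                            plan$replicate[r]))
      labels[k] <- cls
      conc[k] <- plan$concentration[r]
      rep_id[k] <- plan$replicate[r]
    }
  }
  labeled_dataset(samples, labels, concentration = conc, replicate = rep_id,
                  provenance = list(seed = seed,
                                    excitation = unclass(excitation),
                                    model = unclass(model),
                                    schema_version = 1L))
}

#' Simulate a beverage-panel dataset
#'
#' Builds the full factorial beverage design: every class measured at each
#' concentration with independent replicates. The default — 7 beverages x
#' 3 concentrations (14%, 25%, 100%) x 3 replicates = 63 samples, each a
#' 6 x 9000 matrix (60 s cycle at 150 Hz) — matches the design of a
#' self-made MLAPV e-tongue beverage panel.
#'
#' @param class_names beverage class identifiers.
#' @param concentrations dilution fractions in (0, 1].
#' @param replicates replicate measurements per (class, concentration).
#' @param excitation an [excitation_spec()].
#' @param model an [electrode_model()].
#' @param seed integer seed; the dataset is a deterministic function of
#'   the spec and this seed.
#' @return a [labeled_dataset()].
#' @examples
#' \donttest{
#' d <- simulate_beverage_dataset(seed = 1)
#' n_samples(d)  # 63
#' }
#' @export
simulate_beverage_dataset <- function(class_names = c("red_wine",
                                                      "white_spirit",
                                                      "beer", "oolong_tea",
                                                      "black_tea",
                                                      "maofeng_tea",
                                                      "puer_tea"),
                                      concentrations = c(0.14, 0.25, 1.00),
                                      replicates = 3,
                                      excitation = excitation_spec(),
                                      model = electrode_model(),
                                      seed = 1) {
  if (any(concentrations <= 0 | concentrations > 1))
    stop("'concentrations' must lie in (0, 1]")
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("'replicates' must be >= 1")
  plan <- expand.grid(replicate = seq_len(replicates),
                      concentration = concentrations)
  plan <- plan[order(plan$concentration, plan$replicate), ]
  design <- rep(list(plan), length(class_names))
  simulate_dataset(class_names, concentrations, replicates, excitation,
                   model, seed, design)
}

#' Simulate a benchmark-style dataset
#'
#' Mimics a public LAPV e-tongue benchmark: 13 liquid classes, 114 samples
#' in total, each a 6 x 2050 matrix. 114 does not divide by 13; the most
#' even partition is used (ten classes of 9 samples, three of 8). All
#' samples are at full concentration; within-class variation comes from
#' replicate drift and noise.
#'
#' @param class_names class identifiers (13 by default).
#' @param n_total total sample count (114 by default).
#' @param excitation an [excitation_spec()]; the default keeps the 60 s
#'   cycle but samples it at 2050 points.
#' @param model an [electrode_model()].
#' @param seed integer seed.
#' @return a [labeled_dataset()].
#' @export
simulate_benchmark_dataset <- function(class_names = c("beer", "red_wine",
                                                       "white_spirit",
                                                       "black_tea",
                                                       "maofeng_tea",
                                                       "puer_tea",
                                                       "oolong_tea",
                                                       "coffee", "milk",
                                                       "cola", "vinegar",
                                                       "medicine", "salt"),
                                       n_total = 114,
                                       excitation = excitation_spec(
                                         sampling_rate = 2050 / 60),
                                       model = electrode_model(),
                                       seed = 1) {
  C <- length(class_names)
  n_total <- as.integer(n_total)
  base <- n_total %/% C
  extra <- n_total %% C
  if (base < 4L)
    stop("cannot place every class in every four-fold group: ",
         "only ", base, " samples per class")
  sizes <- rep(base, C)
  if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
  design <- lapply(sizes, function(s)
    data.frame(concentration = 1, replicate = seq_len(s)))
  simulate_dataset(class_names, 1, NA, excitation, model, seed, design)
}
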