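# Synthetic generators for the three assay modalities: tethered-larva
# startle trials, two-channel calcium traces, and paired predation
# incubations. Each generator is deterministic given its rng_seed and
# records the ground truth that downstream estimators are tested against.

#' Configuration for synthetic startle-behavior trials
#'
#' Emulates tethered-larva stimulation experiments: per-trial filament
#' speed, a bimodal normalized parapodial elevation angle drawn from a
#' two-component truncated-Gaussian mixture (the low-angle / wide-angle
#' split), ciliary-closure flags whose probability rises with filament
#' speed past a threshold, and onset frames consistent with per-response
#' latency distributions.
#'
#' @param n_larvae Number of larvae; each is stimulated once per speed.
#' @param speeds Filament speeds tested (µm/ms).
#' @param mixture_weights,mixture_means,mixture_sds Two-component mixture
#'   parameters on the normalized-angle scale \[0, 1\]; weights must sum
#'   to 1 and means must be strictly ordered inside \[0, 1\].
#' @param closure_threshold_speed Speed (µm/ms) at which the closure
#'   probability passes 1/2; the probability is logistic in speed with
#'   slope `closure_slope`, so a threshold of 0 puts every tested speed at
#'   the model's ceiling.
#' @param closure_slope Logistic slope (µm/ms) of the closure probability.
#' @param latency_distributions Named list of `c(location, scale)` pairs
#'   (ms) for `wideE`, `lowE`, `prototroch` and `bodytroch` onsets.
#'   Defaults follow the reported medians (wide-angle ~32 ms, prototroch
#'   closure ~65 ms, bodytroch ~46 ms; low-angle onsets are slow and
#'   imprecise).
#' @param fps Recording speed (frames/s); tethered recordings were made at
#'   230-350 fps, default 250.
#' @param stim_start_frame Frame index of stimulus onset.
#' @param rng_seed Integer seed.
#' @return An object of class `behavior_config`.
#' @export
behavior_config <- function(n_larvae = 9,
                            speeds = seq(5, 95, by = 10),
                            mixture_weights = c(0.35, 0.65),
                            mixture_means = c(0.2, 0.75),
                            mixture_sds = c(0.08, 0.12),
                            closure_threshold_speed = 8,
                            closure_slope = 3,
                            latency_distributions = list(
                              wideE = c(location = 32, scale = 6),
                              lowE = c(location = 90, scale = 25),
                              prototroch = c(location = 65, scale = 15),
                              bodytroch = c(location = 46, scale = 10)),
                            fps = 250,
                            stim_start_frame = 100L,
                            rng_seed = 1L) {
  if (length(mixture_weights) != 2 || abs(sum(mixture_weights) - 1) > 1e-8)
    stopf("`mixture_weights` must be two values summing to 1")
  if (length(mixture_means) != 2 || any(mixture_means < 0 | mixture_means > 1))
    stopf("`mixture_means` must lie in [0, 1]")
  if (diff(mixture_means) <= 0)
    stopf("`mixture_means` must be strictly ordered")
  if (length(mixture_sds) != 2 || any(mixture_sds < 0))
    stopf("`mixture_sds` must be two non-negative values")
  check_pos(fps, "fps")
  structure(list(
    n_larvae = as.integer(n_larvae), speeds = speeds,
    mixture_weights = mixture_weights, mixture_means = mixture_means,
    mixture_sds = mixture_sds,
    closure_threshold_speed = closure_threshold_speed,
    closure_slope = closure_slope,
    latency_distributions = latency_distributions,
    fps = fps, stim_start_frame = as.integer(stim_start_frame),
    rng_seed = as.integer(rng_seed)
  ), class = "behavior_config")
}

#' Draw from a Gaussian truncated to [0, 1]
#' @noRd
rtruncnorm01 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  lo <- pnorm(0, mean, sd); hi <- pnorm(1, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Generate synthetic startle trials
#'
#' @param cfg A [behavior_config()].
#' @return A data frame with one row per trial: identifiers
#'   (`larva_id`, `genotype`, `stimulus_site`, `stimulus_distance`),
#'   kinematics (`filament_speed`, `fps`, `max_elevation_angle` in degrees,
#'   closure flags, stimulus/onset frame indices, left/right and
#'   per-segment elevation onsets) and ground-truth columns
#'   (`true_component` 1 = low-angle, 2 = wide-angle; `true_norm_angle`).
#' @export
gen_behavior_trials <- function(cfg) {
  stopifnot(inherits(cfg, "behavior_config"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$rng_seed)

  grid <- expand.grid(larva_id = seq_len(cfg$n_larvae),
                      filament_speed = cfg$speeds)
  n <- nrow(grid)
  comp <- 1L + (runif(n) < cfg$mixture_weights[2])
  ang <- numeric(n)
  for (k in 1:2) {
    idx <- comp == k
    ang[idx] <- rtruncnorm01(sum(idx), cfg$mixture_means[k], cfg$mixture_sds[k])
  }
  # each larva has its own absolute angular range; 0-degree rest is exact
  larva_max <- runif(cfg$n_larvae, 35, 60)
  angle_deg <- ang * larva_max[grid$larva_id]

  p_close <- stats::plogis((grid$filament_speed - cfg$closure_threshold_speed) /
                             cfg$closure_slope)
  proto <- runif(n) < p_close
  body <- proto & runif(n) < 0.9

  lat <- function(which, n) {
    p <- cfg$latency_distributions[[which]]
    pmax(rnorm(n, p[["location"]], p[["scale"]]), 1000 / cfg$fps)
  }
  to_frame <- function(ms) cfg$stim_start_frame + as.integer(round(ms * cfg$fps / 1000))
  elev_ms <- ifelse(comp == 2L, lat("wideE", n), lat("lowE", n))
  elev_frame <- to_frame(elev_ms)
  proto_frame <- ifelse(proto, to_frame(lat("prototroch", n)), NA_integer_)
  body_frame <- ifelse(body, to_frame(lat("bodytroch", n)), NA_integer_)
  # left-right and intersegmental onsets: same frame or one frame apart
  lr_off <- sample(0:1, n, replace = TRUE, prob = c(0.8, 0.2))
  sg_off2 <- sample(0:1, n, replace = TRUE)
  sg_off3 <- sg_off2 + sample(0:1, n, replace = TRUE)

  data.frame(
    grid,
    genotype = "wildtype", stimulus_site = "anterior", stimulus_distance = 100,
    fps = cfg$fps,
    max_elevation_angle = angle_deg,
    prototroch_closed = proto, bodytroch_closed = body,
    stim_start_frame = cfg$stim_start_frame,
    elevation_onset_frame = elev_frame,
    prototroch_closure_frame = proto_frame,
    bodytroch_closure_frame = body_frame,
    elevation_onset_left = elev_frame,
    elevation_onset_right = elev_frame + lr_off,
    elevation_onset_sg1 = elev_frame,
    elevation_onset_sg2 = elev_frame + sg_off2,
    elevation_onset_sg3 = elev_frame + sg_off3,
    true_component = comp,
    true_norm_angle = ang
  )
}

#' Configuration for synthetic two-channel fluorescence traces
#'
#' Emulates paired GCaMP6s (calcium reporter) / tdTomato (calcium
#' insensitive reference) recordings around a vibration stimulus. The
#' reporter channel carries a difference-of-exponentials transient; both
#' channels are multiplied by one shared smooth drift trajectory (the
#' focal Z-shift artifact the ratiometric formula is designed to cancel)
#' and offset by channel backgrounds before noise.
#'
#' @param n_trials Number of trials.
#' @param sampling_rate Hz (recordings were made at 4 Hz, a few at 2.6 Hz).
#' @param pre_stim_duration,post_stim_duration Seconds before/after stimulus.
#' @param baseline_g,baseline_t Channel baselines (arbitrary fluorescence
#'   units), above their backgrounds.
#' @param transient_amplitude Peak fractional response of the reporter
#'   (1.5 means the ratiometric trace peaks at 2.5).
#' @param rise_tau,decay_tau Transient time constants (s); GCaMP6s decays
#'   slowly.
#' @param drift_amplitude Relative amplitude of the shared multiplicative
#'   drift (sinusoid plus linear trend).
#' @param noise_sd Relative Gaussian noise per channel.
#' @param background_g,background_t Scalar non-tissue background levels.
#' @param rng_seed Integer seed.
#' @return An object of class `trace_config`.
#' @export
trace_config <- function(n_trials = 16,
                         sampling_rate = 4,
                         pre_stim_duration = 10,
                         post_stim_duration = 30,
                         baseline_g = 200, baseline_t = 400,
                         transient_amplitude = 1.5,
                         rise_tau = 0.5, decay_tau = 4,
                         drift_amplitude = 0.1,
                         noise_sd = 0.01,
                         background_g = 20, background_t = 30,
                         rng_seed = 1L) {
  check_pos(sampling_rate, "sampling_rate")
  check_pos(rise_tau, "rise_tau"); check_pos(decay_tau, "decay_tau")
  if (baseline_g <= background_g || baseline_t <= background_t)
    stopf("baselines must exceed their backgrounds")
  if (background_g < 0 || background_t < 0)
    stopf("backgrounds must be >= 0")
  structure(as.list(environment()), class = "trace_config")
}

#' Generate synthetic fluorescence traces with known transient amplitude
#'
#' The transient kernel is normalised to peak at exactly 1 on the sample
#' grid, so with zero noise the planted amplitude is recovered exactly by
#' the ratiometric stage.
#'
#' @param cfg A [trace_config()].
#' @return A list of class `synthetic_traces`: `traces` (a list of
#'   [fluorescence_trace()] objects) and `ground_truth` (planted
#'   `transient_amplitude`).
#' @export
gen_traces <- function(cfg) {
  stopifnot(inherits(cfg, "trace_config"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$rng_seed)

  dt <- 1 / cfg$sampling_rate
  time <- seq(0, cfg$pre_stim_duration + cfg$post_stim_duration, by = dt)
  stim <- cfg$pre_stim_duration
  rel <- pmax(time - stim, 0)
  kern <- exp(-rel / cfg$decay_tau) - exp(-rel / cfg$rise_tau)
  kern[rel == 0] <- 0
  if (max(kern) > 0) kern <- kern / max(kern)

  traces <- lapply(seq_len(cfg$n_trials), function(i) {
    phase <- runif(1, 0, 2 * pi)
    period <- runif(1, 20, 60)
    lin <- runif(1, -1, 1)
    span <- max(time)
    drift <- 1 + cfg$drift_amplitude *
      (0.6 * sin(2 * pi * time / period + phase) + 0.4 * lin * (time - span / 2) / span)
    fg <- cfg$background_g +
      cfg$baseline_g * (1 + cfg$transient_amplitude * kern) * drift +
      cfg$noise_sd * cfg$baseline_g * rnorm(length(time))
    ft <- cfg$background_t + cfg$baseline_t * drift +
      cfg$noise_sd * cfg$baseline_t * rnorm(length(time))
    fluorescence_trace(time = time, F_gcamp = fg, F_tdtom = ft,
                       bg_gcamp = cfg$background_g, bg_tdtom = cfg$background_t,
                       stim_start = stim, sampling_rate = cfg$sampling_rate)
  })
  structure(list(traces = traces,
                 ground_truth = list(transient_amplitude = cfg$transient_amplitude)),
            class = "synthetic_traces")
}

#' Configuration for synthetic paired predation experiments
#'
#' Emulates paired incubations in which equal numbers of wildtype and
#' startle-deficient mutant larvae share a container with copepod
#' predators, with a parallel no-copepod control per experiment. Survivor
#' counts are binomial; a batch-level random effect on the consumption
#' probability (shared by both genotypes in a batch) makes the pairing
#' informative, and an independent small background mortality affects all
#' trials including controls.
#'
#' @param n_batches,trials_per_batch Experimental structure (the study ran
#'   42 trials over 12 batches, in duplicates or triplicates).
#' @param prey_per_genotype Larvae of each genotype per container
#'   (default 25).
#' @param volume_L Container volume in litres (default 0.2).
#' @param predators Copepods added per container.
#' @param predator_survival_prob Per-copepod probability of being alive at
#'   the end of the incubation.
#' @param duration_days Incubation time in days (the study used 0.5 or 1).
#' @param baseline_consumption_prob Probability that a wildtype larva is
#'   consumed during the incubation.
#' @param mutant_effect Additive shift of the consumption probability for
#'   mutant larvae (the startle-defect effect).
#' @param batch_effect_sd SD of the batch-level logit-scale random effect
#'   on consumption.
#' @param background_mortality Predation-independent death probability
#'   (controls showed >= 86% survival).
#' @param rng_seed Integer seed.
#' @return An object of class `predation_config`.
#' @export
predation_config <- function(n_batches = 12, trials_per_batch = 3,
                             prey_per_genotype = 25,
                             volume_L = 0.2,
                             predators = 5,
                             predator_survival_prob = 0.95,
                             duration_days = 1,
                             baseline_consumption_prob = 0.3,
                             mutant_effect = 0.3,
                             batch_effect_sd = 0.5,
                             background_mortality = 0.05,
                             rng_seed = 1L) {
  check_prob(baseline_consumption_prob, "baseline_consumption_prob")
  check_prob(background_mortality, "background_mortality")
  check_prob(predator_survival_prob, "predator_survival_prob")
  if (baseline_consumption_prob + mutant_effect > 1 ||
      baseline_consumption_prob + mutant_effect < 0)
    stopf("consumption probability must stay in [0, 1] after `mutant_effect`")
  if (prey_per_genotype < 0 || predators < 0)
    stopf("prey and predator counts must be >= 0")
  check_pos(duration_days, "duration_days")
  structure(as.list(environment()), class = "predation_config")
}

#' Generate synthetic paired predation trials with no-copepod controls
#'
#' @param cfg A [predation_config()].
#' @return A list of class `synthetic_predation`: `trials`, a tidy data
#'   frame with one row per (trial, genotype) holding `batch_id`,
#'   `trial_id`, `condition` (`copepods`/`control`), `genotype`,
#'   `duration_days`, `n_predators_final`, `volume_L`, `initial_prey`,
#'   `survivors`, `Ci` and `Cf` (prey/L); and `ground_truth`
#'   (`mutant_effect`, per-batch logit offsets).
#' @export
gen_predation <- function(cfg) {
  stopifnot(inherits(cfg, "predation_config"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$rng_seed)

  batch_eff <- rnorm(cfg$n_batches, 0, cfg$batch_effect_sd)
  shift_prob <- function(p, eff) {
    if (p <= 0) return(rep(0, length(eff)))
    if (p >= 1) return(rep(1, length(eff)))
    stats::plogis(stats::qlogis(p) + eff)
  }
  n <- cfg$n_batches * cfg$trials_per_batch
  batch <- rep(seq_len(cfg$n_batches), each = cfg$trials_per_batch)
  p_wt <- shift_prob(cfg$baseline_consumption_prob, batch_eff[batch])
  p_mut <- shift_prob(
    min(max(cfg$baseline_consumption_prob + cfg$mutant_effect, 0), 1),
    batch_eff[batch])
  n_pred <- rbinom(n, cfg$predators, cfg$predator_survival_prob)
  prey <- cfg$prey_per_genotype
  draw_surv <- function(p_cons) {
    p_die <- 1 - (1 - p_cons) * (1 - cfg$background_mortality)
    prey - rbinom(n, prey, p_die)
  }
  blocks <- list(
    list(condition = "copepods", genotype = "wildtype", surv = draw_surv(p_wt),
         pred = n_pred),
    list(condition = "copepods", genotype = "mutant", surv = draw_surv(p_mut),
         pred = n_pred),
    list(condition = "control", genotype = "wildtype", surv = draw_surv(0),
         pred = 0L),
    list(condition = "control", genotype = "mutant", surv = draw_surv(0),
         pred = 0L))
  trials <- do.call(rbind, lapply(blocks, function(b) data.frame(
    batch_id = batch, trial_id = seq_len(n), condition = b$condition,
    genotype = b$genotype, duration_days = cfg$duration_days,
    n_predators_final = b$pred, volume_L = cfg$volume_L,
    initial_prey = prey, survivors = b$surv,
    Ci = prey / cfg$volume_L, Cf = b$surv / cfg$volume_L)))
  trials <- trials[order(trials$trial_id, trials$condition, trials$genotype), ]
  rownames(trials) <- NULL
  structure(list(trials = trials,
                 ground_truth = list(mutant_effect = cfg$mutant_effect,
                                     batch_effects = batch_eff)),
            class = "synthetic_predation")
}
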