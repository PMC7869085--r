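#' Evoked dataset for one subject
#'
#' Per-condition multichannel source timeseries (virtual-electrode signals)
#' with sampling metadata.
#'
#' @param standard,deviant `nodes x time` signal matrices.
#' @param time Sample times (ms, peristimulus).
#' @param fs Sampling rate (Hz).
#' @param nodes Node labels.
#' @param subject,group Optional subject id and group label.
#' @return Object of class `evoked_dataset`.
#' @export
evoked_dataset <- function(standard, deviant, time, fs = 500,
                           nodes = cmc_nodes(), subject = NA, group = NA) {
  stopifnot(nrow(standard) == length(nodes), ncol(standard) == length(time),
            all(dim(standard) == dim(deviant)))
  rownames(standard) <- rownames(deviant) <- nodes
  structure(list(data = list(standard = standard, deviant = deviant),
                 time = time, fs = fs, nodes = nodes,
                 subject = subject, group = group,
                 coords = cmc_node_coords()),
            class = "evoked_dataset")
}

#' Oddball paradigm specification
#'
#' Defaults reproduce the multi-deviant auditory oddball design: 75 ms
#' standard tones of 500/1000/1500 Hz, deviants differing in frequency
#' (550/1100/1650 Hz), intensity (+/-6 dB), duration (25 ms), laterality or
#' a silent gap, 500 ms tone-onset-asynchrony, three 5-minute blocks.
#'
#' @param tone_ms Standard tone duration (ms).
#' @param standard_hz Standard tone frequencies (Hz).
#' @param deviant_hz Frequency-deviant frequencies (Hz).
#' @param intensity_db Intensity-deviant change (dB).
#' @param duration_deviant_ms Duration-deviant tone length (ms).
#' @param deviant_types The five deviant dimensions.
#' @param toa_ms Tone-onset-asynchrony (ms).
#' @param blocks Number of blocks.
#' @param block_min Block duration (minutes).
#' @return Object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(tone_ms = 75,
                          standard_hz = c(500, 1000, 1500),
                          deviant_hz = c(550, 1100, 1650),
                          intensity_db = 6,
                          duration_deviant_ms = 25,
                          deviant_types = c("frequency", "intensity",
                                            "duration", "laterality", "gap"),
                          toa_ms = 500, blocks = 3, block_min = 5) {
  stopifnot(toa_ms > 0, blocks >= 0, block_min > 0)
  structure(list(tone_ms = tone_ms, standard_hz = standard_hz,
                 deviant_hz = deviant_hz, intensity_db = intensity_db,
                 duration_deviant_ms = duration_deviant_ms,
                 deviant_types = deviant_types, toa_ms = toa_ms,
                 blocks = blocks, block_min = block_min),
            class = "paradigm_spec")
}

#' Generate an oddball trial schedule
#'
#' Half the trials are standards and half deviants, with the five deviant
#' dimensions in equal proportion, in seeded pseudorandom order. Under the
#' default specification this yields exactly 900 standard and 900 deviant
#' trials (3 blocks x 300 s / 0.5 s = 1800 trials).
#'
#' @param spec A [paradigm_spec()].
#' @param seed Integer seed for the trial order.
#' @return Data frame with columns trial, block, onset_ms, condition,
#'   deviant_type.
#' @export
make_paradigm <- function(spec = paradigm_spec(), seed = 1) {
  per_block <- floor(spec$block_min * 60 * 1000 / spec$toa_ms)
  n <- spec$blocks * per_block
  if (n == 0)
    return(data.frame(trial = integer(0), block = integer(0),
                      onset_ms = numeric(0), condition = character(0),
                      deviant_type = character(0)))
  n_dev <- n %/% 2
  types <- rep(spec$deviant_types, length.out = n_dev)
  labels <- c(rep("standard", n - n_dev), rep("deviant", n_dev))
  dtype <- c(rep(NA_character_, n - n_dev), types)
  set.seed(seed)
  idx <- sample.int(n)
  data.frame(trial = seq_len(n),
             block = rep(seq_len(spec$blocks), each = per_block),
             onset_ms = (seq_len(n) - 1) * spec$toa_ms,
             condition = labels[idx],
             deviant_type = dtype[idx])
}

#' Synthetic cohort specification
#'
#' Group sizes default to the analysed cohort (40 controls, 33 patients).
#' The planted patient effects mirror the reported laminar abnormalities:
#' reduced deep-pyramidal (L5/6) contribution to the STG signal, increased
#' superficial-pyramidal inhibitory self-gain in STG, and decreased
#' deep-pyramidal self-gain in A1 (all in log-scaling units). All subjects
#' share a baseline deviant modulation so that a mismatch response exists;
#' between-subject variability jitters every parameter.
#'
#' @param n_controls,n_patients Group sizes.
#' @param delta_j_dp Patient reduction of the STG deep-pyramidal
#'   contribution weight (log units; applied with negative sign).
#' @param delta_g_sp_stg Patient increase of the STG SP self-gain (log
#'   units).
#' @param delta_g_dp_a1 Patient decrease of the A1 DP self-gain (log units;
#'   applied with negative sign).
#' @param subject_sd Between-subject SD of every log-scaling parameter.
#' @param noise_sd Observation noise SD on the average ERPs (signal units).
#' @param b_mean Baseline deviant-modulation means (extrinsic, self).
#' @param seed Seed recorded with the cohort.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 40, n_patients = 33,
                        delta_j_dp = 0.4,
                        delta_g_sp_stg = 0.4,
                        delta_g_dp_a1 = 0.4,
                        subject_sd = 0.125,
                        noise_sd = 0.02,
                        b_mean = c(extrinsic = 0.4, self = -0.4),
                        seed = 1) {
  stopifnot(n_controls >= 2, n_patients >= 2,
            is.finite(delta_j_dp), is.finite(delta_g_sp_stg),
            is.finite(delta_g_dp_a1), noise_sd >= 0)
  structure(list(n_controls = n_controls, n_patients = n_patients,
                 delta_j_dp = delta_j_dp, delta_g_sp_stg = delta_g_sp_stg,
                 delta_g_dp_a1 = delta_g_dp_a1, subject_sd = subject_sd,
                 noise_sd = noise_sd, b_mean = b_mean, seed = seed),
            class = "cohort_spec")
}

#' Generate ground-truth parameter sets for a synthetic cohort
#'
#' Controls draw every log-scaling parameter around 0 (the prior mean) with
#' SD `subject_sd`; patients are additionally shifted by the planted
#' effects. The generating architecture defaults to model 14 of the model
#' space. Ground truth is returned for recovery scoring.
#'
#' @param spec A [cohort_spec()].
#' @param arch Generating architecture (default: model 14).
#' @return Object of class `cohort`: subject table (`subjects`), truth
#'   parameter matrix (`theta`, subjects x parameters), the generating
#'   [cmc_priors()] and the cohort specification.
#' @export
make_cohort <- function(spec = cohort_spec(),
                        arch = build_model_space()$models[[14]]) {
  n <- spec$n_controls + spec$n_patients
  if (n == 0) stop("cohort must contain at least one subject")
  priors <- cmc_priors(arch, free = c("A", "B", "J", "L", "G"))
  pnames <- priors$table$name
  set.seed(spec$seed)
  theta <- matrix(rnorm(n * length(pnames), 0, spec$subject_sd),
                  n, length(pnames), dimnames = list(NULL, pnames))
  if ("B.extrinsic" %in% pnames)
    theta[, "B.extrinsic"] <- theta[, "B.extrinsic"] + spec$b_mean[["extrinsic"]]
  if ("B.self" %in% pnames)
    theta[, "B.self"] <- theta[, "B.self"] + spec$b_mean[["self"]]

  group <- c(rep("control", spec$n_controls), rep("patient", spec$n_patients))
  pat <- group == "patient"
  theta[pat, "J.STG.DP"] <- theta[pat, "J.STG.DP"] - spec$delta_j_dp
  theta[pat, "G.STG.SP"] <- theta[pat, "G.STG.SP"] + spec$delta_g_sp_stg
  theta[pat, "G.A1.DP"] <- theta[pat, "G.A1.DP"] - spec$delta_g_dp_a1

  subjects <- data.frame(subject = sprintf("S%03d", seq_len(n)), group = group)
  structure(list(subjects = subjects, theta = theta, priors = priors,
                 spec = spec, arch = arch),
            class = "cohort")
}

#' Simulate noisy evoked datasets for a cohort
#'
#' Integrates the generative model for every subject's ground-truth
#' parameters under both conditions and adds seeded observation noise.
#'
#' @param cohort A [make_cohort()] result.
#' @param tspan,dt,fs Simulation window (ms), step (ms) and sampling rate.
#' @param noise_sd Observation noise SD; defaults to the cohort spec value.
#' @param seed Noise seed (default: cohort seed + 1).
#' @return List of [evoked_dataset()] objects, one per subject.
#' @export
simulate_cohort <- function(cohort, tspan = c(-100, 300), dt = 1, fs = 500,
                            noise_sd = cohort$spec$noise_sd,
                            seed = cohort$spec$seed + 1) {
  n <- nrow(cohort$subjects)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- predict_response(cohort$priors, cohort$theta[i, ],
                           tspan = tspan, dt = dt, fs = fs)
    ds <- evoked_dataset(pr$standard, pr$deviant, pr$time, fs,
                         nodes = cohort$arch$nodes,
                         subject = cohort$subjects$subject[i],
                         group = cohort$subjects$group[i])
    out[[i]] <- add_observation_noise(ds, noise_sd, seed = seed + i)
  }
  names(out) <- cohort$subjects$subject
  out
}

#' Add observation noise to an evoked dataset
#'
#' Additive i.i.d. Gaussian noise per sample and node, independently for
#' each condition. `noise_sd = 0` returns the input unchanged.
#'
#' @param clean An [evoked_dataset()].
#' @param noise_sd Noise standard deviation (signal units).
#' @param seed Integer seed.
#' @return A noisy `evoked_dataset`.
#' @export
add_observation_noise <- function(clean, noise_sd, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (noise_sd == 0) return(clean)
  set.seed(seed)
  noisy <- clean
  for (cond in names(clean$data))
    noisy$data[[cond]] <- clean$data[[cond]] +
      matrix(rnorm(length(clean$data[[cond]]), 0, noise_sd),
             nrow(clean$data[[cond]]))
  noisy
}
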