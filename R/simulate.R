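#' Ground truth for a simulated EEG cohort
#'
#' Encodes everything the generator plants and downstream recovery tests
#' check: lagged cross-region coupling (which produces nonzero imaginary
#' coherence), per-band oscillation amplitudes, the 1/f background, sensor
#' noise, the intervention effect on alpha1 coupling at follow-up, and the
#' follow-up missingness mechanism.
#'
#' @param coupling_edges Data frame with columns `source`, `target` (ROI
#'   indices or labels), `band`, `lag_seconds` (>= 0) and `strength` in
#'   `[0, 1]`.
#' @param band_amplitudes Named numeric vector (microvolts), one entry per
#'   band of the scheme; recycled across regions.
#' @param noise_exponent Spectral slope of the 1/f background (~1 = pink).
#' @param background_sd Background noise SD per region (microvolts).
#' @param sensor_noise_sd White sensor noise SD (microvolts).
#' @param group_effect Additive change in alpha1 coupling strength for
#'   intervention arms at follow-up.
#' @param missing_rate Fraction of follow-ups missing, in `[0, 1]`.
#' @param missing_mechanism `"MCAR"` or `"MAR-age"` (logistic in
#'   standardized age, slope 1).
#' @param seed Integer master seed.
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(coupling_edges = NULL,
                             band_amplitudes = c(delta = 2, theta = 2,
                                                 alpha1 = 3, alpha2 = 2,
                                                 beta1 = 1, beta2 = 0.8,
                                                 beta3 = 0.6, gamma = 0.4),
                             noise_exponent = 1,
                             background_sd = 2,
                             sensor_noise_sd = 1,
                             group_effect = 0.3,
                             missing_rate = 0.1,
                             missing_mechanism = c("MCAR", "MAR-age"),
                             seed = 1) {
  missing_mechanism <- match.arg(missing_mechanism)
  if (is.null(coupling_edges))
    coupling_edges <- data.frame(source = integer(), target = integer(),
                                 band = character(), lag_seconds = numeric(),
                                 strength = numeric())
  stopifnot(all(c("source", "target", "band", "lag_seconds", "strength")
                %in% names(coupling_edges)))
  if (any(coupling_edges$strength < 0 | coupling_edges$strength > 1))
    stop("coupling strengths must lie in [0, 1]", call. = FALSE)
  if (any(coupling_edges$lag_seconds < 0))
    stop("lags must be non-negative", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]", call. = FALSE)
  structure(list(coupling_edges = coupling_edges,
                 band_amplitudes = band_amplitudes,
                 noise_exponent = noise_exponent,
                 background_sd = background_sd,
                 sensor_noise_sd = sensor_noise_sd,
                 group_effect = group_effect,
                 missing_rate = missing_rate,
                 missing_mechanism = missing_mechanism,
                 seed = seed),
            class = "simulation_truth")
}

#' Simulate band-structured oscillatory region time series
#'
#' Each region's series is a sum over bands of amplitude-scaled band-limited
#' noise (white noise through an exact zero-phase Butterworth-magnitude
#' band-pass) plus a 1/f background.  For every coupling edge the target
#' region additionally receives a strength-scaled copy of the source
#' region's band component delayed by the edge lag (rounded to the nearest
#' sample, applied circularly), which is what makes the planted pairs show
#' nonzero imaginary coherence downstream.
#'
#' @param truth A [simulation_truth()].
#' @param scheme A [band_scheme()].
#' @param n_rois Number of regions.
#' @param fs Sampling rate (Hz); must be at least twice the highest band
#'   edge.
#' @param duration Seconds (> 0).
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return `n_rois` x samples matrix, zero mean per row.
#' @export
simulate_roi_signals <- function(truth, scheme = band_scheme(), n_rois = 68,
                                 fs = 250, duration = 180, seed = truth$seed) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (fs < 2 * max(scheme$f_high))
    stop("fs must be at least twice the highest band edge (",
         2 * max(scheme$f_high), " Hz)", call. = FALSE)
  edges <- truth$coupling_edges
  if (nrow(edges) && any(edges$lag_seconds >= duration))
    stop("coupling lag must be shorter than the recording", call. = FALSE)
  if (nrow(edges) && !all(edges$band %in% scheme$name))
    stop("coupling band not in the active band scheme", call. = FALSE)
  n <- round(fs * duration)
  amps <- truth$band_amplitudes
  if (is.null(names(amps))) names(amps) <- scheme$name
  set.seed(seed)

  edges$source <- roi_index(edges$source, n_rois)
  edges$target <- roi_index(edges$target, n_rois)

  # background for all regions in one shaped-noise pass (samples x rois)
  xt <- truth$background_sd *
    pink_noise(n, fs, truth$noise_exponent, m = n_rois)
  for (b in seq_len(nrow(scheme))) {
    a <- amps[[scheme$name[b]]]
    in_band <- edges$band == scheme$name[b]
    if (is.null(a) || is.na(a) || a == 0) {
      if (any(in_band))
        stop("coupling edge refers to a band with zero amplitude at its ",
             "source region", call. = FALSE)
      next
    }
    comp <- a * bandlimited_noise(n, scheme$f_low[b], scheme$f_high[b],
                                  fs, m = n_rois)
    xt <- xt + comp
    for (e in which(in_band)) {
      d <- round(edges$lag_seconds[e] * fs)
      xt[, edges$target[e]] <- xt[, edges$target[e]] +
        edges$strength[e] * circular_shift(comp[, edges$source[e]], d)
    }
  }
  x <- t(xt)
  x <- x - rowMeans(x)
  rownames(x) <- if (n_rois == 68) dk_roi_labels() else
    paste0("roi", seq_len(n_rois))
  x
}

roi_index <- function(x, n_rois) {
  if (is.numeric(x)) return(as.integer(x))
  i <- match(x, dk_roi_labels())
  if (anyNA(i)) stop("unknown ROI label in coupling edges", call. = FALSE)
  i
}

#' Project region signals to sensors through a leadfield
#'
#' Mixing is strictly instantaneous (zero lag): sensor series are the gain
#' matrix applied to the region series plus white Gaussian sensor noise.
#' Instantaneous mixing is the volume-conduction phenomenon the imaginary
#' part of coherency is designed to suppress.
#'
#' @param roi_signals Regions x samples matrix (one series per ROI).
#' @param leadfield A [make_toy_leadfield()] result.
#' @param sensor_noise_sd White noise SD in microvolts.
#' @param seed Integer seed for the noise.
#' @param subject_id,visit Metadata for the resulting recording.
#' @param fs Sampling rate attached to the recording.
#' @return An [recording()].
#' @export
project_to_sensors <- function(roi_signals, leadfield, sensor_noise_sd = 1,
                               seed = 1, fs = 250,
                               subject_id = NA_character_,
                               visit = "baseline") {
  n_roi <- length(leadfield$roi_labels)
  if (nrow(roi_signals) != n_roi)
    stop("roi_signals rows (", nrow(roi_signals),
         ") must match leadfield ROI count (", n_roi, ")", call. = FALSE)
  # each source carries its region's series; multi-source regions average
  mem <- tabulate(leadfield$roi_of_source, n_roi)
  src <- roi_signals[leadfield$roi_of_source, , drop = FALSE] /
    mem[leadfield$roi_of_source]
  y <- leadfield$gain %*% src
  if (sensor_noise_sd > 0) {
    set.seed(seed)
    y <- y + matrix(stats::rnorm(length(y), sd = sensor_noise_sd),
                    nrow(y), ncol(y))
  }
  recording(y, fs = fs, channel_labels = rownames(leadfield$gain),
            subject_id = subject_id, visit = visit)
}

#' Inject stereotyped artifacts into a recording
#'
#' `blink` adds a low-frequency, high-amplitude transient on the frontal
#' channels; `emg` adds a broadband burst on temporal channels; `flat`
#' zeroes a span on all channels.  Returned annotations give ground truth
#' for epoch-rejection tests.
#'
#' @param rec An [recording()].
#' @param kinds Subset of `c("blink", "emg", "flat")`.
#' @param events_per_minute Expected event rate (>= 0); each event's kind is
#'   drawn uniformly from `kinds`.
#' @param blink_amplitude,emg_amplitude Peak amplitudes (microvolts).
#' @param seed Integer seed.
#' @return List with the modified `recording` and an `annotations` data
#'   frame (`start`, `end` in seconds, `kind`).
#' @export
inject_artifacts <- function(rec, kinds = c("blink", "emg", "flat"),
                             events_per_minute = 1,
                             blink_amplitude = 300, emg_amplitude = 60,
                             seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  ok <- c("blink", "emg", "flat")
  if (!length(kinds) || !all(kinds %in% ok))
    stop("unknown artifact kind: ", paste(setdiff(kinds, ok), collapse = ", "),
         call. = FALSE)
  if (events_per_minute < 0) stop("rate must be >= 0", call. = FALSE)
  n <- ncol(rec$data)
  dur <- n / rec$fs
  n_events <- round(events_per_minute * dur / 60)
  ann <- data.frame(start = numeric(), end = numeric(), kind = character())
  if (n_events == 0)
    return(list(recording = rec, annotations = ann))
  set.seed(seed)
  frontal <- intersect(c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8"),
                       rec$channel_labels)
  temporal <- intersect(c("T7", "T8", "P7", "P8"), rec$channel_labels)
  for (i in seq_len(n_events)) {
    kind <- sample(kinds, 1)
    len <- switch(kind, blink = 0.4, emg = 1.0, flat = 1.0)
    start <- stats::runif(1, 0, max(dur - len, 0))
    i0 <- max(1, round(start * rec$fs))
    i1 <- min(n, i0 + round(len * rec$fs) - 1)
    idx <- i0:i1
    if (kind == "blink") {
      pulse <- blink_amplitude *
        sin(pi * seq_along(idx) / length(idx))^2
      ch <- if (length(frontal)) frontal else rec$channel_labels[1]
      rec$data[ch, idx] <- sweep(rec$data[ch, idx, drop = FALSE], 2, pulse, "+")
    } else if (kind == "emg") {
      ch <- if (length(temporal)) temporal else rec$channel_labels[1]
      burst <- matrix(stats::rnorm(length(ch) * length(idx),
                                   sd = emg_amplitude), length(ch))
      rec$data[ch, idx] <- rec$data[ch, idx, drop = FALSE] + burst
    } else {
      rec$data[, idx] <- 0
    }
    ann <- rbind(ann, data.frame(start = (i0 - 1) / rec$fs,
                                 end = i1 / rec$fs, kind = kind))
  }
  list(recording = rec, annotations = ann)
}

#' Stratified permuted-block randomization
#'
#' Within each center, subjects are assigned by concatenated permuted blocks
#' whose sizes are drawn from `block_sizes`; every complete block contains
#' each arm equally often (1:1:1), so per-center arm counts differ by at
#' most the final partial block.
#'
#' @param subject_ids Character vector (non-empty, unique).
#' @param centers Center of each subject (same length).
#' @param arms Three distinct arm labels.
#' @param block_sizes Block sizes, each a multiple of `length(arms)`.
#' @param seed Integer seed.
#' @return Named character vector: arm per subject, in input order.
#' @export
permuted_block_randomize <- function(subject_ids, centers,
                                     arms = c("FMI", "HMI", "control"),
                                     block_sizes = c(3, 6), seed = 1) {
  if (!length(subject_ids)) stop("empty subject list", call. = FALSE)
  if (length(centers) != length(subject_ids))
    stop("every subject needs a center", call. = FALSE)
  if (length(unique(arms)) != length(arms))
    stop("arm labels must be distinct", call. = FALSE)
  if (any(block_sizes %% length(arms) != 0))
    stop("block sizes must be multiples of the number of arms", call. = FALSE)
  set.seed(seed)
  out <- character(length(subject_ids))
  for (ctr in unique(centers)) {
    idx <- which(centers == ctr)
    seq_arm <- character(0)
    while (length(seq_arm) < length(idx)) {
      bs <- if (length(block_sizes) == 1) block_sizes else
        sample(block_sizes, 1)
      seq_arm <- c(seq_arm, sample(rep(arms, bs / length(arms))))
    }
    out[idx] <- seq_arm[seq_along(idx)]
  }
  names(out) <- subject_ids
  out
}

#' Simulate a three-arm randomized EEG cohort
#'
#' Builds a cohort table (center-stratified permuted-block randomization,
#' demographics, a cognitive index score at both visits), plants the
#' intervention effect — intervention-arm subjects' follow-up recordings use
#' alpha1 coupling strengths increased by `truth$group_effect` times a
#' per-subject multiplier — and applies follow-up missingness under the
#' stated mechanism.  Recordings are not materialized here; they are
#' regenerated deterministically per subject and visit by
#' [cohort_recording()], so arbitrarily large cohorts stay memory-light.
#'
#' @param n_per_arm Subjects per arm (>= 2).
#' @param truth A [simulation_truth()].
#' @param scheme A [band_scheme()].
#' @param fs,duration Recording parameters passed to the signal generator.
#' @param n_centers Number of participating centers.
#' @param artifact_rate Artifact events per minute in each recording.
#' @param seed Integer master seed; all per-subject seeds derive from it.
#' @return A `qeeg_cohort` list: `table` (subject, center, arm, age, sex,
#'   education, cognitive scores, missingness flags), `truth`, `leadfield`,
#'   and the generation parameters.
#' @export
simulate_cohort <- function(n_per_arm = 50, truth = default_truth(),
                            scheme = band_scheme(), fs = 250, duration = 180,
                            n_centers = 4, artifact_rate = 0, seed = 1) {
  if (n_per_arm < 2) stop("n_per_arm must be >= 2", call. = FALSE)
  arms <- c("FMI", "HMI", "control")
  n <- 3 * n_per_arm
  set.seed(derive_seed(seed, 11))
  subject <- sprintf("S%03d", seq_len(n))
  center <- sample(rep_len(paste0("C", seq_len(n_centers)), n))
  arm <- assign_balanced_arms(subject, center, arms,
                              seed = derive_seed(seed, 13))
  age <- round(stats::runif(n, 60, 79))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  education <- pmin(pmax(round(stats::rnorm(n, 10, 3)), 6), 18)

  is_int <- arm %in% c("FMI", "HMI")
  # per-subject realized intervention effect on alpha1 coupling; the same
  # multiplier drives the cognitive change, giving the within-arm
  # association the regression stage looks for
  eff_mult <- ifelse(is_int, stats::runif(n, 0.75, 1.25), 0)
  eff <- truth$group_effect * eff_mult
  if (nrow(truth$coupling_edges)) {
    a1 <- truth$coupling_edges$band == "alpha1"
    if (any(a1)) {
      hi <- max(truth$coupling_edges$strength[a1]) + max(eff)
      if (hi > 1)
        stop("group_effect pushes a coupling strength above 1", call. = FALSE)
    }
  }
  cog_base <- round(stats::rnorm(n, 90, 10), 1)
  cog_change <- round(ifelse(is_int, 10 * eff, 0) +
                        stats::rnorm(n, 0, 4), 1)
  cog_end <- cog_base + cog_change

  p_miss <- switch(truth$missing_mechanism,
                   "MCAR" = rep(truth$missing_rate, n),
                   "MAR-age" = stats::plogis(stats::qlogis(
                     max(min(truth$missing_rate, 1 - 1e-9), 1e-9)) +
                       as.numeric(scale(age))))
  missing_end <- stats::runif(n) < p_miss
  cog_end[missing_end] <- NA_real_

  tab <- data.frame(subject = subject, center = center, arm = arm,
                    age = age, sex = sex, education = education,
                    cog_baseline = cog_base, cog_end = cog_end,
                    eeg_missing_end = missing_end,
                    effect = eff,
                    stringsAsFactors = FALSE)
  lf <- make_toy_leadfield(19, 1, seed = derive_seed(seed, 17))
  structure(list(table = tab, truth = truth, scheme = scheme, fs = fs,
                 duration = duration, leadfield = lf,
                 artifact_rate = artifact_rate, seed = seed,
                 condition = "eyes-closed"),
            class = "qeeg_cohort")
}

# permuted-block randomization retried until arms are exactly balanced at
# n_per_arm each (a simulated trial design fixes the arm totals)
assign_balanced_arms <- function(subject, center, arms, seed) {
  n_target <- length(subject) / length(arms)
  for (k in 0:50) {
    a <- permuted_block_randomize(subject, center, arms,
                                  seed = derive_seed(seed, k))
    if (all(table(factor(a, arms)) == n_target)) return(a)
  }
  a  # worst case: within partial-block imbalance, still a valid assignment
}

#' Default planted truth for the simulated cohort
#'
#' Three lagged alpha1 couplings (25 ms, strength 0.3 at baseline) plus one
#' theta coupling, against the default band amplitudes and pink background.
#' @param group_effect Follow-up alpha1 coupling increase in intervention
#'   arms.
#' @param missing_rate,missing_mechanism Follow-up missingness.
#' @param seed Integer seed.
#' @return A [simulation_truth()].
#' @export
default_truth <- function(group_effect = 0.3, missing_rate = 0.1,
                          missing_mechanism = "MCAR", seed = 1) {
  edges <- data.frame(
    source = c(30, 26, 10, 5),
    target = c(64, 60, 44, 39),
    band = c("alpha1", "alpha1", "alpha1", "theta"),
    lag_seconds = c(0.025, 0.025, 0.030, 0.040),
    strength = c(0.3, 0.3, 0.3, 0.4))
  simulation_truth(coupling_edges = edges, group_effect = group_effect,
                   missing_rate = missing_rate,
                   missing_mechanism = missing_mechanism, seed = seed)
}

#' Regenerate one subject-visit recording of a simulated cohort
#'
#' Deterministic in the cohort's master seed, the subject and the visit.
#' Intervention subjects' follow-up uses the planted alpha1 coupling
#' increase; a missing follow-up returns `NULL`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param subject Subject id.
#' @param visit `"baseline"` or `"end"`.
#' @return An [recording()], or `NULL` when the visit is missing.
#' @export
cohort_recording <- function(cohort, subject, visit = c("baseline", "end")) {
  visit <- match.arg(visit)
  i <- match(subject, cohort$table$subject)
  if (is.na(i)) stop("unknown subject: ", subject, call. = FALSE)
  if (visit == "end" && cohort$table$eeg_missing_end[i]) return(NULL)
  truth <- cohort$truth
  if (visit == "end" && cohort$table$effect[i] > 0) {
    a1 <- truth$coupling_edges$band == "alpha1"
    truth$coupling_edges$strength[a1] <-
      pmin(1, truth$coupling_edges$strength[a1] + cohort$table$effect[i])
  }
  s <- derive_seed(cohort$seed, 1000 + i, if (visit == "end") 2 else 1)
  x <- simulate_roi_signals(truth, cohort$scheme,
                            n_rois = length(cohort$leadfield$roi_labels),
                            fs = cohort$fs, duration = cohort$duration,
                            seed = s)
  rec <- project_to_sensors(x, cohort$leadfield,
                            sensor_noise_sd = truth$sensor_noise_sd,
                            seed = derive_seed(s, 3), fs = cohort$fs,
                            subject_id = subject, visit = visit)
  if (cohort$artifact_rate > 0)
    rec <- inject_artifacts(rec, events_per_minute = cohort$artifact_rate,
                            seed = derive_seed(s, 4))$recording
  rec
}
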