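#' Trial flow accounting to the analyzable set
#'
#' From per-arm flow counts, the analyzable (modified intention-to-treat)
#' N per arm is `eeg_at_both_visits + early_termination_with_eeg -
#' excluded_bad_quality`.
#'
#' @param flow Data frame with columns `arm`, `randomized`, `completed`,
#'   `eeg_at_both_visits`, `early_termination_with_eeg`,
#'   `excluded_bad_quality`.
#' @return The data frame with an `analyzable` column appended, plus
#'   attribute `total`; printing gives a human-readable flow report.
#' @export
flow_accounting <- function(flow) {
  need <- c("arm", "randomized", "completed", "eeg_at_both_visits",
            "early_termination_with_eeg", "excluded_bad_quality")
  if (!all(need %in% names(flow)))
    stop("flow needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  num <- flow[setdiff(need, "arm")]
  if (any(unlist(num) < 0))
    stop("negative count in arm ",
         flow$arm[which(rowSums(num < 0) > 0)[1]], call. = FALSE)
  flow$analyzable <- flow$eeg_at_both_visits +
    flow$early_termination_with_eeg - flow$excluded_bad_quality
  if (any(flow$analyzable < 0))
    stop("negative analyzable count in arm ",
         flow$arm[flow$analyzable < 0][1], call. = FALSE)
  attr(flow, "total") <- sum(flow$analyzable)
  class(flow) <- c("flow_counts", "data.frame")
  flow
}

#' @export
print.flow_counts <- function(x, ...) {
  cat("Trial flow to the analyzable (modified intention-to-treat) set\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf(
      "  %s: randomized %d -> completed %d -> EEG both visits %d (+%d early-termination EEG) - %d bad quality = %d analyzable\n",
      x$arm[i], x$randomized[i], x$completed[i], x$eeg_at_both_visits[i],
      x$early_termination_with_eeg[i], x$excluded_bad_quality[i],
      x$analyzable[i]))
  cat(sprintf("  total analyzable: %d\n", attr(x, "total")))
  invisible(x)
}

#' QEEG features for one recording
#'
#' One subject-visit pass of the analysis chain: band-pass filter,
#' epoching, threshold epoch rejection, sensor band powers (with relative
#' powers and ratios), source inversion and region aggregation, band-wise
#' imaginary coherence among the 68 regions, density-thresholded graph and
#' nodal path length per requested band.
#'
#' @param rec An [recording()].
#' @param leadfield Leadfield for the source stage.
#' @param scheme Band scheme.
#' @param bands Bands for which connectivity/graph metrics are computed.
#' @param epoch_length,overlap,density,alpha,filter_low,filter_high Stage
#'   parameters (epoching, graph density, inverse regularization, filter
#'   edges).
#' @param inverse Optional precomputed [build_inverse()] operator (saves
#'   recomputation across subjects).
#' @return List: `band_power` (a `band_power_table`), `icoh` (list per
#'   band), `nodal_path_length` (matrix band x ROI), `n_epochs_kept`.
#' @export
recording_features <- function(rec, leadfield, scheme = band_scheme(),
                               bands = "alpha1", epoch_length = 4,
                               overlap = 0, density = 0.25, alpha = NULL,
                               filter_low = 0.5, filter_high = 70,
                               inverse = NULL) {
  rec <- bandpass_filter(rec, filter_low, min(filter_high, rec$fs / 2 - 1))
  ep <- epoch_recording(rec, epoch_length = epoch_length, overlap = overlap)
  ep <- reject_bad_epochs(ep)
  spec <- power_spectrum(ep)
  bp <- band_ratios(relative_powers(band_powers(spec, scheme)))
  occ <- intersect(c("O1", "O2"), rec$channel_labels)
  bp$alpha_peak <- vapply(occ, function(ch)
    alpha_peak_frequency(spec, ch), numeric(1))
  if (is.null(inverse)) inverse <- build_inverse(leadfield, alpha)
  src <- apply_inverse(ep, inverse)
  roi <- aggregate_rois(src, inverse)
  fmax <- max(scheme$f_high[scheme$name %in% bands])
  csd <- cross_spectra(roi, fs = rec$fs, fmax = fmax)
  coh <- coherency(csd)
  icoh <- imaginary_coherence(coh, scheme, bands = bands)
  npl <- t(vapply(bands, function(b) {
    g <- binarize_by_density(icoh[[b]], density)
    graph_metrics(g, n_surrogates = 0)$nodal$path_length
  }, numeric(length(inverse$roi_labels))))
  rownames(npl) <- bands
  colnames(npl) <- inverse$roi_labels
  list(band_power = bp, icoh = icoh, nodal_path_length = npl,
       n_epochs_kept = dim(ep$epochs)[1])
}

#' Run the full simulated-trial pipeline
#'
#' Simulates (or accepts) a cohort, computes per-subject QEEG features at
#' both visits, forms change scores (end minus baseline), and runs the
#' group-comparison layer: per-region Mann-Whitney tests of nodal path
#' length change (pooled intervention vs control) with Benjamini-Hochberg
#' correction per band family, per-region median change with IQR per arm
#' (the shape of a per-region descriptive table), mean imaginary-coherence
#' change comparisons, and a covariate-adjusted regression of cognitive
#' change on mean path-length change within each intervention arm.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param bands Bands analyzed at the network level.
#' @param density Graph density.
#' @param epoch_length Epoch length (s).
#' @param fdr_q FDR level for the region families.
#' @param alpha Inverse regularization (`NULL` = default).
#' @param progress Print per-subject progress.
#' @return A `qeeg_run` list: `subject_features`, `changes` (per subject:
#'   mean iCoh and per-region path-length change per band), `tests`
#'   (per-region Mann-Whitney + FDR), `medians` (per-region median (IQR)
#'   change per arm), `icoh_test`, `regression`, `manifest`.
#' @export
run_pipeline <- function(cohort, bands = "alpha1", density = 0.25,
                         epoch_length = 4, fdr_q = 0.05, alpha = NULL,
                         progress = FALSE) {
  stopifnot(inherits(cohort, "qeeg_cohort"))
  tab <- cohort$table
  inv <- build_inverse(cohort$leadfield, alpha)
  n_roi <- length(cohort$leadfield$roi_labels)
  feats <- list()
  for (i in seq_len(nrow(tab))) {
    sid <- tab$subject[i]
    for (visit in c("baseline", "end")) {
      rec <- cohort_recording(cohort, sid, visit)
      if (is.null(rec)) next
      if (progress) message(sid, " ", visit)
      feats[[paste(sid, visit)]] <- recording_features(
        rec, cohort$leadfield, cohort$scheme, bands = bands,
        epoch_length = epoch_length, density = density, inverse = inv)
    }
  }
  # change scores: end - baseline
  changes <- list()
  for (b in bands) {
    npl <- matrix(NA_real_, nrow(tab), n_roi,
                  dimnames = list(tab$subject, cohort$leadfield$roi_labels))
    icoh_mean <- rep(NA_real_, nrow(tab))
    for (i in seq_len(nrow(tab))) {
      f0 <- feats[[paste(tab$subject[i], "baseline")]]
      f1 <- feats[[paste(tab$subject[i], "end")]]
      if (is.null(f0) || is.null(f1)) next
      npl[i, ] <- f1$nodal_path_length[b, ] - f0$nodal_path_length[b, ]
      ut <- upper.tri(f1$icoh[[b]])
      icoh_mean[i] <- mean(f1$icoh[[b]][ut]) - mean(f0$icoh[[b]][ut])
    }
    changes[[b]] <- list(nodal_path_length = npl, icoh_mean = icoh_mean)
  }
  is_int <- tab$arm %in% c("FMI", "HMI")
  tests <- list(); medians <- list(); icoh_test <- list()
  for (b in bands) {
    npl <- changes[[b]]$nodal_path_length
    p <- vapply(seq_len(n_roi), function(r) {
      xi <- npl[is_int, r]; xc <- npl[!is_int, r]
      xi <- xi[!is.na(xi)]; xc <- xc[!is.na(xc)]
      if (length(xi) < 2 || length(xc) < 2) return(NA_real_)
      mann_whitney_u(xi, xc)$p
    }, numeric(1))
    ok <- !is.na(p)
    adj <- rep(NA_real_, n_roi); rej <- rep(NA, n_roi)
    if (any(ok)) {
      f <- bh_fdr(p[ok], fdr_q)
      adj[ok] <- f$p_adjusted; rej[ok] <- f$reject
    }
    med_change <- function(x) stats::median(x, na.rm = TRUE)
    tests[[b]] <- data.frame(
      roi = cohort$leadfield$roi_labels, band = b, p_raw = p, p_fdr = adj,
      reject = rej,
      median_change_intervention = apply(npl[is_int, , drop = FALSE], 2,
                                         med_change),
      median_change_control = apply(npl[!is_int, , drop = FALSE], 2,
                                    med_change),
      row.names = NULL)
    medians[[b]] <- do.call(rbind, lapply(unique(tab$arm), function(a) {
      x <- npl[tab$arm == a, , drop = FALSE]
      data.frame(arm = a, roi = cohort$leadfield$roi_labels, band = b,
                 median = apply(x, 2, med_change),
                 iqr_lo = apply(x, 2, stats::quantile, 0.25, na.rm = TRUE),
                 iqr_hi = apply(x, 2, stats::quantile, 0.75, na.rm = TRUE),
                 row.names = NULL)
    }))
    ic <- changes[[b]]$icoh_mean
    xi <- ic[is_int & !is.na(ic)]; xc <- ic[!is_int & !is.na(ic)]
    icoh_test[[b]] <- if (length(xi) >= 2 && length(xc) >= 2)
      two_sample_t(xi, xc) else NULL
  }
  # regression of cognitive change on mean path-length change, per
  # intervention arm, adjusted for age/sex/education
  regression <- list()
  for (b in bands) {
    npl_mean <- rowMeans(changes[[b]]$nodal_path_length, na.rm = FALSE)
    for (a in c("FMI", "HMI")) {
      sel <- tab$arm == a & !is.na(npl_mean) & !is.na(tab$cog_end)
      if (sum(sel) > 6) {
        cog_change <- tab$cog_end[sel] - tab$cog_baseline[sel]
        regression[[paste(a, b)]] <- linear_regression_adjusted(
          cog_change, npl_mean[sel], tab$age[sel], tab$sex[sel],
          tab$education[sel])
      }
    }
  }
  structure(list(subject_features = feats, changes = changes, tests = tests,
                 medians = medians, icoh_test = icoh_test,
                 regression = regression,
                 manifest = list(seed = cohort$seed, bands = bands,
                                 density = density,
                                 epoch_length = epoch_length,
                                 fdr_q = fdr_q, fs = cohort$fs,
                                 duration = cohort$duration,
                                 n_subjects = nrow(tab),
                                 condition = cohort$condition)),
            class = "qeeg_run")
}

#' Planted-effect recovery on one simulated cohort
#'
#' Convenience driver for power/recovery studies: simulates a three-arm
#' cohort, computes each subject's alpha1 imaginary coherence averaged over
#' the planted coupled pairs and nodal path length averaged over the
#' coupled regions at both visits, and compares the change scores
#' (pooled intervention vs control) by Mann-Whitney tests.
#'
#' @param n_per_arm Subjects per arm.
#' @param group_effect Planted follow-up alpha1 coupling increase.
#' @param fs,duration Recording parameters.
#' @param seed Integer seed.
#' @param density Graph density.
#' @param overlap Epoch overlap fraction (Welch-style averaging).
#' @return List: `p_icoh`, `p_npl`, `delta_icoh`, `delta_npl` (intervention
#'   minus control mean change; recovery expects `delta_icoh > 0`,
#'   `delta_npl < 0`), and the per-subject change scores.
#' @export
planted_effect_recovery <- function(n_per_arm = 30, group_effect = 0.3,
                                    fs = 96, duration = 120, seed = 1,
                                    density = 0.25, overlap = 0.5) {
  truth <- default_truth(group_effect = group_effect, seed = seed)
  cohort <- simulate_cohort(n_per_arm, truth, fs = fs, duration = duration,
                            seed = seed)
  lf <- cohort$leadfield
  inv <- build_inverse(lf)
  a1 <- truth$coupling_edges[truth$coupling_edges$band == "alpha1", ]
  pair_idx <- cbind(a1$source, a1$target)
  rois <- unique(c(a1$source, a1$target))
  tab <- cohort$table
  icoh_chg <- npl_chg <- rep(NA_real_, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    vals <- lapply(c("baseline", "end"), function(v) {
      rec <- cohort_recording(cohort, tab$subject[i], v)
      if (is.null(rec)) return(NULL)
      f <- recording_features(rec, lf, cohort$scheme, bands = "alpha1",
                              density = density, overlap = overlap,
                              filter_high = max(cohort$scheme$f_high),
                              inverse = inv)
      c(icoh = mean(f$icoh$alpha1[pair_idx]),
        npl = mean(f$nodal_path_length["alpha1", rois]))
    })
    if (is.null(vals[[1]]) || is.null(vals[[2]])) next
    icoh_chg[i] <- vals[[2]]["icoh"] - vals[[1]]["icoh"]
    npl_chg[i] <- vals[[2]]["npl"] - vals[[1]]["npl"]
  }
  is_int <- tab$arm %in% c("FMI", "HMI")
  ok <- !is.na(icoh_chg)
  ok2 <- !is.na(npl_chg)
  xi <- icoh_chg[is_int & ok]; xc <- icoh_chg[!is_int & ok]
  yi <- npl_chg[is_int & ok2]; yc <- npl_chg[!is_int & ok2]
  list(p_icoh = mann_whitney_u(xi, xc)$p,
       p_npl = mann_whitney_u(yi, yc)$p,
       delta_icoh = mean(xi) - mean(xc),
       delta_npl = mean(yi) - mean(yc),
       icoh_change = icoh_chg, npl_change = npl_chg, arm = tab$arm)
}
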