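# Cohort-level orchestration: preprocess -> band power -> coupling ->
# group statistics, with provenance.

#' Study configuration
#'
#' Collects every tunable of the pipeline in one validated list.
#'
#' @param window_min analysis window length in minutes; one of 10, 7, 5, 3,
#'   2, 1 (the tested set).
#' @param alpha raw per-channel significance level (default 0.01).
#' @param min_cluster minimum spatial cluster size (default 2).
#' @param n_perm permutations for the cluster null (default 1000).
#' @param seed RNG seed for the permutation draw.
#' @param estimator list: `window_s`, `step_s`, `lag_s`, `grid_step_s`,
#'   `hrv_method`.
#' @param eeg_bands,hrv_bands band subsets to analyse.
#' @param directions coupling directions to analyse (default both).
#' @param mode comparison mode (currently `preictal_vs_postictal` or
#'   `surrogate_interictal`).
#' @return list of class `run_config`.
#' @export
run_config <- function(window_min = 10, alpha = 0.01, min_cluster = 2L,
                       n_perm = 1000L, seed = 7L,
                       estimator = list(window_s = 15, step_s = 1, lag_s = 1,
                                        grid_step_s = 1,
                                        hrv_method = "spwvd"),
                       eeg_bands = c("delta", "theta", "alpha", "beta"),
                       hrv_bands = c("LF", "HF"),
                       directions = c("bth", "htb"),
                       mode = c("preictal_vs_postictal",
                                "surrogate_interictal")) {
  if (!window_min %in% c(10, 7, 5, 3, 2, 1))
    stopf("window_min must be one of 10, 7, 5, 3, 2, 1")
  stopifnot(alpha > 0, alpha < 1)
  mode <- match.arg(mode)
  est <- utils::modifyList(list(window_s = 15, step_s = 1, lag_s = 1,
                                grid_step_s = 1, hrv_method = "spwvd"),
                           estimator)
  structure(list(window_min = window_min, alpha = alpha,
                 min_cluster = as.integer(min_cluster),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 estimator = est, eeg_bands = eeg_bands,
                 hrv_bands = hrv_bands, directions = directions, mode = mode),
            class = "run_config")
}

#' Run the full group study on a cohort
#'
#' For every event: window extraction (with the insufficient-data exclusion
#' rule), band power estimation, directional coupling series, and phase
#' summaries. Then, per (direction, EEG band, HRV band): Shapiro-Wilk
#' normality screen, paired signed-rank channel map, spatial cluster
#' permutation correction, and the z-scored one-minute group trend.
#'
#' @param events cohort: a list of `sim_output` objects, or a list of
#'   `list(edf =, annotations =)` paths.
#' @param config a `run_config`.
#' @param out_dir optional directory; when given, coefficient summaries,
#'   stat maps, trends and a JSON run manifest are written there.
#' @return list of class `bhi_study`: `maps` (per band pair, corrected
#'   `stat_map`), `trends`, `screen`, `summaries`, `exclusions`, `config`.
#' @export
run_study <- function(events, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  L <- config$window_min * 60
  est <- config$estimator
  exclusions <- list()
  phase_meds <- list()
  minute_meds <- list()

  for (e in seq_along(events)) {
    ev <- events[[e]]
    if (inherits(ev, "sim_output")) {
      rec <- ev$recording; ann <- ev$annotations
      eid <- sprintf("ev%03d", e)
    } else {
      got <- read_recording(ev$edf, ev$annotations)
      rec <- got$recording; ann <- got$annotations
      eid <- basename(ev$edf)
    }
    if (!nrow(ann)) {
      exclusions[[eid]] <- "no seizure annotation"
      next
    }
    win <- if (config$mode == "surrogate_interictal") {
      sw <- surrogate_windows(ann$onset_s[1], window_min = config$window_min)
      if (!isTRUE(sw$excluded)) sw$event_id <- eid
      sw
    } else {
      extract_windows(rec, ann[1, ], window_len_s = L, event_id = eid)
    }
    if (isTRUE(win$excluded)) {
      exclusions[[eid]] <- win$reason
      next
    }
    co <- compute_bhi_event(rec, win, eeg_bands = config$eeg_bands,
                            hrv_bands = config$hrv_bands,
                            directions = config$directions,
                            window_s = est$window_s, step_s = est$step_s,
                            lag_s = est$lag_s,
                            grid_step_s = est$grid_step_s,
                            hrv_method = est$hrv_method)
    sm <- event_phase_summary(co, win)
    phase_meds[[eid]] <- sm$phase_median
    minute_meds[[eid]] <- sm$minute_median
  }
  if (length(phase_meds) < 6L)
    stopf("fewer than 6 usable events (%d excluded)", length(exclusions))

  pm <- do.call(rbind, phase_meds)
  mm <- do.call(rbind, minute_meds)
  pairs <- unique(pm[, c("direction", "eeg_band", "hrv_band")])
  channels <- sort(unique(pm$channel))
  adj <- channel_adjacency(montage_1020(channels))

  maps <- list(); trends <- list(); screens <- list()
  for (r in seq_len(nrow(pairs))) {
    key <- sprintf("%s_%s_%s", pairs$direction[r], pairs$eeg_band[r],
                   pairs$hrv_band[r])
    sub <- pm[pm$direction == pairs$direction[r] &
                pm$eeg_band == pairs$eeg_band[r] &
                pm$hrv_band == pairs$hrv_band[r], ]
    pre <- stats::reshape(
      sub[sub$phase == "preictal", c("event_id", "channel", "median_coeff")],
      idvar = "event_id", timevar = "channel", direction = "wide")
    post <- stats::reshape(
      sub[sub$phase == "postictal", c("event_id", "channel", "median_coeff")],
      idvar = "event_id", timevar = "channel", direction = "wide")
    post <- post[match(pre$event_id, post$event_id), , drop = FALSE]
    cn <- sub("^median_coeff\\.", "", names(pre)[-1])
    preM <- as.matrix(pre[, -1, drop = FALSE]); colnames(preM) <- cn
    postM <- as.matrix(post[, -1, drop = FALSE]); colnames(postM) <- cn
    ord <- match(channels, cn)
    preM <- preM[, ord, drop = FALSE]; postM <- postM[, ord, drop = FALSE]
    keep <- stats::complete.cases(cbind(preM, postM))
    preM <- preM[keep, , drop = FALSE]; postM <- postM[keep, , drop = FALSE]
    if (nrow(preM) < 6L) next

    screens[[key]] <- shapiro_wilk_screen(preM - postM)
    map <- wilcoxon_paired_map(preM, postM, alpha = config$alpha)
    maps[[key]] <- cluster_permutation_correct(
      map, adj, min_cluster = config$min_cluster,
      n_perm = config$n_perm, seed = config$seed)

    msub <- mm[mm$direction == pairs$direction[r] &
                 mm$eeg_band == pairs$eeg_band[r] &
                 mm$hrv_band == pairs$hrv_band[r], ]
    trends[[key]] <- trend_from_minutes(msub, config$window_min)
  }

  res <- structure(list(maps = maps, trends = trends, screen = screens,
                        summaries = list(phase = pm, minute = mm),
                        exclusions = exclusions, config = config,
                        channels = channels),
                   class = "bhi_study")
  if (!is.null(out_dir)) write_study(res, out_dir)
  res
}

# build the events x (2*n_min) minute matrix (channel-median per minute)
# and z-score it; preictal minutes first, oldest first
trend_from_minutes <- function(msub, window_min) {
  n_min <- window_min
  agg <- stats::aggregate(msub["median_coeff"],
                          msub[c("event_id", "phase", "minute")],
                          stats::median)
  evs <- unique(agg$event_id)
  M <- matrix(NA_real_, length(evs), 2L * n_min)
  for (i in seq_along(evs)) {
    for (ph in c("preictal", "postictal")) {
      s <- agg[agg$event_id == evs[i] & agg$phase == ph, ]
      col0 <- if (ph == "preictal") 0L else n_min
      M[i, col0 + s$minute] <- s$median_coeff
    }
  }
  ok <- stats::complete.cases(M)
  if (sum(ok) < 2L) return(NULL)
  tz <- trend_zscore(M[ok, , drop = FALSE])
  tz$minute_axis <- c(-(n_min:1), 1:n_min)  # minutes relative to seizure
  tz
}

#' @export
print.bhi_study <- function(x, ...) {
  cat(sprintf("<bhi_study> %d band pairs, %d channels, %d events (%d excluded)\n",
              length(x$maps), length(x$channels),
              length(unique(x$summaries$phase$event_id)), length(x$exclusions)))
  for (k in names(x$maps)) {
    m <- x$maps[[k]]
    cat(sprintf("  %-18s %2d raw-significant, %2d cluster-corrected\n", k,
                sum(m$raw_significant), sum(m$corrected_significant)))
  }
  invisible(x)
}

write_study <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$summaries$phase,
                   file.path(out_dir, "phase_medians.csv"), row.names = FALSE)
  utils::write.csv(res$summaries$minute,
                   file.path(out_dir, "minute_medians.csv"), row.names = FALSE)
  for (k in names(res$maps)) {
    utils::write.csv(as.data.frame(res$maps[[k]]),
                     file.path(out_dir, sprintf("statmap_%s.csv", k)),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, sprintf("topomap_%s.png", k)),
                   width = 480, height = 480)
    render_topomap(res$maps[[k]], montage_1020(res$channels), main = k)
    grDevices::dev.off()
  }
  tr <- lapply(res$trends, function(t)
    if (is.null(t)) NULL else data.frame(minute = t$minute_axis,
                                         trend = t$trend, se = t$se))
  for (k in names(tr)) if (!is.null(tr[[k]]))
    utils::write.csv(tr[[k]], file.path(out_dir, sprintf("trend_%s.csv", k)),
                     row.names = FALSE)
  manifest <- list(
    config = unclass(res$config),
    n_events = length(unique(res$summaries$phase$event_id)),
    exclusions = res$exclusions,
    channels = res$channels,
    package_version = as.character(utils::packageVersion("bhisdg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
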