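# Group statistics: normality screen, paired signed-rank channel maps,
# spatial cluster permutation correction, z-scored minute trends.

#' Exact/approximate two-sided Wilcoxon signed-rank test
#'
#' Paired signed-rank test with the conventions used throughout the channel
#' maps: zero differences dropped (their count returned), average ranks for
#' ties. For `n <= exact_max` the null distribution of the positive-rank sum
#' W+ is computed exactly by the sign-flip generating function (valid under
#' ties, where the textbook tables are not); beyond that a normal
#' approximation with tie and continuity correction is used.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max largest n for the exact null (default 25).
#' @return list: `p` (two-sided), `w` (W+ statistic), `n_used`, `n_zero`,
#'   `sign` (+1 if positive median difference, -1 otherwise, 0 if all zero),
#'   `method`.
#' @export
signed_rank_test <- function(d, exact_max = 25L) {
  d <- d[is.finite(d)]
  nz <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p = 1, w = NA_real_, n_used = 0L, n_zero = nz, sign = 0,
                method = "degenerate"))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  sgn <- sign(stats::median(d))
  if (sgn == 0) sgn <- sign(sum(sign(d) * r))
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, w)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(p = p, w = w, n_used = n, n_zero = nz, sign = sgn, method = method)
}

# exact two-sided p for W+ = w given rank magnitudes r (ties allowed):
# convolve the generating function over the 2^n equiprobable sign vectors.
# Ranks are doubled so half-integer average ranks become integer support.
signed_rank_exact_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  tot <- sum(r2)
  dist <- numeric(tot + 1L)   # index k+1 <-> W2 = k
  dist[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dist[seq_len(tot + 1L - ri)])
    dist <- (dist + shifted) / 2
  }
  w2 <- as.integer(round(2 * w))
  lo <- sum(dist[seq_len(w2 + 1L)])            # P(W2 <= w2)
  hi <- sum(dist[(w2 + 1L):(tot + 1L)])        # P(W2 >= w2)
  min(1, 2 * min(lo, hi))
}

#' Shapiro-Wilk normality screen across channels
#'
#' Screens the per-channel paired differences and recommends nonparametric
#' testing when a majority of channels reject normality at the screen level.
#'
#' @param diffs events x channels matrix of paired differences.
#' @param alpha screen level (default 0.05).
#' @return list: `p` (per channel; `NA` for constant samples, which are
#'   flagged), `reject` (logical), `flagged` (constant channels),
#'   `recommend_nonparametric`.
#' @export
shapiro_wilk_screen <- function(diffs, alpha = 0.05) {
  diffs <- as.matrix(diffs)
  if (nrow(diffs) < 3L) stopf("need at least 3 paired events per channel")
  p <- apply(diffs, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(unique(v)) < 3L) return(NA_real_)
    stats::shapiro.test(v)$p.value
  })
  rej <- !is.na(p) & p < alpha
  list(p = p, reject = rej, flagged = is.na(p),
       recommend_nonparametric = mean(rej, na.rm = TRUE) > 0.5)
}

#' Channel adjacency from montage coordinates
#'
#' Two channels are neighbours when their distance is below
#' `factor` times the median nearest-neighbour spacing of the montage —
#' the standard distance-neighbourhood rule for sensor-level cluster
#' statistics. Symmetric, no self-loops.
#'
#' @param montage_xy data.frame with `label`, `x`, `y`.
#' @param factor neighbourhood radius multiplier (default 2.0, which on the
#'   reference montage connects neighbouring outer-ring electrodes such as
#'   F7-T3 while keeping the graph local).
#' @return logical adjacency matrix with channel labels as dimnames.
#' @export
channel_adjacency <- function(montage_xy, factor = 2.0) {
  D <- as.matrix(stats::dist(montage_xy[, c("x", "y")]))
  diag(D) <- Inf
  thr <- factor * stats::median(apply(D, 1, min))
  A <- D <= thr
  diag(A) <- FALSE
  dimnames(A) <- list(montage_xy$label, montage_xy$label)
  A
}

# connected components of `mask` under adjacency A; returns integer labels
# (0 = not in mask)
find_clusters <- function(mask, A) {
  n <- length(mask)
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!mask[i] || lab[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(A[v, ] & mask & lab == 0L)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Uncorrected paired signed-rank channel map
#'
#' One two-sided signed-rank test per channel on the per-event preictal
#' minus postictal summary values.
#'
#' @param pre,post events x channels matrices of per-event phase summaries
#'   (e.g. median coupling coefficients). Rows are paired events.
#' @param alpha raw significance level (default 0.01).
#' @return data.frame of class `stat_map`: `channel`, `p`, `sign`
#'   (+1 = preictal higher), `raw_significant`; cluster columns are added by
#'   [cluster_permutation_correct()].
#' @export
wilcoxon_paired_map <- function(pre, post, alpha = 0.01) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  stopifnot(identical(dim(pre), dim(post)))
  if (nrow(pre) < 6L) stopf("need at least 6 paired events")
  d <- pre - post
  res <- apply(d, 2, signed_rank_test)
  out <- data.frame(
    channel = colnames(pre) %||% paste0("ch", seq_len(ncol(pre))),
    p = vapply(res, `[[`, numeric(1), "p"),
    sign = vapply(res, `[[`, numeric(1), "sign"),
    row.names = NULL, stringsAsFactors = FALSE)
  out$raw_significant <- out$p < alpha
  attr(out, "alpha") <- alpha
  attr(out, "diffs") <- d
  class(out) <- c("stat_map", "data.frame")
  out
}

#' Spatial cluster permutation correction of a channel map
#'
#' Connected sets of raw-significant channels smaller than `min_cluster`
#' are discarded outright. The remaining clusters are kept when their size
#' (channel count) exceeds the null distribution of the maximum cluster
#' size, built by random within-event pre/post label swaps (sign flips of
#' the paired differences, re-testing every channel per permutation).
#' Positive and negative clusters are formed separately, as both effect
#' directions are reported.
#'
#' @param map a `stat_map` from [wilcoxon_paired_map()] (carries the paired
#'   differences).
#' @param adjacency logical adjacency matrix over the map's channels.
#' @param min_cluster minimum cluster size (default 2).
#' @param n_perm number of permutations (default 1000; below 100 is refused).
#' @param seed RNG seed for the permutation draw.
#' @param cluster_alpha cluster-level significance (default 0.05).
#' @return the map with columns `cluster_id` (0 = none) and
#'   `corrected_significant`, plus attributes `null_max_size` and
#'   `cluster_p` (empirical p per cluster id).
#' @export
cluster_permutation_correct <- function(map, adjacency, min_cluster = 2L,
                                        n_perm = 1000L, seed = 1L,
                                        cluster_alpha = 0.05) {
  if (n_perm < 100L) stopf("n_perm < 100 gives an unstable permutation null")
  d <- attr(map, "diffs")
  if (is.null(d)) stopf("map carries no paired differences; use wilcoxon_paired_map()")
  alpha <- attr(map, "alpha")
  A <- adjacency
  stopifnot(ncol(d) == nrow(map), all(dim(A) == nrow(map)))

  signed_mask <- function(dd) {
    res <- apply(dd, 2, signed_rank_test)
    p <- vapply(res, `[[`, numeric(1), "p")
    s <- vapply(res, `[[`, numeric(1), "sign")
    list(pos = p < alpha & s > 0, neg = p < alpha & s < 0)
  }
  clusters_of <- function(mask) {
    lab <- find_clusters(mask, A)
    sizes <- if (max(lab) > 0L) tabulate(lab[lab > 0L]) else integer(0)
    list(lab = lab, sizes = sizes)
  }
  obs <- signed_mask(d)
  cl_pos <- clusters_of(obs$pos); cl_neg <- clusters_of(obs$neg)
  # merged labelling: negative clusters numbered after positive ones
  lab <- cl_pos$lab
  lab[cl_neg$lab > 0L] <- cl_neg$lab[cl_neg$lab > 0L] + max(cl_pos$lab)
  sizes <- c(cl_pos$sizes, cl_neg$sizes)

  # sign flips leave |d| (hence its ranks) untouched, so in the
  # normal-approximation regime W+ per permutation is just a masked column
  # sum of the precomputed rank matrix
  fast <- all(colSums(d != 0) > 25L)
  if (fast) {
    R <- apply(d, 2, function(v) {
      r <- numeric(length(v)); nzv <- v != 0
      r[nzv] <- rank(abs(v[nzv])); r
    })
    S <- sign(d)
    nn <- colSums(d != 0)
    mu <- nn * (nn + 1) / 4
    sig <- vapply(seq_len(ncol(d)), function(c2) {
      r <- R[, c2][R[, c2] > 0]
      tt <- table(r)
      sqrt(nn[c2] * (nn[c2] + 1) * (2 * nn[c2] + 1) / 24 - sum(tt^3 - tt) / 48)
    }, numeric(1))
  }
  perm_masks <- function(flip) {
    if (fast) {
      pos <- (S * flip) > 0
      W <- colSums(R * pos)
      z <- (W - mu - sign(W - mu) * 0.5) / sig
      p <- 2 * stats::pnorm(-abs(z))
      list(pos = p < alpha & W > mu, neg = p < alpha & W < mu)
    } else signed_mask(d * flip)
  }

  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(i) {
    flip <- sample(c(-1, 1), nrow(d), replace = TRUE)
    m <- perm_masks(flip)
    s1 <- clusters_of(m$pos)$sizes; s2 <- clusters_of(m$neg)$sizes
    s <- c(s1[s1 >= min_cluster], s2[s2 >= min_cluster])
    if (length(s)) max(s) else 0L
  }, numeric(1))

  cl_p <- vapply(seq_along(sizes), function(k) {
    if (sizes[k] < min_cluster) return(1)
    (1 + sum(null_max >= sizes[k])) / (1 + n_perm)
  }, numeric(1))
  sig_cluster <- which(sizes >= min_cluster & cl_p <= cluster_alpha)

  map$cluster_id <- lab
  map$corrected_significant <- lab %in% sig_cluster & map$raw_significant
  attr(map, "null_max_size") <- null_max
  attr(map, "cluster_p") <- cl_p
  attr(map, "min_cluster") <- min_cluster
  map
}

#' Z-scored one-minute coupling trends across events
#'
#' Each event contributes per-minute medians for both phases (10 + 10 for
#' the 10-minute setting). The values of one event are z-scored jointly
#' across both phases — making seizures comparable — and then averaged
#' across events per minute index. Events with zero within-event variance
#' are excluded with a warning.
#'
#' @param minute_medians events x (2 * n_min) matrix: preictal minutes
#'   first (oldest first), then postictal minutes.
#' @return list: `trend` (mean z-score per minute index), `se` (standard
#'   error across events), `n_events`, `excluded` (row indices).
#' @export
trend_zscore <- function(minute_medians) {
  M <- as.matrix(minute_medians)
  sds <- apply(M, 1, stats::sd)
  bad <- which(!is.finite(sds) | sds == 0)
  if (length(bad)) {
    warnf("%d event(s) with zero within-event variance excluded from trend",
          length(bad))
    M <- M[-bad, , drop = FALSE]
  }
  if (!nrow(M)) stopf("no events left for trend")
  Z <- t(scale(t(M)))
  list(trend = colMeans(Z), se = apply(Z, 2, stats::sd) / sqrt(nrow(Z)),
       n_events = nrow(Z), excluded = bad)
}

#' Surrogate interictal control analysis
#'
#' Applies the identical pre/post pipeline to two windows taken from a
#' seizure-free stretch, separated by `gap_s` to simulate a surrogate ictal
#' event. Under stationary coupling the corrected map is expected empty.
#'
#' @param pre,post events x channels matrices of surrogate-window summaries
#'   (same form as for [wilcoxon_paired_map()]).
#' @param adjacency channel adjacency matrix.
#' @param ... passed to [cluster_permutation_correct()].
#' @return corrected `stat_map`.
#' @export
surrogate_map <- function(pre, post, adjacency, ...) {
  cluster_permutation_correct(wilcoxon_paired_map(pre, post), adjacency, ...)
}

#' Surrogate window placement in a seizure-free stretch
#'
#' Two `window_min`-minute windows separated by `gap_s`, ending
#' `lead_s` before the first seizure onset.
#'
#' @param first_onset_s first seizure onset (seconds).
#' @param window_min window length in minutes (default 5).
#' @param gap_s separation simulating the surrogate event (default 60).
#' @param lead_s distance of the block's end from onset (default 3600).
#' @return `analysis_window_pair`-shaped list, or an exclusion record when
#'   the record has insufficient interictal data.
#' @export
surrogate_windows <- function(first_onset_s, window_min = 5, gap_s = 60,
                              lead_s = 3600) {
  L <- window_min * 60
  end2 <- first_onset_s - lead_s
  start1 <- end2 - gap_s - 2 * L
  if (start1 < 0)
    return(list(excluded = TRUE,
                reason = sprintf("needs %.0f s before onset, record has %.0f s",
                                 lead_s + gap_s + 2 * L, first_onset_s)))
  structure(list(preictal = c(start1, start1 + L),
                 postictal = c(start1 + L + gap_s, end2),
                 window_len_s = L, event_id = "surrogate", excluded = FALSE),
            class = "analysis_window_pair")
}
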