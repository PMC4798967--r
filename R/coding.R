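#' Segment a spike train into bursts
#'
#' A new burst opens at any spike whose preceding inter-spike interval
#' exceeds `isi_gap_threshold`; the first spike always opens a burst.  The
#' default threshold (25 ms) sits below the smallest inter-burst interval
#' expected in the stimulus set (50 ms at SP 0.5 mm and 10 mm/s) and above
#' the intra-burst intervals produced by the encoder.
#'
#' @param train A `spike_train` (times in s).
#' @param isi_gap_threshold Gap threshold in ms.
#' @return An object of class `burst_segmentation` with `burst_onsets` (s),
#'   `spikes_per_burst` (integer counts) and the threshold used.  An empty
#'   train yields an empty segmentation.
#' @export
segment_bursts <- function(train, isi_gap_threshold = 25) {
  stopifnot(inherits(train, "spike_train"))
  if (isi_gap_threshold <= 0) stop("isi_gap_threshold must be positive")
  s <- train$spike_times
  if (length(s) == 0) {
    return(structure(list(burst_onsets = numeric(0),
                          spikes_per_burst = integer(0),
                          isi_gap_threshold = isi_gap_threshold),
                     class = "burst_segmentation"))
  }
  new_burst <- c(TRUE, diff(s) * 1000 > isi_gap_threshold)
  id <- cumsum(new_burst)
  structure(list(burst_onsets = s[new_burst],
                 spikes_per_burst = as.integer(tabulate(id)),
                 isi_gap_threshold = isi_gap_threshold),
            class = "burst_segmentation")
}

#' Temporal-coding metrics of one slide-phase spike train
#'
#' Computes, for a spike train windowed to the 2 s sliding phase:
#' * the inter-burst intervals (IBI, ms) between onsets of consecutive
#'   bursts, summarised by their median;
#' * the average firing rate (AFR), total spikes divided by the fixed slide
#'   duration, spikes/s;
#' * the instantaneous firing rate, the inverse of each inter-spike
#'   interval assigned to its right edge;
#' * the spatial modulation index at the grating's ridge frequency, when a
#'   grating and velocity are supplied.
#'
#' @param train A `spike_train` windowed to the slide phase.
#' @param slide_duration Slide duration, s (default 2).
#' @param grating Optional [grating_spec()] for the spatial modulation index.
#' @param velocity Sliding velocity, mm/s (required with `grating`).
#' @param isi_gap_threshold Burst gap threshold, ms.
#' @return An object of class `coding_metrics`: `ibis`, `ibi_median` (ms,
#'   `NA` with `ibi_defined = FALSE` when fewer than two bursts), `afr`
#'   (spikes/s), `inst_rate` (data frame `time`, `rate`), `smi`, and the
#'   burst segmentation.
#' @export
compute_metrics <- function(train, slide_duration = 2,
                            grating = NULL, velocity = NULL,
                            isi_gap_threshold = 25) {
  stopifnot(inherits(train, "spike_train"))
  seg <- segment_bursts(train, isi_gap_threshold)
  ibis <- diff(seg$burst_onsets) * 1000
  ibi_defined <- length(seg$burst_onsets) >= 2
  s <- train$spike_times
  inst <- if (length(s) >= 2) {
    data.frame(time = s[-1], rate = 1 / diff(s))
  } else {
    data.frame(time = numeric(0), rate = numeric(0))
  }
  smi <- if (!is.null(grating)) {
    if (is.null(velocity)) stop("velocity is required to compute the spatial modulation index")
    spatial_modulation_index(train, grating, velocity,
                             duration = slide_duration)
  } else NA_real_
  structure(list(ibis = ibis,
                 ibi_median = if (ibi_defined) median(ibis) else NA_real_,
                 ibi_defined = ibi_defined,
                 afr = length(s) / slide_duration,
                 inst_rate = inst,
                 smi = smi,
                 bursts = seg),
            class = "coding_metrics")
}

#' Spatial modulation index at the ridge frequency
#'
#' Degree to which firing is modulated at the grating's ridge-passage
#' frequency `f = v / SP`.  The spike train is binned (5 ms bins over the
#' slide), the binned rate is smoothed with a fixed Gaussian kernel
#' (sigma 15 ms, a receptor-like temporal integration window), and the
#' index is the amplitude of the Fourier component of the smoothed rate at
#' `f`, normalised by the mean rate:
#' `SMI = 2 |sum_k r_k exp(-2 pi i f t_k)| / sum_k r_k`.
#' The index is 0 for an unmodulated train and approaches 2 for firing
#' fully concentrated at the ridge frequency (at periods long relative to
#' the smoothing window).
#'
#' @param train A `spike_train` windowed to the slide phase.
#' @param grating A [grating_spec()].
#' @param velocity Sliding velocity, mm/s.
#' @param bin_ms Bin width, ms.
#' @param smooth_sd_ms Gaussian smoothing sigma, ms.
#' @param duration Analysis window, s.
#' @return The index (>= 0), or `NA` for an empty train.
#' @export
spatial_modulation_index <- function(train, grating, velocity,
                                     bin_ms = 5, smooth_sd_ms = 15,
                                     duration = 2) {
  stopifnot(inherits(train, "spike_train"), inherits(grating, "grating_spec"))
  s <- train$spike_times
  if (length(s) == 0) return(NA_real_)
  f <- velocity / grating$spatial_period       # Hz
  edges <- seq(0, duration, by = bin_ms / 1000)
  sc <- s[s >= 0 & s < duration]
  counts <- tabulate(findInterval(sc, edges), nbins = length(edges) - 1)
  rate <- counts / (bin_ms / 1000)
  # Gaussian smoothing by direct convolution, zero-padded edges
  half <- ceiling(4 * smooth_sd_ms / bin_ms)
  kern <- dnorm(seq(-half, half), sd = smooth_sd_ms / bin_ms)
  kern <- kern / sum(kern)
  n <- length(rate)
  padded <- c(numeric(half), rate, numeric(half))
  sm <- vapply(seq_len(n), function(i)
    sum(padded[i:(i + 2 * half)] * kern), numeric(1))
  centers <- edges[-length(edges)] + bin_ms / 2000
  if (sum(sm) <= 0) return(0)
  2 * Mod(sum(sm * exp(-2i * pi * f * centers))) / sum(sm)
}

#' Signed pair features for one presentation
#'
#' Differences (first half minus second half) of the coding metrics of a
#' stimulus pair: `delta_ibi` (ms), `delta_afr` (spikes/s) and the signed
#' `delta_sp` (mm) from the pair definition.
#'
#' @param first,second `coding_metrics` of the two slide phases.
#' @param pair The presented [make_stimulus_pair()].
#' @return An object of class `pair_features`; `ibi_defined` is `FALSE`
#'   (and `delta_ibi` is `NA`) when either half has an undefined IBI.
#' @export
pair_features <- function(first, second, pair) {
  stopifnot(inherits(first, "coding_metrics"),
            inherits(second, "coding_metrics"),
            inherits(pair, "stimulus_pair"))
  ok <- first$ibi_defined && second$ibi_defined
  structure(list(label = pair$label, order = pair$order,
                 delta_sp = pair$delta_sp,
                 delta_ibi = if (ok) first$ibi_median - second$ibi_median else NA_real_,
                 delta_afr = first$afr - second$afr,
                 ibi_defined = ok),
            class = "pair_features")
}

#' Regression of a pair feature on the spatial-period difference
#'
#' Ordinary least squares of the signed feature (delta-IBI or delta-AFR) on
#' the signed delta-SP across presentations, with the squared Pearson
#' correlation as the goodness of fit.
#'
#' @param features A list of [pair_features()] objects, or a data frame
#'   with columns `delta_sp`, `delta_ibi`, `delta_afr`.
#' @param which `"delta_ibi"` or `"delta_afr"`.
#' @return A list with `slope`, `intercept`, `r_squared` and `n`.
#' @export
feature_vs_dsp_regression <- function(features, which = c("delta_ibi", "delta_afr")) {
  which <- match.arg(which)
  df <- if (is.data.frame(features)) features else
    do.call(rbind, lapply(features, function(f)
      data.frame(delta_sp = f$delta_sp, delta_ibi = f$delta_ibi,
                 delta_afr = f$delta_afr)))
  df <- df[is.finite(df$delta_sp) & is.finite(df[[which]]), ]
  if (length(unique(df$delta_sp)) < 3)
    stop("need at least 3 distinct delta-SP values for the regression")
  if (stats::var(df$delta_sp) == 0) stop("degenerate delta-SP variance")
  fit <- lm(df[[which]] ~ df$delta_sp)
  r2 <- if (stats::var(df[[which]]) == 0) 0 else
    cor(df$delta_sp, df[[which]])^2
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = nrow(df))
}

#' IBI specificity across spatial periods
#'
#' One-way ANOVA of per-trial IBI medians across spatial-period groups,
#' followed by Tukey-Kramer pairwise comparisons, reporting which SP pairs
#' separate at the given level.
#'
#' @param ibi Numeric vector of per-trial IBI medians (ms).
#' @param sp Grouping vector of spatial periods (mm), same length.
#' @param alpha Familywise level for the pairwise report.
#' @return A list with the ANOVA `p_value`, `f_statistic`, a data frame
#'   `pairs` (`pair`, `diff`, `p_adj`, `separated`) and `all_separated`.
#' @export
ibi_specificity_test <- function(ibi, sp, alpha = 0.05) {
  stopifnot(length(ibi) == length(sp))
  g <- factor(sp)
  if (nlevels(g) < 2) stop("need at least 2 spatial-period groups")
  if (any(table(g) < 2)) stop("every spatial-period group needs at least 2 trials")
  fit <- aov(ibi ~ g)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      separated = tk[, "p adj"] < alpha,
                      row.names = NULL)
  list(p_value = an[["Pr(>F)"]][1], f_statistic = an[["F value"]][1],
       pairs = pairs, all_separated = all(pairs$separated))
}

#' Tidy metrics table for a set of encoded trials
#'
#' One row per trial half: stimulus label, order, half index, SP, IBI
#' median, AFR and spatial modulation index.
#'
#' @param trials A list of `encoded_trial` objects.
#' @param protocol The [sliding_protocol()] used (for velocity and slide
#'   duration).
#' @return A data frame.
#' @export
metrics_table <- function(trials, protocol = sliding_protocol()) {
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    sps <- c(tr$pair$first_sp, tr$pair$second_sp)
    do.call(rbind, lapply(1:2, function(h) {
      m <- compute_metrics(tr$halves[[h]], protocol$slide_duration,
                           grating = grating_spec(sps[h]),
                           velocity = protocol$velocity)
      data.frame(trial = i, stimulus = tr$pair$label, order = tr$pair$order,
                 half = h, sp = sps[h], ibi_median = m$ibi_median,
                 afr = m$afr, smi = m$smi)
    }))
  })
  do.call(rbind, rows)
}
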