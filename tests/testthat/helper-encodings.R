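# Shared fixtures, built in code and cached across test files.

.ms_cache <- new.env(parent = emptyenv())

# calibration with every stochastic element switched off: deterministic
# traces, first ridge locked to slide onset
noise_free_calib <- function() {
  sensor_calibration(noise_sd = 0, gain_jitter_sd = 0, phase_jitter = FALSE)
}

.pair_labels <- c("D0.0", "D1.0", "D2.0", "D2.5")

# encode the four "+" pairs once, noise-free; returns per-pair traces,
# encoded trials and per-half metrics
noise_free_encodings <- function() {
  if (!is.null(.ms_cache$nf)) return(.ms_cache$nf)
  prot <- sliding_protocol()
  cal <- noise_free_calib()
  out <- lapply(.pair_labels, function(lab) {
    pair <- make_stimulus_pair(lab, "+")
    trace <- synth_sensor_trace(pair, prot, cal, seed = 1)
    enc <- encode_trial(trace)
    metrics <- lapply(1:2, function(h) {
      sp <- c(pair$first_sp, pair$second_sp)[h]
      compute_metrics(enc$halves[[h]], prot$slide_duration,
                      grating = grating_spec(sp), velocity = prot$velocity)
    })
    list(pair = pair, trace = trace, enc = enc, metrics = metrics)
  })
  names(out) <- .pair_labels
  .ms_cache$nf <- out
  out
}

# per-half metrics of the noise-free encodings, one row per distinct SP
noise_free_by_sp <- function() {
  if (!is.null(.ms_cache$nf_sp)) return(.ms_cache$nf_sp)
  rows <- list()
  for (e in noise_free_encodings()) {
    for (h in 1:2) {
      sp <- c(e$pair$first_sp, e$pair$second_sp)[h]
      key <- sprintf("%.1f", sp)
      if (is.null(rows[[key]])) {
        m <- e$metrics[[h]]
        spb <- m$bursts$spikes_per_burst
        rows[[key]] <- data.frame(
          sp = sp, ibi_median = m$ibi_median, afr = m$afr, smi = m$smi,
          modal_spb = as.numeric(names(sort(table(spb), decreasing = TRUE))[1]))
      }
    }
  }
  out <- do.call(rbind, rows[order(as.numeric(names(rows)))])
  rownames(out) <- NULL
  .ms_cache$nf_sp <- out
  out
}

# n_reps seeded repetitions of the four "+" pairs under the default
# calibration; returns per-half metrics and per-trial pair features
default_run <- function(n_reps = 20) {
  key <- paste0("run", n_reps)
  if (!is.null(.ms_cache[[key]])) return(.ms_cache[[key]])
  if (n_reps < 20 && !is.null(.ms_cache$run20)) {
    full <- .ms_cache$run20
    out <- list(halves = full$halves[full$halves$rep <= n_reps, ],
                features = full$features[full$features$rep <= n_reps, ])
    .ms_cache[[key]] <- out
    return(out)
  }
  prot <- sliding_protocol()
  cal <- sensor_calibration()
  halves <- list()
  feats <- list()
  for (rep in seq_len(n_reps)) {
    for (lab in .pair_labels) {
      pair <- make_stimulus_pair(lab, "+")
      trace <- synth_sensor_trace(pair, prot, cal,
                                  seed = derive_seed(rep, match(lab, .pair_labels)))
      enc <- encode_trial(trace)
      ms <- lapply(1:2, function(h) {
        sp <- c(pair$first_sp, pair$second_sp)[h]
        compute_metrics(enc$halves[[h]], prot$slide_duration,
                        grating = grating_spec(sp), velocity = prot$velocity)
      })
      for (h in 1:2) {
        sp <- c(pair$first_sp, pair$second_sp)[h]
        spb <- ms[[h]]$bursts$spikes_per_burst
        halves[[length(halves) + 1]] <- data.frame(
          rep = rep, label = lab, half = h, sp = sp,
          ibi_median = ms[[h]]$ibi_median, afr = ms[[h]]$afr,
          smi = ms[[h]]$smi,
          modal_spb = as.numeric(names(sort(table(spb), decreasing = TRUE))[1]))
      }
      f <- pair_features(ms[[1]], ms[[2]], pair)
      feats[[length(feats) + 1]] <- data.frame(
        rep = rep, label = lab, delta_sp = f$delta_sp,
        delta_ibi = f$delta_ibi, delta_afr = f$delta_afr)
    }
  }
  out <- list(halves = do.call(rbind, halves),
              features = do.call(rbind, feats))
  .ms_cache[[key]] <- out
  out
}

# regular spike train: one spike per period_s, n periods
comb_train <- function(period_s, n, duration = 2) {
  spike_train(seq(0, by = period_s, length.out = n), duration)
}
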