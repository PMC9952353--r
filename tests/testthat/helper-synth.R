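# Shared fixture builders (everything generated in code, nothing stored).

# random annotated record for round-trip and invariant tests
rand_record <- function(seed, n = 2000, fs = 360) {
  set.seed(seed)
  n_beats <- sample(3:12, 1)
  pos <- sort(sample(0:(n - 1), n_beats))
  while (any(diff(pos) == 0)) pos <- sort(sample(0:(n - 1), n_beats))
  labs <- sample(beat_vocabulary(), n_beats, replace = TRUE)
  cuts <- sort(sample(1:(n - 1), sample(0:2, 1)))
  bounds <- c(0, cuts, n)
  regions <- data.frame(start = bounds[-length(bounds)], end = bounds[-1],
                        label = sample(rhythm_vocabulary(),
                                       length(bounds) - 1, replace = TRUE))
  ecg_record(round(rnorm(n), 4), fs, record_id = paste0("r", seed),
             beats = data.frame(position = pos, label = labs),
             regions = regions)
}

# 10-s rhythm window with given relative beat positions/labels
make_window <- function(positions, labels, fs = 360, window_s = 10,
                        rhythm = "N") {
  structure(list(source_record = "w", start = 0L, fs = fs,
                 signal = numeric(round(window_s * fs)), label = rhythm,
                 beats = data.frame(position = as.integer(positions),
                                    label = labels)),
            class = "rhythm_window")
}

# labelled scalogram set from noisy renderings of distinct beat templates
make_template_scalograms <- function(labels, n_per, seed, noise_sd = 0.03,
                                     fs = 360) {
  set.seed(seed)
  scal <- list(); labs <- character(); k <- 0
  for (lb in labels) {
    tm <- beat_template(lb, fs)
    for (i in seq_len(n_per)) {
      sig <- numeric(864)
      c0 <- 432 - round(0.1 * fs)
      sig[c0 + seq_along(tm)] <- tm
      sig <- sig + rnorm(864, 0, noise_sd)
      ch <- extract_chunk(sig, 432, fs, true_label = lb)
      k <- k + 1
      scal[[k]] <- cwt_scalogram(ch)
      labs <- c(labs, lb)
    }
  }
  list(scalograms = scal, labels = labs)
}

# brute-force block max used as the independent oracle for reduce_time
brute_block_max <- function(m, factor) {
  t_out <- nrow(m) %/% factor
  out <- matrix(0, t_out, ncol(m))
  for (t in seq_len(t_out)) {
    for (c in seq_len(ncol(m))) {
      out[t, c] <- max(m[((t - 1) * factor + 1):(t * factor), c])
    }
  }
  out
}

# independent per-class metric computation straight from the definitions
brute_metrics <- function(cm) {
  total <- sum(cm)
  res <- list()
  for (i in seq_len(nrow(cm))) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    tn <- total - tp - fn - fp
    sen <- tp / (tp + fn); pre <- tp / (tp + fp)
    res[[rownames(cm)[i]]] <- c(
      sen = sen, pre = pre, spec = tn / (tn + fp),
      acc = (tp + tn) / total,
      f1 = if (pre + sen > 0) 2 * pre * sen / (pre + sen) else 0
    )
  }
  res
}
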