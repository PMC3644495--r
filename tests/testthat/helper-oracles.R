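# Independent brute-force oracles and fixture builders used across tests.
# These deliberately take the slow, literal route (explicit window
# enumeration, iterative merging, full sign enumeration) so they share no
# code path with the package implementation.

# Channel bursts by explicit window enumeration: every window [t_j, t_j + w]
# holding >= m spikes marks its member spikes as co-bursting; bursts are the
# connected components of the "appeared in a common qualifying window"
# relation, found by iterative merging.
oracle_channel_bursts <- function(times, w, m) {
  n <- length(times)
  if (n < m) return(list())
  times <- sort(times)
  groups <- lapply(seq_len(n), function(i) i)  # singleton components
  comp <- seq_len(n)                           # component id per spike
  for (j in seq_len(n)) {
    members <- which(times >= times[j] & times <= times[j] + w)
    if (length(members) >= m) {
      target <- min(comp[members])
      comp[comp %in% comp[members]] <- target
    }
  }
  out <- list()
  for (id in unique(comp)) {
    idx <- which(comp == id)
    if (length(idx) >= m)
      out[[length(out) + 1L]] <- list(start = times[min(idx)],
                                      end = times[max(idx)],
                                      n_spikes = length(idx))
  }
  ord <- order(vapply(out, `[[`, numeric(1), "start"))
  out[ord]
}

# Single-linkage clustering of channel-burst onsets by exhaustive pairwise
# merging until a fixed point; clusters with >= min_channels distinct
# channels qualify.
oracle_global_clusters <- function(onsets, channels, link, min_channels) {
  k <- length(onsets)
  if (k == 0L) return(list())
  comp <- seq_len(k)
  repeat {
    merged <- FALSE
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (comp[a] != comp[b] && abs(onsets[a] - onsets[b]) <= link) {
        comp[comp == comp[b]] <- comp[a]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  out <- list()
  for (id in unique(comp)) {
    idx <- which(comp == id)
    if (length(unique(channels[idx])) >= min_channels)
      out[[length(out) + 1L]] <- sort(idx)
  }
  ord <- order(vapply(out, function(i) min(onsets[i]), numeric(1)))
  out[ord]
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Random raster: a mix of dense per-channel clumps and uniform background,
# exercising both burst and non-burst regimes of the detector.
random_raster <- function(seed, n_channels = 8L, duration = 20) {
  set.seed(seed)
  time <- numeric(); chan <- integer()
  n_clumps <- sample(0:12, 1)
  for (i in seq_len(n_clumps)) {
    t0 <- runif(1, 0, duration - 1)
    for (ch in sample(n_channels, sample(1:6, 1))) {
      k <- sample(2:8, 1)
      time <- c(time, t0 + abs(rnorm(1, 0, 0.05)) + cumsum(rexp(k, 1 / 0.02)))
      chan <- c(chan, rep(ch, k))
    }
  }
  n_bg <- sample(20:120, 1)
  time <- c(time, runif(n_bg, 0, duration))
  chan <- c(chan, sample(n_channels, n_bg, replace = TRUE))
  keep <- time <= duration
  spike_recording(
    data.frame(time = time[keep], channel = chan[keep],
               amplitude = -rep(80, sum(keep))),
    duration = duration, n_channels = n_channels)
}

# Deterministic multi-channel burst fixture: `n_ch` channels each firing
# `k` spikes at `isi` spacing, onsets staggered by `stagger`, burst
# starting at `at`.
burst_fixture_events <- function(at, n_ch = 4L, k = 5L, isi = 0.01,
                                 stagger = 0.002) {
  do.call(rbind, lapply(seq_len(n_ch), function(ch)
    data.frame(time = at + (ch - 1L) * stagger + (0:(k - 1L)) * isi,
               channel = ch, amplitude = -100)))
}

# Minimal measure_set carrying given means, for comparison-level tests.
fake_measure_set <- function(culture_id, values) {
  structure(list(
    summary = data.frame(measure = names(values),
                         mean = as.numeric(values),
                         sd = NA_real_, sem = NA_real_,
                         n = 1L, units = ""),
    raw = list(), n_total_spikes = 0L, n_burst_spikes = 0L, n_bursts = 0L,
    culture_id = culture_id, condition = "x", div = NA_integer_),
    class = "measure_set")
}

# Minimal network_profile on given offsets/rates.
fake_profile <- function(offsets, rates) {
  structure(list(profile = data.frame(offset = offsets,
                                      offset_ms = 4 * offsets,
                                      mean_rate = rates,
                                      n_inside = 1L),
                 bin_width = 0.004, window = c(0.1, 0.3),
                 t0 = numeric(), n_bursts = 1L),
            class = "network_profile")
}
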