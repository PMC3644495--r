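#' Array-wide network spike rate
#'
#' Total spike count over all channels per half-open time bin
#' `[k b, (k+1) b)`. Events falling exactly at `duration` are excluded by
#' the half-open convention; all other events are counted exactly once, so
#' the counts sum to the remaining event total.
#'
#' @param recording a [spike_recording()].
#' @param bin_width bin width in seconds (default 0.004 = 4 ms).
#' @return Data frame with `bin_start` (seconds) and `count`.
#' @export
network_spike_rate <- function(recording, bin_width = 0.004) {
  stopifnot(inherits(recording, "spike_recording"))
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  n_bins <- ceiling(recording$duration / bin_width)
  idx <- floor(recording$events$time / bin_width) + 1L
  counts <- tabulate(idx[idx <= n_bins], nbins = n_bins)
  data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_width, count = counts)
}

#' Spiking and bursting measures of one recording
#'
#' Computes the standard measure suite from a recording and its detected
#' global bursts. Per burst: `c_active` (participating channels, i.e.
#' channels contributing a channel burst), `g_spikes` (all member spikes),
#' `c_spikes` (`g_spikes / c_active`), `c_duration` (mean over participating
#' channels of last minus first member spike on that channel, ms),
#' `g_duration` (burst end minus start, ms), `isi_burst` (mean inter-spike
#' interval *within* channels: consecutive-spike gaps on each participating
#' channel during the burst, pooled; ms) and `isi_burst_pooled` (gaps of the
#' burst's member spikes interleaved across channels in one time-ordered
#' sequence; ms). Recording level: `isi_all` (mean gap between consecutive
#' events, all channels pooled; ms), `sib` (percentage of all spikes inside
#' global bursts), `ibi` (mean gap from the last spike of one burst to the
#' first spike of the next; s) and `ibi_cv` (coefficient of variation of
#' those gaps, a regularity index).
#'
#' The per-channel `isi_burst` is the headline in-burst ISI: it is the
#' definition consistent with the classical per-channel burst statistics
#' (channel duration divided by within-channel gaps), whereas the pooled
#' variant scales inversely with the number of active channels and drops
#' below a millisecond for a well-populated array burst.
#'
#' @param recording a [spike_recording()].
#' @param bursts result of [detect_bursts()] (list with `channel_bursts`
#'   and `global_bursts`) for this recording.
#' @param active_channel_rule `"burst"` (default): a channel participates
#'   in a burst when it contributes a channel burst; `"any_spike"`: any
#'   channel with a spike inside the burst window counts.
#' @return An object of class `measure_set`: list with `summary` (data
#'   frame: measure, mean, sd, sem, n, units), `raw` (named list of the
#'   per-burst / per-interval vectors behind each mean), and integer counts
#'   `n_total_spikes`, `n_burst_spikes`, `n_bursts`.
#' @examples
#' rec <- simulate_culture(simulation_params(duration = 120, seed = 1))
#' flt <- filter_artifacts(rec$recording)
#' ms <- burst_measures(flt, detect_bursts(flt))
#' ms$summary
#' @export
burst_measures <- function(recording, bursts,
                           active_channel_rule = c("burst", "any_spike")) {
  stopifnot(inherits(recording, "spike_recording"))
  active_channel_rule <- match.arg(active_channel_rule)
  ev <- recording$events
  gb <- bursts$global_bursts
  cb <- bursts$channel_bursts
  n_total <- nrow(ev)
  n_bursts <- if (is.null(gb)) 0L else nrow(gb)

  isi_all_v <- if (n_total >= 2L) diff(ev$time) else numeric()

  raw <- list(c_spikes = numeric(), g_spikes = numeric(),
              c_active = numeric(), c_duration = numeric(),
              g_duration = numeric(), isi_burst = numeric(),
              isi_burst_pooled = numeric(), isi_all = isi_all_v,
              ibi = numeric(), spikes_per_channel = numeric())
  n_burst_spikes <- 0L

  if (n_bursts > 0L) {
    per <- lapply(seq_len(n_bursts), function(i) {
      members <- gb$member_spikes[[i]]
      if (active_channel_rule == "burst") {
        chans <- gb$channels[[i]]
      } else {
        chans <- sort(unique(ev$channel[members]))
      }
      tm <- ev$time[members]
      chv <- ev$channel[members]
      per_ch <- split(tm, chv)
      ch_counts <- lengths(per_ch)
      ch_span <- vapply(per_ch, function(x) max(x) - min(x), numeric(1))
      within_gaps <- unlist(lapply(per_ch, function(x)
        if (length(x) >= 2L) diff(sort(x)) else numeric()), use.names = FALSE)
      list(c_active = length(chans),
           g_spikes = length(members),
           c_spikes = length(members) / length(chans),
           c_duration = mean(ch_span),
           g_duration = gb$end[i] - gb$start[i],
           isi_burst = within_gaps,
           isi_pooled = if (length(tm) >= 2L) diff(sort(tm)) else numeric(),
           spikes_per_channel = as.numeric(ch_counts),
           first = min(tm), last = max(tm))
    })
    raw$c_active <- vapply(per, `[[`, numeric(1), "c_active")
    raw$g_spikes <- vapply(per, `[[`, numeric(1), "g_spikes")
    raw$c_spikes <- vapply(per, `[[`, numeric(1), "c_spikes")
    raw$c_duration <- vapply(per, `[[`, numeric(1), "c_duration")
    raw$g_duration <- vapply(per, `[[`, numeric(1), "g_duration")
    raw$isi_burst <- unlist(lapply(per, `[[`, "isi_burst"), use.names = FALSE)
    raw$isi_burst_pooled <- unlist(lapply(per, `[[`, "isi_pooled"),
                                   use.names = FALSE)
    raw$spikes_per_channel <- unlist(lapply(per, `[[`, "spikes_per_channel"),
                                     use.names = FALSE)
    n_burst_spikes <- as.integer(sum(raw$g_spikes))
    if (n_bursts >= 2L) {
      lasts <- vapply(per, `[[`, numeric(1), "last")
      firsts <- vapply(per, `[[`, numeric(1), "first")
      raw$ibi <- firsts[-1L] - lasts[-n_bursts]
    }
  }

  sib <- if (n_total > 0L) 100 * n_burst_spikes / n_total else 0
  ms <- function(x) if (length(x)) mean(x) else NA_real_

  summary <- data.frame(
    measure = c("c_spikes", "g_spikes", "c_active", "c_duration",
                "g_duration", "isi_burst", "isi_burst_pooled", "isi_all",
                "sib", "ibi", "ibi_cv"),
    mean = c(ms(raw$c_spikes), ms(raw$g_spikes), ms(raw$c_active),
             1000 * ms(raw$c_duration), 1000 * ms(raw$g_duration),
             1000 * ms(raw$isi_burst), 1000 * ms(raw$isi_burst_pooled),
             1000 * ms(raw$isi_all), sib, ms(raw$ibi),
             if (length(raw$ibi) >= 2L && mean(raw$ibi) > 0)
               stats::sd(raw$ibi) / mean(raw$ibi) else NA_real_),
    sd = c(sdz(raw$c_spikes), sdz(raw$g_spikes), sdz(raw$c_active),
           1000 * sdz(raw$c_duration), 1000 * sdz(raw$g_duration),
           1000 * sdz(raw$isi_burst), 1000 * sdz(raw$isi_burst_pooled),
           1000 * sdz(raw$isi_all), NA_real_, sdz(raw$ibi), NA_real_),
    n = c(lengths(raw[c("c_spikes", "g_spikes", "c_active", "c_duration",
                        "g_duration", "isi_burst", "isi_burst_pooled",
                        "isi_all")]),
          n_total, length(raw$ibi), length(raw$ibi)),
    units = c("spikes", "spikes", "channels", "ms", "ms", "ms", "ms", "ms",
              "%", "s", "ratio"))
  summary$sem <- summary$sd / sqrt(pmax(summary$n, 1L))
  summary <- summary[c("measure", "mean", "sd", "sem", "n", "units")]

  structure(list(summary = summary, raw = raw,
                 n_total_spikes = n_total,
                 n_burst_spikes = n_burst_spikes,
                 n_bursts = n_bursts,
                 culture_id = recording$culture_id,
                 condition = recording$condition,
                 div = recording$div),
            class = "measure_set")
}

sdz <- function(x) if (length(x) >= 2L) stats::sd(x) else NA_real_

#' @export
print.measure_set <- function(x, ...) {
  cat(sprintf("<measure_set> %s [%s]: %d bursts, %d/%d spikes in bursts\n",
              x$culture_id, x$condition, x$n_bursts, x$n_burst_spikes,
              x$n_total_spikes))
  print(transform(x$summary, mean = signif(mean, 4), sd = signif(sd, 4),
                  sem = signif(sem, 4)), row.names = FALSE)
  invisible(x)
}

#' Extract a single measure mean from a measure set
#'
#' @param ms a `measure_set` from [burst_measures()].
#' @param measure measure name as in `ms$summary$measure`.
#' @return The measure's mean (scalar, possibly `NA`).
#' @export
measure_mean <- function(ms, measure) {
  i <- match(measure, ms$summary$measure)
  if (is.na(i)) stop("unknown measure: ", measure, call. = FALSE)
  ms$summary$mean[i]
}

#' Peak-aligned network spike profile
#'
#' For each global burst, the array-wide spike counts in `bin_width` bins
#' are aligned at the burst's own maximum-rate bin: `t0` is the start of
#' the bin with the highest count among bins overlapping the burst
#' (earliest such bin on ties). Profiles are then averaged across bursts
#' over a fixed window around `t0`. Bins extending beyond the recording
#' contribute zero counts and are flagged in `n_inside`.
#'
#' @param recording a [spike_recording()].
#' @param bursts result of [detect_bursts()] with at least one global
#'   burst.
#' @param bin_width bin width in seconds (default 0.004).
#' @param window numeric length-2: extent before and after `t0` in seconds
#'   (default `c(0.1, 0.3)`).
#' @return Object of class `network_profile`: list with `profile` (data
#'   frame: `offset` in bins, `offset_ms`, `mean_rate` spikes per bin,
#'   `n_inside` bursts whose bin lay inside the recording), `bin_width`,
#'   `window`, `t0` (per-burst alignment times) and `n_bursts`.
#' @export
network_spike_profile <- function(recording, bursts, bin_width = 0.004,
                                  window = c(0.1, 0.3)) {
  stopifnot(inherits(recording, "spike_recording"))
  gb <- bursts$global_bursts
  if (is.null(gb) || nrow(gb) == 0L)
    stop("network_spike_profile needs at least one global burst",
         call. = FALSE)
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  nsr <- network_spike_rate(recording, bin_width)
  counts <- nsr$count
  n_bins <- length(counts)
  pre <- ceiling(window[1] / bin_width)
  post <- ceiling(window[2] / bin_width)
  offsets <- (-pre):post
  acc <- numeric(length(offsets))
  inside <- integer(length(offsets))
  t0 <- numeric(nrow(gb))
  for (i in seq_len(nrow(gb))) {
    # bins overlapping [start, end]
    lo <- floor(gb$start[i] / bin_width) + 1L
    hi <- min(floor(gb$end[i] / bin_width) + 1L, n_bins)
    peak <- lo + which.max(counts[lo:hi]) - 1L  # earliest max
    t0[i] <- (peak - 1L) * bin_width
    idx <- peak + offsets
    ok <- idx >= 1L & idx <= n_bins
    acc[ok] <- acc[ok] + counts[idx[ok]]
    inside <- inside + as.integer(ok)
  }
  profile <- data.frame(offset = offsets,
                        offset_ms = 1000 * offsets * bin_width,
                        mean_rate = acc / nrow(gb),
                        n_inside = inside)
  structure(list(profile = profile, bin_width = bin_width,
                 window = window, t0 = t0, n_bursts = nrow(gb)),
            class = "network_profile")
}

#' @export
print.network_profile <- function(x, ...) {
  cat(sprintf(
    "<network_profile> %d bursts, %g ms bins, window -%g/+%g ms, peak %.3g spikes/bin at offset %d\n",
    x$n_bursts, 1000 * x$bin_width, 1000 * x$window[1], 1000 * x$window[2],
    max(x$profile$mean_rate), x$profile$offset[which.max(x$profile$mean_rate)]))
  invisible(x)
}

#' Histogram of a raw measure vector
#'
#' Half-open binning `[e_k, e_{k+1})` of per-burst or per-interval values;
#' values outside `[min(edges), max(edges))` are dropped, so the counts sum
#' to the number of in-range values.
#'
#' @param values numeric vector.
#' @param edges strictly increasing bin edges.
#' @return Data frame with `bin_start`, `bin_end`, `count`.
#' @examples
#' measure_histogram(c(2, 3, 12), edges = c(0, 5, 10, 15))$count  # 2 0 1
#' @export
measure_histogram <- function(values, edges) {
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("`edges` must be strictly increasing with >= 2 values",
         call. = FALSE)
  k <- length(edges) - 1L
  idx <- findInterval(values, edges, rightmost.closed = FALSE,
                      left.open = FALSE)
  idx <- idx[idx >= 1L & idx <= k & values < edges[k + 1L]]
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1L],
             count = tabulate(idx, nbins = k))
}

#' Write a measure set summary as delimited text
#'
#' @param ms a `measure_set`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_measure_table <- function(ms, path) {
  utils::write.csv(ms$summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
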