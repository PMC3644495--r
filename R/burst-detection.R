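#' Burst detection criteria
#'
#' The network burst definition used throughout: a channel burst needs at
#' least `min_spikes_per_channel` spikes falling within a window of
#' `channel_window` seconds on one electrode, and a global burst needs
#' channel bursts on at least `min_channels` distinct electrodes whose
#' onsets chain together within `overlap_window` seconds (single linkage).
#'
#' @param min_spikes_per_channel minimum spikes per channel window
#'   (default 4).
#' @param channel_window channel-level window in seconds (default 0.100).
#' @param min_channels minimum distinct participating channels (default 4).
#' @param overlap_window channel-burst onset linkage distance in seconds
#'   (default 0.250).
#' @return An object of class `burst_criteria`.
#' @examples
#' burst_criteria()  # the standard >=4 spikes / 100 ms / >=4 ch / 250 ms
#' @export
burst_criteria <- function(min_spikes_per_channel = 4L,
                           channel_window = 0.100,
                           min_channels = 4L,
                           overlap_window = 0.250) {
  min_spikes_per_channel <- as.integer(min_spikes_per_channel)
  min_channels <- as.integer(min_channels)
  if (min_spikes_per_channel < 2L)
    stop("`min_spikes_per_channel` must be >= 2", call. = FALSE)
  if (channel_window <= 0 || overlap_window <= 0 || min_channels < 1L)
    stop("burst criteria must be strictly positive", call. = FALSE)
  structure(list(min_spikes_per_channel = min_spikes_per_channel,
                 channel_window = channel_window,
                 min_channels = min_channels,
                 overlap_window = overlap_window),
            class = "burst_criteria")
}

#' @export
print.burst_criteria <- function(x, ...) {
  cat(sprintf(
    "<burst_criteria> >=%d spikes within %g ms on >=%d channels, %g ms overlap window\n",
    x$min_spikes_per_channel, 1000 * x$channel_window, x$min_channels,
    1000 * x$overlap_window))
  invisible(x)
}

#' Detect single-channel bursts
#'
#' A window of `channel_window` seconds is *tight* if it holds at least
#' `min_spikes_per_channel` spikes of one channel; two spikes belong to the
#' same channel burst when they are connected by a chain of shared tight
#' windows. Each connected component is one channel burst. This
#' construction is deterministic, needs no parameters beyond the printed
#' criteria, reduces to the obvious answer for well-separated bursts, and
#' never bridges a silent gap longer than the window.
#'
#' On the sorted spike times `t` of one channel this reduces to runs:
#' a block of `m` consecutive spikes is tight iff `t[j + m - 1] - t[j] <=
#' w`; consecutive spikes `i`, `i + 1` are linked iff some tight block
#' contains both, and channel bursts are the maximal linked runs (each
#' necessarily holding at least `m` spikes).
#'
#' @param recording an artifact-filtered [spike_recording()].
#' @param criteria a [burst_criteria()].
#' @return Data frame with one row per channel burst: `channel`, `start`,
#'   `end` (first/last member spike time, seconds), `n_spikes`, and a list
#'   column `spike_index` of row indices into `recording$events`. Ordered by
#'   channel, then start.
#' @export
detect_channel_bursts <- function(recording, criteria = burst_criteria()) {
  stopifnot(inherits(recording, "spike_recording"),
            inherits(criteria, "burst_criteria"))
  ev <- recording$events
  m <- criteria$min_spikes_per_channel
  w <- criteria$channel_window
  res <- vector("list", recording$n_channels)
  for (ch in sort(unique(ev$channel))) {
    rows <- which(ev$channel == ch)
    t <- ev$time[rows]
    n <- length(t)
    if (n < m) next
    # spans[j] = t[j+m-1] - t[j]; block j..j+m-1 is "tight" if spans[j] <= w
    tight <- (t[m:n] - t[1:(n - m + 1)]) <= w
    if (!any(tight)) next
    # spikes i, i+1 linked iff a tight block starting in [i-m+2, i] holds both
    cs <- cumsum(c(0L, as.integer(tight)))
    i <- seq_len(n - 1L)
    lo <- pmax(1L, i - m + 2L)
    hi <- pmin(i, n - m + 1L)
    link <- hi >= lo & (cs[hi + 1L] - cs[lo]) > 0L
    # maximal linked runs; runs of length >= 2 spikes are channel bursts
    r <- rle(c(link, FALSE))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)  # run of k TRUE links spans spikes starts..ends+1
    if (!length(keep)) next
    ends <- ends + 1L
    res[[ch]] <- data.frame(
      channel = ch,
      start = t[starts[keep]],
      end = t[ends[keep]],
      n_spikes = ends[keep] - starts[keep] + 1L,
      spike_index = I(lapply(keep, function(k) rows[starts[k]:ends[k]])))
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(channel = integer(), start = numeric(),
                      end = numeric(), n_spikes = integer(),
                      spike_index = I(list()))
  rownames(out) <- NULL
  out
}

#' Aggregate channel bursts into global bursts
#'
#' Channel bursts are clustered by single linkage on their onset times with
#' linkage distance `overlap_window`: sorted by onset, a new cluster starts
#' wherever the gap between consecutive onsets exceeds the window. Clusters
#' with at least `min_channels` distinct channels become global bursts. A
#' burst's `start`/`end` are the min/max of its member channel-burst
#' boundaries, and `member_spikes` collects every spike of a participating
#' channel falling within `[start, end]` (including tonic spikes that
#' happen to fall inside the window).
#'
#' @param channel_bursts output of [detect_channel_bursts()].
#' @param criteria a [burst_criteria()].
#' @param recording the same [spike_recording()] the channel bursts came
#'   from (needed to collect member spikes).
#' @return Data frame with one row per global burst, ordered by start:
#'   `burst_id`, `start`, `end`, `n_channels`, `n_spikes`, `truncated`
#'   (burst begins or ends within `channel_window` of a recording edge),
#'   and list columns `channels`, `channel_burst_index` (rows of
#'   `channel_bursts`) and `member_spikes` (rows of `recording$events`).
#' @export
detect_global_bursts <- function(channel_bursts,
                                 criteria = burst_criteria(),
                                 recording) {
  stopifnot(inherits(criteria, "burst_criteria"),
            inherits(recording, "spike_recording"))
  empty <- data.frame(burst_id = integer(), start = numeric(),
                      end = numeric(), n_channels = integer(),
                      n_spikes = integer(), truncated = logical(),
                      channels = I(list()), channel_burst_index = I(list()),
                      member_spikes = I(list()))
  if (is.null(channel_bursts) || nrow(channel_bursts) == 0L) return(empty)
  ord <- order(channel_bursts$start, channel_bursts$channel)
  onsets <- channel_bursts$start[ord]
  # single linkage on sorted onsets: chain breaks where gap > overlap_window
  new_cluster <- c(TRUE, diff(onsets) > criteria$overlap_window)
  cluster <- cumsum(new_cluster)
  ev <- recording$events
  rows <- lapply(split(ord, cluster), function(idx) {
    chans <- unique(channel_bursts$channel[idx])
    if (length(chans) < criteria$min_channels) return(NULL)
    start <- min(channel_bursts$start[idx])
    end <- max(channel_bursts$end[idx])
    members <- which(ev$channel %in% chans & ev$time >= start &
                       ev$time <= end)
    data.frame(start = start, end = end,
               n_channels = length(chans), n_spikes = length(members),
               truncated = start < criteria$channel_window |
                 end > recording$duration - criteria$channel_window,
               channels = I(list(sort(chans))),
               channel_burst_index = I(list(sort(idx))),
               member_spikes = I(list(members)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  out <- cbind(burst_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Detect channel and global bursts in one call
#'
#' Convenience wrapper running [detect_channel_bursts()] then
#' [detect_global_bursts()].
#'
#' @inheritParams detect_channel_bursts
#' @return List with elements `channel_bursts` and `global_bursts`.
#' @examples
#' rec <- simulate_culture(simulation_params(duration = 60, seed = 1))
#' b <- detect_bursts(filter_artifacts(rec$recording))
#' nrow(b$global_bursts)
#' @export
detect_bursts <- function(recording, criteria = burst_criteria()) {
  cb <- detect_channel_bursts(recording, criteria)
  gb <- detect_global_bursts(cb, criteria, recording)
  list(channel_bursts = cb, global_bursts = gb)
}

#' Global burst incidence
#'
#' @param bursts global burst table from [detect_bursts()].
#' @param duration recording duration in seconds (> 0).
#' @return Bursts per second (Hz).
#' @export
burst_incidence <- function(bursts, duration) {
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  n <- if (is.null(bursts)) 0L else nrow(bursts)
  n / duration
}

#' Write a global burst table as delimited text
#'
#' @param bursts global burst table from [detect_bursts()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_burst_table <- function(bursts, path) {
  utils::write.csv(
    data.frame(burst_id = bursts$burst_id, start_s = bursts$start,
               end_s = bursts$end, n_channels = bursts$n_channels,
               n_spikes = bursts$n_spikes, truncated = bursts$truncated),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
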