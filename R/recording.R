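#' Construct a spike recording
#'
#' A `spike_recording` bundles the detected spike events of one MEA recording
#' with its culture metadata. It is the universal input of the pipeline: burst
#' detection, measures and comparisons all consume this object and nothing
#' else.
#'
#' @param events data frame with numeric columns `time` (seconds from
#'   recording start), `channel` (integer electrode index, 1-based) and
#'   `amplitude` (signed microvolts; negative-going spikes are negative).
#'   Rows need not be sorted; they are sorted by time, ties broken by channel.
#' @param duration recording length in seconds; every event time must be
#'   `<= duration`.
#' @param n_channels number of electrodes on the array (default 59, the
#'   standard 8 x 8 layout with corner positions absent).
#' @param culture_id opaque culture label used to pair drug and control
#'   recordings from the same culture.
#' @param div culture age in days in vitro (integer, `NA` if unknown).
#' @param condition condition label, e.g. `"control"`, `"atropine"`.
#'
#' @return An object of class `spike_recording`: a list with elements
#'   `events` (sorted data frame), `duration`, `n_channels`, `culture_id`,
#'   `div`, `condition`.
#' @examples
#' ev <- data.frame(time = c(0.5, 0.1), channel = c(2L, 1L),
#'                  amplitude = c(-80, -120))
#' rec <- spike_recording(ev, duration = 1, n_channels = 4)
#' rec$events$time  # sorted
#' @export
spike_recording <- function(events, duration, n_channels = 59L,
                            culture_id = "culture", div = NA_integer_,
                            condition = "control") {
  if (!is.data.frame(events))
    stop("`events` must be a data frame", call. = FALSE)
  needed <- c("time", "channel", "amplitude")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols))
    stop("events table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  events <- events[needed]
  events$channel <- as.integer(events$channel)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be a single positive number", call. = FALSE)
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L)
    stop("`n_channels` must be >= 1", call. = FALSE)
  if (nrow(events)) {
    bad <- which(events$time < 0 | !is.finite(events$time))
    if (length(bad))
      stop("negative or non-finite event time at row ", bad[1L], call. = FALSE)
    bad <- which(events$time > duration)
    if (length(bad))
      stop("event time exceeds duration at row ", bad[1L], call. = FALSE)
    bad <- which(events$channel < 1L | events$channel > n_channels |
                   is.na(events$channel))
    if (length(bad))
      stop("channel outside 1..", n_channels, " at row ", bad[1L],
           call. = FALSE)
    events <- events[order(events$time, events$channel), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(
    list(events = events, duration = as.numeric(duration),
         n_channels = n_channels, culture_id = as.character(culture_id),
         div = as.integer(div), condition = as.character(condition)),
    class = "spike_recording")
}

#' @export
print.spike_recording <- function(x, ...) {
  cat(sprintf(
    "<spike_recording> %s [%s], DIV %s\n  %d events on %d channels over %.6g s (%.3g Hz array-wide)\n",
    x$culture_id, x$condition,
    ifelse(is.na(x$div), "?", x$div), nrow(x$events), x$n_channels,
    x$duration, nrow(x$events) / x$duration))
  invisible(x)
}

#' Read a spike table from disk
#'
#' Reads a comma-delimited spike table with header
#' `time_s,channel,amplitude_uv` (one row per detected spike) and returns a
#' [spike_recording()]. Recording metadata comes either from the `metadata`
#' list or from a YAML sidecar file (same path with extension `.yaml`)
#' written by [write_spike_table()].
#'
#' @param path path to the CSV spike table.
#' @param metadata named list with `duration_s`, and optionally `n_channels`,
#'   `culture_id`, `div`, `condition`. If `NULL`, the sidecar
#'   `<path minus .csv>.yaml` is read and must exist.
#' @return A [spike_recording()].
#' @seealso [write_spike_table()]
#' @export
read_spike_table <- function(path, metadata = NULL) {
  if (!file.exists(path))
    stop("spike table not found: ", path, call. = FALSE)
  if (is.null(metadata)) {
    side <- sidecar_path(path)
    if (!file.exists(side))
      stop("no metadata given and no sidecar file at ", side, call. = FALSE)
    metadata <- yaml::read_yaml(side)
  }
  if (is.null(metadata$duration_s))
    stop("metadata is missing `duration_s`", call. = FALSE)
  tab <- utils::read.csv(path, colClasses = "numeric")
  needed <- c("time_s", "channel", "amplitude_uv")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("spike table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  spike_recording(
    data.frame(time = tab$time_s, channel = as.integer(tab$channel),
               amplitude = tab$amplitude_uv),
    duration = metadata$duration_s,
    n_channels = metadata$n_channels %||% 59L,
    culture_id = metadata$culture_id %||% "culture",
    div = metadata$div %||% NA_integer_,
    condition = metadata$condition %||% "control")
}

#' Write a spike table (and metadata sidecar) to disk
#'
#' Writes the events of a recording as a comma-delimited table with header
#' `time_s,channel,amplitude_uv`, and the recording metadata as a YAML
#' sidecar next to it. Numeric values are written with full precision
#' (17 significant digits), so a read/write round trip reproduces times,
#' channels and amplitudes exactly.
#'
#' @param recording a [spike_recording()].
#' @param path destination CSV path; the sidecar goes to the same path with
#'   a `.yaml` extension.
#' @param sidecar write the metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(recording, path, sidecar = TRUE) {
  stopifnot(inherits(recording, "spike_recording"))
  ev <- recording$events
  out <- data.frame(
    time_s = format_full(ev$time),
    channel = ev$channel,
    amplitude_uv = format_full(ev$amplitude))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(duration_s = recording$duration,
                 n_channels = recording$n_channels,
                 culture_id = recording$culture_id,
                 div = if (is.na(recording$div)) NULL else recording$div,
                 condition = recording$condition)
    yaml::write_yaml(meta[!vapply(meta, is.null, logical(1))],
                     sidecar_path(path))
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".yaml")

# full round-trip precision for doubles; integers print plainly
format_full <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  trimws(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove rectification artifacts
#'
#' Positive-going spikes of at most 50 microvolts are taken to be the
#' rectification phase of a preceding negative-going spike rather than
#' genuine events, and are dropped. All other events (negative-going spikes
#' of any size, and positive-going spikes above the threshold) are kept
#' unchanged, as is all metadata. The filter is idempotent.
#'
#' @param recording a [spike_recording()].
#' @param max_positive_uv artifact threshold in microvolts (default 50);
#'   an event is removed iff `amplitude > 0` and
#'   `amplitude <= max_positive_uv`.
#' @return The filtered [spike_recording()].
#' @examples
#' ev <- data.frame(time = c(0.1, 0.2, 0.3), channel = 1L,
#'                  amplitude = c(40, -30, 60))
#' nrow(filter_artifacts(spike_recording(ev, 1, 4))$events)  # 2
#' @export
filter_artifacts <- function(recording, max_positive_uv = 50) {
  stopifnot(inherits(recording, "spike_recording"))
  a <- recording$events$amplitude
  keep <- !(a > 0 & a <= max_positive_uv)
  recording$events <- recording$events[keep, , drop = FALSE]
  rownames(recording$events) <- NULL
  recording
}

#' Classify culture maturity from age
#'
#' Cultures aged 14-25 days in vitro are `"immature"`, 37-61 `"mature"`;
#' ages in neither range are `"unclassified"` (such cultures were simply not
#' used in the underlying experimental design, so this is not an error).
#'
#' @param div integer days in vitro (vectorised); must be `>= 0`.
#' @return Character vector over `{"immature", "mature", "unclassified"}`.
#' @examples
#' classify_culture(c(20, 40, 30))
#' @export
classify_culture <- function(div) {
  div <- as.integer(div)
  if (any(is.na(div)) || any(div < 0L))
    stop("`div` must be a non-negative integer", call. = FALSE)
  ifelse(div >= 14L & div <= 25L, "immature",
         ifelse(div >= 37L & div <= 61L, "mature", "unclassified"))
}

#' Recording inclusion gate on early burst incidence
#'
#' A recording is retained for analysis only if its mean global burst
#' incidence over the opening window strictly exceeds `threshold_hz`.
#' Incidence counts bursts whose onset falls in `[0, window)`.
#'
#' @param recording a [spike_recording()] with `duration >= window`.
#' @param bursts global burst table from [detect_bursts()] for this
#'   recording.
#' @param window gate window in seconds (default 300, i.e. the first
#'   5 minutes).
#' @param threshold_hz strict incidence threshold in Hz (default 0.25).
#' @return `TRUE` if the recording passes the gate, with attribute
#'   `incidence_hz` carrying the measured incidence.
#' @export
check_inclusion <- function(recording, bursts, window = 300,
                            threshold_hz = 0.25) {
  stopifnot(inherits(recording, "spike_recording"))
  if (recording$duration < window)
    stop("recording shorter than the gate window (", window, " s)",
         call. = FALSE)
  n <- if (is.null(bursts) || nrow(bursts) == 0L) 0L
       else sum(bursts$start >= 0 & bursts$start < window)
  incidence <- n / window
  structure(incidence > threshold_hz, incidence_hz = incidence)
}

#' Array-wide firing rate per time bin
#'
#' The stability check on a recording session: total spike count over all
#' channels in half-open bins `[k b, (k+1) b)` divided by the bin width. A
#' trailing partial bin is discarded.
#'
#' @param recording a [spike_recording()] with `duration >= bin`.
#' @param bin bin width in seconds (default 300 = 5 minutes).
#' @return Data frame with `bin_start` (seconds) and `rate_hz`.
#' @export
array_rate_stability <- function(recording, bin = 300) {
  stopifnot(inherits(recording, "spike_recording"))
  if (bin <= 0) stop("`bin` must be positive", call. = FALSE)
  if (recording$duration < bin)
    stop("recording shorter than one bin", call. = FALSE)
  n_bins <- floor(recording$duration / bin)
  edges <- (0:n_bins) * bin
  idx <- findInterval(recording$events$time, edges,
                      rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(idx[idx >= 1 & idx <= n_bins], nbins = n_bins)
  data.frame(bin_start = edges[seq_len(n_bins)], rate_hz = counts / bin)
}
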