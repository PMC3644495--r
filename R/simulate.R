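#' Simulation parameters for a synthetic cultured network
#'
#' Hierarchical generative model of spontaneous MEA culture activity:
#' global burst onsets follow a gamma renewal process; at each burst every
#' channel joins independently with probability `p_participate`; a joining
#' channel fires a jittered-onset train whose spike count is a
#' criteria-floored shifted geometric (negative binomial) draw and whose
#' in-burst inter-spike intervals are exponential; an independent Poisson
#' tonic background runs on every channel; amplitudes come from a
#' negative-going mixture (large compound first spike, smaller followers
#' and tonic spikes) plus a small fraction of small positive rectification
#' artifacts so the artifact filter is exercised end to end.
#'
#' The default parameter set (`preset = "mature_control"` via
#' [simulation_presets()]) is calibrated to the published mature-culture
#' statistics: mean inter-burst interval 5.1 s, in-burst ISI 4 ms, global
#' burst duration ~100 ms, ~12 of 59 channels active per burst
#' (`p_participate = 12/59`), and ~58% of spikes inside bursts.
#'
#' @param n_channels electrodes on the array (default 59).
#' @param duration recording length, seconds (default 600).
#' @param ibi_mean mean of the gamma inter-burst (onset-to-onset) interval,
#'   seconds (default 5.1).
#' @param ibi_shape gamma shape; larger = more regular bursting
#'   (default 3).
#' @param p_participate probability a channel joins a given burst
#'   (default 12/59).
#' @param spikes_per_channel_mean mean in-burst spikes of a joining channel
#'   (default 11); counts are `count_min + NegBin(count_size, mu = mean -
#'   count_min)`.
#' @param count_min smallest in-burst spike count of a joining channel
#'   (default 4, the per-channel burst criterion: channels engaging below
#'   it are represented by the tonic background instead).
#' @param count_size negative-binomial size (dispersion) of the count
#'   (default 4; larger = tighter counts).
#' @param in_burst_isi_mean mean exponential in-burst ISI, seconds
#'   (default 0.004).
#' @param onset_jitter_sd SD of the per-channel burst onset jitter, seconds
#'   (default 0.008, calibrated so the programmed global span matches the
#'   ~100 ms mature target).
#' @param tonic_rate Poisson background rate per channel, Hz
#'   (default 0.31, calibrated for ~58% spikes in bursts).
#' @param amplitude_model list: `first_mean`, `first_sd` (compound first
#'   spike of each channel train), `burst_mean`, `burst_sd` (followers),
#'   `tonic_mean`, `tonic_sd` (all negative-going microvolts, given as
#'   magnitudes), `artifact_fraction` (share of extra small positive
#'   events, default 0.02), `artifact_max` (their cap, default 50).
#' @param seed integer RNG seed; the same params and seed give a
#'   byte-identical recording.
#' @return Object of class `simulation_params` (a validated list).
#' @seealso [simulation_presets()], [simulate_culture()],
#'   [apply_drug_transform()]
#' @export
simulation_params <- function(n_channels = 59L, duration = 600,
                              ibi_mean = 5.1, ibi_shape = 3,
                              p_participate = 12 / 59,
                              spikes_per_channel_mean = 11,
                              count_min = 4L, count_size = 4,
                              in_burst_isi_mean = 0.004,
                              onset_jitter_sd = 0.008,
                              tonic_rate = 0.31,
                              amplitude_model = list(),
                              seed = 1L) {
  am <- utils::modifyList(
    list(first_mean = 200, first_sd = 40, burst_mean = 90, burst_sd = 25,
         tonic_mean = 70, tonic_sd = 20, artifact_fraction = 0.02,
         artifact_max = 50),
    amplitude_model)
  p <- list(n_channels = as.integer(n_channels), duration = duration,
            ibi_mean = ibi_mean, ibi_shape = ibi_shape,
            p_participate = p_participate,
            spikes_per_channel_mean = spikes_per_channel_mean,
            count_min = as.integer(count_min), count_size = count_size,
            in_burst_isi_mean = in_burst_isi_mean,
            onset_jitter_sd = onset_jitter_sd, tonic_rate = tonic_rate,
            amplitude_model = am, seed = as.integer(seed))
  validate_simulation_params(p)
  structure(p, class = "simulation_params")
}

validate_simulation_params <- function(p) {
  if (p$n_channels < 1L) stop("n_channels must be >= 1", call. = FALSE)
  if (p$duration <= 0) stop("duration must be positive", call. = FALSE)
  if (p$ibi_mean <= 0 || p$ibi_shape <= 0)
    stop("ibi_mean and ibi_shape must be positive", call. = FALSE)
  if (p$p_participate < 0 || p$p_participate > 1)
    stop("p_participate must be in [0, 1]", call. = FALSE)
  if (p$spikes_per_channel_mean < p$count_min)
    stop("spikes_per_channel_mean must be >= count_min", call. = FALSE)
  if (p$in_burst_isi_mean <= 0)
    stop("in_burst_isi_mean must be positive", call. = FALSE)
  if (p$onset_jitter_sd < 0 || p$tonic_rate < 0)
    stop("onset_jitter_sd and tonic_rate must be >= 0", call. = FALSE)
  am <- p$amplitude_model
  if (am$artifact_fraction < 0 || am$artifact_fraction > 1)
    stop("artifact_fraction must be in [0, 1]", call. = FALSE)
  invisible(p)
}

#' Calibrated parameter presets
#'
#' `"mature_control"` and `"immature_control"` carry the published
#' mature/immature culture statistics (see [simulation_params()]);
#' immature cultures burst on more channels (19/59), with more spikes per
#' channel (13), longer bursts (~140 ms programmed span), slower in-burst
#' firing (4.6 ms ISI), longer inter-burst intervals (7.3 s) and ~56% of
#' spikes in bursts.
#'
#' @param preset preset name.
#' @param ... overrides passed on to [simulation_params()].
#' @return A `simulation_params` object.
#' @examples
#' simulation_presets("immature_control", duration = 300)
#' @export
simulation_presets <- function(preset = c("mature_control",
                                          "immature_control"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    mature_control = list(ibi_mean = 5.1, p_participate = 12 / 59,
                          spikes_per_channel_mean = 11,
                          in_burst_isi_mean = 0.004,
                          onset_jitter_sd = 0.008, tonic_rate = 0.31),
    immature_control = list(ibi_mean = 7.3, p_participate = 19 / 59,
                            spikes_per_channel_mean = 13,
                            in_burst_isi_mean = 0.0046,
                            onset_jitter_sd = 0.012, tonic_rate = 0.44))
  do.call(simulation_params, utils::modifyList(base, list(...)))
}

#' Drug-state parameter transforms
#'
#' Multiplicative transforms of a base parameter set reproducing the
#' direction of the published drug effects on network activity:
#' \describe{
#'   \item{none}{identity.}
#'   \item{atropine_like}{muscarinic blockade: longer and much more regular
#'     inter-burst intervals (`ibi_mean` x1.8, `ibi_shape` x4), suppressed
#'     tonic firing (x0.2), more participating channels
#'     (`p_participate` x1.4, capped at 1) and more spikes per channel
#'     (x1.3) — converting irregular mixed firing into synchronised burst
#'     firing with a higher proportion of spikes in bursts.}
#'   \item{oxom_mature_like}{muscarinic activation, mature phenotype:
#'     strong tonic firing (x6), fewer participating channels (x0.75),
#'     longer intervals between burst-like events (`ibi_mean` x1.5) and a
#'     lower proportion of spikes in bursts.}
#'   \item{oxom_immature_like}{muscarinic activation, immature phenotype:
#'     same directions but attenuated (tonic x2, `p_participate` x0.9,
#'     `ibi_mean` x1.2).}
#'   \item{mec_like}{nicotinic blockade: markedly shorter global bursts
#'     via tighter synchrony — onset jitter x0.2 and train-count
#'     dispersion tightened (`count_size` x4, i.e. less straggling of the
#'     longest trains) — with slightly less firing outside bursts
#'     (`tonic_rate` x0.8), raising the in-burst share of spikes; mean
#'     counts, in-burst intervals and burst timing are untouched.}
#' }
#'
#' @param params a [simulation_params()] object.
#' @param transform transform name.
#' @return A transformed, validated `simulation_params` object.
#' @examples
#' p <- simulation_presets("mature_control")
#' apply_drug_transform(p, "atropine_like")$ibi_mean  # 5.1 * 1.8
#' @export
apply_drug_transform <- function(params,
                                 transform = c("none", "atropine_like",
                                               "oxom_mature_like",
                                               "oxom_immature_like",
                                               "mec_like")) {
  stopifnot(inherits(params, "simulation_params"))
  transform <- match.arg(transform)
  p <- unclass(params)
  mult <- switch(transform,
    none = list(),
    atropine_like = list(ibi_mean = 1.8, ibi_shape = 4, tonic_rate = 0.2,
                         p_participate = 1.4, spikes_per_channel_mean = 1.3),
    oxom_mature_like = list(tonic_rate = 6, p_participate = 0.75,
                            ibi_mean = 1.5),
    oxom_immature_like = list(tonic_rate = 2, p_participate = 0.9,
                              ibi_mean = 1.2),
    mec_like = list(onset_jitter_sd = 0.2, count_size = 4,
                    tonic_rate = 0.8))
  for (nm in names(mult)) p[[nm]] <- p[[nm]] * mult[[nm]]
  p$p_participate <- min(1, p$p_participate)
  validate_simulation_params(p)
  structure(p, class = "simulation_params")
}

#' Simulate one culture recording
#'
#' Draws a synthetic [spike_recording()] from the generative model in
#' [simulation_params()], together with the ground-truth burst
#' annotations (one row per programmed burst that produced at least one
#' spike train: onset, first/last programmed spike, participating
#' channels). Identical params and seed give identical output.
#'
#' @param params a [simulation_params()] object.
#' @param culture_id,condition metadata labels for the recording.
#' @param div days in vitro recorded in the metadata (defaults to a
#'   representative age: 45 if `p_participate <= 0.25` — the mature
#'   calibration — else 20).
#' @return List with `recording` (a [spike_recording()]) and
#'   `ground_truth` (data frame: `burst_id`, `onset`, `start`, `end`,
#'   `n_channels`, `n_spikes`, plus list column `channels`).
#' @examples
#' sim <- simulate_culture(simulation_params(duration = 60, seed = 7))
#' sim$recording
#' nrow(sim$ground_truth)
#' @export
simulate_culture <- function(params, culture_id = "sim",
                             condition = "control", div = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  validate_simulation_params(params)
  if (is.null(div)) div <- if (params$p_participate <= 0.25) 45L else 20L
  rng <- local_rng(params$seed)
  on.exit(rng(), add = TRUE)

  am <- params$amplitude_model
  # global burst onsets: gamma renewal
  onsets <- numeric()
  t <- stats::rgamma(1, shape = params$ibi_shape,
                     scale = params$ibi_mean / params$ibi_shape)
  while (t < params$duration) {
    onsets <- c(onsets, t)
    t <- t + stats::rgamma(1, shape = params$ibi_shape,
                           scale = params$ibi_mean / params$ibi_shape)
  }

  ev_time <- list(); ev_chan <- list(); ev_amp <- list()
  gt <- vector("list", length(onsets))
  for (b in seq_along(onsets)) {
    joined <- which(stats::runif(params$n_channels) < params$p_participate)
    if (!length(joined)) next
    bt <- list(); bc <- list(); ba <- list()
    for (k in seq_along(joined)) {
      ch <- joined[k]
      start <- onsets[b] + stats::rnorm(1, 0, params$onset_jitter_sd)
      n_sp <- params$count_min +
        stats::rnbinom(1, size = params$count_size,
                       mu = params$spikes_per_channel_mean - params$count_min)
      times <- start + c(0, cumsum(stats::rexp(n_sp - 1L,
                                               rate = 1 / params$in_burst_isi_mean)))
      amp <- -abs(c(stats::rnorm(1, am$first_mean, am$first_sd),
                    stats::rnorm(n_sp - 1L, am$burst_mean, am$burst_sd)))
      bt[[k]] <- times; bc[[k]] <- rep(ch, n_sp); ba[[k]] <- amp
    }
    tb <- unlist(bt); cb <- unlist(bc); ab <- unlist(ba)
    keep <- tb >= 0 & tb <= params$duration
    ev_time[[length(ev_time) + 1L]] <- tb[keep]
    ev_chan[[length(ev_chan) + 1L]] <- cb[keep]
    ev_amp[[length(ev_amp) + 1L]] <- ab[keep]
    if (any(keep))
      gt[[b]] <- data.frame(onset = onsets[b], start = min(tb[keep]),
                            end = max(tb[keep]),
                            n_channels = length(unique(cb[keep])),
                            n_spikes = sum(keep),
                            channels = I(list(sort(unique(cb[keep])))))
  }

  # tonic Poisson background per channel
  if (params$tonic_rate > 0) {
    n_tonic <- stats::rpois(params$n_channels,
                            params$tonic_rate * params$duration)
    for (ch in seq_len(params$n_channels)) {
      if (n_tonic[ch] == 0L) next
      ev_time[[length(ev_time) + 1L]] <-
        stats::runif(n_tonic[ch], 0, params$duration)
      ev_chan[[length(ev_chan) + 1L]] <- rep(ch, n_tonic[ch])
      ev_amp[[length(ev_amp) + 1L]] <-
        -abs(stats::rnorm(n_tonic[ch], am$tonic_mean, am$tonic_sd))
    }
  }

  time <- unlist(ev_time) %||% numeric()
  chan <- unlist(ev_chan) %||% integer()
  amp <- unlist(ev_amp) %||% numeric()

  # small positive rectification artifacts
  if (am$artifact_fraction > 0 && length(time)) {
    n_art <- stats::rpois(1, am$artifact_fraction * length(time))
    if (n_art > 0L) {
      time <- c(time, stats::runif(n_art, 0, params$duration))
      chan <- c(chan, sample.int(params$n_channels, n_art, replace = TRUE))
      amp <- c(amp, stats::runif(n_art, 1, am$artifact_max))
    }
  }

  rec <- spike_recording(
    data.frame(time = time, channel = chan, amplitude = amp),
    duration = params$duration, n_channels = params$n_channels,
    culture_id = culture_id, div = div, condition = condition)
  gt <- gt[!vapply(gt, is.null, logical(1))]
  ground_truth <- if (length(gt)) {
    g <- do.call(rbind, gt)
    g <- g[order(g$start), , drop = FALSE]
    cbind(burst_id = seq_len(nrow(g)), g)
  } else {
    data.frame(burst_id = integer(), onset = numeric(), start = numeric(),
               end = numeric(), n_channels = integer(), n_spikes = integer(),
               channels = I(list()))
  }
  rownames(ground_truth) <- NULL
  list(recording = rec, ground_truth = ground_truth)
}

# run code under a private RNG stream; returns a restorer function
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a paired control/drug experiment
#'
#' Generates `n_cultures` paired recordings: per culture, lognormal
#' culture-level multipliers (SD `culture_sd` on the log scale, applied to
#' `ibi_mean`, `spikes_per_channel_mean`, `tonic_rate` and
#' `in_burst_isi_mean`) emulate inherent culture-to-culture variability;
#' the *same* perturbed baseline then yields one control recording and one
#' drug recording under [apply_drug_transform()], so the pair shares its
#' culture effect and differs only by the transform and sampling noise.
#'
#' @param base a [simulation_params()] object (the population baseline).
#' @param transform drug transform name (see [apply_drug_transform()]).
#' @param n_cultures number of paired cultures (default 6, the replicate
#'   count of the underlying protocol).
#' @param seed experiment seed; per-culture seeds are derived from it.
#' @param culture_sd lognormal sigma of the culture effect (default 0.1).
#' @return List with `control` and `drug` (lists of
#'   [simulate_culture()] results, paired by index and `culture_id`) and
#'   `cultures` (ids).
#' @examples
#' exp <- make_paired_experiment(simulation_params(duration = 60),
#'                               "none", n_cultures = 2, seed = 3)
#' exp$cultures
#' @export
make_paired_experiment <- function(base, transform = "none",
                                   n_cultures = 6L, seed = 1L,
                                   culture_sd = 0.1) {
  stopifnot(inherits(base, "simulation_params"), n_cultures >= 1L)
  rng <- local_rng(seed)
  eff <- matrix(stats::rlnorm(n_cultures * 4L, 0, culture_sd),
                nrow = n_cultures)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 2L * n_cultures), nrow = n_cultures)
  rng()
  ids <- sprintf("culture%02d", seq_len(n_cultures))
  control <- vector("list", n_cultures)
  drug <- vector("list", n_cultures)
  for (i in seq_len(n_cultures)) {
    p <- unclass(base)
    p$ibi_mean <- p$ibi_mean * eff[i, 1]
    p$spikes_per_channel_mean <-
      max(p$count_min, p$spikes_per_channel_mean * eff[i, 2])
    p$tonic_rate <- p$tonic_rate * eff[i, 3]
    p$in_burst_isi_mean <- p$in_burst_isi_mean * eff[i, 4]
    pc <- structure(utils::modifyList(p, list(seed = sub_seeds[i, 1])),
                    class = "simulation_params")
    pd <- apply_drug_transform(pc, transform)
    pd$seed <- sub_seeds[i, 2]
    control[[i]] <- simulate_culture(pc, culture_id = ids[i],
                                     condition = "control")
    drug[[i]] <- simulate_culture(pd, culture_id = ids[i],
                                  condition = transform)
  }
  list(control = control, drug = drug, cultures = ids)
}

#' Write ground-truth burst annotations as delimited text
#'
#' @param ground_truth the `ground_truth` table of [simulate_culture()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  utils::write.csv(
    data.frame(burst_id = ground_truth$burst_id,
               onset_s = ground_truth$onset,
               start_s = ground_truth$start, end_s = ground_truth$end,
               n_channels = ground_truth$n_channels,
               n_spikes = ground_truth$n_spikes),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Match detected bursts to ground truth
#'
#' Greedy one-to-one matching by time overlap: a detected burst matches a
#' ground-truth burst if their intervals (padded by `tol` seconds)
#' intersect; each truth burst is consumed by at most one detection.
#'
#' @param detected global burst table from [detect_bursts()].
#' @param truth ground-truth table from [simulate_culture()].
#' @param tol interval padding in seconds (default 0.05).
#' @return List with `n_matched`, `precision`, `recall`, and the matched
#'   index pairs (`detected_id`, `truth_id`).
#' @export
match_bursts <- function(detected, truth, tol = 0.05) {
  nd <- nrow(detected); nt <- nrow(truth)
  used <- logical(nt)
  pairs <- list()
  for (i in seq_len(nd)) {
    hit <- which(!used & truth$start - tol <= detected$end[i] &
                   truth$end + tol >= detected$start[i])
    if (length(hit)) {
      used[hit[1L]] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(i, hit[1L])
    }
  }
  n <- length(pairs)
  m <- if (n) do.call(rbind, pairs) else matrix(integer(), ncol = 2)
  list(n_matched = n,
       precision = if (nd) n / nd else NA_real_,
       recall = if (nt) n / nt else NA_real_,
       detected_id = m[, 1], truth_id = m[, 2])
}
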