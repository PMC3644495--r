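test_that("network spike rate bins counts and conserves totals", {
  # 10 spikes in [0, 4) ms -> first bin holds all of them
  rec <- spike_recording(data.frame(time = seq(0, 0.0039, length.out = 10),
                                    channel = 1L, amplitude = -80), 1, 4)
  nsr <- network_spike_rate(rec)
  expect_equal(nsr$count[1], 10L)
  expect_equal(sum(nsr$count), 10L)
  expect_equal(nsr$bin_start[2] - nsr$bin_start[1], 0.004)

  empty <- spike_recording(data.frame(time = numeric(), channel = integer(),
                                      amplitude = numeric()), 1, 4)
  expect_true(all(network_spike_rate(empty)$count == 0L))

  # an event exactly at duration is excluded by the half-open convention
  rec_end <- spike_recording(data.frame(time = c(0.5, 1), channel = 1L,
                                        amplitude = -80), 1, 4)
  expect_equal(sum(network_spike_rate(rec_end)$count), 1L)
  expect_error(network_spike_rate(rec, bin_width = 0), "positive")
})

test_that("burst measures match a hand-worked two-burst recording", {
  # burst 1: 4 channels x 5 spikes, 10 ms ISI, 2 ms stagger, at 0.1 s
  # burst 2: same shape at 5.0 s; one tonic spike far from both
  ev <- rbind(burst_fixture_events(0.1), burst_fixture_events(5.0),
              data.frame(time = 2.5, channel = 7L, amplitude = -60))
  rec <- spike_recording(ev, 10, 8)
  b <- detect_bursts(rec)
  ms <- burst_measures(rec, b)

  expect_equal(ms$n_bursts, 2L)
  expect_equal(measure_mean(ms, "c_active"), 4)
  expect_equal(measure_mean(ms, "g_spikes"), 20)
  expect_equal(measure_mean(ms, "c_spikes"), 5)
  # per-channel duration: 4 x 10 ms = 40 ms on every channel
  expect_equal(measure_mean(ms, "c_duration"), 40)
  # global span: first spike at offset 0, last at 3 * 2 + 40 = 46 ms
  expect_equal(measure_mean(ms, "g_duration"), 46)
  # within-channel gaps are all 10 ms
  expect_equal(measure_mean(ms, "isi_burst"), 10)
  # interleaved gaps: 2 ms within each 4-channel volley (15 of them),
  # 4 ms between volleys (4 of them) -> mean 46/19 ms
  expect_equal(measure_mean(ms, "isi_burst_pooled"), 46 / 19)
  # ibi: last spike of burst 1 at 0.146, first of burst 2 at 5.0
  expect_equal(measure_mean(ms, "ibi"), 5.0 - 0.146)
  # 40 of 41 events are in bursts
  expect_equal(measure_mean(ms, "sib"), 100 * 40 / 41)
  expect_equal(ms$n_burst_spikes, 40L)
})

test_that("ibi follows the last-spike-to-first-spike definition", {
  ev <- rbind(burst_fixture_events(0.0, stagger = 0, isi = 0.025),
              burst_fixture_events(5.0, stagger = 0, isi = 0.025))
  rec <- spike_recording(ev, 10, 8)
  ms <- burst_measures(rec, detect_bursts(rec))
  expect_equal(measure_mean(ms, "ibi"), 5.0 - 0.1)  # 4.9 s
})

test_that("burst-free and single-burst recordings degrade gracefully", {
  tonic <- spike_recording(data.frame(time = seq(0.1, 9, by = 0.5),
                                      channel = 1L, amplitude = -80), 10, 8)
  ms <- burst_measures(tonic, detect_bursts(tonic))
  expect_equal(ms$n_bursts, 0L)
  expect_equal(measure_mean(ms, "sib"), 0)
  expect_true(is.na(measure_mean(ms, "g_duration")))
  expect_false(is.na(measure_mean(ms, "isi_all")))
  expect_equal(measure_mean(ms, "isi_all"), 500)

  one <- spike_recording(burst_fixture_events(0.5), 2, 8)
  ms1 <- burst_measures(one, detect_bursts(one))
  expect_equal(ms1$n_bursts, 1L)
  expect_true(is.na(measure_mean(ms1, "ibi")))  # < 2 bursts
})

test_that("spikes-in-bursts conservation holds on simulated recordings", {
  for (s in 1:5) {
    sim <- simulate_culture(simulation_presets("mature_control",
                                               duration = 120, seed = s))
    rec <- filter_artifacts(sim$recording)
    ms <- burst_measures(rec, detect_bursts(rec))
    expect_identical(ms$n_burst_spikes, as.integer(sum(ms$raw$g_spikes)))
    expect_equal(measure_mean(ms, "sib") / 100 * ms$n_total_spikes,
                 ms$n_burst_spikes)
    # c_duration <= g_duration per burst; c_spikes <= g_spikes
    expect_true(all(ms$raw$c_duration <= ms$raw$g_duration + 1e-12))
    expect_true(all(ms$raw$c_spikes <= ms$raw$g_spikes))
    # bursts denser than background
    expect_lt(measure_mean(ms, "isi_burst"), measure_mean(ms, "isi_all"))
  }
})

test_that("removing non-burst spikes drives sib to 100% and fixes bursts", {
  sim <- simulate_culture(simulation_presets("mature_control",
                                             duration = 120, seed = 9))
  rec <- filter_artifacts(sim$recording)
  b <- detect_bursts(rec)
  ms <- burst_measures(rec, b)
  keep <- sort(unlist(b$global_bursts$member_spikes))
  rec2 <- spike_recording(rec$events[keep, ], rec$duration,
                          rec$n_channels, rec$culture_id, rec$div,
                          rec$condition)
  ms2 <- burst_measures(rec2, detect_bursts(rec2))
  expect_equal(measure_mean(ms2, "sib"), 100)
  expect_equal(ms2$n_bursts, ms$n_bursts)
  expect_equal(measure_mean(ms2, "g_spikes"), measure_mean(ms, "g_spikes"))
  expect_equal(measure_mean(ms2, "c_active"), measure_mean(ms, "c_active"))
  expect_equal(measure_mean(ms2, "g_duration"),
               measure_mean(ms, "g_duration"))
})

test_that("profile aligns at each burst's maximum-rate bin", {
  # symmetric triangular burst: profile max must sit at offset 0
  mk_burst <- function(at) {
    counts <- c(2, 5, 9, 5, 2)  # spikes per 4 ms bin, peak in the middle
    do.call(rbind, lapply(seq_along(counts), function(k) {
      n <- counts[k]
      data.frame(time = at + (k - 1) * 0.004 +
                   seq(0.0005, 0.0035, length.out = n),
                 channel = rep_len(1:4, n), amplitude = -100)
    }))
  }
  ev <- rbind(mk_burst(1.0), mk_burst(5.0), mk_burst(9.0))
  rec <- spike_recording(ev, 12, 8)
  b <- detect_bursts(rec)
  expect_equal(nrow(b$global_bursts), 3L)
  prof <- network_spike_profile(rec, b)
  expect_equal(prof$profile$offset[which.max(prof$profile$mean_rate)], 0L)
  expect_equal(max(prof$profile$mean_rate), 9)
  # symmetry of the mean profile around the peak
  expect_equal(prof$profile$mean_rate[prof$profile$offset %in% -2:-1],
               rev(prof$profile$mean_rate[prof$profile$offset %in% 1:2]))
})

test_that("profile equals a brute-force per-burst histogram", {
  sim <- simulate_culture(simulation_presets("mature_control",
                                             duration = 60, seed = 4))
  rec <- filter_artifacts(sim$recording)
  b <- detect_bursts(rec)
  prof <- network_spike_profile(rec, b)
  bw <- prof$bin_width
  offsets <- prof$profile$offset
  # independent route: full-recording histogram by table(), explicit
  # per-burst peak scan, manual accumulation
  n_bins <- ceiling(rec$duration / bw)
  counts <- rep(0L, n_bins)
  tb <- table(floor(rec$events$time / bw) + 1)
  counts[as.integer(names(tb))] <- as.integer(tb)
  acc <- numeric(length(offsets))
  gb <- b$global_bursts
  for (i in seq_len(nrow(gb))) {
    bins <- (floor(gb$start[i] / bw) + 1):(min(floor(gb$end[i] / bw) + 1,
                                               n_bins))
    peak <- bins[which(counts[bins] == max(counts[bins]))[1]]
    for (k in seq_along(offsets)) {
      j <- peak + offsets[k]
      if (j >= 1 && j <= n_bins) acc[k] <- acc[k] + counts[j]
    }
  }
  expect_equal(prof$profile$mean_rate, acc / nrow(gb))
})

test_that("tied maximum bins resolve to the earliest", {
  # two equal 8-spike bins inside one burst: every channel fires twice in
  # the bin starting at 1.000 and twice in the bin starting at 1.008
  ev <- expand.grid(t0 = c(1.0005, 1.0015, 1.0085, 1.0095), channel = 1:4)
  ev <- data.frame(time = ev$t0, channel = ev$channel, amplitude = -100)
  rec <- spike_recording(ev, 3, 8)
  b <- detect_bursts(rec)
  expect_equal(nrow(b$global_bursts), 1L)
  prof <- network_spike_profile(rec, b)
  expect_equal(prof$t0, 1.000)
})

test_that("measure histograms are half-open and conserve in-range counts", {
  h <- measure_histogram(c(2, 3, 12), edges = c(0, 5, 10, 15))
  expect_equal(h$count, c(2L, 0L, 1L))
  expect_equal(measure_histogram(numeric(), c(0, 1, 2))$count, c(0L, 0L))
  # value on an interior edge goes right; value on the last edge is out
  expect_equal(measure_histogram(c(5, 15), c(0, 5, 10, 15))$count,
               c(0L, 1L, 0L))
  expect_error(measure_histogram(1, c(0, 0, 1)), "increasing")
})
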