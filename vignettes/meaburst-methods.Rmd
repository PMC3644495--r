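---
title: "Methods: burst detection, measures and paired statistics in meaburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst detection, measures and paired statistics in meaburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaburst)
```

`meaburst` analyses spontaneous network activity of neuronal cultures on
multi-electrode arrays (MEAs): tables of detected spikes (time, electrode,
signed amplitude) from 59-electrode planar arrays. This vignette is the
package's own account of the methods: the detection rules and their exact
semantics, the measure definitions, the statistical conventions, the
generative model behind the synthetic cultures, and the design decisions
taken where conventions genuinely diverge.

## Input model and artifact filtering

All times are stored in seconds internally; reports render milliseconds
where the measure conventionally uses them. Events are kept sorted by
time, ties broken by channel index, so every downstream computation is
deterministic. Binning is always half-open, `[a, b)`, 0-based: no event is
ever counted twice, and an event falling exactly at the recording end is
excluded.

Extracellular spike detection rectifies large negative-going spikes into a
small positive after-phase; `filter_artifacts()` therefore drops events
with signed amplitude in `(0, 50]` μV. The rule operates on the *signed*
amplitude — "positive-going" is read as `amplitude > 0` — because that is
the phrasing of the convention; a +60 μV event survives, a −30 μV event is
never touched. The filter is idempotent and never alters surviving events.

Cultures are classed by age as immature (DIV 14–25) or mature (DIV 37–61);
ages in neither range are `"unclassified"` rather than errors, since such
cultures are simply outside the two study windows.

## Burst detection

The criteria (`burst_criteria()`) are: ≥ 4 spikes within 100 ms on one
channel, on ≥ 4 distinct channels, overlapping within 250 ms. Two points
of these printed rules need a precise semantics:

**Channel bursts.** Call a 100 ms window holding ≥ 4 spikes of a channel
*tight*. Two spikes belong to the same channel burst iff they are
connected by a chain of shared tight windows; channel bursts are the
connected components (necessarily ≥ 4 spikes). We chose this over the
superficially simpler "maximal runs of window-qualified spikes" because
the run formulation silently bridges arbitrary silent gaps on a channel
whose only spikes are two well-separated bursts — the component
formulation reduces to the obvious answer on well-separated bursts and
never links spikes more than one window apart. On sorted times it is
computed in linear passes: block `j..j+m-1` is tight iff
`t[j+m-1] - t[j] <= w`, and consecutive spikes are linked iff some tight
block contains both.

**Global bursts.** Channel bursts are clustered by single linkage on
their *onset* times with 250 ms linkage distance (equivalently: sort
onsets, cut where consecutive onsets differ by more than 250 ms). We
preferred onset linkage over pairwise interval-intersection tests because
it is deterministic, order-independent, and yields disjoint clusters by
construction. Clusters with ≥ 4 distinct channels become global bursts;
`start`/`end` are the min/max of member channel-burst boundaries, and
member spikes are *all* spikes of participating channels inside
`[start, end]` — including tonic spikes that happen to fall in the window,
which is what "spikes during the burst" means operationally. Bursts
beginning or ending within one channel-window of the recording edge are
flagged `truncated` but retained (duration statistics include them by
default); flagging preserves the information without inventing an
exclusion rule.

The test suite holds the implementation to an exhaustive brute-force
oracle — explicit enumeration of every candidate window and iterative
cluster merging — on 100 random rasters, plus monotonicity (relaxing any
criterion never reduces the burst count) and time-shift equivariance.

## The measure suite

Per burst: `c_active` (channels contributing a channel burst), `g_spikes`
(member spikes), `c_spikes = g_spikes / c_active`, `c_duration` (mean
channel-wise first-to-last span), `g_duration` (global span). Recording
level: `isi_all` (pooled consecutive gaps over all events), `sib`
(100 × burst spikes / total spikes, an exact counting identity on
integers), `ibi` (last spike of one burst to first spike of the next) and
`ibi_cv` (its coefficient of variation, the burst-regularity index).

**In-burst ISI.** Two readings of "mean inter-spike interval from all
events on all channels during a burst" exist: pool every member spike into
one interleaved sequence and difference it, or difference within each
channel and pool the gaps. The two differ by an order of magnitude: a
well-populated burst (≈ 140 spikes over ≈ 100 ms on ≈ 12 channels) has
interleaved gaps below 1 ms, while the within-channel gaps equal
channel-duration ÷ (spikes − 1) ≈ 40 ms / 10 = 4 ms. Only the per-channel
reading is arithmetically consistent with the classical descriptive
statistics of such cultures (and with this package's own calibration
targets), and under the detection criteria the interleaved reading cannot
even reach the millisecond scale those statistics report. `isi_burst` is
therefore per-channel; the interleaved variant is retained as
`isi_burst_pooled` since it is a legitimate quantity in its own right.

**C-active ambiguity.** "Channels showing spiking activity during a burst
when channel-burst criteria are met" can mean channels *meeting the
criteria* or channels *with any spike* in the window. The former is the
default (`active_channel_rule = "burst"`); the latter is exposed as
`"any_spike"`.

**Network spike profile.** Array-wide counts at 4 ms, aligned per burst
at the bin with the maximum count among bins overlapping the burst
(earliest bin on ties — determinism), averaged across bursts over a
window of −100 ms/+300 ms around t₀. The window is a package choice: it
covers the longest printed burst durations (~190 ms) with margin; the
convention's own plotted extent is not stated anywhere. Bins falling
outside the recording contribute zero and are counted in `n_inside`.

## Paired statistics

Effects are normalised per culture, `100 × (drug − control)/control`
(`pct_change()`); a zero control yields a flagged missing value, never an
aborted batch. Histogram-of-change applies the same rule per bin.

`wilcoxon_signed_rank()` drops zero differences before ranking (the
classical treatment; Pratt's method was the alternative — the convention
this follows is silent, so the classical default was chosen and the
zero-handling is visible in `n`). Mid-ranks handle ties. For n ≤ 15 the
p-value is exact: the distribution of the positive-rank sum over all 2ⁿ
sign assignments, computed by convolution on a half-integer grid so tied
ranks are handled exactly; above 15 a normal approximation with tie
correction and continuity correction takes over. The tests verify
exactness against explicit enumeration of all sign vectors for every
n ≤ 12 and against `stats::wilcox.test` where both are exact.

Two thresholds are reported side by side, because they answer different
questions. The family-wise threshold α = 0.05/4 mirrors the printed
correction convention (kept at family size 4 even when more measures are
tabulated — fidelity to the printed rule over statistical orthodoxy; it is
configurable). Direction markers (increase/decrease/none) use the
conventional P ≤ 0.05 marker level with the sign of the median percentage
change. The distinction matters: with n = 6 paired cultures the smallest
achievable exact two-sided signed-rank p is 2/64 = 0.03125, so *no*
measure can ever clear α = 0.0125 at that replicate count — the
family-wise flag is structurally conservative there, and the marker level
is what carries the directional summary.

`profile_anova()` is a plain two-factor ANOVA (condition × time bin, with
interaction) on per-culture mean per-bin rates via `stats::aov`. Culture
is *not* modelled as a blocking factor — whether the original convention
blocked on culture is not derivable, so the plainest reading is
implemented and noted here as an interpretation.

## The synthetic-culture generator

`simulate_culture()` draws, in order: global burst onsets from a gamma
renewal process (mean `ibi_mean`, shape `ibi_shape`); per burst, each
channel joins independently with probability `p_participate`; a joining
channel gets a normal onset jitter (`onset_jitter_sd`) and a spike train
whose count is `4 + NegBin(size = count_size, mu = mean − 4)` with
exponential in-burst ISIs (`in_burst_isi_mean`), the first spike drawn
from a large-amplitude component (the compound spike that opens a burst)
and followers from a smaller one; an independent Poisson tonic background
(`tonic_rate` per channel); and ~2% small positive artifact events so the
artifact filter is exercised end to end. All randomness flows from the
explicit `seed` — identical parameters give byte-identical spike tables,
and the generator restores the caller's RNG state.

The mature preset pins every mean the published descriptive statistics
provide: IBI 5.1 s, in-burst ISI 4 ms, ~11 spikes per channel,
`p_participate = 12/59`, tonic rate 0.31 Hz/channel chosen so ~58% of
spikes fall in bursts; immature analogously (7.3 s, 4.6 ms, 13 spikes,
19/59, 0.44 Hz, ~56%). Distributional *shapes* are the generator's own
choices — only means and ranges are published — selected for positivity
and two-parameter control of regularity: gamma IBIs (shape 3 ≈ CV 0.58,
irregular control-like bursting; regularising drugs raise the shape),
exponential in-burst ISIs, lognormal culture-level multipliers (σ = 0.1)
shared by both members of a control/drug pair. Two generator parameters
were calibrated once against the printed global-duration target by
simulating the burst-span model alone and then frozen: the onset jitter
SD (8 ms mature, 12 ms immature) and the count dispersion (`count_size =
4`; a pure geometric count's heavy tail would push the longest
channel train — and hence the global span — well past the printed
duration at the published count mean). The count floor of 4 equals the
per-channel criterion: a channel engaging with fewer spikes is, by
definition of the detector, not a bursting channel, and such weak
engagement is represented by the tonic background instead; without the
floor, ~a quarter of programmed "participating" channels would be
invisible to any detector honouring the printed criteria, biasing every
calibration target.

Drug transforms are multiplicative parameter maps reproducing published
effect *directions*, with magnitudes chosen once to emulate clearly
significant effects: `atropine_like` (IBI ×1.8, shape ×4 — much more
regular bursting, tonic ×0.2, participation ×1.4, counts ×1.3),
`oxom_mature_like` (tonic ×6, participation ×0.75, IBI ×1.5),
`oxom_immature_like` (the same, attenuated), `mec_like` (onset jitter
×0.2 and count dispersion tightened ×4 — markedly shorter global bursts
through tighter synchrony — plus tonic ×0.8, reducing out-of-burst
spiking). Two mechanical couplings are worth knowing: shrinking the
global window slightly raises the in-burst share of spikes and the
overall ISI (fewer tonic spikes, shorter windows), so a "duration-only"
transform still moves those two measures coherently; and a channel-level
duration change cannot be programmed while holding both spike counts and
in-burst ISIs fixed, because channel duration ≈ (count − 1) × ISI is an
identity of the generator.

**What the generator does not emulate:** electrode geometry and spatial
correlation (channels are exchangeable), within-burst rate envelopes
(trains are renewal, so profiles lack the sharp compound-spike peak of
real bursts beyond the first-spike amplitude), amplitude dynamics,
development over time within a recording, and any biophysics. Passing
tests therefore demonstrate that the *pipeline* is correct and that its
statistics recover programmed population parameters — not that real
cultures satisfy the generator's independence assumptions.

## Inclusion gate

The early-recording gate retains a culture only if global burst incidence
over the first 5 minutes strictly exceeds 0.25 Hz. Note a tension a user
should be aware of: typical published mature cultures have mean IBI
around 5 s, i.e. incidence ≈ 0.2 Hz, *below* this printed gate. The gate
is therefore applied as a flag: `run_analyze()` logs the incidence and
excludes failing recordings from group summaries while still writing
their per-recording outputs, and the threshold is configurable
(`[io] inclusion_threshold_hz`).

## Problem sizes and runtime choices

The validation suite runs at sizes chosen to give stable statistics on a
single CPU: the detector oracle on 100 random rasters of ≤ 1,000 spikes;
calibration recovery on 10 mature 600 s cultures (tolerance 20%, matching
the published between-culture spread); null calibration of the
family-wise error rate on 100 replicate paired experiments of 6 cultures
at 300 s (the replicate count of the underlying protocol; 300 s keeps
~60 bursts per recording, ample for every measure); drug-direction
reproduction on 5 replicate experiments of 6 cultures at 600 s, with
directions taken by majority across replicates — a single null measure
flips to an all-same-sign fluke in ~3% of experiments, so majority voting
makes the check a property of the design rather than of one seed.

## Known limitations

* One detector. Alternative burst detectors (rank-surprise, MaxInterval,
  CMA) are out of scope by design; the criteria are configurable but the
  algorithm is single.
* Measures assume the burst table came from the same recording; nothing
  stops a caller mixing objects, beyond the container invariants.
* The exact signed-rank path is O(n · Σ ranks) per test — fine to n = 15,
  which is why the normal approximation takes over beyond it.
* The profile ANOVA treats bins as independent factor levels;
  autocorrelation across bins is not modelled.
* `spike_recording` keeps events in memory as a plain data frame;
  multi-hour high-density recordings would want a chunked backend.
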