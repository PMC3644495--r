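#' Percentage change from control
#'
#' `100 * (drug - control) / control`, the per-culture normalisation that
#' absorbs inherent culture-to-culture variability in baseline activity.
#' A zero or non-finite control value makes the change undefined and yields
#' `NA` rather than an error, so a batch of measures is never aborted by a
#' single degenerate baseline.
#'
#' @param control baseline value(s).
#' @param drug treated value(s), same length.
#' @return Numeric vector of percentage changes (`NA` where undefined).
#' @examples
#' pct_change(10, 15)  # +50
#' @export
pct_change <- function(control, drug) {
  out <- 100 * (drug - control) / control
  out[!is.finite(control) | control == 0 | !is.finite(drug)] <- NA_real_
  out
}

#' Per-bin percentage change between two histograms
#'
#' Applies [pct_change()] bin-wise to two histograms on identical edges;
#' bins with an empty control count are `NA`.
#'
#' @param control_counts,drug_counts histograms as returned by
#'   [measure_histogram()] (data frames with `bin_start`, `bin_end`,
#'   `count`), on identical edges.
#' @return Data frame with `bin_start`, `bin_end`, `pct_change`.
#' @export
histogram_change <- function(control_counts, drug_counts) {
  if (nrow(control_counts) != nrow(drug_counts) ||
      any(control_counts$bin_start != drug_counts$bin_start) ||
      any(control_counts$bin_end != drug_counts$bin_end))
    stop("histogram bin edges differ between control and drug",
         call. = FALSE)
  data.frame(bin_start = control_counts$bin_start,
             bin_end = control_counts$bin_end,
             pct_change = pct_change(control_counts$count,
                                     drug_counts$count))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples. Zero differences are
#' dropped before ranking (the classical treatment); absolute differences
#' are mid-ranked, so ties are handled. For `n <= exact_limit` remaining
#' pairs the p-value comes from the exact distribution of the
#' positive-rank sum `W` over all `2^n` equiprobable sign assignments
#' (computed by convolution over the observed ranks, ties included):
#' `p = min(1, 2 * min(P(W <= w), P(W >= w)))`. Above the limit, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param paired_a,paired_b paired numeric vectors (differences are
#'   `b - a`, i.e. `a` is the control).
#' @param alpha significance threshold; the default `0.05 / family_size`
#'   applies Bonferroni-style family-wise control over the measure family.
#' @param family_size size of the measure family the threshold divides by
#'   (default 4, the printed convention of the underlying protocol, kept
#'   even when more measures are tabulated).
#' @param exact_limit largest n for which the exact distribution is used
#'   (default 15).
#' @return List of class `signed_rank_test`: `statistic` (W, sum of ranks
#'   of positive differences), `n` (pairs after zero removal), `p_value`,
#'   `alpha`, `significant` (`p_value <= alpha`), `degenerate` (all
#'   differences zero; then `p_value = 1`), `method` ("exact" or
#'   "normal_approx").
#' @examples
#' wilcoxon_signed_rank(rep(0, 6), 1:6)$p_value  # 2/64 = 0.03125
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b,
                                 alpha = 0.05 / family_size,
                                 family_size = 4L, exact_limit = 15L) {
  if (length(paired_a) != length(paired_b))
    stop("paired samples differ in length", call. = FALSE)
  d <- paired_b - paired_a
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(structure(list(statistic = NA_real_, n = 0L, p_value = 1,
                          alpha = alpha, significant = FALSE,
                          degenerate = TRUE, method = "degenerate"),
                     class = "signed_rank_test"))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, w)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    # variance with tie correction on the mid-ranks
    sigma2 <- sum(r^2) / 4
    cc <- 0.5 * sign(w - mu)
    z <- (w - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(statistic = w, n = n, p_value = p, alpha = alpha,
                 significant = p <= alpha, degenerate = FALSE,
                 method = method),
            class = "signed_rank_test")
}

# Exact two-sided p for the positive-rank sum given the observed ranks.
# Distribution over all 2^n sign assignments via convolution on a grid of
# doubled ranks (mid-ranks are multiples of 1/2, so 2*r is integral).
signed_rank_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)  # f[s+1] = #assignments with doubled-sum s
  f[1L] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total + 1L - r)]
    f <- g
  }
  f <- f / sum(f)
  w2 <- as.integer(round(2 * w))
  lower <- sum(f[seq_len(w2 + 1L)])
  upper <- sum(f[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(lower, upper))
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf(
    "<signed_rank_test> W = %s, n = %d, p = %.5g (%s), alpha = %g%s\n",
    format(x$statistic), x$n, x$p_value, x$method, x$alpha,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Two-way ANOVA on burst profiles
#'
#' Tests whether the peak-aligned network spike profile differs between
#' conditions with a plain two-factor ANOVA (condition x time bin, with
#' interaction) on the per-culture mean per-bin rates. Each culture
#' contributes one profile per condition; cultures are the replicates
#' within each condition x bin cell.
#'
#' @param profiles_control,profiles_drug lists of `network_profile`
#'   objects (one per culture), all on identical offsets.
#' @param alpha significance threshold (default 0.05).
#' @return Data frame with rows `condition`, `bin`, `condition:bin`:
#'   columns `term`, `df`, `F`, `p`, `significant`.
#' @export
profile_anova <- function(profiles_control, profiles_drug, alpha = 0.05) {
  stack <- function(lst, label) {
    if (length(lst) < 2L)
      stop("profile_anova needs >= 2 cultures per condition (",
           label, " has ", length(lst), ")", call. = FALSE)
    do.call(rbind, lapply(seq_along(lst), function(i) {
      p <- lst[[i]]$profile
      data.frame(rate = p$mean_rate, bin = factor(p$offset),
                 condition = label, culture = i)
    }))
  }
  dc <- stack(profiles_control, "control")
  dd <- stack(profiles_drug, "drug")
  if (nlevels(dc$bin) != nlevels(dd$bin) ||
      any(levels(dc$bin) != levels(dd$bin)))
    stop("profiles are binned differently between conditions",
         call. = FALSE)
  dat <- rbind(dc, dd)
  dat$condition <- factor(dat$condition)
  fit <- stats::aov(rate ~ condition * bin, data = dat)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  keep <- terms %in% c("condition", "bin", "condition:bin")
  data.frame(term = terms[keep], df = tab$Df[keep],
             F = tab$`F value`[keep], p = tab$`Pr(>F)`[keep],
             significant = tab$`Pr(>F)`[keep] <= alpha)
}

#' Paired drug-versus-control comparison over the measure family
#'
#' For every measure in `measures`, pairs the per-culture means of the
#' control and drug recordings (matched by `culture_id`), computes the
#' per-culture percentage changes, tests those normalised changes against
#' zero with [wilcoxon_signed_rank()], and calls a direction. Two thresholds
#' are reported side by side: `significant` applies the family-wise
#' threshold `alpha = 0.05 / family_size`, while `direction`
#' (increase / decrease / none) uses the conventional `P <= 0.05` marker
#' level with the sign of the median percentage change.
#'
#' @param control,drug lists of `measure_set` objects (one per culture),
#'   paired by their `culture_id`.
#' @param measures character vector of measure names to compare.
#' @param family_size family size for the family-wise threshold
#'   (default 4).
#' @param direction_alpha marker-level threshold for direction calls
#'   (default 0.05).
#' @return Object of class `paired_comparison`: list with `table` (data
#'   frame: measure, n, median_pct_change, p, alpha, significant,
#'   direction), `pct_change` (measure x culture matrix), `control_values`,
#'   `drug_values`, `cultures`.
#' @export
compare_conditions <- function(control, drug,
                               measures = c("c_spikes", "g_spikes",
                                            "c_active", "c_duration",
                                            "g_duration", "isi_burst",
                                            "isi_all", "sib", "ibi",
                                            "ibi_cv"),
                               family_size = 4L, direction_alpha = 0.05) {
  ids_c <- unname(vapply(control, `[[`, character(1), "culture_id"))
  ids_d <- unname(vapply(drug, `[[`, character(1), "culture_id"))
  unpaired <- c(setdiff(ids_c, ids_d), setdiff(ids_d, ids_c))
  if (length(unpaired))
    stop("unpaired culture id(s): ", paste(unique(unpaired), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ids_c))
    stop("duplicate culture ids within a condition", call. = FALSE)
  drug <- drug[match(ids_c, ids_d)]
  alpha <- 0.05 / family_size
  getm <- function(lst, m) vapply(lst, measure_mean, numeric(1), m)
  cv <- sapply(measures, function(m) getm(control, m))
  dv <- sapply(measures, function(m) getm(drug, m))
  cv <- matrix(cv, ncol = length(measures),
               dimnames = list(ids_c, measures))
  dv <- matrix(dv, ncol = length(measures),
               dimnames = list(ids_c, measures))
  pc <- 100 * (dv - cv) / cv
  pc[!is.finite(cv) | cv == 0 | !is.finite(dv)] <- NA_real_
  rows <- lapply(measures, function(m) {
    pcm <- pc[, m]
    ok <- is.finite(pcm)
    if (sum(ok) == 0L) {
      return(data.frame(measure = m, n = 0L, median_pct_change = NA_real_,
                        p = NA_real_, alpha = alpha, significant = FALSE,
                        direction = "none"))
    }
    # test the normalised per-culture changes against zero
    test <- wilcoxon_signed_rank(rep(0, sum(ok)), pcm[ok], alpha = alpha)
    med <- stats::median(pcm[ok])
    dir <- if (!test$degenerate && test$p_value <= direction_alpha &&
               is.finite(med) && med != 0) {
      if (med > 0) "increase" else "decrease"
    } else "none"
    data.frame(measure = m, n = sum(ok), median_pct_change = med,
               p = test$p_value, alpha = alpha,
               significant = test$significant, direction = dir)
  })
  structure(list(table = do.call(rbind, rows), pct_change = pc,
                 control_values = cv, drug_values = dv, cultures = ids_c),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %d cultures, family alpha %.4g\n",
              length(x$cultures), x$table$alpha[1]))
  tab <- x$table
  tab$median_pct_change <- signif(tab$median_pct_change, 4)
  tab$p <- signif(tab$p, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Paired t-test on non-normalised means
#'
#' Companion test for population-mean quantities (e.g. spike amplitude)
#' where percentage-change normalisation is not applied.
#'
#' @param control,drug paired numeric vectors of per-culture means.
#' @param alpha significance threshold (default 0.05).
#' @return List with `t`, `df`, `p_value`, `significant`,
#'   `mean_difference`.
#' @export
paired_t_test <- function(control, drug, alpha = 0.05) {
  fit <- stats::t.test(drug, control, paired = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value, significant = fit$p.value <= alpha,
       mean_difference = unname(fit$estimate))
}
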