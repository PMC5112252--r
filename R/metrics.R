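#' Per-block correct-response rates
#'
#' Splits one phase's correct/incorrect sequence into consecutive blocks
#' (default 40 trials) and returns the correct rate of each block.
#'
#' @param correct Logical (or 0/1) vector, one entry per trial of the phase.
#' @param block_size Trials per block.
#' @return Numeric vector of per-block correct rates.
#' @export
block_rates <- function(correct, block_size = 40L) {
  n <- length(correct)
  if (n < 1) stop("empty trial sequence")
  blk <- ceiling(seq_len(n) / block_size)
  as.numeric(tapply(as.numeric(correct), blk, mean))
}

#' Classify a run (or subject) as a learner
#'
#' A run counts as a learner if it responded correctly in over `threshold`
#' (strictly more than 70% by default) of the trials in each phase.
#'
#' @param phase_rates Per-phase overall correct rates.
#' @param threshold Learner threshold (default 0.7, strict inequality).
#' @return Logical flag.
#' @export
classify_learner <- function(phase_rates, threshold = 0.7) {
  all(phase_rates > threshold)
}

#' Interpolated time to criterion
#'
#' The ordinate of the first linear intersection between the criterion level
#' (default 80%) and the per-block correct rate, with block `i` at ordinate
#' `i` (1-based).  If the first block already meets the criterion the time is
#' 1; if the curve never reaches it, `NA`.
#'
#' @param rates Per-block correct rates (see [block_rates()]).
#' @param criterion Criterion level (default 0.8); the crossing point is the
#'   first passage from below to `>= criterion`.
#' @return Fractional block ordinate, or `NA_real_` if never reached.
#' @examples
#' time_to_criterion(c(0.5, 0.9))        # 1 + (0.8 - 0.5) / (0.9 - 0.5)
#' time_to_criterion(c(0.85, 0.9))       # 1
#' time_to_criterion(c(0.5, 0.6, 0.7))   # NA
#' @export
time_to_criterion <- function(rates, criterion = 0.8) {
  if (length(rates) < 1) stop("empty block sequence")
  if (rates[1] >= criterion) return(1)
  for (i in seq_len(length(rates) - 1)) {
    if (rates[i] < criterion && rates[i + 1] >= criterion)
      return(i + (criterion - rates[i]) / (rates[i + 1] - rates[i]))
  }
  NA_real_
}

#' Paired comparison of time-to-criterion between phases
#'
#' Two-sided paired test of the per-subject (per-run) times to criterion of
#' two phases.  Pairs in which either value is undefined are dropped.  The
#' paired t-test is used for simulation groups; the paired Wilcoxon
#' signed-rank test matches the analysis applied to experimental data.
#'
#' @param ttc_a,ttc_b Equal-length vectors of times to criterion (may contain
#'   `NA`).
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @return A list with `statistic`, `df` (`NA` for Wilcoxon), `p_value`,
#'   `mean_a`, `mean_b`, and `n` (pairs retained).  Degenerate input (all
#'   differences zero) signals an error.
#' @examples
#' compare_phases(c(3, 4, 5), c(2, 3, 5))  # t = 2, df = 2
#' @export
compare_phases <- function(ttc_a, ttc_b, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(ttc_a) != length(ttc_b)) stop("vectors must have equal length")
  keep <- !is.na(ttc_a) & !is.na(ttc_b)
  a <- ttc_a[keep]; b <- ttc_b[keep]
  if (length(a) < 2) stop("fewer than 2 complete pairs")
  if (all(a == b)) stop("degenerate test: all paired differences are zero")
  if (method == "t") {
    tt <- t.test(a, b, paired = TRUE)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
         n = length(a), method = "paired t")
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
    list(statistic = unname(wt$statistic), df = NA_real_,
         p_value = wt$p.value, mean_a = mean(a), mean_b = mean(b),
         n = length(a), method = "paired Wilcoxon")
  }
}

#' Sensitivity index d'
#'
#' `qnorm(hit_rate) - qnorm(false_alarm_rate)`, for Go/NoGo-style trial logs.
#' Rates of exactly 0 or 1 are shrunk by the standard 1/(2n) correction when
#' the trial counts are supplied.
#'
#' @param hit_rate,fa_rate Hit and false-alarm rates in `[0, 1]`.
#' @param n_go,n_nogo Optional trial counts used for the extreme-rate
#'   correction.
#' @return d' value.
#' @export
dprime <- function(hit_rate, fa_rate, n_go = NULL, n_nogo = NULL) {
  fix <- function(rate, n) {
    if (!is.null(n)) rate <- pmin(pmax(rate, 1 / (2 * n)), 1 - 1 / (2 * n))
    rate
  }
  qnorm(fix(hit_rate, n_go)) - qnorm(fix(fa_rate, n_nogo))
}

#' Behavioural metrics from a trial log
#'
#' Computes per-phase correct rates, per-block rates, the learner flag and
#' the per-phase interpolated time to criterion from a per-trial table.  The
#' table needs at least the columns `phase` (0-based or any sortable labels)
#' and `correct` (logical or 0/1) — the format written by [run_experiment()]
#' and also the minimal content of an external experimental trial log.
#'
#' @param log A data frame with columns `phase` and `correct`.
#' @param block_size Trials per block (default 40; the human analysis used
#'   20-trial blocks).
#' @param criterion Time-to-criterion level (default 0.8).
#' @param threshold Learner threshold (default 0.7).
#' @return A list with `phase_rates`, `block_rates` (list per phase),
#'   `learner`, and `ttc` (vector per phase, `NA` where never reached).
#' @export
analyze_trial_log <- function(log, block_size = 40L, criterion = 0.8,
                              threshold = 0.7) {
  if (!all(c("phase", "correct") %in% names(log)))
    stop("log must have columns 'phase' and 'correct'")
  phases <- sort(unique(log$phase))
  by_phase <- lapply(phases, function(ph) as.numeric(log$correct[log$phase == ph]))
  phase_rates <- vapply(by_phase, mean, numeric(1))
  br <- lapply(by_phase, block_rates, block_size = block_size)
  ttc <- vapply(br, time_to_criterion, numeric(1), criterion = criterion)
  names(phase_rates) <- names(br) <- names(ttc) <- paste0("phase", phases)
  list(phase_rates = phase_rates, block_rates = br,
       learner = classify_learner(phase_rates, threshold), ttc = ttc)
}
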