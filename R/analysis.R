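#' Spike train container
#'
#' @param times Spike times in seconds, strictly increasing.
#' @param window Observation window `c(start, end)` in seconds; defaults
#'   to `c(0, max(times))` (or `c(0, 0)` for an empty train).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, window = NULL) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (is.null(window))
    window <- c(0, if (length(times)) max(times) else 0)
  if (length(times) && (times[1] < window[1] || times[length(times)] > window[2]))
    stop("spike times fall outside the observation window")
  structure(list(times = times, window = window), class = "spike_train")
}

#' Inter-spike intervals and firing regularity
#'
#' ISIs are consecutive spike-time differences; the coefficient of
#' variation is the population standard deviation of the ISIs divided by
#' their mean. A perfectly periodic train has CV = 0 and a Poisson train
#' CV = 1.
#'
#' @param train A [spike_train()] (or a numeric vector of spike times in
#'   seconds).
#' @return `NULL` when the train has fewer than 2 spikes (ISI undefined).
#'   Otherwise a list with `isi_ms` (vector), `mean_isi_ms`, and `cv`
#'   (`NA` when fewer than 3 spikes).
#' @examples
#' isi_stats(spike_train(c(0, 1, 2, 3)))   # periodic: CV 0
#' @export
isi_stats <- function(train) {
  if (!inherits(train, "spike_train")) train <- spike_train(train)
  n <- length(train$times)
  if (n < 2) return(NULL)
  isi <- diff(train$times) * 1000
  m <- mean(isi)
  cv <- if (n >= 3) sqrt(mean((isi - m)^2)) / m else NA_real_
  list(isi_ms = isi, mean_isi_ms = m, cv = cv)
}

#' Binned population mean firing rate
#'
#' Counts all spikes per bin and divides by `bin * n_neurons`, the mean
#' per-neuron rate in Hz. Multiplying the series by `bin * n_neurons` and
#' summing recovers the total spike count.
#'
#' @param times All spike times pooled across the population, seconds.
#' @param n_neurons Number of neurons contributing (denominator).
#' @param bin Bin width, seconds.
#' @param window Observation window `c(start, end)`, seconds.
#' @return A data.frame with `t_s` (bin centre) and `rate_hz`.
#' @export
population_rate <- function(times, n_neurons, bin = 0.05,
                            window = c(0, if (length(times)) max(times) else bin)) {
  stopifnot(bin > 0, n_neurons >= 1)
  breaks <- seq(window[1], window[2] + bin * 1e-9, by = bin)
  if (breaks[length(breaks)] < window[2]) breaks <- c(breaks, window[2])
  times <- times[times >= window[1] & times <= window[2]]
  counts <- if (length(breaks) < 2) integer(0) else
    as.vector(table(cut(times, breaks, include.lowest = TRUE)))
  widths <- diff(breaks)
  data.frame(t_s = (breaks[-length(breaks)] + breaks[-1]) / 2,
             rate_hz = counts / (widths * n_neurons))
}

#' Percent change between two spike counts
#'
#' `100 * (treatment - reference) / reference`, the signed dose-response
#' measure used to compare spike counts across temperature elevations.
#'
#' @param reference Reference (baseline) count; must be positive.
#' @param treatment Treatment count.
#' @return Signed percent change.
#' @examples
#' percent_change(22, 52)   # +136.36...
#' percent_change(22, 9)    # -59.09...
#' @export
percent_change <- function(reference, treatment) {
  if (any(reference <= 0))
    stop("reference count must be positive for a percent change")
  100 * (treatment - reference) / reference
}
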