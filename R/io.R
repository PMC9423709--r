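#' Seeded homogeneous Poisson spike train
#'
#' Fixture generator for synapse-driving experiments and property tests.
#'
#' @param rate Mean rate, Hz (>= 0).
#' @param duration Duration, seconds.
#' @param seed Integer seed.
#' @return A [spike_train()] over `c(0, duration)`.
#' @export
make_poisson_train <- function(rate, duration, seed = 1L) {
  stopifnot(rate >= 0, duration > 0)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(as.integer(seed))
  n <- stats::rpois(1, rate * duration)
  spike_train(sort(stats::runif(n, 0, duration)), c(0, duration))
}

#' Write simulation outputs to a directory
#'
#' Emits `spikes.csv` (`neuron_id`, `time_s`, `population`), `rate.csv`
#' (`t_s`, `rate_hz`), `summary.json` (counts, ISI statistics, the fully
#' resolved metadata echo and package version), and optional
#' `trace_<id>.csv` voltage traces. Columns and units are fixed.
#'
#' @param result An `insnet_sim` result from [run_network()] or
#'   [simulate_neuron()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (is.data.frame(result$spikes)) {
    spikes <- data.frame(neuron_id = result$spikes$neuron,
                         time_s = result$spikes$time_s,
                         population = result$spikes$population)
  } else {
    spikes <- data.frame(neuron_id = rep(1L, length(result$spikes)),
                         time_s = result$spikes,
                         population = rep("E", length(result$spikes)))
  }
  p <- file.path(outdir, "spikes.csv")
  utils::write.csv(spikes, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  if (!is.null(result$rate)) {
    p <- file.path(outdir, "rate.csv")
    utils::write.csv(result$rate, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  by_neuron <- split(spikes$time_s, spikes$neuron_id)
  isi <- lapply(by_neuron, function(ts) isi_stats(spike_train(ts)))
  isi <- isi[!vapply(isi, is.null, TRUE)]
  summary <- list(
    n_spikes = nrow(spikes),
    n_neurons_firing = length(by_neuron),
    mean_isi_ms = if (length(isi))
      mean(vapply(isi, `[[`, 0, "mean_isi_ms")) else NULL,
    mean_cv = if (length(isi)) {
      cvs <- vapply(isi, `[[`, 0, "cv")
      if (any(!is.na(cvs))) mean(cvs, na.rm = TRUE) else NULL
    } else NULL,
    metadata = result$metadata,
    package_version = as.character(utils::packageVersion("insnet"))
  )
  p <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, p)
  if (!is.null(result$trace)) {
    p <- file.path(outdir, "trace_1.csv")
    utils::write.csv(result$trace, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(result$traces)) {
    p <- file.path(outdir, "traces.csv")
    utils::write.csv(result$traces, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
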