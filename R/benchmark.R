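#' HCM-vs-FCM noise-robustness benchmark
#'
#' Runs a phantom noise sweep (impulse fractions, canonically 0-5%) through
#' the chosen algorithms for several replicate seeds and tabulates one record
#' per (algorithm, noise, seed): validity indices, iteration count, and
#' overlap metrics against the phantom's ground truth.  For HCM the
#' partition coefficient/entropy come from the \code{\link{soft_membership}}
#' relaxation at the HCM centers (see \code{\link{segment_image}}).
#' Deterministic for a given seed list.
#'
#' @param noise_fractions impulse-noise pixel fractions (default 0, 0.01,
#'   ..., 0.05).
#' @param algorithms subset of \code{c("hcm", "fcm", "fcm-hist")}.
#' @param seeds integer vector of replicate seeds (default 1:3).
#' @param base_spec a \code{\link{phantom_spec}}; its seed is replaced by
#'   each replicate seed in turn.
#' @param c,fuzzifier,max_iter,tol fit parameters (defaults c = 3 tissue
#'   classes, r = 2).
#' @param n_levels gray levels for \code{"fcm-hist"}.
#' @return A data.frame with columns \code{algorithm}, \code{noise},
#'   \code{partition_coefficient}, \code{partition_entropy},
#'   \code{iterations}, \code{dice}, \code{sensitivity}, \code{specificity},
#'   \code{seed}.
#' @examples
#' \donttest{
#' bm <- run_benchmark(noise_fractions = c(0, 0.02), seeds = 1)
#' aggregate(dice ~ algorithm, bm, mean)
#' }
#' @export
run_benchmark <- function(noise_fractions = seq(0, 0.05, by = 0.01),
                          algorithms = c("hcm", "fcm"), seeds = 1:3,
                          base_spec = phantom_spec(), c = 3L, fuzzifier = 2,
                          max_iter = 300L, tol = 1e-5, n_levels = 256L) {
  algorithms <- match.arg(algorithms, c("hcm", "fcm", "fcm-hist"),
                          several.ok = TRUE)
  rows <- list()
  for (seed in seeds) {
    spec <- base_spec
    spec$seed <- seed
    sweep_phantoms <- noise_sweep(spec, noise_fractions)
    for (j in seq_along(noise_fractions)) {
      ph <- sweep_phantoms[[j]]
      for (alg in algorithms) {
        cfg <- fit_config(c = c, fuzzifier = fuzzifier, max_iter = max_iter,
                          tol = tol, seed = seed)
        seg <- segment_image(ph$image, alg, cfg, n_levels = n_levels,
                             truth = ph$lesion)
        m <- seg$metrics
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg,
          noise = noise_fractions[j],
          partition_coefficient = m$partition_coefficient,
          partition_entropy = m$partition_entropy,
          iterations = m$iterations,
          dice = m$dice,
          sensitivity = m$sensitivity,
          specificity = m$specificity,
          seed = seed,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate benchmark records across seeds
#'
#' Mean and standard deviation of every metric per (algorithm, noise) cell.
#'
#' @param records a data.frame from \code{\link{run_benchmark}}.
#' @return A data.frame with one row per (algorithm, noise) and
#'   \code{<metric>_mean} / \code{<metric>_sd} columns.
#' @export
summarize_benchmark <- function(records) {
  metrics <- c("partition_coefficient", "partition_entropy", "iterations",
               "dice", "sensitivity", "specificity")
  key <- records[c("algorithm", "noise")]
  agg_mean <- stats::aggregate(records[metrics], by = key, FUN = mean)
  agg_sd <- stats::aggregate(records[metrics], by = key, FUN = stats::sd)
  names(agg_mean)[-(1:2)] <- paste0(metrics, "_mean")
  names(agg_sd)[-(1:2)] <- paste0(metrics, "_sd")
  out <- merge(agg_mean, agg_sd, by = c("algorithm", "noise"), sort = TRUE)
  out[order(out$algorithm, out$noise), , drop = FALSE]
}

#' Run the benchmark and write its CSV outputs
#'
#' File-level counterpart of \code{\link{run_benchmark}}: writes
#' \code{benchmark.csv} (one row per algorithm x noise x seed record) and
#' \code{benchmark_summary.csv} (mean and sd across seeds) into
#' \code{output_dir}.  Reruns with the same seeds produce byte-identical
#' files.
#'
#' @param output_dir output directory (created if missing).
#' @param quiet suppress the progress message.
#' @inheritParams run_benchmark
#' @return Invisibly, a list with \code{records_path}, \code{summary_path}
#'   and the records data.frame.
#' @export
benchmark_command <- function(output_dir = ".",
                              noise_fractions = seq(0, 0.05, by = 0.01),
                              algorithms = c("hcm", "fcm"), seeds = 1:3,
                              base_spec = phantom_spec(), c = 3L,
                              fuzzifier = 2, max_iter = 300L, tol = 1e-5,
                              n_levels = 256L, quiet = FALSE) {
  records <- run_benchmark(noise_fractions = noise_fractions,
                           algorithms = algorithms, seeds = seeds,
                           base_spec = base_spec, c = c,
                           fuzzifier = fuzzifier, max_iter = max_iter,
                           tol = tol, n_levels = n_levels)
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  records_path <- file.path(output_dir, "benchmark.csv")
  summary_path <- file.path(output_dir, "benchmark_summary.csv")
  utils::write.csv(records, records_path, row.names = FALSE)
  utils::write.csv(summarize_benchmark(records), summary_path,
                   row.names = FALSE)
  if (!quiet)
    message("benchmark: ", nrow(records), " records (",
            length(unique(records$algorithm)), " algorithms x ",
            length(noise_fractions), " noise levels x ", length(seeds),
            " seeds); wrote ", records_path, " and ", summary_path)
  invisible(list(records_path = records_path, summary_path = summary_path,
                 records = records))
}
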