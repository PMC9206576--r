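# Type-7 quantile of a multiset given by sorted distinct values and counts.
# Identical arithmetic to the plain path so pixel-domain and histogram-domain
# initializations agree bit-for-bit.
.quantile7_counts <- function(v, counts, p) {
  n <- sum(counts)
  cum <- cumsum(counts)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    x_lo <- v[which(cum >= lo)[1L]]
    if (h > lo) {
      x_hi <- v[which(cum >= lo + 1)[1L]]
      x_lo + (h - lo) * (x_hi - x_lo)
    } else x_lo
  }, numeric(1))
}

.quantile7 <- function(values, p) {
  sv <- sort(values)
  .quantile7_counts(sv, rep(1L, length(sv)), p)
}

# Shared initializer over the intensity support (sorted distinct observed
# values).  "quantile" places centers at the (i+0.5)/c type-7 quantiles of
# the support: invariant to how many pixels each intensity occupies, so a
# small lesion mode still attracts a center even when background dominates
# the pixel count, and strictly increasing (hence distinct) whenever
# c <= number of distinct values.  "random" samples c support values.
# Both the pixel-domain and histogram-domain fits call this with the same
# support, so their initializations agree bit-for-bit.
.init_centers_support <- function(v, config) {
  c <- config$c
  if (c > length(v))
    stop("init_centers: c = ", c, " exceeds the number of distinct values (",
         length(v), "); input is degenerate for this cluster count",
         call. = FALSE)
  if (config$init == "quantile") {
    .quantile7_counts(v, rep(1L, length(v)), (seq_len(c) - 0.5) / c)
  } else {
    sort(.with_seed(config$seed, sample(v, c, replace = FALSE)))
  }
}

#' Initialize cluster centers
#'
#' Deterministic \code{"quantile"} initialization places the c centers at the
#' (i + 0.5)/c type-7 quantiles of the \emph{distinct} observed intensities
#' (the gray-level support), i = 1..c.  Working on the support rather than
#' the raw pixel multiset makes the start invariant to tissue-volume
#' imbalance -- a lesion occupying 3% of the pixels still attracts a center
#' -- and guarantees c distinct starting centers whenever the input has at
#' least c distinct values.  \code{"random"} draws c distinct support values
#' using \code{config$seed}.
#'
#' @param features a \code{\link{feature_set}} (or anything
#'   \code{\link{as_feature_set}} accepts).
#' @param config a \code{\link{fit_config}}.
#' @return A \code{"cluster_model"} holding only the initial \code{centers}
#'   (sorted ascending).
#' @examples
#' init_centers(feature_set(1:100), fit_config(c = 4))$centers
#' @export
init_centers <- function(features, config) {
  f <- as_feature_set(features)
  centers <- .init_centers_support(sort(unique(f$values)), config)
  new_cluster_model(centers = centers, fuzzifier = config$fuzzifier,
                    method = "init")
}

#' Construct a cluster model
#'
#' Low-level constructor bundling cluster centers with the fuzzifier, the
#' per-iteration objective trace and convergence bookkeeping.  Fits return
#' these; building one by hand is mainly useful to evaluate
#' \code{\link{fcm_update_membership}} / \code{\link{fcm_objective}} at
#' chosen centers.
#'
#' @param centers numeric vector of cluster centers.
#' @param fuzzifier fuzzifier r associated with the model (1 for HCM).
#' @param objective_trace numeric vector of objective values, one per
#'   completed update cycle.
#' @param iterations number of completed update cycles.
#' @param converged logical convergence flag.
#' @param method label: "hcm", "fcm", "fcm-hist" or "init".
#' @return An object of class \code{"cluster_model"}.
#' @export
new_cluster_model <- function(centers, fuzzifier = NA_real_,
                              objective_trace = numeric(0),
                              iterations = 0L, converged = NA,
                              method = "fcm") {
  structure(list(centers = as.numeric(centers), fuzzifier = fuzzifier,
                 objective_trace = objective_trace,
                 iterations = as.integer(iterations),
                 converged = converged, method = method),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model:", x$method, "> c =", length(x$centers), "\n")
  cat("  centers:", paste(format(x$centers, digits = 6), collapse = ", "), "\n")
  if (length(x$objective_trace)) {
    cat("  iterations:", x$iterations,
        if (isTRUE(x$converged)) "(converged)" else "(max_iter reached)", "\n")
    cat("  final objective:",
        format(x$objective_trace[length(x$objective_trace)]), "\n")
  }
  invisible(x)
}

# c x x matrix of squared Euclidean distances between scalar samples and
# centers.
.sqdist <- function(values, centers) {
  outer(centers, values, function(w, s) (s - w)^2)
}

# Columnwise minima of a c x x matrix (c is small; pmin beats apply here).
.col_mins <- function(d) {
  m <- d[1L, ]
  if (nrow(d) > 1L) for (i in 2L:nrow(d)) m <- pmin(m, d[i, ])
  m
}
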