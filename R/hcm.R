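#' Hard C-means (HCM) objective
#'
#' The mean-square-error criterion of hard clustering:
#' J_HCM(U, W) = sum_i sum_g mu_ig * d_ig^2, with d_ig^2 the squared
#' Euclidean distance between sample s_g and center w_i.  Defined only for
#' hard partitions.
#'
#' @param features a \code{\link{feature_set}} (or coercible).
#' @param u a \emph{hard} membership matrix (c x x).
#' @param model a \code{"cluster_model"} (or plain numeric vector of centers).
#' @return The scalar objective value.
#' @examples
#' fs <- feature_set(c(0, 10))
#' u <- one_hot(c(0, 1))
#' hcm_objective(fs, u, c(0, 10))  # 0 at the true centers
#' @export
hcm_objective <- function(features, u, model) {
  f <- as_feature_set(features)
  u <- as.matrix(u)
  centers <- if (inherits(model, "cluster_model")) model$centers
             else as.numeric(model)
  if (ncol(u) != f$x || nrow(u) != length(centers))
    stop("hcm_objective: dimension mismatch between u, features and centers",
         call. = FALSE)
  if (!is_hard_membership(u))
    stop("hcm_objective: the HCM objective is defined on hard partitions; ",
         "harden() the matrix first", call. = FALSE)
  sum(u * .sqdist(f$values, centers))
}

# Nearest-center assignment; equidistant ties go to the lowest cluster index.
.hcm_assign <- function(d) max.col(-t(d), ties.method = "first")

#' Fit hard C-means (HCM) clustering
#'
#' Alternates nearest-center assignment (ties to the lowest cluster index)
#' with per-cluster mean updates until the assignment stops changing or
#' \code{max_iter} is reached.  A cluster left empty during iteration has its
#' center relocated to the sample currently farthest from its assigned center,
#' which keeps the cluster count fixed without breaking the monotone descent
#' of the objective (an empty cluster contributes nothing to it).
#'
#' @param features a \code{\link{feature_set}} (or coercible).
#' @param config a \code{\link{fit_config}}; \code{fuzzifier} is ignored.
#' @param centers optional numeric vector of initial centers overriding
#'   \code{\link{init_centers}} (used e.g. for multi-start searches).
#' @return A list with components \code{u} (hard
#'   \code{\link{membership_matrix}}) and \code{model} (a
#'   \code{"cluster_model"} with centers, per-iteration objective trace,
#'   iteration count and convergence flag).
#' @examples
#' fit <- hcm_fit(feature_set(c(0, 0, 0, 10, 10, 10)), fit_config(c = 2))
#' fit$model$centers
#' @export
hcm_fit <- function(features, config, centers = NULL) {
  f <- as_feature_set(features)
  s <- f$values
  c <- config$c
  if (is.null(centers)) centers <- init_centers(f, config)$centers
  centers <- as.numeric(centers)
  if (length(centers) != c)
    stop("hcm_fit: length(centers) must equal config$c", call. = FALSE)

  trace <- numeric(0)
  labels_old <- NULL
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    d <- .sqdist(s, centers)
    labels <- .hcm_assign(d)
    # revive empty clusters at the sample farthest from its assigned center
    for (attempt in seq_len(c)) {
      counts <- tabulate(labels, nbins = c)
      empty <- which(counts == 0L)
      if (!length(empty)) break
      far <- which.max((s - centers[labels])^2)
      centers[empty[1L]] <- s[far]
      labels <- .hcm_assign(.sqdist(s, centers))
    }
    if (any(tabulate(labels, nbins = c) == 0L))
      stop("hcm_fit: could not populate all ", c,
           " clusters; input is degenerate for this cluster count",
           call. = FALSE)
    if (identical(labels, labels_old)) {
      converged <- TRUE
      it <- it - 1L
      break
    }
    centers <- as.vector(rowsum(s, labels, reorder = TRUE)) /
      tabulate(labels, nbins = c)
    trace <- c(trace, sum((s - centers[labels])^2))
    labels_old <- labels
  }

  u <- one_hot(labels_old - 1L, c = c)
  model <- new_cluster_model(centers = centers, fuzzifier = 1,
                             objective_trace = trace, iterations = it,
                             converged = converged, method = "hcm")
  list(u = u, model = model)
}
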