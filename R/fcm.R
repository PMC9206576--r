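# ---- internal weighted FCM engine ------------------------------------------
# The pixel-domain fit is the unit-weight case; the histogram fit passes the
# gray-level probabilities as weights.  Memberships never depend on the
# weights, so both domains share one membership routine.

# Fuzzy membership update from squared distances (c x x).  Stable form: each
# column is normalized by its minimum distance before exponentiation, so
# (d/m)^(-1/(r-1)) lies in [0, 1] and cannot overflow.  Columns containing an
# exact zero distance place unit mass on the zero-distance center(s), split
# equally when several coincide.
.fcm_membership_d <- function(d, r) {
  e <- 1 / (r - 1)
  m <- .col_mins(d)
  zero_col <- m == 0
  m[zero_col] <- 1  # placeholder; these columns are overwritten below
  q <- sweep(d, 2L, m, "/")^(-e)
  u <- sweep(q, 2L, colSums(q), "/")
  if (any(zero_col)) {
    z <- d[, zero_col, drop = FALSE] == 0
    u[, zero_col] <- sweep(z, 2L, colSums(z), "/")
  }
  u
}

.fcm_centers_w <- function(s, u, r, w = NULL) {
  ur <- u^r
  if (!is.null(w)) ur <- sweep(ur, 2L, w, "*")
  denom <- rowSums(ur)
  if (any(denom == 0))
    stop("degenerate partition: cluster ", which(denom == 0)[1L],
         " has zero total membership weight", call. = FALSE)
  as.vector(ur %*% s) / denom
}

.fcm_objective_w <- function(s, u, centers, r, w = NULL) {
  term <- u^r * .sqdist(s, centers)
  if (!is.null(w)) term <- sweep(term, 2L, w, "*")
  sum(term)
}

# Alternating optimization shared by fcm_fit and histogram_fcm_fit.  The
# objective is recorded after each full membership+center cycle, where the
# standard two-block argument guarantees monotone descent.
.fcm_engine <- function(s, centers, config, w = NULL) {
  r <- config$fuzzifier
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  u <- NULL
  while (it < config$max_iter) {
    it <- it + 1L
    u <- .fcm_membership_d(.sqdist(s, centers), r)
    new_centers <- .fcm_centers_w(s, u, r, w)
    trace <- c(trace, .fcm_objective_w(s, u, new_centers, r, w))
    delta <- max(abs(new_centers - centers))
    centers <- new_centers
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
  }
  list(u = u, centers = centers, trace = trace, iterations = it,
       converged = converged)
}

# ---- exported operations ----------------------------------------------------

#' FCM membership update
#'
#' Recomputes the fuzzy affiliation of every sample to every cluster from the
#' current centers: mu_ig = 1 / sum_k (d_ig / d_kg)^(2/(r-1)) with d the
#' Euclidean distance, when all distances to sample g are positive.  A sample
#' coinciding exactly with one or more centers receives membership 1 split
#' equally among the zero-distance centers and 0 elsewhere.  Every column
#' sums to 1.
#'
#' @param features a \code{\link{feature_set}} (or coercible).
#' @param model a \code{"cluster_model"} (or list) with \code{centers} and
#'   \code{fuzzifier} r > 1.
#' @return A \code{\link{membership_matrix}} (c x x).
#' @examples
#' fs <- feature_set(2)
#' m <- new_cluster_model(centers = c(0, 10), fuzzifier = 2)
#' fcm_update_membership(fs, m)  # (16/17, 1/17)
#' @export
fcm_update_membership <- function(features, model) {
  f <- as_feature_set(features)
  r <- model$fuzzifier
  .check_fuzzifier(r)
  membership_matrix(.fcm_membership_d(.sqdist(f$values, model$centers), r))
}

#' FCM center update
#'
#' The fuzzified weighted mean w_i = sum_g mu_ig^r s_g / sum_g mu_ig^r.
#' For a hard matrix this reduces to the per-cluster mean; a cluster with
#' all-zero memberships is a degenerate partition and raises an error.
#'
#' @param features a \code{\link{feature_set}} (or coercible).
#' @param u membership matrix (c x x).
#' @param r fuzzifier exponent (> 1).
#' @return Numeric vector of c updated centers.
#' @export
fcm_update_centers <- function(features, u, r) {
  f <- as_feature_set(features)
  u <- as.matrix(u)
  .validate_membership(u)
  .check_fuzzifier(r)
  .fcm_centers_w(f$values, u, r)
}

#' FCM objective
#'
#' J_FCM(U, W) = sum_i sum_g mu_ig^r d_ig^2, the fuzzified within-cluster
#' squared-distance criterion the alternating updates minimize.
#'
#' @inheritParams fcm_update_centers
#' @param model a \code{"cluster_model"} (or plain vector of centers; then
#'   \code{r} is taken from the model when present).
#' @param r fuzzifier; defaults to \code{model$fuzzifier}.
#' @return The scalar objective value.
#' @export
fcm_objective <- function(features, u, model, r = NULL) {
  f <- as_feature_set(features)
  u <- as.matrix(u)
  centers <- if (inherits(model, "cluster_model") || is.list(model))
    model$centers else as.numeric(model)
  if (is.null(r))
    r <- if (inherits(model, "cluster_model") || is.list(model))
      model$fuzzifier else stop("fcm_objective: supply r", call. = FALSE)
  if (ncol(u) != f$x || nrow(u) != length(centers))
    stop("fcm_objective: dimension mismatch", call. = FALSE)
  .fcm_objective_w(f$values, u, centers, r)
}

#' Fit fuzzy C-means (FCM) clustering
#'
#' Alternates the membership update (\code{\link{fcm_update_membership}}) and
#' center update (\code{\link{fcm_update_centers}}) from
#' \code{\link{init_centers}} until the maximum absolute center change falls
#' below \code{config$tol} or \code{config$max_iter} cycles.  The objective
#' trace is recorded once per cycle and is non-increasing; the fit is
#' deterministic given the config (and seed, for random init).
#'
#' @param features a \code{\link{feature_set}} (or coercible).
#' @param config a \code{\link{fit_config}} with \code{fuzzifier} r > 1.
#' @param centers optional numeric vector of initial centers overriding
#'   \code{\link{init_centers}}.
#' @return A list with components \code{u} (fuzzy
#'   \code{\link{membership_matrix}}) and \code{model} (a
#'   \code{"cluster_model"}).
#' @examples
#' fit <- fcm_fit(feature_set(c(0, 0, 0, 10, 10, 10)),
#'                fit_config(c = 2, fuzzifier = 2))
#' round(fit$model$centers, 3)
#' @export
fcm_fit <- function(features, config, centers = NULL) {
  f <- as_feature_set(features)
  .check_fuzzifier(config$fuzzifier)
  if (is.null(centers)) centers <- init_centers(f, config)$centers
  centers <- as.numeric(centers)
  if (length(centers) != config$c)
    stop("fcm_fit: length(centers) must equal config$c", call. = FALSE)
  res <- .fcm_engine(f$values, centers, config)
  model <- new_cluster_model(centers = res$centers,
                             fuzzifier = config$fuzzifier,
                             objective_trace = res$trace,
                             iterations = res$iterations,
                             converged = res$converged, method = "fcm")
  list(u = membership_matrix(res$u), model = model)
}

#' Soft membership relaxation of a crisp clustering
#'
#' Computes Eq.-11-style fuzzy memberships at a fixed set of centers (by
#' default with fuzzifier r = 2).  Used to report validity indices for HCM on
#' a comparable footing with FCM: a hard partition trivially has partition
#' coefficient 1 and entropy 0, so crispness around the \emph{HCM centers} is
#' what a soft index can meaningfully measure.
#'
#' @param features a \code{\link{feature_set}} (or coercible).
#' @param centers numeric vector of cluster centers (or a
#'   \code{"cluster_model"}).
#' @param r fuzzifier for the relaxation (default 2).
#' @return A fuzzy \code{\link{membership_matrix}}.
#' @export
soft_membership <- function(features, centers, r = 2) {
  if (inherits(centers, "cluster_model")) centers <- centers$centers
  f <- as_feature_set(features)
  .check_fuzzifier(r)
  membership_matrix(.fcm_membership_d(.sqdist(f$values, centers), r))
}
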