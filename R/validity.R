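#' Partition coefficient (V_pc)
#'
#' Bezdek's crispness index V_pc = (1/x) sum_i sum_g mu_ig^2, in [1/c, 1]:
#' 1 exactly for hard partitions, 1/c for the maximally fuzzy uniform
#' partition.  Invariant under permutation of the cluster rows.
#'
#' @param u membership matrix (c x x).
#' @return Scalar in [1/c, 1].
#' @examples
#' partition_coefficient(rbind(c(0.8, 0.5), c(0.2, 0.5)))  # 0.59
#' @export
partition_coefficient <- function(u) {
  u <- as.matrix(u)
  .validate_membership(u)
  sum(u^2) / ncol(u)
}

#' Partition entropy (V_pe)
#'
#' Bezdek's fuzziness index V_pe = -(1/x) sum_i sum_g mu_ig ln(mu_ig) with
#' the convention 0 ln 0 = 0, in [0, ln c]: 0 exactly for hard partitions,
#' ln c for the uniform partition.
#'
#' @param u membership matrix (c x x).
#' @return Scalar in [0, ln c].
#' @export
partition_entropy <- function(u) {
  u <- as.matrix(u)
  .validate_membership(u)
  pos <- u > 0
  -sum(u[pos] * log(u[pos])) / ncol(u)
}

#' Validity report for a membership matrix
#'
#' Bundles the partition coefficient and partition entropy with the partition
#' dimensions.  For a crisp (HCM) result these are trivially 1 and 0; pass
#' the \code{\link{soft_membership}} relaxation instead to measure crispness
#' around the hard centers on a footing comparable with FCM.
#'
#' @param u membership matrix (c x x).
#' @return An object of class \code{"validity_report"}: list with
#'   \code{partition_coefficient}, \code{partition_entropy}, \code{c},
#'   \code{x}.
#' @export
validity_report <- function(u) {
  u <- as.matrix(u)
  .validate_membership(u)
  structure(list(partition_coefficient = partition_coefficient(u),
                 partition_entropy = partition_entropy(u),
                 c = nrow(u), x = ncol(u)),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("<validity_report> c =", x$c, " x =", x$x, "\n")
  cat("  partition coefficient:", format(x$partition_coefficient), "\n")
  cat("  partition entropy:    ", format(x$partition_entropy), "\n")
  invisible(x)
}
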