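#' Assemble and validate a tape-strip dataset
#'
#' A tape-strip experiment removes the stratum corneum with 70 sequential
#' adhesive strips, pooled two per microtube (35 tubes), each tube assayed
#' for drug amount. Each strip removes 0.5-1 um of tissue, so the full
#' series spans a stripped depth of 0.0035-0.0070 cm.
#'
#' @param data Data frame with columns \code{tube_index} (1..n_tubes,
#'   contiguous within each replicate), \code{amount_mg} (>= 0), and
#'   optionally \code{replicate}.
#' @param n_tubes Expected number of microtubes.
#' @return The validated data frame with class \code{tape_strip_dataset}.
#' @export
tape_strip_dataset <- function(data, n_tubes = 35L) {
  stopifnot(is.data.frame(data),
            all(c("tube_index", "amount_mg") %in% names(data)))
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  if (any(!is.finite(data$amount_mg)) || any(data$amount_mg < 0)) {
    stop("strip amounts must be finite and non-negative", call. = FALSE)
  }
  for (r in unique(data$replicate)) {
    tubes <- sort(data$tube_index[data$replicate == r])
    if (anyDuplicated(tubes)) {
      stop("duplicate tube index in replicate ", r, call. = FALSE)
    }
    if (!identical(as.integer(tubes), seq_len(n_tubes))) {
      stop("replicate ", r, " must contain tubes 1..", n_tubes,
           " exactly once", call. = FALSE)
    }
  }
  data <- data[order(data$replicate, data$tube_index), ]
  rownames(data) <- NULL
  class(data) <- c("tape_strip_dataset", "data.frame")
  data
}

#' Total drug retained in the strips
#'
#' Sums the per-tube amounts within each replicate and averages across
#' replicates, reporting the standard deviation when several replicates are
#' present.
#'
#' @param dataset A \code{\link{tape_strip_dataset}} (or a data frame
#'   accepted by it).
#' @return List with \code{total} (mean across replicates, mg), \code{sd},
#'   \code{n_replicates}, and the per-replicate \code{totals}.
#' @export
validate_and_total <- function(dataset) {
  if (!inherits(dataset, "tape_strip_dataset")) {
    dataset <- tape_strip_dataset(dataset,
                                  n_tubes = max(dataset$tube_index))
  }
  totals <- tapply(dataset$amount_mg, dataset$replicate, sum)
  list(total = mean(totals),
       sd = if (length(totals) > 1L) stats::sd(totals) else NA_real_,
       n_replicates = length(totals),
       totals = as.numeric(totals))
}

#' Depth profile of a tape-strip dataset
#'
#' Tube k pools strips 2k-1 and 2k, so its cumulative stripped depth lies
#' between 2k x 0.5 um and 2k x 1 um. Amounts are averaged across
#' replicates.
#'
#' @param dataset A \code{\link{tape_strip_dataset}}.
#' @param strip_thickness_bounds_um Per-strip thickness bounds, um.
#' @param strips_per_tube Strips pooled per microtube.
#' @return Data frame with \code{tube_index}, cumulative
#'   \code{depth_lower_cm} / \code{depth_upper_cm}, \code{amount_mg} (mean)
#'   and \code{amount_sd_mg}.
#' @export
depth_profile <- function(dataset, strip_thickness_bounds_um = c(0.5, 1.0),
                          strips_per_tube = 2L) {
  if (!inherits(dataset, "tape_strip_dataset")) {
    dataset <- tape_strip_dataset(dataset, n_tubes = max(dataset$tube_index))
  }
  mean_amt <- tapply(dataset$amount_mg, dataset$tube_index, mean)
  sd_amt <- tapply(dataset$amount_mg, dataset$tube_index, stats::sd)
  k <- as.integer(names(mean_amt))
  um_to_cm <- 1e-4
  data.frame(
    tube_index = k,
    depth_lower_cm = k * strips_per_tube * strip_thickness_bounds_um[1] * um_to_cm,
    depth_upper_cm = k * strips_per_tube * strip_thickness_bounds_um[2] * um_to_cm,
    amount_mg = as.numeric(mean_amt),
    amount_sd_mg = as.numeric(sd_amt)
  )
}
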