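# Region- / network-stratified SPICE testing with Bonferroni correction.

#' Bonferroni-adjusted significance threshold
#'
#' Returns `alpha / m`, the threshold against which raw p-values are compared
#' when `m` comparisons are declared. The division is kept at full precision;
#' rounding (e.g. 0.05/16 = 0.003125 displayed as 0.003) is a display
#' decision left to the caller.
#'
#' @param alpha Nominal level, in (0, 1).
#' @param m Declared number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 16)  # 0.003125
#' bonferroni_threshold(0.05, 7)   # 0.00714...
bonferroni_threshold <- function(alpha, m) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 1) {
    stop("'m' must be a comparison count >= 1", call. = FALSE)
  }
  alpha / m
}

#' Region-stratified SPICE tests
#'
#' Runs one SPICE test per requested region: both modalities are restricted
#' to the region's masked-in locations and [spice_test()] is run on the
#' restricted dataset. Each region gets its own deterministic permutation
#' stream, seeded by `spawn_seed(seed, label)`, so any region can be re-run
#' in isolation and results do not depend on which other regions were
#' requested. Regions with fewer than 3 usable locations are reported as
#' skipped (with a reason), never silently dropped.
#'
#' The returned table carries the Bonferroni threshold `alpha / m`, where `m`
#' defaults to the number of tests actually run; studies with a different
#' multiplicity declaration (e.g. correcting across age groups rather than
#' regions) should pass `m_comparisons` explicitly. Raw p-values are always
#' reported alongside so alternative corrections can be applied.
#'
#' @param data A [modality_dataset()].
#' @param labels A [region_labels()] object (or integer vector) aligned with
#'   the dataset's locations.
#' @param regions Integer vector of label values to test; default: all
#'   nonzero labels present.
#' @param measure,k,sidedness Passed to [spice_test()].
#' @param seed Master seed for region-stream spawning.
#' @param alpha Nominal level for the Bonferroni threshold.
#' @param m_comparisons Declared comparison count; default: number of tested
#'   regions.
#' @return A `data.frame` of class `spice_by_region` with one row per
#'   requested region: `region`, `label`, `n_locations`, `a0`, `p_value`,
#'   `threshold`, `k_permutations`, `seed`, `skipped`, `reason`.
#' @export
spice_by_region <- function(data, labels, regions = NULL,
                            measure = c("pearson", "spearman"), k = 999L,
                            seed = 1L, alpha = 0.05, m_comparisons = NULL,
                            sidedness = c("two_sided", "greater")) {
  measure <- match.arg(measure)
  sidedness <- match.arg(sidedness)
  stopifnot(inherits(data, "modality_dataset"))
  if (!inherits(labels, "region_labels")) labels <- region_labels(labels)
  v <- ncol(data$x)
  if (length(labels$labels) != v) {
    stop(sprintf("labels cover %d locations but the dataset has %d",
                 length(labels$labels), v), call. = FALSE)
  }
  present <- sort(unique(labels$labels[labels$labels != 0L]))
  if (is.null(regions)) {
    regions <- present
    if (length(regions) == 0L) {
      stop("all locations are unassigned (label 0); no regions to test",
           call. = FALSE)
    }
  } else {
    regions <- as.integer(regions)
    unknown <- setdiff(regions, present)
    if (length(unknown) > 0L) {
      stop("unknown region label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }

  keep_mask <- if (is.null(data$mask)) rep(TRUE, v) else data$mask
  m <- m_comparisons %||% length(regions)
  threshold <- bonferroni_threshold(alpha, m)

  rows <- lapply(regions, function(lab) {
    nm <- unname(labels$names[as.character(lab)])
    idx <- which(labels$labels == lab & keep_mask)
    region_seed <- spawn_seed(seed, lab)
    row <- data.frame(
      region = nm, label = lab, n_locations = length(idx),
      a0 = NA_real_, p_value = NA_real_, threshold = threshold,
      k_permutations = as.integer(k), seed = region_seed,
      skipped = FALSE, reason = "", stringsAsFactors = FALSE
    )
    if (length(idx) < 3L) {
      row$skipped <- TRUE
      row$reason <- if (length(idx) == 0L) {
        "empty region after masking"
      } else {
        sprintf("only %d masked-in location(s); at least 3 required", length(idx))
      }
      return(row)
    }
    sub <- modality_dataset(data$x[, idx, drop = FALSE],
                            data$y[, idx, drop = FALSE],
                            subject_ids = data$subject_ids)
    res <- spice_test(sub, measure = measure, k = k, seed = region_seed,
                      sidedness = sidedness)
    row$a0 <- res$a0
    row$p_value <- res$p_value
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "m_comparisons") <- m
  class(out) <- c("spice_by_region", "data.frame")
  out
}

#' @export
print.spice_by_region <- function(x, ...) {
  cat(sprintf("Region-stratified SPICE tests (alpha = %g, m = %d, threshold = %.6g)\n",
              attr(x, "alpha"), attr(x, "m_comparisons"), x$threshold[1L]))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
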