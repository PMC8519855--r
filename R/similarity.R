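#' Intermodal similarity between two maps
#'
#' Computes the spatial similarity psi between two aligned per-location
#' intensity vectors, over masked-in locations only. Two measures are
#' supported: the Pearson correlation across locations (the conventional
#' choice for intermodal correspondence) and the Spearman rank correlation
#' (more robust to monotone nonlinear relationships; ties receive average
#' ranks).
#'
#' Degenerate inputs are an error, never a silent `NA` or 0: a zero-variance
#' vector has no defined correlation, and returning a placeholder would let a
#' broken map bias a permutation null undetected.
#'
#' @param x,y Numeric vectors of equal length `V` (per-location intensities).
#' @param measure `"pearson"` (default) or `"spearman"`.
#' @param mask Optional logical vector of length `V`; only `TRUE` locations
#'   enter the computation.
#' @return A scalar in `[-1, 1]`.
#' @export
#' @examples
#' intermodal_similarity(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
intermodal_similarity <- function(x, y, measure = c("pearson", "spearman"),
                                  mask = NULL) {
  measure <- match.arg(measure)
  if (length(x) != length(y)) {
    stop(sprintf("'x' (length %d) and 'y' (length %d) must have equal length",
                 length(x), length(y)), call. = FALSE)
  }
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != length(x)) {
      stop("'mask' must have the same length as 'x' and 'y'", call. = FALSE)
    }
    if (!any(mask)) stop("all locations are masked out", call. = FALSE)
    x <- x[mask]
    y <- y[mask]
  }
  if (length(x) < 3L) {
    stop("at least 3 masked-in locations are required", call. = FALSE)
  }
  for (nm in c("x", "y")) {
    v <- if (nm == "x") x else y
    if (any(!is.finite(v))) {
      stop(sprintf("non-finite value in '%s' among masked-in locations", nm),
           call. = FALSE)
    }
    if (stats::var(v) == 0) {
      stop(sprintf("zero variance in '%s' over masked-in locations; similarity is undefined", nm),
           call. = FALSE)
    }
  }
  # The sample Pearson correlation over locations (Spearman = Pearson on
  # average ranks). Published renderings of this formula are sometimes
  # garbled in the denominator; the standard sample correlation is the
  # intended quantity and is what stats::cor computes.
  stats::cor(x, y, method = measure)
}

#' Mean within-subject intermodal similarity (the observed statistic)
#'
#' The SPICE test statistic A0: the arithmetic mean over subjects of the
#' intermodal similarity between subject i's map in modality X and the same
#' subject's map in modality Y.
#'
#' @param data A [modality_dataset()].
#' @param measure `"pearson"` (default) or `"spearman"`.
#' @return A scalar in `[-1, 1]`.
#' @export
#' @examples
#' x <- matrix(rnorm(40), 4, 10)
#' mean_within_subject(modality_dataset(x, x))  # exactly 1
mean_within_subject <- function(data, measure = c("pearson", "spearman")) {
  measure <- match.arg(measure)
  stopifnot(inherits(data, "modality_dataset"))
  keep <- active_locations(data)
  vals <- vapply(seq_len(nrow(data$x)), function(i) {
    tryCatch(
      intermodal_similarity(data$x[i, keep], data$y[i, keep], measure = measure),
      error = function(e) {
        stop(sprintf("subject %s: %s", data$subject_ids[i], conditionMessage(e)),
             call. = FALSE)
      }
    )
  }, numeric(1))
  mean(vals)
}
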