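#' Construct an aligned two-modality dataset
#'
#' Bundles the subject-by-location intensity matrices of two imaging
#' modalities, subject identifiers, and an optional location mask into a
#' validated container. Row `i` of `x` and row `i` of `y` must belong to the
#' same subject; columns index locations (e.g. vertices of a common surface
#' template) and must be aligned across modalities. No resampling is done:
#' both modalities are assumed to live in the same space already.
#'
#' Validation enforces:
#' * `x` and `y` have identical dimensions, with at least 2 subjects;
#' * at least 3 locations survive the mask;
#' * all masked-in values are finite (non-finite values outside the mask are
#'   permitted and ignored downstream). Non-finite values inside the mask are
#'   an error rather than being dropped silently, because dropping them
#'   per-vector would let the two modalities be correlated over different
#'   location sets;
#' * subject identifiers are unique (duplicates would corrupt the permutation
#'   null, which relies on subjects being distinct exchangeable units).
#'
#' @param x,y Numeric matrices, `n` subjects by `V` locations.
#' @param subject_ids Character or integer vector of length `n`; defaults to
#'   `"subj1" ... "subjn"`.
#' @param mask Optional logical vector of length `V`; `TRUE` marks locations
#'   included in analysis (e.g. `FALSE` over the medial wall). Default: all
#'   locations included.
#' @return An object of class `modality_dataset`: a list with elements
#'   `x`, `y`, `subject_ids`, `mask`.
#' @export
#' @examples
#' x <- matrix(rnorm(20), 4, 5)
#' y <- x + matrix(rnorm(20, sd = 0.1), 4, 5)
#' modality_dataset(x, y)
modality_dataset <- function(x, y, subject_ids = NULL, mask = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("'x' and 'y' must be numeric matrices", call. = FALSE)
  }
  if (!identical(dim(x), dim(y))) {
    stop(sprintf("'x' (%d x %d) and 'y' (%d x %d) must have identical dimensions",
                 nrow(x), ncol(x), nrow(y), ncol(y)), call. = FALSE)
  }
  n <- nrow(x)
  v <- ncol(x)
  if (n < 2L) stop("at least 2 subjects are required", call. = FALSE)

  if (is.null(subject_ids)) subject_ids <- paste0("subj", seq_len(n))
  if (length(subject_ids) != n) {
    stop(sprintf("'subject_ids' has length %d but there are %d subjects",
                 length(subject_ids), n), call. = FALSE)
  }
  if (anyDuplicated(subject_ids)) {
    dup <- unique(subject_ids[duplicated(subject_ids)])
    stop("duplicate subject_ids: ", paste(dup, collapse = ", "),
         " (duplicated subjects would corrupt the permutation null)",
         call. = FALSE)
  }

  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != v) {
      stop(sprintf("'mask' has length %d but there are %d locations",
                   length(mask), v), call. = FALSE)
    }
    if (anyNA(mask)) stop("'mask' must not contain NA", call. = FALSE)
  }
  keep <- if (is.null(mask)) rep(TRUE, v) else mask
  if (sum(keep) < 3L) {
    stop(sprintf("only %d location(s) survive the mask; at least 3 are required",
                 sum(keep)), call. = FALSE)
  }
  for (mod in c("x", "y")) {
    m <- if (mod == "x") x else y
    bad <- which(!is.finite(m[, keep, drop = FALSE]), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      i <- bad[1L, 1L]
      stop(sprintf("non-finite value inside the mask in modality '%s' (subject %s)",
                   mod, subject_ids[i]), call. = FALSE)
    }
  }

  structure(
    list(x = x, y = y, subject_ids = as.character(subject_ids), mask = mask),
    class = "modality_dataset"
  )
}

#' @export
print.modality_dataset <- function(x, ...) {
  v <- ncol(x$x)
  v_eff <- if (is.null(x$mask)) v else sum(x$mask)
  cat("Two-modality dataset:", nrow(x$x), "subjects x", v, "locations")
  if (v_eff < v) cat(" (", v_eff, " masked-in)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.modality_dataset <- function(x) dim(x$x)

# Indices of masked-in locations.
active_locations <- function(data) {
  if (is.null(data$mask)) seq_len(ncol(data$x)) else which(data$mask)
}
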