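# Parcellation / network labels per location, with readers and writers for
# delimited text, GIFTI label files and FreeSurfer .annot.

#' Construct per-location region labels
#'
#' Integer labels map locations to parcels or networks for region-stratified
#' testing; label 0 is the conventional sentinel for unassigned locations
#' (e.g. the medial wall) and is never treated as a region.
#'
#' @param labels Integer vector, one label per location.
#' @param names Optional named character vector mapping label values
#'   (as names) to region names. Defaults to `"region_<label>"` for every
#'   nonzero label.
#' @return An object of class `region_labels`: list with `labels` and
#'   `names`.
#' @export
#' @examples
#' region_labels(c(0L, 1L, 1L, 2L), names = c(`1` = "visual", `2` = "motor"))
region_labels <- function(labels, names = NULL) {
  if (any(!is.finite(labels)) || any(labels != round(labels))) {
    stop("'labels' must be finite integers", call. = FALSE)
  }
  labels <- as.integer(labels)
  present <- sort(unique(labels[labels != 0L]))
  if (is.null(names)) {
    names <- stats::setNames(sprintf("region_%d", present), as.character(present))
  } else {
    names <- stats::setNames(as.character(names), names(names))
    missing <- setdiff(as.character(present), names(names))
    if (length(missing) > 0L) {
      names[missing] <- sprintf("region_%s", missing)
    }
  }
  structure(list(labels = labels, names = names), class = "region_labels")
}

#' @export
print.region_labels <- function(x, ...) {
  present <- sort(unique(x$labels[x$labels != 0L]))
  cat(sprintf("Region labels over %d locations: %d region(s), %d unassigned\n",
              length(x$labels), length(present), sum(x$labels == 0L)))
  invisible(x)
}

# ---- FreeSurfer .annot (version -2 colortable) -----------------------------

# Label values are packed into the annotation color code
# (code = r + g*256 + b*65536) so the label partition round-trips exactly.
label_to_code <- function(lab) {
  r <- lab %% 256L
  g <- (lab %/% 256L) %% 256L
  b <- (lab %/% 65536L) %% 256L
  list(r = r, g = g, b = b, code = r + g * 256L + b * 65536L)
}

write_fs_string <- function(con, s) {
  chars <- charToRaw(s)
  writeBin(length(chars) + 1L, con, size = 4L, endian = "big")
  writeBin(c(chars, as.raw(0L)), con)
}

read_fs_string <- function(con) {
  len <- readBin(con, integer(), size = 4L, endian = "big")
  chars <- readBin(con, raw(), n = len)
  rawToChar(chars[chars != as.raw(0L)])
}

write_annot <- function(rl, path) {
  entries <- sort(unique(rl$labels))
  con <- file(path, "wb")
  on.exit(close(con))
  v <- length(rl$labels)
  codes <- label_to_code(rl$labels)$code
  writeBin(v, con, size = 4L, endian = "big")
  inter <- integer(2L * v) # (vertex index, code) interleaved, 0-based vertices
  inter[seq(1L, 2L * v, by = 2L)] <- seq_len(v) - 1L
  inter[seq(2L, 2L * v, by = 2L)] <- codes
  writeBin(inter, con, size = 4L, endian = "big")
  writeBin(1L, con, size = 4L, endian = "big")  # colortable present
  writeBin(-2L, con, size = 4L, endian = "big") # colortable version
  writeBin(length(entries), con, size = 4L, endian = "big")
  write_fs_string(con, "synthetic.ctab")
  writeBin(length(entries), con, size = 4L, endian = "big")
  for (i in seq_along(entries)) {
    lab <- entries[i]
    nm <- if (lab == 0L) "unassigned" else unname(rl$names[as.character(lab)])
    cc <- label_to_code(lab)
    writeBin(i - 1L, con, size = 4L, endian = "big") # structure index
    write_fs_string(con, nm)
    writeBin(c(cc$r, cc$g, cc$b, 0L), con, size = 4L, endian = "big")
  }
  invisible(path)
}

read_annot <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, integer(), size = 4L, endian = "big")
  if (!length(v) || is.na(v) || v <= 0L) {
    stop(sprintf("'%s' is not a readable annotation file", path), call. = FALSE)
  }
  inter <- readBin(con, integer(), n = 2L * v, size = 4L, endian = "big")
  vert <- inter[seq(1L, 2L * v, by = 2L)]
  codes <- inter[seq(2L, 2L * v, by = 2L)]
  codes <- codes[order(vert)]
  has_ctab <- readBin(con, integer(), size = 4L, endian = "big")
  code_to_lab <- NULL
  nm <- character(0)
  if (length(has_ctab) && !is.na(has_ctab) && has_ctab != 0L) {
    version <- readBin(con, integer(), size = 4L, endian = "big")
    if (version >= 0L) {
      stop(sprintf("'%s' uses the original colortable format; only version -2 is supported",
                   path), call. = FALSE)
    }
    readBin(con, integer(), size = 4L, endian = "big") # declared max entries
    read_fs_string(con)                                # colortable filename
    n_entries <- readBin(con, integer(), size = 4L, endian = "big")
    code_to_lab <- integer(0)
    for (i in seq_len(n_entries)) {
      readBin(con, integer(), size = 4L, endian = "big") # structure index
      name_i <- read_fs_string(con)
      rgba <- readBin(con, integer(), n = 4L, size = 4L, endian = "big")
      code <- rgba[1L] + rgba[2L] * 256L + rgba[3L] * 65536L
      lab <- code # color packing encodes the label value
      code_to_lab[as.character(code)] <- lab
      if (lab != 0L) nm[as.character(lab)] <- name_i
    }
  }
  labels <- if (is.null(code_to_lab)) {
    codes
  } else {
    out <- code_to_lab[as.character(codes)]
    if (anyNA(out)) {
      stop(sprintf("'%s' contains annotation codes absent from its colortable", path),
           call. = FALSE)
    }
    unname(out)
  }
  region_labels(labels, names = if (length(nm)) nm else NULL)
}

# ---- user-facing label I/O -------------------------------------------------

#' Read per-location region labels
#'
#' @param path File path.
#' @param format `"auto"` (guess from extension), `"delimited"` (integers
#'   separated by newlines, commas or whitespace), `"gifti_label"` (GIFTI
#'   with a LabelTable), or `"freesurfer_annot"`.
#' @param names Optional named character vector of region names keyed by
#'   label value; overrides names found in the file.
#' @return A [region_labels()] object.
#' @export
read_labels <- function(path,
                        format = c("auto", "delimited", "gifti_label",
                                   "freesurfer_annot"),
                        names = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  if (format == "auto") format <- guess_format(path, "labels")
  if (format == "delimited") {
    vals <- read_delimited_vector(path)
    return(region_labels(vals, names = names))
  }
  if (format == "freesurfer_annot") {
    rl <- read_annot(path)
    if (!is.null(names)) rl <- region_labels(rl$labels, names = names)
    return(rl)
  }
  g <- read_gifti_arrays(path)
  if (length(g$arrays) != 1L) {
    stop(sprintf("'%s' holds %d data arrays; expected a single label map",
                 path, length(g$arrays)), call. = FALSE)
  }
  labels <- as.integer(gifti_decode_data(g$arrays[[1L]], path))
  if (is.null(names)) {
    label_nodes <- xml2::xml_find_all(g$doc, ".//LabelTable/Label")
    if (length(label_nodes) > 0L) {
      keys <- xml2::xml_attr(label_nodes, "Key")
      vals <- xml2::xml_text(label_nodes)
      keep <- keys != "0"
      if (any(keep)) names <- stats::setNames(vals[keep], keys[keep])
    }
  }
  region_labels(labels, names = names)
}

#' Write per-location region labels
#'
#' @param rl A [region_labels()] object (or an integer vector).
#' @param path Output path.
#' @param format As in [read_labels()]; `"auto"` guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_labels <- function(rl, path,
                         format = c("auto", "delimited", "gifti_label",
                                    "freesurfer_annot")) {
  format <- match.arg(format)
  if (!inherits(rl, "region_labels")) rl <- region_labels(rl)
  if (format == "auto") format <- guess_format(path, "labels")
  switch(format,
    delimited = writeLines(as.character(rl$labels), path),
    freesurfer_annot = write_annot(rl, path),
    gifti_label = {
      present <- sort(unique(rl$labels))
      lt <- lapply(present, function(lab) {
        if (lab == 0L) "unassigned" else unname(rl$names[as.character(lab)])
      })
      names(lt) <- as.character(present)
      writeLines(gifti_xml(rl$labels, "NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32",
                           label_table = lt), path)
    }
  )
  invisible(path)
}
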