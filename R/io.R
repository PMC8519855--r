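# Readers and writers for per-location surface data.
#
# Three formats are supported for subject maps: GIFTI functional data
# (XML with base64-encoded arrays), FreeSurfer per-vertex morphometry
# ("curv" binary: 0xFFFFFF magic, big-endian 32-bit floats), and delimited
# text. Labels additionally support GIFTI label files (with a LabelTable)
# and FreeSurfer .annot (version -2 colortable). File order defines location
# identity; both modalities must come from the same surface space, and no
# resampling is performed.

guess_format <- function(path, kind = c("map", "labels")) {
  kind <- match.arg(kind)
  lower <- tolower(path)
  if (grepl("\\.gii$", lower)) {
    if (kind == "labels" || grepl("\\.label\\.gii$", lower)) {
      if (kind == "labels") return("gifti_label")
    }
    return(if (kind == "map") "gifti_func" else "gifti_label")
  }
  if (grepl("\\.annot$", lower)) return("freesurfer_annot")
  if (grepl("\\.(curv|sulc|thickness|area|volume)$", lower)) {
    return("freesurfer_morph")
  }
  if (grepl("\\.(txt|csv|tsv|asc|dat)$", lower)) return("delimited")
  stop(sprintf("cannot guess format of '%s'; pass 'format' explicitly", path),
       call. = FALSE)
}

# ---- delimited -------------------------------------------------------------

read_delimited_vector <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  vals <- scan(text = gsub("[,;]", " ", paste(txt, collapse = " ")),
               what = numeric(), quiet = TRUE)
  if (length(vals) == 0L) {
    stop(sprintf("no numeric values found in '%s'", path), call. = FALSE)
  }
  vals
}

#' Read a subjects-as-rows map matrix from a delimited file
#'
#' Expects a header row naming locations and one row per subject; separators
#' are auto-detected among tab, comma and whitespace.
#'
#' @param path File path.
#' @return A numeric matrix (subjects x locations).
#' @export
read_map_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop(sprintf("'%s' contains non-numeric columns", path),
                           call. = FALSE)
  m
}

#' Write a subjects-as-rows map matrix as TSV with header
#'
#' @param m Numeric matrix (subjects x locations).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_matrix <- function(m, path) {
  m <- as.matrix(m)
  colnames(m) <- colnames(m) %||% paste0("v", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- GIFTI -----------------------------------------------------------------

gifti_decode_data <- function(node, path) {
  dtype <- xml2::xml_attr(node, "DataType")
  enc <- xml2::xml_attr(node, "Encoding")
  endian <- tolower(xml2::xml_attr(node, "Endian") %||% "LittleEndian")
  endian <- if (identical(endian, "bigendian")) "big" else "little"
  n <- as.integer(xml2::xml_attr(node, "Dim0"))
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(data_node)
  if (identical(enc, "ASCII")) {
    vals <- scan(text = txt, what = numeric(), quiet = TRUE)
  } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
    raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
    if (identical(enc, "GZipBase64Binary")) raw <- memDecompress(raw, type = "gzip")
    vals <- switch(dtype,
      "NIFTI_TYPE_FLOAT32" = readBin(raw, numeric(), n = n, size = 4L, endian = endian),
      "NIFTI_TYPE_FLOAT64" = readBin(raw, numeric(), n = n, size = 8L, endian = endian),
      "NIFTI_TYPE_INT32" = readBin(raw, integer(), n = n, size = 4L, endian = endian),
      "NIFTI_TYPE_UINT8" = as.integer(readBin(raw, integer(), n = n, size = 1L,
                                              signed = FALSE)),
      stop(sprintf("unsupported GIFTI DataType '%s' in '%s'", dtype, path),
           call. = FALSE)
    )
  } else {
    stop(sprintf("unsupported GIFTI Encoding '%s' in '%s'", enc, path),
         call. = FALSE)
  }
  if (!is.na(n) && length(vals) != n) {
    stop(sprintf("GIFTI data array in '%s' has %d values but Dim0 = %d",
                 path, length(vals), n), call. = FALSE)
  }
  vals
}

read_gifti_arrays <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("'%s' is not parseable XML/GIFTI: %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!identical(xml2::xml_name(doc), "GIFTI")) {
    stop(sprintf("'%s' is XML but not a GIFTI document (root <%s>)",
                 path, xml2::xml_name(doc)), call. = FALSE)
  }
  list(doc = doc, arrays = xml2::xml_find_all(doc, ".//DataArray"))
}

gifti_xml <- function(values, intent, dtype, label_table = NULL) {
  v <- length(values)
  payload <- switch(dtype,
    "NIFTI_TYPE_FLOAT32" = writeBin(as.numeric(values), raw(), size = 4L,
                                    endian = "little"),
    "NIFTI_TYPE_INT32" = writeBin(as.integer(values), raw(), size = 4L,
                                  endian = "little")
  )
  b64 <- jsonlite::base64_enc(payload)
  lt <- ""
  if (!is.null(label_table)) {
    entries <- vapply(seq_along(label_table), function(i) {
      sprintf('      <Label Key="%s"><![CDATA[%s]]></Label>',
              names(label_table)[i], label_table[[i]])
    }, character(1))
    lt <- paste0("   <LabelTable>\n", paste(entries, collapse = "\n"),
                 "\n   </LabelTable>\n")
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="1">\n', lt,
    sprintf(paste0('   <DataArray Intent="%s" DataType="%s"',
                   ' ArrayIndexingOrder="RowMajorOrder" Dimensionality="1"',
                   ' Dim0="%d" Encoding="Base64Binary" Endian="LittleEndian"',
                   ' ExternalFileName="" ExternalFileOffset="">\n'),
            intent, dtype, v),
    "      <Data>", b64, "</Data>\n",
    "   </DataArray>\n</GIFTI>\n"
  )
}

# ---- FreeSurfer curv -------------------------------------------------------

CURV_MAGIC <- as.raw(c(0xff, 0xff, 0xff))

read_curv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), n = 3L)
  if (!identical(magic, CURV_MAGIC)) {
    stop(sprintf("'%s' lacks the morphometry magic bytes (old-format or not a curv file)",
                 path), call. = FALSE)
  }
  vnum <- readBin(con, integer(), size = 4L, endian = "big")
  readBin(con, integer(), n = 2L, size = 4L, endian = "big") # fnum, vals/vertex
  vals <- readBin(con, numeric(), n = vnum, size = 4L, endian = "big")
  if (length(vals) != vnum) {
    stop(sprintf("'%s' is truncated: header promises %d values, found %d",
                 path, vnum, length(vals)), call. = FALSE)
  }
  vals
}

write_curv <- function(values, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(CURV_MAGIC, con)
  writeBin(c(length(values), 0L, 1L), con, size = 4L, endian = "big")
  writeBin(as.numeric(values), con, size = 4L, endian = "big")
  invisible(path)
}

# ---- subject maps ----------------------------------------------------------

#' Read a single subject's per-location map
#'
#' Values are returned in file order (file order defines location identity);
#' non-finite values are preserved as read — masking happens downstream in
#' [modality_dataset()].
#'
#' @param path File path.
#' @param format One of `"auto"` (guess from the extension), `"delimited"`
#'   (one value per line, or comma/whitespace separated), `"gifti_func"`
#'   (single-data-array GIFTI), `"freesurfer_morph"` (curv binary).
#' @return Numeric vector of per-location intensities.
#' @export
read_subject_map <- function(path,
                             format = c("auto", "delimited", "gifti_func",
                                        "freesurfer_morph")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  if (format == "auto") format <- guess_format(path, "map")
  switch(format,
    delimited = read_delimited_vector(path),
    freesurfer_morph = read_curv(path),
    gifti_func = {
      g <- read_gifti_arrays(path)
      if (length(g$arrays) != 1L) {
        stop(sprintf("'%s' holds %d data arrays; expected a single map per file",
                     path, length(g$arrays)), call. = FALSE)
      }
      as.numeric(gifti_decode_data(g$arrays[[1L]], path))
    }
  )
}

#' Write a single subject's per-location map
#'
#' @param values Numeric vector of per-location intensities.
#' @param path Output path.
#' @param format As in [read_subject_map()]; `"auto"` guesses from the
#'   extension. GIFTI and curv store 32-bit floats, so round trips are exact
#'   only to single precision (~1e-7 relative).
#' @return `path`, invisibly.
#' @export
write_subject_map <- function(values,
                              path,
                              format = c("auto", "delimited", "gifti_func",
                                         "freesurfer_morph")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path, "map")
  values <- as.numeric(values)
  switch(format,
    delimited = writeLines(format(values, digits = 17, trim = TRUE,
                                  scientific = FALSE), path),
    freesurfer_morph = write_curv(values, path),
    gifti_func = writeLines(gifti_xml(values, "NIFTI_INTENT_NONE",
                                      "NIFTI_TYPE_FLOAT32"), path)
  )
  invisible(path)
}

#' Assemble a two-modality dataset from per-subject map files
#'
#' Reads one file per subject per modality (list order defines subject order)
#' and returns a validated [modality_dataset()]. Every map must have the same
#' number of locations; a mismatch is reported with the offending path.
#'
#' @param x_paths,y_paths Character vectors of file paths, equal length, one
#'   per subject, aligned.
#' @param subject_ids Optional identifiers (default `"subj1"`, ...).
#' @param mask Optional logical/0-1 vector of length `V`, or a path to a
#'   delimited file of 0/1 values.
#' @param format Map format passed to [read_subject_map()].
#' @return A [modality_dataset()].
#' @export
assemble_dataset <- function(x_paths, y_paths, subject_ids = NULL, mask = NULL,
                             format = "auto") {
  x_paths <- as.character(x_paths)
  y_paths <- as.character(y_paths)
  if (length(x_paths) != length(y_paths)) {
    stop(sprintf("x list has %d files but y list has %d; one file per subject per modality",
                 length(x_paths), length(y_paths)), call. = FALSE)
  }
  if (length(x_paths) < 2L) stop("at least 2 subjects are required", call. = FALSE)

  read_all <- function(paths) {
    maps <- lapply(paths, read_subject_map, format = format)
    v <- length(maps[[1L]])
    for (i in seq_along(maps)) {
      if (length(maps[[i]]) != v) {
        stop(sprintf("'%s' has %d locations but '%s' has %d; all maps must share one surface space",
                     paths[i], length(maps[[i]]), paths[1L], v), call. = FALSE)
      }
    }
    do.call(rbind, maps)
  }
  x <- read_all(c(x_paths, y_paths)) # single pass guards cross-modality V too
  y <- x[length(x_paths) + seq_along(y_paths), , drop = FALSE]
  x <- x[seq_along(x_paths), , drop = FALSE]

  if (is.character(mask) && length(mask) == 1L) {
    mask <- read_delimited_vector(mask) != 0
  }
  modality_dataset(x, y, subject_ids = subject_ids, mask = mask)
}
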