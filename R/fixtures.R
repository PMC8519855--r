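#' Write a synthetic example dataset exercising every supported file format
#'
#' Generates a small strongly coupled two-modality dataset (each subject's Y
#' map is its X map plus mild independent noise, so the within-subject
#' correlation is near 1 while between-subject correlations hover near 0) and
#' writes it out in every format the package reads: per-subject GIFTI
#' functional files for modality X, FreeSurfer curv files for modality Y,
#' subjects-as-rows TSV matrices for both, a mask file, and a two-region
#' parcellation in delimited, GIFTI label and FreeSurfer annot forms. Two
#' list files (`x_files.txt`, `y_files.txt`) enumerate the per-subject maps
#' in subject order for use with [assemble_dataset()] or the command line.
#'
#' All files are synthetic; they exist so the full I/O surface can be
#' exercised without any imaging dataset.
#'
#' @param dir Output directory (created if absent).
#' @param n Number of subjects (default 10).
#' @param v Number of locations (default 80).
#' @param seed Integer seed.
#' @return Invisibly, a named list of the paths written.
#' @export
make_fixtures <- function(dir, n = 10L, v = 80L, seed = 1L) {
  stopifnot(n >= 2, v >= 6)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  draws <- withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * v), n, v)
    list(x = x, y = x + matrix(stats::rnorm(n * v, sd = 0.1), n, v))
  })
  x <- draws$x
  y <- draws$y

  x_paths <- file.path(dir, sprintf("x_%02d.func.gii", seq_len(n)))
  y_paths <- file.path(dir, sprintf("y_%02d.curv", seq_len(n)))
  for (i in seq_len(n)) {
    write_subject_map(x[i, ], x_paths[i])
    write_subject_map(y[i, ], y_paths[i])
  }
  x_list <- file.path(dir, "x_files.txt")
  y_list <- file.path(dir, "y_files.txt")
  writeLines(x_paths, x_list)
  writeLines(y_paths, y_list)

  x_matrix <- file.path(dir, "x_matrix.tsv")
  y_matrix <- file.path(dir, "y_matrix.tsv")
  write_map_matrix(x, x_matrix)
  write_map_matrix(y, y_matrix)

  mask_path <- file.path(dir, "mask.txt")
  writeLines(as.character(rep(1L, v)), mask_path)

  rl <- region_labels(
    rep(c(1L, 2L), c(ceiling(v / 2), floor(v / 2))),
    names = c(`1` = "anterior", `2` = "posterior")
  )
  labels_txt <- file.path(dir, "labels.txt")
  labels_gii <- file.path(dir, "labels.label.gii")
  labels_annot <- file.path(dir, "labels.annot")
  write_labels(rl, labels_txt)
  write_labels(rl, labels_gii)
  write_labels(rl, labels_annot)

  invisible(list(
    dir = dir, x_paths = x_paths, y_paths = y_paths,
    x_list = x_list, y_list = y_list,
    x_matrix = x_matrix, y_matrix = y_matrix,
    mask = mask_path,
    labels_delimited = labels_txt, labels_gifti = labels_gii,
    labels_annot = labels_annot
  ))
}
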