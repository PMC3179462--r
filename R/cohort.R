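#' Fiber-count cohorts
#'
#' A cohort bundles per-subject symmetric region-pair fiber-count
#' matrices with optional mean fiber lengths (mm) and subject metadata.
#' It is the raw input of every backbone analysis.
#'
#' @param counts Numeric array, subjects x N x N; each slice must be a
#'   symmetric nonnegative integer matrix; diagonals are forced to 0.
#' @param subjects Data frame with one row per subject; must contain
#'   `subject_id`, and typically `age_group` and `sex`.
#' @param atlas A [region_atlas()] with N regions.
#' @param lengths Optional array, subjects x N x N, of mean fiber
#'   lengths in mm; positive only where the matching count is positive.
#'
#' @return An object of class `fiber_cohort`: a list with elements
#'   `counts`, `lengths`, `subjects` (tibble) and `atlas`.
#' @export
fiber_cohort <- function(counts, subjects, atlas, lengths = NULL) {
  stopifnot(inherits(atlas, "region_atlas"))
  n <- nrow(atlas)
  dm <- dim(counts)
  if (length(dm) != 3 || dm[2] != n || dm[3] != n) {
    stop("counts must be a subjects x ", n, " x ", n, " array",
         call. = FALSE)
  }
  subjects <- tibble::as_tibble(subjects)
  if (!"subject_id" %in% names(subjects)) {
    stop("subjects metadata needs a subject_id column", call. = FALSE)
  }
  if (nrow(subjects) != dm[1]) {
    stop("metadata rows must match the number of count matrices",
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("fiber counts must be nonnegative integers", call. = FALSE)
  }
  for (s in seq_len(dm[1])) {
    m <- counts[s, , ]
    if (!isTRUE(all.equal(m, t(m)))) {
      stop("count matrix for subject '", subjects$subject_id[s],
           "' is not symmetric", call. = FALSE)
    }
    diag(m) <- 0
    counts[s, , ] <- m
  }
  if (!is.null(lengths)) {
    if (!identical(dim(lengths), dm)) {
      stop("lengths array must match counts dimensions", call. = FALSE)
    }
    if (any(lengths[counts == 0] != 0)) {
      stop("lengths must be 0 where counts are 0", call. = FALSE)
    }
    if (any(lengths < 0)) stop("lengths must be nonnegative", call. = FALSE)
  }
  structure(list(counts = counts, lengths = lengths,
                 subjects = subjects, atlas = atlas),
            class = "fiber_cohort")
}

#' @export
print.fiber_cohort <- function(x, ...) {
  cat(sprintf("<fiber_cohort: %d subjects, %d regions%s>\n",
              nrow(x$subjects), nrow(x$atlas),
              if (is.null(x$lengths)) "" else ", with fiber lengths"))
  if (all(c("age_group", "sex") %in% names(x$subjects))) {
    print(dplyr::count(x$subjects, .data$age_group, .data$sex))
  }
  invisible(x)
}

#' Restrict a cohort to a subset of subjects
#'
#' @param cohort A [fiber_cohort()].
#' @param subjects Logical/integer index into the metadata rows, or a
#'   character vector of subject ids (in which case all matching rows,
#'   e.g. all timepoints of those subjects, are kept).
#' @return A [fiber_cohort()] with the selected subjects.
#' @export
cohort_subset <- function(cohort, subjects) {
  stopifnot(inherits(cohort, "fiber_cohort"))
  idx <- if (is.character(subjects)) {
    which(cohort$subjects$subject_id %in% subjects)
  } else {
    seq_len(nrow(cohort$subjects))[subjects]
  }
  fiber_cohort(cohort$counts[idx, , , drop = FALSE],
               cohort$subjects[idx, , drop = FALSE],
               cohort$atlas,
               lengths = if (!is.null(cohort$lengths)) {
                 cohort$lengths[idx, , , drop = FALSE]
               })
}

# read one square matrix from TSV/CSV, tolerating an optional header
# row and/or leading label column
read_square_matrix <- function(path, n_expected) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  is_num <- function(x) !anyNA(suppressWarnings(as.numeric(x)))
  if (!is_num(m[1, ])) m <- m[-1, , drop = FALSE]
  if (!is_num(m[, 1])) m <- m[, -1, drop = FALSE]
  if (!is_num(m)) stop("non-numeric entries in ", path, call. = FALSE)
  out <- matrix(as.numeric(m), nrow(m), ncol(m))
  if (nrow(out) != ncol(out)) {
    stop("shape mismatch: ", path, " is ", nrow(out), "x", ncol(out),
         ", not square", call. = FALSE)
  }
  if (nrow(out) != n_expected) {
    stop("shape mismatch: ", path, " is ", nrow(out), "x", ncol(out),
         " but the atlas has ", n_expected, " regions", call. = FALSE)
  }
  out
}

#' Read a fiber-count cohort from disk
#'
#' Count matrices are square TSV/CSV files (one per subject, an optional
#' header row/column of region labels is tolerated); they must be
#' exactly symmetric — asymmetry indicates an upstream bug and is an
#' error, not something to silently repair. Diagonals are zeroed.
#'
#' @param count_files Character vector of matrix file paths. Names are
#'   used as subject ids; unnamed entries fall back to the file base
#'   name without extension.
#' @param atlas_file Path to the atlas TSV (see [read_atlas()]).
#' @param metadata_file CSV with columns `subject_id`, `age_group`,
#'   `sex`; every id must match a count file and vice versa.
#' @param length_files Optional vector of mean-length matrix files,
#'   parallel to `count_files`.
#' @return A [fiber_cohort()].
#' @export
read_cohort <- function(count_files, atlas_file, metadata_file,
                        length_files = NULL) {
  atlas <- read_atlas(atlas_file)
  n <- nrow(atlas)
  ids <- names(count_files) %||%
    sub("\\.[^.]*$", "", basename(count_files))
  ids[ids == ""] <- sub("\\.[^.]*$", "", basename(count_files))[ids == ""]
  meta <- readr::read_csv(metadata_file, show_col_types = FALSE,
                          progress = FALSE)
  if (!"subject_id" %in% names(meta)) {
    stop("metadata needs a subject_id column", call. = FALSE)
  }
  meta$subject_id <- as.character(meta$subject_id)
  if (anyDuplicated(meta$subject_id)) {
    stop("subject_id must be unique per scan ",
         "(use e.g. '<id>_<timepoint>' for longitudinal data)",
         call. = FALSE)
  }
  unknown <- setdiff(meta$subject_id, ids)
  if (length(unknown) > 0) {
    stop("unknown subject id in metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(ids, meta$subject_id)
  if (length(missing) > 0) {
    stop("no metadata row for subject(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- array(0, dim = c(length(ids), n, n))
  for (s in seq_along(count_files)) {
    counts[s, , ] <- read_square_matrix(count_files[s], n)
  }
  lengths <- NULL
  if (!is.null(length_files)) {
    if (length(length_files) != length(count_files)) {
      stop("length_files must parallel count_files", call. = FALSE)
    }
    lengths <- array(0, dim = c(length(ids), n, n))
    for (s in seq_along(length_files)) {
      lengths[s, , ] <- read_square_matrix(length_files[s], n)
    }
  }
  meta <- meta[match(ids, meta$subject_id), , drop = FALSE]
  fiber_cohort(counts, meta, atlas, lengths = lengths)
}

#' Write a cohort to a directory of delimited files
#'
#' Inverse of [read_cohort()]: writes `atlas.tsv`, `metadata.csv`, and
#' one labelled count (and, if present, length) matrix per metadata row
#' under `counts/` and `lengths/`.
#'
#' @param cohort A [fiber_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the written file paths (`atlas`,
#'   `metadata`, `counts`, `lengths`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fiber_cohort"))
  dir.create(file.path(dir, "counts"), recursive = TRUE,
             showWarnings = FALSE)
  atlas_path <- file.path(dir, "atlas.tsv")
  readr::write_tsv(tibble::as_tibble(cohort$atlas), atlas_path,
                   progress = FALSE)
  meta_path <- file.path(dir, "metadata.csv")
  readr::write_csv(cohort$subjects, meta_path, progress = FALSE)
  write_mat <- function(m, path) {
    dimnames(m) <- list(NULL, cohort$atlas$label)
    readr::write_tsv(tibble::as_tibble(m), path, progress = FALSE)
  }
  stub <- as.character(cohort$subjects$subject_id)
  if (anyDuplicated(stub)) {
    stop("subject_id must be unique per scan to write one file each",
         call. = FALSE)
  }
  count_paths <- file.path(dir, "counts", paste0(stub, ".tsv"))
  for (s in seq_along(stub)) write_mat(cohort$counts[s, , ], count_paths[s])
  length_paths <- NULL
  if (!is.null(cohort$lengths)) {
    dir.create(file.path(dir, "lengths"), showWarnings = FALSE)
    length_paths <- file.path(dir, "lengths", paste0(stub, ".tsv"))
    for (s in seq_along(stub)) {
      write_mat(cohort$lengths[s, , ], length_paths[s])
    }
  }
  invisible(list(atlas = atlas_path, metadata = meta_path,
                 counts = count_paths, lengths = length_paths))
}
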