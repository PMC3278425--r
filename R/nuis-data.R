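#' Construct a nuisance-aware dataset
#'
#' A `nuis_data` object is a tibble of one row per subject plus column-role
#' metadata: which column identifies the subject, which holds the group
#' label, which columns are classification features (the quantities used to
#' discriminate study groups, e.g. test scores or imaging biomarkers) and
#' which are nuisance features (covariates such as age or gender that affect
#' the classification features but are not of diagnostic interest).
#'
#' @param data A data frame with one row per subject.
#' @param id Name of the subject-identifier column. Values must be unique.
#' @param group Name of the group-label column.
#' @param features Character vector of classification-feature column names.
#'   Defaults to every numeric column not named elsewhere in the schema.
#' @param nuisances Character vector of nuisance-feature column names
#'   (may be empty).
#' @param group_levels Declared set of admissible group labels. Defaults to
#'   the labels observed in `data`.
#'
#' @return A `nuis_data` object. `as_tibble()` recovers the underlying
#'   tibble; [feature_names()] and [nuisance_names()] recover the roles.
#' @export
#' @examples
#' df <- tibble::tibble(sid = c("s1", "s2"), grp = c("A", "B"),
#'                      vol = c(1.2, 0.8), age = c(70, 75))
#' as_nuis_data(df, id = "sid", group = "grp",
#'              features = "vol", nuisances = "age")
as_nuis_data <- function(data, id = "subject_id", group = "group",
                         features = NULL, nuisances = character(),
                         group_levels = NULL) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  for (col in c(id, group, nuisances)) {
    if (!col %in% names(data)) {
      stop("column '", col, "' not found in data", call. = FALSE)
    }
  }
  if (is.null(features)) {
    reserved <- c(id, group, nuisances)
    features <- names(data)[vapply(data, is.numeric, logical(1))]
    features <- setdiff(features, reserved)
  } else if (!all(features %in% names(data))) {
    missing_cols <- setdiff(features, names(data))
    stop("column '", missing_cols[1], "' not found in data", call. = FALSE)
  }
  if (anyDuplicated(data[[id]])) {
    stop("duplicate subject ids", call. = FALSE)
  }
  if (length(intersect(features, nuisances)) > 0) {
    stop("feature and nuisance roles must be disjoint", call. = FALSE)
  }
  for (col in c(features, nuisances)) {
    if (!is.numeric(data[[col]])) {
      data[[col]] <- as.numeric(data[[col]])
    }
  }
  data[[group]] <- as.character(data[[group]])
  if (is.null(group_levels)) group_levels <- unique(stats::na.omit(data[[group]]))
  bad <- setdiff(unique(stats::na.omit(data[[group]])), group_levels)
  if (length(bad) > 0) {
    stop("group labels outside declared set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      data = data[, c(id, group, features, nuisances), drop = FALSE],
      id = id, group = group,
      features = features, nuisances = nuisances,
      group_levels = group_levels
    ),
    class = "nuis_data"
  )
}

#' @export
print.nuis_data <- function(x, ...) {
  cat("<nuis_data> ", nrow(x$data), " subjects, ",
      length(x$features), " classification feature(s), ",
      length(x$nuisances), " nuisance feature(s)\n", sep = "")
  cat("groups: ", paste(x$group_levels, collapse = ", "), "\n", sep = "")
  print(x$data, ...)
  invisible(x)
}

#' @export
as_tibble.nuis_data <- function(x, ...) x$data

#' @export
as.data.frame.nuis_data <- function(x, ...) as.data.frame(x$data, ...)

#' @export
dim.nuis_data <- function(x) dim(x$data)

#' Column roles and basic accessors
#'
#' @param x A [as_nuis_data()] object.
#' @return `feature_names()` and `nuisance_names()` return character vectors;
#'   `group_labels()` returns the per-subject label vector; `subject_ids()`
#'   the identifier vector; `n_subjects()` the subject count.
#' @export
feature_names <- function(x) {
  stopifnot(inherits(x, "nuis_data"))
  x$features
}

#' @rdname feature_names
#' @export
nuisance_names <- function(x) {
  stopifnot(inherits(x, "nuis_data"))
  x$nuisances
}

#' @rdname feature_names
#' @export
group_labels <- function(x) {
  stopifnot(inherits(x, "nuis_data"))
  x$data[[x$group]]
}

#' @rdname feature_names
#' @export
subject_ids <- function(x) {
  stopifnot(inherits(x, "nuis_data"))
  x$data[[x$id]]
}

#' @rdname feature_names
#' @export
n_subjects <- function(x) nrow(x$data)

# numeric matrix of a column block (features or nuisances)
block_matrix <- function(x, cols) {
  m <- as.matrix(x$data[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$data[[x$id]]
  m
}

#' Keep a subset of subjects
#'
#' Rows are kept in their original order; column roles are unchanged.
#'
#' @param data A `nuis_data` object.
#' @param mask Logical vector, one entry per subject, or an integer index
#'   vector.
#' @return A `nuis_data` containing the selected subjects.
#' @export
subset_subjects <- function(data, mask) {
  stopifnot(inherits(data, "nuis_data"))
  if (is.logical(mask)) {
    if (length(mask) != nrow(data$data)) {
      stop("mask length must equal subject count", call. = FALSE)
    }
    idx <- which(mask)
  } else {
    idx <- as.integer(mask)
  }
  out <- data
  out$data <- data$data[idx, , drop = FALSE]
  out
}

#' Declare the study-group pair for a classification run
#'
#' @param group_a,group_b The two study-group labels to discriminate.
#' @param reference The reference (typically healthy-control) group label
#'   used to fit nuisance-correction models. Defaults to `group_a`: in a
#'   control-vs-patient comparison, controls are their own reference; in a
#'   patient-vs-patient comparison pass the control label explicitly.
#' @return A `group_pair` object.
#' @export
group_pair <- function(group_a, group_b, reference = group_a) {
  stopifnot(is.character(group_a), is.character(group_b),
            length(group_a) == 1, length(group_b) == 1)
  if (identical(group_a, group_b)) {
    stop("group_a and group_b must differ", call. = FALSE)
  }
  structure(list(group_a = group_a, group_b = group_b,
                 reference = reference),
            class = "group_pair")
}

#' @export
print.group_pair <- function(x, ...) {
  cat("<group_pair> ", x$group_a, " vs ", x$group_b,
      " (reference: ", x$reference, ")\n", sep = "")
  invisible(x)
}

# indices of subjects whose group is in the pair
pair_indices <- function(data, pair) {
  which(group_labels(data) %in% c(pair$group_a, pair$group_b))
}

#' Read a subject table from CSV
#'
#' Expects a comma-separated file with a header row; empty cells are read
#' as missing values (never as zero).
#'
#' @param path Path to the CSV file.
#' @param schema Named list with elements `id`, `group`, `features`,
#'   `nuisances` assigning column roles, as in [as_nuis_data()].
#' @return A `nuis_data` object.
#' @export
read_dataset <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(is.list(schema), !is.null(schema$id), !is.null(schema$group))
  df <- readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                        progress = FALSE)
  as_nuis_data(df, id = schema$id, group = schema$group,
               features = schema$features,
               nuisances = schema$nuisances %||% character())
}

#' Write a subject table to CSV
#'
#' Missing values are written as empty cells so that
#' `read_dataset(write_dataset(d))` round-trips values, labels and
#' missingness.
#'
#' @param data A `nuis_data` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "nuis_data"))
  readr::write_csv(data$data, path, na = "")
  invisible(path)
}
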