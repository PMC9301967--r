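# Readers and writers for the CSV formats the toolkit touches.
#
# All files are delimited text (comma by default, configurable), UTF-8, with
# labels in the first row/column. Time is always minutes at the I/O
# boundary. Missing cells are read as NA and excluded from downstream
# statistics, never silently zero-filled.

read_delim_frame <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", na.strings = c("", "NA"))
}

looks_numeric <- function(x) {
  x <- trim_label(x)
  x != "" & !is.na(suppressWarnings(as.numeric(x)))
}

#' Read a screen summary matrix from CSV
#'
#' Expects condition labels in the first row and substrate labels in the
#' first column. Duplicate labels (matched case-insensitively after
#' whitespace trimming) either raise an error (`"strict"`, default) or are
#' collapsed by their mean (`"mean"`).
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter, default comma.
#' @param duplicate_policy `"strict"` or `"mean"`.
#' @param measurement_kind Measurement kind recorded on the result; see
#'   [screen_matrix()].
#' @param screen_name Screen name; defaults to the file name without
#'   extension.
#' @return A [screen_matrix()].
#' @export
read_screen_matrix <- function(path, delim = ",",
                               duplicate_policy = c("strict", "mean"),
                               measurement_kind = "raw_intensity",
                               screen_name = NULL) {
  duplicate_policy <- match.arg(duplicate_policy)
  screen_name <- screen_name %||% sub("\\.[^.]*$", "", basename(path))
  df <- read_delim_frame(path, delim)
  if (ncol(df) < 2L) {
    stop("format error: expected a label column plus at least one condition column in ",
         path, call. = FALSE)
  }
  header <- colnames(df)[-1]
  if (all(looks_numeric(header))) {
    stop("format error: first row of ", path,
         " looks like data, not condition labels (missing header?)",
         call. = FALSE)
  }
  labels <- trim_label(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!is.na(vals) & is.na(suppressWarnings(
      matrix(as.numeric(vals), nrow = nrow(vals)))), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("parse error: non-numeric value '%s' at substrate '%s', condition '%s'",
                   vals[bad[1, 1], bad[1, 2]], labels[bad[1, 1]],
                   header[bad[1, 2]]), call. = FALSE)
    }
    vals <- matrix(suppressWarnings(as.numeric(vals)), nrow = nrow(vals),
                   dimnames = list(NULL, colnames(vals)))
  }
  rownames(vals) <- labels
  vals <- collapse_duplicates(vals, duplicate_policy, "substrate")
  vals <- t(collapse_duplicates(t(vals), duplicate_policy, "condition"))
  sm <- screen_matrix(vals, screen_name = screen_name,
                      measurement_kind = measurement_kind)
  attr(sm, "source") <- path
  sm
}

collapse_duplicates <- function(m, policy, axis) {
  keys <- label_key(rownames(m))
  if (!anyDuplicated(keys)) return(m)
  if (policy == "strict") {
    stop("validation error: duplicate ", axis, " label(s): ",
         paste(unique(rownames(m)[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  keep <- !duplicated(keys)
  out <- matrix(NA_real_, nrow = sum(keep), ncol = ncol(m),
                dimnames = list(rownames(m)[keep], colnames(m)))
  for (i in seq_len(nrow(out))) {
    rows <- m[keys == keys[keep][i], , drop = FALSE]
    out[i, ] <- colMeans(rows, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Write a labelled table to CSV
#'
#' Writes any labelled matrix (including a [screen_matrix()]) so that
#' [read_screen_matrix()] reproduces it up to floating-point formatting
#' (15 significant digits).
#'
#' @param table A `screen_matrix`, matrix or data frame with row and column
#'   labels.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_table <- function(table, path, delim = ",") {
  if (inherits(table, "screen_matrix")) table <- table$values
  m <- as.matrix(table)
  if (nrow(m) == 0L || ncol(m) == 0L) {
    writeLines("\"\"", path)
    return(invisible(path))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("table must have row and column labels", call. = FALSE)
  }
  df <- data.frame(format(m, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, row.names = rownames(m))
  df[is.na(m)] <- NA
  utils::write.table(df, path, sep = delim, row.names = TRUE,
                     col.names = NA, quote = TRUE, na = "")
  invisible(path)
}

#' Read a substrate-name to peptide-sequence map
#'
#' Two-column delimited file (header `label,sequence`). Duplicate labels
#' carrying the same sequence are deduplicated; conflicting sequences for one
#' label are an error. Sequences containing letters outside the 20 standard
#' one-letter amino-acid codes are kept but flagged via the `"nonstandard"`
#' attribute and a warning.
#'
#' @param path Path to the file.
#' @param delim Field delimiter.
#' @return A named character vector of class `sequence_map` (names are
#'   substrate labels).
#' @export
read_sequence_map <- function(path, delim = ",") {
  df <- read_delim_frame(path, delim)
  if (ncol(df) < 2L) {
    stop("format error: sequence map needs two columns (label, sequence)",
         call. = FALSE)
  }
  sequence_map(stats::setNames(as.character(df[[2]]), trim_label(df[[1]])))
}

#' Construct a validated sequence map
#'
#' @param x Named character vector: substrate label -> peptide sequence.
#' @return A `sequence_map` object.
#' @export
sequence_map <- function(x) {
  labels <- trim_label(names(x))
  seqs <- toupper(trim_label(unname(x)))
  if (any(is.na(seqs) | seqs == "")) {
    stop("validation error: empty sequence for label(s): ",
         paste(labels[is.na(seqs) | seqs == ""], collapse = ", "),
         call. = FALSE)
  }
  keys <- label_key(labels)
  for (k in unique(keys[duplicated(keys)])) {
    if (length(unique(seqs[keys == k])) > 1L) {
      stop("validation error: conflicting sequences for label '",
           labels[keys == k][1], "'", call. = FALSE)
    }
  }
  keep <- !duplicated(keys)
  out <- stats::setNames(seqs[keep], labels[keep])
  nonstd <- names(out)[grepl("[^ACDEFGHIKLMNPQRSTVWY]", out)]
  if (length(nonstd) > 0) {
    warning("non-standard amino-acid tokens in sequence(s) for: ",
            paste(nonstd, collapse = ", "), call. = FALSE)
  }
  structure(out, nonstandard = nonstd, class = "sequence_map")
}

#' @export
print.sequence_map <- function(x, ...) {
  cat(sprintf("<sequence_map> %d substrate sequences\n", length(x)))
  print(utils::head(stats::setNames(as.character(x), names(x))))
  invisible(x)
}

#' Write a sequence map to CSV
#' @param map A `sequence_map` (or named character vector).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_sequence_map <- function(map, path, delim = ",") {
  utils::write.table(
    data.frame(label = names(map), sequence = as.character(map)),
    path, sep = delim, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an amino-acid colour map
#'
#' Delimited file with columns `amino_acid,color`. Every key must be a single
#' character.
#'
#' @param path Path to the file.
#' @param grouping_kind What the colours encode: `"hydrophobicity"`,
#'   `"chemistry"`, `"identity"` or `"custom"`.
#' @param delim Field delimiter.
#' @return Named character vector of class `color_map`.
#' @export
read_color_map <- function(path, grouping_kind = c("custom", "hydrophobicity",
                                                   "chemistry", "identity"),
                           delim = ",") {
  grouping_kind <- match.arg(grouping_kind)
  df <- read_delim_frame(path, delim)
  keys <- trim_label(df[[1]])
  if (any(nchar(keys) != 1L)) {
    stop("validation error: colour map keys must be single characters",
         call. = FALSE)
  }
  structure(stats::setNames(as.character(df[[2]]), keys),
            grouping_kind = grouping_kind, class = "color_map")
}

default_kinetic_layout <- function() {
  list(substrate = "substrate", condition = "condition",
       replicate = "replicate")
}

#' Read raw kinetic time courses from wide CSV
#'
#' Wide layout: one row per series, identifier columns naming the substrate,
#' condition and replicate, and the remaining columns holding intensities at
#' the time (in minutes) given by each column name. The layout spec maps the
#' identifier columns, either as a named list or as a path to a JSON file
#' with keys `substrate`, `condition`, `replicate`.
#'
#' Time columns may appear in any order; they are sorted. Duplicated time
#' points are a validation error.
#'
#' @param path Path to the file.
#' @param layout `NULL` for the default column names
#'   (`substrate`, `condition`, `replicate`), a named list, or a JSON file
#'   path.
#' @param delim Field delimiter.
#' @param screen_name Assay name; defaults to the file name.
#' @return A [kinetic_raw()] object.
#' @export
read_kinetic_raw <- function(path, layout = NULL, delim = ",",
                             screen_name = NULL) {
  screen_name <- screen_name %||% sub("\\.[^.]*$", "", basename(path))
  if (is.character(layout) && length(layout) == 1L) {
    layout <- jsonlite::read_json(layout, simplifyVector = TRUE)
  }
  layout <- utils::modifyList(default_kinetic_layout(), as.list(layout %||% list()))
  df <- read_delim_frame(path, delim)
  id_cols <- unlist(layout[c("substrate", "condition", "replicate")])
  missing_cols <- setdiff(id_cols, colnames(df))
  if (length(missing_cols) > 0) {
    stop("format error: identifier column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  time_cols <- colnames(df)[!(colnames(df) %in% id_cols)]
  times <- suppressWarnings(as.numeric(time_cols))
  if (length(time_cols) == 0L || anyNA(times)) {
    stop("format error: time columns must be named by their time in minutes",
         call. = FALSE)
  }
  vals <- as.matrix(df[, time_cols, drop = FALSE])
  if (!is.numeric(vals)) {
    stop("parse error: non-numeric intensity values in ", path, call. = FALSE)
  }
  kinetic_raw(times, vals,
              substrate = df[[layout$substrate]],
              condition = df[[layout$condition]],
              replicate = df[[layout$replicate]],
              screen_name = screen_name)
}

#' Write raw kinetic time courses to wide CSV
#' @param raw A [kinetic_raw()] object.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_kinetic_raw <- function(raw, path, delim = ",") {
  df <- cbind(raw$series,
              as.data.frame(raw$values) |>
                stats::setNames(as.character(raw$time_points)))
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Validate an input file
#'
#' Attempts to parse a file as one of the supported kinds and reports whether
#' it is valid. Backs the `paa io validate` command-line entry point.
#'
#' @param path Path to the file.
#' @param kind `"screen"`, `"sequences"` or `"kinetic"`.
#' @param ... Passed to the corresponding reader.
#' @return A list with elements `ok` (logical) and `message`.
#' @export
validate_activity_file <- function(path, kind = c("screen", "sequences",
                                                  "kinetic"), ...) {
  kind <- match.arg(kind)
  reader <- switch(kind,
                   screen = read_screen_matrix,
                   sequences = read_sequence_map,
                   kinetic = read_kinetic_raw)
  res <- tryCatch(
    {
      obj <- reader(path, ...)
      list(ok = TRUE, message = paste0("valid ", kind, " file"))
    },
    error = function(e) list(ok = FALSE, message = conditionMessage(e)),
    warning = function(w) list(ok = TRUE,
                               message = paste0("valid with warning: ",
                                                conditionMessage(w)))
  )
  res
}
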