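#' Screen summary matrix
#'
#' A `screen_matrix` holds one screen's substrate-by-condition activity
#' summary: an n x k numeric matrix whose rows are peptide substrates and
#' whose columns are the assayed conditions (recombinant proteases, lysates,
#' samples). The measurement kind records whether cells are raw fluorescence
#' intensities, fold changes, or initial rates.
#'
#' Row and column labels must be unique after whitespace trimming and case
#' folding; raw intensities and fold changes must be nonnegative. Missing
#' cells are allowed and are excluded from downstream statistics.
#'
#' @param values Numeric matrix with row names (substrates) and column names
#'   (conditions).
#' @param screen_name Single string identifying the screen.
#' @param measurement_kind One of `"raw_intensity"`, `"fold_change"`,
#'   `"initial_rate"`.
#' @return An object of class `screen_matrix`.
#' @export
screen_matrix <- function(values, screen_name = "screen",
                          measurement_kind = c("raw_intensity", "fold_change",
                                               "initial_rate")) {
  measurement_kind <- match.arg(measurement_kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry substrate row names and condition column names",
         call. = FALSE)
  }
  rownames(values) <- trim_label(rownames(values))
  colnames(values) <- trim_label(colnames(values))
  if (anyDuplicated(label_key(rownames(values)))) {
    stop("duplicate substrate labels (case-insensitive): ",
         paste(unique(rownames(values)[duplicated(label_key(rownames(values)))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(label_key(colnames(values)))) {
    stop("duplicate condition labels (case-insensitive): ",
         paste(unique(colnames(values)[duplicated(label_key(colnames(values)))]),
               collapse = ", "), call. = FALSE)
  }
  if (measurement_kind %in% c("raw_intensity", "fold_change") &&
      any(values < 0, na.rm = TRUE)) {
    stop("negative values are not allowed for measurement kind '",
         measurement_kind, "'", call. = FALSE)
  }
  structure(
    list(screen_name = as.character(screen_name)[1],
         values = values,
         measurement_kind = measurement_kind),
    class = "screen_matrix"
  )
}

#' @export
dim.screen_matrix <- function(x) dim(x$values)

#' @export
as.matrix.screen_matrix <- function(x, ...) x$values

#' Substrate labels of a screen matrix
#' @param x A `screen_matrix`.
#' @return Character vector of substrate (row) labels.
#' @export
substrate_labels <- function(x) {
  UseMethod("substrate_labels")
}

#' @export
substrate_labels.screen_matrix <- function(x) rownames(x$values)

#' Condition labels of a screen matrix
#' @param x A `screen_matrix`.
#' @return Character vector of condition (column) labels.
#' @export
condition_labels <- function(x) {
  UseMethod("condition_labels")
}

#' @export
condition_labels.screen_matrix <- function(x) colnames(x$values)

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("<screen_matrix> '%s': %d substrates x %d conditions (%s)\n",
              x$screen_name, nrow(x$values), ncol(x$values),
              x$measurement_kind))
  if (nrow(x$values) > 0 && ncol(x$values) > 0) {
    print(utils::head(x$values, 5L))
    if (nrow(x$values) > 5L) cat("...\n")
  }
  invisible(x)
}
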