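#' Raw kinetic time-course container
#'
#' Holds fluorescence progress curves from an enzyme activity assay: a
#' strictly increasing vector of time points (minutes) and, for each
#' (substrate, condition, replicate) series, a vector of intensities aligned
#' to those time points.
#'
#' @param time_points Strictly increasing numeric vector of times in minutes.
#' @param values Numeric matrix, one row per series, `length(time_points)`
#'   columns.
#' @param substrate,condition Character vectors, one entry per series.
#' @param replicate Integer vector of replicate indices; within each
#'   (substrate, condition) pair the indices must be contiguous from 1.
#' @param screen_name Single string identifying the assay.
#' @return An object of class `kinetic_raw`.
#' @export
kinetic_raw <- function(time_points, values, substrate, condition,
                        replicate = rep(1L, length(substrate)),
                        screen_name = "screen") {
  time_points <- as.numeric(time_points)
  values <- as.matrix(values)
  if (anyNA(time_points)) stop("time points must be numeric", call. = FALSE)
  ord <- order(time_points)
  time_points <- time_points[ord]
  values <- values[, ord, drop = FALSE]
  if (any(diff(time_points) <= 0)) {
    stop("time points must be strictly increasing (duplicated times found)",
         call. = FALSE)
  }
  n <- length(substrate)
  if (length(condition) != n || length(replicate) != n || nrow(values) != n) {
    stop("substrate, condition, replicate and rows of `values` must align",
         call. = FALSE)
  }
  if (ncol(values) != length(time_points)) {
    stop("every series must have one intensity per time point", call. = FALSE)
  }
  substrate <- trim_label(substrate)
  condition <- trim_label(condition)
  replicate <- as.integer(replicate)
  pair <- paste(label_key(substrate), label_key(condition), sep = "\r")
  for (p in unique(pair)) {
    reps <- sort(replicate[pair == p])
    if (!identical(reps, seq_len(length(reps)))) {
      stop("replicate indices must be contiguous from 1 for ",
           sub("\r", " / ", p), call. = FALSE)
    }
  }
  structure(
    list(screen_name = as.character(screen_name)[1],
         time_points = time_points,
         series = data.frame(substrate = substrate, condition = condition,
                             replicate = replicate,
                             stringsAsFactors = FALSE),
         values = unname(values)),
    class = "kinetic_raw"
  )
}

#' @export
print.kinetic_raw <- function(x, ...) {
  cat(sprintf(
    "<kinetic_raw> '%s': %d series (%d substrates x %d conditions), %d time points (%g-%g min)\n",
    x$screen_name, nrow(x$series),
    length(unique(label_key(x$series$substrate))),
    length(unique(label_key(x$series$condition))),
    length(x$time_points), min(x$time_points), max(x$time_points)))
  invisible(x)
}

# Subset the intensity rows of one (substrate, condition) pair.
kinetic_series <- function(raw, substrate, condition) {
  sel <- label_key(raw$series$substrate) == label_key(substrate) &
    label_key(raw$series$condition) == label_key(condition)
  raw$values[sel, , drop = FALSE]
}
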