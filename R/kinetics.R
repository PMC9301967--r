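# In vitro kinetics: initial rates, fold changes, the KineticDataset
# workflow and its derived tables.

#' Rate-window specification
#'
#' The initial rate is fitted over the early, approximately linear phase of
#' the progress curve: all points within the first `minutes` minutes, or the
#' first `min_points` points, whichever set is larger.
#'
#' @param minutes Window length in minutes (default 30).
#' @param min_points Minimum number of points (default 5).
#' @return A list used by [initial_rate()] and [kinetic_config()].
#' @export
rate_window <- function(minutes = 30, min_points = 5L) {
  list(minutes = as.numeric(minutes), min_points = as.integer(min_points))
}

average_replicates <- function(intensity) {
  if (is.matrix(intensity)) colMeans(intensity, na.rm = TRUE)
  else as.numeric(intensity)
}

#' Initial reaction rate from a progress curve
#'
#' Ordinary least-squares slope of fluorescence intensity versus time over
#' the rate window (intensity per minute). When `intensity` is a matrix the
#' rows are treated as replicates and averaged pointwise before fitting.
#'
#' @param intensity Numeric vector (one series) or matrix (replicates x
#'   time).
#' @param time Numeric vector of times in minutes, aligned to the series.
#' @param window A [rate_window()].
#' @return The fitted slope (intensity / min).
#' @export
initial_rate <- function(intensity, time, window = rate_window()) {
  y <- average_replicates(intensity)
  time <- as.numeric(time)
  if (length(y) != length(time)) {
    stop("`intensity` and `time` must align", call. = FALSE)
  }
  sel <- which(time <= time[1] + window$minutes)
  if (length(sel) < window$min_points) {
    sel <- seq_len(min(window$min_points, length(time)))
  }
  sel <- sel[!is.na(y[sel])]
  if (length(sel) < 2L) {
    stop("insufficient data: fewer than 2 usable points in the rate window",
         call. = FALSE)
  }
  t <- time[sel]
  yy <- y[sel]
  unname(sum((t - mean(t)) * (yy - mean(yy))) / sum((t - mean(t))^2))
}

#' Fold change at an evaluation time
#'
#' Intensity at the evaluation time divided by the baseline intensity (first
#' time point). With the `"blank"` background policy the blank-well value is
#' subtracted from both; with `"first_point"` the first point is subtracted
#' and the baseline is floored at `floor` to keep the ratio defined.
#' Replicate rows are averaged pointwise first. If `t_eval` is not a
#' sampled time it is linearly interpolated when `interpolate = TRUE`.
#'
#' @inheritParams initial_rate
#' @param t_eval Evaluation time in minutes (default: last time point).
#' @param background `"none"`, `"blank"` or `"first_point"`.
#' @param blank_value Blank-well intensity used when `background = "blank"`.
#' @param floor Lower bound applied to the baseline under `"first_point"`.
#' @param interpolate Allow linear interpolation of `t_eval`.
#' @return The (dimensionless) fold change.
#' @export
fold_change <- function(intensity, time, t_eval = NULL,
                        background = c("none", "blank", "first_point"),
                        blank_value = 0, floor = 1e-6, interpolate = TRUE) {
  background <- match.arg(background)
  y <- average_replicates(intensity)
  time <- as.numeric(time)
  if (length(y) != length(time)) {
    stop("`intensity` and `time` must align", call. = FALSE)
  }
  t_eval <- t_eval %||% time[length(time)]
  bg <- switch(background, none = 0, blank = blank_value, first_point = y[1])
  y <- y - bg
  baseline <- y[1]
  if (background == "first_point") baseline <- max(baseline, floor)
  if (!is.finite(baseline) || baseline <= 0) {
    stop("degenerate input: nonpositive baseline intensity after background policy",
         call. = FALSE)
  }
  idx <- which(abs(time - t_eval) < 1e-9)
  if (length(idx) >= 1L) {
    val <- y[idx[1]]
  } else if (interpolate && t_eval >= min(time) && t_eval <= max(time)) {
    val <- stats::approx(time, y, xout = t_eval)$y
  } else {
    stop("`t_eval` = ", t_eval, " is not a sampled time point", call. = FALSE)
  }
  val / baseline
}

#' Kinetic analysis configuration
#'
#' @param rate_window A [rate_window()].
#' @param fold_time Fold-change evaluation time in minutes; `NULL` uses the
#'   last common time point.
#' @param background,blank_value,floor Background policy, see
#'   [fold_change()].
#' @param replicate_policy `"average"` (pointwise averaging before fitting,
#'   default) or `"per_replicate"` (fit each replicate, then average the
#'   slopes).
#' @return A list of class `kinetic_config`.
#' @export
kinetic_config <- function(rate_window = proteasekit::rate_window(),
                           fold_time = NULL,
                           background = c("none", "blank", "first_point"),
                           blank_value = 0, floor = 1e-6,
                           replicate_policy = c("average", "per_replicate")) {
  structure(list(rate_window = rate_window, fold_time = fold_time,
                 background = match.arg(background),
                 blank_value = blank_value, floor = floor,
                 replicate_policy = match.arg(replicate_policy)),
            class = "kinetic_config")
}

#' Build a kinetic dataset from raw time courses
#'
#' Computes, for every (substrate, condition) pair, the initial rate and the
#' fold change at the configured evaluation time, yielding two derived
#' screen matrices alongside the raw data. Optionally writes
#' `rate_table.csv`, `fold_table.csv` and `sve.csv` to `out_dir`.
#'
#' @param raw A [kinetic_raw()] object.
#' @param config A [kinetic_config()].
#' @param classes Optional named character vector: protease -> catalytic
#'   class.
#' @param out_dir Optional output directory for the derived tables.
#' @return An object of class `kinetic_dataset` with elements `raw`,
#'   `rate_table`, `fold_table`, `classes`, `config`.
#' @export
build_kinetic_dataset <- function(raw, config = kinetic_config(),
                                  classes = NULL, out_dir = NULL) {
  stopifnot(inherits(raw, "kinetic_raw"))
  subs <- unique_by_key(raw$series$substrate)
  conds <- unique_by_key(raw$series$condition)
  rate <- fold <- matrix(NA_real_, length(subs), length(conds),
                         dimnames = list(subs, conds))
  for (s in subs) {
    for (p in conds) {
      series <- kinetic_series(raw, s, p)
      if (nrow(series) == 0L) next
      res <- tryCatch({
        r <- if (config$replicate_policy == "per_replicate") {
          mean(apply(series, 1L, initial_rate, time = raw$time_points,
                     window = config$rate_window))
        } else {
          initial_rate(series, raw$time_points, config$rate_window)
        }
        f <- fold_change(series, raw$time_points, t_eval = config$fold_time,
                         background = config$background,
                         blank_value = config$blank_value,
                         floor = config$floor)
        list(r = r, f = f)
      }, error = function(e) {
        stop("substrate '", s, "', condition '", p, "': ",
             conditionMessage(e), call. = FALSE)
      })
      rate[s, p] <- res$r
      fold[s, p] <- res$f
    }
  }
  ds <- structure(
    list(raw = raw,
         rate_table = screen_matrix(rate, paste0(raw$screen_name, "_rates"),
                                    "initial_rate"),
         fold_table = screen_matrix(fold, paste0(raw$screen_name, "_folds"),
                                    "fold_change"),
         classes = classes, config = config),
    class = "kinetic_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(ds$rate_table, file.path(out_dir, "rate_table.csv"))
    write_table(ds$fold_table, file.path(out_dir, "fold_table.csv"))
    utils::write.csv(sve_table(ds$fold_table),
                     file.path(out_dir, "sve.csv"), row.names = FALSE)
  }
  ds
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  cat(sprintf("<kinetic_dataset> '%s': %d substrates x %d conditions, %d time points\n",
              x$raw$screen_name, nrow(x$rate_table$values),
              ncol(x$rate_table$values), length(x$raw$time_points)))
  invisible(x)
}

#' Specificity-versus-efficiency (SvE) table
#'
#' For every cell of an activity table, pairs the efficiency standard score
#' (the value scored across substrates within its protease column, a
#' surrogate for cleavage efficiency) with the specificity standard score
#' (scored across proteases within its substrate row, a surrogate for
#' specificity). Constant rows/columns yield scores of 0.
#'
#' @param x A `screen_matrix` (typically a fold-change or rate table) or a
#'   `kinetic_dataset` (its fold table is used by default).
#' @param value For a `kinetic_dataset`: `"fold"` or `"rate"`.
#' @return Data frame with columns `substrate`, `protease`, `raw_value`,
#'   `efficiency_z`, `specificity_z`.
#' @export
sve_table <- function(x, value = c("fold", "rate")) {
  if (inherits(x, "kinetic_dataset")) {
    value <- match.arg(value)
    x <- if (value == "fold") x$fold_table else x$rate_table
  }
  m <- as.matrix(x)
  eff <- apply(m, 2L, zscore_guard)
  spec <- t(apply(m, 1L, zscore_guard))
  if (nrow(m) == 1L) eff <- matrix(eff, nrow = 1L)
  if (ncol(m) == 1L) spec <- matrix(spec, ncol = 1L)
  data.frame(substrate = rep(rownames(m), times = ncol(m)),
             protease = rep(colnames(m), each = nrow(m)),
             raw_value = as.vector(m),
             efficiency_z = as.vector(eff),
             specificity_z = as.vector(spec),
             stringsAsFactors = FALSE)
}

#' Bidirectional hierarchical clustering of an activity table
#'
#' Agglomerative clustering performed independently on the rows (substrates
#' clustered by their protease profiles) and on the columns (proteases
#' clustered by their substrate profiles), returning both dendrograms and
#' their leaf orders for heatmap rendering. Rows may be standardized to
#' z-scores first, as is usual for cleavage heatmaps.
#'
#' @param x A `screen_matrix` or numeric matrix with at least 2 rows and 2
#'   columns.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param distance Distance measure for [stats::dist()].
#' @param standardize Z-score rows before clustering.
#' @return List of class `biclustering`: `row_order`, `col_order` (labels in
#'   dendrogram leaf order), `row_hclust`, `col_hclust`.
#' @export
cluster_bidirectional <- function(x, linkage = "average",
                                  distance = "euclidean",
                                  standardize = FALSE) {
  m <- as.matrix(x)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("bidirectional clustering needs at least 2 rows and 2 columns",
         call. = FALSE)
  }
  if (standardize) {
    m <- t(apply(m, 1L, zscore_guard))
    colnames(m) <- colnames(as.matrix(x))
  }
  rh <- stats::hclust(stats::dist(m, method = distance), method = linkage)
  ch <- stats::hclust(stats::dist(t(m), method = distance), method = linkage)
  structure(list(row_order = rownames(m)[rh$order],
                 col_order = colnames(m)[ch$order],
                 row_hclust = rh, col_hclust = ch),
            class = "biclustering")
}

#' Pairwise Spearman correlation of conditions
#'
#' Spearman rank correlation of every pair of conditions across substrates
#' (average ranks for ties), as a symmetric condition-by-condition matrix
#' with unit diagonal. Constant columns have undefined correlations and are
#' reported as `NA` with a warning.
#'
#' @param x A `screen_matrix` (typically the initial-rate table) or numeric
#'   matrix with at least 2 substrates.
#' @return Symmetric numeric matrix in `[-1, 1]`.
#' @export
spearman_matrix <- function(x) {
  m <- as.matrix(x)
  if (nrow(m) < 2L) {
    stop("Spearman correlation needs at least 2 substrates", call. = FALSE)
  }
  const <- apply(m, 2L, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(const, na.rm = TRUE)) {
    warning("correlation undefined for constant condition(s): ",
            paste(colnames(m)[which(const)], collapse = ", "), call. = FALSE)
  }
  C <- suppressWarnings(stats::cor(m, method = "spearman",
                                   use = "pairwise.complete.obs"))
  diag(C) <- 1
  C
}

#' Cleavage susceptibility by catalytic class
#'
#' For each substrate, counts how many proteases of each catalytic class
#' cleave it, i.e. reach a fold change at or above the threshold.
#' Unannotated proteases fall into class `"other"`.
#'
#' @param fold_table A `screen_matrix` of fold changes (or numeric matrix).
#' @param classes Named character vector: protease -> class (`metallo`,
#'   `serine`, `cysteine`, `aspartic`, ...).
#' @param threshold Fold-change threshold defining cleavage (default 1.5).
#' @return Integer matrix, substrates x classes.
#' @export
class_summary <- function(fold_table, classes, threshold = 1.5) {
  m <- as.matrix(fold_table)
  cls <- as.character(classes[match(label_key(colnames(m)),
                                    label_key(names(classes)))])
  cls[is.na(cls)] <- "other"
  lev <- unique(c(intersect(c("metallo", "serine", "cysteine", "aspartic"),
                            cls), setdiff(cls, c("metallo", "serine",
                                                 "cysteine", "aspartic"))))
  out <- matrix(0L, nrow(m), length(lev), dimnames = list(rownames(m), lev))
  for (j in seq_len(ncol(m))) {
    hit <- !is.na(m[, j]) & m[, j] >= threshold
    out[hit, cls[j]] <- out[hit, cls[j]] + 1L
  }
  out
}

#' Read protease catalytic-class annotations
#'
#' CSV with columns `protease,class`; class is one of `metallo`, `serine`,
#' `cysteine`, `aspartic`, `other`.
#'
#' @param path Path to the file.
#' @param delim Field delimiter.
#' @return Named character vector.
#' @export
read_class_annotations <- function(path, delim = ",") {
  df <- read_delim_frame(path, delim)
  stats::setNames(trim_label(df[[2]]), trim_label(df[[1]]))
}
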