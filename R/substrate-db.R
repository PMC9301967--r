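#' Build an aggregated enzyme-substrate database
#'
#' Aggregates one or more screen summary matrices plus a substrate-sequence
#' map into a single queryable structure. Substrates and proteases occurring
#' in several screens are identified case-insensitively; every screen keeps
#' its own values (no cross-screen averaging), and queries aggregate over
#' screens at ranking time.
#'
#' @param screens A `screen_matrix` or list of them. Screen names must be
#'   unique.
#' @param sequences A [sequence_map()] covering the screened substrates.
#' @param colors Optional `color_map`.
#' @param classes Optional named character vector mapping protease labels to
#'   catalytic classes (`metallo`, `serine`, `cysteine`, `aspartic`, ...).
#' @param missing_sequence `"warn"` (default) or `"error"`: policy when a
#'   screened substrate has no sequence.
#' @return An object of class `substrate_db`.
#' @export
build_database <- function(screens, sequences, colors = NULL, classes = NULL,
                           missing_sequence = c("warn", "error")) {
  missing_sequence <- match.arg(missing_sequence)
  if (inherits(screens, "screen_matrix")) screens <- list(screens)
  if (!is.list(screens) || length(screens) == 0L) {
    stop("`screens` must be a nonempty list of screen_matrix objects",
         call. = FALSE)
  }
  if (!all(vapply(screens, inherits, logical(1), "screen_matrix"))) {
    stop("every element of `screens` must be a screen_matrix", call. = FALSE)
  }
  nms <- vapply(screens, function(s) s$screen_name, character(1))
  if (anyDuplicated(nms)) {
    stop("screen names must be unique: ", paste(nms[duplicated(nms)],
                                                collapse = ", "),
         call. = FALSE)
  }
  names(screens) <- nms
  if (!inherits(sequences, "sequence_map")) sequences <- sequence_map(sequences)
  all_subs <- unique_by_key(unlist(lapply(screens, substrate_labels)))
  missing <- all_subs[!(label_key(all_subs) %in% label_key(names(sequences)))]
  if (length(missing) > 0) {
    msg <- paste0("no sequence for substrate(s): ",
                  paste(missing, collapse = ", "))
    if (missing_sequence == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  structure(list(screens = screens, sequences = sequences, colors = colors,
                 classes = classes),
            class = "substrate_db")
}

unique_by_key <- function(labels) {
  labels <- trim_label(labels)
  labels[!duplicated(label_key(labels))]
}

#' Unique substrate labels across all screens
#' @param db A `substrate_db`.
#' @return Character vector (first spelling encountered is kept).
#' @export
db_substrates <- function(db) {
  unique_by_key(unlist(lapply(db$screens, substrate_labels)))
}

#' Unique protease/condition labels across all screens
#' @param db A `substrate_db`.
#' @return Character vector.
#' @export
db_proteases <- function(db) {
  unique_by_key(unlist(lapply(db$screens, condition_labels)))
}

#' @export
print.substrate_db <- function(x, ...) {
  cat(sprintf("<substrate_db> %d screen(s), %d unique substrates, %d unique proteases\n",
              length(x$screens), length(db_substrates(x)),
              length(db_proteases(x))))
  invisible(x)
}

near_misses <- function(query, candidates, cutoff = 0.8) {
  sims <- vapply(label_key(candidates), function(cand)
    similarity_ratio(label_key(query), cand), numeric(1))
  candidates[sims >= cutoff]
}

# Per-screen efficiency/specificity standard scores for one protease column
# (or substrate row when transpose = TRUE).
screen_query_scores <- function(m, key, transpose = FALSE) {
  if (transpose) m <- t(m)
  idx <- match(key, label_key(colnames(m)))
  if (is.na(idx)) return(NULL)
  eff <- zscore_guard(m[, idx])                       # across entities in the column
  spec <- apply(m, 1L, function(row) zscore_guard(row)[idx])  # within each row
  data.frame(label = rownames(m), efficiency_z = eff, specificity_z = spec,
             stringsAsFactors = FALSE, row.names = NULL)
}

ranked_query <- function(db, query, top_k, direction = c("protease", "substrate")) {
  direction <- match.arg(direction)
  if (top_k < 1L) stop("`top_k` must be at least 1", call. = FALSE)
  key <- label_key(query)
  transpose <- direction == "substrate"
  per_screen <- list()
  for (nm in names(db$screens)) {
    sc <- screen_query_scores(db$screens[[nm]]$values, key, transpose)
    if (!is.null(sc)) {
      sc$screen <- nm
      per_screen[[nm]] <- sc
    }
  }
  if (length(per_screen) == 0L) {
    universe <- if (transpose) db_substrates(db) else db_proteases(db)
    hint <- near_misses(query, universe)
    stop_not_found(paste0(
      if (transpose) "substrate '" else "protease '", query,
      "' not found in any screen",
      if (length(hint) > 0) paste0("; did you mean: ",
                                   paste(hint, collapse = ", "), "?") else ""))
  }
  long <- do.call(rbind, per_screen)
  long$combined <- (long$efficiency_z + long$specificity_z) / 2
  keys <- label_key(long$label)
  agg <- do.call(rbind, lapply(split(long, keys), function(d) {
    data.frame(label = d$label[1],
               efficiency_z = mean(d$efficiency_z, na.rm = TRUE),
               specificity_z = mean(d$specificity_z, na.rm = TRUE),
               combined_score = mean(d$combined, na.rm = TRUE),
               n_screens = nrow(d), stringsAsFactors = FALSE)
  }))
  agg <- agg[is.finite(agg$combined_score), , drop = FALSE]
  ord <- order(-agg$combined_score, agg$label)
  agg <- agg[ord, , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  out <- utils::head(agg, min(top_k, nrow(agg)))
  structure(out, query = query, direction = direction, per_screen = long,
            class = c("ranked_query", "data.frame"))
}

#' Rank substrates for a protease of interest
#'
#' For every screen containing the protease (matched case-insensitively),
#' each substrate receives an efficiency standard score (its value scored
#' against all substrates in that protease's column) and a specificity
#' standard score (the value scored against all proteases in the substrate's
#' row). The combined score is the mean of the two, averaged over screens
#' where both are defined; substrates are ranked by combined score, ties
#' broken by label. Constant rows/columns yield standard scores of 0.
#'
#' @param db A `substrate_db`.
#' @param protease Protease name.
#' @param top_k Number of rows to return.
#' @return A `ranked_query` data frame with columns `label`,
#'   `efficiency_z`, `specificity_z`, `combined_score`, `n_screens`, `rank`;
#'   per-screen scores are attached as the `"per_screen"` attribute.
#' @export
query_protease <- function(db, protease, top_k = 10L) {
  ranked_query(db, protease, top_k, "protease")
}

#' Rank proteases for a substrate of interest
#'
#' Mirror of [query_protease()] with the axes swapped: identifies proteases
#' that robustly (efficiency) and specifically cleave the given substrate.
#'
#' @param db A `substrate_db`.
#' @param substrate Substrate name.
#' @param top_k Number of rows to return.
#' @return A `ranked_query` data frame; see [query_protease()].
#' @export
query_substrate <- function(db, substrate, top_k = 10L) {
  ranked_query(db, substrate, top_k, "substrate")
}

#' @export
print.ranked_query <- function(x, ...) {
  cat(sprintf("<ranked_query> '%s' (%s query), top %d\n",
              attr(x, "query"), attr(x, "direction"), nrow(x)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Summarize a substrate database
#'
#' Per-screen substrate/protease counts, the union counts across screens,
#' and (when protease classes are annotated) the catalytic-class
#' composition.
#'
#' @param db A `substrate_db`.
#' @return A list of class `substrate_db_summary` with elements `per_screen`
#'   (data frame), `n_substrates`, `n_proteases` and optionally
#'   `class_composition`.
#' @export
summarize_database <- function(db) {
  per_screen <- data.frame(
    screen = names(db$screens),
    n_substrates = vapply(db$screens, nrow, integer(1)),
    n_proteases = vapply(db$screens, ncol, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- list(per_screen = per_screen,
              n_substrates = length(db_substrates(db)),
              n_proteases = length(db_proteases(db)))
  if (!is.null(db$classes)) {
    cls <- db$classes[match(label_key(db_proteases(db)),
                            label_key(names(db$classes)))]
    cls[is.na(cls)] <- "other"
    out$class_composition <- table(class = cls)
  }
  structure(out, class = "substrate_db_summary")
}

#' @export
print.substrate_db_summary <- function(x, ...) {
  cat(sprintf("Union: %d substrates, %d proteases across %d screen(s)\n",
              x$n_substrates, x$n_proteases, nrow(x$per_screen)))
  print(x$per_screen)
  if (!is.null(x$class_composition)) print(x$class_composition)
  invisible(x)
}

#' Serialize a substrate database to JSON
#'
#' Writes screens (values, labels, measurement kinds), sequences, optional
#' colour map and provenance (source paths when known, write timestamp) into
#' one JSON document readable by [read_database()].
#'
#' @param db A `substrate_db`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_database <- function(db, path) {
  doc <- list(
    format = "proteasekit-substrate-db",
    version = 1L,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    screens = lapply(db$screens, function(s) list(
      screen_name = s$screen_name,
      measurement_kind = s$measurement_kind,
      substrates = rownames(s$values),
      conditions = colnames(s$values),
      values = unname(apply(s$values, 1L, as.numeric, simplify = FALSE)),
      source = attr(s, "source")
    )),
    sequences = as.list(stats::setNames(as.character(db$sequences),
                                        names(db$sequences))),
    colors = if (!is.null(db$colors))
      as.list(stats::setNames(as.character(db$colors), names(db$colors))),
    classes = if (!is.null(db$classes))
      as.list(stats::setNames(as.character(db$classes), names(db$classes)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a substrate database from JSON
#' @param path Path written by [write_database()].
#' @return A `substrate_db`.
#' @export
read_database <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "proteasekit-substrate-db")) {
    stop("not a proteasekit substrate database file: ", path, call. = FALSE)
  }
  screens <- lapply(doc$screens, function(s) {
    vals <- do.call(rbind, lapply(s$values, function(v)
      vapply(v, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
             numeric(1))))
    dimnames(vals) <- list(unlist(s$substrates), unlist(s$conditions))
    sm <- screen_matrix(vals, screen_name = s$screen_name,
                        measurement_kind = s$measurement_kind)
    attr(sm, "source") <- s$source
    sm
  })
  seqs <- sequence_map(unlist(doc$sequences))
  classes <- if (!is.null(doc$classes)) unlist(doc$classes)
  colors <- if (!is.null(doc$colors)) unlist(doc$colors)
  suppressWarnings(build_database(screens, seqs, colors = colors,
                                  classes = classes))
}
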