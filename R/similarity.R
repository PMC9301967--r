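# Peptide sequence similarity: Levenshtein edit distance, a normalized
# similarity ratio, and the partial ratio (best window match of the shorter
# sequence against the longer one). Edit distances are computed with
# utils::adist (generalized Levenshtein, unit costs).

#' Levenshtein edit distance between two sequences
#'
#' Minimum number of single-character insertions, deletions or substitutions
#' transforming one amino-acid sequence into the other. Comparison is
#' case-sensitive on the upper-cased sequences stored by the toolkit.
#'
#' @param a,b Character scalars (peptide sequences; may be empty).
#' @return Nonnegative integer distance.
#' @export
levenshtein_distance <- function(a, b) {
  as.integer(utils::adist(as.character(a), as.character(b))[1, 1])
}

#' Levenshtein similarity ratio
#'
#' Similarity on `[0, 1]` derived from the edit distance `d(a, b)`. The
#' default normalization is `1 - d / max(|a|, |b|)`; the `"indel"`
#' alternative `( |a| + |b| - d ) / ( |a| + |b| )` is offered for parity with
#' common fuzzy-matching libraries. Two empty sequences are defined as
#' identical (ratio 1).
#'
#' @param a,b Character scalars.
#' @param normalization `"max_length"` (default) or `"indel"`.
#' @return Similarity in `[0, 1]`; 1 if and only if the sequences are equal.
#' @export
similarity_ratio <- function(a, b, normalization = c("max_length", "indel")) {
  normalization <- match.arg(normalization)
  a <- as.character(a); b <- as.character(b)
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L && nb == 0L) return(1)
  d <- levenshtein_distance(a, b)
  if (normalization == "max_length") 1 - d / max(na, nb)
  else (na + nb - d) / (na + nb)
}

#' Partial similarity ratio
#'
#' Takes the shorter of the two sequences and compares it with every
#' contiguous window of the same length in the longer one, returning the best
#' [similarity_ratio()]. High when a short cleavage motif is embedded in a
#' longer substrate with different flanking spacers. Equal-length inputs
#' reduce to the plain similarity ratio.
#'
#' @inheritParams similarity_ratio
#' @return Similarity in `[0, 1]`.
#' @export
partial_ratio <- function(a, b, normalization = c("max_length", "indel")) {
  normalization <- match.arg(normalization)
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) <= nchar(b)) {
    s <- a; l <- b
  } else {
    s <- b; l <- a
  }
  m <- nchar(s)
  if (m == 0L) return(if (nchar(l) == 0L) 1 else 0)
  starts <- seq_len(nchar(l) - m + 1L)
  windows <- substring(l, starts, starts + m - 1L)
  d <- as.integer(utils::adist(s, windows))
  if (normalization == "max_length") max(1 - d / m)
  else max((2 * m - d) / (2 * m))
}

db_sequences <- function(db) {
  if (inherits(db, "substrate_db")) db$sequences
  else if (inherits(db, "sequence_map") ||
           (is.character(db) && !is.null(names(db)))) db
  else stop("expected a substrate_db or sequence_map", call. = FALSE)
}

#' Retrieve substrates most similar to a query sequence
#'
#' Scores every substrate sequence in the database against the query with
#' both similarity metrics and returns the top `k` hits under the chosen
#' one. Ties are broken by the secondary metric (descending), then by label.
#'
#' @param db A `substrate_db` or `sequence_map`.
#' @param query Query peptide sequence.
#' @param k Number of hits to return; if larger than the database, all
#'   substrates are returned (still sorted).
#' @param metric `"ratio"` or `"partial_ratio"`.
#' @return Data frame with columns `substrate`, `sequence`, `edit_distance`,
#'   `ratio`, `partial_ratio`, sorted best-first.
#' @export
query_sequence <- function(db, query, k = 5L,
                           metric = c("ratio", "partial_ratio")) {
  metric <- match.arg(metric)
  seqs <- db_sequences(db)
  if (length(seqs) == 0L) stop("database holds no sequences", call. = FALSE)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  query <- toupper(trim_label(query))
  hits <- data.frame(
    substrate = names(seqs),
    sequence = as.character(seqs),
    edit_distance = as.integer(utils::adist(query, as.character(seqs))),
    ratio = vapply(as.character(seqs), function(s)
      similarity_ratio(query, s), numeric(1), USE.NAMES = FALSE),
    partial_ratio = vapply(as.character(seqs), function(s)
      partial_ratio(query, s), numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  secondary <- setdiff(c("ratio", "partial_ratio"), metric)
  ord <- order(-hits[[metric]], -hits[[secondary]], hits$substrate)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  utils::head(hits, min(k, nrow(hits)))
}

#' Find all substrates containing a k-mer motif
#'
#' Case-insensitive exact substring search for a motif (e.g. the
#' metalloprotease cleavage motif `"PLGL"`) across every sequence in the
#' database. All match start positions are reported 0-based, overlapping
#' matches included.
#'
#' @param db A `substrate_db` or `sequence_map`.
#' @param kmer Nonempty motif string.
#' @return Data frame with one row per matching substrate: `substrate`,
#'   `sequence`, `n_matches`, and a list column `positions` of 0-based match
#'   starts. Zero rows when nothing matches.
#' @export
search_kmer <- function(db, kmer) {
  kmer <- toupper(trim_label(kmer))
  if (nchar(kmer) == 0L) stop("`kmer` must be nonempty", call. = FALSE)
  seqs <- db_sequences(db)
  pat <- paste0("(?=", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", kmer), ")")
  pos <- lapply(toupper(as.character(seqs)), function(s) {
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  })
  hit <- lengths(pos) > 0L
  out <- data.frame(substrate = names(seqs)[hit],
                    sequence = as.character(seqs)[hit],
                    n_matches = lengths(pos)[hit],
                    stringsAsFactors = FALSE)
  out$positions <- pos[hit]
  rownames(out) <- NULL
  out
}

#' Pairwise sequence-similarity matrix with hierarchical clustering
#'
#' Computes the full symmetric matrix of pairwise similarity scores between
#' all substrate sequences and clusters it hierarchically on the distance
#' `1 - similarity`. A compact summary of sequence diversity/redundancy in a
#' substrate library.
#'
#' @param db A `substrate_db` or `sequence_map` with at least two sequences.
#' @param metric `"ratio"` or `"partial_ratio"`.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return An object of class `similarity_clustering`: list with the
#'   similarity `matrix` (diagonal exactly 1), the dendrogram leaf `order`
#'   (labels), and the `hclust` tree.
#' @export
similarity_matrix <- function(db, metric = c("ratio", "partial_ratio"),
                              linkage = "average") {
  metric <- match.arg(metric)
  seqs <- db_sequences(db)
  if (length(seqs) < 2L) {
    stop("similarity matrix needs at least two sequences", call. = FALSE)
  }
  s <- as.character(seqs)
  n <- length(s)
  if (metric == "ratio") {
    d <- utils::adist(s, s)
    lens <- outer(nchar(s), nchar(s), pmax)
    M <- 1 - d / lens
  } else {
    M <- diag(1, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        M[i, j] <- M[j, i] <- partial_ratio(s[i], s[j])
      }
    }
  }
  diag(M) <- 1
  dimnames(M) <- list(names(seqs), names(seqs))
  hc <- stats::hclust(stats::as.dist(1 - M), method = linkage)
  structure(list(matrix = M, order = names(seqs)[hc$order], hclust = hc,
                 metric = metric, linkage = linkage),
            class = "similarity_clustering")
}

#' @export
print.similarity_clustering <- function(x, ...) {
  cat(sprintf("<similarity_clustering> %d sequences, metric = %s, linkage = %s\n",
              nrow(x$matrix), x$metric, x$linkage))
  invisible(x)
}
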