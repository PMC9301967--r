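# Independent oracles and small fixture builders used across tests.

# Memoized recursive edit distance: the textbook recurrence, independent of
# the C implementation behind the package.
lev_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- if (A[i] == B[j]) 0L else 1L
    v <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
             rec(i - 1L, j - 1L) + cost)
    memo[[key]] <- v
    v
  }
  rec(length(A), length(B))
}

# Explicit all-windows maximization for the partial ratio.
partial_oracle <- function(a, b) {
  if (nchar(a) > nchar(b)) {
    tmp <- a; a <- b; b <- tmp
  }
  m <- nchar(a)
  if (m == 0L) return(if (nchar(b) == 0L) 1 else 0)
  best <- 0
  for (s in seq_len(nchar(b) - m + 1L)) {
    w <- substr(b, s, s + m - 1L)
    best <- max(best, 1 - lev_oracle(a, w) / m)
  }
  best
}

random_peptide <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len,
               replace = TRUE), collapse = "")
}

# Small labelled screen matrix with reproducible values.
toy_screen <- function(n = 3L, k = 3L, seed = 42L, name = "toy",
                       kind = "fold_change") {
  set.seed(seed)
  m <- matrix(round(stats::runif(n * k, 0.5, 5), 3), n, k,
              dimnames = list(paste0("S", seq_len(n)),
                              paste0("P", seq_len(k))))
  screen_matrix(m, name, kind)
}

toy_sequences <- function(labels) {
  sequence_map(stats::setNames(
    vapply(seq_along(labels), function(i) {
      set.seed(1000L + i)
      random_peptide(8L)
    }, character(1)),
    labels))
}
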