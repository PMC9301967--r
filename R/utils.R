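# Shared internal helpers.

trim_label <- function(x) gsub("^[[:space:]]+|[[:space:]]+$", "", as.character(x))

# Case-insensitive matching key: labels keep their original spelling
# everywhere, but are matched after whitespace trim + case fold.
label_key <- function(x) tolower(trim_label(x))

#' Standard score with a zero-variance guard
#'
#' Computes `(x - mean(x)) / sd(x)` (sample standard deviation). If the
#' vector is constant, has fewer than two non-missing values, or has zero
#' variance, all standard scores are defined as 0 rather than `NaN`, so that
#' rankings built on them remain total. Missing values stay missing.
#'
#' @param x Numeric vector.
#' @return Numeric vector of standard scores, same length as `x`.
#' @export
zscore_guard <- function(x) {
  x <- as.numeric(x)
  z <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  if (sum(ok) < 2L) {
    z[ok] <- 0
    return(z)
  }
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s == 0) {
    z[ok] <- 0
    return(z)
  }
  z[ok] <- (x[ok] - mean(x[ok])) / s
  z
}

# Derive a reproducible sub-seed from a master seed and a component id, so
# that adding one generator call does not perturb draws made by another.
# Kept strictly below 2^31 - 1.
substream_seed <- function(seed, id) {
  codes <- utf8ToInt(as.character(id))
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((as.numeric(seed) %% 1048573) * 2048 + h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seeded functions restore the caller's RNG stream on exit, so interleaving
# package calls with user-level sample()/rnorm() draws stays well defined.
# Call at the top of any function that sets seeds internally.
preserve_rng <- function(envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  expr <- if (is.null(old)) {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(old)
}

stop_not_found <- function(msg) {
  stop(errorCondition(msg, class = c("paa_not_found", "error", "condition")))
}
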