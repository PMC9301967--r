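# Seeded synthetic-data generators with known ground truth for every input
# kind the toolkit reads: kinetic screens, reporter datasets, substrate
# libraries. All generators are pure functions of (spec, seed); one master
# seed fans out to per-component substreams so adding one generator call
# does not perturb draws made by another.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a synthetic kinetic screen with known ground truth
#'
#' Simulates fluorogenic substrate cleavage progress curves. Each
#' (substrate, protease) pair receives an amplitude `A`, rate constant
#' `k_rc` (per minute) and baseline `F0` drawn uniformly from the given
#' ranges; the noiseless curve is the saturating exponential
#' `F(t) = F0 + A (1 - exp(-k_rc t))` (or its linear early phase
#' `F0 + A k_rc t` under `model = "linear"`), so the true initial rate is
#' `A * k_rc` in both cases. Gaussian noise is added per point and the
#' signal truncated at zero.
#'
#' @param n_substrates,n_proteases Screen dimensions.
#' @param time_points Increasing sampling times in minutes.
#' @param A_range,k_range,F0_range Ranges for amplitude (intensity units),
#'   rate constant (min^-1) and baseline fluorescence.
#' @param noise_sd Gaussian noise standard deviation; interpreted as a
#'   fraction of each pair's amplitude when `noise_relative = TRUE`.
#' @param noise_relative Scale `noise_sd` by the amplitude.
#' @param n_replicates Replicate wells per pair (default 3).
#' @param model `"exponential"` (default) or `"linear"` early-phase-only.
#' @param seed Integer master seed.
#' @return List with `raw` (a [kinetic_raw()]) and `truth` (data frame of
#'   per-pair `A`, `k_rc`, `F0`, `noise_sd`, `true_rate`).
#' @export
gen_kinetic_screen <- function(n_substrates, n_proteases,
                               time_points = seq(0, 60, by = 5),
                               A_range = c(100, 500),
                               k_range = c(0.002, 0.008),
                               F0_range = c(40, 60),
                               noise_sd = 0, noise_relative = FALSE,
                               n_replicates = 3L,
                               model = c("exponential", "linear"),
                               seed = 1L) {
  model <- match.arg(model)
  preserve_rng()
  if (n_substrates < 1L || n_proteases < 1L || n_replicates < 1L) {
    stop("dimensions and replicate count must be at least 1", call. = FALSE)
  }
  time_points <- as.numeric(time_points)
  if (any(diff(time_points) <= 0)) {
    stop("`time_points` must be strictly increasing", call. = FALSE)
  }
  if (any(c(A_range, k_range, F0_range) < 0) || noise_sd < 0) {
    stop("amplitudes, rates, baselines and noise must be nonnegative",
         call. = FALSE)
  }
  subs <- paste0("S", seq_len(n_substrates))
  prots <- paste0("P", seq_len(n_proteases))
  npair <- n_substrates * n_proteases
  set.seed(substream_seed(seed, "kinetic_truth"))
  truth <- data.frame(
    substrate = rep(subs, times = n_proteases),
    protease = rep(prots, each = n_substrates),
    A = stats::runif(npair, A_range[1], A_range[2]),
    k_rc = stats::runif(npair, k_range[1], k_range[2]),
    F0 = stats::runif(npair, F0_range[1], F0_range[2]),
    stringsAsFactors = FALSE)
  truth$noise_sd <- if (noise_relative) noise_sd * truth$A else
    rep(noise_sd, npair)
  truth$true_rate <- truth$A * truth$k_rc
  nt <- length(time_points)
  set.seed(substream_seed(seed, "kinetic_noise"))
  rows <- vector("list", npair * n_replicates)
  meta_sub <- meta_prot <- character(npair * n_replicates)
  meta_rep <- integer(npair * n_replicates)
  i <- 0L
  for (p in seq_len(npair)) {
    clean <- if (model == "exponential") {
      truth$F0[p] + truth$A[p] * (1 - exp(-truth$k_rc[p] * time_points))
    } else {
      truth$F0[p] + truth$true_rate[p] * time_points
    }
    for (r in seq_len(n_replicates)) {
      i <- i + 1L
      noisy <- clean + stats::rnorm(nt, 0, truth$noise_sd[p])
      rows[[i]] <- pmax(noisy, 0)
      meta_sub[i] <- truth$substrate[p]
      meta_prot[i] <- truth$protease[p]
      meta_rep[i] <- r
    }
  }
  raw <- kinetic_raw(time_points, do.call(rbind, rows),
                     substrate = meta_sub, condition = meta_prot,
                     replicate = meta_rep,
                     screen_name = sprintf("synthetic_%dx%d", n_substrates,
                                           n_proteases))
  list(raw = raw, truth = truth)
}

#' Generate a synthetic reporter dataset with known ground truth
#'
#' Emulates multiplexed urinary reporter concentrations: each reporter has
#' a log-scale base level; each class multiplies selected reporters by an
#' effect size; measured values are lognormal,
#' `exp(Normal(log(base * effect), sd))`, hence strictly positive.
#'
#' @param n_per_class Named integer vector, e.g.
#'   `c(Control = 10, KP = 10)`.
#' @param n_reporters Number of reporters (default 14, a typical multiplexed
#'   panel size).
#' @param effects Named list mapping a class name to a length-`n_reporters`
#'   vector of positive multipliers; classes not listed (and the default)
#'   have all effects 1.
#' @param log_mean,log_base_sd Log-scale location of reporter base levels
#'   and their reporter-to-reporter spread.
#' @param sd Lognormal noise standard deviation on the log scale (default
#'   0.25, a realistic ~25% coefficient of variation).
#' @param seed Integer master seed.
#' @return List with `dataset` (a [reporter_dataset()]) and `truth`
#'   (base levels, effect multipliers, sd, seed).
#' @export
gen_reporter_dataset <- function(n_per_class = c(Control = 10L, KP = 10L),
                                 n_reporters = 14L, effects = NULL,
                                 log_mean = log(100), log_base_sd = 0.25,
                                 sd = 0.25, seed = 1L) {
  preserve_rng()
  if (is.null(names(n_per_class)) || any(n_per_class < 1L)) {
    stop("`n_per_class` must be a named vector of positive counts",
         call. = FALSE)
  }
  classes <- names(n_per_class)
  eff <- matrix(1, length(classes), n_reporters,
                dimnames = list(classes, NULL))
  for (cl in names(effects %||% list())) {
    if (!cl %in% classes) {
      stop("effects given for unknown class '", cl, "'", call. = FALSE)
    }
    v <- effects[[cl]]
    if (length(v) != n_reporters || any(v <= 0)) {
      stop("effect multipliers must be positive and length ", n_reporters,
           call. = FALSE)
    }
    eff[cl, ] <- v
  }
  set.seed(substream_seed(seed, "reporter_truth"))
  base <- exp(stats::rnorm(n_reporters, log_mean, log_base_sd))
  set.seed(substream_seed(seed, "reporter_noise"))
  n <- sum(n_per_class)
  cls <- rep(classes, times = n_per_class)
  vals <- matrix(NA_real_, n, n_reporters)
  for (i in seq_len(n)) {
    mu <- log(base) + log(eff[cls[i], ])
    vals[i, ] <- exp(stats::rnorm(n_reporters, mu, sd))
  }
  ids <- unlist(lapply(classes, function(cl)
    paste0(cl, "_", seq_len(n_per_class[[cl]]))))
  reporters <- paste0("R", seq_len(n_reporters))
  ds <- reporter_dataset(vals, class_labels = cls, sample_ids = ids,
                         reporter_ids = reporters)
  list(dataset = ds,
       truth = list(base = stats::setNames(base, reporters),
                    effects = `colnames<-`(eff, reporters), sd = sd,
                    seed = seed))
}

random_peptides <- function(n, length, alphabet) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, length, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a synthetic substrate library with planted motifs
#'
#' Random peptide sequences over the given alphabet in which each requested
#' motif occurs in exactly `count` sequences (planted at a random position);
#' all other sequences are rejection-sampled to contain none of the motifs.
#'
#' @param n Library size.
#' @param length Sequence length.
#' @param alphabet Character vector of residues (default: the 20 standard
#'   amino acids).
#' @param motifs Named integer vector, motif -> number of sequences that
#'   must contain it (e.g. `c(PLGL = 3)`).
#' @param seed Integer master seed.
#' @return A [sequence_map()] with labels `S1..Sn`; planted assignments are
#'   attached as the `"planted"` attribute (named list motif -> labels).
#' @export
gen_substrate_library <- function(n, length = 8L, alphabet = AA_STANDARD,
                                  motifs = NULL, seed = 1L) {
  preserve_rng()
  motifs <- motifs %||% integer(0)
  if (length(motifs) > 0 && (is.null(names(motifs)) || any(motifs < 0))) {
    stop("`motifs` must be a named vector of nonnegative counts",
         call. = FALSE)
  }
  if (any(nchar(names(motifs)) > length)) {
    stop("motif longer than the sequence length", call. = FALSE)
  }
  if (sum(motifs) > n) {
    stop("infeasible spec: motif counts exceed the library size",
         call. = FALSE)
  }
  set.seed(substream_seed(seed, "library"))
  motif_names <- toupper(names(motifs))
  contains_any <- function(s, pats) any(vapply(pats, grepl, logical(1),
                                               x = s, fixed = TRUE))
  draw_clean <- function(avoid) {
    for (try in seq_len(10000L)) {
      s <- random_peptides(1L, length, alphabet)
      if (length(avoid) == 0L || !contains_any(s, avoid)) return(s)
    }
    stop("could not sample a sequence avoiding the motifs; spec infeasible",
         call. = FALSE)
  }
  seqs <- character(n)
  slots <- sample.int(n)                   # random disjoint planting slots
  planted <- list()
  used <- 0L
  for (m in seq_along(motifs)) {
    mot <- motif_names[m]
    idx <- slots[seq_len(motifs[m]) + used]
    used <- used + motifs[m]
    for (i in idx) {
      repeat {
        s <- draw_clean(motif_names)
        pos <- sample.int(length - nchar(mot) + 1L, 1L)
        s <- paste0(substr(s, 1L, pos - 1L), mot,
                    substr(s, pos + nchar(mot), length))
        others <- setdiff(motif_names, mot)
        if (length(others) == 0L || !contains_any(s, others)) break
      }
      seqs[i] <- s
    }
    planted[[mot]] <- paste0("S", sort(idx))
  }
  for (i in which(seqs == "")) seqs[i] <- draw_clean(motif_names)
  out <- sequence_map(stats::setNames(seqs, paste0("S", seq_len(n))))
  attr(out, "planted") <- planted
  out
}

#' Write synthetic fixtures to disk
#'
#' Convenience wrapper generating one kinetic screen and one reporter
#' dataset and writing them in the toolkit's CSV dialects, for use as
#' external fixtures or demo inputs.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param ... Passed on to [gen_kinetic_screen()].
#' @return Invisibly, the vector of written paths.
#' @export
write_synthetic_fixtures <- function(dir, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kin <- gen_kinetic_screen(4L, 3L, seed = seed, ...)
  rep <- gen_reporter_dataset(seed = seed)
  paths <- c(
    kinetic = file.path(dir, "kinetic_raw.csv"),
    reporters = file.path(dir, "reporters.csv"),
    truth = file.path(dir, "kinetic_truth.csv")
  )
  write_kinetic_raw(kin$raw, paths[["kinetic"]])
  write_reporter_csv(rep$dataset, paths[["reporters"]])
  utils::write.csv(kin$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
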