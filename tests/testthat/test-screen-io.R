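# Readers/writers and validated containers for screen, sequence and kinetic
# files.

test_that("screen matrices round-trip through CSV", {
  # minimal 1x1
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",MMP13", "S1,5.0"), p)
  sm <- read_screen_matrix(p)
  expect_equal(dim(sm), c(1L, 1L))
  expect_equal(unname(sm$values[1, 1]), 5.0)
  expect_equal(substrate_labels(sm), "S1")
  expect_equal(condition_labels(sm), "MMP13")

  # random 3x2 write -> read reproduces values and labels
  set.seed(11)
  m <- matrix(stats::runif(6, 0, 100), 3, 2,
              dimnames = list(c("S1", "S2", "S3"), c("MMP1", "MMP9")))
  sm0 <- screen_matrix(m, "rt", "raw_intensity")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_table(sm0, p2)
  back <- read_screen_matrix(p2, screen_name = "rt")
  expect_equal(back$values, sm0$values, tolerance = 1e-9)
  expect_identical(dimnames(back$values), dimnames(sm0$values))

  # 5x7 random round trip within 1e-9, with a missing cell preserved as NA
  set.seed(12)
  m2 <- matrix(stats::runif(35, 0, 1e4), 5, 7,
               dimnames = list(paste0("S", 1:5), paste0("P", 1:7)))
  m2[2, 3] <- NA
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_table(m2, p3)
  expect_equal(read_screen_matrix(p3)$values, m2, tolerance = 1e-9)
})

test_that("write_table handles degenerate tables", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_table(matrix(numeric(0), 0, 0), p)
  expect_length(readLines(p), 1L)  # header-only file

  m <- diag(2)
  dimnames(m) <- list(c("a", "b"), c("x", "y"))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_table(m, p2)
  expect_equal(read_screen_matrix(p2)$values, m)
})

test_that("malformed screen files raise informative errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2", "3,4"), p)  # all-numeric first row: no header
  expect_error(read_screen_matrix(p), "header")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",P1,P2", "S1,1.5,abc"), p2)
  expect_error(read_screen_matrix(p2), "S1.*P2|P2.*S1")

  expect_error(read_screen_matrix(withr::local_tempfile()), "not found")
})

test_that("duplicate labels follow the configured policy", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",P1", "S1,1", " s1 ,3", "S2,5"), p)
  expect_error(read_screen_matrix(p), "duplicate")
  sm <- read_screen_matrix(p, duplicate_policy = "mean")
  expect_equal(dim(sm), c(2L, 1L))
  expect_equal(unname(sm$values["S1", 1]), 2)  # mean of 1 and 3
})

test_that("label normalization trims whitespace and is idempotent", {
  m <- matrix(1:4, 2, 2, dimnames = list(c(" S1", "S2 "), c("P1", " P2 ")))
  sm <- screen_matrix(m, "t", "raw_intensity")
  expect_identical(substrate_labels(sm), c("S1", "S2"))
  expect_identical(condition_labels(sm), c("P1", "P2"))
  sm2 <- screen_matrix(sm$values, "t", "raw_intensity")
  expect_identical(dimnames(sm2$values), dimnames(sm$values))
})

test_that("screen_matrix enforces its invariants", {
  m <- matrix(c(-1, 2, 3, 4), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(screen_matrix(m, "k", "raw_intensity"), "negative")
  expect_silent(screen_matrix(m, "k", "initial_rate"))  # rates may be < 0
  dup <- matrix(1:4, 2, 2, dimnames = list(c("a", "A"), c("x", "y")))
  expect_error(screen_matrix(dup, "k", "raw_intensity"), "duplicate")
})

test_that("sequence maps validate, deduplicate and round-trip", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,sequence", "S1,GGPLGL"), p)
  sm <- read_sequence_map(p)
  expect_length(sm, 1L)
  expect_equal(unname(sm["S1"]), "GGPLGL")

  # duplicate label with identical sequence is deduplicated
  writeLines(c("label,sequence", "S1,GGPLGL", "S1,GGPLGL"), p)
  expect_length(read_sequence_map(p), 1L)

  # conflicting sequence is an error; empty sequence is an error
  writeLines(c("label,sequence", "S1,GGPLGL", "S1,AAAA"), p)
  expect_error(read_sequence_map(p), "conflicting")
  expect_error(sequence_map(c(S1 = "")), "empty")

  # 10-entry generated fixture round-trips every pair
  set.seed(21)
  seqs <- stats::setNames(vapply(1:10, function(i) random_peptide(8L),
                                 character(1)), paste0("S", 1:10))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_sequence_map(sequence_map(seqs), p2)
  back <- read_sequence_map(p2)
  expect_equal(stats::setNames(as.character(back), names(back)), seqs)
})

test_that("non-standard residues are kept but flagged", {
  expect_warning(sm <- sequence_map(c(S1 = "GGPLXL")), "non-standard")
  expect_identical(attr(sm, "nonstandard"), "S1")
})

test_that("kinetic raw files parse, validate and round-trip", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("substrate,condition,replicate,0,1,2",
               "S1,MMP13,1,10,20,30"), p)
  kr <- read_kinetic_raw(p)
  expect_equal(kr$time_points, c(0, 1, 2))
  expect_equal(unname(kr$values[1, ]), c(10, 20, 30))

  # two replicates of the same substrate live under indices 1, 2
  writeLines(c("substrate,condition,replicate,0,1,2",
               "S1,MMP13,1,10,20,30", "S1,MMP13,2,12,22,32"), p)
  kr2 <- read_kinetic_raw(p)
  expect_equal(sort(kr2$series$replicate), c(1L, 2L))

  # replicate indices must be contiguous from 1
  writeLines(c("substrate,condition,replicate,0,1,2",
               "S1,MMP13,1,10,20,30", "S1,MMP13,3,12,22,32"), p)
  expect_error(read_kinetic_raw(p), "contiguous")

  # shuffled time columns come back sorted; duplicated times are an error
  writeLines(c("substrate,condition,replicate,2,0,1",
               "S1,MMP13,1,30,10,20"), p)
  kr3 <- read_kinetic_raw(p)
  expect_equal(kr3$time_points, c(0, 1, 2))
  expect_equal(unname(kr3$values[1, ]), c(10, 20, 30))
  writeLines(c("substrate,condition,replicate,0,0,1",
               "S1,MMP13,1,10,11,20"), p)
  expect_error(read_kinetic_raw(p), "strictly increasing")

  # generated 4x6 fixture round-trips exactly
  g <- gen_kinetic_screen(4, 1, time_points = seq(0, 25, 5), noise_sd = 2,
                          n_replicates = 2, seed = 5)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_kinetic_raw(g$raw, p2)
  back <- read_kinetic_raw(p2)
  expect_equal(back$time_points, g$raw$time_points)
  expect_equal(back$values, g$raw$values, tolerance = 1e-9)
  expect_equal(back$series, g$raw$series)
})

test_that("kinetic layout specs map identifier columns", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("peptide,enzyme,well,0,5", "S1,P1,1,10,30"), p)
  lay <- list(substrate = "peptide", condition = "enzyme",
              replicate = "well")
  kr <- read_kinetic_raw(p, layout = lay)
  expect_equal(kr$series$substrate, "S1")
  # same spec via a JSON sidecar file
  pj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(lay, pj, auto_unbox = TRUE)
  expect_equal(read_kinetic_raw(p, layout = pj)$series$condition, "P1")
  expect_error(read_kinetic_raw(p), "identifier column")
})

test_that("validate_activity_file reports verdicts without raising", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",P1", "S1,1.0"), p)
  expect_true(validate_activity_file(p, "screen")$ok)
  writeLines(c("1,2", "3,4"), p)
  v <- validate_activity_file(p, "screen")
  expect_false(v$ok)
  expect_match(v$message, "header")
})
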