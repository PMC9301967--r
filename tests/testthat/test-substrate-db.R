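# Database aggregation and efficiency/specificity ranked queries.

make_db <- function(values, name = "s1", seqs = NULL) {
  sm <- screen_matrix(values, name, "fold_change")
  seqs <- seqs %||% toy_sequences(rownames(values))
  build_database(list(sm), seqs)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("databases aggregate screens and count unions", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("S1", "S2"), c("P1", "P2")))
  db <- make_db(m)
  expect_equal(db_substrates(db), c("S1", "S2"))
  expect_equal(db_proteases(db), c("P1", "P2"))

  # two screens sharing 1 of 3 substrates -> 5 unique substrates
  m1 <- matrix(1:6, 3, 2, dimnames = list(c("S1", "S2", "S3"),
                                          c("P1", "P2")))
  m2 <- matrix(1:6, 3, 2, dimnames = list(c("S3", "S4", "S5"),
                                          c("P2", "P3")))
  db2 <- build_database(
    list(screen_matrix(m1, "a", "fold_change"),
         screen_matrix(m2, "b", "fold_change")),
    toy_sequences(paste0("S", 1:5)))
  expect_length(db_substrates(db2), 5L)
  expect_length(db_proteases(db2), 3L)

  s <- summarize_database(db2)
  expect_equal(s$n_substrates, 5L)
  expect_equal(s$n_proteases, 3L)
  expect_equal(s$per_screen$n_substrates, c(3L, 3L))

  # disjoint screens: union is the sum
  m3 <- matrix(1:4, 2, 2, dimnames = list(c("X1", "X2"), c("Q1", "Q2")))
  db3 <- build_database(
    list(screen_matrix(m, "a", "fold_change"),
         screen_matrix(m3, "b", "fold_change")),
    toy_sequences(c("S1", "S2", "X1", "X2")))
  s3 <- summarize_database(db3)
  expect_equal(s3$n_substrates, 4L)
  expect_equal(s3$n_proteases, 4L)
})

test_that("database construction enforces its preconditions", {
  expect_error(build_database(list(), toy_sequences("S1")), "nonempty")
  m <- matrix(1:4, 2, 2, dimnames = list(c("S1", "S2"), c("P1", "P2")))
  sm <- screen_matrix(m, "a", "fold_change")
  expect_error(build_database(list(sm, sm), toy_sequences(c("S1", "S2"))),
               "unique")
  expect_warning(build_database(list(sm), toy_sequences("S1")),
                 "no sequence.*S2")
  expect_error(build_database(list(sm), toy_sequences("S1"),
                              missing_sequence = "error"), "S2")
})

test_that("protease queries rank by combined efficiency/specificity z", {
  # 1x1: single substrate at rank 1 with combined score 0
  m1 <- matrix(5, 1, 1, dimnames = list("S1", "P1"))
  q1 <- query_protease(make_db(m1), "P1", top_k = 5)
  expect_equal(q1$label, "S1")
  expect_equal(q1$combined_score, 0)
  expect_equal(q1$rank, 1L)

  # 3x3 with one dominant cell: hand-computed z oracle
  m <- matrix(1, 3, 3, dimnames = list(paste0("S", 1:3), paste0("P", 1:3)))
  m["S2", "P2"] <- 10
  db <- make_db(m)
  q <- query_protease(db, "P2", top_k = 3)
  expect_equal(q$label[1], "S2")
  col <- m[, "P2"]; row <- m["S2", ]
  eff_or <- (10 - mean(col)) / stats::sd(col)
  spec_or <- (10 - mean(row)) / stats::sd(row)
  expect_equal(q$efficiency_z[1], eff_or)
  expect_equal(q$specificity_z[1], spec_or)
  expect_equal(q$combined_score[1], (eff_or + spec_or) / 2)
  expect_equal(q$rank, 1:3)

  # matching is case-insensitive; a constant column gives efficiency z 0
  flat <- matrix(c(2, 2, 2, 1, 5, 9), 3, 2,
                 dimnames = list(paste0("S", 1:3), c("Pc", "Pv")))
  qf <- query_protease(make_db(flat), "pc", top_k = 3)
  expect_equal(qf$efficiency_z, rep(0, 3))

  # mirror query: the dominant substrate names its protease first
  qs <- query_substrate(db, "S2", top_k = 3)
  expect_equal(qs$label[1], "P2")
  expect_error(query_protease(db, "P2", top_k = 0), "at least 1")
})

test_that("rankings are invariant to screen row/column permutation", {
  set.seed(55)
  m <- matrix(stats::runif(20, 0, 8), 5, 4,
              dimnames = list(paste0("S", 1:5), paste0("P", 1:4)))
  db <- make_db(m)
  perm <- m[sample(5), sample(4)]
  db_p <- make_db(perm, seqs = toy_sequences(paste0("S", 1:5)))
  q <- query_protease(db, "P3", top_k = 5)
  qp <- query_protease(db_p, "P3", top_k = 5)
  expect_identical(q$label, qp$label)
  expect_equal(q$combined_score, qp$combined_score)
})

test_that("queries across multiple screens average per-screen scores", {
  m1 <- matrix(c(1, 2, 4, 1, 1, 1), 3, 2,
               dimnames = list(paste0("S", 1:3), c("P1", "P2")))
  m2 <- matrix(c(2, 8, 2, 2, 2, 2), 3, 2,
               dimnames = list(paste0("S", 1:3), c("P1", "P3")))
  db <- build_database(list(screen_matrix(m1, "a", "fold_change"),
                            screen_matrix(m2, "b", "fold_change")),
                       toy_sequences(paste0("S", 1:3)))
  q <- query_protease(db, "P1", top_k = 3)
  expect_equal(q$n_screens, rep(2L, 3))
  per <- attr(q, "per_screen")
  for (lab in q$label) {
    expect_equal(q$combined_score[q$label == lab],
                 mean(per$combined[per$label == lab]))
  }
})

test_that("unknown names raise not-found errors with near-miss hints", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("S1", "S2"), c("MMP13", "MMP9")))
  db <- make_db(m)
  err <- tryCatch(query_protease(db, "MMP12", 3), error = identity)
  expect_s3_class(err, "paa_not_found")
  expect_match(conditionMessage(err), "MMP1[39]")
})

test_that("databases serialize to JSON and back", {
  m <- matrix(c(1.5, NA, 3.25, 4), 2, 2,
              dimnames = list(c("S1", "S2"), c("P1", "P2")))
  sm <- screen_matrix(m, "screenA", "fold_change")
  db <- build_database(list(sm), toy_sequences(c("S1", "S2")),
                       classes = c(P1 = "metallo", P2 = "serine"))
  p <- withr::local_tempfile(fileext = ".json")
  write_database(db, p)
  back <- read_database(p)
  expect_equal(back$screens$screenA$values, m)
  expect_equal(as.character(back$sequences), as.character(db$sequences))
  expect_equal(back$classes, db$classes)
  expect_equal(summarize_database(back)$class_composition,
               summarize_database(db)$class_composition)
})
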