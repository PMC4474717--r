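test_that("hit selection filters strictly, sorts ascending, truncates to S", {
  h <- alignment_hits(query_id = rep("q", 12), subject_id = sprintf("s%02d", 1:12),
                      e_value = 12:1,
                      query_start = 1L, query_end = 3L,
                      subject_start = 1L, subject_end = 3L,
                      aligned_query = "AAA", aligned_subject = "AAA")
  sel <- select_hits(h, e_threshold = 10, S = 10)
  expect_equal(nrow(sel), 9L)                     # strict: e < 10
  expect_equal(sel$e_value, as.numeric(1:9))      # ascending
  sel3 <- select_hits(h, e_threshold = 10, S = 3)
  expect_equal(sel3$e_value, as.numeric(1:3))
  expect_equal(nrow(select_hits(alignment_hits())), 0L)
  # ties broken by (subject_id, query_start) for a stable top-S
  tie <- alignment_hits(query_id = rep("q", 3), subject_id = c("b", "a", "a"),
                        e_value = c(1, 1, 1),
                        query_start = c(1L, 5L, 1L), query_end = c(3L, 7L, 3L),
                        subject_start = 1L, subject_end = 3L,
                        aligned_query = "AAA", aligned_subject = "AAA")
  expect_equal(select_hits(tie, S = 2)$subject_id, c("a", "a"))
  expect_equal(select_hits(tie, S = 2)$query_start, c(1L, 5L))
})

test_that("count accumulation walks alignment columns with gap rules", {
  counts <- matrix(0L, 5, 3)
  hit <- list(aligned_query = "MKVLA", aligned_subject = "MKVLA",
              query_start = 1L, query_end = 5L,
              subject_start = 1L, subject_end = 5L)
  counts <- accumulate_counts(hit, "DDDDD", counts)
  expect_equal(counts, matrix(c(0L, 0L, 0L, 0L, 0L,
                                0L, 0L, 0L, 0L, 0L,
                                1L, 1L, 1L, 1L, 1L), 5, 3))
  # a query position opposite a subject gap contributes nothing
  counts2 <- matrix(0L, 3, 3)
  hit2 <- list(aligned_query = "MKV", aligned_subject = "M-V",
               query_start = 1L, query_end = 3L,
               subject_start = 1L, subject_end = 2L)
  counts2 <- accumulate_counts(hit2, "ON", counts2)
  expect_equal(counts2[2, ], c(0L, 0L, 0L))
  expect_equal(counts2[1, ], c(1L, 0L, 0L))
  expect_equal(counts2[3, ], c(0L, 1L, 0L))
  # subject insertion advances the subject cursor only
  counts3 <- matrix(0L, 2, 3)
  hit3 <- list(aligned_query = "M-V", aligned_subject = "MKV",
               query_start = 1L, query_end = 2L,
               subject_start = 1L, subject_end = 3L)
  counts3 <- accumulate_counts(hit3, "OND", counts3)
  expect_equal(counts3, matrix(c(1L, 0L, 0L, 0L, 0L, 1L), 2, 3))
  # additive accumulation across hits
  counts4 <- matrix(0L, 1, 3)
  h4 <- list(aligned_query = "A", aligned_subject = "A", query_start = 1L,
             query_end = 1L, subject_start = 1L, subject_end = 1L)
  counts4 <- accumulate_counts(h4, "O", counts4)
  counts4 <- accumulate_counts(h4, "D", counts4)
  expect_equal(counts4[1, ], c(1L, 0L, 1L))
  expect_error(accumulate_counts(hit, "DD", counts), "shorter than subject_end")
})

test_that("profile normalization follows the three-box convention", {
  prof <- compute_profile(rbind(c(2, 0, 1), c(0, 0, 0), c(1, 0, 0)))
  expect_equal(prof$values[1, ], c(O = 2/3, N = 0, D = 1/3))
  expect_equal(prof$values[2, ], c(O = 0, N = 0, D = 0))  # zero coverage
  expect_equal(prof$values[3, ], c(O = 1, N = 0, D = 0))
  expect_equal(prof$coverage, c(3L, 0L, 1L))
})

test_that("profile rows with coverage sum to one; values in [0,1]", {
  set.seed(11)
  for (rep in 1:25) {
    L <- sample(1:40, 1)
    counts <- matrix(rpois(L * 3, lambda = 0.8), L, 3)
    prof <- compute_profile(counts)
    expect_true(all(prof$values >= 0 & prof$values <= 1))
    covered <- prof$coverage > 0
    if (any(covered)) {
      expect_equal(rowSums(prof$values[covered, , drop = FALSE]),
                   rep(1, sum(covered)), tolerance = 1e-9)
    }
    expect_true(all(prof$values[!covered, ] == 0))
    expect_equal(prof$coverage, as.integer(rowSums(counts)))
  }
})

test_that("a self-hit reproduces the record's one-hot labels", {
  seq <- "MKVLAWTTTTGHILKVMKVLAW"
  labels <- "NNNOOOOODDDDDOOOOONNNN"
  db <- mcs_database("self", seq, labels)
  hits <- toy_align(seq, "q", db)
  expect_equal(nrow(hits), 1L)
  prof <- mcs_for_query(seq, db, hits)
  onehot <- t(vapply(strsplit(labels, "")[[1]],
                     function(s) as.numeric(c("O", "N", "D") == s), numeric(3)))
  dimnames(onehot) <- dimnames(prof$values)
  expect_equal(prof$values, onehot)
  expect_equal(prof$coverage, rep(1L, nchar(seq)))
})

test_that("profile is invariant to hit order and errors on unknown subjects", {
  seq <- "MKVLAWTTGH"
  db <- mcs_database(c("s1", "s2"), c(seq, seq),
                     c("OOOOOOOOOO", "DDDDDDDDDD"))
  hits <- rbind(toy_align(seq, "q", db))
  perm <- hits[rev(seq_len(nrow(hits))), ]
  class(perm) <- class(hits)
  p1 <- mcs_for_query(seq, db, hits)
  p2 <- mcs_for_query(seq, db, perm)
  expect_equal(p1, p2)
  expect_equal(unname(p1$values[1, ]), c(0.5, 0, 0.5))
  bad <- hits
  bad$subject_id <- c("s1", "zz")
  expect_error(mcs_for_query(seq, db, bad), "unknown subject")
})

test_that("hits round-trip through the BLAST-style tabular format", {
  d <- withr::local_tempdir()
  p <- file.path(d, "hits.tsv")
  h <- alignment_hits(query_id = c("q1", "q2"), subject_id = c("s1", "s2"),
                      e_value = c(0.001, 2.5),
                      query_start = c(1L, 3L), query_end = c(5L, 6L),
                      subject_start = c(2L, 1L), subject_end = c(6L, 5L),
                      aligned_query = c("MKVLA", "KV-LA"),
                      aligned_subject = c("MKVLA", "KVHLA"))
  write_hits_tsv(h, p)
  expect_equal(read_hits_tsv(p), h)
  file.create(p2 <- file.path(d, "empty.tsv"))
  expect_equal(nrow(read_hits_tsv(p2)), 0L)
  expect_error(alignment_hits(query_id = "q", subject_id = "s", e_value = 1,
                              query_start = 1L, query_end = 5L,
                              subject_start = 1L, subject_end = 3L,
                              aligned_query = "MKV", aligned_subject = "MKV"),
               "disagrees with coordinates")
})
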