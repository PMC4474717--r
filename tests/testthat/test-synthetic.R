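test_that("chain generation is deterministic and hits the disorder target", {
  cfg <- synth_config(seed = 5)
  set.seed(1); a <- generate_chain(cfg)
  set.seed(1); b <- generate_chain(cfg)
  expect_identical(a, b)
  expect_equal(nchar(a$sequence), nchar(a$labels))
  expect_true(nchar(a$sequence) >= 80 && nchar(a$sequence) <= 300)
  # disorder_target = 0 with zero segment rates -> all ordered
  cfg0 <- synth_config(disorder_target = 0, terminal_disorder_prob = 0,
                       internal_segment_rate = 0)
  set.seed(2)
  c0 <- generate_chain(cfg0)
  expect_false(grepl("D", c0$labels))
  # pooled disorder fraction over 200 chains near the 5% target
  set.seed(99)
  labs <- replicate(200, generate_chain(cfg)$labels)
  frac <- sum(strsplit(paste(labs, collapse = ""), "")[[1]] == "D") /
    sum(nchar(labs))
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("disordered segments carry the expected composition bias", {
  set.seed(12)
  cfg <- synth_config(terminal_disorder_prob = 1, segment_length_mean = 30)
  chains <- replicate(60, generate_chain(cfg), simplify = FALSE)
  aa <- unlist(lapply(chains, function(ch) strsplit(ch$sequence, "")[[1]]))
  lab <- unlist(lapply(chains, function(ch) strsplit(ch$labels, "")[[1]]))
  p_dis <- mean(aa[lab == "D"] %in% c("P", "E", "S", "K", "G", "Q"))
  p_ord <- mean(aa[lab == "O"] %in% c("P", "E", "S", "K", "G", "Q"))
  expect_gt(p_dis, p_ord)
  h_dis <- mean(aa[lab == "D"] %in% c("W", "C", "F", "I", "Y", "V"))
  h_ord <- mean(aa[lab == "O"] %in% c("W", "C", "F", "I", "Y", "V"))
  expect_lt(h_dis, h_ord)
})

test_that("homolog families inherit mutated sequences and noisy labels", {
  cfg <- synth_config(n_homologs = 40, indel_prob = 0, seed = 3)
  set.seed(3)
  chain <- generate_chain(cfg)
  fam <- generate_family(chain, "c1", cfg)
  expect_equal(nrow(fam), 40L)
  expect_true(all(nchar(fam$sequence) == nchar(chain$sequence)))
  # mean identity ~ 1 - substitution_prob (substitution may redraw the same
  # residue, so identity sits slightly above the naive expectation)
  base <- strsplit(chain$sequence, "")[[1]]
  ident <- vapply(fam$sequence, function(s)
    mean(strsplit(s, "")[[1]] == base), numeric(1))
  expect_equal(mean(ident), 1 - cfg$substitution_prob, tolerance = 0.03)
  # noiseless family reproduces the parent exactly
  cfg0 <- synth_config(substitution_prob = 0, indel_prob = 0,
                       label_flip_prob = 0, n_homologs = 2)
  set.seed(4)
  fam0 <- generate_family(chain, "c1", cfg0)
  expect_true(all(fam0$sequence == chain$sequence))
  expect_true(all(fam0$labels == add_near_disorder(chain$labels, cfg0$K)))
  # zero homologs -> empty family
  cfgz <- synth_config(n_homologs = 0)
  expect_equal(nrow(generate_family(chain, "c1", cfgz)), 0L)
})

test_that("secondary-structure oracle correlates with the truth labels", {
  cfg <- synth_config(ss_noise = 0)
  set.seed(6)
  lab <- "DDDDOOOOOOOOOOOOOOOODDDD"
  ss <- generate_ss(lab, cfg)
  sch <- strsplit(ss, "")[[1]]
  lch <- strsplit(lab, "")[[1]]
  expect_true(all(sch[lch == "D"] %in% c("-", "C")))
  expect_true(all(sch[lch == "O"] %in% c("H", "E", "T")))
  expect_true(all(sch %in% SS_ALPHABET))
})

test_that("the built-in aligner finds identity hits and orders by score", {
  db <- mcs_database(c("r1", "r2"),
                     c("MKVLAWTTTTGHILKVMKVLAW", "PPPPGGGGSSSSKKKKEEEE"),
                     c(strrep("O", 22), strrep("D", 20)))
  q <- "MKVLAWTTTTGHILKVMKVLAW"
  hits <- toy_align(q, "q1", db)
  expect_equal(hits$subject_id[1], "r1")
  self <- hits[hits$subject_id == "r1", ]
  expect_equal(self$query_start, 1L)
  expect_equal(self$query_end, 22L)
  expect_false(grepl("-", self$aligned_query))
  # pseudo e-value: m * n * 2^(-score/4) with score 2L for identity
  expect_equal(self$e_value, 22 * 42 * 2^(-44 / 4))
  expect_equal(nrow(toy_align(q, "q1", mcs_database())), 0L)
  # e-value strictly decreasing in score for fixed m, n
  sc <- c(12, 20, 44)
  ev <- 22 * 42 * 2^(-sc / 4)
  expect_true(all(diff(ev) < 0))
})

test_that("corpus generation is reproducible and internally consistent", {
  cfg <- tiny_config(seed = 11)
  corp1 <- generate_corpus(cfg)
  corp2 <- generate_corpus(cfg)
  expect_identical(corp1, corp2)
  expect_equal(nrow(corp1$queries), 6L)
  expect_equal(nrow(corp1$db), 24L)
  # cross-references resolve
  expect_true(all(corp1$hits$subject_id %in% corp1$db$id))
  expect_true(all(corp1$hits$query_id %in% corp1$queries$id))
  expect_equal(nchar(corp1$ss[corp1$queries$id]),
               setNames(nchar(corp1$queries$sequence), corp1$queries$id))
  # file round trip feeds the production parsers
  d <- withr::local_tempdir()
  paths <- write_corpus(corp1, d)
  expect_equal(read_mcsbase(paths[["mcsbase"]]), corp1$db)
  expect_equal(read_hits_tsv(paths[["hits"]]), corp1$hits)
  expect_equal(read_truth_tsv(paths[["truth"]]),
               setNames(corp1$queries$labels, corp1$queries$id))
  expect_equal(read_ss_fasta(paths[["ss"]]), corp1$ss)
})

test_that("profile argmax recovers the truth three-state label on covered positions", {
  cfg <- tiny_config(seed = 19, n_homologs = 15L)   # default family size
  corp <- generate_corpus(cfg)
  agree <- 0L
  covered <- 0L
  for (i in seq_len(nrow(corp$queries))) {
    id <- corp$queries$id[i]
    h <- corp$hits[corp$hits$query_id == id, , drop = FALSE]
    class(h) <- c("alignment_hits", "data.frame")
    prof <- mcs_for_query(corp$queries$sequence[i], corp$db, h)
    truth3 <- strsplit(add_near_disorder(corp$queries$labels[i], cfg$K), "")[[1]]
    cov <- prof$coverage > 0
    call <- c("O", "N", "D")[max.col(prof$values[cov, , drop = FALSE], "first")]
    agree <- agree + sum(call == truth3[cov])
    covered <- covered + sum(cov)
  }
  expect_gt(covered, 0L)
  expect_gte(agree / covered, 0.90)
})
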