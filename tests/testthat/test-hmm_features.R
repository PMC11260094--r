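AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

test_that("profiles from identical ungapped sequences are deterministic", {
  msa <- setNames(rep("ACDEFGHIKL", 5), paste0("s", 1:5))
  h <- build_msa_profile(msa, pseudocount_weight = 0)
  expect_identical(h$model_length, 10L)
  # each match state emits its observed residue with probability 1
  expect_true(all(apply(h$emissions, 1, max) == 1))
  # closed form: L * log2(1 / f_bg) for uniform background
  s <- viterbi_score(h, "ACDEFGHIKL")
  expect_equal(s, 10 * log2(20), tolerance = 1e-9)
  expect_equal(h$presence_threshold, 0.9 * 10 * log2(20), tolerance = 1e-9)
  expect_error(build_msa_profile(msa[1]), "two")
  expect_error(build_msa_profile(setNames(c("", ""), c("a", "b"))), "length 0")
})

test_that("the 50% gap rule assigns insert columns", {
  msa <- c(a = "AC-DE", b = "AC-DE", c = "ACFDE", d = "AC-DE", e = "ACFDE")
  h <- build_msa_profile(msa)   # column 3 is gap in 3/5 sequences
  expect_identical(h$model_length, 4L)
  expect_identical(h$match_cols, c(1L, 2L, 4L, 5L))
})

test_that("pseudocount emissions match the hand calculation", {
  msa <- c(x = "AAC", y = "AAC", z = "ACC")
  h <- build_msa_profile(msa, pseudocount_weight = 1)
  bg <- 1 / 20
  # column 1: AAA -> (3 + bg) / 4 for A, bg / 4 elsewhere
  expect_equal(unname(h$emissions[1, "A"]), (3 + bg) / 4)
  expect_equal(unname(h$emissions[1, "C"]), bg / 4)
  # column 2: AAC -> (2 + bg) / 4 for A, (1 + bg) / 4 for C
  expect_equal(unname(h$emissions[2, "A"]), (2 + bg) / 4)
  expect_equal(unname(h$emissions[2, "C"]), (1 + bg) / 4)
  expect_equal(rowSums(h$emissions), rep(1, 3))
})

test_that("training sequences outscore random sequences", {
  set.seed(21)
  anc <- paste(sample(AA20, 60, TRUE), collapse = "")
  msa <- setNames(rep(anc, 4), paste0("s", 1:4))
  h <- build_msa_profile(msa)
  train_score <- viterbi_score(h, anc)
  rand <- replicate(100, paste(sample(AA20, 60, TRUE), collapse = ""))
  rand_scores <- vapply(rand, function(s) viterbi_score(h, s), 0)
  expect_lt(mean(rand_scores), train_score)
  expect_error(viterbi_score(h, ""), "empty")
  expect_warning(vs <- viterbi_score(h, "XXXX"), "unknown residue")
})

test_that("presence calls respect the threshold and are monotone", {
  msa <- setNames(rep("ACDEFGHIKLMNPQRSTVWY", 3), paste0("s", 1:3))
  h <- build_msa_profile(msa)
  proteome <- c(p1 = "ACDEFGHIKLMNPQRSTVWY", p2 = "MMMM")
  expect_true(call_family_presence(h, proteome)$present)
  expect_false(call_family_presence(h, character(0))$present)
  # raising the threshold can only turn present into absent
  scores_cut <- seq(0, 200, by = 10)
  calls <- vapply(scores_cut, function(ct) {
    h2 <- h; h2$presence_threshold <- ct
    call_family_presence(h2, proteome)$present
  }, TRUE)
  expect_true(all(diff(as.integer(calls)) <= 0))
})

test_that("feature vectors follow library order and union coverage", {
  st <- small_study()
  fams <- names(Filter(function(m) length(m) >= 2, st$msas))[1:4]
  lib <- build_hmm_library(st$msas[fams])
  empty <- genome_feature_vector(lib, character(0))
  expect_identical(unname(empty), rep(0L, 4L))
  expect_identical(names(empty), fams)
  union_prot <- vapply(fams, function(f) st$msas[[f]][1], "")
  expect_identical(unname(genome_feature_vector(lib, union_prot)),
                   rep(1L, 4L))
  # order equals library order regardless of proteome order
  expect_identical(genome_feature_vector(lib, rev(union_prot)),
                   genome_feature_vector(lib, union_prot))
})

test_that("HMM library serialization round trips scores", {
  st <- small_study()
  fams <- names(Filter(function(m) length(m) >= 2, st$msas))[1:3]
  lib <- build_hmm_library(st$msas[fams])
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmm_library(lib, f)
  lib2 <- read_hmm_library(f)
  expect_identical(names(lib2), names(lib))
  seq <- st$msas[[fams[1]]][1]
  expect_equal(viterbi_score(lib2[[1]], seq), viterbi_score(lib[[1]], seq),
               tolerance = 1e-9)
  expect_equal(lib2[[2]]$presence_threshold, lib[[2]]$presence_threshold,
               tolerance = 1e-9)
})

test_that("tblout parsing matches the built-in scorer (self-consistency)", {
  st <- small_study()
  fams <- names(Filter(function(m) length(m) >= 2, st$msas))[1:4]
  lib <- build_hmm_library(st$msas[fams])
  genomes <- names(st$proteomes)[1:8]
  native <- build_feature_table(lib, st$proteomes[genomes])
  hits <- do.call(rbind, lapply(genomes, function(g) {
    do.call(rbind, lapply(fams, function(f) {
      bh <- call_family_presence(lib[[f]], st$proteomes[[g]])$best_hit
      if (is.null(bh)) return(NULL)
      data.frame(target = paste0(g, "|", bh$sequence_id), family = f,
                 score = bh$bit_score, stringsAsFactors = FALSE)
    }))
  }))
  f <- withr::local_tempfile(fileext = ".tbl")
  write_tblout(hits, f)
  thr <- vapply(lib, function(h) h$presence_threshold, 0)
  parsed <- parse_hmmsearch_tblout(f, thr, genome_ids = genomes)
  expect_identical(unclass(parsed), unclass(native))
})

test_that("tblout parser handles thresholds, comments and bad lines", {
  f <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c("# comment", "g1|p1 - famA - 1e-30 80.0 0.1"), f)
  ft <- parse_hmmsearch_tblout(f, c(famA = 25))
  expect_identical(unname(ft["g1", "famA"]), 1L)
  ft2 <- parse_hmmsearch_tblout(f, c(famA = 90))
  expect_identical(unname(ft2["g1", "famA"]), 0L)
  writeLines("# only comments", f)
  ft3 <- parse_hmmsearch_tblout(f, c(famA = 25), genome_ids = "g1")
  expect_identical(sum(ft3), 0L)
  writeLines(c("g1|p1 - famA - 1e-30 80.0", "g1|p2 badline"), f)
  expect_error(parse_hmmsearch_tblout(f, c(famA = 25)), "line 2")
})
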