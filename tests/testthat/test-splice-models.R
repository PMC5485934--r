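test_that("splice windows follow the -3..+6 and -20..+3 conventions", {
  g <- toy_genome()
  w <- splice_windows(g, "chrT", TOY_LEND, TOY_RSTART)
  expect_equal(w$donor_plus, "CAGGTAAGT")
  expect_equal(nchar(w$acceptor_plus), 23L)
  expect_match(w$acceptor_plus, "CAGGCC$")   # ...AG | 3 exonic bases
  expect_equal(w$donor_minus,
               revcomp(as.character(Biostrings::subseq(g[[1]],
                                                       TOY_RSTART - 6L,
                                                       TOY_RSTART + 2L))))
  expect_equal(nchar(w$acceptor_minus), 23L)
})

test_that("windows on the reverse-complemented genome mirror strandwise", {
  g <- toy_genome()
  len <- Biostrings::width(g)[1]
  grc <- Biostrings::DNAStringSet(Biostrings::reverseComplement(g[[1]]))
  names(grc) <- "chrT"
  lend2 <- len - TOY_RSTART + 1L
  rstart2 <- len - TOY_LEND + 1L
  w <- splice_windows(g, "chrT", TOY_LEND, TOY_RSTART)
  w2 <- splice_windows(grc, "chrT", lend2, rstart2)
  expect_equal(w2$donor_plus, w$donor_minus)
  expect_equal(w2$donor_minus, w$donor_plus)
  expect_equal(w2$acceptor_plus, w$acceptor_minus)
  expect_equal(w2$acceptor_minus, w$acceptor_plus)
})

test_that("windows beyond chromosome bounds are unscorable", {
  g <- toy_genome()
  w <- splice_windows(g, "chrT", 4L, TOY_RSTART)   # acceptor_minus leftward overflow is fine; donor_plus needs lend-2 >= 1
  expect_false(is.na(w$donor_plus))
  w2 <- splice_windows(g, "chrT", 2L, TOY_RSTART)
  expect_true(is.na(w2$donor_plus))
  w3 <- splice_windows(g, "chrT", TOY_LEND, 10L)   # rstart - 20 < 1
  expect_true(is.na(w3$acceptor_plus))
  w4 <- splice_windows(g, "chrX", TOY_LEND, TOY_RSTART)
  expect_true(all(is.na(unlist(w4))))
})

test_that("a WMM scores its own training sequence maximally", {
  s <- "CAGGTAAGT"
  m <- train_wmm(s, pseudocount = 0.5)
  all9 <- function(k) {
    ## random probe set plus the training sequence itself
    probes <- vapply(1:200, function(i) {
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    }, character(1))
    unique(c(probes, s))
  }
  set.seed(5)
  probes <- all9(9)
  sc <- score5(train_wmm(s), probes)
  expect_equal(probes[which.max(sc)], s)
})

test_that("a WMM with signal equal to background scores everything zero", {
  uni <- matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- wmm_from_profile(uni)
  expect_equal(score5(m, c("CAGGTAAGT", "AAAAAAAAA", "TTTTTTTTT")),
               c(0, 0, 0))
})

test_that("training rejects mixed widths and empty sets", {
  expect_error(train_wmm(character(0)), "at least one")
  expect_error(train_wmm(c("ACGT", "ACGTA")), "mixed")
})

test_that("increasing the pseudocount shrinks the model toward background", {
  train <- c("CAGGTAAGT", "CAGGTAAGT", "AAGGTAAGA")
  pcs <- c(0.1, 0.5, 2, 10, 100)
  models <- lapply(pcs, function(pc) train_wmm(train, pseudocount = pc))
  ## every per-position log-odds weight moves toward 0 monotonically
  los <- sapply(models, function(m) as.vector(m$logodds))
  expect_true(all(diff(t(abs(los))) <= 1e-9))
  expect_true(all(sign(los[, 1]) * los >= -1e-9))   # no sign flips
  ## hence the consensus (all-positive terms) score decreases toward 0
  cons <- sapply(models, score5, seqs = "CAGGTAAGT")
  expect_true(all(diff(cons) <= 1e-9) && all(cons >= 0))
})

test_that("non-ACGT content makes a window unscorable", {
  m <- train_wmm("CAGGTAAGT")
  expect_true(is.na(score5(m, "CAGGTNAGT")))
  expect_true(is.na(score5(m, NA)))
  expect_true(is.na(score5(m, "CAGG")))
})

test_that("scoring is pure: identical input, identical output", {
  m <- train_wmm(c("CAGGTAAGT", "CTGGTAAGT"))
  s1 <- score5(m, "CAGGTGAGT")
  s2 <- score5(m, "CAGGTGAGT")
  expect_identical(s1, s2)
})

test_that("constant maxent tables give log2 of the constant", {
  dir <- write_constant_maxent(tempfile(), value = 2)
  mt <- load_maxent_tables(dir)
  expect_equal(mt$kind, "maxent-table")
  set.seed(8)
  for (i in 1:5) {
    d9 <- paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = "")
    a23 <- paste(sample(c("A", "C", "G", "T"), 23, TRUE), collapse = "")
    expect_equal(score5(mt, d9), 1)    # log2(2)
    expect_equal(score3(mt, a23), 1)   # log2(2^5 / 2^4)
  }
  model <- splice_score_model(mt, mt)
  expect_equal(model$kind, "maxent-table")
})

test_that("maxent table loading validates the directory layout", {
  expect_error(load_maxent_tables(tempfile()), "not found")
  d <- tempfile(); dir.create(d)
  expect_error(load_maxent_tables(d), "missing maxent table")
  writeLines(rep("2", 10), file.path(d, "donor.txt"))
  expect_error(load_maxent_tables(d), "expected")
})

test_that("maxent lookup uses the base-4 sequence index", {
  d <- tempfile()
  write_constant_maxent(d, value = 1)
  ## overwrite donor table: value = index, so the score identifies the row
  writeLines(format(seq_len(4^9)), file.path(d, "donor.txt"))
  mt <- load_maxent_tables(d)
  expect_equal(score5(mt, "AAAAAAAAA"), log2(1))
  expect_equal(score5(mt, "AAAAAAAAC"), log2(2))
  expect_equal(score5(mt, "TTTTTTTTT"), log2(4^9))
  expect_equal(score5(mt, "CAAAAAAAA"), log2(4^8 + 1))
})
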