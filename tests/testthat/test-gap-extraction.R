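test_that("CIGAR walking follows SAM reference-consumption rules", {
  o <- extract_gap_observations(100, "50M200N50M")
  expect_equal(o$lend, 149L)
  expect_equal(o$rstart, 350L)
  expect_equal(o$lstart, 100L)
  expect_equal(o$rend, 399L)
  expect_equal(o$mcl, 50L)

  expect_equal(nrow(extract_gap_observations(7, "100M")), 0L)

  o2 <- extract_gap_observations(1, "30M100N40M200N30M")
  expect_equal(o2$lend, c(30L, 170L))
  expect_equal(o2$rstart, c(131L, 371L))
  expect_equal(o2$mcl, c(30L, 30L))

  ## D consumes reference but not match length; I and S consume query only
  o3 <- extract_gap_observations(10, "5S20M5D10M100N30M2I8M")
  expect_equal(o3$lend, 10L + 20L + 5L + 10L - 1L)
  expect_equal(o3$rstart, o3$lend + 101L)
  expect_equal(o3$mcl, min(20L + 10L, 30L + 8L))

  expect_error(extract_gap_observations(5, "12Q", qname = "r1"), "r1")
  expect_error(extract_gap_observations(5, "*"), "malformed")
})

test_that("gaps with a zero-length matched flank are rejected and tallied", {
  o <- extract_gap_observations(1, "20M100N5D10M")
  ## right segment has only a deletion adjacent? no: 5D10M has 10 matches
  expect_equal(nrow(o), 1L)
  o2 <- extract_gap_observations(1, "20M100N5D")
  expect_equal(nrow(o2), 0L)
  expect_equal(attr(o2, "rejected"), 1L)
})

test_that("observations map back onto the CIGAR reference span", {
  set.seed(11)
  for (i in 1:50) {
    n_seg <- sample(2:4, 1)
    m <- sample(10:60, n_seg, replace = TRUE)
    g <- sample(50:500, n_seg - 1, replace = TRUE)
    cig <- paste0(m[1], "M",
                  paste0(g, "N", m[-1], "M", collapse = ""))
    pos <- sample(1:10000, 1)
    o <- extract_gap_observations(pos, cig)
    span <- sum(m) + sum(g)
    expect_true(all(o$lstart == pos))
    expect_true(all(o$rend == pos + span - 1L))
    expect_true(all(o$lend < o$rstart - 1L))
  }
})

test_that("gap coordinates agree with the GenomicAlignments CIGAR walker", {
  set.seed(12)
  for (i in 1:30) {
    n_seg <- sample(2:4, 1)
    m <- sample(5:80, n_seg, replace = TRUE)
    g <- sample(30:900, n_seg - 1, replace = TRUE)
    cig <- paste0(m[1], "M", paste0(g, "N", m[-1], "M", collapse = ""))
    pos <- sample(1:5000, 1)
    o <- extract_gap_observations(pos, cig)
    ref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cig, ops = "N", pos = pos)[[1]]
    expect_equal(o$lend, BiocGenerics::start(ref) - 1L)
    expect_equal(o$rstart, BiocGenerics::end(ref) + 1L)
  }
})

test_that("accumulation builds the saturating evidence statistics", {
  obs <- data.table::data.table(
    seqid = "chr1", lend = 100L, rstart = 301L,
    lstart = c(100L, 101L, 102L), rend = c(400L, 401L, 402L),
    mcl = c(50L, 40L, 30L))
  r <- accumulate_gap_sites(obs, "s1")
  expect_equal(r$nAligns, 3L)
  expect_equal(r$nlstart, 3L)
  expect_equal(unlist(r[, .(mcl1, mcl2, mcl3, mcl4)]),
               c(mcl1 = 50L, mcl2 = 40L, mcl3 = 30L, mcl4 = 0L))
  expect_equal(r$qsm, 120L)
  expect_equal(r$nProbes, 1L)
  expect_equal(r$range_start, 100L)
  expect_equal(r$range_end, 402L)

  obs5 <- data.table::copy(obs[rep(1, 5)])
  obs5[, mcl := c(10L, 20L, 30L, 40L, 50L)]
  r5 <- accumulate_gap_sites(obs5, "s1")
  expect_equal(r5$qsm, 140L)   # drop the smallest

  obs12 <- data.table::copy(obs[rep(1, 12)])
  obs12[, lstart := 1:12]
  r12 <- accumulate_gap_sites(obs12, "s1", capacity = 8L)
  expect_equal(r12$nlstart, 8L)     # saturated
  expect_equal(r12$nAligns, 12L)
})

test_that("merging keeps the top-4 mcl of the union and adds counts", {
  mk <- function(mcls, lstarts) {
    accumulate_gap_sites(data.table::data.table(
      seqid = "chr1", lend = 100L, rstart = 301L,
      lstart = lstarts, rend = 400L, mcl = mcls), "s")
  }
  a <- mk(c(50L, 50L, 40L, 30L), 100:103)
  b <- mk(c(45L, 45L, 20L, 10L), 104:107)
  m <- merge_gap_sites(a, b)
  expect_equal(unlist(m[, .(mcl1, mcl2, mcl3, mcl4)]),
               c(mcl1 = 50L, mcl2 = 50L, mcl3 = 45L, mcl4 = 45L))
  expect_equal(m$qsm, 190L)
  expect_equal(m$nAligns, 8L)
  expect_equal(m$nProbes, 2L)
  expect_equal(m$nlstart, 8L)
})

test_that("merging disjoint keys concatenates without changing records", {
  set.seed(3)
  o1 <- random_observations(20, n_keys = 2)
  o2 <- data.table::copy(random_observations(20, n_keys = 2))
  o2[, lend := lend + 100000L]     # force disjoint keys
  o2[, rstart := rstart + 100000L]
  a <- accumulate_gap_sites(o1, "s1")
  b <- accumulate_gap_sites(o2, "s2")
  m <- merge_gap_sites(a, b)
  expect_equal(nrow(m), nrow(a) + nrow(b))
  cols <- setdiff(names(a), "lstarts")
  both <- data.table::rbindlist(list(a[, ..cols], b[, ..cols]))
  data.table::setkeyv(both, c("seqid", "lend", "rstart"))
  expect_equal(plain(m[, ..cols]), plain(both))
})

test_that("split-accumulate-merge equals accumulating the whole stream", {
  set.seed(21)
  for (rep in 1:10) {
    obs <- random_observations(60, n_keys = 4, n_starts = 6)
    whole <- accumulate_gap_sites(obs, "all")
    cut <- sample(2:58, 2)
    parts <- split(obs, findInterval(seq_len(nrow(obs)), sort(cut)))
    tabs <- lapply(parts, accumulate_gap_sites, sample_id = "part")
    merged <- merge_gap_sites(tabs)
    merged[, nProbes := 1L]   # same-sample split: multiplicity is not additive here
    expect_equal(plain(merged[, !"lstarts"]),
                 plain(whole[, !"lstarts"]))
    expect_equal(lapply(merged$lstarts, sort), lapply(whole$lstarts, sort))
  }
})

test_that("merge is associative and commutative on random records", {
  set.seed(31)
  for (rep in 1:5) {
    r1 <- accumulate_gap_sites(random_observations(30), "a")
    r2 <- accumulate_gap_sites(random_observations(30), "b")
    r3 <- accumulate_gap_sites(random_observations(30), "c")
    left <- merge_gap_sites(merge_gap_sites(r1, r2), r3)
    right <- merge_gap_sites(r1, merge_gap_sites(r2, r3))
    swapped <- merge_gap_sites(r2, r1)
    expect_equal(plain(left), plain(right))
    expect_equal(plain(merge_gap_sites(r1, r2)[, !"lstarts"]),
                 plain(swapped[, !"lstarts"]))
  }
})

test_that("evidence accumulation is monotone", {
  set.seed(41)
  obs <- random_observations(40, n_keys = 2)
  base <- accumulate_gap_sites(obs, "s1")
  for (rep in 1:10) {
    extra <- random_observations(10, n_keys = 2)
    extra[, `:=`(seqid = base$seqid[1], lend = base$lend[1],
                 rstart = base$rstart[1])]
    grown <- merge_gap_sites(base, accumulate_gap_sites(extra, "s2"))
    g1 <- grown[base[1], on = c("seqid", "lend", "rstart")]
    expect_gte(g1$qsm, base$qsm[1])
    expect_gte(g1$nlstart, base$nlstart[1])
    expect_gte(gqs(g1$nlstart, g1$qsm), gqs(base$nlstart[1], base$qsm[1]))
  }
})

test_that("gap-site tables round-trip through TSV", {
  set.seed(51)
  tab <- accumulate_gap_sites(random_observations(30), "s1")
  f <- tempfile(fileext = ".tsv")
  write_gap_sites(tab, f)
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_equal(hdr[1:13],
               c("seqid", "lend", "rstart", "nAligns", "nlstart",
                 "mcl1", "mcl2", "mcl3", "mcl4", "qsm", "nProbes",
                 "range_start", "range_end"))
  back <- read_gap_sites(f)
  expect_equal(plain(back), plain(tab[, !"lstarts"]))
})
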