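## Shared fixtures, built in code at test time.

## Strip bookkeeping attributes for value comparisons.
plain <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names", "class")]
  x
}

## Toy single-junction chromosome: exon1 "CCCAG" (lend = 5), intron
## "GTAAGT" + 13 T + "CAG" (positions 6..27), exon2 "GCCC" (rstart = 28).
toy_genome <- function() {
  s <- paste0("CCCAG", "GTAAGT", strrep("T", 13), "CAG", "GCCC")
  Biostrings::DNAStringSet(c(chrT = s))
}
TOY_LEND <- 5L
TOY_RSTART <- 28L

## Random gap observations over a few keys; lstart drawn from a small pool
## so saturation effects can be switched on/off via n_starts.
random_observations <- function(n, n_keys = 3L, n_starts = 6L) {
  keys <- data.table::data.table(
    seqid = sample(c("chr1", "chr2"), n_keys, replace = TRUE),
    lend = sample(500:5000, n_keys),
    gap = sample(100:5000, n_keys))
  pick <- sample.int(n_keys, n, replace = TRUE)
  start_off <- sample(seq_len(n_starts), n, replace = TRUE)
  data.table::data.table(
    seqid = keys$seqid[pick],
    lend = keys$lend[pick],
    rstart = keys$lend[pick] + keys$gap[pick] + 1L,
    lstart = keys$lend[pick] - 30L - start_off,
    rend = keys$lend[pick] + keys$gap[pick] + sample(20:80, n, replace = TRUE),
    mcl = sample(10:50, n, replace = TRUE))
}

## Constant-valued maxent score tables in the canonical directory layout.
write_constant_maxent <- function(dir, value = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- format(value)
  writeLines(rep(v, 4^9), file.path(dir, "donor.txt"))
  for (i in 1:5) writeLines(rep(v, 4^7),
                            file.path(dir, sprintf("acceptor_m%d.txt", i)))
  for (i in 1:4) writeLines(rep(v, 4^3),
                            file.path(dir, sprintf("acceptor_o%d.txt", i)))
  dir
}

## Exon table (data.frame input path of build_exon_pairs).
exon_df <- function(starts, ends, seqid = "chr1", strand = "+",
                    transcript_id = "t1", gene_id = "g1",
                    exon_number = seq_along(starts)) {
  data.frame(seqid = seqid, start = starts, end = ends, strand = strand,
             type = "exon", transcript_id = transcript_id,
             gene_id = gene_id, exon_number = exon_number)
}

## Independent brute-force annotation oracle: full scan over all pairs.
brute_force_annotate <- function(sites, pairs, read_length = 100L) {
  res <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    qs <- if ("range_start" %in% names(sites)) s$range_start
          else max(s$lend - read_length, 1L)
    qe <- if ("range_end" %in% names(sites)) s$range_end
          else s$rstart + read_length
    best <- NULL
    for (j in seq_len(nrow(pairs))) {
      p <- pairs[j, ]
      if (p$seqid != s$seqid) next
      if (p$right_exon_end < qs || p$left_exon_start > qe) next
      sod <- abs(s$lend - p$left_exon_end) + abs(s$rstart - p$right_exon_start)
      cand <- list(sod = sod, tid = p$transcript_id, lee = p$left_exon_end,
                   gene = p$gene_id, strand = p$strand)
      if (is.null(best) ||
          sod < best$sod ||
          (sod == best$sod && (cand$tid < best$tid ||
            (cand$tid == best$tid && cand$lee < best$lee)))) {
        best <- cand
      }
    }
    if (is.null(best)) {
      data.frame(sod = NA_integer_, transcript_id = NA_character_)
    } else {
      data.frame(sod = best$sod, transcript_id = best$tid)
    }
  })
  do.call(rbind, res)
}

## Small universe shared by the heavier tests (generated once per test run).
small_universe <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_universe(file.path(tempdir(), "gapsites-universe"),
                                  n_chrom = 2L, chrom_length = 20000L,
                                  n_genes = 4L, exons_per_gene = 3L,
                                  coverage_true = 12L, noise_fraction = 0.5,
                                  seed = 42L)
    }
    cache
  }
})

universe_model <- function(u) {
  splice_score_model(wmm_from_profile(u$donor_profile),
                     wmm_from_profile(u$acceptor_profile))
}
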