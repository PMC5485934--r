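#' @title Annotation of gap-sites against intron-connected exon pairs
#' @description
#' Ensembl-dialect GTF files describe exons as independent features related
#' only by `transcript_id` and `exon_number`; introns must be reconstructed
#' by pairing adjacent exons per transcript. A gap-site is then annotated
#' with the overlapping exon pair minimising the sum of distances
#' `sod = |lend - left_exon_end| + |rstart - right_exon_start|`; `sod == 0`
#' means the gap-site sits exactly on an annotated splice junction.
#' @name annotation
NULL

gtf_to_exon_table <- function(gtf) {
  if (is.character(gtf) && length(gtf) == 1L) {
    gtf <- rtracklayer::import(gtf, format = "gtf")
  }
  if (methods::is(gtf, "GRanges")) {
    md <- S4Vectors::mcols(gtf)
    dt <- data.table(
      seqid = as.character(GenomicRanges::seqnames(gtf)),
      start = GenomicRanges::start(gtf),
      end = GenomicRanges::end(gtf),
      strand = as.character(GenomicRanges::strand(gtf)),
      type = as.character(md$type),
      transcript_id = if ("transcript_id" %in% names(md))
        as.character(md$transcript_id) else NA_character_,
      gene_id = if ("gene_id" %in% names(md))
        as.character(md$gene_id) else NA_character_,
      exon_number = if ("exon_number" %in% names(md))
        suppressWarnings(as.integer(as.character(md$exon_number)))
      else NA_integer_)
  } else {
    dt <- as.data.table(gtf)
  }
  dt
}

#' Build intron-connected exon pairs from a GTF
#'
#' Exon features are grouped by transcript, ordered by `exon_number` when
#' present (genomic order, strand-aware, otherwise), and adjacent exons are
#' paired. Pairs sharing identical coordinates across transcripts are
#' deduplicated, with all transcript/gene ids retained as comma-separated
#' lists (sorted, so the first id is the lexicographic minimum used for
#' tie-breaking during annotation). Exons lacking a `transcript_id` are
#' skipped; their number is reported in the `skipped` attribute.
#'
#' @param gtf path to a GTF file, a `GRanges` from [rtracklayer::import()],
#'   or a data.frame with columns `seqid`, `start`, `end`, `strand`,
#'   `type`, `transcript_id`, `gene_id` and optionally `exon_number`.
#' @return `data.table` of exon pairs sorted by `(seqid, left_exon_start)`
#'   with columns `seqid`, `strand`, `left_exon_start`, `left_exon_end`,
#'   `right_exon_start`, `right_exon_end`, `transcript_id`, `gene_id`,
#'   `left_exon_number`.
#' @export
build_exon_pairs <- function(gtf) {
  dt <- gtf_to_exon_table(gtf)
  if (!"exon_number" %in% names(dt)) dt[, exon_number := NA_integer_]
  ex <- dt[type == "exon"]
  skipped <- sum(is.na(ex$transcript_id))
  if (skipped > 0L) {
    warning(skipped, " exon feature(s) without transcript_id skipped")
    ex <- ex[!is.na(transcript_id)]
  }
  if (nrow(ex) == 0L) {
    out <- data.table(seqid = character(), strand = character(),
                      left_exon_start = integer(), left_exon_end = integer(),
                      right_exon_start = integer(), right_exon_end = integer(),
                      transcript_id = character(), gene_id = character(),
                      left_exon_number = integer())
    setattr(out, "skipped", skipped)
    return(out)
  }
  pairs <- ex[, {
    o <- if (all(!is.na(exon_number))) order(exon_number)
         else if (strand[1] == "-") order(-start) else order(start)
    s <- start[o]; e <- end[o]; en <- exon_number[o]
    if (.N < 2L) NULL else {
      i <- seq_len(.N - 1L)
      ## genomic left/right regardless of transcript orientation
      ls <- pmin(s[i], s[i + 1L]); le_ <- pmin(e[i], e[i + 1L])
      rs <- pmax(s[i], s[i + 1L]); re_ <- pmax(e[i], e[i + 1L])
      list(seqid = seqid[o][i], strand = strand[o][i],
           left_exon_start = ls, left_exon_end = le_,
           right_exon_start = rs, right_exon_end = re_,
           gene_id = gene_id[o][i], left_exon_number = en[i])
    }
  }, by = transcript_id]
  if (nrow(pairs) == 0L || !"seqid" %in% names(pairs)) {
    out <- data.table(seqid = character(), strand = character(),
                      left_exon_start = integer(), left_exon_end = integer(),
                      right_exon_start = integer(), right_exon_end = integer(),
                      transcript_id = character(), gene_id = character(),
                      left_exon_number = integer())
    setattr(out, "skipped", skipped)
    return(out)
  }
  bad <- pairs$left_exon_end >= pairs$right_exon_start
  if (any(bad)) {
    warning(sum(bad), " overlapping/abutting exon pair(s) dropped")
    pairs <- pairs[!bad]
  }
  out <- pairs[, .(
    transcript_id = paste(sort(unique(transcript_id)), collapse = ","),
    gene_id = paste(sort(unique(gene_id)), collapse = ","),
    left_exon_number = left_exon_number[1]
  ), by = .(seqid, strand, left_exon_start, left_exon_end,
            right_exon_start, right_exon_end)]
  setcolorder(out, c("seqid", "strand", "left_exon_start", "left_exon_end",
                     "right_exon_start", "right_exon_end",
                     "transcript_id", "gene_id", "left_exon_number"))
  setorder(out, seqid, left_exon_start, left_exon_end, right_exon_start)
  setattr(out, "skipped", skipped)
  out[]
}

check_sorted <- function(dt, cols, what) {
  o <- do.call(order, unname(as.list(dt[, cols, with = FALSE])))
  if (!identical(o, seq_len(nrow(dt)))) {
    stop(what, " must be sorted by (", paste(cols, collapse = ", "), ")")
  }
}

#' Annotate gap-sites with their optimal exon pair
#'
#' Both inputs must be sorted by `(seqid, start)`. Overlap is a non-empty
#' intersection of the site's supported range `[range_start, range_end]`
#' with the pair's span `[left_exon_start, right_exon_end]`, irrespective
#' of strand (a gap-site carries no strand before wgis scoring; the matched
#' pair's strand is reported as `annotated_strand` for comparison). Among
#' overlapping pairs the one with minimal
#' `sod = |lend - left_exon_end| + |rstart - right_exon_start|` is
#' reported; ties break on lexicographically smallest
#' `(transcript_id, left_exon_end)`. Sites without any overlap get `NA`s.
#' Sites lacking `range_start`/`range_end` (minimal imported tables) fall
#' back to `[lend - read_length, rstart + read_length]`.
#'
#' @param sites gap-site `data.table` sorted by `(seqid, lend, rstart)`.
#' @param pairs exon-pair table from [build_exon_pairs()], sorted by
#'   `(seqid, left_exon_start)`.
#' @param read_length fallback half-window for missing ranges (default 100).
#' @return copy of `sites` with `transcript_id`, `gene_id`, `sod`,
#'   `annotated_strand` appended.
#' @export
annotate_gap_sites <- function(sites, pairs, read_length = 100L) {
  out <- as.data.table(sites)
  if (nrow(out)) check_sorted(out, c("seqid", "lend", "rstart"), "sites")
  if (nrow(pairs)) check_sorted(pairs, c("seqid", "left_exon_start"), "pairs")
  out[, `:=`(transcript_id = NA_character_, gene_id = NA_character_,
             sod = NA_integer_, annotated_strand = NA_character_)]
  if (nrow(out) == 0L || nrow(pairs) == 0L) return(out[])
  qs <- if ("range_start" %in% names(out)) out$range_start else
    pmax(out$lend - as.integer(read_length), 1L)
  qe <- if ("range_end" %in% names(out)) out$range_end else
    out$rstart + as.integer(read_length)
  q <- GenomicRanges::GRanges(out$seqid, IRanges::IRanges(qs, qe))
  r <- GenomicRanges::GRanges(pairs$seqid,
                              IRanges::IRanges(pairs$left_exon_start,
                                               pairs$right_exon_end))
  hits <- GenomicRanges::findOverlaps(q, r, ignore.strand = TRUE)
  if (length(hits) == 0L) return(out[])
  h <- data.table(site = S4Vectors::queryHits(hits),
                  pair = S4Vectors::subjectHits(hits))
  h[, sod := abs(out$lend[site] - pairs$left_exon_end[pair]) +
      abs(out$rstart[site] - pairs$right_exon_start[pair])]
  h[, `:=`(tid = pairs$transcript_id[pair],
           lee = pairs$left_exon_end[pair])]
  setorder(h, site, sod, tid, lee)
  best <- h[, .SD[1], by = site]
  out[best$site, `:=`(transcript_id = pairs$transcript_id[best$pair],
                      gene_id = pairs$gene_id[best$pair],
                      sod = best$sod,
                      annotated_strand = pairs$strand[best$pair])]
  out[]
}
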