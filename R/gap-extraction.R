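#' @title Gap-site extraction from gapped alignments
#' @description
#' A gap-site is the unique genomic location of an alignment gap, keyed by
#' `(seqid, lend, rstart)`: `lend` is the last aligned reference base left of
#' the gap, `rstart` the first aligned reference base right of it (1-based;
#' the intron occupies `[lend + 1, rstart - 1]`). Each `N` operation in a
#' CIGAR yields one gap observation; observations are accumulated per site
#' with saturating, monotone statistics so that evidence from further
#' alignments or samples can only confirm, never degrade, a site.
#' @name gap_extraction
NULL

## CIGAR ops by reference/query consumption
.REF_OPS   <- c("M", "=", "X", "D", "N")
.MATCH_OPS <- c("M", "=", "X")

parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)) {
    stop("malformed CIGAR: ", deparse(cigar))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops  <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  list(op = ops, len = lens)
}

#' Extract gap observations from one alignment
#'
#' Walks a CIGAR string under SAM reference-consumption rules (`M`, `=`, `X`,
#' `D`, `N` consume reference; `I`, `S` consume query only; `H`, `P` neither)
#' and emits one observation per `N` operation, left to right. The flanking
#' matched-segment length on each side of a gap is the total `M`/`=`/`X`
#' length of the adjacent segment (segments delimited by read ends or
#' neighbouring `N` ops; `D` contributes nothing); `mcl` is the minimum of
#' the two. Gaps with a zero-length matched flank are rejected and counted
#' in the `rejected` attribute.
#'
#' @param pos 1-based leftmost aligned reference position.
#' @param cigar CIGAR string.
#' @param seqid reference sequence name carried into the observations.
#' @param qname read name used in error messages.
#' @param mcl_cap individual `mcl` values are capped here before storage
#'   (byte-packing convention; irrelevant for read length 100).
#' @return `data.table` with columns `seqid`, `lend`, `rstart`, `lstart`,
#'   `rend`, `mcl` (zero rows when the CIGAR has no `N`), with attribute
#'   `rejected` giving the number of discarded zero-flank gaps.
#' @export
#' @examples
#' extract_gap_observations(100, "50M200N50M")
extract_gap_observations <- function(pos, cigar, seqid = NA_character_,
                                     qname = NULL, mcl_cap = 255L) {
  cig <- tryCatch(parse_cigar(cigar), error = function(e) {
    stop("record ", if (is.null(qname)) "<unnamed>" else qname, ": ",
         conditionMessage(e), call. = FALSE)
  })
  empty <- data.table(seqid = character(), lend = integer(),
                      rstart = integer(), lstart = integer(),
                      rend = integer(), mcl = integer())
  n_idx <- which(cig$op == "N")
  if (!length(n_idx)) {
    setattr(empty, "rejected", 0L)
    return(empty)
  }
  ref_len <- ifelse(cig$op %in% .REF_OPS, cig$len, 0L)
  ref_before <- cumsum(ref_len) - ref_len      # ref consumed before each op
  lstart <- as.integer(pos)
  rend <- lstart + sum(ref_len) - 1L

  ## matched length per inter-N segment
  seg_id <- cumsum(cig$op == "N") + 1L         # N belongs to following segment boundary
  seg_of_op <- seg_id - (cig$op == "N")        # ops before k-th N are segment k
  match_len <- ifelse(cig$op %in% .MATCH_OPS, cig$len, 0L)
  n_seg <- length(n_idx) + 1L
  seg_match <- vapply(seq_len(n_seg), function(s) {
    sum(match_len[seg_of_op == s & cig$op != "N"])
  }, numeric(1))

  lend <- lstart + ref_before[n_idx] - 1L
  rstart <- lend + cig$len[n_idx] + 1L
  left_m <- seg_match[seq_along(n_idx)]
  right_m <- seg_match[seq_along(n_idx) + 1L]
  mcl <- pmin(left_m, right_m)

  keep <- mcl >= 1
  out <- data.table(seqid = rep(seqid, sum(keep)),
                    lend = as.integer(lend[keep]),
                    rstart = as.integer(rstart[keep]),
                    lstart = rep(lstart, sum(keep)),
                    rend = rep(as.integer(rend), sum(keep)),
                    mcl = as.integer(pmin(mcl[keep], mcl_cap)))
  setattr(out, "rejected", sum(!keep))
  out
}

#' Read gap observations from a SAM/BAM file
#'
#' Loads alignments with [Rsamtools::scanBam] (SAM input is converted with
#' [Rsamtools::asBam] into a temporary file first) and extracts all gap
#' observations. Unmapped, secondary (0x100) and supplementary (0x800)
#' records are skipped by default; no mapping-quality filter is applied
#' unless `min_mapq` is set.
#'
#' @param file path to a SAM or BAM file.
#' @param keep_secondary keep secondary/supplementary alignments.
#' @param min_mapq optional minimum mapping quality (records with MAPQ 255 =
#'   "unavailable" are kept).
#' @inheritParams extract_gap_observations
#' @return `data.table` of observations as in [extract_gap_observations()],
#'   attribute `rejected` totalled over all records.
#' @export
gap_observations_from_bam <- function(file, keep_secondary = FALSE,
                                      min_mapq = NULL, mcl_cap = 255L) {
  if (!file.exists(file)) stop("alignment file not found: ", file)
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(file, destination = dest,
                                             overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(rec$pos) & !bitwAnd(rec$flag, 0x4)
  if (!keep_secondary) {
    keep <- keep & !bitwAnd(rec$flag, 0x100) & !bitwAnd(rec$flag, 0x800)
  }
  if (!is.null(min_mapq)) {
    keep <- keep & (rec$mapq >= min_mapq | rec$mapq == 255L)
  }
  keep[is.na(keep)] <- FALSE
  idx <- which(keep & grepl("N", rec$cigar))
  rejected <- 0L
  parts <- lapply(idx, function(i) {
    o <- extract_gap_observations(rec$pos[i], rec$cigar[i],
                                  seqid = as.character(rec$rname[i]),
                                  qname = rec$qname[i], mcl_cap = mcl_cap)
    rejected <<- rejected + attr(o, "rejected")
    o
  })
  out <- if (length(parts)) rbindlist(parts) else
    data.table(seqid = character(), lend = integer(), rstart = integer(),
               lstart = integer(), rend = integer(), mcl = integer())
  setattr(out, "rejected", rejected)
  out
}

top4 <- function(x) {
  s <- sort(x, decreasing = TRUE)
  out <- integer(4)
  out[seq_len(min(4L, length(s)))] <- s[seq_len(min(4L, length(s)))]
  out
}

## first-`capacity` distinct values in order of appearance
saturate_first <- function(x, capacity) {
  u <- unique(x)
  u[seq_len(min(length(u), capacity))]
}

#' Accumulate gap observations of one sample into gap-site records
#'
#' Groups observations by `(seqid, lend, rstart)` and builds the saturating
#' evidence statistics: supporting-alignment count `nAligns`, distinct left
#' alignment start positions (`lstarts`, insertion stops once the capacity
#' `n` is reached; their count is `nlstart`), the four largest `mcl` values
#' (`mcl1..mcl4`, missing slots 0) and their sum `qsm`, the sample
#' multiplicity `nProbes = 1`, and the supported range
#' `[range_start, range_end]` (extremes of `lstart`/`rend` over all
#' supporting alignments).
#'
#' @param observations `data.table` of gap observations (one sample).
#' @param sample_id identifier recorded with the table (attribute
#'   `sample_ids`).
#' @param capacity saturation capacity `n` for distinct left starts
#'   (default 8).
#' @return keyed `data.table` of gap-site records, sorted by
#'   `(seqid, lend, rstart)`, with a list-column `lstarts` retaining the
#'   kept distinct starts (needed for exact merging).
#' @export
accumulate_gap_sites <- function(observations, sample_id = "sample",
                                 capacity = 8L) {
  stopifnot(capacity >= 1L)
  cols <- c("seqid", "lend", "rstart", "lstart", "rend", "mcl")
  if (!all(cols %in% names(observations))) {
    stop("observations must have columns: ", paste(cols, collapse = ", "))
  }
  obs <- as.data.table(observations)
  if (nrow(obs) == 0L) {
    out <- data.table(seqid = character(), lend = integer(), rstart = integer(),
                      nAligns = integer(), nlstart = integer(),
                      mcl1 = integer(), mcl2 = integer(), mcl3 = integer(),
                      mcl4 = integer(), qsm = integer(), nProbes = integer(),
                      range_start = integer(), range_end = integer(),
                      lstarts = list())
  } else {
    out <- obs[, {
      ls <- saturate_first(lstart, capacity)
      t4 <- top4(mcl)
      list(nAligns = .N, nlstart = length(ls),
           mcl1 = t4[1], mcl2 = t4[2], mcl3 = t4[3], mcl4 = t4[4],
           qsm = sum(t4), nProbes = 1L,
           range_start = min(lstart), range_end = max(rend),
           lstarts = list(sort(ls)))
    }, by = .(seqid, lend, rstart)]
  }
  setkeyv(out, c("seqid", "lend", "rstart"))
  setattr(out, "capacity", as.integer(capacity))
  setattr(out, "sample_ids", as.character(sample_id))
  out[]
}

merge_two_records <- function(a, b, capacity) {
  t4 <- top4(c(a$mcl1, a$mcl2, a$mcl3, a$mcl4,
               b$mcl1, b$mcl2, b$mcl3, b$mcl4))
  la <- a$lstarts[[1]]; lb <- b$lstarts[[1]]
  exact <- !is.null(la) && !is.null(lb)
  if (exact) {
    u <- sort(unique(c(la, lb)))
    ls <- u[seq_len(min(length(u), capacity))]   # n smallest: commutative, associative
    nls <- length(ls)
  } else {
    ls <- NULL
    nls <- min(a$nlstart + b$nlstart, capacity)
  }
  list(nAligns = a$nAligns + b$nAligns, nlstart = as.integer(nls),
       mcl1 = t4[1], mcl2 = t4[2], mcl3 = t4[3], mcl4 = t4[4],
       qsm = sum(t4), nProbes = a$nProbes + b$nProbes,
       range_start = min(a$range_start, b$range_start),
       range_end = max(a$range_end, b$range_end),
       lstarts = list(ls))
}

#' Merge gap-site tables across samples
#'
#' Records sharing a key are combined under saturating semantics:
#' `nAligns` and `nProbes` add, the four largest `mcl` of the union are
#' kept, distinct left starts are united and saturated at the capacity `n`
#' (the `n` smallest are retained, which makes merging commutative and
#' associative), and the supported range widens to the extremes. Disjoint
#' keys concatenate unchanged, so merging never decreases any evidence
#' statistic.
#'
#' Tables imported from TSV lack the `lstarts` sets; for those, merged
#' `nlstart` falls back to the saturating sum `min(sum, n)`.
#'
#' @param ... two or more gap-site tables from [accumulate_gap_sites()] or
#'   [read_gap_sites()].
#' @param capacity saturation capacity `n` (default 8).
#' @return merged keyed `data.table` of gap-site records.
#' @export
merge_gap_sites <- function(..., capacity = 8L) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]])) {
    tabs <- tabs[[1]]
  }
  if (!length(tabs)) stop("no tables to merge")
  for (t in tabs) {
    if (!all(c("seqid", "lend", "rstart", "nAligns") %in% names(t))) {
      stop("not a gap-site table")
    }
  }
  tabs <- lapply(tabs, function(t) {
    t <- as.data.table(t)
    if (!"lstarts" %in% names(t)) t[, lstarts := list(rep(list(NULL), .N))]
    t
  })
  all <- rbindlist(tabs, use.names = TRUE, fill = FALSE)
  out <- all[, {
    acc <- .SD[1]
    if (.N > 1L) for (i in 2:.N) acc <- as.data.table(
      merge_two_records(acc, .SD[i], capacity))
    acc
  }, by = .(seqid, lend, rstart)]
  setkeyv(out, c("seqid", "lend", "rstart"))
  setattr(out, "capacity", as.integer(capacity))
  sids <- unlist(lapply(tabs, attr, "sample_ids"))
  setattr(out, "sample_ids", unique(sids))
  out[]
}

#' Extract and accumulate gap-sites from one alignment file
#'
#' Convenience composition of [gap_observations_from_bam()] and
#' [accumulate_gap_sites()].
#'
#' @inheritParams gap_observations_from_bam
#' @inheritParams accumulate_gap_sites
#' @return gap-site `data.table`; attribute `rejected` carries the
#'   zero-flank diagnostics tally.
#' @export
extract_gap_sites <- function(file, sample_id = basename(file),
                              capacity = 8L, keep_secondary = FALSE,
                              min_mapq = NULL) {
  obs <- gap_observations_from_bam(file, keep_secondary = keep_secondary,
                                   min_mapq = min_mapq)
  out <- accumulate_gap_sites(obs, sample_id = sample_id, capacity = capacity)
  setattr(out, "rejected", attr(obs, "rejected"))
  out
}

#' Write / read a gap-site table as TSV
#'
#' The on-disk format has a mandatory header and the columns `seqid`,
#' `lend`, `rstart`, `nAligns`, `nlstart`, `mcl1..mcl4` (missing slots 0),
#' `qsm`, `nProbes`, `range_start`, `range_end`; any scoring or annotation
#' columns present are appended after these. The in-memory `lstarts`
#' list-column is not serialised.
#'
#' @param sites gap-site `data.table`.
#' @param file output/input path.
#' @return `write_gap_sites()` returns `file` invisibly; `read_gap_sites()`
#'   returns a keyed `data.table`.
#' @export
write_gap_sites <- function(sites, file) {
  core <- c("seqid", "lend", "rstart", "nAligns", "nlstart",
            "mcl1", "mcl2", "mcl3", "mcl4", "qsm", "nProbes",
            "range_start", "range_end")
  extra <- setdiff(names(sites), c(core, "lstarts"))
  keep <- c(core, extra)
  out <- as.data.table(sites)[, ..keep]
  if ("wgis" %in% names(out)) out[, wgis := round(wgis, 3)]
  fwrite(out, file, sep = "\t", quote = FALSE, na = "NA")
  invisible(file)
}

#' @rdname write_gap_sites
#' @export
read_gap_sites <- function(file) {
  out <- fread(file, sep = "\t", header = TRUE,
               colClasses = list(character = "seqid"))
  setkeyv(out, c("seqid", "lend", "rstart"))
  out[]
}
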