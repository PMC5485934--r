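#' @title Intronic dinucleotide (IDIN) and sequence-logo statistics
#' @description
#' The intronic dinucleotides are the two intron bases adjacent to each
#' gap-site boundary: the left IDIN follows `lend`, the right IDIN precedes
#' `rstart` (genome orientation). With a strand assignment they are
#' reclassified into 5' and 3' splice-junction dinucleotides: on the plus
#' strand 5'IDIN = left and 3'IDIN = right; on the minus strand 5'IDIN is
#' the reverse complement of the right IDIN and 3'IDIN the reverse
#' complement of the left IDIN. Canonical major-spliceosome junctions read
#' GT..AG in strand-corrected orientation, minor-spliceosome ones AT..AC.
#' @name idin_stats
NULL

#' Extract raw intronic dinucleotides for gap-sites
#'
#' `left = genome[lend+1 .. lend+2]`, `right = genome[rstart-2 .. rstart-1]`
#' (genome orientation). Sites with an intron shorter than 4 bases (where
#' the two dinucleotides would overlap or be ill-defined) are flagged `NA`
#' and excluded from downstream tables.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param sites gap-site `data.table` (columns `seqid`, `lend`, `rstart`).
#' @return copy of `sites` with `left_idin`, `right_idin` appended.
#' @export
site_idin <- function(genome, sites) {
  genome <- load_genome(genome)
  out <- as.data.table(sites)
  if (nrow(out) == 0L) {
    out[, `:=`(left_idin = character(), right_idin = character())]
    return(out[])
  }
  ok <- (out$rstart - out$lend - 1L) >= 4L
  li <- ri <- rep(NA_character_, nrow(out))
  li[ok] <- genome_slice(genome, out$seqid[ok], out$lend[ok] + 1L,
                         out$lend[ok] + 2L)
  ri[ok] <- genome_slice(genome, out$seqid[ok], out$rstart[ok] - 2L,
                         out$rstart[ok] - 1L)
  out[, `:=`(left_idin = toupper(li), right_idin = toupper(ri))]
  out[]
}

#' Strand-correct intronic dinucleotides
#'
#' @param left_idin,right_idin raw dinucleotides in genome orientation.
#' @param strand `"+"`, `"-"` or `NA` (undefined; yields `NA`s).
#' @return `data.table` with columns `idin5`, `idin3` in strand-corrected
#'   (5' to 3') orientation.
#' @export
strand_correct_idin <- function(left_idin, right_idin, strand) {
  minus <- !is.na(strand) & strand == "-"
  plus <- !is.na(strand) & strand == "+"
  i5 <- i3 <- rep(NA_character_, length(strand))
  i5[plus] <- left_idin[plus]
  i3[plus] <- right_idin[plus]
  if (any(minus)) {
    i5[minus] <- revcomp(right_idin[minus])
    i3[minus] <- revcomp(left_idin[minus])
  }
  data.table(idin5 = i5, idin3 = i3)
}

#' Tabulate IDIN pairs by occurrence
#'
#' Each gap-site counts once regardless of its alignment coverage
#' (occurrence, not abundance). `NA` dinucleotides are dropped.
#'
#' @param first,second dinucleotide vectors (raw left/right or
#'   strand-corrected 5'/3').
#' @return `data.table` with columns `pair` (e.g. `"GT-AG"`), `count`,
#'   `percent`, sorted by decreasing count.
#' @export
idin_pair_table <- function(first, second) {
  ok <- !is.na(first) & !is.na(second)
  if (!any(ok)) {
    return(data.table(pair = character(), count = integer(),
                      percent = numeric()))
  }
  dt <- data.table(pair = paste0(first[ok], "-", second[ok]))
  out <- dt[, .(count = .N), by = pair]
  out[, percent := 100 * count / sum(count)]
  setorder(out, -count, pair)
  out[]
}

#' Upper bound for the proportion of canonical GT-AG junctions
#'
#' Without strand information a minus-strand GT-AG junction appears as
#' CT-AG read from the genome, so the proportions of raw GT-AG and CT-AG
#' pairs added together bound the true GT-AG fraction from above.
#'
#' @param pair_table `data.table` from [idin_pair_table()], or a named
#'   count vector keyed like `"GT-AG"`.
#' @return percentage in `[0, 100]`.
#' @export
#' @examples
#' gtag_upper_bound(c("GT-AG" = 50, "CT-AG" = 46, "AT-AC" = 4))  # 96
gtag_upper_bound <- function(pair_table) {
  if (is.data.frame(pair_table)) {
    counts <- setNames(pair_table$count, pair_table$pair)
  } else {
    counts <- pair_table
  }
  if (!length(counts) || sum(counts) == 0) stop("empty IDIN pair table")
  hit <- sum(counts[names(counts) %in% c("GT-AG", "CT-AG")])
  100 * hit / sum(counts)
}

#' Per-position nucleotide frequency matrix for sequence logos
#'
#' @param windows equal-width strand-corrected sequences; windows with
#'   non-ACGT characters are dropped (their number is in the `dropped`
#'   attribute).
#' @param junction_after optional position index marking the junction
#'   (stored as attribute for labelling).
#' @return `data.table` with columns `position`, `A`, `C`, `G`, `T`
#'   (relative frequencies summing to 1 per row) plus attribute `ordering`:
#'   per position, the bases in decreasing frequency (ties alphabetical).
#' @export
logo_matrix <- function(windows, junction_after = NULL) {
  if (!length(windows)) stop("no windows for logo matrix")
  w <- unique(nchar(windows))
  if (length(w) != 1L) stop("mixed window widths: ", paste(w, collapse = ", "))
  keep <- !is.na(windows) & !grepl("[^ACGTacgt]", windows)
  dropped <- sum(!keep)
  if (!any(keep)) stop("no ACGT-only windows for logo matrix")
  m <- seq_matrix(toupper(windows[keep]), w)
  freq <- t(sapply(seq_len(w), function(j) {
    tabulate(factor(m[, j], levels = BASES), nbins = 4L) / sum(keep)
  }))
  colnames(freq) <- BASES
  out <- data.table(position = seq_len(w))
  out <- cbind(out, as.data.table(freq))
  ordering <- lapply(seq_len(w), function(j) {
    f <- freq[j, ]
    names(sort(f, decreasing = TRUE))   # sort() is stable; names pre-sorted A<C<G<T
  })
  setattr(out, "ordering", ordering)
  setattr(out, "dropped", dropped)
  setattr(out, "junction_after", junction_after)
  out[]
}

#' Strand-corrected junction windows for logos
#'
#' Extracts fixed-width windows around the 5' (donor) or 3' (acceptor)
#' junction of each stranded gap-site, reverse-complementing minus-strand
#' windows so all sequences read 5' to 3'. Defaults follow the scoring
#' conventions: donor 3 exonic + 6 intronic bases; acceptor 8 intronic +
#' 4 exonic bases (junction after position 8). Sites with undefined strand
#' or out-of-bounds windows are skipped.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param sites scored gap-site table with a `strand` column.
#' @param side `"donor"` or `"acceptor"`.
#' @param exonic,intronic window extents in bases on each side of the
#'   junction.
#' @return character vector of windows.
#' @export
junction_logo_windows <- function(genome, sites,
                                  side = c("donor", "acceptor"),
                                  exonic = if (side == "donor") 3L else 4L,
                                  intronic = if (side == "donor") 6L else 8L) {
  side <- match.arg(side)
  genome <- load_genome(genome)
  s <- as.data.table(sites)
  s <- s[!is.na(strand)]
  if (nrow(s) == 0L) return(character())
  if (side == "donor") {
    ## 5' junction: at lend on "+", at rstart on "-"
    fw <- genome_slice(genome, s$seqid, s$lend - exonic + 1L,
                       s$lend + intronic)
    rv <- genome_slice(genome, s$seqid, s$rstart - intronic,
                       s$rstart + exonic - 1L)
  } else {
    ## 3' junction: at rstart on "+", at lend on "-"
    fw <- genome_slice(genome, s$seqid, s$rstart - intronic,
                       s$rstart + exonic - 1L)
    rv <- genome_slice(genome, s$seqid, s$lend - exonic + 1L,
                       s$lend + intronic)
  }
  out <- ifelse(s$strand == "+", fw,
                ifelse(is.na(rv), NA_character_, revcomp(rv)))
  toupper(out[!is.na(out)])
}

#' Export gap-sites as BED6
#'
#' One record per site: name `idin5-idin3` (raw left/right when no strand),
#' score = `gql` when present (else 0), strand from wgis (`.` when
#' undefined). Coordinates cover the intron, converted to BED half-open.
#'
#' @param sites gap-site table (ideally scored and passed through
#'   [site_idin()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_gap_sites_bed <- function(sites, file) {
  s <- as.data.table(sites)
  name <- if (all(c("left_idin", "right_idin") %in% names(s))) {
    str <- if ("strand" %in% names(s)) s$strand else NA_character_
    corr <- strand_correct_idin(s$left_idin, s$right_idin, str)
    ifelse(is.na(corr$idin5), paste0(s$left_idin, "-", s$right_idin),
           paste0(corr$idin5, "-", corr$idin3))
  } else rep(".", nrow(s))
  bed <- data.table(
    chrom = s$seqid,
    start = s$lend,                 # 0-based start of intron = lend (1-based) + 1 - 1
    end = s$rstart - 1L,            # half-open end = last intron base
    name = name,
    score = if ("gql" %in% names(s)) s$gql else 0L,
    strand = if ("strand" %in% names(s)) ifelse(is.na(s$strand), ".", s$strand)
             else ".")
  fwrite(bed, file, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(file)
}
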