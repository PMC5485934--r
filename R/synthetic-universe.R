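#' @title Seeded synthetic test universe
#' @description
#' Generates a self-contained desk-scale dataset with known ground truth: a
#' random genome (FASTA), multi-exon genes with canonical splice-site
#' windows planted at every exon-intron boundary (Ensembl-dialect GTF), and
#' spliced reads emitted directly as aligned SAM records with exact
#' coordinates and `M-N-M` CIGARs, so no external aligner is ever invoked.
#' Noise junctions with low coverage and random boundaries are planted away
#' from the true ones. Everything derives from one seeded pseudo-random
#' stream, so identical configurations give byte-identical outputs.
#' @name synthetic_data
NULL

#' Default donor / acceptor sampling profiles
#'
#' Position probability matrices the generator samples splice-site windows
#' from. The donor profile is centred on the canonical 9-mer `CAGGTAAGT`
#' with the invariant intronic GT at window positions 4-5 fixed; the
#' acceptor profile has a pyrimidine-rich tract over intronic positions
#' 1-17, a branch-adjacent C at 18 and the invariant AG at positions 19-20
#' fixed, followed by 3 exonic bases. These are generic consensus
#' stand-ins, not calibrated to any particular dataset.
#'
#' @return 4 x width probability matrix (rows A, C, G, T).
#' @export
default_donor_profile <- function() {
  consensus <- strsplit("CAGGTAAGT", "")[[1]]
  p <- matrix(0.01, 4, 9, dimnames = list(BASES, NULL))
  for (j in 1:9) p[consensus[j], j] <- 0.97
  p[, 4] <- c(0, 0, 1, 0)   # G
  p[, 5] <- c(0, 0, 0, 1)   # T
  p
}

#' @rdname default_donor_profile
#' @export
default_acceptor_profile <- function() {
  p <- matrix(0.25, 4, 23, dimnames = list(BASES, NULL))
  for (j in 1:17) p[, j] <- c(0.015, 0.485, 0.015, 0.485)  # pyrimidine tract
  p[, 18] <- c(0.01, 0.97, 0.01, 0.01)                     # C
  p[, 19] <- c(1, 0, 0, 0)                                 # A
  p[, 20] <- c(0, 0, 1, 0)                                 # G
  p[, 21] <- c(0.1, 0.1, 0.7, 0.1)                         # exonic G bias
  p
}

sample_from_profile <- function(profile) {
  paste(vapply(seq_len(ncol(profile)), function(j) {
    sample(BASES, 1L, prob = profile[, j])
  }, character(1)), collapse = "")
}

profile_mode <- function(profile) {
  paste(BASES[apply(profile, 2, which.max)], collapse = "")
}

replace_slice <- function(chrom_chars, start, s) {
  chrom_chars[start:(start + nchar(s) - 1L)] <- strsplit(s, "")[[1]]
  chrom_chars
}

## off-centre left-segment lengths: 4 centred reads (mcl 50) + distinct starts
read_left_lengths <- function(coverage) {
  if (coverage > 34L) stop("coverage_true > 34 not supported (left-segment ",
                           "lengths would leave the 20..80 range)")
  base <- rep(50L, min(coverage, 4L))
  k <- seq_len(max(coverage - 4L, 0L))
  delta <- as.integer(ceiling(k / 2) * 2 * ifelse(k %% 2 == 1, -1, 1))
  c(base, 50L + delta)
}

fasta_lines <- function(seqs) {
  unlist(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    c(paste0(">", nm),
      substring(s, seq(1, nchar(s), 70), pmin(seq(1, nchar(s), 70) + 69,
                                              nchar(s))))
  }))
}

#' Generate the synthetic universe
#'
#' Places `n_genes` genes (each `exons_per_gene` exons of 150 bases joined
#' by 300-base introns) on `n_chrom` random chromosomes, planting
#' donor/acceptor windows sampled from the profiles at every junction in
#' strand orientation. Every true junction receives `coverage_true` spliced
#' reads of length `read_length`: four centred on the gap (flanking match
#' length 50, so `qsm = 200`) and the rest at distinct off-centre start
#' positions, which makes every true plant gqs-validated when
#' `coverage_true >= 12`. Noise junctions (a `noise_fraction` of the true
#' count) are placed at least 50 bases from any true plant, with coverage
#' drawn from `coverage_noise` and random boundaries.
#'
#' @param outdir output directory (created if missing).
#' @param n_chrom,chrom_length,n_genes,exons_per_gene universe dimensions.
#' @param read_length read length (default 100; the scoring conventions
#'   assume this scale).
#' @param coverage_true supporting alignments per true junction
#'   (default 12).
#' @param noise_fraction noise junctions as a fraction of true junctions.
#' @param coverage_noise vector to draw noise coverage from (default 1:3).
#' @param donor_profile,acceptor_profile sampling profiles (4 x 9 and
#'   4 x 23 probability matrices).
#' @param seed mandatory integer seed.
#' @return list with paths `fasta`, `gtf`, `sam`, `truth`, the `truth`
#'   table (`data.table`: `seqid`, `lend`, `rstart`, `strand`, `class`,
#'   `coverage`, `donor_window`, `acceptor_window`), and the profiles used.
#' @export
generate_universe <- function(outdir,
                              n_chrom = 2L, chrom_length = 100000L,
                              n_genes = 6L, exons_per_gene = 4L,
                              read_length = 100L,
                              coverage_true = 12L,
                              noise_fraction = 0.3,
                              coverage_noise = 1:3,
                              donor_profile = default_donor_profile(),
                              acceptor_profile = default_acceptor_profile(),
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (read_length != 100L) {
    stop("read_length is fixed at 100 in this generator")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  exon_len <- 150L; intron_len <- 300L
  gene_span <- exons_per_gene * exon_len + (exons_per_gene - 1L) * intron_len
  margin <- 1000L; spacing <- 1500L
  genes_per_chrom <- ceiling(n_genes / n_chrom)
  need <- margin * 2L + genes_per_chrom * (gene_span + spacing)
  if (n_genes > 0L && chrom_length < need) {
    stop("chrom_length ", chrom_length, " too small for ", genes_per_chrom,
         " gene(s) per chromosome (need >= ", need, ")")
  }

  chroms <- paste0("chr", seq_len(n_chrom))
  genome_chars <- lapply(chroms, function(x) {
    sample(BASES, chrom_length, replace = TRUE)
  })
  names(genome_chars) <- chroms

  truth <- list(); gtf_lines <- character(); reads <- list()
  junction_keys <- data.table(seqid = character(), pos = integer())

  for (g in seq_len(n_genes)) {
    ci <- ((g - 1L) %% n_chrom) + 1L
    slot <- (g - 1L) %/% n_chrom
    gstart <- margin + slot * (gene_span + spacing) + 1L
    strand <- sample(c("+", "-"), 1L)
    ex_start <- gstart + (seq_len(exons_per_gene) - 1L) * (exon_len + intron_len)
    ex_end <- ex_start + exon_len - 1L
    gid <- paste0("gene", g); tid <- paste0(gid, ".t1")

    exon_no <- if (strand == "+") seq_len(exons_per_gene)
               else rev(seq_len(exons_per_gene))
    gtf_lines <- c(gtf_lines, vapply(seq_len(exons_per_gene), function(k) {
      paste(chroms[ci], "gapsites_synth", "exon", ex_start[k], ex_end[k],
            ".", strand, ".",
            sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                    gid, tid, exon_no[k]),
            sep = "\t")
    }, character(1)))

    for (j in seq_len(exons_per_gene - 1L)) {
      lend <- ex_end[j]; rstart <- ex_start[j + 1L]
      donor <- sample_from_profile(donor_profile)
      acceptor <- sample_from_profile(acceptor_profile)
      gc <- genome_chars[[ci]]
      if (strand == "+") {
        gc <- replace_slice(gc, lend - 2L, donor)
        gc <- replace_slice(gc, rstart - 20L, acceptor)
      } else {
        gc <- replace_slice(gc, rstart - 6L, revcomp(donor))
        gc <- replace_slice(gc, lend - 2L, revcomp(acceptor))
      }
      genome_chars[[ci]] <- gc
      truth[[length(truth) + 1L]] <- data.table(
        seqid = chroms[ci], lend = lend, rstart = rstart, strand = strand,
        class = "true-splice", coverage = as.integer(coverage_true),
        donor_window = donor, acceptor_window = acceptor)
      junction_keys <- rbind(junction_keys,
                             data.table(seqid = chroms[ci],
                                        pos = c(lend, rstart)))
    }
  }

  n_true <- length(truth)
  n_noise <- round(noise_fraction * n_true)
  for (k in seq_len(n_noise)) {
    placed <- FALSE
    for (try in 1:200) {
      ci <- sample.int(n_chrom, 1L)
      lend <- sample(200:(chrom_length - 1500L), 1L)
      ilen <- sample(80:1000, 1L)
      rstart <- lend + ilen + 1L
      cand <- c(lend, rstart)
      clash <- junction_keys[seqid == chroms[ci]]
      if (nrow(clash) == 0L ||
          min(abs(outer(cand, clash$pos, "-"))) >= 50L) {
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place noise junction ", k,
                      " at least 50 bases from existing plants")
    cov <- sample(coverage_noise, 1L)
    truth[[length(truth) + 1L]] <- data.table(
      seqid = chroms[ci], lend = lend, rstart = rstart,
      strand = sample(c("+", "-"), 1L),
      class = "noise", coverage = as.integer(cov),
      donor_window = NA_character_, acceptor_window = NA_character_)
    junction_keys <- rbind(junction_keys,
                           data.table(seqid = chroms[ci],
                                      pos = c(lend, rstart)))
  }
  truth_dt <- if (n_true + n_noise > 0L) rbindlist(truth) else
    data.table(seqid = character(), lend = integer(), rstart = integer(),
               strand = character(), class = character(),
               coverage = integer(), donor_window = character(),
               acceptor_window = character())

  ## reads: emitted pre-aligned
  genome_str <- vapply(genome_chars, paste, character(1), collapse = "")
  rid <- 0L
  for (i in seq_len(nrow(truth_dt))) {
    tr <- truth_dt[i]
    ilen <- tr$rstart - tr$lend - 1L
    lls <- if (tr$class == "true-splice") read_left_lengths(tr$coverage)
           else sample(30:70, tr$coverage)
    for (L in lls) {
      rid <- rid + 1L
      pos <- tr$lend - L + 1L
      rlen <- read_length - L
      seqs <- paste0(substr(genome_str[[tr$seqid]], pos, tr$lend),
                     substr(genome_str[[tr$seqid]], tr$rstart,
                            tr$rstart + rlen - 1L))
      reads[[length(reads) + 1L]] <- data.table(
        qname = sprintf("read%06d", rid), flag = 0L, rname = tr$seqid,
        pos = pos, mapq = 60L,
        cigar = sprintf("%dM%dN%dM", L, ilen, rlen),
        seq = seqs)
    }
  }
  reads_dt <- if (length(reads)) rbindlist(reads) else
    data.table(qname = character(), flag = integer(), rname = character(),
               pos = integer(), mapq = integer(), cigar = character(),
               seq = character())
  setorder(reads_dt, rname, pos, qname)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(outdir, "genome.fa")
  gtf <- file.path(outdir, "annotation.gtf")
  sam <- file.path(outdir, "reads.sam")
  truth_path <- file.path(outdir, "truth.tsv")

  writeLines(fasta_lines(genome_str), fasta)
  writeLines(gtf_lines, gtf)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", chroms, "\tLN:", chrom_length))
  body <- if (nrow(reads_dt)) {
    reads_dt[, paste(qname, flag, rname, pos, mapq, cigar,
                     "*", 0L, 0L, seq, "*", sep = "\t")]
  } else character()
  writeLines(c(header, body), sam)
  setorder(truth_dt, seqid, lend, rstart)
  fwrite(truth_dt, truth_path, sep = "\t", quote = FALSE, na = "NA")

  list(fasta = fasta, gtf = gtf, sam = sam, truth = truth_path,
       truth_table = truth_dt,
       donor_profile = donor_profile, acceptor_profile = acceptor_profile)
}
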