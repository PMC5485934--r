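#' @title Splice-site sequence windows and scoring models
#' @description
#' Donor (5') sites are scored on 9-mers spanning positions -3..+6 around
#' the exon-intron boundary (3 exonic, 6 intronic bases) and acceptor (3')
#' sites on 23-mers spanning -20..+3 (20 intronic, 3 exonic bases). For an
#' unstranded gap-site both strand hypotheses are evaluated: forward
#' windows at `lend` (donor) and `rstart` (acceptor), and
#' reverse-complemented windows at `rstart` (donor) and `lend` (acceptor).
#' Scoring is pluggable: pre-calculated maximum-entropy odds tables, or a
#' trainable log-odds position weight matrix (WMM) for self-contained use.
#' @name splice_models
NULL

DONOR_WIDTH <- 9L
ACCEPTOR_WIDTH <- 23L

#' Extract donor/acceptor windows for gap-sites
#'
#' 1-based inclusive window arithmetic, derived solely from `(lend, rstart)`:
#' * `donor_plus    = genome[lend-2 .. lend+6]`
#' * `acceptor_plus = genome[rstart-20 .. rstart+2]`
#' * `donor_minus   = revcomp(genome[rstart-6 .. rstart+2])`
#' * `acceptor_minus= revcomp(genome[lend-2 .. lend+20])`
#'
#' Windows exceeding chromosome bounds are `NA` (unscorable).
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param seqid,lend,rstart vectors of gap-site keys.
#' @return `data.table` with columns `donor_plus`, `acceptor_plus`,
#'   `donor_minus`, `acceptor_minus` (uppercase character, `NA` when out of
#'   bounds).
#' @export
splice_windows <- function(genome, seqid, lend, rstart) {
  genome <- load_genome(genome)
  dp <- genome_slice(genome, seqid, lend - 2L, lend + 6L)
  ap <- genome_slice(genome, seqid, rstart - 20L, rstart + 2L)
  dm <- genome_slice(genome, seqid, rstart - 6L, rstart + 2L)
  am <- genome_slice(genome, seqid, lend - 2L, lend + 20L)
  data.table(donor_plus = toupper(dp),
             acceptor_plus = toupper(ap),
             donor_minus = ifelse(is.na(dm), NA, revcomp(toupper(dm))),
             acceptor_minus = ifelse(is.na(am), NA, revcomp(toupper(am))))
}

BASES <- c("A", "C", "G", "T")

seq_matrix <- function(seqs, width) {
  bad <- is.na(seqs) | nchar(seqs) != width
  if (any(bad)) stop("all sequences must have width ", width)
  matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
         nrow = length(seqs), ncol = width, byrow = TRUE)
}

#' Train a log-odds position weight matrix (WMM)
#'
#' Per-position nucleotide frequencies of the signal windows, smoothed with
#' a pseudocount, against a per-position background (uniform by default).
#' Scores are `sum(log2(p_signal / p_background))` over positions;
#' deterministic given its inputs. Increasing the pseudocount shrinks every
#' score toward 0.
#'
#' @param signal_windows character vector of equal-width ACGT strings
#'   (at least one).
#' @param background `"uniform"` or a 4 x width matrix of per-position
#'   background probabilities (rows A, C, G, T).
#' @param pseudocount added to every per-position base count (default 0.5).
#' @return object of class `wmm` with fields `width`, `prob` (4 x width
#'   signal probabilities) and `logodds`.
#' @export
train_wmm <- function(signal_windows, background = "uniform",
                      pseudocount = 0.5) {
  if (length(signal_windows) < 1L) stop("need at least one signal window")
  w <- unique(nchar(signal_windows))
  if (length(w) != 1L) stop("mixed window widths: ", paste(w, collapse = ", "))
  m <- seq_matrix(signal_windows, w)
  counts <- sapply(seq_len(w), function(j) {
    tabulate(factor(m[, j], levels = BASES), nbins = 4L)
  })                                           # 4 x w
  prob <- (counts + pseudocount) / rep(colSums(counts) + 4 * pseudocount,
                                       each = 4)
  dimnames(prob) <- list(BASES, NULL)
  wmm_from_profile(prob, background = background)
}

#' Build a WMM directly from a probability profile
#'
#' @param profile 4 x width matrix of per-position signal probabilities
#'   (rows named A, C, G, T; columns sum to 1).
#' @inheritParams train_wmm
#' @return object of class `wmm`.
#' @export
wmm_from_profile <- function(profile, background = "uniform") {
  stopifnot(is.matrix(profile), nrow(profile) == 4L)
  if (is.null(rownames(profile))) rownames(profile) <- BASES
  profile <- profile[BASES, , drop = FALSE]
  w <- ncol(profile)
  bg <- if (identical(background, "uniform")) {
    matrix(0.25, 4, w, dimnames = list(BASES, NULL))
  } else {
    stopifnot(is.matrix(background), dim(background) == c(4L, w))
    bg <- background[BASES, , drop = FALSE]
  }
  structure(list(kind = "wmm", width = w, prob = profile, background = bg,
                 logodds = log2(profile / bg)),
            class = "wmm")
}

score_wmm <- function(model, seqs) {
  out <- rep(NA_real_, length(seqs))
  ok <- !is.na(seqs) & nchar(seqs) == model$width &
    !grepl("[^ACGT]", seqs)
  if (any(ok)) {
    m <- seq_matrix(seqs[ok], model$width)
    idx_row <- match(m, BASES)                     # column-major over positions
    lo <- matrix(model$logodds[cbind(as.vector(idx_row),
                                     rep(seq_len(model$width),
                                         each = sum(ok)))],
                 nrow = sum(ok))
    out[ok] <- rowSums(lo)
  }
  out
}

## acceptor decomposition: 7-mer marginals and 3-mer overlaps over the 23-mer
ACC_MARGINALS <- list(1:7, 5:11, 9:15, 13:19, 17:23)
ACC_OVERLAPS  <- list(5:7, 9:11, 13:15, 17:19)

kmer_index <- function(seqs, positions) {
  ## base-4 index (A=0 C=1 G=2 T=3), first position most significant; 1-based
  m <- seq_matrix(seqs, nchar(seqs[1]))
  sub <- m[, positions, drop = FALSE]
  dig <- match(sub, BASES) - 1L
  dim(dig) <- dim(sub)
  k <- length(positions)
  idx <- rep(0, nrow(sub))
  for (j in seq_len(k)) idx <- idx * 4 + dig[, j]
  as.integer(idx + 1L)
}

#' Load maximum-entropy splice-site score tables
#'
#' Canonical table layout: a directory containing plain-text files with one
#' positive odds value per line, line `i` holding the value for the k-mer
#' whose base-4 index (A=0, C=1, G=2, T=3, first position most significant)
#' is `i - 1`:
#' * `donor.txt` — 4^9 = 262144 values, the full 9-mer table;
#'   `score5 = log2(donor[window])`.
#' * `acceptor_m1.txt` .. `acceptor_m5.txt` — 4^7 values each, marginal
#'   tables over 23-mer positions 1-7, 5-11, 9-15, 13-19, 17-23; and
#'   `acceptor_o1.txt` .. `acceptor_o4.txt` — 4^3 values each, overlap
#'   tables over positions 5-7, 9-11, 13-15, 17-19. By inclusion-exclusion
#'   `score3 = log2(prod(marginals) / prod(overlaps))`.
#'
#' @param path directory with the table files.
#' @return object of class `maxent_table` usable by [score5()] /
#'   [score3()].
#' @export
load_maxent_tables <- function(path) {
  if (!dir.exists(path)) stop("maxent table directory not found: ", path)
  read_tab <- function(name, n) {
    f <- file.path(path, name)
    if (!file.exists(f)) stop("missing maxent table file: ", f)
    v <- scan(f, what = numeric(), quiet = TRUE)
    if (length(v) != n) {
      stop("maxent table ", name, " has ", length(v), " values, expected ", n)
    }
    v
  }
  donor <- read_tab("donor.txt", 4^DONOR_WIDTH)
  marg <- lapply(seq_along(ACC_MARGINALS), function(i) {
    read_tab(sprintf("acceptor_m%d.txt", i), 4^7)
  })
  ovl <- lapply(seq_along(ACC_OVERLAPS), function(i) {
    read_tab(sprintf("acceptor_o%d.txt", i), 4^3)
  })
  structure(list(kind = "maxent-table", donor = donor,
                 marginals = marg, overlaps = ovl),
            class = "maxent_table")
}

score_maxent5 <- function(model, seqs) {
  out <- rep(NA_real_, length(seqs))
  ok <- !is.na(seqs) & nchar(seqs) == DONOR_WIDTH & !grepl("[^ACGT]", seqs)
  if (any(ok)) {
    out[ok] <- log2(model$donor[kmer_index(seqs[ok], 1:DONOR_WIDTH)])
  }
  out
}

score_maxent3 <- function(model, seqs) {
  out <- rep(NA_real_, length(seqs))
  ok <- !is.na(seqs) & nchar(seqs) == ACCEPTOR_WIDTH & !grepl("[^ACGT]", seqs)
  if (any(ok)) {
    s <- seqs[ok]
    num <- rep(1, length(s))
    for (i in seq_along(ACC_MARGINALS)) {
      num <- num * model$marginals[[i]][kmer_index(s, ACC_MARGINALS[[i]])]
    }
    den <- rep(1, length(s))
    for (i in seq_along(ACC_OVERLAPS)) {
      den <- den * model$overlaps[[i]][kmer_index(s, ACC_OVERLAPS[[i]])]
    }
    out[ok] <- log2(num / den)
  }
  out
}

#' Combine donor and acceptor scorers into a splice-site model
#'
#' @param donor scorer for 9-mers: a `wmm` of width 9, or a `maxent_table`.
#' @param acceptor scorer for 23-mers: a `wmm` of width 23, or the same
#'   `maxent_table`.
#' @return object of class `splice_score_model` with fields `kind`,
#'   `donor`, `acceptor`.
#' @export
splice_score_model <- function(donor, acceptor) {
  chk <- function(m, width, what) {
    if (inherits(m, "wmm")) {
      if (m$width != width) stop(what, " wmm must have width ", width)
    } else if (!inherits(m, "maxent_table")) {
      stop(what, " scorer must be a wmm or maxent_table")
    }
  }
  chk(donor, DONOR_WIDTH, "donor")
  chk(acceptor, ACCEPTOR_WIDTH, "acceptor")
  kind <- if (inherits(donor, "maxent_table") &&
              inherits(acceptor, "maxent_table")) "maxent-table" else "wmm"
  structure(list(kind = kind, donor = donor, acceptor = acceptor),
            class = "splice_score_model")
}

#' Score donor 9-mers / acceptor 23-mers
#'
#' Total deterministic functions on ACGT strings of the declared width;
#' windows containing other characters (e.g. `N`) or of wrong width score
#' `NA` (unscorable, which fails the wgis threshold).
#'
#' @param model `splice_score_model`, `wmm` or `maxent_table`.
#' @param seqs character vector of windows.
#' @return numeric vector of log2-odds scores.
#' @export
score5 <- function(model, seqs) {
  m <- if (inherits(model, "splice_score_model")) model$donor else model
  if (inherits(m, "wmm")) score_wmm(m, seqs) else score_maxent5(m, seqs)
}

#' @rdname score5
#' @export
score3 <- function(model, seqs) {
  m <- if (inherits(model, "splice_score_model")) model$acceptor else model
  if (inherits(m, "wmm")) score_wmm(m, seqs) else score_maxent3(m, seqs)
}
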