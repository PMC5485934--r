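#' @title Gap-site quality scores
#' @description
#' Two validation scores for gap-sites. The gap quality score (gqs) uses
#' alignment evidence alone; the weighted gap information score (wgis)
#' additionally weighs donor (5') and acceptor (3') splice-site sequence
#' scores and carries the inferred strand in its sign. Both are monotone
#' under evidence accumulation: merging further alignments into a record
#' can only raise them.
#' @name scoring
NULL

#' Gap quality score (gqs)
#'
#' `gqs = trunc(10 * (2 * min(nlstart, n) / n) * qsm / 4)`, evaluated in
#' exact integer arithmetic. With the default capacity `n = 8` and read
#' length 100 the score lies in `[0, 1000]`; 1000 requires a saturated
#' `nlstart` (at least 8 distinct left alignment starts) and `qsm = 200`
#' (four gaps flanked by at least 50 matching bases on both sides).
#'
#' @param nlstart number of distinct left alignment start positions
#'   (integer >= 1); saturated at `n` internally.
#' @param qsm quartet sum of the four largest `mcl` values (integer >= 0).
#' @param n saturation capacity (default 8; 4 mimics a 32-bit build).
#' @return integer vector of scores.
#' @export
#' @examples
#' gqs(8, 200)   # 1000
#' gqs(4, 200)   # 500
gqs <- function(nlstart, qsm, n = 8L) {
  stopifnot(all(nlstart >= 1), all(qsm >= 0), n >= 1)
  as.integer((20 * pmin(as.numeric(nlstart), n) * as.numeric(qsm)) %/% (4 * n))
}

#' wgis weight factors
#'
#' The four non-negative factors of the weighted gap information score:
#' * `fnls(nlstart) = log2(log2(nlstart) + 1) + 1`, in `(0, 3]` for
#'   `nlstart` in `1..8`;
#' * `fqsm(qsm) = log2(log2(max(qsm - 13, 2)))`, zero for `qsm <= 15`,
#'   about 2.916 at `qsm = 200`;
#' * `fs5(score5) = log2(max(score5, 1))`, zero for `score5 <= 1`;
#' * `fs3(score3) = log2(max(score3, 1))`, zero for `score3 <= 1`.
#'
#' `fnls` expects `nlstart` already saturated at the capacity.
#'
#' @param nlstart,qsm,score5,score3 numeric vectors.
#' @return numeric vector of factor values.
#' @export
fnls <- function(nlstart) log2(log2(nlstart) + 1) + 1

#' @rdname fnls
#' @export
fqsm <- function(qsm) log2(log2(pmax(qsm - 13, 2)))

#' @rdname fnls
#' @export
fs5 <- function(score5) log2(pmax(score5, 1))

#' @rdname fnls
#' @export
fs3 <- function(score3) log2(pmax(score3, 1))

#' Strand sign from opposing acceptor-site scores
#'
#' A gap-site's strand is inferred from the acceptor (3' splice-site)
#' scores of the two strand hypotheses: when the right boundary read
#' forward resembles an acceptor at least as strongly as the left boundary
#' read in reverse complement, the plus strand is assumed. Ties map to +1.
#'
#' @param score3_plus acceptor score at `rstart`, window read forward.
#' @param score3_minus acceptor score at `lend`, window read
#'   reverse-complemented.
#' @return integer vector of +1 / -1; `NA` where either score is `NA`
#'   (unscorable window).
#' @export
strand_sign <- function(score3_plus, score3_minus) {
  ifelse(is.na(score3_plus) | is.na(score3_minus), NA_integer_,
         ifelse(score3_plus >= score3_minus, 1L, -1L))
}

#' Weighted gap information score (wgis)
#'
#' `wgis = fnls * fqsm * fs5 * fs3 * sstr`: the strand is chosen by
#' [strand_sign()] from the two acceptor scores, the donor/acceptor factors
#' are evaluated on the chosen strand's score pair, and the product is
#' signed by the strand sign. The score is exactly zero when `qsm <= 15`
#' or the chosen strand's `score5 <= 1` or `score3 <= 1`; such sites are
#' not wgis-validated and get no strand. Unscorable windows (`NA` scores,
#' e.g. chromosome edge or non-ACGT content) also give zero, with the
#' reason in `score_status`.
#'
#' @param nlstart,qsm evidence statistics of the record (`nlstart`
#'   saturated at `capacity` internally).
#' @param score5_plus,score3_plus donor score at `lend` / acceptor score at
#'   `rstart`, windows read forward.
#' @param score5_minus,score3_minus donor score at `rstart` / acceptor
#'   score at `lend`, windows read reverse-complemented.
#' @param capacity saturation capacity `n` (default 8).
#' @return `data.table` with columns `fnls`, `fqsm`, `fs5`, `fs3`, `sstr`,
#'   `wgis`, `strand` (`"+"`, `"-"` or `NA` when wgis is zero), `gql`, and
#'   `score_status` (`"ok"` or `"unscorable"`).
#' @export
#' @examples
#' wgis(8, 200, 11.8, 16.1, 0, 0)$wgis   # 124.88... -> the 124.9 maximum
wgis <- function(nlstart, qsm, score5_plus, score3_plus,
                 score5_minus, score3_minus, capacity = 8L) {
  nls <- pmin(nlstart, capacity)
  sstr <- strand_sign(score3_plus, score3_minus)
  unscorable <- is.na(sstr) | is.na(score5_plus) | is.na(score5_minus)
  s5 <- ifelse(!unscorable & sstr > 0, score5_plus, score5_minus)
  s3 <- ifelse(!unscorable & sstr > 0, score3_plus, score3_minus)
  f1 <- fnls(nls)
  f2 <- fqsm(qsm)
  f3 <- ifelse(unscorable, 0, fs5(s5))
  f4 <- ifelse(unscorable, 0, fs3(s3))
  w <- ifelse(unscorable, 0, f1 * f2 * f3 * f4 * sstr)
  strand <- ifelse(w == 0, NA_character_, ifelse(sstr > 0, "+", "-"))
  data.table(fnls = f1, fqsm = f2, fs5 = f3, fs3 = f4,
             sstr = ifelse(unscorable, NA_integer_, sstr),
             wgis = w, strand = strand, gql = gql(w),
             score_status = ifelse(unscorable, "unscorable", "ok"))
}

#' Gap quality level (gql)
#'
#' Partition of the absolute wgis value into four quality levels:
#' `|wgis| = 0` is level 0 (not wgis-validated), `0 < |wgis| <= 30` level 1,
#' `30 < |wgis| <= 80` level 2, `|wgis| > 80` level 3.
#'
#' @param wgis_value numeric vector of signed wgis values.
#' @return integer vector of levels 0-3.
#' @export
gql <- function(wgis_value) {
  a <- abs(wgis_value)
  ifelse(a == 0, 0L, ifelse(a <= 30, 1L, ifelse(a <= 80, 2L, 3L)))
}

#' Validation predicates
#'
#' A gap-site is gqs-validated when its gqs reaches 1000 (kept as `>=` so
#' longer reads cannot un-validate a site) and wgis-validated when its wgis
#' is nonzero.
#'
#' @param gqs_value,wgis_value numeric vectors.
#' @return logical vector.
#' @export
is_gqs_validated <- function(gqs_value) gqs_value >= 1000

#' @rdname is_gqs_validated
#' @export
is_wgis_validated <- function(wgis_value) wgis_value != 0

#' Score a gap-site table
#'
#' Extracts donor/acceptor windows for every site in both orientations
#' ([splice_windows()]), scores them with the given splice-site model, and
#' appends `gqs`, the four window scores, `strand`, `wgis`, `gql` and the
#' validation flags to the table.
#'
#' @param sites gap-site `data.table`.
#' @param genome `DNAStringSet` or FASTA path.
#' @param model a `splice_score_model` (see [splice_score_model()],
#'   [train_wmm()], [load_maxent_tables()]).
#' @param capacity saturation capacity `n` (default 8).
#' @return copy of `sites` with scoring columns appended.
#' @export
score_gap_sites <- function(sites, genome, model, capacity = 8L) {
  genome <- load_genome(genome)
  out <- as.data.table(sites)
  if (nrow(out) == 0L) {
    out[, c("gqs", "score5_plus", "score3_plus", "score5_minus",
            "score3_minus", "strand", "wgis", "gql",
            "gqs_validated", "wgis_validated") :=
          list(integer(), numeric(), numeric(), numeric(), numeric(),
               character(), numeric(), integer(), logical(), logical())]
    return(out[])
  }
  win <- splice_windows(genome, out$seqid, out$lend, out$rstart)
  s5p <- score5(model, win$donor_plus)
  s3p <- score3(model, win$acceptor_plus)
  s5m <- score5(model, win$donor_minus)
  s3m <- score3(model, win$acceptor_minus)
  res <- wgis(out$nlstart, out$qsm, s5p, s3p, s5m, s3m, capacity = capacity)
  out[, `:=`(gqs = gqs(nlstart, qsm, n = capacity),
             score5_plus = s5p, score3_plus = s3p,
             score5_minus = s5m, score3_minus = s3m,
             strand = res$strand, wgis = res$wgis, gql = res$gql)]
  out[, `:=`(gqs_validated = is_gqs_validated(gqs),
             wgis_validated = is_wgis_validated(wgis))]
  out[]
}
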