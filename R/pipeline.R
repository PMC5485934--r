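#' @title End-to-end gap-site validation pipeline
#' @name pipeline
NULL

RUN_CONFIG_KEYS <- c("bam", "genome", "gtf", "model", "outdir",
                     "capacity", "read_length", "logo_exonic",
                     "logo_intronic", "keep_secondary", "min_mapq",
                     "sample_ids", "seed", "log_level")

#' Read and validate a flat key-value run configuration
#'
#' One `key = value` (or `key: value`) pair per line; `#` comments and
#' blank lines ignored. Comma-separated values become vectors. Unknown
#' keys are rejected.
#'
#' @param path config file path.
#' @param allowed permitted key names (defaults to the pipeline keys; the
#'   CLI `simulate` subcommand passes the generator's argument names).
#' @return named list of configuration values.
#' @export
read_run_config <- function(path, allowed = RUN_CONFIG_KEYS) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.*)$",
                                  lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("unparseable config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- lapply(vals, function(v) {
    v <- trimws(strsplit(v, ",")[[1]])
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  names(cfg) <- keys
  cfg
}

validate_run_config <- function(config) {
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  for (k in c("bam", "genome")) {
    if (is.null(config[[k]])) stop("config requires '", k, "'")
  }
  for (f in c(config$bam, config$genome, config$gtf)) {
    if (is.character(f) && !file.exists(f)) stop("input path missing: ", f)
  }
  defaults <- list(capacity = 8L, read_length = 100L, logo_exonic = NA,
                   logo_intronic = NA, keep_secondary = FALSE,
                   min_mapq = NULL, gtf = NULL, model = NULL, outdir = NULL,
                   sample_ids = NULL, log_level = "info")
  modifyList(defaults, config)
}

pipe_log <- function(level, cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

#' Run the full gap-site pipeline
#'
#' Stages run in order: extract gap-sites per sample, merge across samples,
#' score (gqs and, when a model is given, wgis/strand/gql), annotate
#' (when a GTF is given), and compute IDIN statistics. A stage failure
#' aborts with the failing stage named. When `outdir` is set, the gap-site
#' TSV, IDIN pair TSV, logo matrices, a BED6 export and a JSON summary are
#' written there.
#'
#' @param config named list (see [read_run_config()] for keys): `bam`
#'   (vector of SAM/BAM paths), `genome`, optional `gtf`, optional `model`
#'   (a `splice_score_model` object, or a path: a directory is loaded as
#'   maxent tables), `outdir`, `capacity`, `read_length`, `keep_secondary`,
#'   `min_mapq`, `sample_ids`.
#' @return list with `sites` (the merged, scored, annotated table) and
#'   `summary` (counts per gql, percent gqs/wgis-validated, GT-AG upper
#'   bound, annotation rate).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sample_ids <- if (!is.null(cfg$sample_ids)) cfg$sample_ids
                else basename(unlist(cfg$bam))
  pipe_log("info", cfg, "extracting gap-sites from ", length(cfg$bam),
           " file(s)")
  tabs <- stage("extract", mapply(function(f, sid) {
    extract_gap_sites(f, sample_id = sid, capacity = cfg$capacity,
                      keep_secondary = isTRUE(cfg$keep_secondary),
                      min_mapq = cfg$min_mapq)
  }, unlist(cfg$bam), sample_ids, SIMPLIFY = FALSE))
  sites <- stage("merge", if (length(tabs) == 1L) tabs[[1]] else
    merge_gap_sites(tabs, capacity = cfg$capacity))

  genome <- stage("score", load_genome(cfg$genome))
  model <- cfg$model
  if (is.character(model)) {
    model <- stage("score", load_maxent_tables(model))
    model <- splice_score_model(model, model)
  }
  if (!is.null(model)) {
    sites <- stage("score",
                   score_gap_sites(sites, genome, model,
                                   capacity = cfg$capacity))
  } else if (nrow(sites)) {
    sites[, gqs := gqs(nlstart, qsm, n = cfg$capacity)]
    sites[, gqs_validated := is_gqs_validated(gqs)]
  }

  if (!is.null(cfg$gtf)) {
    pairs <- stage("annotate", build_exon_pairs(cfg$gtf))
    sites <- stage("annotate",
                   annotate_gap_sites(sites, pairs,
                                      read_length = cfg$read_length))
  }

  sites <- stage("idin", site_idin(genome, sites))
  summary <- list(n_sites = nrow(sites))
  if (nrow(sites)) {
    summary$pct_gqs_validated <-
      if ("gqs" %in% names(sites)) 100 * mean(sites$gqs_validated) else NA
    if ("wgis" %in% names(sites)) {
      summary$pct_wgis_validated <- 100 * mean(sites$wgis_validated)
      summary$gql_counts <- as.list(table(factor(sites$gql, levels = 0:3)))
    }
    raw <- idin_pair_table(sites$left_idin, sites$right_idin)
    summary$gtag_upper_bound <-
      if (nrow(raw)) gtag_upper_bound(raw) else NA
    if ("sod" %in% names(sites)) {
      summary$pct_annotated <- 100 * mean(!is.na(sites$sod))
      summary$pct_exact_annotated <-
        100 * mean(!is.na(sites$sod) & sites$sod == 0)
    }
  } else {
    summary$pct_gqs_validated <- NA
    summary$gtag_upper_bound <- NA
  }

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    write_gap_sites(sites, file.path(cfg$outdir, "gap_sites.tsv"))
    if (nrow(sites)) {
      raw <- idin_pair_table(sites$left_idin, sites$right_idin)
      fwrite(raw, file.path(cfg$outdir, "idin_pairs.tsv"), sep = "\t")
      if ("strand" %in% names(sites) && any(!is.na(sites$strand))) {
        corr <- strand_correct_idin(sites$left_idin, sites$right_idin,
                                    sites$strand)
        fwrite(idin_pair_table(corr$idin5, corr$idin3),
               file.path(cfg$outdir, "idin_pairs_stranded.tsv"), sep = "\t")
        for (side in c("donor", "acceptor")) {
          wins <- junction_logo_windows(genome, sites, side = side)
          if (length(wins)) {
            fwrite(logo_matrix(wins),
                   file.path(cfg$outdir, paste0("logo_", side, ".tsv")),
                   sep = "\t")
          }
        }
      }
      write_gap_sites_bed(sites, file.path(cfg$outdir, "gap_sites.bed"))
    }
    jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  pipe_log("info", cfg, "done: ", nrow(sites), " gap-site(s)")
  list(sites = sites, summary = summary)
}
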