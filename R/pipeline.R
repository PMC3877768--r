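#' Run the full small-RNA quantification pipeline
#'
#' Orchestrates trim -> collapse -> seed-and-growth match -> count ->
#' condition comparison over a set of libraries (in-memory read data.frames
#' or FASTQ paths). Duplicate raw sequences are trimmed once and the result
#' mapped back, which leaves the per-read results identical.
#'
#' @param libraries Named list (by sample_id) of read data.frames (columns
#'   \code{read_id}, \code{sequence}) or of FASTQ paths.
#' @param refs Reference set data.frame (see [reference_set()]).
#' @param sample_conditions Named character vector sample_id -> condition.
#' @param control,treated Condition labels to compare (skipped when either
#'   is \code{NULL}).
#' @param adapter,min_overlap,max_mismatch_rate,min_insert_length Trimming
#'   settings (see [trim_adapter_3p()]).
#' @param k Seed length.
#' @param mode Match mode for quantification (default \code{"best"}).
#' @param add_reverse_complements Also index each reference's reverse
#'   complement (anti-sense matching).
#' @param use_cpm Compare counts-per-million instead of raw counts.
#' @param output_dir If non-NULL, write trimmed FASTQs, per-sample match
#'   TSVs, the count table and the comparison report there, each TSV with a
#'   provenance header (package version, configuration hash, seed).
#' @param seed Seed recorded in provenance headers (the pipeline itself is
#'   deterministic).
#' @return A \code{seedgrow_pipeline} object: list with \code{count_table},
#'   \code{comparison}, \code{matches} (per sample), \code{trim_stats},
#'   \code{provenance}.
#' @export
run_pipeline <- function(libraries, refs, sample_conditions,
                         control = NULL, treated = NULL,
                         adapter = "TGGAATTCTCGGGTGCCAAGG",
                         min_overlap = 6L, max_mismatch_rate = 0.1,
                         min_insert_length = 16L, k = 16L,
                         mode = c("best", "all"),
                         add_reverse_complements = FALSE, use_cpm = FALSE,
                         output_dir = NULL, seed = NA_integer_) {
  mode <- match.arg(mode)
  stopifnot(k >= 8L)
  if (is.null(names(libraries)))
    stop("libraries must be named by sample_id", call. = FALSE)
  missing_cond <- setdiff(names(libraries), names(sample_conditions))
  if (length(missing_cond))
    stop("samples without condition label: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  if (is.character(libraries[[1L]])) {
    absent <- !file.exists(unlist(libraries))
    if (any(absent))
      stop("missing input FASTQ: ", unlist(libraries)[absent][1L],
           call. = FALSE)
  }
  index <- build_index(refs, k = k,
                       add_reverse_complements = add_reverse_complements)
  tab <- count_table(names(index$sequences),
                     sample_conditions[names(libraries)])
  prov <- .provenance(list(adapter = adapter, min_overlap = min_overlap,
                           max_mismatch_rate = max_mismatch_rate,
                           min_insert_length = min_insert_length, k = k,
                           mode = mode, rc = add_reverse_complements,
                           cpm = use_cpm, refs = refs$sequence), seed)
  if (!is.null(output_dir))
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  matches <- list()
  trim_stats <- list()
  for (sid in names(libraries)) {
    reads <- libraries[[sid]]
    if (is.character(reads)) reads <- read_fastq(reads)
    uniq <- unique(reads$sequence)
    tr_u <- trim_adapter_3p(uniq, adapter = adapter,
                            min_overlap = min_overlap,
                            max_mismatch_rate = max_mismatch_rate,
                            min_insert_length = min_insert_length)
    ix <- match(reads$sequence, uniq)
    tr <- tr_u[ix, , drop = FALSE]
    trim_stats[[sid]] <- data.frame(
      sample_id = sid, total_reads = nrow(reads),
      adapter_found = sum(tr$adapter_found), kept = sum(tr$kept),
      stringsAsFactors = FALSE)
    kept_seq <- tr$sequence[tr$kept]
    collapsed <- collapse_reads(kept_seq)
    rec <- match_library(collapsed, index, mode = mode)
    matches[[sid]] <- rec
    tab <- count_matches(tab, rec, sid)
    if (!is.null(output_dir)) {
      keep <- reads[tr$kept, , drop = FALSE]
      keep$sequence <- tr$sequence[tr$kept]
      keep$quality <- substr(keep$quality, 1L, nchar(keep$sequence))
      write_fastq(keep, file.path(output_dir,
                                  paste0(sid, ".trimmed.fastq")))
      write_matches_tsv(rec, file.path(output_dir,
                                       paste0(sid, ".matches.tsv")),
                        header = prov)
    }
  }
  comparison <- NULL
  if (!is.null(control) && !is.null(treated))
    comparison <- compare_all(tab, control, treated, use_cpm = use_cpm)
  if (!is.null(output_dir)) {
    write_count_tsv(tab, file.path(output_dir, "counts.tsv"), header = prov)
    if (!is.null(comparison)) {
      con <- file(file.path(output_dir, "comparison.tsv"), "w")
      writeLines(prov, con)
      utils::write.table(comparison, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
    }
  }
  structure(list(count_table = tab, comparison = comparison,
                 matches = matches,
                 trim_stats = do.call(rbind, c(trim_stats,
                                               list(make.row.names = FALSE))),
                 provenance = prov),
            class = "seedgrow_pipeline")
}

#' @export
print.seedgrow_pipeline <- function(x, ...) {
  cat("seedgrow pipeline run\n")
  print(x$trim_stats)
  cat("\ncounts:\n")
  print(x$count_table$counts)
  if (!is.null(x$comparison)) {
    cat("\ncomparison:\n")
    print(x$comparison)
  }
  invisible(x)
}

# '#'-prefixed provenance header: package version, config hash, seed
.provenance <- function(config, seed) {
  tf <- tempfile()
  writeLines(paste(deparse(config), collapse = ""), tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  sprintf("# seedgrow %s config=%s seed=%s",
          as.character(utils::packageVersion("seedgrow")), h,
          ifelse(is.na(seed), "NA", as.character(seed)))
}
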