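#' Configure a synthetic small-RNA-seq experiment
#'
#' Defines a two-(or more-)condition experiment with known ground truth:
#' reads are reference-derived inserts with 5'/3' end-shift heterogeneity
#' (isomiRs) and uniform substitution errors, followed by the 3' sequencing
#' adapter. Positive end shifts are templated extensions drawn from a short
#' fixed precursor-like flanking context attached to each reference at
#' configuration time (sampled once from \code{rng_seed}); negative shifts
#' trim reference bases. Everything downstream of the configuration is a
#' pure function of (\code{rng_seed}, condition, replicate).
#'
#' @param references Reference set data.frame (see [reference_set()]).
#' @param abundance Numeric matrix of true abundance fractions, rows matching
#'   \code{references$ref_id}, one column per condition; each column sums
#'   to 1.
#' @param reads_per_library Reads simulated per replicate library.
#' @param replicates_per_condition Replicate libraries per condition.
#' @param end_shift_probs Named probability vector over end-shift offsets
#'   \code{-2..2}, applied independently at the 5' and 3' end (negative =
#'   trimmed bases, positive = templated extra bases).
#' @param substitution_error_rate Per-base substitution probability on the
#'   insert (the adapter is written error-free).
#' @param adapter 3' adapter appended to every insert.
#' @param rng_seed Integer master seed.
#' @return A \code{sim_config} object.
#' @export
simulation_config <- function(references, abundance,
                              reads_per_library = 50000L,
                              replicates_per_condition = 3L,
                              end_shift_probs = c("-2" = 0.05, "-1" = 0.10,
                                                  "0" = 0.70, "1" = 0.10,
                                                  "2" = 0.05),
                              substitution_error_rate = 0.005,
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              rng_seed = 1L) {
  abundance <- as.matrix(abundance)
  if (nrow(abundance) != nrow(references))
    stop("abundance must have one row per reference", call. = FALSE)
  if (is.null(rownames(abundance))) rownames(abundance) <- references$ref_id
  if (is.null(colnames(abundance)))
    stop("abundance columns must be named by condition", call. = FALSE)
  bad <- abs(colSums(abundance) - 1) > 1e-9
  if (any(bad))
    stop("abundance fractions must sum to 1 per condition: ",
         paste(colnames(abundance)[bad], collapse = ", "), call. = FALSE)
  if (any(abundance < 0)) stop("abundance fractions must be >= 0", call. = FALSE)
  shifts <- as.integer(names(end_shift_probs))
  stopifnot(!any(is.na(shifts)), all(end_shift_probs >= 0),
            abs(sum(end_shift_probs) - 1) < 1e-9)
  ctx <- max(0L, max(shifts))
  max_trim <- max(0L, -min(shifts))
  if (any(nchar(references$sequence) <= 2L * max_trim))
    stop("end shift longer than a reference sequence", call. = FALSE)
  adapter <- normalize_alphabet(adapter, allow_n = FALSE)
  # fixed per-reference precursor-like context for templated extensions
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(rng_seed %% 2147483647L)
  ctx5 <- vapply(seq_len(nrow(references)), function(i)
    paste(sample(c("A", "C", "G", "T"), ctx, replace = TRUE), collapse = ""),
    character(1L))
  ctx3 <- vapply(seq_len(nrow(references)), function(i)
    paste(sample(c("A", "C", "G", "T"), ctx, replace = TRUE), collapse = ""),
    character(1L))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(references = references, abundance = abundance,
                 reads_per_library = as.integer(reads_per_library),
                 replicates_per_condition = as.integer(replicates_per_condition),
                 end_shift_probs = end_shift_probs, shifts = shifts,
                 substitution_error_rate = substitution_error_rate,
                 adapter = adapter, rng_seed = as.integer(rng_seed),
                 context5 = ctx5, context3 = ctx3, context_len = ctx),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d reference(s), conditions [%s], ",
                     "%d x %d reads, error rate %g, seed %d\n"),
              nrow(x$references), paste(colnames(x$abundance), collapse = ", "),
              x$replicates_per_condition, x$reads_per_library,
              x$substitution_error_rate, x$rng_seed))
  invisible(x)
}

#' The default two-condition antagomir experiment
#'
#' The package's standing simulation scenario: mock versus anti-miR21
#' transfection over the five bundled references, three replicate libraries
#' of 50,000 reads per condition. Treated-condition truth: miR21 at 0.87x
#' its mock fraction (a 13\% reduction), miR30 at 0.5x, miR20 and miR28
#' unchanged, and the star strand miR21* absorbing the remainder (a roughly
#' ten-fold increase, mimicking the flood of antagomir-derived star-strand
#' reads).
#'
#' @param rng_seed Integer master seed.
#' @param reads_per_library Reads per replicate library.
#' @param replicates_per_condition Replicates per condition.
#' @param ... Further arguments passed to [simulation_config()].
#' @return A \code{sim_config}.
#' @export
default_simulation_config <- function(rng_seed = 1L,
                                      reads_per_library = 50000L,
                                      replicates_per_condition = 3L, ...) {
  refs <- bundled_references()
  mock <- c(miR21 = 0.40, miR21star = 0.02, miR30 = 0.28, miR20 = 0.18,
            miR28 = 0.12)
  treated <- c(miR21 = 0.40 * 0.87, miR21star = 0, miR30 = 0.28 * 0.5,
               miR20 = 0.18, miR28 = 0.12)
  treated["miR21star"] <- 1 - sum(treated)
  ab <- cbind(mock = mock[refs$ref_id], antimir21 = treated[refs$ref_id])
  rownames(ab) <- refs$ref_id
  simulation_config(refs, ab, reads_per_library = reads_per_library,
                    replicates_per_condition = replicates_per_condition,
                    rng_seed = rng_seed, ...)
}

# deterministic per-library seed below 2^31
.library_seed <- function(config, condition, replicate_index) {
  ci <- match(condition, colnames(config$abundance))
  if (is.na(ci)) stop("unknown condition: ", condition, call. = FALSE)
  (config$rng_seed %% 100000L) * 20011L + ci * 5003L +
    replicate_index * 211L
}

#' Simulate one replicate library
#'
#' Draws \code{reads_per_library} reads from the condition's true abundance
#' fractions, applies independent 5'/3' end shifts and per-base substitution
#' errors to the insert, and appends the error-free 3' adapter. Truth counts
#' are recorded at the draw, before shifts or errors. The output is a pure
#' function of (\code{rng_seed}, condition, replicate_index).
#'
#' @param config A \code{sim_config}.
#' @param condition Condition label (a column of the abundance matrix).
#' @param replicate_index Replicate number (1-based).
#' @return List with \code{reads} (data.frame: read_id, sequence, quality)
#'   and \code{truth} (data.frame: ref_id, true_count).
#' @export
simulate_library <- function(config, condition, replicate_index) {
  stopifnot(inherits(config, "sim_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(.library_seed(config, condition, replicate_index))
  n <- config$reads_per_library
  refs <- config$references
  prob <- config$abundance[refs$ref_id, condition]
  ref_idx <- sample.int(nrow(refs), n, replace = TRUE, prob = prob)
  truth <- data.frame(ref_id = refs$ref_id,
                      true_count = tabulate(ref_idx, nbins = nrow(refs)),
                      stringsAsFactors = FALSE)
  cx <- config$context_len
  ext <- paste0(config$context5, refs$sequence, config$context3)
  ns <- length(config$shifts)
  d5 <- config$shifts[sample.int(ns, n, replace = TRUE,
                                 prob = config$end_shift_probs)]
  d3 <- config$shifts[sample.int(ns, n, replace = TRUE,
                                 prob = config$end_shift_probs)]
  L <- nchar(refs$sequence)[ref_idx]
  insert <- substr(ext[ref_idx], cx + 1L - d5, cx + L + d3)
  # per-base substitution errors on the insert only
  e <- config$substitution_error_rate
  if (e > 0) {
    nerr <- stats::rbinom(n, nchar(insert), e)
    for (i in which(nerr > 0L)) {
      ch <- strsplit(insert[i], "", fixed = TRUE)[[1L]]
      pos <- sample.int(length(ch), min(nerr[i], length(ch)))
      for (p in pos)
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      insert[i] <- paste(ch, collapse = "")
    }
  }
  seqs <- paste0(insert, config$adapter)
  list(reads = data.frame(
         read_id = sprintf("%s_rep%d_read%06d", condition, replicate_index,
                           seq_len(n)),
         sequence = seqs, quality = strrep("I", nchar(seqs)),
         stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate the full multi-replicate experiment
#'
#' Runs [simulate_library()] for every condition and replicate; sample
#' identifiers are \code{"{condition}_{replicate}"}.
#'
#' @param config A \code{sim_config}.
#' @return List with \code{libraries} (named list of read data.frames),
#'   \code{truth} (data.frame: ref_id, sample_id, true_count) and
#'   \code{sample_conditions} (named character vector).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  conds <- colnames(config$abundance)
  libraries <- list()
  truth <- list()
  sample_conditions <- character(0)
  for (cond in conds) {
    for (r in seq_len(config$replicates_per_condition)) {
      sid <- sprintf("%s_%d", cond, r)
      lib <- simulate_library(config, cond, r)
      libraries[[sid]] <- lib$reads
      tr <- lib$truth
      tr$sample_id <- sid
      truth[[sid]] <- tr
      sample_conditions[sid] <- cond
    }
  }
  list(libraries = libraries,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       sample_conditions = sample_conditions)
}

#' Write a simulated experiment to disk
#'
#' One FASTQ per library plus a ground-truth TSV.
#'
#' @param experiment Result of [simulate_experiment()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_experiment <- function(experiment, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(experiment$libraries), function(sid)
    write_fastq(experiment$libraries[[sid]],
                file.path(outdir, paste0(sid, ".fastq"))), character(1L))
  tp <- file.path(outdir, "truth.tsv")
  utils::write.table(experiment$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, tp))
}
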