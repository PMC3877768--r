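#' Enumerate the k-mer seeds of a reference small RNA
#'
#' Every contiguous k-mer of the reference is a seed: a reference of length
#' L yields exactly L - k + 1 seeds (bases 1..k, 2..k+1, and so on). With the
#' default k = 16, a 23-nt small RNA yields 8 seeds.
#'
#' @param sequence Reference sequence (normalized alphabet, no N).
#' @param k Seed length in bases (default 16).
#' @param ref_id Identifier used in error messages.
#' @return data.frame with columns \code{offset} (0-based start of the seed
#'   in the reference, ascending) and \code{kmer}.
#' @export
enumerate_seeds <- function(sequence, k = 16L, ref_id = "reference") {
  stopifnot(k >= 1L)
  L <- nchar(sequence)
  if (L < k)
    stop(sprintf("reference '%s' is shorter (%d nt) than the seed length %d",
                 ref_id, L, k), call. = FALSE)
  offs <- 0:(L - k)
  data.frame(offset = offs,
             kmer = substring(sequence, offs + 1L, offs + k),
             stringsAsFactors = FALSE)
}

#' Build a seed index over a set of reference small RNAs
#'
#' Indexes every k-mer of every reference (and, optionally, of each
#' reference's reverse complement, so reads are matched against both the
#' sense and anti-sense strand). Duplicate k-mers across references map to
#' multi-entry lists.
#'
#' @param refs data.frame from [reference_set()] with columns \code{ref_id},
#'   \code{sequence}.
#' @param k Seed length (default 16).
#' @param add_reverse_complements If \code{TRUE}, each reference also
#'   contributes its reverse complement under \code{ref_id} + \code{"|rc"}.
#' @return A \code{seed_index} object: list with \code{k}, the k-mer hash
#'   \code{env} (k-mer -> matrix of ref index/offset pairs), and the indexed
#'   \code{sequences} (named character vector, including any reverse
#'   complements).
#' @export
build_index <- function(refs, k = 16L, add_reverse_complements = FALSE) {
  if (anyDuplicated(refs$ref_id))
    stop("duplicate ref_id in reference set: ",
         refs$ref_id[duplicated(refs$ref_id)][1L], call. = FALSE)
  seqs <- stats::setNames(refs$sequence, refs$ref_id)
  if (add_reverse_complements) {
    rc <- stats::setNames(reverse_complement(refs$sequence),
                          paste0(refs$ref_id, "|rc"))
    seqs <- c(seqs, rc)
  }
  env <- new.env(parent = emptyenv(), size = 4L * sum(nchar(seqs)))
  for (ri in seq_along(seqs)) {
    sd <- enumerate_seeds(seqs[[ri]], k, ref_id = names(seqs)[ri])
    for (j in seq_len(nrow(sd))) {
      key <- sd$kmer[j]
      env[[key]] <- rbind(env[[key]], c(ri, sd$offset[j]))
    }
  }
  structure(list(k = as.integer(k), env = env, sequences = seqs,
                 ref_chars = lapply(seqs, function(s)
                   strsplit(s, "", fixed = TRUE)[[1L]])),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("seed_index: %d sequence(s), k = %d, %d distinct %d-mers\n",
              length(x$sequences), x$k, length(ls(x$env)), x$k))
  invisible(x)
}

empty_match_df <- function() {
  data.frame(sequence = character(0), ref_id = character(0),
             ref_start = integer(0), ref_end = integer(0),
             flank5 = character(0), flank3 = character(0),
             matched_length = integer(0), stringsAsFactors = FALSE)
}

#' Match one read against an indexed reference set by seed-and-growth
#'
#' Every k-mer of the read shared with an indexed reference anchors a
#' candidate match, which is then grown one base at a time at the 5' end and
#' then at the 3' end, for as long as read and reference agree and neither is
#' exhausted (a perfect, gapless match; N never matches). Bases of the read
#' left outside the grown region are reported as the non-matching 5' and 3'
#' flanks. Anchors growing to the same reference span are deduplicated;
#' distinct maximal spans (e.g. on internal repeats) are all reported.
#'
#' @param sequence One read sequence (normalized alphabet).
#' @param index A \code{seed_index} from [build_index()].
#' @return data.frame of match records, sorted by descending matched length,
#'   then \code{ref_id}, then \code{ref_start} (1-based inclusive reference
#'   coordinates); zero rows when no seed anchors exist. Every row satisfies
#'   \code{sequence == flank5 + reference span + flank3}.
#' @export
match_read <- function(sequence, index) {
  k <- index$k
  L <- nchar(sequence)
  if (L < k) return(empty_match_df())
  rchars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  kmers <- substring(sequence, 1:(L - k + 1L), k:L)
  hits <- mget(unique(kmers), envir = index$env, ifnotfound = list(NULL))
  if (all(vapply(hits, is.null, logical(1L)))) return(empty_match_df())
  seen <- character(0)
  out <- list()
  for (i in seq_along(kmers)) {
    anchors <- hits[[kmers[i]]]
    if (is.null(anchors)) next
    for (a in seq_len(nrow(anchors))) {
      ri <- anchors[a, 1L]; off <- anchors[a, 2L]
      tchars <- index$ref_chars[[ri]]
      # anchor: read[i .. i+k-1] == ref[off+1 .. off+k] (1-based)
      s_r <- i; s_t <- off + 1L
      while (s_r > 1L && s_t > 1L &&
             rchars[s_r - 1L] == tchars[s_t - 1L] &&
             rchars[s_r - 1L] != "N") { s_r <- s_r - 1L; s_t <- s_t - 1L }
      e_r <- i + k - 1L; e_t <- off + k
      Lt <- length(tchars)
      while (e_r < L && e_t < Lt &&
             rchars[e_r + 1L] == tchars[e_t + 1L] &&
             rchars[e_r + 1L] != "N") { e_r <- e_r + 1L; e_t <- e_t + 1L }
      key <- paste(ri, s_t, e_t, sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- data.frame(
        sequence = sequence,
        ref_id = names(index$sequences)[ri],
        ref_start = s_t, ref_end = e_t,
        flank5 = substr(sequence, 1L, s_r - 1L),
        flank3 = substr(sequence, e_r + 1L, L),
        matched_length = e_t - s_t + 1L,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$matched_length, res$ref_id, res$ref_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Match a collapsed read library against the reference index
#'
#' Runs [match_read()] on every distinct sequence and carries its occurrence
#' count onto the resulting records. Mode \code{"best"} keeps only the top
#' record per sequence (longest match; ties broken by \code{ref_id} then
#' \code{ref_start}) so a read is counted at most once; mode \code{"all"}
#' keeps every record.
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param index \code{seed_index} from [build_index()].
#' @param mode \code{"best"} (default, used for quantification) or
#'   \code{"all"}.
#' @return data.frame of match records with an \code{occurrences} column.
#' @export
match_library <- function(collapsed, index, mode = c("best", "all")) {
  mode <- match.arg(mode)
  res <- lapply(seq_len(nrow(collapsed)), function(i) {
    m <- match_read(collapsed$sequence[i], index)
    if (nrow(m) == 0L) return(NULL)
    if (mode == "best") m <- m[1L, , drop = FALSE]
    m$occurrences <- collapsed$occurrences[i]
    m
  })
  res <- res[!vapply(res, is.null, logical(1L))]
  if (length(res) == 0L) {
    out <- empty_match_df(); out$occurrences <- integer(0); return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export a gapless stacked alignment of matches on one reference
#'
#' Renders match records as a padded text stack: the first row is the
#' reference, each record one row with its matched bases (uppercase) directly
#' under reference positions \code{ref_start..ref_end}, non-matching flanks
#' in lowercase, and '.' padding; all rows have equal length. This is a
#' deterministic, gap-free pileup of the isomiR end heterogeneity around one
#' small RNA.
#'
#' @param records Match records for a single \code{ref_id}.
#' @param ref_sequence The reference sequence.
#' @param ref_id Reference identifier (first row name).
#' @return Named character vector of alignment rows (reference first).
#' @export
export_stack <- function(records, ref_sequence, ref_id = "reference") {
  L <- nchar(ref_sequence)
  if (nrow(records) == 0L)
    return(stats::setNames(ref_sequence, ref_id))
  span <- substring(ref_sequence, records$ref_start, records$ref_end)
  bad <- records$sequence != paste0(records$flank5, span, records$flank3)
  if (any(bad))
    stop("integrity error: record ", which(bad)[1L],
         " does not decompose as flank5 + reference span + flank3",
         call. = FALSE)
  pad5 <- max(0L, max(nchar(records$flank5) - (records$ref_start - 1L)))
  pad3 <- max(0L, max(nchar(records$flank3) - (L - records$ref_end)))
  rows <- paste0(
    strrep(".", pad5 + records$ref_start - 1L - nchar(records$flank5)),
    tolower(records$flank5), span, tolower(records$flank3),
    strrep(".", pad3 + L - records$ref_end - nchar(records$flank3)))
  ids <- if (!is.null(records$occurrences))
    sprintf("read_%d_x%d", seq_len(nrow(records)), records$occurrences)
  else sprintf("read_%d", seq_len(nrow(records)))
  stats::setNames(c(paste0(strrep(".", pad5), ref_sequence, strrep(".", pad3)),
                    rows),
                  c(ref_id, ids))
}

#' Write a stacked alignment as padded FASTA
#' @param stack Named character vector from [export_stack()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_stack_fasta <- function(stack, path) {
  writeLines(paste0(">", names(stack), "\n", stack), path)
  invisible(path)
}

#' Write match records to TSV
#' @param records Match records data.frame.
#' @param path Output path.
#' @param header Optional character vector of '#'-prefixed comment lines.
#' @return Invisibly, \code{path}.
#' @export
write_matches_tsv <- function(records, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
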