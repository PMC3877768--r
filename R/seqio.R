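#' Normalize a nucleotide sequence to the DNA alphabet
#'
#' Uppercases the sequence and converts RNA U to DNA T, so that RNA
#' references (mature miRNAs, antagomirs) and DNA sequencing reads live in
#' one alphabet. Characters outside \{A, C, G, T, N\} are rejected.
#'
#' @param seq Character vector of sequences.
#' @param allow_n Logical; if \code{FALSE}, N is also rejected (used for
#'   reference sequences, which must be fully determined).
#' @return Character vector of normalized sequences over \{A,C,G,T\} (plus N
#'   when \code{allow_n}).
#' @examples
#' normalize_alphabet("ACGGCAACACCAGUCGAUGGGCUGU")
#' @export
normalize_alphabet <- function(seq, allow_n = TRUE) {
  if (length(seq) == 0L) return(character(0))
  if (any(!nzchar(seq)) || any(is.na(seq)))
    stop("sequence must be non-empty", call. = FALSE)
  out <- chartr("u", "t", toupper(seq))
  out <- chartr("U", "T", out)
  pattern <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- regexpr(pattern, out)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid alphabet: character '%s' at position %d in sequence %d",
                 substr(out[i], bad[i], bad[i]), bad[i], i), call. = FALSE)
  }
  out
}

#' Read a 4-line FASTQ file
#'
#' Strict 4-line-per-record FASTQ reader. Sequences are normalized with
#' [normalize_alphabet()]; qualities are kept verbatim (Phred+33 accepted,
#' unused downstream). A file ending mid-record raises a parse error naming
#' the 0-based index of the offending record.
#'
#' @param path Path to a FASTQ file (plain text or gzipped).
#' @return A data.frame with columns \code{read_id}, \code{sequence},
#'   \code{quality}, one row per read, in file order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("truncated FASTQ: file ends mid-record at record %d (0-based)",
                 n %/% 4L), call. = FALSE)
  if (n == 0L)
    return(data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  hdr <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(qual))
  if (length(bad))
    stop(sprintf("malformed FASTQ record at record %d (0-based)", bad[1L] - 1L),
         call. = FALSE)
  data.frame(read_id = sub("^@", "", sub("[ \t].*$", "", hdr)),
             sequence = normalize_alphabet(seqs),
             quality = qual,
             stringsAsFactors = FALSE)
}

#' Write reads to a 4-line FASTQ file
#'
#' @param reads data.frame with columns \code{read_id}, \code{sequence} and
#'   optionally \code{quality} (constant maximum quality is written when
#'   absent).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads) && !all(is.na(reads$quality)))
    reads$quality else strrep("I", nchar(reads$sequence))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste(paste0("@", reads$read_id), reads$sequence, "+", qual,
                     sep = "\n"), con)
  invisible(path)
}

#' Read reference small RNAs from FASTA
#'
#' Reads a FASTA file of reference small RNAs (mature miRNA, star strand,
#' antagomir, pri-miRNA hairpin) via Biostrings and normalizes the alphabet
#' (RNA U becomes T). The role of each reference is taken from a
#' \code{role=} tag in the FASTA description when present, else from the
#' \code{role} argument.
#'
#' @param path FASTA path.
#' @param role Default role for references without a \code{role=} tag; one of
#'   \code{"mature"}, \code{"star"}, \code{"antagomir"}, \code{"pri_hairpin"}.
#' @return data.frame with columns \code{ref_id}, \code{sequence},
#'   \code{role}.
#' @export
read_reference_fasta <- function(path, role = "mature") {
  role <- match.arg(role, c("mature", "star", "antagomir", "pri_hairpin"))
  ss <- Biostrings::readBStringSet(path)
  hdr <- names(ss)
  ids <- sub("[ \t].*$", "", hdr)
  roles <- rep(role, length(ss))
  tagged <- regmatches(hdr, regexpr("role=[A-Za-z_]+", hdr))
  has_tag <- grepl("role=", hdr)
  roles[has_tag] <- sub("^role=", "", tagged)
  reference_set(ids, as.character(ss), roles)
}

#' Construct a validated set of reference small RNAs
#'
#' @param ref_id Character vector of unique identifiers.
#' @param sequence Sequences (RNA or DNA; normalized to DNA, no N allowed).
#' @param role Role per reference: \code{mature}, \code{star},
#'   \code{antagomir} or \code{pri_hairpin}.
#' @return data.frame with columns \code{ref_id}, \code{sequence},
#'   \code{role}.
#' @export
reference_set <- function(ref_id, sequence,
                          role = rep("mature", length(ref_id))) {
  stopifnot(length(ref_id) == length(sequence))
  if (anyDuplicated(ref_id))
    stop("duplicate ref_id: ", ref_id[duplicated(ref_id)][1L], call. = FALSE)
  ok <- c("mature", "star", "antagomir", "pri_hairpin")
  if (!all(role %in% ok))
    stop("role must be one of: ", paste(ok, collapse = ", "), call. = FALSE)
  data.frame(ref_id = as.character(ref_id),
             sequence = normalize_alphabet(sequence, allow_n = FALSE),
             role = rep_len(as.character(role), length(ref_id)),
             stringsAsFactors = FALSE)
}

#' Trim the 3' sequencing adapter from reads
#'
#' Finds the leftmost position p in each read where a prefix of the adapter
#' of length l = min(adapter length, read length - p), with l >=
#' \code{min_overlap}, aligns with at most floor(l * \code{max_mismatch_rate})
#' mismatches; the read is truncated to the bases before p. Reads without an
#' adapter hit are returned unchanged. N in a read never matches an adapter
#' base. Degenerate reads are flagged \code{kept = FALSE}, never an error.
#'
#' @param sequence Character vector of read sequences (normalized alphabet).
#' @param adapter 3' adapter sequence (default: Illumina TruSeq small-RNA 3'
#'   adapter).
#' @param min_overlap Minimum adapter prefix length to call a hit.
#' @param max_mismatch_rate Fraction of mismatches tolerated in the aligned
#'   adapter prefix (in [0, 0.5)).
#' @param min_insert_length Inserts shorter than this are flagged
#'   \code{kept = FALSE}; the default 16 is the seed length, below which no
#'   read can match.
#' @return data.frame with columns \code{sequence} (the trimmed insert),
#'   \code{adapter_found}, \code{trimmed_length}, \code{kept}.
#' @export
trim_adapter_3p <- function(sequence,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            min_overlap = 6L, max_mismatch_rate = 0.1,
                            min_insert_length = 16L) {
  adapter <- normalize_alphabet(adapter, allow_n = FALSE)
  alen <- nchar(adapter)
  stopifnot(alen >= min_overlap, min_overlap >= 1L,
            max_mismatch_rate >= 0, max_mismatch_rate < 0.5)
  n <- length(sequence)
  cut <- rep(NA_integer_, n)          # 0-based cut position p
  # fast path: leftmost exact full-adapter occurrence
  hit <- regexpr(adapter, sequence, fixed = TRUE)
  cut[hit > 0L] <- hit[hit > 0L] - 1L
  need_scan <- which(is.na(cut) | max_mismatch_rate > 0)
  achars <- strsplit(adapter, "", fixed = TRUE)[[1L]]
  for (i in need_scan) {
    L <- nchar(sequence[i])
    upper <- if (is.na(cut[i])) L - min_overlap else cut[i] - 1L
    if (upper < 0L) next
    rchars <- strsplit(sequence[i], "", fixed = TRUE)[[1L]]
    for (p in 0L:upper) {
      l <- min(alen, L - p)
      if (l < min_overlap) break
      mm <- sum(rchars[(p + 1L):(p + l)] != achars[seq_len(l)])
      if (mm <= floor(l * max_mismatch_rate)) { cut[i] <- p; break }
    }
  }
  found <- !is.na(cut)
  insert <- sequence
  insert[found] <- substr(sequence[found], 1L, cut[found])
  data.frame(sequence = insert,
             adapter_found = found,
             trimmed_length = ifelse(found, nchar(sequence) - cut, 0L),
             kept = nchar(insert) >= min_insert_length,
             stringsAsFactors = FALSE)
}

#' Collapse identical reads to (sequence, occurrences) pairs
#'
#' Deduplicates a trimmed read library. Entries are ordered by descending
#' occurrence count, ties broken lexicographically by sequence, so the most
#' abundant species (typically the unshifted mature miRNA) comes first.
#'
#' @param sequence Character vector of trimmed read sequences.
#' @return data.frame with columns \code{sequence}, \code{occurrences};
#'   occurrences sum to \code{length(sequence)}.
#' @export
collapse_reads <- function(sequence) {
  if (length(sequence) == 0L)
    return(data.frame(sequence = character(0), occurrences = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(sequence)
  out <- data.frame(sequence = names(tab),
                    occurrences = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$occurrences, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write collapsed reads to TSV
#' @param collapsed data.frame from [collapse_reads()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_collapsed_tsv <- function(collapsed, path) {
  utils::write.table(collapsed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read collapsed reads from TSV
#' @param path TSV with columns \code{sequence}, \code{count} or
#'   \code{occurrences}.
#' @return data.frame with columns \code{sequence}, \code{occurrences}.
#' @export
read_collapsed_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if ("count" %in% names(df) && !"occurrences" %in% names(df))
    names(df)[names(df) == "count"] <- "occurrences"
  data.frame(sequence = normalize_alphabet(df$sequence),
             occurrences = as.integer(df$occurrences),
             stringsAsFactors = FALSE)
}
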