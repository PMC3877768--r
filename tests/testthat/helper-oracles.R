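# Independent brute-force oracles and small fixture builders. These stay
# index-free / loop-based on purpose: they re-derive expected results by
# exhaustive enumeration rather than by the package's own code paths.

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# exhaustive diagonal-walk matcher: every (read pos, ref pos) alignment is
# examined, maximal equal runs >= k become records; duplicates of one
# reference span keep the smallest read start.
oracle_match_read <- function(sequence, ref_seqs, k = 16L) {
  rch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(rch)
  recs <- list()
  for (rid in names(ref_seqs)) {
    tch <- strsplit(ref_seqs[[rid]], "", fixed = TRUE)[[1L]]
    Lt <- length(tch)
    for (d in (-(L - 1L)):(Lt - 1L)) {   # d = ref position - read position
      i0 <- max(1L, 1L - d)
      i1 <- min(L, Lt - d)
      if (i1 - i0 + 1L < k) next
      run <- NA_integer_
      for (i in i0:(i1 + 1L)) {
        eq <- i <= i1 && rch[i] == tch[i + d] && rch[i] != "N"
        if (eq && is.na(run)) run <- i
        if (!eq && !is.na(run)) {
          len <- i - run
          if (len >= k)
            recs[[length(recs) + 1L]] <- data.frame(
              sequence = sequence, ref_id = rid,
              ref_start = run + d, ref_end = i - 1L + d,
              flank5 = substr(sequence, 1L, run - 1L),
              flank3 = substr(sequence, i, L),
              matched_length = len, read_start = run,
              stringsAsFactors = FALSE)
          run <- NA_integer_
        }
      }
    }
  }
  if (length(recs) == 0L) {
    out <- data.frame(sequence = character(0), ref_id = character(0),
                      ref_start = integer(0), ref_end = integer(0),
                      flank5 = character(0), flank3 = character(0),
                      matched_length = integer(0), stringsAsFactors = FALSE)
    return(out)
  }
  df <- do.call(rbind, recs)
  df <- df[order(df$read_start), , drop = FALSE]
  key <- paste(df$ref_id, df$ref_start, df$ref_end)
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(-df$matched_length, df$ref_id, df$ref_start), , drop = FALSE]
  df$read_start <- NULL
  rownames(df) <- NULL
  df
}

# position-by-position window recount, with explicit pairing rules
oracle_scan_best <- function(query, target, mode = "complement",
                             wobble_weight = 0.5) {
  q <- strsplit(query, "", fixed = TRUE)[[1L]]
  t <- strsplit(target, "", fixed = TRUE)[[1L]]
  n <- length(q)
  best <- -Inf
  for (s in 1:(length(t) - n + 1L)) {
    sc <- 0
    for (j in 1:n) {
      tb <- t[s + j - 1L]
      qb <- if (mode == "complement") q[n + 1L - j] else q[j]
      if (mode == "identity") {
        if (tb == qb && tb != "N") sc <- sc + 1
      } else {
        wc <- (tb == "A" && qb == "T") || (tb == "T" && qb == "A") ||
          (tb == "G" && qb == "C") || (tb == "C" && qb == "G")
        wob <- (tb == "G" && qb == "T") || (tb == "T" && qb == "G")
        if (wc) sc <- sc + 1
        else if (wob) sc <- sc + wobble_weight
      }
    }
    best <- max(best, sc)
  }
  best
}

# hand-rolled pooled-variance two-sample t (the textbook formula)
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# independent reverse complement (chartr-based, no Biostrings)
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# mutate one or more positions of a sequence to different bases
mutate_seq <- function(s, positions) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (p in positions)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# a tiny two-reference set used across tests
tiny_refs <- function() {
  reference_set(c("refA", "refB"),
                c("TAGCTTATCAGACTGATGTTGA",    # 22 nt
                  "TGTAAACATCCTCGACTGGAAG"),   # 22 nt
                c("mature", "mature"))
}
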