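#' Reverse complement
#'
#' Watson-Crick reverse complement over the normalized DNA alphabet
#' (N maps to N), via Biostrings.
#'
#' @param seq Character vector of sequences (normalized alphabet).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Watson-Crick pairing lookup: complement of each base (N pairs with nothing)
.wc <- c(A = "T", C = "G", G = "C", T = "A", N = "")

#' Scan an antagomir against a pri-miRNA for the best ungapped hybrid
#'
#' Slides the full-length query as a window over the target and scores every
#' offset position by position, without gaps. In \code{complement} mode the
#' duplex is antiparallel: target base j of the window pairs with query base
#' (window length + 1 - j), scoring Watson-Crick pairs as matches and,
#' optionally, G:U (here G:T) wobble pairs at a fractional credit. In
#' \code{identity} mode the window is scored by plain sequence equality
#' (homology rather than hybridization). The top-ranked hit's span is the
#' hybrid (or homology) area.
#'
#' @param query Query sequence (e.g. the antagomir), used full length.
#' @param target Target sequence (e.g. a pri-miRNA hairpin), at least as
#'   long as the query.
#' @param mode \code{"complement"} (default) or \code{"identity"}.
#' @param allow_wobble Credit G:T wobble pairs (complement mode only).
#' @param wobble_weight Credit per wobble pair, in [0, 1].
#' @param query_id,target_id Identifiers carried into the report.
#' @return data.frame of hits, one per window offset, sorted by descending
#'   \code{score} then ascending \code{target_start}: columns
#'   \code{query_id}, \code{target_id}, \code{target_start},
#'   \code{target_end} (1-based inclusive), \code{mode},
#'   \code{matched_bases}, \code{wobble_bases}, \code{score},
#'   \code{window_length}.
#' @export
complementarity_scan <- function(query, target,
                                 mode = c("complement", "identity"),
                                 allow_wobble = TRUE, wobble_weight = 0.5,
                                 query_id = "query", target_id = "target") {
  mode <- match.arg(mode)
  stopifnot(wobble_weight >= 0, wobble_weight <= 1)
  query <- normalize_alphabet(query)
  target <- normalize_alphabet(target)
  qlen <- nchar(query); tlen <- nchar(target)
  if (qlen > tlen)
    stop(sprintf("query (%d nt) is longer than target (%d nt)", qlen, tlen),
         call. = FALSE)
  qchars <- strsplit(query, "", fixed = TRUE)[[1L]]
  tchars <- strsplit(target, "", fixed = TRUE)[[1L]]
  # in complement mode, window position j pairs with query position L+1-j
  qeff <- if (mode == "complement") rev(qchars) else qchars
  qpair <- unname(.wc[qeff])            # base a target position must show
  starts <- 1:(tlen - qlen + 1L)
  matched <- integer(length(starts))
  wobble <- integer(length(starts))
  for (i in seq_along(starts)) {
    w <- tchars[starts[i]:(starts[i] + qlen - 1L)]
    if (mode == "identity") {
      matched[i] <- sum(w == qeff & w != "N")
    } else {
      matched[i] <- sum(w == qpair & nzchar(qpair))
      if (allow_wobble)
        wobble[i] <- sum((w == "G" & qeff == "T") | (w == "T" & qeff == "G"))
    }
  }
  score <- matched + if (mode == "complement" && allow_wobble)
    wobble_weight * wobble else 0
  out <- data.frame(query_id = query_id, target_id = target_id,
                    target_start = starts, target_end = starts + qlen - 1L,
                    mode = mode, matched_bases = matched,
                    wobble_bases = if (mode == "complement" && allow_wobble)
                      wobble else 0L,
                    score = score, window_length = qlen,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$target_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
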