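#' Construct a table of qPCR Ct measurements
#'
#' @param sample_id Sample identifiers.
#' @param condition Condition label per row (e.g. "mock", "antimir21").
#' @param gene Gene / miRNA assayed per row.
#' @param ct Threshold cycle; must lie in (0, 40), the run length.
#' @param is_reference_gene Logical; \code{TRUE} for the internal-standard
#'   rows (e.g. 18s rRNA) used to normalize target expression.
#' @return data.frame of validated Ct measurements.
#' @export
ct_table <- function(sample_id, condition, gene, ct,
                     is_reference_gene = gene == "18s") {
  ct <- as.numeric(ct)
  if (any(!is.finite(ct)) || any(ct <= 0) || any(ct >= 40))
    stop("Ct values must lie in (0, 40) cycles", call. = FALSE)
  data.frame(sample_id = as.character(sample_id),
             condition = as.character(condition),
             gene = as.character(gene),
             is_reference_gene = as.logical(is_reference_gene),
             ct = ct, stringsAsFactors = FALSE)
}

#' Read a Ct table from TSV
#' @param path TSV with columns sample_id, condition, gene,
#'   is_reference_gene, ct.
#' @return data.frame as from [ct_table()].
#' @export
read_ct_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  ct_table(df$sample_id, df$condition, df$gene, df$ct,
           as.logical(df$is_reference_gene))
}

#' Delta-Ct of a target gene within one condition
#'
#' mean(target Ct) - mean(reference-gene Ct), with replicate Ct values
#' averaged within the condition before subtraction.
#'
#' @param measurements Ct table (see [ct_table()]).
#' @param condition Condition to evaluate.
#' @param gene Target gene.
#' @return Numeric delta-Ct in cycles.
#' @export
delta_ct <- function(measurements, condition, gene) {
  m <- measurements[measurements$condition == condition, , drop = FALSE]
  tgt <- m$ct[m$gene == gene & !m$is_reference_gene]
  ref <- m$ct[m$is_reference_gene]
  if (length(tgt) == 0L)
    stop("no measurements of gene '", gene, "' in condition '", condition,
         "'", call. = FALSE)
  if (length(ref) == 0L)
    stop("normalization error: no reference-gene (internal standard) ",
         "measurements in condition '", condition, "'", call. = FALSE)
  mean(tgt) - mean(ref)
}

#' Relative quantity by the Livak 2^-ddCt method
#'
#' ddCt = dCt(treated) - dCt(control); the relative quantity is
#' RQ = 2^-ddCt, and percent change is (RQ - 1) x 100. One cycle of extra
#' delay in the treated condition therefore halves the relative quantity.
#'
#' @param delta_ct_treated,delta_ct_control Delta-Ct values (cycles).
#' @param gene Optional gene label carried into the result.
#' @return One-row data.frame: \code{gene}, \code{delta_ct_treated},
#'   \code{delta_ct_control}, \code{delta_delta_ct}, \code{rq},
#'   \code{percent_change}.
#' @export
relative_quantity <- function(delta_ct_treated, delta_ct_control,
                              gene = NA_character_) {
  stopifnot(is.finite(delta_ct_treated), is.finite(delta_ct_control))
  ddct <- delta_ct_treated - delta_ct_control
  rq <- 2^(-ddct)
  data.frame(gene = gene, delta_ct_treated = delta_ct_treated,
             delta_ct_control = delta_ct_control, delta_delta_ct = ddct,
             rq = rq, percent_change = (rq - 1) * 100,
             stringsAsFactors = FALSE)
}

#' Full ddCt analysis of a Ct table
#'
#' For every non-reference gene, computes the within-condition delta-Ct
#' against the internal standard, the ddCt of treated versus control, and
#' RQ = 2^-ddCt.
#'
#' @param measurements Ct table (see [ct_table()]).
#' @param control,treated Condition labels.
#' @return data.frame with one [relative_quantity()] row per target gene.
#' @export
ddct_analysis <- function(measurements, control, treated) {
  genes <- unique(measurements$gene[!measurements$is_reference_gene])
  if (length(genes) == 0L) stop("no target genes in Ct table", call. = FALSE)
  out <- do.call(rbind, lapply(genes, function(g)
    relative_quantity(delta_ct(measurements, treated, g),
                      delta_ct(measurements, control, g), gene = g)))
  rownames(out) <- NULL
  out
}
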