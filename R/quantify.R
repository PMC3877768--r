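#' Construct an empty count table
#'
#' A \code{count_table} holds matched-read counts as a reference x sample
#' matrix together with the condition label of each sample (e.g. "mock" vs
#' "anti-miR21").
#'
#' @param ref_ids Reference identifiers (rows).
#' @param sample_conditions Named character vector: sample_id -> condition.
#' @return A \code{count_table} object.
#' @export
count_table <- function(ref_ids, sample_conditions) {
  if (is.null(names(sample_conditions)) || any(!nzchar(names(sample_conditions))))
    stop("sample_conditions must be a named vector (sample_id -> condition)",
         call. = FALSE)
  counts <- matrix(0, nrow = length(ref_ids), ncol = length(sample_conditions),
                   dimnames = list(ref_ids, names(sample_conditions)))
  structure(list(counts = counts, conditions = sample_conditions),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d reference(s) x %d sample(s)\n",
              nrow(x$counts), ncol(x$counts)))
  cat("conditions:", paste(sprintf("%s=%s", names(x$conditions), x$conditions),
                           collapse = ", "), "\n")
  print(x$counts)
  invisible(x)
}

#' @export
summary.count_table <- function(object, ...) {
  tot <- colSums(object$counts)
  data.frame(sample_id = colnames(object$counts),
             condition = unname(object$conditions[colnames(object$counts)]),
             total_count = unname(tot), row.names = NULL)
}

#' Add one sample's match records to a count table
#'
#' Each reference's count for the sample is the sum of \code{occurrences}
#' over its match records (records should come from \code{mode = "best"} so
#' each collapsed sequence is counted once); unmatched reads contribute
#' nothing.
#'
#' @param table A \code{count_table}.
#' @param records Match records from [match_library()].
#' @param sample_id Sample to fill; must have a condition label in the table.
#' @return The updated \code{count_table}.
#' @export
count_matches <- function(table, records, sample_id) {
  stopifnot(inherits(table, "count_table"))
  if (!sample_id %in% names(table$conditions))
    stop("sample '", sample_id, "' has no condition label", call. = FALSE)
  if (nrow(records)) {
    agg <- tapply(records$occurrences, records$ref_id, sum)
    new_refs <- setdiff(names(agg), rownames(table$counts))
    if (length(new_refs)) {
      add <- matrix(0, nrow = length(new_refs), ncol = ncol(table$counts),
                    dimnames = list(new_refs, colnames(table$counts)))
      table$counts <- rbind(table$counts, add)
    }
    table$counts[names(agg), sample_id] <- as.numeric(agg)
  }
  table
}

#' Counts-per-million normalization
#'
#' Scales each sample's counts to sum to one million, removing library-size
#' differences. Left opt-in for condition comparisons, whose default follows
#' raw total counts.
#'
#' @param table A \code{count_table}.
#' @return A \code{count_table} whose columns each sum to 1e6.
#' @export
cpm_normalize <- function(table) {
  stopifnot(inherits(table, "count_table"))
  tot <- colSums(table$counts)
  if (any(tot <= 0))
    stop("degenerate library with zero total matched count: ",
         paste(colnames(table$counts)[tot <= 0], collapse = ", "),
         call. = FALSE)
  table$counts <- sweep(table$counts, 2L, tot, "/") * 1e6
  table
}

#' Two-tailed unpaired Student's t-test
#'
#' Equal-variance pooled t-test with df = n_a + n_b - 2, via
#' \code{stats::t.test(var.equal = TRUE)}. Zero-pooled-variance inputs (which
#' make the t statistic undefined) are resolved explicitly: equal means give
#' t = 0, p = 1; unequal means give p = 0, flagged degenerate.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param var_equal If \code{FALSE}, Welch's unequal-variance test instead.
#' @return List with \code{t}, \code{p_value}, \code{df}, \code{degenerate}.
#' @export
students_t_test <- function(group_a, group_b, var_equal = TRUE) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L)
    stop("insufficient replicates: each group needs >= 2 values",
         call. = FALSE)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, p_value = 1, df = na + nb - 2L, degenerate = FALSE))
    return(list(t = Inf * sign(mean(group_a) - mean(group_b)), p_value = 0,
                df = na + nb - 2L, degenerate = TRUE))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Compare one reference between two conditions
#'
#' Computes group means, treated/control fold change, percent change
#' ((fold - 1) x 100) and, when both conditions have at least two samples, a
#' two-tailed unpaired Student's t-test p-value. The default compares raw
#' total counts; set \code{use_cpm} to compare counts-per-million.
#'
#' @param table A \code{count_table}.
#' @param ref_id Reference to compare.
#' @param control,treated Condition labels.
#' @param use_cpm Normalize to CPM before comparing.
#' @param var_equal Passed to [students_t_test()].
#' @return One-row data.frame: \code{ref_id}, \code{mean_control},
#'   \code{mean_treated}, \code{fold_change}, \code{percent_change},
#'   \code{p_value} (NA when either group has < 2 samples).
#' @export
compare_conditions <- function(table, ref_id, control, treated,
                               use_cpm = FALSE, var_equal = TRUE) {
  stopifnot(inherits(table, "count_table"))
  if (use_cpm) table <- cpm_normalize(table)
  if (!ref_id %in% rownames(table$counts))
    stop("unknown reference: ", ref_id, call. = FALSE)
  for (cond in c(control, treated))
    if (!cond %in% table$conditions)
      stop("no samples with condition '", cond, "'", call. = FALSE)
  a <- table$counts[ref_id, names(table$conditions)[table$conditions == control]]
  b <- table$counts[ref_id, names(table$conditions)[table$conditions == treated]]
  ma <- mean(a); mb <- mean(b)
  if (ma == 0)
    stop("undefined fold change: control mean is zero for ", ref_id,
         call. = FALSE)
  p <- if (length(a) >= 2L && length(b) >= 2L)
    students_t_test(b, a, var_equal = var_equal)$p_value else NA_real_
  data.frame(ref_id = ref_id, mean_control = ma, mean_treated = mb,
             fold_change = mb / ma, percent_change = (mb / ma - 1) * 100,
             p_value = p, stringsAsFactors = FALSE)
}

#' Compare every reference between two conditions
#'
#' @inheritParams compare_conditions
#' @return data.frame with one row per reference (see
#'   [compare_conditions()]), ordered as in the table.
#' @export
compare_all <- function(table, control, treated, use_cpm = FALSE,
                        var_equal = TRUE) {
  if (use_cpm) table <- cpm_normalize(table)
  rows <- lapply(rownames(table$counts), function(r)
    compare_conditions(table, r, control, treated, use_cpm = FALSE,
                       var_equal = var_equal))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a count table to TSV
#'
#' Rows are references, columns samples; a '#'-prefixed header line carries
#' the condition of each sample column.
#'
#' @param table A \code{count_table}.
#' @param path Output path.
#' @param header Optional extra '#'-prefixed comment lines.
#' @return Invisibly, \code{path}.
#' @export
write_count_tsv <- function(table, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines(paste0("# condition\t",
                    paste(table$conditions[colnames(table$counts)],
                          collapse = "\t")), con)
  df <- data.frame(ref_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_count_tsv()]
#' @param path TSV path.
#' @return A \code{count_table}.
#' @export
read_count_tsv <- function(path) {
  lines <- readLines(path)
  cond_line <- grep("^# condition\t", lines, value = TRUE)
  if (length(cond_line) != 1L)
    stop("count TSV lacks the '# condition' header line", call. = FALSE)
  conds <- strsplit(sub("^# condition\t", "", cond_line), "\t")[[1L]]
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                          header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$ref_id
  tab <- count_table(rownames(m), stats::setNames(conds, colnames(m)))
  tab$counts <- m
  tab
}
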