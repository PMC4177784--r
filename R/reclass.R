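#' Cross-tabulate risk categories before and after correction
#'
#' Builds the 3x3 reclassification table: rows are the category before
#' correction, columns the category after, aligned per patient.
#'
#' @param before,after equal-length vectors of categories (factors or
#'   strings with values `low`, `intermediate`, `high`).
#' @return object of class `reclass_table`: `counts` (3x3 integer matrix)
#'   and `n_total`.
#' @examples
#' build_reclass_table(c("high", "low"), c("low", "low"))
#' @export
build_reclass_table <- function(before, after) {
  if (length(before) != length(after))
    stop("'before' and 'after' must have equal length", call. = FALSE)
  lev <- c("low", "intermediate", "high")
  before <- factor(as.character(before), levels = lev)
  after <- factor(as.character(after), levels = lev)
  if (any(is.na(before)) || any(is.na(after)))
    stop("categories must be one of: ", paste(lev, collapse = ", "),
         call. = FALSE)
  counts <- table(before = before, after = after)
  structure(list(counts = unclass(counts), n_total = length(before)),
            class = "reclass_table")
}

#' Reclassification table from known cell counts
#'
#' Convenience constructor when the 3x3 flow is known directly (e.g. from
#' a published table) rather than from per-patient category pairs.
#'
#' @param counts 3x3 matrix, rows = before, columns = after, in the order
#'   low, intermediate, high.
#' @return object of class `reclass_table`.
#' @export
reclass_table_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be a 3x3 matrix of non-negative integers",
         call. = FALSE)
  lev <- c("low", "intermediate", "high")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(before = lev, after = lev)
  structure(list(counts = counts, n_total = sum(counts)),
            class = "reclass_table")
}

#' Summarize a reclassification table
#'
#' Per category: the before and after counts with their percent of the
#' cohort, and the net change with its percent of the *before* count.
#' Overall: the number and percent of patients whose category changed
#' (off-diagonal total). Percentages are whole percents rounded half away
#' from zero.
#'
#' @param table a [build_reclass_table()] result.
#' @return list of class `reclass_summary`: `by_category` (data.frame) and
#'   `reclassified_n`, `reclassified_pct`, `n_total`.
#' @export
summarize_reclass <- function(table) {
  stopifnot(inherits(table, "reclass_table"))
  if (table$n_total == 0) stop("empty reclassification table", call. = FALSE)
  cnt <- table$counts
  n <- table$n_total
  before_n <- rowSums(cnt)
  after_n <- colSums(cnt)
  net <- after_n - before_n
  by_cat <- data.frame(
    category = factor(rownames(cnt), levels = rownames(cnt)),
    before_n = as.integer(before_n),
    before_pct = round_half_away(100 * before_n / n),
    after_n = as.integer(after_n),
    after_pct = round_half_away(100 * after_n / n),
    net_change = as.integer(net),
    net_change_pct = ifelse(before_n > 0,
                            round_half_away(100 * abs(net) / before_n), NA),
    row.names = NULL, stringsAsFactors = FALSE
  )
  moved <- n - sum(diag(cnt))
  structure(list(by_category = by_cat,
                 reclassified_n = as.integer(moved),
                 reclassified_pct = round_half_away(100 * moved / n),
                 n_total = n),
            class = "reclass_summary")
}

#' @export
print.reclass_summary <- function(x, ...) {
  cat("CV risk reclassification\n")
  b <- x$by_category
  lab <- c(low = "Low (<10%)", intermediate = "Intermediate (10-20%)",
           high = "High (>20%)")
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %-22s before %4d (%2.0f%%)  after %4d (%2.0f%%)  net %+4d (%.0f%%)\n",
                lab[[as.character(b$category[i])]],
                b$before_n[i], b$before_pct[i],
                b$after_n[i], b$after_pct[i],
                b$net_change[i], b$net_change_pct[i]))
  }
  cat(sprintf("  Total %d patients; %d (%.0f%%) reclassified\n",
              x$n_total, x$reclassified_n, x$reclassified_pct))
  invisible(x)
}

#' @export
print.reclass_table <- function(x, ...) {
  cat(sprintf("Reclassification table (n = %d)\n", x$n_total))
  print(x$counts)
  invisible(x)
}

#' Write a reclassification summary as CSV
#'
#' Emits the 3-row per-category summary (category, before n and %, after n
#' and %, net change n and %) followed by a total row, mirroring the usual
#' published layout.
#'
#' @param summary a [summarize_reclass()] result.
#' @param path output CSV path.
#' @param header_lines optional comment lines (prefixed `#`) written above
#'   the header, e.g. a run manifest reference.
#' @return `path`, invisibly.
#' @export
write_reclass_csv <- function(summary, path, header_lines = character()) {
  stopifnot(inherits(summary, "reclass_summary"))
  b <- summary$by_category
  out <- rbind(
    data.frame(category = as.character(b$category), before_n = b$before_n,
               before_pct = b$before_pct, after_n = b$after_n,
               after_pct = b$after_pct, net_change = b$net_change,
               net_change_pct = b$net_change_pct),
    data.frame(category = "total", before_n = summary$n_total,
               before_pct = 100, after_n = summary$n_total, after_pct = 100,
               net_change = summary$reclassified_n,
               net_change_pct = summary$reclassified_pct)
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}
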