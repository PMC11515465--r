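#' Read a confusion matrix from delimited text
#'
#' Accepts either a single line `tp,fp,fn,tn` or a 2x2 comma-delimited block
#' (row 1: tp, fp; row 2: fn, tn). Blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return A [confusion_matrix()].
#' @export
read_confusion_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parse_line <- function(ln, where) {
    vals <- suppressWarnings(as.numeric(strsplit(ln, ",")[[1]]))
    if (anyNA(vals))
      stop("line ", where, ": cannot parse '", ln,
           "' as comma-separated numbers", call. = FALSE)
    vals
  }
  if (length(lines) == 1L) {
    v <- parse_line(lines, 1L)
    if (length(v) != 4L)
      stop("line 1: expected 4 values tp,fp,fn,tn, got ", length(v),
           call. = FALSE)
    return(confusion_matrix(v[1], v[2], v[3], v[4]))
  }
  if (length(lines) == 2L) {
    r1 <- parse_line(lines[1], 1L)
    r2 <- parse_line(lines[2], 2L)
    if (length(r1) != 2L || length(r2) != 2L)
      stop("2x2 block must have two values per line", call. = FALSE)
    return(confusion_matrix(r1[1], r1[2], r2[1], r2[2]))
  }
  stop("expected one line (tp,fp,fn,tn) or a 2x2 block, got ",
       length(lines), " lines", call. = FALSE)
}

#' Write a flat metric report
#'
#' Two-column comma-delimited text, fixed order (`metric`, `value`), full
#' precision.
#'
#' @param values Named numeric vector of metric values.
#' @param path Output path (or `""` for stdout).
#' @export
write_metric_report <- function(values, path = "") {
  df <- data.frame(metric = names(values), value = unname(values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a score set from delimited text
#'
#' Comma-separated with a mandatory header containing at least `truth` and
#' `score` columns (an `id` column, if present, is ignored).
#'
#' @param path File path.
#' @return A [score_set()].
#' @export
read_score_set <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8", comment.char = "#")
  miss <- setdiff(c("truth", "score"), names(df))
  if (length(miss))
    stop("score-set file must have columns truth, score (missing: ",
         paste(miss, collapse = ", "), ")", call. = FALSE)
  score_set(df$score, df$truth)
}

#' Write an ROC curve as (fpr, tpr) rows
#'
#' @param curve A `roc_curve`.
#' @param path Output path (or `""` for stdout).
#' @export
write_roc_curve <- function(curve, path = "") {
  stopifnot(inherits(curve, "roc_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(curve)
}

#' Read / write an MRMC ratings table
#'
#' Comma-separated with a mandatory header (`modality`, `reader`, `case`,
#' `truth`, `rating`).
#'
#' @param path File path.
#' @param positive_cut,strict Positivity rule, see [mrmc_table()].
#' @return `read_mrmc_table()`: an [mrmc_table()].
#' @export
read_mrmc_table <- function(path, positive_cut = 4, strict = FALSE) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8", comment.char = "#")
  mrmc_table(df, positive_cut = positive_cut, strict = strict)
}

#' @rdname read_mrmc_table
#' @param t An [mrmc_table()] to write.
#' @export
write_mrmc_table <- function(t, path) {
  stopifnot(inherits(t, "mrmc_table"))
  utils::write.csv(as.data.frame(t), path, row.names = FALSE, quote = FALSE)
  invisible(t)
}

#' Write bootstrap results as delimited text
#'
#' One row per result with columns (`modality_or_contrast`, `metric`,
#' `estimate`, `ci_lower`, `ci_upper`, `level`, `B`, `seed`, `mode`).
#'
#' @param results Named list of `bootstrap_result` objects; names become the
#'   `modality_or_contrast` column.
#' @param path Output path, `""` for stdout, or `NULL` to only return the
#'   assembled data frame.
#' @export
write_bootstrap_results <- function(results, path = "") {
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    data.frame(modality_or_contrast = nm, metric = x$metric,
               estimate = x$estimate, ci_lower = x$ci_lower,
               ci_upper = x$ci_upper, level = x$level, B = x$B,
               seed = if (is.null(x$seed)) NA_integer_ else x$seed,
               mode = x$mode)
  })
  df <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write a benchmark grid as delimited text
#'
#' Columns (`metric`, `auroc`, `prevalence`, `value`, `bias`, `replicates`,
#' `seed`).
#'
#' @param grid A [benchmark_grid()].
#' @param path Output path (or `""` for stdout).
#' @export
write_benchmark_grid <- function(grid, path = "") {
  stopifnot(inherits(grid, "benchmark_grid"))
  df <- as.data.frame(grid)
  df$replicates <- attr(grid, "replicates")
  df$seed <- attr(grid, "seed")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a benchmark grid written by [write_benchmark_grid()]
#'
#' @param path File path.
#' @return A [benchmark_grid()].
#' @export
read_benchmark_grid <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8", comment.char = "#")
  need <- c("metric", "auroc", "prevalence", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("benchmark file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  reps <- if ("replicates" %in% names(df)) df$replicates[1] else NA_integer_
  seed <- if ("seed" %in% names(df)) df$seed[1] else NA_integer_
  if (!"bias" %in% names(df)) df$bias <- NA_real_
  structure(df[c("metric", "auroc", "prevalence", "value", "bias")],
            class = c("benchmark_grid", "data.frame"),
            replicates = reps, seed = seed, n = NA_integer_)
}
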