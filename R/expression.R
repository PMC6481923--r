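#' Time-course expression matrix with replicates
#'
#' Container for a genes x samples matrix of log2-scale expression values
#' taken at an ordered series of time points with one or more replicates
#' each. This is the primary input to [compute_contrasts()] and [twm()].
#'
#' @param values Numeric matrix, genes in rows (unique rownames required),
#'   one column per (time point, replicate) sample.
#' @param sample_time Numeric vector, one entry per column: the time (e.g.
#'   hours) at which that sample was taken.
#' @param sample_rep Optional integer vector of replicate indices per
#'   column; defaults to 1, 2, ... within each time point in column order.
#' @param condition Optional character vector of per-column condition
#'   labels (e.g. induced vs control).
#' @param check_scale If `TRUE` (default), warn when values look like raw
#'   counts (maximum above 30) rather than log2-scale expression.
#' @return An object of class `"expression_ts"`: a list with elements
#'   `values`, `gene_ids`, `time_points` (sorted unique times),
#'   `sample_time`, `sample_rep`, `condition`.
#' @details Values are expected to be already log2-normalized; upstream
#'   normalization (GC/length correction, batch removal) is out of scope.
#'   Time points must number at least 3 so at least one consecutive pair of
#'   contrasts exists. Genes whose values are missing for every sample are
#'   dropped with a message.
#' @examples
#' m <- matrix(rnorm(24, 8), 4, 6,
#'             dimnames = list(paste0("g", 1:4), NULL))
#' x <- expression_ts(m, sample_time = rep(c(0, 6, 24), each = 2))
#' x$time_points
#' @export
expression_ts <- function(values, sample_time, sample_rep = NULL,
                          condition = NULL, check_scale = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("expression matrix must have gene ids as rownames")
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  if (length(sample_time) != ncol(values))
    stop("sample_time must have one entry per column")
  storage.mode(values) <- "double"

  all_missing <- rowSums(is.finite(values)) == 0
  if (any(all_missing)) {
    message(sum(all_missing), " gene(s) with no finite values dropped")
    values <- values[!all_missing, , drop = FALSE]
  }

  tp <- sort(unique(sample_time))
  if (length(tp) < 3)
    stop("need at least 3 time points, got ", length(tp))
  if (is.null(sample_rep)) {
    sample_rep <- stats::ave(seq_along(sample_time), sample_time,
                             FUN = seq_along)
  }
  if (!is.null(condition) && length(condition) != ncol(values))
    stop("condition must have one entry per column")
  if (check_scale && max(values, na.rm = TRUE) > 30)
    warning("values exceed 30; input may be raw counts, not log2 expression")

  structure(list(values = values,
                 gene_ids = rownames(values),
                 time_points = tp,
                 sample_time = as.numeric(sample_time),
                 sample_rep = as.integer(sample_rep),
                 condition = condition),
            class = "expression_ts")
}

#' @export
print.expression_ts <- function(x, ...) {
  cat("expression_ts:", nrow(x$values), "genes,",
      length(x$time_points), "time points (",
      paste(x$time_points, collapse = ", "), "),",
      ncol(x$values), "samples\n")
  invisible(x)
}

#' @export
dim.expression_ts <- function(x) dim(x$values)

#' Read a time-course expression matrix from TSV
#'
#' Reads a genes-in-rows TSV. Sample columns are mapped to (time,
#' replicate) either from their labels, which must follow the
#' `t{time}_r{rep}` convention (e.g. `t06_r2`), or from a sample sheet.
#'
#' @param path Path to a TSV file; first column gene ids, remaining columns
#'   samples. Lines starting with `#` are ignored.
#' @param sample_sheet Optional data.frame (or TSV path) with columns
#'   `sample`, `time` and optionally `rep`, `condition`, overriding the
#'   column-label convention.
#' @inheritParams expression_ts
#' @return An [expression_ts()] object.
#' @export
read_expression <- function(path, sample_sheet = NULL, check_scale = TRUE) {
  tab <- read_tsv_plain(path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids

  if (!is.null(sample_sheet)) {
    if (is.character(sample_sheet)) sample_sheet <- read_tsv_plain(sample_sheet)
    idx <- match(colnames(m), sample_sheet$sample)
    if (anyNA(idx))
      stop("sample(s) missing from sample sheet: ",
           paste(colnames(m)[is.na(idx)], collapse = ", "))
    st <- as.numeric(sample_sheet$time[idx])
    sr <- if ("rep" %in% names(sample_sheet)) as.integer(sample_sheet$rep[idx]) else NULL
    cond <- if ("condition" %in% names(sample_sheet)) as.character(sample_sheet$condition[idx]) else NULL
  } else {
    parsed <- regmatches(colnames(m),
                         regexec("^t([0-9]+(?:\\.[0-9]+)?)_r([0-9]+)$", colnames(m)))
    bad <- lengths(parsed) != 3
    if (any(bad))
      stop("column label(s) not of the form t{time}_r{rep}: ",
           paste(colnames(m)[bad], collapse = ", "),
           " (supply a sample sheet instead)")
    st <- as.numeric(vapply(parsed, `[`, character(1), 2))
    sr <- as.integer(vapply(parsed, `[`, character(1), 3))
    cond <- NULL
  }
  expression_ts(m, sample_time = st, sample_rep = sr, condition = cond,
                check_scale = check_scale)
}

#' Write a time-course expression matrix to TSV
#'
#' Columns are labelled `t{time}_r{rep}` so the file round-trips through
#' [read_expression()].
#'
#' @param x An [expression_ts()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_ts"))
  lab <- sprintf("t%s_r%d", format(x$sample_time, trim = TRUE,
                                   scientific = FALSE), x$sample_rep)
  # 17 significant digits so values survive the round trip bit for bit
  chr <- apply(x$values, 2, formatC, digits = 17, format = "g")
  if (!is.matrix(chr)) chr <- matrix(chr, nrow = nrow(x$values))
  df <- data.frame(gene = x$gene_ids, chr, check.names = FALSE)
  colnames(df) <- c("gene", lab)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# twmatrix %s expression matrix (log2 scale)",
                     as.character(utils::packageVersion("twmatrix"))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
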