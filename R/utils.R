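#' Odds ratio of a 2x2 table with Haldane-Anscombe correction
#'
#' Computes the sample odds ratio `(a*d)/(b*c)` of a 2x2 contingency table.
#' If any cell is zero, 0.5 is added to all four cells before the ratio is
#' formed (Haldane-Anscombe correction), so the result is always finite and
#' strictly positive.
#'
#' @param a,b,c,d Non-negative cell counts: `a` = both conditions hold,
#'   `b` = first only, `c` = second only, `d` = neither.
#' @return A list with `or` (the odds ratio), `corrected` (logical, whether
#'   the continuity correction was applied) and `table` (the 2x2 matrix of
#'   raw counts).
#' @examples
#' odds_ratio_2x2(8, 2, 20, 70)$or  # 14
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("cell counts must be finite and non-negative")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(
    or = (cells[1] * cells[4]) / (cells[2] * cells[3]),
    corrected = corrected,
    table = matrix(c(a, c, b, d), 2, 2,
                   dimnames = list(in_set = c("yes", "no"),
                                   outcome = c("yes", "no")))
  )
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. Used wherever an operation takes an
# explicit seed so that library calls do not perturb user-level randomness.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Write a data.frame as TSV with a commented header recording provenance.
write_tsv_commented <- function(x, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# twmatrix %s",
                     as.character(utils::packageVersion("twmatrix"))), con)
  if (length(params))
    writeLines(paste0("# ", names(params), " = ",
                      vapply(params, function(p) paste(format(p), collapse = ","),
                             character(1))), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# read.table wrapper that skips comment lines and keeps strings as characters
read_tsv_plain <- function(path, header = TRUE, ...) {
  utils::read.table(path, header = header, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
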