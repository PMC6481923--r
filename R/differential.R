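#' Per-gene log2 fold changes between consecutive time points
#'
#' For each pair of adjacent time points the contrast is the mean log2
#' expression at the later time minus the mean at the earlier one. Because
#' values are on the log scale this is a log2 fold change, and adding a
#' constant to all values leaves every contrast unchanged.
#'
#' @param expr An [expression_ts()] object with at least 3 time points.
#' @param condition If the object carries condition labels, restrict to
#'   this condition (default: use all samples).
#' @return An object of class `"contrast_series"`: list with `logfc`
#'   (genes x contrasts matrix), `contrasts` (labels `"t0->t6"` etc.),
#'   `times` (the time points), `pairs` (labels of consecutive contrast
#'   pairs, length A-2) and `de` (`NULL` until filled by
#'   [fallback_de_test()] or [set_de()]).
#' @details Genes with no finite value at one of the two time points of a
#'   contrast get `NA` for that contrast and are excluded from downstream
#'   scoring there rather than imputed.
#' @examples
#' m <- cbind(a1 = c(2, 1), a2 = c(2, 1), b1 = c(3, 1), b2 = c(3, 1),
#'            c1 = c(3.5, 1), c2 = c(3.5, 1))
#' rownames(m) <- c("g1", "g2")
#' cs <- compute_contrasts(expression_ts(m, rep(c(0, 6, 24), each = 2)))
#' cs$logfc["g1", ]  # 1.0 then 0.5
#' @export
compute_contrasts <- function(expr, condition = NULL) {
  stopifnot(inherits(expr, "expression_ts"))
  v <- expr$values
  st <- expr$sample_time
  if (!is.null(condition)) {
    if (is.null(expr$condition)) stop("object has no condition labels")
    keep <- expr$condition == condition
    v <- v[, keep, drop = FALSE]
    st <- st[keep]
  }
  tp <- sort(unique(st))
  if (length(tp) < 3) stop("need at least 3 time points")
  means <- vapply(tp, function(t) {
    cols <- which(st == t)
    if (!length(cols)) stop("time point ", t, " has no replicates")
    rowMeans(v[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(v)))
  if (!is.matrix(means))  # single-gene edge case: vapply simplifies
    means <- matrix(means, nrow = nrow(v),
                    dimnames = list(rownames(v), NULL))
  means[!is.finite(means)] <- NA_real_
  lf <- means[, -1, drop = FALSE] - means[, -length(tp), drop = FALSE]
  labs <- sprintf("t%s->t%s", tp[-length(tp)], tp[-1])
  colnames(lf) <- labs
  rownames(lf) <- rownames(v)
  structure(list(logfc = lf,
                 contrasts = labs,
                 times = tp,
                 pairs = if (length(labs) >= 2)
                   sprintf("(%s,%s)", labs[-length(labs)], labs[-1])
                 else character(),
                 de = NULL),
            class = "contrast_series")
}

#' Build a contrast series from a precomputed fold-change matrix
#'
#' For workflows where per-contrast log2 fold changes (and differential
#' calls) come from an upstream model fit rather than from
#' [compute_contrasts()]: wraps a genes x contrasts matrix into the
#' `"contrast_series"` container consumed by [twm()].
#'
#' @param logfc Numeric matrix, genes x consecutive contrasts (rownames =
#'   gene ids), at least 2 columns.
#' @param times Optional time points (length `ncol(logfc) + 1`); defaults
#'   to `0, 1, 2, ...`.
#' @param de Optional 0/1 indicator matrix passed to [set_de()].
#' @return A `"contrast_series"`.
#' @export
contrast_series <- function(logfc, times = NULL, de = NULL) {
  logfc <- as.matrix(logfc)
  if (is.null(rownames(logfc))) stop("logfc needs gene ids as rownames")
  if (ncol(logfc) < 2) stop("need at least 2 contrasts")
  if (is.null(times)) times <- seq_len(ncol(logfc) + 1) - 1
  if (length(times) != ncol(logfc) + 1)
    stop("times must have one more entry than there are contrasts")
  labs <- sprintf("t%s->t%s", times[-length(times)], times[-1])
  colnames(logfc) <- labs
  cs <- structure(list(logfc = logfc, contrasts = labs, times = times,
                       pairs = sprintf("(%s,%s)", labs[-length(labs)],
                                       labs[-1]),
                       de = NULL),
                  class = "contrast_series")
  if (!is.null(de)) cs <- set_de(cs, de)
  cs
}

#' @export
print.contrast_series <- function(x, ...) {
  cat("contrast_series:", nrow(x$logfc), "genes,",
      length(x$contrasts), "contrasts,",
      length(x$pairs), "contrast pairs; de",
      if (is.null(x$de)) "not set" else "set", "\n")
  invisible(x)
}

#' Attach differential-expression indicators to a contrast series
#'
#' @param contrasts A `"contrast_series"`.
#' @param de Genes x contrasts matrix of 0/1 indicators (or logical), rows
#'   and columns matching `contrasts$logfc`. A genes-only vector/matrix is
#'   recycled across contrasts.
#' @return The contrast series with `de` filled.
#' @export
set_de <- function(contrasts, de) {
  stopifnot(inherits(contrasts, "contrast_series"))
  lf <- contrasts$logfc
  if (is.vector(de) || (is.matrix(de) && ncol(de) == 1))
    de <- matrix(as.numeric(de), nrow(lf), ncol(lf),
                 dimnames = dimnames(lf))
  de <- as.matrix(de)
  storage.mode(de) <- "double"
  if (!all(de %in% c(0, 1))) stop("de indicators must be 0/1")
  if (!is.null(rownames(de))) de <- de[rownames(lf), , drop = FALSE]
  if (!identical(dim(de), dim(lf)))
    stop("de matrix dimensions do not match the contrast series")
  dimnames(de) <- dimnames(lf)
  contrasts$de <- de
  contrasts
}

#' Per-contrast Welch t-test differential expression
#'
#' A plain per-contrast two-sample test for when no upstream model fit
#' (moderated linear model, time-course regression) is available: for each
#' gene and each consecutive contrast, a Welch t-test between the replicate
#' values of the two time points, Benjamini-Hochberg corrected across genes
#' within each contrast.
#'
#' @param expr An [expression_ts()] with at least 2 replicates per time
#'   point.
#' @param alpha Adjusted-p cutoff for the 0/1 indicator (default 0.05).
#' @param condition Optional condition restriction as in
#'   [compute_contrasts()].
#' @return A `"contrast_series"` with `logfc`, `de`, and additionally `p`
#'   and `adj_p` matrices.
#' @details Degenerate variance cases: if both groups have zero variance
#'   the p-value is 1 when the means agree and 0 when they differ.
#' @export
fallback_de_test <- function(expr, alpha = 0.05, condition = NULL) {
  stopifnot(inherits(expr, "expression_ts"))
  cs <- compute_contrasts(expr, condition = condition)
  v <- expr$values
  st <- expr$sample_time
  if (!is.null(condition)) {
    keep <- expr$condition == condition
    v <- v[, keep, drop = FALSE]
    st <- st[keep]
  }
  tp <- cs$times
  grp <- lapply(tp, function(t) which(st == t))
  if (any(lengths(grp) < 2))
    stop("fallback test needs >= 2 replicates per time point; ",
         "supply external differential statistics instead")

  stat_one <- function(cols) {
    x <- v[, cols, drop = FALSE]
    n <- rowSums(is.finite(x))
    m <- rowMeans(x, na.rm = TRUE)
    s2 <- apply(x, 1, stats::var, na.rm = TRUE)
    list(n = n, m = m, s2 = s2)
  }
  stats_tp <- lapply(grp, stat_one)

  nc <- length(tp) - 1
  p <- matrix(NA_real_, nrow(v), nc, dimnames = dimnames(cs$logfc))
  for (j in seq_len(nc)) {
    a <- stats_tp[[j]]; b <- stats_tp[[j + 1]]
    se2 <- a$s2 / a$n + b$s2 / b$n
    diff <- b$m - a$m
    tt <- diff / sqrt(se2)
    df <- se2^2 / ((a$s2 / a$n)^2 / (a$n - 1) + (b$s2 / b$n)^2 / (b$n - 1))
    pj <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    zero <- is.finite(diff) & se2 == 0
    pj[zero] <- ifelse(diff[zero] == 0, 1, 0)
    p[, j] <- pj
  }
  adj <- matrix(apply(p, 2, stats::p.adjust, method = "BH"),
                nrow = nrow(p), dimnames = dimnames(p))
  de <- (adj < alpha) * 1
  de[is.na(de)] <- 0
  cs$p <- p
  cs$adj_p <- adj
  cs$de <- de
  cs
}

#' Consensus differential-expression call over supplied model statistics
#'
#' Combines the false-discovery rate of a moderated linear-model F test
#' with the R-squared of a polynomial time-course regression into a single
#' boolean call. A gene is differentially expressed iff any of:
#' (a) `fdr < 0.001`, (b) `r2 > 0.90`, or (c) `fdr < 0.01` and `r2 > 0.60`.
#'
#' @param fdr Numeric vector in \[0,1\].
#' @param r2 Numeric vector in \[0,1\], or `NA` where the time-course model
#'   was not fit; missing values fail the r2 clauses.
#' @return Logical vector of consensus calls.
#' @examples
#' consensus_de(c(5e-4, 5e-3, 5e-3), c(0.10, 0.65, 0.50))
#' # TRUE TRUE FALSE
#' @export
consensus_de <- function(fdr, r2 = rep(NA_real_, length(fdr))) {
  if (length(fdr) != length(r2)) stop("fdr and r2 must have equal length")
  if (any(fdr < 0 | fdr > 1, na.rm = TRUE)) stop("fdr out of [0,1]")
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) stop("r2 out of [0,1]")
  r2ok_hi <- !is.na(r2) & r2 > 0.90
  r2ok_lo <- !is.na(r2) & r2 > 0.60
  (fdr < 0.001) | r2ok_hi | (fdr < 0.01 & r2ok_lo)
}

#' Label the temporal trend of a per-contrast fold-change vector
#'
#' Signs of the consecutive-contrast fold changes (zeros dropped) are run-
#' length encoded: no sign change and positive gives `"up"`, negative
#' `"down"`; exactly one change gives `"up-down"` or `"down-up"`; more than
#' one gives `"complex"`; all-zero gives `"flat"`.
#'
#' @param logfc Numeric vector of consecutive-contrast log2 fold changes.
#' @param epsilon Dead zone: |logfc| below this counts as zero.
#' @return A single trend label.
#' @export
trend_label <- function(logfc, epsilon = 0) {
  s <- sign(logfc)
  s[abs(logfc) < epsilon] <- 0
  s <- s[s != 0 & !is.na(s)]
  if (!length(s)) return("flat")
  r <- rle(s)$values
  if (length(r) == 1) return(if (r > 0) "up" else "down")
  if (length(r) == 2) return(if (r[1] > 0) "up-down" else "down-up")
  "complex"
}

#' Select candidate driver TFs from a contrast series
#'
#' A TF qualifies as a candidate regulator of the transition if (i) its
#' absolute log2 fold change exceeds `logfc_threshold` in any consecutive
#' contrast, or (ii) it is differentially expressed in a supplied in-vivo
#' reference contrast (`adj_p < invivo_alpha`), or (iii) its trend over the
#' time course is nonmonotonic (`up-down`, `down-up` or `complex`) —
#' nonmonotonic factors may matter even when start and end expression
#' agree.
#'
#' @param contrasts A `"contrast_series"`.
#' @param tf_list Character vector of TF gene ids (must be rows of the
#'   expression/contrast table).
#' @param logfc_threshold Absolute per-contrast log2 fold-change cutoff
#'   (default 1.5).
#' @param in_vivo Optional data.frame with columns `gene`, `logfc`, `adj_p`
#'   from an external (in vivo) differential contrast.
#' @param invivo_alpha Adjusted-p cutoff for the in-vivo rescue (default
#'   0.01).
#' @param epsilon Dead zone passed to [trend_label()].
#' @return data.frame with one row per TF: `tf`, `max_abs_logfc`, `trend`,
#'   `invivo_de`, `candidate`, `criteria` (comma-separated rules met).
#' @export
select_candidate_tfs <- function(contrasts, tf_list, logfc_threshold = 1.5,
                                 in_vivo = NULL, invivo_alpha = 0.01,
                                 epsilon = 0) {
  stopifnot(inherits(contrasts, "contrast_series"))
  missing_tf <- setdiff(tf_list, rownames(contrasts$logfc))
  if (length(missing_tf))
    stop("TF(s) absent from the contrast table: ",
         paste(missing_tf, collapse = ", "))
  lf <- contrasts$logfc[tf_list, , drop = FALSE]
  mx <- apply(abs(lf), 1, max, na.rm = TRUE)
  tr <- apply(lf, 1, trend_label, epsilon = epsilon)
  iv <- rep(FALSE, length(tf_list))
  if (!is.null(in_vivo)) {
    idx <- match(tf_list, in_vivo$gene)
    iv <- !is.na(idx) & in_vivo$adj_p[idx] < invivo_alpha
  }
  big <- mx > logfc_threshold
  nonmono <- tr %in% c("up-down", "down-up", "complex")
  crit <- mapply(function(b, v, n)
    paste(c(if (b) "logfc", if (v) "in_vivo", if (n) "nonmonotonic"),
          collapse = ","),
    big, iv, nonmono)
  data.frame(tf = tf_list, max_abs_logfc = unname(mx), trend = unname(tr),
             invivo_de = iv, candidate = big | iv | nonmono,
             criteria = unname(crit), stringsAsFactors = FALSE)
}
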