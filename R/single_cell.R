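#' Tertile grouping of a gene's single-cell expression
#'
#' Cells with zero expression are excluded; the remaining cells are split
#' at empirical quantiles (by default 0.33/0.66 into low/mid/high). Cut
#' points use type-7 quantiles and assignment is right-closed (a value
#' exactly at a cut goes to the lower group), so ties are resolved
#' deterministically.
#'
#' @param values Numeric vector of one gene's expression across cells
#'   (non-negative).
#' @param cuts Quantile cut points in (0,1); default `c(1, 2)/3`. For the
#'   6-level variant use `(1:5)/6`.
#' @param labels Group labels; default low/mid/high for 2 cuts, `"q1"`...
#'   otherwise.
#' @param min_cells Minimum number of positive cells required (default 9).
#' @return A factor with one entry per cell; `NA` for excluded (zero or
#'   missing) cells.
#' @examples
#' table(quantile_group(1:9))
#' @export
quantile_group <- function(values, cuts = c(1, 2) / 3, labels = NULL,
                           min_cells = 9) {
  if (any(values < 0, na.rm = TRUE)) stop("expression must be non-negative")
  pos <- !is.na(values) & values > 0
  if (sum(pos) < min_cells)
    stop("only ", sum(pos), " cells with positive expression (need >= ",
         min_cells, ")")
  q <- stats::quantile(values[pos], probs = cuts, type = 7, names = FALSE)
  if (is.null(labels)) {
    labels <- if (length(cuts) == 2) c("low", "mid", "high")
              else paste0("q", seq_len(length(cuts) + 1))
  }
  g <- cut(values, breaks = c(-Inf, q, Inf), labels = labels, right = TRUE)
  g[!pos] <- NA
  g
}

#' Association between a TF's and a gene's single-cell levels
#'
#' Contingency-table test of independence between the TF grouping and the
#' gene's own tertile grouping. The gene is filtered (> 0) and tertiled
#' independently of the TF; only cells present in both groupings enter the
#' table. The p-value is a Fisher exact test (Freeman-Halton for larger
#' than 2x2); when the exact computation would be too large the p-value is
#' simulated with a fixed seed.
#'
#' @param tf_groups Factor of per-cell TF groups from [quantile_group()]
#'   (possibly pooled via [pooled_variants()]); `NA` = cell excluded.
#' @param gene_values Numeric per-cell expression of the gene.
#' @param alpha Significance level for the `significant` flag (default
#'   0.01).
#' @param exact_max Largest table total for which the exact network
#'   algorithm is attempted (default 60); above it Monte-Carlo simulation
#'   is used.
#' @param B Monte-Carlo replicates (default 1e5).
#' @param seed Seed for the simulated p-value (default 1; isolated from
#'   the caller's RNG).
#' @param min_cells Passed to [quantile_group()] for the gene.
#' @return List with `p_value`, `table`, `method` (`"exact"`,
#'   `"simulated"` or `"degenerate"`), `significant`.
#' @details A degenerate table (an empty row or column margin after
#'   filtering) returns `p_value = 1` with a warning.
#' @export
gene_association <- function(tf_groups, gene_values, alpha = 0.01,
                             exact_max = 60, B = 1e5, seed = 1,
                             min_cells = 9) {
  if (length(tf_groups) != length(gene_values))
    stop("tf_groups and gene_values must cover the same cells")
  gg <- quantile_group(gene_values, min_cells = min_cells)
  keep <- !is.na(tf_groups) & !is.na(gg)
  tab <- table(tf = droplevels(factor(tf_groups[keep])),
               gene = droplevels(factor(gg[keep])))
  if (nrow(tab) < 2 || ncol(tab) < 2 ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate contingency table; p set to 1")
    return(list(p_value = 1, table = tab, method = "degenerate",
                significant = FALSE))
  }
  # 2x2 tables are always exact (hypergeometric); larger tables use the
  # exact network algorithm only under the size bound
  use_exact <- all(dim(tab) == 2) || sum(tab) <= exact_max
  if (use_exact) {
    ft <- try(stats::fisher.test(tab, workspace = 2e6), silent = TRUE)
    if (!inherits(ft, "try-error"))
      return(list(p_value = ft$p.value, table = tab, method = "exact",
                  significant = ft$p.value < alpha))
  }
  ft <- with_preserved_seed(seed,
    stats::fisher.test(tab, simulate.p.value = TRUE, B = B))
  list(p_value = ft$p.value, table = tab, method = "simulated",
       significant = ft$p.value < alpha)
}

#' Pooled two-level variants of a three-level TF grouping
#'
#' Returns the two collapsed labelings used alongside the full tertile
#' analysis: low+mid vs high, and low vs mid+high. A gene is then called
#' TF-regulated if the association test is significant for any of the
#' three labelings (see [sc_coherence()]).
#'
#' @param tf_groups Factor with levels low/mid/high.
#' @return List with factors `low_mid` (levels `low+mid`, `high`) and
#'   `mid_high` (levels `low`, `mid+high`).
#' @export
pooled_variants <- function(tf_groups) {
  f <- factor(tf_groups, levels = c("low", "mid", "high"))
  low_mid <- factor(ifelse(is.na(f), NA,
                           ifelse(f == "high", "high", "low+mid")),
                    levels = c("low+mid", "high"))
  mid_high <- factor(ifelse(is.na(f), NA,
                            ifelse(f == "low", "low", "mid+high")),
                     levels = c("low", "mid+high"))
  list(low_mid = low_mid, mid_high = mid_high)
}

#' Enrichment of a gene set among significant genes
#'
#' 2x2 Fisher exact test of target membership against significance over a
#' gene universe, with the Haldane-Anscombe corrected sample odds ratio.
#'
#' @param significant Character vector of genes called significant.
#' @param targets Character vector of the TF's target genes (non-empty).
#' @param universe Character vector of all tested genes.
#' @return List with `or` (corrected sample odds ratio), `p` (Fisher exact
#'   p), `table`, `corrected` (whether the zero-cell correction fired).
#' @export
target_enrichment <- function(significant, targets, universe) {
  if (!length(targets)) stop("empty target set")
  enrichment_2x2(significant, targets, universe)
}

#' Single-cell TF-target coherence analysis
#'
#' The full per-gene workflow: tertile the TF, test every gene's
#' association with the TF grouping under the three labelings (full
#' tertiles and the two pooled variants of [pooled_variants()]), call a
#' gene TF-regulated if any of the three tests is significant, and measure
#' enrichment of the TF's bound targets among regulated genes.
#'
#' @param sc Cells x genes non-negative expression matrix with column
#'   names; rows are cells.
#' @param tf Column name of the TF.
#' @param targets Character vector of the TF's target genes.
#' @param genes Genes to test (default: all columns except the TF).
#' @param alpha Per-test significance level (default 0.01).
#' @param ... Passed to [gene_association()].
#' @return List with `per_gene` (data.frame of the three p-values and the
#'   combined call), `enrichment` (from [target_enrichment()]), and
#'   `tf_groups`.
#' @export
sc_coherence <- function(sc, tf, targets, genes = NULL, alpha = 0.01, ...) {
  sc <- as.matrix(sc)
  if (!tf %in% colnames(sc)) stop("TF ", tf, " not in the matrix")
  if (is.null(genes)) genes <- setdiff(colnames(sc), tf)
  tf_g <- quantile_group(sc[, tf])
  pooled <- pooled_variants(tf_g)
  res <- lapply(genes, function(g) {
    ps <- vapply(list(tf_g, pooled$low_mid, pooled$mid_high), function(grp) {
      out <- try(gene_association(grp, sc[, g], alpha = alpha, ...),
                 silent = TRUE)
      if (inherits(out, "try-error")) NA_real_ else out$p_value
    }, numeric(1))
    ps
  })
  pm <- do.call(rbind, res)
  colnames(pm) <- c("p_full", "p_low_mid", "p_mid_high")
  per_gene <- data.frame(gene = genes, pm,
                         regulated = apply(pm < alpha, 1, any, na.rm = TRUE),
                         stringsAsFactors = FALSE)
  sig <- per_gene$gene[per_gene$regulated]
  enr <- if (length(intersect(targets, genes)))
    target_enrichment(sig, intersect(targets, genes), genes) else NULL
  list(per_gene = per_gene, enrichment = enr, tf_groups = tf_g)
}

#' Partition single-cell expression variance between time and TF level
#'
#' Fits three ordinary least-squares models for one gene over cells with
#' positive expression: expression ~ time (categorical), expression ~ TF
#' level (categorical, typically a 6-level grouping of the TF's
#' expression), and the additive joint model. Returns each model's
#' coefficient of determination and the increment of the joint model over
#' time alone — how much the TF level explains beyond time.
#'
#' @param gene_values Numeric per-cell expression of the gene.
#' @param time Per-cell time labels (coerced to factor).
#' @param tf_levels Per-cell TF grouping (coerced to factor), e.g.
#'   `quantile_group(tf_values, cuts = (1:5)/6)`.
#' @param min_cells Minimum cells after filtering (default 12).
#' @return List with `r2_time`, `r2_tf`, `r2_joint`, `increment`
#'   (`r2_joint - r2_time`) and `n` (cells used). Empty factor levels are
#'   dropped with a warning when present.
#' @export
variance_partition <- function(gene_values, time, tf_levels, min_cells = 12) {
  keep <- !is.na(gene_values) & gene_values > 0 &
    !is.na(time) & !is.na(tf_levels)
  if (sum(keep) < min_cells)
    stop("only ", sum(keep), " usable cells (need >= ", min_cells, ")")
  y <- gene_values[keep]
  ft <- factor(time[keep])
  fl <- factor(tf_levels[keep])
  if (nlevels(ft) < length(unique(time[!is.na(time)])) ||
      nlevels(fl) < length(unique(tf_levels[!is.na(tf_levels)])))
    warning("empty factor level(s) dropped after filtering")
  r2 <- function(fit) summary(fit)$r.squared
  m_time <- stats::lm(y ~ ft)
  m_tf <- stats::lm(y ~ fl)
  m_joint <- stats::lm(y ~ ft + fl)
  list(r2_time = r2(m_time), r2_tf = r2(m_tf), r2_joint = r2(m_joint),
       increment = r2(m_joint) - r2(m_time), n = sum(keep))
}
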