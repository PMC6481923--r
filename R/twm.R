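#' Pairwise aggregation of per-contrast values
#'
#' For a vector over consecutive contrasts, returns the sums over each
#' consecutive pair of contrasts: `out[j] = x[j] + x[j+1]`, length one less
#' than the input. [aggregate_logfc()] and [aggregate_or()] are the same
#' aggregation applied to fold changes and odds ratios respectively.
#'
#' @param logfc,or Numeric vector over consecutive contrasts, length >= 2.
#' @return Numeric vector over consecutive contrast pairs.
#' @examples
#' aggregate_logfc(c(0.5, 0.7, -0.2))  # 1.2, 0.5
#' @export
aggregate_logfc <- function(logfc) {
  if (length(logfc) < 2) stop("need at least 2 contrasts")
  logfc[-length(logfc)] + logfc[-1]
}

#' @rdname aggregate_logfc
#' @export
aggregate_or <- function(or) aggregate_logfc(or)

#' Odds ratio of TF-target membership against differential expression
#'
#' For one contrast, the 2x2 association between being a target of the TF
#' and being differentially expressed, over the whole gene universe:
#' `a` = DE targets, `b` = non-DE targets, `c` = DE non-targets, `d` =
#' non-DE non-targets; `OR = (a d)/(b c)`, Haldane-Anscombe corrected
#' (+0.5 to all cells) whenever a cell is zero.
#'
#' @param targets Character vector of target gene ids (subset of the
#'   universe).
#' @param de Named 0/1 vector of differential-expression indicators; its
#'   names define the gene universe.
#' @return The odds ratio (a single positive number).
#' @examples
#' de <- setNames(rep(c(1, 0), c(28, 72)), paste0("g", 1:100))
#' # 8 of 10 targets DE: a=8 b=2 c=20 d=70 -> OR 14
#' contrast_odds_ratio(paste0("g", c(1:8, 99, 100)), de)
#' @export
contrast_odds_ratio <- function(targets, de) {
  if (is.null(names(de)) || !length(de)) stop("de must be a named, non-empty vector")
  if (!all(targets %in% names(de))) stop("targets must be a subset of the universe")
  a <- sum(de[targets])
  nt <- length(targets)
  odds_ratio_2x2(a, nt - a, sum(de) - a, length(de) - nt - (sum(de) - a))$or
}

#' Sign coherence of one gene with its TF over a contrast pair
#'
#' Returns 1 iff the four-way product of fold-change signs — the gene's and
#' the TF's over the two contrasts of the pair — is strictly positive, i.e.
#' the gene moves consistently with (or consistently against) its TF in
#' both contrasts. Any zero sign gives 0.
#'
#' @param sign_g,sign_tf Length-2 vectors of signs in `{-1, 0, 1}` for the
#'   two contrasts of the pair.
#' @return 0 or 1.
#' @examples
#' gene_coherence(c(1, 1), c(1, 1))   # 1
#' gene_coherence(c(1, -1), c(1, 1))  # 0
#' @export
gene_coherence <- function(sign_g, sign_tf) {
  stopifnot(length(sign_g) == 2, length(sign_tf) == 2)
  as.numeric(prod(sign_g, sign_tf) > 0)
}

#' Mean target coherence of a TF over one contrast pair
#'
#' Averages [gene_coherence()] over the TF's targets that are
#' differentially expressed in *both* contrasts of the pair. When no target
#' qualifies the coherence is undefined and `NA` is returned (in the final
#' score an undefined pair contributes 0 unless `skip_undefined`).
#'
#' @param tf TF gene id (must be a row of the contrast table).
#' @param pair Index of the contrast pair (1 .. A-2).
#' @param graph A [binding_graph()].
#' @param contrasts A `"contrast_series"` with `de` set.
#' @param epsilon Dead zone: |logfc| below this counts as sign 0.
#' @return A number in \[0,1\], or `NA` if no target is eligible.
#' @export
pair_coherence <- function(tf, pair, graph, contrasts, epsilon = 0) {
  stopifnot(inherits(graph, "binding_graph"),
            inherits(contrasts, "contrast_series"))
  if (is.null(contrasts$de)) stop("contrast series has no de indicators")
  lf <- contrasts$logfc
  tg <- intersect(graph$targets[[tf]], rownames(lf))
  if (!length(tg)) {
    warning("TF ", tf, " has no targets in the gene universe")
    return(NA_real_)
  }
  j <- pair
  elig <- tg[contrasts$de[tg, j] == 1 & contrasts$de[tg, j + 1] == 1]
  if (!length(elig)) return(NA_real_)
  s <- sign(lf)
  s[is.na(lf) | abs(lf) < epsilon] <- 0
  stf <- s[tf, c(j, j + 1)]
  mean((s[elig, j] * s[elig, j + 1] * stf[1] * stf[2]) > 0)
}

# Vectorized single-TF scoring kernel shared by twm() and twm_null().
# tf_lf: TF logfc vector; tidx: integer target rows; s: precomputed sign
# matrix; de: 0/1 matrix; de_tot: colSums(de); n_genes: universe size.
.twm_one <- function(tf_lf, tidx, s, de, de_tot, n_genes,
                     signed, pair_average, skip_undefined, epsilon) {
  nc <- length(tf_lf)
  s_tf <- sign(tf_lf)
  s_tf[is.na(tf_lf) | abs(tf_lf) < epsilon] <- 0

  nt <- length(tidx)
  de_t <- de[tidx, , drop = FALSE]
  a <- colSums(de_t)
  or_j <- vapply(seq_len(nc), function(j) {
    odds_ratio_2x2(a[j], nt - a[j], de_tot[j] - a[j],
                   n_genes - nt - (de_tot[j] - a[j]))$or
  }, numeric(1))

  agg_lf <- tf_lf[-nc] + tf_lf[-1]
  agg_or <- or_j[-nc] + or_j[-1]
  if (pair_average) {
    agg_lf <- agg_lf / 2
    agg_or <- agg_or / 2
  }

  s_t <- s[tidx, , drop = FALSE]
  np <- nc - 1
  coh_pair <- numeric(np)
  n_elig <- integer(np)
  for (j in seq_len(np)) {
    el <- de_t[, j] == 1 & de_t[, j + 1] == 1
    n_elig[j] <- sum(el)
    coh_pair[j] <- if (!n_elig[j]) NA_real_ else
      mean((s_t[el, j] * s_t[el, j + 1] * s_tf[j] * s_tf[j + 1]) > 0)
  }

  comb <- sum((if (signed) agg_lf else abs(agg_lf)) * agg_or)
  coh <- if (skip_undefined) {
    def <- coh_pair[!is.na(coh_pair)]
    if (!length(def)) 0 else prod(def)
  } else prod(ifelse(is.na(coh_pair), 0, coh_pair))

  list(pair_logfc = agg_lf, pair_or = agg_or, coh_pair = coh_pair,
       n_elig = n_elig, n_targets = nt, comb = comb, coh = coh,
       twm = comb * coh)
}

#' Rank transcription factors by transition weight
#'
#' The central fitting function: scores every TF of a binding graph
#' against a time-course expression data set and ranks them as candidate
#' drivers of the transition. For each TF the score combines three
#' ingredients across consecutive contrast pairs:
#'
#' 1. the TF's own log2 fold change, summed over each pair of consecutive
#'    contrasts;
#' 2. the odds ratio of its bound targets against differentially expressed
#'    genes, summed the same way;
#' 3. the coherence of its targets — the fraction of targets (DE in both
#'    contrasts of a pair) whose fold-change signs agree with the TF's in a
#'    four-sign product.
#'
#' The combined enrichment term is `comb = sum over pairs of
#' |aggregated logFC| * aggregated OR`, the global coherence `coh` is the
#' product of per-pair coherences (an undefined pair counts 0), and the
#' transition weight is `twm = comb * coh`.
#'
#' @param x An [expression_ts()] object, or a `"contrast_series"` from
#'   [compute_contrasts()] / [fallback_de_test()].
#' @param graph A [binding_graph()] of TF -> target edges.
#' @param de Differential-expression indicators: a genes x contrasts 0/1
#'   matrix, or `NULL`. When `x` is an expression object and `de` is
#'   `NULL`, indicators come from [fallback_de_test()] at level `alpha`.
#' @param alpha Level for the fallback test (default 0.05).
#' @param signed Use the signed aggregated log fold change in `comb`
#'   instead of its absolute value (the literal formula; makes
#'   down-regulated drivers score negative).
#' @param pair_average Average instead of sum within each contrast pair
#'   (halves both aggregates, rescaling every score by exactly 1/4 and
#'   leaving the ranking unchanged).
#' @param skip_undefined Multiply coherence over defined pairs only
#'   instead of letting an undefined pair zero the score (exploratory).
#' @param epsilon Dead zone: |logfc| below `epsilon` counts as sign 0.
#' @param condition Optional condition restriction for the contrasts.
#' @return An object of class `"twm"`: list with `results` (ranked
#'   data.frame: `tf`, `n_targets`, `comb`, `coh`, `twm`), per-pair
#'   matrices `pair_logfc`, `pair_or`, `pair_coh`, `n_eligible`, the
#'   underlying `contrasts` (with `de`), `targets` (index list), `params`
#'   and `call`. Methods: `print`, `summary`, `coef`, `plot`.
#' @seealso [twm_null()] for a permutation significance aid,
#'   [simulate_bulk()] to generate benchmark inputs.
#' @examples
#' sim <- simulate_bulk(sim_config(n_genes = 300, n_tfs = 4, seed = 1))
#' fit <- twm(sim$expr, sim$graph, de = sim$truth$de)
#' fit
#' coef(fit)[1:2]
#' @export
twm <- function(x, graph, de = NULL, alpha = 0.05, signed = FALSE,
                pair_average = FALSE, skip_undefined = FALSE, epsilon = 0,
                condition = NULL) {
  stopifnot(inherits(graph, "binding_graph"))
  if (inherits(x, "expression_ts")) {
    cs <- if (is.null(de)) fallback_de_test(x, alpha = alpha, condition = condition)
          else compute_contrasts(x, condition = condition)
  } else if (inherits(x, "contrast_series")) {
    cs <- x
  } else stop("x must be an expression_ts or a contrast_series")
  if (!is.null(de)) cs <- set_de(cs, de)
  if (is.null(cs$de)) stop("no differential-expression indicators available")
  if (length(cs$pairs) < 1)
    stop("need at least 3 time points so one consecutive contrast pair exists")

  lf <- cs$logfc
  genes <- rownames(lf)
  tfs <- intersect(graph$tf_ids, genes)
  drop_tf <- setdiff(graph$tf_ids, genes)
  if (length(drop_tf))
    warning("TF(s) absent from the expression table, skipped: ",
            paste(drop_tf, collapse = ", "))
  if (!length(tfs)) stop("no TF of the graph is present in the expression table")

  s <- sign(lf)
  s[is.na(lf) | abs(lf) < epsilon] <- 0
  de_m <- cs$de
  de_tot <- colSums(de_m)
  n_genes <- nrow(lf)

  tidx_list <- lapply(tfs, function(tf) {
    tg <- graph$targets[[tf]]
    idx <- match(tg, genes)
    n_out <- sum(is.na(idx))
    if (n_out)
      warning(n_out, " target(s) of ", tf, " absent from the expression table")
    idx <- idx[!is.na(idx)]
    if (!length(idx)) warning("TF ", tf, " has no targets in the gene universe")
    idx
  })
  names(tidx_list) <- tfs

  np <- length(cs$pairs)
  rows <- vector("list", length(tfs))
  for (i in seq_along(tfs)) {
    tf <- tfs[i]
    if (!length(tidx_list[[tf]])) {
      rows[[i]] <- list(pair_logfc = rep(NA_real_, np),
                        pair_or = rep(NA_real_, np),
                        coh_pair = rep(NA_real_, np),
                        n_elig = rep(0L, np), n_targets = 0L,
                        comb = NA_real_, coh = 0, twm = 0)
      next
    }
    rows[[i]] <- .twm_one(lf[tf, ], tidx_list[[tf]], s, de_m, de_tot, n_genes,
                          signed, pair_average, skip_undefined, epsilon)
  }

  res <- data.frame(
    tf = tfs,
    n_targets = vapply(rows, `[[`, integer(1), "n_targets"),
    comb = vapply(rows, `[[`, numeric(1), "comb"),
    coh = vapply(rows, `[[`, numeric(1), "coh"),
    twm = vapply(rows, `[[`, numeric(1), "twm"),
    stringsAsFactors = FALSE)

  mat <- function(field) {
    m <- do.call(rbind, lapply(rows, `[[`, field))
    dimnames(m) <- list(tfs, cs$pairs)
    m
  }

  fit <- structure(list(
    results = res,
    pair_logfc = mat("pair_logfc"),
    pair_or = mat("pair_or"),
    pair_coh = mat("coh_pair"),
    n_eligible = mat("n_elig"),
    contrasts = cs,
    targets = tidx_list,
    params = list(signed = signed, pair_average = pair_average,
                  skip_undefined = skip_undefined, epsilon = epsilon,
                  alpha = alpha),
    call = match.call()),
    class = "twm")
  fit$results <- rank_tfs(fit$results)
  fit
}

#' Order a TWM result table
#'
#' Descending by transition weight; ties broken by higher global coherence,
#' then lexicographic TF id, so the ordering is deterministic and invariant
#' to input row order.
#'
#' @param results data.frame with columns `tf`, `coh`, `twm` (e.g.
#'   `fit$results`).
#' @return The same data.frame, reordered, with a `rank` column.
#' @export
rank_tfs <- function(results) {
  o <- order(-results$twm, -results$coh, results$tf)
  out <- results[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Permutation null for a TF's transition weight
#'
#' Recomputes the TF's score under random degree-preserving relabelings of
#' its target set (same number of targets drawn without replacement from
#' the gene universe, the TF itself excluded) and reports where the
#' observed score sits in that null.
#'
#' @param fit A `"twm"` fit.
#' @param tf TF id present in the fit.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; the permutation stream is isolated from the
#'   caller's RNG state.
#' @return List with `percentile` (fraction of null scores below the
#'   observed one, ties counted half — a mid-fraction, robust when many
#'   null scores coincide), `observed`, `null` (the permuted scores),
#'   `n_perm`, `seed`.
#' @export
twm_null <- function(fit, tf, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(fit, "twm"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!tf %in% names(fit$targets)) stop("TF ", tf, " not in the fit")
  tidx <- fit$targets[[tf]]
  if (length(tidx) < 5)
    warning("TF ", tf, " has fewer than 5 targets; null may be unstable")
  cs <- fit$contrasts
  lf <- cs$logfc
  p <- fit$params
  s <- sign(lf)
  s[is.na(lf) | abs(lf) < p$epsilon] <- 0
  de_m <- cs$de
  de_tot <- colSums(de_m)
  tf_row <- match(tf, rownames(lf))
  pool <- setdiff(seq_len(nrow(lf)), tf_row)
  obs <- fit$results$twm[fit$results$tf == tf]

  null <- with_preserved_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample(pool, length(tidx))
      .twm_one(lf[tf_row, ], idx, s, de_m, de_tot, nrow(lf),
               p$signed, p$pair_average, p$skip_undefined, p$epsilon)$twm
    }, numeric(1))
  })
  list(percentile = (sum(null < obs) + 0.5 * sum(null == obs)) / n_perm,
       observed = obs, null = null, n_perm = n_perm, seed = seed)
}

#' @export
print.twm <- function(x, n = 10, ...) {
  cat("Transition weight matrix fit\n")
  cat(sprintf("  %d TFs, %d genes, %d contrasts (%d pairs)\n",
              nrow(x$results), nrow(x$contrasts$logfc),
              length(x$contrasts$contrasts), length(x$contrasts$pairs)))
  p <- x$params
  flags <- c(if (p$signed) "signed", if (p$pair_average) "pair-average",
             if (p$skip_undefined) "skip-undefined",
             if (p$epsilon > 0) sprintf("epsilon=%g", p$epsilon))
  if (length(flags)) cat("  options:", paste(flags, collapse = ", "), "\n")
  cat("\n")
  print(utils::head(x$results, n), digits = 4)
  if (nrow(x$results) > n) cat("  ...", nrow(x$results) - n, "more TFs\n")
  invisible(x)
}

#' @method summary twm
#' @export
summary.twm <- function(object, ...) {
  res <- object$results
  structure(list(results = res,
                 pair_coh = object$pair_coh,
                 pair_logfc = object$pair_logfc,
                 pair_or = object$pair_or,
                 n_eligible = object$n_eligible,
                 n_zero = sum(res$twm == 0),
                 params = object$params),
            class = "summary.twm")
}

#' @export
print.summary.twm <- function(x, ...) {
  cat("TWM summary:", nrow(x$results), "TFs;",
      x$n_zero, "with collapsed (zero) score\n\n")
  print(x$results, digits = 4)
  cat("\nPer-pair coherence:\n")
  print(round(x$pair_coh, 3))
  invisible(x)
}

#' @method coef twm
#' @export
coef.twm <- function(object, ...) {
  stats::setNames(object$results$twm, object$results$tf)
}

#' @method plot twm
#' @export
plot.twm <- function(x, n = 15, ...) {
  res <- utils::head(x$results, n)
  op <- graphics::par(mar = c(4, 6, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(res$twm), names.arg = rev(res$tf), horiz = TRUE,
                    las = 1, xlab = "transition weight (TWM)",
                    col = "steelblue", ...)
  invisible(x)
}

#' @method as.data.frame twm
#' @export
as.data.frame.twm <- function(x, ...) x$results
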