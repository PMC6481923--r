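#' Tau tissue-specificity index
#'
#' `tau = sum_i(1 - x_i / max(x)) / (n - 1)` over a gene's expression
#' across tissues: 0 for a uniformly expressed (housekeeping-like) gene, 1
#' for single-tissue expression. Invariant to positive rescaling.
#'
#' @param x Non-negative expression vector over >= 2 tissues, max > 0.
#' @return A number in \[0,1\].
#' @examples
#' compute_tau(c(10, 5, 0, 0))  # 0.8333
#' @export
compute_tau <- function(x) {
  if (length(x) < 2) stop("need expression over at least 2 tissues")
  if (any(!is.finite(x)) || any(x < 0)) stop("x must be finite and non-negative")
  m <- max(x)
  if (m == 0) stop("all-zero expression vector")
  sum(1 - x / m) / (length(x) - 1)
}

#' Housekeeping vs tissue-specific classification from tau
#'
#' @param tau Tau value(s) from [compute_tau()].
#' @param expr_filter Logical: whether the gene passes the expression
#'   filter (conventionally expressed above 0.5 FPKM in the tissues of
#'   interest). Recycled.
#' @param housekeeping_max Tau below this (and filter passed) gives
#'   `"housekeeping"` (default 0.25).
#' @param specific_min Tau above this (and filter passed) gives
#'   `"tissue_specific"` (default 0.70).
#' @return Character vector in `{housekeeping, tissue_specific,
#'   unclassified}`.
#' @export
classify_specificity <- function(tau, expr_filter = TRUE,
                                 housekeeping_max = 0.25,
                                 specific_min = 0.70) {
  n <- max(length(tau), length(expr_filter))
  tau <- rep_len(tau, n)
  expr_filter <- rep_len(expr_filter, n)
  ifelse(expr_filter & tau < housekeeping_max, "housekeeping",
         ifelse(expr_filter & tau > specific_min, "tissue_specific",
                "unclassified"))
}

#' Partition regulated genes by sensitivity to a co-expressed antagonist
#'
#' Splits the genes regulated by an induced factor (e.g. Ikaros) into
#' those still differentially expressed when a second factor (e.g. Myc) is
#' co-expressed ("resistant") and those whose response is lost
#' ("sensitive"). The two classes exactly partition the regulated set.
#'
#' @param de_single data.frame with columns `gene`, `adj_p` and optionally
#'   `direction` (`"up"`/`"down"`, carried through) for the
#'   single-induction contrast.
#' @param de_combo data.frame with columns `gene`, `adj_p` for the
#'   co-expression contrast.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return data.frame with `gene`, `class` (`"resistant"`/`"sensitive"`)
#'   and `direction` if supplied, restricted to regulated genes present in
#'   both tables; genes present in only one table are dropped with a
#'   warning giving the count.
#' @export
myc_partition <- function(de_single, de_combo, alpha = 0.05) {
  stopifnot(all(c("gene", "adj_p") %in% names(de_single)),
            all(c("gene", "adj_p") %in% names(de_combo)))
  shared <- intersect(de_single$gene, de_combo$gene)
  n_only <- length(setdiff(de_single$gene, shared)) +
    length(setdiff(de_combo$gene, shared))
  if (n_only)
    warning(n_only, " gene(s) present in only one table were excluded")
  s <- de_single[match(shared, de_single$gene), ]
  cmb <- de_combo[match(shared, de_combo$gene), ]
  reg <- s$adj_p < alpha
  out <- data.frame(gene = shared[reg],
                    class = ifelse(cmb$adj_p[reg] < alpha,
                                   "resistant", "sensitive"),
                    stringsAsFactors = FALSE)
  if ("direction" %in% names(de_single))
    out$direction <- s$direction[reg]
  out
}

#' 2x2 set enrichment by Fisher exact test
#'
#' Association between membership in two gene sets over a universe:
#' Fisher exact p-value and the Haldane-Anscombe corrected sample odds
#' ratio (odds ratios above 1 indicate enrichment).
#'
#' @param setA,setB Character vectors of genes (subsets of `universe`).
#' @param universe Character vector of all genes considered.
#' @return List with `or`, `p`, `table` (2x2 counts), `corrected`.
#' @examples
#' u <- paste0("g", 1:100)
#' enrichment_2x2(u[1:20], u[c(1:10, 21:30)], u)
#' @export
enrichment_2x2 <- function(setA, setB, universe) {
  universe <- unique(universe)
  setA <- intersect(unique(setA), universe)
  setB <- intersect(unique(setB), universe)
  inA <- universe %in% setA
  inB <- universe %in% setB
  a <- sum(inA & inB); b <- sum(!inA & inB)
  c <- sum(inA & !inB); d <- sum(!inA & !inB)
  orr <- odds_ratio_2x2(a, b, c, d)
  tab <- matrix(c(a, b, c, d), 2, 2,
                dimnames = list(inB = c("yes", "no"), inA = c("yes", "no")))
  p <- stats::fisher.test(tab)$p.value
  list(or = orr$or, p = p, table = tab, corrected = orr$corrected)
}

# Keyword lists for the broad functional classes; matching is
# case-insensitive substring containment, first class in priority order
# wins (most specific first, since a term can match several classes).
.go_classes <- list(
  "Immune system" = c("immune", "host defense", "b cell", "t cell",
                      "myeloid", "lymphocyte", "leukocyte", "hematopoiesis"),
  "Adhesion" = c("adhesion", "integrin"),
  "Translation" = c("translation", "ribosome", "ribonuclear"),
  "Proliferation" = c("proliferation", "chromatid", "spindle", "mitosis",
                      "mitotic", "cell cycle", "cell division",
                      "dna synthesis", "dna replication"),
  "Metabolism" = c("metabolic", "metabolism", "biosynthetic",
                   "biosynthesis", "catabolic"),
  "Differentiation" = c("differentiation", "development"),
  "Signaling" = c("signal", "signaling", "response", "stimulus",
                  "communication", "activation")
)

#' Categorize GO term descriptions into broad functional classes
#'
#' Case-insensitive keyword containment against seven fixed keyword lists
#' (Immune system, Adhesion, Translation, Proliferation, Metabolism,
#' Differentiation, Signaling). When a term matches several classes the
#' first in that priority order wins; no match gives `"other"`.
#'
#' @param term Character vector of GO term descriptions.
#' @return Character vector of class labels.
#' @examples
#' categorize_go(c("integrin-mediated signaling pathway",
#'                 "ribosome biogenesis", "xylem development"))
#' @export
categorize_go <- function(term) {
  lt <- tolower(term)
  vapply(lt, function(x) {
    for (cl in names(.go_classes)) {
      if (any(vapply(.go_classes[[cl]], grepl, logical(1), x = x,
                     fixed = TRUE)))
        return(cl)
    }
    "other"
  }, character(1), USE.NAMES = FALSE)
}
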