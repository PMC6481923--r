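#' Transcription-factor binding graph
#'
#' A directed bipartite graph of TF -> target-gene edges, typically derived
#' from promoter-proximal binding peaks ([assign_peaks()]) or supplied
#' directly as a two-column table.
#'
#' @param edges A data.frame with columns `tf` and `gene` (extra columns are
#'   kept as edge annotation; a `source` column records provenance, one of
#'   `"chip"`, `"footprint"`, `"supplied"`).
#' @return An object of class `"binding_graph"`: list with `edges`
#'   (deduplicated data.frame), `tf_ids` (unique TFs) and `targets` (named
#'   list mapping each TF to its character vector of target genes, for O(1)
#'   amortized membership work).
#' @examples
#' g <- binding_graph(data.frame(tf = c("A", "A", "B"),
#'                               gene = c("g1", "g2", "g1")))
#' g$targets$A
#' @export
binding_graph <- function(edges) {
  edges <- as.data.frame(edges)
  if (!all(c("tf", "gene") %in% names(edges)))
    stop("edges must have columns 'tf' and 'gene'")
  if (nrow(edges) == 0) stop("binding graph has no edges")
  edges$tf <- as.character(edges$tf)
  edges$gene <- as.character(edges$gene)
  if (!"source" %in% names(edges)) edges$source <- "supplied"
  edges <- edges[!duplicated(edges[c("tf", "gene")]), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 tf_ids = unique(edges$tf),
                 targets = split(edges$gene, factor(edges$tf, unique(edges$tf)))),
            class = "binding_graph")
}

#' @export
print.binding_graph <- function(x, ...) {
  nt <- lengths(x$targets)
  cat("binding_graph:", length(x$tf_ids), "TFs,", nrow(x$edges),
      "edges, median targets/TF =", stats::median(nt), "\n")
  invisible(x)
}

#' Read a binding graph from a two-column TSV
#'
#' @param path TSV with columns `tf` and `gene` (header optional if exactly
#'   two columns). Duplicate edges are collapsed.
#' @param source Provenance tag recorded on every edge.
#' @return A [binding_graph()].
#' @export
read_binding_graph <- function(path, source = "supplied") {
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#")]
  if (!length(first)) stop("empty binding graph file: ", path)
  header <- grepl("^tf\\t", first[1])
  tab <- read_tsv_plain(path, header = header)
  if (!header) names(tab)[1:2] <- c("tf", "gene")
  if (nrow(tab) == 0) stop("empty binding graph file: ", path)
  g <- binding_graph(data.frame(tf = tab$tf, gene = tab$gene, source = source))
  message(sprintf("binding graph: %d TFs, %d edges, median targets/TF = %g",
                  length(g$tf_ids), nrow(g$edges),
                  stats::median(lengths(g$targets))))
  g
}

#' Write a binding graph to TSV
#'
#' @param x A [binding_graph()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_binding_graph <- function(x, path) {
  stopifnot(inherits(x, "binding_graph"))
  write_tsv_commented(x$edges, path)
}
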