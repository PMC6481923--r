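#' Assign binding peaks to genes through a promoter window
#'
#' Emits a TF -> gene edge whenever a peak interval overlaps the promoter
#' window of a gene: `[TSS - upstream, TSS + downstream)` on the plus
#' strand, mirrored for minus-strand genes when `strand_aware` is `TRUE`.
#' This is the "proximal gene" step that turns ChIP-seq or
#' footprint-derived peaks into a [binding_graph()].
#'
#' All coordinates follow the BED convention: 0-based, half-open intervals;
#' the TSS is a single 0-based position. The default window (2,000 bp
#' upstream to 500 bp downstream) approximates a promoter-proximal
#' assignment and deliberately changes the graph when changed — choose it
#' to match how the peak set was produced.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` and
#'   optionally `adj_p` (see `adjp`). See [read_peaks_bed()].
#' @param tss data.frame with columns `gene`, `chrom`, `tss` (0-based
#'   position), `strand` (`+`/`-`). See [read_tss()].
#' @param tf_id TF identifier stamped on every emitted edge.
#' @param upstream,downstream Window extent in bp (non-negative integers).
#' @param strand_aware Mirror the window for minus-strand genes (default
#'   `TRUE`); when `FALSE` every gene is treated as plus-strand.
#' @param adjp If non-`NULL`, peaks with `adj_p >=` this threshold are
#'   discarded before assignment (the conventional peak filter is 0.01).
#' @param source Provenance tag for the edges (`"chip"` or `"footprint"`).
#' @return A data.frame of deduplicated edges (`tf`, `gene`, `source`),
#'   suitable for [binding_graph()]. Zero overlaps yield an empty
#'   data.frame with a warning.
#' @examples
#' pk <- data.frame(chrom = "chr1", start = 1000, end = 1200)
#' ts <- data.frame(gene = "g1", chrom = "chr1", tss = 1100, strand = "+")
#' assign_peaks(pk, ts, "MYC")
#' @export
assign_peaks <- function(peaks, tss, tf_id, upstream = 2000, downstream = 500,
                         strand_aware = TRUE, adjp = NULL, source = "chip") {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream > 0)
  peaks <- as.data.frame(peaks)
  tss <- as.data.frame(tss)
  if (!all(c("chrom", "start", "end") %in% names(peaks)))
    stop("peaks need columns chrom, start, end")
  if (!all(c("gene", "chrom", "tss", "strand") %in% names(tss)))
    stop("tss table needs columns gene, chrom, tss, strand")
  if (any(peaks$start >= peaks$end)) stop("peak start must be < end")
  if (any(peaks$start < 0) || any(tss$tss < 0)) stop("negative coordinates")
  if (!all(tss$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")

  if (!is.null(adjp)) {
    if (!"adj_p" %in% names(peaks))
      stop("adjp filtering requested but peaks have no adj_p column")
    peaks <- peaks[peaks$adj_p < adjp, , drop = FALSE]
  }

  shared <- intersect(unique(peaks$chrom), unique(tss$chrom))
  if (length(setdiff(unique(peaks$chrom), unique(tss$chrom))) ||
      length(setdiff(unique(tss$chrom), unique(peaks$chrom)))) {
    warning("chromosome sets differ between peaks and TSS table; ",
            "peaks per chromosome: ",
            paste(sprintf("%s=%d", names(table(peaks$chrom)),
                          table(peaks$chrom)), collapse = " "))
  }

  if (nrow(peaks) == 0 || length(shared) == 0) {
    warning("no overlapping peaks; empty edge set")
    return(data.frame(tf = character(), gene = character(),
                      source = character()))
  }

  minus <- strand_aware & tss$strand == "-"
  win_start <- ifelse(minus, tss$tss - downstream, tss$tss - upstream)
  win_end <- ifelse(minus, tss$tss + upstream, tss$tss + downstream)
  win_start <- pmax(win_start, 0)

  # 0-based half-open -> 1-based closed for IRanges
  prom <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = win_start + 1L, end = win_end))
  pk <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  suppressWarnings(
    ov <- GenomicRanges::findOverlaps(pk, prom, ignore.strand = TRUE))

  if (length(ov) == 0) {
    warning("no overlapping peaks; empty edge set")
    return(data.frame(tf = character(), gene = character(),
                      source = character()))
  }
  genes <- unique(tss$gene[S4Vectors::subjectHits(ov)])
  data.frame(tf = tf_id, gene = sort(genes), source = source,
             stringsAsFactors = FALSE)
}

#' Read peak intervals from a BED-like file
#'
#' @param path BED file (0-based half-open): columns chrom, start, end and
#'   optionally name, score. Lines starting with `#` or `track` are
#'   skipped.
#' @param adjp_col Optional column index holding the adjusted p-value of
#'   each peak; stored as `adj_p`.
#' @return data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `adj_p`.
#' @export
read_peaks_bed <- function(path, adjp_col = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   nzchar(lines)]
  if (!length(lines)) stop("empty BED file: ", path)
  tab <- utils::read.table(text = lines, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 4) out$name <- as.character(tab[[4]])
  if (!is.null(adjp_col)) out$adj_p <- as.numeric(tab[[adjp_col]])
  out
}

#' Read a gene TSS table
#'
#' Accepts either a 4-column TSV (`gene`, `chrom`, `tss`, `strand`; TSS
#' 0-based) or a GTF file (detected by extension), in which case the TSS of
#' each `gene` (or, failing that, `transcript`) feature is taken as the
#' start for plus-strand and the end for minus-strand entries, converted to
#' 0-based.
#'
#' @param path TSV or GTF path.
#' @return data.frame with columns `gene`, `chrom`, `tss`, `strand`.
#' @export
read_tss <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gtf")
    keep <- gr$type == "gene"
    if (!any(keep)) keep <- gr$type == "transcript"
    gr <- gr[keep]
    plus <- as.character(GenomicRanges::strand(gr)) != "-"
    data.frame(
      gene = as.character(gr$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      tss = ifelse(plus, GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr) - 1L),
      strand = ifelse(plus, "+", "-"),
      stringsAsFactors = FALSE)
  } else {
    tab <- read_tsv_plain(path)
    if (!all(c("gene", "chrom", "tss", "strand") %in% names(tab)))
      stop("TSS table needs columns gene, chrom, tss, strand")
    tab[c("gene", "chrom", "tss", "strand")]
  }
}
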