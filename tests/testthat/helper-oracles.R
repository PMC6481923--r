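# Independent oracles used across tests. These are deliberately naive,
# loop-based transcriptions that share no code with the package internals.

# Literal transcription of the four scoring steps for one TF:
# per-contrast logFC and OR, pairwise sums, four-sign coherence averaged
# over targets DE in both contrasts of a pair, comb = sum(logFC * OR) over
# pairs (signed or absolute), coh = product over pairs (NA pair -> 0),
# twm = comb * coh.
oracle_twm_one <- function(tf, logfc, de, targets, signed = TRUE) {
  nc <- ncol(logfc)
  genes <- rownames(logfc)
  or_j <- numeric(nc)
  for (j in seq_len(nc)) {
    a <- b <- cc <- d <- 0
    for (g in genes) {
      is_t <- g %in% targets
      is_d <- de[g, j] == 1
      if (is_t && is_d) a <- a + 1
      else if (is_t) b <- b + 1
      else if (is_d) cc <- cc + 1
      else d <- d + 1
    }
    if (a == 0 || b == 0 || cc == 0 || d == 0) {
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    }
    or_j[j] <- (a * d) / (b * cc)
  }
  lf_tf <- logfc[tf, ]
  agg_lf <- agg_or <- coh_p <- numeric(nc - 1)
  for (j in seq_len(nc - 1)) {
    agg_lf[j] <- lf_tf[j] + lf_tf[j + 1]
    agg_or[j] <- or_j[j] + or_j[j + 1]
    num <- den <- 0
    for (g in targets) {
      if (de[g, j] == 1 && de[g, j + 1] == 1) {
        den <- den + 1
        pr <- sign(logfc[g, j]) * sign(logfc[g, j + 1]) *
          sign(lf_tf[j]) * sign(lf_tf[j + 1])
        if (pr > 0) num <- num + 1
      }
    }
    coh_p[j] <- if (den == 0) NA_real_ else num / den
  }
  comb <- 0
  for (j in seq_len(nc - 1))
    comb <- comb + (if (signed) agg_lf[j] else abs(agg_lf[j])) * agg_or[j]
  coh <- 1
  for (j in seq_len(nc - 1))
    coh <- coh * (if (is.na(coh_p[j])) 0 else coh_p[j])
  list(comb = comb, coh = coh, twm = comb * coh,
       pair_or = agg_or, pair_logfc = agg_lf, coh_pair = coh_p)
}

# Random small scoring instance: logfc matrix, 0/1 de matrix, a target
# list per TF (TFs are rows of the matrix too).
random_instance <- function(seed, G = NULL, n_tf = NULL, A = NULL) {
  set.seed(seed)
  if (is.null(G)) G <- sample(30:200, 1)
  if (is.null(n_tf)) n_tf <- sample(2:10, 1)
  if (is.null(A)) A <- sample(4:6, 1)
  nc <- A - 1
  genes <- c(sprintf("TF%02d", seq_len(n_tf)), sprintf("g%03d", seq_len(G)))
  logfc <- matrix(round(rnorm(length(genes) * nc), 3), length(genes), nc,
                  dimnames = list(genes, paste0("c", seq_len(nc))))
  de <- matrix(rbinom(length(genes) * nc, 1, 0.4), length(genes), nc,
               dimnames = dimnames(logfc))
  targets <- lapply(seq_len(n_tf), function(i)
    sample(sprintf("g%03d", seq_len(G)), sample(5:min(30, G), 1)))
  names(targets) <- sprintf("TF%02d", seq_len(n_tf))
  list(logfc = logfc, de = de, targets = targets,
       tfs = names(targets), times = seq_len(A))
}

# Binding graph of a random instance
instance_graph <- function(inst) {
  binding_graph(data.frame(
    tf = rep(names(inst$targets), lengths(inst$targets)),
    gene = unlist(inst$targets, use.names = FALSE)))
}

# Brute-force all-pairs promoter-overlap scan (interval oracle for
# assign_peaks): half-open arithmetic, one pass over every peak x gene.
brute_overlap_edges <- function(peaks, tss, tf_id, upstream, downstream,
                                strand_aware = TRUE) {
  hit <- character()
  for (i in seq_len(nrow(tss))) {
    minus <- strand_aware && tss$strand[i] == "-"
    ws <- if (minus) tss$tss[i] - downstream else tss$tss[i] - upstream
    we <- if (minus) tss$tss[i] + upstream else tss$tss[i] + downstream
    ws <- max(ws, 0)
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] == tss$chrom[i] &&
          peaks$start[j] < we && ws < peaks$end[j]) {
        hit <- c(hit, tss$gene[i])
        break
      }
    }
  }
  if (!length(hit)) return(data.frame(tf = character(), gene = character()))
  data.frame(tf = tf_id, gene = sort(unique(hit)), stringsAsFactors = FALSE)
}
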