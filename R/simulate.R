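#' Configuration for the synthetic-data generators
#'
#' Collects every knob of [simulate_bulk()] and [simulate_cells()] with
#' defaults describing the benchmark condition used throughout the
#' package's tests: a 6-time-point induction course (0-24 h) of 2,000
#' genes measured in duplicate, 20 TFs with 100 bound targets each, one
#' planted driver whose targets follow it sign-coherently 90% of the time,
#' and replicate noise of 0.5 log2 units.
#'
#' @param n_genes Number of non-TF genes in the expression universe.
#' @param n_tfs Number of TFs (each TF is itself a gene, prepended to the
#'   universe).
#' @param times Time points in hours (length A >= 3).
#' @param n_replicates Replicates per time point.
#' @param targets_per_tf Bound targets drawn per TF (without replacement
#'   from the non-TF genes; distinct TFs may share targets).
#' @param driver_ids Which TFs are planted drivers (default the first).
#' @param driver_effect Per-contrast expression step of a driver, log2
#'   units.
#' @param driver_shape `"up"`, `"down"`, or `"up-down"` trajectory for
#'   drivers.
#' @param p_coh Probability that a driver target's per-contrast step sign
#'   matches the driver's.
#' @param background_coh Same probability for background TFs' targets
#'   (0.5 = independent signs).
#' @param noise_sd Replicate noise standard deviation, log2 units.
#' @param de_fraction Fraction of unbound background genes that change
#'   (random sign) at every contrast.
#' @param step_sd Spread of target/background step magnitudes around
#'   `driver_effect` (|N(driver_effect, step_sd)|).
#' @param cells_per_time,sc_effect,dropout Single-cell generator knobs:
#'   cells per time point, per-tertile shift of true targets (log scale),
#'   and dropout-zero rate.
#' @param seed Integer seed; both generators are fully reproducible.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000, n_tfs = 20,
                       times = c(0, 2, 6, 12, 18, 24), n_replicates = 2,
                       targets_per_tf = 100, driver_ids = NULL,
                       driver_effect = 1.0, driver_shape = "up",
                       p_coh = 0.9, background_coh = 0.5,
                       noise_sd = 0.5, de_fraction = 0.3, step_sd = 0.25,
                       cells_per_time = 54, sc_effect = 1.0, dropout = 0.3,
                       seed = 1) {
  stopifnot(n_genes >= 1, n_tfs >= 1, length(times) >= 3,
            !is.unsorted(times, strictly = TRUE),
            n_replicates >= 1, targets_per_tf >= 0,
            p_coh >= 0, p_coh <= 1, background_coh >= 0, background_coh <= 1,
            noise_sd > 0, de_fraction >= 0, de_fraction <= 1,
            dropout >= 0, dropout < 1)
  driver_shape <- match.arg(driver_shape, c("up", "down", "up-down"))
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  if (is.null(driver_ids)) driver_ids <- tf_ids[1]
  if (!all(driver_ids %in% tf_ids)) stop("driver_ids must be among the TF ids")
  structure(list(n_genes = n_genes, n_tfs = n_tfs, tf_ids = tf_ids,
                 times = times, n_replicates = n_replicates,
                 targets_per_tf = targets_per_tf, driver_ids = driver_ids,
                 driver_effect = driver_effect, driver_shape = driver_shape,
                 p_coh = p_coh, background_coh = background_coh,
                 noise_sd = noise_sd, de_fraction = de_fraction,
                 step_sd = step_sd, cells_per_time = cells_per_time,
                 sc_effect = sc_effect, dropout = dropout, seed = seed),
            class = "sim_config")
}

#' Simulate a bulk time course with planted driver TFs
#'
#' Generates an expression time series, a TF -> target binding graph and a
#' ground-truth table. Driver TFs follow a deterministic mean trajectory
#' stepping by `driver_effect` per contrast; each driver target steps at
#' every contrast with sign matching the driver's with probability
#' `p_coh` and magnitude `|N(driver_effect, step_sd)|`. Background TFs
#' step with random signs, and their targets match them only with
#' probability `background_coh` (0.5 = no relation). A `de_fraction` of
#' the remaining genes also step with random signs; all other genes are
#' flat. Replicate noise is i.i.d. `N(0, noise_sd^2)`.
#'
#' When a gene is bound by several TFs its steps are written in the order
#' background TFs then drivers, so the planted driver structure always
#' survives target-set overlap.
#'
#' @param config A [sim_config()].
#' @return List with `expr` ([expression_ts()]), `graph`
#'   ([binding_graph()]) and `truth`: list with `steps` (true per-contrast
#'   mean changes, genes x contrasts), `de` (0/1 matrix, `steps != 0`),
#'   `driver_ids`, and the config.
#' @examples
#' sim <- simulate_bulk(sim_config(n_genes = 100, n_tfs = 3,
#'                                 targets_per_tf = 10, seed = 7))
#' sim$expr
#' @export
simulate_bulk <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  if (cf$targets_per_tf > cf$n_genes)
    stop("targets_per_tf exceeds the number of non-TF genes")
  with_preserved_seed(cf$seed, {
    gene_ids <- c(cf$tf_ids, sprintf("g%05d", seq_len(cf$n_genes)))
    G <- length(gene_ids)
    A <- length(cf$times)
    nc <- A - 1
    steps <- matrix(0, G, nc, dimnames = list(gene_ids, NULL))

    mag <- function(n) abs(stats::rnorm(n, cf$driver_effect, cf$step_sd))
    rsign <- function(n) sample(c(-1, 1), n, replace = TRUE)

    # TF trajectories
    driver_sign <- function() {
      base <- if (cf$driver_shape == "down") -1 else 1
      s <- rep(base, nc)
      if (cf$driver_shape == "up-down")
        s[(floor(nc / 2) + 1):nc] <- -1
      s
    }
    for (tf in cf$tf_ids) {
      steps[tf, ] <- if (tf %in% cf$driver_ids)
        driver_sign() * cf$driver_effect
      else rsign(nc) * mag(nc)
    }

    # background changers among non-TF genes (may be overwritten below)
    pool <- setdiff(gene_ids, cf$tf_ids)
    changer <- pool[stats::runif(length(pool)) < cf$de_fraction]
    if (length(changer))
      steps[changer, ] <- rsign(length(changer) * nc) *
        mag(length(changer) * nc)

    # targets: background TFs first, drivers last
    targets <- lapply(stats::setNames(cf$tf_ids, cf$tf_ids), function(tf)
      sample(pool, cf$targets_per_tf))
    order_tfs <- c(setdiff(cf$tf_ids, cf$driver_ids), cf$driver_ids)
    for (tf in order_tfs) {
      p <- if (tf %in% cf$driver_ids) cf$p_coh else cf$background_coh
      tg <- targets[[tf]]
      n <- length(tg) * nc
      match_sign <- stats::runif(n) < p
      tf_sign <- matrix(sign(steps[tf, ]), length(tg), nc, byrow = TRUE)
      sgn <- ifelse(match_sign, tf_sign, -tf_sign)
      steps[tg, ] <- sgn * mag(n)
    }

    # row-wise cumulative sums: cums[, j] = sum of steps up to contrast j
    cums <- steps %*% (outer(seq_len(nc), seq_len(nc), "<=") * 1)
    means <- cbind(0, cums) + stats::rnorm(G, 8, 1.5)
    values <- means[, rep(seq_len(A), each = cf$n_replicates)] +
      stats::rnorm(G * A * cf$n_replicates, 0, cf$noise_sd)
    colnames(values) <- sprintf("t%s_r%d",
                                rep(cf$times, each = cf$n_replicates),
                                rep(seq_len(cf$n_replicates), A))
    rownames(values) <- gene_ids

    expr <- expression_ts(values,
                          sample_time = rep(cf$times, each = cf$n_replicates),
                          check_scale = FALSE)
    edges <- data.frame(tf = rep(cf$tf_ids, each = cf$targets_per_tf),
                        gene = unlist(targets, use.names = FALSE),
                        source = "supplied", stringsAsFactors = FALSE)
    de <- (steps != 0) * 1
    list(expr = expr, graph = binding_graph(edges),
         truth = list(steps = steps, de = de,
                      driver_ids = cf$driver_ids, config = cf))
  })
}

#' Simulate a single-cell expression matrix with planted TF targets
#'
#' Cells are drawn per time point; the TF's per-cell level is lognormal
#' with a location that shifts upward over time. True target genes are
#' lognormal with location shifted by `sc_effect * (tertile - 2)` of the
#' TF's empirical tertile in that cell, so their levels track the TF's;
#' null genes are independent lognormals. Dropout zeros are injected
#' uniformly at rate `dropout`.
#'
#' @param config A [sim_config()]; uses `cells_per_time`, `times`,
#'   `n_genes`, `targets_per_tf`, `sc_effect`, `dropout`, `seed`.
#' @return List with `sc` (cells x genes matrix, TF in column `"TF01"`),
#'   `time` (per-cell labels), `targets` (true target gene ids), `config`.
#' @export
simulate_cells <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_preserved_seed(cf$seed + 1L, {
    n_cells <- cf$cells_per_time * length(cf$times)
    time <- rep(cf$times, each = cf$cells_per_time)
    mu_t <- 1 + 0.4 * (match(time, cf$times) - 1)
    tf_vals <- exp(stats::rnorm(n_cells, mu_t, 0.5))

    tert <- as.integer(quantile_group(tf_vals))  # 1/2/3 over all cells
    n_tg <- min(cf$targets_per_tf, cf$n_genes)
    gene_ids <- sprintf("g%05d", seq_len(cf$n_genes))
    m <- matrix(0, n_cells, cf$n_genes,
                dimnames = list(sprintf("cell%03d", seq_len(n_cells)),
                                gene_ids))
    shift <- cf$sc_effect * (tert - 2)
    for (j in seq_len(cf$n_genes)) {
      mu <- if (j <= n_tg) 2 + shift else 2
      m[, j] <- exp(stats::rnorm(n_cells, mu, 1))
    }
    if (cf$dropout > 0)
      m[stats::runif(length(m)) < cf$dropout] <- 0
    sc <- cbind(TF01 = tf_vals, m)
    list(sc = sc, time = time, targets = gene_ids[seq_len(n_tg)],
         config = cf)
  })
}
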