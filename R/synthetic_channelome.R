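#' Configuration of the synthetic channelome generator
#'
#' Describes an RNA-seq-style FPKM table with two groups of replicates:
#' a log-normal baseline per gene, multiplicative (log2) treatment
#' effects, replicate-level log-normal noise, random detection dropout
#' (point mass at zero), and two structural classes of channel genes that
#' are switched entirely off in one group ("appeared" = absent in
#' control, "disappeared" = absent in treated). Defaults emulate a
#' 4 + 4 replicate design with 190 channel genes among 2000, 20 appeared
#' and 7 disappeared channel genes, the scale of the study this package
#' models.
#'
#' @param n_genes total genes, >= `n_channel_genes`.
#' @param n_channel_genes channel genes, taken from the head of
#'   [channel_gene_list()].
#' @param n_control,n_treated replicates per group.
#' @param baseline_meanlog,baseline_sdlog natural-log mean/sd of the
#'   per-gene baseline FPKM.
#' @param rep_sdlog natural-log sd of replicate noise within a group.
#' @param log2_effects optional numeric vector (length `n_genes`, or
#'   named by gene id) of per-gene treatment effects in log2 units;
#'   default all zero.
#' @param dropout_prob probability in \[0, 1\] that any single
#'   measurement drops to zero.
#' @param n_appeared,n_disappeared channel genes forced all-zero in
#'   control / in treated.
#' @param seed master RNG seed.
#' @return An object of class `channelome_config`.
#' @export
channelome_config <- function(n_genes = 2000, n_channel_genes = 190,
                              n_control = 4, n_treated = 4,
                              baseline_meanlog = log(20),
                              baseline_sdlog = 1.5,
                              rep_sdlog = 0.3,
                              log2_effects = NULL,
                              dropout_prob = 0.02,
                              n_appeared = 20, n_disappeared = 7,
                              seed = 1L) {
  if (n_channel_genes > n_genes) stopf("n_channel_genes must be <= n_genes")
  if (dropout_prob < 0 || dropout_prob > 1)
    stopf("dropout_prob must lie in [0, 1]")
  if (n_appeared + n_disappeared > n_channel_genes)
    stopf("appeared + disappeared genes exceed the channel gene count")
  if (n_control < 2 || n_treated < 2) stopf("need >= 2 replicates per group")
  structure(as.list(environment()), class = "channelome_config")
}

#' Generate a synthetic channelome FPKM table
#'
#' Draws the table described by a [channelome_config()] together with its
#' ground truth. Channel genes use real symbols from the curated list so
#' that [filter_channel_genes()] recovers exactly `n_channel_genes` rows;
#' filler genes are labelled `GENE<k>`. The first `n_appeared` channel
#' genes (after those, `n_disappeared`) are forced to zero in all control
#' (treated) replicates, mirroring appeared/disappeared classification
#' structurally.
#'
#' @param config a [channelome_config()].
#' @return list with `table` (a `channelome_table`) and `truth`
#'   (data.frame: `gene`, `is_channel`, `log2_effect`, `zero_in_control`,
#'   `zero_in_treated`).
#' @export
gen_channelome_table <- function(config) {
  if (!inherits(config, "channelome_config"))
    stopf("config must be a channelome_config")
  ng <- config$n_genes
  chan <- channel_gene_list()$symbol
  if (config$n_channel_genes > length(chan))
    stopf("curated list has only %d symbols", length(chan))
  genes <- c(chan[seq_len(config$n_channel_genes)],
             sprintf("GENE%05d", seq_len(ng - config$n_channel_genes)))
  eff <- rep(0, ng)
  if (!is.null(config$log2_effects)) {
    le <- config$log2_effects
    if (!is.null(names(le))) {
      idx <- match(names(le), genes)
      if (anyNA(idx)) stopf("log2_effects names not in gene set")
      eff[idx] <- as.numeric(le)
    } else {
      if (length(le) != ng)
        stopf("log2_effects must have length n_genes or be named")
      eff <- as.numeric(le)
    }
  }
  zero_c <- seq_len(ng) <= config$n_appeared
  zero_t <- seq_len(ng) > config$n_appeared &
    seq_len(ng) <= config$n_appeared + config$n_disappeared
  nc <- config$n_control; nt <- config$n_treated
  fpkm <- with_seed(config$seed, {
    base <- stats::rnorm(ng, config$baseline_meanlog, config$baseline_sdlog)
    mc <- matrix(exp(base + stats::rnorm(ng * nc, 0, config$rep_sdlog)),
                 nrow = ng)
    mt <- matrix(exp(base + log(2) * eff +
                       stats::rnorm(ng * nt, 0, config$rep_sdlog)),
                 nrow = ng)
    if (config$dropout_prob > 0) {
      mc[matrix(stats::runif(ng * nc) < config$dropout_prob,
                nrow = ng)] <- 0
      mt[matrix(stats::runif(ng * nt) < config$dropout_prob,
                nrow = ng)] <- 0
    }
    mc[zero_c, ] <- 0
    mt[zero_t, ] <- 0
    m <- cbind(mc, mt)
    rownames(m) <- genes
    colnames(m) <- c(sprintf("control_%d", seq_len(nc)),
                     sprintf("treated_%d", seq_len(nt)))
    m
  })
  groups <- structure(rep(c("control", "treated"), c(nc, nt)),
                      names = colnames(fpkm))
  list(table = as_channelome_table(fpkm, groups),
       truth = data.frame(
         gene = genes,
         is_channel = seq_len(ng) <= config$n_channel_genes,
         log2_effect = eff,
         zero_in_control = zero_c,
         zero_in_treated = zero_t,
         stringsAsFactors = FALSE))
}
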