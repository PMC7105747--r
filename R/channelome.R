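#' Construct a channelome expression table
#'
#' Wraps a gene x sample FPKM matrix with group assignments. Gene ids
#' must be unique; every sample must belong to exactly one group; FPKM
#' values must be finite and non-negative.
#'
#' @param fpkm numeric matrix, rows = genes (rownames = ids), columns =
#'   samples (colnames = sample labels).
#' @param groups named character vector mapping each sample label to its
#'   group.
#' @return An object of class `channelome_table`: list with `fpkm`,
#'   `genes`, `samples`, `groups`.
#' @export
as_channelome_table <- function(fpkm, groups) {
  fpkm <- as.matrix(fpkm)
  if (is.null(colnames(fpkm)) ||
      (nrow(fpkm) > 0 && is.null(rownames(fpkm))))
    stopf("fpkm matrix needs gene rownames and sample colnames")
  if (nrow(fpkm) == 0 && is.null(rownames(fpkm)))
    rownames(fpkm) <- character(0)
  dup <- rownames(fpkm)[duplicated(rownames(fpkm))]
  if (length(dup))
    stopf("duplicate gene ids: %s", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(fpkm) | fpkm < 0, arr.ind = TRUE)
  if (nrow(bad))
    stopf("negative or non-numeric FPKM at gene '%s', sample '%s'",
          rownames(fpkm)[bad[1, 1]], colnames(fpkm)[bad[1, 2]])
  missing <- setdiff(colnames(fpkm), names(groups))
  if (length(missing))
    stopf("samples without group assignment: %s",
          paste(missing, collapse = ", "))
  groups <- groups[colnames(fpkm)]
  structure(
    list(fpkm = fpkm, genes = rownames(fpkm), samples = colnames(fpkm),
         groups = groups),
    class = "channelome_table")
}

#' @export
print.channelome_table <- function(x, ...) {
  cat(sprintf("<channelome_table> %d genes x %d samples (%s)\n",
              length(x$genes), length(x$samples),
              paste(sprintf("%s n=%d", names(table(x$groups)),
                            table(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Read a gene-level FPKM table
#'
#' Reads a TSV/CSV file whose first column is `gene_id` followed by one
#' numeric column per sample. Group membership is taken from `group_map`,
#' or parsed from column names of the form `<group>_<replicate>` when
#' `group_map` is `NULL`.
#'
#' @param path file path; comma-separated if the extension is `.csv`,
#'   tab-separated otherwise.
#' @param group_map optional named character vector sample -> group.
#' @return a [as_channelome_table()] object.
#' @export
read_fpkm_table <- function(path, group_map = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "gene_id")
    stopf("expected a gene_id column followed by sample columns")
  for (j in 2:ncol(df))
    if (!is.numeric(df[[j]]))
      stopf("sample column '%s' is not numeric", names(df)[j])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (is.null(group_map)) {
    g <- sub("_[^_]*$", "", colnames(m))
    group_map <- structure(g, names = colnames(m))
  }
  as_channelome_table(m, group_map)
}

#' Write a channelome table as TSV
#'
#' Inverse of [read_fpkm_table()]: `gene_id` column plus one column per
#' sample.
#'
#' @param table a `channelome_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fpkm_table <- function(table, path) {
  df <- data.frame(gene_id = table$genes, table$fpkm,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Curated ion-channel gene list
#'
#' The channel-gene list shipped with the package: pore-forming and
#' auxiliary subunits (alpha to epsilon) of the major channel families,
#' plus connexins, pannexins and porins (VDACs, aquaporins); channel-
#' interacting and regulatory proteins are excluded. The list is an
#' independently curated resource and can be replaced by any two-column
#' (symbol, family) TSV.
#'
#' @param path optional path to an alternative list.
#' @return data.frame with columns `symbol`, `family`.
#' @export
channel_gene_list <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "channel_genes.tsv",
                        package = "flsephys", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("symbol", "family") %in% names(df)))
    stopf("gene list needs 'symbol' and 'family' columns")
  if (nrow(df) == 0) stopf("gene list is empty")
  dup <- duplicated(tolower(df$symbol))
  if (any(dup))
    stopf("duplicate symbols in gene list: %s",
          paste(df$symbol[dup], collapse = ", "))
  df
}

# Strip transcript suffixes such as "-201" or ".3" from a gene/transcript
# id and lower-case it for matching.
normalize_symbol <- function(id) {
  tolower(sub("([._-][0-9]+)+$", "", id))
}

#' Filter an expression table to ion-channel genes
#'
#' Keeps rows whose symbol, after case normalisation and stripping of
#' transcript suffixes (e.g. `Kcnma1-203` -> `kcnma1`), appears in the
#' curated channel list. Row order is preserved. An empty intersection
#' produces a warning and an empty table, not an error.
#'
#' @param table a `channelome_table`.
#' @param genelist a data.frame as returned by [channel_gene_list()].
#' @return a filtered `channelome_table` with attribute `n_channel`.
#' @export
filter_channel_genes <- function(table, genelist = channel_gene_list()) {
  if (!inherits(table, "channelome_table"))
    stopf("table must be a channelome_table")
  keep <- normalize_symbol(table$genes) %in% tolower(genelist$symbol)
  if (!any(keep))
    warning("no channel genes found in the table", call. = FALSE)
  out <- as_channelome_table(table$fpkm[keep, , drop = FALSE],
                             table$groups)
  attr(out, "n_channel") <- sum(keep)
  out
}

#' Log2 expression ratio with confidence interval
#'
#' Point estimate `log2((mean_t + eps)/(mean_c + eps))` with a small
#' pseudocount for stability near zero. Confidence intervals by either a
#' bias-corrected bootstrap over replicates (resampling each group with
#' replacement, default 2000 resamples, seeded) or a Welch t-interval on
#' per-replicate `log2(FPKM + eps)` values.
#'
#' @param control,treated per-replicate FPKM vectors (length >= 2 for a
#'   CI).
#' @param method `"bootstrap"` or `"t"`.
#' @param pseudocount FPKM pseudocount `eps`.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap (`NULL`: current stream).
#' @return list with `mean_control`, `mean_treated`, `log2_ratio`,
#'   `ci_lo`, `ci_hi`, `method`. If both groups are entirely zero the
#'   ratio and CI are `NA` (status "undetected" downstream).
#' @export
log2_ratio_ci <- function(control, treated,
                          method = c("bootstrap", "t"),
                          pseudocount = 0.05, n_boot = 2000,
                          conf = 0.95, seed = NULL) {
  method <- match.arg(method)
  mc <- mean(control); mt <- mean(treated)
  if (all(control == 0) && all(treated == 0))
    return(list(mean_control = 0, mean_treated = 0,
                log2_ratio = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                method = method))
  est <- log2((mt + pseudocount) / (mc + pseudocount))
  nc <- length(control); nt <- length(treated)
  if (nc < 2 || nt < 2)
    return(list(mean_control = mc, mean_treated = mt, log2_ratio = est,
                ci_lo = NA_real_, ci_hi = NA_real_, method = method))
  alpha <- 1 - conf
  if (method == "bootstrap") {
    boots <- with_seed(seed, {
      ic <- matrix(sample.int(nc, nc * n_boot, replace = TRUE), ncol = n_boot)
      it <- matrix(sample.int(nt, nt * n_boot, replace = TRUE), ncol = n_boot)
      log2((colMeans(matrix(treated[it], ncol = n_boot)) + pseudocount) /
             (colMeans(matrix(control[ic], ncol = n_boot)) + pseudocount))
    })
    # bias-corrected percentile interval
    prop <- mean(boots < est) + 0.5 * mean(boots == est)
    z0 <- stats::qnorm(min(max(prop, 1 / n_boot), 1 - 1 / n_boot))
    zl <- stats::qnorm(alpha / 2); zu <- stats::qnorm(1 - alpha / 2)
    ci <- stats::quantile(boots,
                          c(stats::pnorm(2 * z0 + zl),
                            stats::pnorm(2 * z0 + zu)),
                          names = FALSE, type = 7)
  } else {
    lc <- log2(control + pseudocount); lt <- log2(treated + pseudocount)
    if (stats::sd(lc) == 0 && stats::sd(lt) == 0) {
      d <- mean(lt) - mean(lc)
      ci <- c(d, d)
    } else {
      tt <- stats::t.test(lt, lc, conf.level = conf, var.equal = FALSE)
      ci <- as.numeric(tt$conf.int)
    }
  }
  list(mean_control = mc, mean_treated = mt, log2_ratio = est,
       ci_lo = ci[1], ci_hi = ci[2], method = method)
}

#' Detection rule for one group of replicates
#'
#' A gene counts as detected in a group when its mean FPKM exceeds
#' `min_mean_fpkm` and it is non-zero in at least half of the replicates
#' (`ceiling(n/2)`). This single rule controls the appeared/disappeared
#' classification.
#'
#' @param x per-replicate FPKM vector.
#' @param min_mean_fpkm detection threshold on the group mean.
#' @param min_frac fraction of replicates required non-zero.
#' @return logical.
#' @export
is_detected <- function(x, min_mean_fpkm = 0.1, min_frac = 0.5) {
  mean(x) > min_mean_fpkm && sum(x > 0) >= ceiling(min_frac * length(x))
}

#' Classify a gene's expression change
#'
#' Applies the detection rule to both groups, then:
#' \itemize{
#'   \item detected in neither -> `"undetected"`;
#'   \item detected only in treated -> `"appeared"`;
#'   \item detected only in control -> `"disappeared"`;
#'   \item detected in both -> `"up"` / `"down"` when the log2 ratio
#'     reaches `+cutoff` / `-cutoff`, else `"unchanged"`.
#' }
#'
#' @param control,treated per-replicate FPKM vectors.
#' @param log2_ratio precomputed log2 ratio; computed with the default
#'   pseudocount when `NULL`.
#' @param cutoff log2 threshold for up/down.
#' @param min_mean_fpkm,min_frac detection rule, see [is_detected()].
#' @param pseudocount used when `log2_ratio` is `NULL`.
#' @return one of `"up"`, `"down"`, `"unchanged"`, `"appeared"`,
#'   `"disappeared"`, `"undetected"`.
#' @export
classify_expression <- function(control, treated, log2_ratio = NULL,
                                cutoff = 1.5, min_mean_fpkm = 0.1,
                                min_frac = 0.5, pseudocount = 0.05) {
  dc <- is_detected(control, min_mean_fpkm, min_frac)
  dt <- is_detected(treated, min_mean_fpkm, min_frac)
  if (!dc && !dt) return("undetected")
  if (!dc && dt) return("appeared")
  if (dc && !dt) return("disappeared")
  if (is.null(log2_ratio))
    log2_ratio <- log2((mean(treated) + pseudocount) /
                         (mean(control) + pseudocount))
  if (log2_ratio >= cutoff) return("up")
  if (log2_ratio <= -cutoff) return("down")
  "unchanged"
}

#' Differential expression table for a channelome
#'
#' Runs [log2_ratio_ci()] and [classify_expression()] on every gene of a
#' two-group table. The log2 ratio is reported only for genes detected in
#' both groups.
#'
#' @param table a `channelome_table` with exactly two groups.
#' @param control_group,treated_group group labels; default: the first
#'   and second group in order of appearance.
#' @param cutoff log2 threshold for up/down.
#' @param method CI method, see [log2_ratio_ci()].
#' @param n_boot,conf,pseudocount,min_mean_fpkm,min_frac see
#'   [log2_ratio_ci()] and [is_detected()].
#' @param seed master seed for the per-gene bootstrap CIs.
#' @return data.frame with columns `gene`, `mean_control`,
#'   `mean_treated`, `detected_control`, `detected_treated`,
#'   `log2_ratio`, `ci_lo`, `ci_hi`, `status`.
#' @export
diff_expr_table <- function(table, control_group = NULL,
                            treated_group = NULL, cutoff = 1.5,
                            method = c("bootstrap", "t"), n_boot = 2000,
                            conf = 0.95, pseudocount = 0.05,
                            min_mean_fpkm = 0.1, min_frac = 0.5,
                            seed = NULL) {
  method <- match.arg(method)
  if (!inherits(table, "channelome_table"))
    stopf("table must be a channelome_table")
  glev <- unique(table$groups)
  if (is.null(control_group)) control_group <- glev[1]
  if (is.null(treated_group)) treated_group <- glev[2]
  if (!all(c(control_group, treated_group) %in% glev))
    stopf("groups '%s'/'%s' not found in table", control_group,
          treated_group)
  ic <- table$groups == control_group
  it <- table$groups == treated_group
  seeds <- if (is.null(seed)) rep(list(NULL), length(table$genes))
  else with_seed(seed,
                 as.list(sample.int(.Machine$integer.max,
                                    length(table$genes))))
  rows <- lapply(seq_along(table$genes), function(i) {
    ctrl <- table$fpkm[i, ic]; trt <- table$fpkm[i, it]
    dc <- is_detected(ctrl, min_mean_fpkm, min_frac)
    dt <- is_detected(trt, min_mean_fpkm, min_frac)
    both <- dc && dt
    r <- if (both)
      log2_ratio_ci(ctrl, trt, method = method, pseudocount = pseudocount,
                    n_boot = n_boot, conf = conf, seed = seeds[[i]])
    else list(mean_control = mean(ctrl), mean_treated = mean(trt),
              log2_ratio = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
    status <- classify_expression(ctrl, trt,
                                  log2_ratio = r$log2_ratio,
                                  cutoff = cutoff,
                                  min_mean_fpkm = min_mean_fpkm,
                                  min_frac = min_frac,
                                  pseudocount = pseudocount)
    data.frame(gene = table$genes[i], mean_control = r$mean_control,
               mean_treated = r$mean_treated, detected_control = dc,
               detected_treated = dt, log2_ratio = r$log2_ratio,
               ci_lo = r$ci_lo, ci_hi = r$ci_hi, status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Threshold filter on log2 ratios
#'
#' Splits records with defined log2 ratios into down-regulated
#' (`ratio <= -cutoff`) and up-regulated (`ratio >= +cutoff`) lists, each
#' sorted by absolute ratio, largest first. At the conventional cutoff of
#' 1.5 log2 units this is the filter behind the published
#' channel-gene tables.
#'
#' @param records data.frame with columns `gene` and `log2_ratio` (rows
#'   with `NA` ratios are ignored).
#' @param cutoff log2 threshold, >= 0.
#' @return list with data.frames `down` and `up`.
#' @export
threshold_filter <- function(records, cutoff = 1.5) {
  if (cutoff < 0) stopf("cutoff must be >= 0")
  ok <- records[!is.na(records$log2_ratio), , drop = FALSE]
  down <- ok[ok$log2_ratio <= -cutoff, , drop = FALSE]
  up <- ok[ok$log2_ratio >= cutoff, , drop = FALSE]
  if (cutoff == 0) {
    # sign partition: put exact zeros in neither list twice
    up <- ok[ok$log2_ratio >= 0, , drop = FALSE]
    down <- ok[ok$log2_ratio < 0, , drop = FALSE]
  }
  list(down = down[order(-abs(down$log2_ratio)), , drop = FALSE],
       up = up[order(-abs(up$log2_ratio)), , drop = FALSE])
}

#' Published channel-gene differential expression values
#'
#' The 36 per-gene log2 ratios (with 95% CIs) of channel genes reported
#' as decreased or increased after 72 h cytokine (TNF-alpha + IL-1beta)
#' treatment, transcribed from the published tables: 15 down-regulated
#' and 21 up-regulated at the +/-1.5 log2 threshold.
#'
#' @return data.frame with columns `gene`, `direction`, `log2_ratio`,
#'   `ci_lo`, `ci_hi`.
#' @export
cytokine_response_tables <- function() {
  path <- system.file("extdata", "cytokine_channel_log2.tsv",
                      package = "flsephys", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' qPCR relative expression helpers
#'
#' `delta_ct` computes expression relative to a housekeeping gene,
#' `dCt = Ct_gene - Ct_housekeeper` (for FLS panels the housekeeper is
#' Rplp1). `ddct` compares conditions: `ddCt = dCt_treated - dCt_control`
#' and `fold = 2^(-ddCt)`.
#'
#' @param ct_gene,ct_housekeeper threshold cycles of target and
#'   housekeeping gene.
#' @return `delta_ct`: dCt value(s).
#' @examples
#' delta_ct(25, 20)      # 5
#' ddct(4, 5)$fold_change  # 2
#' @export
delta_ct <- function(ct_gene, ct_housekeeper) {
  if (any(!is.finite(c(ct_gene, ct_housekeeper))))
    stopf("Ct values must be finite")
  ct_gene - ct_housekeeper
}

#' @rdname delta_ct
#' @param dct_treated,dct_control dCt values of the two conditions.
#' @return `ddct`: list with `ddct` and `fold_change`.
#' @export
ddct <- function(dct_treated, dct_control) {
  if (any(!is.finite(c(dct_treated, dct_control))))
    stopf("dCt values must be finite")
  d <- dct_treated - dct_control
  list(ddct = d, fold_change = 2^(-d))
}
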