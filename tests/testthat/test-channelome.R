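make_table <- function(fpkm_list, n_control = 4, n_treated = 4) {
  m <- do.call(rbind, fpkm_list)
  colnames(m) <- c(sprintf("control_%d", seq_len(n_control)),
                   sprintf("treated_%d", seq_len(n_treated)))
  groups <- structure(rep(c("control", "treated"),
                          c(n_control, n_treated)),
                      names = colnames(m))
  as_channelome_table(m, groups)
}

test_that("channelome table validation catches bad input", {
  m <- matrix(1, 2, 2, dimnames = list(c("A", "A"), c("s1", "s2")))
  expect_error(as_channelome_table(m, c(s1 = "a", s2 = "b")), "duplicate")
  m2 <- matrix(c(1, -2, 3, 4), 2, 2,
               dimnames = list(c("A", "B"), c("s1", "s2")))
  err <- tryCatch(as_channelome_table(m2, c(s1 = "a", s2 = "b")),
                  error = conditionMessage)
  expect_match(err, "B")
  expect_match(err, "s1")
  m2[2, 1] <- 2
  expect_error(as_channelome_table(m2, c(s1 = "a")), "without group")
})

test_that("filter_channel_genes matches case-insensitively with suffix stripping", {
  tab <- make_table(list(Kcnma1 = rep(5, 8), Actb = rep(100, 8),
                         Trpv4 = rep(2, 8)))
  gl <- data.frame(symbol = c("Kcnma1", "Trpv4"), family = c("KCa", "TRP"))
  out <- filter_channel_genes(tab, gl)
  expect_equal(out$genes, c("Kcnma1", "Trpv4"))
  expect_equal(attr(out, "n_channel"), 2)

  # transcript ids map to their parent symbol
  tab2 <- make_table(list(`KCNMA1-203` = rep(5, 8), `Trpv4.2` = rep(1, 8),
                          GENE1 = rep(1, 8)))
  expect_equal(filter_channel_genes(tab2, gl)$genes,
               c("KCNMA1-203", "Trpv4.2"))

  # the curated list filtered against itself is the identity
  full <- channel_gene_list()
  self_tab <- make_table(stats::setNames(
    rep(list(rep(1, 8)), nrow(full)), full$symbol))
  expect_equal(filter_channel_genes(self_tab)$genes, full$symbol)

  none <- make_table(list(Actb = rep(1, 8)))
  expect_warning(empty <- filter_channel_genes(none, gl), "no channel")
  expect_length(empty$genes, 0)
})

test_that("configured channel-gene count is recovered exactly after filtering", {
  out <- gen_channelome_table(channelome_config(n_genes = 500,
                                                n_channel_genes = 190,
                                                seed = 4))
  expect_equal(attr(filter_channel_genes(out$table), "n_channel"), 190)
})

test_that("log2 ratio point estimates and degenerate cases", {
  r <- log2_ratio_ci(c(10, 10, 10, 10), c(40, 40, 40, 40), method = "t")
  expect_equal(r$log2_ratio, log2(40.05 / 10.05))  # pseudocount 0.05
  expect_lt(abs(r$log2_ratio - 2), 0.01)

  same <- log2_ratio_ci(c(5, 6, 7, 8), c(8, 7, 6, 5), method = "t")
  expect_equal(same$log2_ratio, 0)

  undet <- log2_ratio_ci(rep(0, 4), rep(0, 4))
  expect_true(is.na(undet$log2_ratio))
})

test_that("bootstrap CIs are seeded and antisymmetric under group swap", {
  set.seed(10)
  a <- rlnorm(4, log(20), 0.3); b <- rlnorm(4, log(80), 0.3)
  r1 <- log2_ratio_ci(a, b, seed = 5)
  r2 <- log2_ratio_ci(a, b, seed = 5)
  expect_identical(r1, r2)
  swap <- log2_ratio_ci(b, a, seed = 5)
  expect_equal(swap$log2_ratio, -r1$log2_ratio, tolerance = 1e-12)
  # mirrored interval within bootstrap noise at fixed resamples
  expect_equal(swap$ci_lo, -r1$ci_hi, tolerance = 0.15)
  expect_equal(swap$ci_hi, -r1$ci_lo, tolerance = 0.15)
  expect_true(r1$ci_lo <= r1$ci_hi)
})

test_that("classification: appeared/disappeared/up/down and group-swap duality", {
  expect_equal(classify_expression(rep(0, 4), c(5, 6, 4, 5)), "appeared")
  expect_equal(classify_expression(c(5, 6, 4, 5), rep(0, 4)), "disappeared")
  expect_equal(classify_expression(rep(2, 4), rep(2 * 2^2.3, 4)), "up")
  expect_equal(classify_expression(rep(2 * 2^2.3, 4), rep(2, 4)), "down")
  expect_equal(classify_expression(rep(2, 4), rep(2.5, 4)), "unchanged")
  expect_equal(classify_expression(rep(0, 4), rep(0, 4)), "undetected")
  # detection needs non-zero in at least half the replicates
  expect_equal(classify_expression(rep(0, 4), c(80, 0, 0, 0)), "undetected")

  swap_map <- c(appeared = "disappeared", disappeared = "appeared")
  for (x in list(list(rep(0, 4), c(5, 6, 4, 5)),
                 list(c(1, 2, 1, 2), rep(0, 4)))) {
    s1 <- classify_expression(x[[1]], x[[2]])
    s2 <- classify_expression(x[[2]], x[[1]])
    if (s1 %in% names(swap_map)) expect_equal(s2, unname(swap_map[s1]))
  }
})

test_that("forced treated-only genes are classified appeared, exactly", {
  cfg <- channelome_config(n_genes = 400, n_channel_genes = 100,
                           n_appeared = 20, n_disappeared = 7, seed = 12)
  out <- gen_channelome_table(cfg)
  de <- diff_expr_table(out$table, method = "t")
  expect_equal(sum(de$status == "appeared"), 20)
  expect_equal(sum(de$status == "disappeared"), 7)
  expect_equal(de$gene[de$status == "appeared"],
               out$truth$gene[out$truth$zero_in_control])
  # log2 ratio undefined when a group is undetected
  expect_true(all(is.na(de$log2_ratio[de$status %in%
                                        c("appeared", "disappeared")])))
})

test_that("threshold filter reproduces the published 15 down / 21 up split", {
  printed <- cytokine_response_tables()
  expect_equal(nrow(printed), 36)
  split <- threshold_filter(printed, cutoff = 1.5)
  expect_equal(nrow(split$down), 15)
  expect_equal(nrow(split$up), 21)
  expect_equal(sort(split$down$gene),
               sort(printed$gene[printed$direction == "down"]))
  # sorted by |ratio| descending
  expect_equal(split$up$log2_ratio[1], 4.32)
  expect_equal(split$down$log2_ratio[1], -5.51)

  expect_equal(nrow(threshold_filter(printed, 10)$up), 0)
  expect_equal(nrow(threshold_filter(printed, 10)$down), 0)
  by_sign <- threshold_filter(printed, 0)
  expect_equal(nrow(by_sign$up) + nrow(by_sign$down), 36)
  # disjoint and exhaustive over records passing the cutoff
  expect_length(intersect(split$up$gene, split$down$gene), 0)
  expect_setequal(c(split$up$gene, split$down$gene),
                  printed$gene[abs(printed$log2_ratio) >= 1.5])
})

test_that("genes with |log2 effect| >= 2 are recovered with sensitivity >= 0.9", {
  eff <- rep(0, 2000)
  eff[101:150] <- 2          # 50 true positives among 2000 genes
  cfg <- channelome_config(n_genes = 2000, n_channel_genes = 190,
                           log2_effects = eff, seed = 77)
  out <- gen_channelome_table(cfg)
  de <- diff_expr_table(out$table, method = "t")
  called_up <- de$gene[!is.na(de$log2_ratio) & de$log2_ratio >= 1.5]
  truth_up <- out$truth$gene[out$truth$log2_effect >= 2 &
                               !out$truth$zero_in_control &
                               !out$truth$zero_in_treated]
  hits <- length(intersect(called_up, truth_up))
  expect_gte(hits, 45)
})

test_that("qPCR helpers: delta Ct, delta-delta Ct and fold change", {
  expect_equal(delta_ct(25, 20), 5)
  expect_equal(ddct(4, 5)$ddct, -1)
  expect_equal(ddct(4, 5)$fold_change, 2)
  expect_equal(ddct(5, 5)$fold_change, 1)
  expect_error(delta_ct(Inf, 20), "finite")
})
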