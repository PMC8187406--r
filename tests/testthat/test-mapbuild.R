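human_expr_fixture <- function(genes, expressed = genes) {
  m <- matrix(1, length(genes), 2,
              dimnames = list(genes, c("placenta", "brain")))
  m[setdiff(genes, expressed), "placenta"] <- 0
  m
}

test_that("stream integration records evidence streams and the shared split", {
  streams <- list(cells = c("m1", "m2", "m3"), media = c("m1", "m4"),
                  sorted = c("m1"))
  pairs <- data.frame(mouse_gene = c("m1", "m2"), human_gene = c("H1", "H2"))
  hx <- human_expr_fixture(c("H1", "H2"), expressed = "H1")
  entries <- integrate_streams(streams, pairs, hx)
  expect_equal(nrow(entries), 4)  # |A u B u C| by inclusion-exclusion
  e1 <- entries[entries$mouse_gene == "m1", ]
  expect_equal(e1$n_streams, 3)
  expect_equal(e1$streams, "cells,media,sorted")
  expect_true(e1$shared_with_human)
  # ortholog present but human expression zero -> mouse-only
  expect_false(entries$shared_with_human[entries$mouse_gene == "m2"])
  expect_false(entries$shared_with_human[entries$mouse_gene == "m4"])
})

test_that("venn counts match brute-force enumeration and conserve set sizes", {
  s <- list(a = c("x", "y"), b = c("x", "y"))
  v <- venn_counts(s)
  expect_equal(v$count[v$region == "a&b"], 2)
  expect_equal(sum(v$count[v$region != "a&b"]), 0)

  d <- list(a = "x", b = "y", c = "z")
  vd <- venn_counts(d)
  expect_equal(sum(vd$count), 3)
  expect_true(all(vd$count[!vd$region %in% c("a", "b", "c")] == 0))

  set.seed(21)
  for (rep in 1:5) {
    sets <- lapply(1:4, function(i) sample(sprintf("g%03d", 1:150), 100))
    names(sets) <- letters[1:4]
    v <- venn_counts(sets)
    oracle <- oracle_venn(sets)
    expect_equal(setNames(v$count, v$region)[names(oracle)], oracle)
    # region counts reproduce each set's cardinality
    for (nm in names(sets)) {
      expect_equal(sum(v$count[v[[nm]]]), length(unique(sets[[nm]])))
    }
  }
  expect_error(venn_counts(list(a = "x")), "2 to 5")
})

test_that("tissue enrichment uses the max comparator and the fold threshold", {
  expr <- rbind(g1 = c(100, 9, 5), g2 = c(0, 1, 1), g3 = c(50, 10, 2))
  colnames(expr) <- c("placenta", "brain", "liver")
  res <- tissue_enrichment(expr, rownames(expr), "placenta", fold = 10)
  expect_true(res$enriched[res$gene == "g1"])
  expect_equal(res$fold_value[res$gene == "g1"], 100 / 9)
  expect_false(res$enriched[res$gene == "g2"])  # zero target never enriched
  expect_false(res$enriched[res$gene == "g3"])  # 5-fold < threshold
  # monotone: raising the threshold never adds genes
  res20 <- tissue_enrichment(expr, rownames(expr), "placenta", fold = 20)
  expect_true(all(res20$gene[res20$enriched] %in% res$gene[res$enriched]))
  expect_error(tissue_enrichment(expr, "g1", "muscle"), "muscle")
})

test_that("planted tissue-enriched genes are recovered at the 10-fold threshold", {
  cfg <- sim_config(n_genes = 150, seed = 9)
  study <- generate_study(cfg, withr::local_tempdir())
  expr <- as.matrix(read.delim(study$paths[["mouse_expression"]],
                               row.names = 1))
  res <- tissue_enrichment(expr, rownames(expr), "placenta", fold = 10)
  expect_setequal(res$gene[res$enriched],
                  study$truth$true_tissue_enriched_mouse)
})

test_that("complication overlay flags entries and summarizes unique/shared genes", {
  entries <- data.frame(mouse_gene = c("m1", "m2", "m3"),
                        human_gene = c("H1", "H2", NA),
                        streams = "cells", n_streams = 1,
                        shared_with_human = c(TRUE, TRUE, FALSE))
  sets <- list(PE = c("H1"), GDM = c("H1", "H2"), IUGR = "H1",
               SGA = "H1", LGA = "H1")
  ov <- complication_overlay(entries, sets, k = 4)
  e <- ov$entries
  expect_equal(e$n_complications[e$mouse_gene == "m1"], 5)
  expect_equal(e$complications[e$mouse_gene == "m2"], "GDM")
  expect_true(e$unmatchable[e$mouse_gene == "m3"])
  expect_equal(e$n_complications[e$mouse_gene == "m3"], 0)
  expect_equal(ov$unique_to$GDM, "H2")
  expect_equal(ov$shared_core, "H1")
  expect_error(complication_overlay(entries, list(XYZ = "H1")), "XYZ")
})

test_that("over-representation p-values are exact hypergeometric tails", {
  universe <- sprintf("g%02d", 1:20)
  hits <- universe[1:5]
  # full-overlap extreme category: p = 1 / C(20, 5)
  res <- overrepresentation(hits, universe,
                            list(top = universe[1:5], all = universe))
  expect_equal(res$p[res$category == "top"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$p[res$category == "all"], 1)
  # BH q monotone in p-rank and >= p
  set.seed(4)
  cats <- lapply(1:10, function(i) sample(universe, 8))
  names(cats) <- paste0("c", 1:10)
  res2 <- overrepresentation(hits, universe, cats)
  expect_true(all(res2$q >= res2$p - 1e-15))
  expect_true(all(diff(res2$q) >= -1e-15))
  expect_error(overrepresentation(c(hits, "zz"), universe, cats),
               "subset")
})

test_that("hypergeometric p-values are calibrated under the null", {
  # an exact discrete test has super-uniform p-values: P(p <= a) <= a at
  # every level, approaching a as the support refines; assert the
  # rejection-rate curve stays in [a - slack, a]
  set.seed(77)
  universe <- sprintf("g%04d", 1:1000)
  hits <- sample(universe, 100)
  ps <- replicate(2000, {
    overrepresentation(hits, universe,
                       list(c = sample(universe, 200)))$p
  })
  atom <- max(dhyper(0:100, 200, 800, 100))  # largest possible p-value gap
  for (a in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    rate <- mean(ps <= a)
    # never anti-conservative; deficits bounded by the modal atom size
    expect_lte(rate, a + 2 * sqrt(a * (1 - a) / 2000))
    expect_gte(rate, a - atom - 2 * sqrt(a * (1 - a) / 2000))
  }
})
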