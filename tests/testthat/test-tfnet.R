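test_that("PWM construction validates shape and normalization", {
  good <- matrix(0.25, 4, 6)
  expect_s3_class(new_pwm("m", good), "pwm")
  expect_error(new_pwm("m", good[1:3, ]), "4 rows")
  expect_error(new_pwm("m", good[, 1:3]), ">= 4")
  counts <- matrix(c(8, 1, 1, 0), 4, 5)
  pwm <- new_pwm("m", counts, pseudocount = 0.5)
  expect_equal(colSums(pwm$mat), rep(1, 5))
})

test_that("the consensus sequence scores the column-max log-odds sum", {
  pwm <- random_pwm_fixture(6, seed = 1)
  cons <- pwm_consensus(pwm)
  flank <- "ACGTACGTAC"
  seq <- setNames(paste0(flank, cons, flank), "g1")
  hits <- scan_pwm(seq, pwm, pwm_max_score(pwm))
  top <- hits[hits$strand == "+", ]
  expect_equal(nrow(top[top$score >= pwm_max_score(pwm) - 1e-9, ]), 1)
  expect_equal(top$position[which.max(top$score)], nchar(flank))
  expect_equal(max(top$score), pwm_max_score(pwm), tolerance = 1e-12)
})

test_that("all-N and too-short sequences yield no hits", {
  pwm <- random_pwm_fixture(6, seed = 2)
  expect_equal(nrow(scan_pwm(c(g = strrep("N", 30)), pwm, -100)), 0)
  expect_warning(h <- scan_pwm(c(g = "ACG"), pwm, -100), "shorter")
  expect_equal(nrow(h), 0)
})

test_that("scanning matches position-by-position brute force on random promoters", {
  pwm <- random_pwm_fixture(6, seed = 3)
  thr <- 6
  proms <- random_promoters(20, 200, seed = 4)
  got <- scan_pwm(proms, pwm, thr)
  want <- oracle_scan(proms, pwm, thr)
  key <- function(df) {
    df <- df[order(df$gene, df$position, df$strand), ]
    paste(df$gene, df$position, df$strand, signif(df$score, 10))
  }
  expect_identical(key(got), key(want))
})

test_that("reverse-complementing a promoter preserves its hit count", {
  pwm <- random_pwm_fixture(8, seed = 5)
  proms <- random_promoters(10, 150, seed = 6)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  thr <- 0.5 * pwm_max_score(pwm)
  for (g in names(proms)) {
    n1 <- nrow(scan_pwm(proms[g], pwm, thr))
    n2 <- nrow(scan_pwm(setNames(rc(proms[[g]]), g), pwm, thr))
    expect_equal(n1, n2)
  }
})

test_that("motif enrichment reproduces closed-form Fisher extremes", {
  pwm <- random_pwm_fixture(8, seed = 7)
  cons <- pwm_consensus(pwm)
  pad <- function(n) random_promoters(n, 60, seed = n)
  fg <- pad(10)
  fg[] <- vapply(fg, function(s)
    paste0(substr(s, 1, 20), cons, substr(s, 29, 60)), character(1))
  bg <- pad(11)[1:10]
  names(bg) <- paste0("bg", 1:10)
  # resample any background promoter carrying a chance consensus match so
  # the table is exactly (10, 0; 0, 10)
  thr <- pwm_max_score(pwm) - 1e-9
  repeat {
    hit_genes <- unique(scan_pwm(bg, pwm, thr)$gene)
    if (length(hit_genes) == 0) break
    bg[hit_genes] <- vapply(hit_genes, function(g)
      paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
            collapse = ""), character(1))
  }
  res <- motif_enrichment(fg, bg, pwm, score_threshold = thr)
  expect_equal(res$fg_hits, 10)
  expect_equal(res$bg_hits, 0)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-10)
})

test_that("equal hit proportions give a Fisher p of 1", {
  pwm <- random_pwm_fixture(6, seed = 8)
  cons <- pwm_consensus(pwm)
  mk <- function(prefix) {
    out <- random_promoters(8, 40, seed = 9)
    names(out) <- paste0(prefix, 1:8)
    out[1:4] <- paste0(cons, substr(out[1:4], nchar(cons) + 1, 40))
    out
  }
  res <- motif_enrichment(mk("f"), mk("b"), pwm,
                          score_threshold = pwm_max_score(pwm) - 1e-9)
  expect_gte(res$p, 0.99)
})

test_that("enrichment rejects overlapping or empty promoter sets", {
  p <- random_promoters(4, 30, seed = 10)
  pwm <- random_pwm_fixture(6, seed = 10)
  expect_error(motif_enrichment(p, p, pwm), "disjoint")
  expect_error(motif_enrichment(p[0], p, pwm), "non-empty")
})

test_that("consensus keeps only TFs predicted by both sources, pooling targets", {
  a <- data.frame(tf = c("T1", "T1", "T2"), target = c("g1", "g2", "g3"))
  b <- data.frame(tf = c("T1", "T3"), target = c("g4", "g5"))
  res <- consensus_tfs(a, b)
  expect_setequal(unique(res$tf), "T1")
  expect_setequal(res$target, c("g1", "g2", "g4"))
  # brute-force intersection oracle on random tables
  set.seed(14)
  ra <- data.frame(tf = sample(paste0("T", 1:8), 30, TRUE),
                   target = sample(paste0("g", 1:20), 30, TRUE))
  rb <- data.frame(tf = sample(paste0("T", 1:8), 30, TRUE),
                   target = sample(paste0("g", 1:20), 30, TRUE))
  res2 <- consensus_tfs(ra, rb)
  expect_setequal(unique(res2$tf), intersect(unique(ra$tf), unique(rb$tf)))
})

test_that("expression filtering requires STB TFs with secretome targets and is idempotent", {
  edges <- data.frame(tf = c("T1", "T1", "T2", "T3"),
                      target = c("g1", "g2", "g1", "g1"))
  stb <- c("T1", "T2", "g1")
  secretome <- c("g1", "g3")
  out <- filter_by_expression(edges, stb, secretome)
  expect_setequal(unique(out$tf), c("T1", "T2"))  # T3 not STB-expressed
  expect_setequal(unique(out$target), "g1")       # g2 not in secretome
  expect_identical(filter_by_expression(out, stb, secretome), out)
  # TF whose targets all fall outside the secretome is excluded
  out2 <- filter_by_expression(data.frame(tf = "T1", target = "g9"),
                               stb, secretome)
  expect_equal(nrow(out2), 0)
})

test_that("network assembly counts nodes and flags by complication", {
  edges <- data.frame(tf = "T1", target = c("g1", "g2", "g3"))
  net <- build_network(edges,
                       complication_tfs = data.frame(
                         tf = "T1", complication = c("GDM", "PE")),
                       complication_sets = list(GDM = c("g1", "g2")))
  s <- attr(net, "summary")
  expect_equal(unname(s["n_edges"]), 3)
  expect_equal(unname(s["n_flagged_targets"]), 2)
  tf_node <- net$nodes[net$nodes$id == "T1", ]
  expect_true(tf_node$dysregulated)
  expect_equal(tf_node$complications, "GDM,PE")
  empty <- build_network(data.frame(tf = character(0),
                                    target = character(0)))
  expect_equal(nrow(empty$nodes), 0)
  expect_error(build_network(data.frame(tf = "", target = "g1")),
               "dangling")
})

test_that("MEME motif files round-trip through write and read", {
  pwms <- list(random_pwm_fixture(5, seed = 15), random_pwm_fixture(7, seed = 16))
  pwms[[1]]$id <- "A1"; pwms[[2]]$id <- "B2"
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, path)
  back <- read_meme(path)
  expect_setequal(names(back), c("A1", "B2"))
  expect_equal(back$A1$mat, pwms[[1]]$mat, tolerance = 1e-5)
  expect_equal(back$B2$mat, pwms[[2]]$mat, tolerance = 1e-5)
})

test_that("the TF funnel equals brute-force reapplication of each filter", {
  cfg <- sim_config(n_genes = 150, seed = 17)
  dir <- withr::local_tempdir()
  study <- generate_study(cfg, dir)
  res <- run_all(pipeline_config(seed = 17), dir, file.path(dir, "out"))
  consensus <- res$tfnet$consensus
  upstream <- read.delim(study$paths[["upstream_regulators"]])
  enr <- res$tfnet$enrichment
  motif_tfs <- enr$motif[enr$q <= 0.05]
  # both-tools rule, recomputed from the raw tables
  expect_setequal(unique(consensus$tf),
                  intersect(motif_tfs, unique(upstream$tf)))
  stb <- readLines(study$paths[["stb_expressed"]])
  filt <- res$tfnet$filtered
  for (tf in unique(consensus$tf)) {
    targets <- consensus$target[consensus$tf == tf]
    ok <- tf %in% stb &&
      length(intersect(targets,
                       intersect(res$map$shared_human, stb))) > 0
    expect_equal(tf %in% filt$tf, ok)
  }
})

test_that("planted 0.6 vs 0.05 occurrence rates are detected in nearly all replicates", {
  major <- 0.85
  set.seed(71)
  mat <- matrix((1 - major) / 3, 4, 10)
  mat[cbind(sample(4, 10, replace = TRUE), 1:10)] <- major
  pwm <- new_pwm("M", mat)
  cons <- pwm_consensus(pwm)
  plant <- function(proms, rate) {
    hit <- runif(length(proms)) < rate
    proms[hit] <- vapply(proms[hit], function(s) {
      pos <- sample.int(nchar(s) - nchar(cons) + 1, 1)
      paste0(substr(s, 1, pos - 1), cons,
             substr(s, pos + nchar(cons), nchar(s)))
    }, character(1))
    proms
  }
  hits <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    fg <- plant(random_promoters(50, 150), 0.6)
    bg <- plant(random_promoters(50, 150), 0.05)
    names(bg) <- paste0("b", seq_along(bg))
    q <- motif_enrichment(fg, bg, pwm)$q
    if (q < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})
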