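# Independent brute-force oracles used to cross-check the package's
# implementations, plus small fixture builders. These deliberately use
# the most literal formulation of each rule (explicit loops, pairwise
# means, direct enumeration).

oracle_kofn <- function(m, k, floor = 0) {
  keep <- character(0)
  for (r in rownames(m)) {
    npos <- 0
    for (c in seq_len(ncol(m))) if (m[r, c] > floor) npos <- npos + 1
    if (npos >= k) keep <- c(keep, r)
  }
  keep
}

oracle_consensus <- function(assertions, universe) {
  universe <- unique(c(universe, assertions$mouse_gene))
  out <- lapply(universe, function(g) {
    hs <- unique(assertions$human_gene[assertions$mouse_gene == g])
    if (length(hs) == 0L) list(class = "unmapped", human = NA_character_)
    else if (length(hs) == 1L) list(class = "one_to_one", human = hs)
    else list(class = "one_to_many", human = NA_character_)
  })
  names(out) <- universe
  out
}

oracle_venn <- function(sets) {
  k <- length(sets)
  genes <- unique(unlist(sets))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  counts <- apply(patterns, 1, function(p) {
    sum(vapply(genes, function(g) {
      all(vapply(seq_len(k), function(i) (g %in% sets[[i]]) == p[i],
                 logical(1)))
    }, logical(1)))
  })
  names(counts) <- apply(patterns, 1, function(p)
    paste(names(sets)[as.logical(p)], collapse = "&"))
  counts
}

oracle_normalize <- function(q, standard = "__STANDARD__") {
  rows <- setdiff(rownames(q), standard)
  out <- matrix(NA_real_, length(rows), ncol(q),
                dimnames = list(rows, colnames(q)))
  for (r in rows) for (c in colnames(q))
    out[r, c] <- q[r, c] / q[standard, c]
  out
}

oracle_scan <- function(promoters, pwm, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_window <- function(chars) {
    s <- 0
    for (j in seq_along(chars)) {
      b <- chars[j]
      if (b == "N") return(-Inf)
      s <- s + log2(pwm$mat[b, j] / pwm$background[b])
    }
    s
  }
  L <- ncol(pwm$mat)
  hits <- list()
  for (g in names(promoters)) {
    chars <- strsplit(promoters[[g]], "")[[1]]
    n <- length(chars)
    if (n < L) next
    rc <- rev(unname(comp[chars]))
    for (p in seq_len(n - L + 1)) {
      s <- score_window(chars[p:(p + L - 1)])
      if (s >= threshold)
        hits[[length(hits) + 1]] <- data.frame(
          gene = g, position = p - 1L, strand = "+", score = s,
          stringsAsFactors = FALSE)
      s2 <- score_window(rc[p:(p + L - 1)])
      if (s2 >= threshold)
        hits[[length(hits) + 1]] <- data.frame(
          gene = g, position = n - L - (p - 1L), strand = "-", score = s2,
          stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(gene = character(0), position = integer(0),
                      strand = character(0), score = numeric(0)))
  do.call(rbind, hits)
}

# Brute-force average linkage: the distance between two clusters is the
# arithmetic mean of all pairwise leaf distances; ties (within 1e-9)
# broken by the lexicographically smallest sorted pair of minimal leaf
# labels. Returns merge heights and the leaf partition after each step.
oracle_average_linkage <- function(d, labels) {
  clusters <- as.list(seq_along(labels))
  heights <- numeric(0)
  partitions <- list()
  cdist <- function(a, b) mean(d[a, b])
  while (length(clusters) > 1L) {
    pairs <- utils::combn(length(clusters), 2)
    dds <- apply(pairs, 2, function(p) cdist(clusters[[p[1]]],
                                             clusters[[p[2]]]))
    tied <- which(dds <= min(dds) + 1e-9)
    keys <- vapply(tied, function(t) {
      p <- pairs[, t]
      paste(sort(c(min(labels[clusters[[p[1]]]]),
                   min(labels[clusters[[p[2]]]]))), collapse = "\r")
    }, character(1))
    best <- pairs[, tied[order(keys)[1]]]
    heights <- c(heights, cdist(clusters[[best[1]]], clusters[[best[2]]]))
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    partitions[[length(partitions) + 1]] <-
      sort(vapply(clusters, function(cl)
        paste(sort(labels[cl]), collapse = ","), character(1)))
  }
  list(heights = heights, partitions = partitions)
}

# Partition sequence of an hclust object, comparable to the oracle's.
hclust_partitions <- function(h) {
  n <- length(h$labels)
  clusters <- as.list(seq_len(n))
  alive <- rep(TRUE, n)
  out <- list()
  store <- list()
  for (s in seq_len(n - 1L)) {
    members <- function(k) if (k < 0) -k else store[[k]]
    m <- c(members(h$merge[s, 1]), members(h$merge[s, 2]))
    store[[s]] <- m
    # partition = singletons not yet merged + all current top-level merges
    tops <- setdiff(seq_len(s), unlist(lapply(seq_len(s), function(t)
      h$merge[t, ][h$merge[t, ] > 0])))
    leaves_in_tops <- unlist(lapply(tops, function(t) store[[t]]))
    singles <- setdiff(seq_len(n), leaves_in_tops)
    part <- c(lapply(singles, identity), lapply(tops, function(t) store[[t]]))
    out[[s]] <- sort(vapply(part, function(cl)
      paste(sort(h$labels[cl]), collapse = ","), character(1)))
  }
  out
}

random_detection <- function(nr, nc, presence = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rbinom(nr * nc, 1, presence) *
                stats::rexp(nr * nc, 1 / 100),
              nrow = nr,
              dimnames = list(sprintf("P%03d", seq_len(nr)),
                              sprintf("s%d", seq_len(nc))))
  m
}

random_pwm_fixture <- function(len = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(stats::runif(4 * len, 0.05, 1), nrow = 4)
  new_pwm("M1", counts)
}

random_promoters <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
  names(out) <- sprintf("g%02d", seq_len(n))
  out
}
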