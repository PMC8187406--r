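# Secretome map construction: integration of per-stream secreted gene
# lists, Venn partition counts, tissue enrichment, pregnancy-complication
# overlays and hypergeometric over-representation.

COMPLICATION_LABELS <- c("PE", "GDM", "IUGR", "SGA", "LGA")

#' Integrate per-stream secreted gene lists into a secretome map
#'
#' Takes the secreted gene list of each evidence stream (for example
#' cultured cells, conditioned medium and sorted cells), the one-to-one
#' mouse-human ortholog pairs, and a human expression table, and builds
#' one map entry per gene in the union. An entry is shared with human
#' when the gene has a one-to-one human ortholog whose expression in the
#' human placenta passes the floor; otherwise it is mouse-only.
#'
#' @param stream_sets named list of character vectors (mouse gene ids per
#'   stream); at least one stream.
#' @param ortholog_pairs data.frame with columns `mouse_gene`,
#'   `human_gene` (one-to-one pairs, e.g. from [apply_exclusion()]).
#' @param human_expression numeric matrix, human genes x tissues.
#' @param human_tissue human placenta column name (default "placenta").
#' @param min_expression expression floor for "expressed by human
#'   placenta" (default 0; value must be strictly greater when the floor
#'   is 0, i.e. any positive expression counts).
#' @return data.frame with one row per mouse gene: `mouse_gene`,
#'   `human_gene` (NA when no one-to-one ortholog), `streams`
#'   (comma-separated contributing streams), `n_streams`,
#'   `shared_with_human`.
#' @export
integrate_streams <- function(stream_sets, ortholog_pairs, human_expression,
                              human_tissue = "placenta", min_expression = 0) {
  if (length(stream_sets) < 1L)
    stopf("at least one stream set is required")
  if (is.null(names(stream_sets)) || any(!nzchar(names(stream_sets))))
    stopf("stream sets must be named")
  all_genes <- sort(unique(unlist(stream_sets, use.names = FALSE)))
  membership <- vapply(stream_sets, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  membership <- matrix(membership, nrow = length(all_genes),
                       dimnames = list(all_genes, names(stream_sets)))
  streams <- apply(membership, 1L, function(m)
    paste(names(stream_sets)[m], collapse = ","))
  human <- ortholog_pairs$human_gene[match(all_genes,
                                           ortholog_pairs$mouse_gene)]
  expr_ok <- rep(FALSE, length(all_genes))
  has_h <- !is.na(human) & human %in% rownames(human_expression)
  if (!human_tissue %in% colnames(human_expression))
    stopf("tissue '%s' not found in human expression table", human_tissue)
  floor_pass <- if (min_expression > 0) {
    function(v) v >= min_expression
  } else {
    function(v) v > 0
  }
  expr_ok[has_h] <- floor_pass(human_expression[human[has_h], human_tissue])
  data.frame(mouse_gene = all_genes,
             human_gene = human,
             streams = unname(streams),
             n_streams = unname(rowSums(membership)),
             shared_with_human = !is.na(human) & expr_ok,
             stringsAsFactors = FALSE)
}

#' Count genes in every region of a Venn partition
#'
#' For 2 to 5 named gene sets, counts the genes falling in each of the
#' 2^k - 1 non-empty membership patterns. Region counts sum back to each
#' set's cardinality.
#'
#' @param sets named list of 2-5 character vectors.
#' @return data.frame with one row per membership pattern: one logical
#'   column per set, a `region` label (sets joined by "&") and `count`.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 5L)
    stopf("venn_counts supports 2 to 5 sets, got %d", k)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("sets must be named")
  sets <- lapply(sets, unique)
  union_genes <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) union_genes %in% s,
                   logical(length(union_genes)))
  member <- matrix(member, ncol = k, dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  colnames(patterns) <- names(sets)
  sig <- apply(member, 1L, paste, collapse = ".")
  pat_sig <- apply(patterns, 1L, paste, collapse = ".")
  counts <- vapply(pat_sig, function(p) sum(sig == p), integer(1))
  region <- apply(patterns, 1L, function(m)
    paste(names(sets)[as.logical(m)], collapse = "&"))
  out <- data.frame(patterns, region = region, count = unname(counts),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Tissue enrichment at a fold threshold
#'
#' A gene is enriched in the target tissue when its expression there
#' exceeds `fold` times the maximum of its expression over all other
#' tissues (the strictest standard comparator; the mean is available via
#' `comparator`). Genes with zero target expression are never enriched.
#'
#' @param expression numeric matrix, genes x tissues (at least 2).
#' @param genes gene ids to evaluate (genes absent from the table are
#'   dropped with a warning).
#' @param target target tissue column name.
#' @param fold fold threshold (> 0; default 10).
#' @param comparator summary of the non-target tissues: "max" (default)
#'   or "mean".
#' @return data.frame per gene: `gene`, `target_expression`, `other`,
#'   `fold_value` and `enriched`.
#' @export
tissue_enrichment <- function(expression, genes, target, fold = 10,
                              comparator = c("max", "mean")) {
  comparator <- match.arg(comparator)
  if (!target %in% colnames(expression))
    stopf("target tissue '%s' not found", target)
  if (ncol(expression) < 2L)
    stopf("at least 2 tissues are required")
  if (fold <= 0)
    stopf("fold threshold must be > 0")
  genes <- unique(as.character(genes))
  missing <- setdiff(genes, rownames(expression))
  if (length(missing))
    warnf("%d gene(s) absent from expression table were dropped",
          length(missing))
  genes <- intersect(genes, rownames(expression))
  tgt <- expression[genes, target]
  oth <- expression[genes, setdiff(colnames(expression), target),
                    drop = FALSE]
  other <- if (comparator == "max") apply(oth, 1L, max) else rowMeans(oth)
  fold_value <- ifelse(tgt > 0 & other == 0, Inf, tgt / ifelse(other == 0, NA, other))
  fold_value[tgt == 0] <- 0
  data.frame(gene = genes,
             target_expression = unname(tgt),
             other = unname(other),
             fold_value = unname(fold_value),
             enriched = unname(tgt > 0 & tgt > fold * other),
             stringsAsFactors = FALSE)
}

#' Overlay pregnancy-complication differential sets on the map
#'
#' Flags each map entry with the complications (PE, GDM, IUGR, SGA, LGA)
#' whose placental differential-expression gene set contains the entry's
#' human ortholog. Mouse-only entries cannot be matched and are flagged
#' unmatchable. Also summarizes genes unique to each complication and
#' genes shared by at least `k` complications.
#'
#' @param entries secretome map from [integrate_streams()].
#' @param differential_sets named list, complication label to human gene
#'   set; labels must be among PE, GDM, IUGR, SGA, LGA.
#' @param k minimum number of complications for the shared-core summary
#'   (default 4).
#' @return List with `entries` (input plus `complications`,
#'   `n_complications`, `unmatchable` columns), `unique_to` (named list
#'   of map genes found in exactly one complication set) and `shared_core`
#'   (human genes of the map in >= k sets).
#' @export
complication_overlay <- function(entries, differential_sets, k = 4L) {
  labels <- names(differential_sets)
  bad <- setdiff(labels, COMPLICATION_LABELS)
  if (length(bad))
    stopf("unknown complication label(s): %s", paste(bad, collapse = ", "))
  hg <- entries$human_gene
  flags <- vapply(differential_sets, function(s) !is.na(hg) & hg %in% s,
                  logical(nrow(entries)))
  flags <- matrix(flags, nrow = nrow(entries), dimnames = list(NULL, labels))
  entries$complications <- apply(flags, 1L, function(m)
    paste(labels[m], collapse = ","))
  entries$n_complications <- rowSums(flags)
  entries$unmatchable <- is.na(hg)
  in_one <- entries$n_complications == 1L
  unique_to <- lapply(labels, function(l)
    hg[in_one & flags[, l]])
  names(unique_to) <- labels
  list(entries = entries,
       unique_to = unique_to,
       shared_core = hg[!is.na(hg) & entries$n_complications >= k])
}

#' Hypergeometric over-representation analysis
#'
#' Tests each category (pathway, GO term, complication set, ...) for
#' over-representation among the hit genes relative to the universe,
#' using the exact upper-tail hypergeometric probability
#' P(X >= overlap), with Benjamini-Hochberg adjustment across
#' categories.
#'
#' @param hits character vector of hit genes; must be a subset of
#'   `universe`.
#' @param universe character vector, the gene universe.
#' @param categories named list of gene sets; genes outside the universe
#'   are ignored.
#' @return data.frame sorted by p: `category`, `overlap`, `size`,
#'   `expected`, `p`, `q`.
#' @export
overrepresentation <- function(hits, universe, categories) {
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  if (!all(hits %in% universe))
    stopf("hits must be a subset of the universe")
  if (is.null(names(categories)) || any(!nzchar(names(categories))))
    stopf("categories must be named")
  N <- length(universe)
  n <- length(hits)
  res <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(unique(categories[[nm]]), universe)
    m <- length(cat_genes)
    x <- length(intersect(cat_genes, hits))
    p <- stats::phyper(x - 1L, m, N - m, n, lower.tail = FALSE)
    data.frame(category = nm, overlap = x, size = m,
               expected = n * m / N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
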