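# Mouse-human ortholog consensus across assertion sources, with
# classification into one-to-one / one-to-many / unmapped and the
# exclusion of ambiguous (one-to-many) genes.

#' Build a mouse-human ortholog consensus map
#'
#' Pools ortholog assertions from several sources (for example MGI, NCBI
#' HomoloGene and Ensembl) and classifies each mouse gene by the number
#' of distinct human partners asserted across all sources: exactly one
#' partner is `one_to_one`, more than one (within or across sources) is
#' `one_to_many`, none is `unmapped`. Cross-source disagreement therefore
#' counts as one-to-many: if two sources name different human partners
#' the identity of the ortholog is ambiguous and the gene is later
#' excluded. Many mouse genes may map to the same human gene; the
#' classification is per mouse gene.
#'
#' Gene ids are compared after trimming whitespace and stripping a
#' trailing version suffix, since source dialects differ.
#'
#' @param assertions data.frame with columns `mouse_gene`, `human_gene`,
#'   `source`.
#' @param universe character vector of mouse genes to classify. Genes
#'   asserted but absent from `universe` are added to it so the
#'   classification always partitions the full set of genes seen.
#' @return data.frame with one row per mouse gene: `mouse_gene`,
#'   `classification` (one_to_one / one_to_many / unmapped),
#'   `human_gene` (NA unless one_to_one), `n_human` (number of distinct
#'   partners) and `sources` (comma-separated supporting sources).
#' @export
build_consensus <- function(assertions, universe) {
  req <- c("mouse_gene", "human_gene", "source")
  if (!all(req %in% names(assertions)))
    stopf("assertions must have columns %s", paste(req, collapse = ", "))
  bad <- which(!nzchar(trimws(assertions$mouse_gene)) |
               !nzchar(trimws(assertions$human_gene)) |
               !nzchar(trimws(assertions$source)))
  if (length(bad))
    stopf("malformed assertion row(s): %s (empty field)",
          paste(bad, collapse = ", "))
  mouse <- normalize_gene_id(assertions$mouse_gene)
  human <- normalize_gene_id(assertions$human_gene)
  src <- trimws(assertions$source)
  universe <- unique(c(normalize_gene_id(universe), mouse))

  partners <- split(human, mouse)
  sources <- split(src, mouse)
  n_human <- vapply(partners, function(h) length(unique(h)), integer(1))

  classification <- rep("unmapped", length(universe))
  names(classification) <- universe
  classification[names(n_human)[n_human == 1L]] <- "one_to_one"
  classification[names(n_human)[n_human > 1L]] <- "one_to_many"

  human_gene <- rep(NA_character_, length(universe))
  names(human_gene) <- universe
  one <- names(n_human)[n_human == 1L]
  human_gene[one] <- vapply(partners[one], function(h) unique(h)[1L],
                            character(1))

  n_col <- integer(length(universe))
  names(n_col) <- universe
  n_col[names(n_human)] <- n_human

  src_col <- rep("", length(universe))
  names(src_col) <- universe
  src_col[names(sources)] <- vapply(sources, function(s)
    paste(sort(unique(s)), collapse = ","), character(1))

  # name-indexed assembly: row order follows the (sorted) universe so the
  # result is invariant to assertion input order
  universe <- sort(universe)
  data.frame(mouse_gene = universe,
             classification = unname(classification[universe]),
             human_gene = unname(human_gene[universe]),
             n_human = unname(n_col[universe]),
             sources = unname(src_col[universe]),
             stringsAsFactors = FALSE)
}

#' Exclude one-to-many orthologs
#'
#' Restricts a gene set to mouse genes with an unambiguous (one-to-one)
#' human ortholog; one-to-many and unmapped genes are excluded and
#' counted by class.
#'
#' @param map consensus map from [build_consensus()].
#' @param genes character vector of mouse genes (subset of the map's
#'   universe).
#' @return data.frame with columns `mouse_gene`, `human_gene` for the
#'   surviving genes; attribute `excluded` is a named vector of counts by
#'   classification.
#' @export
apply_exclusion <- function(map, genes) {
  genes <- unique(normalize_gene_id(genes))
  missing <- setdiff(genes, map$mouse_gene)
  if (length(missing))
    stopf("gene(s) not in consensus universe: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  sub <- map[map$mouse_gene %in% genes, , drop = FALSE]
  keep <- sub$classification == "one_to_one"
  excluded <- table(factor(sub$classification[!keep],
                           levels = c("one_to_many", "unmapped")))
  out <- data.frame(mouse_gene = sub$mouse_gene[keep],
                    human_gene = sub$human_gene[keep],
                    stringsAsFactors = FALSE)
  structure(out, excluded = c(excluded))
}
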