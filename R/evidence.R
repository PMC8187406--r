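# Detection-evidence stage: k-of-n sample filtering of MS detection
# matrices, protein-to-gene identifier mapping, and expression
# verification against a gene x tissue table.

#' Retain proteins detected in at least k of n samples
#'
#' Label-free MS detection is noisy at the presence/absence level, so a
#' protein is only carried forward when it is observed in at least `k` of
#' the `n` replicate samples of a stream. Presence means a peak area
#' strictly greater than `floor` (default 0; no intensity floor).
#'
#' @param matrix numeric matrix, proteins in rows (rownames are protein
#'   accessions), samples in columns; peak areas or presence flags, all
#'   finite and non-negative.
#' @param k minimum number of positive samples (default 4).
#' @param n expected number of samples; must equal `ncol(matrix)`
#'   (default 5).
#' @param floor detection intensity floor; a value must exceed it to count
#'   as present.
#' @return Character vector of retained accessions, with attributes
#'   `dropped` (accessions failing the filter) and `counts` (named vector
#'   `input`/`retained`/`dropped`).
#' @examples
#' m <- matrix(c(1, 1, 1, 1, 0,
#'               1, 0, 0, 1, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("p1", "p2"), paste0("s", 1:5)))
#' filter_k_of_n(m, k = 4, n = 5)
#' @export
filter_k_of_n <- function(matrix, k = 4L, n = 5L, floor = 0) {
  if (is.null(rownames(matrix)))
    stopf("detection matrix must have protein accessions as rownames")
  if (anyDuplicated(rownames(matrix)))
    stopf("duplicate protein rows in detection matrix")
  if (ncol(matrix) != n)
    stopf("sample count mismatch: matrix has %d columns, n = %d",
          ncol(matrix), n)
  if (k < 1L || k > n)
    stopf("k must satisfy 1 <= k <= n; got k = %d, n = %d", k, n)
  if (any(!is.finite(matrix)) || any(matrix < 0))
    stopf("detection values must be finite and >= 0")
  positive <- rowSums(matrix > floor)
  retained <- rownames(matrix)[positive >= k]
  dropped <- setdiff(rownames(matrix), retained)
  structure(retained,
            dropped = dropped,
            counts = c(input = nrow(matrix), retained = length(retained),
                       dropped = length(dropped)))
}

#' Map protein accessions to gene identifiers
#'
#' De-duplicates the gene image of an accession set under an
#' accession-to-gene map. Accessions mapping to several genes contribute
#' all their target genes (the ambiguity is reported, nothing is lost);
#' accessions absent from the map are reported as unmapped, never
#' silently dropped.
#'
#' @param proteins character vector of accessions.
#' @param idmap data.frame with columns `accession` and `gene`; one row
#'   per (accession, gene) pair.
#' @return List with elements `genes` (unique mapped gene ids),
#'   `unmapped` (accessions with no mapping) and `ambiguous` (accessions
#'   mapping to more than one gene).
#' @export
map_to_genes <- function(proteins, idmap) {
  if (!all(c("accession", "gene") %in% names(idmap)))
    stopf("idmap must have columns 'accession' and 'gene'")
  proteins <- unique(as.character(proteins))
  if (length(proteins) == 0L) {
    warnf("empty accession set: returning empty gene set")
    return(list(genes = character(0), unmapped = character(0),
                ambiguous = character(0)))
  }
  if (any(!nzchar(idmap$gene)))
    stopf("idmap contains empty gene ids")
  sub <- idmap[idmap$accession %in% proteins, , drop = FALSE]
  genes_per_acc <- split(sub$gene, sub$accession)
  unmapped <- setdiff(proteins, names(genes_per_acc))
  ambiguous <- names(genes_per_acc)[vapply(genes_per_acc,
                                           function(g) length(unique(g)) > 1L,
                                           logical(1))]
  list(genes = unique(unlist(genes_per_acc, use.names = FALSE)),
       unmapped = unmapped,
       ambiguous = ambiguous)
}

#' Verify gene expression in a tissue
#'
#' Restricts a gene set to those with expression at or above `min_value`
#' in the named tissue column of an expression table. Genes absent from
#' the table are excluded and reported via the `missing` attribute.
#'
#' @param genes character vector of gene ids.
#' @param expression numeric matrix, genes in rows (rownames), tissues in
#'   columns.
#' @param tissue tissue column name.
#' @param min_value minimum expression to count as expressed (default 0,
#'   i.e. any non-negative value passes).
#' @return Character vector of verified genes with attribute `missing`.
#' @export
verify_expression <- function(genes, expression, tissue, min_value = 0) {
  if (!tissue %in% colnames(expression))
    stopf("tissue '%s' not found in expression table", tissue)
  genes <- unique(as.character(genes))
  present <- genes[genes %in% rownames(expression)]
  missing <- setdiff(genes, present)
  verified <- present[expression[present, tissue] >= min_value]
  structure(verified, missing = missing)
}
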