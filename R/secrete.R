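# Secretion classification combining the conventional route (an
# N-terminal signal peptide, excluding ER-lumen residents) with the
# unconventional route (membership in extracellular GO terms).

#' Default secretion GO term set
#'
#' The canonical identifiers of the extracellular compartment terms used
#' to capture unconventionally secreted (leaderless) proteins:
#' extracellular region (GO:0005576), extracellular space (GO:0005615),
#' extracellular exosome (GO:0070062) and extracellular region part
#' (GO:0044421).
#'
#' @return Character vector of GO identifiers.
#' @export
secretion_go_terms <- function() {
  c("GO:0005576", "GO:0005615", "GO:0070062", "GO:0044421")
}

#' Classify a single gene as secreted
#'
#' A gene is called secreted when it carries a signal peptide and is not
#' an ER-lumen resident (conventional route), or when any of its GO
#' annotations belongs to the secretion term set (unconventional route).
#' Signal peptides on ER-lumen proteins are discounted: the peptide
#' targets the protein to the ER, where it stays.
#'
#' @param signal_peptide logical, signal peptide predicted.
#' @param er_lumen logical, annotated as an ER-lumen protein.
#' @param go_terms character vector of GO ids annotated to the gene (may
#'   be empty).
#' @param terms secretion GO term set (default [secretion_go_terms()]);
#'   must be non-empty.
#' @return List with `secreted` (logical) and `evidence` (character
#'   subset of `c("conventional", "unconventional")`).
#' @export
classify_secreted <- function(signal_peptide, er_lumen,
                              go_terms = character(0),
                              terms = secretion_go_terms()) {
  if (length(terms) == 0L)
    stopf("secretion GO term set must be non-empty")
  stopifnot(is.logical(signal_peptide), is.logical(er_lumen),
            !is.na(signal_peptide), !is.na(er_lumen))
  conventional <- signal_peptide && !er_lumen
  unconventional <- length(intersect(go_terms, terms)) > 0L
  list(secreted = conventional || unconventional,
       evidence = c("conventional", "unconventional")[
         c(conventional, unconventional)])
}

#' Partition a gene set by secretion status
#'
#' Applies [classify_secreted()] to every gene of a set using an
#' annotation table, partitioning the input into secreted, not secreted
#' and unannotated genes (genes missing from the table are never silently
#' called secreted).
#'
#' @param annotations data.frame with columns `gene`, `signal_peptide`
#'   (logical), `er_lumen` (logical), `go_terms` (semicolon-separated GO
#'   ids, possibly empty).
#' @param genes character vector of gene ids to classify.
#' @param terms secretion GO term set.
#' @return List with `secreted`, `not_secreted`, `unannotated` (disjoint
#'   character vectors covering `genes`) and `evidence_counts` (named
#'   counts of conventional / unconventional / both evidence among the
#'   secreted).
#' @export
classify_set <- function(annotations, genes, terms = secretion_go_terms()) {
  req <- c("gene", "signal_peptide", "er_lumen", "go_terms")
  if (!all(req %in% names(annotations)))
    stopf("annotations must have columns %s", paste(req, collapse = ", "))
  if (any(is.na(annotations$signal_peptide)) || any(is.na(annotations$er_lumen)))
    stopf("signal_peptide/er_lumen flags must be TRUE or FALSE, not missing")
  genes <- unique(as.character(genes))
  idx <- match(genes, annotations$gene)
  unannotated <- genes[is.na(idx)]
  annotated <- genes[!is.na(idx)]
  idx <- idx[!is.na(idx)]

  go_list <- strsplit(as.character(annotations$go_terms[idx]), ";", fixed = TRUE)
  go_list <- lapply(go_list, function(g) trimws(g[nzchar(trimws(g))]))
  conv <- as.logical(annotations$signal_peptide[idx]) &
    !as.logical(annotations$er_lumen[idx])
  unconv <- vapply(go_list, function(g) length(intersect(g, terms)) > 0L,
                   logical(1))
  if (length(terms) == 0L)
    stopf("secretion GO term set must be non-empty")
  secreted <- annotated[conv | unconv]
  list(secreted = secreted,
       not_secreted = annotated[!(conv | unconv)],
       unannotated = unannotated,
       evidence_counts = c(conventional = sum(conv & !unconv),
                           unconventional = sum(!conv & unconv),
                           both = sum(conv & unconv)))
}
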