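# Transcription-factor network stage: position weight matrix (PWM)
# handling in MEME format, log-odds promoter scanning, threshold-hit
# Fisher motif enrichment, two-source consensus of TF predictions,
# trophoblast-expression filtering and network assembly.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param id motif identifier.
#' @param mat 4 x L numeric matrix (rows A, C, G, T) of per-position
#'   base probabilities or counts; length L >= 4.
#' @param background base composition 4-vector (default uniform); must
#'   sum to 1.
#' @param pseudocount value added to every cell before column
#'   normalization (default 0 when `mat` is already a probability
#'   matrix).
#' @return Object of class `pwm`: list with `id`, `mat` (probability
#'   matrix), `background`.
#' @export
new_pwm <- function(id, mat, background = rep(0.25, 4), pseudocount = 0) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stopf("PWM matrix must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 4L) stopf("motif length must be >= 4")
  if (pseudocount < 0) stopf("pseudocount must be >= 0")
  mat <- mat + pseudocount
  mat <- sweep(mat, 2L, colSums(mat), "/")
  if (any(abs(colSums(mat) - 1) > 1e-9))
    stopf("PWM columns must normalize to 1")
  if (abs(sum(background) - 1) > 1e-9)
    stopf("background frequencies must sum to 1")
  rownames(mat) <- DNA_ALPHABET
  names(background) <- DNA_ALPHABET
  structure(list(id = id, mat = mat, background = background),
            class = "pwm")
}

#' Maximal achievable log-odds score of a PWM
#'
#' The sum over positions of the maximum per-base log2 odds against the
#' background; the score of the motif consensus sequence.
#'
#' @param pwm a [new_pwm()] object.
#' @return Score in bits.
#' @export
pwm_max_score <- function(pwm) {
  sum(apply(log2(pwm$mat / pwm$background), 2L, max))
}

#' Consensus sequence of a PWM
#' @param pwm a [new_pwm()] object.
#' @return Character string of the per-position modal bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_ALPHABET[apply(pwm$mat, 2L, which.max)], collapse = "")
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

score_positions <- function(seq, score_mat) {
  L <- ncol(score_mat)
  bases <- match(strsplit(seq, "")[[1]], DNA_ALPHABET)
  n <- length(bases)
  if (n < L) return(numeric(0))
  vapply(seq_len(n - L + 1L), function(p) {
    idx <- bases[p:(p + L - 1L)]
    if (anyNA(idx)) return(-Inf)  # N scores -Inf
    sum(score_mat[cbind(idx, seq_len(L))])
  }, numeric(1))
}

#' Scan promoter sequences with a PWM
#'
#' Slides the motif over both strands of each promoter and reports every
#' window whose summed log2 odds (motif probability over background)
#' reaches the threshold. Positions are 0-based on the given (forward)
#' sequence and mark the start of the matching window; windows
#' containing N never match.
#'
#' @param promoters named character vector of promoter sequences
#'   (alphabet A, C, G, T, N), or a `Biostrings::DNAStringSet`.
#' @param pwm a [new_pwm()] object.
#' @param score_threshold minimum score in bits; defaults to 60 percent
#'   of the maximal achievable score.
#' @return data.frame of hits: `gene`, `position`, `strand`, `score`.
#' @export
scan_pwm <- function(promoters, pwm, score_threshold = 0.6 * pwm_max_score(pwm)) {
  if (!is.finite(score_threshold)) stopf("score threshold must be finite")
  promoters <- as_promoter_vector(promoters)
  score_mat <- log2(pwm$mat / pwm$background)
  L <- ncol(score_mat)
  hits <- lapply(names(promoters), function(g) {
    seq <- toupper(promoters[[g]])
    n <- nchar(seq)
    if (n < L) {
      warnf("promoter '%s' shorter than the motif: no hits", g)
      return(NULL)
    }
    fwd <- score_positions(seq, score_mat)
    rev <- score_positions(revcomp(seq), score_mat)
    keep_f <- which(fwd >= score_threshold)
    keep_r <- which(rev >= score_threshold)
    if (!length(keep_f) && !length(keep_r)) return(NULL)
    data.frame(gene = g,
               position = c(keep_f - 1L, n - L - (keep_r - 1L)),
               strand = rep(c("+", "-"), c(length(keep_f), length(keep_r))),
               score = c(fwd[keep_f], rev[keep_r]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(gene = character(0), position = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

as_promoter_vector <- function(promoters) {
  if (inherits(promoters, "DNAStringSet")) {
    out <- as.character(promoters)
    names(out) <- names(promoters)
    promoters <- out
  }
  if (is.null(names(promoters)) || any(!nzchar(names(promoters))))
    stopf("promoters must be named by gene id")
  promoters
}

#' Motif enrichment in foreground vs background promoters
#'
#' For each motif, promoters are dichotomized by whether they carry at
#' least one hit at the score threshold, and the resulting 2 x 2 table
#' (hit status x foreground/background) is tested with a two-sided
#' Fisher exact test; q-values are Benjamini-Hochberg adjusted across
#' motifs. This threshold-hit test is a declared approximation of
#' rank-based motif enrichment tools.
#'
#' @param foreground,background named promoter vectors (disjoint gene
#'   ids, both non-empty).
#' @param pwms list of [new_pwm()] objects (or a single one).
#' @param score_threshold passed to [scan_pwm()]; default 60 percent of
#'   each motif's maximal score.
#' @return data.frame per motif: `motif`, `fg_hits`, `fg_n`, `bg_hits`,
#'   `bg_n`, `odds_ratio`, `p`, `q`.
#' @export
motif_enrichment <- function(foreground, background, pwms,
                             score_threshold = NULL) {
  foreground <- as_promoter_vector(foreground)
  background <- as_promoter_vector(background)
  if (length(foreground) == 0L || length(background) == 0L)
    stopf("foreground and background must both be non-empty")
  if (length(intersect(names(foreground), names(background))))
    stopf("foreground and background must be disjoint")
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  res <- lapply(pwms, function(pwm) {
    thr <- if (is.null(score_threshold)) 0.6 * pwm_max_score(pwm) else
      score_threshold
    fg_hit <- length(unique(scan_pwm(foreground, pwm, thr)$gene))
    bg_hit <- length(unique(scan_pwm(background, pwm, thr)$gene))
    tab <- matrix(c(fg_hit, length(foreground) - fg_hit,
                    bg_hit, length(background) - bg_hit), nrow = 2L)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    data.frame(motif = pwm$id, fg_hits = fg_hit, fg_n = length(foreground),
               bg_hits = bg_hit, bg_n = length(background),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' TFs predicted by both sources, with pooled targets
#'
#' A TF survives only when both prediction sources (e.g. motif
#' enrichment and an upstream-regulator analysis) report it; its target
#' set is the union of the targets from both sources.
#'
#' @param predsA,predsB data.frames with columns `tf`, `target`.
#' @return data.frame of edges `tf`, `target` for the consensus TFs.
#' @export
consensus_tfs <- function(predsA, predsB) {
  for (p in list(predsA, predsB))
    if (!all(c("tf", "target") %in% names(p)))
      stopf("prediction tables need columns 'tf' and 'target'")
  keep <- intersect(unique(predsA$tf), unique(predsB$tf))
  pooled <- rbind(predsA[predsA$tf %in% keep, c("tf", "target")],
                  predsB[predsB$tf %in% keep, c("tf", "target")])
  pooled <- unique(pooled)
  pooled <- pooled[order(pooled$tf, pooled$target), , drop = FALSE]
  rownames(pooled) <- NULL
  pooled
}

#' Filter TFs by trophoblast expression and secretome targets
#'
#' A TF is retained when it is itself expressed in the
#' syncytiotrophoblast (STB) and has at least one target that is both in
#' the secretome and STB-expressed; surviving edges are restricted to
#' those targets.
#'
#' @param edges data.frame `tf`, `target`.
#' @param stb_expression character vector of STB-expressed gene ids
#'   (covers TFs and targets).
#' @param secretome character vector of secretome gene ids.
#' @return Filtered edge data.frame.
#' @export
filter_by_expression <- function(edges, stb_expression, secretome) {
  ok_target <- edges$target %in% intersect(secretome, stb_expression)
  ok_tf <- edges$tf %in% stb_expression
  out <- edges[ok_tf & ok_target, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the TF-target regulatory network
#'
#' Builds node and edge tables from filtered TF predictions, flagging TF
#' nodes dysregulated in pregnancy complications and target nodes that
#' are differentially expressed in any complication set.
#'
#' @param edges data.frame `tf`, `target` (e.g. from
#'   [filter_by_expression()]); restricted to TFs in `complication_tfs`
#'   when that filter is applied upstream.
#' @param complication_tfs data.frame `tf`, `complication` (or a
#'   character vector of TF ids) naming TFs linked to complications.
#' @param complication_sets named list of complication gene sets used to
#'   flag differentially expressed targets.
#' @return List of class `tf_network` with `nodes` (id, type,
#'   dysregulated, complications, differential) and `edges`; attribute
#'   `summary` holds node/edge counts.
#' @export
build_network <- function(edges, complication_tfs = character(0),
                          complication_sets = list()) {
  if (nrow(edges) > 0 && (any(!nzchar(edges$tf)) || any(!nzchar(edges$target))))
    stopf("dangling edge: empty endpoint id")
  if (is.data.frame(complication_tfs)) {
    comp_by_tf <- split(complication_tfs$complication, complication_tfs$tf)
    comp_tf_ids <- names(comp_by_tf)
  } else {
    comp_tf_ids <- as.character(complication_tfs)
    comp_by_tf <- stats::setNames(as.list(rep("", length(comp_tf_ids))),
                                  comp_tf_ids)
  }
  tfs <- sort(unique(edges$tf))
  targets <- sort(unique(edges$target))
  diff_genes <- unique(unlist(complication_sets, use.names = FALSE))
  nodes <- rbind(
    data.frame(id = tfs, type = rep("TF", length(tfs)),
               dysregulated = tfs %in% comp_tf_ids,
               complications = vapply(tfs, function(t)
                 paste(sort(unique(unlist(comp_by_tf[t]))), collapse = ","),
                 character(1)),
               differential = logical(length(tfs)),
               stringsAsFactors = FALSE),
    data.frame(id = targets, type = rep("target", length(targets)),
               dysregulated = logical(length(targets)),
               complications = character(length(targets)),
               differential = targets %in% diff_genes,
               stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  if (!all(c(edges$tf, edges$target) %in% nodes$id))
    stopf("dangling edge: endpoint missing from node table")
  structure(list(nodes = nodes, edges = edges[, c("tf", "target")]),
            class = "tf_network",
            summary = c(n_tfs = length(tfs), n_targets = length(targets),
                        n_edges = nrow(edges),
                        n_flagged_targets = sum(nodes$differential)))
}

#' Export a TF network as an edge list and GraphML
#'
#' @param net a [build_network()] result.
#' @param edges_path TSV edge-list path.
#' @param graphml_path optional GraphML path.
#' @return Invisibly, the paths written.
#' @export
export_network <- function(net, edges_path, graphml_path = NULL) {
  write_tsv(net$edges, edges_path)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                       vertices = net$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(c(edges_path, graphml_path))
}

#' Read motifs from a MEME-format file
#'
#' Minimal reader for the MEME motif text format (version 4):
#' background letter frequencies and letter-probability matrices.
#'
#' @param path file path.
#' @return Named list of [new_pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1L]), "\\s+")[[1]]
    bg <- as.numeric(toks[seq(2, 8, by = 2)])
  }
  motif_i <- grep("^MOTIF\\b", lines)
  pwms <- lapply(motif_i, function(i) {
    id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    hdr <- grep("letter-probability matrix", lines[i:length(lines)])[1] + i - 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4))
    dimnames(mat) <- NULL
    new_pwm(id, mat, background = bg)
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "id")
  pwms
}

#' Write motifs to a MEME-format file
#'
#' @param pwms list of [new_pwm()] objects.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  out <- c("MEME version 4", "",
           "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           paste(DNA_ALPHABET, formatC(bg, format = "f", digits = 5),
                 collapse = " "), "")
  for (pwm in pwms) {
    out <- c(out,
             paste("MOTIF", pwm$id),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     ncol(pwm$mat)),
             apply(pwm$mat, 2L, function(col)
               paste(formatC(col, format = "f", digits = 6), collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}
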