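# End-to-end orchestration: a single configuration drives every stage
# (evidence -> ortho -> secrete -> map -> plasma -> biomarker -> tfnet)
# over the files of a study directory, with a funnel report of per-stage
# counts and a deterministic manifest.

#' Pipeline configuration
#'
#' Houses every analysis constant with its default: the 4-of-5 detection
#' filter, the secretion GO term set, the 10-fold tissue-enrichment
#' threshold, the 1.5-fold pregnancy classification threshold, the MoM
#' reference group, the t-test variant, the PWM score threshold (as a
#' fraction of the maximal score) and the significance level.
#'
#' @param k,n detection filter: present in at least `k` of `n` samples
#'   (defaults 4 and 5).
#' @param go_terms secretion GO term set.
#' @param min_expression_mouse expression floor for mouse placenta
#'   verification (default any positive value).
#' @param tissue_fold tissue-enrichment fold threshold (default 10).
#' @param pregnancy_fold plasma fold-change classification threshold
#'   (default 1.5).
#' @param mom_reference MoM reference group (default "healthy").
#' @param test_variant "student" (default) or "welch".
#' @param pwm_threshold_frac PWM hit threshold as a fraction of the
#'   maximal log-odds score (default 0.6).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed recorded in the manifest.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 4L, n = 5L,
                            go_terms = secretion_go_terms(),
                            min_expression_mouse = 1e-9,
                            tissue_fold = 10,
                            pregnancy_fold = 1.5,
                            mom_reference = "healthy",
                            test_variant = c("student", "welch"),
                            pwm_threshold_frac = 0.6,
                            alpha = 0.05,
                            seed = 1L) {
  test_variant <- match.arg(test_variant)
  cfg <- list(k = as.integer(k), n = as.integer(n), go_terms = go_terms,
              min_expression_mouse = min_expression_mouse,
              tissue_fold = tissue_fold, pregnancy_fold = pregnancy_fold,
              mom_reference = mom_reference, test_variant = test_variant,
              pwm_threshold_frac = pwm_threshold_frac, alpha = alpha,
              seed = as.integer(seed))
  if (cfg$k < 1L || cfg$k > cfg$n)
    stopf("invalid config: k must satisfy 1 <= k <= n (k = %d, n = %d)",
          cfg$k, cfg$n)
  for (f in c("tissue_fold", "pregnancy_fold", "alpha",
              "pwm_threshold_frac"))
    if (cfg[[f]] <= 0)
      stopf("invalid config: %s must be > 0", f)
  if (length(cfg$go_terms) == 0L)
    stopf("invalid config: go_terms must be non-empty")
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full secretome pipeline on a study directory
#'
#' Executes every stage in order on the input files of `study_dir` (as
#' laid out by [generate_study()]), writes all result tables under
#' `out_dir`, and records a funnel report (in/out counts per stage) and
#' a manifest (configuration hash, seed and the MD5 checksum of every
#' output file). A failing stage halts the run, names itself in the
#' error, and leaves a `FAILED` marker next to any partial outputs.
#'
#' @param config a [pipeline_config()].
#' @param study_dir directory holding the input tables.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the main intermediate results, the
#'   `funnel` report and the `manifest`.
#' @export
run_all <- function(config, study_dir, out_dir) {
  if (!inherits(config, "pipeline_config"))
    stopf("config must be a pipeline_config object")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  inp <- function(f) file.path(study_dir, f)
  outp <- function(f) file.path(out_dir, f)
  funnel <- list()
  streams <- c("cells", "media", "sorted")

  ## evidence ----------------------------------------------------------
  mouse_expr <- read_matrix_tsv(inp("mouse_expression.tsv"))
  idmap <- read_tsv(inp("idmap.tsv"))
  stream_genes <- run_stage("evidence", out_dir, {
    lapply(stats::setNames(streams, streams), function(s) {
      m <- read_matrix_tsv(inp(sprintf("detection_%s.tsv", s)))
      kept <- filter_k_of_n(m, k = config$k, n = config$n)
      mapped <- map_to_genes(kept, idmap)
      verified <- verify_expression(mapped$genes, mouse_expr, "placenta",
                                    config$min_expression_mouse)
      funnel[[paste0("evidence_", s)]] <<- list(
        proteins_in = nrow(m),
        proteins_detected = length(kept),
        genes_mapped = length(mapped$genes),
        accessions_unmapped = length(mapped$unmapped),
        genes_expressed = length(verified))
      as.character(verified)
    })
  })
  union_genes <- sort(unique(unlist(stream_genes)))

  ## ortho -------------------------------------------------------------
  ortho <- run_stage("ortho", out_dir, {
    assertions <- read_tsv(inp("ortholog_assertions.tsv"))
    map <- build_consensus(assertions, union_genes)
    pairs <- apply_exclusion(map, union_genes)
    funnel$ortho <- list(genes_in = length(union_genes),
                          one_to_one = nrow(pairs),
                          excluded = sum(attr(pairs, "excluded")))
    list(map = map, pairs = pairs)
  })

  ## secrete -----------------------------------------------------------
  secreted_streams <- run_stage("secrete", out_dir, {
    annotations <- read_tsv(inp("secretion_annotations.tsv"))
    annotations$signal_peptide <- as.logical(annotations$signal_peptide)
    annotations$er_lumen <- as.logical(annotations$er_lumen)
    annotations$go_terms[is.na(annotations$go_terms)] <- ""
    out <- lapply(stream_genes, function(g) {
      cl <- classify_set(annotations, g, config$go_terms)
      cl$secreted
    })
    funnel$secrete <- lapply(out, length)
    out
  })

  ## map ---------------------------------------------------------------
  human_expr <- read_matrix_tsv(inp("human_expression.tsv"))
  comp_tab <- read_tsv(inp("complication_sets.tsv"))
  comp_sets <- split(comp_tab$gene, comp_tab$complication)
  mapres <- run_stage("map", out_dir, {
    entries <- integrate_streams(secreted_streams, ortho$pairs, human_expr)
    venn <- venn_counts(secreted_streams)
    enr <- tissue_enrichment(mouse_expr, entries$mouse_gene, "placenta",
                             config$tissue_fold)
    overlay <- complication_overlay(entries, comp_sets)
    shared_h <- entries$human_gene[entries$shared_with_human]
    ora <- overrepresentation(intersect(shared_h, rownames(human_expr)),
                              rownames(human_expr), comp_sets)
    funnel$map <- list(entries = nrow(entries),
                        shared_with_human = sum(entries$shared_with_human),
                        mouse_only = sum(!entries$shared_with_human),
                        tissue_enriched = sum(enr$enriched))
    write_tsv(overlay$entries, outp("secretome_map.tsv"))
    write_tsv(venn, outp("venn_counts.tsv"))
    write_tsv(enr, outp("tissue_enrichment.tsv"))
    write_tsv(ora, outp("overrepresentation.tsv"))
    list(entries = overlay$entries, venn = venn, enrichment = enr,
         overlay = overlay, ora = ora, shared_human = sort(shared_h))
  })

  ## plasma ------------------------------------------------------------
  plasma <- run_stage("plasma", out_dir, {
    quant <- read_matrix_tsv(inp("plasma_quant.tsv"))
    groups_tab <- read_tsv(inp("plasma_groups.tsv"))
    groups <- stats::setNames(groups_tab$group, groups_tab$animal)
    normalized <- normalize_to_standard(quant)
    folds <- pregnancy_fold_change(normalized, groups,
                                   threshold = config$pregnancy_fold)
    z <- row_zscore(normalized)
    hr <- hcluster(z, "rows")
    hc <- hcluster(z, "columns")
    funnel$plasma <- list(proteins = nrow(normalized),
                           higher_in_pregnancy = sum(folds$higher_in_pregnancy))
    write_matrix_tsv(normalized, outp("plasma_normalized.tsv"),
                     id_name = "protein")
    write_tsv(folds, outp("plasma_folds.tsv"))
    write_matrix_tsv(z, outp("plasma_zscore.tsv"), id_name = "protein")
    cluster_newick(hr, outp("plasma_rows.nwk"))
    cluster_newick(hc, outp("plasma_columns.nwk"))
    list(normalized = normalized, folds = folds, zscore = z,
         row_tree = hr, column_tree = hc)
  })

  ## biomarker ----------------------------------------------------------
  biomarker <- run_stage("biomarker", out_dir, {
    serum <- read_tsv(inp("serum_biomarkers.tsv"))
    moms <- compute_mom(serum, config$mom_reference)
    ratios <- list(sFLT1_MIF = mom_ratio(moms, "sFLT1", "MIF"),
                   ANGPT2_MIF = mom_ratio(moms, "ANGPT2", "MIF"))
    tests <- do.call(rbind, lapply(names(ratios), function(nm) {
      r <- ratios[[nm]]
      r12 <- r[r$week == 12, ]
      gdm <- r12$ratio[r12$group == "GDM"]
      healthy <- r12$ratio[r12$group == config$mom_reference]
      tt <- two_sample_ttest(gdm, healthy, config$test_variant)
      data.frame(ratio = nm, week = 12,
                 percent_increase = percent_increase(gdm, healthy),
                 t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
    }))
    anovas <- do.call(rbind, lapply(unique(moms$analyte), function(a) {
      sub <- moms[moms$analyte == a, ]
      res <- two_way_anova(sub$mom, sub$group, sub$week)
      cbind(analyte = a, res, stringsAsFactors = FALSE)
    }))
    funnel$biomarker <- list(subjects = length(unique(serum$subject)),
                              analytes = length(unique(serum$analyte)))
    write_tsv(moms, outp("mom.tsv"))
    write_tsv(do.call(rbind, Map(cbind, ratio = names(ratios), ratios)),
              outp("mom_ratios.tsv"))
    write_tsv(tests, outp("ratio_tests.tsv"))
    write_tsv(anovas, outp("mom_anova.tsv"))
    list(moms = moms, ratios = ratios, tests = tests, anovas = anovas)
  })

  ## tfnet ---------------------------------------------------------------
  tfnet <- run_stage("tfnet", out_dir, {
    promoters <- as_promoter_vector(
      Biostrings::readDNAStringSet(inp("promoters.fasta")))
    pwms <- read_meme(inp("motifs.meme"))
    fg <- promoters[names(promoters) %in% mapres$shared_human]
    bg <- promoters[!names(promoters) %in% mapres$shared_human]
    enr <- motif_enrichment(fg, bg, pwms)
    enriched_motifs <- enr$motif[enr$q <= config$alpha]
    predsA <- do.call(rbind, lapply(enriched_motifs, function(m) {
      thr <- config$pwm_threshold_frac * pwm_max_score(pwms[[m]])
      hits <- scan_pwm(fg, pwms[[m]], thr)
      if (nrow(hits) == 0L) return(NULL)
      data.frame(tf = m, target = unique(hits$gene), stringsAsFactors = FALSE)
    }))
    if (is.null(predsA))
      predsA <- data.frame(tf = character(0), target = character(0))
    predsB <- read_tsv(inp("upstream_regulators.tsv"))
    consensus <- consensus_tfs(predsA, predsB)
    stb <- read_gene_set(inp("stb_expressed.txt"))
    filtered <- filter_by_expression(consensus, stb, mapres$shared_human)
    comp_tfs <- read_tsv(inp("complication_tfs.tsv"))
    final <- filtered[filtered$tf %in% comp_tfs$tf, , drop = FALSE]
    net <- build_network(final, comp_tfs, comp_sets)
    funnel$tfnet <- list(
      motifs_tested = nrow(enr),
      motifs_enriched = length(enriched_motifs),
      tfs_both_tools = length(unique(consensus$tf)),
      tfs_stb_filtered = length(unique(filtered$tf)),
      tfs_complication = length(unique(final$tf)),
      edges = nrow(final))
    write_tsv(enr, outp("motif_enrichment.tsv"))
    export_network(net, outp("tf_edges.tsv"), outp("tf_network.graphml"))
    list(enrichment = enr, consensus = consensus, filtered = filtered,
         network = net)
  })

  ## funnel + manifest ----------------------------------------------------
  jsonlite::write_json(funnel, outp("funnel.json"), auto_unbox = TRUE,
                       digits = NA)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_file <- outp("pipeline_config.json")
  writeLines(cfg_json, cfg_file)
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, outputs))
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   seed = config$seed,
                   checksums = as.list(stats::setNames(unname(sums), outputs)))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(streams = stream_genes, ortho = ortho,
                 secreted = secreted_streams, map = mapres, plasma = plasma,
                 biomarker = biomarker, tfnet = tfnet, funnel = funnel,
                 manifest = manifest))
}
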