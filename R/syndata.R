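# Synthetic study generator: emits every pipeline input (detection
# tables, id maps, ortholog assertions, secretion annotations,
# expression tables, complication sets, plasma quantitation, serum
# biomarker cohort, promoters and motifs, regulator predictions) with a
# known, machine-readable ground truth so each downstream stage can be
# validated without any external download.

NONSECRETION_GO <- c("GO:0005634", "GO:0005739", "GO:0005829")
SERUM_ANALYTES <- c("sFLT1", "MIF", "ANGPT2", "IGF2")
MOUSE_TISSUES <- c("placenta", "brain", "liver", "kidney", "lung")
HUMAN_TISSUES <- c("placenta", "brain", "liver", "kidney", "lung")

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic study. Defaults
#' encode the study conditions the pipeline is designed around: five
#' replicate samples per stream with a 4-of-5 detection filter, a cohort
#' of 10 healthy and 6 GDM pregnancies, a 3.1-fold GDM effect on sFLT1
#' with no effect on MIF (a 210 percent increase of the sFLT1/MIF MoM
#' ratio), and a motif planted in 60 percent of foreground promoters.
#'
#' @param n_genes number of mouse genes (default 500).
#' @param n_samples_per_stream replicate samples per detection stream
#'   (default 5).
#' @param detection_dropout per-(protein, sample) probability that a
#'   truly present protein is not detected (default 0.15).
#' @param lognormal_sigma log-scale SD of abundances (default 0.5).
#' @param n_healthy,n_gdm serum cohort sizes (defaults 10 and 6).
#' @param biomarker_sigma log-scale SD of serum concentrations (default
#'   0.3).
#' @param gdm_effects named positive multipliers applied to GDM
#'   concentrations (default sFLT1 3.1, MIF 1, ANGPT2 1.97, IGF2 1).
#' @param seed integer random seed.
#' @param motif_length PWM length (default 10; long enough that chance
#'   hits at the 60-percent score threshold stay rare in 1.1 kb
#'   promoters, so planted occurrence-rate contrasts are detectable).
#' @param n_promoters foreground/background promoter count (default 60).
#' @param planted_occurrence_rate probability that a foreground promoter
#'   carries the planted motif (default 0.6).
#' @param frac_secreted,frac_one_to_one,frac_one_to_many,frac_expressed_mouse,frac_expressed_human
#'   class fractions of the gene universe.
#' @param n_tissue_enriched genes planted as >10-fold placenta enriched
#'   (default 20).
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 500L,
                       n_samples_per_stream = 5L,
                       detection_dropout = 0.15,
                       lognormal_sigma = 0.5,
                       n_healthy = 10L,
                       n_gdm = 6L,
                       biomarker_sigma = 0.3,
                       gdm_effects = c(sFLT1 = 3.1, MIF = 1,
                                       ANGPT2 = 1.97, IGF2 = 1),
                       seed = 1L,
                       motif_length = 10L,
                       n_promoters = 60L,
                       planted_occurrence_rate = 0.6,
                       frac_secreted = 0.4,
                       frac_one_to_one = 0.78,
                       frac_one_to_many = 0.10,
                       frac_expressed_mouse = 0.9,
                       frac_expressed_human = 0.9,
                       n_tissue_enriched = 20L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_stream = as.integer(n_samples_per_stream),
              detection_dropout = detection_dropout,
              lognormal_sigma = lognormal_sigma,
              n_healthy = as.integer(n_healthy),
              n_gdm = as.integer(n_gdm),
              biomarker_sigma = biomarker_sigma,
              gdm_effects = gdm_effects,
              seed = as.integer(seed),
              motif_length = as.integer(motif_length),
              n_promoters = as.integer(n_promoters),
              planted_occurrence_rate = planted_occurrence_rate,
              frac_secreted = frac_secreted,
              frac_one_to_one = frac_one_to_one,
              frac_one_to_many = frac_one_to_many,
              frac_expressed_mouse = frac_expressed_mouse,
              frac_expressed_human = frac_expressed_human,
              n_tissue_enriched = as.integer(n_tissue_enriched))
  counts <- c("n_genes", "n_samples_per_stream", "n_healthy", "n_gdm",
              "motif_length", "n_promoters")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stopf("invalid config: %s must be a count >= 1", f)
  probs <- c("detection_dropout", "planted_occurrence_rate",
             "frac_secreted", "frac_one_to_one", "frac_one_to_many",
             "frac_expressed_mouse", "frac_expressed_human")
  for (f in probs)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stopf("invalid config: %s must be a probability in [0, 1]", f)
  for (f in c("lognormal_sigma", "biomarker_sigma"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stopf("invalid config: %s must be >= 0", f)
  if (cfg$frac_one_to_one + cfg$frac_one_to_many > 1)
    stopf("invalid config: frac_one_to_one + frac_one_to_many must be <= 1")
  if (any(cfg$gdm_effects <= 0))
    stopf("invalid config: gdm_effects must be > 0")
  if (cfg$motif_length < 4L)
    stopf("invalid config: motif_length must be >= 4")
  structure(cfg, class = "sim_config")
}

rlnorm_med <- function(n, median, sigma) {
  median * exp(stats::rnorm(n, 0, sigma))
}

#' Generate a serum biomarker cohort
#'
#' Simulates per-subject serum concentrations of sFLT1, MIF, ANGPT2 and
#' IGF2 at gestational weeks 12 and 28 for healthy and GDM pregnancies.
#' Concentrations are log-normal around week- and analyte-specific
#' healthy medians; GDM subjects' concentrations are multiplied by the
#' analyte's effect. The healthy medians encode the expected gestational
#' profile (MIF and ANGPT2 decline from week 12 to 28).
#'
#' @param config a [sim_config()] (uses `n_healthy`, `n_gdm`,
#'   `biomarker_sigma`).
#' @param effects named positive multipliers per analyte (default taken
#'   from `config$gdm_effects`).
#' @return Long data.frame `subject`, `group`, `week`, `analyte`,
#'   `concentration`.
#' @export
generate_biomarker_cohort <- function(config, effects = config$gdm_effects) {
  set.seed(config$seed)
  if (config$n_healthy < 2L || config$n_gdm < 2L)
    stopf("invalid config: n_healthy and n_gdm must be >= 2")
  if (any(effects <= 0))
    stopf("effect multipliers must be > 0")
  if (!all(SERUM_ANALYTES %in% names(effects)))
    stopf("effects must name every analyte: %s",
          paste(SERUM_ANALYTES, collapse = ", "))
  healthy_median <- rbind(
    `12` = c(sFLT1 = 1200, MIF = 40, ANGPT2 = 18, IGF2 = 600),
    `28` = c(sFLT1 = 2500, MIF = 25, ANGPT2 = 12, IGF2 = 620))
  subjects <- c(sprintf("H%03d", seq_len(config$n_healthy)),
                sprintf("G%03d", seq_len(config$n_gdm)))
  groups <- rep(c("healthy", "GDM"), c(config$n_healthy, config$n_gdm))
  grid <- expand.grid(subject = subjects, week = c(12L, 28L),
                      analyte = SERUM_ANALYTES, stringsAsFactors = FALSE)
  grid$group <- groups[match(grid$subject, subjects)]
  med <- healthy_median[cbind(as.character(grid$week), grid$analyte)]
  eff <- ifelse(grid$group == "GDM", effects[grid$analyte], 1)
  grid$concentration <- rlnorm_med(nrow(grid), med * eff,
                                   config$biomarker_sigma)
  grid[, c("subject", "group", "week", "analyte", "concentration")]
}

random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

plant_motif <- function(seq, consensus) {
  L <- nchar(consensus)
  pos <- sample.int(nchar(seq) - L + 1L, 1L)
  paste0(substr(seq, 1L, pos - 1L), consensus,
         substr(seq, pos + L, nchar(seq)))
}

random_pwm <- function(id, length, major = 0.85) {
  consensus <- sample(4L, length, replace = TRUE)
  mat <- matrix((1 - major) / 3, nrow = 4L, ncol = length)
  mat[cbind(consensus, seq_len(length))] <- major
  new_pwm(id, mat)
}

detection_matrix <- function(accessions, n_samples, dropout, sigma, prefix) {
  m <- matrix(rlnorm_med(length(accessions) * n_samples, 1e6, sigma),
              nrow = length(accessions),
              dimnames = list(accessions, paste0(prefix, seq_len(n_samples))))
  if (dropout > 0)
    m[matrix(stats::runif(length(m)) < dropout, nrow = nrow(m))] <- 0
  m
}

#' Generate the full synthetic study
#'
#' Writes every pipeline input table to `dir` (TSV with header rows,
#' FASTA promoters, MEME motifs) together with the ground truth and the
#' configuration as JSON. The ground truth file is a validation record:
#' the pipeline itself never reads it.
#'
#' With `detection_dropout = 0` every true protein is detected in all
#' samples of every stream, and the pipeline's shared secretome equals
#' the planted `true_shared_secretome` exactly.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with `truth`, `paths` (named file paths)
#'   and `config`.
#' @export
generate_study <- function(config, dir) {
  if (!inherits(config, "sim_config"))
    stopf("config must be a sim_config object")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("Mgene%04d", seq_len(n))
  human_of <- sprintf("HGENE%04d", seq_len(n))
  names(human_of) <- genes

  ## ortholog classes ------------------------------------------------
  cls <- sample(c("one_to_one", "one_to_many", "unmapped"), n,
                replace = TRUE,
                prob = c(config$frac_one_to_one, config$frac_one_to_many,
                         1 - config$frac_one_to_one - config$frac_one_to_many))
  names(cls) <- genes
  one_to_one <- genes[cls == "one_to_one"]
  one_to_many <- genes[cls == "one_to_many"]
  unmapped <- genes[cls == "unmapped"]
  pairs <- human_of[one_to_one]

  ## planted gene classes --------------------------------------------
  secreted <- sort(sample(genes, round(config$frac_secreted * n)))
  expressed_mouse <- sort(sample(genes, round(config$frac_expressed_mouse * n)))
  expressed_human <- sort(sample(unname(pairs),
                                 round(config$frac_expressed_human *
                                         length(pairs))))
  shared <- sort(intersect(intersect(secreted, expressed_mouse),
                           one_to_one[pairs %in% expressed_human]))

  ## accessions and id map -------------------------------------------
  acc <- sprintf("ACC%05d", seq_len(n))
  names(acc) <- genes
  n_dup <- max(1L, round(0.02 * n))
  dup_genes <- sort(sample(genes, n_dup))
  dup_acc <- sprintf("ACCD%04d", seq_len(n_dup))
  idmap <- data.frame(accession = c(unname(acc), dup_acc),
                      gene = c(genes, dup_genes),
                      stringsAsFactors = FALSE)
  orphan_acc <- sprintf("ACCX%04d", 1:10)

  ## detection streams ------------------------------------------------
  all_acc <- c(unname(acc), dup_acc, orphan_acc)
  streams <- c("cells", "media", "sorted")
  detection <- lapply(streams, function(s)
    detection_matrix(all_acc, config$n_samples_per_stream,
                     config$detection_dropout, config$lognormal_sigma,
                     paste0(s, "_s")))
  names(detection) <- streams

  ## secretion annotations --------------------------------------------
  go_terms <- character(n)
  sp <- logical(n)
  er <- logical(n)
  route <- sample(c("conventional", "unconventional", "both"), n,
                  replace = TRUE, prob = c(0.4, 0.4, 0.2))
  extra_go <- stats::runif(n) < 0.2
  er_trap <- stats::runif(n) < 0.1
  for (i in seq_len(n)) {
    g <- genes[i]
    terms <- if (extra_go[i]) sample(NONSECRETION_GO, 1L) else character(0)
    if (g %in% secreted) {
      if (route[i] %in% c("conventional", "both")) { sp[i] <- TRUE; er[i] <- FALSE }
      if (route[i] %in% c("unconventional", "both"))
        terms <- c(terms, sample(secretion_go_terms(), 1L))
    } else if (er_trap[i]) {
      sp[i] <- TRUE; er[i] <- TRUE
    }
    go_terms[i] <- paste(terms, collapse = ";")
  }
  annotations <- data.frame(gene = genes, signal_peptide = sp,
                            er_lumen = er, go_terms = go_terms,
                            stringsAsFactors = FALSE)

  ## ortholog assertions ----------------------------------------------
  sources <- c("MGI", "NCBI", "Ensembl")
  arows <- list()
  for (g in one_to_one) {
    use <- stats::runif(3) < 0.9
    if (!any(use)) use[sample.int(3, 1L)] <- TRUE
    arows[[g]] <- data.frame(mouse_gene = g, human_gene = human_of[[g]],
                             source = sources[use], stringsAsFactors = FALSE)
  }
  for (g in one_to_many) {
    alt <- paste0(human_of[[g]], "ALT")
    if (stats::runif(1) < 0.5) {
      # one source asserts two partners
      arows[[g]] <- data.frame(mouse_gene = g,
                               human_gene = c(human_of[[g]], alt),
                               source = "MGI", stringsAsFactors = FALSE)
    } else {
      # two sources conflict
      arows[[g]] <- data.frame(mouse_gene = g,
                               human_gene = c(human_of[[g]], alt),
                               source = c("MGI", "NCBI"),
                               stringsAsFactors = FALSE)
    }
  }
  assertions <- do.call(rbind, arows)
  rownames(assertions) <- NULL

  ## expression tables -------------------------------------------------
  n_enr <- min(config$n_tissue_enriched, length(shared))
  enriched <- sort(sample(shared, n_enr))
  other_m <- matrix(rlnorm_med(n * (length(MOUSE_TISSUES) - 1L), 30, 0.5),
                    nrow = n)
  placenta_m <- numeric(n)
  max_other <- apply(other_m, 1L, max)
  in_expr <- genes %in% expressed_mouse
  placenta_m[in_expr] <- 2 * max_other[in_expr]
  placenta_m[genes %in% enriched] <- 12 * max_other[genes %in% enriched]
  mouse_expr <- cbind(placenta = placenta_m, other_m)
  colnames(mouse_expr) <- MOUSE_TISSUES
  rownames(mouse_expr) <- genes

  hgenes <- sort(unique(unname(pairs)))
  other_h <- matrix(rlnorm_med(length(hgenes) * (length(HUMAN_TISSUES) - 1L),
                               30, 0.5), nrow = length(hgenes))
  placenta_h <- numeric(length(hgenes))
  placenta_h[hgenes %in% expressed_human] <-
    rlnorm_med(sum(hgenes %in% expressed_human), 50, 0.5)
  human_expr <- cbind(placenta = placenta_h, other_h)
  colnames(human_expr) <- HUMAN_TISSUES
  rownames(human_expr) <- hgenes

  ## complication sets and overlays ------------------------------------
  core <- sample(expressed_human, min(3L, length(expressed_human)))
  comp_sets <- lapply(COMPLICATION_LABELS, function(l)
    sort(unique(c(core, sample(expressed_human,
                               min(30L, length(expressed_human)))))))
  names(comp_sets) <- COMPLICATION_LABELS
  shared_h <- unname(pairs[shared])
  organoid <- sort(sample(expressed_human, min(40L, length(expressed_human))))
  stb_expressed <- sort(sample(expressed_human,
                               round(0.9 * length(expressed_human))))
  damp <- sort(sample(expressed_human, min(15L, length(expressed_human))))

  ## plasma quantitation ------------------------------------------------
  n_plasma <- min(45L, length(secreted))
  plasma_genes <- sort(sample(secreted, n_plasma))
  n_up <- min(24L, n_plasma)
  up_idx <- sort(sample.int(n_plasma, n_up))
  fold <- exp(stats::runif(n_plasma, log(0.8), log(1.25)))
  fold[up_idx] <- exp(stats::runif(n_up, log(1.5), log(52)))
  names(fold) <- plasma_genes
  animals <- c(paste0("NP", 1:3), paste0("P", 1:8))
  plasma_groups <- data.frame(animal = animals,
                              group = rep(c("NP", "P"), c(3L, 8L)),
                              stringsAsFactors = FALSE)
  base <- rlnorm_med(n_plasma, 1, config$lognormal_sigma)
  norm_true <- matrix(0, n_plasma, length(animals),
                      dimnames = list(plasma_genes, animals))
  for (j in seq_along(animals)) {
    f <- if (plasma_groups$group[j] == "P") fold else rep(1, n_plasma)
    norm_true[, j] <- base * f *
      exp(stats::rnorm(n_plasma, 0, config$lognormal_sigma))
  }
  standard <- rlnorm_med(length(animals), 1e5, 0.3)
  plasma_raw <- rbind(sweep(norm_true, 2L, standard, "*"),
                      `__STANDARD__` = standard)

  ## serum biomarker cohort ---------------------------------------------
  serum <- generate_biomarker_cohort(config)

  ## promoters and motifs -----------------------------------------------
  prom_len <- 1101L  # -1000 .. +100 around the TSS
  pwms <- list(random_pwm("TF01", config$motif_length),
               random_pwm("TF02", config$motif_length),
               random_pwm("TF03", config$motif_length))
  names(pwms) <- vapply(pwms, `[[`, character(1), "id")
  fg_pool <- if (length(shared_h) >= config$n_promoters)
    sort(sample(shared_h, config$n_promoters)) else sort(shared_h)
  bg_ids <- sprintf("BGGENE%04d", seq_len(config$n_promoters))
  fg_seq <- vapply(fg_pool, function(g) random_dna(prom_len), character(1))
  bg_seq <- vapply(bg_ids, function(g) random_dna(prom_len), character(1))
  planted <- names(fg_seq)[stats::runif(length(fg_seq)) <
                             config$planted_occurrence_rate]
  cons1 <- pwm_consensus(pwms$TF01)
  for (g in planted) fg_seq[[g]] <- plant_motif(fg_seq[[g]], cons1)
  bg_planted <- names(bg_seq)[stats::runif(length(bg_seq)) < 0.05]
  for (g in bg_planted) bg_seq[[g]] <- plant_motif(bg_seq[[g]], cons1)
  # TF03 occurs at a background rate everywhere: present, not enriched
  cons3 <- pwm_consensus(pwms$TF03)
  for (g in names(fg_seq)[stats::runif(length(fg_seq)) < 0.05])
    fg_seq[[g]] <- plant_motif(fg_seq[[g]], cons3)
  true_tf_edges <- data.frame(tf = rep("TF01", length(planted)),
                              target = planted, stringsAsFactors = FALSE)

  ## upstream-regulator predictions --------------------------------------
  upstream <- rbind(
    data.frame(tf = "TF01",
               target = unique(c(planted,
                                 sample(fg_pool, min(5L, length(fg_pool))))),
               stringsAsFactors = FALSE),
    data.frame(tf = "TF02",
               target = sample(fg_pool, min(8L, length(fg_pool))),
               stringsAsFactors = FALSE),
    data.frame(tf = "TFX9",
               target = sample(fg_pool, min(6L, length(fg_pool))),
               stringsAsFactors = FALSE))
  stb_with_tfs <- sort(unique(c(stb_expressed, "TF01", "TF02")))
  complication_tfs <- data.frame(tf = c("TF01", "TF01"),
                                 complication = c("GDM", "PE"),
                                 stringsAsFactors = FALSE)

  ## write everything -----------------------------------------------------
  p <- function(f) file.path(dir, f)
  paths <- c(
    detection_cells = p("detection_cells.tsv"),
    detection_media = p("detection_media.tsv"),
    detection_sorted = p("detection_sorted.tsv"),
    idmap = p("idmap.tsv"),
    ortholog_assertions = p("ortholog_assertions.tsv"),
    secretion_annotations = p("secretion_annotations.tsv"),
    mouse_expression = p("mouse_expression.tsv"),
    human_expression = p("human_expression.tsv"),
    complication_sets = p("complication_sets.tsv"),
    organoid_secretome = p("organoid_secretome.txt"),
    stb_expressed = p("stb_expressed.txt"),
    damp_genes = p("damp_genes.txt"),
    plasma_quant = p("plasma_quant.tsv"),
    plasma_groups = p("plasma_groups.tsv"),
    serum_biomarkers = p("serum_biomarkers.tsv"),
    promoters = p("promoters.fasta"),
    motifs = p("motifs.meme"),
    upstream_regulators = p("upstream_regulators.tsv"),
    complication_tfs = p("complication_tfs.tsv"),
    ground_truth = p("ground_truth.json"),
    sim_config = p("sim_config.json"))
  for (s in streams)
    write_matrix_tsv(detection[[s]], paths[[paste0("detection_", s)]],
                     id_name = "accession")
  write_tsv(idmap, paths[["idmap"]])
  write_tsv(assertions, paths[["ortholog_assertions"]])
  write_tsv(annotations, paths[["secretion_annotations"]])
  write_matrix_tsv(mouse_expr, paths[["mouse_expression"]], id_name = "gene")
  write_matrix_tsv(human_expr, paths[["human_expression"]], id_name = "gene")
  write_tsv(data.frame(
    complication = rep(names(comp_sets), lengths(comp_sets)),
    gene = unlist(comp_sets, use.names = FALSE),
    stringsAsFactors = FALSE), paths[["complication_sets"]])
  write_gene_set(organoid, paths[["organoid_secretome"]])
  write_gene_set(stb_with_tfs, paths[["stb_expressed"]])
  write_gene_set(damp, paths[["damp_genes"]])
  write_matrix_tsv(plasma_raw, paths[["plasma_quant"]], id_name = "protein")
  write_tsv(plasma_groups, paths[["plasma_groups"]])
  write_tsv(serum, paths[["serum_biomarkers"]])
  seqs <- Biostrings::DNAStringSet(c(fg_seq, bg_seq))
  Biostrings::writeXStringSet(seqs, paths[["promoters"]], width = 80L)
  write_meme(pwms, paths[["motifs"]])
  write_tsv(upstream, paths[["upstream_regulators"]])
  write_tsv(complication_tfs, paths[["complication_tfs"]])

  truth <- list(
    true_secreted = secreted,
    true_ortholog_pairs = as.list(pairs),
    true_one_to_many = one_to_many,
    true_unmapped = unmapped,
    true_placenta_expressed_mouse = expressed_mouse,
    true_placenta_expressed_human = expressed_human,
    true_tissue_enriched_mouse = enriched,
    true_shared_secretome = shared,
    true_shared_secretome_human = sort(shared_h),
    true_pregnancy_fold = as.list(fold),
    true_gdm_effects = as.list(config$gdm_effects),
    true_tf_edges = true_tf_edges,
    true_foreground_promoters = fg_pool,
    true_complication_sets = comp_sets)
  jsonlite::write_json(truth, paths[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(unclass(config), paths[["sim_config"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(list(truth = truth, paths = paths, config = config))
}
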