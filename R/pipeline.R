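# End-to-end orchestration: (optional) forge -> translated search ->
# annotate-tune-iterate -> catalytic classification -> orthology and
# family-status calls -> trees for ambiguous/multi-copy families -> a
# reproducible artifact directory. All randomness flows from one master
# seed; identical config + seed give byte-identical outputs.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations. Either supply `forge` (a
#' [forge_config()]) to generate genomes, or `genomes` directly.
#'
#' @param seeds seed-protein tibble.
#' @param forge optional [forge_config()].
#' @param genomes optional genome tibble (`contig`, `species`, `sequence`).
#' @param bati a [bati_config()].
#' @param rbh_margin margin for [rbh()].
#' @param max_separation tandem-call separation in nt.
#' @param bootstrap_replicates,consensus_threshold tree stage settings
#'   (strictly-more-than display rule).
#' @param seed master RNG seed; stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seeds, forge = NULL, genomes = NULL,
                            bati = bati_config(), rbh_margin = 0L,
                            max_separation = 1e6,
                            bootstrap_replicates = 100L,
                            consensus_threshold = 50L, seed = 1L) {
  if (is.null(forge) && is.null(genomes))
    abort("supply either a forge plan or genomes")
  structure(list(seeds = validate_seed_proteins(seeds), forge = forge,
                 genomes = genomes, bati = bati,
                 rbh_margin = as.integer(rbh_margin),
                 max_separation = max_separation,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 consensus_threshold = as.integer(consensus_threshold),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' The demonstration study: three species, twelve protease families
#'
#' A forge plan exercising every comparative pattern the pipeline calls:
#' one family tandem-duplicated in species 1 only, one family with seven
#' dispersed copies in species 1 (one of them a catalytic knockout), one
#' family triplicated in species 1 and 2 but single-copy in species 3,
#' two families absent from species 1 and 2, and seven ordinary
#' single-copy families; protein divergence 0.15.
#'
#' @param seed master RNG seed.
#' @param divergence expected per-copy amino-acid divergence.
#' @return a [pipeline_config()].
#' @export
demo_config <- function(seed = 1L, divergence = 0.15) {
  fams <- c("CASPL", "ACRL", "MALTL", "GZMKL", "ELAL", "BACEL", "GZMAL",
            "MMPL", "ADAML", "PGAL", "CTSL", "PRSSL")
  classes <- c("cysteine", "serine", "cysteine", "serine", "serine",
               "aspartyl", "serine", "metallo", "metallo", "aspartyl",
               "serine", "serine")
  seeds <- demo_seed_set(fams, protein_length = c(160, 210),
                         classes = classes, rng_seed = child_seed(seed, "seeds"))
  species <- c("sp1", "sp2", "sp3")
  plan <- bind_rows(
    tibble(species = "sp1", family = "CASPL", copies = 2L, placement = "tandem"),
    tibble(species = c("sp2", "sp3"), family = "CASPL", copies = 1L,
           placement = "dispersed"),
    tibble(species = "sp1", family = "ACRL", copies = 7L, placement = "dispersed"),
    tibble(species = c("sp2", "sp3"), family = "ACRL", copies = 1L,
           placement = "dispersed"),
    tibble(species = c("sp1", "sp2"), family = "MALTL", copies = 3L,
           placement = "dispersed"),
    tibble(species = "sp3", family = "MALTL", copies = 1L, placement = "dispersed"),
    tibble(species = "sp3", family = "GZMKL", copies = 1L, placement = "dispersed"),
    tibble(species = "sp3", family = "ELAL", copies = 1L, placement = "dispersed"),
    tidyr::expand_grid(species = species,
                       family = c("BACEL", "GZMAL", "MMPL", "ADAML", "PGAL",
                                  "CTSL", "PRSSL")) |>
      mutate(copies = 1L, placement = "dispersed"))
  forge <- forge_config(
    species = species, plan = plan, divergence = divergence,
    knockouts = tibble(species = "sp1", family = "ACRL", copy_index = 1L,
                       mode = "catalytic_substitution"),
    rng_seed = child_seed(seed, "forge"))
  pipeline_config(seeds = seeds, forge = forge, seed = seed)
}

#' Run the full degradome-annotation pipeline
#'
#' Executes forge (when configured), per-species search + annotation,
#' catalytic classification, cross-species reciprocal-best-hit orthology,
#' tandem/expansion detection and the family-status matrix, and bootstrap
#' consensus trees for families that are multi-copy or contain
#' no-clear-orthologue genes. When `outdir` is given, writes the full
#' artifact set (GFF3 models, protein FASTA, HSP/bgmix/orthology/status
#' TSVs, Newick trees, run manifest).
#'
#' @param config a [pipeline_config()].
#' @param outdir optional artifact directory (created if needed).
#' @return a `degradome_run` object.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  forged <- NULL
  if (!is.null(config$forge)) {
    forged <- forge_genome(config$seeds, config$forge)
    genomes <- forged$genomes
  } else genomes <- config$genomes
  species <- unique(genomes$species)
  log_stage <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))

  models <- list(); hsps <- list()
  for (sp in species) {
    g_sp <- filter(genomes, species == sp)
    m <- bati_iterate(config$seeds, g_sp, config$bati)
    hsps[[sp]] <- attr(m, "hsps")
    models[[sp]] <- m
    log_stage("annotate", "%s: %d models from %d HSPs", sp, nrow(m),
              nrow(hsps[[sp]]) %||% 0L)
  }
  models <- bind_rows(models)
  hsps <- bind_rows(hsps)

  cls <- classify_models(models, config$seeds)
  models <- cls$models

  proteome <- models |>
    filter(nchar(gsub("\\*", "", protein)) > 0) |>
    transmute(id = model_id, species = species, family = family,
              protein = gsub("\\*", "", protein))
  orthology <- list()
  pairs <- if (length(species) > 1) utils::combn(sort(species), 2, simplify = FALSE)
           else list()
  for (pr in pairs) {
    pa <- filter(proteome, species == pr[1])
    pb <- filter(proteome, species == pr[2])
    if (!nrow(pa) || !nrow(pb)) next
    calls <- rbh(pa, pb, margin = config$rbh_margin) |>
      mutate(species_a = pr[1], species_b = pr[2])
    orthology[[paste(pr, collapse = "-")]] <- calls
  }
  orthology <- bind_rows(orthology)
  log_stage("orthology", "%d RBH pairs / %d calls",
            sum(orthology$call == "rbh_orthologue"), nrow(orthology))

  tandem <- detect_tandem_duplication(models, config$max_separation)
  fam_status <- detect_family_status(models, config$seeds, species)
  status_matrix <- family_status_matrix(fam_status)

  # trees for families that are multi-copy anywhere or contain genes
  # without a clear orthologue
  ambiguous <- unique(c(
    fam_status$family[fam_status$copy_count >= 2],
    proteome$family[proteome$id %in%
                      orthology$gene_a[orthology$call == "no_clear_orthologue"]]))
  trees <- list()
  for (fam in sort(ambiguous)) {
    member <- filter(proteome, family == fam)
    srow <- config$seeds[match(fam, config$seeds$family), ]
    taxa <- bind_rows(select(member, id, protein),
                      tibble(id = srow$id, protein = srow$sequence))
    if (nrow(taxa) < 4) next
    aln <- progressive_align(tibble(taxon = taxa$id, sequence = taxa$protein))
    reps <- bootstrap_resample(aln, config$bootstrap_replicates,
                               rng_seed = child_seed(config$seed,
                                                     paste0("boot_", fam)))
    per_rep <- lapply(reps, parsimony_search, starts = 1L)
    cons <- majority_consensus(per_rep, config$consensus_threshold)
    trees[[fam]] <- root_with_outgroup(cons, srow$id)
    log_stage("phylo", "%s: %d taxa", fam, nrow(taxa))
  }

  run <- structure(list(
    models = models, hsps = hsps, classification = cls$classification,
    orthology = orthology, tandem = tandem, family_status = fam_status,
    status_matrix = status_matrix, trees = trees, genomes = genomes,
    truth = forged$truth, seeds = config$seeds, config = config,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "degradome_run")
  if (!is.null(outdir)) write_run_artifacts(run, outdir)
  run
}

#' Write the artifact directory of a pipeline run
#'
#' @param run a `degradome_run`.
#' @param outdir directory path.
#' @return `outdir`, invisibly.
#' @export
write_run_artifacts <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, paste0(...))
  for (sp in unique(run$models$species)) {
    m <- filter(run$models, species == sp)
    write_models_gff3(m, p(sp, "_models.gff3"))
    if (nrow(m)) write_proteins_fasta(m, p(sp, "_proteins.fa"))
  }
  write_hsps_tsv(run$hsps, p("hsps.tsv"))
  readr::write_tsv(bgmix_report(run$hsps, run$models) |>
                     select(-qaln, -saln), p("bgmix.tsv"))
  readr::write_tsv(run$orthology, p("orthology.tsv"))
  readr::write_tsv(run$classification, p("classification.tsv"))
  readr::write_tsv(run$family_status, p("family_status.tsv"))
  readr::write_tsv(run$status_matrix, p("status_matrix.tsv"))
  if (length(run$trees))
    write_trees_newick(setNames(run$trees, NULL), p("trees.nwk"))
  if (!is.null(run$truth)) {
    write_truth_tsv(run$truth, p("truth.tsv"))
    write_truth_gff3(run$truth, p("truth.gff3"))
    write_genomes_fasta(run$genomes, p("genomes.fa"))
  }
  manifest <- list(
    package = "degradomics",
    version = as.character(utils::packageVersion("degradomics")),
    seed = run$config$seed,
    config_hash = rlang::hash(run$config),
    n_models = nrow(run$models), n_hsps = nrow(run$hsps),
    n_trees = length(run$trees),
    model_ids_by_family = split(run$models$model_id, run$models$family))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(outdir)
}

#' @export
print.degradome_run <- function(x, ...) {
  cat("<degradome_run>\n")
  cat(sprintf("  species: %s\n", paste(unique(x$models$species), collapse = ", ")))
  cat(sprintf("  models: %d (%d intact, %d non-peptidase, %d pseudogene)\n",
              nrow(x$models), sum(x$models$status == "intact"),
              sum(x$models$status == "non_peptidase_homolog"),
              sum(x$models$status == "pseudogene_fragment")))
  cat(sprintf("  RBH orthologue pairs: %d\n",
              sum(x$orthology$call == "rbh_orthologue")))
  cat(sprintf("  trees: %d families\n", length(x$trees)))
  invisible(x)
}

# ---- evaluation against forge truth -------------------------------------

# family-status calls implied by a truth table (same mapping as the
# model-based calls)
truth_family_status <- function(truth, seeds, species) {
  detect_family_status(truth, seeds, species)
}

#' Score a pipeline run against the forge truth
#'
#' Per-species precision and recall of locus discovery (a truth locus is
#' recovered by a same-family model on the same contig and strand whose
#' extent covers at least half of it), the exact-match rate of the
#' family-status matrix, and the confusion matrix of peptidase-status
#' calls over recovered loci.
#'
#' @param run a `degradome_run` (must carry forge truth, or pass `truth`).
#' @param truth optional truth table overriding `run$truth`.
#' @param min_overlap fraction of the truth extent a model must cover.
#' @return list of tibbles: `locus_metrics`, `status_metrics`,
#'   `status_confusion`, plus scalar `status_exact_rate`.
#' @export
compare_to_truth <- function(run, truth = NULL, min_overlap = 0.5) {
  truth <- truth %||% run$truth
  if (is.null(truth)) abort("no truth table available")
  models <- run$models
  truth <- truth |>
    rowwise() |>
    mutate(tstart = min(exons[, 1]), tend = max(exons[, 2])) |>
    ungroup()
  match_one <- function(tr) {
    hit <- models |>
      filter(species == tr$species, contig == tr$contig, strand == tr$strand,
             family == tr$family) |>
      mutate(ov = pmax(0, pmin(gend, tr$tend) - pmax(gstart, tr$tstart)) /
               (tr$tend - tr$tstart)) |>
      filter(ov >= min_overlap) |>
      arrange(desc(ov))
    if (nrow(hit)) hit$model_id[1] else NA_character_
  }
  truth$matched_model <- vapply(seq_len(nrow(truth)),
                                function(i) match_one(truth[i, ]), "")
  locus_metrics <- truth |>
    group_by(species) |>
    summarise(n_truth = n(), n_recovered = sum(!is.na(matched_model)),
              recall = n_recovered / n_truth, .groups = "drop") |>
    left_join(models |>
                group_by(species) |>
                summarise(n_models = n(), .groups = "drop"),
              by = "species") |>
    mutate(n_matched_models = vapply(species, function(sp)
      length(unique(stats::na.omit(truth$matched_model[truth$species == sp]))), 0L),
      precision = ifelse(n_models > 0, n_matched_models / n_models, NA_real_))
  species <- unique(truth$species)
  want <- truth_family_status(truth, run$seeds, species)
  got <- detect_family_status(models, run$seeds, species)
  status_cmp <- want |>
    select(family, species, truth_status = status) |>
    left_join(select(got, family, species, called_status = status),
              by = c("family", "species")) |>
    mutate(match = truth_status == called_status)
  confusion <- truth |>
    filter(!is.na(matched_model)) |>
    left_join(select(models, model_id, predicted = status),
              by = c("matched_model" = "model_id")) |>
    count(truth_status = status, predicted)
  list(locus_metrics = locus_metrics,
       status_metrics = status_cmp,
       status_exact_rate = mean(status_cmp$match),
       status_confusion = confusion,
       locus_table = select(truth, species, family, locus_id, matched_model))
}
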