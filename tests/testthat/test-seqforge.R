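# synthetic-genome forge: identity round trips, event bookkeeping,
# determinism, realized divergence

test_that("zero-divergence forge reproduces the seed protein exactly", {
  fg <- forge_single(n_fam = 1, divergence = 0, rng_seed = 11)
  expect_equal(nrow(fg$truth), 1L)
  expect_equal(fg$truth$status, "intact")
  expect_equal(fg$truth$event, "single")
  tp <- truth_proteins(fg$genomes, fg$truth)
  expect_identical(tp$protein_extracted, fg$seeds$sequence[1])
  expect_identical(tp$protein, tp$protein_extracted)
})

test_that("splicing + translating every truth locus matches the stored protein", {
  seeds <- tiny_seeds(3)
  plan <- dplyr::bind_rows(
    tibble::tibble(species = "spA", family = seeds$family[1], copies = 2L,
                   placement = "tandem"),
    tibble::tibble(species = "spA", family = seeds$family[2:3], copies = 1L,
                   placement = "dispersed"))
  cfg <- forge_config(species = "spA", plan = plan, divergence = 0.2,
                      rng_seed = 5)
  fg <- forge_genome(seeds, cfg)
  tp <- truth_proteins(fg$genomes, fg$truth)
  expect_identical(tp$protein, tp$protein_extracted)
  # exon spans disjoint, ordered, GT/AG introns
  for (i in seq_len(nrow(fg$truth))) {
    ex <- fg$truth$exons[[i]]
    expect_true(all(diff(ex[, 1]) > 0))
    expect_true(all(ex[, 2] > ex[, 1]))
    if (nrow(ex) > 1) expect_true(all(ex[-1, 1] >= head(ex[, 2], -1) + 20))
    g <- fg$genomes$sequence[fg$genomes$contig == fg$truth$contig[i]]
    for (j in seq_len(nrow(ex) - 1)) {
      a <- ex[j, 2]; b <- ex[j + 1, 1]
      don <- substr(g, a + 1, a + 2); acc <- substr(g, b - 1, b)
      if (fg$truth$strand[i] == "+") {
        expect_identical(don, "GT"); expect_identical(acc, "AG")
      } else {
        expect_identical(don, "CT"); expect_identical(acc, "AC")
      }
    }
  }
})

test_that("tandem plan yields adjacent same-contig loci flagged tandem_dup", {
  seeds <- tiny_seeds(1)
  plan <- tibble::tibble(species = "spA", family = seeds$family, copies = 2L,
                         placement = "tandem")
  cfg <- forge_config(species = "spA", plan = plan, rng_seed = 2)
  fg <- forge_genome(seeds, cfg)
  expect_equal(nrow(fg$truth), 2L)
  expect_equal(unique(fg$truth$contig), fg$truth$contig[1])
  expect_setequal(fg$truth$event, "tandem_dup")
  expect_equal(nrow(fg$genomes), 1L)
})

test_that("dispersed copies land on one contig each", {
  seeds <- tiny_seeds(1)
  plan <- tibble::tibble(species = "spA", family = seeds$family, copies = 4L,
                         placement = "dispersed")
  fg <- forge_genome(seeds, forge_config("spA", plan, rng_seed = 3))
  expect_equal(nrow(fg$genomes), 4L)
  expect_equal(length(unique(fg$truth$contig)), 4L)
  expect_setequal(fg$truth$event, "dispersed_dup")
})

test_that("forge is bit-for-bit reproducible under a fixed seed", {
  a <- forge_single(n_fam = 2, rng_seed = 42)
  b <- forge_single(n_fam = 2, rng_seed = 42)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$truth, b$truth)
  c <- forge_single(n_fam = 2, rng_seed = 43)
  expect_false(identical(a$genomes$sequence, c$genomes$sequence))
})

test_that("knockout_protein edits exactly the catalytic positions", {
  seeds <- tiny_seeds(4)   # classes cycle: serine, cysteine, aspartyl, metallo
  ser <- seeds[seeds$catalytic_class == "serine", ]
  pos <- ser$catalytic_positions[[1]]
  withr::with_seed(1, {
    ko <- knockout_protein(ser$sequence, pos, "catalytic_substitution")
    diffs <- which(strsplit(ko, "")[[1]] != strsplit(ser$sequence, "")[[1]])
    expect_equal(diffs - 1L, pos)      # all three triad residues changed
    expect_length(diffs, 3L)

    cys <- seeds[seeds$catalytic_class == "cysteine", ]
    ko2 <- knockout_protein(cys$sequence, cys$catalytic_positions[[1]],
                            "catalytic_substitution")
    expect_equal(sum(strsplit(ko2, "")[[1]] != strsplit(cys$sequence, "")[[1]]), 2L)
  })
  expect_identical(knockout_protein(ser$sequence, integer(),
                                    "catalytic_substitution"), ser$sequence)
  expect_identical(knockout_protein(ser$sequence, pos, "inframe_stop"),
                   ser$sequence)
  expect_error(knockout_protein("", 0L, "catalytic_substitution"))
})

test_that("knockout modes propagate to truth status and protein", {
  seeds <- tiny_seeds(1)
  plan <- tibble::tibble(species = "spA", family = seeds$family, copies = 2L,
                         placement = "dispersed")
  cfg <- forge_config(
    "spA", plan, divergence = 0.1,
    knockouts = tibble::tibble(species = "spA", family = seeds$family,
                               copy_index = 1:2,
                               mode = c("catalytic_substitution", "inframe_stop")),
    rng_seed = 9)
  fg <- forge_genome(seeds, cfg)
  expect_setequal(fg$truth$event, "knockout")
  st <- setNames(fg$truth$status, fg$truth$locus_id)
  expect_equal(unname(st[grepl("_c1$", names(st))]), "non_peptidase_homolog")
  expect_equal(unname(st[grepl("_c2$", names(st))]), "pseudogene_fragment")
  # the stop knockout's implanted protein really contains a stop
  expect_match(fg$truth$protein[fg$truth$status == "pseudogene_fragment"],
               "\\*")
  # catalytic knockout: substitutions exactly at catalytic positions
  ko <- fg$truth[fg$truth$status == "non_peptidase_homolog", ]
  tp <- truth_proteins(fg$genomes, fg$truth)
  expect_identical(tp$protein, tp$protein_extracted)
})

test_that("realized divergence tracks the configured expectation", {
  seeds <- tiny_seeds(1, len = c(200, 200))
  plan <- tibble::tibble(species = "spA", family = seeds$family, copies = 60L,
                         placement = "dispersed")
  fg <- forge_genome(seeds, forge_config("spA", plan, divergence = 0.2,
                                         rng_seed = 8))
  ref <- strsplit(seeds$sequence, "")[[1]]
  div <- vapply(fg$truth$protein, function(p)
    mean(strsplit(p, "")[[1]] != ref), 0)
  expect_gt(mean(div), 0.2 * 0.5)
  expect_lt(mean(div), 0.2 * 1.5)
  # catalytic residues never touched outside knockouts
  pos <- seeds$catalytic_positions[[1]] + 1L
  expect_true(all(vapply(fg$truth$protein, function(p)
    all(strsplit(p, "")[[1]][pos] == ref[pos]), TRUE)))
})

test_that("forge validates its configuration", {
  seeds <- tiny_seeds(1)
  plan <- single_copy_plan(seeds)
  expect_error(forge_config("spA", plan, divergence = 0.6), "divergence")
  expect_error(forge_config("spA", plan, intron_length = c(10, 50)), "intron")
  bad_plan <- tibble::tibble(species = "spA", family = "NOPE", copies = 1L,
                             placement = "dispersed")
  expect_error(forge_genome(seeds, forge_config("spA", bad_plan)), "missing")
})

test_that("the bundled synthetic seed set loads and validates", {
  fa <- system.file("extdata", "synthetic_seed_set.fa",
                    package = "degradomics")
  tsv <- system.file("extdata", "synthetic_seed_set.tsv",
                     package = "degradomics")
  seeds <- read_seed_proteins(fa, tsv)
  expect_equal(nrow(seeds), 6L)
  expect_identical(seeds,
                   demo_seed_set(6, protein_length = c(120, 160),
                                 rng_seed = 42))
})

test_that("truth round-trips through TSV and GFF3 text forms", {
  fg <- forge_single(n_fam = 2, rng_seed = 4)
  tmp <- withr::local_tempdir()
  write_truth_tsv(fg$truth, file.path(tmp, "truth.tsv"))
  back <- read_truth_tsv(file.path(tmp, "truth.tsv"))
  expect_equal(back$locus_id, sort(fg$truth$locus_id))
  i <- match(fg$truth$locus_id, back$locus_id)
  expect_true(all(mapply(function(a, b) all(a == b),
                         fg$truth$exons, back$exons[i])))
  write_truth_gff3(fg$truth, file.path(tmp, "truth.gff3"))
  lines <- readLines(file.path(tmp, "truth.gff3"))
  expect_identical(lines[1], "##gff-version 3")
  expect_equal(sum(grepl("\tgene\t", lines)), nrow(fg$truth))
  write_genomes_fasta(fg$genomes, file.path(tmp, "g.fa"))
  back_g <- read_genomes_fasta(file.path(tmp, "g.fa"), species = "spA")
  expect_identical(back_g$sequence, fg$genomes$sequence)
})
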