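# annotate-tune-iterate: clustering vs connected components, chain DP vs
# exhaustive subsets, splice tuning, iteration, composite report

test_that("HSP clustering matches brute-force connected components", {
  brute_components <- function(h, max_intron) {
    n <- nrow(h)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      gap <- max(h$gstart[i], h$gstart[j]) - min(h$gend[i], h$gend[j])
      adj[i, j] <- h$contig[i] == h$contig[j] && h$strand[i] == h$strand[j] &&
        gap <= max_intron
    }
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n))
        if (adj[i, j] && comp[j] != comp[i]) {
          comp[pmax(comp[i], comp[j]) == comp] <-
            min(comp[i], comp[j]); changed <- TRUE
        }
      if (!changed) break
    }
    comp
  }
  withr::with_seed(91, {
    for (rep in 1:10) {
      n <- sample(3:10, 1)
      h <- tibble::tibble(
        query_id = "q", contig = sample(c("c1", "c2"), n, replace = TRUE),
        species = "sp", strand = sample(c("+", "-"), n, replace = TRUE),
        frame = 0L, qstart = 0L, qend = 10L,
        gstart = sample.int(20000, n), score = 50L, evalue = 1e-6,
        pident = 90, qaln = "A", saln = "A") |>
        dplyr::mutate(gend = gstart + 30L)
      got <- cluster_hsps(h, max_intron = 2000L)
      want <- brute_components(h, 2000L)
      # same partition: locus labels induce the same equivalence classes
      key_got <- got$locus[match(paste(h$contig, h$strand, h$gstart),
                                 paste(got$contig, got$strand, got$gstart))]
      expect_equal(length(unique(key_got)), length(unique(want)))
      expect_true(all(tapply(key_got, want, function(v)
        length(unique(v)) == 1)))
      expect_true(all(tapply(want, key_got, function(v)
        length(unique(v)) == 1)))
    }
  })
  # forced examples: 1 kb gap joins, 10 kb gap splits (max_intron 5 kb)
  two <- tibble::tibble(query_id = "q", contig = "c", species = "sp",
                        strand = "+", frame = 0L, qstart = c(0L, 20L),
                        qend = c(10L, 30L), gstart = c(0L, 1030L),
                        gend = c(30L, 1060L), score = 50L, evalue = 1e-8,
                        pident = 99, qaln = "A", saln = "A")
  expect_equal(length(unique(cluster_hsps(two, 5000L)$locus)), 1L)
  two$gstart[2] <- 10030L; two$gend[2] <- 10060L
  expect_equal(length(unique(cluster_hsps(two, 5000L)$locus)), 2L)
})

test_that("chain DP equals exhaustive subset enumeration on random loci", {
  dummy_genome <- NULL
  withr::with_seed(101, {
    dummy_genome <- tibble::tibble(
      contig = "ctg", species = "sp",
      sequence = degradomics:::random_dna(20000))
    for (rep in 1:30) {
      h <- random_locus_hsps(sample(2:8, 1))
      got <- chain_hsps(h, dummy_genome, bati_config())
      want <- oracle_chain_score(h)
      expect_equal(got$chain_score, want)
    }
  })
})

test_that("single and colinear-pair chains behave as forced", {
  withr::with_seed(7, {
    g <- tibble::tibble(contig = "ctg", species = "sp",
                        sequence = degradomics:::random_dna(5000))
    h1 <- random_locus_hsps(1)
    m1 <- chain_hsps(h1, g, bati_config())
    expect_equal(m1$chain_score, h1$score)
    expect_equal(m1$n_exons, 1L)
    # disjoint query spans 0-40 / 45-90: both chained, two exons
    h2 <- tibble::tibble(
      query_id = "q", contig = "ctg", species = "sp", strand = "+",
      frame = 0L, qstart = c(0L, 45L), qend = c(40L, 90L),
      gstart = c(300L, 900L), gend = c(300L + 120L, 900L + 135L),
      score = c(100L, 120L), evalue = 1e-9, pident = 95,
      qaln = c(random_aa_string(40), random_aa_string(45)),
      saln = c(random_aa_string(40), random_aa_string(45)))
    m2 <- chain_hsps(h2, g, bati_config())
    expect_equal(m2$n_exons, 2L)
    expect_equal(m2$chain_score, 220L)
  })
  expect_error(chain_hsps(degradomics:::empty_hsps() |>
                            dplyr::mutate(locus = integer()),
                          NULL, bati_config()), "empty")
})

test_that("boundary tuning restores displaced splice sites", {
  fg <- forge_single(n_fam = 1, divergence = 0, rng_seed = 33)
  tr <- fg$truth[1, ]
  ex <- tr$exons[[1]]
  skip_if(nrow(ex) < 2)   # forge default plans 3 exons; guard only
  displaced <- ex
  displaced[1, 2] <- displaced[1, 2] + 2L   # donor +2
  displaced[2, 1] <- displaced[2, 1] + 2L   # acceptor +2 (frame preserved)
  model <- tibble::tibble(
    model_id = "m1", contig = tr$contig, species = "spA", strand = tr$strand,
    exons = list(displaced), protein = "", query_id = "q", hsp_ids = list("h"),
    chain_score = 100L, n_exons = nrow(ex),
    gstart = min(displaced[, 1]), gend = max(displaced[, 2]),
    status = "intact")
  tuned <- tune_boundaries(model, fg$genomes, window = 12L)
  expect_equal(tuned$exons[[1]], ex, ignore_attr = TRUE)
  expect_identical(tuned$protein, fg$seeds$sequence[1])
  # a model already at GT/AG is a fixed point
  model2 <- dplyr::mutate(model, exons = list(ex))
  tuned2 <- tune_boundaries(model2, fg$genomes, window = 12L)
  expect_equal(tuned2$exons[[1]], ex, ignore_attr = TRUE)
  # window 0 is the identity
  tuned0 <- tune_boundaries(model, fg$genomes, window = 0L)
  expect_equal(tuned0$exons[[1]], displaced, ignore_attr = TRUE)
})

test_that("iteration finds a divergence-ladder gene only via its relative", {
  seeds <- tiny_seeds(1, len = c(160, 160), rng_seed = 55)
  withr::with_seed(56, {
    s <- seeds$sequence[1]
    protect <- seeds$catalytic_positions[[1]]
    a <- degradomics:::diverge_protein(s, 0.22, protect)
    a2 <- degradomics:::diverge_protein(a, 0.22, protect)
    pad <- function(n) degradomics:::random_dna(n)
    g <- tibble::tibble(
      contig = c("cA", "cA2"), species = "spA",
      sequence = c(paste0(pad(300), degradomics:::back_translate(a), pad(300)),
                   paste0(pad(300), degradomics:::back_translate(a2), pad(300))))
  })
  m <- bati_iterate(seeds, g, bati_config())
  expect_equal(nrow(m), 2L)
  found <- setNames(m$iteration_found, m$contig)
  expect_equal(unname(found["cA"]), 1L)
  expect_gte(unname(found["cA2"]), 1L)
  expect_true(all(m$family == seeds$family[1]))
})

test_that("iterate terminates immediately with no homologs and caps rounds", {
  seeds <- tiny_seeds(1)
  withr::with_seed(3, {
    g <- tibble::tibble(contig = "bg", species = "spA",
                        sequence = degradomics:::random_dna(20000))
  })
  m <- bati_iterate(seeds, g, bati_config())
  expect_equal(nrow(m), 0L)
  expect_error(bati_config(max_iterations = 0L), "max_iterations")
})

test_that("bgmix report is position-sorted and flags unmodelled HSPs", {
  fg <- forge_single(n_fam = 2, divergence = 0.1, rng_seed = 41)
  h <- search_hsps(fg$seeds, fg$genomes)
  # call models for family 1 only: family 2 HSPs must show as unmodelled
  fam1 <- fg$seeds[1, ]
  m <- bati_iterate(fam1, fg$genomes, bati_config())
  rep_tab <- bgmix_report(h, m)
  expect_true(all(diff(order(rep_tab$contig, rep_tab$gstart)) > 0) ||
                !is.unsorted(order(rep_tab$contig, rep_tab$gstart)))
  by_ctg <- split(rep_tab, rep_tab$contig)
  for (d in by_ctg) expect_true(!is.unsorted(d$gstart))
  fam2_ctg <- fg$truth$contig[fg$truth$family == fg$seeds$family[2]]
  expect_true(all(!rep_tab$modelled[rep_tab$contig == fam2_ctg]))
  expect_true(any(rep_tab$modelled[rep_tab$contig != fam2_ctg]))
  empty <- bgmix_report(degradomics:::empty_hsps())
  expect_equal(nrow(empty), 0L)
  expect_true("modelled" %in% names(empty))
})

test_that("models on forged genomes pass GFF3/protein export sanity", {
  fg <- forge_single(n_fam = 2, divergence = 0.15, rng_seed = 61)
  m <- bati_iterate(fg$seeds, fg$genomes, bati_config())
  tmp <- withr::local_tempdir()
  write_models_gff3(m, file.path(tmp, "m.gff3"))
  lines <- readLines(file.path(tmp, "m.gff3"))
  expect_equal(sum(grepl("\tgene\t", lines)), nrow(m))
  expect_true(all(grepl("chain_score=", lines[grepl("\tgene\t", lines)])))
  write_proteins_fasta(m, file.path(tmp, "p.fa"))
  aa <- Biostrings::readAAStringSet(file.path(tmp, "p.fa"))
  expect_equal(length(aa), nrow(m))
})
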