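# progressive alignment, bootstrap, Fitch parsimony vs brute force,
# exhaustive/heuristic search, strict-majority consensus, outgroup rooting

test_that("progressive alignment: identity, pairwise and indel-free cases", {
  two <- progressive_align(c(a = "MKTLLV", b = "MKTLLV"))
  expect_identical(two$aligned, c("MKTLLV", "MKTLLV"))
  withr::with_seed(8, {
    a <- random_aa_string(30); b <- random_aa_string(25)
    pw <- progressive_align(c(x = a, y = b))
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      type = "global")
    expect_identical(pw$aligned[pw$taxon == "x"],
                     as.character(Biostrings::alignedPattern(pa)))
  })
  # substitution-only family -> gapless alignment, order-independent
  seeds <- tiny_seeds(1, len = c(80, 80), rng_seed = 12)
  withr::with_seed(13, {
    fam <- vapply(1:5, function(i)
      degradomics:::diverge_protein(seeds$sequence, 0.2), "")
  })
  names(fam) <- paste0("m", 1:5)
  al <- progressive_align(fam)
  expect_true(all(!grepl("-", al$aligned)))
  al_rev <- progressive_align(rev(fam))
  expect_identical(al, al_rev)
  expect_error(progressive_align(c(one = "MKT")), "at least 2")
})

test_that("bootstrap replicates preserve shape and are seeded", {
  al <- tibble::tibble(taxon = c("a", "b"), aligned = c("MKTLV", "METLV"))
  reps <- bootstrap_resample(al, 100, rng_seed = 5)
  expect_length(reps, 100)
  expect_true(all(vapply(reps, function(r) all(nchar(r$aligned) == 5), TRUE)))
  reps2 <- bootstrap_resample(al, 100, rng_seed = 5)
  expect_identical(reps, reps2)
  # single-column alignment: every replicate equals the original
  one <- tibble::tibble(taxon = c("a", "b"), aligned = c("M", "K"))
  expect_true(all(vapply(bootstrap_resample(one, 20, 1),
                         function(r) identical(r, one), TRUE)))
  expect_error(bootstrap_resample(al, 0), "replicates")
})

test_that("Fitch score: forced examples and invariances", {
  al <- tibble::tibble(taxon = c("A", "B", "C", "D"),
                       aligned = c("L", "L", "V", "V"))
  expect_equal(parsimony_score(ape::read.tree(text = "((A,B),(C,D));"), al), 1)
  expect_equal(parsimony_score(ape::read.tree(text = "((A,C),(B,D));"), al), 2)
  al0 <- tibble::tibble(taxon = c("A", "B", "C"),
                        aligned = rep("MKTW", 3))
  expect_equal(parsimony_score(ape::read.tree(text = "(A,B,C);"), al0), 0)
  expect_error(parsimony_score(ape::read.tree(text = "(A,B,X);"), al0),
               "match")
  # invariance under rerooting and leaf-order permutation
  withr::with_seed(14, {
    al5 <- tibble::tibble(
      taxon = letters[1:5],
      aligned = replicate(5, paste(sample(c(degradomics:::AA20, "-"), 12,
                                          TRUE), collapse = "")))
    tr <- ape::rtree(5, tip.label = letters[1:5])
    s0 <- parsimony_score(tr, al5)
    expect_equal(parsimony_score(ape::unroot(tr), al5), s0)
    for (og in letters[2:4])
      expect_equal(parsimony_score(ape::root(ape::unroot(tr), og,
                                             resolve.root = TRUE), al5), s0)
    expect_equal(parsimony_score(tr, al5[sample(5), ]), s0)
  })
})

test_that("Fitch equals the internal-state brute force on random data", {
  withr::with_seed(40, {
    for (rep in 1:12) {
      al <- tibble::tibble(
        taxon = letters[1:5],
        aligned = replicate(5, paste(sample(c("A", "C", "D", "E", "-"),
                                            6, TRUE), collapse = "")))
      trees <- phangorn::allTrees(5, rooted = FALSE, tip.label = letters[1:5])
      tr <- trees[[sample(length(trees), 1)]]
      expect_equal(parsimony_score(tr, al), brute_fitch(tr, al))
    }
  })
})

test_that("Fitch agrees with an independent parsimony implementation", {
  withr::with_seed(41, {
    al <- tibble::tibble(
      taxon = letters[1:6],
      aligned = replicate(6, paste(sample(degradomics:::AA20, 30, TRUE),
                                   collapse = "")))
    pd <- phangorn::phyDat(setNames(strsplit(al$aligned, ""), al$taxon),
                           type = "AA")
    for (rep in 1:5) {
      tr <- ape::rtree(6, tip.label = letters[1:6])
      expect_equal(parsimony_score(tr, al),
                   as.numeric(phangorn::parsimony(tr, pd, method = "fitch")))
    }
  })
})

test_that("exhaustive search visits the full topology space", {
  expect_length(phangorn::allTrees(4, rooted = FALSE), 3)
  expect_length(phangorn::allTrees(6, rooted = FALSE), 105)
  withr::with_seed(50, {
    al <- tibble::tibble(
      taxon = letters[1:6],
      aligned = replicate(6, paste(sample(c("A", "C", "D", "E", "F", "G"),
                                          15, TRUE), collapse = "")))
  })
  found <- parsimony_search(al)
  best <- attr(found, "score")
  all6 <- phangorn::allTrees(6, rooted = FALSE, tip.label = sort(al$taxon))
  scores <- vapply(all6, parsimony_score, 0, alignment = al)
  expect_equal(best, min(scores))
  expect_length(found, sum(scores == min(scores)))
  expect_error(parsimony_search(al[1:2, ]), "at least 3")
})

test_that("stepwise+NNI heuristic matches the exhaustive optimum on forged families", {
  seeds <- tiny_seeds(1, len = c(60, 60), rng_seed = 61)
  hits <- 0
  for (rep in 1:15) {
    withr::with_seed(7000 + rep, {
      fam <- vapply(1:7, function(i)
        degradomics:::diverge_protein(seeds$sequence, 0.25), "")
      names(fam) <- sprintf("x%d", 1:7)
    })
    al <- tibble::tibble(taxon = names(fam), aligned = unname(fam))
    ex <- parsimony_search(al)                      # exhaustive at 7 taxa
    heu <- parsimony_search(al, exhaustive_limit = 3L)  # force the heuristic
    if (attr(heu, "score") == attr(ex, "score")) hits <- hits + 1
  }
  expect_gte(hits, 14)   # >= 95% of replicates hit the global optimum
})

test_that("consensus keeps strictly-more-than-threshold bipartitions", {
  t_ab <- ape::read.tree(text = "((a,b),(c,d),e);")
  t_ac <- ape::read.tree(text = "((a,c),(b,d),e);")
  mk_reps <- function(n_ab, n_ac) c(replicate(n_ab, t_ab, simplify = FALSE),
                                    replicate(n_ac, t_ac, simplify = FALSE))
  # 51/100 retained with its count
  cons51 <- majority_consensus(mk_reps(51, 49), 50)
  supp <- attr(cons51, "support")
  expect_true("c|d" %in% supp$bipartition)   # {a,b}|{c,d,e} canonical side
  expect_true(any(abs(supp$support - 51) < 1e-9))
  # exactly 50/100 collapsed
  cons50 <- majority_consensus(mk_reps(50, 50), 50)
  expect_false(any(attr(cons50, "support")$support <= 50 + 1e-9 &
                     grepl("b", attr(cons50, "support")$bipartition)))
  # unanimity: fully resolved, every support 100
  consU <- majority_consensus(mk_reps(100, 0), 50)
  expect_true(all(abs(attr(consU, "support")$support - 100) < 1e-9))
  expect_true(ape::is.binary(ape::unroot(consU)))
  # a replicate with several co-optimal trees counts fractionally
  consF <- majority_consensus(
    c(replicate(60, t_ab, simplify = FALSE),
      replicate(40, list(t_ab, t_ac), simplify = FALSE)), 50)
  sF <- attr(consF, "support")
  expect_equal(sF$support[sF$bipartition == "c|d"], 60 + 40 / 2)
  expect_error(majority_consensus(list(t_ab,
    ape::read.tree(text = "((a,b),(c,x),e);")), 1), "leaf")
})

test_that("consensus supports are anti-monotone in the threshold", {
  withr::with_seed(70, {
    reps <- lapply(1:30, function(i) {
      al <- tibble::tibble(
        taxon = letters[1:5],
        aligned = replicate(5, paste(sample(c("A", "C", "D"), 8, TRUE),
                                     collapse = "")))
      parsimony_search(al)[[1]]
    })
  })
  lower <- attr(majority_consensus(reps, 15), "support")$bipartition
  higher <- attr(majority_consensus(reps, 25), "support")$bipartition
  expect_true(all(higher %in% lower))
})

test_that("outgroup rooting places the root and rejects paraphyly", {
  tr <- ape::read.tree(text = "((a,b)80,(c,d)90,e);")
  r1 <- root_with_outgroup(tr, "e")
  expect_true(ape::is.rooted(r1))
  expect_setequal(r1$tip.label, tr$tip.label)
  # a clade outgroup works; its complement rooting is equivalent
  r2 <- root_with_outgroup(tr, c("c", "d"))
  expect_true(ape::is.monophyletic(r2, c("c", "d")))
  # non-clade outgroup errors with a diagnostic bipartition
  expect_error(root_with_outgroup(tr, c("a", "c")), "bipartition")
  expect_error(root_with_outgroup(tr, "zzz"), "missing")
  # supports survive rerooting
  expect_true(all(c("80", "90") %in% r1$node.label))
})

test_that("trees serialize to Newick with integer supports", {
  tr <- ape::read.tree(text = "((a,b)75,(c,d)99,e);")
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_trees_newick(list(x = tr, y = tr), tmp)
  lines <- readLines(tmp)
  expect_length(lines, 2)
  expect_match(lines[1], "75")
  back <- ape::read.tree(tmp)
  expect_length(back, 2)
  expect_length(format_tree_ascii(tr), 8)  # 5 tips + 2 internals + root line
})

test_that("a forged within-species duplication pair comes out as sisters", {
  seeds <- tiny_seeds(1, len = c(120, 120), rng_seed = 80)
  wins <- 0
  for (rep in 1:5) {
    withr::with_seed(8000 + rep, {
      anc <- degradomics:::diverge_protein(seeds$sequence, 0.10)
      fam <- c(sp1_a = degradomics:::diverge_protein(anc, 0.05),
               sp1_b = degradomics:::diverge_protein(anc, 0.05),
               sp2 = degradomics:::diverge_protein(seeds$sequence, 0.15),
               sp3 = degradomics:::diverge_protein(seeds$sequence, 0.15),
               outg = seeds$sequence)
    })
    al <- progressive_align(fam)
    per <- lapply(bootstrap_resample(al, 100, rng_seed = 90 + rep),
                  parsimony_search)
    cons <- majority_consensus(per, 50)
    supp <- attr(cons, "support")
    i <- match("sp1_a|sp1_b", supp$bipartition)
    if (!is.na(i) && supp$support[i] > 50) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
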