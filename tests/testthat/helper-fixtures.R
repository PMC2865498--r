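# shared fixtures: tiny seed sets and forge plans, built in code

tiny_seeds <- function(n = 2, len = c(120, 150), rng_seed = 7) {
  demo_seed_set(n, protein_length = len, rng_seed = rng_seed)
}

single_copy_plan <- function(seeds, species = "spA") {
  tibble::tibble(species = species, family = seeds$family,
                 copies = 1L, placement = "dispersed")
}

forge_single <- function(n_fam = 2, divergence = 0.15, rng_seed = 1, ...) {
  seeds <- tiny_seeds(n_fam)
  cfg <- forge_config(species = "spA", plan = single_copy_plan(seeds),
                      divergence = divergence, rng_seed = rng_seed, ...)
  c(forge_genome(seeds, cfg), list(seeds = seeds, config = cfg))
}

# fraction of truth coding nucleotides covered by a model's exons
coding_overlap <- function(truth_exons, model_exons) {
  tcov <- unlist(apply(truth_exons, 1, function(r) seq(r[1], r[2] - 1)))
  mcov <- unlist(apply(model_exons, 1, function(r) seq(r[1], r[2] - 1)))
  length(intersect(tcov, mcov)) / length(tcov)
}

random_aa_string <- function(n) {
  paste(sample(degradomics:::AA20, n, replace = TRUE), collapse = "")
}

# synthetic colinear-ish HSPs with consistent span/alignment geometry
random_locus_hsps <- function(n, rng_gap = c(-30L, 400L)) {
  qlen <- sample(8:30, n, replace = TRUE)
  qstart <- cumsum(c(sample(0:5, 1), sample(-8:20, n - 1, replace = TRUE)))
  qstart <- pmax(qstart, 0L)
  gstart <- cumsum(c(100L, qlen[-n] * 3L + sample(seq(rng_gap[1], rng_gap[2]),
                                                  n - 1, replace = TRUE)))
  tibble::tibble(
    query_id = "q", contig = "ctg", species = "sp", strand = "+",
    frame = 0L, qstart = as.integer(qstart),
    qend = as.integer(qstart + qlen),
    gstart = as.integer(gstart), gend = as.integer(gstart + 3L * qlen),
    score = as.integer(sample(40:200, n, replace = TRUE)),
    evalue = 1e-6, pident = 90,
    qaln = vapply(qlen, random_aa_string, ""),
    saln = vapply(qlen, random_aa_string, ""))
}

# independent pairwise-compatibility + scoring rules for the chain oracle
oracle_pair_ok <- function(hj, hi, max_overlap = 25L, max_intron = 5000L) {
  if (!(hi$qend > hj$qend && hi$qstart > hj$qstart)) return(NA_integer_)
  if (hi$gend <= hj$gend) return(NA_integer_)
  if (hi$gstart - hj$gend > max_intron) return(NA_integer_)
  qo <- hj$qend - hi$qstart
  go <- hj$gend - hi$gstart
  trim <- max(0L, qo, as.integer(ceiling(max(0L, go) / 3)))
  if (trim > max_overlap) return(NA_integer_)
  if ((hi$gend - hi$gstart) - 3L * trim < 3L) return(NA_integer_)
  trim
}

# exhaustive subset enumeration over all 2^n HSP subsets, honoring the
# pairwise colinearity rules between consecutive members
oracle_chain_score <- function(h, penalty = 4L) {
  h <- h[order(h$gstart, h$gend), ]
  n <- nrow(h)
  best <- -Inf
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (!length(idx)) next
    s <- sum(h$score[idx])
    ok <- TRUE
    if (length(idx) > 1) {
      for (t in 2:length(idx)) {
        tr <- oracle_pair_ok(h[idx[t - 1], ], h[idx[t], ])
        if (is.na(tr)) { ok <- FALSE; break }
        s <- s - tr * penalty
      }
    }
    if (ok) best <- max(best, s)
  }
  best
}

# memoised full demo run shared by acceptance checks (same config + seed)
.acc_env <- new.env(parent = emptyenv())
acceptance_demo_run <- function(seed = 1) {
  key <- paste0("run", seed)
  if (is.null(.acc_env[[key]]))
    .acc_env[[key]] <- run_pipeline(demo_config(seed = seed))
  .acc_env[[key]]
}

# independent affine-gap global alignment score by exhaustive recursion
# (gap of length L costs open + L * extend, end gaps charged); used as the
# brute-force oracle for pairwise_protein_score on short strings
brute_global_score <- function(a, b, open = 11, extend = 1) {
  B <- degradomics::blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  # state: i, j, g (0 none, 1 gap-in-b open, 2 gap-in-a open)
  rec <- function(i, j, g) {
    key <- paste(i, j, g)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, B[av[i], bv[j]] + rec(i + 1, j + 1, 0))
    if (i <= length(av))
      best <- max(best, -extend - (if (g != 1) open else 0) + rec(i + 1, j, 1))
    if (j <= length(bv))
      best <- max(best, -extend - (if (g != 2) open else 0) + rec(i, j + 1, 2))
    memo[[key]] <- best
    best
  }
  rec(1, 1, 0)
}

# brute-force Fitch score: minimize over all internal-node state
# assignments, restricted (w.l.o.g.) to states observed in the column;
# wildcard leaves match anything for free
brute_fitch_column <- function(tree, states) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  nn <- n + tr$Nnode
  pool <- unique(unlist(states[!vapply(states, is.null, TRUE)]))
  pool <- setdiff(pool, NA)
  if (!length(pool)) return(0)
  internal <- (n + 1):nn
  grids <- rep(list(pool), length(internal))
  combos <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  edge_cost <- function(assign) {
    cost <- 0
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      sp <- assign[[p - n]]
      sc <- if (ch <= n) states[[match(tr$tip.label[ch],
                                       names(states))]] else assign[[ch - n]]
      if (is.null(sc) || length(sc) == 0) next      # wildcard leaf
      if (ch <= n) { if (!(sp %in% sc)) cost <- cost + 1 }
      else if (sp != sc) cost <- cost + 1
    }
    cost
  }
  min(apply(combos, 1, function(row) edge_cost(as.list(row))))
}

brute_fitch <- function(tree, alignment) {
  al <- dplyr::arrange(alignment, taxon)
  chars <- strsplit(al$aligned, "")
  L <- length(chars[[1]])
  total <- 0
  for (col in seq_len(L)) {
    states <- lapply(chars, function(ch) {
      s <- ch[col]
      if (s %in% degradomics:::AA20) s else character(0)  # wildcard
    })
    names(states) <- al$taxon
    total <- total + brute_fitch_column(tree, states)
  }
  total
}
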