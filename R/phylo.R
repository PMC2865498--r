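# Phylogenetics for families where pairwise orthology is ambiguous:
# deterministic progressive alignment, bootstrap resampling, Fitch
# parsimony (gaps as missing data), majority-rule consensus with a strict
# "more than `threshold` replicates" display rule, and outgroup rooting.

WILDCARD_MASK <- bitwShiftL(1L, 20L) - 1L

as_alignment_tbl <- function(x) {
  if (is.character(x)) x <- tibble(taxon = names(x), aligned = unname(x))
  if ("sequence" %in% names(x) && !"aligned" %in% names(x))
    x <- rename(x, aligned = sequence)
  stopifnot(all(c("taxon", "aligned") %in% names(x)))
  if (length(unique(nchar(x$aligned))) > 1) abort("rows differ in length")
  arrange(as_tibble(x), taxon)
}

# rows -> integer matrix of per-column state bitmasks; anything that is not
# one of the 20 standard residues (gap, X, *, ambiguity codes) is treated
# as missing data, i.e. the full wildcard state set
alignment_masks <- function(alignment) {
  al <- as_alignment_tbl(alignment)
  chars <- do.call(rbind, strsplit(al$aligned, ""))
  idx <- match(chars, AA20)
  masks <- ifelse(is.na(idx), WILDCARD_MASK, bitwShiftL(1L, idx - 1L))
  m <- matrix(as.integer(masks), nrow = nrow(al))
  rownames(m) <- al$taxon
  m
}

# collapse alignment columns to unique site patterns with weights
site_patterns <- function(masks) {
  key <- apply(masks, 2, paste, collapse = ",")
  tab <- table(factor(key, levels = unique(key)))
  list(masks = masks[, match(names(tab), key), drop = FALSE],
       weights = as.numeric(tab))
}

#' Fitch parsimony score of a tree
#'
#' Sum over alignment columns of the minimal number of state changes on
#' the tree (Fitch's algorithm on amino-acid states). Gaps and ambiguous
#' residues are missing data: they can take any state for free. The score
#' is invariant under rerooting and leaf-order permutation.
#'
#' @param tree an `ape` `phylo` (unrooted binary trees may have the usual
#'   basal trifurcation).
#' @param alignment tibble (`taxon`, `aligned`) or named character vector.
#' @return integer score.
#' @export
parsimony_score <- function(tree, alignment) {
  al <- as_alignment_tbl(alignment)
  if (!setequal(tree$tip.label, al$taxon))
    abort("tree leaves do not match alignment taxa")
  masks <- alignment_masks(al)
  pat <- site_patterns(masks)
  fitch_patterns(tree, pat$masks, pat$weights)
}

fitch_patterns <- function(tree, masks, weights) {
  if (!identical(attr(tree, "order"), "postorder"))
    tree <- ape::reorder.phylo(tree, "postorder")
  tipm <- if (identical(rownames(masks), tree$tip.label)) masks
          else masks[tree$tip.label, , drop = FALSE]
  fitch_cpp(tree$edge, length(tree$tip.label),
            length(tree$tip.label) + tree$Nnode, tipm, weights)
}

# all unrooted topologies on a fixed taxon set, postorder-reordered once
# and reused (bootstrap replicates rescore the same topology set)
all_topologies <- function(taxa) {
  key <- paste0("topo:", paste(taxa, collapse = "|"))
  cached <- get0(key, envir = .pkg_cache)
  if (!is.null(cached)) return(cached)
  trees <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  trees <- lapply(trees, ape::reorder.phylo, order = "postorder")
  assign(key, trees, envir = .pkg_cache)
  trees
}

#' Bootstrap-resample alignment columns
#'
#' Each replicate draws columns with replacement, preserving the column
#' count. Reproducible under `rng_seed`.
#'
#' @param alignment alignment tibble or named character vector.
#' @param replicates number of replicates (>= 1).
#' @param rng_seed integer seed.
#' @return list of alignment tibbles.
#' @export
bootstrap_resample <- function(alignment, replicates, rng_seed = 1) {
  al <- as_alignment_tbl(alignment)
  L <- nchar(al$aligned[1])
  if (L == 0 || !nrow(al)) abort("empty alignment")
  if (replicates < 1) abort("replicates must be >= 1")
  chars <- strsplit(al$aligned, "")
  with_seed(rng_seed, lapply(seq_len(replicates), function(r) {
    cols <- sample.int(L, L, replace = TRUE)
    tibble(taxon = al$taxon,
           aligned = vapply(chars, function(ch) paste(ch[cols], collapse = ""), ""))
  }))
}

# ---- tree search --------------------------------------------------------

# the single unrooted topology on 3 taxa
star3 <- function(taxa) {
  structure(list(edge = rbind(c(4L, 1L), c(4L, 2L), c(4L, 3L)),
                 tip.label = taxa, Nnode = 1L), class = "phylo")
}

# insert a new tip into edge `e` of an unrooted phylo (node ids renumbered
# to keep tips 1..n+1 first)
insert_tip <- function(tree, e, label) {
  n <- length(tree$tip.label)
  remap <- function(v) ifelse(v > n, v + 1L, v)
  edge <- cbind(remap(tree$edge[, 1]), remap(tree$edge[, 2]))
  u <- edge[e, 1]; v <- edge[e, 2]
  w <- n + 1L + tree$Nnode + 1L
  edge[e, ] <- c(u, w)
  edge <- rbind(edge, c(w, v), c(w, n + 1L))
  structure(list(edge = edge, tip.label = c(tree$tip.label, label),
                 Nnode = tree$Nnode + 1L), class = "phylo")
}

#' Search for most-parsimonious trees
#'
#' For eight or fewer taxa the search is exhaustive over all unrooted
#' binary topologies and returns every minimum-score tree. For more taxa
#' it uses deterministic stepwise addition (taxa in lexicographic order,
#' each placed on the best edge) followed by NNI hill-climbing to a local
#' optimum, returning a single tree.
#'
#' @param alignment alignment tibble or named character vector (>= 3 taxa).
#' @param exhaustive_limit taxon count up to which the search is
#'   exhaustive (default 8, i.e. up to 10395 topologies).
#' @param starts number of deterministic stepwise-addition orders (1-3)
#'   tried in the heuristic regime; more starts escape more local optima
#'   at proportional cost (bootstrap replicates typically use 1).
#' @return list of `phylo` trees, with the parsimony score in attribute
#'   `"score"`.
#' @export
parsimony_search <- function(alignment, exhaustive_limit = 8L, starts = 3L) {
  al <- as_alignment_tbl(alignment)
  n <- nrow(al)
  if (n < 3) abort("parsimony search needs at least 3 taxa")
  masks <- alignment_masks(al)
  pat <- site_patterns(masks)
  score_of <- function(tr) fitch_patterns(tr, pat$masks, pat$weights)
  if (n <= exhaustive_limit) {
    trees <- all_topologies(al$taxon)
    tipm <- if (identical(rownames(masks), al$taxon)) pat$masks
            else pat$masks[al$taxon, , drop = FALSE]
    scores <- fitch_batch_cpp(lapply(trees, `[[`, "edge"), n, 2L * n - 2L,
                              tipm, pat$weights)
    best <- trees[scores == min(scores)]
    out <- lapply(best, identity)
    attr(out, "score") <- min(scores)
    return(out)
  }
  climb <- function(order_taxa) {
    tree <- star3(order_taxa[1:3])
    for (t in 4:n) {
      tree <- ape::reorder.phylo(tree, "postorder")
      cand <- lapply(seq_len(nrow(tree$edge)), insert_tip,
                     tree = tree, label = order_taxa[t])
      scores <- vapply(cand, score_of, 0)
      tree <- cand[[which.min(scores)]]
    }
    cur <- score_of(tree)
    repeat {
      nb <- phangorn::nni(tree)
      sc <- vapply(nb, score_of, 0)
      if (min(sc) >= cur) break
      tree <- nb[[which.min(sc)]]
      cur <- min(sc)
    }
    list(tree = tree, score = cur)
  }
  # deterministic addition orders guard against shallow local optima
  orders <- list(al$taxon, rev(al$taxon),
                 c(al$taxon[seq(1, n, by = 2)], al$taxon[seq(2, n, by = 2)]))
  fits <- lapply(orders[seq_len(max(1L, min(3L, starts)))], climb)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "score"))]]
  out <- list(best$tree)
  attr(out, "score") <- best$score
  out
}

# ---- consensus ----------------------------------------------------------

# nontrivial bipartitions of an unrooted tree, each canonicalized to the
# side NOT containing the reference taxon; returned as "a|b|c" keys
tree_splits <- function(tree, taxa) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  nn <- n + tr$Nnode
  below <- vector("list", nn)
  for (i in seq_len(n)) below[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  ref <- taxa[1]
  keys <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= n) next
    side <- below[[ch]]
    if (ref %in% side) side <- setdiff(taxa, side)
    if (length(side) >= 2 && length(side) <= length(taxa) - 2)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

splits_compatible <- function(a, b, taxa) {
  ov <- length(intersect(a, b))
  ov == 0 || ov == length(a) || ov == length(b)
}

#' Majority-rule consensus with a strict display threshold
#'
#' Builds the consensus containing exactly the bipartitions present in
#' strictly more than `threshold` replicate trees, annotated with their
#' replicate counts; everything else collapses into polytomies. When a
#' replicate contributed several equally parsimonious trees, each of its
#' trees carries fractional weight 1/(number of trees), so a replicate
#' never counts more than once.
#'
#' @param trees list with one element per replicate: a `phylo` or a list
#'   of equally parsimonious `phylo` trees.
#' @param threshold display bipartitions with support strictly greater
#'   than this count (e.g. 50 with 100 replicates).
#' @return consensus `phylo`; internal node labels carry the rounded
#'   support counts, and attribute `"support"` the exact weights.
#' @export
majority_consensus <- function(trees, threshold) {
  reps <- lapply(trees, function(x) if (inherits(x, "phylo")) list(x) else x)
  taxa <- sort(reps[[1]][[1]]$tip.label)
  for (r in reps) for (tr in r)
    if (!setequal(tr$tip.label, taxa)) abort("inconsistent leaf sets")
  if (threshold < 0 || threshold > length(reps))
    abort("threshold must lie in [0, number of replicates]")
  counts <- numeric(0)
  for (r in reps) {
    w <- 1 / length(r)
    # each co-optimal tree of a replicate contributes its splits at
    # fractional weight, so one replicate never counts more than once
    per_tree <- unlist(lapply(r, tree_splits, taxa = taxa))
    tb <- table(per_tree)
    for (k in names(tb)) {
      prev <- if (k %in% names(counts)) counts[[k]] else 0
      counts[k] <- prev + w * tb[[k]]
    }
  }
  keep <- counts[counts > threshold]
  sets <- lapply(strsplit(names(keep), "|", fixed = TRUE), identity)
  if (length(sets) > 1) {
    for (i in seq_along(sets)[-1]) for (j in seq_len(i - 1))
      if (!splits_compatible(sets[[i]], sets[[j]], taxa))
        abort("retained bipartitions are incompatible (threshold below half)")
  }
  ord <- order(vapply(sets, length, 0L), names(keep), decreasing = c(TRUE, FALSE),
               method = "radix")
  sets <- sets[ord]; supp <- unname(keep[ord])
  build <- function(members, here) {
    kids <- character(0)
    used <- character(0)
    for (i in seq_along(sets)) {
      s <- sets[[i]]
      if (length(s) < length(members) && all(s %in% members) &&
          !any(s %in% used)) {
        kids <- c(kids, paste0(build(s, i), round(supp[i])))
        used <- c(used, s)
      }
    }
    singles <- setdiff(members, used)
    kids <- c(kids, singles[order(singles)])
    paste0("(", paste(kids, collapse = ","), ")")
  }
  nwk <- paste0(build(taxa, 0L), ";")
  out <- ape::read.tree(text = nwk)
  attr(out, "support") <- tibble(bipartition = names(keep)[ord],
                                 support = supp)
  out
}

#' Root a tree on the edge separating an outgroup
#'
#' The outgroup must be a single taxon or form a clade (its bipartition
#' must exist in the tree); otherwise the call fails with a diagnostic
#' naming a violating bipartition. Internal-edge supports are preserved
#' across the rerooting.
#'
#' @param tree a `phylo`.
#' @param outgroup character vector of outgroup taxa.
#' @return rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  taxa <- sort(tree$tip.label)
  if (!all(outgroup %in% taxa)) abort("outgroup taxa missing from tree")
  if (length(outgroup) > 1 && length(outgroup) < length(taxa) - 1) {
    want <- paste(sort(if (taxa[1] %in% outgroup)
      setdiff(taxa, outgroup) else outgroup), collapse = "|")
    have <- tree_splits(tree, taxa)
    if (!want %in% have) {
      clash <- have[vapply(strsplit(have, "|", fixed = TRUE), function(s) {
        ov <- length(intersect(s, outgroup))
        ov > 0 && ov < length(s) && ov < length(outgroup)
      }, TRUE)]
      abort(paste0("outgroup is not monophyletic; violating bipartition: ",
                   if (length(clash)) clash[1] else "(none resolved)"))
    }
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE, edgelabel = TRUE)
}

#' Write trees as Newick
#'
#' Integer bootstrap supports are written as internal node labels.
#'
#' @param trees a `phylo`, or a (possibly named) list of them.
#' @param path output file.
#' @export
write_trees_newick <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  lines <- vapply(trees, ape::write.tree, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Minimal ASCII rendering of a tree (for logs)
#'
#' @param tree a `phylo`.
#' @return character vector of lines.
#' @export
format_tree_ascii <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  n <- length(tr$tip.label)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  lab <- function(v) {
    if (v <= n) return(tr$tip.label[v])
    s <- if (!is.null(tr$node.label)) tr$node.label[v - n] else ""
    if (is.na(s) || !nzchar(s)) "*" else s
  }
  out <- character(0)
  walk <- function(v, depth) {
    out <<- c(out, paste0(strrep("  ", depth), "+- ", lab(v)))
    for (k in kids[[as.character(v)]]) walk(k, depth + 1L)
  }
  walk(n + 1L, 0L)
  out
}

# ---- progressive alignment ----------------------------------------------

#' Deterministic progressive multiple alignment
#'
#' Pairwise global alignment scores give a normalized score distance;
#' neighbor joining on that distance gives the guide tree (midpoint
#' rooted); profiles are merged bottom-up by global affine-gap
#' profile-profile alignment (BLOSUM62, gaps 11/1). Input order does not
#' matter: taxa are processed in lexicographic order.
#'
#' @param sequences tibble (`taxon`, `sequence`) or named character
#'   vector of at least two amino-acid strings.
#' @return alignment tibble (`taxon`, `aligned`).
#' @export
progressive_align <- function(sequences) {
  if (is.character(sequences))
    sequences <- tibble(taxon = names(sequences), sequence = unname(sequences))
  sequences <- arrange(as_tibble(sequences), taxon)
  n <- nrow(sequences)
  if (n < 2) abort("progressive alignment needs at least 2 sequences")
  if (n == 2) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(sequences$sequence[1]),
      Biostrings::AAString(sequences$sequence[2]),
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      type = "global")
    return(tibble(taxon = sequences$taxon,
                  aligned = c(as.character(Biostrings::alignedPattern(pa)),
                              as.character(Biostrings::alignedSubject(pa)))))
  }
  S <- protein_score_matrix(sequences$sequence, sequences$sequence)
  self <- diag(S)
  D <- matrix(0, n, n, dimnames = list(sequences$taxon, sequences$taxon))
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- 1 - S[i, j] / min(self[i], self[j])
  diag(D) <- 0
  guide <- phangorn::midpoint(ape::nj(stats::as.dist(D)))
  guide <- ape::reorder.phylo(guide, "postorder")
  ntip <- length(guide$tip.label)
  prof <- vector("list", ntip + guide$Nnode)
  for (i in seq_len(ntip))
    prof[[i]] <- tibble(taxon = guide$tip.label[i],
                        aligned = sequences$sequence[
                          match(guide$tip.label[i], sequences$taxon)])
  kids <- split(guide$edge[, 2], guide$edge[, 1])
  # process each parent only once all of its children's subtrees are merged:
  # order parents by their last appearance in the postorder edge list
  parents <- guide$edge[, 1]
  last_seen <- tapply(seq_along(parents), parents, max)
  for (p in as.integer(names(sort(last_seen)))) {
    ks <- kids[[as.character(p)]]
    acc <- prof[[ks[1]]]
    for (k in ks[-1]) acc <- merge_profiles(acc, prof[[k]])
    prof[[p]] <- acc
  }
  root <- ntip + 1L
  arrange(prof[[root]], taxon)
}

profile_matrix <- function(alignment) {
  chars <- do.call(rbind, strsplit(alignment$aligned, ""))
  L <- ncol(chars)
  m <- matrix(0, 20, L)
  for (a in seq_along(AA20)) m[a, ] <- colSums(chars == AA20[a])
  m / nrow(chars)
}

merge_profiles <- function(a, b) {
  pa <- profile_matrix(a); pb <- profile_matrix(b)
  B <- blosum62()[AA20, AA20]
  S <- t(pa) %*% B %*% pb
  res <- nw_affine_cpp(S, 11, 1)
  expand <- function(al, take) {
    chars <- strsplit(al$aligned, "")
    out <- lapply(chars, function(ch) {
      o <- character(length(res$path)); i <- 0L
      for (p in seq_along(res$path)) {
        if (res$path[p] %in% take) { i <- i + 1L; o[p] <- ch[i] }
        else o[p] <- "-"
      }
      paste(o, collapse = "")
    })
    tibble(taxon = al$taxon, aligned = unlist(out))
  }
  bind_rows(expand(a, c(0L, 2L)), expand(b, c(0L, 1L)))
}
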