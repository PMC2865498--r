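# Translated homology search: six-frame translation, k-mer seeding with a
# BLOSUM62 neighborhood threshold, gapped X-drop extension, Karlin-Altschul
# E-values. This is the "Blast" stage of the annotate-tune-iterate loop.
# Genomic coordinates are 0-based half-open on the forward strand.

#' Search configuration
#'
#' BLAST-like defaults, all overridable: word size 4 with neighborhood word
#' score threshold 13, affine gaps 11/1 under BLOSUM62, X-drop 20, minimum
#' HSP score 40, E-value cutoff 1e-4, and the standard gapped
#' BLOSUM62/11/1 Karlin-Altschul parameters (lambda 0.267, K 0.041). A stop
#' codon in a translated frame scores -10 and bounds extension.
#'
#' @param k seed word length (>= 2).
#' @param seed_threshold minimum BLOSUM62 word score for a seed.
#' @param gap_open,gap_extend affine gap penalties (a length-L gap costs
#'   `gap_open + L * gap_extend`).
#' @param xdrop extension stops when the running score falls this far
#'   below the best.
#' @param min_hsp_score HSPs scoring below this are dropped.
#' @param evalue_cutoff maximum reported E-value.
#' @param lambda,K Karlin-Altschul parameters.
#' @param stop_penalty score of `*` against anything.
#' @param gap_trigger minimum ungapped-extension score a seed must reach
#'   before gapped extension is attempted (the two-stage BLAST design;
#'   keeps chance word hits from nucleating HSPs).
#' @param ungapped_xdrop X-drop for the ungapped pre-extension.
#' @param end_anchor HSP ends must be anchored: a terminal run of five or
#'   more columns contributing no more than this many points is shaved.
#' @return a `search_config` list.
#' @export
search_config <- function(k = 4L, seed_threshold = 13L, gap_open = 11L,
                          gap_extend = 1L, xdrop = 20L, min_hsp_score = 40L,
                          evalue_cutoff = 1e-4, lambda = 0.267, K = 0.041,
                          stop_penalty = -10L, gap_trigger = 30L,
                          ungapped_xdrop = 16L, end_anchor = 10L) {
  if (k < 2) abort("seed word length k must be >= 2")
  structure(list(k = as.integer(k), seed_threshold = as.integer(seed_threshold),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), xdrop = as.integer(xdrop),
                 min_hsp_score = as.integer(min_hsp_score),
                 evalue_cutoff = evalue_cutoff, lambda = lambda, K = K,
                 stop_penalty = as.integer(stop_penalty),
                 gap_trigger = as.integer(gap_trigger),
                 ungapped_xdrop = as.integer(ungapped_xdrop),
                 end_anchor = as.integer(end_anchor)),
            class = "search_config")
}

# Trim an extension to its maximal-scoring contiguous run of alignment
# columns (Kadane over per-column contributions, gap-open charged to the
# first column of each gap run). Removes chance low-scoring heads/tails
# that X-drop alone tolerates; spans and score are updated consistently.
trim_extension <- function(ext, config, sub) {
  qa <- ext$qa; sa <- ext$sa
  n <- length(qa)
  gap <- qa < 0L | sa < 0L
  contrib <- numeric(n)
  for (i in seq_len(n)) {
    if (gap[i])
      contrib[i] <- -config$gap_extend -
        (if (i == 1 || !gap[i - 1]) config$gap_open else 0L)
    else contrib[i] <- sub[qa[i] + 1L, sa[i] + 1L]
  }
  best <- -Inf; bl <- 1L; br <- n; run_start <- 1L; run <- 0
  for (i in seq_len(n)) {
    if (run <= 0) { run <- contrib[i]; start_i <- i } else run <- run + contrib[i]
    if (run > best) { best <- run; bl <- start_i; br <- i }
  }
  # anchored ends: an HSP may keep a weakly positive run of chance columns
  # at either end (extension wandering past a splice site); a head or tail
  # of >= 5 columns contributing <= `end_anchor` points is shaved
  anchor <- config$end_anchor %||% 10L
  win <- contrib[bl:br]; wn <- length(win)
  if (wn >= 10L) {
    ps <- cumsum(win)
    weak <- which(seq_len(wn) >= 5L & seq_len(wn) <= wn - 5L & ps <= anchor)
    if (length(weak)) bl <- bl + max(weak)
    win <- contrib[bl:br]; wn <- length(win)
    ss <- rev(cumsum(rev(win)))
    weak_t <- which(seq(wn, 1) >= 5L & seq(wn, 1) <= wn - 5L & ss <= anchor)
    if (length(weak_t)) br <- bl + min(weak_t) - 2L
  }
  if (bl == 1L && br == n) return(ext)
  ext$qstart <- ext$qstart + sum(qa[seq_len(bl - 1L)] >= 0L)
  ext$qend <- ext$qend - sum(qa[seq(br + 1L, length.out = n - br)] >= 0L)
  ext$sstart <- ext$sstart + sum(sa[seq_len(bl - 1L)] >= 0L)
  ext$send <- ext$send - sum(sa[seq(br + 1L, length.out = n - br)] >= 0L)
  ext$qa <- qa[bl:br]; ext$sa <- sa[bl:br]
  # re-derive the exact affine score of the trimmed alignment
  g <- ext$qa < 0L | ext$sa < 0L
  opens <- sum(g & !c(FALSE, head(g, -1)))
  ext$score <- sum(sub[cbind(ext$qa[!g] + 1L, ext$sa[!g] + 1L)]) -
    opens * config$gap_open - sum(g) * config$gap_extend
  ext
}

#' Six-frame translation with coordinate maps
#'
#' Translates a nucleotide sequence in all six reading frames: `+0,+1,+2`
#' read the forward strand at offsets 0..2, `-0,-1,-2` read the reverse
#' complement likewise. Stop codons appear as `*`; codons containing `N`
#' as `X`. Each frame carries the information needed to map a protein
#' index back to its forward-strand nucleotide span (see
#' [frame_to_genome()]).
#'
#' @param sequence nucleotide string over A,C,G,T,N.
#' @return tibble with `strand`, `frame` (0..2), `aa` (translated string)
#'   and `nt_length` (the source length, for coordinate mapping).
#' @export
six_frame_translate <- function(sequence) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  rc <- if (L) revcomp(sequence) else ""
  rows <- lapply(0:5, function(i) {
    strand <- if (i < 3) "+" else "-"
    frame <- i %% 3L
    src <- if (strand == "+") sequence else rc
    aa <- if (L > frame) translate_dna(substr(src, frame + 1L, L)) else ""
    tibble(strand = strand, frame = frame, aa = aa, nt_length = L)
  })
  bind_rows(rows)
}

#' Map a protein span in a reading frame to forward-strand coordinates
#'
#' @param strand,frame which of the six frames.
#' @param nt_length length of the source nucleotide sequence.
#' @param prot_start,prot_end 0-based half-open span in the translated frame.
#' @return integer vector `c(start, end)`, 0-based half-open on the
#'   forward strand.
#' @export
frame_to_genome <- function(strand, frame, nt_length, prot_start, prot_end) {
  a <- frame + 3L * prot_start
  b <- frame + 3L * prot_end
  if (strand == "+") c(a, b) else c(nt_length - b, nt_length - a)
}

# cached per-query seed neighborhoods (depend only on query + config)
query_neighborhood <- function(qcodes, config, sub) {
  neighborhood_cpp(qcodes, config$k, config$seed_threshold, sub)
}

#' Find seed words between a protein query and a translated frame
#'
#' Returns every position pair where the length-`k` query word scores at
#' least `seed_threshold` against the frame word under BLOSUM62 (exact
#' matches always qualify). Ordered by query position, then frame position.
#'
#' @param query,frame amino-acid strings (the frame may contain `*`/`X`).
#' @param k word length.
#' @param seed_threshold minimum word score.
#' @return tibble with 0-based `query_pos`, `frame_pos`.
#' @export
find_seeds <- function(query, frame, k = 4L, seed_threshold = 13L) {
  if (k < 2) abort("k must be >= 2")
  sub <- search_matrix()
  if (nchar(query) < k || nchar(frame) < k)
    return(tibble(query_pos = integer(), frame_pos = integer()))
  qc <- aa_encode(query)
  fc <- aa_encode(frame)
  idx <- word_index_cpp(fc, as.integer(k), nrow(sub))
  neigh <- neighborhood_cpp(qc, as.integer(k), as.integer(seed_threshold), sub)
  m <- seed_scan_cpp(neigh, idx$head, idx$nxt)
  tibble(query_pos = m[, 1], frame_pos = m[, 2])
}

#' Extend a seed into a gapped HSP
#'
#' Banded affine-gap X-drop extension in both directions from the seed,
#' under BLOSUM62 with gaps 11/1. Stop codons (`*`) in the frame bound the
#' extension: an HSP never crosses one. Returns `NULL` when the final
#' score falls below `min_hsp_score` or the seed itself sits on a stop.
#'
#' @param query,frame amino-acid strings.
#' @param query_pos,frame_pos 0-based seed position (from [find_seeds()]).
#' @param config a [search_config()].
#' @return one-row tibble (`qstart`, `qend`, `sstart`, `send` 0-based
#'   half-open, `score`, `qaln`, `saln`) or `NULL`.
#' @export
extend_seed <- function(query, frame, query_pos, frame_pos,
                        config = search_config()) {
  sub <- search_matrix(config$stop_penalty)
  qc <- aa_encode(query); fc <- aa_encode(frame)
  star <- match("*", aa_alphabet()) - 1L
  k <- config$k
  if (any(fc[(frame_pos + 1L):(frame_pos + k)] == star)) return(NULL)
  stops <- which(fc == star) - 1L
  s_lo <- max(c(-1L, stops[stops < frame_pos])) + 1L
  s_hi <- min(c(length(fc), stops[stops > frame_pos]))
  ext <- xdrop_extend_cpp(qc, fc, as.integer(query_pos), as.integer(frame_pos),
                          k, sub, config$gap_open, config$gap_extend,
                          config$xdrop, 0L, length(qc), s_lo, s_hi)
  ext <- trim_extension(ext, config, sub)
  if (ext$score < config$min_hsp_score) return(NULL)
  tibble(qstart = ext$qstart, qend = ext$qend,
         sstart = ext$sstart, send = ext$send, score = ext$score,
         qaln = aa_decode(ext$qa), saln = aa_decode(ext$sa))
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n`
#' the total translated length searched. Edge-effect length corrections
#' are deliberately omitted (a documented small-scale bias).
#'
#' @param score raw alignment score (>= 0).
#' @param query_len,search_len positive lengths.
#' @param lambda,K Karlin-Altschul parameters.
#' @return the expected number of chance HSPs scoring at least `score`.
#' @export
hsp_evalue <- function(score, query_len, search_len,
                       lambda = 0.267, K = 0.041) {
  if (any(query_len <= 0) || any(search_len <= 0))
    abort("sequence lengths must be positive")
  K * query_len * search_len * exp(-lambda * score)
}

# re-score a stored gapped alignment (self-consistency invariant)
score_alignment <- function(qaln, saln, config = search_config()) {
  sub <- search_matrix(config$stop_penalty)
  qa <- strsplit(qaln, "")[[1]]; sa <- strsplit(saln, "")[[1]]
  s <- 0L; in_gap <- FALSE
  for (i in seq_along(qa)) {
    if (qa[i] == "-" || sa[i] == "-") {
      s <- s - config$gap_extend - (if (!in_gap) config$gap_open else 0L)
      in_gap <- TRUE
    } else {
      s <- s + sub[qa[i], sa[i]]
      in_gap <- FALSE
    }
  }
  s
}

#' Translated search of protein queries against genomes
#'
#' The full TBLASTN-style search: each query is seeded and extended
#' against all six frames of every contig; HSPs are E-value-annotated
#' (with `n` = total translated length searched), filtered at the E-value
#' cutoff, deduplicated and deterministically ordered by contig, genomic
#' span and query.
#'
#' @param queries tibble with `id` and `sequence` columns (a seed-protein
#'   set works as-is).
#' @param genomes tibble with `contig`, `species`, `sequence`.
#' @param config a [search_config()].
#' @return HSP tibble: `query_id`, `contig`, `species`, `strand`, `frame`,
#'   `qstart`/`qend` (protein, 0-based half-open), `gstart`/`gend`
#'   (forward-strand nt, 0-based half-open), `score`, `evalue`, `pident`,
#'   `qaln`, `saln`.
#' @export
search_hsps <- function(queries, genomes, config = search_config()) {
  if (!nrow(queries)) abort("empty query set")
  if (!nrow(genomes)) return(empty_hsps())
  sub <- search_matrix(config$stop_penalty)
  star <- match("*", aa_alphabet()) - 1L
  frames <- genomes |>
    rowwise() |>
    reframe(six_frame_translate(sequence), contig = contig, species = species)
  n_search <- sum(nchar(frames$aa))
  if (n_search == 0) return(empty_hsps())
  qcodes <- lapply(queries$sequence, aa_encode)
  neighs <- lapply(qcodes, query_neighborhood, config = config, sub = sub)
  out <- list()
  for (f in seq_len(nrow(frames))) {
    fc <- aa_encode(frames$aa[f])
    if (length(fc) < config$k) next
    idx <- word_index_cpp(fc, config$k, nrow(sub))
    stops <- which(fc == star) - 1L
    for (qi in seq_len(nrow(queries))) {
      qc <- qcodes[[qi]]
      if (length(qc) < config$k) next
      # scan + ungapped-trigger filter in one C++ pass; survivors come back
      # diagonal-major so containment skipping is effective
      m <- seed_scan_trigger_cpp(neighs[[qi]], idx$head, idx$nxt, qc, fc,
                                 config$k, sub, config$ungapped_xdrop,
                                 config$gap_trigger, star)
      if (!nrow(m)) next
      hits <- list()
      for (s in seq_len(nrow(m))) {
        qp <- m[s, 1]; sp <- m[s, 2]
        contained <- FALSE
        for (h in hits)
          if (qp >= h$qstart && qp < h$qend && sp >= h$sstart && sp < h$send) {
            contained <- TRUE; break
          }
        if (contained) next
        s_lo <- max(c(-1L, stops[stops < sp])) + 1L
        s_hi <- min(c(length(fc), stops[stops > sp]))
        ext <- xdrop_extend_cpp(qc, fc, qp, sp, config$k, sub,
                                config$gap_open, config$gap_extend,
                                config$xdrop, 0L, length(qc), s_lo, s_hi)
        ext <- trim_extension(ext, config, sub)
        if (ext$score < config$min_hsp_score) next
        hits[[length(hits) + 1L]] <- ext
      }
      for (h in hits) {
        gsp <- frame_to_genome(frames$strand[f], frames$frame[f],
                               frames$nt_length[f], h$sstart, h$send)
        ident <- mean(h$qa == h$sa & h$qa >= 0)
        out[[length(out) + 1L]] <- tibble(
          query_id = queries$id[qi], contig = frames$contig[f],
          species = frames$species[f], strand = frames$strand[f],
          frame = frames$frame[f], qstart = h$qstart, qend = h$qend,
          gstart = gsp[1], gend = gsp[2], score = h$score,
          evalue = hsp_evalue(h$score, length(qc), n_search,
                              config$lambda, config$K),
          pident = round(100 * ident, 2),
          qaln = aa_decode(h$qa), saln = aa_decode(h$sa))
      }
    }
  }
  if (!length(out)) return(empty_hsps())
  bind_rows(out) |>
    filter(evalue <= config$evalue_cutoff) |>
    distinct(query_id, contig, strand, frame, qstart, qend, gstart, gend,
             .keep_all = TRUE) |>
    arrange(contig, gstart, gend, query_id, strand, frame)
}

empty_hsps <- function() {
  tibble(query_id = character(), contig = character(), species = character(),
         strand = character(), frame = integer(), qstart = integer(),
         qend = integer(), gstart = integer(), gend = integer(),
         score = integer(), evalue = double(), pident = double(),
         qaln = character(), saln = character())
}

#' Read / write HSPs as BLAST-style tabular records
#'
#' Twelve outfmt-6-like columns (query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' evalue, raw score) plus `strand` and `frame`. Coordinates in this file
#' only are 1-based inclusive.
#'
#' @param hsps HSP tibble from [search_hsps()].
#' @param path file path.
#' @export
write_hsps_tsv <- function(hsps, path) {
  tab <- hsps |>
    rowwise() |>
    mutate(
      aln_len = nchar(qaln),
      mismatches = {
        qa <- strsplit(qaln, "")[[1]]; sa <- strsplit(saln, "")[[1]]
        sum(qa != sa & qa != "-" & sa != "-")
      },
      gapopens = {
        g <- strsplit(qaln, "")[[1]] == "-" | strsplit(saln, "")[[1]] == "-"
        sum(g & !c(FALSE, head(g, -1)))
      }) |>
    ungroup() |>
    transmute(query = query_id, subject = contig, pident,
              aln_len, mismatches, gapopens,
              qstart = qstart + 1L, qend = qend,
              sstart = gstart + 1L, send = gend,
              evalue = sprintf("%.3g", evalue), score, strand, frame)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_hsps_tsv
#' @export
read_hsps_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    mutate(qstart = qstart - 1L, sstart = sstart - 1L)
}
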