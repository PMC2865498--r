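# Annotate-Tune-Iterate: cluster HSPs into loci, chain them into multi-exon
# gene models by dynamic programming, refine exon boundaries at GT/AG splice
# signals, and feed novel intact predictions back into the query set until
# no new locus appears.

#' Annotation configuration
#'
#' @param max_intron maximum genomic gap (nt) joining HSPs into one locus.
#' @param max_query_overlap residues of query overlap tolerated (and
#'   trimmed) between chained HSPs.
#' @param overlap_penalty chain-score penalty per trimmed residue.
#' @param tune_window maximum boundary shift (nt) when snapping to GT/AG.
#' @param max_iterations upper bound on annotate-iterate rounds.
#' @param dedup_overlap reciprocal-overlap fraction above which two models
#'   are considered the same locus.
#' @param rescue_evalue linked-HSP rescue: HSPs up to this E-value are
#'   kept when the same query already has an HSP passing the strict
#'   search cutoff within `max_intron` on the same contig and strand (the
#'   sum-statistics idea behind translated-search exon linking — a short
#'   internal exon rarely reaches genome-wide significance on its own).
#' @param search a [search_config()].
#' @return a `bati_config` list.
#' @export
bati_config <- function(max_intron = 5000L, max_query_overlap = 25L,
                        overlap_penalty = 4L, tune_window = 15L,
                        max_iterations = 10L, dedup_overlap = 0.5,
                        rescue_evalue = 0.5, search = search_config()) {
  if (max_iterations < 1) abort("max_iterations must be >= 1")
  structure(list(max_intron = as.integer(max_intron),
                 max_query_overlap = as.integer(max_query_overlap),
                 overlap_penalty = as.integer(overlap_penalty),
                 tune_window = as.integer(tune_window),
                 max_iterations = as.integer(max_iterations),
                 dedup_overlap = dedup_overlap,
                 rescue_evalue = rescue_evalue, search = search),
            class = "bati_config")
}

# strict-cutoff HSPs plus weak same-query HSPs within linking distance of
# a strict one (same contig and strand)
link_rescue_hsps <- function(hsps, strict_cutoff, max_intron) {
  if (!nrow(hsps)) return(hsps)
  strong <- filter(hsps, evalue <= strict_cutoff)
  if (!nrow(strong)) return(strong)
  keep <- vapply(seq_len(nrow(hsps)), function(i) {
    h <- hsps[i, ]
    if (h$evalue <= strict_cutoff) return(TRUE)
    any(strong$query_id == h$query_id & strong$contig == h$contig &
          strong$strand == h$strand &
          pmax(h$gstart - strong$gend, strong$gstart - h$gend, 0) <= max_intron)
  }, TRUE)
  hsps[keep, ]
}

#' Cluster HSPs into candidate loci
#'
#' Single-linkage clustering of HSPs that share a contig and strand and
#' whose genomic gaps do not exceed `max_intron`. Every HSP lands in
#' exactly one locus; loci are numbered in (contig, start) order.
#'
#' @param hsps HSP tibble from [search_hsps()].
#' @param max_intron maximum joining gap in nt.
#' @return the HSPs with a `locus` id column added.
#' @export
cluster_hsps <- function(hsps, max_intron = 5000L) {
  if (!nrow(hsps)) return(mutate(hsps, locus = integer()))
  out <- hsps |>
    group_by(contig, strand) |>
    arrange(gstart, gend, .by_group = TRUE) |>
    mutate(locus_break = {
      reach <- cummax(dplyr::lag(gend, default = dplyr::first(gstart)))
      as.integer(gstart - reach > max_intron)
    }, locus_local = cumsum(locus_break)) |>
    ungroup()
  keys <- out |>
    group_by(contig, strand, locus_local) |>
    summarise(lstart = min(gstart), .groups = "drop") |>
    arrange(contig, lstart, strand) |>
    mutate(locus = row_number())
  out |>
    left_join(keys, by = c("contig", "strand", "locus_local")) |>
    select(-locus_break, -locus_local, -lstart) |>
    arrange(locus, gstart, gend, query_id)
}

# coding-order transition check for a pair of HSPs j (earlier) -> i
# (later). Small query and/or genome overlaps (extension overshoot past a
# splice site) are resolved by trimming residues off the coding-side start
# of the downstream HSP; returns list(trim, penalty) or NULL when the pair
# is incompatible.
chain_step <- function(hj, hi, strand, max_overlap, overlap_penalty,
                       max_intron = Inf) {
  if (!(hi$qend > hj$qend && hi$qstart > hj$qstart)) return(NULL)
  go <- if (strand == "+") hj$gend - hi$gstart else hi$gend - hj$gstart
  if (-go > max_intron) return(NULL)   # implied intron longer than allowed
  if (strand == "+") { if (hi$gend <= hj$gend) return(NULL) } else
    if (hi$gstart >= hj$gstart) return(NULL)
  qo <- hj$qend - hi$qstart
  trim <- max(0L, qo, as.integer(ceiling(max(0L, go) / 3)))
  if (trim > max_overlap) return(NULL)
  # downstream exon must survive the trim
  if ((hi$gend - hi$gstart) - 3L * trim < 3L) return(NULL)
  list(trim = trim, penalty = trim * overlap_penalty)
}

#' Chain the HSPs of one locus into a gene model
#'
#' Selects the maximum-score chain of HSPs colinear in both query and
#' genome coordinates (query overlaps up to `max_query_overlap` residues
#' are trimmed at `overlap_penalty` per residue; genome overlaps are
#' forbidden) by dynamic programming over HSPs in coding order. The
#' chained genome spans become exons; the model protein is their spliced
#' translation; models whose translation contains a stop are flagged
#' `pseudogene_fragment`.
#'
#' @param locus_hsps HSPs of a single locus (one contig and strand).
#' @param genomes genome tibble (for the spliced translation).
#' @param config a [bati_config()].
#' @return a one-row gene-model tibble.
#' @export
chain_hsps <- function(locus_hsps, genomes, config = bati_config()) {
  h <- locus_hsps
  if (!nrow(h)) abort("empty locus")
  if (length(unique(h$contig)) > 1 || length(unique(h$strand)) > 1)
    abort("locus HSPs must share contig and strand")
  strand <- h$strand[1]
  h <- if (strand == "+") arrange(h, gstart, gend, query_id) else
    arrange(h, desc(gend), desc(gstart), query_id)
  n <- nrow(h)
  dp <- h$score; pred <- rep(NA_integer_, n); trim_in <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      st <- chain_step(h[j, ], h[i, ], strand, config$max_query_overlap,
                       config$overlap_penalty, config$max_intron)
      if (is.null(st)) next
      cand <- dp[j] + h$score[i] - st$penalty
      if (cand > dp[i]) { dp[i] <- cand; pred[i] <- j; trim_in[i] <- st$trim }
    }
  }
  best <- which.max(dp)
  chain <- best
  while (!is.na(pred[chain[1]])) chain <- c(pred[chain[1]], chain)
  picked <- h[chain, ]
  # exons in coding order; trimmed residues come off whichever side of the
  # junction aligns worse (extension overshoot past a splice site leaves a
  # weak tail on one of the two HSPs), 3 nt per residue
  ex <- cbind(picked$gstart, picked$gend)
  if (length(chain) >= 2) {
    sub <- search_matrix(config$search$stop_penalty)
    for (t in 2:length(chain)) {
      o <- trim_in[chain[t]]
      if (o == 0) next
      up_tail <- junction_columns(picked[t - 1L, ], o, "tail", sub, config)
      dn_head <- junction_columns(picked[t, ], o, "head", sub, config)
      if (up_tail < dn_head && ex[t - 1L, 2] - ex[t - 1L, 1] > 3L * o + 3L) {
        # upstream tail is the junk: trim its coding-side end
        if (strand == "+") ex[t - 1L, 2] <- ex[t - 1L, 2] - 3L * o
        else ex[t - 1L, 1] <- ex[t - 1L, 1] + 3L * o
        # genome overlap, if any, must still be resolved downstream
        extra <- if (strand == "+")
          as.integer(ceiling(max(0L, ex[t - 1L, 2] - ex[t, 1]) / 3))
        else as.integer(ceiling(max(0L, ex[t, 2] - ex[t - 1L, 1]) / 3))
        if (extra > 0) {
          if (strand == "+") ex[t, 1] <- ex[t, 1] + 3L * extra
          else ex[t, 2] <- ex[t, 2] - 3L * extra
        }
      } else {
        if (strand == "+") ex[t, 1] <- ex[t, 1] + 3L * o
        else ex[t, 2] <- ex[t, 2] - 3L * o
      }
    }
  }
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  colnames(ex) <- c("start", "end")
  seqs <- setNames(genomes$sequence, genomes$contig)
  prot <- splice_translate(seqs[[h$contig[1]]], ex, strand)
  fam_tab <- picked |> arrange(desc(score), query_id)
  tibble(contig = h$contig[1], species = h$species[1], strand = strand,
         exons = list(ex), protein = prot,
         query_id = fam_tab$query_id[1],
         hsp_ids = list(paste0(picked$query_id, "@", picked$gstart)),
         chain_score = dp[best] |> as.integer(),
         n_exons = nrow(ex),
         gstart = min(ex[, 1]), gend = max(ex[, 2]),
         status = if (grepl("*", prot, fixed = TRUE)) "pseudogene_fragment"
                  else "intact")
}

# splice-signal check for an intron [a, b) on a given strand
intron_signals_ok <- function(sequence, a, b, strand) {
  if (b - a < 20L) return(FALSE)
  don <- substr(sequence, a + 1L, a + 2L)
  acc <- substr(sequence, b - 1L, b)
  if (strand == "+") don == "GT" && acc == "AG" else don == "CT" && acc == "AC"
}

#' Snap exon boundaries to GT/AG splice signals
#'
#' Each internal exon junction is shifted by at most `window` nt to the
#' nearest boundary pair that makes the intron start with GT and end with
#' AG on the coding strand while preserving the reading frame (the two
#' shifts must be congruent mod 3). Junctions with no qualifying shift are
#' left unchanged. The model is re-spliced and its status re-evaluated.
#'
#' @param model one-row gene-model tibble from [chain_hsps()].
#' @param genomes genome tibble.
#' @param window maximum shift in nt (0 disables tuning).
#' @param config a [bati_config()] (used for defaults).
#' @return the tuned model.
#' @export
tune_boundaries <- function(model, genomes, window = NULL,
                            config = bati_config()) {
  window <- window %||% config$tune_window
  ex <- model$exons[[1]]
  if (window == 0L || nrow(ex) < 2) return(model)
  seqs <- setNames(genomes$sequence, genomes$contig)
  sequence <- seqs[[model$contig]]
  strand <- model$strand
  shifts <- -window:window
  had_stop <- grepl("*", splice_translate(sequence, ex, strand), fixed = TRUE)
  for (i in seq_len(nrow(ex) - 1L)) {
    a <- ex[i, 2]; b <- ex[i + 1L, 1]
    cand <- expand.grid(da = shifts, db = shifts)
    cand <- cand[(cand$da - cand$db) %% 3L == 0L, , drop = FALSE]
    # shifts that keep the donor exon's codon phase come first: chained
    # exons are codon multiples and phase-0 splice sites dominate, so a
    # phase-breaking shift is almost always a chance GT/AG pair
    cand <- cand[order(cand$da %% 3L != 0L, abs(cand$da) + abs(cand$db),
                       cand$da, cand$db), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      a2 <- a + cand$da[r]; b2 <- b + cand$db[r]
      if (a2 <= ex[i, 1] || b2 >= ex[i + 1L, 2]) next
      if (intron_signals_ok(sequence, a2, b2, strand)) {
        old <- c(ex[i, 2], ex[i + 1L, 1])
        ex[i, 2] <- a2; ex[i + 1L, 1] <- b2
        # a tuning move must never manufacture a stop codon
        if (!had_stop &&
            grepl("*", splice_translate(sequence, ex, strand), fixed = TRUE)) {
          ex[i, 2] <- old[1]; ex[i + 1L, 1] <- old[2]
          next
        }
        break
      }
    }
  }
  prot <- splice_translate(sequence, ex, strand)
  model$exons <- list(ex)
  model$protein <- prot
  model$gstart <- min(ex[, 1]); model$gend <- max(ex[, 2])
  model$status <- if (grepl("*", prot, fixed = TRUE)) "pseudogene_fragment"
                  else if (model$status == "pseudogene_fragment") "intact"
                  else model$status
  model
}

# summed alignment score of the first/last `o` columns of an HSP
junction_columns <- function(hsp, o, side = c("head", "tail"), sub, config) {
  side <- match.arg(side)
  qa <- strsplit(hsp$qaln, "")[[1]]; sa <- strsplit(hsp$saln, "")[[1]]
  n <- length(qa)
  idx <- if (side == "head") seq_len(min(o, n)) else seq(max(1L, n - o + 1L), n)
  s <- 0
  for (i in idx) {
    s <- s + if (qa[i] == "-" || sa[i] == "-")
      -(config$search$gap_extend) else sub[qa[i], sa[i]]
  }
  s
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2))
  min(ov / (e1 - s1), ov / (e2 - s2))
}

# A locus can hold more than one gene (tandem duplicates whose intergenic
# gap is under max_intron). Chain, remove HSPs overlapping the chained
# exons, and chain again; secondary chains are kept while they reach at
# least half the primary chain score (guards against promoting stray
# fragments to gene copies).
chain_locus_models <- function(lh, genomes, config, min_secondary_frac = 0.5) {
  out <- list()
  remaining <- lh
  primary <- NULL
  while (nrow(remaining)) {
    m <- tune_boundaries(chain_hsps(remaining, genomes, config), genomes,
                         config = config)
    if (is.null(primary)) primary <- m$chain_score
    else if (m$chain_score < min_secondary_frac * primary) break
    out[[length(out) + 1L]] <- m
    ex <- m$exons[[1]]
    hit_exon <- vapply(seq_len(nrow(remaining)), function(i)
      any(remaining$gstart[i] < ex[, 2] & remaining$gend[i] > ex[, 1]), TRUE)
    if (all(!hit_exon)) break   # no progress; avoid spinning
    remaining <- remaining[!hit_exon, , drop = FALSE]
    if (length(out) >= 25) break
  }
  bind_rows(out)
}

#' Run the full annotate-tune-iterate loop
#'
#' Round 1 searches the seed set, clusters and chains HSPs into models and
#' tunes their boundaries. Each later round adds all newly predicted
#' intact proteins (inheriting the family of their best-scoring query) to
#' the query set and repeats, stopping when no new locus appears or after
#' `max_iterations`. Overlapping models are deduplicated, keeping the
#' higher chain score.
#'
#' @param seeds seed-protein tibble (`id`, `family`, `sequence`).
#' @param genomes genome tibble for one species.
#' @param config a [bati_config()].
#' @return gene-model tibble with `family` and `iteration_found`, plus the
#'   final round's HSPs as attribute `"hsps"`.
#' @export
bati_iterate <- function(seeds, genomes, config = bati_config()) {
  if (!nrow(seeds)) abort("empty seed set")
  fam_of <- setNames(seeds$family, seeds$id)
  queries <- tibble(id = seeds$id, sequence = seeds$sequence)
  models <- NULL
  all_hsps <- NULL
  loose <- config$search
  loose$evalue_cutoff <- max(config$rescue_evalue, config$search$evalue_cutoff)
  hsp_cache <- list()   # per-query HSPs; the genome never changes mid-run
  for (it in seq_len(config$max_iterations)) {
    todo <- queries[!queries$id %in% names(hsp_cache), , drop = FALSE]
    if (nrow(todo)) {
      fresh <- search_hsps(todo, genomes, loose)
      for (qid in todo$id)
        hsp_cache[[qid]] <- fresh[fresh$query_id == qid, , drop = FALSE]
    }
    hsps <- bind_rows(hsp_cache[queries$id]) |>
      arrange(contig, gstart, gend, query_id, strand, frame)
    hsps <- link_rescue_hsps(hsps, config$search$evalue_cutoff,
                             config$max_intron)
    all_hsps <- hsps
    new_found <- FALSE
    if (nrow(hsps)) {
      clustered <- cluster_hsps(hsps, config$max_intron)
      round_models <- clustered |>
        group_split(locus) |>
        lapply(chain_locus_models, genomes = genomes, config = config) |>
        bind_rows() |>
        mutate(family = unname(fam_of[query_id]), iteration_found = it)
      for (r in seq_len(nrow(round_models))) {
        m <- round_models[r, ]
        if (is.null(models)) { models <- m; new_found <- TRUE; next }
        same <- which(models$contig == m$contig & models$strand == m$strand &
                        mapply(reciprocal_overlap, models$gstart, models$gend,
                               m$gstart, m$gend) >= config$dedup_overlap)
        if (!length(same)) {
          models <- bind_rows(models, m)
          new_found <- TRUE
        } else if (max(models$chain_score[same]) < m$chain_score) {
          # better model of an already-found locus: replace, but keep the
          # iteration at which the locus was first discovered
          m$iteration_found <- min(models$iteration_found[same])
          models <- models[-same, ]
          models <- bind_rows(models, m)
        }
      }
    }
    if (!new_found) break
    preds <- models |> filter(status == "intact")
    if (!nrow(preds)) break
    pred_ids <- sprintf("pred_%s_%05d", preds$contig, preds$gstart)
    fam_of <- c(fam_of[names(fam_of) %in% seeds$id],
                setNames(preds$family, pred_ids))
    queries <- bind_rows(tibble(id = seeds$id, sequence = seeds$sequence),
                         tibble(id = pred_ids, sequence = preds$protein) |>
                           distinct(sequence, .keep_all = TRUE))
  }
  if (is.null(models)) models <- empty_models()
  models <- models |>
    arrange(contig, gstart, gend) |>
    mutate(model_id = sprintf("%s_g%03d",
                              species %||% "sp", row_number())) |>
    relocate(model_id)
  attr(models, "hsps") <- all_hsps
  models
}

empty_models <- function() {
  tibble(contig = character(), species = character(), strand = character(),
         exons = list(), protein = character(), query_id = character(),
         hsp_ids = list(), chain_score = integer(), n_exons = integer(),
         gstart = integer(), gend = integer(), status = character(),
         family = character(), iteration_found = integer())
}

#' Composite position-sorted HSP report
#'
#' Merges all HSPs from all queries into one table sorted by contig,
#' genomic start and descending score, flagging HSPs not covered by any
#' final gene model — the review surface for potentially missed genes.
#'
#' @param hsps HSP tibble.
#' @param models gene-model tibble (may be empty).
#' @return the sorted table with a logical `modelled` column.
#' @export
bgmix_report <- function(hsps, models = empty_models()) {
  if (!nrow(hsps))
    return(mutate(empty_hsps(), modelled = logical()))
  hsps |>
    rowwise() |>
    mutate(modelled = any(models$contig == contig & models$strand == strand &
                            models$gstart < gend & models$gend > gstart)) |>
    ungroup() |>
    arrange(contig, gstart, desc(score))
}

# ---- on-disk forms ------------------------------------------------------

#' Write gene models as GFF3 and their proteins as FASTA
#'
#' GFF3 carries gene/mRNA/CDS features with `status`, `family`,
#' `iteration_found` and `chain_score` attributes (1-based inclusive
#' coordinates).
#'
#' @param models gene-model tibble.
#' @param path output file.
#' @export
write_models_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  if (nrow(models)) {
    models <- arrange(models, contig, gstart)
    for (i in seq_len(nrow(models))) {
      m <- models[i, ]
      ex <- m$exons[[1]]
      base <- sprintf("%s\tdegradomics\t%%s\t%%d\t%%d\t.\t%s\t.\t%%s",
                      m$contig, m$strand)
      lines <- c(lines,
        sprintf(base, "gene", m$gstart + 1L, m$gend,
                sprintf("ID=%s;family=%s;status=%s;iteration_found=%d;chain_score=%d",
                        m$model_id, m$family, m$status, m$iteration_found,
                        m$chain_score)),
        sprintf(base, "mRNA", m$gstart + 1L, m$gend,
                sprintf("ID=%s.t1;Parent=%s", m$model_id, m$model_id)),
        sprintf(base, "CDS", ex[, 1] + 1L, ex[, 2],
                sprintf("ID=%s.cds;Parent=%s.t1", m$model_id, m$model_id)))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_models_gff3
#' @export
write_proteins_fasta <- function(models, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(gsub("\\*", "X", models$protein),
                                     models$model_id)), path)
  invisible(path)
}
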