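# Cross-species comparison: reciprocal best hit orthology, tandem
# duplication and expansion detection, and the family-status matrix
# (families x species, with calls like present / duplicated / expanded).

#' Global protein alignment score
#'
#' Needleman-Wunsch score under BLOSUM62 with affine gaps 11/1 (a length-L
#' gap costs 11 + L); end gaps are penalized. Symmetric in its arguments.
#'
#' @param a,b non-empty amino-acid strings.
#' @return integer alignment score.
#' @export
pairwise_protein_score <- function(a, b) {
  if (!nchar(a) || !nchar(b)) abort("empty sequence")
  as.integer(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global", scoreOnly = TRUE))
}

# score one query against many subjects in a single vectorized call
protein_scores_vs_set <- function(query, subjects) {
  as.integer(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(rep(query, length(subjects))),
    Biostrings::AAStringSet(subjects),
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global", scoreOnly = TRUE))
}

# full score matrix between two protein sets (rows = a, cols = b)
protein_score_matrix <- function(a, b) {
  m <- matrix(0L, length(a), length(b))
  for (i in seq_along(a)) m[i, ] <- protein_scores_vs_set(a[i], b)
  m
}

#' Reciprocal-best-hit orthology calls
#'
#' A gene x in proteome A and y in proteome B are called
#' `rbh_orthologue` when y is x's unique best scorer in B by more than
#' `margin` over the runner-up and x is y's unique best in A likewise.
#' Every other A gene is reported `no_clear_orthologue` — the conservative
#' bucket for large complex families where orthology cannot be pinned
#' down by pairwise score alone. Exact ties never produce an orthologue
#' call.
#'
#' @param proteome_a,proteome_b tibbles with `id` and `protein` (or
#'   `sequence`) columns.
#' @param margin minimum score gap over the runner-up (default 0 =
#'   strictly greater).
#' @param scores optional precomputed score matrix (rows = A, cols = B).
#' @return tibble: `gene_a`, `gene_b` (NA unless paired), `call`,
#'   `score_ab`, `score_ba`.
#' @export
rbh <- function(proteome_a, proteome_b, margin = 0L, scores = NULL) {
  seq_col <- function(p) if ("protein" %in% names(p)) p$protein else p$sequence
  if (!nrow(proteome_a) || !nrow(proteome_b)) abort("empty proteome")
  S <- scores %||% protein_score_matrix(seq_col(proteome_a), seq_col(proteome_b))
  unique_best <- function(v) {
    o <- order(v, decreasing = TRUE)
    if (length(v) > 1 && v[o[1]] - v[o[2]] <= margin) return(NA_integer_)
    o[1]
  }
  best_b <- apply(S, 1, unique_best)   # per A gene: its best B column
  best_a <- apply(S, 2, unique_best)   # per B gene: its best A row
  out <- lapply(seq_len(nrow(proteome_a)), function(i) {
    j <- best_b[i]
    ok <- !is.na(j) && !is.na(best_a[j]) && best_a[j] == i
    tibble(gene_a = proteome_a$id[i],
           gene_b = if (ok) proteome_b$id[j] else NA_character_,
           call = if (ok) "rbh_orthologue" else "no_clear_orthologue",
           score_ab = if (!is.na(j)) S[i, j] else max(S[i, ]),
           score_ba = if (ok) S[i, j] else NA_integer_)
  })
  bind_rows(out)
}

#' Group same-family models into tandem duplication clusters
#'
#' Same-family models on one contig whose pairwise genomic gaps are at
#' most `max_separation` form a group; groups of two or more are flagged
#' tandem. Same-family copies on different contigs (or farther apart)
#' count as dispersed.
#'
#' @param models gene-model tibble with `family` labels.
#' @param max_separation maximum gap in nt (default 1 Mb).
#' @return the models with `tandem_group` (id or NA) and `tandem` flag;
#'   group summary in attribute `"groups"`.
#' @export
detect_tandem_duplication <- function(models, max_separation = 1e6) {
  if (!nrow(models)) {
    out <- mutate(models, tandem_group = character(), tandem = logical())
    attr(out, "groups") <- tibble(tandem_group = character(),
                                  family = character(), contig = character(),
                                  n = integer())
    return(out)
  }
  out <- models |>
    group_by(family, contig) |>
    arrange(gstart, .by_group = TRUE) |>
    mutate(grp = cumsum(c(0L, as.integer(
      gstart[-1] - cummax(gend)[-n()] > max_separation)))) |>
    group_by(family, contig, grp) |>
    mutate(tandem = n() >= 2,
           tandem_group = if (n() >= 2)
             sprintf("%s_%s_t%d", family[1], contig[1], grp[1] + 1L)
           else NA_character_) |>
    ungroup() |>
    select(-grp) |>
    arrange(contig, gstart)
  attr(out, "groups") <- out |>
    filter(!is.na(tandem_group)) |>
    group_by(tandem_group, family, contig) |>
    summarise(n = n(), .groups = "drop")
  out
}

#' Family status calls (the comparison-matrix vocabulary)
#'
#' Maps per-family copy counts to the standard comparative-degradomics
#' vocabulary: 0 copies is `absent` — or `not_found` when the family's
#' expected region is flagged as assembly-gap rich (N fraction above
#' `gap_threshold`), the mechanical form of "the contig where this gene
#' should sit is full of unsequenced stretches"; 1 `present`; 2
#' `duplicated`; 3 `triplicated`; 4 or more `expanded`; any copies but
#' none intact `pseudogene_only`.
#'
#' @param models gene-model tibble for one or more species.
#' @param seeds seed set (defines the family universe).
#' @param species character vector of species to report.
#' @param gap_fraction optional tibble (`family`, `species`,
#'   `n_fraction`) of assembly-gap content in the family's expected
#'   region.
#' @param gap_threshold N-fraction above which a missing family reports
#'   `not_found` instead of `absent`.
#' @return tibble: `family`, `species`, `copy_count`, `intact_count`,
#'   `status`.
#' @export
detect_family_status <- function(models, seeds, species,
                                 gap_fraction = NULL, gap_threshold = 0.2) {
  grid <- tidyr::expand_grid(family = unique(seeds$family), species = species)
  counts <- models |>
    group_by(family, species) |>
    summarise(copy_count = n(),
              intact_count = sum(status != "pseudogene_fragment"),
              .groups = "drop")
  out <- grid |>
    left_join(counts, by = c("family", "species")) |>
    mutate(copy_count = coalesce(copy_count, 0L),
           intact_count = coalesce(intact_count, 0L))
  gappy <- if (is.null(gap_fraction)) out[0, c("family", "species")] else
    gap_fraction |> filter(.data$n_fraction > gap_threshold) |>
      select(family, species)
  out |>
    left_join(mutate(gappy, gappy = TRUE), by = c("family", "species")) |>
    mutate(status = case_when(
      copy_count == 0 & coalesce(gappy, FALSE) ~ "not_found",
      copy_count == 0 ~ "absent",
      intact_count == 0 ~ "pseudogene_only",
      copy_count == 1 ~ "present",
      copy_count == 2 ~ "duplicated",
      copy_count == 3 ~ "triplicated",
      TRUE ~ "expanded")) |>
    select(family, species, copy_count, intact_count, status) |>
    arrange(family, species)
}

#' Family-status matrix in wide (families x species) layout
#'
#' @param status long status tibble from [detect_family_status()].
#' @return wide tibble, one row per family, one status column per species.
#' @export
family_status_matrix <- function(status) {
  status |>
    select(family, species, status) |>
    tidyr::pivot_wider(names_from = species, values_from = status) |>
    arrange(family)
}
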