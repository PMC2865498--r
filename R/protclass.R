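# Catalytic-residue classification: align a candidate protein to its
# family seed, read off the residues at the seed's catalytic positions and
# call the candidate a peptidase or a non-peptidase homolog. A single
# substituted or deleted catalytic residue abolishes the canonical
# mechanism, so the threshold is >= 1 (conservative substitutions such as
# Ser->Thr are not granted; override via `tolerated`).

#' Map seed catalytic positions onto a candidate protein
#'
#' Globally aligns the candidate to the seed (BLOSUM62, affine 11/1 — the
#' same scheme as [pairwise_protein_score()]) and reports, for each
#' catalytic seed position, the aligned candidate position and residue
#' (NA when the position is deleted in the candidate).
#'
#' @param seed one-row seed tibble (or list with `sequence` and
#'   `catalytic_positions`).
#' @param candidate non-empty amino-acid string.
#' @return tibble: `seed_pos`, `seed_residue`, `candidate_pos`,
#'   `candidate_residue` (positions 0-based).
#' @export
map_catalytic_positions <- function(seed, candidate) {
  if (!nchar(candidate)) abort("empty candidate protein")
  seed_seq <- if (is.character(seed)) seed else seed$sequence[[1]]
  pos <- if (is.character(seed)) integer() else seed$catalytic_positions[[1]]
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(candidate), Biostrings::AAString(seed_seq),
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global")
  ca <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  s_idx <- cumsum(sa != "-") - 1L   # seed position at each column
  c_idx <- cumsum(ca != "-") - 1L
  rows <- lapply(pos, function(p) {
    col <- match(p, ifelse(sa == "-", NA_integer_, s_idx))
    deleted <- ca[col] == "-"
    tibble(seed_pos = p,
           seed_residue = sa[col],
           candidate_pos = if (deleted) NA_integer_ else c_idx[col],
           candidate_residue = if (deleted) NA_character_ else ca[col])
  })
  bind_rows(rows)
}

#' Call peptidase status from a catalytic-position mapping
#'
#' A candidate is a `non_peptidase_homolog` when at least one catalytic
#' position is substituted (different residue) or deleted (aligned to a
#' gap); otherwise it is a `peptidase`.
#'
#' @param mapping tibble from [map_catalytic_positions()].
#' @param tolerated optional character vector of substitutions (e.g.
#'   `"S>T"`) to accept as conservative; none by default.
#' @return list with `call` and `n_substituted`.
#' @export
call_peptidase_status <- function(mapping, tolerated = character()) {
  edits <- mapping |>
    mutate(edit = is.na(candidate_residue) | candidate_residue != seed_residue,
           tol = paste0(seed_residue, ">", candidate_residue) %in% tolerated) |>
    filter(edit & !tol)
  list(call = if (nrow(edits)) "non_peptidase_homolog" else "peptidase",
       n_substituted = nrow(edits))
}

#' Classify gene models by catalytic-residue conservation
#'
#' For every model, maps the catalytic positions of its family seed onto
#' the predicted protein and calls peptidase / non-peptidase-homolog
#' status. Intact models called non-peptidase homologs have their status
#' upgraded accordingly; pseudogene fragments are classified but keep
#' their status.
#'
#' @param models gene-model tibble with `family` labels.
#' @param seeds seed-protein set.
#' @param tolerated passed to [call_peptidase_status()].
#' @return list with `models` (statuses updated) and `classification`
#'   (per-gene tibble: id, family, class, substituted positions, call).
#' @export
classify_models <- function(models, seeds, tolerated = character()) {
  if (!nrow(models)) {
    return(list(models = models, classification = tibble(
      model_id = character(), family = character(),
      catalytic_class = character(), substituted_positions = character(),
      n_substituted = integer(), call = character())))
  }
  rows <- lapply(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    srow <- seeds[match(m$family, seeds$family), ]
    prot <- gsub("\\*", "", m$protein)
    if (!nchar(prot))
      return(tibble(model_id = m$model_id, family = m$family,
                    catalytic_class = srow$catalytic_class,
                    substituted_positions = "", n_substituted = NA_integer_,
                    call = "unclassifiable"))
    mp <- map_catalytic_positions(srow, prot)
    st <- call_peptidase_status(mp, tolerated)
    subs <- mp |>
      filter(is.na(candidate_residue) | candidate_residue != seed_residue)
    tibble(model_id = m$model_id, family = m$family,
           catalytic_class = srow$catalytic_class,
           substituted_positions = paste(
             sprintf("%s%d%s", subs$seed_residue, subs$seed_pos,
                     coalesce(subs$candidate_residue, "-")), collapse = ","),
           n_substituted = st$n_substituted, call = st$call)
  })
  classification <- bind_rows(rows)
  models$status <- ifelse(
    models$status == "intact" &
      classification$call == "non_peptidase_homolog",
    "non_peptidase_homolog", models$status)
  list(models = models, classification = classification)
}
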