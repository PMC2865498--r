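# Curated seed proteins: the starting set of protease sequences, each with
# a family label, a catalytic class and the positions of its catalytic
# residues. The seed sidecar TSV is the single source of truth for which
# residues count as "key catalytic residues" per family.

# expected number of catalytic residues per mechanistic class:
# serine -> His/Asp/Ser triad, cysteine -> His/Cys dyad, aspartyl -> two
# catalytic Asp, metallo -> three zinc-binding motif residues
CATALYTIC_COUNT <- c(serine = 3L, cysteine = 2L, aspartyl = 2L, metallo = 3L)

#' Build and validate a seed-protein set
#'
#' A seed set is a tibble with one row per curated protein: `id`, `family`,
#' `catalytic_class` (one of serine, cysteine, aspartyl, metallo),
#' `catalytic_positions` (list column of 0-based indices into the protein)
#' and `sequence` (20-letter amino-acid string). Validation enforces that
#' every catalytic position falls inside the sequence and that the number
#' of catalytic residues matches the class (triad for serine proteases,
#' dyad for cysteine, two aspartates for aspartyl, three zinc-binding
#' residues for metalloproteases).
#'
#' @param id,family,catalytic_class character vectors, one entry per seed.
#' @param catalytic_positions list of integer vectors (0-based).
#' @param sequence amino-acid strings, no gaps.
#' @return a validated `tbl_df` of seed proteins.
#' @export
seed_proteins <- function(id, family, catalytic_class, catalytic_positions,
                          sequence) {
  out <- tibble(
    id = as.character(id), family = as.character(family),
    catalytic_class = as.character(catalytic_class),
    catalytic_positions = lapply(catalytic_positions, function(p) sort(as.integer(p))),
    sequence = toupper(as.character(sequence)))
  validate_seed_proteins(out)
}

#' @rdname seed_proteins
#' @param seeds a seed-protein tibble to validate.
#' @export
validate_seed_proteins <- function(seeds) {
  stopifnot(all(c("id", "family", "catalytic_class", "catalytic_positions",
                  "sequence") %in% names(seeds)))
  if (anyDuplicated(seeds$id)) abort("duplicated seed protein ids")
  bad_class <- setdiff(unique(seeds$catalytic_class), names(CATALYTIC_COUNT))
  if (length(bad_class))
    abort(paste0("unknown catalytic class: ", paste(bad_class, collapse = ", ")))
  bad_aa <- !grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"), seeds$sequence)
  if (any(bad_aa))
    abort(paste0("non-standard residues in seed(s): ",
                 paste(seeds$id[bad_aa], collapse = ", ")))
  for (i in seq_len(nrow(seeds))) {
    pos <- seeds$catalytic_positions[[i]]
    len <- nchar(seeds$sequence[i])
    if (any(pos < 0L) || any(pos >= len))
      abort(sprintf("seed %s: catalytic position outside sequence (length %d)",
                    seeds$id[i], len))
    want <- CATALYTIC_COUNT[[seeds$catalytic_class[i]]]
    if (length(pos) != want)
      abort(sprintf("seed %s: %s class expects %d catalytic residues, got %d",
                    seeds$id[i], seeds$catalytic_class[i], want, length(pos)))
  }
  as_tibble(seeds)
}

#' Read / write a seed set (FASTA plus TSV sidecar)
#'
#' The on-disk form is a protein FASTA plus a tab-separated sidecar with
#' columns `id`, `family`, `catalytic_class`, `catalytic_positions`
#' (comma-separated 0-based indices).
#'
#' @param fasta,tsv file paths.
#' @return `read_seed_proteins()` returns a validated seed tibble.
#' @export
read_seed_proteins <- function(fasta, tsv) {
  aas <- Biostrings::readAAStringSet(fasta)
  meta <- readr::read_tsv(
    tsv, show_col_types = FALSE,
    col_types = readr::cols(catalytic_positions = readr::col_character(),
                            .default = readr::col_guess()))
  seqs <- setNames(as.character(aas), sub("\\s.*$", "", names(aas)))
  if (!all(meta$id %in% names(seqs)))
    abort("sidecar ids missing from FASTA")
  seed_proteins(
    id = meta$id, family = meta$family, catalytic_class = meta$catalytic_class,
    catalytic_positions = lapply(strsplit(as.character(meta$catalytic_positions), ","),
                                 as.integer),
    sequence = unname(seqs[meta$id]))
}

#' @rdname read_seed_proteins
#' @param seeds a seed-protein tibble.
#' @export
write_seed_proteins <- function(seeds, fasta, tsv) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(seeds$sequence, seeds$id)), fasta)
  readr::write_tsv(
    tibble(id = seeds$id, family = seeds$family,
           catalytic_class = seeds$catalytic_class,
           catalytic_positions = vapply(seeds$catalytic_positions,
                                        paste, "", collapse = ",")),
    tsv)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Generate a synthetic curated seed set
#'
#' Draws random seed proteins, cycling through the four catalytic classes,
#' with catalytic residues placed at random interior positions. Stands in
#' for a curated protease collection when exercising the pipeline on forged
#' genomes; it is labelled synthetic and carries no biological information.
#'
#' @param families character vector of family names (one seed per family),
#'   or an integer count (names are generated).
#' @param protein_length residues per seed (single value or range).
#' @param classes optional catalytic class per family (cycled through the
#'   four classes when omitted).
#' @param rng_seed integer seed for reproducibility.
#' @return a validated seed tibble.
#' @export
demo_seed_set <- function(families = 12, protein_length = c(160, 220),
                          classes = NULL, rng_seed = 42) {
  if (is.numeric(families) && length(families) == 1)
    families <- sprintf("FAM%02d", seq_len(families))
  classes <- classes %||% rep(names(CATALYTIC_COUNT), length.out = length(families))
  with_seed(rng_seed, {
    rng <- seq(protein_length[1], protein_length[length(protein_length)])
    lens <- rng[sample.int(length(rng), length(families), replace = TRUE)]
    rows <- lapply(seq_along(families), function(i) {
      seq_i <- random_protein(lens[i])
      k <- CATALYTIC_COUNT[[classes[i]]]
      pos <- sort(sample(seq(10L, lens[i] - 11L), k))
      list(id = paste0(families[i], "_seed"), family = families[i],
           class = classes[i], pos = pos, seq = seq_i)
    })
    seed_proteins(
      id = vapply(rows, `[[`, "", "id"),
      family = vapply(rows, `[[`, "", "family"),
      catalytic_class = vapply(rows, `[[`, "", "class"),
      catalytic_positions = lapply(rows, `[[`, "pos"),
      sequence = vapply(rows, `[[`, "", "seq"))
  })
}
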