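# Synthetic genome forge: implants protease genes with known duplication,
# loss and pseudogenization histories into random intergenic background, and
# emits an exact truth table. Coordinates are 0-based half-open throughout;
# minus-strand spans are forward-strand coordinates, splicing is performed
# on the reverse complement.

#' Forge configuration
#'
#' Describes the genomes to forge: which species exist, how many copies of
#' each family each species carries and whether copies are placed in tandem
#' on one contig or dispersed over separate contigs, the expected amino-acid
#' divergence of implanted copies, and any knockouts (catalytic-residue
#' substitution or in-frame stop).
#'
#' Divergence is applied hierarchically: each species first draws a
#' species-level variant of the family seed (at `divergence * (1 -
#' copy_divergence_fraction)`), and each copy then diverges further from
#' that variant (at `divergence * copy_divergence_fraction`), so the
#' expected per-copy divergence from the seed matches `divergence` while
#' within-species duplicates remain each other's closest relatives — the
#' signature a tandem duplication leaves in a gene tree. Catalytic
#' positions are never substituted unless a knockout requests it.
#'
#' @param species character vector of species names.
#' @param plan tibble with columns `species`, `family`, `copies`,
#'   `placement` (`"tandem"` or `"dispersed"`).
#' @param divergence expected substituted fraction per implanted copy,
#'   in `[0, 0.5)`.
#' @param knockouts tibble with columns `species`, `family`, `copy_index`
#'   (1-based), `mode` (`"catalytic_substitution"` or `"inframe_stop"`).
#' @param n_exons exons per gene.
#' @param intron_length,intergenic_length length ranges (min, max) in nt;
#'   introns must be at least 20 nt.
#' @param min_exon_length minimum exon length in nt (codon-rounded).
#' @param copy_divergence_fraction share of `divergence` spent on the
#'   per-copy branch (see Details).
#' @param rng_seed integer; all forge randomness flows from it.
#' @return a `forge_config` list.
#' @export
forge_config <- function(species, plan, divergence = 0.15,
                         knockouts = NULL, n_exons = 3,
                         intron_length = c(120, 240),
                         intergenic_length = c(5500, 9000),
                         min_exon_length = 75L,
                         copy_divergence_fraction = 1 / 3,
                         rng_seed = 1) {
  if (divergence < 0 || divergence >= 0.5)
    abort("divergence must lie in [0, 0.5)")
  if (intron_length[1] < 20) abort("intron lengths must be >= 20 nt")
  plan <- as_tibble(plan)
  stopifnot(all(c("species", "family", "copies", "placement") %in% names(plan)))
  if (!all(plan$placement %in% c("tandem", "dispersed")))
    abort("placement must be 'tandem' or 'dispersed'")
  if (!all(plan$species %in% species)) abort("plan names unknown species")
  if (is.null(knockouts))
    knockouts <- tibble(species = character(), family = character(),
                        copy_index = integer(), mode = character())
  knockouts <- as_tibble(knockouts)
  if (nrow(knockouts) &&
      !all(knockouts$mode %in% c("catalytic_substitution", "inframe_stop")))
    abort("knockout mode must be catalytic_substitution or inframe_stop")
  structure(list(
    species = species, plan = plan, divergence = divergence,
    knockouts = knockouts, n_exons = as.integer(n_exons),
    intron_length = as.integer(intron_length),
    intergenic_length = as.integer(intergenic_length),
    min_exon_length = as.integer(min_exon_length),
    copy_divergence_fraction = copy_divergence_fraction,
    rng_seed = as.integer(rng_seed)), class = "forge_config")
}

# substitute each unprotected position with probability `rate`, always to a
# different residue
diverge_protein <- function(protein, rate, protect = integer()) {
  if (rate <= 0) return(protein)
  res <- strsplit(protein, "")[[1]]
  hit <- stats::runif(length(res)) < rate
  hit[protect + 1L] <- FALSE
  for (i in which(hit)) res[i] <- sample(setdiff(AA20, res[i]), 1)
  paste(res, collapse = "")
}

#' Knock out catalytic residues of a protein
#'
#' `catalytic_substitution` replaces each listed catalytic residue with a
#' different residue drawn at random — the edit that turns an active
#' protease into a non-peptidase homolog. `inframe_stop` leaves the protein
#' untouched here; the stop codon is written during back-translation.
#'
#' @param protein amino-acid string.
#' @param positions 0-based catalytic positions to edit.
#' @param mode `"catalytic_substitution"` or `"inframe_stop"`.
#' @return the edited amino-acid string.
#' @export
knockout_protein <- function(protein, positions,
                             mode = c("catalytic_substitution", "inframe_stop")) {
  mode <- match.arg(mode)
  if (!nchar(protein)) abort("empty protein")
  if (mode == "inframe_stop" || !length(positions)) return(protein)
  res <- strsplit(protein, "")[[1]]
  for (p in positions) res[p + 1L] <- sample(setdiff(AA20, res[p + 1L]), 1)
  paste(res, collapse = "")
}

back_translate <- function(protein) {
  if (is.null(.pkg_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$codons <- split(names(gc), unname(gc))
  }
  tab <- .pkg_cache$codons
  res <- strsplit(protein, "")[[1]]
  paste(vapply(res, function(a) {
    cs <- tab[[a]]
    if (length(cs) == 1) cs else sample(cs, 1)
  }, ""), collapse = "")
}

# split a CDS into n codon-aligned exon chunks (>= min_exon nt each)
plan_exon_cuts <- function(cds_len, n_exons, min_exon = 30L) {
  n_codons <- cds_len %/% 3L
  min_cod <- max(1L, min_exon %/% 3L)
  n_exons <- max(1L, min(n_exons, n_codons %/% min_cod))
  if (n_exons == 1) return(c(0L, cds_len))
  ok <- FALSE
  while (!ok) {
    cuts <- sort(sample(seq_len(n_codons - 1L), n_exons - 1L))
    bounds <- c(0L, cuts, n_codons)
    ok <- all(diff(bounds) >= min_cod)
  }
  bounds * 3L
}

build_gene <- function(protein, config, stop_knockout = FALSE) {
  cds <- back_translate(protein)
  if (stop_knockout) {
    # overwrite an interior codon with TAA -> mid-exon in-frame stop
    n_codons <- nchar(cds) %/% 3L
    at <- max(2L, n_codons %/% 2L)
    substr(cds, (at - 1L) * 3L + 1L, at * 3L) <- "TAA"
  }
  bounds <- plan_exon_cuts(nchar(cds), config$n_exons,
                           min_exon = config$min_exon_length %||% 75L)
  n_ex <- length(bounds) - 1L
  exon_seqs <- substring(cds, head(bounds, -1) + 1L, tail(bounds, -1))
  introns <- replicate(n_ex - 1L, {
    len <- sample_range(config$intron_length[1], config$intron_length[2])
    paste0("GT", random_dna(len - 4L), "AG")
  })
  pieces <- character(0)
  spans <- matrix(0L, n_ex, 2)
  at <- 0L
  for (i in seq_len(n_ex)) {
    spans[i, ] <- c(at, at + nchar(exon_seqs[i]))
    pieces <- c(pieces, exon_seqs[i])
    at <- at + nchar(exon_seqs[i])
    if (i < n_ex) {
      pieces <- c(pieces, introns[i])
      at <- at + nchar(introns[i])
    }
  }
  list(dna = paste(pieces, collapse = ""), spans = spans,
       protein = translate_dna(cds))
}

#' Forge synthetic genomes with an exact truth table
#'
#' Implants back-translated, diverged copies of the seed proteins into
#' random intergenic background according to the plan in `config`. Tandem
#' copies share a contig; dispersed copies get one contig each. Introns
#' carry canonical GT...AG termini. Returns the genomes together with a
#' truth table recording every implanted locus, its exon structure, the
#' implanted protein and its status.
#'
#' @param seeds a validated seed-protein tibble (see [seed_proteins()]).
#' @param config a [forge_config()].
#' @return list with `genomes` (tibble: `contig`, `species`, `sequence`)
#'   and `truth` (tibble: `species`, `family`, `locus_id`, `contig`,
#'   `strand`, `exons` list column of 0-based half-open spans, `protein`,
#'   `status`, `event`).
#' @export
forge_genome <- function(seeds, config) {
  stopifnot(inherits(config, "forge_config"))
  seeds <- validate_seed_proteins(seeds)
  missing <- setdiff(config$plan$family, seeds$family)
  if (length(missing))
    abort(paste0("plan families missing from seeds: ",
                 paste(missing, collapse = ", ")))
  d_copy <- config$divergence * config$copy_divergence_fraction
  d_species <- config$divergence - d_copy
  with_seed(config$rng_seed, {
    genomes <- list(); truth <- list()
    for (sp in config$species) {
      variants <- list()
      for (fam in unique(config$plan$family[config$plan$species == sp])) {
        srow <- seeds[match(fam, seeds$family), ]
        variants[[fam]] <- diverge_protein(srow$sequence, d_species,
                                           protect = srow$catalytic_positions[[1]])
      }
      ctg_i <- 0L
      plan_sp <- config$plan[config$plan$species == sp, ]
      for (r in seq_len(nrow(plan_sp))) {
        fam <- plan_sp$family[r]
        copies <- plan_sp$copies[r]
        if (copies < 1) next
        placement <- plan_sp$placement[r]
        srow <- seeds[match(fam, seeds$family), ]
        cat_pos <- srow$catalytic_positions[[1]]
        units <- list()
        for (ci in seq_len(copies)) {
          prot <- diverge_protein(variants[[fam]], d_copy, protect = cat_pos)
          ko <- config$knockouts[
            config$knockouts$species == sp & config$knockouts$family == fam &
              config$knockouts$copy_index == ci, , drop = FALSE]
          mode <- if (nrow(ko)) ko$mode[1] else NA_character_
          if (identical(mode, "catalytic_substitution"))
            prot <- knockout_protein(prot, cat_pos, "catalytic_substitution")
          g <- build_gene(prot, config,
                          stop_knockout = identical(mode, "inframe_stop"))
          status <- if (identical(mode, "catalytic_substitution"))
            "non_peptidase_homolog"
          else if (identical(mode, "inframe_stop")) "pseudogene_fragment"
          else "intact"
          event <- if (!is.na(mode)) "knockout"
          else if (copies == 1) "single"
          else if (placement == "tandem") "tandem_dup" else "dispersed_dup"
          units[[ci]] <- list(gene = g, status = status, event = event, copy = ci)
        }
        # layout: tandem -> all copies on one fresh contig; dispersed/single
        # -> one contig per copy
        groups <- if (placement == "tandem") list(units) else
          lapply(units, list)
        for (grp in groups) {
          ctg_i <- ctg_i + 1L
          contig <- sprintf("%s_ctg%02d", sp, ctg_i)
          seq_parts <- character(0); at <- 0L
          pad <- function() {
            random_dna(sample_range(config$intergenic_length[1],
                                    config$intergenic_length[2]))
          }
          p <- pad(); seq_parts <- c(seq_parts, p); at <- at + nchar(p)
          for (u in grp) {
            strand <- sample(c("+", "-"), 1)
            g <- u$gene
            glen <- nchar(g$dna)
            dna <- if (strand == "+") g$dna else revcomp(g$dna)
            spans <- g$spans
            fwd <- if (strand == "+") spans + at else {
              m <- cbind(at + glen - spans[, 2], at + glen - spans[, 1])
              m[order(m[, 1]), , drop = FALSE]
            }
            colnames(fwd) <- c("start", "end")
            truth[[length(truth) + 1L]] <- tibble(
              species = sp, family = fam,
              locus_id = sprintf("%s_%s_c%d", fam, sp, u$copy),
              contig = contig, strand = strand, exons = list(fwd),
              protein = g$protein, status = u$status, event = u$event)
            seq_parts <- c(seq_parts, dna); at <- at + glen
            p <- pad(); seq_parts <- c(seq_parts, p); at <- at + nchar(p)
          }
          genomes[[length(genomes) + 1L]] <- tibble(
            contig = contig, species = sp,
            sequence = paste(seq_parts, collapse = ""))
        }
      }
    }
    list(genomes = bind_rows(genomes), truth = bind_rows(truth))
  })
}

#' Splice and translate a set of exon spans
#'
#' Extracts the exon segments (0-based half-open, forward-strand
#' coordinates), concatenates them in forward order, reverse-complements
#' for minus-strand loci, and translates with the standard genetic code.
#'
#' @param sequence contig nucleotide string.
#' @param exons 2-column matrix of 0-based half-open spans.
#' @param strand `"+"` or `"-"`.
#' @return the predicted amino-acid string (may contain `*`).
#' @export
splice_translate <- function(sequence, exons, strand = "+") {
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  cds <- paste(substring(sequence, exons[, 1] + 1L, exons[, 2]), collapse = "")
  if (strand == "-") cds <- revcomp(cds)
  translate_dna(cds)
}

#' @rdname forge_genome
#' @param genomes,truth the two tables returned by `forge_genome()`.
#' @export
truth_proteins <- function(genomes, truth) {
  seqs <- setNames(genomes$sequence, genomes$contig)
  truth |>
    rowwise() |>
    mutate(protein_extracted = splice_translate(seqs[[contig]], exons, strand)) |>
    ungroup()
}

# ---- on-disk forms ------------------------------------------------------

#' Write forged genomes and truth to disk
#'
#' Genomes as FASTA; truth as both a TSV table and a GFF3 with
#' gene/mRNA/CDS features carrying `status` and `event` attributes
#' (1-based inclusive coordinates, per the format).
#'
#' @param genomes,truth tables from [forge_genome()].
#' @param path file path to write.
#' @export
write_genomes_fasta <- function(genomes, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(genomes$sequence, genomes$contig)), path)
  invisible(path)
}

#' @rdname write_genomes_fasta
#' @export
read_genomes_fasta <- function(path, species = NA_character_) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(contig = sub("\\s.*$", "", names(x)), species = species,
         sequence = unname(toupper(as.character(x))))
}

#' @rdname write_genomes_fasta
#' @export
write_truth_tsv <- function(truth, path) {
  out <- truth |>
    mutate(exons = vapply(exons, spans_to_str, "")) |>
    arrange(species, contig, locus_id)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_genomes_fasta
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    mutate(exons = lapply(exons, str_to_spans))
}

#' @rdname write_genomes_fasta
#' @export
write_truth_gff3 <- function(truth, path) {
  lines <- c("##gff-version 3")
  ord <- order(truth$contig, vapply(truth$exons, function(m) m[1, 1], 0L))
  for (i in ord) {
    r <- truth[i, ]
    ex <- r$exons[[1]]
    g0 <- min(ex[, 1]) + 1L; g1 <- max(ex[, 2])
    base <- sprintf("%s\tdegradomics_forge\t%%s\t%%d\t%%d\t.\t%s\t%%s\t%%s",
                    r$contig, r$strand)
    lines <- c(lines,
      sprintf(base, "gene", g0, g1, ".",
              sprintf("ID=%s;status=%s;event=%s;family=%s",
                      r$locus_id, r$status, r$event, r$family)),
      sprintf(base, "mRNA", g0, g1, ".",
              sprintf("ID=%s.t1;Parent=%s", r$locus_id, r$locus_id)))
    # phase: leading incomplete-codon count in coding order
    coding <- if (r$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    phase <- integer(nrow(ex)); acc <- 0L
    for (j in coding) {
      phase[j] <- (3L - acc %% 3L) %% 3L
      acc <- acc + (ex[j, 2] - ex[j, 1])
    }
    for (j in seq_len(nrow(ex)))
      lines <- c(lines, sprintf(base, "CDS", ex[j, 1] + 1L, ex[j, 2],
                                as.character(phase[j]),
                                sprintf("ID=%s.cds;Parent=%s.t1",
                                        r$locus_id, r$locus_id)))
  }
  readr::write_lines(lines, path)
  invisible(path)
}
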