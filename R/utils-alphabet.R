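# Amino-acid alphabet and scoring-matrix plumbing shared by the search,
# alignment and classification code. The canonical residue order is the
# row order of Biostrings' BLOSUM62 (20 residues + B J Z X *).

.pkg_cache <- new.env(parent = emptyenv())

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

#' BLOSUM62 substitution matrix (25-letter alphabet)
#'
#' The standard BLOSUM62 matrix as shipped with Biostrings, over the
#' alphabet `A R N D C Q E G H I L K M F P S T W Y V B J Z X *`. Used for
#' seeding, extension, chaining and all protein alignments in the package.
#'
#' @param stop_penalty if not `NULL`, every score involving the stop symbol
#'   `*` is replaced by this value (the translated-search convention that a
#'   stop codon in a reading frame scores a flat penalty).
#' @return integer matrix with residue dimnames.
#' @export
blosum62 <- function(stop_penalty = NULL) {
  if (is.null(.pkg_cache$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$B62 <- e$BLOSUM62
  }
  m <- .pkg_cache$B62
  if (!is.null(stop_penalty)) {
    m["*", ] <- as.integer(stop_penalty)
    m[, "*"] <- as.integer(stop_penalty)
  }
  m
}

aa_alphabet <- function() rownames(blosum62())

# 0-based integer codes into the BLOSUM62 row order; unknown letters -> X
aa_encode <- function(x) {
  alpha <- aa_alphabet()
  i <- match(strsplit(x, "", fixed = TRUE)[[1]], alpha)
  i[is.na(i)] <- match("X", alpha)
  i - 1L
}

aa_decode <- function(codes) {
  alpha <- aa_alphabet()
  out <- character(length(codes))
  gap <- codes < 0
  out[gap] <- "-"
  out[!gap] <- alpha[codes[!gap] + 1L]
  paste(out, collapse = "")
}

# search scoring matrix: BLOSUM62 with '*' scoring -10 against everything
search_matrix <- function(stop_penalty = -10L) blosum62(stop_penalty = stop_penalty)

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# uniform draw from [lo, hi] that is safe when lo == hi (sample()'s
# scalar-first-argument expansion would otherwise bite)
sample_range <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1)

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# standard genetic code (translation table 1); codons containing N or any
# other ambiguity translate to X, stops to '*'
translate_dna <- function(x) {
  n <- nchar(x)
  n <- n - n %% 3
  if (n == 0) return("")
  if (is.null(.pkg_cache$gc_table))
    .pkg_cache$gc_table <- Biostrings::GENETIC_CODE
  codons <- substring(x, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
  aa <- unname(.pkg_cache$gc_table[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# exon spans <-> compact text form ("s1-e1;s2-e2", 0-based half-open)
spans_to_str <- function(m) paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ";")

str_to_spans <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("start", "end")
  m
}

# run body with a private RNG stream, leaving the caller's RNG untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# derive a bounded child seed from a master seed and a stage tag
child_seed <- function(seed, tag) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(tag)) * 131L) %% 2147483562L
}
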