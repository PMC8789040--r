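# Library designs, degenerate-codon statistics, and IUPAC motif matching.
# These definitions are shared by the selection simulator and the NGS
# analysis: everything downstream counts exact variable regions against the
# designs declared here.

.IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Canonicalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. All user-facing sequence handling in the
#' package is case-insensitive and treats DNA/RNA input equivalently.
#'
#' @param x character vector of sequences.
#' @return character vector over the RNA alphabet.
#' @export
canonicalize_rna <- function(x) {
  chartr("t", "U", chartr("T", "U", toupper(x)))
}

# error with the position of the first illegal character
.validate_rna <- function(x, what = "sequence") {
  bad <- regexpr("[^ACGU]", x)
  hit <- which(bad > 0L)
  if (length(hit) > 0L) {
    i <- hit[1L]
    stop(sprintf("illegal character '%s' in %s %d at position %d",
                 substr(x[i], bad[i], bad[i]), what, i, bad[i]), call. = FALSE)
  }
  invisible(x)
}

#' IUPAC degenerate RNA motif
#'
#' @param pattern IUPAC RNA string (e.g. "UUGUGASGC", S = C or G). Input is
#'   case-insensitive; T is read as U.
#' @param name optional label; defaults to the pattern itself.
#' @return object of class `motif_pattern`.
#' @export
motif_pattern <- function(pattern, name = NULL) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  pat <- canonicalize_rna(pattern)
  chars <- strsplit(pat, "")[[1L]]
  bad <- which(!chars %in% names(.IUPAC_RNA))
  if (length(bad) > 0L)
    stop(sprintf("illegal IUPAC code '%s' at position %d in motif '%s'",
                 chars[bad[1L]], bad[1L], pattern), call. = FALSE)
  structure(list(pattern = pat, name = if (is.null(name)) pat else name),
            class = "motif_pattern")
}

.motif_regex <- function(pattern) {
  chars <- strsplit(pattern, "")[[1L]]
  paste0(vapply(chars, function(ch) {
    ex <- .IUPAC_RNA[[ch]]
    if (length(ex) == 1L) ex else paste0("[", paste(ex, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

#' Match an IUPAC motif anywhere in RNA sequences
#'
#' Contains-match: TRUE iff some ungapped window of the sequence matches the
#' pattern position-by-position under IUPAC expansion.
#'
#' @param sequences character vector over \{A,C,G,U\} (T accepted as U).
#' @param pattern a [motif_pattern()] or a plain IUPAC string.
#' @return logical vector, one element per sequence.
#' @export
motif_match <- function(sequences, pattern) {
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  seqs <- canonicalize_rna(sequences)
  .validate_rna(seqs)
  grepl(.motif_regex(pattern$pattern), seqs)
}

# ---- NNK degenerate-codon statistics ----------------------------------------

#' All 32 NNK codons (N = A/C/G/T, K = G/T)
#' @return character vector of 32 DNA codons.
#' @export
nnk_codons <- function() {
  n <- c("A", "C", "G", "T")
  k <- c("G", "T")
  as.vector(outer(outer(n, n, paste0), k, paste0))
}

#' Amino-acid distribution of an NNK-randomized codon
#'
#' Enumerates the 32 NNK codons under the standard genetic code, each with
#' weight 1/32. NNK encodes all 20 amino acids plus the amber stop (TAG);
#' arginine, leucine and serine are each encoded by 3/32 of the codons, which
#' is the overrepresentation expected (and observed) in NNK libraries.
#'
#' @return named numeric vector of probabilities over the 20 amino-acid
#'   one-letter codes plus "*" (stop); sums to 1.
#' @export
nnk_amino_acid_distribution <- function() {
  codons <- nnk_codons()
  aa <- Biostrings::GENETIC_CODE[codons]
  tab <- table(aa)
  p <- as.numeric(tab) / length(codons)
  names(p) <- names(tab)
  lev <- sort(setdiff(names(p), "*"))
  p[c(lev, "*")]
}

.nnk_codons_by_aa <- function() {
  codons <- nnk_codons()
  split(codons, Biostrings::GENETIC_CODE[codons])
}

# ---- diversity arithmetic ---------------------------------------------------

#' Theoretical sequence diversity of a randomized library
#'
#' `alphabet_size ^ n_positions`, computed by repeated multiplication.
#' Exact as long as the result stays below 2^53 (the exact-integer range of
#' a double); beyond that a warning marks the result as approximate. The
#' relevant designs here (20^8 = 2.56e10 protein variants, 4^20 = 1.1e12
#' RNA loops) are exact.
#'
#' @param n_positions number of randomized positions (>= 0).
#' @param alphabet_size residues per position (>= 1).
#' @return numeric count (exact integer-valued below 2^53).
#' @export
theoretical_diversity <- function(n_positions, alphabet_size) {
  stopifnot(length(n_positions) == 1L, length(alphabet_size) == 1L)
  if (n_positions < 0 || n_positions != trunc(n_positions))
    stop("n_positions must be a nonnegative integer", call. = FALSE)
  if (alphabet_size < 1 || alphabet_size != trunc(alphabet_size))
    stop("alphabet_size must be a positive integer", call. = FALSE)
  if (n_positions > 0 && n_positions * log2(alphabet_size) > 53)
    warning("diversity exceeds 2^53; result not exact in double precision")
  prod(rep(as.numeric(alphabet_size), n_positions))
}

#' Size of the combinatorial RNA x protein interaction space
#'
#' Product of the two library diversities: the number of pairwise
#' combinations a library-vs-library selection can in principle explore.
#'
#' @param rna_diversity,protein_diversity nonnegative counts.
#' @return numeric product.
#' @export
combination_space <- function(rna_diversity, protein_diversity) {
  stopifnot(rna_diversity >= 0, protein_diversity >= 0)
  rna_diversity * protein_diversity
}

# ---- library designs --------------------------------------------------------

#' RNA library design
#'
#' A variable loop flanked by fixed sequences; the 3' flank carries the
#' docking sequence hybridized by the capture oligonucleotide in the second
#' purification step.
#'
#' @param fixed_5p,fixed_3p fixed flanks (RNA; T read as U), nonempty.
#' @param variable_length loop length in nt (> 0).
#' @param docking_sequence fixed segment that must be a substring of
#'   `fixed_3p`.
#' @return object of class `rna_library_design`.
#' @export
rna_library_design <- function(fixed_5p, variable_length, fixed_3p,
                               docking_sequence) {
  fixed_5p <- canonicalize_rna(fixed_5p)
  fixed_3p <- canonicalize_rna(fixed_3p)
  docking_sequence <- canonicalize_rna(docking_sequence)
  .validate_rna(c(fixed_5p, fixed_3p, docking_sequence), "flank")
  stopifnot(nzchar(fixed_5p), nzchar(fixed_3p),
            length(variable_length) == 1L, variable_length > 0)
  if (!grepl(docking_sequence, fixed_3p, fixed = TRUE))
    stop("docking sequence must be a substring of the 3' fixed flank",
         call. = FALSE)
  structure(list(fixed_5p = fixed_5p,
                 variable_length = as.integer(variable_length),
                 fixed_3p = fixed_3p,
                 docking_sequence = docking_sequence),
            class = "rna_library_design")
}

#' Default hairpin N20-loop RNA library design
#'
#' 20 randomized loop nucleotides between complementary fixed stem segments.
#' The docking sequence is the reverse complement of the bead capture oligo
#' (5'-CGTTCTGTGTCTTTCGTCGAT-3'); the remaining flank sequence is a synthetic
#' stand-in with the same architecture (self-complementary stem closing the
#' loop), as the original flanks are not part of this package.
#'
#' @return an [rna_library_design()].
#' @export
hairpin_n20_design <- function() {
  # docking = revcomp(CGTTCTGTGTCTTTCGTCGAT) on the RNA strand
  docking <- "AUCGACGAAAGACACAGAACG"
  rna_library_design(
    fixed_5p = "GGGAGAGACGCGUGGCC",
    variable_length = 20L,
    fixed_3p = paste0("GGCCACGC", docking),
    docking_sequence = docking
  )
}

#' Protein (phage-display) library design
#'
#' A scaffold with a small set of NNK-randomized surface residues.
#'
#' @param scaffold amino-acid string (one-letter codes).
#' @param randomized_positions strictly increasing 1-based residue indices,
#'   length 8, all within the scaffold.
#' @param read_codon_start 1-based scaffold codon at which sequencing reads
#'   of the mutated region begin (reads are in frame from this codon).
#' @return object of class `protein_library_design`.
#' @export
protein_library_design <- function(scaffold, randomized_positions,
                                   read_codon_start = min(randomized_positions)) {
  stopifnot(is.character(scaffold), length(scaffold) == 1L)
  pos <- as.integer(randomized_positions)
  if (length(pos) != 8L || any(diff(pos) <= 0L))
    stop("randomized_positions must be 8 strictly increasing indices",
         call. = FALSE)
  if (min(pos) < 1L || max(pos) > nchar(scaffold))
    stop("randomized positions outside scaffold", call. = FALSE)
  stopifnot(read_codon_start >= 1L, read_codon_start <= min(pos))
  structure(list(scaffold = toupper(scaffold),
                 randomized_positions = pos,
                 codon_scheme = "NNK",
                 read_codon_start = as.integer(read_codon_start)),
            class = "protein_library_design")
}

#' Default L7Ae-scaffold protein library design
#'
#' Eight NNK-randomized surface residues at scaffold positions 34, 37, 40,
#' 88, 89, 90, 91 and 92 (1-based): three charged residues of the alpha-2
#' helix (E34, K37, E40) and the five-residue loop I88-C92 that together form
#' the kink-turn RNA binding face; R41 is kept fixed. The scaffold string is
#' a synthetic 95-residue stand-in that places the canonical wild-type
#' residues at the randomized positions and at R41; it is a preset, not
#' hard-coded logic, so a real scaffold sequence can be supplied instead.
#'
#' @return a [protein_library_design()].
#' @export
l7ae_scaffold_design <- function() {
  aa <- rep(strsplit("GASLVKTDEA", "")[[1L]], length.out = 95L)
  aa[1L] <- "M"
  fixed <- c("34" = "E", "37" = "K", "40" = "E", "41" = "R",
             "88" = "I", "89" = "E", "90" = "V", "91" = "P", "92" = "C")
  aa[as.integer(names(fixed))] <- fixed
  protein_library_design(paste(aa, collapse = ""),
                         randomized_positions = c(34L, 37L, 40L, 88L, 89L,
                                                  90L, 91L, 92L),
                         read_codon_start = 34L)
}

#' Amino-acid distribution container
#'
#' Validates a probability map over the 20 amino acids plus stop.
#'
#' @param p named numeric vector; nonnegative, sums to 1 within 1e-12.
#' @return the validated vector, classed `aa_distribution`.
#' @export
aa_distribution <- function(p) {
  stopifnot(is.numeric(p), !is.null(names(p)), all(p >= 0))
  if (abs(sum(p) - 1) > 1e-12)
    stop("probabilities must sum to 1 within 1e-12", call. = FALSE)
  structure(p, class = c("aa_distribution", class(p)))
}

# ---- translation of protein-library reads -----------------------------------

#' Translate the randomized residues out of in-frame DNA reads
#'
#' Reads are assumed in frame starting at scaffold codon
#' `design$read_codon_start`. Returns the 8 residues at the randomized
#' positions; stop codons are reported as "*". Reads that are frame-shifted
#' (length not a multiple of 3), too short to cover all randomized codons, or
#' containing non-ACGT characters at a randomized codon are rejected
#' (`NA` with a reason in `attr(, "reject_reason")`).
#'
#' @param dna_reads character vector of DNA reads.
#' @param design a [protein_library_design()].
#' @return character vector of 8-mers (with possible "*"), NA where rejected.
#' @export
translate_variable_region <- function(dna_reads, design) {
  stopifnot(inherits(design, "protein_library_design"))
  reads <- toupper(dna_reads)
  n <- length(reads)
  out <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  offs <- design$randomized_positions - design$read_codon_start  # codon offsets
  need <- (max(offs) + 1L) * 3L
  len <- nchar(reads)
  bad_frame <- len %% 3L != 0L
  short <- len < need
  reason[short] <- "read_too_short"
  reason[bad_frame & !short] <- "frame_shift"
  ok <- !bad_frame & !short
  if (any(ok)) {
    idx <- which(ok)
    codons <- vapply(offs, function(o)
      substr(reads[idx], o * 3L + 1L, o * 3L + 3L), character(length(idx)))
    if (length(idx) == 1L) codons <- matrix(codons, nrow = 1L)
    aa <- matrix(Biostrings::GENETIC_CODE[codons], nrow = length(idx))
    bad_base <- apply(is.na(aa), 1L, any)
    reason[idx[bad_base]] <- "ambiguous_base"
    keep <- idx[!bad_base]
    if (length(keep) > 0L)
      out[keep] <- apply(aa[!bad_base, , drop = FALSE], 1L, paste, collapse = "")
  }
  attr(out, "reject_reason") <- reason
  out
}

#' Encode randomized 8-mers as NNK-consistent DNA reads
#'
#' Inverse of [translate_variable_region()] for simulation: builds an
#' in-frame DNA read covering scaffold codons `read_codon_start` .. max
#' randomized position, back-translating fixed scaffold residues with a
#' deterministic codon choice and randomized residues with a random
#' NNK-consistent codon.
#'
#' @param aa8 character vector of 8-mers over the randomized positions
#'   (may contain "*").
#' @param design a [protein_library_design()].
#' @param seed optional integer seed for the NNK codon draw.
#' @return character vector of DNA reads.
#' @export
encode_variable_region <- function(aa8, design, seed = NULL) {
  stopifnot(inherits(design, "protein_library_design"))
  stopifnot(all(nchar(aa8) == 8L))
  run <- function() .encode_vr(aa8, design)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.encode_vr <- function(aa8, design) {
  by_aa <- .nnk_codons_by_aa()
  # deterministic back-translation table for fixed scaffold residues
  all_aa <- unique(Biostrings::GENETIC_CODE)
  det <- vapply(all_aa, function(a)
    sort(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a])[1L],
    character(1L))
  names(det) <- all_aa
  start <- design$read_codon_start
  stop_at <- max(design$randomized_positions)
  scaff <- strsplit(substr(design$scaffold, start, stop_at), "")[[1L]]
  rand_off <- design$randomized_positions - start + 1L
  vapply(aa8, function(a8) {
    codons <- det[scaff]
    res <- strsplit(a8, "")[[1L]]
    for (k in seq_len(8L)) {
      choices <- by_aa[[res[k]]]
      if (is.null(choices))
        stop(sprintf("residue '%s' is not NNK-encodable", res[k]), call. = FALSE)
      codons[rand_off[k]] <- choices[sample.int(length(choices), 1L)]
    }
    paste(codons, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
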