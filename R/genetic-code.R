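# Genetic-code utilities and protein-variant representation.
#
# Coordinates are 1-based inclusive throughout (residues and codons), the
# clinical convention. The amino-acid alphabet is the 20 canonical residues
# plus the stop signal "Ter"; ambiguity codes and non-canonical residues
# (e.g. selenocysteine) are rejected.

# Standard genetic code, DNA alphabet, keyed by codon.
.GENETIC_CODE <- c(
  TTT = "Phe", TTC = "Phe", TTA = "Leu", TTG = "Leu",
  CTT = "Leu", CTC = "Leu", CTA = "Leu", CTG = "Leu",
  ATT = "Ile", ATC = "Ile", ATA = "Ile", ATG = "Met",
  GTT = "Val", GTC = "Val", GTA = "Val", GTG = "Val",
  TCT = "Ser", TCC = "Ser", TCA = "Ser", TCG = "Ser",
  CCT = "Pro", CCC = "Pro", CCA = "Pro", CCG = "Pro",
  ACT = "Thr", ACC = "Thr", ACA = "Thr", ACG = "Thr",
  GCT = "Ala", GCC = "Ala", GCA = "Ala", GCG = "Ala",
  TAT = "Tyr", TAC = "Tyr", TAA = "Ter", TAG = "Ter",
  CAT = "His", CAC = "His", CAA = "Gln", CAG = "Gln",
  AAT = "Asn", AAC = "Asn", AAA = "Lys", AAG = "Lys",
  GAT = "Asp", GAC = "Asp", GAA = "Glu", GAG = "Glu",
  TGT = "Cys", TGC = "Cys", TGA = "Ter", TGG = "Trp",
  CGT = "Arg", CGC = "Arg", CGA = "Arg", CGG = "Arg",
  AGT = "Ser", AGC = "Ser", AGA = "Arg", AGG = "Arg",
  GGT = "Gly", GGC = "Gly", GGA = "Gly", GGG = "Gly"
)

# Three-letter <-> one-letter amino-acid codes ("Ter"/"*" for stop).
.AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val", "Ter")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W",
          "Y", "V", "*")
names(.AA1) <- .AA3
.AA3_BY_1 <- .AA3
names(.AA3_BY_1) <- .AA1

.check_codon <- function(codon) {
  if (length(codon) != 1L || is.na(codon) || nchar(codon) != 3L ||
      grepl("[^ACGT]", codon))
    stop("invalid codon: '", codon, "' (need a triplet over A/C/G/T)",
         call. = FALSE)
  codon
}

#' Translate a codon with the standard genetic code
#'
#' @param codon Character scalar, a nucleotide triplet over \code{A,C,G,T}
#'   (DNA alphabet, upper case).
#' @return Three-letter amino-acid code, or \code{"Ter"} for a stop codon.
#' @examples
#' translate_codon("ATG")  # "Met"
#' translate_codon("TGA")  # "Ter"
#' @export
translate_codon <- function(codon) {
  unname(.GENETIC_CODE[[.check_codon(toupper(codon))]])
}

#' Amino-acid outcomes reachable from a codon by one nucleotide change
#'
#' Enumerates the nine single-nucleotide neighbours of \code{codon},
#' translates each, and returns the distinct amino-acid outcomes other than
#' the codon's own translation. Stop (\code{"Ter"}) is included where
#' reachable. This is the per-codon primitive behind the SNV-accessibility
#' flag carried by score tables: substitutions reachable by a single
#' nucleotide variant are the ones most likely to be observed clinically.
#'
#' @inheritParams translate_codon
#' @return Character vector of distinct three-letter amino-acid codes
#'   (possibly including \code{"Ter"}), excluding the reference amino acid;
#'   at most 9 long.
#' @examples
#' snv_neighbor_substitutions("TGG")  # Trp codon: 6 reachable outcomes
#' @export
snv_neighbor_substitutions <- function(codon) {
  codon <- .check_codon(toupper(codon))
  ref_aa <- .GENETIC_CODE[[codon]]
  bases <- c("A", "C", "G", "T")
  nts <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (i in 1:3) {
    for (b in setdiff(bases, nts[i])) {
      alt <- nts
      alt[i] <- b
      out <- c(out, .GENETIC_CODE[[paste(alt, collapse = "")]])
    }
  }
  setdiff(unique(out), ref_aa)
}

#' Construct a protein variant
#'
#' A \code{protein_variant} records one amino-acid change: a 1-based residue
#' position, the reference and alternative amino acids (three-letter codes,
#' \code{"Ter"} allowed as alternative), and a derived class:
#' \code{synonymous} when ref and alt are equal, \code{nonsense} when the
#' alternative is \code{Ter}, otherwise \code{missense}.
#'
#' @param position Integer residue index, 1-based.
#' @param ref_aa,alt_aa Three-letter amino-acid codes; \code{alt_aa} may be
#'   \code{"Ter"}.
#' @param protein_length Optional protein length to validate \code{position}
#'   against.
#' @return A list of class \code{"protein_variant"} with fields
#'   \code{position}, \code{ref_aa}, \code{alt_aa}, \code{vclass}.
#' @examples
#' protein_variant(78, "Trp", "Arg")
#' @export
protein_variant <- function(position, ref_aa, alt_aa, protein_length = NULL) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L)
    stop("position must be a positive integer, got '", position, "'",
         call. = FALSE)
  if (!is.null(protein_length) && position > protein_length)
    stop("position ", position, " exceeds protein length ", protein_length,
         call. = FALSE)
  if (!ref_aa %in% setdiff(.AA3, "Ter"))
    stop("unknown reference amino acid: '", ref_aa, "'", call. = FALSE)
  if (!alt_aa %in% .AA3)
    stop("unknown alternative amino acid: '", alt_aa, "'", call. = FALSE)
  vclass <- if (alt_aa == "Ter") "nonsense"
            else if (ref_aa == alt_aa) "synonymous"
            else "missense"
  structure(list(position = position, ref_aa = ref_aa, alt_aa = alt_aa,
                 vclass = vclass),
            class = "protein_variant")
}

#' Parse a protein-level HGVS variant string
#'
#' Accepts the minimal protein-level HGVS dialect used in clinical variant
#' reporting: \code{"p.<Ref3><pos><Alt3>"}, with \code{"Ter"} for a stop
#' gain and \code{"="} for a synonymous change (e.g. \code{"p.Trp78Arg"},
#' \code{"p.Arg92Ter"}, \code{"p.Ser278="}). Genomic and cDNA HGVS are out
#' of scope.
#'
#' @param text Character scalar (or vector) of HGVS-style strings.
#' @inheritParams protein_variant
#' @return A \code{protein_variant} (or a list of them for vector input).
#' @examples
#' parse_protein_variant("p.Trp78Arg")
#' parse_protein_variant("p.Ser278=")
#' @export
parse_protein_variant <- function(text, protein_length = NULL) {
  if (length(text) > 1L)
    return(lapply(text, parse_protein_variant, protein_length = protein_length))
  m <- regmatches(text,
                  regexec("^p\\.([A-Za-z]{3})([0-9]+)([A-Za-z]{3}|=)$", text))[[1]]
  if (length(m) == 0L)
    stop("cannot parse protein variant: '", text, "'", call. = FALSE)
  ref <- m[2]; pos <- as.integer(m[3]); alt <- m[4]
  if (alt == "=") alt <- ref
  protein_variant(pos, ref, alt, protein_length = protein_length)
}

#' Format a protein variant as an HGVS string
#'
#' Inverse of \code{\link{parse_protein_variant}}: synonymous variants are
#' written with the \code{"="} shorthand.
#'
#' @param v A \code{protein_variant}.
#' @return Character scalar like \code{"p.Trp78Arg"}.
#' @export
format_protein_variant <- function(v) {
  stopifnot(inherits(v, "protein_variant"))
  if (v$vclass == "synonymous")
    paste0("p.", v$ref_aa, v$position, "=")
  else
    paste0("p.", v$ref_aa, v$position, v$alt_aa)
}

#' @export
print.protein_variant <- function(x, ...) {
  cat(format_protein_variant(x), " (", x$vclass, ")\n", sep = "")
  invisible(x)
}

#' @export
format.protein_variant <- function(x, ...) format_protein_variant(x)

#' Size of the single-substitution space of a protein
#'
#' Each of the \code{L} residues admits 19 missense substitutions and one
#' nonsense substitution, hence \code{20 * L} possible single amino-acid
#' substitutions.
#'
#' @param protein_length Protein length in residues (\code{>= 1}).
#' @return Integer count of possible substitutions.
#' @examples
#' substitution_space(545)  # 10900
#' @export
substitution_space <- function(protein_length) {
  protein_length <- as.integer(protein_length)
  if (is.na(protein_length) || protein_length < 1L)
    stop("protein_length must be >= 1", call. = FALSE)
  20L * protein_length
}

#' Enumerate substitutions reachable by single-nucleotide variants of a CDS
#'
#' Applies \code{\link{snv_neighbor_substitutions}} to each codon of a
#' coding sequence and maps the outcomes to residue positions. Nonsense
#' outcomes are included (a variant effect map scores nonsense changes);
#' synonymous outcomes are excluded by construction.
#'
#' @param cds Character scalar: in-frame coding nucleotide sequence over
#'   \code{A,C,G,T}, length divisible by 3. A trailing stop codon, if
#'   present, is enumerated like any other codon.
#' @return A data.frame with columns \code{position}, \code{ref_aa},
#'   \code{alt_aa}, \code{vclass}, one row per distinct reachable
#'   substitution.
#' @examples
#' snv_accessible_substitutions("ATGTGG")
#' @export
snv_accessible_substitutions <- function(cds) {
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds))
    stop("CDS contains non-ACGT characters", call. = FALSE)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length ", nchar(cds), " is not divisible by 3", call. = FALSE)
  n <- nchar(cds) %/% 3L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    codon <- substr(cds, 3L * i - 2L, 3L * i)
    ref <- translate_codon(codon)
    alts <- snv_neighbor_substitutions(codon)
    if (length(alts))
      rows[[i]] <- data.frame(position = i, ref_aa = ref, alt_aa = alts,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$vclass <- ifelse(out$alt_aa == "Ter", "nonsense", "missense")
  rownames(out) <- NULL
  out
}

#' Number of alternative codons under an NNN degenerate oligo
#'
#' An NNN degenerate codon encodes all 64 triplets, 63 of which differ from
#' any given reference codon.
#'
#' @param codon Reference codon (validated, otherwise unused).
#' @return 63.
#' @export
n_codon_alternatives <- function(codon = "ATG") {
  .check_codon(toupper(codon))
  63L
}

#' Expected number of clones to avoid library bottlenecks
#'
#' Planning arithmetic for mutagenic library cloning: to carry each codon
#' substitution on an expected \code{clones_per_sub} independent clones, a
#' region of \code{region_length} codons with \code{possible_codon_subs}
#' alternatives per codon and a mean of \code{lambda} substitutions per
#' clone requires \code{possible_codon_subs * region_length *
#' clones_per_sub / lambda} colonies.
#'
#' @param possible_codon_subs Alternatives per codon (63 for NNN oligos).
#' @param region_length Codons in the mutagenic region.
#' @param clones_per_sub Target independent clones per substitution.
#' @param lambda Mean substitutions per clone (> 0).
#' @return Expected colony count.
#' @examples
#' expected_colonies(63, 182, 50, 1.0)  # 573300
#' @export
expected_colonies <- function(possible_codon_subs, region_length,
                              clones_per_sub, lambda) {
  if (!is.numeric(lambda) || lambda <= 0)
    stop("lambda must be > 0", call. = FALSE)
  possible_codon_subs * region_length * clones_per_sub / lambda
}

# one-letter helper used by category analyses
aa_one_letter <- function(aa3) unname(.AA1[aa3])
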