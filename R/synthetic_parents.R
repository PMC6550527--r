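# Synthetic stand-in parent genomes for the packaged mutant catalog.
# The real parent genome sequences are not shipped; these constructs place a
# minus-strand rep gene so that every coordinate-level rep mutation in the
# catalog lands on its annotated codon. The layouts are mutually consistent
# with the catalog coordinates (e.g. both Et2Brutus rep mutations pin the
# same gene 3' end).

PARENT_REP_LAYOUTS <- list(
  Bxb1      = list(start = 44280, end = 44762, len = 160, fixed = c("138" = "CAG")),
  Pioneer   = list(start = 44294, end = 44716, len = 140, fixed = c("48" = "TAC")),
  Et2Brutus = list(start = 44432, end = 44884, len = 150, fixed = c("38" = "GCT", "102" = "TCA")),
  DaVinci   = list(start = 43158, end = 43580, len = 140, fixed = c("52" = "CGT")),
  Gladiator = list(start = 43828, end = 44280, len = 150, fixed = c("135" = "CGT")),
  RedRock   = list(start = 45277, end = 45759, len = 160, fixed = c("149" = "CGT")),
  EagleEye  = list(start = 45800, end = 46300, len = 166, fixed = c()),
  Che12     = list(start = 44200, end = 45000, len = 266, fixed = c()),
  L5        = list(start = 44331, end = 44882, len = 183, fixed = c())
)

# one non-stop codon per amino acid, deterministic
AA_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
              H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
              P = "CCT", Q = "CAG", R = "CGT", S = "TCA", T = "ACT", V = "GTT",
              W = "TGG", Y = "TAC")

#' Synthetic parent genome for a catalog phage
#'
#' Builds a synthetic stand-in genome for one of the mutant catalog's parent
#' phages: random background sequence with a minus-strand repressor gene
#' whose coordinates are consistent with every rep-locus mutation recorded
#' for that parent in the catalog (the annotated codons fall at the
#' annotated coordinates). These are labelled synthetic: only the rep-gene
#' geometry, not the real sequence, reflects the parent phage.
#'
#' @param parent One of `names(synthetic_parent_layouts())`.
#' @param genome_length Total genome length (default 52 kb).
#' @param seed RNG seed for background and unconstrained codons.
#' @return List with `sequence`, `rep_gene` (`start`, `end`, `strand`) and
#'   `protein` (the encoded repressor).
#' @export
synthetic_parent_genome <- function(parent, genome_length = 52000, seed = 404) {
  lay <- PARENT_REP_LAYOUTS[[parent]]
  if (is.null(lay)) stop("no synthetic layout for parent '", parent, "'")
  with_seed(seed + nchar(parent) + lay$start %% 1000, {
    stopifnot(lay$end - lay$start + 1 == 3 * (lay$len + 1))
    prot <- c("M", sample(names(AA_CODON), lay$len - 1, replace = TRUE))
    codons <- unname(AA_CODON[prot])
    for (pos in names(lay$fixed)) codons[as.integer(pos)] <- lay$fixed[[pos]]
    # fixed codons may encode a different residue than the draft; recompute
    prot <- vapply(codons, function(cd) names(AA_CODON)[AA_CODON == cd][1], character(1))
    cds <- paste(c(codons, "TAA"), collapse = "")
    bg <- random_dna(genome_length)
    seq <- bg
    substr(seq, lay$start, lay$end) <- revcomp(cds)
    list(sequence = seq,
         rep_gene = list(start = lay$start, end = lay$end, strand = "-"),
         protein = paste(prot, collapse = ""))
  })
}

#' Available synthetic parent layouts
#'
#' @return Named list of rep-gene layouts used by [synthetic_parent_genome()].
#' @export
synthetic_parent_layouts <- function() PARENT_REP_LAYOUTS
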