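#' Whole-genome nucleotide distance
#'
#' Anchor-based estimator of whole-genome nucleotide distance: exact k-mer
#' seeds (both strands), merged into shared-segment coverage on each genome;
#' the matched fraction `f = (covered_A + covered_B) / (len_A + len_B)` is
#' mapped to `D_Nuc = (1 - f) / 2`, so identical genomes score 0 and genomes
#' with no shared k-mers score 0.5. The estimator is symmetric and invariant
#' under reverse-complementing either genome.
#'
#' @param gA,gB `phage_genome` objects or DNA strings.
#' @param k Seed length (default 13, the stoperator scale).
#' @param min_anchor Minimum merged exact-run length (bp) for a shared
#'   segment to count; short chance seed hits below this length are noise
#'   and are discarded.
#' @param max_occ Low-complexity filter: k-mers occurring more than this many
#'   times in either sequence are not used as seeds.
#' @return Distance in [0, 0.5].
#' @export
nucleotide_distance <- function(gA, gB, k = 13, min_anchor = 40, max_occ = 10) {
  a <- if (inherits(gA, "phage_genome")) gA$sequence else toupper(as.character(gA))
  b <- if (inherits(gB, "phage_genome")) gB$sequence else toupper(as.character(gB))
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  cov <- function(x, y) segment_coverage(x, y, k, min_anchor, max_occ)
  cov_a <- cov(a, b) | cov(a, revcomp(b))
  cov_b <- cov(b, a) | cov(b, revcomp(a))
  f <- (sum(cov_a) + sum(cov_b)) / (nchar(a) + nchar(b))
  max(0, min(0.5, (1 - f) / 2))
}

# positions of x covered by maximal exact shared runs (>= min_anchor) with y
segment_coverage <- function(x, y, k, min_anchor, max_occ) {
  Lx <- nchar(x)
  covv <- logical(Lx)
  if (Lx < k || nchar(y) < k) return(covv)
  kx <- all_kmers(x, k)
  ky <- all_kmers(y, k)
  tx <- table(kx); ty <- table(ky)
  good <- intersect(names(tx)[tx <= max_occ], names(ty)[ty <= max_occ])
  shared <- intersect(good, intersect(kx, ky))
  if (!length(shared)) return(covv)
  pos_x <- which(kx %in% shared)
  posmap_y <- split(seq_along(ky), ky)
  # seed pairs (i, j) grouped by diagonal i - j, merged into maximal runs
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (i in pos_x) {
    js <- posmap_y[[kx[i]]]
    pairs_i <- c(pairs_i, rep.int(i, length(js)))
    pairs_j <- c(pairs_j, js)
  }
  diag <- pairs_i - pairs_j
  for (d in unique(diag)) {
    ii <- sort(pairs_i[diag == d])
    run_start <- ii[c(TRUE, diff(ii) > 1)]
    run_end <- ii[c(diff(ii) > 1, TRUE)] + k - 1L
    long <- (run_end - run_start + 1L) >= min_anchor
    for (r in which(long)) covv[run_start[r]:run_end[r]] <- TRUE
  }
  covv
}

#' Gene content dissimilarity
#'
#' `D_GC = 1 - mean(|A∩B|/|A|, |A∩B|/|B|)`: 0 when all phams are shared,
#' 1 when none are.
#'
#' @param phamsA,phamsB Character vectors (sets) of pham identifiers, or
#'   `phage_genome` objects (phams taken from the gene table).
#' @return Dissimilarity in [0, 1].
#' @export
gene_content_dissimilarity <- function(phamsA, phamsB) {
  if (inherits(phamsA, "phage_genome")) phamsA <- phamsA$genes$pham
  if (inherits(phamsB, "phage_genome")) phamsB <- phamsB$genes$pham
  A <- unique(phamsA); B <- unique(phamsB)
  if (!length(A) || !length(B)) stop("empty pham set")
  shared <- length(intersect(A, B))
  1 - mean(c(shared / length(A), shared / length(B)))
}

#' Pairwise protein distance per 100 aa
#'
#' Globally aligns two protein sequences (affine gaps, BLOSUM62) and reports
#' the uncorrected distance with no gap weight: 100 times the number of
#' mismatched non-gap columns over the number of non-gap aligned columns.
#' Gap columns contribute to neither numerator nor denominator.
#'
#' @param seqA,seqB Protein strings.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return Substitutions per 100 aa in [0, 100], or `NA` when no non-gap
#'   columns exist.
#' @export
protein_distance <- function(seqA, seqB, gap_open = 10, gap_extend = 0.5) {
  if (!nchar(seqA) || !nchar(seqB)) stop("empty protein sequence")
  if (seqA == seqB) return(0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  nongap <- pa != "-" & sa != "-"
  if (!any(nongap)) return(NA_real_)
  100 * sum(pa[nongap] != sa[nongap]) / sum(nongap)
}

#' Split a repressor sequence into N- and C-terminal regions
#'
#' The split position defaults to the end of residue 60 (just downstream of
#' the ~20-aa helix-turn-helix DNA-binding domain); it is configurable
#' because different references place the domain boundary differently.
#'
#' @param rep_seq Repressor protein string.
#' @param split_position Last residue of the N-terminal region.
#' @return List with `nterm` and `cterm` strings.
#' @export
split_rep_regions <- function(rep_seq, split_position = 60) {
  L <- nchar(rep_seq)
  if (split_position <= 0 || split_position >= L)
    stop("split_position must lie strictly inside the sequence")
  list(nterm = substr(rep_seq, 1, split_position),
       cterm = substr(rep_seq, split_position + 1, L))
}

#' Hamming distance between two helix-turn-helix domains
#'
#' @param hthA,hthB 20-residue domain strings.
#' @return Integer count of differing positions (0..20).
#' @export
hth_hamming <- function(hthA, hthB) {
  if (nchar(hthA) != 20 || nchar(hthB) != 20)
    stop("helix-turn-helix domains must be exactly 20 aa")
  hamming(hthA, hthB)
}

#' Assemble all pairwise genotype distance matrices
#'
#' Computes, for every pair of phages, the whole-genome nucleotide distance,
#' gene content dissimilarity, stoperator motif distance (when motif models
#' are supplied), repressor distances (full length, N-terminal, C-terminal,
#' helix-turn-helix Hamming) and distances for any additional annotated
#' protein. Pairs lacking the needed input get `NA`.
#'
#' @param genomes Named list of `phage_genome`.
#' @param motifs Optional named list of `motif_model` (same ids).
#' @param proteins Optional named list: `proteins$rep[[id]]` repressor strings,
#'   `proteins$hth[[id]]` 20-aa domains, plus any further named protein sets
#'   (e.g., `proteins$portal`), each a named character vector/list by phage id.
#' @param rep_split N-/C-terminal split position (see [split_rep_regions()]).
#' @param k Seed length for [nucleotide_distance()].
#' @return Object of class `distance_table`: list with `ids` and `matrices`
#'   (named list of symmetric matrices with zero diagonals).
#' @export
assemble_distance_table <- function(genomes, motifs = NULL, proteins = NULL,
                                    rep_split = 60, k = 13) {
  ids <- names(genomes)
  n <- length(ids)
  mk <- function() matrix(NA_real_, n, n, dimnames = list(ids, ids))
  mats <- list(D_Nuc = mk(), D_GC = mk())
  if (!is.null(motifs)) mats$D_Stop_motif <- mk()
  have_rep <- !is.null(proteins$rep)
  if (have_rep) {
    mats$D_Rep <- mk(); mats$D_Rep_Nterm <- mk(); mats$D_Rep_Cterm <- mk()
  }
  if (!is.null(proteins$hth)) mats$D_Rep_HTH <- mk()
  extra <- setdiff(names(proteins), c("rep", "hth"))
  for (e in extra) mats[[paste0("D_", e)]] <- mk()
  for (i in seq_len(n)) {
    for (j in i:n) {
      A <- ids[i]; B <- ids[j]
      mats$D_Nuc[i, j] <- if (i == j) 0 else nucleotide_distance(genomes[[A]], genomes[[B]], k = k)
      mats$D_GC[i, j] <- if (i == j) 0 else gene_content_dissimilarity(genomes[[A]], genomes[[B]])
      if (!is.null(motifs) && !is.null(motifs[[A]]) && !is.null(motifs[[B]]))
        mats$D_Stop_motif[i, j] <- if (i == j) 0 else
          motif_distance(motifs[[A]], motifs[[B]], offset_mode = TRUE)
      if (have_rep && !is.null(proteins$rep[[A]]) && !is.null(proteins$rep[[B]])) {
        mats$D_Rep[i, j] <- protein_distance(proteins$rep[[A]], proteins$rep[[B]])
        sa <- split_rep_regions(proteins$rep[[A]], rep_split)
        sb <- split_rep_regions(proteins$rep[[B]], rep_split)
        mats$D_Rep_Nterm[i, j] <- protein_distance(sa$nterm, sb$nterm)
        mats$D_Rep_Cterm[i, j] <- protein_distance(sa$cterm, sb$cterm)
      }
      if (!is.null(proteins$hth) && !is.null(proteins$hth[[A]]) && !is.null(proteins$hth[[B]]))
        mats$D_Rep_HTH[i, j] <- hth_hamming(proteins$hth[[A]], proteins$hth[[B]])
      for (e in extra) {
        if (!is.null(proteins[[e]][[A]]) && !is.null(proteins[[e]][[B]]))
          mats[[paste0("D_", e)]][i, j] <- protein_distance(proteins[[e]][[A]], proteins[[e]][[B]])
      }
      for (m in names(mats)) mats[[m]][j, i] <- mats[[m]][i, j]
    }
  }
  structure(list(ids = ids, matrices = mats), class = "distance_table")
}

#' @export
print.distance_table <- function(x, ...) {
  cat("<distance_table> ", length(x$ids), " phages; metrics: ",
      paste(names(x$matrices), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract pairwise distances in long form
#'
#' @param x A `distance_table`.
#' @param metric Metric name (e.g. `"D_Nuc"`).
#' @param upper_only Keep one row per unordered pair.
#' @return `data.frame` with `id_a`, `id_b`, `value`.
#' @export
distance_long <- function(x, metric, upper_only = TRUE) {
  m <- x$matrices[[metric]]
  if (is.null(m)) stop("unknown metric '", metric, "'")
  idx <- which(if (upper_only) upper.tri(m) else row(m) != col(m), arr.ind = TRUE)
  data.frame(id_a = x$ids[idx[, 1]], id_b = x$ids[idx[, 2]],
             value = m[idx], stringsAsFactors = FALSE)
}

#' Write a distance table to TSV (wide form, one file per metric)
#'
#' @param x A `distance_table`.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_distance_table <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (m in names(x$matrices)) {
    p <- file.path(dir, paste0(m, ".tsv"))
    write.table(x$matrices[[m]], p, sep = "\t", quote = FALSE, col.names = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
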