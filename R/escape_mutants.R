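#' Parse one mutation-notation string
#'
#' Understands the compact catalog notation for mutations relative to a
#' parent genome, with 1-based top-strand coordinates:
#' \itemize{
#'   \item substitutions: `"G44351A"` (ref base, position, alt base)
#'   \item deletions: `"Δ44705:47517"` (first and last deleted nucleotide)
#'   \item insertions: `"44333:44334 27-bp ins"` (length only) or
#'     `"45315:45316 G insertion"` (inserted sequence); coordinates flank the
#'     insertion point
#'   \item recombinations: `"rec Tx 44620:44630 and RR 44127:44137"`
#'     (crossover windows in each parent)
#'   \item an optional donor-genome tag prefix (`"RR Δ47296:51394"`) and an
#'     optional parenthesized protein-effect annotation
#'     (`"G44351A (Rep Q138*)"`)
#' }
#'
#' @param notation One notation string (no semicolons; see
#'   [parse_mutation_list()] for compound entries).
#' @return Object of class `mutation_spec`: list with `kind` (`substitution`,
#'   `insertion`, `deletion`, `recombination`, `annotation_only`),
#'   coordinates, payload fields (`ref`/`alt`, `ins_seq`/`ins_len`, `donor`,
#'   crossover windows) and `annotation`.
#' @export
parse_mutation <- function(notation) {
  raw <- trimws(notation)
  s <- raw
  annotation <- NA_character_
  m <- regmatches(s, regexec("^(.*?)\\s*\\(([^()]*)\\)\\s*$", s))[[1]]
  if (length(m)) {
    s <- m[2]
    annotation <- m[3]
  }
  spec <- if (!nzchar(s)) {
    list(kind = "annotation_only")
  } else if (grepl("^rec ", s)) {
    m <- regmatches(s, regexec(
      "^rec (\\S+) (\\d+):(\\d+) and (\\S+) (\\d+):(\\d+)$", s))[[1]]
    if (!length(m)) stop("unparseable recombination at offset 0: '", raw, "'")
    list(kind = "recombination",
         donor_a = m[2], window_a = c(as.integer(m[3]), as.integer(m[4])),
         donor_b = m[5], window_b = c(as.integer(m[6]), as.integer(m[7])))
  } else {
    donor <- NA_character_
    mdon <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9]*) (Δ.*|\\d.*)$", s))[[1]]
    if (length(mdon)) { donor <- mdon[2]; s <- mdon[3] }
    if (grepl("^Δ", s)) {
      m <- regmatches(s, regexec("^Δ(\\d+):(\\d+)$", s))[[1]]
      if (!length(m)) stop("unparseable deletion at offset 0: '", raw, "'")
      st <- as.integer(m[2]); en <- as.integer(m[3])
      if (st > en) stop("deletion start > end: '", raw, "'")
      list(kind = "deletion", start = st, end = en, donor = donor)
    } else if (grepl("ins$", s) || grepl("insertion$", s)) {
      m <- regmatches(s, regexec("^(\\d+):(\\d+) (\\d+)-bp ins$", s))[[1]]
      if (length(m)) {
        st <- as.integer(m[2]); en <- as.integer(m[3])
        if (en != st + 1L) stop("insertion coordinates must be adjacent: '", raw, "'")
        list(kind = "insertion", start = st, end = en,
             ins_len = as.integer(m[4]), ins_seq = NA_character_, donor = donor)
      } else {
        m <- regmatches(s, regexec("^(\\d+):(\\d+) ([ACGT]+) insertion$", s))[[1]]
        if (!length(m)) stop("unparseable insertion at offset 0: '", raw, "'")
        st <- as.integer(m[2]); en <- as.integer(m[3])
        if (en != st + 1L) stop("insertion coordinates must be adjacent: '", raw, "'")
        list(kind = "insertion", start = st, end = en,
             ins_len = nchar(m[4]), ins_seq = m[4], donor = donor)
      }
    } else {
      m <- regmatches(s, regexec("^([ACGT])(\\d+)([ACGT])$", s))[[1]]
      if (!length(m)) stop("unparseable token at offset 0: '", raw, "'")
      if (m[2] == m[4]) stop("substitution bases must differ: '", raw, "'")
      list(kind = "substitution", start = as.integer(m[3]), end = as.integer(m[3]),
           ref = m[2], alt = m[4], donor = donor)
    }
  }
  spec$annotation <- annotation
  spec$notation <- raw
  structure(spec, class = "mutation_spec")
}

#' Parse a compound (semicolon-separated) mutation entry
#'
#' @param entry Catalog entry, e.g. `"G44580T (Rep S102*); T7649G (Holin V9G)"`.
#' @return List of `mutation_spec`.
#' @export
parse_mutation_list <- function(entry) {
  if (is.na(entry) || !nzchar(trimws(entry))) return(list())
  lapply(strsplit(entry, ";")[[1]], parse_mutation)
}

#' Format a mutation spec back to its notation
#'
#' Inverse of [parse_mutation()]: `format_mutation(parse_mutation(x)) == x`
#' for any string in the catalog grammar.
#'
#' @param spec A `mutation_spec`.
#' @return Notation string.
#' @export
format_mutation <- function(spec) {
  body <- switch(spec$kind,
    annotation_only = "",
    substitution = paste0(spec$ref, spec$start, spec$alt),
    deletion = paste0("Δ", spec$start, ":", spec$end),
    insertion = if (is.na(spec$ins_seq))
      paste0(spec$start, ":", spec$end, " ", spec$ins_len, "-bp ins")
    else paste0(spec$start, ":", spec$end, " ", spec$ins_seq, " insertion"),
    recombination = paste0("rec ", spec$donor_a, " ", spec$window_a[1], ":",
                           spec$window_a[2], " and ", spec$donor_b, " ",
                           spec$window_b[1], ":", spec$window_b[2]),
    stop("unknown kind")
  )
  if (spec$kind %in% c("deletion", "insertion") && !is.na(spec$donor))
    body <- paste(spec$donor, body)
  if (!is.na(spec$annotation)) {
    ann <- paste0("(", spec$annotation, ")")
    body <- if (nzchar(body)) paste(body, ann) else ann
  }
  body
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("<mutation_spec> ", x$kind, ": ", format_mutation(x), "\n", sep = "")
  invisible(x)
}

#' Apply mutation specs to a parent sequence
#'
#' Applies substitutions, insertions and deletions right-to-left so that
#' coordinates in the parent frame stay valid. Recombination specs give
#' crossover windows, not exact junctions, and are skipped with a warning
#' (see [build_recombinant()]). Annotation-only specs are ignored.
#'
#' @param parent_seq Parent genome DNA string.
#' @param specs List of `mutation_spec`.
#' @return Mutant DNA string; its length differs from the parent by total
#'   insertions minus total deletion lengths.
#' @export
apply_mutations <- function(parent_seq, specs) {
  seq <- toupper(as.character(parent_seq))
  L <- nchar(seq)
  specs <- Filter(function(s) {
    if (s$kind == "recombination") {
      warning("recombination spec skipped (windows, not junctions): ", format_mutation(s))
      FALSE
    } else s$kind != "annotation_only"
  }, specs)
  if (!length(specs)) return(seq)
  ord <- order(-vapply(specs, function(s) s$start, numeric(1)))
  for (s in specs[ord]) {
    if (s$end > nchar(seq) + (s$kind == "insertion"))
      stop("mutation beyond sequence end: ", format_mutation(s))
    if (s$kind == "substitution") {
      if (substr(seq, s$start, s$start) != s$ref)
        stop("reference mismatch at ", s$start, ": expected ", s$ref,
             ", found ", substr(seq, s$start, s$start))
      substr(seq, s$start, s$start) <- s$alt
    } else if (s$kind == "deletion") {
      seq <- paste0(substr(seq, 1, s$start - 1), substr(seq, s$end + 1, nchar(seq)))
    } else if (s$kind == "insertion") {
      ins <- if (is.na(s$ins_seq)) strrep("N", s$ins_len) else s$ins_seq
      seq <- paste0(substr(seq, 1, s$start), ins, substr(seq, s$end, nchar(seq)))
    }
  }
  seq
}

#' Build a recombinant hybrid genome
#'
#' Joins a left segment of genome A (up to `junction_a`, chosen inside the
#' catalog's crossover window) with the segment of genome B starting at
#' `junction_b`.
#'
#' @param seq_a,seq_b Parent DNA strings.
#' @param junction_a Last retained coordinate of A.
#' @param junction_b First retained coordinate of B.
#' @return Hybrid DNA string.
#' @export
build_recombinant <- function(seq_a, seq_b, junction_a, junction_b) {
  paste0(substr(seq_a, 1, junction_a), substr(seq_b, junction_b, nchar(seq_b)))
}

GENCODE <- NULL

translate_dna <- function(sense) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(sense) %/% 3
  if (n == 0) return("")
  codons <- substring(sense, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1])]
  paste(aa, collapse = "")
}

# sense-space coordinates of a gene region plus downstream margin
gene_sense_region <- function(parent_seq, gene, margin) {
  L <- nchar(parent_seq)
  if (gene$strand == "+") {
    lo <- gene$start; hi <- min(L, gene$end + margin)
    list(seq = substr(parent_seq, lo, hi), lo = lo, hi = hi)
  } else {
    lo <- max(1L, gene$start - margin); hi <- gene$end
    list(seq = revcomp(substr(parent_seq, lo, hi)), lo = lo, hi = hi)
  }
}

#' Classify the impact of mutations on the repressor gene
#'
#' Reconstructs the mutant repressor open reading frame and compares its
#' translation to the parent's. Deletions removing the whole gene classify as
#' `deleted`; deletions removing the 5' end as `truncated_5prime`; otherwise
#' the first affected codon decides between `nonsense` (premature stop),
#' `frameshift` (net indel length not a multiple of 3), `missense` (amino
#' acid change, including in-frame indels) and `sense` (nucleotide change,
#' identical protein). Mutations wholly outside the gene are `none`.
#'
#' @param parent_seq Parent genome DNA string.
#' @param rep_gene List/row with `start`, `end`, `strand` of the repressor.
#' @param specs List of `mutation_spec` (top-strand parent coordinates).
#' @param margin Downstream margin (bp) used to read through frameshifts.
#' @return List with `category` and `position` (affected codon or `NA`).
#' @export
classify_rep_impact <- function(parent_seq, rep_gene, specs, margin = 600) {
  if (is.null(rep_gene) || is.null(rep_gene$start)) stop("rep gene not annotated")
  parent_seq <- toupper(as.character(parent_seq))
  g <- rep_gene
  overl <- Filter(function(s)
    s$kind %in% c("substitution", "deletion", "insertion") &&
      s$start <= g$end && s$end >= g$start, specs)
  if (!length(overl)) return(list(category = "none", position = NA_integer_))
  for (s in overl) {
    if (s$kind == "deletion") {
      if (s$start <= g$start && s$end >= g$end)
        return(list(category = "deleted", position = NA_integer_))
      five_prime <- if (g$strand == "+") g$start else g$end
      if (s$start <= five_prime && s$end >= five_prime)
        return(list(category = "truncated_5prime", position = NA_integer_))
    }
  }
  reg <- gene_sense_region(parent_seq, g, margin)
  sense <- reg$seq
  # transform each spec into sense-space and apply right-to-left
  sspecs <- lapply(overl, function(s) to_sense_spec(s, g, reg))
  ord <- order(-vapply(sspecs, function(s) s$start, numeric(1)))
  mut <- sense
  for (s in sspecs[ord]) {
    if (s$kind == "substitution") {
      if (substr(mut, s$start, s$start) != s$ref)
        stop("reference mismatch in rep at sense position ", s$start)
      substr(mut, s$start, s$start) <- s$alt
    } else if (s$kind == "deletion") {
      mut <- paste0(substr(mut, 1, s$start - 1), substr(mut, s$end + 1, nchar(mut)))
    } else {
      ins <- if (is.na(s$ins_seq)) strrep("N", s$ins_len) else s$ins_seq
      if (g$strand == "-") ins <- revcomp(ins)
      mut <- paste0(substr(mut, 1, s$start), ins, substr(mut, s$end, nchar(mut)))
    }
  }
  gene_len <- g$end - g$start + 1L
  prot_p <- translate_dna(substr(sense, 1, gene_len))
  prot_m <- translate_dna(mut)
  net <- sum(vapply(overl, function(s) switch(s$kind,
    insertion = s$ins_len, deletion = -(min(s$end, g$end) - max(s$start, g$start) + 1L),
    substitution = 0L), numeric(1)))
  # first affected codon
  np <- nchar(prot_p); nm <- nchar(prot_m)
  shared <- min(np, nm)
  pchars <- strsplit(prot_p, "")[[1]]; mchars <- strsplit(prot_m, "")[[1]]
  diff_at <- which(pchars[seq_len(shared)] != mchars[seq_len(shared)])
  first <- if (length(diff_at)) diff_at[1] else if (np != nm) shared + 1L else NA_integer_
  if (net %% 3 != 0)
    return(list(category = "frameshift", position = first))
  if (!is.na(first) && first <= nm && mchars[first] == "*")
    return(list(category = "nonsense", position = first))
  if (nm < np && !is.na(first) && first > nm)
    return(list(category = "nonsense", position = nm))
  if (is.na(first)) {
    changed <- substr(sense, 1, gene_len) != substr(mut, 1, gene_len)
    return(list(category = if (changed) "sense" else "none", position = NA_integer_))
  }
  list(category = "missense", position = first)
}

to_sense_spec <- function(s, g, reg) {
  if (g$strand == "+") {
    off <- reg$lo - 1L
    out <- s
    out$start <- s$start - off; out$end <- s$end - off
    if (s$kind == "insertion") { out$start <- s$start - off; out$end <- out$start + 1L }
    out
  } else {
    e <- reg$hi
    out <- s
    if (s$kind == "substitution") {
      out$start <- e - s$start + 1L; out$end <- out$start
      out$ref <- revcomp(s$ref); out$alt <- revcomp(s$alt)
    } else if (s$kind == "deletion") {
      out$start <- e - s$end + 1L; out$end <- e - s$start + 1L
    } else {  # insertion between top t:t+1 -> sense after position e - t
      out$start <- e - s$end + 1L  # = e - (t+1) + 1 = e - t
      out$end <- out$start + 1L
    }
    out
  }
}

#' Classify a defense escape mutant's virulence breadth
#'
#' Compares a DEM's averaged infection scores against its parent's across the
#' shared defender panel. A defender is a "gain" when the DEM scores at or
#' above `escape_threshold` (plaque formation) while the parent scores below
#' it. Classes: `none` (no gains), `narrow_homotypic` (gains confined to the
#' homotypic system, i.e. the parent's own lysogen/CRS), `narrow_mesotypic`
#' (gains exclude the homotypic system and span at most two systems), `broad`
#' (gains span the homotypic system and mesotypic defenders, or many
#' mesotypic systems).
#'
#' @param matrix An `immunity_matrix`.
#' @param dem_id,parent_id Row ids of the DEM and its parent.
#' @param escape_threshold Minimum score counted as escape (default 3).
#' @param homotypic Defender column name(s) of the homotypic system (default:
#'   the parent's lysogen and `<parent>_CRS`).
#' @return List with `dem`, `parent`, `gains` (defender names), `class`, and
#'   `homotypic_untested` flag.
#' @export
virulence_breadth <- function(matrix, dem_id, parent_id, escape_threshold = 3,
                              homotypic = NULL) {
  if (is.null(homotypic))
    homotypic <- intersect(c(parent_id, paste0(parent_id, "_CRS")), colnames(matrix$mean))
  shared <- colnames(matrix$mean)[matrix$n[dem_id, ] > 0 & matrix$n[parent_id, ] > 0]
  if (length(shared) < 2) stop("DEM and parent share fewer than 2 scored defenders")
  homotypic_untested <- !any(homotypic %in% shared)
  gains <- shared[matrix$mean[dem_id, shared] >= escape_threshold &
                  matrix$mean[parent_id, shared] < escape_threshold]
  sys <- function(cols) unique(sub("_CRS$", "", cols))
  cls <- if (!length(gains)) "none"
  else if (all(gains %in% homotypic)) "narrow_homotypic"
  else if (!any(gains %in% homotypic) && length(sys(gains)) <= 2) "narrow_mesotypic"
  else "broad"
  list(dem = dem_id, parent = parent_id, gains = gains, class = cls,
       homotypic_untested = homotypic_untested)
}

#' Read the packaged mutant catalog
#'
#' Loads the transcription of the study's phage/mutant catalog (shipped as a
#' TSV fixture) and parses each mutation entry into `mutation_spec` lists.
#'
#' @param path Catalog TSV; defaults to the packaged fixture.
#' @return `data.frame` with catalog columns, a list-column `specs`, and
#'   helper columns `is_dem` and `defending_strain`.
#' @export
read_mutant_catalog <- function(path = system.file("extdata", "mutant_catalog.tsv",
                                                   package = "mesoimmunity")) {
  tb <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  tb$specs <- lapply(tb$mutations, function(x)
    if (is.na(x)) list() else parse_mutation_list(x))
  tb$is_dem <- grepl("DEM", tb$mutant_type %1% "")
  tb$defending_strain <- ifelse(tb$is_dem,
    sub("^(\\S+) (Lys|CRS) DEM$", "\\1", tb$mutant_type), NA_character_)
  tb$l5_clade <- as.logical(tb$l5_clade)
  tb
}

`%1%` <- function(x, default) ifelse(is.na(x), default, x)
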