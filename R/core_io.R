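#' @importFrom stats coef cor lm median nls predict quantile runif rnorm rbinom sd setNames
#' @importFrom utils read.delim write.table head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a phage genome object
#'
#' A `phage_genome` bundles one phage's DNA sequence with its gene features,
#' pham (gene phamily) assignments and the prophage-inheritance marker gene
#' (integrase for integrating phages, parA for extrachromosomal ones) whose
#' coordinates define the genome "center" used in stoperator orientation
#' analysis.
#'
#' @param id Phage identifier.
#' @param sequence DNA string over A/C/G/T/N.
#' @param genes `data.frame` with columns `gene_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `pham`, `product`. Coordinates are 1-based inclusive
#'   top-strand throughout the package.
#' @param subcluster Subcluster label such as `"A2"` (optional).
#'
#' @return An object of class `phage_genome`.
#' @export
phage_genome <- function(id, sequence, genes = empty_gene_table(), subcluster = NA_character_) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("genome '", id, "': sequence is empty")
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), DNA_ALPHABET)
  if (length(bad)) stop("genome '", id, "': invalid characters: ", paste(bad, collapse = ","))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  validate_gene_table(genes, nchar(sequence), id)
  obj <- structure(list(
    id = as.character(id),
    subcluster = as.character(subcluster),
    sequence = sequence,
    genes = genes
  ), class = "phage_genome")
  obj
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             strand = character(), pham = character(), product = character(),
             stringsAsFactors = FALSE)
}

validate_gene_table <- function(genes, genome_len, id) {
  need <- c("gene_id", "start", "end", "strand", "pham", "product")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("genome '", id, "': gene table lacks columns: ", paste(miss, collapse = ","))
  if (nrow(genes) == 0L) return(invisible(TRUE))
  if (any(genes$start < 1L))
    stop("genome '", id, "': gene '", genes$gene_id[which(genes$start < 1L)[1]],
         "' has start < 1 (coordinates are 1-based inclusive)")
  if (any(genes$start > genes$end))
    stop("genome '", id, "': gene with start > end")
  if (any(genes$end > genome_len))
    stop("genome '", id, "': gene '", genes$gene_id[which(genes$end > genome_len)[1]],
         "' extends past genome end")
  if (!all(genes$strand %in% c("+", "-")))
    stop("genome '", id, "': strand must be '+' or '-'")
  invisible(TRUE)
}

#' @export
print.phage_genome <- function(x, ...) {
  cat("<phage_genome> ", x$id,
      if (!is.na(x$subcluster)) paste0(" (subcluster ", x$subcluster, ")"), "\n", sep = "")
  cat("  length:", nchar(x$sequence), "bp;", nrow(x$genes), "genes\n")
  marker <- inheritance_marker(x, quiet = TRUE)
  if (!is.null(marker))
    cat("  inheritance: ", marker$type, " at ", marker$start, "-", marker$end, "\n", sep = "")
  invisible(x)
}

# 1-based inclusive -> 0-based half-open, and back (internal converters)
to0 <- function(start, end) c(start - 1L, end)
to1 <- function(lo, hi) c(lo + 1L, hi)

#' Locate the prophage-inheritance marker gene
#'
#' @param genome A `phage_genome`.
#' @param quiet Return `NULL` instead of erroring when no marker is annotated.
#' @return List with `type` (`"integrase"` or `"parA"`), `start`, `end`, or
#'   `NULL` (when `quiet`).
#' @export
inheritance_marker <- function(genome, quiet = FALSE) {
  prod <- tolower(genome$genes$product)
  i <- which(prod %in% c("integrase", "int"))
  type <- "integrase"
  if (!length(i)) {
    i <- which(prod %in% c("para", "par a"))
    type <- "parA"
  }
  if (!length(i)) {
    if (quiet) return(NULL)
    stop("genome '", genome$id, "': no center marker (neither integrase nor parA annotated)")
  }
  g <- genome$genes[i[1], ]
  list(type = type, start = g$start, end = g$end)
}

#' Genome center coordinate
#'
#' The center is the midpoint (rounded down) of the integrase gene for
#' integrating phages or of the parA gene for extrachromosomal phages. It is
#' the reference point for classifying stoperator orientation.
#'
#' @param genome A `phage_genome`.
#' @return Integer coordinate.
#' @export
genome_center <- function(genome) {
  m <- inheritance_marker(genome)
  as.integer((m$start + m$end) %/% 2)
}

#' Read a set of phage genomes
#'
#' Joins a FASTA file of genome sequences with a gene-feature table (GFF3 or a
#' 6-column TSV: `gene_id`, `start`, `end`, `strand`, `pham`, `product`; in
#' GFF3 the attributes `pham=` and `product=` are recognized) and a pham
#' membership table (TSV: `gene_id`, `pham`). Genes lacking a pham assignment
#' get a singleton pham with a warning.
#'
#' @param fasta_path FASTA of genome sequences, one record per phage.
#' @param gene_table_path Gene feature table (TSV dialect or GFF3), or `NULL`.
#' @param pham_table_path TSV mapping gene_id to pham, or `NULL` when phams are
#'   already present in the gene table.
#' @return Named list of `phage_genome` objects.
#' @export
read_genome_set <- function(fasta_path, gene_table_path = NULL, pham_table_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) return(structure(list(), names = character()))
  ids <- sub("\\s.*$", "", names(seqs))
  genes_all <- if (is.null(gene_table_path)) NULL else read_gene_table(gene_table_path)
  phams <- if (is.null(pham_table_path)) NULL else {
    p <- read.delim(pham_table_path, stringsAsFactors = FALSE)
    if (nrow(p) && !all(c("gene_id", "pham") %in% names(p)))
      stop("pham table must have columns gene_id, pham")
    p
  }
  out <- vector("list", length(seqs))
  names(out) <- ids
  for (i in seq_along(seqs)) {
    gt <- empty_gene_table()
    if (!is.null(genes_all)) {
      gt <- genes_all[genes_all$genome_id == ids[i], setdiff(names(genes_all), "genome_id"), drop = FALSE]
      rownames(gt) <- NULL
    }
    if (nrow(gt)) {
      if (!is.null(phams)) {
        m <- match(gt$gene_id, phams$gene_id)
        gt$pham <- ifelse(is.na(m), gt$pham, phams$pham[m])
      }
      nopham <- is.na(gt$pham) | gt$pham == ""
      if (any(nopham)) {
        warning("genome '", ids[i], "': ", sum(nopham),
                " gene(s) without pham assignment; set to singleton phams")
        gt$pham[nopham] <- paste0("singleton_", gt$gene_id[nopham])
      }
    }
    out[[i]] <- phage_genome(ids[i], as.character(seqs[[i]]), gt)
  }
  unmatched <- if (!is.null(genes_all)) setdiff(unique(genes_all$genome_id), ids) else character()
  if (length(unmatched))
    warning("gene table references genomes absent from FASTA: ", paste(unmatched, collapse = ","))
  out
}

read_gene_table <- function(path) {
  first <- readLines(path, n = 5L)
  is_gff <- any(grepl("^##gff-version", first)) || grepl("\\.gff3?$", path, ignore.case = TRUE)
  if (is_gff) {
    gff <- read.delim(path, header = FALSE, comment.char = "#", stringsAsFactors = FALSE,
                      col.names = c("seqid", "source", "type", "start", "end", "score",
                                    "strand", "phase", "attributes"))
    attr_field <- function(attrs, key) {
      m <- regmatches(attrs, regexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attrs))
      out <- rep(NA_character_, length(attrs))
      hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attrs))) > 0
      out[hit] <- sub(paste0(".*", key, "="), "", m)
      out
    }
    data.frame(genome_id = gff$seqid,
               gene_id = attr_field(gff$attributes, "ID"),
               start = as.integer(gff$start), end = as.integer(gff$end),
               strand = gff$strand,
               pham = attr_field(gff$attributes, "pham"),
               product = attr_field(gff$attributes, "product"),
               stringsAsFactors = FALSE)
  } else {
    tb <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("genome_id", "gene_id", "start", "end", "strand", "pham", "product")
    miss <- setdiff(need, names(tb))
    if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ","))
    tb$start <- as.integer(tb$start); tb$end <- as.integer(tb$end)
    tb
  }
}

#' Write a set of phage genomes
#'
#' Inverse of [read_genome_set()]: writes FASTA plus the 6-column TSV gene
#' dialect (with a `genome_id` key column) so that canonicalized input
#' round-trips byte-identically.
#'
#' @param genomes Named list of `phage_genome`.
#' @param fasta_path,gene_table_path Output paths.
#' @export
write_genome_set <- function(genomes, fasta_path, gene_table_path = NULL) {
  seqs <- Biostrings::DNAStringSet(vapply(genomes, function(g) g$sequence, character(1)))
  names(seqs) <- vapply(genomes, function(g) g$id, character(1))
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(gene_table_path)) {
    tabs <- lapply(genomes, function(g) {
      if (nrow(g$genes) == 0L) return(NULL)
      cbind(genome_id = g$id, g$genes)
    })
    tab <- do.call(rbind, tabs)
    if (is.null(tab)) tab <- cbind(genome_id = character(), empty_gene_table())
    write.table(tab, gene_table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

#' Read an infection-assay table
#'
#' Reads a TSV with one row per unique infection assay: columns `challenger`,
#' `defender`, `defender_kind` (`naive`, `lysogen` or `CRS`) and either a
#' `scores` column of semicolon-separated replicate infection scores (0-6) or
#' summary columns `n`, `mean_score`, `min_score`, `max_score` (summary-only
#' rows are kept as such, with `scores` set to `NA`).
#'
#' @param tsv_path Path to the table.
#' @return `data.frame` of assay records with a list-column `scores` plus
#'   `n`, `mean_score`, `min_score`, `max_score`.
#' @export
read_assay_table <- function(tsv_path) {
  tb <- read.delim(tsv_path, stringsAsFactors = FALSE)
  if (nrow(tb) == 0L) return(empty_assay_records())
  need <- c("challenger", "defender", "defender_kind")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("assay table lacks columns: ", paste(miss, collapse = ","))
  has_scores <- "scores" %in% names(tb)
  recs <- empty_assay_records()
  for (i in seq_len(nrow(tb))) {
    scores <- NULL
    if (has_scores && !is.na(tb$scores[i]) && nzchar(tb$scores[i])) {
      scores <- as.numeric(strsplit(as.character(tb$scores[i]), "[;, ]+")[[1]])
      if (anyNA(scores) || any(scores < 0 | scores > 6))
        stop("assay table row ", i, ": scores must be integers in [0,6]")
    }
    if (is.null(scores)) {
      if (!all(c("n", "mean_score", "min_score", "max_score") %in% names(tb)))
        stop("assay table row ", i, ": no replicate scores and no summary columns")
      n <- as.integer(tb$n[i]); mn <- tb$min_score[i]; mx <- tb$max_score[i]; mean_s <- tb$mean_score[i]
      if (any(c(mn, mx, mean_s) < 0) || any(c(mn, mx, mean_s) > 6))
        stop("assay table row ", i, ": score outside [0,6]")
      if (mn > mx) stop("assay table row ", i, ": min > max")
      rec <- assay_record(tb$challenger[i], tb$defender[i], tb$defender_kind[i],
                          scores = NULL, n = n, mean_score = mean_s,
                          min_score = mn, max_score = mx)
    } else {
      rec <- assay_record(tb$challenger[i], tb$defender[i], tb$defender_kind[i], scores)
    }
    recs <- rbind(recs, rec)
  }
  rownames(recs) <- NULL
  recs
}

empty_assay_records <- function() {
  df <- data.frame(challenger = character(), defender = character(),
                   defender_kind = character(), n = integer(),
                   mean_score = numeric(), min_score = numeric(), max_score = numeric(),
                   stringsAsFactors = FALSE)
  df$scores <- list()
  df
}

#' Build a single assay record
#'
#' @param challenger,defender Phage / strain identifiers.
#' @param defender_kind One of `"naive"`, `"lysogen"`, `"CRS"`.
#' @param scores Integer replicate infection scores in 0..6, or `NULL` for a
#'   summary-only record.
#' @param n,mean_score,min_score,max_score Summary statistics (derived from
#'   `scores` when those are given).
#' @return One-row `data.frame` (assay-record shape).
#' @export
assay_record <- function(challenger, defender, defender_kind, scores = NULL,
                         n = NULL, mean_score = NULL, min_score = NULL, max_score = NULL) {
  defender_kind <- match.arg(defender_kind, c("naive", "lysogen", "CRS"))
  if (!is.null(scores)) {
    if (!length(scores)) stop("replicate_scores must be non-empty")
    if (any(scores < 0 | scores > 6 | scores != round(scores)))
      stop("replicate scores must be integers in [0,6]")
    n <- length(scores); mean_score <- mean(scores)
    min_score <- min(scores); max_score <- max(scores)
  } else {
    if (is.null(n) || is.null(mean_score) || is.null(min_score) || is.null(max_score))
      stop("summary-only record needs n, mean_score, min_score, max_score")
    if (min_score > max_score) stop("min > max")
  }
  df <- data.frame(challenger = as.character(challenger), defender = as.character(defender),
                   defender_kind = defender_kind, n = as.integer(n),
                   mean_score = mean_score, min_score = min_score, max_score = max_score,
                   stringsAsFactors = FALSE)
  df$scores <- list(if (is.null(scores)) NA else as.integer(scores))
  df
}

#' Write an infection-assay table
#'
#' @param records Assay-record `data.frame` (see [read_assay_table()]).
#' @param tsv_path Output path.
#' @export
write_assay_table <- function(records, tsv_path) {
  out <- records[, c("challenger", "defender", "defender_kind",
                     "n", "mean_score", "min_score", "max_score")]
  out$scores <- vapply(records$scores, function(s)
    if (length(s) == 1L && is.na(s[1])) "" else paste(s, collapse = ";"), character(1))
  write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

subseq_chr <- function(seq, start, end) substr(seq, start, end)
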