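BASES <- c("A", "C", "G", "T")

code_seq <- function(seq) {
  x <- match(strsplit(seq, "")[[1]], BASES)  # N and anything else -> NA
  x
}

#' Build a position weight matrix motif model
#'
#' Builds a position frequency matrix from aligned sites (or raw counts),
#' smooths it into probabilities with a square-root pseudocount and converts
#' it to a log2 probability-ratio weight matrix:
#' `P[b,j] = (n[b,j] + k*bg_b*sqrt(N)) / (N + k*sqrt(N))`, `W = log2(P/bg)`.
#'
#' @param sites Character vector of equal-width site sequences (sense strand),
#'   or `NULL` when `counts` is given.
#' @param counts 4 x w matrix of base counts (rows A,C,G,T).
#' @param k Pseudocount weight (default 0.8).
#' @param bg Background base probabilities (default uniform).
#' @return Object of class `motif_model` with elements `width`, `counts`,
#'   `P`, `W`, `pseudocount`, `bg`, `nsites`, `consensus`.
#' @export
build_pwm <- function(sites = NULL, counts = NULL, k = 0.8, bg = rep(0.25, 4)) {
  if (is.null(counts)) {
    if (is.null(sites) || !length(sites)) stop("no sites and no counts")
    w <- unique(nchar(sites))
    if (length(w) != 1L) stop("sites have mixed widths")
    counts <- matrix(0, 4, w, dimnames = list(BASES, NULL))
    for (s in toupper(sites)) {
      cs <- code_seq(s)
      ok <- !is.na(cs)
      counts[cbind(cs[ok], which(ok))] <- counts[cbind(cs[ok], which(ok))] + 1
    }
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must be 4 x w")
  rownames(counts) <- BASES
  if (any(counts < 0)) stop("negative counts")
  N <- sum(counts[, 1])
  if (N == 0) stop("empty motif (column total is zero)")
  bg <- bg / sum(bg)
  P <- sweep(counts, 1, k * bg * sqrt(N), "+") / (N + k * sqrt(N))
  W <- log2(P / bg)
  structure(list(width = ncol(counts), counts = counts, P = P, W = W,
                 pseudocount = k, bg = bg, nsites = N,
                 consensus = paste(BASES[apply(P, 2, which.max)], collapse = "")),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model> width ", x$width, ", ", x$nsites, " sites, consensus ",
      x$consensus, "\n", sep = "")
  cat("  information content: ", round(information_content(x), 2), " bits\n", sep = "")
  invisible(x)
}

#' Total information content of a motif (bits)
#'
#' @param model A `motif_model`.
#' @param per_column Return the per-column vector instead of the total.
#' @export
information_content <- function(model, per_column = FALSE) {
  term <- model$P * log2(model$P / model$bg)
  term[model$P == 0] <- 0  # 0 * log(0) contributes nothing
  ic <- colSums(term)
  if (per_column) ic else sum(ic)
}

#' Normalized Euclidean distance between two motif models
#'
#' Per-column Euclidean distance on the probability matrices with a 1/sqrt(2)
#' normalization, averaged over columns, so that the distance lies in [0, 1],
#' equals zero iff the matrices are identical, and larger values reflect more
#' dissimilar motifs:
#' `D = (1/w) * sum_j sqrt( sum_b (P1[b,j] - P2[b,j])^2 / 2 )`.
#'
#' For unequal widths set `offset_mode = TRUE`: the shorter matrix is slid
#' along the longer one and the minimum distance over full-overlap offsets is
#' returned.
#'
#' @param m1,m2 `motif_model` objects.
#' @param offset_mode Allow unequal widths via best-offset alignment.
#' @return Non-negative distance (symmetric).
#' @export
motif_distance <- function(m1, m2, offset_mode = FALSE) {
  P1 <- m1$P; P2 <- m2$P
  if (ncol(P1) != ncol(P2)) {
    if (!offset_mode) stop("motifs have unequal widths (use offset_mode = TRUE)")
    if (ncol(P1) > ncol(P2)) { tmp <- P1; P1 <- P2; P2 <- tmp }
    w <- ncol(P1)
    ds <- vapply(0:(ncol(P2) - w), function(off)
      pwm_coldist(P1, P2[, (off + 1):(off + w), drop = FALSE]), numeric(1))
    return(min(ds))
  }
  pwm_coldist(P1, P2)
}

pwm_coldist <- function(P1, P2) {
  mean(sqrt(colSums((P1 - P2)^2) / 2))
}

#' Reverse complement of a motif model
#'
#' @param model A `motif_model`.
#' @return The model describing the opposite strand (columns reversed, A/T
#'   and C/G rows swapped).
#' @export
pwm_revcomp <- function(model) {
  flip <- function(M) {
    if (is.null(M)) return(NULL)
    M <- M[c("T", "G", "C", "A"), rev(seq_len(ncol(M))), drop = FALSE]
    rownames(M) <- BASES
    M
  }
  out <- model
  out$P <- flip(model$P); out$W <- flip(model$W); out$counts <- flip(model$counts)
  out$consensus <- paste(BASES[apply(out$P, 2, which.max)], collapse = "")
  out
}

window_codes <- function(code, w) {
  nw <- length(code) - w + 1L
  if (nw < 1L) return(NULL)
  idx <- outer(seq_len(nw), 0:(w - 1L), "+")
  matrix(code[idx], nw, w)
}

score_windows <- function(codemat, W) {
  w <- ncol(codemat)
  s <- numeric(nrow(codemat))
  for (j in seq_len(w)) s <- s + W[, j][codemat[, j]]
  s  # NA where a window contains N
}

#' Scan a genome for motif sites
#'
#' Scores every window on both strands with the log-odds matrix and reports
#' non-overlapping sites with score >= `min_score`, resolved greedily by best
#' score first (ties: leftmost, then '+' strand). Site sequences are reported
#' sense-converted (i.e., as the motif-strand sequence).
#'
#' @param genome A `phage_genome` (or a plain DNA string).
#' @param model A `motif_model`.
#' @param min_score Finite log-odds threshold.
#' @return `data.frame` of sites: `genome_id`, `start`, `end`, `strand`,
#'   `sequence`, `score`.
#' @export
scan_sites <- function(genome, model, min_score) {
  if (!is.finite(min_score) && min_score != Inf) stop("min_score must be finite (or +Inf)")
  seq <- if (inherits(genome, "phage_genome")) genome$sequence else toupper(as.character(genome))
  gid <- if (inherits(genome, "phage_genome")) genome$id else NA_character_
  w <- model$width
  L <- nchar(seq)
  if (w > L) stop("motif wider than genome")
  hits <- scan_hits(seq, model$W, w, L)
  hits <- hits[!is.na(hits$score) & hits$score >= min_score, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(genome_id = character(), start = integer(), end = integer(),
                      strand = character(), sequence = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  hits <- greedy_nonoverlap(hits)
  hits$sequence <- site_sequences(seq, hits)
  cbind(genome_id = gid, hits[, c("start", "end", "strand", "sequence", "score")],
        stringsAsFactors = FALSE)
}

scan_hits <- function(seq, W, w, L) {
  code_f <- code_seq(seq)
  cm_f <- window_codes(code_f, w)
  s_f <- score_windows(cm_f, W)
  code_r <- code_seq(revcomp(seq))
  cm_r <- window_codes(code_r, w)
  s_r <- score_windows(cm_r, W)
  nw <- L - w + 1L
  # reverse-strand window i (on revcomp) covers top-strand [L-i-w+2, L-i+1]
  data.frame(start = c(seq_len(nw), L - seq_len(nw) - w + 2L),
             end = c(seq_len(nw) + w - 1L, L - seq_len(nw) + 1L),
             strand = rep(c("+", "-"), each = nw),
             score = c(s_f, s_r), stringsAsFactors = FALSE)
}

greedy_nonoverlap <- function(hits) {
  ord <- order(-hits$score, hits$start, hits$strand)  # '+' < '-' breaks ties to '+'
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  covered_lo <- integer(0); covered_hi <- integer(0)
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]; e <- hits$end[i]
    if (!any(s <= covered_hi & e >= covered_lo)) {
      keep[i] <- TRUE
      covered_lo <- c(covered_lo, s); covered_hi <- c(covered_hi, e)
    }
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

site_sequences <- function(seq, hits) {
  vapply(seq_len(nrow(hits)), function(i) {
    s <- substr(seq, hits$start[i], hits$end[i])
    if (hits$strand[i] == "-") revcomp(s) else s
  }, character(1))
}

#' Discover stoperator motifs in a genome
#'
#' A constrained EM motif finder under an any-number-of-repetitions site
#' model: candidate widths 12-16 bp, 10-50 sites, both strands, at most two
#' motifs. For each width, seeds are taken from the most frequent exact
#' w-mers; EM alternates soft site posteriors with probability-matrix updates.
#' Candidates are ranked by information content times site count; when a
#' reference motif is supplied (e.g., an empirically determined stoperator
#' motif) the candidate closest to it by [motif_distance()] is selected
#' instead. Site counts are clamped into `sites_range` by threshold
#' adjustment, and all reported sites are sense-converted.
#'
#' @param genome A `phage_genome` or DNA string.
#' @param w_range Motif width range (within 12-16).
#' @param sites_range Allowed site-count range (within 10-50).
#' @param n_motifs Maximum number of candidate motifs retained (<= 2).
#' @param reference_motif Optional `motif_model` guiding model selection.
#' @param ic_floor Minimum total information content (bits) for a motif to
#'   count as found.
#' @param max_seeds Seeds per width.
#' @param n_iter EM iterations per seed.
#' @return List with `found` (logical), `model` (`motif_model` or `NULL`),
#'   `sites` (site `data.frame` as in [scan_sites()]), `threshold` (log-odds
#'   used for site calling) and `candidates` (list of runner-up models).
#' @export
discover_stoperators <- function(genome, w_range = c(12, 16), sites_range = c(10, 50),
                                 n_motifs = 2, reference_motif = NULL,
                                 ic_floor = 10, max_seeds = 3, n_iter = 15) {
  stopifnot(w_range[1] >= 12, w_range[2] <= 16, sites_range[1] >= 10, sites_range[2] <= 50,
            n_motifs <= 2)
  seq <- if (inherits(genome, "phage_genome")) genome$sequence else toupper(as.character(genome))
  gid <- if (inherits(genome, "phage_genome")) genome$id else NA_character_
  L <- nchar(seq)
  if (L < 10 * w_range[2]) stop("genome too short for motif discovery")
  cands <- list()
  for (w in seq(w_range[1], w_range[2])) {
    cm <- rbind(window_codes(code_seq(seq), w),
                window_codes(code_seq(revcomp(seq)), w))
    for (seed in em_seeds(seq, w, max_seeds)) {
      fit <- em_motif(cm, seed, n_iter)
      if (!is.null(fit)) cands[[length(cands) + 1L]] <- fit
    }
  }
  if (!length(cands)) return(not_found())
  # rank by mean per-column information content times supporting site count,
  # keep the top n_motifs distinct candidates
  quality <- vapply(cands, function(f) (f$ic / f$model$width) * f$n_sites_raw, numeric(1))
  cands <- cands[order(-quality)]
  keep <- list(cands[[1]])
  for (f in cands[-1]) {
    if (length(keep) >= n_motifs) break
    dd <- motif_distance(f$model, keep[[1]]$model, offset_mode = TRUE)
    if (dd > 0.25) keep[[length(keep) + 1L]] <- f
  }
  if (!is.null(reference_motif)) {
    # consider each candidate in both orientations, pick the closest
    oriented <- list()
    for (f in keep) {
      fr <- f; fr$model <- pwm_revcomp(f$model)
      oriented <- c(oriented, list(f, fr))
    }
    pick <- which.min(vapply(oriented, function(f)
      motif_distance(f$model, reference_motif, offset_mode = TRUE), numeric(1)))
    best <- oriented[[pick]]
    keep <- oriented[-pick]
  } else {
    best <- keep[[1]]
    keep <- keep[-1]
  }
  if (best$ic < ic_floor) return(not_found())
  sites0 <- call_sites(seq, gid, best$model, sites_range)
  model <- build_pwm(sites0$sites$sequence)
  # final site call under the reported model, so that re-scanning with this
  # model at the reported threshold reproduces (a superset of) the site set
  sites <- call_sites(seq, gid, model, sites_range)
  list(found = TRUE, model = model, sites = sites$sites, threshold = sites$threshold,
       candidates = keep)
}

not_found <- function() {
  list(found = FALSE, model = NULL,
       sites = data.frame(genome_id = character(), start = integer(), end = integer(),
                          strand = character(), sequence = character(), score = numeric(),
                          stringsAsFactors = FALSE),
       threshold = NA_real_, candidates = list())
}

em_seeds <- function(seq, w, max_seeds) {
  kmers <- c(all_kmers(seq, w), all_kmers(revcomp(seq), w))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  tab <- sort(table(kmers), decreasing = TRUE)
  tab <- tab[tab >= 2]
  seeds <- character(0)
  for (s in names(tab)) {
    if (length(seeds) >= max_seeds) break
    near <- vapply(seeds, function(x)
      hamming(s, x) <= w %/% 3 || hamming(s, revcomp(x)) <= w %/% 3, logical(1))
    if (!any(near)) seeds <- c(seeds, s)
  }
  seeds
}

all_kmers <- function(seq, w) {
  L <- nchar(seq)
  if (L < w) return(character(0))
  substring(seq, seq_len(L - w + 1L), seq_len(L - w + 1L) + w - 1L)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

em_motif <- function(cm, seed, n_iter) {
  w <- nchar(seed)
  nwin <- nrow(cm)
  bg <- rep(0.25, 4)
  P <- matrix(0.08, 4, w, dimnames = list(BASES, NULL))
  sc <- code_seq(seed)
  P[cbind(sc, seq_len(w))] <- 0.76
  gamma <- 25 / nwin
  for (it in seq_len(n_iter)) {
    llr <- score_windows(cm, log2(P / bg))
    lik <- 2^pmin(llr, 60)
    z <- gamma * lik / (gamma * lik + (1 - gamma))
    z[is.na(z)] <- 0
    counts <- matrix(0.5, 4, w, dimnames = list(BASES, NULL))  # smoothing
    for (j in seq_len(w)) {
      cj <- cm[, j]
      for (b in 1:4) counts[b, j] <- counts[b, j] + sum(z[!is.na(cj) & cj == b])
    }
    P <- sweep(counts, 2, colSums(counts), "/")
    gamma <- min(max(mean(z), 1e-6), 0.02)
  }
  n_sites_raw <- sum(z > 0.5, na.rm = TRUE) / 2  # both strands score each site ~once
  model <- structure(list(width = w, counts = NULL, P = P, W = log2(P / bg),
                          pseudocount = NA, bg = bg, nsites = NA,
                          consensus = paste(BASES[apply(P, 2, which.max)], collapse = "")),
                     class = "motif_model")
  ic <- sum(colSums(P * log2(P / bg)))
  list(model = model, ic = ic, n_sites_raw = max(n_sites_raw, 1))
}

call_sites <- function(seq, gid, model, sites_range) {
  L <- nchar(seq)
  hits <- scan_hits(seq, model$W, model$width, L)
  hits <- hits[!is.na(hits$score), , drop = FALSE]
  # natural threshold: half the consensus score; then clamp count by adjustment
  thr <- 0.5 * sum(apply(model$W, 2, max))
  sel <- greedy_nonoverlap(hits[hits$score >= thr, , drop = FALSE])
  if (nrow(sel) > sites_range[2]) {
    sel <- sel[order(-sel$score), , drop = FALSE][seq_len(sites_range[2]), , drop = FALSE]
    sel <- sel[order(sel$start), , drop = FALSE]
    thr <- min(sel$score)
  } else if (nrow(sel) < sites_range[1]) {
    all_no <- greedy_nonoverlap(hits[hits$score > 0, , drop = FALSE])
    ntake <- min(sites_range[1], nrow(all_no))
    sel <- all_no[order(-all_no$score), , drop = FALSE][seq_len(ntake), , drop = FALSE]
    sel <- sel[order(sel$start), , drop = FALSE]
    thr <- min(sel$score)
  }
  sel$sequence <- site_sequences(seq, sel)
  sites <- cbind(genome_id = gid, sel[, c("start", "end", "strand", "sequence", "score")],
                 stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  list(sites = sites, threshold = thr)
}

#' Classify stoperator orientation relative to the genome center
#'
#' A site is syn-oriented (with the direction of transcription) when it lies
#' on the top strand to the left of the genome center or on the bottom strand
#' to the right of the center; otherwise anti. A site whose midpoint falls
#' exactly on the center is classified by strand ('+' is syn).
#'
#' @param sites Site `data.frame` (`start`, `end`, `strand`).
#' @param center Genome center coordinate (see [genome_center()]).
#' @return Character vector `"syn"`/`"anti"`.
#' @export
classify_orientation <- function(sites, center) {
  mid <- (sites$start + sites$end) / 2
  ifelse(mid == center, ifelse(sites$strand == "+", "syn", "anti"),
         ifelse((sites$strand == "+" & mid < center) |
                (sites$strand == "-" & mid > center), "syn", "anti"))
}

#' Pooled positional distribution of sites relative to an anchor
#'
#' Adjusts all site coordinates relative to a genome-specific anchor feature
#' and pools the offsets across genomes into a binned histogram. Offset zero
#' means the site end coincides with the anchor coordinate.
#'
#' @param sites Site `data.frame` with a `genome_id` column.
#' @param genomes Named list of `phage_genome` supplying anchors.
#' @param anchor Anchor spec: `list(type = "gene_3prime", product = "rep")`,
#'   `list(type = "gene_5prime", product = ...)`, `list(type = "right_terminus")`,
#'   `list(type = "left_terminus")`, or `list(type = "coordinate", at = <named vector>)`.
#' @param bin_width Histogram bin width in bp (default 100).
#' @return `data.frame` with `bin_start` (inclusive lower bound of each bin)
#'   and `count`, pooled across genomes. Genomes whose anchor cannot be
#'   resolved are skipped with a warning.
#' @export
positional_distribution <- function(sites, genomes, anchor, bin_width = 100) {
  offsets <- numeric(0)
  for (gid in unique(sites$genome_id)) {
    g <- genomes[[gid]]
    a <- tryCatch(resolve_anchor(g, anchor, gid), error = function(e) {
      warning("genome '", gid, "': ", conditionMessage(e), " (skipped)")
      NULL
    })
    if (is.null(a)) next
    ss <- sites[sites$genome_id == gid, , drop = FALSE]
    offsets <- c(offsets, ss$end - a)
  }
  if (!length(offsets))
    return(data.frame(bin_start = numeric(0), count = integer(0)))
  bins <- floor(offsets / bin_width) * bin_width
  tab <- table(bins)
  data.frame(bin_start = as.numeric(names(tab)), count = as.integer(tab))
}

resolve_anchor <- function(genome, anchor, gid) {
  if (is.null(genome)) stop("genome not supplied")
  switch(anchor$type,
    gene_3prime = {
      g <- find_gene(genome, anchor$product)
      if (g$strand == "+") g$end else g$start
    },
    gene_5prime = {
      g <- find_gene(genome, anchor$product)
      if (g$strand == "+") g$start else g$end
    },
    right_terminus = nchar(genome$sequence),
    left_terminus = 1,
    coordinate = {
      if (!gid %in% names(anchor$at)) stop("no anchor coordinate for genome")
      anchor$at[[gid]]
    },
    stop("unknown anchor type '", anchor$type, "'")
  )
}

find_gene <- function(genome, product) {
  i <- which(tolower(genome$genes$product) == tolower(product))
  if (!length(i)) stop("anchor gene '", product, "' not annotated")
  genome$genes[i[1], ]
}

#' Export a motif model in MEME minimal format
#'
#' @param model A `motif_model`.
#' @param path Output file.
#' @param name Motif name.
#' @export
write_meme_motif <- function(model, path, name = "motif1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", BASES, model$bg), collapse = " "), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       model$width, ifelse(is.na(model$nsites), 0L, as.integer(model$nsites)))),
             con)
  for (j in seq_len(model$width))
    writeLines(paste(sprintf("%.6f", model$P[, j]), collapse = "  "), con)
  invisible(path)
}

#' Read a MEME minimal format motif
#'
#' @param path MEME minimal motif file (first motif is read).
#' @param k,bg Pseudocount and background used to rebuild the model from the
#'   probability matrix.
#' @return A `motif_model` (counts reconstructed from nsites when available).
#' @export
read_meme_motif <- function(path, k = 0.8, bg = rep(0.25, 4)) {
  lines <- readLines(path)
  hdr <- grep("^letter-probability matrix", lines)[1]
  if (is.na(hdr)) stop("no letter-probability matrix in file")
  w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[hdr]))
  nsites <- as.integer(sub(".*nsites= *(\\d+).*", "\\1", lines[hdr]))
  P <- t(vapply(lines[(hdr + 1):(hdr + w)],
                function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]), numeric(4)))
  P <- t(P)  # 4 x w
  rownames(P) <- BASES
  # the stored matrix is already smoothed probabilities; do not re-smooth
  structure(list(width = w,
                 counts = if (!is.na(nsites) && nsites > 0) round(P * nsites) else NULL,
                 P = P, W = log2(P / bg), pseudocount = k, bg = bg,
                 nsites = if (!is.na(nsites) && nsites > 0) nsites else NA,
                 consensus = paste(BASES[apply(P, 2, which.max)], collapse = "")),
            class = "motif_model")
}
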