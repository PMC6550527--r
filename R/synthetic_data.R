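# run expr under a fixed RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Configuration for the synthetic clade generator
#'
#' Defaults emulate the study system: a clade of Cluster A-like temperate
#' phage genomes of ~50 kb carrying 20-30 planted 13-bp stoperator sites per
#' genome, predominantly syn-oriented around a central inheritance marker;
#' the stoperator consensus, the pham complement and the repressor protein
#' all drift along a balanced phylogeny, with the repressor C-terminal region
#' drifting faster than the N-terminal region.
#'
#' @param n_phages Number of taxa (a balanced tree is grown over them).
#' @param tree Optional `ape::phylo`; default balanced tree with unit edges.
#' @param genome_length Genome length in bp.
#' @param sites_range Planted stoperator count range per genome.
#' @param motif_width Stoperator core width (13).
#' @param motif_sub_rate Per-position, per-unit-branch-length substitution
#'   probability of the motif consensus.
#' @param site_noise Per-position deviation probability of each planted site
#'   from its genome's consensus (keeps sites within ~0-2 mismatches).
#' @param pham_turnover Per-pham, per-unit-branch-length loss probability
#'   (matched by gains of novel phams).
#' @param n_phams Ancestral pham count.
#' @param rep_length Repressor length (aa).
#' @param nterm_rate,cterm_rate Per-site, per-unit-branch-length substitution
#'   probabilities for the repressor N-terminal (residues 1-60) and
#'   C-terminal regions (default 3x faster C-terminal drift).
#' @param syn_prob Probability that a planted site follows the syn
#'   orientation rule relative to the genome center.
#' @return List of class `clade_sim_config`.
#' @export
clade_sim_config <- function(n_phages = 16, tree = NULL, genome_length = 50000,
                             sites_range = c(20, 30), motif_width = 13,
                             motif_sub_rate = 0.04, site_noise = 0.03,
                             pham_turnover = 0.03, n_phams = 90,
                             rep_length = 183, nterm_rate = 0.01,
                             cterm_rate = 0.03, syn_prob = 0.95) {
  stopifnot(sites_range[1] >= 10, sites_range[2] <= 50,
            motif_sub_rate >= 0, pham_turnover >= 0,
            nterm_rate >= 0, cterm_rate >= 0)
  structure(list(n_phages = n_phages, tree = tree, genome_length = genome_length,
                 sites_range = sites_range, motif_width = motif_width,
                 motif_sub_rate = motif_sub_rate, site_noise = site_noise,
                 pham_turnover = pham_turnover, n_phams = n_phams,
                 rep_length = rep_length, nterm_rate = nterm_rate,
                 cterm_rate = cterm_rate, syn_prob = syn_prob),
            class = "clade_sim_config")
}

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")

balanced_tree <- function(n) {
  k <- 2^ceiling(log2(max(n, 2)))
  tr <- ape::stree(k, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  if (k > n) tr <- ape::drop.tip(tr, paste0("t", (n + 1):k))
  tr$tip.label <- sprintf("phage%02d", seq_len(n))
  tr
}

#' Simulate a diverging phage clade with planted stoperators
#'
#' Evolves a stoperator consensus, a pham complement and a repressor protein
#' along a phylogeny, then emits one genome per tip: random background
#' sequence, an integrase marker gene at the genome center, a minus-strand
#' rep gene in the right arm, one gene per pham, and 20-30 planted copies of
#' the tip's motif consensus (with slight per-site deviation), syn-oriented
#' with probability `syn_prob` relative to the center. Deterministic given
#' `(config, seed)`.
#'
#' @param config A `clade_sim_config`.
#' @param seed Integer RNG seed.
#' @return Object of class `simulated_clade`: list with `genomes` (named
#'   `phage_genome` list), `truth` (tree, per-taxon motif consensus, planted
#'   site table, pham sets, rep sequences, rep HTH domains, true motif
#'   models) and `config`.
#' @export
simulate_clade <- function(config = clade_sim_config(), seed = 1) {
  with_seed(seed, simulate_clade_impl(config))
}

simulate_clade_impl <- function(cfg) {
  w <- cfg$motif_width
  if (cfg$genome_length < 5000)
    stop("genome too short to pack genes and planted sites")
  tree <- if (is.null(cfg$tree)) balanced_tree(cfg$n_phages) else cfg$tree
  tree <- ape::reorder.phylo(tree, "cladewise")  # edges parent-before-children
  tips <- tree$tip.label
  L <- cfg$genome_length
  # All randomness is drawn at the root and perturbed only along edges, so
  # zero branch lengths yield byte-identical genomes.
  root <- list(
    motif = sample(BASES, w, replace = TRUE),
    phams = paste0("pham", seq_len(cfg$n_phams)),
    rep = sample(AA20, cfg$rep_length, replace = TRUE),
    background = sample(BASES, L, replace = TRUE)
  )
  center_gene <- c(floor(L / 2) - 500L, floor(L / 2) + 500L)
  center <- (center_gene[1] + center_gene[2]) %/% 2
  n_sites <- sample(seq(cfg$sites_range[1], cfg$sites_range[2]), 1)
  slots <- sort(sample(seq(100L, L - 100L - w, by = 4L * w), n_sites))
  root$sites <- lapply(slots, function(p) {
    dev_pos <- which(runif(w) < cfg$site_noise)
    syn <- runif(1) < cfg$syn_prob
    mid <- p + (w - 1) / 2
    list(start = p, strand = if (xor(mid < center, !syn)) "+" else "-",
         dev_pos = dev_pos, dev_base = sample(BASES, length(dev_pos), replace = TRUE))
  })
  n_node <- ape::Nnode(tree) + length(tips)
  state_at <- vector("list", n_node)
  state_at[[length(tips) + 1L]] <- root
  pham_counter <- cfg$n_phams
  nuc_rate <- 0.01  # background drift per bp per unit branch length
  for (ei in seq_len(nrow(tree$edge))) {
    par <- tree$edge[ei, 1]; child <- tree$edge[ei, 2]
    el <- tree$edge.length[ei]
    st <- state_at[[par]]
    flip <- runif(w) < cfg$motif_sub_rate * el
    st$motif[flip] <- vapply(which(flip), function(j)
      sample(setdiff(BASES, st$motif[j]), 1), character(1))
    lost <- runif(length(st$phams)) < cfg$pham_turnover * el
    gains <- sum(lost)
    if (gains > 0) {
      st$phams <- c(st$phams[!lost], paste0("pham", pham_counter + seq_len(gains)))
      pham_counter <- pham_counter + gains
    } else st$phams <- st$phams[!lost]
    rate <- ifelse(seq_along(st$rep) <= 60, cfg$nterm_rate, cfg$cterm_rate)
    mut <- runif(length(st$rep)) < rate * el
    st$rep[mut] <- vapply(which(mut), function(j)
      sample(setdiff(AA20, st$rep[j]), 1), character(1))
    nsub <- rbinom(1, L, nuc_rate * el)
    if (nsub > 0) {
      at <- sample.int(L, nsub)
      st$background[at] <- sample(BASES, nsub, replace = TRUE)
    }
    st$sites <- lapply(st$sites, function(s) {
      if (runif(1) < 0.5 * el) {  # per-site deviation turnover
        s$dev_pos <- which(runif(w) < cfg$site_noise)
        s$dev_base <- sample(BASES, length(s$dev_pos), replace = TRUE)
      }
      s
    })
    state_at[[child]] <- st
  }
  genomes <- list(); truth_sites <- list(); motifs <- list()
  pham_sets <- list(); reps <- list(); hths <- list()
  for (ti in seq_along(tips)) {
    id <- tips[ti]
    st <- state_at[[ti]]
    seqv <- st$background
    ph <- st$phams
    ngene <- length(ph)
    starts <- floor(seq(200, L - 2500, length.out = ngene))
    genes <- rbind(
      data.frame(gene_id = paste0(id, "_g", seq_len(ngene)),
                 start = as.integer(starts), end = as.integer(starts + 149L),
                 strand = ifelse(starts < floor(L / 2), "+", "-"),
                 pham = ph, product = "hypothetical", stringsAsFactors = FALSE),
      data.frame(gene_id = paste0(id, "_int"), start = center_gene[1],
                 end = center_gene[2], strand = "+", pham = "pham_int",
                 product = "integrase", stringsAsFactors = FALSE),
      data.frame(gene_id = paste0(id, "_rep"), start = as.integer(L - 5000L),
                 end = as.integer(L - 5000L + 3 * cfg$rep_length + 2L),
                 strand = "-", pham = "pham_rep", product = "rep",
                 stringsAsFactors = FALSE))
    site_rows <- lapply(st$sites, function(s) {
      inst <- st$motif
      if (length(s$dev_pos)) inst[s$dev_pos] <- s$dev_base
      data.frame(genome_id = id, start = s$start, end = s$start + w - 1L,
                 strand = s$strand, sequence = paste(inst, collapse = ""),
                 stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, site_rows)
    for (ri in seq_len(nrow(sites))) {
      planted <- if (sites$strand[ri] == "+") sites$sequence[ri] else revcomp(sites$sequence[ri])
      seqv[sites$start[ri]:sites$end[ri]] <- strsplit(planted, "")[[1]]
    }
    genomes[[id]] <- phage_genome(id, paste(seqv, collapse = ""), genes)
    truth_sites[[id]] <- sites
    motifs[[id]] <- build_pwm(sites$sequence)
    pham_sets[[id]] <- ph
    reps[[id]] <- paste(st$rep, collapse = "")
    hths[[id]] <- substr(reps[[id]], 21, 40)
  }
  structure(list(
    genomes = genomes,
    truth = list(tree = tree,
                 motif_consensus = setNames(vapply(seq_along(tips), function(i)
                   paste(state_at[[i]]$motif, collapse = ""), character(1)), tips),
                 sites = do.call(rbind, truth_sites),
                 motifs = motifs, pham_sets = pham_sets,
                 rep_seqs = reps, hth = hths),
    config = cfg), class = "simulated_clade")
}

#' @export
print.simulated_clade <- function(x, ...) {
  cat("<simulated_clade> ", length(x$genomes), " genomes of ",
      x$config$genome_length, " bp; ", nrow(x$truth$sites),
      " planted stoperators\n", sep = "")
  invisible(x)
}

#' Configuration for the ordinal immunity-phenotype simulator
#'
#' Scores are generated from genotype distances through a saturating link,
#' not from repressor-operator biophysics: the true score of challenger B on
#' an A-lysogen is `clamp(round(5 * g(beta * D(A,B) - alpha * promiscuity_A)), 0, 6)`
#' with `g(x) = max(0, 2/(1+exp(-x)) - 1)`, so zero distance gives
#' homoimmunity (score 0) and saturating distance full infection (score 5).
#' Per-defender latent promiscuity (`alpha > 0`) produces asymmetric
#' (mesoimmune) reciprocal scores; replicates get ordinal +/-1 noise.
#'
#' @param beta Slope on distance (default 10; distances of ~0.3 saturate).
#' @param alpha Asymmetry scale on the per-defender latent promiscuity.
#' @param ordinal_noise Probability a replicate score shifts by one.
#' @param replicates Replicates per comparison.
#' @param include_crs Also emit a cognate CRS defender per lysogen.
#' @return List of class `phenotype_sim_config`.
#' @export
phenotype_sim_config <- function(beta = 10, alpha = 0.8, ordinal_noise = 0.15,
                                 replicates = 3, include_crs = FALSE) {
  structure(list(beta = beta, alpha = alpha, ordinal_noise = ordinal_noise,
                 replicates = replicates, include_crs = include_crs),
            class = "phenotype_sim_config")
}

saturating_link <- function(x) pmax(0, 2 / (1 + exp(-x)) - 1)

#' Simulate ordinal immunity assay records from pairwise distances
#'
#' @param distances Symmetric distance matrix with phage ids as dimnames, a
#'   `distance_table` (its `D_Stop_motif`, falling back to the first metric),
#'   or a `simulated_clade` (true motif distances are computed).
#' @param config A `phenotype_sim_config`.
#' @param seed Integer seed.
#' @param outgroup Optional ids whose pairs with all others are heterotypic:
#'   their scores are forced to 5 (no genetic interaction).
#' @return Assay records `data.frame` (see [read_assay_table()]); lysogen
#'   defenders are named by phage id, CRS defenders `<id>_CRS`.
#' @export
simulate_immunity <- function(distances, config = phenotype_sim_config(), seed = 1,
                              outgroup = character()) {
  D <- if (inherits(distances, "simulated_clade")) {
    motifs <- distances$truth$motifs
    ids <- names(motifs)
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_along(ids)) for (j in seq_along(ids))
      if (i < j) m[i, j] <- m[j, i] <- motif_distance(motifs[[i]], motifs[[j]])
    m
  } else if (inherits(distances, "distance_table")) {
    distances$matrices[["D_Stop_motif"]] %||% distances$matrices[[1]]
  } else as.matrix(distances)
  ids <- rownames(D)
  with_seed(seed, {
    prom <- setNames(runif(length(ids)), ids)
    recs <- empty_assay_records()
    for (def in ids) for (ch in ids) {
      true <- true_score(D[ch, def], prom[[def]], config)
      if (ch %in% outgroup || def %in% outgroup) true <- 5L
      scores <- replicate_scores(true, config)
      recs <- rbind(recs, assay_record(ch, def, "lysogen", scores))
      if (config$include_crs) {
        crs_true <- crs_score(true, D[ch, def])
        if (ch %in% outgroup || def %in% outgroup) crs_true <- 5L
        recs <- rbind(recs, assay_record(ch, paste0(def, "_CRS"), "CRS",
                                         replicate_scores(crs_true, config)))
      }
    }
    rownames(recs) <- NULL
    recs
  })
}

true_score <- function(d, prom, cfg) {
  as.integer(pmin(6, pmax(0, round(5 * saturating_link(cfg$beta * d - cfg$alpha * prom)))))
}

# a CRS defends slightly less well than the cognate lysogen against the
# homotypic phage, slightly better at larger motif distances
crs_score <- function(lys_score, d) {
  as.integer(pmin(6, pmax(0, lys_score + (d < 0.05) - (d > 0.25))))
}

replicate_scores <- function(true, cfg) {
  shift <- sample(c(-1L, 0L, 1L), cfg$replicates, replace = TRUE,
                  prob = c(cfg$ordinal_noise / 2, 1 - cfg$ordinal_noise, cfg$ordinal_noise / 2))
  pmin(6L, pmax(0L, true + shift))
}

#' Simulate a plate observation consistent with a rubric score
#'
#' Samples a `plate_observation` from within the rubric cell of the given
#' 0-6 score, so that [score_observation()] maps it back to the same score.
#'
#' @param true_score Integer 0-6.
#' @param seed Integer seed.
#' @return A `plate_observation`.
#' @export
simulate_plate_observations <- function(true_score, seed = 1) {
  stopifnot(true_score %in% 0:6)
  with_seed(seed, {
    eop1 <- runif(1, 0.6, 1.1)  # order-unity EOP
    switch(as.character(true_score),
      "0" = plate_observation(FALSE, spot_titers_with_lysis = 0L),
      "1" = plate_observation(FALSE, spot_titers_with_lysis = sample(1:2, 1)),
      "2" = if (runif(1) < 0.5)
        plate_observation(TRUE, eop = 10^runif(1, -6, -3.1))
      else plate_observation(FALSE, spot_titers_with_lysis = 3L),
      "3" = if (runif(1) < 0.5)
        plate_observation(TRUE, eop = 10^runif(1, -3, -1))
      else plate_observation(FALSE, spot_titers_with_lysis = sample(4:5, 1)),
      "4" = if (runif(1) < 0.5)
        plate_observation(TRUE, eop = eop1, turbidity = "increased")
      else plate_observation(TRUE, eop = eop1, plaque_size = "reduced"),
      "5" = plate_observation(TRUE, eop = eop1),
      "6" = if (runif(1) < 0.5)
        plate_observation(TRUE, eop = eop1, turbidity = "reduced")
      else plate_observation(TRUE, eop = eop1, plaque_size = "increased"))
  })
}

#' Simulate a one-site binding titration
#'
#' `Y = bmax * X / (kd + X)` plus seeded Gaussian noise, clipped to [0, 1].
#'
#' @param kd True dissociation constant (nM, > 0).
#' @param bmax True saturation fraction.
#' @param concentrations Concentrations (nM).
#' @param noise_sd Gaussian noise SD on the fraction bound.
#' @param seed Integer seed.
#' @return A `binding_series`.
#' @export
simulate_binding <- function(kd, bmax, concentrations, noise_sd = 0, seed = 1) {
  stopifnot(kd > 0)
  with_seed(seed, {
    y <- bmax * concentrations / (kd + concentrations)
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
    binding_series(concentrations, pmin(1, pmax(0, y)))
  })
}
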