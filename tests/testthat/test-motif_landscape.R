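test_that("build_pwm matches the brute-force smoothing oracle", {
  set.seed(11)
  for (rep in 1:5) {
    sites <- replicate(sample(3:12, 1), random_dna_str(13))
    m <- build_pwm(sites)
    o <- oracle_pwm(sites)
    expect_lt(max(abs(m$P - o$P)), 1e-12)
    expect_lt(max(abs(m$W - o$W)), 1e-12)
    expect_equal(unname(colSums(m$P)), rep(1, 13), tolerance = 1e-9)
    expect_equal(m$width, 13)
  }
})

test_that("build_pwm handles degenerate and invalid input", {
  m <- build_pwm("AAAA", k = 0)
  expect_equal(unname(m$P["A", ]), rep(1, 4))
  expect_equal(unname(m$P["C", ]), rep(0, 4))
  expect_error(build_pwm(c("AAAA", "AAAAA")), "mixed widths")
  expect_error(build_pwm(counts = matrix(0, 4, 3)), "zero")
  ic <- information_content(m, per_column = TRUE)
  expect_true(all(ic >= 0 & ic <= 2 + 1e-12))
})

test_that("motif_distance matches its formula and is a pseudometric", {
  set.seed(12)
  for (rep in 1:5) {
    m1 <- random_motif_model(); m2 <- random_motif_model()
    d <- motif_distance(m1, m2)
    expect_lt(abs(d - oracle_motif_distance(m1$P, m2$P)), 1e-12)
    expect_identical(d, motif_distance(m2, m1))
  }
  expect_identical(motif_distance(m1, m1), 0)
  # maximal disjoint columns: width-1 point masses
  a <- build_pwm("A", k = 0); t <- build_pwm("T", k = 0)
  expect_equal(motif_distance(a, t), 1)
  # triangle inequality over random triples
  for (i in 1:100) {
    tri <- replicate(3, random_motif_model(), simplify = FALSE)
    d12 <- motif_distance(tri[[1]], tri[[2]])
    d13 <- motif_distance(tri[[1]], tri[[3]])
    d23 <- motif_distance(tri[[2]], tri[[3]])
    expect_lte(d12, d13 + d23 + 1e-12)
    expect_gte(d12, 0)
  }
  expect_error(motif_distance(random_motif_model(12), random_motif_model(13)),
               "unequal widths")
})

test_that("scan_sites recovers exact planted consensus occurrences", {
  set.seed(13)
  cons <- "GGTGGATGTCAAG"
  bg <- random_dna_str(6000)
  pos <- c(500L, 1500L, 3000L, 4500L)
  strand <- c("+", "-", "+", "-")
  seq <- bg
  for (i in seq_along(pos)) {
    planted <- if (strand[i] == "+") cons else as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cons)))
    substr(seq, pos[i], pos[i] + 12L) <- planted
  }
  model <- build_pwm(rep(cons, 10))
  cons_score <- sum(apply(model$W, 2, max))
  hits <- scan_sites(seq, model, cons_score - 1e-9)
  expect_setequal(hits$start, pos)
  expect_equal(hits$strand[order(hits$start)], strand)
  expect_true(all(hits$sequence == cons))
  expect_equal(nrow(scan_sites(seq, model, Inf)), 0L)
})

test_that("palindromic sites are reported once with strand tie to '+'", {
  pal <- "ACGCGT"  # reverse complement of itself
  seq <- paste0(random_dna_str(200), pal, random_dna_str(200))
  m <- build_pwm(rep(pal, 5))
  thr <- sum(apply(m$W, 2, max)) - 1e-9
  hits <- scan_sites(seq, m, thr)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
})

test_that("orientation classification follows the center rule", {
  sites <- data.frame(start = c(9994L, 39994L, 39994L, 24994L),
                      end = c(10006L, 40006L, 40006L, 25006L),
                      strand = c("+", "-", "+", "-"))
  # midpoints 10000, 40000, 40000, 25000 against center 25000
  expect_equal(classify_orientation(sites, 25000),
               c("syn", "syn", "anti", "anti"))
  # exactly-centered site: tie broken by strand
  tie <- data.frame(start = 24994L, end = 25006L, strand = "+")
  expect_equal(classify_orientation(tie, 25000), "syn")
})

test_that("positional distribution pools offsets relative to the anchor", {
  genes <- data.frame(gene_id = "rep", start = 5000L, end = 5600L, strand = "-",
                      pham = "p", product = "rep", stringsAsFactors = FALSE)
  g1 <- phage_genome("g1", random_dna_str(8000), genes)
  genes2 <- genes; genes2$start <- 3000L; genes2$end <- 3600L
  g2 <- phage_genome("g2", random_dna_str(8000), genes2)
  # rep is minus-strand, so its 3' end is the gene start coordinate
  sites <- data.frame(
    genome_id = c("g1", "g1", "g2"),
    start = c(5000L - 212L, 5000L + 88L, 3000L - 212L),
    end = c(5000L - 200L, 5000L + 100L, 3000L - 200L),
    strand = "-", stringsAsFactors = FALSE)
  h <- positional_distribution(sites, list(g1 = g1, g2 = g2),
                               anchor = list(type = "gene_3prime", product = "rep"),
                               bin_width = 100)
  expect_equal(h$count[h$bin_start == -200], 2L)
  expect_equal(h$count[h$bin_start == 100], 1L)
  expect_equal(sum(h$count), 3L)
  empty <- positional_distribution(sites[0, ], list(g1 = g1),
                                   anchor = list(type = "right_terminus"))
  expect_equal(nrow(empty), 0L)
  # unresolvable anchor: genome skipped with a warning
  g3 <- phage_genome("g3", random_dna_str(8000))
  s3 <- data.frame(genome_id = "g3", start = 100L, end = 112L, strand = "+")
  expect_warning(
    h3 <- positional_distribution(s3, list(g3 = g3),
                                  anchor = list(type = "gene_3prime", product = "rep")),
    "skipped")
  expect_equal(nrow(h3), 0L)
})

test_that("discovery on a null i.i.d. genome reports not found", {
  set.seed(14)
  rnd <- random_dna_str(25000)
  res <- discover_stoperators(rnd)
  expect_false(res$found)
  expect_equal(nrow(res$sites), 0L)
})

test_that("re-scanning with the discovered model reproduces the site set", {
  cl <- simulate_clade(clade_sim_config(n_phages = 2, genome_length = 20000),
                       seed = 21)
  g <- cl$genomes[[1]]
  res <- discover_stoperators(g, reference_motif = cl$truth$motifs[[1]])
  expect_true(res$found)
  expect_true(nrow(res$sites) >= 10 && nrow(res$sites) <= 50)
  rescan <- scan_sites(g, res$model, res$threshold)
  found_keys <- paste(res$sites$start, res$sites$strand)
  expect_true(all(found_keys %in% paste(rescan$start, rescan$strand)))
})

test_that("planted syn-orientation dominates in both genome arms", {
  # orientations are inherited within a clade, so pool over independent
  # clades planted at a strongly syn-oriented setting
  tot <- c(left = 0L, right = 0L); syn <- c(left = 0L, right = 0L)
  for (seed in 1:5) {
    cl <- simulate_clade(clade_sim_config(n_phages = 2, genome_length = 15000,
                                          syn_prob = 0.97), seed = seed)
    id <- names(cl$genomes)[1]
    ctr <- genome_center(cl$genomes[[id]])
    ss <- cl$truth$sites[cl$truth$sites$genome_id == id, ]
    mid <- (ss$start + ss$end) / 2
    ori <- classify_orientation(ss, ctr)
    arm <- ifelse(mid < ctr, "left", "right")
    for (a in c("left", "right")) {
      tot[a] <- tot[a] + sum(arm == a)
      syn[a] <- syn[a] + sum(arm == a & ori == "syn")
    }
  }
  expect_gte(syn["left"] / tot["left"], 0.9)
  expect_gte(syn["right"] / tot["right"], 0.9)
})

test_that("MEME minimal motif files round-trip the probability matrix", {
  m <- random_motif_model(13, 20)
  tf <- tempfile(fileext = ".meme")
  write_meme_motif(m, tf)
  back <- read_meme_motif(tf)
  expect_equal(back$width, 13)
  expect_lt(max(abs(back$P - m$P)), 1e-4)
})
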