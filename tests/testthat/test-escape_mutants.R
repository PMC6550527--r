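test_that("the notation grammar parses the documented forms", {
  s <- parse_mutation("G44351A (Rep Q138*)")
  expect_equal(s$kind, "substitution")
  expect_equal(s$start, 44351L)
  expect_equal(s$ref, "G"); expect_equal(s$alt, "A")
  expect_equal(s$annotation, "Rep Q138*")

  d <- parse_mutation("Δ45310:48001 (Δrep)")
  expect_equal(d$kind, "deletion")
  expect_equal(c(d$start, d$end), c(45310L, 48001L))

  i <- parse_mutation("44333:44334 27-bp ins (Rep-HA)")
  expect_equal(i$kind, "insertion")
  expect_equal(i$ins_len, 27L)
  expect_equal(c(i$start, i$end), c(44333L, 44334L))

  r <- parse_mutation("rec Tx 44620:44630 and RR 44127:44137")
  expect_equal(r$kind, "recombination")
  expect_equal(r$donor_a, "Tx")
  expect_equal(r$window_b, c(44127L, 44137L))

  dp <- parse_mutation("RR 45315:45316 G insertion (Rep R149fs)")
  expect_equal(dp$kind, "insertion")
  expect_equal(dp$donor, "RR")
  expect_equal(dp$ins_seq, "G")

  expect_error(parse_mutation("G44351G"), "differ")
  expect_error(parse_mutation("44333:44340 27-bp ins"), "adjacent")
  expect_error(parse_mutation("whatever"), "offset")
})

test_that("parse/format is the identity on every catalog mutation string", {
  tb <- read_mutant_catalog()
  strs <- unlist(lapply(tb$mutations[!is.na(tb$mutations)],
                        function(x) trimws(strsplit(x, ";")[[1]])))
  expect_gte(length(strs), 25)
  for (s in strs) expect_identical(format_mutation(parse_mutation(s)), s)
})

test_that("the catalog carries 9 L5-clade DEMs from 6 defending strains", {
  tb <- read_mutant_catalog()
  dems <- tb[tb$is_dem & tb$l5_clade, ]
  expect_equal(nrow(dems), 9L)
  expect_equal(length(unique(dems$defending_strain)), 6L)
  expect_equal(sum(tb$is_dem), 10L)  # including the non-clade CRS escape
})

test_that("apply_mutations performs exact string surgery", {
  set.seed(51)
  parent <- random_dna_str(2000)
  expect_identical(apply_mutations(parent, list()), parent)
  # substitution changes only the target base
  pos <- 700L
  ref <- substr(parent, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  sub <- parse_mutation(paste0(ref, pos, alt))
  mut <- apply_mutations(parent, list(sub))
  expect_identical(substr(mut, pos - 10, pos - 1), substr(parent, pos - 10, pos - 1))
  expect_identical(substr(mut, pos + 1, pos + 10), substr(parent, pos + 1, pos + 10))
  expect_identical(substr(mut, pos, pos), alt)
  wrong <- parse_mutation(paste0(setdiff(c("A","C","G","T"), c(ref, alt))[1], pos, alt))
  expect_error(apply_mutations(parent, list(wrong)), "reference mismatch")
})

test_that("length accounting is exact for every spec kind", {
  set.seed(52)
  parent <- random_dna_str(3000)
  for (i in 1:20) {
    specs <- list()
    delta <- 0L
    # one deletion and one insertion in disjoint halves
    ds <- sample(100:1200, 1); de <- ds + sample(0:200, 1)
    specs[[1]] <- parse_mutation(paste0("Δ", ds, ":", de))
    delta <- delta - (de - ds + 1L)
    is <- sample(1500:2800, 1)
    len <- sample(1:30, 1)
    specs[[2]] <- parse_mutation(paste0(is, ":", is + 1L, " ", len, "-bp ins"))
    delta <- delta + len
    mut <- apply_mutations(parent, specs)
    expect_equal(nchar(mut), nchar(parent) + delta)
  }
  # recombination specs are represented but not auto-applied
  rec <- parse_mutation("rec Tx 100:110 and RR 200:210")
  expect_warning(out <- apply_mutations(parent, list(rec)), "skipped")
  expect_identical(out, parent)
  hyb <- build_recombinant(parent, parent, 100L, 201L)
  expect_equal(nchar(hyb), 100L + nchar(parent) - 200L)
})

test_that("repressor impact classification reproduces catalog annotations", {
  cases <- list(
    list(mut = "G44351A (Rep Q138*)", parent = "Bxb1", cat = "nonsense", pos = 138L),
    list(mut = "G44573T (Rep Y48*)", parent = "Pioneer", cat = "nonsense", pos = 48L),
    list(mut = "G44580T (Rep S102*)", parent = "Et2Brutus", cat = "nonsense", pos = 102L),
    list(mut = "G44772A (Rep A38V)", parent = "Et2Brutus", cat = "missense", pos = 38L),
    list(mut = "43427:43428 G insertion (Rep R52fs)", parent = "DaVinci",
         cat = "frameshift", pos = 52L),
    list(mut = "43878:43879 G insertion (Rep G135fs)", parent = "Gladiator",
         cat = "frameshift", pos = 135L),
    list(mut = "45315:45316 G insertion (Rep R149fs)", parent = "RedRock",
         cat = "frameshift", pos = 149L),
    list(mut = "Δ45310:48001 (Δrep)", parent = "EagleEye", cat = "deleted", pos = NA),
    list(mut = "Δ44705:47517 (rep Δ5' end)", parent = "Che12",
         cat = "truncated_5prime", pos = NA),
    list(mut = "G50942T (gp89 F47L)", parent = "L5", cat = "none", pos = NA))
  for (cs in cases) {
    pg <- synthetic_parent_genome(cs$parent)
    out <- classify_rep_impact(pg$sequence, pg$rep_gene,
                               list(parse_mutation(cs$mut)))
    expect_equal(out$category, cs$cat, label = cs$mut)
    if (!is.na(cs$pos)) expect_equal(out$position, cs$pos, label = cs$mut)
  }
  pg <- synthetic_parent_genome("L5")
  expect_error(classify_rep_impact(pg$sequence, NULL, list()), "not annotated")
})

test_that("virulence breadth classes follow the gain rule", {
  defs <- c("L5", "Trixie", "Gladiator", "Et2Brutus")
  mk <- function(dem_scores, parent_scores) {
    recs <- empty_assay_records()
    for (k in seq_along(defs)) {
      recs <- rbind(recs, assay_record("dem", defs[k], "lysogen", dem_scores[k]))
      recs <- rbind(recs, assay_record("L5", defs[k], "lysogen", parent_scores[k]))
    }
    aggregate_replicates(recs)
  }
  # gains only on the parent's own lysogen
  m <- mk(c(5L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L))
  expect_equal(virulence_breadth(m, "dem", "L5")$class, "narrow_homotypic")
  # gains everywhere: broad homotypic and mesotypic virulence
  m <- mk(c(5L, 5L, 5L, 4L), c(0L, 0L, 0L, 0L))
  expect_equal(virulence_breadth(m, "dem", "L5")$class, "broad")
  # identical profiles: no gains
  m <- mk(c(2L, 2L, 2L, 2L), c(2L, 2L, 2L, 2L))
  expect_equal(virulence_breadth(m, "dem", "L5")$class, "none")
  # gains on one mesotypic system only
  m <- mk(c(0L, 5L, 0L, 0L), c(0L, 0L, 0L, 0L))
  expect_equal(virulence_breadth(m, "dem", "L5")$class, "narrow_mesotypic")
  # untested homotypic defender is flagged
  recs <- rbind(assay_record("dem", "Trixie", "lysogen", 5L),
                assay_record("dem", "Gladiator", "lysogen", 0L),
                assay_record("L5", "Trixie", "lysogen", 0L),
                assay_record("L5", "Gladiator", "lysogen", 0L))
  vb <- virulence_breadth(aggregate_replicates(recs), "dem", "L5")
  expect_true(vb$homotypic_untested)
})
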