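test_that("demultiplexing partitions reads exhaustively and rejects bad barcode sets", {
  bcs <- c(a = "AAAAAA", b = "TTTTTT", c = "GGGCCC")
  pool <- rna_pool(strrep("A", 20), 10)
  reads <- rbind(
    generate_reads(pool, 5L, barcode = "AAAAAA", seed = 1L),
    generate_reads(pool, 4L, barcode = "TTTTTT", seed = 2L),
    generate_reads(pool, 3L, barcode = "CCCCCC", seed = 3L))
  dmx <- demultiplex(reads, bcs, max_mismatch = 1L)
  expect_identical(vapply(dmx$assigned, nrow, integer(1L)),
                   c(a = 5L, b = 4L, c = 0L))
  expect_identical(nrow(dmx$unassigned), 3L)  # CCCCCC is 3 from GGGCCC
  # partition is exhaustive and disjoint
  expect_identical(sum(vapply(dmx$assigned, nrow, integer(1L))) +
                     nrow(dmx$unassigned), nrow(reads))
  # barcode is stripped from assigned reads
  expect_true(all(startsWith(dmx$assigned$a$sequence,
                             substr(pool$read_template, 1L, 6L))))
  # one mismatch from barcode a -> still assigned to a
  one_off <- reads[1L, , drop = FALSE]
  substr(one_off$sequence, 2L, 2L) <- "C"
  expect_identical(nrow(demultiplex(one_off, bcs, 1L)$assigned$a), 1L)
  # a set violating the pairwise-distance precondition is rejected
  expect_error(demultiplex(reads, c(x = "AAAAAA", y = "AAAATT"), 1L),
               "Hamming")
})

test_that("variable-region extraction anchors on flanks with mismatch tolerance", {
  d <- hairpin_n20_design()
  insert <- "UUGUGACGCAAAACCCCGGG"
  pool <- rna_pool(insert, 10, d)
  perfect <- pool$read_template
  expect_identical(as.vector(extract_variable_region(perfect, d)), insert)
  # one substitution inside the 5' anchor is tolerated
  mutated <- perfect
  substr(mutated, nchar(d$fixed_5p) - 3L, nchar(d$fixed_5p) - 3L) <- "A"
  expect_identical(as.vector(extract_variable_region(mutated, d)), insert)
  # missing 3' anchor -> rejected with reason
  broken <- substr(perfect, 1L, nchar(d$fixed_5p) + 20L + 3L)
  out <- extract_variable_region(broken, d)
  expect_true(is.na(out[1L]))
  expect_identical(attr(out, "reject_reason"), "flank_not_found")
})

test_that("count tables are exact, ordered, and order-invariant", {
  tab <- build_count_table(c("AAA", "AAA", "CCC"), "RNA", 1L)
  expect_identical(tab$sequence, c("AAA", "CCC"))
  expect_identical(tab$count, c(2L, 1L))
  expect_equal(tab$abundance, c(2 / 3, 1 / 3))
  expect_error(build_count_table(character(), "RNA", 1L), "no sequences")
  expect_error(build_count_table(NA_character_, "RNA", 1L), "no sequences")
  # permutation invariance
  withr::with_seed(4L, {
    seqs <- sample(rep(c("GGG", "AAA", "UUU"), c(5, 3, 2)))
  })
  expect_identical(build_count_table(seqs, "x", 1L),
                   build_count_table(rev(seqs), "x", 1L))
  # stop-containing variants dropped on request
  ptab <- build_count_table(c("AA*C", "AAAC", "AAAC"), "PD", 1L,
                            drop_stops = TRUE)
  expect_identical(ptab$sequence, "AAAC")
})

test_that("enrichment factors follow the abundance-ratio definition", {
  t1 <- build_count_table(rep(c("AAA", "CCC", "GGG"), c(300, 600, 100)),
                          "RNA", 1L)
  t2 <- build_count_table(rep(c("AAA", "CCC", "GGG"), c(600, 300, 100)),
                          "RNA", 2L)
  tab <- count_table_bind(t1, t2)
  efs <- enrichment_factors(tab, "RNA", 2L)
  ef <- setNames(efs$ef, efs$sequence)
  expect_equal(unname(ef["AAA"]), 2)
  expect_equal(unname(ef["CCC"]), 0.5)
  expect_equal(unname(ef["GGG"]), 1)
  # absent in later round -> EF 0; absent earlier -> undefined, with warning
  t3 <- build_count_table(rep(c("AAA", "UUU"), c(5, 5)), "RNA", 3L)
  tab2 <- count_table_bind(t2, t3)
  efs2 <- enrichment_factors(tab2, "RNA", 3L)
  expect_equal(efs2$ef[efs2$sequence == "CCC"], 0)
  expect_identical(efs2$status[efs2$sequence == "UUU"], "undefined")
  expect_warning(enrichment_factor(tab2, "UUU", "RNA", 3L), "undefined")
})

test_that("EF coverage identity holds on random tables with no novel species", {
  for (seed in 1:5) {
    tab <- random_two_round_table(seed = seed)
    efs <- enrichment_factors(tab, "RNA", 2L)
    expect_true(all(efs$status == "ok"))
    expect_equal(sum(efs$abundance_from * efs$ef), 1, tolerance = 1e-12)
  }
  # with novel species, the identity gives the coverage of round N by
  # round N-1 species, i.e. 1 - (novel abundance)
  t1 <- build_count_table(rep(c("AAA", "CCC"), c(50, 50)), "p", 1L)
  t2 <- build_count_table(rep(c("AAA", "CCC", "GGG"), c(40, 40, 20)), "p", 2L)
  efs <- enrichment_factors(count_table_bind(t1, t2), "p", 2L)
  ok <- efs$status == "ok"
  expect_equal(sum(efs$abundance_from[ok] * efs$ef[ok]), 0.8)
})

test_that("monotonic EF filter keeps the boundary and drops undefined EFs", {
  mk <- function(counts, round)
    build_count_table(rep(names(counts), counts), "PD", round)
  # species "keep" has EFs exactly (1.2, 1.0); "drop" has (2.0, 0.9);
  # "late" appears only in round 2 (undefined first EF)
  t1 <- mk(c(keep = 100, drop = 10, fill = 890), 1L)
  t2 <- mk(c(keep = 120, drop = 20, late = 10, fill = 850), 2L)
  t3 <- mk(c(keep = 120, drop = 18, late = 20, fill = 842), 3L)
  tab <- count_table_bind(t1, t2, t3)
  surv <- filter_monotonic_enrichment(tab, "PD", 1:3, threshold = 1.0)
  expect_true("keep" %in% surv)
  expect_false("drop" %in% surv)
  expect_false("late" %in% surv)
})

test_that("top-N ranking uses the deterministic tie-break and warns when short", {
  tab <- build_count_table(rep(c("CCC", "AAA", "GGG"), c(5, 5, 9)), "x", 1L)
  top2 <- top_species(tab, "x", 1L, n = 2L)
  expect_identical(top2$sequence, c("GGG", "AAA"))  # tie AAA/CCC -> lexicographic
  expect_warning(full <- top_species(tab, "x", 1L, n = 10L), "only 3")
  expect_true(attr(full, "truncated"))
  expect_identical(nrow(full), 3L)
})

test_that("diversity profile separates singletons and conserves totals", {
  all_single <- build_count_table(c("AAA", "CCC", "GGG"), "x", 1L)
  prof <- diversity_profile(all_single, "x", 1L)
  expect_equal(prof$proportion[prof$bin == "singleton"], 1)
  expect_identical(prof$n_unique[prof$bin == "singleton"], 3L)
  # 10000 singletons + 1 species with 10000 copies -> singleton prop 0.5
  seqs <- c(vapply(1:10000, function(i)
    sprintf("S%05d", i), character(1L)), rep("BIG", 10000))
  tab <- build_count_table(seqs, "x", 1L)
  prof2 <- diversity_profile(tab, "x", 1L)
  expect_equal(prof2$proportion[prof2$bin == "singleton"], 0.5)
  # property: proportions sum to 1, unique counts sum to richness
  for (seed in 1:3) {
    rt <- random_two_round_table(seed = seed)
    p <- diversity_profile(rt, "RNA", 1L)
    expect_equal(sum(p$proportion), 1, tolerance = 1e-12)
    expect_identical(sum(p$n_unique), length(unique(
      rt$sequence[rt$round == 1L])))
  }
  expect_error(diversity_profile(all_single, "x", 1L, bin_edges = c(3, 10)),
               "2")
})

test_that("motif fractions are abundance-weighted", {
  tab <- build_count_table(
    rep(c("AAUUGUGACGCAA", "AAUUGUGAGGCAA", "AAAAAAAAAAAAA"),
        c(40, 30, 30)), "RNA", 6L)
  expect_equal(motif_fraction(tab, "UUGUGASGC", "RNA", 6L), 0.7)
  expect_equal(motif_fraction(tab, "UUUUUUUUU", "RNA", 6L), 0)
  expect_equal(motif_fraction(tab, "A", "RNA", 6L), 1)
})

test_that("positional residue frequencies normalize per position", {
  tab <- build_count_table(rep(c("AWRPIGKE", "AARPIGKE"), c(6, 4)), "PD", 6L)
  fr <- positional_residue_frequency(tab, "PD", 6L, top_k = 2L)
  expect_equal(colSums(fr), rep(1, 8), ignore_attr = TRUE)
  expect_equal(fr["W", "pos2"], 0.5)   # unweighted: each variant counts once
  frw <- positional_residue_frequency(tab, "PD", 6L, top_k = 2L,
                                      weighted = TRUE)
  expect_equal(frw["W", "pos2"], 0.6)  # abundance-weighted
  expect_equal(unname(fr["A", "pos1"]), 1)
})

test_that("k-mer consensus scan recovers a planted degenerate motif", {
  seqs <- c(paste0("AAAA", "UUGUGACGC", "AAAAAAA"),
            paste0("CCCC", "UUGUGAGGC", "CCCCCCC"))
  tab <- build_count_table(rep(seqs, c(55, 45)), "RNA", 6L)
  sc <- scan_kmer_consensus(tab, k = 9L, top = 20L)
  # the planted core ranks among the heaviest 9-mers and its single-position
  # C/G variant pair is collapsed into the degenerate S code
  row <- sc[sc$kmer == "UUGUGACGC", ]
  expect_identical(nrow(row), 1L)
  expect_equal(row$weight, 0.55)
  expect_identical(row$pattern, "UUGUGASGC")
})
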