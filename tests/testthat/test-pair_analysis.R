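test_that("protein-coding filter drops stable-RNA genes and nothing else", {
  genes <- make_genes(
    starts = c(100L, 500L, 900L), stops = c(400L, 800L, 1300L),
    strands = rep("+", 3), is_protein_coding = c(TRUE, FALSE, TRUE)
  )
  kept <- filter_protein_coding(genes)
  expect_equal(kept$locus_tag, c("g001", "g003"))

  all_cds <- make_genes(100L, 400L, "+")
  expect_equal(filter_protein_coding(all_cds), all_cds)
  expect_equal(nrow(filter_protein_coding(all_cds[0, ])), 0)
})

test_that("gene-internal transposases are removed, survivors untouched", {
  genes <- make_genes(
    starts = c(100L, 180L, 900L), stops = c(400L, 800L, 1300L),
    strands = rep("+", 3),
    locus = c("fragment1", "transposase", "fragment2"),
    transposase_internal = c(FALSE, TRUE, FALSE)
  )
  kept <- remove_transposase_insertions(genes)
  expect_equal(kept$locus_tag, c("fragment1", "fragment2"))
  expect_equal(as.data.frame(kept),
               as.data.frame(genes[c(1, 3), ]))
  expect_equal(nrow(remove_transposase_insertions(genes[2, ])), 0)
  expect_equal(remove_transposase_insertions(genes[c(1, 3), ]),
               genes[c(1, 3), ])
})

test_that("adjacent pairs: n-1 per replicon, never across replicons", {
  genes <- genes_with_distances(c(10L, 20L))
  expect_equal(nrow(extract_adjacent_pairs(genes)), 2)

  two_reps <- dplyr::bind_rows(
    genes_with_distances(5L, replicon = "repA"),
    genes_with_distances(5L, replicon = "repB")
  )
  two_reps$locus_tag <- sprintf("g%03d", 1:4)
  pairs <- extract_adjacent_pairs(two_reps)
  expect_equal(nrow(pairs), 2)
  expect_equal(sort(pairs$replicon_id), c("repA", "repB"))
  expect_true(all(pairs$first_start <= pairs$second_start))
})

test_that("equal start coordinates are tie-broken like a stable sort", {
  genes <- make_genes(
    starts = c(100L, 100L, 600L), stops = c(520L, 400L, 900L),
    strands = rep("+", 3), locus = c("gB", "gA", "gC")
  )
  pairs <- extract_adjacent_pairs(genes)
  # brute-force oracle: order by (start, stop, locus_tag)
  ord <- order(genes$start, genes$stop, genes$locus_tag)
  expected_first <- genes$locus_tag[ord][1:2]
  expected_second <- genes$locus_tag[ord][2:3]
  expect_equal(pairs$first_locus, expected_first)
  expect_equal(pairs$second_locus, expected_second)
})

test_that("duplicate records are rejected at pair extraction", {
  genes <- make_genes(starts = c(100L, 100L), stops = c(400L, 400L),
                      strands = c("+", "+"), locus = c("dup", "dup"))
  expect_error(extract_adjacent_pairs(genes), "duplicate")
})

test_that("orientation classification and transcription order", {
  cases <- list(
    list(strands = c("+", "+"), orientation = "serial", upstream = "g001"),
    list(strands = c("-", "-"), orientation = "serial", upstream = "g002"),
    list(strands = c("+", "-"), orientation = "convergent", upstream = NA),
    list(strands = c("-", "+"), orientation = "divergent", upstream = NA)
  )
  for (cs in cases) {
    genes <- make_genes(starts = c(100L, 600L), stops = c(400L, 900L),
                        strands = cs$strands)
    pair <- classify_orientation(extract_adjacent_pairs(genes))
    expect_equal(pair$orientation, cs$orientation)
    if (is.na(cs$upstream)) {
      expect_true(is.na(pair$upstream_locus))
    } else {
      expect_equal(pair$upstream_locus, cs$upstream)
    }
  }
})

test_that("orientation counts partition the n-1 pairs of a replicon", {
  spec <- genome_sim_spec(n_genes = 400L, strand_switch_prob = 0.4, seed = 7L)
  genes <- simulate_genome_annotation(spec)$genes
  pairs <- classify_orientation(extract_adjacent_pairs(genes))
  expect_equal(nrow(pairs), nrow(genes) - 1)
  expect_equal(sum(table(pairs$orientation)), nrow(genes) - 1)
  expect_true(all(c("serial", "convergent", "divergent") %in%
                    pairs$orientation))
})

test_that("pairs with truncated distance-defining termini are dropped", {
  base <- genes_with_distances(10L)

  up_trunc <- base
  up_trunc$truncated_stop[1] <- TRUE   # upstream gene lacks its stop codon
  pairs <- classify_orientation(extract_adjacent_pairs(up_trunc))
  expect_equal(nrow(drop_truncated_pairs(pairs)), 0)

  down_trunc <- base
  down_trunc$truncated_start[2] <- TRUE
  pairs <- classify_orientation(extract_adjacent_pairs(down_trunc))
  expect_equal(nrow(drop_truncated_pairs(pairs)), 0)

  # the opposite termini do not define the distance -> pair kept
  other <- base
  other$truncated_start[1] <- TRUE
  other$truncated_stop[2] <- TRUE
  pairs <- classify_orientation(extract_adjacent_pairs(other))
  expect_equal(nrow(drop_truncated_pairs(pairs)), 1)

  # no flags -> identity
  pairs <- classify_orientation(extract_adjacent_pairs(base))
  expect_equal(drop_truncated_pairs(pairs), pairs)

  # reverse strand: mirroring the replicon keeps g001 transcriptionally
  # upstream, so its truncated stop still kills the pair ...
  rev_genes <- flip_replicon(base)
  rev_genes$truncated_stop[1] <- TRUE
  pairs <- classify_orientation(extract_adjacent_pairs(rev_genes))
  expect_equal(nrow(drop_truncated_pairs(pairs)), 0)
  # ... while a truncated stop on the downstream gene does not
  rev_genes <- flip_replicon(base)
  rev_genes$truncated_stop[2] <- TRUE
  pairs <- classify_orientation(extract_adjacent_pairs(rev_genes))
  expect_equal(nrow(drop_truncated_pairs(pairs)), 1)
})

test_that("intergenic distance is anchored by the printed boundary motifs", {
  # ATGA motif: upstream stop codon 198..200, downstream start codon 197..199
  atga <- make_genes(starts = c(101L, 197L), stops = c(200L, 700L),
                     strands = c("+", "+"))
  expect_equal(serial_gene_pairs(atga)$distance, -4L)

  # TAATG motif: stop codon 198..200, start codon 200..202
  taatg <- make_genes(starts = c(101L, 200L), stops = c(200L, 700L),
                      strands = c("+", "+"))
  expect_equal(serial_gene_pairs(taatg)$distance, -1L)

  # abutting genes: stop last base 300, start first base 301
  abut <- make_genes(starts = c(1L, 301L), stops = c(300L, 600L),
                     strands = c("+", "+"))
  expect_equal(serial_gene_pairs(abut)$distance, 0L)

  # one intervening nucleotide
  plus1 <- make_genes(starts = c(1L, 302L), stops = c(300L, 601L),
                      strands = c("+", "+"))
  expect_equal(serial_gene_pairs(plus1)$distance, 1L)
})

test_that("intergenic distance refuses non-serial pairs", {
  conv <- make_genes(starts = c(100L, 600L), stops = c(400L, 900L),
                     strands = c("+", "-"))
  pairs <- classify_orientation(extract_adjacent_pairs(conv))
  expect_error(intergenic_distance(pairs), "serial")
})

test_that("distances are strand-symmetric under replicon reversal", {
  set.seed(11)
  spec <- genome_sim_spec(n_genes = 300L, strand_switch_prob = 0.3, seed = 3L)
  genes <- simulate_genome_annotation(spec)$genes
  fwd <- serial_gene_pairs(genes)
  rev <- serial_gene_pairs(flip_replicon(genes))
  expect_equal(sort(rev$distance), sort(fwd$distance))
})

test_that("long overlaps are flagged anomalous but kept", {
  genes <- genes_with_distances(c(-70L, 5L))
  pairs <- serial_gene_pairs(genes)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$anomalous_overlap, c(TRUE, FALSE))
})

test_that("two-branch phase formula equals nonnegative mod 3 everywhere", {
  k <- -1000:1000
  oracle <- ((k %% 3L) + 3L) %% 3L
  expect_equal(overlap_phase(k), as.integer(oracle))
  # printed memberships
  expect_equal(overlap_phase(c(-8L, -11L, -14L)), c(1L, 1L, 1L))
  expect_equal(overlap_phase(c(-7L, -10L, -13L)), c(2L, 2L, 2L))
  expect_equal(overlap_phase(c(-4L, -1L)), c(2L, 2L))
  expect_equal(overlap_phase(c(0L, 7L)), c(0L, 1L))
})

test_that("overlap feasibility matches brute-force enumeration", {
  canonical <- codon_sets()
  with_att <- codon_sets(extended_start_codons = "ATT")
  for (k in -5:-1) {
    for (cs in list(canonical, with_att)) {
      starts <- c(cs$start_codons, cs$extended_start_codons)
      expect_equal(
        overlap_feasibility(k, cs)$motifs,
        brute_force_motifs(k, starts, cs$stop_codons),
        info = sprintf("k=%d ext=%d", k, length(cs$extended_start_codons))
      )
    }
  }
})

test_that("feasibility returns the printed motif sets and sentinels", {
  expect_equal(overlap_feasibility(-4, codon_sets(c("ATG", "GTG")))$motifs,
               c("ATGA", "GTGA"))
  expect_setequal(overlap_feasibility(-1)$motifs,
                  c("TAATG", "TGATG", "TAGTG"))
  expect_length(overlap_feasibility(-5)$motifs, 0)
  expect_setequal(
    overlap_feasibility(-5, codon_sets(extended_start_codons = "ATT"))$motifs,
    c("ATTGA", "ATTAG", "ATTAA"))
  expect_length(overlap_feasibility(-2)$motifs, 0)
  # start codon would coincide with the stop codon: impossible at -3
  expect_length(overlap_feasibility(-3)$motifs, 0)
  # outside the collision regime the boundary is unconstrained
  expect_equal(overlap_feasibility(-8)$status, "unconstrained")
  expect_equal(overlap_feasibility(-8, codon_sets("ATG", "TGA"))$pattern,
               "ATGNNTGA")
  expect_equal(overlap_feasibility(0)$status, "unconstrained")
})
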