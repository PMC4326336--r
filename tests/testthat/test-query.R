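test_that("prefix variant counts follow the Hamming-ball closed form", {
  prefix <- "ACGTACGTACGTACGT"
  expect_equal(nrow(enumerate_prefix_variants(prefix, 0)), 1L)
  v1 <- enumerate_prefix_variants(prefix, 1)
  expect_equal(nrow(v1), 1L + 16L * 3L)
  expect_equal(sum(v1$mm == 0), 1L)
  expect_equal(anyDuplicated(v1$variant), 0L)
  v3 <- enumerate_prefix_variants(prefix, 3)
  expect_equal(nrow(v3), sum(choose(16, 0:3) * 3^(0:3)))
  expect_equal(as.vector(table(v3$mm)), as.vector(choose(16, 0:3) * 3^(0:3)))
  # distances are exact
  pc <- strsplit(prefix, "")[[1]]
  set.seed(5)
  for (i in sample(nrow(v3), 50)) {
    d <- sum(strsplit(v3$variant[i], "")[[1]] != pc)
    expect_equal(d, v3$mm[i])
  }
})

test_that("seed positions are never substituted", {
  prefix <- "ACGTACGTACGTACGT"
  expect_equal(nrow(enumerate_prefix_variants(prefix, 2, seed = 0:15)), 1L)
  v <- enumerate_prefix_variants(prefix, 1, seed = "0,1,2,3,4,5,6,7")
  expect_equal(nrow(v), 1L + 8L * 3L)
  pc <- strsplit(prefix, "")[[1]]
  for (i in seq_len(nrow(v))) {
    expect_equal(substring(v$variant[i], 1, 8), substring(prefix, 1, 8))
  }
})

test_that("seed mask parsing accepts vectors, lists, and 3prime shorthand", {
  expect_equal(parse_seed_mask(NULL), integer(0))
  expect_equal(parse_seed_mask("3prime:6"), 14:19)
  expect_equal(parse_seed_mask("3prime:0"), integer(0))
  expect_equal(parse_seed_mask("12,15,19,12"), c(12L, 15L, 19L))
  expect_equal(parse_seed_mask(c(3, 1)), c(1L, 3L))
  expect_error(parse_seed_mask("20,21"), "input error")
  expect_error(parse_seed_mask("3prime:25"), "input error")
})

test_that("a guide planted verbatim is its own unique 0-mismatch hit", {
  g <- synth_genome(5000, 1, 0.5, rng_seed = 41)
  guide <- rand_guide()
  px <- plant_offtargets(g, guide, data.frame(
    chrom = "chr1", position = 1000, strand = "+", mismatches = ""),
    "NGG", rng_seed = 42)
  idx <- build_index(px$genome, "NGG")
  h <- find_offtargets(idx, guide, "NGG", 0)
  expect_equal(h$position, 1000)
  expect_equal(h$mismatch_count, 0L)
  expect_equal(h$sequence, guide)
})

test_that("planted 2-mismatch site respects mismatch sets and seed masks", {
  set.seed(43)
  g <- synth_genome(5000, 1, 0.5, rng_seed = 43)
  guide <- rand_guide()
  px <- plant_offtargets(g, guide, data.frame(
    chrom = "chr1", position = 2000, strand = "+", mismatches = "3,18"),
    "NGG", rng_seed = 44, verify_background = TRUE, max_mm = 2)
  idx <- build_index(px$genome, "NGG")
  h <- find_offtargets(idx, guide, "NGG", 2)
  expect_equal(nrow(h), 1L)
  expect_equal(h$mismatch_positions, "3,18")
  expect_equal(nrow(find_offtargets(idx, guide, "NGG", 2, seed = 18)), 0L)
  expect_equal(nrow(find_offtargets(idx, guide, "NGG", 2, seed = c(5, 9))), 1L)
})

test_that("indexed search equals the brute-force oracle on random inputs", {
  set.seed(47)
  for (trial in 1:12) {
    g <- synth_genome(sample(1000:6000, 1), sample(1:2, 1),
                      runif(1, 0.35, 0.65))
    idx <- build_index(g, ALL_PAMS)
    guide <- if (runif(1) < 0.5) rand_guide() else {
      pos <- sample(nchar(g$seqs[[1]]) - 20, 1)
      gsub("N", "A", substring(g$seqs[[1]], pos, pos + 19))
    }
    pam <- sample(ALL_PAMS, 1)
    mm <- sample(0:5, 1)
    seed <- rand_seed_spec()
    expect_same_hits(find_offtargets(idx, guide, pam, mm, seed),
                     brute_force_offtargets(g, guide, pam, mm, seed))
  }
})

test_that("hit sets are monotone in the mismatch budget and seed nesting", {
  g <- synth_genome(8000, 1, 0.5, rng_seed = 53)
  idx <- build_index(g, "NGG")
  guide <- substring(g$seqs[[1]], 3001, 3020)
  prev <- character(0)
  for (mm in 0:5) {
    k <- hits_key(find_offtargets(idx, guide, "NGG", mm))
    expect_true(all(prev %in% k))
    prev <- k
  }
  # larger seed -> subset of hits
  h_small <- hits_key(find_offtargets(idx, guide, "NGG", 4, seed = "3prime:4"))
  h_large <- hits_key(find_offtargets(idx, guide, "NGG", 4, seed = "3prime:8"))
  expect_true(all(h_large %in% h_small))
})

test_that("every reported hit reads back from the genome with its PAM", {
  g <- synth_genome(10000, 2, 0.5, rng_seed = 59)
  idx <- build_index(g, c("NGG", "NNGRRT"))
  for (pam in c("NGG", "NNGRRT")) {
    L <- nchar(pam)
    # guide = a real protospacer of this PAM, so at least one hit exists
    sites <- scan_pam_sites(g, offtargetr:::make_pam_table(pam))
    st <- sites[1, ]
    raw20 <- substring(g$seqs[[st$chrom + 1]], st$position + 1, st$position + 20)
    guide <- if (st$strand == 0) raw20 else revcomp_chr(raw20)
    h <- find_offtargets(idx, guide, pam, 4)
    expect_gte(nrow(h), 1L)
    for (i in seq_len(nrow(h))) {
      s <- g$seqs[[h$chrom[i]]]
      p <- h$position[i]
      if (h$strand[i] == "+") {
        expect_equal(substring(s, p + 1, p + 20), h$sequence[i])
        expect_equal(substring(s, p + 21, p + 20 + L), h$pam[i])
      } else {
        expect_equal(revcomp_chr(substring(s, p + 1, p + 20)), h$sequence[i])
        expect_equal(revcomp_chr(substring(s, p - L + 1, p)), h$pam[i])
      }
      expect_equal(sum(strsplit(h$sequence[i], "")[[1]] !=
                         strsplit(guide, "")[[1]]), h$mismatch_count[i])
    }
  }
})

test_that("query input validation names the offence", {
  g <- genome(c(c1 = paste0(strrep("A", 20), "AGG")))
  idx <- build_index(g, "NGG")
  expect_error(find_offtargets(idx, "ACGT", "NGG", 1), "input error")
  expect_error(find_offtargets(idx, paste0(strrep("A", 19), "N"), "NGG", 1),
               "input error")
  expect_error(find_offtargets(idx, strrep("A", 20), "NAG", 1), "available")
  expect_error(find_offtargets(idx, strrep("A", 20), "NGG", 6), "max_mm")
})

test_that("mismatch histogram counts hits per mismatch number", {
  expect_equal(unname(mismatch_histogram(offtargetr:::.empty_hits(), 3)),
               rep(0L, 4))
  g <- synth_genome(20000, 1, 0.5, rng_seed = 61)
  guide <- rand_guide()
  px <- plant_offtargets(g, guide, data.frame(
    chrom = "chr1", position = c(500, 5000, 15000), strand = c("+", "-", "+"),
    mismatches = c("2", "17", "0,9,13")), "NGG", rng_seed = 62,
    verify_background = TRUE, max_mm = 3)
  histo <- mismatch_histogram(px$truth, 5)
  expect_equal(unname(histo), c(0L, 2L, 0L, 1L, 0L, 0L))
  idx <- build_index(px$genome, "NGG")
  h <- find_offtargets(idx, guide, "NGG", 3)
  expect_equal(mismatch_histogram(h, 3), mismatch_histogram(px$truth, 3))
  expect_equal(sum(mismatch_histogram(h, 3)), nrow(h))
})

test_that("gc_content is the G+C fraction", {
  expect_equal(gc_content(strrep("A", 20)), 0)
  expect_equal(gc_content(strrep("G", 20)), 1)
  expect_equal(gc_content(strrep("ACGT", 5)), 0.5)
  expect_error(gc_content("ACGN"), "input error")
})

test_that("extract_guides finds PAM-adjacent 20-mers on both strands", {
  eg <- extract_guides(paste0(strrep("A", 20), "AGG"), "NGG")
  expect_equal(eg$guide[eg$strand == "+"], strrep("A", 20))
  expect_equal(eg$offset[eg$strand == "+"], 0)
  # no PAM match on either strand (shortest admissible input for NGG)
  expect_equal(nrow(extract_guides(paste0(strrep("A", 12), strrep("T", 11)), "NGG")), 0L)
  expect_error(extract_guides(strrep("A", 501), "NGG"), "input error")
  expect_error(extract_guides(strrep("A", 22), "NGG"), "input error")
  # agreement with the site scanner on a random target
  set.seed(67)
  tgt <- paste(sample(BASES, 300, replace = TRUE), collapse = "")
  eg <- extract_guides(tgt, "NGG")
  sc <- scan_pam_sites(genome(c(t1 = tgt)), "NGG")
  expect_equal(sort(eg$offset), sort(sc$position))
  for (i in seq_len(nrow(eg))) {
    p <- eg$offset[i]
    expected <- if (eg$strand[i] == "+") substring(tgt, p + 1, p + 20) else
      revcomp_chr(substring(tgt, p + 1, p + 20))
    expect_equal(eg$guide[i], expected)
  }
})
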