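test_that("genotype harmonization replaces indices and complements when flipped", {
  expect_identical(harmonize_genotype(c(0, 1), "A", "G", "+"), c("A", "G"))
  expect_identical(harmonize_genotype(c(0, 1), "A", "G", "-"), c("C", "T"))
  expect_identical(harmonize_genotype(c(1, 1), "C", "T", "-"), c("A", "A"))
  expect_identical(harmonize_genotype(c(1, 0), "A", "G", "+"),
                   harmonize_genotype(c(0, 1), "A", "G", "+"))
  expect_error(harmonize_genotype(c(0, 2), "A", "G", "+"), "\\{0, 1\\}")
})

test_that("identical assemblies and callsets pair every interior SNP with itself", {
  sc <- tiny_scenario()
  asm2 <- reference_assembly(sc$ref_a$contigs, version = "A2")
  tab2 <- variant_table(sc$table_a$sites, sc$table_a$geno,
                        sc$table_a$samples, version = "A2")
  fl1 <- extract_flanks(sc$ref_a, sc$table_a, f = 100)
  fl2 <- extract_flanks(asm2, tab2, f = 100)
  i1 <- build_index(sc$ref_a); i2 <- build_index(asm2)
  pairs <- pair_snps(map_flanks(fl1, i2, asm2), map_flanks(fl2, i1, sc$ref_a),
                     sc$table_a, tab2)
  expect_true(all(pairs$strand == "+"))
  expect_identical(pairs$pos1_a, pairs$pos1_b)
  expect_identical(pairs$contig_a, pairs$contig_b)
  # everything that mapped uniquely got paired (identity mapping)
  expect_equal(nrow(pairs),
               sum(map_flanks(fl1, i2, asm2)$status == "UNIQUE"))
  # and genotype concordance of a table with itself is 1 everywhere
  conc <- genotype_concordance(pairs, sc$table_a, tab2)
  expect_true(all(conc$rate == 1))
})

test_that("candidates are excluded with the right reason codes", {
  asm_a <- reference_assembly(c(c1 = random_dna(300, seed = 61)),
                              version = "A")
  asm_b <- reference_assembly(asm_a$contigs, version = "B")
  ref150 <- substr(asm_a$contigs[["c1"]], 150, 150)
  alt150 <- setdiff(c("A", "C", "G", "T"), ref150)[1]
  tab_a <- make_table(pos1 = 150, ref = ref150, alt = alt150,
                      geno = rbind(c(1L, 1L)), version = "A")
  # B called no SNP at the transferred position
  ref80 <- substr(asm_b$contigs[["c1"]], 80, 80)
  tab_b <- make_table(pos1 = 80, ref = ref80,
                      alt = setdiff(c("A", "C", "G", "T"), ref80)[1],
                      geno = rbind(c(1L, 1L)), version = "B")
  fa <- extract_flanks(asm_a, tab_a, f = 50)
  fb <- extract_flanks(asm_b, tab_b, f = 50)
  ia <- build_index(asm_a); ib <- build_index(asm_b)
  pairs <- pair_snps(map_flanks(fa, ib, asm_b), map_flanks(fb, ia, asm_a),
                     tab_a, tab_b)
  expect_equal(nrow(pairs), 0L)
  expect_identical(attr(pairs, "exclusions")$reason, "TARGET_SITE_ABSENT")

  # same position but different ALT allele on the B side
  alt_other <- setdiff(c("A", "C", "G", "T"), c(ref150, alt150))[1]
  tab_b2 <- make_table(pos1 = 150, ref = ref150, alt = alt_other,
                       geno = rbind(c(1L, 1L)), version = "B")
  fb2 <- extract_flanks(asm_b, tab_b2, f = 50)
  pairs2 <- pair_snps(map_flanks(fa, ib, asm_b),
                      map_flanks(fb2, ia, asm_a), tab_a, tab_b2)
  expect_equal(nrow(pairs2), 0L)
  expect_identical(attr(pairs2, "exclusions")$reason, "ALLELE_MISMATCH")
})

test_that("concordance counts informative samples and rates correctly", {
  pairs <- structure(data.frame(
    snp_id = "A|c1|10|A|G", contig_a = "c1", pos1_a = 10L, ref_a = "A",
    alt_a = "G", contig_b = "c1", pos1_b = 10L, ref_b = "A", alt_b = "G",
    strand = "+", stringsAsFactors = FALSE),
    class = c("paired_snps", "data.frame"))
  ga <- matrix(c(0L, 1L, 2L, 1L, 0L), 1)
  gb <- matrix(c(0L, 1L, 2L, 0L, 0L), 1)   # one mismatch
  ta <- make_table(pos1 = 10, geno = ga, samples = paste0("s", 1:5),
                   version = "A")
  tb <- make_table(pos1 = 10, geno = gb, samples = paste0("s", 1:5),
                   version = "B")
  conc <- genotype_concordance(pairs, ta, tb)
  expect_equal(conc$n_informative, 5L)
  expect_equal(conc$n_match, 4L)
  expect_equal(conc$rate, 0.8)
  # a missing B call drops out of the denominator
  gb2 <- gb; gb2[1, 4] <- NA
  tb2 <- make_table(pos1 = 10, geno = gb2, samples = paste0("s", 1:5),
                    version = "B")
  conc2 <- genotype_concordance(pairs, ta, tb2)
  expect_equal(conc2$n_informative, 4L)
  expect_equal(conc2$rate, 1.0)
  # fixed-denominator reading counts it against the rate
  conc3 <- genotype_concordance(pairs, ta, tb2,
                                denominator = "all_shared")
  expect_equal(conc3$rate, 4 / 5)
  expect_error(genotype_concordance(pairs, ta,
                                    make_table(pos1 = 10, geno = gb,
                                               samples = paste0("x", 1:5),
                                               version = "B")),
               "no shared samples")
})

test_that("a flipped pair with complemented B genotypes is fully concordant", {
  pairs <- structure(data.frame(
    snp_id = "A|c1|10|A|G", contig_a = "c1", pos1_a = 10L, ref_a = "A",
    alt_a = "G", contig_b = "c2", pos1_b = 99L, ref_b = "T", alt_b = "C",
    strand = "-", stringsAsFactors = FALSE),
    class = c("paired_snps", "data.frame"))
  ga <- matrix(c(0L, 1L, 2L, 1L), 1)
  ta <- make_table(pos1 = 10, geno = ga, samples = paste0("s", 1:4),
                   version = "A")
  tb <- make_table(contig = "c2", pos1 = 99, ref = "T", alt = "C",
                   geno = ga, samples = paste0("s", 1:4), version = "B")
  conc <- genotype_concordance(pairs, ta, tb)
  expect_equal(conc$rate, 1.0)
  # the per-call harmonization agrees with the vectorized result
  h_a <- harmonize_genotype(c(0, 1), "A", "G", "+")
  h_b <- harmonize_genotype(c(0, 1), "T", "C", "-")
  expect_identical(h_a, h_b)
})

test_that("reliable selection is inclusive at the threshold", {
  base <- data.frame(
    snp_id = paste0("id", 1:4), contig_a = "c1", pos1_a = 1:4,
    ref_a = "A", alt_a = "G", contig_b = "c1", pos1_b = 1:4,
    ref_b = "A", alt_b = "G", strand = c("+", "+", "-", "-"),
    n_informative = 10L, n_match = c(10L, 9L, 9L, 8L),
    rate = c(1.0, 0.95, 0.90, 0.89), stringsAsFactors = FALSE)
  class(base) <- c("concordance_result", "data.frame")
  base$n_match <- as.integer(round(base$rate * 10))
  kept <- select_reliable(base, lift_params())
  expect_equal(nrow(kept), 3L)
  expect_true(all(kept$rate >= 0.90))
  tal <- attr(kept, "tally")
  expect_equal(as.vector(tal["-", ]), c(1, 1, 0))
  empty <- base[0, ]
  class(empty) <- class(base)
  expect_equal(nrow(select_reliable(empty, lift_params())), 0L)
})

test_that("planted per-pair error rates are selected exactly as recomputed", {
  set.seed(71)
  n_pairs <- 400; n_samp <- 50
  err <- stats::runif(n_pairs, 0, 0.25)
  ga <- matrix(sample(0:2, n_pairs * n_samp, replace = TRUE), n_pairs)
  gb <- ga
  flipped <- matrix(stats::runif(n_pairs * n_samp) < rep(err, n_samp),
                    n_pairs)
  gb[flipped] <- (gb[flipped] + 1L) %% 3L
  pairs <- structure(data.frame(
    snp_id = paste0("p", seq_len(n_pairs)), contig_a = "c1",
    pos1_a = seq_len(n_pairs), ref_a = "A", alt_a = "G", contig_b = "c1",
    pos1_b = seq_len(n_pairs), ref_b = "A", alt_b = "G", strand = "+",
    stringsAsFactors = FALSE), class = c("paired_snps", "data.frame"))
  ta <- make_table(pos1 = seq_len(n_pairs), geno = ga,
                   samples = paste0("s", seq_len(n_samp)), version = "A")
  tb <- make_table(pos1 = seq_len(n_pairs), geno = gb,
                   samples = paste0("s", seq_len(n_samp)), version = "B")
  conc <- genotype_concordance(pairs, ta, tb)
  kept <- select_reliable(conc, lift_params())
  # brute-force recomputation of each rate against the threshold
  brute_rate <- rowSums(ga == gb) / n_samp
  expect_equal(sort(kept$snp_id),
               sort(pairs$snp_id[brute_rate >= 0.90]))
  expect_equal(conc$rate, brute_rate)
  expect_true(all(conc$rate >= 0 & conc$rate <= 1))
})

test_that("swapping the roles of A and B mirrors pairs and keeps rates", {
  sc <- tiny_scenario()
  pipe <- tiny_pipeline()
  rev_pipe <- run_reconciliation(sc$ref_b, sc$ref_a, sc$table_b,
                                 sc$table_a, params = sc$params)
  key_fwd <- paste(pipe$pairs$contig_a, pipe$pairs$pos1_a,
                   pipe$pairs$contig_b, pipe$pairs$pos1_b)
  key_rev <- paste(rev_pipe$pairs$contig_b, rev_pipe$pairs$pos1_b,
                   rev_pipe$pairs$contig_a, rev_pipe$pairs$pos1_a)
  expect_setequal(key_fwd, key_rev)
  m <- match(key_fwd, key_rev)
  expect_equal(pipe$concordance$rate, rev_pipe$concordance$rate[m])
})
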