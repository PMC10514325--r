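identity_reliable <- function(tab) {
  s <- tab$sites
  df <- data.frame(
    snp_id = paste(tab$version, s$contig, s$pos1, s$ref, s$alt, sep = "|"),
    contig_a = s$contig, pos1_a = s$pos1, ref_a = s$ref, alt_a = s$alt,
    contig_b = s$contig, pos1_b = s$pos1, ref_b = s$ref, alt_b = s$alt,
    strand = "+", n_informative = 1L, n_match = 1L, rate = 1,
    stringsAsFactors = FALSE)
  class(df) <- c("reliable_set", "concordance_result", "data.frame")
  df
}

test_that("liftover through an identity reliable set is the identity", {
  tab <- tiny_scenario()$table_a
  rel <- identity_reliable(tab)
  out <- liftover_vcf(tab, rel, from = "a", target_version = tab$version)
  expect_identical(out$sites, tab$sites)
  expect_identical(out$geno, tab$geno)
  expect_equal(attr(out, "dropped"),
               c(not_in_reliable = 0L, allele_mismatch = 0L))
})

test_that("flipped pairs complement alleles and preserve base multisets", {
  rel <- data.frame(
    snp_id = "A|c1|10|A|G", contig_a = "c1", pos1_a = 10L, ref_a = "A",
    alt_a = "G", contig_b = "c2", pos1_b = 55L, ref_b = "T", alt_b = "C",
    strand = "-", n_informative = 1L, n_match = 1L, rate = 1,
    stringsAsFactors = FALSE)
  class(rel) <- c("reliable_set", "concordance_result", "data.frame")
  tab <- make_table(pos1 = 10, ref = "A", alt = "G",
                    geno = matrix(c(0L, 1L, 2L, NA), 1), version = "A",
                    samples = paste0("s", 1:4))
  out <- liftover_vcf(tab, rel, from = "a", target_version = "B")
  expect_identical(out$sites$contig, "c2")
  expect_equal(out$sites$pos1, 55L)
  expect_identical(c(out$sites$ref, out$sites$alt), c("T", "C"))
  # dosage preserved: het stays het, hom REF maps to hom REF(B)
  expect_equal(unname(out$geno[1, ]), c(0L, 1L, 2L, NA))
  # base multiset check via harmonization: A-side {0,1} = {A,G} -> {C,T}
  expect_identical(harmonize_genotype(c(0, 1), "A", "G", "-"),
                   sort(c("T", "C")[c(1, 2)]))
  # sites not in the set are dropped and counted
  tab2 <- make_table(pos1 = c(10, 20), ref = "A", alt = "G",
                     geno = matrix(1L, 2, 1), version = "A")
  out2 <- liftover_vcf(tab2, rel, from = "a")
  expect_equal(n_sites(out2), 1L)
  expect_equal(attr(out2, "dropped")[["not_in_reliable"]], 1L)
})

test_that("liftover A->B->A restores retained sites exactly (simulated)", {
  sc <- tiny_scenario()
  pipe <- tiny_pipeline()
  rel <- pipe$reliable
  lifted <- liftover_vcf(sc$table_a, rel, from = "a", target_version = "B")
  back <- liftover_vcf(lifted, rel, from = "b", target_version = "A")
  keys <- paste(back$sites$contig, back$sites$pos1)
  orig_keys <- paste(sc$table_a$sites$contig, sc$table_a$sites$pos1)
  m <- match(keys, orig_keys)
  expect_false(anyNA(m))
  expect_equal(n_sites(back), nrow(rel))
  expect_equal(back$sites, sc$table_a$sites[m, , drop = FALSE],
               ignore_attr = TRUE)
  expect_identical(unname(back$geno), unname(sc$table_a$geno[m, ,
                                                             drop = FALSE]))
})

test_that("liftover preserves each sample's base multiset at every site", {
  sc <- tiny_scenario()
  rel <- tiny_pipeline()$reliable
  lifted <- liftover_vcf(sc$table_a, rel, from = "a", target_version = "B")
  key_b <- paste(rel$contig_b, rel$pos1_b)
  for (i in seq_len(min(25, n_sites(lifted)))) {
    j <- match(paste(lifted$sites$contig[i], lifted$sites$pos1[i]), key_b)
    pair <- rel[j, ]
    orig_row <- match(paste(pair$contig_a, pair$pos1_a),
                      paste(sc$table_a$sites$contig, sc$table_a$sites$pos1))
    for (smp in c(1L, 7L)) {
      d0 <- sc$table_a$geno[orig_row, smp]
      d1 <- lifted$geno[i, smp]
      if (is.na(d0)) { expect_true(is.na(d1)); next }
      gt0 <- c(rep(0L, 2 - d0), rep(1L, d0))
      gt1 <- c(rep(0L, 2 - d1), rep(1L, d1))
      h0 <- harmonize_genotype(gt0, pair$ref_a, pair$alt_a, pair$strand)
      h1 <- harmonize_genotype(gt1, lifted$sites$ref[i],
                               lifted$sites$alt[i], "+")
      expect_identical(h0, h1)
    }
  }
})

test_that("merging identical panels gives rate 1 everywhere", {
  tab <- tiny_scenario()$table_a
  tab_b <- variant_table(tab$sites, tab$geno, tab$samples, version = "P2")
  merged <- merge_callsets(tab, tab_b, lift_params())
  rates <- attr(merged, "match_rates")
  expect_true(all(rates$rate == 1, na.rm = TRUE))
  expect_equal(length(merged$samples), 2 * length(tab$samples))
  expect_true(all(grepl("\\.", merged$samples)))
  # missing fractions after merge are all within the cap
  expect_true(all(rowSums(is.na(merged$geno)) / ncol(merged$geno) <= 0.05))
})

test_that("merge missingness threshold keeps <= 5% and excludes above", {
  # 40 merged columns; 3 missing -> 0.075 > 0.05 excluded; 2 -> 0.05 kept
  g1 <- matrix(0L, 2, 20); g2 <- matrix(0L, 2, 20)
  g1[1, 1:2] <- NA            # site 1: 2/40 = 0.05 kept
  g1[2, 1:2] <- NA; g2[2, 1] <- NA  # site 2: 3/40 = 0.075 excluded
  t1 <- make_table(pos1 = c(10, 20), geno = g1,
                   samples = paste0("x", 1:20), version = "P1")
  t2 <- make_table(pos1 = c(10, 20), geno = g2,
                   samples = paste0("y", 1:20), version = "P2")
  merged <- merge_callsets(t1, t2, lift_params())
  expect_equal(merged$sites$pos1, 10L)
  expect_equal(attr(merged, "dropped_sites")[["too_missing"]], 1L)
  expect_error(merge_callsets(t1, make_table(pos1 = c(99, 100), geno = g2,
                                             samples = paste0("y", 1:20),
                                             version = "P2")),
               "no shared")
})

test_that("planted cross-panel discordance is recovered in match rates", {
  set.seed(111)
  n <- 60; ns <- 40
  g <- matrix(sample(0:2, n * ns, replace = TRUE), n, ns)
  gb <- g
  bad <- 1:20                     # first 20 sites: 10% per-sample flips
  flip <- matrix(stats::runif(20 * ns) < 0.10, 20, ns)
  sub <- gb[bad, ]
  sub[flip] <- (sub[flip] + 1L) %% 3L
  gb[bad, ] <- sub
  t1 <- make_table(pos1 = seq_len(n) * 5, geno = g,
                   samples = paste0("s", 1:ns), version = "P1")
  t2 <- make_table(pos1 = seq_len(n) * 5, geno = gb,
                   samples = paste0("s", 1:ns), version = "P2")
  merged <- merge_callsets(t1, t2, lift_params())
  rates <- attr(merged, "match_rates")
  # per-site recount oracle
  brute <- rowSums(g == gb) / ns
  expect_equal(rates$rate, brute)
  expect_equal(stats::median(rates$rate[bad]),
               stats::median(brute[bad]))
  expect_gte(stats::median(rates$rate[bad]), 0.80)
  expect_lte(stats::median(rates$rate[bad]), 0.975)
  expect_true(all(rates$rate[-bad] == 1))
})
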