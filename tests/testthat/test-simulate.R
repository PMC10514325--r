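test_that("reference simulation is deterministic and roughly uniform", {
  a1 <- simulate_reference(c(100), seed = 7)
  a2 <- simulate_reference(c(100), seed = 7)
  expect_identical(a1$contigs, a2$contigs)
  a3 <- simulate_reference(c(100), seed = 8)
  expect_false(identical(a1$contigs, a3$contigs))
  expect_equal(length(simulate_reference(integer(0))$contigs), 0L)
  big <- simulate_reference(c(100000), seed = 9)
  comp <- table(strsplit(big$contigs[[1]], "")[[1]]) / 100000
  expect_true(all(abs(comp - 0.25) < 0.01))
})

test_that("an empty edit spec derives an identical assembly", {
  ref <- simulate_reference(c(5000, 3000), seed = 17)
  der <- derive_assembly(ref, edit_spec(sub_rate = 0, n_indels = 0,
                                        n_inversions = 0,
                                        n_duplications = 0,
                                        n_translocations = 0, n_ngaps = 0),
                         seed = 18)
  expect_identical(der$assembly$contigs, setNames(ref$contigs,
                                                  names(ref$contigs)))
  seg <- der$truth$segments
  expect_equal(nrow(seg), 2L)
  expect_true(all(seg$strand == "+"))
  expect_equal(seg$a_start0, c(0L, 0L))
  expect_equal(seg$a_end0, unname(contig_lengths(ref)))
  expect_equal(nrow(der$truth$substitutions), 0L)
})

test_that("a planted inversion maps with strand minus and correct arithmetic", {
  ref <- simulate_reference(c(4000), seed = 19)
  # force a single inversion by constructing blocks through the edit spec:
  # keep drawing until the one inversion is the only event
  der <- derive_assembly(ref, edit_spec(sub_rate = 0, n_indels = 0,
                                        n_inversions = 1,
                                        inv_len = c(500, 500),
                                        n_duplications = 0,
                                        n_translocations = 0, n_ngaps = 0),
                         seed = 20)
  seg <- der$truth$segments
  inv <- seg[seg$strand == "-", ]
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$a_end0 - inv$a_start0, 500L)
  # sequence check: B interval is the reverse complement of the A interval
  a_piece <- substr(ref$contigs[[inv$contig_a]], inv$a_start0 + 1,
                    inv$a_end0)
  b_piece <- substr(der$assembly$contigs[[inv$contig_b]],
                    inv$b_start0 + 1, inv$b_end0)
  expect_identical(b_piece, revcomp(a_piece))
  # coordinate formula b = b_start0 + (a_end0 - 1 - a) at both ends
  pr <- truth_project(der$truth, rep(inv$contig_a, 2),
                      c(inv$a_start0, inv$a_end0 - 1L))
  expect_equal(pr$b_pos0, c(inv$b_end0 - 1L, inv$b_start0))
  expect_true(all(pr$strand == "-"))
})

test_that("truth projection agrees with direct sequence lookup", {
  sc <- tiny_scenario()
  set.seed(23)
  ct <- sample(names(sc$ref_a$contigs), 300, replace = TRUE)
  pos0 <- vapply(ct, function(c.)
    sample.int(nchar(sc$ref_a$contigs[[c.]]), 1) - 1L, integer(1))
  pr <- truth_project(sc$truth, ct, pos0)
  mapped <- !is.na(pr$b_pos0) & !pr$mismatch & !pr$ambiguous
  a_base <- substr(sc$ref_a$contigs[ct], pos0 + 1, pos0 + 1)
  b_base <- rep(NA_character_, length(pos0))
  b_base[mapped] <- substr(sc$ref_b$contigs[pr$contig_b[mapped]],
                           pr$b_pos0[mapped] + 1, pr$b_pos0[mapped] + 1)
  expected <- ifelse(pr$strand == "-", complement_bases(a_base), a_base)
  expect_identical(b_base[mapped], unname(expected[mapped]))
  # substituted positions differ between the assemblies
  subs <- sc$truth$substitutions
  if (nrow(subs)) {
    pr_s <- truth_project(sc$truth, subs$contig, subs$pos0)
    expect_true(all(pr_s$mismatch))
    sa <- substr(sc$ref_a$contigs[subs$contig], subs$pos0 + 1, subs$pos0 + 1)
    sb <- substr(sc$ref_b$contigs[pr_s$contig_b], pr_s$b_pos0 + 1,
                 pr_s$b_pos0 + 1)
    expect_true(all(sa != sb))
  }
})

test_that("panel simulation is deterministic and truth-consistent", {
  sc <- tiny_scenario()
  sp <- panel_spec(n_samples = 20, n_snps = 100, flank = 100, seed = 13)
  again <- simulate_panels(sc$ref_a, sc$ref_b, sc$truth, sp)
  expect_identical(again$table_a$sites, sc$table_a$sites)
  expect_identical(again$table_a$geno, sc$table_a$geno)
  expect_identical(again$truth_sites, sc$truth_sites)
  # B-side alleles are the (possibly complemented) A-side alleles
  ts <- sc$truth_sites
  key_a <- paste(sc$table_a$sites$contig, sc$table_a$sites$pos1)
  key_b <- paste(sc$table_b$sites$contig, sc$table_b$sites$pos1)
  ia <- match(paste(ts$contig_a, ts$pos1_a), key_a)
  ib <- match(paste(ts$contig_b, ts$pos1_b), key_b)
  expect_false(anyNA(ia) || anyNA(ib))
  ref_a <- sc$table_a$sites$ref[ia]
  ref_b <- sc$table_b$sites$ref[ib]
  flip <- ts$strand == "-"
  expect_identical(ref_b[!flip], ref_a[!flip])
  expect_identical(ref_b[flip], complement_bases(ref_a[flip]))
})

test_that("a zero-error simulation reconciles with every rate at 1", {
  ref_a <- simulate_reference(c(30000), seed = 25, version = "A")
  der <- derive_assembly(ref_a, edit_spec(sub_rate = 0, n_indels = 2,
                                          n_inversions = 1,
                                          inv_len = c(400, 900),
                                          n_duplications = 0,
                                          n_translocations = 0,
                                          n_ngaps = 0),
                         seed = 26, version = "B")
  sp <- panel_spec(n_samples = 15, n_snps = 60, missing_rate = 0,
                   error_rate = 0, discordant_fraction = 0,
                   low_quality_fraction = 0, unmapped_fraction = 0,
                   multi_fraction = 0, flank = 80, seed = 27)
  pan <- simulate_panels(ref_a, der$assembly, der$truth, sp)
  res <- run_reconciliation(ref_a, der$assembly, pan$table_a, pan$table_b,
                            params = lift_params(flank = 80))
  expect_true(all(res$concordance$rate == 1))
  ev <- evaluate_recovery(res$reliable, pan$truth_sites)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
})

test_that("evaluate_recovery scores a hand-built case and rejects empty truth", {
  truth <- data.frame(site_id = c("s1", "s2", "s3"),
                      contig_a = "c1", pos1_a = c(10L, 20L, 30L),
                      contig_b = "c1", pos1_b = c(10L, 20L, 30L),
                      strand = "+",
                      label = c("TRANSFERABLE_CONCORDANT",
                                "TRANSFERABLE_CONCORDANT",
                                "EXPECT_MULTI"),
                      low_quality = FALSE, stringsAsFactors = FALSE)
  rel <- data.frame(contig_a = "c1", pos1_a = c(10L, 30L))
  ev <- evaluate_recovery(rel, truth)
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 0.5)
  expect_equal(unname(ev$confusion["EXPECT_MULTI", "kept"]), 1)
  expect_error(evaluate_recovery(rel, truth[0, ]), "empty truth")
})
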