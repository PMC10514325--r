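#' Run the full cross-assembly reconciliation
#'
#' Convenience driver chaining every stage: the calling-stage variant
#' filter on both callsets, flank extraction from each assembly, exact
#' both-strand remapping of each flank set against the other assembly,
#' reciprocal pairing, panel-wide genotype concordance, and reliable-set
#' selection.
#'
#' @param ref_a,ref_b The two `reference_assembly` versions.
#' @param table_a,table_b The matching `variant_table` callsets.
#' @param params A [lift_params()].
#' @param filter Apply [filter_variants()] to both callsets first.
#' @param index_k Seed length for the k-mer indexes.
#' @return List of class `reconciliation`: `table_a`, `table_b` (as
#'   used downstream), `flanks_a`, `flanks_b`, `maps_ab`, `maps_ba`,
#'   `pairs`, `concordance`, `reliable`, `params`.
#' @export
run_reconciliation <- function(ref_a, ref_b, table_a, table_b,
                               params = lift_params(), filter = TRUE,
                               index_k = 31L) {
  if (filter) {
    table_a <- filter_variants(table_a, params)
    table_b <- filter_variants(table_b, params)
  }
  flanks_a <- extract_flanks(ref_a, table_a, params$flank)
  flanks_b <- extract_flanks(ref_b, table_b, params$flank)
  idx_a <- build_index(ref_a, k = index_k)
  idx_b <- build_index(ref_b, k = index_k)
  maps_ab <- map_flanks(flanks_a, idx_b, ref_b)
  maps_ba <- map_flanks(flanks_b, idx_a, ref_a)
  pairs <- pair_snps(maps_ab, maps_ba, table_a, table_b)
  conc <- genotype_concordance(pairs, table_a, table_b, params = params)
  reliable <- select_reliable(conc, params)
  structure(list(table_a = table_a, table_b = table_b,
                 flanks_a = flanks_a, flanks_b = flanks_b,
                 maps_ab = maps_ab, maps_ba = maps_ba, pairs = pairs,
                 concordance = conc, reliable = reliable,
                 params = params),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  sm <- function(m) attr(m, "summary")
  cat("<reconciliation>\n")
  cat(sprintf("  callset A: %d site(s); callset B: %d site(s)\n",
              n_sites(x$table_a), n_sites(x$table_b)))
  cat(sprintf("  flanks A: %d (+%d skipped); flanks B: %d (+%d skipped)\n",
              nrow(x$flanks_a), nrow(attr(x$flanks_a, "skips")),
              nrow(x$flanks_b), nrow(attr(x$flanks_b, "skips"))))
  cat(sprintf("  A->B mapped %.2f%% unique, %.2f%% unmapped, %.3f%% multi\n",
              100 * sm(x$maps_ab)[["unique"]],
              100 * sm(x$maps_ab)[["unmapped"]],
              100 * sm(x$maps_ab)[["multi"]]))
  cat(sprintf("  B->A mapped %.2f%% unique, %.2f%% unmapped, %.3f%% multi\n",
              100 * sm(x$maps_ba)[["unique"]],
              100 * sm(x$maps_ba)[["unmapped"]],
              100 * sm(x$maps_ba)[["multi"]]))
  cat(sprintf("  mutually confirmed pairs: %d\n", nrow(x$pairs)))
  conc_def <- sum(!is.na(x$concordance$rate))
  cat(sprintf("  reliable (rate >= %.2f): %d of %d with defined rates (%.1f%%)\n",
              x$params$concordance_threshold, nrow(x$reliable), conc_def,
              if (conc_def > 0) 100 * nrow(x$reliable) / conc_def else NA))
  invisible(x)
}

#' Build the package's default simulated scenario
#'
#' Generates the desk-scale study system used throughout the tests and
#' the worked examples: two 500-kb contigs, a derived second assembly
#' under the default [edit_spec()], and matched 60-sample, 2000-site
#' panels under the default [panel_spec()].
#'
#' @param seed Integer master seed; the stage seeds are derived from it.
#' @param n_contigs,contig_length Genome shape.
#' @param spec A [panel_spec()]; its seed is overridden by `seed`.
#' @param edits An [edit_spec()].
#' @param params A [lift_params()] used for labeling arithmetic.
#' @return List: `ref_a`, `ref_b`, `truth`, `table_a`, `table_b`,
#'   `truth_sites`, `seed`.
#' @export
default_scenario <- function(seed = 1L, n_contigs = 2L,
                             contig_length = 500000L,
                             spec = panel_spec(), edits = edit_spec(),
                             params = lift_params()) {
  seed <- as.integer(seed)
  ref_a <- simulate_reference(rep(contig_length, n_contigs),
                              seed = seed, version = "simA")
  der <- derive_assembly(ref_a, edits = edits, seed = seed + 1000L,
                         version = "simB")
  spec$seed <- seed + 2000L
  panels <- simulate_panels(ref_a, der$assembly, der$truth, spec = spec,
                            params = params)
  c(list(ref_a = ref_a, ref_b = der$assembly, truth = der$truth,
         seed = seed), panels)
}
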