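#' Lift a callset across assembly versions via the reliable set
#'
#' Re-emits every input site found in the reliable set at its partner
#' coordinates with the partner's REF/ALT. When the pair's strand relation
#' is flipped the alleles are complemented, and genotype allele indices
#' are re-encoded so each sample's base multiset is preserved (when REF
#' and ALT swap roles, dosages map `d -> 2 - d`). Sites absent from the
#' reliable set, or whose alleles disagree with it, are dropped and
#' counted. The output is sorted by (contig, position); lifting back
#' restores the retained sites exactly.
#'
#' @param table `variant_table` in the coordinates of the reliable set's
#'   `from` side.
#' @param reliable A `reliable_set`.
#' @param from `"a"` or `"b"`: which side of the reliable set the input is
#'   in; the output is in the other side's coordinates.
#' @param target_version Version tag for the output table.
#' @return A `variant_table` with attribute `dropped` (named counts:
#'   `not_in_reliable`, `allele_mismatch`).
#' @export
liftover_vcf <- function(table, reliable, from = c("a", "b"),
                         target_version = NULL) {
  from <- match.arg(from)
  to <- if (from == "a") "b" else "a"
  rel <- as.data.frame(reliable)
  pick <- function(side, col) rel[[paste0(col, "_", side)]]
  key_rel <- paste(pick(from, "contig"), pick(from, "pos1"))
  if (anyDuplicated(key_rel))
    stop("duplicate ", from, "-side coordinates in the reliable set")
  s <- table$sites
  idx <- match(paste(s$contig, s$pos1), key_rel)
  in_rel <- !is.na(idx)
  src_ref <- pick(from, "ref")[idx]
  src_alt <- pick(from, "alt")[idx]
  allele_ok <- in_rel &
    ((s$ref == src_ref & s$alt == src_alt) |
     (s$ref == src_alt & s$alt == src_ref))
  keep <- which(allele_ok)
  dropped <- c(not_in_reliable = sum(!in_rel),
               allele_mismatch = sum(in_rel & !allele_ok))
  j <- idx[keep]
  flipped <- rel$strand[j] == "-"
  ref_out <- pick(to, "ref")[j]
  alt_out <- pick(to, "alt")[j]
  # strand-adjusted input ALT; equality with the partner ALT decides
  # whether dosages carry over or reflect (REF/ALT role swap)
  alt_adj <- ifelse(flipped, complement_bases(s$alt[keep]), s$alt[keep])
  same_role <- alt_adj == alt_out
  geno <- table$geno[keep, , drop = FALSE]
  if (any(!same_role))
    geno[!same_role, ] <- 2L - geno[!same_role, , drop = FALSE]
  if (is.null(target_version))
    target_version <- paste0(table$version, "_lifted_", to)
  out <- variant_table(
    sites = data.frame(contig = pick(to, "contig")[j],
                       pos1 = pick(to, "pos1")[j],
                       ref = ref_out, alt = alt_out,
                       qual = s$qual[keep], mq = s$mq[keep],
                       stringsAsFactors = FALSE),
    geno = geno, samples = table$samples, version = target_version)
  attr(out, "dropped") <- dropped
  out
}

#' Consolidate two callsets into one genotype matrix
#'
#' Both inputs must be in the same assembly's coordinates (one of them
#' typically produced by [liftover_vcf()]). Sites are intersected by
#' (contig, position) with equal unordered allele sets — collisions with
#' discordant alleles are dropped with a reason — and samples are the
#' union of the two panels; accessions present in both are kept as two
#' panel-tagged columns (or de-duplicated, preferring the panel with
#' fewer missing calls, when `dedupe = TRUE`). Sites whose merged missing
#' fraction exceeds `merge_max_missing` are excluded (kept when `<=`,
#' unlike the strict calling-stage filter). For accessions shared by
#' name, per-site cross-panel genotype match rates are computed over
#' samples informative in both panels.
#'
#' @param native_b `variant_table` called directly against the target
#'   assembly.
#' @param lifted_a `variant_table` lifted into the same coordinates.
#' @param params A [lift_params()] (`merge_max_missing`).
#' @param dedupe Collapse shared accessions to a single column.
#' @return A `variant_table` over the merged panel, with attributes
#'   `match_rates` (`data.frame`: `contig`, `pos1`, `n_shared`, `rate`),
#'   `dropped_sites` (named counts), and `panel_tags`.
#' @export
merge_callsets <- function(native_b, lifted_a, params = lift_params(),
                           dedupe = FALSE) {
  sb <- native_b$sites; sa <- lifted_a$sites
  key_b <- paste(sb$contig, sb$pos1)
  key_a <- paste(sa$contig, sa$pos1)
  ia <- match(key_b, key_a)
  common <- which(!is.na(ia))
  if (length(common) == 0L)
    stop(sprintf(paste0("merge_callsets: no shared (contig, position) ",
                        "between the callsets (%d vs %d sites); are both ",
                        "in the same assembly's coordinates?"),
                 nrow(sb), nrow(sa)))
  ja <- ia[common]
  same_alleles <- (sb$ref[common] == sa$ref[ja] &
                   sb$alt[common] == sa$alt[ja]) |
                  (sb$ref[common] == sa$alt[ja] &
                   sb$alt[common] == sa$ref[ja])
  allele_drop <- sum(!same_alleles)
  common <- common[same_alleles]; ja <- ja[same_alleles]
  swapped <- sb$ref[common] == sa$alt[ja]

  gb <- native_b$geno[common, , drop = FALSE]
  ga <- lifted_a$geno[ja, , drop = FALSE]
  if (any(swapped))
    ga[swapped, ] <- 2L - ga[swapped, , drop = FALSE]

  tags <- c(native_b$version, lifted_a$version)
  if (tags[1] == tags[2]) tags <- paste0(tags, c("_1", "_2"))
  shared <- intersect(native_b$samples, lifted_a$samples)

  # cross-panel per-site match rates over the shared accessions
  rates <- data.frame(contig = character(0), pos1 = integer(0),
                      n_shared = integer(0), rate = numeric(0))
  if (length(shared)) {
    cb <- match(shared, native_b$samples)
    ca <- match(shared, lifted_a$samples)
    inf <- !is.na(gb[, cb, drop = FALSE]) & !is.na(ga[, ca, drop = FALSE])
    eq <- inf & (gb[, cb, drop = FALSE] == ga[, ca, drop = FALSE])
    n_inf <- rowSums(inf)
    rates <- data.frame(contig = sb$contig[common], pos1 = sb$pos1[common],
                        n_shared = n_inf,
                        rate = ifelse(n_inf > 0, rowSums(eq) / n_inf,
                                      NA_real_),
                        stringsAsFactors = FALSE)
  }

  if (dedupe && length(shared)) {
    miss_b <- colSums(is.na(gb[, match(shared, native_b$samples),
                               drop = FALSE]))
    miss_a <- colSums(is.na(ga[, match(shared, lifted_a$samples),
                               drop = FALSE]))
    use_b <- miss_b <= miss_a
    keep_a_cols <- !(lifted_a$samples %in% shared[use_b])
    keep_b_cols <- !(native_b$samples %in% shared[!use_b])
    geno <- cbind(gb[, keep_b_cols, drop = FALSE],
                  ga[, keep_a_cols, drop = FALSE])
    samples <- c(native_b$samples[keep_b_cols],
                 lifted_a$samples[keep_a_cols])
  } else {
    name_b <- ifelse(native_b$samples %in% shared,
                     paste0(native_b$samples, ".", tags[1]),
                     native_b$samples)
    name_a <- ifelse(lifted_a$samples %in% shared,
                     paste0(lifted_a$samples, ".", tags[2]),
                     lifted_a$samples)
    geno <- cbind(gb, ga)
    samples <- c(name_b, name_a)
  }

  miss_frac <- rowSums(is.na(geno)) / ncol(geno)
  keep_site <- miss_frac <= params$merge_max_missing
  miss_drop <- sum(!keep_site)

  out <- variant_table(
    sites = data.frame(contig = sb$contig[common], pos1 = sb$pos1[common],
                       ref = sb$ref[common], alt = sb$alt[common],
                       qual = sb$qual[common], mq = sb$mq[common],
                       stringsAsFactors = FALSE)[keep_site, , drop = FALSE],
    geno = geno[keep_site, , drop = FALSE],
    samples = samples, version = native_b$version)
  attr(out, "match_rates") <- rates
  attr(out, "dropped_sites") <- c(allele_mismatch = allele_drop,
                                  too_missing = miss_drop)
  attr(out, "panel_tags") <- tags
  out
}

#' Write a genotype dosage matrix as TSV
#'
#' Sites-by-samples table of alternate-allele dosages (0/1/2, `NA`
#' missing), with `contig`, `pos1`, `ref`, `alt` as leading columns.
#'
#' @param table A `variant_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotype_matrix <- function(table, path) {
  df <- cbind(table$sites[c("contig", "pos1", "ref", "alt")],
              as.data.frame(table$geno))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
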