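#' Reciprocally confirm SNP pairs across two assemblies
#'
#' A SNP called in version A is paired with a SNP called in version B when
#' the A probe maps uniquely to exactly the B site's coordinate, the B
#' probe maps uniquely back to the A site's coordinate, the two strand
#' calls agree, and the strand-adjusted allele sets are equal. Candidates
#' failing any clause are excluded with a reason code (`TARGET_SITE_ABSENT`,
#' `NOT_RECIPROCAL`, `STRAND_CONFLICT`, `ALLELE_MISMATCH`); probes that
#' never mapped uniquely are not candidates and are accounted for by the
#' map-result summaries.
#'
#' @param maps_ab `map_result` of A probes against assembly B.
#' @param maps_ba `map_result` of B probes against assembly A.
#' @param table_a,table_b The two `variant_table`s.
#' @return `data.frame` of class `paired_snps`: `snp_id` (the A-side id),
#'   `contig_a`, `pos1_a`, `ref_a`, `alt_a`, `contig_b`, `pos1_b`,
#'   `ref_b`, `alt_b`, `strand` (`"+"` same orientation, `"-"` flipped);
#'   attribute `exclusions` (`snp_id`, `reason`).
#' @export
pair_snps <- function(maps_ab, maps_ba, table_a, table_b) {
  sa <- table_a$sites; sb <- table_b$sites
  key_a <- paste(sa$contig, sa$pos1)
  key_b <- paste(sb$contig, sb$pos1)
  if (anyDuplicated(key_a) || anyDuplicated(key_b))
    stop("duplicate (contig, position) keys within a table")
  id_a <- paste(table_a$version, sa$contig, sa$pos1, sa$ref, sa$alt, sep = "|")
  id_b <- paste(table_b$version, sb$contig, sb$pos1, sb$ref, sb$alt, sep = "|")

  ab <- as.data.frame(maps_ab)
  ba <- as.data.frame(maps_ba)
  ab_u <- ab[ab$status == "UNIQUE", , drop = FALSE]
  # index of A-site / B-site rows by snp_id and by coordinate key
  a_by_id <- match(ab_u$snp_id, id_a)
  if (anyNA(a_by_id))
    stop("map result names a SNP absent from table A")
  b_site <- match(paste(ab_u$contig, ab_u$pos1), key_b)

  n <- nrow(ab_u)
  reason <- character(n)
  for (i in seq_len(n)) {
    j <- b_site[i]
    if (is.na(j)) { reason[i] <- "TARGET_SITE_ABSENT"; next }
    k <- match(id_b[j], ba$snp_id)
    if (is.na(k)) { reason[i] <- "NOT_RECIPROCAL"; next }
    back <- ba[k, ]
    ai <- a_by_id[i]
    if (back$status != "UNIQUE" ||
        !identical(back$contig, sa$contig[ai]) ||
        back$pos1 != sa$pos1[ai]) { reason[i] <- "NOT_RECIPROCAL"; next }
    if (!identical(back$strand, ab_u$strand[i])) {
      reason[i] <- "STRAND_CONFLICT"; next
    }
    ra <- sa$ref[ai]; aa <- sa$alt[ai]
    if (ab_u$strand[i] == "-") {
      ra <- complement_bases(ra); aa <- complement_bases(aa)
    }
    if (!setequal(c(ra, aa), c(sb$ref[j], sb$alt[j])))
      reason[i] <- "ALLELE_MISMATCH"
  }
  keep <- reason == ""
  ai <- a_by_id[keep]; bi <- b_site[keep]
  out <- data.frame(snp_id = ab_u$snp_id[keep],
                    contig_a = sa$contig[ai], pos1_a = sa$pos1[ai],
                    ref_a = sa$ref[ai], alt_a = sa$alt[ai],
                    contig_b = sb$contig[bi], pos1_b = sb$pos1[bi],
                    ref_b = sb$ref[bi], alt_b = sb$alt[bi],
                    strand = ab_u$strand[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exclusions") <- data.frame(snp_id = ab_u$snp_id[!keep],
                                        reason = reason[!keep],
                                        stringsAsFactors = FALSE)
  class(out) <- c("paired_snps", "data.frame")
  out
}

#' Harmonize one genotype call to an orientation-free base multiset
#'
#' Replaces allele indices by their bases from the site's (REF, ALT) and,
#' when the pair's strand relation is flipped, complements each base. The
#' result is an unordered base pair, comparable across assemblies
#' regardless of the strand a region happens to be represented on.
#'
#' @param gt Integer vector of length 2: allele indices, each 0 or 1.
#' @param ref,alt The site's REF and ALT bases.
#' @param strand `"+"` (same orientation) or `"-"` (flipped).
#' @return Character vector of two bases, sorted.
#' @examples
#' harmonize_genotype(c(0, 1), "A", "G", "+")  # "A" "G"
#' harmonize_genotype(c(0, 1), "A", "G", "-")  # "C" "T"
#' @export
harmonize_genotype <- function(gt, ref, alt, strand = "+") {
  if (length(gt) != 2L || any(!gt %in% c(0L, 1L)))
    stop("gt must be two allele indices from {0, 1}")
  bases <- c(ref, alt)[gt + 1L]
  if (strand == "-") bases <- complement_bases(bases)
  sort(bases)
}

#' Panel-wide genotype concordance of paired SNPs
#'
#' For every paired SNP, compares the harmonized diploid calls of the two
#' callsets across the shared sample panel. A sample is informative when
#' both callsets have a non-missing call; it matches when the two
#' harmonized base multisets are equal (strand complementation is applied
#' to the B side once — sufficient, since the comparison is
#' orientation-free). The rate is `n_match / n_informative`, undefined
#' (`NA`) below `min_informative`. `denominator = "all_shared"` gives the
#' fixed-denominator reading in which missing-in-either samples count
#' against the rate.
#'
#' @param pairs A `paired_snps` table.
#' @param table_a,table_b The two `variant_table`s.
#' @param samples Shared sample names; defaults to the intersection.
#' @param params A [lift_params()].
#' @param denominator `"informative"` (default) or `"all_shared"`.
#' @return `data.frame` of class `concordance_result`: the pair columns
#'   plus `n_informative`, `n_match`, `rate`.
#' @export
genotype_concordance <- function(pairs, table_a, table_b,
                                 samples = intersect(table_a$samples,
                                                     table_b$samples),
                                 params = lift_params(),
                                 denominator = c("informative",
                                                 "all_shared")) {
  denominator <- match.arg(denominator)
  if (length(samples) == 0L)
    stop("no shared samples between the two callsets")
  ia <- match(samples, table_a$samples)
  ib <- match(samples, table_b$samples)
  if (anyNA(ia) || anyNA(ib))
    stop("sample(s) absent from one of the callsets")
  key_a <- paste(table_a$sites$contig, table_a$sites$pos1)
  key_b <- paste(table_b$sites$contig, table_b$sites$pos1)
  ra <- match(paste(pairs$contig_a, pairs$pos1_a), key_a)
  rb <- match(paste(pairs$contig_b, pairs$pos1_b), key_b)
  if (anyNA(ra) || anyNA(rb))
    stop("paired site absent from its callset")
  ga <- table_a$geno[ra, ia, drop = FALSE]
  gb <- table_b$geno[rb, ib, drop = FALSE]
  # Orientation of the allele correspondence: does (strand-adjusted) REF_A
  # line up with REF_B, or with ALT_B? Exact flank matching normally forces
  # the former; the latter is handled for generality.
  adj_ref <- ifelse(pairs$strand == "-", complement_bases(pairs$ref_a),
                    pairs$ref_a)
  aligned <- adj_ref == pairs$ref_b
  swapped <- adj_ref == pairs$alt_b
  if (any(!aligned & !swapped))
    stop("pair with inconsistent allele correspondence")
  gb_h <- gb
  if (any(swapped))
    gb_h[swapped, ] <- 2L - gb[swapped, , drop = FALSE]
  inf <- !is.na(ga) & !is.na(gb_h)
  match_m <- inf & (ga == gb_h)
  n_inf <- rowSums(inf)
  n_match <- rowSums(match_m)
  denom <- if (denominator == "informative") n_inf
           else rep(length(samples), nrow(pairs))
  rate <- ifelse(n_inf >= params$min_informative & denom > 0,
                 n_match / denom, NA_real_)
  out <- cbind(as.data.frame(pairs),
               data.frame(n_informative = n_inf, n_match = n_match,
                          rate = rate))
  rownames(out) <- NULL
  class(out) <- c("concordance_result", "data.frame")
  out
}

#' Select the reliable SNP set
#'
#' Keeps paired SNPs whose defined concordance rate is at or above the
#' threshold (inclusive). Attaches a rate histogram and a four-way tally
#' by strand and threshold side as attributes, mirroring the usual
#' reporting of forward/reverse-complement concordant/discordant classes.
#'
#' @param results A `concordance_result`.
#' @param params A [lift_params()] (`concordance_threshold`).
#' @return The kept subset, class `reliable_set`, with attributes
#'   `histogram` (counts over rate bins of width 0.05) and `tally`
#'   (strand x concordance-class counts, including undefined rates).
#' @examples
#' # rates 1.00, 0.95, 0.90, 0.89 at the default 0.90 threshold: 3 kept
#' @export
select_reliable <- function(results, params = lift_params()) {
  thr <- params$concordance_threshold
  defined <- !is.na(results$rate)
  keep <- defined & results$rate >= thr
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  breaks <- seq(0, 1, by = 0.05)
  h <- if (any(defined))
    table(cut(results$rate[defined], breaks = breaks,
              include.lowest = TRUE, right = FALSE,
              labels = sprintf("[%.2f,%.2f)", breaks[-length(breaks)],
                               breaks[-1])))
  else table(factor(character(0)))
  cls <- ifelse(!defined, "undefined",
                ifelse(results$rate >= thr, "concordant", "discordant"))
  tal <- table(strand = factor(results$strand, levels = c("+", "-")),
               class = factor(cls, levels = c("concordant", "discordant",
                                              "undefined")))
  attr(out, "histogram") <- h
  attr(out, "tally") <- tal
  attr(out, "threshold") <- thr
  class(out) <- c("reliable_set", class(results))
  out
}

#' Write / read the reliable-set table
#'
#' TSV with columns `snp_id, contig_a, pos1_a, ref_a, alt_a, contig_b,
#' pos1_b, ref_b, alt_b, strand, n_informative, n_match, rate` (rate to 6
#' decimal places). This file is the pipeline's durable product: the input
#' to [liftover_vcf()] and [merge_callsets()], and exportable as a minimal
#' known-sites VCF for base-quality recalibration.
#'
#' @param reliable A `reliable_set` (or `concordance_result`).
#' @param path File path.
#' @return `write_reliable`: invisibly, `path`. `read_reliable`: the table
#'   with class `reliable_set`.
#' @export
write_reliable <- function(reliable, path) {
  df <- as.data.frame(reliable)
  df$rate <- sprintf("%.6f", df$rate)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_reliable
#' @export
read_reliable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(snp_id = "character",
                                         contig_a = "character",
                                         contig_b = "character",
                                         strand = "character"),
                          stringsAsFactors = FALSE)
  class(df) <- c("reliable_set", "concordance_result", "data.frame")
  df
}

#' Export the reliable set as a known-sites VCF
#'
#' Writes a sample-free VCF of the reliable SNPs in either version's
#' coordinates, suitable as a known-sites input to base-quality
#' recalibration.
#'
#' @param reliable A `reliable_set`.
#' @param path Output path.
#' @param side `"a"` or `"b"`: which version's coordinates to emit.
#' @return Invisibly, `path`.
#' @export
reliable_to_vcf <- function(reliable, path, side = c("a", "b")) {
  side <- match.arg(side)
  df <- as.data.frame(reliable)
  cols <- paste0(c("contig_", "pos1_", "ref_", "alt_"), side)
  d <- df[cols]
  names(d) <- c("contig", "pos1", "ref", "alt")
  d <- d[order(d$contig, d$pos1), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=flanklift known-sites export",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t")), con)
  if (nrow(d))
    writeLines(paste(d$contig, d$pos1, ".", d$ref, d$alt, ".", ".", ".",
                     sep = "\t"), con)
  invisible(path)
}
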