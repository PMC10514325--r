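#' Pipeline parameters
#'
#' Collects every numeric setting of the reconciliation pipeline in one
#' object. Defaults follow the published protocol: 500 bp flanks (1001 bp
#' probes), strict post-calling thresholds QUAL > 30, MQ > 30, MAF > 0.02,
#' missing fraction < 0.05, an inclusive 90\% genotype-concordance
#' threshold, 3-mer signatures, and a merge-stage missingness cap of 5\%.
#'
#' @param flank Half-width of the flanking window in bp; the probe is
#'   `2 * flank + 1` bases with the SNP at its center.
#' @param min_qual Minimum variant QUAL (strict: retained sites have
#'   `qual > min_qual`).
#' @param min_mq Minimum site mapping quality, taken from INFO/MQ (strict).
#' @param min_maf Minimum minor allele frequency over non-missing allele
#'   calls (strict).
#' @param max_missing_call Maximum fraction of missing genotypes at the
#'   calling stage (strict: `missing < max_missing_call`).
#' @param concordance_threshold Minimum panel-wide genotype match rate for a
#'   paired SNP to be called reliable (inclusive: `rate >=` threshold).
#' @param min_informative Minimum number of samples informative in both
#'   callsets for a concordance rate to be defined.
#' @param kmer_k Word size for flank-composition signatures.
#' @param merge_max_missing Merge-stage missingness cap; sites with a merged
#'   missing fraction strictly above this are excluded (i.e. `<=` kept).
#' @param seed Integer seed recorded in outputs and used by any stochastic
#'   step.
#'
#' @return An object of class `lift_params` (a named list).
#' @examples
#' p <- lift_params()
#' p$flank
#' @export
lift_params <- function(flank = 500L, min_qual = 30, min_mq = 30,
                        min_maf = 0.02, max_missing_call = 0.05,
                        concordance_threshold = 0.90, min_informative = 1L,
                        kmer_k = 3L, merge_max_missing = 0.05,
                        seed = 1L) {
  flank <- as.integer(flank)
  stopifnot(length(flank) == 1L, !is.na(flank), flank >= 1L)
  for (r in list(min_maf, max_missing_call, concordance_threshold,
                 merge_max_missing)) {
    stopifnot(is.numeric(r), length(r) == 1L, r >= 0, r <= 1)
  }
  stopifnot(min_qual >= 0, min_mq >= 0, min_informative >= 1)
  structure(list(flank = flank, min_qual = min_qual, min_mq = min_mq,
                 min_maf = min_maf, max_missing_call = max_missing_call,
                 concordance_threshold = concordance_threshold,
                 min_informative = as.integer(min_informative),
                 kmer_k = as.integer(kmer_k),
                 merge_max_missing = merge_max_missing,
                 seed = as.integer(seed)),
            class = "lift_params")
}

#' @export
print.lift_params <- function(x, ...) {
  cat("flanklift parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
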