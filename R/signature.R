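#' Literal k-mer counts of a DNA string
#'
#' Counts overlapping windows on the given strand without canonicalization
#' ("TCG" and its complement are distinct features). Windows containing
#' `N` are skipped, so the counts total `length - k + 1` minus the number
#' of N-touching windows.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param k Word size (default 3), `1 <= k <= nchar(seq)`.
#' @return Named integer vector of length `4^k`, indexed by k-mer in
#'   lexicographic order.
#' @examples
#' kmer_counts("ACGT")[c("ACG", "CGT")]
#' @export
kmer_counts <- function(seq, k = 3L) {
  k <- as.integer(k)
  n <- nchar(seq)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k exceeds sequence length")
  if (grepl("[^ACGTN]", seq)) stop("illegal character in sequence")
  lex <- .all_kmers(k)
  starts <- seq_len(n - k + 1L)
  words <- substring(seq, starts, starts + k - 1L)
  words <- words[!grepl("N", words, fixed = TRUE)]
  counts <- table(factor(words, levels = lex))
  out <- as.integer(counts)
  names(out) <- lex
  out
}

.all_kmers <- function(k) {
  g <- do.call(expand.grid,
               c(rep(list(c("A", "C", "G", "T")), k),
                 stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  sort(do.call(paste0, g))
}

#' GC content of a DNA string
#'
#' `(#G + #C) / #non-N bases`; errors on an all-N sequence.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @return Fraction in `[0, 1]`.
#' @examples
#' gc_content("ACGT")  # 0.5
#' gc_content("NNGG")  # 1
#' @export
gc_content <- function(seq) {
  if (grepl("[^ACGTN]", seq)) stop("illegal character in sequence")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  non_n <- sum(ch != "N")
  if (non_n == 0L) stop("gc_content undefined for an all-N sequence")
  sum(ch %in% c("G", "C")) / non_n
}

#' Compose k-mer/GC signatures for a set of flanks
#'
#' Builds the per-SNP feature table used to contrast concordant and
#' discordant flank composition: one row per flank with its `4^k` literal
#' k-mer counts, GC content, and a group label derived from the
#' concordance rate (`CONCORDANT` at or above the threshold, `OTHER`
#' below).
#'
#' @param flanks A `flank_set`.
#' @param rates Named numeric vector of concordance rates, names matching
#'   `flanks$snp_id` (flanks without a defined rate are dropped).
#' @param params A [lift_params()] (`kmer_k`, `concordance_threshold`).
#' @return `data.frame` of class `kmer_signature`: `snp_id`, `group`,
#'   `gc`, then one column per k-mer.
#' @export
flank_signatures <- function(flanks, rates, params = lift_params()) {
  idx <- match(flanks$snp_id, names(rates))
  keep <- !is.na(idx) & !is.na(rates[idx])
  fl <- flanks[keep, , drop = FALSE]
  r <- rates[idx[keep]]
  k <- params$kmer_k
  lex <- .all_kmers(k)
  mat <- matrix(0L, nrow(fl), length(lex), dimnames = list(NULL, lex))
  gc <- numeric(nrow(fl))
  for (i in seq_len(nrow(fl))) {
    mat[i, ] <- kmer_counts(fl$seq[i], k)
    gc[i] <- gc_content(fl$seq[i])
  }
  out <- cbind(data.frame(snp_id = fl$snp_id,
                          group = ifelse(r >= params$concordance_threshold,
                                         "CONCORDANT", "OTHER"),
                          gc = gc, stringsAsFactors = FALSE),
               as.data.frame(mat, check.names = FALSE))
  class(out) <- c("kmer_signature", "data.frame")
  out
}

#' Per-feature Welch comparison of concordant vs other flanks
#'
#' For each k-mer count feature and for GC content, a Welch two-sample
#' t-test between the `CONCORDANT` and `OTHER` groups: Welch t statistic,
#' Welch-Satterthwaite degrees of freedom, two-sided p-value, group means,
#' and significance stars (`****` at p <= 1e-4, then `***` 1e-3, `**`
#' 1e-2, `*` 0.05). Degenerate features (both group variances zero) get
#' `t = 0, p = 1` when the means agree and are flagged `DEGENERATE` with
#' `p = 0` otherwise. An optional Bonferroni correction over the
#' `4^k + 1` features is available; the default reports raw p-values.
#'
#' @param signatures A `kmer_signature` table with both groups present
#'   (each of size >= 2: the variance is undefined below that).
#' @param bonferroni Multiply p-values by the number of features
#'   (capped at 1) before starring.
#' @return `data.frame` of class `signature_stats`: `feature`,
#'   `mean_concordant`, `mean_other`, `t`, `df`, `p`, `stars`.
#' @export
group_compare <- function(signatures, bonferroni = FALSE) {
  g <- signatures$group
  if (!all(c("CONCORDANT", "OTHER") %in% g))
    stop("both groups must be non-empty")
  if (sum(g == "CONCORDANT") < 2L || sum(g == "OTHER") < 2L)
    stop("each group needs >= 2 members for a variance")
  feats <- setdiff(names(signatures), c("snp_id", "group"))
  rows <- lapply(feats, function(f) {
    x <- signatures[[f]][g == "CONCORDANT"]
    y <- signatures[[f]][g == "OTHER"]
    cbind(data.frame(feature = f, mean_concordant = mean(x),
                     mean_other = mean(y), stringsAsFactors = FALSE),
          as.data.frame(welch_t(x, y)))
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p <- pmin(1, out$p * length(feats))
  out$stars <- ifelse(is.na(out$p), "",
               ifelse(out$p <= 1e-4, "****",
               ifelse(out$p <= 1e-3, "***",
               ifelse(out$p <= 1e-2, "**",
               ifelse(out$p <= 5e-2, "*", "ns")))))
  out$stars[out$degenerate & out$p == 0] <- "DEGENERATE"
  rownames(out) <- NULL
  class(out) <- c("signature_stats", "data.frame")
  out
}

#' Welch two-sample t-test with degenerate-case handling
#'
#' Thin wrapper around [stats::t.test()] (`var.equal = FALSE`) that also
#' defines the zero-variance corner `t.test()` refuses: when both sample
#' variances are zero, `t = 0, p = 1` if the means are equal, otherwise
#' the comparison is flagged degenerate with `p = 0` (an infinite-evidence
#' separation of two constants).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_t needs >= 2 observations per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = NA_real_, p = 1, degenerate = FALSE))
    return(list(t = NA_real_, df = NA_real_, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Write the signature statistics table
#' @param stats_table A `signature_stats`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_signature_stats <- function(stats_table, path) {
  df <- as.data.frame(stats_table)
  df$degenerate <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
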