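#' Extract symmetric flanking sequences around SNPs
#'
#' For each site in `table`, pulls the `2f + 1`-base window of its source
#' assembly centered on the SNP (default `f = 500`, i.e. 1001 bp probes).
#' A site is skipped, with a reason, when (a) fewer than `f` bases exist on
#' either side of it in its contig, (b) the window contains any `N`, or
#' (c) the assembly base at the site differs from the record's REF — the
#' last signals inconsistent inputs and is never silently ignored.
#'
#' @param assembly The `reference_assembly` the calls were made against;
#'   its version tag must match the table's.
#' @param table A `variant_table`.
#' @param f Flank half-width in bp (`>= 1`).
#' @return A `data.frame` of class `flank_set` with columns `snp_id`
#'   (`"version|contig|pos1|ref|alt"`), `contig`, `pos1`, `ref`, `alt`,
#'   `seq`; attributes `center_offset` (= `f`), `source_version`, and
#'   `skips` (a `data.frame` of `snp_id`, `reason`). Rows plus skips
#'   account for every input site.
#' @examples
#' asm <- reference_assembly(c(c1 = "AACGTTT"), version = "v1")
#' tab <- variant_table(
#'   sites = data.frame(contig = "c1", pos1 = 4, ref = "G", alt = "A",
#'                      qual = 50, mq = 50),
#'   geno = matrix(1L), samples = "s1", version = "v1")
#' extract_flanks(asm, tab, f = 2)$seq  # "ACGTT"
#' @export
extract_flanks <- function(assembly, table, f = 500L) {
  stopifnot(inherits(assembly, "reference_assembly"),
            inherits(table, "variant_table"))
  f <- as.integer(f)
  if (f < 1L) stop("flank half-width must be >= 1")
  if (!identical(assembly$version, table$version))
    stop(sprintf("version mismatch: assembly '%s' vs table '%s'",
                 assembly$version, table$version))
  s <- table$sites
  missing_contig <- setdiff(unique(s$contig), names(assembly$contigs))
  if (length(missing_contig))
    stop("contig(s) in table absent from assembly: ",
         paste(missing_contig, collapse = ", "))
  snp_id <- paste(table$version, s$contig, s$pos1, s$ref, s$alt, sep = "|")
  clen <- contig_lengths(assembly)[s$contig]
  n <- nrow(s)
  reason <- character(n)
  seqs <- character(n)
  left_ok <- s$pos1 - f >= 1L
  right_ok <- s$pos1 + f <= clen
  reason[!left_ok] <- "insufficient left context"
  reason[left_ok & !right_ok] <- "insufficient right context"
  idx <- which(left_ok & right_ok)
  if (length(idx)) {
    seqs[idx] <- substr(assembly$contigs[s$contig[idx]],
                        s$pos1[idx] - f, s$pos1[idx] + f)
    center <- substr(seqs[idx], f + 1L, f + 1L)
    has_n <- grepl("N", seqs[idx], fixed = TRUE)
    ref_bad <- center != s$ref[idx]
    reason[idx[has_n]] <- "flank contains N"
    reason[idx[!has_n & ref_bad]] <- "assembly base differs from REF"
  }
  keep <- reason == ""
  out <- data.frame(snp_id = snp_id[keep], contig = s$contig[keep],
                    pos1 = s$pos1[keep], ref = s$ref[keep],
                    alt = s$alt[keep], seq = seqs[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "center_offset") <- f
  attr(out, "source_version") <- table$version
  attr(out, "skips") <- data.frame(snp_id = snp_id[!keep],
                                   reason = reason[!keep],
                                   stringsAsFactors = FALSE)
  class(out) <- c("flank_set", "data.frame")
  out
}

#' Write flank probes to FASTA
#' @param flanks A `flank_set` from [extract_flanks()].
#' @param path Output FASTA path (header is the `snp_id`).
#' @return Invisibly, `path`.
#' @export
write_flanks_fasta <- function(flanks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(flanks))
    writeLines(paste0(">", flanks$snp_id, "\n", flanks$seq), con)
  invisible(path)
}

#' Write the flank skip report
#' @param flanks A `flank_set`.
#' @param path Output TSV path (columns `snp_id`, `reason`).
#' @return Invisibly, `path`.
#' @export
write_flank_skips <- function(flanks, path) {
  utils::write.table(attr(flanks, "skips"), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
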