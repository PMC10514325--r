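#' Build a k-mer seed index of an assembly
#'
#' Indexes every k-mer of the forward strand (k-mers containing `N` are not
#' indexed). The index seeds exact-occurrence search: a candidate placement
#' found through the seed table is always verified over the full query, so
#' search results are complete — identical to a naive scan of both strands.
#'
#' @param assembly A `reference_assembly`.
#' @param k Seed length; 31 by default, long enough for near-unique seeds
#'   in plant-sized genomes yet shorter than any legal flank probe.
#' @return An object of class `seq_index`.
#' @export
build_index <- function(assembly, k = 31L) {
  stopifnot(inherits(assembly, "reference_assembly"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  lens <- contig_lengths(assembly)
  if (length(lens) && all(lens < k))
    stop("k = ", k, " exceeds the length of every contig")
  pieces <- vector("list", length(assembly$contigs))
  for (i in seq_along(assembly$contigs)) {
    s <- assembly$contigs[[i]]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("N", km, fixed = TRUE)
    pieces[[i]] <- data.table::data.table(
      kmer = km[ok], contig = names(assembly$contigs)[i],
      pos0 = starts[ok] - 1L)
  }
  dt <- data.table::rbindlist(pieces)
  if (nrow(dt)) data.table::setkey(dt, kmer)
  structure(list(target_version = assembly$version, k = k, table = dt),
            class = "seq_index")
}

#' @export
print.seq_index <- function(x, ...) {
  cat(sprintf("<seq_index '%s'> k = %d, %s seed position(s)\n",
              x$target_version, x$k,
              format(nrow(x$table), big.mark = ",")))
  invisible(x)
}

#' Find all exact occurrences of a query on both strands
#'
#' Returns every interval of the target assembly that equals the query
#' (strand `"+"`) or its reverse complement (strand `"-"`), full length,
#' zero mismatches. The centered k-mer of the query (or of its reverse
#' complement) seeds the search and each candidate is verified over the
#' full query, which makes the result identical to a naive both-strand
#' window scan.
#'
#' @param index A `seq_index` built from `assembly`.
#' @param assembly The target `reference_assembly`.
#' @param query DNA string over A/C/G/T, `nchar(query) >= index$k`.
#' @return `data.frame` with columns `contig`, `start0` (0-based start of
#'   the matched interval), `strand` (`"+"`/`"-"`), ordered by contig,
#'   start and strand.
#' @examples
#' asm <- reference_assembly(c(t = "ACGTACGT"), version = "t")
#' idx <- build_index(asm, k = 3)
#' find_exact_occurrences(idx, asm, "CGT")  # 2 forward + 2 reverse hits
#' @export
find_exact_occurrences <- function(index, assembly, query) {
  stopifnot(inherits(index, "seq_index"),
            inherits(assembly, "reference_assembly"))
  if (grepl("[^ACGT]", query))
    stop("query must be over A/C/G/T (no N)")
  L <- nchar(query)
  if (L < index$k)
    stop("query shorter than the seed length k = ", index$k)
  hits_for <- function(q) {
    off0 <- (L - index$k) %/% 2L          # 0-based offset of centered seed
    seed <- substr(q, off0 + 1L, off0 + index$k)
    cand <- index$table[.(seed), nomatch = NULL, on = "kmer"]
    if (nrow(cand) == 0L)
      return(data.frame(contig = character(0), start0 = integer(0)))
    start0 <- cand$pos0 - off0
    clen <- contig_lengths(assembly)[cand$contig]
    ok <- start0 >= 0L & (start0 + L) <= clen
    cand <- cand[ok]; start0 <- start0[ok]
    if (nrow(cand) == 0L)
      return(data.frame(contig = character(0), start0 = integer(0)))
    found <- substr(assembly$contigs[cand$contig], start0 + 1L,
                    start0 + L) == q
    data.frame(contig = cand$contig[found], start0 = start0[found],
               stringsAsFactors = FALSE)
  }
  fwd <- hits_for(query)
  rev <- hits_for(revcomp(query))
  fwd$strand <- rep("+", nrow(fwd))
  rev$strand <- rep("-", nrow(rev))
  out <- rbind(fwd, rev, make.row.names = FALSE)
  out <- unique(out)
  out[order(out$contig, out$start0, out$strand), , drop = FALSE]
}

#' Map one flank probe into a target assembly
#'
#' Searches the target for exact full-length occurrences of the probe on
#' both strands and classifies the transfer: no occurrence is `UNMAPPED`,
#' one is `UNIQUE`, two or more (counted across both strands jointly —
#' two equally perfect placements make the transfer ambiguous) is `MULTI`.
#' For a `UNIQUE` hit the SNP coordinate in the target is
#' `start0 + center_offset + 1`; the formula holds for either strand
#' because the probe is symmetric about the SNP.
#'
#' @param flank One-row `flank_set` slice (or a list with `snp_id` and
#'   `seq`).
#' @param index `seq_index` of the target.
#' @param target Target `reference_assembly`.
#' @param center_offset Flank half-width `f`; defaults to the `flank_set`
#'   attribute.
#' @return A one-row `data.frame`: `snp_id`, `status`
#'   (`UNIQUE`/`UNMAPPED`/`MULTI`), `contig`, `pos1`, `strand`,
#'   `target_base` (`NA` unless `UNIQUE`).
#' @export
map_flank <- function(flank, index, target,
                      center_offset = attr(flank, "center_offset")) {
  if (is.null(center_offset))
    stop("center_offset not supplied and absent from flank attributes")
  occ <- find_exact_occurrences(index, target, flank$seq[[1]])
  res <- data.frame(snp_id = flank$snp_id[[1]], status = "UNMAPPED",
                    contig = NA_character_, pos1 = NA_integer_,
                    strand = NA_character_, target_base = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(occ) == 1L) {
    pos1 <- occ$start0 + as.integer(center_offset) + 1L
    res$status <- "UNIQUE"
    res$contig <- occ$contig
    res$pos1 <- pos1
    res$strand <- occ$strand
    res$target_base <- .base_at(target, occ$contig, pos1)
  } else if (nrow(occ) >= 2L) {
    res$status <- "MULTI"
  }
  res
}

#' Map a whole flank set into a target assembly
#'
#' Vector version of [map_flank()]. The summary attribute reports the
#' fractions mapped uniquely, unmapped, and multi-mapped.
#'
#' @param flanks A `flank_set`.
#' @param index `seq_index` of the target.
#' @param target Target `reference_assembly`.
#' @return `data.frame` of class `map_result` (one row per probe, columns
#'   as in [map_flank()]), with attribute `summary`.
#' @export
map_flanks <- function(flanks, index, target) {
  f <- attr(flanks, "center_offset")
  n <- nrow(flanks)
  rows <- vector("list", n)
  for (i in seq_len(n))
    rows[[i]] <- map_flank(flanks[i, , drop = FALSE], index, target,
                           center_offset = f)
  out <- if (n) do.call(rbind, rows) else
    data.frame(snp_id = character(0), status = character(0),
               contig = character(0), pos1 = integer(0),
               strand = character(0), target_base = character(0))
  rownames(out) <- NULL
  tot <- max(n, 1L)
  attr(out, "summary") <- c(unique = sum(out$status == "UNIQUE") / tot,
                            unmapped = sum(out$status == "UNMAPPED") / tot,
                            multi = sum(out$status == "MULTI") / tot)
  attr(out, "center_offset") <- f
  class(out) <- c("map_result", "data.frame")
  out
}

#' Write map results as TSV
#' @param maps A `map_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_map_results <- function(maps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sm <- attr(maps, "summary")
  writeLines(sprintf("# unique=%.4f unmapped=%.4f multi=%.4f",
                     sm[["unique"]], sm[["unmapped"]], sm[["multi"]]), con)
  utils::write.table(as.data.frame(maps), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
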