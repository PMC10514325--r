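#' Multi-sample biallelic SNP table
#'
#' The package's in-memory callset: per-site records (contig, 1-based
#' position, REF, ALT, QUAL, mapping quality) plus a sites-by-samples
#' genotype matrix. Genotypes are unphased diploid calls stored as
#' alternate-allele dosage: `0` = hom REF, `1` = het, `2` = hom ALT,
#' `NA` = missing (`./.`). Because every record is a biallelic SNP, the
#' dosage encodes the unordered allele pair exactly ("0/1" and "1/0" are
#' the same call).
#'
#' @param sites `data.frame` with columns `contig`, `pos1`, `ref`, `alt`,
#'   `qual`, `mq`.
#' @param geno Integer matrix, `nrow(sites)` x `length(samples)`, values in
#'   `{0, 1, 2, NA}`.
#' @param samples Character vector of sample names.
#' @param version Version tag of the reference the calls were made against.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, geno, samples, version = "unversioned") {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("contig", "pos1", "ref", "alt", "qual", "mq")
  if (!all(need %in% names(sites)))
    stop("sites must have columns: ", paste(need, collapse = ", "))
  sites <- sites[need]
  sites$contig <- as.character(sites$contig)
  sites$pos1 <- as.integer(sites$pos1)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(sites))
    stop("geno must have one row per site")
  if (ncol(geno) != length(samples))
    stop("geno must have one column per sample")
  if (anyDuplicated(samples)) stop("duplicate sample names")
  ok <- is.na(geno) | (geno >= 0L & geno <= 2L)
  if (!all(ok)) stop("genotype dosages must be 0, 1, 2 or NA")
  if (nrow(sites) > 0L) {
    if (any(sites$pos1 < 1L)) stop("positions must be >= 1")
    if (any(!sites$ref %in% c("A", "C", "G", "T")) ||
        any(!sites$alt %in% c("A", "C", "G", "T")))
      stop("REF and ALT must be single bases A/C/G/T")
    if (any(sites$ref == sites$alt)) stop("REF must differ from ALT")
    if (any(sites$qual < 0) || any(sites$mq < 0))
      stop("QUAL and MQ must be non-negative")
    o <- order(sites$contig, sites$pos1)
    sites <- sites[o, , drop = FALSE]
    geno <- geno[o, , drop = FALSE]
    rownames(sites) <- NULL
  }
  colnames(geno) <- samples
  structure(list(version = as.character(version),
                 samples = as.character(samples),
                 sites = sites, geno = geno),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table '%s'> %d site(s) x %d sample(s)\n",
              x$version, nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' Number of sites in a variant table
#' @param table A `variant_table`.
#' @return Integer site count.
#' @export
n_sites <- function(table) nrow(table$sites)

.gt_strings <- c("0/0", "0/1", "1/1")

#' Read a VCF into a variant table
#'
#' Loads biallelic SNP records with unphased diploid GT calls. QUAL comes
#' from the QUAL column and mapping quality from INFO key `MQ` (`NA` when
#' absent). Indel and multiallelic records are skipped and counted in the
#' `skipped` attribute; a missing GT FORMAT field is an error.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param version Version tag; defaults to the file name.
#' @return A [variant_table()] with attribute `skipped` (named counts).
#' @export
read_vcf <- function(path, version = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(version))
    version <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L)
    stop("VCF has no genotype columns: ", path)
  samples <- colnames(gt_raw)[-1L]
  nrec <- nrow(fix)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  multi <- !is.na(alt) & grepl(",", alt)
  skipped <- c(indel = sum(!is_snp & !multi), multiallelic = sum(multi))
  keep <- which(is_snp & !multi)
  fmt <- gt_raw[, 1L]
  if (any(!grepl("(^|:)GT(:|$)", fmt[keep])))
    stop("VCF record without GT in FORMAT: ", path)
  info <- paste0(";", fix[keep, "INFO"])
  hit <- regexpr(";MQ=[^;]+", info)
  mq <- rep(NA_real_, length(keep))
  found <- hit > 0L
  mq[found] <- suppressWarnings(as.numeric(
    substring(info[found], hit[found] + 4L,
              hit[found] + attr(hit, "match.length")[found] - 1L)))
  gt_field <- function(i) {
    idx <- match("GT", strsplit(fmt[i], ":", fixed = TRUE)[[1]])
    vapply(strsplit(gt_raw[i, -1L], ":", fixed = TRUE),
           function(p) if (length(p) >= idx) p[idx] else ".",
           character(1))
  }
  geno <- matrix(NA_integer_, nrow = length(keep), ncol = length(samples))
  for (j in seq_along(keep)) {
    g <- gt_field(keep[j])
    g[is.na(g)] <- "./."   # vcfR reads missing calls as NA
    g <- sub("|", "/", g, fixed = TRUE)
    dos <- rep(NA_integer_, length(g))
    dos[g %in% c("0/0")] <- 0L
    dos[g %in% c("0/1", "1/0")] <- 1L
    dos[g %in% c("1/1")] <- 2L
    bad <- !(g %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".", ".|.", "./"))
    if (any(bad))
      stop("unsupported GT value '", g[bad][1], "' in ", path)
    geno[j, ] <- dos
  }
  qual <- suppressWarnings(as.numeric(fix[keep, "QUAL"]))
  tab <- variant_table(
    sites = data.frame(contig = fix[keep, "CHROM"],
                       pos1 = as.integer(fix[keep, "POS"]),
                       ref = ref[keep], alt = alt[keep],
                       qual = qual, mq = mq,
                       stringsAsFactors = FALSE),
    geno = geno, samples = samples, version = version)
  attr(tab, "skipped") <- skipped
  if (sum(skipped) > 0)
    message(sprintf("read_vcf: skipped %d indel and %d multiallelic record(s)",
                    skipped[["indel"]], skipped[["multiallelic"]]))
  tab
}

#' Write a variant table as VCF 4.2
#'
#' Emits plain-text VCF with GT genotypes (`a/b` unphased, `./.` missing),
#' QUAL, and `MQ` in INFO. Reading the file back with [read_vcf()]
#' reproduces the table.
#'
#' @param table A `variant_table`.
#' @param path Output path.
#' @param header_extra Optional character vector of extra `##` header lines
#'   (e.g. provenance comments).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(table, path, header_extra = NULL) {
  stopifnot(inherits(table, "variant_table"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=flanklift"),
           sprintf("##reference=%s", table$version),
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           header_extra,
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", table$samples), collapse = "\t"))
  writeLines(hdr, con)
  n <- nrow(table$sites)
  if (n > 0L) {
    gt <- ifelse(is.na(table$geno), "./.", .gt_strings[table$geno + 1L])
    dim(gt) <- dim(table$geno)
    s <- table$sites
    info <- ifelse(is.na(s$mq), ".", sprintf("MQ=%s", format(s$mq, trim = TRUE,
                                                             scientific = FALSE)))
    qual <- ifelse(is.na(s$qual), ".", format(s$qual, trim = TRUE,
                                              scientific = FALSE))
    body <- paste(s$contig, s$pos1, ".", s$ref, s$alt, qual, ".",
                  info, "GT", sep = "\t")
    body <- paste(body, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Post-calling variant filter
#'
#' Applies the calling-stage quality screen: retained sites satisfy all of
#' `qual > min_qual`, `mq > min_mq`, `MAF > min_maf`, and
#' `missing fraction < max_missing_call`, each a strict inequality. MAF is
#' the lesser of the two allele frequencies over non-missing allele calls
#' (two per called sample); the missing fraction is the share of samples
#' with no call. Per-criterion rejection counts are attached as attribute
#' `rejections` (a site failing several criteria is counted under each).
#'
#' @param table A `variant_table` with at least one sample.
#' @param params A [lift_params()].
#' @return The filtered `variant_table`, with attribute `rejections`.
#' @examples
#' p <- lift_params()
#' tab <- variant_table(
#'   sites = data.frame(contig = "c1", pos1 = 5, ref = "A", alt = "G",
#'                      qual = 40, mq = 40),
#'   geno = matrix(c(1L, 0L), 1), samples = c("s1", "s2"))
#' n_sites(filter_variants(tab, p))  # retained: MAF 0.25, nothing missing
#' @export
filter_variants <- function(table, params = lift_params()) {
  stopifnot(inherits(table, "variant_table"))
  ns <- length(table$samples)
  if (ns == 0L) stop("filter_variants: table has zero samples")
  g <- table$geno
  n_called <- rowSums(!is.na(g))
  alt_ct <- rowSums(g, na.rm = TRUE)
  tot <- 2 * n_called
  af <- ifelse(tot > 0, alt_ct / tot, NA_real_)
  maf <- pmin(af, 1 - af)
  miss <- (ns - n_called) / ns
  s <- table$sites
  pass_qual <- !is.na(s$qual) & s$qual > params$min_qual
  pass_mq <- !is.na(s$mq) & s$mq > params$min_mq
  pass_maf <- !is.na(maf) & maf > params$min_maf
  pass_miss <- miss < params$max_missing_call
  keep <- pass_qual & pass_mq & pass_maf & pass_miss
  out <- variant_table(s[keep, , drop = FALSE],
                       table$geno[keep, , drop = FALSE],
                       table$samples, table$version)
  attr(out, "rejections") <- c(qual = sum(!pass_qual), mq = sum(!pass_mq),
                               maf = sum(!pass_maf),
                               missing = sum(!pass_miss))
  out
}

#' SNP saturation curve
#'
#' For an accession ordering, `count[k]` is the number of sites at which at
#' least one of the first `k` samples has a non-missing genotype carrying
#' the alternate allele — i.e. how many SNPs would have been discovered
#' from the first `k` accessions alone. The curve is non-decreasing; its
#' final value is the number of sites with any observed carrier. With
#' `n_permutations`, the mean curve over random sample orderings is
#' returned (reproducible under `seed`).
#'
#' @param table A `variant_table`.
#' @param order Character vector: a permutation of `table$samples`.
#' @param n_permutations Alternative to `order`: number of random
#'   orderings to average.
#' @param seed Seed for the permutations.
#' @return Numeric vector of length `length(samples)`; `count[k]` as above
#'   (a mean over orderings when `n_permutations` is used).
#' @export
snp_saturation <- function(table, order = NULL, n_permutations = NULL,
                           seed = 1L) {
  stopifnot(inherits(table, "variant_table"))
  ns <- length(table$samples)
  one_curve <- function(idx) {
    carrier <- !is.na(table$geno[, idx, drop = FALSE]) &
      table$geno[, idx, drop = FALSE] >= 1L
    if (nrow(carrier) == 0L) return(numeric(ns))
    first <- apply(carrier, 1L, function(r) {
      w <- which(r)
      if (length(w)) w[1] else NA_integer_
    })
    cumsum(tabulate(first, nbins = ns))
  }
  if (!is.null(order)) {
    if (length(order) == 0L) stop("snp_saturation: empty sample order")
    idx <- match(order, table$samples)
    if (anyNA(idx) || length(idx) != ns || anyDuplicated(idx))
      stop("order must be a permutation of the table's samples")
    return(one_curve(idx))
  }
  if (is.null(n_permutations))
    return(one_curve(seq_len(ns)))
  stopifnot(n_permutations >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  acc <- numeric(ns)
  for (i in seq_len(n_permutations))
    acc <- acc + one_curve(sample.int(ns))
  acc / n_permutations
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
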