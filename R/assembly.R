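#' Reference assembly container
#'
#' A versioned, named collection of contig sequences over the A/C/G/T/N
#' alphabet. Sequences are stored as plain upper-case character strings;
#' internal coordinates throughout the package are 0-based half-open, while
#' every reported or file-borne position is 1-based.
#'
#' @param contigs Named character vector of DNA sequences (A/C/G/T/N only;
#'   lower case is folded to upper).
#' @param version Short version tag, e.g. `"a1"`.
#' @return An object of class `reference_assembly`.
#' @examples
#' asm <- reference_assembly(c(chr1 = "ACGTACGT"), version = "demo")
#' contig_lengths(asm)
#' @export
reference_assembly <- function(contigs, version = "unversioned") {
  if (length(contigs) > 0L) {
    if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
      stop("every contig must be named")
    if (anyDuplicated(names(contigs)))
      stop("contig names must be unique")
    contigs <- toupper(unlist(contigs))
    if (any(!nzchar(contigs))) stop("contig sequences must be non-empty")
    bad <- grepl("[^ACGTN]", contigs)
    if (any(bad))
      stop("illegal character in contig(s): ",
           paste(names(contigs)[bad], collapse = ", "))
  } else {
    contigs <- stats::setNames(character(0), character(0))
  }
  structure(list(version = as.character(version), contigs = contigs),
            class = "reference_assembly")
}

#' @export
print.reference_assembly <- function(x, ...) {
  cat(sprintf("<reference_assembly '%s'> %d contig(s), %s bp total\n",
              x$version, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' Contig lengths of an assembly
#' @param assembly A `reference_assembly`.
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(assembly) {
  stopifnot(inherits(assembly, "reference_assembly"))
  vapply(assembly$contigs, nchar, integer(1))
}

#' Reverse complement of a DNA string
#'
#' Strand-aware allele and probe arithmetic throughout the pipeline relies
#' on this involution; `N` maps to `N`.
#'
#' @param seq A character vector of DNA strings over A/C/G/T/N.
#' @return Character vector of the same length, each element reverse
#'   complemented.
#' @examples
#' revcomp("AAC")    # "GTT"
#' revcomp("ACGT")   # its own reverse complement
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  if (length(seq) == 0L) return(character(0))
  if (any(grepl("[^ACGTN]", seq)))
    stop("revcomp: illegal character (alphabet is A/C/G/T/N)")
  out <- vapply(seq, function(s) {
    if (!nzchar(s)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Complement (without reversal) of DNA strings
#' @param seq Character vector over A/C/G/T/N.
#' @return Complemented strings, same orientation.
#' @export
complement_bases <- function(seq) {
  stopifnot(is.character(seq))
  if (any(grepl("[^ACGTN]", seq)))
    stop("complement_bases: illegal character")
  chartr("ACGTN", "TGCAN", seq)
}

#' Read a reference assembly from FASTA
#'
#' Accepts multi-record FASTA, wrapped or unwrapped; lower-case bases are
#' upper-cased. Any IUPAC ambiguity code other than `N` is rejected with the
#' offending line number.
#'
#' @param path Path to a FASTA file.
#' @param version Version tag to attach; defaults to the file name without
#'   extension.
#' @return A [reference_assembly()].
#' @export
read_fasta <- function(path, version = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(version))
    version <- tools::file_path_sans_ext(basename(path))
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) e)
  if (inherits(set, "error") || (length(set) > 0 && any(Biostrings::width(set) == 0))) {
    .fasta_diagnose(path)  # throws with a line number
    stop("malformed FASTA: ", path)
  }
  seqs <- toupper(as.character(set))
  nms <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) .fasta_diagnose(path)
  if (length(seqs) == 0L) stop("FASTA parse error: no records in ", path)
  reference_assembly(stats::setNames(seqs, nms), version = version)
}

# Secondary line scan used only to attribute a parse failure to a line.
.fasta_diagnose <- function(path) {
  lines <- readLines(path, warn = FALSE)
  in_record <- FALSE
  seen_seq <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      if (in_record && !seen_seq)
        stop(sprintf("FASTA parse error at line %d: empty record", i - 1L))
      if (nchar(ln) < 2L)
        stop(sprintf("FASTA parse error at line %d: empty header", i))
      in_record <- TRUE
      seen_seq <- FALSE
    } else if (nzchar(trimws(ln))) {
      if (!in_record)
        stop(sprintf("FASTA parse error at line %d: sequence before header", i))
      if (grepl("[^ACGTNacgtn]", ln))
        stop(sprintf("FASTA parse error at line %d: illegal character '%s'",
                     i, regmatches(ln, regexpr("[^ACGTNacgtn]", ln))))
      seen_seq <- TRUE
    }
  }
  if (in_record && !seen_seq)
    stop(sprintf("FASTA parse error at line %d: empty record", length(lines)))
  invisible(NULL)
}

#' Write an assembly to FASTA
#' @param assembly A `reference_assembly`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(assembly, path, width = 70L) {
  stopifnot(inherits(assembly, "reference_assembly"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(assembly$contigs)) {
    writeLines(paste0(">", nm), con)
    s <- assembly$contigs[[nm]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

# 0-based half-open slice of a contig; internal helper.
.slice0 <- function(assembly, contig, start0, end0) {
  s <- assembly$contigs[[contig]]
  if (is.null(s)) stop("unknown contig: ", contig)
  substr(s, start0 + 1L, end0)
}

# Single base at a 1-based position.
.base_at <- function(assembly, contig, pos1) {
  s <- assembly$contigs[[contig]]
  if (is.null(s)) stop("unknown contig: ", contig)
  substr(s, pos1, pos1)
}
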