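#' Simulate a random reference assembly
#'
#' I.i.d. uniform A/C/G/T sequence per contig, reproducible under the
#' seed. The simulated pair of assemblies stands in for two releases of a
#' real reference genome, so every pipeline stage can be validated against
#' known ground truth.
#'
#' @param lengths Integer vector of contig lengths (optionally named;
#'   default names `chr1`, `chr2`, ...).
#' @param seed Integer seed.
#' @param version Version tag.
#' @return A [reference_assembly()].
#' @export
simulate_reference <- function(lengths, seed = 1L, version = "simA") {
  stopifnot(all(lengths >= 1) || length(lengths) == 0L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (length(lengths) == 0L)
    return(reference_assembly(stats::setNames(character(0), character(0)),
                              version = version))
  nms <- names(lengths)
  if (is.null(nms)) nms <- paste0("chr", seq_along(lengths))
  contigs <- vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  reference_assembly(stats::setNames(contigs, nms), version = version)
}

#' Assembly edit specification
#'
#' Rates and counts of the tracked differences planted between the two
#' simulated assembly versions. Defaults give the package's desk-scale
#' scenario: 0.05\% substitutions, 20 small indels (1-10 bp), 3
#' inversions (1-10 kb), 3 tandem duplications (2-5 kb), 1 translocation
#' (5-20 kb), and 2 inserted N-gaps (100-500 bp).
#'
#' @param sub_rate Per-base substitution probability outside structural
#'   events.
#' @param n_indels Total small indels (half deletions, half insertions).
#' @param indel_len Length range of indels, bp.
#' @param n_inversions,inv_len Count and length range of inversions.
#' @param n_duplications,dup_len Count and length range of tandem
#'   duplications.
#' @param n_translocations,trans_len Count and length range of moved
#'   segments.
#' @param n_ngaps,ngap_len Count and length range of inserted N runs.
#' @return A list of class `edit_spec`.
#' @export
edit_spec <- function(sub_rate = 5e-4, n_indels = 20L,
                      indel_len = c(1L, 10L), n_inversions = 3L,
                      inv_len = c(1000L, 10000L), n_duplications = 3L,
                      dup_len = c(2000L, 5000L), n_translocations = 1L,
                      trans_len = c(5000L, 20000L), n_ngaps = 2L,
                      ngap_len = c(100L, 500L)) {
  structure(as.list(environment()), class = "edit_spec")
}

#' Derive a second assembly version by tracked edits
#'
#' Applies the edit specification to `genome_a` and returns the derived
#' assembly together with a ground-truth coordinate map. Canonical truth
#' segments are non-overlapping within each assembly and record the exact
#' base-level correspondence (strand `"-"` segments map
#' `b = b_start0 + (a_end0 - 1 - a)`); the second copy of each tandem
#' duplication is an extra segment flagged `ambiguous` (its source bases
#' map one-to-many); substituted positions are recorded so projections
#' through them can be flagged as mismatches.
#'
#' @param genome_a Source `reference_assembly`.
#' @param edits An [edit_spec()].
#' @param seed Integer seed.
#' @param version Version tag for the derived assembly.
#' @return List with `assembly` (the derived `reference_assembly`) and
#'   `truth` (class `truth_map`: `$segments`, `$substitutions`).
#' @export
derive_assembly <- function(genome_a, edits = edit_spec(), seed = 1L,
                            version = "simB") {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lens <- contig_lengths(genome_a)
  cn <- names(lens)
  total <- sum(lens)
  occupied <- data.frame(contig = character(0), s = integer(0),
                         e = integer(0), stringsAsFactors = FALSE)
  place <- function(len) {
    # a length-0 event (insertion point) occupies one base of margin
    span <- max(len, 1L)
    for (try in 1:2000) {
      ct <- sample(cn, 1L, prob = lens)
      if (lens[[ct]] <= span + 2L) next
      s <- sample.int(lens[[ct]] - span - 1L, 1L)  # 0-based start, interior
      e <- s + span
      ov <- occupied$contig == ct & occupied$s < e + 1L & occupied$e > s - 1L
      if (!any(ov)) {
        occupied[nrow(occupied) + 1L, ] <<- list(ct, s, e)
        return(list(contig = ct, s = s, e = e))
      }
    }
    stop("derive_assembly: could not place an event of length ", len,
         " without overlap; edit demands exceed the genome")
  }
  rlen <- function(range) {
    if (range[1] >= range[2]) return(as.integer(range[1]))
    range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
  }

  events <- list()
  add_event <- function(kind, loc, len = NULL, dst = NULL)
    events[[length(events) + 1L]] <<- list(kind = kind, contig = loc$contig,
                                           s = loc$s, e = loc$e, len = len,
                                           dst = dst)
  if (edits$n_indels > 0) {
    n_del <- edits$n_indels %/% 2L
    for (i in seq_len(n_del))
      add_event("del", place(rlen(edits$indel_len)))
    for (i in seq_len(edits$n_indels - n_del)) {
      L <- rlen(edits$indel_len)
      add_event("ins", place(0L), len = L)
    }
  }
  for (i in seq_len(edits$n_inversions))
    add_event("inv", place(rlen(edits$inv_len)))
  for (i in seq_len(edits$n_duplications))
    add_event("dup", place(rlen(edits$dup_len)))
  for (i in seq_len(edits$n_translocations)) {
    src <- place(rlen(edits$trans_len))
    dst <- place(0L)
    add_event("trans", src, dst = dst)
  }
  for (i in seq_len(edits$n_ngaps))
    add_event("ngap", place(0L), len = rlen(edits$ngap_len))

  # blocks of the derived assembly, per target contig
  blocks <- stats::setNames(vector("list", length(cn)), cn)
  point_kind <- c("ins", "ngap")
  ins_at <- stats::setNames(vector("list", length(cn)), cn)  # point events
  for (ev in events) {
    if (ev$kind %in% point_kind)
      ins_at[[ev$contig]] <- c(ins_at[[ev$contig]], list(ev))
    else if (ev$kind == "trans")
      ins_at[[ev$dst$contig]] <-
        c(ins_at[[ev$dst$contig]],
          list(list(kind = "trans_dst", contig = ev$dst$contig,
                    s = ev$dst$s, src = ev)))
  }
  range_events <- Filter(function(e) e$kind %in%
                           c("del", "inv", "dup", "trans"), events)
  for (ct in cn) {
    evs <- Filter(function(e) e$contig == ct, range_events)
    pts <- ins_at[[ct]]
    pos_of <- function(e) e$s
    all_e <- c(evs, pts)
    ord <- order(vapply(all_e, pos_of, numeric(1)))
    all_e <- all_e[ord]
    cur <- 0L
    bl <- list()
    emit <- function(b) bl[[length(bl) + 1L]] <<- b
    ref_block <- function(ctg, s, e, strand = "+", amb = FALSE)
      list(type = "ref", a_contig = ctg, a_s = s, a_e = e, strand = strand,
           ambiguous = amb, seq = NULL)
    for (e in all_e) {
      if (e$s > cur) emit(ref_block(ct, cur, e$s))
      if (is.null(e$kind)) next
      switch(e$kind,
        del = { cur <- e$e; next },
        inv = { emit(ref_block(ct, e$s, e$e, strand = "-")); cur <- e$e },
        dup = {
          emit(ref_block(ct, e$s, e$e))
          emit(ref_block(ct, e$s, e$e, amb = TRUE))
          cur <- e$e
        },
        trans = { cur <- e$e },  # source removed here, re-emitted at dst
        ins = {
          emit(list(type = "novel", len = e$len, seq = NULL))
          cur <- max(cur, e$s)
        },
        ngap = {
          emit(list(type = "nrun", len = e$len, seq = NULL))
          cur <- max(cur, e$s)
        },
        trans_dst = {
          emit(ref_block(e$src$contig, e$src$s, e$src$e))
          cur <- max(cur, e$s)
        })
    }
    if (cur < lens[[ct]]) emit(ref_block(ct, cur, lens[[ct]]))
    blocks[[ct]] <- bl
  }

  seg_rows <- list()
  contigs_b <- stats::setNames(character(length(cn)), cn)
  for (ct in cn) {
    parts <- character(0)
    off <- 0L
    for (b in blocks[[ct]]) {
      if (b$type == "ref") {
        s <- .slice0(genome_a, b$a_contig, b$a_s, b$a_e)
        if (b$strand == "-") s <- revcomp(s)
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          contig_a = b$a_contig, a_start0 = b$a_s, a_end0 = b$a_e,
          contig_b = ct, b_start0 = off, b_end0 = off + nchar(s),
          strand = b$strand, ambiguous = b$ambiguous,
          stringsAsFactors = FALSE)
      } else if (b$type == "novel") {
        s <- paste(sample(c("A", "C", "G", "T"), b$len, replace = TRUE),
                   collapse = "")
      } else {
        s <- strrep("N", b$len)
      }
      parts <- c(parts, s)
      off <- off + nchar(s)
    }
    contigs_b[[ct]] <- paste(parts, collapse = "")
  }
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else
    data.frame(contig_a = character(0), a_start0 = integer(0),
               a_end0 = integer(0), contig_b = character(0),
               b_start0 = integer(0), b_end0 = integer(0),
               strand = character(0), ambiguous = logical(0))

  # substitutions in plain forward segments only, outside all events
  n_sub <- stats::rbinom(1L, total, edits$sub_rate)
  subs <- data.frame(contig = character(0), pos0 = integer(0),
                     stringsAsFactors = FALSE)
  if (n_sub > 0) {
    plain <- segments[segments$strand == "+" & !segments$ambiguous &
                        segments$contig_a == segments$contig_b, ,
                      drop = FALSE]
    # restrict to in-place stretches (identity-offset segments are the
    # un-edited remainder; translocated copies also satisfy contig_a ==
    # contig_b sometimes, but any plain segment projects exactly)
    widths <- plain$a_end0 - plain$a_start0
    if (sum(widths) > 0) {
      pickseg <- sample.int(nrow(plain), n_sub, replace = TRUE,
                            prob = widths)
      offs <- floor(stats::runif(n_sub) * widths[pickseg])
      pos0 <- plain$a_start0[pickseg] + as.integer(offs)
      d <- unique(data.frame(contig = plain$contig_a[pickseg],
                             pos0 = pos0, seg = pickseg,
                             stringsAsFactors = FALSE))
      for (i in seq_len(nrow(d))) {
        sg <- plain[d$seg[i], ]
        bpos <- sg$b_start0 + (d$pos0[i] - sg$a_start0)
        ref <- substr(contigs_b[[sg$contig_b]], bpos + 1L, bpos + 1L)
        newb <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        substr(contigs_b[[sg$contig_b]], bpos + 1L, bpos + 1L) <- newb
      }
      subs <- d[c("contig", "pos0")]
      subs <- subs[order(subs$contig, subs$pos0), , drop = FALSE]
      rownames(subs) <- NULL
    }
  }

  truth <- structure(list(segments = segments, substitutions = subs),
                     class = "truth_map")
  list(assembly = reference_assembly(contigs_b, version = version),
       truth = truth)
}

#' @export
print.truth_map <- function(x, ...) {
  cat(sprintf("<truth_map> %d segment(s) (%d ambiguous), %d substitution(s)\n",
              nrow(x$segments), sum(x$segments$ambiguous),
              nrow(x$substitutions)))
  invisible(x)
}

#' Project source-assembly coordinates through a truth map
#'
#' Maps 0-based positions of assembly A to assembly B via the canonical
#' (non-ambiguous) truth segments.
#'
#' @param truth A `truth_map`.
#' @param contig,pos0 Vectors of A-side contigs and 0-based positions.
#' @return `data.frame`: `contig_b`, `b_pos0` (`NA` where unmapped),
#'   `strand`, `mismatch` (position is a planted substitution),
#'   `ambiguous` (position also lies in a duplicated source region).
#' @export
truth_project <- function(truth, contig, pos0) {
  seg <- truth$segments
  can <- seg[!seg$ambiguous, , drop = FALSE]
  amb <- seg[seg$ambiguous, , drop = FALSE]
  n <- length(pos0)
  out <- data.frame(contig_b = rep(NA_character_, n),
                    b_pos0 = rep(NA_integer_, n),
                    strand = rep(NA_character_, n),
                    mismatch = logical(n), ambiguous = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    hit <- which(can$contig_a == contig[i] & can$a_start0 <= pos0[i] &
                   pos0[i] < can$a_end0)
    if (length(hit)) {
      sgm <- can[hit[1L], ]
      out$contig_b[i] <- sgm$contig_b
      out$strand[i] <- sgm$strand
      out$b_pos0[i] <- if (sgm$strand == "+")
        sgm$b_start0 + (pos0[i] - sgm$a_start0)
      else sgm$b_start0 + (sgm$a_end0 - 1L - pos0[i])
    }
    out$mismatch[i] <- any(truth$substitutions$contig == contig[i] &
                             truth$substitutions$pos0 == pos0[i])
    out$ambiguous[i] <- any(amb$contig_a == contig[i] &
                              amb$a_start0 <= pos0[i] &
                              pos0[i] < amb$a_end0)
  }
  out
}

#' Variant-panel simulation settings
#'
#' Defaults give the desk-scale study panel: 60 samples, 2000 SNP sites,
#' alternate-allele frequencies uniform on [0.05, 0.5], 2\% missing calls
#' and 0.5\% genotype errors per panel, a 2\% site subset with 50\%
#' per-sample error on the second panel (discordance plant), a 5\%
#' low-quality site subset, and unmapped/multi-mapped site pools of 7.5\%
#' and 3\% mirroring the proportions seen in real cross-version mapping.
#'
#' @param n_samples,n_snps Panel dimensions.
#' @param af_range Alternate-allele frequency law (uniform bounds).
#' @param missing_rate,error_rate Per-call missingness and error
#'   probability in each panel.
#' @param discordant_fraction Fraction of sites planted discordant.
#' @param discordant_error Per-sample error rate on panel B at those
#'   sites.
#' @param low_quality_fraction Fraction of sites drawn with QUAL/MQ below
#'   the calling-stage thresholds.
#' @param unmapped_fraction,multi_fraction Fractions of sites placed
#'   where flank transfer is expected to fail (substitution inside the
#'   flank window) or be ambiguous (inside a tandem-duplication source).
#' @param flank Flank half-width the placement rules respect.
#' @param seed Integer seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_samples = 60L, n_snps = 2000L,
                       af_range = c(0.05, 0.5), missing_rate = 0.02,
                       error_rate = 0.005, discordant_fraction = 0.02,
                       discordant_error = 0.5,
                       low_quality_fraction = 0.05,
                       unmapped_fraction = 0.075, multi_fraction = 0.03,
                       flank = 500L, seed = 1L) {
  structure(as.list(environment()), class = "panel_spec")
}

#' Simulate matched variant panels against both assembly versions
#'
#' Places SNP sites on assembly A according to their intended fate, draws
#' per-sample diploid genotypes under Hardy-Weinberg at each site's
#' alternate-allele frequency, and emits two callsets describing the same
#' underlying genotypes: panel A in A coordinates and panel B at the
#' truth-projected positions (alleles complemented on reverse-strand
#' segments), each with independent missingness and genotype error, plus
#' elevated error on panel B at the planted discordant subset. QUAL and
#' MQ are drawn above the calling-stage thresholds except at the labeled
#' low-quality subset.
#'
#' Site truth labels record the expected fate, computed from the
#' generative record by independent arithmetic (never by running the
#' pipeline): `EXPECT_UNMAPPED` (substitution inside the flank window),
#' `EXPECT_MULTI` (inside a duplicated source region),
#' `EXPECT_DISCORDANT` (planted discordance), `EXPECT_FILTERED`
#' (low-quality draw, or realized panel MAF/missingness failing the
#' strict calling-stage thresholds in either panel), and
#' `TRANSFERABLE_CONCORDANT` otherwise.
#'
#' @param genome_a,genome_b The paired assemblies.
#' @param truth The `truth_map` relating them.
#' @param spec A [panel_spec()].
#' @param params A [lift_params()]; only its filter thresholds are used,
#'   for the `EXPECT_FILTERED` labeling arithmetic.
#' @return List: `table_a`, `table_b` (both `variant_table`),
#'   `truth_sites` (`data.frame`: `site_id`, `contig_a`, `pos1_a`,
#'   `contig_b`, `pos1_b`, `strand`, `label`, `low_quality`).
#' @export
simulate_panels <- function(genome_a, genome_b, truth, spec = panel_spec(),
                            params = lift_params()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  f <- as.integer(spec$flank)
  seg <- truth$segments
  can <- seg[!seg$ambiguous, , drop = FALSE]
  dup_src <- unique(seg[seg$ambiguous, c("contig_a", "a_start0", "a_end0")])

  # candidate positions: windows wholly inside one canonical segment
  cand <- list()
  for (i in seq_len(nrow(can))) {
    lo <- can$a_start0[i] + f
    hi <- can$a_end0[i] - 1L - f
    if (hi < lo) next
    p <- lo:hi
    cand[[length(cand) + 1L]] <- data.frame(
      contig = can$contig_a[i], pos0 = p, seg = i,
      stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  cand$dup <- FALSE
  for (ct in unique(dup_src$contig_a)) {
    d <- dup_src[dup_src$contig_a == ct, , drop = FALSE]
    sel <- cand$contig == ct
    for (r in seq_len(nrow(d)))
      cand$dup[sel] <- cand$dup[sel] |
        (cand$pos0[sel] >= d$a_start0[r] & cand$pos0[sel] < d$a_end0[r])
  }
  # distance to nearest substitution
  cand$sub_in_window <- FALSE
  cand$at_sub <- FALSE
  for (ct in unique(cand$contig)) {
    sp <- sort(truth$substitutions$pos0[truth$substitutions$contig == ct])
    sel <- which(cand$contig == ct)
    if (length(sp) == 0L) next
    p <- cand$pos0[sel]
    k <- findInterval(p, sp)
    left <- ifelse(k >= 1L, p - sp[pmax(k, 1L)], Inf)
    right <- ifelse(k < length(sp), sp[pmin(k + 1L, length(sp))] - p, Inf)
    cand$sub_in_window[sel] <- pmin(left, right) <= f
    cand$at_sub[sel] <- left == 0
  }

  pool_tc <- which(!cand$dup & !cand$sub_in_window)
  pool_un <- which(!cand$dup & cand$sub_in_window & !cand$at_sub)
  pool_mu <- which(cand$dup & !cand$sub_in_window)

  n <- spec$n_snps
  n_mu <- round(spec$multi_fraction * n)
  n_un <- round(spec$unmapped_fraction * n)
  n_tc <- n - n_mu - n_un
  if (length(pool_mu) < n_mu || length(pool_un) < n_un ||
      length(pool_tc) < n_tc)
    stop("simulate_panels: insufficient eligible sites for the requested ",
         "panel (pools: clean ", length(pool_tc), ", unmapped ",
         length(pool_un), ", multi ", length(pool_mu), ")")
  pick <- c(sample(pool_tc, n_tc), sample(pool_un, n_un),
            sample(pool_mu, n_mu))
  fate <- c(rep("clean", n_tc), rep("EXPECT_UNMAPPED", n_un),
            rep("EXPECT_MULTI", n_mu))
  sites <- cand[pick, , drop = FALSE]
  sites$fate <- fate

  n_disc <- round(spec$discordant_fraction * n)
  disc <- rep(FALSE, n)
  disc[sample(which(sites$fate == "clean"), n_disc)] <- TRUE
  lowq <- rep(FALSE, n)
  lowq[sample.int(n, round(spec$low_quality_fraction * n))] <- TRUE

  proj <- truth_project(truth, sites$contig, sites$pos0)
  stopifnot(!anyNA(proj$b_pos0))
  ref_a <- substr(genome_a$contigs[sites$contig], sites$pos0 + 1L,
                  sites$pos0 + 1L)
  alt_a <- vapply(ref_a, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
    USE.NAMES = FALSE)
  flip <- proj$strand == "-"
  ref_b <- ifelse(flip, complement_bases(ref_a), ref_a)
  alt_b <- ifelse(flip, complement_bases(alt_a), alt_a)
  ref_b_asm <- substr(genome_b$contigs[proj$contig_b], proj$b_pos0 + 1L,
                      proj$b_pos0 + 1L)
  stopifnot(identical(unname(ref_b), unname(ref_b_asm)))

  ns <- spec$n_samples
  p_alt <- stats::runif(n, spec$af_range[1], spec$af_range[2])
  true_dos <- matrix(stats::rbinom(n * ns, 2L, rep(p_alt, ns)), n, ns)

  corrupt <- function(dos, err_site) {
    e <- matrix(stats::runif(n * ns) < rep(err_site, ns), n, ns)
    if (any(e)) {
      # replace with one of the two other dosages, uniformly
      shift <- matrix(sample(1:2, n * ns, replace = TRUE), n, ns)
      dos[e] <- (dos[e] + shift[e]) %% 3L
    }
    m <- matrix(stats::runif(n * ns) < spec$missing_rate, n, ns)
    dos[m] <- NA_integer_
    dos
  }
  err_a <- rep(spec$error_rate, n)
  err_b <- ifelse(disc, spec$discordant_error, spec$error_rate)
  dos_a <- corrupt(true_dos, err_a)
  dos_b <- corrupt(true_dos, err_b)

  qual <- stats::runif(n, 50, 200)
  mq <- stats::runif(n, 40, 60)
  qual[lowq] <- stats::runif(sum(lowq), 1, 25)
  mq[lowq] <- stats::runif(sum(lowq), 1, 25)

  sample_names <- sprintf("S%03d", seq_len(ns))
  tab_a <- variant_table(
    sites = data.frame(contig = sites$contig, pos1 = sites$pos0 + 1L,
                       ref = ref_a, alt = alt_a, qual = qual, mq = mq,
                       stringsAsFactors = FALSE),
    geno = dos_a, samples = sample_names, version = genome_a$version)
  tab_b <- variant_table(
    sites = data.frame(contig = proj$contig_b, pos1 = proj$b_pos0 + 1L,
                       ref = ref_b, alt = alt_b, qual = qual, mq = mq,
                       stringsAsFactors = FALSE),
    geno = dos_b, samples = sample_names, version = genome_b$version)

  # expected-fate labels, by arithmetic on the generative record
  pass_filter <- function(dos) {
    called <- rowSums(!is.na(dos))
    altc <- rowSums(dos, na.rm = TRUE)
    af <- ifelse(called > 0, altc / (2 * called), NA)
    maf <- pmin(af, 1 - af)
    miss <- (ns - called) / ns
    !is.na(maf) & maf > params$min_maf & miss < params$max_missing_call
  }
  filter_ok <- pass_filter(dos_a) & pass_filter(dos_b) &
    qual > params$min_qual & mq > params$min_mq
  label <- sites$fate
  label[label == "clean" & disc] <- "EXPECT_DISCORDANT"
  label[label == "clean" & !filter_ok] <- "EXPECT_FILTERED"
  label[label == "clean"] <- "TRANSFERABLE_CONCORDANT"

  truth_sites <- data.frame(
    site_id = sprintf("site%05d", seq_len(n)),
    contig_a = sites$contig, pos1_a = sites$pos0 + 1L,
    contig_b = proj$contig_b, pos1_b = proj$b_pos0 + 1L,
    strand = proj$strand, label = label, low_quality = lowq,
    stringsAsFactors = FALSE)
  list(table_a = tab_a, table_b = tab_b, truth_sites = truth_sites)
}

#' Score the reliable set against simulator truth
#'
#' Recall is the fraction of `TRANSFERABLE_CONCORDANT` sites present in
#' the reliable set; precision is the fraction of the reliable set that
#' is `TRANSFERABLE_CONCORDANT`; the confusion table counts kept/excluded
#' sites per truth label.
#'
#' @param reliable A `reliable_set` (A-side coordinates are matched
#'   against `contig_a`, `pos1_a` of the truth).
#' @param truth_sites Truth labels from [simulate_panels()].
#' @return List: `precision`, `recall`, `confusion` (labels x
#'   kept/excluded counts).
#' @export
evaluate_recovery <- function(reliable, truth_sites) {
  if (nrow(truth_sites) == 0L) stop("empty truth")
  rel <- as.data.frame(reliable)
  kept_key <- paste(rel$contig_a, rel$pos1_a)
  truth_key <- paste(truth_sites$contig_a, truth_sites$pos1_a)
  kept <- truth_key %in% kept_key
  tc <- truth_sites$label == "TRANSFERABLE_CONCORDANT"
  confusion <- table(label = truth_sites$label,
                     kept = factor(ifelse(kept, "kept", "excluded"),
                                   levels = c("kept", "excluded")))
  list(precision = if (any(kept)) sum(kept & tc) / sum(kept) else NA_real_,
       recall = if (any(tc)) sum(kept & tc) / sum(tc) else NA_real_,
       confusion = confusion)
}

#' Write the simulator truth table as TSV
#' @param truth_sites Truth labels from [simulate_panels()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_sites <- function(truth_sites, path) {
  utils::write.table(truth_sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
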