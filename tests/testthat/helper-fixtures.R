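# Shared fixtures and independent oracles. Heavyweight objects are
# memoised so the scenario is built once per test run.

.memo <- new.env(parent = emptyenv())

memoise1 <- function(key, builder) {
  if (!exists(key, envir = .memo)) assign(key, builder(), envir = .memo)
  get(key, envir = .memo)
}

# -- small hand-rolled variant tables ---------------------------------------

make_table <- function(contig = "c1", pos1, ref = "A", alt = "G",
                       qual = 50, mq = 50, geno, samples = NULL,
                       version = "v1") {
  geno <- as.matrix(geno)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(geno)))
  n <- length(pos1)
  variant_table(
    sites = data.frame(contig = rep_len(contig, n), pos1 = pos1,
                       ref = rep_len(ref, n), alt = rep_len(alt, n),
                       qual = rep_len(qual, n), mq = rep_len(mq, n),
                       stringsAsFactors = FALSE),
    geno = geno, samples = samples, version = version)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# -- naive both-strand exact-occurrence oracle ------------------------------

naive_occurrences <- function(assembly, query) {
  L <- nchar(query)
  rcq <- flanklift::revcomp(query)
  out <- list()
  for (ct in names(assembly$contigs)) {
    s <- assembly$contigs[[ct]]
    n <- nchar(s)
    if (n < L) next
    starts <- seq_len(n - L + 1L)
    win <- substring(s, starts, starts + L - 1L)
    f <- which(win == query)
    r <- which(win == rcq)
    if (length(f))
      out[[length(out) + 1L]] <- data.frame(contig = ct, start0 = f - 1L,
                                            strand = "+",
                                            stringsAsFactors = FALSE)
    if (length(r))
      out[[length(out) + 1L]] <- data.frame(contig = ct, start0 = r - 1L,
                                            strand = "-",
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(contig = character(0), start0 = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  out[order(out$contig, out$start0, out$strand), , drop = FALSE]
}

# -- per-site brute-force adjudicator of the calling-stage filter -----------

brute_filter_keep <- function(table, params) {
  keep <- logical(nrow(table$sites))
  for (i in seq_len(nrow(table$sites))) {
    q <- table$sites$qual[i]; m <- table$sites$mq[i]
    calls <- table$geno[i, ]
    n_alt <- 0L; n_tot <- 0L; n_miss <- 0L
    for (g in calls) {
      if (is.na(g)) n_miss <- n_miss + 1L
      else { n_alt <- n_alt + g; n_tot <- n_tot + 2L }
    }
    if (n_tot == 0L) { keep[i] <- FALSE; next }
    af <- n_alt / n_tot
    maf <- min(af, 1 - af)
    miss <- n_miss / length(calls)
    keep[i] <- (q > params$min_qual) && (m > params$min_mq) &&
      (maf > params$min_maf) && (miss < params$max_missing_call)
  }
  keep
}

# -- shared simulated scenarios ---------------------------------------------

tiny_scenario <- function() memoise1("tiny", function() {
  ref_a <- simulate_reference(c(20000, 15000), seed = 11, version = "A")
  der <- derive_assembly(
    ref_a,
    edit_spec(sub_rate = 5e-4, n_indels = 4, inv_len = c(500, 1500),
              dup_len = c(600, 900), trans_len = c(500, 800),
              ngap_len = c(50, 100)),
    seed = 12, version = "B")
  sp <- panel_spec(n_samples = 20, n_snps = 100, flank = 100, seed = 13)
  pan <- simulate_panels(ref_a, der$assembly, der$truth, sp)
  c(list(ref_a = ref_a, ref_b = der$assembly, truth = der$truth,
         params = lift_params(flank = 100)), pan)
})

tiny_pipeline <- function() memoise1("tiny_pipe", function() {
  sc <- tiny_scenario()
  run_reconciliation(sc$ref_a, sc$ref_b, sc$table_a, sc$table_b,
                     params = sc$params)
})

default_sc <- function() memoise1("default_sc", function()
  default_scenario(seed = 1L))

default_pipeline <- function() memoise1("default_pipe", function() {
  sc <- default_sc()
  run_reconciliation(sc$ref_a, sc$ref_b, sc$table_a, sc$table_b)
})
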