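# Shared fixtures: alignment-row builders, a brute-force filtering oracle,
# and small deterministic references.

aln_row <- function(query_id = "s1", query_len = 1000L, q_start = 0L,
                    q_end = 100L, strand = "+", ref_id = "chr1",
                    ref_len = 100000L, r_start = 0L, r_end = NULL,
                    matches = NULL, block_len = NULL, mapq = 60L) {
  if (is.null(r_end)) r_end <- r_start + (q_end - q_start)
  if (is.null(block_len)) block_len <- q_end - q_start
  if (is.null(matches)) matches <- block_len
  data.frame(query_id = query_id, query_len = query_len,
             q_start = as.integer(q_start), q_end = as.integer(q_end),
             strand = strand, ref_id = ref_id, ref_len = as.integer(ref_len),
             r_start = as.integer(r_start), r_end = as.integer(r_end),
             matches = as.integer(matches), block_len = as.integer(block_len),
             mapq = as.integer(mapq), stringsAsFactors = FALSE)
}

aln_tab <- function(...) do.call(rbind, list(...))

# Brute-force oracle: enumerate all subsets, keep those where every pair
# obeys the overlap tolerance and no alignment is query-contained in
# another, return the maximum total match weight.
brute_force_best_weight <- function(records, overlap_frac = 0.5) {
  n <- nrow(records)
  if (n == 0L) return(0)
  span <- records$q_end - records$q_start
  ok <- matrix(TRUE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ov <- max(0L, min(records$q_end[i], records$q_end[j]) -
                  max(records$q_start[i], records$q_start[j]))
      contained <- (records$q_start[i] >= records$q_start[j] &&
                      records$q_end[i] <= records$q_end[j]) ||
        (records$q_start[j] >= records$q_start[i] &&
           records$q_end[j] <= records$q_end[i])
      ok[i, j] <- ov <= overlap_frac * min(span[i], span[j]) && !contained
    }
  }
  best <- 0
  for (mask in 0:(2^n - 1)) {
    set <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (all(ok[set, set])) best <- max(best, sum(records$matches[set]))
  }
  best
}

random_instance <- function(n, query_len = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  starts <- sample.int(query_len - 20L, n, replace = TRUE) - 1L
  lens <- sample(10:300, n, replace = TRUE)
  ends <- pmin(starts + lens, query_len)
  do.call(rbind, lapply(seq_len(n), function(i) {
    aln_row(q_start = starts[i], q_end = ends[i],
            ref_id = sample(c("chr1", "chr2"), 1),
            r_start = sample.int(5000L, 1) - 1L,
            matches = sample.int(ends[i] - starts[i], 1))
  }))
}

toy_reference <- function(n_chrom = 3L, len = 50000L, seed = 11L) {
  generate_reference(n_chrom, len, seed = seed)
}

# Perfect tiling assembly: every chromosome is reproduced by `per_chrom`
# equal scaffolds laid end to end; truth alignments are exact.
tiling_assembly <- function(reference, per_chrom = 1L) {
  rows <- list()
  res <- character(0)
  for (e in reference) {
    bounds <- round(seq(0, e$length, length.out = per_chrom + 1L))
    for (j in seq_len(per_chrom)) {
      id <- sprintf("t_%s_%d", e$id, j)
      s <- as.integer(bounds[j]); en <- as.integer(bounds[j + 1L])
      res[id] <- substr(e$residues, s + 1L, en)
      rows[[id]] <- aln_row(query_id = id, query_len = en - s, q_start = 0L,
                            q_end = en - s, ref_id = e$id,
                            ref_len = e$length, r_start = s, r_end = en)
    }
  }
  list(scaffolds = seq_set(res), truth = do.call(rbind, rows))
}

score_truth <- function(sim, reference, ...) {
  score_assembly(sim$scaffolds, filter_chains(sim$truth), reference, ...)
}
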