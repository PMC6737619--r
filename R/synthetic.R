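#' Generate a random toy reference genome
#'
#' Produces random nucleotide chromosomes as a desk-scale stand-in for a real
#' reference build. Deterministic given the seed; the shortest chromosome
#' defines the length scaling factor used when scoring scaffolds.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_lengths Integer vector of chromosome lengths in bp (recycled
#'   to `n_chrom`), each `>= 1000`.
#' @param gc GC content in `[0, 1]` (default 0.41, human-like).
#' @param seed Integer seed.
#' @return A `seq_set` with chromosomes `chr1..chrN`.
#' @export
generate_reference <- function(n_chrom = 5L, chrom_lengths = 500000L,
                               gc = 0.41, seed = 1L) {
  stopifnot(n_chrom >= 1, all(chrom_lengths >= 1000), gc >= 0, gc <= 1)
  set.seed(seed)
  lens <- rep_len(as.integer(chrom_lengths), n_chrom)
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  res <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
  names(res) <- paste0("chr", seq_len(n_chrom))
  seq_set(res)
}

# Draw one scaffold length from the truncated normal used throughout the
# synthetic designs: normal(mean_len, sd_len) clipped to [1, max_len].
draw_length <- function(mean_len, sd_len, max_len) {
  l <- as.integer(round(stats::rnorm(1, mean_len, sd_len)))
  max(1L, min(l, max_len))
}

#' Sample scaffolds from a reference with known truth alignments
#'
#' Emulates an error-free assembly: scaffold lengths are drawn from a normal
#' distribution (truncated to `[1,` chromosome length`]`), source positions
#' are uniform on a chromosome chosen with probability proportional to its
#' length, and scaffolds accumulate until the sampled bases reach
#' `coverage_fold` times the reference size (within one scaffold length).
#' Scaffold residues are copied verbatim from the reference, so each
#' scaffold's true alignment is a single perfect PAF record.
#'
#' @param reference A `seq_set` of reference chromosomes.
#' @param mean_len,sd_len Normal scaffold-length parameters in bp;
#'   `mean_len` must be below the shortest chromosome length.
#' @param coverage_fold Target total sampled bases as a multiple of the
#'   reference size (> 0).
#' @param seed Integer seed.
#' @param prefix Scaffold id prefix.
#' @param with_sequences Materialise scaffold residues (default `TRUE`);
#'   turn off for scoring-only simulations where lengths and truth
#'   alignments suffice.
#' @return List with `scaffolds` (`seq_set`) and `truth` (PAF-layout
#'   `data.frame` of the true alignments).
#' @export
sample_scaffolds <- function(reference, mean_len, sd_len, coverage_fold = 1,
                             seed = 1L, prefix = "scf",
                             with_sequences = TRUE) {
  lens <- seq_lengths(reference)
  stopifnot(mean_len < min(lens), coverage_fold > 0)
  set.seed(seed)
  target <- coverage_fold * sum(as.numeric(lens))
  ids <- character(0)
  rows <- list()
  res <- character(0)
  total <- 0
  i <- 0L
  while (total < target) {
    i <- i + 1L
    chrom <- sample(names(lens), 1L, prob = as.numeric(lens))
    L <- draw_length(mean_len, sd_len, lens[[chrom]])
    start <- as.integer(floor(stats::runif(1, 0, lens[[chrom]] - L + 1)))
    id <- sprintf("%s%05d", prefix, i)
    ids <- c(ids, id)
    rows[[i]] <- data.frame(
      query_id = id, query_len = L, q_start = 0L, q_end = L, strand = "+",
      ref_id = chrom, ref_len = unname(lens[[chrom]]),
      r_start = start, r_end = start + L,
      matches = L, block_len = L, mapq = 60L, stringsAsFactors = FALSE)
    if (with_sequences) {
      res[id] <- extract_interval(reference[[chrom]], start, start + L)
    }
    total <- total + L
  }
  truth <- do.call(rbind, rows)
  scaffolds <- if (with_sequences) {
    seq_set(res)
  } else {
    structure(lapply(seq_along(ids), function(k) {
      new_seq_entry(ids[k], truth$query_len[k],
                    matrix(integer(0), ncol = 2L,
                           dimnames = list(NULL, c("start", "end"))))
    }), names = ids, class = "seq_set")
  }
  list(scaffolds = scaffolds, truth = truth)
}

#' Rebuild a scaffold with a planted number of misassemblies
#'
#' Constructs one scaffold of length `len` as a concatenation of `k + 1`
#' reference segments in which every junction violates collinearity by
#' exactly one event, drawn uniformly from the three types: a relocation
#' with reference offset of magnitude in `(t, 10t]` (unambiguously above
#' threshold yet local), a translocation to a different chromosome, or an
#' inversion on the same chromosome. Counting misassemblies on the truth
#' chain therefore returns exactly `k` at threshold `t`. When a segment sits
#' too close to a chromosome end for the local offset windows to fit, the
#' relocation falls back to any placement with offset magnitude above `t`.
#'
#' @param reference A `seq_set` with at least 2 chromosomes when
#'   translocations can be drawn.
#' @param len Total scaffold length in bp; must allow `k + 1` segments of at
#'   least 500 bp.
#' @param k Number of planted misassemblies (>= 0).
#' @param t Relocation threshold the planted relocations are calibrated
#'   against (default 1000).
#' @param seed Integer seed.
#' @param id Scaffold identifier.
#' @param with_sequences Materialise residues (default `TRUE`).
#' @param types Event types to draw from.
#' @return List with `scaffold` (a `seq_entry`) and `truth` (PAF-layout
#'   `data.frame` with `k + 1` records).
#' @export
plant_misassemblies <- function(reference, len, k, t = 1000L, seed = 1L,
                                id = "scf00001", with_sequences = TRUE,
                                types = c("relocation", "translocation",
                                          "inversion")) {
  stopifnot(k >= 0)
  seg_len <- as.integer(floor(len / (k + 1L)))
  if (seg_len < 500L) {
    stop("scaffold of ", len, " bp too short for ", k,
         " events (+1 segments of >= 500 bp)")
  }
  if (k > 0L && "translocation" %in% types && length(reference) < 2L) {
    stop("translocations require at least two reference chromosomes")
  }
  set.seed(seed)
  lens <- seq_lengths(reference)
  seg_lens <- rep(seg_len, k + 1L)
  seg_lens[k + 1L] <- len - seg_len * k  # absorb the remainder
  # first segment: uniform placement on a length-weighted chromosome
  chrom <- sample(names(lens), 1L, prob = as.numeric(lens))
  strand <- "+"
  start <- as.integer(floor(stats::runif(1, 0, lens[[chrom]] - seg_lens[1L] + 1)))
  segs <- data.frame(chrom = chrom, strand = strand, start = start,
                     end = start + seg_lens[1L], stringsAsFactors = FALSE)
  place_uniform <- function(chrom, L) {
    as.integer(floor(stats::runif(1, 0, lens[[chrom]] - L + 1)))
  }
  for (j in seq_len(k)) {
    prev <- segs[j, ]
    L <- seg_lens[j + 1L]
    ev <- sample(types, 1L)
    if (ev == "translocation") {
      chrom <- sample(setdiff(names(lens), prev$chrom), 1L)
      strand <- sample(c("+", "-"), 1L)
      start <- place_uniform(chrom, L)
    } else if (ev == "inversion") {
      chrom <- prev$chrom
      strand <- if (prev$strand == "+") "-" else "+"
      start <- place_uniform(chrom, L)
    } else {  # relocation: same chrom/strand, offset d with |d| in (t, 10t]
      chrom <- prev$chrom
      strand <- prev$strand
      # feasible segment starts realising |d| in (t, 10t] on either side,
      # clipped to the chromosome
      anchor <- if (strand == "+") prev$end else prev$start - L
      sgn <- if (strand == "+") 1L else -1L
      cand <- rbind(c(anchor + sgn * (t + 1L), anchor + sgn * 10L * t),
                    c(anchor - sgn * 10L * t, anchor - sgn * (t + 1L)))
      cand <- cbind(pmax(pmin(cand[, 1], cand[, 2]), 0L),
                    pmin(pmax(cand[, 1], cand[, 2]), lens[[chrom]] - L))
      cand <- cand[cand[, 1] <= cand[, 2], , drop = FALSE]
      if (nrow(cand) == 0L) {
        # near a chromosome end the (t, 10t] windows may not fit; fall back
        # to any placement with offset magnitude > t
        cand <- rbind(c(0L, anchor - t - 1L),
                      c(anchor + t + 1L, lens[[chrom]] - L))
        cand <- cbind(pmax(cand[, 1], 0L),
                      pmin(cand[, 2], lens[[chrom]] - L))
        cand <- cand[cand[, 1] <= cand[, 2], , drop = FALSE]
      }
      if (nrow(cand) == 0L) {
        stop("cannot place relocation segment within chromosome bounds")
      }
      widths <- cand[, 2] - cand[, 1] + 1L
      side <- sample.int(nrow(cand), 1L, prob = widths)
      start <- cand[side, 1] + sample.int(widths[side], 1L) - 1L
    }
    segs <- rbind(segs, data.frame(chrom = chrom, strand = strand,
                                   start = start, end = start + L,
                                   stringsAsFactors = FALSE))
  }
  q_end <- cumsum(seg_lens)
  q_start <- q_end - seg_lens
  truth <- data.frame(
    query_id = id, query_len = len, q_start = as.integer(q_start),
    q_end = as.integer(q_end), strand = segs$strand, ref_id = segs$chrom,
    ref_len = unname(lens[segs$chrom]), r_start = segs$start,
    r_end = segs$end, matches = seg_lens, block_len = seg_lens, mapq = 60L,
    stringsAsFactors = FALSE)
  residues <- NULL
  if (with_sequences) {
    residues <- paste(vapply(seq_len(nrow(segs)), function(j) {
      extract_interval(reference[[segs$chrom[j]]], segs$start[j],
                       segs$end[j], segs$strand[j])
    }, character(1)), collapse = "")
  }
  scaffold <- new_seq_entry(id, len,
                            matrix(integer(0), ncol = 2L,
                                   dimnames = list(NULL, c("start", "end"))),
                            residues)
  list(scaffold = scaffold, truth = truth)
}

#' Concatenate independent samplings into a redundant assembly
#'
#' Draws `fold` independent 1X scaffold samplings (different sub-seeds) and
#' concatenates them, so the reference is covered about `fold` times and the
#' inverted redundancy ratio approaches `1/fold`.
#'
#' @inheritParams sample_scaffolds
#' @param fold Integer redundancy fold (>= 1).
#' @return List with `scaffolds` and `truth`, as [sample_scaffolds()].
#' @export
replicate_redundancy <- function(reference, mean_len, sd_len, fold = 1L,
                                 seed = 1L, with_sequences = TRUE) {
  stopifnot(fold >= 1)
  parts <- lapply(seq_len(fold), function(f) {
    sample_scaffolds(reference, mean_len, sd_len, coverage_fold = 1,
                     seed = seed * 1000L + f, prefix = sprintf("r%dscf", f),
                     with_sequences = with_sequences)
  })
  scaffolds <- do.call(c, lapply(parts, `[[`, "scaffolds"))
  class(scaffolds) <- "seq_set"
  list(scaffolds = scaffolds,
       truth = do.call(rbind, lapply(parts, `[[`, "truth")))
}

#' Simulate one synthetic assembly design
#'
#' Reproduces the four synthetic study designs used to validate the scoring
#' scheme, each varying one property while holding the others ideal:
#'
#' * `mean_length` — error-free 1X assemblies with normal scaffold lengths
#'   (`level` = mean length; sd = mean/1000, the design's sd-to-mean ratio);
#' * `misassembly` — 1X assemblies whose every scaffold carries `level`
#'   planted misassemblies;
#' * `coverage` — error-free assemblies sampling `level`X of the reference
#'   (`level` in (0, 1]; lengths drawn with sd equal to the mean, the wide
#'   spread this design uses);
#' * `redundancy` — `level` independent 1X samplings concatenated.
#'
#' @param reference A `seq_set`.
#' @param design One of `"mean_length"`, `"misassembly"`, `"coverage"`,
#'   `"redundancy"`.
#' @param level The design's varied parameter (see above).
#' @param seed Integer seed.
#' @param mean_len Scaffold mean length for the designs that do not vary it.
#'   The default, 100 kb, is about one fifth of the default toy reference's
#'   shortest chromosome, mirroring the scaffold-to-chromosome ratio of the
#'   validation datasets this generator emulates.
#' @param t Relocation threshold for planted relocations.
#' @param with_sequences Materialise residues.
#' @return List with `scaffolds`, `truth` and `spec` (the honored
#'   parameters).
#' @export
simulate_assembly <- function(reference, design, level, seed = 1L,
                              mean_len = 100000L, t = 1000L,
                              with_sequences = TRUE) {
  design <- match.arg(design, c("mean_length", "misassembly", "coverage",
                                "redundancy"))
  out <- switch(design,
    mean_length = sample_scaffolds(reference, mean_len = level,
                                   sd_len = level / 1000, coverage_fold = 1,
                                   seed = seed,
                                   with_sequences = with_sequences),
    coverage = sample_scaffolds(reference, mean_len = mean_len,
                                sd_len = mean_len,
                                coverage_fold = level, seed = seed,
                                with_sequences = with_sequences),
    redundancy = replicate_redundancy(reference, mean_len = mean_len,
                                      sd_len = mean_len / 1000,
                                      fold = level, seed = seed,
                                      with_sequences = with_sequences),
    misassembly = {
      base <- sample_scaffolds(reference, mean_len = mean_len,
                               sd_len = mean_len / 1000, coverage_fold = 1,
                               seed = seed, with_sequences = FALSE)
      ids <- seq_ids(base$scaffolds)
      planted <- lapply(seq_along(ids), function(i) {
        plant_misassemblies(reference, len = base$truth$query_len[i],
                            k = level, t = t, seed = seed * 100000L + i,
                            id = ids[i], with_sequences = with_sequences)
      })
      scaffolds <- structure(lapply(planted, `[[`, "scaffold"),
                             names = ids, class = "seq_set")
      list(scaffolds = scaffolds,
           truth = do.call(rbind, lapply(planted, `[[`, "truth")))
    })
  out$spec <- list(design = design, level = level, seed = seed,
                   mean_len = mean_len, t = t)
  out
}
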