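#' Fragment a chromosome into random contiguous pieces (1X coverage)
#'
#' Cuts a chromosome into consecutive, non-overlapping fragments whose
#' lengths are drawn uniformly from `[min_len, max_len]`; the final fragment
#' absorbs the remainder, so the fragments tile the chromosome exactly once.
#' These artificial contigs, aligned back to the reference, reveal how many
#' spurious breakpoints ("artifacts") a perfect sequence of a given length
#' accrues from repeats, gaps and aligner limitations.
#'
#' @param chrom A `seq_entry` for one reference chromosome.
#' @param seed Integer seed; breakpoints are deterministic given the seed.
#' @param min_len,max_len Fragment length bounds in bp. Defaults 50 kb and
#'   1 Mb. A chromosome shorter than `min_len` yields a single fragment.
#' @return `data.frame` with columns `frag_id`, `chrom`, `start`, `end`
#'   (0-based half-open truth coordinates) and `length`.
#' @export
fragment_chromosome <- function(chrom, seed, min_len = 50000L,
                                max_len = 1000000L) {
  stopifnot(inherits(chrom, "seq_entry"), min_len >= 1, min_len <= max_len)
  set.seed(seed)
  L <- chrom$length
  starts <- integer(0)
  ends <- integer(0)
  pos <- 0L
  while (pos < L) {
    len <- as.integer(round(stats::runif(1, min_len, max_len)))
    if (L - pos < min_len || pos + len > L) {
      len <- L - pos  # remainder: the only fragment allowed out of bounds
    }
    starts <- c(starts, pos)
    ends <- c(ends, pos + len)
    pos <- pos + len
  }
  data.frame(
    frag_id = sprintf("%s_frag%04d", chrom$id, seq_along(starts)),
    chrom = chrom$id, start = starts, end = ends,
    length = ends - starts, stringsAsFactors = FALSE)
}

#' Artifact observations over a grid of relocation thresholds
#'
#' For each fragment's filtered chain, counts misassemblies at every
#' relocation threshold in `t_grid`. Translocation and inversion counts do
#' not depend on `t`, so the pair geometry is computed once per chain and
#' only the relocation calls are re-evaluated per threshold.
#'
#' @param chains Named list of `filtered_chain` (fragments aligned back to
#'   the whole reference).
#' @param lengths Named integer vector of fragment lengths (bp), covering at
#'   least the names of `chains`; needed because an unaligned fragment still
#'   contributes observations.
#' @param t_grid Integer thresholds in bp; default 100 to 10,000 in steps of
#'   100.
#' @param query_aware See [classify_pair()].
#' @return `data.frame` with one row per fragment x threshold: `chrom`
#'   (assigned chromosome; `NA` for an unaligned fragment), `l`, `t`, `eps`.
#' @export
artifact_observations <- function(chains, lengths,
                                  t_grid = seq(100L, 10000L, by = 100L),
                                  query_aware = TRUE) {
  stopifnot(length(chains) > 0L, all(names(chains) %in% names(lengths)))
  rows <- lapply(names(chains), function(id) {
    chain <- chains[[id]]
    if (nrow(chain$alignments) == 0L) {
      warning("fragment '", id, "' has no alignments; artifact taken as 0")
      return(data.frame(chrom = NA_character_, l = lengths[[id]], t = t_grid,
                        eps = 0L, stringsAsFactors = FALSE))
    }
    pairs <- pair_inconsistencies(chain$alignments, query_aware = query_aware)
    fixed <- sum(!pairs$same_ref) + sum(pairs$same_ref & !pairs$same_strand)
    d_rel <- abs(pairs$d[pairs$same_ref & pairs$same_strand])
    eps <- vapply(t_grid, function(t) fixed + sum(d_rel > t), numeric(1))
    per_ref <- chain$per_ref_aligned_bp
    cand <- names(per_ref)[per_ref == max(per_ref)]
    data.frame(chrom = min(cand), l = lengths[[id]], t = t_grid, eps = eps,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit the per-chromosome expected-artifact model
#'
#' Fits, separately for each reference chromosome `c`, the linear model
#' `eps = alpha_c * l + beta_c * t + k_c` by ordinary least squares, where
#' `eps` is the misassembly count observed when fragments of the chromosome
#' are aligned back to the reference, `l` is fragment length and `t` the
#' relocation threshold. The fitted surface predicts how many breakpoints a
#' perfectly assembled scaffold of a given length should be forgiven.
#'
#' @param observations `data.frame` from [artifact_observations()]; rows with
#'   `NA` chromosome are dropped.
#' @return An `artifact_model`: `data.frame` with columns `chrom`, `alpha`,
#'   `beta`, `intercept`, one row per chromosome. A chromosome whose design
#'   is rank deficient (e.g. constant `l` and `t`) gets `(0, 0, mean eps)`
#'   with a warning.
#' @export
fit_artifact_model <- function(observations) {
  obs <- observations[!is.na(observations$chrom), , drop = FALSE]
  stopifnot(nrow(obs) > 0L)
  chroms <- sort(unique(obs$chrom))
  coefs <- lapply(chroms, function(ch) {
    d <- obs[obs$chrom == ch, , drop = FALSE]
    fit <- stats::lm(eps ~ l + t, data = d)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      warning("rank-deficient artifact design for chromosome '", ch,
              "'; using intercept-only model")
      return(c(alpha = 0, beta = 0, intercept = mean(d$eps)))
    }
    c(alpha = unname(cf["l"]), beta = unname(cf["t"]),
      intercept = unname(cf["(Intercept)"]))
  })
  out <- cbind(data.frame(chrom = chroms, stringsAsFactors = FALSE),
               as.data.frame(do.call(rbind, coefs)))
  class(out) <- c("artifact_model", "data.frame")
  out
}

#' Expected artifact count for a scaffold
#'
#' Evaluates the calibrated linear model of the scaffold's assigned
#' chromosome at the scaffold's length and the user's relocation threshold,
#' clamped below at zero (a model cannot forgive a negative number of
#' breakpoints).
#'
#' @param model An `artifact_model` from [fit_artifact_model()], or `NULL`
#'   for no calibration (expected artifact 0).
#' @param chrom Assigned chromosome id; a chromosome absent from the model
#'   yields 0 with a warning (no artifact credit).
#' @param l_s Scaffold length in bp.
#' @param t_u Relocation threshold in bp.
#' @return Non-negative numeric expected artifact count.
#' @export
expected_artifact <- function(model, chrom, l_s, t_u) {
  if (is.null(model) || is.na(chrom)) {
    return(0)
  }
  i <- match(chrom, model$chrom)
  if (is.na(i)) {
    warning("no artifact model for chromosome '", chrom,
            "'; expected artifact taken as 0")
    return(0)
  }
  max(0, model$alpha[i] * l_s + model$beta[i] * t_u + model$intercept[i])
}

#' Calibrate the artifact model for a reference genome
#'
#' Fragments every chromosome at 1X (plus the whole chromosome itself as one
#' extra fragment), builds the fragments' alignment chains against the
#' reference, counts misassemblies across the threshold grid and fits the
#' per-chromosome model. In `truth` mode the chains are the fragments' known
#' source intervals — each fragment is one perfect alignment — which is the
#' degenerate calibration appropriate for synthetic references (observed
#' artifacts are all zero). Supplying `paf` instead uses real aligner output
#' for the fragments.
#'
#' @param reference A `seq_set` of reference chromosomes.
#' @param seed Integer seed for fragmentation.
#' @param paf Optional alignment table of the emitted fragments against the
#'   reference; when `NULL`, truth chains are used.
#' @param t_grid Threshold grid; see [artifact_observations()].
#' @param min_len,max_len Fragment length bounds; see
#'   [fragment_chromosome()].
#' @param overlap_frac Chain-filter overlap tolerance.
#' @return List with `model` (an `artifact_model`), `fragments` (the truth
#'   coordinate table) and `observations`.
#' @export
calibrate_reference <- function(reference, seed = 1L, paf = NULL,
                                t_grid = seq(100L, 10000L, by = 100L),
                                min_len = 50000L, max_len = 1000000L,
                                overlap_frac = 0.5) {
  frags <- do.call(rbind, lapply(seq_along(reference), function(i) {
    fragment_chromosome(reference[[i]], seed = seed + i - 1L,
                        min_len = min_len, max_len = max_len)
  }))
  # the whole chromosome joins the pool as one more fragment
  whole <- data.frame(
    frag_id = paste0(seq_ids(reference), "_whole"),
    chrom = seq_ids(reference),
    start = 0L, end = unname(seq_lengths(reference)),
    length = unname(seq_lengths(reference)), stringsAsFactors = FALSE)
  frags <- rbind(frags, whole)
  if (is.null(paf)) {
    paf <- truth_paf_from_fragments(frags, seq_lengths(reference))
  }
  chains <- filter_chains(paf, overlap_frac = overlap_frac)
  lens <- stats::setNames(frags$length, frags$frag_id)
  obs <- artifact_observations(chains, lens, t_grid = t_grid)
  list(model = fit_artifact_model(obs), fragments = frags,
       observations = obs)
}

truth_paf_from_fragments <- function(frags, ref_lens) {
  data.frame(
    query_id = frags$frag_id, query_len = frags$length,
    q_start = 0L, q_end = frags$length, strand = "+",
    ref_id = frags$chrom, ref_len = unname(ref_lens[frags$chrom]),
    r_start = frags$start, r_end = frags$end,
    matches = frags$length, block_len = frags$length, mapq = 60L,
    stringsAsFactors = FALSE)
}

#' Persist or reload calibrated coefficients
#'
#' The model is stored as a 4-column TSV (`chrom`, `alpha`, `beta`,
#' `intercept`) so calibration runs once per reference and can be reused.
#'
#' @param model An `artifact_model`.
#' @param path TSV file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the `artifact_model`.
#' @export
write_calibration <- function(model, path) {
  utils::write.table(as.data.frame(model), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(out), c("chrom", "alpha", "beta", "intercept")))
  class(out) <- c("artifact_model", "data.frame")
  out
}
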