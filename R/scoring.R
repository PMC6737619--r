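#' Scaffold reward: aligned fraction of non-gap bases
#'
#' The reward is the ratio of the scaffold's aligned query bases (the union
#' over its filtered chain, so residual overlaps are not double counted) to
#' its length minus the total scaffolding-gap bases. It is clamped at 1 so
#' the per-scaffold quality stays in `[0, 1]`.
#'
#' @param scaffold A `seq_entry`.
#' @param chain The scaffold's `filtered_chain`.
#' @return Reward in `[0, 1]`. A scaffold that is all gap (zero denominator)
#'   gets reward 0 with a warning.
#' @export
reward <- function(scaffold, chain) {
  denom <- scaffold$length - gap_bp(scaffold)
  if (denom <= 0) {
    warning("scaffold '", scaffold$id,
            "' has no non-gap bases; reward taken as 0")
    return(0)
  }
  min(1, chain$total_aligned_query_bp / denom)
}

#' Misassembly penalty
#'
#' The penalty is the base-100 logarithm of the observed misassembly count
#' minus the expected artifact count, applied only when that difference
#' exceeds 1; a scaffold whose misassemblies are explained by the artifact
#' model (or exceed it by at most one event) is not penalised. With this
#' scale, 100 unexplained events cost a factor of 2 in quality.
#'
#' @param m_s Observed misassembly count (>= 0).
#' @param eps_s Expected artifact count (>= 0).
#' @return Penalty `P >= 0`.
#' @export
penalty <- function(m_s, eps_s) {
  stopifnot(m_s >= 0, eps_s >= 0)
  diff <- m_s - eps_s
  ifelse(diff > 1, log(diff, base = 100), 0)
}

#' Length scaling coefficient
#'
#' Scaffolds at least as long as the shortest reference chromosome
#' (`theta`) score 1; shorter scaffolds are scaled by
#' `-1 / (log10(l_s / theta) - 1)`, a slowly decaying factor in `(0, 1)`
#' chosen so small-to-medium scaffolds are not punished as harshly as a raw
#' length ratio would: one tenth of `theta` scores 0.5, one hundredth scores
#' 1/3.
#'
#' @param l_s Scaffold length(s) in bp.
#' @param theta Shortest reference chromosome length in bp.
#' @return Length scaling in `(0, 1]`, vectorised over `l_s`.
#' @export
length_scaling <- function(l_s, theta) {
  stopifnot(all(l_s >= 1), theta >= 1)
  ifelse(l_s >= theta, 1, -1 / (log10(l_s / theta) - 1))
}

#' Per-scaffold quality score
#'
#' `Q(s) = L(s) * R(s) / (1 + P(s))`: the aligned fraction, discounted by
#' the misassembly penalty and scaled by the length coefficient. All three
#' components keep `Q` in `[0, 1]`.
#'
#' @param R Reward in `[0, 1]`.
#' @param P Penalty `>= 0`.
#' @param L Length scaling in `(0, 1]`.
#' @return Quality in `[0, 1]`, vectorised.
#' @export
scaffold_quality <- function(R, P, L) {
  L * R / (1 + P)
}

#' Score every scaffold of an assembly
#'
#' Combines the chain tallies, misassembly counts, artifact calibration and
#' length scaling into one row per scaffold. Scaffolds without alignments
#' receive reward 0 and quality 0 but still contribute their length to the
#' assembly-level curves.
#'
#' @param entries `seq_set` of assembly scaffolds.
#' @param chains Named list of `filtered_chain` (missing scaffolds are
#'   treated as unaligned).
#' @param reference `seq_set` of reference chromosomes (defines `theta`, the
#'   shortest chromosome length).
#' @param model Optional `artifact_model` for expected-artifact correction.
#' @param t Relocation threshold in bp (default 1000).
#' @param query_aware See [classify_pair()].
#' @return `data.frame` with one row per scaffold: `query_id`, `l_s`,
#'   `gap_bp`, `aligned_query_bp`, `lambda` (aligned reference bp), `m_s`,
#'   `eps_s`, `assigned_chrom`, `R`, `P`, `L`, `Q`.
#' @export
score_scaffolds <- function(entries, chains, reference, model = NULL,
                            t = 1000L, query_aware = TRUE) {
  theta <- min(seq_lengths(reference))
  rows <- lapply(entries, function(e) {
    chain <- chains[[e$id]]
    if (is.null(chain)) {
      chain <- new_chain(e$id, e$length,
                         empty_paf())
    }
    mc <- count_misassemblies(chain, t = t, query_aware = query_aware)
    eps <- expected_artifact(model, mc$assigned_chrom, e$length, t)
    R <- reward(e, chain)
    P <- penalty(mc$m_total, eps)
    L <- length_scaling(e$length, theta)
    data.frame(
      query_id = e$id, l_s = e$length, gap_bp = gap_bp(e),
      aligned_query_bp = chain$total_aligned_query_bp,
      lambda = sum(chain$per_ref_aligned_bp),
      m_s = mc$m_total, eps_s = eps,
      assigned_chrom = if (is.na(mc$assigned_chrom)) NA_character_ else mc$assigned_chrom,
      R = R, P = P, L = L, Q = scaffold_quality(R, P, L),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

quality_thresholds <- function() seq(0, 1, by = 0.01)

trapezoid_area <- function(x, y) {
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Cumulative quality-distribution curve and its area
#'
#' At each quality threshold `q` in 0, 0.01, ..., 1 the curve value is the
#' fraction of assembly base pairs lying in scaffolds with `Q(s) >= q`. The
#' area under this non-increasing step curve (trapezoidal rule on the grid)
#' summarises the quality distribution: 1 when every scaffold is perfect,
#' and close to 0 when all mass sits at low quality.
#'
#' @param scores Scaffold score table from [score_scaffolds()].
#' @return List with `delta` (the area) and `curve`
#'   (`data.frame(threshold, value)`).
#' @export
quality_curve_area <- function(scores) {
  stopifnot(nrow(scores) > 0L)
  total <- sum(as.numeric(scores$l_s))
  qs <- quality_thresholds()
  value <- vapply(qs, function(q) {
    sum(as.numeric(scores$l_s[scores$Q >= q])) / total
  }, numeric(1))
  curve <- data.frame(threshold = qs, value = value)
  list(delta = trapezoid_area(qs, value), curve = curve)
}

# Reference intervals (per chromosome) of each scaffold's chain, as plain
# tables so unions across arbitrary scaffold subsets stay cheap.
chain_ref_intervals <- function(chains) {
  lapply(chains, function(chain) {
    aln <- chain$alignments
    if (nrow(aln) == 0L) {
      return(NULL)
    }
    data.frame(ref_id = aln$ref_id, start = aln$r_start + 1L,
               end = aln$r_end, stringsAsFactors = FALSE)
  })
}

union_size <- function(interval_tabs) {
  # interval_tabs: list over scaffolds of data.frame(ref_id, start, end)
  interval_tabs <- interval_tabs[!vapply(interval_tabs, is.null, logical(1))]
  if (length(interval_tabs) == 0L) return(0)
  tab <- do.call(rbind, interval_tabs)
  sum(vapply(split(seq_len(nrow(tab)), tab$ref_id), function(i) {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(tab$start[i], tab$end[i]))))
  }, numeric(1)))
}

#' Cumulative genome-coverage curve and its area
#'
#' At each quality threshold `q`, the curve value is the fraction of the
#' reference genome covered by the union of the reference intervals of
#' scaffolds with `Q(s) >= q`. The denominator is the total reference length
#' including ambiguous bases. The area under the curve rewards assemblies
#' that cover most of the genome with high-quality scaffolds; its value at
#' `q = 0` gives the total covered reference size.
#'
#' @param scores Scaffold score table from [score_scaffolds()].
#' @param chains Named list of `filtered_chain` for the scored scaffolds.
#' @param reference `seq_set` of reference chromosomes.
#' @return List with `omega` (the area), `curve`
#'   (`data.frame(threshold, value)`) and `phi` (covered reference bp at
#'   threshold 0).
#' @export
coverage_curve_area <- function(scores, chains, reference) {
  total_ref <- sum(as.numeric(seq_lengths(reference)))
  ivs <- chain_ref_intervals(chains[intersect(scores$query_id,
                                              names(chains))])
  q_of <- stats::setNames(scores$Q, scores$query_id)
  qs <- quality_thresholds()
  value <- vapply(qs, function(q) {
    inc <- names(ivs)[q_of[names(ivs)] >= q]
    union_size(ivs[inc]) / total_ref
  }, numeric(1))
  phi <- union_size(ivs)
  list(omega = trapezoid_area(qs, value),
       curve = data.frame(threshold = qs, value = value), phi = phi)
}

#' Inverted redundancy ratio
#'
#' The covered reference size divided by the summed per-scaffold aligned
#' reference bases. Within a scaffold, overlapping reference intervals count
#' once; across scaffolds they count per scaffold, so a region assembled by
#' k scaffolds contributes k times to the denominator and the ratio falls to
#' 1/k. With no redundancy the ratio is 1.
#'
#' @param scores Scaffold score table (column `lambda` holds each scaffold's
#'   aligned reference bp).
#' @param phi Covered reference size in bp (union over all scaffolds).
#' @return `Pi` in `(0, 1]`, or 0 with a warning when nothing aligns.
#' @export
inverted_redundancy <- function(scores, phi) {
  sum_lambda <- sum(as.numeric(scores$lambda))
  if (sum_lambda <= 0) {
    warning("no aligned reference bases; inverted redundancy undefined, using 0")
    return(0)
  }
  phi / sum_lambda
}

#' Consolidated assembly quality score
#'
#' The geometric mean of the three assembly components: area under the
#' quality-distribution curve, area under the genome-coverage curve and the
#' inverted redundancy ratio. Each lies in `[0, 1]`, so the score does too.
#'
#' @param delta,omega,pi_a The three components.
#' @return `Q(A) = (delta * omega * pi_a)^(1/3)`.
#' @export
assembly_quality <- function(delta, omega, pi_a) {
  stopifnot(delta >= 0, delta <= 1, omega >= 0, omega <= 1,
            pi_a >= 0, pi_a <= 1 + 1e-9)
  (delta * omega * pi_a)^(1 / 3)
}

#' Score an assembly against a reference
#'
#' Runs the full per-scaffold and assembly-level scoring given already
#' filtered chains: scaffold scores, the two cumulative curves, the
#' redundancy tallies and the consolidated score.
#'
#' @inheritParams score_scaffolds
#' @return An `assembly_score`: list with `scaffolds` (score table),
#'   `delta`, `omega`, `pi`, `quality`, `phi`, `sum_lambda`, `theta`,
#'   `quality_curve`, `coverage_curve`.
#' @export
score_assembly <- function(entries, chains, reference, model = NULL,
                           t = 1000L, query_aware = TRUE) {
  scores <- score_scaffolds(entries, chains, reference, model = model,
                            t = t, query_aware = query_aware)
  qc <- quality_curve_area(scores)
  cc <- coverage_curve_area(scores, chains, reference)
  pi_a <- inverted_redundancy(scores, cc$phi)
  structure(list(
    scaffolds = scores,
    delta = qc$delta, omega = cc$omega, pi = pi_a,
    quality = assembly_quality(qc$delta, cc$omega, pi_a),
    phi = cc$phi, sum_lambda = sum(as.numeric(scores$lambda)),
    theta = min(seq_lengths(reference)),
    quality_curve = qc$curve, coverage_curve = cc$curve
  ), class = "assembly_score")
}

#' @export
print.assembly_score <- function(x, ...) {
  cat("<assembly_score>\n")
  cat(sprintf("  scaffolds scored : %d\n", nrow(x$scaffolds)))
  cat(sprintf("  quality-dist area (delta) : %.4f\n", x$delta))
  cat(sprintf("  coverage area (omega)     : %.4f\n", x$omega))
  cat(sprintf("  inverted redundancy (pi)  : %.4f\n", x$pi))
  cat(sprintf("  assembly quality Q(A)     : %.4f\n", x$quality))
  invisible(x)
}
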