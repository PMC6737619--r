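#' Classify the breakpoint between two consecutive alignments
#'
#' Given two alignments that are consecutive in query order, assigns at most
#' one misassembly class with precedence translocation > inversion >
#' relocation:
#'
#' * **translocation** — the two segments align to different reference
#'   chromosomes;
#' * **inversion** — same chromosome, opposite strands;
#' * **relocation** — same chromosome and strand, but the strand-consistent
#'   reference separation disagrees with the query separation by more than
#'   `t` bp in either direction (a gap, or an overlap, on the reference).
#'
#' By default the relocation distance is `d = reference separation - query
#' separation`, so a scaffold joint whose N gap matches the true genomic
#' distance is not penalised. For `-`-strand pairs the reference separation is
#' measured against descending reference order. With `query_aware = FALSE`
#' the raw reference separation is used instead.
#'
#' @param a,b Single alignment rows ([parse_paf()] layout), `a` preceding `b`
#'   on the query.
#' @param t Relocation threshold in bp (default 1000): separations of at most
#'   `t` are not relocations.
#' @param query_aware Subtract the query-side separation from the reference
#'   separation before thresholding (default `TRUE`).
#' @return One of `"none"`, `"relocation"`, `"translocation"`, `"inversion"`.
#' @export
classify_pair <- function(a, b, t = 1000L, query_aware = TRUE) {
  stopifnot(t >= 1)
  p <- pair_inconsistencies(rbind(as.data.frame(a), as.data.frame(b)),
                            query_aware = query_aware)
  classify_from_pairs(p, t)
}

# Per-adjacent-pair geometry for a query-sorted alignment table: whether the
# pair shares chromosome and strand, and the relocation distance d.
pair_inconsistencies <- function(aln, query_aware = TRUE) {
  n <- nrow(aln)
  if (n < 2L) {
    return(data.frame(same_ref = logical(0), same_strand = logical(0),
                      d = numeric(0), ref_a = character(0),
                      ref_b = character(0)))
  }
  i <- seq_len(n - 1L)
  j <- i + 1L
  same_ref <- aln$ref_id[i] == aln$ref_id[j]
  same_strand <- aln$strand[i] == aln$strand[j]
  qsep <- aln$q_start[j] - aln$q_end[i]
  # strand-consistent reference separation: '-' pairs run down the reference
  rsep <- ifelse(aln$strand[i] == "+",
                 aln$r_start[j] - aln$r_end[i],
                 aln$r_start[i] - aln$r_end[j])
  d <- if (query_aware) rsep - qsep else rsep
  data.frame(same_ref = same_ref, same_strand = same_strand, d = d,
             ref_a = aln$ref_id[i], ref_b = aln$ref_id[j])
}

classify_from_pairs <- function(pairs, t) {
  cls <- rep("none", nrow(pairs))
  cls[!pairs$same_ref] <- "translocation"
  inv <- pairs$same_ref & !pairs$same_strand
  cls[inv] <- "inversion"
  rel <- pairs$same_ref & pairs$same_strand & abs(pairs$d) > t
  cls[rel] <- "relocation"
  cls
}

#' Count misassemblies along a scaffold's filtered chain
#'
#' Applies [classify_pair()] to every adjacent pair of the query-ordered
#' chain and aggregates the three event counts into the scaffold's total
#' misassembly count. The scaffold is also assigned to the reference
#' chromosome that receives most of its aligned bases (ties broken by
#' lexicographically smallest chromosome id), which selects the artifact
#' model used in the penalty.
#'
#' @param chain A `filtered_chain` from [filter_chain()].
#' @param t Relocation threshold in bp (default 1000).
#' @param query_aware See [classify_pair()].
#' @return A list of class `misassembly_count` with `query_id`,
#'   `n_relocation`, `n_translocation`, `n_inversion`, `m_total`,
#'   `assigned_chrom` (`NA` for an unaligned scaffold) and `events`, a
#'   per-pair diagnostic `data.frame` (pair index, class, d, flanking
#'   reference ids).
#' @export
count_misassemblies <- function(chain, t = 1000L, query_aware = TRUE) {
  stopifnot(inherits(chain, "filtered_chain"), t >= 1)
  pairs <- pair_inconsistencies(chain$alignments, query_aware = query_aware)
  cls <- classify_from_pairs(pairs, t)
  events <- data.frame(
    query_id = rep(chain$query_id, length(cls)),
    pair = seq_along(cls), class = cls, d = pairs$d,
    ref_a = pairs$ref_a, ref_b = pairs$ref_b,
    stringsAsFactors = FALSE)
  per_ref <- chain$per_ref_aligned_bp
  assigned <- if (length(per_ref) == 0L) {
    NA_character_
  } else {
    cand <- names(per_ref)[per_ref == max(per_ref)]
    min(cand)
  }
  structure(list(
    query_id = chain$query_id,
    n_relocation = sum(cls == "relocation"),
    n_translocation = sum(cls == "translocation"),
    n_inversion = sum(cls == "inversion"),
    m_total = sum(cls != "none"),
    assigned_chrom = assigned,
    events = events
  ), class = "misassembly_count")
}

#' @export
print.misassembly_count <- function(x, ...) {
  cat(sprintf(
    "<misassembly_count> %s: %d total (%d relocation, %d translocation, %d inversion), chrom %s\n",
    x$query_id, x$m_total, x$n_relocation, x$n_translocation, x$n_inversion,
    x$assigned_chrom))
  invisible(x)
}

#' Write per-scaffold breakpoint diagnostics as TSV
#'
#' @param counts List of `misassembly_count` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(counts, path) {
  tab <- do.call(rbind, lapply(counts, `[[`, "events"))
  if (is.null(tab)) {
    tab <- data.frame(query_id = character(0), pair = integer(0),
                      class = character(0), d = numeric(0),
                      ref_a = character(0), ref_b = character(0))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
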