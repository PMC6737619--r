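#' Reduce a scaffold's alignments to its longest consistent chain
#'
#' Adapts the delta-filter idea of keeping the best consistent set of local
#' alignments, restricted deliberately to the query axis: reference
#' coordinates impose no constraint, so translocations, inversions and
#' relocations survive filtering and can be counted downstream as
#' misassemblies. The retained subset maximises total exact matches subject
#' to the rule that any two retained alignments may overlap on the query by
#' at most `overlap_frac` times the shorter alignment's query span, and that
#' no retained alignment is fully contained in another retained alignment's
#' query interval. The optimum is found exactly: alignments are grouped into
#' connected components of the pairwise-conflict graph and each component is
#' solved by branch-and-bound with a suffix-weight bound.
#'
#' Ties between equal-weight optima are broken deterministically: prefer the
#' subset with the larger union of query intervals, then the lexicographically
#' smallest sequence of `(q_start, ref_id)` pairs.
#'
#' @param records Alignment `data.frame` rows ([parse_paf()] layout) sharing
#'   one `query_id`. May have zero rows (an unaligned scaffold).
#' @param overlap_frac Allowed pairwise query overlap as a fraction of the
#'   shorter alignment's query span, in `[0, 1]`. Default 0.5.
#' @return A `filtered_chain`: list with `query_id`, `query_len`,
#'   `alignments` (retained rows sorted by `q_start`),
#'   `total_aligned_query_bp` (union of retained query intervals) and
#'   `per_ref_aligned_bp` (named vector, union of retained reference
#'   intervals per chromosome).
#' @export
filter_chain <- function(records, overlap_frac = 0.5) {
  stopifnot(overlap_frac >= 0, overlap_frac <= 1)
  if (nrow(records) == 0L) {
    return(new_chain(NA_character_, NA_integer_, records))
  }
  qid <- unique(records$query_id)
  if (length(qid) != 1L) {
    stop("filter_chain expects alignments of a single query, got: ",
         paste(qid, collapse = ", "))
  }
  # canonical order makes every downstream tie-break reproducible
  records <- records[order(records$q_start, records$q_end, records$ref_id,
                           records$r_start), , drop = FALSE]
  n <- nrow(records)
  keep <- solve_max_weight(records, overlap_frac)
  new_chain(qid, records$query_len[1L], records[keep, , drop = FALSE])
}

#' Filter all scaffolds' alignments
#'
#' Splits an alignment table by `query_id` and applies [filter_chain()] to
#' each scaffold's records.
#'
#' @inheritParams filter_chain
#' @param paf Alignment `data.frame` from [parse_paf()].
#' @return Named list of `filtered_chain`, one per query present.
#' @export
filter_chains <- function(paf, overlap_frac = 0.5) {
  if (nrow(paf) == 0L) return(stats::setNames(list(), character(0)))
  by_q <- split(seq_len(nrow(paf)), paf$query_id)
  lapply(by_q, function(idx) {
    filter_chain(paf[idx, , drop = FALSE], overlap_frac)
  })
}

new_chain <- function(query_id, query_len, alignments) {
  chain <- structure(
    list(query_id = query_id, query_len = query_len,
         alignments = alignments,
         total_aligned_query_bp = 0L,
         per_ref_aligned_bp = stats::setNames(integer(0), character(0))),
    class = "filtered_chain")
  resolve_residual_overlaps(chain)
}

#' @export
print.filtered_chain <- function(x, ...) {
  cat(sprintf("<filtered_chain> %s: %d alignment(s), %d query bp aligned\n",
              x$query_id, nrow(x$alignments), x$total_aligned_query_bp))
  invisible(x)
}

#' Recompute a chain's aligned base-pair tallies from interval unions
#'
#' The retained alignments may still overlap slightly (up to the allowed
#' fraction), so aligned bases are counted as exact interval unions rather
#' than sums: `total_aligned_query_bp` is the union of the query intervals
#' and `per_ref_aligned_bp` the union of the reference intervals per
#' chromosome. This prevents double counting in the reward and redundancy
#' computations.
#'
#' @param chain A `filtered_chain`.
#' @return The chain with both tallies recomputed.
#' @export
resolve_residual_overlaps <- function(chain) {
  aln <- chain$alignments
  if (is.null(aln) || nrow(aln) == 0L) {
    chain$total_aligned_query_bp <- 0L
    chain$per_ref_aligned_bp <- stats::setNames(integer(0), character(0))
    return(chain)
  }
  qr <- IRanges::IRanges(start = aln$q_start + 1L, end = aln$q_end)
  chain$total_aligned_query_bp <- sum(IRanges::width(IRanges::reduce(qr)))
  rr <- IRanges::IRanges(start = aln$r_start + 1L, end = aln$r_end)
  per_ref <- vapply(split(rr, aln$ref_id), function(x) {
    sum(IRanges::width(IRanges::reduce(x)))
  }, integer(1))
  chain$per_ref_aligned_bp <- per_ref
  chain
}

# Query overlap of alignment pairs i, j (vectors), in bp.
pair_overlap <- function(records, i, j) {
  pmax(0L, pmin(records$q_end[i], records$q_end[j]) -
         pmax(records$q_start[i], records$q_start[j]))
}

# Exact maximum-weight subset under the pairwise overlap/containment
# constraint. Returns row indices of the retained alignments.
solve_max_weight <- function(records, overlap_frac) {
  n <- nrow(records)
  if (n == 1L) return(1L)
  span <- records$q_end - records$q_start
  # conflict matrix: overlap beyond tolerance, or query containment
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    ov <- pair_overlap(records, rep(i, length(j)), j)
    contained <- (records$q_start[j] >= records$q_start[i] &
                    records$q_end[j] <= records$q_end[i]) |
      (records$q_start[i] >= records$q_start[j] &
         records$q_end[i] <= records$q_end[j])
    bad <- ov > overlap_frac * pmin(span[i], span[j]) | contained
    conflict[i, j] <- conflict[j, i] <- bad
  }
  comp <- graph_components(conflict)
  keep <- logical(n)
  for (members in comp) {
    if (length(members) == 1L) {
      keep[members] <- TRUE
    } else {
      keep[members[solve_component(records[members, , drop = FALSE],
                                   conflict[members, members,
                                            drop = FALSE])]] <- TRUE
    }
  }
  which(keep)
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp_id <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp_id[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp_id[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp_id == 0L)
      comp_id[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  split(seq_len(n), comp_id)
}

# Branch-and-bound over one conflict component. Vertices are taken in
# decreasing weight order; a branch is cut when even keeping every remaining
# vertex cannot beat the incumbent weight. Equal-weight branches are kept so
# the deterministic tie-break (larger query union, then smallest
# (q_start, ref_id) sequence) sees all optima.
solve_component <- function(records, conflict) {
  n <- nrow(records)
  w <- as.numeric(records$matches)
  ord <- order(-w, records$q_start, records$ref_id)
  suffix <- rev(cumsum(rev(w[ord])))
  best <- list(weight = -1, union = -1L, key = "", set = integer(0))

  tie_key <- function(set) {
    s <- set[order(records$q_start[set], records$ref_id[set])]
    paste(sprintf("%012d", records$q_start[s]), records$ref_id[s],
          collapse = "|")
  }
  q_union <- function(set) {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(records$q_start[set] + 1L, records$q_end[set]))))
  }

  rec <- function(pos, set, weight) {
    if (pos > n) {
      if (weight > best$weight) {
        best <<- list(weight = weight, union = q_union(set),
                      key = tie_key(set), set = set)
      } else if (weight == best$weight) {
        u <- q_union(set)
        k <- tie_key(set)
        if (u > best$union || (u == best$union && k < best$key)) {
          best <<- list(weight = weight, union = u, key = k, set = set)
        }
      }
      return(invisible(NULL))
    }
    if (weight + suffix[pos] < best$weight) return(invisible(NULL))
    v <- ord[pos]
    if (!any(conflict[v, set])) {
      rec(pos + 1L, c(set, v), weight + w[v])
    }
    rec(pos + 1L, set, weight)
    invisible(NULL)
  }
  rec(1L, integer(0), 0)
  sort(best$set)
}
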