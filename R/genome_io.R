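#' Detect scaffolding gaps in a nucleotide sequence
#'
#' A scaffolding gap is a maximal run of ambiguous bases (`N`/`n`) of length at
#' least `min_gap_len`, typically inserted between contigs during scaffolding.
#' Shorter N runs are treated as ordinary ambiguous bases, not gaps. Gap bases
#' are excluded from the denominator of the scaffold reward.
#'
#' @param residues Character scalar of nucleotide residues. Case-insensitive;
#'   characters other than `N`/`n` are never part of a gap.
#' @param min_gap_len Minimum run length (bp) for a run of Ns to count as a
#'   scaffolding gap. Default 10.
#' @return Integer matrix with columns `start`, `end`: sorted, non-overlapping
#'   0-based half-open intervals. Zero rows when there is no gap.
#' @examples
#' detect_gaps("ACGNNNNNNNNNNNACGT", 10)  # one 11-bp run -> (3, 14)
#' detect_gaps("NNAANNN", 3)              # only the 3-run qualifies
#' @export
detect_gaps <- function(residues, min_gap_len = 10L) {
  stopifnot(is.character(residues), length(residues) == 1L, min_gap_len >= 1)
  m <- gregexpr("[Nn]+", residues)[[1L]]
  out <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  if (m[1L] == -1L) {
    return(out)
  }
  len <- attr(m, "match.length")
  keep <- len >= min_gap_len
  if (!any(keep)) {
    return(out)
  }
  start0 <- as.integer(m[keep]) - 1L
  cbind(start = start0, end = start0 + as.integer(len[keep]))
}

new_seq_entry <- function(id, length, gaps, residues = NULL) {
  structure(
    list(id = id, length = as.integer(length), gaps = gaps,
         residues = residues),
    class = "seq_entry"
  )
}

#' @export
print.seq_entry <- function(x, ...) {
  cat(sprintf("<seq_entry> %s: %d bp, %d gap interval(s), %d gap bp\n",
              x$id, x$length, nrow(x$gaps), gap_bp(x)))
  invisible(x)
}

#' Total scaffolding-gap base pairs of a sequence entry
#'
#' @param entry A `seq_entry` as returned by [read_fasta()].
#' @return Integer, the summed widths of the entry's gap intervals.
#' @export
gap_bp <- function(entry) {
  if (nrow(entry$gaps) == 0L) return(0L)
  sum(entry$gaps[, "end"] - entry$gaps[, "start"])
}

#' Sequence lengths of a sequence set
#'
#' @param entries A `seq_set` (list of `seq_entry`).
#' @return Named integer vector of lengths in bp.
#' @export
seq_lengths <- function(entries) {
  vapply(entries, function(e) e$length, integer(1),
         USE.NAMES = FALSE) |> stats::setNames(seq_ids(entries))
}

#' Sequence identifiers of a sequence set
#' @param entries A `seq_set`.
#' @return Character vector of record identifiers, in set order.
#' @export
seq_ids <- function(entries) {
  unname(vapply(entries, function(e) e$id, character(1)))
}

#' Read a FASTA file into a sequence set
#'
#' Each record becomes a `seq_entry` holding its identifier, length, detected
#' scaffolding-gap intervals and (optionally) its residues. Multi-line records
#' and mixed-case residues are handled; the identifier is the first
#' whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @param min_gap_len Minimum N-run length (bp) treated as a scaffolding gap;
#'   see [detect_gaps()].
#' @param keep_residues Keep the residue strings in the returned entries
#'   (needed to re-write FASTA or extract subsequences). Default `TRUE`.
#' @return A `seq_set`: list of `seq_entry`, in file order.
#' @export
read_fasta <- function(path, min_gap_len = 10L, keep_residues = TRUE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- Biostrings::width(set)
  if (any(lens == 0L)) {
    stop("empty FASTA record(s): ", paste(ids[lens == 0L], collapse = ", "))
  }
  entries <- vector("list", length(set))
  for (i in seq_along(set)) {
    res <- as.character(set[[i]])
    entries[[i]] <- new_seq_entry(
      id = ids[i], length = lens[i],
      gaps = detect_gaps(res, min_gap_len),
      residues = if (keep_residues) res else NULL
    )
  }
  structure(entries, names = ids, class = "seq_set")
}

#' Write a sequence set to a FASTA file
#'
#' @param entries A `seq_set` whose entries carry residues.
#' @param path Output file path.
#' @param width Line width for wrapped sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(entries, path, width = 70L) {
  res <- lapply(entries, function(e) {
    if (is.null(e$residues)) {
      stop("entry '", e$id, "' has no residues; cannot write FASTA")
    }
    e$residues
  })
  set <- Biostrings::BStringSet(unlist(res, use.names = FALSE))
  names(set) <- seq_ids(entries)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Build a sequence set from named residue strings
#'
#' Convenience constructor used by the synthetic generator and in tests.
#'
#' @param residues Named character vector of sequences.
#' @param min_gap_len Minimum N-run length (bp) treated as a scaffolding gap.
#' @return A `seq_set`.
#' @export
seq_set <- function(residues, min_gap_len = 10L) {
  stopifnot(is.character(residues), !is.null(names(residues)),
            !anyDuplicated(names(residues)))
  entries <- lapply(seq_along(residues), function(i) {
    new_seq_entry(names(residues)[i], nchar(residues[[i]]),
                  detect_gaps(residues[[i]], min_gap_len), residues[[i]])
  })
  structure(entries, names = names(residues), class = "seq_set")
}

paf_cols <- c("query_id", "query_len", "q_start", "q_end", "strand",
              "ref_id", "ref_len", "r_start", "r_end", "matches",
              "block_len", "mapq")
paf_int_cols <- setdiff(paf_cols, c("query_id", "strand", "ref_id"))

#' Parse a PAF alignment file
#'
#' Reads the 12 mandatory tab-separated PAF columns (minimap2 dialect) into an
#' alignment table; optional SAM-like tag columns are ignored. All coordinates
#' are 0-based half-open on the forward strand of query and reference; for
#' `-`-strand alignments the query coordinates still refer to the forward
#' query strand, per the PAF convention.
#'
#' @param path Path to a PAF file. An empty file yields a zero-row table.
#' @return A `data.frame` with columns `query_id`, `query_len`, `q_start`,
#'   `q_end`, `strand`, `ref_id`, `ref_len`, `r_start`, `r_end`, `matches`,
#'   `block_len`, `mapq`.
#' @export
parse_paf <- function(path) {
  if (!file.exists(path)) {
    stop("PAF file not found: ", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_paf())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1L]
    stop("malformed PAF line ", bad, ": expected >= 12 columns, got ", nf[bad])
  }
  df <- as.data.frame(do.call(rbind, lapply(fields, `[`, 1:12)),
                      stringsAsFactors = FALSE)
  names(df) <- paf_cols
  for (col in paf_int_cols) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v)) {
      stop("malformed PAF line ", which(is.na(v))[1L],
           ": non-integer value in column '", col, "'")
    }
    df[[col]] <- v
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("malformed PAF line ", which(!df$strand %in% c("+", "-"))[1L],
         ": strand must be '+' or '-'")
  }
  bad <- df$q_end <= df$q_start | df$q_start < 0L | df$q_end > df$query_len |
    df$r_end <= df$r_start | df$r_start < 0L | df$r_end > df$ref_len
  if (any(bad)) {
    stop("malformed PAF line ", which(bad)[1L],
         ": invalid interval coordinates")
  }
  df
}

empty_paf <- function() {
  df <- as.data.frame(stats::setNames(
    c(list(character(0)), rep(list(integer(0)), 3), list(character(0)),
      list(character(0)), rep(list(integer(0)), 5), list(integer(0))),
    paf_cols))
  df$strand <- character(0)
  df
}

#' Write an alignment table as PAF
#'
#' @param paf Alignment `data.frame` in the layout produced by [parse_paf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  stopifnot(all(paf_cols %in% names(paf)))
  utils::write.table(paf[, paf_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Partition an assembly into approximately equal-sized parts
#'
#' Assigns scaffolds to `n_parts` partitions so that the total base pairs per
#' partition are as balanced as greedy longest-first placement allows: each
#' scaffold, from longest to shortest, goes to the currently lightest
#' partition. The imbalance (max load minus min load) never exceeds the
#' longest scaffold length. Partitioning is a scheduling plan only and never
#' changes results; it exists so partitions can be aligned in parallel.
#'
#' @param entries A `seq_set`.
#' @param n_parts Number of partitions, `>= 1` (default 1: everything in one
#'   partition).
#' @return A list of class `partition_plan` with `n_parts`, `assignments`
#'   (named integer vector, scaffold id -> partition index in `[0, n_parts)`)
#'   and `loads` (total bp per partition).
#' @export
partition_assembly <- function(entries, n_parts = 1L) {
  if (n_parts < 1L) {
    stop("n_parts must be >= 1, got ", n_parts)
  }
  n_parts <- as.integer(n_parts)
  lens <- seq_lengths(entries)
  ord <- order(-lens, names(lens))  # longest first, id tie-break
  loads <- numeric(n_parts)
  assign <- integer(length(lens))
  names(assign) <- names(lens)
  for (i in ord) {
    p <- which.min(loads)  # lightest, lowest index on ties
    assign[i] <- p - 1L
    loads[p] <- loads[p] + lens[i]
  }
  structure(list(n_parts = n_parts, assignments = assign, loads = loads),
            class = "partition_plan")
}

#' Extract a subsequence on the forward or reverse strand
#'
#' @param entry A `seq_entry` with residues.
#' @param start,end 0-based half-open interval on the forward strand.
#' @param strand `"+"` for the forward sequence, `"-"` for its reverse
#'   complement.
#' @return Character scalar of residues.
#' @keywords internal
extract_interval <- function(entry, start, end, strand = "+") {
  stopifnot(!is.null(entry$residues), start >= 0, end <= entry$length,
            start < end)
  s <- substr(entry$residues, start + 1L, end)
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}
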