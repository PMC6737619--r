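#' Pipeline configuration
#'
#' Bundles every tunable of a scoring run with its default: the relocation
#' threshold (1000 bp), the chain-filter overlap tolerance (0.5), the
#' minimum N-run length treated as a scaffolding gap (10 bp) and the number
#' of partitions for parallel alignment scheduling (1).
#'
#' @param reference Path to the reference FASTA.
#' @param assembly Path to the assembly FASTA.
#' @param alignments Path to a PAF file of assembly-vs-reference alignments
#'   (aligner output, or a truth PAF from the synthetic generator).
#' @param out_dir Optional output directory for report files.
#' @param t Relocation threshold in bp (default 1000).
#' @param overlap_frac Chain-filter overlap tolerance (default 0.5).
#' @param min_gap_len Minimum scaffolding-gap length in bp (default 10).
#' @param n_parts Partition count for the alignment plan (default 1).
#' @param seed Integer seed, recorded in the report (and used by
#'   calibration when requested).
#' @param calibration Optional path to a calibration TSV
#'   ([write_calibration()]) or an `artifact_model`; `NULL` disables the
#'   expected-artifact correction.
#' @param aligner_mode `"truth-paf"` (alignments are trusted as given) or
#'   `"external"` (alignments came from an external aligner); both read the
#'   same PAF dialect.
#' @param query_aware Relocation distance convention; see [classify_pair()].
#' @return A `run_config` list.
#' @export
run_config <- function(reference, assembly, alignments, out_dir = NULL,
                       t = 1000L, overlap_frac = 0.5, min_gap_len = 10L,
                       n_parts = 1L, seed = 1L, calibration = NULL,
                       aligner_mode = c("truth-paf", "external"),
                       query_aware = TRUE) {
  stopifnot(t >= 1, n_parts >= 1)
  structure(list(
    reference = reference, assembly = assembly, alignments = alignments,
    out_dir = out_dir, t = as.integer(t), overlap_frac = overlap_frac,
    min_gap_len = as.integer(min_gap_len), n_parts = as.integer(n_parts),
    seed = as.integer(seed), calibration = calibration,
    aligner_mode = match.arg(aligner_mode), query_aware = query_aware
  ), class = "run_config")
}

#' Run the full scoring pipeline
#'
#' Reads the reference and assembly, ingests PAF alignments, filters each
#' scaffold's alignments to its longest consistent chain, counts
#' misassemblies, applies the artifact calibration if provided and computes
#' the per-scaffold and assembly scores. When `out_dir` is set, writes the
#' report files: `scaffolds.tsv`, `assembly.json`, `quality_curve.csv`,
#' `coverage_curve.csv`, `bins.tsv` and `events.tsv`. The run is
#' deterministic given the configuration: re-running writes byte-identical
#' reports.
#'
#' @param config A `run_config`.
#' @return An `assembly_score` (invisibly the same object that is
#'   reported), with the configuration attached as attribute `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$reference, config$assembly, config$alignments)) {
    if (!file.exists(p)) stop("input not found: ", p)
  }
  reference <- read_fasta(config$reference, min_gap_len = config$min_gap_len,
                          keep_residues = FALSE)
  assembly <- read_fasta(config$assembly, min_gap_len = config$min_gap_len,
                         keep_residues = FALSE)
  paf <- parse_paf(config$alignments)
  unknown <- setdiff(unique(paf$query_id), seq_ids(assembly))
  if (length(unknown)) {
    stop("alignments reference scaffolds absent from the assembly: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  model <- config$calibration
  if (is.character(model)) model <- read_calibration(model)

  # per-partition filtering; partitioning is scheduling only, results are
  # reduced in scaffold-id order and identical to a serial run
  plan <- partition_assembly(assembly, config$n_parts)
  chains <- list()
  for (p in seq_len(plan$n_parts) - 1L) {
    ids <- names(plan$assignments)[plan$assignments == p]
    sub <- paf[paf$query_id %in% ids, , drop = FALSE]
    chains <- c(chains, filter_chains(sub, config$overlap_frac))
  }
  chains <- chains[order(names(chains))]

  result <- score_assembly(assembly, chains, reference, model = model,
                           t = config$t, query_aware = config$query_aware)
  attr(result, "config") <- config
  if (!is.null(config$out_dir)) {
    write_reports(result, chains, config)
  }
  invisible(result)
}

write_reports <- function(result, chains, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  utils::write.table(result$scaffolds, out("scaffolds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(result$quality_curve, out("quality_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(result$coverage_curve, out("coverage_curve.csv"),
                   row.names = FALSE)
  bins <- bin_quality_scores(result$scaffolds)
  utils::write.table(bins, out("bins.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  counts <- lapply(chains, count_misassemblies, t = config$t,
                   query_aware = config$query_aware)
  write_event_table(counts, out("events.tsv"))
  report <- list(
    delta = result$delta, omega = result$omega, pi = result$pi,
    quality = result$quality, theta = result$theta, phi = result$phi,
    sum_lambda = result$sum_lambda, n_scaffolds = nrow(result$scaffolds),
    config = list(
      t = config$t, overlap_frac = config$overlap_frac,
      min_gap_len = config$min_gap_len, n_parts = config$n_parts,
      seed = config$seed, aligner_mode = config$aligner_mode,
      query_aware = config$query_aware))
  jsonlite::write_json(report, out("assembly.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' Ten-bin histogram of scaffold quality scores
#'
#' Bins scaffolds by quality into nine equal left-closed right-open
#' intervals `[0,0.1), ..., [0.8,0.9)` plus the single closed interval
#' `[0.9, 1]`, and reports the percentage of scaffolds (and of assembly base
#' pairs) in each bin. This is the summary used to compare quality
#' distributions across assemblies at a glance.
#'
#' @param scores Scaffold score table from [score_scaffolds()].
#' @return `data.frame` with columns `bin`, `lower`, `upper`,
#'   `pct_scaffolds`, `pct_bp`; both percentage columns sum to 100.
#' @export
bin_quality_scores <- function(scores) {
  stopifnot(nrow(scores) > 0L)
  lower <- seq(0, 0.9, by = 0.1)
  upper <- lower + 0.1
  idx <- pmin(floor(scores$Q * 10) + 1L, 10L)  # Q = 1 and [0.9,1) share bin 10
  n <- tabulate(idx, nbins = 10L)
  bp <- vapply(1:10, function(b) sum(as.numeric(scores$l_s[idx == b])),
               numeric(1))
  data.frame(
    bin = sprintf(ifelse(upper < 1, "[%.1f,%.1f)", "[%.1f,%.1f]"),
                  lower, upper),
    lower = lower, upper = upper,
    pct_scaffolds = 100 * n / sum(n),
    pct_bp = 100 * bp / sum(bp))
}
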