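#' Write synthetic-family outputs to disk
#'
#' Runs [simulate_family()] and writes `synthetic.fasta` (annotated
#' headers), `metadata.tsv`, and `truth.tsv` (per-clade expected planted
#' run lengths) under `out_dir`. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return Named character vector of output paths, invisibly; the
#'   simulated family is attached as attribute `"family"`.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fam <- simulate_family(config)
  paths <- c(
    fasta = file.path(out_dir, "synthetic.fasta"),
    metadata = file.path(out_dir, "metadata.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_fasta(fam$records, paths[["fasta"]])
  readr::write_tsv(fam$metadata, paths[["metadata"]])
  readr::write_tsv(fam$truth$expected_means, paths[["truth"]])
  attr(paths, "family") <- fam
  invisible(paths)
}

#' Score a FASTA file: per-residue tracks and per-protein means
#'
#' Computes SIM and REP profiles for every record and writes
#' `score_tracks.tsv` (`protein_id`, `position`, `score_name`, `value`)
#' and `score_means.tsv` (`id`, `mean_SIM`, `mean_REP`).
#'
#' @param fasta input FASTA path.
#' @param out_dir output directory.
#' @param spec,log_base scoring options (defaults: 20-residue window of
#'   9 upstream + 10 downstream, natural log).
#' @return Named character vector of output paths, invisibly.
#' @export
run_score <- function(fasta, out_dir, spec = window_spec(),
                      log_base = exp(1)) {
  records <- read_fasta(fasta)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tracks = file.path(out_dir, "score_tracks.tsv"),
             means = file.path(out_dir, "score_means.tsv"))
  readr::write_tsv(score_tracks(records, spec = spec,
                                log_base = log_base), paths[["tracks"]])
  readr::write_tsv(protein_score_means(records, spec, log_base),
                   paths[["means"]])
  invisible(paths)
}

#' Composition, AAR, and enrichment tables for a FASTA file
#'
#' Writes `composition.tsv` (per-protein percent occurrences),
#' `aars.bed.tsv` (BED-like homorepeat intervals), and — when a baseline
#' proteome FASTA is given — `enrichment.tsv` with deviation flags at the
#' strict +/- `threshold` percent rule.
#'
#' @param fasta input FASTA path.
#' @param out_dir output directory.
#' @param baseline_fasta optional reference proteome FASTA.
#' @param min_aar_len AAR threshold (default 4).
#' @param threshold enrichment threshold in percent (default 20).
#' @return Named character vector of output paths, invisibly.
#' @export
run_compose <- function(fasta, out_dir, baseline_fasta = NULL,
                        min_aar_len = 4, threshold = 20) {
  records <- read_fasta(fasta)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(composition = file.path(out_dir, "composition.tsv"),
             aars = file.path(out_dir, "aars.bed.tsv"))
  comp <- dplyr::bind_rows(lapply(seq_len(nrow(records)), function(k) {
    pct <- aa_percentages(records$sequence[k])
    tibble::tibble(protein_id = records$id[k], aa = AA20,
                   percent = as.numeric(pct))
  }))
  readr::write_tsv(comp, paths[["composition"]])
  aars <- dplyr::bind_rows(lapply(seq_len(nrow(records)), function(k) {
    a <- find_aars(records$sequence[k], min_aar_len)
    if (nrow(a)) dplyr::bind_cols(
      tibble::tibble(protein_id = rep(records$id[k], nrow(a))), a)
    else NULL
  }))
  if (is.null(aars) || nrow(aars) == 0) {
    aars <- tibble::tibble(protein_id = character(), aa = character(),
                           start = integer(), end = integer(),
                           length = integer())
  }
  write_aar_bed(aars, paths[["aars"]])
  if (!is.null(baseline_fasta)) {
    baseline <- proteome_baseline(read_fasta(baseline_fasta))
    enr <- dplyr::bind_rows(lapply(seq_len(nrow(records)), function(k) {
      rep_tbl <- enrichment_report(aa_percentages(records$sequence[k]),
                                   baseline, threshold)
      dplyr::bind_cols(tibble::tibble(protein_id =
                                        rep(records$id[k], 20)), rep_tbl)
    }))
    paths <- c(paths, enrichment = file.path(out_dir, "enrichment.tsv"))
    readr::write_tsv(enr, paths[["enrichment"]])
  } else {
    message("no baseline proteome given; enrichment table omitted")
  }
  invisible(paths)
}

#' Evolutionary analysis: clade means, stem-age correlations, subsampling
#'
#' Takes annotated records (or a FASTA plus metadata table), builds
#' parameter vectors, and writes `clade_summaries.tsv`,
#' `correlations.tsv`, `per_species_correlations.tsv`, and
#' `subsampling.tsv`.
#'
#' @param fasta input FASTA path.
#' @param metadata metadata TSV path (`id`, `species`, `clade`,
#'   `paralog`).
#' @param registry clade registry (default vertebrate fixture).
#' @param out_dir output directory.
#' @param external_scores optional external-score TSV path.
#' @param k,reps subsampling design (defaults 5 species, 10 repetitions).
#' @param seed root seed for subsampling (required).
#' @param min_aar_len AAR threshold (default 4).
#' @return Named character vector of output paths, invisibly.
#' @export
run_evolve <- function(fasta, metadata, registry = default_registry(),
                       out_dir, external_scores = NULL, k = 5, reps = 10,
                       seed, min_aar_len = 4) {
  records <- read_fasta(fasta)
  meta <- readr::read_tsv(metadata, show_col_types = FALSE)
  records <- join_metadata(records, meta, registry)
  qc <- qc_filter(records)
  ext <- NULL
  if (!is.null(external_scores)) {
    ext <- validate_external_scores(read_external_scores(external_scores),
                                    qc$kept)
  }
  vectors <- parameter_vectors(qc$kept, ext, min_aar_len)
  summaries <- clade_summaries(vectors, registry)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    summaries = file.path(out_dir, "clade_summaries.tsv"),
    correlations = file.path(out_dir, "correlations.tsv"),
    per_species = file.path(out_dir, "per_species_correlations.tsv"),
    subsampling = file.path(out_dir, "subsampling.tsv")
  )
  readr::write_tsv(summaries, paths[["summaries"]])
  readr::write_tsv(correlate_with_stem_age(summaries),
                   paths[["correlations"]])
  readr::write_tsv(per_species_correlation(vectors, registry),
                   paths[["per_species"]])
  sub <- subsample_robustness(vectors, registry, k = k, reps = reps,
                              seed = seed)
  readr::write_tsv(sub$summary, paths[["subsampling"]])
  invisible(paths)
}

#' End-to-end synthetic workflow
#'
#' simulate -> score -> compose -> evolve on one synthetic family, writing
#' all stage outputs under `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param k,reps subsampling design passed to [run_evolve()].
#' @return Named character vector of all output paths, invisibly.
#' @export
run_all <- function(config, out_dir, k = 5, reps = 10) {
  sim <- run_simulate(config, out_dir)
  score <- run_score(sim[["fasta"]], out_dir)
  comp <- run_compose(sim[["fasta"]], out_dir)
  evo <- run_evolve(sim[["fasta"]], sim[["metadata"]], config$registry,
                    out_dir, k = k, reps = reps, seed = config$seed)
  invisible(c(sim, score, comp, evo))
}
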