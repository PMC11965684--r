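#' Per-protein parameter vectors
#'
#' Assembles, for each protein, the registered parameters: the 20
#' amino-acid percent occurrences (`pct_*`), the 20 per-amino-acid total
#' AAR lengths (`aar_*`), the mean per-residue SIM and REP scores, and any
#' ingested per-protein external scores (per-residue external tracks are
#' averaged with [mean_track()]). Missing external scores are stored as
#' `NA`, not zero. The classic 24-parameter set of interest is the 20
#' percents plus mean SIM, mean REP, an LLPS-propensity score, and a
#' prion-likeness score.
#'
#' @param records annotated protein-record tibble.
#' @param external_scores optional tibble from [read_external_scores()].
#' @param min_aar_len AAR detection threshold (default 4).
#' @param spec,log_base passed to the complexity scoring.
#' @return A tibble, one row per protein: `id`, `species`, `clade`,
#'   `paralog`, then one numeric column per parameter.
#' @export
parameter_vectors <- function(records, external_scores = NULL,
                              min_aar_len = 4, spec = window_spec(),
                              log_base = exp(1)) {
  pct <- t(vapply(records$sequence, aa_percentages, numeric(20),
                  USE.NAMES = FALSE))
  colnames(pct) <- paste0("pct_", AA20)
  aar <- t(vapply(records$sequence, function(s) {
    aar_totals(find_aars(s, min_aar_len))
  }, numeric(20), USE.NAMES = FALSE))
  colnames(aar) <- paste0("aar_", AA20)
  means <- protein_score_means(records, spec, log_base)
  out <- dplyr::bind_cols(
    records[c("id", "species", "clade", "paralog")],
    tibble::as_tibble(pct), tibble::as_tibble(aar),
    means[c("mean_SIM", "mean_REP")]
  )
  if (!is.null(external_scores) && nrow(external_scores)) {
    ext_names <- unique(external_scores$score_name)
    clash <- intersect(ext_names, names(out))
    if (length(clash)) {
      stop("external score name(s) collide with built-in parameters: ",
           paste(clash, collapse = ", "), call. = FALSE)
    }
    for (nm in ext_names) {
      sub <- external_scores[external_scores$score_name == nm, ]
      vals <- vapply(seq_len(nrow(sub)), function(k) {
        if (is.null(sub$track[[k]])) sub$value[k]
        else mean_track(sub$track[[k]])
      }, numeric(1))
      out[[nm]] <- vals[match(out$id, sub$protein_id)]
    }
  }
  out
}

# numeric parameter columns of a vectors/summaries tibble
.param_cols <- function(tbl) {
  meta <- c("id", "species", "clade", "paralog", "stem_age_mya",
            "n_orthologs")
  setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))], meta)
}

#' Per-clade parameter means
#'
#' Unweighted arithmetic mean of every parameter across the orthologs of
#' each clade (single-ortholog clades contribute their own values),
#' ordered by descending stem age. Clades in the registry with no
#' orthologs are omitted with a warning. Per-parameter ortholog counts
#' (relevant when external scores are missing for some proteins) are
#' attached as attribute `"param_n"`.
#'
#' @param vectors parameter-vector tibble from [parameter_vectors()].
#' @param registry clade registry.
#' @return A tibble: `clade`, `stem_age_mya`, `n_orthologs`, then one mean
#'   column per parameter.
#' @export
clade_summaries <- function(vectors, registry) {
  unknown <- setdiff(unique(vectors$clade), registry$clade)
  if (length(unknown)) {
    stop("clade(s) not in registry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  empty <- setdiff(registry$clade, unique(vectors$clade))
  if (length(empty)) {
    warning("clade(s) with zero orthologs omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  params <- .param_cols(vectors)
  grouped <- dplyr::group_by(vectors, .data$clade)
  means <- dplyr::summarise(
    grouped,
    n_orthologs = dplyr::n(),
    dplyr::across(dplyr::all_of(params), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
  param_n <- dplyr::summarise(
    grouped,
    dplyr::across(dplyr::all_of(params), ~ sum(!is.na(.x))),
    .groups = "drop"
  )
  out <- dplyr::inner_join(registry[c("clade", "stem_age_mya")], means,
                           by = "clade")
  out <- dplyr::arrange(out, dplyr::desc(.data$stem_age_mya), .data$clade)
  attr(out, "param_n") <- param_n
  attr(out, "reference") <- registry_reference(registry)
  out
}

#' Normalize clade means to a reference clade
#'
#' Divides each clade mean by the corresponding mean of the reference
#' clade (by convention the clade with the oldest stem age), per
#' parameter; the reference clade maps to 1. Parameters whose reference
#' value is 0 are set to `NA` and listed in attribute
#' `"non_normalizable"`. For reporting only: correlations use unnormalized
#' means (normalization is a per-parameter rescale and cannot change r).
#'
#' @param summaries clade-summary tibble from [clade_summaries()].
#' @param reference reference clade name; defaults to the summaries'
#'   registry reference.
#' @return The summaries tibble with parameter columns rescaled.
#' @export
normalize_to_reference <- function(summaries, reference = NULL) {
  if (is.null(reference)) reference <- attr(summaries, "reference")
  if (is.null(reference)) {
    reference <- summaries$clade[which.max(summaries$stem_age_mya)]
  }
  if (!reference %in% summaries$clade) {
    stop("reference clade '", reference, "' not present", call. = FALSE)
  }
  params <- .param_cols(summaries)
  ref_row <- summaries[summaries$clade == reference, ]
  non_norm <- character(0)
  out <- summaries
  for (p in params) {
    ref <- ref_row[[p]]
    if (!is.finite(ref) || ref == 0) {
      out[[p]] <- NA_real_
      non_norm <- c(non_norm, p)
    } else {
      out[[p]] <- out[[p]] / ref
    }
  }
  attr(out, "non_normalizable") <- non_norm
  out
}

# internal: Pearson r with two-tailed t-based p (n - 2 df), on
# pairwise-complete observations. Returns one result row.
.pearson_row <- function(x, y, label) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(parameter = label, r = NA_real_,
                          n = n, p = NA_real_, significant = NA))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(parameter = label,
                 r = unname(ct$estimate),
                 n = n,
                 p = ct$p.value,
                 significant = ct$p.value <= 0.05)
}

#' Correlate clade means with clade stem ages
#'
#' Pearson r of (clade mean, stem age) pairs per parameter, with the
#' two-tailed p from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n - 2
#' degrees of freedom, and significance at p <= 0.05 (no multiple-testing
#' correction — each parameter is tested marginally). Sign convention:
#' negative r means the parameter increases toward younger clades.
#'
#' @param summaries clade-summary tibble from [clade_summaries()].
#' @param parameters parameter names to test; default all.
#' @return A tibble with columns `parameter`, `r`, `n`, `p`,
#'   `significant` (undefined correlations reported with `NA` r and p).
#' @export
correlate_with_stem_age <- function(summaries, parameters = NULL) {
  if (is.null(parameters)) parameters <- .param_cols(summaries)
  dplyr::bind_rows(lapply(parameters, function(p) {
    .pearson_row(summaries[[p]], summaries$stem_age_mya, p)
  }))
}

#' Per-species stem-age correlations
#'
#' As [correlate_with_stem_age()], but each ortholog contributes its own
#' parameter value, inheriting its clade's stem age (n = number of
#' proteins). Quantifies whether clade-mean trends survive intraclade
#' variability.
#'
#' @param vectors parameter-vector tibble.
#' @param registry clade registry.
#' @param parameters parameter names to test; default all.
#' @return A correlation-result tibble.
#' @export
per_species_correlation <- function(vectors, registry, parameters = NULL) {
  if (is.null(parameters)) parameters <- .param_cols(vectors)
  age <- registry$stem_age_mya[match(vectors$clade, registry$clade)]
  if (anyNA(age)) {
    stop("clade(s) without registry stem age: ",
         paste(unique(vectors$clade[is.na(age)]), collapse = ", "),
         call. = FALSE)
  }
  dplyr::bind_rows(lapply(parameters, function(p) {
    .pearson_row(vectors[[p]], age, p)
  }))
}

#' Correlate two clade-mean series
#'
#' Pearson r and p over clades for paralog-vs-paralog (e.g., SIM of one
#' family member vs another) or parameter-vs-parameter (e.g., LLPS
#' propensity vs SIM) comparisons. The two series must follow the same
#' clade ordering.
#'
#' @param series_x,series_y equal-length numeric vectors of clade means.
#' @param label result label (default "x_vs_y").
#' @return A one-row correlation-result tibble.
#' @export
cross_series_correlation <- function(series_x, series_y,
                                     label = "x_vs_y") {
  if (length(series_x) != length(series_y)) {
    stop("series lengths differ (", length(series_x), " vs ",
         length(series_y), ")", call. = FALSE)
  }
  if (length(series_x) < 3) stop("need >= 3 clades", call. = FALSE)
  .pearson_row(series_x, series_y, label)
}

#' Subsampling robustness of stem-age correlations
#'
#' Repeats the clade-mean correlation analysis using only `k` randomly
#' selected species per clade (all species when a clade has fewer than
#' `k`), `reps` times, and tallies how often the full-data outcome is
#' preserved. Sampling is without replacement; one root seed
#' deterministically derives per-repetition seeds, so a fixed seed gives
#' byte-identical output. When `k` is at least the largest clade size,
#' every repetition reproduces the full analysis exactly.
#'
#' @param vectors parameter-vector tibble.
#' @param registry clade registry.
#' @param parameters parameter names to test; default all.
#' @param k species sampled per clade (default 5).
#' @param reps number of repetitions (default 10).
#' @param seed root random seed (required).
#' @return A list with `full` (full-data correlation tibble), `per_rep`
#'   (per-repetition correlation tibble with a `rep` column), and
#'   `summary` (per parameter: full-data r/p/significance, number of
#'   repetitions significant, with the same sign as the full analysis,
#'   and preserving full-data significance).
#' @export
subsample_robustness <- function(vectors, registry, parameters = NULL,
                                 k = 5, reps = 10, seed) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(parameters)) parameters <- .param_cols(vectors)
  full <- correlate_with_stem_age(clade_summaries(vectors, registry),
                                  parameters)
  rep_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max, reps))
  per_rep <- dplyr::bind_rows(lapply(seq_len(reps), function(rix) {
    sub <- withr::with_seed(rep_seeds[rix], {
      picked <- unlist(lapply(split(seq_len(nrow(vectors)),
                                    vectors$clade), function(rows) {
        if (length(rows) <= k) rows else sample(rows, k)
      }), use.names = FALSE)
      vectors[sort(picked), , drop = FALSE]
    })
    res <- correlate_with_stem_age(clade_summaries(sub, registry),
                                   parameters)
    res$rep <- rix
    res
  }))
  summary <- dplyr::bind_rows(lapply(parameters, function(p) {
    f <- full[full$parameter == p, ]
    r <- per_rep[per_rep$parameter == p, ]
    sig <- sum(r$significant %in% TRUE)
    same_sign <- sum(!is.na(r$r) & !is.na(f$r) & sign(r$r) == sign(f$r))
    tibble::tibble(
      parameter = p,
      full_r = f$r, full_p = f$p,
      full_significant = f$significant,
      reps = reps,
      n_significant = sig,
      n_same_sign = same_sign,
      preserved = if (isTRUE(f$significant)) sig else
        sum(!(r$significant %in% TRUE))
    )
  }))
  list(full = full, per_rep = per_rep, summary = summary)
}
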