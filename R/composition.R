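#' Percent occurrence of each amino acid
#'
#' `count(X) / length * 100` per canonical amino acid; ambiguity codes
#' count toward the length only, so percents sum to < 100 in their
#' presence.
#'
#' @param sequence non-empty amino-acid string.
#' @return Named numeric 20-vector of percents, in [AA20] order.
#' @examples
#' aa_percentages("AAAA")["A"]  # 100
#' @export
aa_percentages <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  counts <- tabulate(match(chars, AA20), nbins = 20L)
  stats::setNames(counts / length(chars) * 100, AA20)
}

#' Detect homopolymeric amino-acid repeats (AARs)
#'
#' All maximal runs of identical canonical residues of length >=
#' `min_len`, in positional order. Ambiguity codes terminate runs and never
#' seed them. Coordinates are 1-based inclusive.
#'
#' @param sequence non-empty amino-acid string.
#' @param min_len minimum run length to report (default 4; must be >= 2).
#' @return A tibble with columns `aa`, `start`, `end`, `length`.
#' @examples
#' find_aars("MAAAQQQQW")  # one polyQ of length 4; the 3-A run is below
#'                         # threshold
#' @export
find_aars <- function(sequence, min_len = 4) {
  stopifnot(is.character(sequence), length(sequence) == 1,
            nzchar(sequence))
  if (min_len < 2) stop("min_len must be >= 2", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  amb <- chars %in% AA_AMBIGUOUS
  chars[amb] <- paste0("#", seq_len(sum(amb)))
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len & r$values %in% AA20
  tibble::tibble(
    aa = r$values[keep],
    start = starts[keep],
    end = ends[keep],
    length = r$lengths[keep]
  )
}

#' Total AAR length per amino acid
#'
#' Per amino acid, the sum of the lengths of its individual repeats
#' (each already >= the detection threshold); 0 for amino acids without
#' repeats.
#'
#' @param aars AAR tibble from [find_aars()] (one sequence).
#' @return Named numeric 20-vector of total lengths, in [AA20] order.
#' @export
aar_totals <- function(aars) {
  tot <- stats::setNames(numeric(20), AA20)
  if (nrow(aars)) {
    s <- tapply(aars$length, factor(aars$aa, levels = AA20), sum)
    s[is.na(s)] <- 0
    tot[] <- as.numeric(s)
  }
  tot
}

#' Composition profile of one protein
#'
#' @param sequence amino-acid string.
#' @param min_aar_len AAR detection threshold (default 4).
#' @return A list with `percent` (20-vector), `aar_total` (20-vector),
#'   `length` (sequence length).
#' @export
composition_profile <- function(sequence, min_aar_len = 4) {
  list(
    percent = aa_percentages(sequence),
    aar_total = aar_totals(find_aars(sequence, min_aar_len)),
    length = nchar(sequence)
  )
}

#' Proteome baseline composition
#'
#' Unweighted mean over proteins of each per-protein percent occurrence —
#' the mean occurrence of each amino acid across all proteins of the
#' reference proteome, not the pooled residue frequency (the two differ
#' whenever protein lengths differ).
#'
#' @param records protein-record tibble (>= 1 row), or a character vector
#'   of sequences.
#' @param pooled if `TRUE`, compute the pooled residue-frequency
#'   alternative instead (for sensitivity analysis).
#' @return Named numeric 20-vector of mean percents.
#' @export
proteome_baseline <- function(records, pooled = FALSE) {
  sequences <- if (is.data.frame(records)) records$sequence else records
  if (length(sequences) == 0) stop("empty record set", call. = FALSE)
  if (pooled) {
    chars <- strsplit(paste(sequences, collapse = ""), "", fixed = TRUE)[[1]]
    counts <- tabulate(match(chars, AA20), nbins = 20L)
    return(stats::setNames(counts / length(chars) * 100, AA20))
  }
  mat <- vapply(sequences, aa_percentages, numeric(20), USE.NAMES = FALSE)
  stats::setNames(rowMeans(mat), AA20)
}

#' Enrichment/depletion of amino acids versus a baseline
#'
#' Relative deviation `(observed - baseline) / baseline * 100` per amino
#' acid, flagged `enriched` when strictly > `threshold` percent, `depleted`
#' when strictly < `-threshold`, otherwise `neutral`. A deviation sitting
#' exactly at the threshold (the canonical worked example: 9.6% observed
#' vs 8% baseline = +20%) is boundary and stays `neutral`. Amino acids with
#' a zero baseline are flagged `undefined`.
#'
#' @param profile observed percent 20-vector (e.g., from
#'   [aa_percentages()]).
#' @param baseline baseline percent 20-vector (e.g., from
#'   [proteome_baseline()]).
#' @param threshold percent deviation threshold (default 20).
#' @return A tibble with columns `aa`, `baseline`, `observed`,
#'   `deviation_pct`, `flag`.
#' @export
enrichment_report <- function(profile, baseline, threshold = 20) {
  stopifnot(length(profile) == 20, length(baseline) == 20)
  deviation <- ifelse(baseline > 0,
                      (profile - baseline) / baseline * 100, NA_real_)
  flag <- dplyr::case_when(
    baseline <= 0 ~ "undefined",
    deviation > threshold ~ "enriched",
    deviation < -threshold ~ "depleted",
    TRUE ~ "neutral"
  )
  tibble::tibble(
    aa = AA20,
    baseline = as.numeric(baseline),
    observed = as.numeric(profile),
    deviation_pct = as.numeric(deviation),
    flag = flag
  )
}
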