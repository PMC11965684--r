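#' Sliding-window specification
#'
#' The scores are computed in a nominal 20-residue window centered on each
#' residue: 9 residues upstream and 10 downstream. Near the termini the
#' window is clipped to the sequence, so its effective length grows from 11
#' (residue 1) to 20 over the first 10 residues and shrinks back to 10 at
#' the final residue. Sequences no longer than the nominal window use the
#' whole sequence at every position.
#'
#' @param upstream residues upstream of the focal residue (default 9).
#' @param downstream residues downstream (default 10).
#' @return A list with elements `upstream`, `downstream`, `nominal`.
#' @export
window_spec <- function(upstream = 9L, downstream = 10L) {
  stopifnot(upstream >= 0, downstream >= 0)
  list(upstream = as.integer(upstream),
       downstream = as.integer(downstream),
       nominal = as.integer(upstream + downstream + 1L))
}

#' Window bounds at one residue
#'
#' Sequences no longer than the nominal window use the whole sequence as
#' the window at every position (so a 20-residue homopolymer scores its
#' full-window value everywhere).
#'
#' @param i focal position, 1-based.
#' @param L sequence length.
#' @param spec window specification from [window_spec()].
#' @return Integer vector `c(start, end)`, inclusive.
#' @examples
#' window_bounds(1, 100)    # c(1, 11)
#' window_bounds(100, 100)  # c(91, 100)
#' @export
window_bounds <- function(i, L, spec = window_spec()) {
  if (any(i < 1) || any(i > L)) {
    stop("position out of range [1, ", L, "]", call. = FALSE)
  }
  if (L <= spec$nominal) return(c(1L, as.integer(L)))
  c(max(1L, as.integer(i) - spec$upstream),
    min(as.integer(L), as.integer(i) + spec$downstream))
}

#' Count amino-acid occurrences in a window
#'
#' @param window_sequence window substring (non-empty).
#' @return A list with `a` (named 20-vector of counts in [AA20] order), `b`
#'   (number of amino acids occurring at least once), `w` (effective window
#'   length). Ambiguity-code positions count toward `w` only.
#' @examples
#' count_window("AAXAA")  # a["A"] = 4, b = 1, w = 5
#' @export
count_window <- function(window_sequence) {
  stopifnot(is.character(window_sequence), nzchar(window_sequence))
  chars <- strsplit(window_sequence, "", fixed = TRUE)[[1]]
  idx <- match(chars, AA20)
  a <- tabulate(idx, nbins = 20L)
  names(a) <- AA20
  list(a = a, b = sum(a > 0L), w = length(chars))
}

#' Coefficient of variation of a window count vector
#'
#' Population (divide-by-n) standard deviation of the 20 counts divided by
#' their mean. The population form is required for the score's documented
#' upper endpoint: a pure 20-residue homopolymer gives sqrt(19) = 4.3589
#' (printed 4.35); the sample form would give 4.47.
#'
#' @param counts window counts from [count_window()], or a bare numeric
#'   20-vector.
#' @return Nonnegative CV; errors on an all-zero vector.
#' @export
coefficient_of_variation <- function(counts) {
  a <- if (is.list(counts)) counts$a else counts
  if (sum(a) < 1) {
    stop("all-zero count vector: CV undefined", call. = FALSE)
  }
  m <- mean(a)
  sqrt(mean((a - m)^2)) / m
}

#' SIM score of one window
#'
#' Per-residue simplicity: `SIM = CV(a) / (1 + log b)`, where `a` is the
#' 20-vector of amino-acid counts in the window and `b` the number of
#' distinct amino acids present. Ranges from 0 (all 20 amino acids once) to
#' sqrt(19) = 4.3589 (pure homopolymer; both endpoints are independent of
#' the log base because log(1) = 0). The quotient form is the only
#' arrangement of CV and diversity consistent with both endpoints.
#'
#' @param counts window counts from [count_window()].
#' @param log_base base for the diversity term (default natural log).
#' @return SIM value in \[0, sqrt(19)\].
#' @examples
#' sim_window(count_window("ACDEFGHIKLMNPQRSTVWY"))  # 0
#' sim_window(count_window(strrep("A", 20)))         # 4.3589
#' @export
sim_window <- function(counts, log_base = exp(1)) {
  b <- counts$b
  if (b < 1) stop("no canonical residues in window: SIM undefined",
                  call. = FALSE)
  coefficient_of_variation(counts) / (1 + log(b, base = log_base))
}

#' Tandem-run statistics of one window
#'
#' Identifies maximal runs of two or more identical canonical residues by a
#' single left-to-right scan. Ambiguity codes occupy positions but break
#' runs and never form them.
#'
#' @param window_sequence window substring (non-empty).
#' @return A list with `a_total` (summed run length), `b_runs` (run count),
#'   `c_distinct` (distinct amino acids forming runs).
#' @examples
#' repeat_stats("AACCDDEEFFGGHHIIKKLL")  # a_total 20, b_runs 10, c 10
#' @export
repeat_stats <- function(window_sequence) {
  stopifnot(is.character(window_sequence), nzchar(window_sequence))
  chars <- strsplit(window_sequence, "", fixed = TRUE)[[1]]
  # make each ambiguity position unique so it can't run or join a run
  amb <- chars %in% AA_AMBIGUOUS
  chars[amb] <- paste0("#", seq_len(sum(amb)))
  r <- rle(chars)
  run <- r$lengths >= 2
  list(a_total = as.integer(sum(r$lengths[run])),
       b_runs = as.integer(sum(run)),
       c_distinct = length(unique(r$values[run])))
}

#' REP score of one window
#'
#' Per-residue repetitiveness: `REP = a / (b * c)` with `a` the total
#' length of runs of >= 2 identical residues, `b` the number of such runs,
#' and `c` the number of distinct amino acids forming them. Windows with no
#' runs score 0; a pure 20-residue homopolymer scores 20 — the unique
#' maximum under this grouping. Given a fixed composition the score ranks
#' blocked arrangements above interleaved ones (e.g., 10 A + 10 Q:
#' "AQAQ..." 0, "AAAAAQQQQQ x2" 2.5, "A10Q10" 5).
#'
#' @param stats run statistics from [repeat_stats()].
#' @return REP value in \[0, 20\].
#' @export
rep_window <- function(stats) {
  if (stats$b_runs == 0) return(0)
  stats$a_total / (stats$b_runs * stats$c_distinct)
}

# internal vectorized engines -------------------------------------------

# SIM at every position, via cumulative per-amino-acid counts
.sim_profile <- function(chars, spec, log_base) {
  L <- length(chars)
  idx <- match(chars, AA20)
  if (L <= spec$nominal) {
    starts <- rep(1L, L)
    ends <- rep(L, L)
  } else {
    starts <- pmax(1L, seq_len(L) - spec$upstream)
    ends <- pmin(L, seq_len(L) + spec$downstream)
  }
  # cs[k, j+1] = count of amino acid k in chars[1..j]
  cs <- matrix(0L, nrow = 20L, ncol = L + 1L)
  for (k in 1:20) {
    cs[k, -1] <- cumsum(!is.na(idx) & idx == k)
  }
  A <- cs[, ends + 1L, drop = FALSE] - cs[, starts, drop = FALSE]
  S <- colSums(A)
  m <- S / 20
  v <- colSums(A^2) / 20 - m^2
  b <- colSums(A > 0L)
  out <- rep(NA_real_, L)
  ok <- S >= 1
  out[ok] <- (sqrt(pmax(v[ok], 0)) / m[ok]) / (1 + log(b[ok], log_base))
  out
}

# REP at every position, via rle of the window slice
.rep_profile <- function(chars, spec) {
  L <- length(chars)
  amb <- chars %in% AA_AMBIGUOUS
  chars[amb] <- paste0("#", seq_len(sum(amb)))
  whole <- L <= spec$nominal
  vapply(seq_len(L), function(i) {
    s <- if (whole) 1L else max(1L, i - spec$upstream)
    e <- if (whole) L else min(L, i + spec$downstream)
    r <- rle(chars[s:e])
    run <- r$lengths >= 2
    if (!any(run)) return(0)
    sum(r$lengths[run]) / (sum(run) * length(unique(r$values[run])))
  }, numeric(1))
}

#' Per-residue SIM or REP profile of a protein
#'
#' Applies [sim_window()] or [rep_window()] in the sliding window at every
#' position of the sequence. Positions whose window contains no canonical
#' residue (possible only in ambiguity-code stretches) yield `NA` for SIM.
#'
#' @param sequence amino-acid string, or a one-row protein-record tibble.
#' @param score `"SIM"` or `"REP"`.
#' @param spec window specification ([window_spec()]).
#' @param log_base log base for SIM (default natural).
#' @return Numeric vector, one value per residue.
#' @examples
#' score_profile(strrep("A", 20), "SIM")  # constant 4.3589
#' @export
score_profile <- function(sequence, score = c("SIM", "REP"),
                          spec = window_spec(), log_base = exp(1)) {
  score <- match.arg(score)
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1)
    sequence <- sequence$sequence
  }
  stopifnot(is.character(sequence), length(sequence) == 1,
            nzchar(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (score == "SIM") .sim_profile(chars, spec, log_base)
  else .rep_profile(chars, spec)
}

#' Mean of a per-residue score track
#'
#' @param track numeric per-residue values.
#' @param na.rm drop undefined positions (default TRUE).
#' @return Arithmetic mean across residues.
#' @export
mean_track <- function(track, na.rm = TRUE) {
  if (length(track) == 0) stop("empty track", call. = FALSE)
  mean(track, na.rm = na.rm)
}

#' Per-protein mean SIM and REP scores
#'
#' Convenience wrapper: computes both profiles for every record and returns
#' per-protein means — the per-protein quantities the evolutionary stage
#' consumes.
#'
#' @param records protein-record tibble.
#' @inheritParams score_profile
#' @return A tibble with columns `id`, `mean_SIM`, `mean_REP`.
#' @export
protein_score_means <- function(records, spec = window_spec(),
                                log_base = exp(1)) {
  tibble::tibble(
    id = records$id,
    mean_SIM = vapply(records$sequence, function(s) {
      mean_track(score_profile(s, "SIM", spec, log_base))
    }, numeric(1), USE.NAMES = FALSE),
    mean_REP = vapply(records$sequence, function(s) {
      mean_track(score_profile(s, "REP", spec))
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' Long-format score tracks for a record set
#'
#' @param records protein-record tibble.
#' @param scores which scores to compute (default both).
#' @inheritParams score_profile
#' @return A tibble `(protein_id, position, score_name, value)` matching
#'   the external score-table layout of [read_external_scores()].
#' @export
score_tracks <- function(records, scores = c("SIM", "REP"),
                         spec = window_spec(), log_base = exp(1)) {
  out <- lapply(seq_len(nrow(records)), function(k) {
    L <- nchar(records$sequence[k])
    dplyr::bind_rows(lapply(scores, function(sc) {
      tibble::tibble(
        protein_id = records$id[k],
        position = seq_len(L),
        score_name = sc,
        value = score_profile(records$sequence[k], sc, spec, log_base)
      )
    }))
  })
  dplyr::bind_rows(out)
}
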