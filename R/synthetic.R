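#' Background amino-acid frequency presets
#'
#' `"uniform"` gives 1/20 per amino acid (the default background of the
#' simulator); `"human"` is an approximate human-proteome composition
#' (Swiss-Prot-style average frequencies), for more realistic baselines.
#'
#' @param preset `"uniform"` or `"human"`.
#' @return Named numeric 20-vector summing to 1, in [AA20] order.
#' @export
aa_frequencies <- function(preset = c("uniform", "human")) {
  preset <- match.arg(preset)
  if (preset == "uniform") {
    return(stats::setNames(rep(1 / 20, 20), AA20))
  }
  f <- c(A = 7.0, C = 2.3, D = 4.7, E = 7.1, F = 3.7, G = 6.6, H = 2.6,
         I = 4.3, K = 5.7, L = 10.0, M = 2.1, N = 3.6, P = 6.3, Q = 4.8,
         R = 5.6, S = 8.3, T = 5.3, V = 6.0, W = 1.2, Y = 2.7)
  f <- f[AA20]
  f / sum(f)
}

#' Simulation configuration for synthetic ortholog families
#'
#' Describes an ortholog family across clades: each protein is
#' `"M" + NTR + CTR`, where the C-terminal region (CTR) is a conserved
#' block shared by all species up to per-site substitution noise, and the
#' N-terminal region (NTR) is background sequence carrying planted
#' homorepeat runs whose lengths drift linearly with clade age offset
#' (oldest stem age minus clade stem age, so positive slopes mean "grows
#' toward younger clades", the convention under which an increase yields a
#' negative stem-age correlation).
#'
#' @param registry clade registry (default: nine-clade vertebrate fixture).
#' @param species_per_clade orthologs simulated per clade (default 10).
#' @param ntr_length variable-region length in residues (default 200).
#' @param ctr_length conserved-region length in residues (default 300).
#' @param subst_rate per-site substitution probability applied to the CTR
#'   of each species (default 0.05).
#' @param background background composition: a frequency 20-vector or a
#'   preset name for [aa_frequencies()] (default `"uniform"`).
#' @param aar_base named vector: planted homorepeat base length (residues,
#'   at the oldest clade) per amino acid (default `c(P = 4)`).
#' @param aar_slope named vector: planted length slope in residues per Myr
#'   of age offset (default `c(P = 0.04)`); names must match `aar_base`.
#' @param pct_slope optional named vector of background-frequency drift in
#'   percentage points per Myr of age offset.
#' @param noise_sd SD of the per-protein repeat-length jitter (default
#'   1.5).
#' @param paralog family label carried on every record (default "SYN1").
#' @param seed mandatory integer seed; the simulation is fully
#'   deterministic given the config.
#' @return A validated config list of class `"sim_config"`.
#' @export
sim_config <- function(registry = default_registry(),
                       species_per_clade = 10,
                       ntr_length = 200,
                       ctr_length = 300,
                       subst_rate = 0.05,
                       background = "uniform",
                       aar_base = c(P = 4),
                       aar_slope = c(P = 0.04),
                       pct_slope = NULL,
                       noise_sd = 1.5,
                       paralog = "SYN1",
                       seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.character(background)) background <- aa_frequencies(background)
  stopifnot(length(background) == 20, all(background >= 0))
  background <- background / sum(background)
  names(background) <- AA20
  if (species_per_clade < 1) {
    stop("species_per_clade must be >= 1", call. = FALSE)
  }
  if (!setequal(names(aar_base), names(aar_slope))) {
    stop("aar_base and aar_slope must name the same amino acids",
         call. = FALSE)
  }
  bad <- setdiff(names(aar_base), AA20)
  if (length(bad)) {
    stop("planted repeat amino acid(s) not canonical: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(
    registry = registry, species_per_clade = as.integer(species_per_clade),
    ntr_length = as.integer(ntr_length),
    ctr_length = as.integer(ctr_length),
    subst_rate = subst_rate, background = background,
    aar_base = aar_base, aar_slope = aar_slope[names(aar_base)],
    pct_slope = pct_slope, noise_sd = noise_sd, paralog = paralog,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# build one NTR: background residues with planted maximal runs separated
# by >= 1 non-matching residue. run_lengths: named integer vector (>= 2
# entries are planted; 0/1 entries are skipped).
.build_ntr <- function(ntr_length, run_lengths, freq) {
  run_lengths <- run_lengths[run_lengths >= 2]
  n_runs <- length(run_lengths)
  total_run <- sum(run_lengths)
  n_gap <- n_runs + 1L
  gap_total <- ntr_length - total_run
  if (n_runs > 0 && gap_total < n_gap) {
    stop("infeasible config: planted repeats (", total_run,
         " residues + separators) exceed NTR capacity (", ntr_length,
         ")", call. = FALSE)
  }
  if (n_runs == 0) {
    return(sample(AA20, ntr_length, replace = TRUE, prob = freq))
  }
  # random gap sizes >= 1 summing to gap_total, random run order
  extra <- stats::rmultinom(1, gap_total - n_gap,
                            rep(1 / n_gap, n_gap))[, 1]
  gaps <- extra + 1L
  order_aa <- sample(names(run_lengths))
  chars <- character(0)
  for (j in seq_len(n_runs)) {
    gap <- sample(AA20, gaps[j], replace = TRUE, prob = freq)
    aa <- order_aa[j]
    # flanks must differ from the run amino acid to keep runs maximal
    gap[length(gap)] <- sample(setdiff(AA20, aa), 1)
    if (j > 1) {
      prev <- order_aa[j - 1]
      gap[1] <- sample(setdiff(AA20, c(aa, prev)), 1)
    }
    chars <- c(chars, gap, rep(aa, run_lengths[[aa]]))
  }
  last_gap <- sample(AA20, gaps[n_gap], replace = TRUE, prob = freq)
  last_gap[1] <- sample(setdiff(AA20, order_aa[n_runs]), 1)
  c(chars, last_gap)
}

#' Simulate a synthetic ortholog family
#'
#' Generates one protein family across the registry clades under the
#' configured clade-age-dependent repeat expansion model. Planted run
#' lengths are `max(0, round(base + slope * age_offset + noise))` per
#' protein; the CTR is shared across species up to substitution noise.
#' Fully deterministic given the config seed. Generated records start with
#' M and have equal lengths within a clade, so they pass [qc_filter()] by
#' construction.
#'
#' @param config a [sim_config()].
#' @return A list with `records` (protein-record tibble), `metadata`
#'   (tibble `id`, `species`, `clade`, `paralog`), and `truth` (list:
#'   `slopes`, `expected_means` tibble of per-clade expected planted run
#'   lengths, `realized` tibble of per-protein planted lengths, `seed`).
#' @examples
#' fam <- simulate_family(sim_config(species_per_clade = 2, seed = 1))
#' head(fam$records)
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  reg <- config$registry
  offset <- max(reg$stem_age_mya) - reg$stem_age_mya
  withr::with_seed(config$seed, {
    ctr_ref <- sample(AA20, config$ctr_length, replace = TRUE,
                      prob = config$background)
    records <- list()
    realized <- list()
    for (ci in seq_len(nrow(reg))) {
      freq <- config$background
      if (!is.null(config$pct_slope)) {
        for (aa in names(config$pct_slope)) {
          freq[aa] <- max(0, freq[aa] +
                            config$pct_slope[[aa]] * offset[ci] / 100)
        }
        freq <- freq / sum(freq)
      }
      for (si in seq_len(config$species_per_clade)) {
        species <- sprintf("%s_sp%02d", reg$clade[ci], si)
        id <- sprintf("%s_%s", config$paralog, species)
        lens <- vapply(names(config$aar_base), function(aa) {
          mu <- config$aar_base[[aa]] +
            config$aar_slope[[aa]] * offset[ci]
          max(0, round(mu + rnorm(1, 0, config$noise_sd)))
        }, numeric(1))
        ntr <- .build_ntr(config$ntr_length, lens, freq)
        ctr <- ctr_ref
        if (config$subst_rate > 0) {
          hit <- which(stats::runif(config$ctr_length) <
                         config$subst_rate)
          for (pos in hit) {
            ctr[pos] <- sample(setdiff(AA20, ctr[pos]), 1)
          }
        }
        records[[length(records) + 1]] <- tibble::tibble(
          id = id, species = species, clade = reg$clade[ci],
          paralog = config$paralog,
          sequence = paste(c("M", ntr, ctr), collapse = "")
        )
        realized[[length(realized) + 1]] <- tibble::tibble(
          id = id, clade = reg$clade[ci],
          aa = names(config$aar_base),
          planted_length = as.numeric(lens)
        )
      }
    }
    records <- dplyr::bind_rows(records)
    realized <- dplyr::bind_rows(realized)
    expected <- dplyr::bind_rows(lapply(seq_len(nrow(reg)), function(ci) {
      tibble::tibble(
        clade = reg$clade[ci],
        stem_age_mya = reg$stem_age_mya[ci],
        aa = names(config$aar_base),
        expected_length = unname(config$aar_base +
                                   config$aar_slope * offset[ci])
      )
    }))
    list(
      records = records,
      metadata = records[c("id", "species", "clade", "paralog")],
      truth = list(slopes = config$aar_slope,
                   pct_slopes = config$pct_slope,
                   expected_means = expected,
                   realized = realized,
                   seed = config$seed)
    )
  })
}

#' Simulate a null (no-trend) ortholog family
#'
#' As [simulate_family()] with every planted slope forced to zero; used
#' for type-I-error experiments.
#'
#' @param config a [sim_config()]; its slopes are zeroed.
#' @return As [simulate_family()].
#' @export
null_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$aar_slope[] <- 0
  if (!is.null(config$pct_slope)) config$pct_slope[] <- 0
  simulate_family(config)
}
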