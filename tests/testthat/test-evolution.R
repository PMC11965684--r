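# four-clade toy registry with evenly spaced ages, used where the real
# nine-clade fixture is overkill
toy_registry <- function() {
  clade_registry(clade = c("C1", "C2", "C3", "C4"),
                 stem_age_mya = c(400, 300, 200, 100))
}

test_that("parameter vectors assemble composition + complexity + externals", {
  recs <- tibble::tibble(id = "H", species = "sp", clade = "Cho",
                         paralog = "F", sequence = strrep("A", 20))
  v <- parameter_vectors(recs)
  expect_equal(v$pct_A, 100)
  expect_equal(v$aar_A, 20)
  expect_equal(v$mean_SIM, sqrt(19))
  expect_equal(v$mean_REP, 20)
  # 42 built-in entries: 20 percents + 20 AAR totals + mean SIM + mean REP
  expect_equal(length(.subset(v, !(names(v) %in%
    c("id", "species", "clade", "paralog")))), 42)
  # external per-protein value passes through unchanged; per-residue
  # track is averaged; absent scores stay NA
  ext <- tibble::tibble(protein_id = c("H", "H"),
                        score_name = c("PLAAC_PRD", "ParSe_P"),
                        value = c(0.73, NA),
                        track = list(NULL, rep(c(1, 3), 10)))
  v2 <- parameter_vectors(recs, ext)
  expect_equal(v2$PLAAC_PRD, 0.73)
  expect_equal(v2$ParSe_P, 2)
  recs2 <- dplyr::bind_rows(recs, dplyr::mutate(recs, id = "H2",
                                                species = "sp2"))
  v3 <- parameter_vectors(recs2, ext)
  expect_true(is.na(v3$PLAAC_PRD[v3$id == "H2"]))
})

test_that("clade summaries are unweighted means ordered by stem age", {
  reg <- toy_registry()
  vectors <- tibble::tibble(
    id = paste0("P", 1:5), species = paste0("sp", 1:5),
    clade = c("C1", "C1", "C2", "C3", "C4"), paralog = "F",
    pct_P = c(10, 14, 7, 5, 3), mean_SIM = c(1, 3, 2, 2, 2)
  )
  s <- clade_summaries(vectors, reg)
  expect_equal(s$clade, c("C1", "C2", "C3", "C4"))
  expect_equal(s$pct_P, c(12, 7, 5, 3))
  expect_equal(s$mean_SIM[1], 2)
  expect_equal(s$n_orthologs, c(2L, 1L, 1L, 1L))
  # groupwise-sum oracle
  expect_equal(s$pct_P[1], sum(vectors$pct_P[vectors$clade == "C1"]) / 2)
  # empty clade warns and is omitted
  expect_warning(s2 <- clade_summaries(vectors[1:3, ], reg), "omitted")
  expect_equal(nrow(s2), 2)
})

test_that("normalization to the reference clade rescales per parameter", {
  reg <- toy_registry()
  vectors <- tibble::tibble(
    id = paste0("P", 1:4), species = paste0("sp", 1:4),
    clade = c("C1", "C2", "C3", "C4"), paralog = "F",
    pct_P = c(5, 8, 10, 8), aar_P = c(0, 2, 4, 6)
  )
  s <- clade_summaries(vectors, reg)
  norm <- normalize_to_reference(s)
  expect_equal(norm$pct_P, c(1, 1.6, 2, 1.6))
  # zero reference value: flagged, not Inf
  expect_true(all(is.na(norm$aar_P)))
  expect_true("aar_P" %in% attr(norm, "non_normalizable"))
  # normalization cannot change the stem-age correlation
  r_raw <- correlate_with_stem_age(s, "pct_P")$r
  r_norm <- correlate_with_stem_age(norm, "pct_P")$r
  expect_equal(r_raw, r_norm)
})

test_that("stem-age correlation reproduces printed significance levels", {
  ages <- default_registry()$stem_age_mya
  y <- vector_with_exact_r(ages, -0.96)
  res <- cross_series_correlation(y, ages, "test")
  expect_equal(res$r, -0.96, tolerance = 1e-10)
  expect_equal(res$n, 9)
  expect_lt(res$p, 0.001)
  y2 <- vector_with_exact_r(ages, -0.76)
  res2 <- cross_series_correlation(y2, ages, "test")
  expect_lt(res2$p, 0.03)
  expect_gt(res2$p, 0.01)
  y3 <- vector_with_exact_r(ages, 0.89)
  expect_lt(cross_series_correlation(y3, ages, "t")$p, 0.01)
})

test_that("correlation machinery matches a covariance/t oracle exactly", {
  withr::with_seed(37, {
    for (rep in 1:25) {
      n <- sample(4:30, 1)
      x <- rnorm(n); y <- rnorm(n)
      res <- cross_series_correlation(x, y)
      o <- oracle_pearson(x, y)
      expect_equal(res$r, o$r, tolerance = 1e-12)
      expect_equal(res$p, o$p, tolerance = 1e-12)
    }
  })
})

test_that("p-values are sign-symmetric and monotone in |r|", {
  ages <- default_registry()$stem_age_mya
  p_of_r <- function(r) {
    cross_series_correlation(vector_with_exact_r(ages, r), ages)$p
  }
  rs <- c(0.2, 0.5, 0.7, 0.9, 0.99)
  expect_equal(vapply(rs, p_of_r, numeric(1)),
               vapply(-rs, p_of_r, numeric(1)), tolerance = 1e-9)
  expect_true(all(diff(vapply(rs, p_of_r, numeric(1))) < 0))
})

test_that("correlations on degenerate inputs are reported undefined", {
  reg <- toy_registry()
  s <- tibble::tibble(clade = reg$clade, stem_age_mya = reg$stem_age_mya,
                      n_orthologs = 1L, flat = c(2, 2, 2, 2),
                      lin = c(8, 6, 4, 2))
  res <- correlate_with_stem_age(s)
  expect_true(is.na(res$r[res$parameter == "flat"]))
  # exactly linear in stem age -> r = 1
  expect_equal(res$r[res$parameter == "lin"], 1)
  expect_lt(res$p[res$parameter == "lin"], 1e-6)
})

test_that("per-species correlation inherits clade ages and guards ties", {
  reg <- toy_registry()
  vectors <- tibble::tibble(
    id = paste0("P", 1:8), species = paste0("sp", 1:8),
    clade = rep(c("C1", "C2", "C3", "C4"), each = 2), paralog = "F",
    pct_P = c(1, 1, 2, 2, 3, 3, 4, 4)
  )
  res <- per_species_correlation(vectors, reg, "pct_P")
  expect_equal(res$n, 8)
  expect_equal(res$r, -1)
  # within-clade-constant values: species-level r sign equals mean-level
  means_r <- correlate_with_stem_age(clade_summaries(vectors, reg),
                                     "pct_P")$r
  expect_equal(sign(res$r), sign(means_r))
  # all species in one clade: zero age variance -> undefined
  one <- vectors[vectors$clade == "C1", ]
  res1 <- per_species_correlation(one, reg, "pct_P")
  expect_true(is.na(res1$r))
  # unknown clade errors with its name
  bad <- vectors; bad$clade[1] <- "Zzz"
  expect_error(per_species_correlation(bad, reg, "pct_P"), "Zzz")
})

test_that("species-level |r| does not exceed clade-mean |r| on planted trends", {
  # intraclade noise dilutes the species-level correlation
  reg <- default_registry()
  withr::with_seed(41, {
    n_stronger <- 0
    for (rep in 1:20) {
      vectors <- dplyr::bind_rows(lapply(seq_len(nrow(reg)), function(ci) {
        offset <- max(reg$stem_age_mya) - reg$stem_age_mya[ci]
        tibble::tibble(
          id = paste0("P", ci, "_", 1:6),
          species = paste0("sp", ci, "_", 1:6),
          clade = reg$clade[ci], paralog = "F",
          pct_P = 5 + 0.01 * offset + rnorm(6, 0, 1.5)
        )
      }))
      r_sp <- abs(per_species_correlation(vectors, reg, "pct_P")$r)
      r_cl <- abs(correlate_with_stem_age(
        clade_summaries(vectors, reg), "pct_P")$r)
      n_stronger <- n_stronger + (r_sp <= r_cl)
    }
    expect_gte(n_stronger, 15)  # typically, not universally
  })
})

test_that("cross-series correlation validates inputs", {
  x <- c(1, 2, 3, 4)
  expect_equal(cross_series_correlation(x, x)$r, 1)
  expect_error(cross_series_correlation(x, x[1:3]), "lengths differ")
  expect_error(cross_series_correlation(x[1:2], x[1:2]), ">= 3")
})

test_that("independent random series are significant ~5% of the time", {
  withr::with_seed(43, {
    hits <- 0
    n_sim <- 1000
    for (k in seq_len(n_sim)) {
      x <- rnorm(9); y <- rnorm(9)
      hits <- hits + (cross_series_correlation(x, y)$p <= 0.05)
    }
    expect_gte(hits / n_sim, 0.03)
    expect_lte(hits / n_sim, 0.07)
  })
})

test_that("subsampling is deterministic and degenerates to the full analysis", {
  reg <- toy_registry()
  withr::with_seed(47, {
    vectors <- dplyr::bind_rows(lapply(seq_len(nrow(reg)), function(ci) {
      offset <- max(reg$stem_age_mya) - reg$stem_age_mya[ci]
      tibble::tibble(
        id = paste0("P", ci, "_", 1:8),
        species = paste0("sp", ci, "_", 1:8),
        clade = reg$clade[ci], paralog = "F",
        pct_P = 5 + 0.02 * offset + rnorm(8, 0, 0.5)
      )
    }))
  })
  a <- subsample_robustness(vectors, reg, "pct_P", k = 3, reps = 5,
                            seed = 99)
  b <- subsample_robustness(vectors, reg, "pct_P", k = 3, reps = 5,
                            seed = 99)
  expect_identical(a, b)
  c2 <- subsample_robustness(vectors, reg, "pct_P", k = 3, reps = 5,
                             seed = 100)
  expect_false(identical(a$per_rep$r, c2$per_rep$r))
  # k >= max clade size: every repetition identical to the full analysis
  full <- subsample_robustness(vectors, reg, "pct_P", k = 8, reps = 4,
                               seed = 1)
  for (rix in 1:4) {
    expect_equal(full$per_rep$r[full$per_rep$rep == rix], full$full$r)
    expect_equal(full$per_rep$p[full$per_rep$rep == rix], full$full$p)
  }
  expect_equal(full$summary$n_significant, 4L)
  expect_error(subsample_robustness(vectors, reg, "pct_P", k = 0,
                                    reps = 2, seed = 1), "k")
  expect_error(subsample_robustness(vectors, reg, "pct_P", k = 2,
                                    reps = 2), "seed")
})

test_that("subsampling preserves significance of a strong planted trend", {
  reg <- default_registry()
  withr::with_seed(53, {
    vectors <- dplyr::bind_rows(lapply(seq_len(nrow(reg)), function(ci) {
      offset <- max(reg$stem_age_mya) - reg$stem_age_mya[ci]
      tibble::tibble(
        id = paste0("P", ci, "_", 1:12),
        species = paste0("sp", ci, "_", 1:12),
        clade = reg$clade[ci], paralog = "F",
        aar_P = pmax(0, 4 + 0.04 * offset + rnorm(12, 0, 1.5))
      )
    }))
  })
  out <- subsample_robustness(vectors, reg, "aar_P", k = 5, reps = 10,
                              seed = 7)
  expect_true(out$full$significant)
  expect_lt(out$full$r, 0)
  expect_gte(out$summary$n_significant, 9)
  expect_equal(out$summary$n_same_sign, 10L)
})
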