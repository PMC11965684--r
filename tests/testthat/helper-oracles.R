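# Independent brute-force oracles, kept deliberately naive and separate
# from the package's vectorized implementations.

aa20 <- lcrevol::AA20
ambig <- lcrevol::AA_AMBIGUOUS

random_sequence <- function(len, ambig_prob = 0) {
  pool <- aa20
  chars <- sample(pool, len, replace = TRUE)
  if (ambig_prob > 0) {
    hit <- runif(len) < ambig_prob
    chars[hit] <- sample(ambig, sum(hit), replace = TRUE)
  }
  paste(chars, collapse = "")
}

# window substring at position i: whole sequence when L <= 20, else the
# 9-up/10-down clipped window
oracle_window <- function(sequence, i) {
  L <- nchar(sequence)
  if (L <= 20) return(sequence)
  substr(sequence, max(1, i - 9), min(L, i + 10))
}

# SIM from first principles: counts by table(), population SD, quotient
oracle_sim <- function(window) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  a <- vapply(aa20, function(x) sum(chars == x), numeric(1))
  if (sum(a) == 0) return(NA_real_)
  m <- sum(a) / 20
  cv <- sqrt(sum((a - m)^2) / 20) / m
  b <- sum(a > 0)
  cv / (1 + log(b))
}

# REP from first principles: explicit left-to-right run scan
oracle_rep <- function(window) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  runs <- list()
  j <- 1
  while (j <= length(chars)) {
    k <- j
    while (k < length(chars) && chars[k + 1] == chars[j] &&
           chars[j] %in% aa20) k <- k + 1
    if (k - j + 1 >= 2 && chars[j] %in% aa20) {
      runs[[length(runs) + 1]] <- c(len = k - j + 1)
      names(runs)[length(runs)] <- chars[j]
    }
    j <- k + 1
  }
  if (!length(runs)) return(0)
  a <- sum(vapply(runs, identity, numeric(1)))
  b <- length(runs)
  cc <- length(unique(names(runs)))
  a / (b * cc)
}

oracle_sim_profile <- function(sequence) {
  vapply(seq_len(nchar(sequence)), function(i) {
    oracle_sim(oracle_window(sequence, i))
  }, numeric(1))
}

oracle_rep_profile <- function(sequence) {
  vapply(seq_len(nchar(sequence)), function(i) {
    oracle_rep(oracle_window(sequence, i))
  }, numeric(1))
}

# Pearson r and two-tailed p from covariance / t formulas directly
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    (n * sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

# construct a y-vector with an exact target Pearson r against x
vector_with_exact_r <- function(x, r, seed = 1) {
  withr::with_seed(seed, {
    e <- rnorm(length(x))
    e <- residuals(lm(e ~ x))
    as.numeric(r * scale(x) + sqrt(1 - r^2) * scale(e))
  })
}

# small annotated record set used across seqio/evolution tests
make_records <- function() {
  tibble::tibble(
    id = c("P1", "P2", "P3", "P4"),
    species = c("sp1", "sp2", "sp3", "sp4"),
    clade = c("Cho", "Cho", "Pri", "Pri"),
    paralog = "FAM1",
    sequence = c("MAAAQQQQWSSSSSSS", "MAAAAPPPPPWY",
                 "MQQQQLLLLKK", "MAPAPAPAPAP")
  )
}

write_temp_fasta <- function(records, dir = tempdir()) {
  path <- tempfile(fileext = ".fasta", tmpdir = dir)
  lcrevol::write_fasta(records, path)
  path
}
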