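#' Read protein records from a FASTA file
#'
#' Sequences are uppercased and validated against the canonical 20-letter
#' alphabet plus the permitted ambiguity codes (B, J, O, U, X, Z). Header
#' lines contribute the first whitespace-delimited token as the record id;
#' optional `key=value` tags (`species=`, `clade=`, `paralog=`) in the
#' header are honored, otherwise those fields are left `NA` for later
#' joining with a metadata table (see [join_metadata()]).
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @return A tibble of protein records with columns `id`, `species`,
#'   `clade`, `paralog`, `sequence`, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 species=Homo_sapiens clade=Pri paralog=CPEB2",
#'              "MAAAQ"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  tag <- function(header, key) {
    m <- regmatches(header, regexpr(paste0(key, "=\\S+"), header))
    if (length(m)) sub(paste0(key, "="), "", m) else NA_character_
  }
  sequences <- toupper(as.character(set))
  if (any(duplicated(ids))) {
    stop("duplicate record ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  .assert_sequences_valid(ids, sequences)
  n_ambig <- vapply(sequences, function(s) {
    sum(strsplit(s, "", fixed = TRUE)[[1]] %in% AA_AMBIGUOUS)
  }, integer(1))
  if (any(n_ambig > 0)) {
    warning(sum(n_ambig > 0), " record(s) contain ambiguity codes; ",
            "these positions join no count and break runs", call. = FALSE)
  }
  tibble::tibble(
    id = unname(ids),
    species = vapply(headers, tag, character(1), key = "species",
                     USE.NAMES = FALSE),
    clade = vapply(headers, tag, character(1), key = "clade",
                   USE.NAMES = FALSE),
    paralog = vapply(headers, tag, character(1), key = "paralog",
                     USE.NAMES = FALSE),
    sequence = unname(sequences)
  )
}

#' Write protein records to FASTA
#'
#' Annotations present on the records are serialized as `key=value` header
#' tags so that [read_fasta()] round-trips them.
#'
#' @param records protein-record tibble (columns `id`, `sequence`, optional
#'   `species`, `clade`, `paralog`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  headers <- records$id
  for (key in c("species", "clade", "paralog")) {
    if (key %in% names(records)) {
      val <- records[[key]]
      headers <- ifelse(is.na(val), headers,
                        paste0(headers, " ", key, "=", val))
    }
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Annotate protein records with a metadata table
#'
#' Joins a sidecar metadata table onto records read from FASTA. Metadata
#' rows are matched by `id`; records whose clade is not in the registry are
#' excluded with a warning. Annotations already present on a record (from
#' header tags) are kept unless the table supplies a value.
#'
#' @param records protein-record tibble from [read_fasta()].
#' @param metadata data frame with columns `id`, `species`, `clade`,
#'   `paralog`.
#' @param registry clade registry (see [clade_registry()]).
#' @return Annotated record tibble; excluded records are dropped.
#' @export
join_metadata <- function(records, metadata, registry) {
  metadata <- tibble::as_tibble(metadata)
  need <- c("id", "species", "clade", "paralog")
  if (!all(need %in% names(metadata))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(metadata$species, metadata$paralog, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- metadata[duplicated(key) | duplicated(key, fromLast = TRUE), ]
    stop("duplicate (species, paralog) rows in metadata: ",
         paste(unique(paste0("(", dup$species, ", ", dup$paralog, ")")),
               collapse = ", "), call. = FALSE)
  }
  m <- metadata[match(records$id, metadata$id), ]
  out <- records
  for (col in c("species", "clade", "paralog")) {
    out[[col]] <- ifelse(!is.na(m[[col]]), m[[col]], out[[col]])
  }
  unknown <- !is.na(out$clade) & !(out$clade %in% registry$clade)
  missing_clade <- is.na(out$clade)
  drop <- unknown | missing_clade
  if (any(drop)) {
    warning("excluding ", sum(drop), " record(s) with unknown or missing ",
            "clade: ", paste(out$id[drop], collapse = ", "), call. = FALSE)
  }
  out[!drop, , drop = FALSE]
}

#' Quality-filter ortholog records
#'
#' Discards records that (i) do not begin with the initial methionine, or
#' (ii) are shorter than the median length of their (clade, paralog) group
#' by more than `length_deficit_threshold` residues — a programmatic
#' stand-in for flagging sequences with large deletions by visual
#' alignment inspection. Groups of size 1 skip rule (ii).
#'
#' @param records annotated protein-record tibble (needs `clade`,
#'   `paralog`).
#' @param length_deficit_threshold residues below the group median beyond
#'   which a record is discarded (default 50).
#' @return A list with elements `kept` (record tibble) and `discarded`
#'   (tibble of `id`, `reason`).
#' @export
qc_filter <- function(records, length_deficit_threshold = 50) {
  n <- nrow(records)
  len <- nchar(records$sequence)
  first <- substr(records$sequence, 1, 1)
  reason <- rep(NA_character_, n)
  reason[first != "M"] <- "no initial methionine"
  grp <- paste(records$clade, records$paralog, sep = "\r")
  for (g in unique(grp)) {
    sel <- which(grp == g)
    if (length(sel) < 2) next
    med <- median(len[sel])
    short <- sel[med - len[sel] > length_deficit_threshold]
    short <- short[is.na(reason[short])]
    reason[short] <- sprintf(
      "length deficit %g > %g vs group median %g",
      med - len[short], length_deficit_threshold, med)
  }
  keep <- is.na(reason)
  list(
    kept = records[keep, , drop = FALSE],
    discarded = tibble::tibble(id = records$id[!keep],
                               reason = reason[!keep])
  )
}

#' Read external per-protein or per-residue score tables
#'
#' Ingests predictor output (e.g., PLAAC prion-domain scores, ParSe
#' classifier distances, FuzDrop droplet-promoting probabilities) from a
#' TSV with columns `protein_id`, `score_name`, `position`, `value`. An
#' empty/missing `position` denotes a single per-protein value; otherwise
#' rows for one (protein, score) must cover contiguous 1-based positions.
#'
#' @param path TSV file.
#' @return A tibble with one row per (protein_id, score_name):
#'   columns `protein_id`, `score_name`, `value` (per-protein value or `NA`),
#'   `track` (list column of per-residue numeric vectors or `NULL`).
#' @export
read_external_scores <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           protein_id = readr::col_character(),
                           score_name = readr::col_character(),
                           position = readr::col_integer(),
                           value = readr::col_double()
                         ))
  need <- c("protein_id", "score_name", "position", "value")
  if (!all(need %in% names(raw))) {
    stop("external score table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  groups <- split(raw, paste(raw$protein_id, raw$score_name, sep = "\r"))
  out <- lapply(groups, function(g) {
    per_protein <- is.na(g$position)
    if (any(per_protein) && any(!per_protein)) {
      stop("mixed per-residue and per-protein rows for (",
           g$protein_id[1], ", ", g$score_name[1], ")", call. = FALSE)
    }
    if (all(per_protein)) {
      if (nrow(g) > 1) {
        stop("multiple per-protein values for (", g$protein_id[1], ", ",
             g$score_name[1], ")", call. = FALSE)
      }
      tibble::tibble(protein_id = g$protein_id[1],
                     score_name = g$score_name[1],
                     value = g$value, track = list(NULL))
    } else {
      g <- g[order(g$position), ]
      expected <- seq_len(max(g$position))
      gaps <- setdiff(expected, g$position)
      if (length(gaps) || g$position[1] != 1) {
        stop("non-contiguous positions for (", g$protein_id[1], ", ",
             g$score_name[1], "); missing: ",
             paste(head(sort(unique(c(gaps,
               if (g$position[1] != 1) 1L))), 10), collapse = ", "),
             call. = FALSE)
      }
      tibble::tibble(protein_id = g$protein_id[1],
                     score_name = g$score_name[1],
                     value = NA_real_, track = list(g$value))
    }
  })
  dplyr::bind_rows(out)
}

#' Check external score tracks against sequence lengths
#'
#' @param scores external score tibble from [read_external_scores()].
#' @param records protein-record tibble.
#' @return `scores`, invisibly; errors if any per-residue track length
#'   differs from its protein's sequence length.
#' @export
validate_external_scores <- function(scores, records) {
  len <- stats::setNames(nchar(records$sequence), records$id)
  for (k in seq_len(nrow(scores))) {
    trk <- scores$track[[k]]
    id <- scores$protein_id[k]
    if (!is.null(trk) && id %in% names(len) && length(trk) != len[[id]]) {
      stop("track length ", length(trk), " for (", id, ", ",
           scores$score_name[k], ") does not match sequence length ",
           len[[id]], call. = FALSE)
    }
  }
  invisible(scores)
}

#' Write a long-format parameter table
#'
#' Deterministic output: fixed column order, rows sorted by (clade,
#' species, paralog, parameter), full floating precision. Re-running on the
#' same input yields a byte-identical file.
#'
#' @param rows tibble with columns `id`, `species`, `clade`, `paralog`,
#'   `parameter`, `value`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(rows, path) {
  need <- c("id", "species", "clade", "paralog", "parameter", "value")
  if (!all(need %in% names(rows))) {
    stop("rows must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rows <- rows[need]
  rows <- rows[order(rows$clade, rows$species, rows$paralog,
                     rows$parameter, method = "radix"), , drop = FALSE]
  rows$value <- sprintf("%.17g", rows$value)
  readr::write_tsv(rows, path)
  invisible(path)
}

#' Export homorepeats as a BED-like interval table
#'
#' Columns `protein_id`, `start`, `end`, `amino_acid`, `length`, with
#' `start`/`end` in the 0-based half-open BED convention (internal AAR
#' coordinates are 1-based inclusive).
#'
#' @param aars AAR tibble from [find_aars()] with an added `protein_id`
#'   column, or a tibble already carrying one.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_aar_bed <- function(aars, path) {
  stopifnot(all(c("protein_id", "aa", "start", "end", "length")
                %in% names(aars)))
  bed <- tibble::tibble(
    protein_id = aars$protein_id,
    start = aars$start - 1L,
    end = aars$end,
    amino_acid = aars$aa,
    length = aars$length
  )
  readr::write_tsv(bed, path)
  invisible(path)
}
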