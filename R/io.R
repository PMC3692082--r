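#' Read target (3'UTR or custom) sequences from a FASTA file
#'
#' Sequences are uppercased and canonicalized to the DNA alphabet (U -> T) so
#' that all downstream complementarity checks run over a single alphabet.
#' When several records share a gene identifier -- typically alternative
#' 3'UTR isoforms -- only the longest is retained, the standard rule for
#' collapsing isoforms to one scoring sequence per gene; ties keep the first
#' record encountered.
#'
#' @param path Path to a FASTA file.
#' @param keep_longest_per_gene Keep only the longest sequence per gene id
#'   (default `TRUE`).
#' @param source Provenance tag stored with each sequence, one of
#'   `"reference_utr"` or `"custom"`.
#' @return A tibble with columns `gene`, `sequence`, `source`.
#' @export
read_target_fasta <- function(path, keep_longest_per_gene = TRUE,
                              source = c("reference_utr", "custom")) {
  source <- match.arg(source)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(seqs) == 0L) abort(paste0("FASTA file is empty: ", path))
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- canonicalize_sequence(unname(as.character(seqs)), ids)
  tbl <- tibble(gene = ids, sequence = chars, source = source)
  if (keep_longest_per_gene) {
    tbl <- tbl |>
      mutate(.len = nchar(.data$sequence), .ord = seq_len(dplyr::n())) |>
      group_by(.data$gene) |>
      # stable: first record wins a length tie
      arrange(dplyr::desc(.data$.len), .data$.ord, .by_group = TRUE) |>
      slice(1L) |>
      ungroup() |>
      arrange(.data$.ord) |>
      select(-".len", -".ord")
  }
  tbl
}

# Uppercase, U->T, and validate the alphabet; `ids` only feeds error messages.
canonicalize_sequence <- function(x, ids = NULL) {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    who <- if (is.null(ids)) which(bad)[1] else ids[bad][1]
    abort(paste0("sequence '", who, "' contains characters outside {A,C,G,T,U,N}"))
  }
  if (any(!nzchar(x))) {
    who <- if (is.null(ids)) which(!nzchar(x))[1] else ids[!nzchar(x)][1]
    abort(paste0("sequence '", who, "' is empty"))
  }
  x
}

#' Read a miRNA expression table
#'
#' The expected layout is comma-separated text whose first row holds sample
#' identifiers and whose first column holds miRNA identifiers.  A bare list of
#' miRNA identifiers (one per line, no commas) is also accepted and yields a
#' single implicit sample in which every miRNA has level 1, i.e. all miRNAs
#' equally expressed.
#'
#' @param path Path to a CSV file (or id-only list).
#' @return A wide tibble: column `mirna` plus one numeric column per sample,
#'   levels on whatever scale the file used (see [log_to_linear()]).
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) abort(paste0("expression table not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("expression table is empty: ", path))
  if (!any(grepl(",", lines))) {
    ids <- trimws(lines)
    tbl <- tibble(mirna = ids, sample_1 = rep(1, length(ids)))
    return(validate_expression_table(tbl))
  }
  cells <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    abort(paste0("ragged expression table: row ", which(widths != widths[1])[1],
                 " has ", widths[widths != widths[1]][1], " fields, expected ", widths[1]))
  }
  header <- trimws(cells[[1]])
  samples <- header[-1]
  if (length(samples) == 0L) abort("expression table header declares no samples")
  body <- cells[-1]
  ids <- vapply(body, function(r) trimws(r[1]), character(1))
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples))
  for (i in seq_along(body)) {
    row <- trimws(body[[i]])[-1]
    num <- suppressWarnings(as.numeric(row))
    if (anyNA(num)) {
      j <- which(is.na(num))[1]
      abort(paste0("non-numeric value '", row[j], "' at row ", i + 1L,
                   " (miRNA '", ids[i], "'), column '", samples[j], "'"))
    }
    vals[i, ] <- num
  }
  tbl <- as_tibble(as.data.frame(vals)) |> setNames(samples)
  tbl <- dplyr::bind_cols(tibble(mirna = ids), tbl)
  validate_expression_table(tbl)
}

validate_expression_table <- function(tbl) {
  dup <- tbl$mirna[duplicated(tbl$mirna)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate miRNA id(s) in expression table: ",
                 paste(unique(dup), collapse = ", ")))
  }
  tbl
}

# Sample (value) columns of a wide expression table.
sample_columns <- function(tbl) setdiff(names(tbl), "mirna")

#' Read a per-site binding-score table
#'
#' The interchange format for pre-computed site scores is a 5-column TSV:
#' `gene_id`, `mirna_id`, `start`, `end`, `score`, with 0-based half-open
#' coordinates on the target sequence.  Invalid rows (non-numeric fields,
#' `start >= end`, negative coordinates) cause an error; the number of rows
#' read is attached so no row is ever dropped silently.
#'
#' @param path Path to the TSV (a header line is optional and detected).
#' @param channel One of `"miranda_energy"`, `"pita_ddg"`,
#'   `"targetscan_seed"`, `"mirsvr"`.
#' @param sequences Optional target-sequence tibble (from
#'   [read_target_fasta()]); when given, intervals are checked against
#'   sequence lengths.
#' @return A site tibble: `gene`, `mirna`, `start`, `end`, `score`,
#'   `channel`, `site_class` (`"imported"`).
#' @export
read_site_scores <- function(path, channel, sequences = NULL) {
  channel <- match_channel(channel)
  if (!file.exists(path)) abort(paste0("site-score table not found: ", path))
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (nrow(raw) == 0L) {
    return(empty_site_table(channel))
  }
  if (ncol(raw) != 5L) abort("site-score table must have 5 columns: gene_id, mirna_id, start, end, score")
  names(raw) <- c("gene", "mirna", "start", "end", "score")
  # tolerate a header row
  if (suppressWarnings(is.na(as.numeric(raw$start[1]))) && nrow(raw) >= 1L) {
    raw <- raw[-1, , drop = FALSE]
  }
  if (nrow(raw) == 0L) return(empty_site_table(channel))
  tbl <- tibble(
    gene  = as.character(raw$gene),
    mirna = as.character(raw$mirna),
    start = suppressWarnings(as.integer(raw$start)),
    end   = suppressWarnings(as.integer(raw$end)),
    score = suppressWarnings(as.numeric(raw$score))
  )
  bad <- is.na(tbl$start) | is.na(tbl$end) | is.na(tbl$score)
  if (any(bad)) abort(paste0(sum(bad), " unparseable row(s) in site-score table, first at data row ", which(bad)[1]))
  if (any(tbl$start < 0L)) abort("negative site coordinates are not allowed (0-based half-open expected)")
  if (any(tbl$start >= tbl$end)) {
    abort(paste0(sum(tbl$start >= tbl$end), " row(s) with start >= end rejected, first at data row ",
                 which(tbl$start >= tbl$end)[1]))
  }
  if (!is.null(sequences)) {
    lens <- setNames(nchar(sequences$sequence), sequences$gene)
    known <- tbl$gene %in% names(lens)
    over <- known & tbl$end > lens[tbl$gene]
    if (any(over)) abort(paste0(sum(over), " site(s) extend beyond the target sequence, first gene '",
                                tbl$gene[over][1], "'"))
  }
  tbl$channel <- channel
  tbl$site_class <- "imported"
  tbl
}

empty_site_table <- function(channel = character(0)) {
  tibble(gene = character(0), mirna = character(0),
         start = integer(0), end = integer(0), score = numeric(0),
         channel = if (length(channel)) character(0) else character(0),
         site_class = character(0))
}

#' Write a site tibble back to the 5-column TSV interchange format
#' @param sites A site tibble.
#' @param path Output path.
#' @export
write_site_scores <- function(sites, path) {
  readr::write_tsv(sites[, c("gene", "mirna", "start", "end", "score")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a miRNA id alias table (old id -> current id)
#'
#' Two-column comma- or tab-separated text; lines starting with `#` ignored.
#' @param path Path to the alias table.
#' @return A named character vector mapping old ids to current ids.
#' @export
read_alias_table <- function(path) {
  if (!file.exists(path)) abort(paste0("alias table not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) return(character(0))
  parts <- strsplit(lines, "[,\t]")
  bad <- lengths(parts) < 2L
  if (any(bad)) abort(paste0("alias table line ", which(bad)[1], " lacks two fields"))
  setNames(vapply(parts, function(p) trimws(p[2]), character(1)),
           vapply(parts, function(p) trimws(p[1]), character(1)))
}

#' Write a result table
#'
#' One row per gene, the gene-id column(s) first, then one score column per
#' label (sample or miRNA set), plus any difference / p-value columns the
#' differential analysis appended.
#'
#' @param result A result tibble (see [predict_targets()]).
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @export
write_results <- function(result, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (nrow(result) == 0L) abort("result table is empty")
  if (format == "csv") readr::write_csv(result, path) else readr::write_tsv(result, path)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#' @param path Path to the table.
#' @param format `"csv"` or `"tsv"`.
#' @return A tibble.
#' @export
read_results <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}
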