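#' Convert a log-scale expression table to linear scale
#'
#' Microarray-style miRNA expression values are often reported as logarithms;
#' concentrations must be computed on the linear scale, so every level x is
#' replaced by `base^x`.
#'
#' @param table Wide expression tibble from [read_expression_table()].
#' @param base Logarithm base the input used (default 2; must be > 1).
#' @return The table with all sample columns exponentiated.
#' @export
log_to_linear <- function(table, base = 2) {
  if (!is.numeric(base) || length(base) != 1L || base <= 1) {
    abort("`base` must be a single number > 1")
  }
  mutate(table, across(!dplyr::all_of("mirna"), ~ base^.x))
}

#' Resolve miRNA identifiers against an alias map and a known universe
#'
#' Old-style identifiers are renamed to their current form via `alias_map`;
#' identifiers absent from `known_ids` are removed from the analysis and
#' reported in the `dropped` attribute (and as a message) so the user is
#' notified rather than silently losing rows.
#'
#' @param table Wide expression tibble.
#' @param alias_map Named character vector, old id -> current id (may be
#'   empty).
#' @param known_ids Character vector of valid miRNA ids for the species, or
#'   `NULL` to skip the universe check.
#' @param quiet Suppress the notification message.
#' @return The table with ids resolved; attribute `dropped` holds a tibble
#'   (`mirna`, `reason`) of removed rows.
#' @export
resolve_ids <- function(table, alias_map = character(0), known_ids = NULL,
                        quiet = FALSE) {
  ids <- table$mirna
  hit <- ids %in% names(alias_map)
  ids[hit] <- unname(alias_map[ids[hit]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("alias resolution creates duplicate miRNA row(s): ",
                 paste(dup, collapse = ", ")))
  }
  table$mirna <- ids
  dropped <- tibble(mirna = character(0), reason = character(0))
  if (!is.null(known_ids)) {
    unknown <- setdiff(ids, known_ids)
    if (length(unknown) > 0L) {
      dropped <- tibble(mirna = unknown, reason = "unknown_id")
      table <- filter(table, !.data$mirna %in% unknown)
      if (!quiet) {
        inform(paste0("removed ", length(unknown), " miRNA(s) not in the known set: ",
                      paste(unknown, collapse = ", ")))
      }
    }
  }
  attr(table, "dropped") <- dropped
  table
}

#' Convert expression levels to per-sample concentrations
#'
#' Each miRNA's concentration in a sample is its fraction of the sample's
#' total expression, so concentrations sum to 1 per sample.
#'
#' @param table Wide, linear-scale expression tibble.
#' @return A long tibble: `sample`, `mirna`, `level`, `concentration`.
#' @export
to_concentrations <- function(table) {
  long <- tidyr::pivot_longer(table, !dplyr::all_of("mirna"),
                              names_to = "sample", values_to = "level")
  if (any(long$level < 0)) {
    abort("negative expression levels; convert log-scale input with log_to_linear() first")
  }
  totals <- long |> group_by(.data$sample) |> summarise(total = sum(.data$level))
  zero <- totals$sample[totals$total <= 0]
  if (length(zero) > 0L) {
    abort(paste0("sample(s) with zero total expression: ", paste(zero, collapse = ", ")))
  }
  long |>
    group_by(.data$sample) |>
    mutate(concentration = .data$level / sum(.data$level)) |>
    ungroup() |>
    select("sample", "mirna", "level", "concentration")
}

#' Build a filter policy for the concentration vectors
#'
#' @param coverage_percent Percentage of total miRNA abundance the retained
#'   top-expressed miRNAs must cover, in (0, 100].
#' @param min_level Minimum linear-scale expression level to retain a miRNA.
#' @param always_keep miRNA ids exempt from filtering (always retained).
#' @param mode `"set"` (one concentration vector per sample) or
#'   `"single_mirna"` (each miRNA analysed alone at concentration 1).
#' @param renormalize Rescale retained concentrations to sum to 1 after
#'   filtering; by default the original fractions are kept, preserving the
#'   physical concentration interpretation (a filtered miRNA's mass simply
#'   vanishes).
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(coverage_percent = 100, min_level = 0,
                          always_keep = character(0),
                          mode = c("set", "single_mirna"),
                          renormalize = FALSE) {
  mode <- match.arg(mode)
  if (!is.numeric(coverage_percent) || coverage_percent <= 0 || coverage_percent > 100) {
    abort("`coverage_percent` must be in (0, 100]")
  }
  if (!is.numeric(min_level) || min_level < 0) abort("`min_level` must be >= 0")
  structure(list(coverage_percent = coverage_percent, min_level = min_level,
                 always_keep = always_keep, mode = mode,
                 renormalize = renormalize),
            class = "filter_policy")
}

#' Restrict concentration vectors to the top-expressed miRNAs
#'
#' Per sample, the retained set is the intersection of (i) the minimal prefix
#' of miRNAs, sorted by descending concentration, whose cumulative fraction
#' reaches `coverage_percent`/100, and (ii) the miRNAs whose linear level is
#' at least `min_level`; miRNAs in `always_keep` are retained regardless.
#' Equal concentrations are ordered lexicographically by miRNA id so the
#' prefix is deterministic.  Retained concentrations keep their original
#' fractions unless the policy sets `renormalize`.
#'
#' @param conc Long concentration tibble from [to_concentrations()].
#' @param policy A [filter_policy()].
#' @return The filtered tibble; attribute `dropped` records
#'   (`sample`, `mirna`, `reason`).
#' @export
apply_filter <- function(conc, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  split_by <- split(conc, conc$sample)
  kept <- list(); drops <- list()
  for (s in names(split_by)) {
    v <- split_by[[s]]
    ord <- order(-v$concentration, v$mirna)
    v <- v[ord, , drop = FALSE]
    cum <- cumsum(v$concentration)
    need <- policy$coverage_percent / 100
    k <- which(cum >= need - 1e-12)[1]
    if (is.na(k)) k <- nrow(v)
    in_cov <- seq_len(nrow(v)) <= k
    in_min <- v$level >= policy$min_level
    keep <- (in_cov & in_min) | v$mirna %in% policy$always_keep
    reason <- dplyr::case_when(
      !in_cov & !in_min ~ "below_coverage_and_min_level",
      !in_cov ~ "below_coverage",
      TRUE ~ "below_min_level"
    )
    drops[[s]] <- tibble(sample = s, mirna = v$mirna[!keep], reason = reason[!keep])
    kept[[s]] <- v[keep, , drop = FALSE]
  }
  out <- bind_rows(kept)
  if (isTRUE(policy$renormalize) && nrow(out) > 0L) {
    out <- out |>
      group_by(.data$sample) |>
      mutate(concentration = .data$concentration / sum(.data$concentration)) |>
      ungroup()
  }
  dropped <- bind_rows(drops)
  if (nrow(out) == 0L) warn("filtering removed every miRNA")
  attr(out, "dropped") <- dropped
  out
}

#' Expand concentration vectors into the labelled analysis units
#'
#' In `"set"` mode each sample's concentration vector becomes one labelled
#' unit (one score column per sample downstream).  In `"single_mirna"` mode
#' each miRNA becomes its own unit with concentration 1, regardless of the
#' supplied levels, so each miRNA's individual contribution can be ranked.
#'
#' @param conc Long concentration tibble (possibly filtered).
#' @param policy A [filter_policy()]; only its `mode` is used.
#' @return A long tibble `label`, `mirna`, `concentration`.
#' @export
expand_modes <- function(conc, policy = filter_policy()) {
  if (policy$mode == "set") {
    conc |>
      select(label = "sample", "mirna", "concentration")
  } else {
    mirnas <- sort(unique(conc$mirna))
    tibble(label = mirnas, mirna = mirnas, concentration = 1)
  }
}

#' Dropped-row report attached by [resolve_ids()] and [apply_filter()]
#' @param x A tibble carrying a `dropped` attribute.
#' @return A tibble of dropped miRNAs with reasons (empty if none).
#' @export
dropped_mirnas <- function(x) {
  attr(x, "dropped") %||% tibble(mirna = character(0), reason = character(0))
}
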