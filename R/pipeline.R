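#' End-to-end target prediction for a miRNA set
#'
#' Runs the full two-step pipeline: (1) preprocess the expression table into
#' per-sample miRNA concentration vectors and combine per-site channel
#' scores into per-gene channel scores (Fermi-Dirac occupancy sums for
#' energy channels, concentration-weighted sums for seed counts and mirSVR
#' scores); (2) rank-normalize the channel scores and integrate them with
#' the trained SVM into a per-gene probability of being a functional target
#' of the miRNA set, one score column per sample (or per miRNA in
#' single-miRNA mode).
#'
#' @param expression Wide expression tibble ([read_expression_table()]).
#' @param targets Target-sequence tibble ([read_target_fasta()]).
#' @param model A trained `mirset_model` ([train_target_model()],
#'   [default_model()]).
#' @param mirnas miRNA-sequence tibble ([read_mirna_fasta()]); required for
#'   the built-in seed and energy scanners.
#' @param channels Channels to compute with the built-in scanners.
#' @param imported Named list of imported site tibbles
#'   (`pita_ddg`, `mirsvr`, or overrides for the computable channels).
#' @param policy A [filter_policy()] (abundance filtering and set vs
#'   single-miRNA mode).
#' @param fd An [fd_params()].
#' @param seed_def A [seed_definition()].
#' @param energy_model An [nn_energy_model()].
#' @param log_scale Input expression is log-scale; converted with
#'   [log_to_linear()] using `log_base`.
#' @param log_base Log base of the input when `log_scale`.
#' @param alias_map,known_ids Passed to [resolve_ids()] (skipped when
#'   `known_ids` is `NULL` and `alias_map` empty).
#' @param include_ranks Append per-label fractional-rank columns
#'   (`rank_<label>`) of the probabilities.
#' @return A `mirset_result` tibble: `gene` plus one probability column per
#'   label.  Attributes: `channels` (channels used), `dropped` (miRNAs
#'   removed, with reasons), `features` (the rank-normalized SVM input).
#' @export
predict_targets <- function(expression, targets, model, mirnas = NULL,
                            channels = c("miranda_energy", "targetscan_seed"),
                            imported = list(),
                            policy = filter_policy(),
                            fd = fd_params(),
                            seed_def = seed_definition(),
                            energy_model = nn_energy_model(),
                            log_scale = FALSE, log_base = 2,
                            alias_map = character(0), known_ids = NULL,
                            include_ranks = FALSE) {
  tbl <- expression
  if (log_scale) tbl <- log_to_linear(tbl, log_base)
  dropped_ids <- tibble(mirna = character(0), reason = character(0))
  if (!is.null(known_ids) || length(alias_map) > 0L) {
    tbl <- resolve_ids(tbl, alias_map, known_ids)
    dropped_ids <- dropped_mirnas(tbl)
  }
  conc <- to_concentrations(tbl)
  conc <- apply_filter(conc, policy)
  dropped <- bind_rows(dropped_ids, dropped_mirnas(conc))
  vectors <- expand_modes(conc, policy)

  wanted <- union(channels, names(imported))
  sites <- purrr::map(wanted, function(ch) {
    compute_channel_sites(targets, mirnas, ch, imported = imported[[ch]],
                          seed_def = seed_def, model = energy_model)
  })
  cm <- build_channel_matrix(sites, vectors, genes = targets$gene, params = fd)
  features <- channel_features(cm)
  pred <- predict(model, features)
  out <- tidyr::pivot_wider(pred, names_from = "label",
                            values_from = "probability")
  out <- arrange(out, match(.data$gene, targets$gene))
  if (include_ranks) {
    for (lab in unique(pred$label)) {
      out[[paste0("rank_", lab)]] <- rank_normalize(out[[lab]], "higher_is_target")
    }
  }
  structure(out, channels = attr(cm, "channels"), dropped = dropped,
            features = features,
            class = c("mirset_result", class(out)))
}
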