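#' Fermi-Dirac occupancy parameters
#'
#' Site occupancy is modelled as Fermi-Dirac: a site of energy E is occupied
#' with probability `1 / (1 + exp((E - mu)/kT))`, where the chemical
#' potential `mu = mu0 + kT * log(c)` rises with the miRNA concentration
#' `c`, so abundant miRNAs occupy weaker sites.  `kT` defaults to RT at
#' 25 C (0.593 kcal/mol).  `mu0` anchors the chemical potential at c = 1;
#' it defaults to -12 kcal/mol, the typical seed-anchored duplex energy
#' under the shipped nearest-neighbor table, which keeps occupancy
#' responsive to concentration over the energy range real sites occupy
#' (a chemical potential far above the site-energy scale saturates every
#' occupancy and degenerates the model into site counting).  `epsilon`
#' floors the concentration inside the logarithm.  All three are
#' calibration choices and configurable.
#'
#' @param kT Thermal energy, kcal/mol, > 0.
#' @param mu0 Chemical-potential offset, kcal/mol.
#' @param epsilon Concentration floor in (0, 1).
#' @return An `fd_params` list.
#' @export
fd_params <- function(kT = 0.593, mu0 = -12, epsilon = 1e-9) {
  if (!is.numeric(kT) || kT <= 0) abort("`kT` must be > 0")
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 1) abort("`epsilon` must be in (0, 1)")
  structure(list(kT = kT, mu0 = mu0, epsilon = epsilon), class = "fd_params")
}

#' Fermi-Dirac occupancy probability of a binding site
#'
#' @param energy Site binding energy (kcal/mol); more negative is stronger.
#' @param concentration miRNA concentration in [0, 1] (floored at
#'   `params$epsilon`).
#' @param params An [fd_params()].
#' @return Occupancy probability in (0, 1); vectorized; strictly decreasing
#'   in `energy` and strictly increasing in `concentration`.
#' @export
fermi_dirac_probability <- function(energy, concentration, params = fd_params()) {
  stopifnot(inherits(params, "fd_params"))
  mu <- params$mu0 + params$kT * log(pmax(concentration, params$epsilon))
  # plogis is the overflow-safe logistic
  plogis((mu - energy) / params$kT)
}

#' Combine energy-channel sites into per-gene Fermi-Dirac scores
#'
#' The per-gene score is the expected number of occupied sites: the sum of
#' Fermi-Dirac occupancy probabilities over every site of every miRNA in the
#' concentration vector.  Genes without sites score 0.  Sites whose miRNA is
#' absent from the vector (filtered upstream) contribute nothing; their
#' count is attached as attribute `ignored_sites`.
#'
#' @param sites Site tibble of an energy channel (`miranda_energy` or
#'   `pita_ddg`).
#' @param conc Tibble (`mirna`, `concentration`) for one labelled unit.
#' @param params An [fd_params()].
#' @param genes Optional gene universe; genes with no sites are reported
#'   with score 0.
#' @return Tibble (`gene`, `score`).
#' @export
combine_fermi_dirac <- function(sites, conc, params = fd_params(), genes = NULL) {
  matched <- inner_join(sites, conc[, c("mirna", "concentration")], by = "mirna")
  n_ignored <- nrow(sites) - nrow(matched)
  scored <- matched |>
    mutate(p = fermi_dirac_probability(.data$score, .data$concentration, params)) |>
    group_by(.data$gene) |>
    summarise(score = sum(.data$p))
  out <- fill_gene_universe(scored, genes)
  attr(out, "ignored_sites") <- n_ignored
  out
}

#' Combine per-(gene, miRNA) scores into a concentration-weighted sum
#'
#' Used for the seed-count channel (value = number of sites) and the mirSVR
#' channel (value = sum of site scores): the gene score is
#' `sum_i c_i * s_ik`.
#'
#' @param per_gene_mirna Tibble (`gene`, `mirna`, `value`).
#' @param conc Tibble (`mirna`, `concentration`).
#' @param genes Optional gene universe (absent genes score 0).
#' @return Tibble (`gene`, `score`).
#' @export
combine_weighted_sum <- function(per_gene_mirna, conc, genes = NULL) {
  scored <- per_gene_mirna |>
    inner_join(conc[, c("mirna", "concentration")], by = "mirna") |>
    group_by(.data$gene) |>
    summarise(score = sum(.data$concentration * .data$value))
  fill_gene_universe(scored, genes)
}

fill_gene_universe <- function(scored, genes) {
  if (is.null(genes)) return(scored)
  missing <- setdiff(genes, scored$gene)
  bind_rows(scored, tibble(gene = missing, score = 0)) |>
    filter(.data$gene %in% genes) |>
    arrange(match(.data$gene, genes))
}

# per-(gene, miRNA) single-target scores for the weighted-sum channels:
# seed channel -> site count; mirsvr -> sum of site scores
per_gene_mirna_scores <- function(sites, channel) {
  if (channel == "targetscan_seed") {
    sites |> group_by(.data$gene, .data$mirna) |>
      summarise(value = dplyr::n(), .groups = "drop")
  } else {
    sites |> group_by(.data$gene, .data$mirna) |>
      summarise(value = sum(.data$score), .groups = "drop")
  }
}

#' Build the gene x channel score matrix for every labelled unit
#'
#' First integration step: for each labelled concentration vector (a sample,
#' or a single miRNA in single-miRNA mode) and each available channel, the
#' per-site scores are combined into one per-gene score -- Fermi-Dirac
#' summation for the energy channels, concentration-weighted sums for the
#' seed-count and mirSVR channels.
#'
#' @param sites One site tibble covering all channels (bind the per-channel
#'   tables), or a named list of per-channel tibbles.
#' @param vectors Labelled concentration tibble
#'   (`label`, `mirna`, `concentration`) from [expand_modes()].
#' @param genes Gene universe (character); defaults to all genes seen in
#'   `sites`.
#' @param params An [fd_params()].
#' @return Long tibble (`gene`, `label`, `channel`, `score`); attribute
#'   `channels` lists the channels present.
#' @export
build_channel_matrix <- function(sites, vectors, genes = NULL, params = fd_params()) {
  if (is.list(sites) && !is.data.frame(sites)) sites <- bind_rows(sites)
  channels <- intersect(CHANNELS, unique(sites$channel))
  if (length(channels) == 0L) abort("no site-score channels present")
  if (is.null(genes)) genes <- sort(unique(sites$gene))
  labels <- unique(vectors$label)
  blocks <- purrr::map(labels, function(lab) {
    conc <- vectors |> filter(.data$label == lab)
    per_channel <- purrr::map(channels, function(ch) {
      ch_sites <- sites |> filter(.data$channel == ch)
      scored <- if (ch %in% FD_CHANNELS) {
        combine_fermi_dirac(ch_sites, conc, params, genes = genes)
      } else {
        combine_weighted_sum(per_gene_mirna_scores(ch_sites, ch), conc, genes = genes)
      }
      mutate(scored, label = lab, channel = ch)
    })
    bind_rows(per_channel)
  })
  out <- bind_rows(blocks) |> select("gene", "label", "channel", "score")
  attr(out, "channels") <- channels
  out
}
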