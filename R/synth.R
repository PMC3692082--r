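#' Specification for a synthetic prediction fixture
#'
#' Describes a self-contained synthetic data set emulating a small
#' target-prediction study: random 3'UTR-like target sequences, a miRNA set
#' with a power-law expression profile, planted exact seed-complement sites
#' on the target-class genes for the most abundant miRNAs, decoy genes with
#' background-only matches, noisy pre-computed score tables for the
#' import-only channels, and target/decoy labels for training.
#'
#' @param n_genes Number of genes (split into targets and decoys).
#' @param n_mirnas Number of miRNAs.
#' @param n_samples Number of expression samples.
#' @param frac_targets Fraction of genes in the target class.
#' @param utr_length Length range (min, max) of the random target
#'   sequences, nt.
#' @param sites_per_target Planted seed sites per target-class gene.
#' @param n_planted_mirnas How many of the most abundant miRNAs receive
#'   planted sites.
#' @param expression_exponent Power-law exponent of the expression profile
#'   (level of the i-th miRNA proportional to `i^-exponent`).
#' @param sample_noise_sdlog Log-normal sample-to-sample noise on levels.
#' @param decoy_site_rate Expected number of weak background imported sites
#'   per decoy gene.
#' @param noise_sd Gaussian noise on the imported-channel site scores
#'   (kcal/mol for the ddG channel).
#' @param gc_bias GC fraction of the background sequence composition
#'   (0.5 = uniform).
#' @param seed RNG seed; the fixture is byte-identical given the seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 200, n_mirnas = 20, n_samples = 2,
                         frac_targets = 0.5, utr_length = c(300, 1500),
                         sites_per_target = 3, n_planted_mirnas = 5,
                         expression_exponent = 1, sample_noise_sdlog = 0.25,
                         decoy_site_rate = 0.2, noise_sd = 1,
                         gc_bias = 0.5, seed = 42) {
  if (utr_length[1] < 8L) abort("UTRs must be at least one seed site (8 nt) long")
  n_targets <- round(n_genes * frac_targets)
  if (n_targets < 1L || n_targets >= n_genes) {
    abort("both the target and the decoy class must be non-empty")
  }
  structure(list(n_genes = n_genes, n_mirnas = n_mirnas, n_samples = n_samples,
                 n_targets = n_targets, utr_length = utr_length,
                 sites_per_target = sites_per_target,
                 n_planted_mirnas = min(n_planted_mirnas, n_mirnas),
                 expression_exponent = expression_exponent,
                 sample_noise_sdlog = sample_noise_sdlog,
                 decoy_site_rate = decoy_site_rate, noise_sd = noise_sd,
                 gc_bias = gc_bias, seed = seed),
            class = "fixture_spec")
}

random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(len, function(l) {
    paste(sample(names(p), l, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# target-site sequence (5'->3') of a perfect 8mer for a miRNA
planted_8mer <- function(mirna_sequence) {
  paste0(revcomp_dna(substr(mirna_sequence, 2L, 8L)), "A")
}

#' Generate a synthetic prediction fixture
#'
#' Target-class genes carry `sites_per_target` exact 8mer seed complements
#' of the most abundant miRNAs at non-overlapping positions; decoy genes are
#' pure background.  The import-only channel tables (`pita_ddg`, `mirsvr`)
#' score the planted sites with strength-correlated negative values plus
#' Gaussian noise, and decoys at a weak background rate.  With `dir` given,
#' the bundle is also written to disk (FASTA, CSV, TSV).
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory for the file bundle.
#' @return A list: `targets`, `mirnas`, `expression`, `imported` (named list
#'   of `pita_ddg` / `mirsvr` site tibbles), `labels` (`gene`, `class`),
#'   `planted` (registry of planted sites), `spec`, and `paths` when
#'   written.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  mirna_ids <- sprintf("mir-%02d", seq_len(spec$n_mirnas))
  mirnas <- tibble(mirna = mirna_ids,
                   sequence = random_dna(spec$n_mirnas, rep(22L, spec$n_mirnas)))

  # power-law expression profile with per-sample log-normal noise
  base_level <- 1000 * seq_len(spec$n_mirnas)^(-spec$expression_exponent)
  expression <- tibble(mirna = mirna_ids)
  for (s in seq_len(spec$n_samples)) {
    expression[[sprintf("sample_%d", s)]] <-
      base_level * exp(rnorm(spec$n_mirnas, 0, spec$sample_noise_sdlog))
  }

  gene_ids <- sprintf("gene%03d", seq_len(spec$n_genes))
  classes <- c(rep("target", spec$n_targets),
               rep("decoy", spec$n_genes - spec$n_targets))
  lens <- sample(seq(spec$utr_length[1], spec$utr_length[2]), spec$n_genes,
                 replace = TRUE)
  seqs <- random_dna(spec$n_genes, lens, spec$gc_bias)

  planted <- list()
  planted_pool <- seq_len(spec$n_planted_mirnas)   # most abundant miRNAs
  for (g in which(classes == "target")) {
    L <- lens[g]
    k <- spec$sites_per_target
    chunk <- floor(L / k)
    if (chunk < 9L) abort("UTR length too short for the requested planted sites")
    for (j in seq_len(k)) {
      m <- sample(planted_pool, 1L)
      site <- planted_8mer(mirnas$sequence[m])
      pos <- (j - 1L) * chunk + sample.int(chunk - 8L, 1L)   # 1-based
      substr(seqs[g], pos, pos + 7L) <- site
      planted[[length(planted) + 1L]] <- tibble(
        gene = gene_ids[g], mirna = mirna_ids[m],
        start = pos - 1L, end = pos + 6L,          # seed-region interval
        strength = runif(1, 0.5, 1.5))
    }
  }
  planted <- bind_rows(planted)
  targets <- tibble(gene = gene_ids, sequence = seqs, source = "reference_utr")

  # imported-channel tables: planted-strength-dependent scores plus noise
  pita <- planted |>
    mutate(score = pmin(-0.1, -8 * .data$strength + rnorm(dplyr::n(), 0, spec$noise_sd)),
           channel = "pita_ddg", site_class = "imported") |>
    select("gene", "mirna", "start", "end", "score", "channel", "site_class")
  mirsvr <- planted |>
    mutate(score = pmin(-0.01, -1.2 * .data$strength + rnorm(dplyr::n(), 0, spec$noise_sd / 5)),
           channel = "mirsvr", site_class = "imported") |>
    select("gene", "mirna", "start", "end", "score", "channel", "site_class")

  # weak background sites on decoys
  decoys <- which(classes == "decoy")
  n_bg <- rbinom(length(decoys), 1, min(1, spec$decoy_site_rate))
  bg_rows <- list()
  for (i in seq_along(decoys)) {
    if (n_bg[i] == 0L) next
    g <- decoys[i]
    m <- sample(seq_len(spec$n_mirnas), 1L)
    pos <- sample.int(max(1L, lens[g] - 8L), 1L)
    bg_rows[[length(bg_rows) + 1L]] <- tibble(
      gene = gene_ids[g], mirna = mirna_ids[m],
      start = pos - 1L, end = pos + 6L,
      strength = runif(1, 0.05, 0.3))
  }
  if (length(bg_rows) > 0L) {
    bg <- bind_rows(bg_rows)
    pita <- bind_rows(pita, bg |>
      mutate(score = pmin(-0.1, -8 * .data$strength + rnorm(dplyr::n(), 0, spec$noise_sd)),
             channel = "pita_ddg", site_class = "imported") |>
      select("gene", "mirna", "start", "end", "score", "channel", "site_class"))
    mirsvr <- bind_rows(mirsvr, bg |>
      mutate(score = pmin(-0.01, -1.2 * .data$strength + rnorm(dplyr::n(), 0, spec$noise_sd / 5)),
             channel = "mirsvr", site_class = "imported") |>
      select("gene", "mirna", "start", "end", "score", "channel", "site_class"))
  }

  labels <- tibble(gene = gene_ids, class = classes)
  out <- list(targets = targets, mirnas = mirnas, expression = expression,
              imported = list(pita_ddg = pita, mirsvr = mirsvr),
              labels = labels, planted = planted, spec = spec)
  if (!is.null(dir)) out$paths <- write_fixture(out, dir)
  out
}

write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    targets = file.path(dir, "targets.fa"),
    mirnas = file.path(dir, "mirnas.fa"),
    expression = file.path(dir, "expression.csv"),
    pita_ddg = file.path(dir, "pita_sites.tsv"),
    mirsvr = file.path(dir, "mirsvr_sites.tsv"),
    labels = file.path(dir, "labels.csv")
  )
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(fixture$targets$sequence), fixture$targets$gene),
    paths$targets)
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(fixture$mirnas$sequence), fixture$mirnas$mirna),
    paths$mirnas)
  readr::write_csv(fixture$expression, paths$expression)
  write_site_scores(fixture$imported$pita_ddg, paths$pita_ddg)
  write_site_scores(fixture$imported$mirsvr, paths$mirsvr)
  readr::write_csv(fixture$labels, paths$labels)
  paths
}

#' Wild-type / variant sequence pair around a planted site
#'
#' Produces two target-sequence tables differing by a single substitution
#' inside a planted seed site, emulating a SNP that disrupts a miRNA binding
#' site: the variant base destroys the exact seed complement, so the
#' affected gene loses that site.
#'
#' @param fixture A fixture from [generate_fixture()].
#' @param gene Gene to mutate (default: the first target-class gene).
#' @param position 0-based position of the substitution; must fall inside
#'   the 6mer core of a planted site (default: the middle of the gene's
#'   first planted site).
#' @return A list: `wild_type` and `variant` target tibbles (all genes),
#'   plus `gene`, `position`, `mirna` (the miRNA whose site is destroyed).
#' @export
fixture_snp_pair <- function(fixture, gene = NULL, position = NULL) {
  planted <- fixture$planted
  if (is.null(gene)) gene <- planted$gene[1]
  sites <- planted |> filter(.data$gene == !!gene)
  if (nrow(sites) == 0L) abort(paste0("gene '", gene, "' has no planted sites"))
  # the 6mer core excludes the m8-pairing base at `start`
  if (is.null(position)) {
    position <- sites$start[1] + 4L
  }
  hit <- sites |> filter(position >= .data$start + 1L, position < .data$end)
  if (nrow(hit) == 0L) {
    abort(paste0("position ", position,
                 " is outside the seed core of every planted site of '", gene, "'"))
  }
  seqs <- fixture$targets
  i <- which(seqs$gene == gene)
  old <- substr(seqs$sequence[i], position + 1L, position + 1L)
  new <- setdiff(c("G", "C", "T", "A"), old)[1]
  variant <- seqs
  substr(variant$sequence[i], position + 1L, position + 1L) <- new
  variant$source <- "custom"
  list(wild_type = seqs, variant = variant,
       gene = gene, position = position, mirna = hit$mirna[1])
}

#' Train the default model on the default synthetic fixture
#'
#' Convenience constructor: generates the default synthetic fixture, runs
#' the channel scoring and rank normalization, and trains the SVM on the
#' fixture's target/decoy labels.  The returned model is trained on
#' synthetic data only -- suitable for demonstrations and for workflows on
#' synthetic sequence sets; retrain on your own labelled genes (e.g.
#' AGO-IP-derived target lists) for real analyses.
#'
#' @param seed RNG seed for the fixture and the training.
#' @param spec Optional [fixture_spec()] override.
#' @return A `mirset_model` (attribute `training` = "synthetic-fixture").
#' @export
default_model <- function(seed = 42, spec = NULL) {
  if (is.null(spec)) spec <- fixture_spec(seed = seed)
  fx <- generate_fixture(spec)
  feats <- fixture_features(fx)
  model <- train_target_model(feats, fx$labels, seed = seed)
  attr(model, "training") <- "synthetic-fixture"
  model
}

# channel features of a fixture's first sample, over all four channels
fixture_features <- function(fixture, sample = NULL, fd = fd_params()) {
  conc <- to_concentrations(fixture$expression)
  if (is.null(sample)) sample <- conc$sample[1]
  conc <- conc |> filter(.data$sample == !!sample)
  vectors <- tibble(label = sample, mirna = conc$mirna,
                    concentration = conc$concentration)
  sites <- list(
    compute_channel_sites(fixture$targets, fixture$mirnas, "miranda_energy"),
    compute_channel_sites(fixture$targets, fixture$mirnas, "targetscan_seed"),
    fixture$imported$pita_ddg,
    fixture$imported$mirsvr
  )
  cm <- build_channel_matrix(sites, vectors, genes = fixture$targets$gene, params = fd)
  channel_features(cm)
}
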