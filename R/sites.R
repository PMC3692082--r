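#' Seed-match definition
#'
#' The seed is miRNA nucleotides 2-8 from the 5' end.  Canonical site classes
#' on the target are: 6mer (perfect match to the reverse complement of
#' positions 2-7), 7mer-m8 (6mer plus a match to position 8), 7mer-A1 (6mer
#' plus an A across from position 1) and 8mer (both).  `classes` selects
#' which are reported; a stronger site is reported once, as the strongest
#' accepted class it qualifies for (an 8mer counts as a 7mer when only 7mer
#' classes are accepted).
#'
#' @param classes Non-empty subset of `c("6mer","7mer_A1","7mer_m8","8mer")`.
#'   Default: the three classes with experimentally supported efficacy.
#' @return A `seed_definition` list.
#' @export
seed_definition <- function(classes = c("7mer_A1", "7mer_m8", "8mer")) {
  all_classes <- c("6mer", "7mer_A1", "7mer_m8", "8mer")
  classes <- match.arg(classes, all_classes, several.ok = TRUE)
  if (length(classes) == 0L) abort("at least one seed class must be accepted")
  structure(list(classes = classes), class = "seed_definition")
}

# strength order, weakest first
SEED_CLASS_ORDER <- c("6mer", "7mer_A1", "7mer_m8", "8mer")

# which classes a site of a given native class can be reported as
seed_class_qualifies <- list(
  `6mer`    = "6mer",
  `7mer_A1` = c("7mer_A1", "6mer"),
  `7mer_m8` = c("7mer_m8", "6mer"),
  `8mer`    = c("8mer", "7mer_m8", "7mer_A1", "6mer")
)

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Scan a target sequence for miRNA seed-match sites
#'
#' Reports every occurrence on the target of the reverse complement of the
#' miRNA seed (positions 2-7, extended by position 8 and/or the A1 anchor
#' where present), including overlapping occurrences.  Each occurrence is
#' reported once with the strongest accepted class it qualifies for.
#' Coordinates are 0-based half-open over the target nucleotides pairing the
#' seed region (the A1 anchor adenosine is not part of the interval).
#' Windows containing ambiguous bases (N) are skipped.  No conservation
#' information is used.
#'
#' @param target_sequence Target (3'UTR) sequence, character.
#' @param mirna_sequence Mature miRNA sequence, 5' to 3', length >= 8.
#' @param gene,mirna Identifiers recorded in the output.
#' @param seed_def A [seed_definition()].
#' @return A site tibble (`gene`, `mirna`, `start`, `end`, `score`,
#'   `channel`, `site_class`) with `score` 1 per site and channel
#'   `"targetscan_seed"`.
#' @export
scan_seed_sites <- function(target_sequence, mirna_sequence,
                            gene = "gene", mirna = "mirna",
                            seed_def = seed_definition()) {
  targets <- tibble(gene = gene,
                    sequence = canonicalize_sequence(target_sequence, gene))
  seed_hits_for_mirna(targets, mirna_sequence, mirna, seed_def)
}

# Vectorized scan of one miRNA against many targets.
seed_hits_for_mirna <- function(targets, mirna_sequence, mirna,
                                seed_def = seed_definition()) {
  stopifnot(inherits(seed_def, "seed_definition"))
  mir <- canonicalize_sequence(mirna_sequence, mirna)
  if (nchar(mir) < 8L) abort(paste0("miRNA '", mirna, "' shorter than 8 nt"))
  core <- revcomp_dna(substr(mir, 2L, 7L))          # 6mer core on the target
  m8_base <- comp_base(substr(mir, 8L, 8L))         # target base pairing position 8
  subjects <- Biostrings::DNAStringSet(targets$sequence)
  hits <- Biostrings::vmatchPattern(core, subjects, fixed = TRUE)
  n_hits <- lengths(hits)
  if (sum(n_hits) == 0L) return(empty_site_table("targetscan_seed"))
  gi <- rep.int(seq_len(nrow(targets)), n_hits)
  starts <- unlist(lapply(hits, Biostrings::start), use.names = FALSE) # 1-based
  tgt <- targets$sequence[gi]
  len <- nchar(tgt)
  has_m8 <- starts > 1L & substring(tgt, starts - 1L, starts - 1L) == m8_base
  has_a1 <- starts + 6L <= len & substring(tgt, starts + 6L, starts + 6L) == "A"
  native <- ifelse(has_m8 & has_a1, "8mer",
            ifelse(has_m8, "7mer_m8", ifelse(has_a1, "7mer_A1", "6mer")))
  # strongest accepted class each native class qualifies for (NA = dropped)
  assigned_of <- vapply(SEED_CLASS_ORDER, function(nat) {
    eligible <- intersect(seed_class_qualifies[[nat]], seed_def$classes)
    if (length(eligible) == 0L) NA_character_
    else eligible[which.max(match(eligible, SEED_CLASS_ORDER))]
  }, character(1))
  cls <- unname(assigned_of[native])
  keep <- !is.na(cls)
  if (!any(keep)) return(empty_site_table("targetscan_seed"))
  with_m8 <- cls[keep] %in% c("7mer_m8", "8mer")
  tibble(gene = targets$gene[gi][keep], mirna = mirna,
         start = as.integer(ifelse(with_m8, starts[keep] - 2L, starts[keep] - 1L)),
         end   = as.integer(starts[keep] + 5L),
         score = 1, channel = "targetscan_seed", site_class = cls[keep])
}

#' Nearest-neighbor RNA/RNA duplex energy model
#'
#' A simplified hybridization-energy model: Watson-Crick stack free energies
#' from the standard nearest-neighbor RNA parameter set (kcal/mol, 37 C)
#' plus approximate G:U wobble stack terms, and a duplex initiation penalty.
#' The stack table's symmetric closure is constructed here so the energy is
#' invariant under reversing the duplex.
#'
#' @param initiation Duplex initiation penalty, kcal/mol.
#' @return An `energy_model` list with the 6x6 stack matrix (rows/columns
#'   named by base pairs `AU`, `UA`, `CG`, `GC`, `GU`, `UG`) and the
#'   initiation penalty.
#' @export
nn_energy_model <- function(initiation = 4.09) {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  E <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  canonical <- list(
    # Watson-Crick stacks
    c("AU", "AU", -0.93), c("AU", "UA", -1.10), c("UA", "AU", -1.33),
    c("CG", "UA", -2.08), c("CG", "AU", -2.11), c("GC", "UA", -2.24),
    c("GC", "AU", -2.35), c("CG", "GC", -2.36), c("GC", "GC", -3.26),
    c("GC", "CG", -3.42),
    # G:U wobble stacks (approximate)
    c("AU", "GU", -0.55), c("AU", "UG", -1.36), c("CG", "GU", -1.41),
    c("CG", "UG", -2.11), c("GC", "GU", -1.53), c("GC", "UG", -2.51),
    c("UA", "GU", -1.27), c("UA", "UG", -1.00),
    c("GU", "GU",  0.47), c("GU", "UG",  0.30), c("UG", "GU", -0.50)
  )
  rev_pair <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (entry in canonical) {
    p1 <- entry[1]; p2 <- entry[2]; g <- as.numeric(entry[3])
    E[p1, p2] <- g
    E[rev_pair(p2), rev_pair(p1)] <- g   # duplex-reversal symmetry
  }
  stopifnot(!anyNA(E))
  structure(list(stack = E, initiation = initiation), class = "energy_model")
}

# base-pair name (miRNA base : target base), RNA alphabet, or NA if unpaired
pair_name <- function(mir_base, tgt_base) {
  m <- chartr("T", "U", mir_base)
  t <- chartr("T", "U", tgt_base)
  p <- paste0(m, t)
  ifelse(p %in% c("AU", "UA", "CG", "GC", "GU", "UG"), p, NA_character_)
}

#' Hybridization energy of an ungapped miRNA:target duplex
#'
#' The miRNA (5' to 3') is aligned antiparallel against the target window,
#' its 5' end opposite the window's 3' end.  Consecutive paired positions
#' (Watson-Crick or G:U) form helices; the energy is the initiation penalty
#' plus the nearest-neighbor stack sum of the most stable helix.  More
#' negative is stronger.  Returns `NA` when no helix of at least two pairs
#' forms (no site).
#'
#' @param target_window Target subsequence opposite the miRNA.
#' @param mirna_sequence Mature miRNA sequence, 5' to 3'.
#' @param model An [nn_energy_model()].
#' @return Energy in kcal/mol, or `NA_real_`.
#' @export
duplex_energy <- function(target_window, mirna_sequence, model = nn_energy_model()) {
  stopifnot(inherits(model, "energy_model"))
  tgt <- canonicalize_sequence(target_window)
  mir <- canonicalize_sequence(mirna_sequence)
  lw <- nchar(tgt)
  if (lw < 6L) abort("target window shorter than 6 nt")
  lm <- nchar(mir)
  npair <- min(lm, lw)
  mir_b <- strsplit(mir, "")[[1]]
  tgt_b <- strsplit(tgt, "")[[1]]
  # miRNA position i pairs window position lw - i + 1
  pairs <- pair_name(mir_b[seq_len(npair)], tgt_b[lw - seq_len(npair) + 1L])
  paired <- !is.na(pairs)
  if (!any(paired)) return(NA_real_)
  runs <- rle(paired)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- NA_real_
  for (r in which(runs$values & runs$lengths >= 2L)) {
    idx <- seq(starts[r], ends[r] - 1L)
    g <- sum(model$stack[cbind(pairs[idx], pairs[idx + 1L])])
    if (is.na(best) || g < best) best <- g
  }
  if (is.na(best)) return(NA_real_)
  model$initiation + best
}

#' Compute or import the per-site score table for one channel
#'
#' The seed channel (`targetscan_seed`) and the binding-energy channel
#' (`miranda_energy`) are computed from sequences by the built-in scanners.
#' The accessibility-corrected energy channel (`pita_ddg`) and the
#' `mirsvr` channel depend on external models (secondary-structure
#' ensembles, a trained regression) and are import-only: supply their
#' pre-computed tables via `imported` (see [read_site_scores()]).
#' An imported table also overrides the built-in scorer for the computable
#' channels.
#'
#' Energy sites are anchored on 6mer seed-core matches; around each anchor
#' the full-length ungapped duplex energy is computed and sites with
#' negative energy are emitted.
#'
#' @param targets Target tibble (`gene`, `sequence`) from
#'   [read_target_fasta()].
#' @param mirnas miRNA tibble (`mirna`, `sequence`) from
#'   [read_mirna_fasta()].
#' @param channel Channel name.
#' @param imported Optional pre-computed site tibble for the channel.
#' @param seed_def A [seed_definition()] (seed channel only).
#' @param model An [nn_energy_model()] (energy channel only).
#' @return A site tibble for the channel.
#' @export
compute_channel_sites <- function(targets, mirnas = NULL, channel,
                                  imported = NULL,
                                  seed_def = seed_definition(),
                                  model = nn_energy_model()) {
  channel <- match_channel(channel)
  if (!is.null(imported)) {
    if (!all(imported$channel == channel)) {
      abort(paste0("imported table is not channel '", channel, "'"))
    }
    return(imported)
  }
  if (channel %in% c("pita_ddg", "mirsvr")) {
    abort(paste0("channel '", channel, "' has no built-in scanner; ",
                 "import a pre-computed site table with read_site_scores()"))
  }
  if (is.null(mirnas)) abort("miRNA sequences are required for built-in scanners")
  targets <- mutate(targets, sequence = canonicalize_sequence(.data$sequence, .data$gene))
  if (channel == "targetscan_seed") {
    out <- purrr::map(seq_len(nrow(mirnas)), function(m) {
      seed_hits_for_mirna(targets, mirnas$sequence[m], mirnas$mirna[m], seed_def)
    })
    out <- bind_rows(out)
    return(if (nrow(out) == 0L) empty_site_table(channel) else out)
  }
  # miranda_energy: 6mer-anchored duplex energies over all seed cores
  anchor_def <- seed_definition(c("6mer", "7mer_A1", "7mer_m8", "8mer"))
  seq_of <- setNames(targets$sequence, targets$gene)
  out <- purrr::map(seq_len(nrow(mirnas)), function(m) {
    mir <- canonicalize_sequence(mirnas$sequence[m], mirnas$mirna[m])
    lm <- nchar(mir)
    cores <- seed_hits_for_mirna(targets, mir, mirnas$mirna[m], anchor_def)
    if (nrow(cores) == 0L) return(NULL)
    tgt <- seq_of[cores$gene]
    len <- nchar(tgt)
    s <- cores$end - 5L          # 1-based core start on the target
    b <- s + 6L                  # window 3' end pairs miRNA position 1
    a <- pmax(1L, b - lm + 1L)
    win <- substring(tgt, a, pmin(len, b))
    pad <- pmax(0L, b - len)     # keep the seed anchored at a 3' edge
    win <- paste0(win, strrep("N", pad))
    e <- vapply(win, duplex_energy, numeric(1), mirna_sequence = mir,
                model = model, USE.NAMES = FALSE)
    keep <- !is.na(e) & e < 0
    if (!any(keep)) return(NULL)
    tibble(gene = cores$gene[keep], mirna = mirnas$mirna[m],
           start = a[keep] - 1L, end = pmin(len, b)[keep],
           score = e[keep], channel = "miranda_energy",
           site_class = "energy_site")
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) empty_site_table(channel) else distinct(out)
}

#' Read mature miRNA sequences from FASTA
#' @param path Path to a FASTA file of mature miRNA sequences (RNA or DNA
#'   alphabet; stored internally as DNA).
#' @return A tibble with columns `mirna`, `sequence`.
#' @export
read_mirna_fasta <- function(path) {
  tbl <- read_target_fasta(path, keep_longest_per_gene = FALSE, source = "custom")
  tibble(mirna = tbl$gene, sequence = tbl$sequence)
}
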