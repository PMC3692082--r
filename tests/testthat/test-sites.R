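test_that("seed scan finds the hand-enumerated site with its strongest class", {
  # miRNA 5'-UGGAAGGUUAAA: seed 2-7 = GGAAGG, reverse complement CCTTCC;
  # the target carries it at [3,9) 1-based, preceded by A (pairs position 8)
  # and followed by A (A1 anchor) -> 8mer
  hits <- scan_seed_sites("AAACCTTCCAAA", "UGGAAGGUUAAA")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)
  expect_equal(hits$end, 9L)
  expect_equal(hits$site_class, "8mer")
  expect_equal(hits$score, 1)

  # no complementary 6mer anywhere
  expect_equal(nrow(scan_seed_sites(strrep("A", 40), "UGGAAGGUUAAA")), 0L)

  # tandem duplication -> exactly two records
  two <- scan_seed_sites(strrep("ACCTTCCA", 2), "UGGAAGGUUAAA",
                         seed_def = seed_definition(c("6mer", "7mer_A1",
                                                      "7mer_m8", "8mer")))
  expect_equal(nrow(two), 2L)
})

test_that("seed scan agrees with a brute-force substring oracle", {
  set.seed(101)
  for (rep in 1:40) {
    target <- random_seq(sample(200:2000, 1))
    mir <- random_seq(22)
    for (classes in list(c("7mer_A1", "7mer_m8", "8mer"),
                         c("6mer", "7mer_A1", "7mer_m8", "8mer"),
                         c("7mer_m8"))) {
      got <- scan_seed_sites(target, mir, seed_def = seed_definition(classes))
      want <- brute_seed_scan(target, mir, classes)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want) > 0) {
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(got$site_class, want$site_class)
      }
    }
  }
})

test_that("stronger sites are retained under narrower class sets; counts are monotone", {
  set.seed(202)
  class_sets <- list(c("6mer", "7mer_A1", "7mer_m8", "8mer"),
                     c("7mer_A1", "7mer_m8", "8mer"),
                     c("7mer_m8", "8mer"),
                     "8mer")
  for (rep in 1:20) {
    target <- random_seq(1500)
    mir <- random_seq(21)
    counts <- vapply(class_sets, function(cl) {
      nrow(scan_seed_sites(target, mir, seed_def = seed_definition(cl)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
  # an 8mer is reported as its 7mer class when 8mers are not accepted
  hits <- scan_seed_sites("AAACCTTCCAAA", "UGGAAGGUUAAA",
                          seed_def = seed_definition(c("7mer_m8", "7mer_A1")))
  expect_equal(hits$site_class, "7mer_m8")
})

test_that("ambiguous bases in the window prevent a match", {
  expect_equal(nrow(scan_seed_sites("AAACCTNCCAAA", "UGGAAGGUUAAA",
                                    seed_def = seed_definition(c("6mer", "7mer_A1",
                                                                 "7mer_m8", "8mer")))),
               0L)
  expect_error(scan_seed_sites("ACGTACGTACGT", "ACGTACG"), "shorter than 8")
})

test_that("duplex energy matches the hand-summed stack table", {
  model <- nn_energy_model()
  # 7 G:C pairs -> initiation + 6 GC/GC stacks
  expect_equal(duplex_energy("CCCCCCC", "GGGGGGG", model),
               model$initiation + 6 * model$stack["GC", "GC"])
  # 6 A:U pairs -> initiation + 5 AU/AU stacks
  expect_equal(duplex_energy("TTTTTT", "AAAAAA", model),
               model$initiation + 5 * model$stack["AU", "AU"])
  # fully mismatched duplex -> no helix
  expect_true(is.na(duplex_energy("AAAAAA", "AAAAAA", model)))
  expect_error(duplex_energy("ACGTA", "ACGTACGT", model), "shorter than 6")
})

test_that("duplex energy is symmetric and monotone in helix extension", {
  model <- nn_energy_model()
  # reversal symmetry: swapping the strands gives the same duplex
  set.seed(303)
  for (rep in 1:20) {
    mir <- random_seq(12)
    tgt <- mirset:::revcomp_dna(mir)
    expect_equal(duplex_energy(tgt, mir, model), duplex_energy(mir, tgt, model))
  }
  # each added complementary pair with a negative stack lowers the energy
  e_prev <- duplex_energy("CCCCCC", "GGGGGG", model)
  for (k in 7:12) {
    e_k <- duplex_energy(strrep("C", k), strrep("G", k), model)
    expect_lt(e_k, e_prev)
    e_prev <- e_k
  }
  # the stack table itself is reversal-symmetric
  pairs <- rownames(model$stack)
  flip <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (p1 in pairs) for (p2 in pairs) {
    expect_equal(model$stack[p1, p2], model$stack[flip(p2), flip(p1)])
  }
})

test_that("channel computation composes scanners and validates imports", {
  fx <- small_fixture()
  targets <- fx$targets[1:10, ]
  mirnas <- fx$mirnas[1:4, ]

  seed_sites <- compute_channel_sites(targets, mirnas, "targetscan_seed")
  manual <- dplyr::bind_rows(lapply(seq_len(nrow(targets)), function(g) {
    dplyr::bind_rows(lapply(seq_len(nrow(mirnas)), function(m) {
      scan_seed_sites(targets$sequence[g], mirnas$sequence[m],
                      gene = targets$gene[g], mirna = mirnas$mirna[m])
    }))
  }))
  expect_equal(dplyr::arrange(seed_sites, gene, mirna, start),
               dplyr::arrange(manual, gene, mirna, start))

  # energy channel: all scores negative, intervals inside the sequences
  esites <- compute_channel_sites(targets, mirnas, "miranda_energy")
  expect_true(all(esites$score < 0))
  lens <- setNames(nchar(targets$sequence), targets$gene)
  expect_true(all(esites$end <= lens[esites$gene]))
  expect_true(all(esites$start >= 0))

  # import-only channels refuse to run without a table, pass one through
  expect_error(compute_channel_sites(targets, mirnas, "pita_ddg"),
               "read_site_scores")
  imported <- fx$imported$mirsvr
  expect_identical(compute_channel_sites(targets, mirnas, "mirsvr",
                                         imported = imported), imported)
  expect_error(compute_channel_sites(targets, mirnas, "pita_ddg",
                                     imported = imported), "not channel")
})
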