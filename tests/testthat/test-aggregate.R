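test_that("Fermi-Dirac occupancy obeys its closed forms and limits", {
  p <- fd_params(kT = 1, mu0 = 0)
  # at the chemical potential the site is half occupied
  expect_identical(fermi_dirac_probability(0, 1, p), 0.5)
  # 1 / (1 + 3)
  expect_equal(fermi_dirac_probability(log(3), 1, p), 0.25, tolerance = 1e-14)
  # saturation at very strong binding
  expect_equal(fermi_dirac_probability(-50, 1, fd_params(kT = 0.593)), 1,
               tolerance = 1e-12)
  expect_equal(fermi_dirac_probability(50, 1, fd_params(kT = 0.593)), 0,
               tolerance = 1e-12)
  # strictly decreasing in E, strictly increasing in c
  E <- seq(-5, 5, length.out = 50)
  expect_true(all(diff(fermi_dirac_probability(E, 0.3, p)) < 0))
  cc <- seq(0.01, 1, length.out = 50)
  expect_true(all(diff(fermi_dirac_probability(-1, cc, p)) > 0))
  expect_error(fd_params(kT = 0), "> 0")
  expect_error(fd_params(epsilon = 2), "epsilon")
})

test_that("Fermi-Dirac combiner sums site occupancies per gene", {
  p <- fd_params(kT = 1, mu0 = 0)
  conc <- tibble::tibble(mirna = "m1", concentration = 1)
  # three sites at E = mu -> occupancy 0.5 each
  sites <- tibble::tibble(gene = "g", mirna = "m1", start = 0L, end = 7L,
                          score = c(0, 0, 0), channel = "miranda_energy",
                          site_class = "energy_site")
  expect_equal(combine_fermi_dirac(sites, conc, p)$score, 1.5)
  # a gene without sites scores zero when the universe includes it
  out <- combine_fermi_dirac(sites, conc, p, genes = c("g", "empty"))
  expect_equal(out$score[out$gene == "empty"], 0)
  # sites of miRNAs absent from the vector are ignored and tallied
  sites2 <- dplyr::mutate(sites, mirna = c("m1", "mX", "mX"))
  out2 <- combine_fermi_dirac(sites2, conc, p)
  expect_equal(out2$score, 0.5)
  expect_equal(attr(out2, "ignored_sites"), 2L)
})

test_that("both combiners match naive double-loop oracles on random fixtures", {
  set.seed(404)
  for (rep in 1:30) {
    n_genes <- sample(3:50, 1); n_mir <- sample(2:10, 1)
    genes <- sprintf("g%d", seq_len(n_genes))
    mirs <- sprintf("m%d", seq_len(n_mir))
    conc <- tibble::tibble(mirna = mirs,
                           concentration = as.numeric(rmultinom(1, 1000, runif(n_mir)) / 1000))
    sites <- tibble::tibble(
      gene = sample(genes, 80, replace = TRUE),
      mirna = sample(mirs, 80, replace = TRUE),
      start = 0L, end = 7L,
      score = -runif(80, 0, 25),
      channel = "miranda_energy", site_class = "energy_site")
    pars <- fd_params(kT = runif(1, 0.3, 2), mu0 = runif(1, -3, 3))
    got <- combine_fermi_dirac(sites, conc, pars)
    want <- naive_fd(sites, conc, kT = pars$kT, mu0 = pars$mu0)
    expect_equal(setNames(got$score, got$gene), want[got$gene], tolerance = 1e-12)

    values <- tibble::tibble(gene = sample(genes, 40, replace = TRUE),
                             mirna = sample(mirs, 40, replace = TRUE),
                             value = rnorm(40)) |>
      dplyr::distinct(gene, mirna, .keep_all = TRUE)
    got_w <- combine_weighted_sum(values, conc)
    want_w <- naive_wsum(values, conc)
    expect_equal(setNames(got_w$score, got_w$gene), want_w[got_w$gene],
                 tolerance = 1e-12)
  }
})

test_that("weighted sums follow the stated arithmetic and are linear", {
  conc <- tibble::tibble(mirna = c("a", "b"), concentration = c(0.25, 0.75))
  counts <- tibble::tibble(gene = "g", mirna = c("a", "b"), value = c(4, 0))
  expect_equal(combine_weighted_sum(counts, conc)$score, 1)

  conc2 <- tibble::tibble(mirna = c("a", "b"), concentration = c(0.5, 0.5))
  svr <- tibble::tibble(gene = "g", mirna = c("a", "b"), value = c(-1.2, -0.4))
  expect_equal(combine_weighted_sum(svr, conc2)$score, -0.8)

  # scaling all values by alpha scales the score by alpha
  svr3 <- dplyr::mutate(svr, value = value * 3.7)
  expect_equal(combine_weighted_sum(svr3, conc2)$score, -0.8 * 3.7)
})

test_that("Fermi-Dirac gene scores are bounded, monotone and additive", {
  set.seed(505)
  conc <- tibble::tibble(mirna = c("m1", "m2"), concentration = c(0.7, 0.3))
  sites <- tibble::tibble(gene = "g", mirna = sample(c("m1", "m2"), 9, TRUE),
                          start = 0L, end = 7L, score = -runif(9, 0, 20),
                          channel = "pita_ddg", site_class = "imported")
  pars <- fd_params()
  s <- combine_fermi_dirac(sites, conc, pars)$score
  expect_gt(s, 0); expect_lt(s, nrow(sites))
  # raising a concentration never lowers the score
  conc_up <- dplyr::mutate(conc, concentration = concentration * c(2, 1))
  expect_gte(combine_fermi_dirac(sites, conc_up, pars)$score, s)
  # lowering (strengthening) every energy raises the score
  sites_strong <- dplyr::mutate(sites, score = score - 1)
  expect_gt(combine_fermi_dirac(sites_strong, conc, pars)$score, s)
  # additivity over disjoint site sets
  s1 <- combine_fermi_dirac(sites[1:4, ], conc, pars)$score
  s2 <- combine_fermi_dirac(sites[5:9, ], conc, pars)$score
  expect_equal(s1 + s2, s, tolerance = 1e-12)
  # the c -> infinity / E -> -infinity limit recovers the site count
  sat <- combine_fermi_dirac(dplyr::mutate(sites, score = -1e4), conc, pars)$score
  expect_equal(sat, nrow(sites), tolerance = 1e-9)
})

test_that("the channel matrix has one block per label and is deterministic", {
  fx <- small_fixture()
  vectors <- dplyr::bind_rows(
    tibble::tibble(label = "u1", mirna = fx$mirnas$mirna[1:4],
                   concentration = c(0.4, 0.3, 0.2, 0.1)),
    tibble::tibble(label = "u2", mirna = fx$mirnas$mirna[1:4],
                   concentration = c(0.4, 0.3, 0.2, 0.1)))
  sites <- list(
    compute_channel_sites(fx$targets[1:20, ], fx$mirnas[1:4, ], "targetscan_seed"),
    fx$imported$pita_ddg, fx$imported$mirsvr)
  cm <- build_channel_matrix(sites, vectors, genes = fx$targets$gene[1:20])
  expect_setequal(attr(cm, "channels"),
                  c("targetscan_seed", "pita_ddg", "mirsvr"))
  expect_equal(nrow(cm), 20 * 3 * 2)
  # identical concentration vectors -> identical column blocks
  wide <- tidyr::pivot_wider(cm, names_from = label, values_from = score)
  expect_equal(wide$u1, wide$u2)
  # a gene with no sites on a channel scores exactly zero there
  no_sites <- setdiff(fx$targets$gene[1:20], sites[[2]]$gene)
  if (length(no_sites) > 0) {
    z <- cm[cm$gene == no_sites[1] & cm$channel == "pita_ddg", "score"]
    expect_true(all(z == 0))
  }
  expect_error(build_channel_matrix(mirset:::empty_site_table(), vectors),
               "no site-score channels")
})

test_that("changing one miRNA's concentration only moves genes it has sites on", {
  fx <- small_fixture()
  mirs <- fx$mirnas$mirna[1:4]
  base <- tibble::tibble(label = "s", mirna = mirs,
                         concentration = c(0.4, 0.3, 0.2, 0.1))
  doubled <- dplyr::mutate(base, concentration = ifelse(mirna == mirs[1],
                                                        concentration * 2,
                                                        concentration))
  sites <- compute_channel_sites(fx$targets[1:25, ], fx$mirnas[1:4, ],
                                 "targetscan_seed")
  cm1 <- build_channel_matrix(sites, base, genes = fx$targets$gene[1:25])
  cm2 <- build_channel_matrix(sites, doubled, genes = fx$targets$gene[1:25])
  changed <- cm1$gene[abs(cm1$score - cm2$score) > 1e-12]
  affected <- unique(sites$gene[sites$mirna == mirs[1]])
  expect_true(all(changed %in% affected))
})
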