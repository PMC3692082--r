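# Independent brute-force oracles and tiny fixture builders used across the
# suite.  These deliberately avoid the package's code paths: plain loops and
# hand-rolled string operations only.

rc <- function(x) {
  # manual reverse complement, DNA alphabet
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(x, "")[[1]]])), collapse = "")
}

# Brute-force seed scan: slide a window over the target and compare
# substrings against explicitly constructed site patterns.
brute_seed_scan <- function(target, mir, classes = c("7mer_A1", "7mer_m8", "8mer")) {
  target <- chartr("U", "T", toupper(target))
  mir <- chartr("U", "T", toupper(mir))
  core <- rc(substr(mir, 2, 7))
  m8 <- rc(substr(mir, 8, 8))
  len <- nchar(target)
  out <- list()
  for (s in seq_len(len - 5)) {
    if (substr(target, s, s + 5) != core) next
    has_m8 <- s > 1 && substr(target, s - 1, s - 1) == m8
    has_a1 <- s + 6 <= len && substr(target, s + 6, s + 6) == "A"
    native <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer_m8" else
              if (has_a1) "7mer_A1" else "6mer"
    qualifies <- switch(native,
      "8mer"    = c("8mer", "7mer_m8", "7mer_A1", "6mer"),
      "7mer_m8" = c("7mer_m8", "6mer"),
      "7mer_A1" = c("7mer_A1", "6mer"),
      "6mer"    = "6mer")
    hit <- qualifies[qualifies %in% classes]
    if (length(hit) == 0) next
    cls <- hit[1]   # qualifies is listed strongest-first
    out[[length(out) + 1]] <- data.frame(
      start = if (cls %in% c("7mer_m8", "8mer")) s - 2 else s - 1,
      end = s + 5, site_class = cls)
  }
  if (length(out) == 0) {
    data.frame(start = integer(0), end = integer(0), site_class = character(0))
  } else do.call(rbind, out)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Naive double-loop Fermi-Dirac combiner.
naive_fd <- function(sites, conc, kT = 0.593, mu0 = 0, eps = 1e-9) {
  genes <- unique(sites$gene)
  out <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    s <- 0
    for (i in which(sites$gene == g)) {
      row <- sites[i, ]
      j <- which(conc$mirna == row$mirna)
      if (length(j) == 0) next
      mu <- mu0 + kT * log(max(conc$concentration[j], eps))
      s <- s + 1 / (1 + exp((row$score - mu) / kT))
    }
    out[g] <- s
  }
  out
}

# Naive weighted sum over (gene, mirna) values.
naive_wsum <- function(values, conc) {
  genes <- unique(values$gene)
  out <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    s <- 0
    for (i in which(values$gene == g)) {
      j <- which(conc$mirna == values$mirna[i])
      if (length(j) > 0) s <- s + conc$concentration[j] * values$value[i]
    }
    out[g] <- s
  }
  out
}

# Exhaustive two-sided rank-sum p-value over all C(n+m, n) labelings.
enum_wilcox <- function(xa, xb) {
  n <- length(xa); m <- length(xb)
  r <- rank(c(xa, xb))
  w_obs <- sum(r[seq_len(n)])
  center <- n * (n + m + 1) / 2
  picks <- utils::combn(n + m, n)
  w_all <- apply(picks, 2, function(ix) sum(r[ix]))
  mean(abs(w_all - center) >= abs(w_obs - center) - 1e-9)
}

# Small expression table fixture.
tiny_expression <- function() {
  tibble::tibble(mirna = c("m1", "m2", "m3", "m4"),
                 s1 = c(50, 30, 15, 5),
                 s2 = c(10, 10, 10, 10))
}

# A small fixture shared by pipeline-level tests (cached per session).
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_fixture(fixture_spec(
        n_genes = 60, n_mirnas = 8, n_samples = 2, utr_length = c(120, 400),
        sites_per_target = 2, n_planted_mirnas = 3, seed = 11))
    }
    cache
  }
})
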