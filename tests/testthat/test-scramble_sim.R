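# A minimal designed genome with explicit loxPsym features for exact
# segment arithmetic: segments of 1 kb with sites at the boundaries.
toy_scramble_design <- function(n_sites = 4L, essential_segments = 3L,
                                centromere_segment = 1L) {
  seg <- 1000L
  len <- (n_sites + 1L) * seg
  set.seed(42)
  feats <- empty_features()
  for (i in seq_len(n_sites)) {
    feats <- rbind(feats, features(sprintf("lox%d", i), "loxpsym",
                                   i * seg, i * seg + 34L))
  }
  for (s in essential_segments) {
    orf_start <- (s - 1L) * seg + 100L
    feats <- rbind(feats, features(sprintf("ESS%d", s), "ORF",
                                   orf_start, orf_start + 300L, "+",
                                   essential = "yes", orf_class = "Verified"))
  }
  feats <- rbind(feats, features("CEN", "centromere",
                                 (centromere_segment - 1L) * seg + 500L,
                                 (centromere_segment - 1L) * seg + 620L))
  seqn <- rand_dna(len)
  # ORFs need clean translation for genome validation: overwrite in place
  for (s in essential_segments) {
    orf_start <- (s - 1L) * seg + 100L
    orf <- paste0("ATG", strrep("GCT", 98), "TAA")
    substr(seqn, orf_start + 1L, orf_start + 300L) <- orf
  }
  genome_record("toy_design", seqn, feats)
}

test_that("mask letters control segmentation and recombinability", {
  dg <- toy_scramble_design(n_sites = 12L)
  sg_w <- build_scramble_genome(dg, "W")
  expect_equal(nrow(chromoforge:::molecule_junctions(sg_w)), 0L)

  sg_ss <- build_scramble_genome(dg, "SS")
  expect_equal(length(sg_ss$molecules), 2L)
  expect_true(all(lengths(sg_ss$molecules) == 13L))  # 12 sites -> 13 segments
  expect_equal(nrow(chromoforge:::molecule_junctions(sg_ss)), 24L)

  expect_error(build_scramble_genome(dg, "SW", ploidy = 3L), "match")
})

test_that("segment essential flags equal a direct ORF scan", {
  fx <- make_toy_chromosome(toy_chromosome_spec(seed = 3L))
  res <- apply_design(fx$genome)
  sg <- build_scramble_genome(res$genome, "S")
  f <- res$genome$features
  cuts <- sort(f$start[f$kind == "loxpsym"])
  bounds <- c(0L, cuts, res$genome$length)
  ess <- f[f$kind == "ORF" & f$essential %in% "yes", ]
  oracle <- which(vapply(seq_len(length(bounds) - 1L), function(i) {
    any(ess$start < bounds[i + 1L] & bounds[i] < ess$end)
  }, logical(1)))
  expect_equal(sg$essential_ids, as.integer(oracle))
})

test_that("intramolecular events delete or invert the intervening block", {
  dg <- toy_scramble_design(n_sites = 4L)
  sg <- build_scramble_genome(dg, "S")
  # sites flanking segments 2..3 are junctions 1 and 3
  del <- apply_event(sg, c(1L, 1L), c(1L, 3L), branch = "delete")
  expect_equal(del$molecules[[1]], c(1L, 4L, 5L))
  inv <- apply_event(sg, c(1L, 1L), c(1L, 3L), branch = "invert")
  expect_equal(inv$molecules[[1]], c(1L, -3L, -2L, 4L, 5L))
  # double inversion is the identity
  inv2 <- apply_event(inv, c(1L, 1L), c(1L, 3L), branch = "invert")
  expect_equal(inv2$molecules, sg$molecules)
})

test_that("intermolecular exchange swaps tails and conserves the multiset", {
  dg <- toy_scramble_design(n_sites = 4L)
  sg <- build_scramble_genome(dg, "SS")
  # allelic sites: same junction index on both molecules
  al <- apply_event(sg, c(1L, 2L), c(2L, 2L))
  expect_equal(al$molecules, sg$molecules)
  # non-allelic: one molecule gains (k, j], the other loses
  na <- apply_event(sg, c(1L, 1L), c(2L, 3L))
  expect_equal(na$molecules[[1]], c(1L, 4L, 5L))
  expect_equal(na$molecules[[2]], c(1L, 2L, 3L, 2L, 3L, 4L, 5L))
  multiset <- function(g) sort(abs(unlist(g$molecules)))
  expect_equal(multiset(na), multiset(sg))
  # wild-type molecules cannot recombine
  sw <- build_scramble_genome(dg, "SW")
  expect_error(apply_event(sw, c(1L, 1L), c(2L, 1L)), "wild-type")
})

test_that("event invariants hold: inversion conserves, deletion shrinks", {
  dg <- toy_scramble_design(n_sites = 6L)
  sg <- build_scramble_genome(dg, "SS")
  set.seed(31)
  multiset <- function(g) sort(abs(unlist(g$molecules)))
  for (i in 1:50) {
    jx <- chromoforge:::molecule_junctions(sg)
    p <- sample.int(nrow(jx), 2L)
    s1 <- c(jx$mol[p[1]], jx$junction[p[1]])
    s2 <- c(jx$mol[p[2]], jx$junction[p[2]])
    if (s1[1] == s2[1]) {
      inv <- apply_event(sg, s1, s2, branch = "invert")
      expect_equal(multiset(inv), multiset(sg))
      del <- apply_event(sg, s1, s2, branch = "delete")
      if (s1[2] != s2[2]) expect_lt(length(unlist(del$molecules)),
                                    length(unlist(sg$molecules)))
    } else {
      ex <- apply_event(sg, s1, s2)
      expect_equal(multiset(ex), multiset(sg))
    }
  }
})

test_that("no events means full viability", {
  dg <- toy_scramble_design()
  sg <- build_scramble_genome(dg, "S")
  pop <- simulate_population(sg, lambda = 0, n_cells = 200L, seed = 1L)
  expect_equal(pop$viability, 1.0)
})

test_that("one event on a two-site essential segment kills half the cells", {
  # segment 2 (between the only two sites) is the only essential one:
  # deletion (p = 1/2) removes it, inversion (p = 1/2) is harmless
  dg <- toy_scramble_design(n_sites = 2L, essential_segments = 2L)
  sg <- build_scramble_genome(dg, "S")
  expect_equal(sg$essential_ids, 2L)
  expect_equal(enumerate_viability(sg, 1L), 0.5)
  pop <- simulate_population(sg, n_cells = 4000L, fixed_events = 1L, seed = 7L)
  se <- sqrt(0.25 / 4000)
  expect_lt(abs(pop$viability - 0.5), 3 * se)
})

test_that("simulation matches exhaustive enumeration for small genomes", {
  dg <- toy_scramble_design(n_sites = 4L, essential_segments = c(2L, 4L))
  for (mask in c("S", "SS")) {
    sg <- build_scramble_genome(dg, mask)
    for (k in 1:2) {
      exact <- enumerate_viability(sg, k)
      sim <- simulate_population(sg, n_cells = 4000L, fixed_events = k,
                                 seed = 11L)$viability
      se <- sqrt(max(exact * (1 - exact), 1e-4) / 4000)
      expect_lt(abs(sim - exact), 3.5 * se)
    }
  }
})

test_that("viability decreases with lambda and rises with wild-type copies", {
  fx <- make_toy_chromosome(toy_chromosome_spec(seed = 3L))
  res <- apply_design(fx$genome)
  v_lam <- vapply(c(0.5, 2, 6), function(lam) {
    sg <- build_scramble_genome(res$genome, "S")
    simulate_population(sg, lambda = lam, n_cells = 1500L, seed = 5L)$viability
  }, numeric(1))
  expect_true(all(diff(v_lam) <= 0))

  v_mask <- vapply(c("S", "WS", "WSSS"), function(m) {
    sg <- build_scramble_genome(res$genome, m)
    simulate_population(sg, lambda = 2, n_cells = 1500L, seed = 6L)$viability
  }, numeric(1))
  expect_gte(v_mask[["WS"]], v_mask[["S"]])
  expect_gte(v_mask[["WSSS"]], v_mask[["S"]])
})

test_that("strict centromere rule fails molecules with zero or two centromeres", {
  dg <- toy_scramble_design(n_sites = 4L, essential_segments = 3L,
                            centromere_segment = 2L)
  sg <- build_scramble_genome(dg, "SS")
  expect_true(chromoforge:::cell_viable(sg, "strict"))
  # a non-allelic exchange that duplicates segment 2 onto one molecule
  ex <- apply_event(sg, c(1L, 1L), c(2L, 3L))
  expect_false(chromoforge:::cell_viable(ex, "strict"))
  expect_true(chromoforge:::cell_viable(ex, "off"))
})

test_that("ploidy classification follows the reference G1/G2 rule", {
  ref_h <- simulate_pi_histogram(1, seed = 1L)
  ref_d <- simulate_pi_histogram(2, seed = 2L)
  # sample G1 at the diploid G2 position -> tetraploid
  h4 <- simulate_pi_histogram(4, seed = 3L)
  expect_equal(classify_ploidy(h4, ref_h, ref_d), 4L)
  # sample G1 at the haploid G1 -> haploid
  h1 <- simulate_pi_histogram(1, seed = 4L)
  expect_equal(classify_ploidy(h1, ref_h, ref_d), 1L)
  # flat histogram -> indeterminate
  flat <- data.frame(bin_center = seq(5, 995, 10), count = 0L)
  expect_true(is.na(classify_ploidy(flat, ref_h, ref_d)))
})

test_that("ploidy recovery exceeds 95% per class over 50 seeds", {
  ref_h <- simulate_pi_histogram(1, seed = 901L)
  ref_d <- simulate_pi_histogram(2, seed = 902L)
  for (p in 1:4) {
    hits <- sum(vapply(1:50, function(s) {
      h <- simulate_pi_histogram(p, seed = 7000L + 50L * p + s)
      isTRUE(classify_ploidy(h, ref_h, ref_d) == p)
    }, logical(1)))
    expect_gte(hits, 48L)
  }
})
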