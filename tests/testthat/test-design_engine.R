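test_that("loxPsym insertion point is offset bases 3' of the stop codon", {
  g <- micro_genome()  # plus-strand ORF [100, 400)
  e <- insert_loxpsym_sites(g)
  expect_equal(nrow(e), 1L)
  expect_equal(e$op, "insert")
  expect_equal(e$start, 403L)

  gm <- micro_genome(strand = "-")
  em <- insert_loxpsym_sites(gm)
  expect_equal(em$start, 97L)
})

test_that("essential and dubious ORFs receive no loxPsym site", {
  expect_equal(nrow(insert_loxpsym_sites(micro_genome(essential = "yes"))), 0L)
  expect_equal(nrow(insert_loxpsym_sites(
    micro_genome(orf_class = "Dubious"))), 0L)
})

test_that("colliding insertion points are skipped and logged", {
  g <- micro_genome()
  # another feature straddling position 403
  g$features <- rbind(g$features,
                      features("blocker", "motif", 401L, 440L))
  g <- genome_record(g$id, g$sequence, g$features)
  e <- insert_loxpsym_sites(g)
  expect_equal(nrow(e), 0L)
  expect_equal(attr(e, "skipped"), "ORF1")
})

test_that("eligible-ORF count on a fixture matches planted truth", {
  fx <- make_toy_chromosome(toy_chromosome_spec(seed = 3L))
  e <- insert_loxpsym_sites(fx$genome)
  expect_equal(nrow(e) + length(attr(e, "skipped")),
               sum(fx$truth$loxpsym_eligible))
})

test_that("intron removal honors the retention list and spares proteins", {
  fx <- make_toy_chromosome(toy_chromosome_spec(n_introns = 3L, seed = 12L))
  introns <- fx$genome$features[fx$genome$features$kind == "intron", ]
  retained <- introns$id[1]
  e <- remove_introns(fx$genome, retain_ids = retained)
  expect_equal(nrow(e), 2L)
  expect_false(retained %in% e$note)

  # proteins identical before and after excision from the sequence
  led <- design_ledger(fx$genome$id, "d", e, fx$genome$length)
  newseq <- apply_ledger(fx$genome$sequence, led)
  for (orf_id in setdiff(introns$parent, introns$parent[1])) {
    orf <- fx$genome$features[fx$genome$features$id == orf_id, ]
    iv <- c(lift_position(led, orf$start), lift_position(led, orf$end - 1L) + 1L)
    g2 <- genome_record("d", newseq,
                        features(orf_id, "ORF", iv[1], iv[2], orf$strand,
                                 essential = orf$essential,
                                 orf_class = orf$orf_class))
    expect_identical(translate_orf(g2, orf_id),
                     translate_orf(fx$genome, orf_id))
  }

  g0 <- micro_genome()
  expect_equal(nrow(remove_introns(g0)), 0L)
})

test_that("stop swaps hit TAG only, on either strand, sparing dubious ORFs", {
  e <- swap_stop_codons(micro_genome(stop_codon = "TAG"))
  expect_equal(nrow(e), 1L)
  expect_equal(e$payload, "TAA")
  expect_equal(c(e$start, e$end), c(397L, 400L))

  expect_equal(nrow(swap_stop_codons(micro_genome(stop_codon = "TGA"))), 0L)
  expect_equal(nrow(swap_stop_codons(micro_genome(stop_codon = "TAA"))), 0L)
  expect_equal(nrow(swap_stop_codons(
    micro_genome(stop_codon = "TAG", orf_class = "Dubious"))), 0L)

  em <- swap_stop_codons(micro_genome(stop_codon = "TAG", strand = "-"))
  expect_equal(em$payload, "TTA")  # reverse complement of TAA
  expect_equal(c(em$start, em$end), c(100L, 103L))
})

test_that("feature removal deletes the named kinds with exact arithmetic", {
  fx <- make_toy_chromosome(toy_chromosome_spec(n_trnas = 4L,
                                                n_transposons = 2L, seed = 6L))
  e <- remove_features(fx$genome)
  expect_equal(nrow(e), 6L)
  f <- fx$genome$features
  expect_equal(sum(nchar(e$payload) - (e$end - e$start)),
               -sum(f$end[f$kind %in% c("tRNA", "transposon")] -
                      f$start[f$kind %in% c("tRNA", "transposon")]))
  e2 <- remove_features(fx$genome, kinds = "tRNA")
  expect_equal(nrow(e2), 4L)
})

test_that("telomere caps face outward at both chromosome ends", {
  fx <- make_toy_chromosome(toy_chromosome_spec(seed = 9L))
  cap <- "TGTGGGTGTGGTGTGTGGGTGTGGTG"
  e <- cap_telomeres(fx$genome, cap)
  expect_equal(nrow(e), 2L)
  led <- design_ledger(fx$genome$id, "d", e, fx$genome$length)
  designed <- apply_ledger(fx$genome$sequence, led)
  expect_identical(substr(designed, 1, nchar(cap)), rc(cap))
  expect_identical(substr(designed, nchar(designed) - nchar(cap) + 1,
                          nchar(designed)), cap)
  expect_warning(cap_telomeres(micro_genome(), cap), "no telomere")
})

test_that("PCR-tag recoding is synonymous, divergent and in Tm range", {
  fx <- make_toy_chromosome(toy_chromosome_spec(seed = 14L))
  out <- recode_pcrtags(fx$genome)
  expect_gt(nrow(out$pairs), 0L)
  for (i in seq_len(nrow(out$pairs))) {
    p <- out$pairs[i, ]
    aa_wt <- as.character(Biostrings::translate(Biostrings::DNAString(p$wt_seq),
                                                 no.init.codon = TRUE))
    aa_syn <- as.character(Biostrings::translate(Biostrings::DNAString(p$syn_seq),
                                                 no.init.codon = TRUE))
    expect_identical(aa_wt, aa_syn)
    expect_equal(sum(utf8ToInt(p$wt_seq) != utf8ToInt(p$syn_seq)),
                 p$mismatches)
  }
  clean <- out$pairs[!out$pairs$warn, ]
  expect_true(all(clean$mismatches >= 8L))
  expect_true(all(clean$tm_syn >= 58 & clean$tm_syn <= 62))
})

test_that("nearest-neighbor Tm behaves sensibly", {
  # GC-rich melts higher than AT-rich at the same length
  expect_gt(tm_nn(strrep("GC", 12)), tm_nn(strrep("AT", 12)))
  # longer oligos melt higher
  expect_gt(tm_nn(strrep("GATC", 8)), tm_nn(strrep("GATC", 4)))
})

test_that("empty policy leaves the genome untouched", {
  fx <- make_toy_chromosome(toy_chromosome_spec(seed = 21L))
  introns <- fx$genome$features$id[fx$genome$features$kind == "intron"]
  pol <- design_policy(loxpsym_targets = character(0),
                       intron_retain_ids = introns,
                       stop_swap = character(0),
                       remove_kinds = character(0),
                       telomere_cap = NULL, pcrtag = NULL)
  res <- apply_design(fx$genome, pol)
  expect_identical(res$genome$sequence, fx$genome$sequence)
  expect_equal(nrow(res$ledger$edits), 0L)
})

test_that("apply_design summary counts match the planted truth table", {
  fx <- make_toy_chromosome(toy_chromosome_spec(
    n_orfs = 15L, n_introns = 3L, n_trnas = 4L, n_transposons = 2L,
    seed = 30L))
  introns <- fx$genome$features[fx$genome$features$kind == "intron", ]
  pol <- design_policy(intron_retain_ids = introns$id[1])
  res <- apply_design(fx$genome, pol)
  s <- res$summary
  expect_equal(s$loxpsym_inserted + s$loxpsym_skipped,
               sum(fx$truth$loxpsym_eligible))
  expect_equal(s$introns_removed, 2L)
  expect_equal(s$introns_retained, 1L)
  expect_equal(s$features_removed, 6L)
  # stop swaps: count TAG stops of verified/uncharacterized ORFs directly
  f <- fx$genome$features
  orfs <- f[f$kind == "ORF" & f$orf_class %in% c("Verified", "Uncharacterized"), ]
  n_tag <- sum(vapply(seq_len(nrow(orfs)), function(i) {
    cds <- orf_coding_seq(fx$genome, orfs$id[i])
    substr(cds, nchar(cds) - 2, nchar(cds)) == "TAG"
  }, logical(1)))
  expect_equal(s$stop_swaps, n_tag)
  expect_equal(s$target_len, nchar(res$genome$sequence))
  expect_equal(s$net_delta, s$target_len - s$source_len)
})

test_that("printed synXIV lengths give a 4% size reduction", {
  expect_equal(design_size_reduction(784333, 753097), 4)
})

test_that("verify_design passes on real output and catches corruption", {
  fx <- make_toy_chromosome(toy_chromosome_spec(seed = 33L))
  res <- apply_design(fx$genome)
  rep <- verify_design(fx$genome, res$genome, res$ledger)
  expect_true(rep$pass)

  broken <- res$genome
  orf <- broken$features[broken$features$kind == "ORF", ][1, ]
  flip_at <- orf$start + 10L
  old <- substr(broken$sequence, flip_at, flip_at)
  substr(broken$sequence, flip_at, flip_at) <- if (old == "A") "C" else "A"
  rep2 <- verify_design(fx$genome, broken, res$ledger)
  expect_false(rep2$pass)
})

test_that("adding one eligible ORF adds exactly one loxPsym site", {
  fx <- make_toy_chromosome(toy_chromosome_spec(seed = 40L))
  n0 <- nrow(insert_loxpsym_sites(fx$genome))
  # plant an extra eligible ORF in a large intergenic gap
  f <- fx$genome$features
  outer <- f[order(f$start), ]
  gaps <- data.frame(s = outer$end[-nrow(outer)], e = outer$start[-1])
  gap <- gaps[which.max(gaps$e - gaps$s), ]
  stopifnot(gap$e - gap$s > 400)
  new_orf_start <- gap$s + 50L
  orf_seq <- paste0("ATG", strrep("GCT", 97), "TAA")
  g2 <- fx$genome
  substr(g2$sequence, new_orf_start + 1L, new_orf_start + 300L) <- orf_seq
  g2 <- genome_record(g2$id, g2$sequence, rbind(
    g2$features, features("ORF_EXTRA", "ORF", new_orf_start,
                          new_orf_start + 300L, "+", essential = "no",
                          orf_class = "Verified")))
  expect_equal(nrow(insert_loxpsym_sites(g2)), n0 + 1L)
})

test_that("design policies round-trip through YAML", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "policy.yaml")
  writeLines(c("loxpsym_offset: 5",
               "remove_kinds: [tRNA]",
               "pcrtag:",
               "  tag_len: 21",
               "  min_mismatches: 6"), path)
  pol <- read_design_policy(path)
  expect_equal(pol$loxpsym_offset, 5L)
  expect_equal(pol$remove_kinds, "tRNA")
  expect_equal(pol$pcrtag$tag_len, 21L)
  expect_equal(pol$pcrtag$min_mismatches, 6L)
  expect_equal(pol$loxpsym_seq, design_policy()$loxpsym_seq)
})
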