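test_that("identical pools produce no candidates", {
  win <- data.frame(contig = "c", start = seq(0, 49000, 1000),
                    end = seq(1000, 50000, 1000), depth = 100,
                    partition = "SYN_allele")
  out <- localize_defect(win, win)
  expect_equal(nrow(out), 0L)
})

test_that("full selection with no linkage decay pinpoints the causal window", {
  fx <- make_toy_chromosome(toy_chromosome_spec(seed = 5L))
  sp <- pool_sim_spec(causal_start = 30000L, causal_end = 33000L,
                      selection_strength = 1, linkage_decay = 0, seed = 2L)
  tr <- simulate_pool_coverage(fx$genome, sp)
  out <- localize_defect(tr$fast, tr$slow)
  syn <- out[out$partition == "SYN_allele", ]
  expect_equal(nrow(syn), 1L)
  expect_equal(c(syn$start, syn$end), c(30000L, 33000L))
  expect_true(syn$reciprocal_support)
})

test_that("candidates carry megachunk labels when a plan is supplied", {
  fx <- make_toy_chromosome(toy_chromosome_spec(seed = 5L))
  sp <- pool_sim_spec(causal_start = 30000L, causal_end = 33000L,
                      selection_strength = 1, linkage_decay = 0, seed = 2L)
  tr <- simulate_pool_coverage(fx$genome, sp)
  pj <- plant_junction_sites(fx$genome, seed = 3L)
  plan <- suppressWarnings(group_megachunks(partition_chunks(pj$genome)))
  out <- localize_defect(tr$fast, tr$slow, chunk_plan = plan)
  expect_false(is.na(out$megachunks[1]))
})

test_that("zero-median tracks are rejected", {
  win <- data.frame(contig = "c", start = 0:9 * 1000, end = 1:10 * 1000,
                    depth = 0, partition = "SYN_allele")
  expect_error(localize_defect(win, win), "median")
})

test_that("copy number is a depth ratio anchored to the baseline copies", {
  win <- data.frame(start = seq(0, 29000, 1000), end = seq(1000, 30000, 1000))
  win$depth <- rep(50, 30)
  win$depth[11:15] <- 200
  cn <- estimate_copy_number(win, 10000, 15000,
                             rbind(c(0, 10000), c(15000, 30000)))
  expect_equal(cn$copies, 4.0)
  cn1 <- estimate_copy_number(win, 20000, 25000,
                              rbind(c(20000, 25000)))
  expect_equal(cn1$copies, 1.0)
  expect_error(estimate_copy_number(win, 40000, 45000, rbind(c(0, 10000))),
               "empty")
})

designed_for_discrepancies <- function(seed = 17L) {
  fx <- make_toy_chromosome(toy_chromosome_spec(seed = seed))
  apply_design(fx$genome)
}

test_that("discrepancy classes map to the documented severities", {
  res <- designed_for_discrepancies()
  dg <- res$genome
  f <- dg$features

  # a TAA design stop observed as TAG in a verified ORF: critical
  orfs <- f[f$kind == "ORF" & f$orf_class == "Verified" & f$strand == "+", ]
  tag_stop <- NULL
  for (i in seq_len(nrow(orfs))) {
    stop_seq <- substr(dg$sequence, orfs$end[i] - 2, orfs$end[i])
    if (stop_seq == "TAA") { tag_stop <- orfs[i, ]; break }
  }
  stopifnot(!is.null(tag_stop))
  v1 <- data.frame(chrom = dg$id, pos = tag_stop$end - 1L, ref = "A",
                   alt = "G", end = NA_integer_)
  d1 <- classify_discrepancies(dg, v1)
  expect_equal(d1$class, "residual_TAG_stop")
  expect_equal(d1$severity, "critical")

  # a deletion spanning a loxPsym feature: noncritical
  lox <- f[f$kind == "loxpsym", ][1, ]
  v2 <- data.frame(chrom = dg$id, pos = lox$start, ref = "N",
                   alt = "<DEL>", end = lox$end)
  d2 <- classify_discrepancies(dg, v2)
  expect_equal(d2$class, "missing_loxpsym")
  expect_equal(d2$severity, "noncritical")

  # a symbolic duplication: critical
  v3 <- data.frame(chrom = dg$id, pos = 1000L, ref = "N",
                   alt = "<DUP>", end = 11000L)
  d3 <- classify_discrepancies(dg, v3)
  expect_equal(d3$class, "duplication")
  expect_equal(d3$severity, "critical")

  # synonymous substitution mid-ORF outside tag windows: noncritical
  orf <- orfs[1, ]
  tagf <- f[f$kind == "pcrtag", ]
  syn_pos <- NULL
  for (off in seq(30, 150, by = 3)) {
    p <- orf$start + off + 2L  # third base of a codon
    in_tag <- any(tagf$start <= p & p < tagf$end)
    cod_start <- orf$start + off
    codon <- substr(dg$sequence, cod_start + 1, cod_start + 3)
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, 3, 3)) next
      alt_codon <- paste0(substr(codon, 1, 2), b)
      same_aa <- Biostrings::GENETIC_CODE[[codon]] ==
        Biostrings::GENETIC_CODE[[alt_codon]]
      if (!in_tag && same_aa) {
        syn_pos <- list(pos = p, ref = substr(codon, 3, 3), alt = b)
        break
      }
    }
    if (!is.null(syn_pos)) break
  }
  stopifnot(!is.null(syn_pos))
  v4 <- data.frame(chrom = dg$id, pos = syn_pos$pos, ref = syn_pos$ref,
                   alt = syn_pos$alt, end = NA_integer_)
  d4 <- classify_discrepancies(dg, v4)
  expect_equal(d4$class, "synonymous_other")

  # nonsynonymous substitution: critical
  p <- orf$start + 31L  # second base of codon 11
  ref <- substr(dg$sequence, p + 1, p + 1)
  alt <- if (ref == "A") "C" else "A"
  d5 <- classify_discrepancies(dg, data.frame(chrom = dg$id, pos = p,
                                              ref = ref, alt = alt,
                                              end = NA_integer_))
  expect_true(d5$class %in% c("nonsynonymous", "residual_TAG_stop"))

  # junction-site loss: noncritical
  jx <- data.frame(pos = 500L, site = "GCGGCCGC")
  d6 <- classify_discrepancies(dg, data.frame(chrom = dg$id, pos = 503L,
                                              ref = "G", alt = "T",
                                              end = NA_integer_),
                               junction_sites = jx)
  expect_equal(d6$class, "missing_restriction_site")
})

test_that("classification is total: every variant receives one class", {
  res <- designed_for_discrepancies(23L)
  dg <- res$genome
  set.seed(9)
  n <- 40L
  pos <- sample.int(dg$length - 40L, n) - 1L
  refs <- substring(dg$sequence, pos + 1L, pos + 1L)
  alts <- vapply(refs, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                 character(1), USE.NAMES = FALSE)
  vars <- data.frame(chrom = dg$id, pos = pos, ref = refs, alt = alts,
                     end = NA_integer_)
  recs <- classify_discrepancies(dg, vars)
  expect_equal(nrow(recs), n)
  expect_true(all(recs$class %in% names(chromoforge:::DISCREPANCY_SEVERITY)))
  expect_true(all(recs$severity %in% c("critical", "noncritical")))
  expect_error(classify_discrepancies(
    dg, data.frame(chrom = dg$id, pos = dg$length + 5L, ref = "A", alt = "C",
                   end = NA_integer_)), "outside")
})

test_that("minimal VCF round trips including symbolic alleles", {
  dir <- withr::local_tempdir()
  vars <- data.frame(chrom = "syn_toy", pos = c(100L, 2000L, 5000L),
                     ref = c("A", "N", "N"), alt = c("G", "<DEL>", "<DUP>"),
                     end = c(NA, 2034L, 15000L))
  path <- file.path(dir, "obs.vcf")
  write_variants_vcf(vars, path)
  back <- read_variants_vcf(path)
  expect_equal(back$pos, vars$pos)
  expect_equal(back$alt, vars$alt)
  expect_equal(back$end, vars$end)
})

test_that("repair planning schedules criticals and bundles by proximity", {
  recs <- data.frame(
    pos = c(10000L, 12000L, 40000L),
    class = c("nonsynonymous", "missing_loxpsym", "missing_pcrtag"),
    severity = c("critical", "noncritical", "noncritical"),
    detail = "")
  plan <- plan_repairs(recs, bundle_distance = 5000L)
  expect_equal(nrow(plan$schedule), 1L)
  expect_equal(plan$schedule$bundled, "12000")
  expect_equal(plan$deferred$pos, 40000L)

  # only noncritical records: empty schedule, all deferred
  nc <- recs[recs$severity == "noncritical", ]
  plan2 <- plan_repairs(nc)
  expect_equal(nrow(plan2$schedule), 0L)
  expect_equal(nrow(plan2$deferred), 2L)
})

test_that("repair planning is idempotent and order-independent", {
  set.seed(4)
  recs <- data.frame(
    pos = sample.int(50000L, 12L),
    class = sample(c("nonsynonymous", "missing_loxpsym", "missing_pcrtag",
                     "residual_TAG_stop"), 12L, replace = TRUE),
    detail = "")
  recs$severity <- unname(chromoforge:::DISCREPANCY_SEVERITY[recs$class])
  base <- plan_repairs(recs)
  for (i in 1:5) {
    perm <- recs[sample.int(nrow(recs)), ]
    expect_equal(plan_repairs(perm), base)
  }
})

test_that("coverage tracks round-trip through TSV", {
  fx <- make_toy_chromosome(toy_chromosome_spec(seed = 2L))
  sp <- pool_sim_spec(causal_start = 10000L, causal_end = 12000L, seed = 1L)
  tr <- simulate_pool_coverage(fx$genome, sp)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "fast.tsv")
  write_coverage_track(tr$fast, path)
  expect_equal(read_coverage_track(path), tr$fast)
})
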