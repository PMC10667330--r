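# Seeded fixture generators. Every generator is a pure function of
# (spec, seed): outputs are reproducible and satisfy the preconditions of
# the modules that consume them.

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Specify a toy chromosome
#'
#' Parameters for [make_toy_chromosome()]. Defaults emulate a scaled-down
#' yeast chromosome arm: ~60 kb with 20 ORFs on both strands, a realistic
#' essential fraction (~20%), a handful of dubious ORFs, spliceosomal
#' introns, tRNAs, transposon relics and terminal telomeric repeats.
#'
#' @param length Chromosome length in bases.
#' @param n_orfs Number of ORFs.
#' @param fraction_essential Fraction of ORFs flagged essential.
#' @param fraction_dubious Fraction of ORFs classed Dubious.
#' @param n_introns Number of ORFs carrying one intron each.
#' @param n_trnas Number of tRNA genes.
#' @param n_transposons Number of transposon relics.
#' @param telomere_len Length of each terminal telomere feature.
#' @param intergenic_min Minimum intergenic spacer between features.
#' @param seed RNG seed.
#' @return A list of class `ToyChromosomeSpec`.
#' @export
toy_chromosome_spec <- function(length = 60000L, n_orfs = 20L,
                                fraction_essential = 0.2,
                                fraction_dubious = 0.1,
                                n_introns = 2L, n_trnas = 4L,
                                n_transposons = 2L, telomere_len = 500L,
                                intergenic_min = 100L, seed = 1L) {
  stopifnot(fraction_essential >= 0, fraction_essential <= 1,
            fraction_dubious >= 0, fraction_dubious <= 1,
            fraction_essential + fraction_dubious <= 1,
            n_introns <= n_orfs, length > 0L)
  structure(list(length = as.integer(length), n_orfs = as.integer(n_orfs),
                 fraction_essential = fraction_essential,
                 fraction_dubious = fraction_dubious,
                 n_introns = as.integer(n_introns),
                 n_trnas = as.integer(n_trnas),
                 n_transposons = as.integer(n_transposons),
                 telomere_len = as.integer(telomere_len),
                 intergenic_min = as.integer(intergenic_min),
                 seed = as.integer(seed)),
            class = "ToyChromosomeSpec")
}

# Random ORF in gene orientation: ATG, sense codons, stop.
random_orf_seq <- function(n_codons) {
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Generate a toy chromosome with a planted truth table
#'
#' Builds a fully annotated `GenomeRecord`: ORFs on both strands with
#' essentiality and verification-status attributes, frame-preserving
#' introns, anticodon-tagged tRNAs, transposon relics, and telomeres at
#' both ends. Every ORF translates without internal stops. The truth table
#' records all planted features plus a `loxpsym_eligible` flag (verified or
#' uncharacterized, non-essential).
#'
#' @param spec A [toy_chromosome_spec()].
#' @return `list(genome = GenomeRecord, truth = data.frame)`.
#' @export
make_toy_chromosome <- function(spec) {
  with_seed(spec$seed, {
    cassettes <- list()
    classes <- c(rep("essential", round(spec$n_orfs * spec$fraction_essential)),
                 rep("dubious", round(spec$n_orfs * spec$fraction_dubious)))
    classes <- c(classes, rep("plain", spec$n_orfs - length(classes)))
    classes <- sample(classes)
    intron_in <- sample(which(classes != "dubious"), spec$n_introns)
    for (i in seq_len(spec$n_orfs)) {
      n_codons <- sample(120:300, 1L)
      gene <- random_orf_seq(n_codons)
      strand <- sample(c("+", "-"), 1L)
      intron <- NULL
      if (i %in% intron_in) {
        ilen <- sample(60:90, 1L)
        after_codon <- sample(10:(n_codons - 10L), 1L)
        iseq <- paste0("GT", random_dna(ilen - 4L), "AG")
        gene <- paste0(substr(gene, 1L, 3L * after_codon), iseq,
                       substr(gene, 3L * after_codon + 1L, nchar(gene)))
        intron <- list(offset = 3L * after_codon, len = ilen)
      }
      ess <- if (classes[i] == "essential") "yes" else "no"
      ocl <- switch(classes[i],
                    essential = sample(c("Verified", "Uncharacterized"), 1L, prob = c(0.9, 0.1)),
                    dubious = "Dubious",
                    plain = sample(c("Verified", "Uncharacterized"), 1L, prob = c(0.7, 0.3)))
      cassettes[[length(cassettes) + 1L]] <- list(
        kind = "ORF", id = sprintf("ORF%03d", i), seq = gene, strand = strand,
        essential = ess, orf_class = ocl, intron = intron)
    }
    anticodons <- replicate(spec$n_trnas, paste(sample(BASES, 3L, replace = TRUE),
                                                collapse = ""))
    for (i in seq_len(spec$n_trnas)) {
      cassettes[[length(cassettes) + 1L]] <- list(
        kind = "tRNA", id = sprintf("tRNA%02d", i), seq = random_dna(72L),
        strand = sample(c("+", "-"), 1L), anticodon = anticodons[i])
    }
    for (i in seq_len(spec$n_transposons)) {
      cassettes[[length(cassettes) + 1L]] <- list(
        kind = "transposon", id = sprintf("Ty%02d", i), seq = random_dna(330L),
        strand = "+")
    }
    cassettes[[length(cassettes) + 1L]] <- list(
      kind = "centromere", id = "CEN", seq = random_dna(120L), strand = "+")
    cassettes <- sample(cassettes)

    body_len <- sum(vapply(cassettes, function(x) nchar(x$seq), integer(1)))
    spacer_budget <- spec$length - 2L * spec$telomere_len - body_len
    n_gaps <- length(cassettes) + 1L
    if (spacer_budget < n_gaps * spec$intergenic_min) {
      stopf("toy chromosome spec infeasible: features need %d bases, %d available",
            body_len + n_gaps * spec$intergenic_min + 2L * spec$telomere_len,
            spec$length)
    }
    extra <- spacer_budget - n_gaps * spec$intergenic_min
    cuts <- sort(sample.int(extra + 1L, n_gaps - 1L, replace = TRUE) - 1L)
    gaps <- spec$intergenic_min + diff(c(0L, cuts, extra))

    pieces <- character(0)
    feats <- empty_features()
    truth <- list()
    pos <- 0L
    add_piece <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    add_piece(random_dna(spec$telomere_len))
    feats <- rbind(feats, features("TEL_L", "telomere", 0L, spec$telomere_len))
    for (i in seq_along(cassettes)) {
      add_piece(random_dna(gaps[i]))
      cs <- cassettes[[i]]
      s0 <- pos
      chrom_seq <- if (cs$strand == "-") revcomp(cs$seq) else cs$seq
      add_piece(chrom_seq)
      feats <- rbind(feats, features(cs$id, cs$kind, s0, pos, cs$strand,
                                     essential = cs$essential %||% NA_character_,
                                     orf_class = cs$orf_class %||% NA_character_,
                                     anticodon = cs$anticodon %||% NA_character_))
      if (!is.null(cs$intron)) {
        # gene-orientation interval -> chromosome coordinates
        o1 <- cs$intron$offset; o2 <- o1 + cs$intron$len
        if (cs$strand == "+") {
          is0 <- s0 + o1; is1 <- s0 + o2
        } else {
          is0 <- pos - o2; is1 <- pos - o1
        }
        feats <- rbind(feats, features(paste0(cs$id, "_intron"), "intron",
                                       is0, is1, cs$strand, parent = cs$id))
      }
    }
    add_piece(random_dna(gaps[length(gaps)]))
    if (pos + spec$telomere_len != spec$length) {
      add_piece(random_dna(spec$length - spec$telomere_len - pos))
    }
    tel_r0 <- pos
    add_piece(random_dna(spec$telomere_len))
    feats <- rbind(feats, features("TEL_R", "telomere", tel_r0, pos))
    g <- genome_record("toy_chr", paste(pieces, collapse = ""), feats)
    tr <- g$features
    tr$loxpsym_eligible <- tr$kind == "ORF" & tr$essential == "no" &
      tr$orf_class %in% c("Verified", "Uncharacterized")
    tr$loxpsym_eligible[is.na(tr$loxpsym_eligible)] <- FALSE
    list(genome = g, truth = tr)
  })
}

#' Plant restriction junction sites along a chromosome
#'
#' Emulates the build-oriented side of a synthetic design, where terminal
#' restriction sites for chunk assembly are incorporated into the sequence
#' on purpose: substitutes one rare-cutter recognition site at roughly
#' every `spacing` bases, at an intergenic position jittered around the
#' running target, choosing for each junction an enzyme whose site does
#' not already occur within `exclusion` bases. Sites overlapping annotated
#' features are shifted to nearby intergenic sequence; positions with no
#' clean placement are skipped.
#'
#' @param genome A `GenomeRecord`.
#' @param spacing Target distance between planted sites.
#' @param jitter Uniform jitter half-width around each target.
#' @param enzymes Named recognition-sequence vector.
#' @param exclusion Radius within which the chosen enzyme's site must be
#'   otherwise absent.
#' @param seed RNG seed.
#' @return `list(genome, planted)` where `planted` is a `data.frame`
#'   (`pos`, `enzyme`, `site`).
#' @export
plant_junction_sites <- function(genome, spacing = 10000L, jitter = 400L,
                                 enzymes = default_enzymes(),
                                 exclusion = 20000L, seed = 1L) {
  with_seed(seed, {
    seqc <- genome$sequence
    f <- genome$features
    planted <- list()
    targets <- seq(spacing, max(spacing, genome$length - 2000L), by = spacing)
    enz_i <- 0L
    for (tgt in targets) {
      p <- as.integer(tgt + runif(1, -jitter, jitter))
      placed <- FALSE
      for (k in seq_along(enzymes)) {
        enz_i <- enz_i + 1L
        e <- (enz_i - 1L) %% length(enzymes) + 1L
        site <- enzymes[[e]]
        sl <- nchar(site)
        # slide to an intergenic placement near p
        for (off in c(0L, seq(50L, 600L, by = 50L) * rep(c(1L, -1L), 6L))) {
          q <- p + off
          if (q < 0L || q + sl > genome$length) next
          if (any(f$start < q + sl & q < f$end)) next
          ctx_lo <- max(0L, q - exclusion)
          ctx_hi <- min(genome$length, q + exclusion)
          ctx <- subseq0(seqc, ctx_lo, ctx_hi)
          if (length(find_all(site, ctx)) + length(find_all(revcomp(site), ctx)) > 0L) next
          substr(seqc, q + 1L, q + sl) <- site
          planted[[length(planted) + 1L]] <- data.frame(
            pos = q, enzyme = names(enzymes)[e], site = site,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (placed) break
      }
    }
    g <- genome
    g$sequence <- seqc
    list(genome = g,
         planted = if (length(planted)) do.call(rbind, planted) else
           data.frame(pos = integer(0), enzyme = character(0),
                      site = character(0)))
  })
}

#' Specify a pooled fast/slow coverage simulation
#'
#' Parameters for [simulate_pool_coverage()], emulating bulk-segregant
#' sequencing of phenotypically extreme pools mapped against a hybrid
#' synthetic + wild-type reference. `selection_strength` is the fraction of
#' fast-pool genomes carrying the wild-type allele at the causal locus.
#'
#' @param window Window size in bases.
#' @param mean_depth Mean per-window read depth.
#' @param causal_start,causal_end Causal interval (0-based half-open,
#'   synthetic-allele coordinates).
#' @param selection_strength In `[0, 1]`.
#' @param linkage_decay Bases over which the allele-frequency skew decays
#'   linearly back to baseline.
#' @param seed RNG seed.
#' @return A list of class `PoolSimSpec`.
#' @export
pool_sim_spec <- function(window = 1000L, mean_depth = 100,
                          causal_start, causal_end,
                          selection_strength = 0.8,
                          linkage_decay = 20000L, seed = 1L) {
  stopifnot(mean_depth > 0, selection_strength >= 0, selection_strength <= 1,
            causal_start < causal_end)
  structure(list(window = as.integer(window), mean_depth = mean_depth,
                 causal_start = as.integer(causal_start),
                 causal_end = as.integer(causal_end),
                 selection_strength = selection_strength,
                 linkage_decay = as.numeric(linkage_decay),
                 seed = as.integer(seed)),
            class = "PoolSimSpec")
}

#' Simulate pooled fast/slow coverage tracks
#'
#' Produces Poisson per-window depth tracks for a fast-grower and a
#' slow-grower pool over a hybrid coordinate space: each window exists once
#' in the `SYN_allele` partition and once in the homologous `WT_allele`
#' partition. At the causal window the fast pool's synthetic-allele depth
#' drops to `(1 - selection_strength) * mean_depth` (recovering linearly
#' over `linkage_decay` bases) while the displaced reads appear on the
#' wild-type allele; the slow pool is mirrored.
#'
#' @param genome A `GenomeRecord` (defines chromosome length).
#' @param spec A [pool_sim_spec()].
#' @return `list(fast = track, slow = track)`, each a `data.frame` with
#'   columns `contig`, `start`, `end`, `depth`, `partition`.
#' @export
simulate_pool_coverage <- function(genome, spec) {
  if (spec$window > genome$length) stopf("window larger than chromosome")
  if (spec$causal_end > genome$length) stopf("causal interval outside chromosome")
  with_seed(spec$seed, {
    starts <- seq(0L, genome$length - 1L, by = spec$window)
    ends <- pmin(starts + spec$window, genome$length)
    centers <- (starts + ends) / 2
    d <- pmax(0, pmax(spec$causal_start - centers, centers - spec$causal_end))
    w <- if (spec$linkage_decay > 0) pmax(0, 1 - d / spec$linkage_decay) else
      as.numeric(d == 0)
    s_eff <- spec$selection_strength * w
    mk <- function(lam_syn, lam_wt) {
      data.frame(contig = genome$id,
                 start = c(starts, starts), end = c(ends, ends),
                 depth = c(rpois(length(starts), lam_syn),
                           rpois(length(starts), lam_wt)),
                 partition = rep(c("SYN_allele", "WT_allele"),
                                 each = length(starts)),
                 stringsAsFactors = FALSE)
    }
    list(fast = mk(spec$mean_depth * (1 - s_eff), spec$mean_depth * (1 + s_eff)),
         slow = mk(spec$mean_depth * (1 + s_eff), spec$mean_depth * (1 - s_eff)))
  })
}

# Deterministic expected melt peak per (tag_id, allele), degrees C.
expected_melt <- function(tag_id, allele) {
  h <- vapply(paste0(tag_id, "_", allele),
              function(s) sum(utf8ToInt(s) * seq_len(nchar(s))) %% 80L,
              integer(1), USE.NAMES = FALSE)
  78 + h / 10
}

#' Simulate a PCR-tag qPCR plate
#'
#' Generates well-level Cq + melt data from a genotype truth table.
#' Present templates amplify with `Cq ~ N(cq_mean, cq_sd)` and an
#' on-target melt peak; absent templates do not amplify (empty Cq) except
#' with probability `false_amp_rate`, in which case a late, on-target-melt
#' amplification is emitted (emulating cross-contamination). A no-template
#' control (NTC) well and positive (mixed synthetic chunk DNA) / negative
#' (wild-type DNA) control samples are included per tag and allele.
#'
#' @param truth `data.frame` with columns `sample`, `tag_id`, `megachunk`,
#'   `syn_present`, `wt_present`.
#' @param false_amp_rate Probability an absent template spuriously
#'   amplifies.
#' @param ntc_amp_rate Probability an NTC well amplifies (marks the tag
#'   aberrant downstream).
#' @param cq_mean,cq_sd Cq distribution for present templates.
#' @param melt_sd Melt-peak jitter around the tag's expected peak.
#' @param seed RNG seed.
#' @return `list(table = QpcrTable data.frame, manifest = data.frame)`;
#'   the manifest maps `(tag_id, allele)` to its expected melt peak, and
#'   the table has columns `well`, `sample`, `tag_id`, `allele`, `Cq`,
#'   `melt_c`, `is_ntc`.
#' @export
simulate_qpcr_table <- function(truth, false_amp_rate = 0, ntc_amp_rate = 0,
                                cq_mean = 22, cq_sd = 0.5, melt_sd = 0.15,
                                seed = 1L) {
  with_seed(seed, {
    tags <- unique(truth$tag_id)
    grid <- expand.grid(tag_id = tags, allele = c("SYN", "WT"),
                        stringsAsFactors = FALSE)
    manifest <- data.frame(grid,
                           melt_expected = expected_melt(grid$tag_id, grid$allele),
                           stringsAsFactors = FALSE)
    rows <- list()
    emit <- function(sample, tag_id, allele, present, is_ntc = FALSE) {
      amp <- if (present) TRUE else runif(1) < (if (is_ntc) ntc_amp_rate else false_amp_rate)
      cq <- if (!amp) NA_real_ else if (present) rnorm(1, cq_mean, cq_sd) else rnorm(1, 30, 1)
      melt <- if (!amp) NA_real_ else
        expected_melt(tag_id, allele) + rnorm(1, 0, melt_sd)
      rows[[length(rows) + 1L]] <<- data.frame(
        well = sprintf("W%04d", length(rows) + 1L), sample = sample,
        tag_id = tag_id, allele = allele, Cq = cq, melt_c = melt,
        is_ntc = is_ntc, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(truth))) {
      emit(truth$sample[i], truth$tag_id[i], "SYN", truth$syn_present[i])
      emit(truth$sample[i], truth$tag_id[i], "WT", truth$wt_present[i])
    }
    for (t in tags) {
      emit("POS_CTRL", t, "SYN", TRUE)   # mixed synthetic chunk DNA
      emit("POS_CTRL", t, "WT", FALSE)
      emit("NEG_CTRL", t, "SYN", FALSE)  # wild-type genomic DNA
      emit("NEG_CTRL", t, "WT", TRUE)
      emit("NTC", t, "SYN", FALSE, is_ntc = TRUE)
      emit("NTC", t, "WT", FALSE, is_ntc = TRUE)
    }
    list(table = do.call(rbind, rows), manifest = manifest)
  })
}

#' Simulate a propidium-iodide DNA-content histogram
#'
#' Actively dividing populations show a double-peak fluorescence profile:
#' a G1 peak at a position proportional to DNA content and a G2 peak at
#' twice that position. Reference haploid/diploid histograms generated with
#' the same `base_fluor` share the fluorescence scale.
#'
#' @param ploidy Integer 1-4.
#' @param base_fluor Fluorescence units per 1C DNA content.
#' @param cv Coefficient of variation of each peak.
#' @param g1_frac Fraction of cells in G1.
#' @param n_cells Cells sampled.
#' @param bin_width,max_fluor Histogram binning.
#' @param seed RNG seed.
#' @return `data.frame(bin_center, count)`.
#' @export
simulate_pi_histogram <- function(ploidy, base_fluor = 100, cv = 0.07,
                                  g1_frac = 0.6, n_cells = 20000L,
                                  bin_width = 10, max_fluor = 1200,
                                  seed = 1L) {
  stopifnot(ploidy %in% 1:4)
  with_seed(seed, {
    g1_pos <- base_fluor * ploidy
    g2_pos <- 2 * g1_pos
    n1 <- round(n_cells * g1_frac)
    x <- c(rnorm(n1, g1_pos, cv * g1_pos),
           rnorm(n_cells - n1, g2_pos, cv * g2_pos))
    x <- pmin(pmax(x, 0), max_fluor)
    breaks <- seq(0, max_fluor, by = bin_width)
    counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                       nbins = length(breaks) - 1L)
    data.frame(bin_center = breaks[-length(breaks)] + bin_width / 2,
               count = counts)
  })
}
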