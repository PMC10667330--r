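# Cre-loxPsym SCRaMbLE simulation on synthetic/wild-type hybrid genomes.
# Molecules are signed integer vectors: abs(x) is the segment id in the
# reference segmentation, sign(x) the orientation. loxPsym junctions are
# implicit between consecutive entries of synthetic molecules; wild-type
# molecules carry no recombinable junctions.

#' Build a SCRaMbLE genome from a designed chromosome
#'
#' One molecule per letter of `syn_mask` ("S" synthetic, "W" wild type).
#' Synthetic molecules are segmented at loxPsym features (k sites yield
#' k+1 segments); wild-type molecules carry the same segment ids but no
#' recombinable junctions. A segment is essential iff it contains at
#' least one essential ORF; the centromere-bearing segment is flagged.
#'
#' @param designed Designed `GenomeRecord` with `loxpsym` features.
#' @param syn_mask String over `{S, W}`, e.g. `"WSSS"`; its length is the
#'   ploidy.
#' @param ploidy Optional; must equal `nchar(syn_mask)` when given.
#' @return A list of class `ScrambleGenome`: `molecules` (signed integer
#'   vectors), `recombinable` (logical per molecule), `essential_ids`,
#'   `centromere_ids`, `n_segments`.
#' @export
build_scramble_genome <- function(designed, syn_mask, ploidy = NULL) {
  if (!is.null(ploidy) && ploidy != nchar(syn_mask)) {
    stopf("ploidy %d does not match mask '%s'", ploidy, syn_mask)
  }
  letters_ <- strsplit(toupper(syn_mask), "")[[1]]
  if (!all(letters_ %in% c("S", "W"))) stopf("mask must use only S and W")
  f <- designed$features
  cuts <- sort(f$start[f$kind == "loxpsym"])
  bounds <- c(0L, cuts, designed$length)
  n_seg <- length(bounds) - 1L
  seg_start <- bounds[-length(bounds)]
  seg_end <- bounds[-1L]
  ess_orfs <- f[f$kind == "ORF" & !is.na(f$essential) & f$essential == "yes", , drop = FALSE]
  cen <- f[f$kind == "centromere", , drop = FALSE]
  overlaps <- function(fs, fe) which(fs < seg_end & seg_start < fe)
  essential_ids <- sort(unique(unlist(lapply(seq_len(nrow(ess_orfs)), function(i) {
    overlaps(ess_orfs$start[i], ess_orfs$end[i])
  }))))
  centromere_ids <- sort(unique(unlist(lapply(seq_len(nrow(cen)), function(i) {
    overlaps(cen$start[i], cen$end[i])
  }))))
  structure(list(molecules = replicate(length(letters_), seq_len(n_seg),
                                       simplify = FALSE),
                 recombinable = letters_ == "S",
                 essential_ids = as.integer(essential_ids),
                 centromere_ids = as.integer(centromere_ids),
                 n_segments = n_seg),
            class = "ScrambleGenome")
}

#' @export
print.ScrambleGenome <- function(x, ...) {
  cat(sprintf("ScrambleGenome: %d molecules (%s), %d reference segments, %d essential\n",
              length(x$molecules),
              paste(ifelse(x$recombinable, "S", "W"), collapse = ""),
              x$n_segments, length(x$essential_ids)))
  invisible(x)
}

# junctions of molecule m: j in 1..(len-1), between positions j and j+1
molecule_junctions <- function(genome) {
  lens <- vapply(genome$molecules, length, integer(1))
  n_j <- ifelse(genome$recombinable, pmax(0L, lens - 1L), 0L)
  if (sum(n_j) == 0L) {
    return(data.frame(mol = integer(0), junction = integer(0)))
  }
  data.frame(mol = rep(seq_along(lens), n_j),
             junction = unlist(lapply(n_j, seq_len), use.names = FALSE))
}

#' Apply one Cre recombination event
#'
#' Both sites must be recombinable junctions on synthetic molecules. On
#' the same molecule the intervening segments are deleted (the excised
#' circle is lost) with probability `p_delete`, otherwise inverted (order
#' reversed, orientations flipped) -- loxPsym's palindromic symmetry gives
#' no orientation preference. Between two molecules, the tails distal to
#' each site are exchanged reciprocally; at non-allelic sites this yields
#' one duplication-bearing and one deletion-bearing molecule while
#' conserving the cell-wide segment multiset.
#'
#' @param genome A `ScrambleGenome`.
#' @param site1,site2 Each `c(molecule_index, junction_index)`.
#' @param p_delete Intramolecular deletion probability.
#' @param branch Force `"delete"` or `"invert"` for an intramolecular
#'   event (default draws from `p_delete`).
#' @return The modified `ScrambleGenome`.
#' @export
apply_event <- function(genome, site1, site2, p_delete = 0.5, branch = NULL) {
  m1 <- site1[1]; j1 <- site1[2]
  m2 <- site2[1]; j2 <- site2[2]
  if (!genome$recombinable[m1] || !genome$recombinable[m2]) {
    stopf("recombination site on a wild-type molecule")
  }
  if (m1 == m2) {
    if (j1 == j2) return(genome)
    lo <- min(j1, j2); hi <- max(j1, j2)
    x <- genome$molecules[[m1]]
    do_delete <- if (!is.null(branch)) branch == "delete" else runif(1) < p_delete
    if (do_delete) {
      genome$molecules[[m1]] <- x[-((lo + 1L):hi)]
    } else {
      x[(lo + 1L):hi] <- -rev(x[(lo + 1L):hi])
      genome$molecules[[m1]] <- x
    }
  } else {
    a <- genome$molecules[[m1]]
    b <- genome$molecules[[m2]]
    genome$molecules[[m1]] <- c(a[seq_len(j1)], b[-seq_len(j2)])
    genome$molecules[[m2]] <- c(b[seq_len(j2)], a[-seq_len(j1)])
  }
  genome
}

cell_viable <- function(genome, centromere_rule = c("off", "strict")) {
  centromere_rule <- match.arg(centromere_rule)
  present <- unique(abs(unlist(genome$molecules, use.names = FALSE)))
  if (!all(genome$essential_ids %in% present)) return(FALSE)
  if (centromere_rule == "strict") {
    for (x in genome$molecules) {
      if (sum(abs(x) %in% genome$centromere_ids) != 1L) return(FALSE)
    }
  }
  TRUE
}

#' Simulate a SCRaMbLE'd population
#'
#' For each cell, draws an event count from Poisson(`lambda`) (or uses
#' `fixed_events`), applies events at uniformly chosen unordered pairs of
#' recombinable junctions (intermolecular pairs included when allowed),
#' and scores viability: a cell survives iff every essential reference
#' segment retains at least one intact copy across all molecules (and,
#' under the strict centromere rule, every molecule keeps exactly one
#' centromere). Cells with fewer than two available junctions pass events
#' through unchanged.
#'
#' @param genome A `ScrambleGenome`.
#' @param lambda Mean Cre events per cell per induction.
#' @param n_cells Population size.
#' @param p_delete Intramolecular deletion probability.
#' @param intermolecular Allow events between molecules.
#' @param centromere_rule `"off"` or `"strict"`.
#' @param fixed_events Use exactly this many events per cell instead of a
#'   Poisson draw.
#' @param seed RNG seed.
#' @return List: `viability`, `ci` (binomial 95% CI), `n_cells`,
#'   `outcomes` (`data.frame`: `cell`, `n_events`, `viable`,
#'   `n_molecules`, `total_segments`).
#' @export
simulate_population <- function(genome, lambda = 2, n_cells = 1000L,
                                p_delete = 0.5, intermolecular = TRUE,
                                centromere_rule = "off",
                                fixed_events = NULL, seed = 1L) {
  stopifnot(lambda >= 0, n_cells >= 1L)
  with_seed(seed, {
    viable <- logical(n_cells)
    n_events <- if (is.null(fixed_events)) rpois(n_cells, lambda) else
      rep.int(as.integer(fixed_events), n_cells)
    n_mol <- integer(n_cells)
    tot_seg <- integer(n_cells)
    for (c_i in seq_len(n_cells)) {
      g <- genome
      k <- n_events[c_i]
      for (e in seq_len(k)) {
        jx <- molecule_junctions(g)
        if (nrow(jx) < 2L) break
        pick <- sample.int(nrow(jx), 2L)
        if (!intermolecular && jx$mol[pick[1]] != jx$mol[pick[2]]) next
        g <- apply_event(g, c(jx$mol[pick[1]], jx$junction[pick[1]]),
                         c(jx$mol[pick[2]], jx$junction[pick[2]]),
                         p_delete = p_delete)
      }
      viable[c_i] <- cell_viable(g, centromere_rule)
      n_mol[c_i] <- length(g$molecules)
      tot_seg[c_i] <- sum(lengths(g$molecules))
    }
    v <- mean(viable)
    ci <- stats::binom.test(sum(viable), n_cells)$conf.int
    list(viability = v, ci = as.numeric(ci), n_cells = n_cells,
         outcomes = data.frame(cell = seq_len(n_cells), n_events = n_events,
                               viable = viable, n_molecules = n_mol,
                               total_segments = tot_seg))
  })
}

#' Exact viability by event enumeration
#'
#' Exhaustively enumerates all equally likely site-pair choices and
#' deletion/inversion branches for exactly `n_events` sequential events,
#' returning the exact viability probability. Tractable for small genomes
#' (a handful of sites) and up to 2-3 events; used to validate the
#' stochastic simulator.
#'
#' @param genome A `ScrambleGenome`.
#' @param n_events Exact number of events.
#' @param p_delete Intramolecular deletion probability.
#' @param intermolecular Allow intermolecular pairs.
#' @param centromere_rule `"off"` or `"strict"`.
#' @return Exact viability probability.
#' @export
enumerate_viability <- function(genome, n_events, p_delete = 0.5,
                                intermolecular = TRUE,
                                centromere_rule = "off") {
  recurse <- function(g, k) {
    if (k == 0L) return(as.numeric(cell_viable(g, centromere_rule)))
    jx <- molecule_junctions(g)
    if (nrow(jx) < 2L) return(as.numeric(cell_viable(g, centromere_rule)))
    pairs <- utils::combn(nrow(jx), 2L)
    total <- 0
    n_pairs_all <- ncol(pairs)
    for (p in seq_len(n_pairs_all)) {
      i1 <- pairs[1, p]; i2 <- pairs[2, p]
      s1 <- c(jx$mol[i1], jx$junction[i1])
      s2 <- c(jx$mol[i2], jx$junction[i2])
      if (s1[1] == s2[1]) {
        g_del <- apply_event(g, s1, s2, branch = "delete")
        g_inv <- apply_event(g, s1, s2, branch = "invert")
        total <- total + p_delete * recurse(g_del, k - 1L) +
          (1 - p_delete) * recurse(g_inv, k - 1L)
      } else if (intermolecular) {
        total <- total + recurse(apply_event(g, s1, s2), k - 1L)
      } else {
        # pair drawn but skipped: state unchanged, event consumed
        total <- total + recurse(g, k - 1L)
      }
    }
    total / n_pairs_all
  }
  recurse(genome, as.integer(n_events))
}

# ---- ploidy classification ------------------------------------------------

# locate modes of a (bin_center, count) histogram: local maxima of the
# 3-bin smoothed counts above frac * global max, merged when adjacent
histogram_peaks <- function(hist, frac = 0.2) {
  x <- hist$bin_center
  y <- as.numeric(hist$count)
  n <- length(y)
  if (n < 3L) return(numeric(0))
  sm <- (c(y[1], y[-n]) + y + c(y[-1], y[n])) / 3
  if (max(sm) <= 0) return(numeric(0))
  is_max <- sm >= c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf) & sm >= frac * max(sm)
  idx <- which(is_max)
  if (length(idx) == 0L) return(numeric(0))
  # merge plateaus / adjacent bins into one peak, located by the weighted
  # centroid of a small window around the mode (sub-bin resolution)
  groups <- cumsum(c(1L, diff(idx) > 2L))
  unname(vapply(split(idx, groups), function(ii) {
    w <- max(1L, min(ii) - 3L):min(n, max(ii) + 3L)
    sum(x[w] * sm[w]) / sum(sm[w])
  }, numeric(1)))
}

#' Classify ploidy from a propidium-iodide histogram
#'
#' Locates the sample's G1 mode (first major peak) and compares it with
#' reference haploid and diploid G1/G2 peaks on the same fluorescence
#' scale: near the haploid G1 is 1n; near the haploid G2 / diploid G1 is
#' 2n; near the diploid G2 is 4n; strictly between the diploid G1 and G2
#' peaks, outside tolerance of both, is 3n.
#'
#' @param hist Sample histogram (`bin_center`, `count`).
#' @param reference_haploid,reference_diploid Reference histograms.
#' @param tolerance Relative tolerance for peak matching (default 10%).
#' @return Integer ploidy 1-4, or `NA_integer_` when no peak structure is
#'   discernible or the G1 mode matches no rule.
#' @export
classify_ploidy <- function(hist, reference_haploid, reference_diploid,
                            tolerance = 0.10) {
  hp <- histogram_peaks(reference_haploid)
  dp <- histogram_peaks(reference_diploid)
  sp <- histogram_peaks(hist)
  if (length(hp) < 2L || length(dp) < 2L || length(sp) < 1L) {
    return(NA_integer_)
  }
  h1 <- hp[1]; d1 <- dp[1]; d2 <- dp[length(dp)]
  g1 <- sp[1]
  near <- function(a, b) isTRUE(abs(a - b) <= tolerance * b)
  if (near(g1, h1)) return(1L)
  if (near(g1, d1)) return(2L)
  if (near(g1, d2)) return(4L)
  if (isTRUE(g1 > d1 && g1 < d2)) return(3L)
  NA_integer_
}
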