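# Rule-driven chromosome redesign: loxPsym insertion, intron removal,
# TAG->TAA stop swaps, synonymous PCR-tag recoding, telomere caps,
# tRNA/transposon removal -- all emitted as ledger edits in native
# coordinates, merged and applied once.

# 34-bp loxPsym: a perfect palindrome (13-bp arms, 8-bp symmetric spacer),
# so Cre recombination has no orientation preference.
LOXPSYM_SEQ <- "ATAACTTCGTATAATGTACATTATACGAAGTTAT"

# Synthetic telomere seed cap, written 5'->3' on the right (outward) end;
# the left cap is its reverse complement. Sc2.0-convention TG(1-3) repeat.
TELOMERE_CAP <- paste(rep("TGTGGGTGTGGTG", 4L), collapse = "")

#' PCR-tag recoding parameters
#'
#' Engineering defaults for synonymous PCR-tag design: 24-base tags
#' (8 codons), one pair per ORF placed near the ends of a 200-500-base
#' amplicon, nearest-neighbor Tm target 58-62 degrees C, and at least 8
#' mismatches between the wild-type and recoded tag.
#'
#' @param tag_len Tag length in bases (multiple of 3).
#' @param amplicon_min,amplicon_max Amplicon size range in bases.
#' @param tm_min,tm_max Primer Tm window, degrees C.
#' @param min_mismatches Minimum wt-vs-syn Hamming distance per tag.
#' @return A list of class `PcrTagParams`.
#' @export
pcrtag_params <- function(tag_len = 24L, amplicon_min = 200L,
                          amplicon_max = 500L, tm_min = 58, tm_max = 62,
                          min_mismatches = 8L) {
  stopifnot(tag_len %% 3L == 0L, amplicon_min <= amplicon_max)
  structure(list(tag_len = as.integer(tag_len),
                 amplicon_min = as.integer(amplicon_min),
                 amplicon_max = as.integer(amplicon_max),
                 tm_min = tm_min, tm_max = tm_max,
                 min_mismatches = as.integer(min_mismatches)),
            class = "PcrTagParams")
}

#' Chromosome design policy
#'
#' Bundles all tunable design rules. The defaults implement the standard
#' redesign: a loxPsym site 3 bp after the stop codon of every
#' non-essential verified/uncharacterized ORF (dubious ORFs excluded), all
#' introns removed unless explicitly retained, TAG stops swapped to TAA,
#' tRNAs and transposons deleted, telomeres replaced with a synthetic cap,
#' and two synonymous PCR tags recoded per ORF.
#'
#' @param loxpsym_seq 34-base loxPsym sequence (validated for alphabet;
#'   warned if not palindromic).
#' @param loxpsym_offset Bases 3' of the stop codon at which the site is
#'   inserted.
#' @param loxpsym_targets ORF classes receiving sites.
#' @param intron_retain_ids Intron feature ids to keep (e.g. stable
#'   introns whose removal costs fitness).
#' @param stop_swap Named map of stop-codon substitutions (gene
#'   orientation).
#' @param remove_kinds Feature kinds deleted wholesale.
#' @param telomere_cap Synthetic telomere sequence (right/outward arm);
#'   `NULL` leaves telomeres untouched.
#' @param pcrtag [pcrtag_params()]; `NULL` disables tag recoding.
#' @param forbidden_sites Enzyme recognition sequences that edits must not
#'   create.
#' @return A list of class `DesignPolicy`.
#' @export
design_policy <- function(loxpsym_seq = LOXPSYM_SEQ, loxpsym_offset = 3L,
                          loxpsym_targets = c("Verified", "Uncharacterized"),
                          intron_retain_ids = character(0),
                          stop_swap = c(TAG = "TAA"),
                          remove_kinds = c("tRNA", "transposon"),
                          telomere_cap = TELOMERE_CAP,
                          pcrtag = pcrtag_params(),
                          forbidden_sites = c(NotI = "GCGGCCGC")) {
  loxpsym_seq <- toupper(loxpsym_seq)
  stopifnot(loxpsym_offset >= 0L, !grepl("[^ACGT]", loxpsym_seq))
  if (!is.null(telomere_cap)) {
    telomere_cap <- toupper(telomere_cap)
    stopifnot(!grepl("[^ACGT]", telomere_cap))
  }
  if (revcomp(loxpsym_seq) != loxpsym_seq) {
    warnf("loxPsym sequence is not its own reverse complement")
  }
  structure(list(loxpsym_seq = loxpsym_seq,
                 loxpsym_offset = as.integer(loxpsym_offset),
                 loxpsym_targets = loxpsym_targets,
                 intron_retain_ids = intron_retain_ids,
                 stop_swap = stop_swap, remove_kinds = remove_kinds,
                 telomere_cap = telomere_cap, pcrtag = pcrtag,
                 forbidden_sites = forbidden_sites),
            class = "DesignPolicy")
}

#' Read a design policy from YAML/JSON
#'
#' Fields absent from the file keep their [design_policy()] defaults.
#'
#' @param path YAML (or JSON, a YAML subset) policy file.
#' @return A `DesignPolicy`.
#' @export
read_design_policy <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- design_policy()
  args <- list()
  for (nm in c("loxpsym_seq", "loxpsym_offset", "loxpsym_targets",
               "intron_retain_ids", "remove_kinds", "telomere_cap")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$stop_swap)) args$stop_swap <- unlist(raw$stop_swap)
  if (!is.null(raw$forbidden_sites)) args$forbidden_sites <- unlist(raw$forbidden_sites)
  if (!is.null(raw$pcrtag)) args$pcrtag <- do.call(pcrtag_params, raw$pcrtag)
  do.call(design_policy, args)
}

orf_is_eligible <- function(f, targets) {
  f$kind == "ORF" & !is.na(f$orf_class) & f$orf_class %in% targets
}

#' Plan loxPsym insertions
#'
#' For every non-essential ORF of a targeted class, emits one insert edit
#' placing the loxPsym site `loxpsym_offset` bases 3' of the stop codon in
#' the ORF's own orientation (for minus-strand genes, upstream of the
#' feature start in chromosome coordinates). Insertions landing strictly
#' inside another annotated feature, or beyond the chromosome end, are
#' skipped and reported in the `skipped` attribute.
#'
#' @param genome A `GenomeRecord` with essentiality/class attributes.
#' @param policy A `DesignPolicy`.
#' @return Edit table (see [edit_records()]) with a `skipped` attribute.
#' @export
insert_loxpsym_sites <- function(genome, policy = design_policy()) {
  f <- genome$features
  orfs <- f[orf_is_eligible(f, policy$loxpsym_targets) & f$essential == "no", , drop = FALSE]
  p <- ifelse(orfs$strand == "+", orfs$end + policy$loxpsym_offset,
              orfs$start - policy$loxpsym_offset)
  oob <- p < 0L | p > genome$length
  if (any(oob)) {
    warnf("loxPsym for '%s' falls outside the chromosome; skipped",
          paste(orfs$id[oob], collapse = ","))
  }
  colliding <- vapply(seq_len(nrow(orfs)), function(i) {
    any(f$start < p[i] & p[i] < f$end & f$id != orfs$id[i])
  }, logical(1))
  keep <- !oob & !colliding
  edits <- if (any(keep)) {
    edit_records("insert", p[keep], p[keep], policy$loxpsym_seq,
                 "loxpsym", orfs$id[keep])
  } else empty_edits()
  attr(edits, "skipped") <- orfs$id[!keep]
  edits
}

#' Plan intron removals
#'
#' Delete edits for every annotated intron not listed in `retain_ids`.
#' Excision preserves the parent ORF's reading frame by the genome
#' invariant (coding length divisible by 3 after excision); protein
#' identity is asserted downstream by [verify_design()].
#'
#' @param genome A `GenomeRecord`.
#' @param retain_ids Intron ids to keep in the design.
#' @return Edit table.
#' @export
remove_introns <- function(genome, retain_ids = character(0)) {
  f <- genome$features
  introns <- f[f$kind == "intron" & !(f$id %in% retain_ids), , drop = FALSE]
  if (nrow(introns) == 0L) return(empty_edits())
  edit_records("delete", introns$start, introns$end, "",
               "intron_removal", introns$id)
}

#' Plan TAG-to-TAA stop-codon swaps
#'
#' Every verified or uncharacterized ORF whose stop codon (gene
#' orientation) matches a key of `policy$stop_swap` receives a 3-base
#' substitute edit; dubious ORFs and other stops are untouched.
#'
#' @param genome A `GenomeRecord`.
#' @param policy A `DesignPolicy`.
#' @return Edit table.
#' @export
swap_stop_codons <- function(genome, policy = design_policy()) {
  f <- genome$features
  orfs <- f[orf_is_eligible(f, c("Verified", "Uncharacterized")), , drop = FALSE]
  if (nrow(orfs) == 0L) return(empty_edits())
  plus <- orfs$strand == "+"
  s0 <- ifelse(plus, orfs$end - 3L, orfs$start)
  raw <- substring(genome$sequence, s0 + 1L, s0 + 3L)
  stop_codon <- ifelse(plus, raw, revcomp(raw))
  bad <- !(stop_codon %in% STOP_CODONS)
  if (any(bad)) {
    stopf("ORF '%s' has no valid stop codon (found %s)",
          orfs$id[which(bad)[1]], stop_codon[which(bad)[1]])
  }
  hit <- stop_codon %in% names(policy$stop_swap)
  if (!any(hit)) return(empty_edits())
  new_stop <- unname(unlist(policy$stop_swap)[stop_codon[hit]])
  payload <- ifelse(plus[hit], new_stop, revcomp(new_stop))
  edit_records("substitute", s0[hit], s0[hit] + 3L, payload,
               "stop_swap", orfs$id[hit])
}

#' Plan wholesale feature removals
#'
#' One delete edit per feature of the named kinds (default tRNAs and
#' transposons), spanning the full feature interval.
#'
#' @param genome A `GenomeRecord`.
#' @param kinds Feature kinds to remove.
#' @return Edit table.
#' @export
remove_features <- function(genome, kinds = c("tRNA", "transposon")) {
  f <- genome$features
  victims <- f[f$kind %in% kinds, , drop = FALSE]
  if (nrow(victims) == 0L) return(empty_edits())
  edit_records("delete", victims$start, victims$end, "",
               "feature_removal", victims$id)
}

#' Plan telomere caps
#'
#' Replaces each annotated telomere with the synthetic cap; the left cap
#' is reverse complemented so both chromosome ends present the same
#' outward-facing motif.
#'
#' @param genome A `GenomeRecord`.
#' @param cap_seq Cap sequence, written for the right (outward 3') end.
#' @return Edit table.
#' @export
cap_telomeres <- function(genome, cap_seq = TELOMERE_CAP) {
  f <- genome$features
  tels <- f[f$kind == "telomere", , drop = FALSE]
  if (nrow(tels) == 0L) {
    warnf("no telomere features annotated; no caps placed")
    return(empty_edits())
  }
  tels <- tels[order(tels$start), , drop = FALSE]
  mid <- genome$length / 2
  edits <- empty_edits()
  for (i in seq_len(nrow(tels))) {
    left <- (tels$start[i] + tels$end[i]) / 2 < mid
    payload <- if (left) revcomp(cap_seq) else cap_seq
    edits <- rbind(edits, edit_records("substitute", tels$start[i], tels$end[i],
                                       payload, "telomere_cap", tels$id[i]))
  }
  edits
}

# ---- nearest-neighbor melting temperature ---------------------------------

# SantaLucia (1998) unified NN parameters; dH kcal/mol, dS cal/(mol K).
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)

nn_lookup <- function(pairs, tab) {
  v <- tab[pairs]
  miss <- is.na(v)
  if (any(miss)) v[miss] <- tab[revcomp(pairs[miss])]
  unname(v)
}

#' Nearest-neighbor melting temperature
#'
#' Two-state nearest-neighbor Tm with the SantaLucia (1998) unified
#' parameter set, 50 mM monovalent salt entropy correction and 500 nM
#' total strand concentration.
#'
#' @param seq DNA string (primer-length).
#' @param conc_nM Total strand concentration, nM.
#' @param na_M Monovalent cation concentration, mol/L.
#' @return Tm in degrees C.
#' @export
tm_nn <- function(seq, conc_nM = 500, na_M = 0.05) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2L) stopf("sequence too short for nearest-neighbor Tm")
  pairs <- substring(seq, 1:(n - 1L), 2:n)
  dh <- sum(nn_lookup(pairs, NN_DH))
  ds <- sum(nn_lookup(pairs, NN_DS))
  ends <- substring(seq, c(1L, n), c(1L, n))
  dh <- dh + sum(ifelse(ends %in% c("G", "C"), 0.1, 2.3))
  ds <- ds + sum(ifelse(ends %in% c("G", "C"), -2.8, 4.1))
  ds <- ds + 0.368 * (n - 1L) * log(na_M)
  dh * 1000 / (ds + 1.987 * log(conc_nM * 1e-9 / 4)) - 273.15
}

# ---- PCR-tag recoding -----------------------------------------------------

# Most-different synonymous codons, precomputed once per session.
codon_alternatives <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      syn <- split(names(gc), unname(gc))
      cache <<- lapply(setNames(names(gc), names(gc)), function(cod) {
        alts <- setdiff(syn[[gc[[cod]]]], cod)
        if (length(alts) == 0L) return(character(0))
        d <- vapply(alts, function(a) {
          sum(strsplit(a, "")[[1]] != strsplit(cod, "")[[1]])
        }, integer(1))
        alts[order(-d, alts)]
      })
    }
    cache
  }
})

hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# Greedily recode a codon-aligned window until >= min_mismatch bases
# differ. Forbidden enzyme sites are scanned over the recoded window plus
# its native flanking context (sites can straddle the window edge); any
# newly created occurrence is disrupted by switching the overlapping codon
# to another synonym (or back to the wild type).
recode_window <- function(window, min_mismatch, forbidden = character(0),
                          ctx_left = "", ctx_right = "") {
  alts <- codon_alternatives()
  codons <- substring(window, seq(1L, nchar(window), 3L),
                      seq(3L, nchar(window), 3L))
  new_codons <- codons
  mm <- 0L
  # visit codons with the most recoding headroom first
  headroom <- vapply(codons, function(cd) {
    a <- alts[[cd]]
    if (length(a) == 0L) 0L else hamming(a[1], cd)
  }, integer(1))
  for (i in order(-headroom)) {
    if (mm >= min_mismatch) break
    a <- alts[[codons[i]]]
    if (length(a) == 0L) next
    new_codons[i] <- a[1]
    mm <- mm + hamming(a[1], codons[i])
  }
  out <- paste(new_codons, collapse = "")
  if (length(forbidden) > 0L) {
    nL <- nchar(ctx_left)
    native_ctx <- paste0(ctx_left, window, ctx_right)
    new_hits <- function(s) {
      ctx <- paste0(ctx_left, s, ctx_right)
      hits <- integer(0)
      for (fs in forbidden) {
        for (pat in unique(c(fs, revcomp(fs)))) {
          cand <- setdiff(find_all(pat, ctx), find_all(pat, native_ctx))
          # only occurrences overlapping the recoded window can be fixed
          cand <- cand[cand + nchar(pat) > nL & cand < nL + nchar(s)]
          hits <- c(hits, cand)
        }
      }
      sort(hits)
    }
    guard <- 0L
    while (length(h <- new_hits(out)) > 0L && guard < 20L) {
      guard <- guard + 1L
      ci <- max(0L, h[1] - nL) %/% 3L + 1L
      ci <- min(ci, length(codons))
      cur <- substring(out, 3L * ci - 2L, 3L * ci)
      options_ <- setdiff(c(alts[[codons[ci]]], codons[ci]), cur)
      if (length(options_) == 0L) break
      fixed <- FALSE
      for (o in options_) {
        trial <- out
        substr(trial, 3L * ci - 2L, 3L * ci) <- o
        if (length(new_hits(trial)) < length(h)) {
          out <- trial
          fixed <- TRUE
          break
        }
      }
      if (!fixed) break
    }
  }
  list(seq = out, mismatches = hamming(out, window))
}

#' Recode synonymous PCR tags
#'
#' For each verified/uncharacterized ORF long enough for an amplicon in
#' range, chooses two codon-aligned tag windows near the amplicon ends and
#' recodes each by greedy most-different-synonymous-codon substitution
#' until the minimum mismatch count is reached, subject to the Tm window
#' and to creating no forbidden enzyme site. The encoded protein is
#' unchanged. ORFs too short for the amplicon range (or whose first exon
#' cannot host both windows) are skipped and logged; windows with
#' unattainable mismatch or Tm targets are emitted best-effort with a
#' warning flag.
#'
#' @param genome A `GenomeRecord`.
#' @param params A [pcrtag_params()].
#' @param forbidden_sites Enzyme sites the recoded sequence must not
#'   contain.
#' @return `list(edits, pairs, skipped)`: substitute edits in native
#'   coordinates; a `data.frame` of tag pairs (`orf_id`, `tag_index`,
#'   `wt_seq`, `syn_seq`, `tm_wt`, `tm_syn`, `mismatches`, `warn`,
#'   `start`, `end`, `strand`); ids of skipped ORFs.
#' @export
recode_pcrtags <- function(genome, params = pcrtag_params(),
                           forbidden_sites = character(0)) {
  f <- genome$features
  orfs <- f[orf_is_eligible(f, c("Verified", "Uncharacterized")), , drop = FALSE]
  tag_codons <- params$tag_len %/% 3L
  edits <- empty_edits()
  pairs <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    introns <- f[f$kind == "intron" & !is.na(f$parent) & f$parent == orf$id, , drop = FALSE]
    # usable region: first exon in gene orientation (whole ORF if intronless)
    if (nrow(introns) == 0L) {
      region_len <- orf$end - orf$start
      region_gstart <- orf$start
    } else if (orf$strand == "+") {
      region_len <- min(introns$start) - orf$start
      region_gstart <- orf$start
    } else {
      region_len <- orf$end - max(introns$end)
      region_gstart <- max(introns$end)
    }
    usable_codons <- region_len %/% 3L - 1L  # reserve the terminal codon
    if (region_len < params$amplicon_min || usable_codons < 2L * tag_codons + 2L) {
      skipped <- c(skipped, orf$id)
      next
    }
    amp_codons <- min(params$amplicon_max %/% 3L, usable_codons - 1L)
    best <- NULL
    for (c1 in 1:6) {  # shift the amplicon start to satisfy Tm if possible
      ce <- c1 + amp_codons
      if (ce > usable_codons) ce <- usable_codons
      if (ce - c1 < 2L * tag_codons || (ce - c1) * 3L < params$amplicon_min) break
      w1 <- c(c1, c1 + tag_codons)          # codon intervals [a, b)
      w2 <- c(ce - tag_codons, ce)
      cand <- list(w1 = w1, w2 = w2)
      ctx_k <- if (length(forbidden_sites))
        max(nchar(unlist(forbidden_sites))) - 1L else 0L
      tags <- lapply(list(w1, w2), function(w) {
        o1 <- 3L * w[1]; o2 <- 3L * w[2]    # gene-orientation byte offsets
        if (orf$strand == "+") {
          gs <- region_gstart + o1; ge <- region_gstart + o2
          wt <- subseq0(genome$sequence, gs, ge)
          cl <- subseq0(genome$sequence, max(0L, gs - ctx_k), gs)
          cr <- subseq0(genome$sequence, ge, min(genome$length, ge + ctx_k))
        } else {
          gs <- region_gstart + region_len - o2
          ge <- region_gstart + region_len - o1
          wt <- revcomp(subseq0(genome$sequence, gs, ge))
          cl <- revcomp(subseq0(genome$sequence, ge, min(genome$length, ge + ctx_k)))
          cr <- revcomp(subseq0(genome$sequence, max(0L, gs - ctx_k), gs))
        }
        rec <- recode_window(wt, params$min_mismatches, forbidden_sites,
                             ctx_left = cl, ctx_right = cr)
        list(gs = gs, ge = ge, wt = wt, syn = rec$seq, mm = rec$mismatches)
      })
      tm_ok <- all(vapply(tags, function(t) {
        tm_nn(t$syn) >= params$tm_min && tm_nn(t$syn) <= params$tm_max
      }, logical(1)))
      cand$tags <- tags
      cand$tm_ok <- tm_ok
      if (is.null(best) || (tm_ok && !best$tm_ok)) best <- cand
      if (tm_ok) break
    }
    if (is.null(best)) {
      skipped <- c(skipped, orf$id)
      next
    }
    for (k in 1:2) {
      t <- best$tags[[k]]
      payload <- if (orf$strand == "+") t$syn else revcomp(t$syn)
      edits <- rbind(edits, edit_records("substitute", t$gs, t$ge, payload,
                                         "pcrtag_recode",
                                         sprintf("%s_tag%d", orf$id, k)))
      warn_flag <- t$mm < params$min_mismatches || !best$tm_ok
      pairs[[length(pairs) + 1L]] <- data.frame(
        orf_id = orf$id, tag_index = k, wt_seq = t$wt, syn_seq = t$syn,
        tm_wt = tm_nn(t$wt), tm_syn = tm_nn(t$syn),
        mismatches = t$mm, warn = warn_flag,
        start = t$gs, end = t$ge, strand = orf$strand,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(orf_id = character(0), tag_index = integer(0),
               wt_seq = character(0), syn_seq = character(0),
               tm_wt = numeric(0), tm_syn = numeric(0),
               mismatches = integer(0), warn = logical(0),
               start = integer(0), end = integer(0), strand = character(0))
  list(edits = edits, pairs = pairs, skipped = skipped)
}

# Locate one forbidden-site occurrence newly created by the edits and
# return a single-base substitute edit (native coordinates, intergenic)
# that disrupts it, or NULL when none is found / fixable.
find_created_site_fix <- function(genome, designed_seq, ledger, forbidden) {
  if (length(forbidden) == 0L) return(NULL)
  bump <- c(A = "C", C = "G", G = "T", T = "A")
  f <- genome$features
  e <- ledger$edits
  for (fs in forbidden) {
    for (pat in unique(c(fs, revcomp(fs)))) {
      for (q in find_all(pat, designed_seq)) {
        span <- q:(q + nchar(pat) - 1L)
        nat <- vapply(span, function(d) {
          lift_position(ledger, d, "design_to_native")
        }, integer(1))
        pre_existing <- !any(is.na(nat)) &&
          all(diff(nat) == 1L) &&
          subseq0(genome$sequence, nat[1], nat[1] + nchar(pat)) == pat
        if (pre_existing) next
        # pick a disruptable base: mapped to native, intergenic, untouched
        ord <- order(abs(span - (q + nchar(pat) %/% 2L)))
        for (i in ord) {
          p <- nat[i]
          if (is.na(p)) next
          if (any(f$start <= p & p < f$end)) next
          if (any(e$start <= p & p < e$end)) next
          if (any(e$op == "insert" & e$start == p)) next
          base <- subseq0(genome$sequence, p, p + 1L)
          return(edit_records("substitute", p, p + 1L, bump[[base]],
                              "repair", sprintf("scrub %s at design %d",
                                                fs, q)))
        }
        warnf("created %s site at design position %d could not be scrubbed",
              fs, q)
      }
    }
  }
  NULL
}

# ---- whole-design application --------------------------------------------

#' Apply a full design policy to a native chromosome
#'
#' Computes all edit classes in the native frame in canonical order
#' (feature removal, intron removal, stop swap, PCR-tag recoding, loxPsym
#' insertion, telomere caps), merges them into one non-overlapping ledger,
#' applies it once, and lifts the annotations into the designed frame
#' (removed features are dropped; loxPsym, PCR-tag and cap features are
#' added). Overlapping edits from different rationales are a hard error,
#' except a stop-swap/PCR-tag collision, where the stop swap wins and the
#' tag edit is dropped with a warning.
#'
#' @param genome A native `GenomeRecord`.
#' @param policy A `DesignPolicy`.
#' @return A list of class `DesignResult`: `genome` (designed
#'   `GenomeRecord`), `ledger` (`DesignLedger`), `summary` (named list of
#'   counts and size accounting), `pcrtags` (tag-pair table), `skipped`
#'   (loxPsym + tag skip log).
#' @export
apply_design <- function(genome, policy = design_policy()) {
  rem <- remove_features(genome, policy$remove_kinds)
  intr <- remove_introns(genome, policy$intron_retain_ids)
  stops <- swap_stop_codons(genome, policy)
  tags <- if (is.null(policy$pcrtag)) {
    list(edits = empty_edits(),
         pairs = data.frame(orf_id = character(0), tag_index = integer(0),
                            wt_seq = character(0), syn_seq = character(0),
                            tm_wt = numeric(0), tm_syn = numeric(0),
                            mismatches = integer(0), warn = logical(0),
                            start = integer(0), end = integer(0),
                            strand = character(0)),
         skipped = character(0))
  } else recode_pcrtags(genome, policy$pcrtag, policy$forbidden_sites)
  lox <- insert_loxpsym_sites(genome, policy)
  caps <- if (is.null(policy$telomere_cap)) empty_edits() else
    cap_telomeres(genome, policy$telomere_cap)

  all_edits <- rbind(rem, intr, stops, tags$edits, lox, caps)
  all_edits <- all_edits[order(all_edits$start, all_edits$end), , drop = FALSE]
  # collision resolution: stop swap beats pcrtag; anything else is fatal
  if (nrow(all_edits) > 1L) {
    repeat {
      ov <- which(all_edits$start[-1L] < all_edits$end[-nrow(all_edits)])
      if (length(ov) == 0L) break
      i <- ov[1]
      r1 <- all_edits$rationale[i]; r2 <- all_edits$rationale[i + 1L]
      if (setequal(c(r1, r2), c("stop_swap", "pcrtag_recode"))) {
        drop_i <- if (r1 == "pcrtag_recode") i else i + 1L
        warnf("PCR-tag edit '%s' overlaps a stop swap; tag dropped",
              all_edits$note[drop_i])
        all_edits <- all_edits[-drop_i, , drop = FALSE]
      } else {
        stopf("edit collision between rationales %s and %s at native %d",
              r1, r2, all_edits$start[i + 1L])
      }
    }
  }
  # edit junctions (notably deletions) can assemble a forbidden enzyme
  # site from previously separated flanks; scrub each such site with a
  # single-base intergenic substitution recorded as a repair edit
  guard <- 0L
  repeat {
    ledger <- design_ledger(genome$id, paste0("syn_", genome$id), all_edits,
                            genome$length)
    designed_seq <- apply_ledger(genome$sequence, ledger)
    fix <- find_created_site_fix(genome, designed_seq, ledger,
                                 policy$forbidden_sites)
    guard <- guard + 1L
    if (is.null(fix) || guard > 10L) break
    all_edits <- rbind(all_edits, fix)
    all_edits <- all_edits[order(all_edits$start, all_edits$end), , drop = FALSE]
  }

  # lift annotations
  f <- genome$features
  drop <- f$kind %in% policy$remove_kinds |
    (f$kind == "intron" & !(f$id %in% policy$intron_retain_ids)) |
    (f$kind == "telomere" & !is.null(policy$telomere_cap))
  keep <- f[!drop, , drop = FALSE]
  ivs <- lapply(seq_len(nrow(keep)), function(i) {
    lift_interval(ledger, keep$start[i], keep$end[i])
  })
  ok <- !vapply(ivs, is.null, logical(1))
  keep <- keep[ok, , drop = FALSE]
  keep$start <- vapply(ivs[ok], `[`, integer(1), 1L)
  keep$end <- vapply(ivs[ok], `[`, integer(1), 2L)
  e <- ledger$edits
  orf_strand <- setNames(f$strand, f$id)
  from_edit <- function(rows, kind, ids, strands) {
    if (length(rows) == 0L) return(empty_features())
    dpos <- vapply(rows, function(j) lift_position(ledger, e$end[j]), integer(1))
    features(ids, kind, dpos - nchar(e$payload[rows]), dpos, strands)
  }
  lox_rows <- which(e$rationale == "loxpsym")
  tag_rows <- which(e$rationale == "pcrtag_recode")
  cap_rows <- which(e$rationale == "telomere_cap")
  new_feats <- rbind(
    keep,
    from_edit(lox_rows, "loxpsym", paste0("loxpsym_", e$note[lox_rows]),
              unname(orf_strand[e$note[lox_rows]])),
    from_edit(cap_rows, "telomere", e$note[cap_rows], "+"),
    from_edit(tag_rows, "pcrtag", e$note[tag_rows],
              unname(orf_strand[sub("_tag[12]$", "", e$note[tag_rows])])))

  designed <- genome_record(ledger$target_id, designed_seq, new_feats)
  # "pairs" = wt/syn tag pairs (one per recoded window); "sequences" counts
  # every tag sequence, wild-type and synthetic alike
  n_pairs <- nrow(tags$pairs)
  summary <- list(
    loxpsym_inserted = length(lox_rows),
    loxpsym_skipped = length(attr(lox, "skipped")),
    introns_removed = nrow(intr),
    introns_retained = sum(f$kind == "intron") - nrow(intr),
    stop_swaps = nrow(stops),
    features_removed = nrow(rem),
    telomeres_capped = nrow(caps),
    pcrtag_pairs = n_pairs,
    pcrtag_sequences = 2L * n_pairs,
    source_len = ledger$source_len,
    target_len = ledger$target_len,
    net_delta = ledger$net_delta,
    percent_reduction = design_size_reduction(ledger$source_len, ledger$target_len))
  structure(list(genome = designed, ledger = ledger, summary = summary,
                 pcrtags = tags$pairs,
                 skipped = list(loxpsym = attr(lox, "skipped"),
                                pcrtag = tags$skipped)),
            class = "DesignResult")
}

#' Percent size reduction of a design
#'
#' Relative size reduction of the designed chromosome versus the native
#' one, as a percentage rounded to the nearest integer (e.g. 784,333 bp
#' native and 753,097 bp designed give 4).
#'
#' @param native_len,designed_len Lengths in bases.
#' @return Integer percent reduction.
#' @export
design_size_reduction <- function(native_len, designed_len) {
  round(100 * (native_len - designed_len) / native_len)
}

#' Verify a design against its ledger
#'
#' Structural audit of a designed chromosome: the ledger reproduces the
#' designed sequence bit-exactly from the native one; every verified or
#' uncharacterized ORF retained in the design encodes the native protein;
#' the loxPsym count equals the eligible-ORF count minus logged skips; no
#' targeted ORF still ends in a swappable stop; no forbidden enzyme site
#' was created by the edits.
#'
#' @param native,designed `GenomeRecord`s.
#' @param ledger The connecting `DesignLedger`.
#' @param policy The `DesignPolicy` used (defaults checked otherwise).
#' @return A list of class `DesignReport`: `pass` (logical) and `checks`
#'   (`data.frame` of per-check outcomes).
#' @export
verify_design <- function(native, designed, ledger, policy = design_policy()) {
  checks <- list()
  note <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  note("ledger_reproduces_design",
       identical(apply_ledger(native$sequence, ledger), designed$sequence))

  nf <- native$features
  df <- designed$features
  orfs <- nf[orf_is_eligible(nf, c("Verified", "Uncharacterized")), , drop = FALSE]
  bad <- character(0)
  for (i in seq_len(nrow(orfs))) {
    if (!(orfs$id[i] %in% df$id)) next
    p_nat <- translate_orf(native, orfs$id[i])
    p_des <- translate_orf(designed, orfs$id[i])
    if (!identical(p_nat, p_des)) bad <- c(bad, orfs$id[i])
  }
  note("protein_conservation", length(bad) == 0L, paste(bad, collapse = ","))

  eligible <- sum(orf_is_eligible(nf, policy$loxpsym_targets) & nf$essential == "no",
                  na.rm = TRUE)
  n_lox <- sum(df$kind == "loxpsym")
  n_skip <- sum(ledger$edits$rationale == "loxpsym") - n_lox  # should be 0
  note("loxpsym_count", n_lox + (eligible - sum(ledger$edits$rationale == "loxpsym")) == eligible,
       sprintf("%d sites for %d eligible ORFs", n_lox, eligible))

  swappable <- names(policy$stop_swap)
  residual <- character(0)
  for (i in which(orf_is_eligible(df, c("Verified", "Uncharacterized")))) {
    stop_codon <- if (df$strand[i] == "+") {
      subseq0(designed$sequence, df$end[i] - 3L, df$end[i])
    } else revcomp(subseq0(designed$sequence, df$start[i], df$start[i] + 3L))
    if (stop_codon %in% swappable) residual <- c(residual, df$id[i])
  }
  note("no_swappable_stops_remain", length(residual) == 0L,
       paste(residual, collapse = ","))

  created <- character(0)
  for (k in seq_along(policy$forbidden_sites)) {
    fs <- policy$forbidden_sites[[k]]
    n_nat <- length(find_all(fs, native$sequence)) +
      length(find_all(revcomp(fs), native$sequence))
    n_des <- length(find_all(fs, designed$sequence)) +
      length(find_all(revcomp(fs), designed$sequence))
    if (n_des > n_nat) created <- c(created, names(policy$forbidden_sites)[k] %||% fs)
  }
  note("no_forbidden_sites_created", length(created) == 0L,
       paste(created, collapse = ","))

  checks <- do.call(rbind, checks)
  structure(list(pass = all(checks$pass), checks = checks),
            class = "DesignReport")
}

#' @export
print.DesignReport <- function(x, ...) {
  cat(sprintf("Design verification: %s\n", if (x$pass) "PASS" else "FAIL"))
  print(x$checks)
  invisible(x)
}

#' @export
print.DesignResult <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Design %s: %d -> %d bp (%+d, %d%% reduction)\n",
              x$genome$id, s$source_len, s$target_len, s$net_delta,
              s$percent_reduction))
  cat(sprintf("  loxPsym %d (+%d skipped), introns removed %d (retained %d),\n",
              s$loxpsym_inserted, s$loxpsym_skipped, s$introns_removed,
              s$introns_retained))
  cat(sprintf("  stop swaps %d, removals %d, PCR-tag pairs %d (%d sequences)\n",
              s$stop_swaps, s$features_removed, s$pcrtag_pairs,
              s$pcrtag_sequences))
  invisible(x)
}
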