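# Relocated tRNA-array design: heterologous flanks assigned preferentially
# by anticodon, 5' flank artefact scrubbing, intron excision and rox-site
# interleaving.

# 32-bp rox recombination site (Dre recombinase), palindromic arms.
ROX_SEQ <- "TAACTTTAAATAATGCCAATTATTTAAAGTTA"

# anticodon -> decoded amino acid (the codon is the reverse complement)
anticodon_aa <- function(anticodon) {
  translate_codons(revcomp(toupper(anticodon)))
}

#' Assign heterologous flanks to tRNA genes
#'
#' Stable greedy matching of tRNA genes to donor flank-pool entries:
#' exact anticodon match first, then any entry whose source anticodon
#' decodes the same amino acid, then any unused entry. tRNAs are visited
#' in lexicographic id order; within a tier, pool entries are taken in
#' table order. Each pool entry is used at most once.
#'
#' @param trnas `data.frame` (`id`, `anticodon`, `sequence`, optional
#'   `intron_start`, `intron_end` as 0-based offsets into `sequence`).
#' @param pool `data.frame` (`entry_id`, `donor_species`,
#'   `source_anticodon`, `five_prime_seq`, `three_prime_seq`).
#' @return `data.frame` (`trna_id`, `entry_id`, `match_tier` in
#'   `anticodon`/`amino_acid`/`any`).
#' @export
assign_flanks <- function(trnas, pool) {
  if (nrow(pool) < nrow(trnas)) {
    stopf("flank pool exhausted: %d entries for %d tRNAs", nrow(pool), nrow(trnas))
  }
  used <- rep(FALSE, nrow(pool))
  pool_ac <- toupper(pool$source_anticodon)
  pool_aa <- anticodon_aa(pool$source_anticodon)
  order_ids <- sort(trnas$id)
  trna_ac <- setNames(toupper(trnas$anticodon), trnas$id)
  out <- list()
  for (k in seq_along(order_ids)) {
    id <- order_ids[k]
    ac <- trna_ac[[id]]
    remaining <- trna_ac[order_ids[-seq_len(k)]]
    # fallback tiers must not consume an entry a later tRNA needs for an
    # exact anticodon match, unless that anticodon is in surplus supply
    safe_first <- function(cand) {
      if (length(cand) <= 1L) return(cand)
      safe <- vapply(cand, function(j) {
        x <- pool_ac[j]
        sum(!used & pool_ac == x) > sum(remaining == x)
      }, logical(1))
      c(cand[safe], cand[!safe])
    }
    cand <- which(!used & pool_ac == ac)
    tier <- "anticodon"
    if (length(cand) == 0L) {
      cand <- safe_first(which(!used & pool_aa == anticodon_aa(ac)))
      tier <- "amino_acid"
    }
    if (length(cand) == 0L) {
      cand <- safe_first(which(!used))
      tier <- "any"
    }
    if (length(cand) == 0L) stopf("flank pool exhausted at tRNA '%s'", id)
    used[cand[1]] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      trna_id = id, entry_id = pool$entry_id[cand[1]], match_tier = tier,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Scrub unwanted motifs from a flank sequence
#'
#' Disrupts every occurrence of each motif (e.g. transcriptional start
#' artefacts) with a single-base substitution at the occurrence's central
#' position, preserving length. Rescans after each substitution until the
#' sequence is motif-free.
#'
#' @param five_prime_seq Flank sequence.
#' @param motif_list Character vector of exact motifs.
#' @return The scrubbed sequence (attribute `scrubbed` reports whether
#'   any substitution was made).
#' @export
scrub_flank <- function(five_prime_seq, motif_list) {
  s <- toupper(five_prime_seq)
  touched <- FALSE
  # cyclic base replacement guarantees the central base always changes
  bump <- c(A = "C", C = "G", G = "T", T = "A")
  for (motif in toupper(motif_list)) {
    guard <- 0L
    repeat {
      hits <- find_all(motif, s)
      if (length(hits) == 0L) break
      guard <- guard + 1L
      if (guard > nchar(s)) stopf("motif scrubbing failed to converge")
      center <- hits[1] + nchar(motif) %/% 2L  # 0-based
      old <- substr(s, center + 1L, center + 1L)
      substr(s, center + 1L, center + 1L) <- bump[[old]]
      touched <- TRUE
    }
  }
  attr(s, "scrubbed") <- touched
  s
}

#' Build a relocated tRNA array
#'
#' Concatenates, per assigned tRNA: rox site, 500-base 5' flank,
#' intron-less tRNA gene, 40-base 3' flank -- plus a terminal rox site, so
#' `n` genes yield `n + 1` rox features. tRNA introns are excised; flanks
#' are scrubbed of the motif list before assembly. All parts are annotated
#' as features of the returned record.
#'
#' @param trnas tRNA table (see [assign_flanks()]).
#' @param pool Flank pool table.
#' @param assignment Output of [assign_flanks()] (computed if `NULL`).
#' @param rox_seq rox recombination site sequence.
#' @param scrub_motifs Motifs removed from 5' flanks.
#' @param array_id Identifier of the emitted record.
#' @return A `GenomeRecord` of the assembled array (`rox`, `motif` flank
#'   and `tRNA` features), with the assignment table as attribute
#'   `assignment`.
#' @export
build_trna_array <- function(trnas, pool, assignment = NULL,
                             rox_seq = ROX_SEQ,
                             scrub_motifs = c("TATATAA", "CCCCCC"),
                             array_id = "trna_array") {
  if (is.null(assignment)) assignment <- assign_flanks(trnas, pool)
  pieces <- character(0)
  feats <- empty_features()
  pos <- 0L
  add <- function(s, id = NULL, kind = NULL, strand = "+", anticodon = NA_character_) {
    pieces[[length(pieces) + 1L]] <<- s
    if (!is.null(id)) {
      feats <<- rbind(feats, features(id, kind, pos, pos + nchar(s), strand,
                                      anticodon = anticodon))
    }
    pos <<- pos + nchar(s)
  }
  add(rox_seq, "rox_0", "rox")
  for (i in seq_len(nrow(assignment))) {
    a <- assignment[i, ]
    t <- trnas[trnas$id == a$trna_id, , drop = FALSE]
    p <- pool[pool$entry_id == a$entry_id, , drop = FALSE]
    five <- scrub_flank(p$five_prime_seq, scrub_motifs)
    mature <- toupper(t$sequence)
    if (!is.null(t$intron_start) && !is.na(t$intron_start)) {
      mature <- paste0(substr(mature, 1L, t$intron_start),
                       substr(mature, t$intron_end + 1L, nchar(mature)))
    }
    add(as.character(five), paste0(a$trna_id, "_5p"), "motif")
    add(mature, a$trna_id, "tRNA", anticodon = toupper(t$anticodon))
    add(p$three_prime_seq, paste0(a$trna_id, "_3p"), "motif")
    add(rox_seq, sprintf("rox_%d", i), "rox")
  }
  g <- genome_record(array_id, paste(pieces, collapse = ""), feats)
  attr(g, "assignment") <- assignment
  g
}

#' Read / write tRNA and flank-pool tables
#'
#' TSV round-trip helpers for the array designer's inputs.
#'
#' @param path TSV path.
#' @return A `data.frame`.
#' @export
read_trna_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_trna_table
#' @export
read_flank_pool <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
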