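# Sequencing-based debugging: pooled fast/slow defect localization,
# relative-depth copy number, discrepancy classification and
# proximity-bundled repair planning.

#' Localize growth-defect loci from pooled coverage
#'
#' Each pool's depth track is normalized by its own median; the per-window
#' score is log2(fast/slow), computed separately over the synthetic-allele
#' and wild-type-allele partitions of the hybrid reference. Maximal runs
#' of at least `min_run` windows scoring at or below `log2_threshold` are
#' reported as candidates. Reciprocal logic is cross-checked: a synthetic
#' region depleted in the fast pool should have its homologous wild-type
#' windows depleted in the slow pool (i.e. elevated fast/slow score), and
#' vice versa; `reciprocal_support` records whether the homologous
#' partition's mean score exceeds `-log2_threshold`.
#'
#' @param fast_track,slow_track Coverage tracks (`contig`, `start`, `end`,
#'   `depth`, `partition`) tiling the same coordinate space.
#' @param min_run Minimum run length, windows.
#' @param log2_threshold Depletion threshold on log2(fast/slow).
#' @param chunk_plan Optional completed `ChunkPlan`; candidates gain the
#'   overlapped megachunk labels.
#' @return `data.frame` of candidate intervals (`partition`, `start`,
#'   `end`, `n_windows`, `mean_score`, `reciprocal_support`,
#'   `megachunks`); zero rows when the pools are indistinguishable.
#' @export
localize_defect <- function(fast_track, slow_track, min_run = 3L,
                            log2_threshold = -1, chunk_plan = NULL) {
  key <- function(t) paste(t$partition, t$start)
  if (!identical(sort(key(fast_track)), sort(key(slow_track)))) {
    stopf("fast and slow tracks must tile the same windows and partitions")
  }
  fast_track <- fast_track[order(fast_track$partition, fast_track$start), ]
  slow_track <- slow_track[order(slow_track$partition, slow_track$start), ]
  mf <- median(fast_track$depth)
  ms <- median(slow_track$depth)
  if (mf <= 0 || ms <= 0) stopf("zero-median track cannot be normalized")
  score <- log2((fast_track$depth / mf) / (slow_track$depth / ms))

  cands <- list()
  for (part in unique(fast_track$partition)) {
    sel <- fast_track$partition == part
    sc <- score[sel]
    st <- fast_track$start[sel]; en <- fast_track$end[sel]
    low <- !is.nan(sc) & sc <= log2_threshold
    r <- rle(low)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_run)) {
      i1 <- idx_start[j]; i2 <- idx_end[j]
      other <- setdiff(c("SYN_allele", "WT_allele"), part)
      recip <- NA
      if (length(other) == 1L && any(fast_track$partition == other)) {
        osel <- fast_track$partition == other
        osc <- score[osel]
        ost <- fast_track$start[osel]
        hom <- ost >= st[i1] & ost < en[i2]
        recip <- any(hom) && mean(osc[hom], na.rm = TRUE) >= -log2_threshold
      }
      cands[[length(cands) + 1L]] <- data.frame(
        partition = part, start = st[i1], end = en[i2],
        n_windows = i2 - i1 + 1L,
        mean_score = if (any(is.finite(sc[i1:i2])))
          mean(sc[i1:i2][is.finite(sc[i1:i2])]) else -Inf,
        reciprocal_support = recip, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(cands)) do.call(rbind, cands) else
    data.frame(partition = character(0), start = integer(0), end = integer(0),
               n_windows = integer(0), mean_score = numeric(0),
               reciprocal_support = logical(0))
  out$megachunks <- rep(NA_character_, nrow(out))
  if (!is.null(chunk_plan) && !is.null(chunk_plan$megachunks) && nrow(out) > 0L) {
    mk <- chunk_plan$megachunks
    out$megachunks <- vapply(seq_len(nrow(out)), function(i) {
      hit <- mk$label[mk$start < out$end[i] & out$start[i] < mk$end]
      if (length(hit)) paste0(hit[1], "-", hit[length(hit)]) else NA_character_
    }, character(1))
  }
  out
}

#' Estimate copy number from relative depth
#'
#' Copy number of a target interval relative to baseline intervals of
#' known copy count: `baseline_copies * mean(target depth) /
#' mean(baseline depth)`, with a bootstrap confidence interval over
#' windows.
#'
#' @param track Coverage track (`start`, `end`, `depth`).
#' @param target_start,target_end Target interval (0-based half-open).
#' @param baseline_intervals Two-column matrix / data.frame of baseline
#'   intervals.
#' @param baseline_copies Copy count of the baseline (default 1).
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @return List: `copies`, `ci` (length 2), `n_target`, `n_baseline`.
#' @export
estimate_copy_number <- function(track, target_start, target_end,
                                 baseline_intervals, baseline_copies = 1,
                                 n_boot = 1000L, conf = 0.95) {
  baseline_intervals <- as.matrix(baseline_intervals)
  in_iv <- function(s, e) track$start >= s & track$end <= e
  tgt <- track$depth[in_iv(target_start, target_end)]
  base <- track$depth[Reduce(`|`, lapply(seq_len(nrow(baseline_intervals)),
                                         function(i) in_iv(baseline_intervals[i, 1],
                                                           baseline_intervals[i, 2])))]
  if (length(tgt) == 0L || length(base) == 0L) {
    stopf("empty target or baseline interval")
  }
  if (mean(base) <= 0) stopf("baseline depth must be positive")
  copies <- baseline_copies * mean(tgt) / mean(base)
  boots <- vapply(seq_len(n_boot), function(i) {
    baseline_copies * mean(sample(tgt, replace = TRUE)) /
      mean(sample(base, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(copies = copies,
       ci = unname(quantile(boots, c(alpha, 1 - alpha))),
       n_target = length(tgt), n_baseline = length(base))
}

DISCREPANCY_SEVERITY <- c(residual_TAG_stop = "critical",
                          nonsynonymous = "critical",
                          duplication = "critical",
                          missing_loxpsym = "noncritical",
                          missing_pcrtag = "noncritical",
                          missing_restriction_site = "noncritical",
                          synonymous_other = "noncritical")

#' Read a minimal VCF of observed variants
#'
#' Supports the minimal dialect used for discrepancy calling: `CHROM`,
#' `POS` (1-based), `REF`, `ALT` with literal alleles, plus symbolic
#' `<DEL>`/`<DUP>` alleles carrying `END=` in INFO.
#'
#' @param path VCF file.
#' @return `data.frame` (`chrom`, `pos` 0-based, `ref`, `alt`, `end`).
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      end = integer(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(parts, `[[`, character(1), i)
  info <- vapply(parts, function(p) if (length(p) >= 8L) p[[8]] else ".",
                 character(1))
  end <- suppressWarnings(as.integer(sub(".*END=([0-9]+).*", "\\1", info)))
  alt <- get(5)
  pos0 <- as.integer(get(2)) - 1L
  # VCF END is 1-based inclusive, which equals the 0-based half-open end
  data.frame(chrom = get(1), pos = pos0, ref = get(4), alt = alt,
             end = ifelse(alt %in% c("<DEL>", "<DUP>"), end, NA_integer_),
             stringsAsFactors = FALSE)
}

#' Write observed variants as minimal VCF
#'
#' @param variants `data.frame` as returned by [read_variants_vcf()].
#' @param path Output VCF path.
#' @return Invisibly, `path`.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of symbolic allele\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vapply(seq_len(nrow(variants)), function(i) {
    info <- if (!is.na(variants$end[i])) sprintf("END=%d", variants$end[i]) else "."
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", variants$chrom[i],
            variants$pos[i] + 1L, variants$ref[i], variants$alt[i], info)
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# apply one substitution-type variant to a coding window and re-translate
variant_changes_protein <- function(designed, orf, vpos, ref, alt) {
  cds_des <- orf_coding_seq(designed, orf$id)
  seq_mut <- designed$sequence
  substr(seq_mut, vpos + 1L, vpos + nchar(ref)) <- alt
  mut <- designed
  mut$sequence <- seq_mut
  cds_mut <- orf_coding_seq(mut, orf$id)
  aa_des <- as.character(Biostrings::translate(Biostrings::DNAString(cds_des),
                                               if.fuzzy.codon = "solve"))
  aa_mut <- as.character(Biostrings::translate(Biostrings::DNAString(cds_mut),
                                               if.fuzzy.codon = "solve"))
  !identical(aa_des, aa_mut)
}

#' Classify design-versus-observed discrepancies
#'
#' Maps each observed variant (design coordinates) to one discrepancy
#' class with a fixed severity: a stop codon reading TAG where the design
#' says TAA in a verified/uncharacterized ORF is a residual TAG stop
#' (critical); protein-changing variants in such ORFs are nonsynonymous
#' (critical); symbolic duplications are critical; deletions covering a
#' loxPsym feature, variants reverting a PCR-tag window toward wild type,
#' and junction-site losses are noncritical; anything else synonymous or
#' intergenic is `synonymous_other` (noncritical). Every variant receives
#' exactly one class (first matching rule).
#'
#' @param designed Designed `GenomeRecord` (with `loxpsym` and `pcrtag`
#'   features).
#' @param variants Variant `data.frame` (`pos` 0-based, `ref`, `alt`,
#'   `end` for symbolic alleles).
#' @param junction_sites Optional `data.frame` (`pos`, `site`) of chunk
#'   junction positions in design coordinates.
#' @return `data.frame` (`pos`, `class`, `severity`, `detail`).
#' @export
classify_discrepancies <- function(designed, variants,
                                   junction_sites = NULL) {
  f <- designed$features
  orfs <- f[orf_is_eligible(f, c("Verified", "Uncharacterized")), , drop = FALSE]
  lox <- f[f$kind == "loxpsym", , drop = FALSE]
  tags <- f[f$kind == "pcrtag", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$pos < 0L || v$pos >= designed$length) {
      stopf("variant at %d outside the chromosome", v$pos)
    }
    vend <- if (!is.na(v$end)) v$end else v$pos + nchar(v$ref)
    cls <- NULL; detail <- ""
    if (identical(v$alt, "<DUP>")) {
      cls <- "duplication"
      detail <- sprintf("[%d,%d) gained", v$pos, vend)
    } else if (identical(v$alt, "<DEL>") || nchar(v$alt) < nchar(v$ref)) {
      covered_lox <- lox$id[lox$start >= v$pos & lox$end <= vend]
      if (length(covered_lox) > 0L) {
        cls <- "missing_loxpsym"
        detail <- paste(covered_lox, collapse = ",")
      } else {
        cls <- "synonymous_other"
        detail <- "deletion outside annotated design elements"
      }
    } else {
      host <- orfs[orfs$start <= v$pos & v$pos < orfs$end, , drop = FALSE]
      in_tag <- tags[tags$start <= v$pos & v$pos < tags$end, , drop = FALSE]
      if (nrow(host) > 0L) {
        orf <- host[1, ]
        stop_iv <- if (orf$strand == "+") c(orf$end - 3L, orf$end) else
          c(orf$start, orf$start + 3L)
        in_stop <- v$pos >= stop_iv[1] && v$pos < stop_iv[2]
        if (in_stop) {
          seq_mut <- designed$sequence
          substr(seq_mut, v$pos + 1L, v$pos + nchar(v$ref)) <- v$alt
          obs_stop <- if (orf$strand == "+")
            substr(seq_mut, stop_iv[1] + 1L, stop_iv[2]) else
            revcomp(substr(seq_mut, stop_iv[1] + 1L, stop_iv[2]))
          if (obs_stop == "TAG") {
            cls <- "residual_TAG_stop"
            detail <- orf$id
          }
        }
        if (is.null(cls)) {
          changes <- variant_changes_protein(designed, orf, v$pos, v$ref, v$alt)
          if (changes) {
            cls <- "nonsynonymous"
            detail <- orf$id
          } else if (nrow(in_tag) > 0L) {
            cls <- "missing_pcrtag"
            detail <- in_tag$id[1]
          }
        }
      }
      if (is.null(cls) && !is.null(junction_sites)) {
        for (j in seq_len(nrow(junction_sites))) {
          js <- junction_sites$pos[j]
          jl <- nchar(junction_sites$site[j])
          if (v$pos >= js && v$pos < js + jl) {
            cls <- "missing_restriction_site"
            detail <- junction_sites$site[j]
            break
          }
        }
      }
      if (is.null(cls)) {
        cls <- "synonymous_other"
        detail <- if (nrow(host) > 0L) host$id[1] else "intergenic"
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      pos = v$pos, class = cls,
      severity = unname(DISCREPANCY_SEVERITY[cls]),
      detail = detail, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(pos = integer(0), class = character(0),
               severity = character(0), detail = character(0))
}

#' Plan repairs with proximity bundling
#'
#' All critical discrepancies are scheduled; each noncritical record
#' within `bundle_distance` of a scheduled critical record rides along in
#' that repair (it is worth fixing while the locus is being edited
#' anyway); remaining noncritical records are deferred. The plan is
#' ordered by coordinate and independent of input order.
#'
#' @param records Discrepancy table from [classify_discrepancies()].
#' @param bundle_distance Bundling radius in bases.
#' @return List: `schedule` (`data.frame`: `repair_id`, `pos`, `class`,
#'   `bundled` comma-list of bundled noncritical positions) and `deferred`
#'   (noncritical records left out).
#' @export
plan_repairs <- function(records, bundle_distance = 5000L) {
  records <- records[order(records$pos, records$class), , drop = FALSE]
  crit <- records[records$severity == "critical", , drop = FALSE]
  noncrit <- records[records$severity == "noncritical", , drop = FALSE]
  if (nrow(crit) == 0L) {
    return(list(schedule = data.frame(repair_id = character(0), pos = integer(0),
                                      class = character(0), bundled = character(0)),
                deferred = noncrit))
  }
  bundled_to <- vapply(noncrit$pos, function(p) {
    d <- abs(crit$pos - p)
    if (min(d) <= bundle_distance) which.min(d) else NA_integer_
  }, integer(1))
  schedule <- data.frame(
    repair_id = sprintf("R%03d", seq_len(nrow(crit))),
    pos = crit$pos, class = crit$class,
    bundled = vapply(seq_len(nrow(crit)), function(i) {
      b <- noncrit$pos[!is.na(bundled_to) & bundled_to == i]
      paste(b, collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  list(schedule = schedule,
       deferred = noncrit[is.na(bundled_to), , drop = FALSE])
}

#' Write / read a coverage track
#'
#' Coverage tracks travel as TSV with the partition column; plain
#' four-column bedGraph export/import (per partition) is available via
#' [rtracklayer::export()] on the returned frame if needed.
#'
#' @param track Coverage track `data.frame`.
#' @param path TSV path.
#' @return `write_coverage_track`: `path` invisibly;
#'   `read_coverage_track`: the track.
#' @export
write_coverage_track <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage_track
#' @export
read_coverage_track <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
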