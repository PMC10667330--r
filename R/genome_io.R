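#' @importFrom utils head tail read.delim write.table
#' @importFrom stats rnorm rpois runif median quantile setNames
NULL

FEATURE_KINDS <- c("ORF", "intron", "tRNA", "transposon", "telomere",
                   "centromere", "loxpsym", "rox", "pcrtag", "marker", "motif")

FEATURE_COLS <- c("id", "kind", "start", "end", "strand", "parent",
                  "essential", "orf_class", "anticodon", "retain_intron")

#' Empty feature table
#'
#' Returns a zero-row feature table with the canonical column schema used by
#' [genome_record()]: `id`, `kind`, `start`, `end` (0-based half-open),
#' `strand`, `parent`, `essential`, `orf_class`, `anticodon`,
#' `retain_intron`.
#'
#' @return A zero-row `data.frame`.
#' @export
empty_features <- function() {
  data.frame(id = character(0), kind = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             parent = character(0), essential = character(0),
             orf_class = character(0), anticodon = character(0),
             retain_intron = logical(0), stringsAsFactors = FALSE)
}

#' Construct a feature table
#'
#' Convenience constructor filling optional attribute columns with `NA`.
#'
#' @param id Feature identifiers.
#' @param kind Feature kind (one of `"ORF"`, `"intron"`, `"tRNA"`,
#'   `"transposon"`, `"telomere"`, `"centromere"`, `"loxpsym"`, `"rox"`,
#'   `"pcrtag"`, `"marker"`, `"motif"`).
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @param parent Parent feature id (introns point at their ORF).
#' @param essential `"yes"`/`"no"` (ORFs).
#' @param orf_class `"Verified"`, `"Uncharacterized"` or `"Dubious"`.
#' @param anticodon tRNA anticodon.
#' @param retain_intron Logical; intron flagged for retention in a design.
#' @return A `data.frame` with the canonical feature columns.
#' @export
features <- function(id, kind, start, end, strand = "+", parent = NA_character_,
                     essential = NA_character_, orf_class = NA_character_,
                     anticodon = NA_character_, retain_intron = NA) {
  data.frame(id = as.character(id), kind = as.character(kind),
             start = as.integer(start), end = as.integer(end),
             strand = strand, parent = parent, essential = essential,
             orf_class = orf_class, anticodon = anticodon,
             retain_intron = as.logical(retain_intron),
             stringsAsFactors = FALSE)
}

#' Create a genome record
#'
#' A `GenomeRecord` bundles a chromosome sequence with its typed, stranded
#' feature annotations. Coordinates are 0-based half-open throughout the
#' package; GFF3 conversion happens only at I/O boundaries.
#'
#' @param id Chromosome identifier.
#' @param sequence DNA string over `A`,`C`,`G`,`T` (lowercase is uppercased;
#'   other characters are rejected).
#' @param feats Feature table (see [features()]); sorted by `start` on
#'   construction.
#' @return An object of class `GenomeRecord`.
#' @export
genome_record <- function(id, sequence, feats = empty_features()) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stopf("genome '%s': sequence contains non-ACGT characters", id)
  }
  missing_cols <- setdiff(FEATURE_COLS, names(feats))
  for (col in missing_cols) {
    feats[[col]] <- if (col == "retain_intron") NA else NA_character_
  }
  feats <- feats[order(feats$start, feats$end), FEATURE_COLS, drop = FALSE]
  rownames(feats) <- NULL
  g <- structure(list(id = id, sequence = sequence,
                      features = feats, length = nchar(sequence)),
                 class = "GenomeRecord")
  validate_genome(g)
  g
}

#' Validate a genome record
#'
#' Checks the `GenomeRecord` invariants: feature intervals within
#' `[0, length)`, `start < end`, introns nested in their parent ORFs, ORF
#' lengths divisible by 3 after intron excision, tRNAs carrying an
#' anticodon.
#'
#' @param g A `GenomeRecord`.
#' @return `g`, invisibly; errors on violation.
#' @export
validate_genome <- function(g) {
  f <- g$features
  if (nrow(f) == 0L) return(invisible(g))
  if (any(f$start < 0L) || any(f$end > g$length)) {
    stopf("genome '%s': feature interval outside [0, %d)", g$id, g$length)
  }
  if (any(f$start >= f$end)) stopf("genome '%s': empty or inverted feature interval", g$id)
  if (!all(f$strand %in% c("+", "-"))) stopf("genome '%s': strand must be '+' or '-'", g$id)
  introns <- f[f$kind == "intron", , drop = FALSE]
  if (nrow(introns) > 0L) {
    for (i in seq_len(nrow(introns))) {
      p <- f[f$id == introns$parent[i] & f$kind == "ORF", , drop = FALSE]
      if (nrow(p) != 1L || introns$start[i] < p$start || introns$end[i] > p$end) {
        stopf("intron '%s' is not nested inside its parent ORF", introns$id[i])
      }
    }
  }
  orfs <- f[f$kind == "ORF", , drop = FALSE]
  for (i in seq_len(nrow(orfs))) {
    ilen <- sum(pmax(0L, introns$end[introns$parent == orfs$id[i]] -
                       introns$start[introns$parent == orfs$id[i]]))
    if ((orfs$end[i] - orfs$start[i] - ilen) %% 3L != 0L) {
      stopf("ORF '%s': length not divisible by 3 after intron excision", orfs$id[i])
    }
  }
  trnas <- f[f$kind == "tRNA", , drop = FALSE]
  if (nrow(trnas) > 0L && any(is.na(trnas$anticodon))) {
    stopf("genome '%s': tRNA feature without anticodon", g$id)
  }
  invisible(g)
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord '%s': %d bp, %d features\n",
              x$id, x$length, nrow(x$features)))
  if (nrow(x$features) > 0L) print(table(x$features$kind))
  invisible(x)
}

#' Load a genome from FASTA + GFF3
#'
#' Reads one chromosome from `fasta_path` and its annotations from
#' `gff_path` (1-based inclusive), converting to the package's 0-based
#' half-open convention. GFF3 attributes `essential`, `orf_class`,
#' `anticodon` and `retain_intron` are parsed into feature columns; unknown
#' feature types are kept verbatim with a warning.
#'
#' @param fasta_path FASTA file with a single record.
#' @param gff_path GFF3 annotation file.
#' @return A `GenomeRecord`.
#' @export
load_genome <- function(fasta_path, gff_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) stopf("expected exactly one FASTA record, found %d", length(seqs))
  id <- sub("\\s.*$", "", names(seqs)[1])
  gr <- rtracklayer::import(gff_path)
  mc <- S4Vectors::mcols(gr)
  get_col <- function(name, default = NA_character_) {
    if (name %in% names(mc)) {
      v <- mc[[name]]
      if (methods::is(v, "CharacterList")) {
        v <- vapply(v, function(x) if (length(x)) x[[1]] else NA_character_, character(1))
      }
      as.character(v)
    } else rep(default, length(gr))
  }
  kind <- as.character(mc$type)
  unknown <- setdiff(unique(kind), FEATURE_KINDS)
  if (length(unknown) > 0L) {
    warnf("unknown feature kind(s) kept as opaque: %s", paste(unknown, collapse = ", "))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  f <- data.frame(
    id = get_col("ID"), kind = kind,
    start = BiocGenerics::start(gr) - 1L, end = BiocGenerics::end(gr),
    strand = strand, parent = get_col("Parent"),
    essential = get_col("essential"), orf_class = get_col("orf_class"),
    anticodon = get_col("anticodon"),
    retain_intron = as.logical(get_col("retain_intron")),
    stringsAsFactors = FALSE)
  if (any(f$start < 0L) || any(f$end > nchar(as.character(seqs[[1]])))) {
    stopf("feature outside sequence bounds in '%s'", gff_path)
  }
  genome_record(id, as.character(seqs[[1]]), f)
}

#' Save a genome to FASTA + GFF3
#'
#' Writes 60-column wrapped FASTA and GFF3 (1-based inclusive) such that
#' [load_genome()] reproduces the record exactly, attributes included.
#'
#' @param g A `GenomeRecord`.
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, `g`.
#' @export
save_genome <- function(g, fasta_path, gff_path) {
  dna <- Biostrings::DNAStringSet(g$sequence)
  names(dna) <- g$id
  Biostrings::writeXStringSet(dna, fasta_path, width = 60L)
  f <- g$features
  gr <- GenomicRanges::GRanges(
    seqnames = g$id,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- f$kind
  S4Vectors::mcols(gr)$ID <- f$id
  S4Vectors::mcols(gr)$Parent <- f$parent
  S4Vectors::mcols(gr)$essential <- f$essential
  S4Vectors::mcols(gr)$orf_class <- f$orf_class
  S4Vectors::mcols(gr)$anticodon <- f$anticodon
  S4Vectors::mcols(gr)$retain_intron <- ifelse(is.na(f$retain_intron), NA_character_,
                                               as.character(f$retain_intron))
  rtracklayer::export(gr, gff_path, format = "GFF3")
  invisible(g)
}

# ---- sequence access ------------------------------------------------------

# Chromosome-forward subsequence [start, end), 0-based half-open.
subseq0 <- function(sequence, start, end) {
  if (end <= start) return("")
  substr(sequence, start + 1L, end)
}

#' Gene-orientation coding sequence of an ORF
#'
#' Extracts the ORF sequence, excises annotated introns, and reverse
#' complements for minus-strand genes, yielding the mRNA-sense coding
#' sequence starting at the initiator codon.
#'
#' @param g A `GenomeRecord`.
#' @param orf_id ORF feature id.
#' @param exclude_introns Excise annotated child introns (default `TRUE`).
#' @return DNA string in gene orientation.
#' @export
orf_coding_seq <- function(g, orf_id, exclude_introns = TRUE) {
  f <- g$features
  orf <- f[f$id == orf_id & f$kind == "ORF", , drop = FALSE]
  if (nrow(orf) != 1L) stopf("no unique ORF '%s'", orf_id)
  s <- subseq0(g$sequence, orf$start, orf$end)
  if (exclude_introns) {
    introns <- f[f$kind == "intron" & f$parent == orf_id & !is.na(f$parent), , drop = FALSE]
    if (nrow(introns) > 0L) {
      introns <- introns[order(introns$start), , drop = FALSE]
      keep <- character(0)
      pos <- orf$start
      for (i in seq_len(nrow(introns))) {
        keep <- c(keep, subseq0(g$sequence, pos, introns$start[i]))
        pos <- introns$end[i]
      }
      keep <- c(keep, subseq0(g$sequence, pos, orf$end))
      s <- paste(keep, collapse = "")
    }
  }
  if (orf$strand == "-") s <- revcomp(s)
  s
}

#' Translate an ORF
#'
#' @param g A `GenomeRecord`.
#' @param orf_id ORF feature id.
#' @param strip_stop Drop the terminal stop residue (default `TRUE`).
#' @return Amino-acid string.
#' @export
translate_orf <- function(g, orf_id, strip_stop = TRUE) {
  cds <- orf_coding_seq(g, orf_id)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "error"))
  if (strip_stop) sub("\\*$", "", aa) else aa
}

# ---- design ledger --------------------------------------------------------

EDIT_RATIONALES <- c("loxpsym", "intron_removal", "stop_swap", "feature_removal",
                     "telomere_cap", "pcrtag_recode", "marker", "junction", "repair")

#' Construct edit records
#'
#' Each row describes one edit in native (source) coordinates:
#' `insert` (zero-length interval, non-empty payload), `delete` (empty
#' payload) or `substitute` (payload may differ in length from the native
#' interval).
#'
#' @param op `"insert"`, `"delete"` or `"substitute"`.
#' @param start,end Native 0-based half-open interval (`start == end` for
#'   inserts).
#' @param payload Replacement/insertion DNA (empty for deletes).
#' @param rationale One of the edit classes (e.g. `"loxpsym"`,
#'   `"intron_removal"`, `"stop_swap"`, `"feature_removal"`,
#'   `"telomere_cap"`, `"pcrtag_recode"`, `"marker"`, `"junction"`,
#'   `"repair"`).
#' @param note Free-text annotation.
#' @return A `data.frame` of edit records.
#' @export
edit_records <- function(op, start, end, payload, rationale, note = "") {
  if (length(op) == 0L) {
    return(data.frame(op = character(0), start = integer(0), end = integer(0),
                      payload = character(0), rationale = character(0),
                      note = character(0), stringsAsFactors = FALSE))
  }
  e <- data.frame(op = op, start = as.integer(start), end = as.integer(end),
                  payload = toupper(payload), rationale = rationale,
                  note = note, stringsAsFactors = FALSE)
  bad <- (e$op == "insert" & (e$start != e$end | nchar(e$payload) == 0L)) |
         (e$op == "delete" & nchar(e$payload) != 0L) |
         (e$op == "substitute" & e$start >= e$end) |
         e$start > e$end
  if (any(bad)) stopf("malformed edit record(s) at row(s): %s",
                      paste(which(bad), collapse = ", "))
  if (!all(e$rationale %in% EDIT_RATIONALES)) stopf("unknown edit rationale")
  e
}

empty_edits <- function() {
  edit_records(character(0), integer(0), integer(0), character(0), character(0),
               character(0))
}

#' Create a design ledger
#'
#' An ordered, invertible record of edits mapping a native (source)
#' sequence to a designed (target) sequence. Edits must be sorted by native
#' coordinate and non-overlapping; `net_delta` is the total length change.
#'
#' @param source_id,target_id Sequence identifiers.
#' @param edits Edit table from [edit_records()].
#' @param source_len Length of the source sequence in bases.
#' @return An object of class `DesignLedger`.
#' @export
design_ledger <- function(source_id, target_id, edits, source_len) {
  edits <- edits[order(edits$start, edits$end), , drop = FALSE]
  rownames(edits) <- NULL
  if (nrow(edits) > 1L) {
    prev_end <- edits$end[-nrow(edits)]
    nxt_start <- edits$start[-1L]
    if (any(nxt_start < prev_end)) stopf("ledger contains overlapping edits")
    same_point_inserts <- edits$op[-nrow(edits)] == "insert" &
      edits$op[-1L] == "insert" & edits$start[-1L] == edits$start[-nrow(edits)]
    if (any(same_point_inserts)) stopf("two insertions at the same native position")
  }
  if (nrow(edits) > 0L && (edits$start[1] < 0L || max(edits$end) > source_len)) {
    stopf("edit outside source coordinate space")
  }
  net_delta <- sum(nchar(edits$payload) - (edits$end - edits$start))
  structure(list(source_id = source_id, target_id = target_id, edits = edits,
                 source_len = as.integer(source_len),
                 target_len = as.integer(source_len + net_delta),
                 net_delta = as.integer(net_delta)),
            class = "DesignLedger")
}

#' @export
print.DesignLedger <- function(x, ...) {
  cat(sprintf("DesignLedger %s -> %s: %d edits, %d -> %d bp (net %+d)\n",
              x$source_id, x$target_id, nrow(x$edits),
              x$source_len, x$target_len, x$net_delta))
  if (nrow(x$edits) > 0L) print(table(x$edits$rationale))
  invisible(x)
}

#' Apply a design ledger to a source sequence
#'
#' Splices the ledger's edits into `source_sequence` in one left-to-right
#' pass. Untouched regions are copied verbatim; the result length is
#' `source_len + net_delta`.
#'
#' @param source_sequence DNA string of length `ledger$source_len`.
#' @param ledger A `DesignLedger`.
#' @return The designed (target) sequence.
#' @export
apply_ledger <- function(source_sequence, ledger) {
  if (nchar(source_sequence) != ledger$source_len) {
    stopf("source sequence length %d does not match ledger source_len %d",
          nchar(source_sequence), ledger$source_len)
  }
  e <- ledger$edits
  if (nrow(e) == 0L) return(source_sequence)
  pieces <- character(2L * nrow(e) + 1L)
  pos <- 0L
  for (i in seq_len(nrow(e))) {
    pieces[2L * i - 1L] <- subseq0(source_sequence, pos, e$start[i])
    pieces[2L * i] <- e$payload[i]
    pos <- e$end[i]
  }
  pieces[2L * nrow(e) + 1L] <- subseq0(source_sequence, pos, nchar(source_sequence))
  out <- paste(pieces, collapse = "")
  stopifnot(nchar(out) == ledger$target_len)
  out
}

#' Lift a position through a design ledger
#'
#' Maps a coordinate between native and designed frames. Positions inside
#' deleted native intervals, or inside length-changing substitutions (and,
#' in reverse, inside inserted payload), have no image and map to `NA`
#' ("deleted"). Same-length substitutions map their interiors 1:1. The map
#' is monotone outside edited intervals.
#'
#' @param ledger A `DesignLedger`.
#' @param pos 0-based position in the source frame of `direction`.
#' @param direction `"native_to_design"` or `"design_to_native"`.
#' @return Integer position, or `NA_integer_` if the position was deleted.
#' @export
lift_position <- function(ledger, pos, direction = c("native_to_design", "design_to_native")) {
  direction <- match.arg(direction)
  e <- ledger$edits
  if (direction == "native_to_design") {
    if (pos < 0L || pos > ledger$source_len) stopf("position %d out of range", pos)
    delta <- 0L
    for (i in seq_len(nrow(e))) {
      if (e$end[i] <= pos) {
        delta <- delta + nchar(e$payload[i]) - (e$end[i] - e$start[i])
      } else if (e$start[i] <= pos && pos < e$end[i]) {
        same_len <- e$op[i] == "substitute" &&
          nchar(e$payload[i]) == e$end[i] - e$start[i]
        return(if (same_len) pos + delta else NA_integer_)
      } else break
    }
    pos + delta
  } else {
    if (pos < 0L || pos > ledger$target_len) stopf("position %d out of range", pos)
    delta <- 0L
    for (i in seq_len(nrow(e))) {
      dstart <- e$start[i] + delta
      dend <- dstart + nchar(e$payload[i])
      if (dend <= pos) {
        delta <- delta + nchar(e$payload[i]) - (e$end[i] - e$start[i])
      } else if (dstart <= pos && pos < dend) {
        same_len <- e$op[i] == "substitute" &&
          nchar(e$payload[i]) == e$end[i] - e$start[i]
        return(if (same_len) pos - delta else NA_integer_)
      } else break
    }
    pos - delta
  }
}

# Lift a native [start, end) interval to design coordinates. The end is
# lifted via end-1 so an insertion flush at the boundary is not absorbed.
# Returns NULL when the interval has been wholly removed.
lift_interval <- function(ledger, start, end) {
  s <- lift_position(ledger, start)
  e1 <- lift_position(ledger, end - 1L)
  if (is.na(s) && is.na(e1)) return(NULL)
  if (is.na(s)) {
    covering <- ledger$edits[ledger$edits$start <= start & start < ledger$edits$end, , drop = FALSE]
    s <- lift_position(ledger, covering$end[1])
  }
  if (is.na(e1)) {
    covering <- ledger$edits[ledger$edits$start <= (end - 1L) & (end - 1L) < ledger$edits$end, , drop = FALSE]
    prev <- lift_position(ledger, covering$start[1])
    if (is.na(prev) || prev <= s) return(NULL)
    return(c(s, prev))
  }
  c(s, e1 + 1L)
}

#' Write a design ledger to JSON
#'
#' @param ledger A `DesignLedger`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ledger_json <- function(ledger, path) {
  obj <- list(source_id = ledger$source_id, target_id = ledger$target_id,
              source_len = ledger$source_len, target_len = ledger$target_len,
              net_delta = ledger$net_delta, edits = ledger$edits)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a design ledger from JSON
#'
#' @param path JSON file written by [write_ledger_json()].
#' @return A `DesignLedger`.
#' @export
read_ledger_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edits <- if (length(obj$edits) == 0L) empty_edits() else
    edit_records(obj$edits$op, obj$edits$start, obj$edits$end,
                 obj$edits$payload, obj$edits$rationale, obj$edits$note %||% "")
  design_ledger(obj$source_id, obj$target_id, edits, obj$source_len)
}

#' Export a design ledger as TSV
#'
#' @param ledger A `DesignLedger`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ledger_tsv <- function(ledger, path) {
  write.table(ledger$edits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
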