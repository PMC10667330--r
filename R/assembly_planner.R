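# SwapIn build planning: partition a designed chromosome into ~10-kb
# chunks joined at unique restriction sites, grouped into 30-60-kb
# megachunks of 4-5 chunks with alternating LEU2/URA3 markers.

#' Default junction enzyme panel
#'
#' Rare-cutting (8-base) recognition sequences commonly used for
#' hierarchical DNA assembly; their scarcity makes the
#' once-per-adjacent-chunk-union uniqueness requirement attainable.
#' Supply your own named vector to [partition_chunks()] to override.
#'
#' @return Named character vector of recognition sequences.
#' @export
default_enzymes <- function() {
  c(NotI = "GCGGCCGC", AscI = "GGCGCGCC", PmeI = "GTTTAAAC",
    PacI = "TTAATTAA", SbfI = "CCTGCAGG", FseI = "GGCCGGCC",
    AsiSI = "GCGATCGC", SrfI = "GCCCGGGC")
}

#' Partition a designed chromosome into chunks
#'
#' Greedily scans a slack window around each running size target for a
#' junction: a position where some enzyme's recognition site occurs
#' exactly once within the union of the two adjacent chunks. Intergenic
#' junctions are preferred; ties are broken by smallest deviation from the
#' target. Chunk intervals tile the chromosome exactly; the junction site
#' begins at each internal boundary.
#'
#' @param designed A designed `GenomeRecord`.
#' @param target Chunk size target in bases.
#' @param min_len,max_len Permitted chunk size range.
#' @param slack Half-width of the boundary search window.
#' @param enzymes Named vector of recognition sequences.
#' @return A list of class `ChunkPlan` with element `chunks`
#'   (`data.frame`: `chunk_id`, `start`, `end`, `junction_enzyme`,
#'   `junction_site`, `junction_pos`); megachunk fields are filled in by
#'   [group_megachunks()].
#' @export
partition_chunks <- function(designed, target = 10000L, min_len = 5000L,
                             max_len = 12000L, slack = 2000L,
                             enzymes = default_enzymes()) {
  stopifnot(length(enzymes) > 0L, min_len <= target, target <= max_len)
  L <- designed$length
  if (L <= max_len) {
    chunks <- data.frame(chunk_id = "C1", start = 0L, end = L,
                         junction_enzyme = NA_character_,
                         junction_site = NA_character_,
                         junction_pos = NA_integer_, stringsAsFactors = FALSE)
    return(structure(list(chunks = chunks, megachunks = NULL),
                     class = "ChunkPlan"))
  }
  occ <- lapply(enzymes, function(s) {
    sort(unique(c(find_all(s, designed$sequence),
                  find_all(revcomp(s), designed$sequence))))
  })
  orfs <- designed$features[designed$features$kind == "ORF", , drop = FALSE]
  intergenic <- function(p) !any(orfs$start <= p & p < orfs$end)

  boundaries <- integer(0)
  junction <- list()
  prev <- 0L
  repeat {
    remaining <- L - prev
    if (remaining <= max_len) break
    tgt <- prev + target
    # keep the final chunk feasible
    tgt <- min(tgt, L - min_len)
    lo <- max(prev + min_len, tgt - slack)
    hi <- min(prev + max_len, tgt + slack, L - min_len)
    cand <- list()
    for (k in seq_along(occ)) {
      site_len <- nchar(enzymes[[k]])
      ps <- occ[[k]][occ[[k]] >= lo & occ[[k]] + site_len <= hi]
      for (p in ps) {
        # uniqueness over the union of the two adjacent chunks
        span_lo <- prev
        span_hi <- min(L, p + max_len)
        n_in_union <- sum(occ[[k]] >= span_lo & occ[[k]] + site_len <= span_hi)
        if (n_in_union == 1L) {
          cand[[length(cand) + 1L]] <- data.frame(
            pos = p, enzyme = names(enzymes)[k], site = enzymes[[k]],
            dev = abs(p - tgt), inter = intergenic(p),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(cand) == 0L) {
      stopf("no feasible junction in [%d, %d]: no enzyme site occurs uniquely there",
            lo, hi)
    }
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$inter, cand$dev), , drop = FALSE]
    pick <- cand[1, ]
    boundaries <- c(boundaries, pick$pos)
    junction[[length(junction) + 1L]] <- pick
    prev <- pick$pos
  }
  starts <- c(0L, boundaries)
  ends <- c(boundaries, L)
  jx <- do.call(rbind, junction)
  chunks <- data.frame(
    chunk_id = sprintf("C%d", seq_along(starts)),
    start = starts, end = ends,
    junction_enzyme = c(jx$enzyme, NA_character_),
    junction_site = c(jx$site, NA_character_),
    junction_pos = c(jx$pos, NA_integer_),
    stringsAsFactors = FALSE)
  structure(list(chunks = chunks, megachunks = NULL), class = "ChunkPlan")
}

#' Group chunks into labeled megachunks with alternating markers
#'
#' Consecutive chunks are grouped four or five to a megachunk within the
#' configured span; labels run alphabetically and marker cassettes
#' alternate LEU2, URA3, LEU2, ... so each integration round can select
#' for the new marker and screen for loss of the previous one. The marker
#' cassette is recorded as an insert edit at the 3' end of each
#' megachunk's final chunk. A trailing remainder that cannot reach four
#' chunks is relaxed to three with a warning.
#'
#' @param plan A `ChunkPlan` from [partition_chunks()].
#' @param mega_min,mega_max Megachunk span range in bases.
#' @param chunks_min,chunks_max Chunks per megachunk.
#' @param markers Marker cassette names, alternated in order.
#' @return The completed `ChunkPlan`: `megachunks`
#'   (`data.frame`: `label`, `chunk_ids`, `start`, `end`, `marker`), the
#'   chunk table gaining a `megachunk` column, and `marker_edits` (insert
#'   edit records at megachunk ends).
#' @export
group_megachunks <- function(plan, mega_min = 30000L, mega_max = 60000L,
                             chunks_min = 4L, chunks_max = 5L,
                             markers = c("LEU2", "URA3")) {
  ch <- plan$chunks
  n <- nrow(ch)
  groups <- list()
  i <- 1L
  span <- function(i, take) ch$end[i + take - 1L] - ch$start[i]
  while (i <= n) {
    left <- n - i + 1L
    if (left <= chunks_max) {
      take <- left
    } else {
      take <- chunks_min
      # grow to 5 chunks if 4 fall short of the span floor
      while (take < chunks_max && span(i, take) < mega_min) take <- take + 1L
      # avoid stranding a remainder of 1-2 chunks; a remainder of 3 is the
      # documented relaxation
      if ((left - take) %in% c(1L, 2L)) take <- min(chunks_max, left - 3L)
      # respect the span cap
      while (take > 1L && span(i, take) > mega_max) take <- take - 1L
    }
    groups[[length(groups) + 1L]] <- i:(i + take - 1L)
    i <- i + take
  }
  mk <- lapply(seq_along(groups), function(g) {
    idx <- groups[[g]]
    data.frame(label = LETTERS[g],
               chunk_ids = paste(ch$chunk_id[idx], collapse = ","),
               start = ch$start[idx[1]], end = ch$end[idx[length(idx)]],
               n_chunks = length(idx),
               marker = markers[(g - 1L) %% length(markers) + 1L],
               stringsAsFactors = FALSE)
  })
  mk <- do.call(rbind, mk)
  if (any(mk$n_chunks < chunks_min)) {
    warnf("megachunk(s) %s relaxed below %d chunks",
          paste(mk$label[mk$n_chunks < chunks_min], collapse = ","), chunks_min)
  }
  ch$megachunk <- rep(mk$label, vapply(groups, length, integer(1)))
  # relabel chunks megachunk-wise: A1, A2, ...
  ch$chunk_id <- unlist(lapply(seq_along(groups), function(g) {
    sprintf("%s%d", mk$label[g], seq_along(groups[[g]]))
  }))
  mk$chunk_ids <- vapply(seq_along(groups), function(g) {
    paste(ch$chunk_id[groups[[g]]], collapse = ",")
  }, character(1))
  marker_edits <- edit_records("insert", mk$end, mk$end,
                               paste0("NNN", mk$marker, "NNN"),
                               "marker", paste0("marker_", mk$label))
  plan$chunks <- ch
  plan$megachunks <- mk
  plan$marker_edits <- marker_edits
  plan
}

#' @export
print.ChunkPlan <- function(x, ...) {
  cat(sprintf("ChunkPlan: %d chunks", nrow(x$chunks)))
  if (!is.null(x$megachunks)) {
    cat(sprintf(", %d megachunks (%s)", nrow(x$megachunks),
                paste0(x$megachunks$label[1], "-",
                       x$megachunks$label[nrow(x$megachunks)])))
  }
  cat("\n")
  invisible(x)
}

#' Emit per-chunk sequences and the build-plan table
#'
#' Each emitted chunk carries its right-hand junction site as a terminal
#' overlap shared with the next chunk (the complementary restriction ends
#' used for ligation); collapsing each overlap once reconstructs the
#' designed chromosome exactly.
#'
#' @param plan A completed `ChunkPlan`.
#' @param designed The designed `GenomeRecord`.
#' @return `list(sequences, table)`: a named character vector of chunk
#'   sequences and the plan `data.frame` (`chunk_id`, `start`, `end`,
#'   `enzyme`, `megachunk`, `marker`).
#' @export
emit_build_plan <- function(plan, designed) {
  ch <- plan$chunks
  seqs <- character(nrow(ch))
  for (i in seq_len(nrow(ch))) {
    right_ov <- if (!is.na(ch$junction_site[i])) nchar(ch$junction_site[i]) else 0L
    seqs[i] <- subseq0(designed$sequence, ch$start[i],
                       min(designed$length, ch$end[i] + right_ov))
  }
  names(seqs) <- ch$chunk_id
  mk <- plan$megachunks
  marker_of <- if (!is.null(mk)) setNames(mk$marker, mk$label) else NULL
  tab <- data.frame(chunk_id = ch$chunk_id, start = ch$start, end = ch$end,
                    enzyme = ch$junction_enzyme,
                    megachunk = if (!is.null(mk)) ch$megachunk else NA_character_,
                    marker = if (!is.null(mk)) unname(marker_of[ch$megachunk])
                             else NA_character_,
                    stringsAsFactors = FALSE)
  list(sequences = seqs, table = tab)
}

#' Reconstruct a chromosome from emitted chunks
#'
#' Concatenates emitted chunk sequences, collapsing each junction overlap
#' once. Used to audit tiling exactness.
#'
#' @param build Output of [emit_build_plan()].
#' @return The reconstructed sequence.
#' @export
reconstruct_from_chunks <- function(build) {
  seqs <- build$sequences
  tab <- build$table
  out <- seqs[1]
  for (i in seq_along(seqs)[-1L]) {
    ov <- tab$end[i - 1L] + (nchar(seqs[i - 1L]) - (tab$end[i - 1L] - tab$start[i - 1L])) -
      tab$start[i]
    out <- paste0(out, substr(seqs[i], ov + 1L, nchar(seqs[i])))
  }
  unname(out)
}

#' Write a build-plan table
#'
#' @param build Output of [emit_build_plan()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_build_plan <- function(build, path) {
  write.table(build$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a build-plan table
#'
#' @param path TSV written by [write_build_plan()].
#' @return The plan `data.frame`.
#' @export
read_build_plan <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
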