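# Shared helpers: handcrafted micro-genomes with known geometry, and
# independent oracles kept deliberately naive.

# touch the genetic code once so Biostrings' lazy namespace load happens
# during setup, not inside a timed test
invisible(Biostrings::GENETIC_CODE)

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# A 600-bp genome with one plus-strand ORF at [100, 400) ending in the
# requested stop codon, non-essential and Verified by default.
micro_genome <- function(stop_codon = "TAA", strand = "+",
                         essential = "no", orf_class = "Verified",
                         seed = 99L) {
  set.seed(seed)
  orf_gene <- paste0("ATG",
                     paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                          c("TAA", "TAG", "TGA")),
                                  98, replace = TRUE), collapse = ""),
                     stop_codon)
  stopifnot(nchar(orf_gene) == 300)
  body <- if (strand == "+") orf_gene else rc(orf_gene)
  seqn <- paste0(rand_dna(100), body, rand_dna(200))
  genome_record("mini", seqn,
                features("ORF1", "ORF", 100L, 400L, strand,
                         essential = essential, orf_class = orf_class))
}

# Naive left-to-right string-splice oracle for ledger application.
splice_oracle <- function(seqn, edits) {
  edits <- edits[order(edits$start), , drop = FALSE]
  out <- ""
  pos <- 0L
  for (i in seq_len(nrow(edits))) {
    out <- paste0(out, substr(seqn, pos + 1L, edits$start[i]), edits$payload[i])
    pos <- edits$end[i]
  }
  paste0(out, substr(seqn, pos + 1L, nchar(seqn)))
}

# Random non-overlapping ledger over a sequence of length n.
random_ledger_edits <- function(n, n_edits = 5L) {
  cuts <- sort(sample.int(n - 1L, 2L * n_edits))
  starts <- cuts[seq(1L, length(cuts), 2L)]
  ends <- cuts[seq(2L, length(cuts), 2L)]
  ops <- sample(c("insert", "delete", "substitute"), n_edits, replace = TRUE)
  ends[ops == "insert"] <- starts[ops == "insert"]
  payloads <- vapply(seq_len(n_edits), function(i) {
    switch(ops[i],
           insert = rand_dna(sample(1:40, 1)),
           delete = "",
           substitute = rand_dna(sample(1:40, 1)))
  }, character(1))
  edit_records(ops, starts, ends, payloads,
               sample(c("repair", "loxpsym", "feature_removal"), n_edits,
                      replace = TRUE))
}

# Strand-aware gap between each inserted loxPsym site and its ORF's stop
# codon in a DesignResult; one value per site.
loxpsym_stop_gaps <- function(result) {
  df <- result$genome$features
  lox <- df[df$kind == "loxpsym", , drop = FALSE]
  vapply(seq_len(nrow(lox)), function(i) {
    orf_id <- sub("^loxpsym_", "", lox$id[i])
    orf <- df[df$id == orf_id & df$kind == "ORF", , drop = FALSE]
    if (orf$strand == "+") lox$start[i] - orf$end else orf$start - lox$end[i]
  }, numeric(1))
}

# Genotype truth table for n tags in one megachunk.
tag_truth <- function(n = 8L, sample_id = "s1", megachunk = "A",
                      syn = TRUE, wt = FALSE) {
  data.frame(sample = sample_id, tag_id = sprintf("%s_T%02d", megachunk, 1:n),
             megachunk = megachunk, syn_present = syn, wt_present = wt,
             stringsAsFactors = FALSE)
}
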