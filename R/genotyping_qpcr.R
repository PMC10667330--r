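# PCR-tag genotyping from qPCR plates: per-tag presence calls with
# control-driven exclusion of aberrant tags, the all-SYN/no-WT megachunk
# acceptance rule, and efficiency-corrected relative expression.

#' Call per-tag amplification from a qPCR table
#'
#' A well counts as amplified when its Cq is at most `cq_max` and its melt
#' peak lies within `melt_tolerance` of the tag's expected peak (from the
#' manifest). A tag/allele is `aberrant_excluded` - removed from all
#' downstream evidence - when its no-template control amplifies or its
#' wrong-template control does (a SYN tag amplifying on wild-type control
#' DNA, or a WT tag on synthetic control DNA). Replicate sample wells are
#' aggregated by majority; ties are excluded as aberrant.
#'
#' @param table QpcrTable `data.frame` (`well`, `sample`, `tag_id`,
#'   `allele`, `Cq`, `melt_c`, `is_ntc`).
#' @param manifest `data.frame` (`tag_id`, `allele`, `melt_expected`).
#' @param cq_max Maximum cycle threshold treated as amplification.
#' @param melt_tolerance Allowed deviation from the expected melt peak,
#'   degrees C.
#' @param positive_control,negative_control Sample labels of the mixed
#'   synthetic-chunk-DNA and wild-type-DNA controls.
#' @return `data.frame` (`sample`, `tag_id`, `allele`, `call`) with call
#'   in `amplified`, `not_amplified`, `aberrant_excluded`.
#' @export
call_tag_presence <- function(table, manifest, cq_max = 35,
                              melt_tolerance = 1.0,
                              positive_control = "POS_CTRL",
                              negative_control = "NEG_CTRL") {
  has_pos <- any(table$sample == positive_control & !table$is_ntc)
  has_neg <- any(table$sample == negative_control & !table$is_ntc)
  if (!has_pos || !has_neg) stopf("positive and negative control samples are required")

  mkey <- paste(manifest$tag_id, manifest$allele)
  expected <- setNames(manifest$melt_expected, mkey)
  amp <- !is.na(table$Cq) & table$Cq <= cq_max &
    !is.na(table$melt_c) &
    abs(table$melt_c - expected[paste(table$tag_id, table$allele)]) <= melt_tolerance

  key <- paste(table$tag_id, table$allele)
  aberrant <- character(0)
  ntc_amp <- unique(key[table$is_ntc & amp])
  wrong_template <- unique(c(
    key[table$sample == negative_control & table$allele == "SYN" & amp & !table$is_ntc],
    key[table$sample == positive_control & table$allele == "WT" & amp & !table$is_ntc]))
  aberrant <- union(ntc_amp, wrong_template)

  idx <- !table$is_ntc & !(table$sample %in% c(positive_control, negative_control))
  sub <- table[idx, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(sample = character(0), tag_id = character(0),
                      allele = character(0), call = character(0)))
  }
  sub$amp <- amp[idx]
  agg <- stats::aggregate(amp ~ sample + tag_id + allele, data = sub,
                          FUN = function(v) {
                            n1 <- sum(v); n0 <- length(v) - n1
                            if (n1 > n0) "amplified"
                            else if (n0 > n1) "not_amplified"
                            else "aberrant_excluded"
                          })
  names(agg)[names(agg) == "amp"] <- "call"
  agg$call[paste(agg$tag_id, agg$allele) %in% aberrant] <- "aberrant_excluded"
  agg[order(agg$sample, agg$tag_id, agg$allele), , drop = FALSE]
}

#' Apply the megachunk acceptance rule
#'
#' A megachunk integration is `accepted` for a sample if and only if every
#' informative synthetic tag amplified and no informative wild-type tag
#' did; otherwise `rejected`. With no informative tags (all excluded as
#' aberrant, or none mapped) the call is `indeterminate`.
#'
#' @param calls Per-tag calls from [call_tag_presence()].
#' @param tag_map `data.frame` (`tag_id`, `megachunk`).
#' @return `data.frame` (`sample`, `megachunk`, `call`, `n_informative`,
#'   `syn_amplified`, `wt_amplified`).
#' @export
assess_megachunk <- function(calls, tag_map) {
  unmapped <- setdiff(unique(calls$tag_id), tag_map$tag_id)
  if (length(unmapped) > 0L) {
    warnf("tag(s) not mapped to a megachunk: %s", paste(unmapped, collapse = ","))
  }
  calls <- merge(calls, tag_map, by = "tag_id")
  out <- list()
  for (s in unique(calls$sample)) {
    for (m in unique(calls$megachunk)) {
      cc <- calls[calls$sample == s & calls$megachunk == m, , drop = FALSE]
      if (nrow(cc) == 0L) next
      inf <- cc[cc$call != "aberrant_excluded", , drop = FALSE]
      syn <- inf[inf$allele == "SYN", , drop = FALSE]
      wt <- inf[inf$allele == "WT", , drop = FALSE]
      call <- if (nrow(inf) == 0L) "indeterminate"
        else if (all(syn$call == "amplified") && !any(wt$call == "amplified"))
          "accepted"
        else "rejected"
      out[[length(out) + 1L]] <- data.frame(
        sample = s, megachunk = m, call = call, n_informative = nrow(inf),
        syn_amplified = sum(syn$call == "amplified"),
        wt_amplified = sum(wt$call == "amplified"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Efficiency-corrected relative expression
#'
#' Relative expression of a target gene versus a reference (housekeeping)
#' gene with per-primer-pair amplification efficiencies, not assumed to be
#' 2 per cycle:
#' \deqn{ratio = E_t^{Cq_{t,cal} - Cq_{t,test}} / E_r^{Cq_{r,cal} - Cq_{r,test}}}
#' With both efficiencies equal to 2 this reduces to the classic
#' 2^-ddCq form.
#'
#' @param e_target,e_ref Per-cycle amplification factors in (1, 2].
#' @param cq_target_cal,cq_target_test Target Cq in calibrator and test
#'   samples.
#' @param cq_ref_cal,cq_ref_test Reference Cq in calibrator and test
#'   samples.
#' @return Positive expression ratio.
#' @export
relative_expression <- function(e_target, cq_target_cal, cq_target_test,
                                e_ref, cq_ref_cal, cq_ref_test) {
  if (any(c(e_target, e_ref) <= 1) || any(c(e_target, e_ref) > 2)) {
    stopf("amplification efficiencies must be per-cycle factors in (1, 2]")
  }
  cqs <- c(cq_target_cal, cq_target_test, cq_ref_cal, cq_ref_test)
  if (any(!is.finite(cqs))) stopf("all Cq values must be finite")
  e_target^(cq_target_cal - cq_target_test) / e_ref^(cq_ref_cal - cq_ref_test)
}

#' Write / read a qPCR table
#'
#' CSV round-trip of the well-level QpcrTable.
#'
#' @param table QpcrTable `data.frame`.
#' @param path CSV path.
#' @return `write_qpcr_table`: `path` invisibly; `read_qpcr_table`: the
#'   table.
#' @export
write_qpcr_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_table
#' @export
read_qpcr_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
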