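# Venn-subset classification of RG-motif proteins into the positive
# ("functional": phase-separating and nucleic-acid binding) and negative
# ("non-functional": neither) study sets.

#' Classify one protein into a Venn subset and study set
#'
#' The three attributes are PS (phase-separation score present and strictly
#' above `threshold`; an absent score means not PS), NAB (at least one GO term
#' in the nucleic-acid-binding list) and RG (at least one disorder-filtered
#' motif). A score exactly at the threshold is not PS. The positive study set
#' is RG & PS & NAB; the negative set is RG & !PS & !NAB.
#'
#' @param has_motif Logical.
#' @param saps_score Numeric phase-separation propensity or `NA`.
#' @param go_terms Character vector of the protein's GO ids.
#' @param na_go Character vector of nucleic-acid-binding GO ids (non-empty).
#' @param threshold Phase-separation cutoff (default 0.5).
#' @return list with logicals `ps`, `nab`, `rg`, the Venn `subset_label`
#'   (e.g. `"PS+RG"`, or `"none"`) and `set` in
#'   `c("positive", "negative", "none")`.
#' @export
classify_protein <- function(has_motif, saps_score, go_terms, na_go,
                             threshold = 0.5) {
  stopifnot(length(na_go) > 0L)
  ps <- !is.na(saps_score) && saps_score > threshold
  nab <- length(intersect(go_terms, na_go)) > 0L
  rg <- isTRUE(has_motif)
  parts <- c("PS"[ps], "NA"[nab], "RG"[rg])
  label <- if (length(parts) == 0L) "none" else paste(parts, collapse = "+")
  set <- if (rg && ps && nab) "positive"
         else if (rg && !ps && !nab) "negative"
         else "none"
  list(ps = ps, nab = nab, rg = rg, subset_label = label, set = set)
}

#' Build the study sets for a proteome
#'
#' Applies [classify_protein()] to every protein. Proteins lacking a
#' phase-separation score are treated as non-phase-separating.
#'
#' @param p An `rg_proteome`.
#' @param motifs Motif table from [proteome_motifs()] (disorder-filtered).
#' @param threshold Phase-separation cutoff (default 0.5).
#' @return data.frame with `accession`, `ps`, `nab`, `rg`, `subset_label`,
#'   `set`; a warning is raised if the positive or negative set is empty.
#' @export
build_sets <- function(p, motifs, threshold = 0.5) {
  motif_accs <- unique(motifs$accession)
  rows <- lapply(seq_len(nrow(p$records)), function(i) {
    acc <- p$records$accession[i]
    cl <- classify_protein(acc %in% motif_accs, p$saps[[acc]],
                           p$go[[acc]], p$na_binding_go, threshold)
    data.frame(accession = acc, ps = cl$ps, nab = cl$nab, rg = cl$rg,
               subset_label = cl$subset_label, set = cl$set,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$accession), , drop = FALSE]
  rownames(out) <- NULL
  if (sum(out$set == "positive") == 0L || sum(out$set == "negative") == 0L) {
    warning("empty positive or negative study set; ",
            "set-comparison statistics will be unavailable")
  }
  out
}
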