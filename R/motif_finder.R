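# RG motif detection: greedy RGG/RG unit scan, unit chaining into motifs,
# per-motif statistics, disorder filtering and collagen exclusion.

#' Motif-finder parameters
#'
#' The motif model is a chain of RGG/RG repeat units separated by short
#' spacers: a motif is a maximal run of at least `min_units` units in which
#' the gap between consecutive units never exceeds `max_spacer` residues.
#'
#' @param min_units Minimum number of RGG/RG units per motif (default 3).
#' @param max_spacer Maximum residues between consecutive units (default 4).
#' @return A list of class `motif_params`.
#' @export
motif_params <- function(min_units = 3L, max_spacer = 4L) {
  min_units <- as.integer(min_units)
  max_spacer <- as.integer(max_spacer)
  stopifnot(min_units >= 2L, max_spacer >= 0L)
  structure(list(min_units = min_units, max_spacer = max_spacer),
            class = "motif_params")
}

#' Scan a sequence for RGG/RG units
#'
#' Greedy left-to-right scan: at each position an RGG triplet is matched
#' first, then an RG duplet, else the scan advances one residue. Matched units
#' never overlap, and an RG unit immediately followed by G cannot occur (it
#' would have matched as RGG) — this is what makes duplet and triplet counts
#' non-overlapping.
#'
#' @param sequence Amino-acid string.
#' @return data.frame with 0-based half-open `start`, `end` and `kind`
#'   (`"RGG"` or `"RG"`), ordered by position.
#' @export
scan_units <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  starts <- integer(0); ends <- integer(0); kinds <- character(0)
  i <- 1L
  while (i <= n - 1L) {
    if (ch[i] == "R" && ch[i + 1L] == "G") {
      if (i + 2L <= n && ch[i + 2L] == "G") {
        starts <- c(starts, i - 1L); ends <- c(ends, i + 2L)
        kinds <- c(kinds, "RGG"); i <- i + 3L
      } else {
        starts <- c(starts, i - 1L); ends <- c(ends, i + 1L)
        kinds <- c(kinds, "RG"); i <- i + 2L
      }
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, end = ends, kind = kinds,
             stringsAsFactors = FALSE)
}

#' Assemble units into motif spans
#'
#' Chains units whose inter-unit gap (`next start - previous end`) is at most
#' `max_spacer`; maximal chains with at least `min_units` units become motifs.
#' Chains are maximal by construction, so motifs are pairwise disjoint and not
#' extendable.
#'
#' @param units data.frame from [scan_units()] (sorted by start).
#' @param params A [motif_params()] object.
#' @return data.frame with `start`, `end` (0-based half-open), `n_units`.
#' @export
assemble_motifs <- function(units, params = motif_params()) {
  if (nrow(units) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), n_units = integer(0)))
  }
  gaps <- units$start[-1L] - units$end[-nrow(units)]
  chain <- cumsum(c(0L, as.integer(gaps > params$max_spacer)))
  sizes <- tabulate(chain + 1L)
  keep <- which(sizes >= params$min_units) - 1L
  if (length(keep) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), n_units = integer(0)))
  }
  out <- lapply(keep, function(k) {
    sel <- chain == k
    data.frame(start = min(units$start[sel]), end = max(units$end[sel]),
               n_units = sum(sel))
  })
  do.call(rbind, out)
}

#' Per-motif unit and impurity statistics
#'
#' Counts RGG triplets and RG duplets (duplets never count a position where
#' the sequence reads RGG) among units fully inside the span, and the impurity
#' = fraction of motif residues that are neither R nor G.
#'
#' @param sequence Amino-acid string.
#' @param start,end Motif span, 0-based half-open.
#' @return list with `n_rgg`, `n_rg`, `n_units`, `impurity`.
#' @export
motif_stats <- function(sequence, start, end) {
  units <- scan_units(sequence)
  inside <- units$start >= start & units$end <= end
  n_rgg <- sum(units$kind[inside] == "RGG")
  n_rg <- sum(units$kind[inside] == "RG")
  ch <- strsplit(substr(sequence, start + 1L, end), "", fixed = TRUE)[[1L]]
  impurity <- sum(ch != "R" & ch != "G") / length(ch)
  list(n_rgg = n_rgg, n_rg = n_rg, n_units = n_rgg + n_rg,
       impurity = impurity)
}

#' Find RG motifs in one sequence
#'
#' @param sequence Amino-acid string.
#' @param params A [motif_params()] object.
#' @return data.frame with `start`, `end`, `n_units`, `n_rgg`, `n_rg`,
#'   `impurity` per motif (possibly zero rows).
#' @export
find_motifs <- function(sequence, params = motif_params()) {
  spans <- assemble_motifs(scan_units(sequence), params)
  if (nrow(spans) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_units = integer(0), n_rgg = integer(0),
                      n_rg = integer(0), impurity = numeric(0)))
  }
  st <- lapply(seq_len(nrow(spans)), function(i) {
    motif_stats(sequence, spans$start[i], spans$end[i])
  })
  spans$n_rgg <- vapply(st, `[[`, integer(1), "n_rgg")
  spans$n_rg <- vapply(st, `[[`, integer(1), "n_rg")
  spans$impurity <- vapply(st, `[[`, numeric(1), "impurity")
  spans
}

#' Filter motifs by disorder overlap and assign their mIDR
#'
#' A motif is kept iff at least one of its residues lies in a disorder
#' interval (motifs fully in structured regions are discarded). Each kept
#' motif is assigned `midr_start`/`midr_end`: the disorder interval with
#' maximal overlap, ties broken toward the N-terminus.
#'
#' @param hits data.frame with motif `start`, `end` columns.
#' @param disorder data.frame of disjoint sorted disorder intervals.
#' @return The kept rows of `hits` with `midr_start`, `midr_end` appended.
#' @export
filter_by_disorder <- function(hits, disorder) {
  keep <- logical(nrow(hits))
  midr_start <- integer(nrow(hits)); midr_end <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (nrow(disorder) == 0L) next
    ov <- pmax(0L, pmin(hits$end[i], disorder$end) -
                     pmax(hits$start[i], disorder$start))
    if (any(ov > 0L)) {
      keep[i] <- TRUE
      j <- which.max(ov)  # first max = most N-terminal on ties
      midr_start[i] <- disorder$start[j]
      midr_end[i] <- disorder$end[j]
    }
  }
  out <- hits[keep, , drop = FALSE]
  out$midr_start <- midr_start[keep]
  out$midr_end <- midr_end[keep]
  rownames(out) <- NULL
  out
}

#' Remove collagen-related proteins from a proteome
#'
#' The repetitive G-X-Y collagen pattern matches the RG motif model, so
#' collagens are excluded before any motif analysis. The default patterns drop
#' proteins whose description contains "collagen" (case-insensitive) or whose
#' gene name matches `COL` followed by a digit.
#'
#' @param p An `rg_proteome`.
#' @param description_pattern Regex applied case-insensitively to descriptions.
#' @param gene_pattern Regex applied to gene names.
#' @return The filtered `rg_proteome`; the number of removals is messaged.
#' @export
exclude_collagen <- function(p, description_pattern = "collagen",
                             gene_pattern = "^COL[0-9]") {
  desc_hit <- grepl(description_pattern, p$records$description,
                    ignore.case = TRUE)
  gene <- p$records$gene_name
  gene_hit <- !is.na(gene) & grepl(gene_pattern, gene)
  drop <- desc_hit | gene_hit
  message("exclude_collagen: removed ", sum(drop), " protein(s)")
  keep_acc <- p$records$accession[!drop]
  proteome(p$records[!drop, , drop = FALSE],
           disorder = p$disorder[keep_acc],
           domains = p$domains[p$domains$accession %in% keep_acc, , drop = FALSE],
           go = p$go[keep_acc],
           saps = p$saps[keep_acc],
           ptm = p$ptm[p$ptm$accession %in% keep_acc, , drop = FALSE],
           na_binding_go = p$na_binding_go)
}

#' Find and filter motifs across a whole proteome
#'
#' Runs [find_motifs()] on every sequence and [filter_by_disorder()] against
#' each protein's disorder annotation.
#'
#' @param p An `rg_proteome`.
#' @param params A [motif_params()] object.
#' @return data.frame with one row per kept motif: `accession`, `start`,
#'   `end`, `n_units`, `n_rgg`, `n_rg`, `impurity`, `midr_start`, `midr_end`.
#' @export
proteome_motifs <- function(p, params = motif_params()) {
  res <- lapply(seq_len(nrow(p$records)), function(i) {
    acc <- p$records$accession[i]
    hits <- find_motifs(p$records$sequence[i], params)
    if (nrow(hits) == 0L) return(NULL)
    hits <- filter_by_disorder(hits, pr_disorder(p, acc))
    if (nrow(hits) == 0L) return(NULL)
    cbind(accession = acc, hits, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(data.frame(accession = character(0), start = integer(0),
                      end = integer(0), n_units = integer(0),
                      n_rgg = integer(0), n_rg = integer(0),
                      impurity = numeric(0), midr_start = integer(0),
                      midr_end = integer(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$accession, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
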