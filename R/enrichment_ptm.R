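# Aromatic motif-region sets, offline GO enrichment (one-sided
# hypergeometric) and PTM enrichment with mIDR-length normalization.

#' Motif regions: motif spans extended by a flank on each side
#'
#' The region is the motif plus `flank` residues left and right, clipped to
#' sequence bounds (clipped regions are kept). Amino-acid counts within each
#' region are attached.
#'
#' @param p An `rg_proteome`.
#' @param motifs Motif table.
#' @param flank Flank width in residues (default 30).
#' @return data.frame with `accession`, motif span, `region_start`,
#'   `region_end` and one count column per amino acid.
#' @export
motif_regions <- function(p, motifs, flank = 30L) {
  if (nrow(motifs) == 0L) {
    base <- data.frame(accession = character(0), start = integer(0),
                       end = integer(0), region_start = integer(0),
                       region_end = integer(0))
    for (aa in AA20) base[[aa]] <- integer(0)
    return(base)
  }
  len_of <- stats::setNames(p$records$length, p$records$accession)
  rs <- pmax(0L, motifs$start - flank)
  re <- pmin(unname(len_of[motifs$accession]), motifs$end + flank)
  counts <- t(vapply(seq_len(nrow(motifs)), function(i) {
    count_aa(substr(pr_sequence(p, motifs$accession[i]), rs[i] + 1L, re[i]))
  }, stats::setNames(integer(20L), AA20)))
  out <- data.frame(accession = motifs$accession, start = motifs$start,
                    end = motifs$end, region_start = rs, region_end = re,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(counts))
}

#' Tyrosine-rich and phenylalanine-rich motif-region protein sets
#'
#' A protein joins the Y set (resp. F set) iff any of its motif regions
#' contains at least `min_count` tyrosines (resp. phenylalanines); the
#' overlap is their intersection. Raising `min_count` never adds members.
#'
#' @param regions data.frame from [motif_regions()].
#' @param min_count Residue-count threshold (default 5).
#' @return list with sorted accession vectors `y_set`, `f_set`, `overlap`.
#' @export
aromatic_sets <- function(regions, min_count = 5L) {
  y_set <- sort(unique(regions$accession[regions$Y >= min_count]))
  f_set <- sort(unique(regions$accession[regions$F >= min_count]))
  list(y_set = y_set, f_set = f_set, overlap = intersect(y_set, f_set))
}

#' GO term enrichment by one-sided hypergeometric test
#'
#' For each GO term present in the background, tests overrepresentation in
#' the foreground: p = P(X >= k) for X hypergeometric with K term-positive
#' proteins among N background proteins and n draws (the foreground size).
#' Terms absent from the background are skipped; q is BH across the tested
#' terms.
#'
#' @param foreground Accession vector (subset of `background`).
#' @param background Accession vector (at least 2 proteins).
#' @param go Named list mapping accession to GO id vectors.
#' @return data.frame with `term`, `k`, `K`, `n`, `N`, `odds_ratio`, `p`,
#'   `q`, sorted by p then term.
#' @export
go_enrichment <- function(foreground, background, go) {
  stopifnot(length(background) >= 2L, all(foreground %in% background))
  N <- length(background); n <- length(foreground)
  terms <- sort(unique(unlist(go[background])))
  rows <- lapply(terms, function(tm) {
    has <- vapply(background, function(a) tm %in% go[[a]], logical(1))
    K <- sum(has)
    if (K == 0L) return(NULL)
    k <- sum(has[background %in% foreground])
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; c2 <- K - k; d <- (N - n) - (K - k)
    or <- if (b == 0L || c2 == 0L) Inf else (a * d) / (b * c2)
    data.frame(term = tm, k = k, K = K, n = n, N = N, odds_ratio = or,
               p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Merged scope intervals for one protein under a PTM scope definition.
ptm_scope_intervals <- function(region_map, motifs_acc, scope, flank, len) {
  if (scope == "mIDR_inclusive") {
    idrs <- region_map$idrs
    iv <- idrs[idrs$is_midr, c("start", "end"), drop = FALSE]
    if (nrow(motifs_acc) > 0L) {
      iv <- rbind(iv, motifs_acc[, c("start", "end"), drop = FALSE])
    }
    merge_intervals(iv$start, iv$end)
  } else {  # motif_flank
    merge_intervals(pmax(0L, motifs_acc$start - flank),
                    pmin(len, motifs_acc$end + flank))
  }
}

#' PTM enrichment between study sets with scope-length normalization
#'
#' Counts PTM sites whose position falls inside each protein's scope —
#' either the motif-containing IDRs together with their motifs
#' (`"mIDR_inclusive"`, the default) or the motifs extended by `flank`
#' residues (`"motif_flank"`) — and compares the positive and negative sets.
#' Rates are sites per 1,000 scope residues; the p-value is a two-sided
#' Mann-Whitney test on per-protein site counts.
#'
#' @param membership data.frame from [build_sets()].
#' @param region_maps Named list of region maps for the motif proteins.
#' @param motifs Motif table.
#' @param p An `rg_proteome` (source of PTM sites and lengths).
#' @param modification_names Modifications to summarize (default: all
#'   observed). A modification absent everywhere is reported with zero
#'   counts.
#' @param scope `"mIDR_inclusive"` or `"motif_flank"`.
#' @param flank Flank width for the `motif_flank` scope (default 30).
#' @return data.frame with per-modification site counts, scope sizes, rates,
#'   `rate_ratio` (positive / negative) and the Mann-Whitney `p`.
#' @export
ptm_enrichment <- function(membership, region_maps, motifs, p,
                           modification_names = NULL,
                           scope = c("mIDR_inclusive", "motif_flank"),
                           flank = 30L) {
  scope <- match.arg(scope)
  if (is.null(modification_names)) {
    modification_names <- sort(unique(p$ptm$modification))
  }
  sets <- list(positive = membership$accession[membership$set == "positive"],
               negative = membership$accession[membership$set == "negative"])
  len_of <- stats::setNames(p$records$length, p$records$accession)
  scope_iv <- lapply(stats::setNames(names(region_maps), names(region_maps)),
                     function(acc) {
    ptm_scope_intervals(region_maps[[acc]],
                        motifs[motifs$accession == acc, , drop = FALSE],
                        scope, flank, len_of[[acc]])
  })
  scope_len <- vapply(scope_iv, function(iv) sum(iv$end - iv$start), numeric(1))
  count_sites <- function(acc, modname) {
    iv <- scope_iv[[acc]]
    if (is.null(iv) || nrow(iv) == 0L) return(0L)
    sites <- p$ptm$pos[p$ptm$accession == acc & p$ptm$modification == modname]
    if (length(sites) == 0L) return(0L)
    sum(vapply(sites, function(s) any(iv$start <= s & s < iv$end), logical(1)))
  }
  rows <- lapply(modification_names, function(modname) {
    per <- lapply(sets, function(accs) {
      vapply(accs, count_sites, integer(1), modname = modname)
    })
    tot <- vapply(sets, function(accs) sum(scope_len[accs], na.rm = TRUE),
                  numeric(1))
    n_pos <- sum(per$positive); n_neg <- sum(per$negative)
    rate_pos <- if (tot["positive"] > 0) 1000 * n_pos / tot["positive"] else NA_real_
    rate_neg <- if (tot["negative"] > 0) 1000 * n_neg / tot["negative"] else NA_real_
    pv <- if (length(per$positive) > 0L && length(per$negative) > 0L) {
      # all-tied samples (e.g. a modification absent everywhere) have no test
      tryCatch(mann_whitney_u(per$positive, per$negative, method = "normal")$p,
               error = function(e) NA_real_)
    } else NA_real_
    data.frame(modification = modname,
               n_sites_positive = n_pos, n_sites_negative = n_neg,
               scope_residues_positive = unname(tot["positive"]),
               scope_residues_negative = unname(tot["negative"]),
               rate_positive = unname(rate_pos), rate_negative = unname(rate_neg),
               rate_ratio = unname(rate_pos / rate_neg),
               p = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
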