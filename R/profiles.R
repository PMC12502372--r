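# Compositional and physicochemical profiling in and around RG motifs:
# 10-residue flank blocks, IDR-constrained sliding-window composition
# profiles, four-class region composition, the positive-vs-negative
# enrichment heatmap and the all-IDR background composition.

#' Amino-acid counts of a sequence fragment
#'
#' Counts over the 20-letter alphabet; any other character (notably `X`) is
#' ignored for counting but still occupies sequence positions.
#'
#' @param fragment Amino-acid string.
#' @return Named integer vector over [AA20].
#' @export
count_aa <- function(fragment) {
  ch <- strsplit(fragment, "", fixed = TRUE)[[1L]]
  stats::setNames(tabulate(match(ch, AA20), nbins = 20L), AA20)
}

#' Physicochemical properties of a sequence block
#'
#' NCPR = (#R + #K - #D - #E) / length (histidine neutral); aromaticity =
#' fraction of F/Y/W; hydropathy = mean Kyte-Doolittle rescaled to \eqn{[0,1]}
#' by \eqn{(KD+4.5)/9}, averaged over residues with a defined scale value;
#' disorder-promoting fraction over [DISORDER_PROMOTING]. Length denominators
#' count every position, including `X`.
#'
#' @param fragment Amino-acid string.
#' @return list with `ncpr`, `aromaticity`, `hydropathy`,
#'   `disorder_promoting_fraction`.
#' @export
physchem_properties <- function(fragment) {
  len <- nchar(fragment)
  cnt <- count_aa(fragment)
  kd_norm <- (KD_SCALE[AA20] + 4.5) / 9
  counted <- sum(cnt)
  list(ncpr = unname((cnt["R"] + cnt["K"] - cnt["D"] - cnt["E"]) / len),
       aromaticity = unname((cnt["F"] + cnt["Y"] + cnt["W"]) / len),
       hydropathy = if (counted > 0) unname(sum(cnt * kd_norm) / counted) else NA_real_,
       disorder_promoting_fraction = unname(sum(cnt[DISORDER_PROMOTING]) / len))
}

# TRUE iff the 0-based half-open window lies fully within one disorder interval.
window_in_idr <- function(start, end, disorder) {
  nrow(disorder) > 0L && any(disorder$start <= start & end <= disorder$end)
}

#' Physicochemical blocks around one motif
#'
#' Computes the four properties on the motif span itself and on the
#' `block_len`-residue blocks immediately N- and C-terminal of it. A flank
#' block is emitted only if all of its residues lie inside the sequence and
#' fully within a single disorder interval.
#'
#' @param sequence Amino-acid string.
#' @param motif_start,motif_end Motif span (0-based half-open).
#' @param disorder data.frame of disjoint sorted disorder intervals.
#' @param block_len Flank block length (default 10).
#' @return data.frame with `region_id` in
#'   `c("motif", "left_block", "right_block")`, the block span and the four
#'   properties; flank rows may be absent.
#' @export
block_properties <- function(sequence, motif_start, motif_end, disorder,
                             block_len = 10L) {
  len <- nchar(sequence)
  spans <- list(motif = c(motif_start, motif_end))
  ls <- motif_start - block_len
  if (ls >= 0L && window_in_idr(ls, motif_start, disorder)) {
    spans$left_block <- c(ls, motif_start)
  }
  re <- motif_end + block_len
  if (re <= len && window_in_idr(motif_end, re, disorder)) {
    spans$right_block <- c(motif_end, re)
  }
  rows <- lapply(names(spans), function(id) {
    sp <- spans[[id]]
    pp <- physchem_properties(substr(sequence, sp[1L] + 1L, sp[2L]))
    data.frame(region_id = id, block_start = sp[1L], block_end = sp[2L],
               ncpr = pp$ncpr, aromaticity = pp$aromaticity,
               hydropathy = pp$hydropathy,
               disorder_promoting_fraction = pp$disorder_promoting_fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' IDR-constrained sliding-window composition profile
#'
#' For each motif, each side and each offset d = 1..`max_offset`, the focal
#' position is d residues beyond the motif edge and the window is the
#' `2*half_width + 1` residues centered on it. A window contributes only if it
#' lies fully inside the sequence and fully within one disorder interval.
#' Residue counts are pooled across all contributing windows of all supplied
#' motifs (residue-weighted, not per-protein averaged).
#'
#' @param p An `rg_proteome`.
#' @param motifs Motif table (rows restricted to the set of interest).
#' @param max_offset Maximum offset from the motif edge (default 40).
#' @param half_width Window half-width (default 4; window length 9).
#' @return data.frame with `side` (`"left"`/`"right"`), `offset`,
#'   `n_windows` and one proportion column per amino acid (NA where no window
#'   contributed). Proportions at each axis point sum to 1 over counted
#'   residues.
#' @export
sliding_window_profile <- function(p, motifs, max_offset = 40L,
                                   half_width = 4L) {
  stopifnot(max_offset >= 1L)
  axis <- expand.grid(offset = seq_len(max_offset),
                      side = c("left", "right"),
                      stringsAsFactors = FALSE)[, c("side", "offset")]
  counts <- matrix(0L, nrow = nrow(axis), ncol = 20L,
                   dimnames = list(NULL, AA20))
  n_windows <- integer(nrow(axis))
  for (i in seq_len(nrow(motifs))) {
    acc <- motifs$accession[i]
    seqi <- pr_sequence(p, acc)
    leni <- nchar(seqi)
    dis <- pr_disorder(p, acc)
    for (j in seq_len(nrow(axis))) {
      d <- axis$offset[j]
      focal <- if (axis$side[j] == "left") motifs$start[i] - d
               else motifs$end[i] - 1L + d
      ws <- focal - half_width
      we <- focal + half_width + 1L
      if (ws < 0L || we > leni) next
      if (!window_in_idr(ws, we, dis)) next
      counts[j, ] <- counts[j, ] + count_aa(substr(seqi, ws + 1L, we))
      n_windows[j] <- n_windows[j] + 1L
    }
  }
  tot <- rowSums(counts)
  props <- counts / ifelse(tot > 0, tot, NA_real_)
  out <- cbind(axis, n_windows = n_windows, as.data.frame(props))
  rownames(out) <- NULL
  out
}

#' Amino-acid counts per region class
#'
#' Pools counts per four-class tiling region; mIDR counts therefore exclude
#' motif residues (they carry class motif).
#'
#' @param region_map A [build_region_map()] result.
#' @param sequence The protein's amino-acid string.
#' @return 4 x 20 integer matrix (rows `motif`, `mIDR`, `oIDR`, `structured`;
#'   columns [AA20]).
#' @export
region_composition <- function(region_map, sequence) {
  classes <- c("motif", "mIDR", "oIDR", "structured")
  m <- matrix(0L, nrow = 4L, ncol = 20L, dimnames = list(classes, AA20))
  seg <- region_map$segments
  for (i in seq_len(nrow(seg))) {
    m[seg$class[i], ] <- m[seg$class[i], ] +
      count_aa(substr(sequence, seg$start[i] + 1L, seg$end[i]))
  }
  m
}

# Stack per-protein region compositions: returns list(counts = accession ->
# 4x20 matrix). Used by the heatmap.
set_region_counts <- function(p, region_maps, accs) {
  lapply(stats::setNames(accs, accs), function(acc) {
    region_composition(region_maps[[acc]], pr_sequence(p, acc))
  })
}

#' Positive-vs-negative region enrichment heatmap
#'
#' For each amino acid and region class: the log2 fold change of pooled
#' proportions (add-one pseudocount on the raw pooled counts of both sets),
#' the two-sided Mann-Whitney p-value on per-protein proportions (proteins
#' with no counted residue in the class are excluded from the test), and the
#' Benjamini-Hochberg q across the 20 x 4 cells of the table. A class with no
#' counted residues in either set yields a missing cell.
#'
#' @param p An `rg_proteome`.
#' @param region_maps Named list of region maps (see
#'   [proteome_region_maps()]).
#' @param positive,negative Accession vectors of the two study sets.
#' @return data.frame with `aa`, `class`, `log2fc`, `p`, `q`.
#' @export
enrichment_heatmap <- function(p, region_maps, positive, negative) {
  stopifnot(length(positive) > 0L, length(negative) > 0L)
  classes <- c("motif", "mIDR", "oIDR", "structured")
  pos_counts <- set_region_counts(p, region_maps, positive)
  neg_counts <- set_region_counts(p, region_maps, negative)
  pool <- function(lst) Reduce(`+`, lst)
  pos_pool <- pool(pos_counts)
  neg_pool <- pool(neg_counts)
  # per-protein proportion arrays: [protein, class, aa]
  prop_array <- function(lst) {
    arr <- array(NA_real_, dim = c(length(lst), 4L, 20L),
                 dimnames = list(names(lst), classes, AA20))
    for (k in seq_along(lst)) {
      tot <- rowSums(lst[[k]])
      arr[k, , ] <- lst[[k]] / ifelse(tot > 0, tot, NA_real_)
    }
    arr
  }
  pos_props <- prop_array(pos_counts)
  neg_props <- prop_array(neg_counts)
  out <- expand.grid(aa = AA20, class = classes, stringsAsFactors = FALSE)
  out$log2fc <- NA_real_
  out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    aa <- out$aa[i]; cl <- out$class[i]
    if (sum(pos_pool[cl, ]) == 0L || sum(neg_pool[cl, ]) == 0L) next
    pp <- (pos_pool[cl, aa] + 1) / sum(pos_pool[cl, ] + 1)
    pn <- (neg_pool[cl, aa] + 1) / sum(neg_pool[cl, ] + 1)
    out$log2fc[i] <- log2(pp / pn)
    xs <- pos_props[, cl, aa]; ys <- neg_props[, cl, aa]
    xs <- xs[!is.na(xs)]; ys <- ys[!is.na(ys)]
    if (length(xs) > 0L && length(ys) > 0L) {
      # degenerate all-tied samples (residue absent throughout) have no test
      out$p[i] <- tryCatch(mann_whitney_u(xs, ys, method = "normal")$p,
                           error = function(e) NA_real_)
    }
  }
  out$q <- NA_real_
  testable <- !is.na(out$p)
  if (any(testable)) out$q[testable] <- bh_adjust(out$p[testable])
  out
}

#' Average amino-acid composition of all IDRs in a proteome
#'
#' Pools residue counts over the disorder intervals of every protein (not
#' only motif proteins) and returns proportions.
#'
#' @param p An `rg_proteome`.
#' @return Named numeric vector over [AA20] summing to 1.
#' @export
idr_background <- function(p) {
  counts <- stats::setNames(numeric(20L), AA20)
  any_idr <- FALSE
  for (i in seq_len(nrow(p$records))) {
    iv <- pr_disorder(p, p$records$accession[i])
    if (nrow(iv) == 0L) next
    any_idr <- TRUE
    for (j in seq_len(nrow(iv))) {
      counts <- counts +
        count_aa(substr(p$records$sequence[i], iv$start[j] + 1L, iv$end[j]))
    }
  }
  if (!any_idr) stop("idr_background: no disorder intervals in the proteome")
  counts / sum(counts)
}
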