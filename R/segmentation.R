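# Partition of a protein into the four region classes (motif, mIDR, oIDR,
# structured) and per-IDR statistics.

#' Build the four-class region map of one protein
#'
#' Motif residues get class `motif` (a motif partially extending beyond its
#' IDR keeps class motif for all residues); remaining residues of IDRs that
#' contain at least one motif residue get class `mIDR`; residues of motif-free
#' IDRs get `oIDR`; everything else is `structured`. The classes tile the
#' protein exactly.
#'
#' @param length Protein length in residues.
#' @param disorder data.frame of disjoint sorted disorder intervals
#'   (0-based half-open).
#' @param motifs data.frame of disorder-filtered motif spans (`start`, `end`).
#' @return Object of class `region_map`: list with `length`, `segments`
#'   (tiling data.frame `start`, `end`, `class`) and `idrs` (data.frame
#'   `start`, `end`, `is_midr`, `idr_length` — full IDR lengths, motif
#'   residues included).
#' @export
build_region_map <- function(length, disorder, motifs) {
  if (nrow(motifs) > 0L &&
      any(motifs$start < 0L | motifs$end > length | motifs$start >= motifs$end)) {
    stop("motif span outside protein bounds")
  }
  cls <- rep("structured", length)
  is_midr <- logical(nrow(disorder))
  if (nrow(disorder) > 0L) {
    for (i in seq_len(nrow(disorder))) {
      s <- disorder$start[i]; e <- disorder$end[i]
      overlaps <- nrow(motifs) > 0L &&
        any(pmin(motifs$end, e) - pmax(motifs$start, s) > 0L)
      is_midr[i] <- overlaps
      cls[(s + 1L):e] <- if (overlaps) "mIDR" else "oIDR"
    }
  }
  if (nrow(motifs) > 0L) {
    for (i in seq_len(nrow(motifs))) {
      cls[(motifs$start[i] + 1L):motifs$end[i]] <- "motif"
    }
  }
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  segments <- data.frame(start = c(0L, ends[-base::length(ends)]),
                         end = ends, class = r$values,
                         stringsAsFactors = FALSE)
  stopifnot(sum(segments$end - segments$start) == length)  # tiling invariant
  idrs <- data.frame(start = disorder$start, end = disorder$end,
                     is_midr = is_midr,
                     idr_length = disorder$end - disorder$start)
  structure(list(length = length, segments = segments, idrs = idrs),
            class = "region_map")
}

# Interval center: floor((start + end - 1) / 2); an even-length interval's
# center rounds toward the N-terminus.
interval_center <- function(start, end) (start + end - 1L) %/% 2L

#' Relative position of a motif within its IDR
#'
#' `(center - idr_start) / (idr_length - 1)`, clamped to \eqn{[0,1]}, where
#' the motif center of an even-length span rounds toward the N-terminus. An
#' IDR of length 1 yields 0.5 by convention.
#'
#' @param motif_start,motif_end Motif span (0-based half-open).
#' @param idr_start,idr_end IDR span; must overlap the motif.
#' @return Real in \eqn{[0,1]}.
#' @export
relative_motif_position <- function(motif_start, motif_end,
                                    idr_start, idr_end) {
  if (min(motif_end, idr_end) - max(motif_start, idr_start) <= 0L) {
    stop("motif does not overlap the IDR")
  }
  L <- idr_end - idr_start
  if (L == 1L) return(0.5)
  center <- interval_center(motif_start, motif_end)
  min(1, max(0, (center - idr_start) / (L - 1)))
}

#' Per-protein IDR statistics
#'
#' @param region_map A [build_region_map()] result.
#' @param motifs data.frame of the protein's motif spans with `midr_start`,
#'   `midr_end` columns (from [filter_by_disorder()]); used for the relative
#'   motif positions.
#' @return list with `n_idrs`, `idr_lengths`, `midr_lengths`, `oidr_lengths`,
#'   `disorder_fraction` (total disorder residues / protein length) and
#'   `motif_relative_positions`.
#' @export
idr_statistics <- function(region_map, motifs = NULL) {
  idrs <- region_map$idrs
  rel <- numeric(0)
  if (!is.null(motifs) && nrow(motifs) > 0L) {
    rel <- vapply(seq_len(nrow(motifs)), function(i) {
      relative_motif_position(motifs$start[i], motifs$end[i],
                              motifs$midr_start[i], motifs$midr_end[i])
    }, numeric(1))
  }
  list(n_idrs = nrow(idrs),
       idr_lengths = idrs$idr_length,
       midr_lengths = idrs$idr_length[idrs$is_midr],
       oidr_lengths = idrs$idr_length[!idrs$is_midr],
       disorder_fraction = sum(idrs$idr_length) / region_map$length,
       motif_relative_positions = rel)
}

#' Region maps for every motif-bearing protein in a proteome
#'
#' @param p An `rg_proteome`.
#' @param motifs Motif table from [proteome_motifs()].
#' @param all_proteins If `TRUE`, maps are built for every protein (motif-free
#'   proteins get only oIDR/structured classes); otherwise only for proteins
#'   with at least one motif.
#' @return Named list of `region_map` objects keyed by accession.
#' @export
proteome_region_maps <- function(p, motifs, all_proteins = FALSE) {
  accs <- if (all_proteins) p$records$accession else unique(motifs$accession)
  maps <- lapply(accs, function(acc) {
    build_region_map(p$records$length[match(acc, p$records$accession)],
                     pr_disorder(p, acc),
                     motifs[motifs$accession == acc, , drop = FALSE])
  })
  stats::setNames(maps, accs)
}
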