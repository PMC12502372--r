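# Core domain types, coordinate conventions and snapshot-file I/O.
#
# All coordinates are 0-based half-open internally; every file read or written
# by the package uses 1-based inclusive coordinates (the UniProt convention).

#' The 20-letter amino-acid alphabet
#'
#' Alphabetical one-letter codes. `X` is tolerated in sequences but is never
#' counted as a specific amino acid; it contributes to region lengths only.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy scale
#'
#' Raw Kyte-Doolittle values; [physchem_properties()] rescales them to
#' \eqn{[0,1]} via \eqn{(KD + 4.5)/9}.
#' @export
KD_SCALE <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
              H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
              P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
              W = -0.9, Y = -1.3)

#' Disorder-promoting residues
#'
#' Residues counted as disorder-promoting in the disorder-promoting-fraction
#' property: T, A, G, R, D, H, Q, K, S, E and P.
#' @export
DISORDER_PROMOTING <- c("T", "A", "G", "R", "D", "H", "Q", "K", "S", "E", "P")

#' Read protein sequences from a FASTA file
#'
#' Accepts the UniProt header dialect (`>db|ACC|NAME description GN=GENE ...`)
#' as well as bare identifiers. The accession is the second pipe-delimited
#' field of the first header token when pipes are present, otherwise the full
#' first token. Sequences are upper-cased and `*` terminators stripped.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `accession`, `gene_name`, `description`,
#'   `sequence` and `length` (one row per entry).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no sequences: ", path)
  headers <- names(seqs)
  first_tok <- sub("\\s.*$", "", headers)
  accession <- vapply(strsplit(first_tok, "|", fixed = TRUE), function(parts) {
    if (length(parts) >= 2L) parts[2L] else parts[1L]
  }, character(1))
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  gene_name <- ifelse(grepl("GN=\\S+", description),
                      sub(".*GN=(\\S+).*", "\\1", description),
                      NA_character_)
  sequence <- toupper(gsub("*", "", as.character(seqs), fixed = TRUE))
  if (any(!nzchar(sequence))) {
    stop("empty sequence for accession(s): ",
         paste(accession[!nzchar(sequence)], collapse = ", "))
  }
  dup <- accession[duplicated(accession)]
  if (length(dup) > 0L) {
    stop("duplicate accession(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  data.frame(accession = accession, gene_name = gene_name,
             description = description, sequence = unname(sequence),
             length = nchar(sequence), row.names = NULL,
             stringsAsFactors = FALSE)
}

# Merge overlapping or adjacent 0-based half-open intervals; returns a sorted,
# pairwise-disjoint data.frame(start, end).
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) {           # overlap or adjacency merges
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

parse_interval_payload <- function(payload) {
  m <- regmatches(payload, regexec("^([0-9]+)-([0-9]+)", payload))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed interval payload: ", payload[bad][1L])
  start1 <- as.integer(vapply(m, `[`, character(1), 2L))
  end1 <- as.integer(vapply(m, `[`, character(1), 3L))
  data.frame(start1 = start1, end1 = end1)
}

#' Read a protein annotation snapshot table
#'
#' Reads the tab-separated annotation format with header columns
#' `accession`, `kind`, `payload` and one annotation per row. Supported kinds
#' and payload syntax (coordinates 1-based inclusive in the file):
#' \describe{
#'   \item{disorder}{`start-end` consensus disorder interval. Overlapping or
#'     adjacent intervals are merged on read.}
#'   \item{domain}{`start-end:TYPE_ID` domain instance with its type id.}
#'   \item{go}{a GO identifier, e.g. `GO:0003723`.}
#'   \item{saps}{a scalar phase-separation propensity in \eqn{[0,1]}.}
#'   \item{ptm}{`position:Modification name`, e.g. `17:Phosphotyrosine`.}
#' }
#' Rows for accessions absent from `records` are skipped with a message.
#' Intervals or PTM positions outside protein bounds, or scores outside
#' \eqn{[0,1]}, are hard errors.
#'
#' @param path Path to the annotations TSV.
#' @param records data.frame from [read_fasta()].
#' @param na_binding_go Character vector of GO ids counted as nucleic-acid
#'   binding (descendant closure assumed already applied).
#' @return An object of class `rg_proteome`; see [proteome()].
#' @export
read_annotations <- function(path, records, na_binding_go = character(0)) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "")
  need <- c("accession", "kind", "payload")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  known <- tab$accession %in% records$accession
  n_skip <- sum(!known)
  if (n_skip > 0L) {
    message("read_annotations: skipped ", n_skip, " row(s) for ",
            length(unique(tab$accession[!known])), " unknown accession(s)")
    tab <- tab[known, , drop = FALSE]
  }
  len_of <- stats::setNames(records$length, records$accession)

  check_bounds <- function(acc, start0, end0, what) {
    L <- len_of[acc]
    bad <- start0 < 0L | start0 >= end0 | end0 > L
    if (any(bad)) {
      stop(what, " interval out of bounds for ", acc[bad][1L],
           " (protein length ", L[bad][1L], ")")
    }
  }

  disorder <- stats::setNames(
    rep(list(data.frame(start = integer(0), end = integer(0))),
        nrow(records)), records$accession)
  rows <- tab[tab$kind == "disorder", , drop = FALSE]
  if (nrow(rows) > 0L) {
    iv <- parse_interval_payload(rows$payload)
    start0 <- iv$start1 - 1L; end0 <- iv$end1
    check_bounds(rows$accession, start0, end0, "disorder")
    for (acc in unique(rows$accession)) {
      sel <- rows$accession == acc
      disorder[[acc]] <- merge_intervals(start0[sel], end0[sel])
    }
  }

  rows <- tab[tab$kind == "domain", , drop = FALSE]
  if (nrow(rows) > 0L) {
    type <- sub("^[0-9]+-[0-9]+:", "", rows$payload)
    iv <- parse_interval_payload(rows$payload)
    start0 <- iv$start1 - 1L; end0 <- iv$end1
    check_bounds(rows$accession, start0, end0, "domain")
    domains <- data.frame(accession = rows$accession, start = start0,
                          end = end0, domain_type = type,
                          stringsAsFactors = FALSE)
    domains <- domains[order(domains$accession, domains$start), , drop = FALSE]
    rownames(domains) <- NULL
  } else {
    domains <- data.frame(accession = character(0), start = integer(0),
                          end = integer(0), domain_type = character(0))
  }

  go <- stats::setNames(rep(list(character(0)), nrow(records)), records$accession)
  rows <- tab[tab$kind == "go", , drop = FALSE]
  for (acc in unique(rows$accession)) {
    go[[acc]] <- sort(unique(rows$payload[rows$accession == acc]))
  }

  saps <- stats::setNames(rep(NA_real_, nrow(records)), records$accession)
  rows <- tab[tab$kind == "saps", , drop = FALSE]
  if (nrow(rows) > 0L) {
    val <- suppressWarnings(as.numeric(rows$payload))
    if (any(is.na(val) | val < 0 | val > 1)) {
      bad <- which(is.na(val) | val < 0 | val > 1)[1L]
      stop("saps score outside [0,1] for ", rows$accession[bad], ": ",
           rows$payload[bad])
    }
    saps[rows$accession] <- val
  }

  rows <- tab[tab$kind == "ptm", , drop = FALSE]
  if (nrow(rows) > 0L) {
    pos1 <- as.integer(sub(":.*$", "", rows$payload))
    modification <- sub("^[0-9]+:", "", rows$payload)
    pos0 <- pos1 - 1L
    bad <- is.na(pos0) | pos0 < 0L | pos0 >= len_of[rows$accession]
    if (any(bad)) {
      stop("ptm position out of bounds for ", rows$accession[bad][1L])
    }
    ptm <- data.frame(accession = rows$accession, pos = pos0,
                      modification = modification, stringsAsFactors = FALSE)
    ptm <- ptm[order(ptm$accession, ptm$pos, ptm$modification), , drop = FALSE]
    rownames(ptm) <- NULL
  } else {
    ptm <- data.frame(accession = character(0), pos = integer(0),
                      modification = character(0))
  }

  unknown_kind <- setdiff(unique(tab$kind),
                          c("disorder", "domain", "go", "saps", "ptm"))
  if (length(unknown_kind) > 0L) {
    stop("unknown annotation kind(s): ", paste(unknown_kind, collapse = ", "))
  }

  proteome(records, disorder = disorder, domains = domains, go = go,
           saps = saps, ptm = ptm, na_binding_go = na_binding_go)
}

#' Construct a proteome object
#'
#' Bundles sequence records with their disorder, domain, GO, phase-separation
#' score and PTM annotations, validating every invariant (intervals in bounds,
#' disorder intervals sorted and disjoint, annotations keyed by known
#' accessions).
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param disorder Named list (by accession) of data.frames with 0-based
#'   half-open `start`, `end` disorder intervals.
#' @param domains data.frame with `accession`, `start`, `end`, `domain_type`.
#' @param go Named list of GO identifier character vectors.
#' @param saps Named numeric vector of phase-separation scores (`NA` = absent).
#' @param ptm data.frame with `accession`, `pos` (0-based), `modification`.
#' @param na_binding_go Character vector of nucleic-acid-binding GO ids.
#' @return An object of class `rg_proteome`.
#' @export
proteome <- function(records,
                     disorder = NULL, domains = NULL, go = NULL,
                     saps = NULL, ptm = NULL,
                     na_binding_go = character(0)) {
  accs <- records$accession
  if (is.null(disorder)) {
    disorder <- stats::setNames(
      rep(list(data.frame(start = integer(0), end = integer(0))),
          length(accs)), accs)
  }
  if (is.null(domains)) {
    domains <- data.frame(accession = character(0), start = integer(0),
                          end = integer(0), domain_type = character(0))
  }
  if (is.null(go)) go <- stats::setNames(rep(list(character(0)), length(accs)), accs)
  if (is.null(saps)) saps <- stats::setNames(rep(NA_real_, length(accs)), accs)
  if (is.null(ptm)) {
    ptm <- data.frame(accession = character(0), pos = integer(0),
                      modification = character(0))
  }
  obj <- structure(list(records = records, disorder = disorder,
                        domains = domains, go = go, saps = saps, ptm = ptm,
                        na_binding_go = na_binding_go),
                   class = "rg_proteome")
  validate_proteome(obj)
  obj
}

#' Validate proteome invariants
#'
#' @param p An `rg_proteome`.
#' @return `p`, invisibly; errors on any violated invariant.
#' @export
validate_proteome <- function(p) {
  accs <- p$records$accession
  if (anyDuplicated(accs)) stop("duplicate accessions in proteome")
  if (any(p$records$length != nchar(p$records$sequence))) {
    stop("record length field does not match sequence length")
  }
  len_of <- stats::setNames(p$records$length, accs)
  for (nm in c("disorder", "go")) {
    extra <- setdiff(names(p[[nm]]), accs)
    if (length(extra) > 0L) stop(nm, " annotations for unknown accession: ", extra[1L])
  }
  for (acc in names(p$disorder)) {
    iv <- p$disorder[[acc]]
    if (nrow(iv) == 0L) next
    if (any(iv$start < 0L | iv$start >= iv$end | iv$end > len_of[acc])) {
      stop("disorder interval out of bounds for ", acc)
    }
    if (is.unsorted(iv$start, strictly = TRUE) ||
        any(iv$start[-1L] < iv$end[-nrow(iv)])) {
      stop("disorder intervals not sorted/disjoint for ", acc)
    }
  }
  if (nrow(p$domains) > 0L) {
    if (!all(p$domains$accession %in% accs)) stop("domain for unknown accession")
    if (any(p$domains$start < 0L | p$domains$start >= p$domains$end |
            p$domains$end > len_of[p$domains$accession])) {
      stop("domain interval out of bounds")
    }
  }
  if (nrow(p$ptm) > 0L) {
    if (!all(p$ptm$accession %in% accs)) stop("ptm for unknown accession")
    if (any(p$ptm$pos < 0L | p$ptm$pos >= len_of[p$ptm$accession])) {
      stop("ptm position out of bounds")
    }
  }
  bad_saps <- !is.na(p$saps) & (p$saps < 0 | p$saps > 1)
  if (any(bad_saps)) stop("saps score outside [0,1]")
  invisible(p)
}

#' @export
print.rg_proteome <- function(x, ...) {
  cat("rg_proteome:", nrow(x$records), "proteins;",
      sum(vapply(x$disorder, nrow, integer(1))), "disorder intervals;",
      nrow(x$domains), "domain instances;",
      nrow(x$ptm), "PTM sites\n")
  invisible(x)
}

# Columns holding 0-based starts / half-open ends, by naming convention.
interval_start_cols <- function(nms) nms[grepl("(^|_)start$", nms)]
interval_end_cols <- function(nms) nms[grepl("(^|_)end$", nms)]

#' Write a result table as TSV
#'
#' Interval columns (named `start`/`end` or `*_start`/`*_end`) are converted
#' from the internal 0-based half-open convention to 1-based inclusive on
#' write. Floating-point columns are rounded to 6 significant digits. Rows are
#' sorted by accession and then by the first start column when those columns
#' exist, so output order is deterministic.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_result_table()] for the inverse conversion.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  scols <- interval_start_cols(names(out))
  for (cl in scols) out[[cl]] <- out[[cl]] + 1L
  ord <- NULL
  if ("accession" %in% names(out)) {
    if (length(scols) > 0L) {
      ord <- order(out$accession, out[[scols[1L]]])
    } else {
      ord <- order(out$accession)
    }
    out <- out[ord, , drop = FALSE]
  }
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- signif(out[[cl]], 6L)
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write table to: ", path)
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' Converts interval columns back to the internal 0-based half-open
#' convention.
#'
#' @param path Path to a TSV written by [write_table()].
#' @return A data.frame with internal coordinates.
#' @export
read_result_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  for (cl in interval_start_cols(names(tab))) tab[[cl]] <- tab[[cl]] - 1L
  tab
}

# Fetch one protein's sequence / disorder table from a proteome.
pr_sequence <- function(p, acc) {
  p$records$sequence[match(acc, p$records$accession)]
}
pr_disorder <- function(p, acc) {
  iv <- p$disorder[[acc]]
  if (is.null(iv)) data.frame(start = integer(0), end = integer(0)) else iv
}

# Logical per-residue disorder mask for a protein of length `len`.
disorder_mask <- function(len, intervals) {
  mask <- logical(len)
  if (nrow(intervals) > 0L) {
    for (i in seq_len(nrow(intervals))) {
      mask[(intervals$start[i] + 1L):intervals$end[i]] <- TRUE
    }
  }
  mask
}
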