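# Domain context of RG motifs: domains-per-protein distributions,
# center-to-center motif-domain distances, per-domain-type distance summaries
# and instance-weighted domain GO summaries.

#' Domains-per-protein distribution
#'
#' Counts Pfam-style domain instances (not distinct types) per protein;
#' zero-domain proteins are included. The distinct-type count is reported
#' alongside.
#'
#' @param accessions Accessions of the set of interest.
#' @param domains Domain data.frame (`accession`, `start`, `end`,
#'   `domain_type`).
#' @return data.frame with `accession`, `n_domains` (instances),
#'   `n_domain_types`.
#' @export
domain_count_distribution <- function(accessions, domains) {
  rows <- lapply(sort(unique(accessions)), function(acc) {
    d <- domains[domains$accession == acc, , drop = FALSE]
    data.frame(accession = acc, n_domains = nrow(d),
               n_domain_types = length(unique(d$domain_type)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(accession = character(0), n_domains = integer(0),
                      n_domain_types = integer(0))
  }
  out
}

#' Center-to-center motif-domain distances
#'
#' All motif x domain pairs within each protein. Centers use the
#' even-length-rounds-toward-N-terminus convention; the signed distance is
#' domain center minus motif center, so positive means the domain lies
#' C-terminal of the motif. `single_pair` flags proteins with exactly one
#' motif and one domain.
#'
#' @param motifs Motif table (`accession`, `start`, `end`).
#' @param domains Domain table (`accession`, `start`, `end`, `domain_type`).
#' @return data.frame with `accession`, `domain_type`, `motif_start`,
#'   `motif_end`, `domain_start`, `domain_end`, `signed_distance`,
#'   `single_pair`.
#' @export
motif_domain_distances <- function(motifs, domains) {
  accs <- intersect(unique(motifs$accession), unique(domains$accession))
  rows <- lapply(accs, function(acc) {
    m <- motifs[motifs$accession == acc, , drop = FALSE]
    d <- domains[domains$accession == acc, , drop = FALSE]
    single <- nrow(m) == 1L && nrow(d) == 1L
    grid <- expand.grid(mi = seq_len(nrow(m)), di = seq_len(nrow(d)))
    data.frame(accession = acc,
               domain_type = d$domain_type[grid$di],
               motif_start = m$start[grid$mi], motif_end = m$end[grid$mi],
               domain_start = d$start[grid$di], domain_end = d$end[grid$di],
               signed_distance = interval_center(d$start[grid$di], d$end[grid$di]) -
                 interval_center(m$start[grid$mi], m$end[grid$mi]),
               single_pair = single,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(accession = character(0), domain_type = character(0),
                      motif_start = integer(0), motif_end = integer(0),
                      domain_start = integer(0), domain_end = integer(0),
                      signed_distance = integer(0), single_pair = logical(0))
  }
  out <- out[order(out$accession, out$motif_start, out$domain_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-domain-type distance summary
#'
#' Only domain types with at least `min_occurrences` motif-domain pairs are
#' reported. Side bias is the fraction of pairs with the domain C-terminal of
#' the motif (signed distance > 0).
#'
#' @param distances data.frame from [motif_domain_distances()].
#' @param min_occurrences Minimum pair count per type (default 10).
#' @return data.frame with `domain_type`, `n_pairs`, `median_distance`,
#'   `q25`, `q75`, `iqr`, `side_bias`, sorted by descending `n_pairs` then
#'   type.
#' @export
per_domain_type_table <- function(distances, min_occurrences = 10L) {
  types <- sort(unique(distances$domain_type))
  rows <- lapply(types, function(tp) {
    d <- distances$signed_distance[distances$domain_type == tp]
    if (length(d) < min_occurrences) return(NULL)
    qs <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(domain_type = tp, n_pairs = length(d),
               median_distance = qs[2L], q25 = qs[1L], q75 = qs[3L],
               iqr = qs[3L] - qs[1L], side_bias = mean(d > 0),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(domain_type = character(0), n_pairs = integer(0),
                      median_distance = numeric(0), q25 = numeric(0),
                      q75 = numeric(0), iqr = numeric(0),
                      side_bias = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_pairs, out$domain_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instance-weighted domain GO summary
#'
#' Each domain instance contributes its type's GO terms once; the summary is
#' therefore weighted by occurrence, and the fraction of instances with no GO
#' annotation is reported.
#'
#' @param domains Domain data.frame.
#' @param domain_go_map Named list mapping `domain_type` to a character
#'   vector of GO ids (possibly empty / missing types mean unannotated).
#' @return list with `n_instances`, `n_unannotated`, `unannotated_fraction`
#'   and `term_counts` (data.frame `term`, `count`, sorted by descending
#'   count then term).
#' @export
domain_go_summary <- function(domains, domain_go_map) {
  n_inst <- nrow(domains)
  if (n_inst == 0L) {
    return(list(n_instances = 0L, n_unannotated = 0L,
                unannotated_fraction = NA_real_,
                term_counts = data.frame(term = character(0),
                                         count = integer(0))))
  }
  terms_per_instance <- lapply(domains$domain_type, function(tp) {
    tt <- domain_go_map[[tp]]
    if (is.null(tt)) character(0) else tt
  })
  n_unann <- sum(vapply(terms_per_instance, length, integer(1)) == 0L)
  all_terms <- unlist(terms_per_instance)
  term_counts <- if (length(all_terms) == 0L) {
    data.frame(term = character(0), count = integer(0))
  } else {
    tab <- table(all_terms)
    df <- data.frame(term = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$term), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  list(n_instances = n_inst, n_unannotated = n_unann,
       unannotated_fraction = n_unann / n_inst,
       term_counts = term_counts)
}
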