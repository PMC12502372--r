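# Synthetic proteome generator with planted ground truth. Emits the same
# FASTA + annotation TSV the real pipeline reads, plus a truth JSON, so every
# stage is testable end to end without external databases.

#' Default disorder-biased amino-acid composition
#'
#' Background composition used for IDR residues: G, S, P, E, K and R elevated,
#' aromatics and aliphatics depressed, as is typical of disordered sequence.
#' @export
IDR_BASE_COMPOSITION <- c(
  A = 0.060, C = 0.005, D = 0.050, E = 0.090, F = 0.020, G = 0.110,
  H = 0.020, I = 0.025, K = 0.070, L = 0.045, M = 0.015, N = 0.035,
  P = 0.090, Q = 0.050, R = 0.080, S = 0.125, T = 0.050, V = 0.035,
  W = 0.005, Y = 0.020)

#' Default globular amino-acid composition
#'
#' Background composition for structured segments (ordinary globular
#' frequencies).
#' @export
GLOBULAR_COMPOSITION <- c(
  A = 0.080, C = 0.020, D = 0.055, E = 0.065, F = 0.040, G = 0.070,
  H = 0.025, I = 0.060, K = 0.060, L = 0.095, M = 0.020, N = 0.040,
  P = 0.045, Q = 0.040, R = 0.050, S = 0.065, T = 0.055, V = 0.070,
  W = 0.012, Y = 0.033)

#' Simulation configuration
#'
#' Defines the study conditions for a synthetic two-group proteome. Values
#' given as length-2 vectors named `positive`/`negative` differ between the
#' groups; defaults plant the qualitative direction of the effects the
#' pipeline is meant to detect: longer proteins and IDRs, more and more
#' RGG-like units, aromatic/N/D flank enrichment and higher arginine
#' methylation and phosphotyrosine rates in the positive group.
#'
#' @param n_positive,n_negative Proteins per study group (default 200 each).
#' @param n_collagen Collagen decoy proteins appended to exercise the
#'   collagen exclusion filter (default 3).
#' @param length_meanlog,length_sdlog Log-normal law for target protein
#'   length, per group.
#' @param n_oidr_lambda Poisson mean number of motif-free IDRs per protein.
#' @param oidr_len_meanlog,oidr_len_sdlog Log-normal law for oIDR lengths.
#' @param midr_extra_meanlog,midr_extra_sdlog Log-normal law for mIDR
#'   residues beyond motif + two flanks, per group.
#' @param units_extra_lambda Poisson mean of motif units beyond `min_units`,
#'   per group.
#' @param rgg_fraction Probability a motif unit is RGG rather than RG, per
#'   group.
#' @param spacer_probs Probabilities of inter-unit spacer lengths
#'   `0:max_spacer`.
#' @param flank_bias Named multiplicative enrichment applied to the positive
#'   group's flank and spacer composition (all multipliers 1 = null).
#' @param flank_width Biased flank width each side of the motif (default 30).
#' @param domain_types Named list of domain laws: each
#'   `list(offset, jitter, length, prob)` places the domain center at motif
#'   center + offset +/- jitter with per-protein probability `prob`;
#'   instances that would not fit in the protein are skipped.
#' @param ptm_rates List with `positive`/`negative` named vectors of PTM
#'   rates per 1,000 mIDR residues.
#' @param params [motif_params()] the planted motifs must satisfy.
#' @param na_go Nucleic-acid-binding GO ids granted to positive proteins.
#' @param decoy_go Pool of unrelated GO ids.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_positive = 200L, n_negative = 200L, n_collagen = 3L,
                       length_meanlog = c(positive = 6.35, negative = 6.10),
                       length_sdlog = 0.30,
                       n_oidr_lambda = c(positive = 1.6, negative = 1.0),
                       oidr_len_meanlog = 4.2, oidr_len_sdlog = 0.4,
                       midr_extra_meanlog = c(positive = 4.0, negative = 3.5),
                       midr_extra_sdlog = 0.5,
                       units_extra_lambda = c(positive = 4.0, negative = 2.5),
                       rgg_fraction = c(positive = 0.75, negative = 0.45),
                       spacer_probs = c(0.35, 0.25, 0.20, 0.12, 0.08),
                       flank_bias = c(F = 3.0, Y = 2.0, N = 1.8, D = 1.8),
                       flank_width = 30L,
                       domain_types = list(
                         KH_1 = list(offset = 40L, jitter = 5L,
                                     length = 60L, prob = 0.85),
                         ZnF_C2H2 = list(offset = -90L, jitter = 15L,
                                         length = 25L, prob = 0.30)),
                       ptm_rates = list(
                         positive = c("Phosphotyrosine" = 2.5,
                                      "Omega-N-methylarginine" = 4.0,
                                      "Asymmetric dimethylarginine" = 3.0,
                                      "Symmetric dimethylarginine" = 0.5),
                         negative = c("Phosphotyrosine" = 0.5,
                                      "Omega-N-methylarginine" = 0.8,
                                      "Asymmetric dimethylarginine" = 0.6,
                                      "Symmetric dimethylarginine" = 0.0)),
                       params = motif_params(),
                       na_go = c("GO:0003676", "GO:0003677", "GO:0003723"),
                       decoy_go = c("GO:0005975", "GO:0006412", "GO:0016192",
                                    "GO:0006914", "GO:0007165", "GO:0008152")) {
  stopifnot(all(flank_bias > 0), all(unlist(ptm_rates) >= 0),
            abs(sum(spacer_probs) - 1) < 1e-9,
            length(spacer_probs) == motif_params()$max_spacer + 1L ||
              length(spacer_probs) >= 1L)
  cfg <- list(n_positive = as.integer(n_positive),
              n_negative = as.integer(n_negative),
              n_collagen = as.integer(n_collagen),
              length_meanlog = length_meanlog, length_sdlog = length_sdlog,
              n_oidr_lambda = n_oidr_lambda,
              oidr_len_meanlog = oidr_len_meanlog,
              oidr_len_sdlog = oidr_len_sdlog,
              midr_extra_meanlog = midr_extra_meanlog,
              midr_extra_sdlog = midr_extra_sdlog,
              units_extra_lambda = units_extra_lambda,
              rgg_fraction = rgg_fraction, spacer_probs = spacer_probs,
              flank_bias = flank_bias, flank_width = as.integer(flank_width),
              domain_types = domain_types, ptm_rates = ptm_rates,
              params = params, na_go = na_go, decoy_go = decoy_go)
  class(cfg) <- "sim_config"
  cfg
}

#' Null simulation configuration
#'
#' The same generator with every group-dependent knob equalized: identical
#' length/IDR/motif laws, flank multipliers all 1 and equal PTM rates. Used
#' for calibration experiments where the two groups must be exchangeable.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_null <- function(...) {
  eq_rates <- c("Phosphotyrosine" = 1.0, "Omega-N-methylarginine" = 1.5,
                "Asymmetric dimethylarginine" = 1.0,
                "Symmetric dimethylarginine" = 0.3)
  sim_config(length_meanlog = c(positive = 6.2, negative = 6.2),
             n_oidr_lambda = c(positive = 1.2, negative = 1.2),
             midr_extra_meanlog = c(positive = 3.8, negative = 3.8),
             units_extra_lambda = c(positive = 3.0, negative = 3.0),
             rgg_fraction = c(positive = 0.6, negative = 0.6),
             flank_bias = c(F = 1.0, Y = 1.0, N = 1.0, D = 1.0),
             ptm_rates = list(positive = eq_rates, negative = eq_rates),
             ...)
}

sample_comp <- function(n, comp) {
  if (n <= 0L) return("")
  paste(sample(AA20, n, replace = TRUE, prob = comp), collapse = "")
}

# Planted residues get exactly bias * base proportion; the remaining
# probability mass is rescaled over the unplanted residues, so a multiplier
# of 3 yields a realized proportion 3x the base one.
reweight_comp <- function(comp, bias) {
  planted <- names(bias)
  target <- comp[planted] * bias
  if (sum(target) >= 1) stop("flank_bias multipliers exceed unit mass")
  w <- comp
  w[planted] <- target
  others <- setdiff(names(comp), planted)
  w[others] <- w[others] * (1 - sum(target)) / (1 - sum(comp[planted]))
  w / sum(w)
}

# Build one motif string from RGG/RG units and spacers; returns string + unit
# count. The first and last characters are always unit residues.
build_motif_string <- function(cfg, group, spacer_comp) {
  n_units <- cfg$params$min_units + stats::rpois(1L, cfg$units_extra_lambda[[group]])
  kinds <- ifelse(stats::runif(n_units) < cfg$rgg_fraction[[group]], "RGG", "RG")
  spacer_lens <- sample(seq_along(cfg$spacer_probs) - 1L, n_units - 1L,
                        replace = TRUE, prob = cfg$spacer_probs)
  parts <- character(2L * n_units - 1L)
  parts[seq(1L, 2L * n_units - 1L, by = 2L)] <- kinds
  if (n_units > 1L) {
    parts[seq(2L, 2L * n_units - 2L, by = 2L)] <-
      vapply(spacer_lens, sample_comp, character(1), comp = spacer_comp)
  }
  list(str = paste(parts, collapse = ""), n_units = n_units,
       last_kind = kinds[n_units])
}

# Remove R residues (replaced by K) in the flank positions close enough to
# the motif to chain a spurious unit onto the planted span, and neutralize a
# G immediately after a duplet-terminal motif (it would extend RG to RGG).
sanitize_motif_context <- function(chars, motif_start, motif_end, last_kind,
                                   max_spacer) {
  left_zone <- seq(max(1L, motif_start - max_spacer - 3L + 1L), motif_start)
  right_zone <- seq(motif_end + 1L,
                    min(length(chars), motif_end + max_spacer + 1L))
  for (i in c(left_zone, right_zone)) {
    if (i >= 1L && i <= length(chars) && chars[i] == "R") chars[i] <- "K"
  }
  if (last_kind == "RG" && motif_end + 1L <= length(chars) &&
      chars[motif_end + 1L] == "G") {
    chars[motif_end + 1L] <- "S"
  }
  chars
}

# Generate one synthetic protein; returns NULL if the planted motif is not
# recovered exactly by the configured detector (caller retries).
generate_protein_once <- function(cfg, group, flank_comp, spacer_comp) {
  L_target <- max(250L, min(4000L, round(stats::rlnorm(
    1L, cfg$length_meanlog[[group]], cfg$length_sdlog))))
  motif <- build_motif_string(cfg, group, spacer_comp)
  motif_len <- nchar(motif$str)
  fw <- cfg$flank_width
  extra <- max(0L, round(stats::rlnorm(1L, cfg$midr_extra_meanlog[[group]],
                                       cfg$midr_extra_sdlog)))
  extra_left <- extra %/% 2L
  extra_right <- extra - extra_left
  midr_str <- paste0(sample_comp(extra_left, IDR_BASE_COMPOSITION),
                     sample_comp(fw, flank_comp),
                     motif$str,
                     sample_comp(fw, flank_comp),
                     sample_comp(extra_right, IDR_BASE_COMPOSITION))
  motif_in_idr <- extra_left + fw          # 0-based offset within the mIDR
  ch <- strsplit(midr_str, "", fixed = TRUE)[[1L]]
  ch <- sanitize_motif_context(ch, motif_in_idr, motif_in_idr + motif_len,
                               motif$last_kind, cfg$params$max_spacer)
  midr_str <- paste(ch, collapse = "")
  midr_len <- nchar(midr_str)

  s0 <- max(40L, round(stats::rlnorm(1L, 4.3, 0.35)))
  s1 <- max(130L, round(stats::rlnorm(1L, 4.9, 0.30)))
  segs <- list(list(kind = "struct", len = s0),
               list(kind = "midr", len = midr_len),
               list(kind = "struct", len = s1))
  n_oidr <- stats::rpois(1L, cfg$n_oidr_lambda[[group]])
  for (k in seq_len(n_oidr)) {
    segs <- c(segs, list(
      list(kind = "oidr",
           len = max(30L, round(stats::rlnorm(1L, cfg$oidr_len_meanlog,
                                              cfg$oidr_len_sdlog)))),
      list(kind = "struct", len = max(30L, round(stats::rlnorm(1L, 3.8, 0.3))))))
  }
  built <- sum(vapply(segs, `[[`, numeric(1), "len"))
  tail_len <- L_target - built
  if (tail_len >= 20L) segs <- c(segs, list(list(kind = "struct", len = tail_len)))

  pieces <- character(length(segs))
  starts <- integer(length(segs))
  pos <- 0L
  disorder_s <- integer(0); disorder_e <- integer(0)
  midr_start <- NA_integer_
  for (i in seq_along(segs)) {
    sg <- segs[[i]]
    starts[i] <- pos
    pieces[i] <- switch(sg$kind,
                        struct = sample_comp(sg$len, GLOBULAR_COMPOSITION),
                        oidr = sample_comp(sg$len, IDR_BASE_COMPOSITION),
                        midr = midr_str)
    if (sg$kind != "struct") {
      disorder_s <- c(disorder_s, pos); disorder_e <- c(disorder_e, pos + sg$len)
    }
    if (sg$kind == "midr") midr_start <- pos
    pos <- pos + sg$len
  }
  sequence <- paste(pieces, collapse = "")
  L <- nchar(sequence)
  motif_start <- midr_start + motif_in_idr
  motif_end <- motif_start + motif_len
  disorder <- data.frame(start = disorder_s, end = disorder_e)
  disorder <- disorder[order(disorder$start), , drop = FALSE]

  # planted motif must be recovered exactly by the configured detector
  hits <- filter_by_disorder(find_motifs(sequence, cfg$params), disorder)
  if (!any(hits$start == motif_start & hits$end == motif_end)) return(NULL)

  motif_center <- interval_center(motif_start, motif_end)
  doms <- list()
  for (tp in names(cfg$domain_types)) {
    law <- cfg$domain_types[[tp]]
    if (stats::runif(1L) >= law$prob) next
    offset <- law$offset + sample(seq(-law$jitter, law$jitter), 1L)
    center_d <- motif_center + offset
    ds <- center_d - (law$length - 1L) %/% 2L
    de <- ds + law$length
    if (ds < 0L || de > L) next
    doms[[length(doms) + 1L]] <- data.frame(
      domain_type = tp, start = ds, end = de, planted_offset = offset,
      stringsAsFactors = FALSE)
  }
  domains <- if (length(doms) > 0L) do.call(rbind, doms) else
    data.frame(domain_type = character(0), start = integer(0),
               end = integer(0), planted_offset = integer(0))

  rates <- cfg$ptm_rates[[group]]
  midr_iv <- c(midr_start, midr_start + midr_len)
  ptm_rows <- list()
  for (modname in names(rates)) {
    lam <- rates[[modname]] / 1000 * midr_len
    n_sites <- stats::rpois(1L, lam)
    if (n_sites == 0L) next
    n_sites <- min(n_sites, midr_len)
    pos_s <- sort(sample(seq(midr_iv[1L], midr_iv[2L] - 1L), n_sites))
    ptm_rows[[length(ptm_rows) + 1L]] <-
      data.frame(pos = pos_s, modification = modname, stringsAsFactors = FALSE)
  }
  ptm <- if (length(ptm_rows) > 0L) do.call(rbind, ptm_rows) else
    data.frame(pos = integer(0), modification = character(0))

  saps <- if (group == "positive") stats::runif(1L, 0.55, 0.98)
          else stats::runif(1L, 0.05, 0.50)
  go <- if (group == "positive") {
    c(sample(cfg$na_go, 1L),
      sample(cfg$decoy_go, stats::rbinom(1L, 2L, 0.5)))
  } else {
    sample(cfg$decoy_go, 1L + stats::rbinom(1L, 2L, 0.5))
  }
  list(sequence = sequence, length = L, disorder = disorder,
       motif = c(motif_start, motif_end), midr = midr_iv,
       domains = domains, ptm = ptm, saps = saps, go = sort(unique(go)))
}

collagen_decoy <- function(i) {
  unit <- "GPPGPRGEKGAPGPRGERGFPGERGLQGPP"
  sequence <- paste(rep(unit, 12L), collapse = "")
  list(sequence = sequence, length = nchar(sequence),
       disorder = data.frame(start = 0L, end = nchar(sequence)),
       saps = 0.2, go = character(0))
}

#' Generate a synthetic study on disk
#'
#' Writes `proteome.fasta`, `annotations.tsv`, `na_go.txt`,
#' `domain_go_map.tsv` and `truth.json` under `dir`. Deterministic given
#' `seed`: the same seed yields byte-identical files. Positive proteins
#' receive a phase-separation score above 0.5 and one nucleic-acid-binding GO
#' term; negative proteins neither. Every study protein carries exactly one
#' planted motif inside a disorder segment, built to satisfy the configured
#' [motif_params()]; a protein whose planted motif is not recovered exactly
#' by the detector is re-drawn (bounded retries).
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param seed Integer RNG seed.
#' @return Invisibly, a list with `dir`, file paths and the ground `truth`
#'   (protein table, planted domain offsets, planted PTM sites, flank bias).
#' @export
generate_study <- function(cfg, dir, seed) {
  set.seed(as.integer(seed))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flank_comp_pos <- reweight_comp(IDR_BASE_COMPOSITION, cfg$flank_bias)
  groups <- c(rep("positive", cfg$n_positive), rep("negative", cfg$n_negative))
  n_study <- length(groups)

  fasta_lines <- character(0)
  ann <- list(data.frame(accession = character(0), kind = character(0),
                         payload = character(0)))
  truth_proteins <- list(); truth_domains <- list(); truth_ptm <- list()

  for (i in seq_len(n_study)) {
    group <- groups[i]
    flank_comp <- if (group == "positive") flank_comp_pos else IDR_BASE_COMPOSITION
    spacer_comp <- flank_comp
    prot <- NULL
    for (try in seq_len(50L)) {
      prot <- generate_protein_once(cfg, group, flank_comp, spacer_comp)
      if (!is.null(prot)) break
    }
    if (is.null(prot)) stop("generate_study: could not plant a motif after 50 tries")
    acc <- sprintf("SP%04d", i)
    gene <- sprintf("RGS%d", i)
    fasta_lines <- c(fasta_lines,
                     sprintf(">sp|%s|%s_HUMAN Synthetic RG-motif protein %d GN=%s",
                             acc, gene, i, gene),
                     substring(prot$sequence,
                               seq(1L, prot$length, 60L),
                               pmin(seq(1L, prot$length, 60L) + 59L, prot$length)))
    rows <- data.frame(
      accession = acc, kind = "disorder",
      payload = sprintf("%d-%d", prot$disorder$start + 1L, prot$disorder$end),
      stringsAsFactors = FALSE)
    if (nrow(prot$domains) > 0L) {
      rows <- rbind(rows, data.frame(
        accession = acc, kind = "domain",
        payload = sprintf("%d-%d:%s", prot$domains$start + 1L,
                          prot$domains$end, prot$domains$domain_type)))
    }
    if (length(prot$go) > 0L) {
      rows <- rbind(rows, data.frame(accession = acc, kind = "go",
                                     payload = prot$go))
    }
    rows <- rbind(rows, data.frame(accession = acc, kind = "saps",
                                   payload = sprintf("%.6f", prot$saps)))
    if (nrow(prot$ptm) > 0L) {
      rows <- rbind(rows, data.frame(
        accession = acc, kind = "ptm",
        payload = sprintf("%d:%s", prot$ptm$pos + 1L, prot$ptm$modification)))
    }
    ann[[length(ann) + 1L]] <- rows
    truth_proteins[[i]] <- data.frame(
      accession = acc, group = group, length = prot$length,
      motif_start = prot$motif[1L], motif_end = prot$motif[2L],
      midr_start = prot$midr[1L], midr_end = prot$midr[2L],
      saps = prot$saps, stringsAsFactors = FALSE)
    if (nrow(prot$domains) > 0L) {
      truth_domains[[length(truth_domains) + 1L]] <- data.frame(
        accession = acc, domain_type = prot$domains$domain_type,
        planted_offset = prot$domains$planted_offset, stringsAsFactors = FALSE)
    }
    if (nrow(prot$ptm) > 0L) {
      truth_ptm[[length(truth_ptm) + 1L]] <- data.frame(
        accession = acc, modification = prot$ptm$modification,
        pos = prot$ptm$pos, stringsAsFactors = FALSE)
    }
  }

  for (k in seq_len(cfg$n_collagen)) {
    dec <- collagen_decoy(k)
    acc <- sprintf("CL%04d", k)
    gene <- sprintf("COL%dA1", k)
    fasta_lines <- c(fasta_lines,
                     sprintf(">sp|%s|CO%dA1_HUMAN Collagen alpha chain synthetic decoy %d GN=%s",
                             acc, k, k, gene),
                     substring(dec$sequence,
                               seq(1L, dec$length, 60L),
                               pmin(seq(1L, dec$length, 60L) + 59L, dec$length)))
    ann[[length(ann) + 1L]] <- data.frame(
      accession = acc,
      kind = c("disorder", "saps"),
      payload = c(sprintf("%d-%d", dec$disorder$start + 1L, dec$disorder$end),
                  sprintf("%.6f", dec$saps)),
      stringsAsFactors = FALSE)
  }

  fasta_path <- file.path(dir, "proteome.fasta")
  ann_path <- file.path(dir, "annotations.tsv")
  na_go_path <- file.path(dir, "na_go.txt")
  dgo_path <- file.path(dir, "domain_go_map.tsv")
  truth_path <- file.path(dir, "truth.json")
  writeLines(fasta_lines, fasta_path)
  utils::write.table(do.call(rbind, ann), ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  writeLines(cfg$na_go, na_go_path)
  utils::write.table(
    data.frame(domain_type = "KH_1", go = "GO:0003723"),
    dgo_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)

  truth <- list(
    proteins = do.call(rbind, truth_proteins),
    domains = if (length(truth_domains) > 0L) do.call(rbind, truth_domains) else
      data.frame(accession = character(0), domain_type = character(0),
                 planted_offset = integer(0)),
    ptm = if (length(truth_ptm) > 0L) do.call(rbind, truth_ptm) else
      data.frame(accession = character(0), modification = character(0),
                 pos = integer(0)),
    flank_bias = as.list(cfg$flank_bias),
    planted_domain_offsets = lapply(cfg$domain_types, `[[`, "offset"),
    ptm_rates = cfg$ptm_rates,
    seed = as.integer(seed))
  jsonlite::write_json(truth, truth_path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, fasta = fasta_path, annotations = ann_path,
                 na_go = na_go_path, domain_go_map = dgo_path,
                 truth_json = truth_path, truth = truth))
}

#' Check pipeline outputs against planted ground truth
#'
#' Reports exact-span motif recall and precision, study-set membership
#' accuracy, per-domain-type recovered median offsets and the sign agreement
#' of the mIDR enrichment-heatmap fold changes for the planted flank-biased
#' residues.
#'
#' @param results List returned by [run_all()].
#' @param truth Ground truth from [generate_study()].
#' @return list with `motif_recall`, `motif_precision`, `set_accuracy`,
#'   `domain_offsets` (data.frame per type: planted vs recovered median) and
#'   `heatmap_sign_agreement` (fraction, `NA` if no residue was biased).
#' @export
truth_check <- function(results, truth) {
  planted <- truth$proteins
  key <- function(df, s, e) paste(df$accession, df[[s]], df[[e]])
  planted_keys <- key(planted, "motif_start", "motif_end")
  detected_keys <- paste(results$motifs$accession, results$motifs$start,
                         results$motifs$end)
  motif_recall <- mean(planted_keys %in% detected_keys)
  motif_precision <- mean(detected_keys %in% planted_keys)

  mem <- results$membership
  idx <- match(planted$accession, mem$accession)
  set_accuracy <- mean(mem$set[idx] == planted$group, na.rm = TRUE)

  dom <- NULL
  if (nrow(results$distances) > 0L && nrow(truth$domains) > 0L) {
    types <- sort(unique(truth$domains$domain_type))
    dom <- do.call(rbind, lapply(types, function(tp) {
      rec <- results$distances$signed_distance[
        results$distances$domain_type == tp]
      data.frame(domain_type = tp,
                 planted_offset = truth$planted_domain_offsets[[tp]],
                 n_pairs = length(rec),
                 recovered_median = stats::median(rec),
                 side_bias = mean(rec > 0), stringsAsFactors = FALSE)
    }))
  }

  bias <- unlist(truth$flank_bias)
  biased <- names(bias)[bias != 1]
  sign_agree <- NA_real_
  if (length(biased) > 0L && !is.null(results$heatmap)) {
    hm <- results$heatmap
    cells <- hm[hm$class == "mIDR" & hm$aa %in% biased, , drop = FALSE]
    sign_agree <- mean(sign(cells$log2fc) == sign(log(bias[cells$aa])))
  }
  list(motif_recall = motif_recall, motif_precision = motif_precision,
       set_accuracy = set_accuracy, domain_offsets = dom,
       heatmap_sign_agreement = sign_agree)
}
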