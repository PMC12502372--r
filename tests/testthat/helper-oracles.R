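# Independent oracles and fixture builders used across the test files.

# Random sequence over an R/G-enriched alphabet (motif-prone on purpose).
random_rg_sequence <- function(max_len = 200L) {
  n <- sample.int(max_len, 1L)
  paste(sample(c("R", "G", "A", "S", "F", "P"), n, replace = TRUE,
               prob = c(0.30, 0.30, 0.12, 0.12, 0.08, 0.08)),
        collapse = "")
}

# Regex-based unit scanner: gregexpr's leftmost non-overlapping matching with
# RGG preferred over RG at the same position reproduces the greedy rule by a
# completely different mechanism.
oracle_scan_units <- function(sequence) {
  m <- gregexpr("RGG|RG", sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L, end = as.integer(m) - 1L + len,
             kind = ifelse(len == 3L, "RGG", "RG"), stringsAsFactors = FALSE)
}

# Brute-force chain enumeration: every contiguous unit index range is tested
# for validity (all gaps within max_spacer), size and maximality.
oracle_assemble <- function(units, params) {
  n <- nrow(units)
  out <- list()
  if (n == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_units = integer(0)))
  }
  gap <- function(i, j) units$start[j] - units$end[i]
  for (i in seq_len(n)) {
    for (j in i:n) {
      ok <- j - i + 1L >= params$min_units
      if (ok && j > i) {
        for (k in i:(j - 1L)) {
          if (gap(k, k + 1L) > params$max_spacer) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      left_max <- i == 1L || gap(i - 1L, i) > params$max_spacer
      right_max <- j == n || gap(j, j + 1L) > params$max_spacer
      if (left_max && right_max) {
        out[[length(out) + 1L]] <- data.frame(start = units$start[i],
                                              end = units$end[j],
                                              n_units = j - i + 1L)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_units = integer(0)))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups.
oracle_mwu_exact <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  subsets <- utils::combn(length(vals), n1)
  u_of <- function(idx) {
    xs <- vals[idx]; ys <- vals[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  us <- apply(subsets, 2L, u_of)
  u_obs <- u_of(seq_len(n1))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Naive per-window recomputation of the sliding-window composition profile.
oracle_window_profile <- function(p, motifs, max_offset, half_width) {
  axis <- expand.grid(offset = seq_len(max_offset),
                      side = c("left", "right"),
                      stringsAsFactors = FALSE)[, c("side", "offset")]
  counts <- matrix(0, nrow = nrow(axis), ncol = 20L,
                   dimnames = list(NULL, rgcontext::AA20))
  nw <- integer(nrow(axis))
  for (i in seq_len(nrow(motifs))) {
    acc <- motifs$accession[i]
    s <- p$records$sequence[p$records$accession == acc]
    dis <- p$disorder[[acc]]
    for (j in seq_len(nrow(axis))) {
      focal <- if (axis$side[j] == "left") motifs$start[i] - axis$offset[j]
               else motifs$end[i] - 1L + axis$offset[j]
      ws <- focal - half_width; we <- focal + half_width + 1L
      if (ws < 0L || we > nchar(s)) next
      inside <- FALSE
      if (nrow(dis) > 0L) {
        inside <- any(dis$start <= ws & we <= dis$end)
      }
      if (!inside) next
      frag <- strsplit(substr(s, ws + 1L, we), "")[[1L]]
      tab <- table(factor(frag, levels = rgcontext::AA20))
      counts[j, ] <- counts[j, ] + as.integer(tab)
      nw[j] <- nw[j] + 1L
    }
  }
  list(axis = axis, counts = counts, n_windows = nw)
}

# Textbook Pearson r from raw sums.
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# Closed-form hypergeometric upper tail via binomial coefficients.
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Minimal in-code proteome: records + annotations from plain arguments.
make_proteome <- function(seqs, disorder = NULL, domains = NULL, go = NULL,
                          saps = NULL, ptm = NULL,
                          na_binding_go = "GO:0003723") {
  records <- data.frame(accession = names(seqs), gene_name = NA_character_,
                        description = "", sequence = unname(seqs),
                        length = nchar(seqs), stringsAsFactors = FALSE)
  proteome(records, disorder = disorder, domains = domains, go = go,
           saps = saps, ptm = ptm, na_binding_go = na_binding_go)
}

iv <- function(start, end) data.frame(start = start, end = end)
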