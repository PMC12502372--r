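test_that("physicochemical properties follow the stated conventions", {
  pp <- physchem_properties("AAAAAAAAAA")
  expect_equal(pp$hydropathy, (1.8 + 4.5) / 9)  # Kyte-Doolittle, rescaled
  expect_equal(pp$ncpr, 0)
  expect_equal(pp$disorder_promoting_fraction, 1)

  pr <- physchem_properties("RRRRRRRRRR")
  expect_equal(pr$ncpr, 1)
  expect_equal(pr$aromaticity, 0)

  # histidine is neutral for NCPR; X occupies length but is not counted
  expect_equal(physchem_properties("HHHH")$ncpr, 0)
  px <- physchem_properties("RXRX")
  expect_equal(px$ncpr, 2 / 4)
  expect_equal(sum(count_aa("RXRX")), 2L)
})

test_that("NCPR is reversal-invariant and hydropathy permutation-invariant", {
  set.seed(301)
  for (i in 1:30) {
    s <- paste(sample(rgcontext::AA20, 25, replace = TRUE), collapse = "")
    rev_s <- paste(rev(strsplit(s, "")[[1L]]), collapse = "")
    perm <- paste(sample(strsplit(s, "")[[1L]]), collapse = "")
    expect_equal(physchem_properties(s)$ncpr,
                 physchem_properties(rev_s)$ncpr)
    expect_equal(physchem_properties(s)$hydropathy,
                 physchem_properties(perm)$hydropathy)
  }
})

test_that("flank blocks require full IDR containment", {
  s <- strrep("A", 40)
  # motif at the N-terminus: no left block; right block only if inside an IDR
  b1 <- block_properties(s, 0L, 6L, iv(0L, 16L))
  expect_equal(b1$region_id, c("motif", "right_block"))
  b2 <- block_properties(s, 0L, 6L, iv(0L, 15L))  # (6,16) not contained
  expect_equal(b2$region_id, "motif")
  b3 <- block_properties(s, 12L, 20L, iv(0L, 40L))
  expect_equal(b3$region_id, c("motif", "left_block", "right_block"))
  expect_equal(b3$block_start[b3$region_id == "left_block"], 2L)
})

test_that("sliding-window profile counts windows per the containment rule", {
  # motif (10,17) in IDR (0,40): right offset 1 focal = 17, window (13,22)
  s <- paste0(strrep("G", 13), strrep("A", 9), strrep("G", 20))
  p <- make_proteome(c(P1 = s), disorder = list(P1 = iv(0L, 40L)))
  motifs <- data.frame(accession = "P1", start = 10L, end = 17L)
  prof <- sliding_window_profile(p, motifs, max_offset = 5L, half_width = 4L)
  r1 <- prof[prof$side == "right" & prof$offset == 1L, ]
  expect_equal(r1$n_windows, 1L)
  expect_equal(r1$A, 9 / 9)  # window (13,22) is exactly the A stretch

  # a window crossing the IDR boundary is excluded: right offset 4 has
  # window (16,25) but the IDR ends at 24
  p2 <- make_proteome(c(P1 = s), disorder = list(P1 = iv(0L, 24L)))
  prof2 <- sliding_window_profile(p2, motifs, max_offset = 5L, half_width = 4L)
  expect_equal(prof2$n_windows[prof2$side == "right" & prof2$offset == 3L], 1L)
  expect_equal(prof2$n_windows[prof2$side == "right" & prof2$offset == 4L], 0L)
  expect_true(is.na(prof2$A[prof2$side == "right" & prof2$offset == 4L]))

  # uniform poly-G flank: once the window clears the motif (offset >= 5 at
  # half-width 4) the G proportion is exactly 1; closer windows still see
  # only motif R/G residues
  s3 <- paste0(strrep("G", 30), "RGGRGGRGG", strrep("G", 30))
  p3 <- make_proteome(c(P1 = s3), disorder = list(P1 = iv(0L, nchar(s3))))
  m3 <- data.frame(accession = "P1", start = 30L, end = 39L)
  prof3 <- sliding_window_profile(p3, m3, max_offset = 10L, half_width = 4L)
  left <- prof3[prof3$side == "left", ]
  expect_true(all(left$G[left$n_windows > 0 & left$offset >= 5L] == 1))
  near <- left[left$n_windows > 0 & left$offset < 5L, ]
  expect_true(all(near$G + near$R == 1))
})

test_that("composition vectors sum to one wherever windows contributed", {
  set.seed(302)
  st <- generate_study(sim_config(n_positive = 15L, n_negative = 15L),
                       withr::local_tempdir(), seed = 302)
  rec <- read_fasta(st$fasta)
  p <- read_annotations(st$annotations, rec, readLines(st$na_go))
  motifs <- proteome_motifs(p)
  prof <- sliding_window_profile(p, motifs, max_offset = 20L)
  sums <- rowSums(prof[, rgcontext::AA20])
  expect_true(all(abs(sums[prof$n_windows > 0] - 1) < 1e-9))
})

test_that("region composition re-sums to the sequence content", {
  set.seed(303)
  for (i in 1:25) {
    len <- sample(60:200, 1L)
    s <- paste(sample(rgcontext::AA20, len, replace = TRUE), collapse = "")
    starts <- sample(0:(len - 15L), 2L)
    ends <- pmin(len, starts + sample(5:15, 2L, replace = TRUE))
    dis <- rgcontext:::merge_intervals(starts, ends)
    motifs <- data.frame(start = dis$start[1L],
                         end = min(dis$end[1L], dis$start[1L] + 6L))
    rmap <- build_region_map(len, dis, motifs)
    comp <- region_composition(rmap, s)
    expect_equal(colSums(comp), count_aa(s))
    expect_equal(sum(comp), len)
  }
})

test_that("enrichment heatmap is null for identical sets and tracks planted counts", {
  seqs <- c(P1 = paste0(strrep("G", 10), "RGGRGGRGG", strrep("G", 10)),
            P2 = paste0(strrep("S", 10), "RGGRGGRGG", strrep("S", 10)))
  dis <- list(P1 = iv(0L, 29L), P2 = iv(0L, 29L))
  p <- make_proteome(seqs, disorder = dis)
  motifs <- data.frame(accession = c("P1", "P2"), start = 10L, end = 19L)
  maps <- proteome_region_maps(p, motifs)
  hm <- enrichment_heatmap(p, maps, c("P1", "P2"), c("P1", "P2"))
  expect_true(all(hm$log2fc[!is.na(hm$log2fc)] == 0))

  # doubling the F share of large pooled counts gives log2FC close to 1
  f_rich <- paste0(strrep("FA", 200), "RGGRGGRGG", strrep("FA", 200))
  f_poor <- paste0(strrep("FAAA", 100), "RGGRGGRGG", strrep("FAAA", 100))
  p2 <- make_proteome(c(A1 = f_rich, B1 = f_poor),
                      disorder = list(A1 = iv(0L, nchar(f_rich)),
                                      B1 = iv(0L, nchar(f_poor))))
  m2 <- data.frame(accession = c("A1", "B1"), start = 400L, end = 409L)
  maps2 <- proteome_region_maps(p2, m2)
  hm2 <- enrichment_heatmap(p2, maps2, "A1", "B1")
  got <- hm2$log2fc[hm2$aa == "F" & hm2$class == "mIDR"]
  expect_equal(got, 1, tolerance = 0.02)
})

test_that("IDR background pools all proteins and matches a length-weighted mean", {
  p <- make_proteome(c(P1 = "GGRRAA", P2 = "AAAAGG"),
                     disorder = list(P1 = iv(0L, 4L), P2 = iv(4L, 6L)))
  bg <- idr_background(p)
  expect_equal(unname(bg["G"]), 4 / 6)
  expect_equal(unname(bg["R"]), 2 / 6)
  expect_equal(sum(bg), 1)

  set.seed(304)
  st <- generate_study(sim_config(n_positive = 10L, n_negative = 10L),
                       withr::local_tempdir(), seed = 304)
  rec <- read_fasta(st$fasta)
  p2 <- read_annotations(st$annotations, rec, readLines(st$na_go))
  bg2 <- idr_background(p2)
  # independent recomputation: per-IDR compositions weighted by IDR length
  num <- stats::setNames(numeric(20), rgcontext::AA20)
  den <- 0
  for (acc in names(p2$disorder)) {
    ivs <- p2$disorder[[acc]]
    s <- p2$records$sequence[p2$records$accession == acc]
    for (j in seq_len(nrow(ivs))) {
      frag <- substr(s, ivs$start[j] + 1L, ivs$end[j])
      cnt <- count_aa(frag)
      num <- num + cnt
      den <- den + sum(cnt)
    }
  }
  expect_equal(bg2, num / den, tolerance = 1e-12)

  p_none <- make_proteome(c(P1 = "AAAA"))
  expect_error(idr_background(p_none), "no disorder")
})
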