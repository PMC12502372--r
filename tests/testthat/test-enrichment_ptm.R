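test_that("motif regions extend 30 residues each side, clipped to the sequence", {
  s <- paste0(strrep("Y", 20), "RGGRGGRGG", strrep("F", 50))
  p <- make_proteome(c(P1 = s))
  motifs <- data.frame(accession = "P1", start = 20L, end = 29L)
  reg <- motif_regions(p, motifs, flank = 30L)
  expect_equal(reg$region_start, 0L)   # clipped at the N-terminus
  expect_equal(reg$region_end, 59L)
  expect_equal(reg$Y, 20L)
  expect_equal(reg$F, 30L)
})

test_that("aromatic sets apply the residue threshold and are monotone in it", {
  counts <- data.frame(accession = c("P1", "P2", "P3"),
                       Y = c(5L, 4L, 5L), F = c(0L, 7L, 5L))
  s5 <- aromatic_sets(counts, 5L)
  expect_equal(s5$y_set, c("P1", "P3"))
  expect_equal(s5$f_set, c("P2", "P3"))
  expect_equal(s5$overlap, "P3")

  for (k in 1:8) {
    lo <- aromatic_sets(counts, k)
    hi <- aromatic_sets(counts, k + 1L)
    expect_true(all(hi$y_set %in% lo$y_set))
    expect_true(all(hi$f_set %in% lo$f_set))
  }
})

test_that("GO enrichment reproduces the hypergeometric tail", {
  bg <- sprintf("P%02d", 1:20)
  fg <- bg[1:10]
  go <- stats::setNames(c(as.list(rep("GO:X", 10L)),
                          as.list(rep("GO:Z", 10L))), bg)
  res <- go_enrichment(fg, bg, go)
  row <- res[res$term == "GO:X", ]
  expect_equal(row$p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(row$k, 10L)
  expect_equal(row$odds_ratio, Inf)

  # foreground = background: every p is 1
  res2 <- go_enrichment(bg, bg, go)
  expect_true(all(res2$p == 1))

  # equal in/out frequency: odds ratio about 1
  go3 <- stats::setNames(as.list(rep(c("GO:Y", "none"), 10L)), bg)
  res3 <- go_enrichment(bg[1:10], bg, go3)
  expect_equal(res3$odds_ratio[res3$term == "GO:Y"], 1)
})

test_that("hypergeometric p matches closed-form and fisher.test on small tables", {
  set.seed(501)
  for (i in 1:40) {
    N <- sample(6:30, 1L)
    n <- sample(2:(N - 1L), 1L)
    K <- sample(1:N, 1L)
    bg <- sprintf("P%02d", seq_len(N))
    fg <- sample(bg, n)
    with_term <- sample(bg, K)
    go <- stats::setNames(lapply(bg, function(a) {
      if (a %in% with_term) "GO:T" else character(0)
    }), bg)
    res <- go_enrichment(fg, bg, go)
    k <- sum(fg %in% with_term)
    expect_equal(res$p, oracle_hyper_tail(k, K, N, n), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(k, n - k, K - k, N - n - (K - k)), 2L),
                             alternative = "greater")
    expect_equal(res$p, ft$p.value, tolerance = 1e-9)
  }
})

ptm_fixture <- function(split_disorder = FALSE) {
  s <- paste0(strrep("A", 10), strrep("G", 20), "RGGRGGRGG",
              strrep("G", 20), strrep("A", 10))
  dis_rows <- if (split_disorder) {
    c("P1\tdisorder\t11-30", "P1\tdisorder\t31-49", "P1\tdisorder\t50-59")
  } else {
    "P1\tdisorder\t11-59"
  }
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("accession\tkind\tpayload",
               "P1\tsaps\t0.9", "P1\tgo\tGO:0003723", dis_rows,
               "P1\tptm\t15:Phosphotyrosine", "P1\tptm\t40:Phosphotyrosine",
               "P2\tsaps\t0.1", "P2\tdisorder\t11-59"), f)
  rec <- data.frame(accession = c("P1", "P2"), gene_name = NA,
                    description = "",
                    sequence = c(s, s), length = nchar(s))
  read_annotations(f, rec, na_binding_go = "GO:0003723")
}

test_that("PTM rates normalize per 1,000 mIDR residues and survive row splitting", {
  for (split in c(FALSE, TRUE)) {
    p <- ptm_fixture(split)
    motifs <- proteome_motifs(p)
    mem <- build_sets(p, motifs)
    maps <- proteome_region_maps(p, motifs)
    res <- ptm_enrichment(mem, maps, motifs, p,
                          modification_names = c("Phosphotyrosine",
                                                 "Acetyllysine"))
    py <- res[res$modification == "Phosphotyrosine", ]
    expect_equal(py$n_sites_positive, 2L)
    expect_equal(py$scope_residues_positive, 49)     # the merged mIDR
    expect_equal(py$rate_positive, 1000 * 2 / 49)
    expect_equal(py$n_sites_negative, 0L)
    expect_equal(py$rate_negative, 0)

    # a modification absent everywhere is reported with zero counts
    ak <- res[res$modification == "Acetyllysine", ]
    expect_equal(ak$n_sites_positive + ak$n_sites_negative, 0L)
  }
  # splitting the disorder annotation into adjacent rows changes nothing
  r1 <- ptm_enrichment(build_sets(ptm_fixture(FALSE),
                                  proteome_motifs(ptm_fixture(FALSE))),
                       proteome_region_maps(ptm_fixture(FALSE),
                                            proteome_motifs(ptm_fixture(FALSE))),
                       proteome_motifs(ptm_fixture(FALSE)), ptm_fixture(FALSE),
                       modification_names = "Phosphotyrosine")
  r2 <- ptm_enrichment(build_sets(ptm_fixture(TRUE),
                                  proteome_motifs(ptm_fixture(TRUE))),
                       proteome_region_maps(ptm_fixture(TRUE),
                                            proteome_motifs(ptm_fixture(TRUE))),
                       proteome_motifs(ptm_fixture(TRUE)), ptm_fixture(TRUE),
                       modification_names = "Phosphotyrosine")
  expect_equal(r1[, -1L], r2[, -1L])
})
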