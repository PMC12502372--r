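test_that("region map assigns the four classes with motif precedence", {
  rm1 <- build_region_map(30L, iv(0L, 20L), data.frame(start = 5L, end = 12L))
  widths <- tapply(rm1$segments$end - rm1$segments$start,
                   rm1$segments$class, sum)
  expect_equal(as.vector(widths[c("motif", "mIDR", "structured")]),
               c(7L, 13L, 10L))
  expect_false("oIDR" %in% names(widths))

  rm2 <- build_region_map(30L, iv(0L, 10L),
                          data.frame(start = integer(0), end = integer(0)))
  w2 <- tapply(rm2$segments$end - rm2$segments$start, rm2$segments$class, sum)
  expect_equal(as.vector(w2[c("oIDR", "structured")]), c(10L, 20L))

  # motif straddling the IDR edge keeps class motif for all its residues
  rm3 <- build_region_map(30L, iv(0L, 10L), data.frame(start = 8L, end = 14L))
  seg <- rm3$segments
  expect_equal(seg$class[seg$start == 0L], "mIDR")
  expect_equal(seg$end[seg$class == "mIDR"], 8L)
  expect_equal(seg$class[seg$start == 8L], "motif")
  expect_equal(seg$end[seg$class == "motif"], 14L)
  expect_equal(seg$class[seg$start == 14L], "structured")

  expect_error(build_region_map(10L, iv(0L, 5L),
                                data.frame(start = 8L, end = 14L)),
               "bounds")
})

test_that("relative motif position follows the centered convention", {
  expect_equal(relative_motif_position(10L, 20L, 0L, 29L), 0.5)
  expect_equal(relative_motif_position(0L, 3L, 0L, 20L), 1 / 19)
  expect_equal(relative_motif_position(0L, 2L, 0L, 21L), 0 / 20)
  expect_equal(relative_motif_position(3L, 4L, 3L, 4L), 0.5)  # length-1 IDR
  expect_error(relative_motif_position(0L, 5L, 10L, 20L), "overlap")
})

test_that("IDR statistics separate mIDR and oIDR lengths", {
  rm1 <- build_region_map(60L, iv(c(0L, 40L), c(20L, 55L)),
                          data.frame(start = 5L, end = 12L,
                                     midr_start = 0L, midr_end = 20L))
  st <- idr_statistics(rm1, data.frame(start = 5L, end = 12L,
                                       midr_start = 0L, midr_end = 20L))
  expect_equal(st$n_idrs, 2L)
  expect_equal(st$midr_lengths, 20L)
  expect_equal(st$oidr_lengths, 15L)
  expect_equal(st$disorder_fraction, 35 / 60)
  expect_length(st$motif_relative_positions, 1L)

  rm0 <- build_region_map(40L, iv(integer(0), integer(0)),
                          data.frame(start = integer(0), end = integer(0)))
  st0 <- idr_statistics(rm0)
  expect_equal(st0$n_idrs, 0L)
  expect_equal(st0$disorder_fraction, 0)
})

random_layout <- function() {
  len <- sample(60:400, 1L)
  k <- sample(0:4, 1L)
  dis <- iv(integer(0), integer(0))
  if (k > 0L) {
    s <- sort(sample(seq(0L, len - 10L, by = 10L), k))
    e <- pmin(len, s + sample(5:9, k, replace = TRUE))
    dis <- rgcontext:::merge_intervals(s, e)
  }
  motifs <- data.frame(start = integer(0), end = integer(0))
  if (nrow(dis) > 0L && stats::runif(1) < 0.8) {
    j <- sample.int(nrow(dis), 1L)
    ms <- dis$start[j]
    motifs <- data.frame(start = ms, end = min(dis$end[j], ms + 4L))
  }
  list(len = len, dis = dis, motifs = motifs)
}

test_that("segments tile the protein and reconstruct the disorder intervals", {
  set.seed(104)
  for (i in 1:200) {
    lay <- random_layout()
    rmap <- build_region_map(lay$len, lay$dis, lay$motifs)
    seg <- rmap$segments
    expect_equal(sum(seg$end - seg$start), lay$len)
    expect_true(all(seg$start[-1L] == seg$end[-nrow(seg)]))

    # disorder mask from classes + motif residues inside raw disorder
    mask <- logical(lay$len)
    for (j in seq_len(nrow(seg))) {
      if (seg$class[j] %in% c("mIDR", "oIDR")) {
        mask[(seg$start[j] + 1L):seg$end[j]] <- TRUE
      }
    }
    raw <- rgcontext:::disorder_mask(lay$len, lay$dis)
    if (nrow(lay$motifs) > 0L) {
      mot <- logical(lay$len)
      mot[(lay$motifs$start + 1L):lay$motifs$end] <- TRUE
      mask <- mask | (mot & raw)
    }
    expect_identical(mask, raw)

    st <- idr_statistics(rmap)
    expect_equal(sum(st$idr_lengths) / lay$len, st$disorder_fraction)
  }
})
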