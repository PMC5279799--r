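test_that("deduplicate collapses identical columns within a chromosome", {
  v <- c(0, 2, 0, 2, 2, 0)
  d <- cbind(v, v, 2 - v, c(0, 0, 2, 2, 0, 2))
  dimnames(d) <- NULL
  g <- toy_genotypes(d)
  map <- toy_map(colnames(g$dose), "1A", c(3, 1, 2, 4))
  out <- deduplicate(g, map)
  # columns 1, 2 and the flipped 3 collapse; representative has smallest cM
  expect_equal(out$report$n_retained, 2L)
  expect_setequal(marker_ids(out$genotypes), c("M02", "M04"))
  expect_setequal(out$report$groups[["M02"]], c("M01", "M02", "M03"))

  # identical columns on different chromosomes are both kept
  map2 <- toy_map(colnames(g$dose), c("1A", "1B", "1A", "1B"), c(1, 1, 2, 2))
  out2 <- deduplicate(g, map2)
  expect_true(all(c("M01", "M02") %in% marker_ids(out2$genotypes)))

  # 10-marker toy with 3 duplicate groups constructed by hand
  set.seed(2)
  base <- matrix(sample(c(0, 2), 12 * 4, replace = TRUE), nrow = 12)
  d10 <- base[, c(1, 1, 2, 2, 2, 3, 4, 1, 3, 4)]
  d10[, 8] <- 2 - d10[, 8]      # flipped copy of group 1
  g10 <- toy_genotypes(d10)
  map10 <- toy_map(colnames(g10$dose), "2A", 1:10)
  out10 <- deduplicate(g10, map10)
  expect_setequal(marker_ids(out10$genotypes),
                  c("M01", "M03", "M06", "M07"))
})

test_that("build_blocks follows the half-open window arithmetic", {
  map <- toy_map(paste0("M", 1:5), "1A", c(0, 1, 2, 6, 7))
  b <- build_blocks(map, 5.3)
  expect_equal(nrow(b$blocks), 2L)
  expect_equal(b$members$hap_1A_1, c("M1", "M2", "M3"))
  expect_equal(b$members$hap_1A_2, c("M4", "M5"))
  expect_equal(b$blocks$start, c(0, 6))
  expect_equal(b$blocks$end, c(2, 7))

  one <- build_blocks(toy_map(paste0("M", 1:4), "1B", c(2, 3, 4, 5)), 10)
  expect_equal(nrow(one$blocks), 1L)
  expect_equal(one$blocks$n_snps, 4L)

  # marker exactly at s + w falls in the second window
  edge <- build_blocks(toy_map(paste0("M", 1:4), "1A", c(0, 1, 5.3, 6)), 5.3)
  expect_equal(edge$members$hap_1A_1, c("M1", "M2"))
  expect_equal(edge$members$hap_1A_2, c("M3", "M4"))

  expect_error(build_blocks(map, 0), "positive")
})

test_that("block structure is invariant to input marker order", {
  p <- quick_panel(seed = 40, n_lines = 40, markers = 25)
  map <- p$map
  b1 <- build_blocks(map, 8)
  shuffled <- genetic_map(as.data.frame(map)[sample(nrow(map)), ])
  b2 <- build_blocks(shuffled, 8)
  expect_equal(b1$blocks, b2$blocks)
  expect_equal(b1$members, b2$members)
})

test_that("haplotype alleles are called, pooled and conserved", {
  d <- matrix(c(0, 0, 2, 2,
                2, 2, 0, 0), nrow = 4)
  g <- toy_genotypes(d, data.frame(marker = c("M01", "M02"),
                                   a0 = c("A", "G"), a1 = c("G", "C")))
  map <- toy_map(c("M01", "M02"), "1A", c(0, 1))
  b <- call_block_alleles(g, build_blocks(map, 5.3))
  expect_equal(sort(unname(b$freqs$hap_1A_1)), c(0.5, 0.5))
  # lines 1-2 carry a0 at M01 (A) and a1 at M02 (C); lines 3-4 the reverse
  expect_setequal(names(b$freqs$hap_1A_1), c("AC", "GG"))

  # allele carried by 4 of 100 lines (0.04) pools into "rare"
  d100 <- rbind(matrix(rep(c(0, 0), 48), ncol = 2, byrow = TRUE),
                matrix(rep(c(2, 2), 48), ncol = 2, byrow = TRUE),
                matrix(rep(c(0, 2), 4), ncol = 2, byrow = TRUE))
  b100 <- call_block_alleles(toy_genotypes(d100, NULL),
                             build_blocks(toy_map(c("M01", "M02"), "1A",
                                                  c(0, 1)), 5.3))
  expect_true("rare" %in% names(b100$freqs$hap_1A_1))
  expect_equal(unname(b100$freqs$hap_1A_1[["rare"]]), 0.04)

  # pooling that leaves a single common class drops the block
  d_drop <- rbind(matrix(rep(c(0, 0), 97), ncol = 2, byrow = TRUE),
                  matrix(rep(c(2, 2), 3), ncol = 2, byrow = TRUE))
  b_drop <- call_block_alleles(toy_genotypes(d_drop, NULL),
                               build_blocks(toy_map(c("M01", "M02"), "1A",
                                                    c(0, 1)), 5.3))
  expect_equal(b_drop$dropped, "hap_1A_1")
  expect_equal(nrow(b_drop$blocks), 0L)

  # conservation: members + singletons + dropped = all markers
  p <- quick_panel(seed = 41, n_lines = 60, markers = 20)
  dd <- deduplicate(p$genotypes, p$map)
  bmap <- genetic_map(as.data.frame(
    p$map[p$map$marker %in% marker_ids(dd$genotypes), ]))
  bb <- call_block_alleles(dd$genotypes, build_blocks(bmap, 6))
  dropped_members <- character(0)
  full <- build_blocks(bmap, 6)
  for (loc in bb$dropped) dropped_members <- c(dropped_members,
                                               full$members[[loc]])
  covered <- c(unlist(bb$members), bb$singletons$marker, dropped_members)
  expect_setequal(covered, marker_ids(dd$genotypes))
})

test_that("pic evaluates the Botstein formula", {
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(1), 0)
  expect_equal(pic(rep(0.25, 4)), 0.703125)
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
  expect_error(pic(c(1.2, -0.2)), "negative")
})

test_that("multi-allelic PIC dominates any biallelic collapse", {
  set.seed(12)
  for (i in 1:25) {
    k <- sample(3:6, 1)
    f <- as.numeric(rmultinom(1, 200, runif(k))) / 200
    f <- f[f > 0]
    if (length(f) < 3) next
    full <- pic(f)
    for (j in seq_along(f)) {
      collapsed <- c(f[j], 1 - f[j])
      expect_gte(full + 1e-12, pic(collapsed))
    }
  }
})
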