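test_that("component areas match the canonical fixtures", {
  s <- component_areas(make_configuration("singletons16"), 4)
  expect_equal(s$L, 16L)
  expect_true(all(s$areas == 1L))

  b <- component_areas(make_configuration("block4x4"), 4)
  expect_equal(b$L, 1L)
  expect_equal(b$areas, 16L)

  e <- component_areas(matrix(0L, 5, 5), 4)
  expect_equal(e$L, 0L)
  expect_length(e$areas, 0L)
})

test_that("8-connectivity merges diagonal neighbors, 4 does not", {
  f <- matrix(0L, 5, 5)
  f[2, 2] <- 1L; f[3, 3] <- 1L; f[4, 2] <- 1L  # anti-diagonal zig-zag
  expect_equal(component_areas(f, 4)$L, 3L)
  expect_equal(component_areas(f, 8)$L, 1L)
  expect_equal(component_areas(f, 8)$areas, 3L)
})

test_that("ssmmi statistics follow the five-feature definition", {
  expect_equal(ssmmi_stats(component_areas(make_configuration("blocks2x2"))),
               c(S = 16, L = 4, max = 4, min = 4, mean = 4))
  expect_equal(ssmmi_stats(component_areas(make_configuration("blocks2x4"))),
               c(S = 16, L = 2, max = 8, min = 8, mean = 8))
  expect_equal(ssmmi_stats(c(1, 3)), c(S = 4, L = 2, max = 3, min = 1,
                                       mean = 2))
  expect_equal(ssmmi_stats(integer(0)),
               c(S = 0, L = 0, max = 0, min = 0, mean = 0))
})

test_that("width and height histograms count maximal runs", {
  wh <- width_histogram(make_configuration("block4x4"))
  expect_equal(wh[4], 4L)
  expect_equal(sum(wh), 4L)  # all other bins zero

  bar <- make_configuration("bar1x16")
  expect_equal(width_histogram(bar)[16], 1L)
  expect_equal(height_histogram(bar), rep(16L, 1))  # 16 vertical runs of 1

  hh <- height_histogram(make_configuration("block4x4"))
  expect_equal(hh[4], 4L)

  expect_equal(width_histogram(matrix(0L, 3, 7)), integer(7))
})

test_that("height histogram is the width histogram of the transpose", {
  set.seed(21)
  for (i in 1:20) {
    f <- rand_binary(sample(4:12, 1), sample(4:12, 1))
    expect_equal(height_histogram(f), width_histogram(t(f)))
  }
})

test_that("histograms and components agree with brute-force oracles", {
  set.seed(23)
  for (i in 1:60) {
    f <- rand_binary(sample(8:16, 1), sample(8:16, 1))
    expect_equal(width_histogram(f), brute_hist(brute_width_runs(f), ncol(f)))
    expect_equal(height_histogram(f),
                 brute_hist(brute_height_runs(f), nrow(f)))
    expect_equal(component_areas(f, 4)$areas, brute_component_areas(f, 4))
    expect_equal(component_areas(f, 8)$areas, brute_component_areas(f, 8))
  }
})

test_that("run-length mass conserves the pixel count for every mask", {
  bank <- enumerate_masks(2)
  set.seed(29)
  f <- rand_binary(14, 14)
  for (g in compute_mmi_stack(f, bank)) {
    s <- sum(g)
    expect_equal(sum(seq_len(ncol(g)) * width_histogram(g)), s)
    expect_equal(sum(seq_len(nrow(g)) * height_histogram(g)), s)
    expect_equal(sum(component_areas(g)$areas), s)
  }
})

test_that("L, S and histograms are additive over separated supports", {
  set.seed(31)
  a <- rand_binary(5, 5, 0.6)
  b <- rand_binary(5, 5, 0.6)
  f1 <- matrix(0L, 16, 16); f1[2:6, 2:6] <- a
  f2 <- matrix(0L, 16, 16); f2[10:14, 10:14] <- b
  both <- f1 + f2
  c1 <- component_areas(f1); c2 <- component_areas(f2)
  cb <- component_areas(both)
  expect_equal(cb$L, c1$L + c2$L)
  expect_equal(cb$areas, sort(c(c1$areas, c2$areas)))
  expect_equal(width_histogram(both),
               width_histogram(f1) + width_histogram(f2))
  expect_equal(height_histogram(both),
               height_histogram(f1) + height_histogram(f2))
})

test_that("equal match counts do not imply equal component structure", {
  configs <- c("singletons16", "blocks2x2", "blocks2x4", "block4x4")
  stats <- lapply(configs, function(nm) {
    ssmmi_stats(component_areas(make_configuration(nm)))
  })
  expect_true(all(vapply(stats, `[[`, numeric(1), "S") == 16))
  Ls <- vapply(stats, `[[`, numeric(1), "L")
  expect_equal(Ls, c(16, 4, 2, 1))
  expect_equal(anyDuplicated(Ls), 0L)
  expect_equal(vapply(stats, `[[`, numeric(1), "max"), c(1, 4, 8, 16))
})

test_that("feature vectors have the documented layout and lengths", {
  bank <- enumerate_masks(2)
  set.seed(37)
  img <- matrix(sample(0:255, 30 * 30, TRUE), 30, 30)
  hl <- extract_features(img, bank, "hlac")
  expect_length(hl, 25L)
  expect_equal(unname(hl[1]),
               sum(binarize(img)))  # singleton mask counts set pixels
  expect_named(hl[1], "m1.count")

  ss <- extract_features(img, bank, "ssmmi")
  expect_length(ss, 125L)
  expect_true(all(c("m1.S", "m25.mean") %in% names(ss)))
  # ordering inequalities hold in every block
  for (i in 1:25) {
    blk <- unname(ss[paste0("m", i, ".", c("S", "L", "max", "min", "mean"))])
    s <- blk[1]; l <- blk[2]; mx <- blk[3]; mn <- blk[4]; mean_a <- blk[5]
    expect_true(mn <= mean_a && mean_a <= mx)
    expect_true(l * mn <= s + 1e-9)
    expect_true(s <= l * mx + 1e-9)
  }

  lh <- extract_features(img, bank, "lh")
  expect_length(lh, 25L * 60L)
  expect_true(all(c("m1.w1", "m1.h30", "m25.w30") %in% names(lh)))
})

test_that("feature tables align images and reject mixed sizes", {
  bank <- enumerate_masks(1)
  set.seed(41)
  ds <- list(images = list(matrix(sample(0:255, 100, TRUE), 10, 10),
                           matrix(sample(0:255, 100, TRUE), 10, 10)),
             labels = c("a", "b"), ids = c("a1", "b1"))
  tab <- extract_feature_table(ds, bank, "ssmmi")
  expect_equal(nrow(tab), 2L)
  expect_equal(ncol(tab), 2L + 5L * 5L)
  expect_equal(tab$label, c("a", "b"))

  ds$images[[2]] <- matrix(0L, 9, 10)
  expect_error(extract_feature_table(ds, bank, "ssmmi"), "b1")
})
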