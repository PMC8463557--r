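test_that("binning merges within tolerance and splits beyond it (hand cases)", {
  a <- fake_peaklist(3000.0, id = "A")
  b <- fake_peaklist(3002.0, id = "B")
  res <- bin_peaks(list(a, b), tolerance_rel = 0.001)
  expect_equal(res$bin_masses, 3001.0)  # spread 2/3001 <= 0.001
  expect_equal(res$peaklists[[1]]$masses, 3001.0)
  res2 <- bin_peaks(list(fake_peaklist(3000, id = "A"),
                         fake_peaklist(3010, id = "B")), 0.001)
  expect_equal(res2$bin_masses, c(3000, 3010))  # spread 10/3005 > 0.001
  # a single spectrum keeps its own peak masses
  solo <- fake_peaklist(c(2000, 5000, 7500), id = "A")
  res3 <- bin_peaks(list(solo), 0.001)
  expect_equal(res3$bin_masses, c(2000, 5000, 7500))
  expect_equal(res3$peaklists[[1]]$masses, solo$masses)
})

test_that("two same-spectrum peaks never share a bin", {
  a <- fake_peaklist(c(3000.0, 3001.0), id = "A")
  b <- fake_peaklist(3000.5, id = "B")
  res <- bin_peaks(list(a, b), tolerance_rel = 0.001)
  expect_gte(length(res$bin_masses), 2L)
  # reconstruct bins and assert the constraint
  pooled <- data.frame(
    bin = unlist(lapply(res$peaklists, `[[`, "masses")),
    spec = rep(seq_along(res$peaklists),
               vapply(res$peaklists, function(p) length(p$masses), 0L)))
  expect_false(any(duplicated(pooled[c("bin", "spec")])))
})

test_that("binning satisfies both constraints on arbitrary random input", {
  set.seed(21)
  for (rep in 1:20) {
    n_spec <- sample(2:6, 1)
    pls <- lapply(seq_len(n_spec), function(i)
      fake_peaklist(sort(runif(sample(3:10, 1), 2000, 19000)),
                    id = sprintf("s%d", i)))
    res <- bin_peaks(pls, 0.001)
    pooled_mass <- unlist(lapply(pls, `[[`, "masses"))
    pooled_bin <- unlist(lapply(res$peaklists, `[[`, "masses"))
    spec <- rep(seq_len(n_spec), vapply(pls, function(p) length(p$masses), 0L))
    for (b in unique(pooled_bin)) {
      sel <- pooled_bin == b
      seg <- pooled_mass[sel]
      expect_lte((max(seg) - min(seg)) / mean(seg), 0.001)
      expect_false(anyDuplicated(spec[sel]) > 0)
      expect_equal(b, mean(seg), tolerance = 1e-9)
    }
  }
})

test_that("feature-matrix frequency filter uses a closed >= boundary", {
  pls <- c(list(fake_peaklist(c(3000, 5000), id = "s01", label = "A"),
                fake_peaklist(c(3000.5, 5000.5, 8000), id = "s02", label = "A")),
           lapply(3:40, function(i)
             fake_peaklist(3000 + 0.01 * i, id = sprintf("s%02d", i), label = "B")))
  res <- bin_peaks(pls, 0.001)
  m <- build_feature_matrix(res, min_frequency = 0.05)
  bins <- attr(m, "bin_masses")
  expect_false(any(abs(bins - 8000) < 1))        # 1/40 = 0.025 < 0.05: dropped
  expect_true(any(abs(bins - 5000.25) < 1))      # 2/40 = 0.05: kept (boundary)
  expect_true(any(abs(bins - 3000) < 2))         # present everywhere: kept
  expect_equal(nrow(m), 40L)
  expect_equal(attr(m, "species"), c("A", "A", rep("B", 38)))
  # disjoint single-peak spectra: every column at occupancy 1/2 < 0.6
  res_dis <- bin_peaks(list(fake_peaklist(4000, id = "x1"),
                            fake_peaklist(9000, id = "x2")), 0.001)
  expect_error(build_feature_matrix(res_dis, min_frequency = 0.6),
               "min_frequency")
})

test_that("Hellinger transform normalizes row sums of squares", {
  m <- fake_matrix(rbind(c(1, 1, 1, 1), c(2, 2, 2, 2)))
  h <- hellinger(m)
  expect_equal(unname(h[1, ]), rep(0.5, 4))
  expect_equal(unname(h[2, ]), rep(0.5, 4))
  m2 <- fake_matrix(rbind(c(1, 3, 0), c(2, 1, 1)))
  h2 <- hellinger(m2)
  expect_equal(unname(h2[1, ]), c(0.5, 0.8660, 0), tolerance = 1e-4)
  set.seed(5)
  m3 <- fake_matrix(matrix(runif(60), 6))
  expect_equal(unname(rowSums(hellinger(m3)^2)), rep(1, 6), tolerance = 1e-9)
  m4 <- fake_matrix(rbind(c(1, 2), c(0, 0)))
  expect_error(hellinger(m4), "s02")
})

test_that("peak patterns filter by within-species occupancy and rank by variance", {
  labels <- rep(c("A", "B"), each = 10)
  vals <- matrix(0, 20, 3)
  vals[1:9, 1] <- 1                 # 0.9 in A, 0 in B -> retained, high variance
  vals[sample(1:20, 10), 2] <- 0    # column 2 at 0.5 everywhere
  vals[c(1:5, 11:15), 2] <- 1
  vals[, 3] <- 1                    # ubiquitous
  m <- fake_matrix(vals, labels = labels)
  pat <- peak_patterns(m, pattern_min_frequency = 0.8, labels = labels)
  kept <- colnames(pat)
  expect_true(colnames(m)[1] %in% kept)
  expect_false(colnames(m)[2] %in% kept)   # 0.5 < 0.8 in both species
  expect_true(colnames(m)[3] %in% kept)
  # species-exclusive feature outranks the ubiquitous one
  expect_equal(kept[1], colnames(m)[1])
  expect_true(all(diff(attr(pat, "variance")) <= 0))
  expect_equal(unname(pat["A", colnames(m)[1]]), 0.9)
})

test_that("feature matrix CSV round-trips bit-exactly", {
  set.seed(8)
  m <- fake_matrix(matrix(runif(24), 4), labels = c("A", "A", "B", "B"),
                   bins = c(1750.123456789, 3414.5, 9000.25, 15000.5,
                            17500.75, 19999.9)[1:6])
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(m, path, comment = "unit test")
  m2 <- read_feature_matrix(path)
  expect_identical(unname(as.matrix(m2)), unname(as.matrix(m)))
  expect_identical(attr(m2, "bin_masses"), attr(m, "bin_masses"))
  expect_identical(attr(m2, "species"), attr(m, "species"))
  expect_identical(rownames(m2), rownames(m))
  # header carries the 2-decimal bin masses
  hdr <- grep("^id,", readLines(path), value = TRUE)
  expect_match(hdr, "1750.12", fixed = TRUE)
})

test_that("spectrum ASCII dialect round-trips and rejects bad input", {
  s <- raw_spectrum(c(1500.5, 1501.5, 1502.25), c(0.1, 5.25, 0),
                    list(label = "spZ", id = "zz"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(s, path)
  s2 <- read_spectrum(path, label = "spZ")
  expect_equal(s2$mass, s$mass)
  expect_equal(s2$intensity, s$intensity)
  expect_equal(s2$meta$label, "spZ")
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1500 1", "1400 2"), bad)
  expect_error(read_spectrum(bad), "increasing")
  expect_error(raw_spectrum(c(1, 1), c(1, 2)), "increasing")
})
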