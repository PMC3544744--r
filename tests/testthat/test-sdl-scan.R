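test_that("marker distortion tests recompute the published F2 and outcross statistics", {
  r <- marker_distortion_test(c(A = 0, H = 48, B = 37), "<abxab>")
  expect_equal(round(r$statistic, 2), 33.64)
  expect_equal(r$df, 2L)
  expect_true(r$distorted)
  expect_equal(r$coupling_loss, 0)

  r <- marker_distortion_test(c(A = 4, H = 46, B = 35), "<abxab>")
  expect_equal(round(r$statistic, 2), 23.19)

  r <- marker_distortion_test(c(n = 60, p = 0), "<nnxnp>")
  expect_equal(round(r$statistic, 2), 60)
  expect_equal(r$df, 1L)

  r <- marker_distortion_test(c(e = 33, g = 2), "<efxeg>")
  expect_equal(round(r$statistic, 2), 27.46)

  r <- marker_distortion_test(c(A = 25, H = 50, B = 25), "<abxab>")
  expect_equal(r$statistic, 0)
  expect_false(r$distorted)
  expect_true(r$ambiguous)  # A == B: coupling allele not inferable

  expect_error(marker_distortion_test(c(A = 1), "<zzxzz>"), "unknown")
  expect_error(marker_distortion_test(c(A = 0, H = 0), "<abxab>"), "usable")
})

test_that("composite seg types pool by majority class, reproducing the published pooled values", {
  # two sub-populations whose coupling classes are on opposite codes
  r <- marker_distortion_test(c(c = 0, d = 11, e = 48, g = 1),
                              "<abxcd>/<efxeg>")
  expect_equal(round(r$statistic, 2), 56.07)
  r <- marker_distortion_test(c(e = 23, g = 1, n = 34, p = 2),
                              "<efxeg>/<nnxnp>")
  expect_equal(round(r$statistic, 2), 48.6)
  expect_equal(round(r$coupling_loss, 3), round(3 / 60, 3))
  r <- marker_distortion_test(c(c = 31, d = 3, n = 19, p = 5),
                              "<abxcd>/<nnxnp>")
  expect_equal(round(r$statistic, 2), 30.41)
})

test_that("expected F2 frequencies under pollen selection and their inversion", {
  f <- expected_f2_marker_freqs(c(0, 0.25, 0.5))
  expect_equal(unname(f[1, ]), c(0, 0.5, 0.5))
  expect_equal(unname(f[2, ]), c(0.125, 0.5, 0.375))  # the 1:4:3 case
  expect_equal(unname(f[3, ]), c(0.25, 0.5, 0.25))
  expect_equal(rowSums(f), rep(1, 3))
  expect_error(expected_f2_marker_freqs(0.6), "0.5")

  expect_equal(as.numeric(estimate_r_from_f2(c(A = 0, H = 48, B = 37))), 0)
  expect_equal(as.numeric(estimate_r_from_f2(c(A = 4, H = 46, B = 35))),
               2 * 4 / 85)
  expect_equal(as.numeric(estimate_r_from_f2(c(A = 25, H = 50, B = 25))), 0.5)
  expect_true(attr(estimate_r_from_f2(c(A = 2, H = 10, B = 8)), "low_n"))
})

test_that("coupling-allele loss frequency from carrier calls", {
  expect_equal(as.numeric(coupling_loss_frequency(
    c(rep("H", 48), rep("B", 37)), "<abxab>")), 0)
  calls <- c(rep("A", 4), rep("H", 46), rep("B", 35), "-", NA)
  expect_equal(as.numeric(coupling_loss_frequency(calls, "<abxab>")), 4 / 85)
  expect_error(coupling_loss_frequency(c(NA, "-"), "<abxab>"), "missing")
})

test_that("genome-wide scan flags exactly the published distorted markers", {
  gs <- read_marker_counts(ppmap_example("katy_genome_scan.tsv"))
  sc <- sdl_scan(gs)
  expect_setequal(sc$locus[sc$distorted],
                  c("UDAp468", "PGS3_03", "EPPCU7190", "UDAp420", "Ma027a"))
  expect_setequal(unique(sc$lg[sc$distorted]), c(3, 6))
  # all markers on the other six linkage groups are undistorted
  expect_false(any(sc$distorted[sc$lg %in% c(1, 2, 4, 5, 7, 8)]))
})

test_that("LG3 scans localize the modifier and a balanced table yields no flags", {
  f2 <- read_marker_counts(ppmap_example("katy_lg3_f2.tsv"))
  sc <- sdl_scan(f2)
  expect_equal(sum(sc$distorted), 13L)
  expect_equal(sc$locus[which.max(sc$statistic)], "PGS3_23")
  loc <- localize_locus(sc)
  expect_equal(loc$run_loci, "PGS3_23")
  expect_equal(loc$flank_loci, c("PGS3_22", "PGS3_28"))
  expect_equal(loc$flank_span_mb, c(18.49, 19.14))

  oc <- read_marker_counts(ppmap_example("katy_lg3_outcross.tsv"))
  so <- sdl_scan(oc)
  expect_true(all(c("PGS3_22", "PGS3_23", "PGS3_28") %in%
                  localize_locus(so)$run_loci))
  # every marker from 16.41 Mb distal-ward is distorted, none proximal
  expect_setequal(so$locus[so$distorted], so$locus[so$position_mb >= 16.41])

  balanced <- data.frame(locus = paste0("m", 1:5), seg_type = "<abxab>",
                         position_mb = 1:5, A = 25, H = 50, B = 25)
  expect_equal(sum(sdl_scan(balanced)$distorted), 0L)
})

test_that("localization falls back to the peak marker when no zero-loss marker exists", {
  tab <- data.frame(locus = paste0("m", 1:4), seg_type = "<abxab>",
                    position_mb = 1:4,
                    A = c(20, 10, 2, 18), H = c(50, 52, 55, 50),
                    B = c(30, 38, 43, 32))
  sc <- sdl_scan(tab)
  expect_warning(loc <- localize_locus(sc), "point estimate")
  expect_equal(unname(loc$point_estimate["locus"]), "m3")
})

test_that("distortion flag keeps its type-I error under null simulations", {
  map <- sim_marker_map(paste0("m", 1:16), seq(2, 32, by = 2))
  flags <- 0L; total <- 0L
  for (s in 1:25) {
    pop <- simulate_cross_population(cross_kxk(), map, 85, modifier_cm = 0,
                                     seed = 1000 + s, unlinked = TRUE)
    sc <- sdl_scan(pop$calls)
    flags <- flags + sum(sc$distorted)
    total <- total + nrow(sc)
  }
  rate <- flags / total
  alpha <- 0.05
  expect_lte(rate, alpha + 2 * sqrt(alpha * (1 - alpha) / total))
})

test_that("r estimation is unbiased on simulated F2 populations at the study size", {
  reps <- 500
  for (r_true in c(0, 0.1, 0.25)) {
    cm <- if (r_true == 0) 0 else map_distance(r_true, "haldane")
    map <- sim_marker_map("mk", position_mb = 1, position_cm = 10)
    ests <- vapply(seq_len(reps), function(s) {
      pop <- simulate_cross_population(cross_kxk(), map, 85,
                                       modifier_cm = 10 + cm, seed = 2000 + s)
      cnt <- table(factor(pop$calls$mk, levels = c("A", "H", "B")))
      as.numeric(estimate_r_from_f2(setNames(as.numeric(cnt), c("A", "H", "B"))))
    }, numeric(1))
    se <- stats::sd(ests) / sqrt(reps)
    expect_lte(abs(mean(ests) - r_true), max(2 * se, 1e-3))
  }
})
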