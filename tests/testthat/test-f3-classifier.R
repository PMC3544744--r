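test_that("F3 counts classify F2 modifier genotypes as published", {
  cl <- classify_f2(c(A = 0, H = 14, B = 15))
  expect_equal(cl$call, "M'm'")
  expect_equal(round(cl$chisq_11, 2), 0.03)

  cl <- classify_f2(c(A = 5, H = 15, B = 9))
  expect_equal(cl$call, "m'm'")
  expect_equal(round(cl$chisq_121, 2), 1.14)

  # a borderline 1:2:1 fit is still called homozygous because the A class
  # is populated, which excludes the heterozygous model at tight linkage
  cl <- classify_f2(c(A = 10, H = 8, B = 3))
  expect_equal(cl$call, "m'm'")
  expect_equal(round(cl$chisq_121, 2), 5.86)
  expect_equal(cl$p_A, 0)

  cl <- classify_f2(c(A = 0, H = 20, B = 20))
  expect_equal(cl$call, "M'm'")

  expect_error(classify_f2(c(A = 0, H = 0, B = 0)), "empty")
})

test_that("the bundled F3 panel reproduces all six published calls and the locus flanks", {
  panel <- read_f3_panel(ppmap_example("katy_f3_panel.tsv"))
  cls <- classify_f3_panel(panel)
  calls <- setNames(cls$call[!is.na(cls$call)], cls$f2_id[!is.na(cls$call)])
  expect_equal(calls,
               c(`K05-12` = "M'm'", `K05-24` = "M'm'", `K06-05` = "M'm'",
                 `K06-06` = "M'm'", `K06-17` = "m'm'", `K06-21` = "m'm'"))
  # monomorphic homozygous-F2 rows check out
  expect_true(all(cls$monomorphic_ok[!is.na(cls$monomorphic_ok)]))

  gg <- utils::read.delim(ppmap_example("katy_recombinants.tsv"),
                          comment.char = "#")
  li <- locus_interval_from_recombinants(gg, calls)
  expect_equal(unname(li$flank_markers), c("PGS3_22", "EPPCU7190"))
  expect_equal(unname(li$interval), c(18.49, 19.78))
  expect_equal(li$n_informative, 6L)
})

test_that("families below the embryo threshold are excluded, not called", {
  panel <- data.frame(f2_id = c("x1", "x2"), marker = "mk", f2_genotype = "H",
                      A = c(0, 0), H = c(3, 20), B = c(3, 22))
  cls <- classify_f3_panel(panel, min_n = 7)
  expect_true(cls$excluded[cls$f2_id == "x1"])
  expect_true(is.na(cls$call[cls$f2_id == "x1"]))
  expect_equal(cls$call[cls$f2_id == "x2"], "M'm'")
})

test_that("breakpoints fall between adjacent typed markers with differing codes", {
  gg <- data.frame(marker = c("m1", "m2", "m3", "m4"),
                   position_mb = c(1, 2, 3, 4),
                   genotype = c("A", "A", "H", "H"))
  bp <- infer_breakpoints(gg)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$left_marker, "m2")
  expect_equal(bp$right_marker, "m3")

  gg$genotype <- "H"
  expect_equal(nrow(infer_breakpoints(gg)), 0L)

  # untyped markers are skipped when bracketing the breakpoint
  gg2 <- data.frame(marker = c("m1", "m2", "m3", "m4"),
                    position_mb = c(1, 2, 3, 4),
                    genotype = c("A", NA, "H", "H"))
  bp <- infer_breakpoints(gg2)
  expect_equal(c(bp$left_marker, bp$right_marker), c("m1", "m3"))
  expect_error(infer_breakpoints(gg2[2, ]), "2 typed")
})

test_that("one recombinant gives a one-sided bound; intersections only narrow", {
  gg <- data.frame(f2_id = "r1", marker = c("m1", "m2", "m3"),
                   position_mb = c(1, 2, 3), genotype = c("H", "H", "B"))
  li1 <- locus_interval_from_recombinants(gg, c(r1 = "M'm'"))
  expect_equal(li1$interval, c(-Inf, 3))

  gg2 <- rbind(gg, data.frame(f2_id = "r2", marker = c("m1", "m2", "m3"),
                              position_mb = c(1, 2, 3),
                              genotype = c("A", "H", "H")))
  li2 <- locus_interval_from_recombinants(gg2, c(r1 = "M'm'", r2 = "M'm'"))
  expect_equal(li2$interval, c(1, 3))
  # monotone refinement: adding a recombinant never widens the interval
  expect_gte(li2$interval[1], li1$interval[1])
  expect_lte(li2$interval[2], li1$interval[2])

  # contradictory recombinant is reported, not silently dropped
  gg3 <- rbind(gg2, data.frame(f2_id = "r3", marker = c("m1", "m2", "m3"),
                               position_mb = c(1, 2, 3),
                               genotype = c("B", "A", "A")))
  expect_warning(
    li3 <- locus_interval_from_recombinants(gg3, c(r1 = "M'm'", r2 = "M'm'",
                                                   r3 = "M'm'")),
    "r3")
  expect_equal(li3$conflicts, "r3")
})

test_that("classifier recovers simulated modifier genotypes within the stated error rate", {
  set.seed(31)
  reps <- 500
  n_fam <- 60  # a large F3 family within the study's 2-77 embryo range
  for (r in c(0, 0.05)) {
    x <- stats::rmultinom(reps, n_fam, c(r / 2, 1 / 2, (1 - r) / 2))
    err <- mean(vapply(seq_len(reps), function(i)
      classify_f2(setNames(x[, i], c("A", "H", "B")), r = r)$call != "M'm'",
      logical(1)))
    expect_lte(err, 0.10)
  }
  x <- stats::rmultinom(reps, n_fam, c(1, 2, 1) / 4)
  err <- mean(vapply(seq_len(reps), function(i)
    classify_f2(setNames(x[, i], c("A", "H", "B")), r = 0)$call != "m'm'",
    logical(1)))
  expect_lte(err, 0.10)
})

test_that("locus interval from simulated recombinant panels covers the truth", {
  # modifier at 18.7 Mb; simulate small F2 sets, classify recombinants from
  # their true modifier genotypes, and check the interval brackets 18.7
  map <- lg3_map()
  hit <- 0L; tot <- 0L
  for (s in 1:40) {
    pop <- simulate_cross_population(cross_kxk(), map, 40,
                                     modifier_cm = 18.7 / 0.56, seed = 500 + s)
    region <- map$locus[map$position_mb >= 16 & map$position_mb <= 22]
    gm <- as.matrix(pop$calls[, region])
    rec <- which(apply(gm, 1, function(v) any(v[-1] != v[-length(v)])))
    if (length(rec) == 0) next
    gg <- do.call(rbind, lapply(rec, function(i)
      data.frame(f2_id = pop$calls$individual[i], marker = map$locus,
                 position_mb = map$position_mb,
                 genotype = unlist(pop$calls[i, map$locus]))))
    calls <- setNames(ifelse(pop$m_genotype[rec] == "Mm", "M'm'", "m'm'"),
                      pop$calls$individual[rec])
    li <- tryCatch(suppressWarnings(
      locus_interval_from_recombinants(gg, calls)),
      error = function(e) NULL)
    if (is.null(li)) next
    tot <- tot + 1L
    if (li$interval[1] <= 18.7 && li$interval[2] >= 18.7) hit <- hit + 1L
  }
  expect_gte(tot, 20L)
  expect_gte(hit / tot, 0.95)
})
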