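test_that("gamete distributions of double heterozygotes, homozygotes and linked parents", {
  g <- gamete_distribution(katy())
  expect_equal(nrow(g), 4L)
  expect_equal(g$prob, rep(0.25, 4))
  expect_setequal(paste(g$s, g$modifier), c("S1 M", "S1 m", "S2 M", "S2 m"))

  g <- gamete_distribution(harcot())  # S1S4 MM
  expect_equal(setNames(g$prob, g$s), c(S1 = 0.5, S4 = 0.5))
  expect_true(all(g$modifier == "M"))

  hom <- parent_genotype(c("S1", "S1"), modifier = c("m", "m"))
  g <- gamete_distribution(hom)
  expect_equal(nrow(g), 1L)
  expect_equal(g$prob, 1)

  # complete linkage of the mutated allele to S2: no recombinant gametes
  linked <- parent_genotype(c("S1", "S2"), modifier = c("M", "m"), r_sm = 0,
                            phase = c(S1 = "M", S2 = "m"))
  g <- gamete_distribution(linked)
  expect_equal(nrow(g), 2L)
  expect_equal(setNames(g$prob, paste0(g$s, g$modifier)),
               c(S1M = 0.5, S2m = 0.5))

  # partial linkage: parental (1-r)/2, recombinant r/2
  linked <- parent_genotype(c("S1", "S2"), modifier = c("M", "m"), r_sm = 0.2,
                            phase = c(S1 = "M", S2 = "m"))
  g <- gamete_distribution(linked)
  p <- setNames(g$prob, paste0(g$s, g$modifier))
  expect_equal(p[c("S1M", "S2m", "S1m", "S2M")],
               c(S1M = 0.4, S2m = 0.4, S1m = 0.1, S2M = 0.1))

  expect_error(parent_genotype(c("S1", "S2"), r_sm = 0.7), "r_sm")
  expect_error(parent_genotype(c("S1", "S2"), modifier = c("M", "m"),
                               r_sm = 0.1), "phase")
})

test_that("pollen rejection rule: S-match, defective haplotypes, mutated modifier", {
  pistil <- katy()
  expect_false(pollen_compatible("S1", pistil, modifier = "M"))
  expect_false(pollen_compatible("S2", pistil, modifier = "M"))
  expect_true(pollen_compatible("S2", pistil, modifier = "m"))
  expect_true(pollen_compatible("S3", pistil, modifier = "M"))
  # a pollen-part-defective haplotype escapes rejection regardless of modifier
  expect_true(pollen_compatible("SC", canino(), modifier = "M", defective = TRUE))
  # vectorized
  expect_equal(pollen_compatible(c("S1", "S2", "S4"), pistil,
                                 modifier = c("M", "m", "M")),
               c(FALSE, TRUE, TRUE))
})

test_that("progeny distributions reproduce the published cross ratios", {
  expect_equal(s_genotype_margin(progeny_distribution(cross_kxk())),
               c(S1S1 = 0.25, S1S2 = 0.5, S2S2 = 0.25))
  expect_equal(s_genotype_margin(progeny_distribution(cross_hxk())),
               c(S1S1 = 1, S1S2 = 2, S1S4 = 1, S2S4 = 2) / 6)
  expect_equal(s_genotype_margin(progeny_distribution(cross_cxk())),
               c(S1S2 = 2, S1SC = 2, S2S2 = 1, S2SC = 1) / 6)
  expect_equal(s_genotype_margin(progeny_distribution(cross_kxc())),
               c(S1S2 = 1, S1SC = 2, S2S2 = 1, S2SC = 2) / 6)
  # fully incompatible cross: empty distribution, zero pollen mass
  d <- progeny_distribution(cross_kxg())
  expect_equal(nrow(d), 0L)
  expect_equal(attr(d, "pollen_mass"), 0)
})

test_that("selection-free crosses match the brute-force Mendelian oracle", {
  set.seed(42)
  labels <- c("S1", "S2", "S3", "S4", "S5", "S6")
  for (i in 1:20) {
    sp <- parent_genotype(sample(labels[1:3], 2), modifier = c("M", "M"))
    pp <- parent_genotype(sample(labels[4:6], 2), modifier = c("M", "M"))
    cr <- cross_spec(sp, pp)
    got <- s_genotype_margin(progeny_distribution(cr))
    want <- progeny_oracle(sp, pp)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
  # and crosses WITH selection also match the oracle's inline rejection rule
  for (i in 1:20) {
    sp <- parent_genotype(sample(labels, 2), modifier = c("M", "m"))
    pp <- parent_genotype(sample(labels, 2),
                          modifier = sample(c("M", "m"), 2, replace = TRUE))
    cr <- cross_spec(sp, pp)
    d <- progeny_distribution(cr)
    want <- progeny_oracle(sp, pp)
    if (nrow(d) == 0) {
      expect_length(want, 0)
    } else {
      got <- s_genotype_margin(d)
      expect_equal(sum(got), 1, tolerance = 1e-12)
      expect_equal(got[names(want)], want, tolerance = 1e-12)
    }
  }
})

test_that("expected ratios under competing hypotheses and S-relabel symmetry", {
  hxk <- cross_hxk()
  expect_equal(unname(expected_ratio(hxk, model_hypothesis("het_unlinked"))[
    c("S1S2", "S1S1", "S1S4", "S2S4")]), c(2L, 1L, 1L, 2L))
  expect_equal(as.vector(expected_ratio(hxk, model_hypothesis("homozygous_mutated"))),
               rep(1L, 4))
  expect_equal(as.vector(expected_ratio(hxk, model_hypothesis("het_coupled",
                                                              coupled_to = "S1"))),
               rep(1L, 4))
  expect_equal(unname(expected_ratio(cross_kxk())[c("S1S2", "S2S2", "S1S1")]),
               c(2L, 1L, 1L))
  expect_error(expected_ratio(hxk, model_hypothesis("het_coupled",
                                                    coupled_to = "S9")),
               "absent")

  # consistently relabeling S-haplotypes leaves the ratio multiset invariant
  relab <- c(S1 = "Sx", S2 = "Sy", S4 = "Sz")
  h2 <- parent_genotype(unname(relab[c("S1", "S4")]))
  k2 <- parent_genotype(unname(relab[c("S1", "S2")]), modifier = c("M", "m"))
  r1 <- expected_ratio(cross_hxk())
  r2 <- expected_ratio(cross_spec(h2, k2))
  expect_equal(sort(unname(r1)), sort(unname(r2)))
})

test_that("map functions match closed forms and invert to 1e-9", {
  expect_equal(map_distance(0, "kosambi"), 0)
  expect_equal(map_distance(0, "haldane"), 0)
  expect_equal(map_distance(0.25, "kosambi"), 25 * log(3))
  expect_equal(map_distance(0.25, "haldane"), -50 * log(0.5))
  r <- seq(0, 0.49, by = 0.01)
  for (fn in c("kosambi", "haldane"))
    expect_equal(inverse_map_distance(map_distance(r, fn), fn), r,
                 tolerance = 1e-9)
  expect_error(map_distance(0.5), "0.5")
  expect_error(map_distance(-0.1), "0.5")
})
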