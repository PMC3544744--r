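# Shared fixtures: the four cultivars of the apricot study and their crosses.

katy <- function() parent_genotype(c("S1", "S2"), modifier = c("M", "m"),
                                   label = "Katy")
goldrich <- function() parent_genotype(c("S1", "S2"), label = "Goldrich")
harcot <- function() parent_genotype(c("S1", "S4"), label = "Harcot")
canino <- function() parent_genotype(c("S2", "SC"), defective = c(FALSE, TRUE),
                                     modifier = c("M", "m"), label = "Canino")

cross_kxk <- function() cross_spec(katy(), katy(), "K x K")
cross_gxk <- function() cross_spec(goldrich(), katy(), "G x K")
cross_hxk <- function() cross_spec(harcot(), katy(), "H x K")
cross_cxk <- function() cross_spec(canino(), katy(), "C x K")
cross_kxc <- function() cross_spec(katy(), canino(), "K x C")
cross_kxg <- function() cross_spec(katy(), goldrich(), "K x G")

lg3_map <- function() {
  m <- read_marker_counts(ppmap_example("katy_lg3_f2.tsv"))
  sim_marker_map(m$locus, m$position_mb)
}

# Independent chi-square oracle: integer arithmetic in the numerator,
# statistic = sum_i (o_i * S - n * r_i)^2 / (n * r_i * S) with S = sum(r).
chisq_oracle <- function(o, r) {
  n <- sum(o); S <- sum(r)
  sum((o * S - n * r)^2 / (n * r * S))
}

# Brute-force progeny-distribution oracle: explicit loop over all egg x
# pollen homolog pairs with inline rejection, independent of the package's
# distribution machinery.
progeny_oracle <- function(seed, pollen) {
  acc <- list()
  for (ie in 1:2) for (im in 1:2) for (je in 1:2) for (jm in 1:2) {
    ps <- pollen$s[je]; pm <- pollen$modifier[jm]
    rejected <- ps %in% seed$s && !pollen$defective[je] && pm == "M"
    if (rejected) next
    lab <- paste(sort(c(seed$s[ie], ps)), collapse = "")
    acc[[lab]] <- (if (is.null(acc[[lab]])) 0 else acc[[lab]]) + 1 / 16
  }
  p <- unlist(acc)
  sort(p / sum(p), decreasing = TRUE)
}
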