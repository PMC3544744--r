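#' Gamete distribution of a diploid parent at the S and modifier loci
#'
#' Enumerates the (S-haplotype, modifier-allele) gametes a parent produces,
#' with probabilities. An unlinked double heterozygote yields the four
#' combinations at 1/4 each; with linkage (`r_sm = r` and a declared phase)
#' parental-phase gametes have probability `(1 - r)/2` each and recombinant
#' gametes `r/2` each. Identical gamete types are pooled.
#'
#' @param parent a [parent_genotype()].
#' @return an object of class `"gamete_distribution"`: a data frame with
#'   columns `s`, `defective`, `modifier`, `prob` (probabilities sum to 1).
#' @examples
#' katy <- parent_genotype(c("S1", "S2"), modifier = c("M", "m"))
#' gamete_distribution(katy)
#' @export
gamete_distribution <- function(parent) {
  stopifnot(inherits(parent, "parent_genotype"))
  s <- parent$s
  defect <- parent$defective
  mod <- parent$modifier
  if (!is.null(parent$phase) && parent$r_sm < 0.5) {
    r <- parent$r_sm
    rows <- list()
    other <- function(a) if (a == "M") "m" else "M"
    for (i in 1:2) {
      par_allele <- unname(parent$phase[s[i]])
      rows[[length(rows) + 1L]] <-
        data.frame(s = s[i], defective = defect[i], modifier = par_allele,
                   prob = (1 - r) / 2, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(s = s[i], defective = defect[i], modifier = other(par_allele),
                   prob = r / 2, stringsAsFactors = FALSE)
    }
    g <- do.call(rbind, rows)
  } else {
    g <- expand.grid(i = 1:2, j = 1:2)
    g <- data.frame(s = s[g$i], defective = defect[g$i],
                    modifier = mod[g$j], prob = 0.25,
                    stringsAsFactors = FALSE)
  }
  # pool identical gamete types (homozygosity at either locus)
  key <- paste(g$s, g$modifier)
  agg <- rowsum(g$prob, key)
  first <- !duplicated(key)
  out <- g[first, c("s", "defective", "modifier")]
  out$prob <- agg[match(key[first], rownames(agg)), 1L]
  out <- out[out$prob > 0, , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(abs(sum(out$prob) - 1) < 1e-12)
  structure(out, class = c("gamete_distribution", "data.frame"))
}

#' Is a pollen gamete accepted on a given pistil?
#'
#' GSI rejection rule with a gametophytically acting pollen modifier: a
#' pollen gamete is rejected if and only if its S-haplotype matches either
#' pistil S-haplotype, its pollen determinant is functional (not
#' pollen-part defective), and its modifier allele is functional (`"M"`).
#' Everything else grows.
#'
#' @param s character vector of pollen S-haplotype labels.
#' @param pistil a [parent_genotype()] providing the pistil S-genotype.
#' @param modifier character vector of pollen modifier alleles (`"M"`/`"m"`),
#'   recycled against `s`.
#' @param defective logical vector: pollen-part defective S-haplotype flags,
#'   recycled against `s`.
#' @return logical vector: `TRUE` where the gamete is compatible.
#' @examples
#' katy <- parent_genotype(c("S1", "S2"), modifier = c("M", "m"))
#' pollen_compatible("S1", katy, modifier = "M")  # rejected
#' pollen_compatible("S2", katy, modifier = "m")  # grows
#' @export
pollen_compatible <- function(s, pistil, modifier = "M", defective = FALSE) {
  stopifnot(inherits(pistil, "parent_genotype"))
  n <- length(s)
  modifier <- rep_len(modifier, n)
  defective <- rep_len(defective, n)
  !(s %in% pistil$s & !defective & modifier == "M")
}

#' Expected progeny distribution of a cross under pollen selection
#'
#' Egg gametes are transmitted unselected; pollen gametes are filtered by
#' the GSI rejection rule ([pollen_compatible()]) on the seed parent's
#' pistil and renormalized; offspring classes are unordered diploid
#' (S-genotype, modifier-genotype) combinations.
#'
#' If no pollen gamete survives the pistil screen (a fully incompatible
#' cross), an empty distribution is returned whose `"pollen_mass"`
#' attribute is 0.
#'
#' @param cross a [cross_spec()].
#' @return object of class `"progeny_distribution"`: data frame with columns
#'   `s_genotype`, `m_genotype`, `prob`; attribute `pollen_mass` is the
#'   pre-normalization probability mass of compatible pollen.
#' @examples
#' katy <- parent_genotype(c("S1", "S2"), modifier = c("M", "m"))
#' progeny_distribution(cross_spec(katy, katy, "K x K"))
#' @export
progeny_distribution <- function(cross) {
  stopifnot(inherits(cross, "cross_spec"))
  eggs <- gamete_distribution(cross$seed_parent)
  pollen <- gamete_distribution(cross$pollen_parent)
  ok <- pollen_compatible(pollen$s, cross$seed_parent,
                          modifier = pollen$modifier,
                          defective = pollen$defective)
  mass <- sum(pollen$prob[ok])
  if (mass == 0) {
    out <- data.frame(s_genotype = character(), m_genotype = character(),
                      prob = numeric(), stringsAsFactors = FALSE)
    return(structure(out, pollen_mass = 0,
                     label = cross$label,
                     class = c("progeny_distribution", "data.frame")))
  }
  pollen <- pollen[ok, , drop = FALSE]
  pollen$prob <- pollen$prob / mass
  idx <- expand.grid(e = seq_len(nrow(eggs)), p = seq_len(nrow(pollen)))
  sg <- mapply(function(e, p) s_genotype_label(c(eggs$s[e], pollen$s[p])),
               idx$e, idx$p)
  mg <- modifier_genotype_label(eggs$modifier[idx$e], pollen$modifier[idx$p])
  prob <- eggs$prob[idx$e] * pollen$prob[idx$p]
  key <- paste(sg, mg)
  agg <- rowsum(prob, key)
  first <- !duplicated(key)
  out <- data.frame(s_genotype = sg[first], m_genotype = mg[first],
                    prob = agg[match(key[first], rownames(agg)), 1L],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$prob, out$s_genotype, out$m_genotype), ]
  rownames(out) <- NULL
  stopifnot(abs(sum(out$prob) - 1) < 1e-12)
  structure(out, pollen_mass = mass, label = cross$label,
            class = c("progeny_distribution", "data.frame"))
}

#' @export
print.progeny_distribution <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("Expected progeny distribution%s\n",
              if (!is.null(lab)) paste0(" for '", lab, "'") else ""))
  if (nrow(x) == 0) {
    cat("  no compatible pollen: cross yields no offspring\n")
  } else {
    print.data.frame(x, row.names = FALSE, ...)
  }
  invisible(x)
}

#' Marginal S-genotype distribution of a progeny distribution
#'
#' @param dist a `"progeny_distribution"`.
#' @return named numeric vector of probabilities by S-genotype class.
#' @export
s_genotype_margin <- function(dist) {
  stopifnot(inherits(dist, "progeny_distribution"))
  if (nrow(dist) == 0) return(setNames(numeric(), character()))
  agg <- rowsum(dist$prob, dist$s_genotype)
  setNames(agg[, 1L], rownames(agg))
}

#' Expected S-genotype segregation ratio under a mutation hypothesis
#'
#' Rewrites the pollen parent according to the hypothesis (see
#' [model_hypothesis()]), runs [progeny_distribution()], marginalizes over
#' modifier genotypes and reduces the class probabilities to the smallest
#' integer ratio.
#'
#' @param cross a [cross_spec()]; the hypothesis is applied to its pollen
#'   parent.
#' @param hypothesis a [model_hypothesis()].
#' @param max_denominator largest rational denominator tried when reducing
#'   probabilities to integers (the classical ratios are all small).
#' @return named integer vector, the expected ratio by S-genotype class;
#'   attribute `hypothesis` records the model used. Zero-probability classes
#'   are dropped; an empty vector means the cross is fully incompatible
#'   under the hypothesis.
#' @examples
#' katy <- parent_genotype(c("S1", "S2"), modifier = c("M", "m"))
#' harcot <- parent_genotype(c("S1", "S4"))
#' hxk <- cross_spec(harcot, katy, "H x K")
#' expected_ratio(hxk, model_hypothesis("het_unlinked"))       # 2:1:1:2
#' expected_ratio(hxk, model_hypothesis("homozygous_mutated")) # 1:1:1:1
#' @export
expected_ratio <- function(cross, hypothesis = model_hypothesis("het_unlinked"),
                           max_denominator = 64L) {
  stopifnot(inherits(cross, "cross_spec"),
            inherits(hypothesis, "model_hypothesis"))
  pp <- cross$pollen_parent
  pp2 <- switch(
    hypothesis$kind,
    het_unlinked = parent_genotype(pp$s, pp$defective, c("M", "m"),
                                   r_sm = 0.5, label = pp$label),
    homozygous_mutated = parent_genotype(pp$s, pp$defective, c("m", "m"),
                                         r_sm = 0.5, label = pp$label),
    het_coupled = {
      if (!hypothesis$coupled_to %in% pp$s)
        stop(sprintf("hypothesis couples the mutation to '%s', absent from the pollen parent",
                     hypothesis$coupled_to), call. = FALSE)
      other <- setdiff(pp$s, hypothesis$coupled_to)
      if (length(other) == 0L) other <- hypothesis$coupled_to
      ph <- setNames(c("m", "M"), c(hypothesis$coupled_to, other[1L]))
      parent_genotype(pp$s, pp$defective, c("M", "m"), r_sm = 0,
                      phase = ph[unique(pp$s)], label = pp$label)
    })
  dist <- progeny_distribution(cross_spec(cross$seed_parent, pp2, cross$label))
  marg <- s_genotype_margin(dist)
  structure(reduce_to_ratio(marg, max_denominator), hypothesis = hypothesis)
}

# Reduce rational class probabilities to the smallest integer ratio.
reduce_to_ratio <- function(p, max_denominator = 64L) {
  if (length(p) == 0) return(setNames(integer(), character()))
  for (d in seq_len(max_denominator)) {
    v <- p * d
    if (all(abs(v - round(v)) < 1e-9)) {
      ints <- as.integer(round(v))
      g <- Reduce(gcd2, ints[ints > 0])
      return(setNames(ints %/% g, names(p)))
    }
  }
  stop("probabilities are not rational with denominator <= ", max_denominator,
       call. = FALSE)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Map functions: recombination fraction to genetic distance and back
#'
#' `map_distance()` converts a recombination fraction to centimorgans with
#' the Kosambi (`25 * log((1 + 2r)/(1 - 2r))`) or Haldane
#' (`-50 * log(1 - 2r)`) map function; `inverse_map_distance()` inverts it.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d genetic distance(s) in cM, `>= 0`.
#' @param map_function `"kosambi"` or `"haldane"`.
#' @return numeric vector of distances (cM) or recombination fractions.
#' @examples
#' map_distance(0.25, "kosambi")  # 25 * log(3) = 27.47
#' map_distance(0.25, "haldane")  # 34.66
#' inverse_map_distance(map_distance(0.1), "kosambi")
#' @export
map_distance <- function(r, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  if (any(r < 0 | r >= 0.5))
    stop("recombination fractions must lie in [0, 0.5)", call. = FALSE)
  switch(map_function,
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)),
         haldane = -50 * log(1 - 2 * r))
}

#' @rdname map_distance
#' @export
inverse_map_distance <- function(d, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  if (any(d < 0)) stop("genetic distances must be non-negative", call. = FALSE)
  switch(map_function,
         kosambi = 0.5 * tanh(d / 50),
         haldane = (1 - exp(-d / 50)) / 2)
}
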