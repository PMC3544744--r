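#' Diploid parent genotype at the S-locus and a pollen modifier locus
#'
#' Describes one parent of a cross in a gametophytic self-incompatibility
#' (GSI) system: its two S-haplotypes, whether each haplotype's pollen
#' determinant is defective (an S-locus pollen-part mutation), and its
#' genotype at an S-locus-independent modifier locus whose functional
#' allele is required for pollen-side rejection.
#'
#' The modifier acts strictly gametophytically in pollen; the pistil side
#' is always fully functional. By default the modifier locus segregates
#' independently of the S-locus (`r_sm = 0.5`). A linked configuration is
#' declared by lowering `r_sm` and giving `phase`, the assignment of one
#' modifier allele to each S-haplotype chromosome.
#'
#' @param s character vector of two S-haplotype labels, e.g. `c("S1","S2")`.
#' @param defective logical vector of two flags: is the pollen determinant of
#'   the corresponding S-haplotype non-functional? Recycled if length 1.
#' @param modifier character vector of two modifier alleles, each `"M"`
#'   (functional) or `"m"` (mutated).
#' @param r_sm recombination fraction between S-locus and modifier locus,
#'   in `[0, 0.5]`; `0.5` means unlinked.
#' @param phase named character vector mapping each S-haplotype label to the
#'   modifier allele on the same chromosome, required when `r_sm < 0.5` and
#'   the parent is heterozygous at both loci.
#' @param label optional display label (cultivar name).
#' @return an object of class `"parent_genotype"`.
#' @examples
#' katy <- parent_genotype(c("S1", "S2"), modifier = c("M", "m"), label = "Katy")
#' harcot <- parent_genotype(c("S1", "S4"), label = "Harcot")
#' @seealso [cross_spec()], [gamete_distribution()]
#' @export
parent_genotype <- function(s, defective = FALSE, modifier = c("M", "M"),
                            r_sm = 0.5, phase = NULL, label = NULL) {
  s <- as.character(s)
  if (length(s) != 2L || any(!nzchar(s)))
    stop("a parent must carry exactly two non-empty S-haplotype labels", call. = FALSE)
  defective <- rep_len(as.logical(defective), 2L)
  modifier <- as.character(modifier)
  if (length(modifier) != 2L || !all(modifier %in% c("M", "m")))
    stop("'modifier' must be two alleles drawn from {\"M\", \"m\"}", call. = FALSE)
  if (!is.numeric(r_sm) || length(r_sm) != 1L || is.na(r_sm) ||
      r_sm < 0 || r_sm > 0.5)
    stop("'r_sm' must be a single recombination fraction in [0, 0.5]", call. = FALSE)
  if (!is.null(phase)) {
    if (is.null(names(phase)) || !setequal(names(phase), unique(s)))
      stop("'phase' must be named by the parent's S-haplotype labels", call. = FALSE)
    if (!all(phase %in% c("M", "m")))
      stop("'phase' values must be modifier alleles \"M\" or \"m\"", call. = FALSE)
    if (!setequal(unname(phase[s]), modifier) && length(unique(s)) == 2L)
      stop("'phase' must assign the parent's own modifier alleles", call. = FALSE)
  }
  if (r_sm < 0.5 && is.null(phase) &&
      length(unique(s)) == 2L && length(unique(modifier)) == 2L)
    stop("a linked double heterozygote (r_sm < 0.5) needs an explicit 'phase'",
         call. = FALSE)
  structure(
    list(s = s, defective = defective, modifier = modifier,
         r_sm = r_sm, phase = phase, label = label),
    class = "parent_genotype"
  )
}

#' @export
print.parent_genotype <- function(x, ...) {
  mg <- paste(sort(x$modifier, decreasing = TRUE), collapse = "")
  cat(sprintf("Parent genotype%s: %s %s%s\n",
              if (!is.null(x$label)) paste0(" '", x$label, "'") else "",
              paste(x$s, collapse = ""), mg,
              if (any(x$defective))
                paste0(" [pollen-part defective: ",
                       paste(x$s[x$defective], collapse = ","), "]") else ""))
  if (x$r_sm < 0.5)
    cat(sprintf("  S-modifier linkage: r = %g, phase %s\n", x$r_sm,
                paste(names(x$phase), x$phase, sep = "-", collapse = " / ")))
  invisible(x)
}

#' Specify a cross between two parents
#'
#' @param seed_parent,pollen_parent [parent_genotype()] objects; the seed
#'   parent contributes eggs and its pistil genotype screens the pollen.
#' @param label optional cross label, e.g. `"K x K"`.
#' @return an object of class `"cross_spec"`.
#' @examples
#' katy <- parent_genotype(c("S1", "S2"), modifier = c("M", "m"), label = "Katy")
#' kxk <- cross_spec(katy, katy, label = "K x K")
#' @export
cross_spec <- function(seed_parent, pollen_parent, label = NULL) {
  stopifnot(inherits(seed_parent, "parent_genotype"),
            inherits(pollen_parent, "parent_genotype"))
  structure(list(seed_parent = seed_parent, pollen_parent = pollen_parent,
                 label = label),
            class = "cross_spec")
}

#' @export
print.cross_spec <- function(x, ...) {
  cat(sprintf("Cross%s: seed %s x pollen %s\n",
              if (!is.null(x$label)) paste0(" '", x$label, "'") else "",
              paste(x$seed_parent$s, collapse = ""),
              paste(x$pollen_parent$s, collapse = "")))
  invisible(x)
}

#' Competing hypotheses about the pollen-part mutation of a pollen parent
#'
#' Three genetic models for how a self-compatible pollen parent carries its
#' pollen-part mutation: heterozygous and unlinked to the S-locus
#' (`"het_unlinked"`), heterozygous with the mutated allele in coupling with
#' a named S-haplotype (`"het_coupled"`), or homozygous for the mutation
#' (`"homozygous_mutated"`).
#'
#' @param kind one of `"het_unlinked"`, `"het_coupled"`, `"homozygous_mutated"`.
#' @param coupled_to S-haplotype label carried by the pollen parent; required
#'   for (and only for) `"het_coupled"`.
#' @return an object of class `"model_hypothesis"`.
#' @examples
#' model_hypothesis("het_unlinked")
#' model_hypothesis("het_coupled", coupled_to = "S2")
#' @export
model_hypothesis <- function(kind = c("het_unlinked", "het_coupled",
                                      "homozygous_mutated"),
                             coupled_to = NULL) {
  kind <- match.arg(kind)
  if (kind == "het_coupled" && (is.null(coupled_to) || !nzchar(coupled_to)))
    stop("'het_coupled' requires the coupled S-haplotype label", call. = FALSE)
  if (kind != "het_coupled") coupled_to <- NULL
  structure(list(kind = kind, coupled_to = coupled_to),
            class = "model_hypothesis")
}

#' @export
print.model_hypothesis <- function(x, ...) {
  cat("Hypothesis:", format_hypothesis(x), "\n")
  invisible(x)
}

format_hypothesis <- function(h) {
  switch(h$kind,
         het_unlinked = "heterozygous mutation, unlinked to S",
         het_coupled = paste0("heterozygous mutation in coupling with ",
                              h$coupled_to),
         homozygous_mutated = "homozygous mutation")
}

# Canonical modifier-genotype label, independent of locale collation.
modifier_genotype_label <- function(a, b) {
  c("MM", "Mm", "mm")[(a == "m") + (b == "m") + 1L]
}

#' Canonical label for an unordered diploid S-genotype
#'
#' @param s character vector of two haplotype labels (any order).
#' @return single string, labels sorted, e.g. `"S1S2"`.
#' @examples
#' s_genotype_label(c("S2", "S1"))
#' @export
s_genotype_label <- function(s) {
  stopifnot(length(s) == 2L)
  paste(sort(as.character(s)), collapse = "")
}
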