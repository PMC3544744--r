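#' Physical interval on a reference scaffold
#'
#' Closed interval in megabases on a named scaffold/chromosome of a
#' reference genome, at the printed decimal precision.
#'
#' @param scaffold scaffold or chromosome identifier.
#' @param start_mb,end_mb positions in Mb, `start_mb <= end_mb`.
#' @return object of class `"physical_interval"`.
#' @examples
#' physical_interval("scaffold_3", 18.490, 19.780)
#' @export
physical_interval <- function(scaffold, start_mb, end_mb) {
  if (!is.numeric(start_mb) || !is.numeric(end_mb) || start_mb > end_mb)
    stop("'start_mb' must not exceed 'end_mb'", call. = FALSE)
  structure(list(scaffold = as.character(scaffold),
                 start_mb = start_mb, end_mb = end_mb),
            class = "physical_interval")
}

#' @export
print.physical_interval <- function(x, ...) {
  cat(sprintf("%s: %.3f-%.3f Mb (%.3f Mb)\n", x$scaffold,
              x$start_mb, x$end_mb, interval_length(x)))
  invisible(x)
}

#' Length and overlap of physical intervals
#'
#' `interval_length()` returns `end - start` in Mb; `interval_overlap()`
#' returns `max(0, min(ends) - max(starts))` for two intervals on the same
#' scaffold. Both round away floating-point drift below 1e-9 so that
#' 3-decimal printed endpoints give exact answers; `as_kb()` converts Mb to
#' the nearest integer kb.
#'
#' @param iv,a,b [physical_interval()] objects.
#' @return length/overlap in Mb.
#' @examples
#' mlocus <- physical_interval("scaffold_3", 18.490, 19.780)
#' interval_length(mlocus)  # 1.29
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "physical_interval"))
  round(iv$end_mb - iv$start_mb, 9)
}

#' @rdname interval_length
#' @export
interval_overlap <- function(a, b) {
  stopifnot(inherits(a, "physical_interval"), inherits(b, "physical_interval"))
  if (a$scaffold != b$scaffold)
    stop("intervals lie on different scaffolds: ", a$scaffold, " vs ", b$scaffold,
         call. = FALSE)
  round(max(0, min(a$end_mb, b$end_mb) - max(a$start_mb, b$start_mb)), 9)
}

#' @rdname interval_length
#' @param mb megabase value(s).
#' @export
as_kb <- function(mb) as.integer(round(mb * 1000))

#' Genome-average physical-to-genetic distance ratio
#'
#' @param genome_mb physical genome (or region) size in Mb.
#' @param genome_cm genetic map length in cM, `> 0`.
#' @param digits decimals for the reported ratio (2, as conventionally
#'   printed).
#' @return Mb/cM ratio.
#' @examples
#' mb_per_cm(290, 519)  # 0.56
#' @export
mb_per_cm <- function(genome_mb, genome_cm, digits = 2) {
  if (genome_cm <= 0) stop("'genome_cm' must be positive", call. = FALSE)
  round(genome_mb / genome_cm, digits)
}

as_allele_profile <- function(x) {
  # accept a data.frame(locus, allele, freq) or a named list of named
  # numeric frequency vectors
  if (is.data.frame(x)) {
    stopifnot(all(c("locus", "allele", "freq") %in% names(x)))
    x <- split(setNames(x$freq, x$allele), x$locus)
  }
  stopifnot(is.list(x), !is.null(names(x)))
  for (loc in names(x)) {
    f <- x[[loc]]
    if (is.null(names(f)) || any(f < 0) || abs(sum(f) - 1) > 1e-9)
      stop("allele frequencies at locus '", loc,
           "' must be named, non-negative and sum to 1", call. = FALSE)
  }
  x
}

#' Nei genetic distance and shared-allele fraction between two profiles
#'
#' Computes Nei's (1972) standard genetic distance between two multilocus
#' allele-frequency profiles (for a single diploid cultivar, frequencies
#' per locus are 0, 0.5 or 1):
#' `D = -ln( sum_l sum_i x_i y_i / sqrt(sum_l sum_i x_i^2 * sum_l sum_i y_i^2) )`,
#' identities pooled over loci before normalization. The small-sample
#' (1978-style) variant, which corrects each within-profile identity
#' `J = sum x^2` to `(n_genes * J - 1)/(n_genes - 1)`, is available via
#' `variant = "unbiased"`.
#'
#' The shared-allele fraction is the percentage of distinct alleles present
#' in both profiles, relative to the union of alleles (default) or to the
#' smaller allele set (`shared_basis = "smaller"`).
#'
#' @param a,b allele profiles: data frames with columns `locus`, `allele`,
#'   `freq`, or named lists of named per-locus frequency vectors. Only loci
#'   typed in both profiles enter the distance.
#' @param variant `"standard"` (1972) or `"unbiased"` (small-sample
#'   correction).
#' @param n_genes gene copies behind each profile (2 for one diploid
#'   individual); used only by the unbiased variant.
#' @param shared_basis denominator convention for the shared-allele
#'   percentage.
#' @return list of class `"nei_distance"`: `D` (may be `Inf` when the
#'   pooled identity is 0), `identity`, `shared_percent`, `n_loci`.
#' @examples
#' a <- data.frame(locus = c("L1", "L1", "L2"), allele = c("150", "152", "200"),
#'                 freq = c(0.5, 0.5, 1))
#' nei_distance(a, a)  # D = 0, shared = 100
#' @export
nei_distance <- function(a, b, variant = c("standard", "unbiased"),
                         n_genes = 2, shared_basis = c("union", "smaller")) {
  variant <- match.arg(variant)
  shared_basis <- match.arg(shared_basis)
  a <- as_allele_profile(a); b <- as_allele_profile(b)
  loci <- intersect(names(a), names(b))
  if (length(loci) == 0)
    stop("profiles share no typed locus", call. = FALSE)
  jxy <- jx <- jy <- 0
  for (loc in loci) {
    fa <- a[[loc]]; fb <- b[[loc]]
    alleles <- union(names(fa), names(fb))
    xa <- setNames(rep(0, length(alleles)), alleles); xa[names(fa)] <- fa
    xb <- setNames(rep(0, length(alleles)), alleles); xb[names(fb)] <- fb
    jxy <- jxy + sum(xa * xb)
    if (variant == "unbiased") {
      jx <- jx + (n_genes * sum(xa^2) - 1) / (n_genes - 1)
      jy <- jy + (n_genes * sum(xb^2) - 1) / (n_genes - 1)
    } else {
      jx <- jx + sum(xa^2)
      jy <- jy + sum(xb^2)
    }
  }
  if (jx <= 0 || jy <= 0) {
    # degenerate small-sample correction (too few gene copies)
    identity <- NA_real_
    d <- NA_real_
  } else {
    identity <- jxy / sqrt(jx * jy)
    d <- if (identity <= 0) Inf else -log(identity)
  }
  # shared alleles over all loci typed in either profile
  all_a <- unlist(lapply(names(a), function(l) paste(l, names(a[[l]])[a[[l]] > 0])))
  all_b <- unlist(lapply(names(b), function(l) paste(l, names(b[[l]])[b[[l]] > 0])))
  denom <- switch(shared_basis,
                  union = length(union(all_a, all_b)),
                  smaller = min(length(all_a), length(all_b)))
  shared <- 100 * length(intersect(all_a, all_b)) / denom
  structure(list(D = d, identity = identity, shared_percent = shared,
                 n_loci = length(loci), variant = variant,
                 shared_basis = shared_basis),
            class = "nei_distance")
}

#' @export
print.nei_distance <- function(x, ...) {
  cat(sprintf("Nei %s genetic distance over %d loci: D = %s (identity %.4f)\n",
              x$variant, x$n_loci,
              if (is.infinite(x$D)) "Inf (no shared identity)" else sprintf("%.4f", x$D),
              x$identity))
  cat(sprintf("  shared alleles (%s basis): %.1f%%\n", x$shared_basis,
              x$shared_percent))
  invisible(x)
}
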