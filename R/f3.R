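#' Classify an F2 recombinant from F3 segregation at a linked marker
#'
#' An F2 individual from a selfing population in which every pollen gamete
#' carried the mutated modifier allele is either heterozygous (`M'm'`) or
#' homozygous (`m'm'`) at the modifier locus. Selfing it and scoring a
#' linked marker that is heterozygous in the F2 discriminates the two:
#' under `m'm'` (no pollen selection) the F3 segregates 1:2:1 over
#' (A, H, B), while under `M'm'` with a tightly linked marker the
#' repulsion-homozygote class A is absent and (H, B) segregate 1:1.
#'
#' The `M'm'` hypothesis is operationalized as a 1:1 chi-square test over
#' (H, B) combined with an exact binomial check that the A-class count is
#' compatible with its expected frequency `r/2` (an upper-tail test at
#' `alpha`); with the default `r = 0` any A individual excludes `M'm'`.
#' The `m'm'` hypothesis is the 1:2:1 chi-square test. The classification
#' is the unique non-rejected hypothesis at `alpha`; when both are rejected
#' or both retained the call is `"ambiguous"`, with both statistics
#' reported.
#'
#' @param counts named F3 counts `c(A = , H = , B = )`.
#' @param r assumed marker-modifier recombination fraction for the A-class
#'   check under `M'm'` (default 0: tight linkage).
#' @param alpha significance level.
#' @return object of class `"f3_call"`: a list with `call` (one of
#'   `"M'm'"`, `"m'm'"`, `"ambiguous"`), `chisq_11`, `p_11` (1:1 over H,B),
#'   `chisq_121`, `p_121` (1:2:1), `p_A` (binomial A-class tail), `n`.
#' @examples
#' classify_f2(c(A = 0, H = 14, B = 15))  # M'm', X2(1:1) = 0.03
#' classify_f2(c(A = 5, H = 15, B = 9))   # m'm', X2(1:2:1) = 1.14
#' @export
classify_f2 <- function(counts, r = 0, alpha = 0.05) {
  if (is.null(names(counts))) names(counts) <- c("A", "H", "B")
  counts <- counts[c("A", "H", "B")]
  counts[is.na(counts)] <- 0
  names(counts) <- c("A", "H", "B")
  n <- sum(counts)
  if (n <= 0) stop("all F3 classes are empty", call. = FALSE)
  if (r < 0 || r > 0.5) stop("'r' must lie in [0, 0.5]", call. = FALSE)
  a <- unname(counts["A"])
  hb <- unname(counts[c("H", "B")])
  g11 <- if (sum(hb) > 0) suppressWarnings(chisq_gof(hb, c(1, 1))) else NULL
  p_A <- if (r == 0) {
    if (a > 0) 0 else 1
  } else {
    stats::pbinom(a - 1L, n, r / 2, lower.tail = FALSE)
  }
  g121 <- suppressWarnings(chisq_gof(counts, c(1, 2, 1)))
  keep_Mm <- !is.null(g11) && g11$p.value >= alpha && p_A >= alpha
  keep_mm <- g121$p.value >= alpha
  call <- if (keep_Mm && !keep_mm) "M'm'"
          else if (keep_mm && !keep_Mm) "m'm'"
          else "ambiguous"
  structure(
    list(call = call,
         chisq_11 = if (is.null(g11)) NA_real_ else unname(g11$statistic),
         p_11 = if (is.null(g11)) NA_real_ else g11$p.value,
         chisq_121 = unname(g121$statistic), p_121 = g121$p.value,
         p_A = p_A, counts = counts, n = n, r = r, alpha = alpha),
    class = "f3_call")
}

#' @export
print.f3_call <- function(x, ...) {
  cat(sprintf("F3 classification: %s  (n = %d)\n", x$call, x$n))
  cat(sprintf("  M'm' [1:1 over H,B]: X2 = %.2f, p = %.3g; A-class binomial p = %.3g\n",
              x$chisq_11, x$p_11, x$p_A))
  cat(sprintf("  m'm' [1:2:1]:        X2 = %.2f, p = %.3g\n",
              x$chisq_121, x$p_121))
  invisible(x)
}

#' Classify a panel of F2 recombinants from their F3 families
#'
#' Applies [classify_f2()] to every heterozygous-marker F3 family of a
#' panel, excluding families with fewer than `min_n` embryos. Rows where
#' the F2 is homozygous (`A` or `B`) are carried through as monomorphic
#' checks: all F3 embryos are expected in the F2's own class.
#'
#' @param panel data frame with columns `f2_id`, `marker`, `f2_genotype`
#'   (`A`/`H`/`B`), `A`, `H`, `B` (F3 counts; `NA` rows are markers not
#'   tested in F3).
#' @param min_n minimum F3 family size for classification (families below
#'   it are reported but not called).
#' @param r,alpha passed to [classify_f2()].
#' @return object of class `"f3_panel"`: data frame with one row per tested
#'   (f2, marker) pair — `f2_id`, `marker`, `f2_genotype`, `A`, `H`, `B`,
#'   `n`, `chisq_11`, `chisq_121`, `p_11`, `p_121`, `call`, `excluded`,
#'   `monomorphic_ok`.
#' @export
classify_f3_panel <- function(panel, min_n = 7, r = 0, alpha = 0.05) {
  stopifnot(is.data.frame(panel),
            all(c("f2_id", "marker", "f2_genotype", "A", "H", "B") %in% names(panel)))
  tested <- panel[!is.na(panel$A) | !is.na(panel$H) | !is.na(panel$B), , drop = FALSE]
  rows <- lapply(seq_len(nrow(tested)), function(i) {
    cnt <- unlist(tested[i, c("A", "H", "B")])
    cnt[is.na(cnt)] <- 0
    n <- sum(cnt)
    base <- data.frame(f2_id = tested$f2_id[i], marker = tested$marker[i],
                       f2_genotype = tested$f2_genotype[i],
                       A = cnt[["A"]], H = cnt[["H"]], B = cnt[["B"]], n = n,
                       chisq_11 = NA_real_, chisq_121 = NA_real_,
                       p_11 = NA_real_, p_121 = NA_real_,
                       call = NA_character_, excluded = FALSE,
                       monomorphic_ok = NA, stringsAsFactors = FALSE)
    if (!identical(tested$f2_genotype[i], "H")) {
      base$monomorphic_ok <- sum(cnt[setdiff(c("A", "H", "B"),
                                             tested$f2_genotype[i])]) == 0
      return(base)
    }
    if (n < min_n) { base$excluded <- TRUE; return(base) }
    cl <- classify_f2(cnt, r = r, alpha = alpha)
    base$chisq_11 <- cl$chisq_11; base$chisq_121 <- cl$chisq_121
    base$p_11 <- cl$p_11; base$p_121 <- cl$p_121
    base$call <- cl$call
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, min_n = min_n, alpha = alpha, r = r,
            class = c("f3_panel", "data.frame"))
}

#' @export
print.f3_panel <- function(x, digits = 2, ...) {
  cat(sprintf("F3 progeny-test panel: %d families (%d classified, min n = %d)\n",
              nrow(x), sum(!is.na(x$call)), attr(x, "min_n")))
  y <- x
  for (cc in c("chisq_11", "chisq_121")) y[[cc]] <- round(y[[cc]], digits)
  for (cc in c("p_11", "p_121")) y[[cc]] <- signif(y[[cc]], 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Recombination breakpoints of a graphical genotype
#'
#' A graphical genotype is an individual's ordered marker genotypes along a
#' chromosome. Every adjacent pair of typed (non-missing) markers with
#' different genotype codes implies a recombination breakpoint in the
#' interval between them, half-open toward the distal marker.
#'
#' @param gg data frame with columns `marker`, `position_mb`, `genotype`
#'   (`A`/`H`/`B`, `NA` for untyped), sorted or sortable by position.
#' @return data frame with one row per breakpoint: `left_marker`,
#'   `right_marker`, `left_mb`, `right_mb`, `from`, `to`.
#' @examples
#' gg <- data.frame(marker = c("m1", "m2", "m3", "m4"),
#'                  position_mb = 1:4,
#'                  genotype = c("A", "A", "H", "H"))
#' infer_breakpoints(gg)  # one breakpoint in (m2, m3]
#' @export
infer_breakpoints <- function(gg) {
  stopifnot(is.data.frame(gg),
            all(c("marker", "position_mb", "genotype") %in% names(gg)))
  gg <- gg[order(gg$position_mb), , drop = FALSE]
  typed <- gg[!is.na(gg$genotype) & gg$genotype != "-", , drop = FALSE]
  if (nrow(typed) < 2)
    stop("need at least 2 typed markers to place breakpoints", call. = FALSE)
  i <- which(typed$genotype[-nrow(typed)] != typed$genotype[-1L])
  data.frame(left_marker = typed$marker[i], right_marker = typed$marker[i + 1L],
             left_mb = typed$position_mb[i], right_mb = typed$position_mb[i + 1L],
             from = typed$genotype[i], to = typed$genotype[i + 1L],
             stringsAsFactors = FALSE)
}

# Positions where a recombinant's implied modifier genotype can equal the
# target code: union of open intervals around maximal runs of target-typed
# markers, extended to the nearest differently-typed marker on either side
# (or the chromosome end). Returns a 2-column matrix of (lo, hi).
consistent_region <- function(typed, target) {
  is_t <- typed$genotype == target
  if (!any(is_t)) return(NULL)
  runs <- rle(is_t)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ivs <- lapply(which(runs$values), function(k) {
    lo <- if (starts[k] > 1L) typed$position_mb[starts[k] - 1L] else -Inf
    hi <- if (ends[k] < nrow(typed)) typed$position_mb[ends[k] + 1L] else Inf
    c(lo, hi)
  })
  do.call(rbind, ivs)
}

intersect_interval_sets <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1L], b[j, 1L]); hi <- min(a[i, 2L], b[j, 2L])
    if (lo < hi) out[[length(out) + 1L]] <- c(lo, hi)
  }
  if (length(out) == 0) NULL else do.call(rbind, out)
}

#' Delimit the modifier locus from classified recombinants
#'
#' Intersects, over a set of F2 recombinants with known modifier-genotype
#' classifications, the chromosome regions whose marker-implied genotype is
#' consistent with each recombinant's class: an `M'm'` recombinant places
#' the locus where its graphical genotype is (or may be, between typed
#' markers) heterozygous `H`; an `m'm'` recombinant where it is `B`
#' (coupling homozygote). Regions typed `A` (both chromosomes carrying the
#' functional-side allele) can never contain the locus, because every
#' individual received the mutated allele through pollen.
#'
#' @param genotypes data frame of graphical genotypes: columns `f2_id`,
#'   `marker`, `position_mb`, `genotype` (`A`/`H`/`B`; untyped markers may
#'   be omitted or `NA`).
#' @param calls named character vector mapping `f2_id` to `"M'm'"` or
#'   `"m'm'"` (e.g. from [classify_f3_panel()]); ambiguous or missing
#'   recombinants are skipped.
#' @return object of class `"locus_interval"`: list with `interval`
#'   (`c(lo, hi)` in Mb, possibly infinite at an end), `flank_markers`
#'   (markers at the finite bounds), `n_informative`, and `conflicts`
#'   (recombinants whose constraints emptied the intersection; the
#'   intersection of the remainder is then reported with a warning).
#' @export
locus_interval_from_recombinants <- function(genotypes, calls) {
  stopifnot(is.data.frame(genotypes),
            all(c("f2_id", "marker", "position_mb", "genotype") %in% names(genotypes)))
  calls <- calls[!is.na(calls) & calls %in% c("M'm'", "m'm'")]
  if (length(calls) == 0)
    stop("need at least one classified recombinant", call. = FALSE)
  region <- matrix(c(-Inf, Inf), nrow = 1)
  conflicts <- character()
  used <- 0L
  for (id in names(calls)) {
    gg <- genotypes[genotypes$f2_id == id & !is.na(genotypes$genotype), , drop = FALSE]
    if (nrow(gg) == 0) next
    gg <- gg[order(gg$position_mb), , drop = FALSE]
    target <- if (calls[[id]] == "M'm'") "H" else "B"
    cr <- consistent_region(gg, target)
    if (is.null(cr)) { conflicts <- c(conflicts, id); next }
    nxt <- intersect_interval_sets(region, cr)
    if (is.null(nxt)) { conflicts <- c(conflicts, id); next }
    region <- nxt
    used <- used + 1L
  }
  if (length(conflicts) > 0)
    warning("recombinant(s) inconsistent with the joint interval: ",
            paste(conflicts, collapse = ", "), call. = FALSE)
  if (used == 0L)
    stop("no informative recombinant genotypes", call. = FALSE)
  # report the convex hull of the remaining region (a single interval in
  # all non-pathological panels)
  lo <- min(region[, 1L]); hi <- max(region[, 2L])
  pos <- unique(genotypes[, c("marker", "position_mb")])
  flank <- c(lower = if (is.finite(lo)) pos$marker[match(lo, pos$position_mb)] else NA,
             upper = if (is.finite(hi)) pos$marker[match(hi, pos$position_mb)] else NA)
  structure(list(interval = c(lo, hi), flank_markers = flank,
                 n_informative = used, conflicts = conflicts),
            class = "locus_interval")
}

#' @export
print.locus_interval <- function(x, ...) {
  cat(sprintf("Modifier locus interval from %d recombinant(s): (%s, %s) Mb\n",
              x$n_informative,
              format(x$interval[1]), format(x$interval[2])))
  cat("  flanking markers:",
      paste(ifelse(is.na(x$flank_markers), "<chromosome end>", x$flank_markers),
            collapse = " - "), "\n")
  if (length(x$conflicts))
    cat("  conflicting recombinants:", paste(x$conflicts, collapse = ", "), "\n")
  invisible(x)
}
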