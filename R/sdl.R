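#' @keywords internal
"_PACKAGE"

ABXAB <- "<abxab>"
OUTCROSS_TYPES <- c("<efxeg>", "<nnxnp>", "<abxcd>")
# code pairs per outcross sub-type, in JoinMap order
CODE_PAIRS <- list("<abxcd>" = c("c", "d"),
                   "<efxeg>" = c("e", "g"),
                   "<nnxnp>" = c("n", "p"))

split_seg_type <- function(seg_type) {
  parts <- strsplit(seg_type, "/", fixed = TRUE)[[1L]]
  bad <- setdiff(parts, c(ABXAB, OUTCROSS_TYPES))
  if (length(bad) > 0)
    stop("unknown segregation type code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  parts
}

#' Segregation-distortion test for one marker
#'
#' Tests a marker's genotype class counts against its Mendelian expectation
#' in a population derived from a self-compatible pollen parent:
#' `1:2:1` over (A, H, B) for an `<abxab>` intercross marker, and `1:1`
#' over the two pollen-parent-derived allele classes for the outcross types
#' `<efxeg>`, `<nnxnp>` and `<abxcd>`.
#'
#' Composite segregation types such as `"<efxeg>/<nnxnp>"` (a marker scored
#' with different code pairs in different sub-populations) are pooled by
#' first aligning, within every code pair, the majority-transmitted
#' (coupling) class against the minority class and then summing; ties in a
#' pair are flagged ambiguous.
#'
#' The coupling-allele loss frequency — the fraction of scored individuals
#' whose genotype lacks the allele transmitted in coupling with the
#' mutation — is `min(A, B) / N` for `<abxab>` (the repulsion-homozygote
#' frequency) and the pooled minority fraction for outcross types.
#'
#' @param counts named counts. For `<abxab>`: names among `A`, `H`, `B`.
#'   For outcross types: names among `c`, `d`, `e`, `g`, `n`, `p` (only the
#'   pairs declared by `seg_type`). Missing calls are excluded upstream.
#' @param seg_type segregation type code, possibly composite.
#' @param alpha significance level for the distortion flag.
#' @return a list of class `"sdl_result"`: `counts`, `n`, `statistic`, `df`,
#'   `p.value`, `distorted`, `coupling_loss`, `ambiguous`, `seg_type`.
#' @examples
#' marker_distortion_test(c(A = 0, H = 48, B = 37), "<abxab>")   # 33.64
#' marker_distortion_test(c(n = 60, p = 0), "<nnxnp>")           # 60.00
#' @export
marker_distortion_test <- function(counts, seg_type, alpha = 0.05) {
  parts <- split_seg_type(seg_type)
  counts <- counts[!is.na(counts)]
  if (sum(counts) <= 0) stop("no usable calls for this marker", call. = FALSE)
  ambiguous <- FALSE
  if (identical(parts, ABXAB)) {
    obs <- counts[c("A", "H", "B")]
    obs[is.na(obs)] <- 0
    names(obs) <- c("A", "H", "B")
    g <- suppressWarnings(chisq_gof(obs, c(1, 2, 1)))
    loss <- unname(min(obs["A"], obs["B"]) / sum(obs))
    if (obs["A"] == obs["B"]) ambiguous <- TRUE
  } else if (all(parts %in% OUTCROSS_TYPES)) {
    coup <- 0; rep_ <- 0
    for (tp in parts) {
      pair <- CODE_PAIRS[[tp]]
      v <- counts[pair]
      v[is.na(v)] <- 0
      if (v[1L] == v[2L] && sum(v) > 0) ambiguous <- TRUE
      coup <- coup + max(v)
      rep_ <- rep_ + min(v)
    }
    obs <- c(coupling = coup, repulsion = rep_)
    g <- suppressWarnings(chisq_gof(obs, c(1, 1)))
    loss <- unname(rep_ / (coup + rep_))
  } else {
    stop("segregation type mixes intercross and outcross codes: ", seg_type,
         call. = FALSE)
  }
  structure(
    list(counts = obs, n = sum(obs), statistic = unname(g$statistic),
         df = unname(g$parameter), p.value = g$p.value,
         distorted = g$p.value < alpha, coupling_loss = loss,
         ambiguous = ambiguous, seg_type = seg_type, alpha = alpha),
    class = "sdl_result")
}

#' @export
print.sdl_result <- function(x, ...) {
  cat(sprintf("Marker distortion test (%s): X2 = %.2f, df = %d, p = %.3g%s\n",
              x$seg_type, x$statistic, x$df, x$p.value,
              if (x$distorted) " [distorted]" else ""))
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=", collapse = " "),
      sprintf(" coupling-loss freq = %.3f%s\n", x$coupling_loss,
              if (x$ambiguous) " (coupling allele ambiguous)" else ""))
  invisible(x)
}

#' Expected F2 marker genotype frequencies under pollen selection
#'
#' In a selfing population where only mutation-carrying pollen is
#' transmitted, a marker at recombination fraction `r` from the modifier
#' locus segregates `(r/2, 1/2, (1 - r)/2)` over (repulsion homozygote,
#' heterozygote, coupling homozygote): eggs are unselected while pollen
#' transmits the coupling allele with probability `1 - r`. At `r = 0.25`
#' this is the 1:4:3 ratio; at `r = 0.5`, the Mendelian 1:2:1; at `r = 0`,
#' 0:1:1.
#'
#' @param r recombination fraction(s) in `[0, 0.5]`.
#' @return matrix with columns `repulsion_hom`, `het`, `coupling_hom`
#'   (one row per `r`); rows sum to 1.
#' @examples
#' expected_f2_marker_freqs(c(0, 0.25, 0.5))
#' @export
expected_f2_marker_freqs <- function(r) {
  if (any(r < 0 | r > 0.5))
    stop("recombination fractions must lie in [0, 0.5]", call. = FALSE)
  cbind(repulsion_hom = r / 2, het = 1 / 2, coupling_hom = (1 - r) / 2)
}

#' Method-of-moments estimate of marker-modifier recombination from F2 counts
#'
#' Inverts [expected_f2_marker_freqs()]: the repulsion-homozygote frequency
#' is `r/2`, so `r_hat = min(0.5, 2 * A / N)`.
#'
#' @param counts named vector with elements `A` (repulsion homozygotes),
#'   `H`, `B`; or a plain length-3 vector in (A, H, B) order.
#' @return estimate in `[0, 0.5]`, with attribute `n`; attribute
#'   `low_n = TRUE` when `N < 30` (the estimate is then imprecise).
#' @examples
#' estimate_r_from_f2(c(A = 4, H = 46, B = 35))  # 2*4/85
#' @export
estimate_r_from_f2 <- function(counts) {
  if (is.null(names(counts))) names(counts) <- c("A", "H", "B")
  n <- sum(counts)
  if (n <= 0) stop("total count must be positive", call. = FALSE)
  r <- min(0.5, 2 * unname(counts["A"]) / n)
  structure(r, n = n, low_n = n < 30)
}

#' Coupling-allele loss frequency among mutation carriers
#'
#' Fraction of individuals known to carry the mutated modifier allele whose
#' marker genotype lacks the SSR allele transmitted in coupling phase with
#' the mutation. The coupling allele is inferred as the pollen-parent
#' allele with the larger transmitted count (majority transmission); a tie
#' is flagged ambiguous. Markers absolutely linked to the modifier have
#' loss frequency exactly 0.
#'
#' @param calls character vector of genotype codes for the carrier subset
#'   (`A`/`H`/`B` for `<abxab>`; transmitted-class codes for outcross
#'   types), `NA` or `"-"` for missing.
#' @param seg_type segregation type of the marker (non-composite here;
#'   composite markers go through [marker_distortion_test()]).
#' @return the loss fraction in `[0, 1]`, with attribute `ambiguous`.
#' @examples
#' coupling_loss_frequency(c(rep("H", 48), rep("B", 37)), "<abxab>")  # 0
#' @export
coupling_loss_frequency <- function(calls, seg_type) {
  calls <- calls[!is.na(calls) & calls != "-"]
  if (length(calls) == 0)
    stop("all calls missing in the carrier subset", call. = FALSE)
  tab <- table(calls)
  counts <- setNames(as.numeric(tab), names(tab))
  res <- marker_distortion_test(counts, seg_type)
  structure(res$coupling_loss, ambiguous = res$ambiguous)
}

#' Scan a marker table for segregation-distortion loci
#'
#' Runs [marker_distortion_test()] on every marker of a table, in map
#' order, producing the per-marker chi-square statistic, distortion flag at
#' `alpha`, and coupling-allele loss frequency. The chi-square thresholds
#' corresponding to `alpha` (5.99 at 2 df, 3.84 at 1 df for
#' `alpha = 0.05`) are recorded on the result.
#'
#' @param markers a data frame with columns `locus`, `seg_type`, count
#'   columns (`A`,`H`,`B` and/or `c`,`d`,`e`,`g`,`n`,`p`; `NA` where a code
#'   does not apply), and optionally `lg` (or `scaffold`), `position_mb`,
#'   `position_cm`. Markers are sorted by (`lg`, `position_mb`) when
#'   positions are present. Alternatively a `"genotype_table"` from
#'   [read_genotype_table()] or the simulator, whose calls are tallied.
#' @param alpha significance level for the distortion flag.
#' @return an object of class `"sdl_scan"`: a data frame with one row per
#'   marker (`locus`, `lg`, `position_mb`, `seg_type`, `n`, `statistic`,
#'   `df`, `p.value`, `distorted`, `coupling_loss`, `ambiguous`).
#' @seealso [localize_locus()]
#' @export
sdl_scan <- function(markers, alpha = 0.05) {
  if (inherits(markers, "genotype_table")) markers <- tally_genotype_table(markers)
  stopifnot(is.data.frame(markers))
  if (!all(c("locus", "seg_type") %in% names(markers)))
    stop("'markers' needs at least 'locus' and 'seg_type' columns", call. = FALSE)
  if (is.null(markers$lg) && !is.null(markers$scaffold)) markers$lg <- markers$scaffold
  if (!is.null(markers$position_mb)) {
    o <- order(if (is.null(markers$lg)) rep(1, nrow(markers)) else markers$lg,
               markers$position_mb)
    markers <- markers[o, , drop = FALSE]
  }
  count_cols <- intersect(c("A", "H", "B", "c", "d", "e", "g", "n", "p"),
                          names(markers))
  rows <- lapply(seq_len(nrow(markers)), function(i) {
    cnt <- unlist(markers[i, count_cols, drop = TRUE])
    res <- marker_distortion_test(cnt[!is.na(cnt)], markers$seg_type[i], alpha)
    data.frame(locus = markers$locus[i],
               lg = if (is.null(markers$lg)) NA else markers$lg[i],
               position_mb = if (is.null(markers$position_mb)) NA_real_
                             else markers$position_mb[i],
               seg_type = markers$seg_type[i],
               n = res$n, statistic = res$statistic, df = res$df,
               p.value = res$p.value, distorted = res$distorted,
               coupling_loss = res$coupling_loss, ambiguous = res$ambiguous,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, alpha = alpha,
            thresholds = c(`df=1` = stats::qchisq(1 - alpha, 1),
                           `df=2` = stats::qchisq(1 - alpha, 2)),
            class = c("sdl_scan", "data.frame"))
}

#' @export
print.sdl_scan <- function(x, digits = 2, ...) {
  thr <- attr(x, "thresholds")
  cat(sprintf("SDL scan: %d markers, %d distorted at alpha = %g (X2 thresholds %.2f/%.2f for 1/2 df)\n",
              nrow(x), sum(x$distorted), attr(x, "alpha"), thr[1], thr[2]))
  y <- x
  y$statistic <- round(y$statistic, digits)
  y$p.value <- signif(y$p.value, 3)
  y$coupling_loss <- round(y$coupling_loss, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
summary.sdl_scan <- function(object, ...) {
  lg <- if (all(is.na(object$lg))) rep("?", nrow(object)) else object$lg
  tab <- tapply(object$distorted, lg, sum)
  cat("Distorted markers per linkage group / scaffold:\n")
  print(tab)
  flagged <- names(tab)[tab > 0]
  if (length(flagged))
    cat("Groups carrying at least one distorted marker:",
        paste(flagged, collapse = ", "), "\n")
  invisible(tab)
}

#' @export
plot.sdl_scan <- function(x, y, statistic = c("statistic", "coupling_loss"), ...) {
  statistic <- match.arg(statistic)
  pos <- x$position_mb
  if (all(is.na(pos))) pos <- seq_len(nrow(x))
  val <- x[[statistic]]
  graphics::plot(pos, val, type = "b", pch = 19,
                 xlab = "position (Mb)",
                 ylab = if (statistic == "statistic") expression(chi^2)
                        else "coupling-allele loss frequency", ...)
  if (statistic == "statistic") {
    thr <- attr(x, "thresholds")
    graphics::abline(h = thr, lty = 2, col = "grey40")
  }
  invisible(x)
}

#' Localize the modifier locus from a segregation-distortion scan
#'
#' Finds the maximal run of consecutive markers whose coupling-allele loss
#' frequency is exactly zero (markers through which no recombinant carrier
#' was observed). The locus is reported as lying within the interval
#' bounded by the nearest markers with non-zero loss on either side of the
#' run; the zero run itself is reported as the inner span. Ties between
#' equally long runs are broken towards the run containing the largest
#' chi-square. A run touching a chromosome end yields a one-sided interval
#' flagged as such. If no marker has zero loss, the marker with the largest
#' chi-square is returned as a point estimate, with a warning.
#'
#' @param scan an `"sdl_scan"` result with `position_mb` defined; if it
#'   spans several linkage groups the group holding the largest chi-square
#'   is used.
#' @return object of class `"locus_localization"`: a list with elements
#'   `run_loci`, `run_span_mb`, `flank_loci`, `flank_span_mb`, `one_sided`,
#'   `point_estimate`.
#' @export
localize_locus <- function(scan) {
  stopifnot(inherits(scan, "sdl_scan"))
  x <- scan
  if (!all(is.na(x$lg)) && length(unique(x$lg)) > 1) {
    keep <- x$lg == x$lg[which.max(x$statistic)]
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) < 3)
    stop("localization needs at least 3 markers with loss frequencies",
         call. = FALSE)
  zero <- x$coupling_loss == 0
  if (!any(zero)) {
    i <- which.max(x$statistic)
    warning("no marker with zero coupling-allele loss; returning the maximal-chi-square marker as a point estimate",
            call. = FALSE)
    return(structure(list(run_loci = character(), run_span_mb = c(NA, NA),
                          flank_loci = character(), flank_span_mb = c(NA, NA),
                          one_sided = FALSE,
                          point_estimate = c(locus = x$locus[i],
                                             position_mb = x$position_mb[i])),
                     class = "locus_localization"))
  }
  runs <- rle(zero)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  zi <- which(runs$values)
  # maximal run; ties -> run containing the largest statistic
  len <- runs$lengths[zi]
  best <- zi[len == max(len)]
  if (length(best) > 1) {
    score <- vapply(best, function(k) max(x$statistic[starts[k]:ends[k]]),
                    numeric(1))
    best <- best[which.max(score)]
  } else best <- best[1L]
  lo <- starts[best]; hi <- ends[best]
  left <- if (lo > 1L) lo - 1L else NA_integer_
  right <- if (hi < nrow(x)) hi + 1L else NA_integer_
  one_sided <- is.na(left) || is.na(right)
  flank_idx <- c(left, right)
  structure(
    list(run_loci = x$locus[lo:hi],
         run_span_mb = c(x$position_mb[lo], x$position_mb[hi]),
         flank_loci = x$locus[flank_idx[!is.na(flank_idx)]],
         flank_span_mb = c(if (is.na(left)) x$position_mb[1L] else x$position_mb[left],
                           if (is.na(right)) x$position_mb[nrow(x)] else x$position_mb[right]),
         one_sided = one_sided,
         point_estimate = NULL),
    class = "locus_localization")
}

#' @export
print.locus_localization <- function(x, ...) {
  if (length(x$run_loci) == 0 && !is.null(x$point_estimate)) {
    cat(sprintf("Locus point estimate at %s (%s Mb); no zero-loss marker\n",
                x$point_estimate["locus"], x$point_estimate["position_mb"]))
    return(invisible(x))
  }
  cat(sprintf("Zero-loss run: %s (%.2f-%.2f Mb)\n",
              paste(x$run_loci, collapse = ", "),
              x$run_span_mb[1], x$run_span_mb[2]))
  cat(sprintf("Locus interval (non-zero flanks%s): %s, %.2f-%.2f Mb\n",
              if (x$one_sided) "; one-sided" else "",
              paste(x$flank_loci, collapse = " - "),
              x$flank_span_mb[1], x$flank_span_mb[2]))
  invisible(x)
}
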