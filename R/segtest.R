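#' Chi-square goodness of fit of genotype counts against an expected ratio
#'
#' Pearson chi-square test of observed class counts against expected counts
#' `E_i = N * ratio_i / sum(ratio)`, without continuity correction, with
#' `k - 1` degrees of freedom and an upper-tail p-value. This is the test
#' used for Mendelian segregation-ratio checks of S-genotype and SSR marker
#' classes.
#'
#' A warning of class `"ppmap_small_expected"` is raised when any expected
#' count falls below 5 (the test is still performed).
#'
#' @param observed non-negative integer counts, optionally named by class.
#' @param ratio positive expected-ratio vector of the same length, e.g.
#'   `c(2, 1, 1)`; scale is irrelevant.
#' @return an object of class `"ppmap_gof"` (and `"htest"`-like): a list with
#'   `statistic`, `parameter` (df), `p.value`, `observed`, `expected`,
#'   `ratio`.
#' @examples
#' chisq_gof(c(S1S2 = 45, S2S2 = 33, S1S1 = 16), c(2, 1, 1))  # 6.32
#' @export
chisq_gof <- function(observed, ratio) {
  if (length(observed) != length(ratio))
    stop("'observed' and 'ratio' must have the same length", call. = FALSE)
  if (any(observed < 0) || any(is.na(observed)))
    stop("'observed' must be non-negative counts", call. = FALSE)
  if (any(ratio <= 0))
    stop("all 'ratio' entries must be positive", call. = FALSE)
  n <- sum(observed)
  if (n <= 0) stop("total count must be positive", call. = FALSE)
  expected <- n * ratio / sum(ratio)
  if (any(expected < 5))
    warning(structure(
      class = c("ppmap_small_expected", "warning", "condition"),
      list(message = sprintf("%d expected count(s) below 5; chi-square approximation may be poor",
                             sum(expected < 5)),
           call = sys.call(-1))))
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(
    list(statistic = c(`X-squared` = stat),
         parameter = c(df = df),
         p.value = stats::pchisq(stat, df, lower.tail = FALSE),
         observed = observed, expected = expected, ratio = ratio,
         method = "Pearson chi-square goodness of fit (no continuity correction)"),
    class = c("ppmap_gof", "htest"))
}

#' Compare competing pollen-part-mutation hypotheses on observed counts
#'
#' For each hypothesis, derives the expected S-genotype ratio of the cross
#' via [expected_ratio()], aligns it with the observed classes, and runs
#' [chisq_gof()]. A hypothesis whose expected ratio assigns zero probability
#' to a non-empty observed class is reported as excluded, with an infinite
#' statistic.
#'
#' @param observed named counts; names are canonical S-genotype labels as
#'   produced by [s_genotype_label()] (e.g. `"S1S2"`).
#' @param cross a [cross_spec()].
#' @param hypotheses list of [model_hypothesis()] objects.
#' @return an object of class `"hypothesis_comparison"`: a data frame with
#'   one row per hypothesis (`hypothesis`, `ratio`, `statistic`, `df`,
#'   `p.value`, `excluded`), ordered by ascending statistic.
#' @examples
#' katy <- parent_genotype(c("S1", "S2"), modifier = c("M", "m"))
#' harcot <- parent_genotype(c("S1", "S4"))
#' hxk <- cross_spec(harcot, katy, "H x K")
#' obs <- c(S1S2 = 20, S1S1 = 4, S1S4 = 7, S2S4 = 13)
#' compare_hypotheses(obs, hxk,
#'   list(model_hypothesis("het_unlinked"),
#'        model_hypothesis("homozygous_mutated")))
#' @export
compare_hypotheses <- function(observed, cross, hypotheses) {
  stopifnot(inherits(cross, "cross_spec"))
  if (inherits(hypotheses, "model_hypothesis")) hypotheses <- list(hypotheses)
  if (is.null(names(observed)))
    stop("'observed' must be named by S-genotype class", call. = FALSE)
  # universe of classes the cross can form at all (selection ignored)
  universe <- unique(c(outer(cross$seed_parent$s, cross$pollen_parent$s,
                             Vectorize(function(a, b) s_genotype_label(c(a, b))))))
  unmappable <- setdiff(names(observed), universe)
  if (length(unmappable) > 0)
    stop("observed class label(s) not formable by this cross: ",
         paste(unmappable, collapse = ", "), call. = FALSE)
  rows <- lapply(hypotheses, function(h) {
    er <- expected_ratio(cross, h)
    unknown <- setdiff(names(observed), names(er))
    bad <- unknown[observed[unknown] > 0]
    if (length(bad) > 0 && sum(er) > 0) {
      # observed class impossible under this hypothesis
      return(data.frame(hypothesis = format_hypothesis(h),
                        ratio = paste(er, collapse = ":"),
                        statistic = Inf, df = NA_integer_, p.value = 0,
                        excluded = TRUE, stringsAsFactors = FALSE))
    }
    impossible <- setdiff(unknown, bad)
    if (length(impossible) == length(observed) || sum(er) == 0)
      stop("no observed class maps onto the hypothesis's offspring classes: ",
           paste(names(observed), collapse = ", "), call. = FALSE)
    obs <- observed[setdiff(names(observed), impossible)]
    # classes predicted but unobserved enter with count 0
    miss <- setdiff(names(er), names(obs))
    obs <- c(obs, setNames(rep(0, length(miss)), miss))[names(er)]
    g <- chisq_gof(obs, unname(er))
    data.frame(hypothesis = format_hypothesis(h),
               ratio = paste(er, collapse = ":"),
               statistic = unname(g$statistic), df = unname(g$parameter),
               p.value = g$p.value, excluded = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$statistic), ]
  rownames(out) <- NULL
  structure(out, label = cross$label,
            class = c("hypothesis_comparison", "data.frame"))
}

#' @export
print.hypothesis_comparison <- function(x, digits = 2, ...) {
  lab <- attr(x, "label")
  cat(sprintf("Hypothesis comparison%s\n",
              if (!is.null(lab)) paste0(" for '", lab, "'") else ""))
  y <- x
  y$statistic <- round(y$statistic, digits)
  y$p.value <- signif(y$p.value, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
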