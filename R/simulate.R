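# Forward simulator of GSI crosses with pollen selection over a marker map.
#
# Meiosis model: crossovers between adjacent loci are independent
# (no interference), with recombination fractions obtained from the input
# cM positions through the inverse map function (Haldane by default;
# Kosambi available — at the short distances involved the difference is
# below sampling noise).

# Draw n gametes from a pair of homologous haplotypes.
# haps: 2 x M matrix of marker allele codes (row = homolog);
# modifier: length-2 vector of modifier alleles per homolog;
# loci_cm: marker positions; modifier_cm: modifier position.
# Returns list(alleles = n x M matrix, modifier = length-n vector,
#              homolog_at_modifier = 1/2).
draw_gametes <- function(haps, modifier, loci_cm, modifier_cm, n,
                         map_function = "haldane") {
  pos <- c(loci_cm, modifier_cm)
  ord <- order(pos)
  pos_s <- pos[ord]
  L <- length(pos_s)
  start <- stats::rbinom(n, 1, 0.5)
  if (L > 1) {
    r <- inverse_map_distance(diff(pos_s), map_function)
    sw <- matrix(stats::rbinom(n * (L - 1L), 1, rep(r, each = n)), nrow = n)
    cums <- sw %*% upper.tri(matrix(0, L - 1L, L - 1L), diag = TRUE)
    h <- cbind(start, (start + cums) %% 2)
  } else {
    h <- matrix(start, ncol = 1)
  }
  h <- h[, order(ord), drop = FALSE] + 1L  # back to input locus order, 1/2
  mod_col <- length(loci_cm) + 1L
  marker_h <- h[, seq_along(loci_cm), drop = FALSE]
  alleles <- matrix(0L, n, ncol(marker_h))
  for (j in seq_len(ncol(marker_h))) alleles[, j] <- haps[marker_h[, j], j]
  list(alleles = alleles,
       modifier = modifier[h[, mod_col]],
       homolog_at_modifier = h[, mod_col])
}

# S-haplotype transmitted by each gamete: independent of the modifier
# chromosome when r_sm = 0.5, otherwise co-segregating with the homolog at
# the modifier position, switching with probability r_sm.
draw_s_index <- function(parent, homolog_at_modifier, n) {
  if (parent$r_sm >= 0.5 || is.null(parent$phase)) {
    stats::rbinom(n, 1, 0.5) + 1L
  } else {
    # homolog carrying modifier allele parent$modifier[k] is linked to the
    # S haplotype whose phase entry equals that allele
    mod_allele <- parent$modifier[homolog_at_modifier]
    linked_s <- vapply(mod_allele, function(a) {
      hit <- names(parent$phase)[parent$phase == a][1L]
      match(hit, parent$s)
    }, integer(1))
    flip <- stats::rbinom(n, 1, parent$r_sm) == 1
    ifelse(flip, 3L - linked_s, linked_s)
  }
}

#' Marker map for simulations
#'
#' Convenience constructor for the simulator's marker map: locus names,
#' physical positions (Mb) and genetic positions (cM). When `position_cm`
#' is missing it is derived from the physical positions at a constant
#' `mb_per_cm` ratio (0.56 Mb/cM, a genome-average value for Prunus).
#'
#' @param locus marker names.
#' @param position_mb physical positions in Mb.
#' @param position_cm genetic positions in cM (optional).
#' @param seg_type segregation type per marker (recycled).
#' @param scaffold scaffold id (recycled).
#' @param mb_per_cm conversion ratio used when `position_cm` is absent.
#' @return data frame with columns `locus`, `scaffold`, `position_mb`,
#'   `position_cm`, `seg_type`.
#' @export
sim_marker_map <- function(locus, position_mb, position_cm = NULL,
                           seg_type = "<abxab>", scaffold = "scaffold_3",
                           mb_per_cm = 0.56) {
  if (is.null(position_cm)) position_cm <- position_mb / mb_per_cm
  data.frame(locus = locus, scaffold = scaffold,
             position_mb = position_mb, position_cm = position_cm,
             seg_type = rep_len(seg_type, length(locus)),
             stringsAsFactors = FALSE)
}

#' Simulate a progeny population under GSI pollen selection
#'
#' Draws `n` offspring of a cross: egg gametes are sampled unselected from
#' the seed parent; pollen gametes are sampled from the pollen parent and
#' passed through the pistil screen of [pollen_compatible()] by rejection
#' sampling (optionally weighted by S-haplotype-specific gamete fitness).
#' Each parent's homolog 1 carries its first modifier allele and private
#' marker allele 1, homolog 2 the second; for an `M'm'` parent declared as
#' `modifier = c("M", "m")`, marker allele 1 is therefore in coupling with
#' the functional allele and the repulsion homozygote class `A` counts
#' individuals with two copies of allele 1.
#'
#' Marker genotypes are emitted in JoinMap-style codes per the map's
#' `seg_type`: `A`/`H`/`B` for `<abxab>` intercross markers (count of
#' allele-1 copies 2/1/0), and the transmitted pollen class for the
#' outcross types (`n`/`p` for `<nnxnp>`, `e`/`g` for `<efxeg>`, `c`/`d`
#' for `<abxcd>`; the first code of the pair is the allele in coupling
#' with the pollen parent's second — mutated — homolog).
#'
#' @param cross a [cross_spec()].
#' @param map marker map from [sim_marker_map()] (focal chromosome only).
#' @param n number of offspring.
#' @param modifier_cm position of the modifier locus on the focal
#'   chromosome, in cM. Use a large value (or `Inf`-like distance via
#'   `unlinked = TRUE`) for an unlinked modifier.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param map_function `"haldane"` (default) or `"kosambi"` inverse
#'   transform for inter-locus recombination fractions.
#' @param fitness optional named vector of relative pollen-fitness
#'   multipliers by S-haplotype label (default all 1).
#' @param unlinked if `TRUE` the modifier segregates independently of the
#'   marker chromosome.
#' @return object of class `"sim_population"`: list with `calls` (a
#'   `"genotype_table"` data frame: column `individual` plus one column per
#'   marker), `s_genotype`, `m_genotype`, `s_counts`, the transmitted
#'   haplotypes (`egg_alleles`, `pollen_alleles`, `egg_modifier`,
#'   `pollen_modifier`), `map`, `modifier_cm`, `seed`, `no_offspring`
#'   (TRUE when no compatible pollen exists — then all components are
#'   empty).
#' @examples
#' katy <- parent_genotype(c("S1", "S2"), modifier = c("M", "m"), label = "Katy")
#' map <- sim_marker_map(c("m1", "m2"), c(18.49, 19.14))
#' pop <- simulate_cross_population(cross_spec(katy, katy, "K x K"), map,
#'                                  n = 50, modifier_cm = 33.4, seed = 1)
#' pop$s_counts
#' @export
simulate_cross_population <- function(cross, map, n, modifier_cm, seed,
                                      map_function = c("haldane", "kosambi"),
                                      fitness = NULL, unlinked = FALSE) {
  stopifnot(inherits(cross, "cross_spec"), n > 0)
  map_function <- match.arg(map_function)
  set.seed(as.integer(seed))
  sp <- cross$seed_parent; pp <- cross$pollen_parent
  # analytic feasibility check: is any pollen gamete type compatible?
  pd <- gamete_distribution(pp)
  any_ok <- any(pollen_compatible(pd$s, sp, pd$modifier, pd$defective))
  if (!any_ok) {
    return(structure(list(no_offspring = TRUE, calls = NULL, s_counts = NULL,
                          message = "no offspring possible: all pollen rejected",
                          cross = cross, seed = seed),
                     class = "sim_population"))
  }
  M <- nrow(map)
  hap_alleles <- rbind(rep(1L, M), rep(2L, M))
  mod_pos <- if (unlinked) NULL else modifier_cm

  draw_parent <- function(parent, k) {
    if (unlinked) {
      g <- draw_gametes(hap_alleles, parent$modifier, map$position_cm,
                        max(map$position_cm) + 1, k, map_function)
      # overwrite modifier transmission with an independent draw
      idx <- stats::rbinom(k, 1, 0.5) + 1L
      g$modifier <- parent$modifier[idx]
      g$homolog_at_modifier <- idx
      g
    } else {
      draw_gametes(hap_alleles, parent$modifier, map$position_cm,
                   modifier_cm, k, map_function)
    }
  }

  eggs <- draw_parent(sp, n)
  egg_s <- draw_s_index(sp, eggs$homolog_at_modifier, n)

  # rejection-sample compatible pollen
  w <- if (is.null(fitness)) NULL else fitness / max(fitness)
  pol_alleles <- matrix(0L, 0, M); pol_mod <- character(); pol_s <- integer()
  while (length(pol_s) < n) {
    k <- max(2L * (n - length(pol_s)), 200L)
    g <- draw_parent(pp, k)
    si <- draw_s_index(pp, g$homolog_at_modifier, k)
    ok <- pollen_compatible(pp$s[si], sp, g$modifier, pp$defective[si])
    if (!is.null(w)) ok <- ok & (stats::runif(k) < w[pp$s[si]])
    pol_alleles <- rbind(pol_alleles, g$alleles[ok, , drop = FALSE])
    pol_mod <- c(pol_mod, g$modifier[ok])
    pol_s <- c(pol_s, si[ok])
  }
  pol_alleles <- pol_alleles[seq_len(n), , drop = FALSE]
  pol_mod <- pol_mod[seq_len(n)]
  pol_s <- pol_s[seq_len(n)]

  s_geno <- vapply(seq_len(n), function(i)
    s_genotype_label(c(sp$s[egg_s[i]], pp$s[pol_s[i]])), character(1))
  m_geno <- modifier_genotype_label(eggs$modifier, pol_mod)

  calls <- data.frame(individual = sprintf("ind%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
  for (j in seq_len(M)) {
    st <- map$seg_type[j]
    if (st == ABXAB) {
      ones <- (eggs$alleles[, j] == 1L) + (pol_alleles[, j] == 1L)
      calls[[map$locus[j]]] <- c("B", "H", "A")[ones + 1L]
    } else {
      pair <- CODE_PAIRS[[split_seg_type(st)[1L]]]
      # first code of the pair = allele in coupling with pollen homolog 2
      calls[[map$locus[j]]] <- ifelse(pol_alleles[, j] == 2L, pair[1L], pair[2L])
    }
  }
  attr(calls, "map") <- map
  class(calls) <- c("genotype_table", "data.frame")

  structure(
    list(no_offspring = FALSE, calls = calls,
         s_genotype = s_geno, m_genotype = m_geno,
         s_counts = table(s_geno),
         egg_alleles = eggs$alleles, pollen_alleles = pol_alleles,
         egg_modifier = eggs$modifier, pollen_modifier = pol_mod,
         map = map, modifier_cm = if (unlinked) NA_real_ else modifier_cm,
         map_function = map_function, cross = cross, seed = seed),
    class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  if (isTRUE(x$no_offspring)) {
    cat("Simulated population:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("Simulated population of %d offspring (%d markers, seed %s)\n",
              length(x$s_genotype), nrow(x$map), format(x$seed)))
  cat("S-genotype counts:\n")
  print(x$s_counts)
  cat("Modifier genotype counts:\n")
  print(table(x$m_genotype))
  invisible(x)
}

# Tally a genotype table of calls into per-marker class counts usable by
# sdl_scan(). Missing calls ("-"/NA) are excluded listwise per marker.
tally_genotype_table <- function(gt) {
  map <- attr(gt, "map")
  if (is.null(map)) stop("genotype table lacks its marker map", call. = FALSE)
  codes <- c("A", "H", "B", "c", "d", "e", "g", "n", "p")
  rows <- lapply(seq_len(nrow(map)), function(j) {
    v <- gt[[map$locus[j]]]
    v <- v[!is.na(v) & v != "-"]
    cnt <- table(factor(v, levels = codes))
    out <- as.data.frame(as.list(cnt))
    names(out) <- codes
    st <- split_seg_type(map$seg_type[j])
    used <- if (identical(st, ABXAB)) c("A", "H", "B")
            else unlist(CODE_PAIRS[st], use.names = FALSE)
    out[setdiff(codes, used)] <- NA_integer_
    cbind(data.frame(locus = map$locus[j],
                     lg = if (is.null(map$scaffold)) NA else map$scaffold[j],
                     position_mb = map$position_mb[j],
                     seg_type = map$seg_type[j], stringsAsFactors = FALSE),
          out)
  })
  do.call(rbind, rows)
}

#' Simulate F3 families by selfing F2 individuals
#'
#' Selfs selected F2 individuals of a simulated population under the same
#' transmission model (the F2's own pistil screens its pollen, so only
#' mutation-bearing pollen fertilizes unless the F2 is homozygous mutated)
#' and scores the F3 at each requested marker in A/H/B codes on the
#' grandparental allele frame (A = two copies of allele 1, the allele in
#' coupling with the functional modifier allele of the original parent).
#'
#' @param pop a `"sim_population"` from [simulate_cross_population()]
#'   (a selfing design, so that each F2's two haplotypes are on the same
#'   allele frame).
#' @param f2_ids individual ids (from `pop$calls$individual`) to self.
#' @param markers marker names to score in the F3 (default: all).
#' @param sizes F3 family sizes: either a single number, a vector matching
#'   `f2_ids`, or `NULL` to draw uniformly from `size_range`.
#' @param size_range range family sizes are drawn from when `sizes` is
#'   `NULL` (default 2 to 77 embryos).
#' @param seed integer seed.
#' @return data frame of F3 records: `f2_id`, `marker`, `f2_genotype`,
#'   `A`, `H`, `B`, plus `true_m` (the F2's true modifier genotype).
#' @export
simulate_f3_families <- function(pop, f2_ids, markers = NULL, sizes = NULL,
                                 size_range = c(2, 77), seed = 1) {
  stopifnot(inherits(pop, "sim_population"), !isTRUE(pop$no_offspring))
  set.seed(as.integer(seed))
  if (is.null(markers)) markers <- pop$map$locus
  idx <- match(f2_ids, pop$calls$individual)
  if (anyNA(idx)) stop("unknown f2 id(s): ",
                       paste(f2_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  if (is.null(sizes))
    sizes <- sample(size_range[1]:size_range[2], length(idx), replace = TRUE)
  sizes <- rep_len(sizes, length(idx))
  mcols <- match(markers, pop$map$locus)
  out <- list()
  for (k in seq_along(idx)) {
    i <- idx[k]
    haps <- rbind(pop$egg_alleles[i, ], pop$pollen_alleles[i, ])
    mods <- c(pop$egg_modifier[i], pop$pollen_modifier[i])
    nfam <- sizes[k]
    eggs <- draw_gametes(haps, mods, pop$map$position_cm, pop$modifier_cm,
                         nfam, pop$map_function)
    # pollen: all S alleles match the selfed pistil, so rejection depends
    # only on the modifier allele of the gamete
    pol_all <- matrix(0L, 0, ncol(haps)); pol_mod <- character()
    while (length(pol_mod) < nfam) {
      g <- draw_gametes(haps, mods, pop$map$position_cm, pop$modifier_cm,
                        max(2L * nfam, 50L), pop$map_function)
      ok <- g$modifier == "m"
      if (all(mods == "m")) ok <- rep(TRUE, length(ok))
      pol_all <- rbind(pol_all, g$alleles[ok, , drop = FALSE])
      pol_mod <- c(pol_mod, g$modifier[ok])
    }
    pol_all <- pol_all[seq_len(nfam), , drop = FALSE]
    for (j in mcols) {
      ones <- (eggs$alleles[, j] == 1L) + (pol_all[, j] == 1L)
      cls <- c("B", "H", "A")[ones + 1L]
      f2g <- pop$calls[[pop$map$locus[j]]][i]
      out[[length(out) + 1L]] <- data.frame(
        f2_id = f2_ids[k], marker = pop$map$locus[j], f2_genotype = f2g,
        A = sum(cls == "A"), H = sum(cls == "H"), B = sum(cls == "B"),
        true_m = modifier_genotype_label(mods[1L], mods[2L]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a deterministic bundle of simulated fixture files
#'
#' Generates one end-to-end demonstration data set under a single seed and
#' writes it as tab-delimited files: an S-genotype counts file for a
#' selfing population, an F2 marker genotype table and its per-marker
#' count summary (16 markers at the physical positions of the bundled
#' apricot LG3 map, modifier at 18.7 Mb), an outcross-style transmitted
#' allele table restricted to mutation carriers, and an F3 panel for
#' recombinant F2 individuals. Every file carries a header comment with
#' the seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed governing all randomness.
#' @param n_f2 F2 population size.
#' @param n_outcross number of selected mutation-carrier outcross seedlings.
#' @return named character vector of file paths, invisibly.
#' @export
simulate_fixture_suite <- function(dir, seed = 1, n_f2 = 87, n_outcross = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mapdf <- read_marker_map(ppmap_example("katy_lg3_f2.tsv"))
  map <- sim_marker_map(mapdf$locus, mapdf$position_mb)
  modifier_cm <- 18.7 / 0.56
  katy <- parent_genotype(c("S1", "S2"), modifier = c("M", "m"), label = "Katy")
  kxk <- cross_spec(katy, katy, "K x K")

  pop <- simulate_cross_population(kxk, map, n_f2, modifier_cm, seed)
  hdr <- sprintf("# simulated fixture bundle, seed=%d", as.integer(seed))

  paths <- c(
    s_counts = file.path(dir, "sim_s_counts.tsv"),
    f2_genotypes = file.path(dir, "sim_f2_genotypes.tsv"),
    f2_counts = file.path(dir, "sim_f2_marker_counts.tsv"),
    outcross_counts = file.path(dir, "sim_outcross_counts.tsv"),
    f3_panel = file.path(dir, "sim_f3_panel.tsv"))

  sc <- as.data.frame(pop$s_counts, stringsAsFactors = FALSE)
  names(sc) <- c("class", "count")
  sc <- data.frame(cross = "K x K", sc, ratio = "2:1:1")
  write_tsv_with_header(sc, paths["s_counts"], hdr)
  write_tsv_with_header(as.data.frame(pop$calls), paths["f2_genotypes"], hdr)
  write_tsv_with_header(tally_genotype_table(pop$calls), paths["f2_counts"], hdr)

  # outcross: Harcot x Katy, keep seedlings whose S-genotype proves the
  # pollen carried the mutation (S1 transmitted through an S1 pistil)
  harcot <- parent_genotype(c("S1", "S4"), label = "Harcot")
  omap <- sim_marker_map(map$locus, map$position_mb, seg_type = "<nnxnp>")
  hx <- simulate_cross_population(cross_spec(harcot, katy, "H x K"), omap,
                                  4 * n_outcross, modifier_cm, seed + 1)
  keep <- which(hx$s_genotype %in% c("S1S1", "S1S4"))[seq_len(n_outcross)]
  oc <- hx$calls[keep, , drop = FALSE]
  attr(oc, "map") <- omap
  class(oc) <- c("genotype_table", "data.frame")
  write_tsv_with_header(tally_genotype_table(oc), paths["outcross_counts"], hdr)

  # F3 panel: recombinant F2s (a genotype change across the focal region)
  region <- map$locus[map$position_mb >= 4.8 & map$position_mb <= 21.7]
  gmat <- as.matrix(pop$calls[, region, drop = FALSE])
  nchanges <- apply(gmat, 1, function(v) sum(v[-1] != v[-length(v)]))
  rec <- pop$calls$individual[nchanges > 0]
  rec <- rec[seq_len(min(12L, length(rec)))]
  panel <- simulate_f3_families(pop, rec,
                                markers = map$locus[map$position_mb >= 17.3 &
                                                    map$position_mb <= 19.8],
                                seed = seed + 2)
  write_tsv_with_header(panel, paths["f3_panel"], hdr)
  invisible(paths)
}
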