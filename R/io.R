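# Readers and writers for the tab-delimited formats the package uses:
# marker maps, per-marker count tables, individual-level genotype tables,
# S-genotype count files and F3 panels. All files are tab-delimited with
# one header line; leading '#' lines are comments. Decimal commas in
# numeric columns (a common European table convention, e.g. "18,61") are
# normalized to points on read.

LEGAL_CODES <- c("A", "H", "B", "c", "d", "e", "g", "n", "p")

normalize_decimal <- function(x) {
  if (is.character(x)) suppressWarnings(as.numeric(gsub(",", ".", x, fixed = TRUE)))
  else x
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, comment.char = "#", na.strings = c("NA", ""),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "-")
  invisible(path)
}

#' Path to a bundled example data file
#'
#' The package ships the published segregation tables of a self-compatible
#' apricot mapping study as plain tab-delimited files: `katy_s_counts.tsv`
#' (S-genotype counts per cross), `katy_genome_scan.tsv` (genome-wide SSR
#' distortion counts over eight linkage groups), `katy_lg3_f2.tsv`
#' (high-density LG3 F2 marker counts), `katy_lg3_outcross.tsv` (LG3
#' counts for selected mutation-carrying outcross seedlings),
#' `katy_f3_panel.tsv` (F3 segregation of six F2 recombinants) and
#' `katy_recombinants.tsv` (graphical genotypes of those recombinants).
#'
#' @param file file name; with no argument, lists the available files.
#' @return full path to the file.
#' @examples
#' ppmap_example()
#' ppmap_example("katy_s_counts.tsv")
#' @export
ppmap_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "ppmap")))
  path <- system.file("extdata", file, package = "ppmap")
  if (!nzchar(path)) stop("no bundled file called '", file, "'", call. = FALSE)
  path
}

#' Read a marker map
#'
#' Reads a tab-delimited marker map with columns `locus`, `scaffold` (or
#' `lg`), `position_mb` and optionally `position_cm` and `seg_type`.
#' Markers are sorted by (`scaffold`, `position_mb`). When both physical
#' and genetic positions are present and their orders disagree within a
#' scaffold, physical order wins and a warning lists the markers involved.
#'
#' @param path file path.
#' @return data frame of marker records sorted by physical position.
#' @export
read_marker_map <- function(path) {
  df <- read_tsv_raw(path)
  if (!is.null(df$lg) && is.null(df$scaffold)) df$scaffold <- df$lg
  need <- c("locus", "position_mb")
  if (!all(need %in% names(df)))
    stop("marker map needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) stop("empty marker map: ", path, call. = FALSE)
  df$position_mb <- normalize_decimal(df$position_mb)
  if (!is.null(df$position_cm)) df$position_cm <- normalize_decimal(df$position_cm)
  if (any(df$position_mb < 0, na.rm = TRUE) ||
      (!is.null(df$position_cm) && any(df$position_cm < 0, na.rm = TRUE)))
    stop("negative marker positions in ", path, call. = FALSE)
  if (anyDuplicated(df$locus))
    stop("duplicate marker ids: ",
         paste(unique(df$locus[duplicated(df$locus)]), collapse = ", "),
         call. = FALSE)
  sc <- if (is.null(df$scaffold)) rep(1, nrow(df)) else df$scaffold
  o <- order(sc, df$position_mb)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(df$position_cm)) {
    for (s in unique(sc)) {
      sub <- df[df$scaffold %in% s | is.null(df$scaffold), , drop = FALSE]
      sub <- sub[!is.na(sub$position_cm), , drop = FALSE]
      if (nrow(sub) > 1 && is.unsorted(sub$position_cm)) {
        i <- which(diff(sub$position_cm) < 0)
        warning("cM and Mb orders disagree (Mb order kept): ",
                paste(unique(c(sub$locus[i], sub$locus[i + 1L])), collapse = ", "),
                call. = FALSE)
      }
    }
  }
  df
}

#' Read a per-marker class-count table
#'
#' Reads a tab-delimited table with one row per marker: `locus`,
#' `seg_type`, optional `lg`/`scaffold`, `position_mb`, `position_cm`, and
#' count columns among `A`,`H`,`B`,`c`,`d`,`e`,`g`,`n`,`p` (`-` or empty
#' where a code does not apply). This is the format of the bundled
#' distortion-scan tables and the direct input of [sdl_scan()].
#'
#' @param path file path.
#' @return data frame of marker count records.
#' @export
read_marker_counts <- function(path) {
  df <- read_tsv_raw(path)
  if (!all(c("locus", "seg_type") %in% names(df)))
    stop("marker count table needs 'locus' and 'seg_type' columns", call. = FALSE)
  for (cc in intersect(c("position_mb", "position_cm"), names(df)))
    df[[cc]] <- normalize_decimal(df[[cc]])
  for (cc in intersect(LEGAL_CODES, names(df))) {
    v <- df[[cc]]
    if (is.character(v)) v[v == "-"] <- NA
    df[[cc]] <- suppressWarnings(as.integer(v))
  }
  df
}

#' Read an individual-by-marker genotype table
#'
#' Reads a tab-delimited table whose first column is `individual` and
#' remaining columns are marker calls; a marker map (or the `declarations`
#' data frame with columns `locus`, `seg_type`) supplies each marker's
#' segregation type, against which every call is validated (`A`/`H`/`B`
#' for `<abxab>`, the declared code pair for outcross types; `-` or empty
#' is missing). A parse error names the offending cell.
#'
#' @param path file path.
#' @param declarations data frame with columns `locus`, `seg_type` and
#'   optionally positions (e.g. from [read_marker_map()]).
#' @return a `"genotype_table"`: data frame of calls with the map attached
#'   as attribute `"map"`.
#' @export
read_genotype_table <- function(path, declarations) {
  df <- read_tsv_raw(path)
  if (names(df)[1L] != "individual")
    stop("genotype table must start with an 'individual' column", call. = FALSE)
  markers <- setdiff(names(df), "individual")
  if (anyDuplicated(markers))
    stop("duplicate marker columns: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  miss <- setdiff(markers, declarations$locus)
  if (length(miss) > 0)
    stop("markers without a seg_type declaration: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (mk in markers) {
    st <- declarations$seg_type[match(mk, declarations$locus)]
    parts <- split_seg_type(st)
    legal <- if (identical(parts, ABXAB)) c("A", "H", "B")
             else unlist(CODE_PAIRS[parts], use.names = FALSE)
    v <- df[[mk]]
    v[v %in% c("-", "–")] <- NA
    bad <- which(!is.na(v) & !v %in% legal)
    if (length(bad) > 0)
      stop(sprintf("illegal call '%s' for marker %s (%s) at row %d",
                   v[bad[1L]], mk, st, bad[1L]), call. = FALSE)
    df[[mk]] <- v
  }
  map <- declarations[match(markers, declarations$locus), , drop = FALSE]
  rownames(map) <- NULL
  attr(df, "map") <- map
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' Read an S-genotype count file
#'
#' Long-format tab-delimited file with columns `cross`, `class` (canonical
#' S-genotype label), `count`, and `ratio` (the expected ratio of the
#' cross as a colon-separated string, identical on every row of a cross).
#'
#' @param path file path.
#' @return data frame; use [s_counts_for()] to pull one cross out as a
#'   named count vector plus ratio.
#' @export
read_s_counts <- function(path) {
  df <- read_tsv_raw(path)
  need <- c("cross", "class", "count", "ratio")
  if (!all(need %in% names(df)))
    stop("S-genotype count file needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  df$count <- as.integer(df$count)
  df
}

#' @rdname read_s_counts
#' @param counts data frame from [read_s_counts()].
#' @param cross cross label to extract.
#' @return for `s_counts_for()`: list with `observed` (named counts, in
#'   file order) and `ratio` (integer vector).
#' @export
s_counts_for <- function(counts, cross) {
  sub <- counts[counts$cross == cross, , drop = FALSE]
  if (nrow(sub) == 0) stop("no such cross: ", cross, call. = FALSE)
  list(observed = setNames(sub$count, sub$class),
       ratio = as.integer(strsplit(sub$ratio[1L], ":", fixed = TRUE)[[1L]]))
}

#' Read an F3 panel file
#'
#' Tab-delimited with columns `f2_id`, `marker`, `f2_genotype` and F3
#' counts `A`, `H`, `B` (missing where a marker was not scored in the F3).
#'
#' @param path file path.
#' @return data frame suitable for [classify_f3_panel()].
#' @export
read_f3_panel <- function(path) {
  df <- read_tsv_raw(path)
  need <- c("f2_id", "marker", "f2_genotype", "A", "H", "B")
  if (!all(need %in% names(df)))
    stop("F3 panel needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  for (cc in c("A", "H", "B")) {
    v <- df[[cc]]
    if (is.character(v)) v[v == "-"] <- NA
    df[[cc]] <- suppressWarnings(as.integer(v))
  }
  g <- df$f2_genotype
  g[g %in% c("-", "–")] <- NA
  df$f2_genotype <- g
  df
}

#' Write a distortion-scan report
#'
#' Writes an [sdl_scan()] result as a tab-delimited table mirroring the
#' input marker table plus `statistic`, `p.value`, `distorted` and
#' `coupling_loss` columns.
#'
#' @param scan an `"sdl_scan"` object.
#' @param path output path.
#' @param header optional `#` comment line(s) written before the table.
#' @return the path, invisibly.
#' @export
write_scan_report <- function(scan, path, header = NULL) {
  stopifnot(inherits(scan, "sdl_scan"))
  df <- as.data.frame(scan)
  df$statistic <- round(df$statistic, 2)
  df$coupling_loss <- round(df$coupling_loss, 4)
  write_tsv_with_header(df, path, header)
}
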