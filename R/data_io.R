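#' Expression dataset of tag-count libraries
#'
#' Container for enumeration-based expression data (SAGE, MPSS, RNA-seq tag
#' counts): an integer matrix of per-gene counts, one column per sequenced
#' library, plus the total number of sequenced tags per library. Totals may
#' exceed the column sums when tags were filtered upstream; they can never be
#' smaller.
#'
#' @param counts integer matrix, genes in rows (rownames = gene/tag ids),
#'   libraries in columns (colnames = library ids). Missing genes are zeros.
#' @param totals optional named numeric vector of total sequenced tags per
#'   library; defaults to the column sums.
#' @return an object of class \code{"mdeq_data"}: a list with elements
#'   \code{counts} (integer matrix) and \code{totals} (named numeric).
#' @examples
#' m <- matrix(c(3, 7, 5, 5), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("L1", "L2")))
#' d <- mdeq_data(m)
#' d$totals
#' @export
mdeq_data <- function(counts, totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and library colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in count matrix", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate library ids in count matrix", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "double"
  csum <- colSums(counts)
  if (is.null(totals)) {
    totals <- csum
  } else {
    totals <- unlist(totals)
    if (is.null(names(totals))) names(totals) <- colnames(counts)
    totals <- totals[colnames(counts)]
    if (anyNA(totals))
      stop("totals must cover every library", call. = FALSE)
    bad <- which(totals < csum)
    if (length(bad))
      stop("library ", colnames(counts)[bad[1]],
           ": total tags (", totals[bad[1]],
           ") smaller than the column sum (", csum[bad[1]], ")",
           call. = FALSE)
  }
  structure(list(counts = counts, totals = totals), class = "mdeq_data")
}

#' @export
print.mdeq_data <- function(x, ...) {
  cat("Tag-count expression dataset\n")
  cat("  genes:    ", nrow(x$counts), "\n", sep = "")
  cat("  libraries:", ncol(x$counts), "(",
      paste(utils::head(colnames(x$counts), 5), collapse = ", "),
      if (ncol(x$counts) > 5) ", ..." else "", ")\n")
  cat("  total tags per library:",
      paste(format(x$totals, trim = TRUE), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mdeq_data <- function(x) dim(x$counts)

#' Library ids and gene universe of a dataset
#' @param x an \code{mdeq_data} object.
#' @return character vector of ids.
#' @export
libraries <- function(x) colnames(x$counts)

#' @rdname libraries
#' @export
gene_universe <- function(x) rownames(x$counts)

# opens plain or gzip text transparently
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a tab-separated count table
#'
#' The table has a header row of library ids, a first column of gene or tag
#' ids, and integer counts in the cells. Lines starting with \code{#} are
#' ignored. Per-library totals are either the column sums
#' (\code{totals_mode = "column_sum"}) or taken from a row whose id is
#' \code{TOTAL} (\code{totals_mode = "explicit_row"}), which accommodates
#' libraries whose total sequenced tag count exceeds the sum of the retained
#' tags. Gzip-compressed files (\code{.gz}) are accepted transparently.
#'
#' @param path path to a TSV (optionally \code{.gz}).
#' @param totals_mode \code{"column_sum"} (default) or \code{"explicit_row"}.
#' @return an \code{\link{mdeq_data}} object, row order preserved.
#' @export
read_count_table <- function(path, totals_mode = c("column_sum",
                                                   "explicit_row")) {
  totals_mode <- match.arg(totals_mode)
  con <- open_text(path)
  on.exit(close(con))
  tab <- utils::read.delim(con, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("count table needs an id column and at least one library",
                          call. = FALSE)
  ids <- tab[[1]]
  cells <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = dimnames(cells)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad))) {
    r <- bad[1, 1]; c <- bad[1, 2]
    stop("count table ", path, ": cell at row '", ids[r], "', column '",
         colnames(cells)[c], "' is not a non-negative integer (value '",
         cells[r, c], "')", call. = FALSE)
  }
  totals <- NULL
  if (totals_mode == "explicit_row") {
    hit <- which(ids == "TOTAL")
    if (length(hit) != 1)
      stop("totals_mode='explicit_row' requires exactly one row with id 'TOTAL'",
           call. = FALSE)
    totals <- num[hit, ]
    num <- num[-hit, , drop = FALSE]
    ids <- ids[-hit]
  } else if ("TOTAL" %in% ids) {
    stop("row id 'TOTAL' is reserved; use totals_mode='explicit_row'",
         call. = FALSE)
  }
  if (anyDuplicated(ids))
    stop("duplicate gene id '", ids[duplicated(ids)][1], "' in ", path,
         call. = FALSE)
  rownames(num) <- ids
  mdeq_data(num, totals = totals)
}

#' Write a count table as TSV
#'
#' Inverse of \code{\link{read_count_table}}: the written file reads back to
#' an identical dataset. When the totals differ from the column sums a
#' \code{TOTAL} row is emitted (read it back with
#' \code{totals_mode = "explicit_row"}).
#'
#' @param x an \code{mdeq_data} object.
#' @param path output path.
#' @param totals_row force (or suppress) the explicit \code{TOTAL} row;
#'   default writes it only when needed.
#' @return the path, invisibly.
#' @export
write_count_table <- function(x, path,
                              totals_row = !all(x$totals == colSums(x$counts))) {
  m <- x$counts
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (totals_row)
    df <- rbind(data.frame(id = "TOTAL", t(x$totals), check.names = FALSE),
                df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read gene-set annotation (GMT or two/three-column TSV)
#'
#' GMT follows the Broad convention: one term per line,
#' \code{term<TAB>description<TAB>gene1<TAB>gene2...}. The TSV form has one
#' gene-term pair per row, \code{gene<TAB>term[<TAB>weight]}, no header; the
#' optional third column is a membership weight in [0, 1] for probabilistic
#' annotations (default 1, i.e. crisp membership).
#'
#' @param path annotation file (\code{.gmt} or TSV; \code{.gz} accepted).
#' @param format \code{"auto"} (by extension), \code{"gmt"} or \code{"tsv"}.
#' @return an object of class \code{"mdeq_annotation"}: a named list
#'   \code{sets} (term -> named numeric weight vector over member genes) and
#'   \code{desc} (term descriptions, GMT only).
#' @export
read_annotation <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt(\\.gz)?$", path)) "gmt" else "tsv"
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  sets <- list(); desc <- character()
  if (format == "gmt") {
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3 || !nzchar(f[1])) {
        warning("skipping malformed/empty GMT line: ",
                substr(ln, 1, 40), call. = FALSE)
        next
      }
      genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
      w <- rep(1, length(genes)); names(w) <- genes
      sets[[f[1]]] <- w
      desc[f[1]] <- f[2]
    }
  } else {
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 2 || !nzchar(f[2]) || !nzchar(f[1])) {
        warning("skipping malformed annotation row: ",
                substr(ln, 1, 40), call. = FALSE)
        next
      }
      w <- if (length(f) >= 3) suppressWarnings(as.numeric(f[3])) else 1
      if (is.na(w) || w < 0 || w > 1)
        stop("annotation weight for gene '", f[1], "', term '", f[2],
             "' must be in [0, 1], got '", f[3], "'", call. = FALSE)
      if (!is.null(sets[[f[2]]]) && f[1] %in% names(sets[[f[2]]])) {
        warning("duplicate (term, gene) pair (", f[2], ", ", f[1],
                "); keeping the first", call. = FALSE)
        next
      }
      sets[[f[2]]][f[1]] <- w
    }
  }
  annotation_set(sets, desc)
}

#' Build an annotation set programmatically
#'
#' @param sets named list: term id -> named numeric vector of membership
#'   weights in [0, 1] (names are gene ids). Bare character vectors of gene
#'   ids are accepted and given weight 1.
#' @param desc optional named character vector of term descriptions.
#' @return an \code{"mdeq_annotation"} object.
#' @export
annotation_set <- function(sets, desc = character()) {
  sets <- lapply(sets, function(w) {
    if (is.character(w)) { g <- w; w <- rep(1, length(g)); names(w) <- g }
    if (is.null(names(w)) || !all(nzchar(names(w))))
      stop("annotation weights must be named by gene id", call. = FALSE)
    if (any(w < 0 | w > 1))
      stop("annotation weights must be in [0, 1]", call. = FALSE)
    w
  })
  structure(list(sets = sets, desc = desc), class = "mdeq_annotation")
}

#' @export
print.mdeq_annotation <- function(x, ...) {
  cat("Annotation set:", length(x$sets), "terms,",
      length(unique(unlist(lapply(x$sets, names)))), "distinct genes\n")
  invisible(x)
}

#' @export
length.mdeq_annotation <- function(x) length(x$sets)

#' Read a two-column tag-to-gene map
#'
#' @param path TSV with columns tag, gene; no header; \code{#} comments and
#'   \code{.gz} accepted.
#' @return named character vector: tag -> gene.
#' @export
read_tag_map <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (is.null(f) || ncol(f) < 2)
    stop("tag map must have two tab-separated columns: tag, gene",
         call. = FALSE)
  stats::setNames(f[, 2], f[, 1])
}

#' Collapse tags to genes
#'
#' Counts of tags mapping to the same gene are summed per library (tag
#' sampling is additive). Tags absent from the map keep their tag id; map
#' entries for tags absent from the data are ignored.
#'
#' @param x an \code{mdeq_data} object keyed by tag ids.
#' @param tag_map named character vector tag -> gene
#'   (see \code{\link{read_tag_map}}).
#' @return an \code{mdeq_data} object keyed by gene ids, totals unchanged.
#'   The number of unmapped tags is attached as attribute
#'   \code{"n_unmapped"}.
#' @export
apply_tag_map <- function(x, tag_map) {
  ids <- rownames(x$counts)
  mapped <- tag_map[ids]
  unmapped <- is.na(mapped)
  if (any(unmapped))
    message(sum(unmapped), " tag(s) not in the map kept under their tag id")
  new_ids <- ifelse(unmapped, ids, mapped)
  collapsed <- rowsum(x$counts, group = new_ids, reorder = FALSE)
  out <- mdeq_data(collapsed, totals = x$totals)
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}
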