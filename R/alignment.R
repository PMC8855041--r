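#' Locus alignment container
#'
#' A `locus_aln` is a taxa-by-sites character matrix over the alphabet
#' `{A, C, G, T, -, N}` with a locus identifier and a locus-class tag.
#' Ambiguity codes other than `N` are collapsed to `N`; `N` and `-` are both
#' treated as missing by every downstream statistic.
#'
#' @param x Character matrix (rows = taxa, columns = sites) or a list of
#'   equal-length character vectors named by taxon.
#' @param locus_id Locus identifier (single string).
#' @param class_tag Locus class, one of `"CDS"`, `"INT"`, `"PL"`.
#' @return An object of class `locus_aln`.
#' @export
locus_aln <- function(x, locus_id = "locus", class_tag = c("CDS", "INT", "PL")) {
  class_tag <- match.arg(class_tag)
  if (is.list(x)) {
    len <- lengths(x)
    if (length(unique(len)) > 1L)
      stop("malformed alignment '", locus_id, "': unequal sequence lengths")
    x <- do.call(rbind, x)
  }
  if (!is.matrix(x) || !is.character(x))
    stop("alignment must be a character matrix")
  if (ncol(x) < 1L) stop("alignment '", locus_id, "' has zero length")
  if (is.null(rownames(x))) stop("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(x)))
    stop("duplicate taxon labels in locus '", locus_id, "'")
  x[] <- toupper(x)
  bad <- !(x %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad)) x[bad] <- "N"
  structure(x, class = c("locus_aln", "matrix"),
            locus_id = locus_id, class_tag = class_tag)
}

#' @export
print.locus_aln <- function(x, ...) {
  cat(sprintf("<locus_aln> %s [%s]: %d taxa x %d sites, %.1f%% missing\n",
              attr(x, "locus_id"), attr(x, "class_tag"),
              nrow(x), ncol(x), 100 * missing_fraction(x)))
  invisible(x)
}

#' @export
`[.locus_aln` <- function(x, i, j, ...) {
  if (nargs() < 3L) return(unclass(x)[i])  # single-index: plain vector
  y <- unclass(x)[i, j, drop = FALSE]
  structure(y, class = c("locus_aln", "matrix"),
            locus_id = attr(x, "locus_id"), class_tag = attr(x, "class_tag"))
}

#' Fraction of missing cells (gap or N) in an alignment
#' @param aln A `locus_aln` or character matrix.
#' @return Fraction in `[0, 1]`.
#' @export
missing_fraction <- function(aln) {
  mean(aln == "-" | aln == "N")
}

is_called <- function(x) x == "A" | x == "C" | x == "G" | x == "T"

#' Read aligned FASTA files as locus alignments
#'
#' Each file must contain equal-length aligned sequences. Characters are
#' uppercased and ambiguity codes other than `N` are mapped to `N`.
#'
#' @param paths Character vector of FASTA file paths.
#' @param class_tag Locus class assigned to every file read.
#' @param locus_ids Optional locus identifiers; default is the file base name
#'   without extension.
#' @return A list of [locus_aln] objects.
#' @export
read_alignments <- function(paths, class_tag = c("CDS", "INT", "PL"),
                            locus_ids = NULL) {
  class_tag <- match.arg(class_tag)
  if (is.null(locus_ids))
    locus_ids <- sub("\\.[^.]*$", "", basename(paths))
  out <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    recs <- read_fasta_chars(paths[k])
    if (anyDuplicated(names(recs)))
      stop("duplicate taxon labels in ", paths[k])
    out[[k]] <- locus_aln(recs, locus_id = locus_ids[k], class_tag = class_tag)
  }
  names(out) <- locus_ids
  out
}

read_fasta_chars <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  idx <- cumsum(hdr)
  labels <- sub("^>\\s*", "", lines[hdr])
  labels <- sub("\\s.*$", "", labels)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(z) paste(z, collapse = ""), character(1))
  recs <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  names(recs) <- labels
  recs
}

#' Write a locus alignment to FASTA
#' @param aln A [locus_aln].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln)))
    writeLines(c(paste0(">", rownames(aln)[i]),
                 paste(aln[i, ], collapse = "")), con)
  invisible(path)
}

#' Concatenate loci into a supermatrix
#'
#' Taxa absent from a locus are padded with gaps. The partition map (locus
#' boundaries) is attached as attribute `"partitions"`.
#'
#' @param loci List of [locus_aln] objects.
#' @param taxa Optional taxon set; default is the union over loci.
#' @return A `locus_aln` supermatrix with a `partitions` attribute
#'   (data frame: locus_id, class, start, end).
#' @export
concat_supermatrix <- function(loci, taxa = NULL) {
  stopifnot(length(loci) >= 1L)
  if (is.null(taxa))
    taxa <- Reduce(union, lapply(loci, rownames))
  lens <- vapply(loci, ncol, integer(1))
  if (length(unique(vapply(loci, function(l) attr(l, "class_tag"), character(1)))) == 1L)
    tag <- attr(loci[[1]], "class_tag") else tag <- "CDS"
  mat <- matrix("-", nrow = length(taxa), ncol = sum(lens),
                dimnames = list(taxa, NULL))
  end <- cumsum(lens)
  start <- c(1L, head(end, -1L) + 1L)
  for (k in seq_along(loci)) {
    l <- loci[[k]]
    mat[rownames(l), start[k]:end[k]] <- unclass(l)
  }
  out <- locus_aln(mat, locus_id = "supermatrix", class_tag = tag)
  attr(out, "partitions") <- data.frame(
    locus_id = vapply(loci, function(l) attr(l, "locus_id"), character(1)),
    class = vapply(loci, function(l) attr(l, "class_tag"), character(1)),
    start = start, end = end, row.names = NULL)
  out
}
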