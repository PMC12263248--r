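# Provenance header written at the top of every pipeline output file:
# "# hetchron <version>" plus one "# key = value" line per parameter.
provenance_header <- function(params = list()) {
  ver <- as.character(utils::packageVersion("hetchron"))
  c(sprintf("# hetchron %s", ver),
    vapply(names(params), function(k)
      sprintf("# %s = %s", k, paste(format(params[[k]]), collapse = ",")),
      character(1)))
}

write_lines_tsv <- function(lines, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance_header(provenance), con)
  writeLines(lines, con)
  invisible(path)
}

#' Write / read an expression matrix as TSV
#'
#' Gene ids in the first column (header `gene`), one column per sample;
#' missing values written as `NA`.  Lines starting with `#` (provenance
#' headers) are skipped on read.  Reading validates the file: ragged rows
#' and negative values raise errors naming the offending line, duplicate
#' gene ids raise an error naming the id.
#'
#' @param mat Genes x samples numeric matrix.
#' @param path File path.
#' @param provenance Optional named list recorded as `#` header lines.
#' @return `write_expression_tsv`: the path, invisibly.
#'   `read_expression_tsv`: the matrix.
#' @export
write_expression_tsv <- function(mat, path, provenance = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  header <- paste(c("gene", colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i],
            ifelse(is.na(mat[i, ]), "NA", format(mat[i, ], digits = 10,
                                                 trim = TRUE,
                                                 scientific = FALSE))),
          collapse = "\t"), character(1))
  write_lines_tsv(c(header, body), path, provenance)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  raw <- readLines(path)
  keep <- !startsWith(raw, "#")
  lineno <- which(keep)
  raw <- raw[keep]
  if (length(raw) < 1L) stop("empty expression file: ", path)
  parts <- strsplit(raw, "\t", fixed = TRUE)
  ncols <- length(parts[[1]])
  bad <- which(lengths(parts) != ncols)
  if (length(bad))
    stop("ragged row in ", path, " at line ", lineno[bad[1]],
         ": expected ", ncols, " fields, found ", lengths(parts)[bad[1]])
  samples <- parts[[1]][-1]
  genes <- vapply(parts[-1], `[[`, character(1), 1L)
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene id in ", path, ": ", dup[1])
  vals <- suppressWarnings(
    t(vapply(parts[-1], function(p) as.numeric(p[-1]),
             numeric(length(samples)))))
  if (length(samples) == 1L) vals <- matrix(vals, ncol = 1L)
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative value in ", path, " at line ", lineno[neg[1, 1] + 1L])
  dimnames(vals) <- list(genes, samples)
  vals
}

stage_aliases <- c(no = "egg", yolking = "egg", egg = "egg", early = "early",
                   middle = "middle", mid = "middle", late = "late")

#' Read sample metadata
#'
#' TSV with columns `sample`, `species`, `stage`, `batch`.  Stage labels
#' are normalized to the fixed vocabulary `egg`, `early`, `middle`, `late`
#' (the alias `no`, used for yolking eggs with no developing embryo, maps
#' to `egg`).
#'
#' @param path File path.
#' @return Data frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample", "species", "stage")
  if (!all(need %in% names(md)))
    stop("metadata must contain columns ", paste(need, collapse = ", "))
  st <- stage_aliases[tolower(md$stage)]
  if (anyNA(st))
    stop("unknown stage label(s): ",
         paste(unique(md$stage[is.na(st)]), collapse = ", "))
  md$stage <- unname(st)
  if (anyDuplicated(md$sample)) stop("duplicate sample ids in metadata")
  md
}

#' Write sample metadata
#' @param metadata Data frame with `sample`, `species`, `stage`, `batch`.
#' @inheritParams write_expression_tsv
#' @export
write_sample_metadata <- function(metadata, path, provenance = NULL) {
  lines <- c(paste(names(metadata), collapse = "\t"),
             apply(metadata, 1L, paste, collapse = "\t"))
  write_lines_tsv(lines, path, provenance)
}

#' Read a 12-column BLAST tabular hit file
#'
#' Standard `outfmt 6` dialect: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path File path.
#' @return Hit table data frame.
#' @export
read_blast_tab <- function(path) {
  h <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(h) != 12L)
    stop("expected 12 BLAST tabular columns in ", path, ", found ", ncol(h))
  names(h) <- blast_columns
  check_hits(h)
}

#' @rdname read_blast_tab
#' @param hits Hit table to write.
#' @inheritParams write_expression_tsv
#' @export
write_blast_tab <- function(hits, path, provenance = NULL) {
  check_hits(hits)
  lines <- apply(hits[, blast_columns], 1L, function(r)
    paste(trimws(r), collapse = "\t"))
  write_lines_tsv(lines, path, provenance)
}

#' Read gene coordinates
#'
#' Two dialects: `"bed"` (chrom, start, end, gene; 0-based half-open) and
#' `"tsv1"` (gene, chrom, start, end; 1-based inclusive, converted to
#' 0-based half-open on read).  Coordinates are handled 0-based half-open
#' internally throughout the package.
#'
#' @param path File path.
#' @param dialect `"bed"` or `"tsv1"`.
#' @return Data frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_coords <- function(path, dialect = c("bed", "tsv1")) {
  dialect <- match.arg(dialect)
  x <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 4L) stop("coordinate file needs 4 columns: ", path)
  if (dialect == "bed") {
    out <- data.frame(gene = x[[4]], chrom = x[[1]], start = x[[2]],
                      end = x[[3]])
  } else {
    out <- data.frame(gene = x[[1]], chrom = x[[2]], start = x[[3]] - 1L,
                      end = x[[4]])
  }
  check_coords(out)
}

#' @rdname read_coords
#' @param coords Coordinate table (0-based half-open) to write as BED.
#' @inheritParams write_expression_tsv
#' @export
write_coords_bed <- function(coords, path, provenance = NULL) {
  check_coords(coords)
  lines <- sprintf("%s\t%d\t%d\t%s", coords$chrom, as.integer(coords$start),
                   as.integer(coords$end), coords$gene)
  write_lines_tsv(lines, path, provenance)
}

#' Read / write Newick trees
#'
#' Thin validated wrappers around ape: unbalanced parentheses raise an
#' error with the offending character position; `#` comment lines
#' (provenance) are skipped; numeric internal-node labels are preserved as
#' support values.  Writing uses 10 significant digits for branch lengths,
#' so a parse-write round trip preserves topology, lengths and labels.
#'
#' @param path File path.
#' @return `read_newick`: a `phylo` tree. `write_newick`: the path,
#'   invisibly.
#' @export
read_newick <- function(path) {
  txt <- readLines(path)
  txt <- paste(txt[!startsWith(txt, "#")], collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("unbalanced parenthesis in Newick at position ", i)
  }
  if (depth != 0L)
    stop("unbalanced parentheses in Newick: ", depth, " unclosed '('")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  tr
}

#' @rdname read_newick
#' @param tree A `phylo` tree.
#' @inheritParams write_expression_tsv
#' @export
write_newick <- function(tree, path, provenance = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  write_lines_tsv(txt, path, provenance)
}

#' Write / read a binary character matrix as relaxed PHYLIP
#'
#' Header line `ntaxa nsites`, then one line per taxon: label, whitespace,
#' and the character string over `0`, `1` and `-` (missing).
#'
#' @param chars Taxa x characters 0/1/NA matrix.
#' @param path File path.
#' @inheritParams write_expression_tsv
#' @export
write_phylip_binary <- function(chars, path, provenance = NULL) {
  check_char_matrix(chars)
  rows <- vapply(seq_len(nrow(chars)), function(i) {
    s <- chars[i, ]
    s <- ifelse(is.na(s), "-", as.character(s))
    paste0(rownames(chars)[i], "  ", paste(s, collapse = ""))
  }, character(1))
  write_lines_tsv(c(paste(nrow(chars), ncol(chars)), rows), path, provenance)
}

#' @rdname write_phylip_binary
#' @export
read_phylip_binary <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(trimws(raw))]
  hd <- as.integer(strsplit(trimws(raw[1]), "\\s+")[[1]])
  if (length(hd) != 2L || anyNA(hd)) stop("bad PHYLIP header in ", path)
  rows <- strsplit(trimws(raw[-1]), "\\s+")
  taxa <- vapply(rows, `[[`, character(1), 1L)
  mat <- t(vapply(rows, function(r) {
    s <- strsplit(r[[2]], "")[[1]]
    match(s, c("0", "1")) - 1L   # "-" (missing) maps to NA
  }, integer(hd[2])))
  if (length(taxa) != hd[1]) stop("PHYLIP header/body mismatch in ", path)
  rownames(mat) <- taxa
  mat
}

#' Write a generic data frame as TSV with provenance header
#' @param df Data frame.
#' @inheritParams write_expression_tsv
#' @export
write_table_tsv <- function(df, path, provenance = NULL) {
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) apply(df, 1L, function(r)
               paste(trimws(format(r)), collapse = "\t")))
  write_lines_tsv(lines, path, provenance)
}
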