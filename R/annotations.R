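# Gene Ontology annotations: GAF parsing, the feature vocabulary, and
# binary gene x GO-term feature matrices.

GO_ID_RE <- "^GO:[0-9]{7}$"
GAF_ASPECT <- c(F = "MF", P = "BP", C = "CC")

new_gene_annotation <- function(gene, term, aspect) {
  stopifnot(length(gene) == length(term), length(term) == length(aspect))
  bad <- !grepl(GO_ID_RE, term)
  if (any(bad)) stop("malformed GO id: ", term[which(bad)[1]], call. = FALSE)
  stopifnot(all(aspect %in% c("MF", "BP", "CC")))
  tab <- unique(data.frame(gene = as.character(gene), term = as.character(term),
                           aspect = as.character(aspect), stringsAsFactors = FALSE))
  tab <- tab[order(tab$gene, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab), class = "gene_annotation")
}

#' Read gene-to-GO annotations
#'
#' Supports GAF 2.x (column 2 = DB object id, 4 = qualifier, 5 = GO id,
#' 9 = aspect F/P/C; lines starting with `!` are comments; associations
#' with a `NOT` qualifier are dropped) and a simple 3-column TSV dialect
#' (gene, GO id, aspect as MF/BP/CC or F/P/C; `#` comments).
#'
#' @param path Path to the annotation file.
#' @param format `"gaf"` or `"simple_tsv"`.
#' @return A `gene_annotation` holding a long table of
#'   (gene, term, aspect) rows, deduplicated and sorted.
#' @export
read_annotations <- function(path, format = c("gaf", "simple_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  genes <- character(0); terms <- character(0); aspects <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (format == "gaf" && startsWith(ln, "!")) next
    if (format == "simple_tsv" && startsWith(trimws(ln), "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (format == "gaf") {
      if (length(f) < 9L) stop("malformed GAF line ", i, ": fewer than 9 columns", call. = FALSE)
      qualifier <- f[[4]]
      if (grepl("(^|\\|)NOT($|\\|)", qualifier)) next
      term <- f[[5]]
      if (!grepl(GO_ID_RE, term)) stop("malformed GO id at line ", i, ": ", term, call. = FALSE)
      asp <- GAF_ASPECT[f[[9]]]
      if (is.na(asp)) stop("malformed GAF aspect at line ", i, ": ", f[[9]], call. = FALSE)
      genes <- c(genes, f[[2]]); terms <- c(terms, term); aspects <- c(aspects, asp)
    } else {
      if (length(f) < 3L) stop("malformed line ", i, ": expected 3 columns", call. = FALSE)
      term <- f[[2]]
      if (!grepl(GO_ID_RE, term)) stop("malformed GO id at line ", i, ": ", term, call. = FALSE)
      asp <- if (f[[3]] %in% names(GAF_ASPECT)) GAF_ASPECT[[f[[3]]]] else f[[3]]
      if (!asp %in% c("MF", "BP", "CC")) stop("malformed aspect at line ", i, ": ", f[[3]], call. = FALSE)
      genes <- c(genes, f[[1]]); terms <- c(terms, term); aspects <- c(aspects, asp)
    }
  }
  new_gene_annotation(genes, terms, aspects)
}

#' Write annotations back to disk
#'
#' The GAF writer emits minimal but valid 17-column association lines
#' (evidence code IEA, taxon 9606); the simple writer emits the
#' 3-column dialect [read_annotations()] accepts.
#'
#' @param annotations A `gene_annotation`.
#' @param path Output path.
#' @param format Output dialect.
#' @export
write_annotations <- function(annotations, path, format = c("simple_tsv", "gaf")) {
  format <- match.arg(format)
  tab <- annotations$table
  if (format == "simple_tsv") {
    writeLines(c("# gene\tgo_term\taspect",
                 paste(tab$gene, tab$term, tab$aspect, sep = "\t")), path)
  } else {
    letter <- names(GAF_ASPECT)[match(tab$aspect, GAF_ASPECT)]
    lines <- paste("DB", tab$gene, tab$gene, "", tab$term, "REF:0000000", "IEA", "",
                   letter, "", "", "protein", "taxon:9606", "20190101", "DB", "", "",
                   sep = "\t")
    writeLines(c("!gaf-version: 2.1", lines), path)
  }
  invisible(path)
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("Gene annotation set: ", length(unique(x$table$gene)), " genes, ",
      length(unique(x$table$term)), " GO terms, ",
      nrow(x$table), " associations\n", sep = "")
  invisible(x)
}

# Per-gene term list, optionally restricted to aspects / a gene subset.
gene_terms <- function(annotations, genes = NULL, aspects = c("MF", "BP", "CC")) {
  tab <- annotations$table
  tab <- tab[tab$aspect %in% aspects, , drop = FALSE]
  if (!is.null(genes)) tab <- tab[tab$gene %in% genes, , drop = FALSE]
  lapply(split(tab$term, factor(tab$gene, levels = sort(unique(tab$gene)))), unique)
}

#' Genes passing the well-studied rule
#'
#' At least one non-root MF term or one non-root BP term; see
#' [filter_well_studied()].
#'
#' @param annotations A `gene_annotation`.
#' @return Sorted character vector of gene ids.
#' @export
well_studied_genes <- function(annotations) {
  tab <- annotations$table
  ok <- (tab$aspect == "MF" & tab$term != GO_ROOT_MF) |
        (tab$aspect == "BP" & tab$term != GO_ROOT_BP)
  sort(unique(tab$gene[ok]))
}

#' Build the GO feature vocabulary
#'
#' The vocabulary is the lexicographically sorted union of the GO terms
#' annotated to the given genes (within the included aspects), with the
#' three uninformative namespace roots removed. Terms are used exactly
#' as annotated -- no ancestor propagation over the GO DAG -- so
#' columns carry no built-in inter-term correlation. The vocabulary
#' carries a content hash that trained models store, so a
#' train/predict feature mismatch is detected instead of silently
#' producing garbage.
#'
#' @param annotations A `gene_annotation`.
#' @param genes Genes whose terms define the vocabulary.
#' @param aspects GO namespaces to include; default all three.
#' @param exclude_iea Drop nothing by default; reserved for dialects
#'   carrying evidence codes (the simple dialect does not), kept for
#'   interface stability.
#' @return A `go_vocabulary`: list with sorted `terms` and `hash`.
#' @export
build_vocabulary <- function(annotations, genes,
                             aspects = c("MF", "BP", "CC"),
                             exclude_iea = FALSE) {
  stopifnot(inherits(annotations, "gene_annotation"), length(genes) > 0)
  tab <- annotations$table
  tab <- tab[tab$gene %in% genes & tab$aspect %in% aspects, , drop = FALSE]
  terms <- sort(setdiff(unique(tab$term), GO_ROOTS))
  if (length(terms) == 0L) stop("empty vocabulary: no non-root GO terms for the given genes",
                                call. = FALSE)
  structure(list(terms = terms, hash = content_hash(terms)),
            class = "go_vocabulary")
}

#' @export
print.go_vocabulary <- function(x, ...) {
  cat("GO feature vocabulary: ", length(x$terms), " terms, hash ", x$hash, "\n", sep = "")
  invisible(x)
}

#' Encode genes as binary GO-term vectors
#'
#' Row g, column t of the result is 1 exactly when term t is annotated
#' to gene g and belongs to the vocabulary; annotated terms outside the
#' vocabulary are ignored. Genes entirely absent from the annotation
#' set are an error; a gene whose terms all fall outside the vocabulary
#' yields an all-zero row with a warning (such genes should have been
#' removed by the well-studied filter).
#'
#' @param annotations A `gene_annotation`.
#' @param vocabulary A `go_vocabulary`.
#' @param genes Ordered gene ids to encode (rows, in this order).
#' @return A `go_features`: list with sparse binary `x`
#'   (`Matrix::dgCMatrix`, dimnames gene x term) and the `vocabulary`.
#' @export
vectorize_genes <- function(annotations, vocabulary, genes) {
  stopifnot(inherits(annotations, "gene_annotation"),
            inherits(vocabulary, "go_vocabulary"),
            length(genes) > 0, !anyDuplicated(genes))
  genes <- as.character(genes)
  tab <- annotations$table
  missing <- setdiff(genes, unique(tab$gene))
  if (length(missing) > 0) {
    stop("gene(s) absent from annotations: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[tab$gene %in% genes & tab$term %in% vocabulary$terms, , drop = FALSE]
  i <- match(tab$gene, genes)
  j <- match(tab$term, vocabulary$terms)
  x <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(genes), length(vocabulary$terms)),
                            dimnames = list(genes, vocabulary$terms))
  x@x[] <- 1  # collapse any duplicate (gene, term) rows to presence
  zero <- Matrix::rowSums(x) == 0
  if (any(zero)) {
    warning("all-zero feature row(s): ", paste(utils::head(genes[zero], 5), collapse = ", "))
  }
  structure(list(x = x, vocabulary = vocabulary), class = "go_features")
}

#' @export
print.go_features <- function(x, ...) {
  cat("Binary GO feature matrix: ", nrow(x$x), " genes x ", ncol(x$x), " terms (",
      format(Matrix::nnzero(x$x)), " nonzero)\n", sep = "")
  invisible(x)
}

# Row subset preserving class and vocabulary.
features_subset <- function(features, genes) {
  stopifnot(inherits(features, "go_features"), all(genes %in% rownames(features$x)))
  structure(list(x = features$x[genes, , drop = FALSE], vocabulary = features$vocabulary),
            class = "go_features")
}
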