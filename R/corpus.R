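# Drug-target interaction corpus: ingestion, the well-studied-gene
# filter, and construction of the class space (drug labels plus the
# "others" and "non-target" sentinel classes).

GO_ROOT_MF <- "GO:0003674"
GO_ROOT_BP <- "GO:0008150"
GO_ROOT_CC <- "GO:0005575"
GO_ROOTS <- c(GO_ROOT_MF, GO_ROOT_BP, GO_ROOT_CC)

OTHERS_LABEL <- "others"
NONTARGET_LABEL <- "non-target"

new_dti_corpus <- function(drug, gene) {
  stopifnot(length(drug) == length(gene))
  keep <- !duplicated(paste(drug, gene, sep = "\x1f"))
  drug <- drug[keep]
  gene <- gene[keep]
  d2g <- lapply(split(gene, factor(drug, levels = sort(unique(drug)))), function(g) sort(unique(g)))
  g2d <- lapply(split(drug, factor(gene, levels = sort(unique(gene)))), function(d) sort(unique(d)))
  structure(list(drug_to_genes = d2g, gene_to_drugs = g2d),
            class = "dti_corpus")
}

#' Read a drug-target interaction edge list
#'
#' Parses a STITCH-style chemical-protein links file (3 columns:
#' chemical, protein, combined_score; a header line is tolerated) or a
#' simple 2-3 column tab-separated dialect in which lines starting with
#' `#` are comments. Duplicate edges are collapsed; the result stores
#' the bipartite graph as a pair of exactly inverse maps.
#'
#' @param path Path to the TSV file.
#' @param format `"stitch_tsv"` or `"simple_tsv"`.
#' @param min_score Optional integer in \[0, 1000\]. When given, only
#'   edges whose confidence score is `>= min_score` are kept; edges
#'   without a score are dropped. When absent (the default) no score
#'   filtering happens and scoreless edges are kept.
#' @return A `dti_corpus`: list with `drug_to_genes` and
#'   `gene_to_drugs`, each a named list of sorted identifier vectors.
#' @seealso [write_interactions()], [build_label_space()]
#' @export
read_interactions <- function(path, format = c("stitch_tsv", "simple_tsv"),
                              min_score = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("interaction file not found: ", path, call. = FALSE)
  if (!is.null(min_score)) {
    stopifnot(is_count(min_score), min_score <= 1000)
  }
  lines <- readLines(path, warn = FALSE)
  drugs <- character(0); genes <- character(0); scores <- numeric(0)
  first_data <- TRUE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (format == "simple_tsv" && startsWith(trimws(ln), "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (format == "stitch_tsv") {
      if (length(f) < 3L) stop("malformed STITCH line ", i, ": expected 3 columns", call. = FALSE)
      sc <- suppressWarnings(as.numeric(f[[3]]))
      if (is.na(sc)) {
        # header line ("chemical  protein  combined_score") tolerated once
        if (first_data) { first_data <- FALSE; next }
        stop("malformed STITCH line ", i, ": non-numeric score", call. = FALSE)
      }
      drugs <- c(drugs, f[[1]]); genes <- c(genes, f[[2]]); scores <- c(scores, sc)
    } else {
      if (length(f) < 2L || !nzchar(f[[1]]) || !nzchar(f[[2]])) {
        stop("malformed line ", i, ": expected 2-3 tab-separated columns", call. = FALSE)
      }
      sc <- if (length(f) >= 3L && nzchar(f[[3]])) suppressWarnings(as.numeric(f[[3]])) else NA_real_
      if (length(f) >= 3L && nzchar(f[[3]]) && is.na(sc)) {
        stop("malformed line ", i, ": non-numeric score", call. = FALSE)
      }
      drugs <- c(drugs, f[[1]]); genes <- c(genes, f[[2]]); scores <- c(scores, sc)
    }
    first_data <- FALSE
  }
  if (!is.null(min_score)) {
    keep <- !is.na(scores) & scores >= min_score
    drugs <- drugs[keep]; genes <- genes[keep]
  }
  if (length(drugs) == 0L) warning("no interactions read from ", path)
  new_dti_corpus(drugs, genes)
}

#' Write a corpus back to disk
#'
#' `simple_tsv` writes two columns (drug, gene); `stitch_tsv` writes the
#' 3-column STITCH dialect with a header and a constant placeholder
#' score of 1000 (the corpus does not retain scores).
#'
#' @param corpus A `dti_corpus`.
#' @param path Output path.
#' @param format Output dialect.
#' @export
write_interactions <- function(corpus, path, format = c("simple_tsv", "stitch_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(corpus, "dti_corpus"))
  d <- rep(names(corpus$drug_to_genes), lengths(corpus$drug_to_genes))
  g <- unlist(corpus$drug_to_genes, use.names = FALSE)
  if (format == "simple_tsv") {
    writeLines(c("# drug\tgene", paste(d, g, sep = "\t")), path)
  } else {
    writeLines(c("chemical\tprotein\tcombined_score",
                 paste(d, g, 1000L, sep = "\t")), path)
  }
  invisible(path)
}

#' @export
print.dti_corpus <- function(x, ...) {
  cat("Drug-target interaction corpus\n")
  cat("  drugs: ", length(x$drug_to_genes),
      "  genes: ", length(x$gene_to_drugs),
      "  interactions: ", n_interactions(x), "\n", sep = "")
  invisible(x)
}

#' Number of unique drug-gene interactions in a corpus
#' @param corpus A `dti_corpus`.
#' @export
n_interactions <- function(corpus) sum(lengths(corpus$drug_to_genes))

#' @rdname n_interactions
#' @export
corpus_genes <- function(corpus) names(corpus$gene_to_drugs)

#' @rdname n_interactions
#' @export
corpus_drugs <- function(corpus) names(corpus$drug_to_genes)

#' Test whether an interaction is present
#' @param corpus A `dti_corpus`.
#' @param drug,gene Identifiers.
#' @export
has_interaction <- function(corpus, drug, gene) {
  g <- corpus$drug_to_genes[[drug]]
  !is.null(g) && gene %in% g
}

#' Restrict a corpus to well-studied genes
#'
#' A gene is well-studied when it carries at least one molecular-function
#' annotation other than the MF root `GO:0003674` or at least one
#' biological-process annotation other than the BP root `GO:0008150`.
#' Genes annotated only with cellular-component terms, only with root
#' terms, or absent from the annotation set are removed together with
#' every interaction touching them. This is what keeps feature vectors
#' from being all-zero downstream.
#'
#' @param corpus A `dti_corpus`.
#' @param annotations A `gene_annotation` from [read_annotations()].
#' @return The filtered `dti_corpus`.
#' @export
filter_well_studied <- function(corpus, annotations) {
  stopifnot(inherits(corpus, "dti_corpus"), inherits(annotations, "gene_annotation"))
  keep_genes <- well_studied_genes(annotations)
  d <- rep(names(corpus$drug_to_genes), lengths(corpus$drug_to_genes))
  g <- unlist(corpus$drug_to_genes, use.names = FALSE)
  sel <- g %in% keep_genes
  new_dti_corpus(d[sel], g[sel])
}

#' Build the class space from a corpus
#'
#' Drugs targeting strictly more than `min_targets` well-studied genes
#' become class labels, numbered 1..N-2 in descending order of target
#' count (ties broken lexicographically by drug id). Two sentinel
#' classes follow: `"others"` (index N-1), a seeded uniform sample of
#' `others_size` genes targeted only by the non-selected drugs, and
#' `"non-target"` (index N), a seeded uniform sample of
#' `nontarget_size` genes from `gene_universe` that belong to no other
#' class. Both sentinel gene sets are disjoint from every drug class by
#' construction.
#'
#' @param corpus A `dti_corpus` (already filtered to well-studied genes).
#' @param min_targets Selection cutoff; a drug qualifies when it targets
#'   more than this many genes. Default 400.
#' @param others_size,nontarget_size Sizes of the sentinel gene sets
#'   (defaults 504 and 128). Either may be 0, yielding an empty class.
#' @param gene_universe Character vector of candidate genes for the
#'   non-target class; must contain every corpus gene.
#' @param seed Integer seed driving the two sentinel samples.
#' @return A `label_space`: list with `labels`, `gene_sets` (one sorted
#'   character vector per class index), `others_index`,
#'   `nontarget_index`, and `N`.
#' @export
build_label_space <- function(corpus, min_targets = 400L,
                              others_size = 504L, nontarget_size = 128L,
                              gene_universe = corpus_genes(corpus),
                              seed = 1L) {
  stopifnot(inherits(corpus, "dti_corpus"),
            is_count(min_targets), is_count(others_size), is_count(nontarget_size))
  gene_universe <- sort(unique(as.character(gene_universe)))
  cg <- corpus_genes(corpus)
  if (!all(cg %in% gene_universe)) {
    stop("gene_universe must contain every corpus gene", call. = FALSE)
  }
  sizes <- lengths(corpus$drug_to_genes)
  selected <- names(sizes)[sizes > min_targets]
  # descending size, ties lexicographic by drug id
  selected <- selected[order(-sizes[selected], selected)]
  drug_sets <- corpus$drug_to_genes[selected]
  drug_genes <- sort(unique(unlist(drug_sets, use.names = FALSE)))

  unselected <- setdiff(names(sizes), selected)
  others_pool <- sort(setdiff(unique(unlist(corpus$drug_to_genes[unselected], use.names = FALSE)),
                              drug_genes))
  if (others_size > length(others_pool)) {
    stop("others_size (", others_size, ") exceeds available pool of ",
         length(others_pool), " genes", call. = FALSE)
  }
  nontarget_pool0 <- setdiff(gene_universe, c(drug_genes, others_pool))

  sets <- with_seed(seed, {
    others <- if (others_size > 0) sort(sample(others_pool, others_size)) else character(0)
    pool <- sort(setdiff(c(nontarget_pool0, setdiff(others_pool, others)), others))
    # non-target pool: universe minus all class genes and minus the drawn "others"
    if (nontarget_size > length(pool)) {
      stop("nontarget_size (", nontarget_size, ") exceeds available pool of ",
           length(pool), " genes", call. = FALSE)
    }
    nontarget <- if (nontarget_size > 0) sort(sample(pool, nontarget_size)) else character(0)
    list(others = others, nontarget = nontarget)
  })

  labels <- c(selected, OTHERS_LABEL, NONTARGET_LABEL)
  gene_sets <- c(unname(drug_sets), list(sets$others), list(sets$nontarget))
  names(gene_sets) <- labels
  structure(list(labels = labels,
                 gene_sets = gene_sets,
                 others_index = length(labels) - 1L,
                 nontarget_index = length(labels),
                 N = length(labels)),
            class = "label_space")
}

#' @export
print.label_space <- function(x, ...) {
  nd <- x$N - 2L
  cat("Label space: ", x$N, " classes (", nd, " drugs + \"others\" + \"non-target\")\n", sep = "")
  sz <- lengths(x$gene_sets)
  cat("  drug class sizes: ", if (nd > 0) paste(range(sz[seq_len(nd)]), collapse = "-") else "none",
      "   others: ", sz[[x$others_index]],
      "   non-target: ", sz[[x$nontarget_index]], "\n", sep = "")
  invisible(x)
}

#' Label-space accessors
#'
#' `label_space_genes` returns every gene carried by any class
#' (sorted); `label_space_labelsets` the map gene -> integer vector of
#' class indices carrying it.
#'
#' @param label_space A `label_space`.
#' @export
label_space_genes <- function(label_space) {
  sort(unique(unlist(label_space$gene_sets, use.names = FALSE)))
}

#' @rdname label_space_genes
#' @export
label_space_labelsets <- function(label_space) {
  idx <- rep(seq_along(label_space$gene_sets), lengths(label_space$gene_sets))
  g <- unlist(label_space$gene_sets, use.names = FALSE)
  lapply(split(idx, factor(g, levels = sort(unique(g)))), function(v) sort(unique(v)))
}

label_space_to_list <- function(ls) {
  list(labels = ls$labels, gene_sets = lapply(ls$gene_sets, as.character),
       others_index = ls$others_index, nontarget_index = ls$nontarget_index, N = ls$N)
}

label_space_from_list <- function(x) {
  gs <- lapply(x$gene_sets, as.character)
  names(gs) <- x$labels
  structure(list(labels = as.character(x$labels), gene_sets = gs,
                 others_index = as.integer(x$others_index),
                 nontarget_index = as.integer(x$nontarget_index),
                 N = as.integer(x$N)),
            class = "label_space")
}
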