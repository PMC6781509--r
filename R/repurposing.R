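# Post-prediction interpretation: novel drug-gene associations and
# drug -> disease-phenotype links through a gene-phenotype map.

#' Extract known and novel drug-gene associations
#'
#' Runs the ensemble over every gene in the feature matrix and keeps
#' each (drug, gene) prediction with probability strictly above
#' `min_probability`. Predictions of the "others" and "non-target"
#' sentinel classes are suppressed. A prediction already present in
#' the training corpus is `known`; anything else is `novel` -- the
#' candidate repurposing signal, since absent edges are not
#' necessarily errors when the interaction catalog is incomplete.
#'
#' @param model A fitted `brdti`.
#' @param features A `go_features` for the genes to scan (hash
#'   checked).
#' @param corpus The training `dti_corpus` used to tell known from
#'   novel.
#' @param min_probability Probability cutoff (strict; default 0.5,
#'   equivalent to decision value > 0). Raising it keeps only the
#'   most confident candidates.
#' @return A data frame (`gene_id`, `drug_label`, `probability`,
#'   `status`) sorted by gene then descending probability, with the
#'   model's drug labels in attribute `"drugs"`.
#' @export
extract_novel <- function(model, features, corpus, min_probability = 0.5) {
  stopifnot(inherits(model, "brdti"), inherits(corpus, "dti_corpus"),
            is.numeric(min_probability), min_probability >= 0.5, min_probability < 1)
  prob <- predict(model, features, type = "prob")
  sentinels <- c(model$label_space$others_index, model$label_space$nontarget_index)
  sentinels <- sentinels[!is.na(sentinels)]
  drug_idx <- setdiff(seq_len(model$label_space$N), sentinels)
  out <- data.frame(gene_id = character(0), drug_label = character(0),
                    probability = numeric(0), status = character(0),
                    stringsAsFactors = FALSE)
  rows <- list()
  for (r in seq_len(nrow(prob))) {
    g <- rownames(prob)[r]
    p <- prob[r, drug_idx]
    sel <- which(!is.na(p) & p > min_probability)
    if (length(sel) == 0L) next
    idx <- drug_idx[sel]
    drugs <- model$label_space$labels[idx]
    known <- vapply(drugs, function(d) has_interaction(corpus, d, g), logical(1))
    ord <- order(-p[sel], drugs)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, drug_label = drugs[ord], probability = unname(p[sel][ord]),
      status = ifelse(known[ord], "known", "novel"), stringsAsFactors = FALSE)
  }
  if (length(rows) > 0) out <- do.call(rbind, rows)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drugs") <- model$label_space$labels[drug_idx]
  class(out) <- c("novel_associations", "data.frame")
  out
}

#' @export
print.novel_associations <- function(x, ...) {
  cat("Drug-gene associations: ", nrow(x), " predictions (",
      sum(x$status == "novel"), " novel, ", sum(x$status == "known"), " known) over ",
      length(unique(x$gene_id)), " genes\n", sep = "")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  invisible(x)
}

#' Novel target genes for one drug
#'
#' @param associations Output of [extract_novel()].
#' @param drug_label A drug class label known to the model.
#' @return Data frame (`gene_id`, `probability`) of the drug's
#'   novel-status associations, descending probability.
#' @export
repurposed_genes <- function(associations, drug_label) {
  drugs <- attr(associations, "drugs")
  if (!is.null(drugs) && !drug_label %in% drugs) {
    stop("unknown drug label: ", drug_label, call. = FALSE)
  }
  sel <- associations$drug_label == drug_label & associations$status == "novel"
  out <- associations[sel, c("gene_id", "probability"), drop = FALSE]
  out <- out[order(-out$probability, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  as.data.frame(out)
}

#' Link drugs to disease phenotypes through predicted novel targets
#'
#' Joins the novel-status associations with a gene-to-phenotype map:
#' for every (drug, phenotype) with at least one supporting gene, the
#' supporting genes are the drug's predicted novel targets that carry
#' the phenotype. Support mode is `"all"` when those cover every
#' carrier of the phenotype within the association list's gene
#' universe, else `"any"`. (The full external gene list of a phenotype
#' may exceed the analyzed gene set; coverage is judged relative to
#' the genes actually scanned.)
#'
#' @param associations Output of [extract_novel()].
#' @param gene_phenotypes Named list gene -> character phenotype ids,
#'   or a two-column data frame (`gene_id`, `phenotype_id`).
#' @return Data frame (`drug_label`, `phenotype_id`, `support_mode`,
#'   `n_supporting_genes`, `supporting_genes` semicolon-joined),
#'   sorted by drug then phenotype.
#' @export
drug_phenotype_links <- function(associations, gene_phenotypes) {
  if (is.data.frame(gene_phenotypes)) {
    gene_phenotypes <- lapply(split(gene_phenotypes[[2]], gene_phenotypes[[1]]),
                              function(v) sort(unique(as.character(v))))
  }
  universe <- unique(associations$gene_id)
  carriers <- list()  # phenotype -> genes in universe carrying it
  for (g in universe) {
    for (ph in gene_phenotypes[[g]] %||% character(0)) {
      carriers[[ph]] <- c(carriers[[ph]], g)
    }
  }
  novel <- associations[associations$status == "novel", , drop = FALSE]
  rows <- list()
  for (d in sort(unique(novel$drug_label))) {
    dg <- novel$gene_id[novel$drug_label == d]
    phs <- sort(unique(unlist(lapply(dg, function(g) gene_phenotypes[[g]] %||% character(0)))))
    for (ph in phs) {
      supp <- sort(intersect(dg, carriers[[ph]]))
      if (length(supp) == 0L) next
      mode <- if (all(carriers[[ph]] %in% supp)) "all" else "any"
      rows[[length(rows) + 1L]] <- data.frame(
        drug_label = d, phenotype_id = ph, support_mode = mode,
        n_supporting_genes = length(supp),
        supporting_genes = paste(supp, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(drug_label = character(0), phenotype_id = character(0),
               support_mode = character(0), n_supporting_genes = integer(0),
               supporting_genes = character(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$drug_label, out$phenotype_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a gene-to-phenotype map
#'
#' Two tab-separated columns (gene id, phenotype id, e.g. OMIM:600521);
#' `#` comments allowed.
#'
#' @param path File path.
#' @return `read_gene_phenotypes`: named list gene -> sorted phenotype
#'   ids.
#' @export
read_gene_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  genes <- character(0); phs <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("malformed line ", i, ": expected 2 columns", call. = FALSE)
    genes <- c(genes, f[[1]]); phs <- c(phs, f[[2]])
  }
  lapply(split(phs, factor(genes, levels = sort(unique(genes)))),
         function(v) sort(unique(v)))
}

#' @rdname read_gene_phenotypes
#' @param map Named list gene -> phenotype ids.
#' @export
write_gene_phenotypes <- function(map, path) {
  g <- rep(names(map), lengths(map))
  p <- unlist(map, use.names = FALSE)
  writeLines(c("# gene\tphenotype", if (length(g)) paste(g, p, sep = "\t")), path)
  invisible(path)
}

#' Write associations / phenotype links as TSV
#' @param x A data frame from [extract_novel()] or
#'   [drug_phenotype_links()].
#' @param path Output path.
#' @export
write_associations <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
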