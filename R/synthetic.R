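# Synthetic corpora with planted multi-label structure.
#
# Each simulated drug owns a disjoint (optionally overlapping) block of
# GO terms -- its signature. A gene draws a label set of drugs, then
# carries each signature term of each of its drugs with probability
# p_signal and each background term with probability p_noise, plus one
# guaranteed MF/BP anchor term so every gene passes the well-studied
# filter by construction. Because the ground truth (signatures and
# label sets) is known, the whole pipeline's recovery behaviour is
# quantifiable without any external database.

#' Specification of a synthetic drug-target study
#'
#' Defaults are the package's canonical recovery study: 10 drugs, 500
#' genes with 1-3 labels each, disjoint 8-term signatures inside a
#' 200-term vocabulary, strong signal (p_signal = 0.9) over weak
#' background noise (p_noise = 0.05).
#'
#' @param n_drugs,n_genes Numbers of simulated drugs and labeled genes.
#' @param vocab_size GO vocabulary size (signatures must fit:
#'   the signature blocks need
#'   `(n_drugs - 1) * (signature_size - overlap) + signature_size`
#'   terms).
#' @param signature_size Terms per drug signature.
#' @param p_signal Probability a gene carries each signature term of
#'   each of its drugs.
#' @param p_noise Probability a gene carries each background term.
#'   Must satisfy `0 <= p_noise < p_signal <= 1`.
#' @param labels_per_gene Integer range `c(lo, hi)`; each gene draws a
#'   label-set size uniformly from it.
#' @param n_background_genes Genes with no drug labels (noise-only
#'   profiles), the pool for a "non-target" class.
#' @param signature_overlap Fraction of each signature shared with the
#'   previous drug's (0 = disjoint, the default; > 0 makes classes
#'   confusable on purpose).
#' @param seed Integer seed; generation is fully deterministic given
#'   the spec.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_drugs = 10L, n_genes = 500L, vocab_size = 200L,
                       signature_size = 8L, p_signal = 0.9, p_noise = 0.05,
                       labels_per_gene = c(1L, 3L), n_background_genes = 0L,
                       signature_overlap = 0, seed = 1L) {
  stopifnot(is_count(n_drugs, 1L), is_count(n_genes, 1L), is_count(vocab_size, 1L),
            is_count(signature_size, 1L), is_count(n_background_genes),
            is.numeric(p_signal), is.numeric(p_noise),
            p_noise >= 0, p_noise < p_signal, p_signal <= 1,
            signature_overlap >= 0, signature_overlap < 1)
  labels_per_gene <- as.integer(labels_per_gene)
  if (length(labels_per_gene) == 1L) labels_per_gene <- rep(labels_per_gene, 2L)
  stopifnot(length(labels_per_gene) == 2L, labels_per_gene[1] >= 1L,
            labels_per_gene[2] >= labels_per_gene[1], labels_per_gene[2] <= n_drugs)
  o <- floor(signature_overlap * signature_size)
  span <- (n_drugs - 1L) * (signature_size - o) + signature_size
  if (span > vocab_size) {
    stop("infeasible spec: signatures need ", span, " terms but vocab_size is ",
         vocab_size, call. = FALSE)
  }
  structure(list(n_drugs = as.integer(n_drugs), n_genes = as.integer(n_genes),
                 vocab_size = as.integer(vocab_size),
                 signature_size = as.integer(signature_size),
                 p_signal = p_signal, p_noise = p_noise,
                 labels_per_gene = labels_per_gene,
                 n_background_genes = as.integer(n_background_genes),
                 signature_overlap = signature_overlap, seed = as.integer(seed)),
            class = "synth_spec")
}

# Synthetic GO ids avoid the three namespace roots.
synth_go_terms <- function(n) {
  ids <- seq_len(n + 3L)
  ids <- setdiff(ids, c(3674L, 8150L, 5575L))[seq_len(n)]
  sprintf("GO:%07d", ids)
}

#' Generate a synthetic drug-target corpus
#'
#' @param spec A [synth_spec()].
#' @return List with `corpus` (a `dti_corpus`), `annotations` (a
#'   `gene_annotation`), and `truth` (list with `drug_signatures`,
#'   `gene_labelsets`, `terms`, `aspects`).
#' @examples
#' sim <- synth_corpus(synth_spec(n_drugs = 4, n_genes = 80, vocab_size = 60,
#'                                signature_size = 5, seed = 42))
#' sim$corpus
#' @export
synth_corpus <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  terms <- synth_go_terms(spec$vocab_size)
  aspects <- rep_len(c("MF", "BP", "CC"), spec$vocab_size)
  names(aspects) <- terms
  o <- floor(spec$signature_overlap * spec$signature_size)
  stride <- spec$signature_size - o
  drugs <- sprintf("CIDm%08d", seq_len(spec$n_drugs))
  signatures <- lapply(seq_len(spec$n_drugs), function(i) {
    terms[((i - 1L) * stride + 1L):((i - 1L) * stride + spec$signature_size)]
  })
  names(signatures) <- drugs
  sig_span <- (spec$n_drugs - 1L) * stride + spec$signature_size
  background <- terms[seq.int(sig_span + 1L, length.out = spec$vocab_size - sig_span)]
  # anchor fallbacks guaranteeing a non-root MF/BP term per gene
  mfbp <- function(ts) ts[aspects[ts] %in% c("MF", "BP")]
  bg_anchor <- if (length(mfbp(background)) > 0) mfbp(background)[[1]] else NA_character_

  ngene_total <- spec$n_genes + spec$n_background_genes
  genes <- sprintf("G%05d", seq_len(ngene_total))

  with_seed(spec$seed, {
    labelsets <- vector("list", ngene_total)
    names(labelsets) <- genes
    ann_gene <- character(0); ann_term <- character(0)
    for (gi in seq_len(ngene_total)) {
      g <- genes[[gi]]
      if (gi <= spec$n_genes) {
        nl <- sample(seq.int(spec$labels_per_gene[1], spec$labels_per_gene[2]), 1L)
        dset <- sort(sample(drugs, nl))
      } else {
        dset <- character(0)
      }
      labelsets[[gi]] <- dset
      sig_terms <- unique(unlist(signatures[dset], use.names = FALSE))
      carried <- character(0)
      if (length(sig_terms) > 0) {
        carried <- sig_terms[stats::runif(length(sig_terms)) < spec$p_signal]
      }
      if (length(background) > 0) {
        carried <- c(carried, background[stats::runif(length(background)) < spec$p_noise])
      }
      if (length(mfbp(carried)) == 0L) {
        anchor <- if (length(dset) > 0 && length(mfbp(signatures[[dset[[1]]]])) > 0) {
          mfbp(signatures[[dset[[1]]]])[[1]]
        } else bg_anchor
        if (is.na(anchor)) stop("cannot anchor gene ", g, ": no MF/BP term available",
                                call. = FALSE)
        carried <- c(carried, anchor)
      }
      carried <- sort(unique(carried))
      ann_gene <- c(ann_gene, rep(g, length(carried)))
      ann_term <- c(ann_term, carried)
    }
    edges_d <- unlist(labelsets, use.names = FALSE)
    edges_g <- rep(genes, lengths(labelsets))
    list(
      corpus = new_dti_corpus(edges_d, edges_g),
      annotations = new_gene_annotation(ann_gene, ann_term, unname(aspects[ann_term])),
      truth = list(drug_signatures = signatures, gene_labelsets = labelsets,
                   terms = terms, aspects = aspects, background = background)
    )
  })
}

#' Generate a synthetic gene-to-phenotype map
#'
#' Seeded random bipartite map: each of `n_phenotypes` phenotypes is
#' assigned `genes_per_phenotype` genes sampled uniformly from the
#' truth's gene universe.
#'
#' @param truth The `truth` element of [synth_corpus()] output (or any
#'   list with a `gene_labelsets` named list).
#' @param n_phenotypes Number of phenotypes (`0` gives an empty map).
#' @param genes_per_phenotype Disease genes per phenotype.
#' @param seed Integer seed.
#' @return Named list gene -> sorted phenotype ids (genes with no
#'   phenotype absent).
#' @export
synth_phenotypes <- function(truth, n_phenotypes = 20L, genes_per_phenotype = 5L,
                             seed = 1L) {
  stopifnot(is_count(n_phenotypes), is_count(genes_per_phenotype, 1L))
  genes <- names(truth$gene_labelsets)
  if (genes_per_phenotype > length(genes)) {
    stop("genes_per_phenotype exceeds the number of genes", call. = FALSE)
  }
  if (n_phenotypes == 0L) return(structure(list(), names = character(0)))
  with_seed(seed, {
    g2p <- list()
    for (ph in sprintf("OMIM:%06d", 600000L + seq_len(n_phenotypes))) {
      for (g in sample(genes, genes_per_phenotype)) {
        g2p[[g]] <- c(g2p[[g]], ph)
      }
    }
    g2p <- lapply(g2p, function(v) sort(unique(v)))
    g2p[order(names(g2p))]
  })
}

#' Write a synthetic study to disk in the ingestion dialects
#'
#' Writes `interactions.tsv` (STITCH dialect), `annotations.gaf`,
#' `phenotypes.tsv`, and `truth.json` into `dir`, i.e. exactly the
#' formats [read_interactions()], [read_annotations()] and
#' [read_gene_phenotypes()] accept, so generation round-trips through
#' the ingestion path.
#'
#' @param sim Output of [synth_corpus()].
#' @param dir Output directory (created if missing).
#' @param phenotypes Optional map from [synth_phenotypes()].
#' @return `dir`, invisibly.
#' @export
write_synth <- function(sim, dir, phenotypes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interactions(sim$corpus, file.path(dir, "interactions.tsv"), format = "stitch_tsv")
  write_annotations(sim$annotations, file.path(dir, "annotations.gaf"), format = "gaf")
  if (!is.null(phenotypes)) {
    write_gene_phenotypes(phenotypes, file.path(dir, "phenotypes.tsv"))
  }
  jsonlite::write_json(list(drug_signatures = sim$truth$drug_signatures,
                            gene_labelsets = sim$truth$gene_labelsets),
                       file.path(dir, "truth.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
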