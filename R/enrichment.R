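#' Build an annotation map from gene-term pairs
#'
#' @param pairs Two-column data frame or TSV path (`gene`, `term`), one
#'   annotation per row.
#' @param universe Optional character vector of genes defining the testable
#'   universe (default: all annotated genes). Annotations for genes outside
#'   the universe are dropped.
#' @return A list of class `annotation_map`: `gene2term`, `term2gene`
#'   (named lists of character vectors), `universe`.
#' @export
annotation_map <- function(pairs, universe = NULL) {
  if (is.character(pairs) && length(pairs) == 1) {
    pairs <- readr::read_tsv(pairs, show_col_types = FALSE,
                             col_names = c("gene", "term"),
                             col_types = "cc")
  }
  pairs <- tibble::as_tibble(pairs)
  names(pairs)[1:2] <- c("gene", "term")
  if (is.null(universe)) universe <- sort(unique(pairs$gene))
  pairs <- pairs[pairs$gene %in% universe, ]
  pairs <- unique(pairs[c("gene", "term")])
  structure(
    list(gene2term = split(pairs$term, pairs$gene),
         term2gene = split(pairs$gene, pairs$term),
         universe = sort(unique(universe))),
    class = "annotation_map"
  )
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` annotated genes in a sample of `n` from a universe of `N`
#' genes of which `K` carry the annotation. Computed via the log-scale
#' cumulative distribution for numerical stability.
#'
#' @param N Universe size.
#' @param K Number of annotated genes in the universe.
#' @param n Sample (gene list) size.
#' @param k Observed number of annotated genes in the sample.
#' @return The tail probability in (0, 1].
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (k < 0 || K > N || n > N || k > min(K, n)) {
    abort("invalid hypergeometric parameters: need 0 <= k <= min(K, n), K <= N, n <= N")
  }
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric term enrichment of a gene list
#'
#' Tests every term annotating at least one gene of the list for
#' over-representation relative to the universe, reporting the relative
#' (in-list) and background (in-universe) annotation frequencies, the
#' hypergeometric tail p-value, and Bonferroni-adjusted p-values over the
#' terms tested. Only direct annotations are used; no ontology-graph
#' propagation is performed (pre-propagate the map if ancestor terms are
#' wanted).
#'
#' @param genes Character vector of genes of interest; genes outside the
#'   universe are dropped with a message.
#' @param annotation An `annotation_map`.
#' @param alpha Significance level on the adjusted p-value (default 0.01).
#' @return Tibble sorted by p-value: `term`, `k` (list hits), `n` (list
#'   size), `K` (universe hits), `N` (universe size),
#'   `relative_frequency`, `background_frequency`, `p_value`,
#'   `adjusted_p`, `significant`.
#' @export
enrich <- function(genes, annotation, alpha = 0.01) {
  genes <- unique(genes)
  if (length(genes) == 0) abort("empty gene list")
  N <- length(annotation$universe)
  if (N == 0) abort("empty universe")
  outside <- setdiff(genes, annotation$universe)
  if (length(outside) > 0) {
    inform(sprintf("dropping %d gene(s) outside the universe",
                   length(outside)))
    genes <- setdiff(genes, outside)
  }
  if (length(genes) == 0) abort("no genes left after universe filtering")
  n <- length(genes)
  terms <- sort(unique(unlist(annotation$gene2term[genes], use.names = FALSE)))
  if (length(terms) == 0) {
    return(tibble::tibble(term = character(), k = integer(), n = integer(),
                          K = integer(), N = integer(),
                          relative_frequency = numeric(),
                          background_frequency = numeric(),
                          p_value = numeric(), adjusted_p = numeric(),
                          significant = logical()))
  }
  rows <- lapply(terms, function(tm) {
    members <- annotation$term2gene[[tm]]
    K <- length(members)
    k <- length(intersect(members, genes))
    tibble::tibble(term = tm, k = k, n = n, K = K, N = N,
                   relative_frequency = k / n,
                   background_frequency = K / N,
                   p_value = hypergeom_tail(N, K, n, k))
  })
  out <- dplyr::bind_rows(rows)
  out$adjusted_p <- pmin(out$p_value * nrow(out), 1)
  out$significant <- out$adjusted_p < alpha
  dplyr::arrange(out, .data$p_value, .data$term)
}
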