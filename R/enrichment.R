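#' Read gene sets in GMT format
#'
#' Thin wrapper over [fgsea::gmtPathways()] returning a named list
#' term -> member genes.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Restrict and filter a gene-set collection
#'
#' Intersects every term with the analysis universe and applies the standard
#' over-representation hygiene filter on term size.
#'
#' @param pathways Named list term -> genes.
#' @param universe Character vector: the gene universe (e.g., all genes
#'   surviving preprocessing).
#' @param min_size,max_size Term size bounds after restriction (defaults 10
#'   and 2000).
#' @return Filtered named list.
#' @export
restrict_gene_sets <- function(pathways, universe, min_size = 10L,
                               max_size = 2000L) {
  out <- lapply(pathways, function(g) unique(intersect(g, universe)))
  out[lengths(out) >= min_size & lengths(out) <= max_size]
}

#' Hypergeometric over-representation of a gene list
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least the actual overlap between the query list and the term's members,
#' drawing `|query|` genes without replacement from the universe.
#' Benjamini-Hochberg adjusted values are reported alongside the raw P
#' values.
#'
#' @param query Character vector of genes (e.g., a module's hub genes).
#'   Genes outside the universe are dropped with a warning.
#' @param collection Named list term -> member genes (use
#'   [restrict_gene_sets()] for universe restriction and size filtering).
#' @param universe Character vector defining the sampling frame.
#' @return Data frame (class `enrichment_table`) with `term`, `overlap`,
#'   `term_size`, `query_size`, `universe_size`, `p_value`, `q_value`,
#'   sorted by ascending P (ties by term), one row per term.
#' @export
hypergeometric_enrichment <- function(query, collection, universe) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warnf("dropping %d query gene(s) outside the universe", length(outside))
    query <- setdiff(query, outside)
  }
  if (!length(query)) stopf("query is empty after universe restriction")
  if (!length(collection)) stopf("empty gene-set collection")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(term) {
    members <- intersect(collection[[term]], universe)
    m <- length(members)
    k <- length(intersect(query, members))
    data.frame(term = term, overlap = k, term_size = m, query_size = n,
               universe_size = N,
               p_value = stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Fraction of hub genes with prior coexpression evidence
#'
#' Given externally curated evidence of gene-gene coexpression (unordered
#' pairs, e.g. mined from public expression compendia), computes for each
#' module's hub set the fraction of hub genes having at least one evidence
#' partner *within the same hub set* — an external-validity check for the
#' network modules.
#'
#' @param hub_sets Named list: module -> character vector of hub genes.
#' @param evidence_pairs Two-column character matrix or data frame of
#'   unordered gene pairs.
#' @return A list with `per_module` (named fractions) and `overall` (fraction
#'   over all hub genes, modules pooled).
#' @export
prior_coexpression_fraction <- function(hub_sets, evidence_pairs) {
  ep <- as.matrix(evidence_pairs)
  if (ncol(ep) != 2L) stopf("evidence_pairs must have two columns")
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  keys <- if (nrow(ep)) pair_key(as.character(ep[, 1L]), as.character(ep[, 2L]))
          else character(0)
  per_module <- vapply(names(hub_sets), function(m) {
    hubs <- unique(hub_sets[[m]])
    if (!length(hubs)) {
      warnf("module %s has an empty hub set; skipped", m)
      return(NA_real_)
    }
    if (length(hubs) == 1L) return(0)
    combs <- utils::combn(sort(hubs), 2L)
    hit <- pair_key(combs[1L, ], combs[2L, ]) %in% keys
    supported <- unique(c(combs[1L, hit], combs[2L, hit]))
    length(supported) / length(hubs)
  }, numeric(1))
  all_hubs <- unlist(hub_sets, use.names = FALSE)
  weights <- lengths(hub_sets)
  ok <- !is.na(per_module)
  overall <- if (any(ok)) sum(per_module[ok] * weights[ok]) / sum(weights[ok]) else NA_real_
  list(per_module = per_module, overall = overall)
}
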