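#' Functional similarity between two genes
#'
#' Jaccard index of the genes' annotation-term sets.
#'
#' @param g1,g2 gene ids.
#' @param annotation named list mapping gene id to a character vector of
#'   term ids.
#' @return similarity in \[0, 1\].
#' @export
genePairSimilarity <- function(g1, g2, annotation) {
  t1 <- annotation[[g1]]; t2 <- annotation[[g2]]
  if (is.null(t1) || is.null(t2) || !length(t1) || !length(t2))
    stop("unannotated gene: ", if (is.null(t1) || !length(t1)) g1 else g2)
  length(intersect(t1, t2)) / length(union(t1, t2))
}

#' Gene-set functional similarity (symmetric best-match average)
#'
#' Mean over genes in A of their maximum pairwise similarity to B,
#' averaged with the B-to-A direction. Unannotated genes are excluded
#' (with a message). When A and B are the same set with more than one
#' gene, self-pairings are excluded from the best match; a singleton
#' compared to itself scores 1.
#'
#' @param groupA,groupB character vectors of gene ids.
#' @param annotation as in [genePairSimilarity()].
#' @return raw similarity in \[0, 1\].
#' @export
setSimilarity <- function(groupA, groupB, annotation) {
  keep <- function(g) g[vapply(g, function(x)
    !is.null(annotation[[x]]) && length(annotation[[x]]) > 0, logical(1))]
  a <- keep(unique(groupA)); b <- keep(unique(groupB))
  dropped <- (length(unique(groupA)) - length(a)) +
             (length(unique(groupB)) - length(b))
  if (dropped > 0) message(dropped, " unannotated gene(s) excluded")
  if (!length(a) || !length(b)) stop("empty annotated group")
  same <- setequal(a, b)
  if (same && length(a) == 1L) return(1)
  bestMatch <- function(from, to) {
    mean(vapply(from, function(g) {
      others <- if (same) setdiff(to, g) else to
      max(vapply(others, function(h)
        genePairSimilarity(g, h, annotation), numeric(1)))
    }, numeric(1)))
  }
  (bestMatch(a, b) + bestMatch(b, a)) / 2
}

#' Intra-class normalized gene-set similarity
#'
#' `2 * S(A,B) / (S(A,A) + S(B,B))`, expressing the cross-group score
#' relative to the groups' internal coherence; equals 1 when A = B.
#'
#' @inheritParams setSimilarity
#' @return normalized similarity (can exceed 1 when the cross score
#'   beats the intra scores).
#' @export
normalizedSimilarity <- function(groupA, groupB, annotation) {
  saa <- setSimilarity(groupA, groupA, annotation)
  sbb <- setSimilarity(groupB, groupB, annotation)
  if (saa + sbb == 0)
    stop("undefined normalization: both intra-class scores are zero")
  2 * setSimilarity(groupA, groupB, annotation) / (saa + sbb)
}

#' Annotation-term over-representation
#'
#' One-sided Fisher's exact test per term on the 2x2 membership table
#' (in gene set x annotated with term) over a stated universe, followed
#' by Benjamini-Hochberg adjustment across terms. Terms annotating no
#' universe gene are skipped.
#'
#' @param geneSet character vector, subset of `universe`.
#' @param universe character vector of all eligible genes.
#' @param annotation named list, gene id -> term ids.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return [S4Vectors::DataFrame] per term: counts, `oddsRatio`, `p`,
#'   `q`, `significant`.
#' @export
termEnrichment <- function(geneSet, universe, annotation, alpha = 0.05) {
  if (!length(geneSet)) stop("empty gene set")
  if (!all(geneSet %in% universe)) stop("geneSet must be a subset of universe")
  terms <- sort(unique(unlist(annotation[universe], use.names = FALSE)))
  if (!length(terms)) stop("no term annotates any universe gene")
  inSet <- universe %in% geneSet
  res <- lapply(terms, function(tm) {
    hasTerm <- vapply(universe, function(g) tm %in% annotation[[g]], logical(1))
    if (!any(hasTerm)) return(NULL)
    tab <- matrix(c(sum(inSet & hasTerm), sum(inSet & !hasTerm),
                    sum(!inSet & hasTerm), sum(!inSet & !hasTerm)),
                  nrow = 2, byrow = TRUE)
    f <- fisher2x2(tab, alternative = "greater")
    DataFrame(term = tm, setWithTerm = tab[1, 1], setSize = sum(inSet),
              universeWithTerm = sum(hasTerm), universeSize = length(universe),
              oddsRatio = f$oddsRatio, p = f$pValue)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  out$q <- adjustBH(out$p)
  out$significant <- out$q < alpha
  out[order(out$p), ]
}
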