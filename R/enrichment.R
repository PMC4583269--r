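#' Upper-tail hypergeometric probability
#'
#' Exact probability of observing `k` or more category members among `n`
#' genes drawn without replacement from a universe of `N` genes containing
#' `K` category members: `P(X >= k)`. Thin validated surface over the
#' stable distribution-function machinery in \pkg{stats}.
#'
#' @param N Universe size.
#' @param K Category (success) count in the universe.
#' @param n Number of draws (e.g. significant genes).
#' @param k Observed overlap; must satisfy `0 <= k <= min(K, n)`.
#' @return `P(X >= k)`; exactly 1 when `k = 0`.
#' @examples
#' hypergeomUpperTail(10, 4, 5, 3)   # 66/252
#' @export
hypergeomUpperTail <- function(N, K, n, k) {
  bad <- function(x) !is.numeric(x) || length(x) != 1L || is.na(x) ||
    x != round(x)
  if (bad(N) || bad(K) || bad(n) || bad(k)) {
    stop("N, K, n, k must be single integers", call. = FALSE)
  }
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(K, n)) {
    stop("require 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n)",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric category enrichment of a significant gene set
#'
#' Tests every category of an [AnnotationSet-class] for over-representation
#' among the significant genes, via [hypergeomUpperTail()] with the
#' annotation's universe as background. Raw p-values are reported and
#' flagged at `p <= alpha` by default; Bonferroni or Benjamini-Hochberg
#' adjustment can be requested explicitly (never applied silently). An
#' optional redundancy filter drops a category whose member overlap
#' (Jaccard index) with a more significant category exceeds a threshold.
#'
#' @param significant Character vector of significant genes. Genes outside
#'   the annotation universe are dropped with a warning. An empty set gives
#'   an empty table, not an error.
#' @param annotation An [AnnotationSet-class].
#' @param alpha Flagging threshold on the (possibly adjusted) p-value.
#' @param correction `"none"` (default), `"bonferroni"` or `"BH"`.
#' @param redundancyJaccard NULL (default) or a Jaccard threshold in (0,1].
#' @return data.frame sorted by ascending p with columns `category`,
#'   `name`, `N`, `K`, `n`, `k`, `p`, `pAdjusted`, `flagged`.
#' @examples
#' ann <- AnnotationSet(data.frame(category = rep("C1", 3),
#'                                 gene = c("g1", "g2", "g3")),
#'                      universe = sprintf("g%d", 1:20))
#' enrichCategories(c("g1", "g2", "g3"), ann)
#' @export
enrichCategories <- function(significant, annotation, alpha = 0.05,
                             correction = c("none", "bonferroni", "BH"),
                             redundancyJaccard = NULL) {
  stopifnot(is(annotation, "AnnotationSet"))
  correction <- match.arg(correction)
  assertFraction(alpha, "alpha")
  significant <- unique(as.character(significant))
  outside <- setdiff(significant, annotation@universe)
  if (length(outside) > 0L) {
    warning(length(outside),
            " significant gene(s) outside the annotation universe dropped",
            call. = FALSE)
    significant <- setdiff(significant, outside)
  }
  cats <- annotation@categories
  cats <- cats[lengths(cats) >= 1L]
  N <- length(annotation@universe)
  n <- length(significant)
  if (n == 0L) {
    return(data.frame(category = character(), name = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p = numeric(), pAdjusted = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE))
  }
  res <- data.frame(
    category = names(cats),
    name = unname(annotation@categoryNames[names(cats)]),
    N = N,
    K = lengths(cats),
    n = n,
    k = vapply(cats, function(g) length(intersect(g, significant)),
               integer(1)),
    stringsAsFactors = FALSE)
  res$p <- mapply(hypergeomUpperTail, N, res$K, n, res$k)
  res$pAdjusted <- switch(correction,
    none = res$p,
    bonferroni = stats::p.adjust(res$p, "bonferroni"),
    BH = stats::p.adjust(res$p, "BH"))
  res <- res[order(res$p, res$category), , drop = FALSE]
  if (!is.null(redundancyJaccard)) {
    keep <- rep(TRUE, nrow(res))
    for (i in seq_len(nrow(res))[-1]) {
      gi <- cats[[res$category[i]]]
      for (j in seq_len(i - 1L)[keep[seq_len(i - 1L)]]) {
        gj <- cats[[res$category[j]]]
        jac <- length(intersect(gi, gj)) / length(union(gi, gj))
        if (jac > redundancyJaccard) { keep[i] <- FALSE; break }
      }
    }
    res <- res[keep, , drop = FALSE]
  }
  res$flagged <- res$pAdjusted <= alpha & res$k > 0
  rownames(res) <- NULL
  res
}

#' Hypergeometric significance of the overlap of two gene sets
#'
#' Probability of an overlap at least as large as observed between two gene
#' sets drawn from a common universe; used e.g. to compare screen hits with
#' previously published hit lists.
#'
#' @param setA,setB Character vectors of genes, both subsets of `universe`.
#' @param universe Non-empty character vector of background genes.
#' @return Named list: `N`, `K` (= |setA|), `n` (= |setB|), `k`
#'   (= |intersection|), `p`.
#' @examples
#' overlapSignificance(c("a", "b"), c("b", "c"), letters[1:10])
#' @export
overlapSignificance <- function(setA, setB, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("'universe' is empty", call. = FALSE)
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  if (!all(setA %in% universe) || !all(setB %in% universe)) {
    stop("both gene sets must be subsets of the universe", call. = FALSE)
  }
  k <- length(intersect(setA, setB))
  list(N = length(universe), K = length(setA), n = length(setB), k = k,
       p = hypergeomUpperTail(length(universe), length(setA),
                              length(setB), k))
}
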