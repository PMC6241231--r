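#' Hypergeometric upper-tail p-value
#'
#' Probability of observing at least \code{k} annotated genes in a
#' query of size \code{n} when the background of size \code{N} carries
#' \code{K} annotated genes: \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}. Evaluated in log space for
#' numerical stability; with \code{ease = TRUE} the more conservative
#' EASE-style variant is computed by replacing k with k - 1.
#'
#' @param k observed overlap (query hits in the term), \code{0 <= k <= min(n, K)}.
#' @param n query size (annotated query genes).
#' @param K term size in the background.
#' @param N background size.
#' @param ease logical; EASE-style conservative score (default FALSE).
#' @return the upper-tail probability, in (0, 1].
#' @export
hypergeomPValue <- function(k, n, K, N, ease = FALSE) {
  stopifnot(length(k) == length(n) || length(n) == 1,
            length(k) == length(K) || length(K) == 1,
            length(k) == length(N) || length(N) == 1)
  if (anyNA(c(k, n, K, N))) stop("arguments must not contain NA")
  if (any(n > N) || any(K > N)) stop("n and K must not exceed N")
  if (any(k < 0) || any(k > pmin(n, K))) stop("k must satisfy 0 <= k <= min(n, K)")
  kk <- if (ease) pmax(k - 1, 0) else k
  p <- exp(stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
  pmin(p, 1)
}

#' Fold enrichment
#'
#' The query's in-term frequency relative to the background's:
#' \code{(k/n) / (K/N)}. Undefined for \code{k = 0}, signalled as
#' \code{NA}.
#'
#' @inheritParams hypergeomPValue
#' @return the fold-enrichment ratio (\code{NA} where \code{k = 0}).
#' @export
foldEnrichment <- function(k, n, K, N) {
  if (any(n > N) || any(K > N)) stop("n and K must not exceed N")
  if (any(k < 0) || any(k > pmin(n, K))) stop("k must satisfy 0 <= k <= min(n, K)")
  out <- (k / n) / (K / N)
  out[k == 0] <- NA_real_
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: the i-th smallest p-value is
#' adjusted to \code{min over j >= i of m * p_(j) / j}, capped at 1,
#' and the adjusted values are returned in the input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
adjustBH <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests each annotation term for over-representation in a query gene
#' set with the hypergeometric upper tail. The effective query size n
#' is the number of query symbols present in the annotation background;
#' terms overlapping the query in fewer than \code{minHits} symbols are
#' excluded before multiple-testing adjustment, so m reflects only the
#' tested terms.
#'
#' @param query character vector of gene symbols (case-insensitive).
#' @param annotation an [AnnotationSet-class].
#' @param minHits minimum overlap k for a term to be tested (default 2).
#' @param ease logical, see [hypergeomPValue()].
#' @param background optional integer overriding the annotation's
#'   background size N.
#' @return data.frame with columns \code{term_id}, \code{term_name},
#'   \code{k}, \code{n}, \code{K}, \code{N}, \code{fold_enrichment},
#'   \code{p_value}, \code{q_value}, sorted by p then term id. Zero
#'   rows when no term reaches \code{minHits}.
#' @export
enrich <- function(query, annotation, minHits = 2, ease = FALSE,
                   background = NULL) {
  stopifnot(methods::is(annotation, "AnnotationSet"))
  if (minHits < 1) stop("minHits must be at least 1")
  query <- unique(toupper(query))
  universe <- backgroundSymbols(annotation)
  eff_query <- intersect(query, universe)
  if (length(eff_query) == 0)
    stop("query has no overlap with the annotation background")
  N <- if (is.null(background)) backgroundSize(annotation) else as.integer(background)
  n <- length(eff_query)
  if (n > N) stop("effective query larger than background N")
  K <- lengths(annotation@members)
  k <- vapply(annotation@members, function(m) length(intersect(eff_query, m)),
              integer(1))
  tested <- k >= minHits
  if (!any(tested)) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold_enrichment = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  k <- k[tested]; K <- K[tested]
  p <- hypergeomPValue(k, n, K, N, ease = ease)
  q <- adjustBH(p)
  out <- data.frame(term_id = annotation@termId[tested],
                    term_name = annotation@termName[tested],
                    k = as.integer(k), n = as.integer(n),
                    K = as.integer(K), N = as.integer(N),
                    fold_enrichment = foldEnrichment(k, n, K, N),
                    p_value = p, q_value = q, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' @param results data.frame from [enrich()].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeEnrichmentTable <- function(results, path) {
  df <- results
  for (col in c("fold_enrichment", "p_value", "q_value"))
    if (col %in% names(df)) df[[col]] <- sprintf("%.10g", df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
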