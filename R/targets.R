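#' Canonical miRNA seed-match sites in 3'UTRs
#'
#' Scans UTR sequences (mRNA sense strand) for exact canonical matches to
#' the miRNA seed: the 6mer core is the reverse complement of miRNA
#' positions 2-7; adding complementarity to position 8 upstream gives
#' 7mer-m8; adding an A downstream gives 7mer-A1; both give 8mer. Each
#' core occurrence is reported once, as its longest applicable type
#' (longer types subsume shorter ones at the same locus).
#'
#' @param mirna mature miRNA sequence, length >= 8, RNA alphabet (T read
#'   as U).
#' @param utrs named character vector or \code{RNAStringSet}/
#'   \code{DNAStringSet} of UTR sequences.
#' @return A \code{DFrame} with columns \code{transcript}, \code{start}
#'   (0-based), \code{end} (half-open) and \code{type} in \code{6mer,
#'   7mer-A1, 7mer-m8, 8mer}.
#' @examples
#' seedSites(MIR19A, c(tx1 = "AAUUUGCACAAA"))  # one 8mer site
#' @export
seedSites <- function(mirna, utrs) {
  pat <- .sitePatterns(mirna)
  if (is(utrs, "XStringSet")) utrs <- as.character(utrs)
  if (is.null(names(utrs))) names(utrs) <- paste0("utr", seq_along(utrs))
  utrs <- vapply(utrs, .normalizeRna, character(1))

  # Biostrings reports every core occurrence, including overlapping ones.
  starts <- Biostrings::startIndex(
    Biostrings::vmatchPattern(pat$core, Biostrings::RNAStringSet(utrs)))

  res <- vector("list", length(utrs))
  for (i in seq_along(utrs)) {
    s <- utrs[[i]]
    p <- starts[[i]]                            # 1-based core starts
    if (is.null(p) || !length(p)) next
    prev <- ifelse(p > 1, substr(rep(s, length(p)), p - 1, p - 1), "")
    nxt <- substr(rep(s, length(p)), p + 6, p + 6)
    hasM8 <- prev == pat$m8
    hasA1 <- nxt == "A"
    type <- ifelse(hasM8 & hasA1, "8mer",
                   ifelse(hasM8, "7mer-m8",
                          ifelse(hasA1, "7mer-A1", "6mer")))
    start0 <- ifelse(hasM8, p - 2L, p - 1L)
    len <- c("6mer" = 6L, "7mer-A1" = 7L, "7mer-m8" = 7L, "8mer" = 8L)[type]
    res[[i]] <- data.frame(transcript = names(utrs)[i], start = start0,
                           end = start0 + len, type = type)
  }
  out <- do.call(rbind, c(res, list(data.frame(transcript = character(),
                                               start = integer(),
                                               end = integer(),
                                               type = character()))))
  S4Vectors::DataFrame(out, row.names = NULL)
}

#' Predict miRNA targets from canonical seed sites
#'
#' A transcript is called a target when it carries at least
#' \code{minSites} sites of the accepted types. The default (one 8mer or
#' 7mer-m8 site) is a stringent canonical rule standing in for the
#' intersection of external prediction algorithms.
#'
#' @inheritParams seedSites
#' @param siteTypes accepted site types.
#' @param minSites minimum number of accepted sites.
#' @return Character vector of target transcript ids.
#' @export
predictTargets <- function(mirna, utrs, siteTypes = c("8mer", "7mer-m8"),
                           minSites = 1L) {
  if (!length(utrs)) stop("empty UTR set")
  sites <- seedSites(mirna, utrs)
  sites <- sites[sites$type %in% siteTypes, , drop = FALSE]
  counts <- table(sites$transcript)
  names(counts)[counts >= minSites]
}

#' Hypergeometric tail probabilities
#'
#' Exact tail probabilities of \code{Hypergeometric(N, K, n)} (draw
#' \code{n} from a population of \code{N} with \code{K} successes),
#' computed by summation of log binomial coefficients (log-sum-exp).
#' The over tail is \code{P(X >= k)}, the under tail \code{P(X <= k)};
#' both include the point mass at \code{k}.
#'
#' @param k observed successes (vectorized).
#' @param K successes in the population.
#' @param n draw size.
#' @param N population size.
#' @param tail \code{"over"} or \code{"under"}.
#' @return Numeric vector of exact tail probabilities.
#' @examples
#' hypergeomTail(4, K = 4, n = 5, N = 10, tail = "over")  # 6/252
#' @export
hypergeomTail <- function(k, K, n, N, tail = c("over", "under")) {
  tail <- match.arg(tail)
  if (K > N || n > N || K < 0 || n < 0)
    stop("inconsistent counts: need 0 <= K, n <= N")
  if (any(k < 0 | k > pmin(K, n)))
    stop("k must lie in [0, min(K, n)]")
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  denom <- lchoose(N, n)
  vapply(k, function(ki) {
    j <- if (tail == "over") seq(ki, hi) else seq(lo, ki)
    # empty support below/above is impossible given the validation above
    exp(logSumExp(lchoose(K, j) + lchoose(N - K, n - j) - denom))
  }, numeric(1))
}

#' Target enrichment and depletion per fold-change quadrant
#'
#' For each quadrant of a [QuadrantTable][result-classes], tests whether
#' the quadrant's genes are enriched (\code{pOver}) or depleted
#' (\code{pUnder}) in miRNA targets relative to a background gene universe,
#' using the exact hypergeometric tails. In the rescue design the
#' headline expectation is over-enrichment in QII (up under perturbation,
#' down under treatment) and under-representation in QIV.
#'
#' @param table a [QuadrantTable][result-classes].
#' @param targets character vector of target gene ids; ids absent from the
#'   background are dropped with a warning.
#' @param background character vector: the gene universe (all genes
#'   measured on the array after probe summarization).
#' @return A \code{DFrame} with one row per quadrant: \code{quadrant, N, K,
#'   n, k, pOver, pUnder}.
#' @export
quadrantEnrichment <- function(table, targets, background) {
  background <- unique(background)
  dropped <- setdiff(targets, background)
  if (length(dropped))
    warning(length(dropped), " target id(s) absent from background; dropped")
  targets <- intersect(targets, background)
  if (!all(table$gene %in% background))
    stop("quadrant genes must be a subset of the background")
  N <- length(background)
  K <- length(targets)
  quads <- c("QI", "QII", "QIII", "QIV")
  rows <- lapply(quads, function(qd) {
    g <- table$gene[table$quadrant == qd]
    n <- length(g)
    k <- length(intersect(g, targets))
    S4Vectors::DataFrame(quadrant = qd, N = N, K = K, n = n, k = k,
      pOver = hypergeomTail(k, K, n, N, "over"),
      pUnder = hypergeomTail(k, K, n, N, "under"))
  })
  do.call(rbind, rows)
}
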