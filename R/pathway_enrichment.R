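#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes in a query of size `n` from a universe of
#' `N` genes of which `K` are annotated to the term. This is the classic
#' over-representation p-value, inclusive of the observed count.
#'
#' @param N background (universe) size.
#' @param K genes in the background annotated to the term.
#' @param n query size.
#' @param k query genes annotated to the term.
#' @return p-value in `(0, 1]`; vectorized over all arguments.
#' @export
#' @examples
#' hypergeom_upper_tail(10, 5, 4, 4)  # 5/210
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(k < 0) || any(n > N) || any(K > N) || any(k > n) || any(k > K))
    stop("hypergeometric bounds violated: need k <= n <= N and k <= K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up q-values with monotonicity enforcement; output order
#' matches input order.
#'
#' @param pvalues p-values in `(0, 1]`.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (term id, description, then tab-separated genes).
#' @return data.frame with `term_id`, `term_name` and a list-column `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("GMT line(s) with no genes: ", paste(which(bad), collapse = ","))
  out <- data.frame(term_id = vapply(parts, `[`, "", 1),
                    term_name = vapply(parts, `[`, "", 2),
                    stringsAsFactors = FALSE)
  out$genes <- lapply(parts, function(p) unique(p[-(1:2)]))
  out
}

#' Write gene sets to a GMT file
#'
#' @param pathways data.frame as returned by [read_gmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(seq_len(nrow(pathways)), function(i) {
    paste(c(pathways$term_id[i], pathways$term_name[i],
            pathways$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pathway over-representation with background-size and strength filters
#'
#' Hypergeometric over-representation of a query gene list against pathway
#' gene sets, following the STRING-style workflow: terms whose background
#' annotation count `K` falls outside `[min_bg, max_bg]` are excluded
#' *before* testing (so the BH correction spans only tested terms), the
#' remaining terms are BH-adjusted, and a term is retained when
#' `FDR < fdr_cut` and `strength > strength_cut`, where
#' `strength = log10((k/n) / (K/N))` is the log observed/expected ratio.
#' Terms with `k = 0` have `p = 1`, undefined strength, and are never
#' retained.
#'
#' @param query_genes character vector of query genes (must all be in the
#'   background).
#' @param pathways gene-set table ([read_gmt()] layout).
#' @param background_genes the gene universe; defaults to the union of all
#'   pathway members. For a genome-wide analysis pass the full gene
#'   complement of the organism.
#' @param min_bg,max_bg background-count retention window (default 30-1000).
#' @param fdr_cut,strength_cut retention thresholds (defaults 0.05 and 0.5).
#' @param retain_only if `FALSE`, return all tested terms with a `retained`
#'   flag instead of only the retained ones.
#' @return data.frame with `term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `p`, `fdr`, `strength`, sorted by FDR then decreasing strength.
#' @export
enrich <- function(query_genes, pathways, background_genes = NULL,
                   min_bg = 30, max_bg = 1000, fdr_cut = 0.05,
                   strength_cut = 0.5, retain_only = TRUE) {
  query_genes <- unique(query_genes)
  if (is.null(background_genes))
    background_genes <- unique(unlist(pathways$genes))
  background_genes <- unique(background_genes)
  absent <- setdiff(query_genes, background_genes)
  if (length(absent))
    stop("query gene(s) absent from background: ", paste(absent, collapse = ", "))
  N <- length(background_genes)
  n <- length(query_genes)
  K <- vapply(pathways$genes, function(g) length(intersect(g, background_genes)),
              integer(1))
  tested <- which(K >= min_bg & K <= max_bg)
  if (!length(tested)) {
    out <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(), N = integer(),
                      p = numeric(), fdr = numeric(), strength = numeric(),
                      retained = logical())
    return(if (retain_only) out[, -10] else out)
  }
  k <- vapply(pathways$genes[tested],
              function(g) length(intersect(g, query_genes)), integer(1))
  p <- hypergeom_upper_tail(N, K[tested], n, k)
  fdr <- bh_fdr(p)
  strength <- ifelse(k > 0, log10((k / n) / (K[tested] / N)), NA_real_)
  out <- data.frame(term_id = pathways$term_id[tested],
                    term_name = pathways$term_name[tested],
                    k = k, n = n, K = K[tested], N = N,
                    p = p, fdr = fdr, strength = strength,
                    stringsAsFactors = FALSE)
  out$retained <- !is.na(out$strength) & out$fdr < fdr_cut & out$strength > strength_cut
  out <- out[order(out$fdr, -ifelse(is.na(out$strength), -Inf, out$strength)), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (retain_only) out[out$retained, setdiff(names(out), "retained"), drop = FALSE]
  else out
}
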