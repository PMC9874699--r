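DEFAULT_STAGES <- c("prenatal", "infant", "child", "adolescent", "adult")

DEFAULT_REGIONS <- c(
  "frontal_neocortex", "orbital_frontal_cortex", "primary_motor_cortex",
  "primary_somatosensory_cortex", "primary_auditory_cortex",
  "primary_visual_cortex", "posterior_superior_temporal_cortex",
  "inferior_temporal_cortex", "parietal_neocortex", "hippocampus",
  "amygdala", "striatum", "cerebral_nuclei", "mediodorsal_thalamus",
  "cerebellar_cortex", "upper_rhombic_lip"
)

cell_name <- function(region, stage) paste(region, stage, sep = "|")

#' Brain-biased background gene set from two fold-change tables
#'
#' Genes whose brain-versus-other-tissue log2 fold-change exceeds the
#' threshold (strictly) in *either* of two reference datasets form the
#' background universe for the brain-region enrichment. Genes absent from
#' both tables are excluded.
#'
#' @param fc_a,fc_b data.frames with columns `gene` and `log2fc`.
#' @param threshold strict lower bound on log2 fold-change (default 0.5).
#' @return character vector of background genes.
#' @export
brain_biased_background <- function(fc_a, fc_b, threshold = 0.5) {
  a <- fc_a$gene[!is.na(fc_a$log2fc) & fc_a$log2fc > threshold]
  b <- fc_b$gene[!is.na(fc_b$log2fc) & fc_b$log2fc > threshold]
  unique(c(a, b))
}

#' Highly expressed genes of one region-stage cell
#'
#' Genes whose expression in the given (region, stage) cell strictly
#' exceeds the `q`-th quantile of that cell's expression over the
#' background genes (inclusive linear-interpolation quantile, the R
#' default). With constant expression nothing exceeds the quantile and the
#' set is empty.
#'
#' @param mat expression matrix (genes x `"region|stage"` columns).
#' @param region,stage cell coordinates.
#' @param q quantile cutoff in (0, 1).
#' @param background genes defining the quantile distribution; defaults to
#'   all genes in the matrix.
#' @return character vector of high-expression genes (within background).
#' @export
high_expression_set <- function(mat, region, stage, q, background = rownames(mat)) {
  if (q <= 0 || q >= 1) stop("quantile cutoff must be in (0, 1)")
  col <- cell_name(region, stage)
  if (!col %in% colnames(mat)) stop("no expression cell ", col)
  bg <- intersect(background, rownames(mat))
  x <- mat[bg, col]
  cut <- stats::quantile(x, probs = q, names = FALSE, type = 7)
  bg[x > cut]
}

#' Hypergeometric region-stage enrichment of a target gene set
#'
#' For every (region, stage) cell and every quantile cutoff, tests whether
#' the target genes are over-represented among the cell's highly expressed
#' genes relative to the background universe:
#' `p = P(X >= k)` with `N = |background|`, `K = |high set|`,
#' `n = |target within background|`, `k = |target in high set|`.
#'
#' @param target_genes the gene list under test. Genes outside the
#'   background are dropped with a warning; an empty intersection is an
#'   error.
#' @param mat expression matrix (genes x `"region|stage"`).
#' @param background background gene set (see [brain_biased_background()]);
#'   genes missing from the matrix are ignored.
#' @param quantiles quantile cutoffs (default the five equally spaced
#'   values 0.5, 0.6, 0.7, 0.8, 0.9).
#' @return data.frame with one row per (region, stage, quantile):
#'   `region`, `stage`, `quantile`, `k`, `n`, `K`, `N`, `p`.
#' @export
region_stage_enrichment <- function(target_genes, mat, background,
                                    quantiles = seq(0.5, 0.9, by = 0.1)) {
  background <- intersect(unique(background), rownames(mat))
  target <- unique(target_genes)
  dropped <- setdiff(target, background)
  if (length(dropped))
    warning(length(dropped), " target gene(s) outside the background dropped")
  target <- intersect(target, background)
  if (!length(target)) stop("no target genes left after background intersection")
  cells <- strsplit(colnames(mat), "|", fixed = TRUE)
  res <- list()
  for (q in quantiles) {
    for (i in seq_along(cells)) {
      region <- cells[[i]][1]; stage <- cells[[i]][2]
      high <- high_expression_set(mat, region, stage, q, background)
      k <- length(intersect(target, high))
      res[[length(res) + 1L]] <- data.frame(
        region = region, stage = stage, quantile = q,
        k = k, n = length(target), K = length(high), N = length(background),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$p <- hypergeom_upper_tail(out$N, out$K, out$n, out$k)
  out
}

# logical background x cell matrix of high-expression membership, one per
# quantile; used to vectorize the permutation loop
high_membership <- function(mat, background, q) {
  sub <- mat[background, , drop = FALSE]
  cuts <- apply(sub, 2, stats::quantile, probs = q, names = FALSE, type = 7)
  sweep(sub, 2, cuts, ">")
}

#' Permutation family-wise error rate for region-stage enrichment
#'
#' Competitive min-p permutation test: `R` random gene sets of the target
#' size are drawn uniformly from the background, all cell p-values are
#' recomputed, and each observed cell's FWER at quantile `q` is
#' `(1 + #permutations whose minimum p over all cells at q is <= the
#' observed p) / (R + 1)` (add-one estimator; ties count). The family is
#' the full set of region-stage cells at one quantile, matching a report
#' with one FWER column per quantile.
#'
#' @param observed result of [region_stage_enrichment()].
#' @param mat,background as in [region_stage_enrichment()].
#' @param target_size permutation draw size; defaults to the observed `n`.
#' @param R number of permutations (default 1000).
#' @param seed integer seed; every random draw flows from it.
#' @return `observed` with an added `fwer` column.
#' @export
permutation_fwer <- function(observed, mat, background, target_size = NULL,
                             R = 1000, seed = 1) {
  if (R < 1) stop("R must be >= 1")
  background <- intersect(unique(background), rownames(mat))
  if (is.null(target_size)) target_size <- observed$n[1]
  if (target_size > length(background))
    stop("target_size exceeds background size")
  quantiles <- sort(unique(observed$quantile))
  N <- length(background)
  mem <- lapply(quantiles, function(q) high_membership(mat, background, q))
  names(mem) <- as.character(quantiles)
  Kq <- lapply(mem, colSums)

  minp <- withr::with_seed(seed, {
    mp <- matrix(NA_real_, nrow = R, ncol = length(quantiles),
                 dimnames = list(NULL, names(mem)))
    for (r in seq_len(R)) {
      idx <- sample.int(N, target_size)
      for (qn in names(mem)) {
        k <- colSums(mem[[qn]][idx, , drop = FALSE])
        p <- stats::phyper(k - 1, Kq[[qn]], N - Kq[[qn]], target_size,
                           lower.tail = FALSE)
        mp[r, qn] <- min(p)
      }
    }
    mp
  })

  observed$fwer <- vapply(seq_len(nrow(observed)), function(i) {
    qn <- as.character(observed$quantile[i])
    (1 + sum(minp[, qn] <= observed$p[i])) / (R + 1)
  }, numeric(1))
  observed
}

#' Region-by-stage FWER report table
#'
#' Reshapes long enrichment results into the familiar wide layout: one row
#' per (region, stage), one FWER column per quantile cutoff, plus
#' `n_signif`, the number of cutoffs at which the cell's FWER is below
#' `alpha`.
#'
#' @param results output of [permutation_fwer()].
#' @param alpha significance level for `n_signif` (default 0.05).
#' @return wide data.frame sorted by `n_signif` (descending) then minimum
#'   FWER.
#' @export
fwer_table <- function(results, alpha = 0.05) {
  quantiles <- sort(unique(results$quantile))
  key <- paste(results$region, results$stage, sep = "\r")
  rows <- lapply(split(results, key), function(d) {
    d <- d[order(d$quantile), ]
    out <- data.frame(region = d$region[1], stage = d$stage[1],
                      n_signif = sum(d$fwer < alpha), stringsAsFactors = FALSE)
    for (i in seq_along(quantiles))
      out[[paste0("fwer_q", quantiles[i])]] <- d$fwer[i]
    out
  })
  out <- do.call(rbind, rows)
  fw <- as.matrix(out[, grep("^fwer_q", names(out)), drop = FALSE])
  out <- out[order(-out$n_signif, apply(fw, 1, min)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write an expression matrix TSV
#'
#' Layout: first column `gene`, remaining columns named `region|stage`.
#'
#' @param path TSV path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_matrix
#' @param mat matrix to write.
#' @export
write_expression_matrix <- function(mat, path) {
  d <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
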