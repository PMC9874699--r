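# Independent oracles and random-instance generators. Everything here is
# deliberately implemented with different machinery than the package
# (outer()/union-find instead of findOverlaps/igraph; subset enumeration
# instead of phyper) so oracle agreement is a meaningful check.

# brute-force all-pairs single-linkage merge for ONE sample
oracle_merge <- function(calls, ro_threshold = 0.7, ins_window = 500,
                         ins_ratio = 0.7, min_support = 2) {
  res <- list()
  for (type in unique(calls$svtype)) {
    sub <- calls[calls$svtype == type, , drop = FALSE]
    rownames(sub) <- NULL
    n <- nrow(sub)
    if (type == "INS") {
      dstart <- abs(outer(sub$start, sub$start, "-"))
      ratio <- outer(sub$length, sub$length, pmin) /
               outer(sub$length, sub$length, pmax)
      adj <- dstart <= ins_window & ratio >= ins_ratio
    } else {
      s <- sub$start; e <- sub$start + sub$length
      ov <- pmax(outer(rep(0, n), rep(0, n)),
                 outer(e, e, pmin) - outer(s, s, pmax))
      ov[ov < 0] <- 0
      adj <- ov / outer(sub$length, sub$length, pmax) >= ro_threshold
    }
    adj <- adj & outer(sub$chrom, sub$chrom, "==")
    # union-find over the adjacency matrix
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n)) for (j in which(adj[i, ] & seq_len(n) > i)) {
      rj <- find(j); ri <- find(i)
      if (ri != rj) parent[rj] <- ri
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (grp_ix in split(seq_len(n), comp)) {
      grp <- sub[grp_ix, , drop = FALSE]
      callers <- unique(grp$caller_id)
      if (length(callers) < min_support) next
      med0 <- stats::median(grp$start)
      sel <- do.call(rbind, lapply(callers, function(cl) {
        rows <- grp[grp$caller_id == cl, , drop = FALSE]
        rows <- rows[order(abs(rows$start - med0), rows$start, rows$length), ]
        rows[1, ]
      }))
      res[[length(res) + 1L]] <- data.frame(
        chrom = grp$chrom[1],
        start = floor(stats::median(sel$start) + 0.5),
        length = floor(stats::median(sel$length) + 0.5),
        svtype = type, n_callers = length(callers),
        callers = paste(sort(callers), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = numeric(), length = numeric(),
                      svtype = character(), n_callers = integer(),
                      callers = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start, out$svtype, out$length), , drop = FALSE]
}

# canonical key set for comparing merge outputs
merge_keys <- function(df) {
  if (!nrow(df)) return(character())
  sort(paste(df$chrom, df$start, df$length, df$svtype, df$n_callers, df$callers))
}

# random single-sample multi-caller instance with clustered loci
random_call_instance <- function(n_calls, n_callers = 4, n_loci = NULL) {
  if (is.null(n_loci)) n_loci <- max(2L, ceiling(n_calls / 4))
  locus_start <- sample.int(1e6, n_loci)
  locus_len <- sample(c(30:80, 200:400, 3000:8000), n_loci, replace = TRUE)
  locus_type <- sample(c("DEL", "INS", "DUP", "INV"), n_loci, replace = TRUE)
  locus_chrom <- sample(c("chr1", "chr2"), n_loci, replace = TRUE)
  ix <- sample.int(n_loci, n_calls, replace = TRUE)
  jitter <- as.integer(round(rnorm(n_calls, 0, 25)))
  sv_calls(
    chrom = locus_chrom[ix],
    start = pmax(1L, locus_start[ix] + jitter),
    length = pmax(30L, locus_len[ix] +
                    as.integer(round(rnorm(n_calls, 0, 10)))),
    svtype = locus_type[ix],
    sample_id = "S1",
    caller_id = paste0("c", sample.int(n_callers, n_calls, replace = TRUE))
  )
}

# exhaustive hypergeometric upper tail by subset enumeration
oracle_hypergeom <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  marked <- subsets <= K  # items 1..K are "annotated"
  mean(colSums(marked) >= k)
}

# standard 4-caller test profiles at the planted-recovery study conditions
recovery_profiles <- function(sensitivity = 0.95, jitter = 20) {
  do.call(rbind, lapply(paste0("c", 1:4), caller_profile,
                        sensitivity = sensitivity, breakpoint_jitter = jitter,
                        length_jitter = 0, false_rate = 0))
}
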