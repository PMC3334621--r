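# Shared fixtures and independent oracles, all built in code.

ADAPTOR <- "TCGTATGCCGTCTTCTGCTTG"

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

make_hairpin_df <- function(ids, seqs) {
  data.frame(id = ids,
             species = ifelse(grepl("^[a-z]{3}-", ids), substr(ids, 1, 3), NA),
             sequence = seqs, length = nchar(seqs), stringsAsFactors = FALSE)
}

# 100-nt hairpin whose 3p mature sits at 60..80 with a G at hairpin pos 77;
# mirrors the hsa-miR-143 layout used in the worked examples.
fixture_mir143 <- function() {
  set.seed(143)
  s <- rand_seq(100)
  substr(s, 77, 77) <- "G"
  hp <- make_hairpin_df("hsa-mir-143", s)
  ann <- locate_mature("hsa-miR-143", substr(s, 60, 80), hp)
  list(hairpin = hp, annotation = ann)
}

# Brute-force Hamming oracle: mismatch count at every offset.
oracle_hamming <- function(tag, hp_seq, max_sub) {
  n <- nchar(tag)
  L <- nchar(hp_seq)
  if (n > L) return(data.frame(start = integer(), n_sub = integer()))
  tv <- utf8ToInt(tag)
  hv <- utf8ToInt(hp_seq)
  res <- vapply(1:(L - n + 1), function(s) sum(tv != hv[s:(s + n - 1)]), 0L)
  hits <- which(res <= max_sub)
  data.frame(start = hits, n_sub = res[hits])
}

# Brute-force recursive-trimming oracle over the (length, offset) grid:
# longest length with any placement wins, then minimal mismatches.
oracle_recursive <- function(tag, hairpins, params) {
  len <- nchar(tag)
  while (len >= params$min_len) {
    hits <- do.call(rbind, lapply(seq_len(nrow(hairpins)), function(i) {
      h <- oracle_hamming(substr(tag, 1, len), hairpins$sequence[i],
                          params$max_sub)
      if (nrow(h) == 0) return(NULL)
      cbind(hairpin_id = hairpins$id[i], h)
    }))
    if (!is.null(hits) && nrow(hits) > 0) {
      hits <- hits[hits$n_sub == min(hits$n_sub), , drop = FALSE]
      hits <- hits[order(hits$hairpin_id, hits$start), , drop = FALSE]
      return(list(aligned_len = len, placements = hits))
    }
    len <- len - params$trim_step
  }
  NULL
}

# Direct transcription of the trimmed-mean-of-M-values formula: M and A over
# features positive in both sample and reference, rank-based double trim,
# precision-weighted mean, factors rescaled to geometric mean 1.
oracle_tmm <- function(mat, ref, trim_M = 0.30, trim_A = 0.05) {
  N <- colSums(mat)
  f <- vapply(seq_len(ncol(mat)), function(s) {
    x <- mat[, s]; r <- mat[, ref]
    keep <- x > 0 & r > 0
    x <- x[keep]; r <- r[keep]
    M <- log2((x / N[s]) / (r / N[ref]))
    A <- 0.5 * log2((x / N[s]) * (r / N[ref]))
    w <- (N[s] - x) / (N[s] * x) + (N[ref] - r) / (N[ref] * r)
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    fs <- sum(M[keep2] / w[keep2]) / sum(1 / w[keep2])
    if (!is.finite(fs) || abs(fs) < 1e-6) fs <- 0
    2^fs
  }, 0)
  f / exp(mean(log(f)))
}

# Small zero-error cohort shared by the heavier end-to-end tests; built once
# per test run.
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- sim_spec(seed = 421, error_rate = 0,
                       cohort = data.frame(
                         sample_id = paste0("s", 1:8),
                         tissue = rep(c("brain", "heart", "kidney", "liver"),
                                      each = 2),
                         donor_id = paste0("d", rep(1:4, each = 2)),
                         prep_kit = rep(c("SREK", "WTAK"), 4),
                         depth = 1500L, stringsAsFactors = FALSE))
      co <- simulate_cohort(spec)
      pl <- run_pipeline(co$hairpins, co$annotations, co$tags, co$samples,
                         aligner_params(adaptor_seq = spec$adaptor_seq))
      cache <<- list(spec = spec, cohort = co, pipeline = pl)
    }
    cache
  }
})
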