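#' Build the feature-by-sample count matrix
#'
#' Each annotated placement deposits \code{multiplicity * weight} into its
#' feature's cell, so a multi-mapping tag conserves unit mass and column sums
#' equal per-sample mapped tag mass exactly. Fractional values are kept as
#' reals throughout.
#'
#' @param annotated Annotated alignment table from [annotate_alignments()].
#' @param samples Sample sheet \code{data.frame} (defines column order; every
#'   \code{sample_id} in \code{annotated} must appear here).
#' @return A list of class \code{"isomir_counts"}: \code{matrix}
#'   (features x samples), \code{features} (metadata rows aligned to the
#'   matrix: \code{name}, \code{hairpin_id}, \code{arm}, \code{mature_name},
#'   \code{category}), \code{samples}, and \code{lib_size} (per-sample mapped
#'   mass).
#' @export
build_counts <- function(annotated, samples) {
  unknown <- setdiff(annotated$sample_id, samples$sample_id)
  if (length(unknown) > 0L) {
    stop("sample id(s) not in sample sheet: ", paste(unknown, collapse = ", "))
  }
  feats <- unique(annotated[, c("name", "hairpin_id", "arm", "mature_name",
                                "category")])
  feats <- feats[order(feats$name), , drop = FALSE]
  rownames(feats) <- NULL
  mat <- matrix(0, nrow = nrow(feats), ncol = nrow(samples),
                dimnames = list(feats$name, samples$sample_id))
  mass <- annotated$multiplicity * annotated$weight
  idx <- cbind(match(annotated$name, feats$name),
               match(annotated$sample_id, samples$sample_id))
  for (i in seq_along(mass)) {
    mat[idx[i, 1L], idx[i, 2L]] <- mat[idx[i, 1L], idx[i, 2L]] + mass[i]
  }
  structure(list(matrix = mat, features = feats, samples = samples,
                 lib_size = colSums(mat)),
            class = "isomir_counts")
}

#' @export
print.isomir_counts <- function(x, ...) {
  cat("isomir_counts:", nrow(x$matrix), "features x", ncol(x$matrix),
      "samples\n")
  cat("library sizes:", paste(signif(x$lib_size, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Computes per-sample TMM scaling factors so that tpm values can be
#' corrected for composition bias via effective library sizes
#' (\code{raw size x factor}). The computation is delegated to
#' \code{edgeR::calcNormFactors} (method \code{"TMM"}): for each sample
#' against the reference, log-ratios M and abundances A over features
#' positive in both are doubly trimmed (30\% on M, 5\% on A by default), and
#' the factor is the precision-weighted mean of the surviving M values;
#' factors are rescaled to geometric mean 1. The default reference is the
#' sample whose upper-quartile count fraction is closest to the mean
#' upper-quartile fraction.
#'
#' @param counts An \code{isomir_counts} object or a numeric matrix.
#' @param trim_M Two-sided trim fraction on log-ratios (default 0.30).
#' @param trim_A Two-sided trim fraction on abundances (default 0.05).
#' @param reference Optional reference \code{sample_id} (column name).
#' @return \code{data.frame(sample_id, lib_size, norm_factor,
#'   effective_lib_size)} with the reference id in
#'   \code{attr(, "reference")}.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05,
                        reference = NULL) {
  mat <- if (inherits(counts, "isomir_counts")) counts$matrix else counts
  if (ncol(mat) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(mat)
  ref_col <- if (is.null(reference)) NULL else match(reference, colnames(mat))
  if (!is.null(reference) && is.na(ref_col)) {
    stop("reference sample not found: ", reference)
  }
  # edgeR's default reference rule (upper-quartile fraction closest to mean)
  eff_ref <- if (is.null(ref_col)) {
    uq <- apply(mat, 2L, function(x) stats::quantile(x, 0.75)) / lib
    which.min(abs(uq - mean(uq)))
  } else ref_col
  shared <- vapply(seq_len(ncol(mat)),
                   function(j) sum(mat[, j] > 0 & mat[, eff_ref] > 0), 0L)
  if (any(shared[-eff_ref] < 20L)) {
    warning("fewer than 20 features shared with the reference; ",
            "falling back to unit factors")
    f <- rep(1, ncol(mat))
  } else {
    f <- edgeR::calcNormFactors(mat, lib.size = lib, method = "TMM",
                                refColumn = ref_col, logratioTrim = trim_M,
                                sumTrim = trim_A, doWeighting = TRUE)
    f <- f / exp(mean(log(f)))
  }
  out <- data.frame(sample_id = colnames(mat), lib_size = lib,
                    norm_factor = f, effective_lib_size = lib * f,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "reference") <- colnames(mat)[eff_ref]
  out
}

#' Tags-per-million matrix
#'
#' \code{tpm(f, s) = 1e6 * count(f, s) / effective_library_size(s)}. With
#' unit factors every column sums to exactly 1e6; TMM correction rescales
#' whole columns by \code{1/f_s}.
#'
#' @param counts An \code{isomir_counts} object.
#' @param factors Optional factor table from [tmm_factors()]; \code{NULL}
#'   uses unit factors.
#' @return Numeric tpm matrix with the same dimnames as the counts.
#' @export
tpm_matrix <- function(counts, factors = NULL) {
  mat <- counts$matrix
  eff <- counts$lib_size
  if (!is.null(factors)) {
    eff <- factors$effective_lib_size[match(colnames(mat), factors$sample_id)]
  }
  if (any(!is.finite(eff)) || any(eff <= 0)) {
    stop("zero or invalid effective library size")
  }
  sweep(mat, 2L, eff, "/") * 1e6
}

# Minimum sliding Hamming distance between two sequences (shorter slid over
# longer, full containment only).
min_window_hamming <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  n <- length(av)
  offs <- 0:(length(bv) - n)
  min(vapply(offs, function(o) sum(av != bv[o + seq_len(n)]), 0))
}

#' Estimate the expression noise floor from cross-species decoy matures
#'
#' Tags are aligned (recursively, same parameters) against a set of decoy
#' mature sequences that cannot be genuinely present in the library — e.g.
#' non-conserved matures from distant species. Any decoy signal is therefore
#' noise, and the floor is the maximum decoy tpm over all samples, rounded up
#' to the nearest integer. Decoys within \code{max_sub} mismatches of a
#' target mature (at any offset) are dropped first with a warning; if no
#' decoy is hit at all, the configured default applies.
#'
#' @param tags Tag table covering all samples.
#' @param decoys Decoy set as a hairpin-style \code{data.frame} (\code{id},
#'   \code{sequence}); e.g. from [read_hairpin_fasta()].
#' @param annotations Target mature annotations (for the disjointness check).
#' @param lib_sizes Named per-sample effective library sizes (from the real
#'   alignment; decoy tpm is measured against the same denominators).
#' @param params [aligner_params()].
#' @param default_floor Floor when no decoy draws any signal (default 10).
#' @return Integer noise floor in tpm, with per-sample decoy tpm in
#'   \code{attr(, "decoy_tpm")}.
#' @export
decoy_noise_floor <- function(tags, decoys, annotations, lib_sizes,
                              params = aligner_params(), default_floor = 10) {
  if (is.null(decoys) || nrow(decoys) == 0L) {
    warning("empty decoy set; using default noise floor")
    return(structure(as.integer(default_floor), decoy_tpm = numeric()))
  }
  near <- vapply(decoys$sequence, function(d) {
    any(vapply(annotations$sequence,
               function(m) min_window_hamming(d, m) <= params$max_sub, TRUE))
  }, TRUE)
  if (any(near)) {
    warning("dropping ", sum(near),
            " decoy(s) within max_sub mismatches of a target mature")
    decoys <- decoys[!near, , drop = FALSE]
  }
  if (nrow(decoys) == 0L) {
    warning("no decoys survive the disjointness check; using default floor")
    return(structure(as.integer(default_floor), decoy_tpm = numeric()))
  }
  aligned <- align_tags(tags, decoys, params, strategy = "recursive")
  hit <- aligned[aligned$status == "mapped", , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(structure(as.integer(default_floor), decoy_tpm = numeric()))
  }
  # per (decoy, sample) mass -> tpm against the real library denominators
  mass <- tapply(hit$multiplicity * hit$weight,
                 list(hit$hairpin_id, hit$sample_id), sum)
  mass[is.na(mass)] <- 0
  tpm <- sweep(mass, 2L, lib_sizes[colnames(mass)], "/") * 1e6
  structure(as.integer(ceiling(max(tpm))), decoy_tpm = apply(tpm, 2L, max))
}

#' Robustness filter configuration
#'
#' @param min_tpm Expression threshold for the tissue rule (default 10 tpm).
#' @param min_prep_kits Minimum distinct library-prep kits in which a feature
#'   must be detected (tpm > 0) (default 2).
#' @param drop_orphans Whether to drop orphan isomiRs (default TRUE).
#' @return A list of class \code{"filter_config"}.
#' @export
filter_config <- function(min_tpm = 10, min_prep_kits = 2L,
                          drop_orphans = TRUE) {
  stopifnot(min_tpm >= 0, min_prep_kits >= 1L)
  structure(list(min_tpm = min_tpm, min_prep_kits = as.integer(min_prep_kits),
                 drop_orphans = drop_orphans), class = "filter_config")
}

#' Apply the robustness filters to a tpm matrix
#'
#' A feature is retained iff (i) some tissue has tpm >= \code{min_tpm} in
#' every one of its samples, (ii) it is detected (tpm > 0) in samples
#' spanning at least \code{min_prep_kits} distinct prep kits, and (iii) it is
#' not an orphan isomiR when \code{drop_orphans} is set. The tissue rule uses
#' the expression threshold ("present"); the kit rule uses any evidence
#' ("detected") — the two notions are deliberately distinct.
#'
#' @param tpm Feature-by-sample tpm matrix.
#' @param samples Sample sheet (tissue and prep_kit per sample).
#' @param config [filter_config()].
#' @param orphans Optional logical vector along \code{rownames(tpm)} from
#'   [flag_orphans()]; ignored unless \code{drop_orphans}.
#' @return \code{list(retained = <names>, report = <data.frame>)}; the
#'   report has one row per feature with the per-rule outcomes and the first
#'   rule that removed each dropped feature.
#' @export
apply_filters <- function(tpm, samples, config = filter_config(),
                          orphans = NULL) {
  tissues <- unique(samples$tissue)
  ok_tissue <- rep(FALSE, nrow(tpm))
  for (t in tissues) {
    cols <- samples$sample_id[samples$tissue == t]
    if (length(cols) == 0L) stop("tissue with zero samples: ", t)
    ok_tissue <- ok_tissue |
      apply(tpm[, cols, drop = FALSE] >= config$min_tpm, 1L, all)
  }
  kit_of <- samples$prep_kit[match(colnames(tpm), samples$sample_id)]
  n_kits <- apply(tpm > 0, 1L, function(v) length(unique(kit_of[v])))
  ok_kit <- n_kits >= config$min_prep_kits
  ok_orphan <- if (config$drop_orphans && !is.null(orphans)) !orphans
               else rep(TRUE, nrow(tpm))
  keep <- ok_tissue & ok_kit & ok_orphan
  dropped_by <- rep(NA_character_, nrow(tpm))
  dropped_by[!ok_orphan] <- "orphan"
  dropped_by[!ok_kit] <- "prep_kit"
  dropped_by[!ok_tissue] <- "tissue"
  report <- data.frame(name = rownames(tpm), tissue_rule = ok_tissue,
                       kit_rule = ok_kit, orphan_rule = ok_orphan,
                       retained = keep, dropped_by = dropped_by,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(retained = rownames(tpm)[keep], report = report)
}

#' IsomiR-to-canonical expression ratios
#'
#' For every isomiR feature, the per-sample ratio of its tpm to the tpm of
#' its own arm's canonical feature, plus median ratios per category. Samples
#' where the canonical tpm is 0 are flagged undefined and excluded from the
#' medians.
#'
#' @param tpm Feature-by-sample tpm matrix.
#' @param features Feature metadata aligned to \code{rownames(tpm)}.
#' @return \code{list(ratios = <matrix>, medians = <data.frame>)}: per-isomiR
#'   per-sample ratios (NA where undefined) and per-category medians over all
#'   defined (isomiR, sample) pairs with isomiR tpm > 0.
#' @export
isomir_canonical_ratios <- function(tpm, features) {
  key <- paste(features$hairpin_id, features$arm, sep = "\r")
  canon_idx <- which(!is.na(features$category) &
                     features$category == "canonical")
  canon_of <- stats::setNames(canon_idx, key[canon_idx])
  iso <- which(!is.na(features$category) & features$category != "canonical" &
               key %in% names(canon_of))
  ratios <- matrix(NA_real_, nrow = length(iso), ncol = ncol(tpm),
                   dimnames = list(features$name[iso], colnames(tpm)))
  for (r in seq_along(iso)) {
    i <- iso[r]
    ct <- tpm[canon_of[[key[i]]], ]
    ratios[r, ] <- ifelse(ct > 0, tpm[i, ] / ct, NA_real_)
  }
  cat_of <- features$category[iso]
  meds <- do.call(rbind, lapply(unique(cat_of), function(cc) {
    v <- ratios[cat_of == cc, , drop = FALSE]
    obs <- v[!is.na(v) & v > 0]
    data.frame(category = cc, n = length(obs),
               median_ratio = if (length(obs)) stats::median(obs) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(ratios = ratios, medians = meds)
}
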