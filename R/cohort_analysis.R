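#' Positional tag profile of a hairpin
#'
#' Deposits each mapped tag's mass (\code{multiplicity * weight}) base-by-base
#' along its templated span — using the tag's own bases, so substitutions
#' show up at their positions — and into beyond-end bins for 3' non-templated
#' additions. Per-arm histograms of 5' start and templated 3' end positions
#' are accumulated alongside; suitable for sequence-logo rendering.
#'
#' @param annotated Annotated alignment table (rows for one or more hairpins).
#' @param hairpin One-row hairpin \code{data.frame}.
#' @param nta_max Number of beyond-end bins to keep.
#' @return A list of class \code{"positional_profile"}: \code{base_mass}
#'   (4 x (length + nta_max) matrix, rows A,C,G,T), \code{start_hist} and
#'   \code{end_hist} (named lists with one numeric vector per arm),
#'   \code{total_mass}.
#' @export
build_profile <- function(annotated, hairpin, nta_max = 5L) {
  rows <- annotated[annotated$hairpin_id == hairpin$id &
                    annotated$status == "mapped", , drop = FALSE]
  width <- hairpin$length + nta_max
  bm <- matrix(0, nrow = 4L, ncol = width,
               dimnames = list(c("A", "C", "G", "T"), NULL))
  hist0 <- stats::setNames(numeric(hairpin$length), seq_len(hairpin$length))
  sh <- list("5p" = hist0, "3p" = hist0)
  eh <- list("5p" = hist0, "3p" = hist0)
  for (i in seq_len(nrow(rows))) {
    mass <- rows$multiplicity[i] * rows$weight[i]
    core_len <- rows$end[i] - rows$start[i] + 1L
    tag_core <- substr(rows$sequence[i], 1L, core_len)
    pos <- rows$start[i]:rows$end[i]
    base <- strsplit(tag_core, "")[[1L]]
    for (j in seq_along(pos)) bm[base[j], pos[j]] <- bm[base[j], pos[j]] + mass
    if (nzchar(rows$nta_seq[i])) {
      nb <- strsplit(rows$nta_seq[i], "")[[1L]]
      np <- rows$end[i] + seq_along(nb)
      np_ok <- np <= width
      for (j in which(np_ok)) bm[nb[j], np[j]] <- bm[nb[j], np[j]] + mass
    }
    a <- rows$arm[i]
    if (!is.na(a)) {
      sh[[a]][rows$start[i]] <- sh[[a]][rows$start[i]] + mass
      eh[[a]][rows$end[i]] <- eh[[a]][rows$end[i]] + mass
    }
  }
  structure(list(hairpin_id = hairpin$id, base_mass = bm,
                 start_hist = sh, end_hist = eh,
                 total_mass = sum(rows$multiplicity * rows$weight)),
            class = "positional_profile")
}

#' Arm dominance per (hairpin, tissue)
#'
#' Arm totals are the sum of tpm over all features assigned to the arm,
#' averaged over the tissue's samples. Dominance is read from
#' \code{log2(tpm_5p / tpm_3p)}; a hairpin/tissue pair is eligible when both
#' arm totals reach the noise floor.
#'
#' @param tpm Feature-by-sample tpm matrix.
#' @param features Feature metadata aligned to \code{rownames(tpm)}.
#' @param samples Sample sheet.
#' @param floor Noise floor in tpm (default 10).
#' @return \code{data.frame} with one row per (hairpin, tissue):
#'   \code{tpm_5p}, \code{tpm_3p}, \code{log2_ratio} (NA when either arm is
#'   0), \code{dominant}, \code{eligible}.
#' @export
arm_dominance_table <- function(tpm, features, samples, floor = 10) {
  tissues <- unique(samples$tissue)
  hp <- unique(features$hairpin_id[!is.na(features$arm)])
  out <- list()
  for (h in hp) {
    i5 <- !is.na(features$arm) & features$hairpin_id == h & features$arm == "5p"
    i3 <- !is.na(features$arm) & features$hairpin_id == h & features$arm == "3p"
    for (t in tissues) {
      cols <- samples$sample_id[samples$tissue == t]
      t5 <- mean(colSums(tpm[i5, cols, drop = FALSE]))
      t3 <- mean(colSums(tpm[i3, cols, drop = FALSE]))
      lr <- if (t5 > 0 && t3 > 0) log2(t5 / t3) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        hairpin_id = h, tissue = t, tpm_5p = t5, tpm_3p = t3,
        log2_ratio = lr,
        dominant = if (t5 >= t3) "5p" else "3p",
        eligible = t5 >= floor && t3 >= floor,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Detect arm-switching hairpins
#'
#' A hairpin switches arms when, among its eligible tissues (both arms above
#' the noise floor; at least two such tissues required), the dominant arm is
#' not the same everywhere.
#'
#' @param dominance Table from [arm_dominance_table()].
#' @return \code{data.frame(hairpin_id, n_eligible_tissues, switched,
#'   minority_tissues)}; \code{minority_tissues} lists (comma-separated) the
#'   tissues whose dominant arm is in the minority.
#' @export
detect_arm_switching <- function(dominance) {
  el <- dominance[dominance$eligible, , drop = FALSE]
  out <- lapply(unique(dominance$hairpin_id), function(h) {
    rows <- el[el$hairpin_id == h, , drop = FALSE]
    if (nrow(rows) < 2L) {
      return(data.frame(hairpin_id = h, n_eligible_tissues = nrow(rows),
                        switched = FALSE, minority_tissues = "",
                        stringsAsFactors = FALSE))
    }
    tab <- table(rows$dominant)
    switched <- length(tab) > 1L
    minority <- if (switched) {
      arm_min <- names(tab)[which.min(tab)]
      paste(rows$tissue[rows$dominant == arm_min], collapse = ",")
    } else ""
    data.frame(hairpin_id = h, n_eligible_tissues = nrow(rows),
               switched = switched, minority_tissues = minority,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Thresholds for ac-pre-miRNA candidate screening
#'
#' Formalization of the three qualitative hallmarks of AGO2-cleaved
#' pre-miRNA processing: a highly consistent mature 5' end, a silent opposite
#' arm, and a substantial trail of templated 3' extensions (the trimming
#' intermediates).
#'
#' @param modal5_min Minimum fraction of dominant-arm mass sharing the modal
#'   5' start (default 0.9).
#' @param ext_min_frac Minimum fraction of dominant-arm mass carrying a
#'   templated 3' extension (default 0.1).
#' @param ext_min_nt Minimum extension length past the canonical 3' end to
#'   count as an intermediate (default 2 nt).
#' @param min_distinct_ends Minimum number of distinct extended 3' end
#'   positions (default 3).
#' @return A list of class \code{"acpre_thresholds"}.
#' @export
acpre_thresholds <- function(modal5_min = 0.9, ext_min_frac = 0.1,
                             ext_min_nt = 2L, min_distinct_ends = 3L) {
  structure(list(modal5_min = modal5_min, ext_min_frac = ext_min_frac,
                 ext_min_nt = as.integer(ext_min_nt),
                 min_distinct_ends = as.integer(min_distinct_ends)),
            class = "acpre_thresholds")
}

#' Screen hairpins for ac-pre-miRNA candidates
#'
#' Evaluated per tissue, restricted to tissues whose samples span at least
#' two library-prep kits (so kit idiosyncrasies cannot create a candidate on
#' their own). Both arms are tested as the potential dominant arm. A hairpin
#' is a candidate on an arm iff, in at least one eligible tissue: the modal
#' 5' start carries >= \code{modal5_min} of the arm's tag mass, the opposite
#' arm never exceeds the noise floor in any of the tissue's samples, and at
#' least \code{ext_min_frac} of the arm's mass ends >= \code{ext_min_nt}
#' past the canonical 3' end over >= \code{min_distinct_ends} distinct end
#' positions.
#'
#' @param annotated Annotated alignment table.
#' @param tpm Feature-by-sample tpm matrix.
#' @param features Feature metadata aligned to \code{rownames(tpm)}.
#' @param samples Sample sheet.
#' @param annotations Mature annotations.
#' @param floor Noise floor in tpm.
#' @param thresholds [acpre_thresholds()].
#' @return \code{data.frame} with one row per (hairpin, arm, tissue)
#'   evaluated, criterion values and flags, and \code{pass_overall} per
#'   (hairpin, arm) marked on every row of that pair.
#' @export
find_acpre_candidates <- function(annotated, tpm, features, samples,
                                  annotations, floor = 10,
                                  thresholds = acpre_thresholds()) {
  kits_per_tissue <- tapply(samples$prep_kit, samples$tissue,
                            function(k) length(unique(k)))
  tissues <- names(kits_per_tissue)[kits_per_tissue >= 2L]
  out <- list()
  for (h in unique(annotations$hairpin_id)) {
    ann <- annotations[annotations$hairpin_id == h, , drop = FALSE]
    for (arm in intersect(c("5p", "3p"), ann$arm)) {
      can <- ann[ann$arm == arm, , drop = FALSE]
      opp <- setdiff(c("5p", "3p"), arm)
      fi_opp <- !is.na(features$arm) & features$hairpin_id == h &
        features$arm == opp
      for (t in tissues) {
        cols <- samples$sample_id[samples$tissue == t]
        rows <- annotated[annotated$hairpin_id == h &
                          !is.na(annotated$arm) & annotated$arm == arm &
                          annotated$sample_id %in% cols, , drop = FALSE]
        mass <- rows$multiplicity * rows$weight
        total <- sum(mass)
        if (total == 0) next
        start_mass <- tapply(mass, rows$start, sum)
        modal5 <- max(start_mass) / total
        ext <- rows$end >= can$end + thresholds$ext_min_nt
        ext_frac <- sum(mass[ext]) / total
        n_ends <- length(unique(rows$end[ext]))
        opp_max <- if (any(fi_opp)) {
          max(colSums(tpm[fi_opp, cols, drop = FALSE]))
        } else 0
        p1 <- modal5 >= thresholds$modal5_min
        p2 <- opp_max < floor
        p3 <- ext_frac >= thresholds$ext_min_frac &&
          n_ends >= thresholds$min_distinct_ends
        out[[length(out) + 1L]] <- data.frame(
          hairpin_id = h, dominant_arm = arm, tissue = t,
          modal5_fraction = modal5, opposite_arm_max_tpm = opp_max,
          ext_fraction = ext_frac, n_distinct_ext_ends = n_ends,
          pass_modal5 = p1, pass_opposite = p2, pass_extension = p3,
          pass_tissue = p1 && p2 && p3, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(hairpin_id = character(), dominant_arm = character(),
                      tissue = character(), modal5_fraction = numeric(),
                      opposite_arm_max_tpm = numeric(),
                      ext_fraction = numeric(),
                      n_distinct_ext_ends = integer(),
                      pass_modal5 = logical(), pass_opposite = logical(),
                      pass_extension = logical(), pass_tissue = logical(),
                      pass_overall = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  key <- paste(out$hairpin_id, out$dominant_arm)
  pass <- tapply(out$pass_tissue, key, any)
  out$pass_overall <- as.logical(pass[key])
  out
}

#' Resample a tag multiset to a target depth
#'
#' Uniform sampling without replacement from the expanded read multiset;
#' seeded and reproducible. Used to depth-match a deeper library to a
#' shallower one before paired comparisons.
#'
#' @param tags Tag table (\code{sequence}, \code{multiplicity},
#'   \code{sample_id}).
#' @param target_depth Number of reads to keep; must not exceed the current
#'   depth.
#' @param seed RNG seed.
#' @return A collapsed tag table of total multiplicity \code{target_depth}.
#' @export
resample_to_depth <- function(tags, target_depth, seed = 42L) {
  depth <- sum(tags$multiplicity)
  if (target_depth > depth) {
    stop("target depth ", target_depth, " exceeds library depth ", depth)
  }
  if (target_depth == depth) return(tags)
  idx <- rep(seq_len(nrow(tags)), tags$multiplicity)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  keep <- sample(idx, target_depth, replace = FALSE)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  mult <- table(keep)
  out <- tags[as.integer(names(mult)), , drop = FALSE]
  out$multiplicity <- as.integer(mult)
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction:
#' \code{chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}, 1 degree of
#' freedom, upper-tail p.
#'
#' @param a,b,c,d Cell values (row-wise: a,b / c,d); non-negative, with
#'   non-degenerate margins.
#' @return \code{list(chi2, df = 1, p)}.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (min(a + b, c + d, a + c, b + d) <= 0) {
    stop("degenerate margin in 2x2 table")
  }
  ht <- stats::chisq.test(matrix(c(a, c, b, d), 2L), correct = FALSE)
  list(chi2 = unname(ht$statistic), df = 1L, p = unname(ht$p.value))
}

#' Paired-condition ablation report for candidate hairpins
#'
#' Compares candidate-derived expression between a wild-type and a
#' (depth-matched) mutant condition. The group test is a 2x2 chi-square of
#' (candidate-derived mass vs all other mass) by (wild-type vs mutant).
#' Per candidate, canonical mass drives the support class:
#' \code{complete_ablation} (mutant canonical mass 0),
#' \code{strong_reduction} (canonical reduction > \code{reduction_threshold}),
#' \code{isomiR_support} (total isomiR mass in the mutant below
#' \code{reduction_threshold} x wild-type, i.e. expression < 20\% of
#' wild-type under the default 0.8), else \code{unsupported}. Candidates
#' absent from both conditions are excluded with a note.
#'
#' @param wt_counts,mut_counts \code{isomir_counts} for the two conditions
#'   (mutant already resampled to wild-type depth).
#' @param candidates \code{data.frame(hairpin_id, dominant_arm)} of candidate
#'   hairpin arms (e.g. the passing rows of [find_acpre_candidates()]).
#' @param reduction_threshold Reduction fraction separating strong support
#'   from weak (default 0.8).
#' @return A list of class \code{"ablation_report"}: \code{group_test}
#'   (chi2/df/p over the pooled 2x2) and \code{candidates} (per-candidate
#'   masses, reduction fractions and support class).
#' @export
ablation_report <- function(wt_counts, mut_counts, candidates,
                            reduction_threshold = 0.8) {
  arm_mass <- function(counts, h, arm, what) {
    f <- counts$features
    sel <- !is.na(f$arm) & f$hairpin_id == h & f$arm == arm
    sel <- sel & if (what == "canonical") f$category == "canonical"
                 else f$category != "canonical"
    sum(counts$matrix[sel, , drop = FALSE])
  }
  rows <- list()
  cand_wt <- 0; cand_mut <- 0
  for (i in seq_len(nrow(candidates))) {
    h <- candidates$hairpin_id[i]
    arm <- candidates$dominant_arm[i]
    wc <- arm_mass(wt_counts, h, arm, "canonical")
    mc <- arm_mass(mut_counts, h, arm, "canonical")
    wi <- arm_mass(wt_counts, h, arm, "isomiR")
    mi <- arm_mass(mut_counts, h, arm, "isomiR")
    if (wc + mc + wi + mi == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        hairpin_id = h, dominant_arm = arm, wt_canonical = 0,
        mut_canonical = 0, wt_isomir = 0, mut_isomir = 0,
        canonical_reduction = NA_real_, isomir_reduction = NA_real_,
        support_class = "absent", stringsAsFactors = FALSE)
      next
    }
    cand_wt <- cand_wt + wc + wi
    cand_mut <- cand_mut + mc + mi
    cred <- if (wc > 0) 1 - mc / wc else NA_real_
    ired <- if (wi > 0) 1 - mi / wi else NA_real_
    cls <- if (wc > 0 && mc == 0) "complete_ablation"
      else if (!is.na(cred) && cred > reduction_threshold) "strong_reduction"
      else if (!is.na(ired) && ired > reduction_threshold) "isomiR_support"
      else "unsupported"
    rows[[length(rows) + 1L]] <- data.frame(
      hairpin_id = h, dominant_arm = arm, wt_canonical = wc,
      mut_canonical = mc, wt_isomir = wi, mut_isomir = mi,
      canonical_reduction = cred, isomir_reduction = ired,
      support_class = cls, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  wt_total <- sum(wt_counts$matrix)
  mut_total <- sum(mut_counts$matrix)
  gt <- chi_square_2x2(cand_wt, wt_total - cand_wt,
                       cand_mut, mut_total - cand_mut)
  structure(list(group_test = gt, candidates = tab),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("ablation group test: chi2 =", format(x$group_test$chi2, digits = 7),
      "; df = 1; p =", format(x$group_test$p, digits = 4), "\n")
  cat("support classes:\n")
  print(table(x$candidates$support_class))
  invisible(x)
}
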