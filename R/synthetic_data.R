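#' Simulation specification for synthetic small-RNA cohorts
#'
#' Defines the conditions a generated cohort emulates: a multi-tissue,
#' multi-donor, multi-kit library design; a mixture of canonical reads and
#' the isomiR classes over designed proportions; independent per-base
#' substitution sequencing error; 3' adaptor read-through; and designed
#' arm-switching, ac-pre-miRNA-like, and orphan-isomiR hairpins with full
#' ground truth.
#'
#' Default conditions: 20 random hairpins (70-110 nt) each with one 5p and
#' one 3p mature (20-23 nt, >= 8 nt loop); eight libraries over four tissues
#' with two prep kits per tissue at 3,000 reads each; category mixture
#' dominated by canonical reads with 3'-end variants as the most common
#' isomiR class; 0.5% per-base substitution error; full adaptor
#' read-through (short inserts are always sequenced into the adaptor); no
#' decoy-derived reads (at these depths a single decoy read would already
#' dominate any tpm floor, so default libraries are decoy-clean and the
#' floor machinery falls back to its configured default).
#'
#' @param seed Master RNG seed.
#' @param n_hairpins Number of hairpins.
#' @param hairpin_len Length range (min, max).
#' @param mature_len Mature length range (min, max).
#' @param mixture Named category proportions (must sum to 1) over
#'   [isomir_categories()].
#' @param error_rate Per-base substitution error rate.
#' @param adaptor_seq 3' adaptor appended to inserts.
#' @param read_through_prob Probability a read carries the adaptor.
#' @param decoy_fraction Fraction of reads drawn from decoy matures.
#' @param n_decoys Number of decoy mature sequences to generate.
#' @param cohort \code{data.frame(sample_id, tissue, donor_id, prep_kit,
#'   depth)}; \code{NULL} for the default eight-library design.
#' @param n_switch Number of designed arm-switching hairpins.
#' @param switch_tissue Tissue in which designed switches flip arms.
#' @param n_acpre Number of designed ac-pre-miRNA-like hairpins.
#' @param acpre_ext_frac Fraction of ac-pre reads carrying a templated 3'
#'   extension (2-8 nt past the canonical end).
#' @param n_orphan Number of designed orphan-isomiR hairpins (their 3p arm
#'   emits only a +1 3'-end isomiR, never the canonical).
#' @param arm_bias Probability of the dominant (5p) arm for undesigned
#'   hairpins.
#' @return A list of class \code{"sim_spec"}.
#' @export
sim_spec <- function(seed = 1L, n_hairpins = 20L, hairpin_len = c(70L, 110L),
                     mature_len = c(20L, 23L),
                     mixture = c(canonical = 0.45, start_only = 0.08,
                                 end_only = 0.20, substitution_only = 0.07,
                                 shifted = 0.05, nta3 = 0.08, mixed = 0.07),
                     error_rate = 0.005,
                     adaptor_seq = "TCGTATGCCGTCTTCTGCTTG",
                     read_through_prob = 1, decoy_fraction = 0,
                     n_decoys = 8L, cohort = NULL, n_switch = 2L,
                     switch_tissue = "heart", n_acpre = 1L,
                     acpre_ext_frac = 0.25, n_orphan = 1L, arm_bias = 0.8) {
  stopifnot(n_hairpins >= 1L,
            abs(sum(mixture) - 1) < 1e-9,
            all(sort(names(mixture)) == sort(isomir_categories())),
            error_rate >= 0, error_rate <= 1,
            read_through_prob >= 0, read_through_prob <= 1,
            decoy_fraction >= 0, decoy_fraction < 1,
            n_switch + n_acpre + n_orphan <= n_hairpins)
  if (is.null(cohort)) {
    tissues <- c("brain", "heart", "kidney", "liver")
    cohort <- data.frame(
      sample_id = paste0("s", 1:8),
      tissue = rep(tissues, each = 2L),
      donor_id = paste0("d", rep(1:4, each = 2L)),
      prep_kit = rep(c("SREK", "WTAK"), 4L),
      depth = 3000L, stringsAsFactors = FALSE)
  }
  stopifnot(all(cohort$depth >= 1L))
  structure(list(seed = as.integer(seed), n_hairpins = as.integer(n_hairpins),
                 hairpin_len = hairpin_len, mature_len = mature_len,
                 mixture = mixture, error_rate = error_rate,
                 adaptor_seq = adaptor_seq,
                 read_through_prob = read_through_prob,
                 decoy_fraction = decoy_fraction,
                 n_decoys = as.integer(n_decoys), cohort = cohort,
                 n_switch = as.integer(n_switch),
                 switch_tissue = switch_tissue,
                 n_acpre = as.integer(n_acpre),
                 acpre_ext_frac = acpre_ext_frac,
                 n_orphan = as.integer(n_orphan), arm_bias = arm_bias),
            class = "sim_spec")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate reference hairpins, annotations and decoy matures
#'
#' Hairpins are uniform-random sequences with one 5p and one 3p mature
#' separated by a >= 8-nt loop and flanked so that +/- 2-nt shift variants
#' stay inside the hairpin. Decoy matures are generated by rejection so that
#' every decoy prefix of at least the minimum alignable length is more than
#' \code{max_sub} mismatches from every hairpin window (verified by
#' exhaustive scan), guaranteeing decoy-derived reads can never map to a
#' target hairpin under the default aligner.
#'
#' @param spec A [sim_spec()].
#' @param max_sub,min_len Aligner bounds the decoys must be safe against.
#' @return \code{list(hairpins, annotations, decoys)}; the design roles of
#'   each hairpin (switch / acpre / orphan) are in
#'   \code{attr(, "design")}.
#' @export
make_references <- function(spec, max_sub = 2L, min_len = 20L) {
  set.seed(spec$seed)
  hp <- vector("list", spec$n_hairpins)
  ann <- vector("list", spec$n_hairpins)
  for (i in seq_len(spec$n_hairpins)) {
    len5 <- sample(spec$mature_len[1]:spec$mature_len[2], 1L)
    len3 <- sample(spec$mature_len[1]:spec$mature_len[2], 1L)
    lead <- sample(3:6, 1L)
    loop <- sample(9:14, 1L)
    tail <- sample(3:6, 1L)
    L <- lead + len5 + loop + len3 + tail
    seq <- rand_dna(L)
    id <- sprintf("syn-mir-%03d", i)
    hpdf <- hairpin_set(id, seq)
    s5 <- lead + 1L
    s3 <- lead + len5 + loop + 1L
    a5 <- mature_annotation(hpdf, sprintf("syn-miR-%03d", i), s5,
                            s5 + len5 - 1L)
    a3 <- mature_annotation(hpdf, sprintf("syn-miR-%03d", i), s3,
                            s3 + len3 - 1L)
    stopifnot(a5$arm == "5p", a3$arm == "3p")
    hp[[i]] <- hpdf
    ann[[i]] <- rbind(a5, a3)
  }
  hairpins <- do.call(rbind, hp)
  annotations <- do.call(rbind, ann)
  decoys <- character(0)
  tries <- 0L
  while (length(decoys) < spec$n_decoys) {
    tries <- tries + 1L
    if (tries > 200L * spec$n_decoys) {
      stop("could not generate disjoint decoys after ", tries, " tries")
    }
    d <- rand_dna(sample(spec$mature_len[1]:spec$mature_len[2], 1L))
    ok <- all(vapply(min_len:nchar(d), function(l) {
      pre <- substr(d, 1L, l)
      all(vapply(hairpins$sequence,
                 function(h) nchar(h) < l ||
                   min_window_hamming(pre, h) > max_sub, TRUE))
    }, TRUE))
    if (ok) decoys <- c(decoys, d)
  }
  decoy_df <- hairpin_set(sprintf("decoy-%02d", seq_along(decoys)), decoys)
  roles <- rep("plain", spec$n_hairpins)
  k <- 0L
  if (spec$n_switch > 0L) roles[k + seq_len(spec$n_switch)] <- "switch"
  k <- k + spec$n_switch
  if (spec$n_acpre > 0L) roles[k + seq_len(spec$n_acpre)] <- "acpre"
  k <- k + spec$n_acpre
  if (spec$n_orphan > 0L) roles[k + seq_len(spec$n_orphan)] <- "orphan"
  structure(list(hairpins = hairpins, annotations = annotations,
                 decoys = decoy_df),
            design = data.frame(hairpin_id = hairpins$id, role = roles,
                                stringsAsFactors = FALSE))
}

# Shift offsets (from {-2,-1,1,2}) that keep the span inside the hairpin and
# the tag at least min_len long.
allowed_shifts <- function(ann, hp_len, end_side, min_len = 20L) {
  len <- ann$end - ann$start + 1L
  cand <- c(-2L, -1L, 1L, 2L)
  if (end_side) {
    keep <- ann$end + cand <= hp_len & ann$end + cand >= ann$start &
      len + cand >= min_len
  } else {
    keep <- ann$start + cand >= 1L & ann$start + cand <= ann$end &
      len - cand >= min_len
  }
  cand[keep]
}

# Draw one true read (pre-error) for a hairpin arm under a category.
draw_variant <- function(category, ann, hairpin, min_len = 20L) {
  hseq <- hairpin$sequence
  L <- hairpin$length
  s <- ann$start; e <- ann$end
  subs <- ""; nta <- ""
  if (category == "start_only") {
    ch <- allowed_shifts(ann, L, end_side = FALSE, min_len)
    if (length(ch) == 0L) category <- "canonical" else s <- s + sample(ch, 1L)
  } else if (category == "end_only") {
    ch <- allowed_shifts(ann, L, end_side = TRUE, min_len)
    if (length(ch) == 0L) category <- "canonical" else e <- e + sample(ch, 1L)
  } else if (category == "shifted") {
    ch <- c(-2L, -1L, 1L, 2L)
    ch <- ch[s + ch >= 1L & e + ch <= L]
    if (length(ch) == 0L) category <- "canonical" else {
      d <- sample(ch, 1L); s <- s + d; e <- e + d
    }
  }
  tag <- substr(hseq, s, e)
  if (category == "substitution_only" || category == "mixed") {
    if (category == "mixed") {
      ch <- allowed_shifts(ann, L, FALSE, min_len)
      ch <- ch[abs(ch) == 1L]
      if (length(ch) > 0L) s <- s + sample(ch, 1L)
      tag <- substr(hseq, s, e)
    }
    n <- nchar(tag)
    # interior positions only: terminal variants are genuinely ambiguous
    # between substitution and NTA / shift readings
    pos <- sample(2:(n - 1L), 1L)
    ref <- substr(tag, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    substr(tag, pos, pos) <- alt
    subs <- sprintf("%d:%s>%s", s + pos - 1L, ref, alt)
    if (category == "mixed" && s == ann$start) category <- "substitution_only"
  } else if (category == "nta3") {
    k <- sample(1:3, 1L)
    add <- character(k)
    for (j in seq_len(k)) {
      tmpl <- if (e + j <= L) substr(hseq, e + j, e + j) else ""
      add[j] <- sample(setdiff(c("A", "C", "G", "T"), tmpl), 1L)
    }
    nta <- paste(add, collapse = "")
    tag <- paste0(tag, nta)
  }
  list(category = category, start = s, end = e, subs = subs, nta_seq = nta,
       sequence = tag)
}

apply_seq_error <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(x) {
    n <- nchar(x)
    hit <- which(stats::runif(n) < rate)
    for (p in hit) {
      substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(x, p, p)), 1L)
    }
    x
  }, "", USE.NAMES = FALSE)
}

#' Simulate the reads of one sample with ground truth
#'
#' Reads are drawn per the category mixture with tissue-dependent arm biases
#' for designed switch hairpins, canonical-start/extension-trail profiles for
#' designed ac-pre hairpins, forced +1 3'-end isomiRs on designed orphan
#' arms, optional decoy-derived reads, sequencing error and adaptor
#' read-through. Truth is recorded before error injection.
#'
#' @param spec [sim_spec()].
#' @param refs References from [make_references()].
#' @param sample_row One row of \code{spec$cohort}.
#' @param seed Seed for this sample's draws.
#' @return \code{list(reads, truth)}: \code{reads} is
#'   \code{data.frame(read_id, sample_id, sequence)} (sequence includes any
#'   adaptor), \code{truth} one row per read with span, substitutions, NTA,
#'   category and rendered name (NA for decoy reads).
#' @export
simulate_reads <- function(spec, refs, sample_row, seed) {
  set.seed(seed)
  design <- attr(refs, "design")
  hp <- refs$hairpins
  depth <- sample_row$depth
  reads <- character(depth)
  truth <- vector("list", depth)
  cats <- names(spec$mixture)
  for (r in seq_len(depth)) {
    if (spec$decoy_fraction > 0 && stats::runif(1) < spec$decoy_fraction) {
      d <- refs$decoys[sample(nrow(refs$decoys), 1L), ]
      reads[r] <- d$sequence
      truth[[r]] <- data.frame(
        sample_id = sample_row$sample_id, hairpin_id = NA_character_,
        arm = NA_character_, start = NA_integer_, end = NA_integer_,
        subs = NA_character_, nta_seq = NA_character_, category = "decoy",
        name = NA_character_, stringsAsFactors = FALSE)
      next
    }
    i <- sample(spec$n_hairpins, 1L)
    role <- design$role[i]
    hprow <- hp[i, , drop = FALSE]
    ann <- refs$annotations[refs$annotations$hairpin_id == hprow$id, ,
                            drop = FALSE]
    if (role == "acpre") {
      a <- ann[ann$arm == "5p", , drop = FALSE]
      if (stats::runif(1) < spec$acpre_ext_frac) {
        ext <- sample(2:8, 1L)
        v <- list(category = "end_only", start = a$start, end = a$end + ext,
                  subs = "", nta_seq = "",
                  sequence = substr(hprow$sequence, a$start, a$end + ext))
      } else {
        v <- list(category = "canonical", start = a$start, end = a$end,
                  subs = "", nta_seq = "", sequence = a$sequence)
      }
    } else {
      p5 <- spec$arm_bias
      if (role == "switch" && sample_row$tissue == spec$switch_tissue) {
        p5 <- 1 - spec$arm_bias
      }
      arm <- if (stats::runif(1) < p5) "5p" else "3p"
      a <- ann[ann$arm == arm, , drop = FALSE]
      if (role == "orphan" && arm == "3p") {
        v <- list(category = "end_only", start = a$start, end = a$end + 1L,
                  subs = "", nta_seq = "",
                  sequence = substr(hprow$sequence, a$start, a$end + 1L))
      } else {
        v <- draw_variant(sample(cats, 1L, prob = spec$mixture), a, hprow)
      }
    }
    reads[r] <- v$sequence
    truth[[r]] <- data.frame(
      sample_id = sample_row$sample_id, hairpin_id = hprow$id, arm = a$arm,
      start = v$start, end = v$end, subs = v$subs, nta_seq = v$nta_seq,
      category = v$category,
      name = render_name(v$start, v$end, v$subs, v$nta_seq, a, v$category),
      stringsAsFactors = FALSE)
  }
  with_adaptor <- stats::runif(depth) < spec$read_through_prob
  reads[with_adaptor] <- paste0(reads[with_adaptor], spec$adaptor_seq)
  reads <- apply_seq_error(reads, spec$error_rate)
  truth <- do.call(rbind, truth)
  truth$read_id <- sprintf("%s_r%06d", sample_row$sample_id, seq_len(depth))
  data.frame_reads <- data.frame(read_id = truth$read_id,
                                 sample_id = sample_row$sample_id,
                                 sequence = reads, stringsAsFactors = FALSE)
  list(reads = data.frame_reads,
       truth = truth[, c("read_id", setdiff(names(truth), "read_id"))])
}

#' Simulate a full multi-sample cohort fixture
#'
#' Generates references plus reads and truth for every sample in the spec's
#' cohort design. With \code{out_dir} set, the fixture is written in the
#' standard plain-text formats (\code{references.fasta},
#' \code{annotations.tsv}, \code{decoys.fasta}, \code{samples.tsv},
#' \code{reads/<sample>.fastq}, \code{truth.tsv}) plus a \code{manifest.yaml}
#' carrying the seed. Byte-identical across runs with the same spec.
#'
#' @param spec [sim_spec()].
#' @param out_dir Optional fixture directory.
#' @return \code{list(hairpins, annotations, decoys, samples, tags, truth,
#'   design)}; \code{tags} is the collapsed per-sample tag table ready for
#'   [align_tags()].
#' @export
simulate_cohort <- function(spec, out_dir = NULL) {
  refs <- make_references(spec)
  per <- lapply(seq_len(nrow(spec$cohort)), function(j) {
    simulate_reads(spec, refs, spec$cohort[j, , drop = FALSE],
                   seed = spec$seed + 1000L * j)
  })
  reads <- do.call(rbind, lapply(per, `[[`, "reads"))
  truth <- do.call(rbind, lapply(per, `[[`, "truth"))
  tags <- do.call(rbind, lapply(split(reads, reads$sample_id), function(g) {
    collapse_tags(g$sequence, rep(1L, nrow(g)), g$sample_id[1L])
  }))
  rownames(tags) <- NULL
  samples <- spec$cohort[, c("sample_id", "tissue", "donor_id", "prep_kit")]
  out <- list(hairpins = refs$hairpins, annotations = refs$annotations,
              decoys = refs$decoys, samples = samples, reads = reads,
              tags = tags, truth = truth, design = attr(refs, "design"))
  if (!is.null(out_dir)) write_fixture(out, spec, out_dir)
  out
}

write_fixture <- function(cohort, spec, out_dir) {
  dir.create(file.path(out_dir, "reads"), recursive = TRUE,
             showWarnings = FALSE)
  write_hairpin_fasta(cohort$hairpins, file.path(out_dir, "references.fasta"))
  write_hairpin_fasta(cohort$decoys, file.path(out_dir, "decoys.fasta"))
  utils::write.table(cohort$annotations[, c("hairpin_id", "mature_name",
                                            "start", "end")],
                     file.path(out_dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$samples, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  for (s in unique(cohort$reads$sample_id)) {
    g <- cohort$reads[cohort$reads$sample_id == s, , drop = FALSE]
    fq <- rbind(paste0("@", g$read_id), g$sequence, "+",
                vapply(nchar(g$sequence),
                       function(n) strrep("I", n), ""))
    writeLines(as.vector(fq), file.path(out_dir, "reads",
                                        paste0(s, ".fastq")))
  }
  yaml::write_yaml(list(seed = spec$seed,
                        n_hairpins = spec$n_hairpins,
                        samples = cohort$samples$sample_id),
                   file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
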