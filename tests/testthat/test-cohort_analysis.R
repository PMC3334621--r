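test_that("positional profiles conserve mass and carry tag bases", {
  set.seed(61)
  hp <- make_hairpin_df("h", rand_seq(100))
  ann <- rbind(locate_mature("m", substr(hp$sequence, 5, 26), hp),
               locate_mature("m", substr(hp$sequence, 60, 80), hp))
  canon <- substr(hp$sequence, 60, 80)
  sub_tag <- canon
  ref77 <- substr(hp$sequence, 77, 77)
  alt77 <- setdiff(c("A", "C", "G", "T"), ref77)[1]
  substr(sub_tag, 18, 18) <- alt77
  rows <- data.frame(
    sequence = c(canon, sub_tag), sample_id = "s1",
    multiplicity = c(4L, 2L), strategy = "adaptor_trimmed",
    status = "mapped", hairpin_id = "h", start = 60L, end = 80L,
    aligned_len = 21L, n_sub = c(0L, 1L),
    subs = c("", paste0("77:", ref77, ">", alt77)), nta_seq = "",
    weight = 1, arm = "3p", stringsAsFactors = FALSE)
  pr <- build_profile(rows, hp)
  # single canonical span: every canonical position carries at least mass 4
  expect_true(all(colSums(pr$base_mass)[60:80] == 6))
  expect_equal(unname(pr$base_mass[alt77, 77]), 2)
  expect_equal(unname(pr$base_mass[ref77, 77]), 4)
  expect_equal(sum(pr$start_hist[["3p"]]), 6)
  expect_equal(sum(pr$end_hist[["3p"]]), 6)
  expect_equal(pr$total_mass, 6)
  # total positional mass equals tag mass x span length
  expect_equal(sum(pr$base_mass), 6 * 21)
})

test_that("arm dominance arithmetic and eligibility", {
  feats <- data.frame(name = c("a5", "a3"), hairpin_id = "h",
                      arm = c("5p", "3p"), category = "canonical",
                      stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("s1", "s2"), tissue = "kidney",
                        donor_id = "d", prep_kit = c("K1", "K2"),
                        stringsAsFactors = FALSE)
  tpm <- rbind(a5 = c(s1 = 100, s2 = 100), a3 = c(10, 10))
  d <- arm_dominance_table(tpm, feats, samples, floor = 10)
  expect_equal(d$dominant, "5p")
  expect_equal(d$log2_ratio, log2(10), tolerance = 1e-12)
  expect_true(d$eligible)

  tpm2 <- rbind(a5 = c(s1 = 100, s2 = 100), a3 = c(5, 5))
  expect_false(arm_dominance_table(tpm2, feats, samples, floor = 10)$eligible)

  # arm totals equal hand-summed feature tpm
  feats3 <- rbind(feats, data.frame(name = "i5", hairpin_id = "h", arm = "5p",
                                    category = "end_only"))
  tpm3 <- rbind(a5 = c(s1 = 40, s2 = 60), a3 = c(20, 20), i5 = c(10, 30))
  d3 <- arm_dominance_table(tpm3, feats3, samples, floor = 10)
  expect_equal(d3$tpm_5p, mean(c(40 + 10, 60 + 30)))
  expect_equal(d3$tpm_3p, 20)
})

test_that("arm switching needs two eligible tissues and a flipped arm", {
  dom <- data.frame(
    hairpin_id = rep(c("h1", "h2", "h3"), each = 3),
    tissue = rep(c("t1", "t2", "t3"), 3),
    tpm_5p = 0, tpm_3p = 0, log2_ratio = 0,
    dominant = c("5p", "5p", "3p",    # h1 switches
                 "5p", "5p", "5p",    # h2 constant
                 "5p", "3p", "3p"),   # h3 switches but t1 ineligible
    eligible = c(TRUE, TRUE, TRUE,
                 TRUE, TRUE, TRUE,
                 FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  sw <- detect_arm_switching(dom)
  expect_equal(sw$switched[sw$hairpin_id == "h1"], TRUE)
  expect_equal(sw$minority_tissues[sw$hairpin_id == "h1"], "t3")
  expect_equal(sw$switched[sw$hairpin_id == "h2"], FALSE)
  expect_equal(sw$switched[sw$hairpin_id == "h3"], FALSE)

  # invariance to tissue order
  sw2 <- detect_arm_switching(dom[sample(nrow(dom)), ])
  expect_equal(sw2[order(sw2$hairpin_id), ]$switched,
               sw[order(sw$hairpin_id), ]$switched)
})

test_that("ac-pre screening keys on modal 5' start, silent opposite arm and
          an extension trail", {
  set.seed(71)
  hp <- make_hairpin_df("h", rand_seq(100))
  ann <- rbind(locate_mature("m", substr(hp$sequence, 5, 26), hp),
               locate_mature("m", substr(hp$sequence, 60, 81), hp))
  can5 <- ann[ann$arm == "5p", ]
  samples <- data.frame(sample_id = c("s1", "s2"), tissue = "embryo",
                        donor_id = "d", prep_kit = c("K1", "K2"),
                        stringsAsFactors = FALSE)
  mk_rows <- function(starts, ends, mult, sample) data.frame(
    sequence = sprintf("seq%d", seq_along(starts)), sample_id = sample,
    multiplicity = mult, strategy = "adaptor_trimmed", status = "mapped",
    hairpin_id = "h", start = starts, end = ends,
    aligned_len = ends - starts + 1L, n_sub = 0L, subs = "", nta_seq = "",
    weight = 1, arm = "5p", stringsAsFactors = FALSE)
  # 75% canonical, 25% spread over 4 distinct extended ends (+2..+5)
  ann_rows <- rbind(mk_rows(rep(5L, 5), c(26L, 26L, 26L, 26L, 26L) ,
                            c(60L, 60L, 60L, 60L, 60L), "s1"),
                    mk_rows(rep(5L, 4), 26L + 2:5, rep(25L, 4), "s1"),
                    mk_rows(rep(5L, 5), rep(26L, 5), rep(60L, 5), "s2"),
                    mk_rows(rep(5L, 4), 26L + 2:5, rep(25L, 4), "s2"))
  feats <- data.frame(name = "x5", hairpin_id = "h", arm = "5p",
                      category = "canonical", stringsAsFactors = FALSE)
  tpm <- rbind(x5 = c(s1 = 1000, s2 = 1000))
  res <- find_acpre_candidates(ann_rows, tpm, feats, samples, ann, floor = 10)
  r5 <- res[res$dominant_arm == "5p", ]
  expect_true(all(r5$pass_overall))
  expect_equal(r5$modal5_fraction[1], 1)
  expect_equal(r5$ext_fraction[1], 0.25)
  expect_equal(r5$n_distinct_ext_ends[1], 4L)

  # two equal 5' starts: only the modal-start criterion fails
  half <- rbind(mk_rows(rep(5L, 2), rep(26L, 2), rep(100L, 2), "s1"),
                mk_rows(rep(6L, 2), rep(26L, 2), rep(100L, 2), "s1"),
                mk_rows(rep(5L, 4), 26L + 2:5, rep(25L, 4), "s1"))
  res2 <- find_acpre_candidates(half, tpm, feats, samples, ann, floor = 10)
  r2 <- res2[res2$dominant_arm == "5p" & res2$tissue == "embryo", ]
  expect_false(r2$pass_modal5[1])
  expect_true(r2$pass_opposite[1])
  expect_true(r2$pass_extension[1])
  expect_false(r2$pass_overall[1])

  # expressed opposite arm disqualifies
  feats3 <- rbind(feats, data.frame(name = "x3", hairpin_id = "h",
                                    arm = "3p", category = "canonical"))
  tpm3 <- rbind(x5 = c(s1 = 1000, s2 = 1000), x3 = c(s1 = 500, s2 = 500))
  res3 <- find_acpre_candidates(ann_rows, tpm3, feats3, samples, ann,
                                floor = 10)
  expect_false(any(res3$pass_overall[res3$dominant_arm == "5p"]))
})

test_that("depth resampling is seeded, exact and proportion-preserving", {
  tags <- data.frame(sequence = c("AAAA", "CCCC", "GGGG"),
                     multiplicity = c(600L, 300L, 100L), sample_id = "s",
                     stringsAsFactors = FALSE)
  expect_identical(resample_to_depth(tags, 1000L), tags)
  expect_error(resample_to_depth(tags, 2000L), "exceeds")

  r1 <- resample_to_depth(tags, 400L, seed = 7)
  r2 <- resample_to_depth(tags, 400L, seed = 7)
  expect_identical(r1, r2)
  expect_equal(sum(r1$multiplicity), 400L)

  # expectation of each tag's count ~ multiplicity x target/depth
  draws <- sapply(1:100, function(s) {
    r <- resample_to_depth(tags, 400L, seed = s)
    r$multiplicity[match("AAAA", r$sequence)]
  })
  exp_mean <- 600 * 400 / 1000
  sd_bin <- sqrt(400 * 0.6 * 0.4)
  expect_lt(abs(mean(draws) - exp_mean), 3 * sd_bin / sqrt(100))
})

test_that("2x2 chi-square matches the closed form and a distribution oracle", {
  z <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(z$chi2, 0)
  expect_equal(z$p, 1)

  z2 <- chi_square_2x2(10, 20, 20, 10)
  expect_equal(z2$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(z2$df, 1L)

  set.seed(81)
  prev_chi <- NULL
  for (i in 1:50) {
    abcd <- as.numeric(sample(1:500, 4))
    a <- abcd[1]; b <- abcd[2]; c <- abcd[3]; d <- abcd[4]
    n <- a + b + c + d
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    z <- chi_square_2x2(a, b, c, d)
    expect_equal(z$chi2, closed, tolerance = 1e-10)
    expect_equal(z$p, stats::pchisq(closed, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_error(chi_square_2x2(0, 0, 3, 4), "degenerate")
})

test_that("ablation classes follow the reduction thresholds", {
  feats <- function(h) data.frame(
    name = paste0(h, c("-c", "-i")), hairpin_id = h, arm = "5p",
    category = c("canonical", "end_only"), stringsAsFactors = FALSE)
  fmeta <- do.call(rbind, lapply(c("h1", "h2", "h3", "h4", "h5"), feats))
  mk <- function(vals) {
    m <- matrix(vals, ncol = 1, dimnames = list(fmeta$name, "s"))
    structure(list(matrix = m, features = fmeta,
                   samples = data.frame(sample_id = "s"),
                   lib_size = colSums(m)), class = "isomir_counts")
  }
  # h5 is background (not a candidate) so the group 2x2 has other-mass
  #            h1-c h1-i h2-c h2-i h3-c h3-i h4-c h4-i h5-c h5-i
  wt <- mk(c(1000, 200, 1000, 200, 1000, 500, 1000, 200, 2000, 100))
  mut <- mk(c(   0,   0,  150,  30, 1000,  50,  900, 180, 2000, 100))
  cand <- data.frame(hairpin_id = c("h1", "h2", "h3", "h4"),
                     dominant_arm = "5p", stringsAsFactors = FALSE)
  rep <- ablation_report(wt, mut, cand)
  cls <- setNames(rep$candidates$support_class, rep$candidates$hairpin_id)
  expect_equal(unname(cls["h1"]), "complete_ablation")
  expect_equal(unname(cls["h2"]), "strong_reduction")  # reduction 0.85
  expect_equal(unname(cls["h3"]), "isomiR_support")    # isomiR down 90%
  expect_equal(unname(cls["h4"]), "unsupported")
  expect_equal(rep$candidates$canonical_reduction[
    rep$candidates$hairpin_id == "h2"], 0.85)
  expect_equal(rep$group_test$df, 1L)
  expect_lt(rep$group_test$p, 0.05)
})
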