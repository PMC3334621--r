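test_that("hamming_scan reports all bounded-mismatch offsets with details", {
  fx <- fixture_mir143()
  hp <- fx$hairpin
  tag <- substr(hp$sequence, 10, 31)
  h <- hamming_scan(tag, hp, 2)
  expect_true(any(h$start == 10 & h$end == 31 & h$n_sub == 0))

  # 3 mismatches at the only near-match offset -> empty at max_sub 2
  tag3 <- tag
  for (p in c(3, 9, 15)) {
    substr(tag3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(tag3, p, p))[1]
  }
  h3 <- hamming_scan(tag3, hp, 2)
  expect_false(any(h3$start == 10))

  # tag longer than hairpin is an empty result, not an error
  expect_equal(nrow(hamming_scan(strrep("A", 200), hp, 2)), 0)

  # full agreement with the brute-force oracle on random pairs
  set.seed(5)
  for (i in 1:50) {
    t <- rand_seq(22)
    s <- rand_seq(100)
    got <- hamming_scan(t, s, 2)
    exp <- oracle_hamming(t, s, 2)
    expect_equal(got$start, exp$start)
    expect_equal(got$n_sub, exp$n_sub)
  }
})

test_that("substitution details are encoded in hairpin coordinates", {
  fx <- fixture_mir143()
  tag <- substr(fx$hairpin$sequence, 60, 80)
  ref <- substr(tag, 18, 18)  # hairpin pos 77
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  substr(tag, 18, 18) <- alt
  h <- hamming_scan(tag, fx$hairpin, 2)
  row <- h[h$start == 60, ]
  expect_equal(row$n_sub, 1L)
  expect_equal(row$subs, paste0("77:", ref, ">", alt))
})

test_that("adaptor trimming finds the 5'-most qualifying overlap", {
  p <- aligner_params(adaptor_seq = ADAPTOR)
  set.seed(2)
  insert <- rand_seq(22)

  r <- trim_adaptor(paste0(insert, ADAPTOR), p)
  expect_true(r$found)
  expect_equal(r$tag, insert)

  # only a 6-nt adaptor prefix present at the 3' end
  r2 <- trim_adaptor(paste0(insert, substr(ADAPTOR, 1, 6)), p)
  expect_true(r2$found)
  expect_equal(r2$tag, insert)

  # no adaptor content at all: sequence unchanged, flag false
  clean <- gsub("T", "A", rand_seq(30))
  r3 <- trim_adaptor(clean, p)
  expect_false(r3$found)
  expect_equal(r3$tag, clean)

  # one mismatch inside a long overlap is tolerated (<= 10%)
  noisy <- ADAPTOR
  substr(noisy, 4, 4) <- setdiff(c("A", "C", "G", "T"), substr(noisy, 4, 4))[1]
  r4 <- trim_adaptor(paste0(insert, noisy), p)
  expect_true(r4$found)
  expect_equal(r4$tag, insert)
})

test_that("recursive mapping enforces the minimum length", {
  fx <- fixture_mir143()
  p <- aligner_params()
  r19 <- recursive_map(substr(fx$hairpin$sequence, 30, 48), fx$hairpin, p)
  expect_equal(r19$status, "unmapped")
  r20 <- recursive_map(substr(fx$hairpin$sequence, 30, 49), fx$hairpin, p)
  expect_equal(r20$status, "mapped")
  expect_equal(r20$aligned_len, 20L)
})

test_that("recursive mapping trims a corrupted 3' end to the longest
          tolerable length", {
  fx <- fixture_mir143()
  hp <- fx$hairpin
  # first 20 bases exact; last 5 complemented, so length L carries L - 20
  # mismatches at the true offset: within default tolerance the longest
  # mapped length is 22 (2 substitutions), and with no tolerance the tag
  # trims all the way to its clean 20-nt core
  core <- substr(hp$sequence, 30, 49)
  tail <- chartr("ACGT", "TGCA", substr(hp$sequence, 50, 54))
  tag <- paste0(core, tail)
  r <- recursive_map(tag, hp, aligner_params())
  expect_equal(r$status, "mapped")
  expect_equal(r$aligned_len, 22L)
  expect_true(any(r$placements$start == 30 & r$placements$n_sub == 2))
  ora <- oracle_recursive(tag, hp, aligner_params())
  expect_equal(r$aligned_len, ora$aligned_len)

  r0 <- recursive_map(tag, hp, aligner_params(max_sub = 0))
  expect_equal(r0$aligned_len, 20L)
  expect_true(any(r0$placements$start == 30 & r0$placements$n_sub == 0))
})

test_that("equal-best multi-maps share fractional weight", {
  set.seed(3)
  shared <- rand_seq(22)
  hp <- make_hairpin_df(c("h1", "h2"),
                        c(paste0(rand_seq(30), shared, rand_seq(30)),
                          paste0(rand_seq(40), shared, rand_seq(20))))
  r <- recursive_map(shared, hp, aligner_params())
  expect_equal(nrow(r$placements), 2)
  expect_equal(r$placements$weight, c(0.5, 0.5))
  expect_equal(r$placements$hairpin_id, c("h1", "h2"))  # deterministic order

  # minimal-substitution placements displace worse ones
  pl <- data.frame(hairpin_id = c("h1", "h2"), start = c(5L, 9L),
                   end = c(26L, 30L), n_sub = c(2L, 0L),
                   subs = c("6:A>C;8:G>T", ""), stringsAsFactors = FALSE)
  best <- resolve_multimap(pl)
  expect_equal(best$hairpin_id, "h2")
  expect_equal(best$weight, 1)

  # weights always sum to 1 over random multimap sets
  set.seed(8)
  for (i in 1:200) {
    k <- sample(1:6, 1)
    pl <- data.frame(hairpin_id = paste0("h", 1:k),
                     start = sample(50, k, replace = TRUE), end = 0L,
                     n_sub = sample(0:2, k, replace = TRUE), subs = "",
                     stringsAsFactors = FALSE)
    pl$end <- pl$start + 21L
    expect_equal(sum(resolve_multimap(pl)$weight), 1)
  }
})

test_that("NTA peeling prefers fewer substitutions, then the longer core", {
  fx <- fixture_mir143()
  hp <- fx$hairpin
  canon <- substr(hp$sequence, 60, 80)
  p <- aligner_params(adaptor_seq = ADAPTOR)

  # canonical + one base differing from the templated base at 81 -> NTA
  tmpl81 <- substr(hp$sequence, 81, 81)
  added <- setdiff(c("A", "C", "G", "T"), tmpl81)[1]
  sp <- extract_nta(paste0(canon, added), hp, p)
  expect_equal(sp$nta_seq, added)
  expect_equal(sp$placements$start, 60L)
  expect_equal(sp$placements$end, 80L)
  expect_equal(sp$placements$n_sub, 0L)

  # exact canonical: no NTA
  sp0 <- extract_nta(canon, hp, p)
  expect_equal(sp0$nta_seq, "")
  expect_equal(sp0$placements$end, 80L)

  # two bases matching the template: end-extended templated placement
  sp2 <- extract_nta(paste0(canon, substr(hp$sequence, 81, 82)), hp, p)
  expect_equal(sp2$nta_seq, "")
  expect_equal(sp2$placements$end, 82L)

  # the split equals an exhaustive enumeration over (core, suffix) splits
  tag <- paste0(canon, added)
  best <- NULL
  for (k in 0:min(5, nchar(tag) - 20)) {
    core <- substr(tag, 1, nchar(tag) - k)
    hits <- oracle_hamming(core, hp$sequence, 2)
    if (k > 0 && nrow(hits) > 0) {
      ok <- vapply(seq_len(nrow(hits)), function(i) {
        e <- hits$start[i] + nchar(core) - 1
        suf <- strsplit(substr(tag, nchar(core) + 1, nchar(tag)), "")[[1]]
        all(e + seq_along(suf) > 100 |
              suf != strsplit(substr(hp$sequence, e + 1, e + k), "")[[1]])
      }, TRUE)
      hits <- hits[ok, , drop = FALSE]
    }
    if (nrow(hits) > 0 && (is.null(best) || min(hits$n_sub) < best$n_sub)) {
      best <- list(k = k, n_sub = min(hits$n_sub))
    }
  }
  expect_equal(nchar(sp$nta_seq), best$k)
  expect_equal(min(sp$placements$n_sub), best$n_sub)
})

test_that("adaptor-trimmed mapping places the exact trimmed length", {
  fx <- fixture_mir143()
  hp <- fx$hairpin
  p <- aligner_params(adaptor_seq = ADAPTOR)
  canon <- substr(hp$sequence, 60, 80)

  r <- adaptor_trim_map(paste0(canon, ADAPTOR), hp, p)
  expect_equal(r$status, "mapped")
  expect_equal(r$aligned_len, 21L)
  expect_equal(r$placements$start, 60L)
  expect_equal(r$strategy, "adaptor_trimmed")

  # 1-nt 3' NTA survives trimming as nta_seq
  tmpl81 <- substr(hp$sequence, 81, 81)
  added <- setdiff(c("A", "C", "G", "T"), tmpl81)[1]
  r2 <- adaptor_trim_map(paste0(canon, added, ADAPTOR), hp, p)
  expect_equal(r2$nta_seq, added)
  expect_equal(r2$placements$end, 80L)

  # no adaptor -> unusable by this strategy
  r3 <- adaptor_trim_map(gsub("T", "A", rand_seq(40)), hp, p)
  expect_equal(r3$status, "unusable")
})

test_that("recursive mapping equals the brute-force (length, offset) oracle", {
  set.seed(17)
  p <- aligner_params()
  for (i in 1:120) {
    hp <- make_hairpin_df(paste0("h", 1:2), c(rand_seq(90), rand_seq(110)))
    tag <- if (i %% 2 == 0) {
      # planted: substring with up to 3 mutations
      s <- sample(60, 1)
      t <- substr(hp$sequence[1], s, s + 21)
      for (m in seq_len(sample(0:3, 1))) {
        q <- sample(nchar(t), 1)
        substr(t, q, q) <- sample(c("A", "C", "G", "T"), 1)
      }
      t
    } else rand_seq(22)
    got <- recursive_map(tag, hp, p)
    exp <- oracle_recursive(tag, hp, p)
    if (is.null(exp)) {
      expect_equal(got$status, "unmapped")
    } else {
      expect_equal(got$status, "mapped")
      expect_equal(got$aligned_len, exp$aligned_len)
      expect_equal(got$placements$hairpin_id, exp$placements$hairpin_id)
      expect_equal(got$placements$start, exp$placements$start)
      expect_equal(got$placements$n_sub, exp$placements$n_sub)
    }
  }
})

test_that("alignment results are deterministic and conserve read accounting", {
  co <- shared_cohort()$cohort
  p <- aligner_params(adaptor_seq = ADAPTOR)
  sub <- co$tags[co$tags$sample_id == co$samples$sample_id[1], ][1:40, ]
  a1 <- align_tags(sub, co$hairpins, p)
  a2 <- align_tags(sub, co$hairpins, p)
  expect_identical(a1, a2)
  # per-tag weights sum to 1 for mapped tags
  w <- tapply(a1$weight[a1$status == "mapped"],
              a1$sequence[a1$status == "mapped"], sum)
  expect_true(all(abs(w - 1) < 1e-12))
  # every input tag appears (mapped or not)
  expect_setequal(unique(a1$sequence), sub$sequence)
})
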