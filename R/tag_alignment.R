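#' Aligner parameter set
#'
#' Defaults follow the operating point used throughout the package: up to 2
#' nucleotide substitutions and no indels, a 20-nt minimum matched length
#' (specificity collapses for shorter tags), 3'-only recursive trimming in
#' 1-nt steps, and at most 5 nt of 3' non-templated addition.
#'
#' @param max_sub Maximum substitutions per placement.
#' @param min_len Minimum aligned tag length in nt.
#' @param trim_step Bases removed from the 3' end per recursive-trim round.
#' @param nta_max Maximum 3' non-templated addition length.
#' @param adaptor_seq 3' adaptor sequence (DNA; required for the
#'   adaptor-trimmed strategy).
#' @param adaptor_min_overlap Minimum read/adaptor overlap to call the adaptor.
#' @param adaptor_max_mismatch_frac Maximum mismatch fraction in the overlap.
#' @return A list of class \code{"aligner_params"}.
#' @export
aligner_params <- function(max_sub = 2L, min_len = 20L, trim_step = 1L,
                           nta_max = 5L, adaptor_seq = NULL,
                           adaptor_min_overlap = 5L,
                           adaptor_max_mismatch_frac = 0.1) {
  stopifnot(max_sub >= 0L, min_len >= 1L, trim_step >= 1L, nta_max >= 0L,
            adaptor_max_mismatch_frac >= 0, adaptor_max_mismatch_frac < 0.5)
  if (!is.null(adaptor_seq)) adaptor_seq <- normalize_dna(adaptor_seq)
  structure(list(max_sub = as.integer(max_sub), min_len = as.integer(min_len),
                 trim_step = as.integer(trim_step), nta_max = as.integer(nta_max),
                 adaptor_seq = adaptor_seq,
                 adaptor_min_overlap = as.integer(adaptor_min_overlap),
                 adaptor_max_mismatch_frac = adaptor_max_mismatch_frac),
            class = "aligner_params")
}

.empty_placements <- data.frame(
  hairpin_id = character(), start = integer(), end = integer(),
  n_sub = integer(), subs = character(), stringsAsFactors = FALSE)

empty_placements <- function() .empty_placements

# Substitution list at a fixed offset, encoded "pos:ref>alt;..." in hairpin
# coordinates. Assumes the window fits inside the hairpin.
sub_string <- function(tag_seq, hairpin_seq, start) {
  n <- nchar(tag_seq)
  ref <- utf8ToInt(substr(hairpin_seq, start, start + n - 1L))
  alt <- utf8ToInt(tag_seq)
  idx <- which(ref != alt)
  if (length(idx) == 0L) return("")
  paste(sprintf("%d:%s>%s", start + idx - 1L,
                strsplit(intToUtf8(ref[idx]), "")[[1L]],
                strsplit(intToUtf8(alt[idx]), "")[[1L]]),
        collapse = ";")
}

#' Substitution-only placement scan of a tag against one hairpin
#'
#' Returns every offset where the tag matches the hairpin with at most
#' \code{max_sub} mismatches (Hamming distance; no indels), together with the
#' substitution list in hairpin coordinates. A tag longer than the hairpin
#' yields an empty result.
#'
#' @param tag_seq Tag sequence (DNA).
#' @param hairpin One-row hairpin \code{data.frame}, or a plain DNA string.
#' @param max_sub Maximum substitutions.
#' @return \code{data.frame} with columns \code{hairpin_id}, \code{start},
#'   \code{end}, \code{n_sub}, \code{subs} (encoded \code{"pos:ref>alt;..."}).
#' @export
hamming_scan <- function(tag_seq, hairpin, max_sub = 2L) {
  if (is.data.frame(hairpin)) {
    hp_id <- hairpin$id
    hp_seq <- hairpin$sequence
  } else {
    hp_id <- "hairpin"
    hp_seq <- as.character(hairpin)
  }
  n <- nchar(tag_seq)
  if (n > nchar(hp_seq)) return(empty_placements())
  m <- Biostrings::matchPattern(Biostrings::DNAString(tag_seq),
                                Biostrings::DNAString(hp_seq),
                                max.mismatch = max_sub, with.indels = FALSE)
  st <- Biostrings::start(m)
  st <- st[st >= 1L & st + n - 1L <= nchar(hp_seq)]
  if (length(st) == 0L) return(empty_placements())
  subs <- vapply(st, function(s) sub_string(tag_seq, hp_seq, s), "")
  data.frame(hairpin_id = hp_id, start = as.integer(st),
             end = as.integer(st + n - 1L),
             n_sub = ifelse(subs == "", 0L,
                            lengths(regmatches(subs, gregexpr(";", subs))) + 1L),
             subs = subs, stringsAsFactors = FALSE)
}

# Precomputed scan index: all hairpins concatenated into one subject so a
# whole reference set is scanned with a single C-level mismatch-count call
# per tag length. Window starts are restricted to lie fully inside one
# hairpin, so no separators are needed.
hairpin_index <- function(hairpins) {
  lens <- nchar(hairpins$sequence)
  off <- c(0L, cumsum(lens))[seq_along(lens)]
  list(subject = Biostrings::DNAString(paste(hairpins$sequence,
                                             collapse = "")),
       ids = hairpins$id, seqs = hairpins$sequence,
       lens = lens, off = off)
}

# One fuzzy scan of a tag against every hairpin in the index.
scan_all <- function(tag_seq, idx, max_sub) {
  n <- nchar(tag_seq)
  keep <- which(idx$lens >= n)
  if (length(keep) == 0L) return(empty_placements())
  starts <- unlist(lapply(keep, function(i) {
    (idx$off[i] + 1L):(idx$off[i] + idx$lens[i] - n + 1L)
  }))
  ned <- Biostrings::neditStartingAt(Biostrings::DNAString(tag_seq),
                                     idx$subject, starting.at = starts,
                                     with.indels = FALSE)
  hits <- starts[ned <= max_sub]
  if (length(hits) == 0L) return(empty_placements())
  hi <- findInterval(hits - 1L, idx$off)
  local <- hits - idx$off[hi]
  subs <- vapply(seq_along(hits),
                 function(j) sub_string(tag_seq, idx$seqs[hi[j]], local[j]),
                 "")
  data.frame(hairpin_id = idx$ids[hi], start = as.integer(local),
             end = as.integer(local + n - 1L),
             n_sub = ifelse(subs == "", 0L,
                            lengths(regmatches(subs, gregexpr(";", subs))) + 1L),
             subs = subs, stringsAsFactors = FALSE)
}

#' Strip the 3' sequencing adaptor from a read
#'
#' Scans for the 5'-most position at which a prefix of the adaptor matches the
#' read suffix with overlap at least \code{adaptor_min_overlap} and mismatch
#' fraction at most \code{adaptor_max_mismatch_frac}; the read prefix before
#' that position is the tag. When no such position exists the read is returned
#' unchanged with \code{found = FALSE}.
#'
#' @param read_seq Read sequence.
#' @param params An [aligner_params()] with \code{adaptor_seq} set.
#' @return \code{list(tag, found)}.
#' @export
trim_adaptor <- function(read_seq, params) {
  ad <- params$adaptor_seq
  if (is.null(ad) || !nzchar(ad)) stop("adaptor_seq not configured")
  n <- nchar(read_seq)
  na <- nchar(ad)
  rv <- utf8ToInt(read_seq)
  av <- utf8ToInt(ad)
  last <- n - params$adaptor_min_overlap + 1L
  if (last >= 1L) {
    for (i in seq_len(last)) {
      ov <- min(n - i + 1L, na)
      if (ov < params$adaptor_min_overlap) break
      mm <- sum(rv[i:(i + ov - 1L)] != av[seq_len(ov)])
      if (mm / ov <= params$adaptor_max_mismatch_frac) {
        return(list(tag = substr(read_seq, 1L, i - 1L), found = TRUE))
      }
    }
  }
  list(tag = read_seq, found = FALSE)
}

unmapped_result <- function(strategy, reason) {
  list(status = if (reason == "no_adaptor") "unusable" else "unmapped",
       strategy = strategy, reason = reason, aligned_len = NA_integer_,
       placements = empty_placements(), nta_seq = "")
}

#' Keep only the equal-best placements and weight them
#'
#' Retains the minimal-substitution subset of a placement table, orders it by
#' \code{(hairpin_id, start)} and attaches fractional weights \code{1/k} so a
#' multi-mapping tag conserves unit mass.
#'
#' @param placements Placement \code{data.frame} (as from [hamming_scan()]).
#' @return The filtered, ordered table with a \code{weight} column.
#' @export
resolve_multimap <- function(placements) {
  stopifnot(nrow(placements) > 0L)
  best <- placements[placements$n_sub == min(placements$n_sub), , drop = FALSE]
  best <- best[order(best$hairpin_id, best$start), , drop = FALSE]
  best$weight <- 1 / nrow(best)
  rownames(best) <- NULL
  best
}

#' Recursive length-trimming alignment of one tag
#'
#' Tries the tag at full length, then repeatedly trims \code{trim_step} bases
#' from the 3' end and retries while the remaining length is at least
#' \code{min_len}. The first (longest) length with any placement wins; its
#' equal-best placements (minimal substitutions) are returned with fractional
#' weights. Deterministic given its inputs.
#'
#' @param tag_seq Tag sequence.
#' @param hairpins Hairpin set \code{data.frame}.
#' @param params [aligner_params()].
#' @return A list with \code{status} (\code{"mapped"}/\code{"unmapped"}),
#'   \code{strategy}, \code{aligned_len}, \code{placements}, \code{nta_seq}
#'   (always empty for this strategy: the true 3' end is unknown).
#' @export
recursive_map <- function(tag_seq, hairpins, params = aligner_params()) {
  recursive_map_pre(tag_seq, hairpin_index(hairpins), params)
}

recursive_map_pre <- function(tag_seq, idx, params) {
  len <- nchar(tag_seq)
  # lengths longer than every subject cannot place; skip them on the same
  # trimming grid
  longest <- max(idx$lens)
  if (len > longest) {
    len <- len - params$trim_step *
      as.integer(ceiling((len - longest) / params$trim_step))
  }
  while (len >= params$min_len) {
    hits <- scan_all(substr(tag_seq, 1L, len), idx, params$max_sub)
    if (nrow(hits) > 0L) {
      return(list(status = "mapped", strategy = "recursive",
                  aligned_len = len, placements = resolve_multimap(hits),
                  nta_seq = ""))
    }
    len <- len - params$trim_step
  }
  unmapped_result("recursive", "no_placement")
}

#' Split an adaptor-trimmed tag into a templated core and a 3' NTA suffix
#'
#' Considers every split of the tag into a templated prefix (core) and a 3'
#' suffix of length 0..\code{nta_max}. A split is admissible when the core has
#' a placement with at most \code{max_sub} mismatches and every suffix base is
#' non-templated there: it either falls beyond the hairpin 3' end or differs
#' from the hairpin base at its position. Among admissible splits the one with
#' fewest substitutions wins, ties broken toward the longer core, so terminal
#' mismatches that could be read either way are absorbed as substitutions
#' only when that does not cost extra mismatches.
#'
#' @param tag_seq Adaptor-trimmed tag (exact 3' end known).
#' @param hairpins Hairpin set \code{data.frame}.
#' @param params [aligner_params()].
#' @return \code{list(placements, nta_seq, aligned_len)} with an empty
#'   placement table when no admissible split exists.
#' @export
extract_nta <- function(tag_seq, hairpins, params = aligner_params()) {
  nta_split(tag_seq, hairpin_index(hairpins), params)
}

nta_split <- function(tag_seq, idx, params) {
  len <- nchar(tag_seq)
  best <- NULL
  best_k <- NA_integer_
  for (k in 0:min(params$nta_max, len - params$min_len)) {
    core <- substr(tag_seq, 1L, len - k)
    hits <- scan_all(core, idx, params$max_sub)
    if (k > 0L && nrow(hits) > 0L) {
      sufv <- utf8ToInt(substr(tag_seq, len - k + 1L, len))
      ok <- vapply(seq_len(nrow(hits)), function(i) {
        hj <- match(hits$hairpin_id[i], idx$ids)
        pos <- hits$end[i] + seq_len(k)
        beyond <- pos > idx$lens[hj]
        tmpl <- rep(NA_integer_, k)
        if (any(!beyond)) {
          tmpl[!beyond] <- utf8ToInt(substr(idx$seqs[hj], pos[1L],
                                            max(pos[!beyond])))
        }
        all(beyond | tmpl != sufv)
      }, TRUE)
      hits <- hits[ok, , drop = FALSE]
    }
    if (nrow(hits) == 0L) next
    cand_sub <- min(hits$n_sub)
    if (is.null(best) || cand_sub < min(best$n_sub)) {
      best <- hits
      best_k <- k
    }
    if (min(best$n_sub) == 0L) break
  }
  if (is.null(best)) {
    return(list(placements = empty_placements(), nta_seq = "",
                aligned_len = NA_integer_))
  }
  list(placements = resolve_multimap(best),
       nta_seq = if (best_k > 0L) substr(tag_seq, len - best_k + 1L, len) else "",
       aligned_len = len - best_k)
}

#' Adaptor-trimmed exact-end alignment of one read
#'
#' Strips the 3' adaptor (so the exact captured 3' end of the tag is known),
#' then performs a single substitution-bounded placement of the trimmed tag at
#' full length after peeling any 3' non-templated addition via [extract_nta()].
#' There is no recursive trimming. Reads without a detectable adaptor are
#' \code{"unusable"} by this strategy (they may still map recursively); tags
#' shorter than \code{min_len} after trimming are \code{"unmapped"}.
#'
#' @inheritParams recursive_map
#' @param read_seq Raw read sequence (tag + adaptor read-through).
#' @return Same shape as [recursive_map()], with strategy
#'   \code{"adaptor_trimmed"} and possibly non-empty \code{nta_seq}.
#' @export
adaptor_trim_map <- function(read_seq, hairpins, params = aligner_params()) {
  adaptor_trim_map_pre(read_seq, hairpin_index(hairpins), params)
}

adaptor_trim_map_pre <- function(read_seq, idx, params) {
  tr <- trim_adaptor(read_seq, params)
  if (!tr$found) return(unmapped_result("adaptor_trimmed", "no_adaptor"))
  if (nchar(tr$tag) < params$min_len) {
    return(unmapped_result("adaptor_trimmed", "too_short"))
  }
  sp <- nta_split(tr$tag, idx, params)
  if (nrow(sp$placements) == 0L) {
    return(unmapped_result("adaptor_trimmed", "no_placement"))
  }
  list(status = "mapped", strategy = "adaptor_trimmed",
       aligned_len = sp$aligned_len, placements = sp$placements,
       nta_seq = sp$nta_seq)
}

#' Align a collapsed tag table against hairpin references
#'
#' Batch driver over unique sequences. With strategy
#' \code{"adaptor_trimmed"} each read is adaptor-stripped and placed at its
#' exact length ([adaptor_trim_map()]); reads unusable by that strategy fall
#' back to [recursive_map()] when \code{strategy = "both"}.
#'
#' @param tags Tag \code{data.frame} from [read_tags()] (columns
#'   \code{sequence}, \code{multiplicity}, \code{sample_id}).
#' @param hairpins Hairpin set.
#' @param params [aligner_params()].
#' @param strategy \code{"adaptor_trimmed"}, \code{"recursive"}, or
#'   \code{"both"} (adaptor-trimmed with recursive fallback).
#' @return A long \code{data.frame}, one row per (tag, placement), with
#'   columns \code{sequence}, \code{sample_id}, \code{multiplicity},
#'   \code{strategy}, \code{status}, \code{hairpin_id}, \code{start},
#'   \code{end}, \code{aligned_len}, \code{n_sub}, \code{subs},
#'   \code{nta_seq}, \code{weight}. Unmapped/unusable tags keep one row with
#'   \code{NA} placement fields so read accounting is conserved.
#' @export
align_tags <- function(tags, hairpins, params = aligner_params(),
                       strategy = c("adaptor_trimmed", "recursive", "both")) {
  strategy <- match.arg(strategy)
  idx <- hairpin_index(hairpins)
  uniq <- unique(tags$sequence)
  res <- lapply(uniq, function(s) {
    r <- if (strategy == "recursive") {
      recursive_map_pre(s, idx, params)
    } else {
      a <- adaptor_trim_map_pre(s, idx, params)
      if (strategy == "both" && a$status == "unusable") {
        recursive_map_pre(s, idx, params)
      } else a
    }
    if (r$status != "mapped") {
      return(data.frame(sequence = s, strategy = r$strategy, status = r$status,
                        hairpin_id = NA_character_, start = NA_integer_,
                        end = NA_integer_, aligned_len = NA_integer_,
                        n_sub = NA_integer_, subs = NA_character_,
                        nta_seq = "", weight = NA_real_,
                        stringsAsFactors = FALSE))
    }
    p <- r$placements
    data.frame(sequence = s, strategy = r$strategy, status = "mapped",
               hairpin_id = p$hairpin_id, start = p$start, end = p$end,
               aligned_len = r$aligned_len, n_sub = p$n_sub, subs = p$subs,
               nta_seq = r$nta_seq, weight = p$weight,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  out <- merge(tags, res, by = "sequence", sort = FALSE)
  out <- out[order(out$sample_id, out$sequence, out$hairpin_id, out$start), ]
  rownames(out) <- NULL
  out
}

#' Write an alignment table to TSV
#'
#' @param aligned Output of [align_tags()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_alignments <- function(aligned, path) {
  utils::write.table(aligned, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
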