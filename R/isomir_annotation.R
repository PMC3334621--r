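#' Assign a placement to a hairpin arm
#'
#' Picks the mature annotation (5p or 3p) whose span overlaps the placement
#' the most, in absolute nucleotides then as a fraction of the placement;
#' remaining ties go to 5p. A placement overlapping neither arm (e.g. wholly
#' inside the loop) is an orphan-side placement and returns \code{NULL}.
#'
#' @param start,end 1-based inclusive hairpin coordinates of the templated
#'   placement.
#' @param annotations Annotation \code{data.frame} for the placement's
#'   hairpin (1 or 2 rows).
#' @return The winning one-row annotation, or \code{NULL} for orphan-side.
#' @export
assign_arm <- function(start, end, annotations) {
  if (nrow(annotations) == 0L) stop("hairpin has no mature annotations")
  ov <- pmax(0L, pmin(end, annotations$end) - pmax(start, annotations$start) + 1L)
  if (all(ov == 0L)) return(NULL)
  best <- which(ov == max(ov))
  if (length(best) > 1L) {
    best <- best[order(match(annotations$arm[best], c("5p", "3p")))][1L]
  }
  annotations[best, , drop = FALSE]
}

#' IsomiR feature vector of a placement relative to its canonical mature
#'
#' @param start,end Templated placement span (hairpin coordinates).
#' @param n_sub Number of substitutions in the placement.
#' @param nta_seq 3' non-templated addition ("" if none).
#' @param annotation The arm's canonical annotation (one row).
#' @return \code{data.frame(delta_start, delta_end, n_sub, nta_len, nta_seq)}:
#'   \code{delta_start = start - canonical start},
#'   \code{delta_end = end - canonical end} (templated end only).
#' @export
featurize <- function(start, end, n_sub, nta_seq, annotation) {
  data.frame(delta_start = as.integer(start - annotation$start),
             delta_end = as.integer(end - annotation$end),
             n_sub = as.integer(n_sub),
             nta_len = nchar(nta_seq),
             nta_seq = nta_seq, stringsAsFactors = FALSE)
}

#' Classify a feature vector into one of seven mutually exclusive categories
#'
#' Decision table over \code{(delta_start, delta_end, n_sub, nta_len)}:
#' \describe{
#'   \item{canonical}{(0, 0, 0, 0)}
#'   \item{start_only}{start shifted, everything else canonical}
#'   \item{end_only}{templated end shifted, everything else canonical}
#'   \item{substitution_only}{substitutions on a canonical-span tag}
#'   \item{shifted}{start and end shifted by the same non-zero offset
#'     (canonical length, both cut sites moved)}
#'   \item{nta3}{3' non-templated addition on an otherwise canonical tag}
#'   \item{mixed}{any other combination}
#' }
#' The table is total and single-valued: every feature vector gets exactly
#' one category. Vectorized over its arguments.
#'
#' @param delta_start,delta_end,n_sub,nta_len Feature vector components.
#' @return Character vector of category labels.
#' @export
classify_isomir <- function(delta_start, delta_end, n_sub, nta_len) {
  ds0 <- delta_start == 0L
  de0 <- delta_end == 0L
  s0 <- n_sub == 0L
  n0 <- nta_len == 0L
  ifelse(ds0 & de0 & s0 & n0, "canonical",
  ifelse(!ds0 & de0 & s0 & n0, "start_only",
  ifelse(ds0 & !de0 & s0 & n0, "end_only",
  ifelse(ds0 & de0 & !s0 & n0, "substitution_only",
  ifelse(!ds0 & delta_start == delta_end & s0 & n0, "shifted",
  ifelse(ds0 & de0 & s0 & !n0, "nta3", "mixed"))))))
}

#' All isomiR category labels, in display order
#' @export
isomir_categories <- function() {
  c("canonical", "start_only", "end_only", "substitution_only",
    "shifted", "nta3", "mixed")
}

arm_name_of <- function(annotation) {
  if (grepl("-(5p|3p)$", annotation$mature_name)) annotation$mature_name
  else paste0(annotation$mature_name, "-", annotation$arm)
}

#' Render the machine-parsable isomiR name
#'
#' Format: \code{"<arm>|{<label>}|<start>_<end>|<mod1>;<mod2>..."} where
#' \code{<arm>} is the mature name with its 5p/3p suffix, \code{<label>} is
#' the canonical mature name for canonical tags and the literal
#' \code{"isomiR"} otherwise, the coordinate block is the 1-based inclusive
#' templated span on the hairpin, and modifiers are substitutions
#' (\code{"sub.<pos>.<ref>><alt>"}, ascending position) followed by 3'
#' additions (\code{"add.<pos>.<nt>"}, positions continuing hairpin numbering
#' beyond the templated end). A canonical tag renders with an empty modifier
#' field, e.g. \code{"hsa-miR-143-3p|{hsa-miR-143}|60_80|"}.
#'
#' @param start,end Templated span.
#' @param subs Encoded substitution string \code{"pos:ref>alt;..."} or "".
#' @param nta_seq 3' non-templated addition ("" if none).
#' @param annotation The arm's canonical annotation.
#' @param category Category label from [classify_isomir()].
#' @return The name string.
#' @export
render_name <- function(start, end, subs, nta_seq, annotation, category) {
  label <- if (category == "canonical") annotation$mature_name else "isomiR"
  mods <- character()
  if (!is.na(subs) && nzchar(subs)) {
    parts <- strsplit(subs, ";", fixed = TRUE)[[1L]]
    m <- regmatches(parts, regexec("^([0-9]+):([ACGT])>([ACGT])$", parts))
    pos <- as.integer(vapply(m, `[`, "", 2L))
    o <- order(pos)
    mods <- sprintf("sub.%d.%s>%s", pos[o],
                    vapply(m, `[`, "", 3L)[o], vapply(m, `[`, "", 4L)[o])
  }
  if (nzchar(nta_seq)) {
    nt <- strsplit(nta_seq, "")[[1L]]
    mods <- c(mods, sprintf("add.%d.%s", end + seq_along(nt), nt))
  }
  paste0(arm_name_of(annotation), "|{", label, "}|", start, "_", end, "|",
         paste(mods, collapse = ";"))
}

#' Parse an isomiR name back into its components
#'
#' Accepts both the compact substitution form \code{"sub.77.G>A"} and the
#' spaced dialect \code{"sub.77.G > A"}. Validates that the coordinate block
#' is ordered, substitution positions fall inside the span, and addition
#' positions fall beyond it and are consecutive.
#'
#' @param name An isomiR name string.
#' @return A list with \code{arm_name}, \code{label}, \code{start},
#'   \code{end}, \code{subs} (data.frame pos/ref/alt), \code{nta_seq}.
#' @export
parse_name <- function(name) {
  m <- regmatches(name,
    regexec("^([^|]+)\\|\\{([^}]+)\\}\\|([0-9]+)_([0-9]+)\\|(.*)$", name))[[1L]]
  if (length(m) == 0L) stop("cannot parse isomiR name: ", name)
  start <- as.integer(m[4L])
  end <- as.integer(m[5L])
  if (start > end) stop("invalid coordinate block (start > end): ", name)
  subs <- data.frame(pos = integer(), ref = character(), alt = character(),
                     stringsAsFactors = FALSE)
  nta_pos <- integer()
  nta_nt <- character()
  if (nzchar(m[6L])) {
    for (mod in strsplit(m[6L], ";", fixed = TRUE)[[1L]]) {
      sm <- regmatches(mod,
        regexec("^sub\\.([0-9]+)\\.([ACGT]) ?> ?([ACGT])$", mod))[[1L]]
      if (length(sm) > 0L) {
        pos <- as.integer(sm[2L])
        if (pos < start || pos > end) {
          stop("substitution position ", pos, " outside span in: ", name)
        }
        subs <- rbind(subs, data.frame(pos = pos, ref = sm[3L], alt = sm[4L],
                                       stringsAsFactors = FALSE))
        next
      }
      am <- regmatches(mod, regexec("^add\\.([0-9]+)\\.([ACGT])$", mod))[[1L]]
      if (length(am) > 0L) {
        nta_pos <- c(nta_pos, as.integer(am[2L]))
        nta_nt <- c(nta_nt, am[3L])
        next
      }
      stop("unrecognized modifier '", mod, "' in: ", name)
    }
  }
  if (length(nta_pos) > 0L &&
      !identical(nta_pos, end + seq_along(nta_pos))) {
    stop("addition positions must continue the span in: ", name)
  }
  list(arm_name = m[2L], label = m[3L], start = start, end = end,
       subs = subs, nta_seq = paste(nta_nt, collapse = ""))
}

#' Annotate aligned tags with isomiR features, categories and names
#'
#' For every mapped placement, assigns the arm, computes the feature vector
#' against that arm's canonical mature, classifies it and renders its name.
#' Orphan-side placements (no overlap with either mature) keep their mass but
#' get \code{arm = NA} and a hairpin-level name so library accounting is
#' conserved; they are excluded from category statistics downstream.
#'
#' @param aligned Alignment table from [align_tags()].
#' @param annotations Annotation table from [read_annotations()].
#' @return \code{aligned} restricted to mapped rows, with added columns
#'   \code{arm}, \code{mature_name}, \code{delta_start}, \code{delta_end},
#'   \code{nta_len}, \code{category}, \code{name}.
#' @export
annotate_alignments <- function(aligned, annotations) {
  mapped <- aligned[aligned$status == "mapped", , drop = FALSE]
  n <- nrow(mapped)
  arm <- character(n); mname <- character(n)
  ds <- integer(n); de <- integer(n); cat <- character(n); nm <- character(n)
  # cache distinct placements: (hairpin,start,end,subs,nta) determine the call
  key <- paste(mapped$hairpin_id, mapped$start, mapped$end, mapped$subs,
               mapped$nta_seq, sep = "\r")
  uk <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    ann <- annotations[annotations$hairpin_id == mapped$hairpin_id[i], ,
                       drop = FALSE]
    a <- assign_arm(mapped$start[i], mapped$end[i], ann)
    if (is.null(a)) {
      val <- list(arm = NA_character_, mature_name = NA_character_,
                  ds = NA_integer_, de = NA_integer_, cat = NA_character_,
                  nm = paste0(mapped$hairpin_id[i], "|{orphan-side}|",
                              mapped$start[i], "_", mapped$end[i], "|"))
    } else {
      f <- featurize(mapped$start[i], mapped$end[i], mapped$n_sub[i],
                     mapped$nta_seq[i], a)
      cc <- classify_isomir(f$delta_start, f$delta_end, f$n_sub, f$nta_len)
      val <- list(arm = a$arm, mature_name = a$mature_name,
                  ds = f$delta_start, de = f$delta_end, cat = cc,
                  nm = render_name(mapped$start[i], mapped$end[i],
                                   mapped$subs[i], mapped$nta_seq[i], a, cc))
    }
    assign(key[i], val, envir = cache)
  }
  for (i in seq_len(n)) {
    val <- get(key[i], envir = cache)
    arm[i] <- val$arm; mname[i] <- val$mature_name
    ds[i] <- val$ds; de[i] <- val$de; cat[i] <- val$cat; nm[i] <- val$nm
  }
  mapped$arm <- arm
  mapped$mature_name <- mname
  mapped$delta_start <- ds
  mapped$delta_end <- de
  mapped$nta_len <- nchar(mapped$nta_seq)
  mapped$category <- cat
  mapped$name <- nm
  rownames(mapped) <- NULL
  mapped
}

#' Flag orphan isomiRs
#'
#' An orphan isomiR is one whose parent arm's canonical sequence is never
#' detected (above \code{threshold}) in any sample. Orphans are suspect —
#' they may reflect a mis-annotated mature — and can be dropped from
#' category statistics.
#'
#' @param features Feature metadata \code{data.frame} with columns
#'   \code{name}, \code{hairpin_id}, \code{arm}, \code{category} (one row per
#'   quantified feature, as produced by [build_counts()]).
#' @param mat Feature-by-sample matrix (counts or tpm) with rownames matching
#'   \code{features$name}.
#' @param threshold Detection threshold: a canonical is "detected" in a
#'   sample when its value exceeds this (default 0).
#' @return Logical vector along \code{features}: \code{TRUE} for orphans.
#' @export
flag_orphans <- function(features, mat, threshold = 0) {
  key <- paste(features$hairpin_id, features$arm, sep = "\r")
  canon <- !is.na(features$category) & features$category == "canonical"
  detected_arms <- unique(key[canon][
    apply(mat[features$name[canon], , drop = FALSE] > threshold, 1L, any)])
  is_iso <- !is.na(features$category) & features$category != "canonical"
  is_iso & !(key %in% detected_arms)
}

#' Write the per-sample isomiR count table
#'
#' Tab-delimited: first column the isomiR name, one column per sample.
#'
#' @param counts A count object from [build_counts()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_isomir_table <- function(counts, path) {
  tab <- data.frame(name = rownames(counts$matrix), counts$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
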