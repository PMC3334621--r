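#' Read pre-miRNA hairpin references from FASTA
#'
#' Loads a set of hairpin reference sequences (miRBase-style ids such as
#' \code{"hsa-mir-143"}). Sequences are upper-cased and any \code{U} is
#' normalized to \code{T}, so hairpin references written as RNA are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A \code{data.frame} with columns \code{id}, \code{species} (the
#'   3-letter prefix of the id, or \code{NA} when the id has no dash-separated
#'   prefix), \code{sequence} and \code{length}.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">hsa-mir-x", "ACGUACGUACGUACGUACGUACGU"), fa)
#' read_hairpin_fasta(fa)
read_hairpin_fasta <- function(path) {
  stopifnot(file.exists(path))
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(recs))
  seqs <- normalize_dna(as.character(recs), what = ids)
  if (anyDuplicated(ids)) {
    stop("duplicate hairpin id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  hairpin_set(ids, seqs)
}

hairpin_set <- function(ids, seqs) {
  species <- ifelse(grepl("^[A-Za-z]{3}-", ids), substr(ids, 1L, 3L),
                    NA_character_)
  data.frame(id = ids, species = species, sequence = seqs,
             length = nchar(seqs), stringsAsFactors = FALSE,
             row.names = NULL)
}

# Upper-case, U->T, and reject anything outside {A,C,G,T}.
normalize_dna <- function(x, what = NULL) {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    lab <- if (is.null(what)) which(bad)[1L] else what[bad][1L]
    stop("non-ACGTU character in record ", lab)
  }
  x
}

#' Write hairpin references to FASTA
#'
#' @param hairpins A hairpin \code{data.frame} from [read_hairpin_fasta()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_hairpin_fasta <- function(hairpins, path) {
  x <- Biostrings::DNAStringSet(hairpins$sequence)
  names(x) <- hairpins$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Locate a mature miRNA on its hairpin
#'
#' Finds the 1-based inclusive span of a mature sequence within a hairpin by
#' exact substring search. If the mature occurs more than once the 5'-most
#' occurrence is used and a warning is raised. The arm is called from the span
#' midpoint: midpoints in the 5' half of the hairpin (ties included) are
#' \code{"5p"}, otherwise \code{"3p"}.
#'
#' @param mature_name Name of the mature miRNA (e.g. \code{"hsa-miR-143"}).
#' @param mature_seq Mature sequence (RNA accepted, normalized to DNA).
#' @param hairpin A single-row hairpin \code{data.frame} (one element of the
#'   set returned by [read_hairpin_fasta()]).
#' @return A one-row annotation \code{data.frame} with columns
#'   \code{hairpin_id}, \code{mature_name}, \code{arm}, \code{start},
#'   \code{end}, \code{sequence}.
#' @export
locate_mature <- function(mature_name, mature_seq, hairpin) {
  stopifnot(nrow(hairpin) == 1L)
  seq <- normalize_dna(mature_seq, what = mature_name)
  hits <- gregexpr(seq, hairpin$sequence, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) {
    stop("mature '", mature_name, "' not found in hairpin ", hairpin$id)
  }
  if (length(hits) > 1L) {
    warning("mature '", mature_name, "' occurs ", length(hits),
            " times in hairpin ", hairpin$id, "; using the 5'-most span")
  }
  start <- as.integer(hits[1L])
  end <- start + nchar(seq) - 1L
  mature_annotation(hairpin, mature_name, start, end)
}

mature_annotation <- function(hairpin, mature_name, start, end) {
  len <- hairpin$length
  if (start < 1L || end > len || start > end) {
    stop("span ", start, "..", end, " outside hairpin ", hairpin$id,
         " (length ", len, ")")
  }
  mid <- (start + end) / 2
  arm <- if (mid <= (len + 1) / 2) "5p" else "3p"
  data.frame(hairpin_id = hairpin$id, mature_name = mature_name, arm = arm,
             start = as.integer(start), end = as.integer(end),
             sequence = substr(hairpin$sequence, start, end),
             stringsAsFactors = FALSE)
}

#' Read mature annotations (hairpin-relative TSV or GFF3)
#'
#' TSV input requires a header with columns \code{hairpin_id},
#' \code{mature_name}, \code{start}, \code{end}; coordinates are 1-based
#' inclusive and hairpin-relative. GFF3 input follows the miRBase dialect with
#' the hairpin id in column 1, feature rows of type \code{miRNA}, 1-based
#' inclusive coordinates, and the mature name in a \code{Name=} attribute.
#' Every annotation is validated against the loaded hairpins; the arm is
#' inferred from the span midpoint as in [locate_mature()]. At most one 5p and
#' one 3p annotation are allowed per hairpin.
#'
#' @param path Annotation file.
#' @param hairpins Hairpin set from [read_hairpin_fasta()].
#' @param format \code{"auto"} (by extension), \code{"tsv"} or \code{"gff3"}.
#' @return Annotation \code{data.frame}; one row per mature.
#' @export
read_annotations <- function(path, hairpins, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  tab <- if (format == "tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    read_mirbase_gff3(path)
  }
  need <- c("hairpin_id", "mature_name", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    hp <- hairpins[hairpins$id == tab$hairpin_id[i], , drop = FALSE]
    if (nrow(hp) == 0L) stop("unknown hairpin_id: ", tab$hairpin_id[i])
    mature_annotation(hp, tab$mature_name[i],
                      as.integer(tab$start[i]), as.integer(tab$end[i]))
  }))
  dup <- duplicated(out[, c("hairpin_id", "arm")])
  if (any(dup)) {
    stop("more than one ", out$arm[dup][1L], " annotation for hairpin ",
         out$hairpin_id[dup][1L])
  }
  rownames(out) <- NULL
  out
}

read_mirbase_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(hairpin_id = character(), mature_name = character(),
                      start = integer(), end = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(f, length, 1L) != 9L
  if (any(bad)) stop("malformed GFF3 line ", which(bad)[1L])
  m <- do.call(rbind, f)
  keep <- m[, 3L] == "miRNA"
  m <- m[keep, , drop = FALSE]
  name <- sub(".*Name=([^;]+).*", "\\1", m[, 9L])
  data.frame(hairpin_id = m[, 1L], mature_name = name,
             start = as.integer(m[, 4L]), end = as.integer(m[, 5L]),
             stringsAsFactors = FALSE)
}

#' Read small-RNA reads and collapse identical sequences into tags
#'
#' Accepts FASTA or FASTQ. Headers of the form \code{"..._xN"} carry a
#' pre-collapsed multiplicity \code{N}; other reads count once. Identical
#' sequences are collapsed and their multiplicities summed, so the result is
#' independent of input order.
#'
#' @param path Read file.
#' @param sample_id Sample the reads belong to.
#' @param format \code{"auto"} (by extension), \code{"fasta"} or \code{"fastq"}.
#' @return A \code{data.frame} with columns \code{sequence},
#'   \code{multiplicity}, \code{sample_id}, ordered by sequence.
#' @export
read_tags <- function(path, sample_id, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  recs <- Biostrings::readBStringSet(path, format = format)
  if (length(recs) == 0L) {
    warning("no reads in ", path)
    return(data.frame(sequence = character(), multiplicity = integer(),
                      sample_id = character(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(recs))
  mult <- rep(1L, length(recs))
  hasx <- grepl("_x[0-9]+$", ids)
  mult[hasx] <- as.integer(sub(".*_x([0-9]+)$", "\\1", ids[hasx]))
  collapse_tags(normalize_dna(as.character(recs), what = ids), mult, sample_id)
}

collapse_tags <- function(sequences, multiplicities, sample_id) {
  agg <- tapply(multiplicities, sequences, sum)
  data.frame(sequence = names(agg),
             multiplicity = as.integer(agg),
             sample_id = sample_id,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a sample sheet
#'
#' TSV with header columns \code{sample_id}, \code{tissue}, \code{donor_id},
#' \code{prep_kit}. Sample ids must be unique and tissue/prep_kit non-empty.
#'
#' @param path Sample sheet path.
#' @return \code{data.frame} of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "donor_id", "prep_kit")
  if (!all(need %in% names(tab))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in sample sheet")
  if (any(!nzchar(tab$tissue)) || any(!nzchar(tab$prep_kit))) {
    stop("every sample needs a non-empty tissue and prep_kit")
  }
  tab[, need]
}
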