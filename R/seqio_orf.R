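#' Read transcripts from a FASTA file
#'
#' Headers follow the `id key=value ...` dialect; the assembly component and
#' (optionally) the taxon are pulled out of the key=value fields.  Sequences
#' are upper-cased and `U` is mapped to `T`.
#'
#' @param path FASTA file.
#' @param taxon taxon label applied to all records when the header carries
#'   none; a `taxon=` header field wins over this argument.
#' @param component_key,taxon_key header keys holding the assembly component
#'   identifier and the taxon.
#' @param require_component error when a record lacks a component field
#'   (de novo mode needs it; set `FALSE` for genome-guided input).
#' @return data frame with columns `id`, `taxon`, `component_id`, `seq`.
#' @export
read_transcript_fasta <- function(path, taxon = NULL,
                                  component_key = "comp",
                                  taxon_key = "taxon",
                                  require_component = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(!grepl("^\\s*$", lines))
  if (length(nonblank) == 0L)
    return(data.frame(id = character(), taxon = character(),
                      component_id = character(), seq = character(),
                      stringsAsFactors = FALSE))
  if (!startsWith(lines[nonblank[1]], ">"))
    stop(sprintf("malformed FASTA %s: line %d does not start a record",
                 path, nonblank[1]), call. = FALSE)
  hdr <- which(startsWith(lines, ">"))
  rec_end <- c(hdr[-1] - 1L, length(lines))

  parse_one <- function(k) {
    header <- sub("^>", "", lines[hdr[k]])
    toks <- strsplit(trimws(header), "\\s+")[[1]]
    id <- toks[1]
    kv <- toks[-1][grepl("=", toks[-1])]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    body <- if (rec_end[k] > hdr[k]) lines[(hdr[k] + 1L):rec_end[k]] else character()
    seq <- chartr("u", "t", toupper(paste(gsub("\\s", "", body),
                                          collapse = "")))
    seq <- chartr("U", "T", seq)
    comp <- if (component_key %in% keys) vals[match(component_key, keys)] else NA_character_
    tax <- if (taxon_key %in% keys) vals[match(taxon_key, keys)] else taxon
    list(id = id, taxon = tax, comp = comp, seq = seq, line = hdr[k])
  }
  recs <- lapply(seq_along(hdr), parse_one)

  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate transcript id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  for (r in recs) {
    if (nchar(r$seq) < 1L)
      stop(sprintf("empty sequence for '%s' (line %d) in %s",
                   r$id, r$line, path), call. = FALSE)
    if (require_component && (is.na(r$comp) || !nzchar(r$comp)))
      stop(sprintf("record '%s' (line %d) in %s lacks a '%s=' header field",
                   r$id, r$line, path, component_key), call. = FALSE)
  }
  data.frame(id = ids,
             taxon = vapply(recs, function(r) r$taxon %||% NA_character_, ""),
             component_id = vapply(recs, `[[`, "", "comp"),
             seq = vapply(recs, `[[`, "", "seq"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write transcripts to FASTA
#'
#' @param transcripts data frame as returned by [read_transcript_fasta()].
#' @param path output path.
#' @param width line-wrap width for sequence lines.
#' @export
write_transcript_fasta <- function(transcripts, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(transcripts))) {
    hdr <- sprintf(">%s comp=%s", transcripts$id[i],
                   transcripts$component_id[i])
    if (!is.na(transcripts$taxon[i]))
      hdr <- paste0(hdr, " taxon=", transcripts$taxon[i])
    writeLines(hdr, con)
    s <- transcripts$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Translate a coding sequence under the standard genetic code
#'
#' @param cds nucleotide string, length divisible by 3.  A terminal stop
#'   codon is dropped from the protein; an internal stop is an error.
#' @param on_ambiguous `"error"` to reject codons containing non-ACGT
#'   characters, `"X"` to translate them as `X`.
#' @return amino-acid string.
#' @export
translate_cds <- function(cds, on_ambiguous = c("error", "X")) {
  on_ambiguous <- match.arg(on_ambiguous)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("cds length (", n, ") is not a multiple of 3", call. = FALSE)
  if (n == 0L) return("")
  starts <- seq(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  ambig <- grepl("[^ACGT]", codons)
  if (any(ambig) && on_ambiguous == "error")
    stop("ambiguous codon(s) at position(s) ",
         paste(which(ambig), collapse = ", "), call. = FALSE)
  aa <- ifelse(ambig, "X", GENETIC_CODE_TABLE[codons])
  if (length(aa) > 1L && any(aa[-length(aa)] == "*"))
    stop("internal stop codon at codon ",
         which(aa[-length(aa)] == "*")[1], call. = FALSE)
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# Longest ATG-initiated ORF within one reading-frame codon vector.
# Returns NULL or list(atg = codon index, len_aa, has_stop).
.best_span <- function(codons) {
  is_stop <- codons %in% .stop_codons()
  is_atg <- codons == "ATG"
  has_n <- grepl("[^ACGT]", codons)
  n <- length(codons)
  # segment id: codons between stops (stop ends its own segment)
  seg <- cumsum(c(FALSE, is_stop[-n]))
  best <- NULL
  for (s in unique(seg)) {
    idx <- which(seg == s)
    stop_at <- idx[is_stop[idx]][1]         # NA if open-ended segment
    last <- if (is.na(stop_at)) idx[length(idx)] else stop_at - 1L
    cand <- idx[is_atg[idx] & idx <= last]
    if (length(cand) == 0L) next
    # ambiguous codons disqualify spans containing them
    n_pos <- idx[has_n[idx] & idx <= last]
    if (length(n_pos) > 0L) cand <- cand[cand > max(n_pos)]
    if (length(cand) == 0L) next
    atg <- min(cand)
    len <- last - atg + 1L
    if (is.null(best) || len > best$len_aa ||
        (len == best$len_aa && atg < best$atg))
      best <- list(atg = atg, len_aa = len, has_stop = !is.na(stop_at))
  }
  best
}

#' Find the longest open reading frame in six frames
#'
#' An ORF is an ATG-initiated span ending at the first in-frame stop codon,
#' or at the end of the sequence when no stop follows.  All six reading
#' frames are searched; ties on protein length prefer forward frames, then
#' the lower frame index, then the smaller start coordinate.
#'
#' @param seq nucleotide string.
#' @param min_aa minimum protein length (amino acids, stop excluded); spans
#'   shorter than this are discarded.  Default 50.
#' @param transcript_id optional id stored in the result.
#' @return `NULL` when no qualifying ORF exists, otherwise a list of class
#'   `orf_record` with fields `transcript_id`, `frame` (one of +1,+2,+3,
#'   -1,-2,-3), `start_nt`/`end_nt` (0-based half-open on the frame's source
#'   strand, i.e. the reverse complement for negative frames), `cds`
#'   (including the terminal stop codon when present) and `protein`.
#' @export
longest_orf <- function(seq, min_aa = 50, transcript_id = NA_character_) {
  seq <- chartr("U", "T", toupper(seq))
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  sources <- list(fwd = seq, rev = revcomp(seq))
  best <- NULL
  frames <- data.frame(strand = rep(c("fwd", "rev"), each = 3),
                       off = rep(0:2, 2),
                       label = c(1L, 2L, 3L, -1L, -2L, -3L))
  for (k in seq_len(nrow(frames))) {
    src <- sources[[frames$strand[k]]]
    off <- frames$off[k]
    n3 <- (nchar(src) - off) %/% 3L
    if (n3 < 1L) next
    starts <- off + seq(1L, by = 3L, length.out = n3)
    codons <- substring(src, starts, starts + 2L)
    span <- .best_span(codons)
    if (is.null(span) || span$len_aa < min_aa) next
    if (!is.null(best) && span$len_aa <= best$len_aa) next
    start_nt <- off + (span$atg - 1L) * 3L
    cds_len <- (span$len_aa + span$has_stop) * 3L
    best <- list(transcript_id = transcript_id,
                 frame = frames$label[k],
                 start_nt = start_nt,
                 end_nt = start_nt + cds_len,
                 cds = substr(src, start_nt + 1L, start_nt + cds_len),
                 protein = translate_cds(
                   substr(src, start_nt + 1L, start_nt + cds_len)),
                 len_aa = span$len_aa)
    class(best) <- "orf_record"
  }
  best
}

#' Write a table of ORF records
#'
#' @param orfs list of `orf_record` objects.
#' @param path output TSV (columns transcript_id, frame, start, end, aa_len;
#'   coordinates exported 1-based inclusive).
#' @export
write_orf_table <- function(orfs, path) {
  df <- do.call(rbind, lapply(orfs, function(o)
    data.frame(transcript_id = o$transcript_id, frame = o$frame,
               start = o$start_nt + 1L, end = o$end_nt,
               aa_len = o$len_aa, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.blosum62 <- function() {
  if (is.null(.ng_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ng_cache$blosum62 <- e$BLOSUM62
  }
  .ng_cache$blosum62
}

#' Pairwise protein alignment with affine gap costs
#'
#' Wraps [Biostrings::pairwiseAlignment()] under a BLOSUM62 matrix with gap
#' open 11 and gap extension 1 (a gap run of length L costs
#' `11 + L`).  `type = "global"` is a standard Needleman-Wunsch alignment;
#' `type = "overlap"` leaves end gaps free, which is what the locus
#' coalescer uses so that non-overlapping fragments of one gene are not
#' force-aligned across non-homologous regions.
#'
#' @param p_a,p_b amino-acid strings.
#' @param gap_open,gap_extend affine gap costs (positive).
#' @param substitution_matrix scoring matrix; default BLOSUM62.
#' @param type `"global"` or `"overlap"`.
#' @return list of class `protein_alignment`: gapped strings `a` and `b`,
#'   `a_start`/`b_start` (1-based index of the first aligned residue in each
#'   input), and `score`.
#' @export
align_proteins <- function(p_a, p_b, gap_open = 11, gap_extend = 1,
                           substitution_matrix = NULL,
                           type = c("global", "overlap")) {
  type <- match.arg(type)
  stopifnot(nzchar(p_a), nzchar(p_b))
  m <- substitution_matrix %||% .blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p_a), Biostrings::AAString(p_b),
    substitutionMatrix = m, gapOpening = gap_open,
    gapExtension = gap_extend, type = type)
  out <- list(a = as.character(Biostrings::pattern(pa)),
              b = as.character(Biostrings::subject(pa)),
              a_start = Biostrings::start(Biostrings::pattern(pa)),
              b_start = Biostrings::start(Biostrings::subject(pa)),
              score = Biostrings::score(pa),
              type = type)
  class(out) <- "protein_alignment"
  out
}

#' Map a protein alignment back onto its coding sequences
#'
#' @param aln a [align_proteins()] result whose inputs are the translations
#'   of `cds_a` and `cds_b`.
#' @param cds_a,cds_b coding sequences (terminal stop codon allowed).
#' @return list of class `codon_alignment`: `codons_a`, `codons_b`
#'   (character vectors, `NA` for gap columns) and `overlap_bp` (3 times the
#'   number of both-present columns).
#' @export
codon_alignment <- function(aln, cds_a, cds_b) {
  stopifnot(inherits(aln, "protein_alignment"))
  a_chars <- strsplit(aln$a, "")[[1]]
  b_chars <- strsplit(aln$b, "")[[1]]
  if (length(a_chars) != length(b_chars))
    stop("aligned strings differ in length", call. = FALSE)
  take <- function(chars, cds, start) {
    n_res <- sum(chars != "-")
    need <- 3L * (start - 1L + n_res)
    if (nchar(cds) < need)
      stop("cds too short for its aligned protein (need ", need,
           " nt, have ", nchar(cds), ")", call. = FALSE)
    idx <- start - 1L + cumsum(chars != "-")
    out <- substring(cds, (idx - 1L) * 3L + 1L, idx * 3L)
    out[chars == "-"] <- NA_character_
    out
  }
  codons_a <- take(a_chars, toupper(cds_a), aln$a_start)
  codons_b <- take(b_chars, toupper(cds_b), aln$b_start)
  out <- list(codons_a = codons_a, codons_b = codons_b,
              overlap_bp = 3L * sum(!is.na(codons_a) & !is.na(codons_b)))
  class(out) <- "codon_alignment"
  out
}
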