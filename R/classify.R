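.read_tsv_checked <- function(path, col_names, numeric_cols,
                              sep = "[ \t]+") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- strsplit(trimws(lines[keep]), sep)
  line_no <- which(keep)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != length(col_names))
      stop(sprintf("%s line %d: expected %d fields, found %d", path,
                   line_no[i], length(col_names), length(rows[[i]])),
           call. = FALSE)
    out[[i]] <- rows[[i]]
  }
  if (length(out) == 0L) {
    df <- as.data.frame(stats::setNames(
      rep(list(character()), length(col_names)), col_names),
      stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
    names(df) <- col_names
  }
  for (cl in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad) > 0L)
      stop(sprintf("%s line %d: non-numeric value '%s' in column %s", path,
                   line_no[bad[1]], df[[cl]][bad[1]], cl), call. = FALSE)
    df[[cl]] <- v
  }
  df
}

#' Parse a domain hit table
#'
#' Whitespace- or tab-delimited with columns `transcript_id`,
#' `domain_accession`, `evalue`, `score`; `#` comment lines are skipped.
#' Rows with accessions other than the APC/AAAP domains are retained; the
#' filtering happens in [select_candidates()].
#'
#' @param path input path.
#' @return data frame of domain hits.
#' @export
parse_domain_hits <- function(path) {
  df <- .read_tsv_checked(path,
                          c("transcript_id", "domain_accession",
                            "evalue", "score"),
                          c("evalue", "score"))
  if (any(df$evalue <= 0))
    stop("domain hit evalues must be positive in ", path, call. = FALSE)
  df
}

.BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Parse a BLAST tabular hit table with annotation columns
#'
#' Standard 12-column BLAST tabular output (`-outfmt 6`) plus two
#' annotation columns, `subject_family` (APC, AAAP or OTHER) and
#' `subject_taxon_group` (e.g. hemiptera, plant).  Tie rows are preserved
#' in input order.
#'
#' @param path input path.
#' @return data frame of BLAST hits.
#' @export
parse_blast_hits <- function(path) {
  cols <- c(.BLAST_COLS, "subject_family", "subject_taxon_group")
  df <- .read_tsv_checked(path, cols,
                          c("pident", "length", "mismatch", "gapopen",
                            "qstart", "qend", "sstart", "send",
                            "evalue", "bitscore"), sep = "\t")
  if (any(df$evalue <= 0) || any(df$bitscore < 0))
    stop("invalid evalue/bitscore in ", path, call. = FALSE)
  df
}

#' Parse a transcript-to-genome mapping table
#'
#' BLAST tabular (12 columns) where the subject is a genome scaffold.
#' Strand is derived from subject coordinate orientation and coordinates
#' are normalised so `start <= end` (1-based inclusive).
#'
#' @param path input path.
#' @return data frame with columns `transcript_id`, `scaffold`, `strand`,
#'   `start`, `end`, `evalue`, `bitscore`.
#' @export
parse_mapping_hits <- function(path) {
  df <- .read_tsv_checked(path, .BLAST_COLS,
                          c("pident", "length", "mismatch", "gapopen",
                            "qstart", "qend", "sstart", "send",
                            "evalue", "bitscore"), sep = "\t")
  data.frame(transcript_id = df$qseqid,
             scaffold = df$sseqid,
             strand = ifelse(df$sstart <= df$send, "+", "-"),
             start = pmin(df$sstart, df$send),
             end = pmax(df$sstart, df$send),
             evalue = df$evalue,
             bitscore = df$bitscore,
             stringsAsFactors = FALSE)
}

#' Configuration for candidate selection
#'
#' @param domain_evalue,blast_evalue inclusion thresholds (strict `<`) for
#'   the domain scan and the BLAST verification.  Default `1e-3`.
#' @param required_group taxon group the best BLAST hit must come from.
#' @param apc_accession,aaap_accession domain accessions defining the two
#'   transporter families.
#' @param min_orf_aa minimum ORF length for a candidate.
#' @param best_k how many top BLAST hits may satisfy the verification; the
#'   default 1 is the strict best-hit rule.
#' @param on_unknown_transcript `"warn"` (skip hit rows naming unknown
#'   transcripts with a warning) or `"error"`.
#' @return list of class `classify_config`.
#' @export
classify_config <- function(domain_evalue = 1e-3, blast_evalue = 1e-3,
                            required_group = "hemiptera",
                            apc_accession = "PF03024",
                            aaap_accession = "PF01490",
                            min_orf_aa = 50, best_k = 1,
                            on_unknown_transcript = c("warn", "error")) {
  stopifnot(domain_evalue > 0, blast_evalue > 0, min_orf_aa >= 1,
            best_k >= 1)
  cfg <- list(domain_evalue = domain_evalue, blast_evalue = blast_evalue,
              required_group = required_group,
              apc_accession = apc_accession,
              aaap_accession = aaap_accession,
              min_orf_aa = min_orf_aa, best_k = best_k,
              on_unknown_transcript = match.arg(on_unknown_transcript))
  class(cfg) <- "classify_config"
  cfg
}

.drop_unknown <- function(hits, id_col, known, what, cfg) {
  unknown <- !(hits[[id_col]] %in% known)
  if (any(unknown)) {
    msg <- sprintf("%d %s row(s) name transcripts absent from the input: %s",
                   sum(unknown), what,
                   paste(utils::head(unique(hits[[id_col]][unknown]), 5),
                         collapse = ", "))
    if (cfg$on_unknown_transcript == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  hits[!unknown, , drop = FALSE]
}

#' Select candidate APC/AAAP transcripts
#'
#' A transcript becomes a candidate when (i) it has a domain hit to the APC
#' or AAAP accession with evalue below the domain threshold, (ii) its best
#' BLAST hit (minimum evalue, ties broken by maximum bitscore then
#' lexicographic subject id) has evalue below the BLAST threshold, a
#' subject family of APC or AAAP, and the required subject taxon group, and
#' (iii) it carries a qualifying ORF.  The family label comes from the
#' lower-evalue qualifying domain hit.
#'
#' @param transcripts data frame from [read_transcript_fasta()].
#' @param domain_hits data frame from [parse_domain_hits()].
#' @param blast_hits data frame from [parse_blast_hits()].
#' @param cfg a [classify_config()].
#' @return data frame of class `aat_candidates`: transcript columns plus
#'   `family`, `protein`, `cds`, `orf_frame`, `orf_len_aa`.
#' @export
select_candidates <- function(transcripts, domain_hits, blast_hits,
                              cfg = classify_config()) {
  stopifnot(is.data.frame(transcripts))
  domain_hits <- .drop_unknown(domain_hits, "transcript_id",
                               transcripts$id, "domain-hit", cfg)
  blast_hits <- .drop_unknown(blast_hits, "qseqid",
                              transcripts$id, "BLAST-hit", cfg)

  fam_acc <- c(APC = cfg$apc_accession, AAAP = cfg$aaap_accession)
  dq <- domain_hits[domain_hits$domain_accession %in% fam_acc &
                      domain_hits$evalue < cfg$domain_evalue, , drop = FALSE]
  # per transcript keep the lower-evalue qualifying domain hit
  dq <- dq[order(dq$transcript_id, dq$evalue, -dq$score,
                 dq$domain_accession), , drop = FALSE]
  dq <- dq[!duplicated(dq$transcript_id), , drop = FALSE]
  family <- stats::setNames(names(fam_acc)[match(dq$domain_accession,
                                                 fam_acc)],
                            dq$transcript_id)

  ord <- order(blast_hits$qseqid, blast_hits$evalue, -blast_hits$bitscore,
               blast_hits$sseqid)
  bh <- blast_hits[ord, , drop = FALSE]
  pass_blast <- character()
  for (id in unique(bh$qseqid)) {
    top <- utils::head(bh[bh$qseqid == id, , drop = FALSE], cfg$best_k)
    ok <- top$evalue < cfg$blast_evalue &
      top$subject_family %in% c("APC", "AAAP") &
      top$subject_taxon_group == cfg$required_group
    if (any(ok)) pass_blast <- c(pass_blast, id)
  }

  ids <- sort(intersect(names(family), pass_blast))
  rows <- transcripts[match(ids, transcripts$id), , drop = FALSE]
  orfs <- lapply(seq_len(nrow(rows)), function(i)
    longest_orf(rows$seq[i], min_aa = cfg$min_orf_aa,
                transcript_id = rows$id[i]))
  no_orf <- vapply(orfs, is.null, TRUE)
  if (any(no_orf)) {
    warning("dropping ", sum(no_orf),
            " candidate(s) without a qualifying ORF: ",
            paste(rows$id[no_orf], collapse = ", "), call. = FALSE)
    rows <- rows[!no_orf, , drop = FALSE]
    orfs <- orfs[!no_orf]
  }
  out <- rows
  out$family <- unname(family[out$id])
  out$protein <- vapply(orfs, `[[`, "", "protein")
  out$cds <- vapply(orfs, `[[`, "", "cds")
  out$orf_frame <- vapply(orfs, `[[`, 0L, "frame")
  out$orf_len_aa <- vapply(orfs, `[[`, 0L, "len_aa")
  rownames(out) <- NULL
  class(out) <- c("aat_candidates", "data.frame")
  out
}

#' Write the candidate table
#'
#' @param candidates an `aat_candidates` data frame.
#' @param path output TSV.
#' @export
write_candidate_table <- function(candidates, path) {
  cols <- c("id", "taxon", "component_id", "family", "orf_frame",
            "orf_len_aa")
  utils::write.table(as.data.frame(candidates)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
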