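# Independent oracles used to freeze expected values.  They deliberately
# take different routes from the package code: Biostrings' genetic code
# table, naive exhaustive enumeration, and reference implementations from
# ape / stats / igraph.

ORACLE_CODE <- Biostrings::GENETIC_CODE

blosum62_mat <- local({
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  function() e$BLOSUM62
})

oracle_revcomp <- function(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

# Exhaustive enumeration of all ATG..stop spans in all six frames.
oracle_orf <- function(seq, min_aa) {
  seq <- toupper(seq)
  best <- NULL
  sources <- c(fwd = seq, rev = oracle_revcomp(seq))
  labels <- list(fwd = 1:3, rev = -(1:3))
  for (strand in c("fwd", "rev")) {
    src <- sources[[strand]]
    for (off in 0:2) {
      n3 <- (nchar(src) - off) %/% 3
      if (n3 < 1) next
      codons <- substring(src, off + 1 + 3 * (0:(n3 - 1)),
                          off + 3 + 3 * (0:(n3 - 1)))
      aas <- ifelse(grepl("[^ACGT]", codons), "?",
                    ORACLE_CODE[codons])
      for (i in which(codons == "ATG")) {
        j <- i
        ok <- TRUE
        while (j <= n3 && aas[j] != "*") {
          if (aas[j] == "?") {
            ok <- FALSE
            break
          }
          j <- j + 1
        }
        if (!ok) next
        len <- j - i               # protein length, stop excluded
        if (len < min_aa) next
        cand <- list(len_aa = len, frame = labels[[strand]][off + 1],
                     start_nt = off + (i - 1) * 3)
        better <- is.null(best) || len > best$len_aa
        if (better) best <- cand
      }
    }
  }
  best
}

# Brute-force optimal global alignment score by enumerating every
# alignment of two short strings and scoring affine gap runs directly.
oracle_align_score <- function(a, b, mat, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  score_cols <- function(cols) {
    s <- 0
    run <- ""  # current gap run: "", "a", or "b"
    for (col in cols) {
      if (col[1] == "-" || col[2] == "-") {
        side <- if (col[1] == "-") "a" else "b"
        s <- s - ext - if (run == side) 0 else open
        run <- side
      } else {
        s <- s + mat[col[1], col[2]]
        run <- ""
      }
    }
    s
  }
  best <- -Inf
  recurse <- function(i, j, cols) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score_cols(cols))
      return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      recurse(i + 1, j + 1, c(cols, list(c(a[i], b[j]))))
    if (i <= length(a))
      recurse(i + 1, j, c(cols, list(c(a[i], "-"))))
    if (j <= length(b))
      recurse(i, j + 1, c(cols, list(c("-", b[j]))))
  }
  recurse(1, 1, list())
  best
}

# NG86 per-codon sites by flat neighbour enumeration over Biostrings' code.
oracle_sites <- function(codon) {
  aa <- ORACLE_CODE[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    valid <- 0
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (ORACLE_CODE[[mut]] == "*") next
      valid <- valid + 1
      if (ORACLE_CODE[[mut]] == aa) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(oracle_perms(v[-i]), function(p) c(v[i], p))))
}

# NG86 pathway averaging by explicit enumeration of all step orderings.
oracle_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  walk <- function(order, allow_stop) {
    cur <- a
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (!allow_stop && ORACLE_CODE[[nxt]] == "*" && nxt != b)
        return(NULL)
      if (ORACLE_CODE[[cur]] == ORACLE_CODE[[nxt]] &&
          ORACLE_CODE[[cur]] != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- Filter(Negate(is.null),
                  lapply(oracle_perms(pos), walk, allow_stop = FALSE))
  if (length(paths) == 0)
    paths <- lapply(oracle_perms(pos), walk, allow_stop = TRUE)
  Reduce(`+`, paths) / length(paths)
}

SENSE_CODONS <- names(ORACLE_CODE)[ORACLE_CODE != "*"]

random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(c("ATG", sample(SENSE_CODONS, n_codons - 1, replace = TRUE)),
        collapse = "")
}

# Identity codon alignment for two equal-length CDS strings.
identity_codon_aln <- function(cds_a, cds_b) {
  aln <- list(a = translate_cds(cds_a), b = translate_cds(cds_b),
              a_start = 1L, b_start = 1L, score = NA, type = "global")
  class(aln) <- "protein_alignment"
  codon_alignment(aln, cds_a, cds_b)
}

# Build a minimal single-row candidate from a raw transcript sequence.
candidate_row <- function(id, seq, taxon = "tx", component = id,
                          family = "APC", min_aa = 30) {
  orf <- longest_orf(seq, min_aa = min_aa, transcript_id = id)
  stopifnot(!is.null(orf))
  df <- data.frame(id = id, taxon = taxon, component_id = component,
                   seq = seq, family = family, protein = orf$protein,
                   cds = orf$cds, orf_frame = orf$frame,
                   orf_len_aa = orf$len_aa, stringsAsFactors = FALSE)
  class(df) <- c("aat_candidates", "data.frame")
  df
}

as_candidates <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("aat_candidates", "data.frame")
  df
}

published_counts <- function() {
  read.delim(system.file("extdata", "aat_counts_published.tsv",
                         package = "aatcensus"),
             stringsAsFactors = FALSE)
}

synthetic_taxon_tree <- function() {
  read_newick(system.file("extdata", "aat_taxa_tree_synthetic.nwk",
                          package = "aatcensus"))
}
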