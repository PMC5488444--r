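#' Synonymous and nonsynonymous site counts for one codon
#'
#' Counts, by the Nei-Gojobori (1986) method, the fractional number of
#' synonymous (`S`) and nonsynonymous (`N`) sites in a single sense codon.
#' At each of the three positions the fraction of single-nucleotide changes
#' that preserve the encoded amino acid is computed; changes that would
#' create a stop codon are excluded from both numerator and denominator, so
#' `S + N == 3` always holds.
#'
#' @param codon a single sense codon (3 characters over `ACGT`).
#' @return named numeric vector `c(S =, N =)`.
#' @examples
#' ng86_sites("TTT")  # S = 1/3: only TTT->TTC is synonymous
#' ng86_sites("ATG")  # S = 0: Met has a single codon
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  if (!.is_valid_codon(codon))
    stop("'codon' must be a single 3-mer over ACGT, got: ",
         deparse(codon), call. = FALSE)
  aa <- .codon_aa(codon)
  if (aa == "*")
    stop("stop codon '", codon, "' has no defined site counts", call. = FALSE)
  s <- 0
  for (pos in 1:3) {
    alt <- setdiff(.NT, substr(codon, pos, pos))
    muts <- vapply(alt, function(n) {
      x <- codon
      substr(x, pos, pos) <- n
      x
    }, "")
    mut_aa <- GENETIC_CODE_TABLE[muts]
    keep <- mut_aa != "*"
    if (any(keep))
      s <- s + sum(mut_aa[keep] == aa) / sum(keep)
  }
  c(S = s, N = 3 - s)
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.permutations(v[-i]), function(p) c(v[i], p)))
  out
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' For codons differing at `d` positions, all `d!` orderings of the single
#' nucleotide steps are enumerated; each step is scored synonymous when the
#' amino acid is unchanged.  Pathways passing through a stop codon are
#' excluded from the average; if every pathway does, the average falls back
#' to all pathways with steps into or out of a stop counted nonsynonymous.
#'
#' @param codon_a,codon_b sense codons.
#' @return named numeric vector `c(Sd =, Nd =)`; `Sd + Nd` equals the
#'   Hamming distance of the pair.
#' @examples
#' ng86_differences("TTT", "TTC")  # (1, 0)
#' ng86_differences("TTT", "GTA")  # (0.5, 1.5)
#' @export
ng86_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a)
  codon_b <- toupper(codon_b)
  for (cd in c(codon_a, codon_b)) {
    if (!.is_valid_codon(cd))
      stop("invalid codon: ", deparse(cd), call. = FALSE)
    if (.codon_aa(cd) == "*")
      stop("stop codon '", cd, "' is not comparable", call. = FALSE)
  }
  pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(Sd = 0, Nd = 0))

  score_path <- function(order, allow_stops) {
    cur <- codon_a
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(codon_b, p, p)
      aa_cur <- .codon_aa(cur)
      aa_nxt <- .codon_aa(nxt)
      if (!allow_stops && (aa_nxt == "*" && nxt != codon_b))
        return(NULL)  # pathway passes through a stop
      if (aa_cur == aa_nxt && aa_cur != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }

  orders <- .permutations(pos)
  scored <- Filter(Negate(is.null),
                   lapply(orders, score_path, allow_stops = FALSE))
  if (length(scored) == 0L)
    scored <- lapply(orders, score_path, allow_stops = TRUE)
  avg <- Reduce(`+`, scored) / length(scored)
  c(Sd = avg[1], Nd = avg[2])
}

# Core Ks computation on two equal-length codon vectors (NA = gap).  Columns
# where either codon is missing, ambiguous, or a stop are skipped entirely
# (the cleandata convention).
.ks_core <- function(codons_a, codons_b, overlap_bp, min_overlap_bp) {
  stopifnot(length(codons_a) == length(codons_b))
  tab <- .ng_tables()
  sense <- rownames(tab$sites)
  ok <- !is.na(codons_a) & !is.na(codons_b) &
    codons_a %in% sense & codons_b %in% sense
  a <- codons_a[ok]
  b <- codons_b[ok]
  n_codons <- length(a)

  res <- list(S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
              pS = NA_real_, ks = NA_real_, n_codons = n_codons,
              overlap_bp = overlap_bp, status = "ok")
  class(res) <- "ks_result"

  if (overlap_bp < min_overlap_bp) {
    res$status <- "insufficient_overlap"
    return(res)
  }
  sites <- (tab$sites[a, , drop = FALSE] + tab$sites[b, , drop = FALSE]) / 2
  res$S <- sum(sites[, "S"])
  res$N <- sum(sites[, "N"])
  idx <- cbind(match(a, sense), match(b, sense))
  res$Sd <- sum(tab$sd[idx])
  res$Nd <- sum(tab$nd[idx])

  if (res$S <= 0) {
    if (res$Sd > 0) {
      res$status <- "saturated"
    } else {
      res$pS <- 0
      res$ks <- 0
    }
    return(res)
  }
  res$pS <- res$Sd / res$S
  if (res$pS >= 0.75) {
    res$status <- "saturated"
  } else {
    res$ks <- -0.75 * log(1 - 4 / 3 * res$pS)
  }
  res
}

#' Pairwise synonymous substitution rate (Ks) from a codon alignment
#'
#' Sums Nei-Gojobori site and difference counts over the aligned,
#' both-present, unambiguous, non-stop codon columns and applies the
#' Jukes-Cantor correction `ks = -(3/4) * log(1 - (4/3) * pS)`.
#'
#' @param codon_aln a [codon_alignment()] object.
#' @param min_overlap_bp minimum aligned overlap (both-present columns times
#'   3) for the pair to be Ks-comparable; pairs below it get status
#'   `"insufficient_overlap"` and an undefined `ks`.
#' @return object of class `ks_result`: list with `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `ks`, `n_codons`, `overlap_bp` and `status` (one of `"ok"`,
#'   `"saturated"`, `"insufficient_overlap"`).
#' @export
ks_pair <- function(codon_aln, min_overlap_bp = 50) {
  stopifnot(inherits(codon_aln, "codon_alignment"))
  .ks_core(codon_aln$codons_a, codon_aln$codons_b,
           overlap_bp = codon_aln$overlap_bp,
           min_overlap_bp = min_overlap_bp)
}

#' @export
print.ks_result <- function(x, ...) {
  cat("Ks result [", x$status, "]\n", sep = "")
  cat(sprintf("  codons compared: %d (overlap %d bp)\n",
              x$n_codons, x$overlap_bp))
  if (x$status == "ok")
    cat(sprintf("  S=%.2f N=%.2f Sd=%.2f Nd=%.2f pS=%.4f ks=%.4f\n",
                x$S, x$N, x$Sd, x$Nd, x$pS, x$ks))
  invisible(x)
}

#' Write a table of pairwise Ks results
#'
#' @param ks_table data frame with columns `taxon`, `id_a`, `id_b` and the
#'   `ks_result` fields.
#' @param path output TSV path.
#' @export
write_ks_table <- function(ks_table, path) {
  utils::write.table(ks_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
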