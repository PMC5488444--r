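# Standard genetic code (NCBI translation table 1), written out explicitly so
# the synonymous-site machinery does not depend on any other package's table.
GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

.NT <- c("A", "C", "G", "T")

.stop_codons <- function() names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]

.sense_codons <- function() names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]

.is_valid_codon <- function(codon) {
  is.character(codon) && length(codon) == 1L && !is.na(codon) &&
    nchar(codon) == 3L && !grepl("[^ACGT]", codon)
}

.codon_aa <- function(codon) unname(GENETIC_CODE_TABLE[codon])

#' Reverse complement of a nucleotide string
#'
#' @param seq character scalar over the DNA alphabet (ambiguity codes pass
#'   through complemented where defined, `N` maps to `N`).
#' @return character scalar.
#' @keywords internal
revcomp <- function(seq) {
  flipped <- chartr("ACGTUNRYSWKMacgtunryswkm",
                    "TGCAANYRSWMKtgcaanyrswmk", seq)
  vapply(flipped, function(s) intToUtf8(rev(utf8ToInt(s))), "",
         USE.NAMES = FALSE)
}

# Cached NG86 lookup tables keyed by sense codon: per-codon synonymous site
# counts, and pairwise pathway-averaged difference matrices.  Built on first
# use; the builders are the exported, individually tested functions.
.ng_cache <- new.env(parent = emptyenv())

.ng_tables <- function() {
  if (is.null(.ng_cache$sites)) {
    sense <- .sense_codons()
    sites <- t(vapply(sense, ng86_sites, c(S = 0, N = 0)))
    nd <- sd <- matrix(0, length(sense), length(sense),
                       dimnames = list(sense, sense))
    for (i in seq_along(sense)) {
      for (j in seq_len(i)) {
        d <- ng86_differences(sense[i], sense[j])
        sd[i, j] <- sd[j, i] <- d[["Sd"]]
        nd[i, j] <- nd[j, i] <- d[["Nd"]]
      }
    }
    .ng_cache$sites <- sites
    .ng_cache$sd <- sd
    .ng_cache$nd <- nd
    # single-nucleotide synonymous neighbours, used by the sequence simulator
    .ng_cache$syn_neighbors <- lapply(stats::setNames(sense, sense),
                                      function(cd) {
      nb <- unlist(lapply(1:3, function(pos) {
        alt <- setdiff(.NT, substr(cd, pos, pos))
        vapply(alt, function(n) {
          x <- cd
          substr(x, pos, pos) <- n
          x
        }, "")
      }), use.names = FALSE)
      nb[GENETIC_CODE_TABLE[nb] == GENETIC_CODE_TABLE[[cd]]]
    })
  }
  .ng_cache
}
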