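#' In-silico proteolytic digestion
#'
#' LysC cleaves C-terminal to lysine (K); trypsin C-terminal to lysine or
#' arginine (K/R). Returns every digestion product with at most `max_missed`
#' internal (missed) cleavage sites. With `semi = TRUE`, partially digested
#' products — every N- or C-terminal truncation of a fully cleaved product
#' that retains at least one enzymatic terminus — are returned as well.
#' Optionally, cleavage can be blocked when the following residue is
#' proline.
#'
#' @param protein Amino-acid sequence.
#' @param enzyme `"lysc"` or `"trypsin"`.
#' @param max_missed Maximum missed cleavages (default 0).
#' @param semi Include semi-specific (one enzymatic terminus) products.
#' @param block_proline Suppress cleavage before proline (default FALSE).
#' @param min_len Minimum product length reported (default 1).
#' @return Character vector of unique peptides, in order of first occurrence.
#' @export
digest_in_silico <- function(protein, enzyme = c("lysc", "trypsin"),
                             max_missed = 0L, semi = FALSE,
                             block_proline = FALSE, min_len = 1L) {
  enzyme <- match.arg(enzyme)
  stopifnot(max_missed >= 0L)
  aa <- strsplit(toupper(protein), "")[[1]]
  n <- length(aa)
  if (n == 0L) return(character())
  residues <- if (enzyme == "lysc") "K" else c("K", "R")
  cut_after <- which(aa %in% residues)
  cut_after <- cut_after[cut_after < n]
  if (block_proline) {
    cut_after <- cut_after[aa[cut_after + 1L] != "P"]
  }
  # fragment boundaries: 0, each cleavage point, n (0-based cut positions)
  bounds <- c(0L, cut_after, n)
  n_frag <- length(bounds) - 1L
  out <- character()
  for (i in seq_len(n_frag)) {
    for (j in i:min(n_frag, i + max_missed)) {
      full <- substr(protein, bounds[i] + 1L, bounds[j + 1L])
      out <- c(out, full)
      if (semi) {
        # both termini of `full` sit on a cleavage boundary (or protein
        # end); any one-sided truncation keeps one enzymatic terminus
        L <- nchar(full)
        if (L > 1L) {
          out <- c(out, substring(full, 2:L, L),
                   substring(full, 1L, 1:(L - 1L)))
        }
      }
    }
  }
  out <- unique(out)
  out[nchar(out) >= min_len]
}

#' Median digestion product length over a set of proteins
#'
#' @param proteins Character vector of protein sequences.
#' @inheritParams digest_in_silico
#' @return Median peptide length (numeric).
#' @export
digest_median_length <- function(proteins, enzyme = c("lysc", "trypsin"),
                                 max_missed = 0L) {
  enzyme <- match.arg(enzyme)
  lens <- unlist(lapply(proteins, function(p) {
    nchar(digest_in_silico(p, enzyme, max_missed))
  }))
  stats::median(lens)
}
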