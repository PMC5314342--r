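## Watson-Crick bookkeeping for the mixed PNA/RNA alphabet.

.wc_partner <- c(A = "T", T = "A", U = "A", G = "C", C = "G")
## canonical H-bond multiplicity of the pair a base participates in
.hbonds_of_pair <- c(A = 2L, T = 2L, U = 2L, G = 3L, C = 3L)
.base_alphabet <- names(.wc_partner)

#' Nucleobase Watson-Crick properties
#'
#' Look up the canonical Watson-Crick partner and the hydrogen-bond
#' multiplicity of the pair each base engages in.  T and U both pair A and
#' are treated identically (2 H-bonds); G:C pairs carry 3 H-bonds.
#'
#' @param code Character vector of single-letter base codes
#'   (one of `A`, `C`, `G`, `T`, `U`).
#' @return A data.frame with columns `code`, `wc_partner` and
#'   `hbond_count` (integer, 2 or 3).
#' @export
#' @examples
#' nucleobase_info(c("G", "A", "U"))
nucleobase_info <- function(code) {
  code <- toupper(as.character(code))
  bad <- setdiff(code, .base_alphabet)
  if (length(bad) > 0L)
    stop("invalid base code(s): ", paste(unique(bad), collapse = ", "))
  data.frame(code = code,
             wc_partner = unname(.wc_partner[code]),
             hbond_count = unname(.hbonds_of_pair[code]),
             stringsAsFactors = FALSE)
}

#' Watson-Crick partner of a base
#' @param code Character vector of base codes.
#' @return Character vector of partner codes (T/U both map to A; A maps
#'   to T — use [revcomp()] with `kind = "rna"` for a U-alphabet result).
#' @export
wc_partner <- function(code) nucleobase_info(code)$wc_partner

#' Hydrogen-bond multiplicity of the pair a base belongs to
#' @param code Character vector of base codes.
#' @return Integer vector (2 for A/T/U pairs, 3 for G/C pairs).
#' @export
hbond_count <- function(code) nucleobase_info(code)$hbond_count

.split_seq <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L)
    seq <- strsplit(seq, "", fixed = TRUE)[[1L]]
  toupper(as.character(seq))
}

#' Reverse complement of a base string
#'
#' @param seq Base string (single string or character vector of codes).
#' @param kind `"pna"` (T alphabet, default) or `"rna"` (U alphabet).
#' @return Single string, the reverse complement.
#' @export
#' @examples
#' revcomp("GAACTC")            # "GAGTTC"
#' revcomp("GAACTC", "rna")     # "GAGUUC"
revcomp <- function(seq, kind = c("pna", "rna")) {
  kind <- match.arg(kind)
  s <- rev(wc_partner(.split_seq(seq)))
  if (kind == "rna") s[s == "T"] <- "U" else s[s == "U"] <- "T"
  paste(s, collapse = "")
}

.is_wc_pair <- function(a, b) {
  norm <- function(x) ifelse(x == "U", "T", x)
  norm(.wc_partner[a]) == norm(b)
}
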