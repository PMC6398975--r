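# Autosomal allele state machine.
#
# An allele at the drive locus is one of:
#   * drive (G)     -- the gene-drive cassette itself;
#   * wildtype (W)  -- >= 1 susceptible gRNA target sites remaining;
#   * resistant (R) -- 0 susceptible sites remaining (can never be cut or
#                      converted, i.e. drive-resistant).
# W and R alleles additionally record whether an NHEJ deletion of sequence
# between two cut sites ever occurred, and whether the host gene is still
# functional (only consulted under coding placement, where inheriting a
# non-functional allele is embryonic-lethal).

#' Construct an allele
#'
#' @param kind `"wildtype"`, `"resistant"` or `"drive"`.
#' @param sites Remaining susceptible gRNA target sites (ignored for drive
#'   alleles, conventionally 0).
#' @param deletion Has an intervening-sequence deletion occurred?
#' @param functional Is the host gene functional? Always `TRUE` for drive and
#'   pristine wildtype alleles.
#' @return An object of class `allele`.
#' @examples
#' allele("wildtype", sites = 3)
#' allele("drive")
#' @export
allele <- function(kind = c("wildtype", "resistant", "drive"), sites = NULL,
                   deletion = FALSE, functional = TRUE) {
  kind <- match.arg(kind)
  if (kind == "drive") {
    sites <- 0L; deletion <- FALSE; functional <- TRUE
  }
  if (kind == "wildtype") {
    if (is.null(sites)) stop("wildtype alleles need `sites`", call. = FALSE)
    if (sites < 1L) stop("wildtype alleles have >= 1 susceptible site",
                         call. = FALSE)
  }
  if (kind == "resistant" && is.null(sites)) sites <- 0L
  structure(list(kind = kind, sites = as.integer(sites),
                 deletion = isTRUE(deletion), functional = isTRUE(functional)),
            class = "allele")
}

#' @export
print.allele <- function(x, ...) {
  cat(sprintf("<allele> %s%s sites=%d%s%s\n", allele_letter(x),
              if (x$kind == "drive") " (drive)" else "",
              x$sites, if (x$deletion) " del" else "",
              if (!x$functional) " nonfunctional" else ""))
  invisible(x)
}

is_drive <- function(a) a$kind == "drive"

#' Single-letter allele code
#'
#' Classifies an allele as `"W"` (wildtype, still cuttable), `"R"`
#' (resistant) or `"G"` (gene drive), the codes used in all outputs.
#'
#' @param a An [allele()].
#' @return A single character.
#' @export
allele_letter <- function(a) {
  if (a$kind == "drive") return("G")
  if (a$sites >= 1L) "W" else "R"
}

# Integer codes used by the compiled engine. Only viable (functional) W/R
# states and the drive allele can exist in a living individual:
#   0            -> drive (G)
#   1 + 2*s + d  -> W/R allele with s susceptible sites, deletion flag d
allele_code <- function(a) {
  if (a$kind == "drive") return(0L)
  1L + 2L * a$sites + as.integer(a$deletion)
}

allele_from_code <- function(code) {
  if (code == 0L) return(allele("drive"))
  s <- (code - 1L) %/% 2L
  del <- (code - 1L) %% 2L == 1L
  allele(if (s >= 1L) "wildtype" else "resistant", sites = s, deletion = del)
}

# letter ("W"/"R"/"G") from an engine code, vectorised
letter_from_code <- function(code) {
  ifelse(code == 0L, "G", ifelse(code >= 3L, "W", "R"))
}

# unordered autosome genotype label from two engine codes
genotype_label <- function(c1, c2) {
  l <- vapply(seq_along(c1), function(i)
    paste(sort(c(letter_from_code(c1[i]), letter_from_code(c2[i])),
               decreasing = TRUE), collapse = ""), "")
  # canonical order: WW WG GG WR GR RR
  map <- c(WW = "WW", WG = "WG", GW = "WG", GG = "GG", WR = "WR", RW = "WR",
           RG = "GR", GR = "GR", RR = "RR")
  unname(map[l])
}
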